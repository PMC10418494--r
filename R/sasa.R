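# Solvent-accessible surface area (Shrake-Rupley), NIS and BSA ---------------

# Element van der Waals radii (Angstrom), Bondi set; SE/FE cover the odd
# selenomethionine or heme iron encountered in otherwise-protein entries.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, FE = 1.80, ZN = 1.39, MG = 1.73, CA = 2.31)

# Maximum accessible surface areas (A^2) of residue X in an extended
# Gly-X-Gly / Ala-X-Ala context, used as the reference for relative SASA.
.max_asa <- list(
  naccess = c(
    ALA = 107.95, ARG = 238.76, ASN = 143.94, ASP = 140.39, CYS = 134.28,
    GLN = 178.50, GLU = 172.25, GLY = 80.10, HIS = 182.88, ILE = 175.12,
    LEU = 178.63, LYS = 200.81, MET = 194.15, PHE = 199.48, PRO = 136.13,
    SER = 116.50, THR = 139.27, TRP = 249.36, TYR = 212.76, VAL = 151.44
  ),
  tien = c(
    ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
  )
)

# Deterministic quasi-uniform unit sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

atom_radii <- function(elesy) {
  r <- .vdw_radii[toupper(elesy)]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elesy[is.na(r)]), collapse = ", "), call. = FALSE)
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by rolling a probe sphere over the heavy atoms: each atom
#' is covered with a deterministic golden-spiral lattice of `n_points` test
#' points at radius `r_vdw + probe`; a point is accessible when it lies
#' outside every neighbouring atom's expanded sphere. Atom areas are summed
#' per residue and expressed relative to an extended-context maximum per
#' residue type.
#'
#' @param structure An `ab_structure` (or `complex_partition`, in which case
#'   its retained structure is used).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960).
#' @param ref_table `"naccess"` (default) or `"tien"`: maximum-ASA reference
#'   used for relative SASA.
#' @return A `sasa_result`: list with `atoms` (per-atom SASA), `residues`
#'   (per-residue `sasa` and `rel_sasa` in percent; `rel_sasa` is `NA` for
#'   non-standard residues), `total`, `probe`, `n_points`, `ref_table`.
#' @export
compute_sasa <- function(structure, probe = 1.4, n_points = 960,
                         ref_table = c("naccess", "tien")) {
  ref_table <- match.arg(ref_table)
  if (inherits(structure, "complex_partition")) structure <- structure$structure
  stopifnot(inherits(structure, "ab_structure"))
  a <- structure$atoms
  if (!nrow(a)) stop("empty structure", call. = FALSE)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- atom_radii(a$elesy) + probe
  pts <- sphere_points(n_points)
  n <- nrow(xyz)

  nb <- neighbor_list(xyz, rad)
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    js <- nb[[i]]
    acc <- rep(TRUE, n_points)
    for (j in js) {
      dx <- p[, 1] - xyz[j, 1]; dy <- p[, 2] - xyz[j, 2]; dz <- p[, 3] - xyz[j, 3]
      acc <- acc & (dx * dx + dy * dy + dz * dz >= rad[j]^2)
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }

  key <- residue_key(a)
  res <- structure_residues(structure)
  res$sasa <- as.numeric(tapply(area, key, sum)[paste(res$chain, res$resno,
                                                      res$ins, sep = "|")])
  maxasa <- .max_asa[[ref_table]][toupper(res$resid)]
  res$rel_sasa <- 100 * res$sasa / unname(maxasa)

  out <- list(atoms = cbind(a[, c("chain", "resno", "ins", "resid", "elety")],
                            sasa = area),
              residues = res, total = sum(area), probe = probe,
              n_points = n_points, ref_table = ref_table)
  class(out) <- "sasa_result"
  out
}

# atoms j whose expanded sphere can intersect atom i's expanded sphere
neighbor_list <- function(xyz, rad) {
  n <- nrow(xyz)
  cutoff <- 2 * max(rad)
  cell <- cutoff
  ix <- floor(xyz / cell)
  keys <- paste(ix[, 1], ix[, 2], ix[, 3])
  cells <- split(seq_len(n), keys)
  coords <- do.call(rbind, strsplit(names(cells), " "))
  storage.mode(coords) <- "integer"
  lookup <- new.env(parent = emptyenv(), size = length(cells))
  for (k in seq_along(cells)) assign(names(cells)[k], cells[[k]], envir = lookup)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", n)
  for (ci in seq_along(cells)) {
    base <- coords[ci, ]
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      key <- paste(base[1] + offs[o, 1], base[2] + offs[o, 2], base[3] + offs[o, 3])
      hit <- lookup[[key]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    for (i in cells[[ci]]) {
      d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
        (xyz[cand, 3] - xyz[i, 3])^2
      js <- cand[d2 <= (rad[i] + rad[cand])^2 & cand != i]
      # test nearest occluders first so fully buried atoms exit early
      out[[i]] <- js[order(d2[match(js, cand)])]
    }
  }
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("SASA:", format(round(x$total, 1), big.mark = ","), "A^2 over",
      nrow(x$residues), "residues (probe", x$probe, "A,", x$n_points,
      "points/atom,", x$ref_table, "reference)\n")
  invisible(x)
}

#' Non-interacting surface composition
#'
#' NIS residues are the solvent-exposed residues of the complex (relative
#' SASA at or above `threshold_pct`) that are not part of the interface, i.e.
#' appear in no contact pair. The three percentages are the class shares of
#' the NIS residue count and sum to 100.
#'
#' @param partition A `complex_partition`.
#' @param sasa_complex Optional `sasa_result` computed on the full complex
#'   (computed here when `NULL`).
#' @param threshold_pct Relative-SASA threshold in percent (default 5).
#' @param scheme Residue-character table; default `"nis_scheme"`
#'   (histidine charged), `"ic_scheme"` matches the contact table.
#' @param contacts Optional `contact_set` defining interface residues
#'   (computed at the 5.5 A default cutoff when `NULL`).
#' @return A `nis_result`: list with `nis_charged_pct`, `nis_polar_pct`,
#'   `nis_apolar_pct`, class `counts`, `n_nis`, `threshold_pct`, `scheme`.
#' @export
nis_percentages <- function(partition, sasa_complex = NULL, threshold_pct = 5,
                            scheme = c("nis_scheme", "ic_scheme"),
                            contacts = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(partition, "complex_partition"))
  if (is.null(sasa_complex)) sasa_complex <- compute_sasa(partition)
  if (is.null(contacts)) contacts <- find_contacts(partition)

  res <- sasa_complex$residues
  iface <- unique(c(paste(contacts$chain_a, contacts$resno_a, contacts$ins_a,
                          sep = "|"),
                    paste(contacts$chain_b, contacts$resno_b, contacts$ins_b,
                          sep = "|")))
  key <- paste(res$chain, res$resno, res$ins, sep = "|")
  surface <- !is.na(res$rel_sasa) & res$rel_sasa >= threshold_pct
  nis <- surface & !(key %in% iface)

  cls <- classify_residue(res$resid[nis], scheme, on_unknown = "na")
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " non-standard NIS residue(s) skipped",
            call. = FALSE)
    cls <- cls[!is.na(cls)]
  }
  n_nis <- length(cls)
  if (!n_nis) stop("no classifiable NIS residues (degenerate surface)",
                   call. = FALSE)
  counts <- table(factor(cls, levels = c("charged", "polar", "apolar")))
  pct <- 100 * as.numeric(counts) / n_nis
  out <- list(nis_charged_pct = pct[1], nis_polar_pct = pct[2],
              nis_apolar_pct = pct[3],
              counts = stats::setNames(as.integer(counts), names(counts)),
              n_nis = n_nis, threshold_pct = threshold_pct, scheme = scheme)
  class(out) <- "nis_result"
  out
}

#' @export
print.nis_result <- function(x, ...) {
  cat(sprintf(
    "NIS composition (%d residues, threshold %g%%, %s):\n  charged %.1f%%  polar %.1f%%  apolar %.1f%%\n",
    x$n_nis, x$threshold_pct, x$scheme,
    x$nis_charged_pct, x$nis_polar_pct, x$nis_apolar_pct))
  invisible(x)
}

#' Buried surface area of an interface
#'
#' BSA = SASA(side A alone) + SASA(side B alone) - SASA(complex), summed over
#' both sides (the total, not per-side, convention; `halved = TRUE` divides
#' by two). Interface residues are those whose SASA decreases upon complex
#' formation.
#'
#' @param partition A `complex_partition`.
#' @param probe,n_points,ref_table Passed to [compute_sasa()].
#' @param halved Report BSA/2 instead of the total (default `FALSE`).
#' @return An `interface_summary`: list with `bsa` (A^2), per-side interface
#'   residue tables, and the three SASA totals.
#' @export
buried_surface_area <- function(partition, probe = 1.4, n_points = 960,
                                ref_table = "naccess", halved = FALSE) {
  stopifnot(inherits(partition, "complex_partition"))
  s_ab <- compute_sasa(partition, probe, n_points, ref_table)
  str_a <- new_ab_structure(side_atoms(partition, "a"), "side A")
  str_b <- new_ab_structure(side_atoms(partition, "b"), "side B")
  s_a <- compute_sasa(str_a, probe, n_points, ref_table)
  s_b <- compute_sasa(str_b, probe, n_points, ref_table)

  bsa <- s_a$total + s_b$total - s_ab$total
  if (halved) bsa <- bsa / 2

  delta <- function(free, cx_res) {
    key_free <- paste(free$chain, free$resno, free$ins, sep = "|")
    key_cx <- paste(cx_res$chain, cx_res$resno, cx_res$ins, sep = "|")
    d <- free$sasa - cx_res$sasa[match(key_free, key_cx)]
    free[which(d > 0.1), c("chain", "resno", "ins", "resid")]
  }
  out <- list(bsa = bsa, halved = halved,
              interface_a = delta(s_a$residues, s_ab$residues),
              interface_b = delta(s_b$residues, s_ab$residues),
              sasa_complex = s_ab$total, sasa_a = s_a$total, sasa_b = s_b$total)
  class(out) <- "interface_summary"
  out
}

#' @export
print.interface_summary <- function(x, ...) {
  cat(sprintf("Buried surface area: %.1f A^2%s (%d + %d interface residues)\n",
              x$bsa, if (x$halved) " (halved convention)" else "",
              nrow(x$interface_a), nrow(x$interface_b)))
  invisible(x)
}

#' Export per-residue SASA as CSV
#' @param sasa A `sasa_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sasa_csv <- function(sasa, path) {
  utils::write.csv(sasa$residues, path, row.names = FALSE)
  invisible(path)
}
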