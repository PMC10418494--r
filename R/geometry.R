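# Rigid-body superposition, antigen grafting and clash analysis ---------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising
#' ||R (mobile - centroid_m) + centroid_r - reference||^2 over paired
#' coordinates. The rotation is constrained to det(R) = +1: a chirally
#' inverted point set is *not* mirrored, it simply fits with a non-zero
#' residual.
#'
#' @param mobile_coords,reference_coords n x 3 coordinate matrices with
#'   paired rows, n >= 3, not collinear.
#' @return A `superposition`: list with `rotation` (3 x 3), `translation`
#'   (length 3; the transform is `x %*% t(rotation) + translation`), `rmsd`
#'   (Angstrom, after fitting) and `n_atoms`.
#' @export
superpose <- function(mobile_coords, reference_coords) {
  m <- as.matrix(mobile_coords); r <- as.matrix(reference_coords)
  if (ncol(m) != 3 || ncol(r) != 3 || nrow(m) != nrow(r))
    stop("coordinate sets must be paired n x 3 matrices", call. = FALSE)
  n <- nrow(m)
  if (n < 3) stop("at least 3 paired points are required", call. = FALSE)
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  if (any(svd(mc)$d[2] < 1e-9, svd(rc)$d[2] < 1e-9))
    stop("degenerate (collinear) point set", call. = FALSE)
  h <- crossprod(mc, rc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- mc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  out <- list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
              rmsd = rmsd, n_atoms = n)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition: %d paired atoms, RMSD %.4g A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param x An n x 3 matrix or an `ab_structure`.
#' @param sup A `superposition` (or list with `rotation`, `translation`).
#' @return Object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, sup) {
  tf <- function(xyz) sweep(xyz %*% t(sup$rotation), 2, sup$translation, "+")
  if (inherits(x, "ab_structure")) {
    xyz <- tf(as.matrix(x$atoms[, c("x", "y", "z")]))
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    x
  } else tf(as.matrix(x))
}

backbone_coords <- function(atoms) {
  bb <- atoms[atoms$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  bb[order(bb$resno, bb$ins, match(bb$elety, c("N", "CA", "C", "O"))), ,
     drop = FALSE]
}

#' Graft a bound antigen onto the free Fab of a 1:1 complex
#'
#' Implements the rigid stoichiometry construction: the substructure formed
#' by the bound antigen and its Fab light chain is copied, its light-chain
#' backbone (N, CA, C, O of residues common by number) is superposed onto
#' the free Fab's light chain, and the transformed antigen copy is merged
#' into the structure, yielding a virtual 2:1 complex. No minimisation is
#' performed afterwards - the procedure is deliberately rigid, so steric
#' interpenetration of the two antigens is preserved as evidence.
#'
#' @param complex_1_1 An `ab_structure` holding the 1:1 complex within a
#'   whole antibody (both light chains present).
#' @param bound_antigen_chain Chain id of the bound antigen.
#' @param bound_lightchain_chain Chain id of the light chain next to the
#'   bound antigen.
#' @param free_lightchain_chain Chain id of the free Fab's light chain.
#' @param new_chain_id Chain id given to the grafted antigen copy (default
#'   `"Z"`).
#' @return A `graft_result`: list with `structure` (the merged virtual 2:1
#'   complex; the input coordinates are untouched), `superposition` (the
#'   light-chain fit, whose `rmsd` measures how alike the two light chains
#'   are) and `new_chain`.
#' @export
graft_second_antigen <- function(complex_1_1, bound_antigen_chain,
                                 bound_lightchain_chain,
                                 free_lightchain_chain,
                                 new_chain_id = "Z") {
  st <- complex_1_1
  stopifnot(inherits(st, "ab_structure"))
  chains <- unique(st$atoms$chain)
  for (ch in c(bound_antigen_chain, bound_lightchain_chain,
               free_lightchain_chain))
    if (!ch %in% chains) stop("chain ", ch, " not present", call. = FALSE)
  if (new_chain_id %in% chains)
    stop("new chain id ", new_chain_id, " already in use", call. = FALSE)

  bl <- backbone_coords(st$atoms[st$atoms$chain == bound_lightchain_chain, ])
  fl <- backbone_coords(st$atoms[st$atoms$chain == free_lightchain_chain, ])
  key <- function(a) paste(a$resno, a$ins, a$elety)
  common <- intersect(key(bl), key(fl))
  if (length(common) < 3)
    stop("light chains share no mappable backbone residues", call. = FALSE)
  bl <- bl[match(common, key(bl)), ]
  fl <- fl[match(common, key(fl)), ]
  sup <- superpose(as.matrix(bl[, c("x", "y", "z")]),
                   as.matrix(fl[, c("x", "y", "z")]))

  antigen <- st$atoms[st$atoms$chain == bound_antigen_chain, , drop = FALSE]
  xyz <- apply_transform(as.matrix(antigen[, c("x", "y", "z")]), sup)
  antigen$x <- xyz[, 1]; antigen$y <- xyz[, 2]; antigen$z <- xyz[, 3]
  antigen$chain <- new_chain_id

  merged <- new_ab_structure(rbind(st$atoms, antigen),
                             source = paste0(st$source, "+graft"))
  out <- list(structure = merged, superposition = sup,
              new_chain = new_chain_id)
  class(out) <- "graft_result"
  out
}

#' @export
print.graft_result <- function(x, ...) {
  cat("Virtual 2:1 complex: grafted antigen as chain", x$new_chain,
      sprintf("(light-chain fit RMSD %.3g A)\n", x$superposition$rmsd))
  print(x$structure)
  invisible(x)
}

#' Steric clash report between two chain sets
#'
#' Counts heavy-atom pairs across the two sets closer than `cutoff` and
#' reports the minimum interatomic distance and the fraction of side-A atoms
#' having any side-B atom within the cutoff (the overlap fraction).
#'
#' @param structure An `ab_structure`.
#' @param chains_A,chains_B Non-empty, disjoint chain-id vectors.
#' @param cutoff Clash distance in Angstrom (default 2.5, a severe-clash
#'   convention).
#' @return A `clash_report`: list with `n_atom_pairs_below_cutoff`,
#'   `min_distance`, `overlap_fraction`, `cutoff`, atom counts.
#' @export
clash_report <- function(structure, chains_A, chains_B, cutoff = 2.5) {
  stopifnot(inherits(structure, "ab_structure"))
  a <- structure$atoms[structure$atoms$chain %in% chains_A, , drop = FALSE]
  b <- structure$atoms[structure$atoms$chain %in% chains_B, , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    stop("both chain sets must contain atoms", call. = FALSE)
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  n_pairs <- 0L; min_d2 <- Inf
  a_hit <- logical(nrow(xa))
  chunk <- max(1L, floor(2e6 / nrow(xb)))
  for (start in seq(1L, nrow(xa), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(xa))
    d2 <- outer(rowSums(xa[idx, , drop = FALSE]^2), rowSums(xb^2), "+") -
      2 * xa[idx, , drop = FALSE] %*% t(xb)
    d2[d2 < 0] <- 0
    hit <- d2 < cutoff^2
    n_pairs <- n_pairs + sum(hit)
    a_hit[idx] <- a_hit[idx] | rowSums(hit) > 0
    min_d2 <- min(min_d2, min(d2))
  }
  out <- list(n_atom_pairs_below_cutoff = n_pairs,
              min_distance = sqrt(min_d2),
              overlap_fraction = mean(a_hit), cutoff = cutoff,
              n_atoms_A = nrow(xa), n_atoms_B = nrow(xb))
  class(out) <- "clash_report"
  out
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf(
    "Clash report (cutoff %.2f A): %d atom pair(s), min distance %.2f A, overlap fraction %.2f\n",
    x$cutoff, x$n_atom_pairs_below_cutoff, x$min_distance,
    x$overlap_fraction))
  invisible(x)
}
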