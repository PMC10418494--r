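# Residue-character tables ---------------------------------------------------

# Contact-classification table: charged (E,D,K,R), polar (C,H,N,Q,S,T,W),
# apolar (A,F,G,I,L,V,M,P,Y). The NIS variant moves histidine into the
# charged class, following the historical non-interacting-surface protocol.
.aa3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.class_tables <- list(
  ic_scheme = c(
    E = "charged", D = "charged", K = "charged", R = "charged",
    C = "polar", H = "polar", N = "polar", Q = "polar", S = "polar",
    T = "polar", W = "polar",
    A = "apolar", F = "apolar", G = "apolar", I = "apolar", L = "apolar",
    V = "apolar", M = "apolar", P = "apolar", Y = "apolar"
  ),
  nis_scheme = c(
    E = "charged", D = "charged", K = "charged", R = "charged", H = "charged",
    C = "polar", N = "polar", Q = "polar", S = "polar", T = "polar",
    W = "polar",
    A = "apolar", F = "apolar", G = "apolar", I = "apolar", L = "apolar",
    V = "apolar", M = "apolar", P = "apolar", Y = "apolar"
  )
)

#' Classify a residue by physicochemical character
#'
#' Maps a standard amino-acid residue to one of `"charged"`, `"polar"` or
#' `"apolar"`. Two classification tables are provided: the contact table
#' (`"ic_scheme"`: charged = E,D,K,R; polar = C,H,N,Q,S,T,W; apolar =
#' A,F,G,I,L,V,M,P,Y) used to type interfacial contacts, and a
#' non-interacting-surface variant (`"nis_scheme"`) identical except that
#' histidine is counted as charged.
#'
#' @param residue_name Three-letter (e.g. `"GLU"`) or one-letter (`"E"`)
#'   residue code; vectorised.
#' @param scheme `"ic_scheme"` (default) or `"nis_scheme"`.
#' @param on_unknown `"error"` (default) or `"na"`: what to do with
#'   non-standard residues.
#' @return Character vector of classes.
#' @examples
#' classify_residue("GLU")            # "charged"
#' classify_residue("TYR")            # "apolar"
#' classify_residue("HIS", "nis_scheme")  # "charged"
#' @export
classify_residue <- function(residue_name,
                             scheme = c("ic_scheme", "nis_scheme"),
                             on_unknown = c("error", "na")) {
  scheme <- match.arg(scheme)
  on_unknown <- match.arg(on_unknown)
  code <- toupper(residue_name)
  long <- nchar(code) > 1L
  code[long] <- unname(.aa3[code[long]])
  cls <- unname(.class_tables[[scheme]][code])
  if (anyNA(cls) && on_unknown == "error") {
    bad <- unique(residue_name[is.na(cls)])
    stop("cannot classify residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cls
}

.is_standard_aa <- function(resid3) toupper(resid3) %in% names(.aa3)

# Structure container ---------------------------------------------------------

new_ab_structure <- function(atoms, source = "unknown") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "ins", "resid", "elety", "elesy", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing)) stop("atoms table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure", call. = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "ab_structure")
}

residue_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")

#' @export
print.ab_structure <- function(x, ...) {
  a <- x$atoms
  cat("Protein structure (heavy atoms):", nrow(a), "atoms,",
      length(unique(residue_key(a))), "residues,",
      length(unique(a$chain)), "chain(s)",
      paste0("[", paste(sort(unique(a$chain)), collapse = ","), "]"), "\n")
  invisible(x)
}

#' Chains of a structure
#' @param structure An `ab_structure`.
#' @return Character vector of chain identifiers.
#' @export
structure_chains <- function(structure) sort(unique(structure$atoms$chain))

#' Per-residue table of a structure
#'
#' @param structure An `ab_structure`.
#' @return data.frame with one row per residue: chain, resno, ins, resid.
#' @export
structure_residues <- function(structure) {
  a <- structure$atoms
  key <- residue_key(a)
  idx <- !duplicated(key)
  data.frame(chain = a$chain[idx], resno = a$resno[idx], ins = a$ins[idx],
             resid = a$resid[idx], stringsAsFactors = FALSE)
}

# Reading ----------------------------------------------------------------------

#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses a structure file (or raw PDB text) into a heavy-atom table.
#' Hydrogens, waters and hetero ligands are removed at load; alternate
#' locations are resolved by keeping the highest-occupancy conformer (ties
#' broken alphabetically by altloc identifier), so every descriptor downstream
#' sees a single deterministic conformer.
#'
#' @param path_or_text Path to a `.pdb`/`.ent`/`.cif` file, or a character
#'   string containing PDB-format records.
#' @param model_index 1-based model to extract (default 1; crystal structures
#'   are single-model).
#' @return An `ab_structure`: list with an `atoms` data.frame
#'   (chain, resno, ins, resid, elety, elesy, x, y, z in Angstrom).
#' @export
read_structure <- function(path_or_text, model_index = 1L) {
  is_path <- length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
    file.exists(path_or_text)
  if (!is_path) {
    txt <- paste(path_or_text, collapse = "\n")
    if (!grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK|CRYST)", txt) &&
        !grepl("\n(ATOM|HETATM)", txt))
      stop("input is neither an existing file nor PDB-format text",
           call. = FALSE)
    tmp <- tempfile(fileext = ".pdb")
    writeLines(strsplit(txt, "\n")[[1]], tmp)
    on.exit(unlink(tmp))
    path <- tmp
  } else path <- path_or_text

  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- if (is_cif) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    multi <- model_index > 1L
    p <- tryCatch(bio3d::read.pdb(path, multi = multi, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("cannot parse structure: ",
                                           conditionMessage(e), call. = FALSE))
    p
  }
  at <- pdb$atom
  if (model_index > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_index)
      stop("model ", model_index, " not present", call. = FALSE)
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  ins_raw <- if ("insert" %in% names(at)) at$insert else rep(NA_character_, nrow(at))
  at$ins <- ifelse(is.na(ins_raw) | ins_raw == "", "", ins_raw)
  at$chain[is.na(at$chain)] <- " "

  keep <- at$type == "ATOM"
  elesy <- toupper(trimws(at$elesy))
  # fall back to first letter of the atom name when the element field is blank
  blank <- is.na(elesy) | elesy == ""
  elesy[blank] <- substr(gsub("^[0-9 ]+", "", toupper(at$elety[blank])), 1, 1)
  keep <- keep & !(elesy %in% c("H", "D"))
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  elesy <- elesy[keep]
  if (!nrow(at)) stop("structure contains no heavy protein atoms",
                      call. = FALSE)

  # altloc resolution: keep highest occupancy, ties -> first alphabetically
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  akey <- paste(at$chain, at$resno, at$ins, at$elety, sep = "|")
  ord <- order(akey, -occ, alt)
  at <- at[ord, , drop = FALSE]; elesy <- elesy[ord]
  dup <- duplicated(paste(at$chain, at$resno, at$ins, at$elety, sep = "|"))
  at <- at[!dup, , drop = FALSE]; elesy <- elesy[!dup]
  # restore file order
  ord2 <- order(as.numeric(rownames(at)))
  at <- at[ord2, , drop = FALSE]; elesy <- elesy[ord2]

  atoms <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    ins = as.character(at$ins), resid = as.character(at$resid),
    elety = as.character(at$elety), elesy = elesy,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  )
  new_ab_structure(atoms, source = if (is_path) path_or_text else "text")
}

#' Write a structure as a PDB file
#'
#' @param structure An `ab_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- sprintf(
    "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000L,
    formatC(ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
            width = -4),
    "", formatC(a$resid, width = 3), a$chain, a$resno %% 10000L,
    ifelse(a$ins == "", " ", a$ins),
    a$x, a$y, a$z, 1, 0, a$elesy
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Fetch a PDB entry from the RCSB archive
#'
#' Downloads `<id>.pdb` into `destdir` (skipped when already present).
#' Requires network access; offline use should point [read_structure()] at a
#' local copy instead.
#'
#' @param id Four-character PDB accession (e.g. `"1N8Z"`).
#' @param destdir Download directory (default `tempdir()`).
#' @return Path to the downloaded file.
#' @export
fetch_pdb <- function(id, destdir = tempdir()) {
  id <- toupper(id)
  if (!grepl("^[0-9][A-Z0-9]{3}$", id))
    stop("not a PDB accession: ", id, call. = FALSE)
  dest <- file.path(destdir, paste0(id, ".pdb"))
  if (file.exists(dest)) return(dest)
  url <- paste0("https://files.rcsb.org/download/", id, ".pdb")
  status <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
    error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) ||
      file.info(dest)$size < 1000) {
    unlink(dest)
    stop("could not fetch PDB entry ", id,
         " (no network access to the RCSB archive?)", call. = FALSE)
  }
  dest
}

# Partition --------------------------------------------------------------------

#' Partition a complex into antigen and antibody sides
#'
#' Retains only the named chains and labels them side A (antigen) and side B
#' (antibody). All interface descriptors are computed across this partition.
#'
#' @param structure An `ab_structure`.
#' @param antigen_chains,antibody_chains Character vectors of chain ids; must
#'   exist in the structure and be disjoint.
#' @return A `complex_partition`: list(structure, side_a, side_b).
#' @export
partition_complex <- function(structure, antigen_chains, antibody_chains) {
  antigen_chains <- as.character(antigen_chains)
  antibody_chains <- as.character(antibody_chains)
  if (!length(antigen_chains) || !length(antibody_chains))
    stop("both sides of the partition must be non-empty", call. = FALSE)
  if (length(intersect(antigen_chains, antibody_chains)))
    stop("antigen and antibody chain sets overlap: ",
         paste(intersect(antigen_chains, antibody_chains), collapse = ","),
         call. = FALSE)
  have <- unique(structure$atoms$chain)
  missing <- setdiff(c(antigen_chains, antibody_chains), have)
  if (length(missing))
    stop("chain(s) not present in structure: ",
         paste(missing, collapse = ","), call. = FALSE)
  keep <- structure$atoms$chain %in% c(antigen_chains, antibody_chains)
  out <- list(
    structure = new_ab_structure(structure$atoms[keep, , drop = FALSE],
                                 source = structure$source),
    side_a = antigen_chains, side_b = antibody_chains
  )
  class(out) <- "complex_partition"
  out
}

#' @export
print.complex_partition <- function(x, ...) {
  cat("Complex partition: side A (antigen) =",
      paste(x$side_a, collapse = ","),
      "| side B (antibody) =", paste(x$side_b, collapse = ","), "\n")
  print(x$structure)
  invisible(x)
}

side_atoms <- function(partition, side = c("a", "b")) {
  side <- match.arg(side)
  chains <- if (side == "a") partition$side_a else partition$side_b
  a <- partition$structure$atoms
  a[a$chain %in% chains, , drop = FALSE]
}
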