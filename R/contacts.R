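# Interfacial residue-residue contacts ---------------------------------------

#' Find interfacial residue contacts across a partition
#'
#' Two residues, one per side of the partition, are in contact when any pair
#' of their heavy atoms lies within `cutoff` Angstrom (inclusive). Each
#' residue pair is reported once with the minimum heavy-atom distance,
#' regardless of how many atom pairs fall under the cutoff.
#'
#' @param partition A `complex_partition`.
#' @param cutoff Distance cutoff in Angstrom (default 5.5).
#' @return A `contact_set`: data.frame with one row per contacting residue
#'   pair (chain/resno/ins/resid for both sides, `dist` = minimum heavy-atom
#'   distance), ordered by side-A then side-B residue. Attribute `cutoff`.
#' @export
find_contacts <- function(partition, cutoff = 5.5) {
  stopifnot(inherits(partition, "complex_partition"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  aa <- side_atoms(partition, "a")
  ab <- side_atoms(partition, "b")
  if (!nrow(aa) || !nrow(ab))
    stop("both sides of the partition must contain atoms", call. = FALSE)

  xa <- as.matrix(aa[, c("x", "y", "z")])
  xb <- as.matrix(ab[, c("x", "y", "z")])
  key_a <- residue_key(aa)
  key_b <- residue_key(ab)

  # chunked all-pairs atom distances; minimum aggregated per residue pair
  chunk <- max(1L, floor(2e6 / nrow(xb)))
  n_a <- nrow(xa)
  hits_a <- integer(0); hits_b <- integer(0); hits_d <- numeric(0)
  for (start in seq(1L, n_a, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_a)
    d2 <- outer(rowSums(xa[idx, , drop = FALSE]^2), rowSums(xb^2), "+") -
      2 * xa[idx, , drop = FALSE] %*% t(xb)
    d2[d2 < 0] <- 0
    sel <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(sel)) {
      hits_a <- c(hits_a, idx[sel[, 1]])
      hits_b <- c(hits_b, sel[, 2])
      hits_d <- c(hits_d, sqrt(d2[sel]))
    }
  }

  if (!length(hits_a)) {
    out <- data.frame(chain_a = character(0), resno_a = integer(0),
                      ins_a = character(0), resid_a = character(0),
                      chain_b = character(0), resno_b = integer(0),
                      ins_b = character(0), resid_b = character(0),
                      dist = numeric(0), stringsAsFactors = FALSE)
  } else {
    pair_key <- paste(key_a[hits_a], key_b[hits_b], sep = "~")
    mind <- tapply(hits_d, pair_key, min)
    first <- !duplicated(pair_key)
    fa <- hits_a[first]; fb <- hits_b[first]
    fk <- pair_key[first]
    out <- data.frame(
      chain_a = aa$chain[fa], resno_a = aa$resno[fa], ins_a = aa$ins[fa],
      resid_a = aa$resid[fa],
      chain_b = ab$chain[fb], resno_b = ab$resno[fb], ins_b = ab$ins[fb],
      resid_b = ab$resid[fb],
      dist = as.numeric(mind[fk]), stringsAsFactors = FALSE
    )
    out <- out[order(out$chain_a, out$resno_a, out$ins_a,
                     out$chain_b, out$resno_b, out$ins_b), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_set", "data.frame")
  out
}

#' @export
print.contact_set <- function(x, ...) {
  cat("Interfacial contacts:", nrow(x), "residue pair(s) at cutoff",
      attr(x, "cutoff"), "A\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

.tally_names <- c("cc" = "charged-charged", "cp" = "charged-polar",
                  "ca" = "charged-apolar", "pp" = "polar-polar",
                  "pa" = "polar-apolar", "aa" = "apolar-apolar")

pair_class_key <- function(cls_a, cls_b) {
  short <- c(charged = "c", polar = "p", apolar = "a")
  a <- short[cls_a]; b <- short[cls_b]
  # unordered class pair, canonical order charged < polar < apolar
  rank <- c(c = 1L, p = 2L, a = 3L)
  swap <- rank[a] > rank[b]
  key <- paste0(ifelse(swap, b, a), ifelse(swap, a, b))
  unname(key)
}

#' Tally contacts by residue-class pair
#'
#' Counts the contact pairs of [find_contacts()] in the six unordered
#' character-pair categories (charged-charged, charged-polar, charged-apolar,
#' polar-polar, polar-apolar, apolar-apolar). Class pairs are unordered: an
#' antigen-charged/antibody-apolar contact and an antigen-apolar/
#' antibody-charged contact both count as charged-apolar. Pairs containing a
#' residue outside the 20 standard amino acids are skipped with a warning.
#'
#' @param pairs A `contact_set` (or data.frame with `resid_a`, `resid_b`).
#' @param scheme Classification scheme, see [classify_residue()].
#' @return A `contact_tally`: named integer vector
#'   (`cc`, `cp`, `ca`, `pp`, `pa`, `aa`) with attributes `cutoff`,
#'   `n_pairs`, `n_skipped`, `scheme`.
#' @export
tally_contacts <- function(pairs, scheme = c("ic_scheme", "nis_scheme")) {
  scheme <- match.arg(scheme)
  counts <- stats::setNames(integer(6), names(.tally_names))
  n_skipped <- 0L
  if (nrow(pairs)) {
    cls_a <- classify_residue(pairs$resid_a, scheme, on_unknown = "na")
    cls_b <- classify_residue(pairs$resid_b, scheme, on_unknown = "na")
    ok <- !is.na(cls_a) & !is.na(cls_b)
    n_skipped <- sum(!ok)
    if (n_skipped)
      warning(n_skipped, " contact pair(s) with non-standard residues skipped",
              call. = FALSE)
    if (any(ok)) {
      key <- pair_class_key(cls_a[ok], cls_b[ok])
      tab <- table(factor(key, levels = names(.tally_names)))
      counts <- stats::setNames(as.integer(tab), names(.tally_names))
    }
  }
  structure(counts, cutoff = attr(pairs, "cutoff"),
            n_pairs = nrow(pairs), n_skipped = n_skipped,
            scheme = scheme, class = "contact_tally")
}

#' @export
print.contact_tally <- function(x, ...) {
  cat("Interfacial contact tally (", attr(x, "scheme"), ", cutoff ",
      attr(x, "cutoff"), " A):\n", sep = "")
  for (k in names(.tally_names))
    cat(sprintf("  %-16s %d\n", .tally_names[[k]], x[[k]]))
  if (attr(x, "n_skipped") > 0)
    cat("  (", attr(x, "n_skipped"), "pair(s) skipped )\n")
  invisible(x)
}

#' Export a contact list as CSV
#'
#' Writes one row per contact pair with chain, residue number, residue name
#' per side, the minimum heavy-atom distance and the unordered class pair.
#'
#' @param pairs A `contact_set`.
#' @param path Output CSV path.
#' @param scheme Classification scheme used for the class-pair column.
#' @return `path`, invisibly.
#' @export
write_contacts_csv <- function(pairs, path, scheme = "ic_scheme") {
  df <- as.data.frame(pairs)
  if (nrow(df)) {
    cls_a <- classify_residue(df$resid_a, scheme, on_unknown = "na")
    cls_b <- classify_residue(df$resid_b, scheme, on_unknown = "na")
    df$class_pair <- ifelse(is.na(cls_a) | is.na(cls_b), NA_character_,
                            .tally_names[pair_class_key(cls_a, cls_b)])
  } else df$class_pair <- character(0)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
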