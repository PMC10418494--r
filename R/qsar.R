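# Contact-based binding-affinity model ---------------------------------------

.R_CAL <- 1.987  # gas constant, cal K^-1 mol^-1

#' Coefficient set for the contact-based affinity model
#'
#' The linear model predicts the binding free energy (kcal/mol) from four
#' interfacial-contact counts and two non-interacting-surface percentages:
#' \deqn{\Delta G = w_{cc} IC_{cc} + w_{ca} IC_{ca} + w_{pp} IC_{pp} +
#'   w_{pa} IC_{pa} + w_{NISa} \%NIS_{apolar} + w_{NISc} \%NIS_{charged} + b}
#' Apolar-apolar and charged-polar contacts carry no weight in the model.
#' The `"corrected"` default uses +0.13810 for the charged-NIS weight, the
#' originally published value; the `"as_printed"` variant uses +0.3810, a
#' value that circulates in secondary sources but is inconsistent with the
#' model's own worked predictions by ~5 kcal/mol (see the methods vignette).
#'
#' @param variant `"corrected"` (default) or `"as_printed"`.
#' @return A `qsar_coefficients` named numeric vector with elements
#'   `w_cc`, `w_ca`, `w_pp`, `w_pa`, `w_nis_apolar`, `w_nis_charged`,
#'   `intercept`.
#' @export
qsar_coefficients <- function(variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  co <- c(w_cc = -0.09459, w_ca = -0.10007, w_pp = 0.19577, w_pa = -0.22671,
          w_nis_apolar = 0.18681,
          w_nis_charged = if (variant == "corrected") 0.13810 else 0.3810,
          intercept = -15.9433)
  structure(co, variant = variant, class = "qsar_coefficients")
}

#' Predict binding free energy from interface descriptors
#'
#' Evaluates the linear contact-based model on a contact tally and a NIS
#' composition. Only the charged-charged, charged-apolar, polar-polar and
#' polar-apolar contact counts enter; apolar-apolar and charged-polar counts
#' are intentionally unused.
#'
#' @param tally A `contact_tally` (or named vector with `cc`, `ca`, `pp`,
#'   `pa`).
#' @param nis A `nis_result` (or list with `nis_apolar_pct`,
#'   `nis_charged_pct`).
#' @param coeffs A `qsar_coefficients` vector (default: corrected set).
#' @return Predicted binding free energy in kcal/mol (numeric scalar).
#' @examples
#' # all-zero descriptors return the intercept, -15.9433
#' predict_delta_g(c(cc = 0, ca = 0, pp = 0, pa = 0),
#'                 list(nis_apolar_pct = 0, nis_charged_pct = 0))
#' @export
predict_delta_g <- function(tally, nis, coeffs = qsar_coefficients()) {
  unname(
    coeffs[["w_cc"]] * tally[["cc"]] + coeffs[["w_ca"]] * tally[["ca"]] +
    coeffs[["w_pp"]] * tally[["pp"]] + coeffs[["w_pa"]] * tally[["pa"]] +
    coeffs[["w_nis_apolar"]] * nis[["nis_apolar_pct"]] +
    coeffs[["w_nis_charged"]] * nis[["nis_charged_pct"]] +
    coeffs[["intercept"]]
  )
}

#' Dissociation constant from a binding free energy
#'
#' Kd = exp(dG * 1000 / (R T)) with R = 1.987 cal/(K mol); dG in kcal/mol.
#'
#' @param delta_g Binding free energy, kcal/mol.
#' @param temperature Absolute temperature in K (default 309).
#' @return Dissociation constant in molar units.
#' @export
dissociation_constant <- function(delta_g, temperature = 309) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("temperature must be positive", call. = FALSE)
  exp(delta_g * 1000 / (.R_CAL * temperature))
}

#' End-to-end affinity prediction for a structure file
#'
#' Runs the full structure pipeline: read the structure, partition it into
#' antigen and antibody chains, find interfacial contacts, compute SASA, NIS
#' composition and buried surface area, and evaluate the affinity model.
#'
#' @param path Structure file (PDB or mmCIF) or PDB text.
#' @param antigen_chains,antibody_chains Chain identifiers per side.
#' @param cutoff Contact cutoff in Angstrom (default 5.5).
#' @param temperature Temperature (K) for the derived Kd (default 309);
#'   affects only Kd, never the predicted free energy.
#' @param coeffs Coefficient set (default corrected).
#' @param nis_scheme Residue-character table for the NIS composition.
#' @param nis_threshold Relative-SASA surface threshold, percent.
#' @param n_points Sphere points per atom for SASA.
#' @param compute_bsa Also compute buried surface area (default `TRUE`;
#'   triggers two extra SASA evaluations).
#' @param label Optional structure label for reporting.
#' @return An `affinity_prediction`: list with `delta_g` (kcal/mol), `kd`
#'   (M), `temperature`, `tally`, `nis`, `bsa`, `label` and the effective
#'   settings.
#' @export
predict_structure_file <- function(path, antigen_chains, antibody_chains,
                                   cutoff = 5.5, temperature = 309,
                                   coeffs = qsar_coefficients(),
                                   nis_scheme = "nis_scheme",
                                   nis_threshold = 5, n_points = 960,
                                   compute_bsa = TRUE, label = NULL) {
  st <- if (inherits(path, "ab_structure")) path else read_structure(path)
  part <- partition_complex(st, antigen_chains, antibody_chains)
  contacts <- find_contacts(part, cutoff = cutoff)
  tally <- tally_contacts(contacts, scheme = "ic_scheme")
  sasa <- compute_sasa(part, n_points = n_points)
  nis <- nis_percentages(part, sasa_complex = sasa,
                         threshold_pct = nis_threshold,
                         scheme = nis_scheme, contacts = contacts)
  bsa <- if (compute_bsa)
    buried_surface_area(part, n_points = n_points) else NULL
  dg <- predict_delta_g(tally, nis, coeffs)
  out <- list(
    delta_g = dg, kd = dissociation_constant(dg, temperature),
    temperature = temperature, tally = tally, nis = nis, bsa = bsa,
    contacts = contacts,
    label = if (is.null(label)) {
      if (is.character(path) && !grepl("\n", path[1])) basename(path[1])
      else "structure"
    } else label,
    settings = list(cutoff = cutoff, nis_scheme = nis_scheme,
                    nis_threshold = nis_threshold, n_points = n_points,
                    coefficients = unclass(coeffs),
                    coefficient_variant = attr(coeffs, "variant"))
  )
  class(out) <- "affinity_prediction"
  out
}

#' @export
print.affinity_prediction <- function(x, ...) {
  cat(sprintf("Affinity prediction for %s\n", x$label))
  cat(sprintf("  dG = %.2f kcal/mol   Kd = %.3g M at %g K\n",
              x$delta_g, x$kd, x$temperature))
  cat(sprintf("  ICs: cc=%d cp=%d ca=%d pp=%d pa=%d aa=%d (cutoff %g A)\n",
              x$tally[["cc"]], x$tally[["cp"]], x$tally[["ca"]],
              x$tally[["pp"]], x$tally[["pa"]], x$tally[["aa"]],
              x$settings$cutoff))
  cat(sprintf("  NIS: charged %.1f%%  apolar %.1f%%\n",
              x$nis$nis_charged_pct, x$nis$nis_apolar_pct))
  if (!is.null(x$bsa)) cat(sprintf("  BSA: %.0f A^2\n", x$bsa$bsa))
  invisible(x)
}

#' Average affinity predictions over an ensemble of snapshots
#'
#' Applies [predict_structure_file()] to each snapshot and reports the mean
#' and sample (n-1) standard deviation of the predicted free energy. Failing
#' snapshots are recorded and excluded with a warning; if all fail, an error
#' is raised.
#'
#' @param paths Character vector of structure files (or list of
#'   `ab_structure` objects).
#' @param antigen_chains,antibody_chains Chain identifiers per side.
#' @param ... Further arguments to [predict_structure_file()].
#' @return An `ensemble_prediction`: list with `mean_delta_g`, `sd_delta_g`
#'   (`NA` for a single snapshot), `n`, `predictions`, `failures`.
#' @export
predict_ensemble <- function(paths, antigen_chains, antibody_chains, ...) {
  if (!length(paths)) stop("no snapshots supplied", call. = FALSE)
  preds <- list(); fails <- character(0)
  for (i in seq_along(paths)) {
    p <- if (is.list(paths) && !inherits(paths, "ab_structure"))
      paths[[i]] else paths[i]
    r <- tryCatch(
      predict_structure_file(p, antigen_chains, antibody_chains,
                             compute_bsa = FALSE, ...),
      error = function(e) e)
    if (inherits(r, "error")) {
      fails <- c(fails, sprintf("snapshot %d: %s", i, conditionMessage(r)))
    } else preds[[length(preds) + 1L]] <- r
  }
  if (!length(preds))
    stop("all snapshots failed:\n", paste(fails, collapse = "\n"),
         call. = FALSE)
  if (length(fails))
    warning(length(fails), " snapshot(s) failed and were excluded",
            call. = FALSE)
  dgs <- vapply(preds, `[[`, numeric(1), "delta_g")
  out <- list(mean_delta_g = mean(dgs),
              sd_delta_g = if (length(dgs) >= 2) stats::sd(dgs) else NA_real_,
              n = length(dgs), delta_g = dgs, predictions = preds,
              failures = fails)
  class(out) <- "ensemble_prediction"
  out
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("Ensemble affinity: dG = %.2f %s kcal/mol over %d snapshot(s)\n",
              x$mean_delta_g,
              if (is.na(x$sd_delta_g)) "(sd undefined)"
              else sprintf("+/- %.2f", x$sd_delta_g), x$n))
  if (length(x$failures)) cat("  failures:", length(x$failures), "\n")
  invisible(x)
}
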