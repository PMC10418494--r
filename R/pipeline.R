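# Run configuration and batch orchestration ----------------------------------

#' Run configuration
#'
#' Collects every tunable of the two analysis routes in one serialisable
#' record that is embedded in all batch outputs (full provenance: identical
#' inputs and config give identical outputs).
#'
#' @param cutoff Contact cutoff, Angstrom.
#' @param nis_threshold Surface threshold, percent relative SASA.
#' @param nis_scheme Residue-character table for NIS.
#' @param coefficient_variant `"corrected"` or `"as_printed"`.
#' @param temperature Temperature, K.
#' @param water_molarity Water molarity, M.
#' @param n_points SASA sphere points per atom.
#' @param seed Seed for any stochastic step.
#' @return An `ab_config` list with a stable `hash` field.
#' @export
ab_config <- function(cutoff = 5.5, nis_threshold = 5,
                      nis_scheme = "nis_scheme",
                      coefficient_variant = "corrected",
                      temperature = 309, water_molarity = 55.34,
                      n_points = 960, seed = 1L) {
  cfg <- list(cutoff = cutoff, nis_threshold = nis_threshold,
              nis_scheme = nis_scheme,
              coefficient_variant = coefficient_variant,
              temperature = temperature, water_molarity = water_molarity,
              n_points = n_points, seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "ab_config"
  cfg
}

config_hash <- function(cfg) {
  cfg$hash <- NULL
  txt <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                  character(1)),
               sep = "=", collapse = ";")
  # small deterministic polynomial hash; provenance, not cryptography
  h <- 5381
  for (ch in utf8ToInt(txt)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.ab_config <- function(x, ...) {
  cat("Run configuration [", x$hash, "]\n", sep = "")
  for (k in setdiff(names(x), "hash")) cat(" ", k, "=", format(x[[k]]), "\n")
  invisible(x)
}

#' Batch structure-based affinity prediction
#'
#' Applies the full structure pipeline to each file and summarises the
#' ensemble. Per-file failures are collected; the run fails only when every
#' file fails.
#'
#' @param paths Structure files (PDB/mmCIF).
#' @param antigen_chains,antibody_chains Chain ids per side.
#' @param config An [ab_config()].
#' @param out_json,out_csv Optional output paths for machine-readable
#'   records.
#' @return A `run_predict_result`: list with `results` (per-file
#'   `affinity_prediction`s), `table` (data.frame of dG, Kd, descriptors),
#'   `ensemble` (when > 1 file), `failures`, `config`.
#' @export
run_predict <- function(paths, antigen_chains, antibody_chains,
                        config = ab_config(), out_json = NULL,
                        out_csv = NULL) {
  if (!length(paths)) stop("no input structures given", call. = FALSE)
  coeffs <- qsar_coefficients(config$coefficient_variant)
  results <- list(); failures <- character(0)
  for (p in paths) {
    r <- tryCatch(
      predict_structure_file(p, antigen_chains, antibody_chains,
                             cutoff = config$cutoff,
                             temperature = config$temperature,
                             coeffs = coeffs,
                             nis_scheme = config$nis_scheme,
                             nis_threshold = config$nis_threshold,
                             n_points = config$n_points),
      error = function(e) e)
    if (inherits(r, "error"))
      failures <- c(failures, paste0(p, ": ", conditionMessage(r)))
    else results[[length(results) + 1L]] <- r
  }
  if (!length(results))
    stop("all structures failed:\n", paste(failures, collapse = "\n"),
         call. = FALSE)
  tab <- do.call(rbind, lapply(results, function(r) data.frame(
    label = r$label, delta_g = r$delta_g, kd = r$kd,
    ic_cc = r$tally[["cc"]], ic_cp = r$tally[["cp"]], ic_ca = r$tally[["ca"]],
    ic_pp = r$tally[["pp"]], ic_pa = r$tally[["pa"]], ic_aa = r$tally[["aa"]],
    nis_charged = r$nis$nis_charged_pct, nis_apolar = r$nis$nis_apolar_pct,
    bsa = if (is.null(r$bsa)) NA_real_ else r$bsa$bsa,
    stringsAsFactors = FALSE)))
  dgs <- tab$delta_g
  out <- list(results = results, table = tab,
              ensemble = if (length(dgs) > 1)
                list(mean_delta_g = mean(dgs), sd_delta_g = stats::sd(dgs),
                     n = length(dgs)) else NULL,
              failures = failures, config = config)
  class(out) <- "run_predict_result"
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(list(config = unclass(config), table = tab,
                              failures = failures),
                         out_json, auto_unbox = TRUE, digits = NA)
  out
}

#' @export
print.run_predict_result <- function(x, ...) {
  cat("Structure-based affinity batch [config ", x$config$hash, "]\n",
      sep = "")
  print(x$table[, c("label", "delta_g", "kd", "bsa")])
  if (!is.null(x$ensemble))
    cat(sprintf("ensemble: %.2f +/- %.2f kcal/mol (n = %d)\n",
                x$ensemble$mean_delta_g, x$ensemble$sd_delta_g,
                x$ensemble$n))
  if (length(x$failures)) cat("failures:", length(x$failures), "\n")
  invisible(x)
}

#' Batch Goldberg equilibrium analysis
#'
#' Analyses every row of a species table (CSV path or data.frame in the
#' schema of [read_species_csv()]).
#'
#' @param species_table CSV path or data.frame.
#' @param config An [ab_config()].
#' @param out_json,out_csv Optional output paths.
#' @return A `run_equilibrium_result`: list with `results` (per-row
#'   `binding_equilibrium`), `table`, `config`.
#' @export
run_equilibrium <- function(species_table, config = ab_config(),
                            out_json = NULL, out_csv = NULL) {
  df <- if (is.character(species_table)) read_species_csv(species_table)
    else species_table
  if (!nrow(df)) stop("empty species table", call. = FALSE)
  missing <- setdiff(setdiff(.species_cols, "sample"), names(df))
  if (length(missing))
    stop("species table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  results <- lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, ])
    sp <- species_concentrations(
      row$c_a_uM, row$c_g_uM, row$complex1_uM, row$complex2_uM,
      row$free_ab_uM, row$free_ag_uM, row$M_a_kDa, row$M_g_kDa,
      sample = if (!is.null(row$sample)) row$sample else paste0("row", i))
    analyze_mixture(sp, temperature = config$temperature,
                    water_molarity = config$water_molarity)
  })
  tab <- do.call(rbind, lapply(results, function(r) data.frame(
    sample = r$species$sample, p = r$p, K_molar = r$K_molar, K_a = r$K_a,
    delta_g = r$delta_g, stringsAsFactors = FALSE)))
  out <- list(results = results, table = tab, config = config)
  class(out) <- "run_equilibrium_result"
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(list(config = unclass(config), table = tab),
                         out_json, auto_unbox = TRUE, digits = NA)
  out
}

#' @export
print.run_equilibrium_result <- function(x, ...) {
  cat("Goldberg equilibrium batch [config ", x$config$hash, "]\n", sep = "")
  print(x$table)
  invisible(x)
}
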