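# Bivalent-antibody solution equilibrium (Goldberg analysis) -----------------

#' Fraction of reacted antigen sites
#'
#' Inverts the free-antigen relation c_ag = c_g (1-p)^f:
#' p = 1 - (c_ag/c_g)^(1/f). Concentration units cancel (any shared unit).
#'
#' @param free_antigen_conc Free antigen concentration at equilibrium.
#' @param total_antigen_conc Total antigen concentration (same unit).
#' @param f Antibody valence (default 2 for IgG).
#' @return p in `[0, 1]`; p = 1 (complete reaction) raises a warning since
#'   the association constant diverges there.
#' @export
reacted_site_fraction <- function(free_antigen_conc, total_antigen_conc,
                                  f = 2) {
  if (any(f < 1) || any(f != round(f)))
    stop("f must be a positive integer", call. = FALSE)
  if (any(free_antigen_conc < 0) || any(total_antigen_conc <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (any(free_antigen_conc > total_antigen_conc))
    stop("free antigen exceeds total antigen", call. = FALSE)
  p <- 1 - (free_antigen_conc / total_antigen_conc)^(1 / f)
  if (any(free_antigen_conc == 0))
    warning("free antigen is zero: p = 1 boundary (K undefined)",
            call. = FALSE)
  p
}

#' Goldberg association constant for a bivalent antibody
#'
#' K = f M_a p / \[4 c_a (1-p) (1 - p f c_g M_a / (2 c_a M_g))\] in M^-1,
#' with c_a, c_g the total antibody and antigen mass concentrations (g/L)
#' and M_a, M_g the molar masses (g/mol).
#'
#' @param p Fraction of reacted antigen sites, in (0, 1).
#' @param c_a,c_g Total antibody/antigen concentration, g/L.
#' @param M_a,M_g Molar masses, g/mol.
#' @param f Antibody valence (default 2).
#' @return Association constant in M^-1.
#' @export
goldberg_constant <- function(p, c_a, c_g, M_a, M_g, f = 2) {
  if (any(p <= 0) || any(p >= 1)) stop("p must lie in (0, 1)", call. = FALSE)
  if (any(c(c_a, c_g, M_a, M_g) <= 0))
    stop("concentrations and masses must be positive", call. = FALSE)
  bracket <- 1 - p * f * c_g * M_a / (2 * c_a * M_g)
  if (any(bracket <= 0))
    stop("over-saturated inputs: the Goldberg bracket term is non-positive",
         call. = FALSE)
  f * M_a * p / (4 * c_a * (1 - p) * bracket)
}

#' Convert a molar association constant to mole-fraction units
#'
#' K_a = K_molar * water molarity; the free energy relation requires the
#' constant in (mole fraction)^-1.
#'
#' @param K_molar Association constant, M^-1.
#' @param water_molarity Molarity of water (default 55.34 M).
#' @return Mole-fraction association constant (dimensionless).
#' @export
to_mole_fraction <- function(K_molar, water_molarity = 55.34) {
  if (any(K_molar <= 0)) stop("K must be positive", call. = FALSE)
  K_molar * water_molarity
}

#' Binding free energy from a mole-fraction association constant
#'
#' dG = -R T ln(K_a) / 1000 kcal/mol with R = 1.987 cal/(K mol).
#'
#' @param K_a Mole-fraction association constant (> 0).
#' @param temperature Absolute temperature, K (default 309).
#' @return Free energy in kcal/mol.
#' @export
delta_g_from_ka <- function(K_a, temperature = 309) {
  if (any(K_a <= 0)) stop("K_a must be positive", call. = FALSE)
  if (any(temperature <= 0)) stop("temperature must be positive", call. = FALSE)
  -.R_CAL * temperature * log(K_a) / 1000
}

# Species container -----------------------------------------------------------

#' Species concentrations of an antibody-antigen mixture
#'
#' Bundles total and equilibrium molar concentrations (micromolar) with the
#' molar masses needed for the Goldberg analysis. Mass balance
#' (free + complexes vs totals) is checked against `tolerance` and reported
#' via attribute `mass_balance`.
#'
#' @param c_a_uM,c_g_uM Total antibody / antigen concentration, micromolar.
#' @param complex1_uM,complex2_uM 1:1 and 2:1 (antigen:antibody) complex
#'   concentrations, micromolar.
#' @param free_ab_uM,free_ag_uM Free antibody / antigen, micromolar.
#' @param M_a_kDa,M_g_kDa Antibody / antigen molar mass, kDa.
#' @param f Antibody valence (default 2).
#' @param sample Optional sample label.
#' @param tolerance Relative mass-balance tolerance (default 0.05).
#' @param on_violation `"warn"` (default), `"error"` or `"ignore"`.
#' @return A `species_concentrations` list.
#' @export
species_concentrations <- function(c_a_uM, c_g_uM, complex1_uM, complex2_uM,
                                   free_ab_uM, free_ag_uM,
                                   M_a_kDa = 147.0, M_g_kDa = 86.4, f = 2,
                                   sample = NA_character_, tolerance = 0.05,
                                   on_violation = c("warn", "error", "ignore")) {
  on_violation <- match.arg(on_violation)
  vals <- c(c_a_uM, c_g_uM, complex1_uM, complex2_uM, free_ab_uM, free_ag_uM)
  if (any(vals < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (f < 1 || f != round(f)) stop("f must be a positive integer", call. = FALSE)

  ab_balance <- (free_ab_uM + complex1_uM + complex2_uM) / c_a_uM - 1
  ag_balance <- (free_ag_uM + complex1_uM + 2 * complex2_uM) / c_g_uM - 1
  if (max(abs(c(ab_balance, ag_balance))) > tolerance) {
    msg <- sprintf(
      "mass balance violated beyond %.0f%%: antibody %+.1f%%, antigen %+.1f%%",
      100 * tolerance, 100 * ab_balance, 100 * ag_balance)
    if (on_violation == "error") stop(msg, call. = FALSE)
    if (on_violation == "warn") warning(msg, call. = FALSE)
  }
  out <- list(c_a_uM = c_a_uM, c_g_uM = c_g_uM, complex1_uM = complex1_uM,
              complex2_uM = complex2_uM, free_ab_uM = free_ab_uM,
              free_ag_uM = free_ag_uM, M_a_kDa = M_a_kDa, M_g_kDa = M_g_kDa,
              f = f, sample = sample,
              mass_balance = c(antibody = ab_balance, antigen = ag_balance))
  class(out) <- "species_concentrations"
  out
}

#' @export
print.species_concentrations <- function(x, ...) {
  cat(sprintf("Mixture%s (uM): mAb %.3g, antigen %.3g | complex1 %.3g, complex2 %.3g, free mAb %.3g, free antigen %.3g\n",
              if (is.na(x$sample)) "" else paste0(" ", x$sample),
              x$c_a_uM, x$c_g_uM, x$complex1_uM, x$complex2_uM,
              x$free_ab_uM, x$free_ag_uM))
  cat(sprintf("  M_a %.1f kDa, M_g %.1f kDa, f = %d | mass balance: mAb %+.1f%%, antigen %+.1f%%\n",
              x$M_a_kDa, x$M_g_kDa, x$f,
              100 * x$mass_balance[["antibody"]],
              100 * x$mass_balance[["antigen"]]))
  invisible(x)
}

#' Goldberg analysis of a measured mixture
#'
#' Chains the solution-phase analysis: reacted-site fraction from free and
#' total antigen, the bivalent-antibody association constant in M^-1,
#' conversion to mole-fraction units, and the binding free energy.
#'
#' @param species A `species_concentrations` object (or a one-row data.frame
#'   / list with the same fields).
#' @param temperature Temperature, K (default 309).
#' @param water_molarity Water molarity for the mole-fraction conversion
#'   (default 55.34 M).
#' @return A `binding_equilibrium`: list with `p`, `K_molar` (M^-1), `K_a`
#'   (mole fraction^-1), `delta_g` (kcal/mol), the inputs and settings.
#' @export
analyze_mixture <- function(species, temperature = 309,
                            water_molarity = 55.34) {
  if (!inherits(species, "species_concentrations")) {
    species <- do.call(species_concentrations,
                       species[intersect(names(species),
                                         names(formals(species_concentrations)))])
  }
  p <- reacted_site_fraction(species$free_ag_uM, species$c_g_uM, species$f)
  c_a <- species$c_a_uM * 1e-6 * species$M_a_kDa * 1000  # g/L
  c_g <- species$c_g_uM * 1e-6 * species$M_g_kDa * 1000
  K <- goldberg_constant(p, c_a, c_g, species$M_a_kDa * 1000,
                         species$M_g_kDa * 1000, species$f)
  K_a <- to_mole_fraction(K, water_molarity)
  dg <- delta_g_from_ka(K_a, temperature)
  out <- list(p = p, K_molar = K, K_a = K_a, delta_g = dg,
              temperature = temperature, water_molarity = water_molarity,
              species = species)
  class(out) <- "binding_equilibrium"
  out
}

#' @export
print.binding_equilibrium <- function(x, ...) {
  cat(sprintf("Goldberg equilibrium analysis%s:\n",
              if (is.na(x$species$sample)) ""
              else paste0(" (", x$species$sample, ")")))
  cat(sprintf("  p = %.3f   K = %.3g M^-1   K_a = %.3g (mole fraction)^-1\n",
              x$p, x$K_molar, x$K_a))
  cat(sprintf("  dG = %.2f kcal/mol at %g K (water %.2f M)\n",
              x$delta_g, x$temperature, x$water_molarity))
  invisible(x)
}

# Forward simulation ----------------------------------------------------------

#' Simulate a bivalent antibody-antigen equilibrium
#'
#' Two forward models are available. `model = "goldberg"` (default) is the
#' exact inverse of [analyze_mixture()]: the reacted-site fraction p is
#' solved from the Goldberg expression at the requested constant, free
#' antigen follows from c_ag = c_g (1-p)^f, and the bound antigen is split
#' into 1:1 and 2:1 species by bivalent-site statistics (free : single :
#' double antibody weights 1 : 2 xi : rho xi^2), so the analysis chain
#' recovers `K_site` exactly. `model = "mass_action"` solves the
#' independent-sites law of mass action \[AbAg\] = 2 K \[Ab\]\[Ag\],
#' \[AbAg2\] = rho K^2 \[Ab\]\[Ag\]^2 by bounded root-finding on the antigen
#' mass balance; its equilibria are *not* Goldberg-consistent (the two
#' statistical frameworks differ; see the methods vignette).
#'
#' @param K_site Association constant, M^-1 (the Goldberg constant for the
#'   default model; the per-site constant for `"mass_action"`). `K_site = 0`
#'   returns the free species only.
#' @param c_a_uM,c_g_uM Total antibody / antigen, micromolar.
#' @param f Antibody valence (only `f = 2` is supported for the species
#'   split).
#' @param rho Second-site cooperativity factor (default 1; < 1 penalises,
#'   > 1 favours the 2:1 complex). Affects only the 1:1 / 2:1 split under
#'   `"goldberg"`; enters the mass-action law directly otherwise.
#' @param M_a_kDa,M_g_kDa Molar masses, kDa.
#' @param model `"goldberg"` (default) or `"mass_action"`.
#' @param sample Optional label.
#' @return A `species_concentrations` object; attribute `K_site` records the
#'   simulating constant.
#' @export
simulate_equilibrium <- function(K_site, c_a_uM, c_g_uM, f = 2, rho = 1,
                                 M_a_kDa = 147.0, M_g_kDa = 86.4,
                                 model = c("goldberg", "mass_action"),
                                 sample = NA_character_) {
  model <- match.arg(model)
  if (K_site < 0 || rho < 0) stop("K_site and rho must be >= 0", call. = FALSE)
  if (c_a_uM <= 0 || c_g_uM <= 0) stop("totals must be positive", call. = FALSE)
  if (f != 2) stop("only bivalent antibodies (f = 2) are supported",
                   call. = FALSE)
  A <- c_a_uM * 1e-6  # molar
  G <- c_g_uM * 1e-6

  if (K_site == 0) {
    return(species_concentrations(c_a_uM, c_g_uM, 0, 0, c_a_uM, c_g_uM,
                                  M_a_kDa, M_g_kDa, f, sample,
                                  on_violation = "ignore"))
  }

  if (model == "goldberg") {
    # K(p) = f p / (4 A (1-p) (1 - p f G / (2 A))) is monotone increasing on
    # (0, p_max); solve K(p) = K_site
    p_max <- min(1, 2 * A / (f * G)) - 1e-12
    Kp <- function(p) f * p / (4 * A * (1 - p) * (1 - p * f * G / (2 * A)))
    g <- function(p) log(Kp(p)) - log(K_site)
    sol <- stats::uniroot(g, c(1e-14, p_max), tol = .Machine$double.eps^0.75)
    p <- sol$root
    free_ag <- G * (1 - p)^f
    bound_ag <- G - free_ag
    if (bound_ag > f * A)
      stop("bound antigen exceeds antibody sites", call. = FALSE)
    # antibody species weights 1 : 2 xi : rho xi^2; xi from bound-site count
    theta <- bound_ag / A  # bound antigen per antibody in [0, 2)
    if (theta < 1e-14) {
      xi <- 0
    } else {
      # solve (2 xi + 2 rho xi^2) / (1 + 2 xi + rho xi^2) = theta, i.e.
      # rho (2 - theta) xi^2 + 2 (1 - theta) xi - theta = 0; the positive
      # root in a form stable as rho (2 - theta) -> 0
      coef2 <- rho * (2 - theta)
      coef1 <- 2 * (1 - theta)
      coef0 <- -theta
      xi <- -2 * coef0 / (coef1 + sqrt(coef1^2 - 4 * coef2 * coef0))
    }
    Z <- 1 + 2 * xi + rho * xi^2
    free_ab <- A / Z
    c1 <- 2 * xi * A / Z
    c2 <- rho * xi^2 * A / Z
  } else {
    # independent-sites mass action: [AbAg] = 2 K a g, [AbAg2] = rho K^2 a g^2
    resid <- function(g) {
      a <- A / (1 + 2 * K_site * g + rho * K_site^2 * g^2)
      g + a * (2 * K_site * g + 2 * rho * K_site^2 * g^2) - G
    }
    sol <- stats::uniroot(resid, c(G * 1e-16, G), tol = G * 1e-13,
                          maxiter = 2000)
    g <- sol$root
    if (abs(resid(g)) > G * 1e-8)
      stop("mass-balance root finding did not converge", call. = FALSE)
    a <- A / (1 + 2 * K_site * g + rho * K_site^2 * g^2)
    free_ag <- g; free_ab <- a
    c1 <- 2 * K_site * a * g
    c2 <- rho * K_site^2 * a * g^2
  }

  out <- species_concentrations(
    c_a_uM, c_g_uM, c1 * 1e6, c2 * 1e6, free_ab * 1e6, free_ag * 1e6,
    M_a_kDa, M_g_kDa, f, sample, on_violation = "error", tolerance = 1e-6)
  attr(out, "K_site") <- K_site
  attr(out, "rho") <- rho
  attr(out, "model") <- model
  out
}

# CSV interface ---------------------------------------------------------------

.species_cols <- c("sample", "c_a_uM", "c_g_uM", "complex1_uM", "complex2_uM",
                   "free_ab_uM", "free_ag_uM", "M_a_kDa", "M_g_kDa")

#' Read a species table from CSV
#'
#' Expected header: sample, c_a_uM, c_g_uM, complex1_uM, complex2_uM,
#' free_ab_uM, free_ag_uM, M_a_kDa, M_g_kDa.
#'
#' @param path CSV file path.
#' @return data.frame with one row per mixture.
#' @export
read_species_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.species_cols, names(df))
  if (length(missing))
    stop("species table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a species table to CSV
#' @param species A `species_concentrations` object, a list of them, or a
#'   data.frame in the CSV schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_csv <- function(species, path) {
  if (inherits(species, "species_concentrations")) species <- list(species)
  if (!is.data.frame(species)) {
    species <- do.call(rbind, lapply(species, function(s)
      data.frame(sample = s$sample, c_a_uM = s$c_a_uM, c_g_uM = s$c_g_uM,
                 complex1_uM = s$complex1_uM, complex2_uM = s$complex2_uM,
                 free_ab_uM = s$free_ab_uM, free_ag_uM = s$free_ag_uM,
                 M_a_kDa = s$M_a_kDa, M_g_kDa = s$M_g_kDa,
                 stringsAsFactors = FALSE)))
  }
  utils::write.csv(species, path, row.names = FALSE)
  invisible(path)
}
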