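# Synthetic fixtures: toy complexes, chromatograms, mixtures, IgG models -----

# one-letter -> representative 3-letter code
.aa1to3 <- stats::setNames(names(.aa3), unname(.aa3))

toy_atoms <- function(chain, resno, resid, center, with_cb = TRUE) {
  # minimal residue: backbone N, CA, C, O around the CA position plus one
  # side-chain carrier (CB); geometry, not chemistry
  offs <- rbind(N = c(-1.2, 0.6, 0), CA = c(0, 0, 0), C = c(1.2, 0.6, 0),
                O = c(1.9, -0.3, 0.5))
  if (with_cb) offs <- rbind(offs, CB = c(0, -1.0, 1.0))
  data.frame(chain = chain, resno = resno, ins = "", resid = resid,
             elety = rownames(offs),
             elesy = c("N", "C", "C", "O", if (with_cb) "C"),
             x = center[1] + offs[, 1], y = center[2] + offs[, 2],
             z = center[3] + offs[, 3], stringsAsFactors = FALSE)
}

#' Build a toy two-chain complex with known contact ground truth
#'
#' Places minimal residues (backbone + one side-chain carrier atom) so that
#' the requested cross-chain contacts - and no others - exist at the 5.5 A
#' cutoff. Residue pairs intended to touch are placed with their CA atoms at
#' `contact_distance`; all other inter-residue CA distances are at least
#' `spacing`. The generated structure is self-checked against its own
#' ground truth on generation.
#'
#' @param residues_a,residues_b Character vectors of one- or three-letter
#'   residue codes for chain A and chain B.
#' @param contacts Two-column integer matrix (or data.frame) of index pairs
#'   (i in side A, j in side B) intended to be in contact.
#' @param contact_distance CA-CA distance of contact pairs (default 5.0 A).
#' @param spacing Grid spacing separating everything else (default 30 A).
#' @param chain_ids Chain identifiers (default `c("A", "B")`).
#' @return List with `structure` (`ab_structure`), `partition`, `contacts`
#'   (the intended pair list) and `tally` (ground-truth `contact_tally`).
#' @export
make_toy_complex <- function(residues_a, residues_b, contacts,
                             contact_distance = 5.0, spacing = 30,
                             chain_ids = c("A", "B")) {
  if (!length(residues_a) || !length(residues_b))
    stop("empty residue list for a side", call. = FALSE)
  contacts <- as.matrix(contacts)
  if (ncol(contacts) != 2) stop("contacts must have two columns", call. = FALSE)
  if (nrow(contacts)) {
    if (any(contacts[, 1] < 1 | contacts[, 1] > length(residues_a)) ||
        any(contacts[, 2] < 1 | contacts[, 2] > length(residues_b)))
      stop("contact index out of range", call. = FALSE)
    if (anyDuplicated(contacts))
      stop("duplicate contact pairs", call. = FALSE)
    if (anyDuplicated(contacts[, 1]) || anyDuplicated(contacts[, 2]))
      stop("unrealisable spec: each residue may carry at most one intended contact",
           call. = FALSE)
  }
  # with the +-1.9 A atom offsets a CA-CA separation of 5.0 A realises a
  # minimum heavy-atom distance ~4.1 A (< 5.5), while the 30 A grid spacing
  # keeps every unintended residue pair far outside the cutoff
  to3 <- function(x) ifelse(nchar(x) > 1, toupper(x), .aa1to3[toupper(x)])
  res_a <- to3(residues_a); res_b <- to3(residues_b)
  if (anyNA(c(res_a, res_b))) stop("unknown residue code", call. = FALSE)

  # lay residues on a coarse grid; move contact partners next to their mate
  rows <- list(); k <- 0
  pos_a <- cbind(seq_along(res_a) * spacing, 0, 0)
  pos_b <- cbind(seq_along(res_b) * spacing, spacing * 4, 0)
  if (nrow(contacts)) {
    for (r in seq_len(nrow(contacts))) {
      i <- contacts[r, 1]; j <- contacts[r, 2]
      # place the pair on its own site, x offset by a private lane
      site <- c(r * spacing, -spacing * (4 + r), 0)
      pos_a[i, ] <- site
      pos_b[j, ] <- site + c(0, contact_distance, 0)
    }
  }
  atoms <- rbind(
    do.call(rbind, lapply(seq_along(res_a), function(i)
      toy_atoms(chain_ids[1], i, res_a[i], pos_a[i, ]))),
    do.call(rbind, lapply(seq_along(res_b), function(j)
      toy_atoms(chain_ids[2], j, res_b[j], pos_b[j, ])))
  )
  st <- new_ab_structure(atoms, source = "toy complex")
  part <- partition_complex(st, chain_ids[1], chain_ids[2])

  found <- find_contacts(part)
  want <- if (nrow(contacts))
    sort(paste(contacts[, 1], contacts[, 2])) else character(0)
  got <- sort(paste(found$resno_a, found$resno_b))
  if (!identical(want, got))
    stop("generation self-check failed: realised contacts differ from spec",
         call. = FALSE)
  tally <- tally_contacts(found)
  list(structure = st, partition = part, contacts = found, tally = tally)
}

#' Toy complex realising prescribed contact-tally multiplicities
#'
#' Builds isolated residue pairs so that the contact tally equals `counts`
#' exactly: e.g. `counts = c(cc = 7, cp = 7, ca = 16, pp = 2, pa = 8,
#' aa = 21)` reproduces a crystal-interface contact census.
#'
#' @param counts Named vector with entries among `cc`, `cp`, `ca`, `pp`,
#'   `pa`, `aa`.
#' @param n_spectators Non-interface residues appended per side (default 6,
#'   two of each character class) so the complex also has a non-interacting
#'   surface.
#' @param ... Passed to [make_toy_complex()].
#' @return As [make_toy_complex()].
#' @export
make_tally_fixture <- function(counts, n_spectators = 6, ...) {
  reps <- list(cc = c("E", "K"), cp = c("D", "S"), ca = c("R", "L"),
               pp = c("N", "T"), pa = c("Q", "V"), aa = c("I", "F"))
  res_a <- character(0); res_b <- character(0)
  for (k in names(.tally_names)) {
    n <- if (k %in% names(counts)) counts[[k]] else 0
    if (n > 0) {
      res_a <- c(res_a, rep(reps[[k]][1], n))
      res_b <- c(res_b, rep(reps[[k]][2], n))
    }
  }
  if (!length(res_a)) stop("empty tally specification", call. = FALSE)
  pairs <- cbind(seq_along(res_a), seq_along(res_b))
  spect <- rep(c("E", "D", "S", "T", "L", "F"),
               length.out = max(0, n_spectators))
  make_toy_complex(c(res_a, spect), c(res_b, spect), pairs, ...)
}

#' Random toy complex for property-style testing
#'
#' Scatters minimal residues of random type in two slabs a controllable gap
#' apart, so some cross-chain residue pairs fall near the contact cutoff.
#' No ground truth is bundled - intended for comparison against a
#' brute-force oracle.
#'
#' @param seed Integer seed.
#' @param n_a,n_b Residues per side.
#' @param box Slab edge length (A); smaller boxes give denser interfaces.
#' @param gap Offset between the two slabs along y (A).
#' @return List with `structure` and `partition`.
#' @export
random_toy_complex <- function(seed, n_a = 6, n_b = 6, box = 18, gap = 4) {
  set.seed(seed)
  res_a <- sample(unname(.aa1to3), n_a, replace = TRUE)
  res_b <- sample(unname(.aa1to3), n_b, replace = TRUE)
  pos <- function(n, y0) cbind(stats::runif(n, 0, box),
                               y0 + stats::runif(n, 0, box),
                               stats::runif(n, 0, box))
  pa <- pos(n_a, 0); pb <- pos(n_b, box + gap)
  atoms <- rbind(
    do.call(rbind, lapply(seq_len(n_a), function(i)
      toy_atoms("A", i, res_a[i], pa[i, ]))),
    do.call(rbind, lapply(seq_len(n_b), function(j)
      toy_atoms("B", j, res_b[j], pb[j, ])))
  )
  st <- new_ab_structure(atoms, source = sprintf("random toy (seed %d)", seed))
  list(structure = st, partition = partition_complex(st, "A", "B"))
}

# chromatogram generator --------------------------------------------------------

# log-linear retention: V_r = a - b log10(r_h [nm]); anchored so an IgG
# (5.5 nm) elutes at 17.5 mL and a 2:1 complex (7.4 nm) at 14.1 mL
.retention_a <- 17.5 + (17.5 - 14.1) / (log10(7.4) - log10(5.5)) * log10(5.5)
.retention_b <- (17.5 - 14.1) / (log10(7.4) - log10(5.5))

retention_volume <- function(r_h_nm) .retention_a - .retention_b * log10(r_h_nm)

#' Simulate a multi-detector SEC chromatogram
#'
#' Generates aligned RI/UV/RALS/LALS/VIS traces for a set of species.
#' Detector responses per species are proportional to c dn/dc (RI),
#' c dA/dc (UV), c Mw (dn/dc)^2 (RALS, LALS) and c \[eta\] (VIS); peak
#' positions follow a log-linear retention model in the hydrodynamic
#' radius, with Gaussian (or exponentially modified Gaussian) shapes and
#' optional multiplicative noise.
#'
#' @param species data.frame with one row per species: `conc_gL`, `Mw_kDa`,
#'   and optionally `r_h_nm` (default from a globular mass-radius rule),
#'   `dn_dc` (0.185), `dA_dc` (1.0), `eta` (6.5), `center_mL` (overrides the
#'   retention model), `sigma_mL` (0.25), `tau_mL` (0.1, EMG only).
#' @param k_RI,k_UV,k_LS Detector response constants.
#' @param volume_mL Retention grid (default 10-22 mL, 0.01 steps).
#' @param shape `"gaussian"` (default) or `"emg"`.
#' @param noise_sd Relative (multiplicative Gaussian) noise level, default 0
#'   (0.01 corresponds to SNR 100).
#' @param baseline_drift Linear baseline added to every trace over the full
#'   run (instrument-units, default 0).
#' @param seed Seed applied when noise is drawn (default 1).
#' @return A `chromatogram`; attribute `truth` stores the species table
#'   with realised centers and per-detector areas.
#' @export
simulate_chromatogram <- function(species, k_RI = 1000, k_UV = 800,
                                  k_LS = 0.02,
                                  volume_mL = seq(10, 22, by = 0.01),
                                  shape = c("gaussian", "emg"),
                                  noise_sd = 0, baseline_drift = 0,
                                  seed = 1) {
  shape <- match.arg(shape)
  sp <- as.data.frame(species)
  stopifnot(all(c("conc_gL", "Mw_kDa") %in% names(sp)))
  n <- nrow(sp)
  default <- function(col, val) if (col %in% names(sp)) sp[[col]] else
    rep(val, n)
  sp$dn_dc <- default("dn_dc", 0.185)
  sp$dA_dc <- default("dA_dc", 1.0)
  sp$eta <- default("eta", 6.5)
  sp$r_h_nm <- if ("r_h_nm" %in% names(sp)) sp$r_h_nm else
    1.45 * (sp$Mw_kDa)^(1 / 3)  # globular mass-radius rule of thumb
  sp$center_mL <- if ("center_mL" %in% names(sp)) sp$center_mL else
    retention_volume(sp$r_h_nm)
  sp$sigma_mL <- default("sigma_mL", 0.25)
  sp$tau_mL <- default("tau_mL", 0.1)

  resp <- list(
    RI = k_RI * sp$conc_gL * sp$dn_dc,
    UV = k_UV * sp$conc_gL * sp$dA_dc,
    RALS = k_LS * sp$conc_gL * (sp$Mw_kDa * 1000) * sp$dn_dc^2,
    LALS = 0.85 * k_LS * sp$conc_gL * (sp$Mw_kDa * 1000) * sp$dn_dc^2,
    VIS = 10 * sp$conc_gL * sp$eta
  )
  traces <- lapply(resp, function(areas) {
    tr <- numeric(length(volume_mL))
    for (j in seq_len(n))
      tr <- tr + if (shape == "gaussian")
        gaussian_peak(volume_mL, sp$center_mL[j], sp$sigma_mL[j], areas[j])
      else emg_peak(volume_mL, sp$center_mL[j], sp$sigma_mL[j], areas[j],
                    sp$tau_mL[j])
    tr
  })
  if (noise_sd > 0 || baseline_drift != 0) {
    set.seed(seed)
    traces <- stats::setNames(lapply(names(traces), function(d) {
      tr <- traces[[d]]
      if (noise_sd > 0)  # multiplicative: each point keeps its own SNR
        tr <- tr * (1 + stats::rnorm(length(tr), 0, noise_sd))
      tr + baseline_drift * seq(0, 1, length.out = length(tr))
    }), names(traces))
  }
  ch <- chromatogram(volume_mL, traces,
                     metadata = list(flow_mL_min = 0.5, injection_uL = 100,
                                     temperature_K = 309,
                                     shape = shape, noise_sd = noise_sd,
                                     seed = seed))
  truth <- sp
  for (d in names(resp)) truth[[paste0("area_", d)]] <- resp[[d]]
  attr(ch, "truth") <- truth
  ch
}

#' Paper-conditions mixture scenario
#'
#' Bundles a simulated equilibrium and the corresponding synthetic
#' chromatogram with full ground truth. Defaults emulate the trastuzumab
#' study mixture: totals 4.78 uM antibody / 1.46 uM antigen, masses
#' 147.0 / 86.4 kDa, and an association constant and cooperativity derived
#' at run time from that mixture's published equilibrium concentrations (so
#' the 1:1 and 2:1 complexes take up ~0.31 and ~0.10 of the total mass
#' concentration). `kind = "pertuzumab"` switches to the 4.76 / 1.16 uM,
#' 146.4 kDa conditions where the 2:1 complex dominates (~0.12 / ~0.27).
#'
#' @param kind `"trastuzumab"` (default) or `"pertuzumab"` preset, or
#'   `"custom"` (then `K_site` and `rho` are required).
#' @param K_site,rho Override the preset association constant (M^-1) and
#'   cooperativity.
#' @param c_a_uM,c_g_uM,M_a_kDa,M_g_kDa Totals and masses.
#' @param noise_sd Relative detector noise (default 0.01, i.e. SNR 100).
#' @param seed Seed for the noise draw.
#' @param ... Passed to [simulate_chromatogram()].
#' @return A `mixture_scenario`: list with `species` (ground-truth
#'   `species_concentrations`), `chromatogram`, `sec_truth`, `K_site`,
#'   `rho`, `equilibrium` (the Goldberg analysis of the truth) and the
#'   standard chromatogram used for calibration (`standard`).
#' @export
make_mixture_scenario <- function(kind = c("trastuzumab", "pertuzumab",
                                           "custom"),
                                  K_site = NULL, rho = NULL,
                                  c_a_uM = NULL, c_g_uM = NULL,
                                  M_a_kDa = NULL, M_g_kDa = 86.4,
                                  noise_sd = 0.01, seed = 1, ...) {
  kind <- match.arg(kind)
  preset <- switch(kind,
    trastuzumab = list(c_a = 4.78, c_g = 1.46, M_a = 147.0,
                       eq = c(c1 = 1.12, c2 = 0.26, free_ag = 0.08)),
    pertuzumab = list(c_a = 4.76, c_g = 1.16, M_a = 146.4,
                      eq = c(c1 = 0.42, c2 = 0.68, free_ag = 0.04)),
    custom = NULL)
  if (is.null(c_a_uM)) c_a_uM <- preset$c_a
  if (is.null(c_g_uM)) c_g_uM <- preset$c_g
  if (is.null(M_a_kDa)) M_a_kDa <- preset$M_a
  if (is.null(c_a_uM) || is.null(c_g_uM) || is.null(M_a_kDa))
    stop("custom scenarios need totals and masses", call. = FALSE)

  if (is.null(K_site) || is.null(rho)) {
    if (kind == "custom")
      stop("custom scenarios need K_site and rho", call. = FALSE)
    # derive K from the published equilibrium concentrations via the
    # package's own analysis chain, and rho from the 1:1 / 2:1 split
    p <- reacted_site_fraction(preset$eq[["free_ag"]], c_g_uM, 2)
    K_site <- goldberg_constant(
      p, c_a_uM * 1e-6 * M_a_kDa * 1000, c_g_uM * 1e-6 * M_g_kDa * 1000,
      M_a_kDa * 1000, M_g_kDa * 1000, 2)
    # solve rho so the simulated 1:1 / 2:1 split matches the published one
    target_ratio <- preset$eq[["c2"]] / preset$eq[["c1"]]
    fr <- function(log_rho) {
      s <- simulate_equilibrium(K_site, c_a_uM, c_g_uM, rho = exp(log_rho),
                                M_a_kDa = M_a_kDa, M_g_kDa = M_g_kDa)
      log(s$complex2_uM / s$complex1_uM) - log(target_ratio)
    }
    rho <- exp(stats::uniroot(fr, c(-12, 12), tol = 1e-10)$root)
  }

  species <- simulate_equilibrium(K_site, c_a_uM, c_g_uM, rho = rho,
                                  M_a_kDa = M_a_kDa, M_g_kDa = M_g_kDa,
                                  sample = kind)
  tab <- data.frame(
    name = c("free_ab", "free_ag", "complex1", "complex2"),
    conc_uM = c(species$free_ab_uM, species$free_ag_uM,
                species$complex1_uM, species$complex2_uM),
    Mw_kDa = c(M_a_kDa, M_g_kDa, M_a_kDa + M_g_kDa, M_a_kDa + 2 * M_g_kDa),
    r_h_nm = c(5.5, 4.7, 6.8, 7.4),
    dA_dc = c(1.38, 0.90, NA, NA))
  tab$conc_gL <- tab$conc_uM * tab$Mw_kDa / 1000
  # complexes: mass-weighted specific absorbance of their components
  tab$dA_dc[3] <- (tab$dA_dc[1] * M_a_kDa + tab$dA_dc[2] * M_g_kDa) /
    (M_a_kDa + M_g_kDa)
  tab$dA_dc[4] <- (tab$dA_dc[1] * M_a_kDa + 2 * tab$dA_dc[2] * M_g_kDa) /
    (M_a_kDa + 2 * M_g_kDa)

  ch <- simulate_chromatogram(tab, noise_sd = noise_sd, seed = seed, ...)
  standard <- simulate_chromatogram(
    data.frame(conc_gL = 2.0, Mw_kDa = 66.43, center_mL = 20.0,
               dA_dc = 0.66),
    noise_sd = 0, seed = seed)

  out <- list(species = species, chromatogram = ch,
              sec_truth = attr(ch, "truth"), standard = standard,
              K_site = K_site, rho = rho,
              equilibrium = suppressWarnings(analyze_mixture(species)),
              seed = seed)
  class(out) <- "mixture_scenario"
  out
}

#' @export
print.mixture_scenario <- function(x, ...) {
  cat(sprintf("Mixture scenario (%s): K = %.3g M^-1, rho = %.3g\n",
              x$species$sample, x$K_site, x$rho))
  print(x$species)
  invisible(x)
}

# IgG fixture --------------------------------------------------------------------

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

helix_positions <- function(n, origin, axis_step = 3.0, radius = 3.5) {
  t <- seq_len(n)
  cbind(origin[1] + t * axis_step,
        origin[2] + radius * cos(t * 100 * pi / 180),
        origin[3] + radius * sin(t * 100 * pi / 180))
}

#' Toy IgG-like fixture with one bound antigen
#'
#' Builds a minimal two-armed antibody: light chains `L` (arm 1) and `M`
#' (arm 2) as short helical traces radiating from a hinge, with a toy
#' antigen `G` bound at the tip of arm 1. With `symmetric = TRUE` arm 2 is
#' the exact two-fold (C2) rotation of arm 1 about the hinge axis, so
#' grafting the bound antigen onto arm 2 lands it in the mirror-symmetric
#' pose with zero fitting error. With `symmetric = FALSE` arm 2 sits at a
#' small angle `arm_angle` from arm 1, so the grafted antigen is forced
#' into the bound one (steric collapse by construction).
#'
#' @param symmetric Logical (default `TRUE`).
#' @param arm_angle Angle between the two arms when `symmetric = FALSE`,
#'   radians (default 0.05, i.e. nearly superposed arms).
#' @param n_res Residues per light chain (default 12).
#' @param seed Seed controlling the antigen's residue types.
#' @return List with `structure` (`ab_structure`), chain roles
#'   (`antigen = "G"`, `bound_light = "L"`, `free_light = "M"`).
#' @export
make_igg_fixture <- function(symmetric = TRUE, arm_angle = 0.05,
                             n_res = 12, seed = 1) {
  set.seed(seed)
  arm1 <- helix_positions(n_res, origin = c(5, 0, 0))
  tip <- arm1[n_res, ]
  ag_codes <- sample(unname(.aa1to3), 5, replace = TRUE)
  ag_pos <- sweep(helix_positions(5, origin = c(4, 2, 0)), 2, tip, "+")

  theta <- if (symmetric) pi else arm_angle
  arm2 <- arm1 %*% t(rot_z(theta))

  light <- sample(unname(.aa1to3), n_res, replace = TRUE)
  atoms <- rbind(
    do.call(rbind, lapply(seq_len(n_res), function(i)
      toy_atoms("L", i, light[i], arm1[i, ]))),
    do.call(rbind, lapply(seq_len(n_res), function(i)
      toy_atoms("M", i, light[i], arm2[i, ]))),
    do.call(rbind, lapply(seq_len(5), function(i)
      toy_atoms("G", i, ag_codes[i], ag_pos[i, ])))
  )
  # arm 2 must be an exact rigid copy of arm 1 residue-by-residue: rebuild
  # its atoms by transforming arm 1's atoms as a block
  a1 <- atoms[atoms$chain == "L", ]
  xyz2 <- as.matrix(a1[, c("x", "y", "z")]) %*% t(rot_z(theta))
  atoms[atoms$chain == "M", c("x", "y", "z")] <- xyz2
  st <- new_ab_structure(atoms, source = sprintf(
    "toy IgG (%s, seed %d)", if (symmetric) "symmetric" else "bent", seed))
  list(structure = st, antigen = "G", bound_light = "L", free_light = "M")
}
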