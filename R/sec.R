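# Multi-detector size-exclusion chromatography -------------------------------

.BOLTZMANN <- 1.380649e-23  # J/K

#' Chromatogram container
#'
#' @param volume_mL Strictly increasing retention-volume grid (mL).
#' @param traces Named list of equal-length signal vectors; canonical
#'   detector names are `RI`, `UV`, `RALS`, `LALS`, `VIS`.
#' @param metadata Named list (flow rate, injection volume, temperature, ...).
#' @return A `chromatogram` object.
#' @export
chromatogram <- function(volume_mL, traces, metadata = list()) {
  if (any(diff(volume_mL) <= 0))
    stop("retention-volume grid must be strictly increasing", call. = FALSE)
  if (!length(traces) || is.null(names(traces)) || any(names(traces) == ""))
    stop("traces must be a named list", call. = FALSE)
  len <- vapply(traces, length, integer(1))
  if (any(len != length(volume_mL)))
    stop("all traces must share the retention-volume grid", call. = FALSE)
  structure(list(volume_mL = volume_mL, traces = traces, metadata = metadata),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram: %d points, %.2f-%.2f mL, detectors: %s\n",
              length(x$volume_mL), min(x$volume_mL), max(x$volume_mL),
              paste(names(x$traces), collapse = ", ")))
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, detectors = names(x$traces), ...) {
  old <- graphics::par(no.readonly = TRUE); on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(max(3L, length(detectors)), "Dark 2")
  norm <- function(v) if (max(abs(v)) > 0) v / max(abs(v)) else v
  graphics::plot(range(x$volume_mL), c(0, 1.05), type = "n",
                 xlab = "retention volume (mL)",
                 ylab = "normalised signal", ...)
  for (i in seq_along(detectors))
    graphics::lines(x$volume_mL, norm(x$traces[[detectors[i]]]), col = cols[i])
  graphics::legend("topright", legend = detectors,
                   col = cols[seq_along(detectors)], lty = 1, bty = "n")
  invisible(x)
}

# peak shapes ------------------------------------------------------------------

gaussian_peak <- function(v, center, sigma, area) {
  area / (sigma * sqrt(2 * pi)) * exp(-(v - center)^2 / (2 * sigma^2))
}

# exponentially modified Gaussian (tailing); tau > 0 in mL
emg_peak <- function(v, center, sigma, area, tau) {
  z <- (sigma / tau - (v - center) / sigma) / sqrt(2)
  # erfc via pnorm: erfc(z) = 2 pnorm(-z sqrt(2)); log scale to avoid overflow
  log_h <- log(area / (2 * tau)) + sigma^2 / (2 * tau^2) - (v - center) / tau +
    log(2) + stats::pnorm(-z * sqrt(2), log.p = TRUE)
  exp(log_h)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# local maxima above frac of the global maximum, separated by > min_sep mL;
# a light running-mean smooth suppresses noise-induced maxima
find_peaks <- function(volume, signal, frac = 0.05, min_sep = 0.3) {
  if (length(signal) > 15) {
    sm <- stats::filter(signal, rep(1 / 7, 7), sides = 2)
    signal <- ifelse(is.na(sm), signal, as.numeric(sm))
  }
  thr <- frac * max(signal)
  n <- length(signal)
  cand <- which(signal > thr &
                  signal >= c(-Inf, signal[-n]) &
                  signal >= c(signal[-1], -Inf))
  if (!length(cand)) return(integer(0))
  keep <- cand[1]
  for (i in cand[-1]) {
    if (volume[i] - volume[keep[length(keep)]] > min_sep) keep <- c(keep, i)
    else if (signal[i] > signal[keep[length(keep)]]) keep[length(keep)] <- i
  }
  keep
}

# calibration ------------------------------------------------------------------

#' Calibrate detector response constants from a single standard
#'
#' Integrates each detector trace over the standard's (single) peak and
#' derives the per-detector response constants:
#' k_RI = area_RI / (c dn/dc), k_UV = area_UV / (c dA/dc),
#' k_LS = area_LS / (c Mw (dn/dc)^2), with c the injected mass concentration
#' in g/L. Doubling the injected concentration therefore leaves the
#' constants unchanged.
#'
#' @param standard_chromatogram A `chromatogram` of the standard run (e.g.
#'   bovine serum albumin).
#' @param standard_Mw Standard molar mass, g/mol (BSA: 66430).
#' @param standard_conc Injected mass concentration, g/L.
#' @param standard_dn_dc Refractive-index increment, mL/g (default 0.185).
#' @param standard_dA_dc Specific absorbance at 280 nm (A per g/L per cm);
#'   default 0.66, typical for BSA.
#' @param ls_detector Which light-scattering trace calibrates k_LS
#'   (default `"RALS"`).
#' @return A `sec_calibration`: list with `k_RI`, `k_UV`, `k_LS` and the
#'   standard's properties.
#' @export
sec_calibrate <- function(standard_chromatogram, standard_Mw = 66430,
                          standard_conc = 2.0, standard_dn_dc = 0.185,
                          standard_dA_dc = 0.66, ls_detector = "RALS") {
  ch <- standard_chromatogram
  stopifnot(inherits(ch, "chromatogram"))
  for (d in c("RI", "UV", ls_detector))
    if (is.null(ch$traces[[d]]))
      stop("standard chromatogram lacks detector ", d, call. = FALSE)
  if (max(ch$traces$RI) <= 0)
    stop("zero-signal RI trace: cannot calibrate", call. = FALSE)
  pk <- find_peaks(ch$volume_mL, ch$traces$RI)
  if (length(pk) != 1L)
    stop("standard run must contain exactly one resolved peak (found ",
         length(pk), ")", call. = FALSE)
  area <- function(d) trapz(ch$volume_mL, ch$traces[[d]])
  out <- list(
    k_RI = area("RI") / (standard_conc * standard_dn_dc),
    k_UV = area("UV") / (standard_conc * standard_dA_dc),
    k_LS = area(ls_detector) / (standard_conc * standard_Mw * standard_dn_dc^2),
    ls_detector = ls_detector,
    standard = list(Mw = standard_Mw, conc = standard_conc,
                    dn_dc = standard_dn_dc, dA_dc = standard_dA_dc))
  if (any(unlist(out[c("k_RI", "k_UV", "k_LS")]) <= 0))
    stop("calibration produced non-positive constants", call. = FALSE)
  class(out) <- "sec_calibration"
  out
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf("SEC calibration (standard Mw %.0f): k_RI = %.4g, k_UV = %.4g, k_LS = %.4g (%s)\n",
              x$standard$Mw, x$k_RI, x$k_UV, x$k_LS, x$ls_detector))
  invisible(x)
}

# deconvolution ----------------------------------------------------------------

#' Deconvolve a chromatogram into peaks
#'
#' Fits the RI (concentration) trace as a sum of `n_peaks` Gaussian or
#' exponentially-modified-Gaussian peaks by nonlinear least squares
#' (Levenberg-Marquardt). The fitted centers and widths are then transferred
#' to every other detector, whose per-peak areas are obtained by re-fitting
#' amplitudes only (a linear least-squares step), which apportions
#' overlapping peaks consistently across detectors.
#'
#' @param chrom A `chromatogram` with an `RI` trace.
#' @param n_peaks Number of peaks (>= 1).
#' @param init Optional initialisation: data.frame/list with `center`,
#'   `sigma` (and `tau` for `shape = "emg"`); defaults to the `n_peaks`
#'   largest local maxima with sigma 0.2 mL.
#' @param shape `"gaussian"` (default) or `"emg"`.
#' @param max_iter Maximum optimiser evaluations (default 5000).
#' @return A `sec_fit`: list with `peaks` (center, sigma, tau, area on the
#'   RI trace), `areas` (detector x peak matrix), fit diagnostics
#'   (`rms_residual`, `converged`), the shape and the input chromatogram.
#' @export
sec_deconvolve <- function(chrom, n_peaks, init = NULL,
                           shape = c("gaussian", "emg"), max_iter = 5000) {
  shape <- match.arg(shape)
  stopifnot(inherits(chrom, "chromatogram"), n_peaks >= 1)
  v <- chrom$volume_mL
  y <- chrom$traces$RI
  if (is.null(y)) stop("chromatogram lacks an RI trace", call. = FALSE)

  if (is.null(init)) {
    # relax the prominence threshold until enough maxima emerge
    for (frac in c(0.05, 0.02, 0.005, 0.002)) {
      pk <- find_peaks(v, y, frac = frac)
      if (length(pk) >= n_peaks) break
    }
    if (length(pk) < n_peaks) {
      # fall back to evenly spaced centers across the signal support
      supp <- range(v[y > 0.05 * max(y)])
      centers <- seq(supp[1], supp[2], length.out = n_peaks)
    } else {
      pk <- pk[order(-y[pk])][seq_len(n_peaks)]
      centers <- sort(v[pk])
    }
    init <- list(center = centers, sigma = rep(0.2, n_peaks),
                 tau = rep(0.1, n_peaks))
  }
  if (!all(is.finite(unlist(init)))) stop("non-finite initial guesses",
                                          call. = FALSE)

  model_mat <- function(center, sigma, tau) {
    m <- matrix(0, length(v), n_peaks)
    for (j in seq_len(n_peaks))
      m[, j] <- if (shape == "gaussian") gaussian_peak(v, center[j], sigma[j], 1)
        else emg_peak(v, center[j], sigma[j], 1, tau[j])
    m
  }

  # parameters: per peak center, log sigma (, log tau); amplitudes linear
  pack <- function(center, sigma, tau)
    c(center, log(sigma), if (shape == "emg") log(tau))
  unpack <- function(par) {
    center <- par[seq_len(n_peaks)]
    sigma <- exp(par[n_peaks + seq_len(n_peaks)])
    tau <- if (shape == "emg") exp(par[2 * n_peaks + seq_len(n_peaks)])
      else rep(NA_real_, n_peaks)
    list(center = center, sigma = sigma, tau = tau)
  }
  resid_fun <- function(par) {
    p <- unpack(par)
    m <- model_mat(p$center, p$sigma, p$tau)
    amp <- tryCatch(stats::coef(stats::lm.fit(m, y)), error = function(e) NULL)
    if (is.null(amp)) return(rep(1e6, length(y)))
    amp[is.na(amp)] <- 0
    amp <- pmax(amp, 0)
    y - as.numeric(m %*% amp)
  }
  fit <- minpack.lm::nls.lm(
    par = pack(init$center, init$sigma,
               if (is.null(init$tau)) rep(0.1, n_peaks) else init$tau),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = min(1024, max_iter),
                                         ftol = 1e-12, ptol = 1e-12))
  p <- unpack(fit$par)
  m <- model_mat(p$center, p$sigma, p$tau)
  amp_ri <- pmax(stats::coef(stats::lm.fit(m, y)), 0)
  resid <- y - as.numeric(m %*% amp_ri)
  rms <- sqrt(mean(resid^2))
  converged <- fit$info %in% 1:4
  if (!converged)
    stop("peak fit did not converge (info ", fit$info, ", RMS residual ",
         signif(rms, 3), ")", call. = FALSE)

  ord <- order(p$center)
  peaks <- data.frame(center = p$center[ord], sigma = p$sigma[ord],
                      tau = p$tau[ord], area = amp_ri[ord])
  # amplitude-only transfer to the other detectors
  m <- m[, ord, drop = FALSE]
  areas <- matrix(NA_real_, length(chrom$traces), n_peaks,
                  dimnames = list(names(chrom$traces), NULL))
  for (d in names(chrom$traces)) {
    amp <- pmax(stats::coef(stats::lm.fit(m, chrom$traces[[d]])), 0)
    areas[d, ] <- amp
  }
  out <- list(peaks = peaks, areas = areas, rms_residual = rms,
              converged = converged, shape = shape, chromatogram = chrom)
  class(out) <- "sec_fit"
  out
}

#' @export
print.sec_fit <- function(x, ...) {
  cat(sprintf("SEC deconvolution: %d %s peak(s), RMS residual %.3g\n",
              nrow(x$peaks), x$shape, x$rms_residual))
  print(cbind(round(x$peaks, 4)))
  invisible(x)
}

#' @export
coef.sec_fit <- function(object, ...) object$peaks

#' @export
fitted.sec_fit <- function(object, ...) {
  v <- object$chromatogram$volume_mL
  p <- object$peaks
  total <- numeric(length(v))
  for (j in seq_len(nrow(p)))
    total <- total + if (object$shape == "gaussian")
      gaussian_peak(v, p$center[j], p$sigma[j], p$area[j])
    else emg_peak(v, p$center[j], p$sigma[j], p$area[j], p$tau[j])
  total
}

#' @export
residuals.sec_fit <- function(object, ...) {
  object$chromatogram$traces$RI - fitted(object)
}

#' @export
plot.sec_fit <- function(x, ...) {
  v <- x$chromatogram$volume_mL
  graphics::plot(v, x$chromatogram$traces$RI, type = "l",
                 xlab = "retention volume (mL)", ylab = "RI signal", ...)
  graphics::lines(v, fitted(x), col = "red", lty = 2)
  for (j in seq_len(nrow(x$peaks))) {
    comp <- if (x$shape == "gaussian")
      gaussian_peak(v, x$peaks$center[j], x$peaks$sigma[j], x$peaks$area[j])
    else emg_peak(v, x$peaks$center[j], x$peaks$sigma[j], x$peaks$area[j],
                  x$peaks$tau[j])
    graphics::lines(v, comp, col = "grey50", lty = 3)
  }
  invisible(x)
}

# derived quantities ------------------------------------------------------------

#' Absolute molar mass of a deconvolved peak
#'
#' Mw = (area_LS / k_LS) / ((area_RI / k_RI) * dn/dc): the light-scattering
#' signal is proportional to c Mw (dn/dc)^2, the RI signal to c dn/dc, so
#' their calibrated ratio is absolute and independent of concentration.
#'
#' @param fit A `sec_fit`.
#' @param calibration A `sec_calibration`.
#' @param dn_dc Refractive-index increment of the species, mL/g.
#' @param peak Peak index (default: all peaks).
#' @return Molar mass(es) in kDa.
#' @export
sec_molar_mass <- function(fit, calibration, dn_dc = 0.185,
                           peak = seq_len(nrow(fit$peaks))) {
  ls <- fit$areas[calibration$ls_detector, peak]
  ri <- fit$areas["RI", peak]
  if (any(ri <= 0)) stop("vanishing RI area for requested peak(s)",
                         call. = FALSE)
  conc <- ri / (calibration$k_RI * dn_dc)       # g/L
  mw <- (ls / calibration$k_LS) / (conc * dn_dc^2)  # g/mol
  unname(mw) / 1000
}

#' Specific absorbance (dA/dc) of a deconvolved peak
#'
#' dA/dc = (area_UV / k_UV) / (area_RI / (k_RI dn/dc)): the UV area is
#' proportional to c dA/dc and the RI-derived concentration cancels c.
#'
#' @inheritParams sec_molar_mass
#' @return dA/dc value(s), A per (g/L) per cm.
#' @export
sec_absorption_coefficient <- function(fit, calibration, dn_dc = 0.185,
                                       peak = seq_len(nrow(fit$peaks))) {
  uv <- fit$areas["UV", peak]
  ri <- fit$areas["RI", peak]
  if (any(ri <= 0)) stop("vanishing RI area for requested peak(s)",
                         call. = FALSE)
  conc <- ri / (calibration$k_RI * dn_dc)
  unname((uv / calibration$k_UV) / conc)
}

#' Mass and molar concentrations of deconvolved peaks
#'
#' @inheritParams sec_molar_mass
#' @param Mw_kDa Optional known molar masses per peak (kDa); measured from
#'   the light-scattering ratio when `NULL`.
#' @return data.frame per peak: `center`, `conc_gL`, `Mw_kDa`, `conc_uM`,
#'   `fraction_ct` (share of the total mass concentration).
#' @export
sec_quantify <- function(fit, calibration, dn_dc = 0.185, Mw_kDa = NULL) {
  ri <- unname(fit$areas["RI", ])
  conc <- ri / (calibration$k_RI * dn_dc)
  if (is.null(Mw_kDa)) Mw_kDa <- sec_molar_mass(fit, calibration, dn_dc)
  data.frame(center = fit$peaks$center, conc_gL = conc, Mw_kDa = Mw_kDa,
             conc_uM = conc / Mw_kDa * 1000,
             fraction_ct = conc / sum(conc))
}

# small physical utilities -------------------------------------------------------

#' Stokes-Einstein conversion between diffusion coefficient and radius
#'
#' D_s = k_B T / (6 pi eta r_h). Supply exactly one of `D_s` (m^2/s) or
#' `r_h` (m) and the other is returned.
#'
#' @param D_s Diffusion coefficient, m^2/s.
#' @param r_h Hydrodynamic radius, m.
#' @param temperature Absolute temperature, K (default 309).
#' @param viscosity Solvent viscosity, Pa s (default 7.0e-4, water near
#'   36 C).
#' @return The missing quantity (r_h in m, or D_s in m^2/s).
#' @export
stokes_einstein <- function(D_s = NULL, r_h = NULL, temperature = 309,
                            viscosity = 7.0e-4) {
  if (is.null(D_s) == is.null(r_h))
    stop("supply exactly one of D_s or r_h", call. = FALSE)
  known <- if (is.null(D_s)) r_h else D_s
  if (any(known <= 0) || temperature <= 0 || viscosity <= 0)
    stop("all inputs must be positive", call. = FALSE)
  .BOLTZMANN * temperature / (6 * pi * viscosity * known)
}

#' Extinction coefficient and specific absorbance from residue counts
#'
#' Gill-von Hippel estimate at 280 nm:
#' eps = 5690 n_Trp + 1280 n_Tyr + 120 n_cystine (M^-1 cm^-1);
#' dA/dc = eps / Mw, the absorbance of a 1 g/L solution in a 1 cm cell.
#'
#' @param n_trp,n_tyr,n_cystine Residue counts (cystine = disulfide pairs).
#' @param Mw Molar mass, g/mol.
#' @return List with `epsilon_280` (M^-1 cm^-1) and `dA_dc`.
#' @export
extinction_from_sequence <- function(n_trp, n_tyr, n_cystine = 0, Mw) {
  if (any(c(n_trp, n_tyr, n_cystine) < 0) || any(Mw <= 0))
    stop("counts must be >= 0 and Mw > 0", call. = FALSE)
  eps <- 5690 * n_trp + 1280 * n_tyr + 120 * n_cystine
  list(epsilon_280 = eps, dA_dc = eps / Mw)
}

# chromatogram CSV dialect --------------------------------------------------------

#' Write a chromatogram to CSV
#'
#' Columns `volume_mL` then one per detector; metadata as `# key=value`
#' header lines.
#'
#' @param chrom A `chromatogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (k in names(chrom$metadata))
    writeLines(sprintf("# %s=%s", k, format(chrom$metadata[[k]])), con)
  df <- data.frame(volume_mL = chrom$volume_mL, chrom$traces,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a chromatogram from CSV
#' @param path CSV path in the dialect of [write_chromatogram_csv()].
#' @return A `chromatogram`.
#' @export
read_chromatogram_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      val <- suppressWarnings(as.numeric(kv[2]))
      meta[[trimws(kv[1])]] <- if (is.na(val)) trimws(kv[2]) else val
    }
  }
  df <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                            invert = TRUE)),
                        check.names = FALSE)
  chromatogram(df$volume_mL, as.list(df[setdiff(names(df), "volume_mL")]),
               meta)
}
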