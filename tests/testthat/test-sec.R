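std_chrom <- function(conc = 2.0, k_RI = 1000, k_UV = 800, k_LS = 0.02)
  simulate_chromatogram(
    data.frame(conc_gL = conc, Mw_kDa = 66.43, center_mL = 20.0,
               dA_dc = 0.66),
    k_RI = k_RI, k_UV = k_UV, k_LS = k_LS, noise_sd = 0)

test_that("single-standard calibration recovers the generating constants", {
  cal <- sec_calibrate(std_chrom(), standard_Mw = 66430, standard_conc = 2.0,
                       standard_dn_dc = 0.185, standard_dA_dc = 0.66)
  expect_equal(cal$k_RI, 1000, tolerance = 1e-3)
  expect_equal(cal$k_UV, 800, tolerance = 1e-3)
  expect_equal(cal$k_LS, 0.02, tolerance = 1e-3)
})

test_that("calibration constants are invariant to the injected concentration", {
  c1 <- sec_calibrate(std_chrom(conc = 1.0), standard_conc = 1.0)
  c2 <- sec_calibrate(std_chrom(conc = 2.0), standard_conc = 2.0)
  expect_equal(c1$k_RI, c2$k_RI, tolerance = 1e-9)
  expect_equal(c1$k_LS, c2$k_LS, tolerance = 1e-9)
})

test_that("degenerate standards are rejected", {
  ch <- std_chrom()
  flat <- chromatogram(ch$volume_mL,
                       lapply(ch$traces, function(x) x * 0))
  expect_error(sec_calibrate(flat), "zero-signal")
  two <- simulate_chromatogram(
    data.frame(conc_gL = c(1, 1), Mw_kDa = c(66, 140),
               center_mL = c(16, 20)), noise_sd = 0)
  expect_error(sec_calibrate(two), "exactly one")
})

test_that("a single noise-free peak is recovered to high accuracy", {
  ch <- std_chrom()
  fit <- sec_deconvolve(ch, n_peaks = 1)
  truth <- attr(ch, "truth")
  expect_equal(fit$peaks$center, 20.0, tolerance = 0.005 / 20)
  expect_equal(fit$peaks$sigma, 0.25, tolerance = 0.005)
  expect_equal(fit$peaks$area, truth$area_RI, tolerance = 0.005)
  expect_lt(fit$rms_residual / max(ch$traces$RI), 1e-6)
})

test_that("two peaks 2.5 sigma apart resolve to within 2% in area at SNR 100", {
  sp <- data.frame(conc_gL = c(0.6, 0.4), Mw_kDa = c(150, 100),
                   center_mL = c(15.0, 15.625), sigma_mL = 0.25)
  ch <- simulate_chromatogram(sp, noise_sd = 0.01, seed = 11)
  fit <- sec_deconvolve(ch, n_peaks = 2)
  truth <- attr(ch, "truth")
  expect_equal(fit$peaks$area, truth$area_RI, tolerance = 0.02)
})

test_that("tailing peaks fit with the exponentially modified shape", {
  sp <- data.frame(conc_gL = 1.0, Mw_kDa = 150, center_mL = 16.0,
                   sigma_mL = 0.2, tau_mL = 0.3)
  ch <- simulate_chromatogram(sp, shape = "emg", noise_sd = 0)
  fit <- sec_deconvolve(ch, n_peaks = 1, shape = "emg",
                        init = list(center = 16.2, sigma = 0.25, tau = 0.15))
  truth <- attr(ch, "truth")
  expect_equal(fit$peaks$area, truth$area_RI, tolerance = 0.02)
  expect_equal(fit$peaks$tau, 0.3, tolerance = 0.05)
})

test_that("light-scattering over refractive index yields absolute molar mass", {
  cal <- sec_calibrate(std_chrom())
  sp <- data.frame(conc_gL = c(0.5, 0.1), Mw_kDa = c(147, 320),
                   center_mL = c(17.5, 14.1))
  ch <- simulate_chromatogram(sp, noise_sd = 0)
  fit <- sec_deconvolve(ch, n_peaks = 2)
  mw <- sec_molar_mass(fit, cal)
  expect_equal(mw, c(320, 147), tolerance = 0.01)  # peaks sorted by volume
})

test_that("molar mass is invariant to concentration scaling", {
  cal <- sec_calibrate(std_chrom())
  mk <- function(c0) {
    ch <- simulate_chromatogram(
      data.frame(conc_gL = c0, Mw_kDa = 234, center_mL = 15.4), noise_sd = 0)
    sec_molar_mass(sec_deconvolve(ch, n_peaks = 1), cal)
  }
  expect_equal(mk(0.2), mk(1.0), tolerance = 1e-6)
})

test_that("the standard run returns the standard's own molar mass", {
  cal <- sec_calibrate(std_chrom(), standard_Mw = 66430)
  fit <- sec_deconvolve(std_chrom(), n_peaks = 1)
  expect_equal(sec_molar_mass(fit, cal), 66.43, tolerance = 0.005)
})

test_that("specific absorbance comes out of the UV/RI ratio", {
  cal <- sec_calibrate(std_chrom())
  for (dadc in c(1.38, 0.90)) {
    ch <- simulate_chromatogram(
      data.frame(conc_gL = 0.5, Mw_kDa = 147, center_mL = 17.5,
                 dA_dc = dadc), noise_sd = 0)
    fit <- sec_deconvolve(ch, n_peaks = 1)
    expect_equal(sec_absorption_coefficient(fit, cal), dadc,
                 tolerance = 0.01)
  }
  # a chromophore-free species gives zero
  ch0 <- simulate_chromatogram(
    data.frame(conc_gL = 0.5, Mw_kDa = 147, center_mL = 17.5, dA_dc = 0),
    noise_sd = 0)
  fit0 <- sec_deconvolve(ch0, n_peaks = 1)
  expect_equal(sec_absorption_coefficient(fit0, cal), 0, tolerance = 1e-6)
})

test_that("deconvolved mass concentrations conserve the injected total", {
  cal <- sec_calibrate(std_chrom())
  sp <- data.frame(conc_gL = c(0.49, 0.31, 0.10, 0.10),
                   Mw_kDa = c(147, 234, 320, 86.4),
                   center_mL = c(17.5, 15.4, 14.1, 19.3))
  ch <- simulate_chromatogram(sp, noise_sd = 0)
  q <- sec_quantify(sec_deconvolve(ch, n_peaks = 4), cal)
  expect_equal(sum(q$conc_gL), sum(sp$conc_gL), tolerance = 0.02)
  # and the published complex shares are reproduced within 2% of the total
  expect_equal(q$fraction_ct[q$center < 14.5], 0.10, tolerance = 0.02)
  expect_equal(q$fraction_ct[q$center > 15 & q$center < 16], 0.31,
               tolerance = 0.02)
})

test_that("Stokes-Einstein converts both ways and scales as expected", {
  D <- 5.81e-11
  r <- stokes_einstein(D_s = D, temperature = 309, viscosity = 7.0e-4)
  expect_equal(r * 1e9, 5.57, tolerance = 0.01)  # ~5.5 nm antibody
  expect_equal(stokes_einstein(r_h = r, temperature = 309,
                               viscosity = 7.0e-4), D, tolerance = 1e-12)
  # halving the viscosity doubles the diffusion coefficient
  expect_equal(stokes_einstein(r_h = r, viscosity = 3.5e-4) /
                 stokes_einstein(r_h = r, viscosity = 7.0e-4), 2,
               tolerance = 1e-12)
  expect_error(stokes_einstein(D_s = D, r_h = r), "exactly one")
  expect_error(stokes_einstein(D_s = -1), "positive")
})

test_that("residue counts give the 280 nm extinction and specific absorbance", {
  expect_equal(extinction_from_sequence(0, 0, 0, 1000)$epsilon_280, 0)
  # toy 20-mer: 2 Trp + 3 Tyr + 1 cystine
  ext <- extinction_from_sequence(2, 3, 1, 2500)
  expect_equal(ext$epsilon_280, 15340)
  # unit identity: one Trp in a 5690 g/mol protein absorbs 1.0 per g/L
  expect_equal(extinction_from_sequence(1, 0, 0, 5690)$dA_dc, 1.0)
  expect_error(extinction_from_sequence(-1, 0, 0, 100), ">= 0")
})

test_that("chromatograms survive the CSV round trip with metadata", {
  ch <- std_chrom()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram_csv(ch, tmp)
  back <- read_chromatogram_csv(tmp)
  expect_equal(back$volume_mL, ch$volume_mL)
  expect_equal(back$traces$RI, ch$traces$RI, tolerance = 1e-6)
  expect_equal(back$metadata$flow_mL_min, 0.5)
})

test_that("chromatogram construction validates its grid and traces", {
  expect_error(chromatogram(c(1, 1, 2), list(RI = 1:3)), "increasing")
  expect_error(chromatogram(1:3, list(RI = 1:2)), "share the")
  expect_error(chromatogram(1:3, list(1:3)), "named")
})
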