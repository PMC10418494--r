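single_atom <- function(elesy = "C", x = 0)
  atoms_structure(x = x, y = 0, z = 0, elesy = elesy,
                  elety = if (elesy == "C") "CA" else elesy)

test_that("an isolated atom exposes its full probe-expanded sphere", {
  for (el in c("C", "N", "O", "S")) {
    r <- abaffinity:::.vdw_radii[[el]] + 1.4
    s <- compute_sasa(single_atom(el))
    expect_equal(s$total, 4 * pi * r^2, tolerance = 1e-10)
  }
})

test_that("two distant atoms each expose a full sphere; overlapping atoms match the cap formula", {
  r <- 1.70 + 1.4
  far <- atoms_structure(x = c(0, 10), y = 0, z = 0, resno = 1:2)
  expect_equal(compute_sasa(far)$total, 2 * 4 * pi * r^2, tolerance = 1e-10)

  for (d in c(2.0, 3.0, 4.5, 6.0)) {
    st <- atoms_structure(x = c(0, d), y = 0, z = 0, resno = 1:2)
    got <- compute_sasa(st)$total
    want <- oracle_two_sphere_area(r, r, d)
    expect_equal(got, want, tolerance = 0.02, label = sprintf("d = %g", d))
  }
  # mixed radii
  st <- atoms_structure(x = c(0, 2.5), y = 0, z = 0, resno = 1:2,
                        elesy = c("C", "O"), elety = c("CA", "O"))
  want <- oracle_two_sphere_area(1.70 + 1.4, 1.52 + 1.4, 2.5)
  expect_equal(compute_sasa(st)$total, want, tolerance = 0.02)
})

test_that("SASA converges as the sphere lattice is refined", {
  # a single sphere is lattice-exact; occlusion error shrinks with n
  st1 <- single_atom()
  for (n in c(240, 960, 3840))
    expect_equal(compute_sasa(st1, n_points = n)$total,
                 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-10)
  fx <- make_toy_complex(c("E", "K", "W"), c("D", "F", "Y"), cbind(1:3, 1:3))
  t240 <- compute_sasa(fx$structure, n_points = 240)$total
  t960 <- compute_sasa(fx$structure, n_points = 960)$total
  t3840 <- compute_sasa(fx$structure, n_points = 3840)$total
  expect_lt(abs(t960 - t240) / t960, 0.03)
  expect_lt(abs(t3840 - t960) / t3840, 0.01)
})

test_that("SASA respects the additivity bound, hence BSA is non-negative", {
  for (seed in c(3, 14, 27)) {
    toy <- random_toy_complex(seed, gap = 1)
    part <- toy$partition
    s_ab <- compute_sasa(part)$total
    s_a <- compute_sasa(abaffinity:::new_ab_structure(
      abaffinity:::side_atoms(part, "a")))$total
    s_b <- compute_sasa(abaffinity:::new_ab_structure(
      abaffinity:::side_atoms(part, "b")))$total
    expect_lte(s_ab, s_a + s_b + 1e-9)
    expect_gte(buried_surface_area(part)$bsa, -1e-9)
  }
})

test_that("unknown elements raise a parameterisation error", {
  expect_error(compute_sasa(single_atom("XX")), "radius")
})

test_that("NIS percentages sum to 100 and reflect the generator's class composition", {
  # no contacts: every residue is solvent-exposed, none interfacial
  fx <- make_toy_complex(c("E", "K", "R", "D"), c("S", "T", "L", "V", "F"),
                         matrix(numeric(0), 0, 2))
  nis <- nis_percentages(fx$partition, scheme = "ic_scheme")
  expect_equal(nis$nis_charged_pct + nis$nis_polar_pct + nis$nis_apolar_pct,
               100, tolerance = 1e-6)
  expect_identical(nis$n_nis, 9L)
  expect_equal(nis$nis_charged_pct, 100 * 4 / 9, tolerance = 1e-9)
  expect_equal(nis$nis_polar_pct, 100 * 2 / 9, tolerance = 1e-9)
  expect_equal(nis$nis_apolar_pct, 100 * 3 / 9, tolerance = 1e-9)
})

test_that("interface residues are excluded from the NIS count", {
  fx <- make_toy_complex(c("E", "K", "R", "D"), c("S", "T", "L", "V"),
                         cbind(1, 1))
  nis <- nis_percentages(fx$partition, scheme = "ic_scheme")
  # residues A1 (GLU) and B1 (SER) touch, leaving 6 NIS residues
  expect_identical(nis$n_nis, 6L)
  expect_equal(nis$nis_charged_pct, 100 * 3 / 6, tolerance = 1e-9)
})

test_that("residues below the surface threshold are excluded", {
  fx <- make_toy_complex(c("E", "K"), c("L", "V"), matrix(numeric(0), 0, 2))
  sasa <- compute_sasa(fx$partition)
  # an absurdly high threshold empties the NIS set
  expect_error(nis_percentages(fx$partition, sasa, threshold_pct = 1e6),
               "degenerate")
  # relative SASA of fully exposed toy residues is far above 5%
  expect_true(all(sasa$residues$rel_sasa > 50))
})

test_that("the histidine scheme switch moves HIS between classes", {
  fx <- make_toy_complex(c("H", "E"), c("L", "V"), matrix(numeric(0), 0, 2))
  ic <- nis_percentages(fx$partition, scheme = "ic_scheme")
  ns <- nis_percentages(fx$partition, scheme = "nis_scheme")
  expect_equal(ic$counts[["charged"]], 1)
  expect_equal(ns$counts[["charged"]], 2)
})

test_that("BSA vanishes for distant chains and reports the convention used", {
  fx <- make_toy_complex("A", "G", matrix(numeric(0), 0, 2))
  bs <- buried_surface_area(fx$partition)
  expect_equal(bs$bsa, 0, tolerance = 1e-6)
  expect_identical(nrow(bs$interface_a), 0L)

  touch <- make_toy_complex("E", "F", cbind(1, 1))
  full <- buried_surface_area(touch$partition)
  half <- buried_surface_area(touch$partition, halved = TRUE)
  expect_gt(full$bsa, 0)
  expect_equal(half$bsa, full$bsa / 2, tolerance = 1e-12)
  expect_gte(nrow(full$interface_a), 1L)
})

test_that("SASA, NIS and BSA are invariant under rigid motion within 0.5%", {
  # the sphere lattice is fixed in space, so rotational variance shrinks
  # with lattice resolution; 3840 points keeps it comfortably under 0.5%
  fx <- make_toy_complex(c("E", "K", "W", "N"), c("D", "F", "Y"),
                         cbind(1:2, 1:2))
  set.seed(9)
  moved <- rigid_move(fx$structure, random_rotation(), c(-7, 13, 2))
  part0 <- fx$partition
  part1 <- partition_complex(moved, "A", "B")
  expect_equal(compute_sasa(part1, n_points = 3840)$total,
               compute_sasa(part0, n_points = 3840)$total,
               tolerance = 0.005)
  expect_equal(buried_surface_area(part1, n_points = 3840)$bsa,
               buried_surface_area(part0, n_points = 3840)$bsa,
               tolerance = 0.005)
  # the NIS residue set is threshold-robust here, so the shares are identical
  n0 <- nis_percentages(part0); n1 <- nis_percentages(part1)
  expect_equal(n1$nis_charged_pct, n0$nis_charged_pct)
})

test_that("relative SASA uses the requested reference table", {
  st <- single_atom()
  s_nac <- compute_sasa(st, ref_table = "naccess")
  s_tien <- compute_sasa(st, ref_table = "tien")
  expect_equal(s_nac$residues$rel_sasa / s_tien$residues$rel_sasa,
               104 / 80.10, tolerance = 1e-9)  # GLY reference ratio
})
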