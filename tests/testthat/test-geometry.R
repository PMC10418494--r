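test_that("identical point sets superpose with zero residual and identity rotation", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  s <- superpose(x, x)
  expect_lt(s$rmsd, 1e-12)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("applied rigid transforms are recovered to numerical precision", {
  set.seed(2)
  for (i in 1:20) {
    x <- matrix(rnorm(36), 12, 3)
    R0 <- random_rotation()
    t0 <- rnorm(3, sd = 20)
    y <- sweep(x %*% t(R0), 2, t0, "+")
    s <- superpose(x, y)
    expect_lt(s$rmsd, 1e-9)
    expect_equal(s$rotation, R0, tolerance = 1e-9)
    expect_equal(s$translation, t0, tolerance = 1e-6)
    # and the transform reproduces the target coordinates
    expect_equal(apply_transform(x, s), y, tolerance = 1e-9)
  }
})

test_that("chirally inverted sets keep a proper rotation and non-zero residual", {
  set.seed(3)
  x <- matrix(rnorm(30), 10, 3)
  y <- x %*% diag(c(-1, 1, 1))  # reflection
  s <- superpose(x, y)
  expect_gt(s$rmsd, 0.1)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 1), "collinear")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  expect_error(superpose(matrix(0, 4, 3), matrix(0, 3, 3)), "paired")
})

test_that("the fitted RMSD is invariant under a common rigid motion", {
  set.seed(4)
  x <- matrix(rnorm(30), 10, 3)
  y <- x + matrix(rnorm(30, sd = 0.3), 10, 3)
  base <- superpose(x, y)$rmsd
  R <- random_rotation(); t0 <- c(4, -2, 9)
  s2 <- superpose(sweep(x %*% t(R), 2, t0, "+"),
                  sweep(y %*% t(R), 2, t0, "+"))
  expect_equal(s2$rmsd, base, tolerance = 1e-9)
})

test_that("superposition agrees with an established reference implementation", {
  set.seed(5)
  x <- matrix(rnorm(45), 15, 3)
  y <- x + matrix(rnorm(45, sd = 0.5), 15, 3)
  ours <- superpose(x, y)
  ref <- suppressWarnings(  # bio3d notes it defaults to all positions
    bio3d::fit.xyz(fixed = as.numeric(t(y)), mobile = as.numeric(t(x))))
  ref_rmsd <- sqrt(mean(rowSums(
    (matrix(ref, ncol = 3, byrow = TRUE) - y)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("grafting onto a symmetric antibody lands the antigen in the mirror pose", {
  igg <- make_igg_fixture(symmetric = TRUE, seed = 7)
  g <- graft_second_antigen(igg$structure, igg$antigen, igg$bound_light,
                            igg$free_light)
  expect_lt(g$superposition$rmsd, 1e-9)
  # mirror pose: the new chain equals the C2 rotation of the original antigen
  orig <- igg$structure$atoms[igg$structure$atoms$chain == "G", ]
  got <- g$structure$atoms[g$structure$atoms$chain == g$new_chain, ]
  want <- as.matrix(orig[, c("x", "y", "z")]) %*%
    t(abaffinity:::rot_z(pi))
  expect_equal(as.matrix(got[, c("x", "y", "z")]), want,
               tolerance = 1e-6, ignore_attr = TRUE)
  # purity: the original coordinates are untouched
  expect_identical(
    g$structure$atoms[seq_len(nrow(igg$structure$atoms)), ],
    igg$structure$atoms)
})

test_that("imperfectly matching light chains graft with a reported residual", {
  igg <- make_igg_fixture(symmetric = TRUE, seed = 8)
  st <- igg$structure
  set.seed(8)
  jitter_idx <- st$atoms$chain == "M"
  st$atoms[jitter_idx, c("x", "y", "z")] <-
    st$atoms[jitter_idx, c("x", "y", "z")] + rnorm(sum(jitter_idx) * 3, sd = 1)
  g <- graft_second_antigen(st, "G", "L", "M")
  expect_gt(g$superposition$rmsd, 0.5)
  expect_lt(g$superposition$rmsd, 3)
})

test_that("grafting validates its chain arguments", {
  igg <- make_igg_fixture()
  expect_error(graft_second_antigen(igg$structure, "G", "L", "Q"),
               "not present")
  expect_error(graft_second_antigen(igg$structure, "G", "L", "M",
                                    new_chain_id = "G"), "already in use")
})

test_that("clash reports count atom pairs exactly and bound the overlap fraction", {
  far <- make_toy_complex("A", "G", matrix(numeric(0), 0, 2))
  cr <- clash_report(far$structure, "A", "B", cutoff = 2.5)
  expect_identical(cr$n_atom_pairs_below_cutoff, 0L)
  expect_equal(cr$overlap_fraction, 0)
  expect_gt(cr$min_distance, 2.5)

  # an in-place duplicate overlaps completely
  st <- make_toy_complex("E", "F", cbind(1, 1))$structure
  dup <- st$atoms[st$atoms$chain == "A", ]
  dup$chain <- "C"
  both <- abaffinity:::new_ab_structure(rbind(st$atoms, dup))
  cr2 <- clash_report(both, "A", "C")
  expect_equal(cr2$overlap_fraction, 1)
  expect_equal(cr2$min_distance, 0)

  # constructed pairs: k atoms placed under the cutoff by design
  for (k in c(1L, 3L)) {
    xa <- seq_len(3) * 10
    xb <- c(seq_len(k) * 10 + 1.0, seq_len(3 - k) * 10 + 100)
    stk <- atoms_structure(x = c(xa, xb), y = 0, z = 0,
                           chain = rep(c("A", "B"), each = 3),
                           resno = rep(1:3, 2))
    crk <- clash_report(stk, "A", "B", cutoff = 2.5)
    expect_identical(crk$n_atom_pairs_below_cutoff, k)
    expect_identical(crk$n_atom_pairs_below_cutoff,
                     oracle_clash_count(stk, "A", "B", 2.5))
  }
})

test_that("a bent antibody forces the grafted antigen into the bound one", {
  bent <- make_igg_fixture(symmetric = FALSE, seed = 9)
  g <- graft_second_antigen(bent$structure, "G", "L", "M")
  cr <- clash_report(g$structure, "G", g$new_chain)
  expect_gt(cr$n_atom_pairs_below_cutoff, 0L)
  expect_identical(cr$n_atom_pairs_below_cutoff,
                   oracle_clash_count(g$structure, "G", "Z", 2.5))
  expect_error(clash_report(g$structure, "G", "missing"), "atoms")
})
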