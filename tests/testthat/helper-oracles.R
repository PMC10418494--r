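# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (plain loops, no shared code with the package
# internals) so they can arbitrate the package's optimised paths.

# all cross-partition residue pairs with any heavy-atom distance <= cutoff,
# by exhaustive enumeration
oracle_contact_pairs <- function(structure, side_a, side_b, cutoff = 5.5) {
  at <- structure$atoms
  aa <- at[at$chain %in% side_a, ]
  ab <- at[at$chain %in% side_b, ]
  res_a <- unique(paste(aa$chain, aa$resno, aa$ins, sep = "|"))
  res_b <- unique(paste(ab$chain, ab$resno, ab$ins, sep = "|"))
  out <- character(0)
  for (ra in res_a) {
    xa <- aa[paste(aa$chain, aa$resno, aa$ins, sep = "|") == ra,
             c("x", "y", "z")]
    for (rb in res_b) {
      xb <- ab[paste(ab$chain, ab$resno, ab$ins, sep = "|") == rb,
               c("x", "y", "z")]
      found <- FALSE
      for (i in seq_len(nrow(xa))) {
        for (j in seq_len(nrow(xb))) {
          d <- sqrt(sum((as.numeric(xa[i, ]) - as.numeric(xb[j, ]))^2))
          if (d <= cutoff) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) out <- c(out, paste(ra, rb, sep = "~"))
    }
  }
  sort(out)
}

contact_set_keys <- function(cs) {
  sort(paste(paste(cs$chain_a, cs$resno_a, cs$ins_a, sep = "|"),
             paste(cs$chain_b, cs$resno_b, cs$ins_b, sep = "|"), sep = "~"))
}

# exhaustive cross-set atom-pair count below cutoff
oracle_clash_count <- function(structure, chains_a, chains_b, cutoff) {
  at <- structure$atoms
  xa <- as.matrix(at[at$chain %in% chains_a, c("x", "y", "z")])
  xb <- as.matrix(at[at$chain %in% chains_b, c("x", "y", "z")])
  n <- 0L
  for (i in seq_len(nrow(xa)))
    for (j in seq_len(nrow(xb)))
      if (sqrt(sum((xa[i, ] - xb[j, ])^2)) < cutoff) n <- n + 1L
  n
}

# analytic SASA of two intersecting spheres of radius r1, r2 (already
# probe-expanded) at centre distance d: full spheres minus spherical caps
oracle_two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h1 + 4 * pi * r2^2 - 2 * pi * r2 * h2
}

# bare structure from an atom table (defaults: carbon CA atoms)
atoms_structure <- function(x, y, z, chain = "A", resno = seq_along(x),
                            resid = "GLY", elety = "CA", elesy = "C",
                            ins = "") {
  df <- data.frame(chain = chain, resno = resno, ins = ins, resid = resid,
                   elety = elety, elesy = elesy, x = x, y = y, z = z,
                   stringsAsFactors = FALSE)
  abaffinity:::new_ab_structure(df, source = "test fixture")
}

# a random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rigid_move <- function(structure, rot, shift) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

# published study mixtures (totals, equilibrium concentrations in uM;
# masses in kDa) used across equilibrium tests
study_mixtures <- function() {
  list(
    trastuzumab = list(c_a = 4.78, c_g = 1.46, c1 = 1.12, c2 = 0.26,
                       free_ab = 3.37, free_ag = 0.08, M_a = 147.0,
                       M_g = 86.4, K_a_1e7 = 2.49, delta_g = -10.4),
    pertuzumab = list(c_a = 4.76, c_g = 1.16, c1 = 0.42, c2 = 0.68,
                      free_ab = 3.36, free_ag = 0.04, M_a = 146.4,
                      M_g = 86.4, K_a_1e7 = 3.17, delta_g = -10.6)
  )
}

mixture_species <- function(m, sample = "x") {
  suppressWarnings(species_concentrations(
    m$c_a, m$c_g, m$c1, m$c2, m$free_ab, m$free_ag, m$M_a, m$M_g,
    sample = sample))
}
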