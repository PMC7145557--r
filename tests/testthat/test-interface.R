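test_that("SASA: isolated sphere, additivity, burial", {
  one <- conformation(toy_atoms(c(0, 0, 0), names = "C1"))
  expect_equal(sum(sasa(one)), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  two_far <- conformation(toy_atoms(rbind(c(0, 0, 0), c(50, 0, 0)),
                                    names = c("C1", "C2")))
  expect_equal(sum(sasa(two_far)), 2 * 4 * pi * 3.1^2, tolerance = 0.02)
  # an atom caged inside a dense shell is fully buried
  sp <- hairpinscape:::sphere_points(80) * 2.2
  cage <- conformation(toy_atoms(rbind(c(0, 0, 0), sp),
                                 names = paste0("C", 1:81)))
  expect_lt(sasa(cage)[1], 1e-6)
  expect_error(sasa(conformation(toy_atoms(c(0, 0, 0), names = "X1",
                                           element = "X"))),
               "X")
})

test_that("per-atom SASA agrees with a Monte-Carlo oracle within 3%", {
  hairpinscape:::with_seed(31, {
    xyz <- matrix(stats::rnorm(3 * 12, sd = 2.5), ncol = 3)
  })
  conf <- conformation(toy_atoms(xyz, names = paste0("C", 1:12)))
  got <- sasa(conf)
  want <- oracle_sasa(conf)
  total <- 4 * pi * 3.1^2
  expect_lt(max(abs(got - want)) / total, 0.03)
})

test_that("Coulomb energy: closed form, scaling, additivity", {
  mk <- function(d) {
    at <- rbind(
      toy_atoms(c(0, 0, 0), names = "NZ", resid = "LYS", resno = 1,
                chain = "B"),
      toy_atoms(c(d, 0, 0), names = "OP1", resid = "U", resno = 40,
                chain = "A"),
      toy_atoms(c(d + 50, 0, 0), names = "OP2", resid = "U", resno = 40,
                chain = "A"))
    at$serial <- seq_len(nrow(at))
    conformation(at)
  }
  # +1e vs -0.5e at 3.32 A (and -0.5e far away), vacuum dielectric
  e <- coulomb_energy(mk(3.32), dielectric = 1)
  manual <- 332.06 * (1 * -0.5) / 3.32 + 332.06 * (1 * -0.5) / (3.32 + 50)
  expect_equal(e, manual, tolerance = 1e-9)
  # doubling all distances halves the magnitude
  expect_equal(coulomb_energy(mk(2 * 3.32), dielectric = 1) /
                 332.06, (-0.5 / 6.64 - 0.5 / (6.64 + 50)) , tolerance = 1e-9)
  # naive double-loop oracle on a random charged complex
  hp <- build_hairpin(seed = 2)$conformation
  cx <- place_peptide(hp, "groove", seed = 1)$complex
  a <- cx$atoms
  qa <- hairpinscape:::charge_of_atoms(a[a$chain == "B", ])
  qb <- hairpinscape:::charge_of_atoms(a[a$chain == "A", ])
  pa <- as.matrix(a[a$chain == "B", c("x", "y", "z")])
  pb <- as.matrix(a[a$chain == "A", c("x", "y", "z")])
  acc <- 0
  for (i in seq_along(qa)) {
    if (qa[i] == 0) next
    for (j in seq_along(qb)) {
      if (qb[j] == 0) next
      acc <- acc + qa[i] * qb[j] / sqrt(sum((pa[i, ] - pb[j, ])^2))
    }
  }
  expect_equal(coulomb_energy(cx), 332.06 / 78.5 * acc, tolerance = 1e-9)
})

test_that("distance fingerprints: exact values and translation contract", {
  at <- rbind(
    toy_atoms(c(0, 0, 0), names = "CA", resid = "LYS", resno = 149,
              chain = "B", element = "C"),
    toy_atoms(c(4, 0, 0), names = "P", resid = "U", resno = 40, chain = "A"),
    toy_atoms(c(0, 6, 0), names = "C4", resid = "U", resno = 40,
              chain = "A"),
    toy_atoms(c(0, 1, 0), names = "N1", resid = "U", resno = 40,
              chain = "A"))
  at$serial <- seq_len(nrow(at))
  cx <- conformation(at)
  fp <- distance_fingerprint(cx)
  expect_equal(fp$ca_p, 4.0)
  expect_equal(fp$ca_c4, 6.0)
  hp <- build_hairpin(seed = 1)$conformation
  far <- place_peptide(hp, "distant", seed = 1)$complex
  fp_far <- distance_fingerprint(far)
  expect_true(all(fp_far$ca_p > 40))
  # rigid motion leaves fingerprints unchanged
  moved <- apply_rigid(far, hairpinscape:::with_seed(2, random_rigid_motion()))
  expect_equal(distance_fingerprint(moved)$ca_p, fp_far$ca_p,
               tolerance = 1e-9)
})

test_that("groove poses penetrate deeper than surface poses", {
  hp <- build_hairpin(template = family_template("M2"), seed = 1)$conformation
  groove <- place_peptide(hp, "groove", seed = 1)$complex
  surface <- place_peptide(hp, "surface", seed = 1)$complex
  fg <- distance_fingerprint(groove)
  fs <- distance_fingerprint(surface)
  expect_lt(mean(fg$ca_c4), mean(fs$ca_c4))
  # retracting the peptide weakens the Coulomb attraction
  eg <- coulomb_energy(groove)
  retracted <- place_peptide(hp, "surface", seed = 1)$complex
  expect_lt(eg, coulomb_energy(retracted))
  expect_lt(eg, 0)
})

test_that("gap index: slab monotonicity, grid stability, contact errors", {
  slab <- function(sep) {
    g <- as.matrix(expand.grid(x = seq(0, 12, by = 1.6),
                               y = seq(0, 12, by = 1.6)))
    a <- cbind(g, 0)
    b <- cbind(g, sep)
    at <- rbind(
      toy_atoms(a, names = paste0("C", seq_len(nrow(a))), resid = "GLY",
                resno = 1, chain = "B", element = "C"),
      toy_atoms(b, names = paste0("C", seq_len(nrow(b))), resid = "GLY",
                resno = 2, chain = "A", element = "C"))
    at$serial <- seq_len(nrow(at))
    conformation(at)
  }
  g1 <- gap_index(slab(4.2), grid = 0.8)
  g2 <- gap_index(slab(5.0), grid = 0.8)
  g3 <- gap_index(slab(5.8), grid = 0.8)
  expect_lt(g1$gap_index, g2$gap_index)
  expect_lt(g2$gap_index, g3$gap_index)
  # discretization stability: 0.8 vs 0.4 A within 15%
  fine <- gap_index(slab(5.0), grid = 0.4)
  expect_lt(abs(fine$gap_index - g2$gap_index) /
              max(fine$gap_index, g2$gap_index), 0.15)
  # symmetric in the chain roles
  swap <- gap_index(slab(5.0), pep_chain = "A", rna_chain = "B", grid = 0.8)
  expect_equal(swap$gap_index, g2$gap_index, tolerance = 1e-9)
  # chains far apart are not in contact
  hp <- build_hairpin(seed = 1)$conformation
  far <- place_peptide(hp, "distant", seed = 1)$complex
  expect_error(gap_index(far), "not in contact")
})

test_that("buried area is symmetric and positive only in contact", {
  hp <- build_hairpin(template = family_template("M2"), seed = 1)$conformation
  cx <- place_peptide(hp, "groove", seed = 1)$complex
  ba <- buried_area(cx)
  ba_swapped <- buried_area(cx, pep_chain = "A", rna_chain = "B")
  expect_equal(ba, ba_swapped, tolerance = 1e-9)
  expect_gt(ba, 0)
  far <- place_peptide(hp, "distant", seed = 1)$complex
  expect_lt(abs(buried_area(far)), 1e-6)
})

test_that("interface reports aggregate per-frame series", {
  hp <- build_hairpin(template = family_template("M2"), seed = 1)$conformation
  cx <- place_peptide(hp, "groove", seed = 1)$complex
  rep1 <- interface_report(cx)
  expect_equal(rep1$summary$sd, c(0, 0, 0))
  # duplicating the frame leaves means unchanged
  rep2 <- interface_report(ensemble(list(cx, cx)))
  expect_equal(rep2$summary$mean, rep1$summary$mean, tolerance = 1e-9)
  expect_true(all(rep2$hbond_persistence$fraction %in% c(0.5, 1) |
                    nrow(rep2$hbond_persistence) == 0))
})

test_that("groove complexes have a smaller mean gap index than surface ones", {
  hp <- build_hairpin(template = family_template("M2"), seed = 1)$conformation
  g <- gap_index(place_peptide(hp, "groove", seed = 1)$complex)$gap_index
  s <- gap_index(place_peptide(hp, "surface", seed = 1)$complex)$gap_index
  expect_lt(g, s)
})
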