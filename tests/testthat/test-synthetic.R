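test_that("generators are pure functions of arguments and seed", {
  a <- build_hairpin(seed = 5)$conformation
  b <- build_hairpin(seed = 5)$conformation
  expect_identical(a$atoms, b$atoms)
  c <- build_hairpin(seed = 6)$conformation
  expect_false(identical(a$atoms, c$atoms))
  j1 <- jitter_ensemble(a, n = 3, sigma = 0.4, seed = 2)$ensemble
  j2 <- jitter_ensemble(a, n = 3, sigma = 0.4, seed = 2)$ensemble
  expect_identical(j1$frames[[3]]$atoms, j2$frames[[3]]$atoms)
  p1 <- place_peptide(a, "groove", seed = 4)$complex
  p2 <- place_peptide(a, "groove", seed = 4)$complex
  expect_identical(p1$atoms, p2$atoms)
  n1 <- planted_network(seed = 3)$network
  n2 <- planted_network(seed = 3)$network
  expect_identical(n1$minima, n2$minima)
  # generator calls do not disturb the global RNG stream
  set.seed(123)
  r1 <- stats::runif(1)
  set.seed(123)
  invisible(build_hairpin(seed = 9))
  expect_identical(stats::runif(1), r1)
})

test_that("builder output passes the structural validators", {
  hp <- build_hairpin(seed = 1)$conformation
  rt <- residue_table(hp)
  expect_equal(rt$resno, 37:70)
  expect_equal(paste(rt$resid, collapse = ""), hairpinscape:::WT_SEQUENCE)
  # 5'-terminal residue lacks the phosphate group
  expect_false("P" %in% hairpinscape:::residue_atoms(hp, 37)$name)
  expect_true("P" %in% hairpinscape:::residue_atoms(hp, 38)$name)
  # intra-residue covalent bond lengths near standard values
  r45 <- hairpinscape:::residue_atoms(hp, 45)
  d <- function(a, b) {
    sqrt(sum((as.numeric(r45[r45$name == a, c("x", "y", "z")]) -
                as.numeric(r45[r45$name == b, c("x", "y", "z")]))^2))
  }
  expect_lt(abs(d("C1'", "N1") - 1.47) / 1.47, 0.1)
  expect_lt(abs(d("C1'", "C2'") - 1.53) / 1.53, 0.1)
  expect_lt(abs(d("P", "O5'") - 1.59) / 1.59, 0.1)
  expect_error(build_hairpin(sequence = paste(rep("A", 34), collapse = "")),
               "incompatible with pairing")
})

test_that("jitter: sigma zero is exact, CLT bound holds for the mean", {
  hp <- build_hairpin(seed = 1)$conformation
  j0 <- jitter_ensemble(hp, n = 3, sigma = 0, seed = 1)$ensemble
  for (fr in j0$frames) {
    expect_equal(as.matrix(fr$atoms[, c("x", "y", "z")]),
                 as.matrix(hp$atoms[, c("x", "y", "z")]), tolerance = 1e-15)
  }
  n <- 800
  sigma <- 0.5
  je <- jitter_ensemble(hp, n = n, sigma = sigma, seed = 3)$ensemble
  acc <- matrix(0, nrow(hp$atoms), 3)
  for (fr in je$frames) acc <- acc + as.matrix(fr$atoms[, c("x", "y", "z")])
  dev <- abs(acc / n - as.matrix(hp$atoms[, c("x", "y", "z")]))
  frac_ok <- mean(dev <= 3 * sigma / sqrt(n))
  expect_gte(frac_ok, 0.99)
})

test_that("mixtures use largest-remainder counts and record truth", {
  mx <- make_mixture(templates = list("M1", "M2", "E"),
                     fractions = c(0.06, 0.68, 0.26), n = 100, sigma = 0,
                     seed = 2)
  counts <- mx$truth$payload$counts
  expect_equal(as.integer(counts), c(6L, 68L, 26L))
  expect_equal(sum(counts), 100)
  expect_length(mx$ensemble$frames, 100)
  expect_equal(as.vector(table(factor(mx$truth$payload$labels,
                                      c("M1", "M2", "E")))),
               c(6L, 68L, 26L))
  # 50/50 split of 10
  mx2 <- make_mixture(templates = list("M2", "E"), fractions = c(0.5, 0.5),
                      n = 10, sigma = 0, seed = 1)
  expect_equal(as.integer(mx2$truth$payload$counts), c(5L, 5L))
  # fractional remainders go to the largest remainders
  expect_equal(hairpinscape:::largest_remainder(c(0.06, 0.68, 0.27) /
                                                  1.01, 100),
               c(6L, 67L, 27L))
  expect_error(make_mixture(templates = list("M1", "M2"),
                            fractions = c(0.5, 0.5), n = 1), "smaller")
  # classification at sigma = 0 recovers planted counts exactly
  cf <- classify_ensemble(mx2$ensemble)
  folded <- ifelse(cf$family == "M2STAR", "M2", cf$family)
  expect_identical(folded, ifelse(mx2$truth$payload$labels == "M2STAR",
                                  "M2", mx2$truth$payload$labels))
})

test_that("planted networks respect funnel structure", {
  for (s in 1:10) {
    pn <- planted_network(seed = s)
    net <- pn$network
    memb <- pn$truth$payload$membership
    bottoms <- pn$truth$payload$bottoms
    # bottoms are the lowest minima of their funnels
    for (f in unique(memb)) {
      ids <- net$minima$id[memb == f]
      expect_equal(net$minima$energy[match(bottoms[f], net$minima$id)],
                   min(net$minima$energy[memb == f]))
    }
    # intra-funnel barriers all below the joining barrier
    intra <- net$ts[memb[net$ts$min1] == memb[net$ts$min2], ]
    expect_true(all(intra$energy < pn$truth$payload$inter_barrier))
    # funnel assignment recovers membership
    fa <- funnel_assignment(net, bottoms)
    expect_identical(as.integer(fa), as.integer(bottoms[memb]))
    # network passes validation (ids closed, connected)
    expect_s3_class(net, "TransitionNetwork")
    expect_setequal(hairpinscape:::reachable_below(net, 1, Inf),
                    net$minima$id)
  }
})

test_that("peptide poses: distance contract, clash rule, groove geometry", {
  hp <- build_hairpin(template = family_template("M2"), seed = 1)$conformation
  rna_xyz <- as.matrix(hp$atoms[, c("x", "y", "z")])
  min_sep <- function(cx) {
    pa <- as.matrix(cx$atoms[cx$atoms$chain == "B", c("x", "y", "z")])
    min(sqrt(pmax(hairpinscape:::dist2(pa, rna_xyz), 0)))
  }
  far <- place_peptide(hp, "distant", seed = 2)$complex
  expect_gt(min_sep(far), 40)
  expect_lt(min_sep(far), 60)
  for (mode in c("groove", "surface")) {
    cx <- place_peptide(hp, mode, seed = 2)$complex
    expect_gte(min_sep(cx), 2.2)
    expect_lt(min_sep(cx), 6)
  }
  # peptide chain and numbering follow the ARM convention
  cx <- place_peptide(hp, "groove", seed = 1)$complex
  pep <- cx$atoms[cx$atoms$chain == "B", ]
  expect_equal(sort(unique(pep$resno)), 149:165)
  expect_equal(sum(pep$name == "CA"), 17)
  seq3 <- residue_table(conformation(pep))$resid
  expect_equal(seq3[1], "GLY")
  expect_equal(sum(seq3 == "ARG"), 4)
  expect_equal(sum(seq3 == "LYS"), 7)
})
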