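test_that("hydrogen-bond detection honors the distance criterion", {
  far <- conformation(toy_atoms(rbind(c(0, 0, 0), c(10, 0, 0)),
                                names = c("N3", "O2"), resid = "U",
                                resno = c(40, 41)))
  expect_equal(nrow(detect_hbonds(far)), 0)
  # ideal Watson-Crick A-U block: both canonical bonds found
  hp <- build_hairpin(template = family_template("E"), seed = 1)$conformation
  hb <- detect_hbonds(hp)
  au <- hb[(hb$donor_resno == 43 & hb$acceptor_resno == 66) |
             (hb$donor_resno == 66 & hb$acceptor_resno == 43), ]
  expect_gte(nrow(au), 2)
  pairs_au <- paste(pmin(au$donor_atom, au$acceptor_atom),
                    pmax(au$donor_atom, au$acceptor_atom))
  expect_true(all(c("N1 N3", "N6 O4") %in% pairs_au))
  # tight cutoff removes the pairing bonds of an isolated ideal pair
  pb <- hairpinscape:::wc_pair_block("A", "U")
  atoms <- rbind(
    toy_atoms(as.matrix(pb$b1[, c("x", "y", "z")]), names = pb$b1$name,
              resid = "A", resno = 43, element = pb$b1$element),
    toy_atoms(as.matrix(pb$b2[, c("x", "y", "z")]), names = pb$b2$name,
              resid = "U", resno = 66, element = pb$b2$element))
  atoms$serial <- seq_len(nrow(atoms))
  ideal <- conformation(atoms)
  expect_gte(nrow(detect_hbonds(ideal)), 2)
  expect_equal(nrow(detect_hbonds(ideal, hbond_criteria(d_max = 2.0))), 0)
})

test_that("detection is monotone in d_max", {
  hp <- build_hairpin(template = family_template("M2"), seed = 3)$conformation
  key <- function(hb) paste(hb$donor_resno, hb$donor_atom,
                            hb$acceptor_resno, hb$acceptor_atom)
  small <- detect_hbonds(hp, hbond_criteria(d_max = 3.0))
  big <- detect_hbonds(hp, hbond_criteria(d_max = 3.5))
  expect_true(all(key(small) %in% key(big)))
  expect_gte(nrow(big), nrow(small))
})

test_that("the D-H...A angle criterion applies when hydrogens exist", {
  # donor N with H pointing away from the acceptor: rejected; toward: kept
  mk <- function(hx) {
    at <- rbind(
      toy_atoms(c(0, 0, 0), names = "N3", resid = "U", resno = 1),
      toy_atoms(hx, names = "H3", resid = "U", resno = 1, element = "H"),
      toy_atoms(c(3.0, 0, 0), names = "O2", resid = "U", resno = 2))
    at$serial <- seq_len(nrow(at))
    conformation(at)
  }
  toward <- mk(c(1.0, 0, 0))
  away <- mk(c(-1.0, 0, 0))
  expect_equal(nrow(detect_hbonds(toward)), 1)
  expect_equal(nrow(detect_hbonds(away)), 0)
})

test_that("base pairs: stem detected, stacking and strand separation rejected", {
  hp <- build_hairpin(template = family_template("M2"), seed = 1)$conformation
  bp <- detect_base_pairs(hp)
  got <- paste(bp$res_a, bp$res_b)
  for (pr in list(c(37, 70), c(38, 69), c(39, 68), c(42, 67), c(43, 66),
                  c(44, 65), c(45, 64))) {
    expect_true(paste(pr[1], pr[2]) %in% got)
  }
  expect_true(all(bp$n_hbonds >= 2))
  expect_true(all(bp$res_a < bp$res_b))
  # canonical pairs flagged Watson-Crick; G-C carries 3 bonds
  gc <- bp[bp$res_a == 45 & bp$res_b == 64, ]
  expect_true(gc$wc)
  expect_gte(gc$n_hbonds, 3)
  # stretched single-stranded poly-U: no pairs
  n <- 8
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    tm <- hairpinscape:::nucleotide_template("U")
    tm$x <- tm$x + 12 * i
    toy_atoms(as.matrix(tm[, c("x", "y", "z")]), names = tm$name,
              resid = "U", resno = i, element = tm$element)
  }))
  atoms$serial <- seq_len(nrow(atoms))
  expect_equal(nrow(detect_base_pairs(conformation(atoms))), 0)
})

test_that("pair-supporting bonds are consistent with detect_hbonds", {
  hp <- build_hairpin(template = family_template("M2"), seed = 5)$conformation
  bp <- detect_base_pairs(hp)
  hb <- detect_hbonds(hp)
  for (i in seq_len(nrow(bp))) {
    n <- sum((hb$donor_resno == bp$res_a[i] &
                hb$acceptor_resno == bp$res_b[i]) |
               (hb$donor_resno == bp$res_b[i] &
                  hb$acceptor_resno == bp$res_a[i]))
    expect_gte(n, bp$n_hbonds[i])
  }
})

test_that("canonical triplet patterns follow the family templates", {
  pats <- list(M1 = c("T1", "T3"), M2 = "T2", M2STAR = c("T2", "M2STAR"),
               E = character(0))
  for (fam in names(pats)) {
    hp <- build_hairpin(template = family_template(fam),
                        seed = 1)$conformation
    tr <- detect_triplets(hp, include_other = FALSE)
    expect_setequal(tr$label[tr$present], pats[[fam]])
    # invariant under rigid motion
    moved <- apply_rigid(hp, hairpinscape:::with_seed(3, random_rigid_motion()))
    tr2 <- detect_triplets(moved, include_other = FALSE)
    expect_identical(tr2$present, tr$present)
  }
  # canonical member sets
  tr <- detect_triplets(build_hairpin(seed = 1)$conformation,
                        include_other = FALSE)
  expect_identical(tr$label, c("T1", "T2", "T3", "M2STAR"))
  expect_identical(tr$third, c(40L, 40L, 41L, 63L))
})

test_that("triplet patterns survive default jitter in >= 95% of fixtures", {
  ok <- 0L
  n <- 0L
  for (fam in c("M1", "M2", "E")) {
    want <- setdiff(family_template(fam)$triplets, "M2STAR")
    for (s in 1:50) {
      hp <- build_hairpin(template = family_template(fam),
                          seed = s)$conformation
      fr <- jitter_ensemble(hp, n = 1, sigma = 0.3,
                            seed = 2000 + s)$ensemble$frames[[1]]
      tr <- detect_triplets(fr, include_other = FALSE)
      got <- tr$label[tr$present & tr$label %in% c("T1", "T2", "T3")]
      n <- n + 1L
      if (setequal(got, want)) ok <- ok + 1L
    }
  }
  expect_gte(ok / n, 0.95)
})

test_that("per-residue hydrogen-bond counts and ensemble means", {
  hp <- build_hairpin(template = family_template("M2"), seed = 1)$conformation
  expect_equal(hbond_count(hp, 41), 0)
  expect_gte(hbond_count(hp, 40), 2)
  expect_error(hbond_count(hp, 99), "not found")
  # ensemble mean over frames with planted counts {x, x} stays x
  ens <- ensemble(list(hp, hp))
  expect_equal(hbond_count(ens, 41), 0)
  expect_equal(hbond_count(ens, 40), hbond_count(hp, 40))
})

test_that("hydrogen-bond persistence counts fractions of frames", {
  near <- conformation(rbind(
    toy_atoms(c(0, 0, 0), names = "N3", resid = "U", resno = 40,
              chain = "A"),
    toy_atoms(c(3.0, 0, 0), names = "O2", resid = "U", resno = 200,
              chain = "B")))
  far <- near
  far$atoms$x[2] <- 30
  ens <- ensemble(list(near, near, near, far, far, far, far, far, far, far))
  tab <- hbond_persistence(ens, list(chain = "A"), list(chain = "B"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$fraction, 0.3)
  all_near <- ensemble(list(near, near))
  expect_equal(hbond_persistence(all_near, list(chain = "A"),
                                 list(chain = "B"))$fraction, 1.0)
  none <- ensemble(list(far))
  expect_equal(nrow(hbond_persistence(none, list(chain = "A"),
                                      list(chain = "B"))), 0)
  expect_error(hbond_persistence(ens, list(chain = "A"),
                                 list(chain = c("A", "B"))), "overlap")
})
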