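test_that("network loading: dialects, ids, validation", {
  net <- load_network(c("0.0", "1.5"), "5.0 1 2")
  expect_equal(nrow(net$minima), 2)
  expect_equal(nrow(net$ts), 1)
  expect_equal(net$minima$id, 1:2)
  expect_error(load_network(c("0.0", "1.5"), "5.0 1 3"), "unknown minima")
  expect_error(load_network(c("0.0", "oops")), "non-numeric field at line 2")
  expect_warning(load_network(c("0.0", "6.0"), "5.0 1 2"), "below")
  # full dialect round-trips bit-identically through save/load
  minf <- c("0.0 12.5 1 0 0 0", "2.0 11.0 2 0 0 0")
  tsf <- "6.0 10.0 1 1 2"
  net2 <- load_network(minf, tsf)
  expect_equal(net2$minima$log_prod_freq, c(12.5, 11.0))
  expect_equal(net2$minima$symmetry, c(1L, 2L))
  f1 <- tempfile(); f2 <- tempfile()
  save_network(net2, f1, f2, dialect = "full")
  net3 <- load_network(f1, f2)
  expect_equal(net3$minima, net2$minima)
  expect_equal(net3$ts, net2$ts)
})

test_that("occupation matches closed forms and is gauge invariant", {
  p_eq <- occupation(load_network(c("1.0", "1.0")))
  expect_equal(as.numeric(p_eq), c(0.5, 0.5), tolerance = 1e-12)
  kT <- 0.0019872 * 298
  net <- load_network(sprintf("%.10f", c(0, kT * log(2))))
  expect_equal(as.numeric(occupation(net)), c(2 / 3, 1 / 3),
               tolerance = 1e-9)
  # dE = 5 kcal/mol at 298 K: minority population from the closed form
  net5 <- load_network(c("0", "5"))
  expect_equal(as.numeric(occupation(net5))[2],
               exp(-5 / kT) / (1 + exp(-5 / kT)), tolerance = 1e-12)
  # adding a constant to all energies changes nothing
  net_shift <- load_network(c("100", "105"))
  expect_equal(as.numeric(occupation(net_shift)),
               as.numeric(occupation(net5)), tolerance = 1e-9)
  # harmonic-superposition weighting requires all-or-none frequency data
  bad <- load_network(c("0.0 10 1 0 0 0", "1.0 11 1 0 0 0"))
  bad$minima$log_prod_freq[2] <- NA
  expect_error(occupation(bad), "all minima or none")
})

test_that("occupation survives 14 kcal/mol gaps in the log domain", {
  net <- load_network(c("0", "14"))
  p <- occupation(net)
  expect_gt(p[2], 0)
  expect_equal(as.numeric(log(p[2] / p[1])), -14 / (0.0019872 * 298),
               tolerance = 1e-9)
})

test_that("basin content under a cutoff matches the search oracle", {
  pn <- planted_network(
    funnels = list(list(n_minima = 6, bottom_energy = 0, depth_scale = 0.6,
                        family = "E"),
                   list(n_minima = 6, bottom_energy = 2, depth_scale = 0.6,
                        family = "M2")),
    inter_barrier = 18, seed = 5)
  net <- pn$network
  memb <- pn$truth$payload$membership
  # cutoff below the joining barrier: the other funnel is excluded
  bc <- basin_content(net, bottom = 1, cutoff = 15)
  expect_setequal(bc$members, net$minima$id[memb == 1])
  expect_equal(bc$uniform$fractions_folded[["E"]], 1)
  expect_equal(bc$boltzmann$fractions_folded[["E"]], 1)
  # cutoff above everything: all minima
  bc_all <- basin_content(net, bottom = 1, cutoff = 100)
  expect_setequal(bc_all$members, net$minima$id)
  # cutoff zero: only the bottom
  bc0 <- basin_content(net, bottom = 1, cutoff = 0)
  expect_equal(bc0$members, 1)
  expect_equal(bc0$uniform$fractions_folded[["E"]], 1)
  # unlabeled subset member is an error
  net_na <- net
  net_na$minima$family[2] <- NA
  expect_error(basin_content(net_na, bottom = 1, cutoff = 15), "unlabeled")
  # oracle equivalence on random networks at several cutoffs
  for (s in 1:10) {
    rn <- random_small_network(n = 9, seed = 40 + s)
    for (cutoff in c(1, 3, 6)) {
      expect_equal(basin_content_members(rn, 1, cutoff),
                   oracle_basin_members(rn, 1, cutoff))
    }
  }
})

test_that("transition-state rates follow harmonic TST", {
  net <- load_network(c("0", "1"), "10 1 2")
  kT <- 0.0019872 * 298
  expect_equal(ts_rate(net, 1, "forward"), 1e13 * exp(-10 / kT),
               tolerance = 1e-9)
  # zero barrier gives the bare prefactor
  net0 <- load_network(c("0", "0"), "0 1 2")
  expect_warning(k0 <- ts_rate(net0, 1, "forward"), NA)
  expect_equal(k0, 1e13)
  # forward/backward ratio equals the Boltzmann factor of the energy
  # gap (detailed balance: the uphill direction is slower)
  kf <- ts_rate(net, 1, "forward")
  kb <- ts_rate(net, 1, "backward")
  expect_equal(kf / kb, exp(-(1 - 0) / kT), tolerance = 1e-9)
  # negative barrier clamps with a warning
  netn <- suppressWarnings(load_network(c("0", "5"), "2 1 2"))
  expect_warning(kc <- ts_rate(netn, 1, "backward"), "clamped")
  expect_equal(kc, 1e13)
  # frequency data switch the prefactor to the product ratio
  netf <- load_network(c("0 30 1 0 0 0", "1 31 1 0 0 0"), "10 28 1 1 2")
  expect_equal(ts_rate(netf, 1, "forward"), exp(30 - 28) * exp(-10 / kT),
               tolerance = 1e-9)
})

test_that("inter-funnel rates: gt matches the master-equation oracle", {
  # 3-state chain with a high intermediate (clear time-scale separation)
  chain <- load_network(c("0", "10", "1"), c("11.5 1 2", "11.0 2 3"))
  km <- interfunnel_rate(chain, 1, 3, method = "master")
  kg <- interfunnel_rate(chain, 1, 3, method = "gt")
  expect_equal(kg[["k_ab"]], km[["k_ab"]], tolerance = 1e-6)
  expect_equal(kg[["k_ba"]], km[["k_ba"]], tolerance = 1e-6)
  # symmetric double well: equal rates both ways
  dw <- load_network(c("0", "0"), "6 1 2")
  ks <- interfunnel_rate(dw, 1, 2, method = "master")
  expect_equal(ks[["k_ab"]], ks[["k_ba"]], tolerance = 1e-9)
  # detailed balance for both methods
  pn <- planted_network(seed = 11)
  net <- pn$network
  memb <- pn$truth$payload$membership
  a <- net$minima$id[memb == 1]
  b <- net$minima$id[memb == 2]
  p <- occupation(net)
  ratio <- sum(p[b]) / sum(p[a])
  for (m in c("master", "gt")) {
    k <- interfunnel_rate(net, a, b, method = m)
    expect_equal(k[["k_ab"]] / k[["k_ba"]], ratio, tolerance = 1e-6)
  }
  # deep -> shallow much slower than the reverse
  deep <- planted_network(
    funnels = list(list(n_minima = 5, bottom_energy = 0, depth_scale = 0.5,
                        family = "E"),
                   list(n_minima = 5, bottom_energy = 6, depth_scale = 0.5,
                        family = "M1")),
    inter_barrier = 18, seed = 2)
  md <- deep$truth$payload$membership
  kk <- interfunnel_rate(deep$network,
                         deep$network$minima$id[md == 1],
                         deep$network$minima$id[md == 2], method = "gt")
  expect_lt(kk[["k_ab"]], kk[["k_ba"]] * 1e-3)
  expect_error(interfunnel_rate(net, a, c(a[1], b)), "overlap")
  disc <- load_network(c("0", "1"), NULL)
  expect_error(interfunnel_rate(disc, 1, 2), "not connected")
})

test_that("master-equation rate matrix satisfies global balance", {
  pn <- planted_network(seed = 8)
  net <- pn$network
  K <- hairpinscape:::rate_matrix(net, rate_params())
  expect_lt(max(abs(colSums(K))) / max(abs(K)), 1e-8)
  p <- occupation(net)
  resid <- K %*% p
  expect_lt(max(abs(resid)) / max(abs(K) %*% p), 1e-8)
})

test_that("free-energy gaps match independent log-domain evaluation", {
  net <- load_network(c("0", "5"))
  expect_equal(free_energy_gap(net, 1, 2), -5, tolerance = 1e-9)
  expect_equal(free_energy_gap(net, 2, 1), 5, tolerance = 1e-9)
  same <- load_network(c("1", "1", "1", "1"))
  expect_equal(free_energy_gap(same, c(1, 2), c(3, 4)), 0, tolerance = 1e-12)
  # two 10-minimum funnels against a hand-rolled log-sum-exp
  pn <- planted_network(
    funnels = list(list(n_minima = 10, bottom_energy = 0, depth_scale = 0.8,
                        family = "E"),
                   list(n_minima = 10, bottom_energy = 3, depth_scale = 0.8,
                        family = "M2")),
    inter_barrier = 18, seed = 13)
  net2 <- pn$network
  memb <- pn$truth$payload$membership
  a <- net2$minima$id[memb == 1]
  b <- net2$minima$id[memb == 2]
  kT <- 0.0019872 * 298
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  ea <- -net2$minima$energy[match(a, net2$minima$id)] / kT
  eb <- -net2$minima$energy[match(b, net2$minima$id)] / kT
  expect_equal(free_energy_gap(net2, a, b), -kT * (lse(ea) - lse(eb)),
               tolerance = 1e-9)
})
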