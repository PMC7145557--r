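test_that("a single barrier produces a root with two leaves", {
  net <- load_network(c("0", "1"), "5 1 2")
  dg <- build_dgraph(net, level_spacing = 1)
  expect_length(dg$children, 2)
  leaves <- hairpinscape:::dgraph_leaves(dg)
  expect_length(leaves, 2)
  expect_setequal(vapply(leaves, function(l) l$minimum, numeric(1)), 1:2)
  expect_setequal(vapply(leaves, function(l) l$level_energy, numeric(1)),
                  c(0, 1))
  expect_gt(dg$level_energy, 5)
})

test_that("leaf count equals minima count for any spacing", {
  pn <- planted_network(
    funnels = list(list(n_minima = 7, bottom_energy = 0, depth_scale = 0.8),
                   list(n_minima = 5, bottom_energy = 2, depth_scale = 0.8),
                   list(n_minima = 6, bottom_energy = 1, depth_scale = 0.8)),
    inter_barrier = 16, seed = 4)
  for (sp in c(0.3, 1, 2.5)) {
    dg <- build_dgraph(pn$network, level_spacing = sp)
    expect_length(hairpinscape:::dgraph_leaves(dg), 18)
  }
})

test_that("superbasin count is monotone non-increasing with threshold", {
  pn <- planted_network(
    funnels = list(list(n_minima = 8, bottom_energy = 0, depth_scale = 0.9),
                   list(n_minima = 8, bottom_energy = 2, depth_scale = 0.9)),
    inter_barrier = 16, seed = 6)
  dg <- build_dgraph(pn$network, level_spacing = 0.5)
  levels <- seq(0.5, 20, by = 0.5)
  counts <- vapply(levels, function(l) dg_count_nodes_at(dg, l), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a three-funnel landscape shows three branches below the joining barrier", {
  pn <- planted_network(
    funnels = list(list(n_minima = 5, bottom_energy = 0, depth_scale = 0.5),
                   list(n_minima = 5, bottom_energy = 1, depth_scale = 0.5),
                   list(n_minima = 5, bottom_energy = 2, depth_scale = 0.5)),
    inter_barrier = 15, seed = 9)
  dg <- build_dgraph(pn$network, level_spacing = 1)
  expect_equal(dg_count_nodes_at(dg, 15 - 0.5), 3L)
})

test_that("tree structure is invariant to minima input order", {
  net <- random_small_network(8, seed = 17)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  remap <- order(perm)
  min2 <- net$minima[perm, ]
  ts2 <- net$ts
  ts2$min1 <- remap[ts2$min1]
  ts2$min2 <- remap[ts2$min2]
  min_lines <- sprintf("%.6f", min2$energy)
  ts_lines <- sprintf("%.6f %d %d", ts2$energy, ts2$min1, ts2$min2)
  net2 <- load_network(min_lines, ts_lines)
  dg1 <- build_dgraph(net, 1)
  dg2 <- build_dgraph(net2, 1)
  # compare leaf partition by energies at each internal split
  sig <- function(node, emap) {
    if (!length(node$children)) return(sprintf("%.6f", emap[node$minimum]))
    kids <- sort(vapply(node$children, sig, character(1), emap = emap))
    paste0("(", paste(kids, collapse = ","), ")@", node$level_energy)
  }
  e1 <- stats::setNames(net$minima$energy, net$minima$id)
  e2 <- stats::setNames(net2$minima$energy, net2$minima$id)
  expect_identical(sig(dg1, e1), sig(dg2, e2))
})

test_that("LCA level bounds the exhaustive minimax barrier within one spacing", {
  for (s in 1:6) {
    net <- random_small_network(n = 9, seed = 70 + s)
    dg <- build_dgraph(net, level_spacing = 0.7)
    ids <- net$minima$id
    pairs <- utils::combn(ids, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      true_b <- oracle_minimax(net, a, b)
      lca <- dg_lca_level(dg, a, b)
      expect_gte(lca + 1e-9, true_b)
      expect_lte(lca, true_b + 0.7 + 1e-9)
    }
  }
})

test_that("funnel assignment recovers planted membership and the minimax rule", {
  pn <- planted_network(seed = 21)
  memb <- pn$truth$payload$membership
  bottoms <- pn$truth$payload$bottoms
  fa <- funnel_assignment(pn$network, bottoms)
  expect_identical(as.integer(fa), as.integer(bottoms[memb]))
  # single bottom: everything drains there
  fa1 <- funnel_assignment(pn$network, bottoms[1])
  expect_true(all(fa1 == bottoms[1]))
  # equidistant-in-barrier midpoint goes to the lower-energy bottom
  sym <- load_network(c("0", "1", "0.5"), c("5 1 3", "5 2 3"))
  fa_sym <- funnel_assignment(sym, c(1, 2))
  expect_equal(as.integer(fa_sym[["3"]]), 1L)
  # disconnected minima stay unassigned
  disc <- load_network(c("0", "1", "2"), "4 1 2")
  fa_d <- funnel_assignment(disc, 1)
  expect_true(is.na(fa_d[["3"]]))
})

test_that("funnel assignment matches the brute-force minimax oracle", {
  for (s in 1:8) {
    net <- random_small_network(n = 10, seed = 100 + s)
    bottoms <- c(1, 5)
    fa <- funnel_assignment(net, bottoms)
    be <- net$minima$energy[match(bottoms, net$minima$id)]
    for (id in net$minima$id) {
      bars <- vapply(bottoms, function(b) oracle_minimax(net, b, id),
                     numeric(1))
      bars[bottoms == id] <- -Inf
      best <- which(bars == min(bars))
      if (length(best) > 1) best <- best[which.min(be[best])]
      expect_equal(as.integer(fa[[as.character(id)]]),
                   as.integer(bottoms[best]))
    }
  }
})

test_that("SVG rendering is deterministic and colored by family", {
  pn <- planted_network(
    funnels = list(list(n_minima = 4, bottom_energy = 0, depth_scale = 0.5,
                        family = "E"),
                   list(n_minima = 4, bottom_energy = 2, depth_scale = 0.5,
                        family = "M2")),
    inter_barrier = 14, seed = 3)
  net <- pn$network
  coloring <- stats::setNames(net$minima$family, net$minima$id)
  dg <- build_dgraph(net, 1)
  f1 <- tempfile(fileext = ".svg")
  f2 <- tempfile(fileext = ".svg")
  render_dgraph(dg, coloring, f1)
  render_dgraph(dg, coloring, f2)
  expect_identical(readLines(f1), readLines(f2))
  svg <- paste(readLines(f1), collapse = "\n")
  expect_match(svg, "#d62728")  # E red
  expect_match(svg, "#2ca02c")  # M2 green
  # one minimum: a single vertical stroke
  one <- load_network("0")
  f3 <- tempfile(fileext = ".svg")
  render_dgraph(build_dgraph(one, 1), NULL, f3)
  expect_equal(sum(grepl("<line", readLines(f3))) -
                 sum(grepl("stroke=\"#444\"", readLines(f3))), 1)
})
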