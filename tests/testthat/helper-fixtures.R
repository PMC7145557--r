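# Shared fixtures and independent oracle implementations.

toy_atoms <- function(xyz, names = NULL, resid = "U", resno = 1,
                      chain = "A", element = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(names)) names <- paste0("C", seq_len(n))
  if (is.null(element)) element <- substr(names, 1, 1)
  data.frame(serial = seq_len(n), name = names,
             resid = rep(resid, length.out = n),
             chain = rep(chain, length.out = n),
             resno = rep(resno, length.out = n), icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = element, stringsAsFactors = FALSE)
}

random_rigid_motion <- function() {
  ax <- stats::rnorm(3)
  R <- hairpinscape:::rotation_about(ax, stats::runif(1, 0, 2 * pi))
  t <- stats::rnorm(3, sd = 10)
  list(R = R, t = t)
}

apply_rigid <- function(conf, rm) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")]) %*% t(rm$R)
  conf$atoms$x <- xyz[, 1] + rm$t[1]
  conf$atoms$y <- xyz[, 2] + rm$t[2]
  conf$atoms$z <- xyz[, 3] + rm$t[3]
  conf
}

# hand-coded vector-arithmetic angle oracle (acos form)
oracle_angle <- function(v, a, b) {
  u1 <- a - v
  u2 <- b - v
  acos(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))) * 180 / pi
}

# independent superposition oracle: coarse Euler-angle grid + Nelder-Mead
# refinement of the RMSD (never calls the Kabsch implementation)
oracle_superpose_rmsd <- function(x, y) {
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  f <- function(ang) sqrt(mean(rowSums((xc %*% t(rot(ang)) - yc)^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                      b = seq(0, pi, length.out = 7),
                      c = seq(0, 2 * pi, length.out = 13)[-13])
  vals <- apply(grid, 1, f)
  best <- as.numeric(grid[which.min(vals), ])
  stats::optim(best, f, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# exhaustive minimax barrier between two minima: minimum over all simple
# paths of the maximum transition-state energy along the path
oracle_minimax <- function(net, from, to) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net$ts$min1),
               to = as.character(net$ts$min2)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$minima$id)))
  paths <- igraph::all_simple_paths(g, from = as.character(from),
                                    to = as.character(to))
  if (!length(paths)) return(Inf)
  min(vapply(paths, function(p) {
    ids <- as.integer(names(p))
    maxb <- -Inf
    for (i in seq_len(length(ids) - 1)) {
      e <- net$ts$energy[(net$ts$min1 == ids[i] & net$ts$min2 == ids[i + 1]) |
                           (net$ts$min2 == ids[i] & net$ts$min1 == ids[i + 1])]
      maxb <- max(maxb, min(e))
    }
    maxb
  }, numeric(1)))
}

# independent basin-subset oracle via igraph components on the filtered
# graph (the implementation uses its own plain BFS)
oracle_basin_members <- function(net, bottom, cutoff) {
  emax <- net$minima$energy[net$minima$id == bottom] + cutoff
  keep <- net$minima$id[net$minima$energy <= emax]
  if (!(bottom %in% keep)) return(integer(0))
  ts <- net$ts[net$ts$energy <= emax & net$ts$min1 %in% keep &
                 net$ts$min2 %in% keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ts$min1), to = as.character(ts$min2)),
    directed = FALSE, vertices = data.frame(name = as.character(keep)))
  comp <- igraph::components(g)
  sort(as.integer(names(comp$membership)[
    comp$membership == comp$membership[[as.character(bottom)]]]))
}

# random connected network for oracle comparisons
random_small_network <- function(n, seed) {
  hairpinscape:::with_seed(seed, {
    e <- round(stats::runif(n, 0, 5), 3)
    ts <- NULL
    for (i in 2:n) {
      j <- sample.int(i - 1, 1)
      ts <- rbind(ts, c(max(e[i], e[j]) + round(stats::runif(1, 0.2, 4), 3),
                        j, i))
    }
    extra <- sample.int(n, 2)
    if (extra[1] != extra[2]) {
      ts <- rbind(ts, c(max(e[extra]) + round(stats::runif(1, 0.2, 4), 3),
                        extra[1], extra[2]))
    }
    load_network(sprintf("%.3f", e),
                 apply(ts, 1, function(r) paste(r, collapse = " ")))
  })
}

# superbasin (merge-process) count at a threshold: every leaf exists as
# its own basin until an internal node below the threshold merges it
dg_count_nodes_at <- function(node, level) {
  if (!length(node$children)) return(1L)
  if (node$level_energy < level) return(1L)
  sum(vapply(node$children, dg_count_nodes_at, integer(1), level = level))
}

dg_lca_level <- function(node, a, b) {
  for (ch in node$children) {
    if (all(c(a, b) %in% ch$members)) return(dg_lca_level(ch, a, b))
  }
  node$level_energy
}

basin_content_members <- function(net, bottom, cutoff) {
  e0 <- net$minima$energy[net$minima$id == bottom]
  hairpinscape:::reachable_below(net, bottom, e0 + cutoff)
}

# Monte-Carlo per-atom SASA oracle (random sphere directions, not the
# deterministic lattice used by the implementation)
oracle_sasa <- function(conf, probe = 1.4, n_points = 4000, seed = 99) {
  hairpinscape:::with_seed(seed, {
    a <- conf$atoms
    r <- hairpinscape:::VDW_RADII[a$element] + probe
    xyz <- as.matrix(a[, c("x", "y", "z")])
    out <- numeric(nrow(a))
    for (i in seq_len(nrow(a))) {
      dir <- matrix(stats::rnorm(3 * n_points), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      pts <- sweep(dir * r[i], 2, xyz[i, ], "+")
      acc <- rep(TRUE, n_points)
      for (j in seq_len(nrow(a))[-i]) {
        d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        acc <- acc & d2 > r[j]^2
      }
      out[i] <- 4 * pi * r[i]^2 * mean(acc)
    }
    out
  })
}
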