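# Kinetic transition networks: minima/transition-state databases,
# harmonic-superposition thermodynamics and (harmonic TST) kinetics.
# All Boltzmann sums are evaluated in the log domain so that free-energy
# gaps of tens of kcal/mol do not underflow.

#' Temperature and rate-model parameters
#'
#' @param temperature Kelvin (default 298, room temperature).
#' @param prefactor attempt frequency in 1/s used when vibrational
#'   frequency data are absent (default 1e13, a typical molecular
#'   vibrational prefactor).
#' @return list of class `"RateParams"`; `kB` is in kcal/(mol K).
#' @export
rate_params <- function(temperature = 298, prefactor = 1e13) {
  stopifnot(temperature > 0, prefactor > 0)
  structure(list(temperature = temperature, prefactor = prefactor,
                 kB = KB_KCAL), class = "RateParams")
}

new_network <- function(minima, ts) {
  if (nrow(ts)) {
    bad <- !(ts$min1 %in% minima$id) | !(ts$min2 %in% minima$id)
    if (any(bad))
      stop("transition state(s) at line ", paste(which(bad), collapse = ", "),
           " reference unknown minima")
    if (any(ts$min1 == ts$min2))
      stop("transition state connecting a minimum to itself")
    low <- ts$energy < pmax(minima$energy[match(ts$min1, minima$id)],
                            minima$energy[match(ts$min2, minima$id)])
    if (any(low))
      warning(sum(low), " transition state(s) lie below one of their minima")
  }
  structure(list(minima = minima, ts = ts), class = "TransitionNetwork")
}

#' @export
print.TransitionNetwork <- function(x, ...) {
  cat("TransitionNetwork:", nrow(x$minima), "minima,",
      nrow(x$ts), "transition states\n")
  cat("  energy range:", round(min(x$minima$energy), 3), "to",
      round(max(x$minima$energy), 3), "kcal/mol\n")
  invisible(x)
}

#' Load a minima / transition-state database
#'
#' Plain whitespace-separated tables; ids are assigned by line order
#' starting at 1.  Two dialects are recognized by column count:
#' \describe{
#'   \item{minimal}{minima: `energy`; transition states:
#'     `energy min1 min2`.}
#'   \item{full}{minima: `energy logfreq sym ix iy iz`; transition
#'     states: `energy logfreq sym min1 min2` (the common stationary-point
#'     database layout; trailing inertia columns are kept but unused).}
#' }
#'
#' @param min_table,ts_table file paths (or character vectors of lines).
#' @param families optional character vector of family labels, one per
#'   minimum.
#' @return a `TransitionNetwork`.
#' @export
load_network <- function(min_table, ts_table = NULL, families = NULL) {
  read_tab <- function(x) {
    if (is.null(x)) return(NULL)
    lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(data.frame())
    fields <- strsplit(lines, "[[:space:]]+")
    ncol <- unique(lengths(fields))
    if (length(ncol) != 1)
      stop("ragged table: rows have differing field counts")
    m <- matrix(NA_real_, length(fields), ncol)
    for (i in seq_along(fields)) {
      v <- suppressWarnings(as.numeric(fields[[i]]))
      if (anyNA(v)) stop("non-numeric field at line ", i)
      m[i, ] <- v
    }
    as.data.frame(m)
  }
  mt <- read_tab(min_table)
  if (is.null(mt) || !nrow(mt)) stop("empty minima table")
  minima <- if (ncol(mt) == 1) {
    data.frame(id = seq_len(nrow(mt)), energy = mt[[1]],
               log_prod_freq = NA_real_, symmetry = 1L)
  } else if (ncol(mt) >= 3) {
    data.frame(id = seq_len(nrow(mt)), energy = mt[[1]],
               log_prod_freq = mt[[2]], symmetry = as.integer(mt[[3]]))
  } else stop("minima table must have 1 (minimal) or >= 3 (full) columns")
  if (any(minima$symmetry < 1, na.rm = TRUE))
    stop("symmetry numbers must be >= 1")
  ts <- if (is.null(ts_table)) {
    data.frame(id = integer(0), energy = numeric(0), min1 = integer(0),
               min2 = integer(0), log_prod_freq = numeric(0),
               symmetry = integer(0))
  } else {
    tt <- read_tab(ts_table)
    if (!nrow(tt)) {
      data.frame(id = integer(0), energy = numeric(0), min1 = integer(0),
                 min2 = integer(0), log_prod_freq = numeric(0),
                 symmetry = integer(0))
    } else if (ncol(tt) == 3) {
      data.frame(id = seq_len(nrow(tt)), energy = tt[[1]],
                 min1 = as.integer(tt[[2]]), min2 = as.integer(tt[[3]]),
                 log_prod_freq = NA_real_, symmetry = 1L)
    } else if (ncol(tt) >= 5) {
      data.frame(id = seq_len(nrow(tt)), energy = tt[[1]],
                 log_prod_freq = tt[[2]], symmetry = as.integer(tt[[3]]),
                 min1 = as.integer(tt[[4]]), min2 = as.integer(tt[[5]]))
    } else stop("ts table must have 3 (minimal) or >= 5 (full) columns")
  }
  if (!is.null(families)) {
    if (length(families) != nrow(minima))
      stop("families length must equal the number of minima")
    minima$family <- as.character(families)
  } else minima$family <- NA_character_
  new_network(minima, ts)
}

#' Save a network in the plain-table dialects of [load_network()]
#'
#' @param net a `TransitionNetwork`.
#' @param min_file,ts_file output paths.
#' @param dialect `"minimal"` or `"full"` (full requires frequency data).
#' @return invisibly, the two paths.
#' @export
save_network <- function(net, min_file, ts_file, dialect = c("minimal", "full")) {
  dialect <- match.arg(dialect)
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  if (dialect == "minimal") {
    writeLines(fmt(net$minima$energy), min_file)
    writeLines(paste(fmt(net$ts$energy), net$ts$min1, net$ts$min2), ts_file)
  } else {
    if (anyNA(net$minima$log_prod_freq))
      stop("full dialect requires log_prod_freq for all minima")
    writeLines(paste(fmt(net$minima$energy), fmt(net$minima$log_prod_freq),
                     net$minima$symmetry, 0, 0, 0), min_file)
    writeLines(paste(fmt(net$ts$energy), fmt(net$ts$log_prod_freq),
                     net$ts$symmetry, net$ts$min1, net$ts$min2), ts_file)
  }
  invisible(c(min_file, ts_file))
}

# log unnormalized equilibrium weight per minimum
log_weights <- function(net, params) {
  beta <- 1 / (params$kB * params$temperature)
  lw <- -beta * net$minima$energy
  has_freq <- !is.na(net$minima$log_prod_freq)
  if (any(has_freq)) {
    if (!all(has_freq))
      stop("frequency data must be present for all minima or none")
    lw <- lw - net$minima$log_prod_freq - log(net$minima$symmetry)
  }
  lw
}

#' Equilibrium occupation probabilities (harmonic superposition)
#'
#' `p_i` proportional to `exp(-E_i / kB T)`; when vibrational data are
#' present for every minimum the harmonic-superposition weight
#' `exp(-E_i/kB T - log_prod_freq_i) / symmetry_i` is used instead.
#' Evaluated via log-sum-exp.
#'
#' @param net a `TransitionNetwork`.
#' @param params a [rate_params()].
#' @return numeric vector of probabilities summing to one, named by
#'   minimum id.
#' @export
occupation <- function(net, params = rate_params()) {
  if (!nrow(net$minima)) stop("empty network")
  lw <- log_weights(net, params)
  p <- exp(lw - logsumexp(lw))
  names(p) <- net$minima$id
  p / sum(p)
}

# minima reachable from `bottom` through TSs with energy <= emax,
# restricted to minima with energy <= emax (plain BFS)
reachable_below <- function(net, bottom, emax) {
  ok_min <- net$minima$id[net$minima$energy <= emax]
  if (!(bottom %in% ok_min)) return(integer(0))
  ts <- net$ts[net$ts$energy <= emax &
                 net$ts$min1 %in% ok_min & net$ts$min2 %in% ok_min, ,
               drop = FALSE]
  visited <- as.integer(bottom)
  frontier <- visited
  while (length(frontier)) {
    nb <- c(ts$min2[ts$min1 %in% frontier], ts$min1[ts$min2 %in% frontier])
    frontier <- as.integer(setdiff(nb, visited))
    visited <- c(visited, frontier)
  }
  sort(visited)
}

#' Family content of a basin under an energy cutoff
#'
#' Selects the minima connected to `bottom` through transition states no
#' higher than `E(bottom) + cutoff` (and themselves below that energy),
#' then reports the family composition of the subset both uniformly
#' (counting minima) and Boltzmann-weighted (occupation probabilities
#' restricted and renormalized to the subset).
#'
#' @param net a `TransitionNetwork` whose selected minima carry family
#'   labels (via `families` in [load_network()] or a `family` column).
#' @param bottom id of the basin-bottom minimum.
#' @param cutoff energy window above the bottom, kcal/mol (default 15).
#' @param params a [rate_params()] for the Boltzmann view.
#' @return list with `members` (ids), `uniform` and `boltzmann`
#'   ([composition()] objects).
#' @export
basin_content <- function(net, bottom, cutoff = 15, params = rate_params()) {
  if (!(bottom %in% net$minima$id)) stop("unknown bottom minimum ", bottom)
  e0 <- net$minima$energy[net$minima$id == bottom]
  members <- reachable_below(net, bottom, e0 + cutoff)
  idx <- match(members, net$minima$id)
  fam <- net$minima$family[idx]
  if (anyNA(fam))
    stop("unlabeled minimum in basin subset: ",
         paste(members[is.na(fam)], collapse = ", "))
  frames <- data.frame(family = fam)
  p <- occupation(net, params)[as.character(members)]
  list(members = members,
       uniform = composition(frames),
       boltzmann = composition(frames, weights = as.numeric(p)))
}

ts_rate_one <- function(net, ts_row, source_id, params) {
  src <- net$minima[net$minima$id == source_id, ]
  dE <- ts_row$energy - src$energy
  if (dE < 0) {
    warning("negative barrier clamped to zero (TS ", ts_row$id, ")")
    dE <- 0
  }
  beta <- 1 / (params$kB * params$temperature)
  pref <- params$prefactor
  if (!is.na(ts_row$log_prod_freq) && !is.na(src$log_prod_freq)) {
    # harmonic TST: ratio of vibrational frequency products, with
    # symmetry numbers
    pref <- exp(src$log_prod_freq - ts_row$log_prod_freq) *
      src$symmetry / ts_row$symmetry
  }
  pref * exp(-beta * dE)
}

#' Harmonic-TST rate over one transition state
#'
#' `k = prefactor * exp(-(E_ts - E_source) / kB T)`; when vibrational
#' frequency data are available for both stationary points the uniform
#' prefactor is replaced by the harmonic-TST frequency-product ratio.
#' Negative barriers (TS recorded below its minimum) are clamped to zero
#' with a warning.
#'
#' @param net a `TransitionNetwork`.
#' @param ts_id transition-state id.
#' @param direction `"forward"` (min1 -> min2) or `"backward"`.
#' @param params a [rate_params()].
#' @return rate constant in 1/s.
#' @export
ts_rate <- function(net, ts_id, direction = c("forward", "backward"),
                    params = rate_params()) {
  direction <- match.arg(direction)
  row <- net$ts[net$ts$id == ts_id, ]
  if (!nrow(row)) stop("unknown transition state ", ts_id)
  src <- if (direction == "forward") row$min1 else row$min2
  ts_rate_one(net, row, src, params)
}

# full rate matrix K (column convention: K[j, i] = rate i -> j,
# diagonal = -column sums); n x n over minima order in net$minima
rate_matrix <- function(net, params) {
  n <- nrow(net$minima)
  K <- matrix(0, n, n)
  idx <- function(id) match(id, net$minima$id)
  for (r in seq_len(nrow(net$ts))) {
    row <- net$ts[r, ]
    i <- idx(row$min1); j <- idx(row$min2)
    K[j, i] <- K[j, i] + ts_rate_one(net, row, row$min1, params)
    K[i, j] <- K[i, j] + ts_rate_one(net, row, row$min2, params)
  }
  diag(K) <- -colSums(K)
  K
}

# graph-transformation elimination: returns branching probabilities P and
# waiting times tau on the retained node set
gt_reduce <- function(P, tau, keep) {
  nodes <- seq_len(nrow(P))
  for (x in setdiff(nodes, keep)) {
    Pxx <- P[x, x]
    denom <- 1 - Pxx
    if (denom <= 0) stop("graph transformation hit an absorbing node")
    nb <- setdiff(which(P[, x] > 0 | P[x, ] > 0), x)
    tau[nb] <- tau[nb] + P[nb, x] * tau[x] / denom
    for (u in nb) {
      P[nb, u] <- P[nb, u] + P[nb, x] * P[x, u] / denom
    }
    P[, x] <- 0
    P[x, ] <- 0
  }
  list(P = P, tau = tau)
}

#' Inter-funnel rate constants between two sets of minima
#'
#' Two routes are provided.  `"master"` builds the full master-equation
#' rate matrix, extracts the slowest relaxation rate `lambda_1` from its
#' (detailed-balance symmetrized) spectrum, and splits it two-state as
#' `k_ab = lambda_1 P_b`, `k_ba = lambda_1 P_a` with equilibrium
#' probabilities restricted and renormalized to the two sets.  `"gt"`
#' eliminates all intervening minima by graph transformation and forms
#' the steady-state rates from the reduced branching
#' probabilities and waiting times.  Both satisfy detailed balance
#' `k_ab / k_ba = P_b / P_a`; under time-scale separation they agree.
#'
#' @param net a `TransitionNetwork`.
#' @param set_a,set_b disjoint, non-empty vectors of minima ids.
#' @param params a [rate_params()].
#' @param method `"master"` or `"gt"`.
#' @return named vector `c(k_ab, k_ba)` in 1/s.
#' @export
interfunnel_rate <- function(net, set_a, set_b, params = rate_params(),
                             method = c("master", "gt")) {
  method <- match.arg(method)
  if (!length(set_a) || !length(set_b)) stop("empty set")
  if (length(intersect(set_a, set_b))) stop("sets overlap")
  if (!all(c(set_a, set_b) %in% net$minima$id)) stop("unknown minima ids")
  # connectivity check over the whole network
  comp <- reachable_below(net, set_a[1], Inf)
  if (!all(c(set_a, set_b) %in% comp))
    stop("sets are not connected by any transition-state path")
  p <- occupation(net, params)
  ia <- match(set_a, net$minima$id)
  ib <- match(set_b, net$minima$id)
  Pa <- sum(p[ia]); Pb <- sum(p[ib])
  PA <- Pa / (Pa + Pb); PB <- Pb / (Pa + Pb)
  if (method == "master") {
    K <- rate_matrix(net, params)
    keep <- which(net$minima$id %in% comp)
    K <- K[keep, keep, drop = FALSE]
    pk <- p[keep] / sum(p[keep])
    s <- sqrt(pk)
    Ks <- K * outer(1 / s, s)        # symmetrized: S^-1 K S
    Ks <- (Ks + t(Ks)) / 2
    ev <- eigen(Ks, symmetric = TRUE, only.values = TRUE)$values
    lambda1 <- -sort(ev, decreasing = TRUE)[2]
    c(k_ab = lambda1 * PB, k_ba = lambda1 * PA)
  } else {
    K <- rate_matrix(net, params)
    esc <- -diag(K)
    if (any(esc[c(ia, ib)] <= 0))
      stop("a set member has no outgoing transition states")
    tau <- 1 / esc
    P <- sweep(K, 2, esc, "/")       # P[j,i] branching i -> j
    diag(P) <- 0
    P <- t(P)                        # P[i,j]: from i to j
    red <- gt_reduce(P, tau, keep = c(ia, ib))
    k_ab <- sum((p[ia] / Pa) * rowSums(red$P[ia, ib, drop = FALSE]) /
                  red$tau[ia])
    k_ba <- sum((p[ib] / Pb) * rowSums(red$P[ib, ia, drop = FALSE]) /
                  red$tau[ib])
    c(k_ab = k_ab, k_ba = k_ba)
  }
}

#' Free-energy gap between two sets of minima
#'
#' `dF = -kB T ln(P_a / P_b)` with occupation probabilities restricted
#' and renormalized to the union; negative values mean set `a` is more
#' stable.  Computed in the log domain, so gaps of tens of kcal/mol are
#' exact.
#'
#' @inheritParams interfunnel_rate
#' @return free-energy difference in kcal/mol.
#' @export
free_energy_gap <- function(net, set_a, set_b, params = rate_params()) {
  if (!length(set_a) || !length(set_b)) stop("empty set")
  if (length(intersect(set_a, set_b))) stop("sets overlap")
  lw <- log_weights(net, params)
  la <- logsumexp(lw[match(set_a, net$minima$id)])
  lb <- logsumexp(lw[match(set_b, net$minima$id)])
  if (!is.finite(la) || !is.finite(lb))
    stop("zero-probability set (weights underflow); review energies")
  -params$kB * params$temperature * (la - lb)
}
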