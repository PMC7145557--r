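# Deterministic, seeded generators for idealized fixtures: hairpin
# conformations realizing each conformational family, jittered ensembles
# with planted compositions, multi-funnel transition networks and docked
# peptide poses.  Fixtures are geometrically plausible (ideal helical
# parameters, planted hydrogen-bond geometry) but NOT energy-minimized:
# they exist to exercise the classification, contact and interface
# machinery with known ground truth.

# wild-type top-half sequence, author numbering 37..70
WT_SEQUENCE <- "CCAUUGAUCGACUUCGUUCGUUCGUCUGAUCUGG"

HELIX_TWIST <- 32.7   # degrees per step
HELIX_RISE <- 2.81    # Angstrom per step

# stem pairing scheme (5'-residue, 3'-residue), stacked bottom to top
STEM_PAIRS <- list(c(37, 70), c(38, 69), c(39, 68), c(42, 67), c(43, 66),
                   c(44, 65), c(45, 64), c(46, 62), c(47, 61), c(48, 60))
LOOP_RESNOS <- 49:59
BULGE_RESNOS <- c(40, 41, 63)

WC_COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

#' Family templates for the hairpin builder
#'
#' Encodes, per conformational family, the target classification angle,
#' the base triplets the builder realizes, and the in/out mode of the
#' bulged gatekeeper base U63.
#'
#' @param name one of `"M1"`, `"M2"`, `"M2STAR"`, `"E"`.
#' @param u63_mode optional override of the template's default in/out
#'   mode for the bulged gatekeeper base (free placement; the bound,
#'   triplet-forming position is specific to the M2STAR template).
#' @return list of class `"FamilyTemplate"` with `name`, `target_xi`
#'   (degrees: M1 30, M2/M2STAR 90, E 150), `triplets`, `u63_mode`.
#' @export
family_template <- function(name = c("M1", "M2", "M2STAR", "E"),
                            u63_mode = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    M1     = list(target_xi = 30, triplets = c("T1", "T3"), u63_mode = "in"),
    M2     = list(target_xi = 90, triplets = "T2", u63_mode = "out"),
    M2STAR = list(target_xi = 90, triplets = c("T2", "M2STAR"),
                  u63_mode = "in"),
    E      = list(target_xi = 150, triplets = character(0),
                  u63_mode = "out"))
  if (!is.null(u63_mode)) {
    spec$u63_mode <- match.arg(u63_mode, c("in", "out"))
  }
  structure(c(list(name = name), spec), class = "FamilyTemplate")
}

seq_at <- function(sequence, resno) substr(sequence, resno - 36, resno - 36)

#' Build an idealized hairpin conformation for a family template
#'
#' Constructs the 34-nt top-half hairpin (numbering 37-70) as stacked
#' ideal base-pair blocks (twist 32.7 degrees, rise 2.81 Angstrom per
#' step) for the stem pairs 37-70, 38-69, 39-68, the GAUC/GAUC helix
#' 42-45/64-67 and the upper stem 46-48/60-62, an apical arc for the
#' loop 49-59, and family-dependent placement of the bulged residues
#' U40, U41 and U63:
#' \describe{
#'   \item{M1}{U40 tilted against the C45-G64 pair (T1), U41 on the
#'     A43-U66 Hoogsteen edge (T3); xi near 30 degrees.}
#'   \item{M2}{U40 on the A43-U66 Hoogsteen edge (T2); xi near 90; U63
#'     out (or in, forming the U63-U44-A65 triplet, for M2STAR).}
#'   \item{E}{all three bulges extruded, no triplets, xi above 100.}
#' }
#' The seed perturbs placement angles slightly (a few degrees) so
#' different seeds give distinct but in-band fixtures; the same seed
#' reproduces coordinates bit-identically.
#'
#' @param sequence 34-nt sequence for residues 37-70 (default wild
#'   type); must be Watson-Crick-compatible with the pairing scheme.
#' @param template a [family_template()].
#' @param seed integer seed.
#' @param chain chain identifier.
#' @return list with `conformation` and `truth` (a `PlantedTruth` list:
#'   `kind = "family"`, payload with the planted family, triplets and
#'   u63 mode, and the seed).
#' @export
build_hairpin <- function(sequence = WT_SEQUENCE,
                          template = family_template("M2"), seed = 1,
                          chain = "A") {
  stopifnot(inherits(template, "FamilyTemplate"))
  sequence <- toupper(sequence)
  if (nchar(sequence) != 34 || grepl("[^ACGU]", sequence))
    stop("sequence must be 34 nucleotides over ACGU")
  for (pr in STEM_PAIRS) {
    c5 <- seq_at(sequence, pr[1]); c3 <- seq_at(sequence, pr[2])
    if (WC_COMPLEMENT[[c5]] != c3)
      stop("sequence incompatible with pairing scheme at ", pr[1], "-",
           pr[2], " (", c5, "-", c3, ")")
  }
  with_seed(seed, {
    jit <- function(scale) stats::runif(1, -scale, scale)
    res <- list()   # resno -> atom data.frame (name,x,y,z,element)
    put <- function(resno, df) res[[as.character(resno)]] <<- df
    # extra vertical gap above the distal pair for M1, clearing space for
    # the tilted U40
    upper_gap <- if (template$name == "M1") 3.2 else 0
    level_z <- function(i) i * HELIX_RISE + if (i >= 7) upper_gap else 0
    for (i in seq_along(STEM_PAIRS)) {
      pr <- STEM_PAIRS[[i]]
      lev <- i - 1
      blk <- wc_pair_block(seq_at(sequence, pr[1]), seq_at(sequence, pr[2]),
                           with_p5 = pr[1] != 37, with_p3 = TRUE)
      R <- rotation_about(c(0, 0, 1), lev * HELIX_TWIST * pi / 180)
      put(pr[1], transform_atoms(blk$b1, R, c(0, 0, level_z(lev))))
      put(pr[2], transform_atoms(blk$b2, R, c(0, 0, level_z(lev))))
    }
    placed_xyz <- function() {
      do.call(rbind, lapply(res, function(df)
        as.matrix(df[, c("x", "y", "z")])))
    }
    get_atom <- function(resno, name) {
      df <- res[[as.character(resno)]]
      as.numeric(df[df$name == name, c("x", "y", "z")][1, ])
    }
    res_centroid <- function(resno) {
      df <- res[[as.character(resno)]]
      code <- seq_at(sequence, resno)
      colMeans(as.matrix(df[df$name %in% RING_ATOMS[[code]],
                            c("x", "y", "z")]))
    }
    azimuth_of <- function(p) atan2(p[2], p[1])
    # Hoogsteen/major-groove-edge placement of a third uridine: its N3
    # (donor) anchors on `anchor_atom` of `anchor_resno`, and the spin is
    # solved so its O4 sits a bond length from `second_atom` of
    # `second_resno` (a donor or acceptor on the pair)
    plant_uridine <- function(resno, anchor_resno, anchor_atom,
                              second_resno, second_atom, tilt_deg = 0) {
      ctr <- res_centroid(anchor_resno)
      ap <- get_atom(anchor_resno, anchor_atom)
      ghat <- unit(c(ap[1:2] - ctr[1:2], 0))
      alpha <- tilt_deg * pi / 180
      mhat <- unit(cos(alpha) * ghat + sin(alpha) * c(0, 0, 1))
      nrm <- unit(cos(alpha) * c(0, 0, 1) - sin(alpha) * ghat)
      pair_atoms <- placed_xyz()
      placed <- place_third_base(
        seq_at(sequence, resno), with_phosphate = TRUE,
        anchor = "N3", anchor_target = ap + PLANT_HB_DIST * mhat,
        normal = nrm, second = "O4",
        second_partner = get_atom(second_resno, second_atom),
        avoid = pair_atoms)
      put(resno, placed)
    }
    # free placement of a bulged base with clash-avoiding deterministic
    # search over azimuth offsets and radii
    plant_free <- function(resno, centroid_target_fn, base_phi, z,
                           radii = c(8, 9, 10), min_clear = 3.6) {
      cand <- expand.grid(dphi = seq(0, 345, by = 15) * pi / 180, r = radii)
      best <- NULL; best_clear <- -Inf
      others <- placed_xyz()
      for (k in seq_len(nrow(cand))) {
        phi <- base_phi + cand$dphi[k]
        tgt <- centroid_target_fn(phi, cand$r[k], z)
        nrm <- unit(c(cos(phi), sin(phi), 0))
        pl <- place_free_base(seq_at(sequence, resno), TRUE, tgt, nrm,
                              spin = 0)
        dmin <- min(sqrt(pmax(dist2(as.matrix(pl[, c("x", "y", "z")]),
                                    others), 0)))
        if (dmin >= min_clear) { best <- pl; best_clear <- dmin; break }
        if (dmin > best_clear) { best <- pl; best_clear <- dmin }
      }
      put(resno, best)
    }
    xy_target <- function(phi, r, z) c(r * cos(phi), r * sin(phi), z)
    phi_bulge1 <- azimuth_of(get_atom(39, "C1'")) + jit(8) * pi / 180
    phi_bulge2 <- azimuth_of(get_atom(64, "C1'")) + jit(8) * pi / 180
    # azimuth of the major-groove track at height z; free bulges of the
    # open-groove templates are steered to the opposite side so the
    # groove stays accessible (the defining feature of those states)
    helix_rate <- (HELIX_TWIST * pi / 180) / HELIX_RISE
    phi_n7_43 <- azimuth_of(get_atom(43, "N7"))
    groove_phi_at <- function(z) phi_n7_43 + (z - level_z(4)) * helix_rate
    away_phi <- function(z) groove_phi_at(z) + pi + jit(8) * pi / 180
    # family-dependent bulges
    if (template$name == "M1") {
      if (seq_at(sequence, 41) == "U")
        plant_uridine(41, 43, "N7", 43, "N6", tilt_deg = jit(4))
      else plant_free(41, xy_target, phi_bulge1, level_z(4))
      if (seq_at(sequence, 40) == "U")
        plant_uridine(40, 64, "O6", 45, "N4", tilt_deg = 42 + jit(4))
      else plant_free(40, xy_target, phi_bulge1, level_z(6))
    } else if (template$name %in% c("M2", "M2STAR")) {
      if (seq_at(sequence, 40) == "U")
        plant_uridine(40, 43, "N7", 43, "N6", tilt_deg = jit(4))
      else plant_free(40, xy_target, phi_bulge1, level_z(4))
      plant_free(41, xy_target, away_phi(level_z(2) + 1.2),
                 level_z(2) + 1.2, radii = c(8, 9, 10, 11, 12))
    } else {  # E: extruded probe realizing large xi
      v <- (res_centroid(43) + res_centroid(66)) / 2
      w <- (res_centroid(45) + res_centroid(64)) / 2
      up <- unit(w - v)
      xi_t <- (template$target_xi + jit(3)) * pi / 180
      e_target <- function(phi, r, z) {
        rad <- unit(c(cos(phi), sin(phi), 0))
        v + r * (cos(xi_t) * up + sin(xi_t) * rad)
      }
      plant_free(40, e_target, phi_bulge1, NA, radii = c(10, 11, 12))
      low_target <- function(phi, r, z) c(r * cos(phi), r * sin(phi), z)
      plant_free(41, low_target, phi_bulge1 + 40 * pi / 180, 1.5,
                 radii = c(8, 9, 10))
    }
    # U63 gatekeeper
    if (template$name == "M2STAR" && seq_at(sequence, 63) == "U") {
      plant_uridine(63, 65, "N7", 65, "N6", tilt_deg = jit(4))
    } else if (template$u63_mode == "in") {
      c65 <- res_centroid(65); c44 <- res_centroid(44)
      d44 <- unit(c44 - c65)
      hoog <- unit(c((get_atom(65, "N7")[1:2] + get_atom(65, "N6")[1:2]) / 2 -
                       c65[1:2], 0))
      dir_in <- unit(hoog + 0.45 * d44)
      in_target <- function(phi, r, z) c65 + r * dir_in
      plant_free(63, in_target, 0, NA, radii = c(6, 6.5, 7), min_clear = 3.6)
    } else {
      plant_free(63, xy_target, away_phi(level_z(6) + 1.4),
                 level_z(6) + 1.4, radii = c(9, 10))
    }
    # apical loop on an arc above the top pair (crude by design; the
    # native apical loop is outside this package's scope)
    top_z <- level_z(9) + 4.5
    nl <- length(LOOP_RESNOS)
    for (k in seq_len(nl)) {
      phi <- 2 * pi * (k - 0.5) / nl
      tgt <- c(8.5 * cos(phi), 8.5 * sin(phi), top_z + 1.6 * (k %% 2))
      nrm <- unit(c(cos(phi), sin(phi), 0.3))
      put(LOOP_RESNOS[k],
          place_free_base(seq_at(sequence, LOOP_RESNOS[k]), TRUE, tgt, nrm,
                          spin = 20 * k))
    }
    # assemble in author order
    rows <- lapply(37:70, function(rn) {
      df <- res[[as.character(rn)]]
      data.frame(serial = 0L, name = df$name,
                 resid = seq_at(sequence, rn), chain = chain, resno = rn,
                 icode = "", x = df$x, y = df$y, z = df$z,
                 element = df$element, stringsAsFactors = FALSE)
    })
    atoms <- do.call(rbind, rows)
    atoms$serial <- seq_len(nrow(atoms))
    conf <- conformation(atoms, tag = paste0(template$name, "-seed", seed))
    truth <- list(kind = "family",
                  payload = list(family = template$name,
                                 triplets = template$triplets,
                                 u63_mode = template$u63_mode,
                                 target_xi = template$target_xi),
                  seed = seed)
    list(conformation = conf, truth = truth)
  })
}

#' Gaussian coordinate jitter around a conformation
#'
#' `n` frames with i.i.d. Gaussian noise of standard deviation `sigma`
#' added to every coordinate of every atom; seeded and reproducible.
#'
#' @param conf a [conformation()].
#' @param n number of frames.
#' @param sigma per-coordinate noise, Angstrom.
#' @param seed integer seed.
#' @return list with `ensemble` and `truth`.
#' @export
jitter_ensemble <- function(conf, n = 10, sigma = 0.3, seed = 1) {
  stopifnot(inherits(conf, "Conformation"), n >= 1, sigma >= 0)
  with_seed(seed, {
    frames <- lapply(seq_len(n), function(i) {
      xyz <- atom_xyz(conf$atoms)
      noise <- matrix(stats::rnorm(length(xyz), 0, sigma), nrow(xyz), 3)
      fr <- set_xyz(conf, xyz + noise)
      fr$tag <- paste0(conf$tag, "-frame", i)
      fr
    })
    list(ensemble = ensemble(frames),
         truth = list(kind = "jitter",
                      payload = list(sigma = sigma, n = n), seed = seed))
  })
}

# largest-remainder rounding of n * fractions to integers summing to n
largest_remainder <- function(fractions, n) {
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Planted mixture ensemble with known family fractions
#'
#' Builds one hairpin per template, draws jittered copies according to
#' the largest-remainder rounding of `n * fractions`, and concatenates
#' them in a seeded random order.  The truth payload records the exact
#' planted counts and the per-frame family labels.
#'
#' @param templates list of [family_template()] objects (or family
#'   names).
#' @param fractions numeric vector summing to 1.
#' @param n total number of frames.
#' @param sigma per-coordinate jitter, Angstrom.
#' @param seed integer seed.
#' @param sequence forwarded to [build_hairpin()].
#' @return list with `ensemble` and `truth` (planted counts, per-frame
#'   labels, seed).
#' @export
make_mixture <- function(templates = list("M1", "M2", "E"),
                         fractions = c(0.06, 0.68, 0.26), n = 100,
                         sigma = 0.3, seed = 1, sequence = WT_SEQUENCE) {
  templates <- lapply(templates, function(t)
    if (inherits(t, "FamilyTemplate")) t else family_template(t))
  if (length(fractions) != length(templates))
    stop("fractions and templates length mismatch")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (n < sum(fractions > 0)) stop("n smaller than number of templates")
  counts <- largest_remainder(fractions, n)
  frames <- list()
  labels <- character(0)
  for (i in seq_along(templates)) {
    if (counts[i] == 0) next
    hp <- build_hairpin(sequence, templates[[i]], seed = seed + i)
    je <- jitter_ensemble(hp$conformation, n = counts[i], sigma = sigma,
                          seed = seed + 100 * i)
    frames <- c(frames, je$ensemble$frames)
    labels <- c(labels, rep(templates[[i]]$name, counts[i]))
  }
  perm <- with_seed(seed + 7919, sample(length(frames)))
  list(ensemble = ensemble(frames[perm]),
       truth = list(kind = "composition",
                    payload = list(
                      counts = stats::setNames(counts, vapply(
                        templates, function(t) t$name, character(1))),
                      labels = labels[perm]),
                    seed = seed))
}

#' Planted multi-funnel transition network
#'
#' Each funnel is a random tree of minima whose energies sit above the
#' funnel bottom by shifted, truncated-exponential increments
#' (0.3 kcal/mol floor plus an exponential of scale `depth_scale`
#' truncated at 2.5 scales), with transition states 1.0 kcal/mol plus a
#' truncated exponential above the higher of the two minima they
#' connect; funnels are joined by single transition states at
#' `inter_barrier`.  The floors and truncations bound the intra-funnel
#' relaxation time-scales to a narrow band well separated from the
#' inter-funnel exchange -- the regime in which a two-state rate is
#' defined.  Draws are repeated (seeded) until every intra-funnel
#' barrier lies below `inter_barrier`, which the construction requires.
#'
#' @param funnels list of funnel specs: `list(n_minima, bottom_energy,
#'   depth_scale)` (optionally named; a `family` entry labels the
#'   funnel's minima).
#' @param inter_barrier energy of the funnel-joining transition states,
#'   kcal/mol.
#' @param seed integer seed.
#' @return list with `network` (a `TransitionNetwork`) and `truth`
#'   (funnel membership, bottoms ids, seed).
#' @export
planted_network <- function(funnels = list(list(n_minima = 8,
                                                bottom_energy = 0,
                                                depth_scale = 0.5),
                                           list(n_minima = 8,
                                                bottom_energy = 2,
                                                depth_scale = 0.5)),
                            inter_barrier = 15, seed = 1) {
  stopifnot(length(funnels) >= 1)
  with_seed(seed, {
    for (attempt in 1:200) {
      min_e <- numeric(0); ts_e <- numeric(0)
      ts_1 <- integer(0); ts_2 <- integer(0)
      member <- integer(0); bottoms <- integer(0); fam <- character(0)
      ok <- TRUE
      for (f in seq_along(funnels)) {
        fs <- funnels[[f]]
        nm <- fs$n_minima %||% fs[[1]]
        be <- fs$bottom_energy %||% fs[[2]]
        ds <- fs$depth_scale %||% fs[[3]]
        offset <- length(min_e)
        e <- numeric(nm)
        e[1] <- be
        bottoms <- c(bottoms, offset + 1L)
        if (nm > 1) {
          texp <- function() min(stats::rexp(1, rate = 1 / ds), 2.5 * ds)
          for (i in 2:nm) {
            parent <- if (i == 2) 1L else sample.int(i - 1, 1)
            e[i] <- be + 0.3 + texp()
            tse <- max(e[i], e[parent]) + 1.0 + texp()
            ts_e <- c(ts_e, tse)
            ts_1 <- c(ts_1, offset + parent)
            ts_2 <- c(ts_2, offset + i)
          }
        }
        min_e <- c(min_e, e)
        member <- c(member, rep(f, nm))
        fam <- c(fam, rep(fs$family %||% NA_character_, nm))
      }
      if (length(ts_e) && max(ts_e) >= inter_barrier) { next }
      # join consecutive funnels through single top transition states
      if (length(funnels) > 1) {
        for (f in seq_len(length(funnels) - 1)) {
          i <- sample(which(member == f), 1)
          j <- sample(which(member == f + 1), 1)
          ts_e <- c(ts_e, inter_barrier)
          ts_1 <- c(ts_1, i)
          ts_2 <- c(ts_2, j)
        }
      }
      minima <- data.frame(id = seq_along(min_e), energy = min_e,
                           log_prod_freq = NA_real_, symmetry = 1L,
                           family = fam)
      ts <- data.frame(id = seq_along(ts_e), energy = ts_e,
                       min1 = ts_1, min2 = ts_2,
                       log_prod_freq = NA_real_, symmetry = 1L)
      net <- new_network(minima, ts)
      return(list(network = net,
                  truth = list(kind = "funnel",
                               payload = list(membership = member,
                                              bottoms = bottoms,
                                              inter_barrier = inter_barrier),
                               seed = seed)))
    }
    stop("could not realize intra-funnel barriers below inter_barrier; ",
         "raise inter_barrier or lower depth_scale")
  })
}

PEPTIDE_THREE <- c(G = "GLY", A = "ALA", V = "VAL", L = "LEU", I = "ILE",
                   P = "PRO", F = "PHE", W = "TRP", M = "MET", S = "SER",
                   T = "THR", C = "CYS", Y = "TYR", N = "ASN", Q = "GLN",
                   D = "ASP", E = "GLU", K = "LYS", R = "ARG", H = "HIS")

ARM_SEQUENCE <- "GKKKHRRRPSKKKRHWK"

# Helically coiled peptide template in a local frame whose z axis is the
# RNA helix axis: CA atoms track the major-groove path at `radius`, with
# the coil's twist-per-rise locked to the RNA helix (32.7 deg / 2.81 A)
# so the chain keeps a constant azimuthal offset from the backbone
# ridges; the per-residue rise is then fixed by the standard 3.8 A CA-CA
# spacing.  Sidechain pseudo-atoms point radially inward (toward the
# axis) or outward.  Numbering follows the HEXIM1 ARM convention
# 149-165.
build_arm_peptide <- function(sequence = ARM_SEQUENCE, chain = "B",
                              start_resno = 149, radius = 9.5,
                              inward = TRUE, phi0 = 0, z0 = 0) {
  aa <- strsplit(sequence, "")[[1]]
  if (any(!aa %in% names(PEPTIDE_THREE))) stop("unknown amino acid code")
  rate <- (HELIX_TWIST * pi / 180) / HELIX_RISE    # rad per Angstrom
  rise <- stats::uniroot(function(r)
    (2 * radius * sin(rate * r / 2))^2 + r^2 - 3.8^2,
    c(0.05, 3.79))$root
  twist <- rate * rise
  rows <- list()
  for (i in seq_along(aa)) {
    code <- PEPTIDE_THREE[[aa[i]]]
    phi <- phi0 + (i - (length(aa) + 1) / 2) * twist
    rhat <- c(cos(phi), sin(phi), 0)
    that <- c(-sin(phi), cos(phi), 0)
    zhat <- c(0, 0, 1)
    shat <- if (inward) -rhat else rhat
    ca <- radius * rhat + (z0 + (i - (length(aa) + 1) / 2) * rise) * zhat
    at <- list(
      N = ca - 1.25 * that + 0.35 * zhat,
      CA = ca,
      C = ca + 1.30 * that + 0.35 * zhat,
      O = ca + 1.45 * that + 0.45 * zhat + 1.05 * (-shat))
    tip <- function(d, dt = 0, dz = 0) ca + d * shat + dt * that + dz * zhat
    side <- switch(code,
      GLY = list(),
      LYS = list(CB = tip(1.45, 0.3), NZ = tip(4.4, 0.2, 0.2)),
      ARG = list(CB = tip(1.45, 0.3), NE = tip(3.3, 0.2),
                 CZ = tip(4.5, 0.25), NH1 = tip(5.2, 1.0, 0.4),
                 NH2 = tip(5.2, -0.6, -0.5)),
      HIS = list(CB = tip(1.45, 0.3), ND1 = tip(3.3, 0.7),
                 NE2 = tip(3.45, -0.7)),
      PRO = list(CB = tip(1.45, 0.3)),
      SER = list(CB = tip(1.45, 0.3), OG = tip(2.55, 0.2)),
      TRP = list(CB = tip(1.45, 0.3), NE1 = tip(3.75, 0.4)),
      list(CB = tip(1.45, 0.3)))
    at <- c(at, side)
    if (i == length(aa)) at$OXT <- ca + 1.55 * that - 1.15 * zhat
    rows[[i]] <- data.frame(
      serial = 0L, name = names(at), resid = code, chain = chain,
      resno = start_resno + i - 1, icode = "",
      x = vapply(at, `[`, numeric(1), 1),
      y = vapply(at, `[`, numeric(1), 2),
      z = vapply(at, `[`, numeric(1), 3),
      element = substr(names(at), 1, 1), stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  conformation(atoms, tag = "ARM")
}

# Straight extended-chain variant (centered on the origin, chain along
# +x, sidechain pseudo-atoms along -z), used for tangential surface
# poses.
build_arm_straight <- function(sequence = ARM_SEQUENCE, chain = "B",
                               start_resno = 149) {
  aa <- strsplit(sequence, "")[[1]]
  if (any(!aa %in% names(PEPTIDE_THREE))) stop("unknown amino acid code")
  x0 <- 3.8 * (length(aa) - 1) / 2
  rows <- list()
  for (i in seq_along(aa)) {
    code <- PEPTIDE_THREE[[aa[i]]]
    ca <- c(3.8 * (i - 1) - x0, 0.45 * (-1)^i, 0)
    at <- list(N = ca + c(-1.20, 0.75 * (-1)^(i + 1), 0.1),
               CA = ca,
               C = ca + c(1.28, 0.55 * (-1)^(i + 1), -0.1),
               O = ca + c(1.45, 0.6 * (-1)^(i + 1), 1.1))
    tip <- function(d, dx = 0, dy = 0) ca + c(dx, dy, -d)
    side <- switch(code,
      GLY = list(),
      LYS = list(CB = tip(1.45, 0, 0.3), NZ = tip(4.4, 0.3)),
      ARG = list(CB = tip(1.45, 0, 0.3), NE = tip(3.3, 0.2),
                 CZ = tip(4.5, 0.3), NH1 = tip(5.2, 1.05, 0.6),
                 NH2 = tip(5.2, -0.5, -0.75)),
      HIS = list(CB = tip(1.45, 0, 0.3), ND1 = tip(3.3, 0.75),
                 NE2 = tip(3.45, -0.72)),
      PRO = list(CB = tip(1.45, 0, 0.3)),
      SER = list(CB = tip(1.45, 0, 0.3), OG = tip(2.55, 0.2)),
      TRP = list(CB = tip(1.45, 0, 0.3), NE1 = tip(3.75, 0.4)),
      list(CB = tip(1.45, 0, 0.3)))
    at <- c(at, side)
    if (i == length(aa)) at$OXT <- ca + c(1.6, 0.5 * (-1)^(i + 1), -1.25)
    rows[[i]] <- data.frame(
      serial = 0L, name = names(at), resid = code, chain = chain,
      resno = start_resno + i - 1, icode = "",
      x = vapply(at, `[`, numeric(1), 1),
      y = vapply(at, `[`, numeric(1), 2),
      z = vapply(at, `[`, numeric(1), 3),
      element = substr(names(at), 1, 1), stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  conformation(atoms, tag = "ARM")
}

#' Dock the ARM peptide against a hairpin in a planted pose
#'
#' Places the arginine-rich-motif peptide (default HEXIM1 149-165,
#' GKKKHRRRPSKKKRHWK), coiled along the helical track of the GAUC/GAUC
#' helix, relative to the RNA: wrapped inside the major groove with the
#' charged sidechain tips pointing at the base edges (`"groove"`), lying
#' on the phosphate shell with sidechains pointing away
#' (`"surface"`), or 50 Angstrom away (`"distant"`).  Steric overlaps
#' below 2.2 Angstrom are resolved by rigidly expanding the coil radius
#' (up to 20 Angstrom beyond the start, then an error).
#'
#' @param rna a [conformation()] (e.g. from [build_hairpin()]).
#' @param mode `"groove"`, `"surface"` or `"distant"`.
#' @param seed integer seed (small azimuthal/axial perturbations).
#' @param peptide_sequence one-letter sequence.
#' @return list with `complex` (two-chain [conformation()], RNA chain
#'   kept, peptide on chain "B") and `truth` (mode, retraction, seed).
#' @export
place_peptide <- function(rna, mode = c("groove", "surface", "distant"),
                          seed = 1, peptide_sequence = ARM_SEQUENCE) {
  mode <- match.arg(mode)
  stopifnot(inherits(rna, "Conformation"))
  with_seed(seed, {
    a <- rna$atoms
    # helix axis: line through the bottom and top base-pair midpoints of
    # the GAUC/GAUC helix
    mid_lo <- (base_centroid(rna, 42) + base_centroid(rna, 67)) / 2
    mid_hi <- (base_centroid(rna, 45) + base_centroid(rna, 64)) / 2
    ctr <- (mid_lo + mid_hi) / 2
    ax <- unit(mid_hi - mid_lo)
    # groove azimuth: from the axis toward the Hoogsteen edge (N7) of
    # the apex adenine
    n7 <- as.numeric(a[a$name == "N7" & a$resno == 43, c("x", "y", "z")][1, ])
    gv <- n7 - (ctr + sum((n7 - ctr) * ax) * ax)
    ohat <- unit(gv)
    bhat <- unit(cross3(ax, ohat))
    phi_jit <- stats::runif(1, -5, 5) * pi / 180
    z_jit <- stats::runif(1, -1, 1)
    min_dist <- function(p) {
      min(sqrt(pmax(dist2(atom_xyz(p$atoms), atom_xyz(a)), 0)))
    }
    # local frame -> RNA frame: x to the groove azimuth, z along the
    # helix axis, origin at the helix centre
    to_rna <- function(p) {
      xyz <- atom_xyz(p$atoms)
      mapped <- sweep(xyz %*% rbind(ohat, bhat, ax), 2,
                      ctr + z_jit * ax, "+")
      set_xyz(p, mapped)
    }
    if (mode == "groove") {
      # coil wrapped along the helical groove track, charged tips
      # inward; at each radius the azimuthal phase with the largest
      # clearance locks the chain onto the groove canyon
      pose <- function(r, dphi) {
        to_rna(build_arm_peptide(peptide_sequence, radius = r,
                                 inward = TRUE, phi0 = phi_jit + dphi,
                                 z0 = -4))
      }
      cand <- seq(-180, 175, by = 15) * pi / 180
      best_pose <- function(r) {
        clear <- vapply(cand, function(dp) min_dist(pose(r, dp)),
                        numeric(1))
        list(p = pose(r, cand[which.max(clear)]), clear = max(clear))
      }
      r0 <- 9.5
      d <- 0
      bp <- best_pose(r0)
      while (bp$clear < 2.2) {
        d <- d + 0.5
        if (d > 20) stop("cannot satisfy clash rule within 20 A retraction")
        bp <- best_pose(r0 + d)
      }
      p <- bp$p
    } else {
      # straight rod parallel to the helix axis: resting on the outside
      # of the backbone/protrusion shell with sidechains pointing away
      # (surface), or pushed 50 A out (distant).  The surface pose rests
      # at van der Waals contact (no interpenetration of vdW spheres),
      # unlike the docked groove pose which may interdigitate down to
      # the 2.2 A clash floor.
      pose <- function(r) {
        pep <- build_arm_straight(peptide_sequence)
        xyz <- atom_xyz(pep$atoms)
        # local: x along the axis, -z = sidechains -> +oo (outward)
        oo <- as.numeric(rotation_about(ax, 120 * pi / 180 + phi_jit) %*%
                           ohat)
        bb <- unit(cross3(ax, oo))
        mapped <- sweep(xyz %*% rbind(ax, bb, -oo), 2,
                        ctr + r * oo + z_jit * ax, "+")
        set_xyz(pep, mapped)
      }
      vdw_overlap <- function(p) {
        d <- sqrt(pmax(dist2(atom_xyz(p$atoms), atom_xyz(a)), 0))
        rsum <- outer(atom_radii(p$atoms), atom_radii(a), "+")
        min(d - rsum)
      }
      touching <- function(p) {
        if (mode == "distant") min_dist(p) >= 2.2 else vdw_overlap(p) >= 0
      }
      d <- 0
      p <- pose(9)
      while (!touching(p)) {
        d <- d + 0.5
        if (d > 20) stop("cannot satisfy clash rule within 20 A retraction")
        p <- pose(9 + d)
      }
      if (mode == "distant") {
        p <- pose(9 + d + 50 - min_dist(p))
      }
    }
    atoms <- rbind(a, p$atoms)
    atoms$serial <- seq_len(nrow(atoms))
    list(complex = conformation(atoms,
                                tag = paste0(rna$tag, "+ARM-", mode)),
         truth = list(kind = "pose",
                      payload = list(mode = mode, retraction = d),
                      seed = seed))
  })
}

#' Synthetic stand-ins for the four experimentally observed models
#'
#' Idealized builder conformations emulating the experimentally observed
#' states: a compact T1/T3 model (crystal IN-like, M1), a T2 model with
#' U63 out (crystal OUT-like, M2), an extended tripletless model (E) and
#' a compact model with the U63 triplet (M2*).  These are synthetic
#' constructions, not the deposited coordinates; they carry the planted
#' properties (xi band, triplet pattern) but not crystal-specific values
#' such as the experimental radii of gyration.
#'
#' @param seed integer seed forwarded to [build_hairpin()].
#' @return named list of `Conformation` objects
#'   (`synthetic_exp1` ... `synthetic_exp4`).
#' @export
synthetic_reference_models <- function(seed = 1) {
  list(
    synthetic_exp1 = build_hairpin(template = family_template("M1"),
                                   seed = seed)$conformation,
    synthetic_exp2 = build_hairpin(template = family_template("M2"),
                                   seed = seed + 1)$conformation,
    synthetic_exp3 = build_hairpin(template = family_template("E"),
                                   seed = seed + 2)$conformation,
    synthetic_exp4 = build_hairpin(template = family_template("M2STAR"),
                                   seed = seed + 3)$conformation)
}
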