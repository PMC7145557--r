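# Idealized nucleotide geometry: planar base templates built from regular
# ring polygons (bond 1.38 A, exocyclic C-O 1.23 / C-N 1.34 A), a fixed
# ribose/phosphate template attached at the glycosidic nitrogen, and
# helpers that pose bases into Watson-Crick pairs and base triplets.
# These templates serve geometric classification and contact detection;
# they are deliberately idealized, not energy-minimized.

RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C4", "C6", "N1", "C2", "N3"),
  G = c("N9", "C8", "N7", "C5", "C4", "C6", "N1", "C2", "N3"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6"))

EXOCYCLIC_ATOMS <- list(A = "N6", G = c("O6", "N2"), C = c("O2", "N4"),
                        U = c("O2", "O4"))

base_atom_names <- function(code) {
  c(RING_ATOMS[[code]], EXOCYCLIC_ATOMS[[code]])
}

glycosidic_atom <- function(code) if (code %in% c("A", "G")) "N9" else "N1"

# Planar base template, z = 0, glycosidic N at the origin, C1' direction
# along -x.  Returns data.frame(name, x, y, z).
base_template <- function(code) {
  stopifnot(code %in% c("A", "C", "G", "U"))
  hex <- function(center, r, names, start_deg) {
    ang <- (start_deg - 60 * (seq_along(names) - 1)) * pi / 180
    data.frame(name = names,
               x = center[1] + r * cos(ang),
               y = center[2] + r * sin(ang), z = 0,
               stringsAsFactors = FALSE)
  }
  radial <- function(df, center, at, new, bond) {
    p <- as.numeric(df[df$name == at, c("x", "y")])
    d <- unit(c(p - center, 0))[1:2]
    rbind(df, data.frame(name = new, x = p[1] + bond * d[1],
                         y = p[2] + bond * d[2], z = 0))
  }
  side <- 1.38
  if (code %in% c("C", "U")) {
    ctr <- c(side, 0)
    # hexagon N1 C2 N3 C4 C5 C6, N1 at origin (angle 180), clockwise
    df <- hex(ctr, side, c("N1", "C2", "N3", "C4", "C5", "C6"), 180)
    df <- radial(df, ctr, "C2", "O2", 1.23)
    df <- if (code == "U") radial(df, ctr, "C4", "O4", 1.23)
          else radial(df, ctr, "C4", "N4", 1.34)
  } else {
    # five-ring N9 C8 N7 C5 C4 (regular pentagon), N9 at origin
    r5 <- side / (2 * sin(pi / 5))
    c5 <- c(r5, 0)
    ang <- (180 - 72 * (0:4)) * pi / 180
    pent <- data.frame(name = c("N9", "C8", "N7", "C5", "C4"),
                       x = c5[1] + r5 * cos(ang),
                       y = c5[2] + r5 * sin(ang), z = 0,
                       stringsAsFactors = FALSE)
    # six-ring fused on the C4-C5 edge, on the far side from the pentagon
    p4 <- as.numeric(pent[pent$name == "C4", c("x", "y")])
    p5 <- as.numeric(pent[pent$name == "C5", c("x", "y")])
    mid <- (p4 + p5) / 2
    ev <- unit(c(p5 - p4, 0))[1:2]
    nrm <- c(ev[2], -ev[1])
    if (sum(nrm * (mid - c5)) < 0) nrm <- -nrm
    c6 <- mid + side * sqrt(3) / 2 * nrm
    a5 <- atan2(p5[2] - c6[2], p5[1] - c6[1]) * 180 / pi
    hexnames <- c("C5x", "C6", "N1", "C2", "N3", "C4x")
    hx <- hex(c6, side, hexnames, a5)[2:5, ]  # C6 N1 C2 N3 (C5/C4 shared)
    df <- rbind(pent, hx)
    df <- if (code == "A") radial(df, c6, "C6", "N6", 1.34)
          else {
            df <- radial(df, c6, "C6", "O6", 1.23)
            radial(df, c6, "C2", "N2", 1.34)
          }
  }
  df$element <- substr(df$name, 1, 1)
  rownames(df) <- NULL
  df
}

# Ribose + phosphate template in the base frame (glycosidic N at origin,
# C1' along -x); hand-built with bond lengths within a few percent of
# standard values.
SUGAR_TEMPLATE <- data.frame(
  name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
           "C3'", "O3'", "C2'", "O2'", "C1'"),
  x = c(-4.95, -6.35, -4.70, -4.20, -4.35, -3.70, -2.30,
        -3.90, -4.85, -2.45, -2.10, -1.47),
  y = c(4.10, 3.80, 5.45, 3.05, 1.65, 0.75, 1.12,
        -0.72, -1.70, -1.10, -2.42, 0.00),
  z = c(2.30, 2.40, 1.80, 1.40, 1.60, 0.55, 0.20,
        0.55, 1.00, 0.30, 0.20, 0.00),
  element = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "O", "C"),
  stringsAsFactors = FALSE)

# Full nucleotide template: backbone + sugar + base, PDB atom order.
nucleotide_template <- function(code, with_phosphate = TRUE) {
  sug <- SUGAR_TEMPLATE
  if (!with_phosphate)
    sug <- sug[!sug$name %in% c("P", "OP1", "OP2", "O5'"), ]
  base <- base_template(code)
  rbind(sug, base[, c("name", "x", "y", "z", "element")])
}

# Apply rigid transform (3x3 rotation R then translation t) to the x/y/z
# columns of an atom data.frame.
transform_atoms <- function(df, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  df$x <- xyz[, 1] + t[1]
  df$y <- xyz[, 2] + t[2]
  df$z <- xyz[, 3] + t[3]
  df
}

template_ring_centroid <- function(df, code) {
  colMeans(as.matrix(df[df$name %in% RING_ATOMS[[code]], c("x", "y", "z")]))
}

# Heavy-atom pairs (first atom on the 5'-side member) realizing the
# canonical Watson-Crick hydrogen bonds.
WC_BONDS <- list(
  "A|U" = list(c("N1", "N3"), c("N6", "O4")),
  "U|A" = list(c("N3", "N1"), c("O4", "N6")),
  "G|C" = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
  "C|G" = list(c("N4", "O6"), c("N3", "N1"), c("O2", "N2")))

# Planted heavy-atom hydrogen-bond distance in builder fixtures.
# Deliberately tighter than crystallographic averages (2.8-3.0 A): under
# the generators' default coordinate jitter (0.3 A per coordinate, i.e.
# pairwise-distance noise of sd sqrt(2)*0.3 = 0.42 A) a planted contact
# must keep a ~2.4 sigma margin to the 3.5 A detection default for the
# planted pair/triplet patterns to survive jitter reliably.
PLANT_HB_DIST <- 2.50

# 2-D rigid fit (rotation about z + in-plane translation) mapping points
# x (k x 2) onto y (k x 2) in least squares.
fit2d <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xr <- sweep(x, 2, cx); yr <- sweep(y, 2, cy)
  num <- sum(xr[, 1] * yr[, 2] - xr[, 2] * yr[, 1])
  den <- sum(xr[, 1] * yr[, 1] + xr[, 2] * yr[, 2])
  th <- atan2(num, den)
  # R is for the row-vector convention y ~ x %*% R + t
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  list(R = R, t = cy - as.numeric(cx %*% R))
}

# Watson-Crick pair block in the z = 0 plane.  Returns full-nucleotide
# atom tables for the 5'-strand member (code5) and its partner (code3),
# posed so the planted WC bonds are PLANT_HB_DIST long and the block
# centroid (mean of the two ring centroids) sits at the origin.
wc_pair_block <- function(code5, code3, with_p5 = TRUE, with_p3 = TRUE) {
  key <- paste(code5, code3, sep = "|")
  bonds <- WC_BONDS[[key]]
  if (is.null(bonds)) stop("not a Watson-Crick combination: ", key)
  b1 <- nucleotide_template(code5, with_phosphate = with_p5)
  b2 <- nucleotide_template(code3, with_phosphate = with_p3)
  ctr1 <- template_ring_centroid(b1, code5)
  a1 <- t(vapply(bonds, function(b)
    as.numeric(b1[b1$name == b[1], c("x", "y", "z")][1, ]), numeric(3)))
  ghat <- unit(c(colMeans(a1)[1:2] - ctr1[1:2], 0))
  targets <- a1 + matrix(PLANT_HB_DIST * ghat, nrow(a1), 3, byrow = TRUE)
  # Pose the partner by an in-plane fit of its bond atoms onto the
  # targets; of the two face-up/face-down variants (proper rotation by pi
  # about x, or none) keep the one whose base body does not overlap the
  # first base.
  pose_variant <- function(bb) {
    a2 <- t(vapply(bonds, function(b)
      as.numeric(bb[bb$name == b[2], c("x", "y", "z")][1, ]), numeric(3)))
    f <- fit2d(a2[, 1:2, drop = FALSE], targets[, 1:2, drop = FALSE])
    xy <- as.matrix(bb[, c("x", "y")]) %*% f$R
    bb$x <- xy[, 1] + f$t[1]
    bb$y <- xy[, 2] + f$t[2]
    bb
  }
  variants <- list(pose_variant(transform_atoms(b2, diag(c(1, -1, -1)))),
                   pose_variant(b2))
  sep <- vapply(variants, function(bb) {
    p <- as.matrix(bb[bb$name %in% base_atom_names(code3), c("x", "y", "z")])
    q <- as.matrix(b1[b1$name %in% base_atom_names(code5), c("x", "y", "z")])
    d <- as.matrix(stats::dist(rbind(p, q)))
    min(d[seq_len(nrow(p)), -seq_len(nrow(p))])
  }, numeric(1))
  b2 <- variants[[which.max(sep)]]
  ctr2 <- template_ring_centroid(b2, code3)
  mid <- (template_ring_centroid(b1, code5) + ctr2) / 2
  b1[, c("x", "y", "z")] <- sweep(as.matrix(b1[, c("x", "y", "z")]), 2, mid)
  b2[, c("x", "y", "z")] <- sweep(as.matrix(b2[, c("x", "y", "z")]), 2, mid)
  list(b1 = b1, b2 = b2)
}

# Pose a third nucleotide against a placed pair:
#  - its `anchor` atom is put at `anchor_target`,
#  - its base normal is aligned with `normal`,
#  - the remaining spin about the normal is solved so that the distance
#    between its `second` atom and `second_partner` equals `dist`
#    (closest achievable if no exact solution); among candidate spins the
#    one keeping the base farthest from `avoid` points is kept.
place_third_base <- function(code, with_phosphate, anchor, anchor_target,
                             normal, second, second_partner,
                             dist = PLANT_HB_DIST, avoid = NULL) {
  tmpl <- nucleotide_template(code, with_phosphate = with_phosphate)
  a0 <- as.numeric(tmpl[tmpl$name == anchor, c("x", "y", "z")][1, ])
  tmpl[, c("x", "y", "z")] <-
    sweep(as.matrix(tmpl[, c("x", "y", "z")]), 2, a0)
  nhat <- unit(normal)
  z <- c(0, 0, 1)
  ax <- cross3(z, nhat)
  R0 <- if (vnorm(ax) < 1e-9) {
    if (sum(z * nhat) > 0) diag(3) else rotation_about(c(1, 0, 0), pi)
  } else rotation_about(ax, acos(max(-1, min(1, sum(z * nhat)))))
  s0 <- as.numeric(tmpl[tmpl$name == second, c("x", "y", "z")][1, ]) %*% t(R0)
  pose_second <- function(th) {
    as.numeric(s0 %*% t(rotation_about(nhat, th))) + anchor_target
  }
  f <- function(th) vnorm(pose_second(th) - second_partner) - dist
  grid <- seq(-pi, pi, length.out = 241)
  fg <- vapply(grid, f, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (is.finite(fg[i]) && is.finite(fg[i + 1]) && fg[i] * fg[i + 1] <= 0) {
      roots <- c(roots,
                 stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-10)$root)
    }
  }
  if (!length(roots)) roots <- grid[which.min(abs(fg))]
  score <- vapply(roots, function(th) {
    R <- rotation_about(nhat, th) %*% R0
    at <- transform_atoms(tmpl, R, anchor_target)
    if (is.null(avoid)) return(0)
    bxyz <- as.matrix(at[at$name %in% base_atom_names(code), c("x", "y", "z")])
    min(as.matrix(stats::dist(rbind(bxyz, avoid)))[seq_len(nrow(bxyz)),
                                                   -seq_len(nrow(bxyz))])
  }, numeric(1))
  th <- roots[which.max(score)]
  R <- rotation_about(nhat, th) %*% R0
  transform_atoms(tmpl, R, anchor_target)
}

# Pose a nucleotide so its base-ring centroid lands on `centroid_target`
# with base normal `normal` and a fixed spin (degrees) about it.
place_free_base <- function(code, with_phosphate, centroid_target, normal,
                            spin = 0) {
  tmpl <- nucleotide_template(code, with_phosphate = with_phosphate)
  ctr <- template_ring_centroid(tmpl, code)
  tmpl[, c("x", "y", "z")] <-
    sweep(as.matrix(tmpl[, c("x", "y", "z")]), 2, ctr)
  nhat <- unit(normal)
  z <- c(0, 0, 1)
  ax <- cross3(z, nhat)
  R0 <- if (vnorm(ax) < 1e-9) {
    if (sum(z * nhat) > 0) diag(3) else rotation_about(c(1, 0, 0), pi)
  } else rotation_about(ax, acos(max(-1, min(1, sum(z * nhat)))))
  R <- rotation_about(nhat, spin * pi / 180) %*% R0
  transform_atoms(tmpl, R, centroid_target)
}
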