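#' Reference residues for the classification angles
#'
#' The pseudo-angle xi that separates the conformational families is
#' measured at the midpoint of the apex base pair (default A43-U66)
#' between the bulged probe base (default U40) and the midpoint of the
#' distal base pair (default C45-G64).  The gatekeeper angle for the
#' in/out position of U63 is measured over the residues 44-65-63.
#' Defaults encode the wild-type author numbering.
#'
#' @param apex_pair two residue numbers forming the apex base pair.
#' @param distal_pair two residue numbers forming the distal base pair.
#' @param probe bulged residue whose position xi tracks.
#' @param u63_triplet three residue numbers (pair member, pair member,
#'   bulged base) for the gatekeeper angle, in the order used by the
#'   angle: vertex is the second entry.
#' @return list of class `"AngleSpec"`.
#' @export
angle_spec <- function(apex_pair = c(43, 66), distal_pair = c(45, 64),
                       probe = 40, u63_triplet = c(44, 65, 63)) {
  stopifnot(length(apex_pair) == 2, length(distal_pair) == 2,
            length(probe) == 1, length(u63_triplet) == 3)
  if (anyDuplicated(apex_pair) || anyDuplicated(distal_pair) ||
      anyDuplicated(u63_triplet))
    stop("residue numbers within each role must be distinct")
  structure(list(apex_pair = apex_pair, distal_pair = distal_pair,
                 probe = probe, u63_triplet = u63_triplet),
            class = "AngleSpec")
}

#' Base-ring centroid of a nucleotide residue
#'
#' Unweighted mean of the ring heavy atoms (pyrimidines: N1, C2, N3, C4,
#' C5, C6; purines: those of the six-ring plus N7, C8, N9).  Ring
#' centroids are the reference points used by [xi_angle()] and
#' [u63_angle()]: they are rotation-robust and insensitive to missing
#' hydrogens.
#'
#' @param res atom table of one residue (as returned internally), or a
#'   [conformation()] together with `resno`.
#' @param resno,chain residue selector when `res` is a conformation.
#' @return 3-vector (x, y, z) in Angstrom.
#' @export
base_centroid <- function(res, resno = NULL, chain = NULL) {
  if (inherits(res, "Conformation")) res <- residue_atoms(res, resno, chain)
  code <- res$resid[1]
  if (!is_rna_residue(code))
    stop("residue ", res$resno[1], " (", code, ") is not a standard nucleotide")
  ring <- RING_ATOMS[[code]]
  missing_atoms <- setdiff(ring, res$name)
  if (length(missing_atoms))
    stop("residue ", res$resno[1], " lacks ring atoms: ",
         paste(missing_atoms, collapse = ", "))
  unname(colMeans(atom_xyz(res[res$name %in% ring, , drop = FALSE])))
}

pair_midpoint <- function(conf, pair, chain = NULL) {
  (base_centroid(conf, pair[1], chain) + base_centroid(conf, pair[2], chain)) / 2
}

#' Classification pseudo-angle xi
#'
#' Angle (degrees) at the apex base-pair midpoint between the direction
#' to the probe base centroid and the direction to the distal base-pair
#' midpoint.  Low values (<= 60) indicate the compact M1 family, mid
#' values (60, 100] the M2 family, and values above 100 extended (E)
#' structures; see [assign_family()].
#'
#' @param conf a [conformation()].
#' @param spec an [angle_spec()].
#' @param chain chain holding the RNA (default: the unique RNA chain).
#' @return angle in degrees, in \[0, 180\].
#' @export
xi_angle <- function(conf, spec = angle_spec(), chain = NULL) {
  v <- pair_midpoint(conf, spec$apex_pair, chain)
  w <- pair_midpoint(conf, spec$distal_pair, chain)
  p <- base_centroid(conf, spec$probe, chain)
  angle_at(v, p, w)
}

#' Gatekeeper angle for the bulged base U63
#'
#' Angle (degrees) at the centroid of the second triplet residue
#' (default A65) between the first (default U44) and third (default U63),
#' tracking whether the bulged base points into or away from the major
#' groove.
#'
#' @inheritParams xi_angle
#' @return angle in degrees, in \[0, 180\].
#' @export
u63_angle <- function(conf, spec = angle_spec(), chain = NULL) {
  tr <- spec$u63_triplet
  v <- base_centroid(conf, tr[2], chain)
  a <- base_centroid(conf, tr[1], chain)
  b <- base_centroid(conf, tr[3], chain)
  angle_at(v, a, b)
}

# Standard atomic masses for mass-weighted selections.
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                 P = 30.974, S = 32.06)

#' Radius of gyration
#'
#' `sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i))` over the selected atoms,
#' with `w_i` the atomic mass when `mass_weighted` and 1 otherwise;
#' default selection is all heavy atoms.
#'
#' @param conf a [conformation()].
#' @param selection logical or integer index into the atom table
#'   (default: heavy atoms).
#' @param mass_weighted weight atoms by atomic mass.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(conf, selection = NULL,
                               mass_weighted = FALSE) {
  a <- conf$atoms
  if (is.null(selection)) selection <- a$element != "H"
  a <- a[selection, , drop = FALSE]
  if (nrow(a) == 0) stop("empty selection")
  w <- if (mass_weighted) {
    m <- ATOMIC_MASS[a$element]
    if (anyNA(m)) stop("no atomic mass for element(s): ",
                       paste(unique(a$element[is.na(m)]), collapse = ", "))
    m
  } else rep(1, nrow(a))
  xyz <- atom_xyz(a)
  ctr <- colSums(xyz * w) / sum(w)
  sq <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * sq) / sum(w))
}

#' Optimal rigid superposition and RMSD
#'
#' Pairs atoms 1:1 between two conformations by (chain, residue number,
#' atom name) over a selection, computes the least-squares (Kabsch)
#' superposition restricted to proper rotations, and returns the RMSD
#' together with the rotation and translation mapping `a` onto `b`.
#'
#' @param a,b [conformation()] objects.
#' @param selection function taking an atom table and returning a logical
#'   mask, or NULL for all heavy atoms.
#' @return list with `rmsd` (Angstrom), `rotation` (3x3, row-vector
#'   convention), `translation`.
#' @export
superpose_rmsd <- function(a, b, selection = NULL) {
  pick <- function(conf) {
    at <- conf$atoms
    m <- if (is.null(selection)) at$element != "H" else selection(at)
    at[m, , drop = FALSE]
  }
  aa <- pick(a)
  bb <- pick(b)
  ka <- paste(aa$chain, aa$resno, aa$name, sep = "|")
  kb <- paste(bb$chain, bb$resno, bb$name, sep = "|")
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("duplicate (chain, resno, atom) keys; cannot pair atoms 1:1")
  unpaired <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(unpaired))
    stop("mismatched atom sets; unpaired: ",
         paste(utils::head(unpaired, 5), collapse = ", "),
         if (length(unpaired) > 5) " ...")
  bb <- bb[match(ka, kb), , drop = FALSE]
  x <- atom_xyz(aa)
  y <- atom_xyz(bb)
  if (nrow(x) < 3) stop("need at least 3 paired atoms")
  fit <- kabsch(x, y)
  xr <- sweep(x %*% fit$rotation, 2, -fit$translation)
  list(rmsd = sqrt(mean(rowSums((xr - y)^2))),
       rotation = fit$rotation, translation = fit$translation)
}
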