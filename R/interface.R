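# Peptide-RNA interface profiling: distance fingerprints, solvent
# accessible surface area (Shrake-Rupley), gap index, Coulomb energy.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20)

atom_radii <- function(atoms) {
  r <- VDW_RADII[atoms$element]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(atoms$element[is.na(r)]), collapse = ", "))
  as.numeric(r)
}

# squared-distance matrix between two coordinate sets
dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

#' CA-phosphate and CA-C4 distance fingerprints
#'
#' For every peptide residue, the distance from its CA atom to the
#' closest RNA phosphate P (backbone proximity) and to the closest base
#' C4 atom (groove penetration).  5'-terminal RNA residues without a
#' phosphate are simply absent from the P pool.
#'
#' @param x a complex [conformation()] or an [ensemble()] of complexes
#'   (the ensemble version averages per residue).
#' @param pep_chain,rna_chain chain identifiers.
#' @return data.frame with `resno`, `resid`, `ca_p`, `ca_c4` (Angstrom;
#'   ensemble version adds `ca_p_sd`, `ca_c4_sd`).
#' @export
distance_fingerprint <- function(x, pep_chain = "B", rna_chain = "A") {
  if (inherits(x, "Ensemble")) {
    per <- lapply(x$frames, distance_fingerprint, pep_chain = pep_chain,
                  rna_chain = rna_chain)
    out <- per[[1]][, c("resno", "resid")]
    cap <- sapply(per, function(d) d$ca_p)
    cac <- sapply(per, function(d) d$ca_c4)
    if (is.null(dim(cap))) cap <- matrix(cap, nrow = 1)
    if (is.null(dim(cac))) cac <- matrix(cac, nrow = 1)
    out$ca_p <- rowMeans(cap)
    out$ca_c4 <- rowMeans(cac)
    out$ca_p_sd <- apply(cap, 1, stats::sd)
    out$ca_c4_sd <- apply(cac, 1, stats::sd)
    if (length(per) == 1) out$ca_p_sd <- out$ca_c4_sd <- 0
    return(out)
  }
  a <- x$atoms
  pep <- a[a$chain == pep_chain, , drop = FALSE]
  rna <- a[a$chain == rna_chain, , drop = FALSE]
  if (!nrow(pep)) stop("no atoms on peptide chain ", pep_chain)
  if (!nrow(rna)) stop("no atoms on RNA chain ", rna_chain)
  ca <- pep[pep$name == "CA", , drop = FALSE]
  pep_res <- unique(pep$resno)
  if (!all(pep_res %in% ca$resno))
    stop("peptide residue(s) without CA: ",
         paste(setdiff(pep_res, ca$resno), collapse = ", "))
  p_pool <- rna[rna$name == "P", , drop = FALSE]
  c4_pool <- rna[rna$name == "C4" &
                   mapply(function(r, n) n %in% base_atom_names(r),
                          rna$resid, rna$name), , drop = FALSE]
  if (!nrow(p_pool)) stop("no phosphate P atoms on RNA chain")
  if (!nrow(c4_pool)) stop("no base C4 atoms on RNA chain")
  dp <- sqrt(pmax(dist2(atom_xyz(ca), atom_xyz(p_pool)), 0))
  dc <- sqrt(pmax(dist2(atom_xyz(ca), atom_xyz(c4_pool)), 0))
  data.frame(resno = ca$resno, resid = ca$resid,
             ca_p = apply(dp, 1, min), ca_c4 = apply(dc, 1, min),
             stringsAsFactors = FALSE)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA with 960 Fibonacci-lattice sphere points per atom and a
#' probe of 1.4 Angstrom (water) by default.
#'
#' @param conf a [conformation()] (hydrogens, if present, are included;
#'   pass a pre-filtered conformation for heavy-atom-only areas).
#' @param probe probe radius, Angstrom.
#' @param n_points sphere points per atom.
#' @return numeric vector of per-atom areas (sums to the total SASA).
#' @export
sasa <- function(conf, probe = 1.4, n_points = 960) {
  a <- conf$atoms
  r <- atom_radii(a) + probe
  xyz <- atom_xyz(a)
  n <- nrow(xyz)
  sp <- sphere_points(n_points)
  d2 <- dist2(xyz, xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    pts <- sweep(sp * r[i], 2, xyz[i, ], "+")
    if (length(neigh)) {
      acc <- rep(TRUE, n_points)
      for (j in neigh) {
        acc[acc] <- rowSums(sweep(pts[acc, , drop = FALSE], 2,
                                  xyz[j, ])^2) > r[j]^2
        if (!any(acc)) break
      }
      frac <- sum(acc) / n_points
    } else frac <- 1
    out[i] <- 4 * pi * r[i]^2 * frac
  }
  out
}

chain_conf <- function(conf, chains) {
  conformation(conf$atoms[conf$atoms$chain %in% chains, , drop = FALSE],
               tag = conf$tag)
}

#' Buried interface area between two chains
#'
#' `(SASA_A + SASA_B - SASA_AB) / 2`: the mean per-chain surface area
#' buried on complex formation.
#'
#' @inheritParams gap_index
#' @return area in Angstrom^2.
#' @export
buried_area <- function(complex, pep_chain = "B", rna_chain = "A",
                        probe = 1.4) {
  sa <- sum(sasa(chain_conf(complex, pep_chain), probe))
  sb <- sum(sasa(chain_conf(complex, rna_chain), probe))
  sab <- sum(sasa(chain_conf(complex, c(pep_chain, rna_chain)), probe))
  (sa + sb - sab) / 2
}

#' Gap index of a two-chain interface
#'
#' Ratio of the gap volume between the two molecular surfaces to the
#' buried interface area; small values indicate a snug, complementary
#' fit.  The gap volume is measured on a cubic grid (default 0.8 A):
#' cells outside both van der Waals surfaces, within `cap` (4.0 A) of
#' atoms of both chains, and located between the chains (the directions
#' from the cell to the nearest atom of each chain oppose each other,
#' which excludes solvent-open rim cells and is stable under grid
#' refinement).
#'
#' @param complex a [conformation()] holding both chains.
#' @param pep_chain,rna_chain chain identifiers.
#' @param grid grid spacing, Angstrom.
#' @param cap maximum distance from each chain for a gap cell, Angstrom.
#' @param probe probe radius for the buried-area denominator.
#' @return list with `gap_index` (Angstrom), `gap_volume` (A^3),
#'   `interface_area` (A^2).
#' @export
gap_index <- function(complex, pep_chain = "B", rna_chain = "A",
                      grid = 0.8, cap = 4.0, probe = 1.4) {
  area <- buried_area(complex, pep_chain, rna_chain, probe)
  if (area <= 1e-6) stop("chains are not in contact (zero buried area)")
  a <- complex$atoms
  pa <- a[a$chain == pep_chain, , drop = FALSE]
  ra <- a[a$chain == rna_chain, , drop = FALSE]
  px <- atom_xyz(pa); rx <- atom_xyz(ra)
  pr <- atom_radii(pa); rr <- atom_radii(ra)
  lo <- pmax(apply(px, 2, min), apply(rx, 2, min)) - cap
  hi <- pmin(apply(px, 2, max), apply(rx, 2, max)) + cap
  if (any(lo >= hi)) stop("chains are not in contact (disjoint boxes)")
  gx <- seq(lo[1], hi[1], by = grid)
  gy <- seq(lo[2], hi[2], by = grid)
  gz <- seq(lo[3], hi[3], by = grid)
  cells <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  # surface distance and nearest atom per chain, chunked
  near_chain <- function(cells, xyz, rad) {
    nn <- numeric(nrow(cells))
    ni <- integer(nrow(cells))
    step <- 20000
    for (s in seq(1, nrow(cells), by = step)) {
      e <- min(s + step - 1, nrow(cells))
      d2c <- dist2(cells[s:e, , drop = FALSE], xyz)
      d2c <- sweep(sqrt(pmax(d2c, 0)), 2, rad)   # distance to vdW surface
      j <- max.col(-d2c, ties.method = "first")
      ni[s:e] <- j
      nn[s:e] <- d2c[cbind(seq_len(e - s + 1), j)]
    }
    list(dist = nn, idx = ni)
  }
  np <- near_chain(cells, px, pr)
  nr <- near_chain(cells, rx, rr)
  cand <- np$dist > 0 & nr$dist > 0 & np$dist <= cap & nr$dist <= cap
  # betweenness: the two chains must lie on opposite sides of the cell
  va <- px[np$idx, , drop = FALSE] - cells
  vb <- rx[nr$idx, , drop = FALSE] - cells
  between <- rowSums(va * vb) < 0
  n_gap <- sum(cand & between)
  vol <- n_gap * grid^3
  list(gap_index = vol / area, gap_volume = vol, interface_area = area)
}

charge_of_atoms <- function(atoms) {
  q <- numeric(nrow(atoms))
  rna <- is_rna_residue(atoms$resid)
  q[rna & atoms$name %in% c("OP1", "OP2")] <- -0.5
  q[atoms$resid == "LYS" & atoms$name == "NZ"] <- 1
  q[atoms$resid == "ARG" & atoms$name %in% c("NH1", "NH2")] <- 0.5
  q[atoms$resid == "ASP" & atoms$name %in% c("OD1", "OD2")] <- -0.5
  q[atoms$resid == "GLU" & atoms$name %in% c("OE1", "OE2")] <- -0.5
  # peptide termini at pH 7: +1 on the N-terminal N, -1 on the
  # C-terminal carboxylate (split over O/OXT when both are present)
  pep <- which(!rna)
  if (length(pep)) {
    pa <- atoms[pep, ]
    for (ch in unique(pa$chain)) {
      rs <- pa$resno[pa$chain == ch]
      first <- min(rs); last <- max(rs)
      q[pep[pa$chain == ch & pa$resno == first & pa$name == "N"]] <- 1
      term <- pep[pa$chain == ch & pa$resno == last &
                    pa$name %in% c("O", "OXT")]
      if (length(term)) q[term] <- q[term] - 1 / length(term)
    }
  }
  q
}

#' Coulomb interaction energy between two chains
#'
#' `E = 332.06 sum_ij q_i q_j / (eps r_ij)` in kcal/mol over all
#' inter-chain atom pairs, with a simple formal-charge model at pH 7
#' (phosphate -1 split over OP1/OP2; Lys/Arg +1; Asp/Glu -1; charged
#' termini) and a uniform dielectric (default 78.5, water).
#'
#' @param complex a [conformation()].
#' @param pep_chain,rna_chain chain identifiers.
#' @param dielectric relative dielectric constant.
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(complex, pep_chain = "B", rna_chain = "A",
                           dielectric = 78.5) {
  a <- complex$atoms
  pa <- a[a$chain == pep_chain, , drop = FALSE]
  ra <- a[a$chain == rna_chain, , drop = FALSE]
  if (!nrow(pa) || !nrow(ra)) stop("missing chain")
  qp <- charge_of_atoms(pa)
  qr <- charge_of_atoms(ra)
  ip <- which(qp != 0)
  ir <- which(qr != 0)
  if (!length(ip) || !length(ir)) return(0)
  d <- sqrt(pmax(dist2(atom_xyz(pa[ip, , drop = FALSE]),
                       atom_xyz(ra[ir, , drop = FALSE])), 0))
  if (any(d < 1e-6)) stop("overlapping charged atoms")
  332.06 / dielectric * sum(outer(qp[ip], qr[ir]) / d)
}

#' Aggregate interface report over an ensemble of complexes
#'
#' Runs the distance fingerprint, gap index, Coulomb energy and buried
#' area on every frame and the hydrogen-bond persistence across frames;
#' scalar series are summarized as mean and standard deviation.
#'
#' @param ens an [ensemble()] of two-chain complexes (or a single
#'   [conformation()]).
#' @param pep_chain,rna_chain chain identifiers.
#' @param grid,dielectric,probe forwarded to the stage functions.
#' @param criteria an [hbond_criteria()].
#' @return list of class `"InterfaceReport"` with `fingerprint`,
#'   `series` (per-frame gap index, Coulomb energy, buried area),
#'   `summary` (mean/sd), and `hbond_persistence`.
#' @export
interface_report <- function(ens, pep_chain = "B", rna_chain = "A",
                             grid = 0.8, dielectric = 78.5, probe = 1.4,
                             criteria = hbond_criteria()) {
  if (inherits(ens, "Conformation")) ens <- ensemble(list(ens))
  stopifnot(inherits(ens, "Ensemble"))
  g <- vapply(ens$frames, function(fr)
    gap_index(fr, pep_chain, rna_chain, grid = grid,
              probe = probe)$gap_index, numeric(1))
  e <- vapply(ens$frames, function(fr)
    coulomb_energy(fr, pep_chain, rna_chain, dielectric), numeric(1))
  b <- vapply(ens$frames, function(fr)
    buried_area(fr, pep_chain, rna_chain, probe), numeric(1))
  fp <- distance_fingerprint(ens, pep_chain, rna_chain)
  hb <- hbond_persistence(ens, list(chain = pep_chain),
                          list(chain = rna_chain), criteria)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(list(
    fingerprint = fp,
    series = data.frame(frame = seq_along(ens$frames), gap_index = g,
                        coulomb = e, buried_area = b),
    summary = data.frame(
      quantity = c("gap_index", "coulomb", "buried_area"),
      mean = c(mean(g), mean(e), mean(b)),
      sd = c(sd0(g), sd0(e), sd0(b))),
    hbond_persistence = hb), class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat("InterfaceReport over", nrow(x$series), "frame(s)\n")
  print(x$summary, row.names = FALSE)
  cat("persistent peptide-RNA H-bonds:", nrow(x$hbond_persistence), "\n")
  invisible(x)
}
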