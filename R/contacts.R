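# Hydrogen bonds, base pairs and base-triplet annotation.

the_tables <- new.env(parent = emptyenv())

donor_acceptor_table <- function() {
  if (is.null(the_tables$da)) {
    f <- system.file("extdata", "donor_acceptor.csv", package = "hairpinscape")
    if (!nzchar(f)) f <- file.path("inst", "extdata", "donor_acceptor.csv")
    the_tables$da <- utils::read.csv(f, stringsAsFactors = FALSE)
  }
  the_tables$da
}

#' Geometric hydrogen-bond criteria
#'
#' Heavy-atom donor-acceptor distance cutoff plus, when the donor
#' hydrogen is present, a minimum D-H...A angle.  These thresholds follow
#' common structural practice; they are deliberately exposed because the
#' counts reported for crystallographic models depend on them.
#'
#' @param d_max heavy-atom donor-acceptor distance cutoff, Angstrom.
#' @param a_min minimum D-H...A angle in degrees, applied only when a
#'   hydrogen is bonded to the donor (heavy-atom-only structures fall
#'   back to the distance criterion).
#' @return list of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(d_max = 3.5, a_min = 120) {
  stopifnot(d_max > 0, a_min >= 0, a_min <= 180)
  structure(list(d_max = d_max, a_min = a_min), class = "hbond_criteria")
}

atom_res_key <- function(a) paste(a$chain, a$resno, a$icode, sep = "|")

#' Detect hydrogen bonds
#'
#' All donor-acceptor heavy-atom pairs (from the bundled donor/acceptor
#' table covering A/C/G/U and the 20 amino acids) within
#' `criteria$d_max`, excluding intra-residue pairs; when hydrogens are
#' present on a donor the D-H...A angle must also exceed
#' `criteria$a_min`.
#'
#' @param conf a [conformation()].
#' @param criteria an [hbond_criteria()].
#' @return data.frame with one row per bond: donor/acceptor chain,
#'   residue number, residue code and atom name, `distance` (Angstrom)
#'   and `dha_angle` (degrees, NA when no donor hydrogen exists).
#' @export
detect_hbonds <- function(conf, criteria = hbond_criteria()) {
  a <- conf$atoms
  da <- donor_acceptor_table()
  key <- paste(a$resid, a$name)
  don_idx <- which(key %in% paste(da$resid[da$role == "donor"],
                                  da$atom[da$role == "donor"]))
  acc_idx <- which(key %in% paste(da$resid[da$role == "acceptor"],
                                  da$atom[da$role == "acceptor"]))
  empty <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resid = character(0), donor_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      acceptor_resid = character(0),
                      acceptor_atom = character(0),
                      distance = numeric(0), dha_angle = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(don_idx) || !length(acc_idx)) return(empty)
  dx <- atom_xyz(a[don_idx, ])
  ax <- atom_xyz(a[acc_idx, ])
  d2 <- outer(rowSums(dx^2), rep(1, nrow(ax))) +
    outer(rep(1, nrow(dx)), rowSums(ax^2)) - 2 * dx %*% t(ax)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= criteria$d_max^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  di <- don_idx[hit[, 1]]
  ai <- acc_idx[hit[, 2]]
  same_res <- atom_res_key(a[di, ]) == atom_res_key(a[ai, ])
  keep <- !same_res & di != ai
  di <- di[keep]; ai <- ai[keep]
  if (!length(di)) return(empty)
  dist_da <- sqrt(d2[hit[keep, , drop = FALSE]])
  # D-H...A angle when hydrogens ride on the donor (within 1.3 A)
  hyd <- which(a$element == "H")
  ang <- rep(NA_real_, length(di))
  if (length(hyd)) {
    hxyz <- atom_xyz(a[hyd, ])
    hres <- atom_res_key(a[hyd, ])
    for (j in seq_along(di)) {
      don <- as.numeric(a[di[j], c("x", "y", "z")])
      cand <- hyd[hres == atom_res_key(a[di[j], , drop = FALSE])]
      if (!length(cand)) next
      hh <- atom_xyz(a[cand, , drop = FALSE])
      bonded <- sqrt(rowSums(sweep(hh, 2, don)^2)) <= 1.3
      if (!any(bonded)) next
      acc <- as.numeric(a[ai[j], c("x", "y", "z")])
      ang[j] <- max(apply(hh[bonded, , drop = FALSE], 1, function(h)
        angle_at(h, don, acc)))
    }
  }
  ok <- is.na(ang) | ang >= criteria$a_min
  di <- di[ok]; ai <- ai[ok]; dist_da <- dist_da[ok]; ang <- ang[ok]
  # one record per unordered atom pair (atoms that are both donor and
  # acceptor would otherwise be reported twice)
  pair_key <- ifelse(di < ai, paste(di, ai), paste(ai, di))
  first <- !duplicated(pair_key)
  di <- di[first]; ai <- ai[first]
  dist_da <- dist_da[first]; ang <- ang[first]
  out <- data.frame(
    donor_chain = a$chain[di], donor_resno = a$resno[di],
    donor_resid = a$resid[di], donor_atom = a$name[di],
    acceptor_chain = a$chain[ai], acceptor_resno = a$resno[ai],
    acceptor_resid = a$resid[ai], acceptor_atom = a$name[ai],
    distance = dist_da, dha_angle = ang, stringsAsFactors = FALSE)
  out[order(out$donor_resno, out$acceptor_resno, out$donor_atom), ]
}

#' Hydrogen-bond count for one residue
#'
#' Number of detected hydrogen bonds a residue participates in (either
#' role).  For an ensemble the unweighted mean across frames is returned.
#'
#' @param target a [conformation()] or [ensemble()].
#' @param resno residue number.
#' @param chain optional chain restriction for the residue.
#' @param criteria an [hbond_criteria()].
#' @return numeric count (or mean count).
#' @export
hbond_count <- function(target, resno, chain = NULL,
                        criteria = hbond_criteria()) {
  if (inherits(target, "Ensemble")) {
    return(mean(vapply(target$frames, hbond_count, numeric(1),
                       resno = resno, chain = chain, criteria = criteria)))
  }
  residue_atoms(target, resno, chain)  # errors if unknown
  hb <- detect_hbonds(target, criteria)
  in_d <- hb$donor_resno == resno
  in_a <- hb$acceptor_resno == resno
  if (!is.null(chain)) {
    in_d <- in_d & hb$donor_chain == chain
    in_a <- in_a & hb$acceptor_chain == chain
  }
  sum(in_d | in_a)
}

base_ring_xyz <- function(conf, resno, chain = NULL) {
  res <- residue_atoms(conf, resno, chain)
  atom_xyz(res[res$name %in% RING_ATOMS[[res$resid[1]]], , drop = FALSE])
}

#' Detect base pairs
#'
#' Residue pairs supported by at least two inter-base hydrogen bonds,
#' with base-ring centroid distance <= 7 Angstrom and an angle between
#' the least-squares base planes <= 35 degrees (admitting propellered
#' pairs).  The `wc` flag marks canonical Watson-Crick combinations whose
#' canonical atom contacts are among the supporting bonds.
#'
#' @param conf a [conformation()].
#' @param criteria an [hbond_criteria()].
#' @param max_centroid_dist,max_plane_angle geometric cutoffs.
#' @return data.frame with `res_a` < `res_b`, chain, supporting bond
#'   count `n_hbonds`, `plane_angle`, and logical `wc`.
#' @export
detect_base_pairs <- function(conf, criteria = hbond_criteria(),
                              max_centroid_dist = 7,
                              max_plane_angle = 35) {
  hb <- detect_hbonds(conf, criteria)
  rt <- residue_table(conf)
  rt <- rt[is_rna_residue(rt$resid), , drop = FALSE]
  empty <- data.frame(res_a = integer(0), res_b = integer(0),
                      chain_a = character(0), chain_b = character(0),
                      n_hbonds = integer(0), plane_angle = numeric(0),
                      wc = logical(0), stringsAsFactors = FALSE)
  if (nrow(rt) < 2 || !nrow(hb)) return(empty)
  # inter-base bonds only
  is_base_atom <- function(resid, name) {
    mapply(function(r, n) is_rna_residue(r) && n %in% base_atom_names(r),
           resid, name, USE.NAMES = FALSE)
  }
  bb <- hb[is_base_atom(hb$donor_resid, hb$donor_atom) &
             is_base_atom(hb$acceptor_resid, hb$acceptor_atom), ,
           drop = FALSE]
  if (!nrow(bb)) return(empty)
  key <- function(ch, rn) paste(ch, rn, sep = "|")
  pk <- ifelse(key(bb$donor_chain, bb$donor_resno) <
                 key(bb$acceptor_chain, bb$acceptor_resno),
               paste(key(bb$donor_chain, bb$donor_resno),
                     key(bb$acceptor_chain, bb$acceptor_resno)),
               paste(key(bb$acceptor_chain, bb$acceptor_resno),
                     key(bb$donor_chain, bb$donor_resno)))
  counts <- table(pk)
  cand <- names(counts)[counts >= 2]
  rows <- lapply(cand, function(k) {
    pp <- strsplit(k, " ", fixed = TRUE)[[1]]
    p1 <- strsplit(pp[1], "|", fixed = TRUE)[[1]]
    p2 <- strsplit(pp[2], "|", fixed = TRUE)[[1]]
    ch1 <- p1[1]; rn1 <- as.integer(p1[2])
    ch2 <- p2[1]; rn2 <- as.integer(p2[2])
    ring1 <- base_ring_xyz(conf, rn1, ch1)
    ring2 <- base_ring_xyz(conf, rn2, ch2)
    if (nrow(ring1) < 3 || nrow(ring2) < 3) return(NULL)
    cd <- vnorm(colMeans(ring1) - colMeans(ring2))
    if (cd > max_centroid_dist) return(NULL)
    n1 <- fit_plane(ring1)$normal
    n2 <- fit_plane(ring2)$normal
    pa <- acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
    if (pa > max_plane_angle) return(NULL)
    # pairing bonds must run roughly within the base planes (>= 45 deg
    # away from both normals); this separates edge-to-edge pairing from
    # stacking contacts that satisfy the distance criterion alone
    sel_rows <- bb[pk == k, , drop = FALSE]
    inplane <- vapply(seq_len(nrow(sel_rows)), function(r) {
      hbrow <- sel_rows[r, ]
      dpos <- conf$atoms[conf$atoms$chain == hbrow$donor_chain &
                           conf$atoms$resno == hbrow$donor_resno &
                           conf$atoms$name == hbrow$donor_atom, ]
      apos <- conf$atoms[conf$atoms$chain == hbrow$acceptor_chain &
                           conf$atoms$resno == hbrow$acceptor_resno &
                           conf$atoms$name == hbrow$acceptor_atom, ]
      v <- unit(as.numeric(apos[1, c("x", "y", "z")]) -
                  as.numeric(dpos[1, c("x", "y", "z")]))
      a1 <- acos(min(1, abs(sum(v * n1)))) * 180 / pi
      a2 <- acos(min(1, abs(sum(v * n2)))) * 180 / pi
      a1 >= 45 && a2 >= 45
    }, logical(1))
    if (sum(inplane) < 2) return(NULL)
    # canonical Watson-Crick?
    r1 <- residue_atoms(conf, rn1, ch1)$resid[1]
    r2 <- residue_atoms(conf, rn2, ch2)$resid[1]
    wc <- FALSE
    wcb <- WC_BONDS[[paste(r1, r2, sep = "|")]]
    if (!is.null(wcb)) {
      sel <- pk == k
      got <- paste(pmin(paste(bb$donor_resno[sel], bb$donor_atom[sel]),
                        paste(bb$acceptor_resno[sel], bb$acceptor_atom[sel])),
                   pmax(paste(bb$donor_resno[sel], bb$donor_atom[sel]),
                        paste(bb$acceptor_resno[sel], bb$acceptor_atom[sel])))
      want <- vapply(wcb, function(bnd) {
        a1 <- paste(rn1, bnd[1]); a2 <- paste(rn2, bnd[2])
        paste(pmin(a1, a2), pmax(a1, a2))
      }, character(1))
      wc <- sum(want %in% got) >= 2
    }
    swap <- rn1 > rn2
    data.frame(res_a = if (swap) rn2 else rn1,
               res_b = if (swap) rn1 else rn2,
               chain_a = if (swap) ch2 else ch1,
               chain_b = if (swap) ch1 else ch2,
               n_hbonds = as.integer(sum(inplane)), plane_angle = pa,
               wc = wc, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$res_a, out$res_b), ]
}

# Directed donor->acceptor hydrogen bonds between the base moieties of
# two residue atom tables (distance criterion; unordered-unique pairs).
inter_base_hbonds <- function(ra, rb, criteria) {
  da <- donor_acceptor_table()
  pick <- function(res, role) {
    code <- res$resid[1]
    keep <- res$name %in% intersect(
      base_atom_names(code),
      da$atom[da$resid == code & da$role == role])
    res[keep, , drop = FALSE]
  }
  hits <- function(d, a) {
    if (!nrow(d) || !nrow(a)) return(NULL)
    dm <- sqrt(pmax(dist2(atom_xyz(d), atom_xyz(a)), 0))
    w <- which(dm <= criteria$d_max, arr.ind = TRUE)
    if (!nrow(w)) return(NULL)
    data.frame(donor = d$name[w[, 1]], acceptor = a$name[w[, 2]],
               dist = dm[w], stringsAsFactors = FALSE)
  }
  if (!is_rna_residue(ra$resid[1]) || !is_rna_residue(rb$resid[1]))
    return(data.frame())
  h1 <- hits(pick(ra, "donor"), pick(rb, "acceptor"))
  h2 <- hits(pick(rb, "donor"), pick(ra, "acceptor"))
  if (!is.null(h1)) h1$a_side_donor <- TRUE
  if (!is.null(h2)) h2$a_side_donor <- FALSE
  out <- rbind(h1, h2)
  if (is.null(out) || !nrow(out)) return(data.frame())
  # dedupe unordered atom pairs (atoms with both roles)
  akey <- ifelse(out$a_side_donor, paste(out$donor, out$acceptor),
                 paste(out$acceptor, out$donor))
  out[!duplicated(akey), , drop = FALSE]
}

# Is the (r1, r2) base pair supported: >= 2 inter-base bonds running
# within both base planes, centroids <= 7 A, planes <= 35 deg apart.
pair_supported <- function(conf, r1, r2, criteria) {
  ra <- residue_atoms(conf, r1)
  rb <- residue_atoms(conf, r2)
  if (!is_rna_residue(ra$resid[1]) || !is_rna_residue(rb$resid[1]))
    return(FALSE)
  ring1 <- atom_xyz(ra[ra$name %in% RING_ATOMS[[ra$resid[1]]], ,
                       drop = FALSE])
  ring2 <- atom_xyz(rb[rb$name %in% RING_ATOMS[[rb$resid[1]]], ,
                       drop = FALSE])
  if (nrow(ring1) < 3 || nrow(ring2) < 3) return(FALSE)
  if (vnorm(colMeans(ring1) - colMeans(ring2)) > 7) return(FALSE)
  n1 <- fit_plane(ring1)$normal
  n2 <- fit_plane(ring2)$normal
  if (acos(min(1, abs(sum(n1 * n2)))) * 180 / pi > 35) return(FALSE)
  bonds <- inter_base_hbonds(ra, rb, criteria)
  if (nrow(bonds) < 2) return(FALSE)
  coordsA <- atom_xyz(ra)
  coordsB <- atom_xyz(rb)
  inplane <- vapply(seq_len(nrow(bonds)), function(i) {
    pa <- if (bonds$a_side_donor[i])
      coordsA[match(bonds$donor[i], ra$name), ]
    else coordsA[match(bonds$acceptor[i], ra$name), ]
    pb <- if (bonds$a_side_donor[i])
      coordsB[match(bonds$acceptor[i], rb$name), ]
    else coordsB[match(bonds$donor[i], rb$name), ]
    v <- unit(pb - pa)
    acos(min(1, abs(sum(v * n1)))) * 180 / pi >= 45 &&
      acos(min(1, abs(sum(v * n2)))) * 180 / pi >= 45
  }, logical(1))
  sum(inplane) >= 2
}

# Inter-base hydrogen-bond count between a third base and the two pair
# members (distance criterion).
third_support <- function(conf, third, pair, criteria) {
  rt <- residue_atoms(conf, third)
  if (!is_rna_residue(rt$resid[1])) return(0L)
  sum(vapply(pair, function(p)
    nrow(inter_base_hbonds(rt, residue_atoms(conf, p), criteria)),
    numeric(1)))
}

# canonical triplet definitions: third base joining an existing pair
CANONICAL_TRIPLETS <- list(
  T1     = list(third = 40L, pair = c(45L, 64L)),
  T2     = list(third = 40L, pair = c(43L, 66L)),
  T3     = list(third = 41L, pair = c(43L, 66L)),
  M2STAR = list(third = 63L, pair = c(44L, 65L)))

#' Annotate base triplets
#'
#' A triplet is present when its base pair is detected
#' ([detect_base_pairs()]) and the third base forms at least
#' `min_support` inter-base hydrogen bonds with the pair members.  The
#' canonical triplets of the wild-type hairpin are always reported
#' (`T1` = U40 on C45-G64, `T2` = U40 on A43-U66, `T3` = U41 on A43-U66,
#' `M2STAR` = U63 on U44-A65); any non-canonical base joining a detected
#' pair at the same support level is emitted as `OTHER`.
#'
#' @param conf a [conformation()].
#' @param min_support minimum number of supporting hydrogen bonds from
#'   the third base to the pair members (default 2: U-A-U and U-C-G
#'   triplets canonically form two).
#' @param criteria an [hbond_criteria()].
#' @param include_other also scan every detected base pair for
#'   non-canonical joining bases (slower; the canonical rows do not
#'   depend on it).
#' @return data.frame with `label`, `third`, `res_a`, `res_b`, `present`,
#'   `support`.
#' @export
detect_triplets <- function(conf, min_support = 2,
                            criteria = hbond_criteria(),
                            include_other = TRUE) {
  stopifnot(min_support >= 1)
  have <- conf$atoms$resno
  rows <- lapply(names(CANONICAL_TRIPLETS), function(lbl) {
    tr <- CANONICAL_TRIPLETS[[lbl]]
    ok <- all(c(tr$third, tr$pair) %in% have)
    sup <- if (ok) third_support(conf, tr$third, tr$pair, criteria) else 0L
    pres <- ok && sup >= min_support &&
      pair_supported(conf, tr$pair[1], tr$pair[2], criteria)
    data.frame(label = lbl, third = tr$third,
               res_a = min(tr$pair), res_b = max(tr$pair),
               present = pres, support = as.integer(sup),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (include_other) {
    pairs <- detect_base_pairs(conf, criteria)
    rt <- residue_table(conf)
    rt <- rt[is_rna_residue(rt$resid), ]
    for (i in seq_len(nrow(pairs))) {
      pr <- c(pairs$res_a[i], pairs$res_b[i])
      for (third in setdiff(rt$resno, pr)) {
        canon <- any(vapply(CANONICAL_TRIPLETS, function(tr)
          tr$third == third && setequal(tr$pair, pr), logical(1)))
        if (canon) next
        sup <- third_support(conf, third, pr, criteria)
        if (sup >= min_support) {
          out <- rbind(out, data.frame(
            label = "OTHER", third = third, res_a = pr[1], res_b = pr[2],
            present = TRUE, support = as.integer(sup),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond persistence between two groups across an ensemble
#'
#' For every donor/acceptor atom pair observed between two disjoint atom
#' groups in at least one frame, the fraction of frames in which the bond
#' is present.
#'
#' @param ens an [ensemble()].
#' @param group_a,group_b group selectors: a list with `chain` and/or
#'   `resno` entries (e.g. `list(chain = "B")` for the peptide chain).
#' @param criteria an [hbond_criteria()].
#' @return data.frame with donor/acceptor identifiers and `fraction` in
#'   (0, 1\], sorted by decreasing persistence.
#' @export
hbond_persistence <- function(ens, group_a, group_b,
                              criteria = hbond_criteria()) {
  stopifnot(inherits(ens, "Ensemble"))
  mask <- function(a, g) {
    m <- rep(TRUE, nrow(a))
    if (!is.null(g$chain)) m <- m & a$chain %in% g$chain
    if (!is.null(g$resno)) m <- m & a$resno %in% g$resno
    m
  }
  a1 <- ens$frames[[1]]$atoms
  if (any(mask(a1, group_a) & mask(a1, group_b)))
    stop("groups overlap")
  n <- length(ens$frames)
  seen <- list()
  for (fr in ens$frames) {
    hb <- detect_hbonds(fr, criteria)
    if (!nrow(hb)) next
    a <- fr$atoms
    dm <- mask(a, group_a)[match(paste(hb$donor_chain, hb$donor_resno,
                                       hb$donor_atom),
                                 paste(a$chain, a$resno, a$name))]
    am <- mask(a, group_b)[match(paste(hb$acceptor_chain, hb$acceptor_resno,
                                       hb$acceptor_atom),
                                 paste(a$chain, a$resno, a$name))]
    db <- mask(a, group_b)[match(paste(hb$donor_chain, hb$donor_resno,
                                       hb$donor_atom),
                                 paste(a$chain, a$resno, a$name))]
    ab <- mask(a, group_a)[match(paste(hb$acceptor_chain, hb$acceptor_resno,
                                       hb$acceptor_atom),
                                 paste(a$chain, a$resno, a$name))]
    hb <- hb[(dm & am) | (db & ab), , drop = FALSE]
    if (!nrow(hb)) next
    k <- paste(hb$donor_chain, hb$donor_resno, hb$donor_atom, "->",
               hb$acceptor_chain, hb$acceptor_resno, hb$acceptor_atom)
    for (kk in unique(k)) seen[[kk]] <- (seen[[kk]] %||% 0L) + 1L
  }
  if (!length(seen)) {
    return(data.frame(bond = character(0), fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(bond = names(seen),
                    fraction = unlist(seen, use.names = FALSE) / n,
                    stringsAsFactors = FALSE)
  out[order(-out$fraction, out$bond), ]
}
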