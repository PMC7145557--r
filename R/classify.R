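# Family assignment from the xi coordinate and triplet annotations.

FAMILY_LEVELS <- c("M1", "M2", "M2STAR", "E")

#' Assign a conformational family from xi and triplet annotations
#'
#' The xi bands are `[0, 60]` -> M1, `(60, 100]` -> M2, `(100, 180]` -> E.
#' The published band descriptions overlap at 60 and 100; boundaries are
#' resolved downward (the boundary value belongs to the more compact
#' family) for determinism.  An M2 assignment is refined to M2STAR when
#' the U63-on-U44-A65 triplet is present, mirroring the experimental
#' classification of that state as a subset of M2.
#'
#' @param xi classification angle, degrees in \[0, 180\].
#' @param triplets optional data.frame from [detect_triplets()]; only the
#'   M2STAR row is consulted.
#' @return one of `"M1"`, `"M2"`, `"M2STAR"`, `"E"`.
#' @export
assign_family <- function(xi, triplets = NULL) {
  if (!is.finite(xi) || xi < 0 || xi > 180)
    stop("xi must lie in [0, 180], got ", xi)
  fam <- if (xi <= 60) "M1" else if (xi <= 100) "M2" else "E"
  if (fam == "M2" && !is.null(triplets)) {
    m2s <- triplets$present[triplets$label == "M2STAR"]
    if (length(m2s) && isTRUE(m2s[1])) fam <- "M2STAR"
  }
  fam
}

#' Classify every frame of an ensemble
#'
#' Computes per frame the xi angle, the U44-A65-U63 gatekeeper angle,
#' the triplet annotations and the family label.
#'
#' @param ens an [ensemble()].
#' @param spec an [angle_spec()].
#' @param criteria an [hbond_criteria()] for triplet detection.
#' @param chain chain holding the RNA (default: unique).
#' @return data.frame of class `"ClassifiedFrames"`: `frame`, `tag`,
#'   `xi`, `u63`, `family`, logical `t1`, `t2`, `t3`, `m2star`.
#' @export
classify_ensemble <- function(ens, spec = angle_spec(),
                              criteria = hbond_criteria(), chain = NULL) {
  stopifnot(inherits(ens, "Ensemble"))
  rows <- lapply(seq_along(ens$frames), function(i) {
    fr <- ens$frames[[i]]
    xi <- xi_angle(fr, spec, chain)
    u63 <- u63_angle(fr, spec, chain)
    tr <- detect_triplets(fr, criteria = criteria, include_other = FALSE)
    pres <- function(lbl) {
      p <- tr$present[tr$label == lbl]
      length(p) > 0 && isTRUE(p[1])
    }
    data.frame(frame = i, tag = fr$tag, xi = xi, u63 = u63,
               family = assign_family(xi, tr),
               t1 = pres("T1"), t2 = pres("T2"), t3 = pres("T3"),
               m2star = pres("M2STAR"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ClassifiedFrames", class(out))
  out
}

#' Ensemble composition by family
#'
#' Family fractions over classified frames, uniform by default or with
#' caller-supplied weights (e.g. Boltzmann factors).  M2STAR is reported
#' both separately (`fractions`) and folded into M2 (`fractions_folded`),
#' matching the two ways compact-family content is quoted.
#'
#' @param frames data.frame from [classify_ensemble()] (or any data.frame
#'   with a `family` column).
#' @param weights optional non-negative per-frame weights.
#' @return list of class `"EnsembleComposition"`: `fractions`,
#'   `fractions_folded`, `n`, `weighting`.
#' @export
composition <- function(frames, weights = NULL) {
  fam <- as.character(frames$family)
  n <- length(fam)
  if (n < 1) stop("no frames")
  if (is.null(weights)) {
    w <- rep(1, n)
    weighting <- "uniform"
  } else {
    if (length(weights) != n) stop("weights length mismatch")
    if (any(weights < 0)) stop("negative weights")
    if (sum(weights) <= 0) stop("all-zero weights")
    w <- weights
    weighting <- "weighted"
  }
  w <- w / sum(w)
  frac <- vapply(FAMILY_LEVELS, function(f) sum(w[fam == f]), numeric(1))
  folded <- c(M1 = frac[["M1"]], M2 = frac[["M2"]] + frac[["M2STAR"]],
              E = frac[["E"]])
  structure(list(fractions = frac, fractions_folded = folded, n = n,
                 weighting = weighting), class = "EnsembleComposition")
}

#' @export
print.EnsembleComposition <- function(x, ...) {
  cat("Ensemble composition (", x$weighting, ", n = ", x$n, ")\n", sep = "")
  cat("  ", paste(sprintf("%s: %.1f%%", names(x$fractions),
                          100 * x$fractions), collapse = "  "), "\n")
  cat("  folded:",
      paste(sprintf("%s: %.1f%%", names(x$fractions_folded),
                    100 * x$fractions_folded), collapse = "  "), "\n")
  invisible(x)
}

#' 2-D projection histogram over (xi, u63)
#'
#' Counts of classified frames on a grid over the two classification
#' angles, the numeric analogue of the ensemble heat plots used to
#' visualize structural content.
#'
#' @param frames data.frame from [classify_ensemble()].
#' @param xi_bins,u63_bins strictly increasing bin edges covering
#'   \[0, 180\].
#' @param normalize return densities (fractions) instead of counts.
#' @return matrix of counts, xi bins in rows (dimnames give intervals).
#' @export
projection_histogram <- function(frames,
                                 xi_bins = seq(0, 180, by = 10),
                                 u63_bins = seq(0, 180, by = 10),
                                 normalize = FALSE) {
  check_edges <- function(e) {
    if (any(diff(e) <= 0) || e[1] > 0 || e[length(e)] < 180)
      stop("bin edges must be strictly increasing and cover [0, 180]")
  }
  check_edges(xi_bins)
  check_edges(u63_bins)
  xi_cut <- cut(frames$xi, xi_bins, include.lowest = TRUE)
  u63_cut <- cut(frames$u63, u63_bins, include.lowest = TRUE)
  h <- table(xi = xi_cut, u63 = u63_cut)
  m <- matrix(as.integer(h), nrow = nrow(h),
              dimnames = list(xi = rownames(h), u63 = colnames(h)))
  if (normalize) m <- m / sum(m)
  m
}

#' In/out state of the bulged gatekeeper base
#'
#' @param u63 gatekeeper angle in degrees, \[0, 180\].
#' @param threshold out/in threshold in degrees; the boundary value
#'   counts as "out".
#' @return `"in"` or `"out"`.
#' @export
u63_state <- function(u63, threshold = 100) {
  if (!is.finite(u63) || u63 < 0 || u63 > 180)
    stop("u63 must lie in [0, 180]")
  if (u63 >= threshold) "out" else "in"
}
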