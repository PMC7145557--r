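#' Structural checks against deposited hairpin models
#'
#' Given a locally available multi-model PDB file of the hairpin (for
#' example the crystal structure deposited as 5LYU, downloaded
#' separately), truncates every model to the 37-70 window and reports
#' the quantities used to characterize the experimental models: the
#' classification angle xi, the gatekeeper angle, the radius of
#' gyration, the triplet pattern, and hydrogen-bond counts for the
#' bulged uridines 40 and 41.
#'
#' This function performs no downloading; offline workflows can exercise
#' the identical machinery on the synthetic stand-ins from
#' [synthetic_reference_models()] (which carry planted, not
#' experimental, values).
#'
#' @param source path to a PDB file, or an [ensemble()] /
#'   [conformation()].
#' @param chain chain holding the hairpin (default: first chain).
#' @param first,last residue window (default 37-70).
#' @return data.frame with one row per model: `model`, `xi`, `u63`,
#'   `rg`, `family`, `t1`, `t2`, `t3`, `m2star`, `hb40`, `hb41`.
#' @export
deposited_model_checks <- function(source, chain = NULL, first = 37,
                                   last = 70) {
  ens <- if (inherits(source, "Ensemble")) source
         else if (inherits(source, "Conformation")) ensemble(list(source))
         else read_pdb(source)
  rows <- lapply(seq_along(ens$frames), function(i) {
    fr <- ens$frames[[i]]
    ch <- chain %||% fr$atoms$chain[1]
    hp <- truncate_residues(fr, first, last, ch)
    tr <- detect_triplets(hp)
    pres <- function(lbl) {
      p <- tr$present[tr$label == lbl]
      length(p) > 0 && isTRUE(p[1])
    }
    xi <- xi_angle(hp)
    data.frame(model = i, xi = xi, u63 = u63_angle(hp),
               rg = radius_of_gyration(hp),
               family = assign_family(xi, tr),
               t1 = pres("T1"), t2 = pres("T2"), t3 = pres("T3"),
               m2star = pres("M2STAR"),
               hb40 = hbond_count(hp, 40), hb41 = hbond_count(hp, 41),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
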