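# End-to-end report generation: ensemble classification, landscape
# analysis, interface profiling.  Reports are TSV + JSON with the
# resolved configuration and package version embedded for provenance.

#' Run configuration for the report pipelines
#'
#' Collects every tunable the pipelines use; all entries are plain
#' values, so a config serializes cleanly into the reports it produces.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in reports.
#' @param temperature,prefactor kinetic parameters ([rate_params()]).
#' @param cutoff basin-content energy window, kcal/mol.
#' @param d_max,a_min hydrogen-bond criteria ([hbond_criteria()]).
#' @param grid,dielectric interface parameters.
#' @param u63_threshold in/out threshold for the gatekeeper angle.
#' @param level_spacing disconnectivity level spacing, kcal/mol.
#' @return list of class `"RunConfig"`.
#' @export
run_config <- function(out_dir = tempfile("hairpin_report_"), seed = 1,
                       temperature = 298, prefactor = 1e13, cutoff = 15,
                       d_max = 3.5, a_min = 120, grid = 0.8,
                       dielectric = 78.5, u63_threshold = 100,
                       level_spacing = 1) {
  structure(list(out_dir = out_dir, seed = seed, temperature = temperature,
                 prefactor = prefactor, cutoff = cutoff, d_max = d_max,
                 a_min = a_min, grid = grid, dielectric = dielectric,
                 u63_threshold = u63_threshold,
                 level_spacing = level_spacing), class = "RunConfig")
}

report_provenance <- function(config) {
  list(package = "hairpinscape",
       version = as.character(utils::packageVersion("hairpinscape")),
       config = unclass(config))
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Ensemble classification report
#'
#' Classifies every frame, writes the per-frame table
#' (`frames.tsv`), the projection histogram (`histogram.tsv`) and the
#' composition with provenance (`composition.json`).
#'
#' @param ens an [ensemble()] (or a path to a PDB file readable by
#'   [read_pdb()]).
#' @param config a [run_config()].
#' @param energies optional per-frame energies (kcal/mol) for an
#'   additional Boltzmann-weighted composition.
#' @return list with `frames`, `composition`, `histogram`, `files`.
#' @export
run_ensemble_report <- function(ens, config = run_config(),
                                energies = NULL) {
  if (is.character(ens)) ens <- read_pdb(ens)
  crit <- hbond_criteria(config$d_max, config$a_min)
  cf <- classify_ensemble(ens, criteria = crit)
  comp <- composition(cf)
  comp_b <- NULL
  if (!is.null(energies)) {
    beta <- 1 / (KB_KCAL * config$temperature)
    lw <- -beta * energies
    comp_b <- composition(cf, weights = exp(lw - max(lw)))
  }
  h <- projection_histogram(cf)
  d <- ensure_dir(config$out_dir)
  f_frames <- file.path(d, "frames.tsv")
  utils::write.table(cf, f_frames, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  f_hist <- file.path(d, "histogram.tsv")
  utils::write.table(as.data.frame.table(h, responseName = "count"),
                     f_hist, sep = "\t", row.names = FALSE, quote = FALSE)
  f_comp <- file.path(d, "composition.json")
  payload <- list(provenance = report_provenance(config),
                  n = comp$n,
                  fractions = as.list(comp$fractions),
                  fractions_folded = as.list(comp$fractions_folded))
  if (!is.null(comp_b))
    payload$fractions_boltzmann <- as.list(comp_b$fractions)
  jsonlite::write_json(payload, f_comp, auto_unbox = TRUE, digits = NA)
  list(frames = cf, composition = comp, composition_boltzmann = comp_b,
       histogram = h, files = c(f_frames, f_hist, f_comp))
}

#' Energy-landscape report
#'
#' Occupation probabilities, basin content at the configured cutoff for
#' each requested bottom, inter-funnel rates and free-energy gaps for
#' each funnel pair, and a disconnectivity SVG colored by family.
#'
#' @param net a `TransitionNetwork` (labels required for basin content).
#' @param config a [run_config()].
#' @param bottoms minima ids of funnel bottoms (default: the global
#'   minimum).
#' @return list with `occupation`, `basins`, `rates`, `gaps`, `files`.
#' @export
run_landscape_report <- function(net, config = run_config(),
                                 bottoms = NULL) {
  params <- rate_params(config$temperature, config$prefactor)
  occ <- occupation(net, params)
  if (is.null(bottoms))
    bottoms <- net$minima$id[which.min(net$minima$energy)]
  assign <- funnel_assignment(net, bottoms)
  basins <- NULL
  if (!anyNA(net$minima$family)) {
    basins <- lapply(bottoms, function(b)
      basin_content(net, b, cutoff = config$cutoff, params = params))
    names(basins) <- paste0("bottom_", bottoms)
  }
  rates <- list(); gaps <- list()
  if (length(bottoms) > 1 && nrow(net$ts)) {
    for (i in seq_len(length(bottoms) - 1)) {
      for (j in (i + 1):length(bottoms)) {
        sa <- net$minima$id[assign == bottoms[i] & !is.na(assign)]
        sb <- net$minima$id[assign == bottoms[j] & !is.na(assign)]
        key <- paste0(bottoms[i], "_", bottoms[j])
        rates[[key]] <- interfunnel_rate(net, sa, sb, params, "gt")
        gaps[[key]] <- free_energy_gap(net, sa, sb, params)
      }
    }
  }
  d <- ensure_dir(config$out_dir)
  f_svg <- file.path(d, "disconnectivity.svg")
  coloring <- stats::setNames(
    ifelse(is.na(net$minima$family), "unassigned", net$minima$family),
    net$minima$id)
  render_dgraph(build_dgraph(net, config$level_spacing), coloring, f_svg)
  f_json <- file.path(d, "landscape.json")
  jsonlite::write_json(list(
    provenance = report_provenance(config),
    occupation = as.list(occ),
    funnel_assignment = as.list(stats::setNames(as.integer(assign),
                                                names(assign))),
    basin_content = lapply(basins, function(b) list(
      members = b$members,
      uniform = as.list(b$uniform$fractions_folded),
      boltzmann = as.list(b$boltzmann$fractions_folded))),
    interfunnel_rates = rates,
    free_energy_gaps = gaps), f_json, auto_unbox = TRUE, digits = NA)
  list(occupation = occ, assignment = assign, basins = basins,
       rates = rates, gaps = gaps, files = c(f_svg, f_json))
}

#' Peptide-RNA interface report
#'
#' Runs [interface_report()] and writes the fingerprint TSV, the
#' per-frame series TSV and a JSON summary (gap index, Coulomb energy,
#' buried area, hydrogen-bond persistence).
#'
#' @param ens an [ensemble()] of complexes (or single conformation).
#' @param config a [run_config()].
#' @param pep_chain,rna_chain chain identifiers.
#' @return the [interface_report()] list, plus `files`.
#' @export
run_interface_report <- function(ens, config = run_config(),
                                 pep_chain = "B", rna_chain = "A") {
  rep <- interface_report(ens, pep_chain, rna_chain, grid = config$grid,
                          dielectric = config$dielectric,
                          criteria = hbond_criteria(config$d_max,
                                                    config$a_min))
  d <- ensure_dir(config$out_dir)
  f_fp <- file.path(d, "fingerprint.tsv")
  utils::write.table(rep$fingerprint, f_fp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  f_series <- file.path(d, "series.tsv")
  utils::write.table(rep$series, f_series, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  f_json <- file.path(d, "interface.json")
  jsonlite::write_json(list(
    provenance = report_provenance(config),
    summary = rep$summary,
    hbond_persistence = rep$hbond_persistence), f_json,
    auto_unbox = TRUE, digits = NA)
  rep$files <- c(f_fp, f_series, f_json)
  rep
}
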