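#' Read a (multi-model) PDB file into an Ensemble
#'
#' Parses fixed-column PDB text (via bio3d) into one [conformation()] per
#' selected MODEL record.  HETATM records (waters, ions, ligands) are
#' excluded by default; alternate locations are resolved to the highest
#' occupancy copy, ties broken by altloc letter order.
#'
#' @param source path to a PDB file, or a character vector of PDB lines.
#' @param models integer vector selecting models (default: all).
#' @param keep_het keep HETATM records as well.
#' @return an [ensemble()] with one frame per selected model.
#' @examples
#' hp <- build_hairpin(template = family_template("M2"), seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(ensemble(list(hp$conformation)), f)
#' ens <- read_pdb(f)
#' length(ens$frames)
#' @export
read_pdb <- function(source, models = NULL, keep_het = FALSE) {
  if (length(source) > 1 || grepl("\n", source[1], fixed = TRUE)) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    writeLines(unlist(strsplit(source, "\n", fixed = TRUE)), tf)
    source <- tf
  }
  if (!file.exists(source)) stop("no such file: ", source)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(source, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", source, ": ",
                             conditionMessage(e)))
  keep_type <- pdb$atom$type == "ATOM" |
    (keep_het & pdb$atom$type == "HETATM")
  row_ids <- which(keep_type)
  if (!length(row_ids)) stop("no ATOM records in ", source)
  at <- pdb$atom[row_ids, , drop = FALSE]
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad))
    stop("malformed ATOM record (non-numeric coordinates) for atom serial ",
         paste(utils::head(at$eleno[bad], 3), collapse = ", "))
  # altloc resolution: keep highest occupancy, ties by altloc letter
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, sep = "|")
  ord <- order(key, -occ, alt)
  sel <- sort(ord[!duplicated(key[ord])])
  row_ids <- row_ids[sel]
  at <- at[sel, , drop = FALSE]
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  if (is.null(models)) models <- seq_len(nmod)
  models <- as.integer(models)
  if (!length(models)) stop("empty model selection")
  if (any(models < 1 | models > nmod))
    stop("model selection out of range 1..", nmod)
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
  elem <- at$elesy
  elem[is.na(elem) | !nzchar(elem)] <-
    guess_element(at$elety[is.na(elem) | !nzchar(elem)])
  frames <- lapply(models, function(m) {
    ci <- as.numeric(rbind(xyz[m, 3 * row_ids - 2],
                           xyz[m, 3 * row_ids - 1],
                           xyz[m, 3 * row_ids]))
    co <- matrix(ci, ncol = 3, byrow = TRUE)
    conformation(data.frame(
      serial = at$eleno, name = at$elety, resid = at$resid,
      chain = ifelse(is.na(at$chain), "A", at$chain), resno = at$resno,
      icode = ifelse(is.na(at$insert), "", at$insert),
      x = co[, 1], y = co[, 2], z = co[, 3],
      element = toupper(elem), stringsAsFactors = FALSE),
      tag = paste0("model", m))
  })
  ensemble(frames)
}

guess_element <- function(name) {
  e <- sub("^[0-9']*", "", name)
  substr(toupper(e), 1, 1)
}

#' Write an Ensemble to a PDB file
#'
#' Single-frame ensembles are written without MODEL records unless
#' `force_models = TRUE`; multi-frame ensembles get one MODEL/ENDMDL block
#' per frame.  Round-trips through [read_pdb()] preserve topology exactly
#' and coordinates to the PDB fixed-width precision (1e-3 A).
#'
#' @param ens an [ensemble()].
#' @param sink output file path.
#' @param force_models write MODEL records even for one frame.
#' @return `sink`, invisibly.
#' @export
write_pdb <- function(ens, sink, force_models = FALSE) {
  if (!inherits(ens, "Ensemble")) stop("ens must be an Ensemble")
  if (!length(ens$frames)) stop("empty ensemble")
  frame_lines <- lapply(ens$frames, function(fr) {
    a <- fr$atoms
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    suppressWarnings(bio3d::write.pdb(
      file = tf, xyz = as.numeric(t(atom_xyz(a))),
      type = rep("ATOM", nrow(a)), resno = a$resno, resid = a$resid,
      eleno = a$serial, elety = a$name, chain = a$chain,
      insert = ifelse(nzchar(a$icode), a$icode, NA),
      o = rep(1, nrow(a)), b = rep(0, nrow(a)), elesy = a$element))
    ln <- readLines(tf)
    ln[grepl("^(ATOM|HETATM|TER)", ln)]
  })
  con <- file(sink, "w")
  on.exit(close(con), add = TRUE)
  if (length(frame_lines) == 1 && !force_models) {
    writeLines(c(frame_lines[[1]], "END"), con)
  } else {
    for (i in seq_along(frame_lines)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(frame_lines[[i]], con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(sink)
}

#' Select a residue window from a conformation
#'
#' Restricts a conformation to residues `first..last` (author numbering)
#' on one chain, e.g. the 37-70 top-half window of the hairpin.
#'
#' @param conf a [conformation()].
#' @param first,last residue number bounds (inclusive).
#' @param chain chain identifier; may be omitted when the conformation has
#'   a single chain.
#' @return the truncated [conformation()]; residue order is preserved.
#' @export
truncate_residues <- function(conf, first, last, chain = NULL) {
  stopifnot(inherits(conf, "Conformation"))
  if (first > last) stop("first must be <= last")
  chains <- unique(conf$atoms$chain)
  if (is.null(chain)) {
    if (length(chains) > 1)
      stop("conformation has several chains (", paste(chains, collapse = ","),
           "); give chain")
    chain <- chains
  }
  if (!chain %in% chains) stop("no chain ", chain, " in conformation")
  sel <- conf$atoms$chain == chain &
    conf$atoms$resno >= first & conf$atoms$resno <= last
  if (!any(sel))
    stop("no residues in range ", first, "-", last, " on chain ", chain)
  conformation(conf$atoms[sel, , drop = FALSE], tag = conf$tag)
}

#' Apply sequence mutations to an RNA conformation
#'
#' Mutation strings follow the compact convention
#' `"<From><Number><To>"` for substitutions (several joined by `"+"`,
#' order-independent) and `"del<Base><Number>"` for deletions, e.g.
#' `"U40C"`, `"A39G+U68C"`, `"delU63"`.  A substitution rebuilds only the
#' base moiety of the target residue: the ideal base template of the new
#' nucleotide is superposed on the glycosidic attachment frame
#' (glycosidic N, C1' direction, base plane) of the old one, so sugar and
#' backbone atoms are untouched.  Deletion removes the residue without
#' renumbering.
#'
#' @param conf a [conformation()].
#' @param spec mutation string.
#' @return the mutated [conformation()].
#' @export
apply_mutation <- function(conf, spec) {
  stopifnot(inherits(conf, "Conformation"))
  parts <- trimws(strsplit(spec, "+", fixed = TRUE)[[1]])
  for (p in parts) {
    if (grepl("^del", p)) {
      m <- regmatches(p, regexec("^del([ACGU])([0-9]+)$", p))[[1]]
      if (!length(m)) stop("cannot parse deletion '", p, "'")
      conf <- mutate_delete(conf, m[2], as.integer(m[3]))
    } else {
      m <- regmatches(p, regexec("^([ACGU])([0-9]+)([ACGU])$", p))[[1]]
      if (!length(m)) stop("cannot parse mutation '", p, "'")
      conf <- mutate_substitute(conf, m[2], as.integer(m[3]), m[4])
    }
  }
  conf
}

mutate_delete <- function(conf, from, resno) {
  res <- residue_atoms(conf, resno)
  if (res$resid[1] != from)
    stop("residue ", resno, " is ", res$resid[1], ", not ", from)
  keep <- !(conf$atoms$resno == resno & conf$atoms$chain == res$chain[1])
  conformation(conf$atoms[keep, , drop = FALSE], tag = conf$tag)
}

mutate_substitute <- function(conf, from, resno, to) {
  res <- residue_atoms(conf, resno)
  if (res$resid[1] != from)
    stop("residue ", resno, " is ", res$resid[1], ", not ", from)
  chain <- res$chain[1]
  old_glyc <- glycosidic_atom(from)
  need <- c(old_glyc, "C1'")
  if (!all(need %in% res$name))
    stop("residue ", resno, " lacks ", paste(setdiff(need, res$name),
                                             collapse = ","),
         "; cannot anchor the base rebuild")
  gl <- as.numeric(res[res$name == old_glyc, c("x", "y", "z")][1, ])
  c1 <- as.numeric(res[res$name == "C1'", c("x", "y", "z")][1, ])
  ring <- res[res$name %in% RING_ATOMS[[from]], c("x", "y", "z")]
  nrm <- if (nrow(ring) >= 3) fit_plane(as.matrix(ring))$normal
         else c(0, 0, 1)
  # orthonormal frame at the glycosidic N: u along N->C1', w = plane normal
  u <- unit(c1 - gl)
  w <- unit(nrm - sum(nrm * u) * u)
  v <- cross3(w, u)
  frame_old <- cbind(u, v, w)
  tmpl <- base_template(to)
  new_glyc <- glycosidic_atom(to)
  # template frame: glycosidic N at origin, C1' along -x, normal +z
  u0 <- c(-1, 0, 0); w0 <- c(0, 0, 1); v0 <- cross3(w0, u0)
  frame_tmpl <- cbind(u0, v0, w0)
  R <- frame_old %*% t(frame_tmpl)
  placed <- transform_atoms(tmpl, R, gl)
  a <- conf$atoms
  in_res <- a$resno == resno & a$chain == chain
  old_base <- in_res & a$name %in% base_atom_names(from)
  kept <- a[!old_base, , drop = FALSE]
  serial0 <- max(res$serial)
  add <- data.frame(serial = serial0 + seq_len(nrow(placed)) / 100,
                    name = placed$name, resid = to, chain = chain,
                    resno = resno, icode = res$icode[1],
                    x = placed$x, y = placed$y, z = placed$z,
                    element = placed$element, stringsAsFactors = FALSE)
  kept$resid[kept$resno == resno & kept$chain == chain] <- to
  # splice the rebuilt base right after the residue's backbone atoms
  out <- rbind(kept, add)
  out <- out[order(match(paste(out$chain, out$resno),
                         unique(paste(a$chain, a$resno))), out$serial), ]
  out$serial <- seq_len(nrow(out))
  conformation(out, tag = conf$tag)
}
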