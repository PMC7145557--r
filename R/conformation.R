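#' Conformation and Ensemble containers
#'
#' A `Conformation` is one all-atom structure (RNA, optionally with a bound
#' peptide chain) stored as a flat atom table in author residue numbering;
#' an `Ensemble` is a list of conformations sharing residue topology, with
#' optional per-frame weights.
#'
#' @param atoms data.frame with columns `serial`, `name` (PDB atom label),
#'   `resid` (residue code: A/C/G/U or an amino-acid 3-letter code),
#'   `chain`, `resno` (author numbering), `icode`, `x`, `y`, `z`,
#'   `element`.
#' @param tag free-form source label (model index, accession, builder
#'   template name, ...).
#' @return `conformation()` returns an object of class `"Conformation"`;
#'   `ensemble()` an object of class `"Ensemble"`.
#' @examples
#' at <- data.frame(serial = 1, name = "C4", resid = "U", chain = "A",
#'                  resno = 40, icode = "", x = 0, y = 0, z = 0,
#'                  element = "C")
#' conf <- conformation(at, tag = "toy")
#' ens <- ensemble(list(conf))
#' @export
conformation <- function(atoms, tag = "") {
  required <- c("serial", "name", "resid", "chain", "resno", "icode",
                "x", "y", "z", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("a Conformation needs at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$name))) stop("empty atom names")
  atoms <- atoms[required]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, tag = as.character(tag)),
            class = "Conformation")
}

#' @param frames list of `Conformation` objects with identical
#'   (chain, resno, resid) sequences.
#' @param weights optional non-negative per-frame weights; normalized to
#'   sum to one.
#' @rdname conformation
#' @export
ensemble <- function(frames, weights = NULL) {
  if (!length(frames)) stop("an Ensemble needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "Conformation")))
    stop("all frames must be Conformation objects")
  key <- residue_key(frames[[1]])
  for (i in seq_along(frames)[-1]) {
    if (!identical(residue_key(frames[[i]]), key))
      stop("frame ", i, " has a different residue topology than frame 1")
  }
  if (!is.null(weights)) {
    if (length(weights) != length(frames))
      stop("weights length must match frame count")
    if (any(weights < 0)) stop("weights must be non-negative")
    s <- sum(weights)
    if (s <= 0) stop("weights sum to zero")
    weights <- weights / s
  }
  structure(list(frames = frames, weights = weights), class = "Ensemble")
}

residue_key <- function(conf) {
  rt <- residue_table(conf)
  paste(rt$chain, rt$resno, rt$resid, sep = "|")
}

#' Residue-level view of a conformation
#'
#' @param conf a `Conformation`.
#' @return data.frame with one row per residue (`chain`, `resno`, `icode`,
#'   `resid`), in atom-table order.
#' @export
residue_table <- function(conf) {
  a <- conf$atoms
  id <- paste(a$chain, a$resno, a$icode, sep = "|")
  keep <- !duplicated(id)
  out <- data.frame(chain = a$chain[keep], resno = a$resno[keep],
                    icode = a$icode[keep], resid = a$resid[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Atom rows of one residue; chain = NULL matches any chain (error if the
# residue number is ambiguous across chains).
residue_atoms <- function(conf, resno, chain = NULL) {
  a <- conf$atoms
  sel <- a$resno == resno
  if (!is.null(chain)) sel <- sel & a$chain == chain
  rows <- a[sel, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("residue ", resno, if (!is.null(chain)) paste0(" (chain ", chain, ")"),
         " not found")
  if (is.null(chain) && length(unique(rows$chain)) > 1)
    stop("residue number ", resno, " is ambiguous across chains; give chain")
  rows
}

atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

# Replace the coordinate block of a conformation.
set_xyz <- function(conf, xyz) {
  stopifnot(nrow(xyz) == nrow(conf$atoms))
  conf$atoms$x <- xyz[, 1]
  conf$atoms$y <- xyz[, 2]
  conf$atoms$z <- xyz[, 3]
  conf
}

RNA_CODES <- c("A", "C", "G", "U")

is_rna_residue <- function(resid) resid %in% RNA_CODES

#' @export
print.Conformation <- function(x, ...) {
  rt <- residue_table(x)
  cat("Conformation", if (nzchar(x$tag)) paste0("[", x$tag, "]"), ":",
      nrow(rt), "residues,", nrow(x$atoms), "atoms\n")
  for (ch in unique(rt$chain)) {
    rr <- rt[rt$chain == ch, ]
    cat("  chain ", ch, ": ", min(rr$resno), "-", max(rr$resno),
        " (", paste(utils::head(rr$resid, 8), collapse = ""),
        if (nrow(rr) > 8) "...", ")\n", sep = "")
  }
  invisible(x)
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble:", length(x$frames), "frames,",
      nrow(x$frames[[1]]$atoms), "atoms/frame",
      if (!is.null(x$weights)) "(weighted)", "\n")
  invisible(x)
}
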