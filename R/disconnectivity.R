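# Disconnectivity graphs (superbasin trees) and funnel assignment.

# components of `ids` under edges (matrix with columns min1, min2),
# by union-find with canonical ordering for determinism
components_under <- function(ids, edges) {
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- match(edges[r, 1], ids)
      j <- match(edges[r, 2], ids)
      if (is.na(i) || is.na(j)) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  split(ids, roots)
}

#' Build a disconnectivity graph (superbasin tree)
#'
#' Starting from `e_top` (default: highest transition-state energy plus
#' one spacing) and descending in steps of `level_spacing`, minima below
#' each threshold are grouped into superbasins by union-find over
#' transition states below the threshold; the tree records where
#' superbasins split.  Leaves sit at the energies of their minima.
#'
#' @param net a `TransitionNetwork`.
#' @param level_spacing energy spacing between levels, kcal/mol.
#' @param e_top optional top threshold.
#' @return a `DGraphNode`: list with `level_energy`, `members` (minima
#'   ids), `children` (list of `DGraphNode`), and for leaves `minimum`
#'   (the id) — or a list of such trees (a forest) when the network is
#'   disconnected.
#' @export
build_dgraph <- function(net, level_spacing = 1, e_top = NULL) {
  stopifnot(level_spacing > 0)
  if (!nrow(net$minima)) stop("empty network")
  if (is.null(e_top)) {
    e_top <- if (nrow(net$ts)) max(net$ts$energy) + level_spacing
             else max(net$minima$energy) + level_spacing
  }
  ids <- sort(net$minima$id)
  energy_of <- function(id) net$minima$energy[match(id, net$minima$id)]
  descend <- function(members, level) {
    if (length(members) == 1) {
      return(list(level_energy = energy_of(members), members = members,
                  children = list(), minimum = members))
    }
    nxt <- level - level_spacing
    sub_edges <- net$ts[net$ts$energy < nxt, c("min1", "min2"), drop = FALSE]
    sub_ids <- members[energy_of(members) < nxt]
    comps <- if (length(sub_ids))
      components_under(sub_ids, as.matrix(sub_edges)) else list()
    # minima at or above the next threshold terminate as leaves here
    high <- setdiff(members, sub_ids)
    kids <- c(lapply(comps, function(cc) descend(sort(cc), nxt)),
              lapply(high, function(id)
                list(level_energy = energy_of(id), members = id,
                     children = list(), minimum = id)))
    if (length(kids) == 1) return(kids[[1]])
    list(level_energy = level, members = sort(members), children = kids,
         minimum = NA)
  }
  edges <- net$ts[net$ts$energy < e_top, c("min1", "min2"), drop = FALSE]
  top_comps <- components_under(ids, as.matrix(edges))
  trees <- lapply(top_comps, function(cc) descend(sort(cc), e_top))
  if (length(trees) == 1) trees[[1]] else unname(trees)
}

dgraph_leaves <- function(node) {
  if (!length(node$children)) return(list(node))
  do.call(c, lapply(node$children, dgraph_leaves))
}

#' Assign minima to funnels by minimax-path attraction
#'
#' Each minimum is assigned to the designated bottom reachable over the
#' path whose highest transition-state energy is lowest (the minimax
#' barrier); ties go to the lower-energy bottom.  Computed on the
#' minimum spanning tree of the barrier-weighted graph (the minimax
#' barrier between two nodes equals the largest edge on their MST path).
#'
#' @param net a `TransitionNetwork`.
#' @param bottoms vector of minima ids designating funnel bottoms.
#' @return named integer vector: for every minimum id, the id of its
#'   funnel bottom (NA for minima disconnected from all bottoms).
#' @export
funnel_assignment <- function(net, bottoms) {
  if (!length(bottoms)) stop("no bottoms given")
  bottoms <- unique(as.integer(bottoms))
  if (!all(bottoms %in% net$minima$id)) stop("unknown bottom id")
  ids <- net$minima$id
  if (!nrow(net$ts)) {
    out <- rep(NA_integer_, length(ids))
    names(out) <- ids
    out[as.character(bottoms)] <- bottoms
    return(out)
  }
  # collapse parallel transition states to their lowest energy
  ekey <- paste(pmin(net$ts$min1, net$ts$min2),
                pmax(net$ts$min1, net$ts$min2))
  emin <- tapply(net$ts$energy, ekey, min)
  epairs <- do.call(rbind, strsplit(names(emin), " "))
  g <- igraph::graph_from_data_frame(
    data.frame(from = epairs[, 1], to = epairs[, 2],
               weight = as.numeric(emin)),
    directed = FALSE, vertices = data.frame(name = as.character(ids)))
  mst <- igraph::mst(g)
  barrier_to <- function(b) {
    # unique tree paths; weights ignored for path finding (energies may
    # be negative), only the max edge energy along the path matters
    paths <- suppressWarnings(
      igraph::shortest_paths(mst, from = as.character(b),
                             to = igraph::V(mst), output = "epath",
                             weights = NA))
    vapply(seq_along(paths$epath), function(i) {
      ep <- paths$epath[[i]]
      if (length(ep) == 0) {
        v <- igraph::V(mst)$name[i]
        if (v == as.character(b)) -Inf else Inf
      } else max(igraph::E(mst)$weight[ep])
    }, numeric(1))
  }
  B <- vapply(bottoms, barrier_to, numeric(length(ids)))
  if (length(ids) == 1) B <- matrix(B, nrow = 1)
  vnames <- igraph::V(mst)$name
  bot_energy <- net$minima$energy[match(bottoms, net$minima$id)]
  assign_one <- function(rowv) {
    if (all(is.infinite(rowv) & rowv > 0)) return(NA_integer_)
    best <- which(rowv == min(rowv))
    if (length(best) > 1) best <- best[which.min(bot_energy[best])]
    bottoms[best]
  }
  res <- vapply(seq_along(vnames), function(i) assign_one(B[i, ]),
                integer(1))
  out <- res[match(as.character(ids), vnames)]
  names(out) <- ids
  out
}

DG_FAMILY_COLORS <- c(M1 = "#1f4fd8", M2 = "#2ca02c", M2STAR = "#145214",
                      E = "#d62728", unassigned = "#808080")

#' Render a disconnectivity graph to SVG
#'
#' Vertical energy axis in kcal/mol; leaves are ordered deterministically
#' (children sorted by decreasing member count, then by lowest member
#' id) and colored by family (M1 blue, M2 green, M2* dark green, E red).
#'
#' @param root a `DGraphNode` from [build_dgraph()].
#' @param coloring named vector mapping minimum id -> family label.
#' @param sink output SVG path.
#' @param width,height canvas size in pixels.
#' @return `sink`, invisibly.
#' @export
render_dgraph <- function(root, coloring = NULL, sink,
                          width = 600, height = 500) {
  leaves <- list()
  order_children <- function(node) {
    if (!length(node$children)) return(node)
    sizes <- vapply(node$children, function(ch) length(ch$members),
                    numeric(1))
    firsts <- vapply(node$children, function(ch) min(ch$members), numeric(1))
    node$children <- lapply(node$children[order(-sizes, firsts)],
                            order_children)
    node
  }
  root <- order_children(root)
  # assign leaf x slots left to right
  xslot <- new.env(parent = emptyenv())
  xslot$next_x <- 0
  place <- function(node) {
    if (!length(node$children)) {
      node$x <- xslot$next_x
      xslot$next_x <- xslot$next_x + 1
    } else {
      node$children <- lapply(node$children, place)
      node$x <- mean(vapply(node$children, function(ch) ch$x, numeric(1)))
    }
    node
  }
  root <- place(root)
  nleaf <- xslot$next_x
  all_e <- c()
  collect_e <- function(node) {
    all_e <<- c(all_e, node$level_energy)
    lapply(node$children, collect_e)
    invisible(NULL)
  }
  collect_e(root)
  e_range <- range(all_e)
  pad <- 40
  sx <- function(x) pad + (x + 0.5) / max(nleaf, 1) * (width - 2 * pad)
  sy <- function(e) {
    if (diff(e_range) < 1e-12) return(height / 2)
    pad + (e_range[2] - e) / diff(e_range) * (height - 2 * pad)
  }
  segs <- character(0)
  draw <- function(node) {
    for (ch in node$children) {
      col <- "#000000"
      if (!length(ch$children) && !is.null(coloring)) {
        fam <- coloring[as.character(ch$minimum)]
        col <- DG_FAMILY_COLORS[fam]
        if (is.na(col)) col <- "#808080"
      }
      # vertical drop to the child's level, horizontal shift at this level
      segs <<- c(segs,
        sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-width="1.5"/>',
                sx(node$x), sy(node$level_energy), sx(ch$x),
                sy(node$level_energy), "#000000"),
        sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-width="1.5"/>',
                sx(ch$x), sy(node$level_energy), sx(ch$x),
                sy(ch$level_energy), col))
      draw(ch)
    }
  }
  draw(root)
  axis <- sprintf(
    '<line x1="%d" y1="%d" x2="%d" y2="%.2f" stroke="#444" stroke-width="1"/><text x="%d" y="%d" font-size="11" transform="rotate(-90 14 %d)">energy / kcal mol-1</text>',
    18, pad, 18, height - pad, 14, height / 2, height / 2)
  lab <- sprintf('<text x="%d" y="%.2f" font-size="10">%.1f</text><text x="%d" y="%.2f" font-size="10">%.1f</text>',
                 2, sy(e_range[2]) + 4, e_range[2], 2, sy(e_range[1]) + 4,
                 e_range[1])
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   width, height),
           '<rect width="100%" height="100%" fill="white"/>',
           axis, lab, segs,
           if (!length(root$children))
             sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#000" stroke-width="1.5"/>',
                     sx(root$x), sy(e_range[2]), sx(root$x),
                     sy(root$level_energy)),
           '</svg>')
  writeLines(svg, sink)
  invisible(sink)
}
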