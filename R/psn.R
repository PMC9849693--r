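#' Frame-wise interaction records
#'
#' Tidies a table of per-frame non-bonded interactions between residues into
#' the canonical form used by the PSN builder: one row per
#' (frame, unordered residue pair, interaction class), duplicates within a
#' frame collapsed.
#'
#' @param frame Integer frame indices (0-based or 1-based, only the count
#'   matters), all `< n_frames` when `n_frames` is supplied downstream.
#' @param residue_i,residue_j Node identifiers (e.g. `"E31"`, `"A:E31"`).
#' @param interaction_class One of `"hbond"`, `"electrostatic"`,
#'   `"hydrophobic"` per row.
#' @return `data.frame` of class `"interaction_records"` with columns
#'   `frame`, `residue_i`, `residue_j`, `interaction_class`, pairs stored
#'   canonically (i < j lexicographically), same-frame duplicates removed.
#' @export
interaction_records <- function(frame, residue_i, residue_j, interaction_class) {
  stopifnot(length(frame) == length(residue_i),
            length(frame) == length(residue_j),
            length(frame) == length(interaction_class))
  residue_i <- as.character(residue_i)
  residue_j <- as.character(residue_j)
  if (any(residue_i == residue_j))
    stop("self-interactions (residue_i == residue_j) are not allowed")
  cls <- as.character(interaction_class)
  bad <- setdiff(unique(cls), c("hbond", "electrostatic", "hydrophobic"))
  if (length(bad))
    stop("unknown interaction class(es): ", paste(bad, collapse = ", "))
  swap <- residue_i > residue_j
  a <- ifelse(swap, residue_j, residue_i)
  b <- ifelse(swap, residue_i, residue_j)
  df <- unique(data.frame(frame = as.integer(frame), residue_i = a,
                          residue_j = b, interaction_class = cls,
                          stringsAsFactors = FALSE))
  class(df) <- c("interaction_records", "data.frame")
  df
}

#' Interaction persistence from frame-wise records
#'
#' For each residue pair (and interaction class), the fraction of trajectory
#' frames in which the interaction is present. Duplicate records of a pair
#' within the same frame count once.
#'
#' @param records An [interaction_records()] table (or coercible data.frame
#'   with the same columns).
#' @param n_frames Total number of frames in the trajectory (>= 1).
#' @param by_class Keep classes separate (default `TRUE`); otherwise a pair
#'   is "present" in a frame if any class is.
#' @return Object of class `"persistence_matrix"`: list with `pairs`
#'   (data.frame `residue_i`, `residue_j`, `interaction_class`,
#'   `persistence`), `nodes`, `n_frames`.
#' @export
persistence_from_records <- function(records, n_frames, by_class = TRUE) {
  if (!inherits(records, "interaction_records"))
    records <- interaction_records(records$frame, records$residue_i,
                                   records$residue_j, records$interaction_class)
  stopifnot(n_frames >= 1)
  if (nrow(records) && any(records$frame >= n_frames | records$frame < 0))
    stop("frame index out of range [0, n_frames)")
  if (nrow(records) == 0) {
    pairs <- data.frame(residue_i = character(), residue_j = character(),
                        interaction_class = character(),
                        persistence = numeric(), stringsAsFactors = FALSE)
  } else if (by_class) {
    key <- paste(records$residue_i, records$residue_j,
                 records$interaction_class, sep = "\r")
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
    pairs <- data.frame(residue_i = parts[, 1], residue_j = parts[, 2],
                        interaction_class = parts[, 3],
                        persistence = as.numeric(cnt) / n_frames,
                        stringsAsFactors = FALSE)
  } else {
    u <- unique(records[, c("frame", "residue_i", "residue_j")])
    key <- paste(u$residue_i, u$residue_j, sep = "\r")
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
    pairs <- data.frame(residue_i = parts[, 1], residue_j = parts[, 2],
                        interaction_class = "any",
                        persistence = as.numeric(cnt) / n_frames,
                        stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 nodes = sort(unique(c(pairs$residue_i, pairs$residue_j))),
                 n_frames = n_frames),
            class = "persistence_matrix")
}

## Merge per-class persistences of a pair into one value.
.merge_pairs <- function(pm, classes = NULL, merge = c("max", "sum")) {
  merge <- match.arg(merge)
  pr <- pm$pairs
  if (!is.null(classes)) pr <- pr[pr$interaction_class %in% classes, , drop = FALSE]
  if (nrow(pr) == 0) return(pr[, c("residue_i", "residue_j", "persistence")])
  key <- paste(pr$residue_i, pr$residue_j, sep = "\r")
  agg <- tapply(pr$persistence, key, if (merge == "max") max else sum)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(residue_i = parts[, 1], residue_j = parts[, 2],
                    persistence = pmin(as.numeric(agg), 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the persistence threshold from the hydrophobic-cluster curve
#'
#' Scans candidate thresholds and, at each, builds the hydrophobic-only
#' interaction graph and records the size of its largest connected
#' component. The selected threshold sits at the knee of this curve: the
#' last grid point *before* the steepest drop in cluster size (the most
#' inclusive network consistent with the transition; ties between equal
#' drops resolve to the smaller threshold). When the curve is flat or the
#' hydrophobic network is degenerate (largest cluster under 3 nodes at the
#' most permissive threshold), the conventional default 0.2 is returned
#' with a warning.
#'
#' @param persistence A `"persistence_matrix"` (only hydrophobic entries
#'   are used; if none are tagged hydrophobic, all entries are used).
#' @param scan_grid Candidate thresholds in (0, 1), at least 10 points.
#' @param fallback Threshold returned for flat/degenerate curves.
#' @return List with `pt` (selected threshold), `curve` (data.frame `pt`,
#'   `largest_cluster`), `fallback_used`.
#' @export
select_pt <- function(persistence,
                      scan_grid = seq(0.1, 0.9, by = 0.05),
                      fallback = 0.2) {
  stopifnot(inherits(persistence, "persistence_matrix"))
  if (length(scan_grid) < 10 || any(scan_grid <= 0) || any(scan_grid >= 1))
    stop("scan_grid must contain at least 10 thresholds in (0, 1)")
  scan_grid <- sort(scan_grid)
  hp <- .merge_pairs(persistence, classes = "hydrophobic")
  if (nrow(hp) == 0) hp <- .merge_pairs(persistence)

  curve <- data.frame(pt = scan_grid, largest_cluster = 0L)
  if (nrow(hp) == 0) {
    warning("empty hydrophobic network: falling back to pT = ", fallback)
    return(list(pt = fallback, curve = curve, fallback_used = TRUE))
  }
  for (k in seq_along(scan_grid)) {
    keep <- hp[hp$persistence >= scan_grid[k], , drop = FALSE]
    if (nrow(keep) == 0) { curve$largest_cluster[k] <- 0L; next }
    g <- igraph::graph_from_data_frame(keep[, 1:2], directed = FALSE)
    curve$largest_cluster[k] <- max(igraph::components(g)$csize)
  }
  drops <- -diff(curve$largest_cluster)
  if (max(curve$largest_cluster) < 3 || all(drops <= 0)) {
    warning("flat or degenerate hydrophobic-cluster curve: falling back to pT = ",
            fallback)
    return(list(pt = fallback, curve = curve, fallback_used = TRUE))
  }
  k_drop <- which.max(drops)          # first index of the steepest drop
  list(pt = scan_grid[k_drop], curve = curve, fallback_used = FALSE)
}

#' Build a protein structure network from a persistence matrix
#'
#' Residues become nodes; a pair becomes an edge when its interaction
#' persistence (merged across classes, by default taking the maximum) meets
#' the persistence threshold `pt`. Edges are weighted by persistence; the
#' producing `pt` travels with the graph.
#'
#' @param persistence A `"persistence_matrix"`.
#' @param pt Persistence threshold in (0, 1).
#' @param merge How per-class persistences combine into one pair value:
#'   `"max"` (default) or `"sum"` (capped at 1).
#' @param nodes Optional character vector of nodes to force into the graph
#'   even when isolated (e.g. all residues of the chain).
#' @return Object of class `"psn_graph"`: list with `graph` (igraph,
#'   undirected, edge attribute `persistence`), `pt`, `edges` (data.frame).
#' @export
build_psn <- function(persistence, pt, merge = c("max", "sum"), nodes = NULL) {
  stopifnot(inherits(persistence, "persistence_matrix"))
  merge <- match.arg(merge)
  if (pt <= 0 || pt >= 1) stop("pt must lie in (0, 1)")
  pr <- .merge_pairs(persistence, merge = merge)
  keep <- pr[pr$persistence >= pt, , drop = FALSE]
  all_nodes <- sort(unique(c(persistence$nodes, nodes)))
  g <- igraph::graph_from_data_frame(
    keep[, c("residue_i", "residue_j")], directed = FALSE,
    vertices = data.frame(name = all_nodes))
  igraph::E(g)$persistence <- keep$persistence
  structure(list(graph = g, pt = pt, edges = keep), class = "psn_graph")
}

#' @export
print.psn_graph <- function(x, ...) {
  cat(sprintf("<psn_graph> %d nodes, %d edges, pT = %.3g\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$pt))
  invisible(x)
}

#' Hub residues of a structure network
#'
#' Degree centrality of every node, the hub set (degree > `min_degree` is
#' the working notion of "hub"; the default `min_degree = 4` keeps nodes
#' with at least 5 persistent interactions), and a comparative reporting
#' set of nodes reaching `report_degree` in at least one of the supplied
#' graphs.
#'
#' @param psn A `"psn_graph"`.
#' @param min_degree Hub cutoff: nodes with degree > `min_degree` are hubs.
#' @param report_degree Reporting cutoff (degree >= `report_degree`).
#' @param others Optional list of further `"psn_graph"` objects; the
#'   reporting set is the union of nodes reaching `report_degree` in any.
#' @return List with `degrees` (named vector), `hubs` (character),
#'   `reporting_set` (character).
#' @export
hubs <- function(psn, min_degree = 4, report_degree = 6, others = list()) {
  stopifnot(inherits(psn, "psn_graph"))
  deg <- igraph::degree(psn$graph)
  hub_set <- names(deg)[deg > min_degree]
  reach <- names(deg)[deg >= report_degree]
  for (o in others) {
    d2 <- igraph::degree(o$graph)
    reach <- union(reach, names(d2)[d2 >= report_degree])
  }
  list(degrees = deg, hubs = hub_set, reporting_set = sort(reach))
}

#' Degree change of nodes between a variant and a reference network
#'
#' `delta = degree(variant) - degree(reference)` per node; a node absent
#' from one graph contributes degree 0 there (with a notice). The total is
#' the sum over `node_set`.
#'
#' @param variant_psn,wt_psn `"psn_graph"` objects with shared node naming.
#' @param node_set Nodes to compare (default: union of both node sets).
#' @return List with `per_node` (named vector) and `total`.
#' @export
delta_degree <- function(variant_psn, wt_psn, node_set = NULL) {
  stopifnot(inherits(variant_psn, "psn_graph"), inherits(wt_psn, "psn_graph"))
  dv <- igraph::degree(variant_psn$graph)
  dw <- igraph::degree(wt_psn$graph)
  if (is.null(node_set)) node_set <- sort(union(names(dv), names(dw)))
  miss <- setdiff(node_set, intersect(names(dv), names(dw)))
  if (length(miss))
    message("nodes missing from one graph treated as degree 0: ",
            paste(miss, collapse = ", "))
  get0deg <- function(d, n) ifelse(is.na(d[n]), 0, d[n])
  per <- setNames(get0deg(dv, node_set) - get0deg(dw, node_set), node_set)
  list(per_node = per, total = sum(per))
}

#' Shortest communication paths between two residues
#'
#' Unweighted shortest-path length `l` between nodes `X` and `Y`, the number
#' `n_XY` of distinct shortest paths (distinct node sequences), and the
#' paths themselves. A disconnected pair yields `l = Inf`, `n_XY = 0`.
#'
#' @param psn A `"psn_graph"`.
#' @param X,Y Node names.
#' @return List with `l`, `n`, `paths` (list of character vectors).
#' @export
shortest_paths_psn <- function(psn, X, Y) {
  stopifnot(inherits(psn, "psn_graph"))
  g <- psn$graph
  vn <- igraph::V(g)$name
  if (!(X %in% vn) || !(Y %in% vn))
    stop("unknown node(s): ", paste(setdiff(c(X, Y), vn), collapse = ", "))
  if (X == Y) stop("X and Y must be distinct residues")
  l <- suppressWarnings(igraph::distances(g, v = X, to = Y)[1, 1])
  if (!is.finite(l)) return(list(l = Inf, n = 0L, paths = list()))
  sp <- igraph::all_shortest_paths(g, from = X, to = Y)$vpaths
  list(l = as.integer(l), n = length(sp),
       paths = lapply(sp, function(p) igraph::V(g)$name[as.integer(p)]))
}

#' Communication Robustness between two residues
#'
#' Scalar index of how robustly two residues communicate through the
#' persistent-interaction network, combining the number `n_XY` of shortest
#' paths, their length `l`, and the persistence threshold `pT` of the
#' network. Two renderings are provided:
#' \describe{
#'   \item{`"n_pt_over_l"` (default)}{`CR = n_XY * pT / l`}
#'   \item{`"n_pt_pow_l"`}{`CR = n_XY * pT^l`}
#' }
#' A disconnected pair has `CR = 0`.
#'
#' @param psn A `"psn_graph"` (supplies `pT`).
#' @param X,Y Distinct node names.
#' @param form Which rendering of the index to use.
#' @return Non-negative scalar.
#' @export
cr_index <- function(psn, X, Y, form = c("n_pt_over_l", "n_pt_pow_l")) {
  form <- match.arg(form)
  sp <- shortest_paths_psn(psn, X, Y)
  if (!is.finite(sp$l) || sp$n == 0) return(0)
  switch(form,
         n_pt_over_l = sp$n * psn$pt / sp$l,
         n_pt_pow_l = sp$n * psn$pt^sp$l)
}

#' EF-hand communication robustness matrix
#'
#' Computes the Communication Robustness index between the representative
#' bidentate calcium-coordinating glutamates of the four EF-hands of
#' calmodulin (default map: EF1 = E31, EF2 = E67, EF3 = E104, EF4 = E140,
#' mature-protein numbering) over all six pairs, and flags a pair as robust
#' when `CR >= threshold` (default 0.1).
#'
#' @param psn A `"psn_graph"` containing the representative residues.
#' @param ef_map Named character vector mapping EF-hand labels to node
#'   names.
#' @param threshold Robustness cutoff on CR.
#' @param form Passed to [cr_index()].
#' @return Object of class `"cr_matrix"`: list with `cr` (symmetric 4x4
#'   matrix, zero diagonal), `robust` (logical matrix), `pt`, `threshold`,
#'   `pairs` (long-format data.frame).
#' @export
ef_hand_cr <- function(psn,
                       ef_map = c(EF1 = "E31", EF2 = "E67",
                                  EF3 = "E104", EF4 = "E140"),
                       threshold = 0.1,
                       form = c("n_pt_over_l", "n_pt_pow_l")) {
  form <- match.arg(form)
  stopifnot(inherits(psn, "psn_graph"))
  vn <- igraph::V(psn$graph)$name
  miss <- setdiff(ef_map, vn)
  if (length(miss))
    stop("EF-hand representative residue(s) missing from the network: ",
         paste(miss, collapse = ", "))
  k <- length(ef_map)
  cr <- matrix(0, k, k, dimnames = list(names(ef_map), names(ef_map)))
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v <- cr_index(psn, ef_map[[i]], ef_map[[j]], form = form)
    cr[i, j] <- cr[j, i] <- v
    rows[[length(rows) + 1]] <- data.frame(
      ef_a = names(ef_map)[i], ef_b = names(ef_map)[j],
      residue_a = unname(ef_map[i]), residue_b = unname(ef_map[j]),
      cr = v, robust = v >= threshold, stringsAsFactors = FALSE)
  }
  structure(list(cr = cr, robust = cr >= threshold & row(cr) != col(cr),
                 pt = psn$pt, threshold = threshold,
                 pairs = do.call(rbind, rows)),
            class = "cr_matrix")
}

#' @export
print.cr_matrix <- function(x, ...) {
  cat(sprintf("<cr_matrix> pT = %.3g, robustness threshold %.3g\n",
              x$pt, x$threshold))
  print(round(x$cr, 4))
  invisible(x)
}
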