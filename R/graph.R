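# Bond perception and molecular graphs; isomorphism enumeration drives the
# symmetry-corrected RMSD.

#' Perceive bonds from geometry
#'
#' Atoms i and j are bonded iff their distance does not exceed
#' `tolerance * (r_cov(i) + r_cov(j))`, using single-bond covalent radii.
#' The result is an undirected graph whose nodes are atoms labeled by
#' element symbol; bond orders are not assigned.
#'
#' @param s A `conformer`.
#' @param tolerance Scale factor applied to the radii sum (default 1.25, a
#'   common perception heuristic).
#' @return An object of class `"molecular_graph"` with fields `elements`
#'   and `edges` (two-column matrix of 1-based atom index pairs, i < j).
#' @export
perceive_bonds <- function(s, tolerance = 1.25) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    abort_contract("tolerance must be a single value > 0")
  r <- covalent_radius(s$elements)
  n <- length(s$elements)
  edges <- matrix(integer(0), ncol = 2L)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(s$coords))
    cut <- tolerance * outer(r, r, `+`)
    hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit) > 0L)
      edges <- cbind(as.integer(hit[, 1L]), as.integer(hit[, 2L]))
  }
  molecular_graph(s$elements, edges)
}

#' Construct a molecular graph
#'
#' @param elements Character vector of element symbols (one per node).
#' @param edges Two-column integer matrix of bonded pairs (1-based).
#' @return A `"molecular_graph"`.
#' @export
molecular_graph <- function(elements, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L | edges > length(elements)))
      abort_contract("edge refers to a node outside 1..n")
    if (any(edges[, 1L] == edges[, 2L]))
      abort_contract("self-edges are not allowed")
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  structure(list(elements = as.character(elements), edges = edges),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %d atoms, %d bonds\n",
              length(x$elements), nrow(x$edges)))
  invisible(x)
}

# neighbor list (list of integer vectors, 1-based)
mg_neighbors <- function(g) {
  nb <- vector("list", length(g$elements))
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges[k, 1L]; j <- g$edges[k, 2L]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(v) sort(unique(v)))
}

mg_igraph <- function(g) {
  gr <- igraph::make_empty_graph(n = length(g$elements), directed = FALSE)
  if (nrow(g$edges) > 0L) gr <- igraph::add_edges(gr, t(g$edges))
  gr
}

# Heavy-atom (non-H) induced subgraph plus the original atom indices of its
# nodes, as a molecular_graph + index map.
heavy_subgraph <- function(g) {
  keep <- which(g$elements != "H")
  remap <- match(seq_along(g$elements), keep)
  e <- g$edges
  e <- e[!is.na(remap[e[, 1L]]) & !is.na(remap[e[, 2L]]), , drop = FALSE]
  e2 <- cbind(remap[e[, 1L]], remap[e[, 2L]])
  list(graph = molecular_graph(g$elements[keep], e2), idx = keep)
}

#' Enumerate heavy-atom graph isomorphisms
#'
#' Finds element-preserving isomorphisms between the heavy-atom subgraphs
#' of two molecular graphs using VF2. Each result is an atom map: an
#' integer vector whose i-th entry is the atom index in B matched to the
#' i-th heavy atom of A (attribute `"heavy_a"` carries the A-side atom
#' indices). An empty list means the graphs are not isomorphic.
#'
#' Exact symmetry handling is exponential in the worst case, so enumeration
#' stops at `cap` maps; when truncated, the identity-like map is kept and
#' the result carries attribute `"truncated" = TRUE` plus a warning.
#'
#' @param gA,gB `molecular_graph` objects.
#' @param cap Maximum number of maps to return (default 10000).
#' @return List of atom maps (possibly empty).
#' @export
enumerate_isomorphisms <- function(gA, gB, cap = 10000L) {
  if (!is.numeric(cap) || cap < 1L) abort_contract("cap must be >= 1")
  ha <- heavy_subgraph(gA)
  hb <- heavy_subgraph(gB)
  if (length(ha$idx) == 0L || length(hb$idx) == 0L)
    abort_contract("structures must contain at least one heavy atom")
  if (!identical(sort(ha$graph$elements), sort(hb$graph$elements)))
    return(list())
  lv <- sort(unique(c(ha$graph$elements, hb$graph$elements)))
  colA <- as.integer(factor(ha$graph$elements, levels = lv))
  colB <- as.integer(factor(hb$graph$elements, levels = lv))
  maps <- igraph::graph.get.isomorphisms.vf2(
    mg_igraph(ha$graph), mg_igraph(hb$graph),
    vertex.color1 = colA, vertex.color2 = colB)
  out <- lapply(maps, function(m) {
    v <- hb$idx[as.integer(m)]
    attr(v, "heavy_a") <- ha$idx
    v
  })
  truncated <- FALSE
  if (length(out) > cap) {
    is_ident <- vapply(out, function(m)
      identical(as.integer(m), as.integer(ha$idx)), logical(1))
    keep <- out[seq_len(cap)]
    # keep an identity-like map in the truncated set when one exists
    if (any(is_ident) && !any(is_ident[seq_len(cap)]))
      keep[[cap]] <- out[[which(is_ident)[1L]]]
    out <- keep
    truncated <- TRUE
    warning(sprintf("isomorphism enumeration truncated at cap = %d", cap))
  }
  attr(out, "truncated") <- truncated
  out
}

#' Identity atom map between two composition-identical structures
#'
#' @param s A `conformer`.
#' @return The heavy-atom identity map, usable with [kabsch_rmsd()].
#' @export
identity_atom_map <- function(s) {
  h <- heavy_atoms(s)
  v <- h
  attr(v, "heavy_a") <- h
  v
}
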