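# Rotatable-bond torsion detection and circular torsion-angle distances.

#' Dihedral angle of four points
#'
#' Standard signed dihedral about the j-k axis, in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (i, j, k, l).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Detect canonical torsions of the rotatable bonds
#'
#' A bond is rotatable when it is a non-ring (bridge) bond of the
#' heavy-atom graph whose two atoms each have at least two heavy-atom
#' neighbors (terminal bonds excluded). One canonical torsion i-j-k-l is
#' emitted per rotatable bond, with j < k and the reference atoms i and l
#' chosen as the lowest-index heavy neighbors of j and k respectively.
#' Hydrogens never appear in torsion definitions.
#'
#' @param s A `conformer`.
#' @param g Its `molecular_graph`; perceived if omitted.
#' @return A list of class `"torsion_set"` with `torsions` (four-column
#'   integer matrix of atom indices) and `angles` (degrees, one per
#'   torsion, for `s`).
#' @export
detect_torsions <- function(s, g = perceive_bonds(s)) {
  h <- heavy_subgraph(g)
  hg <- h$graph
  quads <- matrix(integer(0), ncol = 4L)
  if (nrow(hg$edges) > 0L) {
    nb <- mg_neighbors(hg)
    deg <- lengths(nb)
    br <- igraph::bridges(mg_igraph(hg))
    bridge_edges <- if (length(br) > 0L)
      igraph::as_edgelist(mg_igraph(hg))[as.integer(br), , drop = FALSE]
    else matrix(integer(0), ncol = 2L)
    if (nrow(bridge_edges) > 0L) {
      bridge_edges <- t(apply(matrix(as.integer(bridge_edges), ncol = 2L),
                              1L, sort))
      for (r in seq_len(nrow(bridge_edges))) {
        j <- bridge_edges[r, 1L]; k <- bridge_edges[r, 2L]
        if (deg[j] < 2L || deg[k] < 2L) next
        i <- min(setdiff(nb[[j]], k))
        l <- min(setdiff(nb[[k]], j))
        quads <- rbind(quads, h$idx[c(i, j, k, l)])
      }
    }
  }
  if (nrow(quads) > 0L)
    quads <- quads[order(quads[, 2L], quads[, 3L]), , drop = FALSE]
  structure(list(torsions = quads, angles = torsion_angles(s, quads)),
            class = "torsion_set")
}

#' @export
print.torsion_set <- function(x, ...) {
  cat(sprintf("<torsion_set> %d torsion(s)\n", nrow(x$torsions)))
  for (r in seq_len(nrow(x$torsions)))
    cat(sprintf("  %s: %8.2f deg\n",
                paste(x$torsions[r, ], collapse = "-"), x$angles[r]))
  invisible(x)
}

#' Evaluate torsion angles on a structure
#'
#' @param s A `conformer`.
#' @param torsions Four-column matrix of atom index quadruples.
#' @return Numeric vector of angles in degrees, in (-180, 180].
#' @export
torsion_angles <- function(s, torsions) {
  torsions <- matrix(as.integer(torsions), ncol = 4L)
  if (nrow(torsions) == 0L) return(numeric(0))
  apply(torsions, 1L, function(q)
    dihedral_angle(s$coords[q[1L], ], s$coords[q[2L], ],
                   s$coords[q[3L], ], s$coords[q[4L], ]))
}

#' Circular distance between torsion-angle vectors
#'
#' Mean over torsions of the wrapped absolute difference
#' `min(|a-b|, 360-|a-b|)`; lies in `[0, 180]` degrees.
#'
#' @param a,b Angle vectors in degrees, equal length.
#' @return Dissimilarity in degrees.
#' @export
torsion_distance <- function(a, b) {
  if (length(a) != length(b))
    abort_contract("torsion angle vectors must have equal length")
  if (length(a) == 0L) return(0)
  d <- abs(a - b) %% 360
  mean(pmin(d, 360 - d))
}
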