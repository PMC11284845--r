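# Compound dissimilarity: fuse symmetry-corrected RMSD, torsion-angle and
# energy differences into one pairwise matrix.

# min-max normalize a nonnegative symmetric matrix to [0, 1]; a component
# that is constant (to within float noise, e.g. identical copies whose
# RMSDs differ by ~1e-16) carries no information and maps to all-zero
# rather than having that noise amplified to full scale.
minmax_normalize <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 1e-10 * max(1, hi)) return(matrix(0, nrow(m), ncol(m)))
  (m - lo) / (hi - lo)
}

#' Compound dissimilarity matrix of a conformer ensemble
#'
#' Computes the requested per-metric pairwise dissimilarities:
#' \describe{
#'   \item{rmsd}{symmetry-corrected heavy-atom RMSD (Angstrom), minimizing
#'     over bond-graph isomorphisms so equivalent atom indexings compare as
#'     identical;}
#'   \item{dihedral}{mean circular distance (degrees) between the
#'     rotatable-bond torsion angles, with torsions detected once on the
#'     first structure and evaluated on every frame by atom index;}
#'   \item{energy}{absolute free-energy difference `|E_i - E_j|`
#'     (kcal/mol).}
#' }
#' Each component is min-max normalized to `[0, 1]` (raw Angstrom, degrees
#' and kcal/mol are incommensurate; a constant component maps to all-zero)
#' and the fused matrix is the weighted mean of the normalized components.
#'
#' @param e A `conformer_ensemble`.
#' @param metrics Subset of `c("rmsd", "dihedral", "energy")`.
#' @param weights Nonnegative per-metric weights, recycled/named as
#'   `metrics`; default equal weights.
#' @param tolerance Bond-perception tolerance.
#' @param cap Isomorphism enumeration cap.
#' @return Object of class `"dissimilarity_matrix"`: `values` (n x n fused
#'   matrix), `components` (named list of raw n x n matrices), `weights`,
#'   `labels`, and `truncated` (logical: any isomorphism cap hit).
#' @export
compound_matrix <- function(e, metrics = c("rmsd", "dihedral", "energy"),
                            weights = NULL, tolerance = 1.25, cap = 10000L) {
  metrics <- match.arg(metrics, c("rmsd", "dihedral", "energy"),
                       several.ok = TRUE)
  if (is.null(weights)) weights <- rep(1, length(metrics))
  if (length(weights) != length(metrics))
    abort_config("need one weight per requested metric")
  if (any(weights < 0) || sum(weights) <= 0)
    abort_config("weights must be nonnegative and not all zero")
  names(weights) <- metrics
  n <- length(e)
  labels <- ensemble_labels(e)
  energies <- ensemble_energies(e)
  if ("energy" %in% metrics && anyNA(energies))
    abort_config(
      "energy metric requested but some structures carry no energy; drop the metric or supply energies")

  components <- list()
  truncated <- FALSE

  if ("rmsd" %in% metrics || "dihedral" %in% metrics)
    graphs <- lapply(e$structures, perceive_bonds, tolerance = tolerance)

  if ("rmsd" %in% metrics) {
    m <- matrix(0, n, n)
    # isomorphism sets depend only on the two bond graphs; cache by edge
    # signature since jittered conformers usually share one graph
    iso_cache <- new.env(parent = emptyenv())
    sig <- vapply(graphs, function(g)
      paste(g$edges, collapse = ","), character(1))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      key <- paste(sig[i], sig[j], sep = "|")
      maps <- if (!is.null(iso_cache[[key]])) iso_cache[[key]]
              else iso_cache[[key]] <-
                enumerate_isomorphisms(graphs[[i]], graphs[[j]], cap = cap)
      if (length(maps) == 0L)
        abort_mismatch(sprintf(
          "structures %d and %d have non-isomorphic bond graphs", i, j))
      vals <- vapply(maps, function(mp)
        kabsch_rmsd(e$structures[[i]], e$structures[[j]], mp), numeric(1))
      m[i, j] <- m[j, i] <- min(vals)
      truncated <- truncated || isTRUE(attr(maps, "truncated"))
    }
    components$rmsd <- m
  }

  if ("dihedral" %in% metrics) {
    ts <- detect_torsions(e$structures[[1L]], graphs[[1L]])
    ang <- lapply(e$structures, torsion_angles, torsions = ts$torsions)
    m <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      m[i, j] <- m[j, i] <- torsion_distance(ang[[i]], ang[[j]])
    }
    components$dihedral <- m
  }

  if ("energy" %in% metrics)
    components$energy <- abs(outer(energies, energies, `-`))

  norm <- lapply(components, minmax_normalize)
  values <- matrix(0, n, n)
  for (mname in metrics)
    values <- values + weights[[mname]] * norm[[mname]]
  values <- values / sum(weights)
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, components = components,
                 weights = weights, labels = labels, truncated = truncated),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf(
    "<dissimilarity_matrix> %d structures; metrics: %s%s\n  fused range [%.4f, %.4f]\n",
    nrow(x$values), paste(names(x$components), collapse = ", "),
    if (x$truncated) " (isomorphism cap hit)" else "",
    min(x$values), max(x$values)))
  invisible(x)
}

#' Export a dissimilarity matrix as CSV
#'
#' Writes the fused matrix as a square CSV with a header row of structure
#' labels; with `components = TRUE`, each raw per-metric matrix is written
#' alongside with the metric name as a suffix (e.g. `dist_rmsd.csv`).
#'
#' @param D A `dissimilarity_matrix`.
#' @param path Output CSV path for the fused matrix.
#' @param components Also write per-component matrices.
#' @return Character vector of the paths written, invisibly.
#' @export
write_matrix_csv <- function(D, path, components = FALSE) {
  write_one <- function(m, p) {
    df <- as.data.frame(m)
    names(df) <- D$labels
    utils::write.csv(cbind(label = D$labels, df), p, row.names = FALSE,
                     quote = FALSE)
    p
  }
  paths <- write_one(D$values, path)
  if (components) {
    stem <- sub("\\.csv$", "", path)
    for (mname in names(D$components))
      paths <- c(paths,
                 write_one(D$components[[mname]],
                           sprintf("%s_%s.csv", stem, mname)))
  }
  invisible(paths)
}
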