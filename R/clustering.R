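# Embed the compound distance matrix, choose k by silhouette, run k-means,
# and pick the lowest-energy representative of each cluster.

#' Metric multidimensional scaling of a dissimilarity matrix
#'
#' Classical (Torgerson) MDS of the fused dissimilarities. The embedding is
#' deterministic; `seed` is accepted for interface uniformity with the
#' stochastic stages. Kruskal-type stress
#' `sqrt(sum((D - Dhat)^2) / sum(D^2))` is attached as attribute
#' `"stress"`.
#'
#' @param D A `dissimilarity_matrix` or a symmetric numeric matrix.
#' @param dims Embedding dimensionality (>= 1).
#' @param seed Unused by the deterministic embedding; kept for a uniform
#'   signature.
#' @return n x dims coordinate matrix with attribute `"stress"`.
#' @export
embed_mds <- function(D, dims = 2L, seed = NULL) {
  m <- if (inherits(D, "dissimilarity_matrix")) D$values else as.matrix(D)
  n <- nrow(m)
  if (n < 2L) abort_contract("need at least 2 structures to embed")
  if (dims < 1L) abort_contract("dims must be >= 1")
  dims <- as.integer(min(dims, n - 1L))
  if (max(m) <= 0) {
    out <- matrix(0, n, dims)
    attr(out, "stress") <- 0
    return(out)
  }
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = dims))
  out <- matrix(0, n, dims)
  if (length(fit) > 0L) out[, seq_len(ncol(fit))] <- fit
  dhat <- as.matrix(stats::dist(out))
  attr(out, "stress") <- sqrt(sum((m - dhat)^2) / sum(m^2))
  out
}

# mean silhouette width of a labeling over Euclidean embedding distances
mean_silhouette <- function(labels, d) {
  sil <- cluster::silhouette(labels, d)
  mean(sil[, "sil_width"])
}

#' Choose the number of clusters by the silhouette method
#'
#' Runs k-means for every candidate k in `2..min(k_max, n - 1)` (bounded by
#' the number of distinct points) and scores each partition by mean
#' silhouette width. Returns the k maximizing the silhouette, with ties
#' broken toward smaller k (parsimony). A single cluster is returned when
#' `n < 3`, when no candidate k is feasible, or when the best silhouette
#' falls below `single_cluster_threshold`: silhouette is undefined at
#' k = 1, so an ensemble whose best split is still weak is treated as one
#' interconvertible family.
#'
#' @param coords Embedding coordinates (n x d).
#' @param k_max Largest candidate k (default 10).
#' @param seed Integer seed; all k-means restarts derive from it.
#' @param single_cluster_threshold Silhouette below which k = 1 is declared
#'   (default 0.40).
#' @param nstart k-means restarts per candidate (default 10).
#' @return List with `k` and `silhouette_by_k` (named numeric over the
#'   candidates examined).
#' @export
choose_k <- function(coords, k_max = 10L, seed = 2024L,
                     single_cluster_threshold = 0.40, nstart = 10L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k_max < 1L) abort_contract("k_max must be >= 1")
  if (n < 2L) abort_contract("need at least 2 points")
  n_distinct <- nrow(unique(coords))
  ks <- seq.int(2L, length.out = max(0L, min(k_max, n - 1L, n_distinct) - 1L))
  sil <- stats::setNames(numeric(0), character(0))
  if (n >= 3L && length(ks) > 0L) {
    d <- stats::dist(coords)
    for (k in ks) {
      set.seed(seed + k)
      km <- stats::kmeans(coords, centers = k, nstart = nstart)
      sil[as.character(k)] <- mean_silhouette(km$cluster, d)
    }
  }
  if (length(sil) == 0L || max(sil) < single_cluster_threshold)
    return(list(k = 1L, silhouette_by_k = sil))
  best <- ks[which(sil >= max(sil) - 1e-12)[1L]]  # ties -> smaller k
  list(k = as.integer(best), silhouette_by_k = sil)
}

#' Cluster a conformer ensemble into interconvertible families
#'
#' Full workflow: compound dissimilarity matrix, metric MDS embedding,
#' silhouette-based choice of k, k-means at the chosen k, and one
#' representative per cluster. When all structures carry energies the
#' representative is the cluster's minimum-energy member (ties broken by
#' lowest index); otherwise it is the member nearest its cluster centroid
#' in the embedding.
#'
#' @param e A `conformer_ensemble`.
#' @param metrics,weights,tolerance,cap Passed to [compound_matrix()].
#' @param k_max,single_cluster_threshold,nstart Passed to [choose_k()].
#' @param dims Embedding dimensionality; default `min(n - 1, 5)`.
#' @param seed Top-level seed; every stochastic stage derives from it.
#' @return Object of class `"clustering_result"`: `labels` (per-structure
#'   cluster index, 1..k), `k`, `silhouette_by_k`, `representatives`
#'   (structure index per cluster), `seed`, `embedding`, `stress`,
#'   `dissimilarity`.
#' @export
cluster_ensemble <- function(e, metrics = c("rmsd", "dihedral", "energy"),
                             weights = NULL, k_max = 10L, dims = NULL,
                             seed = 2024L, single_cluster_threshold = 0.40,
                             tolerance = 1.25, cap = 10000L, nstart = 10L) {
  if (!inherits(e, "conformer_ensemble"))
    abort_contract("e must be a conformer_ensemble")
  n <- length(e)
  energies <- ensemble_energies(e)
  if (anyNA(energies) && "energy" %in% metrics) {
    warning("energies missing; dropping the energy metric")
    metrics <- setdiff(metrics, "energy")
    if (!is.null(weights)) weights <- NULL
  }
  if (n == 1L) {
    res <- list(labels = 1L, k = 1L,
                silhouette_by_k = stats::setNames(numeric(0), character(0)),
                representatives = 1L, seed = as.integer(seed),
                embedding = matrix(0, 1L, 1L), stress = 0,
                dissimilarity = NULL)
    class(res) <- "clustering_result"
    return(res)
  }
  if (is.null(dims)) dims <- min(n - 1L, 5L)
  D <- compound_matrix(e, metrics = metrics, weights = weights,
                       tolerance = tolerance, cap = cap)
  coords <- embed_mds(D, dims = dims, seed = seed)
  sel <- choose_k(coords, k_max = k_max, seed = seed,
                  single_cluster_threshold = single_cluster_threshold,
                  nstart = nstart)
  k <- sel$k
  if (k == 1L) {
    labels <- rep(1L, n)
  } else {
    set.seed(seed + k)  # same stream as the choose_k evaluation of this k
    labels <- stats::kmeans(coords, centers = k, nstart = nstart)$cluster
  }
  reps <- pick_representatives(labels, energies, coords)
  res <- list(labels = as.integer(labels), k = as.integer(k),
              silhouette_by_k = sel$silhouette_by_k,
              representatives = reps, seed = as.integer(seed),
              embedding = coords, stress = attr(coords, "stress"),
              dissimilarity = D)
  class(res) <- "clustering_result"
  res
}

#' Pick one representative structure per cluster
#'
#' Minimum-energy member per cluster when energies are complete (ties
#' broken by lowest structure index); nearest-to-centroid in the embedding
#' otherwise.
#'
#' @param labels Integer cluster labels (1..k).
#' @param energies Per-structure energies (may contain `NA`).
#' @param coords Embedding coordinates (used in the no-energy fallback).
#' @return Integer vector: structure index of the representative of
#'   cluster 1..k.
#' @export
pick_representatives <- function(labels, energies, coords) {
  ks <- sort(unique(labels))
  vapply(ks, function(k) {
    members <- which(labels == k)
    if (!anyNA(energies)) {
      members[which.min(energies[members])]
    } else {
      ctr <- colMeans(coords[members, , drop = FALSE])
      dif <- sweep(coords[members, , drop = FALSE], 2L, ctr)
      members[which.min(rowSums(dif^2))]
    }
  }, integer(1))
}

#' @export
print.clustering_result <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf("<clustering_result> k = %d (sizes: %s), seed %d\n",
              x$k, paste(as.integer(sizes), collapse = "/"), x$seed))
  if (length(x$silhouette_by_k) > 0L) {
    cat("  silhouette by k:",
        paste(sprintf("k=%s %.3f", names(x$silhouette_by_k),
                      x$silhouette_by_k), collapse = ", "), "\n")
  }
  cat("  representatives:", paste(x$representatives, collapse = ", "), "\n")
  invisible(x)
}

#' Write cluster labels as CSV
#'
#' Columns: structure label, cluster index, is_representative flag, energy
#' (kcal/mol, empty when unknown).
#'
#' @param result A `clustering_result`.
#' @param e The clustered `conformer_ensemble`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(result, e, path) {
  df <- data.frame(label = ensemble_labels(e),
                   cluster = result$labels,
                   is_representative =
                     seq_along(result$labels) %in% result$representatives,
                   energy_kcal_mol = ensemble_energies(e))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
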