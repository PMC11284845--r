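# Curtin-Hammett selectivity arithmetic: Boltzmann weights and ensemble
# free energies within interconvertible clusters, Eyring rate-constant
# summation across parallel clusters, product ratios, and the
# repeated-conformer diagnostic.

check_energies <- function(energies) {
  if (length(energies) == 0L)
    abort_contract("energy list must be non-empty")
  if (!all(is.finite(energies)))
    abort_contract("all energies must be finite")
  as.numeric(energies)
}

#' Boltzmann weights of an energy pool
#'
#' `w_j = exp(-G_j/RT) / sum_k exp(-G_k/RT)`, computed shift-stably by
#' subtracting the minimum energy first, so spreads of hundreds of kcal/mol
#' neither overflow nor underflow.
#'
#' @param energies Free energies in kcal/mol.
#' @param T Temperature in K.
#' @return Positive weights summing to 1.
#' @export
#' @examples
#' boltzmann_weights(c(0, 0.5924848))  # RT ln 2 apart -> 2/3, 1/3
boltzmann_weights <- function(energies, T = confsel_constants$T_default) {
  energies <- check_energies(energies)
  rt <- rt_kcal(T)
  x <- exp(-(energies - min(energies)) / rt)
  x / sum(x)
}

#' Boltzmann-weighted ensemble free energy
#'
#' The Boltzmann-weighted arithmetic mean `sum_j w_j G_j` of the conformer
#' free energies of one interconvertible pool. It always lies between the
#' pool minimum and maximum, and strictly above the minimum unless all
#' energies are equal -- which is why every extra high-energy conformer
#' added to a Boltzmann pool pushes the predicted barrier up.
#'
#' @inheritParams boltzmann_weights
#' @return Ensemble free energy in kcal/mol.
#' @export
ensemble_free_energy <- function(energies, T = confsel_constants$T_default) {
  energies <- check_energies(energies)
  sum(boltzmann_weights(energies, T) * energies)
}

#' Effective barrier of parallel pathways
#'
#' `-RT ln sum_j exp(-G_j/RT)`: the single activation energy reproducing
#' the summed Eyring rate constants of parallel, non-interconvertible
#' pathways. Always at or below the pool minimum (each extra pathway adds
#' rate), with equality only for a single entry; a duplicate of the lowest
#' conformer lowers it by up to `RT ln 2`.
#'
#' @inheritParams boltzmann_weights
#' @return Effective activation energy in kcal/mol.
#' @export
effective_barrier <- function(energies, T = confsel_constants$T_default) {
  energies <- check_energies(energies)
  rt <- rt_kcal(T)
  m <- min(energies)
  m - rt * log(sum(exp(-(energies - m) / rt)))
}

#' Eyring rate constant
#'
#' `k = (k_B T / h) exp(-dg / RT)` with the transmission coefficient set
#' to 1.
#'
#' @param dg Activation free energy in kcal/mol.
#' @param T Temperature in K.
#' @return Rate constant in 1/s.
#' @export
eyring_rate <- function(dg, T = confsel_constants$T_default) {
  confsel_constants$kB_over_h * T * exp(-dg / rt_kcal(T))
}

# integer percentage split of a ratio a:b, larger side absorbing the
# rounding remainder so the pair always sums to 100
split_percent <- function(ratio) {
  pa <- 100 * ratio / (1 + ratio)
  pb <- 100 / (1 + ratio)
  ra <- round(pa); rb <- round(pb)
  off <- 100 - (ra + rb)
  if (off != 0) {
    if (ra >= rb) ra <- ra + off else rb <- rb + off
  }
  c(a = ra, b = rb)
}

#' Product ratio from a barrier difference
#'
#' `ratio = exp(-ddg/RT)` where `ddg = dG_a - dG_b` is the difference of
#' the two activation free energies; the percentage split is rounded to
#' integers summing to 100, the larger side absorbing the remainder.
#'
#' @param ddg Barrier difference in kcal/mol (a minus b).
#' @param T Temperature in K.
#' @return List with `ratio` (`[a]/[b]`) and `percent` (named integer pair
#'   `a`, `b`).
#' @export
#' @examples
#' ratio_from_ddg(-2.21)  # 98:2 toward a
ratio_from_ddg <- function(ddg, T = confsel_constants$T_default) {
  ratio <- exp(-ddg / rt_kcal(T))
  list(ratio = ratio, percent = split_percent(ratio))
}

#' Bundle transition-state energies of one product pathway
#'
#' A pathway is a list of clusters; each cluster is the free-energy pool of
#' one interconvertible TS family, all relative to the one shared reference
#' intermediate.
#'
#' @param product_label Identifier, e.g. `"2a"`.
#' @param clusters List of numeric vectors (kcal/mol), every cluster
#'   non-empty.
#' @return Object of class `"pathway_energies"`.
#' @export
pathway_energies <- function(product_label, clusters) {
  if (!is.list(clusters)) clusters <- list(clusters)
  if (length(clusters) == 0L)
    abort_contract("a pathway needs at least one cluster")
  clusters <- lapply(clusters, check_energies)
  structure(list(product_label = as.character(product_label),
                 clusters = clusters),
            class = "pathway_energies")
}

# per-product effective barrier under one of the three treatments
pathway_barrier <- function(p, T, method) {
  pool <- unlist(p$clusters)
  switch(method,
    boltzmann        = ensemble_free_energy(pool, T),
    rate_sum         = effective_barrier(pool, T),
    cluster_resolved = effective_barrier(
      vapply(p$clusters, ensemble_free_energy, numeric(1), T = T), T),
    abort_config(sprintf("unknown method '%s'", method)))
}

#' Two-pathway selectivity under Curtin-Hammett conditions
#'
#' Computes the product ratio `[a]/[b]` from the TS conformer energies of
#' two competing pathways, under one of three treatments:
#' \describe{
#'   \item{boltzmann}{all conformers of a pathway form one freely
#'     interconvertible pool; its Boltzmann-weighted ensemble energy enters
#'     the exponential ratio. Correct only if every conformer truly
#'     interconverts; repeated high-energy conformers bias it.}
#'   \item{rate_sum}{every conformer is its own parallel pathway; Eyring
#'     rate constants are summed, i.e. the effective barrier is the
#'     log-sum-exp of the pool. Repeated low-energy conformers bias it.}
#'   \item{cluster_resolved}{the hybrid: Boltzmann ensemble energy within
#'     each interconvertible cluster, then rate summation across clusters.
#'     Collapses to `rate_sum` when every cluster is a singleton and to
#'     `boltzmann` when each pathway is one cluster.}
#' }
#' The reference-state mole fraction is neglected (no reactant-conformer
#' weighting), as is standard under Curtin-Hammett conditions.
#'
#' @param pathway_a,pathway_b `pathway_energies` objects (or plain lists of
#'   cluster energy vectors).
#' @param T Temperature in K.
#' @param method `"cluster_resolved"`, `"boltzmann"` or `"rate_sum"`.
#' @return Object of class `"selectivity_report"` with per-product
#'   effective barriers, per-cluster ensemble energies, `ddg_eff`, the rate
#'   ratio and the integer percentage split.
#' @export
#' @examples
#' a <- pathway_energies("2a", list(15.3))
#' b <- pathway_energies("2b", list(13.4, 17.5))
#' selectivity(a, b, method = "cluster_resolved")  # ~ 4:96
selectivity <- function(pathway_a, pathway_b,
                        T = confsel_constants$T_default,
                        method = c("cluster_resolved", "boltzmann",
                                   "rate_sum")) {
  if (!inherits(pathway_a, "pathway_energies"))
    pathway_a <- pathway_energies("a", pathway_a)
  if (!inherits(pathway_b, "pathway_energies"))
    pathway_b <- pathway_energies("b", pathway_b)
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("cluster_resolved", "boltzmann", "rate_sum"))
    abort_config(sprintf("unknown method '%s'", method))
  method <- match.arg(method)
  dg_a <- pathway_barrier(pathway_a, T, method)
  dg_b <- pathway_barrier(pathway_b, T, method)
  ddg <- dg_a - dg_b
  r <- ratio_from_ddg(ddg, T)
  res <- list(
    product_labels = c(pathway_a$product_label, pathway_b$product_label),
    method = method, T = T,
    dg_eff = stats::setNames(c(dg_a, dg_b),
                             c(pathway_a$product_label,
                               pathway_b$product_label)),
    cluster_energies = stats::setNames(
      list(vapply(pathway_a$clusters, ensemble_free_energy, numeric(1),
                  T = T),
           vapply(pathway_b$clusters, ensemble_free_energy, numeric(1),
                  T = T)),
      c(pathway_a$product_label, pathway_b$product_label)),
    ddg_eff = ddg, ratio = r$ratio, percent = r$percent)
  class(res) <- "selectivity_report"
  res
}

#' @export
print.selectivity_report <- function(x, ...) {
  la <- x$product_labels[1L]; lb <- x$product_labels[2L]
  cat(sprintf("<selectivity_report> method = %s, T = %.2f K\n", x$method,
              x$T))
  cat(sprintf("  dG_eff(%s) = %.4f kcal/mol  (clusters: %s)\n", la,
              x$dg_eff[[la]],
              paste(sprintf("%.4f", x$cluster_energies[[la]]),
                    collapse = ", ")))
  cat(sprintf("  dG_eff(%s) = %.4f kcal/mol  (clusters: %s)\n", lb,
              x$dg_eff[[lb]],
              paste(sprintf("%.4f", x$cluster_energies[[lb]]),
                    collapse = ", ")))
  cat(sprintf("  ddG_eff = %.4f kcal/mol; [%s]/[%s] = %.4g; split %d:%d\n",
              x$ddg_eff, la, lb, x$ratio, x$percent[["a"]],
              x$percent[["b"]]))
  invisible(x)
}

#' Barrier shift caused by duplicating the lowest-energy conformer
#'
#' Diagnostic for the repeated-conformer pitfall under rate summation:
#' returns `effective_barrier(E) - effective_barrier(c(E, min(E)))`, the
#' amount by which one accidental duplicate of the lowest TS lowers the
#' effective barrier. Bounded above by `RT ln 2`, the bound being attained
#' when the minimum dominates the pool.
#'
#' @inheritParams boltzmann_weights
#' @return Barrier shift in kcal/mol (> 0).
#' @export
duplicate_sensitivity <- function(energies,
                                  T = confsel_constants$T_default) {
  energies <- check_energies(energies)
  effective_barrier(energies, T) -
    effective_barrier(c(energies, min(energies)), T)
}

#' Read pathway energies from a CSV table
#'
#' Expected columns: `label`, `product`, `energy_kcal_mol`, and optionally
#' `cluster`. Exactly two distinct products are required. When the
#' `cluster` column is absent each conformer is treated as its own cluster
#' (so `cluster_resolved` coincides with `rate_sum`); cluster assignments
#' can instead be merged in from a clustering labels CSV via
#' `labels_path`, matched on `label`.
#'
#' @param path CSV path.
#' @param labels_path Optional labels CSV from [write_labels_csv()].
#' @return Named list of two `pathway_energies`, in product sort order.
#' @export
read_pathway_csv <- function(path, labels_path = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "product", "energy_kcal_mol")
  if (!all(need %in% names(df)))
    abort_parse(sprintf("pathway CSV must have columns %s",
                        paste(need, collapse = ", ")))
  if (!is.numeric(df$energy_kcal_mol) || anyNA(df$energy_kcal_mol))
    abort_parse("energy_kcal_mol must be numeric and complete")
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if (!all(c("label", "cluster") %in% names(lab)))
      abort_parse("labels CSV must have columns label, cluster")
    df$cluster <- lab$cluster[match(df$label, lab$label)]
    if (anyNA(df$cluster))
      abort_parse("some pathway labels are missing from the labels CSV")
  }
  products <- sort(unique(df$product))
  if (length(products) != 2L)
    abort_config(sprintf("need exactly 2 products, found %d",
                         length(products)))
  if (is.null(df$cluster)) df$cluster <- seq_len(nrow(df))
  out <- lapply(products, function(p) {
    sub <- df[df$product == p, , drop = FALSE]
    pathway_energies(p, split(sub$energy_kcal_mol, sub$cluster))
  })
  stats::setNames(out, products)
}
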