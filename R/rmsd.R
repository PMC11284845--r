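# Heavy-atom RMSD after optimal rigid superposition (Kabsch), and its
# symmetry-corrected variant minimizing over graph isomorphisms.

#' Heavy-atom RMSD after optimal rigid superposition
#'
#' Superimposes the heavy atoms of `A` onto those of `B` under a given atom
#' map (translation to centroids plus the optimal proper rotation from the
#' Kabsch/SVD construction) and returns the residual RMSD in Angstrom.
#' The rotation determinant is constrained to +1: mirror images are not
#' superimposed, since enantiomeric transition states are chemically
#' distinct pathways.
#'
#' @param A,B `conformer` objects.
#' @param map Atom map as produced by [enumerate_isomorphisms()] or
#'   [identity_atom_map()]: entry i gives the B atom matched to the i-th
#'   heavy atom of A.
#' @return RMSD in Angstrom (>= 0).
#' @export
kabsch_rmsd <- function(A, B, map = identity_atom_map(A)) {
  ha <- attr(map, "heavy_a")
  if (is.null(ha)) ha <- heavy_atoms(A)
  if (length(ha) != length(map))
    abort_contract("atom map length does not match its heavy-atom index set")
  allA <- heavy_atoms(A)
  if (!setequal(ha, allA))
    abort_contract("atom map must cover all heavy atoms of A")
  if (anyDuplicated(map))
    abort_contract("atom map must be a bijection")
  if (!identical(A$elements[ha], B$elements[as.integer(map)]))
    abort_contract("atom map is not element-preserving")
  P <- A$coords[ha, , drop = FALSE]
  Q <- B$coords[as.integer(map), , drop = FALSE]
  P <- sweep(P, 2L, colMeans(P))
  Q <- sweep(Q, 2L, colMeans(Q))
  H <- crossprod(P, Q)                     # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)  # proper rotation, P -> Q
  sqrt(max(0, mean(rowSums((P %*% t(R) - Q)^2))))
}

#' Symmetry-corrected heavy-atom RMSD
#'
#' Minimum of [kabsch_rmsd()] over all element-preserving isomorphisms
#' between the two heavy-atom bond graphs, so that equivalent structures
#' that differ only by the indexing of symmetry-related atoms (rotated
#' tert-butyl or phenyl groups, swapped equivalent halogens, ...) compare
#' as identical.
#'
#' @param A,B `conformer` objects with the same heavy-atom composition.
#' @param gA,gB Their molecular graphs; perceived from geometry if omitted.
#' @param cap Isomorphism enumeration cap (see [enumerate_isomorphisms()]).
#' @return RMSD in Angstrom, with attributes `"map"` (the minimizing atom
#'   map) and `"truncated"`.
#' @export
symmetry_rmsd <- function(A, B, gA = perceive_bonds(A),
                          gB = perceive_bonds(B), cap = 10000L) {
  maps <- enumerate_isomorphisms(gA, gB, cap = cap)
  if (length(maps) == 0L)
    abort_mismatch(
      "structures have non-isomorphic heavy-atom graphs; not conformers of one molecule")
  vals <- vapply(maps, function(m) kabsch_rmsd(A, B, m), numeric(1))
  best <- which.min(vals)
  structure(vals[best], map = maps[[best]],
            truncated = isTRUE(attr(maps, "truncated")))
}
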