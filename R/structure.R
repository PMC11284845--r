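# Conformer and ensemble containers.

#' Create a single conformer structure
#'
#' A conformer holds element symbols, Cartesian coordinates in Angstrom, an
#' optional free energy in kcal/mol, and a free-text label.
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param energy Free energy in kcal/mol, or `NA` when unknown.
#' @param label Free-text identifier.
#' @return An object of class `"conformer"`.
#' @export
#' @examples
#' conformer(c("O", "H", "H"),
#'           rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
conformer <- function(elements, coords, energy = NA_real_, label = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) < 1L)
    abort_contract("a conformer must contain at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L)
    abort_contract(sprintf(
      "coordinate matrix must be %d x 3 to match the element list",
      length(elements)))
  if (!all(is.finite(coords)))
    abort_contract("coordinates must all be finite")
  bad <- !is_element(elements)
  if (any(bad))
    abort_lookup(sprintf("unknown element symbol(s): %s",
                         paste(unique(elements[bad]), collapse = ", ")))
  if (!(length(energy) == 1L && (is.na(energy) || is.finite(energy))))
    abort_contract("energy must be a single finite value or NA")
  dimnames(coords) <- NULL
  structure(list(elements = as.character(elements), coords = coords,
                 energy = as.numeric(energy), label = as.character(label)),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %s: %d atoms (%d heavy)%s\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              length(x$elements), length(heavy_atoms(x)),
              if (is.na(x$energy)) ""
              else sprintf(", G = %.4f kcal/mol", x$energy)))
  invisible(x)
}

#' Indices of heavy (non-hydrogen) atoms
#'
#' @param s A `conformer`.
#' @return Integer vector of 1-based atom indices.
#' @export
heavy_atoms <- function(s) which(s$elements != "H")

#' Create a conformer ensemble
#'
#' An ensemble is an ordered collection of conformers of one molecule: all
#' members must have identical element sequences (same atoms in the same
#' order), which is what makes index-based atom maps and torsion definitions
#' comparable across frames.
#'
#' @param structures List of `conformer` objects.
#' @param name Identifier for the ensemble.
#' @return An object of class `"conformer_ensemble"`.
#' @export
conformer_ensemble <- function(structures, name = "ensemble") {
  if (length(structures) < 1L)
    abort_contract("an ensemble must contain at least one structure")
  if (!all(vapply(structures, inherits, logical(1), "conformer")))
    abort_contract("all ensemble members must be conformer objects")
  ref <- structures[[1L]]$elements
  for (i in seq_along(structures)) {
    if (!identical(structures[[i]]$elements, ref))
      abort_composition(sprintf(
        "structure %d has a different element sequence than structure 1", i))
  }
  structure(list(structures = structures, name = as.character(name)),
            class = "conformer_ensemble")
}

#' @export
length.conformer_ensemble <- function(x) length(x$structures)

#' @export
`[[.conformer_ensemble` <- function(x, i) x$structures[[i]]

#' @export
`[.conformer_ensemble` <- function(x, i) {
  conformer_ensemble(x$structures[i], name = x$name)
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  e <- ensemble_energies(x)
  cat(sprintf("<conformer_ensemble> %s: %d structures of %d atoms, %s\n",
              x$name, length(x), length(x$structures[[1L]]$elements),
              if (anyNA(e)) "energies incomplete"
              else sprintf("G in [%.4f, %.4f] kcal/mol", min(e), max(e))))
  invisible(x)
}

#' Per-structure free energies of an ensemble
#'
#' @param e A `conformer_ensemble`.
#' @return Numeric vector in kcal/mol; `NA` where a frame has no energy.
#' @export
ensemble_energies <- function(e) {
  vapply(e$structures, function(s) s$energy, numeric(1))
}

#' Per-structure labels of an ensemble
#'
#' @param e A `conformer_ensemble`.
#' @return Character vector; empty labels are replaced by `frame_<i>`.
#' @export
ensemble_labels <- function(e) {
  lab <- vapply(e$structures, function(s) s$label, character(1))
  blank <- !nzchar(lab)
  lab[blank] <- sprintf("frame_%d", which(blank))
  lab
}
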