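# Planted-structure synthetic ensembles: torsional families with energy
# offsets, coordinate jitter, and symmetry-equivalent atom permutations.
# Geometry is a testing substrate; energies are assigned, not computed.

# unit vector at ang_deg from the center->partner direction, azimuth az_deg
# around it (deterministic local frame)
substituent_dir <- function(center, partner, az_deg, ang_deg = 109.471) {
  u <- partner - center
  u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  ang <- ang_deg * pi / 180
  az <- az_deg * pi / 180
  cos(ang) * u + sin(ang) * (cos(az) * v + sin(az) * w)
}

#' Deterministic rotor template molecule
#'
#' A small molecule with a rigid core, exactly one rotatable bond, and one
#' pair of symmetry-equivalent heavy atoms: a 2,2-difluoro-1,2-diol-like
#' fragment `HO-CF2-C(H)(CH3)-OH`. The O1-C2-C3-O4 torsion is the single
#' rotatable-bond torsion found by [detect_torsions()], and swapping the
#' two fluorines is the single non-trivial heavy-atom graph automorphism,
#' so permuted copies defeat naive index-based RMSD but not
#' [symmetry_rmsd()]. Coordinates are identical across calls.
#'
#' @return List with `structure` (a `conformer`) and `graph` (its
#'   `molecular_graph`).
#' @export
make_rotor_template <- function() {
  C3 <- c(0, 0, 0)
  C2 <- c(1.52, 0, 0)
  O4 <- C3 + 1.43 * substituent_dir(C3, C2, 0)
  C7 <- C3 + 1.52 * substituent_dir(C3, C2, 120)
  H9 <- C3 + 1.09 * substituent_dir(C3, C2, 240)
  O1 <- C2 + 1.43 * substituent_dir(C2, C3, 60)
  F5 <- C2 + 1.35 * substituent_dir(C2, C3, 180)
  F6 <- C2 + 1.35 * substituent_dir(C2, C3, 300)
  H8 <- O1 + 0.96 * substituent_dir(O1, C2, 0, ang_deg = 104.5)
  H10 <- O4 + 0.96 * substituent_dir(O4, C3, 0, ang_deg = 104.5)
  H11 <- C7 + 1.09 * substituent_dir(C7, C3, 0)
  H12 <- C7 + 1.09 * substituent_dir(C7, C3, 120)
  H13 <- C7 + 1.09 * substituent_dir(C7, C3, 240)
  s <- conformer(
    c("O", "C", "C", "O", "F", "F", "C", "H", "H", "H", "H", "H", "H"),
    rbind(O1, C2, C3, O4, F5, F6, C7, H8, H9, H10, H11, H12, H13),
    label = "rotor_template")
  list(structure = s, graph = perceive_bonds(s))
}

# Rodrigues rotation of points (rows) about unit axis u through the origin
rotate_about <- function(pts, u, theta) {
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) * ct + st * K + (1 - ct) * tcrossprod(u)
  pts %*% t(R)
}

#' Set a torsion angle by rigid rotation
#'
#' Rotates the atoms on the j side of the j-k bond (the connected component
#' of j after removing the bond, hydrogens included) about the bond axis so
#' the i-j-k-l dihedral equals `angle_deg`.
#'
#' @param s A `conformer`.
#' @param quad Length-4 atom index vector (i, j, k, l).
#' @param angle_deg Target dihedral in degrees.
#' @param g Molecular graph of `s`; perceived if omitted.
#' @return The rotated `conformer`.
#' @export
set_torsion <- function(s, quad, angle_deg, g = perceive_bonds(s)) {
  quad <- as.integer(quad)
  j <- quad[2L]; k <- quad[3L]
  e <- g$edges
  keep <- !(e[, 1L] == min(j, k) & e[, 2L] == max(j, k))
  gr <- mg_igraph(molecular_graph(g$elements, e[keep, , drop = FALSE]))
  side <- as.integer(igraph::subcomponent(gr, j))
  if (k %in% side)
    abort_contract("bond j-k is in a ring; torsion cannot be set rigidly")
  cur <- torsion_angles(s, matrix(quad, ncol = 4L))
  delta <- (angle_deg - cur) * pi / 180
  axis <- s$coords[j, ] - s$coords[k, ]
  axis <- axis / sqrt(sum(axis^2))
  apply_delta <- function(d) {
    out <- s
    shifted <- sweep(s$coords[side, , drop = FALSE], 2L, s$coords[k, ])
    out$coords[side, ] <- sweep(rotate_about(shifted, axis, d), 2L,
                                s$coords[k, ], `+`)
    out
  }
  out <- apply_delta(delta)
  got <- torsion_angles(out, matrix(quad, ncol = 4L))
  if (abs(((got - angle_deg + 180) %% 360) - 180) > 1e-6)
    out <- apply_delta(-delta)  # dihedral sign convention flips with side
  out
}

#' Specification of a planted conformer ensemble
#'
#' @param families Data frame with columns `angle` (rotor torsion, deg),
#'   `offset` (family free-energy offset, kcal/mol) and `n` (member
#'   count). Defaults emulate one low family and one family 3.2 kcal/mol
#'   up, on opposite rotor orientations.
#' @param jitter_sigma Isotropic Gaussian coordinate jitter, Angstrom.
#' @param permute_fraction Fraction of all members whose
#'   symmetry-equivalent atom indices get shuffled by a random non-trivial
#'   graph automorphism.
#' @param energy_noise Gaussian noise on member energies, kcal/mol.
#' @param seed Integer seed; the generated ensemble is a pure function of
#'   the spec.
#' @return Object of class `"planted_spec"`.
#' @export
planted_spec <- function(families = data.frame(angle = c(0, 180),
                                               offset = c(0, 3.2),
                                               n = c(10L, 10L)),
                         jitter_sigma = 0.05, permute_fraction = 0.25,
                         energy_noise = 0.05, seed = 2024L) {
  if (!all(c("angle", "offset", "n") %in% names(families)))
    abort_config("families must have columns angle, offset, n")
  if (any(families$n < 1L)) abort_config("family member counts must be >= 1")
  if (jitter_sigma < 0) abort_config("jitter_sigma must be >= 0")
  if (permute_fraction < 0 || permute_fraction > 1)
    abort_config("permute_fraction must lie in [0, 1]")
  structure(list(families = families, jitter_sigma = jitter_sigma,
                 permute_fraction = permute_fraction,
                 energy_noise = energy_noise, seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a planted conformer ensemble
#'
#' For each family the rotor torsion of the template is set to the family
#' angle, members get isotropic Gaussian coordinate jitter and an energy of
#' family offset plus Gaussian noise, and a chosen fraction of all members
#' (deterministic count `round(fraction * total)`) have their
#' symmetry-equivalent atom indices permuted by a random non-trivial graph
#' automorphism. Fully reproducible from the spec seed.
#'
#' @param spec A `planted_spec`.
#' @return List with `ensemble` (a `conformer_ensemble`) and `truth` (data
#'   frame: label, family, angle, energy, permuted).
#' @export
generate_ensemble <- function(spec = planted_spec()) {
  if (!inherits(spec, "planted_spec"))
    abort_config("spec must be a planted_spec")
  tpl <- make_rotor_template()
  ts <- detect_torsions(tpl$structure, tpl$graph)
  quad <- ts$torsions[1L, ]

  # angular jitter induced on the rotor torsion by coordinate jitter: the
  # reference atoms sit ~1.4 A off the bond axis
  ang_jit <- sqrt(2) * spec$jitter_sigma / 1.4 * 180 / pi
  angs <- spec$families$angle
  if (nrow(spec$families) > 1L) {
    gaps <- abs(outer(angs, angs, `-`)) %% 360
    gaps <- pmin(gaps, 360 - gaps)
    mingap <- min(gaps[upper.tri(gaps)])
    if (mingap < 5 * ang_jit)
      warning(sprintf(
        "family angles only %.2f deg apart vs angular jitter %.2f deg; planted structure may be unrecoverable",
        mingap, ang_jit))
  }

  autos <- enumerate_isomorphisms(tpl$graph, tpl$graph)
  ha <- attr(autos[[1L]], "heavy_a")
  nontrivial <- Filter(function(m) !identical(as.integer(m), ha), autos)

  total <- sum(spec$families$n)
  natom <- length(tpl$structure$elements)
  set.seed(spec$seed)
  n_perm <- round(spec$permute_fraction * total)
  permuted <- rep(FALSE, total)
  if (n_perm > 0L) permuted[sample.int(total, n_perm)] <- TRUE
  auto_pick <- if (length(nontrivial) > 0L)
    sample.int(length(nontrivial), total, replace = TRUE)
  else rep(1L, total)

  structures <- vector("list", total)
  truth <- data.frame(label = character(total), family = integer(total),
                      angle = numeric(total), energy = numeric(total),
                      permuted = logical(total))
  idx <- 0L
  for (f in seq_len(nrow(spec$families))) {
    base <- set_torsion(tpl$structure, quad, spec$families$angle[f],
                        tpl$graph)
    for (m in seq_len(spec$families$n[f])) {
      idx <- idx + 1L
      s <- base
      s$coords <- s$coords +
        matrix(stats::rnorm(natom * 3L, 0, spec$jitter_sigma), natom, 3L)
      s$energy <- spec$families$offset[f] +
        stats::rnorm(1L, 0, spec$energy_noise)
      s$label <- sprintf("f%d_m%d", f, m)
      if (permuted[idx] && length(nontrivial) > 0L) {
        map <- nontrivial[[auto_pick[idx]]]
        perm <- seq_len(natom)
        perm[ha] <- as.integer(map)          # atom a -> new index perm[a]
        s$coords[perm, ] <- s$coords
        s$elements[perm] <- s$elements
      }
      structures[[idx]] <- s
      truth[idx, ] <- list(s$label, f, spec$families$angle[f], s$energy,
                           permuted[idx])
    }
  }
  list(ensemble = conformer_ensemble(structures, name = "planted"),
       truth = truth)
}
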