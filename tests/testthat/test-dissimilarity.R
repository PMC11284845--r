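# Kabsch RMSD, isomorphism enumeration, symmetry-corrected RMSD, torsions,
# and the compound matrix.

test_that("kabsch_rmsd is zero on identity and rigid copies", {
  s <- toy_water()
  expect_equal(kabsch_rmsd(s, s), 0)
  expect_lt(kabsch_rmsd(s, rigid_transform(s)), 1e-6)
})

test_that("kabsch_rmsd matches a numerical rotation-search oracle", {
  A <- conformer(c("C", "C", "O"),
                 rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.2, 0)))
  B <- A
  B$coords[3, ] <- B$coords[3, ] + c(0.4, -0.3, 0.5)  # displace one atom
  got <- kabsch_rmsd(A, B)
  expect_equal(got, rotation_search_rmsd(A$coords, B$coords),
               tolerance = 1e-5)
})

test_that("kabsch_rmsd rejects non-element-preserving maps", {
  A <- toy_chain(c("C", "O"))
  bad <- c(2L, 1L)  # maps C onto O
  attr(bad, "heavy_a") <- c(1L, 2L)
  expect_error(kabsch_rmsd(A, A, bad), class = "confsel_contract_error")
})

test_that("isomorphism counts match brute-force permutation checks", {
  ring6 <- ring_graph(6)
  maps <- enumerate_isomorphisms(ring6, ring6)
  expect_length(maps, 12L)  # 6 rotations x 2 reflections
  expect_equal(brute_automorphism_count(ring6), 12L)
  cco <- path_graph(c("C", "C", "O"))
  expect_length(enumerate_isomorphisms(cco, cco), 1L)
  expect_equal(brute_automorphism_count(cco), 1L)
  # non-isomorphic: C3 ring vs C3 path
  expect_length(enumerate_isomorphisms(ring_graph(3), path_graph(rep("C", 3))),
                0L)
})

test_that("isomorphism cap truncates with a warning and keeps identity", {
  ring6 <- ring_graph(6)
  expect_warning(maps <- enumerate_isomorphisms(ring6, ring6, cap = 5L),
                 "truncated")
  expect_length(maps, 5L)
  expect_true(isTRUE(attr(maps, "truncated")))
  expect_true(any(vapply(maps, function(m)
    identical(as.integer(m), 1:6), logical(1))))
})

test_that("symmetry_rmsd sees through equivalent-atom index swaps", {
  tpl <- make_rotor_template()
  s <- tpl$structure
  s2 <- s
  s2$coords[c(5, 6), ] <- s$coords[c(6, 5), ]  # swap the equivalent F pair
  expect_gt(kabsch_rmsd(s, s2), 0.5)           # naive identity map fooled
  expect_lt(symmetry_rmsd(s, s2), 1e-8)
  expect_lt(symmetry_rmsd(s, s), 1e-12)
})

test_that("symmetry_rmsd is symmetric, bounded by the identity map, and matches the exhaustive oracle", {
  tpl <- make_rotor_template()
  set.seed(101)
  for (rep in 1:5) {
    A <- tpl$structure
    B <- tpl$structure
    B$coords <- B$coords + matrix(rnorm(length(B$coords), 0, 0.05),
                                  nrow(B$coords), 3)
    B <- rigid_transform(B, angles = rnorm(3), shift = rnorm(3))
    ab <- symmetry_rmsd(A, B)
    expect_equal(as.numeric(ab), as.numeric(symmetry_rmsd(B, A)),
                 tolerance = 1e-8)
    expect_lte(as.numeric(ab), kabsch_rmsd(A, B) + 1e-12)
    # exhaustive element-preserving permutation oracle (7 heavy atoms here
    # but only 2 C x 2 O x 2 F orderings survive element matching)
    expect_equal(as.numeric(ab), brute_perm_rmsd(A, B), tolerance = 1e-8)
  }
})

test_that("symmetry_rmsd is invariant under automorphism relabeling", {
  tpl <- make_rotor_template()
  autos <- enumerate_isomorphisms(tpl$graph, tpl$graph)
  ha <- attr(autos[[1]], "heavy_a")
  set.seed(5)
  B <- tpl$structure
  B$coords <- B$coords + matrix(rnorm(length(B$coords), 0, 0.03),
                                nrow(B$coords), 3)
  base <- as.numeric(symmetry_rmsd(tpl$structure, B))
  for (m in autos) {
    perm <- seq_along(B$elements)
    perm[ha] <- as.integer(m)
    B2 <- B
    B2$coords[perm, ] <- B$coords
    expect_equal(as.numeric(symmetry_rmsd(tpl$structure, B2)), base,
                 tolerance = 1e-8)
  }
})

test_that("symmetry_rmsd refuses non-isomorphic structures", {
  expect_error(
    symmetry_rmsd(toy_ring(3), toy_chain(rep("C", 3)),
                  ring_graph(3), path_graph(rep("C", 3))),
    class = "confsel_mismatch_error")
})

test_that("detect_torsions applies the rotatable-bond rule", {
  # n-butane heavy chain: one rotatable bond C2-C3
  ts <- detect_torsions(toy_chain(rep("C", 4)), path_graph(rep("C", 4)))
  expect_equal(nrow(ts$torsions), 1L)
  expect_equal(as.integer(ts$torsions[1, ]), c(1L, 2L, 3L, 4L))
  # ethane: terminal bond only
  expect_equal(nrow(detect_torsions(toy_chain(rep("C", 2)),
                                    path_graph(rep("C", 2)))$torsions), 0L)
  # cyclohexane: all bonds in a ring
  expect_equal(nrow(detect_torsions(toy_ring(6), ring_graph(6))$torsions),
               0L)
})

test_that("torsion_distance wraps circularly", {
  expect_equal(torsion_distance(c(30, -170), c(30, -170)), 0)
  expect_equal(torsion_distance(10, 350), 20)
  expect_equal(torsion_distance(c(0, 90), c(180, 90)), 90)
  expect_error(torsion_distance(1:2, 1:3), class = "confsel_contract_error")
})

test_that("compound_matrix fuses normalized components as a weighted mean", {
  sim <- generate_ensemble(planted_spec(
    families = data.frame(angle = c(0, 120, 240), offset = c(0, 1, 2),
                          n = c(3, 3, 3)),
    jitter_sigma = 0.02, permute_fraction = 0, seed = 99))
  e <- sim$ensemble
  D <- compound_matrix(e, weights = c(2, 1, 1))
  n <- length(e)
  # symmetry, zero diagonal, nonnegativity, [0,1] after normalization
  expect_equal(D$values, t(D$values))
  expect_equal(diag(D$values), rep(0, n), ignore_attr = TRUE)
  expect_true(all(D$values >= 0 & D$values <= 1))
  # hand-computed fusion from the raw components (arithmetic oracle)
  mm <- function(m) if (max(m) > min(m)) (m - min(m)) / (max(m) - min(m))
        else m * 0
  manual <- (2 * mm(D$components$rmsd) + mm(D$components$dihedral) +
             mm(D$components$energy)) / 4
  expect_equal(D$values, manual, ignore_attr = TRUE)
  # energy component is |Ei - Ej|
  en <- ensemble_energies(e)
  expect_equal(D$components$energy, abs(outer(en, en, `-`)))
  # single metric: fused values equal that normalized component
  D1 <- compound_matrix(e, metrics = "rmsd")
  expect_equal(D1$values, mm(D1$components$rmsd), ignore_attr = TRUE)
})

test_that("compound_matrix degenerate and error cases", {
  s <- toy_chain(c("C", "C", "O", "C"))
  s$energy <- 1.0
  e <- conformer_ensemble(list(s, s, s))
  D <- compound_matrix(e)
  expect_true(all(D$values == 0))
  s2 <- s; s2$energy <- NA_real_
  expect_error(compound_matrix(conformer_ensemble(list(s, s2))),
               class = "confsel_config_error")
  expect_error(compound_matrix(e, metrics = "rmsd", weights = c(0)),
               class = "confsel_config_error")
})
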