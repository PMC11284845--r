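# Curtin-Hammett arithmetic: Boltzmann weights, ensemble energies,
# effective barriers, Eyring rates, product ratios, and diagnostics.

test_that("boltzmann_weights match closed forms and sum to one", {
  expect_equal(boltzmann_weights(5.0), 1.0)
  expect_equal(boltzmann_weights(c(3, 3)), c(0.5, 0.5))
  # energies 0 and RT ln 2 -> weights 2/3, 1/3
  expect_equal(boltzmann_weights(c(0, RT298 * log(2))), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    w <- boltzmann_weights(rnorm(8, 10, 3))
    expect_true(all(w > 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  expect_error(boltzmann_weights(numeric(0)),
               class = "confsel_contract_error")
})

test_that("ensemble_free_energy is the weighted mean, above the minimum", {
  expect_equal(ensemble_free_energy(7.2), 7.2)
  expect_equal(ensemble_free_energy(c(0, 0, 0)), 0)
  # frozen closed-form check: two levels 13.4 and 17.5 kcal/mol at 298.15 K
  w_hi <- exp(-4.1 / RT298) / (1 + exp(-4.1 / RT298))
  expect_equal(ensemble_free_energy(c(13.4, 17.5)),
               13.4 * (1 - w_hi) + 17.5 * w_hi, tolerance = 1e-12)
  expect_equal(round(ensemble_free_energy(c(13.4, 17.5)), 3), 13.404)
  # min <= G_ens <= max, strictly above min unless degenerate
  set.seed(4)
  for (i in 1:10) {
    en <- rnorm(6, 15, 2)
    g <- ensemble_free_energy(en)
    expect_gt(g, min(en))
    expect_lte(g, max(en))
  }
})

test_that("effective_barrier is the log-sum-exp barrier, below the minimum", {
  expect_equal(effective_barrier(9.9), 9.9)
  expect_equal(effective_barrier(c(8, 8)), 8 - RT298 * log(2),
               tolerance = 1e-12)
  expect_equal(round(effective_barrier(c(13.4, 17.5)), 4), 13.3994)
  set.seed(6)
  for (i in 1:10) {
    en <- rnorm(6, 15, 2)
    eff <- effective_barrier(en)
    expect_lt(eff, min(en))
    # ordering: rate-sum barrier <= min <= Boltzmann ensemble energy
    expect_lte(eff, min(en))
    expect_gte(ensemble_free_energy(en), min(en))
  }
})

test_that("eyring_rate follows kB T / h exp(-dg/RT)", {
  k0 <- eyring_rate(0)
  expect_equal(k0, confsel_constants$kB_over_h * 298.15)
  expect_equal(k0, 6.2124e12, tolerance = 1e-4)
  expect_equal(eyring_rate(RT298 * log(2)), k0 / 2, tolerance = 1e-12)
  dgs <- seq(0, 30, by = 2.5)
  expect_true(all(diff(eyring_rate(dgs)) < 0))
})

test_that("ratio_from_ddg reproduces the printed splits", {
  r <- ratio_from_ddg(-2.21)
  expect_equal(unname(r$percent), c(98, 2))
  expect_equal(sum(r$percent), 100)
  expect_equal(unname(ratio_from_ddg(1.75)$percent), c(5, 95))
  r0 <- ratio_from_ddg(0)
  expect_equal(r0$ratio, 1.0)
  expect_equal(unname(r0$percent), c(50, 50))
})

test_that("selectivity methods agree where they must and differ where they must", {
  a <- pathway_energies("2a", list(15.3))
  b <- pathway_energies("2b", list(13.4, 17.5))
  rep_cr <- selectivity(a, b, method = "cluster_resolved")
  expect_equal(unname(rep_cr$percent), c(4, 96))
  # symmetric input: all methods give 1:1
  for (m in c("boltzmann", "rate_sum", "cluster_resolved")) {
    s <- selectivity(list(c(10)), list(c(10)), method = m)
    expect_equal(s$ratio, 1.0)
    expect_equal(unname(s$percent), c(50, 50))
  }
  # algebraic collapses, asserted numerically on random pools
  set.seed(9)
  for (i in 1:5) {
    ea <- rnorm(6, 15, 1.5); eb <- rnorm(6, 14.5, 1.5)
    singletons_a <- as.list(ea); singletons_b <- as.list(eb)
    expect_equal(
      selectivity(singletons_a, singletons_b,
                  method = "cluster_resolved")$ratio,
      selectivity(list(ea), list(eb), method = "rate_sum")$ratio,
      tolerance = 1e-9)
    expect_equal(
      selectivity(list(ea), list(eb), method = "cluster_resolved")$ratio,
      selectivity(list(ea), list(eb), method = "boltzmann")$ratio,
      tolerance = 1e-9)
  }
  expect_error(selectivity(a, b, method = "bogus"),
               class = "confsel_config_error")
})

test_that("selectivity invariants: antisymmetry, shift, temperature, overflow", {
  a <- list(c(15.3, 15.8), c(16.2))
  b <- list(c(13.4), c(17.5, 17.9))
  for (m in c("boltzmann", "rate_sum", "cluster_resolved")) {
    f <- selectivity(a, b, method = m)
    g <- selectivity(b, a, method = m)
    expect_equal(f$ratio * g$ratio, 1, tolerance = 1e-9)
    # adding a constant to every energy leaves the ratio unchanged
    ac <- lapply(a, `+`, 7.3); bc <- lapply(b, `+`, 7.3)
    expect_equal(selectivity(ac, bc, method = m)$ratio, f$ratio,
                 tolerance = 1e-9)
  }
  # high-temperature limit washes out a fixed ddg; |ratio - 1| is bounded
  # by exp(|ddg|/RT) - 1 (~1.0e-3 at |ddg| = 2, T = 1e6 K)
  for (ddg in c(-2, -1, 0.5, 2)) {
    dev <- abs(ratio_from_ddg(ddg, T = 1e6)$ratio - 1)
    expect_lte(dev, exp(abs(ddg) / (confsel_constants$R * 1e6)) - 1 + 1e-15)
  }
  expect_lt(abs(ratio_from_ddg(1.9, T = 1e6)$ratio - 1), 1e-3)
  # shift-stable exponentials survive a 500 kcal/mol spread
  wide <- c(0, 250, 500)
  expect_true(all(is.finite(boltzmann_weights(wide))))
  expect_true(is.finite(effective_barrier(wide)))
  expect_true(is.finite(
    selectivity(list(wide), list(wide + 1), method = "rate_sum")$ratio))
})

test_that("duplicate_sensitivity quantifies the repeated-conformer error", {
  expect_equal(duplicate_sensitivity(10.0), RT298 * log(2),
               tolerance = 1e-12)
  expect_equal(duplicate_sensitivity(c(10, 10)), RT298 * log(3 / 2),
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:10) {
    en <- rnorm(5, 12, 2)
    shift <- duplicate_sensitivity(en)
    expect_gt(shift, 0)
    expect_lte(shift, RT298 * log(2) + 1e-12)
  }
})

test_that("read_pathway_csv groups clusters and validates products", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("label,product,cluster,energy_kcal_mol",
               "a_down,2a,1,15.3",
               "b_down,2b,1,13.4",
               "b_up,2b,2,17.5"), path)
  pw <- read_pathway_csv(path)
  expect_named(pw, c("2a", "2b"))
  expect_length(pw[["2b"]]$clusters, 2L)
  rep <- selectivity(pw[["2a"]], pw[["2b"]], method = "cluster_resolved")
  expect_equal(unname(rep$percent), c(4, 96))
  # no cluster column: every conformer its own cluster
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("label,product,energy_kcal_mol",
               "x,2a,15.3", "y,2b,13.4", "z,2b,17.5"), path2)
  pw2 <- read_pathway_csv(path2)
  expect_length(pw2[["2b"]]$clusters, 2L)
  # three products rejected
  path3 <- tempfile(fileext = ".csv")
  writeLines(c("label,product,energy_kcal_mol",
               "x,2a,15.3", "y,2b,13.4", "z,2c,17.5"), path3)
  expect_error(read_pathway_csv(path3), class = "confsel_config_error")
})
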