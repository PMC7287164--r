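test_that("paired t maps match stats::t.test cell by cell", {
  set.seed(21)
  stim <- lapply(1:5, function(i) matrix(rnorm(6, 1), 2, 3))
  base <- lapply(1:5, function(i) matrix(rnorm(6), 2, 3))
  tm <- paired_t_map(stim, base)
  expect_equal(tm$df, 4)
  for (cell in list(c(1, 1), c(2, 3))) {
    s <- sapply(stim, function(m) m[cell[1], cell[2]])
    b <- sapply(base, function(m) m[cell[1], cell[2]])
    expect_equal(tm$t_map[cell[1], cell[2]],
                 unname(stats::t.test(s, b, paired = TRUE)$statistic),
                 tolerance = 1e-12)
  }
  # identical conditions -> t = 0 everywhere is a degenerate-variance error
  expect_error(paired_t_map(stim, stim), "zero-variance")
  expect_error(paired_t_map(stim[1:2], base[1:2]), "3 subjects")
})

test_that("cluster formation follows 4- vs 8-adjacency", {
  tm <- matrix(0, 3, 3)
  tm[2, ] <- 3; tm[, 2] <- 3          # plus shape, 5 cells
  cl <- form_clusters(tm, t_crit = 2.5)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$cells), 5)
  expect_equal(cl[[1]]$mass, 15)

  # diagonal-only contact: two clusters under 4-adjacency, one under 8
  tm2 <- matrix(0, 3, 3); tm2[1, 1] <- 4; tm2[2, 2] <- 5
  expect_length(form_clusters(tm2, 2.5, "4"), 2)
  expect_length(form_clusters(tm2, 2.5, "8"), 1)

  expect_length(form_clusters(matrix(0, 4, 4), 2.5), 0)
})

test_that("every supra-threshold cell lands in exactly one cluster", {
  set.seed(33)
  for (i in 1:20) {
    tm <- matrix(rnorm(30, 1), 5, 6)
    cl <- form_clusters(tm, 1.5)
    cells <- do.call(rbind, lapply(cl, `[[`, "cells"))
    sup <- which(tm >= 1.5, arr.ind = TRUE)
    expect_equal(nrow(cells), nrow(sup))
    expect_equal(nrow(unique(as.data.frame(cells))), nrow(sup))
  }
})

test_that("permutation p-values behave at the bounds and reproduce", {
  set.seed(5)
  # strong uniform effect: observed mass should beat every permutation
  stim <- lapply(1:8, function(i) matrix(rnorm(12, 3), 3, 4))
  base <- lapply(1:8, function(i) matrix(rnorm(12), 3, 4))
  params <- cluster_test_params(n_permutations = 500, seed = 2)
  ct <- cluster_permutation_test(stim, base, params)
  expect_gte(nrow(ct$clusters), 1)
  expect_equal(min(ct$clusters$p_corrected), 1 / 501, tolerance = 1e-12)
  ct2 <- cluster_permutation_test(stim, base, params)
  expect_identical(ct$null_max_mass, ct2$null_max_mass)
  expect_identical(ct$clusters, ct2$clusters)
  # corrected p monotone decreasing in mass
  ord <- order(ct$clusters$mass)
  expect_true(all(diff(ct$clusters$p_corrected[ord]) <= 0))
})

test_that("Monte-Carlo p agrees with exhaustive sign-flip enumeration", {
  t_crit_for <- function(n, p = 0.01) stats::qt(1 - p, n - 1)
  set.seed(77)
  for (fix in 1:10) {
    n <- sample(7:8, 1)
    stim <- lapply(1:n, function(i) matrix(rnorm(15, 0.9), 3, 5))
    base <- lapply(1:n, function(i) matrix(rnorm(15), 3, 5))
    ct <- suppressWarnings(cluster_permutation_test(stim, base,
            cluster_test_params(n_permutations = 2000, seed = fix)))
    if (nrow(ct$clusters) == 0) next
    D <- paired_t_map(stim, base)$diffs
    null <- enumerate_null(D, 3, 5, t_crit_for(n))
    for (k in seq_len(nrow(ct$clusters))) {
      exact_p <- mean(null >= ct$clusters$mass[k])
      mc_p <- ct$clusters$p_corrected[k]
      se <- sqrt(max(exact_p * (1 - exact_p), 1e-6) / 2000)
      expect_lt(abs(mc_p - exact_p), 4 * se + 2 / 2001 + 1e-12)
    }
  }
})

test_that("few subjects trigger a resolution warning", {
  stim <- lapply(1:4, function(i) matrix(rnorm(4, 2), 2, 2))
  base <- lapply(1:4, function(i) matrix(rnorm(4), 2, 2))
  expect_warning(cluster_permutation_test(stim, base,
                   cluster_test_params(n_permutations = 100, seed = 1)),
                 "sign patterns")
})

test_that("comodulogram objects are accepted directly", {
  z <- matrix(rnorm(6), 2, 3, dimnames = list(c(5, 6), c(30, 40, 50)))
  cm <- structure(list(values = z), class = "comodulogram")
  stim <- list(cm, cm, cm, cm)
  base <- lapply(1:4, function(i) {
    m <- structure(list(values = z + matrix(rnorm(6, 0, 0.1), 2, 3)),
                   class = "comodulogram")
    m
  })
  tm <- paired_t_map(stim, base)
  expect_equal(dim(tm$t_map), c(2, 3))
  expect_equal(rownames(tm$t_map), c("5", "6"))
})
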