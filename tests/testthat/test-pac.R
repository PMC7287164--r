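test_that("min-max normalization is affine-invariant and flags flat trials", {
  set.seed(3)
  x <- matrix(runif(3 * 40), 3)
  n1 <- minmax_normalize(x)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_equal(apply(n1, 1, min), rep(0, 3))
  expect_equal(apply(n1, 1, max), rep(1, 3))
  # series already spanning [0, 1] is unchanged
  expect_equal(minmax_normalize(n1), n1, tolerance = 1e-12)
  # affine map a*x + b normalizes identically
  expect_equal(minmax_normalize(2.7 * x - 5), n1, tolerance = 1e-12)
  # constant trial -> zeros with a warning
  expect_warning(n2 <- minmax_normalize(rbind(x[1, ], rep(4, 40))),
                 "constant")
  expect_true(all(n2[2, ] == 0))
})

test_that("normalization window restricts where min/max are taken", {
  times <- seq(-1.5, 1.5, by = 0.01)
  x <- matrix(times, 1)                     # ramp
  nw <- minmax_normalize(x, times, c(-1.3, 1.3))
  inw <- times >= -1.3 & times < 1.3
  expect_equal(min(nw[1, inw]), 0, tolerance = 1e-9)
  expect_true(max(nw[1, !inw]) > 1)         # outside may exceed [0, 1]
})

test_that("MVL matches hand-computed and brute-force oracles", {
  a <- rbind(c(1, 0.5), c(0.2, 1), c(0.8, 0.3), c(0.4, 0.9))
  phi <- rbind(c(0, pi / 2), c(pi, 0), c(pi / 2, pi), c(0, 3 * pi / 2))
  # hand computation: (|0.3 + 0.2i| + |0.175 - 0.1i|) / 2
  hand <- (sqrt(0.13) + sqrt(0.040625)) / 2
  expect_equal(mvl_pac(phi, a), hand, tolerance = 1e-15)
  expect_equal(mvl_oracle(phi, a), hand, tolerance = 1e-15)

  # aligned unit vectors -> 1; balanced phases -> 0
  ph0 <- matrix(0.7, 5, 8)
  expect_equal(mvl_pac(ph0, matrix(1, 5, 8)), 1, tolerance = 1e-15)
  phb <- matrix(seq(0, 2 * pi, length.out = 5)[-5], 4, 6)
  expect_equal(mvl_pac(phb, matrix(1, 4, 6)), 0, tolerance = 1e-12)

  # vectorized implementation vs brute force on 50 random fixtures
  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:10, 1); m <- sample(2:15, 1)
    a <- matrix(runif(n * m), n)
    phi <- matrix(runif(n * m, -pi, pi), n)
    expect_equal(mvl_pac(phi, a), mvl_oracle(phi, a), tolerance = 1e-12)
  }

  # homogeneity in amplitude scale
  expect_equal(mvl_pac(phi, 3 * a), 3 * mvl_pac(phi, a), tolerance = 1e-12)
  expect_error(mvl_pac(matrix(0, 1, 4), matrix(1, 1, 4)), "2 trials")
})

test_that("z-scoring uses sample sd and rejects degenerate surrogates", {
  s <- c(1, 2, 3, 4, 5)
  expect_equal(z_score_pac(mean(s), s), 0)
  expect_equal(z_score_pac(mean(s) + 2 * sd(s), s), 2)
  expect_error(z_score_pac(1, rep(2, 10)), "degenerate")
})

test_that("segment swap permutes segments and preserves content", {
  x <- 1:10
  expect_equal(segment_swap(x, 4), c(5:10, 1:4))
  set.seed(1)
  y <- segment_swap(x, c(3, 7))
  expect_equal(sort(y), 1:10)
  # spectrum preservation: a swap is a circular shift (one boundary join)
  set.seed(2)
  z <- one_over_f_noise(512, 100, 1, 1)
  pz <- Mod(stats::fft(z))^2
  ps <- Mod(stats::fft(segment_swap(z, 200)))^2
  expect_gt(stats::cor(pz, ps), 0.95)
  expect_equal(mean(ps), mean(pz), tolerance = 1e-9)  # total power exact
})

test_that("surrogate distributions are reproducible and strictly positive", {
  spec <- fast_spec()
  ens <- baseline_subtract(synthesize_ensemble(spec, coupling_spec(6, 40, 0.8),
                                               noise_spec(), n = 20, seed = 5))
  pp <- pac_params(n_surrogates = 15, seed = 42)
  s1 <- surrogate_pac(ens, 6, 40, pp)
  s2 <- surrogate_pac(ens, 6, 40, pp)
  expect_identical(s1$surrogates, s2$surrogates)
  expect_length(s1$surrogates, 15)
  expect_true(all(s1$surrogates > 0))
  pp$seed <- 43
  s3 <- surrogate_pac(ens, 6, 40, pp)
  expect_false(identical(s1$surrogates, s3$surrogates))
})

test_that("observed MVL sits inside the surrogate distribution when m = 0", {
  spec <- fast_spec()
  inside <- sapply(1:8, function(s) {
    ens <- baseline_subtract(synthesize_ensemble(
      spec, coupling_spec(6, 40, 0), noise_spec(), n = 30, seed = s))
    sp <- surrogate_pac(ens, 6, 40, pac_params(n_surrogates = 60, seed = s))
    q <- stats::quantile(sp$surrogates, c(0.025, 0.975))
    sp$observed >= q[1] && sp$observed <= q[2]
  })
  expect_gte(sum(inside), 6)
})

test_that("comodulograms recover a strongly coupled cell and stay null at baseline", {
  spec <- fast_spec()
  ens <- baseline_subtract(synthesize_ensemble(spec, coupling_spec(6, 40, 0.9),
                                               noise_spec(), n = 60, seed = 12))
  pp <- pac_params(fP_grid = c(5, 6, 7), fA_grid = c(36, 40, 44),
                   n_surrogates = 30, seed = 9)
  cm <- comodulogram(ens, pp)
  expect_named(cm, c("stimulus", "baseline"))
  expect_gt(max(cm$stimulus$values), 2)
  # stimulus-window-only coupling: baseline grid stays unremarkable
  expect_lt(max(cm$baseline$values), max(cm$stimulus$values))
  expect_lt(mean(abs(cm$baseline$values)), 1.5)
  expect_true(all(cm$stimulus$raw_mvl >= 0))
  expect_true(all(cm$stimulus$surrogate_sd > 0))
})

test_that("pac parameter validation enforces paper ranges", {
  expect_error(pac_params(fP_grid = 2:12), "fP_grid")
  expect_error(pac_params(fA_grid = 10:60), "fA_grid")
  expect_error(pac_params(n_surrogates = 0), "n_surrogates")
})
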