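# Conditional density models, bandwidths, Bayes inversion, clipping.

test_that("Silverman bandwidth follows the robust rule-of-thumb", {
  # uniform-shaped sample scaled to unit sd: IQR/1.34 > 1, so the rule
  # reduces to 0.9 * sd * n^(-1/5)
  x <- seq(0, 1, length.out = 900)
  x <- x / sd(x)
  expect_equal(silverman_bandwidth(x), 0.9 * 900^(-1 / 5), tolerance = 1e-10)
  expect_equal(0.9 * 900^(-1 / 5), 0.2309, tolerance = 1e-4)

  # n = 2, values {0, 1}: sd = 1/sqrt(2), IQR (type 7) = 0.5
  h2 <- 0.9 * min(1 / sqrt(2), 0.5 / 1.34) * 2^(-1 / 5)
  expect_equal(silverman_bandwidth(c(0, 1)), h2, tolerance = 1e-12)
  expect_gt(h2, 0)

  # scale equivariance
  set.seed(1)
  y <- rnorm(200)
  expect_equal(silverman_bandwidth(3.7 * y), 3.7 * silverman_bandwidth(y),
               tolerance = 1e-12)

  expect_error(silverman_bandwidth(rep(1, 10)),
               class = "erpleak_degenerate_error")
  expect_error(silverman_bandwidth(1), class = "erpleak_param_error")
})

test_that("fitted priors are the empirical class frequencies", {
  set.seed(2)
  x <- matrix(rnorm(900), ncol = 1)
  labels <- rep(c(1L, 0L), c(150, 750))
  m <- fit_density(x, labels, backend = "kde")
  expect_equal(unname(m$priors), c(5 / 6, 1 / 6))
  expect_named(m$priors, c("0", "1"))
  expect_error(fit_density(x, rep(0L, 900)), class = "erpleak_empty_class_error")
  expect_error(fit_density(x[1:3, , drop = FALSE], c(0L, 0L, 1L)),
               class = "erpleak_empty_class_error")
})

test_that("Gaussian backend recovers the generating moments", {
  set.seed(3)
  x <- matrix(rnorm(2e4), ncol = 2)
  m <- fit_density(x, rep(0:1, each = 5000), backend = "gaussian")
  for (cl in 1:2) for (d in 1:2) {
    expect_equal(m$models[[cl]][[d]]$mean, 0, tolerance = 0.05)
    expect_equal(m$models[[cl]][[d]]$sd, 1, tolerance = 0.05)
  }
})

test_that("KDE density is the average of the kernels (closed form)", {
  x <- matrix(c(-1, 1, 0, 5), ncol = 1)
  m <- fit_density(x, c(1L, 1L, 0L, 0L), backend = "kde")
  h <- m$models[["1"]][[1]]$h
  expect_equal(h, silverman_bandwidth(c(-1, 1)))
  ll <- log2_likelihood(m, matrix(0, 1, 1))
  expected <- mean(dnorm((0 - c(-1, 1)) / h)) / h
  expect_equal(unname(ll[1, "1"]), log2(expected), tolerance = 1e-12)
})

test_that("KDE integrates to one", {
  set.seed(4)
  v <- c(rnorm(30), rexp(20))          # lumpy sample
  x <- matrix(c(v, rnorm(50)), ncol = 1)
  m <- fit_density(x, rep(1:0, each = 50), backend = "kde")
  h <- m$models[["1"]][[1]]$h
  grid <- seq(min(v) - 8 * h, max(v) + 8 * h, length.out = 4000)
  dens <- 2^log2_likelihood(m, matrix(grid, ncol = 1))[, "1"]
  expect_equal(sum(dens) * diff(grid)[1], 1, tolerance = 1e-3)
})

test_that("log2 likelihood obeys the closed form and the product rule", {
  set.seed(5)
  x <- matrix(rnorm(400), ncol = 2)
  labels <- rep(0:1, each = 100)
  m <- fit_density(x, labels, backend = "gaussian")
  # force unit templates to check the closed form at the class mean
  for (cl in 1:2) for (d in 1:2) {
    m$models[[cl]][[d]]$mean <- 0; m$models[[cl]][[d]]$sd <- 1
  }
  ll <- log2_likelihood(m, matrix(0, 1, 2))
  expect_equal(unname(ll[1, "0"]), 2 * log2(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
  # independence: sum of per-dimension log2 densities
  m1 <- fit_density(x[, 1, drop = FALSE], labels, backend = "kde")
  m2 <- fit_density(x[, 2, drop = FALSE], labels, backend = "kde")
  m12 <- fit_density(x, labels, backend = "kde")
  pt <- matrix(c(0.3, -0.2), 1, 2)
  expect_equal(log2_likelihood(m12, pt)[1, "1"],
               log2_likelihood(m1, pt[, 1, drop = FALSE])[1, "1"] +
                 log2_likelihood(m2, pt[, 2, drop = FALSE])[1, "1"],
               tolerance = 1e-10)
  # duplicated training point stays finite under KDE
  expect_true(is.finite(log2_likelihood(m12, x[1, , drop = FALSE])[1, "1"]))
  expect_error(log2_likelihood(m12, matrix(0, 1, 3)),
               class = "erpleak_dim_error")
})

test_that("posterior inversion follows Bayes' rule", {
  set.seed(6)
  x <- matrix(rnorm(900), ncol = 1)
  labels <- rep(c(1L, 0L), c(150, 750))
  m <- fit_density(x, labels, backend = "gaussian")
  # identical class models: uniform prior gives 1/2, empirical (1/6, 5/6)
  m$models[["1"]] <- m$models[["0"]]
  pu <- posterior(m, matrix(0.4, 1, 1), prior_mode = "uniform")
  expect_equal(unname(pu$probs[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  pe <- posterior(m, matrix(0.4, 1, 1), prior_mode = "empirical")
  expect_equal(unname(pe$probs[1, ]), c(5 / 6, 1 / 6), tolerance = 1e-12)

  # hand-built 1-D Gaussian Bayes oracle
  m$models[["0"]][[1]] <- list(mean = 0, sd = 1)
  m$models[["1"]][[1]] <- list(mean = 2, sd = 1.5)
  o <- 1.1
  f0 <- dnorm(o, 0, 1); f1 <- dnorm(o, 2, 1.5)
  pb <- posterior(m, matrix(o, 1, 1), prior_mode = "empirical")
  expect_equal(unname(pb$probs[1, "1"]),
               f1 * (1 / 6) / (f1 * (1 / 6) + f0 * (5 / 6)),
               tolerance = 1e-10)
  # rows sum to one
  pr <- posterior(m, matrix(rnorm(50), ncol = 1))
  expect_equal(unname(rowSums(pr$probs)), rep(1, 50), tolerance = 1e-9)
})

test_that("clipping raises small posteriors without renormalizing", {
  p <- structure(list(probs = matrix(c(0.0005, 0.9995, 0.5, 0.5), 2, 2,
                                     byrow = TRUE,
                                     dimnames = list(NULL, c("0", "1"))),
                      classes = 0:1, prior_mode = "uniform",
                      clipped = FALSE), class = "posterior_array")
  cl <- clip_posteriors(p, 0.001)
  expect_equal(unname(cl$probs[1, ]), c(0.001, 0.9995))
  expect_equal(unname(cl$probs[2, ]), c(0.5, 0.5))
  expect_true(cl$clipped)
  # no-op when everything is above the floor
  p2 <- p; p2$probs[] <- 0.5
  expect_equal(clip_posteriors(p2, 0.001)$probs, p2$probs)
  expect_error(clip_posteriors(p, 0.7), class = "erpleak_param_error")
})

test_that("Gaussian and KDE backends agree on large Gaussian samples", {
  set.seed(7)
  x <- matrix(rnorm(2e4), ncol = 1)
  labels <- rep(0:1, each = 1e4)
  mk <- fit_density(x, labels, backend = "kde")
  mg <- fit_density(x, labels, backend = "gaussian")
  grid <- matrix(seq(-2.5, 2.5, length.out = 200), ncol = 1)
  dk <- log2_likelihood(mk, grid)[, "0"]
  dg <- log2_likelihood(mg, grid)[, "0"]
  expect_lt(mean(abs(dk - dg)), 0.1)
})
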