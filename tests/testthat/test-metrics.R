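# Perceived information, bootstrap CIs, success rate, average rank.

# two-class 1-D Gaussian sample with exact class counts (150 real /
# 750 random per 900, the session's class balance)
gaussian_classes <- function(n = 900, mu1 = 2, sd1 = 1, seed = 1) {
  set.seed(seed)
  n1 <- round(n / 6); n0 <- n - n1
  x <- matrix(c(rnorm(n0, 0, 1), rnorm(n1, mu1, sd1)), ncol = 1)
  list(x = x, labels = rep(c(0L, 1L), c(n0, n1)))
}

test_that("PI is zero when the posterior equals the prior", {
  priors <- c("0" = 5 / 6, "1" = 1 / 6)
  h <- -sum(priors * log2(priors))
  lt <- log2(priors[rep(c("0", "1"), c(20, 4))])
  expect_equal(erpleak:::pi_functional(lt, rep(c("0", "1"), c(20, 4)),
                                       priors, h), 0, tolerance = 1e-12)
})

test_that("perfect separation drives PI to the prior entropy", {
  g <- gaussian_classes(n = 600, mu1 = 50, seed = 2)
  res <- estimate_pi(g$x, g$labels, backend = "gaussian", seed = 3)
  h_expected <- -(1 / 6) * log2(1 / 6) - (5 / 6) * log2(5 / 6)  # ~0.650
  expect_equal(res$h_prior, h_expected, tolerance = 1e-12)
  expect_equal(res$pi, res$h_prior, tolerance = 0.01)
  expect_lte(res$pi, res$h_prior)
})

test_that("PI never exceeds the prior entropy", {
  for (seed in 1:4) {
    set.seed(seed)
    x <- matrix(rnorm(120), ncol = 1)   # no class structure
    labels <- rep(c(0L, 1L), c(100, 20))
    res <- estimate_pi(x, labels, k = 10, seed = seed)
    expect_lte(res$pi, res$h_prior)
  }
})

test_that("leave-one-out KDE recovers the mutual information oracle", {
  # single-seed version of the design-level check: 1-D Gaussians at
  # means 0 and 2, priors (1/6, 5/6); MI by numeric quadrature
  mi_oracle <- function(mu1, p1) {
    f <- function(o) {
      f0 <- dnorm(o); f1 <- dnorm(o, mu1)
      mix <- (1 - p1) * f0 + p1 * f1
      t0 <- (1 - p1) * f0 * log2(pmax(f0 / mix, 1e-300))
      t1 <- p1 * f1 * log2(pmax(f1 / mix, 1e-300))
      t0 + t1
    }
    integrate(f, -8, 10, rel.tol = 1e-9)$value
  }
  mi <- mi_oracle(2, 1 / 6)
  g <- gaussian_classes(seed = 5)
  res <- estimate_pi(g$x, g$labels, backend = "kde",
                     prior_mode = "empirical", seed = 6)
  expect_equal(res$pi, mi, tolerance = 0.05)
  expect_lte(res$pi, mi + 0.05)   # model error only degrades PI
})

test_that("fold construction is stratified and validated", {
  labels <- rep(c(0L, 1L), c(40, 10))
  f <- cv_folds(labels, k = 5, seed = 1)
  for (j in 1:5) {
    expect_equal(sum(labels[f == j] == 1), 2)
    expect_equal(sum(labels[f == j] == 0), 8)
  }
  expect_equal(cv_folds(labels), seq_len(50))   # LOO is the identity
  expect_error(cv_folds(labels, k = 1), class = "erpleak_param_error")
  # a profiling set missing one class is rejected
  x <- matrix(rnorm(6), ncol = 1)
  expect_error(estimate_pi(x, c(1L, 1L, 0L, 0L, 0L, 0L), k = 3, seed = 2),
               class = "erpleak_fold_error")
})

test_that("bootstrap CI collapses on constant terms and brackets the point", {
  lt <- rep(-0.5, 30)
  ci <- bootstrap_ci(lt, seed = 1)
  expect_equal(unname(ci), c(-0.5, -0.5))
  # on Gaussian terms the 5th/95th percentile interval brackets the
  # point estimate in nearly all seeded runs
  set.seed(2)
  lt <- rnorm(200, -1, 0.3)
  point <- mean(lt)
  hits <- vapply(1:40, function(s) {
    ci <- bootstrap_ci(lt, seed = s)
    ci[1] <= point && point <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(bootstrap_ci(numeric(1)), class = "erpleak_param_error")
})

test_that("permuted labels yield a null PI", {
  # scores with genuine structure, labels destroyed by permutation
  hits <- vapply(1:10, function(seed) {
    g <- gaussian_classes(n = 300, mu1 = 1.5, seed = 100 + seed)
    set.seed(seed)
    perm <- sample(g$labels)
    res <- estimate_pi(g$x, perm, k = 20, seed = seed)
    res$pi <= 0 || (res$ci_low <= 0 && res$ci_high >= 0)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

# helper: posterior_array with given probabilities for class "1"
fake_post <- function(p1) {
  structure(list(probs = cbind("0" = 1 - p1, "1" = p1), classes = 0:1,
                 prior_mode = "uniform", clipped = FALSE),
            class = "posterior_array")
}

test_that("success rate is 1 under perfect separation and 1/2 when blind", {
  tags <- rep(1:6, each = 40)
  p1 <- ifelse(tags == 1, 0.99, 0.01)
  sr <- success_rate(fake_post(p1), tags, q = c(1, 3), R = 50, seed = 1)
  expect_true(all(sr == 1))

  set.seed(3)
  p_blind <- plogis(rnorm(240))        # symmetric, uninformative
  sr_b <- success_rate(fake_post(p_blind), tags, q = 1, R = 1000, seed = 2)
  # Bernoulli(0.5) oracle: each tag's rate estimates the fraction of its
  # 40-observation pool with positive margin, Binomial(40, 1/2)/40
  expect_true(all(abs(sr_b - 0.5) < 3 * sqrt(0.25 / 40) + 0.05))
  expect_lt(abs(mean(sr_b) - 0.5), 3 * sqrt(0.25 / 240))
})

test_that("two-observation success products follow the hand computation", {
  # tag-1 pool of two observations with posteriors 0.9 and 0.6 for the
  # real class: 0.9*0.6 = 0.54 > 0.1*0.4 = 0.04, so q = 2 always succeeds
  tags <- c(1L, 1L, rep(2:6, each = 2))
  p1 <- c(0.9, 0.6, rep(0.5, 10))
  sr <- success_rate(fake_post(p1), tags, q = 2, R = 20, seed = 1)
  expect_equal(unname(sr["tag1", 1]), 1)
  expect_error(success_rate(fake_post(p1), tags, q = 3, R = 10, seed = 1),
               class = "erpleak_param_error")
})

test_that("average rank spans chance (3.5) to perfect (1)", {
  tags <- rep(1:6, each = 40)
  set.seed(4)
  p_blind <- plogis(rnorm(240))
  r_blind <- average_rank(fake_post(p_blind), tags, q = 1, R = 2000, seed = 5)
  expect_equal(unname(r_blind), 3.5, tolerance = 0.35)
  p_perfect <- ifelse(tags == 1, 0.99, 0.01)
  r_perfect <- average_rank(fake_post(p_perfect), tags, q = c(1, 5),
                            R = 100, seed = 6)
  expect_true(all(r_perfect == 1))
})

test_that("success rate is non-decreasing in q up to resampling noise", {
  g <- gaussian_classes(n = 360, mu1 = 1, seed = 7)
  # map the binary sample onto 6 tags (tag 1 = class 1)
  tags <- ifelse(g$labels == 1, 1L, 0L)
  tags[tags == 0] <- rep_len(2:6, sum(g$labels == 0))
  res <- estimate_pi(g$x, g$labels, backend = "gaussian", seed = 8)
  post <- fake_post(erpleak::posterior_from_loglik(res$loglik)[, "1"])
  sr <- success_rate(post, tags, q = c(1, 2, 4, 8, 16), R = 2000, seed = 9)
  # the tag-averaged success rate grows with q; individual tags whose
  # finite pool happens to have a negative mean margin may decline
  expect_true(all(diff(colMeans(sr)) >= -0.02))
})
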