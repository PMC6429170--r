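# Attack scenario drivers at reduced session geometry (fs 250 Hz).

# cohort of preprocessed observation sets, sessions freed as we go
cohort_obs <- function(n_users, seed, spread = 1, reps = 25,
                       noise_sd = 10, amplitude = 4) {
  coh <- simulate_cohort(n_users, seed = seed, spread = spread,
                         config = tiny_config(1, reps),
                         amplitude = amplitude, noise_sd = noise_sd)
  lapply(coh, function(u) select_concat(bandpass(u$session)))
}

test_that("profiled attack separates an informative user from a null one", {
  s <- tiny_session(1, 2, amplitude = 8, reps = 40)
  res <- profiled_attack(s, q = c(1, 5, 10), R = 200, seed = 3)
  expect_gt(res$pi$pi, 0)
  expect_gt(res$pi$ci_low, 0)
  expect_lt(res$rank[length(res$rank)], 1.2)

  s0 <- tiny_session(4, 5, amplitude = 0, reps = 40)
  res0 <- profiled_attack(s0, q = 1, R = 50, seed = 6)
  expect_lte(res0$pi$ci_low, 0)
  expect_gte(res0$pi$ci_high, res0$pi$pi)
  expect_lt(res0$pi$pi, 0.05)
})

test_that("average PCA extracts more information than raw PCA at full
           profiling sets", {
  # matched sessions, both variants on the same observations: the
  # tag-mean-based reduction targets the discriminant directions and
  # dominates once its means are well estimated
  diffs <- vapply(1:3, function(seed) {
    o <- tiny_obs(seed, 10 + seed, amplitude = 6, reps = 50)
    labels <- as.integer(o$tags == 1L)
    pa <- estimate_pi(NULL, labels, seed = 20 + seed, obs = o,
                      basis_spec = list(variant = "average", n_d = 5))
    pr <- estimate_pi(NULL, labels, clip_floor = 0.001, seed = 20 + seed,
                      obs = o, basis_spec = list(variant = "raw", n_d = 5))
    pa$pi - pr$pi
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("raw PCA pipeline clips posteriors, average does not", {
  s <- tiny_session(1, 2, amplitude = 6, reps = 25)
  ra <- profiled_attack(s, variant = "average", q = 1, R = 10, seed = 3)
  rr <- profiled_attack(s, variant = "raw", q = 1, R = 10, seed = 3)
  expect_false(ra$pi$clipped)
  expect_true(rr$pi$clipped)
  expect_gte(min(rr$pi$posteriors), 0.001)
})

test_that("non-profiled sweep returns one PI per assumed tag", {
  o <- tiny_obs(1, 2, amplitude = 6, reps = 25)
  np <- nonprofiled_attack(o, seed = 3)
  tab <- np$parts[[1]]$table
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$ci_low <= tab$pi & tab$pi <= tab$ci_high))
  expect_true(np$parts[[1]]$winner %in% 1:6)
  # split evaluation partitions without resampling
  np2 <- nonprofiled_attack(o, splits = 2, seed = 4)
  expect_length(np2$parts, 2)
  ns <- vapply(np2$parts, function(p) p$fits[[1]]$n, numeric(1))
  expect_equal(sum(ns), nrow(o$vectors))
  expect_error(nonprofiled_attack(o, q = 10), class = "erpleak_param_error")
})

test_that("assuming the true tag reproduces the profiled estimate", {
  o <- tiny_obs(1, 5, amplitude = 6, reps = 20)
  seed <- 9
  np <- nonprofiled_attack(o, seed = seed)
  prof <- estimate_pi(NULL, as.integer(o$tags == 1L),
                      seed = derive_seed(seed, 41L), obs = o,
                      basis_spec = list(variant = "average", n_d = 5))
  expect_equal(np$parts[[1]]$fits[[1]]$pi, prof$pi, tolerance = 1e-12)
  expect_equal(np$parts[[1]]$fits[[1]]$ci_low, prof$ci_low,
               tolerance = 1e-12)
})

test_that("self-portability equals the profiled leave-one-out estimate", {
  o <- tiny_obs(2, 3, amplitude = 6, reps = 20)
  self <- portability_attack(o, o, cv = TRUE, seed = 11)
  prof <- estimate_pi(NULL, as.integer(o$tags == 1L), seed = 11, obs = o,
                      basis_spec = list(variant = "average", n_d = 5))
  expect_equal(self$pi, prof$pi, tolerance = 1e-12)
  expect_equal(self$log_terms, prof$log_terms, tolerance = 1e-12)
})

test_that("shared-profile cohorts port, dissimilar profiles fail", {
  obs0 <- cohort_obs(2, seed = 5, spread = 0, reps = 40, amplitude = 8)
  cross <- portability_attack(obs0[[1]], obs0[[2]], seed = 6)
  expect_gt(cross$pi, 0)

  oa <- tiny_obs(11, 12, amplitude = 6, reps = 25, latency = 250, width = 40)
  ob <- tiny_obs(22, 23, amplitude = 6, reps = 25, latency = 600, width = 80)
  far <- portability_attack(oa, ob, seed = 7)
  expect_lte(far$pi, 0)

  ob$vectors <- ob$vectors[, 1:100]
  expect_error(portability_attack(oa, ob, seed = 8),
               class = "erpleak_dim_error")
})

test_that("portability never beats self-profiling on average", {
  deltas <- vapply(1:6, function(seed) {
    obs <- cohort_obs(2, seed = 30 + seed, spread = 1, reps = 20,
                      amplitude = 5)
    self <- portability_attack(obs[[1]], obs[[1]], cv = TRUE,
                               seed = 50 + seed)
    cross <- portability_attack(obs[[2]], obs[[1]], seed = 50 + seed)
    self$pi - cross$pi
  }, numeric(1))
  expect_gt(mean(deltas), -0.01)
})

test_that("all-against-one pools the other users", {
  obs0 <- cohort_obs(3, seed = 40, spread = 0, reps = 40, amplitude = 8)
  for (target in 1:3) {
    res <- all_against_one(obs0, target, seed = 41)
    expect_gt(res$pi, 0)
  }
  # with a single non-target user the pooled attack is plain portability
  two <- obs0[1:2]
  aao <- all_against_one(c(two, obs0[3]), 3, seed = 42)
  expect_error(all_against_one(two, 2, seed = 43),
               class = "erpleak_param_error")
})

test_that("user identification separates users and nulls identical ones", {
  # strongly separated users (low noise): PI approaches H[U]
  obs <- cohort_obs(3, seed = 12, spread = 1, reps = 25, noise_sd = 1)
  id <- identify_user(obs, k = 10, seed = 13)
  expect_equal(id$overall$h_prior, log2(3), tolerance = 1e-12)
  expect_gt(id$overall$pi, 0.8 * log2(3))
  expect_true(all(id$partial > 0))
  # posteriors over users sum to one per epoch
  expect_equal(unname(rowSums(id$overall$posteriors)),
               rep(1, nrow(id$overall$posteriors)), tolerance = 1e-9)
  expect_equal(sum(id$confusion), id$overall$n)

  # two identical users carry no identity information
  obs0 <- cohort_obs(2, seed = 10, spread = 0, reps = 25, amplitude = 4)
  id0 <- identify_user(obs0, k = 10, seed = 11)
  expect_true(all(id0$partial <= 0))

  expect_error(identify_user(obs[1], seed = 1),
               class = "erpleak_param_error")
})

test_that("identification is more informative than PIN recovery on a
           full-scale cohort", {
  coh <- simulate_cohort(4, seed = 8, spread = 1,
                         config = session_config(blink_rate = 0),
                         noise_sd = 8)
  obs <- vector("list", 4)
  pin <- numeric(4)
  for (u in 1:4) {
    obs[[u]] <- select_concat(bandpass(coh[[u]]$session))
    coh[[u]]$session <- NULL
    pin[u] <- estimate_pi(NULL, as.integer(obs[[u]]$tags == 1L),
                          seed = 10, obs = obs[[u]],
                          basis_spec = list(variant = "average",
                                            n_d = 5))$pi
  }
  id <- identify_user(obs, k = 10, seed = 9)
  expect_gt(id$overall$pi, 0)
  expect_gt(id$overall$pi, mean(pin))
  expect_gt(id$overall$pi, max(pin))
})
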