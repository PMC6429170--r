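# Evaluation metrics: cross-validated perceived information (PI) with
# bootstrap confidence intervals, per-tag success rate, average rank.
#
# PI(P;O) = H[P] + sum_p Pr[p] * E_{o|p} log2 Pr_model[p|o]. With a
# perfect model this equals the mutual information; with an imperfect
# model it is what the model actually extracts (negative when the model
# misleads). The estimator is cross-validated: the model is fitted on
# each profiling set and the log2 posterior of the true class evaluated
# on the held-out observations.

#' Cross-validation fold assignment
#'
#' Default `k = n` is leave-one-out (deterministic). For `k < n` folds
#' are stratified by class so every profiling set contains all classes.
#'
#' @param labels Per-observation class labels.
#' @param k Number of folds (default `length(labels)`, i.e. LOO).
#' @param seed Seed for the stratified shuffle (ignored for LOO).
#' @return Integer fold id per observation.
#' @export
cv_folds <- function(labels, k = length(labels), seed = 1L) {
  n <- length(labels)
  if (k < 2 || k > n) err("need 2 <= k <= n folds", "erpleak_param_error")
  if (k == n) return(seq_len(n))
  fold <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  fold
}

# PI functional: class-weighted mean of per-observation log2 posteriors
pi_functional <- function(log_terms, term_class, priors, h_prior) {
  cls <- names(priors)
  h_prior + sum(vapply(cls, function(cl) {
    priors[[cl]] * mean(log_terms[term_class == cl])
  }, numeric(1)))
}

#' Percentile bootstrap confidence interval for the PI estimate
#'
#' Resamples the per-observation log2 posterior terms with replacement
#' within each class (preserving the class weighting), recomputes the PI
#' functional for each of `B` resamples, and returns the requested
#' percentiles of the `B` values.
#'
#' @param log_terms Per-observation log2 posterior of the true class.
#' @param term_class Class label of each term (`NULL`: one class).
#' @param priors Named class priors used in the PI weighting (`NULL`:
#'   single class, weight 1).
#' @param h_prior Prior entropy H in bits added to the weighted mean.
#' @param B Number of bootstrap resamples (default 100).
#' @param percentiles Lower/upper percentile endpoints (default 5 and 95,
#'   a 10 percent interval).
#' @param seed Seed for the resampling.
#' @return Named vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(log_terms, term_class = NULL, priors = NULL,
                         h_prior = 0, B = 100L, percentiles = c(5, 95),
                         seed = 1L) {
  if (length(log_terms) < 2)
    err("need at least 2 log terms", "erpleak_param_error")
  if (is.null(term_class)) term_class <- rep("all", length(log_terms))
  if (is.null(priors)) priors <- c(all = 1)
  term_class <- as.character(term_class)
  stats <- with_seed(seed, {
    idx_by_class <- split(seq_along(log_terms), term_class)
    vapply(seq_len(B), function(b) {
      res_class <- character(0); res_terms <- numeric(0)
      for (cl in names(idx_by_class)) {
        ix <- idx_by_class[[cl]]
        take <- ix[sample.int(length(ix), length(ix), replace = TRUE)]
        res_terms <- c(res_terms, log_terms[take])
        res_class <- c(res_class, rep(cl, length(take)))
      }
      pi_functional(res_terms, res_class, priors, h_prior)
    }, numeric(1))
  })
  q <- stats::quantile(stats, percentiles / 100, type = 7, names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' Cross-validated perceived information
#'
#' For each fold, fits the class-conditional densities on the profiling
#' set and evaluates the log2 posterior of the true class on the held-out
#' observations; all per-observation log terms are then aggregated and
#' weighted once by the empirical class priors (for equal-size folds this
#' equals fold-wise averaging, and it stays well defined for
#' leave-one-out's single-observation test sets).
#'
#' @param reduced A `reduced_obs` or scores matrix.
#' @param labels Per-observation class labels.
#' @param k Folds (default LOO).
#' @param backend Density backend, `"kde"` or `"gaussian"`.
#' @param prior_mode Bayes-inversion prior inside the log:
#'   `"empirical"` (the default; the Bayes formula with the class
#'   frequencies, under which PI equals the mutual information for a
#'   perfect model and 0 for an uninformative one) or `"uniform"`
#'   (maximum-likelihood posteriors).
#' @param clip_floor Posterior clipping floor (e.g. 0.001 for raw-PCA
#'   pipelines) or `NULL` for no clipping.
#' @param B,percentiles Bootstrap CI parameters, see [bootstrap_ci()].
#' @param seed Seed for fold assignment and bootstrap.
#' @param obs Optionally the unreduced `observation_set`; with
#'   `basis_spec` this moves the dimensionality reduction inside the
#'   cross-validation. The `"average"` variant's per-tag means are
#'   label-adjacent (the binary classes derive from tags), so a basis
#'   computed from the full set leaks held-out information into the
#'   reduction and biases null PIs upward; with `obs` given the basis is
#'   recomputed from each fold's profiling epochs (incremental tag sums
#'   keep leave-one-out cheap). The `"raw"` variant uses no labels and
#'   is computed once from all epochs.
#' @param basis_spec `list(variant = "average"|"raw", n_d = <int>)`;
#'   only used together with `obs`.
#' @return Object of class `pi_result`: `pi` (bits), `h_prior`, `ci_low`,
#'   `ci_high`, per-observation `log_terms` and `term_class`, `priors`.
#' @export
estimate_pi <- function(reduced, labels, k = NULL,
                        backend = c("kde", "gaussian"),
                        prior_mode = c("empirical", "uniform"),
                        clip_floor = NULL, B = 100L, percentiles = c(5, 95),
                        seed = 1L, obs = NULL, basis_spec = NULL) {
  backend <- match.arg(backend)
  prior_mode <- match.arg(prior_mode)
  in_fold_basis <- FALSE
  if (!is.null(obs)) {
    stopifnot(inherits(obs, "observation_set"), is.list(basis_spec))
    if (basis_spec$variant == "raw") {
      x <- project_obs(obs, raw_pca(obs, n_d = basis_spec$n_d))$scores
    } else {
      in_fold_basis <- TRUE
      x <- obs$vectors                  # reduced per fold below
    }
  } else {
    x <- if (inherits(reduced, "reduced_obs")) reduced$scores
         else as.matrix(reduced)
  }
  labels <- as.character(labels)
  n <- nrow(x)
  if (is.null(k)) k <- n
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  priors <- counts / n
  names(priors) <- classes
  h_prior <- entropy_bits(priors)

  if (in_fold_basis) {
    tags <- obs$tags
    tag_set <- sort(unique(tags))
    n_tags <- length(tag_set)
    tag_sums <- t(vapply(tag_set, function(tg)
      colSums(x[tags == tg, , drop = FALSE]), numeric(ncol(x))))
    tag_counts <- vapply(tag_set, function(tg) sum(tags == tg), numeric(1))
    n_d <- basis_spec$n_d
    if (n_d > n_tags - 1)
      err(sprintf("n_d must be <= n_tags - 1 = %d", n_tags - 1),
          "erpleak_rank_error")
    # Every fold's basis lies in span{tag sums, held-out rows}, so the
    # per-fold PCA and all projections reduce to precomputed inner
    # products: G1 = X S', SS' (6 x 6) and the observation Gram matrix.
    gram_xs <- x %*% t(tag_sums)          # n x n_tags
    gram_ss <- tag_sums %*% t(tag_sums)   # n_tags x n_tags
    gram_xx <- tcrossprod(x)              # n x n
  }

  fold <- cv_folds(labels, k, seed = derive_seed(seed, 11L))
  log_terms <- numeric(n)
  loglik <- matrix(NA_real_, n, length(classes),
                   dimnames = list(NULL, classes))
  posteriors <- matrix(NA_real_, n, length(classes),
                       dimnames = list(NULL, classes))
  for (j in sort(unique(fold))) {
    test <- which(fold == j)
    train <- which(fold != j)
    tr_lab <- labels[train]
    tr_counts <- vapply(classes, function(cl) sum(tr_lab == cl), integer(1))
    if (any(tr_counts < 2))
      err(sprintf("fold %d has a profiling set missing a class (or with fewer than 2 samples of it)", j),
          "erpleak_fold_error")
    if (in_fold_basis) {
      m <- length(test)
      cnt <- tag_counts
      # profiling-set tag means, expressed in the coefficient space of
      # the spanning set {tag sums, held-out rows}
      c_raw <- matrix(0, n_tags, n_tags + m)
      for (ti in seq_len(n_tags)) c_raw[ti, ti] <- 1
      for (r in seq_len(m)) {
        ti <- match(tags[test[r]], tag_set)
        c_raw[ti, n_tags + r] <- -1
        cnt[ti] <- cnt[ti] - 1
      }
      if (any(cnt < 1))
        err("a fold's profiling set has an empty tag class",
            "erpleak_empty_class_error")
      c_raw <- c_raw / cnt
      c_center <- colMeans(c_raw)
      cc <- sweep(c_raw, 2, c_center)
      gam <- rbind(cbind(gram_ss, t(gram_xs[test, , drop = FALSE])),
                   cbind(gram_xs[test, , drop = FALSE],
                         gram_xx[test, test, drop = FALSE]))
      mc <- cc %*% gam %*% t(cc)          # Gram of the centered means
      eg <- eigen((mc + t(mc)) / 2, symmetric = TRUE)
      if (eg$values[n_d] <= max(eg$values) * 1e-10)
        err("fold tag means have insufficient rank for n_d components",
            "erpleak_rank_error")
      # principal directions in coefficient space: Cc' u / sigma
      w <- t(cc) %*% eg$vectors[, seq_len(n_d), drop = FALSE]
      w <- sweep(w, 2, sqrt(eg$values[seq_len(n_d)]), "/")
      # scores = (x_j - center) . v_k via precomputed inner products
      xb <- cbind(gram_xs, gram_xx[, test, drop = FALSE])   # n x (t+m)
      scores_all <- xb %*% w
      center_scores <- as.numeric((c_center %*% gam) %*% w)
      scores_all <- sweep(scores_all, 2, center_scores)
      xtr <- scores_all[train, , drop = FALSE]
      xte <- scores_all[test, , drop = FALSE]
    } else {
      xtr <- x[train, , drop = FALSE]
      xte <- x[test, , drop = FALSE]
    }
    model <- fit_density(xtr, tr_lab, backend = backend)
    ll <- log2_likelihood(model, xte)
    probs <- posterior_from_loglik(ll, model$priors, prior_mode)
    if (!is.null(clip_floor)) probs <- pmax(probs, clip_floor)
    true_col <- match(labels[test], names(model$priors))
    log_terms[test] <- log2(probs[cbind(seq_along(test), true_col)])
    loglik[test, ] <- ll
    posteriors[test, ] <- probs
  }

  pi <- pi_functional(log_terms, labels, priors, h_prior)
  ci <- bootstrap_ci(log_terms, labels, priors, h_prior, B = B,
                     percentiles = percentiles,
                     seed = derive_seed(seed, 12L))
  structure(list(
    pi = pi, h_prior = h_prior, ci_low = unname(ci[1]),
    ci_high = unname(ci[2]), log_terms = log_terms, term_class = labels,
    posteriors = posteriors, loglik = loglik, priors = priors, k = k, n = n,
    backend = backend, prior_mode = prior_mode,
    clipped = !is.null(clip_floor)
  ), class = "pi_result")
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf(
    "<pi_result> PI = %.4f bits (H = %.4f), 90%% bootstrap CI [%.4f, %.4f], n = %d, k = %d\n",
    x$pi, x$h_prior, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

# shared input handling for the two security metrics
.check_attack_inputs <- function(post, tags, q) {
  stopifnot(inherits(post, "posterior_array"))
  if (nrow(post$probs) != length(tags))
    err("posterior rows must match tags", "erpleak_dim_error")
  pool_sizes <- tabulate(tags)
  if (max(q) > min(pool_sizes[pool_sizes > 0]))
    err(sprintf("q = %d exceeds the smallest tag group (%d observations)",
                max(q), min(pool_sizes[pool_sizes > 0])),
        "erpleak_param_error")
}

#' Per-tag success rate of the real-versus-random classification
#'
#' For each tag and each number of exploited observations `q`, draws `q`
#' observations of that tag without replacement, declares success when
#' the product of the model posteriors for the tag's true class (real for
#' tag 1, random otherwise) exceeds the product for the opposite class,
#' and averages over `R` resampled draws.
#'
#' @param post A binary `posterior_array` (classes `0` = random, `1` =
#'   real) for the test observations, e.g. the cross-validated posteriors
#'   of a profiled attack.
#' @param tags Per-observation tag (1 = real PIN).
#' @param q Vector of observation counts to evaluate.
#' @param R Resampled draws per (tag, q) (default 1000).
#' @param seed Seed for the resampling.
#' @return Matrix `n_tags x length(q)` of success rates in `[0, 1]`.
#' @export
success_rate <- function(post, tags, q = 1:10, R = 1000L, seed = 1L) {
  .check_attack_inputs(post, tags, q)
  lp <- log2(post$probs)
  n_tags <- max(tags)
  out <- matrix(NA_real_, n_tags, length(q),
                dimnames = list(paste0("tag", seq_len(n_tags)),
                                paste0("q", q)))
  with_seed(seed, {
    for (tg in seq_len(n_tags)) {
      pool <- which(tags == tg)
      true_cl <- if (tg == 1L) "1" else "0"
      other_cl <- if (tg == 1L) "0" else "1"
      # per-observation log likelihood-ratio margin for the true class
      margin <- lp[pool, true_cl] - lp[pool, other_cl]
      for (iq in seq_along(q)) {
        wins <- vapply(seq_len(R), function(r)
          sum(margin[sample.int(length(pool), q[iq])]) > 0, logical(1))
        out[tg, iq] <- mean(wins)
      }
    }
  })
  out
}

#' Average rank of the real PIN
#'
#' For each draw, takes `q` observations from every tag, scores each tag
#' by the product over its observations of the posterior of the real-PIN
#' class only, sorts the six products decreasingly, and records the
#' position of tag 1 (ties get the average rank). Averages over `R`
#' draws. 1 means the real PIN always wins; `(n_tags + 1) / 2` is chance.
#'
#' @inheritParams success_rate
#' @return Named numeric vector, mean rank per `q`.
#' @export
average_rank <- function(post, tags, q = 1:10, R = 1000L, seed = 1L) {
  .check_attack_inputs(post, tags, q)
  lp1 <- log2(post$probs[, "1"])
  n_tags <- max(tags)
  pools <- lapply(seq_len(n_tags), function(tg) which(tags == tg))
  out <- stats::setNames(numeric(length(q)), paste0("q", q))
  with_seed(seed, {
    for (iq in seq_along(q)) {
      ranks <- vapply(seq_len(R), function(r) {
        scores <- vapply(pools, function(pool)
          sum(lp1[pool[sample.int(length(pool), q[iq])]]), numeric(1))
        rank(-scores, ties.method = "average")[1]
      }, numeric(1))
      out[iq] <- mean(ranks)
    }
  })
  out
}
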