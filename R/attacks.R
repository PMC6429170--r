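# Orchestrated attack scenarios: profiled (supervised), non-profiled
# (6-way on-the-fly PI), cross-user model portability, "all against one"
# profiling, and user identification.

# basis per variant; dimensionality reduction uses only public tags
.make_basis <- function(obs, variant, n_d) {
  if (variant == "average") average_pca(tag_means(obs), n_d = n_d)
  else raw_pca(obs, n_d = n_d)
}

# posterior clipping (outlier treatment) is needed only for raw PCA
.clip_floor_for <- function(basis, clip_floor) {
  src <- if (is.character(basis)) basis else basis$source
  if (is.null(clip_floor)) return(NULL)
  if (identical(clip_floor, "auto")) {
    if (src == "raw") 0.001 else NULL
  } else clip_floor
}

#' Profiled (supervised) PIN-recovery evaluation
#'
#' Full pipeline on one session: bandpass, EOG artifact rejection,
#' electrode selection, PCA (average or raw variant), leave-one-out
#' cross-validated perceived information, and the security metrics
#' (per-tag success rate, average rank) computed from the cross-validated
#' posteriors. Optionally a PI-versus-profiling-set-size learning curve.
#'
#' @param session An `epoch_set`.
#' @param channels Electrodes to concatenate (default P7, P8).
#' @param variant `"average"` or `"raw"` PCA.
#' @param n_d Number of PCA dimensions (default 5).
#' @param backend Density backend, `"kde"` or `"gaussian"`.
#' @param prior_mode Bayes-inversion prior inside the PI log (default
#'   `"empirical"`, the Bayes formula). The security metrics always
#'   classify with maximum-likelihood (uniform-prior) posteriors, which
#'   avoids the a-priori bias toward the majority random-PIN class.
#' @param lo,hi Bandpass cutoffs, Hz.
#' @param reject_threshold EOG peak-to-peak rejection threshold, microvolt.
#' @param clip_floor `"auto"` (0.001 for raw PCA, none for average),
#'   a number, or `NULL`.
#' @param q Observation counts for the security metrics.
#' @param R Resampled draws per (tag, q).
#' @param B Bootstrap resamples for the PI confidence interval.
#' @param learning_sizes Profiling-set sizes for the learning curve, or
#'   `NULL` to skip it.
#' @param seed Seed for all stochastic stages.
#' @return Object of class `attack_result`: `pi` (a `pi_result`),
#'   `success` (tags x q matrix), `rank` (per q), `learning`
#'   (data.frame or NULL), `rejected`, `basis`.
#' @export
profiled_attack <- function(session, channels = c("P7", "P8"),
                            variant = c("average", "raw"), n_d = 5L,
                            backend = c("kde", "gaussian"),
                            prior_mode = c("empirical", "uniform"),
                            lo = 0.5, hi = 30, reject_threshold = 100,
                            clip_floor = "auto",
                            q = c(1, 2, 5, 10, 20, 40), R = 1000L,
                            B = 100L, learning_sizes = NULL, seed = 1L) {
  variant <- match.arg(variant)
  backend <- match.arg(backend)
  prior_mode <- match.arg(prior_mode)
  stopifnot(inherits(session, "epoch_set"))
  if (length(unique(session$tags)) < 2)
    err("session must contain at least two tags", "erpleak_param_error")

  filt <- bandpass(session, lo = lo, hi = hi)
  rej <- reject_artifacts(filt, threshold = reject_threshold)
  obs <- select_concat(rej$epochs, channels = channels)
  basis <- .make_basis(obs, variant, n_d)   # full-set basis, for reporting
  labels <- as.integer(obs$tags == 1L)
  floor_val <- .clip_floor_for(basis, clip_floor)

  pi_res <- estimate_pi(NULL, labels, backend = backend,
                        prior_mode = prior_mode, clip_floor = floor_val,
                        B = B, seed = derive_seed(seed, 21L),
                        obs = obs,
                        basis_spec = list(variant = variant, n_d = n_d))
  # maximum-likelihood posteriors for the attack decision metrics
  ml_probs <- posterior_from_loglik(pi_res$loglik, prior_mode = "uniform")
  if (!is.null(floor_val)) ml_probs <- pmax(ml_probs, floor_val)
  post <- structure(list(probs = ml_probs,
                         classes = colnames(ml_probs),
                         prior_mode = "uniform",
                         clipped = !is.null(floor_val)),
                    class = "posterior_array")
  q <- q[q <= min(tabulate(obs$tags))]
  succ <- success_rate(post, obs$tags, q = q, R = R,
                       seed = derive_seed(seed, 22L))
  rnk <- average_rank(post, obs$tags, q = q, R = R,
                      seed = derive_seed(seed, 23L))

  learning <- NULL
  if (!is.null(learning_sizes))
    learning <- pi_learning_curve(obs, labels, sizes = learning_sizes,
                                  variant = variant, n_d = n_d,
                                  backend = backend,
                                  prior_mode = prior_mode,
                                  clip_floor = floor_val,
                                  seed = derive_seed(seed, 24L))

  structure(list(pi = pi_res, success = succ, rank = rnk, q = q,
                 learning = learning, rejected = rej$rejected_ids,
                 basis = basis, variant = variant, backend = backend),
            class = "attack_result")
}

#' PI versus profiling-set size (model-convergence curve)
#'
#' For each size m, draws a stratified random profiling subset of m
#' observations, builds the whole model from it (PCA basis and
#' densities), and evaluates the PI on the held-out remainder — the
#' offline profiling complexity of the attack.
#'
#' @param obs An `observation_set`.
#' @param labels Binary (or multiclass) labels aligned with `obs`.
#' @param sizes Profiling-set sizes.
#' @param variant,n_d PCA variant and dimensionality.
#' @param backend,prior_mode,clip_floor As in [estimate_pi()].
#' @param seed Seed for the subset draws.
#' @return data.frame with columns `size` and `pi`.
#' @export
pi_learning_curve <- function(obs, labels, sizes, variant = "average",
                              n_d = 5L, backend = "kde",
                              prior_mode = "empirical",
                              clip_floor = NULL, seed = 1L) {
  stopifnot(inherits(obs, "observation_set"))
  x <- obs$vectors
  labels <- as.character(labels)
  n <- nrow(x)
  classes <- sort(unique(labels))
  pis <- with_seed(seed, vapply(sizes, function(m) {
    if (m >= n - 1) m <- n - 2
    # stratified draw, proportional to class frequencies
    take <- unlist(lapply(classes, function(cl) {
      ix <- which(labels == cl)
      sample(ix, max(2L, round(m * length(ix) / n)))
    }))
    rest <- setdiff(seq_len(n), take)
    sub <- obs
    sub$vectors <- x[take, , drop = FALSE]
    sub$tags <- obs$tags[take]
    basis <- .make_basis(sub, variant, n_d)
    str <- sweep(x[take, , drop = FALSE], 2, basis$center) %*%
      t(basis$components)
    ste <- sweep(x[rest, , drop = FALSE], 2, basis$center) %*%
      t(basis$components)
    model <- fit_density(str, labels[take], backend = backend)
    post <- posterior(model, ste, prior_mode = prior_mode)
    if (!is.null(clip_floor)) post <- clip_posteriors(post, clip_floor)
    tc <- match(labels[rest], names(model$priors))
    lt <- log2(post$probs[cbind(seq_along(rest), tc)])
    pr <- table(labels[rest]) / length(rest)
    pr <- stats::setNames(as.numeric(pr), names(pr))
    pi_functional(lt, labels[rest], pr, entropy_bits(pr))
  }, numeric(1)))
  data.frame(size = sizes, pi = pis)
}

#' Non-profiled (unsupervised) 6-way PI attack
#'
#' Computes the PI independently for each assumed tag: the observations
#' are relabelled with `p = 1` for the assumed tag, the class densities
#' are estimated on the fly by leave-one-out cross-validation, and the
#' assumed tag attaining the maximum PI wins. If the traces of the truly
#' familiar code stand out, that tag's PI dominates.
#'
#' @param obs An `observation_set` (already filtered/rejected).
#' @param q Number of attack observations (`NULL`: all; otherwise a
#'   stratified random subset of size ~q).
#' @param splits Partition the set into this many independent parts
#'   (without resampling) and analyze each part separately.
#' @param variant,n_d,backend,prior_mode,clip_floor,B As in
#'   [profiled_attack()].
#' @param seed Seed.
#' @return Object of class `nonprofiled_result`: `parts`, a list; each
#'   part has `table` (data.frame: tag, pi, ci_low, ci_high), `winner`,
#'   and the per-tag `pi_result`s.
#' @export
nonprofiled_attack <- function(obs, q = NULL, splits = 1L,
                               variant = c("average", "raw"), n_d = 5L,
                               backend = c("kde", "gaussian"),
                               prior_mode = c("empirical", "uniform"),
                               clip_floor = "auto", B = 100L, seed = 1L) {
  variant <- match.arg(variant)
  backend <- match.arg(backend)
  prior_mode <- match.arg(prior_mode)
  stopifnot(inherits(obs, "observation_set"))
  n <- nrow(obs$vectors)
  n_tags <- max(obs$tags)

  subset_obs <- function(o, ix) {
    o$vectors <- o$vectors[ix, , drop = FALSE]
    o$tags <- o$tags[ix]
    o
  }
  if (!is.null(q)) {
    if (q < 4 * n_tags)
      err("q too small for on-the-fly cross-validation",
          "erpleak_param_error")
    obs <- with_seed(derive_seed(seed, 31L), {
      take <- unlist(lapply(seq_len(n_tags), function(tg) {
        ix <- which(obs$tags == tg)
        sample(ix, min(length(ix), max(2L, round(q / n_tags))))
      }))
      subset_obs(obs, sort(take))
    })
    n <- nrow(obs$vectors)
  }

  part_id <- if (splits == 1L) rep(1L, n) else
    with_seed(derive_seed(seed, 32L), {
      p <- integer(n)
      for (tg in seq_len(n_tags)) {
        ix <- which(obs$tags == tg)
        p[ix] <- sample(rep_len(seq_len(splits), length(ix)))
      }
      p
    })

  parts <- lapply(seq_len(splits), function(s) {
    o <- subset_obs(obs, which(part_id == s))
    floor_val <- .clip_floor_for(variant, clip_floor)
    fits <- lapply(seq_len(n_tags), function(tg) {
      estimate_pi(NULL, as.integer(o$tags == tg), backend = backend,
                  prior_mode = prior_mode, clip_floor = floor_val,
                  B = B, seed = derive_seed(seed, 40L + tg),
                  obs = o, basis_spec = list(variant = variant, n_d = n_d))
    })
    tab <- data.frame(
      tag = seq_len(n_tags),
      pi = vapply(fits, `[[`, numeric(1), "pi"),
      ci_low = vapply(fits, `[[`, numeric(1), "ci_low"),
      ci_high = vapply(fits, `[[`, numeric(1), "ci_high"))
    list(table = tab, winner = which.max(tab$pi), fits = fits)
  })
  structure(list(parts = parts, splits = splits, variant = variant),
            class = "nonprofiled_result")
}

# core of the portability evaluations: basis+model from A, scored on B
.score_foreign <- function(red_b, labels_b, model, prior_mode, floor_val,
                           B, seed) {
  post <- posterior(model, red_b, prior_mode = prior_mode)
  if (!is.null(floor_val)) post <- clip_posteriors(post, floor_val)
  lb <- as.character(labels_b)
  tc <- match(lb, names(model$priors))
  lt <- log2(post$probs[cbind(seq_along(lb), tc)])
  classes <- sort(unique(lb))
  pr <- vapply(classes, function(cl) mean(lb == cl), numeric(1))
  names(pr) <- classes
  h <- entropy_bits(pr)
  ci <- bootstrap_ci(lt, lb, pr, h, B = B, seed = seed)
  structure(list(pi = pi_functional(lt, lb, pr, h), h_prior = h,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 log_terms = lt, term_class = lb, posteriors = post$probs,
                 priors = pr, k = 1L, n = length(lt),
                 backend = model$backend, prior_mode = prior_mode,
                 clipped = !is.null(floor_val)), class = "pi_result")
}

#' Cross-user model portability
#'
#' Projects user B's observations with user A's PCA basis and scores them
#' with A's class-conditional model; the PI is computed on B's labels.
#' With `cv = TRUE` (requires A and B of equal size; meaningful when
#' `obs_a` is `obs_b`) the model is refitted per leave-one-out fold, so
#' self-portability reproduces the profiled estimate exactly.
#'
#' @param obs_a,obs_b `observation_set`s of the profiling and target
#'   users (same montage/epoch length).
#' @param variant,n_d,backend,prior_mode,clip_floor,B As in
#'   [profiled_attack()].
#' @param cv Refit per LOO fold (self-portability check).
#' @param seed Seed.
#' @return A `pi_result` on B's labels.
#' @export
portability_attack <- function(obs_a, obs_b, variant = c("average", "raw"),
                               n_d = 5L, backend = c("kde", "gaussian"),
                               prior_mode = c("empirical", "uniform"),
                               clip_floor = "auto", cv = FALSE,
                               B = 100L, seed = 1L) {
  variant <- match.arg(variant)
  backend <- match.arg(backend)
  prior_mode <- match.arg(prior_mode)
  stopifnot(inherits(obs_a, "observation_set"),
            inherits(obs_b, "observation_set"))
  if (ncol(obs_a$vectors) != ncol(obs_b$vectors))
    err("observation length mismatch between users (montage/epoch)",
        "erpleak_dim_error")
  basis <- .make_basis(obs_a, variant, n_d)
  red_a <- project_obs(obs_a, basis)
  red_b <- project_obs(obs_b, basis)
  floor_val <- .clip_floor_for(basis, clip_floor)
  labels_a <- as.integer(obs_a$tags == 1L)
  labels_b <- as.integer(obs_b$tags == 1L)
  if (cv) {
    if (nrow(obs_a$vectors) != nrow(obs_b$vectors))
      err("cv = TRUE requires equal-size observation sets",
          "erpleak_param_error")
    return(estimate_pi(NULL, labels_b, backend = backend,
                       prior_mode = prior_mode, clip_floor = floor_val,
                       B = B, seed = seed, obs = obs_b,
                       basis_spec = list(variant = variant, n_d = n_d)))
  }
  model <- fit_density(red_a, labels_a, backend = backend)
  .score_foreign(red_b, labels_b, model, prior_mode, floor_val, B,
                 derive_seed(seed, 51L))
}

#' "All against one" profiling
#'
#' Profiles one model on the pooled observations of every non-target
#' user (basis from the pooled data, per variant) and evaluates the PI on
#' the target user.
#'
#' @param cohort_obs List of `observation_set`s, one per user.
#' @param target Index of the target user in `cohort_obs`.
#' @param variant,n_d,backend,prior_mode,clip_floor,B,seed As in
#'   [portability_attack()].
#' @return A `pi_result` on the target's labels.
#' @export
all_against_one <- function(cohort_obs, target,
                            variant = c("average", "raw"), n_d = 5L,
                            backend = c("kde", "gaussian"),
                            prior_mode = c("empirical", "uniform"),
                            clip_floor = "auto", B = 100L, seed = 1L) {
  if (length(cohort_obs) < 3)
    err("need at least 2 non-target users", "erpleak_param_error")
  others <- cohort_obs[-target]
  pooled <- others[[1]]
  pooled$vectors <- do.call(rbind, lapply(others, `[[`, "vectors"))
  pooled$tags <- unlist(lapply(others, `[[`, "tags"))
  pooled$user_id <- NA_integer_
  portability_attack(pooled, cohort_obs[[target]], variant = variant,
                     n_d = n_d, backend = backend,
                     prior_mode = prior_mode, clip_floor = clip_floor,
                     B = B, seed = seed)
}

#' User identification from real-PIN epochs
#'
#' Privacy flip side of PIN recovery: restricts every user's session to
#' the epochs of their real PIN, fits one multi-class density model over
#' users (same backends, same PI machinery with U in place of P), and
#' reports the partial PI per user and the overall PI(U;O).
#'
#' @param cohort_obs List of `observation_set`s, one per user (full
#'   sessions; the real-PIN epochs are extracted internally).
#' @param k Cross-validation folds over the pooled epochs (default 10).
#' @param variant `"average"` (PCA of the per-user mean traces) or
#'   `"raw"`.
#' @param n_d PCA dimensions (capped at n_users - 1 for `"average"`).
#' @param backend,prior_mode,B,seed As elsewhere.
#' @return Object of class `identification_result`: `partial` (named
#'   per-user PI), `overall` (a `pi_result`), `confusion` (counts,
#'   true user x decoded user).
#' @export
identify_user <- function(cohort_obs, k = 10L,
                          variant = c("average", "raw"), n_d = 5L,
                          backend = c("kde", "gaussian"),
                          prior_mode = c("empirical", "uniform"),
                          B = 100L, seed = 1L) {
  variant <- match.arg(variant)
  backend <- match.arg(backend)
  prior_mode <- match.arg(prior_mode)
  n_users <- length(cohort_obs)
  if (n_users < 2) err("need at least 2 users", "erpleak_param_error")
  xs <- lapply(seq_len(n_users), function(u) {
    o <- cohort_obs[[u]]
    v <- o$vectors[o$tags == 1L, , drop = FALSE]
    if (nrow(v) < 2)
      err(sprintf("user %d has fewer than 2 real-PIN epochs", u),
          "erpleak_empty_class_error")
    v
  })
  x <- do.call(rbind, xs)
  users <- as.character(rep(seq_len(n_users), vapply(xs, nrow, integer(1))))
  n <- nrow(x)
  k <- min(k, n)
  if (variant == "average") n_d <- min(n_d, n_users - 1L)

  # Unlike PIN profiling (where the per-tag means use only public tags),
  # the per-user means are label-dependent, so the basis must be
  # estimated inside each fold's profiling set to avoid leaking the
  # identity of held-out epochs into the dimensionality reduction.
  fold_basis <- function(xtr, utr) {
    if (variant == "average") {
      means <- t(vapply(sort(unique(utr)), function(u)
        colMeans(xtr[utr == u, , drop = FALSE]), numeric(ncol(xtr))))
      tm <- structure(list(means = means,
                           counts = as.integer(table(utr)),
                           tags = seq_len(nrow(means))), class = "tag_means")
      average_pca(tm, n_d = n_d)
    } else {
      pooled <- structure(list(vectors = xtr, tags = utr,
                               user_id = NA_integer_),
                          class = "observation_set")
      raw_pca(pooled, n_d = n_d)
    }
  }

  fold <- cv_folds(users, k, seed = derive_seed(seed, 61L))
  classes <- sort(unique(users))
  priors <- vapply(classes, function(u) mean(users == u), numeric(1))
  names(priors) <- classes
  h_prior <- entropy_bits(priors)
  log_terms <- numeric(n)
  posteriors <- matrix(NA_real_, n, n_users, dimnames = list(NULL, classes))
  basis <- NULL
  for (j in sort(unique(fold))) {
    test <- which(fold == j); train <- which(fold != j)
    if (length(unique(users[train])) < n_users)
      err(sprintf("fold %d has a profiling set missing a user", j),
          "erpleak_fold_error")
    basis <- fold_basis(x[train, , drop = FALSE], users[train])
    str <- sweep(x[train, , drop = FALSE], 2, basis$center) %*%
      t(basis$components)
    ste <- sweep(x[test, , drop = FALSE], 2, basis$center) %*%
      t(basis$components)
    model <- fit_density(str, users[train], backend = backend)
    probs <- posterior_from_loglik(log2_likelihood(model, ste),
                                   model$priors, prior_mode)
    tc <- match(users[test], names(model$priors))
    log_terms[test] <- log2(probs[cbind(seq_along(test), tc)])
    posteriors[test, ] <- probs
  }
  pi <- pi_functional(log_terms, users, priors, h_prior)
  ci <- bootstrap_ci(log_terms, users, priors, h_prior, B = B,
                     seed = derive_seed(seed, 62L))
  overall <- structure(list(
    pi = pi, h_prior = h_prior, ci_low = unname(ci[1]),
    ci_high = unname(ci[2]), log_terms = log_terms, term_class = users,
    posteriors = posteriors, priors = priors, k = k, n = n,
    backend = backend, prior_mode = prior_mode, clipped = FALSE
  ), class = "pi_result")
  partial <- vapply(classes, function(u)
    h_prior + mean(log_terms[users == u]), numeric(1))
  decoded <- classes[max.col(posteriors)]
  confusion <- table(true = factor(users, levels = classes),
                     decoded = factor(decoded, levels = classes))
  structure(list(partial = partial, overall = overall,
                 confusion = confusion, basis = basis),
            class = "identification_result")
}
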