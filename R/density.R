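# Per-class conditional density models. After PCA the score dimensions
# are orthogonal; treating them as independent reduces the N_d-variate
# estimation problem to N_d univariate ones, per class. Two backends:
# Gaussian templates, and kernel density estimation (Gaussian kernel,
# Silverman rule-of-thumb bandwidth).

# per-dimension log2-density floor: keeps PI finite for extreme outliers
.LOG2_FLOOR <- -1000

#' Silverman's rule-of-thumb bandwidth
#'
#' The robust plug-in form `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, with the
#' n-1 sample standard deviation and linearly interpolated quartiles. If
#' the IQR is degenerate (zero) the standard deviation alone is used.
#'
#' @param samples Numeric vector, n >= 2.
#' @return Positive bandwidth.
#' @examples
#' silverman_bandwidth(rnorm(900)) # ~ 0.9 * 900^(-1/5)
#' @export
silverman_bandwidth <- function(samples) {
  n <- length(samples)
  if (n < 2) err("need at least 2 samples", "erpleak_param_error")
  s <- stats::sd(samples)
  iqr <- stats::IQR(samples, type = 7)
  if (s == 0) err("zero spread: degenerate class", "erpleak_degenerate_error")
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  0.9 * spread * n^(-1 / 5)
}

#' Fit per-class conditional densities
#'
#' One univariate model per class and per score dimension, with class
#' priors taken as empirical class frequencies.
#'
#' @param reduced A `reduced_obs` object, or a plain numeric matrix of
#'   scores (epochs x N_d).
#' @param labels Per-epoch class labels (binary real/random in PIN mode,
#'   user ids in identification mode).
#' @param backend `"kde"` (Gaussian kernel, Silverman bandwidth) or
#'   `"gaussian"` (mean/sd templates).
#' @return Object of class `class_density`.
#' @export
fit_density <- function(reduced, labels, backend = c("kde", "gaussian")) {
  backend <- match.arg(backend)
  x <- if (inherits(reduced, "reduced_obs")) reduced$scores else as.matrix(reduced)
  if (nrow(x) != length(labels))
    err("labels length must match number of observations", "erpleak_dim_error")
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    err("need at least 2 classes to fit conditional densities",
        "erpleak_empty_class_error")
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(counts < 2))
    err(sprintf("class(es) %s have fewer than 2 samples",
                paste(classes[counts < 2], collapse = ", ")),
        "erpleak_empty_class_error")
  models <- lapply(classes, function(cl) {
    xs <- x[labels == cl, , drop = FALSE]
    lapply(seq_len(ncol(x)), function(d) {
      v <- xs[, d]
      if (backend == "kde")
        list(samples = v, h = silverman_bandwidth(v))
      else
        list(mean = mean(v), sd = stats::sd(v))
    })
  })
  names(models) <- as.character(classes)
  priors <- counts / sum(counts)
  names(priors) <- as.character(classes)
  structure(list(classes = classes, models = models, priors = priors,
                 backend = backend, n_dim = ncol(x)),
            class = "class_density")
}

# log2 density of vector `t` under one univariate component
.log2_density_1d <- function(par, t, backend) {
  if (backend == "kde") {
    z <- outer(t, par$samples, "-") / par$h
    ll <- log(rowMeans(stats::dnorm(z)) / par$h) / log(2)
  } else {
    if (par$sd <= 0) return(rep(.LOG2_FLOOR, length(t)))
    ll <- stats::dnorm(t, par$mean, par$sd, log = TRUE) / log(2)
  }
  pmax(ll, .LOG2_FLOOR)
}

#' Per-class log2 likelihood of observations
#'
#' log2 of the product over score dimensions of the fitted univariate
#' densities (computed in the log domain; each dimension's log2 density
#' is floored at -1000 to keep extreme outliers finite).
#'
#' @param model A [fit_density()] object.
#' @param reduced A `reduced_obs` or scores matrix with `model$n_dim`
#'   columns.
#' @return Matrix observations x classes of log2 densities.
#' @export
log2_likelihood <- function(model, reduced) {
  stopifnot(inherits(model, "class_density"))
  x <- if (inherits(reduced, "reduced_obs")) reduced$scores else as.matrix(reduced)
  if (ncol(x) != model$n_dim)
    err(sprintf("model has %d dimensions, scores have %d",
                model$n_dim, ncol(x)), "erpleak_dim_error")
  out <- matrix(0, nrow(x), length(model$classes),
                dimnames = list(NULL, names(model$models)))
  for (k in seq_along(model$classes)) {
    acc <- numeric(nrow(x))
    for (d in seq_len(model$n_dim))
      acc <- acc + .log2_density_1d(model$models[[k]][[d]], x[, d],
                                    model$backend)
    out[, k] <- acc
  }
  out
}

#' Posterior class probabilities (Bayes inversion)
#'
#' Softmax of the per-class log2 likelihoods, optionally weighted by the
#' fitted empirical priors. The default `"uniform"` drops the prior term,
#' i.e. a maximum-likelihood attack (avoids the a-priori bias toward the
#' majority random-PIN class); `"empirical"` is the textbook Bayes rule
#' with the class frequencies.
#'
#' @param model A [fit_density()] object.
#' @param reduced A `reduced_obs` or scores matrix.
#' @param prior_mode `"uniform"` or `"empirical"`.
#' @return Object of class `posterior_array`: `probs` (rows sum to 1),
#'   `classes`, `prior_mode`, `clipped = FALSE`.
#' @export
posterior <- function(model, reduced, prior_mode = c("uniform", "empirical")) {
  prior_mode <- match.arg(prior_mode)
  ll <- log2_likelihood(model, reduced)
  structure(list(probs = posterior_from_loglik(ll, model$priors, prior_mode),
                 classes = model$classes,
                 prior_mode = prior_mode, clipped = FALSE),
            class = "posterior_array")
}

#' Posterior probabilities from cross-validated log2 likelihoods
#'
#' Row-wise softmax of a log2-likelihood matrix, optionally weighted by
#' class priors. Lets one set of cross-validated likelihoods serve both
#' the PI estimate (empirical priors, the Bayes formula) and the
#' maximum-likelihood attack metrics (uniform priors).
#'
#' @param ll Matrix observations x classes of log2 likelihoods, with
#'   class names as column names.
#' @param priors Named class priors (used when `prior_mode =
#'   "empirical"`).
#' @param prior_mode `"uniform"` or `"empirical"`.
#' @return Matrix of posterior probabilities, rows summing to 1.
#' @export
posterior_from_loglik <- function(ll, priors = NULL,
                                  prior_mode = c("uniform", "empirical")) {
  prior_mode <- match.arg(prior_mode)
  if (prior_mode == "empirical") {
    if (is.null(priors)) err("priors required for empirical mode",
                             "erpleak_param_error")
    ll <- sweep(ll, 2, log2(priors[colnames(ll)]), "+")
  }
  m <- apply(ll, 1, max)
  w <- 2^(ll - m)
  w / rowSums(w)
}

#' Clip small posterior probabilities
#'
#' Outlier treatment: entries below `floor` are raised to `floor`, with
#' no renormalization, so extreme observations contribute a bounded log
#' probability to the perceived-information sum. Intended for raw-PCA
#' pipelines, where less targeted dimensions make outliers likely; the
#' attack drivers apply it only when `basis$source == "raw"`.
#'
#' @param post A [posterior()] object.
#' @param floor Clipping floor in (0, 0.5); default 0.001.
#' @return The clipped `posterior_array`, `clipped = TRUE`.
#' @export
clip_posteriors <- function(post, floor = 0.001) {
  stopifnot(inherits(post, "posterior_array"))
  if (floor <= 0 || floor >= 0.5)
    err("floor must lie in (0, 0.5)", "erpleak_param_error")
  post$probs <- pmax(post$probs, floor)
  post$clipped <- TRUE
  post
}
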