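# PCA dimensionality reduction: the "average PCA" on per-tag mean traces
# and the "raw PCA" on raw observation vectors, plus projection.

#' Per-tag mean observation vectors
#'
#' @param obs An `observation_set`.
#' @param n_tags Expected number of tag classes (default: the largest
#'   tag present); every class `1..n_tags` must have surviving epochs.
#' @return Object of class `tag_means`: `means` (n_tags x D matrix) and
#'   `counts` (surviving epochs per tag).
#' @export
tag_means <- function(obs, n_tags = max(obs$tags)) {
  stopifnot(inherits(obs, "observation_set"))
  tags <- sort(unique(obs$tags))
  full <- seq_len(n_tags)
  if (!all(full %in% tags))
    err(sprintf("tag class(es) %s have no surviving epochs",
                paste(setdiff(full, tags), collapse = ", ")),
        "erpleak_empty_class_error")
  means <- t(vapply(tags, function(j)
    colMeans(obs$vectors[obs$tags == j, , drop = FALSE]),
    numeric(ncol(obs$vectors))))
  counts <- vapply(tags, function(j) sum(obs$tags == j), integer(1))
  structure(list(means = means, counts = counts, tags = tags),
            class = "tag_means")
}

# deterministic sign convention: largest-|coefficient| positive
fix_signs <- function(components) {
  for (i in seq_len(nrow(components))) {
    j <- which.max(abs(components[i, ]))
    if (components[i, j] < 0) components[i, ] <- -components[i, ]
  }
  components
}

new_basis <- function(components, center, source, explained_variance) {
  structure(list(components = components, center = center, source = source,
                 explained_variance = explained_variance),
            class = "projection_basis")
}

#' Average PCA: principal components of the per-tag mean traces
#'
#' Eigenvectors of the (unweighted) covariance of the per-tag mean
#' vectors, ordered by decreasing eigenvalue. With 6 tags at most 5
#' components have nonzero eigenvalue. Uses only public tag labels, never
#' the real/random split.
#'
#' @param means A [tag_means()] object.
#' @param n_d Number of components to keep (<= n_tags - 1).
#' @return Object of class `projection_basis` with orthonormal rows
#'   `components`, the `center` (grand mean of the tag means), `source =
#'   "average"` and `explained_variance`.
#' @export
average_pca <- function(means, n_d = 5L) {
  stopifnot(inherits(means, "tag_means"))
  m <- means$means
  n_tags <- nrow(m)
  if (n_d > n_tags - 1)
    err(sprintf("n_d must be <= n_tags - 1 = %d", n_tags - 1),
        "erpleak_rank_error")
  center <- colMeans(m)
  xc <- sweep(m, 2, center)
  sv <- svd(xc, nu = 0, nv = min(n_tags, ncol(m)))
  eig <- sv$d^2 / (n_tags - 1)
  rank <- sum(sv$d > max(sv$d) * 1e-10 * sqrt(ncol(m)))
  if (rank == 0 || n_d > rank)
    err(sprintf("requested n_d = %d exceeds achievable rank %d", n_d, rank),
        "erpleak_rank_error")
  comp <- fix_signs(t(sv$v[, seq_len(n_d), drop = FALSE]))
  new_basis(comp, center, "average", eig[seq_len(n_d)])
}

#' Raw PCA: principal components of the raw observation vectors
#'
#' As [average_pca()] but the covariance is over all epoch vectors and
#' the center is their grand mean. Computed via the Gram matrix
#' (epochs x epochs), cheap when epochs << D.
#'
#' @param obs An `observation_set`.
#' @param n_d Number of components (default 5, a trade-off between
#'   informativeness and outlier risk).
#' @return A `projection_basis` with `source = "raw"`.
#' @export
raw_pca <- function(obs, n_d = 5L) {
  stopifnot(inherits(obs, "observation_set"))
  x <- obs$vectors
  n <- nrow(x)
  if (n_d >= n)
    err(sprintf("n_d = %d must be < number of epochs = %d", n_d, n),
        "erpleak_rank_error")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  g <- tcrossprod(xc)                     # n x n Gram matrix
  eg <- eigen(g, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  rank <- sum(pos)
  if (n_d > rank)
    err(sprintf("requested n_d = %d exceeds achievable rank %d", n_d, rank),
        "erpleak_rank_error")
  d <- sqrt(eg$values[seq_len(n_d)])
  v <- crossprod(xc, eg$vectors[, seq_len(n_d), drop = FALSE])
  v <- sweep(v, 2, d, "/")                # orthonormal columns
  comp <- fix_signs(t(v))
  new_basis(comp, center, "raw", eg$values[seq_len(n_d)] / (n - 1))
}

#' Project observations onto a PCA basis
#'
#' Scores are the inner products of the centered observation vectors with
#' the basis rows: `scores = (X - center) %*% t(components)`.
#'
#' @param obs An `observation_set`.
#' @param basis A `projection_basis`.
#' @return Object of class `reduced_obs`: `scores` (epochs x N_d),
#'   `tags`, `user_id`, `basis`.
#' @export
project_obs <- function(obs, basis) {
  stopifnot(inherits(obs, "observation_set"),
            inherits(basis, "projection_basis"))
  if (ncol(obs$vectors) != ncol(basis$components))
    err(sprintf("dimension mismatch: observations have D = %d, basis D = %d",
                ncol(obs$vectors), ncol(basis$components)),
        "erpleak_dim_error")
  scores <- sweep(obs$vectors, 2, basis$center) %*% t(basis$components)
  structure(list(scores = scores, tags = obs$tags, user_id = obs$user_id,
                 basis = basis), class = "reduced_obs")
}
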