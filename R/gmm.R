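#' Diagonal-covariance Gaussian mixture parameters
#'
#' Constructs and validates a `gmm` object, the package's model class for a
#' mixture density \eqn{p(x|\lambda) = \sum_i w_i p_i(x)} with diagonal
#' covariances. Weights must be nonnegative and sum to 1 (within 1e-10); all
#' variances must exceed the variance floor.
#'
#' @param weights length-`M` mixture weights.
#' @param means `M x D` matrix of component means.
#' @param variances `M x D` matrix of per-dimension variances.
#' @param var_floor positive lower bound enforced on the variances.
#' @param meta optional list of provenance fields (dimension name, seed, ...).
#' @return an object of class `gmm`.
#' @export
gmm <- function(weights, means, variances, var_floor = 1e-8, meta = list()) {
  means <- as.matrix(means); variances <- as.matrix(variances)
  weights <- as.numeric(weights)
  m <- length(weights)
  stopifnot(nrow(means) == m, all(dim(means) == dim(variances)))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-10)
    stop("weights must be nonnegative and sum to 1")
  if (any(variances < var_floor))
    stop("variances below the floor (", var_floor, ")")
  structure(list(weights = weights, means = means, variances = variances,
                 M = m, D = ncol(means), var_floor = var_floor, meta = meta),
            class = "gmm")
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("<gmm: M = %d components, D = %d dimensions>\n", x$M, x$D))
  cat("weights:", paste(signif(x$weights, 3), collapse = " "), "\n")
  if (!is.null(x$meta$dimension))
    cat("feature dimension:", x$meta$dimension, "\n")
  if (!is.null(x$meta$loglik))
    cat(sprintf("mean log-likelihood at fit: %.4f (%d EM iterations)\n",
                utils::tail(x$meta$loglik, 1L), length(x$meta$loglik)))
  invisible(x)
}

#' @export
coef.gmm <- function(object, ...) {
  list(weights = object$weights, means = object$means,
       variances = object$variances)
}

# per-frame per-component log N(x_t | mu_i, diag(sigma2_i)); T x M
.log_comp_dens <- function(X, model) {
  X <- .fm_values(X)
  if (ncol(X) != model$D) stop("feature dimension mismatch: data has ",
                               ncol(X), " columns, model expects ", model$D)
  t_len <- nrow(X)
  out <- matrix(0, t_len, model$M)
  for (i in seq_len(model$M)) {
    v <- model$variances[i, ]
    ctr <- sweep(X, 2L, model$means[i, ])
    out[, i] <- -0.5 * (model$D * log(2 * pi) + sum(log(v)) +
                          drop(ctr^2 %*% (1 / v)))
  }
  out
}

#' Mixture log density of feature vectors
#'
#' Evaluates \eqn{\log p(x_t|\lambda) = \log \sum_i w_i p_i(x_t)} for every
#' row of `X`, computed stably in log space (log-sum-exp).
#'
#' @param X numeric matrix (`T x D`) or `feature_matrix`.
#' @param model a `gmm`.
#' @return numeric vector of length `T`.
#' @export
gmm_log_density <- function(X, model) {
  lg <- .log_comp_dens(X, model) +
    matrix(log(model$weights), nrow(.fm_values(X)), model$M, byrow = TRUE)
  mx <- apply(lg, 1L, max)
  mx + log(rowSums(exp(lg - mx)))
}

#' @export
logLik.gmm <- function(object, X, ...) {
  ll <- sum(gmm_log_density(X, object))
  attr(ll, "df") <- object$M * (1L + 2L * object$D) - 1L
  attr(ll, "nobs") <- nrow(.fm_values(X))
  class(ll) <- "logLik"
  ll
}

#' Component posterior probabilities
#'
#' \eqn{Pr(i|x_t) = w_i p_i(x_t) / \sum_j w_j p_j(x_t)} for each row of `X`.
#' If every component underflows for some frame, that frame receives a
#' uniform posterior with a warning.
#'
#' @inheritParams gmm_log_density
#' @return `T x M` matrix of posteriors; rows sum to 1.
#' @export
responsibilities <- function(X, model) {
  lg <- .log_comp_dens(X, model) +
    matrix(log(model$weights), nrow(.fm_values(X)), model$M, byrow = TRUE)
  mx <- apply(lg, 1L, max)
  bad <- !is.finite(mx)
  if (any(bad)) {
    warning(sum(bad), " frame(s) underflowed in every component; ",
            "uniform posterior assigned")
    lg[bad, ] <- 0
    mx[bad] <- 0
  }
  p <- exp(lg - mx)
  p / rowSums(p)
}

#' @export
predict.gmm <- function(object, newdata,
                        type = c("responsibilities", "classification",
                                 "logdensity"), ...) {
  type <- match.arg(type)
  switch(type,
         responsibilities = responsibilities(newdata, object),
         classification = max.col(responsibilities(newdata, object)),
         logdensity = gmm_log_density(newdata, object))
}

#' @export
simulate.gmm <- function(object, nsim = 1, seed = NULL, ...) {
  sample_gmm(object, t_len = nsim, seed = seed)
}

# k-means++ center seeding (indices into rows of X)
.kmeanspp_centers <- function(X, m) {
  t_len <- nrow(X)
  centers <- integer(m)
  centers[1L] <- sample.int(t_len, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1L], ])^2)
  for (i in seq_len(m - 1L)) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / t_len, t_len)
    centers[i + 1L] <- sample.int(t_len, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[i + 1L], ])^2))
  }
  X[centers, , drop = FALSE]
}

#' Fit a diagonal-covariance Gaussian mixture by expectation maximization
#'
#' The workhorse estimator for universal background models. Components are
#' initialized by k-means++-seeded k-means on a subsample; EM then iterates
#' until the relative change in mean log-likelihood falls below `tol` or
#' `max_iter` is reached. Per-iteration mean log-likelihood is
#' non-decreasing. Variances are floored at `var_floor_frac` times the
#' per-dimension data variance; a component collapsing to (near) zero weight
#' is re-seeded at the frame with the lowest current log-density.
#'
#' @param X numeric `T x D` matrix or `feature_matrix` of training frames.
#' @param m number of mixture components (`T >= m` required).
#' @param seed integer seed controlling initialization.
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative mean log-likelihood convergence threshold
#'   (default 1e-5).
#' @param var_floor_frac variance floor as a fraction of each dimension's
#'   data variance (default 1e-4).
#' @param init_subsample cap on the number of frames used for k-means
#'   initialization (default 5000).
#' @return a fitted `gmm`; the per-iteration mean log-likelihood trace is in
#'   `$meta$loglik`.
#' @export
gmm_fit <- function(X, m, seed = 1L, max_iter = 200L, tol = 1e-5,
                    var_floor_frac = 1e-4, init_subsample = 5000L) {
  X <- .fm_values(X)
  t_len <- nrow(X); d <- ncol(X)
  if (t_len < m) stop("need at least M = ", m, " frames, got ", t_len)
  data_var <- apply(X, 2L, stats::var)
  data_var[!is.finite(data_var) | data_var == 0] <- 1
  floor_vec <- var_floor_frac * data_var
  var_floor <- min(floor_vec)

  if (m == 1L) {
    mu <- matrix(colMeans(X), 1L)
    v <- matrix(pmax(colMeans(sweep(X, 2L, mu[1L, ])^2), floor_vec), 1L)
    model <- gmm(1, mu, v, var_floor,
                 meta = list(seed = seed, loglik = NA_real_))
    model$meta$loglik <- mean(gmm_log_density(X, model))
    return(model)
  }

  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  sub <- if (t_len > init_subsample)
    X[sample.int(t_len, init_subsample), , drop = FALSE] else X
  ctr <- .kmeanspp_centers(sub, m)
  km <- suppressWarnings(stats::kmeans(sub, centers = ctr, iter.max = 20L))
  assign <- km$cluster
  w <- as.numeric(table(factor(assign, levels = seq_len(m)))) / length(assign)
  w <- pmax(w, 1e-6); w <- w / sum(w)
  mu <- km$centers
  v <- matrix(0, m, d)
  for (i in seq_len(m)) {
    xi <- sub[assign == i, , drop = FALSE]
    v[i, ] <- if (nrow(xi) > 1L)
      colMeans(sweep(xi, 2L, mu[i, ])^2) else data_var
  }
  v <- pmax(v, matrix(floor_vec, m, d, byrow = TRUE))

  model <- gmm(w, mu, v, var_floor, meta = list(seed = seed))
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lg <- .log_comp_dens(X, model) +
      matrix(log(model$weights), t_len, m, byrow = TRUE)
    mx <- apply(lg, 1L, max)
    ll <- mean(mx + log(rowSums(exp(lg - mx))))
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lg - mx); resp <- resp / rowSums(resp)
    n_i <- colSums(resp)
    empty <- which(n_i < 1e-8)
    if (length(empty)) {
      # re-seed collapsed components at the worst-modelled frames
      worst <- order(mx + log(rowSums(exp(lg - mx))))[seq_along(empty)]
      for (k in seq_along(empty)) {
        i <- empty[k]
        model$means[i, ] <- X[worst[k], ]
        model$variances[i, ] <- pmax(data_var, floor_vec)
        model$weights[i] <- 1 / t_len
      }
      model$weights <- model$weights / sum(model$weights)
      next
    }
    w_new <- n_i / t_len
    mu_new <- crossprod(resp, X) / n_i
    ex2 <- crossprod(resp, X^2) / n_i
    v_new <- pmax(ex2 - mu_new^2, matrix(floor_vec, m, d, byrow = TRUE))
    model$weights <- w_new / sum(w_new)
    model$means <- mu_new
    model$variances <- v_new
    if (it > 1L) {
      prev <- ll_trace[it - 1L]
      if (abs(ll - prev) < tol * max(1, abs(prev))) break
    }
  }
  model$meta$loglik <- ll_trace
  model
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Serialize a GMM to JSON
#'
#' Writes all parameters (weights, means, variances), the variance floor,
#' and the metadata list to a single JSON document readable by
#' [read_gmm()].
#'
#' @param model a `gmm`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmm <- function(model, path) {
  stopifnot(inherits(model, "gmm"))
  obj <- list(M = model$M, D = model$D, weights = model$weights,
              means = model$means, variances = model$variances,
              var_floor = model$var_floor, meta = model$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a GMM serialized by [write_gmm()]
#' @param path path to the JSON file.
#' @return a `gmm`.
#' @export
read_gmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gmm(obj$weights, obj$means, obj$variances, var_floor = obj$var_floor,
      meta = as.list(obj$meta))
}
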