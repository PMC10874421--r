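#' MAP adaptation configuration
#'
#' @param relevance_factor positive relevance factor `r` balancing the UBM
#'   prior against the recording's data through
#'   `alpha_i = n_i / (n_i + r)`; the standard value is 16.
#' @param adapt_weights,adapt_means,adapt_variances which parameter groups
#'   to update (all `TRUE` by default).
#' @return an object of class `adaptation_config`.
#' @export
adaptation_config <- function(relevance_factor = 16, adapt_weights = TRUE,
                              adapt_means = TRUE, adapt_variances = TRUE) {
  stopifnot(relevance_factor > 0)
  structure(list(relevance_factor = relevance_factor,
                 adapt_weights = adapt_weights,
                 adapt_means = adapt_means,
                 adapt_variances = adapt_variances),
            class = "adaptation_config")
}

#' Sufficient statistics of a feature stream under a UBM
#'
#' Soft counts and first/second moments of the frames of `X` against the
#' components of `ubm`:
#' `n_i = sum_t Pr(i|x_t)`,
#' `E_i(x) = (1/n_i) sum_t Pr(i|x_t) x_t`,
#' `E_i(x^2) = (1/n_i) sum_t Pr(i|x_t) diag(x_t x_t')`.
#' Components with `n_i = 0` carry the UBM's own moments so that the MAP
#' update reduces to the identity for them.
#'
#' @param X numeric `T x D` matrix or `feature_matrix` (`T >= 1`).
#' @param ubm a `gmm`.
#' @return an object of class `sufficient_stats` with fields `n` (length
#'   `M`), `first_moment` and `second_moment` (`M x D`), and `T`.
#' @export
sufficient_stats <- function(X, ubm) {
  X <- .fm_values(X)
  if (nrow(X) == 0L) stop("empty feature matrix")
  resp <- responsibilities(X, ubm)
  n <- colSums(resp)
  ex <- ubm$means
  ex2 <- ubm$variances + ubm$means^2
  live <- n > 0
  if (any(live)) {
    ex[live, ] <- crossprod(resp[, live, drop = FALSE], X) / n[live]
    ex2[live, ] <- crossprod(resp[, live, drop = FALSE], X^2) / n[live]
  }
  structure(list(n = n, first_moment = ex, second_moment = ex2,
                 T = nrow(X)),
            class = "sufficient_stats")
}

#' MAP update of UBM parameters toward a recording
#'
#' Classic relevance-factor maximum a posteriori adaptation. With
#' `alpha_i = n_i / (n_i + r)`:
#' weights `w'_i = [alpha_i n_i / T + (1 - alpha_i) w_i] * gamma` with
#' `gamma` normalizing the weights to sum to 1; means
#' `mu'_i = alpha_i E_i(x) + (1 - alpha_i) mu_i`; variances
#' `sigma'^2_i = alpha_i E_i(x^2) + (1 - alpha_i)(sigma^2_i + mu^2_i) -
#' mu'^2_i`, floored at the UBM's variance floor. A single pass is
#' performed; components that saw no data (`n_i = 0`) are unchanged.
#'
#' @param ubm a `gmm`.
#' @param stats `sufficient_stats` computed against `ubm`.
#' @param cfg an `adaptation_config`.
#' @return the adapted `gmm`; `$meta$n_floored` counts variances that had to
#'   be floored.
#' @export
map_adapt <- function(ubm, stats, cfg = adaptation_config()) {
  stopifnot(inherits(ubm, "gmm"), inherits(stats, "sufficient_stats"))
  if (length(stats$n) != ubm$M) stop("stats/UBM component count mismatch")
  r <- cfg$relevance_factor
  alpha <- stats$n / (stats$n + r)
  w <- ubm$weights; mu <- ubm$means; v <- ubm$variances
  if (cfg$adapt_weights) {
    w <- alpha * stats$n / stats$T + (1 - alpha) * ubm$weights
    w <- w / sum(w)                                   # gamma normalization
  }
  if (cfg$adapt_means) {
    mu <- alpha * stats$first_moment + (1 - alpha) * ubm$means
  }
  n_floored <- 0L
  if (cfg$adapt_variances) {
    v <- alpha * stats$second_moment +
      (1 - alpha) * (ubm$variances + ubm$means^2) - mu^2
    n_floored <- sum(v < ubm$var_floor)
    if (n_floored > 0L)
      warning(n_floored, " adapted variance(s) floored")
    v <- pmax(v, ubm$var_floor)
  }
  out <- gmm(w, mu, v, var_floor = ubm$var_floor, meta = ubm$meta)
  out$meta$adapted <- TRUE
  out$meta$alpha <- alpha
  out$meta$n_floored <- n_floored
  out
}

#' Stack an adapted GMM into a supervector
#'
#' Concatenates the component means and the diagonals of the component
#' covariances in UBM component order:
#' `[mu'_1 ... mu'_M | diag Sigma'_1 ... diag Sigma'_M]`, length `2 M D`.
#'
#' @param adapted a `gmm` (typically from [map_adapt()]).
#' @param source_id recording identifier to attach.
#' @return an object of class `supervector`: numeric vector with attributes
#'   `M`, `D`, `dimension`, `source_id`.
#' @export
build_supervector <- function(adapted, source_id = NULL) {
  stopifnot(inherits(adapted, "gmm"))
  sv <- c(as.numeric(t(adapted$means)), as.numeric(t(adapted$variances)))
  structure(sv, class = "supervector", M = adapted$M, D = adapted$D,
            dimension = adapted$meta$dimension,
            source_id = source_id %||% adapted$meta$source_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.supervector <- function(x, ...) {
  cat(sprintf("<supervector%s: length %d (M = %d, D = %d)%s>\n",
              if (!is.null(attr(x, "source_id")))
                paste0(" '", attr(x, "source_id"), "'") else "",
              length(x), attr(x, "M"), attr(x, "D"),
              if (!is.null(attr(x, "dimension")))
                paste0(" [", attr(x, "dimension"), "]") else ""))
  invisible(x)
}

#' Adapt a UBM to one recording and build its supervector
#'
#' Composition [sufficient_stats()] -> [map_adapt()] ->
#' [build_supervector()]: one supervector per (recording, speech dimension).
#' Deterministic: identical inputs give bitwise-identical supervectors.
#'
#' @param X the recording's `feature_matrix` in one speech dimension.
#' @param ubm the `gmm` UBM for that dimension.
#' @param cfg an `adaptation_config`.
#' @return a `supervector` of length `2 M D`.
#' @export
adapt_recording <- function(X, ubm, cfg = adaptation_config()) {
  src <- if (inherits(X, "feature_matrix")) X$source_id else NULL
  if (nrow(.fm_values(X)) == 0L)
    stop("no frames to adapt", if (!is.null(src))
      paste0(" for recording '", src, "'") else "")
  stats <- sufficient_stats(X, ubm)
  adapted <- map_adapt(ubm, stats, cfg)
  if (inherits(X, "feature_matrix"))
    adapted$meta$dimension <- X$dimension
  build_supervector(adapted, source_id = src)
}
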