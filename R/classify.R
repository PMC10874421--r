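#' Early fusion of per-dimension supervectors
#'
#' Concatenates one recording's supervectors in the fixed order
#' `[articulation | phonation | prosody]`, regardless of input order.
#'
#' @param svs named list with elements `articulation`, `phonation`,
#'   `prosody` (each a `supervector` or numeric vector).
#' @return numeric vector, the fused supervector.
#' @export
fuse_supervectors <- function(svs) {
  order <- c("articulation", "phonation", "prosody")
  missing <- setdiff(order, names(svs))
  if (length(missing))
    stop("missing speech dimension(s): ", paste(missing, collapse = ", "))
  unlist(lapply(svs[order], as.numeric), use.names = FALSE)
}

#' Train-fitted z-score standardization
#'
#' Standardizes columns using the training partition's means and population
#' standard deviations only; the test partition is transformed with the
#' train statistics. Zero-variance columns map to 0.
#'
#' @param train,test numeric matrices with matching columns (`test` may be
#'   `NULL`).
#' @return list with `train`, `test`, `center`, `scale`.
#' @export
zscore_fit_apply <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("empty training matrix")
  ctr <- colMeans(train)
  sc <- sqrt(colMeans(sweep(train, 2L, ctr)^2))
  sc[!is.finite(sc) | sc == 0] <- 1
  tr <- sweep(sweep(train, 2L, ctr), 2L, sc, "/")
  te <- if (!is.null(test))
    sweep(sweep(as.matrix(test), 2L, ctr), 2L, sc, "/") else NULL
  list(train = tr, test = te, center = ctr, scale = sc)
}

#' Train-fitted PCA reduction at a cumulative-variance threshold
#'
#' Principal components are fitted on the training partition only; the
#' number of retained components is the smallest `k` whose cumulative
#' explained variance reaches `var_kept`.
#'
#' @param train,test numeric matrices (`test` may be `NULL`).
#' @param var_kept cumulative variance fraction to retain (default 0.90).
#' @return list with `train`, `test` (score matrices), `k`, `rotation`,
#'   `center`.
#' @export
pca_reduce <- function(train, test = NULL, var_kept = 0.90) {
  train <- as.matrix(train)
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  cum <- cumsum(v) / sum(v)
  k <- which(cum >= var_kept)[1L]
  if (is.na(k)) k <- length(v)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  tr <- pc$x[, seq_len(k), drop = FALSE]
  te <- if (!is.null(test))
    sweep(as.matrix(test), 2L, pc$center) %*% rot else NULL
  list(train = tr, test = te, k = k, rotation = rot, center = pc$center)
}

#' Classification metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted. For two classes, sensitivity is
#' the recall of the declared positive class and specificity the recall of
#' the other; for more classes both are macro-averaged one-vs-rest
#' (sensitivity = mean per-class recall, specificity = mean per-class true
#' negative rate). All metrics are in percent.
#'
#' @param cm square numeric matrix of nonnegative counts.
#' @param positive for the two-class case, the row index or name of the
#'   positive class (default 1).
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent).
#' @export
metrics_from_confusion <- function(cm, positive = 1L) {
  cm <- as.matrix(cm)
  if (length(cm) == 0L || sum(cm) == 0) stop("empty confusion matrix")
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("negative counts")
  total <- sum(cm)
  acc <- 100 * sum(diag(cm)) / total
  k <- nrow(cm)
  if (is.character(positive)) positive <- match(positive, rownames(cm))
  if (k == 2L) {
    pos <- positive; neg <- setdiff(1:2, pos)
    sens <- 100 * cm[pos, pos] / sum(cm[pos, ])
    spec <- 100 * cm[neg, neg] / sum(cm[neg, ])
  } else {
    recall <- diag(cm) / rowSums(cm)
    tnr <- vapply(seq_len(k), function(i) {
      tn <- total - sum(cm[i, ]) - sum(cm[, i]) + cm[i, i]
      fp <- sum(cm[, i]) - cm[i, i]
      tn / (tn + fp)
    }, numeric(1))
    sens <- 100 * mean(recall)
    spec <- 100 * mean(tnr)
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that within every class the
#' members are dealt round-robin after a seeded shuffle; per-fold class
#' proportions deviate from the global proportions by at most one sample.
#'
#' @param y factor (or vector) of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  fold <- integer(length(y))
  offset <- 0L
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Experiment specification for cross-validated SVM evaluation
#'
#' Bundles the evaluation protocol: stratified `folds`-fold cross-validation
#' repeated `repetitions` times, radial-kernel SVM with cost and kernel
#' width selected per training fold from `c_grid` x `gamma_grid` by
#' stratified `inner_folds`-fold cross-validation, optional PCA at
#' `var_kept` cumulative variance. Default grids:
#' `C` in \{0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5, 10, 50, 100, 500,
#' 1000\} and `gamma` in \{1e-4, 1e-3, ..., 1e3\}.
#'
#' @param folds outer folds (default 10).
#' @param repetitions protocol repetitions (default 10).
#' @param c_grid,gamma_grid SVM hyperparameter grids.
#' @param inner_folds folds of the nested hyperparameter search (default 5).
#' @param var_kept PCA cumulative-variance threshold, or `NULL` for no PCA.
#' @param positive_class positive class label for two-class sensitivity
#'   (default: first factor level).
#' @param seed master seed; per-repetition fold seeds are derived from it.
#' @return an object of class `experiment_spec`.
#' @export
experiment_spec <- function(folds = 10L, repetitions = 10L,
                            c_grid = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5,
                                       1, 5, 10, 50, 100, 500, 1000),
                            gamma_grid = 10^(-4:3),
                            inner_folds = 5L, var_kept = NULL,
                            positive_class = NULL, seed = 1L) {
  stopifnot(folds >= 2L, repetitions >= 1L, length(c_grid) > 0,
            length(gamma_grid) > 0)
  structure(list(folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 c_grid = sort(c_grid), gamma_grid = sort(gamma_grid),
                 inner_folds = as.integer(inner_folds), var_kept = var_kept,
                 positive_class = positive_class, seed = as.integer(seed)),
            class = "experiment_spec")
}

# best (C, gamma) cell of an inner-CV accuracy matrix; ties broken toward
# smaller C, then smaller gamma (grids are sorted ascending)
.pick_grid_cell <- function(acc, c_grid, gamma_grid) {
  best <- max(acc)
  cand <- which(acc >= best - 1e-12, arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  c(cost = c_grid[cand[1L, 1L]], gamma = gamma_grid[cand[1L, 2L]])
}

#' Fit a radial-kernel SVM (one-vs-rest for 3+ classes)
#'
#' Binary problems use a single `e1071::svm` C-classifier; problems with
#' three or more classes train one classifier per class against the rest and
#' predict by the largest decision value.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y factor of class labels.
#' @param cost,gamma SVM hyperparameters.
#' @return an object of class `ovr_svm`.
#' @export
svm_ovr_fit <- function(x, y, cost = 1, gamma = 1 / ncol(x)) {
  y <- droplevels(as.factor(y))
  x <- as.matrix(x)
  lev <- levels(y)
  if (length(lev) < 2L) stop("need at least two classes")
  if (length(lev) == 2L) {
    ybin <- factor(ifelse(y == lev[1L], "pos", "neg"),
                   levels = c("pos", "neg"))
    fits <- list(e1071::svm(x, ybin, type = "C-classification",
                            kernel = "radial", cost = cost, gamma = gamma,
                            scale = FALSE))
  } else {
    fits <- lapply(lev, function(cl) {
      ybin <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
      e1071::svm(x, ybin, type = "C-classification", kernel = "radial",
                 cost = cost, gamma = gamma, scale = FALSE)
    })
  }
  structure(list(fits = fits, levels = lev, cost = cost, gamma = gamma),
            class = "ovr_svm")
}

# decision values of one binary fit, oriented so positive = the "pos" label
.binary_score <- function(fit, x) {
  p <- stats::predict(fit, x, decision.values = TRUE)
  d <- attr(p, "decision.values")
  s <- d[, 1L]
  if (grepl("^neg", colnames(d)[1L])) s <- -s
  unname(s)
}

#' Signed SVM decision scores
#'
#' For a binary model, one signed distance to the separating surface per
#' sample, positive on the first-level side (the predicted label is the sign
#' of the score). For a one-vs-rest model, one column of scores per class;
#' the predicted class is the column-wise maximum.
#'
#' @param model an `ovr_svm` from [svm_ovr_fit()].
#' @param samples numeric matrix of samples to score.
#' @return numeric vector (binary) or matrix with one column per class.
#' @export
decision_scores <- function(model, samples) {
  stopifnot(inherits(model, "ovr_svm"))
  samples <- as.matrix(samples)
  if (length(model$levels) == 2L)
    return(.binary_score(model$fits[[1L]], samples))
  out <- vapply(model$fits, .binary_score, numeric(nrow(samples)),
                x = samples)
  out <- matrix(out, nrow = nrow(samples))
  colnames(out) <- model$levels
  out
}

#' @export
predict.ovr_svm <- function(object, newdata, ...) {
  s <- decision_scores(object, newdata)
  if (length(object$levels) == 2L) {
    factor(ifelse(s >= 0, object$levels[1L], object$levels[2L]),
           levels = object$levels)
  } else {
    factor(object$levels[max.col(s)], levels = object$levels)
  }
}

#' Repeated stratified cross-validated SVM evaluation
#'
#' The package's evaluation engine. For each of `spec$repetitions`
#' repetitions a stratified `spec$folds`-fold split is drawn; inside every
#' training fold the pipeline is z-score standardization (train statistics
#' only), optional PCA at `spec$var_kept` cumulative variance, and a
#' `(C, gamma)` grid search scored by stratified `spec$inner_folds`-fold
#' cross-validation; the selected model is then fit on the whole training
#' fold and evaluated on the held-out fold. Accuracy is reported as mean and
#' standard deviation over repetitions; the confusion matrix is pooled over
#' folds and averaged over repetitions; the selected hyperparameters are the
#' mode over all folds and repetitions (ties toward smaller `C`, then
#' smaller `gamma`).
#'
#' @param x numeric matrix of supervectors (rows = recordings).
#' @param y class labels (factor or coercible).
#' @param spec an [experiment_spec()].
#' @return an object of class `cv_result`.
#' @export
run_experiment <- function(x, y, spec = experiment_spec()) {
  x <- as.matrix(x)
  if (length(y) != nrow(x)) stop("labels and rows differ in length")
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  counts <- table(y)
  short <- names(counts)[counts < spec$folds]
  if (length(short))
    stop("class(es) with fewer samples than folds: ",
         paste(short, collapse = ", "))
  n <- nrow(x)
  k <- spec$folds
  n_classes <- length(lev)
  rep_acc <- numeric(spec$repetitions)
  sel <- matrix(NA_real_, spec$repetitions * k, 2L,
                dimnames = list(NULL, c("cost", "gamma")))
  conf_sum <- matrix(0, n_classes, n_classes, dimnames = list(lev, lev))
  score_rows <- vector("list", spec$repetitions * k)

  for (rep in seq_len(spec$repetitions)) {
    rep_seed <- .derive_seed(spec$seed, rep)
    fold <- stratified_folds(y, k, rep_seed)
    pred <- factor(rep(lev[1L], n), levels = lev)
    for (f in seq_len(k)) {
      tr <- which(fold != f); te <- which(fold == f)
      z <- zscore_fit_apply(x[tr, , drop = FALSE], x[te, , drop = FALSE])
      xtr <- z$train; xte <- z$test
      if (!is.null(spec$var_kept)) {
        p <- pca_reduce(xtr, xte, spec$var_kept)
        xtr <- p$train; xte <- p$test
      }
      inner_id <- stratified_folds(y[tr], spec$inner_folds,
                                   .derive_seed(rep_seed, f))
      d2 <- as.matrix(stats::dist(xtr))^2
      acc_grid <- .svm_grid_cv(d2, as.integer(y[tr]), n_classes,
                               spec$c_grid, spec$gamma_grid,
                               inner_id, spec$inner_folds)
      cell <- .pick_grid_cell(acc_grid, spec$c_grid, spec$gamma_grid)
      model <- svm_ovr_fit(xtr, y[tr], cost = cell[["cost"]],
                           gamma = cell[["gamma"]])
      pred[te] <- predict(model, xte)
      sc <- decision_scores(model, xte)
      row_id <- (rep - 1L) * k + f
      sel[row_id, ] <- cell
      score_rows[[row_id]] <- data.frame(
        repetition = rep, fold = f, index = te,
        truth = as.character(y[te]), predicted = as.character(pred[te]),
        score = if (n_classes == 2L) sc else apply(sc, 1L, max),
        stringsAsFactors = FALSE)
    }
    rep_acc[rep] <- mean(pred == y)
    conf_sum <- conf_sum + unclass(table(y, pred))
  }

  confusion <- conf_sum / spec$repetitions
  positive <- spec$positive_class %||% lev[1L]
  metrics <- metrics_from_confusion(confusion, positive = positive)
  sel_mode <- .modal_cell(sel)
  structure(list(
    accuracy_mean = 100 * mean(rep_acc),
    accuracy_sd = 100 * stats::sd(rep_acc),
    per_repetition_accuracy = 100 * rep_acc,
    sensitivity = metrics$sensitivity,
    specificity = metrics$specificity,
    confusion = confusion,
    selected_cost = sel_mode[["cost"]],
    selected_gamma = sel_mode[["gamma"]],
    selections = as.data.frame(sel),
    scores = do.call(rbind, score_rows),
    classes = lev, positive_class = positive, n = n, spec = spec),
    class = "cv_result")
}

# modal (cost, gamma) pair; ties toward smaller cost then smaller gamma
.modal_cell <- function(sel) {
  key <- paste(sel[, 1L], sel[, 2L], sep = "|")
  tab <- table(key)
  cand <- names(tab)[tab == max(tab)]
  parts <- do.call(rbind, strsplit(cand, "|", fixed = TRUE))
  vals <- apply(parts, 2L, as.numeric)
  vals <- matrix(vals, ncol = 2L)
  ord <- order(vals[, 1L], vals[, 2L])
  c(cost = vals[ord[1L], 1L], gamma = vals[ord[1L], 2L])
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d classes, n = %d>\n", length(x$classes), x$n))
  cat(sprintf("accuracy: %.1f +/- %.1f %% (%d x %d-fold CV)\n",
              x$accuracy_mean, x$accuracy_sd, x$spec$repetitions,
              x$spec$folds))
  cat(sprintf("sensitivity: %.1f %%  specificity: %.1f %%%s\n",
              x$sensitivity, x$specificity,
              if (length(x$classes) == 2L)
                paste0("  (positive: ", x$positive_class, ")") else
                "  (macro one-vs-rest)"))
  cat(sprintf("modal hyperparameters: C = %g, gamma = %g\n",
              x$selected_cost, x$selected_gamma))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  print(object)
  cat("\nconfusion matrix (mean counts per repetition; rows = truth):\n")
  print(round(object$confusion, 1))
  invisible(object)
}

#' @export
plot.cv_result <- function(x, ...) {
  s <- x$scores
  if (length(x$classes) == 2L) {
    pos <- s$truth == x$positive_class
    br <- pretty(s$score, 30)
    h1 <- graphics::hist(s$score[pos], breaks = br, plot = FALSE)
    h2 <- graphics::hist(s$score[!pos], breaks = br, plot = FALSE)
    ylim <- c(0, max(h1$counts, h2$counts))
    graphics::plot(h1, col = grDevices::adjustcolor("firebrick", 0.5),
                   ylim = ylim, main = "SVM decision scores",
                   xlab = "signed distance to hyperplane", ...)
    graphics::plot(h2, col = grDevices::adjustcolor("steelblue", 0.5),
                   add = TRUE)
    graphics::abline(v = 0, lty = 2)
    graphics::legend("topright", legend = c(x$positive_class, "other"),
                     fill = c("firebrick", "steelblue"))
  } else {
    graphics::boxplot(score ~ truth, data = s, main = "winning decision score",
                      xlab = "true class", ylab = "max one-vs-rest score", ...)
  }
  invisible(x)
}

#' Two-dimensional linear discriminant projection
#'
#' Projects samples to the leading two linear discriminants for plotting.
#' Rank-deficient inputs are first rotated to their principal-component
#' subspace (removing collinear directions); if the within-class scatter is
#' still singular, a shrinkage estimate is used. With two classes, the
#' single discriminant is returned as the first coordinate and the second
#' coordinate is 0.
#'
#' @param x numeric feature matrix.
#' @param y class labels.
#' @return `n x 2` matrix of projection coordinates.
#' @export
lda_project <- function(x, y) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  pc <- stats::prcomp(x, center = TRUE)
  keep <- pc$sdev > max(pc$sdev) * 1e-8
  keep[seq_len(min(2L, length(keep)))] <- TRUE
  z <- pc$x[, keep, drop = FALSE]
  scal <- tryCatch(
    stats::predict(MASS::lda(z, grouping = y))$x,
    error = function(e) .shrinkage_lda(z, y))
  out <- matrix(0, nrow(x), 2L)
  take <- min(2L, ncol(scal))
  out[, seq_len(take)] <- scal[, seq_len(take)]
  colnames(out) <- c("LD1", "LD2")
  out
}

# eigendecomposition LDA with ridge-shrunk within-class scatter
.shrinkage_lda <- function(z, y, lambda = 1e-3) {
  lev <- levels(y)
  d <- ncol(z)
  gm <- colMeans(z)
  sw <- matrix(0, d, d); sb <- matrix(0, d, d)
  for (cl in lev) {
    zi <- z[y == cl, , drop = FALSE]
    mi <- colMeans(zi)
    ci <- sweep(zi, 2L, mi)
    sw <- sw + crossprod(ci)
    sb <- sb + nrow(zi) * tcrossprod(mi - gm)
  }
  sw <- sw + lambda * mean(diag(sw)) * diag(d)
  e <- eigen(solve(sw, sb))
  v <- Re(e$vectors[, seq_len(min(2L, length(lev) - 1L)), drop = FALSE])
  sweep(z, 2L, gm) %*% v
}
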