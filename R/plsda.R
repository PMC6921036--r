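#' PLS-DA classification of peptides
#'
#' Partial least squares discriminant analysis: ordinary PLS1 regression of a
#' 0/1 class response on the autoscaled descriptor matrix, computed by the
#' NIPALS algorithm with deflation, followed by thresholding of the
#' continuous prediction at 0.5.  Latent components are extracted
#' sequentially; each captures the direction of maximal covariance between
#' the residual descriptors and the residual response.
#'
#' @name plsda
NULL

# NIPALS extraction of one PLS1 component from (deflated) Xc, yc.
# Start vector: the X column of maximal variance; convergence on the change
# in the weight vector.
nipals_component <- function(xc, yc, comp, tol = 1e-10, max_iter = 500) {
  start_col <- which.max(apply(xc, 2, stats::var))
  u <- if (all(yc == 0)) xc[, start_col] else yc
  w_old <- rep(0, ncol(xc))
  for (iter in seq_len(max_iter)) {
    w <- drop(crossprod(xc, u))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      abort(sprintf("NIPALS failed on component %d: zero weight vector.", comp))
    }
    w <- w / nw
    t_score <- drop(xc %*% w)
    q <- sum(yc * t_score) / sum(t_score^2)
    u <- yc * q
    if (sqrt(sum((w - w_old)^2)) < tol) {
      return(list(w = w, t = t_score, q = q))
    }
    w_old <- w
  }
  abort(sprintf("NIPALS did not converge on component %d within %d iterations.",
                comp, max_iter))
}

#' Fit a PLS-DA model
#'
#' @param x Descriptor matrix or data frame (rows = peptides); typically
#'   [descriptor_matrix()] output.  Columns with zero variance are dropped
#'   with a warning.
#' @param y Binary labels (0/1), length `nrow(x)`; both classes required.
#' @param n_components Number of latent components.  `NULL` (default) picks
#'   the count in `1:max_components` maximising cross-validated Q2; the
#'   selection trace is kept in `training_meta`.
#' @param max_components Upper bound for automatic selection.
#' @param folds,seed Cross-validation settings forwarded to [plsda_q2()]
#'   during automatic selection.
#' @param threshold Class-assignment cut on the continuous prediction.
#' @param sequences Optional peptide sequences of the training rows, stored
#'   for the train/test disjointness check in [plsda_evaluate()].
#' @return An object of class `plsda` storing weights, loadings, regression
#'   state (training-data autoscaling statistics are frozen for prediction),
#'   training scores, fitted values and metadata.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 30, 2)
#' y <- as.integer(x[, 1] + 0.2 * rnorm(30) > 0)
#' fit <- plsda_fit(x, y, n_components = 2)
#' glance(fit)
#' @export
plsda_fit <- function(x, y, n_components = NULL, max_components = 10,
                      folds = 7, seed = 1, threshold = 0.5,
                      sequences = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (nrow(x) != length(y)) abort("nrow(x) must equal length(y).")
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    abort("`y` must be binary 0/1 with both classes present.")
  }
  if (anyNA(x)) abort("Descriptor matrix contains missing values.")

  sds <- apply(x, 2, stats::sd)
  zero_var <- sds < .Machine$double.eps^0.5
  if (any(zero_var)) {
    warn(sprintf("Dropping zero-variance descriptor column(s): %s.",
                 paste(colnames(x)[zero_var], collapse = ", ")))
    x <- x[, !zero_var, drop = FALSE]
    sds <- sds[!zero_var]
  }
  if (ncol(x) == 0) abort("No descriptor columns left after variance filter.")

  selection <- NULL
  if (is.null(n_components)) {
    kmax <- min(max_components, ncol(x), nrow(x) - 1L)
    q2s <- vapply(seq_len(kmax), function(k) {
      plsda_q2(x, y, n_components = k, folds = folds, seed = seed)
    }, numeric(1))
    n_components <- which.max(q2s)
    selection <- tibble(n_components = seq_len(kmax), q2 = q2s)
  }
  kmax_allowed <- min(ncol(x), nrow(x) - 1L)
  if (n_components < 1 || n_components > kmax_allowed) {
    abort(sprintf("n_components must be in 1..%d.", kmax_allowed))
  }

  x_mean <- colMeans(x)
  x_scale <- sds
  y_mean <- mean(y)
  xc <- sweep(sweep(x, 2, x_mean), 2, x_scale, `/`)
  yc <- y - y_mean

  k <- n_components
  p_cols <- ncol(xc)
  W <- matrix(0, p_cols, k)
  P <- matrix(0, p_cols, k)
  Q <- numeric(k)
  Tm <- matrix(0, nrow(xc), k)
  x_residual_norm <- numeric(k)
  for (comp in seq_len(k)) {
    cmp <- nipals_component(xc, yc, comp)
    W[, comp] <- cmp$w
    Tm[, comp] <- cmp$t
    Q[comp] <- cmp$q
    p_load <- drop(crossprod(xc, cmp$t)) / sum(cmp$t^2)
    P[, comp] <- p_load
    xc <- xc - tcrossprod(cmp$t, p_load)
    yc <- yc - cmp$t * cmp$q
    x_residual_norm[comp] <- sqrt(sum(xc^2))
  }
  rownames(W) <- rownames(P) <- colnames(x)

  beta <- W %*% solve(crossprod(P, W), Q)
  fitted_score <- drop(
    sweep(sweep(x, 2, x_mean), 2, x_scale, `/`) %*% beta
  ) + y_mean
  r2 <- 1 - sum((y - fitted_score)^2) / sum((y - mean(y))^2)

  structure(list(
    n_components = k,
    columns = colnames(x),
    x_weights = W, x_loadings = P, y_loadings = Q,
    coefficients = drop(beta),
    x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
    threshold = threshold,
    scores = Tm,
    x_residual_norm = x_residual_norm,
    fitted = fitted_score,
    y = y,
    r_squared = r2,
    sequences = sequences,
    training_meta = list(seed = seed, folds = folds,
                         component_selection = selection)
  ), class = "plsda")
}

#' Predict from a PLS-DA model
#'
#' @param object A [plsda_fit()] model.
#' @param newdata Descriptor matrix/data frame with the training column
#'   schema (order-insensitive; missing or extra columns raise an error).
#' @param type `"both"` (default), `"response"` (continuous score only) or
#'   `"class"`.
#' @param ... Unused.
#' @return A tibble with `score` and/or `class` columns.
#' @export
predict.plsda <- function(object, newdata,
                          type = c("both", "response", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$columns)) {
      abort("Unnamed newdata with wrong number of columns.")
    }
    colnames(newdata) <- object$columns
  }
  missing_cols <- setdiff(object$columns, colnames(newdata))
  extra_cols <- setdiff(colnames(newdata), object$columns)
  if (length(missing_cols) || length(extra_cols)) {
    abort(sprintf(
      "Descriptor schema mismatch. Missing: %s. Extra: %s.",
      if (length(missing_cols)) paste(missing_cols, collapse = ", ") else "none",
      if (length(extra_cols)) paste(extra_cols, collapse = ", ") else "none"
    ))
  }
  newdata <- newdata[, object$columns, drop = FALSE]
  xs <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_scale, `/`)
  score <- drop(xs %*% object$coefficients) + object$y_mean
  cls <- as.integer(score >= object$threshold)
  switch(type,
    response = tibble(score = score),
    class = tibble(class = cls),
    both = tibble(score = score, class = cls)
  )
}

#' Cross-validated Q2 of a PLS-DA fit
#'
#' Q2 = 1 - PRESS/TSS, where PRESS accumulates squared out-of-fold
#' prediction errors of the 0/1 response over a seeded k-fold partition and
#' TSS is the total sum of squares of the response about its mean.
#'
#' @inheritParams plsda_fit
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Seed for the fold-assignment shuffle.
#' @return Scalar Q2 (at most 1; can be negative for models worse than the
#'   mean).
#' @export
plsda_q2 <- function(x, y, n_components, folds = 7, seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (folds < 2 || folds > n) abort("`folds` must be in 2..nrow(x).")
  assign <- withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  press <- 0
  for (f in seq_len(folds)) {
    in_fold <- assign == f
    y_train <- y[!in_fold]
    if (length(unique(y_train)) < 2) {
      abort(sprintf("Degenerate fold %d: training part has one class.", f))
    }
    fit <- suppressWarnings(plsda_fit(
      x[!in_fold, , drop = FALSE], y_train,
      n_components = min(n_components, sum(!in_fold) - 1L,
                         ncol(x))
    ))
    pred <- predict(fit,
                    x[in_fold, fit$columns, drop = FALSE],
                    type = "response")$score
    press <- press + sum((y[in_fold] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Evaluate a PLS-DA model on a held-out labeled peptide set
#'
#' Computes descriptors for the test peptides with the supplied scale,
#' predicts classes, and reports confusion counts plus the four performance
#' metrics.  If the model was fitted with `sequences`, any overlap between
#' training and test sequences is an error (external validation requires
#' disjoint sets).
#'
#' @param model A [plsda_fit()] model.
#' @param test Labeled peptide tibble (`sequence`, `label`), or a list with
#'   `x` (descriptor matrix) and `y` (labels) if descriptors are
#'   precomputed.
#' @param scale,delta_deg Descriptor settings (must match training).
#' @return Object of class `plsda_eval`: list with `counts` (tibble `tp`,
#'   `fn`, `tn`, `fp`), `metrics` (tibble from [confusion_metrics()]),
#'   `predictions`, and `n`.
#' @export
plsda_evaluate <- function(model, test, scale = zscale(), delta_deg = 100) {
  if (is.list(test) && !is.data.frame(test) &&
      all(c("x", "y") %in% names(test))) {
    x <- as.matrix(test$x)[, model$columns, drop = FALSE]
    y <- as.numeric(test$y)
    seqs <- NULL
  } else {
    test <- as_peptide_set(test)
    seqs <- test$sequence
    if (!is.null(model$sequences)) {
      overlap <- intersect(toupper(model$sequences), seqs)
      if (length(overlap)) {
        abort(sprintf(
          "Test set overlaps training set (%d sequence(s)): %s%s",
          length(overlap), paste(utils::head(overlap, 5), collapse = ", "),
          if (length(overlap) > 5) ", ..." else ""
        ))
      }
    }
    desc <- peptide_descriptors(test, scale = scale, delta_deg = delta_deg)
    x <- descriptor_matrix(desc)[, model$columns, drop = FALSE]
    y <- test$label
  }
  pred <- predict(model, x)
  counts <- confusion_counts(y, pred$class)
  structure(list(
    counts = counts,
    metrics = confusion_metrics(counts),
    predictions = bind_cols(tibble(truth = y), pred),
    n = length(y)
  ), class = "plsda_eval")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda: %d component(s), %d descriptor(s), n = %d>\n",
              x$n_components, length(x$columns), length(x$y)))
  cat(sprintf("training R2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' @export
print.plsda_eval <- function(x, ...) {
  cat("<plsda_eval>\n")
  print(x$counts)
  print(x$metrics)
  invisible(x)
}

#' @describeIn plsda Long tibble of per-component weights and loadings.
#' @param x,object A `plsda` model.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.plsda <- function(x, ...) {
  k <- x$n_components
  purrr::map_dfr(seq_len(k), function(j) {
    tibble(component = j, term = x$columns,
           weight = x$x_weights[, j], loading = x$x_loadings[, j],
           y_loading = x$y_loadings[j])
  })
}

#' @describeIn plsda One-row model summary (components, descriptors, n,
#'   training R2).
#' @exportS3Method generics::glance
glance.plsda <- function(x, ...) {
  tibble(n_components = x$n_components, n_descriptors = length(x$columns),
         n_obs = length(x$y), r_squared = x$r_squared)
}

#' @describeIn plsda Latent-score plot (t1 vs t2, colored by class).
#' @exportS3Method ggplot2::autoplot
autoplot.plsda <- function(object, ...) {
  if (object$n_components < 2) {
    abort("Score plot needs at least 2 components.")
  }
  df <- tibble(t1 = object$scores[, 1], t2 = object$scores[, 2],
               class = factor(object$y))
  ggplot2::ggplot(df, ggplot2::aes(.data$t1, .data$t2, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "t1", y = "t2", colour = "class",
                  title = "PLS-DA latent scores")
}

#' Serialize / restore a PLS-DA model as JSON
#'
#' @param model A `plsda` model.
#' @param path JSON file path.
#' @return `path` (write) or the restored `plsda` object (read).
#' @export
write_plsda <- function(model, path) {
  payload <- list(
    n_components = model$n_components,
    columns = model$columns,
    x_weights = model$x_weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings,
    coefficients = model$coefficients,
    x_mean = model$x_mean, x_scale = model$x_scale, y_mean = model$y_mean,
    threshold = model$threshold,
    r_squared = model$r_squared,
    training_meta = model$training_meta[c("seed", "folds")]
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_plsda
#' @export
read_plsda <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- p$n_components
  W <- matrix(unlist(p$x_weights), ncol = k)
  P <- matrix(unlist(p$x_loadings), ncol = k)
  rownames(W) <- rownames(P) <- p$columns
  structure(list(
    n_components = k, columns = p$columns,
    x_weights = W, x_loadings = P,
    y_loadings = as.numeric(p$y_loadings),
    coefficients = stats::setNames(as.numeric(p$coefficients), p$columns),
    x_mean = stats::setNames(as.numeric(p$x_mean), p$columns),
    x_scale = stats::setNames(as.numeric(p$x_scale), p$columns),
    y_mean = p$y_mean, threshold = p$threshold,
    r_squared = p$r_squared,
    sequences = NULL,
    training_meta = p$training_meta
  ), class = "plsda")
}
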