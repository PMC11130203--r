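#' Forward step-wise linear regression baseline
#'
#' A simple documented baseline: greedy forward selection of descriptors by
#' validation MSE on a single seeded 80/20 split, skipping any candidate
#' whose absolute Pearson correlation with an already selected descriptor
#' exceeds `collinearity` (default 0.3). Selection stops when no candidate
#' improves the validation MSE or `max_features` is reached. This is a
#' plain reference point for the composite model, not a tuned method.
#'
#' @param table a labeled [reaction_table].
#' @param view feature view.
#' @param collinearity collinearity cutoff on |r| (default 0.3).
#' @param max_features cap on the number of selected descriptors.
#' @param seed integer seed for the split.
#' @return an object of class `stepwise_lr` with `selected` (feature names)
#'   and a [predict][predict.stepwise_lr] method.
#' @export
stepwise_lr <- function(table, view = "all", collinearity = 0.3,
                        max_features = 25, seed = 1L) {
  stopifnot(inherits(table, "reaction_table"))
  if (is.null(table$target)) stop("data error: table has no target",
                                  call. = FALSE)
  tab <- subset_by_view(table, view)
  x <- tab$features; y <- tab$target
  n <- nrow(x)
  set.seed(seed)
  idx <- sample.int(n, floor(0.8 * n))
  xt <- x[idx, , drop = FALSE]; yt <- y[idx]
  xv <- x[-idx, , drop = FALSE]; yv <- y[-idx]
  selected <- character()
  best_mse <- mse(yv, rep(mean(yt), length(yv)))
  repeat {
    if (length(selected) >= max_features) break
    cand <- setdiff(colnames(x), selected)
    if (length(selected))
      cand <- cand[vapply(cand, function(f)
        all(abs(suppressWarnings(stats::cor(xt[, f],
                                            xt[, selected, drop = FALSE]))) <=
              collinearity, na.rm = TRUE), TRUE)]
    if (!length(cand)) break
    scores <- vapply(cand, function(f) {
      df <- data.frame(y = yt, xt[, c(selected, f), drop = FALSE])
      fit <- stats::lm(y ~ ., data = df)
      nd <- data.frame(xv[, c(selected, f), drop = FALSE])
      mse(yv, stats::predict(fit, newdata = nd))
    }, 0)
    if (min(scores) >= best_mse) break
    pick <- names(which.min(scores))
    selected <- c(selected, pick)
    best_mse <- min(scores)
  }
  df <- data.frame(y = y, x[, selected, drop = FALSE])
  structure(list(fit = stats::lm(y ~ ., data = df), selected = selected,
                 view = view, collinearity = collinearity,
                 validation_mse = best_mse, seed = as.integer(seed)),
            class = "stepwise_lr")
}

#' @export
predict.stepwise_lr <- function(object, table, ...) {
  x <- if (inherits(table, "reaction_table")) table$features else
    as.matrix(table)
  missing_f <- setdiff(object$selected, colnames(x))
  if (length(missing_f))
    stop("schema error: table lacks feature '", missing_f[1], "'",
         call. = FALSE)
  nd <- data.frame(x[, object$selected, drop = FALSE])
  unname(stats::predict(object$fit, newdata = nd))
}

#' @export
print.stepwise_lr <- function(x, ...) {
  cat(sprintf("Forward step-wise LR baseline (|r| <= %s collinearity screen)\n",
              format(x$collinearity)))
  cat("  selected:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("  validation MSE %.4g\n", x$validation_mse))
  invisible(x)
}
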