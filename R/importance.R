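#' Permutation feature importance
#'
#' The importance of a descriptor is the increase in the model's MSE when
#' that column is randomly shuffled across the evaluation rows while all
#' other columns are held fixed: per replication,
#' \eqn{I_j = MSE(\hat y^{(j)}) - MSE(\hat y)}. Means and standard
#' deviations are taken over `n_replications` independent shuffles.
#' Importance is evaluated on the supplied (typically training) table.
#'
#' @param model a `reaction_fit`.
#' @param table a labeled [reaction_table] containing all model features.
#' @param n_replications number of shuffles per feature (default 100).
#' @param seed integer seed.
#' @return an object of class `perm_importance`: `per_feature` data frame
#'   (`feature`, `role`, `mean`, `sd`), `baseline_mse`, `n_replications`.
#' @export
permutation_importance <- function(model, table, n_replications = 100,
                                   seed = 1L) {
  stopifnot(inherits(model, "reaction_fit"))
  if (is.null(table$target)) stop("table has no target", call. = FALSE)
  x <- .model_matrix_from_table(model, table)
  n <- nrow(x)
  if (n < 2) stop("data error: need at least 2 rows to permute",
                  call. = FALSE)
  y <- table$target
  baseline <- mse(y, .predict_matrix(model, x))
  p <- ncol(x)
  seeds <- .spawn_seeds(seed, n_replications)
  scores <- matrix(NA_real_, n_replications, p,
                   dimnames = list(NULL, colnames(x)))
  for (r in seq_len(n_replications)) {
    set.seed(seeds[r])
    perms <- replicate(p, sample.int(n))
    for (j in seq_len(p)) {
      xs <- x
      xs[, j] <- x[perms[, j], j]
      scores[r, j] <- mse(y, .predict_matrix(model, xs)) - baseline
    }
  }
  per <- data.frame(feature = colnames(x),
                    role = unname(model$roles[colnames(x)]),
                    mean = colMeans(scores),
                    sd = apply(scores, 2, stats::sd),
                    row.names = NULL)
  structure(list(per_feature = per, baseline_mse = baseline,
                 n_replications = n_replications, kind = model$kind,
                 seed = as.integer(seed)),
            class = "perm_importance")
}

#' @export
print.perm_importance <- function(x, k = 8, ...) {
  cat(sprintf("Permutation importance (%s, %d replications, baseline MSE %.4g)\n",
              x$kind, x$n_replications, x$baseline_mse))
  ord <- order(-x$per_feature$mean, x$per_feature$feature)
  print(utils::head(x$per_feature[ord, ], k), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Top-ranked features by permutation importance
#'
#' Features are sorted by mean importance (descending), ties broken
#' alphabetically; the list may be restricted to one molecule role.
#'
#' @param result a `perm_importance`.
#' @param k number of features to return.
#' @param role_filter optional molecule role to restrict to.
#' @return character vector of at most `k` feature names.
#' @export
top_features <- function(result, k, role_filter = NULL) {
  stopifnot(inherits(result, "perm_importance"), k >= 1)
  pf <- result$per_feature
  if (!is.null(role_filter)) pf <- pf[pf$role == role_filter, , drop = FALSE]
  pf <- pf[order(-pf$mean, pf$feature), , drop = FALSE]
  utils::head(pf$feature, k)
}

#' Partial dependence of predicted enantioselectivity on one descriptor
#'
#' For each of `grid_size` equally spaced values between the observed
#' minimum and maximum of the descriptor, the descriptor is set to that
#' value in every reaction and predictions are averaged — the expected
#' prediction as a function of the descriptor, marginalising over the
#' observed values of all other descriptors.
#'
#' @param model a `reaction_fit`.
#' @param table a [reaction_table] containing all model features.
#' @param feature_name descriptor to vary; must be non-constant in `table`.
#' @param grid_size number of grid points (>= 2, default 20).
#' @return an object of class `partial_dependence`: `grid`,
#'   `averaged_prediction` and `range` (max minus min of the curve).
#' @export
partial_dependence <- function(model, table, feature_name, grid_size = 20) {
  stopifnot(inherits(model, "reaction_fit"), grid_size >= 2)
  if (!feature_name %in% model$feature_names)
    stop("schema error: model has no feature '", feature_name, "'",
         call. = FALSE)
  x <- .model_matrix_from_table(model, table)
  v <- x[, feature_name]
  if (max(v) == min(v))
    stop("degenerate data: feature '", feature_name, "' is constant",
         call. = FALSE)
  grid <- seq(min(v), max(v), length.out = grid_size)
  avg <- vapply(grid, function(g) {
    xs <- x
    xs[, feature_name] <- g
    mean(.predict_matrix(model, xs))
  }, 0)
  structure(list(feature_name = feature_name, grid = grid,
                 averaged_prediction = avg, range = max(avg) - min(avg)),
            class = "partial_dependence")
}

#' @export
print.partial_dependence <- function(x, ...) {
  cat(sprintf("Partial dependence of ddG on '%s' (%d grid points)\n",
              x$feature_name, length(x$grid)))
  cat(sprintf("  prediction range: %.4g kcal/mol\n", x$range))
  invisible(x)
}

#' @export
plot.partial_dependence <- function(x, ...) {
  graphics::plot(x$grid, x$averaged_prediction, type = "l",
                 xlab = x$feature_name,
                 ylab = "expected ddG (kcal/mol)", ...)
  invisible(x)
}
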