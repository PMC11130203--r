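.regressor_kinds <- c("lasso", "decision_tree", "random_forest",
                      "gradient_boosting", "svr")

# each learner exposes exactly one tuned hyperparameter
.hp_names <- c(lasso = "alpha", decision_tree = "min_split",
               random_forest = "num_trees", gradient_boosting = "num_iter",
               svr = "C")

.check_hp <- function(kind, hp) {
  expected <- .hp_names[[kind]]
  if (!is.numeric(hp) || length(hp) != 1 || is.null(names(hp)) ||
      names(hp) != expected)
    stop("configuration error: ", kind, " expects a single hyperparameter ",
         "named '", expected, "'", call. = FALSE)
  v <- unname(hp)
  ok <- switch(expected,
               alpha = v > 0, C = v > 0,
               min_split = v >= 2 && v == round(v),
               num_trees = v >= 1 && v == round(v),
               num_iter = v >= 1 && v == round(v))
  if (!ok) stop("configuration error: invalid value ", v, " for '", expected,
                "'", call. = FALSE)
  v
}

#' Default tuned-hyperparameter settings
#'
#' Reference optima for the five learners on the all-features view of the
#' chiral-phosphoric-acid benchmark: LASSO alpha 0.016, decision-tree
#' minimum split 4, gradient-boosting iterations 93, random-forest trees 69,
#' SVR cost 9.99.
#'
#' @param kind one of `"lasso"`, `"decision_tree"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"svr"`.
#' @return a named length-1 numeric vector suitable for [fit_regressor()].
#' @export
default_hp <- function(kind = .regressor_kinds) {
  kind <- match.arg(kind)
  switch(kind,
         lasso = c(alpha = 0.016),
         decision_tree = c(min_split = 4),
         random_forest = c(num_trees = 69),
         gradient_boosting = c(num_iter = 93),
         svr = c(C = 9.99))
}

# internal feature prep: apply view, order columns, return matrix + scaling.
# scale-sensitive learners (lasso, svr) are fit on z-scored features with
# training statistics; constant columns keep scale 1.
.prep_train <- function(table, kind, view) {
  tab <- subset_by_view(table, view)
  x <- tab$features
  scaled <- kind %in% c("lasso", "svr")
  if (scaled) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
    names(ctr) <- names(scl) <- colnames(x)
  }
  list(x = x, y = tab$target, center = ctr, scale = scl, scaled = scaled,
       feature_names = colnames(x), roles = tab$roles)
}

.zscore <- function(x, center, scale) sweep(sweep(x, 2, center), 2, scale, "/")

#' Fit one of the five base regressors
#'
#' Fits a single learner for enantioselectivity prediction under a uniform
#' contract: LASSO (glmnet, penalty `alpha`), a CART decision tree (rpart,
#' `min_split`), a random forest (`num_trees`), gradient boosting
#' (xgboost, `num_iter` rounds at learning rate 0.1, depth 3), or
#' radial-basis support vector regression (e1071, cost `C`). Features are
#' z-scored with training statistics before the LASSO and SVR fits;
#' tree-based learners consume raw descriptors. Fits are deterministic
#' given `seed`.
#'
#' @param table a labeled [reaction_table].
#' @param kind learner kind; see [default_hp()] for the five names.
#' @param hp named length-1 numeric hyperparameter (name must match the
#'   kind); defaults to [default_hp()].
#' @param view feature view to train on, see [subset_by_view()].
#' @param seed integer seed threaded to every stochastic learner.
#' @return an object of class `reaction_fit` with a [predict][predict.reaction_fit]
#'   method.
#' @export
fit_regressor <- function(table, kind = .regressor_kinds, hp = default_hp(kind),
                          view = "all", seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(table, "reaction_table"))
  if (is.null(table$target)) stop("data error: table has no target",
                                  call. = FALSE)
  if (nrow(table$features) < 2) stop("data error: need at least 2 reactions",
                                     call. = FALSE)
  hv <- .check_hp(kind, hp)
  prep <- .prep_train(table, kind, view)
  x <- if (prep$scaled) .zscore(prep$x, prep$center, prep$scale) else prep$x
  y <- prep$y
  set.seed(seed)
  fit <- switch(
    kind,
    lasso = {
      if (stats::sd(y) == 0) {
        # intercept-only degenerate fit; coordinate descent needs variation
        list(constant = y[1])
      } else {
        glmnet::glmnet(x, y, alpha = 1, lambda = hv, standardize = FALSE,
                       thresh = 1e-10)
      }
    },
    svr = {
      if (stats::sd(y) == 0) list(constant = y[1])
      else e1071::svm(x = x, y = y, type = "eps-regression",
                      kernel = "radial", cost = hv, scale = FALSE)
    },
    decision_tree = {
      df <- data.frame(.y = y, x)
      names(df) <- c(".y", paste0("V", seq_len(ncol(x))))
      rpart::rpart(.y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(minsplit = hv, cp = 0,
                                                  xval = 0, maxdepth = 30,
                                                  maxsurrogate = 0))
    },
    random_forest = randomForest::randomForest(x = x, y = y, ntree = hv),
    gradient_boosting = {
      dtr <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                       eta = 0.1, max_depth = 3,
                                       subsample = 1, nthread = 1,
                                       seed = seed),
                         data = dtr, nrounds = hv, verbose = 0)
    }
  )
  structure(list(kind = kind, hp = stats::setNames(hv, .hp_names[[kind]]),
                 view = view, feature_names = prep$feature_names,
                 roles = prep$roles, center = prep$center,
                 scale = prep$scale, scaled = prep$scaled,
                 fit = fit, seed = as.integer(seed)),
            class = "reaction_fit")
}

# prediction from a raw (unscaled, view-ordered) feature matrix
.predict_matrix <- function(object, x) {
  if (object$scaled) x <- .zscore(x, object$center, object$scale)
  out <- switch(
    object$kind,
    lasso = {
      if (is.list(object$fit) && !is.null(object$fit$constant))
        rep(object$fit$constant, nrow(x))
      else as.numeric(stats::predict(object$fit, newx = x))
    },
    decision_tree = {
      df <- data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(x)))
      as.numeric(stats::predict(object$fit, newdata = df))
    },
    random_forest = as.numeric(stats::predict(object$fit, newdata = x)),
    gradient_boosting = as.numeric(
      stats::predict(object$fit, newdata = xgboost::xgb.DMatrix(x, nthread = 1))),
    svr = {
      if (is.list(object$fit) && !is.null(object$fit$constant))
        rep(object$fit$constant, nrow(x))
      else as.numeric(stats::predict(object$fit, newdata = x))
    }
  )
  unname(out)
}

# extract the model's feature columns (in training order) from a table
.model_matrix_from_table <- function(object, table) {
  stopifnot(inherits(table, "reaction_table"))
  missing_f <- setdiff(object$feature_names, colnames(table$features))
  if (length(missing_f))
    stop("schema error: table lacks model feature '", missing_f[1], "'",
         call. = FALSE)
  table$features[, object$feature_names, drop = FALSE]
}

#' Predict enantioselectivity from a fitted base regressor
#'
#' @param object a `reaction_fit` from [fit_regressor()].
#' @param table a [reaction_table] containing all of the model's features
#'   (extra columns are ignored), or a numeric matrix with named columns.
#' @param ... unused.
#' @return numeric vector of predicted \eqn{\Delta\Delta G^\ddag} (kcal/mol),
#'   one per row.
#' @export
predict.reaction_fit <- function(object, table, ...) {
  x <- if (inherits(table, "reaction_table"))
    .model_matrix_from_table(object, table)
  else {
    x0 <- as.matrix(table)
    missing_f <- setdiff(object$feature_names, colnames(x0))
    if (length(missing_f))
      stop("schema error: matrix lacks model feature '", missing_f[1], "'",
           call. = FALSE)
    x0[, object$feature_names, drop = FALSE]
  }
  .predict_matrix(object, x)
}

#' @export
print.reaction_fit <- function(x, ...) {
  cat("Enantioselectivity regressor: ", x$kind, "\n", sep = "")
  cat("  view: ", x$view, "   features: ", length(x$feature_names), "\n",
      sep = "")
  cat("  ", names(x$hp), " = ", format(x$hp), "   seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# ---- model persistence -----------------------------------------------------

.archive_schema <- 1L

#' Save or load a fitted regressor
#'
#' Persists a `reaction_fit` as a self-describing archive (kind, view,
#' hyperparameter, feature names, standardization statistics, learner state)
#' with a schema version. A load round-trip preserves predictions bit for
#' bit. Gradient-boosting handles are serialised through xgboost's raw
#' format so they survive the session.
#'
#' @param object a `reaction_fit`.
#' @param path file path for the archive.
#' @return `save_regressor()`: the path, invisibly; `load_regressor()`: the
#'   restored `reaction_fit`.
#' @export
save_regressor <- function(object, path) {
  stopifnot(inherits(object, "reaction_fit"))
  payload <- unclass(object)
  if (object$kind == "gradient_boosting")
    payload$fit <- xgboost::xgb.save.raw(object$fit)
  saveRDS(list(schema = .archive_schema, class = "reaction_fit",
               payload = payload), path)
  invisible(path)
}

#' @rdname save_regressor
#' @export
load_regressor <- function(path) {
  arch <- readRDS(path)
  if (!identical(arch$schema, .archive_schema) ||
      !identical(arch$class, "reaction_fit"))
    stop("unrecognised model archive", call. = FALSE)
  obj <- arch$payload
  if (obj$kind == "gradient_boosting")
    obj$fit <- xgboost::xgb.load.raw(obj$fit)
  class(obj) <- "reaction_fit"
  obj
}
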