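#' Define a hyperparameter search space
#'
#' @param name hyperparameter name (one of `alpha`, `min_split`, `num_trees`,
#'   `num_iter`, `C`).
#' @param lower,upper bounds, `lower < upper`; log scale requires
#'   `lower > 0`.
#' @param scale `"linear"` or `"log"` optimisation scale.
#' @param integer_valued round to the nearest integer at evaluation.
#' @return an object of class `search_space`.
#' @export
search_space <- function(name, lower, upper, scale = c("linear", "log"),
                         integer_valued = FALSE) {
  scale <- match.arg(scale)
  if (!(lower < upper))
    stop("configuration error: need lower < upper", call. = FALSE)
  if (scale == "log" && lower <= 0)
    stop("configuration error: log scale requires lower > 0", call. = FALSE)
  structure(list(name = name, lower = lower, upper = upper, scale = scale,
                 integer_valued = integer_valued), class = "search_space")
}

#' Default search space for a learner's key hyperparameter
#'
#' alpha in \[1e-4, 1\] (log), C in \[0.1, 10\] (log), min_split in
#' \[2, 20\], num_iter and num_trees in \[10, 200\] (integers). The ranges
#' bracket all the reference optima.
#'
#' @param kind learner kind.
#' @return a [search_space].
#' @export
default_search_space <- function(kind = .regressor_kinds) {
  kind <- match.arg(kind)
  switch(kind,
         lasso = search_space("alpha", 1e-4, 1, "log"),
         svr = search_space("C", 0.1, 10, "log"),
         decision_tree = search_space("min_split", 2, 20, "linear", TRUE),
         random_forest = search_space("num_trees", 10, 200, "linear", TRUE),
         gradient_boosting = search_space("num_iter", 10, 200, "linear", TRUE))
}

# unit interval <-> hyperparameter value
.from_unit <- function(u, space) {
  v <- if (space$scale == "log")
    exp(log(space$lower) + u * (log(space$upper) - log(space$lower)))
  else space$lower + u * (space$upper - space$lower)
  if (space$integer_valued) v <- round(v)
  pmin(pmax(v, space$lower), space$upper)
}

# Exact 1-d Gaussian-process regression with a squared-exponential kernel.
# The lengthscale is picked from a small grid by marginal likelihood; a
# nugget keeps the Cholesky stable and absorbs duplicate design points.
.gp_fit <- function(u, y) {
  ybar <- mean(y); ysd <- stats::sd(y); if (ysd == 0) ysd <- 1
  yc <- (y - ybar) / ysd
  best <- NULL
  for (ell in c(0.05, 0.1, 0.2, 0.5, 1)) {
    K <- exp(-outer(u, u, "-")^2 / (2 * ell^2)) + diag(1e-6, length(u))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    ml <- -0.5 * sum(yc * alpha) - sum(log(diag(ch)))
    if (is.null(best) || ml > best$ml)
      best <- list(ml = ml, ell = ell, ch = ch, alpha = alpha)
  }
  c(best, list(u = u, ybar = ybar, ysd = ysd))
}

.gp_predict <- function(gp, unew) {
  ks <- exp(-outer(unew, gp$u, "-")^2 / (2 * gp$ell^2))
  mu <- as.numeric(ks %*% gp$alpha)
  v <- backsolve(gp$ch, forwardsolve(t(gp$ch), t(ks)))
  s2 <- pmax(1 - colSums(v * v), 1e-12)
  list(mean = mu * gp$ysd + gp$ybar, sd = sqrt(s2) * gp$ysd)
}

# expected improvement for minimisation
.expected_improvement <- function(mu, sd, best) {
  d <- best - mu
  z <- d / sd
  ei <- d * stats::pnorm(z) + sd * stats::dnorm(z)
  ei[sd <= 0] <- 0
  ei
}

#' Bayesian optimisation of a learner's key hyperparameter
#'
#' Minimises validation MSE over a one-dimensional search space. One fixed
#' 80/20 train/validation split is drawn from `seed` (the validation rows
#' are 20% of the supplied training table). The first quarter of the budget
#' is a space-filling design (always containing the space midpoint); the
#' remaining evaluations are chosen by expected improvement under a
#' Gaussian-process surrogate fitted on the scaled hyperparameter.
#'
#' @param table a labeled [reaction_table].
#' @param kind learner kind.
#' @param view feature view.
#' @param space a [search_space]; defaults to [default_search_space()].
#' @param budget total number of objective evaluations (>= 5, default 25).
#' @param seed integer seed controlling the split, the learner fits and the
#'   surrogate loop.
#' @return an object of class `tuning_result`: `best_setting` (named
#'   hyperparameter for [fit_regressor()]), `best_validation_mse`, and the
#'   full `trace` data frame (`value`, `mse`).
#' @export
bayes_optimize <- function(table, kind, view = "all",
                           space = default_search_space(kind), budget = 25,
                           seed = 1L) {
  kind <- match.arg(kind, .regressor_kinds)
  stopifnot(inherits(space, "search_space"))
  if (space$name != .hp_names[[kind]])
    stop("configuration error: space '", space$name, "' does not match ",
         kind, call. = FALSE)
  if (budget < 5) stop("configuration error: budget must be >= 5",
                       call. = FALSE)
  n <- nrow(table$features)
  set.seed(seed)
  val_idx <- sample.int(n, max(1, round(0.2 * n)))
  train_tab <- subset_rows(table, setdiff(seq_len(n), val_idx))
  val_tab <- subset_rows(table, val_idx)
  objective <- function(u) {
    v <- .from_unit(u, space)
    fit <- fit_regressor(train_tab, kind, stats::setNames(v, space$name),
                         view, seed = seed)
    mse(val_tab$target, predict(fit, val_tab))
  }
  n0 <- min(ceiling(budget / 4), budget)
  u <- seq(0, 1, length.out = max(n0, 2))[seq_len(n0)]
  if (!any(abs(u - 0.5) < 1e-12)) u[which.min(abs(u - 0.5))] <- 0.5
  ys <- vapply(u, objective, 0)
  grid <- seq(0, 1, length.out = 401)
  while (length(u) < budget) {
    gp <- .gp_fit(u, ys)
    pr <- .gp_predict(gp, grid)
    ei <- .expected_improvement(pr$mean, pr$sd, min(ys))
    u_next <- grid[which.max(ei)]
    u <- c(u, u_next)
    ys <- c(ys, objective(u_next))
  }
  vals <- .from_unit(u, space)
  best <- which.min(ys)
  structure(list(
    kind = kind, space = space, budget = budget, seed = as.integer(seed),
    best_setting = stats::setNames(vals[best], space$name),
    best_validation_mse = ys[best],
    trace = data.frame(unit = u, value = vals, mse = ys)),
    class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("Bayesian tuning of %s (%s in [%g, %g], %s scale, budget %d)\n",
              x$kind, x$space$name, x$space$lower, x$space$upper,
              x$space$scale, x$budget))
  cat(sprintf("  best %s = %g  (validation MSE %.4g)\n", x$space$name,
              unname(x$best_setting), x$best_validation_mse))
  invisible(x)
}
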