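#' Mean squared error
#'
#' @param actual,predicted numeric vectors of equal length.
#' @return the mean of the squared deviations.
#' @export
mse <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1)
    stop("actual and predicted must have equal length >= 1", call. = FALSE)
  mean((actual - predicted)^2)
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}; can be negative for models worse than
#' the mean predictor.
#'
#' @param actual,predicted numeric vectors of equal length (at least 2);
#'   `actual` must not be constant.
#' @return \eqn{R^2}.
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 2)
    stop("actual and predicted must have equal length >= 2", call. = FALSE)
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0)
    stop("degenerate data: actual values are constant", call. = FALSE)
  1 - sum((actual - predicted)^2) / ss_tot
}

# deterministic stream of per-replication seeds below 2^31
.spawn_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Monte-Carlo cross-validation of a base regressor
#'
#' Repeats `n_replications` independent random splits of the reactions into
#' training and validation sets (default 4:1, training size
#' `floor(train_fraction * n)`), refits the learner on each training set and
#' scores MSE and \eqn{R^2} on the held-out reactions. Reported summaries
#' are the mean and sample standard deviation over replications.
#'
#' @param table a labeled [reaction_table] with at least 5 reactions.
#' @param kind,hp,view as in [fit_regressor()].
#' @param n_replications number of random splits (default 100).
#' @param train_fraction fraction of reactions used for training
#'   (default 0.8).
#' @param seed master seed; per-replication seeds are spawned from it.
#' @return an object of class `mccv_result` with fields `mse_mean`,
#'   `mse_std`, `r2_mean`, `r2_std` and a `per_replication` data frame.
#' @export
monte_carlo_cv <- function(table, kind, hp = default_hp(kind), view = "all",
                           n_replications = 100, train_fraction = 0.8,
                           seed = 1L) {
  stopifnot(inherits(table, "reaction_table"))
  n <- nrow(table$features)
  if (n < 5) stop("data error: need at least 5 reactions", call. = FALSE)
  n_train <- floor(train_fraction * n)
  if (n_train < 2 || n_train >= n)
    stop("data error: split leaves an empty training or validation set",
         call. = FALSE)
  seeds <- .spawn_seeds(seed, n_replications)
  per <- matrix(NA_real_, n_replications, 2,
                dimnames = list(NULL, c("mse", "r2")))
  for (r in seq_len(n_replications)) {
    set.seed(seeds[r])
    idx <- sample.int(n, n_train)
    fit <- fit_regressor(subset_rows(table, idx), kind, hp, view,
                         seed = seeds[r])
    hold <- subset_rows(table, setdiff(seq_len(n), idx))
    pred <- predict(fit, hold)
    per[r, "mse"] <- mse(hold$target, pred)
    per[r, "r2"] <- r_squared(hold$target, pred)
  }
  structure(list(kind = kind, view = view, hp = hp,
                 n_replications = n_replications,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 mse_mean = mean(per[, "mse"]), mse_std = stats::sd(per[, "mse"]),
                 r2_mean = mean(per[, "r2"]), r2_std = stats::sd(per[, "r2"]),
                 per_replication = as.data.frame(per)),
            class = "mccv_result")
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo CV (%d reps, %s view): %s\n", x$n_replications,
              x$view, x$kind))
  cat(sprintf("  MSE %.3f (%.2f)   R2 %.3f (%.2f)\n", x$mse_mean, x$mse_std,
              x$r2_mean, x$r2_std))
  invisible(x)
}

#' Two-sample z statistic for Monte-Carlo summaries
#'
#' \eqn{z = (\bar m_1 - \bar m_2)/\sqrt{s_1^2/n + s_2^2/n}}, the statistic
#' used to compare two learners' replication summaries (means and standard
#' deviations over the same number of replications).
#'
#' @param mean1,std1 summary of the first sample.
#' @param mean2,std2 summary of the second sample.
#' @param n number of replications in each sample.
#' @return the z statistic.
#' @export
two_sample_z <- function(mean1, std1, mean2, std2, n) {
  stopifnot(std1 >= 0, std2 >= 0, n >= 1)
  if (std1 == 0 && std2 == 0)
    stop("degenerate data: both standard deviations are zero", call. = FALSE)
  (mean1 - mean2) / sqrt(std1^2 / n + std2^2 / n)
}

#' Compare two cross-validated learners with one-sided z-tests
#'
#' Tests whether learner `a` beats learner `b`: lower MSE (reject when
#' \eqn{z \le -z_{crit}}) and higher \eqn{R^2} (reject when
#' \eqn{z \ge z_{crit}}). At the 0.05 level the critical value is taken as
#' 1.64, the conventional two-decimal table value.
#'
#' @param result_a,result_b `mccv_result` objects with equal
#'   `n_replications`.
#' @param alpha one-sided significance level (default 0.05).
#' @return a list of class `model_comparison` with elements `mse` and `r2`,
#'   each holding `z`, `critical`, `reject` and `direction`.
#' @export
compare_models <- function(result_a, result_b, alpha = 0.05) {
  stopifnot(inherits(result_a, "mccv_result"),
            inherits(result_b, "mccv_result"))
  if (result_a$n_replications != result_b$n_replications)
    stop("replication counts differ", call. = FALSE)
  n <- result_a$n_replications
  critical <- if (isTRUE(all.equal(alpha, 0.05))) 1.64 else
    stats::qnorm(1 - alpha)
  z_mse <- two_sample_z(result_a$mse_mean, result_a$mse_std,
                        result_b$mse_mean, result_b$mse_std, n)
  z_r2 <- two_sample_z(result_a$r2_mean, result_a$r2_std,
                       result_b$r2_mean, result_b$r2_std, n)
  structure(list(
    mse = list(z = z_mse, critical = critical, reject = z_mse <= -critical,
               direction = "a_lower_mse"),
    r2 = list(z = z_r2, critical = critical, reject = z_r2 >= critical,
              direction = "a_higher_r2"),
    alpha = alpha), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("MSE: z = %.4f (crit %.2f) -> %s\n", x$mse$z, x$mse$critical,
              if (x$mse$reject) "a significantly lower" else "no claim"))
  cat(sprintf("R2:  z = %.4f (crit %.2f) -> %s\n", x$r2$z, x$r2$critical,
              if (x$r2$reject) "a significantly higher" else "no claim"))
  invisible(x)
}

#' Benchmark the five base learners on a reaction table
#'
#' Runs Monte-Carlo cross-validation for every learner kind on one feature
#' view, optionally tuning each learner's key hyperparameter first with
#' [bayes_optimize()], and returns a benchmark table (one row per learner)
#' plus all pairwise z-test comparisons.
#'
#' @param table a labeled [reaction_table].
#' @param view feature view (default `"all"`).
#' @param kinds learner kinds to include.
#' @param tune if `TRUE`, tune each hyperparameter with [bayes_optimize()]
#'   before cross-validating; otherwise use `settings`.
#' @param settings named list of hyperparameters per kind (defaults to
#'   [default_hp()] for each).
#' @param n_replications,seed passed to [monte_carlo_cv()].
#' @param budget tuning budget per learner when `tune = TRUE`.
#' @return a list of class `learner_benchmark`: `summary` (data frame),
#'   `cv` (the `mccv_result` objects) and `comparisons` (pairwise
#'   [compare_models()] results).
#' @export
evaluate_learners <- function(table, view = "all", kinds = .regressor_kinds,
                              tune = FALSE, settings = NULL,
                              n_replications = 100, budget = 25, seed = 1L) {
  kinds <- match.arg(kinds, .regressor_kinds, several.ok = TRUE)
  cv <- list()
  hps <- list()
  for (k in kinds) {
    hp <- if (!is.null(settings[[k]])) settings[[k]] else default_hp(k)
    if (tune) {
      tr <- bayes_optimize(table, k, view = view, budget = budget,
                           seed = seed)
      hp <- tr$best_setting
    }
    hps[[k]] <- hp
    cv[[k]] <- monte_carlo_cv(table, k, hp, view,
                              n_replications = n_replications, seed = seed)
  }
  summ <- data.frame(
    kind = kinds,
    hyperparameter = vapply(hps[kinds], function(h) names(h), ""),
    value = vapply(hps[kinds], unname, 0),
    mse_mean = vapply(cv[kinds], `[[`, 0, "mse_mean"),
    mse_std = vapply(cv[kinds], `[[`, 0, "mse_std"),
    r2_mean = vapply(cv[kinds], `[[`, 0, "r2_mean"),
    r2_std = vapply(cv[kinds], `[[`, 0, "r2_std"),
    row.names = NULL)
  comps <- list()
  if (length(kinds) > 1) {
    for (i in seq_along(kinds)[-length(kinds)])
      for (j in seq((i + 1), length(kinds))) {
        nm <- paste(kinds[i], "vs", kinds[j])
        comps[[nm]] <- compare_models(cv[[kinds[i]]], cv[[kinds[j]]])
      }
  }
  structure(list(summary = summ, cv = cv, comparisons = comps, view = view,
                 seed = as.integer(seed)),
            class = "learner_benchmark")
}

#' @export
print.learner_benchmark <- function(x, ...) {
  cat("Learner benchmark, view =", x$view, "\n")
  print(x$summary, digits = 3)
  invisible(x)
}
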