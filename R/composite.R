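#' Default key descriptors used by the routing densities
#'
#' The nucleophile density is fitted on the four most important nucleophile
#' descriptors of the nucleophile-focused random forest (`H-X-Nu`,
#' `H-X-CNu`, `Nu`, `Polarizability`); the imine density on four key imine
#' descriptors of the overall SVR ranking (`C`, `N`, `SL`, `LUMO`).
#'
#' @name routing-features
NULL

.default_nucleophile_features <- c("H-X-Nu", "H-X-CNu", "Nu", "Polarizability")
.default_imine_features <- c("C", "N", "SL", "LUMO")

.check_gmm_features <- function(table, features, role) {
  missing_f <- setdiff(features, colnames(table$features))
  if (length(missing_f))
    stop("schema error: table lacks routing feature '", missing_f[1], "'",
         call. = FALSE)
  bad <- features[table$roles[features] != role]
  if (length(bad))
    stop("schema error: routing feature '", bad[1], "' is not a ", role,
         " descriptor", call. = FALSE)
  invisible(features)
}

#' Fit the composite enantioselectivity model
#'
#' Trains the three guarded predictors — an SVR on all features, a
#' nucleophile-focused random forest (imine features excluded), and a LASSO
#' on all features — and fits two Gaussian mixture densities on key
#' nucleophile and imine descriptors of the training reactions, with the
#' number of components chosen by BIC ([select_components()]). At prediction
#' time the mixtures score how similar a new reaction set's key descriptors
#' are to the training distribution and the most appropriate predictor is
#' selected ([route()]).
#'
#' @param table a labeled training [reaction_table].
#' @param svr_hp,rf_hp,lasso_hp hyperparameters of the three predictors;
#'   defaults are the benchmark optima (`C = 9.99`, `num_trees = 28`,
#'   `alpha = 0.016`).
#' @param nucleophile_features,imine_features the descriptors the two
#'   densities are fitted on (defaults above); must exist with the correct
#'   roles.
#' @param k_max largest component count scanned by BIC.
#' @param threshold routing threshold on the average log-likelihood
#'   (default 1).
#' @param seed integer seed threaded to all fits.
#' @return an object of class `composite_model`.
#' @export
composite_model <- function(table,
                            svr_hp = c(C = 9.99),
                            rf_hp = c(num_trees = 28),
                            lasso_hp = c(alpha = 0.016),
                            nucleophile_features = .default_nucleophile_features,
                            imine_features = .default_imine_features,
                            k_max = 20, threshold = 1, seed = 1L) {
  stopifnot(inherits(table, "reaction_table"))
  if (is.null(table$target)) stop("data error: table has no target",
                                  call. = FALSE)
  .check_gmm_features(table, nucleophile_features, "nucleophile")
  .check_gmm_features(table, imine_features, "imine")
  overall_svr <- fit_regressor(table, "svr", svr_hp, view = "all",
                               seed = seed)
  nucleophile_rf <- fit_regressor(table, "random_forest", rf_hp,
                                  view = "exclude_imine", seed = seed)
  lasso_all <- fit_regressor(table, "lasso", lasso_hp, view = "all",
                             seed = seed)
  nuc_sel <- select_components(
    table$features[, nucleophile_features, drop = FALSE], k_max, seed = seed)
  imi_sel <- select_components(
    table$features[, imine_features, drop = FALSE], k_max, seed = seed + 1L)
  structure(list(overall_svr = overall_svr, nucleophile_rf = nucleophile_rf,
                 lasso_all = lasso_all,
                 nucleophile_gmm = nuc_sel$best_fit,
                 imine_gmm = imi_sel$best_fit,
                 nucleophile_selection = nuc_sel, imine_selection = imi_sel,
                 threshold = threshold, seed = as.integer(seed)),
            class = "composite_model")
}

#' Route a reaction set to one of the composite's predictors
#'
#' Computes the average log-likelihood of the set's key nucleophile and
#' imine descriptors under the training-data mixtures. A score is "high"
#' when strictly greater than the threshold. If the nucleophile score is
#' low, the reactions are unlike anything trained on where it matters most
#' and the simple LASSO is used; if the nucleophile score is high but the
#' imine score is low, the nucleophile-focused random forest is used; when
#' both are high the overall SVR is used.
#'
#' @param composite a `composite_model`.
#' @param test_table a non-empty [reaction_table] containing both routing
#'   feature sets.
#' @return an object of class `routing_decision` with both scores, the two
#'   high/low flags and `chosen` (one of `"overall_svr"`,
#'   `"nucleophile_rf"`, `"lasso"`).
#' @export
route <- function(composite, test_table) {
  stopifnot(inherits(composite, "composite_model"),
            inherits(test_table, "reaction_table"))
  if (nrow(test_table$features) == 0)
    stop("data error: empty test set", call. = FALSE)
  nf <- composite$nucleophile_gmm$feature_names
  mf <- composite$imine_gmm$feature_names
  missing_f <- setdiff(c(nf, mf), colnames(test_table$features))
  if (length(missing_f))
    stop("schema error: test table lacks routing feature '", missing_f[1],
         "'", call. = FALSE)
  nuc_ll <- avg_log_likelihood(composite$nucleophile_gmm,
                               test_table$features[, nf, drop = FALSE])
  imi_ll <- avg_log_likelihood(composite$imine_gmm,
                               test_table$features[, mf, drop = FALSE])
  thr <- composite$threshold
  nuc_high <- nuc_ll > thr
  imi_high <- imi_ll > thr
  chosen <- if (!nuc_high) "lasso"
            else if (!imi_high) "nucleophile_rf"
            else "overall_svr"
  structure(list(nucleophile_avg_loglik = nuc_ll,
                 imine_avg_loglik = imi_ll,
                 nucleophile_high = nuc_high, imine_high = imi_high,
                 threshold = thr, chosen = chosen),
            class = "routing_decision")
}

#' @export
print.routing_decision <- function(x, ...) {
  cat(sprintf("Routing decision (threshold %g):\n", x$threshold))
  cat(sprintf("  nucleophile avg log-lik %.2f (%s)   imine avg log-lik %.2f (%s)\n",
              x$nucleophile_avg_loglik,
              if (x$nucleophile_high) "high" else "low",
              x$imine_avg_loglik, if (x$imine_high) "high" else "low"))
  cat("  chosen predictor:", x$chosen, "\n")
  invisible(x)
}

.chosen_fit <- function(composite, chosen)
  switch(chosen, overall_svr = composite$overall_svr,
         nucleophile_rf = composite$nucleophile_rf,
         lasso = composite$lasso_all)

#' Predict with the composite model
#'
#' By default the whole test set is routed once (a set-level decision, as
#' reaction-type groups are scored together) and the chosen predictor is
#' applied to every reaction. With `per_reaction = TRUE` each reaction is
#' routed individually on its own log-likelihoods.
#'
#' @param composite a `composite_model`.
#' @param test_table a [reaction_table].
#' @param per_reaction route each reaction separately (default `FALSE`).
#' @return a list with `predictions` (numeric vector, kcal/mol) and
#'   `decision` (a `routing_decision`, or a data frame of per-reaction
#'   decisions when `per_reaction = TRUE`).
#' @export
predict_composite <- function(composite, test_table, per_reaction = FALSE) {
  stopifnot(inherits(composite, "composite_model"))
  if (!per_reaction) {
    dec <- route(composite, test_table)
    preds <- predict(.chosen_fit(composite, dec$chosen), test_table)
    return(list(predictions = preds, decision = dec))
  }
  n <- nrow(test_table$features)
  decs <- lapply(seq_len(n), function(i) route(composite,
                                               subset_rows(test_table, i)))
  preds <- vapply(seq_len(n), function(i)
    predict(.chosen_fit(composite, decs[[i]]$chosen),
            subset_rows(test_table, i)), 0)
  dec_df <- data.frame(
    id = test_table$ids,
    nucleophile_avg_loglik = vapply(decs, `[[`, 0, "nucleophile_avg_loglik"),
    imine_avg_loglik = vapply(decs, `[[`, 0, "imine_avg_loglik"),
    chosen = vapply(decs, `[[`, "", "chosen"))
  list(predictions = preds, decision = dec_df)
}

#' @export
predict.composite_model <- function(object, table, per_reaction = FALSE, ...) {
  predict_composite(object, table, per_reaction = per_reaction)$predictions
}

#' @export
print.composite_model <- function(x, ...) {
  cat("Composite enantioselectivity model\n")
  cat(sprintf("  overall SVR (C = %g, %d features)\n",
              unname(x$overall_svr$hp), length(x$overall_svr$feature_names)))
  cat(sprintf("  nucleophile-focused RF (num_trees = %d, %d features)\n",
              unname(x$nucleophile_rf$hp),
              length(x$nucleophile_rf$feature_names)))
  cat(sprintf("  LASSO (alpha = %g)\n", unname(x$lasso_all$hp)))
  cat(sprintf("  nucleophile density: %d components on {%s}\n",
              x$nucleophile_gmm$n_components,
              paste(x$nucleophile_gmm$feature_names, collapse = ", ")))
  cat(sprintf("  imine density: %d components on {%s}\n",
              x$imine_gmm$n_components,
              paste(x$imine_gmm$feature_names, collapse = ", ")))
  cat(sprintf("  routing threshold: avg log-likelihood > %g\n", x$threshold))
  invisible(x)
}

#' @export
summary.composite_model <- function(object, ...) {
  print(object)
  cat("\nBIC component scans:\n")
  cat("  nucleophile:", paste(round(object$nucleophile_selection$bic_curve),
                              collapse = " "), "\n")
  cat("  imine:      ", paste(round(object$imine_selection$bic_curve),
                              collapse = " "), "\n")
  invisible(object)
}

#' Evaluate the composite model on one or more test sets
#'
#' Routes and predicts each test table and reports, per set, both average
#' log-likelihoods, the chosen predictor, and (when targets are present)
#' the test MSE and \eqn{R^2}.
#'
#' @param composite a `composite_model`.
#' @param test_tables a named list of [reaction_table]s (or a single table).
#' @return a data frame with one row per test set, of class
#'   `composite_report`.
#' @export
composite_report <- function(composite, test_tables) {
  if (inherits(test_tables, "reaction_table"))
    test_tables <- list(test = test_tables)
  if (is.null(names(test_tables)))
    names(test_tables) <- paste0("set_", seq_along(test_tables))
  rows <- lapply(names(test_tables), function(nm) {
    tab <- test_tables[[nm]]
    out <- predict_composite(composite, tab)
    dec <- out$decision
    data.frame(set = nm,
               chosen = dec$chosen,
               imine_avg_loglik = dec$imine_avg_loglik,
               nucleophile_avg_loglik = dec$nucleophile_avg_loglik,
               mse = if (is.null(tab$target)) NA_real_
                     else mse(tab$target, out$predictions),
               r2 = if (is.null(tab$target)) NA_real_
                    else r_squared(tab$target, out$predictions))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("composite_report", class(out))
  out
}

# ---- persistence ----------------------------------------------------------

#' Save or load a composite model
#'
#' The archive bundles the three predictor archives, the two mixture
#' densities and a manifest (threshold, seed, schema version); a load
#' round-trip preserves predictions bit for bit.
#'
#' @param object a `composite_model`.
#' @param path archive file path.
#' @return `save_composite()`: the path, invisibly; `load_composite()`: the
#'   restored model.
#' @export
save_composite <- function(object, path) {
  stopifnot(inherits(object, "composite_model"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  regs <- lapply(object[c("overall_svr", "nucleophile_rf", "lasso_all")],
                 function(m) { save_regressor(m, tmp); readBin(tmp, "raw",
                   file.size(tmp)) })
  saveRDS(list(schema = .archive_schema, class = "composite_model",
               regressors = regs,
               gmms = object[c("nucleophile_gmm", "imine_gmm")],
               selections = object[c("nucleophile_selection",
                                     "imine_selection")],
               threshold = object$threshold, seed = object$seed), path)
  invisible(path)
}

#' @rdname save_composite
#' @export
load_composite <- function(path) {
  arch <- readRDS(path)
  if (!identical(arch$schema, .archive_schema) ||
      !identical(arch$class, "composite_model"))
    stop("unrecognised composite archive", call. = FALSE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  regs <- lapply(arch$regressors, function(b) { writeBin(b, tmp);
    load_regressor(tmp) })
  structure(c(regs,
              arch$gmms, arch$selections,
              list(threshold = arch$threshold, seed = arch$seed)),
            class = "composite_model")
}
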