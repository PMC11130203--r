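# log densities of each Gaussian component at standardized points z (n x d);
# returns n x K matrix of log N(z; mu_k, Sigma_k)
.component_logdens <- function(z, means, covs) {
  n <- nrow(z); d <- ncol(z); K <- nrow(means)
  out <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    ch <- chol(covs[, , k])
    logdet <- 2 * sum(log(diag(ch)))
    zc <- sweep(z, 2, means[k, ])
    q <- colSums(backsolve(ch, t(zc), transpose = TRUE)^2)
    out[, k] <- -0.5 * (d * log(2 * pi) + logdet + q)
  }
  out
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# one EM run from a k-means-style initialization; returns NULL on failure
.em_run <- function(z, K, restart_seed, ridge, tol, max_iter) {
  n <- nrow(z); d <- ncol(z)
  set.seed(restart_seed)
  assign <- if (K == 1) rep(1L, n) else {
    km <- tryCatch(stats::kmeans(z, K, iter.max = 25, nstart = 1),
                   error = function(e) NULL)
    if (is.null(km)) sample.int(K, n, replace = TRUE) else km$cluster
  }
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), assign)] <- 1
  means <- matrix(0, K, d); covs <- array(0, c(d, d, K))
  weights <- rep(1 / K, K)
  trace <- numeric(0)
  m_step <- function(resp) {
    Nk <- pmax(colSums(resp), 1e-10)
    weights <<- Nk / sum(Nk)
    for (k in seq_len(K)) {
      mu <- colSums(z * resp[, k]) / Nk[k]
      zc <- sweep(z, 2, mu)
      S <- crossprod(zc * sqrt(resp[, k])) / Nk[k] + diag(ridge, d)
      means[k, ] <<- mu
      covs[, , k] <<- S
    }
  }
  m_step(resp)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw <- sweep(.component_logdens(z, means, covs), 2, log(weights), "+")
    lse <- .logsumexp_rows(lw)
    avg_ll <- mean(lse)
    if (!is.finite(avg_ll)) return(NULL)
    trace <- c(trace, avg_ll)
    if (avg_ll - prev < tol && it > 1) { converged <- TRUE; break }
    prev <- avg_ll
    resp <- exp(lw - lse)
    m_step(resp)
  }
  list(weights = weights, means = means, covs = covs, trace = trace,
       converged = converged)
}

#' Fit a Gaussian mixture density by expectation-maximization
#'
#' Approximates the joint distribution of a small set of key descriptors
#' (e.g. the top nucleophile or imine features) with a mixture of `K`
#' full-covariance Gaussians. Features are z-scored with the fit data's
#' statistics; covariances carry a diagonal ridge; EM starts from a seeded
#' k-means partition and the best of `n_restarts` restarts (by final
#' log-likelihood) is kept. The reported log-likelihood trace is on the
#' original feature scale (it includes the change-of-variable constant of
#' the standardization), so it is directly comparable with
#' [avg_log_likelihood()].
#'
#' @param x numeric matrix (rows = reactions, columns = named descriptors).
#' @param n_components number of Gaussian components `K` (at most `nrow(x)`).
#' @param seed integer seed; restart seeds are spawned from it.
#' @param n_restarts independent EM restarts (default 5).
#' @param ridge diagonal ridge added to every covariance (default 1e-6).
#' @param tol convergence threshold on the average log-likelihood
#'   improvement (default 1e-4).
#' @param max_iter maximum EM iterations per restart (default 200).
#' @return an object of class `gmm_density` with `weights`, `means`,
#'   `covariances` (in standardized space), `feature_names`, the
#'   standardization (`center`, `scale`), the per-iteration average
#'   log-likelihood `trace` and a `converged` flag.
#' @export
fit_gmm <- function(x, n_components, seed = 1L, n_restarts = 5,
                    ridge = 1e-6, tol = 1e-4, max_iter = 200) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (n_components < 1 || n_components != round(n_components))
    stop("n_components must be a positive integer", call. = FALSE)
  if (n_components > n)
    stop("n_components exceeds the number of rows", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(d))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- .zscore(x, ctr, scl)
  const <- -sum(log(scl))   # change-of-variable to the original scale
  seeds <- .spawn_seeds(seed, n_restarts)
  best <- NULL
  for (rs in seeds) {
    run <- .em_run(z, n_components, rs, ridge, tol, max_iter)
    if (is.null(run)) next
    if (is.null(best) || utils::tail(run$trace, 1) > utils::tail(best$trace, 1))
      best <- run
  }
  if (is.null(best))
    stop("numerical error: every EM restart failed (singular covariance?)",
         call. = FALSE)
  structure(list(n_components = as.integer(n_components),
                 weights = best$weights, means = best$means,
                 covariances = best$covs, feature_names = colnames(x),
                 center = ctr, scale = scl,
                 trace = best$trace + const, converged = best$converged,
                 seed = as.integer(seed), ridge = ridge),
            class = "gmm_density")
}

#' @export
print.gmm_density <- function(x, ...) {
  cat(sprintf("Gaussian mixture density: %d component(s) over %d feature(s)\n",
              x$n_components, length(x$feature_names)))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  cat(sprintf("  final avg log-likelihood %.4f (%s, %d EM iterations)\n",
              utils::tail(x$trace, 1),
              if (x$converged) "converged" else "not converged",
              length(x$trace)))
  invisible(x)
}

# standardize new data to a fitted gmm's space, checking names
.gmm_standardize <- function(gmm, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(gmm$feature_names))
    stop("dimension mismatch: expected ", length(gmm$feature_names),
         " features", call. = FALSE)
  if (!is.null(colnames(x))) {
    missing_f <- setdiff(gmm$feature_names, colnames(x))
    if (length(missing_f))
      stop("schema error: data lacks feature '", missing_f[1], "'",
           call. = FALSE)
    x <- x[, gmm$feature_names, drop = FALSE]
  }
  .zscore(x, gmm$center, gmm$scale)
}

# per-row log mixture density on the original feature scale
.gmm_logdens <- function(gmm, x) {
  z <- .gmm_standardize(gmm, x)
  lw <- sweep(.component_logdens(z, gmm$means, gmm$covariances), 2,
              log(gmm$weights), "+")
  .logsumexp_rows(lw) - sum(log(gmm$scale))
}

#' Average log-likelihood of data under a fitted mixture
#'
#' The per-reaction mean of \eqn{\log \sum_k w_k N(x; \mu_k, \Sigma_k)},
#' evaluated on the original feature scale (the standardization's
#' change-of-variable constant is included). This is the similarity score
#' the composite model thresholds when routing.
#'
#' @param gmm a `gmm_density`.
#' @param x numeric matrix whose columns match the fitted features.
#' @return the average log-likelihood (a scalar).
#' @export
avg_log_likelihood <- function(gmm, x) {
  stopifnot(inherits(gmm, "gmm_density"))
  mean(.gmm_logdens(gmm, x))
}

#' Bayesian information criterion of a fitted mixture
#'
#' \eqn{BIC = -2\,\log L + p\,\ln n} with
#' \eqn{p = (K-1) + Kd + Kd(d+1)/2} free parameters (weights, means, full
#' covariances).
#'
#' @param gmm a `gmm_density`.
#' @param x data matrix (at least 2 rows) to evaluate the likelihood on.
#' @return the BIC value (lower is better).
#' @export
gmm_bic <- function(gmm, x) {
  stopifnot(inherits(gmm, "gmm_density"))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 rows for BIC", call. = FALSE)
  K <- gmm$n_components; d <- length(gmm$feature_names)
  p <- (K - 1) + K * d + K * d * (d + 1) / 2
  -2 * sum(.gmm_logdens(gmm, x)) + p * log(n)
}

#' Choose the number of mixture components by BIC
#'
#' Fits mixtures with \eqn{K = 1, \dots, k_{max}} components and returns the
#' BIC-minimising fit (ties go to the smaller `K`). `K` values whose fit
#' fails are excluded with a warning.
#'
#' @param x data matrix.
#' @param k_max largest component count to try (default 20).
#' @param seed integer seed; per-`K` seeds are spawned from it.
#' @param ... passed to [fit_gmm()].
#' @return an object of class `component_selection`: `best_k`, `bic_curve`
#'   (length `k_max`, `NA` for failed fits) and `best_fit` (a
#'   `gmm_density`).
#' @export
select_components <- function(x, k_max = 20, seed = 1L, ...) {
  x <- as.matrix(x)
  if (k_max < 1 || k_max > nrow(x))
    stop("k_max must be between 1 and the number of rows", call. = FALSE)
  seeds <- .spawn_seeds(seed, k_max)
  bics <- rep(NA_real_, k_max)
  fits <- vector("list", k_max)
  for (K in seq_len(k_max)) {
    fit <- tryCatch(fit_gmm(x, K, seed = seeds[K], ...),
                    error = function(e) {
                      warning("fit with K = ", K, " failed: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (!is.null(fit)) {
      fits[[K]] <- fit
      bics[K] <- gmm_bic(fit, x)
    }
  }
  if (all(is.na(bics))) stop("every mixture fit failed", call. = FALSE)
  best_k <- which.min(bics)   # which.min skips NA and takes the first tie
  structure(list(best_k = as.integer(best_k), bic_curve = bics,
                 best_fit = fits[[best_k]], seed = as.integer(seed)),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("BIC component selection: best K = %d over 1..%d\n",
              x$best_k, length(x$bic_curve)))
  invisible(x)
}

#' @export
plot.component_selection <- function(x, ...) {
  graphics::plot(seq_along(x$bic_curve), x$bic_curve, type = "b",
                 xlab = "number of Gaussian components", ylab = "BIC", ...)
  invisible(x)
}
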