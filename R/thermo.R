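# Gas constant in kcal/(mol K); enantioselectivity is stored in kcal/mol.
.R_KCAL <- 1.98720425e-3

#' Convert between enantiomeric ratio and enantioselectivity
#'
#' The enantioselectivity of a reaction is the free-energy difference between
#' the two diastereomeric transition states,
#' \eqn{\Delta\Delta G^\ddag = -RT\,\ln(\mathrm{e.r.})}, where e.r. is the
#' enantiomeric ratio (amount of major over minor enantiomer) and
#' \eqn{R = 1.98720425\times 10^{-3}} kcal/(mol K). `er_from_ddg()` is the
#' algebraic inverse, \eqn{\exp(-\Delta\Delta G^\ddag / RT)}.
#'
#' @param er enantiomeric ratio, dimensionless, strictly positive.
#' @param ddg enantioselectivity in kcal/mol.
#' @param temperature_K absolute temperature in kelvin (default 298.15).
#' @return `ddg_from_er()`: \eqn{\Delta\Delta G^\ddag} in kcal/mol;
#'   `er_from_ddg()`: a strictly positive enantiomeric ratio.
#' @examples
#' ddg_from_er(10)                    # about -1.364 kcal/mol at 298.15 K
#' er_from_ddg(ddg_from_er(2.5))      # recovers 2.5
#' @export
ddg_from_er <- function(er, temperature_K = 298.15) {
  if (any(er <= 0)) stop("domain error: e.r. must be > 0", call. = FALSE)
  if (any(temperature_K <= 0))
    stop("domain error: temperature must be > 0 K", call. = FALSE)
  -.R_KCAL * temperature_K * log(er)
}

#' @rdname ddg_from_er
#' @export
er_from_ddg <- function(ddg, temperature_K = 298.15) {
  if (any(temperature_K <= 0))
    stop("domain error: temperature must be > 0 K", call. = FALSE)
  exp(-ddg / (.R_KCAL * temperature_K))
}

#' Screen the enantioselectivity target for normality and outliers
#'
#' Runs a Shapiro-Wilk normality test on the target and flags reactions whose
#' z-score, \eqn{(y_i - \bar y)/s} with the sample standard deviation, lies
#' outside \eqn{[-3, 3]}.
#'
#' @param x a labeled [reaction_table] or a numeric target vector.
#' @return an object of class `target_screen`: `shapiro_p`, `z_min`, `z_max`,
#'   `z` (named z-scores) and `outlier_ids`.
#' @export
screen_target <- function(x) {
  if (inherits(x, "reaction_table")) {
    if (is.null(x$target)) stop("table has no target", call. = FALSE)
    y <- x$target; ids <- x$ids
  } else {
    y <- as.numeric(x); ids <- as.character(seq_along(y))
  }
  if (length(y) < 3) stop("need at least 3 observations", call. = FALSE)
  s <- stats::sd(y)
  if (s == 0) stop("degenerate data: target has zero variance", call. = FALSE)
  z <- (y - mean(y)) / s
  structure(list(shapiro_p = stats::shapiro.test(y)$p.value,
                 z_min = min(z), z_max = max(z),
                 z = stats::setNames(z, ids),
                 outlier_ids = ids[abs(z) > 3]),
            class = "target_screen")
}

#' @export
print.target_screen <- function(x, ...) {
  cat(sprintf("Target screen: Shapiro-Wilk p = %.3g, z range [%.2f, %.2f]\n",
              x$shapiro_p, x$z_min, x$z_max))
  if (length(x$outlier_ids))
    cat("  outliers (|z| > 3):", paste(x$outlier_ids, collapse = ", "), "\n")
  else cat("  no outliers (|z| > 3)\n")
  invisible(x)
}
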