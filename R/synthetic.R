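#' Specification for a synthetic reaction benchmark
#'
#' Describes a synthetic feature table with the structure of the
#' chiral-phosphoric-acid benchmark: 282 descriptors in role blocks of
#' 160 solvent / 85 catalyst / 15 nucleophile / 22 imine columns, 307
#' training and 27 test reactions by default. Reactions reuse a small pool
#' of distinct nucleophile and imine "molecules": the informative
#' descriptors of each role are drawn from a seeded Gaussian mixture with
#' `cluster_count_per_role` tight components (molecule archetypes plus
#' small conformer-level jitter), which is what makes density-based
#' similarity scoring meaningful. The target is a linear combination of the
#' informative descriptors plus a bounded nonlinearity and truncated-normal
#' measurement noise, which keeps the target both unimodal-normal-looking
#' and free of |z| > 3 outliers.
#'
#' @param n_train,n_test numbers of training and test reactions.
#' @param role_counts named integer vector of descriptor counts per role.
#' @param n_informative_nucleophile,n_informative_imine how many descriptors
#'   of each role carry signal (at most the role count).
#' @param nonlinearity_amplitude weight of the interaction + quadratic term
#'   in the target (0 gives an exactly linear target).
#' @param noise_std standard deviation of the target noise (kcal/mol); the
#'   noise is a normal truncated at \eqn{\pm 2.2} standard deviations
#'   (bounded experimental error).
#' @param cluster_count_per_role number of molecule archetypes per role.
#' @param cluster_spread between-archetype standard deviation.
#' @param cluster_jitter within-archetype (conformer) standard deviation.
#' @param nuisance_correlation within-block equicorrelation of the solvent
#'   and catalyst descriptor blocks (descriptor redundancy).
#' @param shared_cluster_prob probability that a reaction's imine archetype
#'   is determined by its nucleophile archetype (imine descriptors being
#'   partially explained by the other molecules).
#' @param shift_kind `"none"`, `"imine_shift"` or `"nucleophile_shift"`:
#'   translate the corresponding informative test descriptors.
#' @param shift_magnitude shift size in training standard deviations
#'   (default 10).
#' @param seed integer seed; generation is fully reproducible from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_train = 307, n_test = 27,
                           role_counts = c(solvent = 160, catalyst = 85,
                                           nucleophile = 15, imine = 22),
                           n_informative_nucleophile = 4,
                           n_informative_imine = 4,
                           nonlinearity_amplitude = 0.2,
                           noise_std = 0.55,
                           cluster_count_per_role = 15,
                           cluster_spread = 0.4,
                           cluster_jitter = 0.04,
                           nuisance_correlation = 0.3,
                           shared_cluster_prob = 0.15,
                           shift_kind = c("none", "imine_shift",
                                          "nucleophile_shift"),
                           shift_magnitude = 10,
                           seed = 1L) {
  shift_kind <- match.arg(shift_kind)
  if (!all(.molecule_roles %in% names(role_counts)) ||
      any(role_counts <= 0))
    stop("configuration error: role_counts must name all four roles with ",
         "positive counts", call. = FALSE)
  if (n_informative_nucleophile > role_counts[["nucleophile"]] ||
      n_informative_imine > role_counts[["imine"]])
    stop("configuration error: informative count exceeds the role's ",
         "feature count", call. = FALSE)
  stopifnot(n_train >= 2, n_test >= 1, noise_std >= 0,
            cluster_count_per_role >= 1)
  if (shift_kind != "none" && shift_magnitude <= 0)
    stop("configuration error: shift_magnitude must be > 0 under a shift",
         call. = FALSE)
  structure(list(n_train = n_train, n_test = n_test,
                 role_counts = role_counts[.molecule_roles],
                 n_informative_nucleophile = n_informative_nucleophile,
                 n_informative_imine = n_informative_imine,
                 nonlinearity_amplitude = nonlinearity_amplitude,
                 noise_std = noise_std,
                 cluster_count_per_role = cluster_count_per_role,
                 cluster_spread = cluster_spread,
                 cluster_jitter = cluster_jitter,
                 nuisance_correlation = nuisance_correlation,
                 shared_cluster_prob = shared_cluster_prob,
                 shift_kind = shift_kind,
                 shift_magnitude = shift_magnitude,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.named_descriptors <- list(
  nucleophile = c("Nu", "H-X-Nu", "H-X-CNu", "Polarizability",
                  "iXH", "nXH", "HOMO", "L"),
  imine = c("C", "N", "SL", "LUMO", "SB1", "SubS", "PG", "iNH"))

.role_feature_names <- function(role, count) {
  named <- .named_descriptors[[role]]
  if (is.null(named)) named <- character()
  n_named <- min(length(named), count)
  c(named[seq_len(n_named)],
    if (count > n_named)
      sprintf("%s_%03d", role, seq(n_named + 1, count)))
}

# truncated normal draw via the quantile transform (deterministic draw
# count, so seeding stays stable)
.rtnorm <- function(n, sd, lim) {
  if (sd == 0) return(rep(0, n))
  lo <- stats::pnorm(-lim); hi <- stats::pnorm(lim)
  sd * stats::qnorm(lo + stats::runif(n) * (hi - lo))
}

# tight mixture block. Archetype centers take one of a few discrete levels
# per descriptor (real descriptors such as bond lengths or orbital energies
# cluster around a handful of typical values), drawn from a truncated
# normal so physical ranges stay bounded. Quantised levels also mean no
# single descriptor can separate all archetypes, so each informative
# descriptor carries signal of its own.
.mixture_block <- function(n, d, m, spread, jitter, assign = NULL,
                           n_levels = 5, beta = NULL) {
  draw_centers <- function() vapply(seq_len(d), function(j) {
    # evenly spaced typical values, slightly perturbed, in random order:
    # every descriptor then has comparable between-archetype variance
    levels_j <- spread * sample(seq(-1.6, 1.6, length.out = n_levels) +
                                  .rtnorm(n_levels, 0.2, 2))
    levels_j[sample.int(n_levels, m, replace = TRUE)]
  }, numeric(m))
  # reject archetype libraries with redundant descriptors: no descriptor's
  # archetype profile may be close to a linear function of its role-mates,
  # so every informative descriptor carries signal of its own
  profile_r2 <- function(C) {
    if (d < 2 || m <= d + 1) return(0)
    max(vapply(seq_len(d), function(j) {
      f <- stats::lm.fit(cbind(1, C[, -j, drop = FALSE]), C[, j])
      1 - sum(f$residuals^2) / sum((C[, j] - mean(C[, j]))^2)
    }, 0))
  }
  # curated libraries also avoid molecules whose combined contribution to
  # the target would be extreme relative to the library's spread
  extreme_sum <- function(C) {
    if (is.null(beta)) return(0)
    s <- as.numeric(C %*% beta)
    max(abs(s - mean(s))) / max(stats::sd(s), 1e-12)
  }
  centers <- draw_centers()
  for (i in seq_len(40)) {
    if (profile_r2(centers) <= 0.4 && extreme_sum(centers) <= 2.1) break
    centers <- draw_centers()
  }
  # balanced archetype usage: curated reaction sets cover every molecule
  # several times, which keeps each mixture component well estimated
  if (is.null(assign)) assign <- sample(rep_len(seq_len(m), n))
  list(x = centers[assign, , drop = FALSE] +
         matrix(stats::rnorm(n * d, 0, jitter), n, d),
       assign = assign)
}

# equicorrelated nuisance block: one shared factor per block
.equicorr_block <- function(n, d, rho) {
  b <- stats::rnorm(n)
  sqrt(rho) * matrix(b, n, d) + sqrt(1 - rho) * matrix(stats::rnorm(n * d), n, d)
}

#' Generate a synthetic train/test pair of reaction tables
#'
#' @param spec a [synthetic_spec].
#' @return a list with elements `train` and `test`, both
#'   [reaction_table]s, each with targets. A nucleophile shift is a genuine
#'   covariate shift (the target follows the moved descriptors); an imine
#'   shift corrupts the imine descriptors after the target is computed
#'   (dissimilar characterisation, unchanged chemistry), the regime in
#'   which the imine-free predictor remains accurate.
#' @export
generate_reactions <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_train + spec$n_test
  rc <- spec$role_counts
  m <- spec$cluster_count_per_role
  d_nu <- spec$n_informative_nucleophile
  d_im <- spec$n_informative_imine

  beta_nu <- rep(c(0.8, 0.7, 0.7, 0.6), length.out = d_nu)
  beta_im <- rep(c(0.8, 0.7, 0.7, 0.6), length.out = d_im)

  nuc_inf <- .mixture_block(n, d_nu, m, spec$cluster_spread,
                            spec$cluster_jitter, beta = beta_nu)
  # the imine archetype is shared with the nucleophile's for a fraction of
  # reactions, so imine descriptors are partially explained by the rest
  perm <- sample.int(m)
  shared <- stats::runif(n) < spec$shared_cluster_prob
  imi_assign <- ifelse(shared, perm[nuc_inf$assign],
                       sample(rep_len(seq_len(m), n)))
  imi_inf <- .mixture_block(n, d_im, m, spec$cluster_spread,
                            spec$cluster_jitter, assign = imi_assign,
                            beta = beta_im)

  solvent <- .equicorr_block(n, rc[["solvent"]], spec$nuisance_correlation)
  catalyst <- .equicorr_block(n, rc[["catalyst"]], spec$nuisance_correlation)
  # a weak continuous trace of the nucleophile archetype in the catalyst
  # block (shared latent factor across molecule roles)
  g <- scale(nuc_inf$assign, scale = stats::sd(nuc_inf$assign))[, 1]
  catalyst[, seq_len(min(5, ncol(catalyst)))] <-
    catalyst[, seq_len(min(5, ncol(catalyst)))] + 0.3 * g
  nuc_rest <- matrix(stats::rnorm(n * (rc[["nucleophile"]] - d_nu)), n)
  imi_rest <- matrix(stats::rnorm(n * (rc[["imine"]] - d_im)), n)

  x <- cbind(solvent, catalyst, nuc_inf$x, nuc_rest, imi_inf$x, imi_rest)
  colnames(x) <- c(.role_feature_names("solvent", rc[["solvent"]]),
                   .role_feature_names("catalyst", rc[["catalyst"]]),
                   .role_feature_names("nucleophile", rc[["nucleophile"]]),
                   .role_feature_names("imine", rc[["imine"]]))
  roles <- stats::setNames(rep(.molecule_roles, rc), colnames(x))

  train_idx <- seq_len(spec$n_train)
  test_idx <- seq(spec$n_train + 1, n)

  shift_block <- function(x, role, d_inf) {
    cols <- .role_feature_names(role, rc[[role]])[seq_len(d_inf)]
    for (cl in cols) {
      s <- stats::sd(x[train_idx, cl])
      x[test_idx, cl] <- x[test_idx, cl] + spec$shift_magnitude * s
    }
    x
  }
  # the nucleophile shift is a genuine covariate shift: descriptors move
  # first and the target is computed from the moved values, so the
  # target-given-features relation is invariant and a linear model can
  # extrapolate while saturating models cannot
  if (spec$shift_kind == "nucleophile_shift")
    x <- shift_block(x, "nucleophile", d_nu)

  nu_cols <- .role_feature_names("nucleophile",
                                 rc[["nucleophile"]])[seq_len(d_nu)]
  im_cols <- .role_feature_names("imine", rc[["imine"]])[seq_len(d_im)]
  lin <- x[, nu_cols, drop = FALSE] %*% beta_nu +
         x[, im_cols, drop = FALSE] %*% beta_im
  nonlin <- if (spec$nonlinearity_amplitude > 0)
    spec$nonlinearity_amplitude *
      (x[, nu_cols[1]] * x[, im_cols[1]] +
       (x[, nu_cols[min(2, d_nu)]]^2 - 1))
  else 0
  # measured selectivities carry bounded experimental error: the noise is a
  # normal truncated at 2.2 standard deviations
  y <- as.numeric(lin) + nonlin + .rtnorm(n, spec$noise_std, 2.2)

  # the imine shift is a descriptor-level corruption: imine descriptors of
  # the test reactions become dissimilar (e.g. a new source characterises
  # imines differently) while the underlying selectivities are unchanged —
  # the regime in which an imine-free model stays accurate
  if (spec$shift_kind == "imine_shift")
    x <- shift_block(x, "imine", d_im)

  list(train = reaction_table(x[train_idx, , drop = FALSE], roles,
                              target = y[train_idx],
                              ids = sprintf("train_%03d", train_idx),
                              source_label = "synthetic-train"),
       test = reaction_table(x[test_idx, , drop = FALSE], roles,
                             target = y[test_idx],
                             ids = sprintf("test_%03d", seq_along(test_idx)),
                             source_label = paste0("synthetic-test-",
                                                   spec$shift_kind)))
}

#' Screen a generated table's target distribution
#'
#' Convenience wrapper around [screen_target()]: the generator is expected
#' to produce approximately normal targets with no |z| > 3 outliers at the
#' default settings.
#'
#' @param table a labeled [reaction_table].
#' @return a `target_screen` report.
#' @export
target_distribution_check <- function(table) screen_target(table)
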