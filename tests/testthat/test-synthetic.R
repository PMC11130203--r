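test_that("the default benchmark reproduces the reference structure", {
  d <- generate_reactions(synthetic_spec(seed = 2))
  expect_equal(dim(d$train), c(307L, 282L))
  expect_equal(dim(d$test), c(27L, 282L))
  rc <- table(d$train$roles)
  expect_equal(unname(rc[c("solvent", "catalyst", "nucleophile", "imine")]),
               c(160L, 85L, 15L, 22L), ignore_attr = TRUE)
  key <- c("Nu", "H-X-Nu", "H-X-CNu", "Polarizability",
           "C", "N", "SL", "LUMO")
  expect_true(all(key %in% colnames(d$train$features)))
  expect_equal(unname(d$train$roles[c("Nu", "LUMO")]),
               c("nucleophile", "imine"))
  expect_false(is.null(d$train$target))
})

test_that("generation is bit-reproducible from the seed", {
  a <- generate_reactions(synthetic_spec(seed = 33))
  b <- generate_reactions(synthetic_spec(seed = 33))
  expect_identical(a$train$features, b$train$features)
  expect_identical(a$train$target, b$train$target)
  expect_identical(a$test$features, b$test$features)
  c2 <- generate_reactions(synthetic_spec(seed = 34))
  expect_false(identical(a$train$target, c2$train$target))
})

test_that("a noise-free linear benchmark is exactly learnable", {
  spec <- synthetic_spec(n_train = 250, n_test = 40, noise_std = 0,
                         nonlinearity_amplitude = 0, seed = 6)
  d <- generate_reactions(spec)
  fit <- fit_regressor(d$train, "lasso", c(alpha = 1e-5), seed = 1)
  expect_gt(r_squared(d$test$target, predict(fit, d$test)), 0.999)
})

test_that("shifts move only the informative descriptors of their role", {
  base <- generate_reactions(synthetic_spec(seed = 9))
  shifted <- generate_reactions(synthetic_spec(seed = 9,
                                               shift_kind = "imine_shift"))
  moved <- colnames(base$test$features)[colSums(abs(
    base$test$features - shifted$test$features)) > 1e-12]
  expect_setequal(moved, c("C", "N", "SL", "LUMO"))
  expect_identical(base$train$features, shifted$train$features)
  # the shift is large in units of the training spread
  s <- sd(base$train$features[, "C"])
  expect_equal(mean(shifted$test$features[, "C"] - base$test$features[, "C"]),
               10 * s, tolerance = 1e-8)
})

test_that("training-density scores drop under either shift", {
  for (s in c(4, 5)) {
    base <- generate_reactions(synthetic_spec(seed = s))
    nuc_cols <- c("H-X-Nu", "H-X-CNu", "Nu", "Polarizability")
    imi_cols <- c("C", "N", "SL", "LUMO")
    g_nuc <- fit_gmm(base$train$features[, nuc_cols], 8, seed = s)
    g_imi <- fit_gmm(base$train$features[, imi_cols], 8, seed = s)
    ll_nuc <- avg_log_likelihood(g_nuc, base$test$features[, nuc_cols])
    ll_imi <- avg_log_likelihood(g_imi, base$test$features[, imi_cols])
    sh_n <- generate_reactions(synthetic_spec(seed = s,
                                              shift_kind = "nucleophile_shift"))
    sh_i <- generate_reactions(synthetic_spec(seed = s,
                                              shift_kind = "imine_shift"))
    expect_lt(avg_log_likelihood(g_nuc, sh_n$test$features[, nuc_cols]),
              ll_nuc)
    expect_lt(avg_log_likelihood(g_imi, sh_i$test$features[, imi_cols]),
              ll_imi)
  }
})

test_that("target screening behaves on generated and corrupted targets", {
  d <- generate_reactions(synthetic_spec(seed = 12))
  sc <- target_distribution_check(d$train)
  expect_s3_class(sc, "target_screen")
  expect_gt(sc$shapiro_p, 0.01)

  corrupted <- d$train
  corrupted$target[5] <- mean(corrupted$target) + 6 * sd(corrupted$target)
  sc2 <- target_distribution_check(corrupted)
  expect_true(corrupted$ids[5] %in% sc2$outlier_ids)
})

test_that("invalid generator specifications are rejected", {
  expect_error(synthetic_spec(role_counts = c(solvent = 160)), "role")
  expect_error(synthetic_spec(n_informative_nucleophile = 99),
               "informative")
  expect_error(synthetic_spec(shift_kind = "imine_shift",
                              shift_magnitude = 0), "shift_magnitude")
})

test_that("the step-wise LR baseline finds signal and screens collinearity", {
  spec <- synthetic_spec(n_train = 200, n_test = 30, seed = 14)
  d <- generate_reactions(spec)
  base <- stepwise_lr(d$train, seed = 2)
  expect_gt(length(base$selected), 0)
  preds <- predict(base, d$test)
  expect_gt(r_squared(d$test$target, preds), 0)
  # selected features respect the pairwise collinearity cap on the split
  # used for selection (checked on the full table as a sanity proxy)
  if (length(base$selected) > 1) {
    cors <- cor(d$train$features[, base$selected])
    diag(cors) <- 0
    expect_lt(max(abs(cors)), 0.6)
  }
})
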