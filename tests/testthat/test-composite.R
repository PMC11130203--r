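# one small composite shared across this file
comp_data <- generate_reactions(synthetic_spec(seed = 101))
comp <- composite_model(comp_data$train, k_max = 8, seed = 101)

test_that("the composite reuses its standalone predictor fits exactly", {
  tab <- comp_data$train
  svr <- fit_regressor(tab, "svr", c(C = 9.99), view = "all", seed = 101)
  rf <- fit_regressor(tab, "random_forest", c(num_trees = 28),
                      view = "exclude_imine", seed = 101)
  las <- fit_regressor(tab, "lasso", c(alpha = 0.016), view = "all",
                       seed = 101)
  test <- comp_data$test
  expect_identical(predict(comp$overall_svr, test), predict(svr, test))
  expect_identical(predict(comp$nucleophile_rf, test), predict(rf, test))
  expect_identical(predict(comp$lasso_all, test), predict(las, test))
  expect_equal(comp$nucleophile_gmm$feature_names,
               c("H-X-Nu", "H-X-CNu", "Nu", "Polarizability"))
  expect_equal(comp$imine_gmm$feature_names, c("C", "N", "SL", "LUMO"))
  expect_equal(comp$overall_svr$view, "all")
  expect_equal(comp$nucleophile_rf$view, "exclude_imine")
})

test_that("routing follows the similarity table with a strict threshold", {
  dec <- route(comp, comp_data$test)
  expect_true(dec$nucleophile_high)
  expect_true(dec$imine_high)
  expect_equal(dec$chosen, "overall_svr")

  # raising the threshold to the observed score flips "high" to "low":
  # similarity is a strict inequality
  at_boundary <- comp
  at_boundary$threshold <- dec$nucleophile_avg_loglik
  dec2 <- route(at_boundary, comp_data$test)
  expect_false(dec2$nucleophile_high)
  expect_equal(dec2$chosen, "lasso")

  # nucleophile dissimilarity dominates: with only the imine score low the
  # nucleophile-focused RF is chosen
  mid <- comp
  mid$threshold <- min(dec$imine_avg_loglik, dec$nucleophile_avg_loglik)
  decm <- route(mid, comp_data$test)
  if (dec$imine_avg_loglik < dec$nucleophile_avg_loglik) {
    expect_false(decm$imine_high)
    expect_equal(decm$chosen, "nucleophile_rf")
  } else {
    expect_equal(decm$chosen, "lasso")
  }
})

test_that("shifted reaction sets are routed away from the overall SVR", {
  imi <- generate_reactions(synthetic_spec(seed = 101,
                                           shift_kind = "imine_shift"))$test
  nuc <- generate_reactions(synthetic_spec(seed = 101,
                                           shift_kind = "nucleophile_shift"))$test
  expect_equal(route(comp, imi)$chosen, "nucleophile_rf")
  expect_equal(route(comp, nuc)$chosen, "lasso")

  out <- predict_composite(comp, imi)
  expect_identical(out$predictions, predict(comp$nucleophile_rf, imi))
  expect_equal(out$decision$chosen, "nucleophile_rf")
})

test_that("per-reaction routing returns one decision per reaction", {
  out <- predict_composite(comp, comp_data$test, per_reaction = TRUE)
  expect_length(out$predictions, 27)
  expect_equal(nrow(out$decision), 27)
  expect_true(all(out$decision$chosen %in%
                  c("overall_svr", "nucleophile_rf", "lasso")))
})

test_that("the composite report carries scores and fit quality per set", {
  sets <- list(
    in_dist = comp_data$test,
    imine_shift = generate_reactions(synthetic_spec(seed = 101,
                                                    shift_kind = "imine_shift"))$test)
  rep <- composite_report(comp, sets)
  expect_equal(rep$set, c("in_dist", "imine_shift"))
  expect_equal(rep$chosen, c("overall_svr", "nucleophile_rf"))
  expect_true(all(is.finite(rep$mse)))
  expect_gt(rep$imine_avg_loglik[1], rep$imine_avg_loglik[2])

  unlabeled <- sets$in_dist
  unlabeled$target <- NULL
  rep2 <- composite_report(comp, list(u = unlabeled))
  expect_true(is.na(rep2$mse))
})

test_that("schema problems in routing inputs are reported", {
  broken <- comp_data$test
  keep <- setdiff(colnames(broken$features), "SL")
  broken$features <- broken$features[, keep]
  broken$roles <- broken$roles[keep]
  expect_error(route(comp, broken), "schema error.*SL")
  empty <- subset_rows(comp_data$test, integer())
  expect_error(route(comp, empty), "empty")
  bad_tab <- comp_data$train
  expect_error(composite_model(bad_tab, imine_features = c("C", "N", "SL", "nope"),
                               k_max = 2),
               "schema error")
})

test_that("composite archives restore routing and predictions exactly", {
  path <- tempfile(fileext = ".rds")
  save_composite(comp, path)
  back <- load_composite(path)
  expect_identical(predict(back, comp_data$test),
                   predict(comp, comp_data$test))
  d1 <- route(comp, comp_data$test); d2 <- route(back, comp_data$test)
  expect_equal(d1$nucleophile_avg_loglik, d2$nucleophile_avg_loglik)
  expect_identical(d1$chosen, d2$chosen)
})
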