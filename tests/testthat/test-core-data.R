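test_that("reaction tables validate their schema", {
  tab <- toy_table(n = 3)
  expect_s3_class(tab, "reaction_table")
  expect_equal(dim(tab), c(3L, 3L))
  expect_setequal(unique(tab$roles), c("nucleophile", "imine"))

  x <- matrix(1:6, 3, dimnames = list(NULL, c("a", "b")))
  expect_error(reaction_table(x, c(a = "nucleophile")), "no role.*'b'")
  expect_error(reaction_table(x, c(a = "nucleophile", b = "ligand")),
               "unknown role")
  x[2, 1] <- NA
  expect_error(reaction_table(x, c(a = "nucleophile", b = "imine")),
               "non-finite")
  expect_error(toy_table(n = 4, target = 1:3), "target length")
})

test_that("CSV round-trip preserves tables bit for bit", {
  tab <- toy_table(n = 10, p_nuc = 4, p_imi = 3, p_solv = 1, seed = 42)
  dp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  write_feature_table(tab, dp, mp)
  back <- read_feature_table(dp, mp)
  expect_identical(back$features, tab$features)
  expect_identical(back$target, tab$target)
  expect_identical(back$roles, tab$roles)
  expect_identical(back$ids, tab$ids)

  # unlabeled and empty tables round-trip too
  tab$target <- NULL
  write_feature_table(tab, dp, mp)
  expect_null(read_feature_table(dp, mp)$target)
  empty <- reaction_table(tab$features[0, , drop = FALSE], tab$roles,
                          ids = character())
  write_feature_table(empty, dp, mp)
  expect_equal(nrow(read_feature_table(dp, mp)$features), 0)
})

test_that("reading rejects unmapped and non-numeric columns", {
  tab <- toy_table(n = 3)
  dp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  write_feature_table(tab, dp, mp)
  meta <- read.csv(mp)
  write.csv(meta[-1, ], mp, row.names = FALSE)
  expect_error(read_feature_table(dp, mp), "schema error.*nuc1")

  write_feature_table(tab, dp, mp)
  raw <- read.csv(dp, check.names = FALSE, colClasses = "character")
  raw[2, "nuc2"] <- "not-a-number"
  write.csv(raw, dp, row.names = FALSE, quote = FALSE)
  expect_error(read_feature_table(dp, mp), "data error.*nuc2.*row 2")
})

test_that("feature views drop exactly the excluded role's columns", {
  d <- generate_reactions(synthetic_spec(seed = 1))
  tab <- d$train
  expect_equal(ncol(tab$features), 282)
  no_imi <- subset_by_view(tab, "exclude_imine")
  no_nuc <- subset_by_view(tab, "exclude_nucleophile")
  expect_equal(ncol(no_imi$features), 260)
  expect_equal(ncol(no_nuc$features), 267)
  expect_identical(subset_by_view(tab, "all"), tab)
  # dropped sets are disjoint and solvent/catalyst columns always survive
  dropped_imi <- setdiff(colnames(tab$features), colnames(no_imi$features))
  dropped_nuc <- setdiff(colnames(tab$features), colnames(no_nuc$features))
  expect_length(intersect(dropped_imi, dropped_nuc), 0)
  expect_true(all(tab$roles[dropped_imi] == "imine"))
  expect_true(all(tab$roles[dropped_nuc] == "nucleophile"))
  expect_identical(no_imi$target, tab$target)
  # column order of the survivors is preserved
  expect_identical(colnames(no_imi$features),
                   setdiff(colnames(tab$features), dropped_imi))
})

test_that("enantioselectivity <-> enantiomeric ratio conversion", {
  expect_equal(ddg_from_er(1, 298.15), 0)
  expect_equal(ddg_from_er(10, 298.15), -1.3642, tolerance = 1e-4)
  expect_equal(er_from_ddg(-1.3642, 298.15), 10, tolerance = 1e-4)
  expect_equal(er_from_ddg(0), 1)
  # inverse pair over a grid, tight relative tolerance
  for (T in c(273, 298.15, 350)) {
    ddg <- seq(-5, 5, by = 0.5)
    expect_equal(ddg_from_er(er_from_ddg(ddg, T), T), ddg,
                 tolerance = 1e-12)
  }
  # monotone decreasing in ddg at fixed temperature
  expect_true(all(diff(er_from_ddg(seq(-2, 2, 0.1))) < 0))
  expect_error(ddg_from_er(0), "domain error")
  expect_error(ddg_from_er(2, -1), "domain error")
  expect_error(er_from_ddg(1, 0), "domain error")
})

test_that("target screening flags outliers and reports normality", {
  set.seed(2)
  y <- rnorm(342)
  sc <- screen_target(y)
  expect_gt(sc$shapiro_p, 0.05)
  expect_length(sc$outlier_ids, 0)
  expect_true(sc$z_min <= sc$z_max)

  y2 <- c(y, mean(y) + 5 * sd(y))
  sc2 <- screen_target(y2)
  expect_true(as.character(length(y2)) %in% sc2$outlier_ids)

  expect_error(screen_target(rep(1, 10)), "zero variance")
  expect_error(screen_target(c(1, 2)), "at least 3")
})
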