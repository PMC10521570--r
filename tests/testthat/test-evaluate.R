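test_that("binarize applies a strict threshold and validates its input", {
  expect_true(all(binarize(matrix(0.4, 3, 3)) == 0))
  expect_true(all(binarize(matrix(0.6, 3, 3)) == 1))
  expect_true(all(binarize(matrix(0.5, 3, 3)) == 0))  # tie maps to 0
  expect_error(binarize(matrix(1.2, 2, 2)), "outside")
  expect_error(binarize(matrix(-0.1, 2, 2)), "outside")
})

test_that("Dice coefficient identities and arithmetic", {
  set.seed(12)
  a <- matrix(rbinom(64, 1, 0.4), 8, 8)
  a[1, 1] <- 1
  expect_equal(dice_coefficient(a, a), 1)
  b <- 1 - a
  expect_equal(dice_coefficient(a, b), 0)
  # |A| = 4, |B| = 6, |A intersect B| = 3 -> 2*3/10
  A <- matrix(0, 4, 4); A[1, 1:4] <- 1
  B <- matrix(0, 4, 4); B[1, 2:4] <- 1; B[2, 1:3] <- 1
  expect_equal(dice_coefficient(A, B), 0.6)
  # conventions and symmetry
  z <- matrix(0, 4, 4)
  expect_equal(dice_coefficient(z, z), 1)
  expect_equal(dice_coefficient(A, z), 0)
  expect_equal(dice_coefficient(A, B), dice_coefficient(B, A))
  expect_error(dice_coefficient(A, matrix(0, 4, 5)), "differ")
  expect_error(dice_coefficient(A, matrix(0.5, 4, 4)), "binary")
})

test_that("Dice is 1 exactly when non-empty masks coincide", {
  set.seed(13)
  for (i in 1:10) {
    a <- matrix(rbinom(36, 1, 0.5), 6, 6)
    b <- matrix(rbinom(36, 1, 0.5), 6, 6)
    d <- dice_coefficient(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    if (sum(a) > 0 && d == 1) expect_identical(a, b)
  }
})

test_that("evaluate_model scores oracle and degenerate predictors correctly", {
  cohort <- generate_cohort(tiny_params(n_subjects = 2L))
  slices <- prepare_subjects(cohort, c("sub01", "sub02"), size = 32L)
  st <- cnnres:::stack_slices(slices)
  oracle <- function(x) st$mask  # returns the ground truth
  rpt <- evaluate_model(oracle, slices)
  expect_equal(attr(rpt, "mean_dice"), 1)
  zero <- function(x) array(0, dim(x))
  rpt0 <- evaluate_model(zero, slices)
  expect_equal(attr(rpt0, "mean_dice"), 0)  # every slice has a lesion
  expect_error(evaluate_model(zero, list()), "empty")
})

test_that("the report matches a per-slice brute-force recomputation", {
  cohort <- generate_cohort(tiny_params(n_subjects = 1L))
  slices <- prepare_subjects(cohort, "sub01", size = 32L)
  set.seed(14)
  rand_probs <- NULL
  rand_model <- function(x) {
    p <- array(runif(length(x)), dim(x))
    rand_probs <<- p
    p
  }
  rpt <- evaluate_model(rand_model, slices, threshold = 0.5)
  for (i in seq_along(slices)) {
    d <- dice_coefficient(slices[[i]]$mask,
                          (rand_probs[, , 1, i] > 0.5) + 0)
    expect_equal(rpt$dice[i], d)
  }
})

test_that("flip-augmented evaluation doubles the sample count", {
  cohort <- generate_cohort(tiny_params(n_subjects = 1L))
  slices <- prepare_subjects(cohort, "sub01", size = 32L)
  rpt1 <- evaluate_model(function(x) array(0.6, dim(x)), slices)
  rpt2 <- evaluate_model(function(x) array(0.6, dim(x)), slices,
                         flip_augment = TRUE)
  expect_equal(nrow(rpt2), 2L * nrow(rpt1))
  expect_setequal(unique(rpt2$transform), c("f0r0", "f1r0"))
})

test_that("summaries aggregate by slice and by subject", {
  cohort <- generate_cohort(tiny_params(n_subjects = 2L))
  slices <- prepare_subjects(cohort, c("sub01", "sub02"), size = 32L)
  st <- cnnres:::stack_slices(slices)
  rpt <- evaluate_model(function(x) st$mask, slices)
  s1 <- summary(rpt)
  expect_equal(s1$mean_dice, 1)
  s2 <- summary(rpt, by = "subject")
  expect_setequal(s2$subject, c("sub01", "sub02"))
  expect_true(all(s2$mean_dice == 1))
  # report files
  dir <- withr::local_tempdir()
  paths <- write_dice_report(rpt, file.path(dir, "report"))
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[2L])
  expect_equal(js$mean_dice_slices, 1)
})
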