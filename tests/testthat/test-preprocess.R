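test_that("center_brain moves a bright square's centroid to the image centre", {
  img <- matrix(0, 40, 40)
  img[1:10, 1:10] <- 1
  out <- center_brain(img)
  fg <- which(out > 0.1, arr.ind = TRUE)
  centroid <- colMeans(fg)
  expect_lt(max(abs(centroid - c(20.5, 20.5))), 1)
  expect_equal(sum(out), sum(img))  # zero-fill, nothing clipped
})

test_that("centering is a no-op on centred or all-background slices", {
  disk <- matrix(0, 31, 31)
  for (i in 1:31) for (j in 1:31)
    if ((i - 16)^2 + (j - 16)^2 <= 64) disk[i, j] <- 1
  expect_identical(center_brain(disk), disk)
  expect_identical(center_brain(matrix(0, 8, 8)), matrix(0, 8, 8))
})

test_that("centering is idempotent up to one pixel", {
  set.seed(3)
  for (rep in 1:5) {
    img <- matrix(0, 30, 30)
    r0 <- sample(1:18, 1); c0 <- sample(1:18, 1)
    img[r0:(r0 + 7), c0:(c0 + 7)] <- runif(64, 0.5, 1)
    once <- center_brain(img)
    twice <- center_brain(once)
    s1 <- cnnres:::center_shift(once)
    expect_lte(max(abs(s1)), 1L)
    expect_lte(max(abs(cnnres:::center_shift(twice))), 1L)
  }
})

test_that("center_volume applies one joint shift to image and mask per slice", {
  cohort <- generate_cohort(tiny_params(n_subjects = 1L))
  v <- cohort[[1L]]
  cv <- center_volume(v)
  expect_equal(sum(cv$mask), sum(v$mask))
  # relative geometry preserved: lesion voxels still inside bright brain
  les <- which(cv$mask == 1)
  expect_true(all(cv$image[les] > 0.25))
})

test_that("select_lesion_slices returns exactly the positive slices in order", {
  img <- array(runif(6 * 6 * 10), c(6, 6, 10))
  msk <- array(0, c(6, 6, 10))
  msk[3, 3, c(2, 5, 6)] <- 1
  v <- subject_volume(img, msk, "s1", "DWI")
  sl <- select_lesion_slices(v)
  expect_length(sl, 3L)
  expect_equal(vapply(sl, function(s) s$slice_index, integer(1)), c(2L, 5L, 6L))
  expect_identical(sl[[1L]]$image, img[, , 2])
  # brute-force oracle: per-slice scan
  oracle <- sum(vapply(1:10, function(z) sum(msk[, , z]) > 0, logical(1)))
  expect_equal(length(sl), oracle)
  # all-zero mask -> empty list
  v0 <- subject_volume(img, array(0, c(6, 6, 10)), "s1", "DWI")
  expect_length(select_lesion_slices(v0), 0L)
})

test_that("per-subject lesion slice counts match the generator's range", {
  cohort <- generate_cohort(tiny_params(n_subjects = 4L,
                                        lesion_slice_range = c(4L, 8L)))
  for (v in cohort) {
    n <- length(select_lesion_slices(v))
    expect_gte(n, 4L); expect_lte(n, 8L)
    # oracle: count mask slices with positive sum directly
    expect_equal(n, sum(apply(v$mask, 3, sum) > 0))
  }
})

test_that("to_model_space resizes, normalises to [0,1] and keeps masks binary", {
  img <- matrix(runif(48 * 48, 1, 5), 48, 48)
  msk <- matrix(0, 48, 48); msk[20:30, 10:22] <- 1
  sl <- to_model_space(slice_pair(img, msk, "s", "DWI", 1L), size = 32L)
  expect_equal(dim(sl$image), c(32L, 32L))
  expect_equal(range(sl$image), c(0, 1))
  expect_true(all(sl$mask %in% c(0, 1)))
  expect_gt(sum(sl$mask), 0)
  # 160x160 input: resampling is the identity, only normalisation applies
  img2 <- matrix(runif(160 * 160, 2, 4), 160, 160)
  sl2 <- to_model_space(slice_pair(img2, (img2 > 3) + 0, "s", "DWI", 1L))
  expect_equal(sl2$image, (img2 - min(img2)) / diff(range(img2)))
  # constant image -> all zeros by convention
  sl3 <- to_model_space(slice_pair(matrix(7, 160, 160),
                                   matrix(0, 160, 160), "s", "DWI", 1L))
  expect_true(all(sl3$image == 0))
})

test_that("split_by_subject reproduces the published partition arithmetic", {
  ids44 <- sprintf("s%02d", 1:44)
  sp <- split_by_subject(ids44, c(34L, 5L, 5L), seed = 2L)
  expect_length(sp$train, 34L); expect_length(sp$val, 5L)
  expect_length(sp$test, 5L)
  ids30 <- sprintf("s%02d", 1:30)
  sp30 <- split_by_subject(ids30, c(20L, 5L, 5L), seed = 2L)
  expect_equal(vapply(sp30, length, integer(1)),
               c(train = 20L, val = 5L, test = 5L))
  # disjoint, exhaustive, deterministic
  expect_length(intersect(sp$train, c(sp$val, sp$test)), 0L)
  expect_setequal(c(sp$train, sp$val, sp$test), ids44)
  expect_identical(sp, split_by_subject(ids44, c(34L, 5L, 5L), seed = 2L))
  expect_error(split_by_subject(ids44, c(30L, 5L, 5L)), "sum")
})

test_that("no subject leaks across partitions at the slice level", {
  cohort <- generate_cohort(tiny_params(n_subjects = 5L))
  ids <- unique(vapply(cohort, function(v) v$subject_id, character(1)))
  sp <- split_by_subject(ids, c(3L, 1L, 1L), seed = 9L)
  slices <- lapply(list(sp$train, sp$val, sp$test), function(part)
    prepare_subjects(cohort, part, size = 32L))
  subj_sets <- lapply(slices, function(ss)
    unique(vapply(ss, function(s) s$subject_id, character(1))))
  expect_length(intersect(subj_sets[[1]], subj_sets[[2]]), 0L)
  expect_length(intersect(subj_sets[[1]], subj_sets[[3]]), 0L)
  expect_length(intersect(subj_sets[[2]], subj_sets[[3]]), 0L)
})

test_that("slice container round-trips through NIfTI stacks with manifest", {
  cohort <- generate_cohort(tiny_params(n_subjects = 2L))
  slices <- prepare_subjects(cohort, c("sub01", "sub02"), size = 32L)
  dir <- withr::local_tempdir()
  export_slices(slices, dir, "prep")
  back <- import_slices(dir, "prep")
  expect_length(back, length(slices))
  expect_equal(back[[3L]]$mask, slices[[3L]]$mask)
  expect_equal(back[[3L]]$image, float32_snap(slices[[3L]]$image))
  expect_identical(back[[3L]]$subject_id, slices[[3L]]$subject_id)
})
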