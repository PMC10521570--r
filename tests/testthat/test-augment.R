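test_that("quarter-turn rotation follows the counter-clockwise convention", {
  sl <- slice_pair(matrix(c(1, 3, 2, 4), 2, 2), matrix(0, 2, 2), "s", "DWI", 1L)
  # [[1,2],[3,4]] in row-major notation -> one CCW turn -> [[2,4],[1,3]]
  out <- apply_transform(sl, flip = FALSE, quarter_turns = 1L)
  expect_equal(out$image, matrix(c(2, 1, 4, 3), 2, 2))
  expect_identical(out$transform_id, "f0r1")
})

test_that("flip is an involution and four quarter turns are the identity", {
  sl <- asym_slice()
  flip2 <- apply_transform(apply_transform(sl, flip = TRUE), flip = TRUE)
  expect_equal(flip2$image, sl$image)
  expect_equal(flip2$mask, sl$mask)
  rot4 <- sl
  for (i in 1:4) rot4 <- apply_transform(rot4, quarter_turns = 1L)
  expect_equal(rot4$image, sl$image)
  expect_error(apply_transform(slice_pair(matrix(0, 2, 3), matrix(0, 2, 3),
                                          "s", "DWI", 1L)), "square")
})

test_that("policies have the stated sizes and augment preserves order and masks", {
  train_pol <- augmentation_policy("train")
  eval_pol <- augmentation_policy("eval")
  expect_equal(nrow(train_pol$transforms), 8L)
  expect_equal(nrow(eval_pol$transforms), 2L)
  sl <- asym_slice()
  out <- augment(list(sl, sl), train_pol)
  expect_length(out, 16L)
  # lock-step: every output mask has the same lesion pixel count
  expect_true(all(vapply(out, function(s) sum(s$mask), numeric(1)) ==
                    sum(sl$mask)))
  # pixel multiset preserved (pure index permutation, no interpolation)
  expect_true(all(vapply(out, function(s)
    identical(sort(as.vector(s$image)), sort(as.vector(sl$image))),
    logical(1))))
  expect_length(augment(list(), train_pol), 0L)
})

test_that("the 8 training transforms of an asymmetric slice are pairwise distinct", {
  out <- augment(list(asym_slice()), augmentation_policy("train"))
  for (i in 1:7) for (j in (i + 1):8)
    expect_false(identical(out[[i]]$image, out[[j]]$image),
                 info = sprintf("transforms %d and %d coincide", i, j))
})

test_that("the transform set is closed under composition (dihedral group)", {
  sl <- asym_slice()
  canon <- lapply(augment(list(sl), augmentation_policy("train")),
                  function(s) s$image)
  # brute-force composition table: applying any transform to any transformed
  # slice lands back in the 8-element set
  for (f1 in c(FALSE, TRUE)) for (r1 in 0:3) {
    s1 <- apply_transform(sl, f1, r1)
    for (f2 in c(FALSE, TRUE)) for (r2 in 0:3) {
      s2 <- apply_transform(s1, f2, r2)
      hits <- vapply(canon, function(im) identical(im, s2$image), logical(1))
      expect_equal(sum(hits), 1L)
    }
  }
})

test_that("sample accounting reproduces the published ledger", {
  led <- augmentation_ledger(560L, 120L, 112L, n_modalities = 2L)
  expect_equal(led$augmented, c(4480L, 240L, 224L))
  expect_equal(led$total_all_modalities, c(8960L, 480L, 448L))
  # direct check with real slice lists
  mk <- function(n) replicate(n, asym_slice(4L), simplify = FALSE)
  expect_length(augment(mk(560L), augmentation_policy("train")), 4480L)
  expect_length(augment(mk(120L), augmentation_policy("eval")), 240L)
  expect_length(augment(mk(112L), augmentation_policy("eval")), 224L)
})

test_that("Dice is invariant under any joint augmentation transform", {
  set.seed(5)
  msk <- matrix(rbinom(64, 1, 0.3), 8, 8)
  pred <- matrix(rbinom(64, 1, 0.3), 8, 8)
  base <- dice_coefficient(msk, pred)
  for (f in c(FALSE, TRUE)) for (r in 0:3) {
    sm <- apply_transform(slice_pair(msk, msk, "s", "DWI", 1L), f, r)
    sp <- apply_transform(slice_pair(pred, pred, "s", "DWI", 1L), f, r)
    expect_equal(dice_coefficient(sm$mask, sp$mask), base)
    expect_equal(dice_coefficient(sm$mask, sm$mask), 1)
  }
})
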