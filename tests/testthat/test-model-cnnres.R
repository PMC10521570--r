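test_that("the default convention reproduces the full output schedule", {
  spec <- cnnres_spec()
  expect_equal(spec$out_h[1L], 160L)
  expect_equal(spec$out_c[1L], 1L)
  got <- block_summary(spec)
  ref <- cnnres_reference_schedule()
  expect_equal(got$label, ref$label)
  for (i in seq_len(nrow(ref))) {
    expect_equal(unlist(got[i, c("out_h", "out_w", "out_c")]),
                 unlist(ref[i, c("out_h", "out_w", "out_c")]),
                 info = ref$label[i])
  }
})

test_that("a two-level toy variant halves sizes and doubles channels per level", {
  spec <- cnnres_spec(input_size = 32L, depth = 2L, base_filters = 8L)
  bs <- block_summary(spec)
  pick <- function(lbl) unname(unlist(
    bs[bs$label == lbl, c("out_h", "out_w", "out_c")]))
  expect_equal(pick("Transition Block 1"), c(16L, 16L, 8L))
  expect_equal(pick("Residual Block 1"), c(16L, 16L, 16L))
  expect_equal(pick("Transition Block 2"), c(8L, 8L, 16L))
  expect_equal(pick("Residual Block 2"), c(8L, 8L, 32L))
  expect_equal(pick("Output"), c(32L, 32L, 1L))
})

test_that("closed-form layer counts follow the conv and batch-norm formulas", {
  spec <- cnnres_spec()
  # first transition conv: 3x3, 1 -> 32 channels, biased
  expect_equal(spec$trainable[spec$layer == "tb1_conv"], 9 * 1 * 32 + 32)
  # its batch-norm: 2C trainable + 2C running statistics
  expect_equal(spec$trainable[spec$layer == "tb1_bn"], 64)
  expect_equal(spec$non_trainable[spec$layer == "tb1_bn"], 64)
})

test_that("default CNN-Res reports 5,952 non-trainable parameters both ways", {
  model <- build_cnnres(init = "zeros")
  rpt <- count_parameters(model)  # errors if allocated != closed form
  expect_identical(rpt$non_trainable, 5952)
  # independent closed form: two running statistics per normalised channel
  bn_channels <- sum(model$spec$out_c[model$spec$op == "bn"])
  expect_identical(bn_channels, 2976L)
  expect_identical(2L * bn_channels, 5952L)
  expect_identical(rpt$total, rpt$trainable + rpt$non_trainable)
})

test_that("allocated parameter arrays match the spec for every convention", {
  grid <- expand.grid(combine = c("concatenate", "projected_add"),
                      width_factor = c(0.5, 1, 2),
                      compress_bn = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    conv <- block_convention(combine = grid$combine[i],
                             width_factor = grid$width_factor[i],
                             compress_bn = grid$compress_bn[i])
    m <- build_cnnres(conv, input_size = 32L, depth = 2L, base_filters = 8L)
    expect_silent(count_parameters(m))  # framework == closed form
  }
})

test_that("parameter counts are invariant to seed and input size", {
  set.seed(1); r1 <- count_parameters(build_cnnres(init = "he_normal",
    input_size = 64L, depth = 2L, base_filters = 8L))
  set.seed(99); r2 <- count_parameters(build_cnnres(init = "he_normal",
    input_size = 64L, depth = 2L, base_filters = 8L))
  r3 <- count_parameters(cnnres_spec(input_size = 128L, depth = 2L,
                                     base_filters = 8L))
  expect_identical(r1$total, r2$total)
  expect_identical(r1$total, r3$total)
})

test_that("concatenative residual blocks double the channel count", {
  spec <- cnnres_spec()
  bs <- block_summary(spec)
  tb <- bs$out_c[grepl("^Transition Block", bs$label)]
  rb <- bs$out_c[grepl("^Residual Block", bs$label)]
  expect_equal(rb, 2L * tb)
  expect_equal(tb, c(32L, 64L, 128L, 256L))
})

test_that("forward pass maps inputs to same-size sigmoid maps in (0,1)", {
  m <- build_cnnres(input_size = 32L, depth = 2L, base_filters = 4L)
  set.seed(2)
  x <- array(runif(32 * 32 * 1 * 3), c(32, 32, 1, 3))
  y <- nn_forward(m, x)$out
  expect_equal(dim(y), c(32L, 32L, 1L, 3L))
  expect_true(all(y > 0 & y < 1))
})

test_that("invalid conventions and input sizes fail at construction", {
  expect_error(build_cnnres(block_convention(width_factor = 0.3)),
               "whole number")
  expect_error(build_cnnres(input_size = 100L), "divisible")
})

test_that("projected_add keeps the published channel schedule", {
  spec <- cnnres_spec(block_convention(combine = "projected_add"))
  got <- block_summary(spec)
  ref <- cnnres_reference_schedule()
  expect_equal(got$out_c[match(ref$label, got$label)], ref$out_c)
})
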