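test_that("soft Dice loss identities", {
  set.seed(6)
  t <- matrix(rbinom(64, 1, 0.3), 8, 8)
  expect_equal(soft_dice_loss(t, t), 0)
  z <- matrix(0, 8, 8)
  expect_equal(soft_dice_loss(z, z), 0)  # both empty: eps convention
  # 4 true pixels, 4 disjoint predicted pixels, eps = 1 -> 1 - 1/9
  t4 <- matrix(0, 4, 4); t4[1, 1:4] <- 1
  p4 <- matrix(0, 4, 4); p4[3, 1:4] <- 1
  expect_equal(soft_dice_loss(t4, p4, eps = 1), 1 - 1 / 9)
  expect_error(soft_dice_loss(t4, matrix(0, 4, 5)), "differ")
})

test_that("loss is bounded in [0,1] for arbitrary predictions", {
  set.seed(8)
  for (i in 1:20) {
    t <- matrix(rbinom(36, 1, runif(1)), 6, 6)
    p <- matrix(runif(36), 6, 6)
    l <- soft_dice_loss(t, p)
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("batch loss equals the brute-force per-image mean", {
  expect_equal(batch_loss(list(matrix(1, 2, 2), matrix(1, 2, 2)),
                          list(matrix(1, 2, 2), matrix(0.2, 2, 2)),
                          eps = 1e-9),
               mean(c(0, soft_dice_loss(matrix(1, 2, 2), matrix(0.2, 2, 2),
                                        eps = 1e-9))))
  set.seed(9)
  tx <- array(rbinom(5 * 5 * 4, 1, 0.3), c(5, 5, 1, 4))
  py <- array(runif(5 * 5 * 4), c(5, 5, 1, 4))
  oracle <- mean(vapply(1:4, function(i)
    soft_dice_loss(tx[, , 1, i], py[, , 1, i]), numeric(1)))
  expect_equal(batch_loss(tx, py), oracle)
  # N identical pairs leave the per-image loss unchanged
  t1 <- tx[, , , 1, drop = FALSE]
  rep4 <- array(rep(t1, 4), dim(tx))
  p1 <- py[, , , 1, drop = FALSE]
  prep4 <- array(rep(p1, 4), dim(py))
  expect_equal(batch_loss(rep4, prep4),
               soft_dice_loss(tx[, , 1, 1], py[, , 1, 1]))
  expect_error(batch_loss(list(), list()), "empty")
})

test_that("analytic gradients match finite differences through the graph", {
  set.seed(42)
  m <- build_cnnres(input_size = 16L, depth = 2L, base_filters = 2L,
                    dropout_rate = 0)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  tm <- array(rbinom(16 * 16 * 2, 1, 0.2), c(16, 16, 1, 2))
  fwd <- nn_forward(m, x, training = TRUE)
  grads <- cnnres:::nn_backward(m, fwd, cnnres:::batch_loss_grad(tm, fwd$out))
  lossfn <- function(model)
    batch_loss(tm, nn_forward(model, x, training = TRUE)$out)
  eps <- 1e-5
  for (nm in c("tb1_conv", "rb1_bn1", "br_conv2", "out_conv")) {
    for (k in names(grads[[nm]])) {
      i <- sample(length(grads[[nm]][[k]]), 1L)
      mp <- m; mp$params[[nm]][[k]][i] <- mp$params[[nm]][[k]][i] + eps
      mm <- m; mm$params[[nm]][[k]][i] <- mm$params[[nm]][[k]][i] - eps
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_equal(grads[[nm]][[k]][i], num, tolerance = 1e-4,
                   info = paste(nm, k))
    }
  }
})

test_that("1 - soft Dice converges to the hard Dice for binary predictions", {
  set.seed(10)
  t <- matrix(rbinom(49, 1, 0.4), 7, 7)
  p <- matrix(rbinom(49, 1, 0.4), 7, 7)
  expect_equal(1 - soft_dice_loss(t, p, eps = 1e-12),
               dice_coefficient(t, p), tolerance = 1e-9)
})
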