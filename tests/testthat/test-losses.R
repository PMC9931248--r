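# independent one-line oracle for the focal loss
focal_oracle <- function(y, t, gamma, w = rep(1, length(y))) {
  -sum(w * t * (1 - y)^gamma * log(y))
}

test_that("focal loss matches direct evaluation on reference cases", {
  # perfect prediction: log 1 = 0 regardless of gamma
  for (g in c(0, 1, 2, 5)) {
    expect_equal(focal_loss(c(1, 0), c(1, 0), loss_spec(gamma = g)), 0)
  }
  # fair binary guess at gamma 0 is plain cross-entropy ln 2
  expect_equal(focal_loss(c(0.5, 0.5), c(1, 0), loss_spec(gamma = 0)),
               log(2), tolerance = 1e-12)
  # confident prediction, gamma 2: -(0.1)^2 ln 0.9
  expect_equal(focal_loss(c(0.9, 0.1), c(1, 0), loss_spec(gamma = 2)),
               focal_oracle(c(0.9, 0.1), c(1, 0), 2), tolerance = 1e-12)
  expect_equal(focal_loss(c(0.9, 0.1), c(1, 0), loss_spec(gamma = 2)),
               0.00105361, tolerance = 1e-5)
  # class-weighted cross-entropy term
  expect_equal(
    focal_loss(c(0.5, 0.5), c(0, 1),
               loss_spec(gamma = 0, class_weights = c(0.9, 0.5))),
    0.5 * log(2), tolerance = 1e-12)
})

test_that("focal loss reduces to cross-entropy at gamma 0", {
  set.seed(42)
  for (i in 1:200) {
    L <- sample(2:6, 1)
    y <- runif(L); y <- y / sum(y)
    t <- integer(L); t[sample(L, 1)] <- 1L
    ce <- -log(max(y[t == 1L], 1e-7))
    expect_lt(abs(focal_loss(y, t, loss_spec(gamma = 0)) - ce), 1e-9)
  }
})

test_that("focal loss is monotone in gamma and in confidence", {
  # decreasing in gamma whenever y_true < 1
  for (ytrue in c(0.2, 0.5, 0.8)) {
    y <- c(ytrue, 1 - ytrue)
    t <- c(1, 0)
    losses <- sapply(c(0, 0.5, 1, 2, 3, 5),
                     function(g) focal_loss(y, t, loss_spec(gamma = g)))
    expect_true(all(diff(losses) < 0))
  }
  # decreasing in y_true for every gamma
  for (g in c(0, 1, 2, 3)) {
    ys <- seq(0.1, 0.9, by = 0.1)
    losses <- sapply(ys, function(p)
      focal_loss(c(p, 1 - p), c(1, 0), loss_spec(gamma = g)))
    expect_true(all(diff(losses) < 0))
  }
})

test_that("focal loss validates its inputs", {
  expect_error(focal_loss(c(0.5, 0.5), c(1, 0, 0), loss_spec()), "length")
  expect_error(focal_loss(c(0.5, 0.5), c(1, 1), loss_spec()), "one-hot")
  expect_error(focal_loss(c(0.5, 0.5), c(0.5, 0.5), loss_spec()), "one-hot")
  expect_error(focal_loss(c(0.7, 0.7), c(1, 0), loss_spec()), "sum to 1")
  expect_error(loss_spec(gamma = -1))
  expect_error(loss_spec(probability_floor = 0.5), "probability_floor")
})

test_that("class weights follow ln N_l / ln N", {
  cw <- compute_class_weights(c(1177, 816, 457, 57))
  expect_equal(cw$total, 2507L)
  expect_equal(cw$weights, log(c(1177, 816, 457, 57)) / log(2507),
               tolerance = 1e-14)
  # single class: ln N / ln N = 1
  expect_equal(compute_class_weights(c(10))$weights, 1)
  # a class observed once contributes weight 0
  expect_equal(compute_class_weights(c(99, 1))$weights[2], 0)
})

test_that("class weights are ordered with counts and bounded by 1", {
  set.seed(7)
  for (i in 1:50) {
    counts <- sample(1:5000, sample(2:6, 1))
    w <- compute_class_weights(counts)$weights
    expect_true(all(w[order(counts)] == sort(w)))
    expect_true(all(w <= 1 + 1e-15))
    expect_false(any(w == 1 & counts != sum(counts)))
  }
})

test_that("degenerate class counts raise errors", {
  expect_error(compute_class_weights(c(10, 0, 5)), "positive")
  expect_error(compute_class_weights(c(1)), "at least 2")
  expect_error(compute_class_weights(c(2.5, 3)), "integer")
})
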