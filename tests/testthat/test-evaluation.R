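# brute-force kappa oracle: enumerate agreement over all label pairs
kappa_pair_oracle <- function(cm) {
  n <- sum(cm)
  truth <- rep(seq_len(nrow(cm)) - 1L, rowSums(cm))
  pred <- unlist(lapply(seq_len(nrow(cm)), function(i)
    rep(seq_len(ncol(cm)) - 1L, cm[i, ])))
  po <- mean(truth == pred)
  # expected agreement from all n^2 cross pairs of marginal draws
  agree <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    agree <- agree + (truth[i] == pred[j])
  }
  pe <- agree / n^2
  if (abs(1 - pe) < 1e-15) return(if (abs(po - 1) < 1e-15) 1 else 0)
  (po - pe) / (1 - pe)
}

test_that("confusion matrix counts truth rows against prediction columns", {
  expect_equal(confusion_matrix(0:3, 0:3, 4), diag(4) * 1L,
               ignore_attr = TRUE)
  expect_equal(sum(diag(confusion_matrix(0:3, 0:3, 4))), 4)
  expect_equal(confusion_matrix(integer(0), integer(0), 3),
               matrix(0L, 3, 3))
  expect_equal(confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2),
               matrix(c(1L, 0L, 1L, 2L), 2, 2))
  expect_error(confusion_matrix(0:2, 0:1, 3), "length")
  expect_error(confusion_matrix(c(0, 3), c(0, 1), 3), "lie in")
})

test_that("kappa matches hand-computed reference values", {
  expect_equal(cohen_kappa(diag(c(5, 3, 2))), 1)
  expect_equal(cohen_kappa(matrix(c(25, 25, 25, 25), 2, 2)), 0)
  # p_o = 0.7, p_e = 0.5 -> kappa 0.4
  expect_equal(cohen_kappa(matrix(c(20, 10, 5, 15), 2, 2)), 0.4)
  expect_error(cohen_kappa(matrix(0, 2, 2)), "empty")
})

test_that("kappa agrees with the brute-force pair oracle on random matrices", {
  set.seed(11)
  for (i in 1:40) {
    L <- sample(2:4, 1)
    cm <- matrix(sample(0:6, L * L, replace = TRUE), L, L)
    if (sum(cm) == 0) cm[1, 1] <- 1
    expect_equal(cohen_kappa(cm), kappa_pair_oracle(cm), tolerance = 1e-12)
  }
})

test_that("precision and recall follow the declared conventions", {
  cm <- matrix(c(9, 1, 1, 9), 2, 2)  # TP=9 FP=1 FN=1 for class 1
  pr <- precision_recall(cm, 1)
  expect_equal(unname(pr), c(0.9, 0.9))
  expect_equal(unname(precision_recall(diag(c(4, 6)), 1)), c(1, 1))
  # no predicted positives: precision NaN with warning, recall 0
  cm2 <- matrix(c(5, 3, 0, 0), 2, 2)
  expect_warning(pr2 <- precision_recall(cm2, 1), "undefined")
  expect_true(is.nan(pr2["precision"]))
  expect_equal(unname(pr2["recall"]), 0)
})

test_that("accuracy equals prevalence-weighted mean of per-class recall", {
  set.seed(13)
  for (i in 1:20) {
    L <- sample(2:5, 1)
    truth <- sample(0:(L - 1), 60, replace = TRUE)
    pred <- sample(0:(L - 1), 60, replace = TRUE)
    er <- eval_report(truth, pred, L)
    prev <- rowSums(er$confusion) / sum(er$confusion)
    rec <- ifelse(is.nan(er$recall), 0, er$recall)
    expect_equal(er$accuracy, sum(prev * rec), tolerance = 1e-12)
  }
})

test_that("grouped split keeps all of a subject's patches together", {
  man <- data.frame(subject_id = rep(sprintf("s%02d", 1:10), each = 2),
                    image_id = sprintf("img%02d", 1:20))
  sp <- group_split(man, seed = 1)
  expect_equal(sort(as.integer(table(sp$subjects$split))), c(1L, 1L, 8L))
  per_subject <- tapply(sp$manifest$split, sp$manifest$subject_id,
                        function(x) length(unique(x)))
  expect_true(all(per_subject == 1))
  # determinism
  sp2 <- group_split(man, seed = 1)
  expect_identical(sp$subjects, sp2$subjects)
  expect_error(group_split(data.frame(subject_id = c("a", "b"))), "3 subjects")
})

test_that("grouped split ratios and leakage hold over many seeds", {
  set.seed(17)
  man <- data.frame(subject_id = rep(sprintf("s%02d", 1:50),
                                     times = sample(1:6, 50, replace = TRUE)))
  man$image_id <- paste0(man$subject_id, "_", seq_len(nrow(man)))
  for (seed in 1:20) {
    sp <- group_split(man, seed = seed)
    counts <- table(factor(sp$subjects$split, c("train", "val", "test")))
    expect_true(all(abs(counts - c(40, 5, 5)) <= 1))
    leak <- tapply(sp$manifest$split, sp$manifest$subject_id,
                   function(x) length(unique(x)))
    expect_equal(sum(leak > 1), 0)
  }
})
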