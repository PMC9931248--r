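test_that("network gradients match finite differences", {
  set.seed(1)
  net <- mdtnet:::nn_build("tiny", 4, input_px = 30)
  x <- array(runif(30 * 30 * 3 * 3), c(30, 30, 3, 3))
  labels <- c(0L, 2L, 3L)
  spec <- loss_spec(gamma = 2, class_weights = c(0.9, 0.8, 0.7, 0.5))
  lossval <- function(layers) {
    fw <- mdtnet:::nn_forward(layers, x)
    mdtnet:::batch_focal_loss(mdtnet:::nn_softmax(fw$out), labels, spec)$loss
  }
  fw <- mdtnet:::nn_forward(net$layers, x, record = TRUE)
  bl <- mdtnet:::batch_focal_loss(mdtnet:::nn_softmax(fw$out), labels, spec)
  bw <- mdtnet:::nn_backward(net$layers, fw$cache, bl$dlogits)
  for (li in seq_along(net$layers)) {
    g <- bw$grads[[li]]
    if (is.null(g)) next
    for (k in sample(length(net$layers[[li]]$W), 4)) {
      l2 <- net$layers
      eps <- 1e-5
      l2[[li]]$W[k] <- l2[[li]]$W[k] + eps
      lp <- lossval(l2)
      l2[[li]]$W[k] <- l2[[li]]$W[k] - 2 * eps
      lm <- lossval(l2)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - g$dW[k]) / max(1e-6, abs(num) + abs(g$dW[k])),
                1e-4)
    }
  }
})

test_that("the registry exposes distinct backbones with stated widths", {
  reg <- architecture_registry()
  expect_gte(nrow(reg), 4)
  expect_true("tiny" %in% reg$architecture_id)
  expect_equal(reg$feature_dim[reg$architecture_id == "tiny"], 64L)
  expect_equal(length(unique(reg$feature_dim)), nrow(reg))
  expect_error(submodel_spec("no_such_backbone"), "architecture_id")
})

test_that("fused feature width is the sum of sub-model feature dims", {
  cfg <- mdtnet_config(base_archs = c("tiny", "convnet_s", "convnet_m"),
                       n_focal = 0, n_classes = 4)
  expect_equal(fused_input_width(cfg), 64 + 96 + 128)
  cfg3 <- mdtnet_config(base_archs = "tiny", n_focal = 3, n_classes = 4)
  expect_equal(fused_input_width(cfg3), 4 * 64)
  # widths follow arbitrary spec dims (concatenation arithmetic)
  cfg_fake <- cfg
  cfg_fake$submodel_specs <- lapply(c(512, 2048, 1024), function(d) {
    s <- submodel_spec("tiny")
    s$feature_dim <- as.integer(d)
    s
  })
  expect_equal(fused_input_width(cfg_fake), 3584)
  # gamma of the focal members runs 1..n
  gammas <- vapply(cfg3$submodel_specs, function(s) s$loss$gamma, numeric(1))
  expect_equal(gammas, c(0, 1, 2, 3))
})

test_that("training keeps the best validation checkpoint and is seeded", {
  d <- small_validity_data()
  m1 <- train_submodel(submodel_spec("tiny"), d$train, d$val, 2L,
                       epochs = 3L, lr = 1e-3, seed = 31)
  expect_gte(m1$best_val_accuracy, m1$history$val_accuracy[1])
  expect_equal(m1$best_val_accuracy, max(m1$history$val_accuracy))
  m2 <- train_submodel(submodel_spec("tiny"), d$train, d$val, 2L,
                       epochs = 3L, lr = 1e-3, seed = 31)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$history, m2$history)
  expect_error(train_submodel(submodel_spec("tiny"), d$train, d$val, 1L,
                              epochs = 1L), "n_classes")
  expect_error(patch_dataset(array(0, c(150, 150, 3, 0)), integer(0)))
})

test_that("feature extraction is deterministic with the declared width", {
  m <- quick_grading_submodel()
  d <- small_grading_data()
  f1 <- extract_features(m, d$test$patches)
  expect_equal(ncol(f1), m$spec$feature_dim)
  expect_equal(nrow(f1), d$test$n)
  f2 <- extract_features(m, d$test$patches)
  expect_identical(f1, f2)
  # patches from different grades produce distinct features
  i0 <- which(d$test$labels == 0)[1]
  i1 <- which(d$test$labels > 0)[1]
  if (!is.na(i0) && !is.na(i1)) {
    expect_false(isTRUE(all.equal(f1[i0, ], f1[i1, ])))
  }
  untrained <- m
  untrained$trained <- FALSE
  expect_error(extract_features(untrained, d$test$patches), "not trained")
})

test_that("fusion trains only the head and freezes sub-models bit-exactly", {
  d <- small_grading_data()
  cfg <- mdtnet_config("tiny", n_focal = 1, n_classes = 4)
  subs <- train_submodels(cfg, d$train, d$val, epochs = 2L, lr = 1e-3,
                          seed = 41)
  before <- lapply(subs, function(s) s$layers)
  ens <- build_and_train_fusion(cfg, subs, d$train, d$val, epochs = 3L,
                                seed = 42)
  for (i in seq_along(subs)) {
    expect_identical(ens$submodels[[i]]$layers, before[[i]])
  }
  expect_equal(ncol(ens$fusion_head[[1]]$W) , cfg$fusion_hidden)
  expect_equal(nrow(ens$fusion_head[[1]]$W), fused_input_width(cfg))
  expect_error(build_and_train_fusion(cfg, subs[1], d$train, d$val),
               "match the configuration")
})

test_that("predictions are proper probabilities with low-index tie-break", {
  m <- quick_grading_submodel()
  d <- small_grading_data()
  pr <- predict(m, d$test$patches)
  expect_true(all(abs(rowSums(pr$probs) - 1) < 1e-6))
  expect_true(all(pr$labels >= 0 & pr$labels < 4))
  # tie-break contract of the argmax
  expect_equal(max.col(matrix(c(0.5, 0.5), 1), ties.method = "first") - 1L,
               0L)
  expect_error(predict(m, array(0, c(100, 100, 3))), "150")
})

test_that("grad-cam localizes a known single-conv response", {
  # stub: one conv with a single positive weight at channel 2 center,
  # uniform classifier -> heatmap must peak where that channel lights up
  W <- array(0, c(3, 3, 3, 1))
  W[2, 2, 2, 1] <- 1
  stub <- structure(list(
    spec = submodel_spec("tiny"),
    layers = list(
      list(type = "conv", W = W, b = 0),
      list(type = "relu"),
      list(type = "flatten"),
      list(type = "dense", W = matrix(1, 150 * 150, 2), b = c(0, 0))),
    feature_index = 3L, spatial_index = 2L, feature_dim = 150L * 150L,
    n_classes = 2L, trained = TRUE), class = "av_submodel")
  img <- array(0, c(150, 150, 3))
  img[80, 40, 2] <- 1
  heat <- explain_prediction(stub, img, 0L)
  expect_equal(dim(heat), c(150, 150))
  expect_gte(min(heat), 0)
  expect_lte(max(heat), 1)
  peak <- which(heat == max(heat), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(80, 40))

  # constant-output model (zero classifier): all-zero map
  stub0 <- stub
  stub0$layers[[4]]$W <- matrix(0, 150 * 150, 2)
  expect_true(all(explain_prediction(stub0, img, 0L) == 0))
  expect_error(explain_prediction(stub, img, 5L), "target_class")
})

test_that("checkpoints round-trip with a JSON sidecar", {
  m <- quick_validity_submodel()
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$architecture_id, "tiny")
  expect_equal(meta$n_classes, 2L)
  m2 <- load_checkpoint(path)
  expect_identical(m2$layers, m$layers)
})
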