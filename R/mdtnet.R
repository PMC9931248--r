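#' Sub-model specification
#'
#' One member of the diagnosis team: a backbone architecture from
#' [architecture_registry()] plus the loss it is trained with. Base-module
#' sub-models use cross-entropy (`gamma = 0`); focal-module sub-models use
#' the focal loss with `gamma` of 1, 2, 3, ...
#'
#' @param architecture_id backbone name from [architecture_registry()].
#' @param loss a [loss_spec()].
#' @return an object of class `submodel_spec` with the architecture's
#'   `feature_dim` attached.
#' @export
submodel_spec <- function(architecture_id = "tiny", loss = loss_spec()) {
  arch <- ARCHITECTURES[[architecture_id]]
  if (is.null(arch)) {
    stop("unknown architecture_id '", architecture_id,
         "'; see architecture_registry()")
  }
  stopifnot(inherits(loss, "loss_spec"))
  structure(list(architecture_id = architecture_id, loss = loss,
                 feature_dim = arch$feature_dim),
            class = "submodel_spec")
}

#' Patch dataset container
#'
#' @param patches 150 x 150 x 3 x N array of patch pixels in \[0, 1\].
#' @param labels integer vector of 0-based class labels, length N.
#' @return an object of class `patch_dataset`.
#' @export
patch_dataset <- function(patches, labels) {
  stopifnot(length(dim(patches)) == 4L, dim(patches)[4] == length(labels))
  if (length(labels) == 0L) stop("dataset is empty")
  structure(list(patches = patches, labels = as.integer(labels),
                 n = length(labels)), class = "patch_dataset")
}

#' Integer grade codes
#'
#' Maps grade names `none/mild/moderate/severe` to 0..3 (and back with
#' `int_to_grade`).
#' @param grade character vector of grade names.
#' @return integer vector (0-based), `NA` for missing grades.
#' @export
grade_to_int <- function(grade) {
  match(grade, GRADE_LEVELS) - 1L
}

#' @rdname grade_to_int
#' @param code integer vector of codes 0..3.
#' @export
int_to_grade <- function(code) {
  GRADE_LEVELS[code + 1L]
}

dataset_batches <- function(n, batch_size, shuffle = TRUE) {
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Train one sub-model
#'
#' Optimizes the sub-model's own loss (cross-entropy or focal, optionally
#' class-weighted) with Adam. After every epoch the model is evaluated on
#' the validation set and the parameters with the highest validation
#' accuracy are retained as the best checkpoint (kappa is recorded as well
#' for multi-class tasks). Fully seeded: the same seed and data give
#' identical results.
#'
#' @param spec a [submodel_spec()].
#' @param train,val [patch_dataset()]s.
#' @param n_classes number of classes (2 for validity, 4 for grading).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed for initialization and shuffling.
#' @param augment_config optional [augmentation_config()] applied to every
#'   training patch each epoch.
#' @param verbose print per-epoch progress.
#' @return an object of class `av_submodel` containing the best-checkpoint
#'   parameters, the spec and the training history.
#' @export
train_submodel <- function(spec, train, val, n_classes, epochs = 20L,
                           lr = 1e-4, batch_size = 32L, seed = 1L,
                           augment_config = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "submodel_spec"),
            inherits(train, "patch_dataset"), inherits(val, "patch_dataset"))
  if (max(train$labels, val$labels) >= n_classes || min(train$labels) < 0) {
    stop("labels outside [0, n_classes)")
  }
  with_seed(seed, {
    net <- nn_build(spec$architecture_id, n_classes)
    state <- adam_new(net$layers)
    best <- list(acc = -1, layers = NULL, kappa = NA_real_, epoch = 0L)
    history <- NULL
    step <- 0L
    for (ep in seq_len(epochs)) {
      for (ix in dataset_batches(train$n, batch_size)) {
        xb <- train$patches[, , , ix, drop = FALSE]
        if (!is.null(augment_config)) {
          for (j in seq_along(ix)) {
            xb[, , , j] <- augment(array(xb[, , , j], dim = dim(xb)[1:3]),
                                   augment_config)
          }
        }
        fw <- nn_forward(net$layers, xb, record = TRUE)
        probs <- nn_softmax(fw$out)
        bl <- batch_focal_loss(probs, train$labels[ix], spec$loss)
        bw <- nn_backward(net$layers, fw$cache, bl$dlogits)
        step <- step + 1L
        up <- adam_step(net$layers, bw$grads, state, lr, step)
        net$layers <- up$layers
        state <- up$state
      }
      ev <- evaluate_net(net$layers, val, n_classes)
      history <- rbind(history, data.frame(epoch = ep, val_accuracy = ev$acc,
                                           val_kappa = ev$kappa))
      if (ev$acc > best$acc) {
        best <- list(acc = ev$acc, layers = net$layers, kappa = ev$kappa,
                     epoch = ep)
      }
      if (verbose) {
        message(sprintf("epoch %d: val acc %.4f kappa %.4f", ep, ev$acc,
                        ev$kappa))
      }
    }
    structure(list(spec = spec, layers = best$layers,
                   feature_index = net$feature_index,
                   spatial_index = net$spatial_index,
                   feature_dim = net$feature_dim, n_classes = n_classes,
                   best_val_accuracy = best$acc, best_val_kappa = best$kappa,
                   best_epoch = best$epoch, history = history,
                   trained = TRUE, seed = seed),
              class = "av_submodel")
  })
}

evaluate_net <- function(layers, dataset, n_classes, batch_size = 64L) {
  pred <- predict_net(layers, dataset$patches, batch_size)
  cm <- confusion_matrix(dataset$labels, pred$labels, n_classes)
  list(acc = sum(diag(cm)) / sum(cm), kappa = cohen_kappa(cm))
}

predict_net <- function(layers, patches, batch_size = 64L) {
  n <- dim(patches)[4]
  probs <- NULL
  for (ix in dataset_batches(n, batch_size, shuffle = FALSE)) {
    fw <- nn_forward(layers, patches[, , , ix, drop = FALSE])
    probs <- rbind(probs, nn_softmax(fw$out))
  }
  list(labels = max.col(probs, ties.method = "first") - 1L, probs = probs)
}

#' Extract penultimate-layer features
#'
#' Deterministic inference-mode forward pass returning the activation of
#' the layer feeding the sub-model's classifier (width `feature_dim`).
#' These frozen features are what the fusion head consumes.
#'
#' @param model a trained `av_submodel`.
#' @param patches 150 x 150 x 3 x N array (or a single 150 x 150 x 3
#'   patch / `labeled_patch`).
#' @return N x feature_dim numeric matrix.
#' @export
extract_features <- function(model, patches) {
  stopifnot(inherits(model, "av_submodel"))
  if (!isTRUE(model$trained)) stop("model is not trained")
  if (inherits(patches, "labeled_patch")) patches <- patches$pixels
  if (length(dim(patches)) == 3L) {
    patches <- array(patches, dim = c(dim(patches), 1L))
  }
  n <- dim(patches)[4]
  out <- NULL
  for (ix in dataset_batches(n, 64L, shuffle = FALSE)) {
    fw <- nn_forward(model$layers[seq_len(model$feature_index)],
                     patches[, , , ix, drop = FALSE])
    out <- rbind(out, fw$out)
  }
  out
}

#' MDTNet ensemble configuration
#'
#' The ensemble combines base sub-models (cross-entropy, distinct
#' architectures) and `n_focal` focal sub-models (gamma = 1..n_focal,
#' shared architecture) by concatenating their frozen penultimate features
#' and training a two-layer fully-connected fusion head (hidden rectifier
#' layer, softmax output).
#'
#' @param base_archs character vector of base-module architecture ids.
#' @param n_focal number of focal sub-models (0..3); gamma takes 1..n_focal.
#' @param focal_arch architecture shared by the focal sub-models.
#' @param fusion_hidden hidden width of the fusion head.
#' @param n_classes 2 (validity) or 4 (grades).
#' @param class_weights optional [compute_class_weights()] result applied
#'   to every sub-model loss and the fusion loss.
#' @return an object of class `mdtnet_config`, including the list of
#'   [submodel_spec()]s.
#' @export
mdtnet_config <- function(base_archs = "tiny", n_focal = 3L,
                          focal_arch = base_archs[1], fusion_hidden = 256L,
                          n_classes = 4L, class_weights = NULL) {
  stopifnot(n_focal %in% 0:3, fusion_hidden >= 1, n_classes >= 2)
  w <- if (is.null(class_weights)) NULL else class_weights$weights
  specs <- lapply(base_archs, function(a)
    submodel_spec(a, loss_spec(gamma = 0, class_weights = w)))
  if (n_focal > 0) {
    specs <- c(specs, lapply(seq_len(n_focal), function(g)
      submodel_spec(focal_arch, loss_spec(gamma = g, class_weights = w))))
  }
  structure(list(base_archs = base_archs, n_focal = as.integer(n_focal),
                 focal_arch = focal_arch, submodel_specs = specs,
                 fusion_hidden = as.integer(fusion_hidden),
                 n_classes = as.integer(n_classes),
                 class_weights = class_weights),
            class = "mdtnet_config")
}

#' Width of the fused feature vector
#'
#' @param config an [mdtnet_config()].
#' @return sum of the feature dimensions of all included sub-models.
#' @export
fused_input_width <- function(config) {
  stopifnot(inherits(config, "mdtnet_config"))
  sum(vapply(config$submodel_specs, function(s) s$feature_dim, integer(1)))
}

#' Train all sub-models of an ensemble configuration
#'
#' Convenience loop calling [train_submodel()] for every spec in the
#' configuration (base module first, then focal module with gamma
#' 1..n_focal). Each sub-model gets a distinct seed derived from `seed`.
#'
#' @inheritParams train_submodel
#' @param config an [mdtnet_config()].
#' @return list of `av_submodel`s.
#' @export
train_submodels <- function(config, train, val, epochs = 20L, lr = 1e-4,
                            batch_size = 32L, seed = 1L,
                            augment_config = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "mdtnet_config"))
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                          length(config$submodel_specs)))
  lapply(seq_along(config$submodel_specs), function(i) {
    train_submodel(config$submodel_specs[[i]], train, val,
                   n_classes = config$n_classes, epochs = epochs, lr = lr,
                   batch_size = batch_size, seed = sub_seeds[i],
                   augment_config = augment_config, verbose = verbose)
  })
}

#' Build and train the fusion head
#'
#' Freezes the given pretrained sub-models, concatenates their
#' penultimate-layer features per patch into one vector of width
#' [fused_input_width()], and trains only the two fully-connected fusion
#' layers on those frozen features. Sub-model parameters are untouched
#' (bit-identical before and after).
#'
#' @param config an [mdtnet_config()].
#' @param submodels list of trained `av_submodel`s matching
#'   `config$submodel_specs`.
#' @param train,val [patch_dataset()]s.
#' @param epochs,lr,batch_size,seed fusion-head training controls.
#' @return an object of class `mdtnet_model`.
#' @export
build_and_train_fusion <- function(config, submodels, train, val,
                                   epochs = 30L, lr = 1e-3, batch_size = 32L,
                                   seed = 1L) {
  stopifnot(inherits(config, "mdtnet_config"))
  if (length(submodels) != length(config$submodel_specs)) {
    stop("number of sub-models does not match the configuration")
  }
  for (i in seq_along(submodels)) {
    s <- submodels[[i]]
    if (!inherits(s, "av_submodel") || !isTRUE(s$trained)) {
      stop("sub-model ", i, " is not a trained av_submodel")
    }
    if (s$feature_dim != config$submodel_specs[[i]]$feature_dim) {
      stop("sub-model ", i, " feature_dim does not match its spec")
    }
  }
  ftr <- do.call(cbind, lapply(submodels, extract_features, train$patches))
  fva <- do.call(cbind, lapply(submodels, extract_features, val$patches))
  stopifnot(ncol(ftr) == fused_input_width(config))

  w <- config$class_weights
  head_loss <- loss_spec(gamma = 0,
                         class_weights = if (is.null(w)) NULL else w$weights)
  with_seed(seed, {
    d <- ncol(ftr)
    head <- list(
      list(type = "dense", W = he_init(c(d, config$fusion_hidden), d),
           b = numeric(config$fusion_hidden)),
      list(type = "relu"),
      list(type = "dense",
           W = he_init(c(config$fusion_hidden, config$n_classes),
                       config$fusion_hidden),
           b = numeric(config$n_classes)))
    state <- adam_new(head)
    best <- list(acc = -1, head = NULL, epoch = 0L)
    step <- 0L
    for (ep in seq_len(epochs)) {
      for (ix in dataset_batches(nrow(ftr), batch_size)) {
        fw <- nn_forward(head, ftr[ix, , drop = FALSE], record = TRUE)
        probs <- nn_softmax(fw$out)
        bl <- batch_focal_loss(probs, train$labels[ix], head_loss)
        bw <- nn_backward(head, fw$cache, bl$dlogits)
        step <- step + 1L
        up <- adam_step(head, bw$grads, state, lr, step)
        head <- up$layers
        state <- up$state
      }
      pv <- nn_softmax(nn_forward(head, fva)$out)
      acc <- mean((max.col(pv, ties.method = "first") - 1L) == val$labels)
      if (acc > best$acc) best <- list(acc = acc, head = head, epoch = ep)
    }
    structure(list(config = config, submodels = submodels,
                   fusion_head = best$head,
                   best_val_accuracy = best$acc, best_epoch = best$epoch,
                   n_classes = config$n_classes, seed = seed),
              class = "mdtnet_model")
  })
}

#' Predict with a model
#'
#' For an `mdtnet_model`, concatenates the frozen sub-model features and
#' applies the fusion head; for an `av_submodel`, applies its own
#' classifier. The probability vector sums to 1 (softmax) and exact ties
#' resolve to the lowest class index.
#'
#' @param object a trained `mdtnet_model` or `av_submodel`.
#' @param patches 150 x 150 x 3 x N array, a single patch array, or a
#'   `labeled_patch`.
#' @param ... unused.
#' @return list with `labels` (0-based integer vector) and `probs`
#'   (N x n_classes matrix).
#' @export
predict.mdtnet_model <- function(object, patches, ...) {
  if (inherits(patches, "labeled_patch")) patches <- patches$pixels
  if (length(dim(patches)) == 3L) {
    patches <- array(patches, dim = c(dim(patches), 1L))
  }
  check_patch_size(patches)
  f <- do.call(cbind, lapply(object$submodels, extract_features, patches))
  probs <- nn_softmax(nn_forward(object$fusion_head, f)$out)
  list(labels = max.col(probs, ties.method = "first") - 1L, probs = probs)
}

#' @rdname predict.mdtnet_model
#' @export
predict.av_submodel <- function(object, patches, ...) {
  if (!isTRUE(object$trained)) stop("model is not trained")
  if (inherits(patches, "labeled_patch")) patches <- patches$pixels
  if (length(dim(patches)) == 3L) {
    patches <- array(patches, dim = c(dim(patches), 1L))
  }
  check_patch_size(patches)
  predict_net(object$layers, patches)
}

check_patch_size <- function(patches, size = 150L) {
  d <- dim(patches)
  if (d[1] != size || d[2] != size || d[3] != 3L) {
    stop("patches must be ", size, " x ", size, " x 3 (x N)")
  }
}

#' Gradient-weighted class activation map
#'
#' Grad-CAM on the last spatial (convolutional) layer of a sub-model: the
#' gradient of the target-class score is average-pooled per channel into
#' weights, the weighted channel sum is rectified, normalized to \[0, 1\]
#' and bilinearly upsampled to the patch size. For an ensemble the
#' designated sub-model is the first base sub-model, with the gradient
#' taken through the fusion head.
#'
#' @param model a trained `mdtnet_model` or `av_submodel`.
#' @param patch a single patch (150 x 150 x 3 array or `labeled_patch`).
#' @param target_class 0-based class index to explain.
#' @return 150 x 150 matrix with values in \[0, 1\].
#' @export
explain_prediction <- function(model, patch, target_class) {
  if (inherits(patch, "labeled_patch")) patch <- patch$pixels
  stopifnot(length(dim(patch)) == 3L)
  x <- array(patch, dim = c(dim(patch), 1L))

  if (inherits(model, "av_submodel")) {
    if (!isTRUE(model$trained)) stop("model is not trained")
    sub <- model
    if (target_class < 0 || target_class >= model$n_classes) {
      stop("target_class out of range")
    }
    fw <- nn_forward(sub$layers, x, record = TRUE)
    dout <- matrix(0, 1, ncol(fw$out))
    dout[1, target_class + 1L] <- 1
    bw <- nn_backward(sub$layers, fw$cache, dout,
                      from = length(sub$layers), to = sub$spatial_index)
    acts <- fw$cache[[sub$spatial_index]]   # input of relu = conv output
    dacts <- bw$dx
  } else if (inherits(model, "mdtnet_model")) {
    sub <- model$submodels[[1]]
    if (target_class < 0 || target_class >= model$n_classes) {
      stop("target_class out of range")
    }
    # forward all sub-models, record the designated one
    fw1 <- nn_forward(sub$layers, x, record = TRUE)
    feats <- lapply(model$submodels, extract_features, x)
    f <- do.call(cbind, feats)
    hfw <- nn_forward(model$fusion_head, f, record = TRUE)
    dout <- matrix(0, 1, ncol(hfw$out))
    dout[1, target_class + 1L] <- 1
    hbw <- nn_backward(model$fusion_head, hfw$cache, dout)
    dfeat <- hbw$dx[, seq_len(sub$feature_dim), drop = FALSE]
    bw <- nn_backward(sub$layers, fw1$cache, dfeat,
                      from = sub$feature_index, to = sub$spatial_index)
    acts <- fw1$cache[[sub$spatial_index]]
    dacts <- bw$dx
  } else {
    stop("model must be an av_submodel or mdtnet_model")
  }
  if (is.na(sub$spatial_index)) stop("model has no spatial feature maps")

  d <- dim(acts)  # (h, w, C, 1)
  da <- array(dacts, d)
  a <- array(pmax(acts, 0), d)
  cam <- matrix(0, d[1], d[2])
  for (ch in seq_len(d[3])) {
    cam <- cam + mean(da[, , ch, 1]) * a[, , ch, 1]
  }
  cam <- pmax(cam, 0)
  if (max(cam) > 0) cam <- cam / max(cam)
  bilinear_resize(cam, dim(patch)[1], dim(patch)[2])
}

bilinear_resize <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  ri <- seq(1, h, length.out = H)
  ci <- seq(1, w, length.out = W)
  r0 <- pmin(floor(ri), max(h - 1L, 1L)); c0 <- pmin(floor(ci), max(w - 1L, 1L))
  fr <- ri - r0; fc <- ci - c0
  r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
  m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
    m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r1, c1, drop = FALSE] * outer(fr, fc)
}

#' Save / load model checkpoints
#'
#' Writes the serialized model plus a JSON sidecar recording the spec,
#' seed and best validation metrics, mirroring common checkpointing
#' practice so runs can be inspected and resumed.
#'
#' @param model an `av_submodel` or `mdtnet_model`.
#' @param path checkpoint file path (`.rds`); the sidecar is `path` +
#'   `.json`.
#' @return `save_checkpoint`: the path, invisibly; `load_checkpoint`: the
#'   model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  meta <- if (inherits(model, "av_submodel")) {
    list(kind = "submodel", architecture_id = model$spec$architecture_id,
         gamma = model$spec$loss$gamma, feature_dim = model$feature_dim,
         n_classes = model$n_classes, seed = model$seed,
         best_val_accuracy = model$best_val_accuracy,
         best_val_kappa = model$best_val_kappa, best_epoch = model$best_epoch)
  } else {
    list(kind = "mdtnet", base_archs = model$config$base_archs,
         n_focal = model$config$n_focal,
         fused_width = fused_input_width(model$config),
         n_classes = model$n_classes, seed = model$seed,
         best_val_accuracy = model$best_val_accuracy,
         best_epoch = model$best_epoch)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
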