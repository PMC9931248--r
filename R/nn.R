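# Minimal CNN engine: a network is a list of layers, each a list with a
# `type` and (for conv/dense) parameter arrays. Tensors flow as (H, W, C, N)
# arrays until `flatten`, then as N x D matrices. Forward passes cache layer
# inputs so the same structure supports backprop (training and Grad-CAM).

nn_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

nn_forward <- function(layers, x, record = FALSE) {
  cache <- if (record) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (record) cache[[i]] <- x
    x <- switch(ly$type,
      avgpool = cpp_avgpool_fw(x, ly$k),
      conv = cpp_conv2d_fw(x, ly$W, ly$b, 1L),
      relu = {
        if (is.matrix(x)) pmax(x, 0) else {
          d <- dim(x); x <- pmax(x, 0); dim(x) <- d; x
        }
      },
      maxpool = {
        mp <- cpp_maxpool_fw(x, ly$k)
        if (record) attr(cache[[i]], "argmax") <- mp$argmax
        mp$out
      },
      flatten = {
        d <- dim(x)
        t(matrix(x, prod(d[1:3]), d[4]))
      },
      dense = sweep(x %*% ly$W, 2, ly$b, "+"),
      stop("unknown layer type: ", ly$type))
  }
  list(out = x, cache = cache)
}

# backward from layer `from` down to layer `to` (inclusive); returns the
# gradient w.r.t. the input of layer `to` and per-layer parameter grads
nn_backward <- function(layers, cache, dout, from = length(layers), to = 1L) {
  grads <- vector("list", length(layers))
  for (i in seq(from, to)) {
    ly <- layers[[i]]
    xin <- cache[[i]]
    dout <- switch(ly$type,
      avgpool = cpp_avgpool_bw(dout, ly$k, dim(xin)),
      conv = {
        bw <- cpp_conv2d_bw(xin, ly$W, dout, 1L)
        grads[[i]] <- list(dW = bw$dw, db = bw$db)
        bw$dx
      },
      relu = {
        m <- dout * (xin > 0)
        if (!is.matrix(xin)) dim(m) <- dim(xin)
        m
      },
      maxpool = cpp_maxpool_bw(dout, attr(xin, "argmax"), dim(xin)),
      flatten = {
        d <- dim(xin)
        array(t(dout), dim = d)
      },
      dense = {
        grads[[i]] <- list(dW = crossprod(xin, dout), db = colSums(dout))
        dout %*% t(ly$W)
      })
  }
  list(dx = dout, grads = grads)
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

# architecture registry ------------------------------------------------------

#' Sub-model architecture registry
#'
#' Named registry of convolutional backbones available to
#' [submodel_spec()]. All are compact CNNs sized for 150 x 150 patches on a
#' CPU; `tiny` (3 conv blocks, 64-d features) is the test backbone, the
#' others are progressively deeper/wider variants giving the base module
#' architectural diversity. Each entry reports the penultimate-layer width
#' (`feature_dim`).
#'
#' @return data frame with `architecture_id` and `feature_dim`.
#' @export
architecture_registry <- function() {
  data.frame(architecture_id = names(ARCHITECTURES),
             feature_dim = vapply(ARCHITECTURES, function(a) a$feature_dim,
                                  integer(1)),
             row.names = NULL)
}

ARCHITECTURES <- list(
  # stem avgpool 5 -> 30x30, three conv blocks, 64-d penultimate dense
  tiny = list(feature_dim = 64L, stem = 5L, channels = c(8L, 16L, 32L),
              pools = c(TRUE, TRUE, FALSE)),
  convnet_s = list(feature_dim = 96L, stem = 5L, channels = c(12L, 24L, 48L),
                   pools = c(TRUE, TRUE, FALSE)),
  convnet_m = list(feature_dim = 128L, stem = 3L,
                   channels = c(12L, 24L, 48L, 64L),
                   pools = c(TRUE, TRUE, TRUE, FALSE)),
  convnet_l = list(feature_dim = 192L, stem = 3L,
                   channels = c(16L, 32L, 64L, 96L),
                   pools = c(TRUE, TRUE, TRUE, FALSE))
)

nn_build <- function(arch_id, n_classes, input_px = 150L) {
  arch <- ARCHITECTURES[[arch_id]]
  if (is.null(arch)) {
    stop("unknown architecture_id '", arch_id, "'; see architecture_registry()")
  }
  layers <- list(list(type = "avgpool", k = arch$stem))
  side <- input_px %/% arch$stem
  cin <- 3L
  spatial_index <- NA_integer_
  for (i in seq_along(arch$channels)) {
    co <- arch$channels[i]
    layers <- c(layers, list(
      list(type = "conv", W = he_init(c(3, 3, cin, co), 9 * cin),
           b = numeric(co)),
      list(type = "relu")))
    spatial_index <- length(layers)
    if (arch$pools[i]) {
      layers <- c(layers, list(list(type = "maxpool", k = 2L)))
      side <- side %/% 2L
    }
    cin <- co
  }
  flat <- side * side * cin
  layers <- c(layers, list(
    list(type = "flatten"),
    list(type = "dense", W = he_init(c(flat, arch$feature_dim), flat),
         b = numeric(arch$feature_dim)),
    list(type = "relu")))
  feature_index <- length(layers)
  layers <- c(layers, list(
    list(type = "dense",
         W = he_init(c(arch$feature_dim, n_classes), arch$feature_dim),
         b = numeric(n_classes))))
  list(layers = layers, feature_index = feature_index,
       spatial_index = spatial_index, feature_dim = arch$feature_dim)
}

# Adam ------------------------------------------------------------------------

adam_new <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type %in% c("conv", "dense")) {
      list(mW = array(0, dim = dim(ly$W)), vW = array(0, dim = dim(ly$W)),
           mb = numeric(length(ly$b)), vb = numeric(length(ly$b)))
    } else NULL
  })
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / b1t) / (sqrt(s$vW / b2t) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / b1t) / (sqrt(s$vb / b2t) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
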