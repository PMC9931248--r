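#' Loss specification for classifier training
#'
#' Bundles the focusing parameter `gamma` of the focal loss, optional
#' per-class weights and the probability floor used before taking
#' logarithms. `gamma = 0` recovers the (optionally class-weighted)
#' cross-entropy, which is how the "base" sub-models are configured; the
#' "focal" sub-models use `gamma` of 1, 2, 3, ...
#'
#' @param gamma non-negative focusing parameter.
#' @param class_weights optional numeric vector of per-class weights in
#'   \[0, 1\] (see [compute_class_weights()]), or `NULL` for unweighted loss.
#' @param probability_floor small positive epsilon; predicted probabilities
#'   are clipped to `[probability_floor, 1]` before `log`.
#' @return an object of class `loss_spec`.
#' @export
loss_spec <- function(gamma = 0, class_weights = NULL, probability_floor = 1e-7) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0)
  if (!is.null(class_weights)) {
    stopifnot(is.numeric(class_weights), all(class_weights >= 0),
              all(class_weights <= 1))
  }
  if (!(probability_floor > 0 && probability_floor <= 1e-3)) {
    stop("probability_floor must lie in (0, 1e-3]")
  }
  structure(list(gamma = gamma, class_weights = class_weights,
                 probability_floor = probability_floor),
            class = "loss_spec")
}

#' Focal loss for a single prediction
#'
#' Computes \deqn{L(y, t) = -\sum_l w_l \, t_l (1 - y_l)^\gamma \log y_l}
#' where `t` is the one-hot label, `y` the softmax output and `w_l` the
#' optional class weight (1 when no weights are supplied). With
#' \eqn{\gamma = 0} this is exactly the cross-entropy; larger \eqn{\gamma}
#' down-weights well-classified (easy) examples so training concentrates on
#' hard or rare ones.
#'
#' @param y numeric probability vector (sums to 1 within 1e-6).
#' @param t one-hot numeric vector of the same length.
#' @param spec a [loss_spec()].
#' @return non-negative scalar loss.
#' @examples
#' focal_loss(c(0.9, 0.1), c(1, 0), loss_spec(gamma = 2))
#' @export
focal_loss <- function(y, t, spec = loss_spec()) {
  stopifnot(inherits(spec, "loss_spec"))
  if (length(y) != length(t)) {
    stop("probability vector and one-hot label have different lengths")
  }
  if (abs(sum(y) - 1) > 1e-6) stop("y must sum to 1 (within 1e-6)")
  if (!all(t %in% c(0, 1)) || sum(t) != 1) {
    stop("t must be a one-hot vector")
  }
  w <- spec$class_weights
  if (is.null(w)) w <- rep(1, length(y))
  if (length(w) != length(y)) stop("class_weights length does not match y")
  yc <- pmin(pmax(y, spec$probability_floor), 1)
  -sum(w * t * (1 - yc)^spec$gamma * log(yc))
}

#' Logarithmic-ratio class weights for imbalanced labels
#'
#' For class counts \eqn{N_l} with total \eqn{N = \sum_l N_l}, the weight of
#' class `l` is \eqn{\alpha_l = \ln N_l / \ln N}. Compared with inverse
#' frequency weighting this shrinks the influence of rare classes only
#' sub-linearly: the majority class keeps a weight near 1 while a class
#' observed once receives weight 0.
#'
#' @param counts vector of positive integer class counts (all at least 1;
#'   total at least 2).
#' @return an object of class `class_weights` with elements `counts`,
#'   `total` and `weights`.
#' @examples
#' compute_class_weights(c(1177, 816, 457, 57))
#' @export
compute_class_weights <- function(counts) {
  if (any(counts != round(counts)) || any(counts < 1)) {
    stop("all class counts must be positive integers (ln of 0 is undefined)")
  }
  total <- sum(counts)
  if (total < 2) stop("total count must be at least 2 (ln N would be 0)")
  w <- log(counts) / log(total)
  structure(list(counts = as.integer(counts), total = as.integer(total),
                 weights = as.numeric(w)),
            class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat("class weights alpha_l = ln N_l / ln N  (N =", x$total, ")\n")
  print(round(stats::setNames(x$weights, paste0("class", seq_along(x$weights) - 1L)), 4))
  invisible(x)
}

# mean focal loss over a batch: probs is N x L, labels are 0-based ints.
# Returns list(loss, dlogits) where dlogits is the gradient with respect to
# the pre-softmax scores (N x L), already divided by N.
batch_focal_loss <- function(probs, labels, spec) {
  n <- nrow(probs); L <- ncol(probs)
  w <- spec$class_weights
  if (is.null(w)) w <- rep(1, L)
  eps <- spec$probability_floor
  gamma <- spec$gamma
  idx <- cbind(seq_len(n), labels + 1L)
  yt <- pmin(pmax(probs[idx], eps), 1)
  wl <- w[labels + 1L]
  loss <- mean(wl * (1 - yt)^gamma * (-log(yt)))

  # dL/dy_true per sample, then softmax jacobian
  one_my <- 1 - yt
  dLdy <- -wl * (one_my^gamma / yt - gamma * ifelse(one_my > 0, one_my^(gamma - 1), 0) * log(yt))
  dY <- matrix(0, n, L)
  dY[idx] <- dLdy / n
  # dz_k = y_k * (dY_k - sum_j dY_j y_j)
  s <- rowSums(dY * probs)
  dZ <- probs * (dY - s)
  list(loss = loss, dlogits = dZ)
}
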