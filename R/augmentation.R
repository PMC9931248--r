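#' Configuration of the training-time augmentation pool
#'
#' Twelve-image operator pool applied during training: starting from the
#' raw patch, each enabled operator is applied independently with
#' probability `apply_prob`, in the fixed order vertical flip, horizontal
#' flip, crop-and-pad, scaling, translation, rotation, shearing, blurring,
#' additive noise, frequency (low-frequency) noise, and color (hue /
#' saturation) modification. Geometric operators use bilinear interpolation
#' with reflected borders so no black corners appear; every operator
#' preserves the 150 x 150 shape and the labels.
#'
#' An operator is disabled by passing `NULL`. Ranges are uniform sampling
#' intervals.
#'
#' @param apply_prob per-operator application probability (default 0.5).
#' @param flip_v,flip_h logical: enable flips.
#' @param crop_pad margin range in pixels cropped from each side before
#'   reflect-padding back.
#' @param scale isotropic scale factor range.
#' @param translate shift range in pixels (both axes drawn independently).
#' @param rotate rotation angle range in degrees.
#' @param shear shear angle range in degrees.
#' @param blur Gaussian blur sigma range in pixels.
#' @param noise additive Gaussian noise sigma range (image scale 0..1).
#' @param freq_noise amplitude range of smooth low-frequency noise.
#' @param color hue shift and saturation scale limits
#'   `c(max_hue_shift, max_sat_change)`.
#' @return an object of class `augmentation_config`.
#' @export
augmentation_config <- function(apply_prob = 0.5,
                                flip_v = TRUE, flip_h = TRUE,
                                crop_pad = c(2, 15),
                                scale = c(0.8, 1.2),
                                translate = c(-15, 15),
                                rotate = c(-30, 30),
                                shear = c(-10, 10),
                                blur = c(0.5, 1.5),
                                noise = c(0.002, 8 / 255),
                                freq_noise = c(0.01, 0.05),
                                color = c(0.03, 0.1)) {
  if (apply_prob < 0 || apply_prob > 1) stop("apply_prob must be in [0, 1]")
  rng_ok <- function(x) is.null(x) || (length(x) == 2L && x[2] >= x[1])
  stopifnot(rng_ok(crop_pad), rng_ok(scale), rng_ok(translate),
            rng_ok(rotate), rng_ok(shear), rng_ok(blur), rng_ok(noise),
            rng_ok(freq_noise))
  structure(list(apply_prob = apply_prob,
                 ops = list(flip_v = isTRUE(flip_v), flip_h = isTRUE(flip_h),
                            crop_pad = crop_pad, scale = scale,
                            translate = translate, rotate = rotate,
                            shear = shear, blur = blur, noise = noise,
                            freq_noise = freq_noise, color = color)),
            class = "augmentation_config")
}

aug_op_names <- function(config) {
  names(which(!vapply(config$ops, is.null, logical(1)) &
                !vapply(config$ops, isFALSE, logical(1))))
}

#' Draw which operators fire
#'
#' One Bernoulli(`apply_prob`) draw per enabled operator, in pool order.
#' Exposed so the firing frequency can be audited cheaply.
#'
#' @param config an [augmentation_config()].
#' @return named logical vector over the enabled operators.
#' @export
draw_operator_mask <- function(config) {
  ops <- aug_op_names(config)
  stats::setNames(runif(length(ops)) < config$apply_prob, ops)
}

# inverse-mapped affine warp with bilinear interpolation and reflected
# borders; A maps output (row, col) offsets from center to source offsets
warp_affine <- function(img, A, shift = c(0, 0)) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  gr <- matrix(seq_len(H), H, W) - ctr[1]
  gc <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2]
  sr <- A[1, 1] * gr + A[1, 2] * gc + ctr[1] + shift[1]
  sc <- A[2, 1] * gr + A[2, 2] * gc + ctr[2] + shift[2]
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  i00 <- cbind(reflect_index(r0, H), reflect_index(c0, W))
  i01 <- cbind(reflect_index(r0, H), reflect_index(c0 + 1, W))
  i10 <- cbind(reflect_index(r0 + 1, H), reflect_index(c0, W))
  i11 <- cbind(reflect_index(r0 + 1, H), reflect_index(c0 + 1, W))
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    p <- img[, , ch]
    v <- p[i00] * (1 - fr) * (1 - fc) + p[i01] * (1 - fr) * fc +
      p[i10] * fr * (1 - fc) + p[i11] * fr * fc
    out[, , ch] <- matrix(v, H, W)
  }
  out
}

gaussian_blur <- function(img, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- dim(img)[1]; W <- dim(img)[2]
  ridx <- reflect_index(seq(1 - rad, H + rad), H)
  cidx <- reflect_index(seq(1 - rad, W + rad), W)
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    p <- img[, , ch]
    pad <- p[ridx, ]
    v <- matrix(0, H, W)
    for (i in seq_along(k)) v <- v + k[i] * pad[i:(i + H - 1L), ]
    pad <- v[, cidx]
    v2 <- matrix(0, H, W)
    for (i in seq_along(k)) v2 <- v2 + k[i] * pad[, i:(i + W - 1L)]
    out[, , ch] <- v2
  }
  out
}

hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

apply_augment_op <- function(px, op, range) {
  H <- dim(px)[1]; W <- dim(px)[2]
  switch(op,
    flip_v = px[H:1, , , drop = FALSE],
    flip_h = px[, W:1, , drop = FALSE],
    crop_pad = {
      m <- round(runif(4, range[1], range[2]))  # top, bottom, left, right
      rows <- reflect_index(seq(1 + m[1], H - m[2]), H)
      cols <- reflect_index(seq(1 + m[3], W - m[4]), W)
      crop <- px[rows, cols, , drop = FALSE]
      ri <- reflect_index(round(seq(1, length(rows), length.out = H)), length(rows))
      ci <- reflect_index(round(seq(1, length(cols), length.out = W)), length(cols))
      crop[ri, ci, , drop = FALSE]
    },
    scale = {
      s <- runif(1, range[1], range[2])
      warp_affine(px, diag(2) / s)
    },
    translate = {
      sh <- runif(2, range[1], range[2])
      warp_affine(px, diag(2), shift = -sh)
    },
    rotate = {
      a <- runif(1, range[1], range[2]) * pi / 180
      warp_affine(px, matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2))
    },
    shear = {
      a <- tan(runif(1, range[1], range[2]) * pi / 180)
      warp_affine(px, matrix(c(1, 0, a, 1), 2, 2))
    },
    blur = gaussian_blur(px, runif(1, range[1], range[2])),
    noise = {
      sd <- runif(1, range[1], range[2])
      pmin(pmax(px + array(rnorm(length(px), 0, sd), dim = dim(px)), 0), 1)
    },
    freq_noise = {
      amp <- runif(1, range[1], range[2])
      g <- 8L
      grid <- matrix(runif(g * g, -amp, amp), g, g)
      ri <- seq(1, g, length.out = H)
      ci <- seq(1, g, length.out = W)
      r0 <- pmin(floor(ri), g - 1L); c0 <- pmin(floor(ci), g - 1L)
      fr <- ri - r0; fc <- ci - c0
      up <- grid[r0, c0] * outer(1 - fr, 1 - fc) +
        grid[r0, c0 + 1L] * outer(1 - fr, fc) +
        grid[r0 + 1L, c0] * outer(fr, 1 - fc) +
        grid[r0 + 1L, c0 + 1L] * outer(fr, fc)
      out <- px
      for (ch in 1:3) out[, , ch] <- pmin(pmax(px[, , ch] + up, 0), 1)
      out
    },
    color = {
      dh <- runif(1, -range[1], range[1])
      ds <- runif(1, -range[2], range[2])
      hsv <- grDevices::rgb2hsv(rbind(as.vector(px[, , 1]),
                                      as.vector(px[, , 2]),
                                      as.vector(px[, , 3])),
                                maxColorValue = 1)
      rgb <- hsv_to_rgb((hsv[1, ] + dh) %% 1,
                        pmin(pmax(hsv[2, ] * (1 + ds), 0), 1), hsv[3, ])
      array(c(rgb[, 1], rgb[, 2], rgb[, 3]), dim = dim(px))
    },
    stop("unknown augmentation operator: ", op))
}

#' Augment a patch
#'
#' Applies the configured operator pool to a patch: each enabled operator
#' fires independently with probability `config$apply_prob`, in the fixed
#' pool order. Labels and shape are preserved. Randomness comes from the
#' current R RNG state, so seeding with `set.seed()` makes the result
#' reproducible byte for byte.
#'
#' @param patch a `labeled_patch` (see [extract_patch()]) or a bare
#'   H x W x 3 array.
#' @param config an [augmentation_config()].
#' @return object of the same type as `patch`, with an `applied` attribute
#'   naming the operators that fired.
#' @export
augment <- function(patch, config = augmentation_config()) {
  stopifnot(inherits(config, "augmentation_config"))
  is_patch <- inherits(patch, "labeled_patch")
  px <- if (is_patch) patch$pixels else patch
  stopifnot(length(dim(px)) == 3L)
  fire <- draw_operator_mask(config)
  for (op in names(fire)) {
    if (fire[[op]]) px <- apply_augment_op(px, op, config$ops[[op]])
  }
  if (is_patch) {
    patch$pixels <- px
    attr(patch, "applied") <- names(which(fire))
    patch
  } else {
    attr(px, "applied") <- names(which(fire))
    px
  }
}
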