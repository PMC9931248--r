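# internal helpers shared across modules

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

# symmetric (edge-repeating) reflection of 1-based indices into 1..n
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j < n, j + 1L, period - j))
}

is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0L, 1L))
}

as_mask <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Read and write raster files
#'
#' Rasters are exchanged as PNG: the fundus as 8-bit RGB, masks as 8-bit
#' single-channel images. The artery/vein map uses pixel codes
#' \{0 = background, 1 = artery, 2 = vein\}; vessel and cup masks use
#' \{0, 255\}. In memory the package uses plain numeric/integer matrices and
#' H x W x 3 arrays in (row, col) order with the origin at the top left.
#'
#' @param path file path.
#' @param image numeric array (values in \[0, 1\]) for `write_fundus_png`;
#'   integer matrix of codes for `write_mask_png`.
#' @param codes for `read_mask_png`: maximum code value expected (2 for an
#'   artery/vein map, 1 for binary masks stored as \{0, 255\}).
#' @return matrices/arrays as described; write functions return the path,
#'   invisibly.
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
write_fundus_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_fundus_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' @rdname raster_io
#' @export
write_mask_png <- function(image, path, codes = max(1L, max(image))) {
  # binary masks are stored as {0, 255}; code maps (e.g. artery/vein) keep
  # the code as the raw byte value
  out <- if (codes == 1L) image * 1.0 else image / 255
  png::writePNG(out, target = path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_mask_png <- function(path, codes = 1L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  m <- as_mask(round(img * if (codes == 1L) 1 else 255))
  if (codes == 1L) m[m > 0L] <- 1L
  m
}
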