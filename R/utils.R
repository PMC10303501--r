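# Internal helpers: seeded evaluation, image i/o, array conventions.

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific child seed from a base seed; kept < 2^31.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * as.numeric(k)) %% 2147483647)
}

# Row-major flattening of an (H, W, C) array: index = ((h*W)+w)*C + c.
flattenRowMajor <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) return(as.numeric(x))
  as.numeric(aperm(x, c(3L, 2L, 1L)))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Bilinear resize of an (H,W,C) array (or matrix) to out dims.
resizeBilinear <- function(x, outH, outW) {
  wasMat <- is.matrix(x)
  if (wasMat) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  y <- bilinear_resize_cpp(as.numeric(x), d[1L], d[2L], d[3L], outH, outW)
  y <- array(y, c(outH, outW, d[3L]))
  if (wasMat) y[, , 1L] else y
}

#' Read an RGB image file
#'
#' Reads a PNG or TIFF image into an `H x W x 3` numeric array with values in
#' `[0, 1]`. Grayscale files are replicated to three channels; an alpha
#' channel, if present, is dropped. JPEG is not supported.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric array `H x W x 3` in `[0, 1]`.
#' @export
readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (PNG and TIFF are supported)"))
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3L] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3L] != 3L) stop("image must have 1, 3 or 4 channels")
  x
}

#' Write an RGB image as PNG
#'
#' @param pixels Numeric array `H x W x 3` in `[0, 1]`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeImageFile <- function(pixels, path) {
  png::writePNG(clamp01(pixels), path)
  invisible(path)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
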