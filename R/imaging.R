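# Image containers, grayscale conversion, quantization and patch sampling.
#
# Pixel conventions: images are stored as H x W (x 3) arrays indexed
# [row, column(, channel)]; user-facing coordinates are 0-based with
# x = column, y = row, y increasing downward; windows are half-open
# [x0, x0 + size) x [y0, y0 + size).

#' Construct an RGB image object
#'
#' @param pixels integer array of dimension `c(H, W, 3)` with values in
#'   0..255.  A plain `H x W` matrix is replicated across the three
#'   channels.
#' @param id image identifier string.
#' @return an object of class `rgb_image` with fields `pixels`, `height`,
#'   `width`, `id`.
#' @export
rgb_image <- function(pixels, id = "image") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L) {
    stop("rgb_image: channel values must be integers in 0..255", call. = FALSE)
  }
  structure(
    list(pixels = pixels, height = dim(pixels)[1], width = dim(pixels)[2],
         id = as.character(id)),
    class = "rgb_image"
  )
}

#' Construct a grayscale image object
#'
#' @param pixels numeric `H x W` matrix.
#' @param levels number of representable intensity levels.
#' @param normalized logical; `TRUE` means values lie in `[0, 1]`,
#'   `FALSE` means integer levels in `0..levels - 1`.
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(pixels, levels, normalized) {
  stopifnot(is.matrix(pixels), levels >= 2)
  if (normalized) {
    if (min(pixels) < 0 || max(pixels) > 1) {
      stop("gray_image: normalized values must lie in [0, 1]", call. = FALSE)
    }
  } else {
    if (any(pixels != floor(pixels)) || min(pixels) < 0 ||
        max(pixels) > levels - 1) {
      stop("gray_image: integer-leveled values must lie in 0..levels-1",
           call. = FALSE)
    }
  }
  structure(
    list(pixels = pixels, levels = as.integer(levels),
         normalized = isTRUE(normalized)),
    class = "gray_image"
  )
}

#' Read an 8-bit RGB image from a PNG or JPEG file
#'
#' Grayscale files are replicated to three channels; an alpha channel,
#' if present, is dropped.
#'
#' @param path file path to a `.png` or `.jpg`/`.jpeg` file.
#' @param id image id; defaults to the file name without extension.
#' @return an [rgb_image()].
#' @export
read_image <- function(path, id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("read_image: file not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = read_jpeg_array(path),
      stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
    ),
    error = function(e) {
      stop(sprintf("read_image: cannot decode '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3] >= 4L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3] == 1L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]
  px <- array(as.integer(round(arr * 255)), dim(arr))
  rgb_image(px, id = id %||% tools::file_path_sans_ext(basename(path)))
}

# JPEG decoding goes through EBImage when available (the 'png' package
# only handles PNG).  PNG is the package's native, lossless format.
read_jpeg_array <- function(path) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("JPEG support requires the 'EBImage' package; use PNG instead",
         call. = FALSE)
  }
  img <- EBImage::readImage(path)
  arr <- EBImage::imageData(img)
  # EBImage stores x,y(,c); transpose to row = y, column = x
  if (length(dim(arr)) == 2L) t(arr) else aperm(arr, c(2L, 1L, 3L))
}

#' Write an RGB image to a PNG file
#'
#' Lossless 8-bit output: reading the file back with [read_image()]
#' reproduces the pixel array exactly.
#'
#' @param img an [rgb_image()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

#' Convert an RGB image to a normalized grayscale image
#'
#' Computes a weighted channel sum then rescales by 255, so output
#' intensities live on `[0, 1]`.  Default weights are the ITU-R BT.601
#' luma coefficients.
#'
#' @param img an [rgb_image()].
#' @param weights three nonnegative channel weights summing to 1.
#' @return a normalized [gray_image()] with 256 representable levels.
#' @export
to_gray <- function(img, weights = c(0.299, 0.587, 0.114)) {
  stopifnot(inherits(img, "rgb_image"))
  if (length(weights) != 3L || any(weights < 0)) {
    stop("to_gray: weights must be 3 nonnegative numbers", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("to_gray: weights must sum to 1", call. = FALSE)
  }
  g <- (weights[1] * img$pixels[, , 1] + weights[2] * img$pixels[, , 2] +
        weights[3] * img$pixels[, , 3]) / 255
  g <- pmin(pmax(g, 0), 1)
  dim(g) <- c(img$height, img$width) # 1-pixel-wide slices drop dims
  gray_image(g, levels = 256L, normalized = TRUE)
}

#' Quantize a normalized grayscale image to L discrete levels
#'
#' A value `v` in `[0, 1]` maps to `min(floor(v * L), L - 1)`, so the
#' map is monotone and 1.0 lands on the top level.
#'
#' @param img a normalized [gray_image()].
#' @param L number of levels, at least 2.
#' @return an integer-leveled [gray_image()] with `levels = L`.
#' @export
quantize <- function(img, L = 8L) {
  stopifnot(inherits(img, "gray_image"))
  if (!isTRUE(img$normalized)) {
    stop("quantize: input must be a normalized gray image", call. = FALSE)
  }
  if (L < 2) stop("quantize: L must be at least 2", call. = FALSE)
  q <- pmin(floor(img$pixels * L), L - 1)
  gray_image(q, levels = L, normalized = FALSE)
}

#' Sample square patches ("keypoints") from an image
#'
#' Top-left corners are drawn uniformly at random over the admissible
#' region (all positions where the window fits inside the image, or
#' inside `roi` when given).  Corners are distinct whenever the region
#' admits at least `n` positions; otherwise sampling falls back to
#' replacement so the requested count is always honoured.  Sampling
#' depends only on the region's extent, not on where the region sits in
#' the image, so patch statistics are translation-consistent.
#'
#' @param img an [rgb_image()].
#' @param n number of patches.
#' @param size patch side length in pixels (default 6).
#' @param seed integer seed; a fixed seed gives identical coordinates.
#' @param roi optional `c(x0, y0, x1, y1)` half-open rectangle
#'   (0-based, `x1`/`y1` exclusive) restricting the sampled region.
#' @param weights grayscale conversion weights for the patch gray view.
#' @return a list of `patch` objects, each with fields `image_id`, `x0`,
#'   `y0`, `size`, `rgb` (an [rgb_image()] view) and `gray` (a
#'   normalized [gray_image()] view).
#' @export
extract_patches <- function(img, n, size = 6L, seed = 1L, roi = NULL,
                            weights = c(0.299, 0.587, 0.114)) {
  stopifnot(inherits(img, "rgb_image"), n >= 1, size >= 2)
  roi <- roi %||% c(0L, 0L, img$width, img$height)
  stopifnot(length(roi) == 4L)
  if (roi[1] < 0 || roi[2] < 0 || roi[3] > img$width || roi[4] > img$height ||
      roi[3] <= roi[1] || roi[4] <= roi[2]) {
    stop(sprintf("extract_patches: invalid roi for image '%s'", img$id),
         call. = FALSE)
  }
  nx <- (roi[3] - roi[1]) - size + 1L # admissible corner counts
  ny <- (roi[4] - roi[2]) - size + 1L
  if (nx < 1L || ny < 1L) {
    stop(sprintf(
      "extract_patches: image '%s' region (%dx%d) cannot fit a %dx%d patch",
      img$id, roi[3] - roi[1], roi[4] - roi[2], size, size), call. = FALSE)
  }
  gray_full <- to_gray(img, weights)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  npos <- as.numeric(nx) * as.numeric(ny)
  idx <- if (npos >= n) sample.int(npos, n) else
    sample.int(npos, n, replace = TRUE)
  x0 <- roi[1] + (idx - 1L) %% nx
  y0 <- roi[2] + (idx - 1L) %/% nx
  lapply(seq_len(n), function(k) {
    rows <- (y0[k] + 1L):(y0[k] + size)
    cols <- (x0[k] + 1L):(x0[k] + size)
    structure(
      list(
        image_id = img$id, x0 = as.integer(x0[k]), y0 = as.integer(y0[k]),
        size = as.integer(size),
        rgb = rgb_image(img$pixels[rows, cols, , drop = FALSE], id = img$id),
        gray = gray_image(gray_full$pixels[rows, cols, drop = FALSE],
                          levels = 256L, normalized = TRUE)
      ),
      class = "patch"
    )
  })
}

# Save/restore the global RNG state so seeded helpers do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image '%s' %dx%d>\n", x$id, x$height, x$width))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, L=%d, %s>\n", nrow(x$pixels),
              ncol(x$pixels), x$levels,
              if (x$normalized) "normalized" else "integer-leveled"))
  invisible(x)
}

#' @export
print.patch <- function(x, ...) {
  cat(sprintf("<patch %dx%d of '%s' at (x0=%d, y0=%d)>\n", x$size, x$size,
              x$image_id, x$x0, x$y0))
  invisible(x)
}
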