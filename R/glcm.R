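# Gray-level co-occurrence matrices and the four Haralick texture
# features used by the pipeline: energy, entropy, correlation and
# contrast.  Offsets follow the standard pixel-grid convention with
# y increasing downward:
#   0 deg -> (+d,  0),   45 deg -> (+d, -d),
#   90 deg -> ( 0, -d), 135 deg -> (-d, -d)   in (dx, dy).

GLCM_ANGLES <- c(0, 45, 90, 135)

glcm_offset <- function(d, theta) {
  stopifnot(d >= 1)
  switch(as.character(theta),
    "0"   = c(dx = d, dy = 0),
    "45"  = c(dx = d, dy = -d),
    "90"  = c(dx = 0, dy = -d),
    "135" = c(dx = -d, dy = -d),
    stop("glcm: theta must be one of 0, 45, 90, 135 degrees", call. = FALSE)
  )
}

new_glcm <- function(counts, d, theta, L, symmetric) {
  n_pairs <- sum(counts)
  probs <- if (n_pairs > 0) counts / n_pairs else counts
  lev <- 0:(L - 1)
  px <- rowSums(probs)
  py <- colSums(probs)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  structure(
    list(counts = counts, probs = probs, d = d, theta = theta,
         L = as.integer(L), symmetric = isTRUE(symmetric),
         n_pairs = n_pairs,
         mu_x = mu_x, mu_y = mu_y,
         sigma_x = sqrt(sum((lev - mu_x)^2 * px)),
         sigma_y = sqrt(sum((lev - mu_y)^2 * py))),
    class = "glcm"
  )
}

#' Compute a gray-level co-occurrence matrix
#'
#' Tallies ordered pixel pairs `(i, j)` separated by the displacement
#' of distance `d` at angle `theta`, then normalizes by the total pair
#' count.  With `symmetric = TRUE` (the Haralick convention, and the
#' default) each pair is also counted in the reverse direction, making
#' the matrix equal to its transpose and the two marginals identical.
#'
#' @param patch an integer-leveled [gray_image()] (see [quantize()]).
#' @param d offset distance in pixels, at least 1.
#' @param theta angle in degrees, one of 0, 45, 90, 135.
#' @param symmetric logical; count each pair in both directions.
#' @return an object of class `glcm` with fields `counts`, `probs`
#'   (both `L x L`), `d`, `theta`, `L`, `symmetric`, `n_pairs` and the
#'   marginal moments `mu_x`, `mu_y`, `sigma_x`, `sigma_y`.
#' @export
compute_glcm <- function(patch, d, theta, symmetric = TRUE) {
  stopifnot(inherits(patch, "gray_image"))
  if (patch$normalized) {
    stop("compute_glcm: patch must be integer-leveled (quantize it first)",
         call. = FALSE)
  }
  off <- glcm_offset(d, theta)
  P <- patch$pixels
  L <- patch$levels
  H <- nrow(P); W <- ncol(P)
  dx <- off[["dx"]]; dy <- off[["dy"]]
  if ((H - abs(dy)) < 1L || (W - abs(dx)) < 1L) {
    stop(sprintf(
      "compute_glcm: empty GLCM: offset (d=%g, theta=%g) exceeds %dx%d patch",
      d, theta, H, W), call. = FALSE)
  }
  rows <- max(1L, 1L - dy):min(H, H - dy)
  cols <- max(1L, 1L - dx):min(W, W - dx)
  i <- P[rows, cols, drop = FALSE]
  j <- P[rows + dy, cols + dx, drop = FALSE]
  idx <- as.vector(i) + as.vector(j) * L + 1L
  counts <- matrix(tabulate(idx, nbins = L * L), nrow = L, ncol = L)
  if (symmetric) counts <- counts + t(counts)
  if (sum(counts) == 0) {
    stop(sprintf(
      "compute_glcm: empty GLCM: offset (d=%g, theta=%g) exceeds %dx%d patch",
      d, theta, H, W), call. = FALSE)
  }
  new_glcm(counts, d = d, theta = theta, L = L, symmetric = symmetric)
}

#' Build a GLCM object from a raw count matrix
#'
#' Mostly useful for constructing analytic cases (uniform matrices,
#' single-cell matrices) and for debugging; [compute_glcm()] is the
#' route taken by the pipeline.
#'
#' @param counts square nonnegative count matrix.
#' @param d,theta offset metadata attached to the object.
#' @param symmetric logical flag recorded on the object.
#' @return a `glcm` object.
#' @export
glcm_from_counts <- function(counts, d = 1L, theta = 0, symmetric = TRUE) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            all(counts >= 0), sum(counts) > 0)
  new_glcm(counts, d = d, theta = theta, L = nrow(counts),
           symmetric = symmetric)
}

#' Haralick features of a single GLCM
#'
#' Energy is the sum of squared cell probabilities; entropy is Shannon
#' entropy in bits with the `0 * log 0 = 0` convention; contrast is the
#' `(i - j)^2`-weighted difference moment; correlation is the Pearson
#' correlation of the row and column level indices under the joint
#' distribution.  A degenerate matrix (all mass in one row/column, so
#' `sigma_x * sigma_y = 0`) has correlation defined as 1 by policy: a
#' constant patch predicts its neighbour perfectly.
#'
#' @param g a `glcm` object with at least one counted pair.
#' @return a named list of class `haralick_features` with entries
#'   `energy`, `entropy`, `correlation`, `contrast`.
#' @export
haralick_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  if (g$n_pairs <= 0) {
    stop("haralick_features: GLCM has no counted pairs", call. = FALSE)
  }
  p <- g$probs
  lev <- 0:(g$L - 1)
  energy <- sum(p^2)
  nz <- p[p > 0]
  entropy <- -sum(nz * log2(nz))
  ii <- matrix(lev, g$L, g$L)
  jj <- t(ii)
  contrast <- sum((ii - jj)^2 * p)
  denom <- g$sigma_x * g$sigma_y
  correlation <- if (denom > 0) {
    sum(p * (ii - g$mu_x) * (jj - g$mu_y)) / denom
  } else 1 # degenerate policy: perfectly predictable neighbour
  structure(
    list(energy = energy, entropy = entropy, correlation = correlation,
         contrast = contrast),
    class = "haralick_features"
  )
}

#' Aggregate Haralick features over distances and angles
#'
#' Computes one GLCM per `(d, theta)` combination and returns the
#' per-feature arithmetic mean over all combinations that admit at
#' least one pixel pair; combinations whose offset exceeds the patch
#' extent are skipped and listed in the `skipped` attribute.
#'
#' @param patch an integer-leveled [gray_image()].
#' @param distances offset distances (default `1:5`).
#' @param angles angles in degrees (default `c(0, 45, 90, 135)`).
#' @param symmetric logical, passed to [compute_glcm()].
#' @param per_combo logical; if `TRUE` also attach the per-combination
#'   feature table as attribute `per_combo`.
#' @return a `haralick_features` list (the mean over valid combos).
#' @export
aggregate_texture <- function(patch, distances = 1:5,
                              angles = GLCM_ANGLES, symmetric = TRUE,
                              per_combo = FALSE) {
  combos <- expand.grid(d = distances, theta = angles)
  vals <- list()
  skipped <- character()
  for (k in seq_len(nrow(combos))) {
    g <- tryCatch(
      compute_glcm(patch, combos$d[k], combos$theta[k], symmetric = symmetric),
      error = function(e) NULL
    )
    if (is.null(g)) {
      skipped <- c(skipped, sprintf("d=%g,theta=%g", combos$d[k],
                                    combos$theta[k]))
    } else {
      vals[[length(vals) + 1L]] <- unlist(haralick_features(g))
    }
  }
  if (length(vals) == 0L) {
    stop("aggregate_texture: every (d, theta) combination yields an empty GLCM",
         call. = FALSE)
  }
  m <- colMeans(do.call(rbind, vals))
  out <- structure(as.list(m), class = "haralick_features")
  attr(out, "skipped") <- skipped
  if (per_combo) {
    keep <- !(sprintf("d=%g,theta=%g", combos$d, combos$theta) %in% skipped)
    attr(out, "per_combo") <- cbind(combos[keep, , drop = FALSE],
                                    as.data.frame(do.call(rbind, vals)))
  }
  out
}

#' Write a GLCM's probability matrix to CSV (debug dump)
#'
#' @param g a `glcm` object.
#' @param path output CSV path (`L` rows by `L` columns).
#' @return `path`, invisibly.
#' @export
write_glcm_csv <- function(g, path) {
  stopifnot(inherits(g, "glcm"))
  utils::write.table(g$probs, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm L=%d d=%g theta=%g %s, %d pairs>\n", x$L, x$d, x$theta,
              if (x$symmetric) "symmetric" else "directed", x$n_pairs))
  invisible(x)
}
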