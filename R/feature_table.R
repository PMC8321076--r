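# Per-patch feature vectors and the on-disk feature table.
#
# Each patch yields 28 features in a fixed order: 10 grayscale entries
# (first-order moments, min/max and the four aggregated Haralick
# features) followed by 6 first-order entries for each of the R, G and
# B channels.

FIRST_ORDER_NAMES <- c("mean", "variance", "skewness", "kurtosis",
                       "min", "max")
HARALICK_NAMES <- c("energy", "entropy", "correlation", "contrast")

#' Canonical feature names, in dataset column order
#' @return character vector of length 28.
#' @export
feature_names <- function() {
  c(paste0("gray_", c(FIRST_ORDER_NAMES, HARALICK_NAMES)),
    paste0("r_", FIRST_ORDER_NAMES),
    paste0("g_", FIRST_ORDER_NAMES),
    paste0("b_", FIRST_ORDER_NAMES))
}

#' Build the feature vector of a single patch
#'
#' First-order statistics are computed on the unquantized normalized
#' grayscale values and on each RGB channel rescaled to `[0, 1]`; the
#' Haralick block is computed on the grayscale patch quantized to `L`
#' levels and aggregated over the given distances and angles.
#'
#' @param p a `patch` from [extract_patches()].
#' @param L quantization level count for the GLCM block (default 8).
#' @param distances,angles,symmetric passed to [aggregate_texture()].
#' @return named numeric vector of length 28 (see [feature_names()])
#'   with attributes `image_id`, `x0`, `y0`.
#' @export
build_feature_vector <- function(p, L = 8L, distances = 1:5,
                                 angles = GLCM_ANGLES, symmetric = TRUE) {
  stopifnot(inherits(p, "patch"))
  fo <- first_order_features(p$gray)
  tex <- aggregate_texture(quantize(p$gray, L), distances = distances,
                           angles = angles, symmetric = symmetric)
  chan <- lapply(1:3, function(k) {
    first_order_features(p$rgb$pixels[, , k] / 255)
  })
  v <- c(unlist(fo[FIRST_ORDER_NAMES]), unlist(tex[HARALICK_NAMES]),
         unlist(chan[[1]][FIRST_ORDER_NAMES]),
         unlist(chan[[2]][FIRST_ORDER_NAMES]),
         unlist(chan[[3]][FIRST_ORDER_NAMES]))
  v <- unname(v)
  names(v) <- feature_names()
  if (any(!is.finite(v))) {
    stop(sprintf("build_feature_vector: non-finite feature for patch of '%s'",
                 p$image_id), call. = FALSE)
  }
  attr(v, "image_id") <- p$image_id
  attr(v, "x0") <- p$x0
  attr(v, "y0") <- p$y0
  v
}

new_feature_dataset <- function(df) {
  stopifnot(all(c("image_id", "label", "x0", "y0") %in% names(df)),
            all(feature_names() %in% names(df)))
  df$label <- factor(as.character(df$label), levels = CLASS_LEVELS)
  if (anyNA(df$label)) {
    stop("feature dataset: labels must be 'melanoma' or 'nevus'",
         call. = FALSE)
  }
  df <- df[, c("image_id", "label", "x0", "y0", feature_names())]
  class(df) <- c("feature_dataset", "data.frame")
  df
}

#' Read an image manifest CSV
#'
#' Expected columns: `path`, `label` (melanoma|nevus) and optionally
#' `roi_x0`, `roi_y0`, `roi_x1`, `roi_y1` (half-open rectangle).
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return data.frame with columns `path`, `label` (+ roi columns).
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m))) {
    stop("read_manifest: manifest needs 'path' and 'label' columns",
         call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Extract the full patch-level feature dataset from a manifest
#'
#' Loads every image, samples `n_per_image` patches from each, and
#' assembles one feature vector per patch.  Patch labels inherit the
#' image label.  Each image gets a sub-seed derived from the master
#' seed and its id, so results do not depend on manifest row order.
#'
#' @param manifest data.frame as returned by [read_manifest()], or a
#'   path to a manifest CSV.
#' @param n_per_image patches sampled per image (default 10).
#' @param patch_size patch side length in pixels (default 6).
#' @param seed master integer seed.
#' @param L,distances,angles,symmetric GLCM settings, see
#'   [build_feature_vector()].
#' @param weights grayscale conversion weights.
#' @return a `feature_dataset`: a data.frame with columns `image_id`,
#'   `label`, `x0`, `y0` and the 28 feature columns.
#' @export
extract_dataset <- function(manifest, n_per_image = 10L, patch_size = 6L,
                            seed = 1L, L = 8L, distances = 1:5,
                            angles = GLCM_ANGLES, symmetric = TRUE,
                            weights = c(0.299, 0.587, 0.114)) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(nrow(manifest) >= 1)
  has_roi <- all(c("roi_x0", "roi_y0", "roi_x1", "roi_y1") %in%
                   names(manifest))
  rows <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    img <- read_image(manifest$path[r])
    roi <- NULL
    if (has_roi && !anyNA(unlist(manifest[r, c("roi_x0", "roi_y0",
                                               "roi_x1", "roi_y1")]))) {
      roi <- as.numeric(manifest[r, c("roi_x0", "roi_y0",
                                      "roi_x1", "roi_y1")])
    }
    patches <- extract_patches(img, n = n_per_image, size = patch_size,
                               seed = derive_seed(seed, img$id), roi = roi,
                               weights = weights)
    feats <- lapply(patches, build_feature_vector, L = L,
                    distances = distances, angles = angles,
                    symmetric = symmetric)
    rows[[r]] <- data.frame(
      image_id = img$id,
      label = manifest$label[r],
      x0 = vapply(patches, `[[`, integer(1), "x0"),
      y0 = vapply(patches, `[[`, integer(1), "y0"),
      do.call(rbind, feats),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  new_feature_dataset(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Per-class patch counts of a feature dataset
#' @param ds a `feature_dataset`.
#' @return named integer vector (melanoma, nevus).
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "feature_dataset"))
  table(ds$label)
}

#' Write a feature dataset to CSV / read it back
#'
#' Values are written at full double precision (17 significant digits)
#' so that a write-read round trip is lossless.
#'
#' @param ds a `feature_dataset`.
#' @param path CSV path.
#' @return `write_feature_csv`: `path` invisibly;
#'   `read_feature_csv`: the `feature_dataset`.
#' @export
write_feature_csv <- function(ds, path) {
  stopifnot(inherits(ds, "feature_dataset"))
  out <- as.data.frame(ds)
  out$label <- as.character(out$label)
  for (nm in feature_names()) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character"))
  expected <- c("image_id", "label", "x0", "y0", feature_names())
  missing <- setdiff(expected, names(df))
  extra <- setdiff(names(df), expected)
  if (length(missing) || length(extra)) {
    stop(sprintf(
      "read_feature_csv: header mismatch (missing: %s; extra: %s)",
      paste(missing, collapse = ", ") %|e|% "none",
      paste(extra, collapse = ", ") %|e|% "none"), call. = FALSE)
  }
  if (nrow(df) == 0) {
    df <- df[, expected]
    class(df) <- c("feature_dataset", "data.frame")
    df$label <- factor(character(), levels = CLASS_LEVELS)
    return(df)
  }
  new_feature_dataset(df)
}

`%|e|%` <- function(a, b) if (nzchar(a)) a else b

#' @export
print.feature_dataset <- function(x, ...) {
  cc <- table(x$label)
  cat(sprintf("<feature_dataset: %d patches from %d images (%s)>\n",
              nrow(x), length(unique(x$image_id)),
              paste(sprintf("%s=%d", names(cc), cc), collapse = ", ")))
  invisible(x)
}
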