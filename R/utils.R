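#' @keywords internal
"_PACKAGE"

# Class labels used throughout; melanoma is the positive class.
CLASS_LEVELS <- c("melanoma", "nevus")
POSITIVE_CLASS <- "melanoma"

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Deterministic polynomial hash of `key` folded into `seed`, reduced
#' modulo 2^31 - 1 so the result is always a valid R integer seed.
#' Keyed derivation makes per-image seeds independent of processing
#' order: the same image id always yields the same sub-seed.
#'
#' @param seed master seed (single integer).
#' @param key character scalar (e.g. an image id) or integer.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  codes <- utf8ToInt(paste0(as.character(key), collapse = "|"))
  for (ch in codes) h <- (h * 131 + ch) %% m
  as.integer(h)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
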