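#' @keywords internal
"_PACKAGE"

# ---- internal image helpers ---------------------------------------------
# Grayscale images are numeric H x W matrices on the 0-255 scale;
# RGB images are H x W x 3 arrays on the same scale.

is_gray_image <- function(x) is.matrix(x) && is.numeric(x)

is_rgb_image <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

clip255 <- function(x) pmin(pmax(x, 0), 255)

stop_domain <- function(...) stop(..., call. = FALSE)

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from one pipeline seed, kept < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}

#' Read an image from a PNG file
#'
#' Returns a grayscale matrix or an RGB array on the 0-255 scale.
#'
#' @param path Path to a PNG file.
#' @return A numeric `H x W` matrix (grayscale PNG) or `H x W x 3` array (RGB);
#'   an alpha channel, if present, is dropped.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop_domain("image file not found: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE]
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1L]
  x * 255
}

#' Write an image to a PNG file
#'
#' @param image Grayscale matrix or RGB array, values on the 0-255 scale.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  if (!is_gray_image(image) && !is_rgb_image(image)) {
    stop_domain("image must be a grayscale matrix or an H x W x 3 array")
  }
  png::writePNG(clip255(image) / 255, target = path)
  invisible(path)
}
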