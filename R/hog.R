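# Histogram of Oriented Gradients, Dalal-Triggs convention: Sobel
# gradients, unsigned orientations in [0, 180) split into 9 bins of 20
# degrees with linear voting, 8x8-pixel cells, 2x2-cell blocks at one-cell
# stride, L2 block normalization. On the 64x128 working size this yields
# 7x15 = 105 blocks of 36 values = 3780 features.

# image(i + dy, j + dx) with reflecting borders
shift2 <- function(x, dy, dx) {
  ri <- pmin(pmax(seq_len(nrow(x)) + dy, 1L), nrow(x))
  ci <- pmin(pmax(seq_len(ncol(x)) + dx, 1L), ncol(x))
  x[ri, ci, drop = FALSE]
}

#' Sobel gradient field of a grayscale image
#'
#' Horizontal and vertical derivatives from the 3x3 Sobel kernels with
#' reflected borders, with per-pixel magnitude and unsigned orientation.
#'
#' @param image Grayscale matrix, at least 3x3.
#' @return An object of class `"gradient_field"`: list with `Mx`, `My`
#'   (signed derivatives along columns and rows), `f_M` (magnitude
#'   `sqrt(Mx^2 + My^2)`) and `theta_M` (orientation in degrees, folded to
#'   `[0, 180)`).
#' @export
sobel_gradients <- function(image) {
  if (!is_gray_image(image) || nrow(image) < 3 || ncol(image) < 3) {
    stop_domain("image must be a grayscale matrix of at least 3x3")
  }
  # x = column direction, y = row direction
  Mx <- (shift2(image, -1, 1) + 2 * shift2(image, 0, 1) + shift2(image, 1, 1)) -
        (shift2(image, -1, -1) + 2 * shift2(image, 0, -1) + shift2(image, 1, -1))
  My <- (shift2(image, 1, -1) + 2 * shift2(image, 1, 0) + shift2(image, 1, 1)) -
        (shift2(image, -1, -1) + 2 * shift2(image, -1, 0) + shift2(image, -1, 1))
  f_M <- sqrt(Mx^2 + My^2)
  theta <- atan2(My, Mx) * 180 / pi
  theta_M <- theta %% 180
  structure(list(Mx = Mx, My = My, f_M = f_M, theta_M = theta_M),
            class = "gradient_field")
}

#' Magnitude-weighted orientation histograms per cell
#'
#' Each pixel votes its gradient magnitude into the 9 unsigned-orientation
#' bins (20 degrees wide, centers at 0, 20, ..., 160, wrapping at 180), with
#' linear interpolation between the two nearest bin centers, accumulated
#' over non-overlapping `cell x cell` pixel cells.
#'
#' @param grad A `"gradient_field"` from [sobel_gradients()].
#' @param cell Cell side in pixels; image dimensions must be divisible by it.
#' @param bins Number of orientation bins.
#' @return Array of dimension `(rows/cell, cols/cell, bins)`.
#' @export
cell_histograms <- function(grad, cell = 8, bins = 9) {
  stopifnot(inherits(grad, "gradient_field"))
  H <- nrow(grad$f_M); W <- ncol(grad$f_M)
  if (H %% cell != 0 || W %% cell != 0) {
    stop_domain("image dimensions must be divisible by the cell size")
  }
  ncr <- H %/% cell; ncc <- W %/% cell
  binw <- 180 / bins
  t <- as.numeric(grad$theta_M) / binw
  b0 <- floor(t)                       # lower bin, 0-based
  w_hi <- t - b0
  b1 <- (b0 + 1) %% bins
  f <- as.numeric(grad$f_M)

  pix_r <- rep(seq_len(H), times = W)
  pix_c <- rep(seq_len(W), each = H)
  cell_id <- ((pix_r - 1) %/% cell) + ncr * ((pix_c - 1) %/% cell)  # 0-based

  acc <- numeric(ncr * ncc * bins)
  add_votes <- function(acc, cell_id, bin0, v) {
    lin <- cell_id + (ncr * ncc) * bin0 + 1
    s <- rowsum(v, lin)
    at <- as.integer(rownames(s))
    acc[at] <- acc[at] + s[, 1]
    acc
  }
  acc <- add_votes(acc, cell_id, b0, f * (1 - w_hi))
  acc <- add_votes(acc, cell_id, b1, f * w_hi)
  array(acc, dim = c(ncr, ncc, bins))
}

#' L2-normalized block vectors from a cell-histogram grid
#'
#' Slides a 2x2-cell block at one-cell stride over the grid (row-major block
#' order); each block concatenates its four 9-vectors into a 36-vector and
#' normalizes it as `v / sqrt(||v||^2 + k^2)` with stabilizer `k = 1e-5`.
#'
#' @param cells Cell-histogram array from [cell_histograms()].
#' @param k Normalization stabilizer.
#' @return Matrix with one 36-dimensional column per block,
#'   `(rows-1) x (cols-1)` blocks in total.
#' @export
block_normalize <- function(cells, k = 1e-5) {
  d <- dim(cells)
  if (d[1] < 2 || d[2] < 2) stop_domain("need at least a 2x2 cell grid")
  nbr <- d[1] - 1L; nbc <- d[2] - 1L
  bins <- d[3]
  out <- matrix(0, 4L * bins, nbr * nbc)
  blk <- 0L
  for (br in seq_len(nbr)) {        # row-major over blocks
    for (bc in seq_len(nbc)) {
      blk <- blk + 1L
      v <- c(cells[br, bc, ], cells[br, bc + 1L, ],
             cells[br + 1L, bc, ], cells[br + 1L, bc + 1L, ])
      out[, blk] <- v / sqrt(sum(v^2) + k^2)
    }
  }
  out
}

#' HOG descriptor of an image
#'
#' Computes the full descriptor on the 64x128 (width x height) working
#' size — the input is bilinearly resized to it if needed — by
#' concatenating all normalized block vectors: 105 blocks x 36 values =
#' 3780 features.
#'
#' @param image Grayscale matrix (any size; resized internally).
#' @param cell Cell side in pixels.
#' @param bins Orientation bins per cell.
#' @return Numeric vector of class `"hog_descriptor"` (length 3780 for the
#'   default geometry) with a `geometry` attribute.
#' @export
hog_descriptor <- function(image, cell = 8, bins = 9) {
  if (!is_gray_image(image)) image <- to_grayscale(image)
  if (nrow(image) != 128 || ncol(image) != 64) {
    image <- resize_image(image, 128, 64)
  }
  cells <- cell_histograms(sobel_gradients(image), cell = cell, bins = bins)
  blocks <- block_normalize(cells)
  structure(as.numeric(blocks),
            geometry = list(image = c(h = 128L, w = 64L), cell = cell,
                            bins = bins, block = c(2L, 2L), stride_cells = 1L,
                            n_blocks = ncol(blocks),
                            block_vector = nrow(blocks)),
            class = "hog_descriptor")
}

#' @export
print.hog_descriptor <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("HOG descriptor: %d features (%d blocks x %d), %d-bin cells\n",
              length(x), g$n_blocks, g$block_vector, g$bins))
  invisible(x)
}
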