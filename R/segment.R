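# Grey-level clustering segmentation: deterministic k-means on the 256-bin
# intensity histogram (each occurring grey level is assigned to the nearest
# centroid, weighted by its pixel frequency), followed by lesion-mask
# extraction as the darkest cluster.

#' Cluster image intensities on the grey-level histogram
#'
#' Deterministic k-means over the 256 grey levels: each occurring level is
#' assigned to the nearest centroid by absolute distance (ties to the lower
#' cluster index), and each centroid is recomputed as the frequency-weighted
#' mean intensity of its member levels. Centroids are initialized evenly
#' spaced at `(k - 0.5) * 256 / B`; empty clusters keep their previous
#' centroid. Iteration stops when the largest centroid shift is at most
#' `tol` or after `max_iter` sweeps. Cost is O(256 B) per iteration,
#' independent of image size.
#'
#' @param image Grayscale matrix, values on 0-255 (quantized to integer
#'   levels internally).
#' @param B Number of clusters (>= 1); 2 separates lesion from skin, 4 gives
#'   a finer intensity partition.
#' @param max_iter Maximum sweeps.
#' @param tol Convergence tolerance on centroid movement (grey levels).
#' @return An object of class `"segmentation"` with `centroids` (length
#'   `B`), `level_assignment` (integer vector of length 256 mapping grey
#'   level `0..255` to cluster index, `NA` for absent levels), `label_map`
#'   (integer matrix of per-pixel cluster indices), `iterations`, and
#'   `objective` (per-iteration frequency-weighted within-cluster squared
#'   deviation).
#' @export
cluster_intensities <- function(image, B = 2, max_iter = 100, tol = 1e-4) {
  if (!is_gray_image(image) || length(image) == 0) {
    stop_domain("image must be a nonempty grayscale matrix")
  }
  if (B < 1) stop_domain("B must be >= 1")
  B <- as.integer(B)
  levels_all <- 0:255
  q <- pmin(pmax(round(image), 0), 255)
  freq <- tabulate(as.integer(q) + 1L, nbins = 256L)
  present <- which(freq > 0)                # 1-based bin index, level = idx-1
  lv <- levels_all[present]
  fr <- freq[present]

  centroids <- (seq_len(B) - 0.5) * 256 / B
  assign_lv <- integer(length(lv))
  objective <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- abs(outer(centroids, lv, "-"))     # B x nlevels
    assign_lv <- apply(d, 2, which.min)     # ties -> lower index
    new_centroids <- centroids
    for (k in seq_len(B)) {
      m <- assign_lv == k
      if (any(m)) new_centroids[k] <- sum(fr[m] * lv[m]) / sum(fr[m])
    }
    objective <- c(objective,
                   sum(fr * (lv - new_centroids[assign_lv])^2))
    shift <- max(abs(new_centroids - centroids))
    centroids <- new_centroids
    if (shift <= tol || iter >= max_iter) break
  }

  level_assignment <- rep(NA_integer_, 256)
  level_assignment[present] <- assign_lv
  label_map <- matrix(level_assignment[as.integer(q) + 1L],
                      nrow(image), ncol(image))
  structure(list(centroids = centroids, level_assignment = level_assignment,
                 label_map = label_map, iterations = iter,
                 objective = objective),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("Grey-level clustering:", length(x$centroids), "clusters,",
      x$iterations, "iterations\n  centroids:",
      paste(sprintf("%.2f", x$centroids), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the lesion mask from a segmentation
#'
#' Lesions are darker than the surrounding skin, so the cluster with the
#' lowest centroid among the populated clusters is taken as the lesion.
#'
#' @param seg A `"segmentation"` from [cluster_intensities()].
#' @return Logical matrix marking lesion pixels.
#' @export
lesion_mask <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  populated <- sort(unique(as.integer(seg$label_map)))
  if (length(populated) < 2) {
    stop_domain("degenerate segmentation: a single populated cluster, no lesion/background contrast")
  }
  darkest <- populated[which.min(seg$centroids[populated])]
  seg$label_map == darkest
}

#' Apply a binary mask to an image
#'
#' Pixels outside the mask are set to 0; pixels inside are unchanged.
#'
#' @param image Grayscale matrix.
#' @param mask Logical matrix of the same shape.
#' @return Masked grayscale matrix.
#' @export
apply_mask <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) {
    stop_domain("image and mask must have the same shape")
  }
  image * (mask * 1)
}

#' Jaccard overlap of two binary masks
#'
#' @param a,b Logical matrices of the same shape.
#' @return Intersection-over-union in `[0, 1]` (1 when both masks are empty).
#' @export
jaccard_index <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_domain("masks must have the same shape")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
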