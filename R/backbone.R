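# VGG19-style convolutional backbone used as a deep feature extractor:
# 16 conv layers (3x3, same padding, ReLU) in 5 blocks of {2,2,4,4,4} with
# widths 64/128/256/512/512, 2x2 max-pooling after each block, then an FC
# head flatten -> 4096 -> 512 -> softmax. The 4096-dimensional first FC
# activation is the feature tap. Weights are seeded-random by default
# (He-normal), so no pretrained download is required; externally obtained
# weights can be injected. Convolutions are evaluated as im2col + BLAS GEMM.

#' Backbone architecture specification
#'
#' Defaults describe the VGG19 layout: 5 conv blocks of `{2,2,4,4,4}` 3x3
#' layers with widths 64/128/256/512/512, max-pooling after each block, and
#' an FC head `flatten -> 4096 -> 512 -> n_classes` softmax. The
#' 4096-dimensional first FC output is the deep feature tap.
#' `width_multiplier` scales the convolutional widths only (the FC sizes and
#' hence the 4096-dim tap are unchanged), giving a compact backbone for
#' desk-scale experiments.
#'
#' @param blocks Integer vector: conv layers per block.
#' @param widths Integer vector: output channels per block (before scaling).
#' @param fc Integer length-2: sizes of the two hidden FC layers.
#' @param n_classes Number of softmax output neurons.
#' @param input_size Expected square RGB input side in pixels.
#' @param width_multiplier Multiplier applied to `widths`.
#' @return An object of class `"backbone_spec"`.
#' @export
backbone_spec <- function(blocks = c(2, 2, 4, 4, 4),
                          widths = c(64, 128, 256, 512, 512),
                          fc = c(4096, 512), n_classes = 8,
                          input_size = 224, width_multiplier = 1) {
  if (length(blocks) != length(widths)) {
    stop_domain("blocks and widths must have the same length")
  }
  if (any(blocks < 1) || any(widths < 1)) stop_domain("malformed backbone spec")
  if (length(fc) != 2 || any(fc < 1)) stop_domain("fc must give two layer sizes")
  if (n_classes < 2) stop_domain("need at least 2 output neurons")
  widths <- pmax(1L, as.integer(round(widths * width_multiplier)))
  s <- input_size
  for (i in seq_along(blocks)) s <- s %/% 2L
  if (s < 1) stop_domain("input_size too small for the pooling depth")
  structure(list(blocks = as.integer(blocks), widths = widths,
                 fc = as.integer(fc), n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 final_spatial = as.integer(s)),
            class = "backbone_spec")
}

#' Build a backbone with seeded-random (or injected) weights
#'
#' Seeded mode draws He-normal weights (`sd = sqrt(2 / fan_in)`) and zero
#' biases, fully deterministically given `seed`. A list of externally
#' obtained weights with the same structure can be injected via `weights`
#' (e.g. converted pretrained parameters); no download is attempted.
#'
#' @param spec A [backbone_spec()].
#' @param seed Integer seed for the weight draw.
#' @param weights Optional weight list to inject (elements `conv`, `fc`).
#' @return An object of class `"backbone"`.
#' @export
build_backbone <- function(spec = backbone_spec(), seed = 1, weights = NULL) {
  stopifnot(inherits(spec, "backbone_spec"))
  layer_channels <- list()
  cin <- 3L
  for (b in seq_along(spec$blocks)) {
    for (l in seq_len(spec$blocks[b])) {
      layer_channels[[length(layer_channels) + 1L]] <- c(cin, spec$widths[b])
      cin <- spec$widths[b]
    }
  }
  flat <- spec$final_spatial^2 * spec$widths[length(spec$widths)]
  fc_dims <- list(c(flat, spec$fc[1]), c(spec$fc[1], spec$fc[2]),
                  c(spec$fc[2], spec$n_classes))
  if (is.null(weights)) {
    weights <- with_seed(seed, {
      conv <- lapply(layer_channels, function(ch) {
        fan_in <- 9L * ch[1]
        list(w = matrix(rnorm(fan_in * ch[2], sd = sqrt(2 / fan_in)),
                        fan_in, ch[2]),
             b = numeric(ch[2]))
      })
      fc <- lapply(fc_dims, function(d) {
        list(w = matrix(rnorm(d[1] * d[2], sd = sqrt(2 / d[1])), d[1], d[2]),
             b = numeric(d[2]))
      })
      list(conv = conv, fc = fc)
    })
    provenance <- list(backbone = "vgg19-style", init = "seeded", seed = seed)
  } else {
    for (i in seq_along(layer_channels)) {
      ch <- layer_channels[[i]]
      if (!identical(dim(weights$conv[[i]]$w), c(9L * ch[1], ch[2]))) {
        stop_domain("injected conv weights do not match the spec")
      }
    }
    provenance <- list(backbone = "vgg19-style", init = "injected", seed = NA)
  }
  structure(list(spec = spec, weights = weights,
                 layer_channels = layer_channels, provenance = provenance),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("VGG19-style backbone: %d conv layers (widths %s), FC %s -> %d, input %dx%d, init %s\n",
              length(x$layer_channels),
              paste(x$spec$widths, collapse = "/"),
              paste(x$spec$fc, collapse = " -> "), x$spec$n_classes,
              x$spec$input_size, x$spec$input_size, x$provenance$init))
  invisible(x)
}

# One 3x3 same-padding conv + ReLU on an H x W x Cin array via im2col and a
# single GEMM. Column order of the im2col matrix matches R's column-major
# flattening of a (3, 3, Cin, Cout) kernel array, so hand-built kernels can
# be supplied as matrix(kernel_array, 9 * Cin, Cout).
conv3x3_relu <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  xpad <- array(0, dim = c(H + 2L, W + 2L, Cin))
  xpad[2:(H + 1), 2:(W + 1), ] <- x
  M <- matrix(0, H * W, 9L * Cin)
  col <- 0L
  for (c in seq_len(Cin)) {
    for (kx in 0:2) {
      for (ky in 0:2) {
        col <- col + 1L
        M[, col] <- xpad[(1L + ky):(H + ky), (1L + kx):(W + kx), c]
      }
    }
  }
  out <- M %*% w
  out <- pmax(sweep(out, 2, b, "+"), 0)
  array(out, dim = c(H, W, ncol(w)))
}

# 2x2/stride-2 max pooling (floor on odd sizes). Returns the pooled array
# and, for Grad-CAM unpooling, the 1..4 code of the winning corner
# (ties to the first in order TL, BL, TR, BR).
maxpool2 <- function(x) {
  d <- dim(x); H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  ri <- seq_len(H2) * 2L; ci <- seq_len(W2) * 2L
  a <- x[ri - 1L, ci - 1L, , drop = FALSE]
  b <- x[ri,      ci - 1L, , drop = FALSE]
  cc <- x[ri - 1L, ci,      , drop = FALSE]
  dd <- x[ri,      ci,      , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  code <- ifelse(a == out, 1L, ifelse(b == out, 2L, ifelse(cc == out, 3L, 4L)))
  list(out = out, code = array(code, dim = dim(out)))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Full forward pass. record = TRUE keeps the intermediates needed for
# Grad-CAM (last-block pre-pool activations, pooling codes, FC
# pre-activations).
backbone_forward <- function(backbone, image, record = FALSE) {
  spec <- backbone$spec
  if (!is_rgb_image(image) ||
      nrow(image) != spec$input_size || ncol(image) != spec$input_size) {
    stop_domain("input must be an RGB array of ", spec$input_size, "x",
                spec$input_size)
  }
  x <- image / 255
  li <- 0L
  last_A <- NULL; last_code <- NULL
  for (bidx in seq_along(spec$blocks)) {
    for (l in seq_len(spec$blocks[bidx])) {
      li <- li + 1L
      wl <- backbone$weights$conv[[li]]
      x <- conv3x3_relu(x, wl$w, wl$b)
    }
    if (bidx == length(spec$blocks) && record) last_A <- x
    mp <- maxpool2(x)
    x <- mp$out
    if (bidx == length(spec$blocks)) last_code <- mp$code
  }
  xf <- as.numeric(x)
  fc <- backbone$weights$fc
  h1pre <- drop(crossprod(fc[[1]]$w, xf)) + fc[[1]]$b
  h1 <- pmax(h1pre, 0)
  h2pre <- drop(crossprod(fc[[2]]$w, h1)) + fc[[2]]$b
  h2 <- pmax(h2pre, 0)
  logits <- drop(crossprod(fc[[3]]$w, h2)) + fc[[3]]$b
  out <- list(tap = h1, probs = softmax(logits), logits = logits)
  if (record) {
    out$last_A <- last_A; out$last_code <- last_code
    out$pooled_dim <- dim(x); out$h1pre <- h1pre; out$h2pre <- h2pre
  }
  out
}

#' Class probabilities or deep features from a backbone
#'
#' @param object A `"backbone"`.
#' @param image RGB array matching the spec's input size (or a list of them).
#' @param type `"prob"` for the softmax output, `"feature"` for the
#'   4096-dimensional tap.
#' @param ... Unused.
#' @return Probability vector / feature vector, or a matrix (one row per
#'   image) for list input.
#' @export
predict.backbone <- function(object, image, type = c("prob", "feature"), ...) {
  type <- match.arg(type)
  if (is.list(image)) {
    return(t(vapply(image, function(im) {
      fw <- backbone_forward(object, im)
      if (type == "prob") fw$probs else fw$tap
    }, numeric(if (type == "prob") object$spec$n_classes else object$spec$fc[1]))))
  }
  fw <- backbone_forward(object, image)
  if (type == "prob") fw$probs else fw$tap
}

#' Extract the deep descriptor of one or more images
#'
#' Runs the backbone forward pass and returns the first-FC (4096-dim)
#' activation. A list of images yields a matrix with one row per image;
#' batch extraction gives exactly the per-image results.
#'
#' @param image RGB array of the spec's input size, or a list of such.
#' @param backbone A `"backbone"` from [build_backbone()].
#' @return For a single image, a numeric vector of class
#'   `"deep_descriptor"` with a `provenance` attribute; for a list, a
#'   numeric matrix `n x fc[1]`.
#' @export
extract_deep <- function(image, backbone) {
  stopifnot(inherits(backbone, "backbone"))
  if (is.list(image)) {
    return(predict(backbone, image, type = "feature"))
  }
  v <- backbone_forward(backbone, image)$tap
  structure(v, provenance = backbone$provenance, class = "deep_descriptor")
}

#' @export
print.deep_descriptor <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf("Deep descriptor: %d features (%s, init %s, seed %s)\n",
              length(x), p$backbone, p$init, p$seed))
  invisible(x)
}

#' Grad-CAM saliency map
#'
#' Gradient-weighted class activation mapping: the gradient of the target
#' class logit with respect to the last conv block's (post-ReLU)
#' activations is averaged per channel into weights, the weighted activation
#' sum is rectified, bilinearly upsampled to the input size, and min-max
#' normalized to `[0, 1]`. If the rectified map is identically zero the map
#' is flagged degenerate and returned uniform.
#'
#' @param backbone A `"backbone"`.
#' @param image RGB array of the spec's input size.
#' @param target_class Integer class index in `1..n_classes`.
#' @return Matrix of class `"saliency_map"` (values in `[0, 1]`, same
#'   height/width as the input) with attributes `target_class` and
#'   `degenerate`.
#' @export
grad_cam <- function(backbone, image, target_class = NULL) {
  stopifnot(inherits(backbone, "backbone"))
  fw <- backbone_forward(backbone, image, record = TRUE)
  if (is.null(target_class)) target_class <- which.max(fw$probs)
  nc <- backbone$spec$n_classes
  if (target_class < 1 || target_class > nc) stop_domain("target_class out of range")
  fc <- backbone$weights$fc

  # gradient of the class logit back to the flattened pooled activations
  g_h2 <- fc[[3]]$w[, target_class] * (fw$h2pre > 0)
  g_h1 <- drop(fc[[2]]$w %*% g_h2) * (fw$h1pre > 0)
  g_flat <- drop(fc[[1]]$w %*% g_h1)
  g_pool <- array(g_flat, dim = fw$pooled_dim)

  # unpool: route each pooled gradient to the argmax corner of its window
  A <- fw$last_A
  gA <- array(0, dim = dim(A))
  d <- dim(g_pool)
  ri <- seq_len(d[1]) * 2L; ci <- seq_len(d[2]) * 2L
  for (k in seq_len(d[3])) {
    code <- matrix(fw$last_code[, , k], d[1], d[2])
    gp <- matrix(g_pool[, , k], d[1], d[2])
    rowsel <- matrix(ri, d[1], d[2]) - (code == 1L | code == 3L)
    colsel <- matrix(ci, d[1], d[2], byrow = TRUE) - (code == 1L | code == 2L)
    sl <- matrix(0, dim(A)[1], dim(A)[2])
    sl[cbind(as.integer(rowsel), as.integer(colsel))] <- as.numeric(gp)
    gA[, , k] <- sl
  }

  alpha <- apply(gA, 3, mean)
  heat <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(dim(A)[3])) heat <- heat + alpha[k] * A[, , k]
  heat <- pmax(heat, 0)
  degenerate <- max(heat) <= 0
  heat <- bilinear_resize(heat, nrow(image), ncol(image))
  heat <- pmax(heat, 0)
  if (degenerate || max(heat) == 0) {
    heat <- matrix(0.5, nrow(image), ncol(image))
    degenerate <- TRUE
  } else {
    heat <- (heat - min(heat)) / (max(heat) - min(heat))
  }
  structure(heat, target_class = target_class, degenerate = degenerate,
            class = c("saliency_map", "matrix", "array"))
}
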