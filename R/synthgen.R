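# Seeded generator of dermoscopy-like labelled images: darker elliptical
# lesions with irregular borders on a textured skin background, optional
# hair-like strokes, and multiplicative speckle noise. Every downstream
# stage of the pipeline is testable against these fixtures without any
# external image archive.

#' Lesion image specification
#'
#' Describes one synthetic dermoscopy-like image: a darker elliptical lesion
#' with a radially perturbed border on a textured background, optional
#' hair-like artifacts, and multiplicative speckle noise. All randomness of
#' the realized image flows from `seed`.
#'
#' @param class_id Character class label (e.g. one of AK, BCC, BK, DF, MEL,
#'   MN, SCC, VASC).
#' @param image_size Side length of the square image in pixels.
#' @param ellipse_center Numeric length-2 `(row, col)` center in pixels.
#' @param axes Numeric length-2 semi-axes `(a, b)` in pixels.
#' @param rotation Ellipse rotation in radians.
#' @param lesion_intensity_mean,background_mean Mean grey levels (0-255);
#'   the lesion must be darker than the background.
#' @param border_irregularity Amplitude of the sinusoidal radial perturbation
#'   of the lesion border, as a fraction of the local radius (0 = exact
#'   ellipse).
#' @param hair_count Number of dark hair-like strokes (integer >= 0).
#' @param speckle_var Variance of the multiplicative speckle noise factor
#'   (mean-one gamma); 0 disables speckle.
#' @param texture_amplitude Peak amplitude (grey levels) of the smooth
#'   low-frequency background texture.
#' @param seed Integer seed; identical specs yield bit-identical images.
#' @return An object of class `"lesion_spec"`.
#' @export
lesion_spec <- function(class_id, image_size = 224,
                        ellipse_center = c(image_size / 2, image_size / 2),
                        axes = c(image_size * 0.25, image_size * 0.18),
                        rotation = 0,
                        lesion_intensity_mean = 90, background_mean = 225,
                        border_irregularity = 0.05, hair_count = 0,
                        speckle_var = 0.05, texture_amplitude = 8, seed = 1) {
  if (speckle_var < 0) stop_domain("speckle_var must be >= 0")
  if (lesion_intensity_mean >= background_mean) {
    stop_domain("lesion_intensity_mean must be below background_mean (lesions are darker)")
  }
  if (any(axes <= 0)) stop_domain("axes must be positive")
  if (hair_count < 0) stop_domain("hair_count must be >= 0")
  if (border_irregularity < 0) stop_domain("border_irregularity must be >= 0")
  reach <- max(axes) * (1 + border_irregularity)
  if (ellipse_center[1] - reach < 1 || ellipse_center[1] + reach > image_size ||
      ellipse_center[2] - reach < 1 || ellipse_center[2] + reach > image_size) {
    stop_domain("ellipse (with border perturbation) does not fit inside the image")
  }
  structure(list(
    class_id = as.character(class_id), image_size = as.integer(image_size),
    ellipse_center = as.numeric(ellipse_center), axes = as.numeric(axes),
    rotation = as.numeric(rotation),
    lesion_intensity_mean = as.numeric(lesion_intensity_mean),
    background_mean = as.numeric(background_mean),
    border_irregularity = as.numeric(border_irregularity),
    hair_count = as.integer(hair_count), speckle_var = as.numeric(speckle_var),
    texture_amplitude = as.numeric(texture_amplitude),
    seed = as.integer(seed)
  ), class = "lesion_spec")
}

#' The eight-class dermoscopy label vocabulary
#'
#' @return Character vector of the eight diagnosis labels.
#' @export
dermfuse_classes <- function() {
  c("AK", "BCC", "BK", "DF", "MEL", "MN", "SCC", "VASC")
}

#' Apply multiplicative speckle noise to an image
#'
#' Multiplies the image elementwise by i.i.d. mean-one gamma noise factors
#' with the requested variance (shape `1/variance`), the standard
#' positivity-preserving model of multiplicative speckle. The result is
#' clipped to the 0-255 scale.
#'
#' @param image Grayscale matrix, values in \[0, 255\].
#' @param variance Variance of the noise factor; 0 returns the input
#'   unchanged.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Noisy grayscale matrix of the same shape.
#' @export
add_speckle <- function(image, variance, seed = 1) {
  if (!is_gray_image(image)) stop_domain("image must be a grayscale matrix")
  if (variance < 0) stop_domain("variance must be >= 0")
  if (variance == 0) return(image)
  n <- with_seed(seed, {
    rgamma(length(image), shape = 1 / variance, rate = 1 / variance)
  })
  out <- clip255(image * n)
  dim(out) <- dim(image)
  out
}

# Radial border perturbation g(phi) in [-1, 1]: a fixed sum of low-order
# sinusoids whose coefficients and phases are drawn from the spec seed.
border_perturbation <- function(phi, seed) {
  par <- with_seed(derive_seed(seed, "border"), {
    amp <- runif(3, 0.2, 1)
    list(amp = amp / sum(amp), phase = runif(3, 0, 2 * pi))
  })
  g <- 0
  for (h in 1:3) {
    g <- g + par$amp[h] * sin((h + 1) * phi + par$phase[h])
  }
  g
}

# Closed-form lesion membership for pixel centers (r, c): inside iff the
# normalized elliptical radius rho <= 1 + irregularity * g(phi).
lesion_membership <- function(r, c, spec) {
  dy <- r - spec$ellipse_center[1]
  dx <- c - spec$ellipse_center[2]
  u <- dx * cos(spec$rotation) + dy * sin(spec$rotation)
  v <- -dx * sin(spec$rotation) + dy * cos(spec$rotation)
  rho <- sqrt((u / spec$axes[1])^2 + (v / spec$axes[2])^2)
  if (spec$border_irregularity == 0) return(rho <= 1)
  phi <- atan2(v, u)
  rho <= 1 + spec$border_irregularity * border_perturbation(phi, spec$seed)
}

# Smooth low-frequency texture field: a coarse uniform grid bilinearly
# upsampled to the full image, scaled to the requested amplitude.
texture_field <- function(size, amplitude, seed) {
  if (amplitude <= 0) return(matrix(0, size, size))
  coarse_n <- max(4L, as.integer(size / 16))
  coarse <- with_seed(seed, matrix(runif(coarse_n^2, -1, 1), coarse_n, coarse_n))
  bilinear_resize(coarse, size, size) * amplitude
}

# Dark quadratic Bezier strokes emulating hairs; drawn 2 px thick.
draw_hairs <- function(img, count, seed) {
  if (count == 0) return(img)
  n <- nrow(img)
  with_seed(derive_seed(seed, "hair"), {
    for (i in seq_len(count)) {
      p0 <- runif(2, 1, n)
      p2 <- runif(2, 1, n)
      p1 <- runif(2, n * 0.2, n * 0.8)
      shade <- runif(1, 15, 50)
      t <- seq(0, 1, length.out = 4L * n)
      b <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
      rr <- round(b[, 1]); cc <- round(b[, 2])
      for (d in list(c(0L, 0L), c(1L, 0L), c(0L, 1L))) {
        r2 <- rr + d[1]; c2 <- cc + d[2]
        ok <- r2 >= 1 & r2 <= n & c2 >= 1 & c2 <= n
        img[cbind(r2[ok], c2[ok])] <- shade
      }
    }
    img
  })
}

#' Generate one synthetic lesion image with its ground-truth mask
#'
#' Composes a textured skin background, a darker radially perturbed
#' elliptical lesion, optional hair strokes, and multiplicative speckle;
#' returns the RGB image together with the exact boolean lesion mask used
#' (computed from the closed-form geometry, before noise).
#'
#' @param spec A [lesion_spec()].
#' @return A list with elements `image` (`H x W x 3` array, 0-255), `mask`
#'   (logical `H x W` matrix), and `spec`.
#' @export
generate_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  n <- spec$image_size
  rc <- expand.grid(r = seq_len(n), c = seq_len(n))
  mask <- matrix(lesion_membership(rc$r, rc$c, spec), n, n)

  img <- spec$background_mean +
    texture_field(n, spec$texture_amplitude, derive_seed(spec$seed, "texture"))
  lesion_tex <- texture_field(n, spec$texture_amplitude * 0.5,
                              derive_seed(spec$seed, "lesion-texture"))
  img[mask] <- spec$lesion_intensity_mean + lesion_tex[mask]
  img <- draw_hairs(img, spec$hair_count, spec$seed)
  img <- clip255(img)
  img <- add_speckle(img, spec$speckle_var, derive_seed(spec$seed, "speckle"))

  # fixed warm channel tint so the RGB image reduces cleanly to luma
  rgb <- array(0, dim = c(n, n, 3L))
  rgb[, , 1] <- img
  rgb[, , 2] <- img * 0.92
  rgb[, , 3] <- img * 0.85
  list(image = clip255(rgb), mask = mask, spec = spec)
}

# Per-class generation parameters: class identity is encoded by
# systematically different lesion intensity, border irregularity, size and
# texture so that classes are learnable from image content. A known
# vocabulary label always maps to the same archetype (by its position in
# the eight-class vocabulary), independent of which classes are requested;
# unknown labels fall back to their request position.
class_archetype <- function(class_name, j, image_size) {
  v <- match(class_name, dermfuse_classes())
  if (!is.na(v)) j <- v
  list(
    lesion_mean = 40 + 18 * ((j - 1) %% 8),
    irregularity = 0.04 + 0.03 * ((j - 1) %% 4),
    axis_a = image_size * (0.20 + 0.02 * ((j - 1) %% 3)),
    axis_b = image_size * (0.14 + 0.015 * ((j - 1) %% 4)),
    texture = 5 + 2 * ((j - 1) %% 3)
  )
}

#' Generate a labelled synthetic dermoscopy dataset
#'
#' Draws `class_counts[k]` images for each named class. Class identity is
#' encoded by systematically different lesion intensity, border shape and
#' texture parameters (with per-image jitter), so the classes are learnable;
#' the default imbalance-free of choice is up to the caller — pass e.g. the
#' archive-like profile `c(AK=440, BCC=600, BK=800, DF=230, MEL=818,
#' MN=1510, SCC=245, VASC=200)` to emulate a class-imbalanced collection.
#'
#' @param class_counts Named integer vector of per-class image counts.
#' @param image_size Side length in pixels (square images).
#' @param seed Integer seed; the full dataset is deterministic given it.
#' @param speckle_var Speckle variance applied to every image.
#' @param hair_prob Per-stroke inclusion probability; each image carries
#'   `rbinom(1, 3, hair_prob)` hair strokes.
#' @return An object of class `"synthetic_dataset"`: a list with `images`
#'   (list of `H x W x 3` arrays), `masks` (list of logical matrices),
#'   `labels` (factor with levels in the order of `names(class_counts)`),
#'   and `manifest` (data frame of the per-image [lesion_spec()] fields).
#' @export
generate_dataset <- function(class_counts, image_size = 224, seed = 1,
                             speckle_var = 0.05, hair_prob = 0.25) {
  if (length(class_counts) == 0) stop_domain("class_counts must be nonempty")
  if (is.null(names(class_counts)) || any(!nzchar(names(class_counts)))) {
    stop_domain("class_counts must be a named vector")
  }
  if (any(class_counts < 0)) stop_domain("class counts must be >= 0")
  classes <- names(class_counts)
  images <- list(); masks <- list(); labels <- character(0)
  rows <- list()
  idx <- 0L
  for (j in seq_along(classes)) {
    arch <- class_archetype(classes[j], j, image_size)
    for (i in seq_len(class_counts[[j]])) {
      idx <- idx + 1L
      img_seed <- derive_seed(seed, paste0(classes[j], "-", i))
      jit <- with_seed(img_seed, list(
        center = image_size / 2 + runif(2, -0.05, 0.05) * image_size,
        rot = runif(1, 0, pi),
        ax = runif(2, 0.85, 1.15),
        dmean = runif(1, -5, 5),
        hairs = rbinom(1, 3, hair_prob)
      ))
      spec <- lesion_spec(
        class_id = classes[j], image_size = image_size,
        ellipse_center = jit$center,
        axes = c(arch$axis_a * jit$ax[1], arch$axis_b * jit$ax[2]),
        rotation = jit$rot,
        lesion_intensity_mean = arch$lesion_mean + jit$dmean,
        background_mean = 225,
        border_irregularity = arch$irregularity,
        hair_count = jit$hairs, speckle_var = speckle_var,
        texture_amplitude = arch$texture, seed = img_seed
      )
      gen <- generate_lesion_image(spec)
      images[[idx]] <- gen$image
      masks[[idx]] <- gen$mask
      labels[idx] <- classes[j]
      rows[[idx]] <- data.frame(
        class_id = classes[j], image_size = image_size,
        center_r = spec$ellipse_center[1], center_c = spec$ellipse_center[2],
        axis_a = spec$axes[1], axis_b = spec$axes[2],
        rotation = spec$rotation,
        lesion_intensity_mean = spec$lesion_intensity_mean,
        background_mean = spec$background_mean,
        border_irregularity = spec$border_irregularity,
        hair_count = spec$hair_count, speckle_var = spec$speckle_var,
        seed = spec$seed
      )
    }
  }
  structure(list(
    images = images, masks = masks,
    labels = factor(labels, levels = classes),
    manifest = do.call(rbind, rows)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dermoscopy dataset:", length(x$images), "images,",
      nlevels(x$labels), "classes\n")
  print(table(x$labels))
  invisible(x)
}

#' Write a synthetic dataset to disk as PNG files plus a CSV manifest
#'
#' The manifest has columns `image_path,label,split` with `split` left empty
#' at generation time.
#'
#' @param dataset A `"synthetic_dataset"` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(dataset$images))
  for (i in seq_along(dataset$images)) {
    paths[i] <- file.path(dir, sprintf("img_%05d.png", i))
    write_image_png(dataset$images[[i]], paths[i])
  }
  manifest <- data.frame(image_path = paths,
                         label = as.character(dataset$labels),
                         split = "")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
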