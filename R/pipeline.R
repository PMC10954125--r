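# End-to-end driver: preprocess -> segment -> HOG + deep features ->
# fuse/select -> rebalance (training rows only) -> train -> evaluate.
# Exposed as one fitting function, dermfuse(), returning a classed object.

#' Pipeline configuration
#'
#' Stage parameters with defaults matching the standard working sizes:
#' 224x224 preprocessing, 64x128 HOG geometry, 2-cluster segmentation,
#' 7876-wide fusion with 1186 selected features, learning rate 0.001, batch
#' 32, 40 epochs, 70:20:10 train:test:validation split, kurtosis tolerance
#' 0.001.
#'
#' @param diffusion A [diffusion_params()].
#' @param clusters Number of grey-level clusters for segmentation.
#' @param resize_to Preprocessing side length in pixels.
#' @param backbone A [backbone_spec()] for the deep branch.
#' @param backbone_seed Seed of the deep backbone weight draw.
#' @param entropy_bins Histogram bins of the entropy scorer.
#' @param select_k Number of features kept by entropy selection.
#' @param smote_k SMOTE neighbourhood size.
#' @param rebalance Whether to apply SMOTE-Tomek to the training rows.
#' @param hidden Hidden width of the classifier head.
#' @param train A [train_config()].
#' @param split Named fractions for [split_dataset()].
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(diffusion = diffusion_params(), clusters = 2,
                            resize_to = 224,
                            backbone = backbone_spec(),
                            backbone_seed = 42,
                            entropy_bins = 256, select_k = 1186,
                            smote_k = 5, rebalance = TRUE, hidden = 512,
                            train = train_config(),
                            split = c(train = 0.7, test = 0.2, validation = 0.1)) {
  stopifnot(inherits(diffusion, "diffusion_params"),
            inherits(backbone, "backbone_spec"),
            inherits(train, "train_config"))
  if (abs(sum(split) - 1) > 1e-8) stop_domain("split fractions must sum to 1")
  structure(list(diffusion = diffusion, clusters = clusters,
                 resize_to = as.integer(resize_to), backbone = backbone,
                 backbone_seed = as.integer(backbone_seed),
                 entropy_bins = as.integer(entropy_bins),
                 select_k = as.integer(select_k), smote_k = as.integer(smote_k),
                 rebalance = rebalance, hidden = as.integer(hidden),
                 train = train, split = split),
            class = "pipeline_config")
}

#' A compact pipeline configuration for desk-scale runs
#'
#' Same pipeline with a quarter-width backbone on 112-pixel deep input and
#' 15 diffusion iterations; all dimension identities (3780, 4096, 7876,
#' 1186) are unchanged. See the methods vignette for the rationale.
#'
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `"pipeline_config"`.
#' @export
pipeline_config_compact <- function(...) {
  args <- list(...)
  defaults <- list(
    backbone = backbone_spec(width_multiplier = 0.25, input_size = 112),
    diffusion = diffusion_params(max_iter = 15)
  )
  defaults[names(args)] <- args
  do.call(pipeline_config, defaults)
}

#' Read and validate a CSV image manifest
#'
#' Expects a header `image_path,label[,split]`. Labels must belong to the
#' eight-class vocabulary (AK, BCC, BK, DF, MEL, MN, SCC, VASC), paths must
#' exist and be unique, and `split` values (if present) must be one of
#' train/test/val/validation or empty; a missing split column marks all rows
#' unassigned.
#'
#' @param path Path to the CSV manifest.
#' @return Data frame of class `"manifest"` with columns `image_path`,
#'   `label` (factor on the eight-class vocabulary) and `split`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_domain("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_path", "label") %in% names(m))) {
    stop_domain("manifest must have columns image_path,label[,split]")
  }
  vocab <- dermfuse_classes()
  bad <- which(!m$label %in% vocab)
  if (length(bad)) {
    stop_domain("unknown label '", m$label[bad[1]], "' in manifest row ", bad[1])
  }
  if (anyDuplicated(m$image_path)) {
    stop_domain("duplicate image_path in manifest: ",
                m$image_path[anyDuplicated(m$image_path)])
  }
  missing <- !file.exists(file.path(dirname(path), m$image_path)) &
    !file.exists(m$image_path)
  if (any(missing)) {
    stop_domain("image file missing for manifest row ", which(missing)[1])
  }
  if (!"split" %in% names(m)) m$split <- "unassigned"
  m$split[is.na(m$split) | m$split == ""] <- "unassigned"
  m$split[m$split == "val"] <- "validation"
  ok <- m$split %in% c("train", "test", "validation", "unassigned")
  if (!all(ok)) stop_domain("invalid split value in manifest row ", which(!ok)[1])
  m$label <- factor(m$label, levels = vocab)
  class(m) <- c("manifest", "data.frame")
  attr(m, "dir") <- dirname(path)
  m
}

# Resolve a dataset argument to list(images, labels, masks?).
resolve_dataset <- function(dataset) {
  if (inherits(dataset, "synthetic_dataset")) {
    return(list(images = dataset$images, labels = dataset$labels,
                masks = dataset$masks))
  }
  if (inherits(dataset, "manifest")) {
    paths <- ifelse(file.exists(dataset$image_path), dataset$image_path,
                    file.path(attr(dataset, "dir"), dataset$image_path))
    return(list(images = lapply(paths, read_image_png),
                labels = droplevels(dataset$label), masks = NULL))
  }
  if (is.list(dataset) && !is.null(dataset$labels)) {
    return(list(images = dataset$images, labels = factor(dataset$labels),
                masks = dataset$masks))
  }
  stop_domain("dataset must be a synthetic_dataset, a manifest, or list(images, labels)")
}

# Per-image feature extraction: grayscale -> resize -> diffusion denoise ->
# grey-level clustering -> lesion mask -> HOG on the masked image; deep
# descriptor from the resized RGB image. Returns n x p matrices.
extract_pipeline_features <- function(images, config, backbone, verbose = FALSE) {
  n <- length(images)
  hog_mat <- NULL; deep_mat <- NULL
  for (i in seq_len(n)) {
    img <- images[[i]]
    g <- to_grayscale(img)
    g <- resize_image(g, config$resize_to, config$resize_to)
    den <- madf(g, config$diffusion)
    mask <- tryCatch(
      lesion_mask(cluster_intensities(den$filtered, B = config$clusters)),
      error = function(e) matrix(TRUE, nrow(den$filtered), ncol(den$filtered)))
    h <- hog_descriptor(apply_mask(den$filtered, mask))
    rgb <- resize_image(img, backbone$spec$input_size, backbone$spec$input_size)
    d <- backbone_forward(backbone, rgb)$tap
    if (is.null(hog_mat)) {
      hog_mat <- matrix(0, n, length(h))
      deep_mat <- matrix(0, n, length(d))
    }
    hog_mat[i, ] <- h
    deep_mat[i, ] <- d
    if (verbose && i %% 50 == 0) message("  features: ", i, "/", n)
  }
  list(hog = hog_mat, deep = deep_mat)
}

stage_log <- function(log, stage, n_in, n_out, t0, seed = NA) {
  rec <- data.frame(stage = stage, n_in = n_in, n_out = n_out,
                    seconds = round(as.numeric(proc.time()[3] - t0), 3),
                    seed = seed)
  rbind(log, rec)
}

#' Fit the dermoscopy classification pipeline
#'
#' Runs the full pipeline on a labelled image set: per-image preprocessing
#' (grayscale, resize, anisotropic-diffusion denoising), grey-level
#' clustering segmentation, HOG descriptor of the masked lesion plus a deep
#' backbone descriptor of the RGB image, fusion, entropy-based feature
#' selection fitted on the training partition, optional SMOTE-Tomek
#' rebalancing of the training rows, and training of the softmax head. The
#' test partition is evaluated into a metrics report. One `seed` fans out
#' deterministically to per-stage seeds.
#'
#' @param dataset A `"synthetic_dataset"`, a `"manifest"` (images are read
#'   from disk), or a `list(images =, labels =)`.
#' @param config A [pipeline_config()].
#' @param seed Integer master seed.
#' @param features Optional precomputed `list(hog =, deep =)` matrices (as
#'   produced by a previous fit's `$features`) to skip extraction.
#' @param keep_features Store the feature matrices on the fit (needed to
#'   refit cheaply, e.g. with and without rebalancing).
#' @param verbose Log stage progress.
#' @return An object of class `"dermfuse_fit"`; see
#'   [predict.dermfuse_fit()], [summary.dermfuse_fit()].
#' @export
dermfuse <- function(dataset, config = pipeline_config(), seed = 1,
                     features = NULL, keep_features = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- resolve_dataset(dataset)
  labels <- droplevels(factor(ds$labels))
  n <- length(ds$images)
  if (!is.null(features)) n <- nrow(features$hog)
  if (n == 0) stop_domain("dataset is empty")
  log <- NULL

  t0 <- proc.time()[3]
  split_seed <- derive_seed(seed, "split")
  splits <- split_dataset(labels, config$split, seed = split_seed)
  log <- stage_log(log, "split", n, length(splits$train), t0, split_seed)

  t0 <- proc.time()[3]
  backbone <- build_backbone(config$backbone, seed = config$backbone_seed)
  if (is.null(features)) {
    if (verbose) message("extracting features for ", n, " images")
    features <- extract_pipeline_features(ds$images, config, backbone, verbose)
  }
  fused <- fuse_features(features$hog, features$deep)
  log <- stage_log(log, "features", n, ncol(fused), t0, config$backbone_seed)

  t0 <- proc.time()[3]
  tr <- splits$train
  scores <- entropy_scores(fused[tr, , drop = FALSE], bins = config$entropy_bins)
  selection <- select_top_k(scores, min(config$select_k, length(scores)))
  Xsel <- apply_selection(fused, selection)
  center <- colMeans(Xsel[tr, , drop = FALSE])
  spread <- apply(Xsel[tr, , drop = FALSE], 2, stats::sd)
  spread[spread == 0] <- 1
  X <- sweep(sweep(Xsel, 2, center, "-"), 2, spread, "/")
  log <- stage_log(log, "select", ncol(fused), ncol(X), t0)

  t0 <- proc.time()[3]
  Xtr <- X[tr, , drop = FALSE]
  ytr <- droplevels(labels[tr])
  rebal <- NULL
  if (isTRUE(config$rebalance)) {
    rebal_seed <- derive_seed(seed, "rebalance")
    rebal <- smote_tomek(Xtr, ytr, k_neighbors = config$smote_k,
                         seed = rebal_seed)
    Xtr <- rebal$X
    ytr <- rebal$y
    log <- stage_log(log, "rebalance", length(tr), nrow(Xtr), t0, rebal_seed)
  }

  t0 <- proc.time()[3]
  tc <- config$train
  tc$seed <- derive_seed(seed, "train")
  head <- train_head(Xtr, ytr, hidden = config$hidden, config = tc)
  log <- stage_log(log, "train", nrow(Xtr), head$n_params, t0, tc$seed)

  t0 <- proc.time()[3]
  te <- splits$test
  probs <- predict(head, X[te, , drop = FALSE], type = "prob")
  pred <- factor(head$levels[max.col(probs, ties.method = "first")],
                 levels = levels(labels))
  cm <- confusion_matrix(labels[te], pred, classes = levels(labels))
  report <- metrics_from_confusion(cm)
  report$auc_macro <- auc_ovr(labels[te], probs)
  report$loss_trace <- head$loss_trace
  log <- stage_log(log, "evaluate", length(te), sum(cm), t0)

  structure(list(config = config, classes = levels(labels),
                 selection = selection, center = center, spread = spread,
                 head = head, backbone = backbone, splits = splits,
                 labels = labels, metrics = report, rebalanced = rebal,
                 features = if (keep_features) features else NULL,
                 log = log, seed = seed),
            class = "dermfuse_fit")
}

# Transform raw feature matrices to the head's input space.
fit_feature_space <- function(object, features) {
  fused <- fuse_features(features$hog, features$deep)
  Xsel <- apply_selection(fused, object$selection)
  sweep(sweep(Xsel, 2, object$center, "-"), 2, object$spread, "/")
}

#' Predict lesion classes for new images
#'
#' Applies the fitted pipeline (same preprocessing, segmentation, feature
#' extraction, selection and scaling) to new images and classifies them
#' with the trained head. Predictions are restricted to the fitted class
#' vocabulary.
#'
#' @param object A `"dermfuse_fit"`.
#' @param newdata A dataset accepted by [dermfuse()] (labels optional), a
#'   list of images, or a precomputed `list(hog =, deep =)`.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted labels or a probability matrix.
#' @export
predict.dermfuse_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.null(newdata$hog) && !is.null(newdata$deep)) {
    features <- newdata
  } else {
    images <- if (is.list(newdata) && is.null(newdata$images) &&
                  !inherits(newdata, c("synthetic_dataset", "manifest"))) {
      newdata
    } else {
      resolve_dataset(newdata)$images
    }
    features <- extract_pipeline_features(images, object$config, object$backbone)
  }
  X <- fit_feature_space(object, features)
  predict(object$head, X, type = type)
}

#' @export
print.dermfuse_fit <- function(x, ...) {
  cat("Dermoscopy feature-fusion classifier\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  features: %d fused -> %d selected; head %d -> %d -> %d\n",
              length(x$selection$scores), x$selection$k,
              x$selection$k, x$config$hidden, length(x$classes)))
  cat(sprintf("  test accuracy %.4f, macro F1 %.4f, macro AUC %.4f\n",
              x$metrics$accuracy, x$metrics$macro["F1"], x$metrics$auc_macro))
  invisible(x)
}

#' @export
summary.dermfuse_fit <- function(object, ...) {
  print(object)
  cat("\nStage log:\n")
  print(object$log, row.names = FALSE)
  cat("\nTest-partition metrics:\n")
  print(object$metrics)
  invisible(object)
}

#' @export
coef.dermfuse_fit <- function(object, ...) {
  list(W1 = object$head$W1, b1 = object$head$b1,
       W2 = object$head$W2, b2 = object$head$b2)
}

#' Plot training loss and the test confusion matrix
#'
#' @param x A `"dermfuse_fit"`.
#' @param which `"loss"`, `"confusion"`, or both.
#' @param ... Passed to the base plotting functions.
#' @export
plot.dermfuse_fit <- function(x, which = c("loss", "confusion"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if ("loss" %in% which) {
    graphics::plot(x$metrics$loss_trace, type = "l", xlab = "epoch",
                   ylab = "cross-entropy", main = "Training loss", ...)
  }
  if ("confusion" %in% which) {
    cm <- x$metrics$confusion
    graphics::image(seq_len(ncol(cm)), seq_len(nrow(cm)),
                    t(cm[rev(seq_len(nrow(cm))), ]),
                    xlab = "predicted", ylab = "true", axes = FALSE,
                    main = "Test confusion", col = grDevices::hcl.colors(32))
    graphics::axis(1, seq_len(ncol(cm)), colnames(cm))
    graphics::axis(2, seq_len(nrow(cm)), rev(rownames(cm)))
  }
  invisible(x)
}

#' Grad-CAM saliency for a fitted pipeline's backbone
#'
#' Convenience wrapper resizing the image to the backbone input and mapping
#' a class label to its backbone output index.
#'
#' @param object A `"dermfuse_fit"`.
#' @param image RGB image (any size).
#' @param target_class Class label (character, matched against the backbone
#'   output order = fitted class order) or integer index; default the
#'   backbone's top class.
#' @return A `"saliency_map"` at the backbone input size.
#' @export
explain_image <- function(object, image, target_class = NULL) {
  stopifnot(inherits(object, "dermfuse_fit"))
  sz <- object$backbone$spec$input_size
  img <- resize_image(image, sz, sz)
  if (is.character(target_class)) {
    target_class <- match(target_class, object$classes)
    if (is.na(target_class)) stop_domain("unknown class label")
  }
  grad_cam(object$backbone, img, target_class)
}
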