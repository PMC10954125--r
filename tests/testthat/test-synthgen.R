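# Synthetic dermoscopy image generator: noise model, geometry, determinism.

test_that("speckle noise has mean one, is seed-deterministic, and vanishes at variance zero", {
  img <- matrix(100, 400, 400)
  expect_identical(add_speckle(img, 0, seed = 1), img)

  noisy <- add_speckle(img, 0.05, seed = 3)
  # law-of-large-numbers check on 160k pixels: sample mean within 1% of 100
  expect_lt(abs(mean(noisy) - 100), 1)
  expect_gt(stats::var(as.numeric(noisy)), 0)

  expect_identical(add_speckle(img, 0.05, seed = 3), noisy)
  expect_false(identical(add_speckle(img, 0.05, seed = 4), noisy))

  expect_error(add_speckle(img, -0.1), "variance")
})

test_that("unperturbed noise-free lesion mask is the exact analytic ellipse", {
  spec <- lesion_spec("MEL", image_size = 64, ellipse_center = c(30, 34),
                      axes = c(14, 9), rotation = 0.4,
                      border_irregularity = 0, hair_count = 0,
                      speckle_var = 0, seed = 11)
  gen <- generate_lesion_image(spec)
  # independent closed-form ellipse membership per pixel center
  expected <- matrix(FALSE, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    dy <- i - 30; dx <- j - 34
    u <- dx * cos(0.4) + dy * sin(0.4)
    v <- -dx * sin(0.4) + dy * cos(0.4)
    expected[i, j] <- (u / 14)^2 + (v / 9)^2 <= 1
  }
  expect_identical(gen$mask, expected)
})

test_that("perturbed-border mask matches a brute-force per-pixel oracle and repeats exactly", {
  spec <- lesion_spec("BCC", image_size = 64, ellipse_center = c(32, 32),
                      axes = c(13, 10), rotation = 1.1,
                      border_irregularity = 0.15, hair_count = 2,
                      speckle_var = 0.05, seed = 5)
  gen <- generate_lesion_image(spec)
  brute <- matrix(FALSE, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    brute[i, j] <- dermfuse:::lesion_membership(i, j, spec)
  }
  expect_identical(gen$mask, brute)
  expect_equal(sum(gen$mask), sum(brute))

  gen2 <- generate_lesion_image(spec)
  expect_identical(gen2$image, gen$image)
  expect_identical(gen2$mask, gen$mask)
})

test_that("an ellipse that does not fit in the frame is rejected", {
  expect_error(lesion_spec("AK", image_size = 64, ellipse_center = c(10, 32),
                           axes = c(15, 10), border_irregularity = 0),
               "fit")
  expect_error(lesion_spec("AK", lesion_intensity_mean = 250,
                           background_mean = 200),
               "darker")
})

test_that("generated datasets honour requested class counts exactly", {
  archive_profile <- c(AK = 440, BCC = 600, BK = 800, DF = 230, MEL = 818,
                       MN = 1510, SCC = 245, VASC = 200)
  ds <- generate_dataset(archive_profile, image_size = 32, seed = 1)
  expect_length(ds$images, 4843)
  expect_identical(as.integer(table(ds$labels)), unname(as.integer(archive_profile)))

  single <- generate_dataset(c(A = 1), image_size = 32, seed = 1)
  expect_length(single$images, 1)

  ds2 <- generate_dataset(c(AK = 3, MEL = 3), image_size = 32, seed = 1)
  ds3 <- generate_dataset(c(AK = 3, MEL = 3), image_size = 32, seed = 2)
  expect_identical(table(ds2$labels), table(ds3$labels))
  expect_false(identical(ds2$images[[1]], ds3$images[[1]]))

  expect_error(generate_dataset(integer(0)), "nonempty")
})

test_that("classes are separable by mean lesion intensity (nearest centroid >= 95%)", {
  ds <- generate_dataset(c(AK = 50, BK = 50, MEL = 50, SCC = 50),
                         image_size = 64, seed = 9)
  mean_int <- vapply(seq_along(ds$images), function(i) {
    g <- to_grayscale(ds$images[[i]])
    mean(g[ds$masks[[i]]])
  }, 0)
  centroids <- tapply(mean_int, ds$labels, mean)
  pred <- names(centroids)[apply(abs(outer(mean_int, centroids, "-")), 1, which.min)]
  expect_gte(mean(pred == as.character(ds$labels)), 0.95)
})

test_that("datasets round-trip through PNG files and a CSV manifest", {
  dir <- tempfile("synthds")
  ds <- generate_dataset(c(MEL = 2, MN = 2), image_size = 32, seed = 4)
  write_dataset(ds, dir)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 4)
  expect_true(all(m$split == "unassigned"))
  img <- read_image_png(m$image_path[1])
  expect_equal(dim(img), c(32, 32, 3))
  # 8-bit PNG quantization: within half a grey level
  expect_lt(max(abs(img - ds$images[[1]])), 0.51)
})
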