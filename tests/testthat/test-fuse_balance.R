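# Fusion, entropy-based selection, SMOTE, Tomek links.

test_that("fusion concatenates HOG-first and preserves widths", {
  expect_equal(as.numeric(fuse(c(1, 2, 3), c(4, 5, 6, 7))), 1:7)
  expect_equal(as.numeric(fuse(rep(0, 3), rep(0, 4))), rep(0, 7))

  f <- fuse(runif(3780), runif(4096))
  expect_length(f, 7876)
  expect_equal(attr(f, "blocks")$deep, c(3781L, 7876L))

  m <- fuse_features(matrix(1, 5, 3), matrix(2, 5, 4))
  expect_equal(dim(m), c(5, 7))
  expect_error(fuse_features(matrix(1, 5, 3), matrix(2, 4, 4)), "rows")
  expect_error(fuse(numeric(0), 1:3), "nonempty")
})

test_that("entropy scores hit the closed-form cases", {
  n <- 256
  X <- cbind(
    constant = rep(3.7, n),
    uniform = seq(0, 1, length.out = n) + 1e-9,  # one sample per bin
    twobin = rep(c(0, 1), each = n / 2)
  )
  s <- entropy_scores(X, bins = 256)
  expect_equal(unname(s["constant"]), 0)
  expect_equal(unname(s["uniform"]), 8)     # log2(256)
  expect_equal(unname(s["twobin"]), 1)      # balanced two-bin split
  expect_true(all(s >= 0))
  expect_error(entropy_scores(matrix(1, 1, 3)), "2 training samples")
})

test_that("top-k selection is rank-faithful with lowest-index tie-breaks", {
  sel <- select_top_k(rep(1, 10), k = 3)
  expect_equal(sel$selected_idx, 1:3)

  set.seed(99)
  sc <- runif(500)
  sel10 <- select_top_k(sc, k = 10)
  oracle <- order(sc, decreasing = TRUE)[1:10]
  expect_equal(sort(sel10$selected_idx), sort(oracle))
  expect_equal(sel10$selected_idx, oracle)

  expect_error(select_top_k(sc, k = 501), "exceeds")

  X <- matrix(rnorm(40), 4, 10)
  expect_equal(apply_selection(X, sel10 <- select_top_k(rep(1, 10), 4)),
               X[, 1:4])
})

test_that("smote grows minority classes to the majority count by convex interpolation", {
  set.seed(1)
  X <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(20, 5), 10, 2))
  y <- rep(c("A", "B"), c(5, 10))
  rb <- smote(X, y, k_neighbors = 3, seed = 2)
  expect_equal(unname(table(rb$y)), array(c(10L, 10L)))
  expect_equal(sum(rb$synthetic), 5)

  # every synthetic row is a convex combination of two real class-A rows
  reals <- X[1:5, ]
  for (i in which(rb$synthetic)) {
    z <- rb$X[i, ]
    found <- FALSE
    for (a in 1:4) for (b in (a + 1):5) {
      d <- reals[b, ] - reals[a, ]
      u <- sum((z - reals[a, ]) * d) / sum(d * d)
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          sqrt(sum((reals[a, ] + u * d - z)^2)) < 1e-9) found <- TRUE
    }
    expect_true(found)
  }

  balanced <- smote(X[1:10, ], rep(c("A", "B"), each = 5), seed = 1)
  expect_equal(nrow(balanced$X), 10)
  expect_false(any(balanced$synthetic))

  expect_identical(smote(X, y, seed = 5)$X, smote(X, y, seed = 5)$X)
  expect_error(smote(X[1:6, ], rep(c("A", "B"), c(1, 5))), "A")
})

test_that("tomek links match the all-pairs mutual-NN oracle", {
  # 1-D worked examples: both mutual cross-class 1-NN pairs are links ...
  X <- matrix(c(0.0, 0.4, 3.0, 3.5), ncol = 1)
  y <- c("A", "B", "A", "B")
  expect_equal(unname(tomek_links(X, y)), unname(naive_tomek(X, y)))
  expect_equal(unname(tomek_links(X, y)), rbind(c(1L, 2L), c(3L, 4L)))
  # ... and exactly one when the second pair shares a class
  X2 <- matrix(c(0.0, 0.4, 3.0, 3.2), ncol = 1)
  y2 <- c("A", "B", "A", "A")
  expect_equal(unname(tomek_links(X2, y2)), matrix(c(1L, 2L), 1))

  far <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2), matrix(rnorm(20, 50, 0.1), 10, 2))
  expect_equal(nrow(tomek_links(far, rep(c("A", "B"), each = 10))), 0)
  expect_equal(nrow(tomek_links(far, rep("A", 20))), 0)

  set.seed(12)
  for (rep in 1:5) {
    Xr <- matrix(rnorm(80), 40, 2)
    yr <- sample(c("A", "B"), 40, replace = TRUE)
    got <- tomek_links(Xr, yr)
    want <- naive_tomek(Xr, yr)
    expect_equal(unname(got), unname(want))
  }
})

test_that("smote_tomek removes both members of every link found after smote", {
  set.seed(3)
  Xsep <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2), matrix(rnorm(30, 9, 0.1), 15, 2))
  ysep <- rep(c("A", "B"), c(5, 15))
  st <- smote_tomek(Xsep, ysep, seed = 4)
  sm <- smote(Xsep, ysep, seed = 4)
  expect_equal(st$X, sm$X)          # no links between separated classes
  expect_equal(nrow(st$removed_pairs), 0)

  # overlapping two-class gaussian toy, n = 40
  set.seed(8)
  Xov <- rbind(matrix(rnorm(30, 0, 1), 15, 2), matrix(rnorm(50, 1, 1), 25, 2))
  yov <- rep(c("A", "B"), c(15, 25))
  smo <- smote(Xov, yov, seed = 6)
  links_oracle <- naive_tomek(smo$X, smo$y)
  sto <- smote_tomek(Xov, yov, seed = 6)
  expect_equal(nrow(sto$X), nrow(smo$X) - 2 * nrow(links_oracle))
  expect_equal(unname(sto$removed_pairs), unname(links_oracle))
})

test_that("an archive-like imbalance profile rebalances to near the majority count", {
  # scaled-down version of the 8-class archival imbalance profile
  counts <- c(44, 60, 80, 23, 82, 151, 25, 20)
  set.seed(10)
  y <- rep(LETTERS[1:8], counts)
  centers <- cbind(cos(2 * pi * (1:8) / 8), sin(2 * pi * (1:8) / 8)) * 10
  X <- centers[as.integer(factor(y)), ] + matrix(rnorm(2 * sum(counts), 0, 0.5),
                                                 sum(counts), 2)
  st <- smote_tomek(X, y, seed = 11)
  final <- table(st$y)
  expect_true(all(abs(final - 151) <= 0.02 * 151))
})
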