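test_that("multilevel Otsu attains the brute-force between-class maximum", {
  set.seed(5)
  for (rep in 1:3) {
    v <- c(rnorm(300, 0.05, 0.02), rnorm(80, 0.5, 0.05), rnorm(40, 0.95, 0.03))
    v <- pmin(pmax(v, 0), 1.2)
    th <- otsu_multithreshold(v, n_classes = 3, n_bins = 32)
    # ties along empty histogram gaps make the argmax non-unique, so the
    # oracle comparison is on the attained criterion value
    expect_equal(bcv3(v, th[1], th[2]), otsu3_bruteforce_value(v, 32),
                 tolerance = 1e-10)
    # thresholds fall in the gaps between the three clusters
    th256 <- otsu_multithreshold(v, n_classes = 3)
    c1 <- v[1:300]; c2 <- v[301:380]; c3 <- v[381:420]
    expect_gt(th256[1], max(c1)); expect_lt(th256[1], min(c2))
    expect_gt(th256[2], max(c2)); expect_lt(th256[2], min(c3))
  }
})

test_that("2-class Otsu behaves and cross-checks against EBImage", {
  set.seed(3)
  v <- c(rep(0, 50), rep(1, 50)) + rnorm(100, 0, 0.01)
  th <- otsu_multithreshold(v, n_classes = 2)
  expect_gt(th, 0.1); expect_lt(th, 0.9)
  expect_error(otsu_multithreshold(rep(1, 10), 3), "distinct values")
  skip_if_not_installed("EBImage")
  img <- matrix(c(runif(200, 0, 0.3), runif(56, 0.7, 1)), 16, 16)
  mine <- otsu_multithreshold(img, n_classes = 2, n_bins = 256)
  ref <- EBImage::otsu(EBImage::Image(img), range = range(img), levels = 256)
  # thresholds may sit anywhere on the criterion plateau; the induced
  # binary classification must agree
  expect_equal(img > mine, img > ref)
})

test_that("8-connected labeling matches a pairwise-adjacency oracle", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(runif(15 * 12) < 0.3, 15, 12)
    lab <- label_components(m)
    expect_equal(lab != 0, m)
    # oracle: two foreground pixels share a label iff connected through a
    # chain of 8-neighbors (transitive closure over the adjacency graph)
    fg <- which(m)
    if (length(fg) < 2) next
    rc <- cbind((fg - 1) %% 15 + 1, (fg - 1) %/% 15 + 1)
    adj <- as.matrix(dist(rc, method = "maximum")) <= 1
    reach <- adj
    for (k in seq_len(length(fg))) reach <- reach | (reach %*% reach > 0)
    same_lab <- outer(lab[fg], lab[fg], "==")
    expect_equal(same_lab, reach > 0, ignore_attr = TRUE)
  }
})

# Paint a disk of the given diameter (um) onto a matrix at 4 um/px.
disk_frame <- function(diams, centers, value = 1, nr = 60, nc = 60, scale = 4,
                       values = NULL) {
  m <- matrix(0, nr, nc)
  for (i in seq_along(diams)) {
    px <- octaflow:::rasterize_disk(centers[[i]], diams[i], c(nr, nc), scale)
    m[px] <- if (is.null(values)) value else values[i]
  }
  m
}

test_that("constructed disks are classified into their diameter bins", {
  # three disks: 8, 16, 28 um -> small, medium, large
  m <- disk_frame(c(8, 16, 28), list(c(40, 40), c(100, 100), c(180, 180)),
                  values = c(0.5, 1, 1))
  m <- m + 0.01 * matrix(runif(60 * 60), 60, 60)  # noise floor well below
  fr <- angiogram_frame(m, scale = 4)
  masks <- segment_vessels(fr)
  truth8 <- disk_frame(8, list(c(40, 40))) > 0
  truth16 <- disk_frame(16, list(c(100, 100))) > 0
  truth28 <- disk_frame(28, list(c(180, 180))) > 0
  expect_true(all(masks$small[truth8]))
  expect_true(all(masks$medium[truth16]))
  expect_true(all(masks$large[truth28]))
  expect_false(any(masks$medium[truth8 | truth28]))
  expect_false(any(masks$large[truth8 | truth16]))
  expect_equal(sort(masks$components$class), sort(c("medium", "large")))
})

test_that("a single 28-um disk yields one large component of that diameter", {
  m <- disk_frame(28, list(c(120, 120)))
  m <- m + 0.005 * matrix(runif(60 * 60), 60, 60)
  masks <- segment_vessels(angiogram_frame(m, scale = 4))
  comp <- masks$components[masks$components$class == "large", ]
  expect_equal(nrow(comp), 1L)
  # equivalent diameter within one pixel-quantization step of truth
  expect_equal(comp$equivalent_diameter_um, 28, tolerance = 4 / 28)
  expect_false(any(masks$medium[disk_frame(28, list(c(120, 120))) > 0]))
})

test_that("masks are pairwise disjoint and scale-invariant", {
  sc <- make_scene(n_small = 20, n_medium = 4, n_large = 3, dim_px = c(48, 64),
                   seed = 13)
  p <- make_protocol(n_repeats_per_frame = 16)
  tr <- simulate_trial_angiograms(p, sc, seed = 1)
  base <- Reduce(`+`, lapply(tr$angiograms[1:9], `[[`, "values")) / 9
  masks <- segment_vessels(angiogram_frame(base, scale = 4))
  expect_false(any(masks$small & masks$medium))
  expect_false(any(masks$small & masks$large))
  expect_false(any(masks$medium & masks$large))
  # global intensity rescaling does not change the classification
  masks2 <- segment_vessels(angiogram_frame(base * 37, scale = 4))
  expect_equal(masks2$small, masks$small)
  expect_equal(masks2$medium, masks$medium)
  expect_equal(masks2$large, masks$large)
  expect_equal(masks2$thresholds, masks$thresholds * 37, tolerance = 1e-6)
  # class assignment matches ground truth away from bin edges
  truth <- scene_truth_mask(sc)
  expect_gt(mean(masks$small[truth == 1]), 0.95)
  expect_gt(mean(masks$medium[truth == 2]), 0.95)
  expect_gt(mean(masks$large[truth == 3]), 0.95)
})

test_that("degenerate frames give empty masks with a warning", {
  expect_warning(masks <- segment_vessels(angiogram_frame(matrix(0, 8, 8), scale = 4)),
                 "constant|empty")
  expect_false(any(masks$small | masks$medium | masks$large))
  expect_equal(nrow(masks$components), 0L)
})

test_that("apply_masks sums per class and matches a loop oracle", {
  small <- medium <- large <- matrix(FALSE, 8, 8)
  small[2:3, 2:3] <- TRUE; medium[6:7, 6] <- TRUE; large[1, 7:8] <- TRUE
  masks <- structure(list(small = small, medium = medium, large = large,
                          components = NULL, thresholds = c(NA, NA), scale = 4),
                     class = "vessel_masks")
  frames <- const_frames(c(2, 3))
  sums <- apply_masks(frames, masks)
  expect_equal(unname(sums[1, "small"]), 2 * sum(masks$small))
  expect_equal(unname(sums[2, "large"]), 3 * sum(masks$large))
  # loop oracle on a random frame
  set.seed(4)
  v <- matrix(runif(64), 8, 8)
  fr2 <- list(angiogram_frame(v, scale = 4))
  s <- apply_masks(fr2, masks)
  oracle <- c(0, 0, 0)
  for (i in 1:8) for (j in 1:8) {
    if (masks$small[i, j]) oracle[1] <- oracle[1] + v[i, j]
    if (masks$medium[i, j]) oracle[2] <- oracle[2] + v[i, j]
    if (masks$large[i, j]) oracle[3] <- oracle[3] + v[i, j]
  }
  expect_equal(unname(s[1, ]), oracle)
  # subadditivity vs whole frame
  expect_lte(sum(s[1, ]), sum(v))
  expect_error(apply_masks(const_frames(1, nr = 5, nc = 5), masks), "geometry")
})
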