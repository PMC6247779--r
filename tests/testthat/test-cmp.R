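test_that("calibration maps concentration to pixel value log-linearly", {
  m <- calibration_model()
  expect_equal(conc_to_pv(0.1, m), 96)
  expect_equal(conc_to_pv(1, m), 160)   # 96 + 64 * log10(10)
  expect_equal(conc_to_pv(10, m), 224)
  expect_error(conc_to_pv(0, m), class = "retcouple_domain_error")
  # round trip on the unclamped domain; monotone
  x <- 10^seq(log10(0.01), log10(30), length.out = 25)
  expect_equal(pv_to_conc(conc_to_pv(x, m), m), x)
  expect_true(all(diff(conc_to_pv(x, m)) > 0))
  # clamping at the 8-bit range
  expect_equal(conc_to_pv(1e6, m), 255)
})

test_that("registration recovers a known injected shift", {
  withr::local_seed(2)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  same <- register_translation(img, img, max_shift_px = 4)
  expect_equal(c(same$dx, same$dy), c(0L, 0L))
  shifted <- shift_image(img, 3, -2)
  r <- register_translation(img, shifted, max_shift_px = 5)
  expect_equal(c(r$dx, r$dy), c(3L, -2L))
  expect_false(r$low_confidence)
  # structureless pair: a shift is still returned but flagged
  noise <- register_translation(matrix(runif(400, 0, 255), 20, 20),
                                matrix(runif(400, 0, 255), 20, 20),
                                max_shift_px = 3)
  expect_true(noise$low_confidence)
  expect_error(register_translation(img, matrix(0, 3, 3)),
               class = "retcouple_format_error")
})

test_that("theme-map clustering recovers well-separated signatures", {
  # three constant regions in two channels, zero noise
  g <- matrix(0, 30, 30)
  e <- matrix(0, 30, 30)
  truth <- matrix(0L, 30, 30)
  g[1:10, ] <- 210; e[1:10, ] <- 100; truth[1:10, ] <- 1L
  g[11:20, ] <- 130; e[11:20, ] <- 200; truth[11:20, ] <- 2L
  g[21:30, ] <- 30; e[21:30, ] <- 200; truth[21:30, ] <- 3L
  stack <- channel_stack(list(gaba = g, glut = e))
  tm <- cluster_theme_map(stack, k = 3, seed = 7)
  # perfect recovery up to label permutation
  tab <- table(truth, tm$labels)
  expect_equal(sum(apply(tab, 1, max)), 900)
  expect_equal(sort(unique(as.vector(tm$labels))), 0:2)
  # determinism under the seed
  tm2 <- cluster_theme_map(stack, k = 3, seed = 7)
  expect_identical(tm$labels, tm2$labels)
  expect_equal(tm$inertia, 0)
  # k = 1 labels everything alike; k too large errors
  expect_true(all(cluster_theme_map(stack, k = 1)$labels == 0))
  expect_error(cluster_theme_map(stack, k = 4),
               class = "retcouple_domain_error")
})

test_that("masked histograms count pixels and peak-normalize", {
  img <- matrix(c(10, 10, 20, 30), 2, 2)
  h <- masked_histogram(img)
  expect_equal(h$count[h$pv == 10], 2)
  expect_equal(h$count[h$pv == 20], 1)
  expect_equal(sum(h$count), 4)
  expect_equal(h$normalized[h$pv == 10], 1)
  expect_equal(h$normalized[h$pv == 20], 0.5)
  # constant image: one bin at 1
  hc <- masked_histogram(matrix(42, 3, 3))
  expect_equal(sum(hc$normalized == 1), 1)
  # empty mask flagged
  he <- masked_histogram(img, mask = matrix(FALSE, 2, 2))
  expect_true(attr(he, "empty"))
  expect_error(masked_histogram(img, mask = matrix(TRUE, 3, 3)),
               class = "retcouple_format_error")
})

test_that("GABA segmentation follows the half-open boundary convention", {
  m <- calibration_model()
  pv <- matrix(conc_to_pv(c(0.05, 0.1, 0.5, 1, 5, 20), m), 1)
  seg <- segment_gaba_classes(pv, m)
  expect_equal(as.vector(seg), c(1L, 2L, 2L, 3L, 3L, 3L))
  expect_error(segment_gaba_classes(pv, m, thresholds_mM = c(1, 0.1, 10)),
               class = "retcouple_domain_error")
})

test_that("colocalization mapping places channels on RGB planes", {
  stack <- channel_stack(list(
    "γ" = matrix(100, 2, 2), E = matrix(200, 2, 2)))
  rgb <- colocalization_rgb(stack, "γE::yb")
  expect_equal(rgb[1, 1, ], c(100, 100, 200))
  # identity mapping per plane
  rgb2 <- colocalization_rgb(stack, "γE::rb")
  expect_equal(rgb2[2, 2, ], c(100, 0, 200))
  # all-zero channels give black
  z <- channel_stack(list(a = matrix(0, 2, 2)))
  expect_true(all(colocalization_rgb(z, "a::g") == 0))
  expect_error(colocalization_rgb(stack, "γQ::yb"),
               class = "retcouple_vocabulary_error")
  expect_error(colocalization_rgb(stack, "γE::yq"),
               class = "retcouple_vocabulary_error")
})

test_that("object counting finds 8-connected components above a size cut", {
  lab <- matrix(0L, 40, 40)
  # two disjoint discs of the target label
  for (ctr in list(c(10, 10), c(30, 30))) {
    for (r in 1:40) for (c in 1:40) {
      if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 36) lab[r, c] <- 2L
    }
  }
  obj <- count_objects(lab, 2L)
  expect_equal(nrow(obj), 2)
  expect_equal(obj$area_px[1], obj$area_px[2])
  expect_equal(sort(round(obj$centroid_x)), c(10, 30))
  # diagonal touching merges under 8-connectivity
  diag2 <- matrix(0L, 4, 4)
  diag2[1, 1] <- 1L
  diag2[2, 2] <- 1L
  expect_equal(nrow(count_objects(diag2, 1L)), 1)
  # size filter removes everything when too strict
  expect_equal(nrow(count_objects(lab, 2L, min_area_px = 1e5)), 0)
})

test_that("separability contrasts histogram pairs", {
  a <- masked_histogram(matrix(c(10, 10, 20, 20), 2, 2))
  expect_equal(separability(a, a), list(ks_D = 0, overlap = 1))
  b <- masked_histogram(matrix(c(200, 200, 210, 210), 2, 2))
  s <- separability(a, b)
  expect_equal(s$ks_D, 1)
  expect_equal(s$overlap, 0)
  empty <- masked_histogram(matrix(5, 1, 1), mask = matrix(FALSE, 1, 1))
  expect_error(separability(a, empty), class = "retcouple_domain_error")
})

test_that("channel images survive a PNG round trip", {
  skip_if_not_installed("png")
  img <- matrix(round(runif(100, 0, 255)), 10, 10)
  path <- withr::local_tempfile(fileext = ".png")
  write_channel(img, path)
  expect_equal(read_channel(path), img)
})
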