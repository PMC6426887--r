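test_that("ASF equals the composition of brute-force opening and closing", {
  cst <- gray_image(matrix(0.4, 16, 16))
  expect_equal(asf_filter(cst)$pixels, cst$pixels)

  # a single-pixel impulse is erased by the first opening
  imp <- matrix(0, 16, 16); imp[8, 8] <- 1
  out <- asf_filter(gray_image(imp), vincent_params(asf_max_radius = 1))
  expect_true(all(out$pixels == 0))

  set.seed(31)
  px <- matrix(runif(16 * 16), 16, 16)
  ref <- px
  for (r in 1:2) ref <- bf_close(bf_open(ref, disc_se(r)), disc_se(r))
  got <- asf_filter(gray_image(px), vincent_params(asf_max_radius = 2))
  expect_equal(got$pixels, ref, tolerance = 1e-12)

  # radius sequence of length 1 is exactly close(open(img))
  got1 <- asf_filter(gray_image(px), vincent_params(asf_max_radius = 1))
  expect_equal(got1$pixels, bf_close(bf_open(px, disc_se(1)), disc_se(1)),
               tolerance = 1e-12)
})

test_that("h-dome matches the closed form for isolated peaks", {
  h <- 0.3
  # constant image: the reconstruction is the constant minus h, so the
  # dome is h everywhere (and carries no regional-maximum marker)
  cst <- matrix(0.5, 15, 15)
  expect_true(all(hdome(gray_image(cst), vincent_params(hdome_h = h)) == h))

  # peak taller than h: dome of height exactly h over the peak support,
  # zero on the background (the clipped peak floods the background)
  pk <- matrix(0.1, 21, 21)
  pk[10:12, 10:12] <- 0.8
  dome <- hdome(gray_image(pk), vincent_params(hdome_h = h))
  expect_equal(max(dome), h, tolerance = 1e-12)
  expect_equal(dome[11, 11], h, tolerance = 1e-12)
  expect_true(all(dome[pk == 0.1] == 0))

  # peak of height H <= h: the reconstruction is the global max minus h,
  # so the dome over the peak rises exactly H above the dome's background
  pk2 <- matrix(0.1, 21, 21)
  pk2[10:12, 10:12] <- 0.3
  dome2 <- hdome(gray_image(pk2), vincent_params(hdome_h = h))
  expect_equal(max(dome2) - dome2[1, 1], 0.2, tolerance = 1e-12)
  expect_equal(max(dome2), h, tolerance = 1e-12)

  # anti-extensive and bounded by h on random images (oracle equivalence)
  set.seed(33)
  px <- matrix(runif(18 * 18), 18, 18)
  d <- hdome(gray_image(px), vincent_params(hdome_h = 0.25))
  expect_equal(d, bf_hdome(px, 0.25), tolerance = 1e-12)
  expect_true(all(d >= -1e-12 & d <= 0.25 + 1e-12))
})

test_that("marker extraction finds isolated peaks and rejects constants", {
  two <- matrix(0.1, 30, 30)
  two[8:10, 8:10] <- 0.8
  two[20:23, 20:23] <- 0.7
  mk <- vincent_markers(gray_image(two),
                        vincent_params(hdome_h = 0.2, min_marker_px = 3))
  expect_equal(max(mk$markers), 2)
  expect_equal(n_centroids(mk$centroids), 2)

  cst <- gray_image(matrix(0.4, 20, 20))
  mk0 <- vincent_markers(cst)
  expect_equal(max(mk0$markers), 0)
  expect_equal(n_centroids(mk0$centroids), 0)
})

test_that("regional maxima agree with the brute-force plateau definition", {
  set.seed(35)
  for (i in 1:10) {
    px <- matrix(sample(seq(0, 1, by = 0.1), 14 * 14, replace = TRUE), 14, 14)
    got <- regional_maxima(px, conn = 8L) > 0
    expect_equal(got, bf_regional_maxima_mask(px, 8))
  }
})

test_that("watershed regions equal marker count and split a flat relief", {
  px <- matrix(0.5, 31, 31)
  markers <- matrix(0L, 31, 31)
  markers[6, 16] <- 1L; markers[26, 16] <- 2L
  lab <- marker_watershed(px, markers)
  expect_true(all(lab[1:15, ] %in% c(0L, 1L)))
  expect_true(all(lab[17:31, ] %in% c(0L, 2L)))
  expect_equal(sum(lab == 0), 31)

  smp <- quick_mosaic(width = 120, height = 120, target_density = 2500,
                      seed = 41)
  seg <- vincent_segment(smp$image)
  expect_equal(length(unique(seg$cell_regions[seg$cell_regions > 0])),
               n_centroids(seg$centroids))
  # full-frame partition after line assignment
  expect_true(all(seg$cell_regions > 0))
})

test_that("marker counts track the true cell count on a clean mosaic", {
  # low-noise fixture; the +/-20% band documents the tolerance of the
  # marker count under the default h
  for (sd in c(43, 44)) {
    smp <- quick_mosaic(width = 200, height = 200, target_density = 2000,
                        noise_sigma = 0.02, jitter = 0.1, seed = sd)
    f <- asf_filter(smp$image)
    mk <- vincent_markers(f)
    n_true <- n_centroids(smp$truth_centroids)
    expect_gt(n_centroids(mk$centroids), 0.8 * n_true)
    expect_lt(n_centroids(mk$centroids), 1.2 * n_true)
  }
})

test_that("vincent over-detects in unreadable regions", {
  smp <- quick_mosaic(width = 160, height = 160, target_density = 2500,
                      blur_region_fraction = 0.5, seed = 45)
  seg <- vincent_segment(smp$image)
  in_blur <- sum(seg$centroids$points$y >= 160 * 0.5)
  expect_gt(in_blur, 0)
})
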