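test_that("image normalization rescales deep images and passes 8-bit through", {
  img16 <- matrix(c(0, 65535, 32767, 1000), 2, 2)
  norm <- normalize_image(img16)
  expect_equal(range(norm), c(0, 255))
  expect_equal(norm[2, 1], 255)
  expect_equal(norm[1, 2], 32767 / 257, tolerance = 1e-3)
  img8 <- matrix(c(0, 255, 15, 100), 2, 2)
  expect_identical(normalize_image(img8), img8)
  expect_warning(norm_const <- normalize_image(matrix(5, 3, 3)), "constant")
  expect_identical(norm_const, matrix(5, 3, 3))
})

test_that("spot detection finds isolated Gaussian peaks and nothing on blanks", {
  expect_equal(nrow(detect_spots(matrix(0, 60, 60))$spots), 0)

  centers <- list(c(20, 20), c(20, 60), c(20, 100), c(60, 20), c(60, 60),
                  c(60, 100), c(100, 60))
  img <- render_spots(centers, dim = c(120, 120), amplitude = 200, sd = 2)
  det <- detect_spots(img)
  expect_equal(nrow(det$spots), 7)
  # centroids land on the rendered centres
  found <- det$spots[order(det$spots$row, det$spots$col), ]
  truth <- do.call(rbind, centers)
  truth <- truth[order(truth[, 1], truth[, 2]), ]
  expect_true(all(abs(found$row - truth[, 1]) < 1.5))
  expect_true(all(abs(found$col - truth[, 2]) < 1.5))
})

test_that("the minimum-area filter removes single-pixel flashes", {
  img <- matrix(0, 50, 50)
  img[25, 25] <- 255
  # after sd-3 smoothing a lone pixel's peak is far below threshold, and
  # with a permissive threshold its area is still tiny; both paths kill it
  det <- detect_spots(img)
  expect_equal(nrow(det$spots), 0)
  det2 <- detect_spots(img, spot_call_params(fixed_threshold = 1,
                                             min_area = 4))
  # area filter alone must remove a component smaller than min_area
  big_enough <- det2$spots$area >= 4
  expect_true(all(big_enough))
})

test_that("raising the fixed threshold never increases a cell's spot count", {
  sim <- gen_fish_image(fish_sim_config(n_nuclei = 6, canvas = c(600, 600),
                                        seed = 21, noise_sd = 3))
  img <- normalize_image(sim$image)
  prev <- NULL
  for (thr in c(10, 15, 25, 40)) {
    det <- detect_spots(img, spot_call_params(fixed_threshold = thr))
    counts <- count_spots_per_cell(det, sim$mask)$spot_count
    if (!is.null(prev)) expect_true(all(counts <= prev))
    prev <- counts
  }
})

test_that("spots are assigned to cells by centroid containment", {
  mask <- matrix(0L, 40, 80)
  mask[5:35, 5:35] <- 1L
  mask[5:35, 45:75] <- 2L
  spots <- tibble::tibble(
    row = c(rep(20, 6), rep(20, 5), 38),
    col = c(seq(6, 31, by = 5), seq(46, 66, by = 5), 40))
  out <- count_spots_per_cell(spots, mask)
  expect_equal(out$spot_count[out$cell_id == 1], 6)
  expect_equal(out$spot_count[out$cell_id == 2], 5)
  expect_true(out$amplified[out$cell_id == 1])   # 6 > 5
  expect_false(out$amplified[out$cell_id == 2])  # 5 is not > 5
  # the (38, 40) spot centroid is on background: counted for no cell
  expect_equal(sum(out$spot_count), 11)
  expect_equal(nrow(count_spots_per_cell(spots, matrix(0L, 40, 80))), 0)
})

test_that("counts depend on the mask only through centroid label lookup", {
  sim <- gen_fish_image(fish_sim_config(n_nuclei = 5, canvas = c(520, 520),
                                        seed = 31))
  det <- detect_spots(normalize_image(sim$image))
  base <- count_spots_per_cell(det, sim$mask)
  # permute label ids: counts permute identically
  perm <- c(3L, 5L, 1L, 2L, 4L)
  mask2 <- sim$mask
  mask2[sim$mask > 0L] <- perm[sim$mask[sim$mask > 0L]]
  permuted <- count_spots_per_cell(det, mask2)
  expect_equal(permuted$spot_count[match(perm, permuted$cell_id)],
               base$spot_count)
})

test_that("per-cell counts match generator truth exactly without noise", {
  for (s in c(41, 42)) {
    sim <- gen_fish_image(fish_sim_config(seed = s))
    counts <- count_spots_per_cell(detect_spots(normalize_image(sim$image)),
                                   sim$mask)
    expect_equal(counts$spot_count, sim$truth$spot_count)
  }
})

test_that("heterogeneity comparison reports location, scale and amplified fraction", {
  ref <- rep(c(2, 3), 25)
  ident <- compare_heterogeneity(list(same = ref), ref)
  expect_equal(ident$tests$levene_statistic, 0)
  expect_gt(ident$tests$ranksum_p, 0.9)

  bimodal <- rep(c(2, 30), 25)
  het <- compare_heterogeneity(list(tumor = bimodal), rep(2, 50))
  expect_lt(het$tests$ranksum_p, 0.01)
  expect_lt(het$tests$levene_p, 0.01)
  expect_equal(
    het$summary$frac_amplified[het$summary$sample == "tumor"], 0.5)

  expect_equal(
    compare_heterogeneity(list(x = c(2, 2, 8, 9)), c(2, 2, 3, 3)
                          )$summary$frac_amplified[1], 0.5)
  expect_error(compare_heterogeneity(list(x = 1), c(1, 2)), "at least 2")
})

test_that("the Levene statistic agrees with the car implementation", {
  set.seed(77)
  for (i in 1:5) {
    a <- rpois(40, 4) + rnorm(40, 0, 0.3)
    b <- rpois(35, 4) * sample(1:2, 35, replace = TRUE)
    mine <- levene_test(list(a, b), center = mean)
    vals <- c(a, b)
    grp <- factor(rep(c("a", "b"), c(40, 35)))
    ref <- car::leveneTest(vals ~ grp, center = mean)
    expect_equal(mine$statistic, ref[["F value"]][1])
    expect_equal(mine$p.value, ref[["Pr(>F)"]][1])
  }
})

test_that("fallback segmentation labels disjoint bright disks", {
  set.seed(5)
  img <- matrix(0, 400, 400)
  centers <- expand.grid(row = c(60, 200, 340), col = c(60, 200, 340))
  centers <- centers[1:9, ]
  for (i in seq_len(9)) {
    d2 <- outer((1:400 - centers$row[i])^2, (1:400 - centers$col[i])^2, "+")
    img[d2 <= 30^2] <- 200
  }
  mask <- fallback_segment(img + rnorm(160000, 0, 3))
  expect_equal(max(mask), 9)
  expect_equal(max(fallback_segment(matrix(0, 100, 100))), 0)
})

test_that("images and masks round-trip through TIFF and PNG", {
  sim <- gen_fish_image(fish_sim_config(n_nuclei = 3, canvas = c(300, 300),
                                        seed = 51))
  tf <- withr::local_tempfile(fileext = ".tif")
  write_fish_image(sim$image, tf, bits = 8)
  expect_equal(read_fish_image(tf), sim$image, ignore_attr = TRUE)
  mf <- withr::local_tempfile(fileext = ".tif")
  write_fish_image(sim$mask, mf, bits = 16)
  expect_equal(read_fish_image(mf), sim$mask, ignore_attr = TRUE)
})
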