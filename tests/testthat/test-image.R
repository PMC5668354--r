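test_that("disk segmentation recovers the analytic area", {
  img <- make_disk_image(50, pixel_size = 0.2)
  seg <- segment_midplane(img)
  expect_equal(seg$A_m_um2, pi * 10^2, tolerance = 0.02)
  # centroid sits at the disk center (0-based)
  n <- nrow(img$channels[[1]])
  expect_equal(unname(seg$centroid), rep((n + 1) / 2 - 1, 2), tolerance = 0.5)
  # area error stays inside the boundary-discretization bound, which itself
  # shrinks like perimeter/area ~ 1/radius
  radii <- c(20, 40, 80)
  errs <- sapply(radii, function(rad) {
    s <- segment_midplane(make_disk_image(rad, pixel_size = 0.2))
    abs(s$A_m_um2 - pi * (rad * 0.2)^2) / (pi * (rad * 0.2)^2)
  })
  expect_true(all(errs < 0.02))
  expect_true(all(errs < 1.5 / radii))
})

test_that("segmentation keeps the largest object and rejects blank images", {
  n <- 201
  d_main <- sqrt(outer((1:n - 101)^2, (1:n - 101)^2, "+"))
  d_small <- sqrt(outer((1:n - 30)^2, (1:n - 30)^2, "+"))
  m <- matrix(0, n, n)
  m[d_main <= 50] <- 100
  m[d_small <= 20] <- 100
  seg <- segment_midplane(midplane_image(m, 0.2))
  expect_equal(seg$A_m_um2, pi * 10^2, tolerance = 0.02)   # larger disk only
  expect_error(segment_midplane(midplane_image(matrix(0, 64, 64), 0.2)),
               class = "mitomech_no_cell")
})

test_that("cortical ratio is 1 for uniform cells and recovers ring contrast", {
  uni <- make_disk_image(50, pixel_size = 0.2)
  seg <- segment_midplane(uni)
  expect_equal(cortical_ratio(uni, seg)$ratio, 1, tolerance = 1e-6)

  cell <- simulate_confined_cell(true_cell_params(MLR_true = 2), seed = 1)
  seg2 <- segment_midplane(cell$image, "membrane")
  cr <- cortical_ratio(cell$image, seg2, "myosin")
  expect_equal(cr$ratio, 2, tolerance = 0.05)
  # gain invariance: scaling all pixels (background included) cancels
  scaled <- midplane_image(lapply(cell$image$channels, function(m) 3 * m),
                           cell$image$pixel_size)
  cr3 <- cortical_ratio(scaled, segment_midplane(scaled, "membrane"), "myosin")
  expect_equal(cr3$ratio, cr$ratio, tolerance = 1e-6)
})

test_that("localization ratios track truth over a grid, also under noise", {
  for (mlr in c(1.0, 1.5, 2.0, 3.0)) {
    cell <- simulate_confined_cell(true_cell_params(MLR_true = mlr), seed = 3)
    seg <- segment_midplane(cell$image, "membrane")
    expect_equal(cortical_ratio(cell$image, seg, "myosin")$ratio, mlr,
                 tolerance = 0.05)
  }
  # Poisson counts around 100 give SNR 10 in the cytoplasm
  cell <- simulate_confined_cell(true_cell_params(MLR_true = 2),
                                 seed = 5, poisson_image = TRUE)
  seg <- segment_midplane(cell$image, "membrane")
  expect_equal(cortical_ratio(cell$image, seg, "myosin")$ratio, 2,
               tolerance = 0.10)
})

test_that("the ratio is stable in the number of rays on symmetric cells", {
  cell <- simulate_confined_cell(true_cell_params(MLR_true = 2), seed = 1)
  seg <- segment_midplane(cell$image, "membrane")
  r48 <- cortical_ratio(cell$image, seg, "myosin", n_rays = 48)$ratio
  r96 <- cortical_ratio(cell$image, seg, "myosin", n_rays = 96)$ratio
  expect_equal(r48, r96, tolerance = 0.01)
  expect_error(cortical_ratio(cell$image, seg, "myosin", n_rays = 4),
               class = "mitomech_invalid_input")
})

test_that("quantify_midplane emits one tidy row per channel", {
  cell <- simulate_confined_cell(true_cell_params(), seed = 2)
  out <- quantify_midplane(cell$image, channels = c("myosin", "actin"),
                           seg_channel = "membrane", cell_id = "c1")
  expect_equal(nrow(out), 2)
  expect_setequal(out$channel, c("myosin", "actin"))
  expect_equal(out$ratio[out$channel == "myosin"], 2, tolerance = 0.05)
  expect_equal(out$ratio[out$channel == "actin"], 1.5, tolerance = 0.05)
})

test_that("midplane images round-trip through 16-bit TIFF", {
  dir <- withr::local_tempdir()
  cell <- simulate_confined_cell(true_cell_params(), seed = 4)
  path <- file.path(dir, "cell.tif")
  write_midplane_tiff(cell$image, path)
  back <- read_midplane_tiff(path, pixel_size = cell$image$pixel_size,
                             channel_labels = names(cell$image$channels))
  expect_equal(names(back$channels), c("membrane", "myosin", "actin"))
  expect_equal(back$channels$myosin, cell$image$channels$myosin,
               tolerance = 1e-6, ignore_attr = TRUE)
})
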