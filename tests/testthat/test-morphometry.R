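test_that("indices follow the area definitions", {
  img <- tissue_image(array(1, c(100, 100, 3)), 1)
  nuc <- matrix(FALSE, 100, 100); nuc[1:30, 1:100] <- TRUE
  m <- segmentation_masks(nuc, !nuc, nuclei_count = 10)
  idx <- compute_indices(m, img)
  expect_equal(idx$xnc, 0.3)
  expect_equal(idx$xcs, 1000)

  all_nuc <- segmentation_masks(matrix(TRUE, 100, 100),
                                matrix(FALSE, 100, 100), nuclei_count = 1)
  expect_equal(compute_indices(all_nuc, img)$xnc, 1)

  none <- segmentation_masks(matrix(FALSE, 100, 100),
                             matrix(TRUE, 100, 100), nuclei_count = 0)
  expect_error(compute_indices(none, img), class = "abebnct_domain_error")
})

test_that("nuclei are counted as 8-connected components with area filtering", {
  size <- 120
  mask <- matrix(FALSE, size, size)
  centres <- expand.grid(x = c(12, 36, 60, 84, 108), y = c(30, 80))
  for (i in 1:10) {
    mask <- mask | disc_mask(size, centres$x[i], centres$y[i], 6)
  }
  m <- segmentation_masks(mask, matrix(FALSE, size, size))
  expect_equal(count_nuclei(m, min_area_um2 = 4, microns_per_pixel = 1), 10)

  # two overlapping discs merge into one component
  blob <- disc_mask(size, 30, 100, 7) | disc_mask(size, 38, 100, 7)
  expect_equal(count_nuclei(segmentation_masks(blob, matrix(FALSE, size, size)),
                            4, 1), 1)

  # diagonal contact joins components under 8-connectivity
  diag2 <- matrix(FALSE, 10, 10)
  diag2[3, 3] <- TRUE; diag2[4, 4] <- TRUE
  expect_equal(count_nuclei(segmentation_masks(diag2, matrix(FALSE, 10, 10)),
                            0, 1), 1)

  # the area filter drops specks
  speck <- disc_mask(size, 60, 60, 6)
  speck[1, 1] <- TRUE
  expect_equal(count_nuclei(segmentation_masks(speck, matrix(FALSE, size, size)),
                            4, 1), 1)
})

test_that("stereological cell diameters reproduce the reference values", {
  expect_equal(printed(estimate_cell_diameter(108), 1), 14.9)
  expect_equal(printed(estimate_cell_diameter(202), 1), 20.4)
  expect_equal(printed(estimate_cell_diameter(123), 1), 15.9)
  expect_error(estimate_cell_diameter(0), class = "abebnct_domain_error")
  # alternative convention is available and differs
  expect_gt(estimate_cell_diameter(108),
            estimate_cell_diameter(108, convention = "profile-area"))
})

test_that("cell diameter scales as the square root of the index", {
  xcs <- c(20, 74.5, 108, 146, 202, 400)
  expect_identical(estimate_cell_diameter(4 * xcs),
                   2 * estimate_cell_diameter(xcs))
  expect_true(all(diff(estimate_cell_diameter(xcs)) > 0))
})

test_that("nucleus diameter uses the cube-root volume relation", {
  expect_equal(printed(estimate_nucleus_diameter(18.5, 0.347), 1), 13.0)
  expect_equal(printed(estimate_nucleus_diameter(15.9, 0.407), 1), 11.8)
  expect_equal(estimate_nucleus_diameter(17.3, 1), 17.3)
  expect_error(estimate_nucleus_diameter(10, 0), class = "abebnct_domain_error")
  expect_error(estimate_nucleus_diameter(10, 1.2), class = "abebnct_domain_error")
  for (xnc in seq(0.05, 1, by = 0.05)) {
    expect_lte(estimate_nucleus_diameter(14, xnc), 14)
  }
})

test_that("estimated diameters track the measured in-vivo diameters", {
  tab <- tumor_reference_data()
  t4 <- tumor_reference_data("diameters_in_vitro")
  m <- merge(tab, t4, by = "name")
  expect_gt(cor(estimate_cell_diameter(m$xcs), m$cell_diameter_in_vivo_um),
            0.98)
})

test_that("colour segmentation recovers the ground-truth nuclear fraction", {
  st <- generate_tissue_image(seed = 7, target_xnc = 0.5)
  masks <- segment_by_color(st$image)
  frac <- sum(masks$nuclei_mask) / sum(st$image$region_mask)
  expect_lt(abs(frac - st$truth$achieved_xnc), 0.02)
  expect_equal(masks$nuclei_count, st$truth$n_cells)
})

test_that("an all-cytoplasm image yields an empty nuclei mask with a warning", {
  px <- array(0, c(40, 40, 3))
  px[, , 1] <- 0.93; px[, , 2] <- 0.62; px[, , 3] <- 0.72
  img <- tissue_image(px, 1)
  expect_warning(masks <- segment_by_color(img), "single class")
  expect_equal(sum(masks$nuclei_mask), 0)
  expect_equal(masks$nuclei_count, 0L)
})

test_that("supplied masks bypass segmentation unchanged", {
  st <- generate_tissue_image(seed = 21, target_xnc = 0.4, n_cells = 30,
                              mean_cell_radius = 5, image_size = 256)
  df <- morphometry_from_image(st$image, masks = st$masks)
  expect_equal(df$xnc, st$truth$achieved_xnc)
  expect_equal(df$xcs_um2, st$truth$xcs)
  expect_equal(df$nuclei_count, st$truth$n_cells)
})

test_that("the N/C ratio is scale invariant", {
  st <- generate_tissue_image(seed = 5, n_cells = 30, mean_cell_radius = 5,
                              image_size = 256)
  base <- compute_indices(segment_by_color(st$image), st$image)
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                      rep(seq_len(ncol(m)), each = 2)]
  px2 <- array(0, c(512, 512, 3))
  for (ch in 1:3) px2[, , ch] <- up(st$image$pixels[, , ch])
  img2 <- tissue_image(px2, st$image$microns_per_pixel / 2,
                       region_mask = up(st$image$region_mask))
  scaled <- compute_indices(segment_by_color(img2), img2)
  expect_lt(abs(scaled$xnc - base$xnc), 0.01)
})
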