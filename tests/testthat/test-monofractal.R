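test_that("scale grids are powers of two capped at 45% of the short side", {
  expect_equal(make_scales(c(512, 512)), c(2L, 4L, 8L, 16L, 32L, 64L, 128L))
  expect_equal(make_scales(c(100, 80)), c(2L, 4L, 8L, 16L, 32L))
  expect_error(make_scales(c(10, 10)), class = "histofract_config_error")
  expect_equal(make_scales(c(243, 243), base = 3), c(3L, 9L, 27L, 81L))
})

test_that("binary box counts reproduce exact tilings and degenerate cases", {
  blk <- matrix(TRUE, 8, 8)
  s <- box_counts_binary(bin_image(blk), scales = c(2L, 4L))
  expect_equal(s$count, c(16L, 4L))

  solo <- matrix(FALSE, 32, 32)
  solo[17, 9] <- TRUE
  s1 <- box_counts_binary(bin_image(solo), scales = c(2L, 4L, 8L))
  expect_equal(s1$count, c(1L, 1L, 1L))

  expect_error(
    box_counts_binary(bin_image(matrix(FALSE, 16, 16)), scales = c(2L, 4L, 8L)),
    class = "histofract_degenerate_error"
  )
})

test_that("binary box counts and mass statistics match the brute-force oracle", {
  for (seed in 1:4) {
    mask <- seeded_mask(32, 0.3, seed)
    s <- box_counts_binary(bin_image(mask), scales = c(2L, 3L, 5L, 8L))
    for (i in seq_along(s$scale)) {
      o <- oracle_box_counts(mask, s$scale[i])
      expect_equal(s$count[i], o$count)
      expect_equal(sort(s$masses[[i]]), sort(o$masses))
      expect_equal(s$mean_mass[i], mean(o$all_masses))
      expect_equal(s$sd_mass[i], sqrt(mean(o$all_masses^2) - mean(o$all_masses)^2))
    }
  }
})

test_that("DBC matches its hand-worked cell count and the brute-force oracle", {
  # 256x256, eps = 2 -> h = 2; a box spanning 0..255 contributes 128 cells
  img <- matrix(128L, 256, 256)
  img[1, 1] <- 0L
  img[2, 2] <- 255L
  s <- dbc_counts_gray(img, scales = c(2L, 4L, 8L))
  expect_equal(s$masses[[1]][1], 128)
  expect_equal(s$count[1], 128 + (128^2 - 1))

  for (seed in 1:3) {
    g <- seeded_gray(64, seed)
    s <- dbc_counts_gray(g, scales = c(2L, 5L, 8L, 16L))
    for (i in seq_along(s$scale)) {
      expect_equal(sort(s$masses[[i]]), sort(oracle_dbc(g, s$scale[i])))
    }
  }
})

test_that("constant grayscale images give one DBC cell per box (flat surface)", {
  img <- matrix(77L, 64, 64)
  s <- dbc_counts_gray(img, scales = c(2L, 4L, 8L))
  expect_equal(s$count, s$n_boxes)
  expect_equal(fit_dimension(s)$fd, 2, tolerance = 1e-12)
})

test_that("log-log fits recover the dimensions of a filled square and a line", {
  sq <- box_counts_binary(bin_image(matrix(TRUE, 8, 8)), scales = c(2L, 4L, 8L))
  f <- fit_dimension(sq)
  expect_equal(f$fd, 2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  line <- matrix(FALSE, 64, 64)
  line[32, ] <- TRUE
  f2 <- fit_dimension(box_counts_binary(bin_image(line)))
  expect_equal(f2$fd, 1, tolerance = 1e-12)

  expect_error(
    fit_dimension(tibble::tibble(scale = c(2L, 4L), count = c(4L, 1L))),
    class = "histofract_degenerate_error"
  )
})

test_that("the Sierpinski triangle's dimension is recovered within tolerance", {
  tri <- gen_mask(image_spec("sierpinski_triangle", 512, depth = 7))
  fd <- fit_dimension(box_counts_binary(tri$mask))$fd
  expect_lt(abs(fd - log(3) / log(2)), 0.05)
})

test_that("lacunarity is zero for homogeneous tilings and matches the oracle", {
  full <- box_counts_binary(bin_image(matrix(TRUE, 16, 16)), scales = c(2L, 4L, 8L))
  expect_equal(lacunarity(full), 0)

  # half the boxes full, half empty at eps = 2 -> (sd/mu)^2 = 1 at that scale
  half <- matrix(FALSE, 16, 16)
  half[, 1:8] <- TRUE
  s <- box_counts_binary(bin_image(half), scales = c(2L))
  expect_equal((s$sd_mass / s$mean_mass)^2, 1)

  for (seed in 1:3) {
    mask <- seeded_mask(32, 0.4, seed)
    scl <- c(2L, 4L, 8L)
    s <- box_counts_binary(bin_image(mask), scl)
    expect_equal(lacunarity(s), oracle_lacunarity(mask, scl))
  }
})

test_that("box counts are monotone in scale and in added foreground, fd <= 2", {
  for (seed in 1:6) {
    mask <- seeded_mask(48, runif(1, 0.05, 0.6), seed)
    s <- box_counts_binary(bin_image(mask))
    expect_true(all(diff(s$count) <= 0))
    expect_lte(fit_dimension(s)$fd, 2 + 1e-9)

    grown <- mask
    set.seed(seed + 50)
    grown[sample(length(grown), 100)] <- TRUE
    s2 <- box_counts_binary(bin_image(grown), s$scale)
    expect_true(all(s2$count >= s$count))
  }
})

test_that("binary fd is invariant under translation by the largest box size", {
  base <- matrix(FALSE, 256, 256)
  blob <- gen_clusters(image_spec("blob_clusters", 128, density = 0.3, seed = 3))$mask
  base[1:128, 1:128] <- unclass(blob)[, ]
  shifted <- matrix(FALSE, 256, 256)
  shifted[65:192, 65:192] <- unclass(blob)[, ] # shift by 64 = largest eps
  f1 <- fit_dimension(box_counts_binary(bin_image(base)))
  f2 <- fit_dimension(box_counts_binary(bin_image(shifted)))
  expect_equal(f1$fd, f2$fd, tolerance = 1e-12)
})

test_that("monofractal_features returns both modalities with sane ranges", {
  cl <- gen_clusters(image_spec("blob_clusters", 128, density = 0.3, seed = 5))
  mf <- monofractal_features(cl$gray, cl$mask)
  expect_equal(mf$modality, c("binary", "grayscale"))
  expect_true(mf$fd[1] > 0 && mf$fd[1] <= 2)
  expect_true(mf$fd[2] >= 2 && mf$fd[2] <= 3)
  expect_true(all(mf$lacunarity >= 0))
  expect_true(all(mf$r2_fd > 0.9))

  # checkerboard at box scale: every box occupied at every eps -> fd = 2
  chk <- outer(1:64, 1:64, function(i, j) (i + j) %% 2 == 0)
  expect_equal(fit_dimension(box_counts_binary(bin_image(chk)))$fd, 2, tolerance = 1e-12)
})

test_that("rougher fBm surfaces give higher DBC dimensions within (2, 3)", {
  fds <- sapply(c(0.2, 0.8), function(h) {
    g <- gen_gray(image_spec("fbm_surface", 128, hurst = h, seed = 11))$image
    fit_dimension(dbc_counts_gray(g))$fd
  })
  expect_gt(fds[1], fds[2]) # H = 0.2 rougher than H = 0.8
  expect_true(all(fds > 2 & fds < 3))
})
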