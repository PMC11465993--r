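# Multi-emitter spot derivation: coordinate sampling, sub-pixel merging,
# padding, dataset assembly.

test_that("emitter coordinates are on-grid, in-disk and sub-diffraction", {
  set.seed(1)
  for (k in 1:50) {
    pts <- sample_emitter_coordinates(sample(2:4, 1))
    expect_true(all(pts == round(pts))) # 1 nm grid
    expect_true(all(rowSums(pts^2) <= 120^2 + 1e-9))
    expect_true(all(stats::dist(pts) <= 240 + 1e-9))
  }
  expect_error(sample_emitter_coordinates(1), ">= 2")
})

test_that("pair distances follow the uniform-disk distance law", {
  set.seed(2)
  n <- 100000
  d <- numeric(n)
  for (i in seq_len(n)) {
    p <- sample_emitter_coordinates(2)
    d[i] <- sqrt(sum((p[1, ] - p[2, ])^2))
  }
  # Kolmogorov distance to the closed-form CDF (Crofton) below 1%
  grid <- seq(5, 235, by = 5)
  emp <- ecdf(d)(grid)
  thee <- pair_distance_cdf(grid, 120)
  expect_lt(max(abs(emp - thee)), 0.01)
})

test_that("constrained pairs hit the requested separation and orientation", {
  set.seed(3)
  p30 <- sample_constrained_pair(c(30, 30))
  expect_lt(abs(sqrt(sum((p30[1, ] - p30[2, ])^2)) - 30), sqrt(2))

  d <- replicate(500, {
    p <- sample_constrained_pair(c(28, 32))
    sqrt(sum((p[1, ] - p[2, ])^2))
  })
  expect_true(all(d >= 28 - sqrt(2) & d <= 32 + sqrt(2)))

  # orientation uniform on [0, 2pi)
  set.seed(4)
  ang <- replicate(10000, {
    p <- sample_constrained_pair(c(100, 100))
    atan2(p[2, 2] - p[1, 2], p[2, 1] - p[1, 1])
  })
  expect_gt(suppressWarnings(
    stats::ks.test(ang, "punif", -pi, pi)$p.value), 0.01)

  expect_error(sample_constrained_pair(c(32, 28)), "interval")
})

test_that("merging is exact for identity and integer-pixel translations", {
  rec <- noiseless_record(c(560, 520))
  # identity: target equals the record's own fitted position
  own <- matrix(c(rec$fit$x0_nm, rec$fit$y0_nm), 1, 2)
  m0 <- merge_spots(list(rec), own, c(7, 7))
  expect_equal(m0$image$data, rec$image$data, tolerance = 1e-12)

  # two identical spots exactly 1 px apart along x: bit-exact integer shifts
  rec2 <- noiseless_record(c(560, 520), id = 2)
  targets <- rbind(own[1, ] + c(4 * 160, 4 * 160),
                   own[1, ] + c(5 * 160, 4 * 160))
  m2 <- merge_spots(list(rec, rec2), targets, c(15, 15))
  manual <- matrix(0, 15, 15)
  manual[5:11, 5:11] <- rec$image$data
  manual[5:11, 6:12] <- manual[5:11, 6:12] + rec$image$data
  expect_identical(m2$image$data, manual)
})

test_that("merged two-emitter spots match a direct two-emitter render", {
  # oracle: render both emitters directly on the 15x15 canvas
  set.seed(5)
  for (k in 1:5) {
    xy1 <- c(560, 520) + runif(2, -40, 40)
    xy2 <- c(560, 560) + runif(2, -40, 40)
    ph <- runif(2, 2000, 9000)
    r1 <- noiseless_record(xy1, ph[1], id = 1)
    r2 <- noiseless_record(xy2, ph[2], id = 2)
    tg <- rbind(c(1200, 1200) + runif(2, -100, 100),
                c(1200, 1200) + runif(2, -100, 100))
    merged <- merge_spots(list(r1, r2), tg, c(15, 15))
    direct <- render_psf(tg[1, ], ph[1], shape_px = c(15, 15))$data +
      render_psf(tg[2, ], ph[2], shape_px = c(15, 15))$data
    expect_lt(max(abs(merged$image$data - direct)), 0.01 * max(direct))
  }
})

test_that("pad_to_input zero-fills and preserves global coordinates", {
  sp <- spot_image(matrix(1, 11, 11), offset_nm = c(800, 480))
  padded <- pad_to_input(sp, c(15, 15))
  expect_equal(dim(padded$data), c(15, 15))
  expect_equal(padded$data[3:13, 3:13], sp$data)
  expect_equal(sum(padded$data), sum(sp$data))
  # a point at global position g has local = g - offset; padding keeps g
  g <- c(1000, 700)
  expect_equal((g - padded$offset_nm) - (g - sp$offset_nm),
               c(2 * 160, 2 * 160))

  same <- pad_to_input(spot_image(matrix(2, 15, 15)), c(15, 15))
  expect_equal(same$data, matrix(2, 15, 15))
  expect_error(pad_to_input(matrix(0, 17, 17), c(15, 15)), "larger")
})

test_that("build_dataset balances classes reproducibly with valid labels", {
  lib <- mini_library()
  ds <- build_dataset(lib, n_per_class = 10, classes = c(1, 2), seed = 77)
  expect_equal(nrow(ds$images), 20)
  expect_equal(as.vector(table(ds$labels$count)), c(10, 10))
  d2 <- ds$labels$pair_dist_nm[ds$labels$count == 2]
  expect_true(all(d2 <= 240 + 1e-9))

  ds2 <- build_dataset(lib, n_per_class = 10, classes = c(1, 2), seed = 77)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$labels, ds2$labels)

  expect_error(build_dataset(lib, 10, classes = c(1, 5)), "capped")
})

test_that("a single Gaussian fit lands between the two true emitters", {
  # sanity property behind crop centering at inference time
  lib <- mini_library()
  set.seed(6)
  ds <- build_dataset(lib, n_per_class = 8, classes = 2, seed = 42)
  for (i in seq_len(4)) {
    img <- matrix(ds$images[i, ], 15, 15)
    fit <- fit_gaussian_2d(img)
    cc <- label_coords(ds$labels, i)
    # center inside the bounding box of the two emitters (with fit tolerance)
    tol <- 40
    expect_gte(fit$x0_nm, min(cc[, 1]) - tol)
    expect_lte(fit$x0_nm, max(cc[, 1]) + tol)
    expect_gte(fit$y0_nm, min(cc[, 2]) - tol)
    expect_lte(fit$y0_nm, max(cc[, 2]) + tol)
  }
})
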