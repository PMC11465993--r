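# Metrics: confusion-matrix statistics, min-cost matching, RMS, binning,
# displacement maps, spike rendering, SSIM.

test_that("classification metrics match direct arithmetic", {
  perfect <- list(TP = 10, FP = 0, FN = 0, TN = 10)
  expect_equal(unname(classification_metrics(perfect)), c(1, 1, 1))
  m <- classification_metrics(list(TP = 9, FP = 1, FN = 1, TN = 9))
  expect_equal(unname(m), c(0.9, 0.9, 0.9))
  # degenerate: no positive predictions -> precision undefined, flagged NaN
  none <- classification_metrics(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_true(is.nan(none["precision"]))
  expect_equal(unname(none["accuracy"]), 0.5)

  # random confusion matrices: metrics equal their defining ratios
  set.seed(20)
  for (i in 1:20) {
    cm <- list(TP = sample(0:50, 1), FP = sample(1:50, 1),
               FN = sample(1:50, 1), TN = sample(0:50, 1))
    mm <- classification_metrics(cm)
    expect_equal(unname(mm["recall"]), cm$TP / (cm$TP + cm$FN))
    expect_equal(unname(mm["precision"]), cm$TP / (cm$TP + cm$FP))
    expect_equal(unname(mm["accuracy"]),
                 (cm$TP + cm$TN) / (cm$TP + cm$FP + cm$FN + cm$TN))
  }
})

test_that("confusion_matrix counts the two-emitter class as positive", {
  cm <- confusion_matrix(predicted = c(2, 2, 1, 1, 2),
                         truth = c(2, 1, 2, 1, 2))
  expect_equal(cm$TP, 2); expect_equal(cm$FP, 1)
  expect_equal(cm$FN, 1); expect_equal(cm$TN, 1)
})

test_that("min-cost matching equals brute-force permutation search", {
  a <- rbind(c(0, 0), c(10, 10))
  expect_equal(as.integer(match_emitters(a, a)), c(1L, 2L))
  expect_equal(attr(match_emitters(a, a), "cost"), 0)
  # swapped labels -> crossing assignment
  expect_equal(as.integer(match_emitters(a, a[2:1, ])), c(2L, 1L))

  set.seed(21)
  perms4 <- spotdecode:::all_permutations(4)
  for (rep in 1:40) {
    k <- sample(2:4, 1)
    pred <- matrix(runif(2 * k, 0, 100), k, 2)
    truth <- matrix(runif(2 * k, 0, 100), k, 2)
    got <- match_emitters(pred, truth)
    costs <- vapply(spotdecode:::all_permutations(k), function(p) {
      sum((pred - truth[p, , drop = FALSE])^2)
    }, numeric(1))
    expect_equal(attr(got, "cost"), min(costs), tolerance = 1e-12)
  }
})

test_that("RMS error follows its formula and matching invariance", {
  p <- rbind(c(1, 2), c(3, 4))
  expect_equal(rms_error(p, p), 0)
  expect_equal(rms_error(rbind(c(3, 4)), rbind(c(0, 0))), sqrt(25 / 2))
  expect_equal(rms_error(rbind(c(3, 4), c(0, 0)),
                         rbind(c(0, 0), c(0, 0))), sqrt(25 / 4))
  # relabeling invariance through matching
  truth <- rbind(c(0, 0), c(50, 60))
  pred <- rbind(c(49, 61), c(1, -1))
  expect_equal(rms_error(pred, truth), rms_error(pred, truth[2:1, ]))
  # linear scaling
  expect_equal(rms_error(3 * pred, 3 * truth), 3 * rms_error(pred, truth))
  # midpoint baseline closed form
  d <- 30
  pair <- rbind(c(-d / 2, 0), c(d / 2, 0))
  mid <- rbind(c(0, 0), c(0, 0))
  expect_equal(rms_error(mid, pair), midpoint_baseline_rms(d))
  expect_equal(midpoint_baseline_rms(30), 30 / (2 * sqrt(2)))
})

test_that("distance binning reproduces a naive group-by", {
  set.seed(22)
  rec <- data.frame(rms = runif(200, 0, 30),
                    pair_dist_nm = runif(200, 1, 239))
  out <- bin_rms_by_distance(rec)
  expect_equal(nrow(out), 4)
  # oracle: naive split
  grp <- split(rec$rms, cut(rec$pair_dist_nm, c(0, 60, 120, 180, 240),
                            include.lowest = TRUE))
  expect_equal(out$mean, vapply(grp, mean, numeric(1)), ignore_attr = TRUE)
  expect_equal(out$n, vapply(grp, length, numeric(1)), ignore_attr = TRUE)

  only30 <- bin_rms_by_distance(data.frame(rms = 1:5, pair_dist_nm = 30))
  expect_equal(only30$n, c(5, 0, 0, 0))
})

test_that("displacement heatmaps conserve mass and center perfection", {
  perfect <- matrix(0, 10, 2)
  H <- displacement_heatmap(perfect, half_range_nm = 20, cell_nm = 2)
  ctr <- (nrow(H) + 1) / 2
  expect_equal(H[ctr, ctr], 10)
  expect_equal(sum(H), 10)

  set.seed(23)
  disp <- matrix(rnorm(8000, sd = 8), ncol = 2)
  H2 <- displacement_heatmap(disp, half_range_nm = 40, cell_nm = 4)
  expect_equal(sum(H2), sum(abs(disp[, 1]) <= 42 & abs(disp[, 2]) <= 42),
               tolerance = 0.02)
  # radial symmetry of isotropic noise: quadrant masses agree within noise
  n <- nrow(H2); h <- (n - 1) / 2
  quads <- c(sum(H2[1:h, 1:h]), sum(H2[1:h, (h + 2):n]),
             sum(H2[(h + 2):n, 1:h]), sum(H2[(h + 2):n, (h + 2):n]))
  expect_lt(max(abs(quads - mean(quads))) / mean(quads), 0.1)
})

test_that("spike rendering and Gaussian heatmaps behave linearly", {
  z <- render_spikes(matrix(numeric(0), 0, 2), c(4, 4), 8)
  expect_true(all(z == 0))
  one <- render_spikes(rbind(c(330, 190)), c(4, 4), 8)
  expect_equal(sum(one), 1)
  expect_equal(sum(one != 0), 1)
  # impulse lands in the hi-res pixel containing the coordinate (20 nm cells)
  expect_equal(which(one != 0, arr.ind = TRUE)[1, ],
               c(row = floor(190 / 20) + 1, col = floor(330 / 20) + 1))
  many <- render_spikes(rbind(c(100, 100), c(100, 100), c(500, 300)),
                        c(4, 4), 8)
  expect_equal(sum(many), 3)
  expect_error(render_spikes(rbind(c(-5, 10)), c(4, 4), 8), "outside")

  expect_true(all(heatmap_from_spikes(z) == 0))
  hm1 <- heatmap_from_spikes(one, 1)
  expect_equal(sum(hm1), 1, tolerance = 1e-6)
  hm_many <- heatmap_from_spikes(many, 1)
  expect_equal(hm_many,
               heatmap_from_spikes(render_spikes(rbind(c(100, 100), c(100, 100)), c(4, 4), 8), 1) +
                 heatmap_from_spikes(render_spikes(rbind(c(500, 300)), c(4, 4), 8), 1),
               tolerance = 1e-12)
})

test_that("SSIM is 1 for identical images, symmetric, and matches the
           reference implementation", {
  set.seed(24)
  a <- matrix(runif(400), 20, 20)
  expect_equal(ssim(a, a), 1)
  b <- matrix(runif(400), 20, 20)
  expect_equal(ssim(a, b), ssim(b, a))
  expect_error(ssim(a, matrix(0, 5, 5)), "shape")

  # frozen oracle: scikit-image structural_similarity (win_size 7,
  # data_range 1) on the same seeded image pairs
  set.seed(424242)
  reference <- c(0.6379411804, 0.6639392151, 0.6862399875,
                 0.6859744672, 0.6721389316, 0.6750832045)
  for (i in 1:6) {
    x <- matrix(runif(20 * 20), 20, 20)
    y <- 0.5 * x + 0.5 * matrix(runif(20 * 20), 20, 20)
    expect_equal(ssim(x, y, data_range = 1), reference[i], tolerance = 1e-6)
  }
})
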