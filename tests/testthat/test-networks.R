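# Loss identities, model construction, and small-scale training checks of
# the compact classification/localization networks.

test_that("cross-entropy loss matches closed forms", {
  expect_equal(classification_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(classification_loss(c(0.5, 0.5), c(1, 0)), log(2))
  expect_equal(classification_loss(c(0.5, 0.5), c(0, 1)), log(2))
  expect_equal(classification_loss(c(0.9, 0.1), 1), -log(0.9))
  expect_warning(v <- classification_loss(c(1, 0), c(0, 1)), "clipping")
  expect_true(is.finite(v) && v > 0)
  expect_error(classification_loss(c(0.7, 0.6), c(1, 0)), "sum to 1")
})

test_that("localization MSE loss matches Eq-style arithmetic", {
  p <- rbind(c(10, 20), c(30, 40))
  expect_equal(localization_loss(p, p), 0)
  expect_equal(localization_loss(rbind(c(3, 4)), rbind(c(0, 0))), 12.5)
  # permutation-min on a swapped well-separated pair equals the canonical
  # loss of the unswapped pair
  truth <- rbind(c(0, 0), c(200, 0))
  pred <- rbind(c(5, 0), c(195, 0))
  swapped <- truth[2:1, ]
  expect_equal(localization_loss(pred, swapped, "permutation_min"),
               localization_loss(pred, truth, "canonical"))
  expect_error(localization_loss(p, p[1, , drop = FALSE]), "equal length")
})

test_that("model heads have the task-determined dimensions", {
  cfg <- train_config(seed = 1, channels = 4, hidden = 16)
  loc2 <- build_model("localize", 2, cfg)
  expect_equal(loc2$out_dim, 4)
  loc3 <- build_model("localize", 3, cfg)
  expect_equal(loc3$out_dim, 6)
  clf <- build_model("classify", 2, cfg)
  expect_equal(clf$out_dim, 2)

  # forward pass on a zero image: finite outputs, classifier on the simplex
  z <- matrix(0, 225, 1)
  probs <- spotdecode:::cpp_net_forward(clf$params, z, softmax = TRUE)
  expect_true(all(is.finite(probs)))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_true(all(probs >= 0))
  out <- spotdecode:::cpp_net_forward(loc2$params, z, softmax = FALSE)
  expect_true(all(is.finite(out)))

  expect_error(build_model("classify", 2, train_config(backbone = "resnet50")),
               "unsupported backbone")
})

test_that("classifier probabilities form a simplex for arbitrary inputs", {
  cfg <- train_config(seed = 2, channels = 4, hidden = 16)
  clf <- build_model("classify", 2, cfg)
  set.seed(8)
  X <- matrix(rnorm(225 * 20, sd = 10), 225, 20)
  probs <- spotdecode:::cpp_net_forward(clf$params, X, softmax = TRUE)
  expect_equal(colSums(probs), rep(1, 20), tolerance = 1e-12)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("a separable-by-construction task trains to >= 0.99 accuracy", {
  # singles at 1000 photons vs 200 nm pairs at 10000 photons total:
  # separable by brightness alone, so a short training must nail it
  cam <- camera_model(); psf <- psf_model()
  set.seed(9)
  n <- 2000
  images <- matrix(0, n, 225)
  count <- integer(n)
  for (i in seq_len(n)) {
    cls <- 1 + (i %% 2)
    ctr <- c(1200, 1200) + runif(2, -80, 80)
    img <- if (cls == 1) {
      render_psf(ctr, 1000, psf, cam, c(15, 15))$data
    } else {
      th <- runif(1, 0, 2 * pi)
      off <- 100 * c(cos(th), sin(th))
      render_psf(ctr + off, 5000, psf, cam, c(15, 15))$data +
        render_psf(ctr - off, 5000, psf, cam, c(15, 15))$data
    }
    images[i, ] <- as.vector(add_camera_noise(
      spot_image(img), cam)$data)
    count[i] <- cls
  }
  labs <- data.frame(count = count, x1 = 1200, y1 = 1200,
                     x2 = NA, y2 = NA, x3 = NA, y3 = NA, x4 = NA, y4 = NA,
                     pair_dist_nm = ifelse(count == 2, 200, NA),
                     split = rep(c("train", "test"), c(1700, 300))[
                       order(runif(n))])
  ds <- structure(list(images = images, labels = labs,
                       canvas_px = c(15, 15), pixel_size_nm = 160,
                       seed = 9, config = list()),
                  class = "labeled_dataset")
  cfg <- train_config(epochs = 20, channels = 4, hidden = 16, seed = 10)
  clf <- train_network(build_model("classify", 2, cfg), ds)
  test_rows <- which(labs$split == "test")
  probs <- spotdecode:::model_forward(clf, images[test_rows, ])
  pred <- clf$classes[apply(probs, 2, which.max)]
  expect_gte(mean(pred == count[test_rows]), 0.99)
  expect_equal(nrow(clf$history), 20)
  expect_true(all(is.finite(clf$history$train_loss)))
})

test_that("a single-emitter localizer learns noiseless positions to < 10 nm", {
  cam <- camera_model(); psf <- psf_model()
  set.seed(12)
  n <- 1200
  images <- matrix(0, n, 225)
  xs <- runif(n, 1200 - 120, 1200 + 120)
  ys <- runif(n, 1200 - 120, 1200 + 120)
  for (i in seq_len(n)) {
    images[i, ] <- as.vector(
      render_psf(c(xs[i], ys[i]), 5000, psf, cam, c(15, 15))$data)
  }
  labs <- data.frame(count = 1L, x1 = xs, y1 = ys,
                     x2 = NA, y2 = NA, x3 = NA, y3 = NA, x4 = NA, y4 = NA,
                     pair_dist_nm = NA,
                     split = rep(c("train", "test"), c(1000, 200)))
  ds <- structure(list(images = images, labels = labs,
                       canvas_px = c(15, 15), pixel_size_nm = 160,
                       seed = 12, config = list()),
                  class = "labeled_dataset")
  cfg <- train_config(epochs = 50, channels = 4, hidden = 24, seed = 13)
  loc <- train_network(build_model("localize", 1, cfg), ds)
  test_rows <- which(labs$split == "test")
  out <- spotdecode:::model_forward(loc, images[test_rows, ])
  rms <- vapply(seq_along(test_rows), function(k) {
    pred <- matrix(out[, k], ncol = 2, byrow = TRUE)
    pred <- pred + matrix(loc$center_nm, 1, 2)
    rms_error(pred, label_coords(labs, test_rows[k]))
  }, numeric(1))
  expect_lt(mean(rms), 10)
})

test_that("training histories trend downward and short runs are well-formed", {
  set.seed(14)
  images <- matrix(runif(10 * 225) * 100, 10, 225)
  labs <- data.frame(count = rep(1:2, 5), x1 = 1200, y1 = 1200,
                     x2 = c(NA, 1100), y2 = c(NA, 1300), x3 = NA, y3 = NA,
                     x4 = NA, y4 = NA, pair_dist_nm = NA, split = "train")
  ds <- structure(list(images = images, labels = labs,
                       canvas_px = c(15, 15), pixel_size_nm = 160,
                       seed = 14, config = list()),
                  class = "labeled_dataset")
  cfg <- train_config(epochs = 1, channels = 4, hidden = 8,
                      val_fraction = 0, seed = 15)
  m <- train_network(build_model("classify", 2, cfg), ds)
  expect_equal(nrow(m$history), 1)
  expect_true(is.finite(m$history$train_loss))
})
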