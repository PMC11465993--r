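# Two-stage model: an emitter-count classifier and per-count coordinate
# regression networks, trained with Adam under a cosine-annealed learning
# rate, cross-entropy (classification) and MSE (localization) losses.

#' Training configuration
#'
#' Hyperparameters of the classification/localization networks. The
#' `"desk"` profile (default) uses the compact convolutional backbone and a
#' schedule sized for a single CPU; the `"paper_scale"` profile carries the
#' full published recipe (400 epochs, learning rate cosine-annealed from
#' 1e-5 to 1e-8) for users with the hardware to run it.
#'
#' @param profile `"desk"` or `"paper_scale"`.
#' @param backbone Network backbone; this implementation provides
#'   `"compact"` (two skip-connected convolution blocks, max-pooling and a
#'   fully-connected head sized for 15x15 single-channel input).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (64).
#' @param lr_initial,lr_final Cosine-annealing endpoints.
#' @param weight_decay L2 penalty strength (0.01).
#' @param channels Channel width of the first conv block.
#' @param hidden Width of the fully-connected hidden layer.
#' @param loss_variant `"canonical"` (emitters sorted by x then y) or
#'   `"permutation_min"` (MSE minimized over emitter orderings).
#' @param val_fraction Fraction of the training split reserved for per-epoch
#'   validation monitoring.
#' @param norm_constant Fixed intensity scale dividing every input image, so
#'   absolute photon counts remain an informative cue across images.
#' @param seed Optional integer seed for weight init and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(profile = c("desk", "paper_scale"),
                         backbone = "compact",
                         epochs = NULL, batch_size = 64,
                         lr_initial = NULL, lr_final = NULL,
                         weight_decay = 0.01, channels = 8, hidden = 48,
                         loss_variant = c("canonical", "permutation_min"),
                         val_fraction = 0.1, norm_constant = 5000,
                         seed = NULL) {
  profile <- match.arg(profile)
  loss_variant <- match.arg(loss_variant)
  defaults <- if (profile == "desk") {
    list(epochs = 30, lr_initial = 1e-3, lr_final = 1e-5)
  } else {
    list(epochs = 400, lr_initial = 1e-5, lr_final = 1e-8)
  }
  epochs <- epochs %||% defaults$epochs
  lr_initial <- lr_initial %||% defaults$lr_initial
  lr_final <- lr_final %||% defaults$lr_final
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (lr_final > lr_initial || lr_final <= 0) {
    stop("need 0 < lr_final <= lr_initial")
  }
  structure(list(profile = profile, backbone = backbone, epochs = epochs,
                 batch_size = batch_size, lr_initial = lr_initial,
                 lr_final = lr_final, weight_decay = weight_decay,
                 channels = channels, hidden = hidden,
                 loss_variant = loss_variant, val_fraction = val_fraction,
                 norm_constant = norm_constant, seed = seed),
            class = "train_config")
}

#' Cross-entropy classification loss
#'
#' Non-negative cross-entropy -sum p(x) log q(x) between a one-hot truth and
#' a predicted class-probability simplex. Zero predicted probability on the
#' true class is clipped at machine epsilon (and flagged with a warning).
#'
#' @param predicted_probs Probability vector (sums to 1).
#' @param true_class One-hot truth vector (or a class index).
#' @return Scalar loss.
#' @export
classification_loss <- function(predicted_probs, true_class) {
  if (length(true_class) == 1) {
    onehot <- rep(0, length(predicted_probs))
    onehot[true_class] <- 1
    true_class <- onehot
  }
  stopifnot(length(predicted_probs) == length(true_class))
  if (abs(sum(predicted_probs) - 1) > 1e-6) {
    stop("`predicted_probs` must sum to 1")
  }
  q <- predicted_probs[true_class > 0]
  if (any(q <= 0)) {
    warning("zero predicted probability on the true class; clipping")
    q <- pmax(q, .Machine$double.eps)
  }
  -sum(true_class[true_class > 0] * log(q))
}

#' Mean-square localization loss
#'
#' L = 1/(2I) sum_i [(x_i - xbar_i)^2 + (y_i - ybar_i)^2] over the I emitters
#' of one spot. With `variant = "permutation_min"` the loss is minimized over
#' all orderings of the true emitters, removing label-order ambiguity.
#'
#' @param pred_coords,true_coords I x 2 matrices of `c(x, y)` coordinates
#'   (nm).
#' @param variant `"canonical"` or `"permutation_min"`.
#' @return Scalar loss (nm^2).
#' @export
localization_loss <- function(pred_coords, true_coords,
                              variant = c("canonical", "permutation_min")) {
  variant <- match.arg(variant)
  pred_coords <- rbind(pred_coords); true_coords <- rbind(true_coords)
  if (!all(dim(pred_coords) == dim(true_coords))) {
    stop("coordinate lists must have equal length")
  }
  I <- nrow(pred_coords)
  sq <- function(truth) sum((pred_coords - truth)^2) / (2 * I)
  if (variant == "canonical" || I == 1) return(sq(true_coords))
  perms <- all_permutations(I)
  min(vapply(perms, function(p) sq(true_coords[p, , drop = FALSE]),
             numeric(1)))
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  # insert n at each position of each (n-1)-permutation
  sub <- all_permutations(n - 1)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(as.integer(p), n, after = pos)
    }
  }
  out
}

#' Build an untrained model
#'
#' Instantiates the compact backbone with the task-specific head: a softmax
#' classifier over emitter counts, or a linear layer emitting 2n coordinates
#' (nm, relative to the crop center) for a localizer.
#'
#' @param task `"classify"` or `"localize"`.
#' @param n Number of count classes (classify) or emitters (localize).
#' @param cfg A [train_config()].
#' @param input_hw Input side length in pixels (15).
#' @return An object of class `spot_model`.
#' @export
build_model <- function(task = c("classify", "localize"), n,
                        cfg = train_config(), input_hw = 15) {
  task <- match.arg(task)
  if (!identical(cfg$backbone, "compact")) {
    stop(sprintf(paste0("unsupported backbone '%s': this implementation ",
                        "provides the 'compact' backbone"), cfg$backbone))
  }
  stopifnot(n >= 1)
  out_dim <- if (task == "classify") n else 2 * n
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  params <- cpp_net_init(cfg$channels, cfg$hidden, out_dim, input_hw)
  structure(list(task = task, n = n, out_dim = out_dim, params = params,
                 cfg = cfg, input_hw = input_hw, history = NULL),
            class = "spot_model")
}

#' @export
print.spot_model <- function(x, ...) {
  cat(sprintf("<spot_model: %s (n = %d), %s backbone, %strained>\n",
              x$task, x$n, x$cfg$backbone,
              if (is.null(x$history)) "un" else ""))
  invisible(x)
}

# Normalize raw photon images (rows of a dataset image matrix) and transpose
# to the column-per-image layout the C++ engine expects.
prepare_inputs <- function(images, norm_constant) {
  t(images) / norm_constant
}

# Targets relative to the canvas center, canonical x-then-y emitter order.
prepare_targets <- function(labels, rows, n_emitters, center_nm) {
  Y <- matrix(0, 2 * n_emitters, length(rows))
  for (k in seq_along(rows)) {
    cc <- label_coords(labels, rows[k])
    ord <- order(cc[, 1], cc[, 2])
    cc <- cc[ord, , drop = FALSE]
    Y[, k] <- as.vector(t(cc)) - rep(center_nm, n_emitters)
  }
  Y
}

#' Train a model on a labeled dataset
#'
#' Runs minibatch Adam with the cosine-annealed learning rate over the
#' dataset's training split. Classifiers train on all spots; a localizer for
#' I emitters trains on the spots whose true count is I, with coordinate
#' targets expressed in nm relative to the canvas center. A fraction of the
#' training split is held aside for per-epoch monitoring.
#'
#' @param model A [build_model()] result.
#' @param dataset A [build_dataset()] result.
#' @param verbose Print per-epoch progress.
#' @return The trained `spot_model`, with a `history` data.frame (epoch,
#'   train loss, validation loss/metric).
#' @export
train_network <- function(model, dataset, verbose = FALSE) {
  stopifnot(inherits(model, "spot_model"), inherits(dataset, "labeled_dataset"))
  cfg <- model$cfg
  labs <- dataset$labels
  center <- c(dataset$canvas_px[2], dataset$canvas_px[1]) / 2 *
    dataset$pixel_size_nm
  rows <- which(labs$split == "train")
  if (model$task == "localize") rows <- rows[labs$count[rows] == model$n]
  if (length(rows) == 0) stop("dataset has no training spots for this task")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_val <- floor(cfg$val_fraction * length(rows))
  val_rows <- if (n_val > 0) sample(rows, n_val) else integer(0)
  tr_rows <- setdiff(rows, val_rows)

  X <- prepare_inputs(dataset$images[tr_rows, , drop = FALSE],
                      cfg$norm_constant)
  if (model$task == "classify") {
    classes <- sort(unique(labs$count))
    Y <- matrix(match(labs$count[tr_rows], classes) - 1, nrow = 1)
    task_code <- 0L
  } else {
    classes <- NULL
    Y <- prepare_targets(labs, tr_rows, model$n, center)
    task_code <- if (cfg$loss_variant == "permutation_min") 2L else 1L
  }
  X_val <- Y_val <- NULL
  if (length(val_rows)) {
    X_val <- prepare_inputs(dataset$images[val_rows, , drop = FALSE],
                            cfg$norm_constant)
    Y_val <- if (model$task == "classify") {
      matrix(match(labs$count[val_rows], classes) - 1, nrow = 1)
    } else {
      prepare_targets(labs, val_rows, model$n, center)
    }
  }
  fit <- cpp_net_train(model$params, X, Y, task_code, cfg$epochs,
                       cfg$batch_size, cfg$lr_initial, cfg$lr_final,
                       cfg$weight_decay, X_val, Y_val, verbose)
  model$params <- fit$params
  model$history <- fit$history
  model$classes <- classes
  model$center_nm <- center
  model$norm_constant <- cfg$norm_constant
  model
}

# Raw network outputs for a matrix of images (rows = spots, raw photons).
model_forward <- function(model, images) {
  X <- prepare_inputs(images, model$norm_constant %||% model$cfg$norm_constant)
  cpp_net_forward(model$params, X, softmax = model$task == "classify")
}

#' Predict class probabilities or emitter positions for spot images
#'
#' Batch prediction helpers for trained models. `predict_counts()` returns
#' the class-probability matrix of a classifier; `predict_positions()`
#' returns the localizer's coordinates mapped back to the canvas frame (nm).
#'
#' @param model A trained `spot_model`.
#' @param images n x 225 matrix of raw photon-count images (one flattened
#'   15x15 canvas per row, as in a [build_dataset()] result).
#' @return `predict_counts()`: classes x n matrix of probabilities.
#'   `predict_positions()`: list of n matrices (emitters x 2, canvas nm).
#' @export
predict_counts <- function(model, images) {
  stopifnot(model$task == "classify")
  out <- model_forward(model, images)
  rownames(out) <- as.character(model$classes)
  out
}

#' @rdname predict_counts
#' @export
predict_positions <- function(model, images) {
  stopifnot(model$task == "localize")
  out <- model_forward(model, images)
  lapply(seq_len(ncol(out)), function(k) {
    coords <- matrix(out[, k], ncol = 2, byrow = TRUE)
    sweep(coords, 2, model$center_nm, "+")
  })
}

#' Bundle a classifier with count-specific localizers
#'
#' @param classifier Trained classification `spot_model`.
#' @param localizers Named list of trained localizers, names = emitter counts
#'   (e.g. `list("1" = m1, "2" = m2)`).
#' @return An object of class `model_bundle`.
#' @export
model_bundle <- function(classifier, localizers) {
  stopifnot(classifier$task == "classify")
  for (nm in names(localizers)) {
    loc <- localizers[[nm]]
    if (loc$out_dim != 2 * as.integer(nm)) {
      stop("localizer output dimension must be 2 x emitter count")
    }
  }
  structure(list(classifier = classifier, localizers = localizers),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle: %d-class classifier + localizers for {%s}>\n",
              length(x$classifier$classes %||% 0),
              paste(names(x$localizers), collapse = ",")))
  invisible(x)
}
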