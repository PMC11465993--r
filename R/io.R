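# Format I/O and configuration: ThunderSTORM-dialect localization CSV,
# multi-page TIFF stacks, YAML run configuration with seed fan-out.

#' Read a ThunderSTORM-dialect localization table
#'
#' Parses a CSV with at least the `frame`, `x [nm]` and `y [nm]` columns of
#' the ThunderSTORM export dialect; all other columns (e.g. `sigma [nm]`,
#' `intensity [photon]`, `count`) are preserved verbatim.
#'
#' @param path CSV file path.
#' @return A `localization_table` data.frame.
#' @export
read_localizations <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  required <- c("frame", "x [nm]", "y [nm]")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("localization file lacks mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  class(tab) <- c("localization_table", class(tab))
  tab
}

#' Write a localization table
#'
#' @param table Data.frame with at least `frame`, `x [nm]`, `y [nm]`
#'   (columns `x_nm`/`y_nm` are renamed on the way out).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  names(table)[names(table) == "x_nm"] <- "x [nm]"
  names(table)[names(table) == "y_nm"] <- "y [nm]"
  required <- c("frame", "x [nm]", "y [nm]")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop(sprintf("localization table lacks mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# TIFF stores 32-bit samples on [0, 1]; photon counts are divided by this
# fixed scale on the way out and restored on the way in, giving ~2^-12
# photon absolute resolution up to ~10^6 photons per pixel.
.tiff_scale <- 2^20

#' Write / read a multi-page TIFF stack
#'
#' Photon-count frames are stored as 32-bit TIFF pages under a fixed
#' intensity scale (photons / 2^20), giving sub-milliphoton resolution over
#' the full dynamic range in use.
#'
#' @param frames List of numeric matrices (or a single matrix).
#' @param path TIFF file path.
#' @return `path` invisibly (write); list of matrices (read).
#' @export
write_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  scaled <- lapply(frames, function(f) pmin(pmax(f / .tiff_scale, 0), 1))
  tiff::writeTIFF(scaled, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(p) p * .tiff_scale)
}

#' Load a run configuration
#'
#' Reads a YAML configuration with nested per-module sections and a global
#' seed; unknown top-level keys are rejected. The global seed fans out to
#' decorrelated per-module seeds by fixed offsets.
#'
#' @param path YAML file path, or NULL for defaults.
#' @param overrides Named list merged over the file contents.
#' @return A `run_config` list with sections `camera`, `psf`, `photons`,
#'   `kinetics`, `dataset`, `train`, `seed`, `profile` and derived
#'   `seeds$<module>`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L, profile = "desk",
    camera = list(pixel_size_nm = 160, read_noise_e = 1,
                  background_photons_per_px = 10),
    psf = list(sigma_nm = 102),
    photons = list(family = "lognormal", median = 5000, geom_sd = 1.8,
                   lower = 500, upper = 50000),
    kinetics = list(p_on = 1e-3, mean_on_frames = 2),
    dataset = list(n_per_class = 10000, classes = c(1, 2),
                   diameter_nm = 240, test_fraction = 0.1,
                   library_molecules = 4000),
    train = list(epochs = NULL, channels = 8, hidden = 48,
                 batch_size = 64, weight_decay = 0.01))
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) {
      stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    }
    cfg <- modifyList(cfg, user)
  }
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  # fixed offsets give reproducible yet decorrelated per-module streams
  cfg$seeds <- list(library = cfg$seed + 1000L,
                    dataset = cfg$seed + 2000L,
                    train = cfg$seed + 3000L,
                    storm = cfg$seed + 4000L)
  class(cfg) <- "run_config"
  cfg
}

#' Instantiate model objects from a run configuration
#'
#' @param cfg A [run_config()].
#' @return List with `camera`, `psf`, `photons`, `kinetics` objects.
#' @export
config_models <- function(cfg) {
  list(camera = do.call(camera_model, cfg$camera),
       psf = do.call(psf_model, cfg$psf),
       photons = do.call(photon_distribution, cfg$photons),
       kinetics = do.call(blink_kinetics, cfg$kinetics))
}

#' Save / load a trained model bundle
#'
#' Checkpoints are a directory of plain-text artifacts: one CSV of flattened
#' weights per network plus a YAML manifest with shapes, classes and the
#' training configuration, so bundles survive text-only storage.
#'
#' @param bundle A [model_bundle()].
#' @param dir Checkpoint directory.
#' @return `dir` invisibly (save); a `model_bundle` (load).
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_model <- function(model, stem) {
    shapes <- lapply(model$params, dim)
    flat <- unlist(lapply(model$params, as.numeric))
    utils::write.table(data.frame(value = flat),
                       file.path(dir, paste0(stem, ".csv")),
                       row.names = FALSE, col.names = TRUE)
    list(shapes = lapply(model$params, function(p)
           if (is.matrix(p)) dim(p) else length(p)),
         names = names(model$params), task = model$task, n = model$n,
         out_dim = model$out_dim, classes = model$classes,
         center_nm = model$center_nm, norm_constant = model$norm_constant,
         input_hw = model$input_hw,
         cfg = unclass(model$cfg))
  }
  manifest <- list(classifier = save_model(bundle$classifier, "classifier"))
  for (nm in names(bundle$localizers)) {
    manifest[[paste0("localizer_", nm)]] <-
      save_model(bundle$localizers[[nm]], paste0("localizer_", nm))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  load_model <- function(meta, stem) {
    flat <- read.csv(file.path(dir, paste0(stem, ".csv")))$value
    params <- list()
    pos <- 0
    for (i in seq_along(meta$names)) {
      shp <- unlist(meta$shapes[[i]])
      len <- prod(shp)
      vals <- flat[(pos + 1):(pos + len)]
      params[[meta$names[i]]] <-
        if (length(shp) == 2) matrix(vals, shp[1], shp[2]) else vals
      pos <- pos + len
    }
    cfg <- meta$cfg; class(cfg) <- "train_config"
    structure(list(task = meta$task, n = meta$n, out_dim = meta$out_dim,
                   params = params, cfg = cfg, input_hw = meta$input_hw,
                   history = NULL, classes = unlist(meta$classes),
                   center_nm = unlist(meta$center_nm),
                   norm_constant = meta$norm_constant),
              class = "spot_model")
  }
  classifier <- load_model(manifest$classifier, "classifier")
  loc_names <- grep("^localizer_", names(manifest), value = TRUE)
  localizers <- list()
  for (nm in loc_names) {
    localizers[[sub("^localizer_", "", nm)]] <- load_model(manifest[[nm]], nm)
  }
  model_bundle(classifier, localizers)
}
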