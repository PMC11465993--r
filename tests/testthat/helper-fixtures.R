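# Shared fixtures, built in code and cached for the session.

fixture_env <- new.env(parent = emptyenv())

# a small fitted library used by dataset/inference tests
mini_library <- function(n = 60, seed = 555) {
  key <- sprintf("lib_%d_%d", n, seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- build_synthetic_library(
      n, psf_model(), camera_model(), photon_distribution(), seed = seed)
  }
  fixture_env[[key]]
}

# noiseless single-emitter record with an exact fit
noiseless_record <- function(xy = c(560, 520), photons = 5000,
                             psf = psf_model(), id = 1) {
  img <- render_psf(xy, photons, psf, camera_model(), c(7, 7))
  list(molecule_id = id, image = img, true_xy_nm = xy,
       photons_true = photons, photons = spot_photons(img),
       fit = fit_gaussian_2d(img))
}

# closed-form CDF of the distance between two uniform points in a disk of
# radius R (Crofton): used as the independent oracle for coordinate sampling
pair_distance_cdf <- function(d, R) {
  vapply(d, function(di) {
    if (di <= 0) return(0)
    if (di >= 2 * R) return(1)
    stats::integrate(function(s) {
      (2 * s / R^2) * (2 / pi) *
        (acos(s / (2 * R)) - (s / (2 * R)) * sqrt(1 - (s / (2 * R))^2))
    }, 0, di, rel.tol = 1e-9)$value
  }, numeric(1))
}
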