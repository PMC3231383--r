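# Shared builders for small synthetic objects used across the test files.

# a minimal species inventory: k_con conifer + k_dec broadleaf species
mini_inventory <- function(k_con = 2, k_dec = 2, count = 10L) {
  data.frame(
    latin_name = c(sprintf("Conifer %d", seq_len(k_con)),
                   sprintf("Broadleaf %d", seq_len(k_dec))),
    habit = c(rep("coniferous", k_con), rep("deciduous", k_dec)),
    count = count, stringsAsFactors = FALSE)
}

# small, fast garden config; effects and noise switchable
mini_config <- function(k_con = 2, k_dec = 2, count = 10L,
                        shape_effect = 1, spectral_effect = 1,
                        point_density = 25,
                        illumination_sdlog = 0.5, pixel_sdlog = 0.25,
                        shaded_reference_prob = 0.05,
                        simulate_frames = TRUE, spectral_sd = NULL,
                        separated = FALSE) {
  inv <- mini_inventory(k_con, k_dec, count)
  bs <- band_set()
  tpl <- canopyfuse:::build_templates(
    inv, bs, shape_effect = shape_effect,
    spectral_effect = spectral_effect, point_density = point_density,
    spectral_sd = if (is.null(spectral_sd)) pixel_sdlog else spectral_sd)
  # separated: one row, wide spacing, so no frame ever sees two crowns and
  # per-point spectra stay uncontaminated (needed for exact-identity checks)
  layout <- if (separated) list(spacing = 6, n_rows = 1, row_y = 6) else
    list(spacing = 3, n_rows = 2, row_y = c(6, 9))
  garden_config(tpl, bs, layout = layout,
                noise = list(illumination_sdlog = illumination_sdlog,
                             pixel_sdlog = pixel_sdlog,
                             shaded_reference_prob = shaded_reference_prob,
                             shade_factor = 0.3),
                simulate_frames = simulate_frames,
                shape_effect = shape_effect,
                spectral_effect = spectral_effect)
}

# hand-built feature table for classifier tests (no scene machinery)
toy_feature_table <- function(values, species = NULL, habit = NULL) {
  n <- nrow(values)
  ft <- data.frame(
    specimen_id = seq_len(n),
    species = if (is.null(species)) rep("sp", n) else species,
    habit = if (is.null(habit)) rep("deciduous", n) else habit,
    values, stringsAsFactors = FALSE, check.names = FALSE)
  class(ft) <- c("feature_table", "data.frame")
  ft
}

# untuned SVM spec (single grid point) for fast deterministic evaluations
fixed_svm_spec <- function(C = 32, gamma = 0.125, seed = 1L) {
  classifier_spec("svm_rbf", C_grid = C, gamma_grid = gamma, seed = seed)
}

# single hand-built spectral frame: ref pixels at the top, given dn fill
toy_frame <- function(n_pixels = 20L, n_channels = 4L, target_dn = 50,
                      ref_dn = 100, timestamp = 0, pose_y = 0,
                      sensor_height = 0, fov_deg = 44.4) {
  ref_idx <- (n_pixels - 9L):n_pixels
  dn <- matrix(target_dn, n_pixels, n_channels,
               dimnames = list(NULL, channel_names(n_channels)))
  dn[ref_idx, ] <- ref_dn
  structure(list(timestamp = timestamp,
                 pose = c(x = 0, y = pose_y, heading = 0),
                 sensor_height = sensor_height,
                 pixel_angles = seq(-fov_deg / 2, fov_deg / 2,
                                    length.out = n_pixels),
                 dn = dn, reference_pixels = ref_idx),
            class = "spectral_frame")
}

# independent brute-force structural features (shares no code with the
# package implementation beyond base arithmetic)
oracle_structural <- function(z) {
  zmin <- min(z); zmax <- max(z)
  hN <- (z - zmin) / (zmax - zmin)
  h <- z - zmin
  n <- length(z)
  pr_lt <- sum(hN < 0.33) / n
  pr_mid <- sum(hN >= 0.33 & hN < 0.67) / n
  bands <- sapply(1:8, function(i)
    sum(hN >= i / 10 & hN < (i + 1) / 10) / n)
  above <- sapply(1:9, function(i) sum(hN > i / 10) / n)
  mu <- sum(h) / n
  m2 <- sum((h - mu)^2) / n
  m3 <- sum((h - mu)^3) / n
  m4 <- sum((h - mu)^4) / n
  # type-7 quantile, written out from the order statistics
  q7 <- function(p) {
    hs <- sort(h)
    idx <- (n - 1) * p
    lo <- floor(idx) + 1
    frac <- idx - floor(idx)
    if (lo >= n) hs[n] else hs[lo] * (1 - frac) + hs[lo + 1] * frac
  }
  hq <- sapply(seq(0.1, 0.9, 0.1), q7)
  out <- c(pr_lt, pr_mid, 1 - pr_lt - pr_mid, bands, above,
           m3 / m2^1.5, m4 / m2^2, hq, max(h), mu, sqrt(m2) / mu)
  names(out) <- structural_feature_names()
  out
}

# two well-separated gaussian classes in 1-D (class means 10 sds apart)
separable_table <- function(n_per = 10, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n_per, 0, 1), rnorm(n_per, 10, 1))
  toy_feature_table(data.frame(f1 = x),
                    habit = rep(c("coniferous", "deciduous"), each = n_per))
}
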