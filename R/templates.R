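#' Species template for the synthetic garden generator
#'
#' A template bundles everything needed to draw specimens of one species:
#' a parametric crown profile (cone for conifers; trunk plus vertically
#' offset ellipsoid for broadleaves), a height range, a volumetric point
#' density, a 123-channel reflectance curve relative to a white reference,
#' and a per-pixel multiplicative spectral noise scale.
#'
#' @param name species name (text).
#' @param habit `"coniferous"` or `"deciduous"`.
#' @param crown list describing the crown profile; see Details.
#' @param height_range numeric length 2, min and max tree height in metres.
#' @param point_density laser returns per cubic metre of crown volume.
#' @param reflectance_curve numeric vector of per-channel reflectance in
#'   \[0, 1.5\] (reference-relative reflectance may exceed 1 under glare).
#' @param spectral_sd sdlog of the per-pixel multiplicative lognormal noise.
#' @param count number of specimens of this species to generate.
#'
#' @details
#' Crown profiles:
#' * cone: `list(type = "cone", base_radius_frac = r)` -- uniform density in
#'   a cone of height H with base radius `r * H`, apex at the top.
#' * ellipsoid: `list(type = "ellipsoid", center = c, half_height = a,
#'   radius_frac = r, crown_fraction = f)` -- a fraction `f` of points
#'   uniform in an ellipsoid of revolution centred at normalized height `c`
#'   with vertical semi-axis `a` (both in units of tree height) and radius
#'   `r * H`; the remainder on a thin trunk below the crown.
#'
#' @return an object of class `species_template`.
#' @export
species_template <- function(name, habit = c("coniferous", "deciduous"),
                             crown, height_range, point_density,
                             reflectance_curve, spectral_sd = 0.25,
                             count = 1L) {
  habit <- match.arg(habit)
  stopifnot(is.character(name), length(height_range) == 2L,
            height_range[1] <= height_range[2], height_range[1] > 0,
            point_density > 0, count >= 0,
            all(reflectance_curve >= 0), all(reflectance_curve <= 1.5),
            spectral_sd >= 0)
  if (!crown$type %in% c("cone", "ellipsoid"))
    stop("unknown crown profile type: ", crown$type)
  if (crown$type == "ellipsoid") {
    stopifnot(crown$center - crown$half_height >= 0,
              crown$center + crown$half_height <= 1)
  }
  structure(list(name = name, habit = habit, crown = crown,
                 height_range = height_range, point_density = point_density,
                 reflectance_curve = reflectance_curve,
                 spectral_sd = spectral_sd, count = as.integer(count)),
            class = "species_template")
}

#' Fraction of crown density above a normalized height
#'
#' Closed-form probability that a point drawn from a template's crown
#' profile lies above normalized height `h`. For the cone this is
#' `(1 - h)^3`; for the trunk-plus-ellipsoid model the crown part follows
#' the Epanechnikov-shaped height density of a uniform ellipsoid. This is
#' the generator's shape-effect knob: broadleaf templates are constructed
#' so their value at `h = 0.5` strictly exceeds the conifer value.
#'
#' @param template a [species_template()].
#' @param h normalized height threshold in \[0, 1\].
#' @return probability in \[0, 1\].
#' @export
crown_fraction_above <- function(template, h = 0.5) {
  cr <- template$crown
  if (cr$type == "cone") return((1 - h)^3)
  # ellipsoid crown: height density on u = (hN - c)/a is 3/4 (1 - u^2)
  u <- max(-1, min(1, (h - cr$center) / cr$half_height))
  p_crown <- 0.75 * (2 / 3 - u + u^3 / 3)  # int_u^1 3/4 (1 - t^2) dt
  trunk_top <- cr$center - cr$half_height
  p_trunk <- if (h >= trunk_top) 0 else (trunk_top - h) / trunk_top
  cr$crown_fraction * p_crown + (1 - cr$crown_fraction) * p_trunk
}

# Parametric vegetation reflectance: dark visible floor, a green bump near
# 550 nm, a logistic red edge around 700-720 nm, and a species-specific NIR
# plateau. Broadleaves get brighter NIR plateaus than conifers, mirroring
# the IR separation the field data showed.
vegetation_curve <- function(bs, visible = 0.06, nir = 0.45,
                             green_amp = 0.05, red_edge = 710,
                             edge_width = 18) {
  w <- as.numeric(bs)
  r <- visible +
    (nir - visible) / (1 + exp(-(w - red_edge) / edge_width)) +
    green_amp * exp(-(w - 550)^2 / (2 * 30^2))
  pmin(pmax(r, 0), 1.5)
}

# Deterministic per-species curve parameters, spread so that species differ
# in NIR level, red-edge position and green bump; conifers darker in NIR.
species_curve_params <- function(index, habit) {
  phase <- (index * 7L) %% 11L
  if (habit == "deciduous") {
    list(visible = 0.05 + 0.004 * (phase %% 4),
         nir = 0.42 + 0.022 * (phase %% 6),
         green_amp = 0.04 + 0.008 * (phase %% 3),
         red_edge = 704 + 2.5 * (phase %% 5))
  } else {
    list(visible = 0.04 + 0.004 * (phase %% 4),
         nir = 0.26 + 0.018 * (phase %% 6),
         green_amp = 0.025 + 0.006 * (phase %% 3),
         red_edge = 698 + 2.5 * (phase %% 5))
  }
}

# Build the template list for a species inventory table (columns
# latin_name, habit, count). shape_effect / spectral_effect in [0, 1] scale
# the between-habit crown difference and the between-species spectral
# difference; 0 gives identical crowns (all cones) and identical curves.
build_templates <- function(inventory, bs, shape_effect = 1,
                            spectral_effect = 1, point_density = 60,
                            spectral_sd = 0.25) {
  n <- nrow(inventory)
  curves <- matrix(NA_real_, n, length(bs))
  for (i in seq_len(n)) {
    p <- species_curve_params(i, inventory$habit[i])
    curves[i, ] <- vegetation_curve(bs, p$visible, p$nir, p$green_amp,
                                    p$red_edge)
  }
  mean_curve <- colMeans(curves)
  templates <- vector("list", n)
  for (i in seq_len(n)) {
    curve <- mean_curve + spectral_effect * (curves[i, ] - mean_curve)
    conifer_like <- inventory$habit[i] == "coniferous" || shape_effect == 0
    if (conifer_like) {
      crown <- list(type = "cone", base_radius_frac = 0.24)
      height_range <- c(2.5, 7.5)
    } else {
      crown <- list(type = "ellipsoid",
                    center = 0.5 + 0.15 * shape_effect,
                    half_height = 0.30,
                    radius_frac = 0.22,
                    crown_fraction = 0.9)
      height_range <- c(2.5, 7.0)
    }
    templates[[i]] <- species_template(
      name = inventory$latin_name[i], habit = inventory$habit[i],
      crown = crown, height_range = height_range,
      point_density = point_density, reflectance_curve = curve,
      spectral_sd = spectral_sd, count = inventory$count[i])
  }
  templates
}

#' Default garden-scene configuration
#'
#' Pure function returning the generator configuration that emulates the
#' study garden: the full species inventory of [table1_fixture()] (168
#' specimens, 23 named species plus an unidentified group), a straight
#' drive-by trajectory, the line spectrometer's geometry (659 pixels over a
#' 44.4 degree vertical field of view, 123 channels over 397--1,086 nm, 10
#' outermost reference pixels), and strong multiplicative illumination
#' noise.
#'
#' @param shape_effect scales the conifer/broadleaf crown-shape difference
#'   (1 = full effect, 0 = all crowns identical cones).
#' @param spectral_effect scales between-species reflectance differences
#'   (1 = full effect, 0 = identical curves).
#' @param point_density laser returns per cubic metre of crown.
#' @param simulate_frames logical; generate spectrometer frames in
#'   [generate_scene()] (disable for structure-only studies).
#' @return a list of class `scene_config`.
#' @examples
#' cfg <- default_garden_config()
#' sum(vapply(cfg$templates, function(t) t$count, integer(1)))  # 168
#' @export
default_garden_config <- function(shape_effect = 1, spectral_effect = 1,
                                  point_density = 60,
                                  simulate_frames = TRUE) {
  bs <- band_set()
  inventory <- table1_fixture()[, c("latin_name", "habit", "count")]
  templates <- build_templates(inventory, bs, shape_effect, spectral_effect,
                               point_density = point_density)
  garden_config(templates, bs, simulate_frames = simulate_frames,
                shape_effect = shape_effect,
                spectral_effect = spectral_effect)
}

#' Assemble a garden-scene configuration from templates
#'
#' @param templates list of [species_template()] objects.
#' @param bs a [band_set()].
#' @param layout list: `spacing` (m between trees along the road), `n_rows`,
#'   `row_y` (distances of the planting rows from the trajectory, m).
#' @param trajectory list: `speed` (m/s), `frame_rate` (Hz), `sensor_height`
#'   (m), `start_margin` (m of lead-in before the first tree).
#' @param sensor list: `n_pixels`, `fov_deg`, `n_reference_pixels`,
#'   `reference_level` (digital numbers from the white panel at unit
#'   illumination), `angular_resolution_deg` (laser angular bin, the default
#'   fusion footprint).
#' @param noise list: `illumination_sdlog` (per-frame, shared by targets and
#'   references, cancelled by normalization), `pixel_sdlog` (per-pixel
#'   multiplicative lognormal), `shaded_reference_prob` and `shade_factor`
#'   (per-frame events where the target is shaded while the panel stays
#'   lit).
#' @param simulate_frames logical, generate frames in [generate_scene()].
#' @param shape_effect,spectral_effect recorded effect sizes (metadata).
#' @return a list of class `scene_config`.
#' @export
garden_config <- function(templates, bs = band_set(),
                          layout = list(spacing = 3, n_rows = 2,
                                        row_y = c(6, 9)),
                          trajectory = list(speed = 5, frame_rate = 2,
                                            sensor_height = 2,
                                            start_margin = 5),
                          sensor = list(n_pixels = 659L, fov_deg = 44.4,
                                        n_reference_pixels = 10L,
                                        reference_level = 1000,
                                        angular_resolution_deg = 0.25),
                          noise = list(illumination_sdlog = 0.5,
                                       pixel_sdlog = 0.25,
                                       shaded_reference_prob = 0.05,
                                       shade_factor = 0.3),
                          simulate_frames = TRUE,
                          shape_effect = NA_real_,
                          spectral_effect = NA_real_) {
  stopifnot(all(vapply(templates, inherits, logical(1), "species_template")))
  structure(list(templates = templates, band_set = bs, layout = layout,
                 trajectory = trajectory, sensor = sensor, noise = noise,
                 simulate_frames = simulate_frames,
                 shape_effect = shape_effect,
                 spectral_effect = spectral_effect),
            class = "scene_config")
}
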