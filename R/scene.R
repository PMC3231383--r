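#' Draw one tree specimen from a species template
#'
#' Samples a point cloud from the template's crown profile using the current
#' RNG state. Tree height is uniform over the template's height range; the
#' point count is the template's volumetric density times the crown volume,
#' with a floor of 20 points.
#'
#' For the cone profile the normalized height density is proportional to
#' the cross-sectional area `(1 - h)^2`, so `E[h_N] = 1/4`. For the
#' trunk-plus-ellipsoid profile the crown part is uniform in an ellipsoid,
#' giving the symmetric height density `3/4 (1 - u^2)` about the crown
#' center, so `E[h_N]` equals the crown center for the crown fraction.
#'
#' @param template a [species_template()].
#' @param specimen_id integer id.
#' @param origin numeric length 2, (x, y) of the stem in metres.
#' @return an object of class `tree_specimen`: list with `specimen_id`,
#'   `species`, `habit`, `origin`, `height`, and a `points` data.frame
#'   (`x`, `y`, `z`, `t`; `t` is 0 until a trajectory assigns times).
#' @export
sample_tree <- function(template, specimen_id = 1L, origin = c(0, 0)) {
  stopifnot(inherits(template, "species_template"))
  cr <- template$crown
  H <- runif(1, template$height_range[1], template$height_range[2])

  if (cr$type == "cone") {
    R <- cr$base_radius_frac * H
    volume <- pi * R^2 * H / 3
  } else {
    r <- cr$radius_frac * H
    a <- cr$half_height * H
    volume <- 4 / 3 * pi * r^2 * a
  }
  if (!is.finite(volume) || volume <= 0)
    stop("degenerate crown profile: zero volume for template '",
         template$name, "'")
  n <- max(20L, as.integer(round(template$point_density * volume)))

  if (cr$type == "cone") {
    hN <- 1 - (1 - runif(n))^(1 / 3)          # density prop. to (1 - h)^2
    rad <- cr$base_radius_frac * H * (1 - hN) * sqrt(runif(n))
  } else {
    in_crown <- runif(n) < cr$crown_fraction
    u <- numeric(n)
    nc <- sum(in_crown)
    # rejection sampling from the 3/4 (1 - u^2) height density
    got <- 0L
    while (got < nc) {
      cand <- runif(2L * (nc - got) + 8L, -1, 1)
      keep <- runif(length(cand)) < (1 - cand^2)
      cand <- cand[keep]
      take <- min(length(cand), nc - got)
      if (take > 0) u[which(in_crown)[got + seq_len(take)]] <- cand[seq_len(take)]
      got <- got + take
    }
    hN <- numeric(n)
    hN[in_crown] <- cr$center + cr$half_height * u[in_crown]
    trunk_top <- cr$center - cr$half_height
    hN[!in_crown] <- runif(n - nc, 0, trunk_top)
    rad <- numeric(n)
    rad[in_crown] <- cr$radius_frac * H *
      sqrt(pmax(0, 1 - u[in_crown]^2)) * sqrt(runif(nc))
    rad[!in_crown] <- 0.08 * sqrt(runif(n - nc))  # thin trunk, ~8 cm radius
  }
  theta <- runif(n, 0, 2 * pi)
  pts <- data.frame(x = origin[1] + rad * cos(theta),
                    y = origin[2] + rad * sin(theta),
                    z = hN * H, t = 0)
  structure(list(specimen_id = as.integer(specimen_id),
                 species = template$name, habit = template$habit,
                 origin = origin, height = H, points = pts),
            class = "tree_specimen")
}

#' @export
print.tree_specimen <- function(x, ...) {
  cat(sprintf("<tree_specimen #%d> %s (%s), height %.1f m, %d points\n",
              x$specimen_id, x$species, x$habit, x$height, nrow(x$points)))
  invisible(x)
}

# pixel center angles (degrees) of the line camera, bottom to top
pixel_centers <- function(sensor) {
  seq(-sensor$fov_deg / 2, sensor$fov_deg / 2, length.out = sensor$n_pixels)
}

#' Simulate line-spectrometer frames along a trajectory
#'
#' Each frame views the vertical plane at the sensor's along-track position
#' through a 44.4 degree vertical fan of 659 pixels. Pixels whose angular
#' bin contains laser points of a tree within the along-track slab receive
#' digital numbers `reference_level * reflectance * illumination * noise`;
#' when two trees fall in the same pixel the nearer one wins (occlusion).
#' The outermost pixels view the white reference panel and receive
#' `reference_level * illumination`, so frame-level illumination cancels
#' under normalization. With configurable probability a frame is a "shaded
#' target" event: the panel stays lit while tree pixels are multiplied by a
#' shade factor, producing dark normalized spectra.
#'
#' Points above the fan at close range are never seen, so tall near trees
#' get truncated spectral coverage.
#'
#' @param specimens list of [sample_tree()] specimens (with assigned times).
#' @param trajectory list with `t` (frame times, s), `x` (pose x, m),
#'   `speed` (m/s), `sensor_height` (m).
#' @param bs a [band_set()].
#' @param sensor,noise sensor and noise blocks as in [garden_config()].
#' @param templates list of templates named by species (for curves and
#'   noise scales).
#' @return list of `spectral_frame` objects.
#' @export
simulate_frames <- function(specimens, trajectory, bs, sensor, noise,
                            templates) {
  if (length(trajectory$t) == 0L) stop("empty trajectory")
  centers <- pixel_centers(sensor)
  spacing <- centers[2] - centers[1]
  n_px <- sensor$n_pixels
  ref_idx <- (n_px - sensor$n_reference_pixels + 1L):n_px
  slab <- trajectory$speed / (2 * trajectory$frame_rate)
  n_ch <- length(bs)
  tpl_by_name <- templates[!duplicated(vapply(templates, `[[`, "", "name"))]
  names(tpl_by_name) <- vapply(tpl_by_name, `[[`, "", "name")

  spec_x <- vapply(specimens, function(s) s$origin[1], numeric(1))
  frames <- vector("list", length(trajectory$t))
  for (f in seq_along(trajectory$t)) {
    x_f <- trajectory$x[f]
    illum <- if (noise$illumination_sdlog > 0)
      rlnorm(1, 0, noise$illumination_sdlog) else 1
    shaded <- runif(1) < noise$shaded_reference_prob
    target_factor <- if (shaded) noise$shade_factor else 1

    dn <- matrix(0, n_px, n_ch, dimnames = list(NULL, names(bs)))
    near <- which(abs(spec_x - x_f) <= slab + 2.5)  # crowns can overhang
    # per-pixel nearest specimen
    px_spec <- integer(n_px)
    px_dist <- rep(Inf, n_px)
    w <- spacing / 2 + sensor$angular_resolution_deg / 2
    max_target <- n_px - sensor$n_reference_pixels
    for (s in near) {
      pts <- specimens[[s]]$points
      sel <- abs(pts$x - x_f) <= slab
      if (!any(sel)) next
      dy <- pts$y[sel]
      ang <- atan2(pts$z[sel] - trajectory$sensor_height, dy) * 180 / pi
      # every pixel within the laser footprint of a point images the crown
      lo <- pmax(ceiling((ang - w - centers[1]) / spacing - 1e-9) + 1L, 1L)
      hi <- pmin(floor((ang + w - centers[1]) / spacing + 1e-9) + 1L,
                 max_target)
      n_cov <- hi - lo + 1L
      ok <- n_cov > 0L
      if (!any(ok)) next
      px <- sequence(n_cov[ok], from = lo[ok])
      dy <- rep(dy[ok], n_cov[ok])
      d_min <- tapply(dy, px, min)
      idx <- as.integer(names(d_min))
      closer <- d_min < px_dist[idx]
      idx <- idx[closer]
      px_spec[idx] <- s
      px_dist[idx] <- d_min[closer]
    }
    lit <- which(px_spec > 0L)
    for (s in unique(px_spec[lit])) {
      rows <- lit[px_spec[lit] == s]
      tpl <- tpl_by_name[[specimens[[s]]$species]]
      pixel_noise <- if (tpl$spectral_sd > 0)
        rlnorm(length(rows), 0, tpl$spectral_sd) else rep(1, length(rows))
      dn[rows, ] <- (sensor$reference_level * illum * target_factor *
                       pixel_noise) %o% tpl$reflectance_curve
    }
    dn[ref_idx, ] <- sensor$reference_level * illum

    frames[[f]] <- structure(
      list(timestamp = trajectory$t[f],
           pose = c(x = x_f, y = 0, heading = 0),
           sensor_height = trajectory$sensor_height,
           pixel_angles = centers, dn = dn, reference_pixels = ref_idx),
      class = "spectral_frame")
  }
  frames
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat(sprintf(
    "<spectral_frame> t=%.2fs pose=(%.1f, %.1f) %d pixels x %d channels, %d reference pixels\n",
    x$timestamp, x$pose[1], x$pose[2], nrow(x$dn), ncol(x$dn),
    length(x$reference_pixels)))
  invisible(x)
}

#' Generate a complete synthetic garden scene
#'
#' Deterministic given `(config, seed)`: plants the configured specimens in
#' staggered rows along a straight road, samples their point clouds, assigns
#' laser time stamps from the constant-speed drive past, and (optionally)
#' simulates the spectrometer frames.
#'
#' @param config a [garden_config()] / [default_garden_config()].
#' @param seed integer RNG seed.
#' @return an object of class `scene`: list with `specimens`, `frames`,
#'   `band_set`, `seed`, `config`.
#' @examples
#' sc <- generate_scene(default_garden_config(simulate_frames = FALSE), seed = 1)
#' length(sc$specimens)  # 168
#' @export
generate_scene <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  counts <- vapply(config$templates, function(t) t$count, integer(1))
  order_idx <- rep(seq_along(config$templates), counts)
  n <- length(order_idx)
  if (n == 0L) {
    return(structure(list(specimens = list(), frames = list(),
                          band_set = config$band_set, seed = seed,
                          config = config), class = "scene"))
  }
  order_idx <- sample(order_idx)

  lay <- config$layout
  traj <- config$trajectory
  specimens <- vector("list", n)
  for (i in seq_len(n)) {
    col <- ceiling(i / lay$n_rows)
    row <- ((i - 1L) %% lay$n_rows) + 1L
    x <- traj$start_margin + (col - 1) * lay$spacing +
      (row - 1) * lay$spacing / lay$n_rows
    origin <- c(x, lay$row_y[row])
    specimens[[i]] <- sample_tree(config$templates[[order_idx[i]]],
                                  specimen_id = i, origin = origin)
    # laser time stamps from the drive-by; sorted so they are non-decreasing
    pts <- specimens[[i]]$points
    pts$t <- pts$x / traj$speed
    specimens[[i]]$points <- pts[order(pts$t), , drop = FALSE]
    rownames(specimens[[i]]$points) <- NULL
  }

  frames <- list()
  if (isTRUE(config$simulate_frames)) {
    x_max <- max(vapply(specimens, function(s) max(s$points$x), numeric(1)))
    t_end <- (x_max + traj$start_margin) / traj$speed
    frame_t <- seq(0, t_end, by = 1 / traj$frame_rate)
    trajectory <- list(t = frame_t, x = traj$speed * frame_t,
                       speed = traj$speed, frame_rate = traj$frame_rate,
                       sensor_height = traj$sensor_height)
    frames <- simulate_frames(specimens, trajectory, config$band_set,
                              config$sensor, config$noise, config$templates)
  }
  structure(list(specimens = specimens, frames = frames,
                 band_set = config$band_set, seed = seed, config = config),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d specimens, %d frames (seed %d)\n",
              length(x$specimens), length(x$frames), x$seed))
  invisible(x)
}

#' Flatten scene specimens to a labelled point table
#'
#' @param specimens a `scene` or list of `tree_specimen` objects.
#' @return data.frame with columns
#'   `specimen_id,species,habit,x,y,z,t`.
#' @export
points_table <- function(specimens) {
  if (inherits(specimens, "scene")) specimens <- specimens$specimens
  if (length(specimens) == 0L)
    return(data.frame(specimen_id = integer(), species = character(),
                      habit = character(), x = numeric(), y = numeric(),
                      z = numeric(), t = numeric()))
  do.call(rbind, lapply(specimens, function(s)
    data.frame(specimen_id = s$specimen_id, species = s$species,
               habit = s$habit, s$points, row.names = NULL)))
}

#' Write / read labelled point clouds as XYZ-CSV
#'
#' Column layout `specimen_id,species,habit,x,y,z,t`.
#'
#' @param specimens a `scene` or list of specimens.
#' @param path CSV file path.
#' @return `write_points_csv` returns `path` invisibly; `read_points_csv`
#'   returns the point table data.frame.
#' @export
write_points_csv <- function(specimens, path) {
  write.csv(points_table(specimens), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "habit", "x", "y", "z", "t")
  if (!all(need %in% names(df)))
    stop("point CSV must have columns: ", paste(need, collapse = ","))
  df
}

#' Write / read spectrometer frames as long CSV
#'
#' One row per pixel with layout
#' `t,pose_x,pose_y,heading,pixel,angle_deg,ref_flag,ch001..ch123`.
#' The sensor mounting height is not part of the exchange format and must
#' be supplied again when reading.
#'
#' @param frames list of `spectral_frame` objects.
#' @param path CSV file path.
#' @param sensor_height sensor height above ground (m) used on read.
#' @return `write_frames_csv` returns `path` invisibly; `read_frames_csv`
#'   returns a list of `spectral_frame` objects.
#' @export
write_frames_csv <- function(frames, path) {
  rows <- lapply(frames, function(fr) {
    n_px <- nrow(fr$dn)
    cbind(data.frame(t = fr$timestamp, pose_x = unname(fr$pose[1]),
                     pose_y = unname(fr$pose[2]),
                     heading = unname(fr$pose[3]),
                     pixel = seq_len(n_px), angle_deg = fr$pixel_angles,
                     ref_flag = as.integer(seq_len(n_px) %in%
                                             fr$reference_pixels)),
          as.data.frame(fr$dn))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(path, sensor_height = 2) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ch_cols <- grep("^ch\\d+$", names(df), value = TRUE)
  lapply(split(df, df$t), function(d) {
    d <- d[order(d$pixel), , drop = FALSE]
    structure(list(timestamp = d$t[1],
                   pose = c(x = d$pose_x[1], y = d$pose_y[1],
                            heading = d$heading[1]),
                   sensor_height = sensor_height,
                   pixel_angles = d$angle_deg,
                   dn = as.matrix(d[, ch_cols]),
                   reference_pixels = which(d$ref_flag == 1L)),
              class = "spectral_frame")
  })
}

#' Scene manifest
#'
#' Serializes every generator parameter and the seed, sufficient to
#' regenerate the scene bit-for-bit with [generate_scene()].
#'
#' @param scene a `scene`.
#' @param path optional path; when given the manifest is written as JSON.
#' @return the manifest list, invisibly when written.
#' @export
scene_manifest <- function(scene, path = NULL) {
  cfg <- scene$config
  manifest <- list(
    package = "canopyfuse",
    version = as.character(utils::packageVersion("canopyfuse")),
    seed = scene$seed,
    n_specimens = length(scene$specimens),
    n_frames = length(scene$frames),
    shape_effect = cfg$shape_effect,
    spectral_effect = cfg$spectral_effect,
    layout = cfg$layout, trajectory = cfg$trajectory,
    sensor = cfg$sensor, noise = cfg$noise,
    band_range_nm = attr(cfg$band_set, "range_nm"),
    n_channels = length(cfg$band_set),
    templates = lapply(cfg$templates, unclass))
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
               path)
    return(invisible(manifest))
  }
  manifest
}
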