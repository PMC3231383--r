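#' Normalized point heights within a specimen
#'
#' `h_N = (z - z_min) / (z_max - z_min)` using the specimen's own extremes,
#' so values span \[0, 1\].
#'
#' @param z numeric vector of point heights (m); at least two distinct
#'   values.
#' @return numeric vector in \[0, 1\].
#' @export
normalized_heights <- function(z) {
  if (length(z) < 2L) stop("need at least 2 points")
  rng <- range(z)
  if (rng[1] == rng[2]) stop("degenerate specimen: all heights equal")
  (z - rng[1]) / (rng[2] - rng[1])
}

#' Proportion of laser hits in a normalized-height interval
#'
#' One-sided thresholds are strict (`h_N > q`, `h_N < q`); two-sided bands
#' are half-open `[lo, hi)`. With continuous heights ties have probability
#' zero, so the convention only matters for constructed inputs.
#'
#' @param h_N normalized heights in \[0, 1\].
#' @param interval one of `list(gt = q)`, `list(lt = q)`, or
#'   `list(band = c(lo, hi))`.
#' @return proportion in \[0, 1\].
#' @export
point_ratio <- function(h_N, interval) {
  n <- length(h_N)
  if (!is.null(interval$gt)) return(sum(h_N > interval$gt) / n)
  if (!is.null(interval$lt)) return(sum(h_N < interval$lt) / n)
  if (!is.null(interval$band)) {
    b <- interval$band
    return(sum(h_N >= b[1] & h_N < b[2]) / n)
  }
  stop("interval must specify gt, lt, or band")
}

#' Height quantile from the tree base
#'
#' The q-th percentile of heights above the base, with linear interpolation
#' between order statistics (R's default type-7 rule).
#'
#' @param h heights above base (m), at least one value.
#' @param q percent in (0, 100).
#' @return height in metres.
#' @export
height_quantile <- function(h, q) {
  if (length(h) < 1L) stop("need at least 1 point")
  if (q <= 0 || q >= 100) stop("q must lie in (0, 100)")
  unname(quantile(h, q / 100, type = 7))
}

#' Height-distribution moments and summaries
#'
#' Skewness and kurtosis are the third and fourth standardized moments of
#' the height distribution, computed from population central moments
#' (kurtosis is raw, normal about 3; set `excess = TRUE` for excess
#' kurtosis). `max` and `mean` summarise the supplied heights directly and
#' `cv` is the population standard deviation over the mean. Heights are
#' expected above the tree base (`z - z_min`), which is how
#' [build_feature_table()] calls this.
#'
#' @param h numeric heights, at least two values.
#' @param excess logical; subtract 3 from kurtosis.
#' @return named numeric vector `skewness`, `kurtosis`, `max`, `mean`,
#'   `cv`.
#' @export
height_moments <- function(h, excess = FALSE) {
  if (length(h) < 2L) stop("need at least 2 points")
  mu <- mean(h)
  m2 <- mean((h - mu)^2)
  if (m2 == 0) stop("zero variance: skewness/kurtosis undefined")
  m3 <- mean((h - mu)^3)
  m4 <- mean((h - mu)^4)
  if (mu == 0) stop("zero mean height: CV undefined")
  c(skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2 - if (excess) 3 else 0,
    max = max(h), mean = mu, cv = sqrt(m2) / mu)
}

#' Names of the 34 structural features
#'
#' The canopy height-distribution feature registry, in fixed column order:
#' the three coarse thirds of the normalized height range, eight interior
#' 0.1-wide bands, nine cumulative above-threshold ratios, skewness and
#' kurtosis, nine height quantiles, and maximum, mean and coefficient of
#' variation of height.
#'
#' @return character vector of length 34.
#' @export
structural_feature_names <- function() {
  c("PR_hN_lt_0.33", "PR_hN_0.33_0.67", "PR_hN_gt_0.67",
    sprintf("PR_hN_%.1f_%.1f", seq(0.1, 0.8, 0.1), seq(0.2, 0.9, 0.1)),
    sprintf("PR_hN_gt_%.1f", seq(0.1, 0.9, 0.1)),
    "skewness", "kurtosis",
    sprintf("hq%d", seq(10, 90, 10)),
    "Max", "Mean", "CV")
}

#' Compute the 34 structural features for one point cloud
#'
#' The three coarse proportions partition \[0, 1\] exactly: the top class
#' is the complement of the other two, i.e. `h_N >= 0.67` at the boundary,
#' while the nine cumulative ratios use strict `>`.
#'
#' @param z point heights (m) of one specimen; at least two distinct
#'   values.
#' @return named numeric vector of length 34 in registry order.
#' @export
structural_features <- function(z) {
  hN <- normalized_heights(z)
  h <- z - min(z)
  pr_lt33 <- point_ratio(hN, list(lt = 0.33))
  pr_mid <- point_ratio(hN, list(band = c(0.33, 0.67)))
  pr_gt67 <- 1 - (pr_lt33 + pr_mid)   # complement: partition sums to 1 exactly
  bands <- vapply(seq(0.1, 0.8, 0.1), function(lo)
    point_ratio(hN, list(band = c(lo, lo + 0.1))), numeric(1))
  above <- vapply(seq(0.1, 0.9, 0.1), function(q)
    point_ratio(hN, list(gt = q)), numeric(1))
  mom <- height_moments(h)
  hq <- vapply(seq(10, 90, 10), function(q) height_quantile(h, q),
               numeric(1))
  out <- c(pr_lt33, pr_mid, pr_gt67, bands, above,
           mom["skewness"], mom["kurtosis"], hq,
           mom["max"], mom["mean"], mom["cv"])
  names(out) <- structural_feature_names()
  out
}

#' Per-tree mean reflectance spectrum
#'
#' Averages the normalized spectra of all fused points of the specimen
#' (unweighted, over points that carry a spectrum; points without spectra
#' are ignored, never counted as zeros).
#'
#' @param cloud a `fused_cloud`.
#' @return named numeric vector of per-channel means; all-`NA` with
#'   attribute `missing = TRUE` when the specimen has no fused spectra.
#' @export
spectral_means <- function(cloud) {
  stopifnot(inherits(cloud, "fused_cloud"))
  has <- cloud$points$n_pixels > 0L
  if (!any(has)) {
    out <- rep(NA_real_, ncol(cloud$reflectance))
    names(out) <- colnames(cloud$reflectance)
    attr(out, "missing") <- TRUE
    return(out)
  }
  out <- colMeans(cloud$reflectance[has, , drop = FALSE])
  attr(out, "missing") <- FALSE
  out
}

#' Assemble the specimen-by-feature table
#'
#' One row per specimen; 34 structural columns (always complete) followed
#' by 123 spectral-mean columns (`NA` for specimens without any fused
#' spectrum, reported with a warning).
#'
#' @param clouds list of `fused_cloud` objects.
#' @param bs a [band_set()] (defines the spectral column names).
#' @return a data.frame of class `feature_table` with columns
#'   `specimen_id`, `species`, `habit`, the 34 structural features, then
#'   `ch001`..`ch123`.
#' @export
build_feature_table <- function(clouds, bs = band_set()) {
  sn <- structural_feature_names()
  cn <- names(bs)
  if (length(clouds) == 0L) {
    out <- as.data.frame(c(
      list(specimen_id = integer(), species = character(),
           habit = character()),
      stats::setNames(rep(list(numeric()), length(sn) + length(cn)),
                      c(sn, cn))))
    class(out) <- c("feature_table", "data.frame")
    return(out)
  }
  rows <- lapply(clouds, function(cl) {
    st <- tryCatch(structural_features(cl$points$z), error = function(e)
      stop("specimen ", cl$specimen_id, ": ", conditionMessage(e),
           call. = FALSE))
    sp <- spectral_means(cl)
    data.frame(specimen_id = cl$specimen_id, species = cl$species,
               habit = cl$habit, as.list(st), as.list(sp),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_missing <- sum(is.na(out[[cn[1]]]))
  if (n_missing > 0)
    warning(n_missing, " specimen(s) without fused spectra; spectral ",
            "features set to NA")
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table as CSV
#'
#' Header `specimen_id,species,habit,<34 structural names>,ch001..ch123`;
#' missing spectral cells are empty.
#'
#' @param table a `feature_table`.
#' @param path CSV file path.
#' @return `write_feature_csv` returns `path` invisibly;
#'   `read_feature_csv` returns the `feature_table`.
#' @export
write_feature_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}
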