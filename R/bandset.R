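#' Spectrometer band set
#'
#' The line spectrometer covers 397--1,086 nm, binned on the CCD into 123
#' channels. The instrument's channel centers are not published, so centers
#' are placed on a linear grid across the stated range (about 5.65 nm
#' spacing); wavelengths quoted for individual channels are resolved to the
#' nearest center with [nearest_channel()].
#'
#' @param n_channels number of binned channels (default 123).
#' @param range_nm two-element numeric, spectral range in nm.
#' @return An object of class `band_set`: a numeric vector of channel center
#'   wavelengths (nm), named `ch001`..`chNNN`.
#' @examples
#' bs <- band_set()
#' nearest_channel(bs, 988)
#' @export
band_set <- function(n_channels = 123L, range_nm = c(397, 1086)) {
  stopifnot(n_channels >= 2L, length(range_nm) == 2L, range_nm[1] < range_nm[2])
  centers <- seq(range_nm[1], range_nm[2], length.out = n_channels)
  names(centers) <- channel_names(n_channels)
  structure(centers, class = "band_set", range_nm = range_nm)
}

#' Channel column names
#'
#' @param n number of channels.
#' @return character vector `ch001`..`chNNN`.
#' @export
channel_names <- function(n = 123L) sprintf("ch%03d", seq_len(n))

#' Resolve a wavelength to the nearest channel
#'
#' @param bs a [band_set()].
#' @param wavelength_nm numeric vector of wavelengths in nm.
#' @return integer vector of channel indices.
#' @export
nearest_channel <- function(bs, wavelength_nm) {
  stopifnot(inherits(bs, "band_set"))
  vapply(wavelength_nm, function(w) which.min(abs(as.numeric(bs) - w)),
         integer(1))
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> %d channels, %.1f-%.1f nm (spacing %.2f nm)\n",
              length(x), min(x), max(x), diff(as.numeric(x[1:2]))))
  invisible(x)
}
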