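#' Amplitude of low-frequency fluctuation (ALFF) map
#'
#' Per voxel, the discrete Fourier transform of the cleaned series is taken,
#' the square root of the power spectrum (i.e. the amplitude spectrum) is
#' formed, and ALFF is its mean over the frequency bins falling in
#' `band` (default 0.01-0.08 Hz). With `normalize = TRUE` the map is
#' divided by its in-mask mean (post-division mean exactly 1).
#'
#' @param b a cleaned [bold_series()] with uniform repetition time.
#' @param band frequency band in Hz.
#' @param normalize divide by the in-mask mean (default `TRUE`).
#' @return A [voxel_volume()] ALFF map.
#' @export
alff_map <- function(b, band = c(0.01, 0.08), normalize = TRUE) {
  if (!inherits(b, "bold_series")) stop("alff_map: need a bold_series")
  alff <- alff_core(bold_matrix(b), b$tr, band, normalize)
  vol <- array(0, dim(b$mask))
  vol[b$mask] <- alff
  voxel_volume(vol, b$mask)
}

alff_core <- function(X, tr, band = c(0.01, 0.08), normalize = TRUE) {
  n <- nrow(X)
  freq <- (seq_len(n) - 1) / (n * tr)
  bins <- which(freq >= band[1] & freq <= band[2])
  if (length(bins) == 0)
    stop(sprintf(paste0("alff_map: no frequency bin in [%g, %g] Hz for ",
                        "n = %d, tr = %g; need n >= %d"),
                 band[1], band[2], n, tr, ceiling(1 / (band[2] * tr))))
  amp <- Mod(stats::mvfft(X)) / n
  alff <- colMeans(amp[bins, , drop = FALSE])
  if (normalize) alff <- alff / mean(alff)
  alff
}
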