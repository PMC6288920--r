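#' Construct an en-face angiogram image with metadata
#'
#' Bundles a 2-D grid of non-negative intensities with the scan metadata the
#' pipeline needs: scan type (macula or optic disc), device segmentation
#' layer, eye laterality, subject, scan index within the visit, and the
#' optional device signal-strength index (SSI).
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param scan_type `"macula"` or `"disc"`.
#' @param segment_label One of the device layers for the scan type; see
#'   [segment_labels()].
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param subject_id Subject identifier.
#' @param scan_index 1 or 2 (first or repeat scan of the visit).
#' @param signal_strength_index Optional device SSI; `NA` when the source
#'   provides none (synthetic phantoms, anonymised exports).
#'
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(pixels, scan_type, segment_label, laterality,
                         subject_id, scan_index,
                         signal_strength_index = NA_real_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (length(pixels) == 0L) stop("`pixels` must be non-empty", call. = FALSE)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("`pixels` must be finite and non-negative", call. = FALSE)
  scan_type <- match.arg(scan_type, c("macula", "disc"))
  segment_label <- match.arg(segment_label, segment_labels(scan_type))
  laterality <- match.arg(laterality, c("OD", "OS"))
  scan_index <- as.integer(scan_index)
  if (!scan_index %in% c(1L, 2L))
    stop("`scan_index` must be 1 or 2", call. = FALSE)
  structure(
    list(pixels = pixels, scan_type = scan_type,
         segment_label = segment_label, laterality = laterality,
         subject_id = as.character(subject_id), scan_index = scan_index,
         signal_strength_index = as.numeric(signal_strength_index)),
    class = "enface_image"
  )
}

#' Canonical segment labels per scan type
#'
#' The device segments each scan into four en-face layers; this order is
#' also the deterministic report order.
#'
#' @param scan_type `"macula"` or `"disc"`.
#' @return Character vector of four segment labels.
#' @export
segment_labels <- function(scan_type = c("macula", "disc")) {
  scan_type <- match.arg(scan_type)
  if (scan_type == "macula")
    c("superficial_retina", "deep_retina", "outer_retina", "choriocapillaris")
  else
    c("vitreoretinal_interface", "superficial_nerve_head", "rpc",
      "disc_choroid")
}

# Signed FFT sample frequencies in cycles/pixel, matching stats::fft layout.
fft_freq <- function(n) {
  f <- (seq_len(n) - 1) / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  f
}

#' Frequency-domain transfer function of the de-striping bandpass
#'
#' Builds the filter `H` applied by [gaussian_bandpass()]: a difference of
#' isotropic Gaussian transfer functions passing spatial scales between
#' `sigma_high` and `sigma_low`, optionally multiplied by a directional
#' Gaussian notch that suppresses the near-zero horizontal-frequency band
#' where full-width horizontal stripes concentrate their energy.
#'
#' A Gaussian blur of spatial scale `s` has transfer function
#' `exp(-2 pi^2 s^2 |f|^2)`; the band is the difference of the `sigma_high`
#' and `sigma_low` blurs, so `H(0) = 0` (DC removed). The notch is
#' `1 - exp(-fx^2 / (2 * (1/ncol)^2))`, i.e. attenuation of horizontal
#' frequencies below about one cycle per image width, at all vertical
#' frequencies.
#'
#' @param dim Length-2 integer, `c(nrow, ncol)` of the image.
#' @param sigma_low Spatial scale (px) of the low-frequency cut (structures
#'   slower than this are removed).
#' @param sigma_high Spatial scale (px) of the high-frequency cut
#'   (structures finer than this are removed); `0 < sigma_high < sigma_low`.
#' @param stripe_notch Apply the directional stripe notch (default `TRUE`).
#' @return Real matrix `H` in `stats::fft` frequency layout.
#' @export
bandpass_transfer <- function(dim, sigma_low = 40, sigma_high = 1.5,
                              stripe_notch = TRUE) {
  if (!(sigma_high > 0 && sigma_high < sigma_low))
    stop("require 0 < sigma_high < sigma_low", call. = FALSE)
  nr <- dim[1]; nc <- dim[2]
  fy <- fft_freq(nr)          # row frequency (vertical)
  fx <- fft_freq(nc)          # column frequency (horizontal)
  F2 <- outer(fy^2, fx^2, `+`)
  H <- exp(-2 * pi^2 * sigma_high^2 * F2) - exp(-2 * pi^2 * sigma_low^2 * F2)
  if (stripe_notch) {
    sfx <- 1 / nc             # about one cycle per image width
    notch <- 1 - exp(-fx^2 / (2 * sfx^2))
    H <- H * matrix(rep(notch, each = nr), nr, nc)
  }
  H
}

#' Gaussian bandpass filter with horizontal-stripe suppression
#'
#' Frequency-domain filtering used before vessel detection: removes slow
#' illumination gradients (scales above `sigma_low`), pixel-level noise
#' (scales below `sigma_high`), the DC offset, and — with `stripe_notch`
#' enabled — the horizontal white-line motion artifacts whose spectrum is
#' concentrated at near-zero horizontal frequency.
#'
#' @inheritParams bandpass_transfer
#' @param image Numeric matrix of finite intensities.
#' @param boundary `"periodic"` (plain FFT; wraparound is harmless for
#'   full-width stripes) or `"symmetric"` (mirror-pad to double size before
#'   filtering, then crop).
#' @return Filtered matrix, same shape, approximately zero mean.
#' @examples
#' img <- matrix(rnorm(64 * 64), 64, 64)
#' out <- gaussian_bandpass(img, sigma_low = 20, sigma_high = 1.5)
#' abs(mean(out)) < 1e-8
#' @export
gaussian_bandpass <- function(image, sigma_low = 40, sigma_high = 1.5,
                              stripe_notch = TRUE,
                              boundary = c("periodic", "symmetric")) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (any(!is.finite(image)))
    stop("image contains non-finite pixels", call. = FALSE)
  boundary <- match.arg(boundary)
  if (boundary == "symmetric") {
    nr <- nrow(image); nc <- ncol(image)
    big <- rbind(cbind(image, image[, nc:1]),
                 cbind(image[nr:1, ], image[nr:1, nc:1]))
    H <- bandpass_transfer(dim(big), sigma_low, sigma_high, stripe_notch)
    filt <- Re(fft(fft(big) * H, inverse = TRUE)) / length(big)
    return(filt[seq_len(nr), seq_len(nc), drop = FALSE])
  }
  H <- bandpass_transfer(dim(image), sigma_low, sigma_high, stripe_notch)
  Re(fft(fft(image) * H, inverse = TRUE)) / length(image)
}

#' Count white-line motion artifacts in an image
#'
#' A row is flagged as part of a white line when it is both bright — its
#' mean exceeds the global mean by `z_thresh` global standard deviations —
#' and uniform across the full width — its within-row coefficient of
#' variation is at most `max_row_cv`. Maximal runs of consecutive flagged
#' rows count as a single line (a thick saturated band is one artifact).
#'
#' @param image Numeric matrix of non-negative intensities (raw, before
#'   bandpass filtering).
#' @param z_thresh Brightness threshold in global SD units (> 0).
#' @param max_row_cv Maximum within-row coefficient of variation for a row
#'   to count as uniform.
#' @return Integer count of white lines; 0 for a constant image.
#' @export
count_white_lines <- function(image, z_thresh = 3, max_row_cv = 0.2) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (length(image) == 0L) stop("image must be non-empty", call. = FALSE)
  if (z_thresh <= 0) stop("`z_thresh` must be > 0", call. = FALSE)
  g_mean <- mean(image)
  g_sd <- sd(as.vector(image))
  if (!is.finite(g_sd) || g_sd == 0) return(0L)
  row_mean <- rowMeans(image)
  row_sd <- apply(image, 1, sd)
  row_cv <- ifelse(row_mean > 0, row_sd / row_mean, Inf)
  flagged <- row_mean > g_mean + z_thresh * g_sd & row_cv <= max_row_cv
  runs <- rle(flagged)
  sum(runs$values)
}

#' Quality-control decision for one segment image
#'
#' Applies the acquisition-review rules: a segment with more than two white
#' lines has high motion artifact; a recorded signal-strength index below
#' `ssi_min` fails the signal gate; either condition discards the segment.
#' Segments are discarded individually — other segments of the same scan
#' remain usable. Images without a recorded SSI pass the signal gate.
#'
#' @param image An [enface_image()] (only its SSI metadata is consulted).
#' @param white_line_count Non-negative integer from [count_white_lines()].
#' @param ssi_min Minimum acceptable signal-strength index (default 40).
#' @return A list of class `qc_report` with fields `white_line_count`,
#'   `high_motion`, `ssi_pass`, `discarded`.
#' @export
qc_evaluate <- function(image, white_line_count, ssi_min = 40) {
  if (!inherits(image, "enface_image"))
    stop("`image` must be an enface_image", call. = FALSE)
  white_line_count <- as.integer(white_line_count)
  if (white_line_count < 0)
    stop("`white_line_count` must be >= 0", call. = FALSE)
  ssi <- image$signal_strength_index
  high_motion <- white_line_count > 2L
  ssi_pass <- is.na(ssi) || ssi >= ssi_min
  structure(
    list(white_line_count = white_line_count,
         high_motion = high_motion,
         ssi_pass = ssi_pass,
         discarded = high_motion || !ssi_pass),
    class = "qc_report"
  )
}
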