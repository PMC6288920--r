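#' Configuration for a synthetic angiogram phantom
#'
#' Defines a square en-face phantom populated with curvilinear bright vessels
#' (constant-curvature arcs rendered with a Gaussian cross-sectional profile)
#' on a speckled background, optionally corrupted by full-width horizontal
#' white-line motion artifacts.
#'
#' Defaults emulate a 3 x 3 mm en-face angiogram cube exported on a
#' 304 x 304 grid: capillary-to-arteriole vessel half-widths of 1.5-3 px,
#' centerline curvatures within the detector's default curvature band, and
#' additive Gaussian speckle.
#'
#' @param grid_size Pixels per side of the square grid (>= 32).
#' @param n_vessels Number of vessels to render (>= 0).
#' @param width_range Length-2 numeric, vessel half-width in pixels
#'   (min, max); the truth mask marks pixels within the half-width of a
#'   centerline.
#' @param curvature_range Length-2 numeric, centerline curvature in 1/pixels
#'   (min, max); each vessel is a constant-curvature arc.
#' @param vessel_intensity Peak centerline brightness (arbitrary units).
#' @param background_noise_sd Standard deviation of the additive Gaussian
#'   speckle applied after rendering (>= 0).
#' @param n_artifact_lines Number of saturated white-line rows to inject
#'   (>= 0).
#' @param seed Integer random seed; fixes the phantom bit-exactly.
#'
#' @return An object of class `phantom_config`.
#' @seealso [generate_vessel_network()], [add_motion_artifacts()]
#' @export
phantom_config <- function(grid_size = 304L,
                           n_vessels = 12L,
                           width_range = c(1.5, 3),
                           curvature_range = c(-0.08, 0.08),
                           vessel_intensity = 1,
                           background_noise_sd = 0.05,
                           n_artifact_lines = 0L,
                           seed = 1L) {
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 1L || is.na(grid_size) || grid_size <= 0L)
    stop("`grid_size` must be a single positive integer", call. = FALSE)
  if (grid_size < 32L)
    stop("`grid_size` must be >= 32", call. = FALSE)
  n_vessels <- as.integer(n_vessels)
  if (n_vessels < 0L) stop("`n_vessels` must be >= 0", call. = FALSE)
  stopifnot(length(width_range) == 2L, length(curvature_range) == 2L)
  if (width_range[1] > width_range[2])
    stop("`width_range` must be (min, max) with min <= max", call. = FALSE)
  if (width_range[1] <= 0)
    stop("vessel half-widths must be positive", call. = FALSE)
  if (curvature_range[1] > curvature_range[2])
    stop("`curvature_range` must be (min, max) with min <= max", call. = FALSE)
  if (background_noise_sd < 0)
    stop("`background_noise_sd` must be >= 0", call. = FALSE)
  if (n_artifact_lines < 0)
    stop("`n_artifact_lines` must be >= 0", call. = FALSE)
  structure(
    list(grid_size = grid_size, n_vessels = n_vessels,
         width_range = as.numeric(width_range),
         curvature_range = as.numeric(curvature_range),
         vessel_intensity = as.numeric(vessel_intensity),
         background_noise_sd = as.numeric(background_noise_sd),
         n_artifact_lines = as.integer(n_artifact_lines),
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Exact distance from every pixel center to a constant-curvature arc.
# The arc starts at (x0, y0), initial direction `phi` (radians, image frame:
# x right, y down), signed curvature `k` (1/px), arc length `len`.
# Pixel centers sit at integer 0-based coordinates. Returns an
# nrow x ncol matrix of Euclidean distances.
arc_distance_field <- function(shape, x0, y0, phi, k, len) {
  nr <- shape[1]; nc <- shape[2]
  X <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  if (abs(k) < 1e-8) {
    ux <- cos(phi); uy <- sin(phi)
    t <- pmin(pmax((X - x0) * ux + (Y - y0) * uy, 0), len)
    sqrt((X - (x0 + t * ux))^2 + (Y - (y0 + t * uy))^2)
  } else {
    R <- 1 / abs(k)
    # circle center sits on the normal, on the side the arc bends towards
    cx <- x0 - sin(phi) / k
    cy <- y0 + cos(phi) / k
    a0 <- atan2(y0 - cy, x0 - cx)
    sweep <- abs(k) * len
    vx <- X - cx; vy <- Y - cy
    r <- sqrt(vx^2 + vy^2)
    ang <- atan2(vy, vx)
    u <- ((ang - a0) * sign(k)) %% (2 * pi)
    on_arc <- u <= sweep
    a1 <- a0 + sign(k) * sweep
    x1 <- cx + R * cos(a1); y1 <- cy + R * sin(a1)
    d_end <- pmin(sqrt((X - x0)^2 + (Y - y0)^2),
                  sqrt((X - x1)^2 + (Y - y1)^2))
    ifelse(on_arc, abs(r - R), d_end)
  }
}

#' Generate a synthetic vessel network phantom
#'
#' Renders `n_vessels` smooth constant-curvature arcs with Gaussian
#' cross-sectional intensity profiles onto a square grid, records the ground
#' truth vessel mask (pixels within the drawn half-width of a centerline),
#' then adds Gaussian background speckle and, if configured, white-line
#' motion artifacts. Overlapping vessels combine by pointwise maximum.
#'
#' The cross-sectional profile of a vessel of half-width `w` is
#' `vessel_intensity * exp(-d^2 / (2 * (w/2)^2))` at distance `d` from the
#' centerline, so the truth-mask edge (`d = w`) sits at two profile sigmas.
#'
#' @param config A [phantom_config()].
#' @param vessels Optional data frame overriding the random geometry, with
#'   columns `x0`, `y0`, `phi`, `k`, `width`, `length` (0-based pixel
#'   coordinates, radians, 1/px, px, px). When supplied, `n_vessels` is
#'   ignored and no vessel parameters are drawn.
#'
#' @return A list of class `phantom` with elements `intensity` (numeric
#'   matrix), `truth_mask` (logical matrix), `vessels` (geometry data frame)
#'   and `config`.
#' @examples
#' ph <- generate_vessel_network(phantom_config(grid_size = 64, n_vessels = 3))
#' mean(ph$truth_mask)  # truth vessel density
#' @export
generate_vessel_network <- function(config, vessels = NULL) {
  if (!inherits(config, "phantom_config"))
    stop("`config` must be a phantom_config", call. = FALSE)
  n <- config$grid_size
  set.seed(config$seed)
  if (is.null(vessels)) {
    nv <- config$n_vessels
    vessels <- data.frame(
      x0 = runif(nv, 0.1 * n, 0.9 * n),
      y0 = runif(nv, 0.1 * n, 0.9 * n),
      phi = runif(nv, 0, 2 * pi),
      k = runif(nv, config$curvature_range[1], config$curvature_range[2]),
      width = runif(nv, config$width_range[1], config$width_range[2]),
      length = runif(nv, 0.5 * n, 1.1 * n)
    )
  } else {
    needed <- c("x0", "y0", "phi", "k", "width", "length")
    if (!all(needed %in% names(vessels)))
      stop("`vessels` must have columns ", paste(needed, collapse = ", "),
           call. = FALSE)
  }
  intensity <- matrix(0, n, n)
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(vessels))) {
    v <- vessels[i, ]
    d <- arc_distance_field(c(n, n), v$x0, v$y0, v$phi, v$k, v$length)
    prof <- config$vessel_intensity * exp(-d^2 / (2 * (v$width / 2)^2))
    intensity <- pmax(intensity, prof)
    mask <- mask | (d <= v$width)
  }
  if (config$background_noise_sd > 0)
    intensity <- pmax(intensity +
                        matrix(rnorm(n * n, 0, config$background_noise_sd),
                               n, n), 0)
  if (config$n_artifact_lines > 0)
    intensity <- add_motion_artifacts(intensity, config$n_artifact_lines,
                                      seed = config$seed + 1L)
  structure(list(intensity = intensity, truth_mask = mask,
                 vessels = vessels, config = config),
            class = "phantom")
}

#' Inject white-line motion artifacts into an image
#'
#' Sets `n_lines` distinct, pairwise non-adjacent rows to a saturated
#' constant intensity, emulating the full-width horizontal white lines that
#' eye movement leaves on en-face angiograms. Rows are chosen
#' pseudo-randomly from the seed; the input is not modified.
#'
#' @param image Numeric matrix of intensities.
#' @param n_lines Number of lines to insert (0 <= n_lines < nrow(image)).
#' @param seed Integer seed for the row choice.
#' @param level Saturation intensity; default 120% of the current image
#'   maximum (or 1 for an all-zero image).
#'
#' @return A new intensity matrix with the artifact rows set to `level`.
#' @export
add_motion_artifacts <- function(image, n_lines, seed = 1L, level = NULL) {
  stopifnot(is.matrix(image), is.numeric(image))
  n_lines <- as.integer(n_lines)
  if (n_lines < 0) stop("`n_lines` must be >= 0", call. = FALSE)
  if (n_lines >= nrow(image))
    stop("`n_lines` must be smaller than the image height", call. = FALSE)
  if (n_lines == 0L) return(image)
  if (n_lines > ceiling(nrow(image) / 2))
    stop("cannot place ", n_lines, " non-adjacent lines in ",
         nrow(image), " rows", call. = FALSE)
  if (is.null(level)) {
    mx <- max(image)
    level <- if (mx > 0) 1.2 * mx else 1
  }
  set.seed(as.integer(seed))
  available <- seq_len(nrow(image))
  rows <- integer(0)
  for (i in seq_len(n_lines)) {
    if (length(available) == 0L)
      stop("cannot place ", n_lines, " non-adjacent lines in ",
           nrow(image), " rows", call. = FALSE)
    r <- if (length(available) == 1L) available else sample(available, 1L)
    rows <- c(rows, r)
    available <- setdiff(available, c(r - 1L, r, r + 1L))
  }
  out <- image
  out[rows, ] <- level
  out
}

#' Configuration for paired-scan density simulation
#'
#' Describes a cohort in which each subject's eye has one true regional
#' vessel density and two observed scans of it, the observation error having
#' a controlled within-subject standard deviation. This is the synthetic
#' stand-in for a test-retest repeatability cohort.
#'
#' Defaults match the repeatability study scale this package targets:
#' 47 subjects, mean density 0.22, within-subject SD 0.02.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param true_density_mean Mean of the true densities (fraction).
#' @param between_subject_sd SD of true densities across subjects (>= 0).
#' @param within_subject_sd SD of the scan-to-scan observation error
#'   (>= 0); this is the sigma_w that [within_subject_sd()] estimates.
#' @param seed Integer random seed.
#'
#' @return An object of class `paired_scan_config`.
#' @export
paired_scan_config <- function(n_subjects = 47L,
                               true_density_mean = 0.22,
                               between_subject_sd = 0.05,
                               within_subject_sd = 0.02,
                               seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("`n_subjects` must be >= 2", call. = FALSE)
  if (between_subject_sd < 0 || within_subject_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (true_density_mean < 0 || true_density_mean > 1)
    stop("`true_density_mean` must be a fraction in [0, 1]", call. = FALSE)
  structure(
    list(n_subjects = n_subjects,
         true_density_mean = as.numeric(true_density_mean),
         between_subject_sd = as.numeric(between_subject_sd),
         within_subject_sd = as.numeric(within_subject_sd),
         seed = as.integer(seed)),
    class = "paired_scan_config"
  )
}

#' Simulate paired test-retest density measurements
#'
#' Per subject, draws a true density from
#' `Normal(true_density_mean, between_subject_sd)` and two observed scans
#' `truth + Normal(0, within_subject_sd)`; all densities are truncated to
#' the unit interval (a slight bias at the extremes, documented rather than
#' resampled away).
#'
#' @param config A [paired_scan_config()].
#' @return A data frame with columns `subject_id`, `true_density`,
#'   `value_1`, `value_2`.
#' @examples
#' pairs <- generate_paired_scans(paired_scan_config(n_subjects = 10))
#' within_subject_sd(pairs)
#' @export
generate_paired_scans <- function(config) {
  if (!inherits(config, "paired_scan_config"))
    stop("`config` must be a paired_scan_config", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_subjects
  truth <- rnorm(n, config$true_density_mean, config$between_subject_sd)
  v1 <- truth + rnorm(n, 0, config$within_subject_sd)
  v2 <- truth + rnorm(n, 0, config$within_subject_sd)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    true_density = clamp01(truth),
    value_1 = clamp01(v1),
    value_2 = clamp01(v2)
  )
}
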