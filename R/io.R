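#' Read a grayscale en-face image from PNG or TIFF
#'
#' Multi-channel files are averaged to one channel. Intensities are
#' returned as stored by the reader (0-1 for 8/16-bit files).
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix of intensities.
#' @export
read_enface <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF files",
             call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  arr
}

#' Write a grayscale image as PNG
#'
#' Intensities are rescaled to `[0, 1]` by the given maximum (default the
#' image maximum) before writing; logical masks become 0/255 images.
#'
#' @param image Numeric or logical matrix.
#' @param path Output path.
#' @param max_value Intensity mapped to white; default `max(image)`.
#' @return `path`, invisibly.
#' @export
write_enface <- function(image, path, max_value = NULL) {
  if (is.logical(image)) {
    arr <- image * 1
  } else {
    if (is.null(max_value)) max_value <- max(image)
    arr <- if (max_value > 0) pmin(pmax(image / max_value, 0), 1) else image * 0
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the density pipeline in one nested list;
#' [read_config()] and [write_config()] round-trip it through a flat
#' `key: value` text file with dotted keys (e.g. `bandpass.sigma_low: 40`).
#'
#' @param ... Dotted-key overrides, e.g.
#'   `pipeline_config("scird.n_theta" = 8)`.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    bandpass = list(sigma_low = 40, sigma_high = 1.5, stripe_notch = TRUE),
    qc = list(z_thresh = 3, max_row_cv = 0.2, ssi_min = 40),
    scird = list(sigma1 = c(4, 6, 8), sigma2 = c(1, 1.5, 2, 3),
                 k = c(-0.1, -0.05, 0, 0.05, 0.1), n_theta = 12,
                 halfsize = NA, threshold_method = "percentile",
                 threshold_param = 0.25),
    region = list(disc_interior = "include", od_nasal_side = "right"),
    stats = list(ci_method = "normal")
  )
  dots <- list(...)
  for (key in names(dots)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(cfg[[parts[1]]]))
      stop("unknown config key: ", key, call. = FALSE)
    cfg[[parts[1]]][[parts[2]]] <- dots[[key]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path Path of a flat `key: value` config file; values may be
#'   comma-separated lists, `true`/`false`, or numbers.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) num
      else if (all(tolower(parts) %in% c("true", "false")))
        tolower(parts) == "true"
      else parts
    overrides[[key]] <- parsed
  }
  do.call(pipeline_config, overrides)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  for (sec in names(unclass(config))) {
    for (key in names(config[[sec]])) {
      v <- config[[sec]][[key]]
      lines <- c(lines, sprintf("%s.%s: %s", sec, key,
                                paste(tolower(as.character(v)),
                                      collapse = ", ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Run manifest: config snapshot, input checksums, versions, seeds, counts.
write_manifest <- function(path, config, inputs = character(0),
                           seed = NULL, counts = list()) {
  manifest <- list(
    software = paste0("angioquant ",
                      as.character(utils::packageVersion("angioquant"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    inputs = if (length(inputs))
      data.frame(path = inputs,
                 md5 = unname(tools::md5sum(inputs)),
                 stringsAsFactors = FALSE)
      else list(),
    counts = counts
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
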