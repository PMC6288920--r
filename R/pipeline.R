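#' Write a self-contained synthetic OCTA dataset
#'
#' Generates phantom en-face images with ground-truth vessel masks for
#' `n_subjects_imaged` subjects (two scans, four segments each), a
#' paired-density table covering every (eye, segment, region) group of a
#' simulated repeatability cohort, the image-metadata table that
#' [run_density()] consumes, and a run manifest.
#'
#' @param out_dir Output directory (created if missing).
#' @param phantom A [phantom_config()]; its seed is combined with the image
#'   index so each phantom differs.
#' @param paired A [paired_scan_config()] for the density cohort.
#' @param n_subjects_imaged Subjects for which phantom images are written.
#' @param scan_type Scan type of the phantom images.
#' @return Invisibly, a list with `metadata` (data frame),
#'   `paired_densities` (data frame), and the file paths written.
#' @export
run_simulate <- function(out_dir, phantom = phantom_config(),
                         paired = paired_scan_config(),
                         n_subjects_imaged = 1L,
                         scan_type = c("macula", "disc")) {
  scan_type <- match.arg(scan_type)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  img_dir <- file.path(out_dir, "images")
  mask_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, showWarnings = FALSE)
  dir.create(mask_dir, showWarnings = FALSE)

  segs <- segment_labels(scan_type)
  meta <- list()
  idx <- 0L
  for (s in seq_len(n_subjects_imaged)) {
    sid <- sprintf("S%03d", s)
    for (scan in 1:2) {
      for (seg in segs) {
        idx <- idx + 1L
        cfg <- phantom
        cfg$seed <- phantom$seed + idx
        ph <- generate_vessel_network(cfg)
        base <- sprintf("%s_OD_%s_%s_scan%d", sid, scan_type, seg, scan)
        img_path <- file.path(img_dir, paste0(base, ".png"))
        mask_path <- file.path(mask_dir, paste0(base, "_truth.png"))
        write_enface(ph$intensity, img_path,
                     max_value = 1.5 * phantom$vessel_intensity)
        write_enface(ph$truth_mask, mask_path)
        meta[[idx]] <- data.frame(
          subject_id = sid, eye = "OD", scan_type = scan_type,
          segment_label = seg, scan_index = scan, path = img_path,
          ssi = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  metadata <- do.call(rbind, meta)
  meta_path <- file.path(out_dir, "metadata.csv")
  write.csv(metadata, meta_path, row.names = FALSE)

  # paired densities for every (eye, segment, region) group of the cohort
  groups <- expand.grid(region = region_order, segment_label = segs,
                        eye = c("OD", "OS"), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  paired_rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    cfg <- paired
    cfg$seed <- paired$seed + i
    sim <- generate_paired_scans(cfg)
    long <- rbind(
      data.frame(subject_id = sim$subject_id, scan_index = 1L,
                 density = sim$value_1, stringsAsFactors = FALSE),
      data.frame(subject_id = sim$subject_id, scan_index = 2L,
                 density = sim$value_2, stringsAsFactors = FALSE))
    cbind(data.frame(eye = g$eye, scan_type = scan_type,
                     segment_label = g$segment_label, region = g$region,
                     stringsAsFactors = FALSE)[rep(1, nrow(long)), ],
          long)
  })
  paired_densities <- do.call(rbind, paired_rows)
  rownames(paired_densities) <- NULL
  paired_path <- file.path(out_dir, "paired_densities.csv")
  write.csv(paired_densities, paired_path, row.names = FALSE)

  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest_path, pipeline_config(),
                 inputs = metadata$path,
                 seed = c(phantom = phantom$seed, paired = paired$seed),
                 counts = list(images = nrow(metadata),
                               paired_rows = nrow(paired_densities)))
  invisible(list(metadata = metadata, paired_densities = paired_densities,
                 paths = list(metadata = meta_path, paired = paired_path,
                              manifest = manifest_path)))
}

scird_bank_from_config <- function(config) {
  hs <- config$scird$halfsize
  scird_bank(sigma1 = config$scird$sigma1, sigma2 = config$scird$sigma2,
             k = config$scird$k, n_theta = config$scird$n_theta,
             halfsize = if (is.null(hs) || is.na(hs)) NULL else hs)
}

#' Run the density pipeline over a set of en-face images
#'
#' For every image listed in the metadata table: counts white lines and
#' applies the QC gates; for retained segments, bandpass-filters the image,
#' computes the SCIRD response with the configured bank, binarizes it into
#' a vessel map, builds the region set (disc scans need an annotation) and
#' computes the per-region densities. Per-file failures are collected; the
#' run aborts only if no file succeeds.
#'
#' @param metadata Data frame or CSV path with columns `subject_id`, `eye`,
#'   `scan_type`, `segment_label`, `scan_index`, `path` and optionally
#'   `ssi`.
#' @param out_dir Output directory for `density.csv`, `qc.csv` and
#'   `manifest.json`; `NULL` to skip writing.
#' @param annotations Data frame or CSV path with columns `subject_id`,
#'   `eye`, `x_min`, `y_min`, `x_max`, `y_max` (0-based, max-exclusive);
#'   required when disc scans are present.
#' @param config A [pipeline_config()].
#' @return A list with `density` (data frame of density records), `qc`
#'   (per-image QC table) and `errors` (named character vector of per-file
#'   failures).
#' @export
run_density <- function(metadata, out_dir = NULL, annotations = NULL,
                        config = pipeline_config()) {
  if (is.character(metadata)) metadata <- read.csv(metadata)
  if (is.character(annotations)) annotations <- read.csv(annotations)
  if (!is.data.frame(metadata) || nrow(metadata) == 0L)
    stop("no input images", call. = FALSE)
  needed <- c("subject_id", "eye", "scan_type", "segment_label",
              "scan_index", "path")
  if (!all(needed %in% names(metadata)))
    stop("metadata must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (!"ssi" %in% names(metadata)) metadata$ssi <- NA_real_

  bank <- scird_bank_from_config(config)
  qc_rows <- list()
  density_rows <- list()
  errors <- character(0)
  n_ok <- 0L

  scan_key <- interaction(metadata$subject_id, metadata$eye,
                          metadata$scan_type, metadata$scan_index,
                          drop = TRUE)
  for (grp in levels(scan_key)) {
    rows <- metadata[scan_key == grp, ]
    vessel_maps <- list()
    region_sets <- list()
    for (j in seq_len(nrow(rows))) {
      r <- rows[j, ]
      result <- tryCatch({
        pix <- read_enface(r$path)
        img <- enface_image(pix, r$scan_type, r$segment_label, r$eye,
                            r$subject_id, r$scan_index,
                            signal_strength_index = r$ssi)
        wl <- count_white_lines(pix, config$qc$z_thresh,
                                config$qc$max_row_cv)
        qc <- qc_evaluate(img, wl, config$qc$ssi_min)
        qc_rows[[length(qc_rows) + 1L]] <- data.frame(
          subject_id = r$subject_id, eye = r$eye, scan_type = r$scan_type,
          segment_label = r$segment_label, scan_index = r$scan_index,
          white_lines = qc$white_line_count, ssi = r$ssi,
          discarded = qc$discarded, stringsAsFactors = FALSE)
        if (!qc$discarded) {
          filt <- gaussian_bandpass(pix, config$bandpass$sigma_low,
                                    config$bandpass$sigma_high,
                                    config$bandpass$stripe_notch)
          resp <- scird_response(filt, bank)
          vm <- binarize_vessels(resp, config$scird$threshold_method,
                                 config$scird$threshold_param)
          ann <- NULL
          if (r$scan_type == "disc") {
            if (is.null(annotations))
              stop("disc scan without annotation table: ", r$path,
                   call. = FALSE)
            hit <- annotations[annotations$subject_id == r$subject_id &
                                 annotations$eye == r$eye, ]
            if (nrow(hit) != 1L)
              stop("need exactly one disc annotation for ", r$subject_id,
                   "/", r$eye, call. = FALSE)
            ann <- disc_annotation(hit$x_min, hit$y_min, hit$x_max,
                                   hit$y_max)
          }
          rs <- build_region_set(img, ann, config$region$disc_interior,
                                 config$region$od_nasal_side)
          vessel_maps[[r$segment_label]] <- vm
          region_sets[[r$segment_label]] <- rs
        }
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(result)) errors[r$path] <- result else n_ok <- n_ok + 1L
    }
    if (length(vessel_maps)) {
      md <- list(subject_id = rows$subject_id[1], eye = rows$eye[1],
                 scan_type = rows$scan_type[1],
                 scan_index = rows$scan_index[1])
      density_rows[[grp]] <- density_table(vessel_maps, region_sets, md)
    }
  }
  if (n_ok == 0L)
    stop("no input image could be processed:\n",
         paste(sprintf("  %s: %s", names(errors), errors), collapse = "\n"),
         call. = FALSE)
  density <- if (length(density_rows)) {
    out <- do.call(rbind, density_rows)
    rownames(out) <- NULL
    out
  } else NULL
  qc <- do.call(rbind, qc_rows)
  rownames(qc) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(density))
      write.csv(density, file.path(out_dir, "density.csv"),
                row.names = FALSE)
    write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
    write_manifest(file.path(out_dir, "manifest.json"), config,
                   inputs = metadata$path,
                   counts = list(images_in = nrow(metadata),
                                 discarded = sum(qc$discarded),
                                 failed = length(errors),
                                 density_rows =
                                   if (is.null(density)) 0L
                                   else nrow(density)))
  }
  list(density = density, qc = qc, errors = errors)
}

# Pivot a long density table (scan_index 1/2) into paired measurements.
pair_scans <- function(density) {
  keys <- c("subject_id", "eye", "scan_type", "segment_label", "region")
  keys <- intersect(keys, names(density))
  s1 <- density[density$scan_index == 1L, c(keys, "density")]
  s2 <- density[density$scan_index == 2L, c(keys, "density")]
  names(s1)[names(s1) == "density"] <- "value_1"
  names(s2)[names(s2) == "density"] <- "value_2"
  merge(s1, s2, by = keys, all = TRUE)
}

#' Run the test-retest repeatability analysis
#'
#' Pairs first and repeat scans from a long density table and emits the
#' per-region repeatability report (see [repeatability_report()]). Input
#' must contain both `scan_index` 1 and 2.
#'
#' @param density Data frame or CSV path with columns `subject_id`, `eye`,
#'   `scan_type`, `segment_label`, `region`, `scan_index`, `density`.
#' @param out_file Optional CSV path for the report.
#' @param config A [pipeline_config()] (CI method is taken from
#'   `stats.ci_method`).
#' @return The repeatability report data frame, with a `scan_type` column
#'   when several scan types are present.
#' @export
run_repeatability <- function(density, out_file = NULL,
                              config = pipeline_config()) {
  if (is.character(density)) density <- read.csv(density)
  stopifnot(is.data.frame(density))
  present <- sort(unique(density$scan_index))
  for (want in 1:2)
    if (!want %in% present)
      stop("density table is missing scan_index ", want,
           "; repeatability needs both scans", call. = FALSE)
  types <- unique(density$scan_type)
  reports <- lapply(types, function(tp) {
    pairs <- pair_scans(density[density$scan_type == tp, ])
    pairs$scan_type <- tp
    rep <- repeatability_report(pairs, ci_method = config$stats$ci_method)
    cbind(scan_type = tp, rep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  if (!is.null(out_file)) write.csv(out, out_file, row.names = FALSE)
  out
}

#' Simulate, quantify and analyse in one call
#'
#' Convenience wrapper chaining [run_simulate()], [run_density()] on the
#' simulated images, and [run_repeatability()] on the simulated paired
#' densities.
#'
#' @inheritParams run_simulate
#' @param config A [pipeline_config()].
#' @return List with `simulate`, `density` and `repeatability` results.
#' @export
run_all <- function(out_dir, phantom = phantom_config(),
                    paired = paired_scan_config(),
                    n_subjects_imaged = 1L, config = pipeline_config()) {
  sim <- run_simulate(out_dir, phantom, paired, n_subjects_imaged)
  dens <- run_density(sim$metadata, out_dir = file.path(out_dir, "density"),
                      config = config)
  rep <- run_repeatability(sim$paired_densities,
                           out_file = file.path(out_dir,
                                                "repeatability.csv"),
                           config = config)
  invisible(list(simulate = sim, density = dens, repeatability = rep))
}
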