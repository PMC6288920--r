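#' Vessel pixel density within a region
#'
#' The fraction of region pixels classified as vessel:
#' `density = |vessel & region| / |region|`. An empty region is an error —
#' it is not the same thing as a region without vessels.
#'
#' @param vessel_map Logical matrix from [binarize_vessels()].
#' @param region_mask Logical matrix of the same shape.
#' @return A list with `density` (fraction in `[0, 1]`), `vessel_pixels`
#'   and `region_pixels`; `density * region_pixels == vessel_pixels`
#'   exactly.
#' @examples
#' vm <- matrix(c(TRUE, FALSE), 10, 10)
#' vessel_density(vm, matrix(TRUE, 10, 10))$density
#' @export
vessel_density <- function(vessel_map, region_mask) {
  stopifnot(is.matrix(vessel_map), is.matrix(region_mask))
  if (!all(dim(vessel_map) == dim(region_mask)))
    stop("vessel map and region mask differ in shape", call. = FALSE)
  region_pixels <- sum(region_mask)
  if (region_pixels == 0L)
    stop("empty region: density is undefined (not zero)", call. = FALSE)
  vessel_pixels <- sum(vessel_map & region_mask)
  list(density = vessel_pixels / region_pixels,
       vessel_pixels = as.integer(vessel_pixels),
       region_pixels = as.integer(region_pixels))
}

# Region report order within one segment.
region_order <- c("segment", "superior", "inferior", "nasal", "temporal")

#' Per-region density table for one scan
#'
#' Computes one density record per (segment, region): the whole segment
#' plus its four quadrants, five regions per segment, in deterministic
#' order (segments in the canonical device order, then segment, superior,
#' inferior, nasal, temporal). Whenever the quadrants tile the segment,
#' segment counts equal the sum of quadrant counts; this is asserted on
#' every call.
#'
#' @param vessel_maps Named list of logical vessel maps, one per segment
#'   label.
#' @param region_sets Named list of [build_region_set()] results with the
#'   same names.
#' @param metadata List with `subject_id`, `eye`, `scan_type`,
#'   `scan_index`.
#' @return A data frame with columns `subject_id`, `eye`, `scan_type`,
#'   `segment_label`, `region`, `scan_index`, `density`, `vessel_pixels`,
#'   `region_pixels`.
#' @export
density_table <- function(vessel_maps, region_sets, metadata) {
  stopifnot(is.list(vessel_maps), is.list(region_sets))
  missing_rs <- setdiff(names(vessel_maps), names(region_sets))
  missing_vm <- setdiff(names(region_sets), names(vessel_maps))
  if (length(missing_rs) || length(missing_vm))
    stop("segment keys do not align; missing region sets: [",
         paste(missing_rs, collapse = ", "), "], missing vessel maps: [",
         paste(missing_vm, collapse = ", "), "]", call. = FALSE)
  canonical <- segment_labels(metadata$scan_type)
  segs <- c(intersect(canonical, names(vessel_maps)),
            setdiff(names(vessel_maps), canonical))
  rows <- list()
  for (seg in segs) {
    vm <- vessel_maps[[seg]]
    rs <- region_sets[[seg]]
    masks <- c(list(segment = rs$segment_mask), rs$quadrant_masks)
    recs <- lapply(region_order, function(rg) {
      d <- vessel_density(vm, masks[[rg]])
      data.frame(subject_id = metadata$subject_id, eye = metadata$eye,
                 scan_type = metadata$scan_type, segment_label = seg,
                 region = rg, scan_index = as.integer(metadata$scan_index),
                 density = d$density, vessel_pixels = d$vessel_pixels,
                 region_pixels = d$region_pixels,
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    # aggregation consistency: segment counts = sum of quadrant counts
    quad <- recs$region != "segment"
    stopifnot(sum(recs$vessel_pixels[quad]) == recs$vessel_pixels[1],
              sum(recs$region_pixels[quad]) == recs$region_pixels[1])
    rows[[seg]] <- recs
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
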