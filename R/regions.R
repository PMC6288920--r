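#' Optic-disc bounding-box annotation
#'
#' A manually drawn, axis-aligned minimum bounding box of the optic disc in
#' 0-based pixel coordinates (pixel centers at integers, y increasing
#' downward), inclusive on the minima and exclusive on the maxima.
#'
#' @param x_min,y_min,x_max,y_max Box corners; `x_min < x_max`,
#'   `y_min < y_max`.
#' @return An object of class `disc_annotation`.
#' @export
disc_annotation <- function(x_min, y_min, x_max, y_max) {
  if (!(x_min < x_max && y_min < y_max))
    stop("degenerate bounding box: need x_min < x_max and y_min < y_max",
         call. = FALSE)
  structure(list(x_min = x_min, y_min = y_min,
                 x_max = x_max, y_max = y_max),
            class = "disc_annotation")
}

#' Inscribed ellipse of a disc bounding box
#'
#' Approximates the optic-disc border as the axis-aligned ellipse inscribed
#' in the annotated bounding box: center at the box midpoint, semi-axes of
#' half the side lengths.
#'
#' @param annotation A [disc_annotation()].
#' @return An object of class `ellipse_geometry` with fields `center`
#'   (`c(cx, cy)`) and `semi_axes` (`c(a, b)`).
#' @examples
#' ellipse_from_bbox(disc_annotation(10, 20, 50, 60))
#' @export
ellipse_from_bbox <- function(annotation) {
  if (!inherits(annotation, "disc_annotation"))
    stop("`annotation` must be a disc_annotation", call. = FALSE)
  a <- (annotation$x_max - annotation$x_min) / 2
  b <- (annotation$y_max - annotation$y_min) / 2
  structure(
    list(center = c((annotation$x_min + annotation$x_max) / 2,
                    (annotation$y_min + annotation$y_max) / 2),
         semi_axes = c(a, b)),
    class = "ellipse_geometry"
  )
}

#' Rasterize the interior of an ellipse
#'
#' @param shape `c(nrow, ncol)` of the target grid.
#' @param ellipse An `ellipse_geometry`.
#' @return Logical matrix, `TRUE` for pixel centers inside or on the
#'   ellipse.
#' @export
ellipse_mask <- function(shape, ellipse) {
  if (!inherits(ellipse, "ellipse_geometry"))
    stop("`ellipse` must be an ellipse_geometry", call. = FALSE)
  nr <- shape[1]; nc <- shape[2]
  x <- seq_len(nc) - 1; y <- seq_len(nr) - 1
  DX2 <- ((x - ellipse$center[1]) / ellipse$semi_axes[1])^2
  DY2 <- ((y - ellipse$center[2]) / ellipse$semi_axes[2])^2
  outer(DY2, DX2, `+`) <= 1
}

#' Diagonal/anti-diagonal quadrant masks
#'
#' Splits the grid into four triangular sectors by the two lines
#' `y - cy = +/-(x - cx)` through the analysis center. With image
#' coordinates (y growing downward) the top sector is anatomically superior
#' and the bottom inferior; the left/right sectors receive nasal/temporal
#' labels according to eye laterality. By the default convention the nasal
#' quadrant of a right eye (OD) lies on the image-right of the center, and
#' OS is mirrored; device exports with flipped orientation can set
#' `od_nasal_side = "left"`.
#'
#' Pixels falling exactly on a dividing line are assigned deterministically
#' by treating the sectors as half-open angular intervals — measuring the
#' angle of `(dx, dy)` from the center, superior is `[-135, -45)` degrees,
#' temporal/nasal-right `[-45, 45)`, inferior `[45, 135)`, and left
#' `[135, 225)` — so each diagonal ray belongs to exactly one sector (the
#' center pixel, if on the grid, goes to superior). The masks therefore
#' tile the grid exactly, and an even-sized grid with a half-integer
#' center splits into four equal quadrants.
#'
#' @param shape `c(nrow, ncol)`.
#' @param center `c(cx, cy)` in 0-based pixel coordinates, strictly inside
#'   the grid; a half-integer center leaves no pixel on either line.
#' @param laterality `"OD"` or `"OS"`.
#' @param od_nasal_side Which image side is nasal for an OD eye
#'   (`"right"`, the default convention, or `"left"`).
#' @return Named list of four disjoint logical masks (`superior`,
#'   `inferior`, `nasal`, `temporal`) whose union covers the grid.
#' @export
quadrant_masks <- function(shape, center, laterality = c("OD", "OS"),
                           od_nasal_side = c("right", "left")) {
  laterality <- match.arg(laterality)
  od_nasal_side <- match.arg(od_nasal_side)
  nr <- shape[1]; nc <- shape[2]
  cx <- center[1]; cy <- center[2]
  if (!(cx > 0 - 0.5 && cx < nc - 0.5 && cy > -0.5 && cy < nr - 0.5))
    stop("center must lie strictly inside the grid", call. = FALSE)
  x <- seq_len(nc) - 1; y <- seq_len(nr) - 1
  DX <- matrix(rep(x - cx, each = nr), nr, nc)
  DY <- matrix(rep(y - cy, times = nc), nr, nc)
  center_px <- DX == 0 & DY == 0
  # half-open angular sectors: each dividing ray belongs to the sector
  # whose interval starts at it; the center pixel goes to superior
  superior <- (DY < -abs(DX)) | (DY == DX & DX < 0) | center_px
  inferior <- (DY > abs(DX)) | (DY == DX & DX > 0)
  right <- (DX > abs(DY)) | (DY == -DX & DX > 0)
  left <- (DX < -abs(DY)) | (DY == -DX & DX < 0)
  nasal_is_right <- (laterality == "OD") == (od_nasal_side == "right")
  out <- list(
    superior = superior,
    inferior = inferior,
    nasal = if (nasal_is_right) right else left,
    temporal = if (nasal_is_right) left else right
  )
  counts <- vapply(out, sum, integer(1))
  stopifnot(sum(counts) == nr * nc)       # exact tiling, asserted every call
  out
}

#' Build the analysis regions for one en-face image
#'
#' Macular scans are analysed over the full frame with the quadrant apex at
#' the image center. Optic-disc scans require a bounding-box annotation of
#' the disc: the inscribed ellipse is computed and its center becomes the
#' quadrant apex. By default the disc segment region is the full frame
#' (matching the macular convention) with the ellipse stored for
#' provenance; `disc_interior` can instead exclude or restrict to the
#' ellipse interior.
#'
#' @param image An [enface_image()].
#' @param annotation A [disc_annotation()] for disc scans; must be `NULL`
#'   for macular scans.
#' @param disc_interior How disc-scan regions treat the ellipse interior:
#'   `"include"` (full frame, default), `"exclude_inside_ellipse"`, or
#'   `"only_inside_ellipse"`.
#' @param od_nasal_side See [quadrant_masks()].
#' @return A list of class `region_set`: `segment_mask`, `quadrant_masks`
#'   (superior/inferior/nasal/temporal, each intersected with the segment
#'   mask), `center_used`, `laterality`, `ellipse` (`NULL` for macula).
#' @export
build_region_set <- function(image, annotation = NULL,
                             disc_interior = c("include",
                                               "exclude_inside_ellipse",
                                               "only_inside_ellipse"),
                             od_nasal_side = c("right", "left")) {
  if (!inherits(image, "enface_image"))
    stop("`image` must be an enface_image", call. = FALSE)
  disc_interior <- match.arg(disc_interior)
  od_nasal_side <- match.arg(od_nasal_side)
  shape <- dim(image$pixels)
  if (image$scan_type == "macula") {
    if (!is.null(annotation))
      stop("macula scans must not carry a disc annotation", call. = FALSE)
    center <- c((shape[2] - 1) / 2, (shape[1] - 1) / 2)
    segment_mask <- matrix(TRUE, shape[1], shape[2])
    ellipse <- NULL
  } else {
    if (is.null(annotation))
      stop("disc scans require a disc annotation", call. = FALSE)
    ellipse <- ellipse_from_bbox(annotation)
    center <- ellipse$center
    segment_mask <- switch(
      disc_interior,
      include = matrix(TRUE, shape[1], shape[2]),
      exclude_inside_ellipse = !ellipse_mask(shape, ellipse),
      only_inside_ellipse = ellipse_mask(shape, ellipse)
    )
  }
  quads <- quadrant_masks(shape, center, image$laterality, od_nasal_side)
  quads <- lapply(quads, function(m) m & segment_mask)
  q_total <- sum(vapply(quads, sum, integer(1)))
  stopifnot(q_total == sum(segment_mask))  # tiling within the segment mask
  structure(
    list(segment_mask = segment_mask, quadrant_masks = quads,
         center_used = center, laterality = image$laterality,
         ellipse = ellipse),
    class = "region_set"
  )
}
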