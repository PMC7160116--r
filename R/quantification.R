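# Intensity-ratio and distance measurements on confocal z-stacks, as used
# in follow-up cell biology: acetylated-tubulin / alpha-tubulin spindle
# ratios, total EB1 levels, and inter-kinetochore distances.

#' Z-stack container
#'
#' An ordered set of 2D planes per channel role with the axial step and
#' pixel size.
#'
#' @param planes named list (channel role) of lists of 2D matrices, one per
#'   optical slice; all planes share one shape and slice count.
#' @param z_step_um axial slice spacing in micrometres.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @return a `z_stack` object.
#' @export
z_stack <- function(planes, z_step_um, pixel_size_um) {
  stopifnot(is.list(planes), length(planes) >= 1, !is.null(names(planes)),
            z_step_um > 0, pixel_size_um > 0)
  nz <- unique(vapply(planes, length, 0L))
  if (length(nz) != 1 || nz < 1) stop("all roles need the same number of slices")
  structure(list(planes = planes, z_step_um = z_step_um,
                 pixel_size_um = pixel_size_um), class = "z_stack")
}

#' Circle region of interest
#' @param center_px (row, col) centre in pixels.
#' @param radius_px radius in pixels (> 0).
#' @export
circle_roi <- function(center_px, radius_px) {
  stopifnot(length(center_px) == 2, radius_px > 0)
  structure(list(center_px = as.numeric(center_px),
                 radius_px = as.numeric(radius_px)), class = "circle_roi")
}

.roi_mask <- function(roi, dims) {
  dr <- outer(seq_len(dims[1]) - roi$center_px[1], rep(1, dims[2]))
  dc <- outer(rep(1, dims[1]), seq_len(dims[2]) - roi$center_px[2])
  m <- dr^2 + dc^2 <= roi$radius_px^2
  if (!any(m)) stop("ROI does not intersect the image")
  m
}

# per-role mean of (ROI integrated intensity / ROI area - background) over
# all z-slices; the shared numerator/denominator path of the ratio and
# total-intensity measurements
.stack_level <- function(stack, roi, role, background) {
  pl <- stack$planes[[role]]
  if (is.null(pl)) stop("role '", role, "' not in stack")
  m <- .roi_mask(roi, dim(pl[[1]]))
  area <- sum(m)
  per_plane <- vapply(pl, function(p) sum(p[m]) / area, 0) - background
  mean(per_plane)
}

# annulus background (median over all slices of the ring r..1.5r outside the
# ROI), estimated once per stack
.annulus_background <- function(stack, roi, role) {
  pl <- stack$planes[[role]]
  dims <- dim(pl[[1]])
  dr <- outer(seq_len(dims[1]) - roi$center_px[1], rep(1, dims[2]))
  dc <- outer(rep(1, dims[1]), seq_len(dims[2]) - roi$center_px[2])
  d2 <- dr^2 + dc^2
  ring <- d2 > roi$radius_px^2 & d2 <= (1.5 * roi$radius_px)^2
  if (!any(ring)) return(0)
  stats::median(unlist(lapply(pl, function(p) p[ring])))
}

resolve_background <- function(stack, roi, roles, background) {
  if (is.null(background))
    return(stats::setNames(vapply(roles, function(r)
      .annulus_background(stack, roi, r), 0), roles))
  if (is.null(names(background)) && length(background) == 1)
    return(stats::setNames(rep(background, length(roles)), roles))
  stats::setNames(as.numeric(background[roles]), roles)
}

#' Spindle intensity ratio between two channels
#'
#' For each optical slice, the raw integrated intensity inside a circular
#' selection around the mitotic spindle is divided by the selection area
#' and the background is subtracted; the per-slice values are then averaged
#' over the stack for each channel, and the ratio of the two channel means
#' is returned (e.g. acetylated tubulin over alpha-tubulin). When
#' `background` is `NULL` it is estimated per channel as the median of an
#' annulus (1-1.5 radii) outside the ROI, once per stack.
#'
#' @param stack a [z_stack()].
#' @param roi a [circle_roi()].
#' @param num_role,den_role channel roles of numerator and denominator.
#' @param background `NULL`, a single value, or a named per-role vector.
#' @return the intensity ratio (dimensionless).
#' @export
intensity_ratio <- function(stack, roi, num_role, den_role, background = NULL) {
  bg <- resolve_background(stack, roi, c(num_role, den_role), background)
  num <- .stack_level(stack, roi, num_role, bg[[num_role]])
  den <- .stack_level(stack, roi, den_role, bg[[den_role]])
  if (!is.finite(den) || den <= 0)
    stop("denominator channel mean is not positive after background subtraction")
  num / den
}

#' Background-subtracted mean channel level over a z-stack
#'
#' The numerator path of [intensity_ratio()]: area-normalized,
#' background-subtracted ROI intensity averaged over all slices (used e.g.
#' for total EB1 levels).
#'
#' @inheritParams intensity_ratio
#' @param role channel role to quantify.
#' @return mean background-subtracted level (arbitrary units).
#' @export
total_intensity <- function(stack, roi, role, background = NULL) {
  bg <- resolve_background(stack, roi, role, background)
  .stack_level(stack, roi, role, bg[[role]])
}

#' Inter-kinetochore distances
#'
#' Euclidean distance, in micrometres, between the two kinetochores of each
#' sister pair measured in one focal plane, plus per-cell summaries.
#'
#' @param pairs data frame with columns `a_row`, `a_col`, `b_row`, `b_col`
#'   (pixel coordinates), optionally `cell_id`, and either a
#'   `pixel_size_um` column or the `pixel_size_um` argument.
#' @param pixel_size_um pixel size applied to all pairs lacking their own.
#' @return list with `distances_um` (per pair) and `per_cell` (data frame
#'   of per-cell median and mean; a single implicit cell if no `cell_id`).
#' @export
interkt_distances <- function(pairs, pixel_size_um = NULL) {
  stopifnot(nrow(pairs) >= 1)
  px <- pairs$pixel_size_um
  if (is.null(px)) {
    if (is.null(pixel_size_um)) stop("pixel_size_um required")
    px <- rep(pixel_size_um, nrow(pairs))
  }
  d_px <- sqrt((pairs$a_row - pairs$b_row)^2 + (pairs$a_col - pairs$b_col)^2)
  if (any(d_px == 0)) stop("coincident kinetochore points")
  d <- d_px * px
  cell <- if (is.null(pairs$cell_id)) rep(1L, nrow(pairs)) else pairs$cell_id
  per_cell <- data.frame(
    cell_id = sort(unique(cell)),
    n_pairs = as.integer(table(cell)[as.character(sort(unique(cell)))]),
    median_um = as.numeric(tapply(d, cell, stats::median)),
    mean_um = as.numeric(tapply(d, cell, mean)))
  list(distances_um = d, per_cell = per_cell)
}
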