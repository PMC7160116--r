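# Nucleus/cytoplasm segmentation, spot detection and per-object feature
# measurement. Standard image operators (smoothing, Otsu, distance-transform
# watershed, seeded propagation, morphology) come from EBImage; only the
# conventions for combining them are defined here.

#' Segment nuclei from the DNA channel
#'
#' Global Otsu threshold on a Gaussian-smoothed DNA plane, followed by a
#' watershed split of touching nuclei. The watershed surface combines the
#' distance transform with the smoothed DNA intensity, so both shape necks
#' (touching round nuclei) and intensity valleys (adjacent condensed
#' figures) separate objects. Objects smaller than `min_area_um2` are
#' discarded.
#'
#' @param image a [multichannel_image()] with a `dna` channel.
#' @param smooth_sigma_px Gaussian smoothing sigma before thresholding.
#' @param min_area_um2 minimum object area kept, in square micrometres.
#'   The default (1.5) keeps small dead-cell fragments and anaphase nuclei,
#'   which the downstream classifier needs, while removing noise specks.
#' @param threshold `"otsu"` (default) or a numeric absolute threshold, or
#'   `"quantile:<q>"` for percentile thresholding.
#' @param tolerance,ext watershed parameters (see [EBImage::watershed()]);
#'   the surface is normalized so `tolerance` is a fraction of its range.
#' @return a `label_mask`: list with `labels` (integer matrix, 0 =
#'   background) and `n_objects`.
#' @export
segment_nuclei <- function(image, smooth_sigma_px = 1, min_area_um2 = 1.5,
                           threshold = "otsu", tolerance = 0.25, ext = 2) {
  stopifnot(inherits(image, "multichannel_image"))
  if (!"dna" %in% names(image$planes)) stop("DNA channel missing")
  dna <- image$planes$dna
  s <- as.matrix(EBImage::gblur(dna, sigma = smooth_sigma_px))
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(s)
    if (diff(rng) < 1e-8) rng[2] + 1  # constant image: nothing above threshold
    else EBImage::otsu(EBImage::Image(s), range = rng)
  } else if (is.character(threshold) && startsWith(threshold, "quantile:")) {
    stats::quantile(s, as.numeric(sub("quantile:", "", threshold)))
  } else as.numeric(threshold)
  mask <- s > thr
  if (!any(mask)) return(label_mask(matrix(0L, nrow(s), ncol(s))))
  dm <- EBImage::distmap(EBImage::Image(mask))
  surf <- dm / max(dm)
  fgi <- s * mask
  surf <- surf + fgi / max(fgi)
  ws <- EBImage::watershed(EBImage::Image(as.matrix(surf) * mask),
                           tolerance = tolerance, ext = ext)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(s), ncol(s))
  # area filter in physical units
  min_px <- min_area_um2 / image$pixel_size_um^2
  sizes <- tabulate(lab)
  drop <- which(sizes > 0 & sizes < min_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  label_mask(relabel(lab))
}

#' Label mask constructor
#'
#' @param labels integer matrix with contiguous positive labels (0 =
#'   background).
#' @return a `label_mask` list with `labels` and `n_objects`.
#' @export
label_mask <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  n <- max(labels, 0L)
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) && !identical(present, seq_len(n)))
    stop("labels must be contiguous positive integers")
  structure(list(labels = labels, n_objects = as.integer(n)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d objects\n",
              nrow(x$labels), ncol(x$labels), x$n_objects))
  invisible(x)
}

relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (!length(u)) return(lab)
  lut <- integer(max(u)); lut[u] <- seq_along(u)
  lab[lab > 0L] <- lut[lab[lab > 0L]]
  lab
}

#' Segment cytoplasm seeded by nuclei
#'
#' Voronoi-style propagation of the nucleus labels over the tubulin channel
#' restricted to a foreground mask, yielding one cytoplasm region per
#' nucleus. The foreground is everything above a robust background estimate
#' (median + `k_mad` * 1.4826 MAD of the tubulin plane), which keeps dim
#' cytoplasm (e.g. of multinucleated cells) that a global Otsu would drop.
#' Nucleus pixels are always foreground.
#'
#' @param image a [multichannel_image()] with a `tubulin` channel.
#' @param nuclei a `label_mask` of nucleus seeds.
#' @param smooth_sigma_px smoothing applied to tubulin before propagation.
#' @param k_mad foreground threshold in robust SDs above background.
#' @return a `label_mask` of cytoplasm regions; label i is the cytoplasm of
#'   nucleus i. An empty seed mask yields an empty cytoplasm mask.
#' @export
segment_cytoplasm <- function(image, nuclei, smooth_sigma_px = 1.5, k_mad = 3) {
  stopifnot(inherits(image, "multichannel_image"), inherits(nuclei, "label_mask"))
  if (!"tubulin" %in% names(image$planes)) stop("tubulin channel missing")
  if (nuclei$n_objects == 0L)
    return(label_mask(matrix(0L, nrow(nuclei$labels), ncol(nuclei$labels))))
  tub <- as.matrix(EBImage::gblur(image$planes$tubulin, sigma = smooth_sigma_px))
  bg <- stats::median(tub)
  thr <- bg + k_mad * stats::mad(tub)
  fg <- tub > thr | nuclei$labels > 0L
  cyto <- EBImage::propagate(EBImage::Image(tub), EBImage::Image(nuclei$labels),
                             mask = EBImage::Image(fg))
  lab <- matrix(as.integer(EBImage::imageData(cyto)), nrow(tub), ncol(tub))
  structure(list(labels = lab, n_objects = nuclei$n_objects),
            class = "label_mask")
}

#' Laplacian-of-Gaussian spot detection
#'
#' Convolves the plane with a scale-normalized LoG kernel and reports local
#' maxima of the (sign-flipped) response above `min_peak`, i.e. bright
#' blobs of radius about `sqrt(2) * scale_px`. Spots are returned sorted by
#' response, strongest first.
#'
#' @param plane 2D numeric matrix.
#' @param scale_px LoG sigma in pixels (> 0).
#' @param min_peak minimum scale-normalized response to accept a spot.
#' @return data frame with `row`, `col`, `peak_intensity` (the response at
#'   the peak) and `scale_px`.
#' @export
detect_spots <- function(plane, scale_px, min_peak) {
  stopifnot(scale_px > 0)
  k <- ceiling(3 * scale_px)
  xs <- -k:k
  g <- exp(-outer(xs^2, xs^2, "+") / (2 * scale_px^2))
  g <- g / sum(g)
  r2 <- outer(xs^2, xs^2, "+")
  log_k <- (r2 - 2 * scale_px^2) / scale_px^2 * g  # sigma^2-normalized LoG
  resp <- -as.matrix(EBImage::filter2(EBImage::Image(plane), log_k,
                                      boundary = "replicate"))
  mx <- as.matrix(EBImage::dilate(EBImage::Image(resp),
                                  EBImage::makeBrush(3, shape = "box")))
  is_peak <- resp >= mx - 1e-12 & resp >= min_peak
  # suppress plateau duplicates: keep strict interior maxima
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(row = numeric(0), col = numeric(0),
                      peak_intensity = numeric(0), scale_px = numeric(0)))
  vals <- resp[is_peak]
  o <- order(vals, decreasing = TRUE)
  idx <- idx[o, , drop = FALSE]; vals <- vals[o]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      d2 <- (idx[(i + 1):nrow(idx), 1] - idx[i, 1])^2 +
            (idx[(i + 1):nrow(idx), 2] - idx[i, 2])^2
      keep[(i + 1):nrow(idx)][d2 <= (2 * scale_px)^2] <- FALSE
    }
  }
  data.frame(row = idx[keep, 1], col = idx[keep, 2],
             peak_intensity = vals[keep], scale_px = scale_px)
}

#' Measure per-object features
#'
#' One record per label: centroid, area, ellipse axes (from second
#' moments), aspect ratio, roundness `4 * pi * area / perimeter^2` (the
#' perimeter uses the crack-length estimator, exposed pixel edges scaled by
#' pi/4, which is unbiased for smooth convex shapes), and per-channel
#' integrated / mean / perinuclear-ring mean intensities. Lengths and areas
#' are in physical units.
#'
#' @param mask a `label_mask`.
#' @param image a [multichannel_image()] of the same shape.
#' @param ring_width_um width of the morphological perinuclear ring
#'   measured outside each object (default 2 um).
#' @return data frame, one row per label.
#' @export
measure_objects <- function(mask, image, ring_width_um = 2) {
  stopifnot(inherits(mask, "label_mask"), inherits(image, "multichannel_image"))
  if (!identical(dim(mask$labels), dim(image$planes[[1]])))
    stop("mask and image shapes differ")
  px <- image$pixel_size_um
  n <- mask$n_objects
  roles <- names(image$planes)
  if (n == 0L) {
    out <- data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_um2 = numeric(0),
                      major_axis_um = numeric(0), minor_axis_um = numeric(0),
                      aspect_ratio = numeric(0), roundness = numeric(0),
                      perimeter_um = numeric(0))
    for (r in roles) {
      out[[paste0("integrated_", r)]] <- numeric(0)
      out[[paste0("mean_", r)]] <- numeric(0)
      out[[paste0("perinuclear_", r)]] <- numeric(0)
    }
    return(out)
  }
  lab <- mask$labels
  labimg <- EBImage::Image(lab)
  mom <- EBImage::computeFeatures.moment(labimg)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1, dimnames = list(NULL, names(mom)))
  area_px <- tabulate(lab, nbins = n)
  # crack-length perimeter: count exposed 4-neighbour edges per label
  crack <- integer(n)
  count_edges <- function(a, b) {
    diffs <- a != b
    for (v in list(a[diffs], b[diffs])) {
      v <- v[v > 0L]
      if (length(v)) {
        t <- tabulate(v, nbins = n)
        crack <<- crack + t
      }
    }
  }
  count_edges(lab[-1, , drop = FALSE], lab[-nrow(lab), , drop = FALSE])
  count_edges(lab[, -1, drop = FALSE], lab[, -ncol(lab), drop = FALSE])
  crack <- crack + tabulate(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]),
                            nbins = n)
  per_px <- crack * pi / 4
  major <- mom[, "m.majoraxis"]
  ecc <- pmin(mom[, "m.eccentricity"], 0.9999)
  minor <- major * sqrt(1 - ecc^2)
  minor <- pmax(minor, 1e-6)
  out <- data.frame(
    label = seq_len(n),
    centroid_row = mom[, "m.cx"], centroid_col = mom[, "m.cy"],
    orientation = mom[, "m.theta"],
    area_um2 = area_px * px^2,
    major_axis_um = major * px, minor_axis_um = minor * px,
    aspect_ratio = pmax(major / minor, 1),
    roundness = pmin(4 * pi * area_px / per_px^2, 1),
    perimeter_um = per_px * px)
  labv <- as.vector(lab)
  inside <- labv > 0L
  # perinuclear rings: per-object dilation on a padded patch
  rw <- max(1L, round(ring_width_um / px))
  brush <- EBImage::makeBrush(2L * rw + 1L, shape = "disc")
  anyobj <- lab > 0L
  ring_idx <- vector("list", n)
  bb <- bounding_boxes(lab, n)
  H <- nrow(lab); W <- ncol(lab)
  for (i in seq_len(n)) {
    r0 <- max(1L, bb[i, 1] - rw - 1L); r1 <- min(H, bb[i, 2] + rw + 1L)
    c0 <- max(1L, bb[i, 3] - rw - 1L); c1 <- min(W, bb[i, 4] + rw + 1L)
    sub <- lab[r0:r1, c0:c1] == i
    dil <- as.matrix(EBImage::dilate(EBImage::Image(sub), brush)) > 0
    ring <- dil & !anyobj[r0:r1, c0:c1]
    rc <- which(ring, arr.ind = TRUE)
    ring_idx[[i]] <- (rc[, 2] + c0 - 2L) * H + (rc[, 1] + r0 - 1L)
  }
  for (r in roles) {
    v <- as.vector(image$planes[[r]])
    tot <- rowsum(v[inside], labv[inside])[, 1]
    tot_full <- numeric(n); tot_full[as.integer(rownames(rowsum(v[inside], labv[inside])))] <- tot
    out[[paste0("integrated_", r)]] <- tot_full
    out[[paste0("mean_", r)]] <- tot_full / area_px
    out[[paste0("perinuclear_", r)]] <-
      vapply(ring_idx, function(ix) if (length(ix)) mean(v[ix]) else NA_real_, 0)
  }
  out
}

bounding_boxes <- function(lab, n) {
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  bb <- matrix(NA_integer_, n, 4)
  bb[, 1] <- as.integer(tapply(idx[, 1], l, min)[as.character(seq_len(n))])
  bb[, 2] <- as.integer(tapply(idx[, 1], l, max)[as.character(seq_len(n))])
  bb[, 3] <- as.integer(tapply(idx[, 2], l, min)[as.character(seq_len(n))])
  bb[, 4] <- as.integer(tapply(idx[, 2], l, max)[as.character(seq_len(n))])
  bb
}
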