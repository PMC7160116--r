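# The screen's rule cascade: dead-cell removal, mitotic classification,
# anaphase/telophase pairing with chromosome-segregation-error scoring,
# two-step multinucleation detection, cytokinetic-bridge detection, and the
# per-well counting conventions (pairs and multinucleated groups count once,
# ratios are relative to viable cells).

#' Classifier configuration
#'
#' All thresholds of the phenotype rule cascade. Intensity thresholds are in
#' the image's arbitrary intensity units; the numeric defaults are
#' calibrated to the simulator's default amplitude scale
#' ([sim_geometry()]). Thresholds marked "auto" are resolved per well by
#' Otsu's method on the relevant per-object distribution.
#'
#' The anaphase/telophase distance caps (0.65 and 2.6 um) are applied, by
#' default, to the gap between nucleus boundaries (`pair_dist_mode =
#' "gap"`); `"centroid"` switches to centroid distance. By default the gap
#' gate only discards already-divided daughter-cell pairs (anything wider
#' than the telophase cap), and the anaphase/telophase split is decided by
#' inter-nucleus tubulin, anaphase being the dimmer corridor; `stage_rule =
#' "distance"` instead assigns anaphase to pairs within the anaphase cap.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(...) {
  cfg <- list(
    # dead-cell filter
    dead_area_um2_range = c(4.5, 150), dead_tubulin_max = 0.25,
    # mitotic classification
    mitotic_marker_min = "auto", mitotic_dna_area_max_um2 = 31,
    mitotic_tubulin_min = "auto", mitotic_cep215_max = "auto",
    # multinucleation (two-step)
    binucleate_max_centroid_dist_um = 6.5, binucleate_max_aspect = 1.5,
    binucleate_min_roundness = 0.75, binucleate_area_um2_range = c(6, 60),
    perinuclear_tubulin_low_max = 0.55,
    # anaphase/telophase pairing
    anatelo_dna_intensity_max_quantile = 0.9, anatelo_elongation_min = 1.25,
    pair_dist_max_anaphase_um = 0.65, pair_dist_max_telophase_um = 2.6,
    pair_dist_mode = "gap", stage_rule = "tubulin",
    anaphase_internuclear_tubulin_max = 0.8,
    # chromosome segregation errors
    cse_dna_threshold_sd = 3, cse_exclusion_um = 0.8,
    cse_reference = "flank",
    # cytokinetic bridges
    bridge_eccentricity_min = 0.85, bridge_length_um_range = c(2, 8),
    bridge_doublet_dist_um_range = c(1, 5),
    require_gamma_tubulin_midbody = TRUE,
    bridge_tubulin_min = 2.0, bridge_spot_scale_um = 0.8,
    bridge_spot_min_response = 0.45, midbody_spot_min_response = 0.4,
    midbody_max_dist_um = 1.3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown classifier fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$pair_dist_mode %in% c("gap", "centroid"),
            cfg$stage_rule %in% c("tubulin", "distance"),
            cfg$anatelo_dna_intensity_max_quantile > 0,
            cfg$anatelo_dna_intensity_max_quantile < 1)
  structure(cfg, class = "classifier_config")
}

# 1D Otsu threshold for per-object feature distributions
otsu_threshold <- function(v, bins = 256) {
  v <- v[is.finite(v)]
  if (length(v) < 2 || diff(range(v)) < 1e-12) return(Inf)
  h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = bins + 1),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(w); w2 <- 1 - w1
  mu <- cumsum(w * mids)
  muT <- mu[length(mu)]
  bc <- (muT * w1 - mu)^2 / (w1 * w2)
  bc[!is.finite(bc)] <- 0
  # the criterion is flat across an empty valley; take the plateau midpoint
  mean(range(mids[bc >= max(bc) - 1e-12]))
}

# Resolve an "auto" threshold by Otsu on the per-object distribution. A
# separation guard protects wells where the positive class is absent: the
# Otsu split of a unimodal background yields two halves whose means differ
# by only a few within-class spreads, in which case no object is called
# positive. Genuinely bimodal wells separate by orders of magnitude more.
resolve_auto <- function(value, v, side = c("upper", "lower")) {
  side <- match.arg(side)
  if (!identical(value, "auto")) return(as.numeric(value))
  none <- if (side == "upper") Inf else -Inf
  thr <- otsu_threshold(v)
  if (!is.finite(thr)) return(none)
  lo <- v[v <= thr]; hi <- v[v > thr]
  if (!length(lo) || !length(hi)) return(none)
  spread <- max(stats::mad(lo), stats::mad(hi), 1e-12)
  if (mean(hi) - mean(lo) <= 5 * spread) return(none)
  thr
}

#' Flag dead cells and debris
#'
#' Objects whose nucleus area falls outside the viable range, or whose mean
#' tubulin intensity is below `dead_tubulin_max` (dead cells and debris lack
#' a cytoskeleton), are flagged dead. The partition is exhaustive.
#'
#' @param features data frame from [measure_objects()].
#' @param cfg a [classifier_config()].
#' @return list with `viable` and `dead` data frames.
#' @export
filter_dead <- function(features, cfg = classifier_config()) {
  if (nrow(features) == 0) return(list(viable = features, dead = features))
  rng <- cfg$dead_area_um2_range
  dead <- features$area_um2 < rng[1] | features$area_um2 > rng[2] |
    features$mean_tubulin < cfg$dead_tubulin_max
  list(viable = features[!dead, , drop = FALSE],
       dead = features[dead, , drop = FALSE])
}

#' Classify mitotic cells
#'
#' Screen B: condensed DNA (nucleus area at most
#' `mitotic_dna_area_max_um2`) together with a high mitotic marker (PHH3)
#' mean intensity. Screen A: condensed DNA together with high alpha-tubulin
#' and low CEP215 staining.
#'
#' @param viable viable-object features (see [filter_dead()]).
#' @param cfg a [classifier_config()].
#' @param mode `"screenB"` (PHH3 marker) or `"screenA"` (tubulin/CEP215).
#' @return the mitotic subset of `viable`.
#' @export
classify_mitotic <- function(viable, cfg = classifier_config(),
                             mode = c("screenB", "screenA")) {
  mode <- match.arg(mode)
  if (nrow(viable) == 0) return(viable)
  condensed <- viable$area_um2 <= cfg$mitotic_dna_area_max_um2
  if (mode == "screenB") {
    if (is.null(viable$mean_phh3)) stop("PHH3 channel features missing")
    thr <- resolve_auto(cfg$mitotic_marker_min, viable$mean_phh3, "upper")
    sel <- condensed & viable$mean_phh3 >= thr
  } else {
    if (is.null(viable$mean_cep215)) stop("CEP215 channel features missing")
    thr_tub <- resolve_auto(cfg$mitotic_tubulin_min, viable$mean_tubulin, "upper")
    thr_cep <- resolve_auto(cfg$mitotic_cep215_max, viable$mean_cep215, "lower")
    sel <- condensed & viable$mean_tubulin >= thr_tub &
      viable$mean_cep215 <= thr_cep
  }
  viable[sel, , drop = FALSE]
}

# pixel coordinates per label, restricted to the given labels
label_pixels <- function(mask, labels) {
  sel <- matrix(mask$labels %in% labels, nrow(mask$labels))
  idx <- which(sel, arr.ind = TRUE)
  l <- mask$labels[sel]
  split.data.frame(idx, l)
}

# boundary gap (um) between two labelled regions: smallest pixel-to-pixel
# distance minus one pixel (touching pixels have gap 0)
boundary_gap_um <- function(pixA, pixB, px) {
  d2 <- outer(pixA[, 1], pixB[, 1], "-")^2 + outer(pixA[, 2], pixB[, 2], "-")^2
  max(0, sqrt(min(d2)) - 1) * px
}

# corridor between two nuclei: band of given width around the segment
# joining the centroids (optionally shifted sideways by `shift_px` for
# matched flanking reference bands). The pair's own nuclei are excluded by
# their fitted moment ellipses (plus an `excl_um` margin), not
# by their segmented masks, so DNA-positive material lying between the
# nuclei stays measurable even when segmentation attaches it to a nucleus;
# all other segmented objects are excluded by mask dilation.
corridor_indices <- function(mask, fa, fb, width_px, excl_um, px, shift_px = 0) {
  lab <- mask$labels
  H <- nrow(lab); W <- ncol(lab)
  p1 <- c(fa$centroid_row, fa$centroid_col)
  p2 <- c(fb$centroid_row, fb$centroid_col)
  if (shift_px != 0) {
    v <- p2 - p1
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      perp <- c(-v[2], v[1]) / nv
      p1 <- p1 + perp * shift_px
      p2 <- p2 + perp * shift_px
    }
  }
  excl_px <- excl_um / px
  ctr <- (p1 + p2) / 2
  r <- sqrt(sum((p2 - p1)^2)) / 2 + width_px + excl_px + 2
  rows <- max(1L, floor(ctr[1] - r)):min(H, ceiling(ctr[1] + r))
  cols <- max(1L, floor(ctr[2] - r)):min(W, ceiling(ctr[2] + r))
  v <- p2 - p1; L2 <- sum(v^2)
  dr <- outer(rows - p1[1], cols * 0, "+")
  dc <- outer(rows * 0, cols - p1[2], "+")
  tt <- if (L2 > 0) pmin(pmax((dr * v[1] + dc * v[2]) / L2, 0), 1) else 0
  d2 <- (dr - tt * v[1])^2 + (dc - tt * v[2])^2
  band <- d2 <= (width_px / 2)^2
  in_ellipse <- function(f) {
    a <- (f$major_axis_um / 2 + excl_um) / px
    # chromatin lying between the nuclei (the signal being scored) inflates
    # the fitted minor axis; cap the exclusion so it cannot swallow the gap
    b <- (min(f$minor_axis_um / 2, 0.35 * f$major_axis_um) + excl_um) / px
    th <- f$orientation
    er <- outer(rows - f$centroid_row, cols * 0, "+")
    ec <- outer(rows * 0, cols - f$centroid_col, "+")
    U <- er * cos(th) + ec * sin(th)
    V <- -er * sin(th) + ec * cos(th)
    (U / a)^2 + (V / b)^2 <= 1
  }
  sub <- lab[rows, cols]
  other <- sub > 0L & sub != fa$label & sub != fb$label
  if (excl_px > 0 && any(other)) {
    brush <- EBImage::makeBrush(2L * ceiling(excl_px) + 1L, shape = "disc")
    other <- as.matrix(EBImage::dilate(EBImage::Image(other), brush)) > 0
  }
  keep <- band & !other & !in_ellipse(fa) & !in_ellipse(fb)
  rc <- which(keep, arr.ind = TRUE)
  if (!nrow(rc)) return(integer(0))
  (rc[, 2] + cols[1] - 2L) * H + (rc[, 1] + rows[1] - 1L)
}

#' Pair anaphase/telophase nuclei and assign the stage
#'
#' Candidate nuclei among the mitotic set are small, elongated (aspect ratio
#' at least `anatelo_elongation_min`) and have low integrated DNA intensity
#' (below the `anatelo_dna_intensity_max_quantile` quantile of the mitotic
#' set). Candidates are paired by greedy mutual nearest neighbour in
#' increasing distance; a pair within the distance gate becomes an
#' anaphase/telophase event, with the stage assigned by inter-nucleus
#' tubulin (see [classifier_config()]).
#'
#' @param mitotic mitotic-subset features from [classify_mitotic()].
#' @param image the [multichannel_image()].
#' @param mask the nucleus `label_mask`.
#' @param cfg a [classifier_config()].
#' @return data frame with one row per pair: `label_a`, `label_b`, `stage`,
#'   `dist_um` (the gated distance), `corridor_tubulin`.
#' @export
pair_ana_telo <- function(mitotic, image, mask, cfg = classifier_config()) {
  empty <- data.frame(label_a = integer(0), label_b = integer(0),
                      stage = character(0), dist_um = numeric(0),
                      corridor_tubulin = numeric(0))
  if (nrow(mitotic) < 2) return(empty)
  px <- image$pixel_size_um
  qthr <- stats::quantile(mitotic$integrated_dna,
                          cfg$anatelo_dna_intensity_max_quantile)
  cand <- mitotic[mitotic$aspect_ratio >= cfg$anatelo_elongation_min &
                    mitotic$integrated_dna <= qthr, , drop = FALSE]
  if (nrow(cand) < 2) return(empty)
  cand <- cand[order(cand$label), , drop = FALSE]
  pix <- label_pixels(mask, cand$label)
  n <- nrow(cand)
  cd <- as.matrix(stats::dist(cand[, c("centroid_row", "centroid_col")])) * px
  diag(cd) <- Inf
  gate_max <- max(cfg$pair_dist_max_anaphase_um, cfg$pair_dist_max_telophase_um)
  # distance used for gating, per interpretation
  gd <- cd
  if (cfg$pair_dist_mode == "gap") {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (cd[i, j] > gate_max + 20 * px) next  # centroid prefilter
      g <- boundary_gap_um(pix[[as.character(cand$label[i])]],
                           pix[[as.character(cand$label[j])]], px)
      gd[i, j] <- gd[j, i] <- g
    }
  }
  # greedy mutual nearest neighbour in increasing distance
  pairs <- list()
  free <- rep(TRUE, n)
  repeat {
    m <- which(free); if (length(m) < 2) break
    sub <- gd[m, m, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    i <- m[k[1]]; j <- m[k[2]]
    if (!is.finite(gd[i, j]) || gd[i, j] > gate_max) break
    nn_i <- m[which.min(gd[i, m])]; nn_j <- m[which.min(gd[j, m])]
    if (nn_i == j && nn_j == i) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
      free[c(i, j)] <- FALSE
    } else break  # minimal remaining distance is always mutual
  }
  if (!length(pairs)) return(empty)
  out <- lapply(pairs, function(pr) {
    fa <- cand[pr[1], ]; fb <- cand[pr[2], ]
    width_px <- mean(c(fa$minor_axis_um, fb$minor_axis_um)) / px
    ci <- corridor_indices(mask, fa, fb, width_px, cfg$cse_exclusion_um, px)
    ctub <- if (length(ci)) mean(image$planes$tubulin[ci]) else NA_real_
    d <- gd[pr[1], pr[2]]
    stage <- if (cfg$stage_rule == "distance") {
      if (d <= cfg$pair_dist_max_anaphase_um) "anaphase" else "telophase"
    } else {
      if (!is.na(ctub) && ctub <= cfg$anaphase_internuclear_tubulin_max)
        "anaphase" else "telophase"
    }
    data.frame(label_a = fa$label, label_b = fb$label, stage = stage,
               dist_um = d, corridor_tubulin = ctub)
  })
  do.call(rbind, out)
}

#' Score a chromosome segregation error on an anaphase pair
#'
#' Measures the remaining DNA signal in the inter-nucleus corridor (the
#' band joining the two nuclei, width equal to their mean minor axis,
#' excluding a margin around every segmented object) and calls an error
#' when the corridor mean exceeds a background reference by
#' `cse_dna_threshold_sd` robust standard deviations. Captures both
#' chromatin bridges and lagging chromatids.
#'
#' With `cse_reference = "flank"` (default) the reference is a matched
#' local background: two bands of the corridor's geometry shifted sideways
#' past the nuclei, which absorbs residual point-spread bleed from the
#' bright daughter nuclei. `"image"` uses the whole-image non-object DNA
#' background instead. A degenerate corridor (nuclei touching) returns
#' `FALSE` with a warning.
#'
#' @param pair one row of the [pair_ana_telo()] result (stage `"anaphase"`).
#' @param image the [multichannel_image()].
#' @param mask the nucleus `label_mask`.
#' @param features the feature table containing the pair's labels.
#' @param cfg a [classifier_config()].
#' @return logical.
#' @export
score_cse <- function(pair, image, mask, features, cfg = classifier_config()) {
  px <- image$pixel_size_um
  fa <- features[features$label == pair$label_a, ]
  fb <- features[features$label == pair$label_b, ]
  width_px <- mean(c(fa$minor_axis_um, fb$minor_axis_um)) / px
  excl_um <- cfg$cse_exclusion_um
  ci <- corridor_indices(mask, fa, fb, width_px, excl_um, px)
  if (!length(ci)) {
    warning("degenerate inter-nucleus corridor; scoring no segregation error")
    return(FALSE)
  }
  dna <- image$planes$dna
  if (identical(cfg$cse_reference, "flank")) {
    shift <- mean(c(fa$major_axis_um, fb$major_axis_um)) / 2 / px +
      width_px / 2 + 1
    ref <- c(dna[corridor_indices(mask, fa, fb, width_px, excl_um, px, shift)],
             dna[corridor_indices(mask, fa, fb, width_px, excl_um, px, -shift)])
    if (!length(ref)) ref <- dna[mask$labels == 0L]
  } else {
    ref <- dna[mask$labels == 0L]
  }
  bg_mean <- stats::median(ref)
  bg_sd <- stats::mad(ref)
  mean(dna[ci]) > bg_mean + cfg$cse_dna_threshold_sd * bg_sd
}

#' Detect multinucleated cells
#'
#' Two-step detection. Step 1 isolates binucleated cells as close nucleus
#' pairs (centroid distance, size, aspect ratio and roundness gates).
#' Step 2 groups the remaining nuclei that share one connected cytoplasm
#' component and whose perinuclear tubulin is low. Overlapping step-1/step-2
#' groups are merged, so a cell is reported once.
#'
#' @param viable non-mitotic viable features.
#' @param cytoplasm cytoplasm `label_mask` from [segment_cytoplasm()].
#' @param cfg a [classifier_config()].
#' @return list of integer vectors of nucleus labels, one per
#'   multinucleated cell.
#' @export
detect_multinucleated <- function(viable, cytoplasm, cfg = classifier_config()) {
  if (nrow(viable) < 2) return(list())
  px_dist <- cfg$binucleate_max_centroid_dist_um
  rngA <- cfg$binucleate_area_um2_range
  edges <- list()
  # step 1: close round nucleus pairs
  ok1 <- viable$area_um2 >= rngA[1] & viable$area_um2 <= rngA[2] &
    viable$aspect_ratio <= cfg$binucleate_max_aspect &
    viable$roundness >= cfg$binucleate_min_roundness
  c1 <- viable[ok1, , drop = FALSE]
  if (nrow(c1) >= 2) {
    d <- as.matrix(stats::dist(c1[, c("centroid_row", "centroid_col")]))
    # distances are in pixels here; convert gate using any pixel size baked
    # into the feature table: area_um2 / (major*minor) gives px scale, but
    # centroids are px, so the caller's pixel size enters via attr
    px <- attr(viable, "pixel_size_um")
    if (is.null(px)) px <- 1
    diag(d) <- Inf
    free <- rep(TRUE, nrow(c1))
    repeat {
      m <- which(free); if (length(m) < 2) break
      sub <- d[m, m, drop = FALSE]
      k <- arrayInd(which.min(sub), dim(sub))
      i <- m[k[1]]; j <- m[k[2]]
      if (d[i, j] * px > px_dist) break
      edges[[length(edges) + 1L]] <- c(c1$label[i], c1$label[j])
      free[c(i, j)] <- FALSE
    }
  }
  # step 2: low perinuclear tubulin nuclei sharing a cytoplasm component
  step1_labels <- unlist(edges)
  rest <- viable[!(viable$label %in% step1_labels), , drop = FALSE]
  low <- rest[!is.na(rest$perinuclear_tubulin) &
                rest$perinuclear_tubulin <= cfg$perinuclear_tubulin_low_max, ,
              drop = FALSE]
  if (nrow(low) >= 2) {
    cc <- EBImage::bwlabel(EBImage::Image(cytoplasm$labels > 0L))
    ccm <- matrix(as.integer(EBImage::imageData(cc)), nrow(cytoplasm$labels),
                  ncol(cytoplasm$labels))
    comp <- ccm[cbind(pmin(pmax(round(low$centroid_row), 1), nrow(ccm)),
                      pmin(pmax(round(low$centroid_col), 1), ncol(ccm)))]
    for (cid in unique(comp[comp > 0])) {
      grp <- low$label[comp == cid]
      if (length(grp) >= 2)
        for (k in 2:length(grp))
          edges[[length(edges) + 1L]] <- c(grp[1], grp[k])
    }
  }
  if (!length(edges)) return(list())
  # union-find over nucleus labels
  labs <- sort(unique(unlist(edges)))
  parent <- stats::setNames(labs, labs)
  find <- function(x) { while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]; x }
  for (e in edges) {
    ra <- find(e[1]); rb <- find(e[2])
    if (ra != rb) parent[[as.character(rb)]] <- ra
  }
  roots <- vapply(labs, find, numeric(1))
  unname(split(labs, roots))
}

#' Detect cytokinetic bridges
#'
#' Bridges are elongated bright tubulin objects split into two half parts.
#' Half parts are found as tubulin spots ([detect_spots()]), sorted into
#' doublets by their separation, and required to connect two distinct
#' cytoplasm regions; the doublet's underlying bright component must be
#' elongated and of plausible length, and (by default) a gamma-tubulin
#' midbody spot must sit near the doublet midpoint.
#'
#' @param image the [multichannel_image()].
#' @param cytoplasm cytoplasm `label_mask`.
#' @param cfg a [classifier_config()].
#' @return data frame, one row per accepted bridge: midpoint coordinates,
#'   the two cytoplasm labels joined, length and eccentricity.
#' @export
detect_bridges <- function(image, cytoplasm, cfg = classifier_config()) {
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      cyto_a = integer(0), cyto_b = integer(0),
                      length_um = numeric(0), eccentricity = numeric(0))
  px <- image$pixel_size_um
  tub <- as.matrix(EBImage::gblur(image$planes$tubulin, sigma = 1))
  bright <- tub >= cfg$bridge_tubulin_min
  if (!any(bright)) return(empty)
  comp <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(bright)))), nrow(tub), ncol(tub))
  spots <- detect_spots(tub, cfg$bridge_spot_scale_um / px,
                        cfg$bridge_spot_min_response)
  if (nrow(spots) < 2) return(empty)
  has_gtub <- "gtub" %in% names(image$planes)
  gspots <- NULL
  if (cfg$require_gamma_tubulin_midbody) {
    if (!has_gtub) {
      warning("no gamma-tubulin channel; skipping midbody requirement")
    } else {
      gspots <- detect_spots(image$planes$gtub, cfg$bridge_spot_scale_um / px,
                             cfg$midbody_spot_min_response)
    }
  }
  drng <- cfg$bridge_doublet_dist_um_range
  lrng <- cfg$bridge_length_um_range
  d <- as.matrix(stats::dist(spots[, c("row", "col")])) * px
  diag(d) <- Inf
  used <- rep(FALSE, nrow(spots))
  out <- list()
  for (i in seq_len(nrow(spots))) {
    if (used[i]) next
    js <- which(!used & d[i, ] >= drng[1] & d[i, ] <= drng[2])
    js <- js[js != i]
    if (!length(js)) next
    j <- js[which.min(d[i, js])]
    # the two daughters' cytoplasm labels are sampled just beyond each half
    # part, away from the midbody, where the propagated boundary cannot fall
    mid0 <- c((spots$row[i] + spots$row[j]) / 2, (spots$col[i] + spots$col[j]) / 2)
    lab_beyond <- function(k) {
      p <- c(spots$row[k], spots$col[k])
      u <- p - mid0
      u <- u / max(sqrt(sum(u^2)), 1e-9)
      for (step in c(3, 5, 7)) {
        q <- round(p + u * step)
        if (q[1] >= 1 && q[1] <= nrow(tub) && q[2] >= 1 && q[2] <= ncol(tub)) {
          l <- cytoplasm$labels[q[1], q[2]]
          if (l > 0L) return(l)
        }
      }
      0L
    }
    la <- lab_beyond(i); lb <- lab_beyond(j)
    if (la == 0L || lb == 0L || la == lb) next
    ra <- round(spots$row[i]); ca <- round(spots$col[i])
    rb <- round(spots$row[j]); cb <- round(spots$col[j])
    compids <- unique(c(comp[ra, ca], comp[rb, cb]))
    compids <- compids[compids > 0]
    if (!length(compids)) next
    pixidx <- which(matrix(comp %in% compids, nrow(comp)), arr.ind = TRUE)
    sh <- pixel_shape(pixidx)
    if (sh$eccentricity < cfg$bridge_eccentricity_min) next
    len <- sh$length_px * px
    if (len < lrng[1] || len > lrng[2]) next
    mid <- c((spots$row[i] + spots$row[j]) / 2, (spots$col[i] + spots$col[j]) / 2)
    if (!is.null(gspots)) {
      if (nrow(gspots) == 0) next
      gd <- sqrt((gspots$row - mid[1])^2 + (gspots$col - mid[2])^2) * px
      if (min(gd) > cfg$midbody_max_dist_um) next
    } else if (cfg$require_gamma_tubulin_midbody && has_gtub) next
    used[c(i, j)] <- TRUE
    out[[length(out) + 1L]] <- data.frame(row = mid[1], col = mid[2],
                                          cyto_a = la, cyto_b = lb,
                                          length_um = len,
                                          eccentricity = sh$eccentricity)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# principal-axis shape of a pixel set: eccentricity and end-to-end length
pixel_shape <- function(idx) {
  if (nrow(idx) < 2) return(list(eccentricity = 0, length_px = 1))
  xy <- sweep(idx, 2, colMeans(idx))
  cv <- crossprod(xy) / nrow(xy)
  ev <- eigen(cv, symmetric = TRUE)
  l1 <- max(ev$values[1], 1e-9); l2 <- max(ev$values[2], 0)
  proj <- xy %*% ev$vectors[, 1]
  list(eccentricity = sqrt(1 - l2 / l1),
       length_px = diff(range(proj)) + 1)
}

#' Count a well
#'
#' Applies the screen's counting conventions to classified cell records:
#' anaphase/telophase pairs and multinucleated groups count once, dead
#' cells are excluded from the viable total, and all ratios are relative to
#' the number of viable cells (the segregation-error rate is relative to
#' anaphase events). A well with no viable cells reports zero ratios with
#' `empty_flag = TRUE` so downstream tables stay rectangular.
#'
#' @param records data frame of cell records: `phenotype`, `members`
#'   (semicolon-joined nucleus labels), `cse_positive`.
#' @param bridges data frame from [detect_bridges()] (or anything with one
#'   row per bridge).
#' @return a `well_phenotypes` list of counts and ratios.
#' @export
count_well <- function(records, bridges = NULL) {
  members <- lapply(strsplit(records$members, ";"), as.integer)
  all_m <- unlist(members)
  if (anyDuplicated(all_m))
    stop("object claimed by more than one cell record: ",
         paste(unique(all_m[duplicated(all_m)]), collapse = ", "))
  n_bridges <- if (is.null(bridges)) 0L else nrow(bridges)
  ph <- records$phenotype
  n_total <- length(all_m)
  n_dead <- sum(ph == "dead")
  n_viable <- sum(ph != "dead")
  n_mitotic <- sum(ph %in% c("mitotic", "anaphase", "telophase"))
  n_multi <- sum(ph == "multinucleated")
  n_ana <- sum(ph == "anaphase")
  n_ana_cse <- sum(ph == "anaphase" & records$cse_positive %in% TRUE)
  ratio <- function(num, den) if (den > 0) num / den else 0
  structure(list(
    n_total_objects = n_total, n_dead = n_dead, n_viable = n_viable,
    n_mitotic = n_mitotic, n_multinucleated = n_multi, n_anaphase = n_ana,
    n_anaphase_cse = n_ana_cse, n_bridges = n_bridges,
    mitotic_index = ratio(n_mitotic, n_viable),
    multinucleation_index = ratio(n_multi, n_viable),
    cse_rate = ratio(n_ana_cse, n_ana),
    bridge_rate = ratio(n_bridges, n_viable),
    empty_flag = n_viable == 0L), class = "well_phenotypes")
}

#' @export
print.well_phenotypes <- function(x, ...) {
  cat(sprintf(paste0("<well_phenotypes> %d objects: %d viable, %d dead | ",
                     "MI %.3f, multinucleation %.3f, CSE %.3f (%d/%d), ",
                     "bridges %.3f (%d)\n"),
              x$n_total_objects, x$n_viable, x$n_dead, x$mitotic_index,
              x$multinucleation_index, x$cse_rate, x$n_anaphase_cse,
              x$n_anaphase, x$bridge_rate, x$n_bridges))
  invisible(x)
}

#' Classify one well image end to end
#'
#' Runs segmentation, feature measurement and the full rule cascade on one
#' multi-channel image, producing cell records and the per-well phenotype
#' counts.
#'
#' @param image a [multichannel_image()].
#' @param cfg a [classifier_config()].
#' @param mode `"screenB"` or `"screenA"`.
#' @param keep_masks logical; include masks and feature table in the result.
#' @return list with `well` (a `well_phenotypes`), `records`, `pairs`,
#'   `bridges`, and (optionally) `nuclei`, `cytoplasm`, `features`.
#' @export
phenotype_well <- function(image, cfg = classifier_config(),
                           mode = c("screenB", "screenA"),
                           keep_masks = FALSE) {
  mode <- match.arg(mode)
  nuc <- segment_nuclei(image)
  cyto <- segment_cytoplasm(image, nuc)
  feats <- measure_objects(nuc, image)
  attr(feats, "pixel_size_um") <- image$pixel_size_um
  fd <- filter_dead(feats, cfg)
  mito <- classify_mitotic(fd$viable, cfg, mode)
  pairs <- pair_ana_telo(mito, image, nuc, cfg)
  if (nrow(pairs)) {
    pairs$cse_positive <- FALSE
    for (k in which(pairs$stage == "anaphase"))
      pairs$cse_positive[k] <- score_cse(pairs[k, ], image, nuc, feats, cfg)
  }
  paired_labels <- if (nrow(pairs)) c(pairs$label_a, pairs$label_b) else integer(0)
  nonmito <- fd$viable[!(fd$viable$label %in% c(mito$label)), , drop = FALSE]
  attr(nonmito, "pixel_size_um") <- image$pixel_size_um
  groups <- detect_multinucleated(nonmito, cyto, cfg)
  bridges <- detect_bridges(image, cyto, cfg)
  # assemble records: each segmented object appears in exactly one record
  recs <- list()
  add <- function(phenotype, members, cse = NA) {
    recs[[length(recs) + 1L]] <<- data.frame(
      phenotype = phenotype, members = paste(members, collapse = ";"),
      cse_positive = cse, stringsAsFactors = FALSE)
  }
  for (l in fd$dead$label) add("dead", l)
  if (nrow(pairs)) for (k in seq_len(nrow(pairs)))
    add(pairs$stage[k], c(pairs$label_a[k], pairs$label_b[k]),
        pairs$cse_positive[k])
  for (l in setdiff(mito$label, paired_labels)) add("mitotic", l)
  grouped <- unlist(groups)
  for (g in groups) add("multinucleated", g)
  for (l in setdiff(nonmito$label, grouped)) add("interphase", l)
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(phenotype = character(0), members = character(0),
               cse_positive = logical(0))
  records <- cbind(record_id = seq_len(nrow(records)), records)
  well <- count_well(records, bridges)
  out <- list(well = well, records = records, pairs = pairs, bridges = bridges)
  if (keep_masks) out <- c(out, list(nuclei = nuc, cytoplasm = cyto,
                                     features = feats))
  out
}
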