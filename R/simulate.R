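# Channel sets of the two screen configurations. Screen A stained for
# CEP215 (centrosome), alpha-tubulin, actin and DNA; screen B for PHH3
# (mitotic marker), alpha-tubulin, gamma-tubulin and DNA.
.channel_sets <- list(
  screenA = c("dna", "tubulin", "cep215", "actin"),
  screenB = c("dna", "tubulin", "phh3", "gtub")
)

.phenotypes <- c("interphase", "mitotic", "anaphase", "telophase",
                 "multinucleated", "dead")

#' Multi-channel image container
#'
#' A set of co-registered 2D intensity planes keyed by channel role, plus
#' the physical pixel size. All planes must share one shape and contain
#' finite, non-negative intensities (arbitrary units).
#'
#' @param planes named list of numeric matrices (channel role -> plane).
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @return an object of class `multichannel_image`.
#' @export
multichannel_image <- function(planes, pixel_size_um) {
  stopifnot(is.list(planes), length(planes) >= 1, !is.null(names(planes)))
  dims <- lapply(planes, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all planes must share the same shape")
  for (p in planes) {
    if (!all(is.finite(p)) || any(p < 0))
      stop("plane intensities must be finite and non-negative")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  structure(list(planes = planes, pixel_size_um = pixel_size_um),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<multichannel_image> %d x %d px, %.3g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$planes), collapse = ", ")))
  invisible(x)
}

#' Well simulation configuration
#'
#' Describes one simulated well image: field geometry, cell number, the
#' mixture of phenotype classes, per-event error rates, optics and noise.
#' `class_fractions` is over cell *events*: an anaphase/telophase pair or a
#' multinucleated group is one event (rendered as several nuclei), matching
#' the counting convention in which such cells count once.
#'
#' @param image_shape_px integer length-2, (H, W) in pixels.
#' @param pixel_size_um physical pixel size; the default 0.65 um/px matches
#'   a x20 air objective on a screening confocal.
#' @param n_cells number of cell events to place.
#' @param class_fractions named fractions over
#'   `c("interphase","mitotic","anaphase","telophase","multinucleated","dead")`,
#'   summing to 1.
#' @param cse_rate probability that an anaphase/telophase event carries a
#'   chromosome segregation error (chromatin bridge / lagging chromatid).
#' @param bridge_rate probability that an interphase event is rendered as a
#'   post-mitotic daughter pair connected by a cytokinetic bridge.
#' @param psf_sigma_px Gaussian point-spread sigma applied to every channel.
#' @param background_level additive background intensity (arbitrary units).
#' @param gaussian_noise_sd read-noise standard deviation.
#' @param poisson_scaling photon-count scaling for shot noise; pixel values
#'   are drawn as `rpois(value * s) / s`. 0 disables shot noise.
#' @param channel_set `"screenA"` or `"screenB"` (see [render_well()]).
#' @param seed integer seed; rendering is bit-reproducible given the config.
#' @param geometry rendering geometry, see [sim_geometry()].
#' @return a `well_sim_config` list.
#' @export
well_sim_config <- function(image_shape_px = c(320L, 320L),
                            pixel_size_um = 0.65,
                            n_cells = 100L,
                            class_fractions = c(interphase = 0.80,
                                                mitotic = 0.08,
                                                anaphase = 0.04,
                                                telophase = 0.03,
                                                multinucleated = 0.03,
                                                dead = 0.02),
                            cse_rate = 0.15,
                            bridge_rate = 0.10,
                            psf_sigma_px = 0.8,
                            background_level = 0.10,
                            gaussian_noise_sd = 0.01,
                            poisson_scaling = 100,
                            channel_set = c("screenB", "screenA"),
                            seed = 1L,
                            geometry = sim_geometry()) {
  channel_set <- match.arg(channel_set)
  image_shape_px <- as.integer(image_shape_px)
  if (length(image_shape_px) != 2L || any(image_shape_px <= 0))
    stop("image_shape_px must be two positive integers")
  cf <- class_fractions[.phenotypes]
  cf[is.na(cf)] <- 0
  names(cf) <- .phenotypes
  if (abs(sum(cf) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (any(cf < 0)) stop("class_fractions must be in [0,1]")
  for (r in c(cse_rate, bridge_rate))
    if (r < 0 || r > 1) stop("rates must be in [0,1]")
  stopifnot(pixel_size_um > 0, psf_sigma_px >= 0, background_level >= 0,
            gaussian_noise_sd >= 0, poisson_scaling >= 0)
  structure(list(image_shape_px = image_shape_px,
                 pixel_size_um = pixel_size_um,
                 n_cells = as.integer(n_cells),
                 class_fractions = cf,
                 cse_rate = cse_rate, bridge_rate = bridge_rate,
                 psf_sigma_px = psf_sigma_px,
                 background_level = background_level,
                 gaussian_noise_sd = gaussian_noise_sd,
                 poisson_scaling = poisson_scaling,
                 channel_set = channel_set,
                 seed = as.integer(seed),
                 geometry = geometry),
            class = "well_sim_config")
}

#' Rendering geometry defaults
#'
#' Free parameters of the renderer, in micrometres and arbitrary intensity
#' units. The values are chosen so that the default classifier thresholds
#' ([classifier_config()]) separate the phenotype classes; they are not
#' meant to be photorealistic. All sizes are semi-axes unless noted.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of geometry parameters.
#' @export
sim_geometry <- function(...) {
  g <- list(
    # interphase nuclei: ellipse semi-axes (um) and DNA amplitude
    inter_major_um = c(3.8, 4.5), inter_minor_um = c(3.0, 3.5),
    inter_dna_amp = 1.0,
    # cytoplasm: Gaussian sigma (um) and tubulin amplitude
    cyto_sigma_um = 3.9, cyto_tub_amp = 1.0,
    # condensed mitotic figures: disc radius (um), amplitudes
    mito_radius_um = c(2.05, 2.4), mito_dna_amp = 2.5,
    mito_spindle_sigma_um = 2.6, mito_spindle_amp = 1.8,
    # anaphase/telophase daughter nuclei: semi-axes along / across the
    # division axis; boundary gap ranges; corridor tubulin amplitudes
    # (anaphase lower than telophase, as the screen's stage rule expects)
    anatelo_along_um = 1.1, anatelo_across_um = 2.6, anatelo_dna_amp = 1.8,
    ana_gap_um = c(3.6, 4.2), telo_gap_um = c(3.6, 4.2),
    ana_corridor_tub_amp = 0.15, telo_corridor_tub_amp = 1.5,
    corridor_width_um = 2.4, pair_cyto_sigma_um = 5.0, pair_cyto_amp = 0.35,
    # chromosome segregation errors: a detached lagging-chromatid blob plus
    # a faint chromatin strand spanning the corridor, both dim enough to
    # stay below the nucleus segmentation threshold so they neither merge
    # the daughter nuclei nor distort their measured shape
    cse_width_um = 0.8, cse_dna_amp = 0.35,
    cse_blob_sigma_um = 0.8, cse_blob_amp = 0.5,
    # multinucleated cells: round nuclei, spacing, low-tubulin groups
    multi_radius_um = c(2.0, 2.3), multi_dna_amp = 1.0,
    binuc_sep_um = c(5.2, 5.8), multi_ring_radius_um = 3.5,
    multi_low_tub_amp = 0.35, multi_cyto_sigma_um = 5.0,
    # dead cells / debris: small bright DNA fragments, no tubulin
    dead_radius_um = c(0.8, 1.0), dead_dna_amp = 1.5,
    # cytokinetic bridges between interphase daughter pairs
    bridge_pair_dist_um = c(9.5, 11.5), bridge_len_um = c(3.5, 5.5),
    bridge_gap_um = 1.2, bridge_width_um = 1.2, bridge_tub_amp = 5.0,
    midbody_sigma_um = 0.8, midbody_amp = 2.0,
    # marker channels
    phh3_amp = 2.0, phh3_bg_amp = 0.05,
    gtub_spot_amp = 1.2, gtub_spot_sigma_um = 0.55,
    cep_inter_amp = 0.8, cep_mito_amp = 0.10, cep_halo_sigma_um = 3.0,
    actin_amp = 0.8,
    # per-event lognormal amplitude jitter (sdlog)
    amp_jitter_sd = 0.10
  )
  dots <- list(...)
  g[names(dots)] <- dots
  g
}

# evaluate code with a private RNG stream, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic per-well substream: a fixed affine counter scheme keeps every
# well independently reproducible from (plate seed, well index)
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + 7919 * as.double(index)) %% 2147483629)
}

runif1 <- function(range) if (length(range) == 2L) stats::runif(1, range[1], range[2]) else range

# ---- ground-truth cell event sampling ---------------------------------------

# Samples cell events, their placement and per-event geometry. Returns a list
# with `cells` (one row per cell), `events` (one row per event, used by the
# renderer) and nucleus-level positions.
sample_cell_specs <- function(cfg) {
  g <- cfg$geometry
  px <- cfg$pixel_size_um
  H <- cfg$image_shape_px[1]; W <- cfg$image_shape_px[2]
  n <- cfg$n_cells
  pheno <- if (n > 0)
    sample(.phenotypes, n, replace = TRUE, prob = cfg$class_fractions)
  else character(0)

  # effective placement radius per event (px)
  evt_radius <- function(ph, bridged) {
    r <- switch(ph, interphase = 7, mitotic = 6, anaphase = 9.5,
                telophase = 9.5, multinucleated = 9.5, dead = 4)
    if (bridged) r <- max(g$bridge_pair_dist_um) / px / 2 + 7
    r
  }

  events <- vector("list", n)
  placed <- matrix(numeric(0), ncol = 3)  # row, col, radius
  for (i in seq_len(n)) {
    ph <- pheno[i]
    bridged <- ph == "interphase" && stats::runif(1) < cfg$bridge_rate
    r <- evt_radius(ph, bridged)
    margin <- r + 3
    best <- NULL; best_clear <- -Inf
    for (try in 1:300) {
      cand <- c(stats::runif(1, margin, H - margin),
                stats::runif(1, margin, W - margin))
      clear <- if (nrow(placed) == 0) Inf else
        min(sqrt((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2) -
              placed[, 3] - r)
      if (clear > best_clear) { best <- cand; best_clear <- clear }
      if (clear >= 2) break
    }
    placed <- rbind(placed, c(best, r))
    theta <- stats::runif(1, 0, pi)
    amp_j <- exp(stats::rnorm(1, 0, g$amp_jitter_sd))
    ev <- list(event_id = i, phenotype = ph, row = best[1], col = best[2],
               orientation = theta, amp_jitter = amp_j, bridged = bridged,
               has_cse = FALSE, gap_um = NA_real_, sep_um = NA_real_,
               n_nuclei = NA_integer_)
    if (ph %in% c("anaphase", "telophase")) {
      ev$has_cse <- stats::runif(1) < cfg$cse_rate
      ev$gap_um <- runif1(if (ph == "anaphase") g$ana_gap_um else g$telo_gap_um)
      # centroid separation = boundary gap + twice the along-axis semi-axis
      ev$sep_um <- ev$gap_um + 2 * g$anatelo_along_um
    }
    if (ph == "multinucleated") {
      ev$n_nuclei <- sample(2:4, 1, prob = c(0.7, 0.2, 0.1))
      ev$sep_px <- runif1(g$binuc_sep_um) / px
    }
    if (bridged) {
      ev$pair_dist_um <- runif1(g$bridge_pair_dist_um)
      ev$bridge_len_um <- runif1(g$bridge_len_um)
    }
    # per-event size draws
    ev$size1 <- switch(ph,
      interphase = c(runif1(g$inter_major_um), runif1(g$inter_minor_um)),
      mitotic = rep(runif1(g$mito_radius_um), 2),
      anaphase = c(g$anatelo_along_um, g$anatelo_across_um),
      telophase = c(g$anatelo_along_um, g$anatelo_across_um),
      multinucleated = rep(runif1(g$multi_radius_um), 2),
      dead = rep(runif1(g$dead_radius_um), 2))
    if (bridged) ev$size2 <- c(runif1(g$inter_major_um), runif1(g$inter_minor_um))
    events[[i]] <- ev
  }

  # expand events into cells and nuclei
  cells <- list(); nuclei <- list(); cid <- 0L
  for (ev in events) {
    cid <- cid + 1L
    base <- list(cell_id = cid, event_id = ev$event_id, phenotype = ev$phenotype,
                 row = ev$row, col = ev$col, orientation = ev$orientation,
                 has_cse = ev$has_cse, pair_separation_um = ev$sep_um,
                 n_nuclei = ev$n_nuclei, has_bridge = isTRUE(ev$bridged))
    cells[[length(cells) + 1L]] <- base
    nuc <- nucleus_positions(ev, px)
    for (k in seq_len(nrow(nuc)))
      nuclei[[length(nuclei) + 1L]] <- list(cell_id = cid, event_id = ev$event_id,
                                            row = nuc[k, 1], col = nuc[k, 2],
                                            phenotype = ev$phenotype)
    if (isTRUE(ev$bridged)) {  # partner daughter cell of a bridged pair
      cid <- cid + 1L
      u <- c(cos(ev$orientation), sin(ev$orientation))
      p2 <- c(ev$row, ev$col) + u * ev$pair_dist_um / px
      cells[[length(cells) + 1L]] <- list(cell_id = cid, event_id = ev$event_id,
        phenotype = "interphase", row = p2[1], col = p2[2],
        orientation = ev$orientation, has_cse = FALSE,
        pair_separation_um = NA_real_, n_nuclei = NA_integer_, has_bridge = TRUE)
      nuclei[[length(nuclei) + 1L]] <- list(cell_id = cid, event_id = ev$event_id,
                                            row = p2[1], col = p2[2],
                                            phenotype = "interphase")
    }
  }
  cells <- do.call(rbind.data.frame, c(cells, stringsAsFactors = FALSE))
  if (nrow(cells)) cells$has_bridge <- vapply(events[cells$event_id],
                                              function(e) isTRUE(e$bridged), TRUE) &
                                       cells$phenotype == "interphase"
  nuclei <- do.call(rbind.data.frame, c(nuclei, stringsAsFactors = FALSE))
  list(cells = cells, nuclei = nuclei, events = events)
}

# nucleus centroid positions (px) for one event
nucleus_positions <- function(ev, px) {
  p <- c(ev$row, ev$col)
  u <- c(cos(ev$orientation), sin(ev$orientation))
  switch(ev$phenotype,
    anaphase = ,
    telophase = rbind(p - u * ev$sep_um / (2 * px), p + u * ev$sep_um / (2 * px)),
    multinucleated = {
      if (ev$n_nuclei == 2L) {
        d <- ev$sep_px
        rbind(p - u * d / 2, p + u * d / 2)
      } else {
        ang <- ev$orientation + 2 * pi * (seq_len(ev$n_nuclei) - 1) / ev$n_nuclei
        t(vapply(ang, function(a) p + c(cos(a), sin(a)) * 3.5 / px, numeric(2)))
      }
    },
    matrix(p, nrow = 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- rasterization primitives ----------------------------------------------

.patch_idx <- function(center, r, H, W) {
  rows <- max(1L, floor(center[1] - r)):min(H, ceiling(center[1] + r))
  cols <- max(1L, floor(center[2] - r)):min(W, ceiling(center[2] + r))
  if (!length(rows) || !length(cols)) return(NULL)
  list(rows = rows, cols = cols)
}

# The draw_* primitives mutate a channel plane held in an environment in
# place (patch-wise), which keeps rendering linear in the number of cells
# rather than in cells x image area.

# add a hard ellipse (amp inside) -- blurred later by the PSF
draw_ellipse <- function(pl, ch, center, semi, theta, amp) {
  p <- .patch_idx(center, max(semi) + 2, nrow(pl[[ch]]), ncol(pl[[ch]]))
  if (is.null(p)) return(invisible())
  dr <- p$rows - center[1]; dc <- p$cols - center[2]
  ct <- cos(theta); st <- sin(theta)
  U <- outer(dr, dc * 0, "+") * ct + outer(dr * 0, dc, "+") * st
  V <- -outer(dr, dc * 0, "+") * st + outer(dr * 0, dc, "+") * ct
  pl[[ch]][p$rows, p$cols] <- pl[[ch]][p$rows, p$cols] +
    amp * ((U / semi[1])^2 + (V / semi[2])^2 <= 1)
  invisible()
}

# add an isotropic Gaussian blob
draw_gauss <- function(pl, ch, center, sigma, amp) {
  p <- .patch_idx(center, 4 * sigma, nrow(pl[[ch]]), ncol(pl[[ch]]))
  if (is.null(p)) return(invisible())
  dr <- p$rows - center[1]; dc <- p$cols - center[2]
  q <- outer(dr^2, dc^2, "+") / (2 * sigma^2)
  pl[[ch]][p$rows, p$cols] <- pl[[ch]][p$rows, p$cols] + amp * exp(-q)
  invisible()
}

# add a hard line segment of given full width
draw_segment <- function(pl, ch, p1, p2, width, amp) {
  ctr <- (p1 + p2) / 2
  r <- sqrt(sum((p2 - p1)^2)) / 2 + width + 1
  p <- .patch_idx(ctr, r, nrow(pl[[ch]]), ncol(pl[[ch]]))
  if (is.null(p)) return(invisible())
  v <- p2 - p1; L2 <- sum(v^2)
  dr <- outer(p$rows - p1[1], p$cols * 0, "+")
  dc <- outer(p$rows * 0, p$cols - p1[2], "+")
  tt <- if (L2 > 0) pmin(pmax((dr * v[1] + dc * v[2]) / L2, 0), 1) else 0
  d2 <- (dr - tt * v[1])^2 + (dc - tt * v[2])^2
  pl[[ch]][p$rows, p$cols] <- pl[[ch]][p$rows, p$cols] + amp * (d2 <= (width / 2)^2)
  invisible()
}

# ---- well rendering ---------------------------------------------------------

#' Render one synthetic well image with ground truth
#'
#' Draws every sampled cell event onto the channel planes of the requested
#' screen configuration, convolves with a Gaussian PSF, and adds Poisson and
#' Gaussian noise. Nuclei are elliptical DNA blobs; mitotic figures carry
#' condensed bright DNA plus a high mitotic marker (PHH3, screen B) or a
#' bright tubulin spindle with low CEP215 (screen A); anaphase/telophase
#' events are two small elongated DNA blobs with inter-nucleus tubulin
#' (lower in anaphase than telophase); segregation errors add a DNA filament
#' across the corridor; cytokinetic bridges add a split bright tubulin line
#' between two daughter cells with a gamma-tubulin midbody spot.
#'
#' Rendering is pure: the same config (including its seed) gives
#' bit-identical output.
#'
#' @param config a [well_sim_config()].
#' @return list with `image` (a [multichannel_image()]) and `truth` (list
#'   with `cells`, `nuclei` data frames and `true_counts`; see
#'   [true_counts()]).
#' @export
render_well <- function(config) {
  stopifnot(inherits(config, "well_sim_config"))
  with_seed(config$seed, {
    spec <- sample_cell_specs(config)
    img <- rasterize_specs(spec, config)
    truth <- list(cells = spec$cells, nuclei = spec$nuclei,
                  true_counts = true_counts(spec$cells))
    list(image = img, truth = truth)
  })
}

rasterize_specs <- function(spec, cfg) {
  g <- cfg$geometry; px <- cfg$pixel_size_um
  H <- cfg$image_shape_px[1]; W <- cfg$image_shape_px[2]
  roles <- .channel_sets[[cfg$channel_set]]
  pl <- new.env(parent = emptyenv())
  for (r in roles) pl[[r]] <- matrix(0, H, W)
  has_gtub <- "gtub" %in% roles

  spot_pair <- function(ch, center, off_px, sigma, amp, theta) {
    u <- c(cos(theta + pi / 2), sin(theta + pi / 2))
    draw_gauss(pl, ch, center + u * off_px, sigma, amp)
    draw_gauss(pl, ch, center - u * off_px, sigma, amp)
  }

  for (ev in spec$events) {
    ctr <- c(ev$row, ev$col); th <- ev$orientation; aj <- ev$amp_jitter
    nuc <- nucleus_positions(ev, px)
    switch(ev$phenotype,
      interphase = {
        semi <- ev$size1 / px
        draw_ellipse(pl, "dna", ctr, semi, th, g$inter_dna_amp * aj)
        draw_gauss(pl, "tubulin", ctr, g$cyto_sigma_um / px, g$cyto_tub_amp * aj)
        if (cfg$channel_set == "screenB") {
          draw_ellipse(pl, "phh3", ctr, semi, th, g$phh3_bg_amp)
          spot_pair("gtub", ctr, semi[1] + 0.7 / px,
                    g$gtub_spot_sigma_um / px, g$gtub_spot_amp, th)
        } else {
          draw_gauss(pl, "cep215", ctr, g$cep_halo_sigma_um / px,
                     g$cep_inter_amp * aj)
          draw_gauss(pl, "actin", ctr, g$cyto_sigma_um / px, g$actin_amp)
        }
        if (isTRUE(ev$bridged)) {
          u <- c(cos(th), sin(th))
          p2 <- ctr + u * ev$pair_dist_um / px
          semi2 <- ev$size2 / px
          draw_ellipse(pl, "dna", p2, semi2, th + pi / 2, g$inter_dna_amp * aj)
          draw_gauss(pl, "tubulin", p2, g$cyto_sigma_um / px, g$cyto_tub_amp * aj)
          if (cfg$channel_set == "screenB") {
            draw_ellipse(pl, "phh3", p2, semi2, th + pi / 2, g$phh3_bg_amp)
            spot_pair("gtub", p2, semi2[1] + 0.7 / px,
                      g$gtub_spot_sigma_um / px, g$gtub_spot_amp, th)
          } else {
            draw_gauss(pl, "cep215", p2, g$cep_halo_sigma_um / px,
                       g$cep_inter_amp * aj)
            draw_gauss(pl, "actin", p2, g$cyto_sigma_um / px, g$actin_amp)
          }
          # bridge: two bright tubulin half segments + midbody
          mid <- (ctr + p2) / 2
          halflen <- (ev$bridge_len_um - g$bridge_gap_um) / 2 / px
          gaphalf <- g$bridge_gap_um / 2 / px
          for (s in c(-1, 1)) {
            a <- mid + u * s * gaphalf
            b <- mid + u * s * (gaphalf + halflen)
            draw_segment(pl, "tubulin", a, b, g$bridge_width_um / px,
                         g$bridge_tub_amp * aj)
          }
          if (has_gtub)
            draw_gauss(pl, "gtub", mid, g$midbody_sigma_um / px, g$midbody_amp)
        }
      },
      mitotic = {
        r <- ev$size1[1] / px
        draw_ellipse(pl, "dna", ctr, c(r, r), 0, g$mito_dna_amp * aj)
        draw_gauss(pl, "tubulin", ctr, g$mito_spindle_sigma_um / px,
                   g$mito_spindle_amp * aj)
        if (cfg$channel_set == "screenB") {
          draw_ellipse(pl, "phh3", ctr, c(r, r), 0, g$phh3_amp * aj)
          spot_pair("gtub", ctr, r + 1.4 / px,
                    g$gtub_spot_sigma_um / px, g$gtub_spot_amp, 0)
        } else {
          draw_gauss(pl, "cep215", ctr, g$cep_halo_sigma_um / px, g$cep_mito_amp)
          draw_gauss(pl, "actin", ctr, g$cyto_sigma_um / px, g$actin_amp)
        }
      },
      anaphase = ,
      telophase = {
        semi <- c(g$anatelo_along_um, g$anatelo_across_um) / px
        corridor_amp <- if (ev$phenotype == "anaphase")
          g$ana_corridor_tub_amp else g$telo_corridor_tub_amp
        draw_gauss(pl, "tubulin", ctr, g$pair_cyto_sigma_um / px,
                   g$pair_cyto_amp * aj)
        u <- c(cos(th), sin(th))
        # inner nucleus boundaries delimit the corridor
        b1 <- ctr - u * ev$gap_um / (2 * px)
        b2 <- ctr + u * ev$gap_um / (2 * px)
        draw_segment(pl, "tubulin", b1, b2, g$corridor_width_um / px,
                     corridor_amp * aj)
        for (k in 1:2) {
          draw_ellipse(pl, "dna", nuc[k, ], semi, th, g$anatelo_dna_amp * aj)
          if (cfg$channel_set == "screenB")
            draw_ellipse(pl, "phh3", nuc[k, ], semi, th, g$phh3_amp * aj)
        }
        if (ev$has_cse) {
          draw_segment(pl, "dna", b1, b2, g$cse_width_um / px,
                       g$cse_dna_amp * aj)
          draw_gauss(pl, "dna", ctr, g$cse_blob_sigma_um / px,
                     g$cse_blob_amp * aj)
        }
      },
      multinucleated = {
        rr <- ev$size1[1] / px
        lowtub <- ev$n_nuclei > 2L
        sig <- (if (lowtub) g$multi_cyto_sigma_um else g$cyto_sigma_um) / px
        amp <- if (lowtub) g$multi_low_tub_amp else g$cyto_tub_amp * aj
        draw_gauss(pl, "tubulin", ctr, sig, amp)
        for (k in seq_len(nrow(nuc))) {
          draw_ellipse(pl, "dna", nuc[k, ], c(rr, rr), 0, g$multi_dna_amp * aj)
          if (cfg$channel_set == "screenB")
            draw_ellipse(pl, "phh3", nuc[k, ], c(rr, rr), 0, g$phh3_bg_amp)
        }
        if (cfg$channel_set == "screenB")
          spot_pair("gtub", ctr, rr + 0.7 / px,
                    g$gtub_spot_sigma_um / px, g$gtub_spot_amp, th)
        else {
          draw_gauss(pl, "cep215", ctr, g$cep_halo_sigma_um / px,
                     g$cep_inter_amp * aj)
          draw_gauss(pl, "actin", ctr, sig, g$actin_amp)
        }
      },
      dead = {
        r <- ev$size1[1] / px
        draw_ellipse(pl, "dna", ctr, c(r, r), 0, g$dead_dna_amp * aj)
      })
  }
  pl <- mget(roles, envir = pl)

  # optics + noise
  for (ch in names(pl)) {
    p <- pl[[ch]] + cfg$background_level
    if (cfg$psf_sigma_px > 0)
      p <- as.matrix(EBImage::gblur(p, sigma = cfg$psf_sigma_px))
    if (cfg$poisson_scaling > 0)
      p <- matrix(stats::rpois(length(p), pmax(p, 0) * cfg$poisson_scaling) /
                    cfg$poisson_scaling, nrow(p), ncol(p))
    if (cfg$gaussian_noise_sd > 0)
      p <- p + stats::rnorm(length(p), 0, cfg$gaussian_noise_sd)
    pl[[ch]] <- pmax(p, 0)
  }
  multichannel_image(pl, cfg$pixel_size_um)
}

#' Ground-truth per-well counts
#'
#' Enumerates a ground-truth `cells` data frame into the per-well counts the
#' screen reports: anaphase/telophase pairs and multinucleated groups count
#' once, dead cells are excluded from the viable total, and each cytokinetic
#' bridge links two viable daughter cells.
#'
#' @param cells ground-truth cells data frame from [render_well()].
#' @return named list of counts and ratios (`viable`, `mitotic`,
#'   `multinucleated`, `anaphase`, `anaphase_with_cse`, `bridges`,
#'   `mitotic_index`, `multinucleation_index`, `cse_rate`, `bridge_rate`).
#' @export
true_counts <- function(cells) {
  n_dead <- sum(cells$phenotype == "dead")
  viable <- nrow(cells) - n_dead
  mitotic <- sum(cells$phenotype %in% c("mitotic", "anaphase", "telophase"))
  multi <- sum(cells$phenotype == "multinucleated")
  ana <- sum(cells$phenotype == "anaphase")
  ana_cse <- sum(cells$phenotype == "anaphase" & cells$has_cse)
  bridges <- sum(cells$has_bridge %in% TRUE) / 2
  list(total_cells = nrow(cells), dead = n_dead, viable = viable,
       mitotic = mitotic, multinucleated = multi, anaphase = ana,
       anaphase_with_cse = ana_cse, bridges = bridges,
       mitotic_index = if (viable > 0) mitotic / viable else 0,
       multinucleation_index = if (viable > 0) multi / viable else 0,
       cse_rate = if (ana > 0) ana_cse / ana else 0,
       bridge_rate = if (viable > 0) bridges / viable else 0)
}

# ---- plate simulation -------------------------------------------------------

#' Plate simulation configuration
#'
#' Describes one simulated multi-well plate: geometry, the shared base well
#' configuration, designated hit and control wells, per-well rate
#' multipliers (e.g. heterogeneous true target effects), and a plate-wide
#' multiplicative batch factor applied to every reported per-well ratio.
#'
#' @param n_rows,n_cols plate geometry (default 16 x 24, a 384-well plate).
#' @param base_well a [well_sim_config()] shared by all wells.
#' @param hit_wells named list: well id -> named multipliers applied to the
#'   mitotic-family class fractions (e.g. `list(B03 = 3)` triples the
#'   mitotic, anaphase and telophase fractions of well B03). A bare numeric
#'   is interpreted as a mitotic-family multiplier.
#' @param control_wells named character: well id -> role, one of
#'   `"negative"`, `"positive_mitotic"`, `"positive_cytokinesis"`.
#' @param well_multipliers named numeric of per-well mitotic-family rate
#'   multipliers for library wells (true biological effect sizes); applied
#'   on top of nothing else -- hit and control overrides take precedence.
#' @param target_map named character: well id -> target id. Defaults to the
#'   well id itself.
#' @param plate_factor multiplicative batch effect (> 0) applied to every
#'   per-well ratio reported for this plate.
#' @param plate_id plate identifier string.
#' @param seed integer; per-well seeds derive from it by a fixed counter
#'   scheme, so any well re-renders identically in isolation.
#' @return a `plate_sim_config` list.
#' @export
plate_sim_config <- function(n_rows = 16L, n_cols = 24L,
                             base_well = well_sim_config(),
                             hit_wells = list(), control_wells = character(),
                             well_multipliers = NULL, target_map = NULL,
                             plate_factor = 1, plate_id = "P1", seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, plate_factor > 0,
            inherits(base_well, "well_sim_config"))
  ids <- plate_well_ids(n_rows, n_cols)
  if (is.numeric(hit_wells)) hit_wells <- as.list(hit_wells)
  bad <- setdiff(c(names(hit_wells), names(control_wells), names(well_multipliers),
                   names(target_map)), ids)
  if (length(bad)) stop("unknown well ids: ", paste(bad, collapse = ", "))
  overlap <- intersect(names(hit_wells), names(control_wells))
  if (length(overlap))
    stop("wells assigned as both hit and control: ", paste(overlap, collapse = ", "))
  if (length(control_wells) &&
      !all(control_wells %in% c("negative", "positive_mitotic", "positive_cytokinesis")))
    stop("unknown control role")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 base_well = base_well, hit_wells = hit_wells,
                 control_wells = control_wells,
                 well_multipliers = well_multipliers, target_map = target_map,
                 plate_factor = plate_factor, plate_id = plate_id,
                 seed = as.integer(seed)),
            class = "plate_sim_config")
}

#' Well identifiers of a plate, row-major ("A01", "A02", ...)
#' @param n_rows,n_cols plate geometry.
#' @export
plate_well_ids <- function(n_rows, n_cols) {
  as.vector(t(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols),
                    function(r, c) sprintf("%s%02d", r, c))))
}

# scale the mitotic-family class fractions by `mult`, absorbing the change
# into the interphase fraction
scale_fractions <- function(fr, mult) {
  if (is.list(mult)) mult <- unlist(mult)
  if (is.null(names(mult)) || identical(names(mult), ""))
    mult <- c(mitotic = unname(mult[1]), anaphase = unname(mult[1]),
              telophase = unname(mult[1]))
  fr[names(mult)] <- fr[names(mult)] * mult
  other <- sum(fr[setdiff(names(fr), "interphase")])
  if (other >= 1) stop("class fraction multipliers leave no interphase mass")
  fr["interphase"] <- 1 - other
  fr
}

well_config_for <- function(cfg, well_id, index) {
  bw <- cfg$base_well
  fr <- bw$class_fractions
  br <- bw$bridge_rate
  role <- unname(cfg$control_wells[well_id])
  if (!is.na(role %||% NA) && length(role)) {
    if (identical(role, "positive_mitotic")) fr <- scale_fractions(fr, 4)
    if (identical(role, "positive_cytokinesis")) {
      fr <- scale_fractions(fr, c(multinucleated = 4))
      br <- min(1, br * 3)
    }
  } else if (well_id %in% names(cfg$hit_wells)) {
    fr <- scale_fractions(fr, cfg$hit_wells[[well_id]])
  } else if (!is.null(cfg$well_multipliers) && well_id %in% names(cfg$well_multipliers)) {
    fr <- scale_fractions(fr, cfg$well_multipliers[[well_id]])
  }
  bw$class_fractions <- fr
  bw$bridge_rate <- br
  bw$seed <- derive_seed(cfg$seed, index)
  bw
}

#' Simulate a whole plate
#'
#' Renders (or, with `render = FALSE`, only samples ground truth for) every
#' well of a plate and returns the per-well results together with a table of
#' true per-well ratios. The plate batch factor multiplies every reported
#' ratio, emulating a plate-wide readout batch effect; ratios are otherwise
#' the enumerated ground-truth ratios of the realized cells.
#'
#' @param config a [plate_sim_config()].
#' @param wells optional character vector restricting which wells to
#'   simulate (default: all wells that have a target, control or hit role if
#'   any such are declared, otherwise the full plate).
#' @param render logical; render images (TRUE) or ground truth only.
#' @return list with `wells` (named list of [render_well()] results) and
#'   `truth_table` (data frame: plate_id, well_id, target_id, feature,
#'   ratio, is_control, control_role).
#' @export
simulate_plate <- function(config, wells = NULL, render = TRUE) {
  stopifnot(inherits(config, "plate_sim_config"))
  ids <- plate_well_ids(config$n_rows, config$n_cols)
  if (is.null(wells)) wells <- default_wells(config, ids)
  out <- vector("list", length(wells)); names(out) <- wells
  rows <- vector("list", length(wells))
  for (i in seq_along(wells)) {
    wid <- wells[i]
    wc <- well_config_for(config, wid, match(wid, ids))
    res <- if (render) render_well(wc) else with_seed(wc$seed, {
      spec <- sample_cell_specs(wc)
      list(image = NULL, truth = list(cells = spec$cells, nuclei = spec$nuclei,
                                      true_counts = true_counts(spec$cells)))
    })
    out[[i]] <- res
    tc <- res$truth$true_counts
    role <- unname(config$control_wells[wid])
    target <- if (!is.null(config$target_map) && wid %in% names(config$target_map))
      config$target_map[[wid]] else wid
    rows[[i]] <- data.frame(
      plate_id = config$plate_id, well_id = wid, target_id = target,
      feature = c("mitotic_index", "multinucleation_index", "cse_rate",
                  "bridge_rate", "viability"),
      ratio = config$plate_factor *
        c(tc$mitotic_index, tc$multinucleation_index, tc$cse_rate,
          tc$bridge_rate, tc$viable),
      is_control = wid %in% names(config$control_wells),
      control_role = if (length(role) && !is.na(role)) role else NA_character_,
      stringsAsFactors = FALSE)
  }
  list(wells = out, truth_table = do.call(rbind, rows),
       plate_factor = config$plate_factor, plate_id = config$plate_id)
}

# which wells a plate simulation covers by default: every well, unless an
# explicit target map restricts the layout (controls/hits must then be
# inside it)
default_wells <- function(config, ids) {
  if (is.null(config$target_map)) return(ids)
  declared <- unique(c(names(config$target_map), names(config$control_wells),
                       names(config$hit_wells), names(config$well_multipliers)))
  ids[ids %in% declared]
}
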