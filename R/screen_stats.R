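# Plate normalization, Z-scores and hit calling for the screen's per-well
# ratio tables, plus replicate concordance.
#
# A screen table is a long-format data frame with columns plate_id, well_id,
# target_id, feature, ratio (and optionally normalized_ratio, z, is_control,
# control_role); one row per (plate, well, feature).

check_screen_table <- function(table, feature) {
  need <- c("plate_id", "well_id", "feature", "ratio")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("screen table lacks columns: ", paste(miss, collapse = ", "))
  tab <- table[table$feature == feature, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rows for feature '", feature, "'")
  if (anyDuplicated(tab[, c("plate_id", "well_id", "feature")]))
    stop("(plate_id, well_id, feature) must be unique")
  if (!all(is.finite(tab$ratio))) stop("ratios must be finite")
  if (is.null(tab$is_control)) tab$is_control <- FALSE
  tab
}

#' Normalize per-well ratios across plates
#'
#' Computes the average ratio per plate and the grand average over plates
#' (the reference mean), then scales every well of each plate so the
#' per-plate average equals the reference. This removes plate-wide
#' multiplicative batch effects. Control wells are excluded from the plate
#' means by default but are scaled along with the rest of their plate.
#'
#' @param table a screen table (see [simulate_plate()]'s `truth_table` or
#'   [measure_plate()]).
#' @param feature which feature's rows to normalize, e.g.
#'   `"mitotic_index"`.
#' @param use_controls include control wells when estimating plate means.
#' @return list with `table` (the feature's rows plus `normalized_ratio`)
#'   and `summary` (per-plate means, the reference mean, scale factors, and
#'   the SD of normalized ratios across library wells).
#' @export
normalize_plates <- function(table, feature, use_controls = FALSE) {
  tab <- check_screen_table(table, feature)
  est <- if (use_controls) tab else tab[!tab$is_control, , drop = FALSE]
  if (nrow(est) == 0) stop("no wells available to estimate plate means")
  pp <- tapply(est$ratio, est$plate_id, mean)
  per_plate <- stats::setNames(as.vector(pp), names(pp))
  reference <- mean(per_plate)
  scale_factors <- ifelse(per_plate == 0, 1, reference / per_plate)
  if (any(per_plate == 0))
    warning("plate(s) with zero mean ratio left unscaled: ",
            paste(names(per_plate)[per_plate == 0], collapse = ", "))
  tab$normalized_ratio <- tab$ratio *
    scale_factors[match(tab$plate_id, names(per_plate))]
  lib <- tab[!tab$is_control, , drop = FALSE]
  sd_wells <- stats::sd(lib$normalized_ratio)
  list(table = tab,
       summary = list(per_plate_mean = per_plate,
                      reference_mean = reference,
                      scale_factors = scale_factors,
                      sd_across_wells = sd_wells))
}

#' Z-scores of normalized ratios
#'
#' z = (x - mu) / sigma, where x is the normalized per-well ratio, mu the
#' reference (grand mean) ratio and sigma the standard deviation of
#' normalized ratios across wells. By default mu and sigma are estimated
#' from library (non-control) wells.
#'
#' @param normalized result of [normalize_plates()], or a screen table that
#'   already has a `normalized_ratio` column.
#' @param use_controls include control wells when estimating mu and sigma.
#' @return the screen table with a `z` column.
#' @export
screen_zscore <- function(normalized, use_controls = FALSE) {
  tab <- if (is.list(normalized) && !is.data.frame(normalized))
    normalized$table else normalized
  if (is.null(tab$normalized_ratio)) stop("normalize_plates() first")
  est <- if (use_controls) tab else tab[!tab$is_control, , drop = FALSE]
  mu <- mean(est$normalized_ratio)
  sigma <- stats::sd(est$normalized_ratio)
  if (!is.finite(sigma) || sigma == 0) stop("zero variance across wells")
  tab$z <- (tab$normalized_ratio - mu) / sigma
  tab
}

#' Call hits from Z-scores
#'
#' Aggregates Z-scores per target (mean over a target's wells by default,
#' e.g. technical replicates) and returns targets past the threshold,
#' ranked by |z| in the requested direction; ties break lexicographically
#' by target id.
#'
#' @param table screen table with a `z` column ([screen_zscore()]).
#' @param z_min absolute Z-score threshold.
#' @param direction `"increase"` (default; depletion increases the defect
#'   frequency), `"decrease"`, or `"both"`.
#' @param aggregate `"mean"`, `"max"` or `"none"` (one row per well).
#' @param include_controls keep control wells in the ranking.
#' @return data frame `target_id`, `z`, `n_wells`, ranked.
#' @export
call_hits <- function(table, z_min = 2, direction = c("increase", "decrease", "both"),
                      aggregate = c("mean", "max", "none"),
                      include_controls = FALSE) {
  direction <- match.arg(direction)
  aggregate <- match.arg(aggregate)
  if (is.null(table$z)) stop("screen_zscore() first")
  tab <- table
  if (!include_controls && !is.null(tab$is_control))
    tab <- tab[!tab$is_control, , drop = FALSE]
  if (is.null(tab$target_id)) tab$target_id <- tab$well_id
  agg <- switch(aggregate,
    mean = stats::aggregate(z ~ target_id, tab, mean),
    max = stats::aggregate(z ~ target_id, tab, function(v) v[which.max(abs(v))]),
    none = data.frame(target_id = tab$target_id, z = tab$z))
  nw <- table(tab$target_id)
  agg$n_wells <- as.integer(nw[agg$target_id])
  sel <- switch(direction,
    increase = agg$z >= z_min,
    decrease = agg$z <= -z_min,
    both = abs(agg$z) >= z_min)
  hits <- agg[sel, , drop = FALSE]
  key <- if (direction == "decrease") hits$z else -abs(hits$z)
  hits[order(key, hits$target_id), , drop = FALSE]
}

#' Spearman concordance between replicate screens
#'
#' Rank correlation (average ranks for ties) of a feature's per-well values
#' between two screen tables, matched on `well_id` (or `target_id` if wells
#' differ). Uses the normalized ratio when present, the raw ratio
#' otherwise.
#'
#' @param tableA,tableB screen tables restricted to, or containing, the
#'   feature of interest.
#' @param feature feature name.
#' @param by matching key, `"well_id"` (default) or `"target_id"`.
#' @return the Spearman correlation coefficient.
#' @export
replicate_correlation <- function(tableA, tableB, feature, by = "well_id") {
  a <- tableA[tableA$feature == feature, , drop = FALSE]
  b <- tableB[tableB$feature == feature, , drop = FALSE]
  val <- function(t) if (!is.null(t$normalized_ratio)) t$normalized_ratio else t$ratio
  common <- intersect(a[[by]], b[[by]])
  if (length(common) < 3) stop("need at least 3 matched wells")
  va <- val(a)[match(common, a[[by]])]
  vb <- val(b)[match(common, b[[by]])]
  stats::cor(va, vb, method = "spearman")
}

#' Measure a simulated plate with the image-analysis cascade
#'
#' Runs [phenotype_well()] on every rendered well of a [simulate_plate()]
#' result and assembles the measured screen table. The plate's batch factor
#' multiplies the measured ratios, mirroring the plate-wide readout batch
#' effect the normalization step is meant to remove.
#'
#' @param plate result of [simulate_plate()] (with `render = TRUE`).
#' @param config a [plate_sim_config()] (for well roles and targets).
#' @param cfg a [classifier_config()].
#' @param mode `"screenB"` or `"screenA"`.
#' @return a measured screen table (long format).
#' @export
measure_plate <- function(plate, config, cfg = classifier_config(),
                          mode = "screenB") {
  ids <- plate_well_ids(config$n_rows, config$n_cols)
  rows <- vector("list", length(plate$wells))
  for (i in seq_along(plate$wells)) {
    wid <- names(plate$wells)[i]
    img <- plate$wells[[i]]$image
    if (is.null(img)) stop("plate was simulated without render = TRUE")
    ph <- phenotype_well(img, cfg, mode)$well
    role <- unname(config$control_wells[wid])
    target <- if (!is.null(config$target_map) && wid %in% names(config$target_map))
      config$target_map[[wid]] else wid
    rows[[i]] <- data.frame(
      plate_id = plate$plate_id, well_id = wid, target_id = target,
      feature = c("mitotic_index", "multinucleation_index", "cse_rate",
                  "bridge_rate", "viability"),
      ratio = plate$plate_factor *
        c(ph$mitotic_index, ph$multinucleation_index, ph$cse_rate,
          ph$bridge_rate, ph$n_viable),
      is_control = wid %in% names(config$control_wells),
      control_role = if (length(role) && !is.na(role)) role else NA_character_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate and measure a plate well by well
#'
#' Streams through a plate: renders each well, runs the phenotype cascade,
#' and discards the image, so whole screens can be processed in bounded
#' memory. Returns both the ground-truth ratio table and the measured
#' table (both carrying the plate batch factor).
#'
#' @param config a [plate_sim_config()].
#' @param cfg a [classifier_config()].
#' @param mode `"screenB"` or `"screenA"`.
#' @param wells optional character vector of wells (default: declared wells).
#' @return list with `truth_table` and `measured_table`.
#' @export
simulate_and_measure_plate <- function(config, cfg = classifier_config(),
                                       mode = "screenB", wells = NULL) {
  stopifnot(inherits(config, "plate_sim_config"))
  ids <- plate_well_ids(config$n_rows, config$n_cols)
  if (is.null(wells)) wells <- default_wells(config, ids)
  feats <- c("mitotic_index", "multinucleation_index", "cse_rate",
             "bridge_rate", "viability")
  truth_rows <- vector("list", length(wells))
  meas_rows <- vector("list", length(wells))
  for (i in seq_along(wells)) {
    wid <- wells[i]
    wc <- well_config_for(config, wid, match(wid, ids))
    res <- render_well(wc)
    ph <- phenotype_well(res$image, cfg, mode)$well
    tc <- res$truth$true_counts
    role <- unname(config$control_wells[wid])
    target <- if (!is.null(config$target_map) && wid %in% names(config$target_map))
      config$target_map[[wid]] else wid
    base <- data.frame(plate_id = config$plate_id, well_id = wid,
                       target_id = target, feature = feats,
                       is_control = wid %in% names(config$control_wells),
                       control_role = if (length(role) && !is.na(role)) role
                                      else NA_character_,
                       stringsAsFactors = FALSE)
    truth_rows[[i]] <- cbind(base, ratio = config$plate_factor *
      c(tc$mitotic_index, tc$multinucleation_index, tc$cse_rate,
        tc$bridge_rate, tc$viable))
    meas_rows[[i]] <- cbind(base, ratio = config$plate_factor *
      c(ph$mitotic_index, ph$multinucleation_index, ph$cse_rate,
        ph$bridge_rate, ph$n_viable))
  }
  list(truth_table = do.call(rbind, truth_rows),
       measured_table = do.call(rbind, meas_rows))
}

#' Configuration of a simulated candidate-validation screen
#'
#' Builds the plate set of a small validation-style screen: `n_replicates`
#' biological replicates, each consisting of `length(plate_factors)`
#' technical-replicate plates sharing one 96-well layout, with a distinct
#' plate-wide batch factor per plate. Library targets carry heterogeneous
#' true effect sizes (truncated-normal multipliers of the mitotic-class
#' fractions, emulating a candidate list spanning a range of phenotype
#' strengths); a designated fraction are strong hits with a fixed
#' multiplier; a few wells are negative controls.
#'
#' @param seed master seed; target effects and per-plate rendering derive
#'   from it.
#' @param n_rows,n_cols plate geometry (default 8 x 12, a 96-well plate).
#' @param n_replicates biological replicates (default 2).
#' @param plate_factors batch factors, one technical-replicate plate each.
#' @param hit_fraction fraction of library targets designated as hits.
#' @param hit_multiplier mitotic-rate multiplier of hit targets (default 3).
#' @param effect_sd SD of the truncated-normal effect multipliers of
#'   non-hit library targets (mean 1, floor 0.15).
#' @param n_controls number of negative-control wells.
#' @param base_well shared [well_sim_config()]; its class fractions set the
#'   base mitotic rate.
#' @return list with `plates` (list of [plate_sim_config()]; elements named
#'   `<replicate>_<plate>`), `replicate` and `plate_factor` per plate,
#'   `targets`, `hit_targets`, `multipliers`.
#' @export
validation_screen_config <- function(seed = 1L, n_rows = 8L, n_cols = 12L,
                                     n_replicates = 2L,
                                     plate_factors = c(0.7, 1, 1.3, 2),
                                     hit_fraction = 0.05, hit_multiplier = 3,
                                     effect_sd = 0.5, n_controls = 4L,
                                     base_well = screen_base_well()) {
  n_wells <- n_rows * n_cols
  ids <- plate_well_ids(n_rows, n_cols)
  ctrl_wells <- ids[round(seq(1, n_wells, length.out = n_controls))]
  lib_wells <- setdiff(ids, ctrl_wells)
  targets <- sprintf("T%03d", seq_along(lib_wells))
  target_map <- stats::setNames(targets, lib_wells)
  with_seed(derive_seed(seed, 0L), {
    n_hits <- max(1L, round(hit_fraction * length(targets)))
    hit_targets <- sort(sample(targets, n_hits))
    mult <- pmax(0.15, stats::rnorm(length(targets), 1, effect_sd))
    names(mult) <- targets
    mult[hit_targets] <- hit_multiplier
  })
  well_mult <- stats::setNames(mult[target_map[lib_wells]], lib_wells)
  plates <- list(); replicate <- integer(0); pf <- numeric(0)
  k <- 0L
  for (r in seq_len(n_replicates)) for (p in seq_along(plate_factors)) {
    k <- k + 1L
    pid <- sprintf("R%dP%d", r, p)
    plates[[pid]] <- plate_sim_config(
      n_rows = n_rows, n_cols = n_cols, base_well = base_well,
      control_wells = stats::setNames(rep("negative", length(ctrl_wells)),
                                      ctrl_wells),
      well_multipliers = well_mult, target_map = target_map,
      plate_factor = plate_factors[p], plate_id = pid,
      seed = derive_seed(seed, k))
    replicate[pid] <- r; pf[pid] <- plate_factors[p]
  }
  list(plates = plates, replicate = replicate, plate_factor = pf,
       targets = targets, hit_targets = hit_targets, multipliers = mult,
       control_wells = ctrl_wells)
}

#' Default per-well configuration for screen simulations
#'
#' The base conditions of the simulated screen: about 100 cells per well
#' and a resting mitotic index near 0.10 (metaphase-like, anaphase and
#' telophase fractions of 0.062/0.025/0.015).
#'
#' @param ... overrides passed to [well_sim_config()].
#' @export
screen_base_well <- function(...) {
  well_sim_config(n_cells = 100L,
                  class_fractions = c(interphase = 0.838, mitotic = 0.062,
                                      anaphase = 0.025, telophase = 0.015,
                                      multinucleated = 0.03, dead = 0.03),
                  cse_rate = 0.15, bridge_rate = 0.08, ...)
}
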