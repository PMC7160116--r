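# Shared fixtures built in code.

# a small, quick well configuration
quick_well <- function(seed = 1, n_cells = 30, ...) {
  well_sim_config(image_shape_px = c(220L, 220L), n_cells = n_cells,
                  seed = seed, ...)
}

# blank multi-channel image (screen B roles)
blank_image <- function(h = 64, w = 64, px = 0.65, level = 0) {
  pl <- lapply(1:4, function(i) matrix(level, h, w))
  names(pl) <- c("dna", "tubulin", "phh3", "gtub")
  multichannel_image(pl, px)
}

# draw a hard disc into a matrix
disc_into <- function(m, center, radius, value) {
  dr <- outer(seq_len(nrow(m)) - center[1], rep(1, ncol(m)))
  dc <- outer(rep(1, nrow(m)), seq_len(ncol(m)) - center[2])
  m[dr^2 + dc^2 <= radius^2] <- value
  m
}

# draw an axis-aligned hard ellipse
ellipse_into <- function(m, center, a, b, value) {
  dr <- outer(seq_len(nrow(m)) - center[1], rep(1, ncol(m)))
  dc <- outer(rep(1, nrow(m)), seq_len(ncol(m)) - center[2])
  m[(dr / a)^2 + (dc / b)^2 <= 1] <- value
  m
}

# gaussian blob added to a matrix
gauss_into <- function(m, center, sigma, amp) {
  dr <- outer(seq_len(nrow(m)) - center[1], rep(1, ncol(m)))
  dc <- outer(rep(1, nrow(m)), seq_len(ncol(m)) - center[2])
  m + amp * exp(-(dr^2 + dc^2) / (2 * sigma^2))
}

# match detected anaphase/telophase pairs against ground-truth events by
# pair-midpoint proximity; returns one row per detected pair
match_pairs_to_truth <- function(ph, truth) {
  prs <- ph$pairs
  ev <- truth$cells[truth$cells$phenotype %in% c("anaphase", "telophase"), ,
                    drop = FALSE]
  if (nrow(prs) == 0 || nrow(ev) == 0) return(NULL)
  f <- ph$features
  out <- NULL
  for (k in seq_len(nrow(prs))) {
    fa <- f[match(prs$label_a[k], f$label), ]
    fb <- f[match(prs$label_b[k], f$label), ]
    mid <- c((fa$centroid_row + fb$centroid_row) / 2,
             (fa$centroid_col + fb$centroid_col) / 2)
    d <- sqrt((ev$row - mid[1])^2 + (ev$col - mid[2])^2)
    j <- which.min(d)
    out <- rbind(out, data.frame(true = ev$phenotype[j],
                                 true_cse = ev$has_cse[j],
                                 stage = prs$stage[k],
                                 cse = prs$cse_positive[k],
                                 match_dist_px = d[j]))
  }
  out
}
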