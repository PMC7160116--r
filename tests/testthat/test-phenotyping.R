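test_that("dead filter flags exactly the debris-class objects", {
  expect_identical(nrow(filter_dead(measure_objects(label_mask(matrix(0L, 4, 4)),
                                                    blank_image(4, 4)))$dead), 0L)
  rw <- render_well(quick_well(seed = 21, n_cells = 25,
                               class_fractions = c(interphase = 0.85, mitotic = 0,
                                                   anaphase = 0, telophase = 0,
                                                   multinucleated = 0, dead = 0.15),
                               bridge_rate = 0))
  nuc <- segment_nuclei(rw$image)
  f <- measure_objects(nuc, rw$image)
  fd <- filter_dead(f)
  truth_dead <- rw$truth$cells[rw$truth$cells$phenotype == "dead", ]
  expect_identical(nrow(fd$dead), nrow(truth_dead))
  # every flagged object matches a true dead fragment
  for (k in seq_len(nrow(fd$dead))) {
    d <- sqrt((truth_dead$row - fd$dead$centroid_row[k])^2 +
                (truth_dead$col - fd$dead$centroid_col[k])^2)
    expect_lt(min(d), 3)
  }
  expect_identical(nrow(fd$viable) + nrow(fd$dead), nrow(f))
})

test_that("a zero marker channel yields no mitotic cells", {
  rw <- render_well(quick_well(seed = 22, n_cells = 20))
  img <- rw$image
  img$planes$phh3 <- matrix(0, nrow(img$planes$phh3), ncol(img$planes$phh3))
  nuc <- segment_nuclei(img)
  f <- filter_dead(measure_objects(nuc, img))$viable
  expect_identical(nrow(classify_mitotic(f, classifier_config())), 0L)
})

test_that("mitotic classification is sensitive and specific at defaults", {
  tp <- 0; fn <- 0; fp <- 0
  for (s in 1:2) {
    rw <- render_well(well_sim_config(seed = 400 + s, n_cells = 100,
      class_fractions = c(interphase = 0.86, mitotic = 0.10, anaphase = 0,
                          telophase = 0, multinucleated = 0.02, dead = 0.02),
      bridge_rate = 0))
    nuc <- segment_nuclei(rw$image)
    f <- filter_dead(measure_objects(nuc, rw$image))$viable
    mito <- classify_mitotic(f, classifier_config())
    tm <- rw$truth$cells[rw$truth$cells$phenotype == "mitotic", ]
    for (k in seq_len(nrow(tm))) {
      d <- sqrt((mito$centroid_row - tm$row[k])^2 + (mito$centroid_col - tm$col[k])^2)
      if (length(d) && min(d) <= 3) tp <- tp + 1 else fn <- fn + 1
    }
    fp <- fp + max(0, nrow(mito) - sum(vapply(seq_len(nrow(mito)), function(k) {
      min(sqrt((tm$row - mito$centroid_row[k])^2 + (tm$col - mito$centroid_col[k])^2)) <= 3
    }, TRUE)))
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_lte(fp / max(1, tp + fp), 0.1)
})

test_that("raising the marker threshold never adds mitotic calls", {
  rw <- render_well(quick_well(seed = 23, n_cells = 40))
  nuc <- segment_nuclei(rw$image)
  f <- filter_dead(measure_objects(nuc, rw$image))$viable
  thr <- c(0.2, 0.5, 0.8, 1.2, 2, 5)
  n <- vapply(thr, function(t)
    nrow(classify_mitotic(f, classifier_config(mitotic_marker_min = t))), 0L)
  expect_true(all(diff(n) <= 0))
})

test_that("a scaled marker copy is the one classified mitotic", {
  f <- data.frame(label = 1:2, centroid_row = c(10, 30), centroid_col = c(10, 30),
                  orientation = 0, area_um2 = 15, major_axis_um = 4,
                  minor_axis_um = 4, aspect_ratio = 1, roundness = 1,
                  perimeter_um = 14, integrated_dna = 50, mean_dna = 2,
                  perinuclear_dna = 0.1, integrated_tubulin = 30,
                  mean_tubulin = 1, perinuclear_tubulin = 1,
                  integrated_phh3 = c(5, 50), mean_phh3 = c(0.2, 2),
                  perinuclear_phh3 = 0.1, integrated_gtub = 1, mean_gtub = 0.1,
                  perinuclear_gtub = 0.1)
  sel <- classify_mitotic(f, classifier_config(mitotic_marker_min = 1))
  expect_identical(sel$label, 2L)
})

test_that("anaphase/telophase pairing obeys the distance gate", {
  rw <- render_well(quick_well(seed = 24, n_cells = 30))
  nuc <- segment_nuclei(rw$image)
  f <- filter_dead(measure_objects(nuc, rw$image))$viable
  expect_identical(nrow(pair_ana_telo(f[0, ], rw$image, nuc)), 0L)
  # two elongated marker-high nuclei far apart must not pair
  rw2 <- render_well(quick_well(seed = 25, n_cells = 2,
    class_fractions = c(interphase = 0, mitotic = 1, anaphase = 0, telophase = 0,
                        multinucleated = 0, dead = 0), bridge_rate = 0))
  nuc2 <- segment_nuclei(rw2$image)
  f2 <- filter_dead(measure_objects(nuc2, rw2$image))$viable
  cfg_loose <- classifier_config(anatelo_elongation_min = 1,
                                 anatelo_dna_intensity_max_quantile = 0.99)
  expect_identical(nrow(pair_ana_telo(f2, rw2$image, nuc2, cfg_loose)), 0L)
})

test_that("simulated anaphases and telophases pair and stage correctly", {
  agg <- NULL
  for (s in 1:4) {
    rw <- render_well(well_sim_config(seed = 500 + s, n_cells = 50,
      class_fractions = c(interphase = 0.50, mitotic = 0.05, anaphase = 0.20,
                          telophase = 0.15, multinucleated = 0.05, dead = 0.05),
      cse_rate = 0.3))
    ph <- phenotype_well(rw$image, keep_masks = TRUE)
    agg <- rbind(agg, match_pairs_to_truth(ph, rw$truth))
  }
  expect_gte(nrow(agg), 20)
  acc <- mean(agg$true == agg$stage)
  expect_gte(acc, 0.9)
})

test_that("segregation errors are scored with high sensitivity and specificity", {
  agg <- NULL
  for (s in 1:5) {
    rw <- render_well(well_sim_config(seed = 600 + s, n_cells = 50,
      class_fractions = c(interphase = 0.45, mitotic = 0.05, anaphase = 0.35,
                          telophase = 0.05, multinucleated = 0.05, dead = 0.05),
      cse_rate = 0.4))
    ph <- phenotype_well(rw$image, keep_masks = TRUE)
    agg <- rbind(agg, match_pairs_to_truth(ph, rw$truth))
  }
  a <- agg[agg$true == "anaphase" & agg$stage == "anaphase", ]
  expect_gte(nrow(a), 30)
  sens <- sum(a$true_cse & a$cse) / sum(a$true_cse)
  spec <- sum(!a$true_cse & !a$cse) / sum(!a$true_cse)
  expect_gte(sens, 0.85)
  expect_gte(spec, 0.9)
})

test_that("binucleated and low-tubulin multinucleated cells are grouped", {
  rw <- render_well(quick_well(seed = 26, n_cells = 20,
    class_fractions = c(interphase = 0.6, mitotic = 0, anaphase = 0,
                        telophase = 0, multinucleated = 0.4, dead = 0),
    bridge_rate = 0))
  ph <- phenotype_well(rw$image, keep_masks = TRUE)
  n_true <- sum(rw$truth$cells$phenotype == "multinucleated")
  n_det <- sum(ph$records$phenotype == "multinucleated")
  expect_gte(n_det, ceiling(0.7 * n_true))
  expect_lte(n_det, n_true + 1)
  # group sizes at least 2
  gm <- ph$records$members[ph$records$phenotype == "multinucleated"]
  expect_true(all(lengths(strsplit(gm, ";")) >= 2))
})

test_that("no multinucleation is reported without close pairs or low tubulin", {
  rw <- render_well(quick_well(seed = 27, n_cells = 15,
    class_fractions = c(interphase = 1, mitotic = 0, anaphase = 0, telophase = 0,
                        multinucleated = 0, dead = 0), bridge_rate = 0))
  ph <- phenotype_well(rw$image)
  expect_identical(sum(ph$records$phenotype == "multinucleated"), 0L)
})

test_that("cytokinetic bridges are detected and stress-fiber mimics rejected", {
  nb <- 0; tb <- 0
  for (s in 1:3) {
    rw <- render_well(quick_well(seed = 700 + s, n_cells = 20, bridge_rate = 0.5,
      class_fractions = c(interphase = 0.9, mitotic = 0.04, anaphase = 0,
                          telophase = 0, multinucleated = 0, dead = 0.06)))
    ph <- phenotype_well(rw$image)
    nb <- nb + nrow(ph$bridges)
    tb <- tb + rw$truth$true_counts$bridges
  }
  expect_gte(nb / tb, 0.6)
  expect_lte(nb, tb)
  # a bright elongated tubulin bar inside one cell is not a bridge
  rw <- render_well(quick_well(seed = 28, n_cells = 6, bridge_rate = 0,
    class_fractions = c(interphase = 1, mitotic = 0, anaphase = 0, telophase = 0,
                        multinucleated = 0, dead = 0)))
  img <- rw$image
  ctr <- c(rw$truth$cells$row[1], rw$truth$cells$col[1])
  tub <- img$planes$tubulin
  for (dd in -3:3) {
    rr <- round(ctr[1]) + dd
    tub[rr, round(ctr[2]) + (-1:1)] <- 5
  }
  img$planes$tubulin <- tub
  nuc <- segment_nuclei(img)
  cyto <- segment_cytoplasm(img, nuc)
  br <- detect_bridges(img, cyto)
  expect_identical(nrow(br), 0L)
})

test_that("well counting follows the paired/grouped conventions", {
  records <- data.frame(
    phenotype = c("dead", "dead", "anaphase", "multinucleated",
                  rep("interphase", 4)),
    members = c("1", "2", "3;4", "5;6", "7", "8", "9", "10"),
    cse_positive = c(NA, NA, TRUE, NA, NA, NA, NA, NA))
  w <- count_well(records, bridges = data.frame(row = 1, col = 1))
  expect_identical(w$n_total_objects, 10L)
  expect_identical(w$n_viable, 6L)
  expect_identical(w$n_mitotic, 1L)
  expect_equal(w$mitotic_index, 1 / 6)
  expect_equal(w$bridge_rate, 1 / 6)
  expect_identical(w$n_anaphase_cse, 1L)
  # duplicated membership errors
  bad <- records; bad$members[7] <- "4"
  expect_error(count_well(bad), "more than one cell record")
  # empty well flags
  w0 <- count_well(records[0, ])
  expect_identical(w0$n_total_objects, 0L)
  expect_true(w0$empty_flag)
  expect_identical(w0$mitotic_index, 0)
})

test_that("records conserve segmented objects in full wells", {
  for (s in c(31, 32)) {
    rw <- render_well(quick_well(seed = s, n_cells = 35))
    ph <- phenotype_well(rw$image, keep_masks = TRUE)
    members <- unlist(strsplit(ph$records$members, ";"))
    expect_identical(length(members), nrow(ph$features))
    expect_setequal(as.integer(members), ph$features$label)
    expect_identical(ph$well$n_total_objects, ph$nuclei$n_objects)
  }
})
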