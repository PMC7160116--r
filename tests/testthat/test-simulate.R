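test_that("rendering is seeded and bit-reproducible", {
  cfg <- quick_well(seed = 42)
  a <- render_well(cfg)
  b <- render_well(cfg)
  expect_identical(a$image$planes, b$image$planes)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("ground-truth counts equal enumeration of the cell list", {
  for (s in c(3, 17, 31)) {
    rw <- render_well(quick_well(seed = s, n_cells = 40))
    cells <- rw$truth$cells
    tc <- rw$truth$true_counts
    # independent enumeration
    expect_identical(tc$dead, sum(cells$phenotype == "dead"))
    expect_identical(tc$viable, nrow(cells) - sum(cells$phenotype == "dead"))
    expect_identical(tc$mitotic,
                     sum(cells$phenotype %in% c("mitotic", "anaphase", "telophase")))
    expect_identical(tc$anaphase, sum(cells$phenotype == "anaphase"))
    expect_identical(tc$anaphase_with_cse,
                     sum(cells$phenotype == "anaphase" & cells$has_cse))
    expect_equal(tc$bridges, sum(cells$has_bridge) / 2)
    expect_equal(tc$mitotic_index, tc$mitotic / tc$viable)
  }
})

test_that("a zero-fraction class never appears", {
  cfg <- quick_well(seed = 5, n_cells = 50,
                    class_fractions = c(interphase = 0.8, mitotic = 0,
                                        anaphase = 0.1, telophase = 0,
                                        multinucleated = 0.05, dead = 0.05))
  rw <- render_well(cfg)
  expect_identical(rw$truth$true_counts$mitotic - rw$truth$true_counts$anaphase -
                     sum(rw$truth$cells$phenotype == "telophase"),
                   0L)
  expect_false(any(rw$truth$cells$phenotype == "telophase"))
})

test_that("seeded class assignment is recovered by recounting", {
  cfg <- quick_well(seed = 7, n_cells = 50,
                    class_fractions = c(interphase = 0.8, mitotic = 0.1,
                                        anaphase = 0.1, telophase = 0,
                                        multinucleated = 0, dead = 0))
  rw <- render_well(cfg)
  counts <- table(factor(rw$truth$cells$phenotype,
                         levels = c("interphase", "mitotic", "anaphase")))
  # bridged interphase events add a partner cell each
  n_events <- 50 + 0  # events; extra cells only inflate interphase
  expect_gte(counts[["interphase"]], 1)
  expect_identical(sum(counts) - sum(rw$truth$cells$has_bridge) / 2, 50)
})

test_that("invalid configurations are rejected", {
  expect_error(well_sim_config(class_fractions = c(interphase = 0.5, mitotic = 0.2)),
               "sum to 1")
  expect_error(well_sim_config(image_shape_px = c(0, 10)), "positive")
  expect_error(well_sim_config(cse_rate = 1.5), "rates")
})

test_that("intensities are finite and non-negative", {
  rw <- render_well(quick_well(seed = 9))
  for (p in rw$image$planes) {
    expect_true(all(is.finite(p)))
    expect_gte(min(p), 0)
  }
})

test_that("plate factor multiplies true ratios exactly", {
  bw <- quick_well(seed = 2, n_cells = 25)
  mk <- function(f) plate_sim_config(n_rows = 2, n_cols = 3, base_well = bw,
                                     plate_factor = f, plate_id = "P",
                                     seed = 123)
  p1 <- simulate_plate(mk(1), render = FALSE)
  p2 <- simulate_plate(mk(2), render = FALSE)
  expect_equal(p2$truth_table$ratio, 2 * p1$truth_table$ratio)
})

test_that("overlapping hit/control well assignment errors", {
  expect_error(plate_sim_config(n_rows = 2, n_cols = 2,
                                base_well = quick_well(),
                                hit_wells = list(A01 = 3),
                                control_wells = c(A01 = "negative")),
               "both hit and control")
  expect_error(plate_sim_config(n_rows = 2, n_cols = 2,
                                base_well = quick_well(),
                                hit_wells = list(Z99 = 3)),
               "unknown well ids")
})

test_that("hit wells elevate the realized mitotic fraction", {
  bw <- quick_well(seed = 3, n_cells = 60)
  cfg <- plate_sim_config(n_rows = 2, n_cols = 4, base_well = bw,
                          hit_wells = list(A01 = 4, A02 = 4), seed = 99)
  p <- simulate_plate(cfg, render = FALSE)
  tt <- p$truth_table[p$truth_table$feature == "mitotic_index", ]
  hit_mi <- mean(tt$ratio[tt$well_id %in% c("A01", "A02")])
  base_mi <- mean(tt$ratio[!tt$well_id %in% c("A01", "A02")])
  expect_gt(hit_mi, base_mi)
})

test_that("raising cse_rate does not decrease expected segregation errors", {
  rates <- c(0.05, 0.3, 0.6)
  means <- vapply(seq_along(rates), function(k) {
    m <- vapply(1:12, function(i) {
      cfg <- quick_well(seed = 1000 * k + i, n_cells = 30, cse_rate = rates[k],
                        class_fractions = c(interphase = 0.5, mitotic = 0.05,
                                            anaphase = 0.35, telophase = 0.05,
                                            multinucleated = 0.02, dead = 0.03))
      with_seed <- getFromNamespace("with_seed", "mitoscan")
      spec <- with_seed(cfg$seed, getFromNamespace("sample_cell_specs", "mitoscan")(cfg))
      true_counts(spec$cells)$anaphase_with_cse
    }, 0)
    mean(m)
  }, 0)
  expect_true(all(diff(means) >= 0))
})

test_that("well TIFF + sidecar round-trips", {
  rw <- render_well(quick_well(seed = 12, n_cells = 10))
  path <- file.path(tempdir(), "well.tif")
  write_well_tiff(rw$image, path)
  back <- read_well_tiff(path)
  expect_identical(names(back$planes), names(rw$image$planes))
  expect_equal(back$pixel_size_um, rw$image$pixel_size_um)
  # float32 round-trip keeps ~7 significant digits
  expect_equal(back$planes$dna, rw$image$planes$dna, tolerance = 1e-6)
  unlink(c(path, sub("\\.tif$", ".json", path)))
})
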