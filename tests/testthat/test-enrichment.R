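# Independent brute-force oracles ---------------------------------------------

simes_oracle <- function(p) {
  m <- length(p); s <- sort(p)
  best <- Inf
  for (i in seq_len(m)) best <- min(best, m * s[i] / i)
  best
}

bh_oracle <- function(p) {
  n <- length(p); o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    v <- min(prev, n * p[o[i]] / i)
    adj[o[i]] <- v; prev <- v
  }
  adj
}

cluster_oracle <- function(windows) {
  n <- nrow(windows)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && windows$chrom[i] == windows$chrom[j] &&
        windows$start[i] < windows$end[j] && windows$start[j] < windows$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 0L)
}

test_that("IUT combination takes directional maxima and assembles two-sided p", {
  df <- data.frame(gene_id = rep("g1", 2), method = c("RNAi", "LNA"),
                   p_up = c(0.01, 0.2), p_down = c(0.99, 0.8))
  r <- iut_combine(df)
  expect_equal(r$p_up_comb, 0.2)
  expect_equal(r$p_down_comb, 0.99)
  expect_identical(r$direction, "up")
  expect_equal(r$p_consistent, 0.4)
  # hand example: consistent up-regulation
  df2 <- data.frame(gene_id = "g", method = c("a", "b"),
                    p_up = c(0.01, 0.03), p_down = c(0.99, 0.97))
  r2 <- iut_combine(df2)
  expect_identical(r2$direction, "up")
  expect_equal(r2$p_consistent, 0.06)
  # disagreement is conservative
  df3 <- data.frame(gene_id = "g", method = c("a", "b"),
                    p_up = c(0.01, 0.99), p_down = c(0.99, 0.01))
  expect_equal(iut_combine(df3)$p_up_comb, 0.99)
  expect_gte(iut_combine(df3)$p_consistent, 0.99)
  # per-direction assembly reports the directional minimum uncorrected
  expect_equal(iut_combine(df2, assembly = "per_direction")$p_consistent, 0.03)
  # fewer than two methods errors
  expect_error(iut_combine(data.frame(gene_id = "g", method = "a",
                                      p_up = 0.5, p_down = 0.5)),
               "fewer than two")
})

test_that("BH adjustment equals the brute-force step-up on random inputs", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(1)
  for (i in 1:200) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 0)), "in \\(0, 1\\]")
})

test_that("Simes combination equals brute force on all subsets", {
  expect_equal(simes_combine(0.37), 0.37)
  expect_equal(simes_combine(c(0.01, 0.04, 0.9)), 0.03)
  expect_equal(simes_combine(rep(0.2, 5)), 0.2)
  expect_error(simes_combine(numeric(0)), "empty")
  set.seed(2)
  p <- runif(8)
  for (m in 1:8) {
    idx <- utils::combn(8, m)
    for (j in seq_len(ncol(idx)))
      expect_equal(simes_combine(p[idx[, j]]), simes_oracle(p[idx[, j]]),
                   tolerance = 1e-12)
  }
  for (i in 1:200) {
    q <- runif(sample(1:8, 1))
    expect_equal(simes_combine(q), simes_oracle(q), tolerance = 1e-12)
  }
})

test_that("windows are filtered at the fold threshold (boundary kept)", {
  w <- data.frame(chrom = "chr1", start = c(0, 100, 200), end = c(50, 150, 250),
                  p = 0.5, abundance = c(4.9, 5.0, 7))
  expect_identical(filter_windows(w, 1, 5)$abundance, c(5.0, 7))
  expect_identical(nrow(filter_windows(w[0, ], 1, 5)), 0L)
  expect_identical(nrow(filter_windows(w, 1, 0)), 3L)
})

test_that("window clustering is single-linkage over half-open overlap", {
  w <- data.frame(chrom = "chr1",
                  start = c(100, 200, 1000), end = c(250, 350, 1150),
                  p = c(0.5, 0.2, 0.9))
  cl <- cluster_windows(w)
  expect_identical(nrow(cl$clusters), 2L)
  expect_equal(cl$clusters$start, c(100, 1000))
  expect_equal(cl$clusters$end, c(350, 1150))
  expect_identical(cl$membership, c(1L, 1L, 2L))
  # abutting half-open windows do not merge
  ab <- data.frame(chrom = "c", start = c(0, 100), end = c(100, 200), p = 0.5)
  expect_identical(nrow(cluster_windows(ab)$clusters), 2L)
  # chained overlap is transitive even when ends do not all overlap
  ch <- data.frame(chrom = "c", start = c(0, 80, 160), end = c(100, 180, 260),
                   p = 0.5)
  expect_identical(nrow(cluster_windows(ch)$clusters), 1L)
  expect_error(cluster_windows(data.frame(chrom = "c", start = 10, end = 10,
                                          p = 0.5)), "malformed")
})

test_that("clustering matches a brute-force transitive closure and ignores order", {
  set.seed(3)
  for (i in 1:40) {
    n <- sample(2:20, 1)
    w <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = sample(0:400, n))
    w$end <- w$start + sample(10:120, n, replace = TRUE)
    w$p <- runif(n)
    w$direction <- sample(c("up", "down"), n, replace = TRUE)
    cl <- cluster_windows(w)
    oracle <- cluster_oracle(w)
    # same partition (compare co-membership)
    expect_identical(outer(cl$membership, cl$membership, "=="),
                     outer(oracle, oracle, "=="))
    # combined p equals Simes over members
    for (k in seq_len(nrow(cl$clusters)))
      expect_equal(cl$clusters$combined_p[k],
                   simes_oracle(w$p[cl$membership == k]), tolerance = 1e-12)
    # permutation invariance of the partition and spans
    perm <- sample(n)
    cl2 <- cluster_windows(w[perm, ])
    key <- function(cl) {
      df <- cl$clusters
      df[order(df$chrom, df$start, df$end),
         c("chrom", "start", "end", "n_windows", "combined_p")]
    }
    a <- key(cl); b <- key(cl2)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})

test_that("max-p combination is the element-wise maximum", {
  expect_equal(max_p_across_methods(0.01, 0.2), 0.2)
  expect_equal(max_p_across_methods(0.4, 0.4), 0.4)
  set.seed(4)
  pa <- runif(50); pb <- runif(50)
  expect_equal(max_p_across_methods(pa, pb),
               vapply(1:50, function(i) max(pa[i], pb[i]), 0), tolerance = 0)
})

test_that("empirical FDR counts directions below the cutoff", {
  cl <- data.frame(combined_p = c(rep(0.01, 13), 0.5),
                   direction = c(rep("down", 3), rep("up", 10), "up"))
  r <- empirical_fdr(cl, 0.05)
  expect_equal(r$efdr, 0.3)
  expect_identical(r$n_discovery, 10L)
  expect_identical(r$n_false_direction, 3L)
  r0 <- empirical_fdr(data.frame(combined_p = 0.01, direction = "up"), 0.05)
  expect_equal(r0$efdr, 0)
  ru <- empirical_fdr(data.frame(combined_p = 0.01, direction = "down"), 0.05)
  expect_true(ru$undefined)
  expect_equal(ru$efdr, 1)
})

test_that("eFDR counts are cumulative in the cutoff and the sweep honours 30%", {
  set.seed(5)
  cl <- data.frame(combined_p = runif(200),
                   direction = sample(c("up", "down"), 200, TRUE,
                                      prob = c(0.8, 0.2)))
  cuts <- sort(unique(cl$combined_p))
  prev_d <- 0; prev_f <- 0
  for (ct in cuts[seq(1, length(cuts), by = 10)]) {
    r <- empirical_fdr(cl, ct)
    expect_gte(r$n_discovery, prev_d)
    expect_gte(r$n_false_direction, prev_f)
    prev_d <- r$n_discovery; prev_f <- r$n_false_direction
  }
  sw <- efdr_threshold(cl, target = 0.30)
  expect_false(is.na(sw$p_cut))
  expect_lte(sw$efdr, 0.30)
  larger <- cuts[cuts > sw$p_cut]
  if (length(larger))
    expect_gt(empirical_fdr(cl, min(larger))$efdr, 0.30)
})

test_that("IUT + BH controls the false-discovery proportion under the null", {
  set.seed(6)
  n <- 10000
  df <- data.frame(gene_id = rep(sprintf("g%05d", 1:n), each = 2),
                   method = rep(c("RNAi", "LNA"), n),
                   p_up = runif(2 * n))
  df$p_down <- 1 - df$p_up + 1e-12
  r <- iut_combine(df)
  adj <- bh_adjust(r$p_consistent)
  fdp <- sum(adj <= 0.05) / max(1, sum(adj <= 0.05))
  expect_lte(sum(adj <= 0.05) / n, 0.05)  # all discoveries are false here
})
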