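# Combination statistics applied to supplied per-gene p-values and genomic
# windows: intersection-union consistency across loss-of-function methods,
# abundance filtering, single-linkage clustering of overlapping windows,
# Simes combination, Benjamini-Hochberg adjustment, and the empirical FDR
# for antisense-pulldown versus sense-control comparisons. Genomic
# intervals are 0-based, half-open (BED convention).

#' Intersection-union test across loss-of-function methods
#'
#' For each gene, the one-sided p-values of all methods are combined per
#' direction by taking the maximum (significance requires every method to
#' be significant), the gene's direction is the smaller combined p, and a
#' single per-gene significance is assembled for FDR correction.
#'
#' Two assemblies are offered: `"two_sided"` (default) reports
#' `p = min(1, 2 * min(p_up_comb, p_down_comb))`; `"per_direction"` leaves
#' the two combined p-values to be FDR-corrected separately (the reported
#' `p_consistent` is then the directional minimum, uncorrected for choosing
#' the direction).
#'
#' @param pvals data frame with columns `gene_id`, `method`, `p_up`,
#'   `p_down`; one-sided p-values in (0, 1], at least two methods per gene.
#' @param assembly `"two_sided"` or `"per_direction"`.
#' @return data frame: `gene_id`, `p_up_comb`, `p_down_comb`, `direction`,
#'   `p_consistent`.
#' @export
iut_combine <- function(pvals, assembly = c("two_sided", "per_direction")) {
  assembly <- match.arg(assembly)
  stopifnot(all(c("gene_id", "method", "p_up", "p_down") %in% names(pvals)))
  check_p(pvals$p_up); check_p(pvals$p_down)
  nm <- tapply(pvals$method, pvals$gene_id, function(m) length(unique(m)))
  if (any(nm < 2))
    stop("genes with fewer than two methods: ",
         paste(utils::head(names(nm)[nm < 2]), collapse = ", "))
  up <- tapply(pvals$p_up, pvals$gene_id, max)
  down <- tapply(pvals$p_down, pvals$gene_id, max)
  genes <- names(up)
  dmin <- pmin(up, down)
  out <- data.frame(gene_id = genes,
                    p_up_comb = as.numeric(up),
                    p_down_comb = as.numeric(down),
                    direction = ifelse(up <= down, "up", "down"),
                    p_consistent = if (assembly == "two_sided")
                      pmin(1, 2 * as.numeric(dmin)) else as.numeric(dmin),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

check_p <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  invisible(p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment with monotonicity enforcement
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  check_p(p)
  stats::p.adjust(p, method = "BH")
}

#' Filter windows by abundance over background
#'
#' Retains windows whose average abundance is at least `fold` times the
#' expected coverage from background non-specific enrichment.
#'
#' @param windows data frame with an `abundance` column.
#' @param background_abundance expected background coverage.
#' @param fold fold-change threshold (default 5).
#' @return the retained windows.
#' @export
filter_windows <- function(windows, background_abundance, fold = 5) {
  stopifnot(all(is.finite(windows$abundance)))
  windows[windows$abundance >= fold * background_abundance, , drop = FALSE]
}

#' Cluster overlapping windows (single linkage)
#'
#' Groups windows of all sizes whose genomic intervals overlap, taking the
#' transitive closure of pairwise overlap per chromosome (half-open
#' intervals: abutting windows do not overlap). Each cluster spans from the
#' smallest member start to the largest member end, carries a Simes
#' combined p-value over its members, and a direction: the common member
#' direction, or for mixed clusters the direction of the smallest-p member
#' (`mixed_rule = "min_p"`, default) or literally `"mixed"`
#' (`mixed_rule = "mixed"`).
#'
#' @param windows data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `p`, and optionally `direction` (`"up"`/`"down"`).
#' @param mixed_rule how to direct clusters with members in both
#'   directions.
#' @return list with `clusters` (data frame: `chrom`, `start`, `end`,
#'   `n_windows`, `combined_p`, `direction`) and `membership` (cluster row
#'   index per input window).
#' @export
cluster_windows <- function(windows, mixed_rule = c("min_p", "mixed")) {
  mixed_rule <- match.arg(mixed_rule)
  stopifnot(all(c("chrom", "start", "end", "p") %in% names(windows)))
  if (any(windows$start >= windows$end)) stop("malformed intervals (start >= end)")
  check_p(windows$p)
  n <- nrow(windows)
  membership <- integer(n)
  rows <- list()
  for (ch in unique(windows$chrom)) {
    sel <- which(windows$chrom == ch)
    # half-open [start, end) -> 1-based closed [start+1, end]
    ir <- IRanges::IRanges(start = windows$start[sel] + 1L,
                           end = windows$end[sel])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (k in seq_along(red)) {
      mem <- sel[grp == k]
      cid <- length(rows) + 1L
      membership[mem] <- cid
      dirs <- if (is.null(windows$direction)) rep("up", length(mem)) else
        windows$direction[mem]
      dir <- if (length(unique(dirs)) == 1L) dirs[1]
        else if (mixed_rule == "mixed") "mixed"
        else dirs[which.min(windows$p[mem])]
      rows[[cid]] <- data.frame(
        chrom = ch,
        start = min(windows$start[mem]), end = max(windows$end[mem]),
        n_windows = length(mem),
        combined_p = simes_combine(windows$p[mem]),
        direction = dir, stringsAsFactors = FALSE)
    }
  }
  list(clusters = do.call(rbind, rows), membership = membership)
}

#' Simes combined p-value
#'
#' `min over i of (m * p_(i) / i)` for the sorted p-values; the evidence
#' against the global null that none of the m hypotheses is false.
#'
#' @param p numeric vector of p-values in (0, 1], length >= 1.
#' @return the combined p-value.
#' @export
simes_combine <- function(p) {
  if (length(p) == 0) stop("empty p-value set")
  check_p(p)
  m <- length(p)
  min(m * sort(p) / seq_len(m))
}

#' Larger of two p-values across methods
#'
#' The per-window intersection-union combination: a window is only as
#' significant as its weaker method.
#'
#' @param pA,pB p-values in (0, 1] (vectorized).
#' @return element-wise maximum.
#' @export
max_p_across_methods <- function(pA, pB) {
  check_p(pA); check_p(pB)
  pmax(pA, pB)
}

#' Empirical FDR for pulldown-versus-control cluster calls
#'
#' Among clusters with combined p-value at most `p_cut`, the empirical FDR
#' is the number of clusters with increased coverage in the sense control
#' (direction `"down"`; false positives) divided by the number with
#' increased coverage in the antisense pulldown (direction `"up"`;
#' potential true discoveries). An empty denominator is reported as eFDR 1
#' with `undefined = TRUE` (maximally conservative).
#'
#' @param clusters cluster data frame from [cluster_windows()] (needs
#'   `combined_p` and `direction`).
#' @param p_cut combined p-value cutoff.
#' @return list `efdr`, `n_discovery` (antisense-up), `n_false_direction`
#'   (sense-up), `undefined`.
#' @export
empirical_fdr <- function(clusters, p_cut) {
  sel <- clusters$combined_p <= p_cut
  n_disc <- sum(sel & clusters$direction == "up")
  n_false <- sum(sel & clusters$direction == "down")
  if (n_disc == 0)
    list(efdr = 1, n_discovery = 0L, n_false_direction = as.integer(n_false),
         undefined = TRUE)
  else
    list(efdr = n_false / n_disc, n_discovery = as.integer(n_disc),
         n_false_direction = as.integer(n_false), undefined = FALSE)
}

#' Largest p-value cutoff meeting an empirical FDR target
#'
#' Sweeps the candidate cutoffs (the observed combined p-values) and
#' returns the largest one whose empirical FDR is at most `target`
#' (default 30%, the binding-site calling level).
#'
#' @param clusters cluster data frame (see [empirical_fdr()]).
#' @param target eFDR target in [0, 1].
#' @return list `p_cut` (NA if no cutoff qualifies), `efdr`,
#'   `n_discovery`, `n_false_direction`.
#' @export
efdr_threshold <- function(clusters, target = 0.30) {
  cuts <- sort(unique(clusters$combined_p), decreasing = TRUE)
  for (ct in cuts) {
    r <- empirical_fdr(clusters, ct)
    if (!r$undefined && r$efdr <= target)
      return(c(list(p_cut = ct), r[c("efdr", "n_discovery", "n_false_direction")]))
  }
  list(p_cut = NA_real_, efdr = NA_real_, n_discovery = 0L,
       n_false_direction = 0L)
}
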