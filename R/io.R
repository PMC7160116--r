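# File interchange: multi-page TIFF wells with JSON sidecars naming the
# channel roles and pixel size, label masks as 16-bit TIFF, and the CSV
# table formats used between pipeline stages.

#' Write a well image as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per channel (float32, page order = channel order) plus
#' `<stem>.json` recording channel roles, pixel size and the intensity
#' scale: pixel values are stored divided by the image maximum (TIFF
#' storage is defined on `[0, 1]`) and restored on read.
#'
#' @param image a [multichannel_image()].
#' @param path output TIFF path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_well_tiff <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  scale <- max(1, vapply(image$planes, max, 0))
  tiff::writeTIFF(lapply(image$planes, function(p) p / scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channels = names(image$planes),
               pixel_size_um = image$pixel_size_um,
               intensity_scale = scale)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Read a well image written by [write_well_tiff()]
#'
#' @param path TIFF path (sidecar JSON expected alongside).
#' @return a [multichannel_image()].
#' @export
read_well_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$channels))
    stop("page count does not match sidecar channel list")
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  pages <- lapply(pages, function(p) p * scale)
  names(pages) <- meta$channels
  multichannel_image(pages, meta$pixel_size_um)
}

#' Write a label mask as 16-bit TIFF
#' @param mask a `label_mask`.
#' @param path output path.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"), max(mask$labels) < 65536)
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [write_mask_tiff()]
#' @param path TIFF path.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  label_mask(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
}

#' Write ground truth to CSV
#'
#' Two files: `<stem>_cells.csv` (one row per cell) and
#' `<stem>_counts.csv` (the per-well true counts).
#'
#' @param truth the `truth` element of a [render_well()] result.
#' @param stem output path stem.
#' @export
write_truth_csv <- function(truth, stem) {
  utils::write.csv(truth$cells, paste0(stem, "_cells.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(truth$true_counts), paste0(stem, "_counts.csv"),
                   row.names = FALSE)
  invisible(stem)
}

#' Read/write screen tables
#'
#' Screen tables use fixed column names `plate_id, well_id, target_id,
#' feature, ratio, normalized_ratio, z, is_control, control_role`; absent
#' optional columns are tolerated.
#'
#' @param table screen table data frame.
#' @param path CSV path.
#' @export
write_screen_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_csv
#' @export
read_screen_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write window clusters as BED plus CSV
#'
#' BED uses the 0-based half-open convention; the score column carries
#' `-log10(combined p)`.
#'
#' @param clusters cluster table from [cluster_windows()].
#' @param stem output path stem (writes `<stem>.bed` and `<stem>.csv`).
#' @export
write_clusters_bed <- function(clusters, stem) {
  bed <- data.frame(clusters$chrom, clusters$start, clusters$end,
                    sprintf("cluster_%d", seq_len(nrow(clusters))),
                    round(-10 * log10(clusters$combined_p), 1),
                    ifelse(clusters$direction == "down", "-", "+"))
  utils::write.table(bed, paste0(stem, ".bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(clusters, paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}
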