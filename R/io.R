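# Plain-text I/O ----------------------------------------------------------

#' Write / read a centroid peak list as TSV
#'
#' Two tab-separated columns `mz`, `intensity` with a header row; polarity
#' and sample id travel in the manifest, not the file.
#'
#' @param peaks a `peak_list`.
#' @param path file path.
#' @param polarity,sample_id metadata restored on read.
#' @return `read_peaklist` returns a `peak_list`.
#' @export
write_peaklist <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_list"))
  utils::write.table(as.data.frame(peaks), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path, polarity, sample_id = basename(path)) {
  df <- utils::read.delim(path)
  peak_list(df$mz, df$intensity, polarity = polarity, sample_id = sample_id)
}

#' Write a simulated dataset to disk (peak lists + manifest)
#'
#' One TSV per sample and polarity plus a `manifest.csv` tying sample ids
#' to files, polarity, region, area, thickness and replicate.
#'
#' @param dataset result of [simulate_area_series()] or
#'   [simulate_regions()].
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- attr(dataset, "manifest")
  rows <- list()
  for (id in names(dataset)) {
    for (pol in c("negative", "positive")) {
      f <- file.path(dir, paste0(id, "_", substr(pol, 1, 3), ".tsv"))
      write_peaklist(dataset[[id]][[pol]], f)
      meta <- manifest[manifest$sample_id == id, , drop = FALSE]
      meta$polarity <- pol
      meta$file <- basename(f)
      meta$thickness <- dataset[[id]]$spot$thickness
      rows[[length(rows) + 1L]] <- meta
    }
  }
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), mf, row.names = FALSE)
  invisible(mf)
}

#' Write a quantified lipidome in long and wide form
#'
#' @param lipidomes list of `quant_lipidome`s.
#' @param long_path CSV path for the long table (sample, class, species,
#'   pmol, mol_percent).
#' @param wide_path optional CSV path for the species x samples pmol matrix.
#' @export
write_lipidomes <- function(lipidomes, long_path, wide_path = NULL) {
  long <- do.call(rbind, lapply(lipidomes, function(q)
    as.data.frame(q)[c("sample_id", "class_name", "species", "pmol",
                       "mol_percent")]))
  utils::write.csv(long, long_path, row.names = FALSE)
  if (!is.null(wide_path)) {
    wide <- stats::reshape(long[c("sample_id", "species", "pmol")],
                           idvar = "species", timevar = "sample_id",
                           direction = "wide")
    names(wide) <- sub("^pmol\\.", "", names(wide))
    utils::write.csv(wide, wide_path, row.names = FALSE)
  }
  invisible(long_path)
}

#' Write ROI geometry as a JSON sidecar
#'
#' Centroids (and polygons when supplied) in micrometers, one record per
#' ROI.
#'
#' @param manifest data.frame with `roi`, `region`, `area` and `cx`, `cy`.
#' @param path JSON file path.
#' @param polygons optional named list of n x 2 matrices (per ROI id).
#' @export
write_roi_geometry <- function(manifest, path, polygons = NULL) {
  rois <- unique(manifest[c("roi", "region", "area", "cx", "cy")])
  recs <- lapply(seq_len(nrow(rois)), function(k) {
    r <- as.list(rois[k, ])
    if (!is.null(polygons) && !is.null(polygons[[as.character(r$roi)]]))
      r$polygon <- unname(apply(polygons[[as.character(r$roi)]], 1, as.list))
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a cluster result (linkage table, heatmap matrix, Newick tree)
#'
#' @param result a `cluster_result`.
#' @param dir output directory.
#' @export
write_cluster_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hc <- result$hclust
  linkage <- data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                        height = hc$height)
  utils::write.csv(linkage, file.path(dir, "linkage.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$zmatrix),
                   file.path(dir, "heatmap_matrix.csv"))
  cluster_newick(result, file.path(dir, "dendrogram.nwk"))
  invisible(dir)
}
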