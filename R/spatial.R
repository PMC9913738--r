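# Spatial heterogeneity analysis ------------------------------------------

#' Assemble an ROI x species mol% matrix
#'
#' Rows are ROI replicates, columns species mol% of membrane lipids.
#' Species missing from a sample get zero (below-floor); columns that are
#' missing everywhere are dropped.
#'
#' @param lipidomes list of `quant_lipidome`s (one per ROI replicate).
#' @param manifest data.frame with one row per lipidome: `sample_id`,
#'   `roi`, `region`, and optionally `cx`, `cy`, `area`.
#' @param species optional fixed species set (column order).
#' @return a `roi_matrix`: numeric matrix with rownames = sample ids and a
#'   `manifest` attribute.
#' @export
roi_matrix <- function(lipidomes, manifest, species = NULL) {
  stopifnot(length(lipidomes) == nrow(manifest))
  vals <- lapply(lipidomes, function(q) {
    d <- q[q$membrane & !is.na(q$mol_percent), c("species", "mol_percent")]
    stats::setNames(d$mol_percent, d$species)
  })
  if (is.null(species))
    species <- sort(unique(unlist(lapply(vals, names))))
  m <- t(vapply(vals, function(v) {
    out <- stats::setNames(numeric(length(species)), species)
    hit <- intersect(names(v), species)
    out[hit] <- v[hit]
    out
  }, numeric(length(species))))
  rownames(m) <- manifest$sample_id
  keep <- colSums(m != 0) > 0
  m <- m[, keep, drop = FALSE]
  structure(m, manifest = manifest, class = c("roi_matrix", class(m)))
}

#' Z-score normalize an ROI matrix per species
#'
#' Column-wise (per species across ROIs) centering and scaling to mean 0,
#' SD 1 — the normalization behind the cluster heatmap's color code.
#' Zero-variance columns are dropped with a warning. The operation is
#' idempotent up to machine precision.
#'
#' @param mat a `roi_matrix` (or plain matrix).
#' @return the z-scored matrix (same class, manifest carried over).
#' @export
zscore_normalize <- function(mat) {
  m <- as.matrix(mat)
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0)) stop("all columns have zero variance")
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance column(s)")
    m <- m[, sds > 0, drop = FALSE]
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  structure(z, manifest = attr(mat, "manifest"),
            class = c("roi_matrix", class(z)))
}

#' Hierarchical clustering of ROI lipidomes (Euclidean / Ward)
#'
#' Agglomerative clustering of the z-scored ROI matrix with Euclidean
#' distance and Ward linkage (ward.D2, the Ward criterion on untransformed
#' Euclidean distances) — the clustering behind the ROI heatmap.
#' stats::hclust is deterministic for tied merges (lowest original index
#' first), so results are reproducible and invariant to row order up to
#' that tie-break.
#'
#' @param mat a `roi_matrix`; z-scored internally unless `zscore = FALSE`.
#' @param zscore apply [zscore_normalize()] first (default TRUE).
#' @return a `cluster_result`: list with `hclust` (the tree), `merge_heights`
#'   (non-decreasing), `leaf_order`, `cophenetic` (dist), `zmatrix` (the
#'   per-cell z-scores the heatmap displays), `manifest`.
#' @export
ward_cluster <- function(mat, zscore = TRUE) {
  m <- as.matrix(mat)
  if (nrow(m) < 2L) stop("need >= 2 rows to cluster")
  z <- if (zscore) zscore_normalize(mat) else mat
  hc <- stats::hclust(stats::dist(as.matrix(z), method = "euclidean"),
                      method = "ward.D2")
  structure(list(hclust = hc,
                 merge_heights = hc$height,
                 leaf_order = hc$order,
                 cophenetic = stats::cophenetic(hc),
                 zmatrix = as.matrix(z),
                 manifest = attr(mat, "manifest")),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$leaf_order), " leaves, max merge height ",
      format(max(x$merge_heights), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Cut a cluster result into k groups
#'
#' @param result a `cluster_result`.
#' @param k number of groups.
#' @return integer cluster assignment named by row.
#' @export
cut_clusters <- function(result, k) {
  stats::cutree(result$hclust, k = k)
}

#' Export a dendrogram as a Newick string
#'
#' @param result a `cluster_result`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to file.
#' @export
cluster_newick <- function(result, path = NULL) {
  phy <- ape::as.phylo(result$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Per-ROI spatial map of selected species
#'
#' Mean and SD of each species' mol% per ROI over successive-section
#' replicates, joined to ROI centroids for map export.
#'
#' @param lipidomes list of `quant_lipidome`s.
#' @param manifest data.frame as in [roi_matrix()] (needs `roi`; `cx`, `cy`
#'   are carried through when present).
#' @param species character vector of species labels to map.
#' @return data.frame with `roi`, `species`, `mean_mol_percent`,
#'   `sd_mol_percent`, `n`, plus centroid columns when available.
#' @export
spatial_map <- function(lipidomes, manifest, species) {
  stopifnot(length(lipidomes) == nrow(manifest), length(species) >= 1L)
  if (nrow(manifest) == 0L) stop("empty ROI set")
  all_sp <- unique(unlist(lapply(lipidomes, function(q) q$species)))
  unknown <- setdiff(species, all_sp)
  if (length(unknown))
    stop("species not quantified in any ROI: ",
         paste(unknown, collapse = ", "))
  long <- do.call(rbind, lapply(seq_along(lipidomes), function(i) {
    q <- lipidomes[[i]]
    hit <- q[q$species %in% species, c("species", "mol_percent")]
    if (!nrow(hit)) return(NULL)
    hit$roi <- manifest$roi[i]
    hit
  }))
  out <- do.call(rbind, lapply(split(long, long[c("roi", "species")],
                                     drop = TRUE), function(d)
    data.frame(roi = d$roi[1], species = d$species[1],
               mean_mol_percent = mean(d$mol_percent),
               sd_mol_percent = if (nrow(d) > 1) stats::sd(d$mol_percent) else 0,
               n = nrow(d))))
  rownames(out) <- NULL
  if (!is.null(manifest$cx)) {
    cent <- unique(manifest[c("roi", "cx", "cy")])
    out <- merge(out, cent, by = "roi")
  }
  out[order(out$species, out$roi), ]
}

#' Heatmap of a cluster result
#'
#' Draws the z-scored ROI x species matrix with the Ward dendrogram when
#' the pheatmap package is available; otherwise falls back to
#' [stats::heatmap()].
#'
#' @param result a `cluster_result`.
#' @param ... passed to the underlying heatmap function.
#' @export
plot_cluster_heatmap <- function(result, ...) {
  z <- result$zmatrix
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(z, cluster_rows = result$hclust,
                       clustering_method = "ward.D2", ...)
  } else {
    stats::heatmap(z, Rowv = stats::as.dendrogram(result$hclust), ...)
  }
  invisible(result)
}
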