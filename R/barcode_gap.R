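#' Barcode-gap analysis of a specimen dataset
#'
#' The package's main entry point: from an aligned, taxonomically annotated
#' set of barcode sequences it computes the full distance-based
#' identification summary — pairwise K2P (or p) distances, per-class rank
#' summaries, congeneric distance banding by family, the conspecific/
#' congeneric fold ratio, below-threshold fractions, nearest-neighbour
#' distances, per-species barcode-gap flags, Tukey boxplot statistics per
#' comparison class, the unrooted neighbour-joining tree and per-species
#' cluster reports — plus, for coding markers, a numt screen.
#'
#' @param dataset A `barcode_dataset` (see [build_dataset()]) or a
#'   `synthetic_dataset`.
#' @param metric `"k2p"` (default) or `"p"`.
#' @param intra_threshold Barcode filter threshold as a proportion
#'   (default 0.01 = 1%).
#' @param bands Percent cut points for congeneric distance banding
#'   (default `c(5, 10)`).
#' @param exclude_numts Drop numt suspects before the distance stages?
#' @param tree Build the NJ tree and cluster report? (default TRUE;
#'   skipped automatically if the matrix has saturated cells).
#' @return Object of class `barcode_gap` with components `dataset`, `qc`,
#'   `dist`, `summaries`, `bands`, `fold_ratio`, `intra_below`, `nnd`,
#'   `flags`, `boxplots`, `tree`, `clusters`, and the call parameters.
#' @seealso [print.barcode_gap()], [summary.barcode_gap()],
#'   [plot.barcode_gap()], [run_barcode_pipeline()]
#' @export
barcode_gap_analysis <- function(dataset, metric = c("k2p", "p"),
                                 intra_threshold = 0.01, bands = c(5, 10),
                                 exclude_numts = FALSE, tree = TRUE) {
  metric <- match.arg(metric)
  dataset <- .unwrap(dataset)
  stopifnot(inherits(dataset, "barcode_dataset"), intra_threshold > 0)

  qc <- if (is_coding_marker(dataset$marker)) screen_dataset(dataset) else NULL
  if (exclude_numts && !is.null(qc)) dataset <- exclude_numts(dataset, qc)

  taxonomy <- dataset_taxonomy(dataset)
  m <- pairwise_matrix(dataset, metric)
  summaries <- rank_summaries(m, taxonomy)
  bt <- tryCatch(band_counts(m, taxonomy, bands = bands),
                 error = function(e) NULL)
  fr <- tryCatch(fold_ratio(summaries), error = function(e) NA_real_)
  ib <- tryCatch(threshold_fraction(m, taxonomy, "within_species",
                                    intra_threshold),
                 error = function(e) NULL)
  nnd <- tryCatch(nearest_neighbor_distances(m, taxonomy),
                  error = function(e) NULL)
  flags <- if (!is.null(nnd)) barcode_gap_flags(m, taxonomy, intra_threshold)
           else NULL
  cls <- pair_class_matrix(m$labels, taxonomy)
  ut <- upper.tri(cls)
  boxplots <- lapply(stats::setNames(seq_along(.CLASSES), .CLASSES),
                     function(k) {
    vals <- m$d[ut & !is.na(cls) & cls == k]
    vals <- vals[!is.na(vals)] * 100
    if (length(vals)) boxplot_stats(vals) else NULL
  })

  tr <- clusters <- NULL
  if (tree && m$n_saturated == 0L && length(m$labels) >= 3L) {
    tr <- neighbor_joining(m)
    clusters <- species_clusters(tr, taxonomy)
  }

  structure(list(dataset = dataset, metric = metric,
                 intra_threshold = intra_threshold, band_edges = bands,
                 qc = qc, dist = m, summaries = summaries, bands = bt,
                 fold_ratio = fr, intra_below = ib, nnd = nnd, flags = flags,
                 boxplots = boxplots, tree = tr, clusters = clusters),
            class = "barcode_gap")
}

round_summary <- function(s) {
  for (cn in c("mean", "minimum", "maximum", "se")) s[[cn]] <- round(s[[cn]], 2)
  s
}

#' @export
print.barcode_gap <- function(x, ...) {
  cat("Barcode-gap analysis (", x$metric, " distances)\n", sep = "")
  print(x$dataset)
  if (!is.null(x$qc)) {
    cat("numt screen: ", attr(x$qc, "n_pass"), " pass, ",
        attr(x$qc, "n_suspect"), " suspect\n", sep = "")
  }
  cat("\nDivergence by comparison class (%):\n")
  print(round_summary(x$summaries), row.names = FALSE)
  if (!is.na(x$fold_ratio)) {
    cat(sprintf("\ncongeneric / conspecific fold ratio: %.1f\n", x$fold_ratio))
  }
  if (!is.null(x$intra_below)) {
    cat(sprintf("conspecific distances below %.2g%%: %d / %d (%.2f%%)\n",
                100 * x$intra_threshold, x$intra_below$count_below,
                x$intra_below$total, x$intra_below$percent))
  }
  if (!is.null(x$nnd)) {
    low <- sum(x$nnd$distance < 100 * x$intra_threshold)
    cat(sprintf("nearest-neighbour distances below %.2g%%: %d / %d (%.2f%%)\n",
                100 * x$intra_threshold, low, nrow(x$nnd),
                round(100 * low / nrow(x$nnd), 2)))
  }
  if (!is.null(x$clusters)) {
    cat(sprintf("species forming NJ clusters: %d / %d\n",
                sum(x$clusters$is_cluster), nrow(x$clusters)))
  }
  if (!is.null(x$flags) && any(x$flags$flagged)) {
    cat("flagged species:",
        paste(x$flags$species[x$flags$flagged], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.barcode_gap <- function(object, ...) {
  print(object)
  if (!is.null(object$bands)) {
    cat("\nCongeneric distances banded by family:\n")
    print(object$bands, row.names = FALSE)
  }
  invisible(object)
}

#' Boxplots of divergence by comparison class and NND histogram
#'
#' @param x A `barcode_gap` object.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.barcode_gap <- function(x, ...) {
  taxonomy <- dataset_taxonomy(x$dataset)
  cls <- pair_class_matrix(x$dist$labels, taxonomy)
  ut <- upper.tri(cls)
  vals <- lapply(seq_along(.CLASSES), function(k) {
    v <- x$dist$d[ut & !is.na(cls) & cls == k]
    v[!is.na(v)] * 100
  })
  names(vals) <- sub("within_", "", .CLASSES)
  vals <- vals[lengths(vals) > 0]
  old <- graphics::par(mfrow = c(1, if (is.null(x$nnd)) 1 else 2))
  on.exit(graphics::par(old))
  graphics::boxplot(vals, ylab = "K2P distance (%)",
                    xlab = "comparison class", ...)
  if (!is.null(x$nnd)) {
    graphics::hist(x$nnd$distance, main = "",
                   xlab = "nearest-neighbour distance (%)")
  }
  invisible(x)
}

#' Run the full pipeline and write the report bundle
#'
#' Composes the analysis end to end and writes every report as UTF-8 TSV
#' (percentages with 2 decimals), the tree as newick, boxplot statistics
#' as JSON and a run log echoing parameters. Outputs are deterministic for
#' fixed inputs.
#'
#' @param fasta Path to a FASTA file, or a named sequence vector.
#' @param taxonomy Path to a taxonomy TSV, or a taxonomy data.frame.
#' @param marker Marker name.
#' @param outdir Output directory (created if needed).
#' @param metric,intra_threshold,bands,exclude_numts As in
#'   [barcode_gap_analysis()].
#' @return Invisibly, the `barcode_gap` object.
#' @export
run_barcode_pipeline <- function(fasta, taxonomy, marker = "COI",
                                 outdir = ".", metric = "k2p",
                                 intra_threshold = 0.01, bands = c(5, 10),
                                 exclude_numts = FALSE) {
  dataset <- build_dataset(fasta, taxonomy, marker)
  res <- barcode_gap_analysis(dataset, metric = metric,
                              intra_threshold = intra_threshold,
                              bands = bands, exclude_numts = exclude_numts)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(res$qc)) tsv(as.data.frame(res$qc), "qc_report.tsv")
  write_distance_matrix(res$dist, file.path(outdir, "distances.phylip"))
  tsv(round_summary(res$summaries), "rank_summaries.tsv")
  if (!is.null(res$bands)) tsv(res$bands, "band_counts.tsv")
  if (!is.null(res$nnd)) {
    nnd <- res$nnd; nnd$distance <- round(nnd$distance, 2)
    tsv(nnd, "nearest_neighbors.tsv")
  }
  if (!is.null(res$flags)) {
    fl <- res$flags
    fl$max_intra <- round(fl$max_intra, 2); fl$nnd <- round(fl$nnd, 2)
    tsv(fl, "gap_flags.tsv")
  }
  if (!is.null(res$tree)) {
    write_newick(res$tree, file.path(outdir, "nj_tree.nwk"))
    tsv(res$clusters, "species_clusters.tsv")
  }
  lib <- tryCatch(diagnostic_library(res$dataset), error = function(e) NULL)
  if (!is.null(lib)) tsv(lib, "diagnostic_library.tsv")
  jsonlite::write_json(
    lapply(Filter(Negate(is.null), res$boxplots), unclass),
    file.path(outdir, "boxplot_stats.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(
    paste0("barcodegap ", as.character(utils::packageVersion("barcodegap"))),
    paste0("R ", R.version.string),
    paste0("marker=", marker, " metric=", metric,
           " intra_threshold=", intra_threshold,
           " bands=", paste(bands, collapse = ","),
           " exclude_numts=", exclude_numts),
    paste0("n_specimens=", nrow(res$dataset$records),
           " n_species=", length(unique(res$dataset$records$species)),
           " n_saturated_pairs=", res$dist$n_saturated)),
    file.path(outdir, "run_log.txt"))
  invisible(res)
}
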