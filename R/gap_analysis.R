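.CLASSES <- c("within_species", "within_genus", "within_family",
              "within_order", "within_class")

# rank whose sharing defines each comparison class, and the rank whose
# taxa are counted as "contributing" to it
.CLASS_RANK <- c(within_species = "species", within_genus = "genus",
                 within_family = "family", within_order = "order",
                 within_class = "class")

#' Classify a specimen pair by its most specific shared rank
#'
#' The five comparison classes are mutually exclusive and exhaustive for
#' any pair sharing the top rank: conspecific (`within_species`),
#' congeneric but heterospecific (`within_genus`), confamilial but in
#' different genera (`within_family`), same order different family
#' (`within_order`), same class different order (`within_class`).
#'
#' @param taxonomy Taxonomy data.frame (see [read_taxonomy()]).
#' @param id_a,id_b Specimen ids present in `taxonomy`.
#' @return One of the class names, or `NA` ("unclassified") when the pair
#'   does not share the top rank.
#' @export
classify_pair <- function(taxonomy, id_a, id_b) {
  i <- match(id_a, taxonomy$specimen_id)
  j <- match(id_b, taxonomy$specimen_id)
  if (is.na(i) || is.na(j)) stop("specimen id not in taxonomy")
  if (taxonomy$class[i] != taxonomy$class[j]) return(NA_character_)
  for (cl in .CLASSES) {
    r <- .CLASS_RANK[[cl]]
    if (taxonomy[[r]][i] == taxonomy[[r]][j]) return(cl)
  }
  NA_character_
}

# integer matrix of pair classes over the matrix labels:
# 1..5 = .CLASSES index, NA = unclassified, diagonal NA
pair_class_matrix <- function(labels, taxonomy) {
  idx <- match(labels, taxonomy$specimen_id)
  if (anyNA(idx)) {
    stop("matrix label(s) absent from taxonomy: ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  tx <- taxonomy[idx, , drop = FALSE]
  cls <- matrix(NA_integer_, length(labels), length(labels))
  # walk from broadest to most specific so later assignments overwrite
  for (k in rev(seq_along(.CLASSES))) {
    r <- tx[[.CLASS_RANK[[.CLASSES[k]]]]]
    cls[outer(r, r, "==")] <- k
  }
  top <- tx$class
  cls[!outer(top, top, "==")] <- NA_integer_
  diag(cls) <- NA_integer_
  cls
}

.get_dist <- function(matrix) {
  if (inherits(matrix, "pairwise_dist")) matrix
  else stop("expected a 'pairwise_dist' object")
}

#' Per-class summaries of pairwise divergence (rank summary table)
#'
#' Partitions every unordered specimen pair into exactly one comparison
#' class and reports, per class: the number of contributing taxa at the
#' class's rank, the number of comparisons, and the mean, minimum, maximum
#' and standard error of the distances in percent.
#'
#' `n_taxa` counts taxa contributing at least one comparison, so singleton
#' species (one specimen) do not appear in the conspecific row, genera with
#' a single sampled species do not appear in the congeneric row, and so on.
#' The standard error is the sample standard deviation of the class's
#' distances divided by the square root of the comparison count; pairwise
#' distances sharing specimens are not independent, so this SE is
#' descriptive, not inferential.
#'
#' @param matrix A `pairwise_dist` from [pairwise_matrix()].
#' @param taxonomy Taxonomy data.frame covering all matrix labels.
#' @param cumulative If `TRUE`, each class also includes all pairs of more
#'   specific classes (the congeneric row then contains conspecific pairs,
#'   etc.). Default `FALSE`: classes are disjoint.
#' @return data.frame with columns `class`, `n_taxa`, `n_comparisons`,
#'   `mean`, `minimum`, `maximum`, `se` (percent, unrounded). Classes with
#'   zero comparisons are omitted with a warning.
#' @export
rank_summaries <- function(matrix, taxonomy, cumulative = FALSE) {
  m <- .get_dist(matrix)
  taxonomy <- validate_taxonomy(taxonomy)
  cls <- pair_class_matrix(m$labels, taxonomy)
  idx <- match(m$labels, taxonomy$specimen_id)
  tx <- taxonomy[idx, , drop = FALSE]
  ut <- upper.tri(cls)
  out <- list()
  for (k in seq_along(.CLASSES)) {
    sel <- ut & !is.na(cls) & (if (cumulative) cls <= k else cls == k)
    vals <- m$d[sel]
    n_sat <- sum(is.na(vals))
    vals <- vals[!is.na(vals)] * 100
    if (length(vals) == 0L) {
      warning("no ", .CLASSES[k], " comparisons; row omitted")
      next
    }
    if (n_sat > 0L) {
      warning(n_sat, " saturated pair(s) excluded from ", .CLASSES[k])
    }
    # taxa at the class's own rank contributing >= 1 comparison
    rank_col <- .CLASS_RANK[[.CLASSES[k]]]
    pair_idx <- which(sel, arr.ind = TRUE)
    n_taxa <- length(unique(tx[[rank_col]][pair_idx[, 1L]]))
    out[[.CLASSES[k]]] <- data.frame(
      class = .CLASSES[k], n_taxa = n_taxa,
      n_comparisons = length(vals) + n_sat,
      mean = mean(vals), minimum = min(vals), maximum = max(vals),
      se = stats::sd(vals) / sqrt(length(vals)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Band congeneric interspecific distances by family
#'
#' Counts congeneric, heterospecific pairwise distances falling in
#' half-open percent bands (default `[0,5)`, `[5,10)`, `[10,Inf)`), grouped
#' by (order, family). Families contributing no congeneric comparison are
#' excluded. The per-row band counts sum to the family's congeneric
#' comparison count, and the grand total equals the congeneric
#' `n_comparisons` of [rank_summaries()].
#'
#' @inheritParams rank_summaries
#' @param bands Increasing percent cut points (default `c(5, 10)`).
#' @return data.frame with `order`, `family`, one column per band, and
#'   `total`; attribute `grand_total` gives the overall congeneric count.
#' @export
band_counts <- function(matrix, taxonomy, bands = c(5, 10)) {
  stopifnot(is.numeric(bands), all(diff(bands) > 0), all(bands > 0))
  m <- .get_dist(matrix)
  taxonomy <- validate_taxonomy(taxonomy)
  cls <- pair_class_matrix(m$labels, taxonomy)
  idx <- match(m$labels, taxonomy$specimen_id)
  tx <- taxonomy[idx, , drop = FALSE]
  sel <- upper.tri(cls) & !is.na(cls) & cls == 2L  # within_genus
  pair_idx <- which(sel, arr.ind = TRUE)
  if (nrow(pair_idx) == 0L) {
    stop("no congeneric interspecific comparisons in dataset")
  }
  vals <- m$d[sel] * 100
  fam <- tx$family[pair_idx[, 1L]]
  ord <- tx$order[pair_idx[, 1L]]
  edges <- c(0, bands, Inf)
  labs <- c(paste0("<", bands[1L], "%"),
            if (length(bands) > 1L)
              paste0(bands[-length(bands)], "-", bands[-1L], "%"),
            paste0(">", bands[length(bands)], "%"))
  band <- cut(vals, breaks = edges, right = FALSE, labels = labs)
  keep_na <- is.na(vals)
  if (any(keep_na)) warning(sum(keep_na), " saturated pair(s) excluded")
  tab <- table(family = fam[!keep_na], band = band[!keep_na])
  fams <- rownames(tab)
  res <- data.frame(
    order = tx$order[match(fams, tx$family)],
    family = fams,
    as.data.frame.matrix(unclass(tab)),
    check.names = FALSE, stringsAsFactors = FALSE)
  res$total <- rowSums(tab)
  res <- res[order(res$order, res$family), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "grand_total") <- sum(tab)
  res
}

#' Fraction of a class's distances below a threshold
#'
#' @inheritParams rank_summaries
#' @param class Comparison class name (default `"within_species"`).
#' @param threshold Divergence threshold as a proportion (default 0.01,
#'   i.e. 1%).
#' @return List with `count_below`, `total`, `percent` (strict `<`
#'   comparison; percent rounded to 2 decimals).
#' @export
threshold_fraction <- function(matrix, taxonomy, class = "within_species",
                               threshold = 0.01) {
  class <- match.arg(class, .CLASSES)
  m <- .get_dist(matrix)
  taxonomy <- validate_taxonomy(taxonomy)
  cls <- pair_class_matrix(m$labels, taxonomy)
  sel <- upper.tri(cls) & !is.na(cls) & cls == match(class, .CLASSES)
  vals <- m$d[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no ", class, " comparisons")
  threshold_percent(sum(vals < threshold), length(vals))
}

#' Percentage from a below-threshold count
#'
#' @param count_below,total Non-negative counts, `count_below <= total`.
#' @return List with `count_below`, `total`, `percent` (2 decimals).
#' @export
threshold_percent <- function(count_below, total) {
  stopifnot(total >= 1, count_below >= 0, count_below <= total)
  list(count_below = as.integer(count_below), total = as.integer(total),
       percent = round(100 * count_below / total, 2))
}

#' Nearest-neighbour distance (NND) per species
#'
#' For every species (singletons included) the minimum distance to any
#' specimen of a different species, the field's standard measure of how
#' close a species sits to its closest relative.
#'
#' @inheritParams rank_summaries
#' @return data.frame with `species`, `nearest_neighbor` (species name),
#'   `distance` (percent, unrounded), one row per species.
#' @export
nearest_neighbor_distances <- function(matrix, taxonomy) {
  m <- .get_dist(matrix)
  taxonomy <- validate_taxonomy(taxonomy)
  idx <- match(m$labels, taxonomy$specimen_id)
  if (anyNA(idx)) stop("matrix label(s) absent from taxonomy")
  sp <- taxonomy$species[idx]
  species <- sort(unique(sp))
  if (length(species) < 2L) stop("nearest-neighbor distances need >= 2 species")
  d <- m$d
  out <- lapply(species, function(s) {
    rows <- sp == s
    sub <- d[rows, !rows, drop = FALSE]
    if (all(is.na(sub))) stop("all heterospecific pairs saturated for ", s)
    j <- which(sub == min(sub, na.rm = TRUE), arr.ind = TRUE)[1L, 2L]
    data.frame(species = s,
               nearest_neighbor = sp[!rows][j],
               distance = min(sub, na.rm = TRUE) * 100,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ratio of congeneric to conspecific mean divergence
#'
#' @param summaries Output of [rank_summaries()].
#' @return Dimensionless fold ratio (congeneric mean / conspecific mean).
#' @export
fold_ratio <- function(summaries) {
  ws <- summaries$mean[summaries$class == "within_species"]
  wg <- summaries$mean[summaries$class == "within_genus"]
  if (length(ws) != 1L || length(wg) != 1L) {
    stop("summaries must contain both within_species and within_genus rows")
  }
  if (ws == 0) stop("within_species mean is 0; fold ratio undefined")
  wg / ws
}

#' Tukey boxplot statistics
#'
#' Quartiles by linear interpolation (the default type-7 quantile),
#' whiskers at the most extreme observations within 1.5 IQR of the
#' quartiles, mild outliers between 1.5 and 3 IQR beyond a quartile,
#' extreme outliers beyond 3 IQR.
#'
#' @param values Numeric vector (percent or proportion, caller's choice).
#' @return Object of class `boxplot_stats`: list with `q1`, `median`, `q3`,
#'   `iqr`, `whisker_low`, `whisker_high`, `mild_outliers`,
#'   `extreme_outliers` (both sorted), `n`.
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  lo_ext <- q[1L] - 3 * iqr
  hi_ext <- q[3L] + 3 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  mild <- (values < lo_fence & values >= lo_ext) |
          (values > hi_fence & values <= hi_ext)
  extreme <- values < lo_ext | values > hi_ext
  structure(list(
    q1 = q[1L], median = q[2L], q3 = q[3L], iqr = iqr,
    whisker_low = min(values[inside]), whisker_high = max(values[inside]),
    mild_outliers = sort(values[mild]),
    extreme_outliers = sort(values[extreme]),
    n = length(values)), class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf("boxplot (n=%d): Q1 %.4g | median %.4g | Q3 %.4g (IQR %.4g)\n",
              x$n, x$q1, x$median, x$q3, x$iqr))
  cat(sprintf("  whiskers [%.4g, %.4g]; %d mild, %d extreme outlier(s)\n",
              x$whisker_low, x$whisker_high,
              length(x$mild_outliers), length(x$extreme_outliers)))
  invisible(x)
}

#' Flag species violating the barcode-gap filter
#'
#' Applies the standard 1% divergence filter: a species is flagged when its
#' maximum intraspecific distance exceeds the threshold (deep intraspecific
#' divergence, e.g. cryptic structure) or when its nearest-neighbour
#' distance falls below it (overlap with the closest heterospecific).
#'
#' @inheritParams rank_summaries
#' @param intra_threshold Threshold as a proportion (default 0.01 = 1%).
#' @return data.frame with one row per species: `species`, `n_specimens`,
#'   `max_intra` (percent; `NA` for singletons), `nnd` (percent),
#'   `deep_intraspecific`, `low_nnd`, `flagged`.
#' @export
barcode_gap_flags <- function(matrix, taxonomy, intra_threshold = 0.01) {
  m <- .get_dist(matrix)
  taxonomy <- validate_taxonomy(taxonomy)
  idx <- match(m$labels, taxonomy$specimen_id)
  sp <- taxonomy$species[idx]
  nnd <- nearest_neighbor_distances(matrix, taxonomy)
  thr_pct <- intra_threshold * 100
  res <- do.call(rbind, lapply(nnd$species, function(s) {
    rows <- which(sp == s)
    max_intra <- if (length(rows) >= 2L) {
      max(m$d[rows, rows][upper.tri(diag(length(rows)))], na.rm = TRUE) * 100
    } else NA_real_
    data.frame(species = s, n_specimens = length(rows),
               max_intra = max_intra,
               nnd = nnd$distance[nnd$species == s],
               stringsAsFactors = FALSE)
  }))
  res$deep_intraspecific <- !is.na(res$max_intra) & res$max_intra > thr_pct
  res$low_nnd <- res$nnd < thr_pct
  res$flagged <- res$deep_intraspecific | res$low_nnd
  rownames(res) <- NULL
  res
}
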