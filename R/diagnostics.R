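# alignment as character matrix (rows = specimens, columns = sites)
alignment_matrix <- function(dataset) {
  if (is.na(dataset$alignment_length)) {
    stop("diagnostic sites require an aligned dataset (equal lengths)")
  }
  mat <- do.call(rbind, strsplit(dataset$records$sequence, "", fixed = TRUE))
  rownames(mat) <- dataset$records$specimen_id
  mat
}

.UNAMBIG <- c("A", "C", "G", "T")

#' Pure diagnostic alignment columns for one species
#'
#' A column is diagnostic for the target species when the set of
#' (unambiguous) nucleotide states carried by target specimens is disjoint
#' from the states carried by all other specimens — the "pure simple"
#' character of character-based identification. Polymorphic targets still
#' qualify as long as the state sets stay disjoint. Specimens with a gap
#' or ambiguity code at a column are excluded from that column's state
#' sets, and a column is only reported when at least `min_informative` of
#' the target's specimens are informative there.
#'
#' @param dataset An aligned `barcode_dataset`.
#' @param target_species Species name present in the dataset.
#' @param min_informative Minimum informative fraction of target specimens
#'   at a reported column (default 0.8).
#' @return data.frame with 1-based `column`, `diagnostic_states` and
#'   `background_states` (comma-joined); zero rows when the species has no
#'   diagnostic column.
#' @export
pure_diagnostics <- function(dataset, target_species, min_informative = 0.8) {
  mat <- alignment_matrix(dataset)
  sp <- dataset$records$species
  in_target <- sp == target_species
  if (!any(in_target)) stop("species not in dataset: ", target_species)
  if (all(in_target)) stop("no non-target specimens for ", target_species)
  tgt <- mat[in_target, , drop = FALSE]
  bkg <- mat[!in_target, , drop = FALSE]
  n_tgt <- nrow(tgt)
  out <- vector("list", ncol(mat))
  for (col in seq_len(ncol(mat))) {
    tv <- tgt[, col]; tv <- tv[tv %in% .UNAMBIG]
    if (length(tv) < min_informative * n_tgt || length(tv) == 0L) next
    bv <- bkg[, col]; bv <- bv[bv %in% .UNAMBIG]
    if (length(bv) == 0L) next
    ts <- unique(tv); bs <- unique(bv)
    if (length(intersect(ts, bs)) == 0L) {
      out[[col]] <- data.frame(
        column = col,
        diagnostic_states = paste(sort(ts), collapse = ","),
        background_states = paste(sort(bs), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(column = integer(0), diagnostic_states = character(0),
                      background_states = character(0),
                      stringsAsFactors = FALSE)
  }
  res
}

#' Diagnostic-site library over all species of a dataset
#'
#' @inheritParams pure_diagnostics
#' @return data.frame with `species`, `column`, `diagnostic_states`,
#'   `background_states`; species without diagnostic columns contribute no
#'   rows but are listed in the `species` attribute.
#' @export
diagnostic_library <- function(dataset, min_informative = 0.8) {
  species <- sort(unique(dataset$records$species))
  if (length(species) < 2L) stop("diagnostic library needs >= 2 species")
  res <- do.call(rbind, lapply(species, function(s) {
    d <- pure_diagnostics(dataset, s, min_informative)
    if (nrow(d)) cbind(species = s, d, stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(res)) {
    res <- data.frame(species = character(0), column = integer(0),
                      diagnostic_states = character(0),
                      background_states = character(0),
                      stringsAsFactors = FALSE)
  }
  attr(res, "species") <- species
  attr(res, "alignment_length") <- dataset$alignment_length
  res
}

#' Assign a query sequence to species via diagnostic sites
#'
#' For each species with diagnostic columns, the fraction of those columns
#' where the query carries one of the species' diagnostic states. Species
#' are ranked by fraction, then by number of diagnostic sites, then
#' alphabetically.
#'
#' @param query_sequence Nucleotide string already aligned to the library's
#'   coordinates (length at least the alignment length).
#' @param library Output of [diagnostic_library()].
#' @return data.frame `species`, `n_sites`, `n_matched`, `fraction`, ranked
#'   best first. Species with no diagnostic column get fraction `NA`.
#' @export
diagnose_query <- function(query_sequence, library) {
  alen <- attr(library, "alignment_length")
  if (!is.null(alen) && nchar(query_sequence) < alen) {
    stop("query length ", nchar(query_sequence),
         " shorter than alignment length ", alen,
         "; align the query to the library coordinates first")
  }
  q <- strsplit(toupper(query_sequence), "", fixed = TRUE)[[1L]]
  species <- attr(library, "species")
  if (is.null(species)) species <- sort(unique(library$species))
  res <- do.call(rbind, lapply(species, function(s) {
    d <- library[library$species == s, , drop = FALSE]
    if (nrow(d) == 0L) {
      return(data.frame(species = s, n_sites = 0L, n_matched = 0L,
                        fraction = NA_real_, stringsAsFactors = FALSE))
    }
    hits <- mapply(function(col, states) {
      q[col] %in% strsplit(states, ",", fixed = TRUE)[[1L]]
    }, d$column, d$diagnostic_states)
    data.frame(species = s, n_sites = nrow(d), n_matched = sum(hits),
               fraction = sum(hits) / nrow(d), stringsAsFactors = FALSE)
  }))
  ord <- order(-ifelse(is.na(res$fraction), -1, res$fraction),
               -res$n_sites, res$species)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
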