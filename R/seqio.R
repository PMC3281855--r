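#' Read aligned nucleotide sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA file into a named character vector.
#' Sequences are uppercased and RNA 'U' is mapped to 'T' so that downstream
#' code sees a single canonical DNA alphabet. IUPAC ambiguity codes and gap
#' characters are retained verbatim.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order; names are the
#'   FASTA identifiers (first whitespace-delimited token of each header).
#' @details Errors identify the offending line: sequence data before the
#'   first header, an empty header, a record with no sequence, or a
#'   duplicated identifier all abort with the line number.
#' @seealso [write_fasta()], [build_dataset()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)

  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("FASTA parse error at line ", line_no[1L],
         ": sequence data before first '>' header")
  }
  ids <- character(0)
  for (i in which(is_header)) {
    id <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1L]][1L]
    if (is.na(id) || !nzchar(id)) {
      stop("FASTA parse error at line ", line_no[i], ": empty header")
    }
    ids <- c(ids, id)
  }
  rec <- cumsum(is_header)
  seqs <- vapply(seq_along(ids), function(k) {
    paste(lines[rec == k & !is_header], collapse = "")
  }, character(1))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA parse error at line ", line_no[which(is_header)[which(empty)[1L]]],
         ": record '", ids[which(empty)[1L]], "' has no sequence")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- chartr("u", "t", seqs)
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTNRYSWKMBDHV.-]", seqs)
  if (any(bad)) {
    stop("record '", ids[which(bad)[1L]],
         "' contains characters outside the IUPAC nucleotide alphabet")
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.RANKS <- c("species", "genus", "family", "order", "class")

#' Read and validate a specimen taxonomy table
#'
#' The taxonomy table is a TSV with header exactly
#' `specimen_id  species  genus  family  order  class`. Every rank must be
#' non-empty, specimen ids unique, and rank nesting consistent: each species
#' maps to exactly one genus, each genus to one family, each family to one
#' order, each order to one class. Specimens with incomplete rank
#' assignments are rejected rather than guessed at.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `specimen_id`, `species`, `genus`,
#'   `family`, `order`, `class` (all character).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  validate_taxonomy(tab)
}

#' Validate an in-memory taxonomy table
#'
#' @param tab data.frame with the six taxonomy columns.
#' @return The validated data.frame (invisible changes: none).
#' @rdname read_taxonomy
#' @export
validate_taxonomy <- function(tab) {
  need <- c("specimen_id", .RANKS)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("taxonomy schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, need, drop = FALSE]
  for (cn in need) tab[[cn]] <- as.character(tab[[cn]])
  blank <- which(apply(tab == "" | is.na(tab), 1L, any))
  if (length(blank)) {
    stop("taxonomy error: empty field(s) in row(s) ",
         paste(blank, collapse = ", "))
  }
  dup <- tab$specimen_id[duplicated(tab$specimen_id)]
  if (length(dup)) {
    stop("duplicate specimen_id(s) in taxonomy: ",
         paste(unique(dup), collapse = ", "))
  }
  # each lower rank must map to exactly one parent rank
  for (k in seq_len(length(.RANKS) - 1L)) {
    child <- .RANKS[k]; parent <- .RANKS[k + 1L]
    m <- unique(tab[, c(child, parent)])
    clash <- m[[child]][duplicated(m[[child]])]
    if (length(clash)) {
      offenders <- m[m[[child]] %in% clash, , drop = FALSE]
      stop("taxonomy nesting violation: ", child, " ",
           paste(unique(clash), collapse = ", "), " appears under multiple ",
           parent, " values (",
           paste(paste(offenders[[child]], offenders[[parent]], sep = " -> "),
                 collapse = "; "), ")")
    }
  }
  tab
}

#' Join sequences and taxonomy into a specimen dataset
#'
#' @param fasta Named character vector of sequences, as from [read_fasta()],
#'   or a path to a FASTA file.
#' @param taxonomy Taxonomy data.frame as from [read_taxonomy()], or a path
#'   to a taxonomy TSV.
#' @param marker Marker name, one of `"COI"`, `"cytb"`, `"16S"`, `"18S"`.
#' @return Object of class `barcode_dataset`: a list with `records`
#'   (data.frame of specimen_id, sequence, five ranks), `marker`, and
#'   `alignment_length` (set iff all sequences are equal length, otherwise
#'   `NA`).
#' @details Every FASTA identifier must be present in the taxonomy; taxonomy
#'   rows without sequences are dropped. The join preserves FASTA order.
#' @export
build_dataset <- function(fasta, taxonomy, marker = c("COI", "cytb", "16S", "18S")) {
  marker <- match.arg(marker)
  if (is.character(fasta) && length(fasta) == 1L && is.null(names(fasta))) {
    fasta <- read_fasta(fasta)
  }
  if (is.character(taxonomy) && length(taxonomy) == 1L) {
    taxonomy <- read_taxonomy(taxonomy)
  } else {
    taxonomy <- validate_taxonomy(taxonomy)
  }
  if (length(fasta) < 2L) stop("dataset needs at least 2 sequences")
  unmatched <- setdiff(names(fasta), taxonomy$specimen_id)
  if (length(unmatched)) {
    stop("sequence id(s) absent from taxonomy: ",
         paste(unmatched, collapse = ", "))
  }
  idx <- match(names(fasta), taxonomy$specimen_id)
  records <- data.frame(
    specimen_id = names(fasta),
    sequence = unname(fasta),
    taxonomy[idx, .RANKS, drop = FALSE],
    stringsAsFactors = FALSE, row.names = NULL
  )
  lens <- nchar(records$sequence)
  alignment_length <- if (length(unique(lens)) == 1L) lens[1L] else NA_integer_
  structure(list(records = records, marker = marker,
                 alignment_length = alignment_length),
            class = "barcode_dataset")
}

#' @export
print.barcode_dataset <- function(x, ...) {
  r <- x$records
  cat("barcode_dataset:", nrow(r), "specimens,", length(unique(r$species)),
      "species,", length(unique(r$genus)), "genera,",
      length(unique(r$family)), "families; marker", x$marker, "\n")
  if (is.na(x$alignment_length)) {
    cat("  sequences of unequal length (", min(nchar(r$sequence)), "-",
        max(nchar(r$sequence)), " bp)\n", sep = "")
  } else {
    cat("  aligned, ", x$alignment_length, " bp\n", sep = "")
  }
  invisible(x)
}

is_coding_marker <- function(marker) marker %in% c("COI", "cytb")

# taxonomy slice of a dataset's records
dataset_taxonomy <- function(dataset) {
  dataset$records[, c("specimen_id", .RANKS), drop = FALSE]
}
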