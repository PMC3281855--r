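# Vertebrate mitochondrial genetic code, built once from seqinr's code
# tables (NCBI translation table 2). Codons with any non-ACGT character
# translate to 'X'; stops render '*'.
.vmt_code_env <- new.env(parent = emptyenv())

vmt_code <- function() {
  if (is.null(.vmt_code_env$tab)) {
    codons <- apply(expand.grid(.BASES, .BASES, .BASES,
                                stringsAsFactors = FALSE)[, 3:1],
                    1L, paste, collapse = "")
    aa <- vapply(codons, function(cd) {
      seqinr::translate(strsplit(cd, "")[[1L]], numcode = 2)
    }, character(1))
    .vmt_code_env$tab <- stats::setNames(aa, codons)
  }
  .vmt_code_env$tab
}

.VMT_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Translate a nucleotide sequence under the vertebrate mitochondrial code
#'
#' @param seq Nucleotide string (gaps and IUPAC ambiguity codes allowed).
#' @param frame Reading frame offset, 0, 1 or 2.
#' @return Amino-acid string; codons containing a gap or ambiguity code
#'   give `'X'`, stop codons give `'*'`. A trailing partial codon is
#'   dropped, so the output has `floor((nchar(seq) - frame) / 3)` residues.
#' @examples
#' translate_vmt("ATGGCC")  # "MA"
#' translate_vmt("AGA")     # "*"  (AGA is a stop in this code)
#' @export
translate_vmt <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  s <- toupper(seq)
  n_codons <- (nchar(s) - frame) %/% 3L
  if (n_codons < 1L) return("")
  starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(s, starts, starts + 2L)
  tab <- vmt_code()
  aa <- tab[codons]
  aa[is.na(aa)] <- "X"  # codon contains gap/ambiguity
  paste(aa, collapse = "")
}

#' Screen one protein-coding sequence for numt signatures
#'
#' Nuclear mitochondrial pseudogenes (numts) co-amplified with the
#' orthologous mtDNA betray themselves through in-frame stop codons or
#' frameshifting indels. A record passes only if its translation in the
#' reading frame is stop-free, it carries no internal gap character, and
#' its ungapped length is congruent mod 3 with the expected dataset length.
#'
#' @param record One-row data.frame (or list) with `specimen_id` and
#'   `sequence`, as in a `barcode_dataset`'s `records`.
#' @param frame Reading frame 0/1/2. If `NULL`, the frame minimizing the
#'   stop-codon count for this sequence is used.
#' @param expected_length Ungapped length whose residue mod 3 defines the
#'   in-frame length class (default: this record's own length, i.e. no
#'   length check).
#' @return One-row data.frame: `specimen_id`, `reading_frame_used`,
#'   `n_stop_codons`, `has_stop_codon`, `has_internal_gap`,
#'   `length_offset_mod3`, `verdict` (`"pass"` or `"suspect_numt"`).
#' @export
screen_numt <- function(record, frame = NULL, expected_length = NULL) {
  s <- record$sequence
  id <- record$specimen_id
  core <- sub("^-+", "", sub("-+$", "", s))
  has_gap <- grepl("-", core, fixed = TRUE)
  ungapped <- gsub("-", "", s, fixed = TRUE)
  if (nchar(ungapped) < 3L) stop("sequence of '", id, "' shorter than one codon")
  if (is.null(expected_length)) expected_length <- nchar(ungapped)
  len_off <- (nchar(ungapped) - expected_length) %% 3L

  if (is.null(frame)) {
    stops_by_frame <- vapply(0:2, function(f) {
      aa <- translate_vmt(ungapped, f)
      sum(strsplit(aa, "")[[1L]] == "*")
    }, numeric(1))
    frame <- which.min(stops_by_frame) - 1L
    n_stops <- stops_by_frame[frame + 1L]
  } else {
    aa <- translate_vmt(ungapped, frame)
    n_stops <- sum(strsplit(aa, "")[[1L]] == "*")
  }
  verdict <- if (n_stops == 0L && !has_gap && len_off == 0L) "pass" else "suspect_numt"
  data.frame(specimen_id = id, reading_frame_used = frame,
             n_stop_codons = n_stops, has_stop_codon = n_stops > 0L,
             has_internal_gap = has_gap, length_offset_mod3 = len_off,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Screen a protein-coding dataset for numts
#'
#' The reading frame is auto-detected once for the whole dataset (the frame
#' giving zero stops on the largest number of records) and then held fixed,
#' so a frameshifted pseudogene cannot rescue itself by shifting frame. The
#' modal ungapped length defines the expected length class for the
#' frameshift (length mod 3) check.
#'
#' @param dataset A `barcode_dataset` with a coding marker (COI or cytb).
#' @param frame Optional fixed reading frame; auto-detected when `NULL`.
#' @return Object of class `numt_screen`: data.frame of per-record reports
#'   (as [screen_numt()]) with attributes `frame`, `n_pass`, `n_suspect`.
#' @export
screen_dataset <- function(dataset, frame = NULL) {
  stopifnot(inherits(dataset, "barcode_dataset"))
  if (!is_coding_marker(dataset$marker)) {
    stop("numt screening applies to protein-coding markers (COI, cytb), not ",
         dataset$marker)
  }
  rec <- dataset$records
  if (nrow(rec) == 0L) stop("empty dataset")
  ungapped <- gsub("-", "", rec$sequence, fixed = TRUE)
  if (is.null(frame)) {
    clean_per_frame <- vapply(0:2, function(f) {
      sum(vapply(ungapped, function(s) {
        !grepl("*", translate_vmt(s, f), fixed = TRUE)
      }, logical(1)))
    }, numeric(1))
    frame <- which.max(clean_per_frame) - 1L
  }
  lens <- nchar(ungapped)
  mode_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1L])
  reports <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    screen_numt(rec[i, ], frame = frame, expected_length = mode_len)
  }))
  structure(reports, class = c("numt_screen", "data.frame"),
            frame = frame,
            n_pass = sum(reports$verdict == "pass"),
            n_suspect = sum(reports$verdict == "suspect_numt"))
}

#' @export
print.numt_screen <- function(x, ...) {
  cat("numt screen: frame ", attr(x, "frame"), "; ",
      attr(x, "n_pass"), " pass, ", attr(x, "n_suspect"), " suspect\n",
      sep = "")
  if (attr(x, "n_suspect") > 0) {
    print.data.frame(x[x$verdict == "suspect_numt", , drop = FALSE])
  }
  invisible(x)
}

#' Drop numt suspects from a dataset
#'
#' @param dataset A `barcode_dataset`.
#' @param screen Result of [screen_dataset()]; recomputed when `NULL`.
#' @return The dataset with suspect records removed.
#' @export
exclude_numts <- function(dataset, screen = NULL) {
  if (is.null(screen)) screen <- screen_dataset(dataset)
  bad <- screen$specimen_id[screen$verdict == "suspect_numt"]
  if (!length(bad)) return(dataset)
  keep <- !(dataset$records$specimen_id %in% bad)
  if (sum(keep) < 2L) stop("fewer than 2 records remain after numt exclusion")
  dataset$records <- dataset$records[keep, , drop = FALSE]
  lens <- unique(nchar(dataset$records$sequence))
  dataset$alignment_length <- if (length(lens) == 1L) lens else NA_integer_
  dataset
}
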