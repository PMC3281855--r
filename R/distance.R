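# integer encoding of the unambiguous DNA alphabet; anything else
# (gaps, N, IUPAC ambiguity codes) becomes NA and is excluded per pair
.BASES <- c("A", "C", "G", "T")

encode_seq <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1L]], .BASES)
}

.is_purine <- function(code) code == 1L | code == 3L  # A, G

#' Count compared sites, transitions and transversions for one pair
#'
#' Applies pairwise deletion: a site contributes only when both sequences
#' carry an unambiguous base (A/C/G/T) there. Transitions are A<->G and
#' C<->T; every other substitution is a transversion.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings (or integer encodings
#'   as produced internally).
#' @return List with `n_compared`, `n_transitions`, `n_transversions`.
#' @export
compare_sites <- function(seq_a, seq_b) {
  a <- if (is.character(seq_a)) encode_seq(seq_a) else seq_a
  b <- if (is.character(seq_b)) encode_seq(seq_b) else seq_b
  if (length(a) != length(b)) {
    stop("sequence length mismatch: ", length(a), " vs ", length(b))
  }
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites: all positions gapped or ambiguous")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- sum(diff & (.is_purine(a) == .is_purine(b)))
  list(n_compared = n, n_transitions = ts, n_transversions = sum(diff) - ts)
}

#' Kimura two-parameter distance from substitution counts
#'
#' Evaluates d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q)) with P and Q the
#' transition and transversion proportions over compared sites.
#'
#' @param counts List as returned by [compare_sites()].
#' @return Non-negative distance in substitutions/site.
#' @keywords internal
k2p_from_counts <- function(counts) {
  P <- counts$n_transitions / counts$n_compared
  Q <- counts$n_transversions / counts$n_compared
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P saturation: log argument non-positive (P=", signif(P, 4),
         ", Q=", signif(Q, 4), ")")
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Kimura two-parameter (K2P) distance between two aligned sequences
#'
#' The K2P correction accounts separately for transitions (proportion P)
#' and transversions (proportion Q): d = -1/2 ln[(1-2P-Q) sqrt(1-2Q)].
#' Sites where either sequence has a gap or ambiguity code are excluded
#' (pairwise deletion). Saturated pairs (non-positive log argument) raise
#' an error rather than returning NaN.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings.
#' @return Distance in substitutions/site (a proportion, not percent).
#' @examples
#' k2p("ACGT", "ACGT")  # 0
#' @export
k2p <- function(seq_a, seq_b) {
  k2p_from_counts(compare_sites(seq_a, seq_b))
}

#' Uncorrected proportion (p) distance between two aligned sequences
#'
#' @inheritParams k2p
#' @return Proportion of differing sites among pairwise-comparable sites.
#' @export
p_distance <- function(seq_a, seq_b) {
  cs <- compare_sites(seq_a, seq_b)
  (cs$n_transitions + cs$n_transversions) / cs$n_compared
}

#' Pairwise distance matrix over a dataset
#'
#' Computes the full symmetric matrix of K2P (or p) distances with pairwise
#' deletion. Saturated pairs (K2P undefined) are not dropped silently: the
#' cell is set to `NA`, recorded in a logical `saturated` mask, and counted.
#'
#' @param dataset A `barcode_dataset` (aligned: equal sequence lengths).
#' @param metric `"k2p"` (default) or `"p"`.
#' @return Object of class `pairwise_dist`: list with `labels`, `metric`,
#'   `d` (symmetric numeric matrix, zero diagonal, proportions),
#'   `saturated` (logical matrix), `n_saturated`.
#' @export
pairwise_matrix <- function(dataset, metric = c("k2p", "p")) {
  metric <- match.arg(metric)
  stopifnot(inherits(dataset, "barcode_dataset"))
  if (is.na(dataset$alignment_length)) {
    stop("pairwise_matrix requires an aligned dataset (equal lengths)")
  }
  rec <- dataset$records
  n <- nrow(rec)
  if (n < 2L) stop("need at least 2 records")
  enc <- lapply(rec$sequence, encode_seq)
  labels <- rec$specimen_id
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  sat <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    ai <- enc[[i]]
    ai_ok <- !is.na(ai)
    for (j in (i + 1L):n) {
      bj <- enc[[j]]
      ok <- ai_ok & !is.na(bj)
      m <- sum(ok)
      if (m == 0L) {
        stop("no comparable sites for pair (", labels[i], ", ", labels[j], ")")
      }
      a <- ai[ok]; b <- bj[ok]
      ndiff <- sum(a != b)
      if (metric == "p") {
        val <- ndiff / m
      } else {
        ts <- sum(a != b & (.is_purine(a) == .is_purine(b)))
        P <- ts / m
        Q <- (ndiff - ts) / m
        w1 <- 1 - 2 * P - Q
        w2 <- 1 - 2 * Q
        if (w1 <= 0 || w2 <= 0) {
          sat[i, j] <- sat[j, i] <- TRUE
          val <- NA_real_
        } else {
          val <- -0.5 * log(w1) - 0.25 * log(w2)
        }
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  structure(list(labels = labels, metric = metric, d = d,
                 saturated = sat, n_saturated = sum(sat) / 2L),
            class = "pairwise_dist")
}

#' @export
print.pairwise_dist <- function(x, ...) {
  cat("pairwise_dist:", length(x$labels), "specimens, metric", x$metric, "\n")
  vals <- x$d[upper.tri(x$d)]
  cat("  mean ", format_pct(mean(vals, na.rm = TRUE)), "%, range ",
      format_pct(min(vals, na.rm = TRUE)), "-",
      format_pct(max(vals, na.rm = TRUE)), "%\n", sep = "")
  if (x$n_saturated > 0) cat("  saturated pairs (masked):", x$n_saturated, "\n")
  invisible(x)
}

#' @export
as.dist.pairwise_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Export a distance matrix as text
#'
#' @param x A `pairwise_dist`.
#' @param path Output path.
#' @param format `"phylip"` (square PHYLIP distance format) or `"lower"`
#'   (tab-delimited lower-triangular with a label column).
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(x, path, format = c("phylip", "lower")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "pairwise_dist"))
  n <- length(x$labels)
  con <- file(path, "wt")
  on.exit(close(con))
  fmt <- function(v) sprintf("%.6f", v)
  if (format == "phylip") {
    writeLines(sprintf("%5d", n), con)
    for (i in seq_len(n)) {
      writeLines(paste(c(x$labels[i], fmt(x$d[i, ])), collapse = "  "), con)
    }
  } else {
    for (i in seq_len(n)) {
      row <- if (i == 1L) x$labels[1L] else
        paste(c(x$labels[i], fmt(x$d[i, seq_len(i - 1L)])), collapse = "\t")
      writeLines(row, con)
    }
  }
  invisible(path)
}

# percent rendering used by all reports: proportions -> %, 2 decimals,
# round-half-even (base R round())
format_pct <- function(p) formatC(round(100 * p, 2), format = "f", digits = 2)

pct <- function(p) round(100 * p, 2)
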