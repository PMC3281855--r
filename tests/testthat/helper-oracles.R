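# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

oracle_site_counts <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  stopifnot(length(av) == length(bv))
  bases <- c("A", "C", "G", "T")
  purines <- c("A", "G")
  n <- ts <- tv <- 0L
  for (i in seq_along(av)) {
    x <- av[i]; y <- bv[i]
    if (x %in% bases && y %in% bases) {
      n <- n + 1L
      if (x != y) {
        if ((x %in% purines) == (y %in% purines)) ts <- ts + 1L
        else tv <- tv + 1L
      }
    }
  }
  list(n = n, ts = ts, tv = tv)
}

oracle_k2p <- function(a, b) {
  cnt <- oracle_site_counts(a, b)
  P <- cnt$ts / cnt$n
  Q <- cnt$tv / cnt$n
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random unrooted tree with strictly positive branch lengths and its
# additive (path-length) distance matrix
random_additive <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 0.4))
  D <- as.matrix(stats::cophenetic(tr))
  list(tree = tr, D = D)
}

# small handcrafted dataset: 2 genera x 2 species x 2 specimens, one family
tiny_taxonomy <- function() {
  data.frame(
    specimen_id = paste0("sp", 1:8),
    species = rep(c("Aus_one", "Aus_two", "Bus_one", "Bus_two"), each = 2),
    genus = rep(c("Aus", "Bus"), each = 4),
    family = "Fidae",
    order = "Ordo",
    class = "Classis",
    stringsAsFactors = FALSE
  )
}

# brute-force re-derivation of pure diagnostic columns for one species
oracle_diagnostics <- function(dataset, target, min_informative = 0.8) {
  rec <- dataset$records
  mat <- do.call(rbind, strsplit(rec$sequence, ""))
  hits <- integer(0)
  for (col in seq_len(ncol(mat))) {
    tv <- mat[rec$species == target, col]
    bv <- mat[rec$species != target, col]
    tv_ok <- tv[tv %in% c("A", "C", "G", "T")]
    bv_ok <- bv[bv %in% c("A", "C", "G", "T")]
    if (length(tv_ok) < min_informative * length(tv) || !length(tv_ok) ||
        !length(bv_ok)) next
    if (!any(tv_ok %in% bv_ok)) hits <- c(hits, col)
  }
  hits
}

tiny_dataset <- function(seed = 7) {
  set.seed(seed)
  tax <- tiny_taxonomy()
  root <- random_root_sequence(120, coding = FALSE)
  gA <- evolve_sequence(root, 0.08)
  gB <- evolve_sequence(root, 0.08)
  mk_species <- function(g) evolve_sequence(g, 0.05)
  seqs <- character(0)
  for (g in list(gA, gB)) {
    for (s in 1:2) {
      spseq <- mk_species(g)
      seqs <- c(seqs, evolve_sequence(spseq, 0.002),
                evolve_sequence(spseq, 0.002))
    }
  }
  names(seqs) <- tax$specimen_id
  build_dataset(seqs, tax, marker = "16S")
}
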