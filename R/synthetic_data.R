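#' Configuration for the rank-structured sequence simulator
#'
#' Defaults emulate the divergence structure of a marine-fish COI barcode
#' survey: intraspecific divergence centred near 0.2%, congeneric near
#' 13.5%, confamilial near 19.7%, ordinal near 24%, on a 652-bp amplicon,
#' with transition-biased substitution (two-parameter model, ratio
#' `kappa`), so the K2P estimator is correctly specified for the
#' simulated process.
#'
#' @param seed Integer seed; all stochastic draws flow from it.
#' @param n_families,genera_per_family,species_per_genus,specimens_per_species
#'   Taxonomy shape (all >= 1); a single order and class contain all
#'   families.
#' @param seq_length Alignment length in sites (default 652).
#' @param kappa Transition/transversion rate ratio, > 0 (default 2).
#' @param divergence Named numeric vector of expected pairwise divergences
#'   (substitutions/site) per comparison class: `within_species`,
#'   `within_genus`, `within_family`, `within_order`; must be strictly
#'   increasing.
#' @param numt_rate Probability that a specimen is replaced by a detectable
#'   numt (default 0).
#' @param marker Marker name; coding markers (COI, cytb) are simulated
#'   stop-free in frame 0 under the vertebrate mitochondrial code.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_families = 4L,
                              genera_per_family = 2L, species_per_genus = 3L,
                              specimens_per_species = 3L, seq_length = 652L,
                              kappa = 2,
                              divergence = c(within_species = 0.002,
                                             within_genus = 0.135,
                                             within_family = 0.197,
                                             within_order = 0.24),
                              numt_rate = 0,
                              marker = c("COI", "cytb", "16S", "18S")) {
  marker <- match.arg(marker)
  counts <- c(n_families, genera_per_family, species_per_genus,
              specimens_per_species)
  stopifnot(all(counts >= 1L), seq_length >= 3L, kappa > 0,
            numt_rate >= 0, numt_rate <= 1)
  need <- c("within_species", "within_genus", "within_family", "within_order")
  if (!all(need %in% names(divergence))) {
    stop("divergence must name: ", paste(need, collapse = ", "))
  }
  divergence <- divergence[need]
  if (any(divergence < 0) || !all(diff(divergence) > 0)) {
    stop("config error: divergences must be >= 0 and increase strictly with rank")
  }
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 specimens_per_species = as.integer(specimens_per_species),
                 seq_length = as.integer(seq_length), kappa = kappa,
                 divergence = divergence, numt_rate = numt_rate,
                 marker = marker),
            class = "sim_config")
}

# K80 per-site transition probabilities after expected divergence d
k80_site_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  p_tv <- (1 - e1) / 4                 # each of the two transversions
  p_ts <- (1 + e1) / 4 - e2 / 2
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

.TS_PARTNER <- c(3L, 4L, 1L, 2L)       # A<->G, C<->T
.TV1 <- c(2L, 1L, 2L, 1L)              # first transversion target
.TV2 <- c(4L, 3L, 4L, 3L)              # second transversion target

# evolve an integer-encoded sequence along one branch of length d
evolve_codes <- function(codes, d, kappa) {
  if (d <= 0) return(codes)
  p <- k80_site_probs(d, kappa)
  u <- stats::runif(length(codes))
  out <- codes
  to_ts <- u >= p[["same"]] & u < p[["same"]] + p[["ts"]]
  to_tv1 <- u >= p[["same"]] + p[["ts"]] & u < p[["same"]] + p[["ts"]] + p[["tv"]]
  to_tv2 <- u >= p[["same"]] + p[["ts"]] + p[["tv"]]
  out[to_ts] <- .TS_PARTNER[codes[to_ts]]
  out[to_tv1] <- .TV1[codes[to_tv1]]
  out[to_tv2] <- .TV2[codes[to_tv2]]
  out
}

# condition the substitution process on the open reading frame staying
# stop-free (purifying selection): frame-0 codons that became stops are
# re-evolved from the parent codon until non-stop, which preserves the
# expected divergence of the surviving draws
revert_stop_codons <- function(child, parent, d = 0, kappa = 2) {
  n_codons <- length(child) %/% 3L
  if (n_codons == 0L) return(child)
  idx <- matrix(seq_len(3L * n_codons), nrow = 3L)
  codon_str <- apply(idx, 2L, function(i) paste(.BASES[child[i]], collapse = ""))
  for (k in which(codon_str %in% .VMT_STOPS)) {
    sites <- idx[, k]
    for (try in 1:100) {
      redraw <- evolve_codes(parent[sites], d, kappa)
      if (!paste(.BASES[redraw], collapse = "") %in% .VMT_STOPS) break
      redraw <- parent[sites]
    }
    child[sites] <- redraw
  }
  child
}

#' Evolve a nucleotide sequence under the two-parameter model
#'
#' One branch of expected length `d` substitutions/site with
#' transition/transversion rate ratio `kappa`. Uses the current RNG state.
#'
#' @param seq Nucleotide string over A/C/G/T.
#' @param d Branch length (expected substitutions/site).
#' @param kappa Transition/transversion rate ratio.
#' @param keep_orf If `TRUE`, frame-0 codons that become vertebrate-mito
#'   stop codons are reverted to the parent codon.
#' @return Evolved sequence string.
#' @export
evolve_sequence <- function(seq, d, kappa = 2, keep_orf = FALSE) {
  codes <- encode_seq(seq)
  if (anyNA(codes)) stop("evolve_sequence needs an unambiguous A/C/G/T sequence")
  out <- evolve_codes(codes, d, kappa)
  if (keep_orf) out <- revert_stop_codons(out, codes, d, kappa)
  paste(.BASES[out], collapse = "")
}

#' Random root sequence
#'
#' Uniform over A/C/G/T; for coding sequences, frame-0 stop codons are
#' resampled so the open reading frame starts clean.
#'
#' @param length Sequence length.
#' @param coding Avoid vertebrate-mito stop codons in frame 0?
#' @return Nucleotide string. Uses the current RNG state.
#' @export
random_root_sequence <- function(length, coding = FALSE) {
  codes <- sample.int(4L, length, replace = TRUE)
  if (coding) {
    n_codons <- length %/% 3L
    if (n_codons > 0L) {
      idx <- matrix(seq_len(3L * n_codons), nrow = 3L)
      repeat {
        codon_str <- apply(idx, 2L, function(i)
          paste(.BASES[codes[i]], collapse = ""))
        bad <- which(codon_str %in% .VMT_STOPS)
        if (!length(bad)) break
        for (k in bad) codes[idx[, k]] <- sample.int(4L, 3L, replace = TRUE)
      }
    }
  }
  paste(.BASES[codes], collapse = "")
}

#' Simulate a pair of sequences at a known divergence
#'
#' Two lineages evolved independently from a random root for `d/2` each,
#' so their expected pairwise divergence is `d`. Uses the current RNG
#' state; convenient for estimator-recovery experiments.
#'
#' @param d True expected pairwise divergence (substitutions/site).
#' @param length Sequence length.
#' @param kappa Transition/transversion rate ratio.
#' @return Character vector of two sequences.
#' @export
simulate_divergent_pair <- function(d, length = 652L, kappa = 2) {
  root <- random_root_sequence(length)
  c(evolve_sequence(root, d / 2, kappa), evolve_sequence(root, d / 2, kappa))
}

#' Simulate a rank-structured barcode dataset
#'
#' Builds a taxonomy of `n_families` families (one order, one class), each
#' with `genera_per_family` genera of `species_per_genus` species sampled
#' `specimens_per_species` times, and evolves sequences down the matching
#' ultrametric tree. Node heights are half the configured expected pairwise
#' divergence of the corresponding comparison class, so for example two
#' conspecific specimens are separated by an expected
#' `divergence["within_species"]` substitutions/site. Coding markers are
#' kept stop-free in frame 0. With `numt_rate > 0`, specimens are
#' independently replaced by detectable numts (planted stop codon or 1-bp
#' deletion) and recorded in the truth.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return Object of class `synthetic_dataset`: list with `dataset` (a
#'   `barcode_dataset`), and `truth` (config echo, true tree in newick,
#'   true per-class divergences, planted `numt_ids` and `deep_splits`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  coding <- is_coding_marker(config$marker)
  dv <- config$divergence
  h <- dv / 2  # node heights: tip=0, species, genus, family, root
  b_tip <- h[["within_species"]]
  b_sp <- h[["within_genus"]] - h[["within_species"]]
  b_gen <- h[["within_family"]] - h[["within_genus"]]
  b_fam <- h[["within_order"]] - h[["within_family"]]

  root <- encode_seq(random_root_sequence(config$seq_length, coding = coding))
  evolve1 <- function(parent, d) {
    child <- evolve_codes(parent, d, config$kappa)
    if (coding) child <- revert_stop_codons(child, parent, d, config$kappa)
    child
  }

  rows <- list(); seqs <- character(0); ids <- character(0)
  tree_fams <- character(0)
  spec_no <- 0L
  for (f in seq_len(config$n_families)) {
    fam_seq <- evolve1(root, b_fam)
    fam_name <- sprintf("Family%02d", f)
    tree_gens <- character(0)
    for (g in seq_len(config$genera_per_family)) {
      gen_seq <- evolve1(fam_seq, b_gen)
      gen_name <- sprintf("Genus%02d_%02d", f, g)
      tree_sps <- character(0)
      for (s in seq_len(config$species_per_genus)) {
        sp_seq <- evolve1(gen_seq, b_sp)
        sp_name <- sprintf("Species%02d_%02d_%02d", f, g, s)
        tree_tips <- character(0)
        for (i in seq_len(config$specimens_per_species)) {
          spec_no <- spec_no + 1L
          id <- sprintf("SP%04d", spec_no)
          tip_seq <- evolve1(sp_seq, b_tip)
          ids <- c(ids, id)
          seqs <- c(seqs, paste(.BASES[tip_seq], collapse = ""))
          rows[[spec_no]] <- data.frame(
            specimen_id = id, species = sp_name, genus = gen_name,
            family = fam_name, order = "Order01", class = "Class01",
            stringsAsFactors = FALSE)
          tree_tips <- c(tree_tips, sprintf("%s:%.6f", id, b_tip))
        }
        tree_sps <- c(tree_sps, sprintf("(%s):%.6f",
                                        paste(tree_tips, collapse = ","), b_sp))
      }
      tree_gens <- c(tree_gens, sprintf("(%s):%.6f",
                                        paste(tree_sps, collapse = ","), b_gen))
    }
    tree_fams <- c(tree_fams, sprintf("(%s):%.6f",
                                      paste(tree_gens, collapse = ","), b_fam))
  }
  newick <- sprintf("(%s);", paste(tree_fams, collapse = ","))
  taxonomy <- do.call(rbind, rows)
  names(seqs) <- ids
  dataset <- build_dataset(seqs, taxonomy, marker = config$marker)

  out <- structure(list(
    dataset = dataset,
    truth = list(config = unclass(config), tree_newick = newick,
                 divergence = as.list(dv), numt_ids = character(0),
                 deep_splits = list())),
    class = "synthetic_dataset")

  if (config$numt_rate > 0 && coding) {
    hit <- ids[stats::runif(length(ids)) < config$numt_rate]
    for (id in hit) out <- inject_numt(out, id, seed = config$seed)
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset (seed ", x$truth$config$seed, ")\n", sep = "")
  print(x$dataset)
  if (length(x$truth$numt_ids)) {
    cat("  planted numts:", paste(x$truth$numt_ids, collapse = ", "), "\n")
  }
  if (length(x$truth$deep_splits)) {
    cat("  planted deep splits:",
        paste(names(x$truth$deep_splits), collapse = ", "), "\n")
  }
  invisible(x)
}

.unwrap <- function(x) if (inherits(x, "synthetic_dataset")) x$dataset else x

per_specimen_seed <- function(seed, specimen_id) {
  (as.integer(seed) + sum(utf8ToInt(specimen_id)) * 131L) %% 2147483046L + 1L
}

#' Plant a detectable numt into one specimen
#'
#' Replaces the specimen's sequence with a pseudogene-like copy carrying
#' either an in-frame stop codon or a single-base deletion (rendered as an
#' internal gap). The change is a deterministic function of
#' `(specimen_id, seed)`, so re-injection is idempotent.
#'
#' @param x A `synthetic_dataset` (truth updated) or `barcode_dataset`.
#' @param specimen_id Specimen to corrupt.
#' @param seed Integer seed.
#' @param type `"stop"` (default) or `"deletion"`.
#' @return Object of the same class as `x`.
#' @export
inject_numt <- function(x, specimen_id, seed = 1L,
                        type = c("stop", "deletion")) {
  type <- match.arg(type)
  dataset <- .unwrap(x)
  if (!is_coding_marker(dataset$marker)) {
    stop("cannot inject a numt into non-coding marker ", dataset$marker)
  }
  i <- match(specimen_id, dataset$records$specimen_id)
  if (is.na(i)) stop("specimen not in dataset: ", specimen_id)
  s <- dataset$records$sequence[i]
  n_codons <- nchar(s) %/% 3L
  if (n_codons < 3L) stop("sequence too short to corrupt")
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old_rng <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old_rng, envir = globalenv()))
  set.seed(per_specimen_seed(seed, specimen_id))
  # avoid first/last codon so the lesion is internal
  codon <- sample(2:(n_codons - 1L), 1L)
  pos <- 3L * (codon - 1L) + 1L
  if (type == "stop") {
    substr(s, pos, pos + 2L) <- "TAA"
  } else {
    substr(s, pos, pos) <- "-"
  }
  dataset$records$sequence[i] <- s
  if (inherits(x, "synthetic_dataset")) {
    x$dataset <- dataset
    x$truth$numt_ids <- sort(unique(c(x$truth$numt_ids, specimen_id)))
    x
  } else dataset
}

#' Plant a deep intraspecific split into one species
#'
#' Evolves half of a species' specimens (the later half by specimen id) by
#' `extra_divergence` additional expected substitutions/site, creating the
#' deep intraspecific divergence pattern that trips the 1% barcode filter.
#'
#' @param x A `synthetic_dataset` (truth updated) or `barcode_dataset`.
#' @param species Species name with >= 2 specimens.
#' @param extra_divergence Additional expected divergence (proportion);
#'   0 leaves the dataset unchanged.
#' @param seed Integer seed.
#' @param kappa Transition/transversion ratio (defaults to the truth's
#'   kappa for a `synthetic_dataset`, else 2).
#' @return Object of the same class as `x`.
#' @export
plant_deep_split <- function(x, species, extra_divergence, seed = 1L,
                             kappa = NULL) {
  dataset <- .unwrap(x)
  if (is.null(kappa)) {
    kappa <- if (inherits(x, "synthetic_dataset")) x$truth$config$kappa else 2
  }
  rows <- which(dataset$records$species == species)
  if (length(rows) == 0L) stop("species not in dataset: ", species)
  if (length(rows) < 2L) stop("species '", species, "' has a single specimen")
  if (extra_divergence < 0) stop("extra_divergence must be >= 0")
  if (extra_divergence == 0) return(x)
  ids <- sort(dataset$records$specimen_id[rows])
  moved <- ids[(length(ids) %/% 2L + 1L):length(ids)]
  coding <- is_coding_marker(dataset$marker)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old_rng <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old_rng, envir = globalenv()))
  set.seed(per_specimen_seed(seed, species))
  for (id in moved) {
    i <- match(id, dataset$records$specimen_id)
    dataset$records$sequence[i] <- evolve_sequence(
      dataset$records$sequence[i], extra_divergence, kappa, keep_orf = coding)
  }
  if (inherits(x, "synthetic_dataset")) {
    x$dataset <- dataset
    x$truth$deep_splits[[species]] <- list(extra_divergence = extra_divergence,
                                           moved = moved)
    x
  } else dataset
}

#' Serialize a synthetic dataset to FASTA + taxonomy TSV + truth JSON
#'
#' @param x A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, named vector of the three paths.
#' @export
write_synthetic <- function(x, dir, prefix = "synthetic") {
  stopifnot(inherits(x, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- x$dataset$records
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  taxonomy <- file.path(dir, paste0(prefix, "_taxonomy.tsv"))
  truth <- file.path(dir, paste0(prefix, "_truth.json"))
  write_fasta(stats::setNames(rec$sequence, rec$specimen_id), fasta)
  utils::write.table(dataset_taxonomy(x$dataset), taxonomy, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$truth, truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(fasta = fasta, taxonomy = taxonomy, truth = truth))
}
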