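make_dist <- function(d, labels) {
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, metric = "k2p", d = d,
                 saturated = matrix(FALSE, nrow(d), ncol(d)),
                 n_saturated = 0L),
            class = "pairwise_dist")
}

test_that("classify_pair picks the most specific shared rank", {
  tax <- tiny_taxonomy()
  expect_equal(classify_pair(tax, "sp1", "sp2"), "within_species")
  expect_equal(classify_pair(tax, "sp1", "sp3"), "within_genus")
  expect_equal(classify_pair(tax, "sp1", "sp5"), "within_family")
  tax2 <- tax
  tax2$family[5:8] <- "Gidae"
  expect_equal(classify_pair(tax2, "sp1", "sp5"), "within_order")
  tax2$order[5:8] <- "Ordo2"
  expect_equal(classify_pair(tax2, "sp1", "sp5"), "within_class")
  tax2$class[5:8] <- "Classis2"
  expect_true(is.na(classify_pair(tax2, "sp1", "sp5")))
})

test_that("rank summaries match brute-force pair enumeration", {
  ds <- tiny_dataset()
  tax <- tiny_taxonomy()
  m <- pairwise_matrix(ds)
  s <- suppressWarnings(rank_summaries(m, tax))  # one family: no higher classes

  # brute force: enumerate all C(8,2) pairs and classify each
  vals <- list()
  for (i in 1:7) for (j in (i + 1):8) {
    cl <- classify_pair(tax, m$labels[i], m$labels[j])
    vals[[cl]] <- c(vals[[cl]], m$d[i, j] * 100)
  }
  # 2 species x 2 specimens per genus: 4 conspecific, 4+4 congeneric pairs...
  expect_equal(lengths(vals)[["within_species"]], 4L)
  expect_equal(lengths(vals)[["within_genus"]], 8L)
  expect_equal(lengths(vals)[["within_family"]], 16L)
  for (cl in names(vals)) {
    row <- s[s$class == cl, ]
    expect_equal(row$n_comparisons, length(vals[[cl]]))
    expect_equal(row$mean, mean(vals[[cl]]))
    expect_equal(row$minimum, min(vals[[cl]]))
    expect_equal(row$maximum, max(vals[[cl]]))
    expect_equal(row$se, sd(vals[[cl]]) / sqrt(length(vals[[cl]])))
  }
  # partition completeness: the classes tile all C(8,2) pairs
  expect_equal(sum(s$n_comparisons), choose(8, 2))
  # n_taxa counts only taxa contributing comparisons
  expect_equal(s$n_taxa[s$class == "within_species"], 4L)
  expect_equal(s$n_taxa[s$class == "within_genus"], 2L)
  expect_equal(s$n_taxa[s$class == "within_family"], 1L)
})

test_that("singleton species are excluded from conspecific statistics", {
  tax <- tiny_taxonomy()[c(1, 3, 5, 7), ]  # one specimen per species
  d <- matrix(0.1, 4, 4); diag(d) <- 0
  m <- make_dist(d, tax$specimen_id)
  w <- capture_warnings(s <- rank_summaries(m, tax))
  expect_true(any(grepl("within_species", w)))
  expect_false("within_species" %in% s$class)
})

test_that("identical sequences give all-zero class means", {
  tax <- tiny_taxonomy()
  seqs <- setNames(rep(paste(rep("ACGT", 20), collapse = ""), 8),
                   tax$specimen_id)
  ds <- build_dataset(seqs, tax, marker = "16S")
  s <- suppressWarnings(rank_summaries(pairwise_matrix(ds), tax))
  expect_true(all(s$mean == 0))
})

test_that("cumulative classes nest the disjoint ones", {
  ds <- tiny_dataset()
  tax <- tiny_taxonomy()
  m <- pairwise_matrix(ds)
  s <- suppressWarnings(rank_summaries(m, tax))
  sc <- suppressWarnings(rank_summaries(m, tax, cumulative = TRUE))
  expect_equal(sc$n_comparisons[sc$class == "within_genus"],
               sum(s$n_comparisons[s$class %in% c("within_species",
                                                  "within_genus")]))
  expect_equal(sc$n_comparisons[sc$class == "within_family"], choose(8, 2))
})

test_that("band counts tile the congeneric comparisons and use half-open edges", {
  # toy family: congeneric distances 3% and 7% -> bands (1,1,0)
  tax <- tiny_taxonomy()[c(1, 3, 5, 7), ]  # 4 species, singletons
  d <- matrix(0, 4, 4)
  # sp1-sp3 congeneric in Aus; sp5-sp7 congeneric in Bus (same family)
  d[1, 2] <- d[2, 1] <- 0.03
  d[3, 4] <- d[4, 3] <- 0.07
  d[1, 3] <- d[3, 1] <- d[1, 4] <- d[4, 1] <- 0.20
  d[2, 3] <- d[3, 2] <- d[2, 4] <- d[4, 2] <- 0.12
  m <- make_dist(d, tax$specimen_id)
  b <- band_counts(m, tax)
  expect_equal(nrow(b), 1L)  # one family
  expect_equal(b[["<5%"]], 1L)
  expect_equal(b[["5-10%"]], 1L)
  expect_equal(b[[">10%"]], 0L)
  expect_equal(attr(b, "grand_total"), 2L)

  # exact 5% falls in the 5-10 band (half-open edges)
  d[1, 2] <- d[2, 1] <- 0.05
  b2 <- band_counts(make_dist(d, tax$specimen_id), tax)
  expect_equal(b2[["<5%"]], 0L)
  expect_equal(b2[["5-10%"]], 2L)

  # consistency with rank_summaries on a richer dataset
  ds <- tiny_dataset()
  taxf <- tiny_taxonomy()
  mf <- pairwise_matrix(ds)
  bf <- band_counts(mf, taxf)
  sf <- suppressWarnings(rank_summaries(mf, taxf))
  expect_equal(attr(bf, "grand_total"),
               sf$n_comparisons[sf$class == "within_genus"])
  expect_equal(sum(bf$total), attr(bf, "grand_total"))
})

test_that("threshold fractions reproduce printed-count arithmetic and are monotone", {
  expect_equal(threshold_percent(5723, 5814)$percent, 98.43)
  expect_equal(threshold_percent(8, 242)$percent, 3.31)

  ds <- tiny_dataset()
  tax <- tiny_taxonomy()
  m <- pairwise_matrix(ds)
  tf0 <- threshold_fraction(m, tax, "within_species", 0)
  expect_equal(tf0$count_below, 0L)  # strict 'below', distances >= 0
  prev <- -1
  for (t in c(0.001, 0.005, 0.01, 0.05, 0.3)) {
    cur <- threshold_fraction(m, tax, "within_species", t)$count_below
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_equal(threshold_fraction(m, tax, "within_species", 0.5)$percent, 100)
})

test_that("nearest-neighbour distances match brute force and invariants", {
  ds <- tiny_dataset()
  tax <- tiny_taxonomy()
  m <- pairwise_matrix(ds)
  nnd <- nearest_neighbor_distances(m, tax)
  expect_equal(nrow(nnd), 4L)  # one row per species, singletons included
  sp <- tax$species[match(m$labels, tax$specimen_id)]
  for (s in unique(sp)) {
    rows <- sp == s
    sub <- m$d[rows, !rows, drop = FALSE] * 100
    expect_equal(nnd$distance[nnd$species == s], min(sub))
    expect_true(nnd$nearest_neighbor[nnd$species == s] != s)
    # NND <= every congeneric mean involving s
    congeners <- sp[sp != s &
      tax$genus[match(m$labels, tax$specimen_id)] ==
      tax$genus[match(m$labels[rows][1], tax$specimen_id)]]
    if (length(congeners)) {
      expect_lte(nnd$distance[nnd$species == s],
                 mean(m$d[rows, sp %in% congeners] * 100))
    }
  }

  # two species sharing identical sequences have NND 0 for both
  tax2 <- tiny_taxonomy()[c(1, 3), ]
  seqs <- setNames(rep(random_seq(40), 2), tax2$specimen_id)
  ds2 <- build_dataset(seqs, tax2, marker = "16S")
  nnd2 <- nearest_neighbor_distances(pairwise_matrix(ds2), tax2)
  expect_equal(nnd2$distance, c(0, 0))

  # single-species dataset is an error
  tax3 <- tiny_taxonomy()[1:2, ]
  seqs3 <- setNames(c(random_seq(40), random_seq(40)), tax3$specimen_id)
  expect_error(
    nearest_neighbor_distances(pairwise_matrix(
      build_dataset(seqs3, tax3, marker = "16S")), tax3),
    ">= 2 species")
})

test_that("fold ratio divides congeneric by conspecific means", {
  s <- data.frame(class = c("within_species", "within_genus"),
                  mean = c(0.18, 13.55))
  expect_equal(fold_ratio(s), 13.55 / 0.18, tolerance = 1e-12)
  expect_gt(fold_ratio(s), 70)
  s$mean <- c(1, 1)
  expect_equal(fold_ratio(s), 1)
  s$mean <- c(0, 1)
  expect_error(fold_ratio(s), "undefined")
})

test_that("boxplot statistics follow the Tukey convention", {
  b <- boxplot_stats(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3)
  expect_equal(b$q1, 2)
  expect_equal(b$q3, 4)
  expect_equal(b$iqr, 2)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 5)
  expect_length(b$mild_outliers, 0)

  # constant vector: IQR 0, no outliers
  b0 <- boxplot_stats(rep(2.5, 10))
  expect_equal(b0$iqr, 0)
  expect_length(b0$mild_outliers, 0)
  expect_length(b0$extreme_outliers, 0)

  # constructed mild and extreme outliers: q1=2, q3=5, IQR=3, so the
  # mild fence is 9.5 and the extreme fence 14
  v <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 12, 40)
  q <- quantile(v, c(.25, .75), type = 7)
  iqr <- diff(q)
  expect_true(12 > q[2] + 1.5 * iqr && 12 <= q[2] + 3 * iqr)
  expect_true(40 > q[2] + 3 * iqr)
  b2 <- boxplot_stats(v)
  expect_equal(b2$mild_outliers, 12)
  expect_equal(b2$extreme_outliers, 40)
  # whiskers clipped to observed data within the fences
  expect_equal(b2$whisker_high, 5)
  expect_equal(b2$whisker_low, 1)
})

test_that("barcode-gap flags catch deep splits and low NND", {
  cfg <- simulation_config(seed = 88, n_families = 2, genera_per_family = 2,
                           species_per_genus = 2, specimens_per_species = 4)
  syn <- simulate_dataset(cfg)
  tax <- syn$dataset$records[, c("specimen_id", "species", "genus",
                                 "family", "order", "class")]
  m <- pairwise_matrix(syn$dataset)
  f <- barcode_gap_flags(m, tax)
  expect_false(any(f$flagged))

  # plant a 2.5% deep split: that species (and only it) gets flagged
  syn2 <- plant_deep_split(syn, "Species01_01_01", 0.025, seed = 4)
  m2 <- pairwise_matrix(syn2$dataset)
  f2 <- barcode_gap_flags(m2, tax)
  expect_true(f2$deep_intraspecific[f2$species == "Species01_01_01"])
  expect_equal(f2$species[f2$deep_intraspecific], "Species01_01_01")

  # species with zero intraspecific variation is never deep-flagged
  expect_false(any(f$deep_intraspecific[f$max_intra == 0]))
})
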