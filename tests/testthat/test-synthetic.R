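test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(seed = 99, n_families = 2, genera_per_family = 2,
                           species_per_genus = 2, specimens_per_species = 2,
                           seq_length = 120)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$records, b$dataset$records)
  expect_identical(a$truth$tree_newick, b$truth$tree_newick)
  c <- simulate_dataset(simulation_config(seed = 100, n_families = 2,
                                          genera_per_family = 2,
                                          species_per_genus = 2,
                                          specimens_per_species = 2,
                                          seq_length = 120))
  expect_false(identical(a$dataset$records$sequence,
                         c$dataset$records$sequence))
})

test_that("zero intraspecific divergence gives identical conspecific sequences", {
  cfg <- simulation_config(seed = 5, n_families = 1, genera_per_family = 1,
                           species_per_genus = 2, specimens_per_species = 2,
                           seq_length = 90,
                           divergence = c(within_species = 0,
                                          within_genus = 0.1,
                                          within_family = 0.15,
                                          within_order = 0.2))
  syn <- simulate_dataset(cfg)
  rec <- syn$dataset$records
  for (sp in unique(rec$species)) {
    expect_length(unique(rec$sequence[rec$species == sp]), 1L)
  }
})

test_that("config validation rejects inconsistent divergence ordering", {
  expect_error(simulation_config(divergence = c(within_species = 0.2,
                                                within_genus = 0.1,
                                                within_family = 0.3,
                                                within_order = 0.4)),
               "increase strictly")
  expect_error(simulation_config(kappa = 0), "kappa")
})

test_that("generated data pass sequence and taxonomy validation round trip", {
  cfg <- simulation_config(seed = 17, n_families = 2, genera_per_family = 2,
                           species_per_genus = 2, specimens_per_species = 2,
                           seq_length = 120)
  syn <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_synthetic(syn, dir)
  ds <- build_dataset(paths[["fasta"]], paths[["taxonomy"]], marker = "COI")
  expect_identical(ds$records, syn$dataset$records)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$config$seed, 17L)
  # true tree serializes to parseable newick with one tip per specimen
  tr <- ape::read.tree(text = truth$tree_newick)
  expect_setequal(tr$tip.label, ds$records$specimen_id)
})

test_that("class means are rank-ordered as configured and on the study scale", {
  cfg <- simulation_config(seed = 301)
  syn <- simulate_dataset(cfg)
  tax <- syn$dataset$records[, c("specimen_id", "species", "genus",
                                 "family", "order", "class")]
  s <- suppressWarnings(rank_summaries(pairwise_matrix(syn$dataset), tax))
  means <- setNames(s$mean, s$class)
  expect_true(means[["within_species"]] < means[["within_genus"]])
  expect_true(means[["within_genus"]] < means[["within_family"]])
  expect_true(means[["within_family"]] < means[["within_order"]])
  # intraspecific mean brackets the empirical ~0.2% scale
  expect_gt(means[["within_species"]], 0.05)
  expect_lt(means[["within_species"]], 0.6)
  # congeneric and confamilial means on the configured scale; only a few
  # deep ancestral branches are drawn, so realized means scatter around
  # the 13.5% / 19.7% targets by a couple of percentage points
  expect_gt(means[["within_genus"]], 10)
  expect_lt(means[["within_genus"]], 17)
  expect_gt(means[["within_family"]], 15)
  expect_lt(means[["within_family"]], 24)
})

test_that("K2P estimator recovery: simulated pairs are unbiased at kappa 2", {
  set.seed(424)
  for (d_true in c(0.002, 0.05, 0.15)) {
    est <- replicate(200, {
      pair <- simulate_divergent_pair(d_true, length = 652, kappa = 2)
      k2p(pair[1], pair[2])
    })
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - d_true), 3 * se + 1e-9)
  }
})

test_that("numt injection is idempotent and marks truth", {
  cfg <- simulation_config(seed = 12, n_families = 1, genera_per_family = 1,
                           species_per_genus = 2, specimens_per_species = 2,
                           seq_length = 120)
  syn <- simulate_dataset(cfg)
  once <- inject_numt(syn, "SP0002", seed = 3, type = "stop")
  twice <- inject_numt(once, "SP0002", seed = 3, type = "stop")
  expect_identical(once$dataset$records, twice$dataset$records)
  expect_equal(once$truth$numt_ids, "SP0002")
  scr <- screen_dataset(once$dataset, frame = 0)
  expect_equal(scr$specimen_id[scr$verdict == "suspect_numt"], "SP0002")
})

test_that("numt_rate plants recorded numts during simulation", {
  cfg <- simulation_config(seed = 77, n_families = 2, genera_per_family = 2,
                           species_per_genus = 2, specimens_per_species = 3,
                           seq_length = 150, numt_rate = 0.2)
  syn <- simulate_dataset(cfg)
  expect_gt(length(syn$truth$numt_ids), 0L)
  scr <- screen_dataset(syn$dataset)
  expect_setequal(scr$specimen_id[scr$verdict == "suspect_numt"],
                  syn$truth$numt_ids)
})

test_that("deep splits push a species over the 1% filter; zero is a no-op", {
  cfg <- simulation_config(seed = 21, n_families = 1, genera_per_family = 2,
                           species_per_genus = 2, specimens_per_species = 4,
                           seq_length = 652)
  syn <- simulate_dataset(cfg)
  same <- plant_deep_split(syn, "Species01_01_01", 0)
  expect_identical(same$dataset$records, syn$dataset$records)

  split <- plant_deep_split(syn, "Species01_01_01", 0.025, seed = 6)
  tax <- split$dataset$records[, c("specimen_id", "species", "genus",
                                   "family", "order", "class")]
  fl <- barcode_gap_flags(pairwise_matrix(split$dataset), tax)
  expect_true(fl$flagged[fl$species == "Species01_01_01"])
  expect_equal(split$truth$deep_splits$Species01_01_01$extra_divergence, 0.025)

  # a singleton species cannot be split
  tax1 <- tiny_taxonomy()[c(1, 3), ]
  seqs <- setNames(c(random_seq(60), random_seq(60)), tax1$specimen_id)
  ds1 <- build_dataset(seqs, tax1, marker = "COI")
  expect_error(plant_deep_split(ds1, "Aus_one", 0.02), "single specimen")
})
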