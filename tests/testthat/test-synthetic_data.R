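test_that("simulation is reproducible and degenerates correctly", {
  cfg <- synthetic_config(mols_per_species = c(3, 5), dim = 4, seed = 101)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$records, s2$dataset$records)
  expect_identical(unclass(s1$table), unclass(s2$table))
  s3 <- simulate_dataset(synthetic_config(mols_per_species = c(3, 5), dim = 4,
                                          seed = 102))
  expect_false(identical(unclass(s1$table), unclass(s3$table)))

  # all standard deviations zero: every point coincides, every d_IJ = 0
  s0 <- simulate_dataset(synthetic_config(
    n_classes = 1, families_per_class = 2, genera_per_family = 2,
    species_per_genus = 2, mols_per_species = c(3, 3), dim = 4,
    level_sd = c(class = 0, family = 0, genus = 0, species = 0),
    within_sd = 0, seed = 1))
  expect_true(all(unclass(s0$table) == 0))
  sps <- names(s0$dataset$species_index)
  d <- species_to_species_distance(species_cloud(s0$dataset, sps[1]),
                                   species_cloud(s0$dataset, sps[4]),
                                   s0$table, 50)
  expect_identical(d, 0)
  expect_error(synthetic_config(within_sd = -1))
})

test_that("lineages encode the generating tree and molecule IDs are unique", {
  sim <- simulate_dataset(synthetic_config(mols_per_species = c(2, 3),
                                           dim = 2, seed = 55))
  rec <- sim$dataset$records
  expect_false(anyDuplicated(rec$molecule_id) > 0)
  expect_true(all(rec$molecule_id %in% rownames(sim$table)))
  # taxonomic distance recomputed from lineages must equal the distance
  # read directly off the path-encoded species names (the generating tree)
  lt <- lineage_table(sim$dataset)
  name_dist <- function(a, b) {
    pa <- strsplit(a, ".", fixed = TRUE)[[1]]
    pb <- strsplit(b, ".", fixed = TRUE)[[1]]
    # components: class, family, genus, species
    if (!identical(pa[1], pb[1])) return(4L)
    if (!identical(pa[2], pb[2])) return(3L)
    if (!identical(pa[3], pb[3])) return(2L)
    if (!identical(pa[4], pb[4])) return(1L)
    0L
  }
  set.seed(9)
  for (i in 1:100) {
    pr <- sample(rownames(lt), 2)
    expect_identical(taxonomic_distance(lt[pr[1], ], lt[pr[2], ]),
                     name_dist(pr[1], pr[2]))
  }
})

test_that("between-species divergence follows the additive Gaussian model", {
  # law of total variance: for two species of the same genus the expected
  # squared molecular distance is dim * (2 sd_species^2 + 2 sd_within^2)
  cfg <- synthetic_config(n_classes = 2, families_per_class = 3,
                          genera_per_family = 5, species_per_genus = 6,
                          mols_per_species = c(10, 10), dim = 16, seed = 303)
  sim <- simulate_dataset(cfg)
  lt <- lineage_table(sim$dataset)
  sq <- c()
  for (g in unique(lt[, "genus"])) {
    sps <- rownames(lt)[lt[, "genus"] == g]
    for (i in seq_along(sps)) for (j in seq_len(i - 1)) {
      a <- sim$table[sim$dataset$species_index[[sps[i]]], , drop = FALSE]
      b <- sim$table[sim$dataset$species_index[[sps[j]]], , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      sq <- c(sq, mean(d2))
    }
  }
  expect_gte(length(sq) * 100, 2000)  # >= 2000 molecule pairs underlying
  expected <- 16 * (2 * 0.5^2 + 2 * 0.25^2)
  expect_equal(mean(sq), expected, tolerance = 0.05)
})

test_that("HGT injection copies blocks from distant donors", {
  sim <- simulate_dataset(synthetic_config(mols_per_species = c(5, 8),
                                           dim = 4, seed = 71))
  same <- inject_hgt(sim$dataset, sim$table, rate = 0, block = 2, seed = 1)
  expect_identical(same$dataset$records, sim$dataset$records)

  out <- inject_hgt(sim$dataset, sim$table, rate = 1, block = 1, seed = 2)
  n0 <- lengths(sim$dataset$species_index)
  n1 <- lengths(out$dataset$species_index)
  expect_true(all(n1[names(n0)] == n0 + 1L))
  expect_true(all(rownames(out$table) %in% c(rownames(sim$table),
                                             grep("^HGT", out$dataset$records$molecule_id,
                                                  value = TRUE))))
  # copied molecules have zero distance to their donor, so the recipient's
  # d_IJ with the donor as reference is non-increasing after injection
  aug <- inject_hgt(sim$dataset, sim$table, rate = 1, block = 3, seed = 5)
  log <- attr(aug$dataset, "hgt_log")
  expect_true(is.data.frame(log) && nrow(log) > 0)
  lt <- lineage_table(sim$dataset)
  for (i in which(!duplicated(log$recipient))[1:5]) {
    rec_sp <- log$recipient[i]
    don_sp <- log$donor[i]
    expect_gte(taxonomic_distance(lt[rec_sp, ], lt[don_sp, ]), 3L)
    d_before <- species_to_species_distance(species_cloud(sim$dataset, rec_sp),
                                            species_cloud(sim$dataset, don_sp),
                                            sim$table, 50)
    d_after <- species_to_species_distance(species_cloud(aug$dataset, rec_sp),
                                           species_cloud(aug$dataset, don_sp),
                                           aug$table, 50)
    expect_lte(d_after, d_before + 1e-12)
  }
  # determinism
  out2 <- inject_hgt(sim$dataset, sim$table, rate = 1, block = 1, seed = 2)
  expect_identical(out$dataset$records, out2$dataset$records)
})

test_that("ubiquitous metabolites self-match at zero and barely move the median", {
  sim <- simulate_dataset(synthetic_config(mols_per_species = c(10, 15),
                                           dim = 8, seed = 81))
  same <- inject_ubiquitous(sim$dataset, sim$table, count = 0, seed = 1)
  expect_identical(same$dataset$records, sim$dataset$records)

  out <- inject_ubiquitous(sim$dataset, sim$table, count = 1, seed = 1)
  n0 <- lengths(sim$dataset$species_index)
  n1 <- lengths(out$dataset$species_index)
  expect_true(all(n1[names(n0)] == n0 + 1L))
  # the shared molecule is in every cloud: d_nJ = 0 against any reference
  sps <- names(out$dataset$species_index)
  for (sp in sps[c(1, 20, 50)]) {
    expect_identical(
      molecule_to_species_distance("UBIQ0001",
                                   species_cloud(out$dataset, sp), out$table),
      0)
  }
  # shared-metabolite zeros inflate the low tail of {d_nJ}: a low percentile
  # (k = 10) is more sensitive to them than the median, which in turn moves
  # by at most one order-statistic gap
  shift_at <- function(kk) {
    clean <- pair_distances(sim$dataset, sim$table, min_current = 10,
                            min_reference = 10, k = kk)
    ubiq <- pair_distances(out$dataset, out$table, min_current = 10,
                           min_reference = 10, k = kk)
    stopifnot(identical(paste(clean$current, clean$reference),
                        paste(ubiq$current, ubiq$reference)))
    mean(abs(ubiq$distance - clean$distance))
  }
  expect_lt(shift_at(50), shift_at(10))
})

test_that("subsampling drops records binomially and reports emptied species", {
  sim <- simulate_dataset(synthetic_config(mols_per_species = c(20, 40),
                                           dim = 2, seed = 91))
  id <- subsample_records(sim$dataset, fraction = 0, seed = 1)
  expect_identical(id$records, sim$dataset$records)
  sub <- subsample_records(sim$dataset, fraction = 0.5, seed = 2)
  n <- nrow(sim$dataset$records)
  kept <- nrow(sub$records)
  expect_gte(kept, qbinom(0.005, n, 0.5))
  expect_lte(kept, qbinom(0.995, n, 0.5))
  sub2 <- subsample_records(sim$dataset, fraction = 0.5, seed = 2)
  expect_identical(sub$records, sub2$records)
  # near-total missingness usually empties species; those are reported
  sub3 <- subsample_records(sim$dataset, fraction = 0.95, seed = 3)
  expect_setequal(names(sub3$species_index),
                  setdiff(names(sim$dataset$species_index),
                          attr(sub3, "removed_species")))
})
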