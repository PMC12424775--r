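test_that("molecule-to-species distance is the nearest-neighbour distance", {
  fx <- make_toy_fixture()
  B <- species_cloud(fx$ds, "B")
  # shared molecule: self-match at zero
  expect_identical(molecule_to_species_distance("shared", B, fx$table), 0)
  # hand fixture: (0,0) against {(1,0), (0,2), (10,10)} -> 1
  expect_identical(molecule_to_species_distance("a1", B, fx$table), 1)
  # singleton reference equals the molecular distance
  solo <- structure(list(species = "B", molecule_ids = "b2"),
                    class = "species_cloud")
  expect_equal(molecule_to_species_distance("a1", solo, fx$table),
               molecular_distance(c(0, 0), c(0, 2)))
  expect_error(molecule_to_species_distance("nope", B, fx$table), "absent")
})

test_that("species distance is the percentile of d_nJ and is asymmetric", {
  fx <- make_toy_fixture()
  A <- species_cloud(fx$ds, "A")
  B <- species_cloud(fx$ds, "B")
  # A = {(0,0),(1,0)} vs B = {(1,0),(0,2),(10,10)}: d_nJ = {1, 0} -> median 0.5
  expect_equal(species_to_species_distance(A, B, fx$table), 0.5)
  # asymmetry: B includes an outlier far from A
  dBA <- species_to_species_distance(B, A, fx$table)
  expect_gt(dBA, species_to_species_distance(A, B, fx$table))

  # interpolated percentile on a constructed {1,2,3,4} set of d_nJ
  rec <- rbind(
    cbind(data.frame(molecule_id = paste0("c", 1:4), smiles = "CC"),
          toy_lineage_row("CUR")[rep(1, 4), ]),
    cbind(data.frame(molecule_id = "r1", smiles = "CC"), toy_lineage_row("REF")))
  mat <- rbind(c1 = c(1, 0), c2 = c(2, 0), c3 = c(3, 0), c4 = c(4, 0),
               r1 = c(0, 0))
  ds <- np_dataset(rec)
  tab <- embedding_table(mat, "toy")
  CUR <- species_cloud(ds, "CUR")
  REF <- species_cloud(ds, "REF")
  expect_equal(species_to_species_distance(CUR, REF, tab, k = 50), 2.5)
  expect_equal(species_to_species_distance(CUR, REF, tab, k = 25), 1.75)
  # subset current: every d_nJ = 0 at any k
  rec2 <- rbind(rec, cbind(data.frame(molecule_id = "c1", smiles = "CC"),
                           toy_lineage_row("SUB")))
  ds2 <- np_dataset(rec2)
  for (k in c(10, 50, 90)) {
    expect_identical(species_to_species_distance(species_cloud(ds2, "SUB"),
                                                 species_cloud(ds2, "CUR"),
                                                 tab, k = k), 0)
  }
})

test_that("d_IJ matches the brute-force oracle on random small instances", {
  set.seed(2024)
  for (i in 1:60) {
    nI <- sample(1:20, 1); nJ <- sample(1:20, 1); d <- sample(2:8, 1)
    cur <- matrix(rnorm(nI * d), nI)
    ref <- matrix(rnorm(nJ * d), nJ)
    rownames(cur) <- paste0("i", seq_len(nI))
    rownames(ref) <- paste0("j", seq_len(nJ))
    k <- runif(1, 1, 99)
    rec <- rbind(
      cbind(data.frame(molecule_id = rownames(cur), smiles = "CC"),
            toy_lineage_row("I")[rep(1, nI), ]),
      cbind(data.frame(molecule_id = rownames(ref), smiles = "CC"),
            toy_lineage_row("J")[rep(1, nJ), ]))
    ds <- np_dataset(rec)
    tab <- embedding_table(rbind(cur, ref), "toy")
    got <- species_to_species_distance(species_cloud(ds, "I"),
                                       species_cloud(ds, "J"), tab, k = k)
    expect_equal(got, brute_dIJ(cur, ref, k), tolerance = 1e-12)
  }
})

test_that("d_IJ is monotone in k and in reference growth, with d_II = 0", {
  set.seed(77)
  sim <- simulate_dataset(synthetic_config(n_classes = 1, families_per_class = 2,
                                           genera_per_family = 2,
                                           species_per_genus = 2,
                                           mols_per_species = c(6, 10),
                                           dim = 4, seed = 13))
  sps <- names(sim$dataset$species_index)
  for (i in 1:20) {
    pair <- sample(sps, 2)
    I <- species_cloud(sim$dataset, pair[1])
    J <- species_cloud(sim$dataset, pair[2])
    ks <- sort(runif(2, 1, 99))
    expect_lte(species_to_species_distance(I, J, sim$table, ks[1]),
               species_to_species_distance(I, J, sim$table, ks[2]) + 1e-12)
    # adding molecules to the reference never increases d_IJ
    J_shrunk <- structure(list(species = J$species,
                               molecule_ids = J$molecule_ids[1:3]),
                          class = "species_cloud")
    expect_lte(species_to_species_distance(I, J, sim$table, 50),
               species_to_species_distance(I, J_shrunk, sim$table, 50) + 1e-12)
    expect_identical(species_to_species_distance(I, I, sim$table, 50), 0)
  }
})

test_that("reference profiles honour thresholds and strata", {
  sim <- simulate_dataset(synthetic_config(mols_per_species = c(20, 40),
                                           dim = 8, seed = 3))
  ref <- names(sim$dataset$species_index)[1]
  prof <- reference_profile(ref, sim$dataset, sim$table, min_current = 15,
                            min_reference = 20, wanted = 1)
  expect_equal(nrow(prof), 3L)  # the three congeners
  expect_true(all(prof$tax_distance == 1L))
  expect_true(all(prof$reference == ref))
  # reference below threshold: empty profile, skip reported
  prof2 <- reference_profile(ref, sim$dataset, sim$table, min_current = 15,
                             min_reference = 1000)
  expect_equal(nrow(prof2), 0L)
  expect_identical(attr(prof2, "skipped_references"), ref)
  # min_current above every species size empties the profile
  prof3 <- reference_profile(ref, sim$dataset, sim$table, min_current = 1000,
                             min_reference = 20)
  expect_equal(nrow(prof3), 0L)
})

test_that("typical pairs are the nearest-to-mean nearest-neighbour pairs", {
  # three current molecules with d_nJ = 1, 2, 3: mean 2, typical pair is c2
  rec <- rbind(
    cbind(data.frame(molecule_id = paste0("c", 1:3), smiles = paste0("C", 1:3)),
          toy_lineage_row("CUR", genus = "G2")[rep(1, 3), ]),
    cbind(data.frame(molecule_id = paste0("r", 1:20),
                     smiles = paste0("R", 1:20)),
          toy_lineage_row("REF", genus = "G1")[rep(1, 20), ]))
  mat <- rbind(c(1, 0), c(2, 0), c(3, 0),
               matrix(c(rep(0, 20), seq(0, -19)), ncol = 2))
  rownames(mat) <- c(paste0("c", 1:3), paste0("r", 1:20))
  ds <- np_dataset(rec)
  tab <- embedding_table(mat, "toy")
  tp <- typical_pairs("REF", stratum = 2, ds, tab, min_current = 3,
                      min_reference = 20, top_r = 1)
  expect_equal(tp$molecule_id, "c2")
  expect_equal(tp$reference_molecule_id, "r1")
  expect_equal(tp$distance, 2)
  # top_r beyond the stratum returns all pairs sorted by |d - mean|
  tp_all <- typical_pairs("REF", stratum = 2, ds, tab, min_current = 3,
                          min_reference = 20, top_r = 10)
  expect_equal(tp_all$molecule_id, c("c2", "c1", "c3"))
  expect_equal(attr(tp_all, "stratum_mean"), 2)
  # empty stratum
  expect_equal(nrow(typical_pairs("REF", stratum = 3, ds, tab, min_current = 3,
                                  min_reference = 20)), 0L)
})

test_that("nearest NP per species matches an exhaustive scan", {
  fx <- make_toy_fixture()
  res <- nearest_np_per_species("a1", c("A", "B"), fx$ds, fx$table,
                                reference_species = "A")
  expect_equal(res$molecule_id[res$species == "A"], "a1")
  expect_equal(res$distance[res$species == "A"], 0)
  expect_equal(res$molecule_id[res$species == "B"], "shared")
  expect_equal(res$distance[res$species == "B"], 1)
  med <- attr(res, "stratum_medians")
  expect_equal(med$median_distance[med$tax_distance == 1], 1)
  # empty species set
  expect_equal(nrow(nearest_np_per_species("a1", character(0), fx$ds,
                                           fx$table)), 0L)
})
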