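# Synthetic occurrence + embedding generator.
#
# Chemical divergence is modeled as rank-level Brownian drift on a balanced
# taxonomy: each taxon's center is its parent's center plus an isotropic
# Gaussian step whose standard deviation is set per rank, and each molecule
# is its species' center plus within-species Gaussian dispersion. Taxonomic
# distance therefore controls the expected embedding divergence between
# species, which is exactly the structure the statistical analysis assumes.
# Confounders observed in real occurrence data can be layered on top:
# ubiquitous metabolites shared by all species, horizontal-transfer-like
# copying of molecules between distant species, and random missingness.

#' Configuration for the synthetic generator
#'
#' Defaults describe a desk-scale study: a single synthetic kingdom and
#' phylum over 2 classes x 3 families x 3 genera x 4 species (72 species),
#' 20-40 molecules per species in a 16-dimensional space, with drift
#' standard deviations per coordinate of 4.0 (class), 2.0 (family), 1.0
#' (genus), 0.5 (species) and within-species dispersion 0.25 -- so strata
#' 1, 2 and 3 are separated but overlapping, as in real chemotaxonomic data.
#'
#' @param n_classes,families_per_class,genera_per_family,species_per_genus
#'   balanced taxonomy shape.
#' @param mols_per_species inclusive integer range, molecules per species.
#' @param dim embedding dimension.
#' @param level_sd named numeric: per-coordinate drift sd for `class`,
#'   `family`, `genus`, `species`.
#' @param within_sd per-coordinate within-species dispersion.
#' @param hgt_rate probability each species receives a horizontal-transfer
#'   block; `hgt_block` molecules are copied from a donor at taxonomic
#'   distance >= 3.
#' @param hgt_block number of molecules copied per affected species.
#' @param ubiquitous_count molecules shared by every species.
#' @param missing_fraction per-record drop probability.
#' @param seed master seed; confounder stages draw from seed+1 (HGT),
#'   seed+2 (ubiquitous), seed+3 (missingness).
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_classes = 2, families_per_class = 3,
                             genera_per_family = 3, species_per_genus = 4,
                             mols_per_species = c(20, 40), dim = 16,
                             level_sd = c(class = 4.0, family = 2.0,
                                          genus = 1.0, species = 0.5),
                             within_sd = 0.25, hgt_rate = 0, hgt_block = 0,
                             ubiquitous_count = 0, missing_fraction = 0,
                             seed = 1) {
  cfg <- list(n_classes = n_classes, families_per_class = families_per_class,
              genera_per_family = genera_per_family,
              species_per_genus = species_per_genus,
              mols_per_species = mols_per_species, dim = dim,
              level_sd = level_sd, within_sd = within_sd, hgt_rate = hgt_rate,
              hgt_block = hgt_block, ubiquitous_count = ubiquitous_count,
              missing_fraction = missing_fraction, seed = seed)
  with(cfg, {
    stopifnot(n_classes >= 1, families_per_class >= 1, genera_per_family >= 1,
              species_per_genus >= 1, dim >= 1,
              length(mols_per_species) == 2L,
              mols_per_species[1] >= 1,
              mols_per_species[1] <= mols_per_species[2],
              all(c("class", "family", "genus", "species") %in% names(level_sd)),
              all(level_sd >= 0), within_sd >= 0,
              hgt_rate >= 0, hgt_rate <= 1, hgt_block >= 0,
              ubiquitous_count >= 0,
              missing_fraction >= 0, missing_fraction < 1)
  })
  structure(cfg, class = "synthetic_config")
}

# synthetic SMILES: simple unbranched carbon chains with varied length and
# terminal heteroatom; valid strings for exercising I/O and the featurizer
synth_smiles <- function(i) {
  len <- 2L + (i - 1L) %% 28L
  term <- c("C", "O", "N", "S")[((i - 1L) %/% 28L) %% 4L + 1L]
  paste0(strrep("C", len), term)
}

#' Simulate an occurrence dataset and its embedding table
#'
#' Builds the balanced taxonomy under one synthetic kingdom and phylum,
#' drifts taxon centers down the ranks, scatters molecules around species
#' centers, then applies any configured confounders (HGT copying, ubiquitous
#' metabolites, missingness). Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return List with `dataset` (an `np_dataset`), `table` (an
#'   `embedding_table`, encoder tag `"simulated"`), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  base <- with_seed(cfg$seed, {
    recs <- list()
    emb <- list()
    mol_counter <- 0L
    for (ci in seq_len(cfg$n_classes)) {
      class_name <- sprintf("C%02d", ci)
      class_center <- stats::rnorm(cfg$dim, 0, cfg$level_sd[["class"]])
      for (fi in seq_len(cfg$families_per_class)) {
        fam_name <- sprintf("%s.F%02d", class_name, fi)
        fam_center <- class_center + stats::rnorm(cfg$dim, 0, cfg$level_sd[["family"]])
        for (gi in seq_len(cfg$genera_per_family)) {
          gen_name <- sprintf("%s.G%02d", fam_name, gi)
          gen_center <- fam_center + stats::rnorm(cfg$dim, 0, cfg$level_sd[["genus"]])
          for (si in seq_len(cfg$species_per_genus)) {
            sp_name <- sprintf("%s.S%02d", gen_name, si)
            sp_center <- gen_center + stats::rnorm(cfg$dim, 0, cfg$level_sd[["species"]])
            n_mol <- if (cfg$mols_per_species[1] == cfg$mols_per_species[2]) {
              cfg$mols_per_species[1]
            } else {
              sample(seq(cfg$mols_per_species[1], cfg$mols_per_species[2]), 1L)
            }
            ids <- sprintf("M%06d", mol_counter + seq_len(n_mol))
            mol_counter <- mol_counter + n_mol
            pts <- matrix(stats::rnorm(n_mol * cfg$dim, 0, cfg$within_sd),
                          n_mol, cfg$dim, byrow = TRUE)
            pts <- sweep(pts, 2L, sp_center, "+")
            rownames(pts) <- ids
            emb[[sp_name]] <- pts
            recs[[sp_name]] <- data.frame(
              molecule_id = ids,
              smiles = vapply(mol_counter - n_mol + seq_len(n_mol),
                              synth_smiles, character(1)),
              species = sp_name, genus = gen_name, family = fam_name,
              class = class_name, phylum = "Synthophyta",
              kingdom = "Synthetica", stringsAsFactors = FALSE)
          }
        }
      }
    }
    list(records = do.call(rbind, recs), emb = do.call(rbind, emb))
  })
  ds <- np_dataset(base$records)
  table <- embedding_table(base$emb, encoder_name = "simulated")
  if (cfg$hgt_rate > 0 && cfg$hgt_block > 0) {
    out <- inject_hgt(ds, table, rate = cfg$hgt_rate, block = cfg$hgt_block,
                      seed = cfg$seed + 1L)
    ds <- out$dataset
    table <- out$table
  }
  if (cfg$ubiquitous_count > 0) {
    out <- inject_ubiquitous(ds, table, count = cfg$ubiquitous_count,
                             seed = cfg$seed + 2L)
    ds <- out$dataset
    table <- out$table
  }
  if (cfg$missing_fraction > 0) {
    ds <- subsample_records(ds, fraction = cfg$missing_fraction,
                            seed = cfg$seed + 3L)
  }
  list(dataset = ds, table = table, config = cfg)
}

#' Inject horizontal-transfer-like molecule copying
#'
#' Each species independently, with probability `rate`, receives copies of
#' `block` molecules sampled from a donor species at taxonomic distance >= 3.
#' Copied molecules get fresh IDs but identical embeddings, mimicking the
#' acquisition of a distant lineage's biosynthetic repertoire.
#'
#' @param ds an `np_dataset`.
#' @param table an `embedding_table` covering `ds`.
#' @param rate per-species probability in `[0, 1]`.
#' @param block molecules copied per affected species.
#' @param seed RNG seed for this stage.
#' @return List with the augmented `dataset` and `table`; the dataset
#'   carries attribute `"hgt_log"`, a data.frame of (recipient, donor,
#'   molecule_id, source_id) describing every copied molecule.
#' @export
inject_hgt <- function(ds, table, rate, block, seed = 1) {
  stopifnot(rate >= 0, rate <= 1, block >= 0)
  if (rate == 0 || block == 0) return(list(dataset = ds, table = table))
  lt <- lineage_table(ds)
  species <- rownames(lt)
  with_seed(seed, {
    new_recs <- list()
    new_emb <- list()
    log_rows <- list()
    counter <- 0L
    smiles_of <- smiles_lookup(ds)
    for (sp in species) {
      if (stats::runif(1) >= rate) next
      td <- taxdist_to_all(lt[sp, ], lt)
      donors <- species[td >= 3L]
      donors <- donors[lengths(ds$species_index[donors]) >= block]
      if (length(donors) == 0L) {
        stop("no donor species at taxonomic distance >= 3 with >= block molecules for ",
             sp, call. = FALSE)
      }
      donor <- donors[sample.int(length(donors), 1L)]
      pool <- ds$species_index[[donor]]
      picked <- pool[sample.int(length(pool), block)]
      new_ids <- sprintf("HGT%06d", counter + seq_along(picked))
      counter <- counter + length(picked)
      rec <- ds$records[ds$records$species == sp, ][1L, ]
      add <- rec[rep(1L, length(picked)), ]
      add$molecule_id <- new_ids
      add$smiles <- unname(smiles_of[picked])
      new_recs[[sp]] <- add
      m <- table[picked, , drop = FALSE]
      rownames(m) <- new_ids
      new_emb[[sp]] <- m
      log_rows[[sp]] <- data.frame(recipient = sp, donor = donor,
                                   molecule_id = new_ids, source_id = picked,
                                   stringsAsFactors = FALSE)
    }
    if (length(new_recs) == 0L) {
      list(dataset = ds, table = table)
    } else {
      ds2 <- np_dataset(rbind(ds$records, do.call(rbind, new_recs)))
      log <- do.call(rbind, log_rows)
      rownames(log) <- NULL
      attr(ds2, "hgt_log") <- log
      mat <- rbind(unclass_table(table), do.call(rbind, new_emb))
      list(dataset = ds2,
           table = embedding_table(mat, attr(table, "encoder_name")))
    }
  })
}

unclass_table <- function(table) {
  m <- table
  attr(m, "encoder_name") <- NULL
  class(m) <- NULL
  m
}

#' Inject ubiquitous metabolites
#'
#' Adds `count` molecules drawn near the global embedding centroid to every
#' species: one shared embedding per molecule, one occurrence record per
#' species. Such universally shared compounds contribute d_nJ = 0 to every
#' species pair, the tail the percentile aggregation is designed to discount.
#'
#' @inheritParams inject_hgt
#' @param count number of ubiquitous molecules (>= 0).
#' @param jitter_sd per-coordinate sd of the offset from the centroid.
#' @return List with the augmented `dataset` and `table`.
#' @export
inject_ubiquitous <- function(ds, table, count, seed = 1, jitter_sd = 0.1) {
  stopifnot(count >= 0)
  if (count == 0) return(list(dataset = ds, table = table))
  with_seed(seed, {
    centroid <- colMeans(unclass_table(table))
    ids <- sprintf("UBIQ%04d", seq_len(count))
    pts <- matrix(stats::rnorm(count * ncol(table), 0, jitter_sd),
                  count, ncol(table))
    pts <- sweep(pts, 2L, centroid, "+")
    rownames(pts) <- ids
    species_rows <- ds$records[!duplicated(ds$records$species), ]
    adds <- list()
    for (i in seq_len(nrow(species_rows))) {
      add <- species_rows[rep(i, count), ]
      add$molecule_id <- ids
      add$smiles <- paste0("O", strrep("C", seq_len(count)), "O")
      adds[[i]] <- add
    }
    ds2 <- np_dataset(rbind(ds$records, do.call(rbind, adds)))
    mat <- rbind(unclass_table(table), pts)
    list(dataset = ds2,
         table = embedding_table(mat, attr(table, "encoder_name")))
  })
}

#' Randomly drop occurrence records (simulated database incompleteness)
#'
#' @param ds an `np_dataset`.
#' @param fraction per-record drop probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return An `np_dataset`; species emptied entirely are removed and listed
#'   in attribute `"removed_species"`.
#' @export
subsample_records <- function(ds, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) {
    out <- ds
    attr(out, "removed_species") <- character(0)
    return(out)
  }
  with_seed(seed, {
    keep <- stats::runif(nrow(ds$records)) >= fraction
    kept <- ds$records[keep, , drop = FALSE]
    out <- np_dataset(kept)
    attr(out, "removed_species") <- setdiff(names(ds$species_index),
                                            names(out$species_index))
    out
  })
}
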