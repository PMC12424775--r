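# The asymmetric interspecies chemical distance.
#
# Three steps define the distance from a "current" species I to a
# "reference" species J:
#   1. d_nm  : Euclidean distance between two molecule embeddings;
#   2. d_nJ  : for molecule n of I, the minimum d_nm over molecules m of J
#              (min over the reference side, whose NP list is assumed the
#              more complete one);
#   3. d_IJ  : the k-th percentile of {d_nJ : n in I}; median by default.
# The percentile discounts both tails: unusually large d_nJ (missing NPs in
# the reference) and zeros from metabolites shared by both species. The
# definition is asymmetric in I and J by design and is never symmetrized.

#' Resolve a species' molecule cloud
#'
#' @param ds an `np_dataset`.
#' @param species species name.
#' @return List with `species` and its `molecule_ids` (record order).
#' @export
species_cloud <- function(ds, species) {
  stopifnot(inherits(ds, "np_dataset"))
  ids <- ds$species_index[[species]]
  if (is.null(ids) || length(ids) == 0L) {
    stop("species has no records in dataset: ", species, call. = FALSE)
  }
  structure(list(species = species, molecule_ids = ids), class = "species_cloud")
}

lookup_embeddings <- function(ids, table, context = "molecule") {
  missing <- setdiff(ids, rownames(table))
  if (length(missing)) {
    stop(sprintf("%s ID(s) absent from embedding table: %s%s", context,
                 paste(utils::head(missing, 10L), collapse = ", "),
                 if (length(missing) > 10L) ", ..." else ""), call. = FALSE)
  }
  # default `[` drops the embedding_table class; a plain matrix comes back
  table[ids, , drop = FALSE]
}

# Row-wise minimum Euclidean distance from each row of cur_mat to ref_mat.
# A molecule shared by both sides (same ID) has distance exactly 0; the
# quadratic-form evaluation would leave a rounding residue there.
min_cross_dist <- function(cur_mat, ref_mat) {
  d2 <- outer(rowSums(cur_mat^2), rowSums(ref_mat^2), "+") -
    2 * tcrossprod(cur_mat, ref_mat)
  d <- sqrt(pmax(do.call(pmin, as.data.frame(d2)), 0))
  d[rownames(cur_mat) %in% rownames(ref_mat)] <- 0
  d
}

# As above, also returning which reference molecule attains the minimum.
argmin_cross_dist <- function(cur_mat, ref_mat) {
  d2 <- outer(rowSums(cur_mat^2), rowSums(ref_mat^2), "+") -
    2 * tcrossprod(cur_mat, ref_mat)
  idx <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(d2)), idx)], 0))
  shared <- match(rownames(cur_mat), rownames(ref_mat))
  hit <- !is.na(shared)
  idx[hit] <- shared[hit]
  dist[hit] <- 0
  list(distance = dist, ref_index = idx)
}

#' Molecule-to-species distance d_nJ
#'
#' Minimum Euclidean distance from molecule `n` to any molecule of the
#' reference species J. If `n` itself belongs to J the distance is 0.
#'
#' @param n molecule ID present in `table`.
#' @param J a [species_cloud()].
#' @param table an `embedding_table`.
#' @return Non-negative distance.
#' @export
molecule_to_species_distance <- function(n, J, table) {
  stopifnot(inherits(J, "species_cloud"))
  x <- lookup_embeddings(n, table)
  ref <- lookup_embeddings(J$molecule_ids, table, "reference molecule")
  min_cross_dist(x, ref)[1L]
}

#' Species-to-species chemical distance d_IJ
#'
#' The k-th percentile (linear interpolation; see [percentile()]) of the
#' molecule-to-species distances d_nJ over all molecules n of the current
#' species I, with J as reference. Asymmetric: `d(I, J)` generally differs
#' from `d(J, I)`.
#'
#' @param I,J [species_cloud()]s for the current and reference species.
#' @param table an `embedding_table`.
#' @param k percentile level in (0, 100); default 50 (the median).
#' @return Non-negative distance.
#' @export
species_to_species_distance <- function(I, J, table, k = 50) {
  stopifnot(inherits(I, "species_cloud"), inherits(J, "species_cloud"))
  if (length(I$molecule_ids) == 0L) stop("current species cloud is empty", call. = FALSE)
  cur <- lookup_embeddings(I$molecule_ids, table, "current molecule")
  ref <- lookup_embeddings(J$molecule_ids, table, "reference molecule")
  percentile(min_cross_dist(cur, ref), k)
}

#' All interspecies distances for the eligible species pairs
#'
#' The workhorse behind the pooled and per-reference analyses: for every
#' reference species (>= `min_reference` distinct molecules, optionally
#' restricted to `references` and/or a clade) and every eligible current
#' species (>= `min_current` molecules, taxonomic distance in `wanted`,
#' also clade-restricted), computes d_IJ.
#'
#' @param ds an `np_dataset`.
#' @param table an `embedding_table` covering all molecules.
#' @param min_current,min_reference inclusion thresholds (defaults 15, 150).
#' @param k percentile level; default 50.
#' @param wanted strata (taxonomic distances) to keep; default 1:3.
#' @param references optional character vector restricting the reference set.
#' @param clade optional `list(rank=, taxon=)`; both current and reference
#'   species must carry that taxon at that rank.
#' @return data.frame with columns `current`, `reference`, `tax_distance`,
#'   `k`, `n_current`, `distance`; attribute `"skipped_references"` lists
#'   requested references below `min_reference`.
#' @export
pair_distances <- function(ds, table, min_current = 15, min_reference = 150,
                           k = 50, wanted = 1:3, references = NULL,
                           clade = NULL) {
  stopifnot(inherits(ds, "np_dataset"))
  lt <- lineage_table(ds)
  counts <- vapply(ds$species_index, function(m) length(unique(m)), integer(1))
  pool <- rownames(lt)
  if (!is.null(clade)) {
    stopifnot(is.list(clade), all(c("rank", "taxon") %in% names(clade)),
              clade$rank %in% TAX_RANKS)
    pool <- pool[lt[pool, clade$rank] == clade$taxon]
    if (length(pool) == 0L) {
      stop(sprintf("no species in clade %s '%s'", clade$rank, clade$taxon),
           call. = FALSE)
    }
  }
  refs <- pool[counts[pool] >= min_reference]
  skipped <- character(0)
  if (!is.null(references)) {
    skipped <- setdiff(intersect(references, pool), refs)
    refs <- intersect(references, refs)
  }
  currents_all <- pool[counts[pool] >= min_current]

  out <- vector("list", length(refs))
  for (i in seq_along(refs)) {
    J <- refs[i]
    cand <- setdiff(currents_all, J)
    if (length(cand) == 0L) next
    td <- taxdist_to_all(lt[J, ], lt[cand, , drop = FALSE])
    sel <- td %in% wanted
    cand <- cand[sel]
    td <- td[sel]
    if (length(cand) == 0L) next
    ref_mat <- lookup_embeddings(ds$species_index[[J]], table, "reference molecule")
    cur_ids <- unlist(ds$species_index[cand], use.names = FALSE)
    cur_species <- rep(cand, lengths(ds$species_index[cand]))
    cur_mat <- lookup_embeddings(cur_ids, table, "current molecule")
    dnJ <- min_cross_dist(cur_mat, ref_mat)
    dIJ <- vapply(split(dnJ, factor(cur_species, levels = cand)),
                  percentile, numeric(1), k = k)
    out[[i]] <- data.frame(current = cand, reference = J,
                           tax_distance = td, k = k,
                           n_current = unname(counts[cand]),
                           distance = unname(dIJ),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(current = character(0), reference = character(0),
                      tax_distance = integer(0), k = numeric(0),
                      n_current = integer(0), distance = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "skipped_references") <- skipped
  res
}

#' Distance profile of a single reference species
#'
#' One row per eligible current species, with the reference fixed as J.
#' A reference below `min_reference` yields an empty profile whose
#' `"skipped_references"` attribute names it.
#'
#' @inheritParams pair_distances
#' @param reference the reference species name.
#' @return data.frame as in [pair_distances()].
#' @export
reference_profile <- function(reference, ds, table, min_current = 15,
                              min_reference = 150, k = 50, wanted = 1:3,
                              clade = NULL) {
  pair_distances(ds, table, min_current = min_current,
                 min_reference = min_reference, k = k, wanted = wanted,
                 references = reference, clade = clade)
}

#' Typical molecule pairs in a stratum
#'
#' Over all molecules n of all eligible current species at taxonomic distance
#' `stratum` from the reference, pairs each with its nearest reference
#' molecule (the argmin of d_nJ) and returns the `top_r` pairs whose d_nJ is
#' closest to the stratum-wide mean of d_nJ -- the "typical" chemistry at
#' that evolutionary remove. Ties are broken by molecule ID order.
#'
#' @inheritParams pair_distances
#' @param reference the reference species.
#' @param stratum taxonomic distance of the current species.
#' @param top_r number of pairs to return.
#' @return data.frame with columns `current_species`, `molecule_id`,
#'   `smiles`, `reference_molecule_id`, `reference_smiles`, `distance`,
#'   sorted by closeness to the stratum mean.
#' @export
typical_pairs <- function(reference, stratum, ds, table, min_current = 15,
                          min_reference = 150, top_r = 3, clade = NULL) {
  lt <- lineage_table(ds)
  counts <- vapply(ds$species_index, function(m) length(unique(m)), integer(1))
  if (!reference %in% rownames(lt)) {
    stop("reference species not present in dataset: ", reference, call. = FALSE)
  }
  empty <- data.frame(current_species = character(0), molecule_id = character(0),
                      smiles = character(0), reference_molecule_id = character(0),
                      reference_smiles = character(0), distance = numeric(0))
  if (counts[reference] < min_reference) return(empty)
  cand <- setdiff(names(counts)[counts >= min_current], reference)
  if (!is.null(clade)) cand <- cand[lt[cand, clade$rank] == clade$taxon]
  if (length(cand)) {
    td <- taxdist_to_all(lt[reference, ], lt[cand, , drop = FALSE])
    cand <- cand[td == stratum]
  }
  if (length(cand) == 0L) return(empty)
  ref_ids <- ds$species_index[[reference]]
  ref_mat <- lookup_embeddings(ref_ids, table, "reference molecule")
  cur_ids <- unlist(ds$species_index[cand], use.names = FALSE)
  cur_species <- rep(cand, lengths(ds$species_index[cand]))
  cur_mat <- lookup_embeddings(cur_ids, table, "current molecule")
  am <- argmin_cross_dist(cur_mat, ref_mat)
  smiles_of <- smiles_lookup(ds)
  pairs <- data.frame(current_species = cur_species,
                      molecule_id = cur_ids,
                      smiles = unname(smiles_of[cur_ids]),
                      reference_molecule_id = ref_ids[am$ref_index],
                      reference_smiles = unname(smiles_of[ref_ids[am$ref_index]]),
                      distance = am$distance,
                      stringsAsFactors = FALSE)
  mu <- mean(pairs$distance)
  ord <- order(abs(pairs$distance - mu), pairs$molecule_id)
  pairs <- pairs[ord[seq_len(min(top_r, nrow(pairs)))], , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "stratum_mean") <- mu
  pairs
}

smiles_lookup <- function(ds) {
  rec <- ds$records[!duplicated(ds$records$molecule_id), ]
  stats::setNames(rec$smiles, rec$molecule_id)
}

#' Nearest natural product per species to a focal molecule
#'
#' For a focal molecule n, finds in each species the molecule nearest to n in
#' chemical space, with its distance. When `reference_species` is supplied,
#' each match is annotated with that species' taxonomic distance to the
#' reference, and per-stratum medians of the match distances are attached as
#' attribute `"stratum_medians"`.
#'
#' @param n focal molecule ID present in `table`.
#' @param species_set character vector of species to scan.
#' @param ds an `np_dataset`.
#' @param table an `embedding_table`.
#' @param reference_species optional species name anchoring taxonomic strata.
#' @return data.frame with columns `species`, `molecule_id`, `distance` (and
#'   `tax_distance` when anchored); species with no embedded molecules are
#'   omitted and listed in attribute `"omitted_species"`.
#' @export
nearest_np_per_species <- function(n, species_set, ds, table,
                                   reference_species = NULL) {
  x <- lookup_embeddings(n, table)
  rows <- list()
  omitted <- character(0)
  for (sp in species_set) {
    ids <- ds$species_index[[sp]]
    ids <- ids[ids %in% rownames(table)]
    if (is.null(ids) || length(ids) == 0L) {
      omitted <- c(omitted, sp)
      next
    }
    m <- table[ids, , drop = FALSE]
    am <- argmin_cross_dist(x, m)
    rows[[sp]] <- data.frame(species = sp, molecule_id = ids[am$ref_index[1L]],
                             distance = am$distance[1L], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(species = character(0), molecule_id = character(0),
               distance = numeric(0))
  }
  rownames(out) <- NULL
  if (!is.null(reference_species) && nrow(out) > 0L) {
    lt <- lineage_table(ds)
    out$tax_distance <- taxdist_to_all(lt[reference_species, ],
                                       lt[out$species, , drop = FALSE])
    med <- tapply(out$distance, out$tax_distance, stats::median)
    attr(out, "stratum_medians") <- data.frame(
      tax_distance = as.integer(names(med)),
      median_distance = as.numeric(med))
  }
  attr(out, "omitted_species") <- omitted
  out
}
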