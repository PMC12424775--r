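# Lineages and integer taxonomic distance.
#
# Taxonomic distance is the proxy for evolutionary distance throughout the
# package: 0 for a species against itself, 1 for two species of the same
# genus, 2 for two genera of the same family, 3 for two families of the same
# class, and so on up the six-rank ladder.

#' Ordered taxonomic ranks used by the package
#'
#' Fixed six-rank ladder, lowest first.
#' @export
TAX_RANKS <- c("species", "genus", "family", "class", "phylum", "kingdom")

#' Construct a lineage
#'
#' A lineage is a named character vector over the six ranks in
#' [TAX_RANKS]. All taxon names must be non-empty.
#'
#' @param species,genus,family,class,phylum,kingdom taxon names.
#' @return Named character vector of length 6, class `"lineage"`.
#' @export
#' @examples
#' lineage("Tripterygium wilfordii", "Tripterygium", "Celastraceae",
#'         "Magnoliopsida", "Tracheophyta", "Plantae")
lineage <- function(species, genus, family, class, phylum, kingdom) {
  x <- c(species = species, genus = genus, family = family,
         class = class, phylum = phylum, kingdom = kingdom)
  if (!all(vapply(x, function(v) is.character(v) && length(v) == 1L, logical(1))) ||
      anyNA(x) || any(!nzchar(x))) {
    stop("all six lineage ranks must be non-empty strings", call. = FALSE)
  }
  structure(x, class = "lineage")
}

as_lineage <- function(x) {
  if (inherits(x, "lineage")) return(x)
  if (is.character(x) && all(TAX_RANKS %in% names(x))) {
    return(do.call(lineage, as.list(unclass(x[TAX_RANKS]))))
  }
  stop("cannot interpret object as a lineage; expected named ranks ",
       paste(TAX_RANKS, collapse = ", "), call. = FALSE)
}

#' Integer taxonomic distance between two lineages
#'
#' Returns the 0-based index of the lowest rank at which the two lineages
#' agree, requiring all higher ranks to agree as well (so taxonomic homonyms
#' -- the same genus name reused in different families -- are not conflated).
#' Two identical lineages give 0, congeneric species 1, confamilial genera 2,
#' and lineages sharing no rank (different kingdoms) give 6.
#'
#' @param a,b lineages (see [lineage()]).
#' @return Integer in 0..6; symmetric in its arguments.
#' @export
taxonomic_distance <- function(a, b) {
  a <- as_lineage(a)
  b <- as_lineage(b)
  agree <- unclass(a) == unclass(b)
  # ok[r]: ranks r..kingdom all agree
  ok <- rev(cumprod(rev(agree))) == 1
  if (!any(ok)) return(length(TAX_RANKS))
  unname(which(ok)[1L]) - 1L
}

# Vectorised taxonomic distance from one lineage to every row of a
# species-by-rank character matrix (columns ordered as TAX_RANKS).
taxdist_to_all <- function(ref_lineage, rank_mat) {
  ref <- unclass(as_lineage(ref_lineage))
  agree <- sweep_eq(rank_mat, ref)
  nr <- ncol(agree)
  suffix <- agree
  if (nr > 1L) {
    for (r in (nr - 1L):1L) suffix[, r] <- agree[, r] & suffix[, r + 1L]
  }
  as.integer(nr - rowSums(suffix))
}

sweep_eq <- function(mat, vec) {
  out <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (j in seq_len(ncol(mat))) out[, j] <- mat[, j] == vec[[j]]
  out
}

#' One lineage per species in a dataset
#'
#' @param ds an `np_dataset`.
#' @return Character matrix, one row per species (rownames are species
#'   names), columns the six ranks; taken from each species' first record.
#' @export
lineage_table <- function(ds) {
  stopifnot(inherits(ds, "np_dataset"))
  rec <- ds$records
  first <- !duplicated(rec$species)
  m <- as.matrix(rec[first, TAX_RANKS, drop = FALSE])
  rownames(m) <- rec$species[first]
  m
}

#' Stratify candidate species by taxonomic distance to a reference
#'
#' @param reference species name present in `ds`.
#' @param candidates character vector of species names to assign.
#' @param ds an `np_dataset` supplying lineages.
#' @param wanted integer strata to keep (subset of 1..6).
#' @return Named list mapping each wanted stratum (as character) to the
#'   species names at that taxonomic distance; the reference itself is never
#'   included.
#' @export
stratify <- function(reference, candidates, ds, wanted = 1:3) {
  lt <- lineage_table(ds)
  if (!reference %in% rownames(lt)) {
    stop("reference species not present in dataset: ", reference, call. = FALSE)
  }
  stopifnot(all(wanted %in% 1:6))
  candidates <- setdiff(intersect(candidates, rownames(lt)), reference)
  out <- stats::setNames(vector("list", length(wanted)), as.character(wanted))
  for (w in as.character(wanted)) out[[w]] <- character(0)
  if (length(candidates) == 0L || length(wanted) == 0L) return(out)
  d <- taxdist_to_all(lt[reference, ], lt[candidates, , drop = FALSE])
  for (i in seq_along(candidates)) {
    w <- as.character(d[i])
    if (w %in% names(out)) out[[w]] <- c(out[[w]], candidates[i])
  }
  out
}
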