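# Reading and writing Lotus-style occurrence tables.
#
# The unit of input is one (molecule, species) observation carrying a SMILES
# string and a full six-rank lineage. A dataset keeps the deduplicated record
# table plus a species -> molecule-id index.

#' Column-name schema for occurrence tables
#'
#' Maps the fields the package needs onto the column names of a particular
#' file. With `molecule_id = NULL` (the default), a `molecule_id` column is
#' used if the file has one; otherwise molecules are keyed on their SMILES
#' string, optionally canonicalized -- Lotus keys on structures, so that is
#' the natural fallback when no explicit ID column exists. The `class` column may
#' be remapped freely (some exports avoid that reserved word).
#'
#' @param molecule_id column holding an explicit molecule ID, or `NULL`.
#' @param smiles,species,genus,family,class,phylum,kingdom column names.
#' @return A named list of class `"occurrence_schema"`.
#' @export
occurrence_schema <- function(molecule_id = NULL, smiles = "smiles",
                              species = "species", genus = "genus",
                              family = "family", class = "class",
                              phylum = "phylum", kingdom = "kingdom") {
  structure(list(molecule_id = molecule_id, smiles = smiles, species = species,
                 genus = genus, family = family, class = class,
                 phylum = phylum, kingdom = kingdom),
            class = "occurrence_schema")
}

#' Construct an occurrence dataset from a record table
#'
#' @param records data.frame with columns `molecule_id`, `smiles` and the six
#'   ranks in [TAX_RANKS]. Duplicate (molecule_id, species) pairs are dropped,
#'   first occurrence wins.
#' @return An `np_dataset`: list with `records` (the deduplicated table) and
#'   `species_index` (species name -> character vector of molecule ids).
#' @export
np_dataset <- function(records) {
  needed <- c("molecule_id", "smiles", TAX_RANKS)
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("record table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)[, needed]
  for (col in needed) records[[col]] <- as.character(records[[col]])
  dup <- duplicated(records[, c("molecule_id", "species")])
  records <- records[!dup, , drop = FALSE]
  rownames(records) <- NULL
  ds <- structure(list(records = records,
                       species_index = split(records$molecule_id, records$species)),
                  class = "np_dataset")
  attr(ds, "n_duplicates_dropped") <- sum(dup)
  ds
}

#' @export
print.np_dataset <- function(x, ...) {
  cat("<np_dataset>", nrow(x$records), "occurrence records,",
      length(x$species_index), "species\n")
  invisible(x)
}

#' Read a Lotus-style occurrence table
#'
#' Delimiter follows the file extension (`.csv` comma, otherwise tab); text is
#' read as UTF-8. Rows with any empty mapped field are dropped and counted.
#' Duplicate (molecule, species) pairs are collapsed, first occurrence wins.
#' The load report (rows read / dropped / deduplicated, molecule-ID policy) is
#' attached as attribute `"load_report"` and can be written with
#' [write_load_report()].
#'
#' @param path CSV/TSV file.
#' @param schema an [occurrence_schema()].
#' @param canonicalize if `TRUE` and the ChemmineOB toolkit is installed,
#'   molecule IDs derived from SMILES are canonical SMILES; otherwise the
#'   verbatim string is used (the policy actually applied is in the load
#'   report).
#' @return An `np_dataset`.
#' @export
read_occurrences <- function(path, schema = occurrence_schema(),
                             canonicalize = FALSE) {
  if (!file.exists(path)) stop("occurrence file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                           quote = "\"", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", comment.char = "")
  mapped <- unlist(schema[!vapply(schema, is.null, logical(1))])
  absent <- setdiff(unname(mapped), names(raw))
  if (length(absent)) {
    stop("occurrence table is missing mapped column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n_read <- nrow(raw)
  if (n_read == 0L) {
    empty <- data.frame(molecule_id = character(0), smiles = character(0))
    for (r in TAX_RANKS) empty[[r]] <- character(0)
    ds <- np_dataset(empty)
    attr(ds, "load_report") <- list(rows_read = 0L, rows_dropped = 0L,
                                    duplicates_dropped = 0L,
                                    molecule_id_policy = "n/a")
    return(ds)
  }
  keep_complete <- rep(TRUE, n_read)
  for (col in unname(mapped)) {
    v <- raw[[col]]
    keep_complete <- keep_complete & !is.na(v) & nzchar(trimws(v))
  }
  raw <- raw[keep_complete, , drop = FALSE]

  smiles <- raw[[schema$smiles]]
  if (is.null(schema$molecule_id) && "molecule_id" %in% names(raw)) {
    schema$molecule_id <- "molecule_id"  # auto-detect an explicit ID column
  }
  if (!is.null(schema$molecule_id)) {
    mol_id <- raw[[schema$molecule_id]]
    policy <- paste0("explicit column '", schema$molecule_id, "'")
  } else if (canonicalize && requireNamespace("ChemmineOB", quietly = TRUE)) {
    mol_id <- vapply(smiles, canonical_smiles, character(1), USE.NAMES = FALSE)
    policy <- "canonical SMILES (ChemmineOB)"
  } else {
    mol_id <- smiles
    policy <- "verbatim SMILES"
  }
  rec <- data.frame(molecule_id = mol_id, smiles = smiles,
                    stringsAsFactors = FALSE)
  for (r in TAX_RANKS) rec[[r]] <- raw[[schema[[r]]]]
  ds <- np_dataset(rec)
  attr(ds, "load_report") <- list(
    rows_read = n_read,
    rows_dropped = n_read - sum(keep_complete),
    duplicates_dropped = attr(ds, "n_duplicates_dropped"),
    molecule_id_policy = policy)
  ds
}

canonical_smiles <- function(s) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = s),
                  error = function(e) s)
  out <- strsplit(trimws(out), "[\t ]")[[1]][1]
  if (is.na(out) || !nzchar(out)) s else out
}

#' Collapse duplicate (molecule, species) records
#'
#' First occurrence wins; the same molecule observed in two species is two
#' distinct records.
#'
#' @param ds an `np_dataset`.
#' @return An `np_dataset` with one record per (molecule_id, species) pair.
#' @export
deduplicate <- function(ds) {
  stopifnot(inherits(ds, "np_dataset"))
  np_dataset(ds$records)
}

#' Species passing a minimum natural-product count
#'
#' Species with few reported NPs are excluded from the statistical analyses;
#' the shipped defaults are 15 distinct molecules to act as a current species
#' and 150 to act as a reference species.
#'
#' @param ds an `np_dataset`.
#' @param min_nps minimum number of distinct molecules (>= 1).
#' @return Character vector of qualifying species names, sorted.
#' @export
eligible_species <- function(ds, min_nps) {
  stopifnot(inherits(ds, "np_dataset"), min_nps >= 1)
  counts <- vapply(ds$species_index, function(m) length(unique(m)), integer(1))
  sort(names(counts)[counts >= min_nps])
}

#' Write a result table as TSV
#'
#' @param rows data.frame of results.
#' @param path output file; tab-separated with header.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a result table written by [write_table()]
#'
#' @param path TSV file.
#' @return data.frame with types inferred (numbers as numeric).
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop("result table not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    comment.char = "")
}

#' Write the JSON load report of a dataset
#'
#' @param ds an `np_dataset` produced by [read_occurrences()].
#' @param path output JSON file.
#' @export
write_load_report <- function(ds, path) {
  rep <- attr(ds, "load_report")
  if (is.null(rep)) stop("dataset carries no load report", call. = FALSE)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
}
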