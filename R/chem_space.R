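# The chemical space: embeddings, encoder contract, molecular distance.
#
# Any function SMILES -> fixed-dimension numeric vector can serve as an
# encoder, and externally computed embedding matrices (from deep molecular
# encoders) can be loaded from delimited text. The built-in hashed n-gram
# encoder is a deterministic featurizer -- deliberately not a stand-in for
# any learned model's chemistry -- so the whole pipeline runs offline.

#' Construct an embedding table
#'
#' @param mat numeric matrix, one row per molecule; rownames are molecule IDs.
#' @param encoder_name tag recorded in outputs and manifests.
#' @return Numeric matrix of class `"embedding_table"` with attribute
#'   `encoder_name`.
#' @export
embedding_table <- function(mat, encoder_name = "external") {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (nrow(mat) > 0L &&
      (is.null(rownames(mat)) || anyNA(rownames(mat)) || any(!nzchar(rownames(mat))))) {
    stop("embedding table requires molecule IDs as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate molecule IDs in embedding table", call. = FALSE)
  }
  if (ncol(mat) > 0L && nrow(mat) > 0L && !all(is.finite(mat))) {
    stop("embeddings must be finite", call. = FALSE)
  }
  structure(mat, class = c("embedding_table", class(mat)),
            encoder_name = encoder_name)
}

# FNV-1a hash, 32-bit variant: offset basis 2166136261, prime 16777619.
# Arithmetic is done in doubles with a split multiply so every intermediate
# stays exactly representable; identical results on any platform.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    h <- (h %% 65536) * 16777619 + (((h %/% 65536) * 16777619) %% 65536) * 65536
    h <- h %% 4294967296
  }
  h
}

#' Deterministic hashed n-gram SMILES featurizer
#'
#' Counts character n-grams (n = 1..`max_n`) of the SMILES string, hashes
#' each `"<n>:<gram>"` token with 32-bit FNV-1a into `dim` buckets
#' (bucket = hash mod dim), and scales the count vector to unit Euclidean
#' norm. Identical input gives identical output across runs and platforms.
#' This is a structural fingerprint for exercising the pipeline, not a model
#' of chemistry; learned embeddings enter through [load_embeddings()].
#'
#' @param smiles non-empty SMILES string.
#' @param dim number of buckets (>= 8); default 256.
#' @param max_n largest n-gram length, 1..6; default 3.
#' @return Numeric vector of length `dim` with unit norm.
#' @export
encode_hashed_ngrams <- function(smiles, dim = 256, max_n = 3) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("smiles must be a single non-empty string", call. = FALSE)
  }
  stopifnot(dim >= 8, max_n >= 1, max_n <= 6)
  len <- nchar(smiles)
  v <- numeric(dim)
  for (n in seq_len(min(max_n, len))) {
    starts <- seq_len(len - n + 1L)
    grams <- substring(smiles, starts, starts + n - 1L)
    for (g in grams) {
      bucket <- fnv1a32(paste0(n, ":", g)) %% dim + 1
      v[bucket] <- v[bucket] + 1
    }
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Encode every molecule of a dataset with the built-in featurizer
#'
#' @param ds an `np_dataset`.
#' @inheritParams encode_hashed_ngrams
#' @return An `embedding_table` covering all distinct molecule IDs, encoded
#'   from each molecule's first recorded SMILES.
#' @export
encode_dataset <- function(ds, dim = 256, max_n = 3) {
  stopifnot(inherits(ds, "np_dataset"))
  rec <- ds$records[!duplicated(ds$records$molecule_id), , drop = FALSE]
  mat <- t(vapply(rec$smiles, encode_hashed_ngrams, numeric(dim),
                  dim = dim, max_n = max_n, USE.NAMES = FALSE))
  if (nrow(rec) == 0L) mat <- matrix(numeric(0), 0L, dim)
  rownames(mat) <- rec$molecule_id
  embedding_table(mat, encoder_name = sprintf("hashed_ngrams(dim=%d,max_n=%d)",
                                              as.integer(dim), as.integer(max_n)))
}

#' Load an embedding matrix from delimited text
#'
#' Expected format: header `molecule_id<sep>e1<sep>...<sep>eD`, one row per
#' molecule; separator by extension (`.csv` comma, otherwise tab). Ragged
#' rows, non-numeric cells and duplicate IDs are format errors reported with
#' their row number.
#'
#' @param path embedding matrix file.
#' @return An `embedding_table`.
#' @export
load_embeddings <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path, call. = FALSE)
  sep <- delim_for(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("embedding file is empty: ", path, call. = FALSE)
  cells <- strsplit(lines, sep, fixed = TRUE)
  width <- length(cells[[1L]])
  if (width < 1L) stop("embedding file has an empty header", call. = FALSE)
  d <- width - 1L
  n <- length(lines) - 1L
  mat <- matrix(NA_real_, n, d)
  ids <- character(n)
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != width) {
      stop(sprintf("embedding file row %d has %d fields, expected %d",
                   i + 1L, length(row), width), call. = FALSE)
    }
    ids[i] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals)) {
      stop(sprintf("non-numeric embedding value in file row %d", i + 1L),
           call. = FALSE)
    }
    mat[i, ] <- vals
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate molecule ID in file row %d",
                 which(duplicated(ids))[1L] + 1L), call. = FALSE)
  }
  rownames(mat) <- ids
  embedding_table(mat, encoder_name = paste0("external:", basename(path)))
}

#' Save an embedding table (write counterpart of [load_embeddings()])
#'
#' @param table an `embedding_table`.
#' @param path output file; delimiter by extension.
#' @export
save_embeddings <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  sep <- delim_for(path)
  d <- ncol(table)
  header <- paste(c("molecule_id", paste0("e", seq_len(d))), collapse = sep)
  body <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i],
            format(table[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = sep)
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
}

#' Euclidean distance between two molecular embeddings
#'
#' @param x,y numeric vectors of equal dimension.
#' @return Non-negative distance; zero iff the vectors are equal.
#' @export
molecular_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("embedding dimension mismatch: %d vs %d",
                 length(x), length(y)), call. = FALSE)
  }
  sqrt(sum((as.numeric(x) - as.numeric(y))^2))
}
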