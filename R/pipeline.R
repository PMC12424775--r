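# End-to-end orchestration: read -> embed -> interspecies distances ->
# pooled and per-reference Welch tests -> optional sweep, with TSV outputs
# and a JSON reproducibility manifest.

#' Build a run configuration
#'
#' Defaults follow the shipped analysis settings: percentile k = 50 (the
#' median), inclusion thresholds of 15 molecules for a current species and
#' 150 for a reference species, strata pairs (1,2), (2,3), (1,3), and a
#' significance threshold of 0.01. `min_reference = 150` suits
#' database-scale inputs; synthetic fixtures typically lower it.
#'
#' @param occurrences path to an occurrence table (or supply `dataset`).
#' @param embeddings path to an embedding matrix (or supply `table`);
#'   ignored unless `encoder = "external"`.
#' @param dataset,table in-memory `np_dataset` / `embedding_table`
#'   alternatives to the file inputs.
#' @param encoder `"hashed_ngrams"` (built-in featurizer) or `"external"`.
#' @param dim,max_n built-in encoder settings.
#' @param min_current,min_reference inclusion thresholds.
#' @param percentile level k defining d_IJ.
#' @param strata_pairs list of integer pairs compared in the pooled tests.
#' @param wanted strata for which distances are computed.
#' @param clades named list of clade filters (`NULL` = all species).
#' @param alpha significance threshold for fractions.
#' @param sweep optional grid for [param_sweep()], e.g.
#'   `list(min_current = c(10, 15, 20, 25, 30))`.
#' @param seed seed recorded in the manifest (the analysis itself is
#'   deterministic given its inputs).
#' @param output_dir directory for result tables and the manifest.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(occurrences = NULL, embeddings = NULL, dataset = NULL,
                       table = NULL, encoder = c("hashed_ngrams", "external"),
                       dim = 256, max_n = 3, min_current = 15,
                       min_reference = 150, percentile = 50,
                       strata_pairs = list(c(1, 2), c(2, 3), c(1, 3)),
                       wanted = 1:3, clades = list(All = NULL), alpha = 0.01,
                       sweep = NULL, seed = 1, output_dir = tempfile("ctd_run_")) {
  encoder <- match.arg(encoder)
  stopifnot(percentile > 0, percentile < 100, min_current >= 1,
            min_reference >= 1, alpha > 0, alpha < 1)
  structure(list(occurrences = occurrences, embeddings = embeddings,
                 dataset = dataset, table = table, encoder = encoder,
                 dim = dim, max_n = max_n, min_current = min_current,
                 min_reference = min_reference, percentile = percentile,
                 strata_pairs = strata_pairs, wanted = wanted,
                 clades = clades, alpha = alpha, sweep = sweep, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

#' Execute a full analysis run
#'
#' Stages: ingest occurrences; build or load the embedding table; verify
#' embedding coverage; compute all eligible interspecies distances; pooled
#' stratum comparisons per clade; per-reference p-values for the widest
#' strata pair; optional hyperparameter sweep. Writes
#' `species_pair_distances.tsv`, `stratum_comparisons.tsv`,
#' `per_reference_pvalues.tsv` (+ `omitted_references.tsv`), optionally
#' `sweep.tsv`, and `manifest.json` under `config$output_dir`.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `status` (`"ok"` or
#'   `"insufficient_data"`), the result tables, and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  ds <- config$dataset
  if (is.null(ds)) {
    if (is.null(config$occurrences)) {
      stop("run_config supplies neither 'dataset' nor 'occurrences'", call. = FALSE)
    }
    ds <- read_occurrences(config$occurrences)
  }
  say(sprintf("ingest: %d records, %d species", nrow(ds$records),
              length(ds$species_index)))

  table <- config$table
  if (is.null(table)) {
    table <- if (config$encoder == "external") {
      if (is.null(config$embeddings)) {
        stop("encoder 'external' requires an embedding file", call. = FALSE)
      }
      load_embeddings(config$embeddings)
    } else {
      encode_dataset(ds, dim = config$dim, max_n = config$max_n)
    }
  }
  lookup_embeddings(unique(ds$records$molecule_id), table)  # coverage check

  manifest <- list(
    package = "chemotaxdist",
    version = as.character(utils::packageVersion("chemotaxdist")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    encoder = attr(table, "encoder_name"),
    parameters = config[c("min_current", "min_reference", "percentile",
                          "wanted", "alpha", "seed")],
    strata_pairs = config$strata_pairs,
    clades = lapply(config$clades, function(cl) cl %||% "All"),
    n_records = nrow(ds$records),
    n_species = length(ds$species_index),
    note = paste("Pooled tests weight every computed interspecies distance",
                 "equally; distances sharing a reference species are not",
                 "independent."))

  refs <- eligible_species(ds, config$min_reference)
  if (length(refs) == 0L) {
    manifest$outcome <- "insufficient data: no species reaches min_reference"
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("no eligible reference species; wrote manifest only")
    return(invisible(list(status = "insufficient_data", manifest = manifest)))
  }
  if (length(refs) < 3L) {
    say(sprintf("notice: only %d reference species survive min_reference = %d",
                length(refs), config$min_reference))
  }

  say(sprintf("distances: %d reference species, percentile k = %g",
              length(refs), config$percentile))
  pd <- pair_distances(ds, table, min_current = config$min_current,
                       min_reference = config$min_reference,
                       k = config$percentile, wanted = config$wanted)
  write_table(pd, file.path(config$output_dir, "species_pair_distances.tsv"))

  comp_rows <- list()
  for (cl in names(config$clades)) {
    for (pairing in config$strata_pairs) {
      cmp <- tryCatch(
        compare_strata(pd, pairing[1], pairing[2],
                       clade = config$clades[[cl]], ds = ds),
        error = function(e) e)
      if (inherits(cmp, "error")) {
        say(sprintf("stratum comparison skipped [%s %d vs %d]: %s", cl,
                    pairing[1], pairing[2], conditionMessage(cmp)))
        next
      }
      w <- cmp$result
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        clade = cl, stratum_a = pairing[1], stratum_b = pairing[2],
        t = w$t, edof = w$edof, p = w$p, n_a = w$n_a, n_b = w$n_b,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(clade = character(0), stratum_a = integer(0),
               stratum_b = integer(0), t = numeric(0), edof = numeric(0),
               p = numeric(0), n_a = integer(0), n_b = integer(0))
  write_table(comparisons, file.path(config$output_dir, "stratum_comparisons.tsv"))

  widest <- config$strata_pairs[[which.max(vapply(config$strata_pairs,
                                                  function(p) p[2] - p[1],
                                                  numeric(1)))]]
  pr <- per_reference_pvalues(ds, table, strata_pair = widest,
                              min_current = config$min_current,
                              min_reference = config$min_reference,
                              k = config$percentile, distances = pd)
  per_ref <- if (length(pr$results)) {
    data.frame(reference = names(pr$results),
               t = vapply(pr$results, `[[`, numeric(1), "t"),
               edof = vapply(pr$results, `[[`, numeric(1), "edof"),
               p = vapply(pr$results, `[[`, numeric(1), "p"),
               log10_p = log10(vapply(pr$results, `[[`, numeric(1), "p")),
               n_a = vapply(pr$results, `[[`, numeric(1), "n_a"),
               n_b = vapply(pr$results, `[[`, numeric(1), "n_b"),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(reference = character(0), t = numeric(0), edof = numeric(0),
               p = numeric(0), log10_p = numeric(0), n_a = integer(0),
               n_b = integer(0))
  }
  write_table(per_ref, file.path(config$output_dir, "per_reference_pvalues.tsv"))
  write_table(pr$omitted, file.path(config$output_dir, "omitted_references.tsv"))
  dist_summary <- pvalue_distribution(pr$results, alpha = config$alpha)
  manifest$per_reference <- list(
    strata_pair = widest, n_tested = dist_summary$n,
    n_omitted = nrow(pr$omitted),
    fraction_significant = dist_summary$fraction_significant)

  sweep_tab <- NULL
  if (!is.null(config$sweep)) {
    say("sweep: ", paste(names(config$sweep), collapse = ", "))
    sweep_tab <- param_sweep(ds, table, grid = config$sweep,
                             strata_pair = widest,
                             min_current = config$min_current,
                             min_reference = config$min_reference,
                             k = config$percentile, clades = config$clades,
                             alpha = config$alpha)
    write_table(sweep_tab, file.path(config$output_dir, "sweep.tsv"))
  }

  manifest$outcome <- "ok"
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", config$output_dir)
  invisible(list(status = "ok", distances = pd, comparisons = comparisons,
                 per_reference = per_ref, omitted = pr$omitted,
                 sweep = sweep_tab, manifest = manifest))
}

#' Built-in oracle self-check
#'
#' Re-derives core quantities with independent brute-force code and reports
#' pass/fail per check: the percentile interpolation dialect, the Welch test
#' against R's own `t.test`, metric axioms of the molecular distance, and
#' the self-distance identity d_II = 0. Failures are reported, not thrown.
#'
#' @param percentile_fun override of the percentile routine (testing hook
#'   for fault injection); default uses the package's [percentile()].
#' @return data.frame with columns `check`, `pass`, `detail`.
#' @export
selfcheck <- function(percentile_fun = NULL) {
  pf <- percentile_fun %||% percentile
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = name, pass = pass,
                                                 detail = detail,
                                                 stringsAsFactors = FALSE)
  }

  # percentile dialect vs explicit order-statistic interpolation
  ok <- TRUE
  with_seed(421L, {
    for (i in 1:25) {
      x <- stats::rnorm(sample(2:15, 1))
      kk <- stats::runif(1, 1, 99)
      s <- sort(x)
      h <- 1 + (length(x) - 1) * kk / 100
      lo <- floor(h)
      expect <- s[lo] + (h - lo) * (s[min(lo + 1, length(x))] - s[lo])
      if (abs(pf(x, kk) - expect) > 1e-12) ok <- FALSE
    }
    if (abs(pf(c(1, 2, 3, 4), 50) - 2.5) > 1e-12) ok <- FALSE
  })
  add("percentile_interpolation", ok,
      "linear interpolation h = 1 + (n-1)k/100; k=50 averages central pair")

  # Welch test vs stats::t.test
  ok <- TRUE
  with_seed(422L, {
    for (i in 1:25) {
      a <- stats::rnorm(sample(3:20, 1), sd = stats::runif(1, 0.5, 2))
      b <- stats::rnorm(sample(3:20, 1), mean = stats::runif(1, -1, 1))
      w <- welch_one_tailed(a, b)
      r <- stats::t.test(a, b, alternative = "less", var.equal = FALSE)
      if (abs(w$t - unname(r$statistic)) > 1e-10 ||
          abs(w$edof - unname(r$parameter)) > 1e-10 ||
          abs(w$p - r$p.value) > 1e-10) ok <- FALSE
    }
  })
  add("welch_vs_t_test", ok, "t, e.d.o.f. and one-tailed p agree to 1e-10")

  # metric axioms of the molecular distance
  ok <- TRUE
  with_seed(423L, {
    for (i in 1:50) {
      x <- stats::rnorm(8); y <- stats::rnorm(8); z <- stats::rnorm(8)
      dxy <- molecular_distance(x, y)
      if (abs(dxy - molecular_distance(y, x)) > 1e-12) ok <- FALSE
      if (dxy > molecular_distance(x, z) + molecular_distance(z, y) + 1e-12) ok <- FALSE
      if (molecular_distance(x, x) != 0) ok <- FALSE
    }
  })
  add("molecular_distance_metric", ok, "symmetry, triangle inequality, identity")

  # self-distance d_II = 0 at several percentile levels
  sim <- simulate_dataset(synthetic_config(n_classes = 1, families_per_class = 1,
                                           genera_per_family = 2,
                                           species_per_genus = 2,
                                           mols_per_species = c(5, 8),
                                           dim = 4, seed = 7))
  ok <- TRUE
  for (sp in names(sim$dataset$species_index)) {
    cl <- species_cloud(sim$dataset, sp)
    for (kk in c(25, 50, 75)) {
      if (species_to_species_distance(cl, cl, sim$table, k = kk) != 0) ok <- FALSE
    }
  }
  add("self_distance_zero", ok, "d_II = 0 at k in {25, 50, 75}")

  do.call(rbind, checks)
}
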