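# Statistical layer: one-tailed Welch tests across taxonomic-distance strata,
# per-reference-species p-value distributions, and hyperparameter sweeps.
#
# The hypothesis is directional -- chemical distances increase with taxonomic
# distance -- so all tests are one-tailed with the "near" stratum expected to
# have the smaller mean. Raw p-values are reported throughout; no
# multiple-testing correction is applied, and the per-reference significance
# fraction uses raw p < 0.01.

#' One-tailed Welch two-sample test
#'
#' Computes the Welch t statistic with unpooled variances,
#' \deqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b},}
#' the Welch-Satterthwaite effective degrees of freedom
#' \deqn{\nu = (s_a^2/n_a + s_b^2/n_b)^2 /
#'       [ (s_a^2/n_a)^2/(n_a-1) + (s_b^2/n_b)^2/(n_b-1) ],}
#' and the lower-tail p-value: the probability, under the null of equal
#' means, of a t at least as extreme in the direction
#' mean(`group_near`) < mean(`group_far`).
#'
#' @param group_near distances at the smaller taxonomic distance (>= 2 values).
#' @param group_far distances at the larger taxonomic distance (>= 2 values).
#' @return A `welch_result`: list with `t`, `edof`, `p`, `n_a`, `n_b`.
#' @export
welch_one_tailed <- function(group_near, group_far) {
  a <- as.numeric(group_near)
  b <- as.numeric(group_far)
  if (length(a) < 2L || length(b) < 2L) {
    stop(sprintf("insufficient data for Welch test: group sizes %d and %d (need >= 2 each)",
                 length(a), length(b)), call. = FALSE)
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    stop("degenerate data: both groups have zero variance", call. = FALSE)
  }
  na <- length(a)
  nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  edof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  structure(list(t = t, edof = edof, p = stats::pt(t, df = edof),
                 n_a = na, n_b = nb),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch one-tailed test: t = %.4g, e.d.o.f. = %.4g, p = %.4g (n = %d vs %d)\n",
              x$t, x$edof, x$p, x$n_a, x$n_b))
  invisible(x)
}

filter_clade_rows <- function(distances, clade, ds) {
  if (is.null(clade)) return(distances)
  if (is.null(ds)) stop("clade filtering requires the dataset (ds)", call. = FALSE)
  lt <- lineage_table(ds)
  in_clade <- rownames(lt)[lt[, clade$rank] == clade$taxon]
  if (length(in_clade) == 0L) {
    stop(sprintf("insufficient data: no species in clade %s '%s'",
                 clade$rank, clade$taxon), call. = FALSE)
  }
  distances[distances$current %in% in_clade & distances$reference %in% in_clade, ,
            drop = FALSE]
}

#' Pooled stratum comparison
#'
#' Pools every interspecies distance d_IJ across all reference species
#' (within an optional clade) into a stratum-`a` and a stratum-`b` sample --
#' each computed distance weighted equally -- and applies the one-tailed
#' Welch test of near < far.
#'
#' @param distances data.frame from [pair_distances()].
#' @param a,b taxonomic-distance strata to compare, `a < b`.
#' @param clade optional `list(rank=, taxon=)` restricting both current and
#'   reference species; requires `ds`.
#' @param ds dataset used for clade lookups.
#' @return A `stratum_comparison`: list with `clade` label, `a`, `b`, and
#'   the `welch_result` in `$result`.
#' @export
compare_strata <- function(distances, a, b, clade = NULL, ds = NULL) {
  stopifnot(a < b)
  distances <- filter_clade_rows(distances, clade, ds)
  xa <- distances$distance[distances$tax_distance == a]
  xb <- distances$distance[distances$tax_distance == b]
  if (length(xa) < 2L) {
    stop(sprintf("insufficient data in stratum %d (%d distances)", a, length(xa)),
         call. = FALSE)
  }
  if (length(xb) < 2L) {
    stop(sprintf("insufficient data in stratum %d (%d distances)", b, length(xb)),
         call. = FALSE)
  }
  structure(list(clade = if (is.null(clade)) "All" else
                   paste(clade$rank, clade$taxon),
                 a = a, b = b, result = welch_one_tailed(xa, xb)),
            class = "stratum_comparison")
}

#' @export
print.stratum_comparison <- function(x, ...) {
  cat(sprintf("[%s] taxonomic distances %d vs %d: ", x$clade, x$a, x$b))
  print(x$result)
  invisible(x)
}

#' Per-reference-species Welch tests
#'
#' For each reference species, its own d_IJ values at the two strata feed a
#' one-tailed Welch test. References with fewer than two distances in either
#' stratum are omitted and reported.
#'
#' @inheritParams pair_distances
#' @param strata_pair integer pair `c(a, b)`, `a < b`.
#' @param distances optional precomputed [pair_distances()] table covering
#'   `strata_pair` (saves recomputation in sweeps).
#' @return List with `results` (named list of `welch_result` keyed by
#'   reference species) and `omitted` (data.frame of reference, reason).
#' @export
per_reference_pvalues <- function(ds, table, references = NULL,
                                  strata_pair = c(1, 3), min_current = 15,
                                  min_reference = 150, k = 50, clade = NULL,
                                  distances = NULL) {
  stopifnot(length(strata_pair) == 2L, strata_pair[1] < strata_pair[2])
  if (is.null(distances)) {
    distances <- pair_distances(ds, table, min_current = min_current,
                                min_reference = min_reference, k = k,
                                wanted = strata_pair, references = references,
                                clade = clade)
  } else {
    distances <- filter_clade_rows(distances, clade, ds)
    if (!is.null(references)) {
      distances <- distances[distances$reference %in% references, , drop = FALSE]
    }
  }
  refs <- unique(distances$reference)
  results <- list()
  omitted <- data.frame(reference = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (J in refs) {
    sub <- distances[distances$reference == J, ]
    xa <- sub$distance[sub$tax_distance == strata_pair[1]]
    xb <- sub$distance[sub$tax_distance == strata_pair[2]]
    if (length(xa) < 2L || length(xb) < 2L) {
      omitted <- rbind(omitted, data.frame(
        reference = J,
        reason = sprintf("stratum %d has %d eligible species (need >= 2)",
                         if (length(xa) < 2L) strata_pair[1] else strata_pair[2],
                         min(length(xa), length(xb))),
        stringsAsFactors = FALSE))
      next
    }
    results[[J]] <- tryCatch(welch_one_tailed(xa, xb), error = function(e) NULL)
    if (is.null(results[[J]])) {
      omitted <- rbind(omitted, data.frame(reference = J,
                                           reason = "degenerate distances",
                                           stringsAsFactors = FALSE))
    }
  }
  skipped <- attr(distances, "skipped_references")
  if (length(skipped)) {
    omitted <- rbind(omitted, data.frame(
      reference = skipped,
      reason = sprintf("below min_reference = %d", min_reference),
      stringsAsFactors = FALSE))
  }
  list(results = results, omitted = omitted)
}

#' Distribution summary of per-reference p-values
#'
#' @param pvals named list of `welch_result`s (as from
#'   [per_reference_pvalues()]`$results`) or a numeric vector of p-values.
#' @param alpha significance threshold for the fraction; default 0.01.
#' @return List with `log10_p` (ascending), `fraction_significant` (share of
#'   p < alpha; `NA` when no p-values are available), `alpha`, `n`.
#' @export
pvalue_distribution <- function(pvals, alpha = 0.01) {
  p <- if (is.list(pvals)) vapply(pvals, function(w) w$p, numeric(1)) else
    as.numeric(pvals)
  if (length(p) == 0L) {
    return(list(log10_p = numeric(0), fraction_significant = NA_real_,
                alpha = alpha, n = 0L))
  }
  stopifnot(all(p > 0 & p < 1))
  list(log10_p = sort(log10(p)),
       fraction_significant = mean(p < alpha),
       alpha = alpha, n = length(p))
}

#' Hyperparameter sweep of the significance fraction
#'
#' Recomputes the per-reference analysis over a grid of values of
#' `min_current` (the threshold size) or `percentile` (the level k defining
#' d_IJ), per clade, and reports the fraction of retained reference species
#' with p < `alpha`. Distances are recomputed whenever the percentile
#' changes.
#'
#' @inheritParams per_reference_pvalues
#' @param grid named list; names in `c("min_current", "percentile")`, values
#'   numeric vectors.
#' @param clades named list of clade filters (`NULL` entry = all species);
#'   default `list(All = NULL)`.
#' @param alpha significance threshold; default 0.01.
#' @return data.frame with columns `parameter`, `value`, `clade`,
#'   `fraction_significant`, `n_references`.
#' @export
param_sweep <- function(ds, table, grid, strata_pair = c(1, 3),
                        min_current = 15, min_reference = 150, k = 50,
                        clades = list(All = NULL), alpha = 0.01) {
  stopifnot(is.list(grid), length(grid) >= 1L,
            all(names(grid) %in% c("min_current", "percentile")))
  cells <- list()
  for (par in names(grid)) {
    for (val in grid[[par]]) {
      mc <- if (par == "min_current") val else min_current
      kk <- if (par == "percentile") val else k
      for (cl in names(clades)) {
        pr <- per_reference_pvalues(ds, table, strata_pair = strata_pair,
                                    min_current = mc, min_reference = min_reference,
                                    k = kk, clade = clades[[cl]])
        dist <- pvalue_distribution(pr$results, alpha = alpha)
        cells[[length(cells) + 1L]] <- data.frame(
          parameter = par, value = val, clade = cl,
          fraction_significant = dist$fraction_significant,
          n_references = dist$n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}
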