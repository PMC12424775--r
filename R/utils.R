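# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Percentile with linear interpolation between order statistics
#'
#' The dialect is fixed package-wide: index h = 1 + (n - 1) k / 100 into the
#' sorted sample, linear interpolation between the flanking order statistics
#' (R's `quantile()` type 7). At k = 50 an even-sized sample yields the mean
#' of the two central values, so the default species distance is the median.
#'
#' @param x numeric sample.
#' @param k percentile level, 0 < k < 100.
#' @return The interpolated k-th percentile of `x`.
#' @export
#' @examples
#' percentile(c(1, 2, 3, 4), 50) # 2.5
percentile <- function(x, k) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k >= 100) {
    stop("percentile level k must lie strictly between 0 and 100", call. = FALSE)
  }
  stats::quantile(x, probs = k / 100, type = 7, names = FALSE)
}

# delimiter from file extension: .csv -> comma, anything else -> tab
delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
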