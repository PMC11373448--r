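# Precision/recall benchmarking against a golden set.
#
# With C the variant set of a compare-set file (or pooled group) and G the
# golden set, correct calls are the exact-match intersection C n G and
#
#   precision = |C n G| / |C|        recall = |C n G| / |G|

#' Precision and recall of one call set against the golden set
#'
#' A variant counts as correct iff its (chrom, pos, ref, alt) key has an
#' exact match in the golden set. Both sets must be non-empty; a division by
#' zero is never silently returned.
#'
#' @param c a `CallSet` or `VariantGroup` (its pooled set is used).
#' @param g a `GoldenSet` (or any variant collection).
#' @return A `BenchmarkResult`: list with `name`, `precision`, `recall`,
#'   `n_correct`, `n_called`, `n_golden`.
#' @export
precision_recall <- function(c, g) {
  name <- if (inherits(c, "VariantGroup")) c$label
          else if (inherits(c, "CallSet")) c$name else "call set"
  ck <- as_key_set(c)
  gk <- as_key_set(g)
  if (length(ck) == 0)
    stop(sprintf("precision is undefined: compare set '%s' is empty", name))
  if (length(gk) == 0)
    stop("recall is undefined: the golden set is empty")
  n_correct <- length(intersect(ck, gk))
  structure(list(name = name,
                 precision = n_correct / length(ck),
                 recall = n_correct / length(gk),
                 n_correct = n_correct,
                 n_called = length(ck),
                 n_golden = length(gk)),
            class = "BenchmarkResult")
}

#' @export
print.BenchmarkResult <- function(x, ...) {
  cat(sprintf("<BenchmarkResult> %s: precision %.4f (%d/%d), recall %.4f (%d/%d)\n",
              x$name, x$precision, x$n_correct, x$n_called,
              x$recall, x$n_correct, x$n_golden))
  invisible(x)
}

#' Benchmark many call sets or groups against the golden set
#'
#' @param items list of `CallSet`s and/or `VariantGroup`s.
#' @param g a `GoldenSet`.
#' @return A list of `BenchmarkResult`s in input order.
#' @export
benchmark_many <- function(items, g) {
  lapply(items, precision_recall, g = g)
}

#' Benchmark results as a data.frame
#'
#' Raw counts are carried alongside the ratios so the CSV output is
#' self-auditing.
#'
#' @param results list of `BenchmarkResult`s.
#' @return A data.frame with one row per result.
#' @export
benchmark_table <- function(results) {
  data.frame(name = vapply(results, `[[`, "", "name"),
             precision = vapply(results, `[[`, 0, "precision"),
             recall = vapply(results, `[[`, 0, "recall"),
             n_correct = vapply(results, `[[`, 0L, "n_correct"),
             n_called = vapply(results, `[[`, 0L, "n_called"),
             n_golden = vapply(results, `[[`, 0L, "n_golden"),
             stringsAsFactors = FALSE)
}
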