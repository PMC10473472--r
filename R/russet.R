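#' Ordinal russet severity score from russeted-area fraction
#'
#' The 0-4 per-fruit scoring scheme: score 0 for 0% of the surface
#' russeted, 1 for (0, 10]%, 2 for (10, 25]%, 3 for (25, 50]%, 4 for
#' (50, 100]%. The printed integer bin boundaries are extended to
#' continuous fractions as half-open intervals, so any nonzero russet
#' yields a nonzero score and every fraction in `[0, 100]` maps to exactly
#' one score.
#'
#' @param fraction_pct Russeted surface fraction(s), percent, in `[0, 100]`.
#' @return Integer score(s) 0-4.
#' @export
russet_score <- function(fraction_pct) {
  if (any(!is.finite(fraction_pct)) ||
      any(fraction_pct < 0) || any(fraction_pct > 100))
    stop("`fraction_pct` must lie in [0, 100]")
  as.integer(cut(fraction_pct, breaks = c(-Inf, 0, 10, 25, 50, 100),
                 labels = FALSE, right = TRUE)) - 1L
}

#' Summarize russet severity over a fruit population
#'
#' Arithmetic mean of the ordinal scores with standard error, plus the
#' score histogram over 0-4 — the "mean score +/- SE" presentation used in
#' cultivar and growing-site comparisons.
#'
#' @param records Data frame with a `score` column (integer 0-4), or with
#'   `russet_fraction_pct` from which scores are derived.
#' @return List with `n`, `mean_score`, `se_score` (0 when n = 1),
#'   and `histogram` (named integer vector over scores "0".."4").
#' @export
severity_summary <- function(records) {
  if (NROW(records) == 0L) stop("`records` must contain at least one fruit")
  score <- if (!is.null(records$score)) records$score
           else if (!is.null(records$russet_fraction_pct))
             russet_score(records$russet_fraction_pct)
           else stop("`records` needs a `score` or `russet_fraction_pct` column")
  if (any(!score %in% 0:4)) stop("scores must be integers in 0..4")
  n <- length(score)
  list(
    n = n,
    mean_score = mean(score),
    se_score = if (n >= 2) stats::sd(score) / sqrt(n) else 0,
    histogram = table(factor(score, levels = 0:4)))
}
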