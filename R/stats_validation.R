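#' Chi-squared test of ramp counts against proportional expectation
#'
#' Goodness-of-fit test for whether ramp-bearing genes are distributed
#' across bins (e.g. expression-level bins) in proportion to the number of
#' sequences per bin. Expected counts are the overall ramp proportion times
#' each bin total; the statistic is the usual sum of (O - E)^2 / E with
#' bins - 1 degrees of freedom, and standardized residuals
#' (O - E) / sqrt(E) show which bins drive the departure.
#'
#' @param observed Integer vector of observed ramp counts per bin.
#' @param total Integer vector of total sequences per bin (all > 0).
#' @param labels Optional bin labels.
#' @return An object of class `ramp_chisq`: list with `table` (label,
#'   observed, total, expected, std_residual), `chi2`, `df`, `p_value`.
#' @export
#' @examples
#' r <- chisq_proportional(c(10, 30), c(100, 100))
#' r$chi2
chisq_proportional <- function(observed, total, labels = NULL) {
  stopifnot(length(observed) == length(total), length(observed) >= 2L,
            all(total > 0), all(observed >= 0), all(observed <= total))
  if (is.null(labels)) labels <- paste0("bin", seq_along(observed))
  expected <- sum(observed) / sum(total) * total
  if (any(expected == 0))
    stop("expected count of zero; cannot form the chi-squared statistic",
         call. = FALSE)
  resid <- (observed - expected) / sqrt(expected)
  chi2 <- sum(resid^2)
  df <- length(observed) - 1L
  structure(list(table = data.frame(label = labels, observed = observed,
                                    total = total, expected = expected,
                                    std_residual = resid,
                                    stringsAsFactors = FALSE),
                 chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE)),
            class = "ramp_chisq")
}

#' @export
print.ramp_chisq <- function(x, ...) {
  tab <- x$table
  tab$expected <- signif(tab$expected, 10)
  tab$std_residual <- round(tab$std_residual, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("\nChi-squared = %.4g, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Mark-and-recapture overlap significance of two gene sets
#'
#' Tests whether the overlap between two detected gene sets (e.g. ramps
#' found with measured tAI values versus with computed relative
#' adaptiveness) exceeds chance, using the hypergeometric upper tail: with
#' `set_a` marked genes in a universe of `universe`, and `set_b` genes
#' recaptured, the p-value is P(X > shared) -- the strictly-greater tail,
#' matching the `phyper(..., lower.tail = FALSE)` convention. Note the
#' off-by-one: P(X > x), not P(X >= x), which matters for extreme tails.
#' The tail is evaluated in log space, so the log10 p-value remains
#' meaningful when the linear value underflows.
#'
#' @param shared Number of genes detected by both methods.
#' @param set_a,set_b Sizes of the two detected sets.
#' @param universe Total number of genes tested.
#' @return List with `p_value` and `log10_p`.
#' @export
#' @examples
#' hypergeometric_overlap(shared = 2, set_a = 5, set_b = 5, universe = 10)
hypergeometric_overlap <- function(shared, set_a, set_b, universe) {
  stopifnot(shared >= 0, set_a >= 0, set_b >= 0,
            shared <= min(set_a, set_b),
            set_a <= universe, set_b <= universe,
            shared >= set_a + set_b - universe)
  log_p <- phyper(shared, set_a, universe - set_a, set_b,
                  lower.tail = FALSE, log.p = TRUE)
  list(p_value = exp(log_p), log10_p = log_p / log(10))
}
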