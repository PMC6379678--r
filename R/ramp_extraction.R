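MIDDLES <- c("hmean", "gmean", "mean", "median")

#' Middle value of a set of efficiencies
#'
#' The "middle" summarizing a window or a whole gene: harmonic mean
#' (default; most sensitive to slow codons), geometric mean, arithmetic
#' mean, or median.
#'
#' @param x Numeric vector of strictly positive values.
#' @param middle One of `"hmean"`, `"gmean"`, `"mean"`, `"median"`.
#' @return A single number.
#' @export
middle_value <- function(x, middle = MIDDLES) {
  middle <- match.arg(middle)
  switch(middle,
         hmean = length(x) / sum(1 / x),
         gmean = exp(mean(log(x))),
         mean = mean(x),
         median = median(x))
}

rolling_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1L):(length(x) + 1L)] - cs[1L:(length(x) - w + 1L)]
}

#' Smooth an efficiency profile with a ribosome-footprint window
#'
#' Slides a window of `window` codons (default 9, the span of one ribosome
#' footprint) along the profile in steps of one codon and summarizes each
#' window with the chosen middle function. Only full windows are emitted,
#' so a profile of length L yields L - window + 1 values; a profile shorter
#' than the window yields an empty vector (the caller treats such genes as
#' having no callable ramp).
#'
#' @param values Numeric profile (strictly positive), as from
#'   [gene_profile()].
#' @param window Window length in codons (>= 1).
#' @param middle Middle function, see [middle_value()].
#' @return Numeric vector of window middles.
#' @export
#' @examples
#' smooth_profile(c(1, 0.5, 0.25), window = 3, middle = "hmean")  # 3/7
smooth_profile <- function(values, window = 9L, middle = MIDDLES) {
  middle <- match.arg(middle)
  window <- as.integer(window)
  stopifnot(window >= 1L)
  if (any(values <= 0))
    stop("efficiency profile must be strictly positive", call. = FALSE)
  L <- length(values)
  if (L < window) return(numeric(0))
  switch(middle,
         hmean = window / rolling_sum(1 / values, window),
         gmean = exp(rolling_sum(log(values), window) / window),
         mean = rolling_sum(values, window) / window,
         median = vapply(seq_len(L - window + 1L), function(k)
           median(values[k:(k + window - 1L)]), numeric(1)))
}

#' Locate the translational bottleneck in a smoothed profile
#'
#' The bottleneck is the sliding window with the minimum smoothed
#' efficiency. The primary bottleneck is the 5'-most window attaining the
#' minimum; all tied minima are also returned, since every tie contributes
#' to the outlier-region counts across the gene set. Ties are detected up
#' to a small relative tolerance to absorb floating-point noise from the
#' cumulative-sum smoother.
#'
#' @param smoothed Non-empty numeric vector of window middles.
#' @param tol Relative tie tolerance.
#' @return List with `primary` (1-based window index) and `ties` (integer
#'   vector of all tied window indices).
#' @export
#' @examples
#' find_bottleneck(c(0.2, 0.9, 0.2))$ties
find_bottleneck <- function(smoothed, tol = 1e-9) {
  if (length(smoothed) == 0L)
    stop("cannot locate a bottleneck in an empty profile", call. = FALSE)
  m <- min(smoothed)
  ties <- which(smoothed - m <= tol * max(1, abs(m)))
  list(primary = ties[1L], ties = ties)
}

#' Map a window position to a percent bin of the gene
#'
#' Divides the gene's window positions into 100 equal parts and reports
#' which part (1..100) a window start falls in:
#' `floor(100 * (window - 1) / num_windows) + 1`, clamped to 100.
#'
#' @param window 1-based window index.
#' @param num_windows Total number of windows in the gene.
#' @return Integer bin in 1..100.
#' @export
#' @examples
#' percent_bin(1, 90)   # 1
#' percent_bin(9, 100)  # 9
percent_bin <- function(window, num_windows) {
  stopifnot(all(window >= 1L), all(window <= num_windows), num_windows >= 1L)
  pmin(100L, as.integer((100 * (window - 1L)) %/% num_windows) + 1L)
}

#' Outlier bins of a bottleneck-position distribution
#'
#' Given per-bin bottleneck counts over the 100 percent bins, flags bins
#' where bottlenecks occur more often than expected by chance. `tukey`
#' flags counts above the upper Tukey fence (Q3 + 1.5 IQR of the 100
#' counts, quartiles by linear interpolation); `percentile` flags counts at
#' or above the given percentile of the counts.
#'
#' @param bin_counts Integer vector of length 100.
#' @param mode `"tukey"` or `"percentile"`.
#' @param percentile Percentile in (0, 100), used when
#'   `mode = "percentile"`.
#' @return Sorted integer vector of outlier bin numbers.
#' @export
outlier_bins <- function(bin_counts, mode = c("tukey", "percentile"),
                         percentile = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(bin_counts) == 100L)
  if (mode == "tukey") {
    fence <- quantile(bin_counts, 0.75, names = FALSE) + 1.5 * IQR(bin_counts)
    which(bin_counts > fence)
  } else {
    stopifnot(is.numeric(percentile), percentile > 0, percentile < 100)
    thr <- quantile(bin_counts, percentile / 100, names = FALSE)
    which(bin_counts >= thr)
  }
}

#' Largest initial run of consecutive outlier bins
#'
#' The most conservative outlier region: the largest n such that bins
#' 1..n are all outliers (e.g. outlier bins 1, 2, 3, 5, 7 give 3, because
#' 4 is not an outlier). Returns 0 when bin 1 itself is not an outlier,
#' in which case no ramp can be called.
#'
#' @param bins Integer vector of outlier bin numbers.
#' @return Integer cutoff percent (0 when bin 1 is not an outlier).
#' @export
#' @examples
#' consecutive_cutoff(c(1, 2, 3, 5, 7))  # 3
consecutive_cutoff <- function(bins) {
  n <- 0L
  while ((n + 1L) %in% bins) n <- n + 1L
  n
}

#' Infer the outlier-region cutoff from bottleneck positions
#'
#' @param bottleneck_bins Integer vector (with repeats) of the percent bins
#'   of all bottlenecks across the gene set, tied minima included.
#' @param mode `"tukey"` (default), `"percentile"`, or `"fixed"`.
#' @param percentile Percentile for `mode = "percentile"`.
#' @param cutoff Fixed cutoff percent for `mode = "fixed"` (default 8).
#' @return Integer cutoff percent c: a ramp may only be called when a
#'   gene's bottleneck lies within the first c percent of the gene.
#' @export
infer_outlier_cutoff <- function(bottleneck_bins,
                                 mode = c("tukey", "percentile", "fixed"),
                                 percentile = NULL, cutoff = 8L) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    stopifnot(cutoff >= 1, cutoff <= 100)
    return(as.integer(cutoff))
  }
  counts <- tabulate(as.integer(bottleneck_bins), nbins = 100L)
  consecutive_cutoff(outlier_bins(counts, mode = mode,
                                  percentile = percentile))
}

ramp_call_row <- function(gene_id, length_codons, sequence_nt,
                          bottleneck_window, bottleneck_percent) {
  data.frame(gene_id = gene_id,
             ramp_length_codons = as.integer(length_codons),
             ramp_sequence_nt = sequence_nt,
             bottleneck_window = as.integer(bottleneck_window),
             bottleneck_percent = as.integer(bottleneck_percent),
             stringsAsFactors = FALSE)
}

#' Call a ramp via the translational-bottleneck method
#'
#' If the gene's primary bottleneck falls within the first `cutoff`
#' percent of the gene, the middle efficiency of the entire profile is
#' computed with the same middle function used for smoothing, and the ramp
#' extends from the 5' end until the first window (at or after the
#' bottleneck) whose smoothed efficiency strictly exceeds that whole-gene
#' level; the ramp comprises the codons strictly 5' of that window's start.
#' Degenerate calls (the exceeding window is the first window, or no window
#' ever exceeds the whole-gene level) yield no ramp.
#'
#' @param codons Trimmed codons of the gene (character vector).
#' @param profile Efficiency profile of those codons.
#' @param smoothed Smoothed profile from [smooth_profile()].
#' @param middle Middle function used for smoothing and the whole-gene
#'   threshold.
#' @param cutoff Outlier-region cutoff percent (>= 1).
#' @param gene_id Identifier used in the returned row.
#' @return One-row data frame describing the ramp, or `NULL` when no ramp
#'   is called.
#' @export
call_ramp <- function(codons, profile, smoothed, middle = MIDDLES,
                      cutoff, gene_id = "gene") {
  middle <- match.arg(middle)
  stopifnot(cutoff >= 1)
  if (length(smoothed) == 0L) return(NULL)
  b <- find_bottleneck(smoothed)$primary
  nwin <- length(smoothed)
  bpct <- percent_bin(b, nwin)
  if (bpct > cutoff) return(NULL)
  thr <- middle_value(profile, middle)
  above <- which(smoothed[b:nwin] > thr)
  if (length(above) == 0L) return(NULL)
  e <- b + above[1L] - 1L       # first window exceeding the gene middle
  len <- e - 1L                 # codons strictly 5' of window e's start
  if (len < 1L) return(NULL)
  ramp_call_row(gene_id, len, paste(codons[seq_len(len)], collapse = ""),
                b, bpct)
}

#' Call a ramp via the standard-deviation method
#'
#' Alternative to the bottleneck method: the threshold is the arithmetic
#' mean of the unsmoothed profile minus `s` standard deviations, and the
#' ramp extends from the start of the gene until the first window whose
#' arithmetic window mean strictly exceeds it. Because codon efficiencies
#' have large variance relative to gene length, `s` typically needs to be
#' below 1 for any ramps to be found.
#'
#' @inheritParams call_ramp
#' @param window Window length in codons.
#' @param s Number of standard deviations below the gene mean (> 0).
#' @return One-row data frame, or `NULL` when no ramp is called.
#' @export
call_ramp_stddev <- function(codons, profile, window = 9L, s,
                             gene_id = "gene") {
  stopifnot(s > 0)
  L <- length(profile)
  if (L < window) return(NULL)
  thr <- mean(profile) - s * sd(profile)
  wmeans <- rolling_sum(profile, window) / window
  above <- which(wmeans > thr)
  if (length(above) == 0L) return(NULL)
  e <- above[1L]
  len <- e - 1L
  if (len < 1L) return(NULL)
  b <- find_bottleneck(wmeans)$primary
  ramp_call_row(gene_id, len, paste(codons[seq_len(len)], collapse = ""),
                b, percent_bin(b, length(wmeans)))
}

#' Filter ramp calls by length
#'
#' Quality-control step removing ramps whose length lies more than `d`
#' standard deviations from the mean ramp length over all calls
#' (recommended d = 2). With a single call the standard deviation is taken
#' as zero and the call is kept.
#'
#' @param calls Data frame of ramp calls (as in `ramp_result$ramps`).
#' @param d Number of standard deviations (> 0).
#' @return List with `kept` and `removed` data frames.
#' @export
filter_ramp_lengths <- function(calls, d) {
  stopifnot(d > 0)
  if (nrow(calls) == 0L) return(list(kept = calls, removed = calls))
  len <- calls$ramp_length_codons
  s <- if (length(len) > 1L) sd(len) else 0
  keep <- abs(len - mean(len)) <= d * s
  list(kept = calls[keep, , drop = FALSE],
       removed = calls[!keep, , drop = FALSE])
}

#' Position-wise consensus efficiency across genes
#'
#' Averages codon efficiency at each codon position over all genes long
#' enough to reach that position (so tail positions average over fewer
#' genes), then smooths the positional means with an arithmetic sliding
#' window. Used to visualize the genome-wide 5' efficiency dip.
#'
#' @param profiles List of numeric efficiency profiles.
#' @param window Smoothing window in codons (1 = no smoothing; 4 matches
#'   classic genome-wide ramp plots).
#' @return Numeric vector of smoothed positional means.
#' @export
consensus_profile <- function(profiles, window = 4L) {
  stopifnot(length(profiles) >= 1L)
  lens <- vapply(profiles, length, integer(1))
  maxlen <- max(lens)
  sums <- numeric(maxlen)
  n <- numeric(maxlen)
  for (p in profiles) {
    idx <- seq_along(p)
    sums[idx] <- sums[idx] + p
    n[idx] <- n[idx] + 1
  }
  means <- sums / n
  if (window <= 1L) return(means)
  if (maxlen < window) return(numeric(0))
  rolling_sum(means, window) / window
}

#' Configuration for a ramp-extraction run
#'
#' Bundles the algorithm parameters: smoothing window and middle function,
#' outlier-region mode, minimum gene length, the optional
#' standard-deviation method and ramp-length filter, and the thread count.
#'
#' @param window Ribosome-footprint smoothing window in codons (default 9).
#' @param middle Middle function (default `"hmean"`), see [middle_value()].
#' @param min_length_nt Minimum CDS length in nucleotides (default 300,
#'   i.e. 100 codons).
#' @param outlier_mode `"tukey"` (infer true outliers; default),
#'   `"percentile"`, or `"fixed"`.
#' @param percentile Percentile for `outlier_mode = "percentile"`.
#' @param cutoff Outlier-region percent for `outlier_mode = "fixed"`
#'   (default 8: the bottleneck must occur in the first eight percent of
#'   the gene).
#' @param stddev If set (> 0), use the standard-deviation method with this
#'   many standard deviations instead of the bottleneck method.
#' @param length_sd If set (> 0), filter ramp calls whose length is more
#'   than this many standard deviations from the mean call length
#'   (recommended 2).
#' @param threads Number of worker processes for the per-gene map.
#' @param is_rna Input sequences use the RNA alphabet.
#' @return An object of class `ramp_config`.
#' @export
ramp_config <- function(window = 9L, middle = "hmean", min_length_nt = 300L,
                        outlier_mode = c("tukey", "percentile", "fixed"),
                        percentile = NULL, cutoff = 8L, stddev = NULL,
                        length_sd = NULL, threads = 1L, is_rna = FALSE) {
  outlier_mode <- match.arg(outlier_mode)
  middle <- match.arg(middle, MIDDLES)
  stopifnot(window >= 1L, min_length_nt >= 3, threads >= 1L)
  if (outlier_mode == "percentile")
    stopifnot(is.numeric(percentile), percentile > 0, percentile < 100)
  if (outlier_mode == "fixed")
    stopifnot(cutoff >= 1, cutoff <= 100)
  if (!is.null(stddev)) stopifnot(stddev > 0)
  if (!is.null(length_sd)) stopifnot(length_sd > 0)
  structure(list(window = as.integer(window), middle = middle,
                 min_length_nt = as.integer(min_length_nt),
                 outlier_mode = outlier_mode, percentile = percentile,
                 cutoff = as.integer(cutoff), stddev = stddev,
                 length_sd = length_sd, threads = as.integer(threads),
                 is_rna = isTRUE(is_rna)),
            class = "ramp_config")
}

#' Run the full ramp-extraction pipeline
#'
#' Orchestrates length filtering, terminal-codon trimming, efficiency
#' profiling, sliding-window smoothing, bottleneck location, outlier-region
#' inference, per-gene ramp calling and the optional ramp-length filter.
#' The per-gene stages are a pure map over genes, so results are
#' deterministic and independent of `threads`.
#'
#' @param records List of [gene_record()], e.g. from [read_cds_fasta()].
#' @param table Optional [efficiency_table()] (the tAI path). When `NULL`,
#'   relative codon adaptiveness is computed from `ref_records` if given,
#'   otherwise from the input records themselves.
#' @param ref_records Optional list of gene records (typically highly
#'   expressed genes) used only to compute relative adaptiveness.
#' @param config A [ramp_config()].
#' @return An object of class `ramp_result`: a list with `ramps` (data
#'   frame of calls in input order), `no_ramp_ids`, `exclusions`,
#'   `cutoff_used`, `table`, and the per-gene `profiles` and `smoothed`
#'   lists.
#' @export
run_ramp_extraction <- function(records, table = NULL, ref_records = NULL,
                                config = ramp_config()) {
  stopifnot(inherits(config, "ramp_config"))
  if (is.null(table))
    table <- codon_adaptiveness(
      if (!is.null(ref_records)) ref_records else records)

  ml <- apply_min_length(records, config$min_length_nt)
  genes <- ml$kept
  ids <- vapply(genes, function(r) r$id, character(1))

  map_fun <- if (config$threads > 1L)
    function(x, f) parallel::mclapply(x, f, mc.cores = config$threads)
  else lapply

  per_gene <- map_fun(genes, function(r) {
    codons <- trim_terminal_codons(r)
    profile <- gene_profile(r, table)
    smoothed <- smooth_profile(profile, config$window, config$middle)
    res <- list(codons = codons, profile = profile, smoothed = smoothed,
                ties = integer(0))
    if (length(smoothed) > 0L)
      res$ties <- find_bottleneck(smoothed)$ties
    res
  })

  profiles <- setNames(lapply(per_gene, `[[`, "profile"), ids)
  smoothed <- setNames(lapply(per_gene, `[[`, "smoothed"), ids)

  use_stddev <- !is.null(config$stddev)
  cutoff_used <- NA_integer_
  if (!use_stddev) {
    if (config$outlier_mode == "fixed") {
      cutoff_used <- config$cutoff
    } else {
      bins <- unlist(lapply(per_gene, function(g) {
        if (length(g$smoothed) == 0L) return(integer(0))
        percent_bin(g$ties, length(g$smoothed))
      }), use.names = FALSE)
      cutoff_used <- infer_outlier_cutoff(bins, mode = config$outlier_mode,
                                          percentile = config$percentile)
    }
  }

  calls <- if (!use_stddev && cutoff_used < 1L) {
    vector("list", length(genes))
  } else {
    map_fun(seq_along(genes), function(i) {
      g <- per_gene[[i]]
      if (use_stddev)
        call_ramp_stddev(g$codons, g$profile, config$window, config$stddev,
                         gene_id = ids[i])
      else if (length(g$smoothed) == 0L) NULL
      else call_ramp(g$codons, g$profile, g$smoothed, config$middle,
                     cutoff_used, gene_id = ids[i])
    })
  }

  ramps <- do.call(rbind, c(list(ramp_call_row(character(0), integer(0),
                                               character(0), integer(0),
                                               integer(0))),
                            calls[!vapply(calls, is.null, logical(1))]))
  if (!is.null(config$length_sd) && nrow(ramps) > 0L) {
    fl <- filter_ramp_lengths(ramps, config$length_sd)
    ramps <- fl$kept
  }
  no_ramp <- setdiff(ids, ramps$gene_id)

  structure(list(ramps = ramps, no_ramp_ids = no_ramp,
                 exclusions = ml$excluded, cutoff_used = cutoff_used,
                 table = table, profiles = profiles, smoothed = smoothed,
                 config = config),
            class = "ramp_result")
}

#' @export
print.ramp_result <- function(x, ...) {
  cat("<ramp_result>\n")
  cat(sprintf("  genes analyzed : %d\n", length(x$profiles)))
  cat(sprintf("  excluded       : %d\n", nrow(x$exclusions)))
  cat(sprintf("  ramps called   : %d (%.1f%%)\n", nrow(x$ramps),
              if (length(x$profiles) > 0)
                100 * nrow(x$ramps) / length(x$profiles) else 0))
  if (!is.na(x$cutoff_used))
    cat(sprintf("  outlier cutoff : first %d%% of the gene\n", x$cutoff_used))
  if (nrow(x$ramps) > 0L)
    cat(sprintf("  ramp length    : mean %.1f codons (range %d-%d)\n",
                mean(x$ramps$ramp_length_codons),
                min(x$ramps$ramp_length_codons),
                max(x$ramps$ramp_length_codons)))
  invisible(x)
}
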