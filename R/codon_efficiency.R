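#' Construct a codon efficiency table
#'
#' An efficiency table maps codons to strictly positive translation
#' efficiencies -- tRNA adaptation index (tAI) values read from a file, or
#' relative codon adaptiveness computed from codon usage. Values of zero are
#' rejected because the sliding-window harmonic and geometric means are
#' undefined at zero.
#'
#' @param values Named numeric vector; names are DNA codons.
#' @param source One of `"tai_csv"`, `"computed_wij"`, `"synthetic"`.
#' @return Named numeric vector of class `efficiency_table` with attributes
#'   `source` and `missing_codons` (sense codons absent from the table).
#' @export
efficiency_table <- function(values, source = c("tai_csv", "computed_wij",
                                                "synthetic")) {
  source <- match.arg(source)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("efficiency values must be named by codon", call. = FALSE)
  nm <- toupper(gsub("U", "T", names(values), fixed = TRUE))
  bad <- setdiff(nm, all_codons())
  if (length(bad) > 0L)
    stop(sprintf("not a standard codon: %s", bad[1L]), call. = FALSE)
  if (anyDuplicated(nm))
    stop(sprintf("duplicate codon in efficiency table: %s",
                 nm[duplicated(nm)][1L]), call. = FALSE)
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("efficiency values must be finite and strictly positive",
         call. = FALSE)
  structure(setNames(values, nm),
            source = source,
            missing_codons = setdiff(sense_codons(), nm),
            class = "efficiency_table")
}

#' @export
print.efficiency_table <- function(x, ...) {
  cat(sprintf("<efficiency_table> %d codons, source = %s\n", length(x),
              attr(x, "source")))
  miss <- attr(x, "missing_codons")
  if (length(miss) > 0L)
    cat(sprintf("  missing sense codons: %d (%s%s)\n", length(miss),
                paste(utils::head(miss, 5), collapse = ", "),
                if (length(miss) > 5) ", ..." else ""))
  print(unclass(structure(as.numeric(x), names = names(x))), ...)
  invisible(x)
}

codon_like <- function(x) grepl("^[ACGTUacgtu]{3}$", trimws(x))

#' Read per-codon efficiency values from CSV
#'
#' Two dialects are accepted: a long form with two columns
#' (`codon,value`, optional header) and a wide form whose first row lists
#' codons and whose second row lists the matching values. Codons may be
#' spelled in DNA or RNA; they are normalized to DNA. Sense codons absent
#' from the file are allowed and recorded in the `missing_codons`
#' attribute of the returned table.
#'
#' @param path Path to the CSV file.
#' @return An [efficiency_table()] with source `"tai_csv"`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("AAA,0.43", "AAC,0.61"), f)
#' read_efficiency_csv(f)[c("AAA", "AAC")]
read_efficiency_csv <- function(path) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                  strip.white = TRUE, colClasses = "character")
  if (nrow(raw) == 0L)
    stop("empty efficiency CSV", call. = FALSE)

  wide <- nrow(raw) == 2L && ncol(raw) >= 2L &&
    all(codon_like(unlist(raw[1L, ]))) &&
    !any(is.na(suppressWarnings(as.numeric(unlist(raw[2L, ])))))
  if (wide) {
    codons <- as.character(unlist(raw[1L, ]))
    vals <- as.numeric(unlist(raw[2L, ]))
  } else {
    if (ncol(raw) != 2L)
      stop("long-form efficiency CSV must have exactly two columns",
           call. = FALSE)
    # drop an optional header row such as "codon,value"
    if (!codon_like(raw[1L, 1L]) &&
        is.na(suppressWarnings(as.numeric(raw[1L, 2L]))))
      raw <- raw[-1L, , drop = FALSE]
    if (nrow(raw) == 0L)
      stop("efficiency CSV contains no data rows", call. = FALSE)
    codons <- as.character(raw[[1L]])
    vals <- suppressWarnings(as.numeric(raw[[2L]]))
    if (any(is.na(vals)))
      stop(sprintf("non-numeric efficiency value for codon %s",
                   codons[which(is.na(vals))[1L]]), call. = FALSE)
  }
  if (any(!codon_like(codons)))
    stop(sprintf("not a codon: '%s'", codons[!codon_like(codons)][1L]),
         call. = FALSE)
  efficiency_table(setNames(vals, toupper(codons)), source = "tai_csv")
}

#' Count sense-codon occurrences across gene records
#'
#' Sums occurrences of each of the 61 sense codons over all genes. With
#' `trim = TRUE` (the default) the first and last codon of each gene are
#' dropped first, so canonical start/stop codons do not inflate counts;
#' stop codons are never counted.
#'
#' @param records List of [gene_record()].
#' @param trim Drop terminal codons before counting.
#' @return Named integer vector over the 61 sense codons (zeros included).
#' @export
#' @examples
#' g <- gene_record("g", c("ATG", "AAA", "AAA", "TAA"))
#' count_codons(list(g))[["AAA"]]
count_codons <- function(records, trim = TRUE) {
  sense <- sense_codons()
  counts <- setNames(integer(length(sense)), sense)
  if (length(records) == 0L) return(counts)
  codons <- unlist(lapply(records, function(r) {
    if (trim) trim_terminal_codons(r) else r$codons
  }), use.names = FALSE)
  tab <- table(factor(codons, levels = sense))
  counts[names(tab)] <- as.integer(tab)
  counts
}

# Split a codon-indexed vector by amino acid (sense codons only).
split_by_family <- function(x) {
  gc <- genetic_code()
  split(x, gc[names(x)])
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon j of amino acid i, RSCU is the observed count divided by the
#' mean count over the n_i synonymous codons of that amino acid, so RSCU
#' values within a family sum to n_i and single-codon amino acids always
#' have RSCU 1. If any sense codon has a zero count, a pseudo-count of 0.5
#' is first added to every sense codon so that downstream relative
#' adaptiveness values are strictly positive.
#'
#' @param counts Named vector of sense-codon counts, as from
#'   [count_codons()]. Missing sense codons are treated as zero.
#' @return Named numeric vector of RSCU values over the 61 sense codons.
#' @export
#' @examples
#' cnt <- count_codons(list(gene_record("g", c("ATG", "AAA", "AAA", "TAA"))))
#' r <- rscu(cnt)
#' sum(r[c("AAA", "AAG")])  # Lys family sums to 2
rscu <- function(counts) {
  sense <- sense_codons()
  full <- setNames(numeric(length(sense)), sense)
  if (length(counts) > 0L) {
    bad <- setdiff(names(counts), sense)
    if (length(bad) > 0L)
      stop(sprintf("count for non-sense codon: %s", bad[1L]), call. = FALSE)
    if (any(counts < 0)) stop("negative codon count", call. = FALSE)
    full[names(counts)] <- counts
  }
  if (any(full == 0)) full <- full + 0.5
  fams <- split_by_family(full)
  out <- unlist(lapply(fams, function(x) x / mean(x)), use.names = FALSE)
  setNames(out, unlist(lapply(fams, names), use.names = FALSE))[sense]
}

#' Relative codon adaptiveness (w) from RSCU values
#'
#' Divides each codon's RSCU by the maximal RSCU in its synonymous family,
#' so the most frequent codon of every amino acid has w = 1 and all values
#' lie in (0, 1]. Used as a proxy for the tRNA adaptation index when no
#' measured efficiencies are available.
#'
#' @param rscu_values Named numeric vector from [rscu()].
#' @return An [efficiency_table()] with source `"computed_wij"`.
#' @export
relative_adaptiveness <- function(rscu_values) {
  fams <- split_by_family(rscu_values)
  w <- unlist(lapply(fams, function(x) x / max(x)), use.names = FALSE)
  w <- setNames(w, unlist(lapply(fams, names), use.names = FALSE))
  efficiency_table(w[sense_codons()], source = "computed_wij")
}

#' Compute relative codon adaptiveness directly from gene records
#'
#' Convenience wrapper chaining [count_codons()], [rscu()] and
#' [relative_adaptiveness()].
#'
#' @inheritParams count_codons
#' @return An [efficiency_table()] with source `"computed_wij"`.
#' @export
codon_adaptiveness <- function(records, trim = TRUE) {
  relative_adaptiveness(rscu(count_codons(records, trim = trim)))
}

#' Per-codon efficiency profile of one gene
#'
#' Walks the trimmed gene codon by codon and looks each codon up in the
#' efficiency table, yielding the ordered list of codon efficiencies the
#' sliding-window analysis operates on. A codon with no table entry is a
#' hard error (an incomplete table would otherwise silently shift window
#' frames).
#'
#' @param record A [gene_record()].
#' @param table An [efficiency_table()].
#' @return Numeric vector, one efficiency per trimmed codon.
#' @export
gene_profile <- function(record, table) {
  codons <- trim_terminal_codons(record)
  vals <- unname(unclass(table)[codons])
  if (anyNA(vals))
    stop(sprintf("gene %s: codon %s has no entry in the efficiency table",
                 record$id, codons[which(is.na(vals))[1L]]), call. = FALSE)
  vals
}
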