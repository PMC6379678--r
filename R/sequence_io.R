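#' Construct a gene record
#'
#' A gene record holds one validated coding sequence: its identifier, the
#' ordered codons (including start and stop), and the original nucleotide
#' length. Records are normally produced by [read_cds_fasta()] or
#' [make_genome()].
#'
#' @param id Non-empty sequence identifier.
#' @param codons Character vector of 3-mers over A/C/G/T.
#' @param raw_length_nt Original CDS length in nucleotides; must equal
#'   `3 * length(codons)`.
#' @return An object of class `gene_record`.
#' @export
#' @examples
#' g <- gene_record("g1", c("ATG", "AAA", "TAA"))
#' g$raw_length_nt
gene_record <- function(id, codons, raw_length_nt = 3L * length(codons)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  codons <- toupper(as.character(codons))
  if (any(nchar(codons) != 3L) || any(grepl("[^ACGT]", codons)))
    stop("codons must be 3-mers over A/C/G/T", call. = FALSE)
  if (raw_length_nt != 3L * length(codons))
    stop("raw_length_nt must be 3 x number of codons", call. = FALSE)
  structure(list(id = id, codons = codons,
                 raw_length_nt = as.integer(raw_length_nt)),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat("<gene_record>", x$id, "-", length(x$codons), "codons (",
      x$raw_length_nt, "nt )\n")
  invisible(x)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

exclusion_frame <- function(id = character(), reason = character()) {
  data.frame(id = as.character(id), reason = as.character(reason),
             stringsAsFactors = FALSE)
}

#' Read and validate coding sequences from a FASTA file
#'
#' Sequences are uppercased and, when `is_rna = TRUE`, U is mapped to T
#' before codon splitting. Sequences whose length is not a multiple of three
#' are excluded with reason `not_divisible_by_3`; sequences containing any
#' character outside A/C/G/T after RNA mapping are excluded with reason
#' `ambiguous_bases` (no efficiency value exists for ambiguous codons).
#' Length is checked first, so a record carries exactly one exclusion reason.
#'
#' @param path Path to a FASTA file. Headers must be unique; the identifier
#'   is the first whitespace-delimited token of each header.
#' @param is_rna Input uses the RNA alphabet (maps U to T).
#' @return A list with `records` (list of [gene_record()], in input order)
#'   and `exclusions` (data frame with columns `id`, `reason`).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "ATGAAATAA", ">g2", "ATGAAAA"), fa)
#' res <- read_cds_fasta(fa)
#' length(res$records)      # 1
#' res$exclusions$reason    # "not_divisible_by_3"
read_cds_fasta <- function(path, is_rna = FALSE) {
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) > 0L && !startsWith(trimws(lines[meaningful[1L]]), ">"))
    stop(sprintf("malformed FASTA: sequence data before first header (line %d)",
                 meaningful[1L]), call. = FALSE)
  if (length(meaningful) == 0L)
    return(list(records = list(), exclusions = exclusion_frame()))

  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("empty FASTA header", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate sequence id: %s", dup[1L]), call. = FALSE)

  seqs <- toupper(as.character(set))
  if (is_rna) seqs <- gsub("U", "T", seqs, fixed = TRUE)

  records <- vector("list", length(seqs))
  excl_id <- character()
  excl_reason <- character()
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (nchar(s) %% 3L != 0L) {
      excl_id <- c(excl_id, ids[i]); excl_reason <- c(excl_reason, "not_divisible_by_3")
    } else if (grepl("[^ACGT]", s)) {
      excl_id <- c(excl_id, ids[i]); excl_reason <- c(excl_reason, "ambiguous_bases")
    } else {
      records[[i]] <- gene_record(ids[i], split_codons(s), nchar(s))
      keep[i] <- TRUE
    }
  }
  list(records = records[keep],
       exclusions = exclusion_frame(excl_id, excl_reason))
}

#' Filter gene records by minimum CDS length
#'
#' The length test uses the untrimmed CDS length in nucleotides, so the
#' default threshold of 300 nt corresponds to 100 codons including start and
#' stop.
#'
#' @param records List of [gene_record()].
#' @param min_length_nt Minimum length in nucleotides (default 300).
#' @return A list with `kept` (records) and `excluded` (data frame with
#'   reason `below_min_length`).
#' @export
apply_min_length <- function(records, min_length_nt = 300) {
  stopifnot(min_length_nt >= 3)
  lens <- vapply(records, function(r) r$raw_length_nt, integer(1))
  keep <- lens >= min_length_nt
  list(kept = records[keep],
       excluded = exclusion_frame(
         vapply(records[!keep], function(r) r$id, character(1)),
         rep("below_min_length", sum(!keep))))
}

#' Drop the terminal codons of a gene record
#'
#' Removes the first and last codon positionally, with no check that they
#' are a canonical start or stop; the remaining codons are the units the
#' ramp-detection algorithm scores.
#'
#' @param record A [gene_record()] with at least 3 codons.
#' @return Character vector of the interior codons.
#' @export
#' @examples
#' trim_terminal_codons(gene_record("g", c("ATG", "AAA", "TAA")))
trim_terminal_codons <- function(record) {
  n <- length(record$codons)
  if (n < 3L)
    stop(sprintf("gene %s has %d codons; cannot trim terminal codons",
                 record$id, n), call. = FALSE)
  record$codons[2:(n - 1L)]
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param file Path, or a connection (e.g. [stdout()]) for streaming.
#' @param width Line width for wrapping when writing to a path.
#' @return Invisibly, `file`.
#' @export
write_fasta <- function(seqs, file = stdout(), width = 80L) {
  if (inherits(file, "connection")) {
    if (length(seqs) > 0L)
      writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), file)
    return(invisible(file))
  }
  set <- Biostrings::DNAStringSet(unlist(lapply(seqs, as.character)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = file, width = width)
  invisible(file)
}

tidy_value_frame <- function(values_by_gene) {
  n <- vapply(values_by_gene, length, integer(1))
  data.frame(gene = rep(names(values_by_gene), n),
             codon_position = unlist(lapply(n, seq_len), use.names = FALSE),
             value = unlist(values_by_gene, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Write the outputs of a ramp-extraction run
#'
#' Side outputs follow the tool's file conventions: detected ramp sequences
#' as FASTA (standard output by default), smoothed and raw per-codon
#' efficiencies as tidy CSV (`gene,codon_position,value`, one row per gene x
#' position, positions 1-based within the trimmed gene), identifiers with no
#' detected ramp as a plain-text list, and excluded sequences as a
#' two-column text file (`id<TAB>reason`).
#'
#' @param result A `ramp_result` from [run_ramp_extraction()].
#' @param out Path for the ramp FASTA, or `NULL` to write to standard
#'   output.
#' @param smoothed_csv,profile_csv Optional CSV paths for the smoothed and
#'   raw efficiency profiles.
#' @param no_ramp_txt Optional path for the no-ramp identifier list.
#' @param excluded_txt Optional path for the exclusion list.
#' @return Invisibly, `result`.
#' @export
write_run_outputs <- function(result, out = NULL, smoothed_csv = NULL,
                              profile_csv = NULL, no_ramp_txt = NULL,
                              excluded_txt = NULL) {
  ramps <- result$ramps
  seqs <- setNames(ramps$ramp_sequence_nt, ramps$gene_id)
  write_fasta(seqs, if (is.null(out)) stdout() else out)
  if (!is.null(smoothed_csv))
    write.csv(tidy_value_frame(result$smoothed), smoothed_csv, row.names = FALSE)
  if (!is.null(profile_csv))
    write.csv(tidy_value_frame(result$profiles), profile_csv, row.names = FALSE)
  if (!is.null(no_ramp_txt))
    writeLines(result$no_ramp_ids, no_ramp_txt)
  if (!is.null(excluded_txt))
    writeLines(paste(result$exclusions$id, result$exclusions$reason,
                     sep = "\t"), excluded_txt)
  invisible(result)
}
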