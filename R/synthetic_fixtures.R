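#' Generate a synthetic codon-efficiency table
#'
#' Draws an efficiency value in (0.05, 1] for each of the 61 sense codons
#' and rescales each synonymous family so that its maximum is exactly 1,
#' mirroring the structure of a relative-adaptiveness table. Deterministic
#' for a given seed; the caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @return An [efficiency_table()] with source `"synthetic"`.
#' @export
#' @examples
#' tab <- make_efficiency_table(1)
#' max(tab)
make_efficiency_table <- function(seed) {
  with_seed(seed, {
    sense <- sense_codons()
    vals <- setNames(runif(length(sense), min = 0.05, max = 1), sense)
    fams <- split_by_family(vals)
    vals <- unlist(lapply(fams, function(x) x / max(x)), use.names = FALSE)
    vals <- setNames(vals, unlist(lapply(fams, names), use.names = FALSE))
    efficiency_table(vals[sense], source = "synthetic")
  })
}

#' Generate a synthetic gene set with planted ramp sequences
#'
#' Builds `n_genes` coding sequences over the 61 sense codons. Codons are
#' partitioned by the `slow_quantile` of the efficiency table into a slow
#' and a fast pool. A planted-ramp gene starts with `ramp_length_codons`
#' codons drawn from the slow pool followed by a body drawn from the fast
#' pool; a gene without a ramp is drawn entirely from the fast pool. ATG is
#' prepended and a stop codon appended, so every sequence is a valid CDS
#' and passes input validation with zero exclusions. Amino-acid realism is
#' deliberately not attempted: the detection algorithm consults amino acids
#' only through the efficiency table, so a purely codon-level fixture
#' exercises it fully.
#'
#' Gene lengths default to 300-450 interior codons with ramps of 20-40
#' codons in 20 percent of genes, so planted bottlenecks fall within the
#' first few percent of each gene, the regime the detector targets.
#'
#' @param n_genes Number of genes (default 500).
#' @param gene_length_codons Length-2 range of interior codon counts
#'   (excluding start/stop).
#' @param ramp_proportion Fraction of genes receiving a planted ramp.
#' @param ramp_length_codons Length-2 range of planted ramp lengths.
#' @param slow_quantile Efficiency quantile splitting slow from fast
#'   codons (default 0.25: slow pool = lowest quartile).
#' @param table Optional [efficiency_table()]; generated from `seed` when
#'   `NULL`.
#' @param seed Integer seed; generation is fully deterministic per seed.
#' @return List with `records` (gene records), `truth` (data frame
#'   `gene_id`, `has_ramp`, `planted_length_codons`) and `table`.
#' @export
#' @examples
#' g <- make_genome(n_genes = 10, seed = 1)
#' sum(g$truth$has_ramp)
make_genome <- function(n_genes = 500L,
                        gene_length_codons = c(300L, 450L),
                        ramp_proportion = 0.2,
                        ramp_length_codons = c(20L, 40L),
                        slow_quantile = 0.25,
                        table = NULL, seed = 1L) {
  stopifnot(n_genes >= 1L, length(gene_length_codons) == 2L,
            gene_length_codons[1L] <= gene_length_codons[2L],
            ramp_proportion >= 0, ramp_proportion <= 1,
            length(ramp_length_codons) == 2L,
            ramp_length_codons[1L] >= 1L,
            ramp_length_codons[1L] <= ramp_length_codons[2L],
            ramp_length_codons[2L] < gene_length_codons[1L],
            slow_quantile > 0, slow_quantile < 1)
  if (is.null(table)) table <- make_efficiency_table(seed)

  q <- quantile(as.numeric(table), slow_quantile, names = FALSE)
  slow_pool <- names(table)[as.numeric(table) <= q]
  fast_pool <- names(table)[as.numeric(table) > q]
  stops <- setdiff(all_codons(), sense_codons())

  with_seed(seed, {
    n_ramp <- round(n_genes * ramp_proportion)
    has_ramp <- rep(FALSE, n_genes)
    if (n_ramp > 0L) has_ramp[sample.int(n_genes, n_ramp)] <- TRUE
    ids <- sprintf("gene%04d", seq_len(n_genes))
    planted <- rep(NA_integer_, n_genes)
    records <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      L <- sample(gene_length_codons[1L]:gene_length_codons[2L], 1L)
      if (has_ramp[i]) {
        k <- sample(ramp_length_codons[1L]:ramp_length_codons[2L], 1L)
        planted[i] <- k
        body <- c(sample(slow_pool, k, replace = TRUE),
                  sample(fast_pool, L - k, replace = TRUE))
      } else {
        body <- sample(fast_pool, L, replace = TRUE)
      }
      records[[i]] <- gene_record(ids[i],
                                  c("ATG", body, sample(stops, 1L)))
    }
    list(records = records,
         truth = data.frame(gene_id = ids, has_ramp = has_ramp,
                            planted_length_codons = planted,
                            stringsAsFactors = FALSE),
         table = table)
  })
}

#' Write a synthetic genome to FASTA plus a truth CSV
#'
#' @param genome Result of [make_genome()].
#' @param fasta_path Output FASTA path.
#' @param truth_path Output CSV path
#'   (`gene_id,has_ramp,planted_length_codons`).
#' @return Invisibly, `genome`.
#' @export
write_genome_fixture <- function(genome, fasta_path, truth_path) {
  seqs <- vapply(genome$records, function(r) paste(r$codons, collapse = ""),
                 character(1))
  names(seqs) <- vapply(genome$records, function(r) r$id, character(1))
  write_fasta(seqs, fasta_path)
  write.csv(genome$truth, truth_path, row.names = FALSE)
  invisible(genome)
}
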