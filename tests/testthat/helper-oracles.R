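# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the package's own vectorized code
# paths.

# Window middles recomputed one window at a time with plain formulas.
naive_smooth <- function(x, w, middle) {
  L <- length(x)
  if (L < w) return(numeric(0))
  fn <- switch(middle,
               mean = function(v) sum(v) / length(v),
               hmean = function(v) length(v) / sum(1 / v),
               gmean = function(v) prod(v)^(1 / length(v)),
               median = function(v) stats::median(v))
  vapply(seq_len(L - w + 1), function(k) fn(x[k:(k + w - 1)]), numeric(1))
}

# Strictly-greater hypergeometric tail by exhaustive enumeration of all
# draws of size k from a universe of size N containing m marked items.
enum_overlap_tail <- function(shared, m, k, N) {
  items <- seq_len(N)
  draws <- utils::combn(N, k)
  marks <- colSums(draws <= m)  # items 1..m are the marked ones
  mean(marks > shared)
}

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

# A gene record with given interior codons (start/stop added).
interior_gene <- function(id, interior) {
  gene_record(id, c("ATG", interior, "TAA"))
}

# Uniform toy efficiency table covering every codon (including stops so
# arbitrary toy genes can be profiled untrimmed if needed).
flat_table <- function(value = 0.5) {
  efficiency_table(setNames(rep(value, 64), rampseq::sense_codons() |>
                              union(c("TAA", "TAG", "TGA"))),
                   source = "synthetic")
}
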