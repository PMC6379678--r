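---
title: "Detecting 5' translational ramps from codon efficiency profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting 5' translational ramps from codon efficiency profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rampseq)
```

## The model

Translation elongation speed varies along a transcript because synonymous
codons are decoded at different rates, largely reflecting adaptation to
the cellular tRNA pool. A *ramp sequence* is a stretch of slowly
translated codons at the 5' end of a coding sequence; by slowing the
first ribosomes, it spaces those that follow and reduces collisions
downstream. The ramp is a property of each gene relative to its own
average efficiency, not an absolute genome-wide threshold, so every gene
must be analyzed individually.

`rampseq` models per-codon speed with an *efficiency table*: a map from
codon to a strictly positive value where higher means faster. Two sources
are supported.

* **Measured efficiencies** (the tAI path): a CSV of per-codon values
  such as tRNA adaptation index values (`read_efficiency_csv()`).
* **Relative codon adaptiveness** (the adaptiveness path): when no
  measured values exist, codon usage itself is the proxy. For codon $j$
  of amino acid $i$ with counts $x_{ij}$ over the $n_i$ synonymous
  codons,
  $$\mathrm{RSCU}_{ij} = \frac{x_{ij}}{\frac{1}{n_i}\sum_{j=1}^{n_i} x_{ij}},
    \qquad w_{ij} = \frac{\mathrm{RSCU}_{ij}}{\mathrm{RSCU}_{i\,\max}},$$
  computed from the input FASTA or from a user-supplied set of (ideally
  highly expressed) genes. The underlying assumption is that preferred
  codons are translated faster — reasonable in organisms with
  translational selection, weaker where mutation bias dominates codon
  usage.

### The detection procedure

1. **Validation.** Sequences not divisible by three, or containing
   non-ACGT characters after optional RNA-to-DNA mapping, are excluded
   (each with a single recorded reason). Genes shorter than a minimum
   length are excluded; the first and last codon of each remaining gene
   are removed positionally, with no check that they are a canonical
   start or stop, so unusual initiator codons are handled uniformly.
2. **Profiling and smoothing.** Each trimmed codon is looked up in the
   efficiency table, and the profile is smoothed with a sliding window of
   one ribosome footprint summarized by a *middle* function. Only full
   windows are emitted ($L - w + 1$ of them, step one codon).
3. **Bottleneck.** The window with minimal smoothed efficiency is the
   gene's translational bottleneck. The 5'-most window is primary when
   several tie; all tied positions contribute to the next step.
4. **Outlier region.** Each gene's window axis is divided into 100 equal
   parts and the bottleneck's part recorded
   ($\lfloor 100\,(k-1)/n_\mathrm{win}\rfloor + 1$ for window $k$ of
   $n_\mathrm{win}$). Pooling these bins over all genes, bins holding
   more bottlenecks than chance are flagged, and the cutoff $c$ is the
   longest initial run of flagged bins (bins 1, 2, 3, 5, 7 flagged gives
   $c = 3$). This is deliberately conservative: a single unflagged bin
   terminates the region.
5. **Calling.** A gene whose bottleneck bin exceeds $c$ has no ramp.
   Otherwise the whole-profile middle efficiency is the threshold, and
   the ramp covers all codons strictly 5' of the start of the first
   window (at or after the bottleneck) whose smoothed efficiency
   *strictly exceeds* it. If that window is the very first one, or no
   window ever exceeds the threshold, no ramp is called.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `window` | 9 | codons | A commonly accepted ribosome footprint is about 28 nt ≈ 9 codons; estimates span 5–15, so it is settable. |
| `middle` | `hmean` | — | The harmonic mean is dominated by small values, making windows containing even a few very slow codons stand out; `gmean`, `mean`, `median` are alternatives. |
| `min_length_nt` | 300 | nt | 100 codons; below this, windowed statistics are noisy and percent bins sparse. Compared against the untrimmed CDS length. |
| `outlier_mode` | `tukey` | — | "True outliers": bin counts above Q3 + 1.5 IQR of the 100 per-bin counts (quartiles by linear interpolation). `percentile` flags bins at or above a count percentile (`percentile`, e.g. 75); `fixed` skips inference and uses the first `cutoff` percent. |
| `cutoff` | 8 | % of gene | The default fixed outlier region: the bottleneck must fall in the first eight percent of the gene. |
| `stddev` | off | SDs | Alternative calling rule: threshold = arithmetic mean − `stddev` × SD of the unsmoothed profile, scanned with arithmetic window means from the gene start. Efficiencies have large variance relative to gene length, so values below 1 are typically needed. |
| `length_sd` | off | SDs | Post-hoc quality filter dropping calls whose length is more than this many SDs from the mean call length; 2 is a reasonable choice. |
| `threads` | 1 | — | The per-gene stages are a pure map, so results are identical at any thread count. |

## Design choices where the procedure was genuinely open

* **Threshold middle.** The extension threshold ("middle efficiency of
  the entire sequence") uses the same middle function as the smoothing,
  so the harmonic-mean default compares like with like; switching to
  `mean` applies the arithmetic mean in both places.
* **Strict inequality.** The ramp ends at the first window that
  *exceeds* the threshold. On a perfectly constant profile nothing
  exceeds it, so no ramp is called — the correct degenerate answer.
* **Percent formula.** $\lfloor 100\,(k-1)/n_\mathrm{win}\rfloor+1$ over
  window start positions, clamped to 100. The first window is always bin
  1; the last window of a 90-window gene is bin 99, since its start lies
  at 98.9% of the axis.
* **No-outlier genomes.** If bin 1 itself is not flagged, the cutoff is
  0 and no ramps are reported — the expected outcome for gene sets
  without positional bottleneck enrichment.
* **Pseudo-count.** If any sense codon has a zero count, 0.5 is added to
  every sense codon before RSCU, the classic codon-adaptation-index
  convention; without it $w_{ij} = 0$ would break harmonic windows.
* **Missing table entries** are a hard error (naming gene and codon)
  rather than being skipped: silently dropping codons would shift every
  downstream window frame.
* **Tie tolerance.** Window middles are computed with cumulative sums
  for speed; exact ties can split by ~1e-16, so bottleneck ties are
  detected with a 1e-9 relative tolerance.
* **Ramp output.** The emitted ramp sequence contains exactly the scored
  codons — the trimmed start codon is not re-prepended — so output
  positions correspond one-to-one to analyzed positions.

## The synthetic generator

`make_genome()` builds seeded, fully deterministic gene sets for testing
and benchmarking. Codons are split at a quantile of the efficiency table
(default: the lowest quartile is the slow pool). A planted-ramp gene
draws its first 20–40 codons from the slow pool and its body from the
fast pool; other genes draw entirely from the fast pool; ATG and a stop
codon are added. Defaults — 500 genes of 300–450 interior codons (typical
eukaryotic CDS scale) with ramps in 20% of genes — put planted
bottlenecks in the first few percent of each gene, the regime the
detector targets, while leaving enough non-ramp genes to measure false
calls.

The generator emulates only what the algorithm consults: codon-level
efficiency composition. It does **not** emulate amino-acid composition
constraints, GC/mutational bias, mRNA secondary structure, expression
levels, or the gradual (rather than step-like) efficiency rise of real
ramps. Passing the recovery tests therefore shows the machinery
implements its definition correctly on well-separated signals — not that
real genomes yield any particular ramp fraction. On real data, slow and
fast codons are interleaved and ramp boundaries are genuinely ambiguous;
expect softer behavior than on fixtures.

## Numerical and testing notes

Smoothing is validated against a brute-force per-window oracle for all
four middles; RSCU/adaptiveness against hand-computed families and exact
family-sum identities; the hypergeometric tail (computed in log space via
the strictly-greater convention, so the log10 p-value survives underflow
at p ≈ 1e-210) against exhaustive enumeration on universes of up to 12
genes; and the chi-squared statistic against `stats::chisq.test`. The
suite's end-to-end checks run on 40–500-gene generated sets with a fixed
seed — sizes chosen so the whole suite stays quick while percent bins are
well populated — and assert planted-ramp sensitivity of at least 0.9 and
a false-call rate of at most 0.1 under the default 8% region, plus
byte-identical outputs across thread counts. The Tukey inference mode is
exercised on the same fixtures without thresholds: with only a few
hundred genes the consecutive-run cutoff is sensitive to single-bin
noise, which is worth remembering when applying it to small gene sets.

## Limitations

* Standard genetic code only; stop codons never carry efficiencies.
* Relative adaptiveness is a usage-based proxy; in genomes without
  translational selection it may not track elongation speed.
* The outlier region is estimated from the input gene set, so calls on
  small or biased sets inherit that noise (use `cutoff` for an explicit
  region instead).
* Alternative ramp mechanisms — mRNA folding energy, amino-acid charge —
  are out of scope; only codon-adaptation ramps are detected.
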