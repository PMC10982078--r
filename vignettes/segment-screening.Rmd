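---
title: "Co-occurrence segment screening and phylogeographic distances for bed bug viromes"
author: "cimexvir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence segment screening and phylogeographic distances for bed bug viromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimexvir)
```

## The problem

RNA virome surveys of arthropods assemble metatranscriptomes per
individual, annotate transcripts against protein databases, and recover
viral sequences by their conserved RNA-dependent RNA polymerase (RdRp).
For multipartite viruses — bunya- and tenui-like viruses in particular —
the RdRp sits on one genome segment (the L segment); the other segments
(M, S) encode divergent proteins that often have *no* detectable database
homology. Those segments are invisible to annotation but not to ecology:
they must travel with their RdRp. `cimexvir` implements the downstream
analyses such a survey needs once assembly and annotation are done:

1. a co-occurrence screen that proposes candidate genome segments,
2. six-frame ORF extraction with `getorf`-style semantics,
3. uncorrected p-distance phylogeography with clade mean summaries,
4. the per-sample endosymbiont-versus-virus read-abundance regression,

plus a synthetic-data generator that produces every input with known
truth.

## The co-occurrence screen

Let `A` be the set of *anchor-positive* samples — samples containing at
least one RdRp-confirmed transcript of the virus (partial and complete
anchor sequences both count as detections) — and `S` the set of samples
containing a candidate transcript. The screen uses two statistics:

* **V~co~ = |S ∩ A| / |A|** — recall against the anchor: how often the
  candidate is present where the virus demonstrably is;
* **T~co~ = |S ∩ A| / |S|** — precision of the candidate's occurrences:
  how rarely it appears where the virus is absent.

The published descriptions of these metrics are verbal; this pair of
formulas is the package's formalisation, chosen because it reproduces the
reported motivating case — a candidate present in 6 of 7 anchor-positive
samples plus 2 anchor-negative ones scores (6/7 ≈ 0.86, 6/8 = 0.75):

```{r worked}
m <- cbind(rdrp = c(rep(1L, 7), rep(0L, 3)),
           cand = c(rep(1L, 6), 0L, 1L, 1L, 0L))
rownames(m) <- sprintf("s%02d", 1:10)
anch <- anchor_set("tenui1", "rdrp")
c(v_co = v_co("cand", anch, m), t_co = t_co("cand", anch, m))
```

A transcript is called a candidate segment when `V_co >= 0.75`,
`T_co >= 0.5` (both inclusive, reading the published thresholds
literally) *and* its longest ORF is strictly greater than 500 nt (the
bound is written as ">", so exactly 500 nt fails). Defaults live in
`screen_config()`; `screen_candidates()` scores every non-anchor
transcript, sorts by (V~co~, T~co~) descending with ID as the
deterministic tie-break, and flags never-observed transcripts instead of
aborting.

`screen_pass_probability()` gives the exact binomial probability that an
independently occurring transcript clears the two thresholds, which is
the analytic reference for both the false-positive rate of background
transcripts and the recovery rate of true companions. Worth stating
plainly: under 30 samples, prevalence 0.4, fidelity 0.9 and spillover
0.05, the per-companion pass probability is ≈ 0.948 and the probability
that *both* companions of a three-segment virus pass is ≈ 0.90 — the
screen's recall at these sample sizes is real but not near-certain, and
the test suite asserts the empirical rate against this exact value.

## ORF semantics

`find_orfs()` scans all six frames. The pipeline default is the
stop-to-stop definition (EMBOSS `getorf -find 2`): an ORF is a maximal
stop-free codon run, with sequence ends acting as virtual stops. The
start-to-stop modes require an explicit `ATG` (only `ATG`; alternative
starts are not used). Conventions the package fixes, since published
methods are typically silent on them:

* reported `nt_seq` **excludes** the terminating stop codon, and
  `min_len` (and the screen's 500-nt bound) applies to that stop-free
  length;
* coordinates are 0-based half-open on the forward strand; a
  reverse-strand record's `nt_seq` is the reverse complement of its
  `[start, end)` slice;
* codons containing `N` never match a start or stop and translate to
  `X`; only genetic code table 1 is exercised.

## p-distance phylogeography

`p_distance()` is the uncorrected proportion of differing sites. The
deletion policy defaults to *pairwise deletion* (MEGA's common setting):
a site is dropped for a pair when either sequence has a gap or any
non-`ACGT` character; `complete_deletion` removes such columns globally
first. The policy is a documented, switchable choice because published
tables rarely state it.

`dedupe_within_sample()` applies the rule used before distance analysis:
exact duplicates *within* a sample are collapsed to the first occurrence
(case-folded comparison), while identical sequences in different samples
are kept — cross-sample identity is signal.

`group_mean_distances()` averages all within-group and cross-group pairs.
A singleton group's within mean is reported as `NA`, never 0, so
summaries cannot be silently deflated. Distances are stored as fractions;
percent rendering (one decimal, rounding half away from zero, via
`format_pct()`) happens only at the reporting layer.

The package ships a published 11-sequence tenuivirus RdRp p-distance
matrix with its Italy / rest-of-the-world / outgroup clade assignment
(`tenuivirus_reference_distances()`). Recomputing clade means from that
printed, 1-decimal matrix reproduces the published within-Italy (3.0%),
within-rest (1.1%), within-outgroup (36.5%), Italy–outgroup (55.8%) and
rest–outgroup (55.9%) summaries to within 0.05 percentage points. The
Italy-versus-rest cell recomputes to ≈ 22.25% against a published 22.4%:
the published group means were evidently computed from unrounded
distances, and for that one cell the rounding of the printed matrix
matters. The package documents rather than "corrects" this.

## Abundance regression

`correlate_abundance()` fits virus read percentage on *Wolbachia* read
percentage by ordinary least squares (`stats::lm`), with Pearson *r* and
the two-sided p-value from `t = r·√(n−2)/√(1−r²)` on `n − 2` degrees of
freedom — identical to the regression slope test, so the choice between
"correlation test" and "regression test" is moot for a simple
regression. The response/predictor orientation (virus on Wolbachia) is
fixed and documented. A suspected outlier can be excluded via
`drop_samples`; the default keeps every row, matching the published fit
on the packaged 22-sample table:

```{r regression}
correlate_abundance(wolbachia_virus_read_pct())
```

## What the synthetic generator emulates

All stochastic operations take a required `seed` and use the
Mersenne-Twister generator, restoring the caller's RNG state afterwards;
identical seeds give byte-identical outputs.

**Presence matrices** (`simulate_presence_matrix()`): each sample
carries a virus with probability `prevalence`, independently per virus
(no co-infection structure — the screen treats viruses marginally).
The anchor column equals the carrier indicator exactly; each non-anchor
segment is detected in carriers with probability `fidelity` and appears
spuriously in non-carriers with probability `spillover`, conditionally
independently across segments. Fidelity and spillover are this package's
parametrisation of segment co-detection; published studies state no
generative model for it. Background transcripts occur independently at
`bg_rate`. The test defaults (30 samples, prevalence 0.4, fidelity 0.9,
spillover 0.05, 200 background transcripts at rate 0.2) mirror a
realistic survey: tens of individuals, a virus in a minority of them,
occasional index bleed.

**Divergent families** (`simulate_divergent_family()`): a uniform random
root, one ancestor per clade at `between_divergence` substitutions per
site, tips at `within_divergence` from their ancestor. Substitutions are
uniform over the three alternative bases with no rate heterogeneity and
no indels — p-distance is the only downstream statistic, so richer
models would add nothing testable. The closed-form expectation
(`expected_p_distance()`) uses the spectral factor `λ = 1 − 4p/3` per
branch: the mismatch probability of two tips is `¾(1 − Πλ)` along the
path joining them. Tests use sequence lengths of 2000–5000 nt and
10–20 replicate seeds, enough to pin means to well under a standard
error of the targets.

**Abundance tables** (`simulate_abundance_table()`): a linear model with
Gaussian noise, truncated at 0 *after* noise addition because read
percentages cannot be negative. The truncation slightly biases fits when
the line dips near zero; zero-noise recovery is exact by construction.

**ORF-bearing transcripts** (`simulate_transcript_with_orfs()`): implants
start-to-stop ORFs at requested frames between spacers built from a
`TTAGTTAG` motif that carries a stop in all six frames (so no stop-free
run spans more than one implant; spacers are extended to at least 12 nt
to guarantee this even for shorter requested spacers). ORF interiors are
sampled from `{C,G}`-only codons: with no `A` or `T` on either strand,
no spurious `ATG` or stop can arise inside or across an implant, so a
start-to-stop scan returns *exactly* the implanted set — a design choice
that makes truth exact rather than probabilistic. Stop-to-stop scans
additionally report the incidental stop-free runs every sequence has in
its other frames; that is inherent to the definition, not an artefact.

What the generator does **not** emulate: reads, coverage, assembly
artefacts, chimeras, clustering errors, or sequence-level causes of
co-occurrence. Presence is simulated directly, so passing tests show the
statistics and their sampling behaviour are right, not that upstream
assembly or clustering is robust.

## Pipeline and formats

Everything is TSV (UTF-8, tab-delimited, header row) or FASTA, and every
writer/reader pair round-trips exactly. BLAST/DIAMOND tabular hits
(12-column `outfmt 6`; extra columns tolerated) are filtered at the
conventional e-value cutoff of 1e−5, and every dropped or defaulted
record is counted in a message — silent data loss is treated as a bug.
"Complete RdRp domain" status is a user-supplied flag: conserved-domain
detection, like alignment, tree inference and read mapping, is upstream
of this package. Transcript IDs must be cluster IDs shared across
samples (clustering happens upstream too). `run_report()` orchestrates
screen → ORFs → distances → regression, skips optional stages explicitly,
records thresholds and versions in `report.json`, and writes
byte-identical outputs on identical inputs.

## Known limitations

* The V~co~/T~co~ formalisation is an interpretation of a verbal method
  description; a different prior formalisation could differ in edge
  cases (the worked example constrains but does not uniquely determine
  it).
* No significance model for co-occurrence: thresholds are fixed, not
  calibrated per dataset, and a transcript is not jointly assigned
  across multiple viruses.
* Distances are uncorrected; saturated comparisons (outgroups at ~55%)
  underestimate true divergence by design.
* The regression is ordinary least squares on percentages; it is a
  descriptive association, not a causal claim about *Wolbachia*
  protection, and is sensitive to high-leverage samples (hence
  `drop_samples`).
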