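---
title: "methyltrace: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methyltrace: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A tumor sheds DNA into plasma, so the cell-free DNA (cfDNA) of a cancer
patient contains a small admixture of circulating tumor DNA (ctDNA). Tumor
DNA carries a distinctive methylation profile: repeat-rich regions lose
methylation and particular promoter CpG islands gain it. At the sequencing
depths practical for screening (1-2x), a locus is covered by a handful of
reads, so cancer detection cannot rely on aggregate methylation fractions:
the signal must be read by read. methyltrace implements that read-level
strategy end to end: it discovers differentially methylated regions (DMRs)
from tumor/para-tumor tissue, cleans the tumor-tissue read set, trains a
small transformer to score each cfDNA read's probability of tumor origin,
and aggregates read probabilities into a per-individual cancer risk score.

## Pipeline stages and their statistics

### DMR discovery

Per CpG site, group-pooled methylated/total counts from tumor and
para-tumor tissue are compared with a two-sided Fisher's exact test
(conditional hypergeometric; our vectorised implementation is checked
against `stats::fisher.test` in the test suite). P-values are
Benjamini-Hochberg adjusted over all tested sites. A differentially
methylated CpG (DMC) must reach `q < 0.01` and an absolute pooled
methylation difference above 25 percentage points; its direction is hyper
or hypo according to the sign of (tumor - para-tumor). Consecutive
same-direction DMCs at most 300 bp apart form a run; runs of five or more
become DMRs. Intervening non-significant CpGs do not break a run — only the
gap rule, a direction change, or a chromosome change does. The DMR span is
`[first DMC, last DMC + 2)`, covering the final CpG dinucleotide.

Two choices here were genuinely open. The reference tool family leaves the
per-site test and the multiple-testing method configurable; we fixed
Fisher's exact on pooled counts (deterministic, no dispersion parameter to
estimate at desk-scale coverage) and BH (the field standard). Sites need a
pooled coverage of at least 5 in each group to be tested; below that the
fraction estimates are too unstable to interpret a 25-point difference.

### Noise reduction (MCS)

Resected tumor tissue contains normal, immune and vascular cells, so
"tumor-tissue reads" are a mixture and naive labelling would train the
classifier on noise. Each read is summarised by its Methylation Continuity
Score over the `L` CpGs it covers in the evaluated interval,

$$\mathrm{MCS} = \frac{\sum_i i^2\, n_i}{L^2},$$

where `n_i` counts maximal blocks of exactly `i` consecutive methylated
CpGs. MCS is 1 only for a fully methylated read and 0 for a fully
unmethylated one, and fragmenting a methylated block strictly lowers it, so
it rewards contiguous methylation rather than methylation level alone.

For every DMR, the MCS range `[S_min, S_max]` of healthy-cfDNA reads
defines the "normal" band. In a hypo-DMR, tumor-tissue reads with
`MCS >= S_min` look healthy and are removed; in a hyper-DMR, reads with
`MCS <= S_max` are removed. Only reads with actual calls at three or more
of the DMR's DMCs participate (on either side); reads below that carry too
little evidence and are excluded from the pool entirely. DMRs longer than
150 bp are processed in 150 bp windows at 50 bp steps; bounds are computed
per window from the healthy reads eligible in that window, and a tumor read
is removed if any window in which it is eligible flags it. The last window
is anchored at `end - 150` so every base is covered. A window with no
eligible healthy read imposes no filtering; a DMR with no usable window at
all is dropped.

### DMR screening (DUS)

Filtering survival varies across DMRs and individuals. The DMR Universality
Score,

$$\mathrm{DUS} = \frac{\sum_{i=1}^n t_i}{n} \times d,$$

combines the mean retained-read fraction `t_i` across the `n` individuals
that had reads in the DMR with the proportion `d` of individuals retaining
any read. Individuals with no reads before filtering are excluded from `n`
(their `t_i` is undefined). DMRs keep their place in training only with
strictly more than a minimum number of retained reads (200 at full scale);
survivors are ranked by DUS and the top 10,000 hypo-DMRs plus all
hyper-DMRs are selected. Ties in DUS break deterministically by retained
total, then genomic position.

### Methylation-aware encoding

In converted (enzymatic methyl-seq) space an unmethylated CpG reads "TG"
while a methylated CpG survives as "CG"; the recoder rewrites each
methylated "CG" as "ML", making methylation explicit in the sequence
alphabet. Reads are tokenized into overlapping k-mers behind a `[CLS]`
sentinel. We default to `k = 6`: the classifier's task couples a
methylation pattern to the locus it sits in (hypomethylation means tumor in
one DMR and healthy in another), and 6-mers carry enough flanking sequence
to identify the locus, which 4-mers at desk scale do not. The vocabulary is
built from the observed corpus (specials first, then lexicographic k-mers)
rather than enumerating the full 7^k space, because M and L occur only in
the "ML" digram and most strings are unrealisable. k-mers containing N, and
unseen k-mers at inference, map to `[UNK]`.

Masked-language-model pre-training uses the standard 15% random-token rule
plus a dedicated methylation rule: every token containing "ML" is
independently selected with probability 0.80 (methylated CpGs are 1-2% of
genomic tokens, far too rare for the 15% rule to teach). The two rules are
drawn independently and OR-ed, giving an expected selection rate of 0.83
for ML tokens; each selected token is replaced by `[MASK]` (80%), a random
vocabulary token (10%) or left unchanged (10%).

### The encoder

The classifier is a bidirectional transformer encoder in the BERT family:
token plus learned position embeddings, post-norm blocks of multi-head
scaled-dot-product self-attention
(`softmax(QK^T / sqrt(d_k)) V`) and a gelu feed-forward network, an MLM
head over masked positions, and a 2-class head on the final-layer `[CLS]`
state. The full-scale geometry (12 layers, 12 heads, hidden 768, ~110M
parameters) is constructible, but the package defaults to a desk preset —
2 layers, 2 heads, hidden 64, intermediate 256 — that trains in minutes on
one CPU. Everything, including backpropagation and the AdamW optimizer
(beta1 0.9, beta2 0.999, decoupled weight decay 0.01, dropout 0.1), is
implemented in base R matrix algebra; the gradients are verified against
finite differences in the test suite, attention rows are checked to be
probability vectors, and the initial MLM loss is checked against its
analytic value `ln |V|`. gelu uses the sigmoid approximation
`x * sigmoid(1.702 x)` (within ~1e-3 of the erf form at a fraction of the
cost). The published full-scale learning rate is 1e-4; desk-scale runs use
2e-3, two pre-training epochs and five fine-tuning epochs — the last number
matters because the individual risk score divides by a small denominator
(see below) and needs sharply calibrated per-read probabilities, not just
good ranking.

Fine-tuning labels retained tumor-tissue reads 1 and non-tumor cfDNA reads
0, splits 90/10 stratified by label, and trains all parameters. No class
weighting is applied (the pools are naturally within a factor ~2). Reads
are clipped to their DMR interval plus 8 bp of context before encoding:
bases outside the DMR are identically distributed in both classes and only
dilute the in-locus signal at desk-scale read counts. Sequences longer than
the 512-token position limit are tail-truncated.

### Individual risk score

With per-read tumor probabilities `p_i` and a ctDNA probability threshold
`t`, an individual's risk score is

$$\mathrm{RS} = \frac{\sum_{p_i > t} p_i}{\sum_i p_i},$$

the fraction of total predicted probability mass carried by confident ctDNA
reads. Thresholds are chosen by the four-fold scheme: individuals are split
into four stratified folds; in each round one fold tunes `(t, RS cutoff)`
by exhaustive grid search (`t` over 0.50-0.99 in steps of 0.01, RS cutoffs
at midpoints of observed scores) and the other three folds are classified
with the frozen thresholds. The search criterion is Youden's J; ties break
toward the smallest `t`, then the smallest cutoff. Per-round metrics are
summarised as mean with a normal-approximation 95% CI across the four
rounds. Metrics with empty denominators are reported as `NA`, never as 0.

Note the score's small-sample behaviour: for a negative individual the
denominator is the (small) summed probability of near-zero reads, so a few
false-positive reads can lift RS substantially. The threshold search
absorbs this — negative and positive RS distributions separate — but it is
the reason per-read probability calibration, not only AUC, matters.

### Spike-in simulation

Simulated cfDNA samples mix reads from an independent tumor tissue into
reads from independent non-tumor cfDNA at a nominal ctDNA fraction:
`round(fraction * total)` tumor reads per replicate, sampled without
replacement within a replicate, 100 replicates per fraction by default
(each replicate seeded as `seed + replicate`). Exact rounding is used — a
positive fraction whose rounded count is 0 yields a blank, by design. The
titration analysis reports per-fraction RS mean/sd, the Pearson correlation
of mean RS with fraction, and a rank-sum test of the lowest non-zero
fraction against blanks.

## What the synthetic data emulates — and what it does not

The generator builds a reference of 20 regions x 5 kb, each with one
centred 400 bp CpG-dense locus (density 0.10 vs 0.01 background; 12
tumor-hypomethylated, 8 tumor-hypermethylated). Background sequence is
CpG-depleted (accidental CG dinucleotides are removed) so that site density
matches the configuration; background CpGs are methylated at 0.75 in every
class, while locus methylation separates classes at 0.9 vs 0.1. Reads are
uniform fragments of 100-290 bp; per-CpG states flip with probability 0.02;
unmethylated cytosines (CpG and non-CpG) convert to T with completeness
0.995; sequencing errors substitute bases at 0.002. CpG calls are derived
from the final converted sequence, so emitted calls are always consistent
with the read (as they are for a real methylation caller). The cohort is 10
tumor/para-tumor tissue pairs (tumor purity 0.8), 6 healthy-reference
cfDNA samples, and a 30-individual validation cohort (8 healthy, 7 liver
disease, 15 HCC at ctDNA fractions 0.10-0.20), 2,000 reads per sample,
fully deterministic under one seed.

Class methylation parameters are deliberately far apart, so green tests
demonstrate pipeline correctness, not statistical power. The generator does
not mimic the human genome's sequence composition, fragment-end biology
(jagged ends), GC or coverage bias, or the far smaller ctDNA fractions of
early-stage disease; passing tests therefore say nothing about clinical
sensitivity. Likewise the desk-scale run sizes everything down: at the
synthetic coverage (~4x per sample) a DMR accumulates only ~120 tumor reads,
so end-to-end runs use a retained-read cutoff of 50 in place of the
full-scale 200, 1,500 pre-training reads, and the desk model preset. The
problem sizes were chosen so the whole study — generation, discovery,
denoising, training, scoring, titration — completes in roughly ten minutes
on a single CPU.

## Numerical and degenerate-case choices

- Fisher p-values sum hypergeometric densities `<= observed * (1 + 1e-7)`;
  the relative tolerance guards ties against floating-point noise (same
  convention as `stats::fisher.test`).
- `MCS` on zero CpGs, `DUS` on zero individuals and `RS` on zero reads are
  errors, not silent zeros; `RS` with all-zero probabilities returns 0 with
  a warning.
- Overlapping mates merge by taking the union of calls; where the mates
  disagree at a shared CpG, read 1 wins and the conflict is counted in an
  attribute — deterministic and auditable, since the upstream convention is
  unstated.
- Softmax rows subtract the row maximum before exponentiation; layer norm
  uses eps 1e-5; `[PAD]` key positions are excluded from every attention
  row (a padded tail provably does not change the `[CLS]` logit).
- Screening and threshold-search ties break deterministically (documented
  above), so re-runs are reproducible without a seed.

## An example session

```{r example}
library(methyltrace)
cohort <- synth_cohort(synth_config(seed = 11))
res <- run_pipeline(cohort, seed = 11, min_retained = 50, verbose = TRUE)
res$risk$summary          # per-metric mean and 95% CI over the four rounds
```

## Known limitations

- The per-site test pools counts within groups, discarding between-sample
  variability; a per-sample regression mode would be the next step for
  noisy cohorts.
- The transformer runs one sequence at a time in R; it is fast enough for
  the desk preset but the full-scale geometry would need a compiled or
  GPU-backed path.
- `RS` is volatile when an individual has very few in-DMR reads; the
  cross-fold threshold search assumes validation and tuning individuals
  have comparable read counts.
- Duplicate marking and alignment are assumed done upstream; the loader
  honours duplicate/secondary flags but does not re-deduplicate.
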