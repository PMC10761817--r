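---
title: "Models and methods behind poolscreen"
author: "poolscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`poolscreen` analyses pooled CRISPR knockout screens of the GeCKO type, in
which a library of 20-nt single-guide RNAs is transduced into a cell
population at single-copy multiplicity, the population passes through one or
more selective regimes (here: mammosphere clone formation and mammary fat-pad
transplantation), and the surviving guide spectrum is read out by amplicon
sequencing. The package covers the dry half of such a screen end to end:

1. a **synthetic screen generator** with known per-gene fitness and per-guide
   efficiency (the ground truth against which everything else is scored);
2. **shift-tolerant sgRNA quantification** from FASTQ;
3. **per-guide enrichment testing** and **alpha-RRA gene aggregation**;
4. a **four-criterion candidate-gene filter** over the screen's sample
   hierarchy.

This vignette records the models, the defaults and the reasoning behind the
design choices that were genuinely open.

# The synthetic screen

## Generative chain

The simulator mirrors the sample hierarchy of a two-arm screen: a plasmid
pool, a transduced cell library, small and large clones from a sphere assay,
and regenerated tissues from transplantation.

* **Plasmid pool.** Guide frequencies are drawn from a symmetric
  Dirichlet with concentration 5, giving a coefficient of variation of about
  0.45 — the skew typical of pooled plasmid preps.
* **Transduction bottleneck.** The cell library is one multinomial draw of
  `bottleneck_cells` from the plasmid frequencies; the default is 100 cells
  per guide, matching the roughly 100-fold coverage at which such screens
  are infected.
* **Knockout and selection.** Each guide's lineage carries a functional
  knockout with probability equal to the guide's efficiency (one Bernoulli
  draw per screen). A functional knockout of gene $g$ multiplies the
  lineage's relative weight by $e^{f_g}$ per passage; selected samples
  (large clones, tissues) therefore reweight the cell-library frequencies by
  $e^{f_g \cdot \text{passages}}$ and renormalise. Small clones are neutral
  passages. With $f = \ln 2$, efficiency 1 and 3 passages, a hit guide's
  pre-normalisation frequency ratio between tissue and cell library is
  exactly $2^3 = 8$ — the ground truth stays analytic because selection is
  deterministic exponential reweighting, not a branching birth–death
  process. The pipeline under test consumes count ratios only, so the extra
  realism of demographic noise would buy nothing but an intractable truth.
* **Sequencing.** Every sample is an independent multinomial draw of
  `depth_per_sample` reads (default $2\times10^5$, about 300 reads per guide
  for the default 650-guide library).

What this simulator does **not** model: MOI optimisation, PCR chimeras,
clone-to-clone demographic noise within a sample, batch effects between
sequencing runs, and the single-lineage character of a literal clone (a real
"large clone" sample is dominated by one lineage; here selected samples are
population-level reweightings). Passing the recovery benchmarks therefore
shows that the statistical machinery is correct and calibrated under the
stated model, not that it is robust to every pathology of real screens.

## Read emission

Amplicon reads place the guide canonically at base 23, drifting by up to
±10 bases — the positional shift that motivates the quantifier. Reads are
synthesised as: 5' flank (outer PCR primer plus U6-style vector context
ending in the `ACCG` cloning scar), guide, invariant sgRNA scaffold,
truncated to 60 bases. The jitter is uniform over the configured range
(a range is reported for real data, not a distribution; uniform is the
maximum-entropy choice) and clipped so the guide stays within the read —
*not* within the matcher's legal window, because shifts that leave the
window are exactly the loss mode worth reproducing end to end.

Error structure and defaults, chosen once for an Illumina-like run on
low-complexity amplicons: substitutions at 0.002 per base; 0.5% of reads
carry a 1-base indel inside the guide; 5% are junk (random sequence).
Quality strings are constant: the matching rule ignores quality, so
modelling quality would only decorate the FASTQ. A sidecar table records
each read's source guide, jitter, substitution count and indel/junk flags,
which lets tests score the quantifier read by read.

# Shift-tolerant quantification

A guide matches a read if its 20-mer aligns ungapped within read positions
15–50 (so legal starts are 15–31), with at most one mismatch and no indels
in the aligned region. Note the deliberate asymmetry with the emitter: the
canonical start 23 ± 10 spans starts 13–33, but the acceptance window stops
at 15–31; reads shifted beyond it are counted as unassigned, as they would
be in a real run.

Search is exact: an index stores each guide's two 10-mer halves, and by the
pigeonhole principle any match with ≤1 substitution preserves at least one
half verbatim; half hits are verified against the full guide. Every legal
start is evaluated. Selection is maximum identity first (0-mismatch
candidates strictly dominate 1-mismatch ones), then uniqueness: if the
best-level candidates name a single guide the read is assigned (earliest
start recorded); if they name two or more guides it is **ambiguous** and
discarded — a read increments at most one guide, so column sums equal
assigned-read tallies by construction. Reads matching nothing are
unassigned; no separate adapter-trimming pass is needed because a read
whose guide was destroyed or displaced simply has no in-window match.

Two boundary subtleties are worth recording. First, synthetic libraries are
generated with pairwise Hamming distance ≥3 so one-mismatch assignment is
unambiguous by construction; real genome-scale libraries do not guarantee
this, so ambiguity handling is exercised with planted near-duplicate pairs
(Hamming 1 and 2) instead. Second, an indel at the guide's first or last
base is indistinguishable, under ungapped comparison, from a shift or a
terminal substitution, and such reads are legitimately recovered; only
interior indels are rejected. The whole matcher is verified exactly —
status, guide, start and mismatch count — against an independent
brute-force scan of every guide at every offset.

# Enrichment testing

## Per-guide statistic

For a treatment/control sample pair, counts are scaled by median-of-ratios
size factors (over guides nonzero in both samples; control-guide-restricted
and total-count variants are available). With pseudocount $c$ (default 1)
and normalised counts $t'_i, c'_i$, the statistic is the centred,
standardised log ratio

$$ z_i = \frac{d_i - \mathrm{median}(d)}{\sqrt{v_i + 2\hat\varphi}},
   \qquad d_i = \ln\frac{t'_i + c}{c'_i + c}, $$

where $v_i$ is the Poisson-level variance of the log ratio evaluated at the
pooled mean count of the pair — evaluating it at the observed counts
instead would shrink the variance exactly when the ratio fluctuates
upward and inflate the upper tail — and $\hat\varphi$ is a pooled
method-of-moments overdispersion: the mean excess of $(d_i - m_0)^2$ over
$v_i$ across all guides, upper-trimmed by 10% so a minority of true hits
cannot inflate it, halved because the dispersion enters once per sample,
floored at zero.

One-sided p-values (enrichment only; the screen selects positively) come
from the standard normal reference by default. An empirical null built from
the non-targeting controls' scores is available
(`null_method = "control_empirical"`): its survival function is linearly
interpolated through the plotting positions $(M+1-j)/(M+1)$ — the
continuous analogue of a mid-p — with a Gaussian fitted to the control
scores extending both tails beyond the observed range, and an automatic
fallback to the all-guide null below 20 controls. The parametric reference
is the default for a reason worth stating: with $M$ control guides the
estimated 5% tail quantile of an empirical null carries sampling error of
order $\sqrt{0.05 \cdot 0.95/M}$ — at $M = 50$ that is ±3 percentage
points on a 5% test, an order of magnitude more miscalibration than the
Gaussian approximation it would replace. The controls still earn their
keep: they are the natural reference set for the dispersion and for
diagnostics, and the empirical option is there for screens whose score
distribution is visibly non-Gaussian and whose control set is large.

Benjamini–Hochberg FDR is applied within each comparison separately
(the candidate filter consumes comparisons independently, so pooling would
only couple unrelated decisions); a guide is **enriched** iff its FDR is
below 0.05 and its log2 fold change is positive.

## Gene aggregation

Gene-level significance uses alpha-RRA-style rank aggregation. All guides
(controls included — they anchor the ranking universe) are ranked by
p-value with average ranks for ties, giving normalised ranks $r = \text{rank}/N$.
For a gene with $n$ guides, only guides with $p < \alpha$ (default 0.25)
are retained; with retained ranks sorted ascending, the score is

$$ \rho = \min_k \; P\!\left(\mathrm{Beta}(k,\, n-k+1) \le r_{(k)}\right), $$

and 1 if nothing passes $\alpha$. Significance comes from $B = 1000$
permutations of the guide-to-gene labels (which preserves each gene's guide
count). The reported p-value is the exact smoothed permutation p

$$ p = \frac{\#\{b: \rho_b < \rho\} + U\,(1 + \#\{b: \rho_b = \rho\})}{B+1},
   \quad U \sim \mathrm{Unif}(0,1), $$

floored at $1/(B+1)$ and deterministic under the run seed. The textbook
$(1 + \#\{\rho_b \le \rho\})/(B+1)$ form was deliberately not used: genes
with no guide below $\alpha$ all score exactly 1, and under the default
$\alpha$ about $0.75^6 \approx 18\%$ of null genes sit in that atom, so the
conservative form concentrates 18% of probability mass at $p = 1$ and is
visibly non-uniform under the null. The smoothed form is exactly uniform,
ties occur only at that uninteresting atom, and the candidate filter never
consumes the gene p-value — it relies on enriched-guide counts — so the
auxiliary randomisation cannot flip a candidate.

# Candidate selection

A gene is a final candidate iff all four hold:

1. ≥2 of its guides enriched in **some** large clone vs the cell library;
2. ≥2 enriched in **some** large clone vs a small clone;
3. ≥2 enriched in **every included** tissue vs the cell library — tissues
   flagged excluded in the design (poor library quality) are skipped;
4. the gene is basal-biased: basal expression ≥ 1.5 × luminal expression.

The existential/universal split in 1–3 follows the screen's logic: one
strongly selected clone is evidence, but an in-vivo hit should reproduce in
every usable transplant. The 1.5 ratio in criterion 4 operationalises
"higher in basal than luminal", for which only the direction is given by
the screen's biology; it is configurable, and the synthetic expression
generator guarantees spiked hits exceed it so that recovery benchmarks test
the screen statistics rather than the expression threshold. Clone-vs-small
pairing is explicit in the design table (by order, recycled), since pooled
designs leave the pairing convention open. A gene missing from the
expression table fails criterion 4 with a warning rather than an error —
in real data that is an annotation gap, not a pipeline failure.

The Fig.-S1-style summary tabulates, per comparison, genes with exactly 1,
exactly 2 and ≥3 enriched guides, and per gene the proportion of
comparisons in which it has any enriched guide.

# Numerical and reproducibility choices

* One master seed; every stochastic stage derives its own stream via a
  stable arithmetic hash of the stage name, so adding a stage never
  perturbs another's draws. Two runs with the same configuration are
  byte-identical in all analysis artifacts.
* Degenerate inputs: empty FASTQ gives an all-zero column; malformed FASTQ
  records fail hard with the record index; an empirical null with identical
  control scores errors with advice rather than silently producing ties;
  normalisation refuses matrices with no all-nonzero guide.
* Library generation rejects parameter sets where Hamming-≥3 sampling
  stalls (bounded attempts) instead of looping forever.
* Benchmark problem sizes: the calibration and recovery suites use
  100 genes × 6 guides + 50 controls at $2\times10^5$ reads/sample over 20
  seeds, and the determinism check uses a smaller FASTQ-routed
  configuration (40 genes, 2 000 reads/sample) — sizes at which every
  property under test is already at its asymptotic behaviour while the
  whole suite stays interactive.

# Known limitations

* Depletion (essentiality) analysis is out of scope; tests are one-sided.
* No copy-number correction, no paired-sample designs, no UMIs.
* Gapped (indel-tolerant) guide recovery is deliberately absent: the
  counting rule is ungapped by definition, and reads with interior indels
  in the guide are evidence of synthesis or sequencing failure, not signal.
* The control-guide empirical null is coarse below ~100 controls; prefer
  the default parametric reference there.
* The simulator's selected samples share one latent frequency vector per
  role; replicate tissues differ only by multinomial noise, which
  understates biological replicate-to-replicate variance.
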