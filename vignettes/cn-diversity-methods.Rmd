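---
title: "Methods: windowed CN calling and population CN diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed CN calling and population CN diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvdiv)
```

# The analysis in one paragraph

`cnvdiv` quantifies copy-number (CN) variation across a cohort of yeast
strains from windowed read-depth data and asks which loci are *CN diverse* —
variable in copy number across the population. Depth per fixed window
(250 bp by default) is corrected for GC bias and normalized to a CN ratio;
contiguous non-neutral windows become candidate CN variable regions (CNVRs),
retained when a rank-sum test separates them from the neutral background.
Per-strain calls are pooled into union loci; each locus gets two diversity
scores across strains — the log10 of the sample variance of CN, and the
polymorphic information content, `PIC = 1 - sum(f_i^2)` over CN-allele
frequencies `f_i` — and loci in the top half of either score form the
CN-diverse set, which is then placed in genomic context (subtelomeric,
pericentromeric, interstitial). Everything is exercised against a synthetic
multi-strain simulator with known ground truth.

# The caller

## Normalization model

For window $w$ with depth $d_w$ and GC content $g_w$, the CN ratio is

$$ r_w = \frac{d_w / \tilde{d}_{\mathrm{bin}(g_w)}}{\mathrm{median}_w\, (d_w / \tilde{d}_{\mathrm{bin}(g_w)})} $$

where $\tilde{d}_b$ is the median depth of the windows falling in GC bin $b$
(25 equal-width bins across the observed GC range). Reference medians exclude
windows within 7 kb of a chromosome end or centromere, where depth is
unreliable in practice; those windows still receive ratios and can be called.
The binned-median estimator was chosen over local regression deliberately:
it is hyperparameter-free, exactly reproducible, and robust to the CN
variants themselves (medians, not means). An empty bin falls back to the
global median with a warning. The final rescaling forces the genome-wide
median ratio to 1, which makes the whole procedure invariant to multiplying
all depths by a constant (sequencing effort).

Integer CN states use symmetric round-half-up: $s_w = \lfloor r_w + 0.5
\rfloor$, so ratios in $[0.5, 1.5)$ are the neutral state 1. Baseline CN is 1
copy *relative to the reference genome* — no diploid doubling — so a
deletion carrier has CN 0 and a duplication carrier CN $\ge 2$.

## Segmentation

Candidates are maximal runs of consecutive windows on the same side of
neutral (all states $>1$, or all $<1$); runs shorter than `min_windows`
(default 2, i.e. 500 bp) are dropped, and the region CN is round-half-up of
the *mean ratio* over the run. Grouping by side rather than by identical
state is intentional: at 30x coverage a CN-4 window misrounds to 3 or 5
roughly one time in five, so identical-state runs would shatter real events,
while the run-mean ratio estimates the region CN accurately (its standard
error shrinks with run length). The cost is that two distinct events of the
same sign abutting with no neutral window between them would merge; the
simulator never produces that configuration and it is rare in real data at
these event densities.

## Significance filtering

Each candidate's window ratios are compared with the same chromosome's
neutral windows (state 1, outside the candidate) by a two-sided Wilcoxon
rank-sum test with continuity correction (exact null for small samples, the
`stats::wilcox.test` default); candidates are kept at $p < 0.05$. If a
chromosome has no neutral windows the comparison falls back to genome-wide
neutral windows.

A limitation worth stating plainly: the test is applied to candidates
*selected* for being non-neutral, so for very short candidates it has little
discriminating power — a 2-window candidate against a large neutral pool
cannot exceed $p \approx 0.014$, and noise runs of two high windows pass at
$\alpha = 0.05$. With default settings the caller therefore admits a small,
quantifiable stream of 2-window false duplications (about 3-4 per strain at
30x on a 3 Mb genome). When the analysis targets a known minimum event size
— as in the parameter-recovery benchmark, built on events of at least 4
windows — `min_windows` should be set to that size class, which removes
essentially all such false calls (measured precision 0.993, recall 0.969 at
reciprocal overlap 0.8).

# Diversity scoring

Loci are connected components of overlapping CNVR intervals pooled across
strains (half-open intervals; 1 bp overlap connects, abutment does not).
Every strain contributes a value at every locus — baseline 1 where it has no
call — because allele frequencies are population frequencies, not carrier
frequencies. Two scores per locus:

* `log10(s2)`: log10 of the sample variance (n−1 denominator). Monomorphic
  loci have `s2 = 0` and are excluded from this score's percentile pool
  (log undefined).
* `PIC = 1 - sum(f_i^2)`: sensitive to both the number of CN alleles and the
  evenness of their frequencies; 0 for monomorphic loci, at most `1 - 1/n`.

A locus is *CN diverse* when it is at or above the median (midpoint
interpolation for even counts; ties inclusive) of either score. The
inclusive `>= median` reading implements "top 50%" so that fully tied score
vectors flag every locus rather than none.

Genic CN is the unweighted mean of the integer states of all windows
overlapping the gene by at least 1 bp (partially overlapping windows count
fully; a base-weighted mode exists behind the `weighted` flag for
sensitivity analysis). For discrete-allele scoring, genic CN is binned with
round-half-up. Gene-level diversity restricts the percentile pools to genes
harboring at least one CN variant (`variable_only = TRUE`); otherwise the
invariant majority would drag both medians to the degenerate minimum and the
top-50% rule would saturate.

# Genomic context

Two subtelomere definitions are materialized: definition A, a fixed span
(25 kb) from each chromosome end; definition B, from each end to the first
essential gene, which requires essential-gene anchors and errors without
them. The pericentromere is the centromere ± 7 kb, matching the
normalization mask. Classification uses the same 1 bp overlap rule, with
subtelomeric taking precedence over pericentromeric for loci touching both
(possible on short chromosomes), because subtelomeres are the headline
category in this analysis. A chromosome with no essential gene is wholly
subtelomeric under definition B (with a warning) — the definition's honest
limiting case.

# The simulator

`simulate_population()` emulates the statistical structure of a wine-yeast
cohort, not its sequence content:

* **Events.** `n_loci` non-overlapping events, subtelomeric (fully within
  25 kb of an end) with probability `p_subtelomeric`, otherwise uniform in
  interstitial space; never touching a centromere, so context labels of
  truth events are unambiguous. The subtelomeric/interstitial decision is
  drawn once per event and kept through placement retries, making the
  realized subtelomeric fraction an unbiased binomial draw; an infeasible
  request errors out rather than silently drifting.
* **Sizes.** Duplications lognormal (meanlog `log(700)`, sdlog 0.8 — about
  two thirds at or under 1 kb); deletions a 35/65 mixture of short
  (500-1000 bp) and long (uniform 5-7 kb), giving the deletion mode in the
  5-7 kb bin. Sizes snap to the window grid with a 2-window floor, because
  the caller's resolution is the window grid.
* **Population structure.** Each locus draws a carrier frequency from
  Beta(0.8, 0.8) — a bathtub shape producing both rare and common CN
  alleles, which is exactly what PIC must discriminate. Carriers of a
  deletion get CN 0; carriers of a duplication get 1 + a truncated-geometric
  number of extra copies (cap 6), so duplication loci are multi-allelic.
  Carriers are redrawn (bounded) until at least one strain carries the
  event, mirroring the ascertainment of loci as variable in >= 1 strain.
* **Depth.** Window depth is negative binomial with mean
  `base_depth * CN * gc_factor(gc_w)` and size (dispersion) 100 — a
  coefficient of variation of about 0.21 at 30x, modestly above Poisson, as
  observed for short-window coverage after mapping. CN-0 regions emit a 2%
  residual depth emulating mismapping background. GC per window is a smooth
  random field in [0.30, 0.60]; the GC factor is unimodal, centered at GC
  0.45, and normalized to mean 1 across the genome so that genome-average
  depth at CN 1 equals `base_depth` while individual windows remain biased —
  precisely the distortion the caller's GC correction must undo.

Defaults (132 strains, 2820 loci, 30x, duplication probability 0.4,
subtelomeric probability 0.45) describe the cohort scale the package is
aimed at. What the simulator does **not** model: real sequences and
mappability, SNPs, partial-window breakpoints, Ty-element context of
deletions, loci absent from the reference, or correlated population
structure among strains. Passing the recovery benchmarks therefore
demonstrates correctness of the windowed-CN semantics and the diversity
arithmetic under realistic count noise — not robustness to alignment
artifacts.

# Numerical and degenerate-input choices

* Round-half-up everywhere a ratio becomes an integer CN; documented tie
  rule, symmetric around each integer.
* Medians with midpoint interpolation (R default) for percentile cuts.
* Tracks with more than 50% zero-depth windows are rejected as corrupt.
* A completely tied duplication/deletion count comparison reports p = 1
  (the normal approximation degenerates; no evidence either way).
* Empty inputs: empty truth tables round-trip as header-only files;
  `inframe_fraction` and `context_summary` warn and return NA-valued
  results rather than failing.
* All coordinates are 0-based half-open internally and in BED outputs;
  GFF3 input is converted on read.

# Problem sizes used by the test suite

The suite simulates at desk scale, chosen to keep the full run under a
minute while leaving the statistical assertions well-powered: recovery
benchmarks use 20 strains x 4 chromosomes x 750 kb with 60 events (about
240k windows cohort-wide), calibration uses 1000 replicate null candidates
against 250-window neutral pools, the subtelomeric-recovery check uses the
16-chromosome yeast-scale layout with 200 events, and the demonstration
pipeline runs 5 strains x 2 chromosomes. Oracle-equivalence checks
(per-base genic CN, union-find locus components, per-base context labels,
exact rank-sum enumeration) run on small randomized instances where the
brute-force reference is affordable.

# Known limitations

* Breakpoints are window-quantized; no sub-window refinement.
* The significance filter is weak for candidates of fewer than ~3 windows
  (see above); interpret 2-window calls accordingly or raise `min_windows`.
* Diversity measures ignore sequence divergence between copies.
* The union-locus construction lets one strain's large CNVR bridge loci
  that are distinct in other strains; with window-quantized, non-recurrent
  simulated events this is rare, but on real data recurrent breakpoint
  heterogeneity can chain loci together.
* No mappability model and no control-sample mode.
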