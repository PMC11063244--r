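---
title: "Cross-species co-expression analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species co-expression analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocoar)
```

## The problem

Fungal stress responses are often studied one species and one stressor at a
time, so transcriptome datasets accumulate that were never designed to be
compared. Yet genes whose up-regulation recurs across species and stressors
are exactly the candidates for conserved stress regulators. `cocoar`
implements a comparative strategy for finding them: take several published
differential-expression (DE) result tables from related species, re-express
each up-regulated gene list in the gene space of one *receiver species*
through orthogroup membership, intersect the transposed sets exhaustively,
and overlay protein-domain annotations on the genes supported by many
datasets. In aspergilli this style of analysis singles out genes such as the
NmrA-like regulator whose up-regulation recurs across chemically unrelated
stress exposures.

## The transposition model

Orthology is taken as given: an OrthoFinder-style table partitions the
multi-species gene inventory into orthogroups, each gene belonging to at
most one. For a dataset from source species $s$ with significant gene set
$D_s$, the transposed set in receiver space $r$ is

$$T_r(D_s) \;=\; \bigcup_{g \in D_s} \{\,g' : g' \in \mathrm{og}(g) \text{ and } \mathrm{species}(g') = r\,\},$$

i.e. a source gene *fans out* to every receiver member of its orthogroup.
This one-to-many policy is deliberate: when a receiver species holds two
in-paralogs in one orthogroup, both are legitimate candidates and both
appear in reports (a `collapse_to_og` flag replaces genes by orthogroup
ids when a coarser unit is wanted). Genes with no orthogroup, or whose
orthogroup has no receiver member, are kept in the provenance table with
their reason rather than silently dropped. Dataset membership of a receiver
gene is binary, no matter how many source genes reached it.

When a dataset already comes from the receiver species, the default is the
identity mapping restricted to the receiver inventory rather than the
orthology route. The alternative (forcing such genes through orthogroups)
would drop receiver genes that sit in no orthogroup, which is hard to
justify when no translation is actually needed; the switch
`identity_for_receiver = FALSE` restores the strict behaviour for
sensitivity analysis.

The Venn decomposition assigns every gene of the union to exactly one
region — the exact subset of datasets containing it — so region sizes sum
to the union and "present in at least $k$ datasets" reports nest
monotonically in $k$. Signatures are canonicalised by the manifest's label
order and ties in reports are broken lexicographically by gene id, making
outputs bit-reproducible.

## Significance filter

A gene counts as up-regulated when its log2 fold change strictly exceeds 1
and its adjusted p-value is present and strictly below 0.05 (both
configurable per dataset in the manifest, since published lists may have
used slightly different cutoffs). Strictness follows the literal reading of
"more than" a one-unit log2 change. Rows with missing adjusted p-values —
routinely produced by independent filtering in DE pipelines — are excluded
because significance cannot be certified, and the reader reports how many
cells failed to parse. Duplicate gene rows are resolved to the
smallest-p-value row before filtering, a deterministic and conservative
choice.

Dataset eligibility mirrors the selection rules of the study design this
package serves: genus on an allowed list, exposure strictly under six days,
compound molar mass strictly under 500 g/mol; `validate_dataset()` reports
every failing rule, not just the first.

## Assay quantifications

**Gompertz EC50.** Radial-growth inhibition series are fit with the
three-parameter decreasing Gompertz form
$f(x) = A\,e^{-e^{s(x-m)}}$, where $A$ is the asymptotic response at zero
dose (response units), $s > 0$ the steepness (per concentration unit) and
$m$ the inflection location (concentration units). The half-maximal
concentration relative to the asymptote has the closed form
$\mathrm{EC}_{50} = m + \ln(\ln 2)/s$, which makes the estimator directly
testable against synthetic series. Spreadsheet dose-response tools do not
document their exact Gompertz parameterisation, so this form was chosen
for its closed-form EC50; when a measured zero-dose control is supplied,
the concentration at half the *control* is reported alongside. Starting
values are $A_0 = \max y$, $m_0$ at the concentration nearest half-max,
$s_0 = 4/\mathrm{range}(x)$; three deterministic jittered starts (scaling
$s_0$ by 1, 4 and 0.25) guard against local minima on steep series and the
lowest-RSS fit wins. Monotone increasing responses are rejected outright —
a decreasing dose-response model is then inapplicable. Fits use
Levenberg-Marquardt least squares; on noiseless 12-point series the EC50 is
recovered to well under 0.1%, and under 5% Gaussian noise the median EC50
error stays below 5% over 100 seeded series.

**MIC.** The minimum inhibitory concentration is the lowest tested
concentration with no visible growth; growth everywhere yields `NA`
("MIC beyond the tested range"). Non-monotone patterns (growth above a
no-growth well, e.g. from skipped wells) trigger a warning but the literal
definition still applies — requiring monotonicity would silently change
the quantity being reported.

**Relative expression.** `ddct_fold_change()` returns
$2^{-\Delta\Delta C_t}$ with the target normalised to a reference gene
(e.g. histone H2B) and a calibrator condition, assuming 100% amplification
efficiency, because thermocycler summary output provides no per-assay
efficiency model. Replicate Cq values should be averaged before the
quartet is formed. The statistic is invariant to adding a constant to all
four Cq values. `normalize_to_control()` rescales measurements so the
control maps to 100 (or any chosen scale), as used for fluorescence-based
ROS readouts and for MIC ratios.

## The synthetic study

The generator exists so the whole pipeline can be exercised with known
ground truth, at the scale of a realistic eight-genome orthology analysis
but without any downloads.

*Orthogroups* come from a gene-family birth-death process on an
ultrametric eight-taxon species tree with unit root-to-tip depth (the tree
is configurable; published branch lengths for the real eight genomes are
not tabulated, so a clock-like shape was fixed once). Each of $F$ root
families starts as one gene; along a branch of length $t$ a gene survives
with probability $e^{-\mu t}$ and accrues $\mathrm{Poisson}(\lambda t)$
duplicates, and new families arise as $\mathrm{Poisson}(\gamma t)$ per
branch. An orthogroup is the clan of one founding family — matching the
granularity of orthogroup inference at the species-set root — so
duplications create within-orthogroup paralogs (the two-receiver-paralogs
situation) and families gained on terminal branches become species-specific
orthogroups. Defaults are $F = 2000$, $\lambda = \mu = 0.05$,
$\gamma = 0.02$: enough families that five datasets across three species
give a realistically sized union, duplication/loss rates low enough that
most orthogroups stay near single-copy (as in real aspergilli cores), and
a small gain rate so species-specific orthogroups exist but stay rare.

*DE datasets* follow the five-datasets-across-three-species design of the
motivating study (one dataset in the receiver species, one in a relative,
three in a third species), each with background responder probability
$p = 0.05$ — a typical fraction of a genome passing an up-regulation filter
in a stress exposure. All members of a *planted* orthogroup draw from a
responder model (log2FC ~ U(1.5, 4), padj ~ U($10^{-6}$, $10^{-3}$)) that
passes the filter with certainty; every other gene is independently a
responder with probability $p$, and non-responders draw padj from
U(0.05, 1) so they never pass. With one-to-one orthology the expected
number of background genes in the full $N$-way intersection is
$G\prod_i p_i$, which the acceptance suite checks against a 99% binomial
envelope over 200 seeds; with defaults the planted receiver orthologue is
recovered at $k = N$ in well over 95% of seeds and is usually the unique
hit — the synthetic analogue of a single gene surviving a five-dataset
intersection.

All generators take an integer seed, are byte-identical under it, and
restore the caller's RNG state. What the simulator does *not* emulate:
correlated responses between datasets (shared pathways), orthology
inference errors, fold-change-dependent significance, or compositional
biases of real DE pipelines. Passing the synthetic recovery tests
therefore demonstrates the bookkeeping of transposition and intersection
is correct, not that real datasets satisfy independence.

*Domain annotations* assign each gene Poisson-many accessions drawn
without replacement from a synthetic vocabulary — enough structure to
exercise the overlay and frequency tallies.

## Numerical and degenerate-input choices

Percentages in genome summaries are reported to one decimal place. The
"share of genes in species-specific orthogroups" is denominated over *all*
genes by default (unassigned genes included), with the
assigned-genes-only variant reported alongside, since the phrasing of such
summary figures is ambiguous in the literature. A species with zero genes
makes percentages undefined and errors. Empty DEG lists, empty orthogroup
tables and empty annotations all flow through without error and produce
empty outputs. Malformed newick, duplicate gene assignments, duplicate
dataset labels, and out-of-range $k$ all fail fast with named offenders.

## Problem sizes used by the test suite

Unit tests run on hand-built tables of a few dozen genes. Property checks
use randomized instances up to 6 datasets and 500 genes for the Venn
oracle, 1000-row DE tables for filter equivalence, 500 families for the
loss-rate calibration, 100 seeds of the default 2000-family bundle for
planted-gene recovery, and 200 seeds of a 5000-gene one-to-one world for
the background envelope. These sizes give stable statistics while keeping
the whole suite fast.

## Known limitations

- Orthology is consumed, never inferred; errors in the input table
  propagate directly into transposed sets.
- The Gompertz EC50 is defined relative to the fitted asymptote; series
  whose observed control differs materially from $A$ should use
  `control_response` and compare both EC50 flavours.
- ΔΔCt assumes equal amplification efficiencies of target and reference.
- The Venn decomposition is exact and exhaustive but counts only; no
  graphical Venn rendering is provided beyond the region bar chart.
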