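---
title: "Methods: seed-site SNP survey, enrichment and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-site SNP survey, enrichment and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the modeling and design choices behind
`mressnp`: the site model and its coordinate conventions, the proxy
duplex scorer, the enrichment null, the population-genetic estimators,
what the synthetic-data generator does and does not emulate, and the
numerical details (tolerances, tie-breaks, degenerate inputs) a
maintainer needs.

## The site model

A mature miR binds its target antiparallel; the bases that matter most
are miR positions 2–7, the seed. We classify an 8-position frame of a
3'UTR (written mRNA 5'→3') against four canonical classes:

* **6mer** — the frame's positions 2–7 equal the reverse complement of
  miR positions 2–7;
* **7mer-A1** — 6mer plus a literal `A` at frame position 8. The A1
  position is an adenine *on the mRNA* regardless of miR position 1,
  reflecting the preference for an A opposite the first miR base rather
  than pairing with it;
* **7mer-m8** — 6mer plus the complement of miR position 8 at frame
  position 1;
* **8mer** — both.

Classification returns the *maximal* class under
8mer > 7mer-m8 > 7mer-A1 > 6mer. The frame is fixed at 8 positions for
every class (a 6mer occupies frame positions 2–7), which keeps
"position in MRE" well-defined for all classes. All internal sequence
handling is in the DNA alphabet; `U` is mapped to `T` at ingestion
because variant coordinates and alleles are genomic.

**Coordinates.** Internally 1-based inclusive (the dbSNP convention);
BED input/output is 0-based half-open. Minus-strand UTRs are handled as
mRNA-strand sequences and mapped back through their placement, so a
frame at mRNA offset $i$ of a minus-strand UTR ending at genomic $e$
spans $[e-i-6,\,e-i+1]$.

**Position-in-MRE numbering.** Two conventions exist: numbering by miR
position (position $k$ is the mRNA base pairing miR position $k$, so
position 1 is the 3'-most base of the site) or along the mRNA 5'→3'.
We default to miR-position numbering, which matches the A1/m8
terminology, and expose `numbering = "mrna"` on `snp_in_site()` and
`classify_disruption()` to flip it; the two are related by
$k \mapsto 9-k$.

**Disruption verdicts** come from re-classifying the frame with each
allele substituted (complemented onto the mRNA strand for minus-strand
sites): `abolished` (any class → none), `downgraded`, `unchanged`,
`upgraded`. A SNP under two overlapping sites yields one call per
interaction — counts are per miR–mRNA interaction, not per SNP. A
reference allele that contradicts the UTR base is a data-integrity
error, not a silent skip.

**Conservation filters.** PhastCons and mirSVR scores are consumed as
input annotation (per-site columns), never computed; the defaults
(keep PhastCons ≥ 0.57, mirSVR ≤ −0.6) correspond to
mammalian-conservation and top-of-distribution score cutoffs for
predicted sites. Without an annotation table no filter applies — which
is also the correct behavior for created sites, where a conservation
requirement would be counter-productive (a newly created site is not
expected to be conserved).

## Created-site detection and the proxy duplex scorer

For each SNP we take 22 bases of flank on each side (window length 45,
SNP at offset 23). Windows truncated by UTR ends are padded with the
sentinel `N`, which never matches a pattern and never pairs — this
avoids phantom sites at UTR boundaries. Only the eight frames that
contain the SNP offset are examined, and a hit requires the frame's
class with the alternate allele to *strictly* exceed its class with the
reference at the same frame (none → any, or lower → higher). This is
the conservative reading of "created by the non-reference allele"; a
`mode = "any_frame"` flag relaxes the comparison to the best reference
class across the considered frames.

Candidate hits must additionally pass a duplex filter. We do not
reproduce any particular alignment program's score matrix or
thermodynamics; instead a small, fully documented proxy stands behind
the same two thresholds a practitioner would use:

* local (Smith–Waterman) alignment of the miR 5'→3' against the
  reversed target (antiparallel), Watson–Crick +5, G:U wobble +2,
  mismatch −3, gap −8, per-position scores doubled over miR seed
  positions 2–8;
* `pairing_score` = the optimal local score. A perfect 21-nt duplex
  scores $5 \times (21 + 7) = 140$; the default cutoff
  `score_min = 70` is half of perfect, the proxy-scale analogue of the
  conventional pairing-score threshold of 150 (likewise roughly half of
  a perfect duplex on that scale);
* `energy_proxy` $= -(3\,\mathrm{GC} + 2\,\mathrm{AU} + 1\,\mathrm{GU})$
  pseudo-kcal/mol over the paired positions of that alignment, cutoff
  `energy_max = -20`, i.e. roughly ten good pairs' worth of stability.

The scorer is deterministic: dynamic-program ties break
diagonal > up > left and the traceback starts at the first maximal cell
in column-major order. Both cutoffs are configuration-driven and are
recorded in every output's metadata header. The scorer is validated in
the tests against a brute-force recursive alignment oracle on short
sequences.

## SNP density over validated sites

Density uses a 6-base window — the size of seed positions 2–7 — slid at
1-base steps across the region from 18 bases upstream of the first seed
base to 18 bases downstream of the last (42 bases, 37 window
positions, offsets −18…+18 of the window start relative to the first
seed base). We adopt the window *start* as the axis convention.
Offsets follow the mRNA 5'→3' direction, so minus-strand sites count
along decreasing genomic coordinate. Density is
$\mathrm{count} \times 1000 / (n_{\text{sites}} \times 6)$ SNPs/kb, and
the seed average is the mean over the six windows starting on seed
positions (offsets 0–5). The flank length is a parameter: the
18/6/18 = 42-base reading is internally consistent (one published
description of the same procedure says "24 bases downstream", which
does not add up to the stated region size and is not used).

## GWAS/LD enrichment and the resampling null

LD expansion is by *direct* pairwise lookup at r² strictly above 0.8 —
no transitive closure — and every SNP's proxy set contains itself, so a
catalog SNP that is itself an MRESS/CNM SNP counts. Catalog SNPs in
mutual LD merge into loci via connected components of the r² > 0.8
graph; the locus count sets the null's draw size, making the null
locus-matched rather than SNP-matched.

Each of the (default 1000) replicates draws that many SNPs *without
replacement* — the draw is from a finite SNP universe — restricted to
folded MAF ≥ 1% (the MAF summary is the maximum over populations of the
folded frequency), expands proxies, and counts the *unique* MRESS/CNM
SNPs tagged. Two tails are reported: the normal tail
$P(Z > (\mathrm{obs} - \bar{x})/s)$ fitted to the replicates, and the
add-one empirical estimate
$(1 + \#\{\text{replicates} \ge \mathrm{obs}\})/(R + 1)$, which cannot
be exactly zero. With the null's SD equal to zero the normal tail is
undefined (`NA`) and only the empirical estimate is meaningful. The
calibration property — uniform empirical p under a catalog drawn with
no enrichment — is exercised in the acceptance tests at 200 runs of 200
replicates.

## F_ST, Box-Cox and outliers

The survey consumes per-group allele counts for four ancestry groups
(Asian, African, European, American). No installed package estimates
multi-population Weir–Cockerham θ from a count matrix directly, so the
estimator is implemented here in its allele-sample ANOVA form:

$$\hat\theta = \frac{\mathrm{MSP} - \mathrm{MSG}}
                    {\mathrm{MSP} + (n_c - 1)\,\mathrm{MSG}}$$

with MSP the among-group mean square of frequencies, MSG the
within-group binomial mean square and $n_c$ the variance-corrected
average allele-sample size. Negative estimates are clamped to 0 (and
SNPs monomorphic across all groups return 0); the tests verify
equality, to $10^{-10}$, with an independent `aov()`-based computation
of the same mean squares, allele-label-swap invariance, and parameter
recovery under Balding–Nichols simulation. One known property of the
per-SNP ratio estimator: averaging $\hat\theta$ over SNPs is slightly
conservative (a ratio is convex in its denominator), so the mean
estimate under a simulated $F = 0.2$ sits near 0.18 rather than 0.20;
the recovery band in the tests reflects this.

Box-Cox normalization maximizes the profile log-likelihood
$-\tfrac{n}{2}\log\hat\sigma^2(\lambda) + (\lambda-1)\sum\log x_i$ over
a λ grid from −3 to 3 in steps of 0.01 (matching `MASS::boxcox` on the
same grid to within one step in the tests). F_ST distributions contain
zeros; these are offset by a configurable ε (default $10^{-6}$) before
the log — the transform is then $(x^\lambda - 1)/\lambda$, or
$\log x$ at λ = 0. The group comparison is an unpaired, pooled-variance
Student's t-test on the transformed values.

Outliers are selected on the *transformed* scale, upper tail only (the
survey's interest is high differentiation; low F_ST is the neutral
default), at mean + 2 SD of the MRESS/CNM distribution; flags switch to
two-sided selection or the raw scale. A degenerate (zero-variance)
distribution has no outliers. Binned counts use 10 equal-width bins on
[0, 1] with the final bin right-closed (so F_ST = 1 lands in the last
bin), and the background group is down-sampled without replacement to
the MRESS/CNM group's size with a seeded RNG before binning.

## What the synthetic generator emulates — and what it does not

`simulate_world()` produces every input the pipeline reads, with ground
truth recorded. Defaults (the reference study conditions used by the
analysis scripts and tests): 12 miRs of 21 nt against 30 UTRs of 2 kb
on alternating strands; 60 planted sites (20/20/10/10 across
8mer/7mer-m8/7mer-A1/6mer), written so the planted class is the maximal
class at that frame; 20 planted creation events; 400 survey SNPs with
30% placed inside planted seed frames; four groups of 120 allele
samples with Balding–Nichols F = 0.25 for MRESS/CNM SNPs versus 0.10
for the background (ancestral frequencies uniform on [0.05, 0.95],
bounded away from fixation to keep θ estimable); LD blocks of 5 SNPs
targeting r² = 0.9; and a 40-record catalog drawn with 5-fold odds for
LD blocks containing an MRESS/CNM SNP.

Design choices worth recording:

* *Planted creation events are strong sites.* Each embeds the full
  reverse complement of the miR (with the A1 position forced to `A`)
  and then breaks one internal seed base with the reference allele, so
  the alternate allele restores a full-complementarity duplex. This
  emulates the situation the duplex filter is meant to pass — a
  prediction-grade site — and makes recall of planted events a
  well-posed property. Weak created sites (bare seed matches in random
  context) sit near the score and energy cutoffs by construction, and
  their detection is governed by the configured thresholds, not by the
  generator.
* *Out-of-seed survey SNPs avoid every seed frame present in the
  reference sequences*, planted or incidental, so seed-frame SNPs arrive
  only through `p_snp_in_seed` and the ground-truth labels are exact.
* *LD is fabricated at the r² summary level* by correlated Bernoulli
  copying within blocks (flip probability $(1-\sqrt{r^2})/2$ on 200
  haplotypes), and the *realized* pairwise r² from those haplotypes is
  what the LD table reports. The pipeline consumes r² tables, so no
  coalescent machinery is simulated.
* Population frequencies and LD are generated independently; real data
  couple them. There is no mutation model, recombination map,
  demography, or allele-frequency spectrum realism, and the UTR
  background is uniform random DNA — so background seed matches are
  more frequent than in real, conservation-structured UTRs.

Consequently, passing tests demonstrate correctness of the machinery
(scanning, intersection, calling, counting, resampling, estimation) and
calibration of the statistics under the stated generative model — not
performance on real genomes, where input quality (prediction sets,
catalog curation, LD panels) dominates.

## Problem sizes and determinism

The test-suite and acceptance checks run at desk scale, chosen as the
smallest sizes at which each property is sharp: oracle equivalence of
the scanner on 200 random UTR × miR pairs; creation-event
soundness/completeness on 500 planted events; enrichment calibration
over 200 runs of 200 replicates (Kolmogorov–Smirnov against uniform)
and power at 5-fold enrichment over 100 runs; the no-LD null mean
against its hypergeometric expectation at 1000 replicates; and F_ST
recovery on 5000 SNPs. Every stochastic component takes an explicit
integer seed, the generator restores the caller's RNG state, and
rerunning any stage with an identical configuration reproduces
byte-identical output bodies; output files carry their seed and
thresholds in a commented metadata header.

## Known limitations

Non-canonical site classes (bulged, centered, 3'-compensatory) are out
of scope; indels and multi-allelic variants are filtered at VCF
ingestion; the duplex scorer is a filter, not a thermodynamic
prediction, and its scores should not be interpreted quantitatively;
and the worked-example tables are fixtures — their summaries test the
filter implementations, not genome-scale claims, which require the
full external inputs (variant database, validated-target catalog, LD
panel, GWAS catalog) this package deliberately does not download.
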