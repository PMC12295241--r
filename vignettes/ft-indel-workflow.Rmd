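---
title: "Promoter indel genotyping and flowering-time association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter indel genotyping and flowering-time association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftindelscan)
```

# Scope and model

`ftindelscan` implements an analysis pipeline that links structural variants
(insertion-deletion polymorphisms, "indels") in the promoter and intron
regions of *FLOWERING LOCUS T* (*FT*) homologs to flowering phenology in a
plant diversity panel. The pipeline has four computational stages, each a
module of this package:

1. **Variant calling from gapped alignments.** Indels and SNP loci are read
   directly off a multiple sequence alignment of a reference gene region
   plus resequenced contigs, and mapped onto a signed coordinate axis
   anchored at the transcription start site (TSS).
2. **Virtual PCR marker genotyping.** PCR assays defined by their product
   endpoint distances from the TSS are evaluated against each haplotype's
   variants, predicting amplicon sizes, presence/absence variants (PAV) and
   gel-level resolvability, and scoring diploid genotypes 0/1/2.
3. **Rank-based marker-trait association.** Phenology traits (days from
   sowing to floral bud emergence, start of flowering, end of flowering)
   are tested for normality, ranked, correlated against raw marker scores,
   and Bonferroni-corrected.
4. **Binding-site exclusivity filtering.** Transcription-factor motifs are
   scanned over the promoter alignment and factors whose every promoter
   site falls inside a polymorphic region (indel or SNP) are reported —
   these are the factors whose regulatory input segregates with the
   indel alleles.

A fifth module simulates all inputs with the statistical structure the
analysis assumes, so every stage can be validated end to end without any
external download.

# Coordinate conventions

All internal coordinates are 1-based inclusive. The TSS-relative axis is a
continuous integer axis that **includes position 0** (the TSS itself):
position $-1$ is the first upstream base, $+1$ the first downstream base.
The inclusive span between two endpoints $a$, $b$ is therefore
$|a - b| + 1$, and a product whose interval crosses the TSS counts position
0 — this is the rule that reproduces the published amplicon lengths (e.g. a
product spanning $-511$ to $+229$ is 741 bp). For genes annotated on the
reverse strand, upstream corresponds to larger genomic coordinates and the
sign of the difference is flipped, so "upstream is negative" holds on both
strands. A small number of published table rows deviate from this rule by
1–4 bp (one of them corrected by Sanger sequencing in the source); we treat
those as source inconsistencies and do not use them as references.

BED export converts to that format's 0-based half-open convention via
`rtracklayer`; VCF records use the left-anchored-base convention (a
deletion of reference positions $s..e$ is reported at $s-1$ with the
preceding base, right-anchored when $s = 1$).

# Variant calling semantics

Calling is pairwise per contig against the reference, by alignment column.
Columns where both sequences are gapped (gaps induced by a third
sequence's insertion) are transparent and do not interrupt a run. A maximal
run of contig gaps over reference bases is a deletion; a maximal run of
contig bases over reference gaps is an insertion anchored at the last
preceding reference base. Two contigs carry *the same* variant only when
their gap runs occupy identical alignment-column intervals; near-identical
runs remain distinct variants, so partially overlapping deletions (the
biologically interesting case of two large promoter deletions sharing a
region) are reported separately. Gap runs touching either end of a contig
are classified as unaligned ends — missing sequence, not deletions —
because a truncated contig carries no evidence of a variant. Ambiguity
characters other than `N` are rejected at parse time.

Every call path is verified against a naive per-column scanner (an
independent oracle implemented in the test suite) on hundreds of random
alignments, and against planted ground truth from the simulator.

# Virtual PCR and gel model

A marker is modelled by its two outer product endpoints on the TSS axis
and a primer window extending a configurable number of bases inward from
each endpoint (default 20 bp, used when true primer sequences are not
available). The predicted product length is

$$\mathrm{len} = \mathrm{span} + \sum_{\text{ins in span}} \ell_i -
\sum_{\text{del in span}} \ell_d,$$

and the assay yields **no product** when any deletion removes at least one
base of either primer window — the presence/absence variant mechanism. "No
product" is treated as a genuine allele call, since the published assays
score it as an allele state.

Two bands are merged into one observable class when their relative length
difference $|\Delta|/\max(\ell)$ is below the gel resolvability threshold.
The default 0.02 reproduces the two published calibration cases: an 8 bp
difference at ~800 bp is unresolvable ($\approx 0.010$), while a 7 bp
difference at ~230 bp is resolvable ($\approx 0.031$); a 0.005
"high-resolution agarose" preset is available. Merging is transitive
(single linkage), so a chain of close lengths forms one class.

Genotypes are scored 0 (reference-allele class), 2 (alternative class), 1
only when the observation equals the band union of one class from each
allele — a PAV heterozygote is physically indistinguishable from the
amplifying homozygote and is never called 1. Multi-allelic assays are
folded into binary one-vs-rest encodings whose allele classes may list
several alternatives (`"2504|378|no_product"`).

Minor allele frequency uses allele counts,
$(2 n_{\text{minor hom}} + n_{\text{het}}) / (2 n_{\text{called}})$,
expressed in percent and bounded by 50; the source does not state its
denominator, so a genotype-count mode is provided for comparison and the
published panel MAF columns are not used as references. The screening
boundary is inclusive: markers with MAF $\ge$ 1.5% are retained, matching
the stated rule that markers *below* 1.5 were discarded.

# Association statistics

The procedure follows the source exactly rather than a textbook Spearman:
phenotype values (per-line means over 3–10 biological replicates) are
ranked with average ranks for ties, and the product-moment correlation is
computed between the **ranks** and the **raw 0/1/2 scores** — the scores
are deliberately not ranked. A classical both-ranked option exists behind
a flag; for 0/1/2 scores the two differ only through the rank transform of
three tied groups, and neither dominates statistically. Significance uses
the two-tailed $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ test on $n-2$ degrees of
freedom, and Bonferroni correction multiplies each raw p by the family
size, capped at 1. The family defaults to *all markers tested in the run*;
a per-gene policy is available because the source does not define its
family unambiguously. Missing data are handled pairwise-complete with the
per-test $n$ recorded.

The Kolmogorov–Smirnov normality screen tests against a normal with the
sample mean and SD. Because the parameters are estimated from the same
data the asymptotic p-value is conservative; this is acceptable here since
the screen only motivates the switch to rank statistics, and the generated
(and observed) phenology distributions are grossly bimodal — the screen
rejects them at any reasonable level.

# Motif scanning and the exclusivity filter

Consensus motifs (IUPAC strings such as the AGL15 CArG-box variant
`CARGNCAT`) match a window when every base is compatible with the code at
its position; such sites score 1. Frequency-matrix motifs score a window
as the matched-frequency sum over the maximal-frequency sum,

$$s = \frac{\sum_i f_i(b_i)}{\sum_i \max_b f_i(b)} \in [0, 1],$$

with sites at $s \ge$ the similarity threshold (default 0.85). The
external annotation tool used by the source does not document its
similarity formula; this ratio is our documented interpretation, chosen
because it is scale-free, equals 1 exactly for the per-position argmax
word, and reduces consensus scanning to a 0/1 matrix at threshold 1 (an
identity verified in the tests). Scanning operates on the ungapped
sequence of each alignment row with positions mapped back to alignment
columns; windows containing `N` are skipped; minus-strand scanning uses
the reverse-complemented model, and a window reaching the threshold on
both strands (palindromic hit) is reported once with strand `both`.

A site lies in a polymorphic region when $\ge$ 1 bp of its window overlaps
the union of indel column intervals and SNP columns (an all-or-nothing
containment mode is available). A SNP's polymorphic region is the single
column. Within the promoter scope — alignment columns upstream of the TSS
column — a factor is *exclusive* when every one of its in-scope sites is
polymorphic; enlarging the polymorphic set can only preserve exclusivity
(a monotonicity property under test). The per-indel report intersects
exclusive factors with a user-supplied flowering-pathway list; the
bundled motif set is a small synthetic fixture (the AGL15 consensus plus
ten random matrices) — the full *Arabidopsis* motif database is deliberately
not redistributed, and published site counts are therefore not reproduced.

# The synthetic panel

The generator's defaults are the study conditions: 626 lines, 20
independent markers (independence approximating the species' very rapid LD
decay), selfing rate 0.95 giving heterozygote frequency $2pq(1-s)$, three
ordered traits in two seasons with 3–10 replicates, and one causal marker
at alternative-allele frequency $\approx 0.32$ with an 8 days/allele
effect, which places its rank-score correlation in the 0.3–0.4 band — the
magnitude regime of the strongest published markers.

The shared genetic value is a two-component normal mixture (60% "early"
lines, sd 6 days; 40% "late" lines shifted +35 days, sd 10), mirroring the
bimodal early-landrace/late-winter-ecotype structure of real panels and
guaranteeing KS rejection of normality. Year-specific deviations are
scaled so that the *rank* correlation of line means between seasons equals
the configured repeatability (default 0.96): with a bimodal genetic
distribution the rank correlation reacts to noise more strongly inside the
dense early cluster than a variance ratio predicts, so the noise scale is
solved numerically (by root finding) on the realised genetic values rather
than set from a Pearson variance ratio. Trait order BE < SF < EF is
enforced per line via strictly positive inter-trait gaps. The alignment
simulator plants a deletion/insertion catalogue spanning 7 bp to 3.8 kbp,
including a partially overlapping deletion pair, a shared identical gap
run, random SNPs and truncated contig ends; every planted variant is
recorded as ground truth.

What the simulation does **not** emulate: linkage between markers,
population structure and kinship (the source defers these explicitly),
genotyping error, repetitive-element artefacts, and environmental trends
within a season. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to
confounding in real panels.

# Numerical and design choices

* Problem sizes in the validation suite: oracle-equivalence runs use
  random alignments up to 500 columns and sequences of 200–300 bp across
  ~100 seeded fixtures per engine; calibration uses 200 null panels of 100
  lines by 20 markers; recovery uses 50 replicates at the full 626-line
  panel size. These sizes give binomial tolerances of about $\pm 1$
  percentage point on the raw type-I rate while keeping the suite fast.
* Ties in ranking use average ranks; rank sums are checked against
  $n(n+1)/2$.
* $|\rho| = 1$ yields the smallest representable positive p, flagged as
  saturated rather than reported as 0.
* Degenerate inputs (all-missing traits, zero-variance markers or traits)
  are flagged and excluded rather than propagated as numeric noise.
* The pipeline orchestrator (`run_all()`) writes a manifest with MD5
  hashes of all outputs, the seed and every threshold; reruns with the
  same configuration are byte-identical. The workflow is also exposed as
  numbered driver scripts under `analysis/`, which is the intended entry
  point for the end-to-end analysis.

# Known limitations

* Amplicon prediction ignores primer thermodynamics and assumes the
  20 bp primer-window default when real primer sequences are absent.
* The KS screen with estimated parameters is conservative; a
  Lilliefors-corrected test would be sharper but changes no decision here.
* MAF published for the real panels cannot be reproduced without the
  original genotype data; the MAF implementation is validated on counts
  and invariances instead.
* Multi-allelic assays are handled through explicit binary encodings; no
  attempt is made to infer a joint multi-allelic genotype from band
  patterns the assay cannot distinguish.
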