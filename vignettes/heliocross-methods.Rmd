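---
title: "Models and methods behind heliocross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heliocross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heliocross)
```

## The biological problem

Mimetic *Heliconius* races in Panama and Peru share a nearly identical
hindwing yellow bar, yet the loci controlling it differ: in *H. erato* the
bar is recessive at *Cr* ("Cream rectangles"), with the Peruvian race
additionally involving *Sd* ("Short band"), while in *H. melpomene* it is
recessive at *Yb* ("Yellow bar", homologous to *Cr*). Crossing two barred
races is a complementation test: if the F1 keeps the bar the alleles are
functionally interchangeable; if the bar breaks down, the races achieve the
same phenotype through different alleles. heliocross packages everything
needed to analyse such two-generation crosses — exact Mendelian enumeration
with race-labelled, phase-tracked alleles, explicit genotype→phenotype
architecture models, diagnostic-SNP genotyping, the segregation statistics,
and a brood simulator — so the whole analysis runs on published count data
or on synthetic broods.

## Genotypes, phase, and cross enumeration

Alleles are strings carrying a race tag and an optional sub-allele tag
(`"pet"`, `"fav"`, `"mel.a1"`). A diplotype is an *ordered* pair
(maternal, paternal); parental origin is never discarded, because the key
melpomene result is precisely about which *paternal* allele an offspring
inherited. "Hybrid" means the two race tags differ; sub-allele tags do not
count (an a1/a2 father is race-homozygous).

`enumerate_gametes()` enumerates transmitted haplotypes exactly. Loci on
different linkage groups assort independently; loci sharing a group are
completely linked by default (r = 0), because the markers used in practice
tag patterning loci so tightly that collapsing marker and locus is the
sensible default — `recomb_map()` accepts explicit recombination fractions
when that assumption should be relaxed. `cross_distribution()` multiplies
the two parental gamete distributions and stores the maternal allele first
in every offspring diplotype. All probabilities arising in the supported
designs are dyadic rationals (products of 1/2), which doubles represent
exactly, so "exact rational" arithmetic and floating point coincide here;
the test suite checks distributions against an independent brute-force
gamete-pair enumeration to 1e-12.

Only two-generation designs (F1, F2, backcross) are supported; there is no
pedigree peeling, mutation, or population-level simulation.

## Architecture models

An `architecture_model` is an ordered rule list over per-locus predicates;
the first matching rule wins and an explicit catch-all makes exhaustiveness
testable by enumeration. Seven models ship as JSON fixtures:

* **ERATO_UNIFIED** — yellow bar iff *Cr* is race-homozygous **or** *Sd* is
  fav/fav; *Cr*-hybrids are otherwise fuzzy-barred. This is the two-locus
  epistatic architecture the favorinus backcross supports (expected 3:1).
* **ERATO_SINGLE_LOCUS** — the 1:1 null (bar controlled by *Cr* alone) that
  the same brood rejects.
* **ERATO_UNIFIED_MODIFIER** — the black-hindwing class of the petiverana
  backcross as a penetrance parameter `p_black` among *Cr*-hybrids
  (default 0.5). The hypothesised third locus is unidentified, so a
  penetrance parameter is the honest minimal encoding; an explicit unlinked
  modifier locus (**ERATO_MODIFIER_LOCUS**) is provided as the alternative
  encoding and yields identical expected ratios when the backcross parent
  is heterozygous for the modifier (asserted in the tests).
* **MELPOMENE_YB** — classical co-dominant *Yb*: yb/yb barred, Yb/yb shadow
  bar, Yb/Yb black.
* **MELPOMENE_CRYPTIC** — cryptic variation in the melpomene father:
  paternal allele a1 behaves as yb (pigmented bar), a2 as Yb (shadow bar).
  The fuzzy/full split among pigmented bars is a 0.5/0.5 stochastic
  sub-variant, not a second locus — the data give no genetic assignment for
  it. The model describes offspring in the rosina background; the father's
  own black phenotype is a statement about his genomic background, outside
  the model's scope.
* **MELPOMENE_COMPLEMENTING** — rosina and amaryllis yb alleles are
  interchangeable; all F1/F2 genotypes are barred (no complementation).

One deliberately ambiguous point: the erato F1-like phenotype is sometimes
described with the same "shadow" wording as the melpomene heterozygote.
heliocross keeps them distinct — `FUZZY_BAR` is the pigmented, broken erato
F1 bar; `SHADOW_BAR` is the unpigmented melpomene heterozygote class.

Genotype combinations never produced by the analysed crosses (e.g. *Cr*
fav/fav with *Sd* pet/pet) still get model-defined predictions, but the
models record their observational support and such predictions are flagged
`extrapolated` in consistency reports.

## Segregation statistics

`chisq_gof()` is the plain Pearson statistic with expectations from
normalised ratio weights and no continuity correction anywhere — the
published 13:5 vs 1:1 statistic (3.56) is the uncorrected value; the
Yates-corrected one would be 2.72. Any pooling (fuzzy + black as
"non-yellow" for the petiverana backcross's 1:1 test) must be declared by
the caller; it is never inferred. One published statistic does not
reproduce: the 33:36 counts give 0.13 (p = 0.72), not the printed 0.03
(whose p would not be 0.72 either); heliocross reports the recomputed
value.

`cosegregation_probability(n)` is the exact probability `(1/2)^n` that `n`
informative offspring all show the observed perfect genotype–phenotype
association under independent 1:1 segregation — the perfect-association
special case only; a general exact test (Fisher) is deliberately out of
scope since the published analysis never uses one. `coseg_test()` counts
only individuals with a definite genotype and phenotype and refuses to
report a probability when the association is imperfect.

Reported values can be rounded (IEEE round-half-even, the default) or
truncated toward zero via `format_signif(..., mode = "truncate")`. The
distinction matters twice: `(1/2)^21 = 4.768e-7` prints as 4.8e-7 rounded
but 4.7e-7 truncated, and `p = 0.7855` prints as 0.79 rounded but 0.78
truncated — the truncated forms are the published ones, and the suite
asserts both forms under the respective flag.

## The brood simulator

`simulate_brood()` draws offspring genotypes i.i.d. from the exact cross
distribution, assigns sex as a fair Bernoulli at conception, and thins
females by a relative viability `v` (egg hatchability is normal in the
emulated incompatible cross, the loss being larval, so inviability is
modelled post-conception). The surviving female fraction is then
`v / (1 + v)`; the packaged L13 configuration uses `v = 10/34` so the
expected adult sex ratio matches the observed 10:34 — a configuration
value, not a hard-coded constant. Direction-dependent sterility rules
(melpomene father × rosina mother ⇒ daughters sterile) set the `fertile`
flag. Each brood gets its own RNG stream keyed by (seed, cross id), so
adding a brood to a run never perturbs another brood's output; identical
configurations give byte-identical tables and FASTA.

`simulate_marker_fasta()` inverts the genotyping step: homozygotes carry
their race's diagnostic base, hybrids the IUPAC code covering both races'
bases, everything else copied from the reference. Reference sequences are
generated by `synthetic_reference()` — random backbones carrying the
diagnostic bases — because real marker references are not redistributed;
simulated sequences have no indels and, by default, no sequencing error
(`error_rate` is a knob, default 0). What passing round-trip tests show is
therefore that calling is exact on clean, perfectly aligned data; they say
nothing about chromatogram noise, alignment error, or indel handling,
which are out of scope. The melpomene marker rows (B9, Parn) are
transcribed as printed — including a paternal ambiguity symbol and a
maternal base outside its expansion, which the source leaves unresolved —
and are therefore genotyped via allele labels rather than simulated
sequence.

## Diagnostic-SNP and RFLP genotyping

Coordinates are 1-based on the named reference, matching how diagnostic
positions are published; conversion to string offsets happens once at the
boundary. Per position, a site is classified pure-A / pure-B /
heterozygous (the observed symbol's expansion equals the diagnostic base
pair) or incompatible; gaps and Ns are skipped as missing evidence. The
aggregation rule is: unanimous sites give that call; at least one
heterozygous site with the rest compatible gives `hybrid`; contradictory
homozygous sites give `conflict`, never a silent majority vote — some
diagnostic sites are polymorphic within races and can make true hybrids
read homozygous, which is why per-cross informative-site subsets and
per-site exclusion lists are first-class arguments.

The in-silico restriction assay models AseI as recognition ATTAAT with cut
offset 2 (AT^TAAT). Only cut-vs-uncut pattern identity affects a genotype
call, so a misread offset cannot change a call. Sites are searched on both
strands by default; ATTAAT is its own reverse complement, so the flag is
inert for the shipped assay. `call_rflp()` expands a two-base ambiguity at
the diagnostic position into both allele sequences, digests each, and
calls heterozygote iff the fragment patterns differ.

## Model scoring and ranking

`score_model()` combines (i) the per-individual log-likelihood of the
phenotype counts under the model's expected ratios (the multinomial
coefficient is omitted — it is constant across models for fixed counts, so
rankings are unchanged and the total log-likelihood never increases as
individuals are added), (ii) the chi-square against those ratios, and
(iii) the consistency fraction: genotyped individuals whose phenotype has
non-zero probability given their called genotype, marginalising over
uncalled loci with the cross distribution conditioned on the calls.
Stochastic penetrance parameters (`p_black`) are profiled at their MLE
rather than fixed. A model assigning probability zero to an observed class
gets log-likelihood −∞ and ranks last.

"Parsimony" is operationalised as an explicit key chain: consistency
fraction, then log-likelihood (ties within 1e-6 treated as equal, so a
boundary MLE cannot win on numerical noise), then fewer free parameters,
then model name. The last key only matters for models that are genuinely
likelihood-equivalent on a design — e.g. on the rosina × amaryllis F2,
where every candidate predicts an all-yellow brood and the data cannot
distinguish them.

## Calibration, problem sizes, and known limitations

The suite checks the test's operating characteristics by simulation: the
type-I error of the uncorrected chi-square at α = 0.05 over 10,000
simulated broods of 50 under the 1:3 backcross expectation is ≈ 0.048,
inside the 0.05 ± 0.01 band. The same exact binomial computation shows the
1:1 design at n = 50 rejects at rate 0.0649 — binomial discreteness, not an
implementation artefact — which is why the calibration experiment uses the
1:3 design (the architecture the data support). Model recovery is checked
by generating 200 broods of 100 under each recoverable architecture and
re-ranking the candidate set; the generating model wins in ≥ 95% of seeds
(in practice 100%). Monte-Carlo cross-checks use broods of 10,000 draws
compared within three standard errors. These sizes were chosen so each
guarantee is sharp enough to catch real defects while the whole suite runs
in a couple of minutes.

Per-individual genotype rows in the packaged broods are synthesized to
match the published class-level counts exactly (individual identities were
never published); assignments the source leaves open — e.g. which yellow
favorinus-backcross individuals are hybrid at which single locus — are
fixed arbitrarily but deterministically, and satisfy every published
constraint (no yellow individual hybrid at both loci; all 15 genotyped
pigmented melpomene offspring carry paternal a1).

Further limitations: phenotype is strictly categorical (no morphometrics);
only the perfect-association co-segregation probability is computed; no
multiple-testing correction is applied (none is applied in the analysis
being reproduced); and the simulator emulates single broods, not
populations.
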