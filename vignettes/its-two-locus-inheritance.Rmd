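---
title: "Intragenomic ITS variation as a two-locus trait: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intragenomic ITS variation as a two-locus trait: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itsloci)
```

## The problem

The internal transcribed spacer (ITS) of the ribosomal RNA gene cluster is
the standard fungal barcode, and its interpretation usually assumes that
the hundreds of rDNA copies within a genome are homogenised by concerted
evolution.  Some wild strains break that assumption.  The package models
the situation found in a wild heterokaryotic *Agaricus subrufescens*
isolate (CA487) that stably carries **three** distinct ITS sequence types,
A, B and C, in roughly equal amounts: a direct Sanger read of such a
strain shows double and triple peaks, a clone library shows three
sequence families, and the offspring show the three types re-assorting.

The genetic explanation the package implements and tests is a two-locus
model: types A and B are **alleles of one ribosomal locus** (*ITSI*),
while type C sits at a **second, unlinked locus** (*ITSII*) that
segregates against a **null allele** (absence of any ITS copy at that
locus).  The type C array is present in only one of the two nuclei of the
heterokaryotic parent.  The package provides, as reusable and tested
components, the full chain of evidence for such a claim:

1. **Clone typing** (`classify_clones`): cloned amplicon sequences are
   assigned to types, minor variants, PCR chimeras, or left unassigned,
   and the type ratio is tested against 1:1:1 (`equal_ratio_chisq`).
2. **Chromatogram superposition** (`superpose_traces`): why a mixed trace
   of three templates of unequal length can *hide* a real substitution
   (masking) — and why cloning is needed.
3. **In-silico CAPS/PCR-RFLP** (`find_sites`, `digest_amplicon`,
   `its_phenotype`): restriction phenotypes that read out which ITS types
   an isolate carries, with a gel model for co-migration and band
   visibility.
4. **Karyotype classification and genotype inference**
   (`classify_karyotype`, `infer_its_genotype`): the multilocus genotype
   test separating homokaryotic from heterokaryotic single-spore isolates
   (SSIs), and the null-allele-aware mapping from band phenotypes to
   two-locus genotypes.
5. **Segregation statistics and hypothesis evaluation**
   (`segregation_test`, `linkage_test`, `evaluate_hypotheses`): 1:1
   Mendelian checks, pairwise linkage, and the formal confrontation of
   the *trikaryon* hypothesis with the two-locus model.
6. **A meiosis simulator** (`simulate_basidia`, `generate_ssi_dataset`,
   `generate_clone_library`): the amphithallic life-cycle model that both
   yields the theoretical expectations (the 33% heterozygosity-loss rate)
   and generates the synthetic data the test suite runs on.

`ssi_analysis()` chains steps 3–5 into one classed result with `print()`
and `summary()` methods.

## Coordinates, haplotypes and clone typing

All site-level work happens on the shared 662-column clone alignment;
positions are 1-based alignment columns.  The three built-in haplotypes
are defined by their states at the 13 polymorphic columns (type A is
absent-gap `T` at 39 and unique at 122, 130, 145, 146, 200; type B unique
at 114, 334, 559, 649; type C unique at 269, 466 and the 475 gap).  A gap
is a coded fifth character everywhere — in polymorphism detection,
parsimony-informative-site counting and group assignment alike.

The full 662-column sequences attached to the built-in haplotypes are
**synthetic**: only the polymorphic columns are published, so the
invariant background is an arbitrary fixed fill.  Everything the package
computes from real data depends only on the polymorphic columns; the
background exists so that clone libraries, traces and round trips can be
exercised end to end.  One deliberate feature is embedded in it: the
columns flanking position 334 carry a `G`, reproducing the masking
geometry discussed below.

`classify_clone` is deterministic and total.  A clone matching one type
at every polymorphic column and elsewhere is `type-exact`; up to
`max_variant_sites` (default 2) substitutions at non-diagnostic columns
make it a `type-variant`; diagnostic columns split into two contiguous
blocks donated by two types make it a `chimera`, with the breakpoint
bracketed between the last column of the 5' donor and the first column of
the 3' donor.  Multi-breakpoint mosaics and heavier damage fall to
`unassigned`.  The single-breakpoint assumption matches how PCR-mediated
recombinants arise (one template switch) and keeps the breakpoint
identifiable.

Region annotation (ITS1 / 5.8S / ITS2) is configurable
(`alignment_regions`).  The published record fixes only the membership of
the polymorphic sites (8 in ITS1, 1 in 5.8S, 4 in ITS2); the default
boundaries (columns 1–299, 300–459, 460–662) realise that split and make
no further claim.

## The masking model

A mixed chromatogram of templates with indels goes out of frame: each
template contributes its own ungapped base sequence, so downstream of the
39 deletion, types B and C run one position ahead of type A.
`superpose_traces` scores every polymorphic column as *detectable* or
*masked* by a counterfactual test: homogenise the column to its consensus
state and ask whether any affected trace position changes its **set** of
observed bases, on the forward and on the reverse-complement read.  Peak
presence, not height, is compared — chromatogram peak heights are not
quantitatively reliable.  Columns with a gap are always detectable: the
frame shift itself is visible downstream.

With the built-in types, exactly one column is masked on both strands:
the type-B `G` at 334, hidden under the flanking `G` of the A/C frame on
the forward strand and symmetrically on the reverse strand.  This is the
model's account of why direct sequencing reconstructed the three types
*except* at 334, and why the clone library was decisive.

## In-silico CAPS

Restriction sites are scanned with IUPAC degeneracy on both strands
(`find_sites`, built on `Biostrings::matchPattern`); a polymorphic base
creates or destroys a site exactly when it completes or breaks the
pattern.  Cut positions honour enzyme geometry: MboII (GAAGA 8/7) and
FokI (GGATG 9/13) cut downstream of their sites, SalI/KpnI/AvaII within
them; offsets are configurable per `enzyme_spec` since Type IIS reach
matters for fragment sizes.

The packaged marker panel (`caps_markers`) specifies each allele by
amplicon length and cut coordinates, calibrated to the published fragment
tables: PRS016/SalI (700 bp; alleles 481+219 and 271+219+210), PRS049/KpnI
(479; uncut and 292+187), PRS088/AvaII (757; uncut and 449+308), and the
two-enzyme ITS marker (773/772/771 bp for types A/B/C).  Amplicon
coordinates and alignment columns are related by an unpublished constant
offset, which is why the fixtures carry coordinates rather than deriving
them; `synthetic_its_amplicons()` provides sequence-level synthetic
counterparts whose digests reproduce the same fragments through the real
scanning path.

The gel model (`gel_model`) has two physical parameters — 5% relative
resolution and a 150 bp visibility floor, matching 2% agarose — plus one
logical rule: a band whose presence pattern across the marker's phenotype
classes duplicates that of a larger band is *redundant* (the FokI 209
fragment always accompanies the ~563 band; the MboII 112 always
accompanies the 264).  Together the three rules reproduce exactly the
published parenthesised bands; all are configurable.  Band strings print
in the conventional table typography (`"396+264 (+395+377+112)"`,
`"563 (562+209)"`).

The MboII digest alone confounds `[C]` with `[A+C]` and `[B+C]` with
`[A+B+C]`; adding FokI separates all seven type combinations — the test
suite checks this exhaustively at gel-band resolution.

## Karyotype, genotypes, hypotheses

The multilocus genotype test is asymmetric by nature: heteroallelicity at
any locus proves a heterokaryon, while homoallelicity at all loci only
suggests a homokaryon — a heterokaryon made of genetically identical
sister nuclei is invisible to it.  The package keeps that asymmetry:
`classify_karyotype` never corrects for the invisible fraction, and the
simulator quantifies it instead (`estimate_misclassification`).

`infer_its_genotype` encodes the full phenotype-to-genotype table of the
two-locus model, including its three diagnostic impossibilities for
homokaryons (`[C]`, `[A+B]`, `[A+B+C]`) and the permanent `c/c` vs `c/n`
ambiguity at *ITSII* (the null allele makes one homozygote class
unobservable; the ambiguity is carried, never guessed).  Rate
computations use only observable classes: the *ITSII* homozygosity rate
among heterokaryons counts null-homozygotes (phenotypes without C bands).

Statistics follow the conventions of the source analyses: Pearson
chi-square, no continuity correction, df = k−1 for ratio tests and df = 1
for the 2×2 contingency linkage test, α = 0.05.  Because the true allele
phase of a wild heterokaryon is unknown, `linkage_test` reports both
complementary phase splits (30:39 on the published homokaryon table) and
labels the larger one parental only as a convention.  Recomputing the
published statistics from the published counts gives 0.710, 1.174 and
1.464 where 0.72, 1.18 and 1.43 were printed; the package reports full
precision and the tests accept the printed values within ±0.05,
attributing the last-digit differences to rounding or minor cell-usage
differences in the original computation.

`evaluate_hypotheses` formalises the model comparison.  The trikaryon
model (three distinct nucleus types, one ITS type each) predicts
single-type homokaryotic offspring in equal thirds; any multi-type
homokaryon is a rejection witness — on the published counts, `[A+C]`
(n = 19) and `[B+C]` (n = 11).  The two-locus model predicts homokaryon
support on `{[A], [B], [A+C], [B+C]}` with 1:1 segregation at each locus
and no `[C]` anywhere; it stands on the published data.

`enumerate_offspring_phenotypes` reports two sets deliberately: the
*combinatorial* phenotype space (all non-empty subsets of the parental
types — seven for a three-type parent, the classical statement) and the
*genotypic* set actually reachable by offspring genotypes, which excludes
pure `[C]` because every nucleus carries an *ITSI* allele.  The
distinction is exactly the observation that motivates the model: `[C]`
was the one combination never found.

## The meiosis simulator

Basidiospore formation is modelled in three steps.  (i) **Meiosis**:
crossing over is abstracted to a per-locus second-division segregation
(SDS) frequency *f* — with probability *f* the two meiosis-II pairs each
carry both alleles, otherwise the pairs are homoallelic and opposite.
*f* is the minimal sufficient parameter for every statistic used here; no
map distances are published.  Loci on the same chromosome can be linked
through a tetrad-type model (parental ditype 1−2r, tetratype 2r), which
preserves the 2:2 tetrad ratio and gives gamete recombination fraction r.
(ii) **Post-meiotic mitosis** with probability `p_mitosis` duplicates the
four products; every spore of such a basidium receives two nuclei.
(iii) **Pairing**: under the default `random_non_twin` rule each spore
draws uniformly one of the 6 unordered pairs of distinct meiotic
products, so one third of heterokaryotic spores receive sister nuclei.
A `sister_bias` parameter (β = 1/3 recovers the random rule) exists
because observed heterozygosity losses of ~50% at some loci exceed the
random model's prediction; no mechanism is asserted.  An `allow_twin`
variant admits genetically identical twin pairs, a case the literature is
silent on; twin spores are treated as effectively homokaryotic.

The central theoretical result the simulator reproduces: under random
non-twin pairing, the fraction of heterokaryotic spores that lose
parental heterozygosity at a locus is **1/3 regardless of f** — sister
pairs (1/3 of spores) are heteroallelic with probability *f*, non-sister
pairs with probability (1−f) + f/2, and the f-dependence cancels.
`estimate_het_loss` verifies this by Monte Carlo at any *f*; the
acceptance script recomputes it over 10⁵ basidia.

### Generator defaults are the study conditions

`ca487_parent()` fixes the five segregating loci: PRS088 centromere-linked
(f = 0), PRS016/PRS049/ITSI/ITSII distal and mutually unlinked.  The SDS
frequency of the distal loci is not published; 0.4 is used as a typical
distal value (it does not affect the 1/3 loss, and only mildly shapes
per-locus homozygosity).  `basidium_model()` defaults to
`p_mitosis = 0.27`, the true heterokaryotic-spore rate matching the
offspring under study (the *called* rate is lower by the sister-miss
fraction); published rates for the species run 40–75%, so this is a
strain-level, not species-level, setting.  SSI datasets default to
n = 94 isolates, sampled one spore per basidium (a spore print pools very
many basidia, so isolates are effectively independent).

`clone_library_model()` defaults to 284 clones, equal type weights (equal
rDNA copy numbers across the three types, and homogeneous copies within
an allele — the simplest reading of the clone and chromatogram evidence),
a per-site substitution probability of 7.5×10⁻⁴ per clone and a 5%
chimera probability.  The two noise rates were chosen once so that the
expected fraction of non-exact clones matches the observed 120/284; they
lump PCR error, sequencing error and genuine minor rDNA variants, which
the data cannot separate.

### What the generator does and does not emulate

It reproduces the statistical structure the inference consumes: 2:2
allele segregation per tetrad, per-locus SDS, independent assortment or
tetrad-level linkage, the heterokaryotic-spore fraction, the sister-pair
geometry, band-level phenotypes, and clone libraries with type-ratio,
variant and chimera structure.  It does not model chromatid-level
crossover interference, non-tetrasporic basidia (<1% in the source
material), rDNA concerted evolution or copy-number variation, viability
selection, or sequencing-quality artefacts.  Passing tests therefore
show that the inference chain is correct *under the stated life-cycle
model*, not that real data must obey it — which is precisely the logic of
the original analysis, where the same model is the null against which the
counts are checked.

One behaviour of the simulator is worth flagging: a sister-pair
heterokaryon that is homoallelic at all three markers is *called* a
homokaryon, and if it is heteroallelic at *ITSI* it then presents an
`[A+B]`-type phenotype that the two-locus model forbids for homokaryons.
On simulated data `evaluate_hypotheses` will thus occasionally report
such witnesses — the published dataset happened to contain none.  The
round-trip invariant (every simulated genotype is recovered by
`infer_its_genotype` under the *true* karyotype) holds unconditionally;
the test suite checks both facts.

## Numerical choices and degenerate inputs

* Chi-square p-values are asymptotic; no Yates correction anywhere (the
  published statistics match the uncorrected forms).
* `equal_ratio_chisq` and `segregation_test` refuse all-zero counts;
  `linkage_test` returns an undefined statistic with a warning when a
  margin is zero and reports complete linkage otherwise.
* Gel clustering merges chained neighbours (396/395/377 form one band);
  the representative is the largest member present in the pattern.
  Equivalent redundant bands lose to the larger representative; ties
  cannot arise with the built-in panel.
* Cut positions falling outside an amplicon (Type IIS sites near an end)
  are dropped with a warning; fragments always sum to the amplicon
  length.
* All stochastic operations draw from R's global RNG under an explicit
  seed and restore the caller's RNG state; identical seeds replay
  byte-identically.
* Problem sizes used by the test suite (10⁵ basidia for loss rates,
  3×10⁴ for misclassification, 200 replicate datasets of 94 spores, 100
  seeds of 164-clone libraries) were sized to keep Monte-Carlo error
  well inside the asserted tolerances.

## Limitations

The package infers genotypes at exactly two ITS loci with at most two
alleles each; it does not build genetic maps, model more than one
breakpoint per chimera, parse chromatogram files (the trace model is a
model, not a base caller), or perform multiple alignment — aligned input
is assumed.  No multiple-testing correction is applied across locus
pairs, matching the source analysis.  The deposited reference sequences
are not bundled; `synthetic_its_amplicons()` is a labelled synthetic
stand-in calibrated to the published fragment sizes.
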