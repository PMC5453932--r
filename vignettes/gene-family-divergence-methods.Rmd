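---
title: "Methods: divergence analysis of duplicated gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence analysis of duplicated gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhxdiverge)
```

This vignette records the models, conventions and design choices behind
the package, in the order the pipeline applies them. Nothing here states a
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Coordinates and gene models

All genomic intervals are 1-based and closed (the GFF3 convention); VCF
positions are already 1-based, so a single convention covers every module
and no half-open coordinates are exposed. A `gene_model` stores exons and
CDS segments in *transcription* order, so minus-strand genes list their
3'-most genomic exon first and all downstream logic (splicing, promoter
extraction, codon effects) is strand-agnostic. Each gene carries exactly
one transcript; inputs with alternative isoforms are rejected with an
error rather than silently picking one.

The TSS is position +1 and there is no position 0: the promoter window
"−1500..+500" means 1,500 bases upstream plus 500 bases starting at the
TSS itself. Windows that run off a contig are truncated and flagged
(`truncated` attribute) rather than fatal, because a promoter shortened by
an assembly edge is still scannable; only a window entirely off the contig
is an error.

Intron phase is the cumulative CDS length upstream of the intron modulo 3,
computed in transcription order; only introns that actually interrupt the
CDS carry a phase. This makes phase invariant under strand mirroring, a
property the tests assert.

## Ka/Ks estimation

The estimator is Nei–Gojobori (1986) with Jukes–Cantor correction. The
choice is deliberate: the upstream tool chain this workflow emulates names
only a codon-alignment converter, not the downstream counting model, so
the package fixes a fully specified, oracle-checkable estimator and keeps
it pluggable behind the `kaks_estimate` surface.

Per codon, the synonymous site fraction at each position is the fraction
of one-step changes that preserve the amino acid, with changes to stop
codons excluded from the denominator — so each codon still contributes
exactly 3 sites and `S + N = 3 ×` codons (an invariant under test). Sites
are averaged between the two sequences. Differences between codons are
averaged with equal weight over all minimal mutational pathways;
pathways passing through a stop codon are excluded unless every pathway
does, in which case all are used. These two stop-handling rules are a
known implementation fork of NG86; they are fixed here, mirrored in the
independent test oracle, and exercised over all 61 × 61 sense-codon pairs.

Correction is `Ks = -3/4 · ln(1 − 4/3 · pS)` (likewise `Ka`); proportions
at or beyond the 3/4 saturation point raise an error rather than returning
a complex number. `Ka/Ks` is reported as undefined (`NA`) when `Ks = 0`,
and `classify_selection` maps ratios to purifying (< 1), neutral (= 1) or
positive (> 1).

Sliding windows are codon-aligned; the defaults are the conventional 60
and 90 bp window sizes with a 6 bp (2 codon) step. The step is not fixed
by any convention, so it is a documented, configurable default chosen to
give dense tracks at negligible cost. Windows in which the estimate is
unavailable (all columns gapped, or saturation inside the window) carry
`NA` rather than aborting the scan. Gapped columns are excluded pairwise
everywhere (complete-codon deletion).

Dating uses `T = Ks / (2λ)` with `λ = 9.1 × 10⁻⁹` synonymous substitutions
per site per year, the customary *Populus* rate; ages print in MYA to two
decimals, matching the precision such tables are reported at. Rounding
happens only at the presentation layer — machine-readable outputs keep
full precision.

## Protein characterization

Pairwise identity uses Needleman–Wunsch with match/mismatch scoring and a
linear gap penalty (affine behavior was considered and rejected as an
extra parameter this analysis never exercises). The alignment backend is
`Biostrings::pairwiseAlignment`; argument order is canonicalized before
aligning so tie-breaking cannot depend on which sequence came first,
making `percent_identity` exactly symmetric. Identity is counted over
*all* alignment columns. Published identity figures for this kind of
analysis come from unstated aligner settings, so external percentages are
treated as approximate anchors, not exact targets.

Molecular weight sums average residue masses plus one water (18.0153 Da).
The isoelectric point solves the Henderson–Hasselbalch net-charge balance
with free termini by bisection on pH ∈ [0, 14] to |charge| < 10⁻⁴; the
charge is strictly decreasing in pH so the root is unique. The pKa set
defaults to the EMBOSS values and is a function argument, because
published pI values are tool-dependent: different pKa tables legitimately
shift pI by ~0.1–0.3 units.

Transmembrane segmentation is a Kyte–Doolittle hydropathy scan: window 19,
threshold 1.6, minimum run length 15, short (< 3 residue) dips merged.
This is an explicit, documented stand-in for HMM-based TM predictors —
reproducing an HMM topology model is out of scope — and is calibrated
against the package's own generator, not against any external predictor.
Note the geometry this implies: a windowed mean erodes roughly
`(window−1)/4 ≈ 4` residues from each end of a hydrophobic segment before
it clears the threshold, so a segment must be ~8 residues longer than
`min_len` to be reliably detected. The membrane-protein generator
therefore plants 25-residue segments (typical of long TM helices) —
21-residue segments would produce above-threshold runs of ~13 residues
and fall below the 15-residue minimum by construction.

Subfamily grouping uses neighbor joining (`ape::nj`, with negative branch
lengths clamped to zero and the deficit moved to the sister branch) on
protein-identity distances, plus nearest-labelled-reference assignment
with a lexicographic, flagged tie-break. NJ is exact on additive matrices
(asserted up to 8 taxa), which is all this desk-scale stand-in for a full
maximum-likelihood phylogeny needs; bootstrap support is deliberately not
implemented.

## Promoter elements

Elements are IUPAC consensus strings in an editable JSON library; the
packaged defaults (ABRE `ACGTG`, HSE `AGAANNTTCT`, ARE `TGGTTT`, MBS
`CAACTG`, Box-W1 `TTGACC`, TC-rich `ATTTTCTTCA`) are standard literature
consensus forms. Proprietary scan services do not publish their matrices,
so absolute element counts on real promoters are not a validation surface
— recovery of planted instances is. Scanning reports every overlapping
match on both strands; minus-strand hits are found on the reverse
complement and reported at the promoter coordinate of their 5'-most base
on the sense strand, TSS-relative with no position 0. A palindromic
consensus therefore legitimately reports the same site twice, once per
strand.

## Expression and networks

qPCR relative expression uses the comparative-Ct method, `2^−ΔΔCt`, with
replicates averaged on the Ct scale before exponentiation.

Co-expression edges require sample Pearson correlation strictly greater
than the threshold (default 0.85 — the strict inequality follows the
"> 0.85" convention). Profiles are `log2(x + 1)`-transformed by default;
the transform is a documented, switchable choice since compendium analyses
rarely state it. Constant-profile genes have undefined correlation and are
skipped with a logged warning. Shared hubs are non-seed genes connected to
at least 2 seeds, ordered by seed-degree.

Enrichment is the upper-tail hypergeometric test (`stats::phyper`) of a
neighborhood against the background of all annotated genes in the matrix,
with Benjamini–Hochberg control (`stats::p.adjust`) and a q < 0.05
reporting cut. Annotations are a flat gene→term map; ontology-graph
propagation is out of scope.

## Variant consequences

Each (variant, gene) pair receives exactly one category, assigned by a
fixed precedence order: splice-site donor/acceptor (the canonical 2-base
intron ends, regardless of the actual dinucleotide) → start lost (any
change touching the initiator codon) → frame shift (CDS indel of length
not divisible by 3) → codon deletion (in-frame CDS indel) → stop gained →
non-synonymous → synonymous → start gained (5'UTR SNV creating a new
sense-strand ATG; no Kozak-context scoring) → non-genic. A precedence
order is necessary because the categories are not mutually exclusive;
one-category-per-call keeps summary tables additive. One consequence of
the order: a deletion running off an exon end always removes splice-window
bases and is therefore classified as a splice-site variant, not a
boundary error.

Coding effects are computed on the transcription-sense spliced CDS and
verified in the tests against an independent oracle that splices,
substitutes, translates both alleles and diffs the proteins — exhaustively
over every coding SNV of a 5-exon toy gene on both strands.

Per-gene summaries count only protein-affecting calls (synonymous and
non-genic calls are excluded from totals), report the fraction of counted
variants falling inside TMH segments to one decimal, and a per-kilobase
density to two decimals. Allele frequency is the alternate-allele count
over twice the number of *called* diploid genotypes; missing calls leave
the denominator entirely.

## Synthetic data and what passing tests mean

Every generator is a pure function of its seed (a private RNG stream is
used and restored, so callers' RNG state is untouched), and each labelled
item is validated against the corresponding analysis module before being
emitted.

The codon evolver is proposal–acceptance, not a matrix-exponential
substitution model: per proposal, a random site and base are drawn;
synonymous changes are accepted, nonsynonymous ones with probability
min(ω, 1) (for ω > 1 the asymmetry moves to the synonymous side at 1/ω,
which realizes the same ratio). A lineage evolves until its accepted
synonymous substitutions reach `target_ks/2` per ancestral synonymous
site, so realized pairwise divergence is calibrated to the target — the
truth bundle records realized event counts, not nominal parameters. This
is adequate at desk scale and keeps ground truth exact, but it is not a
time-reversible continuous-time model: codon-usage and
transition/transversion structure of real genes is absent, and NG86 point
estimates on single pairs scatter a few percent around the realized
values.

Expression modules share one latent profile per module; module profiles
are made exactly orthogonal (QR), so cross-module correlation is purely
noise-driven and within-module correlation at zero noise is exactly 1.
Real compendia have correlated conditions, batch structure and
heavy-tailed counts; recovering planted modules here validates the
thresholding logic, not robustness to those artifacts.

The eight-member scenario (`nhx_scenario`) wires everything together: two
duplicate pairs evolved to target Ks 0.22 and 0.20 under ω ≈ 0.23–0.25
(the regime of a ~11–12 MYA whole-genome duplication at the *Populus*
clock), three subfamilies built from distinct membrane-protein scaffolds
(10 planted TMHs, 12 for the PM class), 14/22/23-exon gene structures,
promoters with planted element complements (HSE-rich in the Endo/PM
members), a 24-condition expression matrix whose Endo/PM members share a
module with dedicated hub genes while one member is deliberately
partnerless, and a 20-individual variant panel spanning the consequence
categories. Elements are planted upstream of the TSS only, since the
+1..+500 part of the promoter window is the gene's own UTR/CDS sequence.

## Problem sizes and numerical tolerances

The shipped tests run the NG86-vs-oracle sweep over all 61 × 61 codon
pairs plus 100 random 50-codon alignments at 10⁻¹² tolerance; estimator
calibration over 200 replicates of 300-codon pairs (mean Ka/Ks within
±0.05 of ω = 0.25, where the mean's sampling error is ~0.004); network
recovery over 50 seeds with the cross-module edge rate held to the
analytic t-distribution tail at n = 24; exhaustive coding-SNV
classification on both strands of a 40-codon, 5-exon toy gene; and one
full scenario-plus-pipeline round trip with a byte-identity re-run check.
These sizes keep the default suite in the minutes range while leaving
every statistical assertion driven by an analytic bound or an independent
oracle rather than a tuned constant.

## Known limitations

* NG86 is a counting estimator: no transition/transversion weighting, no
  codon-frequency model, no among-site rate variation; saturated pairs
  error out rather than being extrapolated.
* Identity percentages depend on alignment scoring; external published
  values are approximate anchors only.
* The hydropathy TM caller knows nothing about topology (inside/outside
  loops) and will merge segments separated by < 3 residues.
* MW/pI reproduce any specific external tool only to the extent its mass
  and pKa tables match the documented defaults.
* Variant annotation is single-transcript; multi-nucleotide variants
  spanning splice junctions are rejected as unsupported rather than
  guessed at.
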