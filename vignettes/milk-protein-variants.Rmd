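---
title: "Milk protein variant analysis: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Milk protein variant analysis: models, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific conventions, models and design
choices behind **milkvar**, in the spirit of a methods section. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Six genes dominate the protein fraction of bovine milk: the casein cluster
*CSN1S1*, *CSN2*, *CSN1S2* and *CSN3* — four tightly linked genes on BTA6
inherited as haplotypes — and the whey protein genes *LALBA* and *LGB*.
Decades of protein electrophoresis established a nomenclature of named
protein variants (β-casein A1/A2, κ-casein A/B, β-lactoglobulin A/B, …)
that modern panel sequencing must map back onto DNA site-alleles. The
package implements the downstream analysis of such a panel: from a cohort
VCF to named-allele frequencies per breed, casein haplotype frequencies,
coding consequence notation, and regulatory-site gain/loss screens.

## Numbering: precursor vs mature protein

Milk protein nomenclature numbers amino acids in the **mature** protein,
after cleavage of the N-terminal signal peptide; translation of a CDS
yields **precursor** numbering. `milk_offsets()` holds the per-gene
difference. Two configurations ship, and this is a deliberate design
choice: the default `"table"` set is derived from the printed
mature/precursor position pairs of the allele catalog (CSN1S1 15, CSN2 50,
CSN1S2 15, CSN3 21, LALBA 48, LGB 16), because those offsets reproduce the
published variant positions verbatim. For CSN2 (50) and LALBA (48) they
disagree with the biological signal peptide lengths (15 and 19); the
`"canonical"` set carries the biological values. We do not attempt to
reconcile the two — the package reports both numberings explicitly in its
consequence records, which avoids the ambiguity altogether.

A consequence of the table-derived CSN2 offset is that mature position 197
corresponds to precursor 247, which exceeds the 224-residue real β-casein
precursor; the synthetic CSN2 model therefore carries a 250-codon CDS so
the published numbering is representable end to end.

## Frameshift notation

Frameshift consequences are written `p.XnYfs*m`. In this package —
following the usage in the milk protein literature rather than strict
HGVS — `m` counts the **changed residues inclusive of the first one**, so
the last amino acid before the novel stop sits at `n + m − 1`. For the
β-lactoglobulin adenine insertion this reads p.Thr92Asnfs*13: residues
92–104 are exchanged, the stop follows at 105, and the product is
104 mature residues long. `truncated_length()` implements exactly that
arithmetic (strict HGVS would place the stop itself at the m-th position
and write *14 for the same molecule). When the shifted frame reaches the
transcript end with no stop codon, the record carries a `no-stop` flag
instead of an offset.

## Variant normalization and decomposition

Records are right-trimmed, then left-trimmed keeping the VCF anchor base
for indels. Multi-nucleotide substitutions split positionally; complex
records are decomposed via Needleman–Wunsch global alignment (match +1,
mismatch −1, gap −2) with alignment columns classified into SNPs,
insertions and deletions. A lone indel is left-aligned; in multi-event
records indels keep their alignment anchors, and the rare cluster in which
a leading insertion shares its anchor base with another event is folded
back into one record rather than emitting overlapping primitives. The
invariant — jointly applying the atomic records reproduces the alternate
haplotype — is enforced by a 1,000-case property test.

Genotype calls whose read depth is known and below 8 are set missing
(configurable); calls with unknown depth are kept. Allele frequencies
exclude missing calls from the denominator and display with
round-half-away-from-zero to two decimals, so a single heterozygote among
27 diploids (1/54 ≈ 0.0185) prints 0.02.

## Allele typing

The allele catalog is **data, not code**: a TSV of defining site-alleles
per named variant (17 alleles over the six genes), extendable without
touching the engine. Assignment matches each chromosome copy to the unique
consistent definition. Animals heterozygous at more than one defining site
of a gene have ambiguous phase; they are resolved by the EM estimator run
over the gene's own sites, taking the maximum-posterior pair
(`phase_confidence = "em_phased"`), or flagged `ambiguous` on a posterior
tie. Site combinations matching no definition are reported
`unresolved-novel` with the observed alleles attached — precisely the
situation in which an intermediate allele (such as *LGB* B1, defined by
the Ala118Val missense plus the Asn88 synonymous site without the second
missense SNP of *LGB* A) is first recognized. Catalog alleles are stored
in forward-strand (VCF) orientation; for the reverse-strand *CSN2* this
means the published transcript-orientation alleles appear complemented.

Allele-name frequencies divide by 2 × resolved animals per group;
EM-phased and ambiguous animals contribute their posterior-weighted
fractional pair counts.

## EM haplotype estimation

Given unphased genotypes at the selected casein sites (overall minor
allele frequency ≥ 5%, boundary included), each individual's genotype
expands into its compatible ordered-pair-collapsed haplotype pairs. The
E-step assigns pair weights proportional to `p_h1 * p_h2` (doubled for
heterozygous pairs); the M-step sets each haplotype frequency to its
expected allele count over `2n`. Initialization is uniform over the
haplotypes observed in any expansion; convergence is declared at
`max |Δp| < 1e-8` (the tolerance is our choice — no published value
exists) with a 1,000-iteration cap. Identical multilocus genotypes are
collapsed to patterns first, so cost scales with the number of distinct
genotypes, not individuals. Individuals missing a genotype at any selected
site are excluded (a documented simplification; expanding over missing
data is a possible extension). Because the likelihood can be multimodal,
`n_start` adds seeded random restarts from the simplex; the default is a
single uniform start, which suffices on the cohort-scale problems the
tests exercise, while the oracle-equivalence tests use restarts to certify
the global maximum against a brute-force multi-start optimizer.

Haplotype labels translate site-alleles into allele names via the catalog
("B-A1-A-B"); a gene with no segregating site contributes its reference
allele name, and a within-gene combination matching no definition is
labelled `gene?` rather than forced to the nearest allele. Reports use the
published display conventions: two decimals, `<0.01` for positive
frequencies below 0.01, and an optional row filter keeping haplotypes
reaching 5% in at least one group.

## Regulatory scanning

miRNA sites follow the canonical seed-match taxonomy. For a seed+m8 (miRNA
positions 2–8), a site exists where the target contains the reverse
complement of positions 2–7; matching the m8 complement immediately 5′
gives 7mer-m8, an A immediately 3′ gives 7mer-A1, both give 8mer, and the
single strongest type is reported per locus. Scanning runs on
transcript-sense sequence in a window of ±(site length − 1) around the
variant, so only sites overlapping the variant can differ between alleles:
sites present only in the reference are losses, only in the alternate are
gains. Context scoring (AU content, conservation) is deliberately out of
scope — only site presence/type is compared.

TFBS scanning is a transparent position-weight-matrix log₂-odds scan
(`Σ log2((f + pseudocount)/background)`, both strands, JASPAR or minimal
MEME input) with a relative-score threshold of 0.85 by default (no
published threshold exists; the value is configurable). The
proprietary/web-based workflow the field often uses for TFBS annotation is
intentionally replaced by this auditable scan, so specific published TF
lists are not a comparison target — the gain/loss mechanics are.
UTR-variant screens cover the 5′UTR, 3′UTR and upstream region tags;
scoring miRNA sites in 5′UTRs is unconventional for target-prediction
tools, and we scan whatever regions are requested while noting that
convention mismatch.

## The synthetic data generator

`generate_reference()` builds a deterministic six-gene reference that
mirrors the real panel's design: gene names, strands and exon counts
(19, 9, 18, 5, 4, 7; *CSN2* on the minus strand), and — the load-bearing
property — the defining coding sites of the shipped catalog pinned to
their published genomic coordinates with codons chosen to produce the
documented amino-acid exchanges. The published inter-site spacings are
self-consistent with contiguous CDS (e.g. the three κ-casein exon-4 sites
are 210 and 246 bp apart, exactly matching their CDS offsets), which is
what makes this pinning possible. Everything else — introns, UTRs,
remaining codons — is pseudo-random but fully seed-determined. All outputs
are synthetic stand-ins and are labelled as such; no Ensembl sequence is
redistributed.

`generate_cohort()` samples two haplotypes per animal: casein haplotypes
jointly over the four genes from group-specific frequencies, whey alleles
independently per gene. The defaults are the study conditions: 27
crossbreed, 20 Lagune and 20 Somba animals; per-breed casein haplotype
frequencies from the published per-breed table (with `<0.01` entries taken
as 0.005 and columns renormalized); whey allele frequencies from the
published per-breed variant table; planted extra variants (synonymous,
splice-region, intronic, upstream/downstream and four regulatory UTR
variants) at frequency 0.10; and per-call depths uniform on 2–60 so the
depth-8 filter is non-trivial (no depth distribution is published; uniform
2–60 brackets the threshold). Planted miRNA sites are written into the
UTRs as 8mer sites over the variant; the two TFBS-gain motifs are 6-column
consensus matrices taken from the alternate-allele window, so a single
mismatch scores 5/6 ≈ 0.833 < 0.85 and the gain is by construction.
Truth tables record per-animal haplotypes and allele names, per-variant
region and consequence notation, and the planted regulatory effects.

What passing tests on this generator do show: coordinate arithmetic,
consequence calling, typing, EM estimation and scanning are correct on
data whose truth is known exactly, at the published coordinates and allele
definitions. What they do not show: robustness to real-data pathologies —
misaligned reads, genotyping error, depth-correlated missingness, catalog
sites in repetitive sequence — which are outside the model of this
generator.

## Problem sizes and numerics

The test suite runs the full pipeline on the 67-animal default cohort;
haplotype-recovery checks use 20 replicates of n = 1,000 and single
cohorts of n = 5,000 (where the top-haplotype estimate is required within
±0.02 of its target). Brute-force EM oracles run on ≤ 3 sites × ≤ 6
individuals, where exhaustive multi-start optimization is reliable.
Degenerate inputs are defined behaviour: empty VCFs produce empty reports
with a warning, a uniform PWM scores no hits (its relative score is
undefined), sites below the MAF threshold skip EM with a warning, and
groups with fewer than two complete individuals are skipped.

## Known limitations

* One transcript per gene; no multi-transcript consequence fan-out.
* Splice-region annotation is positional only (8 intronic / 3 exonic
  bases); no splice-strength scoring.
* The EM excludes individuals with missing genotypes at selected sites
  rather than marginalizing over them.
* Known/novel variant status is input metadata; there is no rs-ID lookup.
* No protein-level prediction (isoelectric point, function, pathogenicity).
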