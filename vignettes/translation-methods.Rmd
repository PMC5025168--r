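---
title: "Star-allele translation: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-allele translation: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxtranslate)
```

## The translation model

A pharmacogene's haplotype table assigns, for each variant (row) and each
named haplotype (column), one allele string. The first column is the
reference (wild-type) haplotype, and — following the PharmGKB convention —
it *defines* the major allele of every variant; a cell differing from the
reference cell carries a minor allele. Alleles are compared verbatim as
strings, so SNVs and short indels are handled identically, and no genomic
coordinates, strand or genome build enter the computation: everything is
keyed by dbSNP rsID.

Translation of an unphased genotype profile proceeds per gene:

1. **Curation** of the downloaded table: (i) variants without an rsID
   matching `^rs[0-9]+$` are deleted (the engine is restricted to
   dbSNP-registered variants); (ii) any haplotype that was defined by a
   minor allele of a deleted variant is deleted too, so every retained
   haplotype still carries all variants of its original definition;
   (iii) duplicate columns are collapsed. Curation is idempotent, never
   grows the table, and never removes the reference column.
2. **Encoding**: major allele → 0; up to three minor alleles per variant →
   1, 3, 5. The reference haplotype is thus the zero vector.
3. **Diplotype enumeration**: all $n(n+1)/2$ unordered pairs of the $n$
   haplotypes, each summarised by the elementwise sum of its two code
   vectors.
4. **Sample encoding**: each genotype call contributes the sum of its two
   allele codes. Addition is commutative, which is exactly why unphased
   genotypes suffice for this representation.
5. **Matching and phenotype**: the sample vector is compared with every
   diplotype sum vector; matches are classified WT/WT (green), WT/Var
   (yellow), Var/Var (red), or NoCall (grey) when nothing matches.

The WT/WT / WT/Var / Var/Var scheme is deliberately generic. It rests on
the strong assumption that haplotypes carrying more minor alleles are more
likely to perturb metabolism; it does not attempt CPIC-style
poor/intermediate/extensive/ultrarapid categories, activity scores or
dosing, which require curated functional evidence per allele.

## Why exhaustive matching, and what ambiguity means

The code set $\{1, 3, 5\}$ makes heterozygous pair sums distinguishable
from homozygous ones at bi-allelic variants (0+1 = 1 ≠ 2 = 1+1), but it is
not collision-free at tri-allelic variants: $1 + 5 = 3 + 3 = 6$. A
first-match loop would therefore silently depend on enumeration order. The
matcher instead returns *all* diplotypes whose sum vector equals the
sample's and sets an `ambiguous` flag; when the tied diplotypes disagree in
category, the most severe (Var/Var > WT/Var > WT/WT) is reported, keeping
the call conservative for screening purposes. Note that the ambiguity is a
property of the numeric representation, not of the genotype: an
allele-multiset comparison can discriminate $\{1,5\}$ from $\{3,3\}$, and
the test suite uses exactly that as an independent oracle — the multiset
matches are always a subset of the sum-vector matches, and the two agree
whenever no tri-allelic collision is present.

## Conventions that the data model fixes

Several details are underdetermined by the table format and had to be
fixed once, deterministically:

* **Minor-allele code order.** Codes 1, 3, 5 are assigned per variant in
  order of first appearance scanning haplotype columns left to right. Any
  fixed rule would do; this one makes encodings reproducible from the
  table alone.
* **Blank cells** in source tables denote the variant's reference allele
  (the common PharmGKB dialect) and are made explicit at load time.
* **Duplicate haplotypes** keep the earliest-listed name; discarded names
  are recorded as aliases rather than dropped silently.
* **Cross-gene rsID conflicts.** The unified annotation requires one major
  allele and one minor-code assignment per rsID. Conflicting definitions
  across gene tables raise an error instead of being resolved by
  precedence — a wrong silent merge would corrupt every downstream call
  for that variant.
* **Missing variants** in a profile are governed by an explicit policy:
  `assume_ref` (default) scores them 0 and records them in
  `missing_rsids`, which suits sparse genotyping panels; `no_call` makes
  the gene NoCall for that sample. The choice is surfaced in the result
  rather than buried.
* **Half and hemizygous calls** (single-allele GT) are treated as missing
  with a warning; sex-chromosome ploidy is out of scope.
* **No-match handling.** A vector matching no diplotype yields NoCall;
  nearest-haplotype imputation is deliberately not attempted.
* **Percentages** in gene/sample summaries are reported to one decimal
  place, with the rounding residual assigned to the largest category so
  rows sum to exactly 100.

## Knowledge-base updates

`add_haplotype()` appends a column defined by minor-allele assignments;
unassigned variants receive the major allele, and an assignment at a
brand-new rsID adds a row on which all existing haplotypes are major. This
construction makes updates *conservative*: existing diplotype sum vectors
are only extended with zeros, so any sample that does not match the new
haplotype keeps its previous call — the test suite asserts this on fixture
cohorts before and after updates. `create_gene_table()` builds a table
from scratch (first haplotype = reference, necessarily all-major) that is
immediately usable by the engine. Both operations are fixed points of the
curation pipeline, and both are file-based: each update writes a new
versioned table file rather than mutating state, so a translation run can
always be reproduced from its exact table files.

## Landscape statistics

For a set of gene records (chromosome, ADMET class, associated drugs) the
package builds the shared-drug graph: genes are nodes and an edge joins
two genes involved in the metabolism of at least one common drug. Density
is $|E| / \binom{|V|}{2}$ on the simple undirected graph; drug names are
matched exactly after case-folding and whitespace trimming, with no
synonym resolution. All input genes count toward $|V|$, including genes
with no drug annotation (their rows simply contribute no edges).
"Squareness" reports each table's variant and haplotype counts and their
ratio. Chromosome/class counts include explicitly the chromosomes with no
pharmacogene at all.

## The synthetic generator

`generate_haplotype_table()` emulates curated star-allele tables: an
all-major reference, 1–3 minor alleles per variant drawn from
$\{A, C, G, T\}$ plus occasional short indel strings (to exercise verbatim
allele comparison), pairwise-distinct columns, and rsIDs disjoint across
genes. `generate_cohort_vcf()` draws a diplotype per sample per gene
(uniform by default, or from user-supplied frequencies), writes genotypes
that are exactly the multiset union of the two haplotypes' alleles as an
unphased VCF, and returns the ground-truth assignment. Output is
byte-identical under a fixed seed, and the generators restore the caller's
RNG state.

What the generator does *not* emulate: linkage disequilibrium,
Hardy–Weinberg structure, population allele frequencies, genotyping error,
copy-number star alleles (`*1xN`) or phasing. Passing round-trip tests
therefore demonstrates the correctness of the translation algebra — that
encoding, enumeration and matching invert the simulation exactly — not
robustness to the noise and structural variation of real sequencing data.
A dedicated `generate_ambiguous_table()` constructs the tri-allelic
$1+5 = 3+3$ collision deterministically so the ambiguity contract is
always exercised.

## Problem sizes used in the checks

The shipped verification runs use tables of up to 30 haplotypes for the
counting law, 200 random tables (≤ 10 variants, ≤ 8 haplotypes, ≤ 3 minors
per variant) for oracle equivalence, and cohorts of 100 samples × 10 genes
(1000 sample-gene diplotypes) for round-trip recovery. These sizes cover
the combinatorial regimes of real pharmacogene tables — NAT2-scale column
counts, tri-allelic variants, indel alleles — while keeping the default
test run fast; all of them are plain parameters of the generators and can
be scaled up freely.

## Known limitations

* Matching is entirely rsID-keyed; VCF records lacking an rsID in the ID
  column are skipped, and positional fallback is not attempted.
* A sample genotyped on a strict subset of a gene's variants can only be
  called under an explicit missingness policy; with `assume_ref` the call
  is a lower bound on variant burden.
* The three-status scheme can over-call (WT/Var samples may metabolise
  normally); it is designed to rarely under-call.
* Tri-allelic sum collisions produce ambiguous (never wrong) calls; a
  future allele-multiset matching mode could resolve them at the cost of
  departing from the numeric-vector formulation.
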