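# pgxtranslate

Star-allele diplotype calling and metabolizer-status translation for
pharmacogenomics.

Clinically relevant pharmacogenes (CYP2D6, TPMT, NAT2, UGT1A5, ...) carry
named haplotypes — *star alleles* — each defined by a characteristic
combination of variant alleles in a gene's *haplotype table*: a variant ×
haplotype matrix whose first column is the reference (wild-type) haplotype
and thereby defines every variant's major allele. `pgxtranslate` takes such
tables together with unphased multi-sample VCF genotype profiles and infers
each sample's per-gene *diplotype* (unordered haplotype pair, e.g. `*2/*3`),
then classifies it into a three-level metabolizer status. It is aimed at
researchers who need reproducible genotype-to-phenotype translation for
panels of pharmacogenes without a phasing step.

## Method

For each gene the pipeline is:

1. **Curation.** Drop variants without a dbSNP rsID (`rs` + digits); drop
   haplotypes defined by a minor allele of a dropped variant (so every
   retained haplotype keeps its full original definition); drop duplicate
   haplotype columns.
2. **Numeric encoding.** Code the major allele 0 and up to three minor
   alleles per variant 1, 3, 5 (in order of first appearance across
   columns). Haplotype *h* becomes a code vector **h**; the reference is
   the zero vector.
3. **Diplotype enumeration.** All n(n+1)/2 unordered haplotype pairs
   {*h*, *k*}, each represented by the sum vector **h** + **k**.
4. **Sample encoding.** Each unphased genotype call maps to the sum of its
   two allele codes, giving the sample's per-gene sum vector — phase is
   never needed because addition is commutative.
5. **Matching and classification.** The sample vector is compared against
   *every* diplotype sum vector; all equal-sum diplotypes are returned
   (code sums can collide at tri-allelic variants, 1+5 = 3+3, so ambiguity
   is flagged rather than hidden). Reference/reference ⇒ WT/WT (green),
   reference/variant ⇒ WT/Var (yellow), variant/variant ⇒ Var/Var (red),
   no match ⇒ NoCall (grey).

The package also provides per-variant translation, gene/sample summary
statistics, knowledge-base updates (adding haplotypes, creating tables for
newly associated genes), landscape statistics over the shared-drug gene
graph (density, table "squareness", chromosome/ADMET-class counts), and a
synthetic-cohort generator with known ground truth for testing.

## Worked example

A UGT1A5-style table ships in `inst/extdata/ugt1a5_synthetic.csv` (a
synthetic reconstruction: four rsID variants, one HGVS-labelled row, four
haplotypes). Curation removes the non-rsID row and its dependent haplotype
`*4`:

```r
library(pgxtranslate)
tab <- read_haplotype_table(system.file("extdata", "ugt1a5_synthetic.csv",
                                        package = "pgxtranslate"), "UGT1A5")
cur <- curate_haplotype_table(tab)
e   <- encode_haplotypes(cur)
d   <- enumerate_diplotypes(e)
print(d)
#> 6 diplotypes for UGT1A5:
#>       rs12475068 rs1000002 rs1000003 rs1000004
#> *1/*1          0         0         0         0
#> *1/*2          1         0         0         0
#> *1/*3          0         1         0         0
#> *2/*2          2         0         0         0
#> *2/*3          1         1         0         0
#> *3/*3          0         2         0         0

p <- genotype_profile("NA00001", list(
  rs12475068 = c("C", "G"), rs1000002 = c("T", "C"),
  rs1000003 = c("A", "A"), rs1000004 = c("G", "G")))
match_diplotype(encode_sample(p, e), d)
#> NA00001 / UGT1A5: *2/*3 -> Var/Var (red)
```

The C/G call at rs12475068 encodes 0+1; the sample vector `<1,1,0,0>`
matches the `*2/*3` diplotype, i.e. two variant haplotypes — an "abnormal"
(red) metabolizer status. `translate_genotypes()` runs the same pipeline
for whole cohorts and returns the five-column report
(`sample_id`, `gene`, `diplotype`, `phenotype_color`,
`recommendation_link`):

```r
translate_genotypes(p, list(cur))$table
#>   sample_id   gene diplotype phenotype_color recommendation_link
#> 1   NA00001 UGT1A5     *2/*3             red        UGT1A5:*2/*3
```

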