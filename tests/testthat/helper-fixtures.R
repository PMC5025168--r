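# Shared fixtures, all built in code. The "UGT1A5-style" table is a
# synthetic reconstruction of a PharmGKB-dialect star-allele table: four
# registered variants plus one HGVS-labelled row, four haplotypes, blank
# cells denoting the reference allele, and haplotype *4 defined solely by
# the minor allele of the unregistered row.

ugt1a5_lines <- function() c(
  "variant,*1,*2,*3,*4",
  "rs12475068,C,G,,",
  "rs1000002,T,,C,",
  "rs1000003,A,,,",
  "rs1000004,G,,,",
  "c.776G>C,G,,,C"
)

ugt1a5_table <- function() read_haplotype_table(ugt1a5_lines(), "UGT1A5")

# the Fig-5-style worked profile: het at the first two variants,
# homozygous-major elsewhere; encodes to <1,1,0,0>
ugt1a5_profile <- function(id = "NA00001") genotype_profile(id, list(
  rs12475068 = c("C", "G"),
  rs1000002  = c("T", "C"),
  rs1000003  = c("A", "A"),
  rs1000004  = c("G", "G")
))

# synthetic TPMT-style table: the update scenario adds a haplotype defined
# jointly by rs1800460 and rs2842934, both already present individually
tpmt_table <- function() {
  alleles <- matrix(c(
    "C", "T", "C",
    "T", "T", "C"
  ), nrow = 2L, byrow = TRUE,
    dimnames = list(c("rs1800460", "rs2842934"), c("*1", "*2", "*3")))
  haplotype_table("TPMT", alleles, curated = TRUE)
}

asic2_table <- function() create_gene_table(
  "ASIC2",
  data.frame(rsid = "rs11869731", major = "G", stringsAsFactors = FALSE),
  list("1" = character(0), "2" = c(rs11869731 = "C"))
)

# brute-force matcher: loop over all unordered haplotype pairs, add the two
# code vectors element by element with scalar arithmetic, and compare to
# the sample vector; independent of the matrix implementation under test
brute_force_matches <- function(e, sample_sum) {
  haps <- c(e$reference_name, sort(setdiff(e$haplotype_names,
                                           e$reference_name)))
  out <- character(0)
  for (i in seq_along(haps)) {
    for (j in i:length(haps)) {
      s <- numeric(length(e$variant_ids))
      for (v in seq_along(e$variant_ids))
        s[v] <- e$codes[v, haps[i]] + e$codes[v, haps[j]]
      if (all(s == sample_sum))
        out <- c(out, paste(haps[i], haps[j], sep = "/"))
    }
  }
  out
}

# brute-force allele-level matcher: pairs whose per-variant allele multisets
# reproduce the sample's genotype exactly
multiset_matches <- function(t, calls) {
  haps <- c(t$reference_name, sort(setdiff(colnames(t$alleles),
                                           t$reference_name)))
  out <- character(0)
  for (i in seq_along(haps)) {
    for (j in i:length(haps)) {
      ok <- TRUE
      for (v in rownames(t$alleles)) {
        pair <- sort(c(t$alleles[v, haps[i]], t$alleles[v, haps[j]]))
        if (!identical(pair, sort(calls[[v]]))) { ok <- FALSE; break }
      }
      if (ok) out <- c(out, paste(haps[i], haps[j], sep = "/"))
    }
  }
  out
}

# a profile exactly consistent with a haplotype pair of a table
profile_from_pair <- function(t, h1, h2, id = "SIM") {
  calls <- lapply(rownames(t$alleles), function(v)
    c(t$alleles[v, h1], t$alleles[v, h2]))
  names(calls) <- rownames(t$alleles)
  genotype_profile(id, calls)
}

gene_metadata_fixture <- function() {
  path <- system.file("extdata", "gene_metadata_synthetic.csv",
                      package = "pgxtranslate")
  read_gene_metadata(path)
}
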