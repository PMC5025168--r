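enc_ugt <- function() encode_haplotypes(curate_haplotype_table(ugt1a5_table()))

test_that("diplotype enumeration yields n(n+1)/2 pairs with summed vectors", {
  e <- enc_ugt()
  d <- enumerate_diplotypes(e)
  expect_length(d, 6L)
  expect_equal(d$labels,
               c("*1/*1", "*1/*2", "*1/*3", "*2/*2", "*2/*3", "*3/*3"))
  expect_equal(unname(d$sums[d$labels == "*2/*3", ]), c(1, 1, 0, 0))
  expect_equal(unname(d$sums[d$labels == "*1/*1", ]), rep(0, 4))
  # single-haplotype gene: one self-pair, all-zero sum
  one <- encode_haplotypes(haplotype_table("G1", matrix("A", 1, 1,
           dimnames = list("rs1", "*1")), curated = TRUE))
  d1 <- enumerate_diplotypes(one)
  expect_length(d1, 1L)
  expect_equal(unname(d1$sums[1, ]), 0)
  for (n in c(2, 5, 12)) {
    t <- generate_haplotype_table("GN", 6, n, seed = n)
    expect_length(enumerate_diplotypes(encode_haplotypes(t)), n * (n + 1) / 2)
  }
})

test_that("sample encoding reproduces the worked sum vector", {
  e <- enc_ugt()
  s <- encode_sample(ugt1a5_profile(), e)
  expect_equal(unname(s$sum), c(1, 1, 0, 0))
  expect_length(s$missing_rsids, 0L)
  hom <- genotype_profile("H", list(rs12475068 = c("C", "C"),
    rs1000002 = c("T", "T"), rs1000003 = c("A", "A"),
    rs1000004 = c("G", "G")))
  expect_equal(unname(encode_sample(hom, e)$sum), rep(0, 4))
})

test_that("missing-variant policies behave as documented", {
  e <- enc_ugt()
  sparse <- genotype_profile("P", list(rs12475068 = c("C", "G"),
                                       rs1000002 = c("T", "C")))
  s <- encode_sample(sparse, e, missing_policy = "assume_ref")
  expect_equal(unname(s$sum), c(1, 1, 0, 0))
  expect_setequal(s$missing_rsids, c("rs1000003", "rs1000004"))
  expect_true(s$usable)
  # assume_ref equals an explicit hom-major oracle profile
  explicit <- encode_sample(ugt1a5_profile("P"), e)
  expect_equal(s$sum, explicit$sum)
  nc <- encode_sample(sparse, e, missing_policy = "no_call")
  expect_false(nc$usable)
  r <- match_diplotype(nc, enumerate_diplotypes(e))
  expect_length(r$matches, 0L)
  expect_equal(r$phenotype$category, "NoCall")
})

test_that("unknown alleles raise a named error", {
  e <- enc_ugt()
  bad <- genotype_profile("B", list(rs12475068 = c("C", "T")))
  expect_error(encode_sample(bad, e), "unknown allele 'T' at rs12475068")
})

test_that("matching returns the worked diplotype and handles edge vectors", {
  e <- enc_ugt()
  d <- enumerate_diplotypes(e)
  r <- match_diplotype(encode_sample(ugt1a5_profile(), e), d)
  expect_equal(r$matches, "*2/*3")
  expect_false(r$ambiguous)
  expect_equal(r$phenotype$category, "Var/Var")
  expect_equal(r$phenotype$color, "red")
  zero <- encode_sample(genotype_profile("Z", list(
    rs12475068 = c("C", "C"), rs1000002 = c("T", "T"),
    rs1000003 = c("A", "A"), rs1000004 = c("G", "G"))), e)
  expect_equal(match_diplotype(zero, d)$matches, "*1/*1")
  # no diplotype sums to an impossible vector -> NoCall
  s <- encode_sample(ugt1a5_profile(), e)
  s$sum[1] <- 99
  rn <- match_diplotype(s, d)
  expect_length(rn$matches, 0L)
  expect_equal(rn$phenotype$category, "NoCall")
  expect_equal(rn$phenotype$color, "grey")
  s2 <- s; s2$sum <- s$sum[-1]
  expect_error(match_diplotype(s2, d), "consistency")
})

test_that("colliding pair sums return all matches flagged ambiguous", {
  t <- generate_ambiguous_table()
  e <- encode_haplotypes(t)
  d <- enumerate_diplotypes(e)
  # a sample carrying alleles A..C minors coded 1 and 5 sums to 6, which
  # the 3+3 self-pair also reaches
  s <- encode_sample(profile_from_pair(t, "*2", "*4", "AMB"), e)
  r <- match_diplotype(s, d)
  expect_setequal(r$matches, c("*2/*4", "*3/*3"))
  expect_true(r$ambiguous)
  expect_equal(r$matches, brute_force_matches(e, s$sum))
  expect_equal(r$phenotype$category, "Var/Var")
})

test_that("phenotype assignment follows the three-status scheme", {
  e <- enc_ugt()
  d <- enumerate_diplotypes(e)
  mk <- function(h1, h2) {
    t <- curate_haplotype_table(ugt1a5_table())
    s <- encode_sample(profile_from_pair(t, h1, h2), e)
    match_diplotype(s, d)$phenotype
  }
  expect_equal(mk("*1", "*1")$category, "WT/WT")
  expect_equal(mk("*1", "*1")$color, "green")
  expect_equal(mk("*1", "*2")$category, "WT/Var")
  expect_equal(mk("*1", "*2")$color, "yellow")
  expect_equal(mk("*2", "*3")$category, "Var/Var")
})

test_that("ambiguous matches of mixed category report the most severe", {
  r <- structure(list(sample_id = "S", gene = "G",
                      matches = c("*1/*2", "*2/*2"),
                      match_pairs = rbind(c("*1", "*2"), c("*2", "*2")),
                      ambiguous = TRUE, phenotype = NULL,
                      missing_rsids = character(0), link_key = ""),
                 class = "translation_result")
  expect_equal(assign_phenotype(r, "*1")$category, "Var/Var")
})

test_that("per-variant translation counts minor alleles", {
  # rs10276036-style tri-state check on a synthetic registry entry
  ann <- structure(list(entries = list(
    rs10276036 = list(genes = "ABCB1", major = "C",
                      minor_codes = c(T = 1L)))),
    class = "variant_annotation")
  expect_equal(translate_variant(c("T", "T"), "rs10276036", ann)$category,
               "Var/Var")
  expect_equal(translate_variant(c("C", "C"), "rs10276036", ann)$category,
               "WT/WT")
  expect_equal(translate_variant(c("C", "T"), "rs10276036", ann)$category,
               "WT/Var")
  expect_equal(translate_variant(NA, "rs10276036", ann)$category, "NoCall")
  expect_error(translate_variant(c("G", "C"), "rs10276036", ann),
               "unknown allele")
  expect_error(translate_variant(c("C", "C"), "rs999", ann), "not in")
})

test_that("adding a minor allele never lowers per-variant severity", {
  ann <- structure(list(entries = list(
    rsX = list(genes = "G", major = "A", minor_codes = c(G = 1L, T = 3L)))),
    class = "variant_annotation")
  sev <- c("WT/WT" = 1, "WT/Var" = 2, "Var/Var" = 3)
  for (first in c("A", "G", "T")) {
    base <- translate_variant(c(first, "A"), "rsX", ann)$category
    for (minor in c("G", "T")) {
      up <- translate_variant(c(first, minor), "rsX", ann)$category
      expect_gte(sev[[up]], sev[[base]])
    }
  }
})

test_that("summaries equal a direct tally and round to exact 100", {
  mk <- function(sample, gene, cat) structure(list(
    sample_id = sample, gene = gene, matches = "x/y",
    match_pairs = rbind(c("x", "y")), ambiguous = FALSE,
    phenotype = phenotype_status(cat), missing_rsids = character(0),
    link_key = ""), class = "translation_result")
  res <- list(mk("S1", "G1", "WT/WT"), mk("S2", "G1", "Var/Var"),
              mk("S1", "G2", "WT/Var"), mk("S2", "G2", "WT/Var"),
              mk("S1", "G3", "WT/Var"), mk("S2", "G3", "NoCall"))
  bg <- summarize_by_gene(res)
  expect_equal(bg$`WT/WT`[bg$gene == "G1"], 50)
  expect_equal(bg$`Var/Var`[bg$gene == "G1"], 50)
  expect_equal(bg$`WT/Var`[bg$gene == "G1"], 0)
  expect_true(all(abs(rowSums(bg[, c("WT/WT", "WT/Var", "Var/Var",
                                     "NoCall")]) - 100) < 1e-9))
  bs <- summarize_by_sample(res)
  s1 <- bs[bs$sample_id == "S1", ]
  expect_equal(s1$`WT/WT`, 33.3)
  expect_equal(s1$`WT/Var`, 66.7)
  expect_true(all(abs(rowSums(bs[, c("WT/WT", "WT/Var", "Var/Var",
                                     "NoCall")]) - 100) < 1e-9))
  # randomized cohort equals the direct tally oracle
  set.seed(42)
  cats <- sample(c("WT/WT", "WT/Var", "Var/Var", "NoCall"), 60, TRUE)
  res2 <- mapply(mk, rep(sprintf("S%02d", 1:6), each = 10),
                 rep(sprintf("G%02d", 1:10), times = 6), cats,
                 SIMPLIFY = FALSE)
  bg2 <- summarize_by_gene(res2)
  df <- data.frame(gene = rep(sprintf("G%02d", 1:10), times = 6),
                   cat = cats)
  for (g in unique(df$gene)) {
    n <- sum(df$gene == g)
    for (k in c("WT/WT", "WT/Var", "Var/Var", "NoCall")) {
      got <- bg2[bg2$gene == g, k]
      want <- sum(df$gene == g & df$cat == k) / n * 100
      expect_lt(abs(got - want), 0.15)
    }
  }
})

test_that("a sample homozygous-major everywhere is WT/WT at every gene", {
  tables <- lapply(1:4, function(i)
    generate_haplotype_table(paste0("GREF", i), 5, 4, seed = i,
                             rsid_start = i * 100000L))
  calls <- list()
  for (t in tables)
    for (v in rownames(t$alleles))
      calls[[v]] <- rep(t$alleles[v, t$reference_name], 2L)
  tr <- translate_genotypes(genotype_profile("REF", calls), tables)
  expect_true(all(tr$table$phenotype_color == "green"))
  expect_true(all(vapply(tr$results, function(r)
    r$phenotype$category, character(1)) == "WT/WT"))
})

test_that("rsID filtering restricts the markers entering translation", {
  t <- curate_haplotype_table(ugt1a5_table())
  p <- ugt1a5_profile()
  full <- translate_genotypes(p, list(t))
  expect_equal(full$table$diplotype, "*2/*3")
  flt <- read_rsid_list(c("rs12475068", "rs1000002"))
  part <- translate_genotypes(p, list(t), rsid_filter = flt)
  expect_equal(part$table$diplotype, "*2/*3")
  expect_error(translate_genotypes(p, list(t), rsid_filter = "rs424242"),
               "no variants")
})

test_that("allele-multiset matching is a refinement of sum matching", {
  # the multiset oracle can distinguish {1,5} from {3,3}; its matches are
  # always a subset of the sum-vector matches, with equality whenever no
  # tri-allelic variant is present
  for (k in 1:25) {
    max_m <- if (k %% 2 == 0) 3L else 2L
    t <- generate_haplotype_table("GMS", 5, 5, max_minors = max_m,
                                  seed = 600 + k)
    e <- encode_haplotypes(t)
    d <- enumerate_diplotypes(e)
    set.seed(700 + k)
    pair <- sample(colnames(t$alleles), 2L, replace = TRUE)
    prof <- profile_from_pair(t, pair[1L], pair[2L])
    sum_m <- match_diplotype(encode_sample(prof, e), d)$matches
    mult_m <- multiset_matches(t, prof$calls)
    expect_true(all(mult_m %in% sum_m))
    tri <- any(vapply(e$minor_codes, length, integer(1)) >= 3L)
    if (!tri) expect_setequal(mult_m, sum_m)
  }
  # on the constructed collision the multiset oracle keeps only the true
  # pair while sum matching reports both
  t <- generate_ambiguous_table()
  e <- encode_haplotypes(t)
  prof <- profile_from_pair(t, "*2", "*4")
  sum_m <- match_diplotype(encode_sample(prof, e),
                           enumerate_diplotypes(e))$matches
  expect_setequal(sum_m, c("*2/*4", "*3/*3"))
  expect_equal(multiset_matches(t, prof$calls), "*2/*4")
})
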