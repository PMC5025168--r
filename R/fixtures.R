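#' Synthetic fixtures: haplotype tables and cohort VCFs with known truth
#'
#' Generators producing star-allele haplotype tables and multi-sample VCFs
#' whose per-sample diplotypes are known, so the translation engine can be
#' exercised end to end without external databases. Alleles are drawn from
#' \{A, C, G, T\} plus occasional short indel strings (to exercise verbatim
#' string comparison); genotypes are written unphased. No population-genetic
#' realism (linkage, Hardy-Weinberg) is attempted: diplotype frequencies
#' are user-specified knobs only.
#'
#' @name synthetic_fixtures
#' @keywords internal
NULL

# run fn() under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  } else assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  fn()
}

.bases <- c("A", "C", "G", "T")

.random_allele <- function(exclude, indel_prob) {
  if (stats::runif(1) < indel_prob) {
    repeat {
      a <- paste(sample(.bases, sample(2:4, 1L), replace = TRUE),
                 collapse = "")
      if (!a %in% exclude) return(a)
    }
  }
  pool <- setdiff(.bases, exclude)
  if (length(pool) == 0L)
    return(.random_allele(exclude, indel_prob = 1))
  sample(pool, 1L)
}

#' Generate a synthetic haplotype table
#'
#' Builds a curated-shape gene table: the reference haplotype carries only
#' major alleles, every other haplotype carries at least one minor allele,
#' and columns are pairwise distinct. Reproducible under \code{seed}.
#'
#' @param gene gene symbol.
#' @param n_variants number of variant rows (>= 1).
#' @param n_haplotypes number of haplotype columns including the reference
#'   (>= 1).
#' @param max_minors maximum distinct minor alleles per variant (1-3).
#' @param indel_prob probability a minor allele is a short indel string.
#' @param seed integer seed.
#' @param rsid_start first rsID number; defaults to a deterministic value
#'   derived from the gene symbol so different genes get disjoint rsIDs.
#' @return a curated \code{\link{haplotype_table}}.
#' @export
generate_haplotype_table <- function(gene, n_variants, n_haplotypes,
                                     max_minors = 3, indel_prob = 0.05,
                                     seed = 1L, rsid_start = NULL) {
  stopifnot(n_variants >= 1L, n_haplotypes >= 1L,
            max_minors >= 1L, max_minors <= 3L)
  if (is.null(rsid_start))
    rsid_start <- sum(utf8ToInt(gene) * seq_along(utf8ToInt(gene))) * 1000L
  if (n_haplotypes - 1 > (max_minors + 1)^n_variants - 1)
    stop("infeasible request: ", n_haplotypes, " distinct haplotypes cannot ",
         "be formed from ", n_variants, " variants with at most ",
         max_minors, " minor alleles each")
  .with_seed(seed, function() {
    ids <- sprintf("rs%d", rsid_start + seq_len(n_variants))
    majors <- sample(.bases, n_variants, replace = TRUE)
    minors <- lapply(seq_len(n_variants), function(i) {
      k <- sample.int(max_minors, 1L)
      out <- character(0)
      for (j in seq_len(k))
        out <- c(out, .random_allele(c(majors[i], out), indel_prob))
      out
    })
    n_states <- vapply(minors, length, integer(1)) + 1L
    if (n_haplotypes - 1 > prod(n_states) - 1) {
      # drawn minor counts too small for the request; force the maximum
      minors <- lapply(seq_len(n_variants), function(i) {
        out <- minors[[i]]
        while (length(out) < max_minors)
          out <- c(out, .random_allele(c(majors[i], out), indel_prob))
        out
      })
      n_states <- rep(max_minors + 1L, n_variants)
    }
    # state 1 = major; states 2.. = minors
    state_allele <- function(i, s)
      if (s == 1L) majors[i] else minors[[i]][s - 1L]
    cols <- matrix(1L, n_variants, 1L)  # reference column
    if (n_haplotypes > 1L) {
      if (prod(n_states) <= 4096) {
        all_states <- as.matrix(expand.grid(lapply(n_states, seq_len)))
        nonref <- all_states[rowSums(all_states != 1L) > 0L, , drop = FALSE]
        pick <- sample.int(nrow(nonref), n_haplotypes - 1L)
        cols <- cbind(cols, t(nonref[pick, , drop = FALSE]))
      } else {
        seen <- paste(cols[, 1L], collapse = ",")
        while (ncol(cols) < n_haplotypes) {
          cand <- vapply(n_states, function(k) sample.int(k, 1L), integer(1))
          if (all(cand == 1L)) next
          key <- paste(cand, collapse = ",")
          if (key %in% seen) next
          seen <- c(seen, key)
          cols <- cbind(cols, cand)
        }
      }
    }
    alleles <- matrix("", n_variants, n_haplotypes,
                      dimnames = list(ids, c("*1",
                                             if (n_haplotypes > 1L)
                                               paste0("*", 1L +
                                                      seq_len(n_haplotypes - 1L)))))
    for (i in seq_len(n_variants))
      for (j in seq_len(n_haplotypes))
        alleles[i, j] <- state_allele(i, cols[i, j])
    haplotype_table(gene, alleles, curated = TRUE)
  })
}

#' Generate a table with colliding diplotype sums
#'
#' Deterministically constructs a table whose minor-allele codes produce a
#' pair-sum collision (1 + 5 = 3 + 3 = 6 at a tri-allelic variant), so that
#' two distinct diplotypes (*2/*4 and *3/*3) share a sum vector. Used to
#' test the all-matches ambiguity contract.
#'
#' @param gene gene symbol.
#' @param rsid_start first rsID number.
#' @return a curated \code{haplotype_table} with 2 variants and 4
#'   haplotypes.
#' @export
generate_ambiguous_table <- function(gene = "AMBIG1", rsid_start = 9000000L) {
  ids <- sprintf("rs%d", rsid_start + 1:2)
  alleles <- matrix(c("A", "G", "T", "C",
                      "C", "C", "C", "C"),
                    nrow = 2L, byrow = TRUE,
                    dimnames = list(ids, c("*1", "*2", "*3", "*4")))
  haplotype_table(gene, alleles, curated = TRUE)
}

#' Generate a multi-sample cohort VCF with known diplotypes
#'
#' Draws a diplotype per sample per gene (uniformly over the gene's
#' diplotypes, or from supplied frequencies), emits genotypes exactly
#' consistent with the drawn haplotype pair (the allele pair at each
#' variant is the multiset union of the two haplotypes' alleles, written
#' unphased), and returns the VCF text together with the ground-truth
#' table for recovery testing. Byte-identical output for identical seeds.
#'
#' @param tables list of curated \code{haplotype_table}s.
#' @param n_samples number of samples.
#' @param diplotype_freqs optional named list: gene -> named numeric vector
#'   of frequencies over that gene's diplotype labels (must sum to 1).
#' @param seed integer seed.
#' @param file optional path; when given the VCF text is written there.
#' @return list with \code{vcf} (character vector of VCF lines) and
#'   \code{truth} (data frame \code{sample_id}, \code{gene},
#'   \code{diplotype}).
#' @export
generate_cohort_vcf <- function(tables, n_samples, diplotype_freqs = NULL,
                                seed = 1L, file = NULL) {
  stopifnot(n_samples >= 1L)
  tables <- lapply(tables, function(t)
    if (t$curated) t else curate_haplotype_table(t))
  encoded <- lapply(tables, encode_haplotypes)
  dipsets <- lapply(encoded, enumerate_diplotypes)
  samples <- sprintf("S%04d", seq_len(n_samples))
  .with_seed(seed, function() {
    truth <- list()
    records <- list()
    pos <- 0L
    for (k in seq_along(tables)) {
      t <- tables[[k]]; e <- encoded[[k]]; d <- dipsets[[k]]
      probs <- rep(1 / length(d$labels), length(d$labels))
      if (!is.null(diplotype_freqs) && !is.null(diplotype_freqs[[t$gene]])) {
        f <- diplotype_freqs[[t$gene]]
        if (!all(names(f) %in% d$labels))
          stop("frequencies name unknown diplotypes for gene ", t$gene)
        if (abs(sum(f) - 1) > 1e-8)
          stop("frequencies for gene ", t$gene, " must sum to 1")
        probs <- stats::setNames(rep(0, length(d$labels)), d$labels)
        probs[names(f)] <- f
      }
      draw <- sample.int(length(d$labels), n_samples, replace = TRUE,
                         prob = probs)
      truth[[k]] <- data.frame(sample_id = samples, gene = t$gene,
                               diplotype = d$labels[draw],
                               stringsAsFactors = FALSE)
      for (i in seq_along(e$variant_ids)) {
        pos <- pos + 100L
        id <- e$variant_ids[i]
        ref <- e$major[[id]]
        alts <- names(e$minor_codes[[id]])
        idx_of <- stats::setNames(seq_along(c(ref, alts)) - 1L, c(ref, alts))
        gts <- vapply(seq_len(n_samples), function(s) {
          pair <- d$pairs[draw[s], ]
          a <- sort(idx_of[c(t$alleles[id, pair[1L]],
                             t$alleles[id, pair[2L]])])
          paste(a, collapse = "/")
        }, character(1))
        records[[length(records) + 1L]] <- paste(
          c("1", pos, id, ref,
            if (length(alts)) paste(alts, collapse = ",") else ".",
            ".", ".", ".", "GT", gts),
          collapse = "\t")
      }
    }
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=pgxtranslate synthetic cohort generator",
      "##contig=<ID=1>",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", samples), collapse = "\t"))
    vcf <- c(header, unlist(records))
    if (!is.null(file)) writeLines(vcf, file)
    list(vcf = vcf, truth = do.call(rbind, truth))
  })
}
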