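#' Phenotype status categories and colors
#'
#' The translation service classifies each sample-gene diplotype into one of
#' three metabolizer statuses, plus a no-call category when no diplotype
#' matches: WT/WT (two reference haplotypes, "normal", green), WT/Var (one
#' reference and one variant haplotype, "intermediate", yellow), Var/Var
#' (two variant haplotypes, "abnormal", red) and NoCall (grey).
#'
#' @param category one of \code{"WT/WT"}, \code{"WT/Var"}, \code{"Var/Var"},
#'   \code{"NoCall"}.
#' @return a \code{phenotype_status} object with fields \code{category} and
#'   \code{color}.
#' @export
phenotype_status <- function(category) {
  colors <- c("WT/WT" = "green", "WT/Var" = "yellow",
              "Var/Var" = "red", "NoCall" = "grey")
  category <- match.arg(category, names(colors))
  structure(list(category = category, color = unname(colors[category])),
            class = "phenotype_status")
}

#' @export
print.phenotype_status <- function(x, ...) {
  cat(x$category, paste0("(", x$color, ")"), "\n")
  invisible(x)
}

# severity order used when ambiguous matches disagree in category
.severity <- c("WT/WT" = 1L, "WT/Var" = 2L, "Var/Var" = 3L)

.pair_category <- function(pair, reference_name) {
  n_ref <- sum(pair == reference_name)
  c("Var/Var", "WT/Var", "WT/WT")[n_ref + 1L]
}

#' Enumerate a gene's diplotypes and their sum vectors
#'
#' Forms all unordered haplotype pairs (including self-pairs) of an encoded
#' table; a gene with n haplotypes has n(n+1)/2 diplotypes. Each diplotype's
#' sum vector is the elementwise sum of its two haplotype code vectors.
#' Pairs are enumerated in a deterministic order: haplotypes are taken
#' reference-first then lexicographically, and pairs nest in that order
#' (ref/ref, ref/h2, ..., h2/h2, h2/h3, ...).
#'
#' @param e an \code{encoded_table}.
#' @return an object of class \code{diplotype_set} with fields \code{gene},
#'   \code{pairs} (2-column character matrix of haplotype names),
#'   \code{labels} (e.g. \code{"*2/*3"}), \code{sums} (numeric matrix,
#'   diplotypes x variants) and \code{reference_name}.
#' @export
enumerate_diplotypes <- function(e) {
  stopifnot(inherits(e, "encoded_table"))
  haps <- e$haplotype_names
  ord <- c(e$reference_name, sort(setdiff(haps, e$reference_name)))
  n <- length(ord)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  pairs <- cbind(ord[idx[, "row"]], ord[idx[, "col"]])
  sums <- e$codes[, pairs[, 1L], drop = FALSE] +
    e$codes[, pairs[, 2L], drop = FALSE]
  structure(list(
    gene = e$gene,
    pairs = pairs,
    labels = paste(pairs[, 1L], pairs[, 2L], sep = "/"),
    sums = t(sums),
    variant_ids = e$variant_ids,
    reference_name = e$reference_name
  ), class = "diplotype_set")
}

#' @export
print.diplotype_set <- function(x, ...) {
  cat(sprintf("%d diplotypes for %s:\n", length(x$labels), x$gene))
  m <- x$sums
  rownames(m) <- x$labels
  print(m)
  invisible(x)
}

#' @export
length.diplotype_set <- function(x) length(x$labels)

#' Construct a sample genotype profile
#'
#' @param sample_id sample identifier.
#' @param calls named list, rsID -> character vector of the two (unordered)
#'   allele strings; a missing call is \code{NA}.
#' @return a \code{genotype_profile} object.
#' @export
genotype_profile <- function(sample_id, calls) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, is.list(calls))
  ok <- vapply(calls, function(x)
    (length(x) == 1L && is.na(x)) || (is.character(x) && length(x) == 2L),
    logical(1))
  if (!all(ok))
    stop("calls must be length-2 allele pairs or NA; offending rsID(s): ",
         paste(names(calls)[!ok], collapse = ", "))
  structure(list(sample_id = sample_id, calls = calls),
            class = "genotype_profile")
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat("Genotype profile", x$sample_id, "-", length(x$calls), "call(s)\n")
  invisible(x)
}

#' Numerically encode a sample's genotypes for one gene
#'
#' Maps each observed allele at the gene's variants to its numeric code
#' (0 for the major allele, 1/3/5 for minors) via the encoded table, and
#' sums the two codes per variant to form the sample's diplotype sum
#' vector. Variants absent from the profile are handled according to
#' \code{missing_policy}: under \code{"assume_ref"} they contribute 0 (the
#' homozygous-major value) and are recorded in \code{missing_rsids}; under
#' \code{"no_call"} any missing variant makes the vector unusable, which
#' downstream matching reports as NoCall.
#'
#' @param profile a \code{genotype_profile}.
#' @param e the gene's \code{encoded_table}.
#' @param annotation optional \code{variant_annotation}; used to validate
#'   alleles against the unified registry when supplied.
#' @param missing_policy \code{"assume_ref"} (default) or \code{"no_call"}.
#' @return a \code{sample_gene_vector} with fields \code{sample_id},
#'   \code{gene}, \code{sum} (numeric vector over the gene's variants),
#'   \code{missing_rsids}, \code{usable} and \code{policy}.
#' @export
encode_sample <- function(profile, e, annotation = NULL,
                          missing_policy = c("assume_ref", "no_call")) {
  stopifnot(inherits(profile, "genotype_profile"), inherits(e, "encoded_table"))
  missing_policy <- match.arg(missing_policy)
  sums <- stats::setNames(numeric(length(e$variant_ids)), e$variant_ids)
  missing_rsids <- character(0)
  for (id in e$variant_ids) {
    call <- profile$calls[[id]]
    if (is.null(call) || anyNA(call)) {
      missing_rsids <- c(missing_rsids, id)
      next
    }
    lut <- c(stats::setNames(0L, e$major[id]), e$minor_codes[[id]])
    if (!is.null(annotation) && !is.null(annotation$entries[[id]])) {
      a <- annotation$entries[[id]]
      lut <- c(stats::setNames(0L, a$major), a$minor_codes, lut)
      lut <- lut[!duplicated(names(lut))]
    }
    unknown <- setdiff(call, names(lut))
    if (length(unknown))
      stop("unknown allele '", unknown[1L], "' at ", id, " for sample ",
           profile$sample_id, " (known: ",
           paste(names(lut), collapse = ", "), ")")
    sums[id] <- sum(lut[call])
  }
  structure(list(
    sample_id = profile$sample_id,
    gene = e$gene,
    sum = sums,
    missing_rsids = missing_rsids,
    usable = !(missing_policy == "no_call" && length(missing_rsids) > 0L),
    policy = missing_policy
  ), class = "sample_gene_vector")
}

#' Match a sample's sum vector against a gene's diplotypes
#'
#' Compares the sample's per-variant sum vector with every diplotype sum
#' vector of the gene and returns all diplotypes whose vectors are equal.
#' Because minor-allele codes are drawn from \{1, 3, 5\}, pair sums can
#' collide at tri-allelic variants (1 + 5 = 3 + 3); exhaustive matching
#' therefore returns every matching pair and flags ambiguity rather than
#' stopping at the first hit. An empty match set yields a NoCall result.
#'
#' @param s a \code{sample_gene_vector}.
#' @param diplotypes the gene's \code{diplotype_set}.
#' @param reference_name reference haplotype name (defaults to the set's).
#' @return a \code{translation_result} with fields \code{sample_id},
#'   \code{gene}, \code{matches} (character vector of diplotype labels),
#'   \code{ambiguous}, \code{phenotype}, \code{missing_rsids} and
#'   \code{link_key}.
#' @export
match_diplotype <- function(s, diplotypes,
                            reference_name = diplotypes$reference_name) {
  stopifnot(inherits(s, "sample_gene_vector"),
            inherits(diplotypes, "diplotype_set"))
  if (length(s$sum) != ncol(diplotypes$sums))
    stop("internal consistency error: sample vector length ", length(s$sum),
         " != diplotype vector length ", ncol(diplotypes$sums),
         " for gene ", s$gene)
  hits <- if (s$usable) {
    which(colSums(t(diplotypes$sums) != s$sum) == 0L)
  } else integer(0)
  matches <- diplotypes$labels[hits]
  r <- structure(list(
    sample_id = s$sample_id,
    gene = s$gene,
    matches = matches,
    match_pairs = diplotypes$pairs[hits, , drop = FALSE],
    ambiguous = length(matches) > 1L,
    phenotype = NULL,
    missing_rsids = s$missing_rsids,
    link_key = if (length(matches) == 1L)
      paste(s$gene, matches, sep = ":") else ""
  ), class = "translation_result")
  r$phenotype <- assign_phenotype(r, reference_name)
  r
}

#' Assign a metabolizer phenotype status to a translation result
#'
#' A reference/reference diplotype is WT/WT (green), reference/other is
#' WT/Var (yellow), other/other is Var/Var (red), and an empty match set is
#' NoCall (grey). When ambiguous matches disagree in category, the most
#' severe (Var/Var > WT/Var > WT/WT) is reported; the ambiguity flag is
#' preserved on the result.
#'
#' @param r a \code{translation_result}.
#' @param reference_name the gene's reference haplotype name.
#' @return a \code{\link{phenotype_status}}.
#' @export
assign_phenotype <- function(r, reference_name) {
  stopifnot(inherits(r, "translation_result"))
  if (length(r$matches) == 0L) return(phenotype_status("NoCall"))
  cats <- apply(r$match_pairs, 1L, .pair_category,
                reference_name = reference_name)
  phenotype_status(names(.severity)[max(.severity[cats])])
}

#' @export
print.translation_result <- function(x, ...) {
  dip <- if (length(x$matches)) paste(x$matches, collapse = "|") else "-"
  cat(sprintf("%s / %s: %s -> %s (%s)%s\n", x$sample_id, x$gene, dip,
              x$phenotype$category, x$phenotype$color,
              if (x$ambiguous) " [ambiguous]" else ""))
  invisible(x)
}

#' Per-variant translation
#'
#' Reports a metabolizer status for a single variant call, independently of
#' any haplotype table: two major alleles give WT/WT, one minor WT/Var, two
#' minor alleles (equal or not) Var/Var, and a missing call NoCall.
#'
#' @param call character vector of the two allele strings, or \code{NA} for
#'   a missing call.
#' @param rsid the variant's rsID.
#' @param annotation a \code{variant_annotation} containing \code{rsid}.
#' @return a \code{\link{phenotype_status}}.
#' @export
translate_variant <- function(call, rsid, annotation) {
  stopifnot(inherits(annotation, "variant_annotation"))
  entry <- annotation$entries[[rsid]]
  if (is.null(entry)) stop("rsID ", rsid, " is not in the annotation")
  if (length(call) == 1L && is.na(call)) return(phenotype_status("NoCall"))
  if (length(call) != 2L) stop("call must be two alleles or NA")
  known <- c(entry$major, names(entry$minor_codes))
  unknown <- setdiff(call, known)
  if (length(unknown))
    stop("unknown allele '", unknown[1L], "' at ", rsid,
         " (known: ", paste(known, collapse = ", "), ")")
  n_minor <- sum(call != entry$major)
  phenotype_status(c("WT/WT", "WT/Var", "Var/Var")[n_minor + 1L])
}

# percentages to one decimal; the rounding residual of an exact-100 row is
# assigned to the largest category
.round_percent <- function(counts) {
  total <- sum(counts)
  if (total == 0L) return(stats::setNames(rep(0, length(counts)), names(counts)))
  p <- round(counts / total * 100, 1L)
  resid <- round(100 - sum(p), 1L)
  if (resid != 0) {
    i <- which.max(counts)
    p[i] <- round(p[i] + resid, 1L)
  }
  p
}

.categories <- c("WT/WT", "WT/Var", "Var/Var", "NoCall")

.results_frame <- function(results) {
  data.frame(
    sample_id = vapply(results, `[[`, character(1), "sample_id"),
    gene = vapply(results, `[[`, character(1), "gene"),
    category = vapply(results, function(r) r$phenotype$category, character(1)),
    stringsAsFactors = FALSE
  )
}

.summarize_by <- function(results, key) {
  df <- .results_frame(results)
  out <- do.call(rbind, lapply(split(df, df[[key]]), function(d) {
    counts <- stats::setNames(
      vapply(.categories, function(k) sum(d$category == k), numeric(1)),
      .categories)
    cbind(data.frame(key = d[[key]][1L], n = nrow(d),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(.round_percent(counts)),
                        check.names = FALSE))
  }))
  names(out)[1L] <- key
  rownames(out) <- NULL
  out[order(out[[key]]), , drop = FALSE]
}

#' Gene summary statistics
#'
#' Per gene, the percentage of samples assigned each diplotype category
#' (WT/WT, WT/Var, Var/Var, NoCall). Percentages are reported to one
#' decimal place and each row sums to exactly 100.
#'
#' @param results list of \code{translation_result} objects.
#' @return a data frame with one row per gene.
#' @export
summarize_by_gene <- function(results) .summarize_by(results, "gene")

#' Sample summary statistics
#'
#' Per sample, the percentage of genes assigned each diplotype category;
#' the mirror of \code{\link{summarize_by_gene}}.
#'
#' @param results list of \code{translation_result} objects.
#' @return a data frame with one row per sample.
#' @export
summarize_by_sample <- function(results) .summarize_by(results, "sample_id")

#' Translate genotype profiles to star-allele diplotypes and phenotypes
#'
#' The main entry point of the package. For every sample and every gene
#' table it encodes the sample's genotypes numerically, matches the
#' resulting sum vector against the gene's enumerated diplotypes, and
#' classifies the match into a metabolizer status. An optional rsID filter
#' restricts the translation to a chosen marker set.
#'
#' @param profiles list of \code{genotype_profile} objects (e.g. from
#'   \code{\link{read_genotype_vcf}}).
#' @param tables list of \code{haplotype_table} objects; uncurated tables
#'   are curated first.
#' @param rsid_filter optional \code{rsid_filter} or character vector of
#'   rsIDs restricting the variants entering the matching.
#' @param missing_policy see \code{\link{encode_sample}}.
#' @return an object of class \code{pgx_translation}: a list with
#'   \code{results} (the per sample-gene \code{translation_result}s),
#'   \code{table} (the five-column report data frame) and the curated
#'   inputs.
#' @examples
#' t <- generate_haplotype_table("GENE1", n_variants = 4, n_haplotypes = 3,
#'                               seed = 1)
#' sim <- generate_cohort_vcf(list(t), n_samples = 3, seed = 2)
#' vcf <- tempfile(fileext = ".vcf"); writeLines(sim$vcf, vcf)
#' ann <- derive_annotation(list(t))
#' profiles <- read_genotype_vcf(vcf, annotation = ann)
#' tr <- translate_genotypes(profiles, list(t))
#' tr$table
#' @export
translate_genotypes <- function(profiles, tables, rsid_filter = NULL,
                                missing_policy = c("assume_ref", "no_call")) {
  missing_policy <- match.arg(missing_policy)
  if (inherits(profiles, "genotype_profile")) profiles <- list(profiles)
  tables <- lapply(tables, function(t)
    if (t$curated) t else curate_haplotype_table(t))
  encoded <- lapply(tables, encode_haplotypes)
  if (!is.null(rsid_filter)) {
    keep_ids <- if (inherits(rsid_filter, "rsid_filter"))
      rsid_filter$rsids else as.character(rsid_filter)
    encoded <- lapply(encoded, function(e) .subset_encoded(e, keep_ids))
    encoded <- Filter(Negate(is.null), encoded)
    if (length(encoded) == 0L)
      stop("rsID filter leaves no variants in any gene table")
  }
  annotation <- derive_annotation(encoded)
  dipsets <- lapply(encoded, enumerate_diplotypes)
  results <- list()
  for (p in profiles) {
    for (k in seq_along(encoded)) {
      s <- encode_sample(p, encoded[[k]], annotation, missing_policy)
      results[[length(results) + 1L]] <- match_diplotype(s, dipsets[[k]])
    }
  }
  structure(list(
    results = results,
    table = report_table(results),
    tables = tables,
    annotation = annotation,
    missing_policy = missing_policy
  ), class = "pgx_translation")
}

# restrict an encoded table to the given rsIDs; NULL when nothing remains
.subset_encoded <- function(e, rsids) {
  keep <- e$variant_ids %in% rsids
  if (!any(keep)) return(NULL)
  e$variant_ids <- e$variant_ids[keep]
  e$codes <- e$codes[keep, , drop = FALSE]
  e$major <- e$major[keep]
  e$minor_codes <- e$minor_codes[keep]
  e
}

#' @export
print.pgx_translation <- function(x, ...) {
  df <- x$table
  cat(sprintf("PGx translation: %d sample(s) x %d gene(s), %d result row(s)\n",
              length(unique(df$sample_id)), length(unique(df$gene)), nrow(df)))
  cats <- vapply(x$results, function(r) r$phenotype$category, character(1))
  print(table(factor(cats, levels = .categories)))
  n_amb <- sum(vapply(x$results, `[[`, logical(1), "ambiguous"))
  if (n_amb) cat(n_amb, "ambiguous result(s)\n")
  invisible(x)
}

#' @export
summary.pgx_translation <- function(object, ...) {
  out <- list(by_gene = summarize_by_gene(object$results),
              by_sample = summarize_by_sample(object$results))
  class(out) <- "summary.pgx_translation"
  out
}

#' @export
print.summary.pgx_translation <- function(x, ...) {
  cat("Per-gene diplotype category percentages:\n")
  print(x$by_gene, row.names = FALSE)
  cat("\nPer-sample diplotype category percentages:\n")
  print(x$by_sample, row.names = FALSE)
  invisible(x)
}
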