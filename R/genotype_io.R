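#' Read an rsID list for customized translation
#'
#' Reads a plain-text file with one rsID per line. Blank lines and
#' \code{#} comments are tolerated; tokens that are not valid rsIDs are
#' reported with their line numbers and skipped.
#'
#' @param source path to a file, or a character vector of lines.
#' @return an object of class \code{rsid_filter} holding the deduplicated
#'   rsID set.
#' @export
read_rsid_list <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  tokens <- trimws(sub("#.*$", "", lines))
  nonblank <- which(nzchar(tokens))
  ok <- is_rsid(tokens[nonblank])
  if (any(!ok))
    warning("skipping ", sum(!ok), " malformed rsID token(s) at line(s) ",
            paste(nonblank[!ok], collapse = ", "), ": ",
            paste(utils::head(tokens[nonblank][!ok], 5L), collapse = ", "))
  rsids <- unique(tokens[nonblank][ok])
  if (length(rsids) == 0L)
    stop("no valid rsIDs found in the list")
  structure(list(rsids = rsids), class = "rsid_filter")
}

#' @export
print.rsid_filter <- function(x, ...) {
  cat("rsID filter:", length(x$rsids), "variant(s)\n")
  invisible(x)
}

#' Read sample genotype profiles from a VCF file
#'
#' Parses a multi-sample VCF (v4.x) and returns one genotype profile per
#' sample. Records are matched to the pharmacovariant registry by the ID
#' column (rsID); records whose ID is absent from the annotation (or from
#' the optional rsID filter) are skipped. Multi-allelic records are
#' expanded so each GT index maps to its allele string. Phase separators
#' \code{|} and \code{/} are both accepted and phase is discarded; missing
#' (\code{./.}) and half calls are marked missing.
#'
#' @param source path to a VCF file (plain or bgzipped).
#' @param annotation a \code{variant_annotation}; only records whose ID it
#'   contains are retained.
#' @param filter optional \code{rsid_filter} restricting records further.
#' @return list of \code{\link{genotype_profile}} objects, one per sample.
#' @export
read_genotype_vcf <- function(source, annotation, filter = NULL) {
  stopifnot(inherits(annotation, "variant_annotation"))
  vcf <- tryCatch(vcfR::read.vcfR(source, verbose = FALSE),
                  error = function(e)
                    stop("unreadable VCF '", source, "': ",
                         conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && is.null(dim(fix)))  # single-record VCF drops dims
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0L) stop("VCF contains no records")
  gt_raw <- vcf@gt
  if (is.null(dim(gt_raw)))
    gt_raw <- matrix(gt_raw, nrow = 1L, dimnames = list(NULL, names(gt_raw)))
  if (!"GT" %in% unlist(strsplit(gt_raw[, "FORMAT"], ":")))
    stop("VCF has no GT field")
  ids <- fix[, "ID"]
  keep <- !is.na(ids) & ids != "." & ids %in% names(annotation$entries)
  if (!is.null(filter)) {
    stopifnot(inherits(filter, "rsid_filter"))
    keep <- keep & ids %in% filter$rsids
  }
  samples <- colnames(gt_raw)[-1L]
  if (length(samples) == 0L) stop("VCF contains no sample columns")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, samples))
  calls_by_sample <- lapply(samples, function(s) list())
  names(calls_by_sample) <- samples
  for (i in which(keep)) {
    id <- ids[i]
    alleles <- c(fix[i, "REF"],
                 if (!is.na(fix[i, "ALT"]) && fix[i, "ALT"] != ".")
                   strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]])
    for (s in samples) {
      g <- gt[i, s]
      call <- .parse_gt(g, alleles)
      if (!is.null(calls_by_sample[[s]][[id]])) next  # first record wins
      calls_by_sample[[s]][[id]] <- call
    }
  }
  lapply(samples, function(s) genotype_profile(s, calls_by_sample[[s]]))
}

# GT string -> unordered allele pair, or NA for missing/half/hemizygous calls
.parse_gt <- function(g, alleles) {
  if (is.na(g) || g == "") return(NA)
  parts <- strsplit(g, "[/|]")[[1L]]
  if (length(parts) != 2L || any(parts == ".")) return(NA)
  idx <- suppressWarnings(as.integer(parts)) + 1L
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(alleles))) return(NA)
  alleles[idx]
}

#' Assemble the five-column translation report table
#'
#' Columns are \code{sample_id}, \code{gene}, \code{diplotype} (matches
#' joined with \code{|} when ambiguous, \code{"-"} for NoCall),
#' \code{phenotype_color} and \code{recommendation_link} (empty string when
#' none). Rows are ordered by sample then gene, lexicographically.
#'
#' @param results list of \code{translation_result} objects.
#' @return a data frame.
#' @export
report_table <- function(results) {
  df <- data.frame(
    sample_id = vapply(results, `[[`, character(1), "sample_id"),
    gene = vapply(results, `[[`, character(1), "gene"),
    diplotype = vapply(results, function(r)
      if (length(r$matches)) paste(r$matches, collapse = "|") else "-",
      character(1)),
    phenotype_color = vapply(results, function(r) r$phenotype$color,
                             character(1)),
    recommendation_link = vapply(results, `[[`, character(1), "link_key"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$sample_id, df$gene, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a translation report
#'
#' Writes the five-column report as TSV, or as a JSON array of result
#' objects (\code{\{sample, gene, diplotype, phenotype: \{category, color\},
#' missing_rsids, link\}}).
#'
#' @param results list of \code{translation_result} objects, or a
#'   \code{pgx_translation}.
#' @param destination output file path.
#' @param format \code{"tsv"} (default) or \code{"json"}.
#' @return \code{destination}, invisibly.
#' @export
write_report <- function(results, destination, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "pgx_translation")) results <- results$results
  if (length(results) == 0L)
    stop("no translation results to write")
  if (format == "tsv") {
    utils::write.table(report_table(results), destination, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    ord <- order(vapply(results, `[[`, character(1), "sample_id"),
                 vapply(results, `[[`, character(1), "gene"),
                 method = "radix")
    objs <- lapply(results[ord], function(r) list(
      sample = r$sample_id,
      gene = r$gene,
      diplotype = if (length(r$matches))
        paste(r$matches, collapse = "|") else "-",
      phenotype = list(category = r$phenotype$category,
                       color = r$phenotype$color),
      missing_rsids = as.list(r$missing_rsids),
      link = r$link_key
    ))
    jsonlite::write_json(objs, destination, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(destination)
}
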