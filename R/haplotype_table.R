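#' Star-allele haplotype tables
#'
#' A haplotype table is a gene's variant-by-haplotype matrix of allele
#' assignments. Rows are variants (keyed by identifier, normally a dbSNP
#' rsID), columns are named haplotypes (star alleles such as \code{"*1"}),
#' and the first haplotype column is the reference (wild-type) haplotype.
#' By convention the reference column defines the major allele of every
#' variant; any cell differing from it carries a minor allele.
#'
#' @name haplotype_table
#' @keywords internal
NULL

.rsid_pattern <- "^rs[0-9]+$"

#' Test whether identifiers are dbSNP-registered rsIDs
#'
#' An identifier is considered registered when it matches \code{rs} followed
#' by digits. HGVS-style labels (\code{"c.776G>C"}) and positional labels
#' (\code{"chr7:117559590"}) are unregistered.
#'
#' @param x character vector of variant identifiers.
#' @return logical vector.
#' @export
is_rsid <- function(x) grepl(.rsid_pattern, x)

#' Construct a haplotype table object
#'
#' Low-level constructor; most users should call
#' \code{\link{read_haplotype_table}} or \code{\link{generate_haplotype_table}}.
#'
#' @param gene gene symbol.
#' @param alleles character matrix of allele strings with variant identifiers
#'   as row names and haplotype names as column names. Column 1 is the
#'   reference haplotype.
#' @param curated logical; whether the table has already passed curation.
#' @return an object of class \code{haplotype_table}.
#' @export
haplotype_table <- function(gene, alleles, curated = FALSE) {
  if (!is.matrix(alleles) || !is.character(alleles))
    stop("'alleles' must be a character matrix")
  if (is.null(rownames(alleles)) || is.null(colnames(alleles)))
    stop("'alleles' must have variant row names and haplotype column names")
  if (ncol(alleles) < 1L || nrow(alleles) < 1L)
    stop("haplotype table for gene '", gene, "' is empty")
  if (anyDuplicated(rownames(alleles)))
    stop("duplicate variant identifiers in table for gene '", gene, "': ",
         paste(unique(rownames(alleles)[duplicated(rownames(alleles))]),
               collapse = ", "))
  if (anyDuplicated(colnames(alleles)))
    stop("duplicate haplotype names in table for gene '", gene, "'")
  if (any(!nzchar(alleles)))
    stop("empty allele cell in table for gene '", gene, "'")
  structure(list(
    gene = gene,
    alleles = alleles,
    reference_name = colnames(alleles)[1L],
    registered = is_rsid(rownames(alleles)),
    curated = curated,
    removed_variants = NULL,
    removed_haplotypes = character(0),
    aliases = list()
  ), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Haplotype table for %s: %d variant(s) x %d haplotype(s)%s\n",
              x$gene, nrow(x$alleles), ncol(x$alleles),
              if (x$curated) " [curated]" else ""))
  cat("Reference haplotype:", x$reference_name, "\n")
  print(x$alleles, quote = FALSE)
  invisible(x)
}

#' @export
dim.haplotype_table <- function(x) dim(x$alleles)

#' Read a haplotype table from delimited text
#'
#' Reads a gene's haplotype table from CSV or TSV text. The header row holds
#' the haplotype names (its first cell labels the variant-identifier column
#' and is ignored); each subsequent row is one variant. Blank cells denote
#' the reference allele of that variant and are filled in from the first
#' haplotype column at load time.
#'
#' @param source path to a file, or a character vector of lines.
#' @param gene gene symbol for the table.
#' @param sep field separator; by default tab if the header contains one,
#'   otherwise comma.
#' @return an uncurated \code{\link{haplotype_table}}.
#' @export
read_haplotype_table <- function(source, gene, sep = NULL) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("haplotype table for gene '", gene,
         "' is empty: need a header and at least one variant row")
  if (is.null(sep)) sep <- if (grepl("\t", lines[1L])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  fields <- lapply(fields, function(f) trimws(f))
  header <- fields[[1L]]
  if (length(header) < 2L)
    stop("header of table for gene '", gene, "' names no haplotypes")
  hap_names <- header[-1L]
  width <- length(header)
  rows <- fields[-1L]
  for (i in seq_along(rows)) {
    # trailing blank cells are legitimate (they denote reference alleles)
    if (length(rows[[i]]) < width)
      rows[[i]] <- c(rows[[i]], rep("", width - length(rows[[i]])))
    if (length(rows[[i]]) != width)
      stop("ragged row in table for gene '", gene, "': row ", i,
           " ('", rows[[i]][1L], "') has ", length(rows[[i]]),
           " fields, expected ", width)
  }
  ids <- vapply(rows, `[[`, character(1), 1L)
  if (any(!nzchar(ids)))
    stop("row ", which(!nzchar(ids))[1L], " of table for gene '", gene,
         "' has no variant identifier")
  if (anyDuplicated(ids))
    stop("duplicate variant identifiers in table for gene '", gene, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  alleles <- do.call(rbind, lapply(rows, function(r) r[-1L]))
  dimnames(alleles) <- list(ids, hap_names)
  blank_ref <- !nzchar(alleles[, 1L])
  if (any(blank_ref))
    stop("reference allele missing for variant(s) ",
         paste(ids[blank_ref], collapse = ", "), " in gene '", gene, "'")
  for (j in seq_len(ncol(alleles))) {
    blank <- !nzchar(alleles[, j])
    alleles[blank, j] <- alleles[blank, 1L]
  }
  haplotype_table(gene, alleles)
}

#' Write a haplotype table to delimited text
#'
#' Inverse of \code{\link{read_haplotype_table}}; round-trips exactly.
#'
#' @param t a \code{haplotype_table}.
#' @param path output file path.
#' @param sep field separator; defaults to comma, or tab when any haplotype
#'   name or allele contains a comma (joint-variant haplotype names such as
#'   \code{"rs1800460, rs2842934"} do).
#' @return \code{path}, invisibly.
#' @export
write_haplotype_table <- function(t, path, sep = NULL) {
  stopifnot(inherits(t, "haplotype_table"))
  if (is.null(sep))
    sep <- if (any(grepl(",", c(colnames(t$alleles), rownames(t$alleles),
                                t$alleles), fixed = TRUE))) "\t" else ","
  header <- paste(c("variant", colnames(t$alleles)), collapse = sep)
  body <- vapply(seq_len(nrow(t$alleles)), function(i)
    paste(c(rownames(t$alleles)[i], t$alleles[i, ]), collapse = sep),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Remove variants lacking a dbSNP rsID
#'
#' Curation sub-step (i): variants whose identifier is not a registered rsID
#' are deleted; the removed rows (with their alleles) are recorded on the
#' returned table so that dependent haplotypes can subsequently be dropped.
#'
#' @param t a \code{haplotype_table}.
#' @return the table restricted to registered variants, with the removed
#'   rows recorded in \code{$removed_variants}.
#' @export
drop_unregistered_variants <- function(t) {
  stopifnot(inherits(t, "haplotype_table"))
  keep <- is_rsid(rownames(t$alleles))
  if (!any(keep))
    stop("all variants of gene '", t$gene,
         "' lack a registered rsID; table would be empty")
  removed <- t$alleles[!keep, , drop = FALSE]
  t$alleles <- t$alleles[keep, , drop = FALSE]
  t$registered <- rep(TRUE, nrow(t$alleles))
  t$removed_variants <- if (nrow(removed)) removed else t$removed_variants
  t
}

#' Remove haplotypes orphaned by variant removal
#'
#' Curation sub-step (ii): any haplotype defined (in part) by the minor
#' allele of a variant removed in sub-step (i) is deleted, so every retained
#' haplotype still carries all variants of its original definition. The
#' reference haplotype is never removed (it carries only major alleles).
#'
#' @param t a \code{haplotype_table}, after
#'   \code{\link{drop_unregistered_variants}}.
#' @param removed allele matrix of the removed variant rows; defaults to the
#'   record stored on \code{t}.
#' @return the table with orphaned haplotype columns removed.
#' @export
drop_orphaned_haplotypes <- function(t, removed = t$removed_variants) {
  stopifnot(inherits(t, "haplotype_table"))
  if (is.null(removed) || nrow(removed) == 0L) return(t)
  # a haplotype survives iff it carried the major (reference) allele at
  # every removed variant
  major <- removed[, t$reference_name]
  orphan <- apply(removed != major, 2L, any)
  orphan[t$reference_name] <- FALSE
  if (any(orphan)) {
    t$removed_haplotypes <- c(t$removed_haplotypes,
                              colnames(t$alleles)[orphan[colnames(t$alleles)]])
    t$alleles <- t$alleles[, !orphan[colnames(t$alleles)], drop = FALSE]
  }
  t
}

#' Remove duplicate haplotype columns
#'
#' Curation sub-step (iii): among haplotypes with identical allele vectors
#' only the earliest-listed (leftmost) is kept; the discarded names are
#' recorded as aliases of the survivor. Marks the table curated.
#'
#' @param t a \code{haplotype_table}.
#' @return the deduplicated, curated table.
#' @export
dedupe_haplotypes <- function(t) {
  stopifnot(inherits(t, "haplotype_table"))
  key <- apply(t$alleles, 2L, paste, collapse = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    for (j in which(dup)) {
      keeper <- colnames(t$alleles)[match(key[j], key)]
      t$aliases[[keeper]] <- c(t$aliases[[keeper]], colnames(t$alleles)[j])
    }
    t$alleles <- t$alleles[, !dup, drop = FALSE]
  }
  t$registered <- is_rsid(rownames(t$alleles))
  t$curated <- TRUE
  t
}

#' Curate a haplotype table
#'
#' Runs the three curation sub-steps in order: (i) delete variants without a
#' registered rsID, (ii) delete haplotypes orphaned by (i), (iii) delete
#' duplicate haplotypes. Idempotent: curating an already-curated table
#' returns it unchanged.
#'
#' @param t a \code{haplotype_table}.
#' @return the curated table.
#' @export
curate_haplotype_table <- function(t) {
  stopifnot(inherits(t, "haplotype_table"))
  if (all(is_rsid(rownames(t$alleles)))) {
    t$registered <- rep(TRUE, nrow(t$alleles))
    return(dedupe_haplotypes(t))
  }
  t <- drop_unregistered_variants(t)
  t <- drop_orphaned_haplotypes(t)
  dedupe_haplotypes(t)
}

#' Numerically encode a curated haplotype table
#'
#' Each allele is converted to a numeric code: 0 for the major allele and
#' 1, 3, 5 for up to three minor alleles of a variant. Minor alleles are
#' assigned codes in order of first appearance scanning the haplotype
#' columns left to right. The reference haplotype therefore encodes to the
#' all-zero vector.
#'
#' @param t a curated \code{haplotype_table}.
#' @return an object of class \code{encoded_table} with fields \code{gene},
#'   \code{variant_ids}, \code{haplotype_names}, \code{codes} (integer
#'   matrix, variants x haplotypes), \code{major} (named character vector of
#'   major alleles) and \code{minor_codes} (per-variant named integer vector
#'   mapping minor alleles to their codes).
#' @export
encode_haplotypes <- function(t) {
  stopifnot(inherits(t, "haplotype_table"))
  if (!t$curated)
    stop("table for gene '", t$gene, "' must be curated before encoding")
  codes <- matrix(0L, nrow(t$alleles), ncol(t$alleles),
                  dimnames = dimnames(t$alleles))
  major <- t$alleles[, 1L]
  names(major) <- rownames(t$alleles)
  minor_codes <- vector("list", nrow(t$alleles))
  names(minor_codes) <- rownames(t$alleles)
  code_set <- c(1L, 3L, 5L)
  for (i in seq_len(nrow(t$alleles))) {
    row <- t$alleles[i, ]
    minors <- unique(row[row != major[i]])
    if (length(minors) > 3L)
      stop("variant ", rownames(t$alleles)[i], " of gene '", t$gene,
           "' has ", length(minors),
           " distinct minor alleles; at most 3 are supported")
    mc <- if (length(minors)) {
      stats::setNames(code_set[seq_along(minors)], minors)
    } else stats::setNames(integer(0), character(0))
    minor_codes[[i]] <- mc
    if (length(mc)) codes[i, ] <- ifelse(row == major[i], 0L, mc[row])
  }
  structure(list(
    gene = t$gene,
    variant_ids = rownames(t$alleles),
    haplotype_names = colnames(t$alleles),
    reference_name = t$reference_name,
    codes = codes,
    major = major,
    minor_codes = minor_codes
  ), class = "encoded_table")
}

#' @export
print.encoded_table <- function(x, ...) {
  cat(sprintf("Encoded haplotype table for %s (%d variants, %d haplotypes)\n",
              x$gene, length(x$variant_ids), length(x$haplotype_names)))
  print(x$codes)
  invisible(x)
}

#' Decode an encoded table back to its allele matrix
#'
#' Maps numeric codes back to allele strings; inverse of
#' \code{\link{encode_haplotypes}}.
#'
#' @param e an \code{encoded_table}.
#' @return character matrix of alleles.
#' @export
decode_haplotypes <- function(e) {
  stopifnot(inherits(e, "encoded_table"))
  out <- matrix("", nrow(e$codes), ncol(e$codes), dimnames = dimnames(e$codes))
  for (i in seq_len(nrow(e$codes))) {
    mc <- e$minor_codes[[i]]
    lut <- stats::setNames(c(e$major[i], names(mc)), c("0", as.character(mc)))
    out[i, ] <- lut[as.character(e$codes[i, ])]
  }
  out
}

#' Derive the unified variant annotation table
#'
#' Builds the per-rsID registry of major and minor alleles across a set of
#' curated gene tables, following the convention that each table's first
#' haplotype column defines the major alleles. An rsID shared by several
#' genes must have consistent major allele and minor-allele code
#' assignments; conflicting definitions raise an error rather than being
#' silently resolved.
#'
#' @param tables list of curated \code{haplotype_table} (or
#'   \code{encoded_table}) objects.
#' @return an object of class \code{variant_annotation}: a named list of
#'   entries, one per rsID, each with fields \code{genes}, \code{major} and
#'   \code{minor_codes} (named integer vector, minor allele -> code).
#' @export
derive_annotation <- function(tables) {
  entries <- list()
  for (t in tables) {
    e <- if (inherits(t, "encoded_table")) t else {
      if (!t$curated) stop("table for gene '", t$gene, "' is not curated")
      encode_haplotypes(t)
    }
    for (i in seq_along(e$variant_ids)) {
      id <- e$variant_ids[i]
      if (!is_rsid(id)) next
      new <- list(genes = e$gene, major = unname(e$major[i]),
                  minor_codes = e$minor_codes[[i]])
      old <- entries[[id]]
      if (is.null(old)) {
        entries[[id]] <- new
      } else {
        if (!identical(old$major, new$major))
          stop("conflicting major alleles for ", id, ": '", old$major,
               "' (", paste(old$genes, collapse = ","), ") vs '", new$major,
               "' (", e$gene, ")")
        shared <- intersect(names(old$minor_codes), names(new$minor_codes))
        if (any(old$minor_codes[shared] != new$minor_codes[shared]))
          stop("conflicting minor-allele codes for ", id, " between genes ",
               paste(old$genes, collapse = ","), " and ", e$gene)
        merged <- old$minor_codes
        extra <- setdiff(names(new$minor_codes), names(merged))
        merged[extra] <- new$minor_codes[extra]
        if (length(merged) > 3L)
          stop("more than 3 distinct minor alleles for ", id,
               " across gene tables")
        old$minor_codes <- merged
        old$genes <- union(old$genes, e$gene)
        entries[[id]] <- old
      }
    }
  }
  structure(list(entries = entries), class = "variant_annotation")
}

#' @export
print.variant_annotation <- function(x, ...) {
  cat("Variant annotation:", length(x$entries), "rsID(s)\n")
  for (id in utils::head(names(x$entries), 10L)) {
    e <- x$entries[[id]]
    cat(sprintf("  %s [%s] major %s; minor %s\n", id,
                paste(e$genes, collapse = ","), e$major,
                paste(sprintf("%s=%d", names(e$minor_codes), e$minor_codes),
                      collapse = ", ")))
  }
  if (length(x$entries) > 10L) cat("  ...\n")
  invisible(x)
}
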