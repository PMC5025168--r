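#' Add a haplotype to an existing gene table
#'
#' Appends a new haplotype column defined by minor-allele assignments at
#' named variants. An assignment at a variant already in the table must use
#' one of that variant's existing alleles (major or minor). An assignment
#' at a brand-new rsID registers a new variant row: its major allele must
#' be supplied via \code{majors}, every existing haplotype receives the
#' major allele at the new row, and the new haplotype receives the assigned
#' (minor) allele. Variants without an assignment receive the major allele.
#' The updated table is revalidated against all curation invariants, so
#' adding a haplotype never perturbs existing diplotype matches: prior sum
#' vectors are merely extended with zeros at any new variant.
#'
#' @param t a curated \code{haplotype_table}.
#' @param name name for the new haplotype (e.g. \code{"rs1800460, rs2842934"}).
#' @param assignments named character vector, rsID -> allele.
#' @param majors named character vector supplying the major allele for any
#'   rsID in \code{assignments} that is new to the table.
#' @return the updated, curated \code{haplotype_table}.
#' @export
add_haplotype <- function(t, name, assignments, majors = character(0)) {
  stopifnot(inherits(t, "haplotype_table"))
  if (!t$curated) t <- curate_haplotype_table(t)
  if (name %in% colnames(t$alleles))
    stop("haplotype '", name, "' already exists in gene '", t$gene, "'")
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    stop("assignments must be named by rsID")
  if (any(!is_rsid(names(assignments))))
    stop("unregistered variant identifier(s) in assignments: ",
         paste(names(assignments)[!is_rsid(names(assignments))],
               collapse = ", "))
  alleles <- t$alleles
  new_ids <- setdiff(names(assignments), rownames(alleles))
  for (id in new_ids) {
    if (is.null(names(majors)) || !id %in% names(majors))
      stop("new variant ", id,
           " needs its major allele supplied via 'majors'")
    if (majors[[id]] == assignments[[id]])
      stop("new variant ", id,
           " must be assigned a minor allele distinct from its major '",
           majors[[id]], "'")
    alleles <- rbind(alleles,
                     matrix(majors[[id]], 1L, ncol(alleles),
                            dimnames = list(id, colnames(alleles))))
  }
  for (id in intersect(names(assignments), rownames(t$alleles))) {
    existing <- unique(t$alleles[id, ])
    if (!assignments[[id]] %in% existing)
      stop("allele '", assignments[[id]], "' at ", id,
           " is not among the variant's existing alleles (",
           paste(existing, collapse = ", "), ")")
  }
  newcol <- alleles[, t$reference_name]
  newcol[names(assignments)] <- assignments
  dup <- which(apply(alleles == newcol, 2L, all))
  if (length(dup))
    stop("new haplotype '", name, "' duplicates existing haplotype '",
         colnames(alleles)[dup[1L]], "'")
  alleles <- cbind(alleles, newcol)
  colnames(alleles)[ncol(alleles)] <- name
  out <- haplotype_table(t$gene, alleles, curated = TRUE)
  out$aliases <- t$aliases
  stopifnot(identical(curate_haplotype_table(out)$alleles, out$alleles))
  out
}

#' Create a haplotype table for a newly associated gene
#'
#' Builds a gene table from scratch, e.g. after the discovery of a new
#' gene-drug association. The first haplotype definition becomes the
#' reference and must carry only major alleles; every other haplotype is
#' defined by minor-allele assignments relative to the supplied majors.
#'
#' @param gene gene symbol.
#' @param variants data frame with columns \code{rsid} and \code{major};
#'   all rsIDs must be registered.
#' @param haplotype_defs named list: haplotype name -> named character
#'   vector of rsID -> allele assignments. The first element is the
#'   reference; its assignments (if any) must equal the major alleles.
#' @return a curated \code{haplotype_table} immediately usable by the
#'   translation engine.
#' @export
create_gene_table <- function(gene, variants, haplotype_defs) {
  stopifnot(is.data.frame(variants),
            all(c("rsid", "major") %in% names(variants)))
  if (nrow(variants) < 1L) stop("at least one variant is required")
  if (any(!is_rsid(variants$rsid)))
    stop("unregistered variant identifier(s): ",
         paste(variants$rsid[!is_rsid(variants$rsid)], collapse = ", "))
  if (length(haplotype_defs) < 1L || is.null(names(haplotype_defs)))
    stop("at least one named haplotype definition is required")
  majors <- stats::setNames(as.character(variants$major), variants$rsid)
  alleles <- matrix(rep(majors, length(haplotype_defs)),
                    nrow = nrow(variants),
                    dimnames = list(variants$rsid, names(haplotype_defs)))
  for (k in seq_along(haplotype_defs)) {
    asg <- haplotype_defs[[k]]
    if (length(asg) == 0L) next
    bad <- setdiff(names(asg), variants$rsid)
    if (length(bad))
      stop("assignment at unknown variant(s): ", paste(bad, collapse = ", "))
    if (k == 1L && any(asg != majors[names(asg)]))
      stop("reference haplotype '", names(haplotype_defs)[1L],
           "' must carry only major alleles")
    alleles[names(asg), k] <- asg
  }
  key <- apply(alleles, 2L, paste, collapse = "\r")
  if (anyDuplicated(key))
    stop("duplicate haplotype definitions: ",
         paste(colnames(alleles)[duplicated(key)], collapse = ", "))
  haplotype_table(gene, alleles, curated = TRUE)
}

#' Write a versioned haplotype table file
#'
#' Updates are file-based for reproducibility of translation runs: each
#' applied update writes a new table version named
#' \code{<gene>_<timestamp>.csv} rather than mutating an online store.
#'
#' @param t a \code{haplotype_table}.
#' @param dir output directory (created if needed).
#' @param timestamp version tag; defaults to the current UTC time.
#' @return the written file path, invisibly.
#' @export
save_table_version <- function(t, dir,
                               timestamp = format(Sys.time(),
                                                  "%Y%m%d%H%M%S",
                                                  tz = "UTC")) {
  stopifnot(inherits(t, "haplotype_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s.csv", t$gene, timestamp))
  write_haplotype_table(t, path)
  invisible(path)
}

#' Apply an update description to a table collection
#'
#' Consumes a JSON update description:
#' \code{\{gene, haplotype_name, assignments: [\{rsid, allele,
#' major_allele?\}]\}}. When \code{gene} names an existing table the
#' haplotype is added to it; otherwise a new gene table is created with the
#' reference haplotype \code{"1"} and the new haplotype named
#' \code{haplotype_name} (each assignment must then carry
#' \code{major_allele}).
#'
#' @param update path to the update JSON, or an equivalent list.
#' @param tables named list of existing \code{haplotype_table}s (names =
#'   gene symbols).
#' @return the updated \code{haplotype_table}.
#' @export
apply_update <- function(update, tables = list()) {
  u <- if (is.character(update)) jsonlite::read_json(update) else update
  if (is.null(u$gene) || is.null(u$haplotype_name) || is.null(u$assignments))
    stop("update description needs fields gene, haplotype_name, assignments")
  asg <- stats::setNames(
    vapply(u$assignments, `[[`, character(1), "allele"),
    vapply(u$assignments, `[[`, character(1), "rsid"))
  maj <- vapply(u$assignments, function(a)
    if (is.null(a$major_allele)) NA_character_ else a$major_allele,
    character(1))
  names(maj) <- names(asg)
  if (u$gene %in% names(tables)) {
    add_haplotype(tables[[u$gene]], u$haplotype_name, asg,
                  majors = maj[!is.na(maj)])
  } else {
    if (anyNA(maj))
      stop("creating a new gene table requires major_allele for every ",
           "assignment")
    create_gene_table(
      u$gene,
      data.frame(rsid = names(asg), major = unname(maj),
                 stringsAsFactors = FALSE),
      stats::setNames(list(character(0), asg), c("1", u$haplotype_name)))
  }
}
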