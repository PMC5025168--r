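#' Pharmacogene landscape statistics
#'
#' Helpers summarising a collection of pharmacogenes: the shared-drug gene
#' graph and its density, the "squareness" of haplotype tables (haplotypes
#' relative to the variants they engage), per-chromosome / ADMET-class
#' counts, and the number of drugs metabolized by two or more genes.
#'
#' @name knowledge_stats
#' @keywords internal
NULL

.admet_classes <- c("phase I", "phase II", "transporter", "modifier",
                    "unknown")

#' Read gene metadata and gene-drug associations
#'
#' Delimited text with columns \code{gene}, \code{chromosome},
#' \code{admet_class} and \code{drug}, one row per gene-drug pair (the
#' drug field may be empty for genes without drug annotations).
#'
#' @param source path to a CSV/TSV file.
#' @param sep field separator; tab if the header contains one, else comma.
#' @return a data frame with the four columns above.
#' @export
read_gene_metadata <- function(source, sep = NULL) {
  first <- readLines(source, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(source, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          fill = TRUE, comment.char = "")
  need <- c("gene", "chromosome", "admet_class", "drug")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("gene metadata is missing column(s): ",
         paste(missing, collapse = ", "))
  df[need]
}

#' Aggregate gene metadata rows into per-gene records
#'
#' Collapses one-row-per-gene-drug metadata into one record per gene with
#' its drug set. Drug names are matched exactly after case-folding and
#' whitespace trimming; no synonym resolution is attempted.
#'
#' @param metadata data frame as returned by \code{\link{read_gene_metadata}},
#'   or a list of pre-built records.
#' @return named list of \code{gene_record}s, each with fields \code{gene},
#'   \code{chromosome}, \code{admet_class} and \code{drugs} (character set).
#' @export
gene_records <- function(metadata) {
  if (!is.data.frame(metadata)) return(metadata)
  recs <- lapply(split(metadata, metadata$gene), function(d) {
    cls <- unique(d$admet_class)
    if (length(cls) != 1L)
      stop("gene ", d$gene[1L], " has conflicting ADMET classes: ",
           paste(cls, collapse = ", "))
    if (!cls %in% .admet_classes)
      stop("unknown ADMET class '", cls, "' for gene ", d$gene[1L],
           " (expected one of: ", paste(.admet_classes, collapse = ", "), ")")
    drugs <- unique(tolower(trimws(d$drug)))
    drugs <- drugs[nzchar(drugs) & !is.na(drugs)]
    structure(list(gene = d$gene[1L],
                   chromosome = as.character(unique(d$chromosome))[1L],
                   admet_class = cls,
                   drugs = drugs),
              class = "gene_record")
  })
  recs[order(names(recs))]
}

#' Build the shared-drug gene graph
#'
#' Nodes are gene symbols; an undirected edge joins two genes when at least
#' one drug is related to both (i.e. their drug sets intersect). The graph
#' is simple, with no self-loops, and invariant under any permutation of
#' the input record order.
#'
#' @param records list of gene records (see \code{\link{gene_records}}).
#' @return an \pkg{igraph} undirected graph with genes as vertex names.
#' @export
build_gene_drug_graph <- function(records) {
  if (length(records) == 0L) stop("no gene records supplied")
  genes <- vapply(records, `[[`, character(1), "gene")
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  ord <- order(genes)
  records <- records[ord]
  genes <- genes[ord]
  n <- length(genes)
  edges <- character(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (length(intersect(records[[i]]$drugs, records[[j]]$drugs)))
          edges <- c(edges, genes[i], genes[j])
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = genes)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' Density of a gene graph
#'
#' The fraction of realised edges out of the maximum possible
#' \eqn{|V|(|V|-1)/2} in a simple undirected graph.
#'
#' @param g an undirected \pkg{igraph} graph.
#' @return a number in \eqn{[0, 1]}.
#' @export
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) stop("graph density needs at least 2 nodes")
  igraph::ecount(g) / (n * (n - 1) / 2)
}

#' Haplotype-table squareness
#'
#' For each gene, the number of haplotypes relative to the number of
#' variants its table engages. Most pharmacogene tables are approximately
#' square ("one variant per haplotype"); genes like NAT2 (32 variants in
#' 86 distinct haplotypes) depart strongly from this rule.
#'
#' @param tables list of curated \code{haplotype_table}s.
#' @return data frame with columns \code{gene}, \code{n_variants},
#'   \code{n_haplotypes} and \code{ratio} (haplotypes per variant), sorted
#'   by gene.
#' @export
squareness <- function(tables) {
  out <- data.frame(
    gene = vapply(tables, `[[`, character(1), "gene"),
    n_variants = vapply(tables, function(t) nrow(t$alleles), numeric(1)),
    n_haplotypes = vapply(tables, function(t) ncol(t$alleles), numeric(1)),
    stringsAsFactors = FALSE
  )
  out$ratio <- out$n_haplotypes / out$n_variants
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene counts by chromosome and ADMET class
#'
#' Cross-tabulates gene records by chromosome and ADMET class, and lists
#' the chromosomes carrying no pharmacogene at all.
#'
#' @param records list of gene records.
#' @param chromosomes chromosome labels to report (default 1-22, X, Y).
#' @return list with \code{counts} (chromosome x class integer matrix,
#'   including all-zero rows) and \code{zero_chromosomes}.
#' @export
count_by_chromosome_and_class <- function(records,
                                          chromosomes = c(as.character(1:22),
                                                          "X", "Y")) {
  chrom <- vapply(records, `[[`, character(1), "chromosome")
  cls <- vapply(records, `[[`, character(1), "admet_class")
  chromosomes <- union(chromosomes, chrom)
  counts <- table(factor(chrom, levels = chromosomes),
                  factor(cls, levels = .admet_classes))
  counts <- unclass(counts)
  list(counts = counts,
       zero_chromosomes = rownames(counts)[rowSums(counts) == 0L])
}

#' Count drugs metabolized by two or more genes
#'
#' Inverts the gene-to-drugs mapping and counts the drugs associated with
#' at least two genes.
#'
#' @param records list of gene records.
#' @return list with \code{multi_gene} (drugs with >= 2 genes) and
#'   \code{total} (distinct drugs overall).
#' @export
multi_gene_drug_count <- function(records) {
  if (length(records) == 0L) stop("no gene records supplied")
  drug_genes <- list()
  for (r in records) {
    for (d in r$drugs) drug_genes[[d]] <- union(drug_genes[[d]], r$gene)
  }
  n_genes <- vapply(drug_genes, length, integer(1))
  list(multi_gene = sum(n_genes >= 2L), total = length(drug_genes))
}

#' Landscape statistics report
#'
#' Convenience wrapper computing overall and per-ADMET-class graph
#' densities, squareness, chromosome/class counts and the multi-gene drug
#' count in one call.
#'
#' @param records list of gene records.
#' @param tables optional list of curated haplotype tables for squareness.
#' @return a list with components \code{density_overall},
#'   \code{density_by_class} (named numeric; NA where a class has fewer
#'   than 2 genes), \code{chromosome_counts}, \code{multi_gene_drugs} and
#'   (when tables are given) \code{squareness}.
#' @export
landscape_stats <- function(records, tables = NULL) {
  g <- build_gene_drug_graph(records)
  cls <- vapply(records, `[[`, character(1), "admet_class")
  by_class <- vapply(.admet_classes, function(k) {
    sub <- records[cls == k]
    if (length(sub) < 2L) return(NA_real_)
    graph_density(build_gene_drug_graph(sub))
  }, numeric(1))
  out <- list(
    density_overall = graph_density(g),
    density_by_class = by_class,
    chromosome_counts = count_by_chromosome_and_class(records),
    multi_gene_drugs = multi_gene_drug_count(records)
  )
  if (!is.null(tables)) out$squareness <- squareness(tables)
  out
}
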