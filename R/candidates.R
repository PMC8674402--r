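# Candidate-gene triage: annotation filter -> variant-impact filter ->
# seed-expression filter.

#' Classify a variant's position relative to a gene
#'
#' @param pos Variant position (bp, 1-based).
#' @param gene_start,gene_end Gene span (bp, closed).
#' @param exons Data frame with columns `start`, `end` (bp) or `NULL`
#'   (whole gene span treated as exonic, as for unannotated models).
#' @param strand `"+"` or `"-"`; governs which side is upstream.
#' @param upstream Promoter length in bp scanned 5' of the gene
#'   (default 2000).
#' @return One of `"upstream"`, `"exonic"`, `"other"`.
#' @export
classify_variant_region <- function(pos, gene_start, gene_end, exons = NULL,
                                    strand = "+", upstream = 2000) {
  if (gene_start > gene_end) stop("malformed gene span")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (strand == "+" && pos < gene_start && pos >= gene_start - upstream) {
    return("upstream")
  }
  if (strand == "-" && pos > gene_end && pos <= gene_end + upstream) {
    return("upstream")
  }
  if (is.null(exons)) {
    if (pos >= gene_start && pos <= gene_end) return("exonic")
    return("other")
  }
  if (any(exons$start > exons$end)) stop("malformed exon spans")
  if (any(pos >= exons$start & pos <= exons$end)) return("exonic")
  "other"
}

#' Is an annotation purely "hypothetical"?
#'
#' A gene is dropped from the candidate list when *every*
#' semicolon-separated clause of its functional annotation is a
#' hypothetical-protein descriptor ("hypothetical protein",
#' "hypothetical gene", "conserved hypothetical protein",
#' "hypothetical conserved gene/protein").  A single clause naming a
#' domain, a similarity or a function keeps the gene.  Empty annotations
#' count as hypothetical.
#'
#' @param annotation Character vector of free-text annotations.
#' @return Logical vector.
#' @examples
#' flag_hypothetical("Conserved hypothetical protein")               # TRUE
#' flag_hypothetical("Sec63 domain containing protein")              # FALSE
#' @export
flag_hypothetical <- function(annotation) {
  pat <- "^(conserved )?hypothetical (conserved )?(protein|gene)$"
  vapply(annotation, function(a) {
    if (is.na(a) || !nzchar(trimws(a))) return(TRUE)
    clauses <- trimws(strsplit(a, ";", fixed = TRUE)[[1]])
    clauses <- clauses[nzchar(clauses)]
    all(grepl(pat, tolower(clauses)))
  }, logical(1), USE.NAMES = FALSE)
}

# derive per-gene qualifying-variant counts from a per-variant table
.count_variants <- function(genes, variants, exons, delta_threshold,
                            upstream) {
  need <- c("pos", "class", "delta")
  stopifnot(all(need %in% names(variants)),
            all(c("start", "end") %in% names(genes)))
  if (is.null(variants$effect)) variants$effect <- NA_character_
  indel_n <- snp_n <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ex <- if (!is.null(exons)) {
      exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
    }
    if (!is.null(ex) && !nrow(ex)) ex <- NULL
    strand <- if (!is.null(genes$strand)) genes$strand[i] else "+"
    for (j in seq_len(nrow(variants))) {
      if (!(variants$delta[j] > delta_threshold)) next
      reg <- classify_variant_region(variants$pos[j], genes$start[i],
                                     genes$end[i], ex, strand, upstream)
      if (variants$class[j] == "InDel" && reg %in% c("upstream", "exonic")) {
        indel_n[i] <- indel_n[i] + 1L
      } else if (variants$class[j] == "SNP" && reg == "exonic" &&
                 identical(variants$effect[j], "nonsynonymous")) {
        snp_n[i] <- snp_n[i] + 1L
      }
    }
  }
  genes$indel_n <- indel_n
  genes$snp_n <- snp_n
  genes
}

#' Run the three-stage candidate-gene filter cascade
#'
#' Stage 1 drops genes annotated only as hypothetical proteins/genes.
#' Stage 2 keeps genes carrying at least one qualifying sequence variant
#' (upstream/exonic InDels or nonsynonymous exonic SNPs whose bulk delta
#' index exceeds `delta_threshold`) and totals the variations.  Stage 3
#' keeps genes whose database seed-expression category is `"High"`.
#' When an assay expression table is supplied, the final candidates are
#' the stage-3 survivors whose assayed category is also `"High"`.
#'
#' @param genes Data frame with columns `gene_id`, `annotation`,
#'   `expr_db`, and either precomputed counts `indel_n`, `snp_n`
#'   (already restricted to qualifying variants, as in published tables)
#'   or `start`/`end` spans for the variant route.
#' @param delta_threshold Strict lower bound on the bulk delta index for
#'   a variant to qualify (default 0.8); used only on the variant route.
#' @param variants Optional per-variant data frame (`pos`, `class`
#'   (`"SNP"`/`"InDel"`), `effect` (`"nonsynonymous"` for SNPs),
#'   `delta`); when given, counts are derived via
#'   [classify_variant_region()].
#' @param exons Optional exon table (`gene_id`, `start`, `end`) for the
#'   variant route.
#' @param assay Optional named character vector, gene id -> assayed
#'   expression category.
#' @param upstream Promoter length in bp (default 2000).
#' @return A `filter_report`: list with `region_gene_count`,
#'   `hypothetical_dropped`, `annotated` (gene ids), `variant_bearing`
#'   (gene ids), `variation_total`, `expr_high` (gene ids), `final`
#'   (gene ids), and the per-gene `genes` table with the counts used.
#' @export
run_cascade <- function(genes, delta_threshold = 0.8, variants = NULL,
                        exons = NULL, assay = NULL, upstream = 2000) {
  stopifnot(is.data.frame(genes), nrow(genes) > 0,
            all(c("gene_id", "annotation", "expr_db") %in% names(genes)))
  if (!is.null(variants)) {
    genes <- .count_variants(genes, variants, exons, delta_threshold,
                             upstream)
  }
  stopifnot(all(c("indel_n", "snp_n") %in% names(genes)))
  genes$indel_n[is.na(genes$indel_n)] <- 0L
  genes$snp_n[is.na(genes$snp_n)] <- 0L
  if (any(genes$indel_n < 0 | genes$snp_n < 0)) stop("negative variant counts")

  genes$hypothetical <- flag_hypothetical(genes$annotation)
  annotated <- genes[!genes$hypothetical, , drop = FALSE]
  bearing <- annotated[annotated$indel_n + annotated$snp_n > 0, , drop = FALSE]
  high <- bearing[bearing$expr_db == "High", , drop = FALSE]
  final <- high$gene_id
  if (!is.null(assay)) {
    final <- final[!is.na(assay[final]) & assay[final] == "High"]
  }
  structure(list(region_gene_count = nrow(genes),
                 hypothetical_dropped = sum(genes$hypothetical),
                 annotated = annotated$gene_id,
                 variant_bearing = bearing$gene_id,
                 variation_total = sum(bearing$indel_n + bearing$snp_n),
                 expr_high = high$gene_id,
                 final = final,
                 genes = genes),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> %d genes in region; %d hypothetical",
                     " dropped; %d annotated;\n  %d variant-bearing with %d",
                     " variations; %d database-High;\n  final: %s\n"),
              x$region_gene_count, x$hypothetical_dropped,
              length(x$annotated), length(x$variant_bearing),
              x$variation_total, length(x$expr_high),
              paste(x$final, collapse = ", ")))
  invisible(x)
}
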