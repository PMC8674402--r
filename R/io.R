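# Input/output: the flat-file formats consumed and produced by the
# pipeline, plus loaders for the packaged in-paper fixtures.

#' Read a long-format phenotype table
#'
#' CSV with columns `line_id`, `season`, `replicate_id` and either
#' `germinated` + `sown` (proportion derived as `germinated / sown`) or a
#' precomputed `prop` column.
#'
#' @param file Path to the CSV.
#' @return Data frame with columns `line_id`, `season`, `replicate_id`,
#'   `prop`.
#' @export
read_phenotypes <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!"prop" %in% names(d)) {
    stopifnot(all(c("germinated", "sown") %in% names(d)))
    if (any(d$sown <= 0)) stop("`sown` must be > 0")
    d$prop <- d$germinated / d$sown
  }
  stopifnot(all(c("line_id", "season") %in% names(d)))
  if (!"replicate_id" %in% names(d)) {
    d$replicate_id <- stats::ave(seq_len(nrow(d)),
                                 d$line_id, d$season, FUN = seq_along)
  }
  d[, c("line_id", "season", "replicate_id", "prop")]
}

#' Collapse a phenotype table to a season-keyed replicate list
#'
#' @param pheno Data frame from [read_phenotypes()].
#' @param line_id Which line to extract.
#' @return Named list, season -> numeric vector of replicate proportions.
#' @export
phenotype_list <- function(pheno, line_id) {
  d <- pheno[pheno$line_id == line_id, , drop = FALSE]
  if (!nrow(d)) stop("no phenotypes for line ", line_id)
  split(d$prop, d$season)
}

#' Read a genetic map TSV (`marker`, `chr`, `cm`)
#'
#' @param file Path to the TSV.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "chr", "cm") %in% names(d)))
  genetic_map(d$marker, d$chr, d$cm)
}

#' Read substituted-segment definitions
#'
#' TSV with columns `line_id`, `chr`, `core_start_marker`,
#' `core_end_marker`, `max_start_marker`, `max_end_marker`; the token
#' `End` denotes a chromosome extremity (see [segment_from_markers()]).
#'
#' @param file Path to the TSV.
#' @param map A [genetic_map()] resolving the marker names.
#' @return Named list, line id -> [substituted_segment()].  Any extra
#'   columns are kept in `attr(, "table")`.
#' @export
read_segments <- function(file, map) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE,
                         colClasses = c(chr = "character"))
  need <- c("line_id", "chr", "core_start_marker", "core_end_marker",
            "max_start_marker", "max_end_marker")
  stopifnot(all(need %in% names(d)))
  segs <- lapply(seq_len(nrow(d)), function(i) {
    segment_from_markers(map, d$chr[i], d$core_start_marker[i],
                         d$core_end_marker[i], d$max_start_marker[i],
                         d$max_end_marker[i])
  })
  names(segs) <- d$line_id
  attr(segs, "table") <- d
  segs
}

#' Read an F2 genotype/phenotype table
#'
#' TSV with `individual_id`, genotype columns coded 1/2/3 (or NA), and a
#' `phenotype` column.
#'
#' @param file Path to the TSV.
#' @return Data frame.
#' @export
read_f2 <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("individual_id", "phenotype") %in% names(d)))
  d
}

#' Read a flat two-bulk variant table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `class`, `ref_hi`,
#' `alt_hi`, `ref_lo`, `alt_lo` (hi = tolerant bulk, lo = sensitive
#' bulk; "alt" oriented to the donor allele).
#'
#' @param file Path to the TSV.
#' @return Data frame of sites.
#' @export
read_bulk_tsv <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref_hi", "alt_hi", "ref_lo", "alt_lo")
  stopifnot(all(need %in% names(d)))
  d
}

#' Extract oriented two-bulk allele depths from a VCF
#'
#' Reads a VCF carrying per-sample allele depths (`AD`) for the two
#' parents and the two bulks, keeps biallelic sites where the parents are
#' opposite homozygotes (judged from their allele-depth fractions), and
#' orients the counts so that "alt" is the donor parent's allele.
#' Requires the `VariantAnnotation` package.
#'
#' @param file Path to the VCF.
#' @param tolerant,sensitive Sample names of the two bulks.
#' @param donor,recipient Sample names of the two parents.
#' @param min_parent_depth Minimum parental depth to judge homozygosity
#'   (default 5).
#' @param hom_fraction Allele fraction beyond which a parent is called
#'   homozygous (default 0.9).
#' @return Data frame as from [read_bulk_tsv()].
#' @export
read_bulk_vcf <- function(file, tolerant, sensitive, donor, recipient,
                          min_parent_depth = 5, hom_fraction = 0.9) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_bulk_vcf() needs the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(file)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no AD genotype field")
  samples <- colnames(ad)
  miss <- setdiff(c(tolerant, sensitive, donor, recipient), samples)
  if (length(miss)) stop("samples absent from VCF: ", paste(miss, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  keep_bi <- lengths(alt) == 1
  depth2 <- function(s) {
    m <- t(vapply(ad[, s], function(v) {
      if (length(v) < 2 || anyNA(v)) c(NA_real_, NA_real_) else v[1:2]
    }, numeric(2)))
    colnames(m) <- c("ref", "alt"); m
  }
  dp <- lapply(stats::setNames(nm = c(tolerant, sensitive, donor, recipient)),
               depth2)
  pfrac <- function(m) m[, "alt"] / pmax(1, m[, "ref"] + m[, "alt"])
  d_tot <- rowSums(dp[[donor]]); r_tot <- rowSums(dp[[recipient]])
  d_fr <- pfrac(dp[[donor]]); r_fr <- pfrac(dp[[recipient]])
  donor_alt <- d_fr >= hom_fraction & r_fr <= 1 - hom_fraction
  donor_ref <- d_fr <= 1 - hom_fraction & r_fr >= hom_fraction
  keep <- keep_bi & d_tot >= min_parent_depth & r_tot >= min_parent_depth &
    (donor_alt | donor_ref) & !is.na(donor_alt)
  ori <- ifelse(donor_alt[keep], 1L, -1L)
  pick <- function(m, w) ifelse(ori == 1L, m[keep, w],
                                m[keep, setdiff(c("ref", "alt"), w)])
  is_indel <- nchar(as.character(VariantAnnotation::ref(vcf)[keep])) != 1 |
    nchar(as.character(unlist(alt[keep]))) != 1
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr))[keep],
             pos = GenomicRanges::start(rr)[keep],
             ref = as.character(VariantAnnotation::ref(vcf)[keep]),
             alt = as.character(unlist(alt[keep])),
             class = ifelse(is_indel, "InDel", "SNP"),
             ref_hi = pick(dp[[tolerant]], "ref"),
             alt_hi = pick(dp[[tolerant]], "alt"),
             ref_lo = pick(dp[[sensitive]], "ref"),
             alt_lo = pick(dp[[sensitive]], "alt"),
             stringsAsFactors = FALSE)
}

# ---- packaged in-paper fixtures ------------------------------------------

.fixture <- function(name) {
  f <- system.file("extdata", name, package = "ltgmap", mustWork = TRUE)
  f
}

#' Packaged SSR map fixture
#'
#' Marker cM positions underlying the packaged SSSL segment fixture.
#' Published sources give marker orders and segment lengths but not cM
#' coordinates; these positions were laid out to be consistent with the
#' printed segment lengths and localized intervals, and markers named
#' `X25A` ... `X28D` (lines S25-S28) are synthetic stand-ins.
#'
#' @return A [genetic_map()].
#' @export
ltg_map <- function() read_genetic_map(.fixture("ssr_map.tsv"))

#' Packaged SSSL segment fixture (28 lines)
#'
#' Substituted-segment definitions for the 24 QTL-bearing lines S1-S24
#' and the 4 overlapping non-significant lines S25-S28.
#'
#' @return Named list of [substituted_segment()]s; the raw table (with
#'   `donor` and `detected` columns) in `attr(, "table")`.
#' @export
ltg_segments <- function() read_segments(.fixture("sssl_segments.tsv"),
                                         ltg_map())

#' Packaged per-line detection fixture (24 lines)
#'
#' Season-averaged additive effects and contributions of the 24
#' QTL-bearing SSSLs, wrapped as [detection_result()]s.
#'
#' @return Named list of [detection_result()]s; the raw table in
#'   `attr(, "table")`.
#' @export
ltg_detections <- function() {
  d <- utils::read.delim(.fixture("table1_detections.tsv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(chr = "character"))
  res <- lapply(seq_len(nrow(d)), function(i) {
    detection_result(d$line_id[i], d$a_mean[i], d$a_sd[i],
                     d$r2_mean[i], d$r2_sd[i],
                     detected_seasons = strsplit(d$detected_seasons[i], "")[[1]],
                     donor_id = d$donor[i])
  })
  names(res) <- d$line_id
  attr(res, "table") <- d
  res
}

#' Published integrated-QTL summary (14 rows)
#'
#' The printed integrated loci (interval, averaged effects) used as the
#' expected values in aggregation checks.
#'
#' @return Data frame.
#' @export
ltg_integrated_expected <- function() {
  utils::read.delim(.fixture("table2_expected.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = c(chr = "character"))
}

#' Packaged candidate-gene fixture (40 genes)
#'
#' Functional annotations, qualifying variant counts (delta index > 0.8)
#' and database seed-expression categories of the 40 genes in the
#' fine-mapped region.  Where the source table prints a single count,
#' it is stored in the InDel column; only per-gene totals are
#' interpreted downstream.
#'
#' @return Data frame with columns `gene_id`, `annotation`, `indel_n`,
#'   `snp_n`, `expr_db`.
#' @export
ltg_genes <- function() {
  utils::read.delim(.fixture("table3_genes.tsv"), stringsAsFactors = FALSE)
}

#' Packaged assayed seed-expression categories (qRT-PCR, 8 genes)
#'
#' @return Named character vector, gene id -> category.
#' @export
ltg_expression_assay <- function() {
  d <- utils::read.delim(.fixture("qrtpcr_expression.tsv"),
                         stringsAsFactors = FALSE)
  stats::setNames(d$expr_assay, d$gene_id)
}

#' Packaged recombinant progeny fixture (synthetic coordinates)
#'
#' Five recombinant-derived progeny populations with heterozygous
#' physical intervals and marker-trait association statistics.  The bp
#' coordinates are synthetic: the published figure fixes the interval
#' topology and the flanking-marker span (332.7 kb) but not absolute
#' coordinates.
#'
#' @return Data frame usable with [fine_map()].
#' @export
ltg_recombinants <- function() {
  utils::read.delim(.fixture("recombinants_synthetic.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}
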