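#' Construct a genome annotation
#'
#' Container for the gene models and CpG islands used for context assignment.
#' All coordinates are 0-based half-open internally. The TSS of a gene is its
#' `start` on the plus strand and `end - 1` on the minus strand. CpG shores
#' extend a fixed 2000 bp from each island edge.
#'
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   if `NULL`, each gene body counts as a single exon.
#' @param cgis data.frame with columns `chrom`, `start`, `end`; overlapping
#'   islands are merged.
#' @param chrom_lengths optional named vector of chromosome lengths (bp).
#' @param promoter_up,promoter_down promoter window around the TSS (bp).
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, exons = NULL, cgis,
                              chrom_lengths = NULL,
                              promoter_up = 1000, promoter_down = 1000) {
  genes <- as.data.frame(genes)
  cgis <- as.data.frame(cgis)
  req <- c("id", "chrom", "start", "end", "strand")
  if (nrow(genes) > 0 && !all(req %in% names(genes))) {
    stop("genes must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(genes) > 0) {
    if (any(genes$end <= genes$start)) stop("gene intervals must have end > start", call. = FALSE)
    if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'", call. = FALSE)
    genes$id <- as.character(genes$id)
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  } else {
    genes <- data.frame(id = character(), chrom = character(), start = integer(),
                        end = integer(), strand = character(), tss = integer())
  }
  if (is.null(exons)) {
    exons <- if (nrow(genes) > 0) {
      data.frame(gene_id = genes$id, chrom = genes$chrom,
                 start = genes$start, end = genes$end, stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer())
    }
  }
  exons <- as.data.frame(exons)
  if (nrow(exons) > 0 && any(exons$end <= exons$start)) {
    stop("exon intervals must have end > start", call. = FALSE)
  }
  if (nrow(cgis) > 0) {
    if (any(cgis$end <= cgis$start)) stop("CGI intervals must have end > start", call. = FALSE)
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      cgis$chrom, IRanges::IRanges(cgis$start + 1L, cgis$end)))
    cgis <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr),
                       stringsAsFactors = FALSE)
    cgis <- cgis[order(cgis$chrom, cgis$start), , drop = FALSE]
  } else {
    cgis <- data.frame(chrom = character(), start = integer(), end = integer())
  }
  structure(
    list(genes = genes, exons = exons, cgis = cgis,
         chrom_lengths = chrom_lengths,
         promoter_up = promoter_up, promoter_down = promoter_down,
         shore_width = 2000L),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d gene(s), %d exon(s), %d CpG island(s)\n",
              nrow(x$genes), nrow(x$exons), nrow(x$cgis)))
  cat(sprintf("  promoter window: -%d/+%d bp of TSS; shore width: %d bp\n",
              x$promoter_up, x$promoter_down, x$shore_width))
  invisible(x)
}

# GRanges views of annotation components (1-based internally for IRanges).
.genes_gr <- function(ann) {
  GenomicRanges::GRanges(ann$genes$chrom,
                         IRanges::IRanges(ann$genes$start + 1L, ann$genes$end),
                         strand = ann$genes$strand, id = ann$genes$id)
}
.exons_gr <- function(ann) {
  GenomicRanges::GRanges(ann$exons$chrom,
                         IRanges::IRanges(ann$exons$start + 1L, ann$exons$end))
}
.cgis_gr <- function(ann) {
  GenomicRanges::GRanges(ann$cgis$chrom,
                         IRanges::IRanges(ann$cgis$start + 1L, ann$cgis$end))
}
.sites_gr <- function(sites) {
  GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L))
}
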