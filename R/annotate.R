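#' Assign genomic contexts to CpG sites
#'
#' Each site receives exactly one label on each of two axes. On the gene axis
#' the precedence is promoter > exon > intron > intergenic, evaluated across
#' all (possibly overlapping) genes: the promoter window is
#' `promoter_up`/`promoter_down` bp around any TSS, exon means overlap with
#' any exon, intron means inside a gene body but neither promoter nor exon.
#' On the CpG-density axis the precedence is island > shore > open sea
#' ("other"): shore means within 2000 bp of an island edge but outside all
#' islands.
#'
#' @param sites data.frame with columns `chrom` and `pos` (0-based).
#' @param annotation a [genome_annotation()] (or a `sim_genome`, whose
#'   annotation is used).
#' @return a data.frame with columns `chrom`, `pos`, `gene_context`
#'   (`promoter`/`exon`/`intron`/`intergenic`) and `cpg_context`
#'   (`cpg_island`/`cpg_shore`/`other`).
#' @export
assign_contexts <- function(sites, annotation) {
  if (inherits(annotation, "sim_genome")) annotation <- annotation$annotation
  stopifnot(inherits(annotation, "genome_annotation"))
  sites <- as.data.frame(sites)
  n <- nrow(sites)
  gene_context <- rep("intergenic", n)
  cpg_context <- rep("other", n)
  if (n > 0) {
    gr <- .sites_gr(sites)
    if (nrow(annotation$genes) > 0) {
      genes_gr <- .genes_gr(annotation)
      prom <- suppressWarnings(GenomicRanges::promoters(
        genes_gr, upstream = annotation$promoter_up,
        downstream = annotation$promoter_down))
      prom <- IRanges::restrict(prom, start = 1L)
      in_gene <- IRanges::overlapsAny(gr, genes_gr, ignore.strand = TRUE)
      in_exon <- IRanges::overlapsAny(gr, .exons_gr(annotation), ignore.strand = TRUE)
      in_prom <- IRanges::overlapsAny(gr, prom, ignore.strand = TRUE)
      gene_context[in_gene] <- "intron"
      gene_context[in_exon & in_gene] <- "exon"
      gene_context[in_prom] <- "promoter"
    }
    if (nrow(annotation$cgis) > 0) {
      cgi_gr <- .cgis_gr(annotation)
      in_cgi <- IRanges::overlapsAny(gr, cgi_gr)
      hit <- GenomicRanges::distanceToNearest(gr, cgi_gr)
      dist <- rep(NA_real_, n)
      dist[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
      near <- !is.na(dist) & dist < annotation$shore_width
      cpg_context[near & !in_cgi] <- "cpg_shore"
      cpg_context[in_cgi] <- "cpg_island"
    }
  }
  data.frame(chrom = sites$chrom, pos = sites$pos,
             gene_context = gene_context, cpg_context = cpg_context,
             stringsAsFactors = FALSE)
}

#' Nearest gene for each CpG site
#'
#' Distance is 0 for sites inside a gene; otherwise the bp distance to the
#' closest gene boundary, signed negative when the site lies before the gene
#' start in genome coordinates and positive when after its end. Ties (equal
#' distance to several genes) are broken toward the lexicographically
#' smallest gene id for determinism. Sites on chromosomes without genes get
#' `NA`.
#'
#' @inheritParams assign_contexts
#' @return data.frame with columns `chrom`, `pos`, `gene_id`, `distance`.
#' @export
nearest_gene <- function(sites, annotation) {
  if (inherits(annotation, "sim_genome")) annotation <- annotation$annotation
  stopifnot(inherits(annotation, "genome_annotation"))
  sites <- as.data.frame(sites)
  n <- nrow(sites)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  if (n > 0 && nrow(annotation$genes) > 0) {
    gr <- .sites_gr(sites)
    genes_gr <- .genes_gr(annotation)
    hits <- GenomicRanges::distanceToNearest(gr, genes_gr, select = "all",
                                             ignore.strand = TRUE)
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      d <- S4Vectors::mcols(hits)$distance
      ids <- annotation$genes$id[s]
      # per site: minimal distance, then smallest id
      ord <- order(q, d, ids)
      keep <- !duplicated(q[ord])
      qk <- q[ord][keep]; sk <- s[ord][keep]; dk <- d[ord][keep]
      gene_id[qk] <- annotation$genes$id[sk]
      # sign: negative when the site precedes the gene start
      before <- sites$pos[qk] < annotation$genes$start[sk]
      distance[qk] <- ifelse(dk == 0, 0, ifelse(before, -dk, dk))
    }
  }
  data.frame(chrom = sites$chrom, pos = sites$pos,
             gene_id = gene_id, distance = distance, stringsAsFactors = FALSE)
}

#' Context distribution of DMS versus background
#'
#' For each context class on each axis, the fraction among the query (DMS)
#' sites, the fraction among the background sites, and the enrichment ratio
#' (query fraction / background fraction). Fractions sum to 1 per axis.
#'
#' @param labels context labels of the query set, as from [assign_contexts()].
#' @param background_labels context labels of the background set.
#' @return a list with data.frames `gene_axis` and `cpg_axis`, each with
#'   columns `class`, `dms_fraction`, `background_fraction`, `enrichment`.
#' @export
distribution_summary <- function(labels, background_labels) {
  if (nrow(background_labels) == 0) stop("background label set is empty", call. = FALSE)
  if (nrow(labels) == 0) {
    warning("empty DMS label set; reporting background fractions only")
  }
  one_axis <- function(col, classes) {
    bg <- table(factor(background_labels[[col]], levels = classes))
    fg <- table(factor(labels[[col]], levels = classes))
    bg_frac <- as.numeric(bg) / sum(bg)
    fg_frac <- if (nrow(labels) > 0) as.numeric(fg) / sum(fg) else rep(NA_real_, length(classes))
    data.frame(class = classes,
               dms_fraction = fg_frac,
               background_fraction = bg_frac,
               enrichment = fg_frac / ifelse(bg_frac > 0, bg_frac, NA_real_),
               stringsAsFactors = FALSE)
  }
  list(gene_axis = one_axis("gene_context", c("promoter", "exon", "intron", "intergenic")),
       cpg_axis = one_axis("cpg_context", c("cpg_island", "cpg_shore", "other")))
}
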