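#' Read a Bismark coverage file
#'
#' The Bismark coverage dialect is tab-separated with six columns: chromosome,
#' 1-based start, 1-based end (equal to start for CpGs), percent methylation,
#' count methylated, count unmethylated. Positions are converted to the
#' package's internal 0-based convention; coverage is the sum of the two
#' counts. If the percent column disagrees with the counts by more than 0.5
#' percentage points a warning is raised and the counts win.
#'
#' @param path path to a coverage file.
#' @return data.frame with columns `chrom`, `pos` (0-based), `strand`
#'   (always `"*"`: the format carries no strand), `methylated`, `coverage`.
#' @export
read_coverage_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(), pos = integer(), strand = character(),
                      methylated = integer(), coverage = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) {
    warning("empty coverage file: ", path)
    return(empty)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    stop(sprintf("%s: malformed line(s) (expected 6 tab-separated fields): %s",
                 path, paste(utils::head(which(nf != 6L), 5L), collapse = ", ")),
         call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  pct <- suppressWarnings(as.numeric(m[, 4]))
  meth <- suppressWarnings(as.integer(m[, 5]))
  unmeth <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(start) | is.na(meth) | is.na(unmeth) | meth < 0 | unmeth < 0 | start < 1)
  if (length(bad)) {
    stop(sprintf("%s: unparseable or negative fields at line(s): %s",
                 path, paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  cov <- meth + unmeth
  expect_pct <- ifelse(cov > 0, 100 * meth / cov, 0)
  off <- which(!is.na(pct) & abs(pct - expect_pct) > 0.5)
  if (length(off)) {
    warning(sprintf("%s: %% methylation column inconsistent with counts at %d line(s); counts win",
                    path, length(off)))
  }
  data.frame(chrom = m[, 1], pos = start - 1L, strand = "*",
             methylated = meth, coverage = cov, stringsAsFactors = FALSE)
}

#' Write records in Bismark coverage format
#'
#' @param records data.frame with columns `chrom`, `pos` (0-based),
#'   `methylated`, `coverage`; rows with zero coverage are skipped (an
#'   uncovered cytosine has no record in this format).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_coverage_file <- function(records, path) {
  r <- records[records$coverage > 0, , drop = FALSE]
  pct <- 100 * r$methylated / r$coverage
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   r$chrom, r$pos + 1L, r$pos + 1L,
                   formatC(pct, format = "fg", digits = 10),
                   r$methylated, r$coverage - r$methylated)
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a cross-sample methylation count matrix
#'
#' Takes per-sample site records (as from [read_coverage_file()]) and a design
#' sheet, and builds the union-of-sites count matrix with explicit
#' missingness: a site absent from a sample's file is `NA` there, which is
#' distinct from zero coverage. Site order is (chrom, pos, strand) and does
#' not depend on input file order.
#'
#' @param records named list of per-sample record data.frames; names are
#'   sample ids.
#' @param design data.frame with columns `sample`, `group`, `hemisphere`,
#'   `animal`.
#' @return an object of class `meth_matrix`: list with `sites` (data.frame
#'   `chrom`, `pos`, `strand`), `samples`, `meth` and `cov` (integer matrices
#'   sites x samples, `NA` = missing) and `design`.
#' @export
assemble_matrix <- function(records, design) {
  if (length(records) < 1) stop("need at least one sample", call. = FALSE)
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("records must be a named list (names = sample ids)", call. = FALSE)
  }
  design <- validate_design(design)
  missing_in_design <- setdiff(names(records), design$sample)
  if (length(missing_in_design)) {
    stop("sample(s) present in files but absent from design: ",
         paste(missing_in_design, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(records))) stop("duplicate sample ids", call. = FALSE)
  for (s in names(records)) {
    r <- records[[s]]
    key <- paste(r$chrom, r$pos, r$strand)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop(sprintf("sample %s: duplicate site at (%s)", s, d), call. = FALSE)
    }
  }
  all_sites <- unique(do.call(rbind, lapply(records, function(r)
    r[, c("chrom", "pos", "strand"), drop = FALSE])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos, all_sites$strand), ,
                         drop = FALSE]
  rownames(all_sites) <- NULL
  key_all <- paste(all_sites$chrom, all_sites$pos, all_sites$strand)
  samples <- names(records)
  meth <- matrix(NA_integer_, nrow(all_sites), length(samples),
                 dimnames = list(NULL, samples))
  cov <- meth
  for (s in samples) {
    r <- records[[s]]
    idx <- match(paste(r$chrom, r$pos, r$strand), key_all)
    meth[idx, s] <- r$methylated
    cov[idx, s] <- r$coverage
  }
  if (any(meth > cov, na.rm = TRUE)) stop("methylated count exceeds coverage", call. = FALSE)
  structure(list(sites = all_sites, samples = samples, meth = meth, cov = cov,
                 design = design),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  pres <- rowSums(!is.na(x$cov))
  cat(sprintf("meth_matrix: %d site(s) x %d sample(s)\n", nrow(x$sites), length(x$samples)))
  cat(sprintf("  present in all samples: %d; median coverage: %s\n",
              sum(pres == length(x$samples)),
              stats::median(x$cov, na.rm = TRUE)))
  invisible(x)
}

#' Per-site count of samples with data
#' @param x a `meth_matrix`.
#' @return integer vector, number of non-missing samples per site.
#' @export
present_count <- function(x) {
  stopifnot(inherits(x, "meth_matrix"))
  rowSums(!is.na(x$cov))
}

validate_design <- function(design) {
  design <- as.data.frame(design)
  req <- c("sample", "group", "hemisphere", "animal")
  if (!all(req %in% names(design))) {
    stop("design must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(design$sample)) stop("duplicate sample ids in design", call. = FALSE)
  bad <- setdiff(unique(design$hemisphere), c("control", "lesioned"))
  if (length(bad)) {
    stop("hemisphere labels must be 'control' or 'lesioned'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  design
}

#' Read a sample design sheet
#'
#' Headered TSV with columns `sample`, `group`, `hemisphere`, `animal`.
#' @param path file path.
#' @return validated design data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_design(d)
}

#' Write a sample design sheet
#' @param design design data.frame.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(validate_design(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genome annotation from BED files
#'
#' Genes come from a BED6 file (name = gene id, strand required); exons from
#' an optional companion BED whose name column is the owning gene id (when
#' absent, each full gene body is treated as one exon). CpG islands come from
#' a BED file; overlapping islands are merged.
#'
#' @param genes_bed path to the gene BED6 file.
#' @param cgi_bed path to the CpG-island BED file.
#' @param exons_bed optional path to the exon BED file.
#' @param promoter_up,promoter_down promoter window (bp) around the TSS.
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(genes_bed, cgi_bed, exons_bed = NULL,
                            promoter_up = 1000, promoter_down = 1000) {
  gr_genes <- rtracklayer::import(genes_bed, format = "BED")
  if (length(gr_genes) && any(GenomicRanges::width(gr_genes) < 1)) {
    stop("gene BED contains intervals with end <= start", call. = FALSE)
  }
  genes <- data.frame(
    id = as.character(gr_genes$name %||% sprintf("gene%03d", seq_along(gr_genes))),
    chrom = as.character(GenomicRanges::seqnames(gr_genes)),
    start = GenomicRanges::start(gr_genes) - 1L,
    end = GenomicRanges::end(gr_genes),
    strand = as.character(GenomicRanges::strand(gr_genes)),
    stringsAsFactors = FALSE)
  if (nrow(genes) && any(!genes$strand %in% c("+", "-"))) {
    stop("gene BED must carry explicit +/- strand", call. = FALSE)
  }
  exons <- NULL
  if (!is.null(exons_bed)) {
    gr_ex <- rtracklayer::import(exons_bed, format = "BED")
    if (length(gr_ex) && any(GenomicRanges::width(gr_ex) < 1)) {
      stop("exon BED contains intervals with end <= start", call. = FALSE)
    }
    exons <- data.frame(gene_id = as.character(gr_ex$name),
                        chrom = as.character(GenomicRanges::seqnames(gr_ex)),
                        start = GenomicRanges::start(gr_ex) - 1L,
                        end = GenomicRanges::end(gr_ex),
                        stringsAsFactors = FALSE)
  }
  gr_cgi <- rtracklayer::import(cgi_bed, format = "BED")
  if (length(gr_cgi) && any(GenomicRanges::width(gr_cgi) < 1)) {
    stop("CGI BED contains intervals with end <= start", call. = FALSE)
  }
  cgis <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr_cgi)),
                     start = GenomicRanges::start(gr_cgi) - 1L,
                     end = GenomicRanges::end(gr_cgi),
                     stringsAsFactors = FALSE)
  genome_annotation(genes, exons, cgis,
                    promoter_up = promoter_up, promoter_down = promoter_down)
}

#' Write intervals as BED6
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `id` and `strand`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  name <- if ("id" %in% names(df)) df$id else "."
  strand <- if ("strand" %in% names(df)) df$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", df$chrom, df$start, df$end, name, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-bin difference track as BEDGRAPH
#' @param track data.frame with `chrom`, `bin_start`, `bin_end`, `difference`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%g", track$chrom, track$bin_start,
                   track$bin_end, track$difference)
  writeLines(lines, path)
  invisible(path)
}
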