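#' Simulate a miniature annotated genome with a CpG site map
#'
#' Builds a small genome for RRBS simulation: non-overlapping gene models with
#' exons and strand, CpG islands (half of them anchored at gene TSSs so that
#' promoter islands exist), MspI recognition (CCGG) positions whose successive
#' gaps define restriction fragments, and a CpG site map with elevated CpG
#' density inside islands. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_genome`: a list with elements
#'   `annotation` (a [genome_annotation()]), `cpgs` (data.frame `chrom`,
#'   `pos` 0-based, `strand`), `ccgg` (data.frame `chrom`, `pos`) and
#'   `config`.
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), .build_genome_impl(config))
}

.build_genome_impl <- function(config) {
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  L <- config$chrom_length
  chrom_lengths <- stats::setNames(rep(L, length(chroms)), chroms)

  # distribute genes/CGIs across chromosomes as evenly as possible
  gene_chrom <- if (config$n_genes > 0) chroms[(seq_len(config$n_genes) - 1L) %% length(chroms) + 1L] else character()
  cgi_chrom <- if (config$n_cgis > 0) chroms[(seq_len(config$n_cgis) - 1L) %% length(chroms) + 1L] else character()

  genes <- list(); exons <- list()
  gi <- 0L
  for (ch in chroms) {
    k <- sum(gene_chrom == ch)
    if (k == 0L) next
    len <- round(stats::runif(k, 5000, 30000))
    if (sum(len) + 10 * (k + 1) > L) {
      stop(sprintf(
        "chromosome %s (%d bp) too short to host %d genes totalling %d bp plus spacing",
        ch, L, k, sum(len)), call. = FALSE)
    }
    frac <- stats::runif(k + 1)
    gaps <- 10 + frac / sum(frac) * (L - sum(len) - 10 * (k + 1))
    starts <- floor(cumsum(gaps[seq_len(k)]) + cumsum(c(0, len[-k])))
    ends <- starts + len
    strand <- sample(c("+", "-"), k, replace = TRUE)
    ids <- sprintf("gene%03d", gi + seq_len(k))
    gi <- gi + k
    genes[[ch]] <- data.frame(id = ids, chrom = ch, start = as.integer(starts),
                              end = as.integer(ends), strand = strand,
                              stringsAsFactors = FALSE)
    # alternating exon/intron segments, exons at odd positions
    ex <- lapply(seq_len(k), function(i) {
      n_ex <- sample(1:3, 1L)
      m <- 2L * n_ex - 1L
      f <- stats::runif(m)
      w <- 50 + f / sum(f) * (len[i] - 50 * m)
      bounds <- starts[i] + floor(cumsum(c(0, w)))
      bounds[m + 1L] <- ends[i]
      odd <- seq(1L, m, by = 2L)
      data.frame(gene_id = ids[i], chrom = ch,
                 start = as.integer(bounds[odd]),
                 end = as.integer(bounds[odd + 1L]),
                 stringsAsFactors = FALSE)
    })
    exons[[ch]] <- do.call(rbind, ex)
  }
  genes <- if (length(genes)) do.call(rbind, genes) else NULL
  exons <- if (length(exons)) do.call(rbind, exons) else NULL

  cgis <- NULL
  if (config$n_cgis > 0) {
    w <- round(stats::runif(config$n_cgis, 400, 1500))
    if (any(w >= L)) {
      stop(sprintf("chromosome length %d bp too short to host CpG islands", L),
           call. = FALSE)
    }
    n_tss <- if (is.null(genes)) 0L else min(floor(config$n_cgis / 2), nrow(genes))
    start <- integer(config$n_cgis)
    chrom <- cgi_chrom
    if (n_tss > 0L) {
      pick <- sample.int(nrow(genes), n_tss)
      chrom[seq_len(n_tss)] <- genes$chrom[pick]
      tss <- ifelse(genes$strand[pick] == "+", genes$start[pick], genes$end[pick] - 1L)
      start[seq_len(n_tss)] <- clamp(tss - floor(w[seq_len(n_tss)] / 2), 0L, L - w[seq_len(n_tss)])
    }
    if (config$n_cgis > n_tss) {
      idx <- (n_tss + 1L):config$n_cgis
      start[idx] <- floor(stats::runif(length(idx), 0, L - w[idx]))
    }
    cgis <- data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(start + w), stringsAsFactors = FALSE)
  }

  ann <- genome_annotation(
    genes = genes %||% data.frame(id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character()),
    exons = exons,
    cgis = cgis %||% data.frame(chrom = character(), start = integer(), end = integer()),
    chrom_lengths = chrom_lengths)

  # CCGG cut sites: mixture of short and long inter-site gaps so that a
  # realistic fraction of fragments falls inside the size-selection window
  ccgg <- lapply(chroms, function(ch) {
    pos <- floor(stats::runif(1, 0, 500))
    out <- numeric(0)
    while (pos < L) {
      out <- c(out, pos)
      n_need <- max(16L, ceiling((L - pos) / 800))
      short <- stats::runif(n_need) < 0.65
      gaps <- ifelse(short, stats::runif(n_need, 50, 1150), stats::runif(n_need, 1300, 4000))
      newpos <- pos + cumsum(round(gaps))
      out <- c(out, newpos[newpos < L])
      pos <- if (length(newpos)) max(newpos) else L
    }
    data.frame(chrom = ch, pos = as.integer(sort(unique(out))), stringsAsFactors = FALSE)
  })
  ccgg <- do.call(rbind, ccgg)

  # CpG map: sparse background plus dense placement inside islands
  cpgs <- lapply(chroms, function(ch) {
    n_bg <- stats::rpois(1, L / config$cpg_spacing)
    pos <- sample.int(L, min(n_bg, L)) - 1L
    ci <- ann$cgis[ann$cgis$chrom == ch, , drop = FALSE]
    if (nrow(ci) > 0) {
      extra <- lapply(seq_len(nrow(ci)), function(i) {
        wd <- ci$end[i] - ci$start[i]
        n <- stats::rpois(1, wd / config$cgi_cpg_spacing)
        ci$start[i] + sample.int(wd, min(n, wd)) - 1L
      })
      pos <- c(pos, unlist(extra))
    }
    data.frame(chrom = ch, pos = sort(unique(as.integer(pos))),
               strand = "*", stringsAsFactors = FALSE)
  })
  cpgs <- do.call(rbind, cpgs)
  rownames(cpgs) <- NULL

  structure(list(annotation = ann, cpgs = cpgs, ccgg = ccgg, config = config),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d chromosome(s), %d CpGs, %d CCGG sites\n",
              length(x$annotation$chrom_lengths), nrow(x$cpgs), nrow(x$ccgg)))
  print(x$annotation)
  invisible(x)
}
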