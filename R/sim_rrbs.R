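#' Simulate RRBS coverage per sample
#'
#' MspI fragments are the intervals between consecutive CCGG positions of the
#' simulated genome. Only CpGs lying on fragments whose length falls inside
#' the closed size-selection window receive coverage; per covered CpG and
#' sample, read depth is drawn from a negative binomial around the configured
#' mean depth. Deterministic under the config seed.
#'
#' @param genome a [build_genome()] result.
#' @param config the [sim_config()].
#' @return a list with `sites` (covered CpGs: `chrom`, `pos`, `strand`),
#'   `cov` (integer matrix sites x samples), `design`, and `covered`
#'   (logical over the genome's full CpG map).
#' @export
simulate_rrbs_coverage <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 2L), .simulate_coverage_impl(genome, config))
}

.simulate_coverage_impl <- function(genome, config) {
  win <- config$fragment_size_window
  cpgs <- genome$cpgs
  covered <- logical(nrow(cpgs))
  for (ch in unique(cpgs$chrom)) {
    cuts <- genome$ccgg$pos[genome$ccgg$chrom == ch]
    idx <- which(cpgs$chrom == ch)
    if (length(cuts) < 2) next
    frag <- findInterval(cpgs$pos[idx], cuts)
    frag_len <- diff(cuts)
    on_frag <- frag >= 1 & frag <= length(frag_len)
    in_window <- rep(FALSE, length(idx))
    in_window[on_frag] <- frag_len[frag[on_frag]] >= win[1] &
      frag_len[frag[on_frag]] <= win[2]
    covered[idx] <- in_window
  }
  design <- sim_design(config)
  sites <- cpgs[covered, , drop = FALSE]
  rownames(sites) <- NULL
  n <- nrow(sites)
  cov <- matrix(NA_integer_, n, nrow(design), dimnames = list(NULL, design$sample))
  for (j in seq_len(nrow(design))) {
    cov[, j] <- as.integer(stats::rnbinom(n, size = 20, mu = config$mean_depth))
  }
  if (n == 0) message("no CpGs covered: no fragment falls inside the size window")
  list(sites = sites, cov = cov, design = design, covered = covered)
}

# Region id per covered site: consecutive CpGs on a chromosome closer than
# the co-methylation radius share a latent region.
.comethylation_regions <- function(sites, radius) {
  n <- nrow(sites)
  if (n == 0) return(integer(0))
  new_region <- c(TRUE, sites$chrom[-1] != sites$chrom[-n] |
                    (sites$pos[-1] - sites$pos[-n]) > radius)
  cumsum(new_region)
}

.region_class <- function(gene_context, cpg_context) {
  ifelse(cpg_context == "cpg_island" | gene_context == "promoter", "cgi_promoter",
         ifelse(cpg_context == "cpg_shore", "shore", "open_sea"))
}

#' Simulate methylation counts with injected group effects
#'
#' Counts are generated from latent regional methylation levels: consecutive
#' covered CpGs within the co-methylation radius share one latent region, so
#' nearby CpGs co-vary, and both hemispheres of an animal share the animal's
#' latent level, making the two sides of an animal near-identical replicates.
#' Region baselines are Beta-distributed around a context-dependent mean (low
#' in CpG islands and promoters, high in open sea). Effects from the config's
#' effect table shift the latent level of the affected regions in the target
#' group(s) only; per-animal levels are Beta-distributed around the group
#' mean with the configured intra-class correlation (beta-binomial counts).
#'
#' @param genome a [build_genome()] result.
#' @param coverage result of [simulate_rrbs_coverage()].
#' @param config the [sim_config()].
#' @return a list with `matrix` (a `meth_matrix`) and `truth` (the truth
#'   table: one row per injected site and target group with `chrom`, `pos`,
#'   `target_group`, `delta`, `gene_context`, `cpg_context`, `region`).
#' @export
simulate_methylation <- function(genome, coverage, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 3L),
            .simulate_methylation_impl(genome, coverage, config))
}

.simulate_methylation_impl <- function(genome, coverage, config) {
  sites <- coverage$sites
  design <- coverage$design
  n <- nrow(sites)
  ctx <- assign_contexts(sites, genome$annotation)
  region <- .comethylation_regions(sites, config$comethylation_radius)
  n_region <- if (n > 0) max(region) else 0L

  # context class of a region = class of its first site
  first <- !duplicated(region)
  rclass <- .region_class(ctx$gene_context, ctx$cpg_context)[first]
  mu0 <- config$baseline_means[rclass]
  kappa <- 30 # concentration of the baseline Beta draw
  baseline <- stats::rbeta(n_region, mu0 * kappa, (1 - mu0) * kappa)
  baseline <- clamp(baseline, 0.02, 0.98)

  # effect placement: delta per (region, group), set at region level so CpGs
  # sharing a region shift together
  groups <- config$groups
  delta_rg <- matrix(0, n_region, length(groups), dimnames = list(NULL, groups))
  truth <- list()
  taken <- logical(n)
  for (spec in config$effect_table) {
    cand <- switch(spec$region_preference,
                   open_sea = which(ctx$cpg_context == "other"),
                   promoter = which(ctx$gene_context == "promoter"),
                   gene_body = which(ctx$gene_context %in% c("exon", "intron")),
                   any = seq_len(n))
    cand <- cand[!taken[cand]]
    # one affected site per region to keep injected effects non-overlapping
    cand <- cand[!duplicated(region[cand])]
    cand <- cand[rowSums(delta_rg[region[cand], , drop = FALSE] != 0) == 0]
    if (length(cand) < spec$n_sites) {
      stop(sprintf(
        "effect table requests %d sites with preference '%s' but only %d candidate CpGs exist",
        spec$n_sites, spec$region_preference, length(cand)), call. = FALSE)
    }
    sel <- sample(cand, spec$n_sites)
    taken[sel] <- TRUE
    for (g in spec$target_group) {
      delta_rg[region[sel], g] <- spec$delta / 100
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = sites$chrom[sel], pos = sites$pos[sel],
        target_group = g, delta = spec$delta,
        gene_context = ctx$gene_context[sel], cpg_context = ctx$cpg_context[sel],
        region = region[sel], stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), pos = integer(), target_group = character(),
               delta = numeric(), gene_context = character(),
               cpg_context = character(), region = integer())

  # small fixed per-site offset: site-level heterogeneity inside a region
  # (identical across samples, cancels in group differences)
  site_offset <- stats::rnorm(n, 0, 0.03)

  rho <- config$dispersion
  meth <- matrix(NA_integer_, n, nrow(design), dimnames = list(NULL, design$sample))
  animals <- unique(design[, c("animal", "group")])
  for (k in seq_len(nrow(animals))) {
    g <- animals$group[k]
    mu_g <- clamp(baseline + delta_rg[, g], 0.02, 0.98)
    p_animal <- if (rho > 0) {
      a <- mu_g * (1 - rho) / rho
      b <- (1 - mu_g) * (1 - rho) / rho
      stats::rbeta(n_region, a, b)
    } else mu_g
    cols <- which(design$animal == animals$animal[k])
    for (j in cols) {
      shift <- if (design$hemisphere[j] == "lesioned") config$side_effect else 0
      p_site <- clamp(p_animal[region] + site_offset + shift, 0.001, 0.999)
      cv <- coverage$cov[, j]
      mj <- as.integer(stats::rbinom(n, ifelse(is.na(cv), 0L, cv), p_site))
      mj[is.na(cv)] <- NA_integer_
      meth[, j] <- mj
    }
  }

  mm <- structure(list(sites = sites, samples = design$sample,
                       meth = meth, cov = coverage$cov, design = design),
                  class = "meth_matrix")
  list(matrix = mm, truth = truth)
}

#' Simulate a complete RRBS dataset
#'
#' Convenience wrapper: [build_genome()], [simulate_rrbs_coverage()] and
#' [simulate_methylation()] under a single config. Byte-identical output for
#' identical configs.
#'
#' @param config a [sim_config()].
#' @return an object of class `rrbs_sim`: list with `genome`, `matrix`
#'   (a `meth_matrix`), `truth`, `design` and `config`.
#' @export
simulate_rrbs <- function(config) {
  genome <- build_genome(config)
  coverage <- simulate_rrbs_coverage(genome, config)
  sim <- simulate_methylation(genome, coverage, config)
  structure(list(genome = genome, matrix = sim$matrix, truth = sim$truth,
                 design = coverage$design, config = config),
            class = "rrbs_sim")
}

#' @export
print.rrbs_sim <- function(x, ...) {
  cat(sprintf("rrbs_sim: %d covered CpG(s) x %d sample(s); %d truth entr%s\n",
              nrow(x$matrix$sites), length(x$matrix$samples), nrow(x$truth),
              if (nrow(x$truth) == 1) "y" else "ies"))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' One Bismark coverage file per sample (`<sample>.cov`), the design sheet
#' (`design.tsv`), the truth table (`truth.tsv`, 1-based positions), and the
#' genome annotation as BED (`genes.bed`, `exons.bed`, `cgi.bed`). Reading
#' the files back through [read_coverage_file()] and [assemble_matrix()]
#' reproduces the counts exactly.
#'
#' @param sim an `rrbs_sim` from [simulate_rrbs()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
emit_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "rrbs_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir, call. = FALSE)
  paths <- character(0)
  for (s in sim$matrix$samples) {
    p <- file.path(dir, paste0(s, ".cov"))
    rec <- data.frame(chrom = sim$matrix$sites$chrom, pos = sim$matrix$sites$pos,
                      methylated = sim$matrix$meth[, s], coverage = sim$matrix$cov[, s])
    rec <- rec[!is.na(rec$coverage), , drop = FALSE]
    write_coverage_file(rec, p)
    paths <- c(paths, p)
  }
  dp <- file.path(dir, "design.tsv")
  write_design(sim$design, dp)
  tp <- file.path(dir, "truth.tsv")
  tt <- sim$truth
  tt$pos <- tt$pos + 1L
  utils::write.table(tt, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- sim$genome$annotation
  gp <- file.path(dir, "genes.bed"); write_bed(ann$genes, gp)
  ep <- file.path(dir, "exons.bed")
  write_bed(data.frame(chrom = ann$exons$chrom, start = ann$exons$start,
                       end = ann$exons$end, id = ann$exons$gene_id), ep)
  cp <- file.path(dir, "cgi.bed"); write_bed(ann$cgis, cp)
  invisible(c(paths, dp, tp, gp, ep, cp))
}
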