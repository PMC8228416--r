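#' Read a pipeline run configuration
#'
#' YAML file with the fields used by [run_pipeline()]: `counts_dir`,
#' `design`, optional `genes_bed`/`exons_bed`/`cgi_bed`, `out_dir`, `seed`,
#' a `comparisons` list (each with `name`, `group_a`, `group_b`, optional
#' `hemisphere`), and optional thresholds (`min_coverage`,
#' `min_samples_per_group`, `q_threshold`, `delta_threshold`, `radius`,
#' `bin_size`, `n_resamples`).
#'
#' @param path YAML config path.
#' @return the config as a named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  cfg
}

.config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full differential-methylation pipeline
#'
#' Orchestrates, for every configured comparison: coverage filtering, the
#' overdispersion-corrected per-CpG test, BH adjustment and DMS calling,
#' genomic-context annotation, and spatial summaries (neighbor distances vs
#' resampling null, same-direction fraction). When two or more comparisons
#' are configured, the first two are additionally compared: 1-Mb bin density
#' differencing, nested correlations, and the absolute
#' methylation-change-difference screen on the shared tested CpGs. Artifacts
#' are written under `out_dir` with the config digest in a header file;
#' results are idempotent given the seed.
#'
#' @param config a named list (see [read_run_config()]) or a YAML path.
#' @param quiet suppress per-stage messages.
#' @return the run report (named list), invisibly written as
#'   `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  req <- c("counts_dir", "design", "out_dir", "comparisons", "seed")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  thr <- list(min_coverage = config$min_coverage %||% 10L,
              min_samples_per_group = config$min_samples_per_group,
              q_threshold = config$q_threshold %||% 0.01,
              delta_threshold = config$delta_threshold %||% 20,
              radius = config$radius %||% 100,
              bin_size = config$bin_size %||% 1e6,
              n_resamples = config$n_resamples %||% 100)
  say <- function(...) if (!quiet) message(sprintf(...))

  design <- read_design(config$design)
  files <- file.path(config$counts_dir, paste0(design$sample, ".cov"))
  ok <- file.exists(files)
  if (!any(ok)) stop("no coverage files found under ", config$counts_dir, call. = FALSE)
  say("stage read: %d coverage file(s)", sum(ok))
  records <- lapply(files[ok], read_coverage_file)
  names(records) <- design$sample[ok]
  mat <- assemble_matrix(records, design)
  say("stage assemble: %d site(s) x %d sample(s)", nrow(mat$sites), length(mat$samples))

  ann <- NULL
  if (!is.null(config$genes_bed) && !is.null(config$cgi_bed)) {
    ann <- read_annotation(config$genes_bed, config$cgi_bed, config$exons_bed)
    say("stage annotation: %d gene(s), %d CGI(s)", nrow(ann$genes), nrow(ann$cgis))
  }

  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  digest <- .config_digest(config)
  writeLines(c(sprintf("config_md5\t%s", digest),
               sprintf("rrbsdm_version\t%s", as.character(utils::packageVersion("rrbsdm")))),
             file.path(out_dir, "run_header.tsv"))

  fits <- list()
  report <- list(package = "rrbsdm",
                 version = as.character(utils::packageVersion("rrbsdm")),
                 config_md5 = digest, seed = config$seed,
                 config = config, comparisons = list())
  for (i in seq_along(config$comparisons)) {
    cc <- config$comparisons[[i]]
    fit <- tryCatch(
      diff_methylation(mat, cc$group_a, cc$group_b,
                       hemisphere = cc$hemisphere,
                       hemisphere_a = cc$hemisphere_a %||% cc$hemisphere,
                       hemisphere_b = cc$hemisphere_b %||% cc$hemisphere,
                       min_coverage = thr$min_coverage,
                       min_samples_per_group = thr$min_samples_per_group,
                       q_threshold = thr$q_threshold,
                       name = cc$name %||% paste0(cc$group_b, "-vs-", cc$group_a),
                       quiet = quiet),
      error = function(e) stop(sprintf("stage test [%s]: %s",
                                       cc$name %||% i, conditionMessage(e)), call. = FALSE))
    fits[[fit$spec$name]] <- fit
    say("stage test [%s]: %d tested, %d DMS", fit$spec$name, fit$n_tested, fit$n_dms)
    write_dms(fit, file.path(out_dir, paste0("dms_", fit$spec$name, ".tsv")))

    entry <- list(name = fit$spec$name, n_tested = fit$n_tested,
                  n_dms = fit$n_dms, n_hyper = fit$n_hyper, n_hypo = fit$n_hypo)
    d <- dms(fit)
    if (!is.null(ann)) {
      bg_ctx <- assign_contexts(fit$results, ann)
      if (nrow(d) > 0) {
        ctx <- assign_contexts(d, ann)
        ng <- nearest_gene(d, ann)
        utils::write.table(
          data.frame(chrom = d$chrom, pos = d$pos + 1L,
                     gene_context = ctx$gene_context, cpg_context = ctx$cpg_context,
                     gene_id = ng$gene_id, distance = ng$distance),
          file.path(out_dir, paste0("contexts_", fit$spec$name, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        summ <- distribution_summary(ctx, bg_ctx)
        entry$context_summary <- summ
      }
    }
    if (nrow(d) >= 3) {
      dd <- distance_distribution(d, fit$results,
                                  n_resamples = thr$n_resamples,
                                  seed = derive_seed(config$seed, 100L + i))
      utils::write.table(
        data.frame(bin_lo = dd$breaks[-length(dd$breaks)],
                   bin_hi = dd$breaks[-1],
                   observed = dd$observed[seq_len(length(dd$breaks) - 1)],
                   null_mean = dd$null_mean[seq_len(length(dd$breaks) - 1)],
                   null_sd = dd$null_sd[seq_len(length(dd$breaks) - 1)]),
        file.path(out_dir, paste0("distances_", fit$spec$name, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      sdf <- same_direction_fraction(d, radius = thr$radius)
      entry$same_direction <- sdf
    }
    report$comparisons[[fit$spec$name]] <- entry
  }

  if (length(fits) >= 2) {
    f1 <- fits[[1]]; f2 <- fits[[2]]
    say("stage compare: %s vs %s", f1$spec$name, f2$spec$name)
    k1 <- paste(f1$results$chrom, f1$results$pos, f1$results$strand)
    k2 <- paste(f2$results$chrom, f2$results$pos, f2$results$strand)
    shared <- intersect(k1, k2)
    i1 <- match(shared, k1); i2 <- match(shared, k2)
    track <- bin_difference(dms(f1), dms(f2), bin_size = thr$bin_size)
    write_bedgraph(track, file.path(out_dir, "bin_difference.bedgraph"))
    nest <- nested_correlations(f1$results$meth_diff[i1], f2$results$meth_diff[i2],
                                f1$results$is_dms[i1], f2$results$is_dms[i2])
    screen <- delta_screen(f1$results[i1, c("chrom", "pos")],
                           f1$results$meth_diff[i1], f2$results$meth_diff[i2],
                           f1$results$is_dms[i1], f2$results$is_dms[i2],
                           threshold = thr$delta_threshold)
    if (!is.null(ann) && nrow(screen) > 0) {
      sctx <- assign_contexts(screen, ann)
      sng <- nearest_gene(screen, ann)
      screen$gene_context <- sctx$gene_context
      screen$cpg_context <- sctx$cpg_context
      screen$gene_id <- sng$gene_id
    }
    sc <- screen
    sc$pos <- sc$pos + 1L
    utils::write.table(sc, file.path(out_dir, "delta_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$comparative <- list(
      pair = c(f1$spec$name, f2$spec$name),
      n_shared = length(shared),
      nested_correlations = nest,
      top_bins = utils::head(track, 10),
      n_screen = nrow(screen),
      delta_threshold = thr$delta_threshold)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
  say("report written to %s", file.path(out_dir, "report.json"))
  invisible(report)
}

#' Generate, write and analyze a packaged demo dataset
#'
#' Simulates a small three-group RRBS study with shared treatment effects,
#' writes it under `dir`, runs the full pipeline on the written files, and
#' reports the truth-recovery of the injected effects together with md5
#' digests of the artifacts for reproducibility checks.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return list with `report` (the pipeline run report), `recovery`
#'   (detection and sign-accuracy of injected sites in the first comparison)
#'   and `digests` (md5 of the written artifacts).
#' @export
make_demo <- function(dir, seed = 1L) {
  config <- sim_config(
    seed = seed, n_chromosomes = 2L, chrom_length = 1e6, n_genes = 20L, n_cgis = 30L,
    effect_table = c(
      list(effect_spec(c("LDOPA", "LDOPA_R"), -40, "open_sea", 40),
           effect_spec(c("LDOPA", "LDOPA_R"), 40, "open_sea", 12),
           effect_spec("LDOPA_R", -40, "gene_body", 12)),
      random_effect_table(16, 45, hypo_fraction = 0.75, target_group = "LDOPA_R")))
  sim <- simulate_rrbs(config)
  data_dir <- file.path(dir, "data")
  emit_dataset(sim, data_dir)
  run_cfg <- list(
    counts_dir = data_dir,
    design = file.path(data_dir, "design.tsv"),
    genes_bed = file.path(data_dir, "genes.bed"),
    exons_bed = file.path(data_dir, "exons.bed"),
    cgi_bed = file.path(data_dir, "cgi.bed"),
    out_dir = file.path(dir, "out"),
    seed = seed,
    comparisons = list(list(name = "LDOPA-vs-UNT", group_a = "UNT", group_b = "LDOPA"),
                       list(name = "LDOPA_R-vs-UNT", group_a = "UNT", group_b = "LDOPA_R")))
  report <- run_pipeline(run_cfg, quiet = TRUE)
  fit <- diff_methylation(sim$matrix, "UNT", "LDOPA", quiet = TRUE)
  recovery <- truth_recovery(fit, sim$truth, group = "LDOPA")
  # report.json and the header echo absolute paths; the data artifacts are
  # the reproducibility surface
  arts <- list.files(run_cfg$out_dir, full.names = TRUE)
  arts <- arts[!grepl("run_header|report[.]json", arts)]
  digests <- tools::md5sum(arts)
  names(digests) <- basename(names(digests))
  list(report = report, recovery = recovery, digests = digests)
}

#' Recovery of injected effects by a differential methylation fit
#'
#' Fraction of truth-table sites (for one target group) that were called DMS,
#' and among those calls the fraction whose realized sign matches the
#' injected sign.
#'
#' @param fit a `dms_fit`.
#' @param truth a simulation truth table.
#' @param group the target group of interest.
#' @return list with `n_truth`, `detected`, `detection_rate`, `sign_accuracy`.
#' @export
truth_recovery <- function(fit, truth, group) {
  tt <- truth[truth$target_group == group, , drop = FALSE]
  r <- fit$results
  key_r <- paste(r$chrom, r$pos)
  idx <- match(paste(tt$chrom, tt$pos), key_r)
  found <- !is.na(idx)
  called <- found & r$is_dms[idx]
  sign_ok <- called & sign(r$meth_diff[idx]) == sign(tt$delta)
  list(n_truth = nrow(tt),
       detected = sum(called, na.rm = TRUE),
       detection_rate = if (nrow(tt)) sum(called, na.rm = TRUE) / nrow(tt) else NA_real_,
       sign_accuracy = if (sum(called, na.rm = TRUE) > 0)
         sum(sign_ok, na.rm = TRUE) / sum(called, na.rm = TRUE) else NA_real_)
}
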