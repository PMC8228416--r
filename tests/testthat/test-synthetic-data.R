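# The RRBS simulator: genome construction, coverage, methylation counts,
# ground truth, and the dataset round trip.

test_that("config validation enforces the biological invariants", {
  expect_error(sim_config(seed = 1, fragment_size_window = c(40, 1200)), "50")
  expect_error(sim_config(seed = 1, fragment_size_window = c(50, 1500)), "1200")
  expect_error(sim_config(seed = 1, hypo_fraction = 1.2), "hypo_fraction")
  expect_error(sim_config(seed = 1, dispersion = 1), "dispersion")
  expect_error(sim_config(seed = 1, mean_depth = 5), "mean_depth")
  expect_error(sim_config(), "seed")
  expect_error(effect_spec("LDOPA", delta = 120), "delta")
  expect_error(effect_spec("LDOPA", delta = 10, n_sites = 0), "n_sites")
})

test_that("genome build is deterministic and populates every context class", {
  cfg <- sim_config(seed = 42)
  g1 <- build_genome(cfg)
  g2 <- build_genome(cfg)
  expect_identical(g1, g2)
  ctx <- assign_contexts(g1$cpgs, g1)
  expect_true(all(c("promoter", "exon", "intron", "intergenic") %in% ctx$gene_context))
  expect_true(all(c("cpg_island", "cpg_shore", "other") %in% ctx$cpg_context))
  # genes have strand, a TSS and at least one exon each
  expect_true(all(g1$annotation$genes$strand %in% c("+", "-")))
  expect_true(all(g1$annotation$genes$id %in% g1$annotation$exons$gene_id))
})

test_that("a featureless genome annotates everything intergenic open sea", {
  cfg <- sim_config(seed = 3, n_genes = 0, n_cgis = 0)
  g <- build_genome(cfg)
  ctx <- assign_contexts(g$cpgs, g)
  expect_true(all(ctx$gene_context == "intergenic"))
  expect_true(all(ctx$cpg_context == "other"))
})

test_that("an undersized chromosome raises a sizing error", {
  expect_error(build_genome(sim_config(seed = 1, chrom_length = 5e4, n_genes = 40)),
               "too short")
})

test_that("size selection controls which fragments yield coverage", {
  cfg <- sim_config(seed = 8, n_chromosomes = 1)
  g <- build_genome(cfg)
  # fixed cut map: fragment of 1500 bp (outside the window) and 300 bp (inside)
  g$ccgg <- data.frame(chrom = "chr1", pos = c(1000L, 2500L, 2800L))
  g$cpgs <- data.frame(chrom = "chr1",
                       pos = c(500L, 1200L, 2000L, 2600L, 2700L, 3500L),
                       strand = "*")
  cov <- simulate_rrbs_coverage(g, cfg)
  # interior CpGs of the 1500 bp fragment and CpGs outside any fragment: no coverage
  expect_setequal(cov$sites$pos, c(2600L, 2700L))
  expect_true(all(!is.na(cov$cov)))
})

test_that("coverage is centered on the configured mean depth", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1, mean_depth = 30)
  sim <- simulate_rrbs(cfg)
  expect_gt(nrow(sim$matrix$sites), 1000)
  expect_lt(abs(mean(sim$matrix$cov) - 30), 3) # within 10% of 30
})

test_that("counts respect conservation and the dataset is seed-deterministic", {
  cfg <- sim_config(seed = 5, effect_table = random_effect_table(20, 40))
  s1 <- simulate_rrbs(cfg)
  s2 <- simulate_rrbs(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth, s2$truth)
  ok <- !is.na(s1$matrix$cov)
  expect_true(all(s1$matrix$meth[ok] >= 0))
  expect_true(all(s1$matrix$meth[ok] <= s1$matrix$cov[ok]))
})

test_that("truth table entries match the requested placement and sign", {
  cfg <- sim_config(seed = 6,
                    effect_table = list(effect_spec("LDOPA", -40, "open_sea", 50)))
  sim <- simulate_rrbs(cfg)
  expect_equal(nrow(sim$truth), 50)
  expect_true(all(sim$truth$cpg_context == "other"))
  expect_true(all(sim$truth$delta < 0))
  expect_true(all(sim$truth$target_group == "LDOPA"))
  # every truth position exists in the covered CpG map
  key <- paste(sim$matrix$sites$chrom, sim$matrix$sites$pos)
  expect_true(all(paste(sim$truth$chrom, sim$truth$pos) %in% key))
})

test_that("a null simulation has an empty truth table and balanced groups", {
  cfg <- sim_config(seed = 7)
  sim <- simulate_rrbs(cfg)
  expect_equal(nrow(sim$truth), 0)
  pooled <- function(g) {
    s <- sim$design$sample[sim$design$group == g]
    sum(sim$matrix$meth[, s], na.rm = TRUE) / sum(sim$matrix$cov[, s], na.rm = TRUE)
  }
  means <- vapply(unique(sim$design$group), pooled, numeric(1))
  expect_lt(max(means) - min(means), 0.02)
})

test_that("an effect request beyond the region capacity errors", {
  cfg <- sim_config(seed = 10, n_chromosomes = 1, chrom_length = 1e5,
                    n_genes = 3, n_cgis = 4,
                    effect_table = list(effect_spec("LDOPA", -40, "promoter", 5000)))
  expect_error(simulate_rrbs(cfg), "candidate")
})

test_that("CpGs sharing a latent region change in the same direction", {
  # 200 seeded replicates of a small open-sea genome with one injected
  # hypomethylation effect; in each affected region the realized group-mean
  # differences of CpG pairs within 100 bp must agree in sign almost always
  agree <- 0L; total <- 0L
  for (seed in 1:200) {
    cfg <- sim_config(seed = seed, n_chromosomes = 1, chrom_length = 5e4,
                      n_genes = 0, n_cgis = 0, cpg_spacing = 30,
                      effect_table = list(effect_spec("LDOPA", -40, "open_sea", 3)))
    sim <- simulate_rrbs(cfg)
    a <- sim$design$sample[sim$design$group == "UNT"]
    b <- sim$design$sample[sim$design$group == "LDOPA"]
    st <- sim$matrix$sites
    regions <- unique(sim$truth$region)
    reg <- cumsum(c(TRUE, st$chrom[-1] != st$chrom[-nrow(st)] |
                      diff(st$pos) > cfg$comethylation_radius))
    for (r in regions) {
      idx <- which(reg == r)
      if (length(idx) < 2) next
      pair <- idx[1:2]
      if (st$pos[pair[2]] - st$pos[pair[1]] > 100) next
      d <- vapply(pair, function(i) pooled_difference(
        sim$matrix$meth[i, a], sim$matrix$cov[i, a],
        sim$matrix$meth[i, b], sim$matrix$cov[i, b]), numeric(1))
      if (all(!is.na(d)) && all(d != 0)) {
        total <- total + 1L
        if (sign(d[1]) == sign(d[2])) agree <- agree + 1L
      }
    }
  }
  expect_gt(total, 100)
  expect_gte(agree / total, 0.95)
})

test_that("emitted datasets round-trip exactly through the reader", {
  cfg <- sim_config(seed = 11, n_chromosomes = 1, chrom_length = 2e5, n_genes = 4, n_cgis = 6)
  sim <- simulate_rrbs(cfg)
  dir <- withr::local_tempdir()
  emit_dataset(sim, dir)
  expect_length(list.files(dir, pattern = "[.]cov$"), 18) # 3 groups x 3 animals x 2 sides
  design <- read_design(file.path(dir, "design.tsv"))
  records <- lapply(design$sample, function(s)
    read_coverage_file(file.path(dir, paste0(s, ".cov"))))
  names(records) <- design$sample
  mat <- assemble_matrix(records, design)
  # every emitted (covered) cell is reproduced exactly
  for (s in design$sample) {
    orig_has <- !is.na(sim$matrix$cov[, s]) & sim$matrix$cov[, s] > 0
    key_orig <- paste(sim$matrix$sites$chrom, sim$matrix$sites$pos)[orig_has]
    key_new <- paste(mat$sites$chrom, mat$sites$pos)
    idx <- match(key_orig, key_new)
    expect_false(anyNA(idx))
    expect_identical(mat$cov[idx, s], unname(sim$matrix$cov[orig_has, s]))
    expect_identical(mat$meth[idx, s], unname(sim$matrix$meth[orig_has, s]))
  }
})

test_that("the percent column in emitted files equals 100*M/(M+U)", {
  cfg <- sim_config(seed = 12, n_chromosomes = 1, chrom_length = 1e5, n_genes = 3, n_cgis = 4)
  sim <- simulate_rrbs(cfg)
  dir <- withr::local_tempdir()
  emit_dataset(sim, dir)
  f <- list.files(dir, pattern = "[.]cov$", full.names = TRUE)[1]
  tab <- utils::read.delim(f, header = FALSE)
  expect_equal(tab$V4, 100 * tab$V5 / (tab$V5 + tab$V6), tolerance = 1e-9)
})
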