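# Shared fixtures and the independent GLM oracle used across tests.

# Build a meth_matrix through the public assembly path from explicit counts.
# meth/cov: matrices (sites x samples); NA cells are missing in that sample.
mk_matrix <- function(pos, meth, cov, groups,
                      hemis = rep("control", ncol(cov)),
                      chrom = "chr1") {
  samples <- sprintf("s%02d", seq_len(ncol(cov)))
  records <- lapply(seq_along(samples), function(j) {
    has <- !is.na(cov[, j])
    data.frame(chrom = chrom, pos = pos[has], strand = "*",
               methylated = meth[has, j], coverage = cov[has, j],
               stringsAsFactors = FALSE)
  })
  names(records) <- samples
  design <- data.frame(sample = samples, group = groups, hemisphere = hemis,
                       animal = samples, stringsAsFactors = FALSE)
  assemble_matrix(records, design)
}

# Independent brute-force likelihood oracle for the per-site test: an IRLS
# binomial logistic fit (stats::glm), coded separately from the package's
# closed-form pooled-proportion fitter, with the same dispersion rule.
oracle_test <- function(ma, ca, mb, cb) {
  g <- factor(c(rep("a", length(ma)), rep("b", length(mb))))
  m <- c(ma, mb)
  n <- c(ca, cb)
  fit <- suppressWarnings(stats::glm(cbind(m, n - m) ~ g, family = stats::binomial,
                                     control = stats::glm.control(epsilon = 1e-12)))
  phi <- max(1, sum(stats::residuals(fit, "pearson")^2) / (length(m) - 2))
  stat <- (fit$null.deviance - fit$deviance) / phi
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE), phi = phi)
}

# Random small test instance with interior maximum-likelihood estimates
# (each group has at least one methylated and one unmethylated read).
random_instance <- function() {
  na <- sample(2:6, 1); nb <- sample(2:6, 1)
  ca <- sample(10:50, na, replace = TRUE)
  cb <- sample(10:50, nb, replace = TRUE)
  pa <- stats::runif(1, 0.1, 0.9); pb <- stats::runif(1, 0.1, 0.9)
  repeat {
    ma <- stats::rbinom(na, ca, pa); mb <- stats::rbinom(nb, cb, pb)
    if (sum(ma) > 0 && sum(ma) < sum(ca) && sum(mb) > 0 && sum(mb) < sum(cb)) break
  }
  list(ma = ma, ca = ca, mb = mb, cb = cb)
}

# Small genome annotation used by the annotation tests: two genes on chr1
# (one per strand), one gene on chr2, a CpG island on chr1, none on chr3.
fixture_annotation <- function() {
  genome_annotation(
    genes = data.frame(id = c("g1", "g2", "g3"),
                       chrom = c("chr1", "chr1", "chr2"),
                       start = c(10000L, 20000L, 1000L),
                       end = c(12000L, 22000L, 2000L),
                       strand = c("+", "-", "+")),
    exons = data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                       chrom = c("chr1", "chr1", "chr1", "chr2"),
                       start = c(10000L, 11500L, 21500L, 1000L),
                       end = c(10400L, 12000L, 22000L, 2000L)),
    cgis = data.frame(chrom = "chr1", start = 1000L, end = 2000L))
}

# Effect table that emulates a shared two-treatment response: mostly shared
# hypo-biased effects across both treated groups plus a small group-specific
# component.
shared_effect_table <- function() {
  list(effect_spec(c("LDOPA", "LDOPA_R"), -40, "open_sea", 40),
       effect_spec(c("LDOPA", "LDOPA_R"), -25, "open_sea", 30),
       effect_spec(c("LDOPA", "LDOPA_R"), 30, "open_sea", 15),
       effect_spec("LDOPA", -25, "any", 6),
       effect_spec("LDOPA_R", -25, "any", 6))
}

nesting_replicate <- function(seed) {
  cfg <- sim_config(seed = seed, n_chromosomes = 1, chrom_length = 1.5e6,
                    n_genes = 20, n_cgis = 30, effect_table = shared_effect_table())
  sim <- simulate_rrbs(cfg)
  f1 <- diff_methylation(sim$matrix, "UNT", "LDOPA", quiet = TRUE)
  f2 <- diff_methylation(sim$matrix, "UNT", "LDOPA_R", quiet = TRUE)
  k1 <- paste(f1$results$chrom, f1$results$pos)
  k2 <- paste(f2$results$chrom, f2$results$pos)
  sh <- intersect(k1, k2)
  i1 <- match(sh, k1); i2 <- match(sh, k2)
  nested_correlations(f1$results$meth_diff[i1], f2$results$meth_diff[i2],
                      f1$results$is_dms[i1], f2$results$is_dms[i2])
}
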