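# Per-CpG differential methylation: binomial logistic model on a group
# indicator, tested by the scaled deviance (chi-square) with an
# overdispersion correction estimated from Pearson residuals.

.P_EPS <- 1e-8 # fitted proportions are clipped to [.P_EPS, 1 - .P_EPS]

xlogy <- function(x, r) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x > 0
  out[pos] <- x[pos] * log(r[pos])
  out[is.na(x)] <- NA_real_
  out
}

# binomial deviance contribution of one cell against fitted proportion p
.dev_terms <- function(m, n, p) {
  p <- clamp(p, .P_EPS, 1 - .P_EPS)
  2 * (xlogy(m, m / (n * p)) + xlogy(n - m, (n - m) / (n * (1 - p))))
}

.pearson_sq <- function(m, n, p) {
  p <- clamp(p, .P_EPS, 1 - .P_EPS)
  (m - n * p)^2 / (n * p * (1 - p))
}

#' Specify a two-group comparison
#'
#' @param name label for the comparison (e.g. `"LDOPA-vs-UNT"`).
#' @param a_samples,b_samples sample ids of the reference group (a) and the
#'   treated group (b); at least two each.
#' @param min_coverage minimum read coverage for a (site, sample) cell to be
#'   used; the standard RRBS filter keeps cells with 10 or more reads.
#' @param min_samples_per_group minimum number of usable cells per group for
#'   a site to be tested; `NULL` (default) requires every sample, the relaxed
#'   convention for six-striata pools is 4 of 6.
#' @param q_threshold FDR threshold; sites are DMS when q is strictly below it.
#' @return an object of class `comparison_spec`.
#' @export
comparison_spec <- function(name, a_samples, b_samples,
                            min_coverage = 10L,
                            min_samples_per_group = NULL,
                            q_threshold = 0.01) {
  if (length(a_samples) < 2 || length(b_samples) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (length(intersect(a_samples, b_samples))) {
    stop("groups share sample(s): ", paste(intersect(a_samples, b_samples), collapse = ", "),
         call. = FALSE)
  }
  if (q_threshold <= 0 || q_threshold >= 1) stop("q_threshold must be in (0,1)", call. = FALSE)
  if (is.null(min_samples_per_group)) {
    min_samples_per_group <- c(length(a_samples), length(b_samples))
  } else if (length(min_samples_per_group) == 1L) {
    min_samples_per_group <- rep(as.integer(min_samples_per_group), 2L)
  }
  structure(list(name = name, a_samples = a_samples, b_samples = b_samples,
                 min_coverage = as.integer(min_coverage),
                 min_samples_per_group = as.integer(min_samples_per_group),
                 q_threshold = q_threshold),
            class = "comparison_spec")
}

#' Coverage filtering of a methylation matrix
#'
#' A (site, sample) cell is retained iff its coverage is at least
#' `min_coverage`; a site is retained iff each group of the comparison keeps
#' at least `min_samples_per_group` cells.
#'
#' @param x a `meth_matrix` from [assemble_matrix()].
#' @param spec a [comparison_spec()].
#' @param quiet suppress the retained/dropped log message.
#' @return a filtered `meth_matrix` restricted to the comparison's samples.
#' @export
filter_by_coverage <- function(x, spec, quiet = FALSE) {
  stopifnot(inherits(x, "meth_matrix"), inherits(spec, "comparison_spec"))
  samp <- c(spec$a_samples, spec$b_samples)
  missing <- setdiff(samp, x$samples)
  if (length(missing)) stop("samples not in matrix: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  meth <- x$meth[, samp, drop = FALSE]
  cov <- x$cov[, samp, drop = FALSE]
  low <- !is.na(cov) & cov < spec$min_coverage
  meth[low] <- NA_integer_
  cov[low] <- NA_integer_
  n_a <- rowSums(!is.na(cov[, spec$a_samples, drop = FALSE]))
  n_b <- rowSums(!is.na(cov[, spec$b_samples, drop = FALSE]))
  keep <- n_a >= spec$min_samples_per_group[1] & n_b >= spec$min_samples_per_group[2]
  if (!quiet) {
    message(sprintf("coverage filter (>= %d reads, >= %d/%d per group): %d of %d sites retained",
                    spec$min_coverage, spec$min_samples_per_group[1],
                    spec$min_samples_per_group[2], sum(keep), nrow(x$sites)))
  }
  structure(list(sites = x$sites[keep, , drop = FALSE],
                 samples = samp,
                 meth = meth[keep, , drop = FALSE],
                 cov = cov[keep, , drop = FALSE],
                 design = x$design[x$design$sample %in% samp, , drop = FALSE]),
            class = "meth_matrix")
}

#' Coverage-weighted pooled methylation difference
#'
#' The per-site methylation difference in percentage points between the
#' pooled proportions of the two groups:
#' `100 * (sum(m_b)/sum(cov_b) - sum(m_a)/sum(cov_a))`.
#'
#' @param meth_a,cov_a methylated counts and coverages of the reference group.
#' @param meth_b,cov_b counts of the treated group.
#' @return the signed difference (treated minus reference); `NA` when a group
#'   has zero total coverage.
#' @export
pooled_difference <- function(meth_a, cov_a, meth_b, cov_b) {
  ca <- sum(cov_a, na.rm = TRUE); cb <- sum(cov_b, na.rm = TRUE)
  if (ca == 0 || cb == 0) return(NA_real_)
  100 * (sum(meth_b, na.rm = TRUE) / cb - sum(meth_a, na.rm = TRUE) / ca)
}

# Vectorized core over a filtered matrix. Returns one row per site with the
# statistic, p-value, dispersion and pooled difference; sites where a group
# has zero usable coverage are dropped (logged).
.test_matrix <- function(meth, cov, a_cols, b_cols) {
  Ma <- rowSums(meth[, a_cols, drop = FALSE], na.rm = TRUE)
  Ca <- rowSums(cov[, a_cols, drop = FALSE], na.rm = TRUE)
  Mb <- rowSums(meth[, b_cols, drop = FALSE], na.rm = TRUE)
  Cb <- rowSums(cov[, b_cols, drop = FALSE], na.rm = TRUE)
  ok <- Ca > 0 & Cb > 0
  pa <- ifelse(Ca > 0, Ma / Ca, NA_real_)
  pb <- ifelse(Cb > 0, Mb / Cb, NA_real_)
  p0 <- ifelse(Ca + Cb > 0, (Ma + Mb) / (Ca + Cb), NA_real_)

  n_sites <- nrow(meth)
  d1 <- numeric(n_sites); d0 <- numeric(n_sites); r2 <- numeric(n_sites)
  group_p <- function(j) if (j %in% a_cols) pa else pb
  cols <- c(a_cols, b_cols)
  for (j in cols) {
    m <- meth[, j]; n <- cov[, j]
    pj <- group_p(j)
    t1 <- .dev_terms(m, n, pj); t0 <- .dev_terms(m, n, p0)
    rj <- .pearson_sq(m, n, pj)
    has <- !is.na(n)
    d1[has] <- d1[has] + t1[has]
    d0[has] <- d0[has] + t0[has]
    r2[has] <- r2[has] + rj[has]
  }
  nsamp <- rowSums(!is.na(cov[, cols, drop = FALSE]))
  df <- nsamp - 2
  raw_phi <- ifelse(df > 0, r2 / df, NA_real_)
  phi <- pmax(1, ifelse(is.na(raw_phi), 1, raw_phi))
  statistic <- pmax(0, d0 - d1) / phi
  p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  data.frame(meth_diff = 100 * (pb - pa),
             statistic = statistic, p = p,
             raw_phi = raw_phi, phi = phi, df = df,
             n_a = rowSums(!is.na(cov[, a_cols, drop = FALSE])),
             n_b = rowSums(!is.na(cov[, b_cols, drop = FALSE])),
             ok = ok)
}

#' Overdispersion-corrected chi-square test at one CpG
#'
#' Fits the per-CpG binomial logistic model of the methylated proportion on
#' the group indicator (trials = coverage). Under that model the fitted
#' proportions are the coverage-weighted pooled proportions per group. The
#' test statistic is the deviance difference between the intercept-only and
#' the two-group fit, scaled by the dispersion
#' `phi = max(1, sum(pearson residuals^2) / (n_samples - 2))`, and referred to
#' a chi-square distribution with one degree of freedom. Boundary fits
#' (all-methylated or all-unmethylated groups) are handled by clipping fitted
#' proportions inside the deviance, never producing infinities.
#'
#' @param meth_a,cov_a,meth_b,cov_b per-sample methylated counts and
#'   coverages for the two groups (equal-length vectors per group).
#' @return a list with `statistic`, `p`, `meth_diff`, `raw_phi`, `phi`, `df`.
#' @export
test_site <- function(meth_a, cov_a, meth_b, cov_b) {
  stopifnot(length(meth_a) == length(cov_a), length(meth_b) == length(cov_b))
  if (length(meth_a) < 2 || length(meth_b) < 2) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  meth <- matrix(c(meth_a, meth_b), nrow = 1)
  cov <- matrix(c(cov_a, cov_b), nrow = 1)
  res <- .test_matrix(meth, cov, seq_along(meth_a), length(meth_a) + seq_along(meth_b))
  if (!res$ok) stop("a group has zero total coverage", call. = FALSE)
  list(statistic = res$statistic, p = res$p, meth_diff = res$meth_diff,
       raw_phi = res$raw_phi, phi = res$phi, df = res$df)
}

#' Benjamini-Hochberg adjustment and DMS calling
#'
#' Adds q-values (BH over all tested sites of the comparison) and flags DMS:
#' sites with q strictly below the threshold. No minimum-difference filter is
#' applied, but a site with a pooled difference of exactly zero is never a
#' DMS. Output is sorted by (chrom, pos).
#'
#' @param tests data.frame of per-site test results (needs columns `chrom`,
#'   `pos`, `p`, `meth_diff`).
#' @param q_threshold FDR threshold (strict).
#' @return the input with added `q`, `is_dms` and `direction`
#'   (`hyper`/`hypo`) columns.
#' @export
adjust_and_call <- function(tests, q_threshold = 0.01) {
  if (nrow(tests) == 0) {
    tests$q <- numeric(0); tests$is_dms <- logical(0); tests$direction <- character(0)
    return(tests)
  }
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  tests$is_dms <- tests$q < q_threshold & tests$meth_diff != 0
  tests$direction <- ifelse(tests$meth_diff > 0, "hyper",
                            ifelse(tests$meth_diff < 0, "hypo", NA_character_))
  tests <- tests[order(tests$chrom, tests$pos), , drop = FALSE]
  rownames(tests) <- NULL
  tests
}

#' Fit per-CpG differential methylation between two groups
#'
#' The central fitting function: filters the count matrix by coverage, tests
#' every retained CpG with the overdispersion-corrected chi-square test
#' ([test_site()]), adjusts p-values by Benjamini-Hochberg across all tested
#' sites, and calls differentially methylated sites (DMS) at `q < q_threshold`
#' with hyper/hypo direction from the sign of the pooled methylation
#' difference (group b minus group a).
#'
#' @param x a `meth_matrix` from [assemble_matrix()] or [simulate_rrbs()].
#' @param group_a,group_b group labels in the design (a = reference, e.g. the
#'   untreated group; b = treated).
#' @param hemisphere optional: restrict both groups to one hemisphere
#'   (`"control"` or `"lesioned"`); default pools both sides.
#' @param hemisphere_a,hemisphere_b per-group hemisphere restriction,
#'   overriding `hemisphere`; with `group_a == group_b` and different
#'   hemispheres this yields the within-group side-vs-side comparison.
#' @param min_coverage,min_samples_per_group,q_threshold see
#'   [comparison_spec()].
#' @param name comparison label; default `"<group_b>-vs-<group_a>"`.
#' @param quiet suppress progress messages.
#' @return an object of class `dms_fit` with components `results` (per-site
#'   data.frame: `chrom`, `pos`, `strand`, `meth_diff`, `statistic`, `p`,
#'   `q`, `raw_phi`, `phi`, `is_dms`, `direction`), `spec`, and bookkeeping
#'   counts. Methods: `print`, `summary`, `coef` (named vector of pooled
#'   differences), `as.data.frame`, `plot` (volcano), and [dms()] to extract
#'   the significant sites.
#' @examples
#' sim <- simulate_rrbs(sim_config(seed = 7, n_chromosomes = 1, n_genes = 5,
#'                                 n_cgis = 8,
#'                                 effect_table = random_effect_table(30, 40)))
#' fit <- diff_methylation(sim$matrix, "UNT", "LDOPA", quiet = TRUE)
#' fit
#' head(dms(fit))
#' @export
diff_methylation <- function(x, group_a, group_b, hemisphere = NULL,
                             hemisphere_a = hemisphere, hemisphere_b = hemisphere,
                             min_coverage = 10L, min_samples_per_group = NULL,
                             q_threshold = 0.01,
                             name = NULL, quiet = FALSE) {
  stopifnot(inherits(x, "meth_matrix"))
  design <- x$design
  pick <- function(g, h) {
    s <- design$sample[design$group == g &
                         (if (is.null(h)) TRUE else design$hemisphere %in% h)]
    if (length(s) == 0) stop("no samples for group ", g, call. = FALSE)
    s
  }
  if (is.null(name)) {
    tag <- function(g, h) if (is.null(h)) g else paste0(g, ".", paste(h, collapse = "+"))
    name <- paste0(tag(group_b, hemisphere_b), "-vs-", tag(group_a, hemisphere_a))
  }
  spec <- comparison_spec(name, pick(group_a, hemisphere_a), pick(group_b, hemisphere_b),
                          min_coverage = min_coverage,
                          min_samples_per_group = min_samples_per_group,
                          q_threshold = q_threshold)
  xf <- filter_by_coverage(x, spec, quiet = quiet)
  a_cols <- match(spec$a_samples, xf$samples)
  b_cols <- match(spec$b_samples, xf$samples)
  res <- .test_matrix(xf$meth, xf$cov, a_cols, b_cols)
  excluded <- !res$ok
  if (any(excluded) && !quiet) {
    message(sprintf("%d site(s) excluded: zero total coverage in a group", sum(excluded)))
  }
  out <- cbind(xf$sites[!excluded, , drop = FALSE],
               res[!excluded, c("meth_diff", "statistic", "p", "raw_phi", "phi",
                                "n_a", "n_b"), drop = FALSE])
  out <- adjust_and_call(out, q_threshold)
  structure(list(results = out, spec = spec,
                 n_input = nrow(x$sites), n_tested = nrow(out),
                 n_dms = sum(out$is_dms),
                 n_hyper = sum(out$is_dms & out$direction == "hyper"),
                 n_hypo = sum(out$is_dms & out$direction == "hypo"),
                 call = match.call()),
            class = "dms_fit")
}

#' Extract the differentially methylated sites from a fit
#' @param fit a `dms_fit`.
#' @return data.frame of DMS records.
#' @export
dms <- function(fit) {
  stopifnot(inherits(fit, "dms_fit"))
  fit$results[fit$results$is_dms, , drop = FALSE]
}

#' @export
print.dms_fit <- function(x, ...) {
  cat(sprintf("Differential methylation fit: %s\n", x$spec$name))
  cat(sprintf("  %d site(s) in, %d tested (coverage >= %d, >= %d/%d per group)\n",
              x$n_input, x$n_tested, x$spec$min_coverage,
              x$spec$min_samples_per_group[1], x$spec$min_samples_per_group[2]))
  cat(sprintf("  DMS at q < %g: %d (%d hyper, %d hypo)\n",
              x$spec$q_threshold, x$n_dms, x$n_hyper, x$n_hypo))
  invisible(x)
}

#' @export
summary.dms_fit <- function(object, ...) {
  r <- object$results
  s <- list(fit = object,
            phi_summary = summary(r$phi),
            p_summary = summary(r$p),
            dms_diff_summary = if (object$n_dms > 0) summary(abs(r$meth_diff[r$is_dms])) else NULL,
            hypo_hyper_ratio = if (object$n_hyper > 0) object$n_hypo / object$n_hyper else NA_real_)
  class(s) <- "summary.dms_fit"
  s
}

#' @export
print.summary.dms_fit <- function(x, ...) {
  print(x$fit)
  cat("  dispersion scale (phi) across sites:\n")
  print(x$phi_summary)
  if (!is.null(x$dms_diff_summary)) {
    cat("  |meth_diff| among DMS (percentage points):\n")
    print(x$dms_diff_summary)
    cat(sprintf("  hypo:hyper ratio: %.2f\n", x$hypo_hyper_ratio))
  }
  invisible(x)
}

#' @export
coef.dms_fit <- function(object, ...) {
  stats::setNames(object$results$meth_diff,
                  paste0(object$results$chrom, ":", object$results$pos + 1L))
}

#' @export
as.data.frame.dms_fit <- function(x, ...) x$results

#' @export
plot.dms_fit <- function(x, ...) {
  r <- x$results
  col <- ifelse(!r$is_dms, "grey60", ifelse(r$direction == "hyper", "firebrick", "steelblue"))
  plot(r$meth_diff, -log10(pmax(r$q, 1e-300)), pch = 20, col = col,
       xlab = "methylation difference (percentage points)",
       ylab = expression(-log[10] ~ q), main = x$spec$name, ...)
  graphics::abline(h = -log10(x$spec$q_threshold), lty = 2)
  invisible(x)
}

#' Write a DMS result table
#'
#' Tab-separated output with 1-based positions (matching the coverage-format
#' convention): chrom, pos, strand, meth_diff, statistic, p, q, direction.
#'
#' @param fit a `dms_fit`.
#' @param path output path.
#' @param dms_only write only the significant sites (default all tested).
#' @export
write_dms <- function(fit, path, dms_only = FALSE) {
  r <- if (dms_only) dms(fit) else fit$results
  out <- data.frame(chrom = r$chrom, pos = r$pos + 1L, strand = r$strand,
                    meth_diff = r$meth_diff, statistic = r$statistic,
                    p = r$p, q = r$q, is_dms = r$is_dms,
                    direction = r$direction)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
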