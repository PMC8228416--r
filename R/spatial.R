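#' Neighbor distances between DMS on each chromosome
#'
#' Successive position differences of the sorted sites, computed within
#' chromosomes only. With `k` chromosomes carrying sites, the number of
#' distances is `n_sites - k`.
#'
#' @param sites data.frame with `chrom` and `pos`; positions must be unique
#'   per chromosome.
#' @return data.frame with columns `chrom` and `distance` (bp).
#' @export
neighbor_distances <- function(sites) {
  sites <- as.data.frame(sites)
  if (anyDuplicated(paste(sites$chrom, sites$pos))) {
    stop("duplicated site position(s): sites must be unique per chromosome",
         call. = FALSE)
  }
  out <- lapply(split(sites$pos, sites$chrom), function(p) diff(sort(p)))
  data.frame(chrom = rep(names(out), lengths(out)),
             distance = unlist(out, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Logarithmic distance histogram bin edges
#'
#' 30 logarithmic bins from 1 bp to 10 Mb; distances beyond the last edge are
#' counted in an overflow bin.
#' @param n_bins number of bins.
#' @param max_bp upper edge (bp).
#' @return numeric vector of bin edges.
#' @export
distance_breaks <- function(n_bins = 30, max_bp = 1e7) {
  10^seq(0, log10(max_bp), length.out = n_bins + 1)
}

.hist_counts <- function(distances, breaks) {
  b <- c(breaks, Inf) # overflow bin for distances beyond the last edge
  as.numeric(table(cut(distances, breaks = b, include.lowest = TRUE, right = TRUE)))
}

#' Resampling null for the DMS distance distribution
#'
#' Each of `n_resamples` draws samples `dms_count` sites uniformly without
#' replacement from the background CpG set genome-wide (or stratified per
#' chromosome), recomputes neighbor distances, and histograms them. The null
#' is the per-bin mean over draws; the per-bin standard deviation is also
#' returned. Deterministic under `seed`.
#'
#' @param dms_count number of sites per draw; must not exceed the background.
#' @param background data.frame of background sites (`chrom`, `pos`).
#' @param n_resamples number of random draws (the conventional choice is 100).
#' @param seed integer seed.
#' @param breaks histogram bin edges, see [distance_breaks()].
#' @param stratify_by_chromosome sample the per-chromosome site counts of a
#'   proportional allocation instead of genome-wide uniform.
#' @return list with `breaks`, `mean` and `sd` (per-bin, last bin = overflow),
#'   and `n_resamples`.
#' @export
resample_null <- function(dms_count, background, n_resamples = 100, seed,
                          breaks = distance_breaks(),
                          stratify_by_chromosome = FALSE) {
  background <- as.data.frame(background)
  if (dms_count > nrow(background)) {
    stop("dms_count exceeds the number of background sites", call. = FALSE)
  }
  counts <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      idx <- if (stratify_by_chromosome) {
        unlist(lapply(split(seq_len(nrow(background)), background$chrom), function(ii) {
          k <- round(length(ii) / nrow(background) * dms_count)
          if (k > 0) sample(ii, min(k, length(ii))) else integer(0)
        }), use.names = FALSE)
      } else {
        sample.int(nrow(background), dms_count)
      }
      d <- neighbor_distances(background[idx, , drop = FALSE])
      .hist_counts(d$distance, breaks)
    }, numeric(length(breaks)))
  })
  list(breaks = breaks,
       mean = rowMeans(counts),
       sd = apply(counts, 1, stats::sd),
       n_resamples = n_resamples)
}

#' Observed vs null DMS distance distribution
#'
#' Combines [neighbor_distances()] on the DMS set with [resample_null()] on
#' the background to expose spatial clustering of DMS: an excess of observed
#' counts over the null in the short-distance bins means CpGs in close
#' proximity tend to change methylation together.
#'
#' @param dms_sites DMS sites (`chrom`, `pos`).
#' @param background background CpG sites.
#' @param n_resamples,seed,breaks see [resample_null()].
#' @return an object of class `distance_distribution`: list with `breaks`,
#'   `observed`, `null_mean`, `null_sd`, `n_resamples`.
#' @export
distance_distribution <- function(dms_sites, background, n_resamples = 100,
                                  seed, breaks = distance_breaks()) {
  obs <- neighbor_distances(dms_sites)
  null <- resample_null(nrow(as.data.frame(dms_sites)), background,
                        n_resamples = n_resamples, seed = seed, breaks = breaks)
  structure(list(breaks = breaks, observed = .hist_counts(obs$distance, breaks),
                 null_mean = null$mean, null_sd = null$sd,
                 n_resamples = n_resamples),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("distance_distribution: %d bins, null = mean of %d resamples\n",
              length(x$observed), x$n_resamples))
  short <- x$breaks <= 100
  cat(sprintf("  observed <=100 bp: %g; null mean: %.2f\n",
              sum(x$observed[short]), sum(x$null_mean[short])))
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, ...) {
  mids <- sqrt(x$breaks[-length(x$breaks)] * x$breaks[-1])
  n <- length(mids)
  plot(mids, x$observed[seq_len(n)], log = "x", type = "b", pch = 20,
       xlab = "neighbor distance (bp)", ylab = "DMS pairs", ...)
  graphics::lines(mids, x$null_mean[seq_len(n)], col = "grey50", lty = 2)
  graphics::legend("topleft", c("observed", "null mean"), lty = c(1, 2),
                   col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Same-direction fraction of close DMS pairs
#'
#' Over all pairs of DMS on the same chromosome separated by at most `radius`
#' bp: the fraction whose methylation differences have the same sign, plus
#' the median absolute difference of amplitudes among same-sign pairs (a
#' summary of how similar the amplitude of change is in close pairs).
#'
#' @param records data.frame with `chrom`, `pos` and `meth_diff`.
#' @param radius maximum pair separation in bp (default 100).
#' @return list with `fraction`, `n_pairs`, `median_amplitude_diff`; when no
#'   pair qualifies, `fraction` is `NA` and this is reported.
#' @export
same_direction_fraction <- function(records, radius = 100) {
  records <- as.data.frame(records)
  same <- 0L; total <- 0L; amp <- numeric(0)
  for (ch in unique(records$chrom)) {
    r <- records[records$chrom == ch, , drop = FALSE]
    r <- r[order(r$pos), , drop = FALSE]
    n <- nrow(r)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      j <- i + 1L
      while (j <= n && r$pos[j] - r$pos[i] <= radius) {
        total <- total + 1L
        if (sign(r$meth_diff[i]) == sign(r$meth_diff[j])) {
          same <- same + 1L
          amp <- c(amp, abs(r$meth_diff[i] - r$meth_diff[j]))
        }
        j <- j + 1L
      }
    }
  }
  if (total == 0) {
    message("no DMS pairs within ", radius, " bp: same-direction fraction undefined")
    return(list(fraction = NA_real_, n_pairs = 0L, median_amplitude_diff = NA_real_))
  }
  list(fraction = same / total, n_pairs = total,
       median_amplitude_diff = if (length(amp)) stats::median(amp) else NA_real_)
}

#' 1-Mb bin DMS density difference between two comparisons
#'
#' Counts DMS per genomic bin (`bin_size` bp, anchored at coordinate 0,
#' half-open) for each comparison and reports the per-bin difference
#' (comparison 2 minus comparison 1), ranked by absolute difference.
#'
#' @param dms_1,dms_2 DMS site data.frames (`chrom`, `pos`).
#' @param bin_size bin width in bp (default 1 Mb).
#' @return data.frame with `chrom`, `bin_start`, `bin_end`, `count_1`,
#'   `count_2`, `difference`, sorted by decreasing `|difference|`.
#' @export
bin_difference <- function(dms_1, dms_2, bin_size = 1e6) {
  dms_1 <- as.data.frame(dms_1); dms_2 <- as.data.frame(dms_2)
  key <- function(d) if (nrow(d)) paste(d$chrom, floor(d$pos / bin_size)) else character(0)
  k1 <- key(dms_1); k2 <- key(dms_2)
  bins <- sort(unique(c(k1, k2)))
  c1 <- as.numeric(table(factor(k1, levels = bins)))
  c2 <- as.numeric(table(factor(k2, levels = bins)))
  parts <- strsplit(bins, " ", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  bk <- as.numeric(vapply(parts, `[`, character(1), 2L))
  out <- data.frame(chrom = chrom, bin_start = as.integer(bk * bin_size),
                    bin_end = as.integer((bk + 1) * bin_size),
                    count_1 = c1, count_2 = c2, difference = c2 - c1,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$difference), out$chrom, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nested correlations of methylation changes between two comparisons
#'
#' Pearson product-moment correlation of per-CpG methylation differences for
#' (i) all shared CpGs, (ii) CpGs that are DMS in at least one comparison,
#' (iii) CpGs that are DMS in both. When the changes are driven by a shared
#' treatment effect plus independent noise the three coefficients nest
#' upward.
#'
#' @param diff_1,diff_2 per-CpG methylation differences of the two
#'   comparisons over a shared site set.
#' @param dms_1,dms_2 logical DMS flags over the same sites.
#' @return list with `r_all`, `r_dms_any`, `r_dms_both` and the subset sizes
#'   `n_all`, `n_any`, `n_both`; a coefficient is `NA` when its subset has
#'   fewer than 3 points.
#' @export
nested_correlations <- function(diff_1, diff_2, dms_1, dms_2) {
  stopifnot(length(diff_1) == length(diff_2),
            length(dms_1) == length(diff_1), length(dms_2) == length(diff_1))
  r_or_na <- function(i) if (sum(i) >= 3) stats::cor(diff_1[i], diff_2[i]) else NA_real_
  all_i <- !is.na(diff_1) & !is.na(diff_2)
  any_i <- all_i & (dms_1 | dms_2)
  both_i <- all_i & dms_1 & dms_2
  list(r_all = r_or_na(all_i), r_dms_any = r_or_na(any_i), r_dms_both = r_or_na(both_i),
       n_all = sum(all_i), n_any = sum(any_i), n_both = sum(both_i))
}

#' Screen for CpGs with divergent methylation change between two comparisons
#'
#' Keeps CpGs that are DMS in at least one of the two comparisons and whose
#' absolute difference of methylation changes is greater than or equal to
#' `threshold` percentage points (the threshold is inclusive).
#'
#' @param sites data.frame of the shared CpGs (`chrom`, `pos`).
#' @param diff_1,diff_2 per-CpG methylation differences (percentage points).
#' @param dms_1,dms_2 logical DMS flags.
#' @param threshold minimum absolute difference of changes (default 20).
#' @return data.frame with `chrom`, `pos`, `diff_1`, `diff_2`, `is_dms_1`,
#'   `is_dms_2`, `abs_delta`, sorted by decreasing `abs_delta`.
#' @export
delta_screen <- function(sites, diff_1, diff_2, dms_1, dms_2, threshold = 20) {
  sites <- as.data.frame(sites)
  stopifnot(nrow(sites) == length(diff_1), length(diff_1) == length(diff_2))
  abs_delta <- abs(diff_1 - diff_2)
  keep <- (dms_1 | dms_2) & !is.na(abs_delta) & abs_delta >= threshold
  out <- data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                    diff_1 = diff_1[keep], diff_2 = diff_2[keep],
                    is_dms_1 = dms_1[keep], is_dms_2 = dms_2[keep],
                    abs_delta = abs_delta[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$abs_delta), , drop = FALSE]
  rownames(out) <- NULL
  out
}
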