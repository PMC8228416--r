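#' Specify an injected methylation effect
#'
#' An effect spec describes a set of CpG sites whose latent methylation level
#' is shifted by `delta` percentage points in one or more target groups.
#' Effects are applied at the level of co-methylation regions, so CpGs that
#' share a latent region with an injected site shift together, mirroring the
#' local co-methylation seen in RRBS data.
#'
#' @param target_group character, one or more group labels that receive the
#'   shift at the same sites (several labels model a shared treatment effect).
#' @param delta signed methylation change in percentage points, |delta| <= 100.
#'   Negative values are methylation losses (hypomethylation).
#' @param region_preference where to place affected sites: `"open_sea"`
#'   (outside CpG islands and shores), `"gene_body"` (exon or intron),
#'   `"promoter"`, or `"any"`.
#' @param n_sites number of affected CpG sites (>= 1).
#' @return an object of class `effect_spec`.
#' @seealso [sim_config()], [random_effect_table()]
#' @export
effect_spec <- function(target_group, delta,
                        region_preference = c("any", "open_sea", "gene_body", "promoter"),
                        n_sites = 1L) {
  region_preference <- match.arg(region_preference)
  stopifnot_scalar(delta)
  stopifnot_scalar(n_sites)
  if (abs(delta) > 100) stop("|delta| must be <= 100 percentage points", call. = FALSE)
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  if (!is.character(target_group) || length(target_group) < 1L) {
    stop("target_group must be one or more group labels", call. = FALSE)
  }
  structure(
    list(target_group = target_group, delta = delta,
         region_preference = region_preference, n_sites = as.integer(n_sites)),
    class = "effect_spec"
  )
}

#' Build a randomized effect table with a hypomethylation bias
#'
#' Convenience constructor producing an effect table in which a fraction
#' `hypo_fraction` of the affected sites lose methylation and the rest gain
#' it, all with magnitude `delta_magnitude`. The default bias of 0.75
#' reflects the greater-than-3:1 hypo:hyper asymmetry typical of chronic
#' drug-treatment methylation responses in brain tissue.
#'
#' @param n_sites total number of affected sites.
#' @param delta_magnitude absolute methylation change in percentage points.
#' @param hypo_fraction fraction of sites that are methylation losses.
#' @param target_group group label(s) receiving the effects.
#' @param region_preference placement preference, see [effect_spec()].
#' @return a list of `effect_spec` objects.
#' @export
random_effect_table <- function(n_sites, delta_magnitude = 40,
                                hypo_fraction = 0.75,
                                target_group = "LDOPA",
                                region_preference = "open_sea") {
  stopifnot(hypo_fraction >= 0, hypo_fraction <= 1)
  n_hypo <- round(n_sites * hypo_fraction)
  n_hyper <- n_sites - n_hypo
  out <- list()
  if (n_hypo > 0) {
    out <- c(out, list(effect_spec(target_group, -abs(delta_magnitude),
                                   region_preference, n_hypo)))
  }
  if (n_hyper > 0) {
    out <- c(out, list(effect_spec(target_group, abs(delta_magnitude),
                                   region_preference, n_hyper)))
  }
  out
}

#' Configure an RRBS simulation
#'
#' Collects all parameters of the synthetic RRBS generator: genome geometry,
#' MspI fragment size selection, sequencing depth, beta-binomial dispersion,
#' the experimental design (groups x animals x hemispheres), and the table of
#' injected effects. The defaults emulate a three-group rodent striatum study
#' (untreated, drug, drug + co-treatment) with three animals per group and
#' both the lesioned and contralateral control hemisphere sequenced, i.e.
#' 18 samples.
#'
#' @param seed integer seed; mandatory, every downstream draw derives from it.
#' @param n_chromosomes,chrom_length genome geometry (bp per chromosome).
#' @param n_genes,n_cgis number of gene models and CpG islands to place.
#' @param fragment_size_window closed interval (bp) of MspI fragment lengths
#'   retained by size selection; must lie within [50, 1200], the detectable
#'   range of RRBS libraries.
#' @param mean_depth mean read coverage per covered CpG (>= 10 so that the
#'   standard coverage filter retains data).
#' @param dispersion beta-binomial intra-class correlation in [0, 1);
#'   variation of animal-level methylation around the group mean.
#' @param n_animals_per_group animals per treatment group.
#' @param groups treatment group labels.
#' @param hemispheres hemisphere labels; both sides of an animal share the
#'   animal's latent methylation levels.
#' @param effect_table list of [effect_spec()] objects.
#' @param hypo_fraction default hypomethylation bias used by helpers that
#'   build effect tables; in [0, 1].
#' @param comethylation_radius bp; consecutive CpGs closer than this share a
#'   latent methylation region.
#' @param side_effect additive shift (on the methylation proportion scale)
#'   applied to the lesioned hemisphere; defaults to 0 (sides exchangeable).
#' @param cpg_spacing,cgi_cpg_spacing mean CpG spacing (bp) outside/inside
#'   CpG islands.
#' @param baseline_means named numeric: latent baseline methylation means for
#'   `cgi_promoter`, `shore` and `open_sea` region classes.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 2L,
                       chrom_length = 1e6,
                       n_genes = 20L,
                       n_cgis = 30L,
                       fragment_size_window = c(50, 1200),
                       mean_depth = 30,
                       dispersion = 0.02,
                       n_animals_per_group = 3L,
                       groups = c("UNT", "LDOPA", "LDOPA_R"),
                       hemispheres = c("control", "lesioned"),
                       effect_table = list(),
                       hypo_fraction = 0.75,
                       comethylation_radius = 100,
                       side_effect = 0,
                       cpg_spacing = 150,
                       cgi_cpg_spacing = 20,
                       baseline_means = c(cgi_promoter = 0.1, shore = 0.5, open_sea = 0.8)) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot_scalar(seed)
  stopifnot_scalar(chrom_length)
  if (length(fragment_size_window) != 2L ||
      fragment_size_window[1] > fragment_size_window[2]) {
    stop("fragment_size_window must be (min, max) with min <= max", call. = FALSE)
  }
  if (fragment_size_window[1] < 50 || fragment_size_window[2] > 1200) {
    stop("fragment_size_window must lie within [50, 1200] bp, the detectable RRBS fragment range",
         call. = FALSE)
  }
  if (hypo_fraction < 0 || hypo_fraction > 1) {
    stop("hypo_fraction must be in [0, 1]", call. = FALSE)
  }
  if (dispersion < 0 || dispersion >= 1) {
    stop("dispersion must be in [0, 1)", call. = FALSE)
  }
  if (mean_depth < 10) {
    stop("mean_depth must be >= 10 so coverage filtering retains data", call. = FALSE)
  }
  if (!all(vapply(effect_table, inherits, logical(1), "effect_spec"))) {
    stop("effect_table must be a list of effect_spec objects", call. = FALSE)
  }
  stopifnot(all(c("cgi_promoter", "shore", "open_sea") %in% names(baseline_means)))
  for (spec in effect_table) {
    bad <- setdiff(spec$target_group, groups)
    if (length(bad)) stop("effect target_group not in groups: ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed),
         n_chromosomes = as.integer(n_chromosomes),
         chrom_length = as.integer(chrom_length),
         n_genes = as.integer(n_genes),
         n_cgis = as.integer(n_cgis),
         fragment_size_window = as.numeric(fragment_size_window),
         mean_depth = mean_depth,
         dispersion = dispersion,
         n_animals_per_group = as.integer(n_animals_per_group),
         groups = groups,
         hemispheres = hemispheres,
         effect_table = effect_table,
         hypo_fraction = hypo_fraction,
         comethylation_radius = comethylation_radius,
         side_effect = side_effect,
         cpg_spacing = cpg_spacing,
         cgi_cpg_spacing = cgi_cpg_spacing,
         baseline_means = baseline_means),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("RRBS simulation config\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp; %d genes, %d CGIs\n",
              x$n_chromosomes, format(x$chrom_length, big.mark = ","),
              x$n_genes, x$n_cgis))
  cat(sprintf("  fragments kept: [%g, %g] bp; mean depth %g; dispersion %g\n",
              x$fragment_size_window[1], x$fragment_size_window[2],
              x$mean_depth, x$dispersion))
  cat(sprintf("  design: %s x %d animals x {%s}\n",
              paste(x$groups, collapse = "/"), x$n_animals_per_group,
              paste(x$hemispheres, collapse = ", ")))
  cat(sprintf("  effects: %d spec(s); seed %d\n", length(x$effect_table), x$seed))
  invisible(x)
}

#' Build the sample design sheet implied by a simulation config
#'
#' @param config a [sim_config()].
#' @return a data.frame with columns `sample`, `group`, `hemisphere`,
#'   `animal`, one row per simulated library.
#' @export
sim_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- expand.grid(hemisphere = config$hemispheres,
                      animal_idx = seq_len(config$n_animals_per_group),
                      group = config$groups,
                      stringsAsFactors = FALSE)
  animal <- sprintf("%s_a%d", rows$group, rows$animal_idx)
  data.frame(sample = sprintf("%s_%s", animal, rows$hemisphere),
             group = rows$group,
             hemisphere = rows$hemisphere,
             animal = animal,
             stringsAsFactors = FALSE)
}
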