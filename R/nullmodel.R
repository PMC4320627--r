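# Monte Carlo randomized-placement null: peaks replaced by uniform random
# single-bp locations, classified and measured exactly like observed peaks.

#' Uniform random genomic sites
#'
#' `n` i.i.d. integer coordinates uniform on `[0, genome length)`, drawn with
#' replacement and reproducible for a fixed seed.
#'
#' @param n number of sites (> 0).
#' @param genome a `genome_model` (or a numeric genome length).
#' @param seed integer seed.
#' @return numeric vector of coordinates.
#' @export
random_sites <- function(n, genome, seed = 1L) {
  assert_that(is_count(n), "n must be a positive integer")
  len <- if (inherits(genome, "genome_model")) genome$length else genome
  set.seed(seed)
  as.numeric(sample.int(len, n, replace = TRUE) - 1L)
}

#' Compare observed peaks with a randomized-placement null
#'
#' Draws `mc_replicates` sets of as many uniform random sites as there are
#' observed peaks, classifies each site as coding or non-coding and measures
#' its signed distance to the nearest predicted TSC, then tests the observed
#' coding/non-coding split against the first randomized replicate with
#' Fisher's exact test.
#'
#' @param annotations annotated observed peaks from [annotate_all()].
#' @param genome a `genome_model`.
#' @param config an [analysis_config()]; `mc_replicates` sets the number of
#'   randomized datasets and `rng_seed` the base seed.
#' @return object of class `null_comparison`: a list with `region_counts`
#'   (per-replicate tibble), `distance_samples` (first replicate's signed
#'   nearest-TSC distances), `contingency` (2x2 matrix observed/random x
#'   noncoding/coding), `fisher_p`, `summary` (mean coding proportion and a
#'   95% Monte Carlo interval), `n_sites`, `n_replicates`, `seed`.
#' @export
null_comparison <- function(annotations, genome,
                            config = analysis_config()) {
  n_sites <- nrow(annotations)
  n_rep <- max(1L, as.integer(config$mc_replicates))
  base_seed <- derive_seed(config$rng_seed, "nullmodel")
  counts <- purrr::map_dfr(seq_len(n_rep), function(r) {
    sites <- random_sites(n_sites, genome, seed = base_seed + r - 1L)
    cls <- classify_region(sites, genome)
    tibble(replicate = r,
           coding = sum(cls == "coding"),
           noncoding = sum(cls == "noncoding"))
  })
  stopifnot(all(counts$coding + counts$noncoding == n_sites))
  first_sites <- random_sites(n_sites, genome, seed = base_seed)
  distances <- nearest_tsc_distance(first_sites, genome)
  obs_nc <- sum(annotations$region_class == "noncoding")
  obs_c <- sum(annotations$region_class == "coding")
  tab <- matrix(c(obs_nc, obs_c,
                  counts$noncoding[1], counts$coding[1]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("observed", "random"),
                                c("noncoding", "coding")))
  p <- fisher_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  prop <- counts$coding / n_sites
  structure(list(
    region_counts = counts,
    distance_samples = distances,
    contingency = tab,
    fisher_p = p,
    summary = tibble(mean_coding_prop = mean(prop),
                     ci_lo = unname(quantile(prop, 0.025)),
                     ci_hi = unname(quantile(prop, 0.975))),
    n_sites = n_sites,
    n_replicates = n_rep,
    seed = base_seed
  ), class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf(
    "<null_comparison> %d sites x %d replicate(s); mean coding %.1f%%; Fisher p = %.3g\n",
    x$n_sites, x$n_replicates, 100 * x$summary$mean_coding_prop, x$fisher_p))
  print(x$contingency)
  invisible(x)
}

#' @rdname null_comparison
#' @param x a `null_comparison`.
#' @param ... unused.
#' @method tidy null_comparison
#' @export
tidy.null_comparison <- function(x, ...) x$region_counts

#' @rdname null_comparison
#' @method glance null_comparison
#' @export
glance.null_comparison <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_sites = x$n_sites, n_replicates = x$n_replicates,
           fisher_p = x$fisher_p, seed = x$seed),
    x$summary)
}
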