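#' Simulator configuration
#'
#' The generative model for synthetic cfDNA coverage over the HBA bins.
#' For a sample with genotype copy-fraction track `cf_i`, the expected raw
#' count of bin i is
#' `mu_i = mean_depth * (length_i / sum(lengths)) * cf_i * bias_i`,
#' where `bias_i` is a per-sample multiplicative bin bias drawn from
#' LogNormal(-bias_sigma^2/2, bias_sigma) (mean 1), absorbing capture and
#' mappability effects. Counts are negative binomial with
#' `Var = mu + mu^2/dispersion`; `dispersion = Inf` gives Poisson counts.
#'
#' `mean_depth` is the expected number of fragments over the whole region.
#' The default corresponds to the targeted assay's ~1852X mean coverage:
#' [coverage_to_fragments()] converts X-coverage to a fragment count via
#' `coverage * region_length / fragment_length`.
#'
#' @param bins A `thal_bins` tibble (default: the 66-bin HBA tiling).
#' @param geometry A `thal_geometry` supplying deletion intervals.
#' @param mean_depth Expected fragments per sample over the region.
#' @param bias_sigma SD of the per-bin log-normal bias (>= 0).
#' @param dispersion Negative-binomial size parameter (`Inf` = Poisson).
#' @param fragment_length_mean,fragment_length_sd Fragment length model (bp),
#'   truncated to \[50, 500\] when fragments are drawn.
#' @param fetal_fraction Fetal cfDNA proportion in \[0, 0.5\]; 0 (default)
#'   simulates pure maternal signal.
#' @param seed Optional integer seed applied by the top-level simulation
#'   entry points.
#' @return A list of class `thal_sim_config`.
#' @export
simulator_config <- function(bins = default_bins(geometry),
                             geometry = hba_geometry(),
                             mean_depth = coverage_to_fragments(1852),
                             bias_sigma = 0.1,
                             dispersion = 20,
                             fragment_length_mean = 166,
                             fragment_length_sd = 40,
                             fetal_fraction = 0,
                             seed = NULL) {
  bins <- validate_bins(bins)
  stopf(mean_depth > 0, "mean_depth must be > 0")
  stopf(bias_sigma >= 0, "bias_sigma must be >= 0")
  stopf(dispersion > 0, "dispersion must be > 0")
  stopf(fetal_fraction >= 0 && fetal_fraction <= 0.5,
        "fetal_fraction must be in [0, 0.5]")
  stopf(fragment_length_mean > 0 && fragment_length_sd >= 0,
        "invalid fragment length model")
  structure(list(bins = bins, geometry = geometry, mean_depth = mean_depth,
                 bias_sigma = bias_sigma, dispersion = dispersion,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 fetal_fraction = fetal_fraction, seed = seed),
            class = "thal_sim_config")
}

#' Convert X-coverage to an expected fragment count
#'
#' @param coverage Mean depth in X over the region.
#' @param region_length Region length in bp (default: the 21 kb HBA target).
#' @param fragment_length Mean fragment length in bp.
#' @return Expected number of fragments: `coverage * region_length /
#'   fragment_length`.
#' @export
coverage_to_fragments <- function(coverage, region_length = 21000,
                                  fragment_length = 166) {
  round(coverage * region_length / fragment_length)
}

draw_bias <- function(config) {
  if (config$bias_sigma == 0) return(rep(1, nrow(config$bins)))
  exp(rnorm(nrow(config$bins), -config$bias_sigma^2 / 2, config$bias_sigma))
}

draw_counts <- function(mu, dispersion) {
  if (is.infinite(dispersion)) rpois(length(mu), mu)
  else rnbinom(length(mu), mu = mu, size = dispersion)
}

#' Simulate one sample's per-bin counts
#'
#' Draws a count profile for a genotype under the configured coverage model
#' (see [simulator_config()] for the generative model).
#'
#' @param genotype A `thal_genotype`.
#' @param config A `thal_sim_config`.
#' @param sample_id Identifier for the returned profile.
#' @param copy_fraction Optional override of the per-bin copy-fraction track
#'   (used internally for fetal admixture); defaults to the genotype's track.
#' @param seed Optional seed; defaults to `config$seed`. Pass `NULL` inside
#'   loops that manage the RNG themselves.
#' @return A `thal_profile` (see [count_profile()]).
#' @examples
#' cfg <- simulator_config(bias_sigma = 0, dispersion = Inf, seed = 1)
#' simulate_counts(genotype("aa", "SEA"), cfg)
#' @export
simulate_counts <- function(genotype, config, sample_id = "sim",
                            copy_fraction = NULL, seed = config$seed) {
  stopf(inherits(config, "thal_sim_config"), "config must be a thal_sim_config")
  if (!is.null(seed)) set.seed(seed)
  cf <- copy_fraction %||%
    copy_fraction_track(genotype, config$bins, config$geometry)
  lens <- bin_lengths(config$bins)
  mu <- config$mean_depth * (lens / sum(lens)) * cf * draw_bias(config)
  raw <- draw_counts(mu, config$dispersion)
  count_profile(sample_id, raw, config$bins)
}

#' Simulate individual cfDNA fragments
#'
#' Draws fragment spans whose midpoint density is proportional to the
#' copy-fraction-times-bias profile over the region (piecewise constant on
#' the partition induced by bin edges and deletion breakpoints), with
#' lengths Normal(`fragment_length_mean`, `fragment_length_sd`) truncated to
#' \[50, 500\] bp. Piping the result through [count_fragments()] is
#' statistically consistent with [simulate_counts()].
#'
#' @inheritParams simulate_counts
#' @param n Expected number of fragments; defaults to `config$mean_depth`.
#'   The realized number is Poisson around the copy-fraction-weighted
#'   expectation.
#' @return A tibble of fragments (`chrom`, `start`, `end`).
#' @export
simulate_fragments <- function(genotype, config, n = config$mean_depth,
                               seed = config$seed) {
  stopf(inherits(config, "thal_sim_config"), "config must be a thal_sim_config")
  stopf(n >= 0, "n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  bins <- config$bins
  chrom <- bins$chrom[1]
  if (n == 0) return(tibble(chrom = character(), start = integer(),
                            end = integer()))
  cf <- copy_fraction_track(genotype, bins, config$geometry)
  bias <- draw_bias(config)

  # partition the region at bin edges and deletion breakpoints so the
  # midpoint density is constant on each segment
  haps <- c(genotype$hap1, genotype$hap2)
  brk <- sort(unique(c(bins$start, bins$end, unlist(lapply(haps, function(h) {
    d <- config$geometry$alleles[config$geometry$alleles$allele == h, ]
    if (nrow(d) == 1 && !is.na(d$start)) c(d$start, d$end) else NULL
  })))))
  brk <- brk[brk >= min(bins$start) & brk <= max(bins$end)]
  seg_start <- head(brk, -1)
  seg_end <- brk[-1]
  seg_mid <- (seg_start + seg_end) / 2
  seg_bin <- findInterval(seg_mid, bins$start)
  seg_cf <- vapply(seq_along(seg_start), function(i) {
    g1 <- seg_frac_intact(genotype$hap1, seg_start[i], seg_end[i], config$geometry)
    g2 <- seg_frac_intact(genotype$hap2, seg_start[i], seg_end[i], config$geometry)
    (g1 + g2) / 2
  }, numeric(1))
  w <- (seg_end - seg_start) * seg_cf * bias[seg_bin]
  lens <- bin_lengths(bins)
  expected <- n * sum(w) / sum(lens)
  n_frag <- rpois(1, expected)
  if (n_frag == 0) return(tibble(chrom = character(), start = integer(),
                                 end = integer()))
  seg <- sample.int(length(w), n_frag, replace = TRUE, prob = w)
  mid <- runif(n_frag, seg_start[seg], seg_end[seg])
  len <- rnorm(n_frag, config$fragment_length_mean, config$fragment_length_sd)
  while (any(out <- len < 50 | len > 500)) {
    len[out] <- rnorm(sum(out), config$fragment_length_mean,
                      config$fragment_length_sd)
  }
  start <- pmax(0L, as.integer(round(mid - len / 2)))
  tibble(chrom = chrom, start = start,
         end = start + as.integer(round(len)))
}

# fraction of [s, e) retained on one haplotype (1 outside its deletion)
seg_frac_intact <- function(hap, s, e, geometry) {
  if (hap == "aa") return(1)
  d <- geometry$alleles[geometry$alleles$allele == hap, ]
  ov <- max(0, min(e, d$end) - max(s, d$start))
  1 - ov / (e - s)
}

#' Cohort composition specification
#'
#' Either fixed per-genotype sample counts, or population genotype
#' frequencies plus a total size (converted to deterministic per-class
#' counts by largest-remainder rounding, so rare genotypes are represented
#' at their expected number in every cohort size).
#'
#' @param counts Named integer vector or tibble (`genotype`, `count`) of
#'   samples per genotype (genotype strings like `"aa/SEA"`).
#' @param frequencies Named numeric vector or tibble (`genotype`, `freq`)
#'   summing to 1.
#' @param n_samples Total cohort size (required with `frequencies`).
#' @return A tibble (`genotype`, `count`) of class `thal_cohort_spec`.
#' @export
cohort_spec <- function(counts = NULL, frequencies = NULL, n_samples = NULL) {
  if (!is.null(counts)) {
    if (!is.data.frame(counts)) {
      counts <- tibble(genotype = names(counts), count = as.integer(counts))
    }
    stopf(all(counts$count >= 0), "counts must be non-negative")
  } else {
    stopf(!is.null(frequencies) && !is.null(n_samples),
          "supply counts, or frequencies plus n_samples")
    if (!is.data.frame(frequencies)) {
      frequencies <- tibble(genotype = names(frequencies),
                            freq = as.numeric(frequencies))
    }
    stopf(abs(sum(frequencies$freq) - 1) < 1e-9,
          "frequencies must sum to 1 (got %.6f)", sum(frequencies$freq))
    raw <- frequencies$freq * n_samples
    base <- floor(raw)
    rem <- n_samples - sum(base)
    add <- head(order(raw - base, decreasing = TRUE), rem)
    base[add] <- base[add] + 1
    counts <- tibble(genotype = frequencies$genotype, count = as.integer(base))
  }
  invisible(lapply(counts$genotype, parse_genotype)) # validates strings
  counts <- counts[counts$count > 0, ]
  stopf(sum(counts$count) > 0, "cohort spec is empty")
  structure(counts, class = c("thal_cohort_spec", class(tibble())))
}

#' Observed cohort genotype frequencies as a default spec
#'
#' Genotype frequencies from the 68,885-woman screening cohort tally
#' (see [vietnam_cohort_counts()]), usable directly as the `frequencies`
#' argument of [cohort_spec()].
#'
#' @return Tibble with `genotype` and `freq` columns summing to 1.
#' @export
default_cohort_frequencies <- function() {
  tab <- vietnam_cohort_counts()
  tibble(genotype = tab$genotype, freq = tab$count / sum(tab$count))
}

#' Simulate a labeled cohort
#'
#' Generates per-sample count profiles for the composition in `spec`. With
#' `fetal_fraction` f > 0 in the config, each sample's copy-fraction track is
#' the mixture `(1 - f) * maternal + f * fetal`, where the fetal genotype
#' inherits one maternal haplotype uniformly and a paternal haplotype drawn
#' from `paternal_freqs` (defaults to the allele frequencies implied by the
#' spec itself). Labels are always the maternal genotype class.
#'
#' @param spec A `thal_cohort_spec` (or anything [cohort_spec()] accepts as
#'   `counts`).
#' @param config A `thal_sim_config`.
#' @param seed Seed; defaults to `config$seed`.
#' @param paternal_freqs Optional named numeric vector of allele frequencies
#'   for the paternal haplotype under fetal admixture.
#' @return A list: `raw` (wide raw-count tibble), `tpm` (TPM tibble),
#'   `labels` (tibble `sample_id`, `genotype`, `label`).
#' @examples
#' cfg <- simulator_config(mean_depth = 5000, seed = 1)
#' sim <- simulate_cohort(cohort_spec(c("aa/aa" = 5, "aa/SEA" = 5)), cfg)
#' sim$labels
#' @export
simulate_cohort <- function(spec, config, seed = config$seed,
                            paternal_freqs = NULL) {
  if (!inherits(spec, "thal_cohort_spec")) spec <- cohort_spec(counts = spec)
  stopf(inherits(config, "thal_sim_config"), "config must be a thal_sim_config")
  if (!is.null(seed)) set.seed(seed)

  genos <- rep(spec$genotype, spec$count)
  n <- length(genos)
  f <- config$fetal_fraction
  if (f > 0 && is.null(paternal_freqs)) {
    paternal_freqs <- spec_allele_freqs(spec)
  }
  ids <- sprintf("S%05d", seq_len(n))
  profiles <- vector("list", n)
  labels <- character(n)
  for (i in seq_len(n)) {
    g <- parse_genotype(genos[i])
    labels[i] <- g$label
    cf <- copy_fraction_track(g, config$bins, config$geometry)
    if (f > 0) {
      mat_hap <- sample(c(g$hap1, g$hap2), 1)
      pat_hap <- sample(names(paternal_freqs), 1, prob = paternal_freqs)
      fet <- genotype(mat_hap, pat_hap)
      cf_fet <- copy_fraction_track(fet, config$bins, config$geometry)
      cf <- (1 - f) * cf + f * cf_fet
    }
    profiles[[i]] <- simulate_counts(g, config, sample_id = ids[i],
                                     copy_fraction = cf, seed = NULL)
  }
  list(raw = profiles_to_table(profiles, "raw"),
       tpm = profiles_to_table(profiles, "tpm"),
       labels = tibble(sample_id = ids, genotype = genos, label = labels))
}

# haplotype frequencies implied by a cohort spec's genotype mix
spec_allele_freqs <- function(spec) {
  haps <- unlist(lapply(seq_len(nrow(spec)), function(i) {
    g <- parse_genotype(spec$genotype[i])
    rep(c(g$hap1, g$hap2), spec$count[i])
  }))
  table(haps) / length(haps)
}
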