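# Small shared fixtures; everything is built in code.

# toy geometry on a 1000 bp region: "SEA"-like deletion spans [200, 800),
# "3.7" is [400, 500), "4.2" is [300, 400), THAI/FIL contain SEA
toy_geometry <- function() {
  hba_geometry(
    region = list(chrom = "chrT", start = 0L, end = 1000L),
    deletions = tibble::tibble(
      allele = c("3.7", "4.2", "SEA", "THAI", "FIL"),
      start  = c(400L, 300L, 200L, 100L, 50L),
      end    = c(500L, 400L, 800L, 900L, 950L)
    )
  )
}

toy_bins <- function(n = 10) make_uniform_bins(toy_geometry()$region, n)

toy_sim_config <- function(...) {
  simulator_config(bins = toy_bins(), geometry = toy_geometry(),
                   mean_depth = 10000, ...)
}

# brute-force per-fragment overlap scan: independent oracle for
# count_fragments (largest overlap, leftmost tie-break)
oracle_count <- function(fragments, bins) {
  counts <- integer(nrow(bins))
  for (i in seq_len(nrow(fragments))) {
    if (fragments$chrom[i] != bins$chrom[1]) next
    ov <- pmin(fragments$end[i], bins$end) - pmax(fragments$start[i], bins$start)
    ov[ov < 0] <- 0
    if (max(ov) == 0) next
    j <- which(ov == max(ov))[1]
    counts[j] <- counts[j] + 1L
  }
  counts
}

# brute-force per-sample one-vs-rest tally: independent oracle for
# class_metrics
oracle_metrics <- function(truth, predicted, labels) {
  res <- lapply(labels, function(k) {
    tp <- sum(truth == k & predicted == k)
    fn <- sum(truth == k & predicted != k)
    fp <- sum(truth != k & predicted == k)
    tn <- sum(truth != k & predicted != k)
    r <- function(a, b) if (b == 0) NA_real_ else a / b
    sens <- r(tp, tp + fn); ppv <- r(tp, tp + fp)
    f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_
          else 2 * sens * ppv / (sens + ppv)
    tibble::tibble(class = k, sensitivity = sens, specificity = r(tn, tn + fp),
                   ppv = ppv, npv = r(tn, tn + fn), f1 = f1)
  })
  dplyr::bind_rows(res)
}
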