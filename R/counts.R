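#' Count cfDNA fragments per bin
#'
#' Tallies aligned fragment spans into the bin set. Each fragment that
#' overlaps at least one bin increments exactly one bin — the bin with the
#' largest overlap, ties broken toward the leftmost bin — emulating unique
#' feature assignment in featureCounts-style counters, so the total count is
#' conserved and adjacent bins never double-count a fragment. Fragments on
#' other chromosomes or overlapping no bin are skipped (a message reports
#' how many).
#'
#' @param fragments Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open fragment spans; a properly paired read pair collapsed
#'   to its outer span).
#' @param bins A `thal_bins` tibble.
#' @param multi If `TRUE`, count a fragment into every bin it overlaps
#'   instead of uniquely assigning it (off by default; totals are then not
#'   conserved).
#' @return Integer vector of per-bin counts, length `nrow(bins)`.
#' @examples
#' bins <- make_uniform_bins(list(chrom = "chr1", start = 0, end = 30), 3)
#' count_fragments(tibble::tibble(chrom = "chr1", start = 8, end = 25), bins)
#' @export
count_fragments <- function(fragments, bins, multi = FALSE) {
  bins <- validate_bins(bins)
  stopf(is.data.frame(fragments) &&
          all(c("chrom", "start", "end") %in% names(fragments)),
        "fragments must be a data frame with columns chrom, start, end")
  nb <- nrow(bins)
  if (nrow(fragments) == 0) return(integer(nb))
  validate_interval(fragments$start, fragments$end)

  same <- fragments$chrom == bins$chrom[1]
  if (any(!same)) {
    inform(sprintf("skipping %d fragment(s) on other chromosomes", sum(!same)))
    fragments <- fragments[same, , drop = FALSE]
  }
  if (nrow(fragments) == 0) return(integer(nb))

  # IRanges is 1-based closed; shift half-open starts by +1
  fr <- IRanges::IRanges(fragments$start + 1L, fragments$end)
  br <- IRanges::IRanges(bins$start + 1L, bins$end)
  hits <- IRanges::findOverlaps(fr, br)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (length(q) == 0) {
    inform(sprintf("%d fragment(s) overlap no bin", nrow(fragments)))
    return(integer(nb))
  }
  w <- IRanges::width(IRanges::pintersect(fr[q], br[s]))
  if (isTRUE(multi)) return(tabulate(s, nbins = nb))

  # per fragment keep the largest overlap; ties -> leftmost (smallest bin idx)
  ord <- order(q, -w, s)
  keep <- !duplicated(q[ord])
  assigned <- s[ord][keep]
  dropped <- nrow(fragments) - length(assigned)
  if (dropped > 0) inform(sprintf("%d fragment(s) overlap no bin", dropped))
  tabulate(assigned, nbins = nb)
}

#' TPM-normalize a per-bin count vector
#'
#' Transcripts-per-million-style normalization of bin counts: the raw count
#' of each bin is first divided by bin length in kb (`A_i = raw_i * 1e3 /
#' length_i`), then rescaled so the vector sums to 1e6
#' (`TPM_i = A_i / sum(A) * 1e6`). This removes both bin-length and
#' library-depth effects, making profiles comparable across samples.
#'
#' @param raw Non-negative integer vector of per-bin counts.
#' @param lengths Per-bin lengths in bp, all positive.
#' @return Numeric vector summing to 1e6.
#' @examples
#' tpm_normalize(c(10, 20), c(100, 400))
#' @export
tpm_normalize <- function(raw, lengths) {
  stopf(length(raw) == length(lengths),
        "raw (%d) and lengths (%d) differ in length", length(raw), length(lengths))
  stopf(all(lengths > 0), "zero-length bin")
  stopf(all(raw >= 0), "negative counts")
  stopf(sum(raw) > 0, "no coverage: all-zero count vector")
  a <- raw * 1e3 / lengths
  a / sum(a) * 1e6
}

#' Build a per-sample count profile
#'
#' Bundles a sample's raw per-bin counts with their TPM normalization.
#'
#' @param sample_id Sample identifier.
#' @param raw Integer vector of per-bin counts.
#' @param bins A `thal_bins` tibble.
#' @return A list of class `thal_profile`: `sample_id`, `raw`, `tpm`,
#'   `total_fragments`.
#' @export
count_profile <- function(sample_id, raw, bins) {
  bins <- validate_bins(bins)
  stopf(length(raw) == nrow(bins),
        "raw length (%d) does not match number of bins (%d)",
        length(raw), nrow(bins))
  structure(list(sample_id = sample_id,
                 raw = as.integer(raw),
                 tpm = tpm_normalize(raw, bin_lengths(bins)),
                 total_fragments = as.integer(sum(raw))),
            class = "thal_profile")
}

#' @export
print.thal_profile <- function(x, ...) {
  cat(sprintf("<count profile %s: %d bins, %d fragments>\n",
              x$sample_id, length(x$raw), x$total_fragments))
  invisible(x)
}

bin_colnames <- function(n) sprintf("bin_%03d", seq_len(n))

#' Assemble profiles into a wide count table
#'
#' @param profiles A list of `thal_profile` objects.
#' @param values `"raw"` or `"tpm"`.
#' @return A tibble with `sample_id` and one column per bin (`bin_001`, ...);
#'   attribute `normalization` records which values it holds.
#' @export
profiles_to_table <- function(profiles, values = c("tpm", "raw")) {
  values <- match.arg(values)
  stopf(length(profiles) > 0, "no profiles")
  mat <- do.call(rbind, lapply(profiles, `[[`, values))
  colnames(mat) <- bin_colnames(ncol(mat))
  out <- dplyr::bind_cols(
    tibble(sample_id = vapply(profiles, `[[`, "", "sample_id")),
    as_tibble(mat)
  )
  attr(out, "normalization") <- values
  out
}

#' Read / write a count table as TSV
#'
#' The table has a `sample_id` column followed by one column per bin. A
#' leading comment line `# normalization: raw|tpm` flags which values the
#' file holds and round-trips through `read_count_table()`.
#'
#' @param path File path.
#' @param bins Optional `thal_bins`; if given, the file's bin-column count is
#'   checked against it.
#' @return `read_count_table()` returns the tibble with attribute
#'   `normalization`.
#' @export
read_count_table <- function(path, bins = NULL) {
  first <- readLines(path, n = 1)
  norm <- if (grepl("^# normalization:", first)) {
    trimws(sub("^# normalization:", "", first))
  } else "unknown"
  df <- readr::read_tsv(path, comment = "#", progress = FALSE,
                        show_col_types = FALSE)
  stopf("sample_id" %in% names(df), "count table lacks a sample_id column")
  nbin_file <- ncol(df) - 1
  if (!is.null(bins)) {
    bins <- validate_bins(bins)
    stopf(nbin_file == nrow(bins),
          "count table has %d bin columns but bin set has %d bins",
          nbin_file, nrow(bins))
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  stopf(length(dup) == 0, "duplicated sample_id(s): %s",
        paste(unique(dup), collapse = ", "))
  attr(df, "normalization") <- norm
  df
}

#' @param table A count table tibble (see [profiles_to_table()]).
#' @rdname read_count_table
#' @export
write_count_table <- function(table, path) {
  norm <- attr(table, "normalization") %||% "unknown"
  writeLines(sprintf("# normalization: %s", norm), path)
  readr::write_tsv(table, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' TPM-normalize every row of a raw count table
#'
#' @param table Wide raw count table (`sample_id` + bin columns).
#' @param bins The `thal_bins` the columns correspond to.
#' @return The table with each row TPM-normalized; attribute
#'   `normalization = "tpm"`.
#' @export
tpm_table <- function(table, bins) {
  bins <- validate_bins(bins)
  feat <- setdiff(names(table), "sample_id")
  stopf(length(feat) == nrow(bins),
        "count table has %d bin columns but bin set has %d bins",
        length(feat), nrow(bins))
  lens <- bin_lengths(bins)
  mat <- t(apply(as.matrix(table[, feat]), 1, tpm_normalize, lengths = lens))
  out <- dplyr::bind_cols(table["sample_id"], as_tibble(mat))
  attr(out, "normalization") <- "tpm"
  out
}

#' Extract fragment spans from a BED-like TSV
#'
#' @param path TSV/BED path with columns chrom, start, end (no header).
#' @return Tibble of fragments.
#' @export
read_fragments_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                        col_types = "cii", progress = FALSE, comment = "#")
  stopf(nrow(df) > 0, "no fragments in %s", path)
  validate_interval(df$start, df$end)
  df
}
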