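#' The default alpha-globin locus geometry
#'
#' Returns the genomic model of the HBA cluster used throughout the package:
#' the ~21 kb target region tiled by the coverage bins, and the approximate
#' breakpoint intervals of the five common deletion alleles. Coordinates are
#' GRCh38 chr16, 0-based half-open (BED convention), and are deliberately
#' configuration rather than constants: published breakpoints for these
#' deletions are approximate, and every downstream computation depends only
#' on the geometry passed to it. Override any interval via the arguments or
#' a YAML config file ([read_geometry_config()]).
#'
#' Alleles and their functional alpha-gene copies per haplotype:
#' * `aa` — intact haplotype (HBA2 + HBA1), 2 functional genes.
#' * `3.7`, `4.2` — rightward/leftward single-gene deletions (alpha+), 1 gene.
#' * `SEA`, `THAI`, `FIL` — large cis deletions removing both genes (alpha0),
#'   0 genes. THAI and FIL contain the SEA interval.
#'
#' @param region A one-row data frame or list with `chrom`, `start`, `end`
#'   giving the targeted region.
#' @param deletions A data frame with columns `allele`, `start`, `end` giving
#'   each deletion allele's removed interval (same chromosome as `region`).
#' @return A list of class `thal_geometry` with elements `region` (tibble) and
#'   `alleles` (tibble with columns `allele`, `n_functional_genes`, `start`,
#'   `end`; `NA` interval for the intact allele).
#' @examples
#' geom <- hba_geometry()
#' geom$alleles
#' @export
hba_geometry <- function(region = NULL, deletions = NULL) {
  region <- region %||%
    list(chrom = "chr16", start = 164000L, end = 185000L)
  deletions <- deletions %||% tibble(
    allele = c("3.7", "4.2", "SEA", "THAI", "FIL"),
    start  = c(172900L, 168700L, 165400L, 163000L, 155000L),
    end    = c(176600L, 172900L, 184700L, 196500L, 186500L)
  )
  region <- as_tibble(region[c("chrom", "start", "end")])
  stopf(nrow(region) == 1, "geometry region must be a single interval")
  validate_interval(region$start, region$end)
  deletions <- as_tibble(deletions)
  stopf(all(c("allele", "start", "end") %in% names(deletions)),
        "deletions must have columns allele, start, end")
  validate_interval(deletions$start, deletions$end)
  alleles <- bind_rows(
    tibble(allele = "aa", start = NA_integer_, end = NA_integer_),
    deletions[, c("allele", "start", "end")]
  )
  alleles$n_functional_genes <- functional_genes(alleles$allele)
  structure(
    list(region = region,
         alleles = alleles[, c("allele", "n_functional_genes", "start", "end")]),
    class = "thal_geometry"
  )
}

validate_interval <- function(start, end) {
  stopf(all(start >= 0), "interval start must be >= 0")
  stopf(all(end > start), "interval end must be > start")
  invisible(TRUE)
}

#' Functional alpha-gene copies carried by a haplotype allele
#'
#' @param allele Character vector of allele names among
#'   `"aa"`, `"3.7"`, `"4.2"`, `"SEA"`, `"THAI"`, `"FIL"`.
#' @return Integer vector: 2 for the intact haplotype, 1 for the alpha+
#'   single-gene deletions, 0 for the alpha0 double-gene deletions.
#' @export
functional_genes <- function(allele) {
  lut <- c(aa = 2L, "3.7" = 1L, "4.2" = 1L, SEA = 0L, THAI = 0L, FIL = 0L)
  unknown <- setdiff(unique(allele), names(lut))
  stopf(length(unknown) == 0, "unknown allele(s): %s",
        paste(unknown, collapse = ", "))
  unname(lut[allele])
}

#' Construct a genotype from two haplotype alleles
#'
#' A genotype is an unordered pair of haplotype alleles. Its canonical class
#' label is one of the five groups the classifier predicts: `aa_aa` (both
#' haplotypes intact), `aa_SEA`, `aa_3.7`, `aa_4.2`, or `Others` (any
#' genotype outside the four common ones, e.g. compound heterozygotes or
#' `aa/THAI`).
#'
#' @param hap1,hap2 Allele names (see [functional_genes()]).
#' @return A list of class `thal_genotype` with `hap1`, `hap2`, `label`.
#' @examples
#' genotype("aa", "SEA")$label   # "aa_SEA"
#' genotype("3.7", "SEA")$label  # "Others"
#' @export
genotype <- function(hap1, hap2) {
  functional_genes(c(hap1, hap2)) # validates names
  # canonical order independent of locale collation
  haps <- sort(c(hap1, hap2), method = "radix")
  structure(list(hap1 = haps[1], hap2 = haps[2], label = genotype_label(haps)),
            class = "thal_genotype")
}

genotype_label <- function(haps) {
  if (all(haps == "aa")) return("aa_aa")
  if (sum(haps == "aa") == 1) {
    other <- haps[haps != "aa"]
    if (other %in% c("SEA", "3.7", "4.2")) return(paste0("aa_", other))
  }
  "Others"
}

#' Parse a genotype string such as "aa/SEA"
#'
#' @param x Character vector of genotype strings, two allele names separated
#'   by "/".
#' @return For length-1 input, a `thal_genotype`; otherwise a list of them.
#' @export
parse_genotype <- function(x) {
  parts <- strsplit(x, "/", fixed = TRUE)
  bad <- lengths(parts) != 2
  stopf(!any(bad), "malformed genotype string(s): %s",
        paste(x[bad], collapse = ", "))
  out <- lapply(parts, function(p) genotype(p[1], p[2]))
  if (length(out) == 1) out[[1]] else out
}

#' @export
print.thal_genotype <- function(x, ...) {
  cat(sprintf("<genotype %s/%s  label: %s  functional genes: %d>\n",
              x$hap1, x$hap2, x$label,
              sum(functional_genes(c(x$hap1, x$hap2)))))
  invisible(x)
}

#' Tile a region with equal-width bins
#'
#' Splits `region` into `n_bins` contiguous bins whose widths differ by at
#' most 1 bp (the remainder of the integer division is spread over the
#' leading bins). The default locus model uses 66 bins over the ~21 kb HBA
#' target, the feature space of the classifier.
#'
#' @param region One-row data frame or list with `chrom`, `start`, `end`.
#' @param n_bins Positive integer number of bins; the region must be at least
#'   `n_bins` bp long.
#' @return A tibble of class `thal_bins` with columns `chrom`, `start`, `end`
#'   (0-based half-open), sorted and non-overlapping.
#' @examples
#' make_uniform_bins(list(chrom = "chr16", start = 0, end = 660), 66)
#' @export
make_uniform_bins <- function(region, n_bins = 66) {
  region <- as_tibble(as.list(region)[c("chrom", "start", "end")])
  validate_interval(region$start, region$end)
  stopf(is_count(n_bins) && n_bins >= 1, "n_bins must be a positive integer")
  len <- region$end - region$start
  stopf(len >= n_bins,
        "region length (%d bp) shorter than n_bins (%d)", len, n_bins)
  base <- len %/% n_bins
  extra <- len %% n_bins
  widths <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  ends <- region$start + cumsum(widths)
  new_bins(tibble(chrom = region$chrom,
                  start = c(region$start, head(ends, -1)),
                  end = ends))
}

#' The default bin set: 66 bins over the HBA target region
#'
#' @param geometry A `thal_geometry`, see [hba_geometry()].
#' @param n_bins Number of bins (default 66).
#' @return A `thal_bins` tibble.
#' @export
default_bins <- function(geometry = hba_geometry(), n_bins = 66) {
  make_uniform_bins(geometry$region, n_bins)
}

new_bins <- function(df) {
  df <- as_tibble(df)
  class(df) <- c("thal_bins", class(df))
  df
}

#' Validate a bin set
#'
#' Checks that bins lie on one chromosome, are sorted by start, and are
#' pairwise non-overlapping. Called by every consumer of a bin set.
#'
#' @param bins A data frame with columns `chrom`, `start`, `end`.
#' @return The validated bins as a `thal_bins` tibble, invisibly usable.
#' @export
validate_bins <- function(bins) {
  stopf(is.data.frame(bins) && all(c("chrom", "start", "end") %in% names(bins)),
        "bins must be a data frame with columns chrom, start, end")
  stopf(nrow(bins) > 0, "no bins")
  validate_interval(bins$start, bins$end)
  stopf(length(unique(bins$chrom)) == 1, "bins must be on one chromosome")
  unsorted <- which(diff(bins$start) < 0)
  stopf(length(unsorted) == 0, "bins unsorted at line(s): %s",
        paste(unsorted + 1, collapse = ", "))
  over <- which(bins$start[-1] < bins$end[-nrow(bins)])
  stopf(length(over) == 0, "overlapping bins at line(s): %s",
        paste(over + 1, collapse = ", "))
  if (!inherits(bins, "thal_bins")) bins <- new_bins(bins) else bins
}

bin_lengths <- function(bins) bins$end - bins$start

#' Per-bin copy fraction of a genotype's coverage signature
#'
#' For each bin, the expected fraction of diploid coverage retained under the
#' genotype's deletions: positions inside a haplotype's deleted interval
#' contribute 0 for that haplotype, 1 otherwise, averaged over the two
#' haplotypes and length-weighted across the bin. An intact genotype gives
#' 1.0 everywhere; a heterozygous alpha0 carrier gives 0.5 across bins fully
#' inside the deletion; compound genotypes stack (0.0 where both haplotypes
#' are deleted). This is the read-depth signature the classifier learns.
#'
#' @param genotype A `thal_genotype` (see [genotype()]).
#' @param bins A `thal_bins` tibble.
#' @param geometry A `thal_geometry` supplying deletion intervals.
#' @return Numeric vector in \[0, 1\], one value per bin.
#' @examples
#' bins <- default_bins()
#' range(copy_fraction_track(genotype("aa", "SEA"), bins))
#' @export
copy_fraction_track <- function(genotype, bins, geometry = hba_geometry()) {
  stopf(inherits(genotype, "thal_genotype"), "genotype must be a thal_genotype")
  bins <- validate_bins(bins)
  stopf(unique(bins$chrom) == geometry$region$chrom,
        "bins and geometry are on different chromosomes")
  lens <- bin_lengths(bins)
  intact <- function(hap) {
    if (hap == "aa") return(rep(1, nrow(bins)))
    del <- geometry$alleles[geometry$alleles$allele == hap, ]
    stopf(nrow(del) == 1 && !is.na(del$start),
          "geometry has no deletion interval for allele %s", hap)
    ov <- pmax(0, pmin(bins$end, del$end) - pmax(bins$start, del$start))
    1 - ov / lens
  }
  (intact(genotype$hap1) + intact(genotype$hap2)) / 2
}

#' Read / write bins as BED3
#'
#' BED records are 0-based half-open, matching the package's coordinate
#' convention, so no shifting occurs. Reading validates that records are
#' sorted and non-overlapping.
#'
#' @param path File path.
#' @return `read_bins_bed()` returns a `thal_bins` tibble.
#' @export
read_bins_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                        col_types = "cii", progress = FALSE,
                        comment = "#")
  stopf(nrow(df) > 0, "no bins in %s", path)
  validate_bins(df)
}

#' @param bins A `thal_bins` tibble.
#' @rdname read_bins_bed
#' @export
write_bins_bed <- function(bins, path) {
  bins <- validate_bins(bins)
  readr::write_tsv(bins[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a locus geometry from a YAML config file
#'
#' The file holds `region:` (chrom/start/end) and `deletions:` (a map of
#' allele name to start/end), letting users supply their own breakpoint
#' model without touching code.
#'
#' @param path YAML file path.
#' @return A `thal_geometry`.
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopf(!is.null(cfg$region), "config %s lacks a 'region' block", path)
  dels <- NULL
  if (!is.null(cfg$deletions)) {
    dels <- purrr::imap_dfr(cfg$deletions, function(iv, nm) {
      tibble(allele = nm, start = as.integer(iv$start), end = as.integer(iv$end))
    })
  }
  hba_geometry(region = cfg$region, deletions = dels)
}
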