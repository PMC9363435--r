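#' Genotype tallies from the 68,885-woman screening cohort
#'
#' The gap-PCR-confirmed alpha-globin genotype counts observed in the
#' Vietnamese pregnant-women screening cohort: 63,541 intact, four common
#' carrier genotypes, and four rare genotypes. These tallies drive the
#' default Hardy-Weinberg burden estimates and the default simulated-cohort
#' composition.
#'
#' @return Tibble with columns `genotype` (e.g. `"aa/SEA"`), `count`, and
#'   `phenotype`.
#' @export
vietnam_cohort_counts <- function() {
  tab <- tibble(
    genotype = c("aa/aa", "aa/SEA", "aa/3.7", "aa/4.2",
                 "3.7/SEA", "aa/THAI", "4.2/SEA", "3.7/4.2"),
    count = c(63541L, 2801L, 2021L, 452L, 49L, 8L, 7L, 6L)
  )
  tab$phenotype <- vapply(tab$genotype, phenotype_from_genotype, "")
  tab
}

#' Phenotype implied by a genotype's functional alpha-gene count
#'
#' Phenotype severity tracks the total number of functional alpha-globin
#' genes across the two haplotypes: 4 = normal, 3 = silent carrier,
#' 2 = alpha-thalassemia trait, 1 = Hb H disease, 0 = Hb Bart's hydrops
#' fetalis.
#'
#' @param genotype A genotype string (`"3.7/SEA"`) or `thal_genotype`.
#' @return One of `"normal"`, `"silent_carrier"`, `"trait"`, `"hbh"`,
#'   `"barts"`.
#' @examples
#' phenotype_from_genotype("aa/SEA")   # trait
#' phenotype_from_genotype("3.7/SEA")  # hbh
#' @export
phenotype_from_genotype <- function(genotype) {
  if (is.character(genotype)) genotype <- parse_genotype(genotype)
  n <- sum(functional_genes(c(genotype$hap1, genotype$hap2)))
  c("barts", "hbh", "trait", "silent_carrier", "normal")[n + 1]
}

allele_class <- function(allele) {
  n <- functional_genes(allele)
  c("alpha_zero", "alpha_plus", "normal")[n + 1]
}

#' Haplotype allele frequencies from a genotype count table
#'
#' Each individual contributes two haplotypes; the frequency of an allele is
#' its haplotype count over 2N. Alleles are also grouped into the three
#' functional classes used by the Punnett expectation: `normal` (aa),
#' `alpha_plus` (3.7, 4.2) and `alpha_zero` (SEA, THAI, FIL).
#'
#' @param table A data frame with columns `genotype` (strings like
#'   `"aa/SEA"`) and `count`, e.g. [vietnam_cohort_counts()].
#' @return Tibble of class `thal_allele_freq` with columns `allele`, `class`,
#'   `count`, `frequency`; attributes `n_individuals` and `n_haplotypes`.
#' @examples
#' allele_frequencies(vietnam_cohort_counts())
#' @export
allele_frequencies <- function(table) {
  stopf(is.data.frame(table) && all(c("genotype", "count") %in% names(table)),
        "table must have columns genotype and count")
  stopf(all(table$count >= 0), "counts must be non-negative")
  n <- sum(table$count)
  stopf(n > 0, "empty genotype table")
  haps <- lapply(table$genotype, function(g) {
    gt <- parse_genotype(g)
    c(gt$hap1, gt$hap2)
  })
  tal <- tibble(allele = unlist(haps),
                count = rep(table$count, each = 2)) |>
    group_by(.data$allele) |>
    summarise(count = sum(.data$count), .groups = "drop")
  tal$class <- vapply(tal$allele, allele_class, "")
  tal$frequency <- tal$count / (2 * n)
  tal <- tal[order(match(tal$class, c("normal", "alpha_plus", "alpha_zero")),
                   tal$allele), c("allele", "class", "count", "frequency")]
  structure(tal, class = c("thal_allele_freq", class(tibble())),
            n_individuals = n, n_haplotypes = 2L * n)
}

#' Pooled allele-class frequencies
#'
#' @param af A `thal_allele_freq` from [allele_frequencies()].
#' @return Named numeric vector `p_norm`, `p_plus`, `p_zero` summing to 1.
#' @export
allele_class_frequencies <- function(af) {
  stopf(inherits(af, "thal_allele_freq"),
        "af must come from allele_frequencies()")
  p <- vapply(c("normal", "alpha_plus", "alpha_zero"),
              function(cl) sum(af$frequency[af$class == cl]), numeric(1))
  setNames(p, c("p_norm", "p_plus", "p_zero"))
}

#' Hardy-Weinberg expected phenotype frequencies (Punnett expectation)
#'
#' Under random mating, offspring draw two haplotypes independently from the
#' pooled allele classes, so the phenotype frequencies are:
#' \deqn{barts = p_0^2, \quad hbh = 2 p_0 p_+, \quad
#'       trait = 2 p_n p_0 + p_+^2, \quad silent = 2 p_n p_+, \quad
#'       normal = p_n^2}
#' which sum to \eqn{(p_n + p_+ + p_0)^2 = 1} identically. alpha0 alleles
#' (SEA, THAI, FIL) are pooled because any two of them give Hb Bart's;
#' likewise 3.7 and 4.2 pool into alpha+.
#'
#' @param af A `thal_allele_freq`, or a named vector with `p_norm`, `p_plus`,
#'   `p_zero`.
#' @return Tibble of class `thal_phenotype_freq` with columns `phenotype`,
#'   `frequency`, `percent` (percent rounded to 4 decimals for display;
#'   `frequency` keeps full precision).
#' @examples
#' expected_phenotype_frequencies(allele_frequencies(vietnam_cohort_counts()))
#' @export
expected_phenotype_frequencies <- function(af) {
  p <- if (inherits(af, "thal_allele_freq")) allele_class_frequencies(af)
       else af
  stopf(all(c("p_norm", "p_plus", "p_zero") %in% names(p)),
        "af must provide p_norm, p_plus, p_zero")
  pn <- p[["p_norm"]]; pp <- p[["p_plus"]]; p0 <- p[["p_zero"]]
  out <- tibble(
    phenotype = c("normal", "silent_carrier", "trait", "hbh", "barts"),
    frequency = c(pn^2, 2 * pn * pp, 2 * pn * p0 + pp^2, 2 * p0 * pp, p0^2)
  )
  out$percent <- round(out$frequency * 100, 4)
  structure(out, class = c("thal_phenotype_freq", class(tibble())))
}

#' Project expected affected births
#'
#' Multiplies phenotype frequencies by an annual birth count and rounds half
#' away from zero, matching how whole-child projections are reported. Also
#' returns the total over the three carrier/disease phenotypes detectable at
#' birth (Hb H, trait, silent carrier) as attribute `carrier_total`.
#'
#' @param pf A `thal_phenotype_freq` from
#'   [expected_phenotype_frequencies()].
#' @param n_births Number of births (>= 0).
#' @return Tibble with `phenotype`, `frequency`, `expected_births`; attribute
#'   `carrier_total`.
#' @examples
#' pf <- expected_phenotype_frequencies(
#'   allele_frequencies(vietnam_cohort_counts()))
#' project_births(pf, 1394401)
#' @export
project_births <- function(pf, n_births) {
  stopf(inherits(pf, "thal_phenotype_freq"),
        "pf must come from expected_phenotype_frequencies()")
  stopf(is_count(n_births) && n_births >= 0, "n_births must be >= 0")
  out <- tibble(phenotype = pf$phenotype, frequency = pf$frequency,
                expected_births = as.integer(round_half_up(pf$frequency * n_births)))
  carriers <- sum(out$expected_births[out$phenotype %in%
                                        c("hbh", "trait", "silent_carrier")])
  structure(out, carrier_total = carriers)
}

#' Observed cohort prevalence summary
#'
#' Per-genotype and overall deletion-carrier prevalences from a genotype
#' count table, as percentages of all individuals.
#'
#' @param table A genotype count table (see [allele_frequencies()]).
#' @return Tibble with `genotype`, `count`, `percent`; attribute
#'   `carrier_percent` gives the overall non-`aa/aa` fraction and
#'   `rare_percent` the fraction with `Others`-class genotypes.
#' @export
cohort_prevalence <- function(table) {
  n <- sum(table$count)
  stopf(n > 0, "empty genotype table")
  out <- tibble(genotype = table$genotype, count = table$count,
                percent = round(table$count / n * 100, 3))
  labels <- vapply(table$genotype,
                   function(g) parse_genotype(g)$label, "")
  carrier <- sum(table$count[labels != "aa_aa"]) / n * 100
  rare <- sum(table$count[labels == "Others"]) / n * 100
  structure(out, carrier_percent = carrier, rare_percent = rare)
}

#' Read a genotype count table from TSV
#'
#' @param path TSV with header columns `genotype` and `count`.
#' @return Tibble usable by [allele_frequencies()].
#' @export
read_genotype_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopf(all(c("genotype", "count") %in% names(df)),
        "%s must have columns genotype and count", path)
  df
}

#' Full population-burden report
#'
#' Chains tally -> allele frequencies -> HWE phenotype expectation -> birth
#' projection into one report list, convertible to JSON.
#'
#' @param table Genotype count table (default: the packaged cohort tallies).
#' @param n_births Annual births for the projection.
#' @return List with `prevalence`, `allele_frequencies`,
#'   `phenotype_frequencies`, `projection`, `carrier_total`.
#' @export
popgen_report <- function(table = vietnam_cohort_counts(),
                          n_births = 1394401) {
  af <- allele_frequencies(table)
  pf <- expected_phenotype_frequencies(af)
  proj <- project_births(pf, n_births)
  list(prevalence = cohort_prevalence(table),
       allele_frequencies = af,
       phenotype_frequencies = pf,
       projection = proj,
       carrier_total = attr(proj, "carrier_total"))
}
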