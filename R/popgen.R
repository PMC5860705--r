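#' Allele frequencies from biallelic genotype counts
#'
#' Gene-counting estimate for an insertion/deletion marker scored as
#' II / ID / DD genotype classes:
#' `p_I = (2 n_II + n_ID) / (2 N)` with `p_D = 1 - p_I`, where `N` is
#' the number of scored individuals in that row.
#'
#' @param genotypes tibble with columns `n_II`, `n_ID`, `n_DD` (one row
#'   per locus x population, as from [read_genotype_table()]).
#' @return the input with `n_ind`, `p_I` and `p_D` appended.
#' @export
allele_frequencies <- function(genotypes) {
  genotypes <- as_tibble(genotypes)
  n <- genotypes$n_II + genotypes$n_ID + genotypes$n_DD
  if (any(n == 0)) abort("all-zero genotype counts")
  genotypes %>%
    mutate(n_ind = n,
           p_I = (2 * .data$n_II + .data$n_ID) / (2 * n),
           p_D = 1 - .data$p_I)
}

#' Diversity statistics from allele frequencies
#'
#' The four classical marker-informativeness statistics for one locus:
#' gene homozygosity `Ho = sum(p^2)`, expected heterozygosity
#' `He = 1 - Ho`, effective allele number `Ne = 1 / sum(p^2)` (the
#' count of equifrequent alleles giving the same homozygosity), and
#' polymorphism information content
#' `PIC = 1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2`. Defined for any
#' number of alleles; `PIC <= He` and `Ho + He = 1` always hold.
#'
#' @param freqs numeric vector of allele frequencies (non-negative,
#'   summing to 1 within `tol`).
#' @param tol tolerance on the frequency sum (default 1e-9).
#' @return one-row tibble: `k` (allele count), `Ho`, `He`, `Ne`, `PIC`.
#' @export
diversity_stats <- function(freqs, tol = 1e-9) {
  if (any(freqs < 0)) abort("allele frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > tol) abort("allele frequencies must sum to 1")
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  tibble(k = length(freqs), Ho = s2, He = 1 - s2, Ne = 1 / s2,
         PIC = 1 - s2 - (s2^2 - s4))
}

#' Per-locus, per-population diversity from a genotype table
#'
#' Chains [allele_frequencies()] and [diversity_stats()] over every row
#' of a biallelic genotype count table.
#'
#' @param genotypes tibble as for [allele_frequencies()].
#' @return the input with `n_ind`, `p_I`, `p_D`, `Ho`, `He`, `Ne`,
#'   `PIC` appended.
#' @export
locus_diversity <- function(genotypes) {
  freqs <- allele_frequencies(genotypes)
  stats <- purrr::map2_dfr(freqs$p_I, freqs$p_D,
                           function(pi, pd) diversity_stats(c(pi, pd))) %>%
    select(-"k")
  dplyr::bind_cols(freqs, stats)
}

#' Compare genotype class distributions between two populations
#'
#' Tests whether the II/ID/DD genotype distribution differs between two
#' populations. Genotype classes absent from both populations are
#' dropped. The default path is a Pearson chi-squared test on the
#' resulting 2 x c table; when any expected cell count falls below 5
#' the test falls back to Fisher's exact test on the 2 x 2 collapse of
#' DD versus the rest (the comparison of interest for a deletion
#' allele), and the `method` column records which path ran.
#'
#' @param counts_a,counts_b named numeric vectors (or one-row tibbles)
#'   with entries `n_II`, `n_ID`, `n_DD`.
#' @param min_expected expected-count threshold triggering the exact
#'   fallback (default 5).
#' @return one-row tibble: `statistic`, `df`, `p_value`, `method`
#'   (`"chisq"` or `"fisher_dd"`; `statistic`/`df` are `NA` for the
#'   exact path).
#' @export
genotype_freq_test <- function(counts_a, counts_b, min_expected = 5) {
  as_counts <- function(x) {
    if (is.data.frame(x)) x <- unlist(x[1, c("n_II", "n_ID", "n_DD")])
    as.numeric(x[c("n_II", "n_ID", "n_DD")])
  }
  a <- as_counts(counts_a); b <- as_counts(counts_b)
  if (sum(a) == 0 || sum(b) == 0) abort("both populations must be nonempty")
  tab <- rbind(a, b)
  colnames(tab) <- c("II", "ID", "DD")
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2) {
    # a single genotype class left: no distributional difference testable
    return(tibble(statistic = 0, df = 0L, p_value = 1, method = "degenerate"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < min_expected)) {
    dd <- if ("DD" %in% colnames(tab)) tab[, "DD"] else c(0, 0)
    other <- rowSums(tab) - dd
    p <- fisher.test(cbind(dd, other))$p.value
    return(tibble(statistic = NA_real_, df = NA_integer_, p_value = p,
                  method = "fisher_dd"))
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df = df, lower.tail = FALSE),
         method = "chisq")
}
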