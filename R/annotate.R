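# consequence classes in precedence order (highest first)
consequence_classes <- function() {
  c("exonic", "utr", "intronic", "upstream", "downstream", "intergenic")
}

# accept chromosome lengths as a named vector or a tibble(chrom, length)
as_chrom_lengths <- function(chrom_lengths) {
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  }
  setNames(as.numeric(chrom_lengths), normalize_chrom(names(chrom_lengths)))
}

sv_granges <- function(callset) {
  # zero-width insertion breakpoints become 1 bp points for overlap tests
  GenomicRanges::GRanges(
    seqnames = callset$chrom,
    ranges = IRanges::IRanges(start = callset$start + 1L,
                              end = pmax(callset$end, callset$start + 1L))
  )
}

#' Classify SVs against gene models
#'
#' For every population SV, reports its position relative to each gene
#' it touches, with class precedence exonic (CDS overlap) > UTR >
#' intronic within a gene. An SV overlapping no gene but lying within
#' `flank_bp` of one is upstream or downstream of that gene according
#' to the gene's strand; an SV near several genes yields one record per
#' gene. SVs touching nothing are reported once as intergenic. Any
#' single shared base pair counts as overlap; insertions are treated as
#' breakpoint positions. An SV disrupting coding exon or UTR sequence
#' is flagged as loss-of-function (`lof`).
#'
#' @param callset population SV tibble (needs `sv_id`, `chrom`,
#'   `start`, `end`, `sv_type`).
#' @param genes a `gene_set` from [read_gene_models()].
#' @param flank_bp up/downstream window in bp (default 5000, the usual
#'   regulatory-flank default of consequence predictors).
#' @return tibble of consequences: `sv_id`, `gene_id` (`NA` for
#'   intergenic), `class`, `lof`.
#' @export
classify_sv <- function(callset, genes, flank_bp = 5000) {
  callset <- as_tibble(callset)
  if (nrow(callset) == 0) {
    return(tibble(sv_id = character(), gene_id = character(),
                  class = character(), lof = logical()))
  }
  gr_sv <- sv_granges(callset)
  g <- genes$genes
  gr_gene <- GenomicRanges::GRanges(g$chrom,
                                    IRanges::IRanges(g$start + 1L, g$end))
  ft <- genes$features
  pair_key <- function(hits, feat_gene) {
    paste(S4Vectors::queryHits(hits),
          feat_gene[S4Vectors::subjectHits(hits)])
  }
  feat_keys <- function(types) {
    f <- ft[ft$feature_type %in% types, , drop = FALSE]
    if (nrow(f) == 0) return(character())
    gr_f <- GenomicRanges::GRanges(f$chrom,
                                   IRanges::IRanges(f$start + 1L, f$end))
    unique(pair_key(suppressWarnings(
      GenomicRanges::findOverlaps(gr_sv, gr_f)), f$gene_id))
  }
  cds_keys <- feat_keys("CDS")
  utr_keys <- feat_keys(c("five_prime_UTR", "three_prime_UTR"))

  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_sv, gr_gene))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  genic <- tibble(
    sv_id = callset$sv_id[qi],
    gene_id = g$gene_id[si],
    key = paste(qi, g$gene_id[si])
  ) %>%
    mutate(class = case_when(.data$key %in% cds_keys ~ "exonic",
                             .data$key %in% utr_keys ~ "utr",
                             TRUE ~ "intronic")) %>%
    select(-"key")

  no_gene <- setdiff(seq_len(nrow(callset)), unique(qi))
  flanked <- tibble(sv_id = character(), gene_id = character(),
                    class = character())
  if (length(no_gene) > 0 && flank_bp > 0) {
    gr_ext <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(pmax(1L, g$start + 1L - as.integer(flank_bp)),
                                g$end + as.integer(flank_bp)))
    ov2 <- suppressWarnings(GenomicRanges::findOverlaps(gr_sv[no_gene], gr_ext))
    q2 <- no_gene[S4Vectors::queryHits(ov2)]
    s2 <- S4Vectors::subjectHits(ov2)
    if (length(q2) > 0) {
      before <- callset$end[q2] <= g$start[s2]  # SV entirely 5' of gene span
      plus <- g$strand[s2] != "-"
      flanked <- tibble(
        sv_id = callset$sv_id[q2],
        gene_id = g$gene_id[s2],
        class = ifelse(before == plus, "upstream", "downstream")
      )
    }
  }
  seen <- unique(c(genic$sv_id, flanked$sv_id))
  intergenic <- tibble(sv_id = setdiff(callset$sv_id, seen),
                       gene_id = NA_character_, class = "intergenic")
  bind_rows(genic, flanked, intergenic) %>%
    mutate(lof = .data$class %in% c("exonic", "utr"),
           class = factor(.data$class, levels = consequence_classes())) %>%
    arrange(match(.data$sv_id, callset$sv_id), .data$class) %>%
    mutate(class = as.character(.data$class))
}

#' Per-class consequence summary
#'
#' Each SV is counted once, under its highest-precedence consequence
#' (exonic > UTR > intronic > upstream > downstream > intergenic), so
#' the class fractions partition the call set and sum to 1.
#'
#' @param consequences tibble from [classify_sv()].
#' @param callset the classified call set (provides the denominator and
#'   catches SVs missing from the classification).
#' @return tibble with `class`, `n`, `fraction`.
#' @export
consequence_summary <- function(consequences, callset) {
  n_sv <- nrow(callset)
  top <- consequences %>%
    mutate(rank = match(.data$class, consequence_classes())) %>%
    group_by(.data$sv_id) %>%
    summarise(class = consequence_classes()[min(.data$rank)], .groups = "drop")
  if (nrow(top) != n_sv) abort("classification does not cover the call set")
  top %>%
    count(class = factor(.data$class, levels = consequence_classes()),
          .drop = FALSE, name = "n") %>%
    mutate(class = as.character(.data$class), fraction = .data$n / n_sv)
}

#' Gene-level SV counts
#'
#' One row per annotated gene with the number of distinct SVs touching
#' it (overlapping or within the flank), its transcript count and its
#' conserved-gene flag. Genes untouched by any SV are included with a
#' zero count — the depletion test needs them.
#'
#' @param consequences tibble from [classify_sv()].
#' @param genes the `gene_set` used for classification.
#' @return tibble with `gene_id`, `symbol`, `sv_count`,
#'   `n_transcripts`, `conserved`.
#' @export
gene_sv_table <- function(consequences, genes) {
  counts <- consequences %>%
    filter(!is.na(.data$gene_id)) %>%
    distinct(.data$gene_id, .data$sv_id) %>%
    count(.data$gene_id, name = "sv_count")
  genes$genes %>%
    select("gene_id", "symbol", "n_transcripts", "conserved") %>%
    left_join(counts, by = "gene_id") %>%
    mutate(sv_count = ifelse(is.na(.data$sv_count), 0L, .data$sv_count)) %>%
    select("gene_id", "symbol", "sv_count", "n_transcripts", "conserved")
}

#' Chi-squared test for SV depletion in conserved genes
#'
#' Pearson chi-squared test, without continuity correction, on the 2x2
#' table crossing gene conservation status (conserved vs other) with SV
#' status (contains an SV vs not). The p-value comes from the
#' chi-squared distribution with one degree of freedom. Used to ask
#' whether highly conserved genes harbour fewer SVs than the rest of
#' the annotation.
#'
#' @param n_conserved_with_sv conserved genes containing at least one SV.
#' @param n_conserved_total conserved genes in the annotation.
#' @param n_genes_with_sv all genes containing at least one SV.
#' @param n_genes_total all annotated genes.
#' @return object of class `sv_chi2`: observed and expected tables,
#'   `statistic`, `df` and `p_value`.
#' @export
conserved_gene_test <- function(n_conserved_with_sv, n_conserved_total,
                                n_genes_with_sv, n_genes_total) {
  if (n_conserved_with_sv > n_conserved_total ||
      n_genes_with_sv > n_genes_total ||
      n_conserved_total > n_genes_total) {
    abort("inconsistent gene counts")
  }
  observed <- matrix(
    c(n_conserved_with_sv, n_conserved_total - n_conserved_with_sv,
      n_genes_with_sv - n_conserved_with_sv,
      (n_genes_total - n_conserved_total) -
        (n_genes_with_sv - n_conserved_with_sv)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("conserved", "other"), c("with_sv", "without_sv")))
  chi2_2x2(observed)
}

# Pearson chi-square on a 2x2 table, no continuity correction
chi2_2x2 <- function(observed) {
  if (any(observed < 0)) abort("negative cell count")
  expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  if (any(expected == 0)) abort("degenerate table: expected cell count 0")
  stat <- sum((observed - expected)^2 / expected)
  structure(list(observed = observed, expected = expected,
                 statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "sv_chi2")
}

#' @export
print.sv_chi2 <- function(x, ...) {
  cat(sprintf("<sv_chi2> X-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$observed)
  invisible(x)
}

#' @describeIn conserved_gene_test one row per table cell.
#' @param x an `sv_chi2` object.
#' @param ... unused.
#' @method tidy sv_chi2
#' @export
tidy.sv_chi2 <- function(x, ...) {
  tibble(row = rep(rownames(x$observed), each = ncol(x$observed)),
         column = rep(colnames(x$observed), nrow(x$observed)),
         observed = as.vector(t(x$observed)),
         expected = as.vector(t(x$expected)))
}

#' @describeIn conserved_gene_test one-row test summary.
#' @method glance sv_chi2
#' @export
glance.sv_chi2 <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Spearman correlation between SV count and transcript count
#'
#' Rank correlation (average ranks for ties) between the number of SVs
#' a gene carries and its number of annotated transcripts, with a
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom. Genes enter as given; filter the table first to restrict
#' to, say, SV-bearing genes.
#'
#' @param gene_table tibble from [gene_sv_table()] (needs `sv_count`
#'   and `n_transcripts`).
#' @return one-row tibble: `rho`, `p_value`, `n`, `status` (`"ok"`, or
#'   `"undefined"` when either variable has zero variance, in which
#'   case `rho` and `p_value` are `NA`).
#' @export
transcript_correlation <- function(gene_table) {
  x <- gene_table$sv_count
  y <- gene_table$n_transcripts
  n <- length(x)
  if (n < 3) abort("need at least three genes")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n,
                  status = "undefined"))
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  tibble(rho = rho, p_value = p, n = n, status = "ok")
}

#' Sliding-window SV density hotspot scan
#'
#' Tiles every chromosome with fixed-size windows advanced by a fixed
#' step, counts SV start positions per window, and converts counts to
#' z-scores against the genome-wide mean and standard deviation of
#' window counts. Windows at or above `z_threshold` are significant;
#' overlapping or abutting significant windows on a chromosome are
#' merged into maximal hotspot intervals. If window counts have zero
#' spread there is no density signal and no hotspot is reported.
#'
#' @param callset population SV tibble.
#' @param chrom_lengths named vector (or tibble `chrom`,`length`) of
#'   chromosome lengths in bp, covering every call chromosome.
#' @param window_bp window size (default 1 Mb).
#' @param step_bp step between window starts (default 0.5 Mb; must not
#'   exceed `window_bp`).
#' @param z_threshold z-score cut-off for a significant window
#'   (default 3).
#' @return tibble of merged hotspots: `chrom`, `start`, `end`,
#'   `n_windows`, `sv_count` (SV starts inside the merged interval) and
#'   `max_z`; the per-window scan is attached as attribute
#'   `"windows"`.
#' @export
hotspot_scan <- function(callset, chrom_lengths, window_bp = 1e6,
                         step_bp = 5e5, z_threshold = 3) {
  if (window_bp <= 0) abort("window_bp must be positive")
  if (step_bp <= 0 || step_bp > window_bp) {
    abort("step_bp must be in (0, window_bp]")
  }
  lens <- as_chrom_lengths(chrom_lengths)
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_windows = integer(), sv_count = integer(),
                  max_z = numeric())
  callset <- as_tibble(callset)
  if (nrow(callset) == 0) {
    attr(empty, "windows") <- tibble(chrom = character(), start = numeric(),
                                     end = numeric(), sv_count = integer(),
                                     z = numeric())
    return(empty)
  }
  chroms <- normalize_chrom(callset$chrom)
  if (!all(chroms %in% names(lens))) {
    abort(paste0("chromosome lengths missing for: ",
                 paste(setdiff(unique(chroms), names(lens)), collapse = ", ")))
  }
  windows <- purrr::map_dfr(names(lens), function(ch) {
    starts <- seq(0, max(0, lens[[ch]] - 1), by = step_bp)
    tibble(chrom = ch, start = starts,
           end = pmin(starts + window_bp, lens[[ch]]))
  })
  pos <- callset$start
  windows$sv_count <- purrr::map2_int(windows$chrom, seq_len(nrow(windows)),
    function(ch, i) {
      sum(chroms == ch & pos >= windows$start[i] & pos < windows$end[i])
    })
  mu <- mean(windows$sv_count)
  sigma <- sd(windows$sv_count)
  windows$z <- if (is.na(sigma) || sigma == 0) 0 else
    (windows$sv_count - mu) / sigma
  sig <- windows %>% filter(.data$z >= z_threshold)
  if (nrow(sig) == 0) {
    attr(empty, "windows") <- windows
    return(empty)
  }
  merged <- sig %>%
    arrange(match(.data$chrom, chrom_levels(.data$chrom)), .data$start) %>%
    group_by(.data$chrom) %>%
    mutate(gap = .data$start > cummax(dplyr::lag(.data$end,
                                                 default = first(.data$start))),
           run = cumsum(.data$gap)) %>%
    group_by(.data$chrom, .data$run) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = n(), max_z = max(.data$z), .groups = "drop") %>%
    select(-"run")
  merged$sv_count <- purrr::map_int(seq_len(nrow(merged)), function(i) {
    sum(chroms == merged$chrom[i] & pos >= merged$start[i] &
          pos < merged$end[i])
  })
  out <- merged %>%
    select("chrom", "start", "end", "n_windows", "sv_count", "max_z") %>%
    arrange_sv()
  attr(out, "windows") <- windows
  out
}
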