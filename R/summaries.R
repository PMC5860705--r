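#' Length-bin table of a call set
#'
#' Counts and summed lengths per SV type in the conventional length
#' bins 50–1000 bp, 1–10 kb and 10–100 kb (closed at the upper bound),
#' plus an overflow bin for anything larger. Every type x bin
#' combination is reported, zeros included, so bin counts always
#' conserve the per-type totals.
#'
#' @param callset population SV tibble.
#' @param breaks bin boundaries in bp (default `c(50, 1000, 10000,
#'   100000)`); the i-th bin is `(breaks[i-1], breaks[i]]` with the
#'   first bin closed on the left.
#' @return tibble with `sv_type`, `bin`, `n`, `total_length`.
#' @export
length_bin_table <- function(callset, breaks = c(50, 1000, 10000, 100000)) {
  fmt <- function(x) formatC(x, format = "d")
  lab <- c(paste0(fmt(breaks[-length(breaks)] + c(0, rep(1, length(breaks) - 2))),
                  "-", fmt(breaks[-1]), " bp"),
           paste0(">", fmt(breaks[length(breaks)])))
  cut_bins <- cut(callset$length,
                  breaks = c(breaks[1] - 1, breaks[-1], Inf),
                  labels = lab)
  tibble(sv_type = factor(callset$sv_type, levels = sv_types()),
         bin = cut_bins, length = callset$length) %>%
    group_by(.data$sv_type, .data$bin, .drop = FALSE) %>%
    summarise(n = n(), total_length = sum(.data$length), .groups = "drop") %>%
    mutate(sv_type = as.character(.data$sv_type),
           bin = as.character(.data$bin),
           total_length = as.numeric(.data$total_length))
}

#' Type composition of a call set
#'
#' @param callset population SV tibble (or any tibble with `sv_type`).
#' @return tibble with `sv_type`, `n` and `percent` (share of the total,
#'   reported to 2 decimal places); percentages recompute exactly from
#'   the counts.
#' @export
type_composition <- function(callset) {
  if (nrow(callset) == 0) abort("empty call set")
  callset %>%
    count(sv_type = factor(.data$sv_type, levels = sv_types()),
          .drop = FALSE, name = "n") %>%
    mutate(sv_type = as.character(.data$sv_type),
           percent = round(100 * .data$n / sum(.data$n), 2))
}

#' Chromosomal distribution of a call set
#'
#' Per-chromosome SV count, share of the total and density in SVs per
#' Mb of chromosome length, ordered naturally (numeric autosomes, then
#' X). All chromosomes in `chrom_lengths` appear, zeros included.
#'
#' @param callset population SV tibble.
#' @param chrom_lengths named vector (or tibble `chrom`,`length`) of
#'   chromosome lengths in bp; must cover every call chromosome.
#' @return tibble with `chrom`, `n`, `fraction`, `percent`,
#'   `density_per_mb`.
#' @export
chromosome_distribution <- function(callset, chrom_lengths) {
  lens <- as_chrom_lengths(chrom_lengths)
  if (any(lens <= 0)) abort("chromosome lengths must be positive")
  chroms <- normalize_chrom(callset$chrom)
  missing <- setdiff(unique(chroms), names(lens))
  if (length(missing) > 0) {
    abort(paste0("chromosome lengths missing for: ",
                 paste(missing, collapse = ", ")))
  }
  lv <- chrom_levels(names(lens))
  counts <- table(factor(chroms, levels = lv))
  tibble(chrom = lv, n = as.integer(counts[lv]),
         length_bp = unname(lens[lv])) %>%
    mutate(fraction = .data$n / sum(.data$n),
           percent = round(100 * .data$fraction, 2),
           density_per_mb = .data$n / (.data$length_bp / 1e6)) %>%
    select("chrom", "n", "fraction", "percent", "density_per_mb")
}

#' Genome length covered by a call set
#'
#' Reports, per SV type and in total, both the simple sum of SV lengths
#' and the union length (bases covered by at least one interval, so
#' overlaps are counted once). Insertions contribute their inserted
#' length to the sums but, being zero-width on the reference, nothing
#' to the union. The two notions differ whenever same- or cross-type
#' records overlap; both are reported rather than silently preferring
#' one.
#'
#' @param callset population SV tibble.
#' @return tibble with one row per SV type plus a `"total"` row:
#'   `sv_type`, `n`, `sum_bp`, `union_bp`.
#' @export
covered_length <- function(callset) {
  callset <- as_tibble(callset)
  union_of <- function(df) {
    df <- df[df$sv_type != "INS" & df$end > df$start, , drop = FALSE]
    if (nrow(df) == 0) return(0)
    sum(IRanges::width(GenomicRanges::reduce(sv_granges(df))))
  }
  per_type <- purrr::map_dfr(sv_types(), function(tp) {
    sub <- callset[callset$sv_type == tp, , drop = FALSE]
    tibble(sv_type = tp, n = nrow(sub), sum_bp = sum(as.numeric(sub$length)),
           union_bp = union_of(sub))
  })
  bind_rows(per_type,
            tibble(sv_type = "total", n = nrow(callset),
                   sum_bp = sum(as.numeric(callset$length)),
                   union_bp = union_of(callset)))
}

#' Aggregate a per-sample sequencing summary table
#'
#' Column totals and arithmetic means (to 2 decimal places) over every
#' numeric column of a sequencing/mapping QC table — raw and clean
#' yield, mapped yield, mapping rate, depth, Q20, GC and the like.
#'
#' @param table tibble with one row per sample; non-numeric columns are
#'   ignored.
#' @return tibble with `metric`, `total`, `mean`.
#' @export
sequencing_summary <- function(table) {
  if (nrow(table) == 0) abort("need at least one sample row")
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  tibble(metric = num,
         total = unname(round(vapply(table[num], sum, numeric(1)), 2)),
         mean = unname(round(vapply(table[num], mean, numeric(1)), 2)))
}
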