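#' Filter raw SV calls by support and chromosome
#'
#' Applies the two raw-data filters of the calling design: a call must
#' be backed by at least `min_support` paired-end reads, and calls on
#' excluded chromosomes are dropped (chromosome Y by default, to remove
#' the sex-composition effect from a mixed-sex cohort). Removal reasons
#' are tallied, with the chromosome exclusion taking precedence when
#' both apply.
#'
#' @param calls validated call tibble.
#' @param min_support minimum paired-end read support (default 3).
#' @param excluded_chroms chromosomes to drop (default `"Y"`).
#' @return filtered tibble with a `"filter_report"` attribute:
#'   a tibble of `reason`, `n` (see [filter_report()]).
#' @export
filter_calls <- function(calls, min_support = 3, excluded_chroms = "Y") {
  calls <- as_tibble(calls)
  excluded_chroms <- normalize_chrom(excluded_chroms)
  reason <- rep(NA_character_, nrow(calls))
  on_excl <- normalize_chrom(calls$chrom) %in% excluded_chroms
  reason[on_excl] <- "excluded chromosome"
  low <- is.na(reason) & calls$support < min_support
  reason[low] <- "support below minimum"
  kept <- calls[is.na(reason), , drop = FALSE]
  rep_tbl <- tibble(reason = c("excluded chromosome", "support below minimum"),
                    n = c(sum(on_excl), sum(low)))
  attr(kept, "filter_report") <- rep_tbl
  kept
}

#' Per-reason removal counts of a filtering step
#'
#' @param x a tibble returned by [filter_calls()].
#' @return tibble with columns `reason` and `n`.
#' @export
filter_report <- function(x) {
  rep_tbl <- attr(x, "filter_report")
  if (is.null(rep_tbl)) tibble(reason = character(), n = integer()) else rep_tbl
}

#' Overlap length between SV intervals
#'
#' Base pairs shared by two half-open intervals; 0 when the chromosomes
#' differ or the intervals are disjoint (abutting intervals share
#' nothing under the half-open convention). Vectorized over rows.
#'
#' @param a,b call tibbles (or one-row records) with `chrom`, `start`,
#'   `end`.
#' @return integer vector of overlap lengths in bp.
#' @export
overlap_length <- function(a, b) {
  same <- normalize_chrom(a$chrom) == normalize_chrom(b$chrom)
  ov <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  as.integer(ifelse(same, ov, 0L))
}

#' Pairwise merge rule
#'
#' Two calls are mergeable when they are on the same chromosome, of the
#' same SV type, and (for DEL/DUP/INV) overlap by at least `min_overlap`
#' bp. Insertions are zero-width breakpoints to which a bp-overlap rule
#' cannot apply; their breakpoints must instead lie within `ins_window`
#' bp of each other.
#'
#' @param a,b call tibbles (vectorized over rows).
#' @param min_overlap minimum shared bp for non-insertions (default 25).
#' @param ins_window breakpoint distance window for insertions
#'   (default 25 bp, mirroring the overlap threshold).
#' @return logical vector.
#' @export
mergeable <- function(a, b, min_overlap = 25, ins_window = 25) {
  same <- normalize_chrom(a$chrom) == normalize_chrom(b$chrom) &
    a$sv_type == b$sv_type
  ins <- a$sv_type == "INS" & b$sv_type == "INS"
  ok_ins <- abs(a$start - b$start) <= ins_window
  ok_len <- overlap_length(a, b) >= min_overlap
  same & ifelse(ins, ok_ins, ok_len)
}

# minimal union-find (pure find; partitions are small enough that
# path compression is not worth the bookkeeping)
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Single-linkage clustering of SV calls
#'
#' Computes the transitive closure of the pairwise [mergeable()]
#' relation: chains of calls linked by >= `min_overlap` bp same-type
#' same-chromosome overlaps collapse into one cluster even when distant
#' chain members do not overlap each other. The implementation
#' partitions calls by (chromosome, type), sorts by start and sweeps,
#' testing each call only against earlier calls that can still reach it;
#' the result is identical to brute-force all-pairs single linkage and
#' invariant to input row order.
#'
#' @param calls call tibble (one sample, or a pooled cohort).
#' @param min_overlap minimum bp overlap (default 25).
#' @param ins_window insertion breakpoint window (default 25).
#' @return the input tibble with an integer `cluster` column; cluster
#'   ids are assigned in (chromosome natural order, cluster start)
#'   order and rows are sorted accordingly.
#' @export
cluster_calls <- function(calls, min_overlap = 25, ins_window = 25) {
  calls <- as_tibble(calls)
  n <- nrow(calls)
  if (n == 0) return(mutate(calls, cluster = integer()))
  chrom <- normalize_chrom(calls$chrom)
  key <- paste(chrom, calls$sv_type, sep = "\r")
  cluster_global <- integer(n)
  next_id <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    is_ins <- calls$sv_type[idx[1]] == "INS"
    ord <- idx[order(calls$start[idx], calls$end[idx])]
    s <- calls$start[ord]; e <- calls$end[ord]
    m <- length(ord)
    parent <- uf_new(m)
    for (i in seq_len(m)) {
      j <- i + 1L
      if (is_ins) {
        while (j <= m && s[j] - s[i] <= ins_window) {
          ri <- uf_find(parent, i); rj <- uf_find(parent, j)
          if (ri != rj) parent[rj] <- ri
          j <- j + 1L
        }
      } else {
        lim <- e[i] - min_overlap
        while (j <= m && s[j] <= lim) {
          if (min(e[i], e[j]) - s[j] >= min_overlap) {
            ri <- uf_find(parent, i); rj <- uf_find(parent, j)
            if (ri != rj) parent[rj] <- ri
          }
          j <- j + 1L
        }
      }
    }
    root <- vapply(seq_len(m), function(i) uf_find(parent, i), integer(1))
    cluster_global[ord] <- next_id + match(root, unique(root[order(s, e)]))
    next_id <- next_id + length(unique(root))
  }
  out <- mutate(calls, cluster = cluster_global)
  # renumber clusters in (chrom, start) order for a canonical labelling
  anchor <- out %>%
    group_by(.data$cluster) %>%
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              .groups = "drop") %>%
    arrange_sv()
  out %>%
    mutate(cluster = match(.data$cluster, anchor$cluster)) %>%
    arrange(.data$cluster, .data$start, .data$end)
}

#' Two-caller consensus within a sample
#'
#' Pools one sample's calls from all callers, clusters them with
#' [cluster_calls()], and keeps only clusters containing at least one
#' call from every required caller: a variant reported by a single
#' program is discarded. Each surviving cluster becomes one consensus
#' SV spanning the union of its members (for insertions: the smallest
#' member breakpoint, with the largest member length).
#'
#' @param calls filtered call tibble for one sample (column `caller_id`
#'   distinguishes the programs).
#' @param required_callers caller ids that must all support a cluster;
#'   default: every caller present in `calls`. At least two are
#'   required — the whole point of the design is program intersection.
#' @param min_overlap,ins_window merge rule parameters, see
#'   [cluster_calls()].
#' @return consensus tibble: `sample_id`, `chrom`, `start`, `end`,
#'   `sv_type`, `length`, `n_calls`, `callers`, `support` (max member
#'   support) and, when the input carries truth bookkeeping, `truth_id`.
#' @export
caller_consensus <- function(calls, required_callers = NULL,
                             min_overlap = 25, ins_window = 25) {
  calls <- as_tibble(calls)
  if (is.null(required_callers)) required_callers <- sort(unique(calls$caller_id))
  if (length(required_callers) < 2) {
    abort("consensus requires at least two callers")
  }
  if (nrow(calls) > 0 && n_distinct(calls$sample_id) > 1) {
    abort("caller_consensus operates on one sample at a time")
  }
  cl <- cluster_calls(calls, min_overlap = min_overlap, ins_window = ins_window)
  summarise_clusters(cl, required_callers = required_callers)
}

# collapse clustered calls into consensus records, keeping only clusters
# supported by every required caller (NULL keeps everything)
summarise_clusters <- function(cl, required_callers = NULL) {
  has_truth <- "truth_id" %in% names(cl)
  if (!has_truth) cl$truth_id <- NA_character_
  out <- cl %>%
    group_by(.data$cluster) %>%
    summarise(
      sample_id = first(.data$sample_id),
      chrom = first(.data$chrom),
      sv_type = first(.data$sv_type),
      start = min(.data$start),
      end = if (first(.data$sv_type) == "INS") min(.data$start) else max(.data$end),
      length = if (first(.data$sv_type) == "INS") max(.data$length)
               else max(.data$end) - min(.data$start),
      n_calls = n(),
      callers = paste(sort(unique(.data$caller_id)), collapse = ","),
      support = max(.data$support),
      truth_id = paste(sort(unique(.data$truth_id[!is.na(.data$truth_id)])),
                       collapse = ";"),
      .groups = "drop"
    ) %>%
    mutate(truth_id = ifelse(.data$truth_id == "", NA_character_, .data$truth_id))
  if (!is.null(required_callers)) {
    keep <- purrr::map_lgl(strsplit(out$callers, ","),
                           function(cs) all(required_callers %in% cs))
    out <- out[keep, , drop = FALSE]
  }
  out <- out %>% select(-"cluster") %>% arrange_sv(.data$end)
  if (!has_truth) out$truth_id <- NULL
  out
}
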