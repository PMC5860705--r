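#' Merge per-sample consensus SVs into a population call set
#'
#' Pools every sample's consensus calls, clusters them with the same
#' 25 bp / same-type / same-chromosome rule used within samples (the
#' design imposes no separate cross-sample threshold), and keeps only
#' clusters whose members come from at least `min_individuals` distinct
#' animals — a sample contributing two calls to one cluster counts
#' once. Each kept cluster becomes one population SV spanning the union
#' of its members, with a zero-padded serial id assigned in
#' (chromosome, start) order, and with breed/group membership derived
#' from its carriers via the sample sheet.
#'
#' @param consensus consensus tibble covering the whole cohort (output
#'   of [caller_consensus()] row-bound over samples).
#' @param samples sample sheet tibble (`sample_id`, `breed`, `group`).
#'   Every `sample_id` occurring in `consensus` must be listed.
#' @param min_overlap,ins_window merge rule parameters.
#' @param min_individuals minimum number of distinct carrier samples
#'   (default 2: singletons never enter the final call set).
#' @param id_prefix prefix for serial ids (default `"SV"`).
#' @return population SV tibble: `sv_id`, `chrom`, `start`, `end`,
#'   `sv_type`, `length`, `n_carriers`, and list-columns `carriers`,
#'   `breeds`, `groups` (plus `truth_id` when bookkeeping is present).
#' @export
merge_across_samples <- function(consensus, samples, min_overlap = 25,
                                 ins_window = 25, min_individuals = 2,
                                 id_prefix = "SV") {
  consensus <- as_tibble(consensus)
  samples <- as_tibble(samples)
  unknown <- setdiff(unique(consensus$sample_id), samples$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("calls from samples missing in the sample sheet: ",
                 paste(unknown, collapse = ", ")))
  }
  has_truth <- "truth_id" %in% names(consensus)
  if (!has_truth) consensus$truth_id <- NA_character_
  cl <- cluster_calls(consensus, min_overlap = min_overlap,
                      ins_window = ins_window)
  out <- cl %>%
    group_by(.data$cluster) %>%
    summarise(
      chrom = first(.data$chrom),
      sv_type = first(.data$sv_type),
      start = min(.data$start),
      end = if (first(.data$sv_type) == "INS") min(.data$start) else max(.data$end),
      length = if (first(.data$sv_type) == "INS") max(.data$length)
               else max(.data$end) - min(.data$start),
      carriers = list(sort(unique(.data$sample_id))),
      truth_id = paste(sort(unique(unlist(
        strsplit(.data$truth_id[!is.na(.data$truth_id)], ";")))),
        collapse = ";"),
      .groups = "drop"
    ) %>%
    mutate(n_carriers = lengths(.data$carriers),
           truth_id = ifelse(.data$truth_id == "", NA_character_,
                             .data$truth_id)) %>%
    filter(.data$n_carriers >= min_individuals) %>%
    arrange_sv(.data$end) %>%
    select(-"cluster")

  breed_of <- setNames(samples$breed, samples$sample_id)
  group_of <- setNames(samples$group, samples$sample_id)
  out <- out %>%
    mutate(
      sv_id = sprintf("%s%0*d", id_prefix, max(5L, nchar(nrow(out))),
                      row_number()),
      breeds = purrr::map(.data$carriers,
                          function(s) sort(unique(unname(breed_of[s])))),
      groups = purrr::map(.data$carriers,
                          function(s) sort(unique(unname(group_of[s]))))
    ) %>%
    select("sv_id", "chrom", "start", "end", "sv_type", "length",
           "n_carriers", "carriers", "breeds", "groups", "truth_id")
  if (!has_truth) out$truth_id <- NULL
  out
}

#' Carrier presence/absence matrix
#'
#' One row per sample (including samples carrying nothing), one 0/1
#' column per population SV; cell (s, v) is 1 iff sample s is a carrier
#' of v. Absence means "not called", not a confirmed reference
#' genotype — no re-genotyping of non-carriers is attempted. This is
#' the input to [group_sets()] and [sv_pca()].
#'
#' @param callset population SV tibble.
#' @param samples sample sheet tibble.
#' @return wide tibble: `sample_id`, `breed`, `group`, then one integer
#'   column per `sv_id` in call-set order.
#' @export
build_presence_matrix <- function(callset, samples) {
  callset <- as_tibble(callset)
  samples <- as_tibble(samples)
  if (nrow(callset) == 0) abort("empty call set")
  long <- callset %>%
    select("sv_id", "carriers") %>%
    tidyr::unnest_longer("carriers", values_to = "sample_id")
  wide <- long %>%
    mutate(present = 1L) %>%
    tidyr::pivot_wider(names_from = "sv_id", values_from = "present",
                       values_fill = 0L)
  out <- samples %>%
    select("sample_id", "breed", "group") %>%
    left_join(wide, by = "sample_id") %>%
    mutate(across(all_of(callset$sv_id), ~ ifelse(is.na(.x), 0L, .x)))
  out[, c("sample_id", "breed", "group", callset$sv_id)]
}
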