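#' Supported structural variant type codes
#'
#' The four SV classes handled by the pipeline: deletions (DEL),
#' insertions (INS), tandem duplications (DUP) and inversions (INV).
#' Translocations are deliberately unsupported because one of the two
#' callers the consensus design targets does not report them.
#'
#' @return Character vector of the four type codes.
#' @export
sv_types <- function() c("DEL", "INS", "DUP", "INV")

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix (any case) and upper-cases the rest so
#' that mixed-source inputs ("chr1", "Chr1", "1", "chrx") compare equal.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_chrom(c("chr1", "ChrX", "12"))
normalize_chrom <- function(x) {
  toupper(sub("^[Cc][Hh][Rr]", "", as.character(x)))
}

#' Natural chromosome ordering
#'
#' Orders numeric autosomes ascending, then X, then any remaining names
#' alphabetically. Used by every writer and report so output order is
#' total and deterministic.
#'
#' @param chroms character vector of (normalized) chromosome names.
#' @return character vector of unique names in report order.
#' @export
chrom_levels <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(u))
  is_num <- !is.na(num)
  c(u[is_num][order(num[is_num])],
    sort(u[!is_num & u == "X"]),
    sort(u[!is_num & u != "X"]))
}

# arrange an SV tibble by (chrom natural order, start, then remaining keys)
arrange_sv <- function(df, ...) {
  lv <- chrom_levels(df$chrom)
  df %>%
    mutate(.chrom_ord = match(.data$chrom, lv)) %>%
    arrange(.data$.chrom_ord, .data$start, ...) %>%
    select(-".chrom_ord")
}

#' Validate raw SV call records
#'
#' Applies the record-level invariants of the call model: a known type
#' code, non-negative coordinates with `end >= start`, a minimum length
#' (50 bp by default, the conventional SV size floor), length equal to
#' `end - start` for DEL/DUP/INV, and a zero-width breakpoint
#' (`start == end`) with explicit length for INS. Failing records are
#' dropped, not repaired, and returned in a rejection report.
#'
#' @param calls tibble with columns `sample_id`, `caller_id`, `chrom`,
#'   `start`, `end`, `sv_type`, `length`, `support`.
#' @param min_length minimum accepted SV length in bp (default 50).
#' @return tibble of accepted calls, chromosome names normalized, with a
#'   `"rejections"` attribute holding the rejected rows plus a `reason`
#'   column (see [rejection_report()]).
#' @export
validate_sv_calls <- function(calls, min_length = 50) {
  calls <- as_tibble(calls)
  need <- c("sample_id", "caller_id", "chrom", "start", "end",
            "sv_type", "length", "support")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0("missing call columns: ", paste(missing_cols, collapse = ", ")))
  }
  calls <- calls %>%
    mutate(chrom = normalize_chrom(.data$chrom),
           sv_type = toupper(as.character(.data$sv_type)))

  reason <- rep(NA_character_, nrow(calls))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- flag(!(calls$sv_type %in% sv_types()), "unsupported type")
  reason <- flag(calls$start < 0 | calls$end < 0, "negative coordinates")
  reason <- flag(calls$end < calls$start, "end before start")
  reason <- flag(calls$sv_type != "INS" &
                   calls$length != calls$end - calls$start,
                 "length does not equal end - start")
  reason <- flag(calls$sv_type == "INS" & calls$start != calls$end,
                 "insertion breakpoint not zero-width")
  reason <- flag(calls$length < min_length, "length below minimum")
  reason <- flag(calls$support < 0, "negative support")

  kept <- calls[is.na(reason), , drop = FALSE]
  rej <- calls[!is.na(reason), , drop = FALSE]
  rej$reason <- reason[!is.na(reason)]
  attr(kept, "rejections") <- rej
  kept
}

#' Rejection report of an ingest step
#'
#' @param x a tibble returned by [validate_sv_calls()] or [read_sv_calls()].
#' @return tibble of rejected records with a `reason` column (zero rows
#'   when nothing was rejected).
#' @export
rejection_report <- function(x) {
  rej <- attr(x, "rejections")
  if (is.null(rej)) {
    return(tibble(sample_id = character(), caller_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  sv_type = character(), length = integer(),
                  support = integer(), reason = character()))
  }
  as_tibble(rej)
}
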