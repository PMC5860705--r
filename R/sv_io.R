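#' Read raw SV calls from a caller table or VCF
#'
#' Ingests one caller's output for one sample. Two dialects are
#' supported and must be declared (caller-native formats are too
#' ambiguous to sniff):
#'
#' * `"tsv"`: a headered tab-separated table with columns `chrom`,
#'   `start`, `end`, `type`, `support` and optionally `length`.
#'   Coordinates are 0-based half-open, so `length = end - start` for
#'   DEL/DUP/INV. Insertions are zero-width breakpoints: when a `length`
#'   column is present an INS row must have `start == end` and carries
#'   its inserted length there; without one, `end - start` is read as
#'   the inserted length and the record is collapsed to its breakpoint.
#' * `"vcf"`: VCF 4.2 with symbolic SV alleles; requires INFO keys
#'   `SVTYPE` and `END` (or `SVLEN` for insertions); `SUPPORT` is used
#'   as read-pair support when present, otherwise 0.
#'
#' Records violating the call invariants (unknown type, negative or
#' inverted coordinates, length below `min_length`, ...) are dropped and
#' tallied; retrieve them with [rejection_report()].
#'
#' @param path input file path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param sample_id,caller_id identifiers attached to every record.
#' @param min_length minimum SV length in bp (default 50).
#' @return tibble of validated calls with columns `sample_id`,
#'   `caller_id`, `chrom`, `start`, `end`, `sv_type`, `length`,
#'   `support`, plus a `"rejections"` attribute.
#' @export
read_sv_calls <- function(path, dialect = c("tsv", "vcf"),
                          sample_id, caller_id, min_length = 50) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("cannot read SV calls: ", path))
  raw <- switch(dialect,
    tsv = read_sv_calls_tsv(path),
    vcf = read_sv_calls_vcf(path)
  )
  raw$sample_id <- as.character(sample_id)
  raw$caller_id <- as.character(caller_id)
  out <- validate_sv_calls(raw, min_length = min_length)
  arrange_sv(out)
}

read_sv_calls_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  need <- c("chrom", "start", "end", "type", "support")
  if (!all(need %in% names(df))) {
    abort(paste0("caller table must have columns ",
                 paste(need, collapse = ", "), ": ", path))
  }
  df <- df %>%
    mutate(type = toupper(as.character(.data$type)),
           start = as.integer(.data$start), end = as.integer(.data$end),
           support = as.integer(.data$support))
  if (!"length" %in% names(df)) {
    df$length <- df$end - df$start
    ins <- df$type == "INS"
    df$end[ins] <- df$start[ins]
  } else {
    df$length <- as.integer(df$length)
  }
  tibble(chrom = df$chrom, start = df$start, end = df$end,
         sv_type = df$type, length = df$length, support = df$support)
}

read_sv_calls_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  sv_type = character(), length = integer(),
                  support = integer()))
  }
  svtype <- vcfR::extract.info(vcf, element = "SVTYPE")
  endpos <- suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "END")))
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "SVLEN")))
  supp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "SUPPORT")))
  if (all(is.na(svtype))) abort(paste0("VCF lacks SVTYPE INFO field: ", path))
  pos <- as.integer(fix$POS)
  is_ins <- !is.na(svtype) & svtype == "INS"
  end <- ifelse(is_ins, pos, endpos)
  len <- ifelse(is_ins, abs(svlen), endpos - pos)
  len <- ifelse(is.na(len) & !is.na(svlen), abs(svlen), len)
  tibble(chrom = fix$CHROM, start = pos, end = as.integer(end),
         sv_type = as.character(svtype), length = as.integer(len),
         support = ifelse(is.na(supp), 0L, supp))
}

#' Write SV calls as a caller-style table
#'
#' Emits the headered TSV dialect accepted by [read_sv_calls()], sorted
#' by (chromosome in natural order, start). The `length` column is
#' always written so insertion lengths round-trip.
#'
#' @param calls validated call tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_calls <- function(calls, path) {
  out <- arrange_sv(as_tibble(calls)) %>%
    select(chrom = "chrom", start = "start", end = "end",
           type = "sv_type", support = "support", length = "length")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort sample sheet
#'
#' A CSV with one row per sequenced animal: `sample_id`, `breed`,
#' `group`, plus one `path_<caller>` column per caller pointing at that
#' caller's raw call file. Sample ids must be unique and each sample
#' needs at least two caller paths for the consensus design to apply.
#'
#' @param path CSV path.
#' @param require_paths if `FALSE`, caller path columns are optional
#'   (useful when calls are already in memory).
#' @return tibble with one row per sample.
#' @export
read_sample_sheet <- function(path, require_paths = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "breed", "group")
  if (!all(need %in% names(df))) {
    abort(paste0("sample sheet must have columns ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in sample sheet")
  callers <- grep("^path_", names(df), value = TRUE)
  if (require_paths && length(callers) < 2) {
    abort("sample sheet must list at least two caller path_ columns")
  }
  as_tibble(df)
}

#' Read conserved gene identifiers
#'
#' Plain text, one gene ID per line; blank lines and `#` comments are
#' ignored. Typically the species projection of a core eukaryotic gene
#' set.
#'
#' @param path file path.
#' @return character vector of unique IDs.
#' @export
read_conserved_ids <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  unique(x[x != "" & !startsWith(x, "#")])
}

#' Read a biallelic genotype count table
#'
#' A CSV with columns `locus_id`, `population_id`, `n_II`, `n_ID`,
#' `n_DD`: genotype class counts at an insertion/deletion marker scored
#' per population (e.g. from gel electrophoresis patterns). Every
#' (locus, population) row must have at least one nonzero count.
#'
#' @param path CSV path.
#' @return tibble of counts.
#' @export
read_genotype_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("locus_id", "population_id", "n_II", "n_ID", "n_DD")
  if (!all(need %in% names(df))) {
    abort(paste0("genotype table must have columns ", paste(need, collapse = ", ")))
  }
  if (any(df$n_II < 0 | df$n_ID < 0 | df$n_DD < 0)) abort("negative genotype count")
  if (any(df$n_II + df$n_ID + df$n_DD == 0)) {
    abort("all-zero genotype counts for some (locus, population)")
  }
  as_tibble(df)
}

#' Write a population call set
#'
#' Writes the non-redundant cohort call set deterministically sorted by
#' (chromosome in natural order, start, id), either as a TSV with
#' carrier/breed/group membership collapsed into comma-separated fields,
#' or as a VCF 4.2 with symbolic ALT alleles and `SVTYPE`/`END`/`SVLEN`
#' INFO keys (`SVLEN` is negative for deletions, as is conventional).
#'
#' @param callset population SV tibble from [merge_across_samples()].
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_population_callset <- function(callset, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  callset <- as_tibble(callset)
  if (anyDuplicated(callset$sv_id)) abort("duplicate sv_id in call set")
  callset <- arrange_sv(callset, .data$sv_id)
  if (format == "tsv") {
    out <- callset %>%
      mutate(carriers = purrr::map_chr(.data$carriers, paste, collapse = ","),
             breeds = purrr::map_chr(.data$breeds, paste, collapse = ","),
             groups = purrr::map_chr(.data$groups, paste, collapse = ",")) %>%
      select("sv_id", "chrom", "start", "end", "sv_type", "length",
             "n_carriers", "carriers", "breeds", "groups")
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    svlen <- ifelse(callset$sv_type == "DEL", -callset$length, callset$length)
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;NCARRIERS=%d;CARRIERS=%s",
                    callset$sv_type, callset$end, svlen, callset$n_carriers,
                    purrr::map_chr(callset$carriers, paste, collapse = ","))
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=svcohort",
      paste0("##ALT=<ID=", sv_types(), ",Description=\"", sv_types(), "\">"),
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End coordinate\">",
      "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
      "##INFO=<ID=NCARRIERS,Number=1,Type=Integer,Description=\"Number of carrier samples\">",
      "##INFO=<ID=CARRIERS,Number=1,Type=String,Description=\"Carrier sample ids\">",
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            sep = "\t")
    )
    body <- if (nrow(callset) == 0) character() else
      paste(callset$chrom, callset$start, callset$sv_id, "N",
            paste0("<", callset$sv_type, ">"), ".", "PASS", info,
            sep = "\t")
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Read a population call set written by [write_population_callset()]
#'
#' @param path input path.
#' @param format `"tsv"` or `"vcf"`.
#' @return population SV tibble; breed/group membership is only present
#'   in the TSV format (recover it from a sample sheet otherwise).
#' @export
read_population_callset <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  split_field <- function(x) strsplit(ifelse(is.na(x) | x == "", "", x), ",")
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    df %>%
      mutate(carriers = split_field(.data$carriers),
             breeds = split_field(.data$breeds),
             groups = split_field(.data$groups)) %>%
      as_tibble()
  } else {
    calls <- read_sv_calls_vcf(path)
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    carriers <- split_field(vcfR::extract.info(vcf, element = "CARRIERS"))
    tibble(sv_id = fix$ID, chrom = calls$chrom, start = calls$start,
           end = calls$end, sv_type = calls$sv_type, length = calls$length,
           n_carriers = lengths(carriers), carriers = carriers)
  }
}
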