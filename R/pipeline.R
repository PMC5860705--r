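#' Run the full cohort SV pipeline
#'
#' Orchestrates every stage end to end: obtain raw two-caller calls
#' (either simulated from `config`, or read from the `path_<caller>`
#' columns of a user-supplied sample sheet), filter them by support and
#' excluded chromosomes, intersect callers within each sample, merge
#' consensus calls across samples into the population call set, build
#' the presence/absence matrix, compute group/breed sets, Venn counts
#' and PCA, classify SVs against gene models, scan for hotspots, and
#' emit summary tables. All outputs are written under `out_dir` as
#' plain TSV/VCF/JSON, and a machine-readable run manifest reconciles
#' record counts across stages (raw = kept + dropped at every
#' filtering step). Reruns with the same configuration and seed
#' reproduce byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()]; drives simulation and supplies the
#'   genome. Ignored for input generation when `sample_sheet` is given.
#' @param sample_sheet optional path to a sample sheet CSV with caller
#'   path columns; when supplied, calls are read instead of simulated.
#' @param gff optional gene annotation path (GFF3); default: simulated
#'   gene models from `config`.
#' @param min_support,excluded_chroms raw-call filter parameters.
#' @param min_overlap,ins_window merge rule parameters.
#' @param min_individuals population merge threshold.
#' @param flank_bp consequence flank.
#' @param hotspot_window_bp,hotspot_step_bp,hotspot_z hotspot scan
#'   parameters.
#' @return the run manifest (a list), invisibly; all tables are also
#'   returned in its `results` element.
#' @export
run_sv_pipeline <- function(out_dir, config = sim_config(),
                            sample_sheet = NULL, gff = NULL,
                            min_support = 3, excluded_chroms = "Y",
                            min_overlap = 25, ins_window = 25,
                            min_individuals = 2, flank_bp = 5000,
                            hotspot_window_bp = 1e6, hotspot_step_bp = 5e5,
                            hotspot_z = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_counts <- list()

  if (is.null(sample_sheet)) {
    samples <- sim_samples(config)
    truth <- simulate_truth(config)
    raw <- purrr::map_dfr(config$callers, function(cl) {
      validate_sv_calls(simulate_caller_calls(truth, config, cl))
    })
    callers <- config$callers
    readr::write_tsv(truth %>%
                       mutate(carriers = purrr::map_chr(.data$carriers,
                                                        paste, collapse = ",")),
                     file.path(out_dir, "truth.tsv"), progress = FALSE)
  } else {
    samples <- read_sample_sheet(sample_sheet)
    callers <- sub("^path_", "", grep("^path_", names(samples), value = TRUE))
    raw <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
      purrr::map_dfr(callers, function(cl) {
        p <- samples[[paste0("path_", cl)]][i]
        if (is.na(p) || !file.exists(p)) {
          abort(paste0("missing input for sample ", samples$sample_id[i],
                       ", caller ", cl, ": ", p))
        }
        dialect <- if (grepl("\\.vcf$", p)) "vcf" else "tsv"
        read_sv_calls(p, dialect, samples$sample_id[i], cl)
      })
    })
    truth <- NULL
  }
  stage_counts$raw_calls <- nrow(raw)

  filtered <- filter_calls(raw, min_support = min_support,
                           excluded_chroms = excluded_chroms)
  stage_counts$filter_dropped <- sum(filter_report(filtered)$n)
  stage_counts$filtered_calls <- nrow(filtered)

  consensus <- filtered %>%
    dplyr::group_split(.data$sample_id) %>%
    purrr::map_dfr(caller_consensus, required_callers = callers,
                   min_overlap = min_overlap, ins_window = ins_window)
  stage_counts$consensus_calls <- nrow(consensus)

  callset <- merge_across_samples(consensus, samples,
                                  min_overlap = min_overlap,
                                  ins_window = ins_window,
                                  min_individuals = min_individuals)
  stage_counts$population_svs <- nrow(callset)
  write_population_callset(callset %>% select(-dplyr::any_of("truth_id")),
                           file.path(out_dir, "callset.tsv"), "tsv")
  write_population_callset(callset %>% select(-dplyr::any_of("truth_id")),
                           file.path(out_dir, "callset.vcf"), "vcf")

  presence <- build_presence_matrix(callset, samples)
  readr::write_tsv(presence, file.path(out_dir, "presence_matrix.tsv"),
                   progress = FALSE)
  sets <- group_sets(presence, "group")
  venn <- venn_counts(sets)
  readr::write_tsv(venn, file.path(out_dir, "venn_groups.tsv"),
                   progress = FALSE)
  pca <- sv_pca(presence)
  readr::write_tsv(tidy(pca), file.path(out_dir, "pca_coords.tsv"),
                   progress = FALSE)

  genes <- if (is.null(gff)) simulate_gene_models(config) else
    read_gene_models(gff)
  cons <- classify_sv(callset, genes, flank_bp = flank_bp)
  readr::write_tsv(cons, file.path(out_dir, "consequences.tsv"),
                   progress = FALSE)
  summary_cls <- consequence_summary(cons, callset)
  gtab <- gene_sv_table(cons, genes)
  readr::write_tsv(gtab, file.path(out_dir, "gene_sv_table.tsv"),
                   progress = FALSE)

  hot <- hotspot_scan(callset, config$chrom_lengths,
                      window_bp = hotspot_window_bp,
                      step_bp = hotspot_step_bp, z_threshold = hotspot_z)
  readr::write_tsv(hot, file.path(out_dir, "hotspots.tsv"), progress = FALSE)

  reports <- list(type_composition = type_composition(callset),
                  length_bins = length_bin_table(callset),
                  chrom_distribution = chromosome_distribution(
                    callset, config$chrom_lengths),
                  covered_length = covered_length(callset),
                  consequence_summary = summary_cls)
  for (nm in names(reports)) {
    readr::write_tsv(reports[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("svcohort")),
    seed = config$seed,
    parameters = list(min_support = min_support,
                      excluded_chroms = excluded_chroms,
                      min_overlap = min_overlap, ins_window = ins_window,
                      min_individuals = min_individuals,
                      flank_bp = flank_bp,
                      hotspot = list(window_bp = hotspot_window_bp,
                                     step_bp = hotspot_step_bp,
                                     z = hotspot_z)),
    stage_counts = stage_counts,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest[c("package_version", "seed", "parameters",
                                  "stage_counts", "outputs")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$results <- c(list(samples = samples, truth = truth,
                             callset = callset, presence = presence,
                             venn = venn, pca = pca, consequences = cons,
                             gene_sv_table = gtab, hotspots = hot), reports)
  invisible(manifest)
}
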