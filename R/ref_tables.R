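# Published headline tables from a 54-animal pig resequencing cohort
# (five Guizhou indigenous breeds plus Chinese and European comparison
# groups). These printed values are the worked examples the package's
# summary operations are validated against; they are data, not code
# paths — every statistic is recomputed from them at run time.

#' Reference per-sample sequencing summary (18 Guizhou pigs)
#'
#' Raw/clean/mapped yield in Gb, mapping rate, mean depth, Q20 and GC
#' content per resequenced animal, as reported for the cohort's 18
#' Guizhou pigs. Feed to [sequencing_summary()] to recover the cohort
#' totals (578.03 Gb raw, 545.4 Gb clean, i.e. 94.35% retained) and the
#' 11.93x mean depth.
#'
#' @return tibble with one row per sample.
#' @export
gzp_sequencing_stats <- function() {
  tribble(
    ~sample_id, ~raw_gb, ~clean_gb, ~mapped_gb, ~map_ratio_pct, ~depth_x, ~q20_pct, ~gc_pct,
    "KL1", 29.51, 28.64, 27.31, 95.36, 11.17, 97.66, 42.77,
    "KL2", 31.20, 30.32, 29.21, 96.34, 11.95, 97.75, 42.62,
    "KL3", 34.76, 33.59, 32.51, 96.78, 13.30, 97.40, 42.44,
    "QB1", 29.94, 28.85, 27.91, 96.74, 11.42, 97.39, 42.06,
    "QB2", 30.72, 29.69, 28.75, 96.83, 11.76, 97.38, 42.30,
    "QB3", 28.90, 27.81, 26.72, 96.08, 10.93, 97.33, 42.19,
    "GL1", 29.20, 28.01, 27.15, 96.93, 11.10, 96.56, 42.82,
    "GL2", 29.42, 28.49, 27.59, 96.84, 11.28, 96.95, 42.95,
    "GL3", 28.38, 27.33, 26.51, 97.00, 10.84, 96.73, 42.99,
    "LB1", 28.86, 27.39, 26.47, 96.64, 10.83, 96.76, 42.96,
    "LB2", 28.10, 26.97, 26.15, 96.96, 10.70, 96.83, 43.05,
    "LB3", 28.23, 26.77, 26.02, 97.20, 10.64, 96.61, 42.72,
    "XP1", 30.11, 28.31, 27.42, 96.86, 11.21, 96.30, 42.52,
    "XP2", 33.52, 31.69, 30.63, 96.66, 12.53, 96.50, 42.26,
    "XP3", 48.46, 42.25, 39.82, 94.25, 16.29, 92.90, 42.42,
    "XP4", 29.22, 27.41, 26.56, 96.90, 10.87, 96.50, 42.64,
    "XP5", 30.88, 29.20, 28.22, 96.64, 11.54, 96.19, 42.94,
    "XP6", 48.62, 42.68, 40.23, 94.26, 16.45, 92.75, 41.73
  )
}

#' Reference SV length-bin table (39,166-SV cohort call set)
#'
#' Counts (`n`) and summed lengths in bp (`total_length`) per SV type
#' and length bin for the cohort's non-redundant call set. Summing the
#' DEL rows gives the 20.65 Mb of deleted sequence and the 32,750 DEL
#' total; insertions all fall in the first bin (50–132 bp inserted
#' sequence, 243,903 bp in total).
#'
#' @return tibble with `sv_type`, `bin`, `n`, `total_length`.
#' @export
gzp_length_bins <- function() {
  tribble(
    ~sv_type, ~bin, ~n, ~total_length,
    "DEL", "50-1000 bp", 29326L, 8397430,
    "DEL", "1001-10000 bp", 3293L, 10531040,
    "DEL", "10001-100000 bp", 131L, 1722145,
    "DUP", "50-1000 bp", 2080L, 454370,
    "DUP", "1001-10000 bp", 551L, 1912944,
    "DUP", "10001-100000 bp", 116L, 2367314,
    "INS", "50-1000 bp", 3268L, 243903,
    "INS", "1001-10000 bp", 0L, 0,
    "INS", "10001-100000 bp", 0L, 0,
    "INV", "50-1000 bp", 120L, 58038,
    "INV", "1001-10000 bp", 180L, 754322,
    "INV", "10001-100000 bp", 101L, 1338534
  )
}

#' Reference type counts of the cohort call set
#'
#' The 39,166 non-redundant SVs by type: 32,750 deletions, 3,268
#' insertions, 2,747 tandem duplications, 401 inversions.
#'
#' @return tibble with `sv_type`, `n`.
#' @export
gzp_type_counts <- function() {
  tibble(sv_type = c("DEL", "INS", "DUP", "INV"),
         n = c(32750L, 3268L, 2747L, 401L))
}

#' Reference gene-overlap marginals of the cohort call set
#'
#' Gene counts behind the conserved-gene depletion test: 25,880
#' annotated genes of which 7,881 contain or neighbour an SV, and 437
#' conserved (core eukaryotic) genes of which 112 do.
#'
#' @return named list of the four counts.
#' @export
gzp_gene_counts <- function() {
  list(n_genes_total = 25880L, n_genes_with_sv = 7881L,
       n_conserved_total = 437L, n_conserved_with_sv = 112L)
}

#' Reference candidate SVs in fertility- and growth-related genes
#'
#' The cohort's reported Guizhou-specific SVs falling in genes tied to
#' reproduction (GO terms) or the oxytocin signalling pathway, with
#' their printed coordinates. Under the package's coordinate
#' convention the printed length equals `end - start` for every row
#' except GZsv06434, whose published length (730) exceeds its
#' coordinate span by 2 bp; the published value is kept as printed.
#'
#' @return tibble with `sv_id`, `chrom`, `start`, `end`, `length`,
#'   `sv_type`, `gene_id`, `symbol`, `location`.
#' @export
gzp_candidate_svs <- function() {
  tribble(
    ~sv_id, ~chrom, ~start, ~end, ~length, ~sv_type, ~gene_id, ~symbol, ~location,
    "GZsv12513", "6", 20311318, 20311590, 272, "DEL", "ENSSSCG00000002799", "CNOT1", "Intron",
    "GZsv11540", "5", 78225835, 78226139, 304, "DEL", "ENSSSCG00000020864", "VDR", "Intron",
    "GZsv18234", "8", 113860056, 113860306, 250, "DEL", "ENSSSCG00000009148", "LEF1", "Intron",
    "GZsv24487", "12", 22838005, 22838322, 317, "DEL", "ENSSSCG00000017505", "MED1", "Intron",
    "GZsv28563", "14", 15027500, 15027652, 152, "DUP", "ENSSSCG00000023666", "CTSB", "Intron",
    "GZsv34554", "16", 48808965, 48809055, 90, "DEL", "ENSSSCG00000016976", "ZNF366", "Intron",
    "GZsv34801", "16", 66140226, 66140303, 77, "DEL", "ENSSSCG00000028875", "HAVCR2", "Intron",
    "GZsv04997", "2", 96288258, 96288329, 71, "DEL", "ENSSSCG00000014149", "MEF2C", "Intron",
    "GZsv06434", "3", 23971756, 23972484, 730, "INV", "ENSSSCG00000007839", "EEF2K", "Intron",
    "GZsv12631", "6", 28764371, 28764445, 74, "DEL", "ENSSSCG00000029578", "NFATC3", "Intron",
    "GZsv13502", "6", 106214603, 106214934, 331, "DEL", "ENSSSCG00000021893", "ROCK1", "Intron",
    "GZsv14469", "6", 165382096, 165383623, 1527, "DEL", "ENSSSCG00000003909", "novel", "Intron",
    "GZsv16830", "8", 11130507, 11130784, 277, "DEL", "ENSSSCG00000008742", "CD38", "3'UTR",
    "GZsv20391", "9", 98239262, 98239451, 189, "DEL", "ENSSSCG00000015402", "CACNA2D1", "Intron",
    "GZsv24985", "12", 49955326, 49955592, 266, "DEL", "ENSSSCG00000017873", "CAMKK1", "Upstream",
    "GZsv27142", "13", 137089754, 137089859, 105, "INS", "ENSSSCG00000027952", "ADCY5", "Intron",
    "GZsv27144", "13", 137107559, 137108002, 443, "DEL", "ENSSSCG00000027952", "ADCY5", "Intron",
    "GZsv34990", "16", 74352283, 74352805, 522, "DEL", "ENSSSCG00000017101", "ADCY2", "Intron",
    "GZsv35481", "17", 17421770, 17421871, 101, "INS", "ENSSSCG00000007056", "PLCB1", "Intron",
    "GZsv35498", "17", 18213874, 18214792, 918, "DEL", "ENSSSCG00000007058", "PLCB4", "Intron",
    "GZsv36345", "18", 5484398, 5484686, 288, "DEL", "ENSSSCG00000016432", "PRKAG2", "Intron",
    "GZsv36357", "18", 6232010, 6232110, 100, "DEL", "ENSSSCG00000016450", "NOS3", "Upstream"
  )
}

#' Reference per-breed SV counts of the cohort call set
#'
#' Total and per-type SV counts for each of the sixteen breeds in the
#' cohort, grouped as Guizhou (GZP), other Chinese native (NPOG) and
#' European (EUP) pigs.
#'
#' @return tibble with `group`, `breed`, `total`, `DEL`, `DUP`, `INS`,
#'   `INV`.
#' @export
gzp_breed_counts <- function() {
  tribble(
    ~group, ~breed, ~total, ~DEL, ~DUP, ~INS, ~INV,
    "GZP", "KL", 15796L, 14044L, 448L, 1224L, 80L,
    "GZP", "QB", 15752L, 14124L, 434L, 1101L, 93L,
    "GZP", "GL", 17260L, 15415L, 471L, 1291L, 83L,
    "GZP", "XP", 28040L, 24352L, 1252L, 2177L, 259L,
    "GZP", "LB", 17028L, 15320L, 479L, 1128L, 101L,
    "NPOG", "NJ", 13844L, 12658L, 618L, 517L, 51L,
    "NPOG", "JH", 12712L, 11870L, 465L, 335L, 42L,
    "NPOG", "RC", 15167L, 14088L, 566L, 455L, 58L,
    "NPOG", "TI", 17773L, 16340L, 768L, 600L, 65L,
    "NPOG", "TC", 17305L, 15875L, 711L, 645L, 74L,
    "NPOG", "MP", 19598L, 17733L, 901L, 819L, 145L,
    "EUP", "DU", 10998L, 9739L, 659L, 545L, 55L,
    "EUP", "LA", 1983L, 1783L, 114L, 78L, 8L,
    "EUP", "LW", 10822L, 9784L, 520L, 482L, 36L,
    "EUP", "HP", 1559L, 1393L, 102L, 59L, 5L,
    "EUP", "BK", 7644L, 6951L, 369L, 297L, 27L
  )
}
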