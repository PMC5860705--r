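test_that("caller TSV ingest maps fields under the half-open convention", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\ttype\tsupport",
               "chr1\t100\t200\tDEL\t5",
               "chr1\t500\t900\tTRA\t9",
               "chr2\t-5\t100\tDEL\t4"), tmp)
  calls <- read_sv_calls(tmp, "tsv", sample_id = "s1", caller_id = "pindel")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$chrom, "1")          # "chr" prefix normalized away
  expect_equal(calls$start, 100)
  expect_equal(calls$end, 200)
  expect_equal(calls$length, 100)
  expect_equal(calls$support, 5)
  rej <- rejection_report(calls)
  expect_setequal(rej$reason, c("unsupported type", "negative coordinates"))
})

test_that("ingest is deterministic and validation enforces the invariants", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\ttype\tsupport",
               "1\t0\t49\tDEL\t3",      # below the 50 bp floor
               "1\t300\t200\tDEL\t3",   # inverted interval
               "1\t100\t600\tDUP\t3"), tmp)
  a <- read_sv_calls(tmp, "tsv", "s", "c")
  b <- read_sv_calls(tmp, "tsv", "s", "c")
  expect_identical(a, b)
  expect_identical(rejection_report(a), rejection_report(b))
  expect_setequal(rejection_report(a)$reason,
                  c("length below minimum", "end before start"))
  expect_equal(a$sv_type, "DUP")
})

test_that("caller table round trip reproduces random records field-for-field", {
  calls <- validate_sv_calls(random_calls(100, seed = 11))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_sv_calls(calls, tmp)
  back <- read_sv_calls(tmp, "tsv", sample_id = "s1", caller_id = "cA")
  expect_equal(nrow(back), nrow(calls))
  expect_setequal(call_key(back), call_key(calls))
  expect_equal(nrow(rejection_report(back)), 0)
})

test_that("population callset writers emit sorted records in both formats", {
  callset <- tibble(
    sv_id = c("SV00001", "SV00002", "SV00003"),
    chrom = c("2", "1", "1"), start = c(100L, 900L, 50L),
    end = c(300L, 1200L, 150L), sv_type = c("DEL", "DUP", "DEL"),
    length = c(200L, 300L, 100L), n_carriers = c(2L, 2L, 3L),
    carriers = list(c("a", "b"), c("a", "c"), c("a", "b", "c")),
    breeds = list("X", "X", c("X", "Y")), groups = list("G", "G", "G"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_population_callset(callset, tsv, "tsv")
  body <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(body$sv_id, c("SV00003", "SV00002", "SV00001"))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_population_callset(callset, vcf, "vcf")
  lines <- readLines(vcf)
  expect_equal(sum(!startsWith(lines, "#")), 3)
  back <- read_population_callset(vcf, "vcf")
  expect_equal(back$sv_id, c("SV00003", "SV00002", "SV00001"))
  expect_equal(back$start, c(50, 900, 100))

  dup <- callset
  dup$sv_id[2] <- "SV00001"
  expect_error(write_population_callset(dup, tsv, "tsv"), "duplicate")
})

test_that("empty callset writes a header-only file in both formats", {
  empty <- tibble(sv_id = character(), chrom = character(),
                  start = integer(), end = integer(), sv_type = character(),
                  length = integer(), n_carriers = integer(),
                  carriers = list(), breeds = list(), groups = list())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_population_callset(empty, tsv, "tsv")
  expect_equal(length(readLines(tsv)), 1)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_population_callset(empty, vcf, "vcf")
  expect_true(all(startsWith(readLines(vcf), "#")))
})

test_that("population callset TSV and VCF round-trip simulated records", {
  cfg <- sim_config(seed = 5, n_truth_svs = 300)
  truth <- simulate_truth(cfg)
  calls <- dplyr::bind_rows(lapply(cfg$callers, function(cl)
    simulate_caller_calls(truth, cfg, cl)))
  cons <- filter_calls(validate_sv_calls(calls)) %>%
    dplyr::group_split(sample_id) %>%
    purrr::map_dfr(caller_consensus, required_callers = cfg$callers)
  callset <- merge_across_samples(cons, sim_samples(cfg)) %>%
    select(-truth_id)
  expect_gt(nrow(callset), 100)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_population_callset(callset, tsv, "tsv")
  back <- read_population_callset(tsv, "tsv")
  expect_equal(back, sort_callset(callset), ignore_attr = TRUE)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_population_callset(callset, vcf, "vcf")
  backv <- read_population_callset(vcf, "vcf")
  cmp <- sort_callset(callset)
  expect_equal(backv$sv_id, cmp$sv_id)
  expect_equal(backv$start, cmp$start)
  expect_equal(backv$end, cmp$end)
  expect_equal(backv$sv_type, cmp$sv_type)
  expect_equal(backv$length, cmp$length)
  expect_equal(backv$carriers, cmp$carriers)
})

test_that("sample sheets, conserved id lists and genotype tables validate", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,breed,group,path_pindel,path_softsv",
               "s1,KL,GZP,a.tsv,b.tsv", "s2,XP,GZP,c.tsv,d.tsv"), csv)
  sheet <- read_sample_sheet(csv)
  expect_equal(nrow(sheet), 2)

  writeLines(c("sample_id,breed,group,path_pindel,path_softsv",
               "s1,KL,GZP,a.tsv,b.tsv", "s1,XP,GZP,c.tsv,d.tsv"), csv)
  expect_error(read_sample_sheet(csv), "duplicate")

  ids <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("G1", "", "# comment", "G2", "G1"), ids)
  expect_equal(read_conserved_ids(ids), c("G1", "G2"))

  gt <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("locus_id,population_id,n_II,n_ID,n_DD",
               "L1,XP,10,20,18", "L1,KL,0,0,0"), gt)
  expect_error(read_genotype_table(gt), "all-zero")
})

test_that("toy GFF3 parses into gene models with transcript counts", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\tsrc\tgene\t1001\t5000\t.\t+\t.\tID=GA;Name=GA;biotype=protein_coding",
    "1\tsrc\tmRNA\t1001\t5000\t.\t+\t.\tID=GA.t1;Parent=GA",
    "1\tsrc\texon\t1001\t1400\t.\t+\t.\tID=e1;Parent=GA.t1",
    "1\tsrc\tmRNA\t1001\t5000\t.\t+\t.\tID=GA.t2;Parent=GA",
    "1\tsrc\texon\t1001\t1600\t.\t+\t.\tID=e2;Parent=GA.t2",
    "1\tsrc\texon\t9001\t9400\t.\t+\t.\tID=orphan;Parent=MISSING"), gff)
  expect_warning(gs <- read_gene_models(gff, conserved_ids = c("GA", "ABSENT")),
                 "unresolved Parent")
  expect_equal(gs$genes$n_transcripts, 2)
  expect_equal(gs$genes$start, 1000)    # converted to 0-based
  expect_equal(gs$genes$end, 5000)
  expect_equal(sum(gs$genes$conserved), 1)  # intersection only
  expect_equal(nrow(gs$features), 2)
})

test_that("simulated gene models round-trip through GFF3 writer and reader", {
  cfg <- sim_config(seed = 9)
  gs <- simulate_gene_models(cfg, n_genes = 20)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(gs, gff)
  back <- read_gene_models(gff, conserved_ids = attr(gs, "conserved_ids"))
  ord <- match(back$genes$gene_id, gs$genes$gene_id)
  expect_equal(back$genes$start, gs$genes$start[ord])
  expect_equal(back$genes$end, gs$genes$end[ord])
  expect_equal(back$genes$strand, gs$genes$strand[ord])
  expect_equal(back$genes$n_transcripts, gs$genes$n_transcripts[ord])
  expect_equal(back$genes$conserved, gs$genes$conserved[ord])
  ftkey <- function(f) sort(paste(f$feature_type, f$transcript_id, f$chrom,
                                  f$start, f$end))
  expect_equal(ftkey(back$features), ftkey(gs$features))
})
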