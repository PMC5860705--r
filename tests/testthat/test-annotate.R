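sv_row <- function(id, chrom, s, e, type = "DEL") {
  tibble(sv_id = id, chrom = chrom, start = as.integer(s),
         end = as.integer(e), sv_type = type,
         length = as.integer(ifelse(type == "INS", 60, e - s)))
}

test_that("consequence classes follow the exonic > utr > intronic precedence", {
  gs <- toy_gene_set()
  # wholly inside the G1 intron [11000, 18000)
  intron <- classify_sv(sv_row("s1", "1", 12000, 12400), gs)
  expect_equal(intron$class, "intronic")
  expect_false(intron$lof)
  # overlaps the CDS part of exon 1
  cds <- classify_sv(sv_row("s2", "1", 10900, 11500), gs)
  expect_equal(cds$class, "exonic")
  expect_true(cds$lof)
  # touches only the 5' UTR
  utr <- classify_sv(sv_row("s3", "1", 10000, 10400), gs)
  expect_equal(utr$class, "utr")
  expect_true(utr$lof)
  # upstream of the + strand gene within 5 kb
  up <- classify_sv(sv_row("s4", "1", 6000, 6200), gs)
  expect_equal(up$class, "upstream")
  # the same position relative to a - strand gene is downstream
  dn <- classify_sv(sv_row("s5", "2", 1000, 1200), gs)
  expect_equal(dn$class, "downstream")
  # far from everything
  ig <- classify_sv(sv_row("s6", "1", 90000, 90500), gs)
  expect_equal(ig$class, "intergenic")
  expect_true(is.na(ig$gene_id))
})

test_that("classification agrees with a per-base feature lookup", {
  gs <- toy_gene_set()
  set.seed(17)
  for (i in 1:120) {
    type <- sample(c("DEL", "DUP", "INS"), 1)
    s <- sample(0:40000, 1)
    e <- if (type == "INS") s else s + sample(50:3000, 1)
    sv <- sv_row(paste0("r", i), sample(c("1", "2"), 1), s, e, type)
    got <- classify_sv(sv, gs) %>% arrange(gene_id) %>%
      select(gene_id, class)
    want <- per_base_classify(sv, gs) %>% arrange(gene_id)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("summary counts each SV once at its highest-precedence class", {
  gs <- toy_gene_set()
  cs <- bind_rows(sv_row("a", "1", 12000, 12400),   # intronic
                  sv_row("b", "1", 50000, 50100),   # intergenic
                  sv_row("c", "2", 50000, 50100),   # intergenic
                  sv_row("d", "1", 12500, 12700))   # intronic
  cons <- classify_sv(cs, gs)
  sm <- consequence_summary(cons, cs)
  expect_equal(sm$fraction[sm$class == "intronic"], 0.5)
  expect_equal(sm$fraction[sm$class == "intergenic"], 0.5)
  expect_equal(sum(sm$fraction), 1)
})

test_that("gene table counts distinct SVs per gene, zeros included", {
  gs <- toy_gene_set()
  cs <- bind_rows(sv_row("a", "1", 10900, 11500),
                  sv_row("b", "1", 12000, 12400),
                  sv_row("c", "1", 90000, 90100))
  gtab <- gene_sv_table(classify_sv(cs, gs), gs)
  expect_equal(gtab$sv_count[gtab$gene_id == "G1"], 2L)
  expect_equal(gtab$sv_count[gtab$gene_id == "G2"], 0L)
})

test_that("chi-square matches the textbook formula and stats::chisq.test", {
  res <- conserved_gene_test(112, 437, 7881, 25880)
  ref <- stats::chisq.test(res$observed, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  # identical proportions give exactly zero
  null <- conserved_gene_test(10, 100, 100, 1000)
  expect_equal(null$statistic, 0)

  # symmetric under transposing the table
  t1 <- svcohort:::chi2_2x2(matrix(c(5, 10, 20, 40) + 3, 2, 2))
  t2 <- svcohort:::chi2_2x2(t(matrix(c(5, 10, 20, 40) + 3, 2, 2)))
  expect_equal(t1$statistic, t2$statistic)

  set.seed(4)
  for (i in 1:50) {
    tab <- matrix(sample(5:200, 4), 2, 2)
    got <- svcohort:::chi2_2x2(tab)
    expect_equal(got$statistic, chi2_brute(tab), tolerance = 1e-9)
    expect_equal(got$expected, outer(rowSums(tab), colSums(tab)) / sum(tab),
                 ignore_attr = TRUE)
  }
  expect_error(conserved_gene_test(500, 437, 7881, 25880), "inconsistent")
})

test_that("spearman matches the rank formula, tie handling included", {
  perfect <- tibble(sv_count = 1:3, n_transcripts = 1:3)
  expect_equal(transcript_correlation(perfect)$rho, 1)
  expect_equal(transcript_correlation(perfect)$p_value, 0)
  rev3 <- tibble(sv_count = 1:3, n_transcripts = 3:1)
  expect_equal(transcript_correlation(rev3)$rho, -1)

  flat <- tibble(sv_count = c(2, 2, 2), n_transcripts = 1:3)
  expect_equal(transcript_correlation(flat)$status, "undefined")

  set.seed(12)
  for (i in 1:30) {
    df <- tibble(sv_count = sample(0:6, 60, replace = TRUE),
                 n_transcripts = sample(1:8, 60, replace = TRUE))
    got <- transcript_correlation(df)
    expect_equal(got$rho,
                 cor(df$sv_count, df$n_transcripts, method = "spearman"),
                 tolerance = 1e-9)
    expect_gte(got$rho, -1); expect_lte(got$rho, 1)
    # invariant under strictly monotone transforms
    tr <- df %>% mutate(sv_count = exp(sv_count),
                        n_transcripts = n_transcripts^3)
    expect_equal(transcript_correlation(tr)$rho, got$rho, tolerance = 1e-12)
  }
})

test_that("hotspot scan returns nothing for an empty call set and rejects bad windows", {
  empty <- tibble(sv_id = character(), chrom = character(), start = integer(),
                  end = integer(), sv_type = character(), length = integer())
  expect_equal(nrow(hotspot_scan(empty, c("1" = 1e7))), 0)
  one <- sv_row("a", "1", 100, 300)
  expect_error(hotspot_scan(one, c("1" = 1e7), window_bp = -1), "positive")
  expect_error(hotspot_scan(one, c("1" = 1e7), window_bp = 1e6,
                            step_bp = 2e6), "step_bp")
  expect_error(hotspot_scan(one, c("2" = 1e7)), "missing")
})

test_that("a strong planted enrichment is found and merged into one interval", {
  cfg <- sim_config(seed = 3, chrom_lengths = c("1" = 1e8),
                    n_truth_svs = 10000,
                    hotspot = list(chrom = "1", start = 2e7, end = 2.5e7,
                                   factor = 10))
  th <- simulate_truth(cfg) %>% mutate(sv_id = truth_id)
  hs <- hotspot_scan(th, cfg$chrom_lengths)
  expect_gte(nrow(hs), 1)
  cov <- sum(pmax(0, pmin(hs$end, 2.5e7) - pmax(hs$start, 2e7)))
  expect_gte(cov / 5e6, 0.8)
  expect_true(all(hs$max_z >= 3))
})
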