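test_that("length bins are closed at their upper boundaries", {
  cs <- tibble(sv_type = "DEL", length = c(50L, 1000L, 1001L, 10000L,
                                           10001L, 100000L, 100001L))
  tab <- length_bin_table(cs)
  del <- tab[tab$sv_type == "DEL", ]
  expect_equal(del$n, c(2L, 2L, 2L, 1L))
  expect_equal(del$bin, c("50-1000 bp", "1001-10000 bp",
                          "10001-100000 bp", ">100000"))
  # bins conserve the callset
  expect_equal(sum(tab$n), nrow(cs))
})

test_that("binning matches a brute-force predicate on random lengths", {
  set.seed(30)
  cs <- tibble(sv_type = sample(sv_types(), 1000, replace = TRUE),
               length = sample(50:150000, 1000, replace = TRUE))
  tab <- length_bin_table(cs)
  for (tp in sv_types()) {
    lens <- cs$length[cs$sv_type == tp]
    expect_equal(tab$n[tab$sv_type == tp],
                 c(sum(lens <= 1000), sum(lens > 1000 & lens <= 10000),
                   sum(lens > 10000 & lens <= 100000), sum(lens > 100000)))
    expect_equal(tab$total_length[tab$sv_type == tp & tab$bin == "50-1000 bp"],
                 sum(lens[lens <= 1000]))
  }
})

test_that("reference length-bin table reproduces the published aggregates", {
  ref <- gzp_length_bins()
  del <- ref[ref$sv_type == "DEL", ]
  expect_equal(sum(del$n), 32750)
  expect_equal(sum(del$total_length), 20650615)        # 20.65 Mb deleted
  expect_equal(round(100 * del$n[del$bin == "50-1000 bp"] / sum(del$n)), 90)
  expect_equal(sum(ref$total_length[ref$sv_type == "INS"]), 243903)
})

test_that("type composition percentages recompute from counts", {
  counts <- gzp_type_counts()
  cs <- tibble(sv_type = rep(counts$sv_type, counts$n))
  tc <- type_composition(cs)
  expect_equal(tc$percent[match(c("DEL", "INS", "INV"), tc$sv_type)],
               c(83.62, 8.34, 1.02))
  expect_equal(sum(tc$n), 39166)
  single <- type_composition(tibble(sv_type = rep("DEL", 7)))
  expect_equal(single$percent[single$sv_type == "DEL"], 100)
  expect_error(type_composition(tibble(sv_type = character())), "empty")
  set.seed(2)
  n <- sample(1:500, 4)
  rand <- type_composition(tibble(sv_type = rep(sv_types(), n)))
  expect_equal(rand$percent, round(100 * n / sum(n), 2))
})

test_that("chromosome distribution reports fractions and densities", {
  cs <- tibble(sv_id = as.character(1:4), chrom = c("1", "1", "1", "2"),
               start = c(10L, 20L, 30L, 40L), end = c(100L, 120L, 130L, 140L),
               sv_type = "DEL", length = 90L)
  cd <- chromosome_distribution(cs, c("1" = 2e6, "2" = 1e6))
  expect_equal(cd$percent, c(75, 25))
  expect_equal(sum(cd$fraction), 1)
  expect_equal(cd$density_per_mb, c(3 / 2, 1 / 1))
  expect_error(chromosome_distribution(cs, c("1" = 2e6)), "missing")
})

test_that("uniform placement yields densities proportional to length", {
  cfg <- sim_config(seed = 99, n_truth_svs = 4000,
                    chrom_lengths = c("1" = 2e7, "2" = 1e7, "3" = 1e7))
  th <- simulate_truth(cfg) %>% mutate(sv_id = truth_id)
  cd <- chromosome_distribution(th, cfg$chrom_lengths)
  # chr1 holds half the genome: its count is binomial(4000, 1/2)
  expect_lt(abs(cd$n[cd$chrom == "1"] - 2000), 3 * sqrt(4000 * 0.25))
})

test_that("covered length separates sums from unions", {
  two <- tibble(sv_id = c("a", "b"), chrom = "1", start = c(0L, 200L),
                end = c(100L, 300L), sv_type = "DEL", length = 100L)
  cl <- covered_length(two)
  expect_equal(cl$sum_bp[cl$sv_type == "total"], 200)
  expect_equal(cl$union_bp[cl$sv_type == "total"], 200)

  nested <- two %>% mutate(start = c(0L, 0L), end = c(100L, 100L))
  cl2 <- covered_length(nested)
  expect_equal(cl2$sum_bp[cl2$sv_type == "total"], 200)
  expect_equal(cl2$union_bp[cl2$sv_type == "total"], 100)

  # insertions count in sums but not in the reference union
  ins <- tibble(sv_id = "i", chrom = "1", start = 500L, end = 500L,
                sv_type = "INS", length = 80L)
  cl3 <- covered_length(bind_rows(two, ins))
  expect_equal(cl3$sum_bp[cl3$sv_type == "total"], 280)
  expect_equal(cl3$union_bp[cl3$sv_type == "total"], 200)
  expect_equal(cl3$union_bp[cl3$sv_type == "INS"], 0)

  # random sets against per-base union counting
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    s <- sample(0:2000, n, replace = TRUE)
    df <- tibble(sv_id = as.character(seq_len(n)),
                 chrom = sample(c("1", "2"), n, replace = TRUE),
                 start = s, end = s + sample(50:400, n, replace = TRUE),
                 sv_type = "DEL")
    df$length <- df$end - df$start
    got <- covered_length(df)
    per_base <- sum(vapply(c("1", "2"), function(ch) {
      sub <- df[df$chrom == ch, ]
      length(unique(unlist(Map(seq2, sub$start, sub$end - 1))))
    }, numeric(1)))
    expect_equal(got$union_bp[got$sv_type == "total"], per_base)
    expect_lte(got$union_bp[got$sv_type == "total"],
               got$sum_bp[got$sv_type == "total"])
  }
})

test_that("sequencing summary reproduces the published cohort aggregates", {
  sm <- sequencing_summary(gzp_sequencing_stats())
  expect_equal(sm$total[sm$metric == "raw_gb"], 578.03)
  expect_equal(sm$total[sm$metric == "clean_gb"], 545.40)
  expect_equal(sm$mean[sm$metric == "depth_x"], 11.93)
  one <- sequencing_summary(tibble(x = 3.14159))
  expect_equal(one$mean, one$total)
  set.seed(6)
  df <- tibble(a = runif(9, 0, 100), b = rpois(9, 30))
  got <- sequencing_summary(df)
  expect_equal(got$total, round(c(sum(df$a), sum(df$b)), 2))
  expect_equal(got$mean, round(c(mean(df$a), mean(df$b)), 2))
})

test_that("candidate SV lengths follow the printed coordinate convention", {
  tab <- gzp_candidate_svs()
  # every non-insertion row except the one known discordant published
  # length satisfies length = end - start
  chk <- tab[tab$sv_type != "INS" & tab$sv_id != "GZsv06434", ]
  expect_equal(chk$length, chk$end - chk$start)
  expect_equal(tab$length[tab$sv_id == "GZsv12513"], 272)
})
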