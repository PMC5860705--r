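test_that("support and chromosome filters match a brute-force predicate", {
  low <- tibble(sample_id = "s", caller_id = "c", chrom = "1", start = 0L,
                end = 100L, sv_type = "DEL", length = 100L, support = 2L)
  expect_equal(nrow(filter_calls(low)), 0)

  y <- low %>% mutate(chrom = "Y", support = 10L)
  expect_equal(nrow(filter_calls(y)), 0)
  expect_equal(filter_report(filter_calls(y))$n, c(1L, 0L))

  calls <- random_calls(50, seed = 3, chroms = c("1", "2", "Y"))
  kept <- filter_calls(calls)
  manual <- calls[calls$support >= 3 & calls$chrom != "Y", ]
  expect_setequal(call_key(kept), call_key(manual))
  expect_equal(nrow(calls), nrow(kept) + sum(filter_report(kept)$n))
})

test_that("overlap length matches per-base set intersection", {
  mk <- function(chrom, s, e) tibble(chrom = chrom, start = s, end = e)
  expect_equal(overlap_length(mk("1", 100, 200), mk("1", 100, 200)), 100L)
  expect_equal(overlap_length(mk("1", 100, 200), mk("1", 200, 300)), 0L)
  expect_equal(overlap_length(mk("1", 100, 200), mk("2", 100, 200)), 0L)

  set.seed(21)
  for (i in 1:200) {
    a <- mk(sample(c("1", "2"), 1), sample(0:500, 1), 0)
    a$end <- a$start + sample(0:300, 1)
    b <- mk(sample(c("1", "2"), 1), sample(0:500, 1), 0)
    b$end <- b$start + sample(0:300, 1)
    expect_equal(overlap_length(a, b), per_base_overlap(a, b))
  }
})

test_that("merge rule honours type, chromosome, threshold and INS window", {
  mk <- function(chrom, s, e, tp) tibble(chrom = chrom, start = s, end = e,
                                         sv_type = tp)
  # exactly 25 bp shared: mergeable under the >= 25 reading
  expect_true(mergeable(mk("1", 100, 200, "DEL"), mk("1", 175, 300, "DEL")))
  expect_false(mergeable(mk("1", 100, 200, "DEL"), mk("1", 176, 300, "DEL")))
  expect_false(mergeable(mk("1", 100, 200, "DEL"), mk("1", 150, 400, "DUP")))
  expect_false(mergeable(mk("1", 100, 200, "DEL"), mk("2", 100, 200, "DEL")))
  expect_true(mergeable(mk("1", 500, 500, "INS"), mk("1", 525, 525, "INS")))
  expect_false(mergeable(mk("1", 500, 500, "INS"), mk("1", 526, 526, "INS")))
})

test_that("chained merges collapse into one cluster by single linkage", {
  calls <- tibble(sample_id = "s", caller_id = c("a", "b", "a"),
                  chrom = "1", start = c(100L, 170L, 240L),
                  end = c(200L, 270L, 340L), sv_type = "DEL",
                  length = 100L, support = 5L)
  # A-B share 30 bp, B-C share 30 bp, A-C are disjoint
  cl <- cluster_calls(calls)
  expect_equal(length(unique(cl$cluster)), 1)

  other <- calls %>% mutate(chrom = c("1", "2", "3"))
  expect_equal(cluster_calls(other)$cluster, 1:3)
})

test_that("sweep clustering equals brute-force all-pairs closure", {
  for (seed in c(101, 202, 303)) {
    calls <- random_calls(120, seed = seed, span = 2e4)
    cl <- cluster_calls(calls)
    bf <- brute_force_clusters(calls)
    expect_equal(partition_of(call_key(calls)[order(call_key(calls))],
                              bf[order(call_key(calls))]),
                 partition_of(call_key(cl), cl$cluster))
    expect_equal(sum(table(cl$cluster)), nrow(calls))  # conservation
  }
})

test_that("clustering is invariant to input row order", {
  calls <- random_calls(80, seed = 7, span = 1e4)
  set.seed(1)
  perm <- calls[sample(nrow(calls)), ]
  a <- cluster_calls(calls)
  b <- cluster_calls(perm)
  expect_equal(partition_of(call_key(a), a$cluster),
               partition_of(call_key(b), b$cluster))
})

test_that("caller consensus keeps only variants seen by every caller", {
  solo <- tibble(sample_id = "s", caller_id = "a", chrom = "1",
                 start = 1000L, end = 1500L, sv_type = "DEL",
                 length = 500L, support = 5L)
  expect_equal(nrow(caller_consensus(solo, required_callers = c("a", "b"))), 0)

  both <- bind_rows(solo, solo %>% mutate(caller_id = "b"))
  cons <- caller_consensus(both, required_callers = c("a", "b"))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 1000)
  expect_equal(cons$end, 1500)   # identical members leave the span unchanged
  expect_equal(cons$callers, "a,b")
  expect_error(caller_consensus(both, required_callers = "a"),
               "at least two")
})

test_that("perfect callers recover the truth exactly, sample by sample", {
  cfg <- sim_config(seed = 31, n_truth_svs = 200, detection_prob = 1,
                    jitter_bp = 0, fp_per_mb = 0, support_lambda = 10)
  truth <- simulate_truth(cfg)
  calls <- bind_rows(lapply(cfg$callers, function(cl)
    simulate_caller_calls(truth, cfg, cl)))
  # support filtering is off: this checks the detection path in isolation
  f <- filter_calls(validate_sv_calls(calls), min_support = 1)
  cons <- f %>% dplyr::group_split(sample_id) %>%
    purrr::map_dfr(caller_consensus, required_callers = cfg$callers)
  # every carried truth SV is recovered in its sample's consensus set, and
  # the consensus count equals the number of truth clusters carried (truth
  # SVs that themselves satisfy the merge rule collapse into one record)
  carried <- truth %>%
    tidyr::unnest_longer(carriers, values_to = "sample_id") %>%
    distinct(truth_id, sample_id)
  recovered <- cons %>%
    tidyr::separate_rows(truth_id, sep = ";") %>%
    distinct(truth_id, sample_id)
  expect_setequal(paste(recovered$truth_id, recovered$sample_id),
                  paste(carried$truth_id, carried$sample_id))
  per_sample <- cons %>% count(sample_id)
  for (s in unique(carried$sample_id)) {
    sub <- truth[purrr::map_lgl(truth$carriers, function(cc) s %in% cc), ]
    n_clusters <- length(unique(brute_force_clusters(sub)))
    expect_equal(per_sample$n[per_sample$sample_id == s], n_clusters)
  }
})

test_that("consensus of its own output is a fixed point", {
  cfg <- sim_config(seed = 13, n_truth_svs = 150)
  truth <- simulate_truth(cfg)
  calls <- bind_rows(lapply(cfg$callers, function(cl)
    simulate_caller_calls(truth, cfg, cl)))
  f <- filter_calls(validate_sv_calls(calls))
  one <- f %>% filter(sample_id == sample_id[1])
  cons <- caller_consensus(one, required_callers = cfg$callers)
  # feed each consensus record back as if reported by both pseudo-callers
  again <- bind_rows(cons %>% mutate(caller_id = "p1"),
                     cons %>% mutate(caller_id = "p2")) %>%
    mutate(support = 5L) %>%
    caller_consensus(required_callers = c("p1", "p2"))
  expect_equal(nrow(again), nrow(cons))
  expect_equal(again$start, cons$start)
  expect_equal(again$end, cons$end)
  expect_equal(again$sv_type, cons$sv_type)
})
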