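#' Simulation configuration for a synthetic SV cohort
#'
#' Bundles every knob of the cohort simulator. The defaults emulate the
#' structure of a livestock resequencing cohort analysed with a
#' two-caller consensus design: a small multi-chromosome toy genome, a
#' truth set dominated by deletions (84% DEL / 8% INS / 7% DUP / 1%
#' INV) with per-type length-bin weights matching what such call sets
#' report, three population groups each split into breeds, a carrier
#' model mixing cohort-wide, group-specific and breed-specific
#' variants, and two independent noisy callers with breakpoint jitter,
#' misses and false positives. Insertions draw their inserted length
#' uniformly from 50–132 bp, the short range typical for read-pair
#' insertion calls.
#'
#' @param seed integer seed; every generator derives its stream from it
#'   deterministically.
#' @param chrom_lengths named vector of toy chromosome lengths in bp.
#' @param n_truth_svs number of truth SVs.
#' @param type_weights named probabilities over DEL/INS/DUP/INV.
#' @param length_bins length-bin boundaries in bp.
#' @param bin_weights per-type list of bin probabilities (lengths are
#'   log-uniform within the sampled bin).
#' @param ins_length_range inserted-length range for INS.
#' @param groups group labels.
#' @param breeds_per_group breeds per group (recycled over groups).
#' @param samples_per_breed animals per breed.
#' @param carrier_prob per-sample carrier probability of a shared SV.
#' @param group_specific_fraction,breed_specific_fraction fractions of
#'   truth SVs restricted to one group / one breed.
#' @param specific_carrier_prob carrier probability within the
#'   restricted label.
#' @param detection_prob,jitter_bp,fp_per_mb,support_lambda caller
#'   model, applied to every caller: per-call detection probability,
#'   uniform breakpoint jitter half-width in bp, false-positive rate
#'   per Mb of genome, and the Poisson rate of `support = 1 +
#'   rpois(support_lambda)`.
#' @param callers caller identifiers (at least two).
#' @param hotspot optional list `(chrom, start, end, factor)` giving a
#'   region whose SV placement rate is multiplied by `factor`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c("1" = 1e7, "2" = 1e7,
                                         "3" = 1e7, "X" = 1e7),
                       n_truth_svs = 2000,
                       type_weights = c(DEL = 0.84, INS = 0.08,
                                        DUP = 0.07, INV = 0.01),
                       length_bins = c(50, 1000, 10000, 100000),
                       bin_weights = list(
                         DEL = c(29326, 3293, 131) / 32750,
                         DUP = c(2080, 551, 116) / 2747,
                         INS = c(1, 0, 0),
                         INV = c(120, 180, 101) / 401),
                       ins_length_range = c(50, 132),
                       groups = c("GZP", "NPOG", "EUP"),
                       breeds_per_group = 2,
                       samples_per_breed = 3,
                       carrier_prob = 0.3,
                       group_specific_fraction = 0.15,
                       breed_specific_fraction = 0.05,
                       specific_carrier_prob = 0.5,
                       detection_prob = 0.9,
                       jitter_bp = 10,
                       fp_per_mb = 1,
                       support_lambda = 5,
                       callers = c("pindel", "softsv"),
                       hotspot = NULL) {
  stopifnot(abs(sum(type_weights) - 1) < 1e-8,
            all(vapply(bin_weights, function(w) abs(sum(w) - 1) < 1e-8,
                       logical(1))),
            carrier_prob >= 0, carrier_prob <= 1,
            detection_prob >= 0, detection_prob <= 1,
            jitter_bp >= 0, length(callers) >= 2)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d: %d truth SVs on %d chromosomes (%.0f Mb), %d samples, callers %s\n",
              x$seed, x$n_truth_svs, length(x$chrom_lengths),
              sum(x$chrom_lengths) / 1e6, nrow(sim_samples(x)),
              paste(x$callers, collapse = "/")))
  invisible(x)
}

#' Sample sheet of a simulated cohort
#'
#' @param config a `sim_config`.
#' @return tibble with `sample_id`, `breed`, `group`.
#' @export
sim_samples <- function(config) {
  nb <- rep_len(config$breeds_per_group, length(config$groups))
  purrr::map2_dfr(config$groups, nb, function(g, k) {
    purrr::map_dfr(seq_len(k), function(j) {
      breed <- sprintf("%s_B%d", g, j)
      tibble(sample_id = sprintf("%s_S%d", breed,
                                 seq_len(config$samples_per_breed)),
             breed = breed, group = g)
    })
  })
}

# sample one SV length for a non-INS type: pick a bin, then log-uniform
sim_lengths <- function(type, n, config) {
  if (n == 0) return(integer())
  if (type == "INS") {
    r <- config$ins_length_range
    return(as.integer(floor(runif(n, r[1], r[2] + 1))))
  }
  b <- config$length_bins
  lo <- c(b[1], b[-c(1, length(b))] + 1)
  hi <- b[-1]
  bin <- sample.int(length(lo), n, replace = TRUE,
                    prob = config$bin_weights[[type]])
  as.integer(pmin(hi[bin], pmax(lo[bin], round(
    exp(runif(n, log(lo[bin]), log(hi[bin])))))))
}

#' Simulate a truth SV set with carriers
#'
#' Draws SV types from the configured weights, lengths from the
#' per-type bin model, placements uniformly along the genome (with
#' optional hotspot enrichment), and carrier sets according to
#' provenance: most SVs are cohort-wide ("shared", each sample a
#' carrier independently), a fraction segregate only within one group,
#' a smaller fraction only within one breed. Every SV is guaranteed at
#' least one carrier. Deterministic given `config$seed`.
#'
#' @param config a `sim_config`.
#' @return tibble with `truth_id`, `chrom`, `start`, `end`, `sv_type`,
#'   `length`, `provenance`, `spec_label` (restricted group/breed, `NA`
#'   for shared), `in_hotspot`, list-column `carriers`, `n_carriers`.
#' @export
simulate_truth <- function(config) {
  set.seed(config$seed)
  samples <- sim_samples(config)
  n <- config$n_truth_svs
  types <- sample(names(config$type_weights), n, replace = TRUE,
                  prob = config$type_weights)
  lens <- integer(n)
  for (tp in unique(types)) {
    lens[types == tp] <- sim_lengths(tp, sum(types == tp), config)
  }
  if (any(lens > max(config$chrom_lengths))) {
    abort("simulated SV longer than every chromosome")
  }
  # placement: segments are chromosomes, with the hotspot interval as an
  # extra segment whose sampling mass is multiplied by its factor
  segs <- tibble(chrom = names(config$chrom_lengths),
                 start = 0, end = unname(config$chrom_lengths), w = 1)
  hs <- config$hotspot
  if (!is.null(hs)) {
    segs <- bind_rows(segs, tibble(chrom = normalize_chrom(hs$chrom),
                                   start = hs$start, end = hs$end,
                                   w = hs$factor - 1))
  }
  mass <- (segs$end - segs$start) * segs$w
  seg_i <- sample.int(nrow(segs), n, replace = TRUE, prob = mass)
  chrom <- segs$chrom[seg_i]
  max_start <- pmin(segs$end[seg_i],
                    config$chrom_lengths[chrom]) - ifelse(types == "INS", 0, lens)
  max_start <- pmax(segs$start[seg_i], max_start)  # long SVs may start in-segment
  start <- as.integer(floor(segs$start[seg_i] +
                              runif(n) * (max_start - segs$start[seg_i])))
  # keep the interval on the chromosome
  start <- pmin(start, as.integer(config$chrom_lengths[chrom] -
                                    ifelse(types == "INS", 0, lens)))
  end <- ifelse(types == "INS", start, start + lens)

  prov <- sample(c("breed_specific", "group_specific", "shared"), n,
                 replace = TRUE,
                 prob = c(config$breed_specific_fraction,
                          config$group_specific_fraction,
                          1 - config$breed_specific_fraction -
                            config$group_specific_fraction))
  breeds <- unique(samples$breed)
  spec_label <- ifelse(prov == "group_specific",
                       sample(config$groups, n, replace = TRUE),
                       ifelse(prov == "breed_specific",
                              sample(breeds, n, replace = TRUE),
                              NA_character_))
  carriers <- purrr::map(seq_len(n), function(i) {
    eligible <- switch(prov[i],
      shared = samples$sample_id,
      group_specific = samples$sample_id[samples$group == spec_label[i]],
      breed_specific = samples$sample_id[samples$breed == spec_label[i]])
    p <- if (prov[i] == "shared") config$carrier_prob else
      config$specific_carrier_prob
    hit <- eligible[runif(length(eligible)) < p]
    if (length(hit) == 0) hit <- sample(eligible, 1)
    sort(hit)
  })
  in_hs <- if (is.null(hs)) rep(FALSE, n) else {
    chrom == normalize_chrom(hs$chrom) & start >= hs$start & start < hs$end
  }
  tibble(truth_id = sprintf("T%0*d", max(4L, nchar(n)), seq_len(n)),
         chrom = chrom, start = start, end = as.integer(end),
         sv_type = types, length = lens, provenance = prov,
         spec_label = spec_label, in_hotspot = in_hs,
         carriers = carriers, n_carriers = lengths(carriers)) %>%
    arrange_sv()
}

#' Simulate one caller's raw calls for every sample
#'
#' For each (carrier, truth SV) pair the caller reports a call with
#' probability `detection_prob`; reported breakpoints are jittered
#' independently by a uniform integer offset in `[-jitter_bp,
#' jitter_bp]` (insertions keep their true inserted length but a
#' jittered breakpoint), and read-pair support is `1 +
#' rpois(support_lambda)`. False positives are added per sample as a
#' Poisson number of random intervals (rate `fp_per_mb` per Mb of
#' genome, first-bin lengths, types from the truth weights) with no
#' `truth_id`. The random stream is derived deterministically from
#' `config$seed` and the caller's position in `config$callers`, so the
#' two callers err independently but reproducibly.
#'
#' @param truth tibble from [simulate_truth()].
#' @param config a `sim_config`.
#' @param caller_id one of `config$callers`.
#' @return call tibble (columns as [read_sv_calls()] plus `truth_id`).
#' @export
simulate_caller_calls <- function(truth, config, caller_id) {
  ci <- match(caller_id, config$callers)
  if (is.na(ci)) abort(paste0("unknown caller: ", caller_id))
  set.seed(config$seed * 131L + 7919L * ci)
  samples <- sim_samples(config)
  j <- config$jitter_bp
  pairs <- truth %>%
    select("truth_id", "chrom", "start", "end", "sv_type", "length",
           "carriers") %>%
    tidyr::unnest_longer("carriers", values_to = "sample_id")
  det <- runif(nrow(pairs)) < config$detection_prob
  pairs <- pairs[det, , drop = FALSE]
  m <- nrow(pairs)
  js <- sample.int(2 * j + 1, m, replace = TRUE) - j - 1L
  je <- sample.int(2 * j + 1, m, replace = TRUE) - j - 1L
  ins <- pairs$sv_type == "INS"
  start <- pmax(0L, pairs$start + js)
  end <- ifelse(ins, start, pmax(start, pairs$end + je))
  calls <- tibble(
    sample_id = pairs$sample_id, caller_id = caller_id,
    chrom = pairs$chrom, start = start, end = as.integer(end),
    sv_type = pairs$sv_type,
    length = as.integer(ifelse(ins, pairs$length, end - start)),
    support = 1L + rpois(m, config$support_lambda),
    truth_id = pairs$truth_id)

  genome_mb <- sum(config$chrom_lengths) / 1e6
  fp <- purrr::map_dfr(samples$sample_id, function(s) {
    nfp <- rpois(1, config$fp_per_mb * genome_mb)
    if (nfp == 0) return(NULL)
    tp <- sample(names(config$type_weights), nfp, replace = TRUE,
                 prob = config$type_weights)
    len <- as.integer(floor(runif(nfp, 50, 1001)))
    ch <- sample(names(config$chrom_lengths), nfp, replace = TRUE,
                 prob = config$chrom_lengths)
    st <- as.integer(floor(runif(nfp) * (config$chrom_lengths[ch] - len)))
    tibble(sample_id = s, caller_id = caller_id, chrom = ch, start = st,
           end = as.integer(ifelse(tp == "INS", st, st + len)),
           sv_type = tp, length = len,
           support = 1L + rpois(nfp, config$support_lambda),
           truth_id = NA_character_)
  })
  bind_rows(calls, fp) %>% arrange(.data$sample_id) %>% arrange_sv()
}

#' Simulate a biallelic genotype count table
#'
#' Hardy–Weinberg sampling of II/ID/DD genotype class counts at
#' `n_loci` markers across populations of the given sizes, at true
#' deletion-allele frequencies either supplied (loci x populations
#' matrix) or drawn uniformly from `freq_range`. The defaults mirror a
#' PCR genotyping panel: 6 markers scored in 8 breed populations of
#' 24–48 animals (284 in total).
#'
#' @param config a `sim_config` (only its seed is used).
#' @param n_loci number of markers.
#' @param pop_sizes named integer vector of animals per population.
#' @param p_D optional matrix (`n_loci` x populations) of true D-allele
#'   frequencies.
#' @param freq_range range for random true frequencies.
#' @return tibble with `locus_id`, `population_id`, `n_II`, `n_ID`,
#'   `n_DD` and the true frequency `p_D_true`.
#' @export
simulate_genotype_table <- function(config, n_loci = 6,
                                    pop_sizes = c(XP = 48, KL = 34, QB = 30,
                                                  LB = 32, GL = 24, LW = 48,
                                                  DU = 24, RC = 44),
                                    p_D = NULL, freq_range = c(0.1, 0.9)) {
  set.seed(config$seed * 131L + 104729L)
  pops <- names(pop_sizes)
  if (is.null(p_D)) {
    p_D <- matrix(runif(n_loci * length(pops), freq_range[1], freq_range[2]),
                  n_loci, length(pops))
  }
  purrr::map_dfr(seq_len(n_loci), function(l) {
    purrr::map_dfr(seq_along(pops), function(pi) {
      p <- p_D[l, pi]
      cnt <- rmultinom(1, pop_sizes[[pi]],
                       prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
      tibble(locus_id = sprintf("L%02d", l), population_id = pops[pi],
             n_II = cnt[1], n_ID = cnt[2], n_DD = cnt[3], p_D_true = p)
    })
  })
}

#' Simulate toy gene models
#'
#' Lays non-overlapping genes along the configured chromosomes with
#' random intergenic gaps, gives each 1–10 transcripts (all spanning
#' the gene) built from 2–6 exons, and carves a CDS with flanking
#' 5'/3' UTR pieces out of the exon chain. A random subset of genes is
#' designated as the conserved ("core") set. Deterministic given
#' `config$seed`.
#'
#' @param config a `sim_config`.
#' @param n_genes number of genes to place (fewer if the genome fills).
#' @param conserved_fraction fraction of genes flagged conserved.
#' @return a `gene_set` (see [read_gene_models()]); the conserved gene
#'   ids are also attached as attribute `"conserved_ids"`.
#' @export
simulate_gene_models <- function(config, n_genes = 80,
                                 conserved_fraction = 0.2) {
  set.seed(config$seed * 131L + 224737L)
  chroms <- names(config$chrom_lengths)
  genes <- list(); txs <- list(); fts <- list()
  gi <- 0L
  per_chrom <- ceiling(n_genes / length(chroms))
  for (ch in chroms) {
    pos <- 0
    for (k in seq_len(per_chrom)) {
      pos <- pos + floor(runif(1, 2e4, 1e5))           # intergenic gap
      glen <- floor(runif(1, 5e3, 5e4))
      if (pos + glen > config$chrom_lengths[[ch]] || gi >= n_genes) break
      gi <- gi + 1L
      gid <- sprintf("GENE%04d", gi)
      strand <- sample(c("+", "-"), 1)
      g_s <- as.integer(pos); g_e <- as.integer(pos + glen)
      n_tx <- sample.int(10, 1, prob = 0.6^(1:10))
      genes[[gi]] <- tibble(gene_id = gid, symbol = gid,
                            biotype = "protein_coding", chrom = ch,
                            strand = strand, start = g_s, end = g_e)
      for (t in seq_len(n_tx)) {
        tid <- sprintf("%s.t%d", gid, t)
        txs[[length(txs) + 1L]] <- tibble(transcript_id = tid, gene_id = gid,
                                          chrom = ch, strand = strand,
                                          start = g_s, end = g_e)
        # short exons on a coarse grid: introns dominate, as in real genes
        grid <- seq(g_s, g_e - 600L, by = 800L)
        n_ex <- sample(2:min(6L, length(grid)), 1)
        ex_s <- as.integer(sort(sample(grid, n_ex)))
        ex_e <- as.integer(ex_s + floor(runif(n_ex, 100, 500)))
        cds_s <- as.integer(floor((ex_s[1] + ex_e[1]) / 2))
        cds_e <- as.integer(ceiling((ex_s[n_ex] + ex_e[n_ex]) / 2))
        piece <- function(type, lo, hi) {
          s <- pmax(ex_s, lo); e <- pmin(ex_e, hi)
          keep <- e > s
          if (!any(keep)) return(NULL)
          tibble(feature_type = type, transcript_id = tid, gene_id = gid,
                 chrom = ch, strand = strand, start = as.integer(s[keep]),
                 end = as.integer(e[keep]))
        }
        utr_left <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
        utr_right <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
        fts[[length(fts) + 1L]] <- bind_rows(
          tibble(feature_type = "exon", transcript_id = tid, gene_id = gid,
                 chrom = ch, strand = strand, start = as.integer(ex_s),
                 end = as.integer(ex_e)),
          piece("CDS", cds_s, cds_e),
          piece(utr_left, g_s, cds_s),
          piece(utr_right, cds_e, g_e))
      }
      pos <- pos + glen
    }
  }
  genes <- bind_rows(genes)
  txs <- bind_rows(txs)
  fts <- bind_rows(fts)
  genes <- genes %>%
    left_join(txs %>% count(.data$gene_id, name = "n_transcripts"),
              by = "gene_id")
  conserved_ids <- sort(sample(genes$gene_id,
                               round(conserved_fraction * nrow(genes))))
  genes$conserved <- genes$gene_id %in% conserved_ids
  out <- structure(list(genes = arrange_sv(genes), transcripts = txs,
                        features = fts), class = "gene_set")
  attr(out, "conserved_ids") <- conserved_ids
  out
}

# analytic survival probability of a jittered call against the length
# floor: reported length = L + (je - js), je/js iid uniform{-j..j}
p_length_survives <- function(L, sv_type, jitter_bp, min_length = 50) {
  j <- jitter_bp
  vapply(seq_along(L), function(i) {
    if (sv_type[i] == "INS" || j == 0) return(as.numeric(L[i] >= min_length))
    d <- seq(-2 * j, 2 * j)
    pd <- (2 * j + 1 - abs(d)) / (2 * j + 1)^2
    sum(pd[L[i] + d >= min_length])
  }, numeric(1))
}

#' Analytic recall expectation from truth bookkeeping
#'
#' For each truth SV, the probability that it survives the full
#' pipeline — per caller, a carrier's call must be detected
#' (`detection_prob`), pass the support filter (`support >=
#' min_support` under the shifted-Poisson support model) and pass the
#' ingest length floor after jitter; a sample yields a consensus call
#' when both callers succeed; the SV enters the population set when at
#' least `min_individuals` carriers do. Returns the expected number of
#' recovered truth SVs and its binomial standard deviation, the
#' yardstick for measured pipeline recall.
#'
#' @param truth tibble from [simulate_truth()].
#' @param config the `sim_config` used to generate the calls.
#' @param min_support support filter threshold (default 3).
#' @param min_individuals population merge threshold (default 2).
#' @param min_length ingest length floor (default 50).
#' @return one-row tibble: `expected`, `sd`, `n_truth`.
#' @export
expected_recall <- function(truth, config, min_support = 3,
                            min_individuals = 2, min_length = 50) {
  p_supp <- 1 - stats::ppois(min_support - 2, config$support_lambda)
  p_len <- p_length_survives(truth$length, truth$sv_type, config$jitter_bp,
                             min_length)
  p_call <- config$detection_prob * p_supp * p_len
  p_sample <- p_call^2                    # both callers, independently
  p_keep <- purrr::map2_dbl(truth$n_carriers, p_sample, function(nc, ps) {
    1 - stats::pbinom(min_individuals - 1, nc, ps)
  })
  tibble(expected = sum(p_keep),
         sd = sqrt(sum(p_keep * (1 - p_keep))),
         n_truth = nrow(truth))
}
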