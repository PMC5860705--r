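# Independent oracles and fixture generators used across test files.
# These deliberately use different algorithms from the package code
# (per-base set arithmetic, all-pairs graph closure, long-hand formulas).

suppressMessages({
  library(dplyr)
  library(tibble)
})

# random valid SV calls on a small genome
random_calls <- function(n, seed, chroms = c("1", "2"), span = 1e5,
                         types = c("DEL", "DUP", "INV", "INS"),
                         sample_id = "s1", caller_id = "cA") {
  set.seed(seed)
  sv_type <- sample(types, n, replace = TRUE)
  len <- sample(50:2000, n, replace = TRUE)
  start <- sample(0:span, n, replace = TRUE)
  end <- ifelse(sv_type == "INS", start, start + len)
  tibble(sample_id = sample_id, caller_id = caller_id,
         chrom = sample(chroms, n, replace = TRUE),
         start = start, end = as.integer(end), sv_type = sv_type,
         length = as.integer(len),
         support = sample(1:12, n, replace = TRUE))
}

# per-base overlap: count shared positions explicitly
per_base_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq2(a$start, a$end - 1), seq2(b$start, b$end - 1)))
}
seq2 <- function(from, to) if (to < from) integer() else seq(from, to)

# all-pairs single-linkage clustering via explicit graph closure (BFS);
# the pairwise rule is re-stated here from scratch so the oracle shares
# no code with the package implementation
brute_force_clusters <- function(calls, min_overlap = 25, ins_window = 25) {
  n <- nrow(calls)
  s <- calls$start; e <- calls$end
  same <- outer(toupper(sub("^chr", "", calls$chrom, ignore.case = TRUE)),
                toupper(sub("^chr", "", calls$chrom, ignore.case = TRUE)),
                "==") & outer(calls$sv_type, calls$sv_type, "==")
  ov <- pmin(outer(e, e, pmin) - outer(s, s, pmax),
             .Machine$integer.max)
  is_ins <- calls$sv_type == "INS"
  near <- abs(outer(s, s, "-")) <= ins_window
  adj <- same & ifelse(outer(is_ins, is_ins, "&"), near, ov >= min_overlap)
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# cluster assignments as canonical partitions (set of sorted member keys)
partition_of <- function(keys, cluster) {
  unname(sort(vapply(split(keys, cluster),
                     function(k) paste(sort(k), collapse = "|"),
                     character(1))))
}

# call keys that survive row reordering
call_key <- function(calls) {
  paste(calls$sample_id, calls$caller_id, calls$chrom, calls$start,
        calls$end, calls$sv_type, calls$length, calls$support, sep = ":")
}

# long-hand polymorphism information content via the double sum
pic_brute <- function(p) {
  k <- length(p)
  acc <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) acc <- acc + 2 * p[i]^2 * p[j]^2
  }
  1 - sum(p^2) - acc
}

# long-hand Pearson chi-square on any table
chi2_brute <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# a tiny deterministic gene set built by hand: one gene on "1" at
# [10000, 20000) with two exons, CDS and UTRs, plus a second gene on "2"
toy_gene_set <- function() {
  genes <- tibble(
    gene_id = c("G1", "G2"), symbol = c("G1", "G2"),
    biotype = "protein_coding", chrom = c("1", "2"),
    strand = c("+", "-"), start = c(10000L, 5000L), end = c(20000L, 9000L),
    n_transcripts = c(1L, 1L), conserved = c(TRUE, FALSE))
  transcripts <- tibble(
    transcript_id = c("G1.t1", "G2.t1"), gene_id = c("G1", "G2"),
    chrom = c("1", "2"), strand = c("+", "-"),
    start = c(10000L, 5000L), end = c(20000L, 9000L))
  features <- bind_rows(
    # G1 (+): exon1 [10000,11000) with 5'UTR [10000,10500) + CDS start,
    # exon2 [18000,20000) with CDS end + 3'UTR [19000,20000)
    tibble(feature_type = "exon", transcript_id = "G1.t1", gene_id = "G1",
           chrom = "1", strand = "+", start = c(10000L, 18000L),
           end = c(11000L, 20000L)),
    tibble(feature_type = "five_prime_UTR", transcript_id = "G1.t1",
           gene_id = "G1", chrom = "1", strand = "+",
           start = 10000L, end = 10500L),
    tibble(feature_type = "CDS", transcript_id = "G1.t1", gene_id = "G1",
           chrom = "1", strand = "+", start = c(10500L, 18000L),
           end = c(11000L, 19000L)),
    tibble(feature_type = "three_prime_UTR", transcript_id = "G1.t1",
           gene_id = "G1", chrom = "1", strand = "+",
           start = 19000L, end = 20000L),
    # G2 (-): single fully coding exon
    tibble(feature_type = c("exon", "CDS"), transcript_id = "G2.t1",
           gene_id = "G2", chrom = "2", strand = "-",
           start = 5000L, end = 9000L))
  structure(list(genes = genes, transcripts = transcripts,
                 features = features), class = "gene_set")
}

# per-base consequence oracle against toy_gene_set()-style objects
per_base_classify <- function(sv, gs, flank_bp = 5000) {
  pos <- if (sv$sv_type == "INS") sv$start else seq2(sv$start, sv$end - 1)
  if (sv$sv_type == "INS") pos <- sv$start  # breakpoint only
  out <- list()
  for (gi in seq_len(nrow(gs$genes))) {
    g <- gs$genes[gi, ]
    if (g$chrom != sv$chrom) next
    gene_pos <- seq2(g$start, g$end - 1)
    hit <- any(pos %in% gene_pos)
    if (hit) {
      ft <- gs$features[gs$features$gene_id == g$gene_id, ]
      in_type <- function(types) {
        f <- ft[ft$feature_type %in% types, ]
        any(unlist(Map(function(s, e) any(pos %in% seq2(s, e - 1)),
                       f$start, f$end)))
      }
      cls <- if (in_type("CDS")) "exonic"
             else if (in_type(c("five_prime_UTR", "three_prime_UTR"))) "utr"
             else "intronic"
      out[[length(out) + 1]] <- tibble(gene_id = g$gene_id, class = cls)
    } else if (any(pos %in% seq2(g$start - flank_bp, g$end + flank_bp - 1))) {
      before <- max(pos) < g$start
      plus <- g$strand != "-"
      out[[length(out) + 1]] <- tibble(
        gene_id = g$gene_id,
        class = if (before == plus) "upstream" else "downstream")
    }
  }
  if (length(out) == 0) {
    return(tibble(gene_id = NA_character_, class = "intergenic"))
  }
  bind_rows(out)
}

# canonical callset ordering, independent of the package's writer
sort_callset <- function(x) {
  lv <- chrom_levels(x$chrom)
  x[order(match(x$chrom, lv), x$start, x$sv_id), ]
}
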