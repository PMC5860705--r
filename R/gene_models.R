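#' Read gene models from GFF3
#'
#' Parses a GFF3 annotation (via rtracklayer) into the flat tables the
#' annotation stage works with: one tibble of genes, one of transcripts
#' and one of sub-transcript features (exon, CDS, UTR). `gene`,
#' `mRNA`/`transcript`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` records are used; anything else is ignored.
#' Features whose `Parent` cannot be resolved are skipped with a
#' warning. Coordinates are converted to the package-wide 0-based
#' half-open convention and chromosome names are normalized.
#'
#' @param path GFF3 file.
#' @param conserved_ids character vector of gene IDs to flag as
#'   conserved (e.g. a core eukaryotic gene set projected onto this
#'   species); IDs absent from the annotation are silently ignored.
#' @return an object of class `gene_set`: a list of tibbles `genes`
#'   (with `n_transcripts` and logical `conserved`), `transcripts` and
#'   `features`.
#' @export
read_gene_models <- function(path, conserved_ids = character()) {
  if (!file.exists(path)) abort(paste0("cannot read gene models: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr, stringsAsFactors = FALSE))
  if (nrow(df) == 0) abort("empty gene annotation")
  df <- df %>%
    mutate(chrom = normalize_chrom(.data$seqnames),
           start = as.integer(.data$start) - 1L,  # to 0-based half-open
           end = as.integer(.data$end),
           type = as.character(.data$type),
           strand = as.character(.data$strand),
           ID = as.character(.data$ID),
           parent = purrr::map_chr(.data$Parent, function(p) {
             if (length(p) == 0) NA_character_ else as.character(p[[1]])
           }))
  if (!"Name" %in% names(df)) df$Name <- NA_character_
  if (!"biotype" %in% names(df)) df$biotype <- NA_character_

  genes <- df %>%
    filter(.data$type == "gene") %>%
    mutate(symbol = ifelse(is.na(.data$Name), .data$ID, as.character(.data$Name)),
           biotype = ifelse(is.na(.data$biotype), "protein_coding",
                            as.character(.data$biotype))) %>%
    select(gene_id = "ID", "symbol", "biotype", "chrom", "strand",
           "start", "end")
  if (nrow(genes) == 0) abort("annotation contains no gene records")

  tx <- df %>%
    filter(.data$type %in% c("mRNA", "transcript")) %>%
    select(transcript_id = "ID", gene_id = "parent", "chrom", "strand",
           "start", "end")
  orphan_tx <- !(tx$gene_id %in% genes$gene_id)
  if (any(orphan_tx)) {
    warn(sprintf("skipping %d transcripts with unresolved Parent", sum(orphan_tx)))
    tx <- tx[!orphan_tx, , drop = FALSE]
  }

  feats <- df %>%
    filter(.data$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")) %>%
    select(feature_type = "type", transcript_id = "parent", "chrom",
           "strand", "start", "end")
  orphan_ft <- !(feats$transcript_id %in% tx$transcript_id)
  if (any(orphan_ft)) {
    warn(sprintf("skipping %d features with unresolved Parent", sum(orphan_ft)))
    feats <- feats[!orphan_ft, , drop = FALSE]
  }
  feats <- feats %>%
    left_join(tx %>% select("transcript_id", "gene_id"), by = "transcript_id")

  genes <- genes %>%
    left_join(tx %>% count(.data$gene_id, name = "n_transcripts"),
              by = "gene_id") %>%
    mutate(n_transcripts = ifelse(is.na(.data$n_transcripts), 0L,
                                  .data$n_transcripts),
           conserved = .data$gene_id %in% conserved_ids) %>%
    arrange_sv()

  structure(list(genes = genes, transcripts = as_tibble(tx),
                 features = as_tibble(feats)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %d genes, %d transcripts, %d features (%d conserved genes)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$features),
              sum(x$genes$conserved)))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]: emits `gene`, `mRNA`, `exon`, `CDS`
#' and UTR records with `ID`/`Parent` links, converting back to GFF3
#' 1-based inclusive coordinates. Mainly used to materialize simulated
#' annotations and for round-trip testing.
#'
#' @param gene_set a `gene_set` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gene_set, path) {
  g <- gene_set$genes
  tx <- gene_set$transcripts
  ft <- gene_set$features
  line <- function(chrom, type, start, end, strand, attrs) {
    paste(chrom, "svcohort", type, start + 1L, end, ".", strand, ".",
          attrs, sep = "\t")
  }
  out <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    out <- c(out, line(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
                       sprintf("ID=%s;Name=%s;biotype=%s",
                               g$gene_id[i], g$symbol[i], g$biotype[i])))
    txi <- tx[tx$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(txi))) {
      out <- c(out, line(txi$chrom[j], "mRNA", txi$start[j], txi$end[j],
                         txi$strand[j],
                         sprintf("ID=%s;Parent=%s", txi$transcript_id[j],
                                 txi$gene_id[j])))
      fti <- ft[ft$transcript_id == txi$transcript_id[j], , drop = FALSE]
      fti <- fti[order(fti$start, fti$feature_type), , drop = FALSE]
      for (k in seq_len(nrow(fti))) {
        out <- c(out, line(fti$chrom[k], fti$feature_type[k], fti$start[k],
                           fti$end[k], fti$strand[k],
                           sprintf("ID=%s:%s:%d;Parent=%s",
                                   fti$transcript_id[k], fti$feature_type[k],
                                   k, fti$transcript_id[k])))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}
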