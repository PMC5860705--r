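#' SV sets per group or breed
#'
#' An SV belongs to a label's set when at least one carrier sample has
#' that label. Sets overlap: a variant segregating in two groups
#' appears in both, so the union over labels is exactly the set of SVs
#' with any carrier.
#'
#' @param presence presence/absence tibble from [build_presence_matrix()].
#' @param level `"group"` or `"breed"`.
#' @return named list mapping each label to a character vector of
#'   `sv_id`s.
#' @export
group_sets <- function(presence, level = c("group", "breed")) {
  level <- match.arg(level)
  sv_cols <- setdiff(names(presence), c("sample_id", "breed", "group"))
  labels <- sort(unique(presence[[level]]))
  setNames(lapply(labels, function(lab) {
    rows <- presence[[level]] == lab
    sub <- presence[rows, sv_cols, drop = FALSE]
    sv_cols[colSums(sub) > 0]
  }), labels)
}

#' Venn partition counts of labelled SV sets
#'
#' Counts, for every nonempty subset of labels, the SVs present in
#' exactly that subset of sets (the Venn diagram regions). Counts over
#' all regions sum to the size of the union, and patterns containing no
#' SV are reported with count 0.
#'
#' @param sets named list of id vectors, e.g. from [group_sets()].
#' @return tibble with columns `labels` (ampersand-joined, in sorted
#'   label order), `n_labels` and `count`, one row per nonempty subset.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2) abort("venn_counts needs at least two sets")
  labs <- sort(names(sets))
  ids <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(labs, function(l) ids %in% sets[[l]],
                   logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, labs))
  sig <- apply(member, 1, function(r) paste(labs[r], collapse = "&"))
  patterns <- unlist(lapply(seq_along(labs), function(k) {
    apply(utils::combn(labs, k), 2, paste, collapse = "&")
  }))
  tab <- table(factor(sig, levels = patterns))
  tibble(labels = patterns,
         n_labels = lengths(strsplit(patterns, "&", fixed = TRUE)),
         count = as.integer(tab[patterns]))
}

#' Label-specific SVs
#'
#' SVs carried exclusively by samples of one label (the "breed-specific"
#' or "group-specific" variants).
#'
#' @param sets named list of id vectors, e.g. from [group_sets()].
#' @return named list mapping each label to the ids found in no other
#'   label's set.
#' @export
specific_sets <- function(sets) {
  setNames(lapply(names(sets), function(l) {
    others <- unique(unlist(sets[setdiff(names(sets), l)], use.names = FALSE))
    setdiff(sets[[l]], others)
  }), names(sets))
}

#' Principal component analysis of the presence matrix
#'
#' Column-mean-centered singular value decomposition of the binary
#' carrier matrix (no unit-variance scaling: presence data are already
#' on a common 0/1 scale). Variance explained is each squared singular
#' value over the total variance. For reproducibility across BLAS
#' implementations each component's sign is fixed so that its
#' largest-magnitude loading is positive. A constant matrix yields
#' all-zero coordinates and zero variance explained rather than an
#' error.
#'
#' @param presence presence/absence tibble from [build_presence_matrix()].
#' @param n_components number of components to retain (default 2;
#'   capped at `min(samples - 1, SVs)`).
#' @return object of class `sv_pca` with elements `scores` (tibble:
#'   sample metadata plus `PC1`, `PC2`, ...), `variance_explained`,
#'   `loadings` (SVs x components matrix) and `n_svs`.
#' @export
sv_pca <- function(presence, n_components = 2) {
  meta_cols <- intersect(c("sample_id", "breed", "group"), names(presence))
  sv_cols <- setdiff(names(presence), meta_cols)
  if (nrow(presence) < 2) abort("PCA needs at least two samples")
  if (length(sv_cols) < 1) abort("PCA needs at least one SV column")
  x <- as.matrix(presence[, sv_cols, drop = FALSE])
  storage.mode(x) <- "double"
  k <- max(1L, min(n_components, nrow(x) - 1L, ncol(x)))
  xc <- scale(x, center = TRUE, scale = FALSE)
  total_var <- sum(xc^2) / (nrow(x) - 1)
  if (total_var == 0) {
    scores <- matrix(0, nrow(x), k)
    loadings <- matrix(0, ncol(x), k)
    ve <- rep(0, k)
  } else {
    p <- prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(k, ncol(p$rotation))
    flip <- vapply(seq_len(k), function(i) {
      l <- p$rotation[, i]
      if (l[which.max(abs(l))] < 0) -1 else 1
    }, numeric(1))
    scores <- sweep(p$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
    loadings <- sweep(p$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
    ve <- p$sdev[seq_len(k)]^2 / sum(p$sdev^2)
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(
    scores = dplyr::bind_cols(presence[, meta_cols, drop = FALSE],
                              as_tibble(scores)),
    variance_explained = ve,
    loadings = loadings,
    n_svs = length(sv_cols)
  ), class = "sv_pca")
}

#' @export
print.sv_pca <- function(x, ...) {
  cat(sprintf("<sv_pca> %d samples x %d SVs, %d components\n",
              nrow(x$scores), x$n_svs, length(x$variance_explained)))
  cat("variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' @describeIn sv_pca per-sample coordinates as a tibble.
#' @param x,object an `sv_pca` object.
#' @param ... unused.
#' @method tidy sv_pca
#' @export
tidy.sv_pca <- function(x, ...) x$scores

#' @describeIn sv_pca one-row model summary.
#' @method glance sv_pca
#' @export
glance.sv_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_svs = x$n_svs,
         n_components = length(x$variance_explained),
         var_explained_total = sum(x$variance_explained))
}

#' @describeIn sv_pca scatter plot of the first two components,
#'   coloured by group with breed as the point label when available.
#' @method autoplot sv_pca
#' @export
autoplot.sv_pca <- function(object, ...) {
  df <- object$scores
  if (!"PC2" %in% names(df)) df$PC2 <- 0
  aes_args <- if ("group" %in% names(df)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  p <- ggplot2::ggplot(df, aes_args) + ggplot2::geom_point(size = 2)
  if ("breed" %in% names(df)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$breed),
                                vjust = -0.8, size = 2.5, show.legend = FALSE)
  }
  ve <- object$variance_explained
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
    y = if (length(ve) > 1) sprintf("PC2 (%.1f%%)", 100 * ve[2]) else "PC2"
  ) + ggplot2::theme_minimal()
}
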