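# TPM normalization, expression filtering, log-ratio profiles, the
# timecourse ANOVA, and ECDF summaries.

#' Convert counts to transcripts per million
#'
#' Standard TPM: per sample, each gene's count is divided by its exonic
#' length, then rescaled so the column sums to 1e6.
#'
#' @param counts Genes x samples non-negative count matrix with gene ids as
#'   rownames.
#' @param annotation Gene annotation providing \code{exonic_length}.
#' @return A numeric matrix of TPM values, same dimnames as \code{counts}.
#' @export
counts_to_tpm <- function(counts, annotation) {
  assert_annotation(annotation)
  if (is.null(rownames(counts)))
    stop("'counts' must have gene ids as rownames")
  len <- annotation$exonic_length[match(rownames(counts), annotation$gene_id)]
  if (anyNA(len))
    stop("genes missing from annotation: ",
         paste(utils::head(rownames(counts)[is.na(len)], 3), collapse = ", "))
  if (any(len < 1)) stop("all exonic lengths must be >= 1")
  rate <- counts / len
  tot <- colSums(rate)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    stop("sample(s) with all-zero counts cannot be TPM-normalized: ",
         paste(bad, collapse = ", "))
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Filter for expressed genes
#'
#' A gene is retained iff it has a nonzero count in strictly more than half
#' of the samples.
#'
#' @param counts Genes x samples count matrix with gene ids as rownames.
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(counts) {
  if (is.null(dim(counts)) || ncol(counts) < 1)
    stop("'counts' must be a matrix with >= 1 sample")
  rownames(counts)[rowSums(counts > 0) > ncol(counts) / 2]
}

#' Per-gene log2 ratio between two sample groups
#'
#' \code{r_g = log2((mean_a + pseudocount) / (mean_b + pseudocount))}, the
#' profile consumed by the directional gene-set enrichment test and the
#' cis/trans comparisons.
#'
#' @param mat Genes x samples expression matrix (TPM).
#' @param group_a,group_b Column selectors (names, indices or logical) for the
#'   numerator and denominator groups; must be non-empty and disjoint.
#' @param pseudocount Added to both group means before the ratio (default 0.5
#'   TPM); 0 is allowed when the caller guarantees positive means.
#' @return A named numeric vector (gene -> log2 ratio) with attributes
#'   \code{numerator} and \code{denominator} listing the group columns.
#' @export
group_log_ratio <- function(mat, group_a, group_b, pseudocount = 0.5) {
  sel <- function(g) {
    if (is.character(g)) {
      cols <- match(g, colnames(mat))
      if (anyNA(cols)) stop("unknown sample(s) in selector")
    } else if (is.logical(g)) {
      if (length(g) != ncol(mat)) stop("logical selector length must match columns")
      cols <- which(g)
    } else {
      cols <- as.integer(g)
      if (any(cols < 1 | cols > ncol(mat))) stop("column index out of range")
    }
    cols
  }
  ia <- sel(group_a); ib <- sel(group_b)
  if (length(ia) == 0 || length(ib) == 0) stop("both groups must be non-empty")
  if (length(intersect(ia, ib)) > 0) stop("groups must be disjoint")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  a <- rowMeans(mat[, ia, drop = FALSE])
  b <- rowMeans(mat[, ib, drop = FALSE])
  r <- log2((a + pseudocount) / (b + pseudocount))
  if (any(!is.finite(r)))
    stop("non-finite log ratios; use a positive pseudocount")
  structure(r, numerator = colnames(mat)[ia], denominator = colnames(mat)[ib])
}

#' Collapse hybrid allele-level expression to total expression
#'
#' For each (condition, replicate, group) the two parental-allele columns are
#' summed, giving the total expression of the gene in the hybrid.
#'
#' @param mat Genes x samples matrix restricted to hybrid samples.
#' @param samples Sample metadata (\code{sample_id}, \code{allele},
#'   \code{condition}, \code{replicate}, optional \code{group}) matching the
#'   columns of \code{mat}.
#' @return A list with \code{mat} (genes x collapsed samples) and
#'   \code{samples} (collapsed metadata).
#' @export
hybrid_total_expression <- function(mat, samples) {
  assert_samples(samples, ncol(mat))
  grp <- samples$group %||% "F1"
  key <- paste(samples$condition, samples$replicate, grp, sep = "|")
  split_idx <- split(seq_len(nrow(samples)), key)
  bad <- names(split_idx)[vapply(split_idx, function(i)
    length(i) != 2L || length(unique(samples$allele[i])) != 2L, logical(1))]
  if (length(bad) > 0)
    stop("unpaired allele samples for (condition, replicate): ",
         paste(bad, collapse = ", "))
  keys <- unique(key)  # preserve input order
  out <- vapply(keys, function(k) rowSums(mat[, split_idx[[k]], drop = FALSE]),
                numeric(nrow(mat)))
  meta <- unique(data.frame(
    condition = samples$condition, replicate = samples$replicate,
    group = grp, key = key, stringsAsFactors = FALSE))
  meta <- meta[match(keys, meta$key), c("condition", "replicate", "group")]
  meta$sample_id <- sprintf("%s_total_r%d", meta$condition, meta$replicate)
  colnames(out) <- meta$sample_id
  rownames(meta) <- NULL
  list(mat = out, samples = meta)
}

# vectorized one-way fixed-effects ANOVA over the rows of a matrix
oneway_f_rows <- function(Y, group) {
  group <- factor(group)
  k <- nlevels(group)
  n <- ncol(Y)
  if (k < 2) stop("at least 2 groups required")
  if (any(table(group) < 2)) stop("at least 2 replicates per group required")
  G <- stats::model.matrix(~ 0 + group)
  ng <- colSums(G)
  M <- (Y %*% G) / rep(ng, each = nrow(Y))     # group means
  gm <- rowMeans(Y)
  ssb <- rowSums(sweep(M, 1, gm)^2 * rep(ng, each = nrow(Y)))
  sst <- rowSums(sweep(Y, 1, gm)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  degenerate <- sst <= 1e-12 * pmax(gm^2, 1)
  f[degenerate] <- NA_real_
  p[degenerate] <- 1
  data.frame(gene_id = rownames(Y), f = f, p = p, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene one-way ANOVA across timecourse points
#'
#' Tests, gene by gene, for expression change across timepoints (e.g. 0h, 6h,
#' 10d, 20d after irradiation) by one-way fixed-effects ANOVA on
#' \code{log2(TPM + 1)}. Genes with zero total variance are flagged
#' \code{degenerate} and returned with p = 1.
#'
#' @param tpm Genes x samples TPM matrix.
#' @param timepoints Character/factor of timepoint labels, one per column.
#' @return data.frame with \code{gene_id}, \code{f}, \code{p},
#'   \code{degenerate}.
#' @export
timecourse_anova <- function(tpm, timepoints) {
  if (length(timepoints) != ncol(tpm))
    stop("'timepoints' must have one label per sample column")
  oneway_f_rows(log2(tpm + 1), timepoints)
}

#' Empirical cumulative distribution table of a log-ratio profile
#'
#' Standard right-continuous ECDF over a gene subset, as used for
#' cumulative-distribution summaries of e.g. SASP gene expression shifts.
#'
#' @param profile Named numeric log-ratio profile.
#' @param genes Gene subset to summarize; must intersect the profile.
#' @return data.frame with \code{x} (sorted unique values) and
#'   \code{proportion} (P(r <= x)); the last proportion is 1.
#' @export
ecdf_table <- function(profile, genes) {
  r <- profile[intersect(genes, names(profile))]
  if (length(r) == 0) stop("gene subset does not intersect the profile")
  x <- sort(unique(unname(r)))
  data.frame(x = x, proportion = stats::ecdf(r)(x))
}
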