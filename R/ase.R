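# Senescence-dependent differential allele-specific expression (dASE):
# per-gene two-factor (allele x condition) ANOVA interaction statistic,
# top-quartile classification, and cis/trans concordance with purebred
# divergence.

# vectorized balanced two-way ANOVA with interaction over matrix rows.
# Y: genes x samples; allele/condition: 2-level factors, one per column.
two_way_interaction_rows <- function(Y, allele, condition) {
  allele <- factor(allele)
  condition <- factor(condition)
  if (nlevels(allele) != 2 || nlevels(condition) != 2)
    stop("a balanced 2 x 2 (allele x condition) design is required")
  cell <- interaction(allele, condition, drop = FALSE)
  tab <- table(cell)
  if (length(tab) != 4 || length(unique(as.integer(tab))) != 1)
    stop("unbalanced design: every (allele, condition) cell needs the same ",
         "number of replicates")
  R <- as.integer(tab[1])
  if (R < 2) stop("at least 2 replicates per cell are required")
  n <- ncol(Y)

  G <- stats::model.matrix(~ 0 + cell)        # samples x 4 indicator
  M <- (Y %*% G) / R                          # cell means, column order = levels(cell)
  # levels(cell) order: a1.c1, a2.c1, a1.c2, a2.c2
  int <- M[, 1] - M[, 2] - M[, 3] + M[, 4]
  ss_int <- R * int^2 / 4
  fitted <- M[, match(cell, levels(cell)), drop = FALSE]
  ss_res <- rowSums((Y - fitted)^2)
  df_res <- n - 4L
  f <- (ss_int / 1) / (ss_res / df_res)
  p <- stats::pf(f, 1, df_res, lower.tail = FALSE)
  gm <- rowMeans(Y)
  ss_tot <- rowSums((Y - gm)^2)
  degenerate <- ss_res <= 1e-12 * pmax(ss_tot, 1)
  f[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  data.frame(gene_id = rownames(Y) %||% as.character(seq_len(nrow(Y))),
             f_interaction = f, p_interaction = p, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-factor ANOVA interaction test for one gene
#'
#' Ordinary two-way fixed-effects ANOVA of expression on allele, condition and
#' their interaction, for a balanced 2 x 2 design with >= 2 replicates per
#' cell. Returns the interaction-term F and p. Zero residual variance (e.g.
#' all values equal) yields \code{degenerate = TRUE} with undefined F.
#'
#' @param values Numeric expression values (TPM on the analysis scale).
#' @param allele,condition Two-level factors, one entry per value.
#' @return A list with \code{f}, \code{p}, \code{degenerate}.
#' @export
interaction_anova <- function(values, allele, condition) {
  Y <- matrix(as.numeric(values), nrow = 1,
              dimnames = list("gene", NULL))
  res <- two_way_interaction_rows(Y, allele, condition)
  list(f = res$f_interaction, p = res$p_interaction,
       degenerate = res$degenerate)
}

#' Genome-wide dASE interaction scan
#'
#' Runs the allele x condition interaction ANOVA for every gene of a TPM
#' matrix. The analysis scale is raw TPM by default (the profiling pipeline's
#' stated input); \code{scale = "log2"} analyzes \code{log2(TPM + 0.5)} as a
#' robustness alternative.
#'
#' @param tpm Genes x samples TPM matrix.
#' @param samples Sample metadata with \code{allele} and \code{condition}.
#' @param scale \code{"tpm"} (default) or \code{"log2"}.
#' @return data.frame with \code{gene_id}, \code{f_interaction},
#'   \code{p_interaction}, \code{degenerate}.
#' @export
ase_scan <- function(tpm, samples, scale = c("tpm", "log2")) {
  scale <- match.arg(scale)
  assert_samples(samples, ncol(tpm))
  Y <- if (scale == "log2") log2(tpm + 0.5) else tpm
  two_way_interaction_rows(Y, samples$allele, samples$condition)
}

#' Classify senescence-dependent differential ASE by top interaction-F rank
#'
#' Flags exactly \code{ceil((1 - quantile) * n_tested)} genes (default: the
#' top 25% by interaction F among non-degenerate tested genes). Ties at the
#' threshold are broken by ascending gene id, deterministically. Degenerate
#' genes are excluded from the denominator and get \code{NA}.
#'
#' @param ase Result of \code{\link{ase_scan}}.
#' @param quantile Rank cutoff (default 0.75: the top quartile is flagged).
#' @return \code{ase} with an added logical \code{delta_ase} column.
#' @export
classify_delta_ase <- function(ase, quantile = 0.75) {
  if (!all(c("gene_id", "f_interaction", "degenerate") %in% names(ase)))
    stop("'ase' must be an ase_scan result")
  assert_prob(quantile, "quantile")
  tested <- which(!ase$degenerate)
  if (length(tested) < 4) stop("at least 4 tested (non-degenerate) genes required")
  k <- ceiling((1 - quantile) * length(tested))
  ord <- tested[order(-ase$f_interaction[tested], ase$gene_id[tested])]
  ase$delta_ase <- rep(NA, nrow(ase))
  ase$delta_ase[tested] <- FALSE
  ase$delta_ase[ord[seq_len(k)]] <- TRUE
  ase
}

#' Concordance of hybrid ASE with purebred expression divergence
#'
#' Spearman rank correlation between the hybrid allele-specific
#' senescence-response difference and the purebred species divergence, over
#' the shared genes. In the hybrid, allele differences isolate cis effects;
#' purebred divergence adds trans effects, so the hybrid profile is expected
#' to be a partial (positive but imperfect) predictor.
#'
#' @param hybrid,purebred Named numeric log-ratio profiles.
#' @return A list with \code{rho}, \code{p}, \code{n}.
#' @export
cis_trans_concordance <- function(hybrid, purebred) {
  common <- intersect(names(hybrid), names(purebred))
  if (length(common) < 10)
    stop("fewer than 10 shared genes between the profiles")
  ct <- suppressWarnings(stats::cor.test(hybrid[common], purebred[common],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(common))
}
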