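# The core screen: map binding sites to target genes through the 5-kb
# strand-aware upstream window, flag interspecies variants in sites, build
# per-TF 2x2 tables of (variant presence x dASE), filter at >= 250 targets
# per cell, Fisher-test, BH-correct, and profile variant positions.

sites_granges <- function(sites, seqlevels) {
  GenomicRanges::GRanges(
    seqnames = factor(sites$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = sites$start + 1, end = sites$end))
}

#' Assign binding sites to target genes
#'
#' A site targets a gene when it overlaps the strand-aware upstream window of
#' the gene's TSS by at least 1 bp (or is fully contained, with
#' \code{containment = TRUE}): for a + strand gene the window is the
#' \code{window} bp ending just before the TSS; for a - strand gene, the
#' \code{window} bp starting just after it. Sites on chromosomes absent from
#' the annotation are skipped with a warning.
#'
#' @param binding_sites Site table (0-based half-open coordinates).
#' @param annotation Gene annotation (1-based TSS).
#' @param window Upstream window size in bp (default 5000).
#' @param containment If TRUE, require the site to lie fully inside the
#'   window rather than merely overlap it.
#' @return data.frame with \code{tf_name}, \code{gene_id}, \code{site_id},
#'   one row per supporting (site, gene) pair.
#' @export
assign_targets <- function(binding_sites, annotation, window = 5000L,
                           containment = FALSE) {
  assert_sites(binding_sites)
  assert_annotation(annotation)
  window <- assert_count(window, "window")

  known <- binding_sites$chrom %in% unique(annotation$chrom)
  if (!all(known)) {
    warning(sprintf("skipping %d binding site(s) on chromosome(s) absent from the annotation: %s",
                    sum(!known),
                    paste(unique(binding_sites$chrom[!known]), collapse = ", ")))
    binding_sites <- binding_sites[known, , drop = FALSE]
  }
  if (nrow(binding_sites) == 0)
    return(data.frame(tf_name = character(0), gene_id = character(0),
                      site_id = character(0), stringsAsFactors = FALSE))

  seqlv <- unique(annotation$chrom)
  wins <- upstream_window(annotation, window)
  wgr <- GenomicRanges::GRanges(
    seqnames = factor(wins$chrom, levels = seqlv),
    ranges = IRanges::IRanges(start = wins$win_start, end = wins$win_end))
  sgr <- sites_granges(binding_sites, seqlv)
  hits <- GenomicRanges::findOverlaps(
    sgr, wgr, minoverlap = 1L,
    type = if (containment) "within" else "any")
  out <- data.frame(
    tf_name = binding_sites$tf_name[S4Vectors::queryHits(hits)],
    gene_id = wins$gene_id[S4Vectors::subjectHits(hits)],
    site_id = binding_sites$site_id[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$tf_name, out$gene_id, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag interspecies variants in binding sites
#'
#' Counts, per site, the SNVs falling inside the 0-based half-open interval
#' (a 1-based variant at \code{pos} is inside iff
#' \code{start <= pos - 1 < end}), and records each variant's signed offset
#' from the site center: \code{(pos - 1 + 0.5) - (start + end)/2}, with the
#' sign oriented 5' to 3' on the site's reference strand (negated for "-"
#' strand sites; unstranded sites are treated as "+").
#'
#' @param binding_sites Site table.
#' @param variants SNV catalog (1-based \code{pos}).
#' @return A list with \code{sites} (\code{site_id}, \code{tf_name},
#'   \code{n_variants}) and \code{offsets} (\code{site_id}, \code{tf_name},
#'   \code{pos}, \code{offset}), one offset row per (variant, site) pair.
#' @export
flag_variant_sites <- function(binding_sites, variants) {
  assert_sites(binding_sites)
  assert_variants(variants)
  seqlv <- unique(c(binding_sites$chrom, variants$chrom))
  sgr <- sites_granges(binding_sites, seqlv)
  vgr <- GenomicRanges::GRanges(
    seqnames = factor(variants$chrom, levels = seqlv),
    ranges = IRanges::IRanges(start = variants$pos, width = 1L))
  n_var <- GenomicRanges::countOverlaps(sgr, vgr)
  hits <- GenomicRanges::findOverlaps(vgr, sgr)
  vi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  center <- (binding_sites$start[si] + binding_sites$end[si]) / 2
  offset <- (variants$pos[vi] - 1 + 0.5) - center
  strand <- binding_sites$strand %||% rep(".", nrow(binding_sites))
  offset <- ifelse(strand[si] == "-", -offset, offset)
  list(
    sites = data.frame(site_id = binding_sites$site_id,
                       tf_name = binding_sites$tf_name,
                       n_variants = n_var, stringsAsFactors = FALSE),
    offsets = data.frame(site_id = binding_sites$site_id[si],
                         tf_name = binding_sites$tf_name[si],
                         pos = variants$pos[vi], offset = offset,
                         stringsAsFactors = FALSE)
  )
}

#' Build the per-(TF, gene) target table
#'
#' Aggregates site-level variant flags to gene level: a target gene of a TF
#' \code{has_variant} if any of the TF's in-window sites for that gene carries
#' a variant ("any" aggregation); \code{n_variants} are summed across sites
#' and \code{min_center_distance} is the minimum absolute variant-center
#' offset. dASE calls are joined by gene; genes without a (non-degenerate)
#' call are dropped, so the table is restricted to the tested gene universe.
#'
#' @param targets Output of \code{\link{assign_targets}}.
#' @param flags Output of \code{\link{flag_variant_sites}}.
#' @param ase Output of \code{\link{classify_delta_ase}}.
#' @return data.frame with \code{tf_name}, \code{gene_id}, \code{has_variant},
#'   \code{n_variants}, \code{min_center_distance}, \code{delta_ase}.
#' @export
build_target_table <- function(targets, flags, ase) {
  if (!"delta_ase" %in% names(ase))
    stop("'ase' must carry delta_ase calls (run classify_delta_ase first)")
  nv_site <- flags$sites$n_variants[match(targets$site_id, flags$sites$site_id)]
  nv_site[is.na(nv_site)] <- 0L
  key <- paste(targets$tf_name, targets$gene_id, sep = "\r")
  nv <- rowsum(nv_site, key)
  pairs <- data.frame(
    key = rownames(nv),
    n_variants = as.integer(nv[, 1]),
    stringsAsFactors = FALSE)
  kk <- strsplit(pairs$key, "\r", fixed = TRUE)
  pairs$tf_name <- vapply(kk, `[`, "", 1L)
  pairs$gene_id <- vapply(kk, `[`, "", 2L)
  pairs$has_variant <- pairs$n_variants >= 1L

  # min |offset| per site, then per (tf, gene) over that pair's sites
  off <- flags$offsets
  if (nrow(off) > 0) {
    site_min <- tapply(abs(off$offset), off$site_id, min)
    tmin <- site_min[targets$site_id]
    ok <- !is.na(tmin)
    pair_min <- tapply(tmin[ok], key[ok], min)
    pairs$min_center_distance <- as.numeric(pair_min[pairs$key])
  } else {
    pairs$min_center_distance <- NA_real_
  }

  idx <- match(pairs$gene_id, ase$gene_id)
  pairs$delta_ase <- ase$delta_ase[idx]
  pairs <- pairs[!is.na(pairs$delta_ase), , drop = FALSE]
  pairs <- pairs[order(pairs$tf_name, pairs$gene_id),
                 c("tf_name", "gene_id", "has_variant", "n_variants",
                   "min_center_distance", "delta_ase")]
  rownames(pairs) <- NULL
  pairs
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric point probabilities no
#' larger than that of the observed table (the standard definition, via
#' \code{stats::fisher.test}); the odds ratio is the sample estimate
#' \code{ad/bc} with the usual 0 and Inf conventions.
#'
#' @param a,b,c,d Non-negative integer cell counts
#'   (variant+/dASE+, variant+/dASE-, variant-/dASE+, variant-/dASE-).
#' @return A list with \code{odds_ratio} and \code{p}.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) < 1) stop("at least one observation is required")
  p <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
  num <- a * d
  den <- b * c
  odds_ratio <- if (den > 0) num / den else if (num > 0) Inf else NaN
  list(odds_ratio = odds_ratio, p = min(p, 1))
}

#' Run the per-TF contingency screen
#'
#' For every TF, counts targets in the four (variant x dASE) categories,
#' eliminates TFs with fewer than \code{min_per_cell} targets in any category,
#' Fisher-tests the remaining tables and BH-corrects across the eligible
#' family only. Output is sorted by ascending q, then p, then TF name, with
#' ineligible TFs (q, p = NA) last.
#'
#' @param target_table Output of \code{\link{build_target_table}}.
#' @param min_per_cell Eligibility threshold on the minimum cell count
#'   (default 250).
#' @return data.frame with \code{tf_name}, \code{a}, \code{b}, \code{c},
#'   \code{d}, \code{odds_ratio}, \code{p}, \code{q}, \code{eligible}.
#' @export
screen <- function(target_table, min_per_cell = 250L) {
  need <- c("tf_name", "gene_id", "has_variant", "delta_ase")
  if (!is.data.frame(target_table) || !all(need %in% names(target_table)))
    stop("'target_table' must be a build_target_table result")
  if (nrow(target_table) == 0) stop("empty target table")
  min_per_cell <- assert_count(min_per_cell, "min_per_cell", min = 0L)

  tf <- sort(unique(target_table$tf_name))
  hv <- target_table$has_variant
  da <- target_table$delta_ase
  idx <- split(seq_len(nrow(target_table)), target_table$tf_name)
  cnt <- t(vapply(tf, function(t) {
    i <- idx[[t]]
    c(a = sum(hv[i] & da[i]), b = sum(hv[i] & !da[i]),
      c = sum(!hv[i] & da[i]), d = sum(!hv[i] & !da[i]))
  }, integer(4)))
  res <- data.frame(tf_name = tf, cnt, stringsAsFactors = FALSE)
  res$eligible <- pmin(res$a, res$b, res$c, res$d) >= min_per_cell
  res$odds_ratio <- NA_real_
  res$p <- NA_real_
  res$q <- NA_real_
  if (!any(res$eligible)) {
    warning("no TF passes the minimum per-cell target filter; nothing tested")
  } else {
    for (i in which(res$eligible)) {
      ft <- fisher_exact(res$a[i], res$b[i], res$c[i], res$d[i])
      res$odds_ratio[i] <- ft$odds_ratio
      res$p[i] <- ft$p
    }
    res$q[res$eligible] <- stats::p.adjust(res$p[res$eligible], method = "BH")
  }
  res <- res[order(!res$eligible, res$q, res$p, res$tf_name), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("tf_name", "a", "b", "c", "d", "odds_ratio", "p", "q", "eligible")]
}

#' Variant-count and variant-position density profiles for one TF
#'
#' Gaussian kernel-density summaries of the screen's input for a single TF,
#' stratified by dASE of the downstream gene: (1) the per-target-gene number
#' of binding-site variants, and (2) the signed offsets of variants from the
#' binding-site center. Strata with fewer than 2 data points are omitted with
#' a warning. Densities are evaluated on a grid spanning the data plus 4
#' bandwidths and integrate to 1 (within 1e-3 by the trapezoid rule).
#'
#' @param tf TF name.
#' @param targets Output of \code{\link{assign_targets}}.
#' @param flags Output of \code{\link{flag_variant_sites}}.
#' @param ase Output of \code{\link{classify_delta_ase}}.
#' @param bandwidth Gaussian kernel bandwidth (counts for the first profile,
#'   bp for the second).
#' @param n_grid Number of grid points (default 512).
#' @return A list with \code{count_density} and \code{offset_density}, each a
#'   data.frame with \code{stratum} ("dASE+" or "dASE-"), \code{x}, \code{density}.
#' @export
variant_position_profile <- function(tf, targets, flags, ase, bandwidth = 5,
                                     n_grid = 512L) {
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("'bandwidth' must be > 0")
  tt <- build_target_table(targets[targets$tf_name == tf, , drop = FALSE],
                           flags, ase)
  if (nrow(tt) == 0) stop(sprintf("TF '%s' has no targets with dASE calls", tf))

  kde_strata <- function(x, stratum, bw) {
    out <- NULL
    for (s in c("dASE+", "dASE-")) {
      xs <- x[stratum == s]
      if (length(xs) < 2) {
        warning(sprintf("stratum %s has < 2 data points; omitted", s))
        next
      }
      d <- stats::density(xs, bw = bw, n = n_grid,
                          from = min(xs) - 4 * bw, to = max(xs) + 4 * bw)
      out <- rbind(out, data.frame(stratum = s, x = d$x, density = d$y,
                                   stringsAsFactors = FALSE))
    }
    out
  }
  gene_stratum <- ifelse(tt$delta_ase, "dASE+", "dASE-")
  count_density <- kde_strata(tt$n_variants, gene_stratum, bandwidth)

  off <- flags$offsets[flags$offsets$tf_name == tf, , drop = FALSE]
  tg <- targets[targets$tf_name == tf, , drop = FALSE]
  gene_of_site <- tg$gene_id[match(off$site_id, tg$site_id)]
  da <- tt$delta_ase[match(gene_of_site, tt$gene_id)]
  keep <- !is.na(da)
  offset_density <- kde_strata(off$offset[keep],
                               ifelse(da[keep], "dASE+", "dASE-"), bandwidth)
  list(count_density = count_density, offset_density = offset_density)
}
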