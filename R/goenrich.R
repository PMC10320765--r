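# Resampling-based directional gene-set enrichment: per term, the signed sum
# of per-gene log2 ratios is compared with the same sum over size-matched
# random gene sets drawn (without replacement) from all profiled genes.

#' Signed term score
#'
#' Sum of the per-gene log2 ratios over the term members present in the
#' profile. The sign carries the direction of the coordinated shift.
#'
#' @param profile Named numeric log-ratio profile (gene -> log2 ratio).
#' @param genes Character vector of term member gene ids.
#' @return A list with \code{s} (signed sum) and \code{n_used} (members found
#'   in the profile).
#' @export
term_score <- function(profile, genes) {
  used <- intersect(genes, names(profile))
  if (length(used) == 0)
    stop("no term gene is present in the profile")
  list(s = sum(profile[used]), n_used = length(used))
}

#' Resampling p-value for a term's absolute score
#'
#' Draws \code{n_resamples} random gene sets of the same size (without
#' replacement, from all profiled genes) and compares \code{|s_rand|} with
#' the observed \code{|s_true|}. The default add-one estimator
#' \code{p = (1 + #(|s_rand| >= |s_true|)) / (n_resamples + 1)} never returns
#' zero; \code{p_method = "proportion_printed"} instead returns the plain
#' proportion of resamples with \code{|s_true| > |s_rand|} (large values of
#' which indicate strong enrichment under that convention).
#'
#' @param profile Named numeric log-ratio profile.
#' @param genes Term member gene ids.
#' @param n_resamples Number of resampled gene sets (>= 100; default 10000).
#' @param seed Seed for the resampling stream.
#' @param p_method \code{"add_one"} (default) or \code{"proportion_printed"}.
#' @return A list with \code{p}, \code{s}, \code{n_used}.
#' @export
resampling_pvalue <- function(profile, genes, n_resamples = 10000L, seed = 1L,
                              p_method = c("add_one", "proportion_printed")) {
  p_method <- match.arg(p_method)
  n_resamples <- assert_count(n_resamples, "n_resamples", min = 100L)
  ts <- term_score(profile, genes)
  pool <- as.numeric(profile)
  n <- length(pool)
  k <- ts$n_used
  if (k > n) stop("term size exceeds the profiled gene population")
  set.seed(op_seed(seed, "resampling"))
  s_rand <- vapply(seq_len(n_resamples),
                   function(i) sum(pool[sample.int(n, k)]), numeric(1))
  p <- if (p_method == "add_one")
    (1 + sum(abs(s_rand) >= abs(ts$s))) / (n_resamples + 1)
  else
    mean(abs(ts$s) > abs(s_rand))
  list(p = p, s = ts$s, n_used = k)
}

#' Directional enrichment over a gene-set catalog
#'
#' Scores and resampling-tests every term, BH-corrects across all tested
#' terms, and reports the direction of each shift from the sign of the score.
#' Terms with no member in the profile are skipped with a warning. Each term
#' draws from its own RNG stream derived from \code{seed} and the term id, so
#' results are independent of catalog order.
#'
#' @param profile Named numeric log-ratio profile.
#' @param catalog Named list mapping term id to member gene ids (optionally
#'   with a \code{term_name} attribute).
#' @param n_resamples Resamples per term (default 10000).
#' @param seed Master seed.
#' @param p_method Passed to \code{\link{resampling_pvalue}}.
#' @return data.frame sorted by ascending q then p, with \code{term_id},
#'   \code{term_name}, \code{n_genes_used}, \code{s_true}, \code{abs_s},
#'   \code{direction}, \code{p}, \code{q}.
#' @export
enrich_catalog <- function(profile, catalog, n_resamples = 10000L, seed = 1L,
                           p_method = c("add_one", "proportion_printed")) {
  p_method <- match.arg(p_method)
  if (length(catalog) == 0 || is.null(names(catalog)))
    stop("'catalog' must be a non-empty named list of gene sets")
  term_names <- attr(catalog, "term_name")
  rows <- vector("list", length(catalog))
  for (i in seq_along(catalog)) {
    id <- names(catalog)[i]
    if (length(intersect(catalog[[i]], names(profile))) == 0) {
      warning(sprintf("term %s shares no gene with the profile; skipped", id))
      next
    }
    rp <- resampling_pvalue(profile, catalog[[i]], n_resamples,
                            seed = op_seed(seed, id), p_method = p_method)
    rows[[i]] <- data.frame(
      term_id = id,
      term_name = if (!is.null(term_names) && id %in% names(term_names))
        unname(term_names[id]) else id,
      n_genes_used = rp$n_used, s_true = rp$s, abs_s = abs(rp$s),
      direction = if (rp$s >= 0) "up" else "down",
      p = rp$p, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no term overlaps the profile")
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
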