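# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive an operation-specific RNG seed
#'
#' Each generator or resampling operation draws from its own RNG stream,
#' seeded deterministically from the master seed and the operation name, so
#' that changing one stage never perturbs the random draws of another.
#'
#' @param seed Master integer seed.
#' @param op Operation name (any string).
#' @return An integer seed in \code{[0, 2^31)}.
#' @export
op_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(as.character(op))
  h <- sum(chars * seq_along(chars)) %% 104729
  as.integer((abs(as.numeric(seed)) * 7919 + h * 131) %% 2147483629)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

assert_annotation <- function(annotation) {
  need <- c("gene_id", "chrom", "strand", "tss", "exonic_length")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation)))
    stop("'annotation' must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(annotation$gene_id))
    stop("gene_id values in 'annotation' must be unique", call. = FALSE)
  invisible(annotation)
}

assert_sites <- function(sites) {
  need <- c("site_id", "tf_name", "chrom", "start", "end")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    stop("'binding_sites' must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(sites$start >= sites$end))
    stop("binding sites must satisfy start < end (0-based half-open)", call. = FALSE)
  invisible(sites)
}

assert_variants <- function(variants) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!is.data.frame(variants) || !all(need %in% names(variants)))
    stop("'variants' must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  invisible(variants)
}

assert_samples <- function(samples, n = NULL) {
  need <- c("sample_id", "allele", "condition", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop("'samples' must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!is.null(n) && nrow(samples) != n)
    stop("sample metadata rows must match count matrix columns", call. = FALSE)
  invisible(samples)
}
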