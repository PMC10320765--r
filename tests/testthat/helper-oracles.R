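# Independent oracles used to cross-check the package's statistics, plus
# small fixture builders. The oracles deliberately take different code paths
# from the implementation (exhaustive enumeration, stats::aov model fits,
# step-up definition from first principles).

# two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins, from log-binomial coefficients
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  x <- max(0, k - n):min(k, m)
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg from the step-up definition: q_(i) = min_{j>=i} p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# interaction F and p from a full stats::aov fit
aov_interaction_oracle <- function(values, allele, condition) {
  fit <- summary(stats::aov(values ~ allele * condition,
                            data = data.frame(values = values,
                                              allele = factor(allele),
                                              condition = factor(condition))))[[1]]
  i <- grep(":", trimws(rownames(fit)))
  list(f = fit[i, "F value"], p = fit[i, "Pr(>F)"])
}

# one-way F from a stats::aov fit
aov_oneway_oracle <- function(values, group) {
  fit <- summary(stats::aov(values ~ group,
                            data = data.frame(values = values,
                                              group = factor(group))))[[1]]
  list(f = fit[1, "F value"], p = fit[1, "Pr(>F)"])
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# a small, fast study used by several module tests
small_study <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_genes = 300L, n_chroms = 3L, chrom_length = 3e6,
               tf_names = sprintf("TF%02d", 1:5), causal_tfs = "TF01",
               library_size = 3e5, n_terms = 10L, size_range = c(5L, 20L))
  args[names(list(...))] <- list(...)
  do.call(simulate_study, args)
}

# balanced 2x2xR design metadata
balanced_meta <- function(R = 3L) {
  expand.grid(replicate = seq_len(R),
              allele = c("parentA", "parentB"),
              condition = c("control", "senescent"),
              stringsAsFactors = FALSE)
}
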