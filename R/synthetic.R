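# Synthetic-data generators: annotations, binding sites, variant catalogs,
# allele-resolved negative-binomial count matrices with planted
# cis-by-condition (allele x senescence interaction) effects, and gene sets.
#
# These generators define the study conditions used throughout the test
# suite: a balanced 2-allele x 2-condition x R-replicate F1-hybrid design in
# which genes carrying interspecies variants in the binding sites of
# designated "causal" transcription factors preferentially receive a planted
# allele-by-condition interaction.

#' Generate a synthetic gene annotation
#'
#' Genes are assigned round-robin to chromosomes and given distinct TSS
#' positions at least 10,001 bp from the chromosome start, so that a 5-kb
#' upstream window never underflows the origin. Strands are assigned roughly
#' 50/50 and exonic lengths follow a log-normal law typical of mammalian
#' transcripts.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_chroms Number of chromosomes (>= 1).
#' @param chrom_length Chromosome length in bp; must leave room for
#'   distinct TSS placement at least 10 kb from either end.
#' @param seed Master seed; the op draws from its own stream via
#'   \code{\link{op_seed}}.
#' @return A data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{tss} (1-based), \code{exonic_length}.
#' @export
generate_annotation <- function(n_genes, n_chroms = 1L, chrom_length = 1e6, seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_chroms <- assert_count(n_chroms, "n_chroms")
  if (!is.numeric(chrom_length) || chrom_length <= 0)
    stop("'chrom_length' must be a positive length in bp")
  set.seed(op_seed(seed, "annotation"))

  chrom_idx <- rep_len(seq_len(n_chroms), n_genes)
  lo <- 10001
  hi <- floor(chrom_length) - 10000
  n_per <- tabulate(chrom_idx, n_chroms)
  if (hi < lo || max(n_per) > (hi - lo + 1))
    stop(sprintf(paste0("infeasible TSS placement: chromosome length %g leaves %d ",
                        "admissible positions (need >= %d per chromosome, with TSS >= ",
                        "10,001 and >= 10 kb from the chromosome end)"),
                 chrom_length, max(0, hi - lo + 1), max(n_per)))

  tss <- integer(n_genes)
  for (k in seq_len(n_chroms)) {
    sel <- which(chrom_idx == k)
    tss[sel] <- sort(sample.int(hi - lo + 1L, length(sel)) + lo - 1L)
  }
  data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    chrom = sprintf("chr%d", chrom_idx),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    tss = tss,
    exonic_length = pmax(200L, as.integer(round(stats::rlnorm(n_genes, log(1500), 0.6)))),
    stringsAsFactors = FALSE
  )
}

# strand-aware 1-based upstream window [win_start, win_end] for each gene
upstream_window <- function(annotation, window) {
  plus <- annotation$strand == "+"
  data.frame(
    gene_id = annotation$gene_id,
    chrom = annotation$chrom,
    win_start = ifelse(plus, pmax(1, annotation$tss - window), annotation$tss + 1),
    win_end = ifelse(plus, annotation$tss - 1, annotation$tss + window),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic TF binding sites
#'
#' For each (TF, gene) pair, with probability \code{sites_per_tf_per_gene_prob}
#' one site of length \code{site_length} is placed fully inside the
#' strand-aware upstream window of the gene. Within a window, sites of
#' different TFs occupy disjoint slots (distinct TF footprints at distinct
#' loci), so a variant in one TF's site is never inside another's and the
#' realized per-TF variant rates equal the nominal simulation parameters.
#' Decoy sites falling outside every upstream window are added at rate
#' \code{decoy_fraction} per (TF, gene) pair. Coordinates are BED-style
#' 0-based half-open.
#'
#' @param annotation Gene annotation from \code{\link{generate_annotation}}.
#' @param tf_names Character vector of TF names.
#' @param sites_per_tf_per_gene_prob Probability an in-window site is placed
#'   for a given (TF, gene) pair.
#' @param site_length Site length in bp; must be smaller than \code{window}.
#' @param window Upstream window size in bp (default 5000).
#' @param decoy_fraction Expected decoy sites per (TF, gene) pair, placed
#'   outside every upstream window.
#' @param chrom_length Chromosome length used when placing decoys; defaults to
#'   just beyond the largest annotated TSS.
#' @param seed Master seed.
#' @return A data.frame with columns \code{site_id}, \code{tf_name},
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open),
#'   \code{strand} (\code{"."}: sites are unstranded), \code{decoy}.
#' @export
generate_binding_sites <- function(annotation, tf_names,
                                   sites_per_tf_per_gene_prob = 0.9,
                                   site_length = 200L, window = 5000L,
                                   decoy_fraction = 0.05,
                                   chrom_length = NULL, seed = 1L) {
  assert_annotation(annotation)
  assert_prob(sites_per_tf_per_gene_prob, "sites_per_tf_per_gene_prob")
  assert_prob(decoy_fraction, "decoy_fraction")
  site_length <- assert_count(site_length, "site_length")
  window <- assert_count(window, "window")
  if (site_length >= window)
    stop("'site_length' must be smaller than 'window'")
  chrom_length <- chrom_length %||% (max(annotation$tss) + window + 10000)
  set.seed(op_seed(seed, "binding_sites"))

  n_genes <- nrow(annotation)
  plus <- annotation$strand == "+"
  # 0-based start of each gene's upstream window
  in_lo <- ifelse(plus, annotation$tss - 1 - window, annotation$tss)
  n_slots <- window %/% site_length  # disjoint site slots per window

  wins <- upstream_window(annotation, window)
  win_by_chrom <- split(seq_len(nrow(wins)), wins$chrom)

  # per gene, draw which TFs bind and place them in distinct window slots
  hit <- matrix(stats::runif(n_genes * length(tf_names)) <
                  sites_per_tf_per_gene_prob, n_genes, length(tf_names))
  slot <- matrix(NA_integer_, n_genes, length(tf_names))
  for (g in seq_len(n_genes)) {
    k <- sum(hit[g, ])
    if (k == 0) next
    if (k > n_slots)
      stop(sprintf(paste0("cannot place %d non-overlapping sites of length %d ",
                          "in a %d-bp window (%d slots)"),
                   k, site_length, window, n_slots))
    slot[g, hit[g, ]] <- sample.int(n_slots, k)
  }

  pieces <- vector("list", length(tf_names))
  for (ti in seq_along(tf_names)) {
    tf <- tf_names[ti]
    sel <- hit[, ti]
    start0 <- (in_lo + (slot[, ti] - 1L) * site_length)[sel]
    site <- data.frame(
      tf_name = rep(tf, sum(sel)),
      chrom = annotation$chrom[sel],
      start = as.numeric(start0),
      end = as.numeric(start0) + site_length,
      decoy = logical(sum(sel)),
      stringsAsFactors = FALSE
    )
    n_dec <- stats::rbinom(1L, n_genes, decoy_fraction)
    if (n_dec > 0) {
      dec <- matrix(NA_real_, 0, 2)
      dec_chrom <- character(0)
      tries <- 0L
      while (nrow(dec) < n_dec && tries < 60L) {
        tries <- tries + 1L
        need <- n_dec - nrow(dec)
        cand_chrom <- sample(unique(annotation$chrom), need, replace = TRUE)
        cand_start <- floor(stats::runif(need) * (chrom_length - site_length))
        keep <- vapply(seq_len(need), function(i) {
          idx <- win_by_chrom[[cand_chrom[i]]]
          if (is.null(idx)) return(TRUE)
          s1 <- cand_start[i] + 1          # 1-based site interval
          e1 <- cand_start[i] + site_length
          !any(wins$win_start[idx] <= e1 & wins$win_end[idx] >= s1)
        }, logical(1))
        dec <- rbind(dec, cbind(cand_start[keep], cand_start[keep] + site_length))
        dec_chrom <- c(dec_chrom, cand_chrom[keep])
      }
      if (nrow(dec) > 0)
        site <- rbind(site, data.frame(
          tf_name = rep(tf, nrow(dec)), chrom = dec_chrom,
          start = dec[, 1], end = dec[, 2], decoy = TRUE,
          stringsAsFactors = FALSE))
    }
    pieces[[ti]] <- site
  }
  out <- do.call(rbind, pieces)
  out$strand <- rep(".", nrow(out))
  out$site_id <- if (nrow(out) == 0) character(0) else
    sprintf("%s_s%05d", out$tf_name,
            stats::ave(seq_len(nrow(out)), out$tf_name, FUN = seq_along))
  rownames(out) <- NULL
  out[, c("site_id", "tf_name", "chrom", "start", "end", "strand", "decoy")]
}

#' Generate an interspecies SNV catalog over binding sites
#'
#' Each site of a causal TF receives a variant with probability
#' \code{p_variant_causal}, every other site with \code{p_variant_background}.
#' The variant position is drawn around the site center
#' (\code{round(center + Normal(0, offset_sd))}) and clipped into the site,
#' emulating the central/near-central placement of functional binding-site
#' variants. Positions are VCF-style 1-based; duplicate (chrom, pos) records
#' are dropped.
#'
#' @param binding_sites Sites from \code{\link{generate_binding_sites}}.
#' @param causal_tfs Character vector of causal TF names.
#' @param p_variant_causal Per-site variant probability for causal TFs.
#' @param p_variant_background Per-site variant probability for all other TFs.
#' @param offset_sd SD (bp) of the variant offset from the site center.
#' @param seed Master seed.
#' @return A data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}.
#' @export
generate_variants <- function(binding_sites, causal_tfs = character(0),
                              p_variant_causal = 0.6, p_variant_background = 0.2,
                              offset_sd = 30, seed = 1L) {
  assert_sites(binding_sites)
  assert_prob(p_variant_causal, "p_variant_causal")
  assert_prob(p_variant_background, "p_variant_background")
  if (!is.numeric(offset_sd) || offset_sd < 0) stop("'offset_sd' must be >= 0")
  set.seed(op_seed(seed, "variants"))

  rate <- ifelse(binding_sites$tf_name %in% causal_tfs,
                 p_variant_causal, p_variant_background)
  hit <- stats::runif(nrow(binding_sites)) < rate
  s <- binding_sites[hit, , drop = FALSE]
  if (nrow(s) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  center <- (s$start + s$end) / 2
  pos0 <- round(center + stats::rnorm(nrow(s), 0, offset_sd))
  pos0 <- pmin(pmax(pos0, s$start), s$end - 1)
  nt <- c("A", "C", "G", "T")
  ref <- nt[sample.int(4L, nrow(s), replace = TRUE)]
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1),
                USE.NAMES = FALSE)
  out <- data.frame(chrom = s$chrom, pos = as.integer(pos0 + 1),
                    ref = ref, alt = alt, stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("chrom", "pos")]), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ground-truth parameters for the synthetic study
#'
#' @param causal_tfs TFs whose variant-bearing targets may receive the planted
#'   allele-by-condition interaction.
#' @param interaction_lfc Planted interaction effect in log2 units.
#' @param planted_fraction Probability a variant-bearing causal-TF target is
#'   planted.
#' @param dispersion Negative-binomial dispersion (var = mu + dispersion*mu^2).
#' @param baseline_log_mean,baseline_log_sd Log-normal (natural-log) parameters
#'   of per-gene baseline means.
#' @param planted_terms Term ids receiving a directional shift in gene-set
#'   simulations.
#' @param seed Master seed recorded with the truth.
#' @return A list of class \code{sim_truth}.
#' @export
sim_truth <- function(causal_tfs = character(0), interaction_lfc = 1.5,
                      planted_fraction = 0.10, dispersion = 0.05,
                      baseline_log_mean = 5, baseline_log_sd = 1,
                      planted_terms = character(0), seed = 1L) {
  assert_prob(planted_fraction, "planted_fraction")
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop("'dispersion' must be > 0")
  structure(list(causal_tfs = causal_tfs, interaction_lfc = interaction_lfc,
                 planted_fraction = planted_fraction, dispersion = dispersion,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 planted_terms = planted_terms, seed = seed),
            class = "sim_truth")
}

#' Generate an allele-resolved count matrix with planted interactions
#'
#' Emulates the balanced F1-hybrid design: 2 alleles x 2 conditions x
#' \code{n_replicates}. Per gene g the expected count for a sample is
#' \code{mu_g * 2^(beta_g*I[allele B] + gamma_g*I[senescent] +
#' delta_g*I[allele B & senescent])}, with \code{mu_g} log-normal,
#' small Normal(0, 0.1) background main effects \code{beta_g, gamma_g}, and
#' \code{delta_g = truth$interaction_lfc} for planted genes (variant-bearing
#' targets of causal TFs, each planted with probability
#' \code{truth$planted_fraction}). Expected counts are rescaled per sample to
#' \code{library_size} before negative-binomial draws.
#'
#' @param annotation,binding_sites,variants Outputs of the upstream generators.
#' @param truth A \code{\link{sim_truth}} object.
#' @param n_replicates Replicates per (allele, condition) cell (>= 2).
#' @param library_size Target per-sample total count.
#' @param window Upstream window (bp) used when resolving causal-TF targets.
#' @return A list with \code{counts} (genes x samples integer matrix),
#'   \code{samples} (sample metadata), and \code{truth_table} (per-gene
#'   planted-effect bookkeeping: mu, beta, gamma, delta, variant_target,
#'   planted).
#' @export
generate_counts <- function(annotation, binding_sites, variants, truth,
                            n_replicates = 3L, library_size = 2e6,
                            window = 5000L) {
  assert_annotation(annotation)
  assert_sites(binding_sites)
  assert_variants(variants)
  if (!inherits(truth, "sim_truth")) stop("'truth' must be a sim_truth object")
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 2L)
  if (!is.numeric(library_size) || library_size <= 0)
    stop("'library_size' must be > 0")
  set.seed(op_seed(truth$seed, "counts"))

  n_genes <- nrow(annotation)
  # genes eligible for planting: variant-bearing targets of causal TFs
  eligible <- character(0)
  causal_sites <- binding_sites[binding_sites$tf_name %in% truth$causal_tfs, , drop = FALSE]
  if (nrow(causal_sites) > 0 && nrow(variants) > 0) {
    tg <- suppressWarnings(assign_targets(causal_sites, annotation, window = window))
    fl <- flag_variant_sites(causal_sites, variants)
    varsites <- fl$sites$site_id[fl$sites$n_variants > 0]
    eligible <- sort(unique(tg$gene_id[tg$site_id %in% varsites]))
  }
  planted <- eligible[stats::runif(length(eligible)) < truth$planted_fraction]

  mu <- stats::rlnorm(n_genes, truth$baseline_log_mean, truth$baseline_log_sd)
  beta <- stats::rnorm(n_genes, 0, 0.1)
  gamma <- stats::rnorm(n_genes, 0, 0.1)
  delta <- ifelse(annotation$gene_id %in% planted, truth$interaction_lfc, 0)

  samples <- expand.grid(
    replicate = seq_len(n_replicates),
    allele = c("parentA", "parentB"),
    condition = c("control", "senescent"),
    stringsAsFactors = FALSE
  )[, c("allele", "condition", "replicate")]
  samples$group <- "F1"
  samples$sample_id <- sprintf("%s_%s_r%d", samples$condition, samples$allele,
                               samples$replicate)
  samples <- samples[, c("sample_id", "allele", "condition", "replicate", "group")]

  counts <- matrix(0L, n_genes, nrow(samples),
                   dimnames = list(annotation$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    isB <- samples$allele[j] == "parentB"
    isS <- samples$condition[j] == "senescent"
    e <- mu * 2^(beta * isB + gamma * isS + delta * (isB && isS))
    e <- e * (library_size / sum(e))
    counts[, j] <- stats::rnbinom(n_genes, mu = e, size = 1 / truth$dispersion)
  }

  list(
    counts = counts,
    samples = samples,
    truth_table = data.frame(
      gene_id = annotation$gene_id,
      mu = mu, beta = beta, gamma = gamma, delta = delta,
      variant_target = annotation$gene_id %in% eligible,
      planted = annotation$gene_id %in% planted,
      stringsAsFactors = FALSE
    )
  )
}

#' Generate a synthetic gene-set catalog
#'
#' Terms sample genes without replacement; planted terms draw a fraction
#' \code{planted_weight} of their members from \code{planted_genes}, creating
#' a directional shift detectable by the resampling enrichment test.
#'
#' @param annotation Gene annotation.
#' @param n_terms Number of terms.
#' @param size_range Integer vector \code{c(min, max)} of term sizes (>= 2).
#' @param planted_terms Character ids (of the form \code{"T0001"}) of terms to
#'   plant.
#' @param planted_genes Genes carrying the planted directional effect.
#' @param planted_weight Fraction of a planted term drawn from
#'   \code{planted_genes}.
#' @param seed Master seed.
#' @return A named list mapping term id to a character vector of gene ids,
#'   with a \code{term_name} attribute.
#' @export
generate_gene_sets <- function(annotation, n_terms = 50L, size_range = c(10L, 50L),
                               planted_terms = character(0),
                               planted_genes = character(0),
                               planted_weight = 0.8, seed = 1L) {
  assert_annotation(annotation)
  n_terms <- assert_count(n_terms, "n_terms")
  if (length(size_range) != 2L || any(size_range < 2L))
    stop("'size_range' must be two integers >= 2")
  if (max(size_range) > nrow(annotation))
    stop("term size exceeds the number of annotated genes")
  assert_prob(planted_weight, "planted_weight")
  set.seed(op_seed(seed, "gene_sets"))

  all_genes <- annotation$gene_id
  other <- setdiff(all_genes, planted_genes)
  ids <- sprintf("T%04d", seq_len(n_terms))
  sizes <- sample(seq(size_range[1], size_range[2]), n_terms, replace = TRUE)
  sets <- vector("list", n_terms)
  names(sets) <- ids
  for (i in seq_len(n_terms)) {
    if (ids[i] %in% planted_terms && length(planted_genes) > 0) {
      k_p <- min(round(planted_weight * sizes[i]), length(planted_genes))
      sets[[i]] <- c(sample(planted_genes, k_p),
                     sample(other, sizes[i] - k_p))
    } else {
      sets[[i]] <- sample(all_genes, sizes[i])
    }
  }
  attr(sets, "term_name") <- stats::setNames(paste("synthetic term", ids), ids)
  sets
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper chaining all generators under one master seed, at the
#' default study conditions: 4000 genes on 19 chromosomes, 20 TFs binding
#' upstream of 90% of genes, one causal TF (variant rate 0.6 vs 0.2
#' background) whose variant-bearing targets receive a planted 1.5-log2
#' allele-by-condition interaction with probability 0.10, and a balanced
#' 2 x 2 x 3 negative-binomial count matrix.
#'
#' @param seed Master seed.
#' @param n_genes,n_chroms,chrom_length Annotation parameters.
#' @param tf_names,causal_tfs TF panel and causal subset.
#' @param sites_per_tf_per_gene_prob,site_length,window,decoy_fraction Site
#'   parameters.
#' @param p_variant_causal,p_variant_background,offset_sd Variant parameters.
#' @param interaction_lfc,planted_fraction,dispersion,baseline_log_mean,baseline_log_sd
#'   Count-model parameters (see \code{\link{sim_truth}}).
#' @param n_replicates,library_size Design and depth.
#' @param n_terms,size_range,n_planted_terms Gene-set parameters.
#' @return A list with \code{annotation}, \code{sites}, \code{variants},
#'   \code{truth}, \code{counts}, \code{samples}, \code{truth_table},
#'   \code{gene_sets}.
#' @export
simulate_study <- function(seed = 1L, n_genes = 4000L, n_chroms = 19L,
                           chrom_length = 5e7,
                           tf_names = sprintf("TF%02d", 1:20),
                           causal_tfs = "TF01",
                           sites_per_tf_per_gene_prob = 0.9,
                           site_length = 200L, window = 5000L,
                           decoy_fraction = 0.05,
                           p_variant_causal = 0.6, p_variant_background = 0.2,
                           offset_sd = 30,
                           interaction_lfc = 1.5, planted_fraction = 0.10,
                           dispersion = 0.05,
                           baseline_log_mean = 5, baseline_log_sd = 1,
                           n_replicates = 3L, library_size = 2e6,
                           n_terms = 50L, size_range = c(10L, 50L),
                           n_planted_terms = 0L) {
  annotation <- generate_annotation(n_genes, n_chroms, chrom_length, seed = seed)
  sites <- generate_binding_sites(annotation, tf_names,
                                  sites_per_tf_per_gene_prob, site_length,
                                  window, decoy_fraction,
                                  chrom_length = chrom_length, seed = seed)
  variants <- generate_variants(sites, causal_tfs, p_variant_causal,
                                p_variant_background, offset_sd, seed = seed)
  truth <- sim_truth(causal_tfs = causal_tfs, interaction_lfc = interaction_lfc,
                     planted_fraction = planted_fraction, dispersion = dispersion,
                     baseline_log_mean = baseline_log_mean,
                     baseline_log_sd = baseline_log_sd,
                     planted_terms = if (n_planted_terms > 0)
                       sprintf("T%04d", seq_len(n_planted_terms)) else character(0),
                     seed = seed)
  cc <- generate_counts(annotation, sites, variants, truth,
                        n_replicates = n_replicates, library_size = library_size,
                        window = window)
  gene_sets <- generate_gene_sets(
    annotation, n_terms = n_terms, size_range = size_range,
    planted_terms = truth$planted_terms,
    planted_genes = cc$truth_table$gene_id[cc$truth_table$planted],
    seed = seed)
  list(annotation = annotation, sites = sites, variants = variants,
       truth = truth, counts = cc$counts, samples = cc$samples,
       truth_table = cc$truth_table, gene_sets = gene_sets)
}
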