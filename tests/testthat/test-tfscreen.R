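# Target assignment, variant flagging, 2x2 construction, Fisher/BH against
# enumeration oracles, eligibility boundaries, and variant-position KDEs.

toy_annotation <- function() {
  data.frame(gene_id = c("gplus", "gminus"),
             chrom = c("chr1", "chr1"),
             strand = c("+", "-"),
             tss = c(10000, 10000),
             exonic_length = c(1000, 1000),
             stringsAsFactors = FALSE)
}

toy_sites <- function(start, end, tf = "TF1", chrom = "chr1", strand = ".") {
  data.frame(site_id = sprintf("%s_s%03d", tf, seq_along(start)),
             tf_name = tf, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

test_that("target assignment follows the strand-aware upstream window", {
  ann <- toy_annotation()
  # + strand, tss 10000 (1-based): window covers 1-based [5000, 9999]
  s <- toy_sites(c(6000, 3000, 12000, 8000),
                 c(6200, 4000, 12100, 8100))
  tg <- assign_targets(s, ann, window = 5000)
  hits <- split(tg$gene_id, tg$site_id)
  expect_true("gplus" %in% hits[["TF1_s001"]])   # [6000,6200) inside
  expect_false("TF1_s002" %in% tg$site_id[tg$gene_id == "gplus"])
  # - strand, tss 10000: window covers 1-based [10001, 15000]
  expect_true("gminus" %in% hits[["TF1_s003"]])  # [12000,12100)
  expect_false(any(tg$gene_id == "gminus" & tg$site_id == "TF1_s004"))

  # 1-bp overlap counts by default; containment mode excludes straddlers
  straddle <- toy_sites(4950, 5150)  # 0-based; overlaps window start 4999
  expect_equal(suppressWarnings(assign_targets(straddle, ann))$gene_id, "gplus")
  expect_equal(nrow(assign_targets(straddle, ann, containment = TRUE)), 0)

  # unknown chromosomes are skipped with a warning
  odd <- toy_sites(c(6000, 6000), c(6200, 6200), chrom = c("chr1", "chrX"))
  expect_warning(tg2 <- assign_targets(odd, ann), "chrX")
  expect_equal(nrow(tg2), 1)
})

test_that("variant flags respect half-open boundaries and signed offsets", {
  s <- toy_sites(100, 120)
  v <- data.frame(chrom = "chr1", pos = c(110, 120, 101),
                  ref = "A", alt = "C", stringsAsFactors = FALSE)
  fl <- flag_variant_sites(s, v)
  # half-open rule start <= pos-1 < end: 1-based 120 maps to 0-based 119,
  # the last base of [100,120); 1-based 100 (0-based 99) would be outside
  expect_equal(fl$sites$n_variants, 3L)
  v_out <- data.frame(chrom = "chr1", pos = c(100, 121), ref = "A",
                      alt = "C", stringsAsFactors = FALSE)
  expect_equal(flag_variant_sites(s, v_out)$sites$n_variants, 0L)
  # center 110; pos 110 -> offset (109 + 0.5) - 110 = -0.5
  expect_equal(sort(fl$offsets$offset), c(-9.5, -0.5, 9.5))

  # three variants inside one site
  v3 <- data.frame(chrom = "chr1", pos = c(101, 105, 119), ref = "A",
                   alt = "G", stringsAsFactors = FALSE)
  expect_equal(flag_variant_sites(s, v3)$sites$n_variants, 3L)

  # "-" strand site flips the offset sign
  sm <- toy_sites(100, 120, strand = "-")
  flm <- flag_variant_sites(sm, v)
  expect_equal(sort(flm$offsets$offset), c(-9.5, 0.5, 9.5))
})

test_that("target table aggregates site flags per gene and drops untested genes", {
  targets <- data.frame(
    tf_name = "TF1", gene_id = c("g1", "g1", "g2", "g3"),
    site_id = c("s1", "s2", "s3", "s4"), stringsAsFactors = FALSE)
  flags <- list(
    sites = data.frame(site_id = c("s1", "s2", "s3", "s4"),
                       tf_name = "TF1", n_variants = c(2L, 0L, 0L, 1L),
                       stringsAsFactors = FALSE),
    offsets = data.frame(site_id = c("s1", "s1", "s4"), tf_name = "TF1",
                         pos = c(10, 20, 30), offset = c(-4.5, 8.5, 2.5),
                         stringsAsFactors = FALSE))
  ase <- data.frame(gene_id = c("g1", "g2"), f_interaction = c(5, 1),
                    p_interaction = c(0.01, 0.5), degenerate = FALSE,
                    delta_ase = c(TRUE, FALSE), stringsAsFactors = FALSE)
  tt <- build_target_table(targets, flags, ase)
  expect_equal(nrow(tt), 2)  # g3 has no dASE call
  g1 <- tt[tt$gene_id == "g1", ]
  expect_true(g1$has_variant)
  expect_equal(g1$n_variants, 2L)
  expect_equal(g1$min_center_distance, 4.5)
  g2 <- tt[tt$gene_id == "g2", ]
  expect_false(g2$has_variant)
  expect_equal(g2$n_variants, 0L)
  expect_true(is.na(g2$min_center_distance))
})

test_that("Fisher p equals the exhaustive fixed-margins oracle", {
  sym <- fisher_exact(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p, 1)

  ex <- fisher_exact(30, 10, 10, 30)
  expect_equal(ex$p, fisher_enum_oracle(30, 10, 10, 30), tolerance = 1e-12)

  extreme <- fisher_exact(10, 0, 0, 10)
  expect_identical(extreme$odds_ratio, Inf)
  expect_equal(extreme$p, fisher_enum_oracle(10, 0, 0, 10), tolerance = 1e-12)
  expect_equal(fisher_exact(0, 10, 10, 0)$odds_ratio, 0)

  set.seed(61)
  for (i in 1:500) {
    cells <- as.integer(rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1)))
    got <- fisher_exact(cells[1], cells[2], cells[3], cells[4])
    want <- fisher_enum_oracle(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p, want, tolerance = 1e-12)
  }
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
})

test_that("screen applies the 250-per-cell filter at its exact boundary", {
  mk_tf <- function(tf, a, b, c, d) {
    data.frame(
      tf_name = tf,
      gene_id = sprintf("%s_g%04d", tf, seq_len(a + b + c + d)),
      has_variant = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d)),
      n_variants = as.integer(rep(c(1, 1, 0, 0), c(a, b, c, d))),
      min_center_distance = NA_real_,
      delta_ase = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d)),
      stringsAsFactors = FALSE)
  }
  tt <- rbind(mk_tf("TFboundary", 300, 300, 300, 249),
              mk_tf("TFok", 300, 300, 300, 250))
  sc <- screen(tt, min_per_cell = 250)
  expect_false(sc$eligible[sc$tf_name == "TFboundary"])
  expect_true(sc$eligible[sc$tf_name == "TFok"])
  expect_true(is.na(sc$p[sc$tf_name == "TFboundary"]))
  # no TF lost or duplicated
  expect_setequal(sc$tf_name, c("TFboundary", "TFok"))

  single <- screen(mk_tf("only", 40, 10, 10, 40), min_per_cell = 5)
  expect_equal(single$q, single$p)

  expect_warning(screen(mk_tf("small", 1, 1, 1, 1), min_per_cell = 250),
                 "no TF passes")
})

test_that("BH correction matches the step-up oracle", {
  # worked example: p = (0.01, 0.02, 0.03, 0.04) over 4 TFs -> all q = 0.04
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  mk_tf <- function(tf, p_shift) {
    # construct an eligible TF whose Fisher p varies with p_shift
    a <- 30 + p_shift
    data.frame(tf_name = tf,
               gene_id = sprintf("%s_g%04d", tf, 1:80),
               has_variant = rep(c(TRUE, FALSE), each = 40),
               n_variants = as.integer(rep(c(1, 0), each = 40)),
               min_center_distance = NA_real_,
               delta_ase = c(rep(TRUE, a), rep(FALSE, 40 - a),
                             rep(TRUE, 40 - a), rep(FALSE, a)),
               stringsAsFactors = FALSE)
  }
  tt <- do.call(rbind, lapply(0:3, function(i) mk_tf(paste0("TF", i), i)))
  sc <- screen(tt, min_per_cell = 5)
  expect_equal(sc$q[order(sc$tf_name)], bh_oracle(sc$p[order(sc$tf_name)]),
               tolerance = 1e-12)

  set.seed(71)
  for (i in 1:500) {
    p <- runif(sample(1:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("variant-position KDEs are symmetric, peaked and normalized", {
  ann <- toy_annotation()
  # three sites upstream of gplus, variants at symmetric offsets
  s <- toy_sites(c(6000, 6500, 7000), c(6200, 6700, 7200))
  tg <- assign_targets(s, ann)
  # offsets symmetric about +0.5 around the center of the first site
  v <- data.frame(chrom = "chr1",
                  pos = c(6091, 6101, 6111),
                  ref = "A", alt = "C", stringsAsFactors = FALSE)
  fl <- flag_variant_sites(s, v)
  expect_equal(sort(fl$offsets$offset), c(-9.5, 0.5, 10.5))

  ase <- data.frame(gene_id = c("gplus", "gminus"), f_interaction = c(4, 1),
                    p_interaction = 0.1, degenerate = FALSE,
                    delta_ase = c(TRUE, FALSE), stringsAsFactors = FALSE)
  prof <- suppressWarnings(
    variant_position_profile("TF1", tg, fl, ase, bandwidth = 2))
  dens <- prof$offset_density
  expect_true(all(dens$stratum == "dASE+"))
  # grid is symmetric around 0, so the density must be too
  expect_lt(max(abs(dens$density - rev(dens$density))), 1e-9)
  expect_lt(abs(trapezoid(dens$x, dens$density) - 1), 1e-3)

  # a single repeated offset puts the mode at that value
  v1 <- data.frame(chrom = "chr1", pos = c(6106, 6606, 7106), ref = "A",
                   alt = "C", stringsAsFactors = FALSE)
  fl1 <- flag_variant_sites(s, v1)
  expect_true(all(fl1$offsets$offset == 5.5))
  prof1 <- suppressWarnings(
    variant_position_profile("TF1", tg, fl1, ase, bandwidth = 0.5))
  d1 <- prof1$offset_density
  expect_lt(abs(d1$x[which.max(d1$density)] - 5.5), 0.1)
})

test_that("dASE+ and dASE- offset strata separate when simulated apart", {
  # synthetic offsets: dASE+ genes N(+15, 5), dASE- genes N(0, 5)
  set.seed(81)
  n <- 60
  ann <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
                    strand = "+", tss = seq(20000, by = 20000, length.out = n),
                    exonic_length = 1000, stringsAsFactors = FALSE)
  s <- toy_sites(ann$tss - 3000, ann$tss - 2800)
  tg <- assign_targets(s, ann)
  expect_equal(nrow(tg), n)
  da <- rep(c(TRUE, FALSE), each = n / 2)
  center <- (s$start + s$end) / 2
  off <- round(ifelse(da, rnorm(n, 15, 5), rnorm(n, 0, 5)))
  v <- data.frame(chrom = "chr1", pos = as.integer(center + off + 1),
                  ref = "A", alt = "C", stringsAsFactors = FALSE)
  fl <- flag_variant_sites(s, v)
  ase <- data.frame(gene_id = ann$gene_id, f_interaction = ifelse(da, 9, 1),
                    p_interaction = 0.1, degenerate = FALSE, delta_ase = da,
                    stringsAsFactors = FALSE)
  prof <- variant_position_profile("TF1", tg, fl, ase, bandwidth = 5)
  dp <- prof$offset_density[prof$offset_density$stratum == "dASE+", ]
  dm <- prof$offset_density[prof$offset_density$stratum == "dASE-", ]
  expect_gt(dp$x[which.max(dp$density)], dm$x[which.max(dm$density)])
  # every stratum density integrates to one
  cp <- prof$count_density[prof$count_density$stratum == "dASE+", ]
  cm <- prof$count_density[prof$count_density$stratum == "dASE-", ]
  for (d in list(dp, dm, cp, cm))
    expect_lt(abs(trapezoid(d$x, d$density) - 1), 1e-3)
})

test_that("screen counts are reconstructible by hand from the ground truth", {
  # with p_background = 0 and site prob 1, the causal TF's 2x2 follows
  # exactly from SimTruth bookkeeping plus the dASE calls; a grid annotation
  # keeps upstream windows disjoint so no variant can straddle gene contexts
  ann <- data.frame(gene_id = sprintf("g%05d", 1:300), chrom = "chr1",
                    strand = rep(c("+", "-"), 150),
                    tss = seq(20001, by = 20000, length.out = 300),
                    exonic_length = 1500, stringsAsFactors = FALSE)
  sites <- generate_binding_sites(ann, sprintf("TF%02d", 1:5), 1, 200,
                                  decoy_fraction = 0, seed = 91)
  variants <- generate_variants(sites, "TF01", 1, 0, 30, seed = 91)
  truth <- sim_truth(causal_tfs = "TF01", seed = 91)
  cc <- generate_counts(ann, sites, variants, truth, 3, 3e5)
  tpm <- counts_to_tpm(cc$counts, ann)
  keep <- filter_expressed(cc$counts)
  tpm <- tpm[rownames(tpm) %in% keep, , drop = FALSE]
  ase <- classify_delta_ase(ase_scan(tpm, cc$samples))
  tt <- build_target_table(assign_targets(sites, ann),
                           flag_variant_sites(sites, variants), ase)
  sc <- suppressWarnings(screen(tt, min_per_cell = 0))
  causal <- sc[sc$tf_name == "TF01", ]

  called <- ase$gene_id[ase$delta_ase %in% TRUE]
  tested <- ase$gene_id[!is.na(ase$delta_ase)]
  hv <- cc$truth_table$gene_id[cc$truth_table$variant_target]
  expect_identical(causal$a, sum(tested %in% hv & tested %in% called))
  expect_identical(causal$b, sum(tested %in% hv & !(tested %in% called)))
  expect_identical(causal$c, sum(!(tested %in% hv) & tested %in% called))
  expect_identical(causal$d, sum(!(tested %in% hv) & !(tested %in% called)))
  # background TFs have no variant-bearing targets at all
  expect_true(all(sc$a[sc$tf_name != "TF01"] == 0))
  expect_true(all(sc$b[sc$tf_name != "TF01"] == 0))
})
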