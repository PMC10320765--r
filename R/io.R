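# Readers and writers for the declared external formats: flat TSVs for
# annotation/counts/metadata/gene sets, GFF3 for gene features, BED6 for
# binding sites, and minimal VCF 4.2 for the SNV catalog. All writers are
# deterministic (byte-identical output for identical inputs).

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read a gene annotation TSV
#' @param annotation Annotation data.frame.
#' @param path File path.
#' @return The path (writer) or the annotation data.frame (reader).
#' @export
write_annotation_tsv <- function(annotation, path) {
  assert_annotation(annotation)
  write_tsv_plain(annotation, path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) assert_annotation(read_tsv_plain(path))

#' Write gene features as GFF3
#'
#' One \code{gene} feature per annotated gene; the TSS is encoded in the
#' strand-aware feature start.
#'
#' @param annotation Annotation data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  assert_annotation(annotation)
  plus <- annotation$strand == "+"
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(
      start = ifelse(plus, annotation$tss,
                     pmax(1, annotation$tss - annotation$exonic_length + 1)),
      end = ifelse(plus, annotation$tss + annotation$exonic_length - 1,
                   annotation$tss)),
    strand = annotation$strand)
  gr$type <- "gene"
  gr$ID <- annotation$gene_id
  gr$exonic_length <- annotation$exonic_length
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write / read binding sites as BED6
#'
#' The BED name field holds the TF name and the score field the number 0;
#' coordinates are BED-native 0-based half-open. Site ids are reconstructed
#' on read as \code{tf_chrom_start}.
#'
#' @param binding_sites Site table.
#' @param path File path.
#' @return The path (writer) or a site data.frame (reader).
#' @export
write_sites_bed <- function(binding_sites, path) {
  assert_sites(binding_sites)
  df <- data.frame(chrom = binding_sites$chrom,
                   start = format(binding_sites$start, scientific = FALSE, trim = TRUE),
                   end = format(binding_sites$end, scientific = FALSE, trim = TRUE),
                   name = binding_sites$tf_name,
                   score = 0L,
                   strand = binding_sites$strand %||% ".",
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_bed
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  out <- data.frame(
    tf_name = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE)
  out$site_id <- sprintf("%s_%s_%d", out$tf_name, out$chrom, out$start)
  # disambiguate identical (tf, chrom, start) duplicates deterministically
  dup <- duplicated(out$site_id)
  if (any(dup))
    out$site_id <- make.unique(out$site_id, sep = "_d")
  out[, c("site_id", "tf_name", "chrom", "start", "end", "strand")]
}

#' Write / read the SNV catalog as minimal VCF 4.2
#'
#' The writer emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO columns with contig
#' headers; the reader (via vcfR) keeps biallelic SNVs only.
#'
#' @param variants SNV data.frame (\code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}).
#' @param path File path.
#' @return The path (writer) or an SNV data.frame (reader).
#' @export
write_variants_vcf <- function(variants, path) {
  assert_variants(variants)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(variants$chrom)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0) {
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", variants$chrom,
                    as.integer(variants$pos), variants$ref, variants$alt)
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  out[nchar(out$ref) == 1 & nchar(out$alt) == 1 &
        !grepl(",", out$alt, fixed = TRUE), , drop = FALSE]
}

#' Write / read the allele-resolved count matrix and its sample sidecar
#'
#' @param counts Genes x samples integer matrix.
#' @param samples Sample metadata data.frame.
#' @param path Counts TSV path; the reader takes the same pair of paths.
#' @param meta_path Sidecar TSV path for the sample metadata.
#' @return The counts path (writer) or \code{list(counts, samples)} (reader).
#' @export
write_counts_tsv <- function(counts, samples, path, meta_path) {
  assert_samples(samples, ncol(counts))
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  write_tsv_plain(samples, meta_path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, meta_path) {
  df <- read_tsv_plain(path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  samples <- read_tsv_plain(meta_path)
  assert_samples(samples, ncol(counts))
  if (!identical(colnames(counts), samples$sample_id))
    stop("count matrix columns do not match the sample metadata order")
  list(counts = counts, samples = samples)
}

#' Write / read a gene-set catalog TSV
#'
#' Long format: one row per (term, gene), with columns \code{term_id},
#' \code{term_name}, \code{gene_id}.
#'
#' @param catalog Named list of gene-id vectors (with optional
#'   \code{term_name} attribute).
#' @param path File path.
#' @return The path (writer) or a catalog list (reader).
#' @export
write_gene_sets_tsv <- function(catalog, path) {
  term_names <- attr(catalog, "term_name")
  df <- data.frame(
    term_id = rep(names(catalog), lengths(catalog)),
    term_name = rep(if (is.null(term_names)) names(catalog)
                    else unname(term_names[names(catalog)]), lengths(catalog)),
    gene_id = unlist(catalog, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' @rdname write_gene_sets_tsv
#' @export
read_gene_sets_tsv <- function(path) {
  df <- read_tsv_plain(path)
  sets <- split(df$gene_id, df$term_id)
  nm <- unique(df[, c("term_id", "term_name")])
  attr(sets, "term_name") <- stats::setNames(nm$term_name, nm$term_id)
  sets
}
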