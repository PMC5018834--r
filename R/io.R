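#' Read protein FASTA with optional species tags
#'
#' Headers may carry a `species=` key (e.g. `>H2A3_like species=mouse`);
#' records without one get species "unknown".
#'
#' @param path FASTA file path.
#' @return A tibble with `id`, `species`, `sequence`.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  id <- sub("[ \t].*$", "", headers)
  species <- ifelse(grepl("species=", headers),
                    sub(".*species=([^ \t]+).*", "\\1", headers), "unknown")
  tibble::tibble(id = id, species = species,
                 sequence = as.character(aas, use.names = FALSE))
}

#' Write protein FASTA with species tags
#'
#' @param records Data frame with `id`, `species`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as.data.frame(records)
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    c(sprintf(">%s species=%s", records$id[i], records$species[i]),
      records$sequence[i])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED peak file
#'
#' BED is 0-based half-open on disk; the returned `GRanges` follows the
#' Bioconductor 1-based closed convention (a BED line `chr1 100 200` covers
#' bases 101..200 1-based, width 100). Column 4, when present, becomes
#' `peak_id`.
#'
#' @param path BED file path.
#' @return `GRanges` with a `peak_id` metadata column.
#' @export
read_bed_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr$peak_id <- if (!is.null(gr$name) && !all(is.na(gr$name))) gr$name else
    sprintf("peak_%d", seq_along(gr))
  gr
}

#' Write peaks to BED
#'
#' @param peaks `GRanges` with optional `peak_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = BiocGenerics::start(peaks) - 1L,
                   end = BiocGenerics::end(peaks),
                   name = .peak_ids(peaks))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects `gene` features with an ID (or gene_id) attribute and `exon`
#' features whose `Parent` (or gene_id) points at a gene. GFF3's 1-based
#' inclusive coordinates map directly onto the internal `GRanges`
#' convention.
#'
#' @param path GFF3 file path.
#' @return A [gene_models()] object.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  gid <- if (!is.null(genes$gene_id) && !all(is.na(genes$gene_id)))
    genes$gene_id else genes$ID
  genes$gene_id <- as.character(gid)
  parent <- if (!is.null(exons$Parent) && length(exons$Parent) > 0)
    as.character(unlist(exons$Parent)) else as.character(exons$gene_id)
  exons$gene_id <- parent
  gene_models(genes, exons)
}

#' Write gene models to GFF3
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(models, path) {
  g <- models$genes
  e <- models$exons
  lines <- c("##gff-version 3",
    sprintf("chr%s\th2aglyco\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s",
            sub("^chr", "", as.character(GenomicRanges::seqnames(g))),
            BiocGenerics::start(g), BiocGenerics::end(g),
            as.character(BiocGenerics::strand(g)), g$gene_id, g$gene_id),
    sprintf("chr%s\th2aglyco\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
            sub("^chr", "", as.character(GenomicRanges::seqnames(e))),
            BiocGenerics::start(e), BiocGenerics::end(e),
            as.character(BiocGenerics::strand(e)), e$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column expression TSV (gene_id, value)
#'
#' @param path TSV path (header optional; detected on the first line).
#' @return Named numeric vector of expression values.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.numeric(df[[2]]) && suppressWarnings(is.na(as.numeric(df[1, 2])))) {
    df <- df[-1, , drop = FALSE]  # header row
  }
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
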