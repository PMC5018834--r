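#' Gene models for peak annotation
#'
#' Bundles a set of strand-aware gene spans with their exons. Internally all
#' intervals are `GRanges` (1-based, closed), the Bioconductor convention;
#' BED/GFF3 files are converted at the I/O boundary. The transcription start
#' site of a gene is its `start` on the plus strand and its `end` on the
#' minus strand.
#'
#' @param genes `GRanges` with a `gene_id` metadata column and strand
#'   in {+, -}.
#' @param exons `GRanges` with a `gene_id` metadata column; every exon must
#'   lie inside its gene's span.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(exons, "GRanges"))
  if (is.null(genes$gene_id) || is.null(exons$gene_id)) {
    stop("genes and exons need a gene_id metadata column", call. = FALSE)
  }
  if (any(as.character(BiocGenerics::strand(genes)) == "*")) {
    stop("gene strand must be + or -", call. = FALSE)
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons\n",
              length(x$genes), length(x$exons)))
  invisible(x)
}

#' Strand-aware TSS positions (1-based)
#'
#' @param genes `GRanges` of genes with strand + or -.
#' @return Integer vector of TSS coordinates.
#' @export
tss_positions <- function(genes) {
  ifelse(as.character(BiocGenerics::strand(genes)) == "+",
         BiocGenerics::start(genes), BiocGenerics::end(genes))
}

.peak_midpoints <- function(peaks) {
  # 0-based midpoint floor((start0+end0)/2), expressed as a 1-based base
  as.integer(floor((BiocGenerics::start(peaks) - 1 +
                      BiocGenerics::end(peaks)) / 2) + 1)
}

.peak_ids <- function(peaks) {
  if (!is.null(peaks$peak_id)) as.character(peaks$peak_id)
  else if (!is.null(names(peaks))) names(peaks)
  else sprintf("peak_%d", seq_along(peaks))
}

#' Assign peaks to TSS / gene body / intergenic categories
#'
#' A peak's category is decided by its midpoint: `TSS` if the midpoint lies
#' within `tss_halfwidth` bp of any gene's strand-aware TSS; otherwise `GB`
#' if the midpoint lies inside any gene span; otherwise `INTERGENIC`. TSS
#' takes priority over GB, so the three categories partition the peaks. All
#' qualifying genes at the winning priority level are reported.
#'
#' @param peaks `GRanges` of peaks (optional `peak_id` metadata column).
#' @param models A [gene_models()] object.
#' @param tss_halfwidth TSS window half-width in bp (default 2000).
#' @return A tibble with `peak_id`, `midpoint` (1-based), `category`, and a
#'   `gene_ids` list-column of owning gene ids.
#' @export
assign_category <- function(peaks, models, tss_halfwidth = 2000) {
  stopifnot(inherits(models, "gene_models"))
  genes <- models$genes
  mid <- .peak_midpoints(peaks)
  midpts <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(start = mid, width = 1))
  tss <- tss_positions(genes)
  tss_win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(start = pmax(tss - tss_halfwidth, 1),
                     end = tss + tss_halfwidth))
  ov_tss <- GenomicRanges::findOverlaps(midpts, tss_win, ignore.strand = TRUE)
  ov_gb <- GenomicRanges::findOverlaps(midpts, genes, ignore.strand = TRUE)
  n <- length(peaks)
  category <- rep("INTERGENIC", n)
  gene_ids <- rep(list(character()), n)
  gb_by_peak <- split(genes$gene_id[S4Vectors::subjectHits(ov_gb)],
                      factor(S4Vectors::queryHits(ov_gb), levels = seq_len(n)))
  tss_by_peak <- split(genes$gene_id[S4Vectors::subjectHits(ov_tss)],
                       factor(S4Vectors::queryHits(ov_tss), levels = seq_len(n)))
  for (k in seq_len(n)) {
    if (length(tss_by_peak[[k]]) > 0) {
      category[k] <- "TSS"
      gene_ids[[k]] <- unique(tss_by_peak[[k]])
    } else if (length(gb_by_peak[[k]]) > 0) {
      category[k] <- "GB"
      gene_ids[[k]] <- unique(gb_by_peak[[k]])
    }
  }
  tibble::tibble(peak_id = .peak_ids(peaks), midpoint = mid,
                 category = category, gene_ids = gene_ids)
}

#' Peak category counts and fractions
#'
#' @inheritParams assign_category
#' @return A list of class `category_report`: `counts` and `fractions` over
#'   {TSS, GB, INTERGENIC} (fractions sum to 1), plus `exon_fraction` /
#'   `intron_fraction` among genic peaks (NA when no peak is genic).
#' @export
category_fractions <- function(peaks, models, tss_halfwidth = 2000) {
  if (length(peaks) == 0) stop("no peaks to categorize", call. = FALSE)
  asg <- assign_category(peaks, models, tss_halfwidth)
  lev <- c("TSS", "GB", "INTERGENIC")
  counts <- vapply(lev, function(l) sum(asg$category == l), integer(1))
  ei <- exon_intron_fraction(peaks, models, tss_halfwidth)
  structure(list(counts = counts, fractions = counts / length(peaks),
                 exon_fraction = ei[["exon_fraction"]],
                 intron_fraction = ei[["intron_fraction"]]),
            class = "category_report")
}

#' @export
print.category_report <- function(x, ...) {
  cat(sprintf("peaks: TSS %.1f%%, GB %.1f%%, intergenic %.1f%%\n",
              100 * x$fractions[["TSS"]], 100 * x$fractions[["GB"]],
              100 * x$fractions[["INTERGENIC"]]))
  if (!is.na(x$exon_fraction)) {
    cat(sprintf("genic peaks: %.1f%% exonic, %.1f%% intronic\n",
                100 * x$exon_fraction, 100 * x$intron_fraction))
  }
  invisible(x)
}

#' Exon/intron split of genic peaks
#'
#' Among peaks whose midpoint lies inside any gene span (including
#' TSS-category peaks whose midpoint is inside a gene), a peak is exonic if
#' its midpoint falls within any exon of an owning gene, else intronic.
#'
#' @inheritParams assign_category
#' @return Named numeric vector `c(exon_fraction, intron_fraction)`;
#'   both `NA` when no peak is genic.
#' @export
exon_intron_fraction <- function(peaks, models, tss_halfwidth = 2000) {
  mid <- .peak_midpoints(peaks)
  midpts <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(start = mid, width = 1))
  in_gene <- IRanges::overlapsAny(midpts, models$genes, ignore.strand = TRUE)
  if (!any(in_gene)) {
    return(c(exon_fraction = NA_real_, intron_fraction = NA_real_))
  }
  in_exon <- IRanges::overlapsAny(midpts, models$exons, ignore.strand = TRUE)
  n_genic <- sum(in_gene)
  n_exonic <- sum(in_gene & in_exon)
  c(exon_fraction = n_exonic / n_genic,
    intron_fraction = 1 - n_exonic / n_genic)
}

#' Target genes of a peak set
#'
#' A gene is a target if any peak is assigned to it under either the TSS or
#' the GB category.
#'
#' @inheritParams assign_category
#' @return Character vector of unique gene ids.
#' @export
target_genes <- function(peaks, models, tss_halfwidth = 2000) {
  asg <- assign_category(peaks, models, tss_halfwidth)
  sort(unique(unlist(asg$gene_ids[asg$category %in% c("TSS", "GB")])))
}

#' Venn counts of two gene sets
#'
#' @param a,b Character vectors (gene ids).
#' @return Named integer vector `c(only_a, shared, only_b)`.
#' @examples
#' venn_counts(c("A", "B", "C"), c("B", "C", "D"))  # 1 2 1
#' @export
venn_counts <- function(a, b) {
  a <- unique(a); b <- unique(b)
  c(only_a = length(setdiff(a, b)), shared = length(intersect(a, b)),
    only_b = length(setdiff(b, a)))
}

#' Association between target genes and expression
#'
#' Compares the expression of target genes with the remaining background
#' genes by a one-sided Wilcoxon rank-sum test (normal approximation with
#' tie correction; alternative: targets greater), and reports five-number
#' summaries for both groups. When every expression value is identical the
#' test is undefined and p = 0.5 is returned by convention.
#'
#' @param targets Character vector of target gene ids (subset of
#'   `background`, at least 2 with expression values).
#' @param expr Named numeric vector of expression values (e.g. log-ratios
#'   vs a reference sample), or a data frame with columns `gene_id`, `value`.
#' @param background Character vector of background gene ids (defaults to
#'   all genes in `expr`).
#' @return A list of class `expression_association`: `summary` (tibble of
#'   group five-number summaries), `p_value`, `n_target`, `n_background`.
#' @export
expression_association <- function(targets, expr, background = NULL) {
  if (is.data.frame(expr)) {
    expr <- stats::setNames(expr$value, expr$gene_id)
  }
  if (is.null(background)) background <- names(expr)
  if (!all(targets %in% background)) {
    stop("targets must be a subset of background", call. = FALSE)
  }
  x <- expr[intersect(targets, names(expr))]
  y <- expr[setdiff(intersect(background, names(expr)), targets)]
  if (length(x) < 2) stop("need >= 2 targets with expression", call. = FALSE)
  if (length(y) < 2) stop("need >= 2 background genes with expression",
                          call. = FALSE)
  five <- function(v) {
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
    tibble::tibble(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  }
  smry <- rbind(cbind(group = "target", n = length(x), five(x)),
                cbind(group = "background", n = length(y), five(y)))
  if (stats::sd(c(x, y)) == 0) {
    p <- 0.5  # complete tie: no evidence either way
  } else {
    p <- stats::wilcox.test(x, y, alternative = "greater",
                            exact = FALSE, correct = TRUE)$p.value
  }
  structure(list(summary = tibble::as_tibble(smry), p_value = p,
                 n_target = length(x), n_background = length(y)),
            class = "expression_association")
}

#' @export
print.expression_association <- function(x, ...) {
  cat(sprintf(
    "targets (n=%d) vs background (n=%d): one-sided rank-sum p = %.3g\n",
    x$n_target, x$n_background, x$p_value))
  print(x$summary)
  invisible(x)
}
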