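test_that("midpoint rules assign TSS, GB and intergenic categories", {
  models <- toy_models()
  # 1 kb upstream of gene A's + TSS (TSS = 10000)
  expect_identical(assign_category(peak_at(9000), models)$category, "TSS")
  # mid-gene, 10 kb holds only for A's far end: midpoint 19500 is > 2 kb from TSS
  asg <- assign_category(peak_at(19500), models)
  expect_identical(asg$category, "GB")
  expect_identical(asg$gene_ids[[1]], "A")
  # gene B is on the minus strand: its TSS is the interval end (60000)
  expect_identical(assign_category(peak_at(61000), models)$category, "TSS")
  expect_identical(assign_category(peak_at(55000), models)$category, "GB")
  # far from everything
  expect_identical(assign_category(peak_at(300000), models)$category,
                   "INTERGENIC")
  # TSS priority over GB inside the window
  expect_identical(assign_category(peak_at(10500), models)$category, "TSS")
})

test_that("exon/intron split follows the midpoint", {
  models <- toy_models()
  ei <- exon_intron_fraction(peak_at(19000), models)   # inside exon 2 of A
  expect_equal(unname(ei[["exon_fraction"]]), 1)
  ei2 <- exon_intron_fraction(peak_at(15000), models)  # between A's exons
  expect_equal(unname(ei2[["intron_fraction"]]), 1)
  # no genic peaks: absent values, not zeros
  ei3 <- exon_intron_fraction(peak_at(300000), models)
  expect_true(all(is.na(ei3)))
})

test_that("category report sums to 1 and degenerate sets behave", {
  models <- toy_models()
  peaks <- c(peak_at(19500, id = "p1"), peak_at(19500, id = "p2"))
  rep_ <- category_fractions(peaks, models)
  expect_equal(sum(rep_$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(rep_$fractions[["GB"]]), 1)
  expect_error(category_fractions(GenomicRanges::GRanges(), models),
               "no peaks")
})

test_that("planted fractions are recovered within binomial tolerance", {
  for (s in 1:3) {
    sim <- sim_genome_and_peaks(n_peaks = 2000, seed = 70 + s)
    rep_ <- category_fractions(sim$peaks, sim$models)
    planted <- table(factor(sim$truth$category,
                            c("TSS", "GB", "INTERGENIC"))) / 2000
    expect_lt(max(abs(rep_$fractions - as.numeric(planted))), 0.03)
    expect_lt(abs(rep_$exon_fraction -
                    mean(sim$truth$exonic, na.rm = TRUE)), 0.04)
  }
})

test_that("interval assignment agrees with a brute-force scan", {
  sim <- sim_genome_and_peaks(n_genes = 50, n_peaks = 500, seed = 99)
  asg <- assign_category(sim$peaks, sim$models)
  g <- sim$models$genes
  tss <- tss_positions(g)
  gs <- BiocGenerics::start(g); ge <- BiocGenerics::end(g)
  mids <- asg$midpoint
  for (k in seq_along(mids)) {
    in_tss <- any(mids[k] >= tss - 2000 & mids[k] <= tss + 2000)
    in_gb <- any(mids[k] >= gs & mids[k] <= ge)
    want <- if (in_tss) "TSS" else if (in_gb) "GB" else "INTERGENIC"
    expect_identical(asg$category[k], want)
  }
})

test_that("annotation is invariant to peak order and coordinate mirroring", {
  sim <- sim_genome_and_peaks(n_genes = 30, n_peaks = 300, seed = 123)
  rep1 <- category_fractions(sim$peaks, sim$models)
  perm <- sample(length(sim$peaks))
  rep2 <- category_fractions(sim$peaks[perm], sim$models)
  expect_identical(rep1$counts, rep2$counts)
  # mirror all coordinates around L and flip strands
  L <- 20e6
  mirror <- function(gr) {
    s <- L - BiocGenerics::end(gr) + 1
    e <- L - BiocGenerics::start(gr) + 1
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::IRanges(start = s, end = e))
    str <- as.character(BiocGenerics::strand(gr))
    BiocGenerics::strand(out) <- chartr("+-", "-+", str)
    S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
    out
  }
  mmodels <- gene_models(mirror(sim$models$genes), mirror(sim$models$exons))
  rep3 <- category_fractions(mirror(sim$peaks), mmodels)
  expect_identical(unname(rep1$counts), unname(rep3$counts))
  expect_equal(rep1$exon_fraction, rep3$exon_fraction)
})

test_that("target genes and Venn counts are set-exact", {
  expect_identical(venn_counts(c("A", "B", "C"), c("B", "C", "D")),
                   c(only_a = 1L, shared = 2L, only_b = 1L))
  expect_identical(venn_counts(c("A", "B"), c("C")),
                   c(only_a = 2L, shared = 0L, only_b = 1L))
  models <- toy_models()
  peaks <- c(peak_at(9000, id = "p1"), peak_at(55000, id = "p2"),
             peak_at(300000, id = "p3"))
  expect_identical(target_genes(peaks, models), c("A", "B"))
})

test_that("expression association detects a planted shift and handles ties", {
  genes <- sprintf("g%04d", 1:2200)
  targets <- genes[1:200]
  expr <- sim_expression(genes, targets, delta = 1, sigma = 1, seed = 7)
  res <- expression_association(targets, expr)
  expect_lt(res$p_value, 0.05)
  expect_identical(res$n_target, 200L)
  # degenerate complete tie
  tied <- tibble::tibble(gene_id = genes, value = 1)
  expect_equal(expression_association(targets, tied)$p_value, 0.5)
  expect_error(expression_association(c("zz"), expr), "subset")
})
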