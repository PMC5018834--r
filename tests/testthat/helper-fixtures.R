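# Shared fixtures and independent oracles.

G37K74 <- "GNYSERVGAGAPVYLAAVLEYLTAEILELAGNAARDNK"

g37k74_peptide <- function(modified = FALSE) {
  p <- peptide(G37K74, start = 37)
  if (modified) p <- add_hexnac(p, 40) else p
}

fixture_fasta <- function() {
  system.file("extdata", "synthetic_h2a_isoforms.fasta", package = "h2aglyco")
}

random_peptide <- function(min_len = 5, max_len = 25) {
  aa <- names(mass_table()$residues)
  paste(sample(aa, sample(min_len:max_len, 1), replace = TRUE), collapse = "")
}

# independent residue-sum oracle: per-character lookup, no shared code path
oracle_mass <- function(seq) {
  mt <- mass_table()
  total <- mt$water
  for (ch in strsplit(seq, "")[[1]]) total <- total + mt$residues[[ch]]
  total
}

# brute-force all-pairs precursor scan on an outer-product matrix
oracle_pairs <- function(ions, delta, tol_ppm) {
  mass <- ions$charge * ions$mz - ions$charge * 1.007276
  dm <- outer(mass, mass, function(a, b) b - a)  # heavy - light
  hits <- which(dm > 0 & abs(dm - delta) <=
                  tol_ppm * 1e-6 * matrix(mass, nrow(dm), ncol(dm),
                                          byrow = TRUE),
                arr.ind = TRUE)
  hits[order(mass[hits[, 1]]), , drop = FALSE]  # (light idx, heavy idx)
}

# random additive distance matrix with known unrooted topology
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
  list(tree = tr, d = stats::cophenetic(tr))
}

# unrooted topology equality via Robinson-Foulds distance
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1] == 0
}

# hand-built two-gene toy genome: gene A on +, gene B on -, two exons each
toy_models <- function() {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(10000, 50000), end = c(20000, 60000)),
    strand = c("+", "-"))
  genes$gene_id <- c("A", "B")
  exons <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(10000, 18000, 50000, 58000),
                     end = c(12000, 20000, 52000, 60000)),
    strand = c("+", "+", "-", "-"))
  exons$gene_id <- c("A", "A", "B", "B")
  gene_models(genes, exons)
}

peak_at <- function(midpoint, width = 200, id = "p1") {
  half <- width %/% 2
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = midpoint - half, end = midpoint + half))
  gr$peak_id <- id
  gr
}
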