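test_that("generators are deterministic and leave the RNG state alone", {
  pep <- g37k74_peptide()
  a <- sim_spectrum(pep, seed = 5)
  b <- sim_spectrum(pep, seed = 5)
  expect_identical(a$spectrum$mz, b$spectrum$mz)
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sim_spectrum(pep, seed = 5)); after <- runif(1)
  expect_identical(before, after)
  f1 <- sim_isoform_family(seed = 8)
  f2 <- sim_isoform_family(seed = 8)
  expect_identical(f1$records, f2$records)
  g1 <- sim_genome_and_peaks(n_peaks = 100, seed = 8)
  g2 <- sim_genome_and_peaks(n_peaks = 100, seed = 8)
  expect_identical(g1$truth, g2$truth)
})

test_that("noise-free spectra equal the theoretical ladder exactly", {
  pep <- g37k74_peptide()
  sim <- sim_spectrum(pep, max_charge = 2, jitter_ppm = 0, n_noise = 0,
                      dropout = 0, seed = 1)
  ions <- theoretical_fragments(pep, max_charge = 2)
  expect_equal(sort(sim$spectrum$mz), sort(ions$mz), tolerance = 1e-9)
  only_noise <- sim_spectrum(pep, max_charge = 2, jitter_ppm = 0,
                             n_noise = 25, dropout = 1, seed = 1)
  expect_length(only_noise$spectrum$mz, 25)
  expect_false(any(only_noise$truth$emitted))
})

test_that("m/z jitter has the requested scale", {
  pep <- peptide("ACSTKGGWK")
  errs <- numeric(0)
  for (s in 1:60) {
    sim <- sim_spectrum(pep, max_charge = 2, jitter_ppm = 5, n_noise = 0,
                        seed = s)
    th <- sim$truth$mz[sim$truth$emitted]
    errs <- c(errs, (sort(sim$spectrum$mz) - sort(th)) / sort(th) * 1e6)
  }
  expect_gt(length(errs), 500)
  expect_gt(sd(errs), 4)
  expect_lt(sd(errs), 6)
})

test_that("a rate-free family is one identical copy per species", {
  fam <- sim_isoform_family(birth_death_params(duplication = 0, loss = 0,
                                               substitution = 0,
                                               n_species = 5,
                                               plant_s40 = FALSE),
                            seed = 2)
  expect_identical(nrow(fam$records), 5L)
  expect_identical(sort(fam$records$species), sprintf("sp%d", 1:5))
  root_a40 <- sub("^(.{39})S", "\\1A", ref_h2a3())
  expect_true(all(fam$records$sequence == root_a40))
  expect_false(fam$extinct)
})

test_that("SER40 leaves are exactly the planted lineage's descendants", {
  for (s in 1:10) {
    fam <- sim_isoform_family(birth_death_params(site40_multiplier = 0),
                              seed = 300 + s)
    if (fam$extinct) next
    expect_identical(unname(fam$site40_states == "S"), unname(fam$planted))
  }
})

test_that("extinction frequency rises with the loss rate", {
  rates <- c(0.5, 2, 8)
  extinct_freq <- vapply(rates, function(lr) {
    mean(vapply(1:40, function(s) {
      sim_isoform_family(birth_death_params(duplication = 0.05, loss = lr,
                                            substitution = 0, n_species = 4,
                                            depth = 2),
                         seed = 7000 + s)$extinct
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(extinct_freq) >= 0))
  expect_gt(extinct_freq[3], extinct_freq[1])
})

test_that("degenerate planted fractions land every peak in one category", {
  sim <- sim_genome_and_peaks(n_genes = 20,
                              fractions = c(tss = 1, gb = 0, intergenic = 0),
                              n_peaks = 50, seed = 3)
  expect_true(all(sim$truth$category == "TSS"))
  rep_ <- category_fractions(sim$peaks, sim$models)
  expect_equal(unname(rep_$fractions[["TSS"]]), 1)
  expect_error(sim_genome_and_peaks(n_genes = 5000, chrom_length = 1e6),
               "infeasible geometry")
})

test_that("expression generator matches its planted model", {
  genes <- sprintf("g%d", 1:10000)
  targets <- genes[1:5000]
  expr <- sim_expression(genes, targets, delta = 1, sigma = 1, seed = 4)
  expect_lt(abs(mean(expr$value[expr$gene_id %in% targets]) - 1), 0.1)
  exact <- sim_expression(genes[1:4], genes[1:2], delta = 2, sigma = 0,
                          seed = 1)
  expect_identical(exact$value, c(2, 2, 0, 0))
})
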