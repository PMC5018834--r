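# spectra built directly from theoretical ladders so presence/absence of
# the diagnostic y ions is exactly controlled

.ladder_spectrum <- function(pep, drop = character(), max_charge = 3) {
  ions <- theoretical_fragments(pep, max_charge = max_charge)
  keep <- !(ions$label %in% drop)
  spectrum(ions$mz[keep], rep(1, sum(keep)))
}

test_that("modification-specific y33 confines the site to residues 37-41", {
  pep <- g37k74_peptide()
  ions <- theoretical_fragments(pep, max_charge = 3)
  # unmodified spectrum lacks y33 at every charge; modified has the full ladder
  mod <- match_spectrum(.ladder_spectrum(pep), ions)
  unmod <- match_spectrum(
    .ladder_spectrum(pep, drop = c("y33^1+", "y33^2+", "y33^3+")), ions)
  loc <- localize_glycosite(mod, unmod, pep)
  expect_identical(loc$window, c(37L, 41L))
  expect_identical(loc$candidate_sites, 40L)
  expect_identical(loc$call, 40L)
  expect_true(any(grepl("^y33", loc$evidence)))
})

test_that("identical spectra give the whole-peptide window and ambiguity", {
  pep <- g37k74_peptide()
  ions <- theoretical_fragments(pep, max_charge = 2)
  ann <- match_spectrum(.ladder_spectrum(pep, max_charge = 2), ions)
  loc <- localize_glycosite(ann, ann, pep)
  expect_identical(loc$window, c(37L, 74L))
  expect_identical(loc$candidate_sites, c(40L, 59L))
  expect_identical(loc$call, "ambiguous")
  expect_length(loc$evidence, 0)
})

test_that("a full modification-specific y-ladder pins a planted site", {
  pep <- peptide("ACSTK")
  ions <- theoretical_fragments(pep, max_charge = 2)
  # site S3: y1 and y2 do not span it and appear only in the modified run
  mod <- match_spectrum(.ladder_spectrum(pep, max_charge = 2), ions)
  unmod <- match_spectrum(
    .ladder_spectrum(pep, drop = c("y1^1+", "y1^2+", "y2^1+", "y2^2+"),
                     max_charge = 2), ions)
  loc <- localize_glycosite(mod, unmod, pep)
  expect_identical(loc$call, 3L)
})

test_that("planted sites are recovered from jittered noisy spectrum pairs", {
  pep <- g37k74_peptide()
  ions <- theoretical_fragments(pep, max_charge = 3)
  y33 <- c("y33^1+", "y33^2+", "y33^3+")
  recovered <- 0L
  for (s in 1:20) {
    modsim <- sim_spectrum(pep, max_charge = 3, jitter_ppm = 5, n_noise = 100,
                           seed = 1000 + s)
    unmodsim <- sim_spectrum(pep, max_charge = 3, jitter_ppm = 5,
                             n_noise = 100, drop_ions = y33, seed = 2000 + s)
    loc <- localize_glycosite(match_spectrum(modsim$spectrum, ions, 15),
                              match_spectrum(unmodsim$spectrum, ions, 15),
                              pep)
    if (identical(loc$call, 40L)) recovered <- recovered + 1L
  }
  expect_gte(recovered / 20, 0.9)
})

test_that("noiseless spectrum pairs always recover the planted site", {
  pep <- g37k74_peptide()
  ions <- theoretical_fragments(pep, max_charge = 3)
  y33 <- c("y33^1+", "y33^2+", "y33^3+")
  for (s in 1:10) {
    modsim <- sim_spectrum(pep, max_charge = 3, jitter_ppm = 0, n_noise = 0,
                           seed = s)
    unmodsim <- sim_spectrum(pep, max_charge = 3, jitter_ppm = 0, n_noise = 0,
                             drop_ions = y33, seed = s + 100)
    loc <- localize_glycosite(match_spectrum(modsim$spectrum, ions, 10),
                              match_spectrum(unmodsim$spectrum, ions, 10),
                              pep)
    expect_identical(loc$call, 40L)
  }
})
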