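test_that("four-point example resolves the AB|CD split with edge 2", {
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  cd <- stats::cophenetic(tr)
  expect_equal(cd["A", "B"], 2)
  expect_equal(cd["C", "D"], 2)
  expect_equal(cd["A", "C"], 4)
  # internal edge = d(A,C) - d(A,B)/2 - d(C,D)/2
  expect_equal(sum(tr$edge.length) - 4, 2)
})

test_that("three taxa resolve by the closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  cd <- stats::cophenetic(tr)
  expect_equal(cd["A", "B"], 3)
  expect_equal(cd["A", "C"], 4)
  expect_equal(cd["B", "C"], 5)
})

test_that("NJ reproduces the generating topology of additive matrices", {
  for (s in 1:50) {
    ra <- random_additive(sample(4:8, 1), seed = s)
    expect_true(same_topology(nj_tree(ra$d), ra$tree))
  }
})

test_that("NJ agrees with the independent ape implementation", {
  for (s in 1:10) {
    set.seed(500 + s)
    n <- sample(5:9, 1)
    x <- matrix(runif(n * 10), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_true(same_topology(nj_tree(d), ape::nj(as.dist(d))))
  }
})

test_that("malformed matrices are rejected", {
  d <- matrix(runif(9), 3, 3)
  expect_error(nj_tree(d), "symmetric")
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("clustering score separates clades and is 1 on a star", {
  clades <- ape::read.tree(text = paste0(
    "((a1:1,a2:1,a3:1,a4:1,a5:1):10,(b1:1,b2:1,b3:1,b4:1,b5:1):10);"))
  lab <- setNames(rep(c("SER40", "ALA40"), each = 5), clades$tip.label)
  expect_gt(type_clustering_score(clades, lab), 1)
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  slab <- setNames(c("SER40", "SER40", "ALA40", "ALA40"), letters[1:4])
  expect_equal(type_clustering_score(star, slab), 1)
  expect_true(is.na(type_clustering_score(star,
    setNames(c("SER40", "ALA40", "ALA40", "ALA40"), letters[1:4]))))
  expect_error(type_clustering_score(star, c(a = "SER40")), "unlabeled")
})

test_that("type labels cluster harder than species labels under birth-death", {
  ratio_type <- numeric(0); ratio_species <- numeric(0)
  for (s in 1:20) {
    fam <- sim_isoform_family(birth_death_params(n_species = 5,
                                                 substitution = 0.05),
                              seed = 6000 + s)
    if (fam$extinct || is.null(fam$tree)) next
    type_lab <- ifelse(fam$site40_states == "S", "SER40", "ALA40")
    names(type_lab) <- names(fam$site40_states)
    sp_lab <- setNames(fam$records$species, fam$records$id)
    ts <- type_clustering_score(fam$tree, type_lab)
    ss <- type_clustering_score(fam$tree, sp_lab)
    if (is.na(ts) || is.na(ss)) next
    ratio_type <- c(ratio_type, ts)
    ratio_species <- c(ratio_species, ss)
  }
  expect_gte(length(ratio_type), 10)
  expect_gt(median(ratio_type), median(ratio_species))
})
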