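# Seeded generators. Each takes an integer seed and restores the caller's
# RNG state, so identical calls are byte-identical across sessions and
# adding one generator call does not perturb another's stream.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an HCD spectrum of a known peptide
#'
#' Emits each theoretical fragment (labile-loss model: HexNAc deltas are
#' dropped from fragments) with Gaussian m/z jitter, independent dropout,
#' and uniform noise peaks over the observed m/z range; intensities are
#' log-normal. The ground-truth ion table is returned alongside so matching
#' and localization can be scored without re-derivation.
#'
#' @param pep A `peptide`.
#' @param max_charge Highest fragment charge emitted.
#' @param jitter_ppm Gaussian m/z jitter standard deviation (ppm).
#' @param n_noise Number of uniform noise peaks.
#' @param dropout Per-ion dropout probability.
#' @param include_internal Emit internal by ions as well.
#' @param drop_ions Optional character vector of ion labels to suppress
#'   (e.g. all y33 charge states, to emulate an unmodified-precursor
#'   spectrum lacking the diagnostic ion).
#' @param seed Integer seed.
#' @return A list: `spectrum` (a [spectrum()]), `truth` (ion table with an
#'   `emitted` flag).
#' @export
sim_spectrum <- function(pep, max_charge = 2, jitter_ppm = 5, n_noise = 100,
                         dropout = 0, include_internal = FALSE,
                         drop_ions = character(), seed = 1L) {
  ions <- theoretical_fragments(pep, max_charge = max_charge,
                                include_internal = include_internal,
                                glycan_retained = FALSE)
  .with_seed(seed, {
    keep <- stats::runif(nrow(ions)) >= dropout
    keep <- keep & !(ions$label %in% drop_ions)
    mz <- ions$mz[keep] *
      (1 + stats::rnorm(sum(keep), 0, jitter_ppm) * 1e-6)
    inten <- stats::rlnorm(sum(keep), meanlog = 10, sdlog = 1)
    if (n_noise > 0) {
      rng <- range(ions$mz)
      nz <- stats::runif(n_noise, rng[1], rng[2])
      mz <- c(mz, nz)
      inten <- c(inten, stats::rlnorm(n_noise, meanlog = 8, sdlog = 1))
    }
    truth <- ions
    truth$emitted <- keep
    sp <- if (length(mz) > 0) {
      spectrum(mz, inten,
               precursor_mz = ion_mz(peptide_mass(pep), max(1L, 3L)),
               precursor_charge = 3L,
               title = sprintf("sim:%s", pep$sequence))
    } else {
      spectrum(numeric(0), numeric(0), title = sprintf("sim:%s", pep$sequence))
    }
    list(spectrum = sp, truth = truth)
  })
}

#' Birth-and-death simulation parameters
#'
#' @param duplication Gene duplication rate per lineage per unit time.
#' @param loss Gene loss rate per lineage per unit time.
#' @param substitution Per-site substitution rate per unit time.
#' @param site40_multiplier Rate multiplier for site 40 (default 0: the
#'   site-40 state is frozen, so Ser40 is inherited, never re-invented).
#' @param depth Species-tree depth in time units.
#' @param n_species Number of species.
#' @param plant_s40 Plant a Ser40-bearing basal duplicate at the root (the
#'   other root copy carries Ala40).
#' @return A list of validated parameters.
#' @export
birth_death_params <- function(duplication = 0.3, loss = 0.1,
                               substitution = 0.02, site40_multiplier = 0,
                               depth = 1, n_species = 6, plant_s40 = TRUE) {
  stopifnot(duplication >= 0, loss >= 0, substitution >= 0,
            site40_multiplier >= 0, depth > 0, n_species >= 2)
  list(duplication = duplication, loss = loss, substitution = substitution,
       site40_multiplier = site40_multiplier, depth = depth,
       n_species = n_species, plant_s40 = plant_s40)
}

.mutate_seq <- function(aa, t, params, site40_index) {
  alphabet <- names(mass_table()$residues)
  p <- 1 - exp(-params$substitution * t)
  p40 <- 1 - exp(-params$substitution * params$site40_multiplier * t)
  probs <- rep(p, length(aa))
  if (!is.na(site40_index) && site40_index <= length(aa)) {
    probs[site40_index] <- p40
  }
  hit <- which(stats::runif(length(aa)) < probs)
  for (i in hit) aa[i] <- sample(setdiff(alphabet, aa[i]), 1)
  aa
}

#' Simulate an isoform family under birth-and-death evolution
#'
#' Simulates gene duplication, loss and sequence substitution along a random
#' ultrametric species tree. One root copy carries Ala at site 40; when
#' `plant_s40` is set, a basal duplicate carrying Ser40 is planted, and with
#' `site40_multiplier = 0` every extant descendant of that duplicate — and
#' only those — is SER40. Along each branch, duplications (Poisson) occur at
#' the branch start, each copy then survives the branch independently and
#' accumulates per-site substitutions.
#'
#' @param params A [birth_death_params()] list.
#' @param root_sequence Root protein sequence (default [ref_h2a3()]).
#' @param seed Integer seed.
#' @return A list: `records` (tibble `id`, `species`, `sequence`), `tree`
#'   (`phylo` gene tree, or NULL), `site40_states` (named "S"/"A"/other per
#'   record), `planted` (named logical: descends from the planted
#'   duplicate), `extinct` (logical).
#' @export
sim_isoform_family <- function(params = birth_death_params(),
                               root_sequence = ref_h2a3(), seed = 1L) {
  .with_seed(seed, {
    sptree <- ape::rcoal(params$n_species,
                         tip.label = sprintf("sp%d", seq_len(params$n_species)))
    sptree$edge.length <- sptree$edge.length /
      max(ape::node.depth.edgelength(sptree)) * params$depth
    root_aa <- strsplit(root_sequence, "")[[1]]
    if (length(root_aa) >= 40) root_aa[40] <- "A"
    counter <- new.env()
    counter$n <- 0L
    leaves <- list()

    # returns list(str=newick fragment sans root length, len=root length)
    # or NULL if every descendant of this copy was lost
    evolve <- function(aa, planted, node, t_in) {
      sp_root <- length(sptree$tip.label) + 1L
      kids <- sptree$edge[sptree$edge[, 1] == node, 2]
      if (length(kids) == 0) {  # species tip: extant gene copy
        counter$n <- counter$n + 1L
        id <- sprintf("%s_g%d", sptree$tip.label[node], counter$n)
        leaves[[id]] <<- list(species = sptree$tip.label[node],
                              sequence = paste(aa, collapse = ""),
                              planted = planted)
        return(list(str = id, len = t_in))
      }
      subs <- list()
      for (kid in kids) {
        t <- sptree$edge.length[which(sptree$edge[, 1] == node &
                                        sptree$edge[, 2] == kid)][1]
        ndup <- stats::rpois(1, params$duplication * t)
        copies <- rep(list(list(aa = aa, planted = planted)), 1 + ndup)
        branch_subs <- list()
        for (cp in copies) {
          if (stats::runif(1) < 1 - exp(-params$loss * t)) next  # lost
          aa2 <- .mutate_seq(cp$aa, t, params, 40L)
          r <- evolve(aa2, cp$planted, kid, t)
          if (!is.null(r)) branch_subs[[length(branch_subs) + 1L]] <- r
        }
        if (length(branch_subs) == 1) {
          subs[[length(subs) + 1L]] <- branch_subs[[1]]
        } else if (length(branch_subs) > 1) {
          # duplication node at branch start
          inner <- paste(vapply(branch_subs, function(s)
            sprintf("%s:%.8g", s$str, s$len), character(1)), collapse = ",")
          subs[[length(subs) + 1L]] <- list(str = sprintf("(%s)", inner),
                                            len = 0)
        }
      }
      if (length(subs) == 0) return(NULL)
      if (length(subs) == 1) {
        return(list(str = subs[[1]]$str, len = subs[[1]]$len + t_in))
      }
      inner <- paste(vapply(subs, function(s)
        sprintf("%s:%.8g", s$str, s$len), character(1)), collapse = ",")
      list(str = sprintf("(%s)", inner), len = t_in)
    }

    root_node <- length(sptree$tip.label) + 1L
    root_copies <- list(list(aa = root_aa, planted = FALSE))
    if (params$plant_s40) {
      aa_s <- root_aa
      if (length(aa_s) >= 40) aa_s[40] <- "S"
      root_copies[[2]] <- list(aa = aa_s, planted = TRUE)
    }
    subs <- list()
    for (cp in root_copies) {
      r <- evolve(cp$aa, cp$planted, root_node, 0)
      if (!is.null(r)) subs[[length(subs) + 1L]] <- r
    }
    if (length(leaves) == 0) {
      return(list(records = tibble::tibble(id = character(),
                                           species = character(),
                                           sequence = character()),
                  tree = NULL, site40_states = character(),
                  planted = logical(), extinct = TRUE))
    }
    ids <- names(leaves)
    records <- tibble::tibble(
      id = ids,
      species = unname(vapply(leaves, `[[`, character(1), "species")),
      sequence = unname(vapply(leaves, `[[`, character(1), "sequence")))
    site40 <- vapply(records$sequence, function(s)
      substr(s, 40, 40), character(1), USE.NAMES = FALSE)
    names(site40) <- ids
    planted <- vapply(leaves, `[[`, logical(1), "planted")
    names(planted) <- ids
    tree <- NULL
    if (length(ids) >= 2) {
      if (length(subs) == 1) {
        txt <- sprintf("%s;", subs[[1]]$str)
      } else {
        txt <- sprintf("(%s);", paste(vapply(subs, function(s)
          sprintf("%s:%.8g", s$str, s$len), character(1)), collapse = ","))
      }
      tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
    }
    list(records = records, tree = tree, site40_states = site40,
         planted = planted, extinct = FALSE)
  })
}

#' Simulate a genome with gene models and category-planted peaks
#'
#' Places non-overlapping genes (with exon/intron structure) on one
#' chromosome, on both strands, with inter-gene gaps wide enough that TSS
#' windows never reach a neighbouring gene, then draws each peak's category
#' from the planted fractions and places its midpoint uniformly within the
#' chosen region type. TSS-planted midpoints are placed in the upstream,
#' gene-external half of the +/- `tss_halfwidth` window so that the planted
#' exon/intron truth among genic peaks stays unambiguous; GB-planted
#' midpoints avoid their own gene's TSS window and are planted exonic with
#' probability `exon_fraction`. Peak widths are log-normal (median 500 bp);
#' category truth is defined by the midpoint, matching [assign_category()].
#'
#' @param n_genes Number of genes.
#' @param chrom_length Chromosome length in bp.
#' @param fractions Named numeric `c(tss=, gb=, intergenic=)` summing to 1.
#' @param exon_fraction Planted probability that a GB peak midpoint is
#'   exonic.
#' @param n_peaks Number of peaks.
#' @param tss_halfwidth TSS window half-width (bp).
#' @param seed Integer seed.
#' @return A list: `models` ([gene_models()]), `peaks` (`GRanges` with
#'   `peak_id`), `truth` (tibble `peak_id`, `category`, `exonic`,
#'   `gene_id`).
#' @export
sim_genome_and_peaks <- function(n_genes = 100, chrom_length = 10e6,
                                 fractions = c(tss = 0.30, gb = 0.55,
                                               intergenic = 0.15),
                                 exon_fraction = 0.5, n_peaks = 2000,
                                 tss_halfwidth = 2000, seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9,
            all(c("tss", "gb", "intergenic") %in% names(fractions)))
  .with_seed(seed, {
    gene_len <- sample(6000:12000, n_genes, replace = TRUE)
    gap <- sample((2 * tss_halfwidth + 2000):(2 * tss_halfwidth + 10000),
                  n_genes, replace = TRUE)
    need <- sum(gene_len) + sum(gap) + 2 * tss_halfwidth + 2000
    if (need > chrom_length) {
      stop(sprintf(
        "infeasible geometry: %d genes need %d bp but chromosome is %d bp",
        n_genes, need, as.integer(chrom_length)), call. = FALSE)
    }
    starts <- cumsum(gap) + cumsum(c(0, gene_len[-n_genes]))  # 1-based
    ends <- starts + gene_len - 1
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_id <- sprintf("gene_%03d", seq_len(n_genes))
    genes <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = starts, end = ends), strand = strand)
    genes$gene_id <- gene_id
    exon_rows <- list()
    exon_seg <- vector("list", n_genes)    # per gene: exon [start, end] matrix
    intron_seg <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      n_ex <- sample(3:6, 1)
      # 2*n_ex - 1 alternating segments (exon first and last)
      cuts <- sort(sample(seq_len(gene_len[g] - 1), 2 * n_ex - 2))
      seg_s <- starts[g] + c(0, cuts)
      seg_e <- starts[g] + c(cuts, gene_len[g]) - 1
      odd <- seq(1, 2 * n_ex - 1, by = 2)
      exon_seg[[g]] <- cbind(seg_s[odd], seg_e[odd])
      intron_seg[[g]] <- cbind(seg_s[-odd], seg_e[-odd])
      exon_rows[[g]] <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = seg_s[odd], end = seg_e[odd]),
        strand = strand[g], gene_id = gene_id[g])
    }
    exons <- do.call(c, exon_rows)
    models <- gene_models(genes, exons)
    tss <- tss_positions(genes)

    cat_truth <- sample(c("TSS", "GB", "INTERGENIC"), n_peaks, replace = TRUE,
                        prob = fractions[c("tss", "gb", "intergenic")])
    gene_cover <- IRanges::IRanges(start = starts, end = ends)
    tss_cover <- IRanges::IRanges(start = pmax(tss - tss_halfwidth, 1),
                                  end = tss + tss_halfwidth)
    blocked <- IRanges::reduce(c(gene_cover, tss_cover))
    mids <- integer(n_peaks)
    owner <- rep(NA_character_, n_peaks)
    exonic <- rep(NA, n_peaks)
    for (k in seq_len(n_peaks)) {
      if (cat_truth[k] == "TSS") {
        g <- sample(n_genes, 1)
        mids[k] <- if (strand[g] == "+") {
          sample((tss[g] - tss_halfwidth):(tss[g] - 1), 1)
        } else {
          sample((tss[g] + 1):(tss[g] + tss_halfwidth), 1)
        }
        owner[k] <- gene_id[g]
      } else if (cat_truth[k] == "GB") {
        want_exon <- stats::runif(1) < exon_fraction
        for (try in 1:200) {
          g <- sample(n_genes, 1)
          lo <- if (strand[g] == "+") tss[g] + tss_halfwidth + 1 else starts[g]
          hi <- if (strand[g] == "+") ends[g] else tss[g] - tss_halfwidth - 1
          if (hi < lo) next
          segs <- if (want_exon) exon_seg[[g]] else intron_seg[[g]]
          s <- pmax(segs[, 1], lo)
          e <- pmin(segs[, 2], hi)
          ok <- which(e >= s)
          if (length(ok) == 0) next
          wdt <- e[ok] - s[ok] + 1
          seg <- ok[sample.int(length(ok), 1, prob = wdt)]
          mids[k] <- max(segs[seg, 1], lo) +
            sample.int(min(segs[seg, 2], hi) - max(segs[seg, 1], lo) + 1L, 1) - 1L
          owner[k] <- gene_id[g]
          exonic[k] <- want_exon
          break
        }
        if (mids[k] == 0) stop("could not place GB peak; exon geometry too tight",
                               call. = FALSE)
      } else {
        repeat {
          pos <- sample.int(as.integer(chrom_length - 4000), 1) + 2000L
          if (!any(pos >= IRanges::start(blocked) &
                     pos <= IRanges::end(blocked))) { mids[k] <- pos; break }
        }
      }
    }
    w <- pmax(50L, as.integer(round(stats::rlnorm(n_peaks,
                                                  meanlog = log(500),
                                                  sdlog = 0.5))))
    half <- w %/% 2L
    start0 <- mids - 1L - half          # 0-based start
    end0 <- start0 + w                  # 0-based exclusive end
    peaks <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = start0 + 1L, end = end0))
    peaks$peak_id <- sprintf("peak_%05d", seq_len(n_peaks))
    truth <- tibble::tibble(peak_id = peaks$peak_id, category = cat_truth,
                            exonic = exonic, gene_id = owner)
    list(models = models, peaks = peaks, truth = truth)
  })
}

#' Simulate an expression table with a planted target shift
#'
#' Background genes draw Normal(0, sigma); target genes Normal(delta,
#' sigma).
#'
#' @param gene_ids All gene ids.
#' @param targets Subset of `gene_ids` receiving the shift.
#' @param delta Planted shift.
#' @param sigma Noise standard deviation.
#' @param seed Integer seed.
#' @return Tibble with `gene_id`, `value`.
#' @export
sim_expression <- function(gene_ids, targets = character(), delta = 1,
                           sigma = 1, seed = 1L) {
  stopifnot(all(targets %in% gene_ids))
  .with_seed(seed, {
    mu <- ifelse(gene_ids %in% targets, delta, 0)
    tibble::tibble(gene_id = gene_ids,
                   value = stats::rnorm(length(gene_ids), mu, sigma))
  })
}
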