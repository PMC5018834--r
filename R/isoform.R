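#' Reference canonical H2A sequence (synthetic H2A3-like scaffold)
#'
#' Returns the packaged 129-residue reference sequence used to anchor
#' "position 40" across species. Histone numbering: position 1 is the
#' residue after the cleaved initiator Met, so Ser40 sits in the Y-S-E
#' context of the L1 loop and the Lys-C peptide G37-K74 spans residues
#' 37-74. The sequence is a constructed canonical-H2A scaffold (synthetic,
#' not a database download); its G37-K74 peptide is the exact peptide whose
#' triply charged precursor has monoisotopic m/z 1327.02.
#'
#' @return A single protein sequence string.
#' @export
ref_h2a3 <- function() {
  paste0(
    "SGRGKQGGKARAKAKTRSSRAGLQFPVGRVHRLLRK",           # 1-36
    "GNYSERVGAGAPVYLAAVLEYLTAEILELAGNAARDNK",         # 37-74 (Lys-C peptide)
    "KTRIIPRHLQLAIRNDEELNKLLGKVTIAQGGVLPNIQAVLLPKKTESHHKAKGK"  # 75-129
  )
}

.aligned_strings <- function(seq, ref) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(seq), subject = Biostrings::AAString(ref),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
    type = "global")
  list(pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)),
       pid = Biostrings::pid(aln))
}

#' Anchor a reference position onto another sequence
#'
#' Globally aligns `seq` to `ref` (BLOSUM62, affine gaps: open 10, extend 1,
#' end gaps penalized) and returns the 1-based position of `seq` aligned to
#' `ref_pos`, or `NA` if `ref_pos` aligns to a gap or the alignment identity
#' falls below `min_identity` (guards against anchoring non-histone input;
#' canonical H2A isoforms are >90% identical so results are insensitive to
#' reasonable parameter choices).
#'
#' @param seq Query protein sequence.
#' @param ref Reference protein sequence.
#' @param ref_pos 1-based position in `ref`.
#' @param min_identity Percent-identity floor (default 40).
#' @return Integer position in `seq`, or `NA_integer_`.
#' @export
anchor_position <- function(seq, ref, ref_pos, min_identity = 40) {
  if (!nzchar(seq) || !nzchar(ref)) stop("empty sequence", call. = FALSE)
  if (ref_pos < 1 || ref_pos > nchar(ref)) {
    stop("ref_pos outside reference", call. = FALSE)
  }
  al <- .aligned_strings(seq, ref)
  if (al$pid < min_identity) return(NA_integer_)
  p <- strsplit(al$pattern, "")[[1]]
  s <- strsplit(al$subject, "")[[1]]
  refpos <- cumsum(s != "-")
  col <- match(ref_pos, refpos)
  if (is.na(col) || p[col] == "-") return(NA_integer_)
  as.integer(sum(p[seq_len(col)] != "-"))
}

#' Classify a sequence by the residue homologous to reference position 40
#'
#' Categories: `SER40` (anchored residue is S), `ALA40` (A), `OTHER` (any
#' other anchored residue), `UNALIGNED` (no reliable anchor). The reported
#' three-residue `context` makes the Y-S-E epitope window checkable.
#'
#' @param seq Protein sequence to classify.
#' @param ref Reference sequence (default [ref_h2a3()]).
#' @param ref_pos Anchored reference position (default 40).
#' @return List with `anchored_index`, `residue`, `category`, `context`.
#' @examples
#' classify_position40(ref_h2a3())$category  # "SER40"
#' @export
classify_position40 <- function(seq, ref = ref_h2a3(), ref_pos = 40L) {
  idx <- anchor_position(seq, ref, ref_pos)
  if (is.na(idx)) {
    return(list(anchored_index = NA_integer_, residue = NA_character_,
                category = "UNALIGNED", context = NA_character_))
  }
  aa <- strsplit(seq, "")[[1]]
  residue <- aa[idx]
  category <- switch(residue, S = "SER40", A = "ALA40", "OTHER")
  ctx <- aa[max(1, idx - 1):min(length(aa), idx + 1)]
  list(anchored_index = idx, residue = residue, category = category,
       context = paste(ctx, collapse = ""))
}

#' Classify a set of isoform records
#'
#' @param records Data frame with columns `id`, `species`, `sequence`
#'   (as returned by [read_fasta()]).
#' @param ref Reference sequence.
#' @param ref_pos Anchored reference position.
#' @return A tibble with one row per record: `id`, `species`,
#'   `anchored_index`, `residue`, `category`, `context`.
#' @export
classify_isoforms <- function(records, ref = ref_h2a3(), ref_pos = 40L) {
  records <- as.data.frame(records)
  calls <- lapply(records$sequence, classify_position40, ref = ref,
                  ref_pos = ref_pos)
  tibble::tibble(
    id = records$id,
    species = records$species,
    anchored_index = vapply(calls, `[[`, integer(1), "anchored_index"),
    residue = vapply(calls, `[[`, character(1), "residue"),
    category = vapply(calls, `[[`, character(1), "category"),
    context = vapply(calls, `[[`, character(1), "context"))
}

#' Per-species Ser40 isoform summary
#'
#' @param records Data frame with `id`, `species`, `sequence`.
#' @param ref Reference sequence.
#' @return A tibble with `species`, `n_ser40`, `n_total`, `ratio_text`
#'   (e.g. "3/5").
#' @export
summarize_species <- function(records, ref = ref_h2a3()) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(species = character(), n_ser40 = integer(),
                          n_total = integer(), ratio_text = character()))
  }
  calls <- classify_isoforms(records, ref)
  sp <- unique(calls$species)
  tibble::tibble(
    species = sp,
    n_ser40 = vapply(sp, function(s)
      sum(calls$category[calls$species == s] == "SER40"), integer(1)),
    n_total = vapply(sp, function(s)
      sum(calls$species == s), integer(1)),
    ratio_text = sprintf("%d/%d",
      vapply(sp, function(s)
        sum(calls$category[calls$species == s] == "SER40"), integer(1)),
      vapply(sp, function(s) sum(calls$species == s), integer(1))))
}

#' Proportion distance between two aligned rows
#'
#' Mismatches divided by compared columns; columns where either row has a
#' gap (`-`) or ambiguity (`X`) are ignored.
#'
#' @param a,b Equal-length aligned sequence strings.
#' @return p-distance in [0, 1].
#' @export
p_distance <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  if (length(va) != length(vb)) stop("rows must have equal length", call. = FALSE)
  ok <- !(va %in% c("-", "X")) & !(vb %in% c("-", "X"))
  if (!any(ok)) stop("no comparable columns", call. = FALSE)
  sum(va[ok] != vb[ok]) / sum(ok)
}

#' Star multiple alignment against a reference
#'
#' Aligns each record pairwise to `ref` and merges the pairwise alignments
#' into common columns: one column per reference position plus merged
#' insertion columns (the maximum insertion length observed between any two
#' reference positions). Deterministic for a fixed input order and invariant
#' to input permutation.
#'
#' @param seqs Named character vector of protein sequences.
#' @param ref Reference sequence.
#' @return Named character vector of equal-length aligned rows.
#' @export
star_msa <- function(seqs, ref = ref_h2a3()) {
  if (length(seqs) < 2) stop("need at least 2 records", call. = FALSE)
  nref <- nchar(ref)
  per <- lapply(seqs, function(sq) {
    al <- .aligned_strings(sq, ref)
    p <- strsplit(al$pattern, "")[[1]]
    s <- strsplit(al$subject, "")[[1]]
    at_ref <- rep("-", nref)              # residue aligned to each ref position
    ins <- vector("list", nref + 1L)      # insertions after ref position 0..nref
    for (k in seq_along(ins)) ins[[k]] <- character()
    refpos <- 0L
    for (col in seq_along(s)) {
      if (s[col] != "-") {
        refpos <- refpos + 1L
        at_ref[refpos] <- p[col]
      } else {
        ins[[refpos + 1L]] <- c(ins[[refpos + 1L]], p[col])
      }
    }
    list(at_ref = at_ref, ins = ins)
  })
  ins_len <- vapply(seq_len(nref + 1L), function(k)
    max(vapply(per, function(x) length(x$ins[[k]]), integer(1))), integer(1))
  rows <- vapply(per, function(x) {
    out <- character()
    for (k in 0:nref) {
      gap_block <- x$ins[[k + 1L]]
      out <- c(out, gap_block, rep("-", ins_len[k + 1L] - length(gap_block)))
      if (k < nref) out <- c(out, x$at_ref[k + 1L])
    }
    paste(out, collapse = "")
  }, character(1))
  names(rows) <- names(seqs)
  rows
}

#' Pairwise p-distance matrix over aligned rows
#'
#' @param rows Named character vector of equal-length aligned rows.
#' @return Symmetric matrix of p-distances with zero diagonal.
#' @export
p_distance_matrix <- function(rows) {
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) d[i, j] <- d[j, i] <- p_distance(rows[i], rows[j])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining: exact topology on additive distance
#' matrices. Ties in the Q matrix are broken by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest
#' leaf label) so results are reproducible; negative branch lengths are
#' clamped to 0.
#'
#' @param d Symmetric labelled distance matrix with zero diagonal
#'   (>= 3 labels).
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (nrow(d) < 3) stop("need at least 3 labels", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  lab <- rownames(d)              # active cluster min-labels
  nwk <- lab                      # partial newick per active cluster
  while (length(lab) > 3) {
    r <- length(lab)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    best <- NULL
    qmin <- min(q)
    for (i in seq_len(r - 1)) for (j in (i + 1):r) {
      if (q[i, j] <= qmin + 1e-12) {
        key <- sort(c(lab[i], lab[j]))
        if (is.null(best) || key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    newlab <- min(lab[c(i, j)])
    rownames(d2) <- colnames(d2) <- c(lab[keep], newlab)
    newnwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], li, nwk[j], lj)
    nwk <- c(nwk[keep], newnwk)
    lab <- c(lab[keep], newlab)
    d <- d2
  }
  # closed-form resolution of the final three clusters
  la <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  lb <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  lc <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nwk[1], la, nwk[2], lb, nwk[3], lc)
  ape::read.tree(text = txt)
}

#' Isoform-type clustering score on a tree
#'
#' Ratio B/W of the mean cophenetic (path-length) distance between leaves of
#' different categories (B) to the mean within-category distance (W). A
#' score above 1 indicates type-dependent clustering — leaves group by
#' isoform type (e.g. Ser40 vs Ala40) rather than mixing freely, the
#' hallmark of birth-and-death gene-family evolution.
#'
#' @param tree A `phylo` tree.
#' @param labels Named character vector mapping every leaf label to a
#'   category (e.g. "SER40"/"ALA40").
#' @return B/W, or `NA` if either category has fewer than 2 leaves.
#' @export
type_clustering_score <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- tree$tip.label
  if (!all(leaves %in% names(labels))) {
    stop("unlabeled leaf: ",
         paste(setdiff(leaves, names(labels)), collapse = ","), call. = FALSE)
  }
  cat_ <- labels[leaves]
  tab <- table(cat_)
  if (length(tab) < 2 || any(tab < 2)) return(NA_real_)
  cd <- stats::cophenetic(tree)
  same <- outer(cat_, cat_, "==")
  ut <- upper.tri(cd)
  b <- mean(cd[ut & !same])
  w <- mean(cd[ut & same])
  b / w
}
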