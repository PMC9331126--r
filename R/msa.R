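# Progressive multiple alignment: k-mer guide tree (UPGMA) + profile-profile
# merge with affine gaps, plus alignment statistics.

#' k-mer distance between two sequences
#'
#' 1 - shared k-mer count / min total k-mers, where shared k-mers are counted
#' with multiplicity.  Symmetric; 0 for identical sequences, 1 for disjoint
#' k-mer sets.  If k exceeds the shorter sequence the distance is 1 with a
#' warning.
#'
#' @param a,b residue strings.
#' @param k word length (default 3).
#' @export
kmer_distance <- function(a, b, k = 3L) {
  a <- one_seq(a)$seq; b <- one_seq(b)$seq
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  if (k > min(nchar(a), nchar(b))) {
    warning("k exceeds sequence length; distance set to 1")
    return(1)
  }
  ka <- table(substring(a, seq_len(nchar(a) - k + 1L), k:nchar(a)))
  kb <- table(substring(b, seq_len(nchar(b) - k + 1L), k:nchar(b)))
  common <- intersect(names(ka), names(kb))
  shared <- sum(pmin(as.numeric(ka[common]), as.numeric(kb[common])))
  1 - shared / min(sum(ka), sum(kb))
}

profile_freq <- function(m, residues) {
  # residues x ncol frequency matrix; gaps carry zero mass, denominator is
  # the number of rows so gappy columns score proportionally less
  f <- matrix(0, length(residues), ncol(m),
              dimnames = list(residues, NULL))
  for (j in seq_len(ncol(m))) {
    cnt <- table(factor(m[, j][m[, j] %in% residues], levels = residues))
    f[, j] <- as.numeric(cnt) / nrow(m)
  }
  f
}

merge_profiles <- function(ma, mb, sub, open, ext, residues) {
  fa <- profile_freq(ma, residues)
  fb <- profile_freq(mb, residues)
  r <- .pp_align(fa, fb, sub, open, ext)
  ncolumns <- length(r$path_a)
  out <- matrix("-", nrow(ma) + nrow(mb), ncolumns)
  rownames(out) <- c(rownames(ma), rownames(mb))
  ia <- r$path_a > 0L
  ib <- r$path_b > 0L
  out[seq_len(nrow(ma)), ia] <- ma[, r$path_a[ia], drop = FALSE]
  out[nrow(ma) + seq_len(nrow(mb)), ib] <- mb[, r$path_b[ib], drop = FALSE]
  out
}

#' Progressive multiple sequence alignment
#'
#' A UPGMA guide tree on [kmer_distance()] orders the merges; leaves and
#' intermediate profiles are merged bottom-up by global profile-profile
#' dynamic programming with affine gaps (same penalties as the search
#' scoring scheme).  Row order of the output equals the input order, and
#' removing gaps from any row reproduces the input sequence.
#'
#' @param seqs sequence set (or named character vector) of >= 1 sequences.
#' @param scheme a [scoring_scheme()].
#' @param k guide-tree word length.
#' @return alignment (named character vector of gapped rows).
#' @export
align_progressive <- function(seqs, scheme = scoring_scheme(), k = 3L) {
  v <- if (is.data.frame(seqs)) seqs_to_vec(seqs) else seqs
  alphabet <- if (is.data.frame(seqs) && alphabet_of(seqs) == "dna")
    c(DNA_CHARS, "N") else c(AA_ORDER, "X")
  n <- length(v)
  if (n == 0L) stop("no sequences to align")
  if (n == 1L) return(v)
  sub <- scheme$matrix[alphabet, alphabet]
  # guide tree
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- suppressWarnings(kmer_distance(v[i], v[j], k))
  profiles <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(v[i], "", fixed = TRUE)[[1L]], nrow = 1L)
    rownames(m) <- names(v)[i]
    m
  })
  if (n == 2L) {
    merged <- merge_profiles(profiles[[1L]], profiles[[2L]], sub,
                             scheme$gap_open, scheme$gap_extend, alphabet)
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    nodes <- vector("list", n - 1L)
    for (s in seq_len(n - 1L)) {
      get <- function(x) if (x < 0L) profiles[[-x]] else nodes[[x]]
      nodes[[s]] <- merge_profiles(get(hc$merge[s, 1L]),
                                   get(hc$merge[s, 2L]), sub,
                                   scheme$gap_open, scheme$gap_extend,
                                   alphabet)
    }
    merged <- nodes[[n - 1L]]
  }
  rows <- stats::setNames(apply(merged, 1L, paste, collapse = ""),
                          rownames(merged))
  rows[names(v)]
}

#' Percent identity between two rows of an alignment
#'
#' @param alignment named character vector of gapped rows.
#' @param id_i,id_j row ids.
#' @param mode "aligned_columns" (denominator = columns where at least one
#'   row has a residue) or "shorter_seq" (denominator = ungapped length of
#'   the shorter row, the CD-HIT convention).
#' @return identity in [0, 100].
#' @export
percent_identity <- function(alignment, id_i, id_j,
                             mode = c("aligned_columns", "shorter_seq")) {
  mode <- match.arg(mode)
  if (!id_i %in% names(alignment)) stop("unknown id: ", id_i)
  if (!id_j %in% names(alignment)) stop("unknown id: ", id_j)
  a <- strsplit(alignment[[id_i]], "", fixed = TRUE)[[1L]]
  b <- strsplit(alignment[[id_j]], "", fixed = TRUE)[[1L]]
  matches <- sum(a == b & a != "-")
  denom <- switch(mode,
    aligned_columns = sum(a != "-" | b != "-"),
    shorter_seq = min(sum(a != "-"), sum(b != "-")))
  if (denom == 0L) return(0)
  100 * matches / denom
}

#' Sum-of-pairs score of an alignment
#'
#' Column-wise sum of substitution scores over all row pairs; gap columns in
#' a pair cost open/extend per gap run.  Used as a coarse alignment-quality
#' statistic.
#' @param alignment named character vector of gapped rows.
#' @param scheme a [scoring_scheme()].
#' @export
sum_of_pairs <- function(alignment, scheme = scoring_scheme()) {
  m <- aln_matrix(alignment)
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- m[i, ]; b <- m[j, ]
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    res <- a != "-" & b != "-"
    ok <- res & a %in% rownames(scheme$matrix) & b %in% rownames(scheme$matrix)
    total <- total + sum(scheme$matrix[cbind(a[ok], b[ok])])
    gp <- a == "-" | b == "-"
    if (any(gp)) {
      runs <- rle(gp)
      nruns <- sum(runs$values)
      total <- total - nruns * scheme$gap_open -
        sum(runs$lengths[runs$values]) * scheme$gap_extend
    }
  }
  total
}
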