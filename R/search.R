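# Local protein search: Smith-Waterman with affine gaps (via Biostrings),
# Karlin-Altschul E-values, six-frame ORF extraction, proteome harvest and
# reciprocal-best-hit family labeling.

#' Scoring scheme for local alignment search
#'
#' Defaults follow gapped BLOSUM62 search with gap penalties 11/1 and the
#' matching Karlin-Altschul constants lambda = 0.267, K = 0.041.  A gap of
#' length L costs gap_open + L * gap_extend (open + extend charged on the
#' first gap residue).
#'
#' @param matrix named 20x20+ integer substitution matrix.
#' @param gap_open,gap_extend positive integer gap penalties.
#' @param lambda,K Karlin-Altschul statistical parameters (> 0).
#' @return list with class "scoring_scheme".
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) {
    matrix <- get_blosum62()
  }
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gap_extend > gap_open) stop("gap_extend must be <= gap_open")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be > 0")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' DNA match/mismatch scheme used for scaffold overlap alignment
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @export
dna_scheme <- function(match = 1L, mismatch = -2L, gap_open = 3L,
                       gap_extend = 2L) {
  b <- c(DNA_CHARS, "N")
  m <- matrix(as.integer(mismatch), 5, 5, dimnames = list(b, b))
  diag(m) <- as.integer(match)
  m["N", ] <- 0L; m[, "N"] <- 0L
  structure(list(matrix = m, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = 1.28, K = 0.46),
            class = "scoring_scheme")
}

#' Best local alignment between two protein sequences
#'
#' Smith-Waterman with affine gaps.  Returns NULL when the best local score
#' is 0 (no positive-scoring alignment) or either sequence is empty.
#'
#' @param query,subject residue strings (or single-row sequence sets).
#' @param scheme a [scoring_scheme()].
#' @param type Biostrings alignment type (local for search; overlap is used
#'   by the scaffold merger).
#' @return list with fields query_id, subject_id, score, bitscore (filled by
#'   callers that know the search space), evalue, query_range, subject_range
#'   (0-based half-open), percent_identity, n_match, frame; or NULL.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        type = "local") {
  q <- one_seq(query); s <- one_seq(subject)
  if (!nzchar(q$seq) || !nzchar(s$seq)) return(NULL)
  check_in_matrix(q$seq, scheme, q$id)
  check_in_matrix(s$seq, scheme, s$id)
  pa <- Biostrings::pairwiseAlignment(
    q$seq, s$seq, type = type,
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- Biostrings::score(pa)
  if (type == "local" && sc <= 0) return(NULL)
  pr <- pa@pattern@range
  sr <- pa@subject@range
  al <- Biostrings::nchar(pa)   # alignment length including gaps
  nm <- Biostrings::nmatch(pa)
  list(query_id = q$id, subject_id = s$id,
       score = sc, bitscore = NA_real_, evalue = NA_real_,
       query_range = c(BiocGenerics::start(pr) - 1L, BiocGenerics::end(pr)),
       subject_range = c(BiocGenerics::start(sr) - 1L, BiocGenerics::end(sr)),
       percent_identity = 100 * nm / al, n_match = nm,
       aligned_length = al, frame = 0L)
}

one_seq <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single sequence")
    return(list(id = x$id, seq = x$seq))
  }
  if (is.character(x) && length(x) == 1L)
    return(list(id = if (!is.null(names(x))) names(x) else "seq",
                seq = toupper(unname(x))))
  stop("cannot interpret sequence input")
}

check_in_matrix <- function(s, scheme, label) {
  ch <- unique(strsplit(s, "", fixed = TRUE)[[1L]])
  bad <- setdiff(ch, rownames(scheme$matrix))
  if (length(bad))
    stop("sequence '", label, "' has characters outside the scoring ",
         "alphabet: ", paste(bad, collapse = " "))
  invisible(TRUE)
}

#' Karlin-Altschul E-value and bit score
#'
#' E = K * m * n * exp(-lambda * S); bitscore = (lambda * S - ln K) / ln 2.
#'
#' @param score raw alignment score (>= 0).
#' @param m query length; @param n total subject letters in the search space.
#' @param scheme a [scoring_scheme()].
#' @return list(evalue, bitscore).
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (m <= 0 || n <= 0) stop("search space m and n must be > 0")
  if (score < 0) stop("score must be >= 0")
  list(evalue = scheme$K * m * n * exp(-scheme$lambda * score),
       bitscore = (scheme$lambda * score - log(scheme$K)) / log(2))
}

#' Search a proteome with a set of protein queries
#'
#' All query/subject pairs are aligned; hits with E-value <= e_cutoff are
#' returned sorted by (query_id, evalue).  The search-space size n is the
#' total residue count of the proteome.
#'
#' @param queries,proteome sequence sets (protein).
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff E-value cutoff (> 0), default 1e-05.
#' @return data.frame with BLAST-outfmt-6-like columns qid, sid, pident,
#'   length, evalue, bitscore, qstart, qend, sstart, send, frame (ranges
#'   0-based half-open).
#' @export
search_proteome <- function(queries, proteome, scheme = scoring_scheme(),
                            e_cutoff = 1e-05) {
  if (e_cutoff <= 0) stop("e_cutoff must be > 0")
  empty <- data.frame(qid = character(), sid = character(),
                      pident = numeric(), length = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      frame = integer(), stringsAsFactors = FALSE)
  if (nrow(proteome) == 0L) {
    warning("empty proteome")
    return(empty)
  }
  n_space <- sum(nchar(proteome$seq))
  qset <- Biostrings::AAStringSet(stats::setNames(queries$seq, queries$id))
  rows <- list()
  for (si in seq_len(nrow(proteome))) {
    pa <- Biostrings::pairwiseAlignment(
      qset, proteome$seq[si], type = "local",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    sc <- Biostrings::score(pa)
    ev <- scheme$K * nchar(queries$seq) * n_space * exp(-scheme$lambda * sc)
    keep <- which(sc > 0 & ev <= e_cutoff)
    if (!length(keep)) next
    pr <- pa@pattern@range[keep]
    sr <- pa@subject@range[keep]
    alen <- Biostrings::nchar(pa)[keep]
    nm <- Biostrings::nmatch(pa)[keep]
    rows[[length(rows) + 1L]] <- data.frame(
      qid = queries$id[keep], sid = proteome$id[si],
      pident = 100 * nm / alen, length = alen, evalue = ev[keep],
      bitscore = (scheme$lambda * sc[keep] - log(scheme$K)) / log(2),
      qstart = BiocGenerics::start(pr) - 1L,
      qend = BiocGenerics::end(pr),
      sstart = BiocGenerics::start(sr) - 1L,
      send = BiocGenerics::end(sr), frame = 0L, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$qid, out$evalue), , drop = FALSE]
}

GENETIC_CODE_X <- local({
  gc <- Biostrings::GENETIC_CODE
  gc
})

translate_frame <- function(nt) {
  # translate an in-frame nucleotide string; fuzzy codons (N) become X
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- GENETIC_CODE_X[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Extract open reading frames from all six frames of a contig
#'
#' Maximal ORFs run from a Met to the next stop, or open-ended to the
#' contig edge when the stop falls outside the contig.  Peptides shorter
#' than min_aa are dropped.  Ids carry the frame and the 1-based aa
#' coordinates within that frame's translation.
#'
#' @param contig one-row dna sequence set (or a nucleotide string).
#' @param min_aa minimum peptide length (default 100).
#' @return protein sequence set (possibly empty).
#' @export
six_frame_orfs <- function(contig, min_aa = 100L) {
  if (min_aa < 1L) stop("min_aa must be >= 1")
  cs <- one_seq(contig)
  nt <- toupper(cs$seq)
  out_id <- character(); out_seq <- character()
  if (nchar(nt) < 3L)
    return(seq_set(out_id, out_seq, alphabet = "protein"))
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (fr > 0L) nt else revcomp(nt)
    off <- abs(fr) - 1L
    aa <- translate_frame(substring(s, off + 1L))
    if (!nzchar(aa)) next
    # stop-free stretches
    parts <- strsplit(aa, "*", fixed = TRUE)[[1L]]
    ends_with_stop <- substring(aa, nchar(aa)) == "*"
    pos <- 1L
    for (k in seq_along(parts)) {
      p <- parts[k]
      pstart <- pos                      # 1-based aa coord of stretch start
      pos <- pos + nchar(p) + 1L         # skip the stop
      if (!nzchar(p)) next
      mpos <- regexpr("M", p, fixed = TRUE)
      if (mpos < 0L) next
      orf <- substring(p, mpos)
      ostart <- pstart + as.integer(mpos) - 1L
      if (nchar(orf) < min_aa) next
      out_id <- c(out_id, sprintf("%s_f%+d_%d-%d", cs$id, fr, ostart,
                                  ostart + nchar(orf) - 1L))
      out_seq <- c(out_seq, orf)
    }
  }
  seq_set(out_id, out_seq, alphabet = "protein")
}

#' Harvest contigs whose translation matches a protein query set
#'
#' tblastn-like: each contig's six-frame peptides are aligned against the
#' queries; contigs whose best E-value is <= e_cutoff are returned together
#' with the best-supported peptide.
#'
#' @param query_proteins protein sequence set.
#' @param contigs dna sequence set.
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff default 1e-20.
#' @param min_aa minimum ORF length passed to [six_frame_orfs()].
#' @return data.frame(contig_id, peptide_id, peptide, evalue, query_id).
#' @export
harvest_contigs <- function(query_proteins, contigs,
                            scheme = scoring_scheme(), e_cutoff = 1e-20,
                            min_aa = 100L) {
  orfs_per_contig <- lapply(seq_len(nrow(contigs)),
                            function(i) six_frame_orfs(contigs[i, ], min_aa))
  n_space <- sum(vapply(orfs_per_contig,
                        function(o) sum(nchar(o$seq)), 0))
  if (n_space == 0L) n_space <- 1L
  rows <- list()
  for (ci in seq_along(orfs_per_contig)) {
    orfs <- orfs_per_contig[[ci]]
    best <- NULL
    for (oi in seq_len(nrow(orfs))) {
      for (qi in seq_len(nrow(query_proteins))) {
        h <- local_align(query_proteins[qi, ], orfs[oi, ], scheme)
        if (is.null(h)) next
        ev <- evalue(h$score, nchar(query_proteins$seq[qi]), n_space,
                     scheme)$evalue
        if (is.null(best) || ev < best$evalue)
          best <- list(evalue = ev, peptide_id = orfs$id[oi],
                       peptide = orfs$seq[oi],
                       query_id = query_proteins$id[qi])
      }
    }
    if (!is.null(best) && best$evalue <= e_cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = contigs$id[ci], peptide_id = best$peptide_id,
        peptide = best$peptide, evalue = best$evalue,
        query_id = best$query_id, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(contig_id = character(), peptide_id = character(),
                      peptide = character(), evalue = numeric(),
                      query_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Reciprocal-best-hit family labeling against a labeled reference panel
#'
#' A candidate is labeled L iff its best panel hit carries label L and (when
#' forward nominations are supplied) the forward search that nominated the
#' candidate was a query of family L.  Ties across distinct labels yield
#' "ambiguous"; no hit at the cutoff yields "none".  Panel entries whose
#' label matches the blacklist (default "hypothetical") are excluded from
#' labeling.
#'
#' @param candidates protein sequence set.
#' @param panel sequence set whose desc column carries the family label.
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff reciprocal-search E-value cutoff.
#' @param forward_family optional named character vector: candidate id ->
#'   family of the forward query that nominated it.
#' @param label_blacklist labels excluded from consideration (regex,
#'   case-insensitive).
#' @return data.frame(candidate_id, family, best_hit, evalue, score).
#' @export
reciprocal_best_hit <- function(candidates, panel,
                                scheme = scoring_scheme(), e_cutoff = 1e-05,
                                forward_family = NULL,
                                label_blacklist = "hypothetical") {
  if (nrow(panel) == 0L) stop("empty reference panel")
  keep <- !grepl(label_blacklist, panel$desc, ignore.case = TRUE)
  panel <- panel[keep, , drop = FALSE]
  if (nrow(panel) == 0L) stop("reference panel empty after blacklist")
  n_space <- sum(nchar(panel$seq))
  out <- data.frame(candidate_id = candidates$id,
                    family = "none", best_hit = NA_character_,
                    evalue = NA_real_, score = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(candidates))) {
    scores <- rep(-Inf, nrow(panel))
    for (j in seq_len(nrow(panel))) {
      h <- local_align(candidates[i, ], panel[j, ], scheme)
      if (!is.null(h)) scores[j] <- h$score
    }
    if (!any(is.finite(scores))) next
    best <- max(scores)
    ev <- evalue(best, nchar(candidates$seq[i]), n_space, scheme)$evalue
    if (ev > e_cutoff) next
    top_labels <- unique(panel$desc[scores == best])
    if (length(top_labels) > 1L) {
      out$family[i] <- "ambiguous"
    } else {
      lab <- top_labels
      fwd_ok <- is.null(forward_family) ||
        identical(unname(forward_family[candidates$id[i]]), lab)
      out$family[i] <- if (fwd_ok) lab else "none"
    }
    out$best_hit[i] <- panel$id[which(scores == best)[1L]]
    out$evalue[i] <- ev
    out$score[i] <- best
  }
  out
}
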