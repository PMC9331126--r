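# Redundancy reduction, profile-HMM domain filtering and the windowed
# gap-pruning alignment editor.

#' Greedy incremental identity clustering (CD-HIT style)
#'
#' Sequences are sorted by decreasing length (ties broken by id) and each
#' joins the first existing cluster whose representative it matches at
#' identity >= c, where identity = matched residues of the best local
#' alignment divided by the shorter sequence length.  The word size n is a
#' prefilter only (candidate pairs must share at least one length-n word);
#' it never changes the identity decision.
#'
#' @param seqs protein sequence set.
#' @param c identity threshold in (0, 1]; default 0.98.
#' @param n word size for the prefilter; default 5.
#' @param scheme scoring scheme for the identity alignment.
#' @return list of clusters, each list(representative, members, identity)
#'   with identity named by member id.
#' @export
cluster_greedy <- function(seqs, c = 0.98, n = 5L,
                           scheme = scoring_scheme()) {
  if (c <= 0 || c > 1) stop("identity threshold c must be in (0, 1]")
  ord <- order(-nchar(seqs$seq), seqs$id)
  seqs <- seqs[ord, , drop = FALSE]
  clusters <- list()
  rep_words <- list()
  for (i in seq_len(nrow(seqs))) {
    sq <- seqs$seq[i]
    wd <- seq_words(sq, n)
    joined <- FALSE
    for (k in seq_along(clusters)) {
      if (length(wd) && length(rep_words[[k]]) &&
          !any(wd %in% rep_words[[k]])) next
      rep_seq <- clusters[[k]]$rep_seq
      h <- local_align(stats::setNames(sq, seqs$id[i]),
                       stats::setNames(rep_seq, clusters[[k]]$representative),
                       scheme)
      idy <- if (is.null(h)) 0 else h$n_match / min(nchar(sq), nchar(rep_seq))
      if (idy >= c) {
        clusters[[k]]$members <- c(clusters[[k]]$members, seqs$id[i])
        clusters[[k]]$identity <- c(clusters[[k]]$identity,
                                    stats::setNames(idy, seqs$id[i]))
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      clusters[[length(clusters) + 1L]] <- list(
        representative = seqs$id[i], rep_seq = sq,
        members = seqs$id[i],
        identity = stats::setNames(1, seqs$id[i]))
      rep_words[[length(clusters)]] <- wd
    }
  }
  lapply(clusters, function(cl) cl[c("representative", "members", "identity")])
}

seq_words <- function(s, n) {
  L <- nchar(s)
  if (L < n) return(character())
  unique(substring(s, seq_len(L - n + 1L), n:L))
}

#' Cluster representatives as a subset of the input sequence set
#' @param clusters output of [cluster_greedy()].
#' @param seqs the clustered sequence set.
#' @export
cluster_representatives <- function(clusters, seqs) {
  ids <- vapply(clusters, `[[`, "", "representative")
  seqs[match(ids, seqs$id), , drop = FALSE]
}

#' CD-HIT-like cluster table
#' @param clusters output of [cluster_greedy()].
#' @return data.frame(cluster, member, representative, identity).
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    data.frame(cluster = k, member = cl$members,
               representative = cl$members == cl$representative,
               identity = unname(cl$identity), stringsAsFactors = FALSE)
  }))
}

AA_ORDER <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
              "R","S","T","V","W","Y")

#' Build a profile HMM from a protein alignment
#'
#' Columns whose gap fraction is at most match_col_gap_max become match
#' states.  Match emissions are residue counts plus pseudocount_weight times
#' the background, normalized; transitions are estimated from the observed
#' per-row state paths with Laplace smoothing.  The background is the
#' overall residue composition of the alignment (pseudocounted), and doubles
#' as the null model for log-odds scoring.
#'
#' @param alignment named character vector of gapped rows.
#' @param match_col_gap_max maximum gap fraction of a match column.
#' @param pseudocount_weight nonnegative emission pseudocount mass.
#' @return object of class "profile_hmm".
#' @export
build_profile_hmm <- function(alignment, match_col_gap_max = 0.5,
                              pseudocount_weight = 1.0) {
  m <- aln_matrix(alignment)
  gapfrac <- colMeans(m == "-")
  match_cols <- which(gapfrac <= match_col_gap_max)
  if (!length(match_cols)) stop("alignment too gappy: no match columns")
  L <- length(match_cols)
  counts_all <- table(factor(m[m %in% AA_ORDER], levels = AA_ORDER))
  background <- (as.numeric(counts_all) + 1) / (sum(counts_all) + 20)
  names(background) <- AA_ORDER
  me <- matrix(0, L, 20, dimnames = list(NULL, AA_ORDER))
  for (j in seq_len(L)) {
    cnt <- table(factor(m[, match_cols[j]][m[, match_cols[j]] %in% AA_ORDER],
                        levels = AA_ORDER))
    e <- as.numeric(cnt) + pseudocount_weight * background
    me[j, ] <- e / sum(e)
  }
  # transition counts from per-row state paths
  is_match <- seq_len(ncol(m)) %in% match_cols
  cnt <- list(MM = rep(0, L), MI = rep(0, L), MD = rep(0, L),
              IM = rep(0, L), II = rep(0, L),
              DM = rep(0, L), DD = rep(0, L))
  for (r in seq_len(nrow(m))) {
    path <- row_state_path(m[r, ], is_match)
    if (length(path$state) < 2L) next
    for (t in seq_len(length(path$state) - 1L)) {
      key <- paste0(path$state[t], path$state[t + 1L])
      j <- path$index[t]
      if (key %in% names(cnt)) cnt[[key]][j] <- cnt[[key]][j] + 1
    }
  }
  norm3 <- function(a, b, c) {
    tot <- a + b + c + 3
    list((a + 1) / tot, (b + 1) / tot, (c + 1) / tot)
  }
  tMM <- tMI <- tMD <- tIM <- tII <- tDM <- tDD <- rep(0, L)
  for (j in seq_len(L)) {
    z <- norm3(cnt$MM[j], cnt$MI[j], cnt$MD[j])
    tMM[j] <- z[[1]]; tMI[j] <- z[[2]]; tMD[j] <- z[[3]]
    ti <- cnt$IM[j] + cnt$II[j] + 2
    tIM[j] <- (cnt$IM[j] + 1) / ti; tII[j] <- (cnt$II[j] + 1) / ti
    td <- cnt$DM[j] + cnt$DD[j] + 2
    tDM[j] <- (cnt$DM[j] + 1) / td; tDD[j] <- (cnt$DD[j] + 1) / td
  }
  structure(list(L = L, match_emissions = me,
                 insert_emissions = background, background = background,
                 transitions = list(MM = tMM, MI = tMI, MD = tMD,
                                    IM = tIM, II = tII, DM = tDM, DD = tDD),
                 pseudocount_weight = pseudocount_weight,
                 match_columns = match_cols),
            class = "profile_hmm")
}

# state path of one aligned row: M/D at match columns, I at insert columns
# (attributed to the preceding match state; leading inserts to state 1's
# predecessor are dropped since entry is handled separately)
row_state_path <- function(row, is_match) {
  state <- character(); index <- integer()
  j <- 0L
  for (k in seq_along(row)) {
    if (is_match[k]) {
      j <- j + 1L
      state <- c(state, if (row[k] == "-") "D" else "M")
      index <- c(index, j)
    } else if (row[k] != "-" && j >= 1L) {
      state <- c(state, "I")
      index <- c(index, j)
    }
  }
  list(state = state, index = index)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile HMM with", x$L, "match states\n")
  invisible(x)
}

#' Serialize a profile HMM to JSON (and back)
#' @param hmm a profile_hmm; @param path file path.
#' @export
write_hmm_json <- function(hmm, path) {
  jsonlite::write_json(unclass(hmm), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$match_emissions <- matrix(unlist(x$match_emissions), nrow = x$L,
                              byrow = FALSE)
  colnames(x$match_emissions) <- AA_ORDER
  structure(x, class = "profile_hmm")
}

encode_protein <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  match(ch, AA_ORDER, nomatch = 0L) - 1L   # -1 marks X/* etc.
}

#' Log-odds score of a sequence under a profile HMM
#'
#' Local (domain anywhere in the sequence) scoring against the background
#' null model, in bits.  The forward score sums over all domain placements;
#' the Viterbi score takes the best single placement.
#'
#' @param hmm a [build_profile_hmm()] object.
#' @param seq a residue string.
#' @param method "forward" (default) or "viterbi".
#' @return log-odds score in bits.
#' @export
hmm_score <- function(hmm, seq, method = c("forward", "viterbi")) {
  method <- match.arg(method)
  s <- one_seq(seq)$seq
  lem <- log(sweep(hmm$match_emissions, 2L, hmm$background, "/"))
  tr <- lapply(hmm$transitions, log)
  r <- .hmm_score_cpp(lem, encode_protein(s), tr$MM, tr$MI, tr$MD,
                      tr$IM, tr$II, tr$DM, tr$DD)
  (if (method == "forward") r$forward else r$viterbi) / log(2)
}

hmm_best_window <- function(hmm, seq) {
  s <- one_seq(seq)$seq
  lem <- log(sweep(hmm$match_emissions, 2L, hmm$background, "/"))
  tr <- lapply(hmm$transitions, log)
  r <- .hmm_viterbi_range(lem, encode_protein(s), tr$MM, tr$MI, tr$MD,
                          tr$IM, tr$II, tr$DM, tr$DD)
  list(bits = r$viterbi / log(2), range = c(r$start, r$end))
}

#' Partition sequences by profile-HMM domain presence
#'
#' @param seqs protein sequence set.
#' @param hmm a [build_profile_hmm()] object.
#' @param bits_cutoff keep sequences scoring at least this many bits
#'   (forward log-odds); default 0.
#' @return list(kept = sequence set, rejected = sequence set with a score
#'   column, scores = named numeric of all scores).
#' @export
filter_by_domain <- function(seqs, hmm, bits_cutoff = 0) {
  sc <- vapply(seqs$seq, function(s) hmm_score(hmm, s), 0,
               USE.NAMES = FALSE)
  names(sc) <- seqs$id
  keep <- sc >= bits_cutoff
  kept <- seqs[keep, , drop = FALSE]
  rejected <- seqs[!keep, , drop = FALSE]
  rejected$score <- sc[!keep]
  attr(kept, "alphabet") <- attr(seqs, "alphabet")
  list(kept = kept, rejected = rejected, scores = sc)
}

#' Remove fragmentary, gap-causing rows from an alignment
#'
#' A row is removed iff some window of w consecutive columns has a gap
#' fraction (within that row) of at least g.  Surviving rows are returned
#' with all-gap columns dropped.  w is clamped to the alignment width.
#'
#' @param alignment named character vector of gapped rows.
#' @param w window width in columns (default 347).
#' @param g gap-fraction threshold in (0, 1] (default 0.9).
#' @return list(alignment, removed) where removed is a character vector of
#'   row ids.
#' @export
alignment_editor <- function(alignment, w = 347L, g = 0.9) {
  if (w < 1L) stop("w must be >= 1")
  if (g <= 0 || g > 1) stop("g must be in (0, 1]")
  m <- aln_matrix(alignment)
  w <- min(as.integer(w), ncol(m))
  gaps <- m == "-"
  removed <- vapply(seq_len(nrow(m)), function(r) {
    cs <- cumsum(gaps[r, ])
    win <- cs[w:length(cs)] - c(0, cs)[seq_len(length(cs) - w + 1L)]
    any(win / w >= g)
  }, TRUE)
  if (all(removed)) stop("editor removed every sequence")
  kept <- alignment[!removed]
  list(alignment = drop_gap_columns(kept),
       removed = names(alignment)[removed])
}
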