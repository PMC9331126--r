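# Hox-cluster genomic cartography: scaffold overlap detection and merging,
# gene order/orientation/intergenic-distance maps, and linear map rendering
# (text + SVG).

#' Merge two scaffolds across a near-identical suffix-prefix overlap
#'
#' The best ends-free (overlap) alignment between the two scaffolds is
#' computed in both relative orientations (right scaffold as-is and
#' reverse-complemented).  The merge is accepted iff the aligned overlap is
#' a suffix of the left scaffold and a prefix of the right one, spans at
#' least min_overlap bases, and has identity >= min_identity percent.  At
#' overlap mismatches the left scaffold's base is kept (the two-sequence
#' consensus tie rule); positions where one scaffold has a gap take the
#' other's base.
#'
#' @param left,right one-row dna sequence sets (or nucleotide strings).
#' @param min_overlap minimum overlap length in bp (default 50).
#' @param min_identity minimum percent identity of the overlap (default
#'   99.8).
#' @param max_search only the terminal max_search bp of each scaffold are
#'   scanned for the overlap (default 10000), keeping the alignment
#'   tractable on chromosome-scale input.
#' @param scheme DNA scoring scheme for the overlap alignment.
#' @return list(merged = one-row dna sequence set, merge = record with
#'   left_id, right_id, overlap_len, overlap_identity, merged_length,
#'   orientation).
#' @export
merge_scaffolds <- function(left, right, min_overlap = 50L,
                            min_identity = 99.8, max_search = 10000L,
                            scheme = dna_scheme()) {
  l <- one_seq(left); r <- one_seq(right)
  nl <- nchar(l$seq)
  cands <- list(list(seq = r$seq, orientation = "as-is"),
                list(seq = revcomp(r$seq),
                     orientation = "right-reverse-complemented"))
  # only the facing ends can overlap; windowing keeps the O(m*n) alignment
  # tractable on chromosome-scale scaffolds
  wl <- min(nl, max_search)
  lw <- substring(l$seq, nl - wl + 1L)
  best <- NULL
  for (cand in cands) {
    rw <- substring(cand$seq, 1L, min(nchar(cand$seq), max_search))
    pa <- Biostrings::pairwiseAlignment(
      lw, rw, type = "overlap",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    ls <- BiocGenerics::start(pa@pattern@range)
    le <- BiocGenerics::end(pa@pattern@range)
    rs <- BiocGenerics::start(pa@subject@range)
    re <- BiocGenerics::end(pa@subject@range)
    # suffix of left, prefix of right
    if (le != nchar(lw) || rs != 1L) next
    ov_len <- le - ls + 1L
    idy <- 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    if (is.null(best) || Biostrings::score(pa) > best$score)
      best <- list(score = Biostrings::score(pa),
                   ls = (nl - wl) + ls, rs = rs, re = re,
                   ov_len = ov_len, idy = idy,
                   orientation = cand$orientation, rseq = cand$seq,
                   pa = pa)
  }
  if (is.null(best) || best$ov_len < min_overlap ||
      best$idy < min_identity)
    stop("scaffolds cannot be confidently concatenated (need overlap >= ",
         min_overlap, " bp at >= ", min_identity, "% identity)")
  la <- strsplit(as.character(Biostrings::alignedPattern(best$pa)),
                 "", fixed = TRUE)[[1L]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(best$pa)),
                 "", fixed = TRUE)[[1L]]
  cons <- ifelse(la != "-", la, ra)
  merged_seq <- paste0(substring(l$seq, 1L, best$ls - 1L),
                       paste(cons, collapse = ""),
                       substring(best$rseq, best$re + 1L))
  merged_id <- paste0(l$id, "+", r$id)
  list(merged = seq_set(merged_id, merged_seq, alphabet = "dna"),
       merge = list(left_id = l$id, right_id = r$id,
                    overlap_len = best$ov_len,
                    overlap_identity = best$idy,
                    merged_length = nchar(merged_seq),
                    orientation = best$orientation))
}

#' Canonical insect Hox gene order
#' @export
HOX_ORDER <- c("lab", "pb", "zen", "Dfd", "Scr", "ftz", "Antp", "Ubx",
               "abd-A", "Abd-B")

lcs_members <- function(a, b) {
  # indices of elements of a that belong to a longest common subsequence
  n <- length(a); m <- length(b)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m))
    L[i + 1L, j + 1L] <- if (a[i] == b[j]) L[i, j] + 1L
                         else max(L[i, j + 1L], L[i + 1L, j])
  keep <- logical(n)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (a[i] == b[j] && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      keep[i] <- TRUE; i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) i <- i - 1L
    else j <- j - 1L
  }
  keep
}

#' Gene order, orientation and distance map of a gene cluster
#'
#' Loci (all on one seqid) are ordered by start coordinate.  The map records
#' intergenic gaps (next start - previous end - 1, negative when loci
#' overlap), the cluster span, per-locus flags for orientation opposite to
#' the majority strand, and order anomalies relative to a reference order
#' (genes outside the longest common subsequence of observed versus
#' expected order).
#'
#' @param loci gene locus data.frame (see [read_gff3()]).
#' @param reference_order expected family order (default the canonical Hox
#'   order).
#' @return list of class "cluster_map".
#' @export
build_cluster_map <- function(loci, reference_order = HOX_ORDER) {
  if (nrow(loci) == 0L) stop("no loci")
  if (length(unique(loci$seqid)) > 1L)
    stop("loci span multiple seqids; merge scaffolds first")
  loci <- loci[order(loci$start, loci$gene_id), , drop = FALSE]
  rownames(loci) <- NULL
  n <- nrow(loci)
  gaps <- if (n > 1L) loci$start[-1L] - loci$end[-n] - 1L else integer()
  majority <- names(sort(table(loci$strand), decreasing = TRUE))[1L]
  flags <- loci$strand != majority
  observed <- loci$family
  expected <- reference_order[reference_order %in% observed]
  anomalies <- data.frame(gene = character(), expected_rank = integer(),
                          observed_rank = integer(),
                          stringsAsFactors = FALSE)
  if (length(expected)) {
    in_ref <- observed %in% expected
    keep <- rep(TRUE, n)
    keep[in_ref] <- lcs_members(observed[in_ref], expected)
    bad <- which(in_ref & !keep)
    if (length(bad))
      anomalies <- data.frame(
        gene = loci$gene_id[bad],
        expected_rank = match(observed[bad], expected),
        observed_rank = match(observed[bad], observed[in_ref]),
        stringsAsFactors = FALSE)
  }
  structure(list(seqid = loci$seqid[1L], loci = loci,
                 intergenic_gaps = gaps,
                 span = loci$end[n] - loci$start[1L] + 1L,
                 majority_strand = majority,
                 orientation_flags = stats::setNames(flags, loci$gene_id),
                 order_anomalies = anomalies),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("cluster map on", x$seqid, ":", nrow(x$loci), "loci spanning",
      format_bp(x$span), "\n")
  if (nrow(x$order_anomalies))
    cat("  order anomalies:", paste(x$order_anomalies$gene,
                                    collapse = ", "), "\n")
  if (any(x$orientation_flags))
    cat("  opposite orientation:",
        paste(names(x$orientation_flags)[x$orientation_flags],
              collapse = ", "), "\n")
  invisible(x)
}

format_bp <- function(bp) {
  if (bp >= 1e6) sprintf("%.4g Mb", bp / 1e6)
  else if (bp >= 1e3) sprintf("%.4g kb", bp / 1e3)
  else paste0(bp, " bp")
}

HOX_COLORS <- c(lab = "#3cb44b", pb = "#f58231", zen = "#555555",
                Dfd = "#87ceeb", Scr = "#e6194b", ftz = "#c0c0c0",
                Antp = "#911eb4", Ubx = "#4363d8", "abd-A" = "#ffe119",
                "Abd-B" = "#f032e6")

#' Render a cluster map as a text diagram and an SVG drawing
#'
#' Gaps larger than gap_ellipsis_threshold are compressed to labeled
#' ellipses.  Boxes are drawn to scale and colored per family; loci on the
#' minority strand get an arrowhead mark.  The footer reports the drawn
#' length and its percentage of the full sequence length.
#'
#' @param cluster_map a [build_cluster_map()] result.
#' @param gap_ellipsis_threshold compress gaps above this many bp (default
#'   500000).
#' @param full_length full sequence length used for the footer percentage
#'   (default the cluster span).
#' @param svg_path optional file to write the SVG to.
#' @return list(text = character vector of diagram lines, svg = SVG string).
#' @export
render_map <- function(cluster_map, gap_ellipsis_threshold = 500000,
                       full_length = NULL, svg_path = NULL) {
  loci <- cluster_map$loci
  n <- nrow(loci)
  gaps <- cluster_map$intergenic_gaps
  # text diagram: one token per locus in coordinate order
  tokens <- character()
  drawn <- 0
  for (i in seq_len(n)) {
    if (i > 1L) {
      gp <- gaps[i - 1L]
      if (gp > gap_ellipsis_threshold) {
        tokens <- c(tokens, paste0("...[", format_bp(gp), "]..."))
      } else {
        drawn <- drawn + max(gp, 0L)
      }
    }
    arrow <- if (loci$strand[i] == "+") ">" else "<"
    mark <- if (cluster_map$orientation_flags[i]) "!" else ""
    tokens <- c(tokens, paste0("[", mark, loci$family[i], arrow, "]"))
    drawn <- drawn + loci$end[i] - loci$start[i] + 1L
  }
  full <- if (is.null(full_length)) cluster_map$span else full_length
  footer <- sprintf("drawn %s (%.1f%% of %s)", format_bp(drawn),
                    100 * drawn / full, format_bp(full))
  text_lines <- c(paste(tokens, collapse = " "), footer)

  svg <- render_svg(cluster_map, gap_ellipsis_threshold, drawn, full)
  if (!is.null(svg_path)) writeLines(svg, svg_path)
  list(text = text_lines, svg = svg)
}

render_svg <- function(cm, thr, drawn, full) {
  loci <- cm$loci
  n <- nrow(loci)
  gaps <- cm$intergenic_gaps
  scale <- 900 / max(drawn, 1)
  x <- 40; y <- 40; h <- 18
  parts <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="1000" height="120">'),
    sprintf('<line x1="40" y1="%d" x2="960" y2="%d" stroke="#999"/>',
            y + h %/% 2L, y + h %/% 2L))
  for (i in seq_len(n)) {
    if (i > 1L) {
      gp <- gaps[i - 1L]
      if (gp > thr) {
        parts <- c(parts, sprintf(
          '<text x="%.1f" y="%d" font-size="10">... %s ...</text>',
          x, y - 6L, format_bp(gp)))
        x <- x + 30
      } else {
        x <- x + max(gp, 0L) * scale
      }
    }
    wd <- max((loci$end[i] - loci$start[i] + 1L) * scale, 2)
    col <- HOX_COLORS[loci$family[i]]
    if (is.na(col)) col <- "#888888"
    parts <- c(parts, sprintf(
      '<rect x="%.1f" y="%d" width="%.1f" height="%d" fill="%s"><title>%s</title></rect>',
      x, y, wd, h, col, loci$gene_id[i]))
    if (cm$orientation_flags[i])
      parts <- c(parts, sprintf(
        '<path d="M %.1f %d l 6 -8 l 6 8 z" fill="#000"/>',
        x + wd / 2 - 6, y - 2L))
    x <- x + wd
  }
  parts <- c(parts, sprintf(
    '<text x="40" y="100" font-size="12">drawn %s (%.1f%% of %s)</text>',
    format_bp(drawn), 100 * drawn / full, format_bp(full)),
    "</svg>")
  paste(parts, collapse = "\n")
}
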