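# Distance-based phylogeny: corrected distances, neighbor joining,
# nonparametric bootstrap supports and support-threshold collapse.

dist_from_matrix <- function(m, correction = c("p", "poisson"),
                             ceiling = 10,
                             zero_overlap = c("error", "ceiling")) {
  correction <- match.arg(correction)
  zero_overlap <- match.arg(zero_overlap)
  n <- nrow(m)
  residues <- sort(unique(as.vector(m[m != "-"])))
  nongap <- (m != "-") * 1L
  valid <- tcrossprod(nongap)
  matches <- matrix(0, n, n)
  for (r in residues) {
    ind <- (m == r) * 1L
    matches <- matches + tcrossprod(ind)
  }
  if (any(valid[upper.tri(valid)] == 0)) {
    if (zero_overlap == "error") {
      ij <- which(valid == 0 & upper.tri(valid), arr.ind = TRUE)[1L, ]
      stop("no comparable columns between '", rownames(m)[ij[1L]],
           "' and '", rownames(m)[ij[2L]], "'")
    }
  }
  p <- 1 - matches / pmax(valid, 1L)
  p[valid == 0] <- NA
  d <- if (correction == "p") p else ifelse(p >= 1, ceiling, -log(1 - p))
  d[is.na(d)] <- ceiling
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Pairwise distances from a protein alignment
#'
#' Pairwise deletion: for each pair, columns where either row is gapped are
#' excluded.  "p" is the mismatch fraction; "poisson" applies
#' d = -ln(1 - p), with p >= 1 mapped to a configured ceiling.
#'
#' @param alignment named character vector of gapped rows.
#' @param correction "p" or "poisson".
#' @param ceiling distance assigned when the correction diverges.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
corrected_distances <- function(alignment, correction = c("p", "poisson"),
                                ceiling = 10) {
  dist_from_matrix(aln_matrix(alignment), match.arg(correction), ceiling,
                   zero_overlap = "error")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via ape); negative branch lengths
#' are clamped to zero.  The result is unrooted, stored with the usual
#' arbitrary basal trifurcation.
#'
#' @param D symmetric distance matrix with labels as dimnames.
#' @return phylo object.
#' @export
neighbor_joining <- function(D) {
  if (is.null(dim(D)) || nrow(D) < 3L)
    stop("neighbor joining needs at least 3 labels")
  tr <- ape::nj(as.matrix(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' B column-resampled replicates of the alignment are each run through the
#' distance + neighbor-joining engine; the support of an internal edge of
#' the full-alignment tree is 100 times the fraction of replicates whose
#' tree contains the same bipartition.  Supports are stored in node.label.
#'
#' @param alignment named character vector of gapped rows (>= 4 for
#'   supports; 3 rows give a tree without supports, with a warning).
#' @param B number of replicates (>= 1).
#' @param seed integer seed (recorded in the result's "seed" attribute).
#' @param correction distance correction, see [corrected_distances()].
#' @param tree optional tree on the same leaves to attach supports to;
#'   defaults to the tree inferred from the full alignment.
#' @return phylo object with supports in node.label.
#' @export
bootstrap_support <- function(alignment, B = 100L, seed = 1L,
                              correction = "poisson", tree = NULL) {
  if (B < 1L) stop("B must be >= 1")
  m <- aln_matrix(alignment)
  if (is.null(tree))
    tree <- neighbor_joining(dist_from_matrix(m, correction,
                                              zero_overlap = "ceiling"))
  if (nrow(m) < 4L) {
    warning("fewer than 4 sequences: supports not computed")
    return(tree)
  }
  set.seed(as.integer(seed))
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    db <- dist_from_matrix(m[, cols, drop = FALSE], correction,
                           zero_overlap = "ceiling")
    reps[[b]] <- neighbor_joining(db)
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- 100 * counts / B
  lab <- as.character(round(sup, 1))
  lab[1L] <- ""  # root of the stored (arbitrary) basal node carries no edge
  tree$node.label <- lab
  attr(tree, "seed") <- as.integer(seed)
  attr(tree, "B") <- as.integer(B)
  tree
}

node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Collapse weakly supported internal edges into polytomies
#'
#' Every internal edge whose child node's support is present and strictly
#' less than the threshold is contracted: the node's children are promoted
#' to its parent and keep their own branch lengths.  The leaf set is
#' unchanged.
#'
#' @param tree phylo with supports in node.label.
#' @param threshold collapse supports < threshold (default 95).
#' @return phylo object (possibly with polytomies).
#' @export
collapse_low_support <- function(tree, threshold = 95) {
  sup <- node_supports(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  drop <- which(!is.na(sup) & sup < threshold) + ntip
  drop <- setdiff(drop, root)
  if (!length(drop)) return(tree)
  edge <- tree$edge
  len <- if (is.null(tree$edge.length)) rep(NA_real_, nrow(edge))
         else tree$edge.length
  children <- split(seq_len(nrow(edge)), edge[, 1L])
  lab <- tree$node.label
  # expand a node's children, recursively splicing contracted descendants
  expand <- function(node) {
    parts <- character()
    for (e in children[[as.character(node)]]) {
      child <- edge[e, 2L]
      if (child > ntip && child %in% drop) {
        parts <- c(parts, expand(child))
      } else {
        parts <- c(parts, build(child, len[e]))
      }
    }
    parts
  }
  build <- function(node, incoming) {
    # returns the newick fragment for `node` with its incoming edge length
    if (node <= ntip) {
      s <- tree$tip.label[node]
    } else {
      nl <- if (!is.null(lab)) lab[node - ntip] else ""
      if (is.na(nl)) nl <- ""
      s <- paste0("(", paste(expand(node), collapse = ","), ")", nl)
    }
    if (!is.na(incoming)) s <- paste0(s, ":", format(incoming, digits = 10))
    s
  }
  # recursion is over the (possibly contracted) child lists; drop set never
  # contains the root, so the top call is safe
  txt <- paste0(build(root, NA_real_), ";")
  out <- ape::read.tree(text = txt)
  out
}
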