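# Sequence, alignment, locus and tree I/O.
#
# Conventions used throughout the package:
#  * a "sequence set" is a data.frame with columns id, desc, seq and an
#    attribute "alphabet" ("protein" or "dna"); residues are upper case and
#    ungapped,
#  * an "alignment" is a named character vector of equal-length gapped rows
#    ('-' is the gap character), names are the sequence ids,
#  * gene loci are data.frames with columns gene_id, family, seqid, start,
#    end, strand using GFF3 1-based inclusive coordinates,
#  * trees are ape "phylo" objects; bootstrap supports (0-100) live in
#    node.label.
# All other coordinates in the package (motif ranges, alignment hits) are
# 0-based half-open; conversion happens only at these boundaries.

PROTEIN_CHARS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                   "R","S","T","V","W","Y")
DNA_CHARS <- c("A","C","G","T")

#' Construct a validated sequence set
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of residue strings (no gaps).
#' @param desc optional descriptions (free text).
#' @param alphabet "protein" or "dna".  Protein residues may include X and a
#'   single terminal "*" (a stop from six-frame translation); DNA may include
#'   N.
#' @return data.frame with columns id, desc, seq and attribute "alphabet".
#' @export
seq_set <- function(id, seq, desc = "", alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("id and seq must have equal length")
  if (any(!nzchar(id))) stop("sequence ids must be nonempty")
  if (anyDuplicated(id))
    stop("duplicate sequence id: ", id[duplicated(id)][1L])
  desc <- rep_len(as.character(desc), length(id))
  for (i in seq_along(seq)) check_residues(seq[i], alphabet, id[i])
  out <- data.frame(id = id, desc = desc, seq = seq,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

check_residues <- function(s, alphabet, label) {
  ok <- if (alphabet == "protein") c(PROTEIN_CHARS, "X") else c(DNA_CHARS, "N")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  # '*' permitted only as the final protein residue (translation product)
  if (alphabet == "protein" && length(ch) && any(ch == "*")) {
    if (any(which(ch == "*") != length(ch)))
      stop("in '", label, "': '*' allowed only as final residue")
    ch <- ch[-length(ch)]
  }
  bad <- setdiff(unique(ch), ok)
  if (length(bad))
    stop("in '", label, "': character(s) not in ", alphabet,
         " alphabet: ", paste(bad, collapse = " "), " at position ",
         which(ch %in% bad)[1L])
  invisible(TRUE)
}

alphabet_of <- function(seqs) {
  a <- attr(seqs, "alphabet")
  if (is.null(a)) "protein" else a
}

#' Read a FASTA file into a sequence set
#'
#' The header token before the first whitespace becomes the id; the remainder
#' the description.  Wrapped sequence lines are concatenated; residues are
#' upper-cased and validated against the declared alphabet.
#'
#' @param path file path.
#' @param alphabet "protein" or "dna".
#' @param aligned read an aligned (gapped) FASTA; the result is then an
#'   alignment (named character vector of rows) rather than a sequence set,
#'   and residues are validated after gap removal.
#' @return sequence set (see [seq_set()]); empty file gives a zero-row set
#'   with a warning.  With aligned = TRUE, a named character vector.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"),
                       aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path)
    if (aligned) return(stats::setNames(character(), character()))
    return(seq_set(character(), character(), alphabet = alphabet))
  }
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(id))
    stop("duplicate FASTA id: ", id[duplicated(id)][1L])
  if (aligned) {
    rows <- toupper(as.character(ss))
    if (length(unique(nchar(rows))) != 1L)
      stop("aligned FASTA rows differ in length in ", path)
    for (i in seq_along(rows))
      check_residues(gsub("-", "", rows[i], fixed = TRUE), alphabet, id[i])
    return(stats::setNames(rows, id))
  }
  seq_set(id, as.character(ss), desc, alphabet)
}

#' Write a sequence set (or alignment) as FASTA
#'
#' Lines are wrapped at 60 columns.  Alignments (named character vectors)
#' are accepted as-is, gaps included.
#' @param seqs sequence set or named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    nm <- ifelse(nzchar(seqs$desc), paste(seqs$id, seqs$desc), seqs$id)
    ss <- Biostrings::BStringSet(stats::setNames(seqs$seq, nm))
  } else {
    ss <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

#' Read gene loci from a GFF3 file
#'
#' Coordinates are kept 1-based inclusive as in GFF3.  The gene identifier is
#' taken from the ID attribute, falling back to Name.  Multiple CDS rows
#' sharing one gene id are collapsed to their envelope
#' (min(start)..max(end)).  An optional "family" attribute populates the
#' family column (defaults to the gene id).
#'
#' @param path GFF3 file.
#' @param feature_types which feature types to retain.
#' @return data.frame(gene_id, family, seqid, start, end, strand).
#' @export
read_gff3 <- function(path, feature_types = c("gene", "CDS")) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  keep <- g$type %in% feature_types
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0L) {
    warning("no rows of type ", paste(feature_types, collapse = "/"),
            " in ", path)
    return(data.frame(gene_id = character(), family = character(),
                      seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  bad <- which(g$start > g$end)
  if (length(bad))
    stop("start > end in GFF3 row for feature at line entry ", bad[1L],
         " (", g$seqid[bad[1L]], ":", g$start[bad[1L]], "-", g$end[bad[1L]],
         ")")
  strand <- as.character(g$strand)
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand symbol '",
         strand[which(!strand %in% c("+", "-"))[1L]], "' in ", path)
  gid <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
  if ("Name" %in% names(g)) {
    nm <- as.character(g$Name)
    gid <- ifelse(is.na(gid) | !nzchar(gid), nm, gid)
  }
  if (any(is.na(gid) | !nzchar(gid)))
    stop("GFF3 feature without ID or Name attribute in ", path)
  fam <- if ("family" %in% names(g)) as.character(g$family) else gid
  fam <- ifelse(is.na(fam), gid, fam)
  out <- do.call(rbind, lapply(split(seq_len(nrow(g)), gid), function(ix) {
    if (length(unique(g$seqid[ix])) > 1L || length(unique(strand[ix])) > 1L)
      stop("feature '", gid[ix[1L]], "' spans multiple seqids or strands")
    data.frame(gene_id = gid[ix[1L]], family = fam[ix[1L]],
               seqid = as.character(g$seqid[ix[1L]]),
               start = min(g$start[ix]), end = max(g$end[ix]),
               strand = strand[ix[1L]], stringsAsFactors = FALSE)
  }))
  out <- out[order(out$seqid, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a Newick tree
#'
#' Numeric internal-node labels are retained as branch supports in
#' node.label.  Negative branch lengths are clamped to zero with a message.
#' Polytomies are allowed.
#'
#' @param x a Newick string or a file path.
#' @return an ape "phylo" object.
#' @export
read_newick <- function(x) {
  tr <- if (length(x) == 1L && grepl("\\(", x)) ape::read.tree(text = x)
        else ape::read.tree(file = x)
  if (is.null(tr)) stop("Newick parse error in input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf name: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    message("clamping ", sum(tr$edge.length < 0),
            " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write a tree as Newick
#'
#' Supports stored in node.label are written as internal labels.
#' @param tree phylo object.
#' @param path optional file; when NULL the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

# ---- alignment helpers -----------------------------------------------------

#' Convert an alignment to a character matrix (rows = sequences)
#' @param alignment named character vector of gapped rows.
#' @export
aln_matrix <- function(alignment) {
  if (length(alignment) == 0L) stop("empty alignment")
  n <- nchar(alignment)
  if (length(unique(n)) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

#' Remove gaps from alignment rows
#' @param alignment named character vector of gapped rows.
#' @return named character vector of ungapped sequences.
#' @export
ungap <- function(alignment) {
  vapply(alignment, function(r) gsub("-", "", r, fixed = TRUE), "")
}

#' Drop columns that are gaps in every row
#' @param alignment named character vector of gapped rows.
#' @export
drop_gap_columns <- function(alignment) {
  m <- aln_matrix(alignment)
  keep <- colSums(m != "-") > 0L
  apply_cols(m, keep)
}

apply_cols <- function(m, keep) {
  m <- m[, keep, drop = FALSE]
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Write gene loci as a GFF3 file
#' @param loci gene locus data.frame (see [read_gff3()]).
#' @param path output path.
#' @param type feature type to write (default "gene").
#' @export
write_gff3 <- function(loci, path, type = "gene") {
  lines <- c("##gff-version 3",
             sprintf("%s\thoxfocus\t%s\t%d\t%d\t.\t%s\t.\tID=%s;family=%s",
                     loci$seqid, type, loci$start, loci$end, loci$strand,
                     loci$gene_id, loci$family))
  writeLines(lines, path)
  invisible(path)
}

seqs_to_vec <- function(seqs) stats::setNames(seqs$seq, seqs$id)

vec_to_seqs <- function(v, alphabet = "protein") {
  seq_set(names(v), unname(v), alphabet = alphabet)
}
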