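# Independent oracles and small generators used across the test files.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")

rand_prot <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")

# Exhaustive enumeration of all gapped local alignments: maximum over all
# substring pairs of the best global alignment score with affine gaps
# (open + ext charged on the first gap residue).  No DP tables; plain
# recursive path enumeration.  Only usable for short sequences.
sw_enumerate <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  global_best <- function(ai, bi) {
    rec <- function(i, j, prev) {
      if (i > length(ai) && j > length(bi)) return(0)
      best <- -Inf
      if (i <= length(ai) && j <= length(bi))
        best <- max(best, mat[ai[i], bi[j]] + rec(i + 1L, j + 1L, "M"))
      if (i <= length(ai))
        best <- max(best,
                    -(if (prev == "X") ext else open + ext) +
                      rec(i + 1L, j, "X"))
      if (j <= length(bi))
        best <- max(best,
                    -(if (prev == "Y") ext else open + ext) +
                      rec(i, j + 1L, "Y"))
      best
    }
    rec(1L, 1L, "M")
  }
  best <- 0
  for (i1 in seq_along(A)) for (i2 in i1:length(A))
    for (j1 in seq_along(B)) for (j2 in j1:length(B))
      best <- max(best, global_best(A[i1:i2], B[j1:j2]))
  best
}

# Independent six-frame ORF scan built on seqinr's translator.
orf_oracle <- function(nt, min_aa) {
  out <- character()
  rc <- paste(rev(chartr("ACGT", "TGCA",
                         strsplit(nt, "")[[1L]])), collapse = "")
  for (fr in 0:2) {
    for (s in c(nt, rc)) {
      aa <- paste(seqinr::translate(strsplit(s, "")[[1L]],
                                    frame = fr), collapse = "")
      for (m in regmatches(aa, gregexpr("M[^*]*", aa))[[1L]])
        if (nchar(m) >= min_aa) out <- c(out, m)
    }
  }
  sort(out)
}

# Brute-force clade enumeration: every clade of a rooted tree as a tip set.
all_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  cl <- lapply(seq_len(ntip), function(i) tree$tip.label[i])
  for (node in (ntip + 1L):(ntip + tree$Nnode))
    cl <- c(cl, list(ape::extract.clade(tree, node)$tip.label))
  cl
}

# Oracle for the focal subclade: smallest clade covering all ingroup ids.
focal_oracle <- function(tree, ingroup) {
  cl <- all_clades(tree)
  ok <- Filter(function(tips) all(ingroup %in% tips), cl)
  sizes <- vapply(ok, length, 0L)
  sort(ok[[which.min(sizes)]])
}

# Oracle for family assignment: smallest pure clade per family.
assign_oracle <- function(tree, ref_labels) {
  cl <- all_clades(tree)
  unknowns <- setdiff(tree$tip.label, names(ref_labels))
  out <- stats::setNames(rep("unassigned", length(unknowns)), unknowns)
  for (fam in unique(ref_labels)) {
    refs <- names(ref_labels)[ref_labels == fam]
    refs <- intersect(refs, tree$tip.label)
    if (!length(refs)) next
    ok <- Filter(function(tips) all(refs %in% tips), cl)
    sizes <- vapply(ok, length, 0L)
    tips <- ok[[which.min(sizes)]]
    others <- intersect(tips, names(ref_labels)[ref_labels != fam])
    if (length(others)) next
    out[intersect(tips, unknowns)] <- fam
  }
  out
}

# A small planted-family simulation convenient for focused tests.
tiny_sim <- function(seed, n_species = 2L, n_decoys = 10L) {
  simulate_proteomes(sim_config(seed = seed, n_species = n_species,
                                n_decoys = n_decoys))
}

precision_recall <- function(assignments, truth) {
  m <- merge(assignments, truth, by = "seq_id")
  assigned <- m[m$family.x != "unassigned", , drop = FALSE]
  planted <- m[m$family.y != "decoy", , drop = FALSE]
  list(precision = if (nrow(assigned)) {
         mean(assigned$family.x == assigned$family.y)
       } else NA_real_,
       recall = mean(planted$family.x == planted$family.y))
}
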