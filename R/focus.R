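# The phylogenetic focusing pipeline: per-species harvest -> dedup -> tree
# -> root on outgroup -> focal subclade extraction -> pooling -> filtering
# -> final tree -> clade assignment of unknowns.

#' Pipeline configuration
#'
#' Defaults mirror the pipeline's published operating point: BLASTp-style
#' harvest at E <= 1e-05, CD-HIT dedup at c = 0.98 / n = 5, alignment editor
#' w = 347 / g = 0.9, and support collapse below 95.  B is the bootstrap
#' replicate count of the distance/NJ support engine (100 by default: with a
#' collapse threshold of 95 the support granularity of 1 percentage point is
#' sufficient, and replicates are the dominant cost).
#'
#' @param e_cutoff harvest E-value cutoff.
#' @param c,n identity threshold and word size for dedup clustering.
#' @param w,g alignment-editor window and gap fraction.
#' @param support_collapse collapse internal edges with support below this.
#' @param hmm_bits_cutoff domain-filter log-odds cutoff in bits.
#' @param B bootstrap replicates; @param seed integer seed.
#' @param family_labels ordered family names used for assignment reports.
#' @param min_overlap,min_identity scaffold-merge acceptance parameters.
#' @return list of class "focus_config".
#' @export
focus_config <- function(e_cutoff = 1e-05, c = 0.98, n = 5L, w = 347L,
                         g = 0.9, support_collapse = 95,
                         hmm_bits_cutoff = 0, B = 100L, seed = 1L,
                         family_labels = c("lab", "pb", "zen", "Dfd", "Scr",
                                           "ftz", "Antp", "Ubx", "abd-A",
                                           "Abd-B"),
                         min_overlap = 50L, min_identity = 99.8) {
  stopifnot(e_cutoff > 0, c > 0, c <= 1, n >= 1, w >= 1, g > 0, g <= 1,
            support_collapse >= 0, support_collapse <= 100, B >= 1)
  structure(list(e_cutoff = e_cutoff, c = c, n = as.integer(n),
                 w = as.integer(w), g = g,
                 support_collapse = support_collapse,
                 hmm_bits_cutoff = hmm_bits_cutoff, B = as.integer(B),
                 seed = as.integer(seed), family_labels = family_labels,
                 min_overlap = as.integer(min_overlap),
                 min_identity = min_identity),
            class = "focus_config")
}

query_roles <- function(queries) {
  if (!"role" %in% names(queries))
    stop("queries must carry a 'role' column (ingroup/outgroup)")
  if (!all(queries$role %in% c("ingroup", "outgroup")))
    stop("query roles must be 'ingroup' or 'outgroup'")
  list(ingroup = queries$id[queries$role == "ingroup"],
       outgroup = queries$id[queries$role == "outgroup"])
}

#' Root a tree on the edge above an outgroup clade
#'
#' The root is placed on the edge above the smallest clade containing all
#' outgroup ids present in the tree.  If that clade is the whole tree (the
#' outgroup is not separable), the largest outgroup-only clade is used
#' instead, with a warning.  Pairwise path lengths are preserved.
#'
#' @param tree phylo object.
#' @param outgroup_ids leaf names considered outgroup.
#' @return rooted phylo object.
#' @export
root_on_outgroup <- function(tree, outgroup_ids) {
  present <- intersect(tree$tip.label, outgroup_ids)
  if (!length(present)) stop("no outgroup id present in tree")
  if (length(present) == length(tree$tip.label))
    stop("every leaf is an outgroup; cannot root")
  og <- present
  if (length(present) > 1L) {
    mrca <- ape::getMRCA(tree, present)
    tips <- clade_tips(tree, mrca)
    if (length(tips) == length(tree$tip.label)) {
      og <- largest_pure_clade(tree, present)
      warning("outgroup spans the whole tree; rooting above the largest ",
              "outgroup-only clade (", length(og), " leaves)")
    } else {
      og <- tips
    }
  }
  ape::root(tree, outgroup = og, resolve.root = TRUE)
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

largest_pure_clade <- function(tree, pure_set) {
  ntip <- length(tree$tip.label)
  best <- intersect(tree$tip.label, pure_set)[1L]
  for (node in (ntip + 2L):(ntip + tree$Nnode)) {
    tips <- clade_tips(tree, node)
    if (all(tips %in% pure_set) && length(tips) > length(best)) best <- tips
  }
  best
}

#' Leaves of the focal subclade
#'
#' All leaves under the most recent common ancestor of the ingroup ids
#' present in the rooted tree (reference and unknown leaves alike).  If the
#' MRCA is the root the whole leaf set is returned with a "focus
#' uninformative" warning.
#'
#' @param rooted_tree rooted phylo object.
#' @param ingroup_ids leaf names anchoring the focal clade.
#' @return character vector of leaf names.
#' @export
extract_focal_subclade <- function(rooted_tree, ingroup_ids) {
  present <- intersect(rooted_tree$tip.label, ingroup_ids)
  if (!length(present)) stop("no ingroup id present in tree")
  if (length(present) == 1L) {
    node <- match(present, rooted_tree$tip.label)
  } else {
    node <- ape::getMRCA(rooted_tree, present)
  }
  tips <- clade_tips(rooted_tree, node)
  if (length(tips) == length(rooted_tree$tip.label))
    warning("focus uninformative: ingroup spans the whole tree")
  tips
}

#' Per-species phylogenetic focusing
#'
#' Harvest the proteome with the query panel, deduplicate the hits, build a
#' bootstrap NJ tree of queries plus candidates, root on the outgroup
#' queries and return the candidate sequences falling inside the focal
#' (ingroup) subclade.
#'
#' @param proteome protein sequence set of one species.
#' @param queries query panel with a role column (ingroup/outgroup) and a
#'   family column for ingroup references.
#' @param cfg a [focus_config()].
#' @param scheme scoring scheme.
#' @return character vector of focused candidate ids (possibly empty).
#' @export
focus_species <- function(proteome, queries, cfg = focus_config(),
                          scheme = scoring_scheme()) {
  roles <- query_roles(queries)
  hits <- search_proteome(queries, proteome, scheme, cfg$e_cutoff)
  cand_ids <- setdiff(unique(hits$sid), queries$id)
  if (!length(cand_ids)) {
    message("no hits at E <= ", cfg$e_cutoff, "; species dropped")
    return(character())
  }
  cand <- proteome[match(cand_ids, proteome$id), , drop = FALSE]
  clusters <- cluster_greedy(cand, cfg$c, cfg$n, scheme)
  reps <- cluster_representatives(clusters, cand)
  pool <- rbind(queries[, c("id", "desc", "seq")],
                reps[, c("id", "desc", "seq")])
  attr(pool, "alphabet") <- "protein"
  if (nrow(pool) < 4L) return(reps$id)   # too few leaves for a tree
  aln <- align_progressive(pool, scheme)
  tree <- bootstrap_support(aln, B = cfg$B, seed = cfg$seed)
  rooted <- root_on_outgroup(tree, roles$outgroup)
  focal <- extract_focal_subclade(rooted, roles$ingroup)
  intersect(reps$id, focal)
}

#' Pool focused candidates, filter, and build the final tree
#'
#' Concatenates the per-species focused sets with the queries, removes
#' duplicates by greedy identity clustering, removes non-domain proteins
#' with a profile HMM built from the aligned queries, aligns, prunes
#' gap-causing rows with the alignment editor, re-aligns, and infers the
#' final bootstrap NJ tree rooted on the outgroup queries with weak edges
#' collapsed.
#'
#' @param per_species_sets list of sequence sets of focused candidates.
#' @param queries query panel (see [focus_species()]).
#' @param cfg a [focus_config()].
#' @param scheme scoring scheme.
#' @return list(alignment, tree, hmm, removed_by_editor, rejected_by_hmm,
#'   counts).
#' @export
pool_and_refine <- function(per_species_sets, queries,
                            cfg = focus_config(),
                            scheme = scoring_scheme()) {
  sets <- Filter(function(s) nrow(s) > 0L, per_species_sets)
  if (!length(sets)) stop("no nonempty species set to pool")
  pooled <- do.call(rbind, lapply(sets, function(s)
    s[, c("id", "desc", "seq")]))
  pooled <- pooled[!duplicated(pooled$id), , drop = FALSE]
  pooled <- pooled[!pooled$id %in% queries$id, , drop = FALSE]
  attr(pooled, "alphabet") <- "protein"
  n_pooled <- nrow(pooled)

  # dedup candidates together with the queries; queries are always retained
  allseq <- rbind(queries[, c("id", "desc", "seq")], pooled)
  attr(allseq, "alphabet") <- "protein"
  clusters <- cluster_greedy(allseq, cfg$c, cfg$n, scheme)
  rep_ids <- vapply(clusters, `[[`, "", "representative")
  cand_ids <- setdiff(intersect(rep_ids, pooled$id), queries$id)
  cand <- pooled[match(cand_ids, pooled$id), , drop = FALSE]

  # domain filter against an HMM built from the aligned queries
  q_aln <- align_progressive(queries, scheme)
  hmm <- build_profile_hmm(q_aln)
  flt <- filter_by_domain(cand, hmm, cfg$hmm_bits_cutoff)

  keep <- rbind(queries[, c("id", "desc", "seq")],
                flt$kept[, c("id", "desc", "seq")])
  attr(keep, "alphabet") <- "protein"
  aln1 <- align_progressive(keep, scheme)
  ed <- alignment_editor(aln1, cfg$w, cfg$g)
  survivors <- vec_to_seqs(ungap(ed$alignment))
  survivors$desc <- keep$desc[match(survivors$id, keep$id)]
  aln2 <- if (nrow(survivors) > 1L) align_progressive(survivors, scheme)
          else seqs_to_vec(survivors)

  roles <- query_roles(queries)
  base <- neighbor_joining(dist_from_matrix(aln_matrix(aln2), "poisson",
                                            zero_overlap = "ceiling"))
  og <- intersect(base$tip.label, roles$outgroup)
  if (length(og) && length(og) < length(base$tip.label))
    base <- root_on_outgroup(base, og)
  tree <- bootstrap_support(aln2, B = cfg$B, seed = cfg$seed, tree = base)
  tree <- collapse_low_support(tree, cfg$support_collapse)

  list(alignment = aln2, tree = tree, hmm = hmm,
       removed_by_editor = ed$removed, rejected_by_hmm = flt$rejected,
       counts = c(pooled = n_pooled, dedup = nrow(cand),
                  domain_kept = nrow(flt$kept),
                  final = length(aln2)))
}

#' Assign unknown leaves to reference-anchored family clades
#'
#' For each family, the smallest clade containing all of that family's
#' reference leaves is located in the (rooted, support-collapsed) final
#' tree.  If the clade contains no references of other families, every
#' unknown leaf inside is assigned to the family with the clade's support;
#' otherwise the family is reported as a monophyly failure and yields no
#' assignments.  Unknown leaves outside every family clade are
#' "unassigned".
#'
#' @param final_tree rooted phylo with supports in node.label.
#' @param reference_labels named character vector: reference leaf id ->
#'   family.
#' @param min_support assignments require clade support >= min_support when
#'   a support value is present (default 0).
#' @return data.frame(seq_id, family, clade_support, n_references_in_clade)
#'   for every non-reference leaf, with attribute "monophyly_failures".
#' @export
assign_clades <- function(final_tree, reference_labels, min_support = 0) {
  tips <- final_tree$tip.label
  refs <- reference_labels[names(reference_labels) %in% tips]
  unknowns <- setdiff(tips, names(reference_labels))
  sup <- node_supports(final_tree)
  ntip <- length(tips)
  out <- data.frame(seq_id = unknowns, family = "unassigned",
                    clade_support = NA_real_,
                    n_references_in_clade = 0L, stringsAsFactors = FALSE)
  failures <- character()
  for (fam in unique(reference_labels)) {
    fam_refs <- intersect(names(refs)[refs == fam], tips)
    if (!length(fam_refs)) {
      warning("family '", fam, "' has no reference leaves; skipped")
      next
    }
    node <- if (length(fam_refs) == 1L) match(fam_refs, tips)
            else ape::getMRCA(final_tree, fam_refs)
    ctips <- clade_tips(final_tree, node)
    other_refs <- intersect(ctips, names(refs)[refs != fam])
    if (length(other_refs)) {
      failures <- c(failures, fam)
      message("monophyly failure for '", fam, "': clade contains ",
              "references of ", paste(unique(refs[other_refs]),
                                      collapse = ", "))
      next
    }
    csup <- if (node > ntip) sup[node - ntip] else NA_real_
    if (!is.na(csup) && csup < min_support) next
    inside <- intersect(ctips, unknowns)
    sel <- out$seq_id %in% inside
    out$family[sel] <- fam
    out$clade_support[sel] <- csup
    out$n_references_in_clade[sel] <- length(fam_refs)
  }
  attr(out, "monophyly_failures") <- failures
  out
}

#' Flag possible chimeric sequences
#'
#' A sequence with two disjoint high-scoring profile-HMM windows (both at or
#' above the cutoff) is flagged as a possible chimera; no split or repair is
#' attempted.
#'
#' @param seqs protein sequence set.
#' @param hmm profile HMM.
#' @param bits_cutoff per-window Viterbi cutoff in bits.
#' @return data.frame(id, flagged, first_bits, second_bits).
#' @export
flag_chimeras <- function(seqs, hmm, bits_cutoff = 10) {
  res <- lapply(seq_len(nrow(seqs)), function(i) {
    s <- seqs$seq[i]
    w1 <- hmm_best_window(hmm, s)
    second <- -Inf
    if (is.finite(w1$bits) && w1$bits >= bits_cutoff) {
      left <- substring(s, 1L, w1$range[1L])
      right <- substring(s, w1$range[2L] + 1L)
      for (part in c(left, right)) {
        if (nchar(part) >= 10L) {
          w2 <- hmm_best_window(hmm, part)
          if (w2$bits > second) second <- w2$bits
        }
      }
    }
    data.frame(id = seqs$id[i],
               flagged = is.finite(second) && second >= bits_cutoff,
               first_bits = w1$bits, second_bits = second,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
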