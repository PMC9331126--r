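# Synthetic-data generators: proteomes with planted, domain-anchored gene
# families among random decoys, and clustered gene loci on scaffolds
# (optionally split with an exact overlap), each with a truth table.
#
# All generators are pure functions of (configuration, seed).

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 3 species,
#' 8 planted families anchored by a shared 60-residue domain, per-edge
#' substitution probability 0.15 (domain sites at a third of that,
#' mimicking purifying selection), 50 random decoy proteins per species,
#' and gene clusters spaced 2-20 kb apart.
#'
#' @param n_species number of species.
#' @param families ordered family labels (one planted ancestor each).
#' @param n_refs_per_family reference homologs per family in the query
#'   panel (at least 2 so that a family clade is anchored by the
#'   references' most recent common ancestor).
#' @param query_divergence per-site divergence of the reference homologs
#'   from the family ancestor; kept above subs_prob so that references
#'   bracket the within-family diversity, as homologs drawn from distant
#'   insect orders do.
#' @param subs_prob per-site substitution probability per tree edge.
#' @param indel_prob per-site indel probability (flanks only).
#' @param n_decoys decoy proteins per species.
#' @param decoy_length (min, max) decoy length in aa.
#' @param cluster_spacing (min, max) intergenic spacing in bp.
#' @param cds_length planted coding-sequence length in bp.
#' @param split_scaffold cut the simulated scaffold in two.
#' @param overlap exact overlap length of the split pieces in bp.
#' @param inversion flip the strand of one random gene.
#' @param translocation move the first family after the last one.
#' @param seed integer seed.
#' @export
sim_config <- function(n_species = 3L,
                       families = c("lab", "pb", "Dfd", "Scr", "Antp",
                                    "Ubx", "abd-A", "Abd-B"),
                       n_refs_per_family = 2L, query_divergence = 0.2,
                       subs_prob = 0.15, indel_prob = 0.01,
                       n_decoys = 50L, decoy_length = c(80L, 300L),
                       cluster_spacing = c(2000L, 20000L),
                       cds_length = 900L,
                       split_scaffold = FALSE, overlap = 200L,
                       inversion = FALSE, translocation = FALSE,
                       seed = 1L) {
  stopifnot(subs_prob >= 0, subs_prob < 0.75, indel_prob >= 0,
            n_species >= 1, n_decoys >= 0)
  structure(list(n_species = as.integer(n_species), families = families,
                 n_refs_per_family = as.integer(n_refs_per_family),
                 query_divergence = query_divergence,
                 subs_prob = subs_prob, indel_prob = indel_prob,
                 n_decoys = as.integer(n_decoys),
                 decoy_length = as.integer(decoy_length),
                 cluster_spacing = as.integer(cluster_spacing),
                 cds_length = as.integer(cds_length),
                 split_scaffold = isTRUE(split_scaffold),
                 overlap = as.integer(overlap),
                 inversion = isTRUE(inversion),
                 translocation = isTRUE(translocation),
                 seed = as.integer(seed)),
            class = "sim_config")
}

rand_protein <- function(n) paste(sample(AA_ORDER, n, replace = TRUE),
                                  collapse = "")
rand_dna <- function(n) paste(sample(DNA_CHARS, n, replace = TRUE),
                              collapse = "")

mutate_seq <- function(s, p, alphabet = AA_ORDER) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(ch)) < p
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(alphabet, a), 1L), "")
  paste(ch, collapse = "")
}

apply_indels <- function(s, p, alphabet = AA_ORDER) {
  if (p <= 0 || !nzchar(s)) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  out <- character(0)
  for (a in ch) {
    u <- stats::runif(1)
    if (u < p / 2) next                         # deletion
    out <- c(out, a)
    if (u >= p / 2 && u < p)                    # insertion after the site
      out <- c(out, sample(alphabet, 1L))
  }
  paste(out, collapse = "")
}

#' Evolve a protein down a species tree
#'
#' Independent per-edge evolution: each site substitutes with probability
#' subs_prob per edge (uniformly to another residue); sites inside the
#' marked domain interval substitute at subs_prob / 3 (a purifying-selection
#' surrogate) and never take indels.  Deterministic for a fixed seed.
#'
#' @param ancestor residue string at the root.
#' @param species_tree phylo whose tips name the descendants, or an integer
#'   n for a star tree over n tips ("sp1".."spn").
#' @param subs_prob,indel_prob per-site, per-edge probabilities.
#' @param seed integer seed.
#' @param domain_range 0-based half-open interval of the conserved domain
#'   in the ancestor, or NULL.
#' @return named character vector of leaf sequences.
#' @export
evolve_protein <- function(ancestor, species_tree, subs_prob,
                           indel_prob = 0, seed = 1L, domain_range = NULL) {
  if (!nzchar(ancestor)) stop("ancestor must be nonempty")
  set.seed(as.integer(seed))
  if (is.numeric(species_tree)) {
    n <- as.integer(species_tree)
    tips <- paste0("sp", seq_len(n))
    out <- vapply(tips, function(t)
      evolve_once(ancestor, subs_prob, indel_prob, domain_range), "")
    return(out)
  }
  tr <- species_tree
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  seqs <- list(); seqs[[root]] <- ancestor
  # walk edges in preorder
  pre <- ape::reorder.phylo(tr, "cladewise")$edge
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1L]; c <- pre[e, 2L]
    seqs[[c]] <- evolve_once(seqs[[p]], subs_prob, indel_prob, domain_range)
  }
  stats::setNames(unlist(seqs[seq_len(ntip)]), tr$tip.label)
}

evolve_once <- function(s, subs_prob, indel_prob, domain_range) {
  if (is.null(domain_range)) {
    s2 <- mutate_seq(s, subs_prob)
    return(apply_indels(s2, indel_prob))
  }
  pre <- substring(s, 1L, domain_range[1L])
  dom <- substring(s, domain_range[1L] + 1L, domain_range[2L])
  post <- substring(s, domain_range[2L] + 1L)
  paste0(apply_indels(mutate_seq(pre, subs_prob), indel_prob),
         mutate_seq(dom, subs_prob / 3),
         apply_indels(mutate_seq(post, subs_prob), indel_prob))
}

#' Simulate per-species proteomes with planted families and a truth table
#'
#' Each family gets one domain-bearing ancestor (random flanks, a planted
#' hexapeptide and a copy of the packaged homeodomain consensus); each
#' species receives one descendant per family plus n_decoys uniform-random
#' decoy proteins.  The query panel carries n_refs_per_family reference
#' homologs per family (independent draws at query_divergence from the
#' ancestor) plus three outgroup references descended from a single
#' diverged domain-bearing outgroup ancestor, so the outgroup forms a
#' coherent rootable clade.  Sequence headers encode nothing about the
#' truth; ids are per-species serial numbers over a shuffled order.
#'
#' @param cfg a [sim_config()].
#' @return list(proteomes = named list of protein sequence sets, queries =
#'   query panel with role/family columns, truth = data.frame(seq_id,
#'   species, family), ancestors = per-family ancestor records (seq,
#'   domain_start), domain_length, config = cfg).
#' @export
simulate_proteomes <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  domain <- unname(hd_reference_alignment()[1L])
  fam <- cfg$families
  anc <- list()
  for (f in fam) {
    nfl <- rand_protein(sample(30:90, 1L))
    linker <- rand_protein(sample(4:30, 1L))
    cfl <- rand_protein(sample(20:60, 1L))
    dom_f <- mutate_seq(domain, 0.10)
    anc[[f]] <- list(seq = paste0(nfl, "YPWM", linker, dom_f, cfl),
                     domain_start = nchar(nfl) + 4L + nchar(linker))
  }
  # reference homologs: independent draws around each family ancestor
  nref <- cfg$n_refs_per_family
  ref_id <- character(); ref_seq <- character(); ref_fam <- character()
  for (f in fam) {
    a <- anc[[f]]
    dr <- c(a$domain_start, a$domain_start + nchar(domain))
    for (r in seq_len(nref)) {
      ref_id <- c(ref_id, sprintf("Q_%s_%d", f, r))
      ref_seq <- c(ref_seq,
                   evolve_once(a$seq, cfg$query_divergence, cfg$indel_prob,
                               dr))
      ref_fam <- c(ref_fam, f)
    }
  }
  # one coherent outgroup family (a diverged domain-bearing clade)
  og_nfl <- rand_protein(sample(30:90, 1L))
  og_anc <- paste0(og_nfl, mutate_seq(domain, 0.35),
                   rand_protein(sample(20:60, 1L)))
  og_dr <- c(nchar(og_nfl), nchar(og_nfl) + nchar(domain))
  og_seq <- vapply(1:3, function(k)
    evolve_once(og_anc, cfg$subs_prob, cfg$indel_prob, og_dr), "")
  queries <- data.frame(
    id = c(ref_id, paste0("Q_og", 1:3)),
    desc = c(paste("reference", ref_fam), rep("outgroup reference", 3L)),
    seq = c(ref_seq, og_seq),
    family = c(ref_fam, rep(NA_character_, 3L)),
    role = c(rep("ingroup", length(ref_id)), rep("outgroup", 3L)),
    stringsAsFactors = FALSE)
  attr(queries, "alphabet") <- "protein"

  proteomes <- list()
  truth <- list()
  for (s in seq_len(cfg$n_species)) {
    sp <- paste0("sp", s)
    members <- vapply(fam, function(f) {
      a <- anc[[f]]
      evolve_once(a$seq, cfg$subs_prob, cfg$indel_prob,
                  c(a$domain_start, a$domain_start + nchar(domain)))
    }, "")
    decoys <- vapply(seq_len(cfg$n_decoys), function(i)
      rand_protein(sample(cfg$decoy_length[1L]:cfg$decoy_length[2L], 1L)),
      "")
    seqs <- c(members, decoys)
    labels <- c(fam, rep("decoy", cfg$n_decoys))
    ord <- sample(length(seqs))
    ids <- sprintf("%s_p%03d", sp, seq_along(seqs))
    proteomes[[sp]] <- seq_set(ids, seqs[ord], alphabet = "protein")
    truth[[sp]] <- data.frame(seq_id = ids, species = sp,
                              family = labels[ord],
                              stringsAsFactors = FALSE)
  }
  list(proteomes = proteomes, queries = queries,
       truth = do.call(rbind, truth), ancestors = anc,
       domain_length = nchar(domain), config = cfg)
}

#' Simulate a clustered gene scaffold with GFF3-style loci and truth
#'
#' Families are placed in their listed (canonical) order with intergenic
#' spacing drawn from cluster_spacing; optionally one gene is inverted and
#' the first family translocated after the last.  With split_scaffold the
#' scaffold is cut into two pieces sharing an exact overlap of the
#' configured length.
#'
#' @param cfg a [sim_config()].
#' @return list(scaffold, pieces (NULL unless split), loci, truth,
#'   config).
#' @export
simulate_cluster <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  fam <- cfg$families
  order_fam <- fam
  if (cfg$translocation)
    order_fam <- c(order_fam[-1L], order_fam[1L])
  strands <- rep("+", length(order_fam))
  if (cfg$inversion)
    strands[sample(length(order_fam), 1L)] <- "-"
  pos <- sample(cfg$cluster_spacing[1L]:cfg$cluster_spacing[2L], 1L)
  rows <- list()
  chunks <- character()
  cursor <- 1L
  for (i in seq_along(order_fam)) {
    gap_before <- if (i == 1L) pos
      else sample(cfg$cluster_spacing[1L]:cfg$cluster_spacing[2L], 1L)
    chunks <- c(chunks, rand_dna(gap_before))
    cursor <- cursor + gap_before
    cds <- rand_dna(cfg$cds_length)
    chunks <- c(chunks, cds)
    rows[[i]] <- data.frame(
      gene_id = order_fam[i], family = order_fam[i], seqid = "scf_sim",
      start = cursor, end = cursor + cfg$cds_length - 1L,
      strand = strands[i], stringsAsFactors = FALSE)
    cursor <- cursor + cfg$cds_length
  }
  chunks <- c(chunks, rand_dna(sample(cfg$cluster_spacing[1L]:
                                        cfg$cluster_spacing[2L], 1L)))
  scaffold_seq <- paste(chunks, collapse = "")
  scaffold <- seq_set("scf_sim", scaffold_seq, alphabet = "dna")
  loci <- do.call(rbind, rows)
  pieces <- NULL
  if (cfg$split_scaffold) {
    L <- nchar(scaffold_seq)
    cut <- sample(seq(L %/% 3, 2L * L %/% 3), 1L)
    left <- substring(scaffold_seq, 1L, cut + cfg$overlap - 1L)
    right <- substring(scaffold_seq, cut, L)
    pieces <- seq_set(c("scf_sim_left", "scf_sim_right"),
                      c(left, right), alphabet = "dna")
  }
  list(scaffold = scaffold, pieces = pieces, loci = loci,
       truth = loci, config = cfg)
}
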