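test_that("local alignment scores match hand-computed diagonal sums", {
  h <- local_align(c(q = "YPWM"), c(s = "YPWM"))
  expect_equal(h$score, 7 + 7 + 11 + 5)  # BLOSUM62 diagonal
  expect_equal(h$percent_identity, 100)
  expect_equal(h$query_range, c(0L, 4L))
  expect_null(local_align(c(q = "YPWM"), c(s = "")))
})

test_that("local alignment equals exhaustive enumeration on short pairs", {
  set.seed(42)
  sch <- scoring_scheme()
  sub <- c("A", "R", "N", "D")   # 4-letter reduced alphabet
  for (rep in 1:12) {
    a <- rand_prot(sample(2:5, 1L), sub)
    b <- rand_prot(sample(2:5, 1L), sub)
    want <- sw_enumerate(a, b, sch$matrix, sch$gap_open, sch$gap_extend)
    h <- local_align(c(q = a), c(s = b), sch)
    got <- if (is.null(h)) 0 else h$score
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("alphabet is enforced for protein search", {
  expect_error(local_align(c(q = "ACGU"), c(s = "MKL")), "alphabet")
})

test_that("E-values follow the Karlin-Altschul closed form", {
  ev <- evalue(40, 100, 100)
  expect_equal(ev$evalue, 0.041 * 1e4 * exp(-0.267 * 40), tolerance = 1e-12)
  expect_equal(ev$evalue, 9.4e-3, tolerance = 0.01)
  expect_equal(evalue(0, 50, 70)$evalue, 0.041 * 50 * 70)
  # linear in n, monotone decreasing in score
  expect_equal(evalue(25, 100, 200)$evalue, 2 * evalue(25, 100, 100)$evalue)
  expect_lt(evalue(30, 100, 100)$evalue, evalue(20, 100, 100)$evalue)
  expect_error(evalue(10, 0, 100), "search space")
})

test_that("proteome search equals all-pairs filtering and sorts by E", {
  set.seed(7)
  q <- seq_set(c("q1", "q2"), c(rand_prot(60), rand_prot(50)))
  prot <- seq_set(paste0("p", 1:6),
                  c(q$seq[1L], rand_prot(80), rand_prot(120),
                    paste0(rand_prot(10), q$seq[2L], rand_prot(5)),
                    rand_prot(70), rand_prot(90)))
  hits <- search_proteome(q, prot, e_cutoff = 1e-05)
  # oracle: exhaustive pairing through local_align + evalue
  n_space <- sum(nchar(prot$seq))
  want <- list()
  for (qi in 1:2) for (si in 1:6) {
    h <- local_align(q[qi, ], prot[si, ])
    if (is.null(h)) next
    e <- evalue(h$score, nchar(q$seq[qi]), n_space)$evalue
    if (e <= 1e-05) want[[length(want) + 1L]] <- c(q$id[qi], prot$id[si])
  }
  expect_equal(nrow(hits), length(want))
  expect_setequal(paste(hits$qid, hits$sid),
                  vapply(want, paste, "", collapse = " "))
  # the exact self-match is the top hit for q1
  expect_equal(hits$sid[hits$qid == "q1"][1L], "p1")
  expect_true(all(diff(order(hits$qid, hits$evalue)) > 0))
  expect_error(search_proteome(q, prot, e_cutoff = 0), "> 0")
  expect_warning(search_proteome(q, prot[0, ]), "empty")
})

test_that("six-frame ORFs match a hand translation and the seqinr oracle", {
  o <- six_frame_orfs(seq_set("c", "ATGAAATAA", alphabet = "dna"),
                      min_aa = 2)
  expect_equal(o$seq, "MK")
  expect_match(o$id, "f\\+1")
  # strand symmetry: reverse complement yields the same peptide
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAATAA")))
  o2 <- six_frame_orfs(seq_set("c", rc, alphabet = "dna"), min_aa = 2)
  expect_equal(o2$seq, "MK")
  expect_match(o2$id, "f-")
  set.seed(11)
  for (rep in 1:8) {
    nt <- rand_dna(sample(60:150, 1L))
    got <- sort(six_frame_orfs(seq_set("c", nt, alphabet = "dna"),
                               min_aa = 5)$seq)
    expect_equal(got, orf_oracle(nt, 5), info = nt)
  }
  expect_equal(nrow(six_frame_orfs(seq_set("c", "AT", alphabet = "dna"),
                                   min_aa = 1)), 0L)
})

test_that("contig harvest keeps encoding contigs and drops random ones", {
  set.seed(3)
  q <- paste0("M", rand_prot(79))
  codons <- vapply(strsplit(q, "")[[1L]], function(a)
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1L], "")
  enc <- paste0("GG", paste(codons, collapse = ""), "TAAC")
  contigs <- seq_set(c("enc", "rnd"), c(enc, rand_dna(300)),
                     alphabet = "dna")
  h <- harvest_contigs(seq_set("q1", q), contigs, min_aa = 50)
  expect_equal(h$contig_id, "enc")
  expect_lte(h$evalue, 1e-20)
  # monotone in the cutoff
  h2 <- harvest_contigs(seq_set("q1", q), contigs, e_cutoff = 1,
                        min_aa = 50)
  expect_gte(nrow(h2), nrow(h))
  # harvested peptides come from the contig's own ORF set
  orfs <- six_frame_orfs(contigs[1L, ], min_aa = 50)
  expect_true(h$peptide %in% orfs$seq)
})

test_that("reciprocal best hit labels, breaks ties, ignores order", {
  set.seed(9)
  ubx <- rand_prot(90); abda <- rand_prot(90)
  panel <- seq_set(c("P1", "P2", "P3"), c(ubx, abda, rand_prot(90)),
                   desc = c("Ubx", "Abd-A", "hypothetical protein"))
  cand <- seq_set("c1", ubx)
  r <- reciprocal_best_hit(cand, panel)
  expect_equal(r$family, "Ubx")
  # tie across labels -> ambiguous
  panel2 <- seq_set(c("P1", "P2"), c(ubx, ubx), desc = c("Ubx", "Abd-A"))
  expect_equal(reciprocal_best_hit(cand, panel2)$family, "ambiguous")
  # order independence
  r2 <- reciprocal_best_hit(cand, panel[c(3, 1, 2), ])
  expect_equal(r2$family, r$family)
  # forward nomination must agree
  r3 <- reciprocal_best_hit(cand, panel, forward_family = c(c1 = "Antp"))
  expect_equal(r3$family, "none")
  # blacklisted labels never win
  hypo <- seq_set("c2", panel$seq[3L])
  expect_false(reciprocal_best_hit(hypo, panel)$family == "hypothetical protein")
  expect_error(reciprocal_best_hit(cand, panel[0, ]), "empty")
})
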