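# A planted Hox-like construct with known geometry is the main fixture:
# M + G-flank + YPWM + linker + homeodomain + C-terminal motifs.
planted_hox <- function(linker_len, hex = "YPWM", nflank = 25L,
                        tail = "QAQAKELNEAAAA") {
  dom <- gsub("-", "", hd_reference_alignment()[[1L]])
  paste0("M", strrep("G", nflank), hex, strrep("S", linker_len), dom, tail)
}

test_that("the homeodomain is located exactly on planted constructs", {
  s <- planted_hox(12L)
  hd <- find_homeodomain(s)
  expect_true(hd$present)
  start <- 1L + 25L + 4L + 12L
  expect_equal(hd$range, c(start, start + 60L))
  expect_gte(diff(hd$range), 50L)
  expect_lte(diff(hd$range), 70L)
  # shuffled sequence scores below the default cutoff
  set.seed(61)
  shuf <- paste(sample(strsplit(s, "")[[1L]]), collapse = "")
  expect_false(find_homeodomain(shuf)$present)
})

test_that("a second domain copy raises the chimera warning", {
  dom <- gsub("-", "", hd_reference_alignment()[[1L]])
  s <- paste0("M", strrep("G", 20L), dom, strrep("A", 30L), dom)
  expect_warning(hd <- find_homeodomain(s), "chimera")
  expect_true(hd$chimera)
})

test_that("hexapeptide search finds the nearest upstream core", {
  s <- planted_hox(12L)
  hd <- find_homeodomain(s)
  hex <- find_hexapeptide(s, hd$range)
  expect_equal(hex$matched, "YPWM")
  # YKWM variant is matched by the strict pattern too
  s2 <- planted_hox(12L, hex = "YKWM")
  hex2 <- find_hexapeptide(s2, find_homeodomain(s2)$range)
  expect_equal(hex2$matched, "YKWM")
  # relaxed pattern widens the first/second positions
  s3 <- planted_hox(12L, hex = "FAWM")
  hd3 <- find_homeodomain(s3)$range
  expect_null(find_hexapeptide(s3, hd3))
  expect_equal(find_hexapeptide(s3, hd3, relaxed = TRUE)$matched, "FAWM")
  # no upstream match -> absent
  dom <- gsub("-", "", hd_reference_alignment()[[1L]])
  s4 <- paste0("M", strrep("G", 20L), dom)
  expect_null(find_hexapeptide(s4, find_homeodomain(s4)$range))
})

test_that("linker lengths are measured to the planted spacing", {
  for (lr in c(69L, 15L, 14L, 4L, 0L)) {
    s <- planted_hox(lr)
    hd <- find_homeodomain(s)
    hex <- find_hexapeptide(s, hd$range)
    expect_equal(linker_length(hex, hd$range), lr)
  }
  expect_error(linker_length(list(range = c(10L, 14L)), c(12L, 72L)),
               "inside homeodomain")
})

test_that("auxiliary motifs are scanned in their regions", {
  s <- paste0("MSSYF", strrep("G", 20L), "YPWM", "AATDWMGGPFERCC",
              gsub("-", "", hd_reference_alignment()[[1L]]),
              "QQKELNEGGQAQAGGAAAAG")
  hd <- find_homeodomain(s)
  hex <- find_hexapeptide(s, hd$range)
  hits <- scan_aux_motifs(s, hd$range, hex)
  nm <- vapply(hits, `[[`, "", "motif")
  expect_setequal(nm, c("SSYF", "UbdA", "QAQA", "polyA", "TDWM", "PFER"))
  pA <- hits[[which(nm == "polyA")]]
  expect_equal(nchar(pA$matched), 4L)
  for (h in hits)
    expect_equal(h$matched,
                 substring(s, h$range[1L] + 1L, h$range[2L]))
  # SSYF must sit at the N-terminus
  s2 <- sub("MSSYF", "MGGGG", s, fixed = TRUE)
  s2 <- paste0(substring(s2, 1L, 40L), "SSYF", substring(s2, 41L))
  hd2 <- find_homeodomain(s2)
  nm2 <- vapply(scan_aux_motifs(s2, hd2$range,
                                find_hexapeptide(s2, hd2$range)),
                `[[`, "", "motif")
  expect_false("SSYF" %in% nm2)
})

test_that("Abd-B-like proteins report the single conserved tryptophan", {
  dom <- gsub("-", "", hd_reference_alignment()[["syn_hd8"]])
  s <- paste0("M", strrep("G", 15L), "W", strrep("G", 10L), dom)
  hd <- find_homeodomain(s)
  expect_true(hd$present)
  expect_null(find_hexapeptide(s, hd$range))
  hits <- scan_aux_motifs(s, hd$range, NULL)
  nm <- vapply(hits, `[[`, "", "motif")
  expect_true("AbdB_W" %in% nm)
  w <- hits[[which(nm == "AbdB_W")]]
  expect_equal(w$matched, "W")
  expect_equal(w$range, c(16L, 17L))
})

test_that("diagnostic residues pass, fail and flag gaps per column", {
  ref <- hd_reference_alignment()[[1L]]
  res <- check_diagnostic_residues(ref)
  expect_true(all(res$pass))
  expect_equal(res$observed, c("E", "R", "E", "M"))
  # substitute one spec column
  ch <- strsplit(ref, "")[[1L]]
  ch[54L] <- "V"
  res2 <- check_diagnostic_residues(paste(ch, collapse = ""))
  expect_equal(res2$pass, c(TRUE, TRUE, TRUE, FALSE))
  ch[19L] <- "-"
  res3 <- check_diagnostic_residues(paste(ch, collapse = ""))
  expect_equal(res3$note[1L], "gap")
  expect_false(res3$pass[1L])
  expect_error(check_diagnostic_residues("MK"), "beyond")
})

test_that("annotation combines regions, completeness and hints", {
  s <- planted_hox(14L)
  a <- annotate_hox(s, id = "ubx_like")
  expect_true(a$homeodomain$present)
  expect_equal(a$linker_length, 14L)
  expect_true(a$n_terminus_complete)
  expect_true(a$c_terminus_complete)
  expect_equal(a$family_hint, "Ubx")
  # trailing X marks an incomplete C-terminus; missing Met an incomplete N
  a2 <- annotate_hox(paste0(substring(s, 2L), "X"), id = "partial")
  expect_false(a2$n_terminus_complete)
  expect_false(a2$c_terminus_complete)
})

test_that("classification trusts the tree and annotates motif conflicts", {
  a <- annotate_hox(planted_hox(10L), id = "u1")
  cls <- classify_hox(a, "Ubx")
  expect_equal(cls$family, "Ubx")
  expect_true(all(c("UbdA", "QAQA", "hexapeptide") %in% cls$corroborating))
  expect_length(cls$conflicting, 0L)
  # same motifs under an Antp assignment conflict
  cls2 <- classify_hox(a, "Antp")
  expect_equal(cls2$family, "Antp")
  expect_true("UbdA" %in% cls2$conflicting)
  cls3 <- classify_hox(a, "unassigned")
  expect_equal(cls3$family, "unassigned")
  expect_length(cls3$corroborating, 0L)
  expect_true("hexapeptide" %in% cls3$motifs)
})
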