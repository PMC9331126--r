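# Hox protein functional-region annotation: homeodomain localization via a
# profile HMM, hexapeptide, linker length, and the short diagnostic motifs
# (SSYF, UbdA, QAQA, poly-A, TDWM, PFER, the Abd-B conserved tryptophan).
#
# Motif coordinates are 0-based half-open on the protein sequence.

#' Packaged homeodomain reference alignment
#'
#' A synthetic 60-column homeodomain panel built around the canonical
#' Antp-class consensus (file homeodomain_ref_synthetic.fasta).  The four
#' Hox-diagnostic residues sit at alignment columns 19 (Glu, helix 1),
#' 31 (Arg) and 33 (Glu, helix 2), and 54 (Met, helix 3).
#' @return alignment (named character vector).
#' @export
hd_reference_alignment <- function() {
  f <- system.file("extdata", "homeodomain_ref_synthetic.fasta",
                   package = "hoxfocus")
  seqs_to_vec(read_fasta(f))
}

.hoxfocus_env <- new.env(parent = emptyenv())

#' Profile HMM of the packaged homeodomain reference
#' @return profile_hmm object (cached after first build).
#' @export
hd_profile <- function() {
  if (is.null(.hoxfocus_env$hd_hmm))
    .hoxfocus_env$hd_hmm <- build_profile_hmm(hd_reference_alignment())
  .hoxfocus_env$hd_hmm
}

#' Default diagnostic-residue specification
#'
#' Columns are 1-based positions in the packaged homeodomain reference
#' alignment.
#' @return data.frame(column, allowed, note).
#' @export
hd_residue_spec <- function() {
  f <- system.file("extdata", "hd_residue_spec.json", package = "hoxfocus")
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  x$allowed <- lapply(x$allowed, unlist)
  x
}

motif_hit <- function(motif, start, end, seq) {
  list(motif = motif, range = c(start, end),
       matched = substring(seq, start + 1L, end))
}

#' Locate the homeodomain in a protein sequence
#'
#' Best-scoring local profile-HMM window (Viterbi).  The domain is reported
#' absent when its score is below bits_cutoff.  A second disjoint window at
#' or above the cutoff raises a chimera flag.
#'
#' @param seq residue string.
#' @param hd_hmm profile HMM (default: the packaged reference).
#' @param bits_cutoff minimum Viterbi log-odds in bits (default 10).
#' @return list(present, range (0-based half-open), bits, chimera) or, when
#'   absent, list(present = FALSE, bits).
#' @export
find_homeodomain <- function(seq, hd_hmm = hd_profile(), bits_cutoff = 10) {
  s <- one_seq(seq)$seq
  w <- hmm_best_window(hd_hmm, s)
  if (!is.finite(w$bits) || w$bits < bits_cutoff)
    return(list(present = FALSE, range = NULL, bits = w$bits,
                chimera = FALSE))
  chim <- FALSE
  left <- substring(s, 1L, w$range[1L])
  right <- substring(s, w$range[2L] + 1L)
  for (part in c(left, right)) {
    if (nchar(part) >= 20L) {
      w2 <- hmm_best_window(hd_hmm, part)
      if (is.finite(w2$bits) && w2$bits >= bits_cutoff) {
        chim <- TRUE
        warning("second homeodomain-scoring window found; possible chimera")
      }
    }
  }
  list(present = TRUE, range = w$range, bits = w$bits, chimera = chim)
}

#' Find the hexapeptide motif upstream of the homeodomain
#'
#' Nearest match of the core pattern Y-[PK]-W-M upstream of the homeodomain
#' start; the relaxed flag generalizes to [YF]-x-W-M.
#'
#' @param seq residue string.
#' @param hd_range homeodomain range (0-based half-open).
#' @param relaxed use the generalized pattern.
#' @return motif hit (list(motif, range, matched)) or NULL.
#' @export
find_hexapeptide <- function(seq, hd_range, relaxed = FALSE) {
  s <- one_seq(seq)$seq
  pat <- if (relaxed) "[YF].WM" else "Y[PK]WM"
  m <- gregexpr(pat, s)[[1L]]
  if (m[1L] < 0L) return(NULL)
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  ok <- ends <= hd_range[1L]
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.max(starts[ok])]
  motif_hit("hexapeptide", starts[i], ends[i], s)
}

#' Linker length between hexapeptide and homeodomain
#'
#' Number of residues strictly between the end of the 4-residue hexapeptide
#' core and the homeodomain start.
#' @param hexapeptide_hit motif hit from [find_hexapeptide()].
#' @param hd_range homeodomain range (0-based half-open).
#' @export
linker_length <- function(hexapeptide_hit, hd_range) {
  if (hexapeptide_hit$range[2L] > hd_range[1L])
    stop("hexapeptide inside homeodomain")
  hd_range[1L] - hexapeptide_hit$range[2L]
}

# default short-motif patterns; UbdA has no universal literal consensus, so
# its pattern is exposed and configurable
MOTIF_PATTERNS <- c(SSYF = "SSYF", UbdA = "KELNE", QAQA = "QAQA",
                    polyA = "AAA+", TDWM = "TDWM", PFER = "PFER")

MOTIF_FAMILIES <- list(
  SSYF = c("Scr", "Antp", "Ubx", "abd-A"),
  hexapeptide = c("lab", "pb", "zen", "Dfd", "Scr", "ftz", "Antp", "Ubx",
                  "abd-A"),
  UbdA = c("Ubx", "abd-A"), QAQA = "Ubx", polyA = "Ubx",
  TDWM = "abd-A", PFER = "abd-A", AbdB_W = "Abd-B")

#' Scan the auxiliary Hox motifs
#'
#' SSYF is searched within the first 10 residues; UbdA, QAQA and poly-A
#' (>= 3 consecutive A) C-terminal of the homeodomain; TDWM and PFER in the
#' linker between the hexapeptide and the homeodomain; and, when the
#' hexapeptide is absent, a single conserved tryptophan in the pre-domain
#' region is reported as AbdB_W.
#'
#' @param seq residue string.
#' @param hd_range homeodomain range (0-based half-open).
#' @param hexapeptide_hit hexapeptide hit or NULL.
#' @param patterns named motif patterns (see MOTIF_PATTERNS).
#' @return list of motif hits.
#' @export
scan_aux_motifs <- function(seq, hd_range, hexapeptide_hit = NULL,
                            patterns = MOTIF_PATTERNS) {
  s <- one_seq(seq)$seq
  hits <- list()
  grab <- function(name, region_start, region_end, max_start = Inf) {
    region <- substring(s, region_start + 1L, region_end)
    m <- regexpr(patterns[[name]], region)
    if (m < 0L) return(NULL)
    st <- region_start + as.integer(m) - 1L
    if (st > max_start) return(NULL)
    motif_hit(name, st, st + attr(m, "match.length"), s)
  }
  h <- grab("SSYF", 0L, nchar(s), max_start = 9L)
  if (!is.null(h)) hits <- c(hits, list(h))
  for (nm in c("UbdA", "QAQA", "polyA")) {
    h <- grab(nm, hd_range[2L], nchar(s))
    if (!is.null(h)) hits <- c(hits, list(h))
  }
  linker_start <- if (!is.null(hexapeptide_hit))
    hexapeptide_hit$range[2L] else 0L
  for (nm in c("TDWM", "PFER")) {
    h <- grab(nm, linker_start, hd_range[1L])
    if (!is.null(h)) hits <- c(hits, list(h))
  }
  if (is.null(hexapeptide_hit)) {
    pre <- substring(s, 1L, hd_range[1L])
    w <- gregexpr("W", pre)[[1L]]
    if (w[1L] > 0L && length(w) == 1L) {
      st <- as.integer(w) - 1L
      hits <- c(hits, list(motif_hit("AbdB_W", st, st + 1L, s)))
    }
  }
  hits
}

#' Check diagnostic residues on an aligned homeodomain row
#'
#' @param aligned_hd_row one gapped row aligned to the reference
#'   homeodomain alignment.
#' @param residue_spec data.frame(column, allowed, note); default the
#'   packaged Hox-diagnostic spec.
#' @return data.frame(column, observed, pass, note); a gap at a spec column
#'   fails with note "gap".
#' @export
check_diagnostic_residues <- function(aligned_hd_row,
                                      residue_spec = hd_residue_spec()) {
  ch <- strsplit(aligned_hd_row, "", fixed = TRUE)[[1L]]
  out <- lapply(seq_len(nrow(residue_spec)), function(i) {
    col <- residue_spec$column[i]
    if (col > length(ch)) stop("spec column ", col, " beyond alignment")
    obs <- ch[col]
    if (obs == "-")
      return(data.frame(column = col, observed = obs, pass = FALSE,
                        note = "gap", stringsAsFactors = FALSE))
    data.frame(column = col, observed = obs,
               pass = obs %in% residue_spec$allowed[[i]],
               note = residue_spec$note[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Annotate one Hox protein
#'
#' Runs homeodomain localization, hexapeptide search, linker measurement,
#' auxiliary motif scan and terminus-completeness checks.  N-terminal
#' completeness is the presence of an initial Met; C-terminal completeness
#' the absence of a trailing partial-codon X.
#'
#' @param seq residue string (or one-row sequence set).
#' @param id sequence id for the report.
#' @param hd_hmm profile HMM; @param bits_cutoff homeodomain cutoff.
#' @param relaxed_hexapeptide use the generalized hexapeptide pattern.
#' @return list of class "hox_annotation".
#' @export
annotate_hox <- function(seq, id = NULL, hd_hmm = hd_profile(),
                         bits_cutoff = 10, relaxed_hexapeptide = FALSE) {
  sq <- one_seq(seq)
  if (!is.null(id)) sq$id <- id
  s <- sub("\\*$", "", sq$seq)
  hd <- find_homeodomain(s, hd_hmm, bits_cutoff)
  hex <- NULL; lr <- NA_integer_; aux <- list()
  if (hd$present) {
    hex <- find_hexapeptide(s, hd$range, relaxed_hexapeptide)
    if (!is.null(hex)) lr <- linker_length(hex, hd$range)
    aux <- scan_aux_motifs(s, hd$range, hex)
  }
  fam_hint <- family_hint(hex, aux)
  structure(list(
    seq_id = sq$id, homeodomain = hd, hexapeptide = hex,
    linker_length = lr, aux_motifs = aux,
    n_terminus_complete = startsWith(s, "M"),
    c_terminus_complete = !endsWith(s, "X"),
    family_hint = fam_hint), class = "hox_annotation")
}

family_hint <- function(hex, aux) {
  nm <- vapply(aux, `[[`, "", "motif")
  if (all(c("UbdA", "QAQA") %in% nm) || "polyA" %in% nm && "UbdA" %in% nm)
    return("Ubx")
  if (any(c("TDWM", "PFER") %in% nm)) return("abd-A")
  if ("AbdB_W" %in% nm && is.null(hex)) return("Abd-B")
  NA_character_
}

#' @export
print.hox_annotation <- function(x, ...) {
  cat("Hox annotation for", x$seq_id, "\n")
  if (x$homeodomain$present)
    cat(sprintf("  homeodomain: %d-%d (%.1f bits)\n",
                x$homeodomain$range[1L], x$homeodomain$range[2L],
                x$homeodomain$bits))
  else cat("  homeodomain: absent\n")
  if (!is.null(x$hexapeptide))
    cat("  hexapeptide:", x$hexapeptide$matched, "at",
        x$hexapeptide$range[1L], "; linker", x$linker_length,
        "residues\n")
  for (h in x$aux_motifs)
    cat("  motif", h$motif, ":", h$matched, "at", h$range[1L], "\n")
  invisible(x)
}

#' Combine tree-based assignment with motif evidence
#'
#' The clade assignment is authoritative; motifs only corroborate or
#' conflict.
#'
#' @param annotation a [annotate_hox()] result.
#' @param clade_assignment one row of the [assign_clades()] table (or a
#'   family string).
#' @return list(family, corroborating, conflicting, motifs).
#' @export
classify_hox <- function(annotation, clade_assignment) {
  fam <- if (is.character(clade_assignment)) clade_assignment
         else clade_assignment$family
  nm <- vapply(annotation$aux_motifs, `[[`, "", "motif")
  if (!is.null(annotation$hexapeptide)) nm <- c(nm, "hexapeptide")
  corro <- nm[vapply(nm, function(m) fam %in% MOTIF_FAMILIES[[m]], TRUE)]
  confl <- setdiff(nm, corro)
  if (fam == "unassigned") { corro <- character(); confl <- character() }
  list(family = fam, corroborating = unname(corro),
       conflicting = unname(confl), motifs = unname(nm))
}
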