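test_that("pattern compilation reproduces the family signature layout", {
  cat_p <- compile_pattern("D-x-H")
  expect_equal(cat_p$span, 3L)
  expect_equal(cat_p$literal_pos, c(1L, 3L))
  expect_equal(cat_p$template[c(1, 3)], c("D", "H"))

  sig <- glcnk_signature_pattern()
  expect_equal(sig$span, 16L)
  # offsets (0-based) of the conserved residues along helix alpha-12
  expect_equal(sig$literal_pos - 1L, c(0L, 3L, 4L, 7L, 8L, 12L, 13L, 15L))
  expect_equal(sig$template[sig$literal_pos],
               c("Q", "R", "E", "Y", "A", "L", "P", "W"))

  expect_error(compile_pattern("x(0)"), "wildcard count")
  expect_error(compile_pattern("Q-??-W"), "malformed token")
  expect_error(compile_pattern(""), "non-empty")
})

test_that("compile(render(pattern)) round-trips", {
  for (txt in c("D-x-H", "Q-x(2)-RE-x(2)-YA-x(3)-LP-x-W", "AC-x-DE",
                "W", "x(4)-K")) {
    p <- compile_pattern(txt)
    expect_equal(compile_pattern(render_pattern(p)), p)
  }
})

test_that("scanning finds canonical and degraded signature windows", {
  sig <- glcnk_signature_pattern()
  canonical <- "QAAREAAYAAAALPAW"
  hits <- scan_motif(canonical, sig)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$end, 16L)

  # tyrosine -> alanine partial signature (the SCO2662-style degradation)
  degraded <- "QAAREAAAAAAALPAW"
  expect_equal(nrow(scan_motif(degraded, sig, max_mismatches = 0L)), 0L)
  h1 <- scan_motif(degraded, sig, max_mismatches = 1L)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$mismatches, 1L)

  expect_equal(nrow(scan_motif("", sig)), 0L)
  # case-insensitive; ambiguity letters mismatch literals
  expect_equal(nrow(scan_motif(tolower(canonical), sig)), 1L)
  x_seq <- sub("Q", "X", canonical)
  expect_equal(nrow(scan_motif(x_seq, sig)), 0L)
  expect_equal(scan_motif(x_seq, sig, max_mismatches = 1L)$mismatches, 1L)
})

test_that("overlapping hits are all reported, sorted by start", {
  p <- compile_pattern("A-x-A")
  hits <- scan_motif("AAAAA", p)
  expect_equal(hits$start, 1:3)
  expect_equal(hits$end, 3:5)
})

test_that("scanner equals the brute-force window oracle on random sequences", {
  sig <- glcnk_signature_pattern()
  set.seed(2024)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:1000) {
    s <- paste(sample(aa, 200, replace = TRUE), collapse = "")
    mm_oracle <- oracle_window_mismatches(s, sig$template)
    for (mm in 0:2) {
      hits <- scan_motif(s, sig, max_mismatches = mm)
      expect_identical(hits$start, which(mm_oracle <= mm))
      expect_identical(hits$mismatches, mm_oracle[mm_oracle <= mm])
    }
  }
})

test_that("planted motifs are recalled perfectly with no false positives", {
  sig <- glcnk_signature_pattern()
  planted <- data.frame(seq = 1:50, position = 10L + 3L * (0:49),
                        mismatches = 0L)
  ms <- make_motif_set(n_seqs = 50L, length = 250L, planted = planted,
                       seed = 77)
  found <- 0L
  for (i in 1:50) {
    hits <- scan_motif(ms$seqs[[i]], sig)
    expect_identical(hits$start,
                     which(oracle_window_mismatches(ms$seqs[[i]],
                                                    sig$template) == 0L))
    if (planted$position[i] %in% hits$start) found <- found + 1L
  }
  expect_equal(found, 50L)  # recall 1.0

  # one-mismatch plants surface only when tolerance admits them
  ms1 <- make_motif_set(n_seqs = 10L, length = 100L,
                        planted = data.frame(seq = 1:10, position = 20L,
                                             mismatches = 1L),
                        seed = 78)
  for (i in 1:10) {
    expect_false(20L %in% scan_motif(ms1$seqs[[i]], sig)$start)
    h <- scan_motif(ms1$seqs[[i]], sig, max_mismatches = 1L)
    expect_true(20L %in% h$start)
    expect_equal(h$mismatches[h$start == 20L], 1L)
  }
})

test_that("family classification applies the motif-spacing rule", {
  sig <- glcnk_signature_pattern()
  cat_p <- glcnk_catalytic_pattern()
  bg <- function(n) paste(rep("G", n), collapse = "")
  # catalytic loop starting at 300 and signature at 405, as in the
  # reference enzyme (gap 105)
  s <- paste0(bg(299), "DGH", bg(405 - 303), "QAAREAAYAAAALPAW", bg(30))
  call <- classify_glcnk(s, seq_id = "sj_like")
  expect_true(call$is_glcnk)
  expect_equal(call$signature_hits$start, 405L)
  expect_true(300L %in% call$catalytic_hits$start)

  # signature alone is not enough under the default rule
  s2 <- paste0(bg(404), "QAAREAAYAAAALPAW", bg(30))
  expect_false(classify_glcnk(s2)$is_glcnk)
  expect_true(classify_glcnk(s2, require_catalytic = FALSE)$is_glcnk)

  # both motifs present but 500 residues apart: rejected
  s3 <- paste0(bg(99), "DGH", bg(500), "QAAREAAYAAAALPAW", bg(10))
  call3 <- classify_glcnk(s3)
  expect_false(call3$is_glcnk)
  expect_match(call3$rationale, "gap")
})

test_that("scan_fasta classifies records in input order", {
  sig16 <- "QAAREAAYAAAALPAW"
  bg <- function(n) paste(rep("S", n), collapse = "")
  seqs <- c(pos = paste0(bg(299), "DFH", bg(102), sig16, bg(5)),
            neg = bg(450),
            partial = paste0(bg(299), "DFH", bg(102),
                             sub("Y", "A", sig16), bg(5)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_seqs(seqs, f)
  tab <- scan_fasta(f, max_mismatches = 1L)
  expect_equal(tab$seq_id, c("pos", "neg", "partial"))
  expect_equal(tab$is_glcnk, c(TRUE, FALSE, FALSE))
  expect_equal(tab$signature_start[1], 405L)
  expect_equal(tab$best_signature_mismatches[3], 1L)
})

test_that("column conservation counts modal residues over non-gap rows", {
  aln <- c("AAG-", "AAG-", "AGG-", "AG--")
  cons <- column_conservation(aln)
  expect_equal(cons[1], 1.0)
  expect_equal(cons[2], 0.5)
  expect_equal(cons[3], 1.0)
  expect_true(is.na(cons[4]))
  expect_error(column_conservation(c("AA", "AAA")), "equal length")
  expect_error(column_conservation("AA"), ">= 2")
})
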