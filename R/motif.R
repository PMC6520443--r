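#' Compile a PROSITE-style motif pattern
#'
#' Parses the dash-separated motif grammar used for kinase family
#' signatures: a token is either a run of literal one-letter residue codes
#' (e.g. `RE`) or a wildcard `x` / `x(n)` matching any `n` residues. The
#' actinobacterial glucosamine-kinase signature
#' `Q-x(2)-RE-x(2)-YA-x(3)-LP-x-W` compiles to a span of 16 with literals
#' Q, R, E, Y, A, L, P, W at offsets 0, 3, 4, 7, 8, 12, 13, 15; the
#' catalytic-loop motif `D-x-H` to a span of 3.
#'
#' @param text pattern string.
#' @return object of class `motif_pattern`: `template` (character vector
#'   of length `span`, `NA` at wildcard positions), `span`, `literal_pos`
#'   (1-based offsets of literal positions), `source` (the input string).
#' @examples
#' glcnk_signature_pattern()
#' compile_pattern("D-x-H")
#' @export
compile_pattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("compile_pattern: pattern must be a non-empty string")
  tokens <- strsplit(text, "-", fixed = TRUE)[[1]]
  template <- character(0)
  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    if (grepl("^x(\\([0-9]+\\))?$", tok)) {
      n <- if (tok == "x") 1L else
        as.integer(sub("^x\\(([0-9]+)\\)$", "\\1", tok))
      if (n < 1L)
        stop("compile_pattern: wildcard count must be >= 1 in token ", k,
             " ('", tok, "')")
      template <- c(template, rep(NA_character_, n))
    } else if (grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", toupper(tok))) {
      template <- c(template, strsplit(toupper(tok), "")[[1]])
    } else {
      stop("compile_pattern: malformed token ", k, " ('", tok, "')")
    }
  }
  if (length(template) < 1L) stop("compile_pattern: empty pattern")
  structure(list(template = template, span = length(template),
                 literal_pos = which(!is.na(template)), source = text),
            class = "motif_pattern")
}

#' Render a compiled pattern back to its string form
#'
#' `compile_pattern(render_pattern(p))` reproduces `p` exactly.
#'
#' @param pattern a `motif_pattern`.
#' @return pattern string in canonical form (`x(n)` for runs of n >= 2
#'   wildcards, `x` for single ones).
#' @export
render_pattern <- function(pattern) {
  tpl <- pattern$template
  runs <- rle(is.na(tpl))
  pos <- 1L
  out <- character(0)
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    if (runs$values[k]) {
      out <- c(out, if (len == 1L) "x" else sprintf("x(%d)", len))
    } else {
      out <- c(out, paste(tpl[pos:(pos + len - 1L)], collapse = ""))
    }
    pos <- pos + len
  }
  paste(out, collapse = "-")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s (span %d, %d literal positions)\n",
              x$source, x$span, length(x$literal_pos)))
  invisible(x)
}

#' The glucosamine-kinase consensus signature
#'
#' The helix-alpha12 consensus `Q-x(2)-RE-x(2)-YA-x(3)-LP-x-W` proposed as
#' the family fingerprint for actinobacterial glucosamine kinases, compiled.
#' @return a `motif_pattern` of span 16.
#' @export
glcnk_signature_pattern <- function() {
  compile_pattern("Q-x(2)-RE-x(2)-YA-x(3)-LP-x-W")
}

#' The catalytic-loop motif
#'
#' The catalytic-loop `D-x-H` motif that, together with the helix-alpha12
#' signature, defines the glucosamine-kinase family call.
#' @return a `motif_pattern` of span 3.
#' @export
glcnk_catalytic_pattern <- function() {
  compile_pattern("D-x-H")
}

#' Scan a sequence for a motif with mismatch tolerance
#'
#' Tests every window of length `span` against the pattern's literal
#' positions (wildcards never mismatch) and returns all windows with at
#' most `max_mismatches` violated literals. Matching is case-insensitive;
#' ambiguity codes and non-standard letters (B, Z, X, ...) mismatch every
#' literal. Overlapping hits are all reported.
#'
#' @param sequence one-letter amino acid string.
#' @param pattern a `motif_pattern`.
#' @param max_mismatches maximum violated literal positions (default 0).
#' @param seq_id identifier recorded in the hits.
#' @return data frame with `seq_id`, `start`, `end` (1-based, inclusive),
#'   `mismatches`, `matched_span`, sorted by `start`.
#' @export
scan_motif <- function(sequence, pattern, max_mismatches = 0L,
                       seq_id = "seq") {
  stopifnot(inherits(pattern, "motif_pattern"), max_mismatches >= 0L)
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      matched_span = character(0), stringsAsFactors = FALSE)
  s <- toupper(sequence)
  n <- nchar(s)
  span <- pattern$span
  if (n < span) return(empty)
  chars <- strsplit(s, "")[[1]]
  n_win <- n - span + 1L
  # vectorised over windows: one comparison sweep per literal position
  mm <- integer(n_win)
  for (off in pattern$literal_pos) {
    mm <- mm + (chars[seq.int(off, off + n_win - 1L)] !=
                  pattern$template[off])
  }
  starts <- which(mm <= max_mismatches)
  if (length(starts) == 0L) return(empty)
  data.frame(seq_id = seq_id, start = starts,
             end = starts + span - 1L, mismatches = mm[starts],
             matched_span = substring(s, starts, starts + span - 1L),
             stringsAsFactors = FALSE)
}

#' Classify a sequence as a glucosamine kinase
#'
#' A sequence is called a family member when it carries at least one full
#' (mismatch-free) signature hit preceded by a catalytic-loop hit at a
#' sequence separation within `spacing` (start-to-start, in residues). In
#' SjGlcNK the catalytic motif starts at residue 300 and the signature at
#' 405, a gap of 105; the default window 60-160 brackets that gap while
#' tolerating family-scale indel variation. Set `require_catalytic =
#' FALSE` to call on the signature alone.
#'
#' @param sequence one-letter string.
#' @param signature signature `motif_pattern`
#'   (default [glcnk_signature_pattern()]).
#' @param catalytic catalytic-loop `motif_pattern`
#'   (default [glcnk_catalytic_pattern()]).
#' @param spacing numeric length-2 vector: allowed (min, max) gap between
#'   catalytic and signature start positions.
#' @param max_mismatches mismatch tolerance used for reporting signature
#'   hits (the family call itself requires a full hit).
#' @param require_catalytic require the catalytic motif and spacing rule?
#' @param seq_id identifier for the hit tables.
#' @return object of class `family_call`: `seq_id`, `signature_hits`,
#'   `catalytic_hits` (data frames), `is_glcnk`, `rationale`.
#' @export
classify_glcnk <- function(sequence,
                           signature = glcnk_signature_pattern(),
                           catalytic = glcnk_catalytic_pattern(),
                           spacing = c(60, 160),
                           max_mismatches = 0L,
                           require_catalytic = TRUE,
                           seq_id = "seq") {
  sig_hits <- scan_motif(sequence, signature,
                         max_mismatches = max(max_mismatches, 0L),
                         seq_id = seq_id)
  cat_hits <- scan_motif(sequence, catalytic, max_mismatches = 0L,
                         seq_id = seq_id)
  full_sig <- sig_hits$start[sig_hits$mismatches == 0L]
  if (length(full_sig) == 0L) {
    is_glcnk <- FALSE
    rationale <- if (nrow(sig_hits)) {
      sprintf("no full signature hit (best has %d mismatch(es))",
              min(sig_hits$mismatches))
    } else "no signature hit"
  } else if (!require_catalytic) {
    is_glcnk <- TRUE
    rationale <- sprintf("full signature hit at %d (catalytic rule disabled)",
                         full_sig[1])
  } else if (nrow(cat_hits) == 0L) {
    is_glcnk <- FALSE
    rationale <- "signature present but no catalytic-loop motif"
  } else {
    gaps <- outer(full_sig, cat_hits$start, "-")  # signature - catalytic
    ok <- which(gaps >= spacing[1] & gaps <= spacing[2], arr.ind = TRUE)
    if (nrow(ok)) {
      is_glcnk <- TRUE
      i <- ok[1, 1]; j <- ok[1, 2]
      rationale <- sprintf(
        "signature at %d with catalytic motif at %d (gap %d in [%g, %g])",
        full_sig[i], cat_hits$start[j], gaps[i, j], spacing[1], spacing[2])
    } else {
      is_glcnk <- FALSE
      rationale <- sprintf(
        "both motifs present but no catalytic/signature gap in [%g, %g]",
        spacing[1], spacing[2])
    }
  }
  structure(list(seq_id = seq_id, signature_hits = sig_hits,
                 catalytic_hits = cat_hits, is_glcnk = is_glcnk,
                 rationale = rationale),
            class = "family_call")
}

#' @export
print.family_call <- function(x, ...) {
  cat(sprintf("<family_call> %s: %s (%s)\n", x$seq_id,
              if (x$is_glcnk) "GlcN kinase" else "not a GlcN kinase",
              x$rationale))
  invisible(x)
}

#' Classify every sequence in a FASTA file
#'
#' @param fasta path to a FASTA file.
#' @inheritParams classify_glcnk
#' @return data frame with one row per record (input order): `seq_id`,
#'   `length`, `n_signature_hits`, `best_signature_mismatches`,
#'   `signature_start` (first full hit, NA otherwise), `n_catalytic_hits`,
#'   `catalytic_start`, `is_glcnk`, `rationale`.
#' @export
scan_fasta <- function(fasta, signature = glcnk_signature_pattern(),
                       catalytic = glcnk_catalytic_pattern(),
                       spacing = c(60, 160), max_mismatches = 0L,
                       require_catalytic = TRUE) {
  seqs <- read_fasta_seqs(fasta)
  rows <- lapply(seq_along(seqs), function(i) {
    fc <- classify_glcnk(seqs[[i]], signature, catalytic, spacing,
                         max_mismatches, require_catalytic,
                         seq_id = names(seqs)[i])
    full <- fc$signature_hits[fc$signature_hits$mismatches == 0L, ,
                              drop = FALSE]
    data.frame(
      seq_id = fc$seq_id, length = nchar(seqs[[i]]),
      n_signature_hits = nrow(fc$signature_hits),
      best_signature_mismatches = if (nrow(fc$signature_hits))
        min(fc$signature_hits$mismatches) else NA_integer_,
      signature_start = if (nrow(full)) full$start[1] else NA_integer_,
      n_catalytic_hits = nrow(fc$catalytic_hits),
      catalytic_start = if (nrow(fc$catalytic_hits))
        fc$catalytic_hits$start[1] else NA_integer_,
      is_glcnk = fc$is_glcnk, rationale = fc$rationale,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-column conservation of an alignment
#'
#' Fraction of (non-gap) sequences carrying the modal residue in each
#' column — a simple conservation surrogate for colouring alignments.
#'
#' @param alignment character vector (>= 2) of equal-length aligned
#'   sequences; `-` and `.` are gaps.
#' @return numeric vector of per-column modal fractions in
#'   `[1/n_sequences, 1]`; fully gapped columns are `NA`.
#' @export
column_conservation <- function(alignment) {
  if (length(alignment) < 2L)
    stop("column_conservation: need >= 2 sequences")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("column_conservation: sequences must have equal length")
  M <- do.call(rbind, strsplit(toupper(alignment), ""))
  apply(M, 2, function(col) {
    col <- col[!col %in% c("-", ".")]
    if (length(col) == 0L) return(NA_real_)
    max(table(col)) / length(col)
  })
}
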