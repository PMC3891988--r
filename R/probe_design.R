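# Intrinsic probe filters and one-probe-per-gene selection.
#
# A candidate is a 60-mer window of the transcript, scored on base
# composition (GC fraction), simple-repeat content (longest mono- or
# dinucleotide tandem run), self-complementarity (longest hairpin stem
# proxy), and distance to the 3' terminus. Filters mirror standard
# long-oligo design rules: GC between 40 and 60 percent inclusive, no
# simple repeat of 6 nt or more, probes confined to the 3'-proximal window.

#' Probe design parameters
#'
#' @param probe_len probe length in nt (default 60).
#' @param gc_min,gc_max inclusive GC-fraction bounds (defaults 0.40, 0.60).
#' @param max_repeat longest tolerated mono-/dinucleotide tandem run in nt
#'   (default 5: a run of 6 or more fails).
#' @param window 3'-terminal design window in nt (default 1200).
#' @param selfcomp_max longest tolerated self-complementary segment in nt
#'   (default 15).
#' @param step stride between successive candidate start positions
#'   (default 1 = exhaustive).
#' @return list of class `design_params`.
#' @export
design_params <- function(probe_len = 60L, gc_min = 0.40, gc_max = 0.60,
                          max_repeat = 5L, window = 1200L,
                          selfcomp_max = 15L, step = 1L) {
  stopifnot(probe_len >= 1L, gc_min >= 0, gc_max <= 1, gc_min < gc_max,
            max_repeat >= 1L, window >= probe_len, step >= 1L)
  structure(list(probe_len = as.integer(probe_len), gc_min = gc_min,
                 gc_max = gc_max, max_repeat = as.integer(max_repeat),
                 window = as.integer(window),
                 selfcomp_max = as.integer(selfcomp_max),
                 step = as.integer(step)),
            class = "design_params")
}

#' GC fraction of a DNA sequence
#'
#' @param seq character vector of DNA strings over `{A,C,G,T}` (N is an
#'   error: a window containing N carries no defined composition and is
#'   discarded upstream).
#' @return numeric vector, `(#G + #C) / length`.
#' @export
gc_fraction <- function(seq) {
  if (any(nchar(seq) == 0L)) stop("empty sequence")
  check_dna(seq, allow_n = FALSE)
  gc <- nchar(gsub("[AT]", "", seq))
  gc / nchar(seq)
}

#' Longest simple-repeat run
#'
#' Maximum length, in nucleotides, over (a) homopolymer runs and (b) tandem
#' dinucleotide repeats (period 2, the two letters distinct). `"AAAAAA"`
#' scores 6; five `"AT"` units score 10.
#'
#' @param seq character vector of DNA strings.
#' @return integer vector of run lengths in nt.
#' @export
max_repeat_run <- function(seq) {
  vapply(seq, function(s) {
    x <- strsplit(s, "")[[1]]
    n <- length(x)
    if (n == 0L) stop("empty sequence")
    best <- max(rle(x)$lengths)
    if (n >= 3L) {
      # period-2 stretches: positions where x[i] == x[i-2]
      d <- x[3:n] == x[1:(n - 2L)]
      r <- rle(d)
      ends <- cumsum(r$lengths)
      for (k in seq_along(r$lengths)) {
        if (!r$values[k]) next
        start <- ends[k] - r$lengths[k] + 1L   # index into d
        if (x[start] != x[start + 1L]) {       # distinct alternating letters
          best <- max(best, r$lengths[k] + 2L)
        }
      }
    }
    as.integer(best)
  }, integer(1), USE.NAMES = FALSE)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Self-complementarity score (hairpin-stem proxy)
#'
#' Length of the longest contiguous segment whose reverse complement also
#' occurs in the sequence. A palindromic segment (its own reverse
#' complement) counts: it can fold back on itself. Homopolymers score 0
#' because the complement run never occurs.
#'
#' Computed by binary search on the length of the longest common substring
#' between the sequence and its reverse complement (common-substring
#' existence is monotone in length).
#'
#' @param seq character vector of DNA strings over `{A,C,G,T}`.
#' @return integer vector of stem lengths in nt.
#' @export
self_complementarity <- function(seq) {
  check_dna(seq, allow_n = FALSE)
  rc <- revcomp(seq)
  vapply(seq_along(seq), function(i) {
    s <- seq[i]; r <- rc[i]; n <- nchar(s)
    has_common <- function(k) {
      a <- unique(substring(s, 1:(n - k + 1L), k:n))
      b <- substring(r, 1:(n - k + 1L), k:n)
      any(b %in% a)
    }
    lo <- 0L; hi <- n
    while (lo < hi) {
      mid <- as.integer(ceiling((lo + hi) / 2))
      if (has_common(mid)) lo <- mid else hi <- mid - 1L
    }
    lo
  }, integer(1), USE.NAMES = FALSE)
}

# Score one candidate window; returns the verdict of the FIRST failing
# filter in fixed order (fail_N, fail_window, fail_gc, fail_repeat,
# fail_selfcomp), or "pass".
score_candidate <- function(seq, dist_3prime, p) {
  if (grepl("N", seq, fixed = TRUE)) {
    return(list(gc = NA_real_, run = NA_integer_, sc = NA_integer_,
                verdict = "fail_N"))
  }
  gc <- gc_fraction(seq)
  run <- max_repeat_run(seq)
  sc <- self_complementarity(seq)
  verdict <- if (dist_3prime > p$window - 1L) "fail_window"
    else if (gc < p$gc_min || gc > p$gc_max) "fail_gc"
    else if (run > p$max_repeat) "fail_repeat"
    else if (sc > p$selfcomp_max) "fail_selfcomp"
    else "pass"
  list(gc = gc, run = run, sc = sc, verdict = verdict)
}

#' Enumerate scored probe candidates for one transcript
#'
#' One candidate per start position (at stride `step`) whose final base
#' lies within the 3'-terminal design window. Every candidate carries all
#' metric fields and a verdict: the first failing filter in the fixed order
#' N-content, window, GC, repeat, self-complementarity, else `pass`.
#'
#' @param transcript one-row [transcript_set()] (or list with `gene_id`,
#'   `transcript_id`, `sequence`).
#' @param params [design_params()].
#' @return data.frame of candidates (zero rows, with a warning, if the
#'   transcript is shorter than the probe length).
#' @export
enumerate_candidates <- function(transcript, params = design_params()) {
  p <- params
  seq <- toupper(transcript$sequence[1])
  gid <- transcript$gene_id[1]
  len <- nchar(seq)
  empty <- data.frame(probe_id = character(), gene_id = character(),
                      start = integer(), end = integer(),
                      sequence = character(), gc_fraction = numeric(),
                      max_repeat_run = integer(),
                      self_comp_score = integer(), dist_3prime = integer(),
                      verdict = character(), stringsAsFactors = FALSE)
  if (len < p$probe_len) {
    warning("transcript ", gid, " too short for any probe (", len, " nt)")
    return(empty)
  }
  # probe 3' end must land in the final `window` nt
  s_min <- max(1L, len - p$window - p$probe_len + 2L)
  starts <- seq.int(s_min, len - p$probe_len + 1L, by = p$step)
  ends <- starts + p$probe_len - 1L
  seqs <- substring(seq, starts, ends)
  scored <- lapply(seq_along(starts), function(i) {
    score_candidate(seqs[i], len - ends[i], p)
  })
  data.frame(
    probe_id = sprintf("%s_%d", gid, starts),
    gene_id = gid,
    start = starts, end = ends, sequence = seqs,
    gc_fraction = vapply(scored, `[[`, numeric(1), "gc"),
    max_repeat_run = vapply(scored, `[[`, integer(1), "run"),
    self_comp_score = vapply(scored, `[[`, integer(1), "sc"),
    dist_3prime = len - ends,
    verdict = vapply(scored, `[[`, character(1), "verdict"),
    stringsAsFactors = FALSE)
}

#' Select one probe per gene among passing candidates
#'
#' Deterministic rule: the passing candidate closest to the 3' terminus;
#' ties broken by GC fraction closest to 0.50, then by smallest start.
#'
#' @param cands candidate data.frame from [enumerate_candidates()] (one
#'   gene).
#' @return one-row data.frame, or `NULL` if no candidate passes.
#' @export
select_probe <- function(cands) {
  ok <- cands[cands$verdict == "pass", , drop = FALSE]
  if (nrow(ok) == 0L) return(NULL)
  ord <- order(ok$dist_3prime, abs(ok$gc_fraction - 0.5), ok$start)
  ok[ord[1], , drop = FALSE]
}

#' Design one probe per gene for a transcript set
#'
#' @param transcripts [transcript_set()].
#' @param params [design_params()].
#' @return list with `probes` (selected probes, one row per covered gene),
#'   `candidates` (all scored candidates) and `coverage` (fraction of genes
#'   with a selected probe).
#' @export
design_probes <- function(transcripts, params = design_params()) {
  cand_list <- lapply(seq_len(nrow(transcripts)), function(i) {
    enumerate_candidates(transcripts[i, , drop = FALSE], params)
  })
  cands <- do.call(rbind, cand_list)
  sel <- do.call(rbind, lapply(cand_list, select_probe))
  if (is.null(sel)) sel <- cands[0, , drop = FALSE]
  list(probes = sel, candidates = cands,
       coverage = nrow(sel) / nrow(transcripts))
}
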