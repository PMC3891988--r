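# Cross-genome specificity: search each probe against two genomes with a
# seed-and-extend matcher, call per-genome hit status (none / unique /
# multiple), and assign one of seven cross-genome groups.
#
# Group table (japonica status, indica status):
#   A (unique, unique)    B (unique, none)     C (none, unique)
#   D (unique, multiple)  E (multiple, unique) F (multiple, none)
#   G (multiple, multiple)
# (none, none) and (none, multiple) have no group and map to UNASSIGNED.
# Genome-represented sets follow: japonica {A,B,D,E,F,G}, indica
# {A,C,D,E,G}.

GROUP_TABLE <- data.frame(
  status_j = rep(c("none", "unique", "multiple"), each = 3),
  status_i = rep(c("none", "unique", "multiple"), times = 3),
  group = c("UNASSIGNED", "C", "UNASSIGNED",
            "B", "A", "D",
            "F", "E", "G"),
  stringsAsFactors = FALSE)

JAPONICA_GROUPS <- c("A", "B", "D", "E", "F", "G")
INDICA_GROUPS <- c("A", "C", "D", "E", "G")

#' Genome-matcher parameters
#'
#' The matcher is ungapped seed-and-extend: genome windows sharing at least
#' one exact `seed_len`-mer with the probe are compared end-to-end and kept
#' when the identical-base count reaches `min_matches`. `seed_len = 1`
#' disables seeding (every offset evaluated) and is exact. The default 47
#' of 60 (~78% identity) follows common cross-hybridization screening
#' practice for long oligos.
#'
#' @param seed_len exact-match seed length in nt (default 16).
#' @param min_matches minimum identical bases out of the probe length
#'   (default 47).
#' @param both_strands search the reverse strand too (default TRUE).
#' @return list of class `match_params`.
#' @export
match_params <- function(seed_len = 16L, min_matches = 47L,
                         both_strands = TRUE) {
  stopifnot(seed_len >= 1L, min_matches >= 1L)
  structure(list(seed_len = as.integer(seed_len),
                 min_matches = as.integer(min_matches),
                 both_strands = isTRUE(both_strands)),
            class = "match_params")
}

#' Build a genome record
#'
#' @param genome_id identifier.
#' @param contigs named character vector of contig sequences, or data.frame
#'   with `id`/`sequence` columns (as from [read_fasta()]).
#' @param subspecies label.
#' @return list of class `genome_record`.
#' @export
genome_record <- function(genome_id, contigs, subspecies = "other") {
  if (is.data.frame(contigs)) {
    contigs <- stats::setNames(contigs$sequence, contigs$id)
  }
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must have unique names")
  }
  contigs <- toupper(contigs)
  check_dna(contigs)
  if (sum(nchar(contigs)) < 1L) stop("empty genome")
  structure(list(genome_id = genome_id, subspecies = subspecies,
                 contigs = contigs), class = "genome_record")
}

# Identity counts of `probe` (integer-coded) against contig (integer-coded)
# at the given 1-based offsets: ungapped end-to-end comparison.
match_counts_at <- function(gint, pint, offsets) {
  plen <- length(pint)
  m <- integer(length(offsets))
  for (k in seq_len(plen)) {
    m <- m + (gint[offsets + k - 1L] == pint[k])
  }
  m
}

# Candidate window offsets in one contig sharing an exact seed with probe.
seed_offsets <- function(contig, probe, seed_len, plen) {
  glen <- nchar(contig)
  if (glen < plen) return(integer())
  if (seed_len == 1L) return(seq_len(glen - plen + 1L))
  n_seeds <- plen - seed_len + 1L
  offs <- integer()
  subj <- Biostrings::DNAString(contig)
  for (k in seq_len(n_seeds)) {
    seed <- substr(probe, k, k + seed_len - 1L)
    hits <- Biostrings::start(
      Biostrings::matchPattern(seed, subj, fixed = TRUE))
    if (length(hits)) offs <- c(offs, hits - k + 1L)
  }
  offs <- unique(offs)
  offs[offs >= 1L & offs <= glen - plen + 1L]
}

# Merge accepted windows on one contig+strand lying within `gap` nt of each
# other, keeping the best-matching position (ties: leftmost).
merge_windows <- function(df, gap) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$position), , drop = FALSE]
  cluster <- cumsum(c(1L, diff(df$position) > gap))
  keep <- unlist(lapply(split(seq_len(nrow(df)), cluster), function(idx) {
    idx[which.max(df$matches[idx])]
  }), use.names = FALSE)
  df[sort(keep), , drop = FALSE]
}

#' Find genomic hits of a probe
#'
#' Every genome window (on either strand when `both_strands`) sharing at
#' least one exact seed with the probe is scored by ungapped end-to-end
#' comparison; windows with at least `min_matches` identical bases are
#' reported. Overlapping accepted windows on the same contig and strand
#' within one probe length of each other are merged into a single hit at
#' the best-matching position, so one genomic locus is never counted twice.
#'
#' A minus-strand hit means the reverse complement of the probe matches the
#' forward contig; `position` is always the forward-strand window start.
#'
#' @param probe probe sequence (no N).
#' @param genome [genome_record()].
#' @param params [match_params()].
#' @return data.frame with columns `contig_id`, `position`, `strand`,
#'   `matches`.
#' @export
find_hits <- function(probe, genome, params = match_params()) {
  probe <- toupper(probe)
  if (grepl("N", probe, fixed = TRUE)) stop("probe contains N")
  check_dna(probe, allow_n = FALSE, what = "probe")
  plen <- nchar(probe)
  queries <- list(`+` = probe)
  if (params$both_strands) queries$`-` <- revcomp(probe)
  out <- list()
  for (cid in names(genome$contigs)) {
    contig <- genome$contigs[[cid]]
    gint <- utf8ToInt(contig)
    for (strand in names(queries)) {
      q <- queries[[strand]]
      offs <- seed_offsets(contig, q, params$seed_len, plen)
      if (!length(offs)) next
      m <- match_counts_at(gint, utf8ToInt(q), offs)
      keep <- m >= params$min_matches
      if (!any(keep)) next
      df <- data.frame(contig_id = cid, position = offs[keep],
                       strand = strand, matches = m[keep],
                       stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- merge_windows(df, gap = plen - 1L)
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(), position = integer(),
                      strand = character(), matches = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res[order(res$contig_id, res$position, res$strand), , drop = FALSE]
}

#' Hit status from a hit list or count
#'
#' @param hits data.frame from [find_hits()], or a nonnegative count.
#' @return `"none"`, `"unique"` or `"multiple"`.
#' @export
hit_status <- function(hits) {
  n <- if (is.data.frame(hits)) nrow(hits) else as.integer(hits)
  if (n == 0L) "none" else if (n == 1L) "unique" else "multiple"
}

#' Cross-genome specificity group
#'
#' Total over all nine status pairs; pairs hitting neither genome, or only
#' hitting the second genome multiply, have no group and return
#' `"UNASSIGNED"`.
#'
#' @param status_j,status_i hit status in the first (japonica-like) and
#'   second (indica-like) genome.
#' @return one of `"A"`..`"G"` or `"UNASSIGNED"`.
#' @export
classify_group <- function(status_j, status_i) {
  status_j <- match.arg(status_j, c("none", "unique", "multiple"))
  status_i <- match.arg(status_i, c("none", "unique", "multiple"))
  GROUP_TABLE$group[GROUP_TABLE$status_j == status_j &
                      GROUP_TABLE$status_i == status_i]
}

#' Classify a probe set against two genomes
#'
#' @param probes named character vector of probe sequences, or data.frame
#'   with `probe_id` and `sequence`.
#' @param genome_j,genome_i the two [genome_record()]s.
#' @param params [match_params()].
#' @return data.frame with per-genome hit counts, statuses and group.
#' @export
classify_probes <- function(probes, genome_j, genome_i,
                            params = match_params()) {
  if (is.data.frame(probes)) {
    probes <- stats::setNames(probes$sequence, probes$probe_id)
  }
  rows <- lapply(names(probes), function(pid) {
    hj <- find_hits(probes[[pid]], genome_j, params)
    hi <- find_hits(probes[[pid]], genome_i, params)
    sj <- hit_status(hj); si <- hit_status(hi)
    data.frame(probe_id = pid, hits_j = nrow(hj), hits_i = nrow(hi),
               status_j = sj, status_i = si,
               group = classify_group(sj, si), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-group and per-genome coverage summary
#'
#' @param classifications data.frame from [classify_probes()].
#' @return list with `group_counts` (named vector over A..G, UNASSIGNED),
#'   `japonica` and `indica` represented-probe counts, and `total`.
#' @export
coverage_summary <- function(classifications) {
  lev <- c("A", "B", "C", "D", "E", "F", "G", "UNASSIGNED")
  counts <- table(factor(classifications$group, levels = lev))
  list(group_counts = stats::setNames(as.integer(counts), lev),
       japonica = sum(counts[JAPONICA_GROUPS]),
       indica = sum(counts[INDICA_GROUPS]),
       total = nrow(classifications))
}
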