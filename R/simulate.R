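# Synthetic data with known ground truth: a pair of divergent subspecies
# genomes derived from a common ancestor (with gene duplications and
# losses that create multi-hit and genome-absent probes), and replicate
# one-channel intensity data with planted differential expression.
#
# Intensities follow a log-normal model: per-probe baseline log2 level
# drawn once, replicate noise added on the log2 scale, then
# exponentiated; the reported foreground is signal plus the background
# draw, so background subtraction in the analysis recovers the signal.

#' Simulation configuration
#'
#' Defaults emulate the validation study design this toolkit targets:
#' five technical arrays per tissue, a planted effect of 2 log2 units with
#' replicate noise of 0.3 log2 units, and two genomes at 1% sequence
#' divergence with a modest rate of gene duplication and loss.
#'
#' @param seed RNG seed; the same seed gives byte-identical outputs.
#' @param n_genes number of ancestor genes.
#' @param gene_len gene length in nt.
#' @param divergence per-base substitution probability applied
#'   independently to each genome copy.
#' @param dup_fraction fraction of genes duplicated within one genome
#'   (half in each genome; creates multi-hit probes).
#' @param absent_fraction fraction of genes deleted from one genome (half
#'   from each; creates genome-absent probes).
#' @param n_arrays_per_tissue technical replicates per tissue.
#' @param de_fraction fraction of probes with a planted expression effect.
#' @param effect_log2 planted log2 fold (applied in tissue A, either sign).
#' @param noise_sd log2-scale replicate noise standard deviation.
#' @param floor intensity floor used downstream.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 50L, gene_len = 600L,
                       divergence = 0.01, dup_fraction = 0.05,
                       absent_fraction = 0.10, n_arrays_per_tissue = 5L,
                       de_fraction = 0.10, effect_log2 = 2,
                       noise_sd = 0.3, floor = 1) {
  stopifnot(n_genes >= 1L, gene_len >= 60L,
            divergence >= 0, divergence <= 1,
            dup_fraction >= 0, dup_fraction <= 1,
            absent_fraction >= 0, absent_fraction <= 1,
            dup_fraction + absent_fraction <= 1,
            n_arrays_per_tissue >= 1L, de_fraction >= 0, de_fraction <= 1,
            noise_sd >= 0)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_len = as.integer(gene_len), divergence = divergence,
                 dup_fraction = dup_fraction,
                 absent_fraction = absent_fraction,
                 n_arrays_per_tissue = as.integer(n_arrays_per_tissue),
                 de_fraction = de_fraction, effect_log2 = effect_log2,
                 noise_sd = noise_sd, floor = floor),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(x)) < rate)
  for (i in hit) {
    x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  }
  paste(x, collapse = "")
}

#' Simulate a divergent genome pair with known probe-level truth
#'
#' Ancestor genes are mutated independently into a japonica-like and an
#' indica-like genome. A `dup_fraction` of genes is then duplicated
#' verbatim within one genome (alternating genomes), and an
#' `absent_fraction` deleted from one genome (alternating), producing the
#' full range of cross-genome hit-status pairs. Divergence is applied
#' before duplication, so within-genome paralogs are identical copies —
#' a deliberate simplification guaranteeing multi-hit status at any
#' identity threshold. Genes are laid out on a single contig per genome
#' separated by random 100-nt spacers.
#'
#' Transcripts are the japonica-side gene sequences (or the indica copy
#' for genes absent from japonica), mirroring a design pipeline that
#' starts from one subspecies' mRNA models.
#'
#' @param config [sim_config()].
#' @return list with `genome_j`, `genome_i` ([genome_record()]s),
#'   `transcripts` ([transcript_set()]), and `truth` (per gene: copies and
#'   expected hit-status pair and group at exact-match thresholds).
#' @export
simulate_genomes <- function(config = sim_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    anc <- vapply(genes, function(g) random_dna(cfg$gene_len), character(1))
    seq_j <- vapply(anc, mutate_seq, character(1), rate = cfg$divergence)
    seq_i <- vapply(anc, mutate_seq, character(1), rate = cfg$divergence)
    names(seq_j) <- names(seq_i) <- genes

    n_dup <- round(cfg$dup_fraction * cfg$n_genes)
    n_abs <- round(cfg$absent_fraction * cfg$n_genes)
    shuffled <- sample(genes)
    dup_genes <- utils::head(shuffled, n_dup)
    abs_genes <- utils::head(setdiff(shuffled, dup_genes), n_abs)
    # alternate which genome carries the duplication / suffers the loss
    dup_in_j <- dup_genes[seq_along(dup_genes) %% 2L == 1L]
    dup_in_i <- setdiff(dup_genes, dup_in_j)
    abs_from_i <- abs_genes[seq_along(abs_genes) %% 2L == 1L]
    abs_from_j <- setdiff(abs_genes, abs_from_i)

    copies_j <- stats::setNames(rep(1L, cfg$n_genes), genes)
    copies_i <- copies_j
    copies_j[dup_in_j] <- 2L
    copies_i[dup_in_i] <- 2L
    copies_j[abs_from_j] <- 0L
    copies_i[abs_from_i] <- 0L

    build_contig <- function(seqs, copies) {
      parts <- character()
      for (g in genes) {
        if (copies[g] == 0L) next
        for (k in seq_len(copies[g])) {
          parts <- c(parts, random_dna(100L), seqs[[g]])
        }
      }
      paste(c(parts, random_dna(100L)), collapse = "")
    }
    contig_j <- build_contig(seq_j, copies_j)
    contig_i <- build_contig(seq_i, copies_i)

    status <- function(k) {
      ifelse(k == 0L, "none", ifelse(k == 1L, "unique", "multiple"))
    }
    truth <- data.frame(
      gene_id = genes,
      copies_j = unname(copies_j), copies_i = unname(copies_i),
      status_j = status(unname(copies_j)),
      status_i = status(unname(copies_i)),
      stringsAsFactors = FALSE)
    truth$group <- mapply(classify_group, truth$status_j, truth$status_i)

    tr_seq <- ifelse(copies_j[genes] > 0L, seq_j[genes], seq_i[genes])
    list(
      genome_j = genome_record("sim_japonica", c(chr1 = contig_j),
                               subspecies = "japonica"),
      genome_i = genome_record("sim_indica", c(chr1 = contig_i),
                               subspecies = "indica"),
      transcripts = transcript_set(transcript_id = genes,
                                   gene_id = genes,
                                   sequence = unname(tr_seq),
                                   subspecies = "japonica"),
      truth = truth)
  })
}

#' Simulate replicate one-channel arrays with planted effects
#'
#' Per probe a baseline log2 level is drawn from Normal(10, 1.5). A
#' `de_fraction` of probes receives a planted shift of `±effect_log2`
#' (random sign) in tissue A. Replicate arrays add Normal(0, noise_sd) on
#' the log2 scale; the linear signal is then added to a per-spot
#' background draw from Normal(100, 10) truncated at 0, and all flags are
#' `good`.
#'
#' @param config [sim_config()].
#' @param probe_ids character vector of probe identifiers.
#' @param tissues the two tissue labels (default shoot/root).
#' @return list with `arrays` (long spot table usable by
#'   [median_scale()]) and `truth` (per probe: `is_de`, `direction`,
#'   `effect_log2`, baseline).
#' @export
simulate_arrays <- function(config = sim_config(), probe_ids,
                            tissues = c("shoot", "root")) {
  cfg <- config
  stopifnot(length(tissues) == 2L, length(probe_ids) >= 1L)
  with_seed(cfg$seed + 1L, {
    np <- length(probe_ids)
    baseline <- stats::rnorm(np, mean = 10, sd = 1.5)
    is_de <- stats::runif(np) < cfg$de_fraction
    sign_de <- ifelse(stats::runif(np) < 0.5, 1, -1)
    effect <- ifelse(is_de, sign_de * cfg$effect_log2, 0)

    n_rep <- cfg$n_arrays_per_tissue
    rows <- vector("list", 2L * n_rep)
    idx <- 0L
    for (t in seq_along(tissues)) {
      shift <- if (t == 1L) effect else 0
      for (r in seq_len(n_rep)) {
        idx <- idx + 1L
        lg <- baseline + shift + stats::rnorm(np, sd = cfg$noise_sd)
        bg <- pmax(stats::rnorm(np, mean = 100, sd = 10), 0)
        fg <- 2^lg + bg
        rows[[idx]] <- data.frame(
          array_id = sprintf("%s_%02d", tissues[t], r),
          tissue = tissues[t], probe_id = probe_ids,
          foreground = fg, background = bg, flag = "good",
          stringsAsFactors = FALSE)
      }
    }
    truth <- data.frame(probe_id = probe_ids, is_de = is_de,
                        direction = ifelse(!is_de, "ns",
                                    ifelse(effect > 0, "up", "down")),
                        effect_log2 = effect, baseline_log2 = baseline,
                        stringsAsFactors = FALSE)
    list(arrays = do.call(rbind, rows), truth = truth)
  })
}
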