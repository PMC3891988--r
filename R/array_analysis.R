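# One-channel intensity pipeline: flag/SNR detection calls, background
# subtraction with a floor, median-scaling normalization, technical
# replicate QC, error-weighted log2 ratios with Welch tests, DE calling
# and tissue-specificity calling.

SPOT_FLAGS <- c("good", "bad", "not_found", "empty")

#' Read a spot-level intensity table
#'
#' GPR-like TSV with columns `probe_id`, `foreground` (or `F_median`),
#' `background` (or `B_median`), `flag`, and optionally `snr`. When `snr`
#' is absent it is computed as foreground/background.
#'
#' @param path file path.
#' @return data.frame with canonical column names.
#' @export
read_spot_table <- function(path) {
  df <- read_tsv_plain(path)
  nm <- names(df)
  nm[nm == "F_median"] <- "foreground"
  nm[nm == "B_median"] <- "background"
  names(df) <- nm
  need <- c("probe_id", "foreground", "background", "flag")
  if (!all(need %in% names(df))) {
    stop("spot table ", path, " missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id in ", path)
  }
  bad <- setdiff(unique(df$flag), SPOT_FLAGS)
  if (length(bad)) stop("unknown flag value(s): ", paste(bad, collapse = ", "))
  if (any(df$foreground < 0) || any(df$background < 0)) {
    stop("negative intensity in ", path)
  }
  if (!"snr" %in% names(df)) {
    df$snr <- ifelse(df$background > 0, df$foreground / df$background, Inf)
  }
  df[, c("probe_id", "foreground", "background", "flag", "snr")]
}

#' Spot detection call
#'
#' A spot is detected when its flag is `good` and its signal-to-noise
#' ratio (foreground/background) reaches `snr_min`. A zero background with
#' a good flag counts as detected.
#'
#' @param foreground,background intensities (vectors).
#' @param flag spot flags.
#' @param snr_min detection threshold on foreground/background (default 2).
#' @return logical vector.
#' @export
detection_call <- function(foreground, background, flag, snr_min = 2) {
  snr <- ifelse(background > 0, foreground / background, Inf)
  flag == "good" & snr >= snr_min
}

#' Median-scaling normalization into an expression matrix
#'
#' Per spot, the working value is `max(foreground - background, floor)`.
#' Each array is rescaled multiplicatively so that its median over
#' detected spots equals the global reference median (the median of the
#' per-array detected-spot medians).
#'
#' @param arrays long data.frame with columns `array_id`, `tissue`,
#'   `probe_id`, `foreground`, `background`, `flag` (and optional `snr`),
#'   e.g. from [simulate_arrays()] or rbind-ed [read_spot_table()]s.
#' @param snr_min detection threshold (see [detection_call()]).
#' @param floor background-subtracted intensity floor (default 1).
#' @return list of class `expression_matrix`: `values` (probes x arrays,
#'   normalized linear scale), `detected` (logical matrix), `tissue`
#'   (per-array labels), `floor`.
#' @export
median_scale <- function(arrays, snr_min = 2, floor = 1) {
  stopifnot(all(c("array_id", "tissue", "probe_id", "foreground",
                  "background", "flag") %in% names(arrays)))
  aids <- unique(arrays$array_id)
  pids <- unique(arrays$probe_id)
  val <- matrix(NA_real_, nrow = length(pids), ncol = length(aids),
                dimnames = list(pids, aids))
  det <- matrix(FALSE, nrow = length(pids), ncol = length(aids),
                dimnames = list(pids, aids))
  tissue <- character(length(aids)); names(tissue) <- aids
  for (a in aids) {
    sub <- arrays[arrays$array_id == a, , drop = FALSE]
    tissue[a] <- as.character(sub$tissue[1])
    v <- pmax(sub$foreground - sub$background, floor)
    d <- detection_call(sub$foreground, sub$background, sub$flag, snr_min)
    val[sub$probe_id, a] <- v
    det[sub$probe_id, a] <- d
  }
  med <- vapply(seq_along(aids), function(j) {
    dv <- val[det[, j], j]
    if (!length(dv)) stop("array ", aids[j], " has no detected spots")
    stats::median(dv)
  }, numeric(1))
  ref <- stats::median(med)
  for (j in seq_along(aids)) val[, j] <- val[, j] * (ref / med[j])
  structure(list(values = val, detected = det, tissue = tissue,
                 floor = floor), class = "expression_matrix")
}

#' Pairwise technical-replicate Pearson correlation
#'
#' Pearson correlation of log2 normalized intensities over spots detected
#' in both arrays of each pair. Entries with fewer than 3 common detected
#' spots are `NA`.
#'
#' @param em [median_scale()] result.
#' @return symmetric arrays x arrays matrix with unit diagonal.
#' @export
replicate_correlation <- function(em) {
  n <- ncol(em$values)
  if (n < 2L) stop("need at least 2 arrays")
  lg <- log2(em$values)
  r <- diag(1, n)
  dimnames(r) <- list(colnames(em$values), colnames(em$values))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      common <- em$detected[, i] & em$detected[, j]
      r[i, j] <- r[j, i] <- if (sum(common) < 3L) NA_real_ else
        stats::cor(lg[common, i], lg[common, j])
    }
  }
  r
}

#' Average technical replicates of one tissue
#'
#' Per-probe mean and standard error of log2 normalized intensity over the
#' arrays of `tissue` in which the spot is detected, with the detection
#' count. Probes detected in no array of the tissue have `NA` mean/SE and
#' `n_detected` 0.
#'
#' @param em [median_scale()] result.
#' @param tissue tissue label.
#' @return data.frame with `probe_id`, `mean_log2`, `se_log2`,
#'   `n_detected`, `n_arrays`.
#' @export
average_replicates <- function(em, tissue) {
  cols <- which(em$tissue == tissue)
  if (!length(cols)) stop("no arrays with tissue ", tissue)
  lg <- log2(em$values[, cols, drop = FALSE])
  det <- em$detected[, cols, drop = FALSE]
  n_det <- rowSums(det)
  mean_l <- se_l <- rep(NA_real_, nrow(lg))
  for (i in which(n_det > 0L)) {
    x <- lg[i, det[i, ]]
    mean_l[i] <- mean(x)
    se_l[i] <- if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  }
  data.frame(probe_id = rownames(lg), mean_log2 = mean_l, se_log2 = se_l,
             n_detected = n_det, n_arrays = length(cols),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Welch two-sample p on log2 replicate values, robust to the degenerate
# (near-)zero-variance case (then 0 if means differ, 1 if not).
welch_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  tryCatch(stats::t.test(x, y)$p.value,
           error = function(e) if (mean(x) != mean(y)) 0 else 1)
}

#' Error-weighted log2 ratio and Welch test per probe
#'
#' For probes detected in both tissues the log2 ratio is the
#' inverse-variance-weighted mean of all pairwise differences
#' `log2(a_i) - log2(b_j)`; with equal per-pair weights this equals
#' `mean(log2 A) - mean(log2 B)`, which is used. The p-value is a Welch
#' two-sample t-test on the log2 replicate intensities. Probes detected in
#' only one tissue are compared against the floor's log2 value by a
#' one-sample t-test and flagged `one_sided = TRUE`; probes detected in
#' neither tissue get `NA`s.
#'
#' @param em [median_scale()] result.
#' @param tissue_a,tissue_b contrast labels (ratio is A over B, e.g.
#'   shoot over root).
#' @return data.frame with `probe_id`, `log2_ratio`, `p_value`, `det_a`,
#'   `det_b`, `n_a`, `n_b`, `one_sided`.
#' @export
log2_ratio_ew <- function(em, tissue_a, tissue_b) {
  ca <- which(em$tissue == tissue_a)
  cb <- which(em$tissue == tissue_b)
  if (!length(ca) || !length(cb)) stop("unknown tissue label")
  lg <- log2(em$values)
  lfloor <- log2(em$floor)
  n <- nrow(lg)
  ratio <- p <- rep(NA_real_, n)
  one_sided <- rep(FALSE, n)
  det_a <- rowSums(em$detected[, ca, drop = FALSE])
  det_b <- rowSums(em$detected[, cb, drop = FALSE])
  for (i in seq_len(n)) {
    xa <- lg[i, ca][em$detected[i, ca]]
    xb <- lg[i, cb][em$detected[i, cb]]
    if (det_a[i] > 0L && det_b[i] > 0L) {
      # mean of all pairwise differences == mean(xa) - mean(xb)
      ratio[i] <- mean(xa) - mean(xb)
      p[i] <- welch_p(xa, xb)
    } else if (det_a[i] > 0L || det_b[i] > 0L) {
      x <- if (det_a[i] > 0L) xa else xb
      sgn <- if (det_a[i] > 0L) 1 else -1
      ratio[i] <- sgn * (mean(x) - lfloor)
      one_sided[i] <- TRUE
      p[i] <- if (length(x) < 2L) NA_real_
        else tryCatch(stats::t.test(x, mu = lfloor)$p.value,
                      error = function(e) if (mean(x) != lfloor) 0 else 1)
    }
  }
  data.frame(probe_id = rownames(lg), log2_ratio = ratio, p_value = p,
             det_a = det_a, det_b = det_b,
             n_a = length(ca), n_b = length(cb), one_sided = one_sided,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential-expression calls
#'
#' A probe is called up when `log2_ratio >= lfc_min` (inclusive) and
#' `p_value < alpha` (strict); down symmetrically; `ns` otherwise
#' (including undetected probes with `NA` statistics).
#'
#' @param de data.frame from [log2_ratio_ew()].
#' @param lfc_min log2-ratio threshold (default 1).
#' @param alpha p-value threshold (default 0.05).
#' @param adjust `"none"` (default: raw p-values are thresholded) or
#'   `"BH"` for Benjamini-Hochberg adjusted p-values.
#' @return `de` with added `p_used`, `direction` (`up`/`down`/`ns`) and
#'   `significant` columns.
#' @export
select_de <- function(de, lfc_min = 1, alpha = 0.05, adjust = "none") {
  adjust <- match.arg(adjust, c("none", "BH"))
  p_used <- if (adjust == "BH") stats::p.adjust(de$p_value, "BH")
            else de$p_value
  up <- !is.na(de$log2_ratio) & !is.na(p_used) &
    de$log2_ratio >= lfc_min & p_used < alpha
  down <- !is.na(de$log2_ratio) & !is.na(p_used) &
    de$log2_ratio <= -lfc_min & p_used < alpha
  de$p_used <- p_used
  de$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  de$significant <- up | down
  de
}

#' Tissue-specificity call
#'
#' A probe is A-specific (e.g. shoot-specific) when it is significantly
#' up, detected in at least half (rounded up) of the tissue-A arrays, and
#' detected in no tissue-B array; symmetrically for B-specific. Probes
#' detected anywhere else are `shared`; probes detected nowhere are
#' `undetected`. This detection-based definition is a toolkit convention
#' and is labeled as such in outputs.
#'
#' @param de data.frame from [select_de()].
#' @param label_a,label_b names used for the two specificity labels
#'   (defaults `"shoot_specific"`, `"root_specific"`).
#' @return `de` with an added `specificity` column.
#' @export
call_specific <- function(de, label_a = "shoot_specific",
                          label_b = "root_specific") {
  stopifnot(all(c("direction", "det_a", "det_b", "n_a", "n_b")
                %in% names(de)))
  spec_a <- de$direction == "up" & de$det_a >= ceiling(de$n_a / 2) &
    de$det_b == 0L
  spec_b <- de$direction == "down" & de$det_b >= ceiling(de$n_b / 2) &
    de$det_a == 0L
  detected <- de$det_a + de$det_b > 0L
  de$specificity <- ifelse(spec_a, label_a,
                    ifelse(spec_b, label_b,
                    ifelse(detected, "shared", "undetected")))
  de
}

#' Full one-channel analysis pipeline
#'
#' Normalizes, QCs and tests a set of arrays for a two-tissue contrast.
#'
#' @param arrays long data.frame (see [median_scale()]).
#' @param tissue_a,tissue_b contrast labels.
#' @param snr_min,floor,lfc_min,alpha,adjust passed to the steps.
#' @return list with `em`, `correlation`, `de` (with DE and specificity
#'   calls) and `summary` counts.
#' @export
analyze_arrays <- function(arrays, tissue_a, tissue_b, snr_min = 2,
                           floor = 1, lfc_min = 1, alpha = 0.05,
                           adjust = "none") {
  em <- median_scale(arrays, snr_min = snr_min, floor = floor)
  qc <- replicate_correlation(em)
  de <- log2_ratio_ew(em, tissue_a, tissue_b)
  de <- select_de(de, lfc_min = lfc_min, alpha = alpha, adjust = adjust)
  de <- call_specific(de)
  list(em = em, correlation = qc, de = de,
       summary = c(up = sum(de$direction == "up"),
                   down = sum(de$direction == "down"),
                   ns = sum(de$direction == "ns"),
                   specific_a = sum(de$specificity == "shoot_specific"),
                   specific_b = sum(de$specificity == "root_specific")))
}
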