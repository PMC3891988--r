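make_arrays <- function(values, tissues, bg = 0) {
  # values: probes x arrays matrix of intended background-subtracted
  # intensities; builds the long spot table with constant background
  do.call(rbind, lapply(seq_len(ncol(values)), function(j) {
    data.frame(array_id = colnames(values)[j], tissue = tissues[j],
               probe_id = rownames(values),
               foreground = values[, j] + bg, background = bg,
               flag = "good", stringsAsFactors = FALSE)
  }))
}

pmat <- function(...) {
  m <- cbind(...)
  rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  m
}

test_that("detection_call combines flag and SNR threshold", {
  expect_false(detection_call(3000, 100, "bad"))
  expect_true(detection_call(3000, 100, "good"))
  expect_false(detection_call(150, 100, "good", snr_min = 2))
  expect_true(detection_call(150, 100, "good", snr_min = 1.2))
  expect_true(detection_call(10, 0, "good"))   # zero background
  expect_equal(detection_call(c(300, 10), c(100, 100), c("good", "good")),
               c(TRUE, FALSE))
})

test_that("median_scale equalizes detected-spot medians", {
  set.seed(31)
  v <- pmat(a1 = rlnorm(101, 7, 1), a2 = rlnorm(101, 7, 1))
  v[, 1] <- v[, 1] * 1000 / median(v[, 1])
  v[, 2] <- v[, 2] * 2000 / median(v[, 2])
  em <- median_scale(make_arrays(v, c("s", "s")), snr_min = 0)
  meds <- apply(em$values, 2, median)
  expect_equal(unname(meds), c(1500, 1500))
  # single array: reference is itself, values unchanged (up to floor)
  em1 <- median_scale(make_arrays(v[, 1, drop = FALSE], "s"), snr_min = 0)
  expect_equal(em1$values[, 1], v[, 1])
  # identical arrays: identity
  vv <- pmat(a1 = v[, 1], a2 = v[, 1])
  em2 <- median_scale(make_arrays(vv, c("s", "s")), snr_min = 0)
  expect_equal(em2$values[, 1], em2$values[, 2])
})

test_that("median_scale errors on an array with no detected spots", {
  v <- pmat(a1 = c(300, 400), a2 = c(10, 20))
  arr <- make_arrays(v, c("s", "s"), bg = 100)
  expect_error(median_scale(arr, snr_min = 2), "a2")
})

test_that("normalization invariant holds on random data", {
  set.seed(32)
  for (i in 1:5) {
    n_arr <- sample(2:6, 1)
    v <- matrix(rlnorm(400 * n_arr, 8, 1.2), nrow = 400)
    rownames(v) <- sprintf("p%03d", 1:400)
    colnames(v) <- sprintf("a%d", 1:n_arr)
    em <- median_scale(make_arrays(v, rep("s", n_arr), bg = 50),
                      snr_min = 1.5)
    meds <- vapply(seq_len(n_arr), function(j) {
      median(em$values[em$detected[, j], j])
    }, numeric(1))
    expect_lt(diff(range(meds)) / meds[1], 1e-9)
  }
})

test_that("replicate correlation is 1 for duplicated or rescaled arrays", {
  set.seed(33)
  x <- rlnorm(500, 7, 1)
  v <- pmat(a1 = x, a2 = x, a3 = 2 * x)
  em <- median_scale(make_arrays(v, rep("s", 3)), snr_min = 0)
  r <- replicate_correlation(em)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], 1)  # scaling is a log2 shift
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 3))
})

test_that("replicate correlation matches the additive-noise closed form", {
  # log2 values: probe effect ~ N(10, 1.5), replicate noise sd 0.1
  # => expected Pearson r on log2 scale = var / (var + sd^2)
  cfg <- sim_config(seed = 77, n_arrays_per_tissue = 2, de_fraction = 0,
                    noise_sd = 0.1)
  sim <- simulate_arrays(cfg, probe_ids = sprintf("p%04d", 1:5000))
  em <- median_scale(sim$arrays)
  r <- replicate_correlation(em)
  shoot <- which(em$tissue == "shoot")
  expected <- 1.5^2 / (1.5^2 + 2 * 0.1^2 / 2)  # both replicates noisy
  expect_equal(r[shoot[1], shoot[2]], expected, tolerance = 0.005)
})

test_that("replicate correlation needs 3 common detected spots", {
  v <- pmat(a1 = c(300, 400, 500, 600), a2 = c(10, 10, 350, 650))
  em <- median_scale(make_arrays(v, c("s", "s"), bg = 100), snr_min = 2)
  expect_true(is.na(replicate_correlation(em)[1, 2]))
})

test_that("average_replicates equals a direct recomputation", {
  set.seed(34)
  v <- matrix(rlnorm(50 * 5, 7, 1), nrow = 50,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("a%d", 1:5)))
  em <- median_scale(make_arrays(v, rep("shoot", 5)), snr_min = 0)
  av <- average_replicates(em, "shoot")
  i <- 17
  x <- log2(em$values[i, ])
  expect_equal(av$mean_log2[i], sum(x) / 5)
  expect_equal(av$se_log2[i], sqrt(sum((x - mean(x))^2) / 4) / sqrt(5))
  expect_equal(av$n_detected[i], 5)
  # equal values => SE 0; undetected probe => NA marker
  vv <- pmat(a1 = rep(128, 4), a2 = rep(128, 4))
  vv[2, ] <- 0.0001
  em2 <- median_scale(make_arrays(vv, c("t", "t"), bg = 1), snr_min = 2)
  av2 <- average_replicates(em2, "t")
  expect_equal(av2$se_log2[1], 0)
  expect_equal(av2$n_detected[2], 0)
  expect_true(is.na(av2$mean_log2[2]))
})

test_that("log2_ratio_ew reproduces exact folds and the Welch test", {
  set.seed(35)
  x <- rlnorm(40, 7, 1)
  v <- pmat(s1 = x, s2 = x, r1 = x, r2 = x)
  em <- median_scale(make_arrays(v, c("A", "A", "B", "B")), snr_min = 0)
  de <- log2_ratio_ew(em, "A", "B")
  expect_equal(de$log2_ratio, rep(0, 40))

  # exact 4x fold, expression matrix built directly (median scaling would
  # by design remove a fold shared by every probe)
  v4 <- pmat(s1 = 4 * x, s2 = 4 * x, r1 = x, r2 = x)
  em4 <- structure(list(values = v4,
                        detected = matrix(TRUE, 40, 4,
                                          dimnames = dimnames(v4)),
                        tissue = c(s1 = "A", s2 = "A", r1 = "B", r2 = "B"),
                        floor = 1), class = "expression_matrix")
  de4 <- log2_ratio_ew(em4, "A", "B")
  expect_equal(de4$log2_ratio, rep(2, 40))

  # Welch test against the textbook formula, 5 vs 5
  lg <- matrix(rnorm(20 * 10, 10, 1), nrow = 20,
               dimnames = list(sprintf("p%02d", 1:20),
                               sprintf("a%02d", 1:10)))
  emw <- median_scale(make_arrays(2^lg, rep(c("A", "B"), each = 5)),
                      snr_min = 0)
  dew <- log2_ratio_ew(emw, "A", "B")
  lgn <- log2(emw$values)
  for (i in c(3, 11)) {
    ref <- oracle_welch(lgn[i, 1:5], lgn[i, 6:10])
    expect_equal(dew$p_value[i], ref$p)
    expect_equal(dew$log2_ratio[i], mean(lgn[i, 1:5]) - mean(lgn[i, 6:10]))
  }
})

test_that("one-sided detections are flagged and ratioed against the floor", {
  v <- pmat(s1 = c(4096, 4096), s2 = c(4096, 4096),
            r1 = c(4096, 1), r2 = c(4096, 1))
  arr <- make_arrays(v, c("A", "A", "B", "B"), bg = 100)
  em <- median_scale(arr, snr_min = 2)
  de <- log2_ratio_ew(em, "A", "B")
  expect_false(de$one_sided[1])
  expect_true(de$one_sided[2])
  expect_equal(de$det_b[2], 0)
  expect_gt(de$log2_ratio[2], 5)  # vs floor log2 = 0
})

test_that("DE thresholds are inclusive on fold, strict on p", {
  de <- data.frame(probe_id = c("a", "b", "c", "d"),
                   log2_ratio = c(1.0, 0.99, 2.0, -1.0),
                   p_value = c(0.049, 0.001, 0.05, 0.049),
                   stringsAsFactors = FALSE)
  out <- select_de(de)
  expect_equal(out$direction, c("up", "ns", "ns", "down"))
  # partition is exhaustive and disjoint
  set.seed(36)
  rde <- data.frame(probe_id = sprintf("p%d", 1:200),
                    log2_ratio = rnorm(200, 0, 2),
                    p_value = runif(200), stringsAsFactors = FALSE)
  rde$log2_ratio[1] <- NA; rde$p_value[1] <- NA
  out2 <- select_de(rde)
  expect_true(all(out2$direction %in% c("up", "down", "ns")))
  expect_equal(sum(out2$direction == "up") + sum(out2$direction == "down") +
                 sum(out2$direction == "ns"), 200)
  expect_equal(out2$significant, out2$direction != "ns")
  # BH adjustment is monotone and never creates new calls
  out3 <- select_de(rde, adjust = "BH")
  expect_true(all(out3$p_used >= out2$p_used, na.rm = TRUE))
  expect_true(all(out2$direction[out3$significant] != "ns"))
})

test_that("tissue-specificity calls follow the detection rule", {
  de <- data.frame(probe_id = c("a", "b", "c", "d"),
                   log2_ratio = c(3, 3, 0.2, NA),
                   p_value = c(1e-4, 1e-4, 0.9, NA),
                   det_a = c(5L, 5L, 5L, 0L), det_b = c(0L, 2L, 5L, 0L),
                   n_a = 5L, n_b = 5L,
                   one_sided = c(TRUE, FALSE, FALSE, FALSE),
                   stringsAsFactors = FALSE)
  out <- call_specific(select_de(de))
  expect_equal(out$specificity,
               c("shoot_specific", "shared", "shared", "undetected"))
  # symmetric root-specific case
  de2 <- de[1, ]; de2$log2_ratio <- -3; de2$det_a <- 0L; de2$det_b <- 5L
  expect_equal(call_specific(select_de(de2))$specificity, "root_specific")
})
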