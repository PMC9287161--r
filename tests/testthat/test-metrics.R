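# Synthetic evaluation tables with known confusion structure.

perfect_records <- function(n = 20) {
  cls <- rep(c("SEC_SPI", "NO_SP"), length.out = n)
  eval_records(id = paste0("s", 1:n), true_class = cls, pred_class = cls,
               true_cs = ifelse(cls == "SEC_SPI", 20L, NA_integer_),
               pred_cs = ifelse(cls == "SEC_SPI", 20L, NA_integer_),
               group = rep(ORGANISM_GROUPS, length.out = n))
}

test_that("detection MCC matches the closed form and the mode semantics", {
  expect_equal(detection_mcc(perfect_records(), "SEC_SPI"), 1)
  # printed toy counts: TP=8, TN=85, FP=5, FN=2
  tp <- 8; tn <- 85; fp <- 5; fn <- 2
  recs <- eval_records(
    id = as.character(1:100),
    true_class = c(rep("SEC_SPI", tp + fn), rep("NO_SP", tn + fp)),
    pred_class = c(rep("SEC_SPI", tp), rep("NO_SP", fn),
                   rep("NO_SP", tn), rep("SEC_SPI", fp)))
  closed <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(detection_mcc(recs, "SEC_SPI"), closed)
  # MCC1 drops other SP types; MCC2 keeps them as negatives
  extra <- eval_records(id = paste0("x", 1:10),
                        true_class = rep("SEC_SPII", 10),
                        pred_class = rep("SEC_SPI", 10))
  both <- rbind(recs, extra)
  expect_equal(detection_mcc(both, "SEC_SPI", mode = "MCC1"), closed)
  expect_lt(detection_mcc(both, "SEC_SPI", mode = "MCC2"), closed)
  # label-independent predictions on a large balanced fixture: MCC near 0
  set.seed(6)
  n <- 4000
  rnd <- eval_records(id = as.character(1:n),
                      true_class = sample(c("SEC_SPI", "NO_SP"), n, TRUE),
                      pred_class = sample(c("SEC_SPI", "NO_SP"), n, TRUE))
  expect_lt(abs(detection_mcc(rnd, "SEC_SPI")), 0.06)
  # degenerate margins
  expect_warning(z <- detection_mcc(rnd[rnd$true_class == "NO_SP", ], "SEC_SPI"),
                 "degenerate")
  expect_equal(z, 0)
})

test_that("CS precision/recall implements the class-match and window rules", {
  expect_equal(cs_precision_recall(perfect_records(), "SEC_SPI", 0),
               c(precision = 1, recall = 1))
  # hand-counted example: 10 true SPI CSs; 8 predicted as SPI (6 within
  # window), 1 predicted as SPII with a CS -> precision 6/8, recall 6/10
  recs <- eval_records(
    id = as.character(1:10),
    true_class = rep("SEC_SPI", 10),
    true_cs = rep(20L, 10),
    pred_class = c(rep("SEC_SPI", 8), "SEC_SPII", "NO_SP"),
    pred_cs = c(rep(20L, 6), 28L, 28L, 20L, NA))
  pr <- cs_precision_recall(recs, "SEC_SPI", window = 0)
  expect_equal(unname(pr), c(6 / 8, 6 / 10))
  # off-by-2 prediction: correct at windows 2-3, incorrect at 0-1
  one <- eval_records(id = "a", true_class = "SEC_SPI", pred_class = "SEC_SPI",
                      true_cs = 20L, pred_cs = 22L)
  expect_equal(cs_precision_recall(one, "SEC_SPI", 1)[["recall"]], 0)
  expect_equal(cs_precision_recall(one, "SEC_SPI", 2)[["recall"]], 1)
  # monotone in the window
  set.seed(8)
  noisy <- eval_records(
    id = as.character(1:50), true_class = rep("SEC_SPI", 50),
    true_cs = rep(20L, 50),
    pred_class = sample(c("SEC_SPI", "SEC_SPII"), 50, TRUE, prob = c(.8, .2)),
    pred_cs = 20L + sample(-4:4, 50, TRUE))
  prev <- c(precision = -1, recall = -1)
  for (w in 0:3) {
    cur <- cs_precision_recall(noisy, "SEC_SPI", w)
    expect_true(all(cur >= prev))
    prev <- cur
  }
  # no predicted CS -> precision 0 with a warning
  none <- eval_records(id = "b", true_class = "SEC_SPI",
                       pred_class = "NO_SP", true_cs = 10L, pred_cs = NA)
  expect_warning(p0 <- cs_precision_recall(none, "SEC_SPI", 0), "undefined")
  expect_equal(p0[["precision"]], 0)
})

test_that("Gorodkin multiclass MCC agrees with reductions and an oracle", {
  # identity confusion matrix -> 1
  expect_equal(multiclass_mcc(diag(5) * 7), 1)
  # K = 2 equals the binary MCC on the same counts
  conf2 <- matrix(c(8, 2, 5, 85), 2, 2, byrow = TRUE)
  tp <- 8; fn <- 2; fp <- 5; tn <- 85
  expect_equal(multiclass_mcc(conf2),
               (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  # 3x3 case vs an independent covariance-form implementation
  set.seed(12)
  conf3 <- matrix(sample(0:30, 9, TRUE), 3, 3)
  cov_oracle <- function(conf) {
    K <- nrow(conf)
    tru <- rep(rep(seq_len(K), K), times = as.vector(t(conf)))
    prd <- rep(rep(seq_len(K), each = K), times = as.vector(t(conf)))
    X <- outer(tru, seq_len(K), "=="); Y <- outer(prd, seq_len(K), "==")
    num <- sum(vapply(seq_len(K), function(k) cov(X[, k], Y[, k]), 0))
    num / sqrt(sum(vapply(seq_len(K), function(k) cov(X[, k], X[, k]), 0)) *
                 sum(vapply(seq_len(K), function(k) cov(Y[, k], Y[, k]), 0)))
  }
  expect_equal(multiclass_mcc(conf3), cov_oracle(conf3), tolerance = 1e-12)
  expect_warning(z <- multiclass_mcc(matrix(c(5, 0, 3, 0), 2, 2)), "degenerate")
  expect_equal(z, 0)
})

test_that("identity-binned performance pools and stratifies correctly", {
  recs <- perfect_records(12)
  recs$max_train_identity <- 0.95
  out <- performance_by_identity_bin(recs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mcc, multiclass_mcc(recs))
  # two bins: perfect vs label-shuffled
  set.seed(4)
  good <- perfect_records(40); good$max_train_identity <- 0.35
  bad <- perfect_records(40)
  bad$pred_class <- sample(bad$pred_class)
  bad$max_train_identity <- 0.95
  out2 <- performance_by_identity_bin(rbind(good, bad))
  expect_equal(out2$mcc[out2$bin == "[0.30,0.40)"], 1)
  expect_lt(abs(out2$mcc[out2$bin == "[0.90,1.00)"]), 0.5)
  # empty bins are absent, not zero
  expect_false(any(out2$n == 0))
  expect_error(performance_by_identity_bin(perfect_records(3)), "max_train_identity")
})
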