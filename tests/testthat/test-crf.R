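test_that("emissions are the affine projection of hidden states", {
  space <- build_state_space()
  C <- nrow(space$states)
  set.seed(1)
  params <- crf_params(matrix(rnorm(3 * C), 3, C), rnorm(C),
                       matrix(0, C, C), space)
  h <- matrix(rnorm(6), 2, 3)
  em <- crf_emissions(h, params)
  expect_equal(em, sweep(h %*% params$W_psi, 2, params$b_psi, "+"))
  expect_equal(crf_emissions(matrix(0, 4, 3), params)[3, ], params$b_psi)
  expect_error(crf_emissions(matrix(0, 4, 2), params), "dimension")
})

test_that("degenerate lattices have closed-form partition functions", {
  # single-state chain: logZ is the sum of emissions
  lat <- list(C = 1L, T = 3L, allowed = matrix(TRUE, 1, 1),
              start_allowed = TRUE, end_allowed = TRUE,
              em = matrix(c(1.5, -2, 0.25), 3, 1),
              phi = matrix(0, 1, 1))
  expect_equal(crf_log_partition(lat$em, as_params(lat), as_space(lat)),
               1.5 - 2 + 0.25)
  # two free states, zero scores, T = 2: four equiprobable paths
  lat2 <- list(C = 2L, T = 2L, allowed = matrix(TRUE, 2, 2),
               start_allowed = c(TRUE, TRUE), end_allowed = c(TRUE, TRUE),
               em = matrix(0, 2, 2), phi = matrix(0, 2, 2))
  expect_equal(crf_log_partition(lat2$em, as_params(lat2), as_space(lat2)),
               log(4))
  expect_equal(crf_marginals(lat2$em, as_params(lat2), as_space(lat2)),
               matrix(0.5, 2, 2))
  # no allowed path
  lat3 <- lat2
  lat3$start_allowed <- c(FALSE, FALSE)
  expect_error(crf_log_partition(lat3$em, as_params(lat3), as_space(lat3)),
               "no allowed path")
})

test_that("lattice quantities match exhaustive enumeration on random instances", {
  set.seed(202)
  for (k in 1:60) {
    lat <- random_lattice()
    space <- as_space(lat); params <- as_params(lat)
    or <- oracle_lattice(lat$em, lat$phi, lat$start_allowed,
                         lat$end_allowed, lat$allowed)
    expect_equal(crf_log_partition(lat$em, params, space), or$logZ,
                 tolerance = 1e-10)
    expect_equal(crf_marginals(lat$em, params, space), or$marginals,
                 tolerance = 1e-10)
    v <- crf_viterbi(lat$em, params, space)
    # re-scoring the decoded path with the oracle's own scorer must attain
    # the enumerated maximum
    expect_equal(path_score(as.integer(v), lat$em, lat$phi), or$best,
                 tolerance = 1e-12)
    tags <- random_tags(lat)
    orc <- oracle_lattice(lat$em, lat$phi, lat$start_allowed,
                          lat$end_allowed, lat$allowed, tags)
    if (is.finite(orc$logZ)) {
      expect_equal(crf_multitag_nll(lat$em, params, space, tags),
                   or$logZ - orc$logZ, tolerance = 1e-8)
    } else {
      expect_error(crf_multitag_nll(lat$em, params, space, tags),
                   "infeasible position")
    }
  }
})

test_that("viterbi tie-break is deterministic towards low state ids", {
  lat <- list(C = 3L, T = 3L, allowed = matrix(TRUE, 3, 3),
              start_allowed = rep(TRUE, 3), end_allowed = rep(TRUE, 3),
              em = matrix(0, 3, 3), phi = matrix(0, 3, 3))
  v <- crf_viterbi(lat$em, as_params(lat), as_space(lat))
  expect_equal(as.integer(v), c(1L, 1L, 1L))
})

test_that("multitag NLL reduces to path NLL for singleton sets and is monotone", {
  set.seed(5)
  for (k in 1:10) {
    lat <- random_lattice()
    space <- as_space(lat); params <- as_params(lat)
    or <- oracle_lattice(lat$em, lat$phi, lat$start_allowed,
                         lat$end_allowed, lat$allowed)
    # full sets -> NLL exactly 0
    full <- structure(rep(list(seq_len(lat$C)), lat$T),
                      class = "multitag_matrix")
    expect_equal(crf_multitag_nll(lat$em, params, space, full), 0)
    # singleton sets along an allowed path -> logZ - path score
    p <- or$paths[[1]]
    single <- structure(as.list(p), class = "multitag_matrix")
    expect_equal(crf_multitag_nll(lat$em, params, space, single),
                 or$logZ - path_score(p, lat$em, lat$phi), tolerance = 1e-8)
    # enlarging sets never increases the NLL; exp(-nll) in (0, 1]
    grown <- structure(lapply(seq_len(lat$T), function(t)
      unique(c(p[t], sample(lat$C, 1)))), class = "multitag_matrix")
    n1 <- crf_multitag_nll(lat$em, params, space, single)
    n2 <- crf_multitag_nll(lat$em, params, space, grown)
    expect_lte(n2, n1 + 1e-12)
    expect_gt(exp(-n1), 0); expect_lte(exp(-n1), 1)
  }
})

test_that("class probabilities are the length-normalized class marginal mass", {
  space <- build_state_space()
  C <- nrow(space$states)
  set.seed(8)
  # random row-stochastic matrix vs direct double sum
  M <- matrix(rexp(12 * C), 12, C)
  M <- M / rowSums(M)
  cp <- class_probs(M, space)
  direct <- vapply(SP_CLASSES, function(g)
    sum(M[, space$states$class == g]) / 12, 0)
  expect_equal(cp, direct)
  expect_equal(sum(cp), 1, tolerance = 1e-9)
  # all mass on NO_SP states
  M2 <- matrix(0, 5, C)
  M2[, which(space$states$class == "NO_SP")[1]] <- 1
  expect_equal(unname(class_probs(M2, space)), c(1, 0, 0, 0, 0, 0))
  # invariant to permuting state ids within a class
  perm <- seq_len(C)
  ix <- which(space$states$class == "SEC_SPI")
  perm[ix] <- rev(ix)
  expect_equal(class_probs(M[, perm], space), cp)
})

test_that("CS inference returns the last SP state position", {
  space <- build_state_space()
  iN <- which(space$states$class == "SEC_SPI" & space$states$tag == "N")
  iH <- which(space$states$class == "SEC_SPI" & space$states$tag == "H")
  iC <- which(space$states$class == "SEC_SPI" & space$states$tag == "C")
  iO <- which(space$states$class == "SEC_SPI" & space$states$tag == "O")
  path <- c(rep(iN, 3), rep(iH, 8), rep(iC, 11), rep(iO, 5))
  expect_equal(infer_cs(path, space), 22L)
  iI <- which(space$states$class == "NO_SP" & space$states$tag == "I")
  expect_identical(infer_cs(rep(iI, 10), space), NA_integer_)
  iL3 <- which(space$states$class == "SEC_SPII" & space$states$tag == "L3")
  iO2 <- which(space$states$class == "SEC_SPII" & space$states$tag == "O")
  path2 <- c(rep(which(space$states$class == "SEC_SPII" &
                         space$states$tag == "H"), 17), iL3, rep(iO2, 4))
  expect_equal(infer_cs(path2, space), 18L)
})

test_that("sp_predict composes the pipeline and respects invariants", {
  set.seed(31)
  recs <- toy_records(3, seed = 12)
  res <- sp_train(recs, train_config(epochs = 1, batch_size = 8, seed = 2,
                                     degeneracy_check = FALSE))
  model <- res$model
  p <- sp_predict("MKKLLLLLLASAGTDEAQRKL", "EUKARYA", model)
  expect_equal(sum(p$class_probs), 1, tolerance = 1e-9)
  expect_true(all(rowSums(p$marginals) - 1 < 1e-9))
  path <- p$path
  space <- model$space
  expect_true(space$start_allowed[path[1]])
  if (length(path) > 1)
    expect_true(all(space$allowed[cbind(path[-length(path)], path[-1])]))
  # length-1 sequence degenerates gracefully
  p1 <- sp_predict("M", "UNKNOWN", model)
  expect_equal(sum(p1$class_probs), 1, tolerance = 1e-9)
  expect_true(is.na(p1$cs) || p1$cs == 1L)
  # non-standard residues never crash
  px <- sp_predict("MKXBZUOLLLASA", "UNKNOWN", model)
  expect_s3_class(px, "sp_prediction")
  expect_error(sp_predict("", "UNKNOWN", model), "empty")
})
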