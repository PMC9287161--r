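# Desk-scale training: multitag NLL + composition regularizer, Adamax with
# a slanted triangular learning rate, degeneracy guard, nested
# cross-validation.

#' Training configuration
#'
#' @param epochs Number of passes over the training data (default 15).
#' @param optimizer Only `"adamax"` is implemented.
#' @param lr_peak Peak learning rate of the slanted triangular schedule.
#' @param lr_floor Final learning rate the linear decay ends at.
#' @param warmup Fraction of total steps spent ramping up to `lr_peak`.
#' @param dropout Dropout rate applied to encoder hidden states.
#' @param alpha Weight of the composition regularizer (0 disables it).
#' @param batch_size Minibatch size.
#' @param seed RNG seed; a fixed seed makes a run reproducible.
#' @param degeneracy_check Abort runs that collapse to the degenerate
#'   2-residue n-region solution after the first epoch.
#' @param degeneracy_tol Tolerance of [detect_degenerate()].
#' @param D,E,window Encoder hyperparameters (see [encoder_init()]).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 15L, optimizer = "adamax",
                         lr_peak = 1e-2, lr_floor = 1e-4, warmup = 0.1,
                         dropout = 0.1, alpha = 0.5, batch_size = 32L,
                         seed = 1L, degeneracy_check = TRUE,
                         degeneracy_tol = 0.05,
                         D = 64L, E = 8L, window = 3L) {
  stopifnot(epochs >= 1, alpha >= 0, identical(optimizer, "adamax"))
  structure(as.list(environment()), class = "train_config")
}

# Slanted triangular learning rate: linear warmup to the peak, then linear
# decay to the floor.
stlr <- function(step, total, peak, floor, warmup) {
  cut <- max(1, round(total * warmup))
  if (step <= cut) return(peak * step / cut)
  floor + (peak - floor) * (total - step) / max(1, total - cut)
}

# One Adamax update. state holds u (exp. moving avg) and m (inf. norm).
adamax_step <- function(theta, grad, state, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  state$u <- b1 * state$u + (1 - b1) * grad
  state$m <- pmax(b2 * state$m, abs(grad))
  theta <- theta - (lr / (1 - b1^t)) * state$u / (state$m + eps)
  list(theta = theta, state = state)
}

# Which regularizer terms a true class contributes.
reg_terms_of_class <- function(cls) {
  switch(cls,
         SEC_SPI = c("nh", "hc"), TAT_SPI = c("nh", "hc"),
         SEC_SPII = "nh", TAT_SPII = "nh",
         character(0))
}

#' Train the encoder + CRF on annotated records
#'
#' Minimizes the multitag negative log likelihood plus `alpha` times the
#' composition regularizer with Adamax and a slanted triangular learning
#' rate, end to end through the encoder. After the first epoch a
#' validation slice is decoded and checked for the degenerate short
#' n-region solution; such runs abort with status `"degenerate"` and must
#' be restarted with a different seed.
#'
#' @param records List of [annotated_sp()] records (SP records are labeled
#'   with [label_regions()]; `NO_SP` records use their I/M/O annotation).
#' @param config A [train_config()].
#' @param space State space (default [build_state_space()]).
#' @param init Optional list with components `enc` and/or `crf` overriding
#'   the random initialization (used e.g. to probe degenerate starts).
#' @param val_records Records decoded for the degeneracy check; defaults to
#'   a slice of the training set.
#' @return A list with `model` (`sp_model`), `log` (per-epoch data.frame
#'   with `nll`, `reg`, `degenerate`), `status` (`"ok"` or
#'   `"degenerate"`), and `manifest` (ids trained on).
#' @export
sp_train <- function(records, config = train_config(),
                     space = build_state_space(), init = NULL,
                     val_records = NULL) {
  if (!length(records)) stop("empty training set")
  set.seed(config$seed)
  C <- nrow(space$states)

  enc <- encoder_init(D = config$D, E = config$E, window = config$window)
  crf <- list(W_psi = matrix(stats::rnorm(config$D * C, sd = 0.1), config$D, C),
              b_psi = numeric(C),
              phi = ifelse(space$allowed, 0, -Inf))
  if (!is.null(init$enc)) enc[names(init$enc)] <- init$enc
  if (!is.null(init$crf)) crf[names(init$crf)] <- init$crf
  class(crf) <- "crf_params"

  tags <- lapply(records, record_multitag, space = space)
  toks <- lapply(records, function(r) tokenize(r$sequence))
  terms <- lapply(records, function(r) reg_terms_of_class(r$sp_class))

  pnames <- c("emb", "gemb", "pemb", "W1", "b1")
  opt <- list()
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  for (nm in pnames) opt[[paste0("enc.", nm)]] <- list(u = zero_like(enc[[nm]]), m = zero_like(enc[[nm]]))
  for (nm in c("W_psi", "b_psi", "phi")) opt[[paste0("crf.", nm)]] <- list(u = zero_like(crf[[nm]]), m = zero_like(crf[[nm]]))
  phi_mask <- space$allowed

  n <- length(records)
  nbatch <- ceiling(n / config$batch_size)
  total_steps <- config$epochs * nbatch
  step <- 0L
  log_rows <- list()
  status <- "ok"

  if (is.null(val_records))
    val_records <- records[seq_len(min(64L, n))]

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_nll <- 0; ep_reg <- 0; ep_terms <- 0L
    for (b in seq_len(nbatch)) {
      ix <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n)]
      step <- step + 1L
      lr <- stlr(step, total_steps, config$lr_peak, config$lr_floor, config$warmup)
      g_enc <- lapply(enc[pnames], zero_like)
      g_crf <- lapply(crf[c("W_psi", "b_psi", "phi")], zero_like)
      g_crf$phi[] <- 0
      n_nh <- sum(vapply(terms[ix], function(tt) "nh" %in% tt, TRUE))
      n_hc <- sum(vapply(terms[ix], function(tt) "hc" %in% tt, TRUE))
      nb <- length(ix)
      for (i in ix) {
        fwd <- encoder_forward(toks[[i]], records[[i]]$organism_group, enc)
        Hd <- fwd$H
        mask <- NULL
        if (config$dropout > 0) {
          mask <- matrix(stats::rbinom(length(Hd), 1, 1 - config$dropout),
                         nrow(Hd)) / (1 - config$dropout)
          Hd <- Hd * mask
        }
        em <- sweep(Hd %*% crf$W_psi, 2, crf$b_psi, "+")
        gr <- crf_nll_grad(em, crf, space, tags[[i]])
        bar_em <- gr$bar_em / nb
        bar_phi <- gr$bar_phi / nb
        ep_nll <- ep_nll + gr$nll

        tt <- terms[[i]]
        if (config$alpha > 0 && length(tt)) {
          w_nh <- if ("nh" %in% tt && n_nh > 0) config$alpha / n_nh else 0
          w_hc <- if ("hc" %in% tt && n_hc > 0) config$alpha / n_hc else 0
          barM <- reg_grad_barM(gr$fb$M, records[[i]]$sequence, space, w_nh, w_hc)
          if (any(barM != 0)) {
            vjp <- crf_marginal_vjp(em, crf$phi, space, gr$fb$A, gr$fb$B,
                                    gr$fb$logZ, gr$fb$M, barM)
            bar_em <- bar_em + vjp$bar_em
            bar_phi <- bar_phi + vjp$bar_phi
          }
          sv <- region_scores(gr$fb$M, records[[i]]$sequence, space)
          ep_reg <- ep_reg + reg_loss(list(sv), config$alpha, list(tt))
          ep_terms <- ep_terms + 1L
        }

        g_crf$W_psi <- g_crf$W_psi + crossprod(Hd, bar_em)
        g_crf$b_psi <- g_crf$b_psi + colSums(bar_em)
        g_crf$phi <- g_crf$phi + bar_phi
        bar_H <- tcrossprod(bar_em, crf$W_psi)
        if (!is.null(mask)) bar_H <- bar_H * mask
        ge <- encoder_backward(fwd, bar_H, enc)
        for (nm in pnames) g_enc[[nm]] <- g_enc[[nm]] + ge[[nm]]
      }
      for (nm in pnames) {
        up <- adamax_step(enc[[nm]], g_enc[[nm]], opt[[paste0("enc.", nm)]], lr, step)
        enc[[nm]] <- up$theta; opt[[paste0("enc.", nm)]] <- up$state
      }
      for (nm in c("W_psi", "b_psi")) {
        up <- adamax_step(crf[[nm]], g_crf[[nm]], opt[[paste0("crf.", nm)]], lr, step)
        crf[[nm]] <- up$theta; opt[[paste0("crf.", nm)]] <- up$state
      }
      gphi <- g_crf$phi; gphi[!phi_mask] <- 0
      phi0 <- crf$phi; phi0[!phi_mask] <- 0
      up <- adamax_step(phi0, gphi, opt[["crf.phi"]], lr, step)
      opt[["crf.phi"]] <- up$state
      up$theta[!phi_mask] <- -Inf
      crf$phi <- up$theta
    }

    degen <- FALSE
    if (epoch == 1L && config$degeneracy_check) {
      model_now <- sp_model(enc, crf, space, config)
      nlens <- numeric(0)
      for (r in val_records) {
        p <- sp_predict(r$sequence, r$organism_group, model_now)
        if (p$predicted_class != "NO_SP") {
          nl <- n_region_length(p$path, space)
          if (nl > 0) nlens <- c(nlens, nl)
        }
      }
      degen <- if (length(nlens)) detect_degenerate(nlens, tol = config$degeneracy_tol)
               else suppressWarnings(detect_degenerate(numeric(0)))
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, nll = ep_nll / n,
      reg = if (ep_terms > 0) ep_reg / ep_terms else 0,
      degenerate = degen)
    if (degen) { status <- "degenerate"; break }
  }

  list(model = sp_model(enc, crf, space, config),
       log = do.call(rbind, log_rows), status = status,
       manifest = vapply(records, `[[`, "", "id"))
}

#' Threefold nested cross-validation
#'
#' Outer loop over the three partitions; for each outer test partition the
#' remaining two partitions form a twofold inner loop (train on one,
#' degeneracy-check on the other, then swap), yielding 3 x 2 = 6 models.
#' Each test sequence is predicted only by the two models that never saw
#' its partition; their class probabilities and marginals are averaged and
#' the CS re-decoded from the averaged marginals under the mask.
#'
#' @param partitions List of exactly 3 lists of [annotated_sp()] records.
#' @param config A [train_config()].
#' @param space State space.
#' @return List with `models` (6 training results), `predictions` (pooled
#'   over the three outer folds: list of `sp_prediction` plus record
#'   metadata), and `manifest` (data.frame model id x train/test ids).
#' @export
nested_cv <- function(partitions, config = train_config(),
                      space = build_state_space()) {
  if (length(partitions) != 3L) stop("nested_cv requires exactly 3 partitions")
  models <- list()
  manifest <- list()
  predictions <- list()
  for (outer in 1:3) {
    inner <- setdiff(1:3, outer)
    fold_models <- list()
    for (k in 1:2) {
      tr <- inner[k]; va <- inner[3 - k]
      cfg <- config
      cfg$seed <- config$seed + 7L * outer + k
      res <- sp_train(partitions[[tr]], cfg, space,
                      val_records = partitions[[va]])
      mid <- sprintf("outer%d_model%d", outer, k)
      models[[mid]] <- res
      fold_models[[k]] <- res$model
      manifest[[mid]] <- data.frame(
        model = mid,
        train_ids = I(list(vapply(partitions[[tr]], `[[`, "", "id"))),
        test_ids = I(list(vapply(partitions[[outer]], `[[`, "", "id"))))
    }
    for (r in partitions[[outer]]) {
      p <- ensemble_predict(r$sequence, r$organism_group, fold_models)
      predictions[[r$id]] <- list(id = r$id, true_class = r$sp_class,
                                  true_cs = r$cs, group = r$organism_group,
                                  prediction = p)
    }
  }
  list(models = models, predictions = predictions,
       manifest = do.call(rbind, manifest))
}
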