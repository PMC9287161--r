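# Model serialization: a single self-describing JSON container holding the
# grammar version, encoder hyperparameters and all weights. Text-only, so
# models survive plain-text pipelines; numbers are written at full
# precision.

#' Save a model to a JSON container
#'
#' @param model An `sp_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  enc <- model$enc
  crf <- model$crf
  phi <- crf$phi
  phi[!is.finite(phi)] <- NA   # JSON has no -Inf; mask restored on load
  obj <- list(
    version = model$version,
    grammar = "sp-grammar-1",
    encoder = list(D = enc$D, E = enc$E, window = enc$window,
                   pos_max = enc$pos_max, emb = enc$emb, gemb = enc$gemb,
                   pemb = enc$pemb, W1 = enc$W1, b1 = enc$b1),
    crf = list(W_psi = crf$W_psi, b_psi = crf$b_psi, phi = phi),
    config = model$config[c("epochs", "lr_peak", "lr_floor", "warmup",
                            "dropout", "alpha", "batch_size", "seed")]
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Load a model from a JSON container
#'
#' @param path Path written by [save_model()].
#' @return An `sp_model` (state space rebuilt from the grammar version).
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$grammar, "sp-grammar-1"))
    stop("unsupported grammar version: ", obj$grammar)
  space <- build_state_space()
  e <- obj$encoder
  enc <- structure(list(D = as.integer(e$D), E = as.integer(e$E),
                        window = as.integer(e$window),
                        pos_max = as.integer(e$pos_max),
                        emb = as.matrix(e$emb), gemb = as.matrix(e$gemb),
                        pemb = as.matrix(e$pemb), W1 = as.matrix(e$W1),
                        b1 = as.numeric(e$b1)), class = "sp_encoder")
  phi <- as.matrix(obj$crf$phi)
  phi[is.na(phi)] <- -Inf
  phi[!space$allowed] <- -Inf
  crf <- structure(list(W_psi = as.matrix(obj$crf$W_psi),
                        b_psi = as.numeric(obj$crf$b_psi), phi = phi),
                   class = "crf_params")
  sp_model(enc, crf, space, as.list(obj$config))
}
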