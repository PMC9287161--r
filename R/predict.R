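# Model container and prediction.

# Assemble a model object from encoder + CRF parameters.
sp_model <- function(enc, crf, space, config = list()) {
  structure(list(version = "sigcrf-model-1", enc = enc, crf = crf,
                 space = space, config = config),
            class = "sp_model")
}

#' Predict signal peptide class, cleavage site and regions for one sequence
#'
#' Composes encoder, CRF emissions, forward-backward marginals and Viterbi
#' decoding. The sequence class is the argmax of the global class
#' probabilities (mean marginal mass of each class's states); the cleavage
#' site is the position of the last SP state on the Viterbi path, with its
#' confidence reported as the marginal probability of that state at that
#' position.
#'
#' @param sequence Amino acid string. Non-standard residues (B, Z, X, U, O,
#'   J) are mapped to an UNK token and never fail.
#' @param organism_group One of [ORGANISM_GROUPS] or `"UNKNOWN"` (default),
#'   the no-organism-information mode.
#' @param model An `sp_model` from [sp_train()] or [load_model()].
#' @return An object of class `sp_prediction`: list with `class_probs`
#'   (named 6-vector), `predicted_class`, `path` (state row indices),
#'   `tags` (region tag per position), `marginals`, `cs`, `cs_prob`.
#' @export
sp_predict <- function(sequence, organism_group = "UNKNOWN", model) {
  if (!nzchar(sequence)) stop("cannot predict an empty sequence")
  check_group(organism_group)
  space <- model$space
  H <- encode_sequence(sequence, organism_group, model$enc)
  em <- crf_emissions(H, model$crf)
  fb <- crf_forward_backward(em, model$crf, space)
  path <- crf_viterbi(em, model$crf, space)
  cp <- class_probs(fb$M, space)
  cs <- infer_cs(path, space)
  structure(list(
    class_probs = cp,
    predicted_class = names(cp)[which.max(cp)],
    path = as.integer(path),
    tags = space$states$tag[path],
    marginals = fb$M,
    cs = cs,
    cs_prob = if (is.na(cs)) NA_real_ else fb$M[cs, path[cs]]
  ), class = "sp_prediction")
}

#' Predict a set of records and tabulate the results
#'
#' @param records List of [annotated_sp()] records (annotation fields are
#'   ignored) or named character vector of sequences.
#' @param model An `sp_model`.
#' @param organism_group Group token used for records without one.
#' @return A data.frame with one row per sequence: id, predicted class,
#'   the six class probabilities, CS position (`NA` if none) and CS
#'   probability.
#' @export
predict_records <- function(records, model, organism_group = "UNKNOWN") {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("seq", seq_along(records))
    records <- mapply(function(s, id) annotated_sp(s, "NO_SP", id = id,
                                                   organism_group = organism_group),
                      records, ids, SIMPLIFY = FALSE)
  }
  rows <- lapply(records, function(r) {
    grp <- if (is.null(r$organism_group)) organism_group else r$organism_group
    p <- sp_predict(r$sequence, grp, model)
    c(list(id = r$id, predicted_class = p$predicted_class),
      as.list(p$class_probs),
      list(cs = p$cs, cs_prob = p$cs_prob))
  })
  do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
}

# Ensemble of models (nested CV): average class probabilities and
# marginals, then decode a path from the averaged marginals under the
# transition mask (emission = log mean marginal, transitions 0/allowed).
ensemble_predict <- function(sequence, organism_group, models) {
  space <- models[[1]]$space
  preds <- lapply(models, function(m) sp_predict(sequence, organism_group, m))
  cp <- Reduce(`+`, lapply(preds, `[[`, "class_probs")) / length(preds)
  M <- Reduce(`+`, lapply(preds, `[[`, "marginals")) / length(preds)
  em <- log(M)
  phi0 <- ifelse(space$allowed, 0, -Inf)
  params0 <- structure(list(W_psi = diag(ncol(M)), b_psi = numeric(ncol(M)),
                            phi = phi0), class = "crf_params")
  path <- crf_viterbi(em, params0, space)
  cs <- infer_cs(path, space)
  structure(list(
    class_probs = cp, predicted_class = names(cp)[which.max(cp)],
    path = as.integer(path), tags = space$states$tag[path],
    marginals = M, cs = cs,
    cs_prob = if (is.na(cs)) NA_real_ else M[cs, path[cs]]
  ), class = "sp_prediction")
}
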