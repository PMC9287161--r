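# Evaluation metrics: per-type detection MCC under two negative-set
# definitions, class-conditional CS precision/recall with tolerance
# windows, Gorodkin multiclass MCC, identity-stratified performance.
#
# Records are rows of a data.frame with columns: id, true_class,
# pred_class, true_cs, pred_cs, group, and optionally max_train_identity.

#' Assemble an evaluation record table
#'
#' @param id,true_class,pred_class,group Character vectors.
#' @param true_cs,pred_cs Integer vectors (`NA` where no CS).
#' @param max_train_identity Optional numeric vector.
#' @return data.frame of evaluation records.
#' @export
eval_records <- function(id, true_class, pred_class, true_cs = NA_integer_,
                         pred_cs = NA_integer_, group = "UNKNOWN",
                         max_train_identity = NA_real_) {
  data.frame(id = id, true_class = true_class, pred_class = pred_class,
             true_cs = true_cs, pred_cs = pred_cs, group = group,
             max_train_identity = max_train_identity,
             stringsAsFactors = FALSE)
}

# Binary MCC from confusion counts; degenerate margins give 0 + warning.
mcc_from_counts <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) {
    warning("degenerate confusion matrix (zero margin); MCC reported as 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(den2)
}

#' SP detection MCC for one type (MCC1 or MCC2)
#'
#' Positives are sequences of `sp_type`. Under `MCC1` the negative set
#' consists only of non-SP (soluble/transmembrane) sequences - records of
#' other SP types are excluded entirely; under `MCC2` other SP types are
#' additionally included as negatives. A prediction counts as positive iff
#' the predicted class equals `sp_type`.
#'
#' @param records Evaluation record data.frame.
#' @param sp_type SP class being detected.
#' @param group Optional organism group to restrict to.
#' @param mode `"MCC1"` or `"MCC2"`.
#' @return MCC in `[-1, 1]`.
#' @export
detection_mcc <- function(records, sp_type, group = NULL, mode = c("MCC2", "MCC1")) {
  mode <- match.arg(mode)
  check_class(sp_type)
  r <- records
  if (!is.null(group)) r <- r[r$group == group, , drop = FALSE]
  if (mode == "MCC1")
    r <- r[r$true_class == sp_type | r$true_class == "NO_SP", , drop = FALSE]
  pos <- r$true_class == sp_type
  ppos <- r$pred_class == sp_type
  mcc_from_counts(tp = sum(pos & ppos), fp = sum(!pos & ppos),
                  tn = sum(!pos & !ppos), fn = sum(pos & !ppos))
}

#' Cleavage-site precision and recall with a tolerance window
#'
#' A predicted CS is correct iff the predicted class matches the true class
#' (`sp_type`) and the predicted position is within `window` residues of
#' the true CS. A CS predicted under the wrong class counts as "no CS
#' predicted". Precision = correct / number of CSs predicted as `sp_type`;
#' recall = correct / number of true `sp_type` CSs.
#'
#' @param records Evaluation record data.frame.
#' @param sp_type SP class.
#' @param window Tolerance window, one of 0:3.
#' @param group Optional organism-group restriction.
#' @return Named vector `c(precision = , recall = )`; precision is 0 with
#'   attribute `undefined = TRUE` when no CS was predicted.
#' @export
cs_precision_recall <- function(records, sp_type, window = 0L, group = NULL) {
  stopifnot(window %in% 0:3)
  check_class(sp_type)
  r <- records
  if (!is.null(group)) r <- r[r$group == group, , drop = FALSE]
  predicted <- r$pred_class == sp_type & !is.na(r$pred_cs)
  correct <- predicted & r$true_class == sp_type & !is.na(r$true_cs) &
    abs(r$pred_cs - r$true_cs) <= window
  truth <- r$true_class == sp_type & !is.na(r$true_cs)
  prec <- if (sum(predicted) == 0) {
    warning("no predicted CSs for ", sp_type, "; precision undefined, reported 0")
    structure(0, undefined = TRUE)
  } else sum(correct) / sum(predicted)
  rec <- if (sum(truth) == 0) NA_real_ else sum(correct) / sum(truth)
  c(precision = as.numeric(prec), recall = rec)
}

#' Gorodkin multiclass Matthews correlation coefficient
#'
#' The K-category correlation coefficient computed from the K x K confusion
#' matrix; reduces to the binary MCC for K = 2.
#'
#' @param records Evaluation record data.frame, or a square confusion
#'   matrix (rows = true, columns = predicted).
#' @return R_K in `[-1, 1]`; degenerate denominators give 0 with a warning.
#' @export
multiclass_mcc <- function(records) {
  conf <- if (is.matrix(records)) records else {
    lev <- SP_CLASSES
    table(factor(records$true_class, levels = lev),
          factor(records$pred_class, levels = lev))
  }
  conf <- unclass(as.matrix(conf))
  N <- sum(conf)
  t_k <- rowSums(conf)   # true class margins
  p_k <- colSums(conf)   # predicted class margins
  num <- N * sum(diag(conf)) - sum(t_k * p_k)
  den <- sqrt(N^2 - sum(p_k^2)) * sqrt(N^2 - sum(t_k^2))
  if (den == 0) {
    warning("degenerate confusion matrix; multiclass MCC reported as 0")
    return(0)
  }
  num / den
}

#' Multiclass MCC stratified by identity to the training set
#'
#' @param records Evaluation record data.frame carrying
#'   `max_train_identity` (predictions from all models pooled beforehand).
#' @param bin_edges Increasing bin edges; bin k is `[e_k, e_{k+1})`, the
#'   last bin closed above.
#' @return data.frame with bin label, n and MCC; empty bins are absent.
#' @export
performance_by_identity_bin <- function(records,
                                        bin_edges = seq(0.3, 1, by = 0.1)) {
  if (any(is.na(records$max_train_identity)))
    stop("all records must carry max_train_identity")
  k <- findInterval(records$max_train_identity, bin_edges,
                    rightmost.closed = TRUE)
  out <- list()
  for (kk in sort(unique(k))) {
    sub <- records[k == kk, , drop = FALSE]
    lab <- if (kk == 0) sprintf("<%.2f", bin_edges[1]) else
      sprintf("[%.2f,%.2f)", bin_edges[kk], c(bin_edges, Inf)[kk + 1])
    out[[length(out) + 1L]] <- data.frame(
      bin = lab, n = nrow(sub), mcc = multiclass_mcc(sub),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
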