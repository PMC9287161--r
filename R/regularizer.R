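# Composition-divergence regularizer.
#
# The multitag labels leave region borders underdetermined; to steer
# training towards biologically plausible borders, the amino acid
# composition of the n-, h- and c-regions is pushed apart. Per sequence,
# soft per-region amino acid score vectors are accumulated from the CRF
# marginals, and the cosine similarities cos(n, h) and cos(h, c) (each in
# [0, 1] since scores are nonnegative) are added to the loss, averaged over
# the batch and scaled by alpha. Sequences lacking a region (no c-region in
# SPII classes, nothing in SPIII/NO_SP) skip the affected term.

# Region tag pooling across classes: which state rows belong to n, h, c.
region_state_sets <- function(space) {
  list(n = which(space$states$tag %in% c("N", "N1", "N2")),
       h = which(space$states$tag == "H"),
       c = which(space$states$tag == "C"))
}

#' Soft per-region amino acid score vectors
#'
#' For each region `r` in `{n, h, c}`, sums the marginal probability of the
#' region's states (pooled across SP classes) at every position, then
#' accumulates these per-position scores by the amino acid at that
#' position.
#'
#' @param marg `T x C` marginal matrix.
#' @param sequence Amino acid string of length `T`.
#' @param space State space.
#' @return List with components `n`, `h`, `c`: named nonnegative length-20
#'   vectors over [AA20].
#' @export
region_scores <- function(marg, sequence, space) {
  sets <- region_state_sets(space)
  ch <- split_chars(toupper(sequence))
  ai <- match(ch, AA20)
  lapply(sets, function(ix) {
    s_t <- rowSums(marg[, ix, drop = FALSE])
    v <- numeric(length(AA20))
    names(v) <- AA20
    ok <- !is.na(ai)
    acc <- rowsum(s_t[ok], ai[ok])
    v[as.integer(rownames(acc))] <- acc
    v
  })
}

cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

#' Regularization loss for a batch of score vectors
#'
#' Computes, per sequence, the cosine similarity between the n and h score
#' vectors and between h and c, skipping a term when the sequence lacks the
#' region (zero-norm vector, or the term is not listed in `terms`). Cosine
#' similarity is scale invariant, so the normalized score vectors give the
#' same value as the raw ones.
#'
#' @param scores List of per-sequence score-vector lists (as returned by
#'   [region_scores()]).
#' @param alpha Nonnegative weight of the regularizer.
#' @param terms Optional list (same length as `scores`) of character
#'   vectors naming which of `"nh"`, `"hc"` apply to each sequence; by
#'   default both are attempted and zero-norm vectors skip themselves.
#' @return `alpha * (mean cos(n,h) + mean cos(h,c))`, each mean over the
#'   sequences contributing that term (0 when none do).
#' @export
reg_loss <- function(scores, alpha, terms = NULL) {
  stopifnot(alpha >= 0)
  nh <- hc <- numeric(0)
  for (i in seq_along(scores)) {
    sv <- scores[[i]]
    want <- if (is.null(terms)) c("nh", "hc") else terms[[i]]
    if ("nh" %in% want) {
      v <- cosine_sim(sv$n, sv$h)
      if (!is.na(v)) nh <- c(nh, v)
    }
    if ("hc" %in% want) {
      v <- cosine_sim(sv$h, sv$c)
      if (!is.na(v)) hc <- c(hc, v)
    }
  }
  m <- function(x) if (length(x)) mean(x) else 0
  alpha * (m(nh) + m(hc))
}

# d cos(u, v) / du; assumes both norms > 0.
.dcos_du <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  cs <- sum(u * v) / (nu * nv)
  v / (nu * nv) - cs * u / nu^2
}

# Gradient of the per-sequence regularizer terms w.r.t. the marginal matrix.
# w_nh / w_hc are the weights of this sequence's cos terms in the total loss
# (alpha / number of contributing sequences); either may be 0.
reg_grad_barM <- function(marg, sequence, space, w_nh, w_hc) {
  sets <- region_state_sets(space)
  sv <- region_scores(marg, sequence, space)
  bar_score <- list(n = numeric(20), h = numeric(20), c = numeric(20))
  if (w_nh > 0 && !is.na(cosine_sim(sv$n, sv$h))) {
    bar_score$n <- bar_score$n + w_nh * .dcos_du(sv$n, sv$h)
    bar_score$h <- bar_score$h + w_nh * .dcos_du(sv$h, sv$n)
  }
  if (w_hc > 0 && !is.na(cosine_sim(sv$h, sv$c))) {
    bar_score$h <- bar_score$h + w_hc * .dcos_du(sv$h, sv$c)
    bar_score$c <- bar_score$c + w_hc * .dcos_du(sv$c, sv$h)
  }
  ai <- match(split_chars(toupper(sequence)), AA20)
  bar_M <- matrix(0, nrow(marg), ncol(marg))
  for (r in names(sets)) {
    bs <- bar_score[[r]]
    per_pos <- ifelse(is.na(ai), 0, bs[ai])
    bar_M[, sets[[r]]] <- bar_M[, sets[[r]]] + per_pos
  }
  bar_M
}

#' Detect the degenerate short-n-region solution
#'
#' With the regularizer active, training can collapse to predicting an
#' n-region of length 2 in every SP regardless of sequence content (the
#' minimum allowed by the labeling rules, plausible as a minimum but not as
#' the average). Runs showing this after the first epoch must be stopped
#' and restarted.
#'
#' @param n_lengths Numeric vector of predicted n-region lengths over the
#'   SP-predicted sequences of a validation slice (see
#'   [n_region_length()]), or a list of decoded paths together with
#'   `space`.
#' @param space State space (only needed when `n_lengths` is a list of
#'   paths).
#' @param tol Tolerance above the degenerate length 2 (default 0.05).
#' @return `TRUE` iff the mean predicted n-region length is `<= 2 + tol`.
#'   Returns `FALSE` with a warning when no SP predictions are available.
#' @export
detect_degenerate <- function(n_lengths, space = NULL, tol = 0.05) {
  if (is.list(n_lengths)) {
    stopifnot(!is.null(space))
    n_lengths <- vapply(n_lengths, n_region_length, 0, space = space)
    n_lengths <- n_lengths[n_lengths > 0]
  }
  if (!length(n_lengths)) {
    warning("no SP predictions in the validation slice; degeneracy indeterminate")
    return(FALSE)
  }
  mean(n_lengths) <= 2 + tol
}

#' n-region length of a decoded path
#'
#' @param path Integer state path.
#' @param space State space.
#' @return Number of n-tagged positions (`N`, `N1`, `N2`); 0 for paths
#'   without an n-region.
#' @export
n_region_length <- function(path, space) {
  sum(space$states$tag[path] %in% c("N", "N1", "N2"))
}
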