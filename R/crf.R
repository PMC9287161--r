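# Grammar-constrained linear-chain CRF.
#
# The model: P(y | h) = (1/Z) prod_t exp(psi(h_t)[y_t]) prod_t exp(phi[y_t, y_t+1]),
# with psi(h_t) = W_psi h_t + b_psi the emissions and phi the learnable
# transition matrix, -Inf at entries forbidden by the state-space mask.
# All lattice computations run in log space; per-step scalar shifts plus a
# global shift of phi keep exp() in range for arbitrary finite scores.

#' Construct CRF parameters
#'
#' @param W_psi `D x C` emission projection matrix.
#' @param b_psi Length-`C` emission bias.
#' @param phi `C x C` transition score matrix; entries forbidden by
#'   `space$allowed` are forced to `-Inf`.
#' @param space State space the parameters refer to.
#' @return An object of class `crf_params`.
#' @export
crf_params <- function(W_psi, b_psi, phi, space) {
  C <- nrow(space$states)
  stopifnot(ncol(W_psi) == C, length(b_psi) == C,
            nrow(phi) == C, ncol(phi) == C)
  phi[!space$allowed] <- -Inf
  if (any(!is.finite(phi[space$allowed])))
    stop("phi must be finite on allowed transitions")
  structure(list(W_psi = W_psi, b_psi = b_psi, phi = phi),
            class = "crf_params")
}

#' Compute CRF emissions from hidden states
#'
#' Row `t` of the result is `W_psi' h_t + b_psi`.
#'
#' @param hidden `T x D` matrix of per-residue hidden states.
#' @param params A [crf_params()] object.
#' @return `T x C` emission matrix.
#' @export
crf_emissions <- function(hidden, params) {
  if (ncol(hidden) != nrow(params$W_psi))
    stop("hidden dimension ", ncol(hidden), " does not match W_psi (",
         nrow(params$W_psi), ")")
  sweep(hidden %*% params$W_psi, 2, params$b_psi, "+")
}

# log of start/end indicator vectors
.log_ind <- function(b) ifelse(b, 0, -Inf)

# Forward recursion in log space. Returns the T x C matrix of log-alpha
# (including start constraints and emissions) and logZ.
crf_forward <- function(em, phi, start_allowed, end_allowed) {
  T <- nrow(em); C <- ncol(em)
  K <- suppressWarnings(max(phi[is.finite(phi)], 0))
  P0 <- exp(phi - K); P0[!is.finite(phi)] <- 0
  A <- matrix(-Inf, T, C)
  A[1, ] <- em[1, ] + .log_ind(start_allowed)
  if (T > 1) for (t in 2:T) {
    s <- max(A[t - 1, ])
    if (!is.finite(s)) break
    u <- as.vector(crossprod(P0, exp(A[t - 1, ] - s)))
    A[t, ] <- em[t, ] + log(u) + s + K
  }
  aT <- A[T, ] + .log_ind(end_allowed)
  s <- max(aT)
  logZ <- if (is.finite(s)) s + log(sum(exp(aT - s))) else -Inf
  list(A = A, logZ = logZ)
}

# Backward recursion in log space; B[T, ] = log(end indicator).
crf_backward <- function(em, phi, end_allowed) {
  T <- nrow(em); C <- ncol(em)
  K <- suppressWarnings(max(phi[is.finite(phi)], 0))
  P0 <- exp(phi - K); P0[!is.finite(phi)] <- 0
  B <- matrix(-Inf, T, C)
  B[T, ] <- .log_ind(end_allowed)
  if (T > 1) for (t in (T - 1):1) {
    x <- em[t + 1, ] + B[t + 1, ]
    s <- max(x)
    if (!is.finite(s)) break
    v <- as.vector(P0 %*% exp(x - s))
    B[t, ] <- log(v) + s + K
  }
  B
}

# Full forward-backward pass: log-alpha, log-beta, logZ and marginals.
crf_forward_backward <- function(em, params, space) {
  fw <- crf_forward(em, params$phi, space$start_allowed, space$end_allowed)
  if (!is.finite(fw$logZ)) stop("no allowed path through the lattice")
  B <- crf_backward(em, params$phi, space$end_allowed)
  logM <- fw$A + B - fw$logZ
  M <- exp(logM)
  M[!is.finite(logM)] <- 0
  list(A = fw$A, B = B, logZ = fw$logZ, M = M)
}

#' Log-partition function of the constrained CRF
#'
#' @param em `T x C` emissions.
#' @inheritParams crf_emissions
#' @param space State space (transition mask, start/end states).
#' @return `log Z` as a scalar.
#' @export
crf_log_partition <- function(em, params, space) {
  fw <- crf_forward(em, params$phi, space$start_allowed, space$end_allowed)
  if (!is.finite(fw$logZ)) stop("no allowed path through the lattice")
  fw$logZ
}

#' Per-position marginal state probabilities (forward-backward)
#'
#' @inheritParams crf_log_partition
#' @return `T x C` row-stochastic matrix; entries of mask-unreachable states
#'   are exactly 0.
#' @export
crf_marginals <- function(em, params, space) {
  crf_forward_backward(em, params, space)$M
}

#' Most probable state path (Viterbi decoding)
#'
#' Ties are broken deterministically towards the lowest state id at the
#' latest differing position.
#'
#' @inheritParams crf_log_partition
#' @return Integer vector of state row indices (1-based into
#'   `space$states`), with attribute `"score"` holding the path log-score.
#' @export
crf_viterbi <- function(em, params, space) {
  T <- nrow(em); C <- ncol(em)
  phi <- params$phi
  V <- em[1, ] + .log_ind(space$start_allowed)
  ptr <- matrix(0L, T, C)
  if (T > 1) for (t in 2:T) {
    MM <- phi + V            # MM[c', c] = V[c'] + phi[c', c]
    MM[!is.finite(MM)] <- -Inf
    p <- max.col(t(MM), ties.method = "first")
    ptr[t, ] <- p
    V <- em[t, ] + MM[cbind(p, seq_len(C))]
  }
  V <- V + .log_ind(space$end_allowed)
  if (!any(is.finite(V))) stop("no allowed path through the lattice")
  path <- integer(T)
  path[T] <- which.max(V)
  if (T > 1) for (t in T:2) path[t - 1] <- ptr[t, path[t]]
  structure(path, score = max(V))
}

#' Multitag negative log likelihood
#'
#' The weak-supervision likelihood marginalizes over all mask-allowed paths
#' that pass through the admissible tag set `M_t` at every position:
#' `NLL = log Z - log Z_constrained`, where the constrained partition sum
#' runs on the lattice with emissions outside `M_t` set to `-Inf`. With
#' singleton tag sets this reduces to the standard CRF path NLL.
#'
#' @inheritParams crf_log_partition
#' @param tags A `multitag_matrix` (list of integer vectors of admissible
#'   state row indices, length `T`).
#' @return Nonnegative scalar NLL.
#' @export
crf_multitag_nll <- function(em, params, space, tags) {
  T <- nrow(em)
  if (length(tags) != T) stop("tag matrix length != number of positions")
  emc <- constrain_emissions(em, tags)
  logZ <- crf_log_partition(em, params, space)
  fw <- crf_forward(emc, params$phi, space$start_allowed, space$end_allowed)
  if (!is.finite(fw$logZ)) {
    t_bad <- first_infeasible(params$phi, space, tags)
    stop("no allowed path through the tag sets (first infeasible position: ",
         t_bad, ")")
  }
  max(logZ - fw$logZ, 0)
}

# Emissions restricted to the admissible tag sets (-Inf elsewhere).
constrain_emissions <- function(em, tags) {
  emc <- matrix(-Inf, nrow(em), ncol(em))
  for (t in seq_along(tags)) emc[t, tags[[t]]] <- em[t, tags[[t]]]
  emc
}

# Boolean reachability scan to name the first position at which the
# tag-constrained lattice dies.
first_infeasible <- function(phi, space, tags) {
  C <- nrow(space$states)
  inset <- function(t) { z <- rep(FALSE, C); z[tags[[t]]] <- TRUE; z }
  r <- space$start_allowed & inset(1)
  if (!any(r)) return(1L)
  allowed <- space$allowed
  for (t in seq_along(tags)[-1]) {
    r <- (as.vector(crossprod(allowed, r)) > 0) & inset(t)
    if (!any(r)) return(t)
  }
  length(tags)
}

#' Global sequence-class probabilities from marginals
#'
#' Sums the per-position marginal probabilities of all states belonging to
#' each class and divides by the sequence length, turning the `T x C`
#' marginal matrix into a probability vector over the six classes.
#'
#' @param marg `T x C` row-stochastic marginal matrix.
#' @param space State space.
#' @return Named probability 6-vector over [SP_CLASSES], summing to 1.
#' @export
class_probs <- function(marg, space) {
  p <- vapply(SP_CLASSES, function(g) {
    sum(marg[, class_state_idx(space, g), drop = FALSE]) / nrow(marg)
  }, 0)
  names(p) <- SP_CLASSES
  p
}

#' Infer the cleavage site from a decoded state path
#'
#' The CS is the position of the last SP-region state in the path; cleavage
#' falls between it and the following residue. Paths with no SP states have
#' no CS.
#'
#' @param path Integer state path (row indices).
#' @param space State space.
#' @return 1-based CS position, or `NA_integer_`.
#' @export
infer_cs <- function(path, space) {
  sp <- which(space$states$is_sp_state[path])
  if (!length(sp)) return(NA_integer_)
  max(sp)
}
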