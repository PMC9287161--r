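# Gradient machinery for CRF training.
#
# The multitag NLL gradient is the classic expectation difference:
#   d NLL / d em  = M_unconstrained - M_constrained
#   d NLL / d phi = E[transition counts]_unconstrained - E[...]_constrained.
# The composition regularizer is a function of the marginals themselves, so
# its gradient needs a vector-Jacobian product through the forward-backward
# recursions; crf_marginal_vjp implements the exact reverse-mode adjoint of
# the log-space recursions.

# Expected transition counts: sum_t P(y_{t-1}=c', y_t=c | x) as a C x C
# matrix, from stored log-alpha/log-beta.
#
# Each pairwise-marginal slice factorizes as diag(u_t) P0 diag(v_t) with
# P0 = exp(phi - K), so the sum over t is P0 * crossprod(U, V) - one
# matrix product instead of T outer products. The per-step scalar shifts
# keep every stored row in exp range (xi entries are probabilities <= 1).
crf_transition_expectations <- function(em, phi, A, B, logZ) {
  T <- nrow(em); C <- ncol(em)
  E <- matrix(0, C, C)
  if (T < 2) return(E)
  K <- suppressWarnings(max(phi[is.finite(phi)], 0))
  P0 <- exp(phi - K); P0[!is.finite(phi)] <- 0
  U <- matrix(0, T - 1, C); V <- matrix(0, T - 1, C)
  for (t in 2:T) {
    sA <- max(A[t - 1, ])
    x <- em[t, ] + B[t, ]
    sB <- max(x)
    u <- exp(A[t - 1, ] - sA)
    v <- exp(x - sB + (sA + sB + K - logZ))
    u[!is.finite(u)] <- 0; v[!is.finite(v)] <- 0
    U[t - 1, ] <- u; V[t - 1, ] <- v
  }
  P0 * crossprod(U, V)
}

# Exact reverse-mode adjoint of the forward-backward marginals.
#
# Given bar_M = dL/dM for some scalar L(M), returns bar_em and bar_phi.
# A, B, logZ, M are the stored forward-backward quantities for (em, phi).
crf_marginal_vjp <- function(em, phi, space, A, B, logZ, M, bar_M) {
  T <- nrow(em); C <- ncol(em)
  bar_em <- matrix(0, T, C)
  bar_phi <- matrix(0, C, C)
  bar_A <- bar_M * M
  bar_B <- bar_M * M
  bar_logZ <- -sum(bar_A)

  # logZ = LSE(A[T, ] + log(end))
  pT <- exp(A[T, ] + .log_ind(space$end_allowed) - logZ)
  pT[!is.finite(pT)] <- 0
  bar_A[T, ] <- bar_A[T, ] + bar_logZ * pT

  K <- suppressWarnings(max(phi[is.finite(phi)], 0))
  P0 <- exp(phi - K); P0[!is.finite(phi)] <- 0
  P0t <- t(P0)

  # reverse the forward chain: A_t = em_t + LSE_{c'}(A_{t-1} + phi[c', .]).
  # The softmax weight matrix factorizes as diag(u) P0 diag(w), so the
  # propagation is u * (P0 %*% (w * bar)) and the bar_phi contributions
  # accumulate as P0 * crossprod(U, WB).
  if (T > 1) {
    Uacc <- matrix(0, T - 1, C); WBacc <- matrix(0, T - 1, C)
    for (t in T:2) {
      bar_em[t, ] <- bar_em[t, ] + bar_A[t, ]
      sA <- max(A[t - 1, ])
      u <- exp(A[t - 1, ] - sA)
      w <- exp(em[t, ] - A[t, ] + sA + K)
      u[!is.finite(u)] <- 0; w[!is.finite(w)] <- 0
      wb <- w * bar_A[t, ]
      Uacc[t - 1, ] <- u; WBacc[t - 1, ] <- wb
      bar_A[t - 1, ] <- bar_A[t - 1, ] + u * as.vector(P0 %*% wb)
    }
    bar_phi <- bar_phi + P0 * crossprod(Uacc, WBacc)
  }
  bar_em[1, ] <- bar_em[1, ] + bar_A[1, ]

  # reverse the backward chain: B_t = LSE_{c'}(phi[., c'] + em_{t+1} + B_{t+1});
  # weights factorize as diag(g) P0 diag(h).
  if (T > 1) {
    Gacc <- matrix(0, T - 1, C); Hacc <- matrix(0, T - 1, C)
    for (t in 1:(T - 1)) {
      x <- em[t + 1, ] + B[t + 1, ]
      s <- max(x)
      h <- exp(x - s)
      g <- exp(s + K - B[t, ])
      h[!is.finite(h)] <- 0; g[!is.finite(g)] <- 0
      gb <- g * bar_B[t, ]
      Gacc[t, ] <- gb; Hacc[t, ] <- h
      contrib <- h * as.vector(P0t %*% gb)
      bar_em[t + 1, ] <- bar_em[t + 1, ] + contrib
      bar_B[t + 1, ] <- bar_B[t + 1, ] + contrib
    }
    bar_phi <- bar_phi + P0 * crossprod(Gacc, Hacc)
  }
  bar_phi[!space$allowed] <- 0
  list(bar_em = bar_em, bar_phi = bar_phi)
}

# Loss pieces for one sequence during training: NLL value and gradients
# w.r.t. emissions and phi, plus the stored unconstrained forward-backward
# (reused by the regularizer).
crf_nll_grad <- function(em, params, space, tags) {
  fb <- crf_forward_backward(em, params, space)
  emc <- constrain_emissions(em, tags)
  fwc <- crf_forward(emc, params$phi, space$start_allowed, space$end_allowed)
  if (!is.finite(fwc$logZ)) {
    t_bad <- first_infeasible(params$phi, space, tags)
    stop("no allowed path through the tag sets (first infeasible position: ",
         t_bad, ")")
  }
  Bc <- crf_backward(emc, params$phi, space$end_allowed)
  logMc <- fwc$A + Bc - fwc$logZ
  Mc <- exp(logMc); Mc[!is.finite(logMc)] <- 0
  Ec <- crf_transition_expectations(emc, params$phi, fwc$A, Bc, fwc$logZ)
  Eu <- crf_transition_expectations(em, params$phi, fb$A, fb$B, fb$logZ)
  bar_phi <- Eu - Ec
  bar_phi[!space$allowed] <- 0
  list(nll = max(fb$logZ - fwc$logZ, 0),
       bar_em = fb$M - Mc, bar_phi = bar_phi, fb = fb)
}
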