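# Independent oracles used across the suite. These deliberately avoid the
# package's lattice code paths: path enumeration is explicit recursion,
# alignment is a second DP implementation, clustering uses igraph.

# --- brute-force path enumeration over a (small) masked lattice ----------

# All mask-allowed state paths of length T as a list of integer vectors.
enum_paths <- function(T, allowed, start_allowed, end_allowed) {
  C <- nrow(allowed)
  out <- list()
  rec <- function(path) {
    t <- length(path)
    if (t == T) {
      if (end_allowed[path[T]]) out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in which(allowed[path[t], ])) rec(c(path, nxt))
  }
  for (s in which(start_allowed)) rec(s)
  out
}

lse <- function(x) { m <- max(x); if (!is.finite(m)) -Inf else m + log(sum(exp(x - m))) }

path_score <- function(path, em, phi) {
  s <- sum(em[cbind(seq_along(path), path)])
  if (length(path) > 1)
    s <- s + sum(phi[cbind(path[-length(path)], path[-1])])
  s
}

# Enumeration-based logZ, marginals, best score, and multitag logZ.
oracle_lattice <- function(em, phi, start_allowed, end_allowed, allowed,
                           tags = NULL) {
  T <- nrow(em); C <- ncol(em)
  paths <- enum_paths(T, allowed, start_allowed, end_allowed)
  if (!is.null(tags)) {
    keep <- vapply(paths, function(p) all(mapply(function(s, tt) s %in% tt,
                                                 p, tags)), TRUE)
    paths <- paths[keep]
  }
  if (!length(paths))
    return(list(logZ = -Inf, marginals = NULL, best = -Inf))
  sc <- vapply(paths, path_score, 0, em = em, phi = phi)
  logZ <- lse(sc)
  w <- exp(sc - logZ)
  M <- matrix(0, T, C)
  for (k in seq_along(paths))
    M[cbind(seq_len(T), paths[[k]])] <- M[cbind(seq_len(T), paths[[k]])] + w[k]
  list(logZ = logZ, marginals = M, best = max(sc), paths = paths, scores = sc)
}

# Random small constrained lattice with at least one allowed path.
random_lattice <- function(Tmax = 5L, Cmax = 9L) {
  repeat {
    C <- sample(2:Cmax, 1)
    T <- sample(1:Tmax, 1)
    allowed <- matrix(runif(C * C) < 0.5, C, C)
    start_allowed <- runif(C) < 0.6
    end_allowed <- runif(C) < 0.6
    if (!any(start_allowed)) start_allowed[sample(C, 1)] <- TRUE
    if (!any(end_allowed)) end_allowed[sample(C, 1)] <- TRUE
    em <- matrix(rnorm(T * C, sd = 2), T, C)
    phi <- matrix(rnorm(C * C), C, C)
    phi[!allowed] <- -Inf
    if (length(enum_paths(T, allowed, start_allowed, end_allowed)))
      return(list(em = em, phi = phi, allowed = allowed,
                  start_allowed = start_allowed, end_allowed = end_allowed,
                  T = T, C = C))
  }
}

# Wrap a raw lattice as the state-space / params objects the package takes.
as_space <- function(lat) {
  C <- lat$C
  structure(list(
    states = data.frame(id = seq_len(C) - 1L, class = rep("NO_SP", C),
                        tag = rep("I", C), is_sp_state = FALSE),
    allowed = lat$allowed, start_allowed = lat$start_allowed,
    end_allowed = lat$end_allowed), class = "sp_state_space")
}

as_params <- function(lat) {
  structure(list(W_psi = diag(lat$C), b_psi = numeric(lat$C), phi = lat$phi),
            class = "crf_params")
}

# --- independent Gotoh affine-gap Needleman-Wunsch -----------------------

# Global alignment score with BLOSUM62 and gap cost open + k * extend for a
# gap of length k (matches pairwiseAlignment's gapOpening/gapExtension).
oracle_nw_score <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)   # X: gap in y (x aligned to -)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[x[i - 1], y[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Identity from the oracle DP with traceback (diagonal-preferring).
oracle_nw_identity <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[x[i - 1], y[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
  }
  i <- n + 1; j <- m + 1
  state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  len <- 0L; ident <- 0L
  while (i > 1 || j > 1) {
    len <- len + 1L
    if (state == "M") {
      if (x[i - 1] == y[j - 1]) ident <- ident + 1L
      s <- S[x[i - 1], y[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- c("M", "X", "Y")[which.max(prev)]
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      from_m <- M[i - 1, j] - open - extend
      state <- if (X[i, j] == from_m ||
                   from_m >= X[i - 1, j] - extend) "M" else "X"
      if (i == 2 && j == 1) state <- "M"
      i <- i - 1
    } else {
      from_m <- M[i, j - 1] - open - extend
      state <- if (Y[i, j] == from_m ||
                   from_m >= Y[i, j - 1] - extend) "M" else "Y"
      if (j == 2 && i == 1) state <- "M"
      j <- j - 1
    }
    if (i == 1 && j > 1) state <- "Y"
    if (j == 1 && i > 1) state <- "X"
  }
  ident / len
}

# --- misc ---------------------------------------------------------------

rand_aa <- function(n) paste(sample(names(sigcrf::KD_SCALE), n,
                                    replace = TRUE), collapse = "")

# Mutated-copy pair whose optimal alignment is essentially unique (the
# regime in which "identity" is well defined across implementations;
# unrelated random pairs have many co-optimal alignments with differing
# match counts, so only their scores are comparable).
related_pair <- function(len_range = 30:60, rate_range = c(0.05, 0.65)) {
  n <- sample(len_range, 1)
  a <- rand_aa(n)
  rate <- runif(1, rate_range[1], rate_range[2])
  ch <- strsplit(a, "")[[1]]
  mut <- which(runif(n) < rate)
  if (length(mut))
    ch[mut] <- sample(names(sigcrf::KD_SCALE), length(mut), replace = TRUE)
  if (runif(1) < 0.5) ch <- ch[-sample(n - 5, 1)]
  if (runif(1) < 0.5)
    ch <- append(ch, sample(names(sigcrf::KD_SCALE), 1),
                 after = sample(length(ch), 1))
  list(a = a, b = paste(ch, collapse = ""))
}

# Random tag sets (1-3 admissible states per position) for a lattice.
random_tags <- function(lat) {
  structure(lapply(seq_len(lat$T), function(t)
    sort(sample(lat$C, sample(seq_len(min(3L, lat$C)), 1)))),
    class = "multitag_matrix")
}

# Tiny training set for smoke tests.
toy_records <- function(n_per_class = 4, seed = 42) {
  cfg <- generator_config(counts = c(NO_SP = n_per_class,
                                     SEC_SPI = n_per_class),
                          seed = seed)
  generate_dataset(cfg)
}
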