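# Desk-scale sequence encoder.
#
# Stand-in for a large protein language model: a learned residue embedding,
# plus organism-group and position embeddings, combined over a symmetric
# residue window by a linear layer with tanh nonlinearity. Output is a
# T x D matrix of hidden states aligned to the input residues (boundary
# positions see a learned padding token playing the role of the sequence
# start/end markers). Deterministic given parameters and input.

ENC_VOCAB <- c(AA20, "UNK", "PAD")   # residue tokens; PAD marks boundaries

#' Initialize encoder parameters
#'
#' @param D Hidden state dimension (default 64).
#' @param E Embedding dimension per token (default 8).
#' @param window Half-width of the residue window (default 3, i.e. 7
#'   residues feed each position).
#' @param pos_max Positions beyond `pos_max` share one position embedding
#'   (signal peptides are N-terminal, so only early positions need to be
#'   distinguished).
#' @return An `sp_encoder` parameter list.
#' @export
encoder_init <- function(D = 64L, E = 8L, window = 3L, pos_max = 50L) {
  nwin <- 2L * window + 1L
  din <- (nwin + 2L) * E   # window residues + group + position
  rn <- function(n, m, s) matrix(stats::rnorm(n * m, sd = s), n, m)
  structure(list(
    D = D, E = E, window = window, pos_max = pos_max,
    emb = rn(length(ENC_VOCAB), E, 0.3),
    gemb = rn(length(ORGANISM_GROUPS_EXT), E, 0.3),
    pemb = rn(pos_max, E, 0.3),
    W1 = rn(din, D, sqrt(1 / din)),
    b1 = numeric(D)
  ), class = "sp_encoder")
}

# Residue characters -> token indices (non-standard residues -> UNK).
tokenize <- function(sequence) {
  ch <- split_chars(toupper(sequence))
  ix <- match(ch, AA20)
  ix[is.na(ix)] <- length(AA20) + 1L
  ix
}

# Input feature matrix: concatenated window embeddings + group + position.
encoder_features <- function(tokens, group, enc) {
  T <- length(tokens)
  w <- enc$window; E <- enc$E
  pad <- length(ENC_VOCAB)
  blocks <- lapply(-w:w, function(o) {
    ix <- seq_len(T) + o
    tok <- ifelse(ix >= 1L & ix <= T, tokens[pmax(pmin(ix, T), 1L)], pad)
    enc$emb[tok, , drop = FALSE]
  })
  gix <- match(group, ORGANISM_GROUPS_EXT)
  pix <- pmin(seq_len(T), enc$pos_max)
  F <- do.call(cbind, c(blocks,
                        list(matrix(enc$gemb[gix, ], T, E, byrow = TRUE),
                             enc$pemb[pix, , drop = FALSE])))
  F
}

# Forward pass keeping intermediates for backprop.
encoder_forward <- function(tokens, group, enc) {
  F <- encoder_features(tokens, group, enc)
  H <- tanh(sweep(F %*% enc$W1, 2, enc$b1, "+"))
  list(H = H, F = F, tokens = tokens, group = group)
}

#' Encode a sequence into per-residue hidden states
#'
#' @param sequence Amino acid string (non-standard residues map to UNK).
#' @param group_token One of [ORGANISM_GROUPS] or `"UNKNOWN"`.
#' @param enc Encoder parameters from [encoder_init()].
#' @return `T x D` matrix of hidden states, `T = nchar(sequence)`.
#' @export
encode_sequence <- function(sequence, group_token, enc) {
  if (!nzchar(sequence)) stop("cannot encode an empty sequence")
  check_group(group_token)
  encoder_forward(tokenize(sequence), group_token, enc)$H
}

# Backprop through the encoder. fwd is an encoder_forward() result, bar_H
# the upstream gradient. Returns gradients for every encoder parameter.
encoder_backward <- function(fwd, bar_H, enc) {
  T <- length(fwd$tokens)
  w <- enc$window; E <- enc$E
  bar_pre <- bar_H * (1 - fwd$H^2)
  g <- list(W1 = crossprod(fwd$F, bar_pre), b1 = colSums(bar_pre))
  bar_F <- tcrossprod(bar_pre, enc$W1)
  g$emb <- matrix(0, nrow(enc$emb), E)
  pad <- length(ENC_VOCAB)
  for (k in seq_len(2L * w + 1L)) {
    o <- k - w - 1L
    ix <- seq_len(T) + o
    tok <- ifelse(ix >= 1L & ix <= T, fwd$tokens[pmax(pmin(ix, T), 1L)], pad)
    blk <- bar_F[, ((k - 1L) * E + 1L):(k * E), drop = FALSE]
    acc <- rowsum(blk, tok)
    g$emb[as.integer(rownames(acc)), ] <- g$emb[as.integer(rownames(acc)), ] + acc
  }
  nb <- 2L * w + 1L
  gblk <- bar_F[, (nb * E + 1L):((nb + 1L) * E), drop = FALSE]
  g$gemb <- matrix(0, nrow(enc$gemb), E)
  gix <- match(fwd$group, ORGANISM_GROUPS_EXT)
  g$gemb[gix, ] <- colSums(gblk)
  pblk <- bar_F[, ((nb + 1L) * E + 1L):((nb + 2L) * E), drop = FALSE]
  pix <- pmin(seq_len(T), enc$pos_max)
  pacc <- rowsum(pblk, pix)
  g$pemb <- matrix(0, nrow(enc$pemb), E)
  g$pemb[as.integer(rownames(pacc)), ] <- pacc
  g
}
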