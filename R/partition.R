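# Homology-aware dataset partitioning.
#
# Pairwise global identities (Needleman-Wunsch, BLOSUM62, gap open 11 /
# extend 1, identity = identical aligned positions / alignment length
# including gap columns), single-linkage clustering at the identity
# threshold, greedy balanced assignment of clusters to partitions per
# class, and iterative removal of sequences violating the cross-partition
# threshold. Whole-matrix computation is O(N^2) alignments - intended for
# desk-scale sets.

.nw_align <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11, extend 1);
#' identity is the fraction of identical aligned positions over the full
#' alignment length, gap columns included.
#'
#' @param a,b Amino acid sequences.
#' @return Identity in `[0, 1]`, with the alignment score as attribute
#'   `"score"`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  al <- .nw_align(a, b)
  p <- split_chars(as.character(Biostrings::alignedPattern(al)))
  s <- split_chars(as.character(Biostrings::alignedSubject(al)))
  structure(sum(p == s & p != "-") / length(p),
            score = Biostrings::score(al))
}

# Symmetric identity matrix for a character vector of sequences.
identity_matrix <- function(seqs) {
  n <- length(seqs)
  M <- diag(1, n)
  if (n > 1) for (j in 2:n) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[seq_len(j - 1)]),
      Biostrings::AAString(seqs[j]), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")
    M[seq_len(j - 1), j] <- M[j, seq_len(j - 1)] <-
      mapply(function(pp, ss) sum(pp == ss & pp != "-") / length(pp), p, s)
  }
  M
}

#' Single-linkage clusters at an identity threshold
#'
#' Connected components of the graph whose edges are sequence pairs with
#' identity strictly above the threshold (union-find).
#'
#' @param idm Symmetric identity matrix.
#' @param threshold Identity threshold in `(0, 1)`.
#' @return Integer vector of cluster memberships (1-based, by order of
#'   first member).
#' @export
single_linkage <- function(idm, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  n <- nrow(idm)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (idm[i, j] > threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# Greedy balanced assignment of clusters to partitions: clusters sorted by
# size descending, each placed in the partition minimizing the partition
# size plus a weighted organism-group imbalance.
.assign_clusters <- function(clusters, groups, n_partitions, balance_weight = 0.5) {
  sizes <- table(clusters)
  order_cl <- as.integer(names(sort(sizes, decreasing = TRUE)))
  glob <- prop.table(table(factor(groups, levels = ORGANISM_GROUPS)))
  pcount <- numeric(n_partitions)
  pgroup <- matrix(0, n_partitions, length(ORGANISM_GROUPS),
                   dimnames = list(NULL, ORGANISM_GROUPS))
  part_of_cluster <- integer(max(clusters))
  for (cl in order_cl) {
    members <- which(clusters == cl)
    addg <- table(factor(groups[members], levels = ORGANISM_GROUPS))
    score <- vapply(seq_len(n_partitions), function(p) {
      newc <- pcount[p] + length(members)
      newg <- pgroup[p, ] + addg
      imb <- sum(abs(newg - newc * glob))
      newc + balance_weight * imb
    }, 0)
    p <- which.min(score)
    part_of_cluster[cl] <- p
    pcount[p] <- pcount[p] + length(members)
    pgroup[p, ] <- pgroup[p, ] + addg
  }
  part_of_cluster[clusters]
}

#' Homology-partition a labeled dataset
#'
#' Runs the partitioning procedure separately for each of the six classes
#' (pairwise identities, single-linkage clusters, greedy organism-balanced
#' assignment to `n_partitions`), concatenates the per-class partitions,
#' then iteratively removes the sequence with the most cross-partition
#' identity violations (ties to the smaller id) until no pair of sequences
#' in different partitions exceeds the threshold.
#'
#' @param records List of [annotated_sp()] records.
#' @param threshold Maximum cross-partition identity (default 0.30).
#' @param n_partitions Number of partitions (default 3).
#' @param balance_weight Weight of the organism-group imbalance term in the
#'   greedy cluster assignment.
#' @return List of class `sp_partition_result`: `assignment` (named
#'   integer, partition 1..n or `NA` for removed), `removed` (data.frame
#'   id, max cross-partition identity, nearest neighbor), `counts`
#'   (partition x class table), `identity` (full identity matrix, rows in
#'   record order).
#' @export
partition_dataset <- function(records, threshold = 0.30, n_partitions = 3L,
                              balance_weight = 0.5) {
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate record ids")
  seqs <- vapply(records, `[[`, "", "sequence")
  classes <- vapply(records, `[[`, "", "sp_class")
  groups <- vapply(records, `[[`, "", "organism_group")
  n <- length(records)
  idm <- identity_matrix(seqs)
  dimnames(idm) <- list(ids, ids)

  assignment <- rep(NA_integer_, n)
  names(assignment) <- ids
  for (cls in SP_CLASSES) {
    ix <- which(classes == cls)
    if (!length(ix)) next
    cl <- single_linkage(idm[ix, ix, drop = FALSE], threshold)
    if (length(unique(cl)) < n_partitions)
      warning("class ", cls, " has fewer clusters (", length(unique(cl)),
              ") than partitions; some partitions get no ", cls, " sequences")
    assignment[ix] <- .assign_clusters(cl, groups[ix], n_partitions,
                                       balance_weight)
  }

  # iterative removal of cross-partition violators
  removed <- integer(0)
  repeat {
    act <- which(!is.na(assignment) & !(seq_len(n) %in% removed))
    viol <- matrix(FALSE, n, n)
    if (length(act) > 1) {
      sub <- idm[act, act, drop = FALSE] > threshold &
        outer(assignment[act], assignment[act], "!=")
      diag(sub) <- FALSE
      viol[act, act] <- sub
    }
    cnt <- rowSums(viol)
    if (!any(cnt > 0)) break
    worst <- which.max(cnt)   # ties -> smallest index (record order)
    removed <- c(removed, worst)
    assignment[worst] <- NA_integer_
  }

  removed_df <- NULL
  if (length(removed)) {
    removed_df <- do.call(rbind, lapply(removed, function(i) {
      other <- which(!is.na(assignment))
      mx <- if (length(other)) max(idm[i, other]) else NA_real_
      nb <- if (length(other)) ids[other[which.max(idm[i, other])]] else NA_character_
      data.frame(id = ids[i], max_identity = mx, nearest = nb,
                 stringsAsFactors = FALSE)
    }))
  }
  counts <- table(partition = assignment[!is.na(assignment)],
                  class = classes[!is.na(assignment)])
  structure(list(assignment = assignment, removed = removed_df,
                 counts = counts, identity = idm),
            class = "sp_partition_result")
}

#' Bin sequences by maximum identity to a training set
#'
#' @param removed_records,training_records Lists of records (or character
#'   vectors of sequences).
#' @param bin_edges Increasing numeric vector of bin edges; sequence with
#'   maximum identity `x` falls in the bin `[e_k, e_{k+1})` (last bin
#'   closed above).
#' @return data.frame with id, max identity and bin label per removed
#'   sequence.
#' @export
bin_by_max_identity <- function(removed_records, training_records,
                                bin_edges = seq(0.3, 1, by = 0.1)) {
  getseq <- function(x) if (is.character(x)) x else vapply(x, `[[`, "", "sequence")
  getid <- function(x) if (is.character(x)) {
    if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x)
  } else vapply(x, `[[`, "", "id")
  tr <- getseq(training_records)
  if (!length(tr)) stop("empty training set")
  rs <- getseq(removed_records)
  mx <- vapply(rs, function(s)
    max(vapply(tr, function(t) as.numeric(pairwise_identity(s, t)), 0)), 0)
  k <- findInterval(mx, bin_edges, rightmost.closed = TRUE)
  lab <- ifelse(k == 0, sprintf("<%.2f", bin_edges[1]),
                sprintf("[%.2f,%.2f)", bin_edges[k],
                        c(bin_edges, Inf)[k + 1]))
  data.frame(id = getid(removed_records), max_identity = unname(mx),
             bin = lab, stringsAsFactors = FALSE)
}
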