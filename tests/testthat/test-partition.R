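test_that("pairwise identity behaves on canonical cases", {
  expect_equal(as.numeric(pairwise_identity("HEAGAWGHEE", "HEAGAWGHEE")), 1)
  # fully dissimilar, no gaps opened at equal length
  expect_equal(as.numeric(pairwise_identity("AAAA", "TTTT")), 0)
  expect_error(pairwise_identity("", "AAA"), "empty")
})

test_that("identity and score match the independent Gotoh DP oracle", {
  set.seed(99)
  for (k in 1:12) {
    p <- related_pair()
    id <- pairwise_identity(p$a, p$b)
    expect_identical(attr(id, "score"), oracle_nw_score(p$a, p$b))
    # co-optimal alignments may differ slightly in match count between
    # tracebacks; scores agree exactly, identity to 0.05
    expect_equal(as.numeric(id), oracle_nw_identity(p$a, p$b),
                 tolerance = 0.05)
  }
  # unrelated pairs: many co-optimal alignments, so scores only
  for (k in 1:5) {
    a <- rand_aa(sample(20:40, 1)); b <- rand_aa(sample(20:40, 1))
    expect_identical(attr(pairwise_identity(a, b), "score"),
                     oracle_nw_score(a, b))
  }
  expect_equal(as.numeric(pairwise_identity("HEAGAWGHEE", "PAWHEAE")),
               oracle_nw_identity("HEAGAWGHEE", "PAWHEAE"))
})

test_that("single linkage equals connected components (igraph oracle)", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (k in 1:5) {
    n <- 20
    idm <- matrix(runif(n * n, 0, 0.6), n, n)
    idm[lower.tri(idm)] <- t(idm)[lower.tri(idm)]
    diag(idm) <- 1
    cl <- single_linkage(idm, 0.3)
    g <- igraph::graph_from_adjacency_matrix(idm > 0.3, mode = "undirected",
                                             diag = FALSE)
    mem <- igraph::components(g)$membership
    # same partition of indices (labels may differ)
    expect_equal(length(unique(cl)), max(mem))
    expect_true(all(tapply(mem, cl, function(x) length(unique(x))) == 1))
  }
  # chain transitivity: a-b and b-c above, a-c below -> one cluster
  idm <- diag(1, 3)
  idm[1, 2] <- idm[2, 1] <- 0.5
  idm[2, 3] <- idm[3, 2] <- 0.5
  idm[1, 3] <- idm[3, 1] <- 0.1
  expect_equal(single_linkage(idm, 0.3), c(1L, 1L, 1L))
  # all below threshold -> singletons
  expect_equal(single_linkage(diag(1, 4), 0.3), 1:4)
})

test_that("partitioning the homology fixture enforces the hard threshold", {
  fams <- generate_homology_families(seed = 3)
  res <- partition_dataset(fams)
  asg <- res$assignment
  expect_true(all(table(asg) > 0))
  # exhaustive cross-partition scan: zero pairs above threshold
  idm <- res$identity
  act <- which(!is.na(asg))
  cross <- outer(asg[act], asg[act], "!=") & idm[act, act] > 0.3
  expect_false(any(cross))
  # families stay together (well-separated fixture, nothing removed)
  expect_null(res$removed)
  fam <- vapply(fams, `[[`, 0, "family")
  expect_true(all(tapply(asg, fam, function(x) length(unique(x))) == 1))
})

test_that("forced duplicates are removed minimally", {
  set.seed(30)
  base <- generate_homology_families(n_families = 3, members = 3, seed = 8)
  # plant a near-duplicate of a family-1 sequence inside another family's
  # class-free record set by relabeling its id
  dup <- base[[1]]
  dup$id <- "dup_of_fam1"
  dup$sequence <- base[[1]]$sequence
  recs <- c(base, list(dup))
  res <- partition_dataset(recs)
  asg <- res$assignment
  act <- which(!is.na(asg))
  idm <- res$identity
  cross <- outer(asg[act], asg[act], "!=") & idm[act, act] > 0.3
  expect_false(any(cross))
  # the duplicate clusters with family 1, so either nothing was removed
  # (same partition) or exactly the minimal violator was dropped
  if (!is.null(res$removed)) expect_lte(nrow(res$removed), 1L)
})

test_that("group proportions stay near global proportions on a balanced fixture", {
  fams <- generate_homology_families(n_families = 12, members = 3, seed = 5)
  res <- partition_dataset(fams)
  grp <- vapply(fams, `[[`, "", "organism_group")
  asg <- res$assignment
  glob <- prop.table(table(grp))
  for (p in unique(na.omit(asg))) {
    pp <- prop.table(table(factor(grp[which(asg == p)], levels = names(glob))))
    expect_true(all(abs(pp - glob) <= 0.25))
  }
})

test_that("binning by max train identity follows interval arithmetic", {
  tr <- c(t1 = "MKKLLLLLASTGA", t2 = "WWWWYYYYFFFF")
  edges <- c(0.2, 0.4, 0.6, 0.8)
  # identical to a training sequence -> top bin
  b <- bin_by_max_identity(c(q = "MKKLLLLLASTGA"), tr, edges)
  expect_equal(b$max_identity, 1)
  expect_equal(b$bin, "[0.80,Inf)")
  # brute-force agreement on a small fixture
  set.seed(23)
  qs <- vapply(1:6, function(i) rand_aa(15), "")
  names(qs) <- paste0("q", 1:6)
  b2 <- bin_by_max_identity(qs, tr, edges)
  brute <- vapply(qs, function(q)
    max(as.numeric(pairwise_identity(q, tr[[1]])),
        as.numeric(pairwise_identity(q, tr[[2]]))), 0)
  expect_equal(b2$max_identity, unname(brute))
  expect_error(bin_by_max_identity(qs, character(0), edges), "empty")
})
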