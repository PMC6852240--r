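fake_pool <- function(identities, L = 30) {
  q <- strrep("A", L)
  homolog_pool(q, tibble::tibble(
    name = sprintf("h%02d", seq_along(identities)),
    seq = rep(q, length(identities)),
    identity = identities))
}

test_that("subset sampling stratifies the four identity bins into quarters", {
  pool <- fake_pool(rep(c(25, 45, 65, 85), each = 12))
  subs <- sample_subsets(pool, n_subsets = 5, subset_size = 8, seed = 1)
  expect_length(subs, 5)
  idmap <- setNames(pool$homologs$identity, pool$homologs$name)
  for (s in subs) {
    expect_length(s, 8)
    expect_equal(anyDuplicated(s), 0)
    counts <- table(cut(idmap[s], c(20, 40, 60, 80, 98)))
    expect_true(all(counts == 2))
  }
})

test_that("out-of-range homologs are excluded and deficits are redistributed", {
  # identities 10 and 99/100 fall outside (20, 98]
  pool <- fake_pool(c(10, 99, 100, rep(25, 10), rep(85, 2)))
  subs <- sample_subsets(pool, n_subsets = 3, subset_size = 8, seed = 2)
  idmap <- setNames(pool$homologs$identity, pool$homologs$name)
  for (s in subs) {
    expect_length(s, 8)
    expect_true(all(idmap[s] > 20 & idmap[s] <= 98))
    # only two bins occupied: the 80-98 bin holds 2, the rest comes from 20-39
    expect_equal(sum(idmap[s] == 85), 2)
    expect_equal(sum(idmap[s] == 25), 6)
  }
  # degenerate pool: everything in one bin
  one_bin <- fake_pool(rep(30, 10))
  subs1 <- sample_subsets(one_bin, n_subsets = 2, subset_size = 6, seed = 1)
  expect_true(all(vapply(subs1, length, integer(1)) == 6))
  # pool smaller than the subset size collapses to a single full subset
  expect_warning(small <- sample_subsets(fake_pool(c(30, 50)), 4, 5, seed = 1),
                 "whole pool")
  expect_length(small, 1)
  expect_setequal(small[[1]], c("h01", "h02"))
})

test_that("subset sampling is deterministic for a fixed seed", {
  pool <- fake_pool(rep(c(25, 45, 65, 85), each = 6))
  expect_identical(sample_subsets(pool, 4, 8, seed = 7),
                   sample_subsets(pool, 4, 8, seed = 7))
  expect_false(identical(sample_subsets(pool, 4, 8, seed = 7),
                         sample_subsets(pool, 4, 8, seed = 8)))
})

test_that("alignment distances count mismatches over comparable columns only", {
  expect_equal(distance_matrix(c(a = "AAAA", b = "AAAA"))[1, 2], 0)
  expect_equal(distance_matrix(c(a = "AAAA", b = "AATA"))[1, 2], 0.25)
  expect_equal(distance_matrix(c(a = "A-CG", b = "AACG"))[1, 2], 0)
  d <- distance_matrix(c(a = "AACG", b = "ATCG", c = "TTTT"))
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_error(distance_matrix(c(a = "--", b = "AA")), "comparable")
  expect_error(distance_matrix(c(a = "AA", b = "AAA")), "lengths")
})

test_that("NJ small cases use the closed-form branch lengths", {
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$edge.length), c(0.5, 0.5))
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(d3)
  # three-point formulas: v_a = (d_ab + d_ac - d_bc)/2, etc.
  v <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(v[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.2, 1)
    d <- ape::cophenetic.phylo(tr)
    d <- d[order(rownames(d)), order(colnames(d))]
    rec <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), rec)), 0)
  }
})

test_that("trace levels match exhaustive node enumeration on a hand-built tree", {
  tr <- ape::read.tree(text = "((query:1,h1:1):1,(h2:1,h3:1):1);")
  aln <- c(query = "AAC", h1 = "AAA", h2 = "ATA", h3 = "AAA")
  got <- trace_levels(tr, aln, "query")
  # col 1: conserved across all leaves -> root level 0
  # col 2: query's A present in (query,h1) clade only -> level 1
  # col 3: query-only amino acid -> no trace, level L
  expect_equal(got$level, c(0, 1, got$L[3]))
  expect_equal(got$traced, c(TRUE, TRUE, FALSE))
  # exhaustive oracle: scan ALL internal nodes containing the query leaf
  rl <- surfpatch:::root_and_levels(tr)
  rt <- rl$tree
  ntip <- ape::Ntip(rt)
  M <- do.call(rbind, strsplit(aln[rt$tip.label], ""))
  qrow <- match("query", rt$tip.label)
  for (j in 1:3) {
    best <- NA
    for (node in (ntip + 1):(ntip + rt$Nnode)) {
      tips <- unlist(phangorn::Descendants(rt, node, "tips"))
      if (!(qrow %in% tips)) next
      if (all(M[tips, j] == M[qrow, j])) {
        best <- min(best, rl$depth[node], na.rm = TRUE)
      }
    }
    if (is.na(best)) {
      expect_false(got$traced[j])
    } else {
      expect_equal(got$level[j], best)
    }
  }
})

test_that("T_JET follows the trace-average formula and its limits", {
  mk <- function(level, L, traced = TRUE, tree = 1) {
    tibble::tibble(position = 1, level = level, L = L, traced = traced,
                   tree = tree)
  }
  # conserved at the root in every tree -> 1
  expect_equal(compute_tjet(rbind(mk(0, 4, tree = 1), mk(0, 2, tree = 2)))$tjet, 1)
  # trace at the deepest level wherever defined -> 0
  expect_equal(compute_tjet(rbind(mk(4, 4, tree = 1), mk(2, 2, tree = 2)))$tjet, 0)
  # (L=4, l=2) and (L=2, l=1): (0.5 + 0.5)/2 = 0.5
  two <- compute_tjet(rbind(mk(2, 4, tree = 1), mk(1, 2, tree = 2)))
  expect_equal(two$tjet, 0.5)
  expect_equal(two$m, 2)
  # untraced trees are excluded from M_j; no trace anywhere scores 0
  part <- compute_tjet(rbind(mk(0, 4, tree = 1), mk(4, 4, FALSE, tree = 2)))
  expect_equal(part$m, 1)
  expect_equal(part$tjet, 1)
  none <- compute_tjet(mk(4, 4, FALSE))
  expect_equal(none$tjet, 0)
  expect_equal(none$m, 0)
})

test_that("planted conserved columns outrank the background and the pipeline is deterministic", {
  tj <- compute_conservation(POOL_A, seed = 5)
  expect_true(all(tj$tjet >= 0 & tj$tjet <= 1))
  expect_equal(tj$tjet[WIN_A], rep(1, length(WIN_A)))
  expect_gt(min(tj$tjet[WIN_A]), max(tj$tjet[-WIN_A]))
  expect_identical(tj, compute_conservation(POOL_A, seed = 5))
})
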