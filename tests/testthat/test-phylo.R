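# Tree I/O, midpoint rooting, monophyly, root-edge enumeration, clade
# cover and fusion-event parsimony, all checked against brute-force
# oracles and independent implementations.

test_that("newick I/O round-trips and reports malformed input", {
  tmp <- withr::local_tempdir()
  tr <- read_newick(text = "((A:1,B:2):0.5,C:3);")
  expect_equal(ape::Ntip(tr), 3)
  p <- file.path(tmp, "t.nwk")
  write_newick(tr, p)
  back <- read_newick(p)
  expect_identical(back$tip.label, tr$tip.label)
  expect_equal(back$edge.length, tr$edge.length)
  # absent branch lengths stay absent, not zero
  expect_null(read_newick(text = "(A,B);")$edge.length)
  expect_error(read_newick(text = "((A,B);"), "offset")
  expect_error(read_newick(text = "(A,B));"), "offset 6")
  expect_error(read_newick(text = "((A,B),(A,C));"), "duplicate")
})

test_that("midpoint rooting halves the diameter path", {
  # two tips: root 2 from each
  r2 <- midpoint_root(read_newick(text = "(A:1,B:3);"))
  d <- ape::dist.nodes(r2)
  root <- ape::Ntip(r2) + 1
  expect_equal(unname(d[root, 1:2]), c(2, 2))
  # balanced quartet: root on the internal edge, height 2
  q <- midpoint_root(read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  dq <- ape::dist.nodes(q)
  expect_equal(max(dq[ape::Ntip(q) + 1, 1:4]), 2)
  expect_error(midpoint_root(read_newick(text = "(A,B);")),
               "branch lengths")
})

test_that("midpoint root height equals the brute-force minimum", {
  for (seed in 1:10) {
    set.seed(seed)
    tr <- ape::unroot(ape::rtree(20))
    rooted <- midpoint_root(tr)
    droot <- ape::dist.nodes(rooted)
    height <- max(droot[ape::Ntip(rooted) + 1, seq_len(ape::Ntip(rooted))])
    expect_equal(height, oracle_min_height(tr), tolerance = 1e-6)
    # the unrooted tip-to-tip metric is preserved
    expect_equal(ape::cophenetic.phylo(rooted)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-8)
  }
})

test_that("midpoint rooting agrees with phangorn's implementation", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    set.seed(seed)
    tr <- ape::unroot(ape::rtree(15))
    mine <- midpoint_root(tr)
    theirs <- phangorn::midpoint(tr)
    h <- function(x) max(ape::dist.nodes(x)[ape::Ntip(x) + 1,
                                            seq_len(ape::Ntip(x))])
    expect_equal(h(mine), h(theirs), tolerance = 1e-8)
  }
})

test_that("monophyly matches the MRCA-descendant definition", {
  tr <- read_newick(text = "((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D")))
  expect_true(is_monophyletic(tr, "C"))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown tip")
  # cross-check against ape on random trees and random tip sets
  for (seed in 1:20) {
    set.seed(seed)
    t <- ape::rtree(8)
    tips <- sample(t$tip.label, sample(2:6, 1))
    expect_identical(is_monophyletic(t, tips),
                     ape::is.monophyletic(t, tips))
  }
})

test_that("monophyly-compatible root edges match the reroot oracle", {
  # quartet: 3 of the 5 edges leave {A,B} monophyletic
  q <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  r <- monophyly_roots(q, c("A", "B"))
  expect_length(r, 3)
  expect_identical(sort(unname(r)),
                   sort(oracle_monophyly_roots(attr(r, "tree"),
                                               c("A", "B"))))
  # a singleton is monophyletic under any rooting
  r1 <- monophyly_roots(q, "A")
  expect_length(r1, nrow(attr(r1, "tree")$edge))
  expect_warning(monophyly_roots(q, c("A", "B", "C", "D")), "all tips")
  # random trees and tip sets, scattered ones included
  for (seed in 1:15) {
    set.seed(seed)
    t8 <- ape::rtree(8)
    tips <- sample(t8$tip.label, sample(2:6, 1))
    r8 <- monophyly_roots(t8, tips)
    expect_identical(sort(as.integer(r8)),
                     sort(oracle_monophyly_roots(attr(r8, "tree"), tips)))
  }
})

test_that("clade cover counts maximal pure clades", {
  tr <- read_newick(text = "((A,B),(C,D));")
  expect_equal(min_clade_cover(tr, c("A", "B")), 1)
  expect_equal(min_clade_cover(tr, c("A", "C")), 2)
  expect_equal(min_clade_cover(tr, c("A", "B", "C")), 2)
  expect_error(min_clade_cover(tr, c("A", "Z")), "unknown tip")
  for (seed in 1:20) {
    set.seed(seed)
    t <- ape::rtree(9)
    tips <- sample(t$tip.label, sample(2:7, 1))
    cover <- min_clade_cover(t, tips)
    expect_equal(cover, oracle_clade_cover(t, tips))
    # equivalence with monophyly
    expect_identical(cover == 1L, is_monophyletic(t, tips))
  }
})

test_that("unordered fusion parsimony equals the exhaustive minimum", {
  tr <- read_newick(text = "((A,B),(C,D));")
  expect_equal(fitch_fusion_events(tr, c(A = 1, B = 1, C = 1, D = 1)), 0)
  expect_equal(fitch_fusion_events(tr, c(A = 1, B = 0, C = 1, D = 0)), 2)
  expect_error(fitch_fusion_events(tr, c(A = 1, B = 2, C = 0, D = 0)),
               "binary")
  expect_error(fitch_fusion_events(tr, c(A = 1, B = 0, C = 0)),
               "missing")
  for (seed in 1:15) {
    set.seed(seed)
    t <- ape::rtree(8)
    st <- stats::setNames(sample(0:1, 8, replace = TRUE), t$tip.label)
    expect_equal(fitch_fusion_events(t, st), oracle_fitch(t, st))
  }
})

test_that("parsimony agrees with phangorn and is rooting-invariant", {
  skip_if_not_installed("phangorn")
  for (seed in 1:8) {
    set.seed(seed)
    t <- ape::rtree(10)
    st <- stats::setNames(sample(0:1, 10, replace = TRUE), t$tip.label)
    dat <- phangorn::phyDat(matrix(st, ncol = 1,
                                   dimnames = list(names(st), NULL)),
                            type = "USER", levels = 0:1)
    score <- fitch_fusion_events(t, st)
    expect_equal(score, phangorn::parsimony(t, dat))
    # rerooting never changes the unordered score
    ut <- ape::unroot(t)
    for (e in sample(nrow(ut$edge), 3)) {
      rr <- phytools::reroot(ut, ut$edge[e, 2],
                             position = ut$edge.length[e] / 2)
      expect_equal(fitch_fusion_events(rr, st), score)
    }
  }
})

test_that("dollo mode counts one gain plus minimal losses", {
  # nested loss: gain at the clade ancestor, one loss inside
  tr <- read_newick(text = "(((f1,(f2,l1)),f3),(o1,o2));")
  st <- c(f1 = 1, f2 = 1, l1 = 0, f3 = 1, o1 = 0, o2 = 0)
  expect_equal(fitch_fusion_events(tr, st, mode = "dollo"), 2)
  expect_equal(fitch_fusion_events(tr, st, mode = "unordered"), 2)
  # no fused tip: no event; all fused: single gain
  expect_equal(fitch_fusion_events(tr, stats::setNames(rep(0, 6),
                                                       names(st)),
                                   mode = "dollo"), 0)
  expect_equal(fitch_fusion_events(tr, stats::setNames(rep(1, 6),
                                                       names(st)),
                                   mode = "dollo"), 1)
  # dollo is never below the unordered minimum
  for (seed in 1:10) {
    set.seed(seed)
    t <- ape::rtree(8)
    st <- stats::setNames(sample(0:1, 8, replace = TRUE), t$tip.label)
    expect_gte(fitch_fusion_events(t, st, "dollo"),
               fitch_fusion_events(t, st, "unordered"))
  }
})

test_that("single-gain simulations are fully recoverable", {
  for (seed in 1:10) {
    sim <- gen_fusion_tree(10, fusion_clade_size = 4, loss_count = 0,
                           seed = seed)
    fused <- names(sim$states)[sim$states == 1]
    expect_true(is_monophyletic(sim$tree, fused))
    expect_equal(min_clade_cover(sim$tree, fused), 1)
    expect_equal(fitch_fusion_events(sim$tree, sim$states), 1)
    roots <- monophyly_roots(sim$tree, fused)
    expect_gt(length(roots), 0)
    # rooting on any compatible edge keeps the single-event history
    ut <- attr(roots, "tree")
    e <- roots[1]
    rr <- phytools::reroot(ut, ut$edge[e, 2],
                           position = ut$edge.length[e] / 2)
    expect_equal(fitch_fusion_events(rr, sim$states), 1)
    expect_true(is_monophyletic(rr, fused))
  }
})
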