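# Synthetic-data generators: determinism, ground-truth structure, and
# round-trips through the plain-text formats.

test_that("family generation is deterministic and architecture-true", {
  cfg <- sim_config(seed = 7, n_fuk = 5, n_gfpp = 5, n_fkp = 5,
                    domain_len_fuk = 40, domain_len_gfpp = 30,
                    linker_len = 6)
  a <- gen_domain_families(cfg)
  b <- gen_domain_families(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$proteins), 15)
  expect_true(all(a$proteins$length[a$truth$family == "FKP"] ==
                    30 + 6 + 40))
  expect_true(all(a$proteins$length[a$truth$family == "FUK"] == 40))
  # a different seed gives different sequences
  expect_false(identical(
    a$proteins$sequence,
    gen_domain_families(sim_config(seed = 8, n_fuk = 5, n_gfpp = 5,
                                   n_fkp = 5, domain_len_fuk = 40,
                                   domain_len_gfpp = 30,
                                   linker_len = 6))$proteins$sequence))
})

test_that("zero substitution rate yields exact ancestor concatenations", {
  cfg <- sim_config(seed = 3, n_fuk = 2, n_gfpp = 2, n_fkp = 2,
                    domain_len_fuk = 25, domain_len_gfpp = 20,
                    linker_len = 5, substitution_rate = 0)
  fam <- gen_domain_families(cfg)
  seqs <- stats::setNames(fam$proteins$sequence, fam$proteins$id)
  # identical within family
  expect_identical(seqs[["FKP01"]], seqs[["FKP02"]])
  expect_identical(seqs[["FUK01"]], seqs[["FUK02"]])
  # fused = GFPP ancestor + linker + FUK ancestor
  expect_true(startsWith(seqs[["FKP01"]], seqs[["GFPP01"]]))
  expect_true(endsWith(seqs[["FKP01"]], seqs[["FUK01"]]))
  expect_equal(nchar(seqs[["FKP01"]]), 20 + 5 + 25)
})

test_that("zero-length domains are rejected", {
  cfg <- sim_config(seed = 1, domain_len_fuk = 0)
  expect_error(gen_domain_families(cfg), "domain_len_fuk")
})

test_that("noiseless hit tables rank the true architecture on top", {
  fam <- gen_domain_families(small_family_config(seed = 2))
  hits <- gen_hit_table(fam$proteins, fam$truth, score_noise_sd = 0)
  ranked <- rank_models(hits)
  for (i in seq_len(nrow(fam$truth))) {
    id <- fam$truth$id[i]
    top3 <- ranked[[id]][1:3]
    if (fam$truth$family[i] == "FUK") {
      expect_identical(top3[1], "COG2605")
    } else if (fam$truth$family[i] == "GFPP") {
      expect_identical(top3[1], "PF07959")
    } else {
      expect_identical(top3[1], "PRK13412")
      expect_setequal(top3, c("PRK13412", "COG2605", "PF07959"))
    }
  }
  # determinism + every protein gets target and decoy models
  expect_identical(hits, gen_hit_table(fam$proteins, fam$truth, 0))
  expect_equal(nrow(hits), nrow(fam$proteins) * 8)
})

test_that("large score noise degrades classification below 100%", {
  fam <- gen_domain_families(small_family_config(seed = 2))
  hits <- gen_hit_table(fam$proteins, fam$truth, score_noise_sd = 200,
                        seed = 11)
  pred <- predict_family(classify_architecture(
    rank_models(hits),
    stats::setNames(fam$proteins$length, fam$proteins$id),
    no_length_filter()))
  acc <- mean(!is.na(pred[fam$truth$id]) &
                pred[fam$truth$id] == fam$truth$family)
  expect_lt(acc, 1)
})

test_that("fusion trees carry exactly one observable gain", {
  sim <- gen_fusion_tree(12, fusion_clade_size = 4, loss_count = 0,
                         seed = 5)
  fused <- names(sim$states)[sim$states == 1]
  expect_length(fused, 4)
  expect_true(is_monophyletic(sim$tree, fused))
  # losses remove exactly that many fused tips
  sim2 <- gen_fusion_tree(8, fusion_clade_size = 3, loss_count = 1,
                          seed = 5)
  expect_equal(sum(sim2$states), 2)
  # determinism down to the Newick string
  expect_identical(write_newick(gen_fusion_tree(10, 3, seed = 9)$tree),
                   write_newick(gen_fusion_tree(10, 3, seed = 9)$tree))
  expect_error(gen_fusion_tree(8, 3, loss_count = 3, seed = 1),
               "gained subtree")
  expect_error(gen_fusion_tree(8, 9, seed = 1), "exceed")
})

test_that("rate data follow the configured rate law", {
  tr <- kinetic_truth(KM = 77, kcat = 0.90, E0 = 0.277, noise_cv = 0)
  d <- gen_rate_data(tr, substrate_concs = 77, n_reps = 2)
  # half-saturation identity at S = KM
  expect_equal(d$rate_uM_per_s, rep(0.90 * 0.277 / 2, 2))
  d2 <- gen_rate_data(tr, substrate_concs = 1000, n_reps = 1)
  expect_equal(d2$rate_uM_per_s, 0.90 * 0.277 * 1000 / (77 + 1000),
               tolerance = 1e-12)
  # substrate inhibition: monotone decline after the peak
  tri <- kinetic_truth(KM = 1000, kcat = 0.9, Ki = 9000, E0 = 0.277,
                       noise_cv = 0)
  S <- c(3000, 6000, 12000, 24000, 1e5)  # peak at sqrt(KM*Ki) = 3000
  v <- gen_rate_data(tri, S, n_reps = 1,
                     model = "substrate_inhibition")$rate_uM_per_s
  expect_true(all(diff(v) < 0))
  expect_error(gen_rate_data(tr, 100, model = "nope"), "arg")
})

test_that("melt curves are deterministic logistic sums", {
  mt <- melt_truth(data.frame(midpoint_C = 50, steepness = 1,
                              amplitude = 1000), noise_sd = 2)
  a <- gen_melt_curve(mt, seed = 4)
  expect_identical(a, gen_melt_curve(mt, seed = 4))
  expect_equal(nrow(a), length(seq(20, 95, 0.5)))
  # single noiseless transition: unique derivative trough at midpoint
  clean <- gen_melt_curve(melt_truth(data.frame(
    midpoint_C = 50, steepness = 1, amplitude = 1000)), seed = 1)
  tms <- melt_tms(clean, max_peaks = 1)
  expect_equal(tms$tm, 50, tolerance = 0.5)
  # zero amplitude: flat curve, no troughs
  flat <- gen_melt_curve(melt_truth(data.frame(
    midpoint_C = 50, steepness = 1, amplitude = 0)), seed = 1)
  expect_warning(res <- melt_tms(flat), "no melting transition")
  expect_equal(nrow(res), 0)
  expect_error(melt_truth(data.frame(midpoint_C = 10, steepness = 1,
                                     amplitude = 1)),
               "inside the grid")
})

test_that("generated files round-trip through the I/O layers", {
  tmp <- withr::local_tempdir()
  fam <- gen_domain_families(small_family_config(seed = 6))
  fa <- file.path(tmp, "prot.fasta")
  write_protein_fasta(fam$proteins, fa)
  back <- read_protein_fasta(fa)
  expect_identical(unname(back[fam$proteins$id]), fam$proteins$sequence)
  hits <- gen_hit_table(fam$proteins, fam$truth, 1.5, seed = 3)
  ht <- file.path(tmp, "hits.tsv")
  write_hit_table(hits, ht)
  back_h <- read_hit_table(ht)
  expect_equal(back_h$score, hits$score, tolerance = 1e-10)
  expect_identical(back_h$query_id, hits$query_id)
  sim <- gen_fusion_tree(9, 4, seed = 2)
  nw <- file.path(tmp, "tree.nwk")
  write_newick(sim$tree, nw)
  back_t <- read_newick(nw)
  expect_identical(sort(back_t$tip.label), sort(sim$tree$tip.label))
  expect_true(ape::all.equal.phylo(back_t, sim$tree,
                                   use.edge.length = FALSE))
  expect_equal(sort(back_t$edge.length), sort(sim$tree$edge.length),
               tolerance = 1e-6)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  expected <- stats::runif(1)
  set.seed(123)
  invisible(gen_domain_families(small_family_config(seed = 99)))
  invisible(gen_fusion_tree(8, 3, seed = 42))
  expect_identical(stats::runif(1), expected)
})
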