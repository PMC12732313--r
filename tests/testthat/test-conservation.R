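# Reference-anchored conservation census: position mapping, the
# gap-prefix exclusion rule, per-position conservation and clade
# stratification.

simple_aln <- c(
  ref = "GACRK-TW",
  s1  = "GACRKKTW",   # identical at reference columns
  s2  = "GACAK-TW",   # differs at position 4
  s3  = "---RK-TW",   # gapped prefix over positions 1..3
  s4  = "G-CRK--W"
)

test_that("reference positions map through gaps", {
  aln <- c(ref = "-A-C", other = "AAAC")
  m <- map_ref_positions(aln, "ref", 2)
  expect_equal(m$column, 4)
  # ungapped reference: column equals position
  m2 <- map_ref_positions(simple_aln, "s1", c(2, 5))
  expect_equal(m2$column, c(2, 5))
  # expected-residue syntax is verified against the reference row
  m3 <- map_ref_positions(simple_aln, "ref", c("G1", "R4"))
  expect_equal(m3$column, c(1, 4))
  expect_error(map_ref_positions(simple_aln, "ref", "K4"),
               "mismatch.*found R")
  expect_error(map_ref_positions(simple_aln, "ref", 20), "beyond")
  expect_error(map_ref_positions(simple_aln, "nope", 1), "not found")
})

test_that("the gap-prefix exclusion rule drops late-aligning rows", {
  retained <- apply_exclusion(simple_aln, "ref", boundary = 3)
  expect_setequal(retained, c("ref", "s1", "s2", "s4"))
  # boundary past the gapped stretch retains everything
  expect_setequal(apply_exclusion(simple_aln, "ref", boundary = 5),
                  names(simple_aln))
  # the reference itself is always retained
  expect_true("ref" %in% apply_exclusion(simple_aln, "ref", 3))
})

test_that("a census-sized alignment retains 186 - 15 = 171 rows", {
  cen <- gen_census_alignment(n_rows = 186, n_gap_prefixed = 15,
                              seed = 42)
  retained <- apply_exclusion(cen$alignment, cen$ref_id, cen$boundary)
  expect_length(retained, 171)
})

test_that("conservation percentages count identical residues only", {
  m <- map_ref_positions(simple_aln, "ref", c("G1", "R4", "T6"))
  all_rows <- names(simple_aln)
  cons <- conservation_fraction(simple_aln, m, all_rows)
  # G1: s3 gapped -> 4/5; R4: s2 differs + s3 ok -> 4/5; T7: s4 gap -> 4/5
  expect_equal(cons$pct_conserved, c(80, 80, 80))
  expect_equal(cons$n_retained, rep(5, 3))
  # identical rows only: 100% everywhere
  ident <- c(ref = "ACDEF", a = "ACDEF", b = "ACDEF")
  mi <- map_ref_positions(ident, "ref", 1:5)
  expect_equal(conservation_fraction(ident, mi,
                                     names(ident))$pct_conserved,
               rep(100, 5))
  # 3 of 4 retained rows matching -> 75%
  four <- c(ref = "A", a = "A", b = "A", c = "G")
  expect_equal(conservation_fraction(
    four, map_ref_positions(four, "ref", 1), names(four))$pct_conserved,
    75)
})

test_that("row order never changes the census", {
  cen <- gen_census_alignment(n_rows = 40, n_gap_prefixed = 4, seed = 9)
  m <- map_ref_positions(cen$alignment, cen$ref_id, cen$positions)
  retained <- apply_exclusion(cen$alignment, cen$ref_id, cen$boundary)
  base <- conservation_fraction(cen$alignment, m, retained)
  set.seed(1)
  shuf <- cen$alignment[sample(length(cen$alignment))]
  m2 <- map_ref_positions(shuf, cen$ref_id, cen$positions)
  expect_equal(conservation_fraction(shuf, m2, retained), base)
})

test_that("measured conservation converges to the generating rates", {
  cen <- gen_census_alignment(n_rows = 400, n_gap_prefixed = 0,
                              seed = 13)
  m <- map_ref_positions(cen$alignment, cen$ref_id, cen$positions)
  retained <- apply_exclusion(cen$alignment, cen$ref_id, cen$boundary)
  cons <- conservation_fraction(cen$alignment, m, retained)
  # kinase-domain residues nearly invariant
  cterm <- cons$pct_conserved[cons$position > cen$boundary]
  expect_true(all(cterm > 97))
  # N-terminal residues: mixture of per-clade rates, ~0.96/0.96/0.30
  clade_n <- table(cen$clades[retained])
  expected <- 100 * (clade_n[["A"]] * 0.96 + clade_n[["B"]] * 0.96 +
                       clade_n[["C"]] * 0.30) / sum(clade_n)
  nterm <- cons$pct_conserved[cons$position <= cen$boundary]
  sigma <- 100 * sqrt(0.65 * 0.35 / length(retained))
  expect_true(all(abs(nterm - expected) < 4 * sigma))
})

test_that("missing residues stratify by clade with fractions summing to 1", {
  rows <- matrix(c(TRUE, TRUE,
                   FALSE, TRUE,
                   FALSE, FALSE,
                   TRUE, FALSE,
                   FALSE, TRUE,
                   FALSE, TRUE,
                   FALSE, TRUE,
                   FALSE, TRUE,
                   FALSE, TRUE,
                   TRUE, TRUE),
                 ncol = 2, byrow = TRUE,
                 dimnames = list(sprintf("r%02d", 1:10), c("G75", "R79")))
  clades <- stats::setNames(c(rep("C", 8), "A", "B"), rownames(rows))
  # lacking rows: r02..r09 (8 rows); r09 is clade A -> C gets 7/8... but
  # count from the matrix: rows with any FALSE = r02..r09
  strat <- stratify_missing(rows, clades)
  expect_equal(sum(strat), 1)
  expect_equal(unname(strat[["C"]]), 7 / 8)
  # all lacking rows in one clade
  one <- stratify_missing(rows[1:4, , drop = FALSE],
                          stats::setNames(rep("C", 4), rownames(rows)[1:4]))
  expect_equal(unname(one[["C"]]), 1)
  # 8 of 9 lacking rows in clade C mirrors the ~89% pattern
  c9 <- stats::setNames(c(rep("C", 8), "A"), sprintf("x%d", 1:9))
  m9 <- matrix(FALSE, 9, 1, dimnames = list(names(c9), "G75"))
  expect_equal(unname(stratify_missing(m9, c9)[["C"]]), 8 / 9,
               tolerance = 1e-12)
  # no lacking rows: empty result with a warning
  full <- matrix(TRUE, 3, 1, dimnames = list(c("a", "b", "c"), "G75"))
  expect_warning(empty <- stratify_missing(
    full, stats::setNames(rep("A", 3), c("a", "b", "c"))), "no rows")
  expect_length(empty, 0)
  expect_error(stratify_missing(rows, clades[1:5]), "no clade label")
})
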