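d1 <- toy_design(1)

test_that("proportions follow the pseudocount formula", {
  uni <- count_table_from_counts(c(A = 25, C = 25, G = 25, T = 25), d1)
  expect_equal(unname(proportions(uni)), rep(0.25, 4))
  skew <- count_table_from_counts(c(A = 50, C = 25, G = 15, T = 10), d1)
  expect_equal(unname(proportions(skew)), c(0.5, 0.25, 0.15, 0.10))
  one <- count_table_from_counts(c(A = 1, C = 0, G = 0, T = 0), d1)
  expect_equal(unname(proportions(one, pseudocount = 1)), c(0.4, 0.2, 0.2, 0.2))
  zero <- count_table_from_counts(c(A = 0, C = 0, G = 0, T = 0), d1)
  expect_error(proportions(zero), "all-zero")
  expect_equal(sum(proportions(zero, pseudocount = 1)), 1)
})

test_that("relative binding energy is -log2 of the proportion ratio", {
  it <- count_table_from_counts(c(A = 25, C = 25, G = 25, T = 25), d1, "input")
  bt <- count_table_from_counts(c(A = 50, C = 25, G = 15, T = 10), d1, "bound")
  land <- relative_binding_energy(it, bt)
  expect_equal(unname(land$ddg),
               c(-1, 0, -log2(0.6), -log2(0.4)), tolerance = 1e-12)
  # identical pools give a flat landscape
  flat <- relative_binding_energy(it, it)
  expect_true(all(flat$ddg == 0))
  # normalization invariant
  expect_equal(sum(land$p_input), 1, tolerance = 1e-9)
  expect_equal(sum(land$p_bound), 1, tolerance = 1e-9)
})

test_that("ddg matches a brute-force oracle on random tables", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:2, 1)
    d <- toy_design(n)
    it <- random_count_table(d, "input")
    bt <- random_count_table(d, "bound")
    pc <- sample(c(0, 1), 1)
    if (sum(it$counts) + pc == 0 || sum(bt$counts) + pc == 0) next
    land <- relative_binding_energy(it, bt, pc)
    expect_equal(land$ddg, oracle_ddg(it$counts, bt$counts, pc),
                 tolerance = 1e-12)
  }
})

test_that("ddg is invariant under uniform count rescaling", {
  set.seed(7)
  d <- toy_design(2)
  it <- random_count_table(d, "input")
  bt <- random_count_table(d, "bound")
  it10 <- count_table_from_counts(it$counts * 10L, d, "input")
  bt10 <- count_table_from_counts(bt$counts * 10L, d, "bound")
  expect_equal(relative_binding_energy(it, bt)$ddg,
               relative_binding_energy(it10, bt10)$ddg, tolerance = 1e-12)
})

test_that("raising a bound count strictly lowers that sequence's ddg", {
  d <- toy_design(2)
  set.seed(9)
  it <- random_count_table(d, "input")
  it$counts[it$counts == 0] <- 1L
  bt_lo <- count_table_from_counts(it$counts, d, "bound")
  bumped <- it$counts; bumped[["GA"]] <- bumped[["GA"]] + 20L
  bt_hi <- count_table_from_counts(bumped, d, "bound")
  lo <- relative_binding_energy(it, bt_lo)$ddg[["GA"]]
  hi <- relative_binding_energy(it, bt_hi)$ddg[["GA"]]
  expect_lt(hi, lo)
})

test_that("zero-count types are flagged undefined, not fabricated", {
  it <- count_table_from_counts(c(A = 10, C = 10, G = 10, T = 0), d1, "input")
  bt <- count_table_from_counts(c(A = 10, C = 0, G = 10, T = 10), d1, "bound")
  land <- relative_binding_energy(it, bt)
  expect_true(is.na(land$ddg[["C"]]))
  expect_true(is.na(land$ddg[["T"]]))
  expect_false(anyNA(land$ddg[c("A", "G")]))
  # a pseudocount defines every type
  expect_false(anyNA(relative_binding_energy(it, bt, 1)$ddg))
})

test_that("mismatched designs are a hard error", {
  it <- random_count_table(toy_design(2), "input")
  bt <- random_count_table(toy_design(3), "bound")
  expect_error(relative_binding_energy(it, bt), "different library designs")
})

test_that("select_high_affinity thresholds strictly below the cutoff", {
  land <- structure(list(ddg = c(GACC = -2.1, GACT = -1.3, AAAA = 0.2,
                                 CCCC = NA)),
                    class = "energy_landscape")
  expect_identical(select_high_affinity(land, -1), c("GACC", "GACT"))
  expect_identical(select_high_affinity(land, 1e9), c("GACC", "GACT", "AAAA"))
  flat <- structure(list(ddg = c(A = 0, C = 0, G = 0, T = 0)),
                    class = "energy_landscape")
  expect_length(select_high_affinity(flat, -1), 0L)
})

test_that("compare_landscapes computes correlation over shared defined types", {
  a <- c(s1 = 0, s2 = 1, s3 = 2)
  expect_equal(compare_landscapes(a, a), 1)
  expect_equal(compare_landscapes(a, -a), -1)
  b <- c(s1 = 0, s2 = 2, s3 = 3)
  expect_equal(compare_landscapes(a, b), stats::cor(c(0, 1, 2), c(0, 2, 3)),
               tolerance = 1e-12)
  expect_equal(round(compare_landscapes(a, b), 3), 0.982)
  expect_equal(compare_landscapes(a, c(s1 = 1, s2 = 2, s3 = 4),
                                  method = "spearman"), 1)
  expect_error(compare_landscapes(a, c(s1 = 0, s2 = 1, s3 = NA)), "fewer than 3")
})

test_that("marginalization sums counts over both length-K windows", {
  d2 <- toy_design(2)
  it <- count_table_from_counts(c(AA = 3, CG = 1), d2, "input")
  # oracle by hand: AA -> A,A ; CG -> C,G
  seqs <- names(it$counts)
  marg <- stats::setNames(numeric(4), c("A", "C", "G", "T"))
  for (s in seqs[it$counts > 0]) {
    marg[substr(s, 1, 1)] <- marg[substr(s, 1, 1)] + it$counts[[s]]
    marg[substr(s, 2, 2)] <- marg[substr(s, 2, 2)] + it$counts[[s]]
  }
  expect_equal(unname(marg), c(6, 1, 1, 0))
  bt <- count_table_from_counts(c(AA = 3, CG = 1), d2, "bound")
  land <- marginalize(it, bt)
  expect_equal(unname(land$input_counts), c(6L, 1L, 1L, 0L))
  expect_identical(sum(land$input_counts), 2L * sum(it$counts))
  # identical pools marginalize to a flat landscape
  expect_true(all(land$ddg[!is.na(land$ddg)] == 0))
})

test_that("uniform (K+1)-mer pools marginalize to a flat K-mer landscape", {
  d3 <- toy_design(3)
  u <- stats::setNames(rep(5L, 64L), enumerate_space(3)$sequences)
  it <- count_table_from_counts(u, d3, "input")
  bt <- count_table_from_counts(u, d3, "bound")
  land <- marginalize(it, bt)
  expect_length(land$ddg, 16L)
  expect_true(all(abs(land$ddg) < 1e-12))
})

test_that("prefix-window marginalization recovers prefix-only energies", {
  # bound = input * 2^-ddg with ddg a function of the first K bases only
  d3 <- toy_design(3)
  sp3 <- enumerate_space(3)$sequences
  dimers <- enumerate_space(2)$sequences
  set.seed(5)
  ddg_k <- stats::setNames(sample(c(0, -1, -2, 1), 16, replace = TRUE), dimers)
  it <- count_table_from_counts(stats::setNames(rep(16L, 64L), sp3), d3, "input")
  bt <- count_table_from_counts(
    stats::setNames(16 * 2^(-ddg_k[substr(sp3, 1, 2)]), sp3), d3, "bound")
  land <- marginalize(it, bt, windows = "prefix")
  offs <- land$ddg - ddg_k[names(land$ddg)]
  expect_lt(max(offs) - min(offs), 1e-9)
})

test_that("energy-averaging marginalization is available and offset-consistent", {
  d3 <- toy_design(3)
  sp3 <- enumerate_space(3)$sequences
  dimers <- enumerate_space(2)$sequences
  ddg_k <- stats::setNames(rep(c(-2, -1, 0, 1), 4), dimers)
  it <- count_table_from_counts(stats::setNames(rep(16L, 64L), sp3), d3, "input")
  bt <- count_table_from_counts(
    stats::setNames(16 * 2^(-ddg_k[substr(sp3, 1, 2)]), sp3), d3, "bound")
  avg <- marginalize(it, bt, scheme = "average", windows = "prefix")
  offs <- avg - ddg_k[names(avg)]
  expect_lt(max(offs) - min(offs), 1e-9)
})

test_that("emsa_statistic is -log2(bound/unbound) on positive intensities", {
  expect_equal(emsa_statistic(10, 10), 0)
  expect_equal(emsa_statistic(20, 10), -1)
  expect_equal(emsa_statistic(2.5, 10), 2)
  expect_error(emsa_statistic(0, 10), "positive")
  expect_error(emsa_statistic(10, -1), "positive")
})

test_that("energy unit conversions invert each other at RT = 0.593 kcal/mol", {
  x <- c(-3, 0, 0.5, 5)
  expect_equal(log2_to_kcal(kcal_to_log2(x)), x, tolerance = 1e-12)
  expect_equal(kcal_to_log2(0.5), 1.2165, tolerance = 1e-3)
  expect_equal(kcal_to_log2(5), 12.165, tolerance = 1e-3)
})

test_that("landscape TSV export has the documented columns and NA policy", {
  it <- count_table_from_counts(c(A = 10, C = 10, G = 10, T = 0), d1, "input")
  bt <- count_table_from_counts(c(A = 20, C = 5, G = 10, T = 10), d1, "bound")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_landscape_tsv(relative_binding_energy(it, bt), path)
  df <- read.delim(path)
  expect_identical(names(df), c("sequence", "input_count", "bound_count",
                                "p_input", "p_bound", "ddg_log2"))
  expect_true(is.na(df$ddg_log2[df$sequence == "T"]))
  expect_identical(df$sequence, c("A", "C", "G", "T"))
})
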