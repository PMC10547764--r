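test_that("make_truth builds input probabilities as per-position products", {
  d <- toy_design()
  uni <- make_truth(d, bias_spec = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_equal(unname(uni$input_probs), rep(1 / 256, 256))
  bias <- c(T = 0.30, A = 0.27, C = 0.23, G = 0.20)
  tr <- make_truth(d, bias_spec = bias)
  expect_equal(sum(tr$input_probs), 1, tolerance = 1e-12)
  expect_equal(unname(tr$input_probs[["TTTT"]]), 0.30^4, tolerance = 1e-12)
  expect_equal(unname(tr$input_probs[["GGGG"]]), 0.20^4, tolerance = 1e-12)
  # synthesis-bias ordering T > A > C > G propagates to homopolymers
  hp <- tr$input_probs[c("TTTT", "AAAA", "CCCC", "GGGG")]
  expect_true(all(diff(unname(hp)) < 0))
  expect_error(make_truth(d, bias_spec = c(A = 0.5, C = 0.5, G = 0.2, T = -0.2)),
               "positive")
  expect_error(make_truth(d, bias_spec = c(A = 0.3, C = 0.3, G = 0.3, T = 0.3)),
               "sum to 1")
})

test_that("planted motifs grade energies by the base after the core", {
  d <- toy_design()
  tr <- make_truth(d, motif_spec = list(core = "GAC", strong = -2))
  hits <- core_mask(enumerate_space(4), "GAC")
  expect_true(all(tr$true_ddg[hits] <= -2 + 1.7 + 1e-12))
  expect_true(all(tr$true_ddg[setdiff(names(tr$true_ddg), hits)] == 0))
  expect_equal(unname(tr$true_ddg[["GACC"]]), -2)
  expect_true(tr$true_ddg[["GACC"]] < tr$true_ddg[["GACT"]])
  expect_true(tr$true_ddg[["GACT"]] < tr$true_ddg[["GACG"]])
  expect_true(tr$true_ddg[["GACG"]] < tr$true_ddg[["GACA"]])
})

test_that("motif-free truths span the requested kcal/mol range in log2 units", {
  d <- toy_design()
  tr <- make_truth(d, seed = 3, energy_range_kcal = c(0.5, 5))
  expect_true(all(tr$true_ddg >= kcal_to_log2(0.5) - 1e-9))
  expect_true(all(tr$true_ddg <= kcal_to_log2(5) + 1e-9))
  # explicit energies override generation
  e <- stats::setNames(rep(c(0, -1), 128), enumerate_space(4)$sequences)
  expect_equal(make_truth(d, true_ddg = e)$true_ddg, e)
  expect_error(make_truth(d, true_ddg = e[-1]), "every core sequence")
})

test_that("sample_assay reweights the bound pool by 2^(-ddg)", {
  d <- toy_design(1)
  # flat truth: bound pool distribution equals the input pool
  flat <- make_truth(d, true_ddg = c(A = 0, C = 0, G = 0, T = 0),
                     bias_spec = c(A = 0.4, C = 0.3, G = 0.2, T = 0.1))
  asy <- sample_assay(flat, 2e5, 2e5, seed = 8)
  p_in <- proportions(asy$input)
  p_bd <- proportions(asy$bound)
  expect_equal(unname(p_bd), unname(p_in), tolerance = 0.02)
  # at high depth the estimate recovers truth up to log2(sum q 2^-ddg)
  tr <- make_truth(d, true_ddg = c(A = -1, C = 0, G = 0, T = 0),
                   bias_spec = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  asy2 <- sample_assay(tr, 2e6, 2e6, seed = 9)
  est <- relative_binding_energy(asy2$input, asy2$bound)$ddg
  offset <- log2(sum(tr$input_probs * 2^(-tr$true_ddg)))
  expect_equal(unname(est), unname(tr$true_ddg) + offset, tolerance = 0.05)
})

test_that("sampling operations are deterministic under a fixed seed", {
  d <- toy_design()
  tr <- make_truth(d, seed = 5)
  a1 <- sample_assay(tr, 1e4, 1e4, seed = 21)
  a2 <- sample_assay(tr, 1e4, 1e4, seed = 21)
  a3 <- sample_assay(tr, 1e4, 1e4, seed = 22)
  expect_identical(a1$input$counts, a2$input$counts)
  expect_identical(a1$bound$counts, a2$bound$counts)
  expect_false(identical(a1$input$counts, a3$input$counts))

  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  g1 <- withr::local_tempfile(fileext = ".fastq")
  g2 <- withr::local_tempfile(fileext = ".fastq")
  synth_fastq(tr, f1, f2, n_pairs = 500, error_rate = 0.01,
              corrupt_pair_rate = 0.1, seed = 13)
  synth_fastq(tr, g1, g2, n_pairs = 500, error_rate = 0.01,
              corrupt_pair_rate = 0.1, seed = 13)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
})

test_that("synthetic reads round-trip planted multiplicities exactly", {
  d <- toy_design()
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  planted <- c(GACC = 7L, ACGT = 4L, TTTT = 2L)
  synth_fastq(planted, f1, f2, design = d, seed = 2)
  tab <- count_pool(design = d, pool = "input", fastq1 = f1, fastq2 = f2)
  expect_identical(tab$counts[names(planted)], planted)
  expect_identical(sum(tab$qc), 0L)
})

test_that("corrupted pairs are rejected by the pair filter at the exact rate", {
  d <- toy_design()
  planted <- stats::setNames(rep(10L, 20), sample(enumerate_space(4)$sequences, 20))
  for (rate in c(0, 0.5, 1)) {
    f1 <- withr::local_tempfile(fileext = ".fastq")
    f2 <- withr::local_tempfile(fileext = ".fastq")
    synth_fastq(planted, f1, f2, design = d, corrupt_pair_rate = rate, seed = 4)
    tab <- count_pool(design = d, pool = "input", fastq1 = f1, fastq2 = f2)
    expect_identical(sum(tab$counts), as.integer(200 - round(rate * 200)),
                     info = paste("rate", rate))
    expect_identical(unname(tab$qc[["not_reverse_complement"]]),
                     as.integer(round(rate * 200)))
  }
})

test_that("downsampling is hypergeometric with exact totals", {
  d <- toy_design(1)
  tab <- count_table_from_counts(c(A = 10, C = 0, G = 0, T = 0), d)
  down <- downsample(tab, target_reads = 4, seed = 1)
  expect_identical(unname(down$counts[["A"]]), 4L)
  full <- count_table_from_counts(c(A = 10, C = 20, G = 5, T = 15), d)
  expect_identical(downsample(full, fraction = 1, seed = 1)$counts, full$counts)
  expect_error(downsample(full, target_reads = 100), "exceeds")
  expect_error(downsample(full, fraction = 0), "fraction")

  # mean downsampled count ~ fraction * original, within 3 SE over replicates
  reps <- 200
  frac <- 0.3
  sums <- matrix(0, reps, 4)
  for (r in seq_len(reps)) {
    sums[r, ] <- downsample(full, fraction = frac, seed = 100 + r)$counts
  }
  N <- sum(full$counts); k <- round(frac * N)
  for (j in 1:4) {
    m <- full$counts[[j]]
    mu <- k * m / N
    se <- sqrt(k * (m / N) * (1 - m / N) * (N - k) / (N - 1)) / sqrt(reps)
    expect_lt(abs(mean(sums[, j]) - mu), max(3 * se, 1e-9))
  }
  # totals always match the target exactly
  expect_true(all(rowSums(sums) == k))
})

test_that("depth_curve improves with depth and flags degenerate truths", {
  d <- toy_design()
  tr <- make_truth(d, seed = 6)
  dc <- depth_curve(tr, depths = c(2e3, 5e4), replicates = 3, seed = 7)
  expect_identical(dc$curve$depth, c(2e3, 5e4))
  expect_true(all(dc$values >= -1 & dc$values <= 1))
  expect_gt(dc$curve$mean[2], dc$curve$mean[1])

  flat <- make_truth(d, true_ddg = stats::setNames(rep(0, 256),
                                                   enumerate_space(4)$sequences))
  expect_warning(dcf <- depth_curve(flat, depths = 1e3, replicates = 2),
                 "zero energy variance")
  expect_true(all(is.na(dcf$curve$mean)))
})

test_that("alternative accuracy metrics are available", {
  d <- toy_design()
  tr <- make_truth(d, seed = 16)
  dc_s <- depth_curve(tr, depths = 5e4, replicates = 2, metric = "spearman",
                      seed = 8)
  expect_gt(dc_s$curve$mean, 0.8)
  dc_r <- depth_curve(tr, depths = 5e4, replicates = 2, metric = "rank-accuracy",
                      seed = 8, top_frac = 0.1)
  expect_true(dc_r$curve$mean >= 0 && dc_r$curve$mean <= 1)
  expect_gt(dc_r$curve$mean, 0.5)
})

test_that("sequencing throughput arithmetic matches the platform geometry", {
  expect_equal(sequencing_bases(1e5), 3e7)
  expect_equal(sequencing_bases(1e5, bases_per_pair = 200), 2e7)
  expect_error(sequencing_bases(-1), "read_pairs")
})
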