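#' Construct a ground-truth model of the assay
#'
#' A truth model fixes, for every core sequence, (i) its probability in the
#' input pool and (ii) its true relative binding energy, and is the generative
#' source for count-level and read-level synthetic data. The input pool
#' emulates the base-composition bias of randomized oligo synthesis (usage
#' order T > A > C > G) as a product of independent per-position base
#' probabilities. Energies come either from a planted core motif (sequences
#' containing the core get a strong low energy, graded by the base following
#' the core; all others sit near 0) or, with `motif_spec = NULL`, from a
#' uniform draw over `energy_range_kcal`, emulating an unstructured affinity
#' spectrum for depth studies.
#'
#' @param design a [library_design()].
#' @param motif_spec `NULL`, or a list with elements `core` (DNA string),
#'   `strong` (energy of the best core-containing sequence, log2 units,
#'   default -2), `grading` (named offsets added per following base, default
#'   `c(C = 0, T = 0.4, G = 1.3, A = 1.7)` so the preference order after the
#'   core is C < T < G < A and only the C/T-followed core drops below the -1
#'   selection cutoff) and `end` (offset when the core sits at the very end of
#'   the sequence with no following base; default `max(grading)`, making
#'   end-anchored occurrences bind weakly).
#' @param bias_spec per-position base probabilities: a named length-4 vector
#'   (recycled across positions) or a 4 x n matrix with rows A/C/G/T. The
#'   default `c(A = 0.27, C = 0.23, G = 0.20, T = 0.30)` honors the
#'   T > A > C > G synthesis-bias ordering.
#' @param seed integer seed for the random components, or NULL.
#' @param energy_range_kcal range (kcal/mol) from which motif-free energies
#'   are drawn; the default 0.5–5 kcal/mol spans weak to strong binding and
#'   maps to roughly 1.2–12.2 log2 units.
#' @param noise_sd standard deviation (log2 units) of Gaussian noise added to
#'   motif-model energies; 0 disables it.
#' @param true_ddg optional explicit energy vector (log2 units) named by core
#'   sequence, overriding both the motif model and the random draw.
#' @return an object of class `truth_model`: `design`, `true_ddg` (named,
#'   log2 units), `input_probs` (named, sums to 1), `seed`.
#' @export
make_truth <- function(design, motif_spec = NULL, bias_spec = NULL, seed = NULL,
                       energy_range_kcal = c(0.5, 5), noise_sd = 0,
                       true_ddg = NULL) {
  stopifnot(inherits(design, "library_design"))
  space <- enumerate_space(design$n)
  if (is.null(bias_spec)) {
    bias_spec <- c(A = 0.27, C = 0.23, G = 0.20, T = 0.30)
  }
  bias <- validate_bias(bias_spec, design$n)
  chars <- matrix(unlist(strsplit(space$sequences, "", fixed = TRUE)),
                  ncol = design$n, byrow = TRUE)
  input_probs <- rep(1, length(space$sequences))
  for (j in seq_len(design$n)) {
    input_probs <- input_probs * bias[chars[, j], j]
  }
  input_probs <- input_probs / sum(input_probs)
  names(input_probs) <- space$sequences

  if (!is.null(true_ddg)) {
    if (is.null(names(true_ddg)) ||
        !setequal(names(true_ddg), space$sequences) ||
        any(!is.finite(true_ddg))) {
      stop("explicit true_ddg must be finite and named by every core sequence")
    }
    return(structure(list(design = design,
                          true_ddg = true_ddg[space$sequences],
                          input_probs = input_probs, seed = seed),
                     class = "truth_model"))
  }
  true_ddg <- with_seed(seed, {
    if (is.null(motif_spec)) {
      kcal_to_log2(stats::runif(length(space$sequences),
                                min(energy_range_kcal), max(energy_range_kcal)))
    } else {
      core <- motif_spec$core
      stopifnot_dna(core, "motif core")
      strong <- if (is.null(motif_spec$strong)) -2 else motif_spec$strong
      grading <- if (is.null(motif_spec$grading)) {
        c(C = 0, T = 0.4, G = 1.3, A = 1.7)
      } else motif_spec$grading
      end_off <- if (is.null(motif_spec$end)) max(grading) else motif_spec$end
      e <- numeric(length(space$sequences))
      hit <- grepl(core, space$sequences, fixed = TRUE)
      pos <- regexpr(core, space$sequences, fixed = TRUE)
      nxt_at <- pos + nchar(core)
      nxt <- substr(space$sequences, nxt_at, nxt_at)
      off <- ifelse(nzchar(nxt), grading[nxt], end_off)
      e[hit] <- strong + off[hit]
      if (noise_sd > 0) e <- e + stats::rnorm(length(e), 0, noise_sd)
      e
    }
  })
  names(true_ddg) <- space$sequences
  structure(list(design = design, true_ddg = true_ddg,
                 input_probs = input_probs, seed = seed),
            class = "truth_model")
}

validate_bias <- function(bias_spec, n) {
  if (is.matrix(bias_spec)) {
    if (nrow(bias_spec) != 4L || ncol(bias_spec) != n) {
      stop("bias matrix must be 4 x n with rows A/C/G/T")
    }
    bias <- bias_spec[DNA_BASES, , drop = FALSE]
  } else {
    if (length(bias_spec) != 4L || is.null(names(bias_spec))) {
      stop("bias_spec must be a named length-4 vector or a 4 x n matrix")
    }
    bias <- matrix(rep(bias_spec[DNA_BASES], n), nrow = 4,
                   dimnames = list(DNA_BASES, NULL))
  }
  if (any(is.na(bias)) || any(bias <= 0)) {
    stop("bias probabilities must be positive for all four bases")
  }
  sums <- colSums(bias)
  if (any(abs(sums - 1) > 1e-6)) stop("bias probabilities must sum to 1 per position")
  sweep(bias, 2, sums, "/")
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf("truth_model: n = %d, true ddg range [%.3f, %.3f] log2, seed %s\n",
              x$design$n, min(x$true_ddg), max(x$true_ddg),
              if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}

#' Sample count tables from a truth model
#'
#' Input counts are multinomial over the input-pool probabilities; the bound
#' pool is a Boltzmann-type reweighting of the input pool, b_i proportional to
#' input_probs_i * 2^(-true_ddg_i), sampled multinomially at the requested
#' depth. With all energies equal the bound pool equals the input pool.
#'
#' @param truth a [make_truth()] model.
#' @param input_reads,bound_reads read-pair depths (>= 0).
#' @param seed integer seed or NULL.
#' @return list with `input` and `bound` `count_table`s.
#' @export
sample_assay <- function(truth, input_reads, bound_reads, seed = NULL) {
  stopifnot(inherits(truth, "truth_model"),
            input_reads >= 0, bound_reads >= 0)
  b <- bound_probs(truth)
  cts <- with_seed(seed, {
    list(input = as.integer(stats::rmultinom(1, input_reads, truth$input_probs)),
         bound = as.integer(stats::rmultinom(1, bound_reads, b)))
  })
  nm <- names(truth$input_probs)
  list(input = count_table_from_counts(stats::setNames(cts$input, nm),
                                       truth$design, "input"),
       bound = count_table_from_counts(stats::setNames(cts$bound, nm),
                                       truth$design, "bound"))
}

bound_probs <- function(truth) {
  w <- truth$input_probs * 2^(-truth$true_ddg)
  w / sum(w)
}

#' Write synthetic paired-end FASTQ for a pool
#'
#' Each read pair carries the full construct: mate 1 is
#' left_flank + core + right_flank, mate 2 its reverse complement.
#' Per-base substitution errors are applied at `error_rate`, and a
#' `corrupt_pair_rate` fraction of pairs (exactly `round(rate * N)` of them)
#' get one deliberately substituted core base in mate 2, guaranteeing the pair
#' fails the reverse-complement consistency filter. Quality strings are
#' constant 'I'. Output is byte-identical for a fixed seed.
#'
#' @param x multiplicities: a `count_table`, a named count vector, or a
#'   `truth_model` (then `n_pairs` and `pool` choose the depth and which pool
#'   distribution to sample).
#' @param design a [library_design()]; defaults to the design carried by `x`.
#' @param fastq1,fastq2 output paths (mate 1 / mate 2); `.gz` suffix compresses.
#' @param n_pairs,pool used only when `x` is a `truth_model`.
#' @param error_rate per-base substitution probability in [0, 1].
#' @param corrupt_pair_rate fraction of pairs given a mate-2 core mismatch.
#' @param seed integer seed or NULL.
#' @return invisibly, a list with the planted count vector and the indices of
#'   corrupted pairs.
#' @export
synth_fastq <- function(x, fastq1, fastq2, design = NULL,
                        n_pairs = NULL, pool = c("input", "bound"),
                        error_rate = 0, corrupt_pair_rate = 0, seed = NULL) {
  pool <- match.arg(pool)
  if (error_rate < 0 || error_rate > 1 || corrupt_pair_rate < 0 ||
      corrupt_pair_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (inherits(x, "truth_model")) {
    if (is.null(n_pairs)) stop("n_pairs is required when sampling from a truth model")
    if (is.null(design)) design <- x$design
    p <- if (pool == "input") x$input_probs else bound_probs(x)
    mult <- with_seed(child_seed(seed, 1L),
                      stats::setNames(as.integer(stats::rmultinom(1, n_pairs, p)),
                                      names(p)))
  } else if (inherits(x, "count_table")) {
    if (is.null(design)) design <- x$design
    mult <- x$counts
  } else {
    if (is.null(design)) stop("a design is required with a plain count vector")
    if (is.null(names(x))) stop("multiplicities must be a named count vector")
    mult <- x
  }
  stopifnot(inherits(design, "library_design"))
  mult <- mult[mult > 0]

  cores <- rep(names(mult), times = as.integer(mult))
  out <- with_seed(child_seed(seed, 2L), {
    cores <- sample(cores)  # shuffle so corrupted pairs are not grouped
    n <- length(cores)
    read1 <- paste0(design$left_flank, cores, design$right_flank)
    read2 <- reverse_complement(read1)
    n_bad <- round(corrupt_pair_rate * n)
    bad <- if (n_bad > 0) sort(sample.int(n, n_bad)) else integer(0)
    if (length(bad)) {
      # substitute one mate-2 core base to a guaranteed-different base
      core_start <- nchar(design$right_flank) + 1L  # rc(read1): rc(right) first
      pos <- core_start + sample.int(design$n, length(bad), replace = TRUE) - 1L
      old <- substr(read2[bad], pos, pos)
      new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
      substr(read2[bad], pos, pos) <- new
    }
    if (error_rate > 0) {
      read1 <- mutate_bases(read1, error_rate)
      read2 <- mutate_bases(read2, error_rate)
    }
    list(read1 = read1, read2 = read2, bad = bad)
  })
  ids <- sprintf("pair_%06d", seq_along(out$read1))
  write_fastq(out$read1, ids, fastq1)
  write_fastq(out$read2, ids, fastq2)
  invisible(list(counts = mult, corrupted = out$bad,
                 n_pairs = length(out$read1)))
}

# iid per-base substitutions at rate `rate` (uses current RNG stream)
mutate_bases <- function(reads, rate) {
  chars <- strsplit(reads, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars)
  hit <- stats::runif(length(flat)) < rate
  if (any(hit)) {
    flat[hit] <- vapply(flat[hit],
                        function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
  }
  vapply(split(flat, rep(seq_along(lens), lens)), paste, character(1), collapse = "")
}

write_fastq <- function(seqs, ids, path) {
  qual <- Biostrings::PhredQuality(strrep("I", nchar(seqs)))
  x <- Biostrings::QualityScaledDNAStringSet(Biostrings::DNAStringSet(seqs), qual)
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Downsample a count table
#'
#' Draws reads without replacement from the table's read multiset (multivariate
#' hypergeometric, realized as sequential univariate hypergeometric draws), so
#' the downsampled total matches the target exactly — the in-silico equivalent
#' of sequencing the same library at lower depth.
#'
#' @param table a `count_table`.
#' @param fraction fraction of reads to keep (0 < fraction <= 1); ignored if
#'   `target_reads` is given.
#' @param target_reads absolute number of reads to keep.
#' @param seed integer seed or NULL.
#' @return a `count_table` with the downsampled counts.
#' @export
downsample <- function(table, fraction = NULL, target_reads = NULL, seed = NULL) {
  stopifnot(inherits(table, "count_table"))
  total <- sum(table$counts)
  if (is.null(target_reads)) {
    if (is.null(fraction) || fraction <= 0 || fraction > 1) {
      stop("fraction must lie in (0, 1]")
    }
    target_reads <- round(fraction * total)
  }
  if (target_reads > total) stop("target exceeds the table's total read count")
  counts <- as.numeric(table$counts)
  out <- with_seed(seed, {
    res <- numeric(length(counts))
    remaining <- total
    k <- target_reads
    for (i in seq_along(counts)) {
      if (k <= 0) break
      remaining <- remaining - counts[i]
      if (remaining <= 0) { res[i] <- k; k <- 0; break }
      res[i] <- stats::rhyper(1, counts[i], remaining, k)
      k <- k - res[i]
    }
    res
  })
  count_table_from_counts(stats::setNames(as.integer(out), names(table$counts)),
                          table$design, pool = table$pool)
}

#' Estimator accuracy as a function of sequencing depth
#'
#' For each depth d, samples an assay with d input and d bound read pairs,
#' estimates the relative binding-energy landscape, and scores it against the
#' true energies with an additive-offset-invariant metric (Pearson by default;
#' Spearman and a top-set rank accuracy — the overlap fraction of the true and
#' estimated strongest `top_frac` sets — are available), averaged over
#' replicates. Degenerate truths with zero energy variance yield NA with a
#' warning rather than a fabricated score.
#'
#' @param truth a [make_truth()] model.
#' @param depths increasing vector of read depths.
#' @param replicates assays per depth.
#' @param metric `"pearson"`, `"spearman"`, or `"rank-accuracy"`.
#' @param seed integer seed or NULL; replicate seeds are derived from it.
#' @param pseudocount passed to the landscape estimate.
#' @param top_frac top-set size for `"rank-accuracy"`.
#' @return an object of class `depth_curve`: data.frame `curve` with columns
#'   depth, mean, sd, plus `values` (replicates x depths matrix), `metric`,
#'   `replicates`, `seed`.
#' @export
depth_curve <- function(truth, depths, replicates = 5,
                        metric = c("pearson", "spearman", "rank-accuracy"),
                        seed = NULL, pseudocount = 0, top_frac = 0.1) {
  metric <- match.arg(metric)
  stopifnot(inherits(truth, "truth_model"), length(depths) >= 1)
  depths <- sort(as.numeric(depths))
  if (stats::sd(truth$true_ddg) == 0) {
    warning("truth has zero energy variance: accuracy metric undefined")
    vals <- matrix(NA_real_, replicates, length(depths))
  } else {
    vals <- matrix(NA_real_, replicates, length(depths))
    for (j in seq_along(depths)) {
      for (r in seq_len(replicates)) {
        s <- child_seed(seed, j * 1000L + r)
        asy <- sample_assay(truth, depths[j], depths[j], seed = s)
        est <- relative_binding_energy(asy$input, asy$bound, pseudocount)
        vals[r, j] <- score_landscape(est$ddg, truth$true_ddg, metric, top_frac)
      }
    }
  }
  curve <- data.frame(depth = depths,
                      mean = colMeans(vals),
                      sd = apply(vals, 2, stats::sd))
  structure(list(curve = curve, values = vals, metric = metric,
                 replicates = replicates, seed = seed),
            class = "depth_curve")
}

score_landscape <- function(est, truth, metric, top_frac = 0.1) {
  ok <- !is.na(est)
  if (sum(ok) < 3L) return(NA_real_)
  if (metric == "pearson") {
    stats::cor(est[ok], truth[ok])
  } else if (metric == "spearman") {
    stats::cor(est[ok], truth[ok], method = "spearman")
  } else {
    m <- max(1L, round(top_frac * length(truth)))
    top_true <- names(sort(truth))[seq_len(m)]
    top_est <- names(sort(est[ok]))[seq_len(min(m, sum(ok)))]
    length(intersect(top_true, top_est)) / m
  }
}

#' @export
print.depth_curve <- function(x, ...) {
  cat(sprintf("depth_curve (%s, %d replicates):\n", x$metric, x$replicates))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Sequencing throughput needed for a depth target
#'
#' Total sequenced bases for a number of read pairs on a paired-end platform:
#' pairs x bases_per_pair. At the 100,000-pair depth adequate for an n = 4
#' library, PE150 (300 bases per pair) needs 30 million bases.
#'
#' @param read_pairs number of read pairs.
#' @param bases_per_pair sequenced bases per pair (default 300, i.e. PE150).
#' @return total bases.
#' @examples
#' sequencing_bases(1e5) / 1e6  # 30 Mb
#' @export
sequencing_bases <- function(read_pairs, bases_per_pair = 300) {
  stopifnot(read_pairs >= 0, bases_per_pair > 0)
  read_pairs * bases_per_pair
}

#' Export a depth curve as TSV
#'
#' @param dc a `depth_curve`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_depth_curve_tsv <- function(dc, path) {
  stopifnot(inherits(dc, "depth_curve"))
  write_tsv_file(dc$curve, path)
}
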