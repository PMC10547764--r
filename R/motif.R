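#' Build a position weight matrix from a sequence set
#'
#' Column probabilities are (optionally weighted) base frequencies of the
#' selected sequences; per-column information content against the uniform
#' background is info_j = 2 + sum_b p_bj log2 p_bj bits (0*log0 = 0), so a
#' fully determined column carries 2 bits and a uniform one 0.
#'
#' @param sequences character vector of equal-length A/C/G/T sequences,
#'   typically the output of [select_high_affinity()].
#' @param weights optional nonnegative per-sequence weights (e.g. bound-pool
#'   counts); default is uniform weighting, one vote per sequence.
#' @return an object of class `pwm`: `probs` (4 x L matrix, rows A/C/G/T),
#'   `info` (length-L vector, bits), `length`, `source_count`, `weights_mode`,
#'   `dropped` (indices trimmed away; empty until [trim_logo()]).
#' @examples
#' pwm <- build_pwm(c("GACC", "GACT"))
#' pwm$info  # 2 2 2 1
#' @export
build_pwm <- function(sequences, weights = NULL) {
  if (length(sequences) == 0L) stop("cannot build a PWM from an empty sequence set")
  stopifnot_dna(sequences, "sequences")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must all have the same length")
  if (is.null(weights)) {
    weights <- rep(1, length(sequences))
    mode <- "uniform"
  } else {
    if (length(weights) != length(sequences) || any(weights < 0) ||
        sum(weights) == 0) {
      stop("weights must be nonnegative, one per sequence, not all zero")
    }
    mode <- "bound-count"
  }
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                  ncol = L, byrow = TRUE)
  probs <- vapply(seq_len(L), function(j) {
    w <- tapply(weights, factor(chars[, j], levels = DNA_BASES), sum, default = 0)
    as.numeric(w / sum(w))
  }, numeric(4))
  probs <- matrix(probs, nrow = 4, dimnames = list(DNA_BASES, seq_len(L)))
  plogp <- ifelse(probs > 0, probs * log2(probs), 0)
  info <- 2 + colSums(plogp)
  structure(list(probs = probs, info = as.numeric(info), length = L,
                 source_count = length(sequences), weights_mode = mode,
                 dropped = integer(0)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: %d columns from %d sequences (%s weights)\n",
              x$length, x$source_count, x$weights_mode))
  cat("  consensus:", paste(consensus_bases(x), collapse = ""), "\n")
  cat("  info (bits):", paste(sprintf("%.2f", x$info), collapse = " "), "\n")
  if (length(x$dropped)) {
    cat("  dropped columns:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Consensus bases of a PWM
#'
#' Top base per column; ties resolve to the alphabetically first base.
#'
#' @param pwm a [build_pwm()] result.
#' @return character vector of length `pwm$length`.
#' @export
consensus_bases <- function(pwm) {
  DNA_BASES[apply(pwm$probs, 2, which.max)]
}

#' Drop poorly informative logo positions
#'
#' Restricts a PWM to its maximal contiguous run of columns with information
#' content >= `min_info` (leftmost run on ties), recording the dropped column
#' indices; the full matrix is retained in the `full` element.
#'
#' @param pwm a [build_pwm()] result.
#' @param min_info information threshold in bits; the default 0.2 removes
#'   near-background flanking positions while keeping weak preferences.
#' @return a trimmed `pwm` (possibly zero columns, with a warning) with
#'   elements `dropped` (original column indices removed) and `full`.
#' @export
trim_logo <- function(pwm, min_info = 0.2) {
  stopifnot(inherits(pwm, "pwm"))
  ok <- pwm$info >= min_info
  if (!any(ok)) {
    warning("all columns fall below the information threshold: empty logo")
    keep <- integer(0)
  } else {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    keep <- seq.int(starts[best], ends[best])
  }
  out <- pwm
  out$probs <- pwm$probs[, keep, drop = FALSE]
  out$info <- pwm$info[keep]
  out$length <- length(keep)
  out$dropped <- setdiff(seq_len(pwm$length), keep)
  out$full <- pwm
  out
}

#' Export a PWM as TSV
#'
#' Base rows A/C/G/T by position columns, probabilities with 6 decimals,
#' followed by a `#info` line of per-column information content in bits.
#'
#' @param pwm a `pwm`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pwm_tsv <- function(pwm, path) {
  stopifnot(inherits(pwm, "pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("base", paste0("pos", seq_len(pwm$length))), collapse = "\t"), con)
  for (b in DNA_BASES) {
    writeLines(paste(c(b, sprintf("%.6f", pwm$probs[b, ])), collapse = "\t"), con)
  }
  writeLines(paste(c("#info_bits", sprintf("%.6f", pwm$info)), collapse = "\t"), con)
  invisible(path)
}
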