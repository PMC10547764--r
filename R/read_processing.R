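QC_REASONS <- c("flank_not_found", "wrong_region_length",
                "ambiguous_base", "not_reverse_complement")

#' Extract the randomized core from reads
#'
#' Locates the first occurrence of the left flank, then the first occurrence of
#' the right flank after it, and returns the intervening substring when it has
#' length `n` and contains only A/C/G/T. Failures are returned as data (a
#' reason string), never raised: they become the QC tallies of a count table.
#'
#' @param reads character vector of read sequences (A/C/G/T/N).
#' @param design a [library_design()]; mate-2 reads should be matched against
#'   the mirrored design (see [extract_pairs()]).
#' @param max_mismatch maximum Hamming mismatches allowed when locating each
#'   flank; the default 0 is exact matching. Tolerant matching uses
#'   Biostrings::vmatchPattern and is substantially slower.
#' @return data.frame with columns `core` (NA on failure) and `reason`
#'   (NA on success, otherwise one of `flank_not_found`,
#'   `wrong_region_length`, `ambiguous_base`).
#' @examples
#' d <- library_design("TTGGA", "CCAAT", 4)
#' extract_region("TTGGAGACCCCAAT", d)$core  # "GACC"
#' @export
extract_region <- function(reads, design, max_mismatch = 0L) {
  stopifnot(inherits(design, "library_design"))
  reads <- toupper(as.character(reads))
  if (length(reads) == 0L) {
    return(data.frame(core = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  if (any(!nzchar(reads) | is.na(reads))) stop("reads must be nonempty strings")
  lf <- design$left_flank
  rf <- design$right_flank
  n <- design$n

  if (max_mismatch > 0L) {
    starts_l <- first_match_start(reads, lf, max_mismatch)
    # search the right flank only downstream of the left flank end
    tail_off <- ifelse(is.na(starts_l), NA_integer_, starts_l + nchar(lf))
    tails <- ifelse(is.na(tail_off), "", substr(reads, tail_off, nchar(reads)))
    starts_r <- first_match_start(tails, rf, max_mismatch)
    core_start <- tail_off
    core_end <- tail_off + starts_r - 2L
  } else {
    p1 <- regexpr(lf, reads, fixed = TRUE)
    core_start <- ifelse(p1 > 0L, p1 + nchar(lf), NA_integer_)
    tails <- ifelse(p1 > 0L, substr(reads, core_start, nchar(reads)), "")
    p2 <- regexpr(rf, tails, fixed = TRUE)
    core_end <- ifelse(p1 > 0L & p2 > 0L, core_start + p2 - 2L, NA_integer_)
  }

  found <- !is.na(core_start) & !is.na(core_end)
  core <- ifelse(found, substr(reads, core_start, core_end), NA_character_)
  len_ok <- found & nchar(core) == n
  base_ok <- len_ok & grepl("^[ACGT]*$", core)

  reason <- rep(NA_character_, length(reads))
  reason[!found] <- "flank_not_found"
  reason[found & !len_ok] <- "wrong_region_length"
  reason[len_ok & !base_ok] <- "ambiguous_base"
  core[!base_ok] <- NA_character_
  data.frame(core = core, reason = reason, stringsAsFactors = FALSE)
}

# vectorized first-match start with Hamming tolerance (1-based; NA if none)
first_match_start <- function(subjects, pattern, max_mismatch) {
  ok <- nzchar(subjects)
  out <- rep(NA_integer_, length(subjects))
  if (!any(ok)) return(out)
  hits <- Biostrings::vmatchPattern(pattern,
                                    Biostrings::DNAStringSet(gsub("[^ACGTN]", "N", subjects[ok])),
                                    max.mismatch = max_mismatch)
  st <- Biostrings::startIndex(hits)
  out[ok] <- vapply(st, function(v) if (length(v)) min(v) else NA_integer_, integer(1))
  out
}

#' Apply the reverse-complement pair-consistency filter
#'
#' Mate 1 is matched against the design, mate 2 against the mirrored design
#' (left flank = reverse complement of the right flank and vice versa, since
#' mate 2 reads the bottom strand). A pair is kept only when both cores extract
#' cleanly and the mate-2 core is the reverse complement of the mate-1 core;
#' the kept value is the mate-1 core, which defines sequence-type orientation.
#'
#' @param read1,read2 character vectors of mate sequences, same length.
#' @inheritParams extract_region
#' @return data.frame with columns `core` and `reason`; reasons as in
#'   [extract_region()] plus `not_reverse_complement`. When both mates fail,
#'   the mate-1 reason is reported.
#' @export
extract_pairs <- function(read1, read2, design, max_mismatch = 0L) {
  if (length(read1) != length(read2)) {
    stop("mate streams have different lengths (", length(read1), " vs ",
         length(read2), ")")
  }
  r1 <- extract_region(read1, design, max_mismatch)
  r2 <- extract_region(read2, mirror_design(design), max_mismatch)
  core <- r1$core
  reason <- ifelse(!is.na(r1$reason), r1$reason, r2$reason)
  both_ok <- is.na(reason)
  if (any(both_ok)) {
    rc_ok <- rep(FALSE, length(core))
    rc_ok[both_ok] <- r2$core[both_ok] == reverse_complement(r1$core[both_ok])
    reason[both_ok & !rc_ok] <- "not_reverse_complement"
  }
  core[!is.na(reason)] <- NA_character_
  data.frame(core = core, reason = reason, stringsAsFactors = FALSE)
}

#' Count core sequence types for one pool
#'
#' Tallies kept pairs into counts over the full 4^n sequence space (types never
#' observed are present with count 0) and records discarded pairs by reason.
#' These are the per-type read counts of the input pool and of the bound pool
#' from which proportions and relative binding energies are computed.
#'
#' @param read1,read2 character vectors of mate sequences, or `NULL` to count
#'   from `fastq1`/`fastq2`.
#' @param design a [library_design()].
#' @param pool `"input"` or `"bound"`.
#' @param fastq1,fastq2 paths to paired FASTQ (optionally .gz) files, used when
#'   `read1` is NULL.
#' @param collapse_rc collapse each type with its reverse complement (summing
#'   counts into the lexicographically smaller member); off by default — the
#'   assay counts all 4^n strand-oriented types.
#' @inheritParams extract_region
#' @return an object of class `count_table`: `design`, `pool`, `counts` (named
#'   integer vector over the whole space, lexicographic), `qc` (named integer
#'   vector of discard tallies), `total_pairs`.
#' @examples
#' d <- library_design("TTGGA", "CCAAT", 4)
#' r1 <- rep("TTGGAGACCCCAAT", 3)
#' tab <- count_pool(r1, reverse_complement(r1), d, "input")
#' tab$counts[["GACC"]]  # 3
#' @export
count_pool <- function(read1 = NULL, read2 = NULL, design, pool = c("input", "bound"),
                       fastq1 = NULL, fastq2 = NULL,
                       max_mismatch = 0L, collapse_rc = FALSE) {
  pool <- match.arg(pool)
  stopifnot(inherits(design, "library_design"))
  if (is.null(read1)) {
    if (is.null(fastq1) || is.null(fastq2)) {
      stop("provide either read vectors or a pair of FASTQ paths")
    }
    rp <- read_fastq_pair(fastq1, fastq2)
    read1 <- rp$read1
    read2 <- rp$read2
  }
  if (length(read1) != length(read2)) {
    stop("mate streams have different lengths (", length(read1), " vs ",
         length(read2), ")")
  }
  space <- enumerate_space(design$n)
  counts <- stats::setNames(integer(length(space$sequences)), space$sequences)
  qc <- stats::setNames(integer(length(QC_REASONS)), QC_REASONS)
  if (length(read1) == 0L) {
    warning("empty read stream: returning an all-zero count table")
  } else {
    ex <- extract_pairs(read1, read2, design, max_mismatch)
    kept <- ex$core[is.na(ex$reason)]
    tab <- table(factor(kept, levels = space$sequences))
    counts[] <- as.integer(tab)
    fails <- table(factor(ex$reason[!is.na(ex$reason)], levels = QC_REASONS))
    qc[] <- as.integer(fails)
  }
  if (collapse_rc) {
    rc <- reverse_complement(space$sequences)
    canon <- pmin(space$sequences, rc)
    agg <- rowsum(as.integer(counts), canon)
    counts[] <- 0L
    counts[rownames(agg)] <- as.integer(agg[, 1])
  }
  structure(list(design = design, pool = pool, counts = counts, qc = qc,
                 total_pairs = length(read1)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table (%s pool): n = %d, %d types, %d kept / %d pairs\n",
              x$pool, x$design$n, length(x$counts), sum(x$counts), x$total_pairs))
  bad <- x$qc[x$qc > 0]
  if (length(bad)) {
    cat("  discarded:", paste(sprintf("%s=%d", names(bad), bad), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a count table from pre-computed counts
#'
#' Wraps a named count vector (e.g. counts computed elsewhere, or a planted
#' simulation truth) into a `count_table` over the full 4^n space; types not
#' named get count 0.
#'
#' @param counts named nonnegative counts; names must be length-n sequences.
#' @param design a [library_design()].
#' @param pool `"input"` or `"bound"`.
#' @param qc optional named QC tally vector; defaults to all zero.
#' @param total_pairs optional total pairs processed; defaults to
#'   `sum(counts) + sum(qc)`.
#' @return a `count_table`.
#' @export
count_table_from_counts <- function(counts, design, pool = "input",
                                    qc = NULL, total_pairs = NULL) {
  space <- enumerate_space(design$n)
  full <- stats::setNames(integer(length(space$sequences)), space$sequences)
  if (length(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% space$sequences)) {
      stop("counts must be named with length-n core sequences")
    }
    if (any(counts < 0)) stop("counts must be nonnegative")
    full[names(counts)] <- as.integer(round(counts))
  }
  if (is.null(qc)) qc <- stats::setNames(integer(length(QC_REASONS)), QC_REASONS)
  if (is.null(total_pairs)) total_pairs <- sum(full) + sum(qc)
  structure(list(design = design, pool = pool, counts = full, qc = qc,
                 total_pairs = total_pairs),
            class = "count_table")
}

#' Read a pair of FASTQ files
#'
#' @param fastq1,fastq2 paths to mate-1 and mate-2 FASTQ(.gz) files.
#' @return list with character vectors `read1`, `read2` and `id` (mate-1 ids).
#' @export
read_fastq_pair <- function(fastq1, fastq2) {
  s1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  if (length(s1) != length(s2)) {
    stop("mate files have different numbers of records (",
         length(s1), " vs ", length(s2), ")")
  }
  list(read1 = as.character(s1), read2 = as.character(s2),
       id = sub(" .*", "", names(s1)))
}

#' Write / read a count table as TSV
#'
#' The table body has columns `sequence`, `count` (header line, lexicographic
#' order); QC tallies and totals follow as `#key<TAB>value` comment lines so a
#' single file round-trips the whole object.
#'
#' @param table a `count_table`.
#' @param path file path.
#' @return `write_count_tsv`: the path, invisibly. `read_count_tsv`: a
#'   `count_table`.
#' @export
write_count_tsv <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#left_flank\t%s", table$design$left_flank),
               sprintf("#right_flank\t%s", table$design$right_flank),
               sprintf("#n\t%d", table$design$n),
               sprintf("#pool\t%s", table$pool),
               sprintf("#total_pairs\t%d", table$total_pairs),
               sprintf("#qc_%s\t%d", names(table$qc), table$qc),
               "sequence\tcount",
               sprintf("%s\t%d", names(table$counts), table$counts)),
             con)
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#", "", meta_lines), "\t", fixed = TRUE))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE,
                            colClasses = c("character", "integer"))
  design <- suppressWarnings(
    library_design(meta[["left_flank"]], meta[["right_flank"]],
                   as.integer(meta[["n"]])))
  qc <- stats::setNames(integer(length(QC_REASONS)), QC_REASONS)
  for (r in QC_REASONS) {
    key <- paste0("qc_", r)
    if (key %in% names(meta)) qc[r] <- as.integer(meta[[key]])
  }
  count_table_from_counts(stats::setNames(body$count, body$sequence), design,
                          pool = meta[["pool"]], qc = qc,
                          total_pairs = as.integer(meta[["total_pairs"]]))
}
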