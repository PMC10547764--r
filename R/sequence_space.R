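#' Define a randomized-core library construct
#'
#' A library construct is a fixed left flank, `n` randomized bases, and a fixed
#' right flank; the randomized core takes all 4^n values over A/C/G/T. The
#' flanks anchor extraction of the core from sequencing reads.
#'
#' @param left_flank fixed sequence 5' of the random region (uppercase ACGT).
#' @param right_flank fixed sequence 3' of the random region.
#' @param n number of randomized bases; 4..7 is the designed range, larger
#'   values (up to 12) are accepted with a warning.
#' @return an object of class `library_design`.
#' @examples
#' design <- library_design("TTGGA", "CCAAT", n = 4)
#' @export
library_design <- function(left_flank, right_flank, n) {
  stopifnot_dna(left_flank, "left_flank")
  stopifnot_dna(right_flank, "right_flank")
  if (!is.numeric(n) || length(n) != 1L || n != as.integer(n) || n < 1) {
    stop("'n' must be a single positive integer")
  }
  n <- as.integer(n)
  if (n > 12L) stop("random region length n > 12 is not supported (4^n sequence types)")
  if (n < 4L || n > 7L) {
    warning(sprintf("n = %d is outside the designed range 4..7", n))
  }
  if (grepl(left_flank, right_flank, fixed = TRUE) ||
      grepl(right_flank, left_flank, fixed = TRUE)) {
    stop("left_flank and right_flank must not contain each other")
  }
  structure(list(left_flank = left_flank, right_flank = right_flank, n = n),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf("library_design: %s-[N x %d]-%s (4^%d = %d core sequence types)\n",
              x$left_flank, x$n, x$right_flank, x$n, 4L^x$n))
  invisible(x)
}

# design seen by mate 2, which reads the bottom strand
mirror_design <- function(design) {
  library_design_unchecked(reverse_complement(design$right_flank),
                           reverse_complement(design$left_flank),
                           design$n)
}

# internal constructor bypassing the 4..7 warning (mirroring, marginalization)
library_design_unchecked <- function(left_flank, right_flank, n) {
  structure(list(left_flank = left_flank, right_flank = right_flank,
                 n = as.integer(n)),
            class = "library_design")
}

#' Enumerate the exhaustive core-sequence space
#'
#' All 4^n sequences of length `n` over A/C/G/T in lexicographic order
#' (A < C < G < T), with the inverse sequence-to-ordinal index.
#'
#' @param n core length (1..12; the assay's designed range is 4..7).
#' @return an object of class `sequence_space` with elements `n`, `sequences`
#'   (character vector of length 4^n) and `index` (named integer vector,
#'   1-based ordinals).
#' @examples
#' sp <- enumerate_space(2)
#' head(sp$sequences)      # "AA" "AC" "AG" "AT" "CA" "CC"
#' sp$index[["GT"]]        # 12
#' @export
enumerate_space <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != as.integer(n) || n < 1) {
    stop("'n' must be a single positive integer")
  }
  n <- as.integer(n)
  if (n > 12L) stop("n > 12 rejected: 4^n sequence types would be impractically large")
  cols <- rev(do.call(expand.grid,
                      c(rep(list(DNA_BASES), n),
                        list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))))
  seqs <- do.call(paste0, cols)
  structure(list(n = n, sequences = seqs,
                 index = stats::setNames(seq_along(seqs), seqs)),
            class = "sequence_space")
}

#' @export
print.sequence_space <- function(x, ...) {
  cat(sprintf("sequence_space: n = %d, 4^%d = %d sequences (%s .. %s)\n",
              x$n, x$n, length(x$sequences),
              x$sequences[1], x$sequences[length(x$sequences)]))
  invisible(x)
}

#' Watson-Crick reverse complement
#'
#' @param s character vector of DNA sequences over A/C/G/T.
#' @return character vector of the same length.
#' @examples
#' reverse_complement("GACC")  # "GGTC"
#' @export
reverse_complement <- function(s) {
  if (length(s) == 0L) return(character(0))
  if (!all(is_dna(s))) stop("sequences must be over A/C/G/T only")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Find all core-containing sequences in a space
#'
#' Returns the sequences of `space` that contain `core` as a contiguous
#' substring, e.g. for highlighting every NGAC/GACN cell in a landscape plot.
#'
#' @param space a `sequence_space`.
#' @param core DNA string, 1 <= nchar(core) <= n.
#' @return character vector of matching sequences (lexicographic order).
#' @examples
#' core_mask(enumerate_space(4), "GAC")  # 8 sequences: GACN and NGAC
#' @export
core_mask <- function(space, core) {
  stopifnot(inherits(space, "sequence_space"))
  stopifnot_dna(core, "core")
  if (nchar(core) > space$n) {
    warning("core is longer than the random region; no sequence can contain it")
    return(character(0))
  }
  space$sequences[grepl(core, space$sequences, fixed = TRUE)]
}

#' Recursive-quadrant K-mer grid layout
#'
#' Places every length-k sequence in a unique cell of a 2^k x 2^k grid by the
#' chaos-game-style recursion: base i of the sequence selects a quadrant of the
#' remaining block, so all sequences sharing a length-p prefix occupy one
#' contiguous 2^(k-p) x 2^(k-p) block. This is the x-y plane on which read
#' depth and binding-energy landscapes are drawn.
#'
#' @param k sequence length (grid is 2^k x 2^k).
#' @param base_quadrants named list mapping each base to its (row-bit, col-bit)
#'   corner; the default A=(0,0), C=(0,1), G=(1,0), T=(1,1) puts all
#'   G-prefixed sequences in the lower-left quadrant block. Must be a bijection
#'   onto the four corners.
#' @return an object of class `kmer_layout`: `k`, `cell` (data.frame with
#'   columns sequence, row, col; 0-based, row 0 rendered at top), and
#'   `base_quadrants`.
#' @examples
#' lay <- kmer_layout(2)
#' lay$cell[lay$cell$sequence == "GA", ]  # row 2, col 0
#' @export
kmer_layout <- function(k, base_quadrants = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != as.integer(k)) {
    stop("'k' must be a single positive integer")
  }
  k <- as.integer(k)
  if (k > 12L) stop("k > 12 rejected")
  if (is.null(base_quadrants)) {
    base_quadrants <- list(A = c(0L, 0L), C = c(0L, 1L),
                           G = c(1L, 0L), T = c(1L, 1L))
  }
  if (!setequal(names(base_quadrants), DNA_BASES)) {
    stop("base_quadrants must assign exactly the bases A, C, G, T")
  }
  corners <- vapply(base_quadrants[DNA_BASES],
                    function(b) paste(as.integer(b), collapse = ""), character(1))
  if (!setequal(corners, c("00", "01", "10", "11"))) {
    stop("base_quadrants must be a bijection onto the four corners (0,0)..(1,1)")
  }
  space <- enumerate_space(k)
  chars <- matrix(unlist(strsplit(space$sequences, "", fixed = TRUE)),
                  ncol = k, byrow = TRUE)
  rowbit <- vapply(DNA_BASES, function(b) as.integer(base_quadrants[[b]][1]), integer(1))
  colbit <- vapply(DNA_BASES, function(b) as.integer(base_quadrants[[b]][2]), integer(1))
  w <- as.integer(2^(k - seq_len(k)))  # base i weights the 2^(k-i) sub-block
  rows <- integer(length(space$sequences))
  cols <- integer(length(space$sequences))
  for (i in seq_len(k)) {
    b <- match(chars[, i], DNA_BASES)
    rows <- rows + rowbit[b] * w[i]
    cols <- cols + colbit[b] * w[i]
  }
  structure(list(k = k,
                 cell = data.frame(sequence = space$sequences,
                                   row = unname(rows), col = unname(cols),
                                   stringsAsFactors = FALSE),
                 base_quadrants = base_quadrants),
            class = "kmer_layout")
}

#' @export
print.kmer_layout <- function(x, ...) {
  cat(sprintf("kmer_layout: k = %d, %d cells on a %d x %d grid\n",
              x$k, nrow(x$cell), 2L^x$k, 2L^x$k))
  invisible(x)
}

#' Export a K-mer grid layout as TSV
#'
#' Columns `sequence`, `row`, `col`; header line; lexicographic order.
#'
#' @param layout a `kmer_layout`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_layout_tsv <- function(layout, path) {
  stopifnot(inherits(layout, "kmer_layout"))
  write_tsv_file(layout$cell[order(layout$cell$sequence), ], path)
}
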