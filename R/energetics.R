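#' Sequence-type proportions from a count table
#'
#' p_i = (count_i + pseudocount) / sum_j (count_j + pseudocount). With the
#' default pseudocount 0, types absent from the pool get proportion 0 and will
#' carry an undefined (NA) relative binding energy rather than a fabricated
#' one; an opt-in pseudocount (1 is a reasonable choice) regularizes instead.
#'
#' @param table a `count_table`.
#' @param pseudocount nonnegative number added to every type's count.
#' @return named numeric vector summing to 1 over the whole 4^n space.
#' @export
proportions <- function(table, pseudocount = 0) {
  stopifnot(inherits(table, "count_table"))
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  x <- as.numeric(table$counts) + pseudocount
  tot <- sum(x)
  if (tot <= 0) stop("all-zero count table with pseudocount 0: proportions undefined")
  stats::setNames(x / tot, names(table$counts))
}

#' Relative binding-energy landscape from an input/bound table pair
#'
#' For every core sequence type S_i the relative binding energy is
#' ddg_i = -log2( P(S_i | bound) / P(S_i) ), the negative log2 ratio of the
#' type's proportion in the bound pool to its proportion in the input pool.
#' Lower values mean stronger binding; the landscape is defined up to an
#' additive constant set by overall pool composition. Types with a zero
#' proportion in either pool (after the pseudocount policy) have ddg = NA —
#' they are flagged absent, never fabricated.
#'
#' @param input_table `count_table` for the random input pool.
#' @param bound_table `count_table` for the protein-bound pool.
#' @param pseudocount nonnegative number added to every count in both pools.
#' @return an object of class `energy_landscape`: `design`, `p_input`,
#'   `p_bound`, `ddg` (named, log2 units, NA where undefined), `pseudocount`,
#'   `provenance`, and the two count vectors.
#' @examples
#' d <- suppressWarnings(library_design("TTGGA", "CCAAT", 1))
#' it <- count_table_from_counts(c(A = 25, C = 25, G = 25, T = 25), d, "input")
#' bt <- count_table_from_counts(c(A = 50, C = 25, G = 15, T = 10), d, "bound")
#' relative_binding_energy(it, bt)$ddg  # A: -1, C: 0, G: ~0.737, T: ~1.32
#' @export
relative_binding_energy <- function(input_table, bound_table, pseudocount = 0) {
  stopifnot(inherits(input_table, "count_table"),
            inherits(bound_table, "count_table"))
  if (!identical(unclass(input_table$design), unclass(bound_table$design))) {
    stop("input and bound tables come from different library designs")
  }
  p_in <- proportions(input_table, pseudocount)
  p_bd <- proportions(bound_table, pseudocount)
  ddg <- rep(NA_real_, length(p_in))
  ok <- p_in > 0 & p_bd > 0
  ddg[ok] <- -log2(p_bd[ok] / p_in[ok])
  names(ddg) <- names(p_in)
  structure(list(design = input_table$design,
                 input_counts = input_table$counts,
                 bound_counts = bound_table$counts,
                 p_input = p_in, p_bound = p_bd, ddg = ddg,
                 pseudocount = pseudocount,
                 provenance = c(input = input_table$pool, bound = bound_table$pool)),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  def <- sum(!is.na(x$ddg))
  cat(sprintf("energy_landscape: n = %d, %d/%d types defined, ddg range [%.3f, %.3f] log2\n",
              x$design$n, def, length(x$ddg),
              suppressWarnings(min(x$ddg, na.rm = TRUE)),
              suppressWarnings(max(x$ddg, na.rm = TRUE))))
  invisible(x)
}

#' Select the high-affinity sequence set
#'
#' All sequences with a defined relative binding energy strictly below
#' `cutoff`. The default cutoff of -1 log2 unit (a two-fold enrichment in the
#' bound pool) is the threshold used to feed the PWM sequence logo.
#'
#' @param landscape an `energy_landscape`.
#' @param cutoff finite number, log2 units.
#' @return character vector of selected sequences (lexicographic order).
#' @export
select_high_affinity <- function(landscape, cutoff = -1) {
  stopifnot(inherits(landscape, "energy_landscape"), is.finite(cutoff))
  names(landscape$ddg)[!is.na(landscape$ddg) & landscape$ddg < cutoff]
}

#' Correlate two landscapes
#'
#' Pearson (default) or Spearman correlation of relative binding energies over
#' the intersection of sequences defined in both landscapes — the replicate
#' reproducibility / cross-protein comparison statistic. Plain named numeric
#' vectors are accepted in place of landscapes.
#'
#' @param a,b `energy_landscape` objects or named numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return the correlation coefficient.
#' @export
compare_landscapes <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  va <- if (inherits(a, "energy_landscape")) a$ddg else a
  vb <- if (inherits(b, "energy_landscape")) b$ddg else b
  if (is.null(names(va)) || is.null(names(vb))) {
    if (length(va) != length(vb)) stop("unnamed vectors must have equal length")
    names(va) <- names(vb) <- seq_along(va)
  }
  shared <- intersect(names(va)[!is.na(va)], names(vb)[!is.na(vb)])
  if (length(shared) < 3L) {
    stop("fewer than 3 sequences defined in both landscapes")
  }
  stats::cor(va[shared], vb[shared], method = method)
}

#' Marginalize (K+1)-mer count tables to a K-mer landscape
#'
#' Each (K+1)-mer contributes its count to its two length-K windows (the
#' prefix and the suffix), independently for the input and the bound pool; the
#' relative binding energy is then computed on the marginal tables. Summing
#' counts before taking ratios propagates sampling weight correctly; the
#' alternative of averaging (K+1)-mer energies over windows is available via
#' `scheme = "average"`. `windows` restricts which windows contribute (count
#' scheme only): prefix-window marginalization exactly recovers, up to an
#' additive constant, any landscape whose (K+1)-mer energies depend only on
#' the first K bases, whereas both-window marginalization mixes shifted
#' contexts (see the methods vignette).
#'
#' @param input_table,bound_table `count_table`s at core length K+1 (>= 2).
#' @param pseudocount passed to [relative_binding_energy()] on the marginals.
#' @param scheme `"counts"` (default) or `"average"`.
#' @param windows which length-K windows contribute: `"both"` (default),
#'   `"prefix"` or `"suffix"`.
#' @return an `energy_landscape` at core length K (scheme "counts"), or a
#'   named numeric vector of averaged energies (scheme "average").
#' @export
marginalize <- function(input_table, bound_table, pseudocount = 0,
                        scheme = c("counts", "average"),
                        windows = c("both", "prefix", "suffix")) {
  scheme <- match.arg(scheme)
  windows <- match.arg(windows)
  stopifnot(inherits(input_table, "count_table"))
  n1 <- input_table$design$n
  if (n1 < 2L) stop("need core length K+1 >= 2 to marginalize")
  K <- n1 - 1L
  seqs <- names(input_table$counts)
  pre <- substr(seqs, 1L, K)
  suf <- substr(seqs, 2L, n1)
  sub_design <- library_design_unchecked(input_table$design$left_flank,
                                         input_table$design$right_flank, K)
  space_k <- enumerate_space(K)$sequences

  marginal_counts <- function(counts) {
    out <- stats::setNames(numeric(length(space_k)), space_k)
    if (windows %in% c("both", "prefix")) {
      agg <- rowsum(as.numeric(counts), pre)
      out[rownames(agg)] <- out[rownames(agg)] + agg[, 1]
    }
    if (windows %in% c("both", "suffix")) {
      agg <- rowsum(as.numeric(counts), suf)
      out[rownames(agg)] <- out[rownames(agg)] + agg[, 1]
    }
    out
  }

  if (scheme == "average") {
    land <- relative_binding_energy(input_table, bound_table, pseudocount)
    w <- as.numeric(input_table$counts)
    num <- stats::setNames(numeric(length(space_k)), space_k)
    den <- num
    for (win in list(pre, suf)[if (windows == "both") 1:2 else
                               if (windows == "prefix") 1L else 2L]) {
      ok <- !is.na(land$ddg) & w > 0
      a <- rowsum((land$ddg * w)[ok], win[ok])
      b <- rowsum(w[ok], win[ok])
      num[rownames(a)] <- num[rownames(a)] + a[, 1]
      den[rownames(b)] <- den[rownames(b)] + b[, 1]
    }
    return(ifelse(den > 0, num / den, NA_real_))
  }

  mt_in <- count_table_from_counts(marginal_counts(input_table$counts),
                                   sub_design, pool = input_table$pool)
  mt_bd <- count_table_from_counts(marginal_counts(bound_table$counts),
                                   sub_design, pool = bound_table$pool)
  relative_binding_energy(mt_in, mt_bd, pseudocount)
}

#' EMSA comparison statistic
#'
#' The gel-based validation statistic -log2(bound/unbound) computed from mean
#' grayscale intensities of the bound and unbound bands; plotted against the
#' sequencing-derived relative binding energy for validation.
#'
#' @param bound_gray,unbound_gray positive band intensities (vectorized).
#' @return numeric vector of statistics.
#' @export
emsa_statistic <- function(bound_gray, unbound_gray) {
  if (any(bound_gray <= 0) || any(unbound_gray <= 0)) {
    stop("band intensities must be positive")
  }
  -log2(bound_gray / unbound_gray)
}

#' Export an energy landscape as TSV
#'
#' Columns `sequence`, `input_count`, `bound_count`, `p_input`, `p_bound`,
#' `ddg_log2` (6 decimals, `NA` for undefined); header line; lexicographic
#' order.
#'
#' @param landscape an `energy_landscape`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_landscape_tsv <- function(landscape, path) {
  stopifnot(inherits(landscape, "energy_landscape"))
  df <- as.data.frame(landscape)
  write_tsv_file(df, path)
}

#' @export
as.data.frame.energy_landscape <- function(x, ...) {
  data.frame(sequence = names(x$ddg),
             input_count = as.integer(x$input_counts),
             bound_count = as.integer(x$bound_counts),
             p_input = as.numeric(x$p_input),
             p_bound = as.numeric(x$p_bound),
             ddg_log2 = as.numeric(x$ddg),
             stringsAsFactors = FALSE)
}
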