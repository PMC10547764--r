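DNA_BASES <- c("A", "C", "G", "T")

# RT at 298 K, kcal/mol; log2 unit = RT*ln2 kcal/mol
RT_KCAL <- 0.593

#' Convert energies between kcal/mol and log2 units
#'
#' Relative binding energies are stored internally in dimensionless log2 units
#' (one unit = a two-fold change in bound/input enrichment). One log2 unit
#' corresponds to RT*ln(2) ~ 0.411 kcal/mol at 298 K (RT = 0.593 kcal/mol).
#'
#' @param x numeric vector of energies.
#' @return converted numeric vector.
#' @examples
#' kcal_to_log2(0.411)  # ~1
#' @export
kcal_to_log2 <- function(x) x / (RT_KCAL * log(2))

#' @rdname kcal_to_log2
#' @export
log2_to_kcal <- function(x) x * (RT_KCAL * log(2))

# run expr with a temporary RNG state seeded by `seed`; restores global state.
# seed = NULL means use (and advance) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed (kept well below 2^31) from a base seed and an offset
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1009L + as.integer(offset)) %% 1000000007L
}

is_dna <- function(x) !is.na(x) & grepl("^[ACGT]+$", x)

stopifnot_dna <- function(x, what = "sequence") {
  if (length(x) == 0L || !all(is_dna(x))) {
    stop(sprintf("%s must be a nonempty string over A/C/G/T", what), call. = FALSE)
  }
}

write_tsv_file <- function(df, path, digits = 6) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), "NA", sprintf(paste0("%.", digits, "f"), v))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
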