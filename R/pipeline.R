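#' Run the full landscape pipeline
#'
#' Executes extract -> count -> energy -> select -> logo -> render on a pair
#' of FASTQ libraries (input pool and bound pool) and writes every artifact —
#' count tables, landscape TSV, selected high-affinity set, PWM, figures, QC
#' report and a run manifest — under `out_dir`. Identical config and seed give
#' byte-identical TSV outputs.
#'
#' @param config a named list or the path to a YAML file with fields:
#'   `left_flank`, `right_flank`, `n` (library design);
#'   `input_fastq1`, `input_fastq2`, `bound_fastq1`, `bound_fastq2`;
#'   `out_dir`; optional `pseudocount` (default 0), `cutoff` (default -1),
#'   `min_info` (default 0.2), `max_mismatch` (default 0), `highlight_core`,
#'   `seed`.
#' @return invisibly, a list with the main objects (`input`, `bound`,
#'   `landscape`, `selected`, `pwm`, `trimmed`) and `paths` of all artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  req <- c("left_flank", "right_flank", "n", "input_fastq1", "input_fastq2",
           "bound_fastq1", "bound_fastq2", "out_dir")
  missing_keys <- setdiff(req, names(config))
  if (length(missing_keys)) {
    stop("config is missing required fields: ", paste(missing_keys, collapse = ", "))
  }
  for (f in c("input_fastq1", "input_fastq2", "bound_fastq1", "bound_fastq2")) {
    if (!file.exists(config[[f]])) stop("missing file for ", f, ": ", config[[f]])
  }
  opt <- function(key, default) if (is.null(config[[key]])) default else config[[key]]
  pseudocount <- opt("pseudocount", 0)
  cutoff <- opt("cutoff", -1)
  min_info <- opt("min_info", 0.2)
  max_mm <- opt("max_mismatch", 0L)
  highlight <- opt("highlight_core", NULL)

  design <- library_design(config$left_flank, config$right_flank, as.integer(config$n))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, paste0(...))
  message("design: ", design$left_flank, "-[Nx", design$n, "]-", design$right_flank)

  input <- count_pool(design = design, pool = "input",
                      fastq1 = config$input_fastq1, fastq2 = config$input_fastq2,
                      max_mismatch = max_mm)
  bound <- count_pool(design = design, pool = "bound",
                      fastq1 = config$bound_fastq1, fastq2 = config$bound_fastq2,
                      max_mismatch = max_mm)
  paths <- character(0)
  paths["input_counts"] <- write_count_tsv(input, path("input_counts.tsv"))
  paths["bound_counts"] <- write_count_tsv(bound, path("bound_counts.tsv"))

  land <- selected <- pwm <- trimmed <- NULL
  usable <- sum(input$counts) + pseudocount > 0 && sum(bound$counts) + pseudocount > 0
  if (!usable) {
    message("a pool has no kept reads (see the QC report): ",
            "skipping the energy landscape")
  } else {
    land <- relative_binding_energy(input, bound, pseudocount)
    paths["landscape"] <- write_landscape_tsv(land, path("landscape.tsv"))

    selected <- select_high_affinity(land, cutoff)
    writeLines(selected, path("high_affinity.txt"))
    paths["high_affinity"] <- path("high_affinity.txt")

    if (length(selected)) {
      pwm <- build_pwm(selected)
      trimmed <- trim_logo(pwm, min_info)
      paths["pwm"] <- write_pwm_tsv(pwm, path("pwm.tsv"))
      if (trimmed$length > 0) {
        plot_logo(trimmed, path("logo.png"))
        paths["logo"] <- path("logo.png")
      }
    } else {
      message("no sequences below cutoff ", cutoff, ": skipping the logo")
    }

    lay <- kmer_layout(design$n)
    render_landscape(land$input_counts, lay, "read_depth",
                     highlight_core = highlight,
                     file = path("read_depth_input.png"))
    render_landscape(land$ddg, lay, "minus_ddg", highlight_core = highlight,
                     file = path("energy_landscape.png"))
    paths["read_depth_fig"] <- path("read_depth_input.png")
    paths["energy_fig"] <- path("energy_landscape.png")
  }

  qc <- data.frame(pool = rep(c("input", "bound"), each = length(QC_REASONS) + 2L),
                   key = rep(c("pairs_total", "pairs_kept", QC_REASONS), 2),
                   value = c(input$total_pairs, sum(input$counts), input$qc,
                             bound$total_pairs, sum(bound$counts), bound$qc))
  paths["qc"] <- write_tsv_file(qc, path("qc_report.tsv"))

  manifest <- list(
    package = "bindscape",
    version = as.character(utils::packageVersion("bindscape")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    design = list(left_flank = design$left_flank,
                  right_flank = design$right_flank, n = design$n),
    parameters = list(pseudocount = pseudocount, cutoff = cutoff,
                      min_info = min_info, max_mismatch = max_mm,
                      seed = opt("seed", NULL)),
    inputs = config[c("input_fastq1", "input_fastq2",
                      "bound_fastq1", "bound_fastq2")],
    outputs = as.list(paths))
  yaml::write_yaml(manifest, path("run_manifest.yaml"))
  paths["manifest"] <- path("run_manifest.yaml")
  for (p in paths) message("wrote ", p)

  invisible(list(design = design, input = input, bound = bound,
                 landscape = land, selected = selected, pwm = pwm,
                 trimmed = trimmed, paths = paths))
}

#' Look up landscape values for sequences
#'
#' The batch replacement for interactively clicking a bar in a landscape
#' viewer: returns the grid cell and values for the queried sequences.
#'
#' @param landscape an `energy_landscape`.
#' @param sequences character vector of core sequences.
#' @param layout optional [kmer_layout()]; defaults to the design's n.
#' @return data.frame with sequence, row, col, input_count, bound_count,
#'   ddg_log2 and minus_ddg.
#' @examples
#' # query_value(landscape, "GACC")
#' @export
query_value <- function(landscape, sequences, layout = NULL) {
  stopifnot(inherits(landscape, "energy_landscape"))
  bad <- setdiff(sequences, names(landscape$ddg))
  if (length(bad)) stop("not in the sequence space: ", paste(bad, collapse = ", "))
  if (is.null(layout)) layout <- kmer_layout(landscape$design$n)
  cell <- layout$cell[match(sequences, layout$cell$sequence), ]
  data.frame(sequence = sequences, row = cell$row, col = cell$col,
             input_count = as.integer(landscape$input_counts[sequences]),
             bound_count = as.integer(landscape$bound_counts[sequences]),
             ddg_log2 = as.numeric(landscape$ddg[sequences]),
             minus_ddg = -as.numeric(landscape$ddg[sequences]),
             stringsAsFactors = FALSE)
}
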