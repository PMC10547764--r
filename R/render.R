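#' Render a value landscape on the K-mer grid
#'
#' Draws one cell (heatmap tile) or bar (3-D style) per sequence at its
#' recursive-quadrant grid position, colored by the transformed value:
#' `read_depth` and `ddg` are shown as-is, `minus_ddg` negates the relative
#' binding energy so that taller/warmer means stronger binding. Sequences
#' containing `highlight_core` are outlined. A sidecar TSV (sequence, row,
#' col, value, highlighted) is always the bit-exact record of the figure.
#'
#' @param values named numeric vector (sequence -> value); every name must be
#'   a sequence of the layout. Sequences missing from `values` render as NA.
#' @param layout a [kmer_layout()] of matching k.
#' @param value_kind `"read_depth"`, `"ddg"`, or `"minus_ddg"`.
#' @param highlight_core optional core sequence to highlight (see
#'   [core_mask()]).
#' @param file optional image path (.png or .svg by extension); NULL skips the
#'   image and returns the data.
#' @param sidecar optional TSV path; defaults to `file` with a .tsv extension
#'   when `file` is given.
#' @param style `"heatmap"` (ggplot2 tiles) or `"bars3d"` (lattice cloud,
#'   vertical bars).
#' @param palette viridis option letter for the fill scale.
#' @param width,height image size in inches.
#' @return invisibly, the sidecar data.frame.
#' @export
render_landscape <- function(values, layout,
                             value_kind = c("read_depth", "ddg", "minus_ddg"),
                             highlight_core = NULL, file = NULL, sidecar = NULL,
                             style = c("heatmap", "bars3d"),
                             palette = "D", width = 7, height = 6) {
  value_kind <- match.arg(value_kind)
  style <- match.arg(style)
  stopifnot(inherits(layout, "kmer_layout"))
  if (is.null(names(values))) stop("'values' must be a named vector")
  unknown <- setdiff(names(values), layout$cell$sequence)
  if (length(unknown)) {
    stop("values given for sequences absent from the layout: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  df <- layout$cell
  df$value <- unname(values[df$sequence])
  if (value_kind == "minus_ddg") df$value <- -df$value
  df$highlighted <- FALSE
  if (!is.null(highlight_core)) {
    sp <- enumerate_space(layout$k)
    df$highlighted <- df$sequence %in% core_mask(sp, highlight_core)
  }
  df <- df[order(df$sequence), ]
  if (!is.null(sidecar) || !is.null(file)) {
    if (is.null(sidecar)) sidecar <- sub("\\.[a-zA-Z]+$", ".tsv", file)
    write_tsv_file(df, sidecar)
  }
  if (!is.null(file)) {
    if (style == "heatmap") {
      p <- landscape_heatmap(df, layout$k, value_kind, palette)
      ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
    } else {
      open_device(file, width, height)
      print(landscape_bars3d(df, value_kind))
      grDevices::dev.off()
    }
  }
  invisible(df)
}

landscape_heatmap <- function(df, k, value_kind, palette) {
  hl <- df[df$highlighted, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::scale_fill_viridis_c(option = palette, na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = value_kind,
                  title = sprintf("%s landscape on the %d-mer grid",
                                  value_kind, k)) +
    ggplot2::theme_minimal()
  if (nrow(hl)) {
    p <- p + ggplot2::geom_tile(data = hl, fill = NA, colour = "red",
                                linewidth = 0.6)
  }
  if (k <= 2) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$sequence),
                                colour = "white", size = 3)
  }
  p
}

landscape_bars3d <- function(df, value_kind) {
  df2 <- df[!is.na(df$value), , drop = FALSE]
  lattice::cloud(value ~ col * row, data = df2, type = "h", lwd = 3,
                 pch = 16, cex = 0.4,
                 col = ifelse(df2$highlighted, "red", "steelblue"),
                 screen = list(z = 40, x = -60),
                 xlab = "col", ylab = "row", zlab = value_kind)
}

open_device <- function(file, width, height) {
  if (grepl("\\.svg$", file)) {
    grDevices::svg(file, width = width, height = height)
  } else {
    grDevices::png(file, width = width, height = height, units = "in", res = 150)
  }
}

#' Plot an information-content sequence logo
#'
#' Letter heights within a column are the base probabilities scaled by the
#' column's information content in bits, the standard information logo. Letters
#' are drawn as text glyphs scaled to their cell.
#'
#' @param pwm a [build_pwm()] (optionally [trim_logo()]-ed) matrix.
#' @param file optional image path; NULL returns the ggplot object only.
#' @param width,height image size in inches.
#' @return the ggplot object, invisibly.
#' @export
plot_logo <- function(pwm, file = NULL, width = 5, height = 3) {
  stopifnot(inherits(pwm, "pwm"))
  if (pwm$length == 0L) stop("cannot plot an empty logo")
  base_cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  pieces <- do.call(rbind, lapply(seq_len(pwm$length), function(j) {
    h <- pwm$probs[, j] * pwm$info[j]
    ord <- order(h)  # stack small to large, tallest on top
    data.frame(pos = j, base = DNA_BASES[ord], h = h[ord],
               y0 = cumsum(c(0, h[ord]))[seq_len(4)], stringsAsFactors = FALSE)
  }))
  pieces <- pieces[pieces$h > 1e-9, , drop = FALSE]
  p <- ggplot2::ggplot(pieces) +
    ggplot2::geom_text(ggplot2::aes(x = .data$pos, y = .data$y0 + .data$h / 2,
                                    label = .data$base, colour = .data$base,
                                    size = .data$h),
                       fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = base_cols) +
    ggplot2::scale_size_continuous(range = c(2, 14), limits = c(0, 2)) +
    ggplot2::scale_x_continuous(breaks = seq_len(pwm$length)) +
    ggplot2::ylim(0, 2) +
    ggplot2::labs(x = "position", y = "bits") +
    ggplot2::theme_classic()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
  invisible(p)
}

#' Plot a depth-accuracy curve
#'
#' @param dc a [depth_curve()] result.
#' @param file optional image path.
#' @return the ggplot object, invisibly.
#' @export
plot_depth_curve <- function(dc, file = NULL) {
  stopifnot(inherits(dc, "depth_curve"))
  p <- ggplot2::ggplot(dc$curve, ggplot2::aes(x = .data$depth, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.05) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "read pairs per pool", y = dc$metric) +
    ggplot2::theme_classic()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 5, height = 4, dpi = 150)
  invisible(p)
}
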