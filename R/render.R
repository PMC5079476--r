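# Heatmap rendering and table export. Figures use a diverging palette on
# the fixed domain [-1, 1] (never rescaled to the data) so panels from
# different runs share one color key; undefined correlations are drawn in
# a distinct missing-data color, never as numeric 0.

#' Heatmap rendering specification
#'
#' Bundles a clustered [pairwise_matrix()] result with presentation
#' parameters. The color domain is always exactly `[-1, 1]`.
#'
#' @param cm a `CorrelationMatrix` (clustered or not; unclustered matrices
#'   are drawn in their current ordering without a dendrogram).
#' @param format `"png"`, `"svg"` or `"pdf"`.
#' @param width,height figure size in inches.
#' @param dpi raster resolution (png only).
#' @param highlight optional experiment id (typically the user sample) to
#'   outline on the heatmap.
#' @param labels `"auto"` (hide above `label_limit` experiments),
#'   `"show"` or `"hide"`.
#' @param label_limit auto-hide threshold (default 80).
#' @param na_color fill for undefined correlations.
#' @param title optional plot title.
#' @return an object of class `HeatmapSpec`.
#' @export
heatmap_spec <- function(cm, format = c("png", "svg", "pdf"), width = 7,
                         height = 7, dpi = 150, highlight = NULL,
                         labels = c("auto", "show", "hide"),
                         label_limit = 80, na_color = "grey75",
                         title = NULL) {
  stopifnot(inherits(cm, "CorrelationMatrix"))
  format <- match.arg(format)
  labels <- match.arg(labels)
  if (!is.null(highlight) && !highlight %in% cm$ids) {
    stop(usage_error("highlight id '", highlight, "' is not in the matrix"))
  }
  structure(list(cm = cm, format = format, width = width, height = height,
                 dpi = dpi, highlight = highlight, labels = labels,
                 label_limit = label_limit, na_color = na_color,
                 title = title),
            class = "HeatmapSpec")
}

# diverging blue-white-red ramp over [-1, 1]
correlation_palette <- function(n = 255L) {
  grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(n)
}

# map r values to palette colors on the fixed [-1, 1] domain; NA -> na_color
correlation_colors <- function(r, na_color = "grey75") {
  pal <- correlation_palette()
  idx <- pmin(length(pal), pmax(1L, 1L + floor((r + 1) / 2 * length(pal))))
  out <- pal[idx]
  out[is.na(r)] <- na_color
  out
}

#' Render a clustered correlation heatmap
#'
#' Draws the correlation matrix in its clustering order with the
#' dendrogram on top, a fixed `[-1, 1]` color key, optional highlighting
#' of one experiment (the user sample), and labels auto-hidden for large
#' matrices. The input matrix is not modified.
#'
#' @param spec a [heatmap_spec()] (or a `CorrelationMatrix`, in which case
#'   defaults are used and extra arguments are passed to [heatmap_spec()]).
#' @param path output file; must match the spec's format.
#' @param ... passed to [heatmap_spec()] when `spec` is a matrix.
#' @export
render_heatmap <- function(spec, path, ...) {
  if (inherits(spec, "CorrelationMatrix")) spec <- heatmap_spec(spec, ...)
  stopifnot(inherits(spec, "HeatmapSpec"))
  cm <- spec$cm
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(usage_error("output directory does not exist: ", dir))

  switch(spec$format,
    png = grDevices::png(path, width = spec$width, height = spec$height,
                         units = "in", res = spec$dpi, type = "cairo"),
    svg = grDevices::svg(path, width = spec$width, height = spec$height),
    pdf = grDevices::pdf(path, width = spec$width, height = spec$height,
                         useDingbats = FALSE))
  on.exit(grDevices::dev.off())

  ord <- cm$ordering
  n <- length(ord)
  M <- cm$r[ord, ord, drop = FALSE]
  ids <- cm$ids[ord]
  show_labels <- switch(spec$labels,
                        show = TRUE, hide = FALSE,
                        auto = n <= spec$label_limit)
  has_dend <- !is.null(cm$linkage) && !is.null(cm$linkage$hclust)

  if (has_dend) {
    graphics::layout(matrix(c(1L, 2L), nrow = 2L), heights = c(1, 4.5))
  } else {
    graphics::layout(matrix(c(1L, 2L), nrow = 2L), heights = c(0.35, 5.15))
  }
  old_par <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old_par), add = TRUE, after = FALSE)
  lab_space <- if (show_labels) 5.5 else 1.2

  # top panel: dendrogram (spanning the clustered leaves) or title strip
  graphics::par(mar = c(0.2, lab_space, if (is.null(spec$title)) 0.6 else 2, 1.2))
  if (has_dend) {
    dend <- stats::as.dendrogram(cm$linkage$hclust)
    plot(dend, leaflab = "none", axes = FALSE,
         xlim = c(0.5, n + 0.5), xaxs = "i", main = spec$title)
  } else {
    graphics::plot.new()
    if (!is.null(spec$title)) graphics::title(main = spec$title)
  }

  # bottom panel: heatmap; row 1 of the ordering at the top
  graphics::par(mar = c(lab_space, lab_space, 0.2, 1.2))
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(0.5, n + 0.5),
                 xaxs = "i", yaxs = "i", axes = FALSE, xlab = "", ylab = "")
  cols <- correlation_colors(as.vector(M), spec$na_color)
  idx <- seq_len(n * n)                 # column-major over M
  ri <- ((idx - 1L) %% n) + 1L          # row index -> y (flipped: row 1 on top)
  cj <- ((idx - 1L) %/% n) + 1L         # column index -> x
  graphics::rect(cj - 0.5, n + 0.5 - ri, cj + 0.5, n + 1.5 - ri,
                 col = cols, border = NA)
  if (show_labels) {
    cex <- min(0.8, 40 / n)
    graphics::axis(1, at = seq_len(n), labels = ids, las = 2, tick = FALSE,
                   cex.axis = cex, line = -0.5)
    graphics::axis(2, at = n + 1L - seq_len(n), labels = ids, las = 2,
                   tick = FALSE, cex.axis = cex, line = -0.5)
  }
  if (!is.null(spec$highlight)) {
    k <- match(spec$highlight, ids)
    graphics::rect(k - 0.5, 0.5, k + 0.5, n + 0.5, border = "black", lwd = 2)
    graphics::rect(0.5, n + 0.5 - k, n + 0.5, n + 1.5 - k,
                   border = "black", lwd = 2)
  }
  graphics::box()
  invisible(NULL)
}

#' Export a correlation table or matrix
#'
#' Tab- or comma-separated output with a header row; correlation values
#' are written with 10 significant digits and undefined values as the
#' literal `NA`, so re-reading reproduces the ranking exactly.
#'
#' @param x a `CorrelationTable` or `CorrelationMatrix`.
#' @param path output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @export
export_table <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  fmt_r <- function(v) ifelse(is.na(v), "NA", sprintf("%.10g", v))
  if (inherits(x, "CorrelationTable")) {
    df <- as.data.frame(x)
    df$r <- fmt_r(df$r)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "CorrelationMatrix")) {
    ord <- x$ordering
    M <- x$r[ord, ord, drop = FALSE]
    ids <- x$ids[ord]
    header <- paste(c("experiment_id", ids), collapse = sep)
    rows <- vapply(seq_along(ids), function(i) {
      paste(c(ids[i], fmt_r(M[i, ])), collapse = sep)
    }, "")
    writeLines(c(header, rows), path)
  } else {
    stop(usage_error("export_table expects a CorrelationTable or CorrelationMatrix"))
  }
  invisible(NULL)
}

#' Read an exported correlation matrix
#'
#' Re-loads a matrix written by [export_table()] (e.g. for the `plot`
#' subcommand). The result carries no linkage tree; identity ordering.
#'
#' @param path file written by [export_table()] for a `CorrelationMatrix`.
#' @param format `"tsv"` or `"csv"`.
#' @return a `CorrelationMatrix`.
#' @export
read_matrix_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  lines <- read_text_lines(path)
  if (length(lines) < 3L) stop(data_error(path, ": not a correlation matrix"))
  ids <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]][-1L]
  n <- length(ids)
  r <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], sep, fixed = TRUE)[[1L]]
    if (length(f) != n + 1L) {
      stop(data_error(path, " line ", i + 1L, ": expected ", n + 1L,
                      " fields, found ", length(f)))
    }
    r[i, ] <- suppressWarnings(as.numeric(f[-1L]))
  }
  row_ids <- vapply(seq_len(n), function(i) {
    strsplit(lines[i + 1L], sep, fixed = TRUE)[[1L]][1L]
  }, "")
  if (!identical(row_ids, ids)) {
    stop(data_error(path, ": row ids disagree with header"))
  }
  undef <- ids[vapply(seq_len(n), function(i) all(is.na(r[i, -i])), TRUE) &
                 n > 1L]
  structure(list(ids = ids, r = r, undefined = undef, user_id = NULL,
                 ordering = seq_len(n), linkage = NULL),
            class = "CorrelationMatrix")
}
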