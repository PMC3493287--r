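#' Rendering options for the OSCAR heatmap
#'
#' @param colors Named vector mapping `green`, `red`, `yellow`, `gray` to hex
#'   colors. The default palette is colorblind-safe (bluish green / vermillion
#'   / pale yellow); `classic = TRUE` switches to pure green/red/yellow.
#' @param annotate `"diff_value"` prints the signed difference in each cell;
#'   `"none"` leaves cells blank.
#' @param row_order,col_order Optional permutations of the matrix axes. The
#'   default row order groups the panels: inflammatory (IL-6, IL-8, IL-16,
#'   TNF-a), injury-and-repair (VEGF, MMP-9), chemoattractant (MCP-1, PARC).
#' @param classic Use the classic pure green/red/yellow palette.
#' @return An object of class `oscar_render_spec`.
#' @export
oscar_render_spec <- function(colors = NULL,
                              annotate = c("diff_value", "none"),
                              row_order = NULL, col_order = NULL,
                              classic = FALSE) {
  annotate <- match.arg(annotate)
  if (is.null(colors)) {
    colors <- if (classic) {
      c(green = "#00A000", red = "#D00000", yellow = "#F0E000",
        gray = "#B0B0B0")
    } else {
      c(green = "#009E73", red = "#D55E00", yellow = "#F0E442",
        gray = "#B0B0B0")
    }
  }
  need <- c("green", "red", "yellow", "gray")
  if (!all(need %in% names(colors))) {
    stop("colors must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colors[need])) {
    stop("the four cell colors must be distinct", call. = FALSE)
  }
  structure(list(colors = colors, annotate = annotate,
                 row_order = row_order, col_order = col_order),
            class = "oscar_render_spec")
}

.default_row_order <- c("il6", "il8", "il16", "tnfa", "vegf", "mmp9",
                        "mcp1", "parc")

.svg_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

.svg_text <- function(x, y, s, size = 11, anchor = "middle") {
  sprintf('<text x="%.1f" y="%.1f" font-size="%d" font-family="sans-serif" text-anchor="%s">%s</text>',
          x, y, size, anchor, .svg_escape(s))
}

.svg_rect <- function(x, y, w, h, fill, stroke = "#404040") {
  sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="%s" stroke="%s" stroke-width="0.5"/>',
          x, y, w, h, fill, stroke)
}

#' Render the OSCAR heatmap to SVG
#'
#' One colored cell per biomarker-by-outcome pair, an optional signed
#' difference annotation, a legend tying the three colors to
#' better / worse / no clinically important difference, and a footnote when
#' gray (insufficient-data) cells are present. Rendering is a pure function
#' of its inputs: identical matrix and spec give byte-identical SVG.
#'
#' @param matrix An `oscar_matrix` from [build_oscar_matrix].
#' @param spec An [oscar_render_spec].
#' @param path Output path (`.svg`).
#' @return `path`, invisibly.
#' @export
render_oscar <- function(matrix, spec = oscar_render_spec(), path) {
  stopifnot(inherits(matrix, "oscar_matrix"),
            inherits(spec, "oscar_render_spec"))
  if (length(matrix$biomarkers) == 0 || length(matrix$outcomes) == 0) {
    stop("cannot render an empty matrix", call. = FALSE)
  }
  rows <- spec$row_order
  if (is.null(rows)) {
    rows <- c(intersect(.default_row_order, matrix$biomarkers),
              setdiff(matrix$biomarkers, .default_row_order))
  }
  cols <- if (is.null(spec$col_order)) matrix$outcomes else spec$col_order
  if (!setequal(rows, matrix$biomarkers)) {
    stop("row_order is not a permutation of the matrix biomarkers",
         call. = FALSE)
  }
  if (!setequal(cols, matrix$outcomes)) {
    stop("unknown outcome in ordering: ",
         paste(setdiff(cols, matrix$outcomes), collapse = ", "),
         call. = FALSE)
  }
  cw <- 86
  ch <- 30
  left <- 70
  top <- 60
  has_gray <- any(matrix$colors[rows, cols] == "gray")
  width <- left + cw * length(cols) + 20
  height <- top + ch * length(rows) + 70 + if (has_gray) 16 else 0

  cell_df <- matrix$cells
  key <- paste(cell_df$biomarker, cell_df$outcome)
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF"/>',
            width, height),
    .svg_text(left + cw * length(cols) / 2, 22,
              "OSCAR plot: upper vs lower biomarker quartile", 14)
  )
  for (j in seq_along(cols)) {
    out <- c(out, .svg_text(left + (j - 0.5) * cw, top - 8, cols[j], 11))
  }
  for (i in seq_along(rows)) {
    out <- c(out, .svg_text(left - 6, top + (i - 0.5) * ch + 4, rows[i], 11,
                            anchor = "end"))
    for (j in seq_along(cols)) {
      color <- matrix$colors[rows[i], cols[j]]
      x <- left + (j - 1) * cw
      y <- top + (i - 1) * ch
      out <- c(out, .svg_rect(x, y, cw, ch, spec$colors[[color]]))
      if (spec$annotate == "diff_value") {
        idx <- match(paste(rows[i], cols[j]), key)
        d <- cell_df$diff[idx]
        if (!is.na(idx) && !is.na(d)) {
          out <- c(out, .svg_text(x + cw / 2, y + ch / 2 + 4,
                                  sprintf("%+.3g", d), 10))
        }
      }
    }
  }
  ly <- top + ch * length(rows) + 24
  legend <- c(green = "better", red = "worse",
              yellow = "no clinically important difference")
  lx <- left
  for (nm in names(legend)) {
    out <- c(out, .svg_rect(lx, ly - 10, 14, 14, spec$colors[[nm]]),
             .svg_text(lx + 20, ly + 2, legend[[nm]], 11, anchor = "start"))
    lx <- lx + 28 + 7.2 * nchar(legend[[nm]])
  }
  if (has_gray) {
    out <- c(out, .svg_rect(left, ly + 10, 14, 14, spec$colors[["gray"]]),
             .svg_text(left + 20, ly + 22, "insufficient data", 11,
                       anchor = "start"))
  }
  out <- c(out, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Render per-stage biomarker distributions to SVG
#'
#' Box-and-whisker summary (median, IQR, whiskers at 1.5 IQR) of one
#' biomarker per GOLD stage, on a log10 axis (serum analytes span orders of
#' magnitude).
#'
#' @param cohort Cohort data.frame with `gold` and the biomarker column.
#' @param biomarker Biomarker column name.
#' @param path Output path (`.svg`).
#' @return `path`, invisibly.
#' @export
render_stage_distributions <- function(cohort, biomarker, path) {
  if (is.null(cohort[[biomarker]])) {
    stop("biomarker '", biomarker, "' not in cohort", call. = FALSE)
  }
  ok <- !is.na(cohort[[biomarker]]) & !is.na(cohort$gold) &
    cohort[[biomarker]] > 0
  stages <- sort(unique(cohort$gold[ok]))
  if (length(stages) < 2) {
    stop("need >= 2 GOLD stages present to draw stage distributions",
         call. = FALSE)
  }
  v <- log10(cohort[[biomarker]][ok])
  g <- cohort$gold[ok]
  stats_by <- lapply(stages, function(s) grDevices::boxplot.stats(v[g == s]))

  width <- 120 + 90 * length(stages)
  height <- 320
  top <- 50
  bottom <- height - 50
  rng <- range(unlist(lapply(stats_by, function(b) b$stats)))
  if (diff(rng) < 1e-9) rng <- rng + c(-0.5, 0.5)
  yscale <- function(val) bottom - (val - rng[1]) / diff(rng) * (bottom - top)

  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF"/>',
            width, height),
    .svg_text(width / 2, 24, sprintf("%s by GOLD stage (log10 scale)",
                                     biomarker), 13)
  )
  ticks <- pretty(rng, 4)
  ticks <- ticks[ticks >= rng[1] & ticks <= rng[2]]
  for (t in ticks) {
    out <- c(out,
             sprintf('<line x1="70" y1="%.1f" x2="%d" y2="%.1f" stroke="#E0E0E0" stroke-width="0.5"/>',
                     yscale(t), width - 20, yscale(t)),
             .svg_text(64, yscale(t) + 4, sprintf("%.3g", 10^t), 10,
                       anchor = "end"))
  }
  bw <- 46
  for (i in seq_along(stages)) {
    b <- stats_by[[i]]$stats  # lower whisker, q1, median, q3, upper whisker
    cx <- 80 + (i - 0.5) * 90
    out <- c(out,
             sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#404040" stroke-width="1"/>',
                     cx, yscale(b[1]), cx, yscale(b[2])),
             sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#404040" stroke-width="1"/>',
                     cx, yscale(b[4]), cx, yscale(b[5])),
             .svg_rect(cx - bw / 2, yscale(b[4]), bw,
                       yscale(b[2]) - yscale(b[4]), "#9ECAE1"),
             sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#08306B" stroke-width="2"/>',
                     cx - bw / 2, yscale(b[3]), cx + bw / 2, yscale(b[3])),
             .svg_text(cx, bottom + 18, paste0("GOLD ", stages[i]), 11))
  }
  out <- c(out, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}
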