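# Every rendered image has a lossless tabular twin; the tables are the
# contract (and what the tests assert on), the images are a convenience.

write_tsv_table <- function(tab, path) {
  if (!is.null(path)) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(tab)
}

# deterministic devices: fixed size, PNG always, SVG when cairo exists
with_devices <- function(file, draw) {
  if (is.null(file)) return(invisible(NULL))
  dir.create(dirname(file), showWarnings = FALSE, recursive = TRUE)
  png_path <- paste0(tools::file_path_sans_ext(file), ".png")
  grDevices::png(png_path, width = 1600, height = 1600, res = 200)
  on.exit(grDevices::dev.off(), add = TRUE)
  draw()
  if (isTRUE(capabilities("cairo")[[1L]])) {
    svg_path <- paste0(tools::file_path_sans_ext(file), ".svg")
    grDevices::svg(svg_path, width = 8, height = 8)
    draw()
    grDevices::dev.off()
  }
  invisible(png_path)
}

composition_color <- function(composition, grayscale = FALSE) {
  if (grayscale)
    c(transcripts_only = "gray20", metabolites_only = "gray60",
      mixed = "black", empty = "white")[composition]
  else
    c(transcripts_only = "red", metabolites_only = "blue",
      mixed = "black", empty = "white")[composition]
}

# marker radius: area proportional to count, largest marker bounded
area_cex <- function(counts, max_cex = 3) {
  if (!length(counts) || max(counts) == 0) return(rep(0, length(counts)))
  max_cex * sqrt(counts / max(counts))
}

#' Render the activation map
#'
#' One marker per nonempty unit, colored by composition at the pooling
#' radius `vn` (red transcripts only, blue metabolites only, black
#' mixed; or a gray scale), with marker area proportional to the member
#' count.  Units listed in `highlight` are drawn green, the
#' already-analysed marker of the interactive original reinterpreted as
#' a static option.
#'
#' @param assignment a [assign_patterns()] result.
#' @param dataset the assigned [profile_dataset()].
#' @param map the trained `som_map`.
#' @param vn pooling radius for composition.
#' @param grayscale use a black/white scale instead of red/blue/black.
#' @param highlight integer unit indices to paint green.
#' @param file base path for the image(s) (`.png` appended; `NULL` for
#'   table only).
#' @param table_file optional path for the tabular twin.
#' @return The companion table (one row per nonempty unit), invisibly.
#' @export
render_activation_map <- function(assignment, dataset, map, vn = 0L,
                                  grayscale = FALSE,
                                  highlight = integer(0),
                                  file = NULL, table_file = NULL) {
  tab <- neuron_report(assignment, dataset, map, vn)
  write_tsv_table(tab, table_file)
  with_devices(file, function() {
    col <- composition_color(tab$composition, grayscale)
    col[tab$unit %in% highlight] <- "green3"
    graphics::plot(NA, xlim = c(0.5, map$config$cols + 0.5),
                   ylim = c(0.5, map$config$rows + 0.5),
                   xlab = "map column", ylab = "map row", asp = 1,
                   main = sprintf("activation map (Vn = %d)", vn))
    graphics::points(tab$col, tab$row, pch = 19, col = col,
                     cex = area_cex(tab$n_members))
  })
  invisible(tab)
}

#' Render the member curves of one neuron
#'
#' One curve per member pattern across the genotype dimensions, using
#' the normalized values or, with `raw = TRUE`, the un-normalized log
#' ratios from the companion files.  Pseudo-zero points (invalid
#' measurements: metabolites without enough detected replicates,
#' transcripts without significant expression) are circled in red.
#'
#' @param unit unit index (must be nonempty).
#' @param assignment a [assign_patterns()] result.
#' @param dataset the assigned [profile_dataset()].
#' @param raw plot un-normalized values (requires loaded companions).
#' @param file,table_file as in [render_activation_map()].
#' @return Long-format companion table (`entity_id`, `kind`, `sign`,
#'   `genotype`, `value`, `valid`), invisibly.
#' @export
render_detail <- function(unit, assignment, dataset, raw = FALSE,
                          file = NULL, table_file = NULL) {
  members <- which(assignment$bmu == unit)
  if (!length(members)) stopf("unit %d is empty", unit)
  if (raw && is.null(dataset$raw_values))
    stopf(paste0("raw values not loaded: the un-normalized companion files ",
                 "(nonormsq for metabolites, nolowess for transcripts) ",
                 "were not found"))
  mat <- if (raw) dataset$raw_values else dataset$values
  P <- n_genotypes(dataset)
  tab <- data.frame(
    entity_id = rep(dataset$entity_id[members], each = P),
    kind = rep(dataset$kind[members], each = P),
    sign = rep(dataset$sign[members], each = P),
    genotype = rep(dataset$genotypes, times = length(members)),
    value = as.vector(t(mat[members, , drop = FALSE])),
    valid = as.vector(t(dataset$validity[members, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
  write_tsv_table(tab, table_file)
  with_devices(file, function() {
    graphics::matplot(t(mat[members, , drop = FALSE]), type = "l",
                      lty = 1, xaxt = "n", xlab = "genotype (IL)",
                      ylab = if (raw) "log ratio" else "normalized log ratio",
                      main = sprintf("neuron %d (%s)", unit,
                                     if (raw) "original values" else "normalized"))
    graphics::axis(1, at = seq_len(P), labels = dataset$genotypes,
                   las = 2, cex.axis = 0.7)
    bad <- which(!dataset$validity[members, , drop = FALSE], arr.ind = TRUE)
    if (nrow(bad))
      graphics::points(bad[, 2L], mat[members, , drop = FALSE][bad],
                       col = "red", pch = 1, cex = 1.6, lwd = 2)
    graphics::legend("topright",
                     legend = pattern_labels(dataset$entity_id[members],
                                             dataset$sign[members]),
                     col = seq_along(members), lty = 1, cex = 0.7)
  })
  invisible(tab)
}

#' Render the per-neuron cohesion map
#'
#' Marker area monotone in the cohesion (intracluster variance) of each
#' nonempty unit; empty units stay blank.  The companion table equals
#' the [neuron_report()] cohesion column exactly.
#'
#' @inheritParams render_activation_map
#' @return Companion table (`unit`, `row`, `col`, `cohesion`),
#'   invisibly.
#' @export
render_cohesion_map <- function(assignment, dataset, map,
                                file = NULL, table_file = NULL) {
  units <- sort(unique(assignment$bmu))
  coh <- vapply(units, cohesion, numeric(1),
                assignment = assignment, dataset = dataset, map = map)
  tab <- data.frame(unit = units,
                    row = map$grid[units, "row"],
                    col = map$grid[units, "col"],
                    cohesion = coh)
  write_tsv_table(tab, table_file)
  with_devices(file, function() {
    graphics::plot(NA, xlim = c(0.5, map$config$cols + 0.5),
                   ylim = c(0.5, map$config$rows + 0.5),
                   xlab = "map column", ylab = "map row", asp = 1,
                   main = "per-neuron cohesion")
    graphics::points(tab$col, tab$row, pch = 19, col = "gray30",
                     cex = if (max(tab$cohesion) > 0)
                       area_cex(tab$cohesion) else rep(1, nrow(tab)))
  })
  invisible(tab)
}

#' Render one genotype dimension of a three-color map
#'
#' @param tcm a [three_color_map()] result.
#' @param genotype genotype name (one of `tcm$genotypes`).
#' @param file,table_file as in [render_activation_map()].
#' @return Companion table (`unit`, `row`, `col`, `color`), invisibly.
#' @export
render_three_color_map <- function(tcm, genotype, file = NULL,
                                   table_file = NULL) {
  p <- match(genotype, tcm$genotypes)
  if (is.na(p)) stopf("unknown genotype '%s'", genotype)
  tab <- data.frame(unit = seq_len(nrow(tcm$colors)),
                    row = tcm$grid[, "row"],
                    col = tcm$grid[, "col"],
                    color = tcm$colors[, p])
  write_tsv_table(tab, table_file)
  with_devices(file, function() {
    fill <- c(green = "green3", gray = "gray60", white = "white")[tab$color]
    graphics::plot(NA, xlim = c(0.5, max(tab$col) + 0.5),
                   ylim = c(0.5, max(tab$row) + 0.5),
                   xlab = "map column", ylab = "map row", asp = 1,
                   main = sprintf("3-color map, IL %s", genotype))
    graphics::symbols(tab$col, tab$row, squares = rep(0.95, nrow(tab)),
                      inches = FALSE, add = TRUE, bg = fill, fg = "gray80")
  })
  invisible(tab)
}
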