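#' Read the main `.data` profile matrix
#'
#' Parses the plain-text training-matrix format: a first row holding the
#' number of genotypes P, an optional second row (detected by a
#' non-numeric first token) naming the genotypes, then one row per
#' pattern: P whitespace-separated log-ratio values, an optional kind
#' token (`t` for transcript, `m` for metabolite), and a trailing label.
#' A label ending in `(inv)` (case-insensitive) marks the sign-inverted
#' twin of the original row with the same label stem; inverted rows must
#' immediately carry the negated values of their original.
#'
#' @param path path to a `.data` file.
#' @return A [profile_dataset()] in file row order, with an all-valid
#'   mask (validity markers live in companion files, see
#'   [read_validity_markers()]).
#' @export
read_main_data <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stopf("%s: need a header row and at least one pattern row", path)
  head_tok <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]][1L]
  P <- suppressWarnings(as.integer(head_tok))
  if (is.na(P) || P < 1L)
    stopf("%s: first row must hold the number of genotypes, got '%s'", path, head_tok)
  body <- lines[-1L]
  first_tok <- strsplit(trimws(body[[1L]]), "[ \t]+")[[1L]][1L]
  if (!is_number_token(first_tok)) {
    genotypes <- strsplit(trimws(body[[1L]]), "[ \t]+")[[1L]]
    if (length(genotypes) != P)
      stopf("%s: genotype name row has %d entries, expected P=%d",
            path, length(genotypes), P)
    body <- body[-1L]
  } else {
    genotypes <- paste0("IL_", seq_len(P))
  }
  if (!length(body)) stopf("%s: no pattern rows", path)

  parsed <- lapply(seq_along(body), function(i)
    parse_pattern_row(body[[i]], P, path, i))
  entity <- vapply(parsed, `[[`, character(1), "label")
  kind <- vapply(parsed, `[[`, character(1), "kind")
  values <- do.call(rbind, lapply(parsed, `[[`, "values"))
  if (any(kind == "")) {
    warnf("%s: %d row(s) carry no t/m kind token; assuming transcript",
          path, sum(kind == ""))
    kind[kind == ""] <- "t"
  }
  kind <- ifelse(kind == "m", "metabolite", "transcript")

  inv <- grepl("\\(inv\\)$", entity, ignore.case = TRUE)
  stem <- sub("\\(inv\\)$", "", entity, ignore.case = TRUE)
  sign <- ifelse(inv, "inverted", "original")
  lab <- pattern_labels(stem, sign)
  if (anyDuplicated(lab))
    stopf("%s: duplicate row label(s): %s", path,
          paste(unique(lab[duplicated(lab)]), collapse = ", "))
  # every inverted row needs its original, and must carry negated values
  for (i in which(inv)) {
    j <- which(!inv & stem == stem[i] & kind == kind[i])
    if (!length(j))
      stopf("%s: inverted row '%s' has no matching original", path, entity[i])
    if (max(abs(values[i, ] + values[j, ])) >
        1e-9 * max(1, max(abs(values[j, ]))))
      stopf("%s: inverted row '%s' disagrees with the negated original", path, entity[i])
  }

  profile_dataset(genotypes = genotypes, entity_id = stem, kind = kind,
                  sign = sign, values = values)
}

parse_pattern_row <- function(line, P, path, rownum) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1L]]
  numeric_lead <- 0L
  while (numeric_lead < length(toks) && is_number_token(toks[numeric_lead + 1L]))
    numeric_lead <- numeric_lead + 1L
  tail_toks <- if (numeric_lead < length(toks)) toks[(numeric_lead + 1L):length(toks)] else character(0)
  label_guess <- if (length(tail_toks)) paste(tail_toks, collapse = " ")
                 else sprintf("row %d", rownum)
  if (numeric_lead != P)
    stopf("%s: row '%s' has %d values, expected P=%d",
          path, label_guess, numeric_lead, P)
  values <- as.numeric(toks[seq_len(P)])
  kind <- ""
  if (length(tail_toks) && tolower(tail_toks[1L]) %in% c("t", "m")) {
    kind <- tolower(tail_toks[1L])
    tail_toks <- tail_toks[-1L]
  }
  if (!length(tail_toks))
    stopf("%s: row %d has no label", path, rownum)
  list(values = values, kind = kind, label = paste(tail_toks, collapse = " "))
}

#' Write the main `.data` profile matrix
#'
#' Emits the format read by [read_main_data()]: values in fixed notation
#' with 6 significant digits, a `t`/`m` kind token, then the label
#' (inverted patterns get the `(inv)` suffix).  `read_main_data()` of the
#' written file reproduces the dataset exactly on labels, kinds, signs
#' and masks, and on values to the declared formatting precision.
#'
#' @param dataset a [profile_dataset()].
#' @param path output path.
#' @param what `"values"` (default) or `"raw"` to emit the un-normalized
#'   companion matrix instead.
#' @return `path`, invisibly.
#' @export
write_main_data <- function(dataset, path, what = c("values", "raw")) {
  what <- match.arg(what)
  mat <- if (what == "raw") dataset$raw_values else dataset$values
  if (is.null(mat)) stopf("dataset carries no raw_values")
  lines <- c(
    as.character(n_genotypes(dataset)),
    paste(dataset$genotypes, collapse = "\t"),
    vapply(seq_len(n_patterns(dataset)), function(i) {
      paste(c(format_value(mat[i, ]),
              substr(dataset$kind[i], 1L, 1L),
              pattern_labels(dataset$entity_id[i], dataset$sign[i])),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Resolve the companion files of a main `.data` file
#'
#' The main training matrix is named
#' `omesom<dataversion>_-_<date>T<time>_-oToM.data`; from it the loader
#' derives, in the same directory, the expressed-IL validity markers per
#' component (`trs` transcripts, `mts` metabolites) and the
#' un-normalized companions (`nonormsq` metabolites, `nolowess`
#' transcripts):
#' `omesom<dv>_-<comp>_-_<date>T<time>_-<suffix>.data`.
#' Absent companions are flagged, not fatal: the core pipeline runs off
#' the main file alone with an all-valid mask and no raw values.
#'
#' @param main_path path to the main `.data` file (must match the naming
#'   convention; `<dataversion>` and `<date>T<time>` are opaque).
#' @return A data.frame with columns `role` (`ilexp`, `nonormsq`,
#'   `nolowess`), `comp` (`trs`/`mts`), `path`, `exists`.
#' @export
resolve_companions <- function(main_path) {
  base <- basename(main_path)
  dir <- dirname(main_path)
  m <- regmatches(base, regexec("^omesom(.+)_-_(.+T.+)_-oToM\\.data$", base))[[1L]]
  if (!length(m))
    stopf(paste0("main file name '%s' does not match the convention ",
                 "'omesom<dataversion>_-_<date>T<time>_-oToM.data'"), base)
  dv <- m[2L]; dt <- m[3L]
  candidate <- function(comp, suffix)
    sprintf("omesom%s_-%s_-_%s_-%s.data", dv, comp, dt, suffix)
  out <- data.frame(
    role = c("ilexp", "ilexp", "nonormsq", "nolowess"),
    comp = c("trs", "mts", "mts", "trs"),
    path = file.path(dir, c(candidate("trs", "ilexp"),
                            candidate("mts", "ilexp"),
                            candidate("mts", "nonormsq"),
                            candidate("trs", "nolowess"))),
    stringsAsFactors = FALSE
  )
  out$exists <- file.exists(out$path)
  out
}

#' Apply an expressed-IL validity marker file to a dataset
#'
#' Marker files share the `.data` layout but hold 0/1 entries: one row
#' per *original* pattern of one component type, in the main-file order.
#' A 0 marks a pseudo-zero: a (pattern, genotype) cell without enough
#' significantly detected replicates.  The mask of an original is copied
#' to its inverted twin.
#'
#' @param path marker file path.
#' @param dataset the [profile_dataset()] to update.
#' @param comp which component the file covers: `"trs"` or `"mts"`.
#' @return The dataset with an updated validity mask.
#' @export
read_validity_markers <- function(path, dataset, comp = c("trs", "mts")) {
  comp <- match.arg(comp)
  kind <- if (comp == "trs") "transcript" else "metabolite"
  mk <- read_main_data(path)
  if (n_genotypes(mk) != n_genotypes(dataset))
    stopf("%s: marker file has P=%d genotypes, dataset has P=%d",
          path, n_genotypes(mk), n_genotypes(dataset))
  orig <- which(dataset$kind == kind & dataset$sign == "original")
  if (n_patterns(mk) != length(orig))
    stopf("%s: marker file has %d rows, dataset has %d original %s pattern(s)",
          path, n_patterns(mk), length(orig), kind)
  vals <- mk$values
  if (!all(vals %in% c(0, 1)))
    stopf("%s: marker entries must be 0 or 1", path)
  mask <- vals == 1
  dataset$validity[orig, ] <- mask
  pairs <- inversion_pairs(dataset)
  for (r in seq_len(nrow(pairs))) {
    o <- pairs$original[r]; i <- pairs$inverted[r]
    if (!is.na(i) && o %in% orig)
      dataset$validity[i, ] <- dataset$validity[o, ]
  }
  dataset
}

#' Attach an un-normalized companion matrix to a dataset
#'
#' `nonormsq` (metabolites) and `nolowess` (transcripts) files carry the
#' un-normalized log ratios of the original patterns of one component,
#' in main-file order; the raw values of an inverted twin are the
#' negated originals.
#'
#' @inheritParams read_validity_markers
#' @return The dataset with `raw_values` filled for that component.
#' @export
read_raw_companion <- function(path, dataset, comp = c("trs", "mts")) {
  comp <- match.arg(comp)
  kind <- if (comp == "trs") "transcript" else "metabolite"
  raw <- read_main_data(path)
  if (n_genotypes(raw) != n_genotypes(dataset))
    stopf("%s: companion has P=%d genotypes, dataset has P=%d",
          path, n_genotypes(raw), n_genotypes(dataset))
  orig <- which(dataset$kind == kind & dataset$sign == "original")
  if (n_patterns(raw) != length(orig))
    stopf("%s: companion has %d rows, dataset has %d original %s pattern(s)",
          path, n_patterns(raw), length(orig), kind)
  if (is.null(dataset$raw_values))
    dataset$raw_values <- matrix(NA_real_, n_patterns(dataset), n_genotypes(dataset))
  dataset$raw_values[orig, ] <- raw$values
  pairs <- inversion_pairs(dataset)
  for (r in seq_len(nrow(pairs))) {
    o <- pairs$original[r]; i <- pairs$inverted[r]
    if (!is.na(i) && o %in% orig)
      dataset$raw_values[i, ] <- -dataset$raw_values[o, ]
  }
  dataset
}

#' Load a main `.data` file together with its companion family
#'
#' Reads the main matrix, resolves companions by the naming convention,
#' and folds in whichever validity-marker and un-normalized files are
#' present.  Missing companions degrade gracefully (all-valid mask, raw
#' values unset).
#'
#' @param main_path path to the main `.data` file.
#' @return A [profile_dataset()].
#' @export
read_data_family <- function(main_path) {
  dataset <- read_main_data(main_path)
  comp <- resolve_companions(main_path)
  for (r in seq_len(nrow(comp))) {
    if (!comp$exists[r]) next
    dataset <- switch(comp$role[r],
      ilexp = read_validity_markers(comp$path[r], dataset, comp$comp[r]),
      nonormsq = ,
      nolowess = read_raw_companion(comp$path[r], dataset, comp$comp[r]))
  }
  dataset
}

#' Write a dataset as a complete `.data` file family
#'
#' Emits the main matrix plus, per component present, the expressed-IL
#' marker file and (when `raw_values` is set) the un-normalized
#' companion, all named by the convention understood by
#' [resolve_companions()].
#'
#' @param dataset a [profile_dataset()].
#' @param dir output directory (created if needed).
#' @param dataversion opaque version tag in the file names.
#' @param datetime opaque `<date>T<time>` tag in the file names.
#' @return Character vector of the written paths, invisibly.
#' @export
write_data_family <- function(dataset, dir, dataversion = "1",
                              datetime = "20100101T1200") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  main <- file.path(dir, sprintf("omesom%s_-_%s_-oToM.data", dataversion, datetime))
  write_main_data(dataset, main)
  written <- main
  companion <- function(comp, suffix)
    file.path(dir, sprintf("omesom%s_-%s_-_%s_-%s.data", dataversion, comp, datetime, suffix))
  for (comp in c("trs", "mts")) {
    kind <- if (comp == "trs") "transcript" else "metabolite"
    orig <- which(dataset$kind == kind & dataset$sign == "original")
    if (!length(orig)) next
    marker <- subset_patterns(dataset, orig)
    marker$values <- matrix(as.numeric(dataset$validity[orig, , drop = FALSE]),
                            nrow = length(orig))
    p <- companion(comp, "ilexp")
    write_main_data(marker, p)
    written <- c(written, p)
    if (!is.null(dataset$raw_values)) {
      p <- companion(comp, if (comp == "trs") "nolowess" else "nonormsq")
      write_main_data(subset_patterns(dataset, orig), p, what = "raw")
      written <- c(written, p)
    }
  }
  invisible(written)
}
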