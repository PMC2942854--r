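#' Load a local annotation lookup table
#'
#' Two tab-separated schemas, selected by `type`:
#' \describe{
#'   \item{transcript}{columns `probe_code`, `at_id` (Arabidopsis),
#'     `sgn_u` (Solanaceae Unigene), `description`.  Probe-code lookups
#'     are case-insensitive.}
#'   \item{metabolite}{columns `name`, `kegg_compound`, `pathways`
#'     (semicolon-separated `pathwayID|pathway name` entries).}
#' }
#' Rows with missing key or wrong column count are skipped with a
#' warning and a count.  Duplicate keys: last wins, with a warning.
#' Lookups are local by design: export the mappings from KEGG or the
#' array annotation release once, then work offline.
#'
#' @param path annotation file path.
#' @param type `"transcript"` or `"metabolite"`.
#' @return An object of class `annotation_table`: named list of
#'   annotation records keyed by lower-cased identifier.
#' @export
load_annotation_table <- function(path, type = c("transcript", "metabolite")) {
  type <- match.arg(type)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  need <- if (type == "transcript")
    c("probe_code", "at_id", "sgn_u", "description")
  else c("name", "kegg_compound", "pathways")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warnf("%s: empty annotation file", path)
    return(structure(list(type = type, records = list()),
                     class = "annotation_table"))
  }
  hdr <- strsplit(lines[[1L]], "\t")[[1L]]
  if (!all(need %in% hdr))
    stopf("%s: expected tab-separated columns %s", path,
          paste(need, collapse = ", "))
  body <- lines[-1L]
  if (!length(body)) warnf("%s: empty annotation table", path)
  records <- list()
  skipped <- 0L
  for (line in body) {
    toks <- strsplit(line, "\t")[[1L]]
    if (length(toks) < length(hdr)) toks <- c(toks, rep("", length(hdr) - length(toks)))
    rec <- as.list(toks[match(need, hdr)])
    names(rec) <- need
    key <- tolower(trimws(rec[[1L]]))
    if (!nzchar(key)) { skipped <- skipped + 1L; next }
    if (type == "metabolite") {
      pw <- strsplit(rec$pathways, ";", fixed = TRUE)[[1L]]
      pw <- pw[nzchar(pw)]
      rec$pathways <- lapply(strsplit(pw, "|", fixed = TRUE), function(x)
        list(id = x[1L], name = if (length(x) > 1L) x[2L] else ""))
    }
    if (key %in% names(records))
      warnf("%s: duplicate key '%s'; keeping the last entry", path, key)
    records[[key]] <- rec
  }
  if (skipped > 0L)
    warnf("%s: skipped %d malformed row(s)", path, skipped)
  structure(list(type = type, records = records), class = "annotation_table")
}

annotation_lookup <- function(table, id) {
  table$records[[tolower(trimws(id))]]
}

#' Annotate the members of a neuron report
#'
#' Decorates each member of a [neuron_report()] (or any data.frame with
#' an `entity_id`/`members` structure) with its annotations; entities
#' absent from the tables are marked `"unannotated"`, never dropped.
#' Annotation never changes membership, counts, composition or
#' cohesion.
#'
#' @param report a [neuron_report()] data.frame.
#' @param assignment,dataset the assignment and dataset the report was
#'   built from.
#' @param transcript_table,metabolite_table [load_annotation_table()]
#'   results (either may be `NULL`).
#' @return data.frame with one row per (unit, member): `unit`,
#'   `entity_id`, `kind`, `sign`, `annotation` (transcripts:
#'   `at_id|sgn_u|description`; metabolites: compound ID), `pathways`
#'   (semicolon-joined `id|name` pairs, metabolites only).
#' @export
annotate_neuron <- function(report, assignment, dataset,
                            transcript_table = NULL,
                            metabolite_table = NULL) {
  keep <- assignment$bmu %in% report$unit
  idx <- which(keep)
  ann <- character(length(idx))
  pw <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (dataset$kind[i] == "transcript") {
      rec <- if (!is.null(transcript_table))
        annotation_lookup(transcript_table, dataset$entity_id[i])
      ann[k] <- if (is.null(rec)) "unannotated"
                else paste(rec$at_id, rec$sgn_u, rec$description, sep = "|")
      pw[k] <- ""
    } else {
      rec <- if (!is.null(metabolite_table))
        annotation_lookup(metabolite_table, dataset$entity_id[i])
      if (is.null(rec)) {
        ann[k] <- "unannotated"; pw[k] <- ""
      } else {
        ann[k] <- rec$kegg_compound
        pw[k] <- paste(vapply(rec$pathways, function(p)
          paste(p$id, p$name, sep = "|"), character(1)), collapse = ";")
      }
    }
  }
  out <- data.frame(unit = assignment$bmu[idx],
                    entity_id = dataset$entity_id[idx],
                    kind = dataset$kind[idx],
                    sign = dataset$sign[idx],
                    annotation = ann,
                    pathways = pw,
                    stringsAsFactors = FALSE)
  out[order(out$unit), , drop = FALSE]
}
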