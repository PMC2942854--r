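#' Average replicate ratios into per-genotype log ratios
#'
#' For each genotype with at least `min_replicates` detected replicate
#' ratios, the value is the log (base `log_base`) of the mean of those
#' ratios ("mean-then-log").  Genotypes below the replicate threshold
#' become pseudo-zeros: validity `FALSE` and a 0 placeholder that is
#' excluded from normalization and distances downstream, never treated
#' as a real measurement.
#'
#' @param replicates named list: one element per genotype, each a
#'   numeric vector of detected replicate relative-measurement ratios
#'   (positive; absent replicates simply missing from the vector).
#' @param min_replicates minimum detected replicates for validity.
#' @param log_base base of the logarithm (10 by default, the microarray
#'   ratio convention).
#' @return list with `values` (numeric, one per genotype) and `validity`
#'   (logical).
#' @export
average_valid_log_ratios <- function(replicates, min_replicates = 2L,
                                     log_base = 10) {
  stopifnot(min_replicates >= 1L)
  n_rep <- vapply(replicates, length, integer(1))
  valid <- n_rep >= min_replicates
  values <- numeric(length(replicates))
  values[valid] <- vapply(replicates[valid],
                          function(r) log(mean(r), base = log_base),
                          numeric(1))
  list(values = values, validity = valid)
}

#' Magnitude filter for metabolite profiles
#'
#' A metabolite is retained iff the maximum absolute log ratio over its
#' *valid* genotypes strictly exceeds `threshold` (default 0.1).  The
#' criterion is sign-free: down-regulation is as informative as
#' up-regulation.  Transcripts are never passed through this filter.
#'
#' @param values numeric matrix (entities x genotypes) of log ratios.
#' @param validity logical matrix of the same shape.
#' @param threshold non-negative magnitude threshold.
#' @return Logical vector: `TRUE` for retained rows.
#' @export
filter_metabolites_by_magnitude <- function(values, validity = NULL,
                                            threshold = 0.1) {
  stopifnot(threshold >= 0)
  values <- as.matrix(values)
  if (is.null(validity)) validity <- matrix(TRUE, nrow(values), ncol(values))
  mags <- abs(values)
  mags[!validity] <- -Inf
  apply(mags, 1L, max) > threshold
}

#' Detect non-expressed array spots
#'
#' A spot is non-expressed when its foreground signal mean is strictly
#' less than the spot mean background plus two times the spot background
#' standard deviation.  Spots carrying any quality flag (poor, negative,
#' empty, not expressed in both channels) are excluded from downstream
#' data regardless of the signal rule.
#'
#' @param spots data.frame with columns `spot_id`, `foreground_mean`,
#'   `background_mean`, `background_sd`, and optionally `quality_flags`
#'   (character; `""` or `NA` for clean spots).
#' @return list with `non_expressed` (spot ids failing the signal rule)
#'   and `quality_filtered` (spot ids removed by quality flags).
#' @export
detect_nonexpressed_spots <- function(spots) {
  stopifnot(all(spots$background_sd >= 0))
  flagged <- if ("quality_flags" %in% names(spots))
    !is.na(spots$quality_flags) & nzchar(spots$quality_flags)
  else rep(FALSE, nrow(spots))
  nonexp <- spots$foreground_mean <
    spots$background_mean + 2 * spots$background_sd
  list(non_expressed = spots$spot_id[nonexp & !flagged],
       quality_filtered = spots$spot_id[flagged])
}

#' Unit sum-of-squares normalization of a log-ratio vector
#'
#' Scales a pattern so that the sum of squared *valid* components equals
#' 1: `x_i = logR_i / sqrt(sum over valid j of logR_j^2)`.  Invalid
#' components keep the pseudo-zero placeholder (0) and are excluded from
#' the sum.  The operation is idempotent.
#'
#' @param logR numeric vector of log ratios.
#' @param validity logical vector; defaults to all-valid.
#' @return Numeric vector of the same length with unit sum of squares
#'   over valid components.
#' @export
normalize_unit <- function(logR, validity = NULL) {
  if (is.null(validity)) validity <- rep(TRUE, length(logR))
  ss <- sum(logR[validity]^2)
  if (!any(validity) || ss == 0)
    stopf("cannot normalize an all-zero or all-invalid pattern")
  x <- logR / sqrt(ss)
  x[!validity] <- 0
  x
}

#' Close a dataset under sign inversion
#'
#' Every original pattern gains an inverted twin: same entity and kind,
#' element-wise negated values, identical validity mask, interleaved
#' immediately after its original.  With both signs on the map, direct
#' relations (up t with up m, up t with up t, up m with up m) and cross
#' relations (up t with down m, up t with down t, up m with down m)
#' both surface as co-located patterns.  Augmenting an already-closed
#' dataset is the identity.
#'
#' @param dataset a [profile_dataset()] of originals (or already closed).
#' @return An inversion-closed [profile_dataset()].
#' @export
augment_inverted <- function(dataset) {
  if (any(dataset$sign == "inverted")) {
    if (is_inversion_closed(dataset)) return(dataset)
    stopf("dataset has inverted patterns but is not inversion-closed")
  }
  n <- n_patterns(dataset)
  idx <- rep(seq_len(n), each = 2L)
  sgn <- rep(c("original", "inverted"), n)
  flip <- rep(c(1, -1), n)
  vals <- dataset$values[idx, , drop = FALSE] * flip
  raw <- if (!is.null(dataset$raw_values))
    dataset$raw_values[idx, , drop = FALSE] * flip
  profile_dataset(
    genotypes = dataset$genotypes,
    entity_id = dataset$entity_id[idx],
    kind = dataset$kind[idx],
    sign = sgn,
    values = vals,
    validity = dataset$validity[idx, , drop = FALSE],
    raw_values = raw
  )
}

#' Read / write a replicate-level measurement table
#'
#' Tab-separated text with one detected replicate per row and columns
#' `entity_id`, `kind` (`transcript`/`metabolite`), `genotype`,
#' `ratio` (positive relative measurement).
#'
#' @param path file path.
#' @return A data.frame with those four columns.
#' @export
read_replicate_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("entity_id", "kind", "genotype", "ratio")
  if (!all(need %in% names(tab)))
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  tab
}

#' @rdname read_replicate_table
#' @param replicates a replicate table data.frame.
#' @export
write_replicate_table <- function(replicates, path) {
  utils::write.table(replicates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a normalized, inversion-closed dataset from replicate tables
#'
#' The full preprocessing pipeline: per-entity replicate averaging
#' ([average_valid_log_ratios()]), drop of entities with no valid
#' genotype, the metabolite magnitude filter
#' ([filter_metabolites_by_magnitude()]), unit sum-of-squares
#' normalization ([normalize_unit()]; the un-normalized log ratios are
#' kept as `raw_values`), and inversion augmentation
#' ([augment_inverted()]).  Originals are ordered transcripts first,
#' then metabolites, preserving first appearance within kind.
#'
#' @param replicates a replicate table (see [read_replicate_table()]).
#' @param genotypes genotype order; defaults to order of appearance.
#' @param min_replicates passed to [average_valid_log_ratios()].
#' @param log_base passed to [average_valid_log_ratios()].
#' @param mag_threshold passed to [filter_metabolites_by_magnitude()].
#' @return An inversion-closed, normalized [profile_dataset()].
#' @export
profile_dataset_from_replicates <- function(replicates, genotypes = NULL,
                                            min_replicates = 2L,
                                            log_base = 10,
                                            mag_threshold = 0.1) {
  if (is.null(genotypes)) genotypes <- unique(replicates$genotype)
  P <- length(genotypes)
  key <- paste(replicates$entity_id, replicates$kind, sep = "\r")
  ord <- order(match(replicates$kind, c("transcript", "metabolite")),
               match(key, unique(key)))
  replicates <- replicates[ord, ]
  key <- key[ord]
  entities <- unique(key)
  ids <- sub("\r.*$", "", entities)
  kinds <- sub("^.*\r", "", entities)

  values <- matrix(0, length(entities), P)
  validity <- matrix(FALSE, length(entities), P)
  for (e in seq_along(entities)) {
    sel <- replicates[key == entities[e], ]
    reps <- split(sel$ratio, factor(sel$genotype, levels = genotypes))
    av <- average_valid_log_ratios(reps, min_replicates, log_base)
    values[e, ] <- av$values
    validity[e, ] <- av$validity
  }

  drop <- !apply(validity, 1L, any)
  if (any(drop)) {
    warnf("dropping %d entit%s with no valid genotype: %s",
          sum(drop), if (sum(drop) == 1L) "y" else "ies",
          paste(utils::head(ids[drop], 5L), collapse = ", "))
    values <- values[!drop, , drop = FALSE]
    validity <- validity[!drop, , drop = FALSE]
    ids <- ids[!drop]; kinds <- kinds[!drop]
  }

  is_met <- kinds == "metabolite"
  keep <- rep(TRUE, length(ids))
  if (any(is_met))
    keep[is_met] <- filter_metabolites_by_magnitude(
      values[is_met, , drop = FALSE], validity[is_met, , drop = FALSE],
      mag_threshold)
  values <- values[keep, , drop = FALSE]
  validity <- validity[keep, , drop = FALSE]
  ids <- ids[keep]; kinds <- kinds[keep]
  if (!length(ids)) stopf("no entities survive preprocessing")

  norm <- t(vapply(seq_along(ids),
                   function(i) normalize_unit(values[i, ], validity[i, ]),
                   numeric(P)))
  dataset <- profile_dataset(genotypes = genotypes, entity_id = ids,
                             kind = kinds, sign = "original",
                             values = norm, validity = validity,
                             raw_values = values)
  augment_inverted(dataset)
}
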