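#' Genotype-indexed profile dataset
#'
#' The central container of the package: an ordered set of molecular
#' patterns (transcripts and metabolites), each a vector of P normalized
#' log ratios indexed by genotype (one introgression line per dimension),
#' together with a validity mask marking pseudo-zero entries (measurements
#' undetectable in some genotypes but valid in others) and, optionally,
#' the un-normalized log ratios.
#'
#' A dataset is *inversion-closed* when every original pattern is
#' immediately followed by a sign-inverted twin (same entity, values
#' negated, identical validity mask).  Inversion closure is what lets a
#' single Euclidean map expose both direct relations (up-regulated
#' transcript with up-regulated metabolite) and cross relations
#' (up-regulated transcript with a down-regulated metabolite): the
#' inverted twin of a down-regulated pattern lands next to the
#' up-regulated patterns it mirrors.
#'
#' @param genotypes character vector of P genotype identifiers.  Names of
#'   the form `"12-1-1"` carry a leading chromosome tag used by
#'   [chromosome_subset()].
#' @param entity_id character vector, one label per pattern.
#' @param kind `"transcript"` or `"metabolite"` per pattern.
#' @param sign `"original"` or `"inverted"` per pattern.
#' @param values numeric matrix, patterns x genotypes.
#' @param validity logical matrix, same shape; `FALSE` marks a
#'   pseudo-zero (invalid) measurement.  Defaults to all-valid.
#' @param raw_values optional numeric matrix of un-normalized log ratios,
#'   same shape.
#' @return An object of class `profile_dataset`.
#' @seealso [augment_inverted()], [read_main_data()]
#' @export
profile_dataset <- function(genotypes, entity_id, kind, sign, values,
                            validity = NULL, raw_values = NULL) {
  values <- as.matrix(values)
  P <- length(genotypes)
  n <- length(entity_id)
  if (!all(dim(values) == c(n, P)))
    stopf("values must be a %d x %d matrix (patterns x genotypes)", n, P)
  kind <- match.arg(kind, c("transcript", "metabolite"), several.ok = TRUE)
  if (length(kind) == 1L) kind <- rep(kind, n)
  sign <- match.arg(sign, c("original", "inverted"), several.ok = TRUE)
  if (length(sign) == 1L) sign <- rep(sign, n)
  if (length(kind) != n || length(sign) != n)
    stopf("kind and sign must have one value per pattern")
  if (is.null(validity)) validity <- matrix(TRUE, n, P)
  validity <- as.matrix(validity)
  if (!all(dim(validity) == c(n, P)))
    stopf("validity mask must match the values matrix (%d x %d)", n, P)
  if (!is.null(raw_values)) {
    raw_values <- as.matrix(raw_values)
    if (!all(dim(raw_values) == c(n, P)))
      stopf("raw_values must match the values matrix (%d x %d)", n, P)
    dimnames(raw_values) <- NULL
  }
  lab <- pattern_labels(entity_id, sign)
  if (anyDuplicated(lab))
    stopf("duplicate pattern label(s): %s",
          paste(unique(lab[duplicated(lab)]), collapse = ", "))
  dimnames(values) <- NULL
  dimnames(validity) <- NULL
  structure(list(
    genotypes = as.character(genotypes),
    entity_id = as.character(entity_id),
    kind = kind,
    sign = sign,
    values = values,
    validity = validity,
    raw_values = raw_values
  ), class = "profile_dataset")
}

pattern_labels <- function(entity_id, sign) {
  paste0(entity_id, ifelse(sign == "inverted", "(inv)", ""))
}

#' @export
print.profile_dataset <- function(x, ...) {
  cat(sprintf("profile_dataset: %d patterns x %d genotypes\n",
              n_patterns(x), n_genotypes(x)))
  cat(sprintf("  transcripts: %d  metabolites: %d  (original rows)\n",
              sum(x$kind == "transcript" & x$sign == "original"),
              sum(x$kind == "metabolite" & x$sign == "original")))
  cat(sprintf("  inversion-closed: %s  pseudo-zero entries: %d  raw values: %s\n",
              is_inversion_closed(x), sum(!x$validity),
              if (is.null(x$raw_values)) "absent" else "present"))
  invisible(x)
}

#' Number of patterns / genotypes in a dataset
#' @param dataset a [profile_dataset()].
#' @return An integer count.
#' @export
n_patterns <- function(dataset) length(dataset$entity_id)

#' @rdname n_patterns
#' @export
n_genotypes <- function(dataset) length(dataset$genotypes)

#' Test whether a dataset is inversion-closed
#'
#' TRUE when every original pattern has exactly one inverted twin with the
#' same entity identifier, element-wise negated values and an identical
#' validity mask (and vice versa).
#'
#' @param dataset a [profile_dataset()].
#' @param tol numeric tolerance on the value negation check.
#' @return Logical scalar.
#' @export
is_inversion_closed <- function(dataset, tol = 0) {
  orig <- which(dataset$sign == "original")
  inv <- which(dataset$sign == "inverted")
  if (length(orig) != length(inv)) return(FALSE)
  key <- function(i) paste(dataset$entity_id[i], dataset$kind[i])
  m <- match(key(orig), key(inv))
  if (anyNA(m) || anyDuplicated(m)) return(FALSE)
  iv <- inv[m]
  ok_vals <- max(abs(dataset$values[orig, , drop = FALSE] +
                     dataset$values[iv, , drop = FALSE]), 0) <= tol
  ok_mask <- identical(dataset$validity[orig, , drop = FALSE],
                       dataset$validity[iv, , drop = FALSE])
  ok_vals && ok_mask
}

# index of the inverted twin for each original pattern (NA when absent)
inversion_pairs <- function(dataset) {
  orig <- which(dataset$sign == "original")
  inv <- which(dataset$sign == "inverted")
  key <- function(i) paste(dataset$entity_id[i], dataset$kind[i])
  m <- match(key(orig), key(inv))
  data.frame(original = orig, inverted = inv[m])
}

# subset patterns by row index, keeping all metadata aligned
subset_patterns <- function(dataset, idx) {
  profile_dataset(
    genotypes = dataset$genotypes,
    entity_id = dataset$entity_id[idx],
    kind = dataset$kind[idx],
    sign = dataset$sign[idx],
    values = dataset$values[idx, , drop = FALSE],
    validity = dataset$validity[idx, , drop = FALSE],
    raw_values = if (!is.null(dataset$raw_values))
      dataset$raw_values[idx, , drop = FALSE]
  )
}
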