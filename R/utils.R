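# internal helpers shared across modules

# Run an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards so library calls never perturb user simulations.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# fixed notation, 6 significant digits; the declared round-trip precision
# of the .data writers
format_value <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(signif(v, 6L), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
  out
}

is_number_token <- function(tok) {
  suppressWarnings(!is.na(as.numeric(tok)))
}

chromosome_of <- function(genotype_names) {
  tag <- sub("[-_].*$", "", genotype_names)
  tag[!grepl("^[0-9]+$", tag)] <- NA_character_
  tag
}
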