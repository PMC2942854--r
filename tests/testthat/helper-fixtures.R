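# fixtures built in code; no binary data anywhere in the suite

# a tiny hand-written dataset: 2 transcripts + 1 metabolite, P = 3
tiny_dataset <- function() {
  vals <- rbind(c(3, 4, 0),
                c(0, 1, 0),
                c(1, 1, 1))
  vals <- t(apply(vals, 1L, normalize_unit))
  profile_dataset(
    genotypes = c("12-1-1", "12-1", "5-1"),
    entity_id = c("LE12J18", "LE13G19", "L-aspartic acid"),
    kind = c("transcript", "transcript", "metabolite"),
    sign = "original",
    values = vals
  )
}

# random inversion-closed dataset of unit-normalized patterns
random_closed_dataset <- function(n_transcripts = 8L, n_metabolites = 4L,
                                  P = 5L, seed = 1L, missing_frac = 0) {
  set.seed(seed)
  n <- n_transcripts + n_metabolites
  vals <- matrix(rnorm(n * P), n, P)
  validity <- matrix(runif(n * P) >= missing_frac, n, P)
  validity[, 1L] <- TRUE  # keep every pattern at least partly valid
  vals <- t(vapply(seq_len(n),
                   function(i) normalize_unit(vals[i, ], validity[i, ]),
                   numeric(P)))
  vals[!validity] <- 0
  ds <- profile_dataset(
    genotypes = paste0("IL_", seq_len(P)),
    entity_id = c(sprintf("TR%03d", seq_len(n_transcripts)),
                  sprintf("MET%03d", seq_len(n_metabolites))),
    kind = c(rep("transcript", n_transcripts),
             rep("metabolite", n_metabolites)),
    sign = "original",
    values = vals, validity = validity
  )
  augment_inverted(ds)
}

# independent brute-force oracles --------------------------------------

# masked Euclidean BMU by explicit scan
bmu_bruteforce <- function(x, validity, codebook) {
  d2 <- vapply(seq_len(nrow(codebook)), function(j)
    sum(((x - codebook[j, ])[validity])^2), numeric(1))
  which.min(d2)
}

# cohesion by explicit member loop (masked, P/n_valid rescaling)
cohesion_bruteforce <- function(unit, bmu, values, validity, codebook) {
  members <- which(bmu == unit)
  if (!length(members)) return(NA_real_)
  P <- ncol(values)
  mean(vapply(members, function(i) {
    v <- validity[i, ]
    sum(((values[i, ] - codebook[unit, ])[v])^2) * P / sum(v)
  }, numeric(1)))
}

# one Lloyd k-means step: assign to nearest center (lowest index on
# ties), replace each center by the masked per-component member mean
lloyd_step <- function(values, validity, centers) {
  n <- nrow(values)
  assign <- vapply(seq_len(n), function(i)
    bmu_bruteforce(values[i, ], validity[i, ], centers), integer(1))
  new_centers <- centers
  for (k in sort(unique(assign))) {
    m <- which(assign == k)
    for (p in seq_len(ncol(values))) {
      v <- validity[m, p]
      if (any(v)) new_centers[k, p] <- mean(values[m, p][v])
    }
  }
  list(centers = new_centers, assign = assign)
}

train_tiny <- function(dataset, rows = 4L, cols = 4L, n_epochs = 12L) {
  train_batch(dataset, som_config(rows = rows, cols = cols,
                                  n_epochs = n_epochs))
}
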