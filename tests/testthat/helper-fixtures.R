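# Shared fixtures, all generated in code.

# K spherical Gaussian blobs in p dimensions, centers sep apart on axes
make_blobs <- function(K, n_per = 20, p = 2, sep = 10, sd = 1) {
  centers <- matrix(0, K, p)
  for (k in seq_len(K)) centers[k, ((k - 1) %% p) + 1] <- (k - 1) * sep
  x <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(rnorm(n_per * p, sd = sd), n_per, p), 2,
          centers[k, ], "+")))
  rownames(x) <- sprintf("r%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_len(K), each = n_per))
}

# minimal valid morpho table built in code
make_table <- function(n = 6, nests = 3, seed = 42) {
  set.seed(seed)
  df <- data.frame(
    specimen_id = sprintf("SP%02d", 1:n),
    nest_id = rep(sprintf("N%02d", seq_len(nests)), length.out = n),
    CL = runif(n, 600, 700),
    CWb = runif(n, 500, 600),
    SL = runif(n, 400, 500))
  as_morpho_table(df)
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# small Table-2-shaped dataset for end-to-end tests (subset of species to
# keep runtime down where full 8-species data are not required)
small_sim <- function(n_species = 4, nests = 8, nest_size = 3, seed = 7) {
  simulate_dataset(table2_params()[seq_len(n_species)],
                   nests_per_species = nests, nest_size = nest_size,
                   seed = seed)
}

trait_matrix <- function(tab, traits = NULL) {
  if (is.null(traits)) {
    traits <- intersect(analysis_traits(), names(tab))
    traits <- traits[vapply(traits, function(t) !anyNA(tab[[t]]), logical(1))]
  }
  X <- as.matrix(as.data.frame(tab)[, traits, drop = FALSE])
  rownames(X) <- tab$specimen_id
  X
}
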