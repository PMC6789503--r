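# fixture builders shared across test files; everything is generated in code

# nine points exactly on F = 3R plus one gross outlier at (1, 100)
outlier_fixture <- function() {
  replicate_set(renilla = c(1:9, 1), firefly = c(3 * (1:9), 100))
}

# random positive-slope data with modest vertical noise; slope drawn in
# (0.5, 8) so grid oracles over [0, 10] always bracket the answer
random_fixture <- function(seed, n = 8) {
  set.seed(seed)
  slope <- runif(1, 0.5, 8)
  r <- runif(n, 1, 20)
  f <- slope * r + rnorm(n, sd = 0.2 * slope)
  list(data = replicate_set(r, f), slope = slope)
}

# grid minimizer of the orthogonal objective, the independent EIV oracle
eiv_grid_oracle <- function(data, lo = 0, hi = 10, step = 1e-4) {
  a <- seq(lo, hi, by = step)
  sxx <- sum(data$renilla^2); syy <- sum(data$firefly^2)
  sxy <- sum(data$renilla * data$firefly)
  obj <- (syy - 2 * a * sxy + a^2 * sxx) / (1 + a^2)
  a[which.min(obj)]
}

# temporary luminescence CSV from vectors; returns the path
write_fixture_csv <- function(luc, ren, construct, ..., path = tempfile(fileext = ".csv")) {
  df <- data.frame(Luc = luc, Ren = ren, Construct = construct, ...)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
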