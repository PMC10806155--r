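# fixture factories shared across test files

stdMatrix <- function(n = 12, p = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
    dimnames = list(paste0("S", seq_len(n)), paste0("f", seq_len(p))))
  standardizeBlock(x, rownames(x))$values
}

# two well-separated Gaussian clusters with standardized features
clusterData <- function(n = 20, p = 3, sep = 6, seed = 1) {
  set.seed(seed)
  mu <- rbind(rep(0, p), rep(sep / sqrt(p), p))
  lab <- rep(c("A", "B"), each = n)
  X <- mu[rep(1:2, each = n), ] + matrix(rnorm(2 * n * p), 2 * n, p)
  dimnames(X) <- list(paste0("S", seq_len(2 * n)), paste0("f", seq_len(p)))
  list(X = standardizeBlock(X, rownames(X))$values,
    labels = factor(lab))
}

tinyBlockCsv <- function(path, ids = c("S1", "S2", "S3")) {
  writeLines(c("sample_id,f1,f2",
    paste(ids, c("1.5,2.25", "2,3", "3.75,4.5"), sep = ",")), path)
  path
}
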