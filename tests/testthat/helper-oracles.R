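# Independent oracles, deliberately coded with naive loops so they share no
# code path with the package implementations they check.

# exhaustive greedy Kennard-Stone: explicit distance loops, ties -> lowest index
ksOracle <- function(X, k) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- NULL; bestD <- -Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (d(i, j) > bestD) { bestD <- d(i, j); best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < k) {
    bestIdx <- NA_integer_; bestMin <- -Inf
    for (r in setdiff(seq_len(n), sel)) {
      mn <- Inf
      for (s in sel) mn <- min(mn, d(r, s))
      if (mn > bestMin) { bestMin <- mn; bestIdx <- r }
    }
    sel <- c(sel, bestIdx)
  }
  sel
}

# reference NIPALS loop (deflating X and Y, u initialised from the
# max-variance response column), coded independently
nipalsOracle <- function(X, Y, A) {
  E <- sweep(X, 2, colMeans(X)); F <- sweep(Y, 2, colMeans(Y))
  out <- list(W = NULL, T = NULL, P = NULL, Q = NULL)
  for (a in seq_len(A)) {
    u <- F[, order(-apply(F, 2, var))[1]]
    tv <- NULL
    repeat {
      w <- as.vector(t(E) %*% u); w <- w / sqrt(sum(w * w))
      tNew <- as.vector(E %*% w)
      q <- as.vector(t(F) %*% tNew) / sum(tNew * tNew)
      u <- as.vector(F %*% q) / sum(q * q)
      if (!is.null(tv) && sqrt(sum((tNew - tv)^2)) < 1e-12 * sqrt(sum(tNew^2)))
        { tv <- tNew; break }
      tv <- tNew
    }
    p <- as.vector(t(E) %*% tv) / sum(tv * tv)
    out$W <- cbind(out$W, w); out$T <- cbind(out$T, tv)
    out$P <- cbind(out$P, p); out$Q <- cbind(out$Q, q)
    E <- E - tv %*% t(p)
    F <- F - tv %*% t(q)
  }
  out
}

# brute-force sums of squares for the univariate Wilk's lambda
wilksOracle <- function(x, g) {
  tot <- 0; for (v in x) tot <- tot + (v - mean(x))^2
  within <- 0
  for (lev in unique(g)) {
    xi <- x[g == lev]
    for (v in xi) within <- within + (v - mean(xi))^2
  }
  within / tot
}

# exhaustive pair-counting AUC, ties counted one half
aucOracle <- function(scores, pos) {
  num <- 0; den <- 0
  for (i in which(pos)) for (j in which(!pos)) {
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  num / den
}

# independent grid evaluation for the SVM selection check (same fold
# assignment, naive loop over pairs calling libsvm directly)
svmGridOracle <- function(X, y, gGrid, cGrid, foldIds) {
  err <- matrix(NA_real_, length(gGrid), length(cGrid))
  for (i in seq_along(gGrid)) for (j in seq_along(cGrid)) {
    wrong <- 0
    for (f in unique(foldIds)) {
      hold <- foldIds == f
      fit <- e1071::svm(X[!hold, , drop = FALSE], droplevels(y[!hold]),
        scale = FALSE, kernel = "radial", gamma = gGrid[i], cost = cGrid[j])
      wrong <- wrong +
        sum(predict(fit, X[hold, , drop = FALSE]) != y[hold])
    }
    err[i, j] <- wrong / length(y)
  }
  err
}

# two concentric rings: linearly inseparable two-class data
ringData <- function(n = 30, seed = 1) {
  set.seed(seed)
  th <- runif(2 * n, 0, 2 * pi)
  r <- c(rep(1, n), rep(3, n)) + rnorm(2 * n, 0, 0.1)
  X <- cbind(r * cos(th), r * sin(th))
  rownames(X) <- paste0("S", seq_len(2 * n))
  colnames(X) <- c("x", "y")
  list(X = X, y = factor(rep(c("in", "out"), each = n)))
}
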