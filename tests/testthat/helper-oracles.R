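# independent oracles used to verify the implementation; all written from
# scratch against the stated definitions, never calling the code they check

# naive residual-update coordinate descent for
# (1/2N)||y - b0 - X beta||^2 + lambda (alpha |beta|_1 + (1-alpha)/2 |beta|_2^2)
oracle_cd_penalized <- function(X, y, lambda, alpha = 1, sweeps = 200000L,
                                tol = 1e-15) {
  N <- nrow(X)
  p <- ncol(X)
  beta <- numeric(p)
  b0 <- mean(y)
  r <- y - b0
  xs <- colSums(X^2) / N
  for (s in seq_len(sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      rho <- sum(X[, j] * r) / N + xs[j] * beta[j]
      bj <- sign(rho) * max(abs(rho) - lambda * alpha, 0) /
        (xs[j] + lambda * (1 - alpha))
      if (bj != beta[j]) {
        r <- r - X[, j] * (bj - beta[j])
        delta <- max(delta, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    b0_new <- b0 + mean(r)
    r <- r - (b0_new - b0)
    delta <- max(delta, abs(b0_new - b0))
    b0 <- b0_new
    if (delta < tol) break
  }
  list(intercept = b0, beta = beta)
}

# glmnet route for the same objective. glmnet internally standardizes y by
# its 1/N standard deviation, which rescales the L1 and L2 terms differently;
# feeding standardized y with remapped (lambda, alpha) reproduces the
# textbook objective exactly.
oracle_glmnet_penalized <- function(X, y, lambda, alpha = 1) {
  s <- sqrt(mean((y - mean(y))^2))
  lp <- lambda * alpha / s + lambda * (1 - alpha)
  ap <- (lambda * alpha / s) / lp
  fit <- glmnet::glmnet(X, y / s, alpha = ap, standardize = FALSE,
                        thresh = 1e-16)
  cf <- as.numeric(glmnet::coef.glmnet(
    fit, s = lp, exact = TRUE, x = X, y = y / s, alpha = ap,
    standardize = FALSE, thresh = 1e-16)) * s
  list(intercept = cf[1L], beta = cf[-1L])
}

# exhaustive-permutation edge p-values for a single-run ensemble: fraction of
# all cell permutations whose value at a cell is >= |F| there
oracle_exhaustive_perm_fraction <- function(F) {
  cells <- as.numeric(F)
  nm <- length(cells)
  perms <- oracle_all_perms(nm)
  target <- abs(cells)
  counts <- numeric(nm)
  for (l in seq_len(nrow(perms))) {
    counts <- counts + (abs(cells[perms[l, ]]) >= target)
  }
  matrix(counts / nrow(perms), nrow(F))
}

oracle_all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# exact binomial upper tail by direct summation of the mass function
oracle_binom_tail <- function(n_correct, n_scored, p0) {
  if (n_correct <= 0) return(1)
  k <- n_correct:n_scored
  sum(choose(n_scored, k) * p0^k * (1 - p0)^(n_scored - k))
}

# P(|A' intersect B'| >= k) for random subsets of sizes na, nb from a
# universe of size U, by complete enumeration of all subset pairs
oracle_overlap_tail <- function(na, nb, U, k) {
  As <- utils::combn(U, na, simplify = FALSE)
  Bs <- utils::combn(U, nb, simplify = FALSE)
  hits <- 0L
  for (a in As) for (b in Bs) if (length(intersect(a, b)) >= k) hits <- hits + 1L
  hits / (length(As) * length(Bs))
}
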