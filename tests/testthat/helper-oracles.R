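# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct linear algebra, triple loops, exhaustive
# enumeration.

# Closed-form weighted ridge with an unpenalised intercept:
# minimise sum_i w_i (y_i - b0 - z_i'b)^2 + lambda ||b||^2.
ridge_oracle <- function(Z, y, w, lambda) {
  X <- cbind(1, Z)
  A <- crossprod(X * w, X)
  diag(A)[-1] <- diag(A)[-1] + lambda
  drop(solve(A, crossprod(X * w, y)))[-1]
}

# Brute-force PCIT: literal triple loop over ordered trios, recomputing the
# three partials and the mean-ratio tolerance each time.
pcit_oracle <- function(C) {
  n <- nrow(C)
  keep <- matrix(TRUE, n, n)
  diag(keep) <- FALSE
  flag_edge <- function(rab, ra, rb, eps) {
    abs(rab) <= abs(eps * ra) && abs(rab) <= abs(eps * rb)
  }
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- C[x, y]; rxz <- C[x, z]; ryz <- C[y, z]
    dxy <- (1 - rxz^2) * (1 - ryz^2)
    dxz <- (1 - rxy^2) * (1 - ryz^2)
    dyz <- (1 - rxy^2) * (1 - rxz^2)
    if (dxy <= 0 || dxz <= 0 || dyz <= 0) next
    pxy <- (rxy - rxz * ryz) / sqrt(dxy)
    pxz <- (rxz - rxy * ryz) / sqrt(dxz)
    pyz <- (ryz - rxy * rxz) / sqrt(dyz)
    ratios <- c()
    if (abs(rxy) >= 1e-12) ratios <- c(ratios, abs(pxy / rxy))
    if (abs(rxz) >= 1e-12) ratios <- c(ratios, abs(pxz / rxz))
    if (abs(ryz) >= 1e-12) ratios <- c(ratios, abs(pyz / ryz))
    if (!length(ratios)) next
    eps <- mean(ratios)
    if (flag_edge(rxy, rxz, ryz, eps)) keep[x, y] <- keep[y, x] <- FALSE
    if (flag_edge(rxz, rxy, ryz, eps)) keep[x, z] <- keep[z, x] <- FALSE
    if (flag_edge(ryz, rxy, rxz, eps)) keep[y, z] <- keep[z, y] <- FALSE
  }
  keep
}

# Random correlation matrix via a random Gram matrix (always valid PSD).
random_corr <- function(n, p = n + 2) {
  X <- matrix(rnorm(n * p), n, p)
  stats::cov2cor(tcrossprod(X))
}

# Exhaustive PWM p-value: enumerate all 4^L sequences, using the same
# integer score discretization as the DP.
pwm_pvalue_enum <- function(scores, threshold, background = rep(0.25, 4),
                            granularity = 1e-3) {
  S <- round(scores / granularity)
  L <- ncol(S)
  seqs <- as.matrix(expand.grid(rep(list(1:4), L)))
  tot <- 0
  t_int <- round(threshold / granularity)
  for (r in seq_len(nrow(seqs))) {
    sc <- sum(S[cbind(seqs[r, ], seq_len(L))])
    if (sc >= t_int) tot <- tot + prod(background[seqs[r, ]])
  }
  tot
}

# Exhaustive trio search returning the best coverage value only.
trio_coverage_oracle <- function(sets) {
  best <- -1L
  ids <- names(sets)
  for (i in 1:(length(ids) - 2))
    for (j in (i + 1):(length(ids) - 1))
      for (k in (j + 1):length(ids)) {
        cov <- length(unique(c(sets[[i]], sets[[j]], sets[[k]])))
        if (cov > best) best <- cov
      }
  best
}

# Small simulation bundle shared by several tests.
small_bundle <- function(seed = 42, ...) {
  simulate_all(sim_config(n_markers = 300, n_animals = 150,
                          n_chromosomes = 3, n_genes = 40, n_tfs = 4,
                          seed = seed, ...))
}

# True per-window share (%) of genetic variance, from the simulated truth.
true_window_shares <- function(G, beta, map, center = colMeans(G)) {
  Z <- sweep(as.matrix(G), 2, center)
  g <- drop(Z %*% beta)
  win <- assign_window(map$chrom, map$pos_bp)
  shares <- vapply(unique(win), function(w) {
    j <- which(win == w)
    stats::var(drop(Z[, j, drop = FALSE] %*% beta[j])) / stats::var(g)
  }, numeric(1))
  100 * shares
}
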