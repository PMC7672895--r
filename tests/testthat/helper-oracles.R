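# Independent straight-line oracles used to verify the vectorized feature
# implementations, plus small fixture builders. These deliberately share no
# code with the package internals beyond the bundled residue tables.

random_fragment <- function(len = sample(4:20, 1)) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

random_profile <- function(len = sample(4:20, 1), lo = -6L, hi = 8L) {
  res <- paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
  pssm_profile(res, matrix(sample(lo:hi, len * 20L, replace = TRUE), len, 20L))
}

# PseAAC by direct transcription of the type-1 formulas
oracle_pseaac <- function(residues, lam, w) {
  res <- strsplit(residues, "")[[1]]
  L <- length(res)
  tab <- read.delim(system.file("extdata", "property_scales.tsv",
                                package = "deepfragk"), comment.char = "#")
  std <- function(col) {
    v <- setNames(tab[[col]], tab$residue)
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }
  h1 <- std("hydrophobicity"); h2 <- std("hydrophilicity"); m <- std("sidechain_mass")
  theta_fn <- function(ri, rj)
    ((h1[ri] - h1[rj])^2 + (h2[ri] - h2[rj])^2 + (m[ri] - m[rj])^2) / 3
  k_max <- min(lam, L - 1)
  theta <- numeric(k_max)
  for (k in seq_len(k_max)) {
    acc <- 0
    for (i in 1:(L - k)) acc <- acc + theta_fn(res[i], res[i + k])
    theta[k] <- acc / (L - k)
  }
  f <- sapply(AA_ALPHABET, function(a) sum(res == a) / L)
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom, numeric(20 - k_max))
}

# 32x32 orthonormal 3-level Haar analysis matrix, built row by row
oracle_haar_matrix <- function() {
  H2 <- function(n) {   # one analysis level on length n
    m <- matrix(0, n, n)
    for (i in 1:(n / 2)) {
      m[i, 2 * i - 1] <- 1 / sqrt(2); m[i, 2 * i] <- 1 / sqrt(2)          # approx
      m[n / 2 + i, 2 * i - 1] <- 1 / sqrt(2); m[n / 2 + i, 2 * i] <- -1 / sqrt(2)  # detail
    }
    m
  }
  lvl1 <- H2(32)
  lvl2 <- diag(32); lvl2[1:16, 1:16] <- H2(16)
  lvl3 <- diag(32); lvl3[1:8, 1:8] <- H2(8)
  # rows after all levels: A3 (1:4), D3 (5:8), D2 (9:16), D1 (17:32)
  lvl3 %*% lvl2 %*% lvl1
}

# dipeptide-style PSSM summaries by explicit double loops
oracle_pssm_dc <- function(tv) {
  L <- nrow(tv)
  m <- matrix(0, 20, 20)
  for (a in 1:20) for (b in 1:20) {
    s <- 0
    for (k in 1:(L - 1)) s <- s + tv[k, a] * tv[k + 1, b]
    m[a, b] <- s / (L - 1)
  }
  as.vector(t(m))
}

oracle_bigram <- function(scores) {
  L <- nrow(scores)
  n <- t(apply(scores, 1, function(r) exp(r) / sum(exp(r))))
  m <- matrix(0, 20, 20)
  for (a in 1:20) for (b in 1:20)
    for (k in 1:(L - 1)) m[a, b] <- m[a, b] + n[k, a] * n[k + 1, b]
  as.vector(t(m))
}

oracle_ed_pssm <- function(tv, d) {
  L <- nrow(tv)
  m <- matrix(0, 20, 20)
  for (a in 1:20) for (b in 1:20) {
    s <- 0
    for (k in 1:(L - d)) s <- s + (tv[k, a] - tv[k + d, b])^2
    m[a, b] <- s / (L - d)
  }
  as.vector(t(m))
}

# Oracle for the exact RBM gradient: enumerate every joint (v, h)
# configuration of a tiny Bernoulli machine and average the sufficient
# statistics directly under the Boltzmann distribution.
oracle_rbm_grad <- function(rbm, data) {
  nv <- nrow(rbm$W); nh <- ncol(rbm$W)
  vs <- as.matrix(expand.grid(rep(list(0:1), nv)))
  hs <- as.matrix(expand.grid(rep(list(0:1), nh)))
  logp <- matrix(0, nrow(vs), nrow(hs))
  for (i in seq_len(nrow(vs))) for (j in seq_len(nrow(hs)))
    logp[i, j] <- sum(rbm$a * vs[i, ]) + sum(rbm$b * hs[j, ]) +
      as.numeric(t(vs[i, ]) %*% rbm$W %*% hs[j, ])
  p <- exp(logp - max(logp)); p <- p / sum(p)
  negW <- matrix(0, nv, nh); nega <- numeric(nv); negb <- numeric(nh)
  for (i in seq_len(nrow(vs))) for (j in seq_len(nrow(hs))) {
    negW <- negW + p[i, j] * outer(vs[i, ], hs[j, ])
    nega <- nega + p[i, j] * vs[i, ]
    negb <- negb + p[i, j] * hs[j, ]
  }
  posW <- matrix(0, nv, nh); posb <- numeric(nh)
  for (r in seq_len(nrow(data))) {
    lp <- sapply(seq_len(nrow(hs)), function(j)
      sum(rbm$b * hs[j, ]) + sum((data[r, ] %*% rbm$W) * hs[j, ]))
    ph <- exp(lp - max(lp)); ph <- ph / sum(ph)
    eh <- colSums(ph * hs)
    posW <- posW + outer(data[r, ], eh) / nrow(data)
    posb <- posb + eh / nrow(data)
  }
  list(W = posW - negW, a = colMeans(data) - nega, b = posb - negb)
}
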