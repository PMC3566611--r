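# Independent oracles and shared fixtures. Each oracle is a deliberately
# naive re-derivation (loops, enumeration) kept separate from the package's
# vectorised code paths.

# Direct per-gene evaluation of the sex-bias statistic, scalar loops only.
oracle_bias <- function(counts, sex, cap = 10) {
  sexes <- c("male", "female")
  nbar <- list()
  nhat <- list()
  for (s in sexes) {
    cols <- which(sex == s)
    Ni <- numeric(length(cols))
    for (j in seq_along(cols)) Ni[j] <- sum(counts[, cols[j]])
    N <- sum(Ni)
    w <- Ni / N
    nb <- numeric(nrow(counts))
    for (g in seq_len(nrow(counts))) {
      acc <- 0
      for (j in seq_along(cols)) acc <- acc + w[j] * counts[g, cols[j]]
      nb[g] <- acc
    }
    nbar[[s]] <- nb
    nhat[[s]] <- N / length(cols)
  }
  B <- log2(nhat$male / nhat$female)
  out <- numeric(0)
  for (g in seq_len(nrow(counts))) {
    if (sum(counts[g, ]) == 0) next
    b <- log2(nbar$male[g] / nbar$female[g]) - B
    b <- max(min(b, cap), -cap)
    names(b) <- rownames(counts)[g]
    out <- c(out, b)
  }
  out
}

# Random expression matrix for property tests; guarantees nonzero depth in
# both sexes.
random_expr <- function(n_genes = 20, n_male = 3, n_female = 3,
                        zero_frac = 0.1) {
  n_samp <- n_male + n_female
  m <- matrix(rpois(n_genes * n_samp, lambda = 50), nrow = n_genes)
  zero <- runif(n_genes) < zero_frac
  m[zero, ] <- 0
  if (all(zero)) m[1, ] <- rpois(n_samp, 50) + 1
  if (sum(m[, seq_len(n_male)]) == 0) m[1, 1] <- 1
  if (sum(m[, n_male + seq_len(n_female)]) == 0) m[1, n_male + 1] <- 1
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- c(sprintf("m%d", seq_len(n_male)),
                   sprintf("f%d", seq_len(n_female)))
  expression_matrix(m, rep(c("male", "female"), c(n_male, n_female)))
}

# Hypergeometric pmf by direct enumeration over binomial coefficients.
oracle_hyper_pmf <- function(N, K, n, k) {
  if (k < max(0, n + K - N) || k > min(n, K)) return(0)
  choose(K, k) * choose(N - K, n - k) / choose(N, n)
}

# Kendall tau-b by O(n^2) pair counting.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# Five-node toy graph used across the network tests:
# u1-m1, m1-f1, f1-u1, m1-m2 with labels u->U, m->M, f->F.
toy_graph <- function() {
  net <- interaction_network(rbind(c("u1", "m1"), c("m1", "f1"),
                                   c("f1", "u1"), c("m1", "m2")))
  labels <- c(u1 = "U", m1 = "M", m2 = "M", f1 = "F")
  list(net = net, labels = labels)
}

# Random labelled network for property tests.
random_labelled_net <- function(n = 30, p = 0.15) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  labels <- sample(c("M", "F", "U"), igraph::vcount(g), replace = TRUE)
  names(labels) <- igraph::V(g)$name
  list(net = g, labels = labels)
}
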