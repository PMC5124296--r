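# Independent brute-force oracles used across test files. These follow the
# defining formulas with explicit loops and stay deliberately independent
# of the package's computational routes.

# population moments by direct summation
oracle_moments <- function(x) {
  n <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v / n
  m2 <- m3 <- m4 <- 0
  for (v in x) {
    m2 <- m2 + (v - mu)^2 / n
    m3 <- m3 + (v - mu)^3 / n
    m4 <- m4 + (v - mu)^4 / n
  }
  list(mean = mu, variance = m2,
       skewness = m3 / m2^1.5, kurtosis_excess = m4 / m2^2 - 3)
}

# feature-selection coefficient via the explicit double loop over class
# pairs and a per-sample loop for the within-class variances
oracle_fisher <- function(X, classes) {
  labs <- unique(classes)
  N <- nrow(X)
  P <- mu <- list()
  Vk2 <- numeric(length(labs))
  for (k in seq_along(labs)) {
    rows <- which(classes == labs[k])
    P[[k]] <- length(rows) / N
    mu[[k]] <- colMeans(X[rows, , drop = FALSE])
    s <- 0
    for (i in rows) s <- s + sum((X[i, ] - mu[[k]])^2)
    Vk2[k] <- s / length(rows)
  }
  num <- 0
  for (k in seq_along(labs))
    for (j in seq_along(labs))
      num <- num + P[[k]] * P[[j]] * sum((mu[[k]] - mu[[j]])^2)
  D2 <- num / (1 - sum(unlist(P)^2))
  V2 <- sum(unlist(P) * Vk2)
  list(D2 = D2, V2 = V2, F = D2 / V2)
}

# textbook pooled two-sample t
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# random multi-class feature matrix for property tests
random_feature_matrix <- function(seed, n_classes = 3, dim = 4,
                                  per_class = 10, sep = 3) {
  set.seed(seed)
  X <- NULL; labs <- character(0)
  for (k in seq_len(n_classes)) {
    center <- rnorm(dim, sd = sep)
    X <- rbind(X, matrix(rnorm(per_class * dim), per_class, dim) +
                 matrix(center, per_class, dim, byrow = TRUE))
    labs <- c(labs, rep(paste0("c", k), per_class))
  }
  feature_matrix(X, labs)
}
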