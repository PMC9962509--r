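# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small mixed-group dataset for structural tests
tiny_dataset <- function() memo("tiny", generate_dataset(
  n_healthy = 2, n_mkoa = 2, duration = 20, seed = 42))

# healthy-only dataset long enough for model fits with a small reservoir
fit_dataset <- function() memo("fit_ds", generate_dataset(
  n_healthy = 3, n_mkoa = 0, duration = 12, seed = 7))

small_hp <- function(seed = 1) esn_hyperparameters(n_nodes = 30, seed = seed)

# independent spectral-radius oracle: power-iteration warm-up followed by
# Rayleigh-Ritz on a small Arnoldi (Krylov) basis, which handles the
# complex-conjugate dominant pairs a plain power iteration cannot
power_iteration_radius <- function(W, warm = 500, d = 8, seed = 99) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  x <- rnorm(nrow(W))
  for (i in seq_len(warm)) { x <- W %*% x; x <- x / sqrt(sum(x^2)) }
  Q <- matrix(0, nrow(W), d)
  H <- matrix(0, d, d)
  Q[, 1] <- x / sqrt(sum(x^2))
  for (j in seq_len(d - 1)) {
    v <- W %*% Q[, j]
    for (i in 1:j) { H[i, j] <- sum(Q[, i] * v); v <- v - H[i, j] * Q[, i] }
    for (i in 1:j) {  # re-orthogonalize for numerical safety
      c2 <- sum(Q[, i] * v); H[i, j] <- H[i, j] + c2; v <- v - c2 * Q[, i]
    }
    H[j + 1, j] <- sqrt(sum(v^2))
    if (H[j + 1, j] < 1e-14) { d <- j; break }
    Q[, j + 1] <- v / H[j + 1, j]
  }
  v <- W %*% Q[, d]
  for (i in 1:d) H[i, d] <- sum(Q[, i] * v)
  max(Mod(eigen(H[1:d, 1:d, drop = FALSE], only.values = TRUE)$values))
}

# independent ridge oracle: augmented least squares solved by QR
# (minimizes ||t(Y) - t(X) B||^2 + gamma ||B||^2 columnwise)
ridge_oracle <- function(X, Y, gamma) {
  N <- nrow(X)
  A <- rbind(t(X), sqrt(gamma) * diag(N))
  B <- rbind(t(Y), matrix(0, N, nrow(Y)))
  t(qr.solve(A, B))
}
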