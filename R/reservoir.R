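# Leaky-integrator echo state network: fixed random input and recurrent
# weights, tanh activation, convex leaky state update.

#' Echo state network hyperparameters
#'
#' The defaults are the operating point used throughout the package:
#' 100 nodes, leak rate 0.1053, recurrent spectral radius 0.7471, recurrent
#' sparsity 0.21 and ridge regularization 1e-6.
#'
#' @param n_nodes number of reservoir nodes N.
#' @param leak_rate leak rate in (0, 1]; the state update is
#'   `x(t) = a * tanh(W_in u(t) + W x(t-1)) + (1 - a) * x(t-1)`.
#' @param spectral_radius target spectral radius of the recurrent matrix W.
#' @param sparsity fraction of non-zero entries of W, in (0, 1].
#' @param regularization ridge parameter gamma (>= 0) used by the readout.
#' @param input_scaling half-width of the uniform distribution of input
#'   weights.
#' @param seed integer seed; reservoirs rebuilt from identical
#'   hyperparameters are bit-identical.
#' @return object of class `esn_hyperparameters`.
#' @export
esn_hyperparameters <- function(n_nodes = 100, leak_rate = 0.1053,
                                spectral_radius = 0.7471, sparsity = 0.21,
                                regularization = 1e-6, input_scaling = 1,
                                seed = 1L) {
  check_scalar_num(n_nodes, "n_nodes", lower = 1)
  check_scalar_num(leak_rate, "leak_rate", lower = 0, upper = 1,
                   strict_lower = TRUE)
  check_scalar_num(spectral_radius, "spectral_radius", lower = 0,
                   strict_lower = TRUE)
  check_scalar_num(sparsity, "sparsity", lower = 0, upper = 1,
                   strict_lower = TRUE)
  check_scalar_num(regularization, "regularization", lower = 0)
  check_scalar_num(input_scaling, "input_scaling", lower = 0,
                   strict_lower = TRUE)
  structure(list(n_nodes = as.integer(n_nodes), leak_rate = leak_rate,
                 spectral_radius = spectral_radius, sparsity = sparsity,
                 regularization = regularization,
                 input_scaling = input_scaling, seed = as.integer(seed)),
            class = "esn_hyperparameters")
}

#' @export
print.esn_hyperparameters <- function(x, ...) {
  cat(sprintf(paste0("<esn_hyperparameters: N=%d, leak=%.4f, radius=%.4f, ",
                     "sparsity=%.2f, gamma=%g, seed=%d>\n"),
              x$n_nodes, x$leak_rate, x$spectral_radius, x$sparsity,
              x$regularization, x$seed))
  invisible(x)
}

#' Build a seeded reservoir
#'
#' Samples a dense input matrix `W_in` (N x n_inputs, uniform on
#' +/- `input_scaling`) and a sparse recurrent matrix `W` (non-zero entries
#' uniform on \[-1, 1\] at the configured sparsity), then rescales `W` so
#' its spectral radius equals the configured value exactly (scale by
#' target / actual).  An all-zero draw of `W` is resampled from the
#' continuing random stream, with a bounded number of retries.
#'
#' @param hp an [esn_hyperparameters()] object.
#' @param n_inputs input dimension (bias row plus >= 1 signal rows).
#' @return object of class `esn_reservoir` with elements `W_in`, `W`, `hp`,
#'   `n_inputs`.
#' @export
build_reservoir <- function(hp, n_inputs) {
  stopifnot(inherits(hp, "esn_hyperparameters"))
  if (n_inputs < 2) stop_invalid("n_inputs must be >= 2 (bias + one axis)")
  N <- hp$n_nodes
  with_seed(hp$seed, {
    W_in <- matrix(stats::runif(N * n_inputs, -hp$input_scaling,
                                hp$input_scaling), N, n_inputs)
    W <- NULL
    for (try in 1:10) {
      mask <- stats::runif(N * N) < hp$sparsity
      vals <- stats::runif(N * N, -1, 1)
      Wc <- matrix(mask * vals, N, N)
      radius <- max(abs(eigen(Wc, only.values = TRUE)$values))
      if (radius > 1e-12) {
        W <- Wc * (hp$spectral_radius / radius)
        break
      }
    }
    if (is.null(W))
      stop_invalid("sampled recurrent matrix had zero spectral radius after 10 retries; increase sparsity or n_nodes")
    structure(list(W_in = W_in, W = W, hp = hp,
                   n_inputs = as.integer(n_inputs)),
              class = "esn_reservoir")
  })
}

#' @export
print.esn_reservoir <- function(x, ...) {
  cat(sprintf("<esn_reservoir: N=%d, n_inputs=%d, radius=%.4f>\n",
              x$hp$n_nodes, x$n_inputs, x$hp$spectral_radius))
  invisible(x)
}

#' Run the reservoir over an input sequence
#'
#' Iterates the leaky state update
#' `x~(t) = tanh(W_in u(t) + W x(t-1))`,
#' `x(t) = a x~(t) + (1 - a) x(t-1)` from `x0` (default zero) and returns
#' all states.  By convention the first input row is the constant bias 1.
#' States stay in \[-1, 1\] for any input when `x0` does.
#'
#' `leak_variant = "printed"` uses `(a - 1)` in place of `(1 - a)` on the
#' retained state, an alternative form kept only for comparison; it flips
#' the sign of the remembered state every step and is not a fading-memory
#' update.
#'
#' @param res an `esn_reservoir`.
#' @param U n_inputs x T input sequence.
#' @param x0 initial state (length N, entries in \[-1, 1\]); default zeros.
#' @param leak_variant `"convex"` (default) or `"printed"`.
#' @return N x T matrix of reservoir states.
#' @export
run_reservoir <- function(res, U, x0 = NULL,
                          leak_variant = c("convex", "printed")) {
  stopifnot(inherits(res, "esn_reservoir"))
  leak_variant <- match.arg(leak_variant)
  if (!is.matrix(U)) U <- matrix(U, nrow = 1L)
  if (nrow(U) != res$n_inputs)
    stop_invalid("input has ", nrow(U), " rows but the reservoir expects ",
                 res$n_inputs)
  N <- res$hp$n_nodes
  if (is.null(x0)) x0 <- numeric(N)
  if (length(x0) != N) stop_invalid("x0 must have length ", N)
  if (any(abs(x0) > 1)) stop_invalid("x0 entries must lie in [-1, 1]")
  a <- res$hp$leak_rate
  ret <- if (leak_variant == "convex") 1 - a else a - 1
  Tn <- ncol(U)
  WU <- res$W_in %*% U
  W <- res$W
  X <- matrix(0, N, Tn)
  x <- x0
  for (t in seq_len(Tn)) {
    x <- drop(a * tanh(WU[, t] + W %*% x) + ret * x)
    X[, t] <- x
  }
  X
}

#' Linear readout of reservoir states
#'
#' @param W_out N_out x N readout matrix.
#' @param X N x T state matrix.
#' @return N_out x T predictions `W_out %*% X`.
#' @export
readout <- function(W_out, X) {
  if (!is.matrix(W_out)) W_out <- matrix(W_out, nrow = 1L)
  if (ncol(W_out) != nrow(X))
    stop_invalid("W_out has ", ncol(W_out), " columns but X has ", nrow(X),
                 " states")
  W_out %*% X
}
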