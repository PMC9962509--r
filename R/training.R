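# Readout training: streaming (optionally weighted) normal equations,
# ridge solve, and the Gaussian temporal-parameter kernel method that fits
# a bank of specialized readouts.

#' Accumulate (weighted) normal equations over records
#'
#' Streams over records, accumulating the state Gram matrix
#' `XXT = sum_p X_p P_p X_p'` and the target–state cross matrix
#' `YXT = sum_p Y_p P_p X_p'`, where `P_p` is the diagonal matrix of
#' per-sample importance weights (identity when `weights` is `NULL`).  No
#' concatenated matrix is ever materialized, so memory is independent of
#' the number of records.
#'
#' @param states list of N x T_p state matrices, one per record.
#' @param targets list of N_out x T_p target matrices, matching `states`.
#' @param weights optional list of non-negative per-sample weight vectors.
#' @return object of class `normal_equations` with `XXT`, `YXT`,
#'   `n_samples`, `total_weight`.
#' @export
accumulate_normal_equations <- function(states, targets, weights = NULL) {
  stopifnot(is.list(states), is.list(targets),
            length(states) == length(targets))
  if (length(states) == 0L) stop_invalid("no records to accumulate")
  N <- nrow(states[[1]])
  N_out <- nrow(targets[[1]])
  XXT <- matrix(0, N, N)
  YXT <- matrix(0, N_out, N)
  n_samples <- 0L
  total_weight <- 0
  for (p in seq_along(states)) {
    Xp <- states[[p]]
    Yp <- targets[[p]]
    if (!is.matrix(Yp)) Yp <- matrix(Yp, nrow = 1L)
    if (ncol(Xp) != ncol(Yp))
      stop_invalid("record ", p, ": states have ", ncol(Xp),
                   " samples but targets have ", ncol(Yp))
    if (is.null(weights)) {
      XXT <- XXT + tcrossprod(Xp)
      YXT <- YXT + tcrossprod(Yp, Xp)
      total_weight <- total_weight + ncol(Xp)
    } else {
      w <- weights[[p]]
      if (length(w) != ncol(Xp))
        stop_invalid("record ", p, ": ", length(w), " weights for ",
                     ncol(Xp), " samples")
      if (any(w < 0)) stop_invalid("importance weights must be non-negative")
      Xw <- Xp * rep(w, each = nrow(Xp))
      XXT <- XXT + tcrossprod(Xw, Xp)
      YXT <- YXT + tcrossprod(Yp * rep(w, each = nrow(Yp)), Xp)
      total_weight <- total_weight + sum(w)
    }
    n_samples <- n_samples + ncol(Xp)
  }
  XXT <- (XXT + t(XXT)) / 2  # enforce exact symmetry
  structure(list(XXT = XXT, YXT = YXT, n_samples = n_samples,
                 total_weight = total_weight),
            class = "normal_equations")
}

#' Solve the ridge-regularized readout
#'
#' Computes `W_out = YXT (XXT + gamma I)^{-1}` through a Cholesky solve of
#' the regularized Gram matrix (never an explicit inverse).
#'
#' @param ne a `normal_equations` object.
#' @param gamma ridge regularization (>= 0).
#' @return N_out x N readout matrix.
#' @export
solve_ridge <- function(ne, gamma) {
  stopifnot(inherits(ne, "normal_equations"))
  check_scalar_num(gamma, "gamma", lower = 0)
  N <- nrow(ne$XXT)
  A <- ne$XXT + diag(gamma, N)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    sol <- tryCatch(solve(A, t(ne$YXT)), error = function(e) NULL)
    if (is.null(sol))
      stop_invalid("normal equations are singular; use gamma > 0 to regularize")
    return(t(sol))
  }
  t(backsolve(R, backsolve(R, t(ne$YXT), transpose = TRUE)))
}

#' Gaussian importance of temporal-parameter values
#'
#' `exp(-(v - center)^2 / (2 width^2))`: records whose temporal parameter
#' (cycle duration, stance duration or stance proportion) lies near the
#' kernel centre get importance close to 1, distant records close to 0.
#' Every sample of a record shares the record's mean parameter value, so
#' the importance is constant within a record.
#'
#' @param values numeric vector of parameter values.
#' @param center kernel centre, in the parameter's units.
#' @param width Gaussian standard deviation (> 0); `Inf` gives unit weights.
#' @return weights in (0, 1].
#' @export
kernel_importance <- function(values, center, width) {
  if (!is.numeric(width) || length(width) != 1L || is.na(width) || width <= 0)
    stop_invalid("'width' must be a positive number")
  exp(-(values - center)^2 / (2 * width^2))
}

#' Train a single readout by standard ridge regression
#'
#' One output-weight matrix over all records, with unit sample weights.
#'
#' @param states,targets lists of per-record state / target matrices.
#' @param gamma ridge regularization.
#' @return object of class `esn_readout` (mode `"standard"`).
#' @export
train_standard <- function(states, targets, gamma = 1e-6) {
  if (length(states) < 1L) stop_invalid("empty training set")
  ne <- accumulate_normal_equations(states, targets)
  structure(list(mode = "standard",
                 W_out = solve_ridge(ne, gamma),
                 gamma = gamma, n_records = length(states),
                 n_samples = ne$n_samples),
            class = "esn_readout")
}

#' Train a bank of kernel-specialized readouts
#'
#' Fits one ridge readout per kernel centre, weighting each training record
#' by the Gaussian importance of its temporal-parameter value
#' ([kernel_importance()]).  Centres default to an equally spaced grid over
#' the 5th–95th percentile range of the observed parameter values, with
#' width half the centre spacing, so the bank spans the range seen in
#' training.  A centre whose total importance underflows to zero is marked
#' unusable.
#'
#' @param states,targets lists of per-record state / target matrices.
#' @param record_params numeric vector, one temporal-parameter value per
#'   record (the record mean).
#' @param variable which parameter the bank is specialized on
#'   (`"cycle_duration"`, `"stance_proportion"` or `"stance_duration"`).
#' @param centers optional strictly increasing centre values.
#' @param width optional Gaussian width; `Inf` reduces every readout to the
#'   standard solution.
#' @param gamma ridge regularization.
#' @param n_centers number of centres when `centers` is `NULL`.
#' @return object of class `esn_kernel_bank`.
#' @export
train_kernel <- function(states, targets, record_params,
                         variable = c("cycle_duration", "stance_proportion",
                                      "stance_duration"),
                         centers = NULL, width = NULL, gamma = 1e-6,
                         n_centers = 5L) {
  variable <- match.arg(variable)
  if (length(record_params) != length(states))
    stop_invalid("need one temporal-parameter value per training record")
  if (is.null(centers)) {
    rng <- stats::quantile(record_params, c(0.05, 0.95), names = FALSE)
    if (diff(rng) <= 0) rng <- range(record_params) + c(-1e-6, 1e-6)
    centers <- seq(rng[1], rng[2], length.out = max(2L, n_centers))
  }
  if (length(centers) < 2L) stop_invalid("need at least 2 kernel centres")
  if (any(diff(centers) <= 0))
    stop_invalid("centers must be strictly increasing")
  if (is.null(width)) width <- diff(centers[1:2]) / 2
  readouts <- vector("list", length(centers))
  usable <- logical(length(centers))
  for (k in seq_along(centers)) {
    imp <- kernel_importance(record_params, centers[k], width)
    w <- lapply(seq_along(states),
                function(p) rep(imp[p], ncol(states[[p]])))
    ne <- accumulate_normal_equations(states, targets, w)
    if (ne$total_weight <= .Machine$double.xmin * ne$n_samples) {
      warning(sprintf("kernel centre %g has no effective training weight; readout marked unusable",
                      centers[k]))
      usable[k] <- FALSE
    } else {
      readouts[[k]] <- solve_ridge(ne, gamma)
      usable[k] <- TRUE
    }
  }
  structure(list(mode = "kernel", variable = variable, centers = centers,
                 width = width, readouts = readouts, usable = usable,
                 gamma = gamma, n_records = length(states)),
            class = "esn_kernel_bank")
}

#' Select the kernel readout nearest a record's temporal parameter
#'
#' Hard nearest-centre selection; midpoint ties resolve to the lower
#' centre, and parameters outside the centre range take the nearest
#' extreme centre.
#'
#' @param bank an `esn_kernel_bank`.
#' @param record_parameter finite parameter value of the record to predict.
#' @return the selected N_out x N readout matrix, with attribute `"center"`.
#' @export
select_kernel <- function(bank, record_parameter) {
  stopifnot(inherits(bank, "esn_kernel_bank"))
  if (!is.finite(record_parameter))
    stop_invalid("record_parameter must be finite")
  if (!any(bank$usable))
    stop_invalid("all kernel readouts are degenerate; no usable readout")
  ok <- which(bank$usable)
  d <- abs(bank$centers[ok] - record_parameter)
  sel <- ok[which.min(d)]  # first minimum = lower centre on ties
  structure(bank$readouts[[sel]], center = bank$centers[sel])
}

#' @export
print.esn_readout <- function(x, ...) {
  cat(sprintf("<esn_readout: standard, %d x %d, gamma %g, %d records>\n",
              nrow(x$W_out), ncol(x$W_out), x$gamma, x$n_records))
  invisible(x)
}

#' @export
print.esn_kernel_bank <- function(x, ...) {
  cat(sprintf("<esn_kernel_bank: %s, %d centres in [%.3g, %.3g], width %.3g>\n",
              x$variable, length(x$centers), min(x$centers), max(x$centers),
              x$width))
  invisible(x)
}
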