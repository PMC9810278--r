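#' Default ring-network kernel parameters
#'
#' Connectivity, nonlinearity, noise, and feedforward parameters for the
#' stochastic stabilized supralinear ring. Each of the four connection
#' blocks (E->E, I->E as `EI`, E->I as `IE`, I->I) has a kernel amplitude
#' `J` (magnitude; inhibitory signs are applied internally) and a Gaussian
#' width in degrees of preferred-orientation difference. The firing-rate
#' nonlinearity is `r = k * max(u, 0)^m`. Process noise is an
#' Ornstein-Uhlenbeck input with a ring-kernel spatial covariance.
#'
#' @param ... named overrides of any default element.
#' @return list of parameters accepted by [build_ring()].
#' @export
ring_defaults <- function(...) {
  p <- list(
    J = c(EE = 1.65, EI = 0.75, IE = 2.50, II = 0.90),
    width = c(EE = 30, EI = 75, IE = 30, II = 75),
    tau_E = 20, tau_I = 10,       # ms
    k = 0.3, m = 2,
    noise = list(sd_E = 1.6, sd_I = 1.6, width = 60, shared = 0.5,
                 tau_ms = 5),
    ff = list(gain_E = 0.15, gain_I = 0.026, baseline_E = 1.6, baseline_I = 1.3)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% c("J", "width") && !is.null(names(dots[[nm]]))) {
      p[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else if (nm %in% c("noise", "ff") && is.list(dots[[nm]])) {
      p[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      p[[nm]] <- dots[[nm]]
    }
  }
  p
}

#' Build a stochastic E-I ring network
#'
#' Constructs `n_pairs` excitatory-inhibitory pairs arranged on a ring of
#' preferred orientations uniformly spaced on \[-90, 90). Recurrent weights
#' decay smoothly with the wrapped orientation difference between neurons;
#' every block is a circulant matrix, so the whole network is rotation
#' symmetric. Columns obey Dale's principle: excitatory (first `n_pairs`)
#' columns are nonnegative, inhibitory columns nonpositive.
#'
#' @param n_pairs number of E-I pairs (>= 4).
#' @param params parameter list from [ring_defaults()].
#' @param ff_filters optional pixels x n_pairs matrix of feedforward filters
#'   (one per pair, e.g. the observer's Gabor bank); needed by
#'   [feedforward_input()].
#' @return an object of class `ring_network`.
#' @export
build_ring <- function(n_pairs, params = ring_defaults(), ff_filters = NULL) {
  stopifnot(n_pairs >= 4)
  J <- params$J; width <- params$width
  blocks <- c("EE", "EI", "IE", "II")
  if (!all(blocks %in% names(J)) || !all(blocks %in% names(width)))
    stop("params$J and params$width need entries EE, EI, IE, II")
  if (any(J < 0))
    stop("kernel amplitudes are magnitudes and must be >= 0 ",
         "(signs are applied by block; negative J would violate Dale's principle)")
  if (any(width <= 0)) stop("kernel widths must be positive")
  if (params$m < 1) stop("rate exponent m must be >= 1")
  if (params$k <= 0 || params$tau_E <= 0 || params$tau_I <= 0)
    stop("k and time constants must be positive")

  orientations <- seq(-90, 90, length.out = n_pairs + 1)[seq_len(n_pairs)]
  # row-normalized circulant kernels: J is the summed synaptic weight a
  # neuron receives from a whole block, independent of n_pairs
  K <- lapply(blocks, function(b) {
    Kb <- ring_kernel_matrix(orientations, width[[b]])
    Kb / sum(Kb[1, ])
  })
  names(K) <- blocks
  W <- rbind(
    cbind(J[["EE"]] * K$EE, -J[["EI"]] * K$EI),
    cbind(J[["IE"]] * K$IE, -J[["II"]] * K$II)
  )

  ns <- params$noise
  corr <- ns$shared * kronecker(matrix(1, 2, 2),
                                ring_kernel_matrix(orientations, ns$width)) +
    (1 - ns$shared) * diag(2 * n_pairs)
  sd_vec <- c(rep(ns$sd_E, n_pairs), rep(ns$sd_I, n_pairs))
  Sigma <- diag(sd_vec) %*% corr %*% diag(sd_vec) +
    1e-9 * diag(2 * n_pairs)
  L <- t(chol(Sigma))

  W_ff <- NULL
  if (!is.null(ff_filters)) {
    stopifnot(ncol(ff_filters) == n_pairs)
    W_ff <- rbind(params$ff$gain_E * t(ff_filters),
                  params$ff$gain_I * t(ff_filters))
  }

  net <- list(
    n_pairs = n_pairs,
    orientations = orientations,
    W = W,
    tau = c(rep(params$tau_E, n_pairs), rep(params$tau_I, n_pairs)),
    k = params$k, m = params$m,
    noise = list(Sigma = Sigma, L = L, tau_ms = ns$tau_ms),
    W_ff = W_ff,
    ff = params$ff,
    params = params
  )
  class(net) <- "ring_network"
  dale_check(net$W, n_pairs)
  net
}

# Dale's principle: E columns >= 0, I columns <= 0 (exactly).
dale_check <- function(W, n_pairs) {
  nE <- seq_len(n_pairs)
  if (any(W[, nE] < 0) || any(W[, n_pairs + nE] > 0))
    stop("Dale's principle violated in W")
  invisible(TRUE)
}

#' @export
print.ring_network <- function(x, ...) {
  cat("ring_network:", x$n_pairs, "E-I pairs (", 2 * x$n_pairs, "neurons )\n")
  cat("  r = k*max(u,0)^m with k =", x$k, ", m =", x$m, "\n")
  cat("  tau_E =", x$tau[1], "ms, tau_I =", x$tau[x$n_pairs + 1], "ms\n")
  cat("  OU noise: tau =", x$noise$tau_ms, "ms\n")
  invisible(x)
}

#' Feedforward drive for an image patch
#'
#' Applies the linear feedforward filter bank to the patch and passes the
#' result through a rectifying nonlinearity on top of a constant baseline:
#' `h = baseline + max(W_ff %*% patch, 0)`. The drive is constant over a
#' trial.
#'
#' @param net `ring_network` built with `ff_filters`.
#' @param patch pixel vector.
#' @return length-`2 n_pairs` drive vector (E cells first).
#' @export
feedforward_input <- function(net, patch) {
  if (is.null(net$W_ff)) stop("network was built without feedforward filters")
  patch <- as.numeric(patch)
  if (length(patch) != ncol(net$W_ff))
    stop("patch length ", length(patch), " does not match feedforward filters (",
         ncol(net$W_ff), " pixels)")
  base <- c(rep(net$ff$baseline_E, net$n_pairs),
            rep(net$ff$baseline_I, net$n_pairs))
  base + pmax(drop(net$W_ff %*% patch), 0)
}

#' Baseline (zero-stimulus) drive
#' @param net `ring_network`.
#' @return the drive vector for a blank (zero-contrast) stimulus.
#' @export
baseline_input <- function(net) {
  c(rep(net$ff$baseline_E, net$n_pairs), rep(net$ff$baseline_I, net$n_pairs))
}

#' Simulate the stochastic ring network
#'
#' Euler-Maruyama integration of
#' `tau_i du_i = (-u_i + h_i + sum_j W_ij r_j + eta_i) dt`
#' with `r = k * max(u, 0)^m` and `eta` an Ornstein-Uhlenbeck input with the
#' network's spatial covariance and correlation time. Results are thinned to
#' `record_every` ms. Bit-reproducible for fixed `(parameters, seed, dt)`.
#'
#' @param net `ring_network`.
#' @param h drive vector (length `2 n_pairs`), or a patch via
#'   [feedforward_input()] beforehand.
#' @param duration total simulated time, ms.
#' @param dt integration step, ms; must satisfy `dt <= min(tau)/10`.
#' @param seed integer RNG seed.
#' @param record_every recording interval, ms (multiple of `dt`).
#' @param u0 initial potentials (default 0).
#' @param noise logical; `FALSE` integrates the deterministic drift.
#' @param h_pre optional pre-onset drive for onset protocols.
#' @param onset_ms optional per-neuron onset times (ms) at which the drive
#'   switches from `h_pre` to `h`.
#' @param stimulus_id optional identifier stored in the trajectory.
#' @param rectify if `FALSE`, use the unrectified linear rate `r = k u`
#'   (only meaningful with `m = 1`; used for linear-regime checks).
#' @return object of class `trajectory` with fields `t`, `u`, `r` (time x
#'   neurons), `dt`, `seed`, `stimulus_id`.
#' @export
simulate_ring <- function(net, h, duration, dt = 0.2, seed = 1,
                          record_every = 1, u0 = NULL, noise = TRUE,
                          h_pre = NULL, onset_ms = NULL, stimulus_id = NA,
                          rectify = TRUE) {
  n <- 2 * net$n_pairs
  stopifnot(length(h) == n, duration > 0)
  if (dt > min(net$tau) / 10 + 1e-12)
    stop("dt must be <= min(tau)/10 for a faithful integration")
  rec_steps <- round(record_every / dt)
  if (abs(rec_steps * dt - record_every) > 1e-9)
    stop("record_every must be a multiple of dt")
  n_steps <- round(duration / dt)
  if (is.null(u0)) u0 <- rep(0, n)

  onset_step <- rep(0L, n)
  h0 <- h
  if (!is.null(onset_ms)) {
    stopifnot(!is.null(h_pre), length(h_pre) == n, length(onset_ms) == n)
    onset_step <- as.integer(round(onset_ms / dt))
    h0 <- h_pre
  }

  set.seed(seed)
  eta0 <- if (noise) drop(net$noise$L %*% stats::rnorm(n)) else rep(0, n)
  if (!rectify && net$m != 1)
    stop("rectify = FALSE is only supported for m = 1")
  out <- .simulate_cpp(net$W, h0, h, onset_step, net$tau, net$k, net$m,
                       rectify, net$noise$L, net$noise$tau_ms, noise,
                       dt, n_steps, rec_steps, u0, eta0)
  traj <- list(t = drop(out$t), u = out$u, r = out$r,
               dt = record_every, dt_int = dt, seed = seed,
               stimulus_id = stimulus_id, n_pairs = net$n_pairs,
               onset_ms = onset_ms)
  class(traj) <- "trajectory"
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", nrow(x$u), "samples x", ncol(x$u), "neurons, dt_rec =",
      x$dt, "ms, seed =", x$seed, "\n")
  invisible(x)
}

#' Deterministic fixed point of the network drift
#'
#' Newton iteration with step halving on the residual
#' `g(u) = -u + h + W r(u)`; the returned state satisfies
#' `max|g(u*)| < tol`.
#'
#' @param net `ring_network`.
#' @param h drive vector.
#' @param u0 initial guess (default 0).
#' @param tol residual tolerance (default 1e-10).
#' @param maxit maximum Newton iterations.
#' @return fixed-point state `u*` with attribute `"residual"`.
#' @export
fixed_point <- function(net, h, u0 = NULL, tol = 1e-10, maxit = 200) {
  n <- 2 * net$n_pairs
  u <- if (is.null(u0)) rep(0, n) else u0
  g <- function(u) -u + h + drop(net$W %*% (net$k * pmax(u, 0)^net$m))
  # damped-Euler warm start pulls the iterate into the Newton basin
  if (is.null(u0)) {
    for (i in seq_len(4000)) {
      gu <- g(u)
      u <- u + 0.1 * gu
      if (!all(is.finite(u))) stop("drift diverged during fixed-point search")
      if (max(abs(gu)) < 1e-6) break
    }
  }
  gv <- g(u)
  for (it in seq_len(maxit)) {
    if (max(abs(gv)) < tol) break
    rp <- net$k * net$m * pmax(u, 0)^(net$m - 1)
    Jg <- -diag(n) + net$W %*% (diag(rp, n))
    step <- tryCatch(solve(Jg, -gv), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in fixed_point")
    lambda <- 1
    repeat {
      u_new <- u + lambda * step
      g_new <- g(u_new)
      if (max(abs(g_new)) < max(abs(gv)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    u <- u_new; gv <- g_new
  }
  if (max(abs(gv)) >= tol)
    stop(sprintf("fixed_point did not converge: residual %.3e", max(abs(gv))))
  attr(u, "residual") <- max(abs(gv))
  u
}

#' Jacobian of the deterministic dynamics at a state
#'
#' Returns `diag(1/tau) %*% (-I + W diag(r'(u)))`; eigenvalues with negative
#' real part indicate local stability.
#'
#' @param net `ring_network`.
#' @param u state at which to linearize.
#' @return `2 n_pairs` square matrix (units 1/ms).
#' @export
ring_jacobian <- function(net, u) {
  n <- 2 * net$n_pairs
  rp <- net$k * net$m * pmax(u, 0)^(net$m - 1)
  diag(1 / net$tau) %*% (-diag(n) + net$W %*% diag(rp, n))
}

#' Serialize a ring network to JSON
#' @param net `ring_network`.
#' @param path output file.
#' @export
write_ring <- function(net, path) {
  params <- net$params
  params$J <- as.list(params$J)          # keep names through JSON
  params$width <- as.list(params$width)
  obj <- list(n_pairs = net$n_pairs, params = params,
              W = net$W, W_ff = net$W_ff)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a ring network from JSON written by [write_ring()]
#' @param path input file.
#' @return `ring_network`.
#' @export
read_ring <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- obj$params
  params$J <- unlist(params$J); params$width <- unlist(params$width)
  ff_filters <- NULL
  if (!is.null(obj$W_ff) && length(obj$W_ff)) {
    Wff <- as.matrix(obj$W_ff)
    ff_filters <- t(Wff[seq_len(obj$n_pairs), , drop = FALSE]) / params$ff$gain_E
  }
  net <- build_ring(obj$n_pairs, params, ff_filters = ff_filters)
  # stored W is authoritative (it may carry deficit scalings)
  net$W <- as.matrix(obj$W)
  dimnames(net$W) <- NULL
  dale_check(net$W, net$n_pairs)
  net
}
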