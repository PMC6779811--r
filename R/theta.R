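#' Parameters of the theta-model network simulation
#'
#' The dynamics of node `j` follow the canonical theta model,
#' `dtheta_j = (1 - cos theta_j) + (1 + cos theta_j) * I_j(t)`, where the
#' input `I_j = I_o + xi_j + (K/N) * sum_i a_ij * (1 - cos(theta_i - theta_s))`
#' combines a mean drive `I_o`, white Gaussian noise `xi_j` and diffusive
#' network coupling scaled by the global factor `K`. With `I_o < 0` each node
#' has a stable resting phase and an unstable (saddle) phase; noise and input
#' can push the phase over the saddle into a full rotation, the model's
#' seizure-like event (SNIC excitability). Integration is Euler-Maruyama with
#' step `dt`; the noise standard deviation is interpreted as the intensity of
#' the driving white noise, so each increment carries `noise_sd * sqrt(dt)`.
#'
#' @param i_o mean input current (default -1.2; must be below the SNIC point
#'   for a resting state to exist).
#' @param noise_sd standard deviation of the Gaussian input noise
#'   (default 0.6).
#' @param k global coupling scale `K` (>= 0).
#' @param dt integration step in dimensionless time (default 0.01).
#' @param n_steps number of integration steps (default 4e6, the full-fidelity
#'   setting; searches use far fewer, see the vignette).
#' @param seed integer master seed for the noise streams.
#' @param n_realizations number of independent noise realizations averaged
#'   when estimating seizure fractions.
#' @return a list of class `theta_params`.
#' @export
theta_params <- function(i_o = -1.2, noise_sd = 0.6, k = 0, dt = 0.01,
                         n_steps = 4e6, seed = 1L, n_realizations = 1L) {
  stopifnot(dt > 0, n_steps >= 1, noise_sd >= 0, k >= 0, n_realizations >= 1)
  if (!is.finite(i_o)) stop("i_o must be finite")
  structure(list(i_o = i_o, noise_sd = noise_sd, k = k, dt = dt,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 n_realizations = as.integer(n_realizations)),
            class = "theta_params")
}

#' Fixed points of the uncoupled theta neuron
#'
#' Solves `(1 - cos theta) + (1 + cos theta) * i = 0`, i.e.
#' `cos theta = (1 + i) / (1 - i)`. For `i < 0` this yields a stable resting
#' phase `theta_s = -theta_u` and an unstable saddle `theta_u` in `(0, pi]`;
#' for `i > 0` no fixed point exists and the phase rotates perpetually.
#'
#' @param i input current; `i = 1` is degenerate and rejected.
#' @return a list with `theta_stable`, `theta_unstable`, `exists`.
#' @export
#' @examples
#' fixed_points(-1.2)
fixed_points <- function(i) {
  stopifnot(is.numeric(i), length(i) == 1L, is.finite(i))
  if (i == 1) stop("i = 1 is degenerate: (1 + i)/(1 - i) is undefined")
  cstar <- (1 + i) / (1 - i)
  if (abs(cstar) > 1) {
    return(list(theta_stable = NA_real_, theta_unstable = NA_real_,
                exists = FALSE))
  }
  tu <- acos(cstar)
  list(theta_stable = -tu, theta_unstable = tu, exists = TRUE)
}

#' Classifier configuration for epileptiform activity
#'
#' `saddle_crossing` (default) flags a node as epileptiform from the moment
#' its phase crosses the unstable fixed point in the increasing direction
#' until it next crosses the stable fixed point in the increasing direction
#' (wrap-aware), i.e. while a seizure-like rotation is in progress.
#' `amplitude_threshold` instead smooths the phase distance from rest,
#' `1 - cos(theta - theta_s)` (zero at the resting phase, near 2 at the
#' antipode), with a moving average and flags samples above a threshold;
#' with a window spanning most of a rotation it flags sustained spiking
#' continuously.
#'
#' @param method `"saddle_crossing"` or `"amplitude_threshold"`.
#' @param amp_threshold threshold on the smoothed amplitude, in `(0, 2)`.
#' @param smooth_window moving-average window in steps (>= 1).
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(method = c("saddle_crossing", "amplitude_threshold"),
                              amp_threshold = 0.9, smooth_window = 100L) {
  method <- match.arg(method)
  stopifnot(smooth_window >= 1, amp_threshold > 0, amp_threshold < 2)
  structure(list(method = method, amp_threshold = amp_threshold,
                 smooth_window = as.integer(smooth_window)),
            class = "classifier_config")
}

# Noise increment matrix (n_steps x n) for one realization; full Euler-
# Maruyama increments sigma * sqrt(dt) * eta.
make_noise_matrix <- function(params, n, realization = 1L) {
  with_seed(derive_seed(params$seed, "theta-noise", realization), {
    matrix(rnorm(params$n_steps * n, 0, params$noise_sd * sqrt(params$dt)),
           params$n_steps, n)
  })
}

#' Simulate the theta model on a network
#'
#' Advances all node phases with Euler-Maruyama, starting from the stable
#' fixed point, and returns the fraction of simulated time each node spends
#' in epileptiform dynamics according to the chosen classifier. With
#' `n_realizations > 1`, independent noise realizations (sub-seeded from
#' `params$seed`) are run and the per-node fractions averaged.
#'
#' @param net an `icto_network`.
#' @param params a [theta_params()].
#' @param classifier a [classifier_config()].
#' @param noise optional list of noise matrices (one per realization, each
#'   `n_steps x N`), overriding internal generation; used for common-random-
#'   number comparisons.
#' @param return_trace keep the full phase traces (memory-heavy; intended for
#'   small runs).
#' @return a list of class `simulation_result` with `seizure_fraction`
#'   (per-node, averaged over realizations), `per_realization` (matrix
#'   `n_realizations x N`), `params`, `flagged` (TRUE when no resting state
#'   exists for `i_o`) and optionally `traces`.
#' @export
simulate_theta <- function(net, params, classifier = classifier_config(),
                           noise = NULL, return_trace = FALSE) {
  validate_network(net)
  stopifnot(inherits(params, "theta_params"),
            inherits(classifier, "classifier_config"))
  n <- n_nodes(net)
  fp <- fixed_points(params$i_o)
  flagged <- !fp$exists
  if (flagged) {
    warning("no resting fixed point exists for i_o = ", params$i_o,
            "; every node oscillates and the run is flagged")
    # SNIC remnant: both fixed points collapse onto phase 0
    fp$theta_stable <- 0
    fp$theta_unstable <- 0
  }
  if (!is.null(noise)) {
    stopifnot(is.list(noise), length(noise) == params$n_realizations)
  }
  need_trace <- return_trace || classifier$method == "amplitude_threshold"
  theta0 <- rep(fp$theta_stable, n)
  per_real <- matrix(NA_real_, params$n_realizations, n)
  traces <- if (return_trace) vector("list", params$n_realizations)
  for (r in seq_len(params$n_realizations)) {
    nm <- if (is.null(noise)) make_noise_matrix(params, n, r) else noise[[r]]
    res <- .theta_sim_core(net$weights, params$k, params$i_o, params$dt,
                           params$n_steps, fp$theta_stable, fp$theta_unstable,
                           nm, seq_len(n), n, theta0, need_trace)
    frac <- if (classifier$method == "amplitude_threshold") {
      apply(res$trace, 2, function(tr)
        mean(classify_epileptiform(tr, params$i_o, classifier)))
    } else if (flagged) {
      rep(1, n)
    } else {
      res$seizure_fraction
    }
    per_real[r, ] <- frac
    if (return_trace) traces[[r]] <- res$trace
  }
  out <- list(seizure_fraction = colMeans(per_real), per_realization = per_real,
              params = params, classifier = classifier, flagged = flagged)
  if (return_trace) out$traces <- traces
  structure(out, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d nodes, K = %g, %d steps x %d realization(s)\n",
    length(x$seizure_fraction), x$params$k, x$params$n_steps,
    x$params$n_realizations))
  cat(sprintf("  mean seizure fraction: %.4f\n", mean(x$seizure_fraction)))
  invisible(x)
}

#' Classify a phase trace into normal vs epileptiform samples
#'
#' Reference implementation of the per-sample classifier on a single-node
#' phase trace (see [classifier_config()] for the two rules). Used standalone
#' on stored traces; full simulations classify on the fly.
#'
#' @param trace numeric vector of phases, wrapped to `(-pi, pi]`.
#' @param i_o the input current the trace was generated with (determines the
#'   fixed points).
#' @param classifier a [classifier_config()].
#' @return a logical vector, `TRUE` for epileptiform samples.
#' @export
classify_epileptiform <- function(trace, i_o,
                                  classifier = classifier_config()) {
  stopifnot(is.numeric(trace), inherits(classifier, "classifier_config"))
  fp <- fixed_points(i_o)
  if (!fp$exists) {
    warning("no resting fixed point for i_o = ", i_o,
            "; whole trace classified epileptiform")
    return(rep(TRUE, length(trace)))
  }
  if (classifier$method == "amplitude_threshold") {
    amp <- 1 - cos(trace - fp$theta_stable)
    k <- min(classifier$smooth_window, length(trace))
    sm <- as.numeric(stats::filter(amp, rep(1 / k, k), sides = 1))
    sm[seq_len(min(k - 1, length(sm)))] <- cumsum(amp[seq_len(min(k - 1, length(amp)))]) /
      seq_len(min(k - 1, length(amp)))
    return(sm > classifier$amp_threshold)
  }
  ts <- fp$theta_stable
  tu <- fp$theta_unstable
  state <- FALSE
  out <- logical(length(trace))
  prev <- trace[1]
  # wrap-aware upward-crossing test between consecutive wrapped samples
  crossed_up <- function(a, b, target) {
    d <- b - a
    if (d <= -pi) d <- d + 2 * pi else if (d > pi) d <- d - 2 * pi
    if (d <= 0) return(FALSE)
    t1 <- if (target <= a) target + 2 * pi else target
    a + d >= t1
  }
  for (i in seq_along(trace)) {
    if (i > 1L) {
      cur <- trace[i]
      if (state && crossed_up(prev, cur, ts)) state <- FALSE
      if (!state && crossed_up(prev, cur, tu)) state <- TRUE
      prev <- cur
    }
    out[i] <- state
  }
  out
}
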