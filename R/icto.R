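#' SI/BNI evaluator with common random numbers
#'
#' Builds a closure environment that evaluates the Brain Network Ictogenicity
#' of the unperturbed network and of arbitrary node-set removals, reusing one
#' fixed set of noise realizations (common random numbers) and caching
#' results by set identity. All search strategies draw their SI values from
#' one evaluator so comparisons between sets are paired and reproducible.
#'
#' Two exact shortcuts keep large searches tractable: removed nodes receive
#' no coupling, so their trajectories equal the isolated (K = 0) trajectories
#' under the same noise and are simulated once per realization; and only the
#' surviving subnetwork is integrated for each set, with the coupling still
#' normalized by the full network size.
#'
#' @param net an `icto_network`.
#' @param params a [theta_params()] carrying `k` (usually the calibrated
#'   value), `n_steps`, `seed` and `n_realizations`.
#' @return an environment with functions `bni_ref()`, `bni(x)`, `si(x)`,
#'   `n_evaluations()`, `cache_size()`; see Details.
#' @details
#' `bni(x)` returns the per-realization BNI values of the network with set
#' `x` removed (at the evaluator's `K`); `si(x)` returns an `si_result`.
#' `n_evaluations()` counts distinct simulated sets (cache misses).
#' @param crn optional precomputed common-random-number state from
#'   `make_crn_state()`; lets several evaluators (e.g. across a K bisection)
#'   share noise matrices and the K-independent isolated baselines.
#' @export
make_si_evaluator <- function(net, params, crn = NULL) {
  validate_network(net)
  stopifnot(inherits(params, "theta_params"))
  n <- n_nodes(net)
  fp <- fixed_points(params$i_o)
  if (!fp$exists)
    stop("no resting fixed point for i_o = ", params$i_o,
         "; BNI/SI are not defined in the perpetually oscillating regime")
  nreal <- params$n_realizations
  if (is.null(crn)) crn <- make_crn_state(params, n)
  stopifnot(crn$n == n, crn$n_steps == params$n_steps,
            crn$n_realizations == nreal)
  noise <- crn$noise
  iso <- crn$iso
  theta0 <- rep(fp$theta_stable, n)

  cache <- new.env(parent = emptyenv())
  misses <- 0L

  bni_of_set <- function(x) {
    x <- check_node_set(x, n)
    key <- paste0("s", paste(x, collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    keep <- setdiff(seq_len(n), x)
    vals <- vapply(seq_len(nreal), function(r) {
      frac_kept <- if (length(keep)) {
        .theta_sim_core(net$weights[keep, keep, drop = FALSE], params$k,
                        params$i_o, params$dt, params$n_steps,
                        fp$theta_stable, fp$theta_unstable, noise[[r]],
                        keep, n, theta0[keep], FALSE)$seizure_fraction
      } else numeric(0)
      (sum(frac_kept) + sum(iso[x, r])) / n
    }, numeric(1))
    cache[[key]] <- vals
    misses <<- misses + 1L
    vals
  }

  ref <- bni_of_set(integer(0))

  ev <- new.env(parent = emptyenv())
  ev$net <- net
  ev$params <- params
  ev$bni <- bni_of_set
  ev$bni_ref <- function() ref
  ev$si <- function(x) {
    x <- check_node_set(x, n)
    pert <- bni_of_set(x)
    per_real <- ifelse(ref > 0, (ref - pert) / ref, 0)
    raw <- mean(per_real)
    structure(list(x = x, si = max(0, raw), raw_si = raw,
                   bni_ref = mean(ref), bni_perturbed = mean(pert),
                   per_realization_si = per_real, k_used = params$k,
                   n_steps = params$n_steps, seed = params$seed,
                   n_realizations = nreal),
              class = "si_result")
  }
  ev$n_evaluations <- function() misses
  ev$cache_size <- function() length(ls(cache))
  class(ev) <- "si_evaluator"
  ev
}

# Common-random-number state shared across evaluators: the per-realization
# noise matrices and the K-independent isolated-node seizure fractions.
make_crn_state <- function(params, n) {
  fp <- fixed_points(params$i_o)
  stopifnot(fp$exists)
  nreal <- params$n_realizations
  noise <- lapply(seq_len(nreal), function(r) make_noise_matrix(params, n, r))
  theta0 <- rep(fp$theta_stable, n)
  iso <- vapply(seq_len(nreal), function(r) {
    .theta_sim_core(matrix(0, n, n), 0, params$i_o, params$dt, params$n_steps,
                    fp$theta_stable, fp$theta_unstable, noise[[r]],
                    seq_len(n), n, theta0, FALSE)$seizure_fraction
  }, numeric(n))
  list(noise = noise, iso = matrix(iso, nrow = n), n = n,
       n_steps = params$n_steps, n_realizations = nreal)
}

#' @export
print.si_evaluator <- function(x, ...) {
  cat(sprintf("<si_evaluator> %d nodes, K = %g, %d steps x %d realizations, %d sets evaluated\n",
              n_nodes(x$net), x$params$k, x$params$n_steps,
              x$params$n_realizations, x$n_evaluations()))
  invisible(x)
}

#' @export
print.si_result <- function(x, ...) {
  cat(sprintf("<si_result> set {%s}: SI = %.4f (raw %.4f; BNI %.4f -> %.4f at K = %g)\n",
              paste(x$x, collapse = ","), x$si, x$raw_si, x$bni_ref,
              x$bni_perturbed, x$k_used))
  invisible(x)
}

#' Brain Network Ictogenicity
#'
#' BNI is the mean over nodes of the fraction of simulation time spent in
#' epileptiform dynamics, estimated by simulating the theta model and
#' averaging over independent noise realizations. It ranges from 0 (all nodes
#' always at rest) to 1 (all nodes seizing throughout).
#'
#' @param net an `icto_network`.
#' @param params a [theta_params()] (its `k` is the coupling used).
#' @param classifier a [classifier_config()].
#' @return a list of class `bni_result` with `bni`, `per_node_fractions`,
#'   `per_realization` (realization x node matrix), `k_used`, `n_steps`,
#'   `seeds`, `n_realizations`.
#' @export
compute_bni <- function(net, params, classifier = classifier_config()) {
  sim <- simulate_theta(net, params, classifier)
  structure(list(bni = mean(sim$seizure_fraction),
                 per_node_fractions = sim$seizure_fraction,
                 per_realization = sim$per_realization,
                 k_used = params$k, n_steps = params$n_steps,
                 seeds = vapply(seq_len(params$n_realizations), function(r)
                   derive_seed(params$seed, "theta-noise", r), integer(1)),
                 n_realizations = params$n_realizations),
            class = "bni_result")
}

#' @export
print.bni_result <- function(x, ...) {
  cat(sprintf("<bni_result> BNI = %.4f at K = %g (%d steps x %d realizations)\n",
              x$bni, x$k_used, x$n_steps, x$n_realizations))
  invisible(x)
}

#' Calibrate the global coupling to a reference BNI
#'
#' Tunes `K` by bisection so that the unperturbed network's BNI matches a
#' target (0.5 by default: the network spends half its time in epileptiform
#' dynamics, the reference operating point at which removal effects are most
#' visible). All BNI evaluations share one fixed noise-realization set
#' (common random numbers), making BNI(K) effectively deterministic and
#' monotone during the search. The bracket is found by doubling `K` from
#' `k_init` up to `k_max`; failure to bracket (e.g. an edgeless network,
#' whose BNI does not depend on K) is an error.
#'
#' @param net an `icto_network` with at least one edge.
#' @param params a [theta_params()]; its `k` is ignored.
#' @param target target BNI in (0, 1), default 0.5.
#' @param tol convergence tolerance on `|BNI - target|`, default 0.05.
#' @param k_init initial upper-bracket guess.
#' @param k_max cap on the bracket search.
#' @param max_iter maximum bisection iterations.
#' @param aim fraction of `tol` the bisection aims for before stopping
#'   (default 0.5): converging to the centre of the tolerance band leaves
#'   margin for re-estimation noise when the operating point is re-measured
#'   with fresh noise seeds. Success is still judged against `tol`.
#' @return a list of class `calibration_result` with `k_star`,
#'   `achieved_bni`, `target`, `tol`, `iterations`, `history` (a data.frame
#'   of the K values tried and their BNI), `converged`.
#' @export
calibrate_k <- function(net, params, target = 0.5, tol = 0.05,
                        k_init = 1, k_max = 2^20, max_iter = 60L,
                        aim = 0.5) {
  validate_network(net)
  stopifnot(target > 0, target < 1, tol > 0, aim > 0, aim <= 1)
  if (all(net$weights == 0))
    stop("calibration failure: network has no edges, BNI does not depend on K")
  history <- data.frame(k = numeric(0), bni = numeric(0))
  crn <- make_crn_state(params, n_nodes(net))
  eval_bni <- local({
    memo <- new.env(parent = emptyenv())
    function(k) {
      key <- format(k, digits = 17)
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
      p <- params
      p$k <- k
      ev <- make_si_evaluator(net, p, crn = crn)
      b <- mean(ev$bni_ref())
      memo[[key]] <- b
      history <<- rbind(history, data.frame(k = k, bni = b))
      b
    }
  })
  # bracket: BNI(0) is the uncoupled baseline; double K until BNI >= target
  lo <- 0
  b_lo <- eval_bni(lo)
  if (b_lo >= target) {
    return(structure(list(k_star = 0, achieved_bni = b_lo, target = target,
                          tol = tol, iterations = 0L, history = history,
                          converged = abs(b_lo - target) <= tol),
                     class = "calibration_result"))
  }
  hi <- k_init
  b_hi <- eval_bni(hi)
  while (b_hi < target && hi < k_max) {
    lo <- hi
    b_lo <- b_hi
    hi <- hi * 2
    b_hi <- eval_bni(hi)
  }
  if (b_hi < target)
    stop(sprintf(
      "calibration failure: BNI reaches only %.3f at K = %g (target %g)",
      b_hi, hi, target))
  iter <- 0L
  k_star <- hi
  achieved <- b_hi
  while (iter < max_iter && abs(achieved - target) > tol * aim &&
         (hi - lo) > 1e-6 * max(1, hi)) {
    mid <- (lo + hi) / 2
    b_mid <- eval_bni(mid)
    iter <- iter + 1L
    if (b_mid < target) {
      lo <- mid
    } else {
      hi <- mid
    }
    k_star <- mid
    achieved <- b_mid
  }
  if (abs(achieved - target) > tol) {
    # bisection exhausted: return the bracket endpoint closest to target
    cand <- history[which.min(abs(history$bni - target)), ]
    k_star <- cand$k
    achieved <- cand$bni
  }
  structure(list(k_star = k_star, achieved_bni = achieved, target = target,
                 tol = tol, iterations = iter, history = history,
                 converged = abs(achieved - target) <= tol),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> K* = %g, BNI = %.4f (target %g +/- %g, %d bisection steps)\n",
              x$k_star, x$achieved_bni, x$target, x$tol, x$iterations))
  invisible(x)
}

#' Set Ictogenicity
#'
#' SI of a node set `X` is the relative reduction in BNI caused by removing
#' `X`: `SI = (BNI0 - BNI_X) / BNI0`, computed at the calibrated coupling of
#' the *unperturbed* network (no recalibration after removal) and clamped at
#' zero, so `SI = 1` means the removal eliminated epileptiform dynamics and
#' `SI = 0` means it achieved nothing (or made things worse). SI is averaged
#' over noise realizations as the mean of per-realization SI values.
#'
#' @param net an `icto_network`.
#' @param x node set to remove (1-based indices; may be empty).
#' @param k_star calibrated coupling from [calibrate_k()].
#' @param params a [theta_params()]; its `k` is replaced by `k_star`.
#' @param evaluator optionally a prebuilt [make_si_evaluator()] (its `K`
#'   must already be `k_star`); reused for caching across calls.
#' @return an `si_result`: `x`, `si` (clamped), `raw_si`, `bni_ref`,
#'   `bni_perturbed`, `per_realization_si`, provenance fields.
#' @export
compute_si <- function(net, x, k_star, params, evaluator = NULL) {
  if (is.null(evaluator)) {
    params$k <- k_star
    evaluator <- make_si_evaluator(net, params)
  }
  evaluator$si(x)
}

#' Node Ictogenicity
#'
#' NI is the SI of each singleton set: the relative BNI reduction achieved by
#' removing one node alone.
#'
#' @inheritParams compute_si
#' @return numeric vector of length N with the NI of every node.
#' @export
node_ictogenicity <- function(net, k_star, params, evaluator = NULL) {
  if (is.null(evaluator)) {
    params$k <- k_star
    evaluator <- make_si_evaluator(net, params)
  }
  vapply(seq_len(n_nodes(evaluator$net)), function(j) evaluator$si(j)$si,
         numeric(1))
}
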