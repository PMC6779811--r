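#' Coupled multichannel signals from a known network
#'
#' Simulates the theta model on a network at a super-critical coupling and
#' emits the amplitude observable `1 - cos(theta)` per node plus independent
#' Gaussian sensor noise, one sample per integration step at the requested
#' rate. Connected node pairs carry elevated statistical dependence, so the
#' planted edges are recoverable by [surrogate_corrected_network()] — the
#' validation fixture for network inference.
#'
#' @param net an `icto_network`.
#' @param duration signal duration in seconds.
#' @param rate sampling rate in Hz.
#' @param noise_level standard deviation of the additive sensor noise on the
#'   amplitude observable (default 0.1).
#' @param k coupling; default `4 * N`, super-critical for the sparse binary
#'   topologies generated here.
#' @param seed integer seed.
#' @param params optionally a full [theta_params()] overriding the
#'   dynamics defaults (its `n_steps` is set from `duration * rate`).
#' @return an [recording()] at `rate` Hz.
#' @export
make_coupled_signals <- function(net, duration = 20, rate = 256,
                                 noise_level = 0.1, k = NULL, seed = 1L,
                                 params = NULL) {
  validate_network(net)
  stopifnot(duration > 0, rate > 0)
  n_samples <- round(duration * rate)
  if (n_samples < 100) stop("duration x rate must give at least 100 samples")
  if (is.null(k)) k <- 4 * n_nodes(net)
  if (is.null(params)) params <- theta_params()
  params$k <- k
  params$n_steps <- n_samples
  params$seed <- derive_seed(seed, "coupled-signals-dynamics")
  params$n_realizations <- 1L
  sim <- simulate_theta(net, params, return_trace = TRUE)
  amp <- 1 - cos(sim$traces[[1]]) # n_samples x N
  sensor <- with_seed(derive_seed(seed, "coupled-signals-sensor"), {
    matrix(rnorm(length(amp), 0, noise_level), nrow(amp), ncol(amp))
  })
  recording(t(amp + sensor), rate = rate, channel_labels = net$labels)
}

#' Synthetic cohort specification
#'
#' Shape of the emulated surgical cohort: 13 good-outcome (Engel I) and 7
#' poor-outcome (Engel IV) cases by default. Each case gets a network with a
#' planted ictogenic set — a dense mutually-coupled clique wired to drive
#' the rest of the network — plus a resection mask and outcome label: good
#' cases had the planted set resected, poor cases had at least half of it
#' missed.
#'
#' @param n_good,n_poor group sizes (defaults 13 and 7).
#' @param n_nodes nodes per case network.
#' @param planted_size size of the planted ictogenic clique.
#' @param resection_extra range (min, max) of additional non-planted nodes
#'   included in each resection.
#' @param w_in clique (within planted set) weight.
#' @param w_out weight of edges from planted nodes to the driven half of the
#'   remaining network.
#' @param w_background weight of the sparse background edges.
#' @param p_background background edge probability.
#' @param seed master seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_good = 13L, n_poor = 7L, n_nodes = 16L,
                        planted_size = 3L, resection_extra = c(1L, 3L),
                        w_in = 1.0, w_out = 0.6, w_background = 0.1,
                        p_background = 0.15, seed = 1L) {
  stopifnot(n_good >= 1, n_poor >= 1, n_nodes >= 6,
            planted_size >= 2, planted_size < n_nodes / 2,
            length(resection_extra) == 2,
            resection_extra[1] >= 0,
            resection_extra[2] >= resection_extra[1])
  structure(list(n_good = as.integer(n_good), n_poor = as.integer(n_poor),
                 n_nodes = as.integer(n_nodes),
                 planted_size = as.integer(planted_size),
                 resection_extra = as.integer(resection_extra),
                 w_in = w_in, w_out = w_out, w_background = w_background,
                 p_background = p_background, seed = as.integer(seed)),
            class = "cohort_spec")
}

# one cohort network: planted driver clique + directed drive + weak background
make_planted_network <- function(spec, seed) {
  with_seed(seed, {
    n <- spec$n_nodes
    w <- matrix(0, n, n)
    bg <- matrix(runif(n * n) < spec$p_background, n, n)
    w[bg] <- spec$w_background
    planted <- sort(sample.int(n, spec$planted_size))
    w[planted, planted] <- spec$w_in
    rest <- setdiff(seq_len(n), planted)
    driven <- sample(rest, ceiling(length(rest) / 2))
    w[planted, driven] <- spec$w_out
    diag(w) <- 0
    list(network = icto_network(w, directed = TRUE), planted = planted)
  })
}

#' Generate a synthetic surgical cohort
#'
#' Builds `n_good + n_poor` cases according to the cohort shape (see
#' [cohort_spec()]): good-outcome resections contain the whole planted
#' ictogenic set, poor-outcome resections miss at least half of it (the
#' missed count is drawn uniformly between `ceiling(size/2)` and `size`).
#' The planted set is recorded per case as ground truth.
#'
#' @param spec a [cohort_spec()].
#' @return a list of [patient_case()] objects with a `planted` field.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_cases <- spec$n_good + spec$n_poor
  outcomes <- c(rep("good", spec$n_good), rep("poor", spec$n_poor))
  lapply(seq_len(n_cases), function(i) {
    net_seed <- derive_seed(spec$seed, "cohort-network", i)
    pl <- make_planted_network(spec, net_seed)
    n <- spec$n_nodes
    pick1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)
    resected <- with_seed(derive_seed(spec$seed, "cohort-resection", i), {
      extra_n <- pick1(seq(spec$resection_extra[1], spec$resection_extra[2]))
      rest <- setdiff(seq_len(n), pl$planted)
      if (outcomes[i] == "good") {
        sort(c(pl$planted, sample(rest, extra_n)))
      } else {
        sz <- spec$planted_size
        n_missed <- pick1(seq(ceiling(sz / 2), sz))
        kept <- if (n_missed < sz) {
          sample(pl$planted, sz - n_missed)
        } else integer(0)
        sort(c(kept, sample(rest, extra_n + n_missed)))
      }
    })
    patient_case(id = sprintf("case%02d", i), network = pl$network,
                 resected = resected, outcome = outcomes[i],
                 planted = pl$planted)
  })
}
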