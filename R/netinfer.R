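#' Multichannel recording container
#'
#' Holds a channels x time sample matrix with its sampling rate, channel
#' labels and a bad-channel mask (channels excluded from re-referencing and
#' from the inferred network, e.g. because of permanent artifacts).
#'
#' @param samples numeric matrix, channels in rows, samples in columns.
#' @param rate sampling rate in Hz.
#' @param channel_labels optional labels (default `"ch1" ...`).
#' @param bad_channels logical mask (or integer indices) of excluded
#'   channels.
#' @return an object of class `icto_recording`.
#' @export
recording <- function(samples, rate, channel_labels = NULL,
                      bad_channels = NULL) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), rate > 0)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("recording samples must be finite")
  nc <- nrow(samples)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nc))
  stopifnot(length(channel_labels) == nc)
  bad <- rep(FALSE, nc)
  if (!is.null(bad_channels)) {
    if (is.logical(bad_channels)) {
      stopifnot(length(bad_channels) == nc)
      bad <- bad_channels
    } else {
      bad[check_node_set(bad_channels, nc)] <- TRUE
    }
  }
  structure(list(samples = samples, rate = rate,
                 channel_labels = as.character(channel_labels),
                 bad_channels = bad, preprocessed = FALSE),
            class = "icto_recording")
}

#' @export
print.icto_recording <- function(x, ...) {
  cat(sprintf("<icto_recording> %d channels x %d samples @ %g Hz (%d bad)%s\n",
              nrow(x$samples), ncol(x$samples), x$rate, sum(x$bad_channels),
              if (x$preprocessed) ", preprocessed" else ""))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Defaults follow standard clinical iEEG practice: anti-aliased
#' downsampling to 512 Hz, re-referencing each sample against the median of
#' the artifact-free channels, and a fourth-order Butterworth band-pass
#' between 0.5 and 150 Hz applied forward and backward (zero phase).
#'
#' @param target_rate output sampling rate in Hz.
#' @param band two-element band edges in Hz, inside `(0, target_rate/2)`.
#' @param filter_order Butterworth order (>= 1).
#' @return a list of class `preproc_config`.
#' @export
preproc_config <- function(target_rate = 512, band = c(0.5, 150),
                           filter_order = 4L) {
  stopifnot(target_rate > 0, length(band) == 2, band[1] > 0,
            band[2] > band[1], band[2] < target_rate / 2, filter_order >= 1)
  structure(list(target_rate = target_rate, band = band,
                 filter_order = as.integer(filter_order)),
            class = "preproc_config")
}

#' Preprocess a recording
#'
#' Downsample (polyphase resampling with anti-alias filtering) to the target
#' rate, subtract the per-sample median of the good channels from every
#' channel, and band-pass with a zero-phase (forward-backward) Butterworth
#' filter. The output length after resampling from rate `r` to rate `r'` is
#' `ceiling(n * r' / r)`.
#'
#' @param rec an [recording()].
#' @param config a [preproc_config()].
#' @return a preprocessed `icto_recording` at the target rate.
#' @export
preprocess_recording <- function(rec, config = preproc_config()) {
  stopifnot(inherits(rec, "icto_recording"), inherits(config, "preproc_config"))
  if (rec$rate < config$target_rate)
    stop(sprintf("recording rate (%g Hz) is below the target rate (%g Hz)",
                 rec$rate, config$target_rate))
  if (all(rec$bad_channels)) stop("all channels are marked bad")
  x <- rec$samples
  if (rec$rate > config$target_rate) {
    fr <- fractions_ratio(config$target_rate, rec$rate)
    x <- t(apply(x, 1, function(ch)
      signal::resample(ch, p = fr[1], q = fr[2])))
  }
  good <- !rec$bad_channels
  ref <- apply(x[good, , drop = FALSE], 2, median)
  x <- sweep(x, 2, ref, "-")
  bf <- signal::butter(config$filter_order,
                       config$band / (config$target_rate / 2), type = "pass")
  x <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  out <- rec
  out$samples <- x
  out$rate <- config$target_rate
  out$preprocessed <- TRUE
  out
}

# small integer ratio p/q == a/b
fractions_ratio <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  scale <- 1e6 # tolerate non-integer rates
  p <- round(a * scale)
  q <- round(b * scale)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Mutual-information configuration
#'
#' The estimator is the binned plug-in MI on per-channel equiquantile bins
#' (`n_bins = floor(sqrt(n/5))`, capped at 32, unless given), which makes
#' the estimate invariant under monotone rescaling of either channel. The
#' surrogate correction subtracts the 95th percentile of the MI values
#' obtained from circularly time-shifted copies of one channel (minimum
#' shift 5% of the window), clamping at zero, so only dependence in excess
#' of chance survives.
#'
#' @param n_bins number of bins per channel (`NULL` for the rule above).
#' @param n_surrogates number of surrogates (>= 19; default 99).
#' @param quantile_level null-distribution percentile subtracted.
#' @param min_shift_frac minimum circular shift as a fraction of the window.
#' @param seed seed for the surrogate shifts.
#' @return a list of class `mi_config`.
#' @export
mi_config <- function(n_bins = NULL, n_surrogates = 99L,
                      quantile_level = 0.95, min_shift_frac = 0.05,
                      seed = 1L) {
  stopifnot(is.null(n_bins) || n_bins >= 2, n_surrogates >= 19,
            quantile_level > 0, quantile_level < 1,
            min_shift_frac > 0, min_shift_frac < 0.5)
  structure(list(n_bins = n_bins, n_surrogates = as.integer(n_surrogates),
                 quantile_level = quantile_level,
                 min_shift_frac = min_shift_frac, seed = as.integer(seed)),
            class = "mi_config")
}

mi_bins_for <- function(n, config) {
  if (!is.null(config$n_bins)) return(as.integer(config$n_bins))
  max(2L, min(32L, floor(sqrt(n / 5))))
}

# equiquantile discretization into 1..n_bins (ties share a bin)
discretize_channel <- function(x, n_bins) {
  if (length(unique(x)) < 2) return(NULL)
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2) return(NULL)
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

mi_discrete <- function(dx, dy, nb) {
  tab <- tabulate(dx + nb * (dy - 1L), nbins = nb * nb)
  n <- length(dx)
  p <- tab[tab > 0] / n
  px <- tabulate(dx, nbins = nb) / n
  py <- tabulate(dy, nbins = nb) / n
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy <- -sum(p * log(p))
  max(0, hx + hy - hxy)
}

#' Plug-in mutual information between two signals
#'
#' Binned plug-in estimate of the mutual information in nats, on
#' equiquantile bins (see [mi_config()]). Symmetric in its arguments and
#' nonnegative; detects nonlinear dependence beyond linear correlation.
#' Constant channels carry no information and return 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (at least 100 samples).
#' @param config a [mi_config()].
#' @return MI estimate in nats.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(5000)
#' mutual_information(x, x) # about log(n_bins)
mutual_information <- function(x, y, config = mi_config()) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 100) stop("need at least 100 samples")
  nb <- mi_bins_for(length(x), config)
  dx <- discretize_channel(x, nb)
  dy <- discretize_channel(y, nb)
  if (is.null(dx) || is.null(dy)) {
    warning("constant input channel: MI = 0")
    return(0)
  }
  mi_discrete(dx, dy, nb)
}

#' Infer a functional network via surrogate-corrected mutual information
#'
#' For every pair of good channels, the edge weight is the plug-in MI of the
#' pair minus the 95th percentile of the MI values of `n_surrogates`
#' circularly time-shifted surrogates of the second channel, clamped at zero.
#' Circular shifting preserves each channel's sample distribution and
#' autocorrelation while destroying the cross-channel alignment, so the
#' subtracted quantile estimates the chance level of the estimator on these
#' exact signals. The result is an undirected, nonnegative, zero-diagonal
#' network over the good channels.
#'
#' @param rec a preprocessed [recording()].
#' @param config a [mi_config()].
#' @param window optional integer range `c(from, to)` of samples to use
#'   (default: the full segment).
#' @return an `icto_network` labelled by the good channels.
#' @export
surrogate_corrected_network <- function(rec, config = mi_config(),
                                        window = NULL) {
  stopifnot(inherits(rec, "icto_recording"), inherits(config, "mi_config"))
  x <- rec$samples
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] >= 1, window[2] <= ncol(x),
              window[1] < window[2])
    x <- x[, window[1]:window[2], drop = FALSE]
  }
  nsamp <- ncol(x)
  if (nsamp < 100) stop("analysis window shorter than 100 samples")
  good <- which(!rec$bad_channels)
  ng <- length(good)
  if (ng < 2) stop("need at least two good channels")
  nb <- mi_bins_for(nsamp, config)
  disc <- lapply(good, function(i) discretize_channel(x[i, ], nb))
  min_shift <- max(1L, floor(config$min_shift_frac * nsamp))
  shifts <- with_seed(derive_seed(config$seed, "mi-surrogates"), {
    sample(seq(min_shift, nsamp - min_shift), config$n_surrogates,
           replace = TRUE)
  })
  w <- matrix(0, ng, ng)
  for (a in seq_len(ng - 1)) {
    da <- disc[[a]]
    for (b in (a + 1):ng) {
      db <- disc[[b]]
      if (is.null(da) || is.null(db)) {
        warning("constant channel; edge weight set to 0")
        next
      }
      mi_obs <- mi_discrete(da, db, nb)
      mi_null <- vapply(shifts, function(s) {
        db_s <- c(db[(s + 1):nsamp], db[1:s])
        mi_discrete(da, db_s, nb)
      }, numeric(1))
      wgt <- max(0, mi_obs - quantile(mi_null, config$quantile_level,
                                      names = FALSE))
      w[a, b] <- wgt
      w[b, a] <- wgt
    }
  }
  icto_network(w, labels = rec$channel_labels[good], directed = FALSE)
}
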