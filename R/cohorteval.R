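#' Patient case container
#'
#' The unit of cohort evaluation: a functional network, the set of actually
#' resected nodes, the binary post-surgical outcome (Engel class I = good,
#' free of disabling seizures; Engel class IV = poor, no worthwhile
#' improvement) and optionally one or more model-suggested optimal sets.
#'
#' @param id case identifier.
#' @param network an `icto_network`.
#' @param resected integer vector of resected node indices.
#' @param outcome `"good"` or `"poor"`.
#' @param suggested_sets optional list of suggested node sets.
#' @param planted optional ground-truth ictogenic set (synthetic cohorts).
#' @return an object of class `patient_case`.
#' @export
patient_case <- function(id, network, resected, outcome,
                         suggested_sets = NULL, planted = NULL) {
  validate_network(network)
  resected <- check_node_set(resected, n_nodes(network))
  outcome <- match.arg(outcome, c("good", "poor"))
  if (!is.null(suggested_sets)) {
    stopifnot(is.list(suggested_sets), length(suggested_sets) >= 1)
    suggested_sets <- lapply(suggested_sets, check_node_set,
                             n = n_nodes(network), allow_empty = FALSE)
  }
  structure(list(id = id, network = network, resected = resected,
                 outcome = outcome, suggested_sets = suggested_sets,
                 planted = planted),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s: %d nodes, %d resected, outcome %s, %s suggestion(s)\n",
              x$id, n_nodes(x$network), length(x$resected), x$outcome,
              if (is.null(x$suggested_sets)) "no"
              else length(x$suggested_sets)))
  invisible(x)
}

#' Percentage overlap of a suggested set with the actual resection
#'
#' The portion of nodes in the model suggestion that belongs to the actually
#' resected tissue: `100 * |suggested intersect resected| / |suggested|`.
#'
#' @param suggested nonempty node set suggested by the model.
#' @param resected node set actually resected.
#' @return overlap percentage in `[0, 100]`.
#' @export
#' @examples
#' overlap_pct(c(2, 3, 4, 5), c(3, 4, 5, 6, 7)) # 75
overlap_pct <- function(suggested, resected) {
  if (length(suggested) == 0) stop("suggested set must be nonempty")
  100 * length(intersect(suggested, resected)) / length(suggested)
}

#' Random-resection overlap baseline
#'
#' Overlap of uniformly random node sets (of the same size as the model
#' suggestion) with the actual resection: mean and standard error over
#' `n_samples` draws. The expected value is hypergeometric,
#' `100 * |resected| / N`.
#'
#' @param case a [patient_case()], or the network size via `n_nodes`.
#' @param suggested_size size of the random sets.
#' @param n_samples number of random sets (default 100).
#' @param seed sampling seed.
#' @return a list with `mean`, `se` and the sampled `overlaps`.
#' @export
random_baseline <- function(case, suggested_size = NULL, n_samples = 100L,
                            seed = 1L) {
  stopifnot(inherits(case, "patient_case"))
  n <- n_nodes(case$network)
  if (is.null(suggested_size)) {
    if (is.null(case$suggested_sets))
      stop("no suggested sets; pass suggested_size")
    suggested_size <- length(case$suggested_sets[[1]])
  }
  if (suggested_size > n) stop("suggested size exceeds the network size")
  ov <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i)
      overlap_pct(sample.int(n, suggested_size), case$resected), numeric(1))
  })
  list(mean = mean(ov), se = stats::sd(ov) / sqrt(n_samples), overlaps = ov)
}

#' One-sided Wilcoxon rank-sum test (exact with ties)
#'
#' Tests whether the first group's values are stochastically larger
#' (`alternative = "greater"`) or smaller than the second group's. For
#' combined sample sizes up to 25 the p-value is exact: midranks are
#' assigned, and the null distribution of the first group's rank sum is
#' enumerated over all `choose(n1 + n2, n1)` group assignments by dynamic
#' programming. Larger samples use the normal approximation with tie
#' correction.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param exact_limit maximal `n1 + n2` for exact enumeration (default 25).
#' @return a list with `p_value`, `statistic` (rank sum of `x`, `W`),
#'   `exact`, `alternative`.
#' @export
#' @examples
#' rank_sum_test(c(5, 6, 7), c(1, 2, 3))$p_value # 1/20
rank_sum_test <- function(x, y, alternative = c("greater", "less", "two.sided"),
                          exact_limit = 25L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y)) # midranks
  w <- sum(r[seq_len(n1)])
  if (length(unique(c(x, y))) == 1L)
    warning("all values tied across both groups; test is uninformative")
  if (n1 + n2 <= exact_limit) {
    # DP over doubled midranks (integers): number of n1-subsets per rank sum
    s <- as.integer(round(2 * r))
    total <- sum(s)
    dp <- matrix(0, nrow = n1 + 1, ncol = total + 1)
    dp[1, 1] <- 1
    for (v in s) {
      # dp_new[k, s] = dp[k, s] + dp[k - 1, s - v]; the RHS block is read
      # in full before assignment, so each item is counted at most once
      dp[2:(n1 + 1), (v + 1):(total + 1)] <-
        dp[2:(n1 + 1), (v + 1):(total + 1)] + dp[1:n1, 1:(total + 1 - v)]
    }
    counts <- dp[n1 + 1, ]
    denom <- choose(n1 + n2, n1)
    w2 <- as.integer(round(2 * w))
    p_ge <- sum(counts[(w2 + 1):(total + 1)]) / denom
    p_le <- sum(counts[1:(w2 + 1)]) / denom
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    return(list(p_value = p, statistic = w, exact = TRUE,
                alternative = alternative))
  }
  mu <- n1 * (n1 + n2 + 1) / 2
  ties <- table(r)
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z_g <- (w - 0.5 - mu) / sqrt(sig2)
  z_l <- (w + 0.5 - mu) / sqrt(sig2)
  p <- switch(alternative,
              greater = pnorm(z_g, lower.tail = FALSE),
              less = pnorm(z_l),
              two.sided = min(1, 2 * min(pnorm(z_g, lower.tail = FALSE),
                                         pnorm(z_l))))
  list(p_value = p, statistic = w, exact = FALSE, alternative = alternative)
}

#' ROC analysis of an overlap classifier
#'
#' Treats the score (e.g. percentage overlap) as a classifier of the
#' positive class. AUC is the Mann-Whitney concordance (ties count 1/2);
#' the reported operating point maximizes Youden's J
#' (sensitivity + specificity - 1).
#'
#' @param scores numeric scores.
#' @param labels logical (or coercible) vector, `TRUE` for the positive
#'   class; both classes must be present.
#' @return a list with `auc`, `roc` (data.frame of `threshold`,
#'   `sensitivity`, `specificity`), `operating_point` (row of `roc` at the
#'   Youden optimum).
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg))
    stop("both classes must be present")
  conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(conc)
  thr <- sort(unique(c(scores, Inf)))
  roc <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(neg < t), numeric(1)))
  j <- roc$sensitivity + roc$specificity - 1
  op <- roc[which.max(j), , drop = FALSE]
  list(auc = auc, roc = roc, operating_point = op)
}

#' Evaluate a cohort of cases against their actual resections
#'
#' For each case with suggested sets: the maximal and minimal percentage
#' overlap across co-optimal suggestions and a random-resection baseline.
#' Group-level: a one-sided rank-sum test of max overlap (good > poor) and
#' an ROC analysis of max overlap as an outcome classifier.
#'
#' @param cases list of [patient_case()] objects carrying `suggested_sets`.
#' @param n_baseline random baseline samples per case (default 100).
#' @param seed baseline seed.
#' @return a list of class `cohort_evaluation` with `per_case` (data.frame),
#'   `rank_sum` (see [rank_sum_test()]), `roc` (see [roc_analysis()]).
#' @export
evaluate_cohort <- function(cases, n_baseline = 100L, seed = 1L) {
  stopifnot(is.list(cases), length(cases) >= 2)
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    stopifnot(inherits(cs, "patient_case"))
    if (is.null(cs$suggested_sets))
      stop("case ", cs$id, " has no suggested sets; run suggest_resection()")
    ov <- vapply(cs$suggested_sets, overlap_pct, numeric(1),
                 resected = cs$resected)
    bl <- random_baseline(cs, length(cs$suggested_sets[[1]]),
                          n_samples = n_baseline,
                          seed = derive_seed(seed, "cohort-baseline", i))
    data.frame(id = as.character(cs$id), outcome = cs$outcome,
               n_nodes = n_nodes(cs$network), n_resected = length(cs$resected),
               n_suggestions = length(cs$suggested_sets),
               suggestion_size = length(cs$suggested_sets[[1]]),
               max_overlap_pct = max(ov), min_overlap_pct = min(ov),
               baseline_mean = bl$mean, baseline_se = bl$se,
               stringsAsFactors = FALSE)
  })
  per_case <- do.call(rbind, rows)
  good <- per_case$max_overlap_pct[per_case$outcome == "good"]
  poor <- per_case$max_overlap_pct[per_case$outcome == "poor"]
  rs <- rank_sum_test(good, poor, alternative = "greater")
  roc <- roc_analysis(per_case$max_overlap_pct, per_case$outcome == "good")
  structure(list(per_case = per_case, rank_sum = rs, roc = roc),
            class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort_evaluation> %d cases (%d good / %d poor)\n",
              nrow(x$per_case), sum(x$per_case$outcome == "good"),
              sum(x$per_case$outcome == "poor")))
  cat(sprintf("  one-sided rank-sum p = %.4g (%s)\n", x$rank_sum$p_value,
              if (x$rank_sum$exact) "exact" else "normal approximation"))
  cat(sprintf("  AUC = %.3f; operating point: sensitivity %.2f, specificity %.2f\n",
              x$roc$auc, x$roc$operating_point$sensitivity,
              x$roc$operating_point$specificity))
  invisible(x)
}

#' Suggest optimal resections for a case
#'
#' Runs the full single-case pipeline: calibrate the coupling on the case's
#' network, search with the genetic algorithm, and extract the smallest
#' set(s) whose SI exceeds the threshold. When nothing reaches the
#' threshold, the best set found is used with a warning.
#'
#' @param case a [patient_case()].
#' @param params a [theta_params()] (simulation fidelity for the search).
#' @param ga a [ga_config()].
#' @param threshold_si optimality threshold (default 0.99).
#' @param calib_tol calibration tolerance (default 0.05).
#' @return the case, with `suggested_sets` filled in and attributes
#'   `k_star` and `search` attached.
#' @export
suggest_resection <- function(case, params, ga = ga_config(),
                              threshold_si = 0.99, calib_tol = 0.05) {
  stopifnot(inherits(case, "patient_case"))
  cal <- calibrate_k(case$network, params, tol = calib_tol)
  p <- params
  p$k <- cal$k_star
  ev <- make_si_evaluator(case$network, p)
  res <- nsga2_search(ev, ga)
  opt <- optimal_set_extraction(res, threshold = threshold_si)
  if (!opt$found) {
    warning(sprintf("case %s: no set exceeded SI > %g (max SI %.3f); using the best set found",
                    case$id, threshold_si, opt$max_si))
    best <- res$front[which.max(res$front$si), ]
    opt$sets <- best$sets[[1]]
    opt$size <- best$size
  }
  case$suggested_sets <- opt$sets
  attr(case, "k_star") <- cal$k_star
  attr(case, "search") <- res
  case
}
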