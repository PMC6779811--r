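#' Count candidate sets of an exhaustive search
#'
#' Number of distinct nonempty node sets of size at most `max_size` in an
#' `n`-node network, `sum_{k=1..max_size} choose(n, k)`. Exact as a double
#' for all feasible sizes (the full 40-node search is `2^40 - 1` sets).
#'
#' @param n network size.
#' @param max_size largest set size considered (defaults to `n`).
#' @return the exact count (double).
#' @export
count_subsets <- function(n, max_size = n) {
  stopifnot(n >= 1, max_size >= 1, max_size <= n)
  sum(choose(n, seq_len(max_size)))
}

new_strategy_result <- function(strategy, per_size, n_evaluations,
                                seed_protocol, all = NULL) {
  per_size <- per_size[order(per_size$size), , drop = FALSE]
  rownames(per_size) <- NULL
  structure(list(strategy = strategy, per_size = per_size,
                 n_evaluations = n_evaluations,
                 seed_protocol = seed_protocol, all = all),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: %d sizes, %d SI evaluations\n",
              x$strategy, nrow(x$per_size), x$n_evaluations))
  ps <- x$per_size
  ps$set <- vapply(ps$set, function(s) paste(s, collapse = ","), character(1))
  print(ps, ...)
  invisible(x)
}

seed_protocol_of <- function(evaluator) {
  p <- evaluator$params
  list(seed = p$seed, n_realizations = p$n_realizations,
       n_steps = p$n_steps, k = p$k)
}

#' Exhaustive (ground-truth) search
#'
#' Evaluates the SI of every node set of size up to `max_size` and records
#' the per-size maximum. This is the only strategy guaranteed to find the
#' most ictogenic set, and it is refused outright when the number of
#' candidate sets exceeds `budget`: the refusal reports the exact count (a
#' full 40-node search would need 2^40 - 1 = 1,099,511,627,775 evaluations).
#'
#' @param evaluator an [make_si_evaluator()] for the calibrated network.
#' @param max_size largest set size enumerated.
#' @param budget ceiling on the number of candidate sets (default 1e6).
#' @param keep_all also return every evaluated set and its SI (`$all`).
#' @return a `strategy_result`; `$per_size` has columns `size`, `si` and a
#'   list-column `set` holding the best set of each size (ties broken by
#'   lexicographic node order).
#' @export
ground_truth_search <- function(evaluator, max_size, budget = 1e6,
                                keep_all = FALSE) {
  stopifnot(inherits(evaluator, "si_evaluator"))
  n <- n_nodes(evaluator$net)
  max_size <- min(max_size, n)
  total <- count_subsets(n, max_size)
  if (total > budget) {
    stop(errorCondition(
      sprintf(paste0("exhaustive search refused: %s candidate sets of size ",
                     "<= %d in a %d-node network exceed the budget of %s"),
              format(total, big.mark = ",", scientific = FALSE), max_size, n,
              format(budget, big.mark = ",", scientific = FALSE)),
      n_sets = total, class = c("ictonet_budget_error", "error", "condition")))
  }
  sizes <- seq_len(max_size)
  best <- data.frame(size = sizes, si = NA_real_)
  best$set <- vector("list", length(sizes))
  all_rows <- if (keep_all) vector("list", length(sizes))
  for (k in sizes) {
    sets <- combn(n, k, simplify = FALSE)
    si <- vapply(sets, function(s) evaluator$si(s)$si, numeric(1))
    ix <- which.max(si)
    best$si[k] <- si[ix]
    best$set[[k]] <- sets[[ix]]
    if (keep_all) {
      all_rows[[k]] <- data.frame(size = k, si = si)
      all_rows[[k]]$set <- sets
    }
  }
  new_strategy_result("ground_truth", best, evaluator$n_evaluations(),
                      seed_protocol_of(evaluator),
                      all = if (keep_all) do.call(rbind, all_rows))
}

#' Node-ordering heuristics
#'
#' `simple_ordering()` computes the Node Ictogenicity of every node on the
#' unperturbed network once, ranks nodes by decreasing NI (ties broken by
#' lower index) and adds them to the removal set in that order, evaluating
#' the cumulative SI after each addition and stopping once it exceeds
#' `stop_si`. `recurrent_ordering()` instead re-scores all remaining nodes
#' after each removal: the node whose addition yields the largest SI of the
#' *perturbed* network (still referenced to the original BNI) is added next.
#'
#' @param evaluator an [make_si_evaluator()] for the calibrated network.
#' @param stop_si stop once the cumulative SI exceeds this value
#'   (default 0.99).
#' @return a `strategy_result` with one row per cumulative set size.
#' @export
simple_ordering <- function(evaluator, stop_si = 0.99) {
  stopifnot(inherits(evaluator, "si_evaluator"))
  n <- n_nodes(evaluator$net)
  ni <- vapply(seq_len(n), function(j) evaluator$si(j)$si, numeric(1))
  ord <- order(-ni, seq_len(n))
  rows <- data.frame(size = integer(0), si = numeric(0))
  rows$set <- list()
  cur <- integer(0)
  for (j in ord) {
    cur <- c(cur, j)
    s <- evaluator$si(cur)$si
    rows <- rbind(rows, {
      r <- data.frame(size = length(cur), si = s)
      r$set <- list(sort(cur))
      r
    })
    if (s > stop_si) break
  }
  res <- new_strategy_result("simple_ordering", rows,
                             evaluator$n_evaluations(),
                             seed_protocol_of(evaluator))
  res$ni <- ni
  res$order <- ord
  res
}

#' @rdname simple_ordering
#' @export
recurrent_ordering <- function(evaluator, stop_si = 0.99) {
  stopifnot(inherits(evaluator, "si_evaluator"))
  n <- n_nodes(evaluator$net)
  rows <- data.frame(size = integer(0), si = numeric(0))
  rows$set <- list()
  cur <- integer(0)
  order_taken <- integer(0)
  repeat {
    rest <- setdiff(seq_len(n), cur)
    if (!length(rest)) break
    cand_si <- vapply(rest, function(j) evaluator$si(c(cur, j))$si, numeric(1))
    j <- rest[order(-cand_si, rest)[1]]
    cur <- c(cur, j)
    order_taken <- c(order_taken, j)
    s <- evaluator$si(cur)$si
    rows <- rbind(rows, {
      r <- data.frame(size = length(cur), si = s)
      r$set <- list(sort(cur))
      r
    })
    if (s > stop_si) break
  }
  res <- new_strategy_result("recurrent_ordering", rows,
                             evaluator$n_evaluations(),
                             seed_protocol_of(evaluator))
  res$order <- order_taken
  res
}

#' Allocate a random-search budget across set sizes
#'
#' Sample counts per size are proportional to the logarithm of the number of
#' possible sets of that size, rounded by largest remainder so they sum
#' exactly to `budget`. Sizes whose full enumeration fits inside their
#' allocation are enumerated completely, and the spare budget is
#' redistributed over the remaining sizes (iterated to a fixed point).
#'
#' @param n network size.
#' @param max_size largest set size sampled.
#' @param budget total number of SI evaluations.
#' @return integer vector of length `max_size`, summing to `budget`.
#' @export
allocate_random_search <- function(n, max_size, budget) {
  stopifnot(max_size >= 1, max_size <= n)
  if (budget < max_size)
    stop("budget must be at least the number of set sizes")
  sizes <- seq_len(max_size)
  n_sets <- choose(n, sizes)
  alloc <- integer(max_size)
  full <- rep(FALSE, max_size)
  remaining <- budget
  repeat {
    open <- which(!full)
    wts <- log(n_sets[open])
    wts[wts <= 0] <- min(wts[wts > 0], 1) # size-1/size-(n-1) rows: log C = 0
    share <- remaining * wts / sum(wts)
    cnt <- floor(share)
    rem <- remaining - sum(cnt)
    if (rem > 0) {
      top <- order(share - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[top] <- cnt[top] + 1L
    }
    alloc[open] <- as.integer(cnt)
    newly_full <- open[alloc[open] >= n_sets[open]]
    if (!length(newly_full)) break
    full[newly_full] <- TRUE
    alloc[newly_full] <- as.integer(n_sets[newly_full])
    remaining <- budget - sum(alloc[full])
    if (all(full) || remaining <= 0) break
  }
  # exactness: dump any residual on the largest open stratum
  diff <- budget - sum(alloc)
  if (diff != 0) {
    open <- which(!full)
    if (length(open)) alloc[open[length(open)]] <- alloc[open[length(open)]] + diff
  }
  stopifnot(sum(alloc) == budget)
  alloc
}

#' Stratified random search
#'
#' Samples node sets without replacement within each size stratum, with
#' per-size sample counts from [allocate_random_search()] (log-proportional,
#' denser at small sizes where the optimum is expected), and records the best
#' SI per size. Sizes whose allocation covers all possible sets are
#' enumerated exhaustively.
#'
#' @param evaluator an [make_si_evaluator()].
#' @param budget total number of sets to evaluate (e.g. the GA's
#'   population x generations).
#' @param max_size largest set size sampled.
#' @param seed sampling seed.
#' @return a `strategy_result`.
#' @export
random_search <- function(evaluator, budget, max_size, seed = 1L) {
  stopifnot(inherits(evaluator, "si_evaluator"))
  n <- n_nodes(evaluator$net)
  max_size <- min(max_size, n)
  alloc <- allocate_random_search(n, max_size, budget)
  rows <- data.frame(size = integer(0), si = numeric(0))
  rows$set <- list()
  for (k in seq_len(max_size)) {
    m <- alloc[k]
    if (m == 0L) next
    total_k <- choose(n, k)
    sets <- if (m >= total_k && total_k <= 2e5) {
      combn(n, k, simplify = FALSE)
    } else {
      sample_distinct_sets(n, k, m, derive_seed(seed, "random-search", k))
    }
    si <- vapply(sets, function(s) evaluator$si(s)$si, numeric(1))
    ix <- which.max(si)
    rows <- rbind(rows, {
      r <- data.frame(size = k, si = si[ix])
      r$set <- list(sort(sets[[ix]]))
      r
    })
  }
  res <- new_strategy_result("random_search", rows, evaluator$n_evaluations(),
                             seed_protocol_of(evaluator))
  res$allocation <- alloc
  res
}

# m distinct k-subsets of 1..n, uniform, without replacement across sets
sample_distinct_sets <- function(n, k, m, seed) {
  with_seed(seed, {
    seen <- new.env(parent = emptyenv())
    out <- vector("list", m)
    got <- 0L
    guard <- 0L
    while (got < m) {
      guard <- guard + 1L
      if (guard > 100L * m + 1000L)
        stop("could not draw enough distinct sets")
      s <- sort(sample.int(n, k))
      key <- paste(s, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[[got]] <- s
      }
    }
    out
  })
}

#' Fast non-dominated sort
#'
#' Partitions objective vectors (minimization on every coordinate) into
#' Pareto fronts: front 1 is the non-dominated set, front k+1 collects the
#' points dominated only by members of fronts 1..k.
#'
#' @param points numeric matrix, one row per point, one column per objective.
#' @return a list of integer vectors of row indices, one per front.
#' @export
fast_nondominated_sort <- function(points) {
  points <- as.matrix(points)
  np <- nrow(points)
  if (np == 0L) return(list())
  # dom[p, q]: p dominates q (all objectives <=, at least one <)
  le <- matrix(TRUE, np, np)
  lt <- matrix(FALSE, np, np)
  for (m in seq_len(ncol(points))) {
    cm <- points[, m]
    le <- le & outer(cm, cm, "<=")
    lt <- lt | outer(cm, cm, "<")
  }
  dom <- le & lt
  dom_count <- colSums(dom)
  fronts <- list()
  alive <- rep(TRUE, np)
  cur <- which(dom_count == 0L & alive)
  while (length(cur)) {
    fronts[[length(fronts) + 1L]] <- cur
    alive[cur] <- FALSE
    dom_count <- dom_count - colSums(dom[cur, , drop = FALSE])
    cur <- which(dom_count == 0L & alive)
  }
  fronts
}

dominates <- function(a, b) all(a <= b) && any(a < b)

# NSGA-II crowding distance within one front (rows of `pts`)
crowding_distance <- function(pts) {
  pts <- as.matrix(pts)
  np <- nrow(pts)
  if (np <= 2L) return(rep(Inf, np))
  d <- numeric(np)
  for (m in seq_len(ncol(pts))) {
    ord <- order(pts[, m])
    rng <- pts[ord[np], m] - pts[ord[1], m]
    d[ord[c(1, np)]] <- Inf
    if (rng > 0) {
      for (i in 2:(np - 1)) {
        d[ord[i]] <- d[ord[i]] + (pts[ord[i + 1], m] - pts[ord[i - 1], m]) / rng
      }
    }
  }
  d
}

#' NSGA-II configuration
#'
#' @param population_size even number of individuals (default 200).
#' @param generations number of generations (default 100; 150 was used for
#'   40-node networks).
#' @param n_runs independent runs pooled (default 8).
#' @param crossover_prob per-pair uniform-crossover probability.
#' @param mutation_prob per-bit mutation probability; `NULL` means `1/N`.
#' @param size_cap sets larger than this get the penalty objectives
#'   (`NULL` means `floor(N/2)`).
#' @param penalty_size,penalty_si objective values assigned to penalized
#'   candidates (`NULL` penalty_size means `N + 1`).
#' @param forbidden_nodes candidates containing any of these nodes are
#'   penalized.
#' @param seed master seed for the runs.
#' @return a list of class `ga_config`.
#' @export
ga_config <- function(population_size = 200L, generations = 100L,
                      n_runs = 8L, crossover_prob = 0.9,
                      mutation_prob = NULL, size_cap = NULL,
                      penalty_size = NULL, penalty_si = 2,
                      forbidden_nodes = integer(0), seed = 1L) {
  stopifnot(population_size >= 4, population_size %% 2 == 0,
            generations >= 1, n_runs >= 1,
            crossover_prob >= 0, crossover_prob <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 n_runs = as.integer(n_runs),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob, size_cap = size_cap,
                 penalty_size = penalty_size, penalty_si = penalty_si,
                 forbidden_nodes = as.integer(forbidden_nodes),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Constrained multi-objective search for minimal ictogenic sets (NSGA-II)
#'
#' Minimizes two objectives simultaneously: the number of removed nodes and
#' `1 - SI`. Candidates are fixed-length binary membership vectors evolved
#' with binary-tournament selection on (front rank, crowding distance),
#' uniform crossover, per-bit mutation and elitist (mu + lambda) survival.
#' Candidates larger than the size cap (half the network by default), empty
#' candidates and candidates containing forbidden nodes are discarded by
#' assigning arbitrarily large objective values without simulating them.
#' Several independent runs (initialized from sizes drawn uniformly up to
#' the cap) are pooled; SI evaluations are cached across runs by set
#' identity through the shared evaluator.
#'
#' @param evaluator an [make_si_evaluator()] for the calibrated network.
#' @param config a [ga_config()].
#' @return a list of class `nsga2_result` with elements
#'   `front` (a `pareto_front`: data.frame of `size`, `one_minus_si`, `si`
#'   and list-column `sets` of all co-optimal member sets),
#'   `per_size` (best SI per size over everything evaluated, as a
#'   `strategy_result`), `convergence` (a `convergence_report`), `runs`
#'   (per-run archives) and `n_evaluations`.
#' @export
nsga2_search <- function(evaluator, config = ga_config()) {
  stopifnot(inherits(evaluator, "si_evaluator"), inherits(config, "ga_config"))
  n <- n_nodes(evaluator$net)
  cap <- if (is.null(config$size_cap)) floor(n / 2) else config$size_cap
  stopifnot(cap >= 1, cap <= n)
  pmut <- if (is.null(config$mutation_prob)) 1 / n else config$mutation_prob
  pen_size <- if (is.null(config$penalty_size)) n + 1 else config$penalty_size
  pen_si <- config$penalty_si
  forb <- check_node_set(config$forbidden_nodes, n)
  if (length(forb) >= n)
    stop("all nodes are forbidden; no feasible candidate exists")

  evaluate <- function(bits) {
    # returns c(size, 1 - SI); penalized candidates are not simulated
    idx <- which(bits)
    if (length(idx) == 0L || length(idx) > cap || any(idx %in% forb))
      return(c(pen_size, pen_si))
    c(length(idx), 1 - evaluator$si(idx)$si)
  }

  run_one <- function(run_seed) {
    with_seed(run_seed, {
      mu <- config$population_size
      pop <- lapply(seq_len(mu), function(i) {
        k <- sample.int(cap, 1L)
        bits <- rep(FALSE, n)
        bits[sample.int(n, k)] <- TRUE
        bits
      })
      obj <- t(vapply(pop, evaluate, numeric(2)))
      best_per_size <- rep(NA_real_, cap) # best SI per size, archive
      best_series <- matrix(NA_real_, config$generations, cap)
      update_archive <- function() {
        ok <- obj[, 1] <= cap & obj[, 2] <= 1
        for (i in which(ok)) {
          k <- obj[i, 1]
          s <- 1 - obj[i, 2]
          if (is.na(best_per_size[k]) || s > best_per_size[k])
            best_per_size[k] <<- s
        }
      }
      update_archive()
      rank_crowd <- function(objm) {
        fronts <- fast_nondominated_sort(objm)
        rk <- integer(nrow(objm))
        cd <- numeric(nrow(objm))
        for (f in seq_along(fronts)) {
          rk[fronts[[f]]] <- f
          cd[fronts[[f]]] <- crowding_distance(objm[fronts[[f]], , drop = FALSE])
        }
        list(rank = rk, crowd = cd, fronts = fronts)
      }
      rc <- rank_crowd(obj)
      for (g in seq_len(config$generations)) {
        # binary tournaments pick mu parents
        parents <- vapply(seq_len(mu), function(i) {
          a <- sample.int(mu, 2L)
          if (rc$rank[a[1]] < rc$rank[a[2]] ||
              (rc$rank[a[1]] == rc$rank[a[2]] && rc$crowd[a[1]] > rc$crowd[a[2]]))
            a[1] else a[2]
        }, integer(1))
        off <- vector("list", mu)
        for (i in seq(1, mu, by = 2)) {
          c1 <- pop[[parents[i]]]
          c2 <- pop[[parents[i + 1]]]
          if (runif(1) < config$crossover_prob) {
            swap <- runif(n) < 0.5
            tmp <- c1[swap]
            c1[swap] <- c2[swap]
            c2[swap] <- tmp
          }
          flip1 <- runif(n) < pmut
          flip2 <- runif(n) < pmut
          c1[flip1] <- !c1[flip1]
          c2[flip2] <- !c2[flip2]
          off[[i]] <- c1
          off[[i + 1]] <- c2
        }
        obj_off <- t(vapply(off, evaluate, numeric(2)))
        pool <- c(pop, off)
        obj_pool <- rbind(obj, obj_off)
        rcp <- rank_crowd(obj_pool)
        keep <- integer(0)
        for (f in seq_along(rcp$fronts)) {
          fr <- rcp$fronts[[f]]
          if (length(keep) + length(fr) <= mu) {
            keep <- c(keep, fr)
          } else {
            need <- mu - length(keep)
            fr_cd <- rcp$crowd[fr]
            keep <- c(keep, fr[order(-fr_cd)][seq_len(need)])
            break
          }
        }
        pop <- pool[keep]
        obj <- obj_pool[keep, , drop = FALSE]
        rc <- rank_crowd(obj)
        update_archive()
        best_series[g, ] <- best_per_size
      }
      # final-front feasible points of this run
      f1 <- rc$fronts[[1]]
      feas <- f1[obj[f1, 1] <= cap & obj[f1, 2] <= 1]
      list(best_per_size = best_per_size, best_series = best_series,
           front_obj = obj[feas, , drop = FALSE],
           front_sets = lapply(pop[feas], which))
    })
  }

  runs <- lapply(seq_len(config$n_runs), function(r)
    run_one(derive_seed(config$seed, "nsga2-run", r)))

  # pooled per-size best over every cached (feasible) evaluation
  pooled <- do.call(rbind, lapply(runs, function(r)
    data.frame(size = seq_len(cap), si = r$best_per_size)))
  per_size_best <- stats::aggregate(
    si ~ size, data = pooled,
    FUN = function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
    na.action = stats::na.pass)
  per_size_best <- per_size_best[is.finite(per_size_best$si), , drop = FALSE]

  # pooled Pareto front over per-run front members, all co-optimal sets kept
  all_obj <- do.call(rbind, lapply(runs, function(r) r$front_obj))
  all_sets <- do.call(c, lapply(runs, function(r) r$front_sets))
  if (is.null(all_obj) || nrow(all_obj) == 0L)
    stop("no feasible candidate survived; constraints may be infeasible")
  fr1 <- fast_nondominated_sort(all_obj)[[1]]
  fobj <- all_obj[fr1, , drop = FALSE]
  fsets <- all_sets[fr1]
  front <- unique(data.frame(size = fobj[, 1], one_minus_si = fobj[, 2]))
  front <- front[order(front$size), , drop = FALSE]
  front$si <- 1 - front$one_minus_si
  front$sets <- lapply(seq_len(nrow(front)), function(i) {
    ix <- which(fobj[, 1] == front$size[i] & fobj[, 2] == front$one_minus_si[i])
    ss <- unique(lapply(fsets[ix], sort))
    ss[order(vapply(ss, function(s) paste(sprintf("%06d", s), collapse = ","),
                    character(1)))]
  })
  rownames(front) <- NULL
  class(front) <- c("pareto_front", "data.frame")

  # convergence proxies: per-run hypervolume w.r.t. (cap + 1, 1.1) and
  # across-run IQR of best SI per size
  hv <- vapply(runs, function(r)
    hypervolume2d(r$front_obj, ref = c(cap + 1, 1.1)), numeric(1))
  spread <- vapply(seq_len(cap), function(k) {
    v <- vapply(runs, function(r) r$best_per_size[k], numeric(1))
    v <- v[!is.na(v)]
    if (length(v) < 2) return(0)
    stats::IQR(v)
  }, numeric(1))
  convergence <- structure(
    list(hypervolume = hv, spread_per_size = spread,
         max_spread = max(spread), converged = max(spread) <= 0.05),
    class = "convergence_report")

  best_rows <- data.frame(size = per_size_best$size, si = per_size_best$si)
  best_rows$set <- lapply(seq_len(nrow(best_rows)), function(i) {
    k <- best_rows$size[i]
    hit <- which(front$size == k & abs(front$si - best_rows$si[i]) < 1e-12)
    if (length(hit)) front$sets[[hit[1]]][[1]] else integer(0)
  })
  per_size <- new_strategy_result("nsga2", best_rows,
                                  evaluator$n_evaluations(),
                                  seed_protocol_of(evaluator))
  structure(list(front = front, per_size = per_size,
                 convergence = convergence, runs = runs,
                 n_evaluations = evaluator$n_evaluations(),
                 config = config),
            class = "nsga2_result")
}

#' @export
print.nsga2_result <- function(x, ...) {
  cat(sprintf("<nsga2_result> %d runs, %d front points, %d SI evaluations\n",
              length(x$runs), nrow(x$front), x$n_evaluations))
  print(x$front[, c("size", "si")], ...)
  invisible(x)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> hypervolumes: %s; max per-size SI spread %.4f (%s)\n",
              paste(sprintf("%.3f", x$hypervolume), collapse = ", "),
              x$max_spread,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# 2-D dominated hypervolume (minimization) w.r.t. a reference point
hypervolume2d <- function(pts, ref) {
  pts <- as.matrix(pts)
  if (nrow(pts) == 0L) return(0)
  fr <- fast_nondominated_sort(pts)[[1]]
  pts <- pts[fr, , drop = FALSE]
  pts <- pts[pts[, 1] <= ref[1] & pts[, 2] <= ref[2], , drop = FALSE]
  if (nrow(pts) == 0L) return(0)
  pts <- pts[order(pts[, 1]), , drop = FALSE]
  hv <- 0
  prev_y <- ref[2]
  for (i in seq_len(nrow(pts))) {
    hv <- hv + (ref[1] - pts[i, 1]) * (prev_y - pts[i, 2])
    prev_y <- pts[i, 2]
  }
  hv
}

#' Per-size SI gap between two strategies
#'
#' `delta_si(reference, other)` returns `SI_ref(n) - SI_other(n)` for every
#' resection size present in both results. Against the ground truth this is
#' nonnegative by construction; against the GA as reference it may be
#' negative when another strategy wins. Sizes present in only one result are
#' skipped with a warning.
#'
#' @param reference,other `strategy_result` objects (or an `nsga2_result`,
#'   whose per-size table is used).
#' @return data.frame with columns `size`, `si_ref`, `si_other`, `delta_si`.
#' @export
delta_si <- function(reference, other) {
  ref <- as_per_size(reference)
  oth <- as_per_size(other)
  common <- intersect(ref$size, oth$size)
  only <- c(setdiff(ref$size, oth$size), setdiff(oth$size, ref$size))
  if (length(only))
    warning("sizes present in one result only are skipped: ",
            paste(sort(only), collapse = ", "))
  data.frame(size = common,
             si_ref = ref$si[match(common, ref$size)],
             si_other = oth$si[match(common, oth$size)],
             delta_si = ref$si[match(common, ref$size)] -
               oth$si[match(common, oth$size)])
}

as_per_size <- function(x) {
  if (inherits(x, "nsga2_result")) x <- x$per_size
  stopifnot(inherits(x, "strategy_result"))
  x$per_size
}

#' Extract the optimal resection set(s)
#'
#' The optimal resection is the smallest set whose SI exceeds a threshold
#' (0.99 by default). All co-optimal sets of that minimal size are returned;
#' when nothing reaches the threshold the result is empty and carries the
#' best SI observed as a diagnostic.
#'
#' @param x a `strategy_result`, `nsga2_result` or `pareto_front`.
#' @param threshold SI threshold (default 0.99).
#' @return a list with `found`, `size`, `si`, `sets` (list of node sets) and
#'   `max_si` (diagnostic when not found).
#' @export
optimal_set_extraction <- function(x, threshold = 0.99) {
  if (inherits(x, "nsga2_result")) {
    front <- x$front
    ok <- which(front$si > threshold)
    if (length(ok)) {
      i <- ok[which.min(front$size[ok])]
      return(list(found = TRUE, size = front$size[i], si = front$si[i],
                  sets = front$sets[[i]], max_si = max(front$si)))
    }
    return(list(found = FALSE, size = NA_integer_, si = NA_real_,
                sets = list(), max_si = max(front$si)))
  }
  ps <- as_per_size(x)
  ok <- which(ps$si > threshold)
  if (length(ok)) {
    i <- ok[which.min(ps$size[ok])]
    sets <- ps$set[ps$size == ps$size[i] & ps$si > threshold]
    return(list(found = TRUE, size = ps$size[i], si = ps$si[i],
                sets = sets, max_si = max(ps$si)))
  }
  list(found = FALSE, size = NA_integer_, si = NA_real_, sets = list(),
       max_si = if (nrow(ps)) max(ps$si) else NA_real_)
}
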