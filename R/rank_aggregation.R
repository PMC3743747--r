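# Consensus ordering of weighted ranked lists: Borda baseline, weighted
# Spearman footrule objective, cross-entropy Monte Carlo optimizer, and
# an exhaustive oracle for small instances.

#' Construct a ranked list
#'
#' One experiment's ordering of candidate assays, best (most stable,
#' lowest M-value) first, together with the per-assay importance weights
#' that produced the order. Because the list is ordered by its own
#' weights, the weight vector must be non-decreasing.
#'
#' @param experiment_id label of the originating experiment.
#' @param assays ordered unique assay names, best first.
#' @param weights numeric vector of importance scores (M-values),
#'   non-decreasing, same length as `assays`.
#' @return an object of class `ranked_list`.
#' @export
ranked_list <- function(experiment_id, assays, weights) {
  assays <- as.character(assays)
  check_unique_ids(assays, "assay")
  weights <- as.numeric(weights)
  if (length(weights) != length(assays)) {
    stop("`weights` must match `assays` in length", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and >= 0", call. = FALSE)
  }
  if (is.unsorted(weights)) {
    stop("weights must be non-decreasing along the list", call. = FALSE)
  }
  structure(list(experiment_id = experiment_id, assays = assays,
                 weights = weights),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> %s: %s\n", x$experiment_id,
              paste(sprintf("%s(%.2g)", x$assays, x$weights), collapse = " ")))
  invisible(x)
}

#' Min-max normalize a ranked list's weights to [0, 1]
#'
#' M-value magnitudes differ up to ~20-fold between experiments; mapping
#' each list's weights affinely onto [0, 1] keeps high-noise experiments
#' from dominating the aggregation objective. A degenerate all-equal
#' weight vector maps to all zeros (such a list carries no order
#' information and contributes 0 to every distance). Idempotent.
#'
#' @param l a [ranked_list()].
#' @return the list with weights rescaled to span [0, 1].
#' @export
normalize_weights <- function(l) {
  stopifnot(inherits(l, "ranked_list"))
  w <- l$weights
  rng <- max(w) - min(w)
  l$weights <- if (rng == 0) rep(0, length(w)) else (w - min(w)) / rng
  l
}

#' Weighted Spearman footrule distance between a candidate order and a list
#'
#' With `W(r)` the weight attached to position `r` of list `l`, the
#' distance is `sum over assays t of |W(rank of t in l) - W(rank of t in
#' candidate)|`: an assay displaced between positions of similar weight
#' costs little, while moving it across the list's weight range costs up
#' to the full span. Zero iff the candidate attaches the same position
#' weight to every assay as the list itself does (in particular, for the
#' list's own order). `l` is expected to be weight-normalized (see
#' [normalize_weights()]).
#'
#' @param candidate character vector, an ordering of the same assay set.
#' @param l a [ranked_list()].
#' @param weighted if `FALSE`, the classic unweighted footrule
#'   `sum |rank difference|` is computed instead (weights ignored).
#' @return a non-negative scalar.
#' @export
footrule_distance <- function(candidate, l, weighted = TRUE) {
  stopifnot(inherits(l, "ranked_list"))
  if (!setequal(candidate, l$assays) || length(candidate) != length(l$assays)) {
    stop("candidate and list must cover the same assay set", call. = FALSE)
  }
  rank_in_l <- match(l$assays, l$assays)        # 1..k by construction
  rank_in_cand <- match(l$assays, candidate)
  if (!weighted) return(sum(abs(rank_in_l - rank_in_cand)))
  sum(abs(l$weights[rank_in_l] - l$weights[rank_in_cand]))
}

#' Total aggregation objective of a candidate order
#'
#' Sum of [footrule_distance()] over all input lists. Lists are
#' weight-normalized before evaluation.
#'
#' @param candidate ordering of the common assay set.
#' @param lists list of [ranked_list()] objects over a common assay set.
#' @param weighted passed to [footrule_distance()].
#' @return a non-negative scalar.
#' @export
total_objective <- function(candidate, lists, weighted = TRUE) {
  lists <- check_common_assays(lists)
  sum(vapply(lists,
             function(l) footrule_distance(candidate, normalize_weights(l),
                                           weighted = weighted),
             numeric(1)))
}

check_common_assays <- function(lists) {
  if (!length(lists)) stop("need at least one ranked list", call. = FALSE)
  if (inherits(lists, "ranked_list")) lists <- list(lists)
  ref <- lists[[1]]$assays
  for (l in lists) {
    if (!setequal(l$assays, ref) || length(l$assays) != length(ref)) {
      diff <- c(setdiff(ref, l$assays), setdiff(l$assays, ref))
      stop(sprintf("assay-set mismatch in list '%s': %s",
                   l$experiment_id, paste(diff, collapse = ", ")),
           call. = FALSE)
    }
  }
  lists
}

# Precompute the objective as a fast closure over the normalized lists.
# With A[t, l] the normalized weight of assay t in list l and B[r, l]
# the normalized weight at position r of list l, the objective of a
# candidate is sum_t sum_l |A[t, l] - B[pos(t), l]|. It is therefore
# separable by (item, position): precomputing the cost matrix
# C[t, r] = sum_l |A[t, l] - B[r, l]| reduces every evaluation to a
# k-term lookup sum.
make_objective <- function(lists) {
  lists <- lapply(check_common_assays(lists), normalize_weights)
  items <- sort(lists[[1]]$assays)
  k <- length(items)
  L <- length(lists)
  A <- matrix(0, k, L)
  B <- matrix(0, k, L)
  for (j in seq_len(L)) {
    l <- lists[[j]]
    A[, j] <- l$weights[match(items, l$assays)]
    B[, j] <- l$weights
  }
  C <- matrix(0, k, k)
  tA <- t(A)
  for (r in seq_len(k)) C[, r] <- colSums(abs(tA - B[r, ]))
  idx <- seq_len(k)
  list(items = items, k = k, cost = C,
       of_positions = function(pos_of_item) sum(C[cbind(idx, pos_of_item)]),
       of_order = function(candidate) {
         sum(C[cbind(idx, match(items, candidate))])
       })
}

# Deterministic hill climbing over the swap + single-item-insertion
# neighborhood; returns a locally optimal pos_of_item vector. Used to
# polish the cross-entropy best-ever candidate, which protects against
# premature convergence of the sampling distribution.
refine_positions <- function(obj, pos_of_item) {
  k <- obj$k
  val <- obj$of_positions(pos_of_item)
  repeat {
    improved <- FALSE
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        cand <- pos_of_item
        cand[c(a, b)] <- cand[c(b, a)]
        v <- obj$of_positions(cand)
        if (v < val - 1e-12) {
          val <- v; pos_of_item <- cand; improved <- TRUE
        }
      }
    }
    perm <- order(pos_of_item)  # item index at each position
    for (a in seq_len(k)) {
      for (p in seq_len(k)) {
        if (p == pos_of_item[a]) next
        cand <- order(append(perm[perm != a], a, after = p - 1))
        v <- obj$of_positions(cand)
        if (v < val - 1e-12) {
          val <- v; pos_of_item <- cand; perm <- order(cand); improved <- TRUE
        }
      }
    }
    if (!improved) return(list(val = val, pos = pos_of_item))
  }
}

new_aggregation_result <- function(consensus, objective, method, trace = NULL,
                                   seed = NULL) {
  structure(list(consensus = consensus, objective = objective, method = method,
                 trace = trace, seed = seed),
            class = "aggregation_result")
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf("<aggregation_result> method=%s objective=%.6g\n",
              x$method, x$objective))
  cat("  consensus (most -> least stable):",
      paste(x$consensus, collapse = " > "), "\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Borda-count consensus of ranked lists
#'
#' Orders assays by their mean rank across lists (ascending), breaking
#' ties alphabetically by assay id. A deterministic voting-theory
#' baseline that ignores the weights.
#'
#' @param lists list of [ranked_list()] objects over a common assay set.
#' @return an `aggregation_result` with `method = "borda"`.
#' @export
borda_aggregate <- function(lists) {
  lists <- check_common_assays(lists)
  items <- sort(lists[[1]]$assays)
  ranks <- vapply(lists, function(l) match(items, l$assays), numeric(length(items)))
  ranks <- matrix(ranks, nrow = length(items))
  mean_rank <- rowMeans(ranks)
  consensus <- items[order(mean_rank, items)]
  new_aggregation_result(consensus, total_objective(consensus, lists), "borda")
}

#' Exhaustive minimizer of the aggregation objective
#'
#' Enumerates all permutations of the assay set (feasible up to 8 assays,
#' 8! = 40320 candidates) and returns the global minimizer of
#' [total_objective()]; ties are broken lexicographically. Serves as the
#' oracle the stochastic optimizer is validated against.
#'
#' @param lists list of [ranked_list()] objects over a common assay set.
#' @return an `aggregation_result` with `method = "brute"`.
#' @export
brute_force_aggregate <- function(lists) {
  obj <- make_objective(lists)
  if (obj$k > 8) stop("brute force limited to <= 8 assays", call. = FALSE)
  perms <- permutations_lex(obj$k)
  best <- NULL
  best_val <- Inf
  for (i in seq_len(nrow(perms))) {
    ord <- perms[i, ]
    pos_of_item <- order(ord)  # items[ord] puts item ord[r] at position r
    val <- obj$of_positions(pos_of_item)
    if (val < best_val - 1e-12) {  # strict improvement; lex order wins ties
      best_val <- val
      best <- obj$items[ord]
    }
  }
  new_aggregation_result(best, best_val, "brute")
}

# All permutations of 1..n in lexicographic row order, n! x n matrix.
permutations_lex <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_lex(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- matrix(rest[sub], nrow(sub), n - 1L)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(first, block)
    row <- row + nrow(sub)
  }
  out
}

#' Cross-entropy Monte Carlo hyperparameters
#'
#' @param k number of assays (used only for the sample-size default).
#' @param n_samples_per_iter permutations sampled per iteration; default
#'   `10 * k^2`.
#' @param elite_fraction fraction rho of samples re-fitted on, in (0, 1).
#' @param smoothing update weight w in (0, 1]: `P <- w*P_new + (1-w)*P`.
#' @param convergence_patience iterations without elite improvement
#'   before stopping.
#' @param max_iters hard iteration cap.
#' @param seed RNG seed recorded in every result.
#' @param init `"uniform"` or `"borda"` (seed the position-probability
#'   matrix around the Borda consensus).
#' @return an object of class `ce_params`.
#' @export
ce_params <- function(k = NULL, n_samples_per_iter = if (!is.null(k)) 10L * k^2 else NULL,
                      elite_fraction = 0.1, smoothing = 0.25,
                      convergence_patience = 5L, max_iters = 1000L,
                      seed = 1L, init = c("uniform", "borda")) {
  init <- match.arg(init)
  if (!is.null(n_samples_per_iter) && n_samples_per_iter < 1) {
    stop("n_samples_per_iter must be positive", call. = FALSE)
  }
  if (elite_fraction <= 0 || elite_fraction >= 1) {
    stop("elite_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (smoothing <= 0 || smoothing > 1) {
    stop("smoothing must lie in (0, 1]", call. = FALSE)
  }
  if (convergence_patience < 1 || max_iters < 1) {
    stop("patience and max_iters must be >= 1", call. = FALSE)
  }
  if (!is.null(n_samples_per_iter)) {
    n_samples_per_iter <- as.integer(n_samples_per_iter)
  }
  structure(list(n_samples_per_iter = n_samples_per_iter,
                 elite_fraction = elite_fraction, smoothing = smoothing,
                 convergence_patience = as.integer(convergence_patience),
                 max_iters = as.integer(max_iters), seed = seed, init = init),
            class = "ce_params")
}

# Run `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cross-entropy Monte Carlo consensus of weighted ranked lists
#'
#' Maintains a k x k matrix `P[item, position]` of position
#' probabilities, initialized uniform (or Borda-seeded). Each iteration
#' samples permutations position by position without replacement from
#' `P`, scores them with [total_objective()], re-estimates `P` from the
#' elite fraction of samples and smooths `P <- w*P_new + (1-w)*P`.
#' Stops after `convergence_patience` iterations without elite
#' improvement or at `max_iters`. The best permutation ever sampled is
#' kept throughout and finished with a deterministic hill climb over the
#' swap/insertion neighborhood (a standard memetic polish that guards
#' against premature convergence of the sampling distribution); the
#' final answer is the better of that candidate and the Borda consensus,
#' so the stochastic search can never underperform the deterministic
#' baseline. Fully reproducible from `params$seed`.
#'
#' @param lists list of [ranked_list()] objects over a common assay set.
#' @param params a [ce_params()]; `NULL` uses the defaults for the
#'   instance's size.
#' @return an `aggregation_result` with `method = "ce"`, a per-iteration
#'   trace of the best sampled objective, and the seed.
#' @export
ce_aggregate <- function(lists, params = NULL) {
  obj <- make_objective(lists)
  k <- obj$k
  if (is.null(params)) params <- ce_params(k = k)
  if (is.null(params$n_samples_per_iter)) params$n_samples_per_iter <- 10L * k^2
  n <- as.integer(params$n_samples_per_iter)
  n_elite <- max(1L, as.integer(ceiling(params$elite_fraction * n)))
  w <- params$smoothing
  borda <- borda_aggregate(lists)

  P <- matrix(1 / k, k, k)
  if (params$init == "borda") {
    # modest pull toward the Borda order
    target <- match(obj$items, borda$consensus)
    for (t in seq_len(k)) P[t, target[t]] <- P[t, target[t]] + 1
    P <- sweep(P, 2, colSums(P), "/")
  }

  best_val <- Inf
  best_pos <- NULL  # pos_of_item vector
  trace <- numeric(0)
  stale <- 0L

  with_seed(params$seed, {
    for (iter in seq_len(params$max_iters)) {
      samples <- matrix(0L, n, k)  # samples[i, r] = item index at position r
      vals <- numeric(n)
      for (i in seq_len(n)) {
        avail <- rep(TRUE, k)
        perm <- integer(k)
        for (r in seq_len(k)) {
          p <- P[avail, r]
          idx <- which(avail)
          perm[r] <- if (length(idx) == 1L) idx else if (sum(p) <= 0)
            sample(idx, 1L) else sample(idx, 1L, prob = p)
          avail[perm[r]] <- FALSE
        }
        samples[i, ] <- perm
        vals[i] <- obj$of_positions(order(perm))
      }
      elite <- order(vals)[seq_len(n_elite)]
      iter_best <- vals[elite[1]]
      trace <- c(trace, iter_best)
      if (iter_best < best_val - 1e-12) {
        best_val <- iter_best
        best_pos <- order(samples[elite[1], ])
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (stale >= params$convergence_patience) break
      Pnew <- matrix(0, k, k)
      for (i in elite) {
        perm <- samples[i, ]
        Pnew[cbind(perm, seq_len(k))] <- Pnew[cbind(perm, seq_len(k))] + 1
      }
      Pnew <- Pnew / n_elite
      P <- w * Pnew + (1 - w) * P
    }
  })

  refined <- refine_positions(obj, best_pos)
  best_val <- refined$val
  best_pos <- refined$pos
  ce_consensus <- obj$items[order(best_pos)]
  if (borda$objective < best_val - 1e-12) {
    new_aggregation_result(borda$consensus, borda$objective, "ce",
                           trace = trace, seed = params$seed)
  } else {
    new_aggregation_result(ce_consensus, best_val, "ce",
                           trace = trace, seed = params$seed)
  }
}

#' Aggregate an M-value table into one consensus ranking
#'
#' Builds one weighted ranked list per experiment (assays sorted by
#' ascending M, M-values as weights), min-max normalizes the weights per
#' list, and aggregates with the chosen method.
#'
#' @param t an [mvalue_table()], e.g. [load_table1_fixture()].
#' @param method `"ce"`, `"borda"` or `"brute"` (the latter only for
#'   <= 8 assays).
#' @param params optional [ce_params()] for `method = "ce"`.
#' @return an `aggregation_result`; the per-experiment lists are attached
#'   as attribute `"lists"`.
#' @export
aggregate_table <- function(t, method = c("ce", "borda", "brute"),
                            params = NULL) {
  method <- match.arg(method)
  lists <- table_to_ranked_lists(t)
  res <- switch(method,
                ce = ce_aggregate(lists, params),
                borda = borda_aggregate(lists),
                brute = brute_force_aggregate(lists))
  attr(res, "lists") <- lists
  res
}
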