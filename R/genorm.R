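# The geNorm expression-stability statistic family: pairwise variation,
# M-value, stepwise-exclusion ranking, normalization factors, V-values.
#
# All ratios are log2; dispersion is the sample (n-1) standard deviation.
# Every statistic here is invariant to per-assay rescaling of the
# quantity matrix, because constants cancel in log-ratios.

#' Pairwise variation between two assays
#'
#' The sample standard deviation, over samples, of the log2 expression
#' ratio of two assays. Two assays that are exactly proportional across
#' samples have pairwise variation 0; the statistic is symmetric in its
#' two assays.
#'
#' @param q a [quantity_matrix()] with at least 2 samples.
#' @param assay_j,assay_k assay ids present in `q`.
#' @return a non-negative scalar (log2 units).
#' @export
pairwise_variation <- function(q, assay_j, assay_k) {
  stopifnot(inherits(q, "quantity_matrix"))
  if (ncol(q$q) < 2) stop("pairwise variation needs >= 2 samples", call. = FALSE)
  for (a in c(assay_j, assay_k)) {
    if (!a %in% q$assay_ids) stop(sprintf("unknown assay '%s'", a), call. = FALSE)
  }
  stats::sd(log2(q$q[assay_j, ] / q$q[assay_k, ]))
}

#' geNorm M-value of one assay within a candidate set
#'
#' The average pairwise variation of `assay_j` with every other assay of
#' `within`: the lower the M-value, the more stably the assay co-varies
#' with the rest of the candidate panel. M-values below 0.5 are
#' conventionally regarded as good reference assays.
#'
#' @param q a [quantity_matrix()].
#' @param assay_j the assay to score.
#' @param within character vector of candidate assay ids (must contain
#'   `assay_j` and at least one partner); defaults to all assays.
#' @return a non-negative scalar.
#' @export
m_value <- function(q, assay_j, within = q$assay_ids) {
  stopifnot(inherits(q, "quantity_matrix"))
  if (length(within) < 2) stop("M-value needs >= 2 assays", call. = FALSE)
  if (!assay_j %in% within) stop("`within` must contain `assay_j`", call. = FALSE)
  partners <- setdiff(within, assay_j)
  mean(vapply(partners, function(k) pairwise_variation(q, assay_j, k),
              numeric(1)))
}

#' Rank assays by expression stability via stepwise exclusion
#'
#' Repeatedly computes M-values within the current candidate set and
#' excludes the assay with the highest M (ties: the assay appearing later
#' in input order is excluded). Excluded assays are recorded least stable
#' first; the two survivors are appended last, ordered by their full-set
#' M descending (so the most stable assay sits at the end). The final
#' pair cannot be distinguished by the statistic itself -- their mutual
#' pairwise variation is the only information left -- so
#' `final_pair_tied` is always `TRUE`.
#'
#' @param q a [quantity_matrix()] with >= 3 assays and >= 2 samples.
#' @return a `stability_result` with fields `assay_ids`, `m_values`
#'   (full-set M for every assay, the table-publication convention),
#'   `ranking` (least stable first), `exclusion_trace` (per step:
#'   excluded assay and its M at that step) and `final_pair_tied`.
#' @export
rank_stepwise <- function(q) {
  stopifnot(inherits(q, "quantity_matrix"))
  assays <- q$assay_ids
  if (length(assays) < 3) stop("stepwise ranking needs >= 3 assays", call. = FALSE)
  m_full <- vapply(assays, function(a) m_value(q, a, assays), numeric(1))
  current <- assays
  ranking <- character(0)
  trace <- data.frame(assay = character(0), m = numeric(0),
                      stringsAsFactors = FALSE)
  while (length(current) > 2) {
    ms <- vapply(current, function(a) m_value(q, a, current), numeric(1))
    # on a tie for the max, exclude the assay latest in input order
    tied <- current[ms >= max(ms) - 1e-12]
    pick <- tied[length(tied)]
    trace <- rbind(trace, data.frame(assay = pick, m = unname(ms[pick]),
                                     stringsAsFactors = FALSE))
    ranking <- c(ranking, pick)
    current <- setdiff(current, pick)
  }
  # final pair: higher full-set M first, most stable assay last; ties by id
  pair <- rev(current[order(m_full[current], current)])
  ranking <- c(ranking, pair)
  structure(
    list(assay_ids = assays, m_values = m_full, ranking = ranking,
         exclusion_trace = trace, final_pair_tied = TRUE),
    class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result>\n")
  cat("  ranking (least -> most stable):",
      paste(x$ranking, collapse = " > "), "\n")
  cat("  full-set M:",
      paste(sprintf("%s=%.3f", names(x$m_values), x$m_values), collapse = " "),
      "\n")
  invisible(x)
}

#' Per-sample normalization factor for a set of reference assays
#'
#' The geometric mean, per sample, of the selected assays' relative
#' quantities. With a single assay this is that assay's quantity vector.
#'
#' @param q a [quantity_matrix()].
#' @param assays non-empty character vector of assay ids.
#' @return a positive named numeric vector, one value per sample.
#' @export
normalization_factor <- function(q, assays) {
  stopifnot(inherits(q, "quantity_matrix"))
  if (length(assays) == 0) stop("`assays` must be non-empty", call. = FALSE)
  missing <- setdiff(assays, q$assay_ids)
  if (length(missing)) {
    stop(sprintf("unknown assay(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  sub <- q$q[assays, , drop = FALSE]
  exp(colMeans(log(sub)))
}

#' Sequential normalization-factor curve and V-values
#'
#' Starting from the two most stable assays of `ranking` and adding the
#' next most stable one at each step, computes the normalization factor
#' NF_n (geometric mean of the n best assays) and the pairwise variation
#' `V_{n,n+1} = sd(log2(NF_n / NF_{n+1}))` between sequential factors.
#' The smallest n whose V falls below `cutoff` (default 0.15) is the
#' recommended number of reference assays; if no V does, all assays are
#' recommended.
#'
#' @param q a [quantity_matrix()] with >= 3 assays.
#' @param ranking a `stability_result` for `q` (or a character ranking,
#'   least stable first).
#' @param cutoff V-value threshold below which adding another reference
#'   assay brings no benefit; the published default is 0.15.
#' @return an `nf_curve` with fields `nf` (list NF_2 ... NF_k),
#'   `v_values` (named vector, names `"2"` ... `"k-1"`), `recommended_n`
#'   and `cutoff`.
#' @export
v_curve <- function(q, ranking, cutoff = 0.15) {
  stopifnot(inherits(q, "quantity_matrix"))
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  rk <- if (inherits(ranking, "stability_result")) ranking$ranking else ranking
  if (!setequal(rk, q$assay_ids) || length(rk) != length(q$assay_ids)) {
    stop("`ranking` must be a permutation of the matrix assays", call. = FALSE)
  }
  k <- length(rk)
  if (k < 3) stop("V-curve needs >= 3 assays", call. = FALSE)
  stable_first <- rev(rk)
  nf <- lapply(2:k, function(n) normalization_factor(q, stable_first[1:n]))
  names(nf) <- as.character(2:k)
  v <- vapply(2:(k - 1), function(n) {
    stats::sd(log2(nf[[as.character(n)]] / nf[[as.character(n + 1)]]))
  }, numeric(1))
  names(v) <- as.character(2:(k - 1))
  below <- which(v < cutoff)
  recommended_n <- if (length(below)) as.integer(names(v)[below[1]]) else k
  structure(list(nf = nf, v_values = v, recommended_n = recommended_n,
                 cutoff = cutoff),
            class = "nf_curve")
}

#' @export
print.nf_curve <- function(x, ...) {
  cat("<nf_curve>\n  V:",
      paste(sprintf("V%s/%d=%.4f", names(x$v_values),
                    as.integer(names(x$v_values)) + 1L, x$v_values),
            collapse = " "), "\n")
  cat(sprintf("  recommended number of reference assays: %d (cutoff %.2f)\n",
              x$recommended_n, x$cutoff))
  invisible(x)
}
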