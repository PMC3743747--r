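# Synthetic qPCR generator with known ground-truth stability structure,
# and the closed-form expected-M oracle for the simulation model.
#
# Model (all noise in log2 units):
#   x[g, s] = mu_g * 2^(c_s) * 2^(delta_g * treated[s]) * 2^(eps_gs)
# with c_s ~ N(0, sigma_content^2) shared by all genes of sample s (the
# global mRNA-content factor) and eps_gs ~ N(0, sigma_g^2) independent
# gene-specific stability noise. The Cq view is cq = offset_g - log2(x)
# at efficiency 2, with offsets placing Cq in a realistic 15-35 window.

#' Simulation configuration
#'
#' Defaults emulate one perturbation experiment of a multi-experiment
#' reference-gene screen: 11 candidate assays measured across 22 samples
#' (418 samples spread over 19 experiments), gene stability noise
#' sigma_g spanning 0.1-0.5 log2 units (producing M-values in the range
#' published screens report), a sample-specific mRNA-content factor with
#' SD 0.5 log2 units, and half of the samples treated.
#'
#' @param n_genes number of candidate reference assays.
#' @param n_samples number of samples.
#' @param mu per-gene baseline expression on the linear scale (> 0);
#'   scalar recycled.
#' @param sigma per-gene stability noise SD in log2 units (>= 0); scalar
#'   recycled. Defaults to an even grid on [0.1, 0.5].
#' @param sigma_content SD (log2) of the shared per-sample mRNA-content
#'   factor. It cancels in all expression ratios, so it moves quantities
#'   without moving any stability statistic.
#' @param perturbed named numeric vector: gene id -> treatment effect
#'   delta (log2 fold-change) applied to treated samples.
#' @param treated_fraction fraction of samples treated (first
#'   `round(f * n_samples)` samples).
#' @param seed RNG seed for [simulate_qpcr()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 11, n_samples = 22,
                       mu = 2^seq(6, 12, length.out = n_genes),
                       sigma = seq(0.1, 0.5, length.out = n_genes),
                       sigma_content = 0.5,
                       perturbed = numeric(0),
                       treated_fraction = 0.5,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_samples <- as.integer(n_samples)
  if (n_genes < 2 || n_samples < 2) {
    stop("need at least 2 genes and 2 samples", call. = FALSE)
  }
  mu <- rep_len(as.numeric(mu), n_genes)
  sigma <- rep_len(as.numeric(sigma), n_genes)
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma < 0)) stop("sigma must be >= 0",
                                                     call. = FALSE)
  if (sigma_content < 0) stop("sigma_content must be >= 0", call. = FALSE)
  if (treated_fraction < 0 || treated_fraction > 1) {
    stop("treated_fraction must lie in [0, 1]", call. = FALSE)
  }
  gene_ids <- sprintf("gene%02d", seq_len(n_genes))
  names(mu) <- names(sigma) <- gene_ids
  perturbed <- as.numeric(perturbed) |> stats::setNames(names(perturbed))
  if (length(perturbed)) {
    bad <- setdiff(names(perturbed), gene_ids)
    if (length(bad)) stop(sprintf("perturbed names not in gene set: %s",
                                  paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(n_genes = n_genes, n_samples = n_samples, mu = mu,
                 sigma = sigma, sigma_content = sigma_content,
                 perturbed = perturbed, treated_fraction = treated_fraction,
                 seed = seed, gene_ids = gene_ids),
            class = "sim_config")
}

#' Simulate one qPCR experiment with known stability structure
#'
#' Draws the model described in [sim_config()] and returns both matrix
#' views (quantities and Cq at efficiency 2) plus the ground truth: the
#' noise draws, which samples were treated, and the true stability order
#' (genes sorted by sigma ascending, with perturbed genes ranked below
#' all unperturbed ones regardless of sigma).
#'
#' @param config a [sim_config()].
#' @return a `synthetic_dataset` with fields `quantities`
#'   ([quantity_matrix()]), `cq` ([cq_matrix()]), `config`,
#'   `true_stability_order`, `treated_samples` and `truth` (sigma, delta,
#'   per-sample content factors, seed).
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genes
  s <- config$n_samples
  sample_ids <- sprintf("sample%02d", seq_len(s))
  n_treated <- round(config$treated_fraction * s)
  treated <- c(rep(1, n_treated), rep(0, s - n_treated))
  delta <- stats::setNames(rep(0, g), config$gene_ids)
  if (length(config$perturbed)) delta[names(config$perturbed)] <- config$perturbed

  # draw standard normals and scale explicitly: rnorm(n, sd = 0) consumes
  # no RNG draws, which would decouple paired runs differing only in a SD
  draws <- with_seed(config$seed, {
    list(content = stats::rnorm(s) * config$sigma_content,
         eps = matrix(stats::rnorm(g * s), g, s) * config$sigma)
  })
  log2x <- log2(config$mu) + outer(rep(1, g), draws$content) +
    outer(delta, treated) + draws$eps
  # per-gene Cq offsets put simulated Cq in a realistic 15-35 window
  offset <- 25 + log2(config$mu)
  cqm <- offset - log2x
  dimnames(cqm) <- list(config$gene_ids, sample_ids)
  cq <- cq_matrix(cqm, efficiency = 2)
  is_pert <- config$gene_ids %in% names(config$perturbed)
  true_order <- config$gene_ids[order(is_pert, config$sigma, seq_len(g))]
  structure(
    list(quantities = cq_to_quantity(cq), cq = cq, config = config,
         true_stability_order = true_order,
         treated_samples = sample_ids[treated == 1],
         truth = list(sigma = config$sigma, delta = delta,
                      content = stats::setNames(draws$content, sample_ids),
                      seed = config$seed)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genes x %d samples (seed %s)\n",
              x$config$n_genes, x$config$n_samples, format(x$config$seed)))
  cat("  true stability order:",
      paste(utils::head(x$true_stability_order, 5), collapse = " > "),
      if (x$config$n_genes > 5) "..." else "", "\n")
  invisible(x)
}

#' Closed-form expected M-value under the simulation model
#'
#' For independent Gaussian log2 noise, the log2 ratio of genes j and k
#' has SD `sqrt(sigma_j^2 + sigma_k^2)`, so the expected M of gene j
#' within the full panel is `mean over k != j of sqrt(sigma_j^2 +
#' sigma_k^2)`. Valid for unperturbed genes (a treatment shift adds a
#' bimodal component the closed form does not cover).
#'
#' @param config a [sim_config()].
#' @param gene_j gene id (must be unperturbed).
#' @return the expected M in log2 units.
#' @export
expected_m <- function(config, gene_j) {
  stopifnot(inherits(config, "sim_config"))
  if (!gene_j %in% config$gene_ids) stop("unknown gene", call. = FALSE)
  if (gene_j %in% names(config$perturbed)) {
    stop("closed form only covers unperturbed genes", call. = FALSE)
  }
  sj <- config$sigma[[gene_j]]
  others <- config$sigma[setdiff(config$gene_ids, gene_j)]
  mean(sqrt(sj^2 + others^2))
}

#' Simulate a suite of related experiments
#'
#' Emulates a multi-experiment screen: each experiment draws its own
#' data from `base` with the per-gene sigma vector jittered
#' multiplicatively (`sigma * 2^N(0, heterogeneity^2)`), so all
#' experiments share the same underlying stability tendency while
#' disagreeing in detail -- the situation cross-experiment rank
#' aggregation is designed for.
#'
#' @param base a [sim_config()].
#' @param n_experiments number of datasets.
#' @param heterogeneity SD (log2) of the per-experiment sigma jitter;
#'   0 makes all experiments identically distributed.
#' @param seed master seed; per-experiment seeds are derived from it.
#' @return a list of `synthetic_dataset` objects.
#' @export
simulate_experiment_suite <- function(base, n_experiments = 19,
                                      heterogeneity = 0.2, seed = 1L) {
  stopifnot(inherits(base, "sim_config"))
  if (n_experiments < 1) stop("n_experiments must be >= 1", call. = FALSE)
  if (heterogeneity < 0) stop("heterogeneity must be >= 0", call. = FALSE)
  setup <- with_seed(seed, {
    list(seeds = sample.int(2^31 - 1, n_experiments),
         jitter = matrix(stats::rnorm(n_experiments * base$n_genes,
                                      0, heterogeneity),
                         n_experiments, base$n_genes))
  })
  lapply(seq_len(n_experiments), function(e) {
    cfg <- base
    cfg$sigma <- base$sigma * 2^setup$jitter[e, ]
    cfg$seed <- setup$seeds[e]
    simulate_qpcr(cfg)
  })
}
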