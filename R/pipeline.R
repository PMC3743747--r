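# End-to-end orchestration: per-experiment stability analysis,
# cross-experiment aggregation, reports, and the command-line interface.

fmt6 <- function(x) signif(x, 6)

#' Run the stability analysis for one experiment
#'
#' Reads or accepts a measurement matrix, converts Cq input to relative
#' quantities, computes the stepwise stability ranking and the
#' sequential V-curve, and (optionally) writes a dual-format report:
#' a human-readable summary plus machine-readable TSV records. All real
#' numbers in reports carry 6 significant digits.
#'
#' @param input a [quantity_matrix()], [cq_matrix()], or a file path.
#' @param value_kind `"quantity"` or `"cq"`; used when `input` is a path.
#' @param efficiency per-assay efficiency for Cq input.
#' @param v_cutoff V-value cutoff (default 0.15).
#' @param out_dir if non-NULL, reports are written here.
#' @param label experiment label used in report file names and messages.
#' @return a list with components `stability` (a `stability_result`) and
#'   `nf_curve` (an `nf_curve`).
#' @export
run_stability <- function(input, value_kind = c("quantity", "cq"),
                          efficiency = 2, v_cutoff = 0.15, out_dir = NULL,
                          label = "experiment") {
  value_kind <- match.arg(value_kind)
  q <- tryCatch({
    if (is.character(input)) {
      input <- read_matrix(input, value_kind = value_kind,
                           efficiency = efficiency)
    }
    if (inherits(input, "cq_matrix")) {
      if (!is.null(input$replicate_groups)) input <- average_replicates(input)
      cq_to_quantity(input)
    } else if (inherits(input, "quantity_matrix")) {
      input
    } else stop("unsupported input type", call. = FALSE)
  }, error = function(e) {
    stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE)
  })
  stab <- rank_stepwise(q)
  curve <- v_curve(q, stab, cutoff = v_cutoff)
  if (!is.null(out_dir)) write_stability_report(stab, curve, out_dir, label)
  list(stability = stab, nf_curve = curve)
}

write_stability_report <- function(stab, curve, out_dir, label) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rank_pos <- match(names(stab$m_values), rev(stab$ranking))
  excl_step <- match(names(stab$m_values), stab$exclusion_trace$assay)
  records <- data.frame(
    assay = names(stab$m_values),
    m_full = fmt6(unname(stab$m_values)),
    stability_rank = rank_pos,           # 1 = most stable
    exclusion_step = ifelse(is.na(excl_step), "", excl_step))
  utils::write.table(records,
                     file.path(out_dir, paste0(label, "_stability.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vrec <- data.frame(n = as.integer(names(curve$v_values)),
                     v = fmt6(unname(curve$v_values)))
  utils::write.table(vrec, file.path(out_dir, paste0(label, "_vcurve.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- c(sprintf("Stability report: %s", label),
           sprintf("ranking (least -> most stable): %s",
                   paste(stab$ranking, collapse = " > ")),
           sprintf("recommended number of reference assays: %d (cutoff %s)",
                   curve$recommended_n, format(curve$cutoff)))
  writeLines(txt, file.path(out_dir, paste0(label, "_summary.txt")))
  invisible(NULL)
}

#' Aggregate per-experiment stability results into a consensus
#'
#' Accepts either an [mvalue_table()] or a named list of
#' `stability_result` objects (whose full-set M-values are assembled
#' into a table). All experiments must cover the same assay set; any
#' mismatch is a validation error naming the offending assays.
#'
#' @param x an `mvalue_table` or list of `stability_result`s.
#' @param method `"ce"`, `"borda"` or `"brute"`.
#' @param params optional [ce_params()].
#' @param out_dir if non-NULL, a consensus report is written here.
#' @return an `aggregation_result`.
#' @export
run_aggregation <- function(x, method = c("ce", "borda", "brute"),
                            params = NULL, out_dir = NULL) {
  method <- match.arg(method)
  if (!inherits(x, "mvalue_table")) {
    if (!is.list(x) || !length(x) ||
        !all(vapply(x, inherits, logical(1), "stability_result"))) {
      stop("`x` must be an mvalue_table or a list of stability_result objects",
           call. = FALSE)
    }
    ref <- sort(x[[1]]$assay_ids)
    for (i in seq_along(x)) {
      ids <- x[[i]]$assay_ids
      if (!setequal(ids, ref)) {
        diff <- c(setdiff(ref, ids), setdiff(ids, ref))
        stop(sprintf("assay-set mismatch in experiment %s: %s",
                     names(x)[i] %||% i, paste(diff, collapse = ", ")),
             call. = FALSE)
      }
    }
    labels <- names(x) %||% sprintf("exp%02d", seq_along(x))
    m <- t(vapply(x, function(r) r$m_values[ref], numeric(length(ref))))
    rownames(m) <- labels
    x <- mvalue_table(m)
  }
  res <- aggregate_table(x, method = method, params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rec <- data.frame(position = seq_along(res$consensus),
                      assay = res$consensus)
    utils::write.table(rec, file.path(out_dir, "consensus.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    meta <- c(sprintf("method\t%s", res$method),
              sprintf("objective\t%s", fmt6(res$objective)),
              sprintf("seed\t%s", format(res$seed %||% NA)),
              if (length(res$trace))
                sprintf("trace\t%s", paste(fmt6(res$trace), collapse = ",")))
    writeLines(meta, file.path(out_dir, "consensus_meta.tsv"))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-command reproduction of the packaged multi-experiment screen
#'
#' Loads the packaged 19 x 11 M-value table, aggregates it with the
#' cross-entropy optimizer (Borda computed alongside for comparison) and
#' summarizes: the consensus order, the consensus position of the
#' Alu-repeat assay, and each assay's mean M across the 19 experiments.
#'
#' @param seed RNG seed for the cross-entropy run.
#' @param params optional [ce_params()] (its seed is overridden by
#'   `seed`).
#' @return a list with `consensus` (the CE `aggregation_result`),
#'   `borda`, `alu_position`, and `mean_m` (named, sorted ascending).
#' @export
reproduce_table1 <- function(seed = 1L, params = NULL) {
  tab <- load_table1_fixture()
  if (is.null(params)) params <- ce_params(k = ncol(tab$m))
  params$seed <- seed
  ce <- aggregate_table(tab, method = "ce", params = params)
  borda <- aggregate_table(tab, method = "borda")
  mean_m <- sort(colMeans(tab$m))
  out <- list(consensus = ce, borda = borda,
              alu_position = match("Alu-Sq", ce$consensus),
              mean_m = mean_m)
  class(out) <- "table1_reproduction"
  out
}

#' @export
print.table1_reproduction <- function(x, ...) {
  cat("Consensus over 19 perturbation experiments (cross-entropy):\n  ",
      paste(x$consensus$consensus, collapse = " > "), "\n", sep = "")
  cat(sprintf("Alu-Sq consensus position: %d\n", x$alu_position))
  cat(sprintf("objective: CE %.6g vs Borda %.6g (seed %s)\n",
              x$consensus$objective, x$borda$objective,
              format(x$consensus$seed)))
  cat("mean M across experiments (ascending):\n")
  cat(paste(sprintf("  %-7s %.3f", names(x$mean_m), x$mean_m),
            collapse = "\n"), "\n")
  invisible(x)
}

# ---- command-line interface -------------------------------------------------
# Subcommands: simulate, stability, aggregate, reproduce-table1, version.
# Exit codes: 0 success, 2 validation/usage error, 3 I/O error.

cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a),
                                   call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `stability`, `aggregate`,
#' `reproduce-table1` and `version`. Designed to be called from the
#' wrapper script installed under `inst/cli/refstab`; errors are printed
#' to standard error and converted to exit codes (0 success, 2
#' validation error, 3 I/O error).
#'
#' @param args character vector of command-line arguments.
#' @return the exit code, invisibly.
#' @export
refstab_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: refstab <command> [options]",
    "  simulate         --out PREFIX [--n-genes N] [--n-samples N] [--seed S]",
    "  stability        --input FILE [--value-kind cq|quantity]",
    "                   [--efficiency E] [--v-cutoff V] [--out DIR] [--label L]",
    "  aggregate        --table FILE [--method ce|borda|brute] [--seed S]",
    "                   [--out DIR]",
    "  reproduce-table1 [--seed S]",
    "  version", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[[1]]
  status <- tryCatch({
    opts <- cli_opts(args[-1])
    switch(cmd,
      version = { cat("refstab", as.character(utils::packageVersion("refstab")), "\n"); 0L },
      simulate = {
        if (is.null(opts$out)) stop("--out PREFIX is required", call. = FALSE)
        cfg <- sim_config(
          n_genes = as.integer(opts[["n-genes"]] %||% 11),
          n_samples = as.integer(opts[["n-samples"]] %||% 22),
          seed = as.integer(opts$seed %||% 1))
        ds <- simulate_qpcr(cfg)
        write_matrix(ds$cq, paste0(opts$out, "_cq.tsv"))
        write_matrix(ds$quantities, paste0(opts$out, "_quantities.tsv"))
        truth <- data.frame(gene = cfg$gene_ids,
                            sigma = fmt6(unname(cfg$sigma)),
                            delta = fmt6(unname(ds$truth$delta)))
        utils::write.table(truth, paste0(opts$out, "_truth.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        message(sprintf("simulated %d x %d dataset (seed %d)",
                        cfg$n_genes, cfg$n_samples, cfg$seed))
        0L
      },
      stability = {
        if (is.null(opts$input)) stop("--input FILE is required", call. = FALSE)
        res <- run_stability(opts$input,
                             value_kind = opts[["value-kind"]] %||% "quantity",
                             efficiency = as.numeric(opts$efficiency %||% 2),
                             v_cutoff = as.numeric(opts[["v-cutoff"]] %||% 0.15),
                             out_dir = opts$out,
                             label = opts$label %||% "experiment")
        print(res$stability); print(res$nf_curve)
        0L
      },
      aggregate = {
        if (is.null(opts$table)) stop("--table FILE is required", call. = FALSE)
        df <- utils::read.delim(opts$table, check.names = FALSE)
        m <- as.matrix(df[, -1]); rownames(m) <- df[[1]]
        tab <- mvalue_table(m)
        method <- opts$method %||% "ce"
        params <- if (method == "ce")
          ce_params(k = ncol(m), seed = as.integer(opts$seed %||% 1)) else NULL
        res <- run_aggregation(tab, method = method, params = params,
                               out_dir = opts$out)
        print(res)
        0L
      },
      `reproduce-table1` = {
        print(reproduce_table1(seed = as.integer(opts$seed %||% 1)))
        0L
      },
      { message(sprintf("unknown command '%s'", cmd)); message(usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("file not found|cannot open", conditionMessage(e))) 3L else 2L
  })
  invisible(status)
}
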