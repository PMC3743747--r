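# Data model and I/O for wide-format qPCR measurement matrices
# (rows = assays, columns = samples).

#' Construct a Cq matrix
#'
#' A `cq_matrix` holds quantification cycles (Cq) for a set of assays
#' (rows) measured across samples or raw wells (columns), together with a
#' per-assay amplification efficiency `E` (fold amplification per cycle;
#' `E = 2` is perfect doubling).
#'
#' Missing wells (`NA`) are only permitted while `replicate_groups` maps
#' raw wells to samples; after [average_replicates()] the matrix must be
#' complete.
#'
#' @param cq numeric matrix of quantification cycles with assay row names
#'   and sample (or well) column names.
#' @param efficiency per-assay amplification efficiency; a scalar is
#'   recycled. Must satisfy `1 < E <= 2`.
#' @param replicate_groups optional named character vector mapping each
#'   column (well) of `cq` to a sample id; `NULL` means columns already
#'   are samples.
#' @return an object of class `cq_matrix`.
#' @seealso [cq_to_quantity()], [average_replicates()], [read_matrix()]
#' @export
cq_matrix <- function(cq, efficiency = 2, replicate_groups = NULL) {
  cq <- as.matrix(cq)
  if (!is.numeric(cq)) stop("`cq` must be numeric", call. = FALSE)
  assay_ids <- rownames(cq)
  well_ids <- colnames(cq)
  if (is.null(assay_ids) || is.null(well_ids)) {
    stop("`cq` must carry assay row names and sample column names", call. = FALSE)
  }
  check_unique_ids(assay_ids, "assay")
  check_unique_ids(well_ids, if (is.null(replicate_groups)) "sample" else "well")
  efficiency <- rep_len(as.numeric(efficiency), nrow(cq))
  names(efficiency) <- assay_ids
  if (any(!is.finite(efficiency)) || any(efficiency <= 1) || any(efficiency > 2)) {
    stop("amplification efficiency must satisfy 1 < E <= 2", call. = FALSE)
  }
  if (is.null(replicate_groups)) {
    if (any(!is.finite(cq))) {
      stop("Cq values must be finite; missing wells require `replicate_groups`",
           call. = FALSE)
    }
  } else {
    if (is.null(names(replicate_groups)) ||
        !all(well_ids %in% names(replicate_groups))) {
      stop("`replicate_groups` must name every well column", call. = FALSE)
    }
    replicate_groups <- replicate_groups[well_ids]
    if (any(is.infinite(cq) | is.nan(cq))) {
      stop("Cq values must be finite or NA", call. = FALSE)
    }
  }
  structure(
    list(assay_ids = assay_ids,
         sample_ids = if (is.null(replicate_groups)) well_ids else
           unique(unname(replicate_groups)),
         cq = cq, efficiency = efficiency,
         replicate_groups = replicate_groups),
    class = "cq_matrix")
}

#' Construct a relative-quantity matrix
#'
#' Linear-scale relative quantities, strictly positive and finite. Values
#' are defined up to a per-assay scale factor; the [cq_to_quantity()]
#' convention scales each assay so its maximum over samples is 1.
#'
#' @param q numeric matrix (assays x samples) of relative quantities with
#'   dimnames.
#' @return an object of class `quantity_matrix`.
#' @export
quantity_matrix <- function(q) {
  q <- as.matrix(q)
  if (!is.numeric(q)) stop("`q` must be numeric", call. = FALSE)
  if (is.null(rownames(q)) || is.null(colnames(q))) {
    stop("`q` must carry assay row names and sample column names", call. = FALSE)
  }
  check_unique_ids(rownames(q), "assay")
  check_unique_ids(colnames(q), "sample")
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("relative quantities must be strictly positive and finite", call. = FALSE)
  }
  structure(list(assay_ids = rownames(q), sample_ids = colnames(q), q = q),
            class = "quantity_matrix")
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicated %s id(s): %s", what, paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("<cq_matrix> %d assays x %d %s\n", nrow(x$cq), ncol(x$cq),
              if (is.null(x$replicate_groups)) "samples" else "wells"))
  cat("  assays:", paste(utils::head(x$assay_ids, 6), collapse = ", "),
      if (length(x$assay_ids) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat(sprintf("<quantity_matrix> %d assays x %d samples\n",
              nrow(x$q), ncol(x$q)))
  invisible(x)
}

#' Read a wide-format qPCR matrix from a delimited text file
#'
#' The expected layout is the field's usual wide export: row 1 holds
#' sample ids, column 1 holds assay ids, cells are numeric. Parse errors
#' report the offending row and column.
#'
#' @param path path to a TSV/CSV file.
#' @param value_kind `"cq"` for quantification cycles or `"quantity"` for
#'   linear relative quantities.
#' @param sep field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param efficiency per-assay efficiency for `value_kind = "cq"`.
#' @param replicate_groups optional well-to-sample map (see
#'   [cq_matrix()]); empty cells are only allowed for Cq input with
#'   replicate groups.
#' @return a [cq_matrix()] or [quantity_matrix()].
#' @export
read_matrix <- function(path, value_kind = c("quantity", "cq"), sep = NULL,
                        efficiency = 2, replicate_groups = NULL) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("matrix file needs a header and >= 1 assay row",
                              call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1]]
  sample_ids <- trimws(header[-1])
  ncols <- length(sample_ids)
  assay_ids <- character(length(cells) - 1)
  m <- matrix(NA_real_, nrow = length(cells) - 1, ncol = ncols)
  allow_empty <- value_kind == "cq" && !is.null(replicate_groups)
  for (i in seq_along(assay_ids)) {
    row <- cells[[i + 1]]
    assay_ids[i] <- trimws(row[[1]])
    vals <- trimws(row[-1])
    length(vals) <- ncols  # pad short rows with NA
    for (j in seq_len(ncols)) {
      v <- vals[[j]]
      if (is.na(v) || !nzchar(v)) {
        if (!allow_empty) {
          stop(sprintf("empty cell at row %d (%s), column %d (%s)",
                       i + 1, assay_ids[i], j + 1, sample_ids[j]), call. = FALSE)
        }
        next
      }
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) {
        stop(sprintf("non-numeric cell '%s' at row %d (%s), column %d (%s)",
                     v, i + 1, assay_ids[i], j + 1, sample_ids[j]), call. = FALSE)
      }
      m[i, j] <- num
    }
  }
  dimnames(m) <- list(assay_ids, sample_ids)
  if (value_kind == "cq") {
    cq_matrix(m, efficiency = efficiency, replicate_groups = replicate_groups)
  } else {
    quantity_matrix(m)
  }
}

#' Write a qPCR matrix in the wide text format
#'
#' Values are written with the C `%.15g` format so that
#' `read_matrix(write_matrix(x))` round-trips them exactly.
#'
#' @param m a `cq_matrix` or `quantity_matrix`.
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  mat <- if (inherits(m, "cq_matrix")) m$cq else if (inherits(m, "quantity_matrix"))
    m$q else stop("`m` must be a cq_matrix or quantity_matrix", call. = FALSE)
  header <- paste(c("assay", colnames(mat)), collapse = sep)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    vals <- vapply(mat[i, ], function(v)
      if (is.na(v)) "" else sprintf("%.15g", v), character(1))
    paste(c(rownames(mat)[i], vals), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Average technical replicates on the Cq scale
#'
#' Collapses raw wells to samples by arithmetic mean of the available
#' replicate Cq values (averaging on the cycle scale, as the qbase
#' framework does). Every (assay, sample) pair must retain at least one
#' non-missing well.
#'
#' @param m a [cq_matrix()] with `replicate_groups`.
#' @return a complete `cq_matrix` whose columns are samples.
#' @export
average_replicates <- function(m) {
  stopifnot(inherits(m, "cq_matrix"))
  if (is.null(m$replicate_groups)) {
    stop("`m` has no replicate_groups; nothing to average", call. = FALSE)
  }
  groups <- m$replicate_groups
  sample_ids <- unique(unname(groups))
  out <- matrix(NA_real_, nrow = nrow(m$cq), ncol = length(sample_ids),
                dimnames = list(m$assay_ids, sample_ids))
  for (s in sample_ids) {
    wells <- names(groups)[groups == s]
    block <- m$cq[, wells, drop = FALSE]
    n_ok <- rowSums(!is.na(block))
    if (any(n_ok == 0)) {
      bad <- m$assay_ids[n_ok == 0][1]
      stop(sprintf("no non-missing replicate for assay '%s', sample '%s'",
                   bad, s), call. = FALSE)
    }
    out[, s] <- rowMeans(block, na.rm = TRUE)
  }
  cq_matrix(out, efficiency = m$efficiency)
}

#' Transform quantification cycles to relative quantities
#'
#' Applies the standard efficiency-corrected transform
#' `q[g, s] = E_g ^ (min_s' Cq[g, s'] - Cq[g, s])`, so that within each
#' assay the most expressed sample (lowest Cq) has quantity 1 and every
#' quantity lies in (0, 1]. All downstream stability statistics are
#' invariant to this per-assay scaling.
#'
#' @param m a complete [cq_matrix()] (replicates already averaged).
#' @return a [quantity_matrix()].
#' @export
cq_to_quantity <- function(m) {
  stopifnot(inherits(m, "cq_matrix"))
  if (!is.null(m$replicate_groups)) {
    stop("average replicates before converting to quantities", call. = FALSE)
  }
  q <- m$cq
  for (i in seq_len(nrow(q))) {
    q[i, ] <- m$efficiency[i]^(min(m$cq[i, ]) - m$cq[i, ])
  }
  quantity_matrix(q)
}

#' Construct an M-value table
#'
#' A complete experiments x assays matrix of geNorm M-values, the shape
#' in which multi-experiment stability screens are published.
#'
#' @param m numeric matrix with experiment row names and assay column
#'   names; all values finite and >= 0.
#' @param descriptions optional named character vector of experiment
#'   descriptions.
#' @return an object of class `mvalue_table`.
#' @export
mvalue_table <- function(m, descriptions = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("`m` needs experiment row names and assay column names", call. = FALSE)
  }
  check_unique_ids(rownames(m), "experiment")
  check_unique_ids(colnames(m), "assay")
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("M-values must be complete, finite and >= 0", call. = FALSE)
  }
  structure(list(experiment_ids = rownames(m), assay_ids = colnames(m), m = m,
                 descriptions = descriptions),
            class = "mvalue_table")
}

#' @export
print.mvalue_table <- function(x, ...) {
  cat(sprintf("<mvalue_table> %d experiments x %d assays\n",
              nrow(x$m), ncol(x$m)))
  print(utils::head(x$m, 4))
  if (nrow(x$m) > 4) cat("...\n")
  invisible(x)
}

# md5 of the packaged M-value fixture; guards against silent corruption.
TABLE1_MD5 <- "e601d210af3eb73e78846bc1f01e702d"

#' Load the packaged 19-experiment reference-gene M-value table
#'
#' Returns the published stability screen of 11 candidate reference
#' assays (Alu-Sq, TBP, HPRT1, YWHAZ, GAPDH, SDHA, HMBS, B2M, UBC, ACTB,
#' RPL13A) across 19 cancer-cell perturbation experiments labelled A-S,
#' exactly as printed, with the experiment descriptions attached.
#'
#' @return an [mvalue_table()] with 19 rows and 11 columns.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_mvalues.tsv", package = "refstab",
                      mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), TABLE1_MD5)) {
    stop("packaged M-value table failed its integrity check", call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  dpath <- system.file("extdata", "table1_experiments.tsv", package = "refstab",
                       mustWork = TRUE)
  dd <- utils::read.delim(dpath, check.names = FALSE)
  descriptions <- stats::setNames(dd$description, dd$experiment)
  mvalue_table(m, descriptions = descriptions)
}

#' Turn an M-value table into per-experiment ranked lists
#'
#' Each experiment's assays are sorted by ascending M-value (most stable
#' first); the per-assay weight carried along is its M-value. Ties are
#' broken by the table's printed column order, which keeps the result
#' deterministic.
#'
#' @param t an [mvalue_table()].
#' @return a list of [ranked_list()] objects, one per experiment.
#' @export
table_to_ranked_lists <- function(t) {
  stopifnot(inherits(t, "mvalue_table"))
  lapply(t$experiment_ids, function(e) {
    mv <- t$m[e, ]
    ord <- order(mv, seq_along(mv))  # column order breaks ties
    ranked_list(experiment_id = e, assays = t$assay_ids[ord],
                weights = unname(mv[ord]))
  })
}
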