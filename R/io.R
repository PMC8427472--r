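# Delimited-text readers/writers for the package's table formats.
# All files are UTF-8 CSV; lines beginning `#` are comments.

#' Write / read a dU/dlambda table
#'
#' Long-format CSV with columns `replica, window, lambda, step,
#' dhdl_kcal_mol`; `#`-comment lines are permitted and skipped on read.
#' A JSON sidecar (`<path>.meta.json`) records temperature, truth and
#' the lambda grid so a round trip preserves the ensemble's metadata.
#'
#' @param dhdl A `dhdl_ensemble` tibble.
#' @param path Output CSV path.
#' @return `write_dhdl()` returns `path` invisibly; `read_dhdl()` returns
#'   a validated `dhdl_ensemble`.
#' @export
write_dhdl <- function(dhdl, path) {
  readr::write_csv(tibble::as_tibble(dhdl), path)
  meta <- list(
    temperature = attr(dhdl, "temperature"),
    truth = attr(dhdl, "truth"),
    lambda = unique(dhdl$lambda)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dhdl
#' @param schedule Optional [lambda_schedule()] to cross-check the file's
#'   lambda grid against.
#' @export
read_dhdl <- function(path, schedule = NULL) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  req <- c("replica", "window", "lambda", "step", "dhdl_kcal_mol")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    abort(paste0("missing columns in ", path, ": ",
                 paste(miss, collapse = ", ")))
  }
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(sprintf("malformed rows in %s (first at line %d: %s)",
                  path, probs$row[1] + 1L, probs$expected[1]))
  }
  num_cols <- setdiff(req, "replica")
  for (cn in num_cols) {
    if (!is.numeric(df[[cn]])) {
      parsed <- suppressWarnings(as.numeric(df[[cn]]))
      bad_row <- which(is.na(parsed) & !is.na(df[[cn]]))
      abort(sprintf("non-numeric `%s` value in %s at data row %d",
                    cn, path, if (length(bad_row)) bad_row[1] else 1L))
    }
  }
  bad <- !stats::complete.cases(df[req])
  if (any(bad)) {
    abort(sprintf("missing values in %s at data row %d",
                  path, which(bad)[1]))
  }
  meta_path <- paste0(path, ".meta.json")
  temperature <- 298.15
  truth <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    temperature <- meta$temperature %||% temperature
    truth <- meta$truth
  }
  dhdl_ensemble(df, schedule = schedule, temperature = temperature,
                truth = truth)
}

#' Write / read a reduced-potential matrix
#'
#' Text format: one `# counts: n1,n2,...` header comment carrying the
#' per-state sample counts and a `# temperature:` line, then the K x N
#' matrix as CSV rows (one row per state).
#'
#' @param rp A [reduced_potential_set()].
#' @param path Output path.
#' @return `write_ukn()` returns `path` invisibly; `read_ukn()` a
#'   [reduced_potential_set()].
#' @export
write_ukn <- function(rp, path) {
  stopifnot(inherits(rp, "reduced_potential_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# counts: ", paste(rp$counts, collapse = ",")),
    paste0("# temperature: ", rp$temperature),
    if (!is.null(rp$truth)) paste0("# truth: ", format(rp$truth, digits = 17))
  ), con)
  utils::write.table(rp$u_kn, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_ukn
#' @export
read_ukn <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  counts_line <- grep("^# counts:", hdr, value = TRUE)
  if (length(counts_line) != 1) abort("missing `# counts:` header")
  counts <- as.integer(strsplit(sub("^# counts: *", "", counts_line),
                                ",")[[1]])
  temp_line <- grep("^# temperature:", hdr, value = TRUE)
  temperature <- if (length(temp_line)) {
    as.numeric(sub("^# temperature: *", "", temp_line[1]))
  } else 298.15
  truth_line <- grep("^# truth:", hdr, value = TRUE)
  truth <- if (length(truth_line)) {
    as.numeric(sub("^# truth: *", "", truth_line[1]))
  } else NULL
  body <- lines[!grepl("^#", lines)]
  u_kn <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
  reduced_potential_set(u_kn, counts, temperature = temperature,
                        truth = truth)
}

#' Write / read a ligand-pair table
#'
#' CSV with columns `pair_id, ddg_exp, ddg_exp_err, ddg_cal, ddg_cal_err,
#' rep1..repN`.
#'
#' @param pairs Pair tibble.
#' @param path Output path.
#' @return `write_pairs()` returns `path` invisibly; `read_pairs()` the
#'   tibble.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_csv(pairs, path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  req <- c("pair_id", "ddg_exp", "ddg_cal")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    abort(paste0("missing columns in ", path, ": ",
                 paste(miss, collapse = ", ")))
  }
  df
}

#' Write free-energy estimates as a flat CSV
#'
#' One row per estimate: `pair_id, method, value, error, replica_sd,
#' n_replicas`.
#'
#' @param estimates Named list of [fe_estimate()] objects (names become
#'   `pair_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  rows <- purrr::imap_dfr(estimates, function(e, id) {
    g <- glance(e)
    tibble::tibble(pair_id = id, method = g$method, value = g$value,
                   error = g$error, replica_sd = g$replica_sd,
                   n_replicas = g$n_replicas)
  })
  readr::write_csv(rows, path)
  invisible(path)
}

#' Serialise an evaluation report to JSON
#'
#' The JSON carries a `schema_version` field, the package version, the
#' seed, and every statistic of the report. Identical inputs produce
#' byte-identical files (no timestamps).
#'
#' @param report An `eval_report` from [evaluate_pairs()].
#' @param path Output path.
#' @param seed Seed to record.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, seed = NULL) {
  payload <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("alchemble")),
    seed = seed,
    n_pairs = report$n_pairs,
    metrics = report$metrics,
    regression = report$regression,
    bins = report$bins,
    settings = report$settings
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows", pretty = TRUE)
  invisible(path)
}
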