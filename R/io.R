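#' Read a subject-indexed block table
#'
#' Reads a TSV/CSV table whose first column is `subject_id` (unique IDs) and
#' whose remaining columns are features (`sites` tables: a single site
#' column; `quality`: a single numeric score column). Empty cells and "NA"
#' are parsed as missing, never as zero.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param role One of `"imaging"`, `"nonimaging"`, `"sites"`, `"quality"`.
#' @return For matrix roles, a numeric matrix with subject rownames; for
#'   `"sites"` a named factor; for `"quality"` a named numeric vector.
#' @export
read_block_table <- function(path,
                             role = c("imaging", "nonimaging", "sites",
                                      "quality")) {
  role <- match.arg(role)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NA", ""), check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "subject_id")
    stop("expected a header with first column 'subject_id' in ", path)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated subject_id in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  if (role == "sites") {
    f <- factor(as.character(body[[1]]))
    names(f) <- ids
    return(f)
  }
  bad <- names(body)[!vapply(body, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric cells in numeric column(s) of ", path, ": ",
         paste(bad, collapse = ", "))
  if (role == "quality") {
    v <- body[[1]]
    names(v) <- ids
    return(v)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (role == "imaging" && anyNA(m))
    stop("missing values in imaging block ", path,
         "; only non-imaging features may contain NA")
  m
}

write_table_with_ids <- function(m, path) {
  df <- data.frame(subject_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic cohort in the standard dataset layout
#'
#' Emits `imaging.tsv`, `nonimaging.tsv`, `sites.tsv`, `quality.tsv`,
#' optional `imaging_followup.tsv` / `nonimaging_followup.tsv`, and
#' `truth.json` (true weights, supports, canonical correlations, seed) into
#' a directory. Tables are TSV with a header row and `subject_id` first.
#'
#' @param generated Output of [generate_linked_blocks()] or
#'   [generate_longitudinal_pair()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  longitudinal <- !is.null(generated$baseline)
  data <- if (longitudinal) generated$baseline else generated$data
  truth <- generated$truth
  files <- c(imaging = "imaging.tsv", nonimaging = "nonimaging.tsv")
  write_table_with_ids(data$X, file.path(dir, "imaging.tsv"))
  write_table_with_ids(data$Y, file.path(dir, "nonimaging.tsv"))
  utils::write.table(
    data.frame(subject_id = data$subject_id, site = as.character(data$sites)),
    file.path(dir, "sites.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(subject_id = data$subject_id, quality = data$quality),
    file.path(dir, "quality.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  written <- c("imaging.tsv", "nonimaging.tsv", "sites.tsv", "quality.tsv")
  if (longitudinal) {
    write_table_with_ids(generated$followup$X,
                         file.path(dir, "imaging_followup.tsv"))
    write_table_with_ids(generated$followup$Y,
                         file.path(dir, "nonimaging_followup.tsv"))
    written <- c(written, "imaging_followup.tsv", "nonimaging_followup.tsv")
  }
  spec <- truth$spec
  jsonlite::write_json(list(
    seed = spec$seed, n_modes = spec$n_modes,
    target_r = spec$target_r,
    support_x = spec$support_x, support_y = spec$support_y,
    true_weights_x = truth$true_weights_x,
    true_weights_y = truth$true_weights_y,
    signal_scale = truth$signal_scale
  ), file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  written <- c(written, "truth.json")
  invisible(file.path(dir, written))
}

#' Write the machine-readable run report and its table views
#'
#' Emits `report.json` (the source of truth), `weights.tsv` and
#' `cross_loadings.tsv` (per-variable weight, cross-loading and the
#' strict `|loading| > threshold` reported flag), `inference.json`,
#' `permutations.tsv`, `tuning_grid.tsv`, `robustness_report.json` when
#' robustness was run, and `run_log.txt` (R version, seed, config echo).
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  written <- character(0)
  add <- function(p) written <<- c(written, p)

  vt <- report$variable_table
  w <- vt[, c("variable", "block", "weight", "reported")]
  utils::write.table(w, file.path(outdir, "weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add("weights.tsv")
  cl <- vt[, c("variable", "block", "cross_loading", "reported")]
  utils::write.table(cl, file.path(outdir, "cross_loadings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add("cross_loadings.tsv")

  utils::write.table(data.frame(permuted_r = report$permutation$permuted_r),
                     file.path(outdir, "permutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add("permutations.tsv")
  utils::write.table(report$tuning$fit_table,
                     file.path(outdir, "tuning_grid.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add("tuning_grid.tsv")

  inference <- list(observed_r = report$r,
                    exact_p = report$exact_p,
                    fdr_adjusted_p = report$fdr_adjusted_p,
                    mean_permuted = report$permutation$mean_permuted,
                    sd_permuted = report$permutation$sd_permuted,
                    n_perm = report$permutation$n_perm)
  jsonlite::write_json(inference, file.path(outdir, "inference.json"),
                       digits = NA, auto_unbox = TRUE)
  add("inference.json")

  if (!is.null(report$robustness)) {
    rb <- report$robustness
    jsonlite::write_json(list(
      rr_median = rb$rr_median,
      test_train_ratio = rb$test_train_ratio,
      quality_rho = rb$quality_rho,
      pass_flags = rb$pass_flags
    ), file.path(outdir, "robustness_report.json"), digits = NA,
    auto_unbox = TRUE)
    add("robustness_report.json")
    if (!is.null(rb$stability)) {
      utils::write.table(rb$stability, file.path(outdir, "stability.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      add("stability.tsv")
    }
    if (!is.null(rb$split_half)) {
      utils::write.table(rb$split_half, file.path(outdir, "split_half.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      add("split_half.tsv")
    }
  }

  jsonlite::write_json(report_as_list(report),
                       file.path(outdir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  add("report.json")

  log_lines <- c(
    paste("sccapipe run", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("R version:", R.version.string),
    paste("seed:", report$config$seed),
    paste("analysis kind:", report$config$kind),
    paste("penalties:", report$penalty_x, report$penalty_y),
    paste("n_perm:", report$config$n_perm),
    report$log)
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  add("run_log.txt")
  invisible(file.path(outdir, written))
}

report_as_list <- function(report) {
  list(
    seed = report$config$seed,
    kind = report$config$kind,
    penalty_x = report$penalty_x,
    penalty_y = report$penalty_y,
    observed_r = report$r,
    exact_p = report$exact_p,
    fdr_adjusted_p = report$fdr_adjusted_p,
    covariance_explained_percent = report$covariance_explained_percent,
    mean_permuted = report$permutation$mean_permuted,
    sd_permuted = report$permutation$sd_permuted,
    robustness_pass_flags = if (is.null(report$robustness)) NULL
                            else report$robustness$pass_flags,
    reported = report$reported,
    n_subjects = report$n_subjects,
    excluded_subjects = report$excluded_subjects,
    variable_table = report$variable_table
  )
}
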