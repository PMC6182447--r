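#' Read a partially linear model dataset
#'
#' Reads a CSV or TSV file (chosen by extension, `.tsv`/`.tab` for
#' tab-separated) with a header containing `t`, `y` and covariate columns
#' `x1, ..., xd`.  Rows are reordered by `t` with a warning if needed;
#' `t` outside `[0, 1]` or non-numeric cells are rejected with the
#' offending row named.
#'
#' @param path Path to the file.
#' @return A validated tibble with columns `t`, `y`, `x1, ...`.
#' @export
read_plm <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  nms <- names(raw)
  xcols <- grep("^x[0-9]+$", nms, value = TRUE)
  missing <- setdiff(c("t", "y"), nms)
  if (length(missing) > 0 || length(xcols) == 0) {
    stop("Dataset must have header columns t, y and x1, ...; missing: ",
         paste(c(missing, if (length(xcols) == 0) "x1"), collapse = ", "),
         ".", call. = FALSE)
  }
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  raw <- raw[c("t", "y", xcols)]
  for (cl in names(raw)) {
    v <- raw[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop("Non-numeric value in column '", cl, "', data row ", bad[1],
             ": '", v[bad[1]], "'.", call. = FALSE)
      }
      raw[[cl]] <- vn
    }
    if (anyNA(raw[[cl]])) {
      stop("Missing value in column '", cl, "', data row ",
           which(is.na(raw[[cl]]))[1], ".", call. = FALSE)
    }
  }
  bad_t <- which(raw$t < 0 | raw$t > 1)
  if (length(bad_t) > 0) {
    stop("`t` must lie in [0, 1]; data row ", bad_t[1], " has t = ",
         raw$t[bad_t[1]], ".", call. = FALSE)
  }
  if (is.unsorted(raw$t)) {
    warning("Rows were not sorted by t; reordering.", call. = FALSE)
    raw <- raw[order(raw$t), ]
  }
  tibble::as_tibble(raw)
}

#' Write a partially linear model dataset
#'
#' @param data A data frame with columns `t`, `y`, `x1, ...`.
#' @param path Output path; `.tsv`/`.tab` extensions write tab-separated,
#'   anything else comma-separated.
#' @return `path`, invisibly.
#' @export
write_plm <- function(data, path) {
  as_plm_data(data)  # validate
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `fit` (DOLS plus plug-in covariance, JSON
#' report), `smooth` (nonparametric curve as TSV), `simulate` (write a
#' simulated dataset as CSV), `study` (normality study, JSON report plus
#' ECDF/QQ TSVs) and `check-inequality` (moment-bound ratio, JSON).  A
#' thin executable wrapper lives at `system.file("cli", "diffplm",
#' package = "diffplm")`.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status: 0 on success, 1 on computational failure,
#'   2 on usage errors.
#' @export
plm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: diffplm <fit|smooth|simulate|study|check-inequality> ",
    "[options]\nRun `diffplm <subcommand> --help` for options.\n"
  )
  if (length(args) < 1 || args[1] %in% c("-h", "--help")) {
    cat(usage)
    return(if (length(args) < 1) 2L else 0L)
  }
  sub <- args[1]
  rest <- args[-1]
  handler <- switch(sub,
    "fit" = cli_fit,
    "smooth" = cli_smooth,
    "simulate" = cli_simulate,
    "study" = cli_study,
    "check-inequality" = cli_check,
    NULL
  )
  if (is.null(handler)) {
    cat("Unknown subcommand: ", sub, "\n", usage, sep = "")
    return(2L)
  }
  tryCatch({
    handler(rest)
    0L
  }, error = function(cnd) {
    message("Error: ", conditionMessage(cnd))
    1L
  })
}

cli_common_log <- function(opts, out) {
  log <- c(opts, list(package_version = as.character(
    utils::packageVersion("diffplm")), r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")))
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

cli_out_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

cli_fit <- function(args) {
  parser <- optparse::OptionParser(
    option_list = list(
      optparse::make_option("--data", type = "character"),
      optparse::make_option("--m", type = "integer", default = 3),
      optparse::make_option("--lag", type = "integer", default = NA),
      optparse::make_option("--out", type = "character", default = ".")
    ), prog = "diffplm fit")
  o <- optparse::parse_args(parser, args = args)
  if (is.null(o$data)) stop("--data is required")
  fit <- dols(read_plm(o$data), m = o$m)
  lag <- if (is.na(o$lag)) fit$seq$order + 5 else o$lag
  cov <- tau2_beta_plugin(fit, lag)
  td <- tidy(fit, lag_truncation = lag)
  out <- cli_out_dir(o$out)
  jsonlite::write_json(
    list(beta_hat = unname(fit$beta_hat), se = td$std.error,
         tau2_method = cov$method, lag = cov$lag_truncation,
         m = fit$seq$order, n = fit$n),
    file.path(out, "fit.json"), auto_unbox = TRUE, digits = NA)
  cli_common_log(o[names(o) != "help"], out)
  cat("Wrote", file.path(out, "fit.json"), "\n")
}

cli_smooth <- function(args) {
  parser <- optparse::OptionParser(
    option_list = list(
      optparse::make_option("--data", type = "character"),
      optparse::make_option("--m", type = "integer", default = 3),
      optparse::make_option("--family", type = "character",
                            default = "daubechies-2"),
      optparse::make_option("--resolution", type = "integer", default = NA),
      optparse::make_option("--out", type = "character", default = ".")
    ), prog = "diffplm smooth")
  o <- optparse::parse_args(parser, args = args)
  if (is.null(o$data)) stop("--data is required")
  d <- read_plm(o$data)
  fit <- dols(d, m = o$m)
  res <- if (is.na(o$resolution)) choose_resolution(nrow(d)) else o$resolution
  sm <- smooth_plm(d, fit, kernel = repro_kernel(scaling_function(o$family),
                                                 res))
  out <- cli_out_dir(o$out)
  readr::write_tsv(sm$estimate, file.path(out, "smooth.tsv"))
  cli_common_log(o[names(o) != "help"], out)
  cat("Wrote", file.path(out, "smooth.tsv"), "\n")
}

cli_simulate <- function(args) {
  parser <- optparse::OptionParser(
    option_list = list(
      optparse::make_option("--n", type = "integer", default = 128),
      optparse::make_option("--beta", type = "double", default = 5),
      optparse::make_option("--seed", type = "integer", default = 1),
      optparse::make_option("--no-center", action = "store_true",
                            default = FALSE, dest = "no_center"),
      optparse::make_option("--out", type = "character", default = ".")
    ), prog = "diffplm simulate")
  o <- optparse::parse_args(parser, args = args)
  d <- simulate_plm(o$n, beta = o$beta, center = !o$no_center,
                    seed = o$seed)
  out <- cli_out_dir(o$out)
  write_plm(d, file.path(out, "dataset.csv"))
  truth <- attr(d, "truth")
  grid <- seq(0, 1, length.out = 201)
  jsonlite::write_json(
    list(beta = truth$beta, f_grid = list(t = grid, f = truth$f_fn(grid))),
    file.path(out, "truth.json"), digits = NA)
  cli_common_log(o[names(o) != "help"], out)
  cat("Wrote", file.path(out, "dataset.csv"), "\n")
}

cli_study <- function(args) {
  parser <- optparse::OptionParser(
    option_list = list(
      optparse::make_option("--target", type = "character", default = "beta",
                            help = "beta or f"),
      optparse::make_option("--n", type = "integer", default = 128),
      optparse::make_option("--reps", type = "integer", default = 1000),
      optparse::make_option("--m", type = "integer", default = 3),
      optparse::make_option("--family", type = "character",
                            default = "daubechies-2"),
      optparse::make_option("--resolution", type = "integer", default = NA),
      optparse::make_option("--t-eval", type = "double", default = 0.5,
                            dest = "t_eval"),
      optparse::make_option("--seed", type = "integer", default = 1),
      optparse::make_option("--no-center", action = "store_true",
                            default = FALSE, dest = "no_center"),
      optparse::make_option("--out", type = "character", default = ".")
    ), prog = "diffplm study")
  o <- optparse::parse_args(parser, args = args)
  rep <- if (o$target == "f") {
    run_f_study(n = o$n, reps = o$reps, m = o$m, family = o$family,
                resolution = if (is.na(o$resolution)) NULL else o$resolution,
                t_eval = o$t_eval, center = !o$no_center, seed = o$seed)
  } else {
    run_beta_study(n = o$n, reps = o$reps, m = o$m, center = !o$no_center,
                   seed = o$seed)
  }
  out <- cli_out_dir(o$out)
  jsonlite::write_json(as.list(glance(rep)), file.path(out, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(rep$ecdf, file.path(out, "ecdf.tsv"))
  readr::write_tsv(rep$qq, file.path(out, "qq.tsv"))
  cli_common_log(o[names(o) != "help"], out)
  cat("Wrote", file.path(out, "study.json"), "\n")
}

cli_check <- function(args) {
  parser <- optparse::OptionParser(
    option_list = list(
      optparse::make_option("--p", type = "double", default = 2),
      optparse::make_option("--n", type = "integer", default = 50),
      optparse::make_option("--reps", type = "integer", default = 2000),
      optparse::make_option("--m", type = "integer", default = NA,
                            help = "if set, check the weighted bound"),
      optparse::make_option("--seed", type = "integer", default = 1),
      optparse::make_option("--out", type = "character", default = ".")
    ), prog = "diffplm check-inequality")
  o <- optparse::parse_args(parser, args = args)
  sq <- if (is.na(o$m)) NULL else diff_sequence(o$m)
  res <- check_moment_inequality(o$p, o$n, reps = o$reps, seq = sq,
                                 seed = o$seed)
  out <- cli_out_dir(o$out)
  jsonlite::write_json(as.list(res), file.path(out, "inequality.json"),
                       auto_unbox = TRUE, digits = NA)
  cli_common_log(o[names(o) != "help"], out)
  cat("Wrote", file.path(out, "inequality.json"), "\n")
}
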