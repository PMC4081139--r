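fmt_full <- function(x) sprintf("%.17g", x)

#' Write / read a posterior parameter sample (TSV)
#'
#' The posterior sample is the artifact that makes a published model usable
#' for prediction-uncertainty analysis, so its on-disk form is plain,
#' self-describing and lossless: two `#` header lines (format tag, then
#' `seed=<int> chains=<int> thin=<int>` provenance), a tab-separated header of
#' parameter names, and one tab-separated row per draw printed with 17
#' significant digits so the write-read round trip is bit exact.
#'
#' @param sample A `predq_sample`.
#' @param path File path.
#' @return `write_sample` returns `path` invisibly; `read_sample` returns a
#'   `predq_sample` (draws plus provenance; `.chain`/`.iteration` are not
#'   stored in the file).
#' @export
write_sample <- function(sample, path) {
  nms <- attr(sample, "param_names")
  cfg <- attr(sample, "config")
  dm <- draws_matrix(sample)
  head <- c(
    "# predq posterior sample",
    sprintf("# seed=%d chains=%d thin=%d",
            as.integer(attr(sample, "seed")),
            if (is.null(cfg)) length(unique(sample$.chain)) else cfg$n_chains,
            if (is.null(cfg)) 1L else cfg$thin),
    paste(nms, collapse = "\t")
  )
  rows <- apply(dm, 1L, function(r) paste(fmt_full(r), collapse = "\t"))
  writeLines(c(head, rows), path, sep = "\n")
  invisible(path)
}

#' @rdname write_sample
#' @export
read_sample <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("sample file not found: ", path),
                 class = "predq_parse_error")
  }
  lines <- readLines(path)
  if (length(lines) < 4L || !startsWith(lines[1L], "# predq posterior sample")) {
    rlang::abort("not a predq posterior sample file (missing format header)",
                 class = "predq_parse_error")
  }
  meta <- lines[2L]
  grab <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[0-9-]+"), meta))
    if (!length(m)) NA_integer_ else as.integer(sub(paste0(key, "="), "", m))
  }
  seed <- grab("seed"); chains <- grab("chains"); thin <- grab("thin")
  nms <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(rows)
  bad <- which(widths != length(nms))
  if (length(bad)) {
    rlang::abort(paste0("row width ", widths[bad[1L]], " != ", length(nms),
                        " parameters at line ", bad[1L] + 3L),
                 class = "predq_parse_error")
  }
  dm <- matrix(as.numeric(unlist(rows)), ncol = length(nms), byrow = TRUE)
  badv <- which(!is.finite(dm) | dm <= 0, arr.ind = TRUE)
  if (nrow(badv)) {
    rlang::abort(paste0("non-positive or non-finite draw at line ",
                        badv[1L, 1L] + 3L),
                 class = "predq_parse_error")
  }
  colnames(dm) <- nms
  tb <- tibble::as_tibble(as.data.frame(dm))
  new_predq_sample(tb, param_names = nms, seed = seed,
                   config = list(n_chains = chains, thin = thin))
}

#' Write / read a time-series dataset (CSV)
#'
#' Header `time,component,value,sigma`, one record per row, `.` decimal point,
#' LF line endings; lines starting with `#` are comments. Values are written
#' with 17 significant digits so round trips are exact. `sigma` must be
#' strictly positive.
#'
#' @param data A `predq_data` tibble.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` a
#'   `predq_data` tibble.
#' @export
write_dataset <- function(data, path) {
  data <- validate_dataset(data)
  rows <- sprintf("%s,%d,%s,%s", fmt_full(data$time), as.integer(data$component),
                  fmt_full(data$value), fmt_full(data$sigma))
  writeLines(c("time,component,value,sigma", rows), path, sep = "\n")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("dataset file not found: ", path),
                 class = "predq_parse_error")
  }
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines) || trimws(lines[1L]) != "time,component,value,sigma") {
    rlang::abort("dataset file must start with header time,component,value,sigma",
                 class = "predq_parse_error")
  }
  body <- lines[-1L]; body_lineno <- lineno[-1L]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    rlang::abort(paste0("expected 4 fields at line ", body_lineno[bad[1L]]),
                 class = "predq_parse_error")
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 4L, byrow = TRUE)
  if (any(!is.finite(m))) {
    badr <- which(rowSums(!is.finite(m)) > 0)[1L]
    rlang::abort(paste0("unparseable number at line ", body_lineno[badr]),
                 class = "predq_parse_error")
  }
  d <- tibble::tibble(time = m[, 1L], component = as.integer(m[, 2L]),
                      value = m[, 3L], sigma = m[, 4L])
  bads <- which(!(d$sigma > 0))
  if (length(bads)) {
    rlang::abort(paste0("sigma must be > 0 at line ", body_lineno[bads[1L]]),
                 class = "predq_parse_error")
  }
  new_predq_data(validate_dataset(d))
}

#' Export Q results, scans and bands as CSV
#'
#' Small fixed-dialect CSV writers for the analysis artifacts: per-draw Q
#' values (`draw_index,Q,<per-component Q_i...>` plus `# Q_alpha=` comment),
#' perturbation-scan tables (`parameter,direction,factor,Q_alpha,n_failed,flag`)
#' and envelope / linearized bands (`time,component,center,lower,upper`,
#' `center` empty when no reference trajectory was attached).
#'
#' @param x The result object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_qresult <- function(x, path) {
  stopifnot(inherits(x, "predq_qresult"))
  qi_cols <- grep("^q_", names(x), value = TRUE)
  header <- paste(c("draw_index", "Q", sub("^q_", "Q_", qi_cols)), collapse = ",")
  rows <- apply(cbind(x$.draw, as.matrix(as.data.frame(x)[, c("q", qi_cols)])), 1L,
                function(r) paste(c(sprintf("%d", r[1L]), fmt_full(r[-1L])), collapse = ","))
  writeLines(c(sprintf("# Q_alpha=%s alpha=%s b=%s n_failed=%d",
                       fmt_full(attr(x, "q_alpha")), fmt_full(attr(x, "alpha")),
                       fmt_full(attr(x, "b")), attr(x, "n_failed")),
               header, rows), path, sep = "\n")
  invisible(path)
}

#' @rdname write_qresult
#' @export
write_scan <- function(x, path) {
  stopifnot(inherits(x, "predq_scan"))
  rows <- sprintf("%s,%s,%s,%s,%s,%s", x$parameter, x$direction,
                  fmt_full(x$factor), fmt_full(x$q_alpha),
                  ifelse(is.na(x$n_failed), "NA", sprintf("%d", x$n_failed)),
                  ifelse(is.na(x$flag), "NA", x$flag))
  writeLines(c("parameter,direction,factor,Q_alpha,n_failed,flag", rows),
             path, sep = "\n")
  invisible(path)
}

#' @rdname write_qresult
#' @export
write_band <- function(x, path) {
  stopifnot(inherits(x, "predq_envelope") || inherits(x, "predq_lca"))
  center <- if ("center" %in% names(x)) x$center else x$reference
  center_s <- ifelse(is.na(center), "", fmt_full(center))
  rows <- sprintf("%s,%s,%s,%s,%s", fmt_full(x$time), x$component,
                  center_s, fmt_full(x$lower), fmt_full(x$upper))
  writeLines(c("time,component,center,lower,upper", rows), path, sep = "\n")
  invisible(path)
}

#' Read a run configuration file
#'
#' A single declarative YAML file drives the command-line interface: model
#' name, prior bounds, data path, sampler settings, uncertainty settings
#' (`b`, `alpha`, `grid_size`), named scenario definitions, seed, output
#' directory, verbosity. Scenario entries accept `y0` (initial-state
#' override), `input_scale`, `param_factors` (named map), `horizon` and
#' `grid_size`.
#'
#' @param path YAML file path.
#' @return A list of class `predq_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path),
                 class = "predq_parse_error")
  }
  cfg <- yaml::read_yaml(path)
  for (field in c("model", "prior")) {
    if (is.null(cfg[[field]])) {
      rlang::abort(paste0("config is missing required field '", field, "'"),
                   class = "predq_parse_error")
    }
  }
  if (is.null(cfg$uq)) cfg$uq <- list()
  cfg$uq$b <- cfg$uq$b %||% 2
  cfg$uq$alpha <- cfg$uq$alpha %||% 0.95
  cfg$uq$grid_size <- cfg$uq$grid_size %||% 201L
  if (!is.null(cfg$scenarios)) {
    if (is.null(names(cfg$scenarios)) || anyDuplicated(names(cfg$scenarios))) {
      rlang::abort("scenario names must be present and unique",
                   class = "predq_parse_error")
    }
  }
  structure(cfg, class = "predq_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_scenario <- function(cfg, name) {
  sc <- cfg$scenarios[[name]]
  if (is.null(sc)) {
    rlang::abort(paste0("unknown scenario '", name, "'"), class = "predq_parse_error")
  }
  prediction_scenario(
    initial_state = sc$y0,
    input_scale = sc$input_scale,
    param_factors = if (!is.null(sc$param_factors)) unlist(sc$param_factors),
    horizon = sc$horizon,
    grid_size = sc$grid_size %||% cfg$uq$grid_size
  )
}
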