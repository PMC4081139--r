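#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summaries of posterior samples
#'
#' `tidy()` gives one row per parameter: posterior mean, SD, median and the
#' equal-tailed credible interval at `conf.level` (quantiles of the draws).
#' `glance()` gives a one-row run summary: draw count, acceptance rate,
#' worst split-R-hat, smallest effective sample size, integration failures.
#'
#' @param x A `predq_sample`.
#' @param conf.level Credible-interval mass.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.predq_sample <- function(x, conf.level = 0.95, ...) {
  dm <- draws_matrix(x)
  a <- (1 - conf.level) / 2
  purrr::map_dfr(colnames(dm), function(par) {
    v <- dm[, par]
    qs <- stats::quantile(v, c(a, 0.5, 1 - a), names = FALSE)
    tibble::tibble(parameter = par, estimate = mean(v), std.error = stats::sd(v),
                   median = qs[2L], conf.low = qs[1L], conf.high = qs[3L])
  })
}

#' @rdname tidy.predq_sample
#' @export
glance.predq_sample <- function(x, ...) {
  diag <- tryCatch(convergence_diagnostics(x), error = function(e) NULL)
  tibble::tibble(
    n_draws = nrow(x),
    n_parameters = length(attr(x, "param_names")),
    acceptance_rate = attr(x, "acceptance_rate"),
    max_rhat = if (is.null(diag)) NA_real_ else max(diag$rhat, na.rm = TRUE),
    min_ess = if (is.null(diag)) NA_real_ else min(diag$ess, na.rm = TRUE),
    n_integration_failures = attr(x, "n_integration_failures")
  )
}

#' Tidy summaries of Q results
#'
#' `tidy()` returns the per-draw Q values in long form (overall and per
#' component); `glance()` the one-row scenario summary with `q_alpha`.
#'
#' @param x A `predq_qresult`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.predq_qresult <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -".draw",
                      names_to = "component", values_to = "q") |>
    dplyr::mutate(component = sub("^q_?", "", .data$component),
                  component = dplyr::if_else(.data$component == "",
                                             "overall", .data$component))
}

#' @rdname tidy.predq_qresult
#' @export
glance.predq_qresult <- function(x, ...) {
  tibble::tibble(
    scenario = attr(x, "scenario_id") %||% NA_character_,
    q_alpha = attr(x, "q_alpha"),
    alpha = attr(x, "alpha"),
    b = attr(x, "b"),
    reference = attr(x, "reference_kind"),
    n_draws = attr(x, "n_draws"),
    n_failed = attr(x, "n_failed"),
    tight = attr(x, "q_alpha") < 1
  )
}
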