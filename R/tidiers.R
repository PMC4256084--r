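#' Tidy a null-ensemble report
#'
#' One row per communication metric with the ensemble means, null spread,
#' z-score and p-values.
#'
#' @param x A `null_ensemble_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.null_ensemble_report <- function(x, ...) {
  x$table
}

#' @rdname tidy.null_ensemble_report
#' @export
glance.null_ensemble_report <- function(x, ...) {
  tibble::tibble(focal = x$focal, kind = x$kind, fraction = x$fraction,
                 R = x$R, S = x$S, seed = x$seed,
                 lambda = x$params$lambda, mu = x$params$mu,
                 K = x$params$K, T = x$params$T)
}

#' Tidy a phase map
#'
#' @param x A `phase_map`.
#' @param ... Unused.
#' @return The underlying tibble (`lambda`, `slope`, `mean_contents`,
#'   `regime`).
#' @export
tidy.phase_map <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.phase_map
#' @export
glance.phase_map <- function(x, ...) {
  steady <- x$lambda[x$regime == "steady"]
  jammed <- x$lambda[x$regime == "jammed"]
  tibble::tibble(
    n_rates = nrow(x),
    max_steady_lambda = if (length(steady)) max(steady) else NA_real_,
    min_jammed_lambda = if (length(jammed)) min(jammed) else NA_real_)
}

#' Tidy a simulation result
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return The node metric table (see [node_metrics()]).
#' @export
tidy.sim_result <- function(x, ...) {
  node_metrics(x)
}

#' @rdname tidy.sim_result
#' @export
glance.sim_result <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    generated = x$ledger$generated, delivered = x$ledger$delivered,
    ejected = x$ledger$ejected, residual = x$ledger$residual,
    window_start = unname(x$window[["start"]]),
    window_end = unname(x$window[["end"]]))
}
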