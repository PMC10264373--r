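#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an EFM collection
#'
#' One row per EFM in discovery order: id, support size, occurrence count,
#' explored flag, and the support as a list-column.
#'
#' @param x An [efm_collection()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy efm_collection
#' @export
tidy.efm_collection <- function(x, ...) {
  tibble::tibble(
    efm = seq_along(x$efms),
    length = vapply(x$efms, function(e) e$length, integer(1)),
    occurrences = x$occurrences,
    explored = x$explored,
    support = lapply(x$efms, function(e) e$support_ids))
}

#' @rdname tidy.efm_collection
#' @method tidy enumeration_result
#' @export
tidy.enumeration_result <- function(x, ...) tidy(x$collection, ...)

#' Tidy a PiEFM extraction trace
#'
#' The per-EFM table of the underlying collection joined with each EFM's
#' discovery event (step and source: `seed_coverage`, `seed_biomass`, or
#' `pivot`).
#'
#' @param x A `piefm_trace` from [run_piefm()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy piefm_trace
#' @export
tidy.piefm_trace <- function(x, ...) {
  dplyr::left_join(tidy(x$collection), x$events, by = "efm") |>
    dplyr::relocate("step", "source", .after = "efm")
}

#' One-row summary of a PiEFM run
#'
#' Reports the distinct EFM count, LPs solved, pivots attempted, the
#' efficiency ratio (distinct EFMs per LP solved), rank-test failures among
#' pivot candidates, skipped anchors, and elapsed seconds.
#'
#' @inheritParams tidy.piefm_trace
#' @return A one-row tibble.
#' @method glance piefm_trace
#' @export
glance.piefm_trace <- function(x, ...) {
  tibble::tibble(
    n_efms = length(x$collection),
    lp_count = x$lp_count,
    pivot_count = x$pivot_count,
    efficiency = length(x$collection) / max(1L, x$lp_count),
    rank_failures = x$rank_failures,
    skipped_anchors = x$skipped_no_irreversible,
    elapsed = x$elapsed)
}

#' @rdname glance.piefm_trace
#' @method glance enumeration_result
#' @export
glance.enumeration_result <- function(x, ...) {
  lens <- vapply(collection_efms(x), function(e) e$length, integer(1))
  tibble::tibble(
    n_efms = length(x$collection),
    method = x$method,
    mean_length = mean(lens),
    n_futile = x$n_futile)
}

#' Plot a parameter trace
#'
#' Line plot of a checkpointed parameter ([mean_length_trace()],
#' [stability_trace()], [jaccard_trace()]) against the number of EFMs
#' extracted; an optional horizontal reference line marks a target value or
#' stability threshold.
#'
#' @param object A `parameter_trace` tibble.
#' @param threshold Optional horizontal reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot parameter_trace
#' @export
autoplot.parameter_trace <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "EFMs extracted",
                  y = attr(object, "parameter") %||% "value")
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  p
}

#' Compare parameter traces across extraction methods
#'
#' Binds named traces into one tibble and plots them as colored lines —
#' the side-by-side view used to compare extractors on the same network.
#'
#' @param ... Named `parameter_trace` tibbles.
#' @param threshold Optional horizontal reference line.
#' @return A ggplot object.
#' @export
plot_trace_comparison <- function(..., threshold = NULL) {
  traces <- list(...)
  stopifnot(length(traces) >= 1, !is.null(names(traces)),
            all(nzchar(names(traces))))
  tbl <- dplyr::bind_rows(lapply(traces, as.data.frame), .id = "method")
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$k, y = .data$value,
                                         color = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "EFMs extracted", y = "value")
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  p
}

#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"
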