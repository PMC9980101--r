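#' Tidy a phase fit into a per-segment haplotype table
#'
#' @param x A `phase_fit` from [phase_by_contacts()] or [phase_by_trio()].
#' @param ... Unused.
#' @return Tibble with one row per bubble side: `segment`, `haplotype`,
#'   `bubble`, `merged_set`, `supported`.
#' @export
tidy.phase_fit <- function(x, ...) {
  x$segments
}

#' One-row summary of a phase fit
#'
#' @param x A `phase_fit`.
#' @param ... Unused.
#' @return Tibble with `method`, `n_bubbles`, `n_supported`, `objective`,
#'   `n_rounds`, `largest_merged_set`, `anchored`.
#' @export
glance.phase_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_bubbles = nrow(x$bubbles),
    n_supported = sum(x$bubbles$supported),
    objective = x$objective,
    n_rounds = if (is.null(x$rounds)) 0L else nrow(x$rounds),
    largest_merged_set = if (is.null(x$rounds) || nrow(x$rounds) == 0L) 1L
      else max(x$rounds$largest_set),
    anchored = x$anchored)
}

#' Plot the optimization trace of a contact phase fit
#'
#' Best objective and largest merged-set size per round.
#'
#' @param object A `phase_fit` with a rounds log.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_fit <- function(object, ...) {
  if (is.null(object$rounds) || nrow(object$rounds) == 0L) {
    stop("this phase_fit has no per-round log to plot")
  }
  df <- object$rounds |>
    tidyr::pivot_longer(c("best_objective", "largest_set"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "merge round", y = NULL,
                  title = "Sampled greedy max-cut optimization trace") +
    ggplot2::theme_minimal()
}

#' Compare a phase fit with a truth assignment
#'
#' Per-bubble phasing error against a known orientation, scored up to a
#' global flip for contact phasing (the objective is invariant under
#' flipping every orientation) and literally for anchored trio phasing.
#'
#' Contact phasing is identifiable only within a connected component of the
#' contact graph, so for multi-component graphs the error is minimized over
#' one flip per component (`groups`), the way Hamming error is computed per
#' phase block.
#'
#' @param fit A `phase_fit`.
#' @param truth Tibble with columns `bubble`, `orientation`.
#' @param up_to_global_flip Score the better of the two phasings (per
#'   group)? Defaults to `!fit$anchored`.
#' @param groups Optional tibble with columns `bubble`, `group`: phase
#'   blocks flipped independently. Default: one global group.
#' @return Tibble with `n_compared`, `n_wrong`, `error_rate`.
#' @export
phase_error <- function(fit, truth, up_to_global_flip = !fit$anchored,
                        groups = NULL) {
  cmp <- fit$bubbles |>
    dplyr::filter(.data$supported) |>
    dplyr::inner_join(tibble::as_tibble(truth), by = "bubble",
                      suffix = c("", "_truth"))
  if (nrow(cmp) == 0L) {
    return(tibble::tibble(n_compared = 0L, n_wrong = 0L,
                          error_rate = NA_real_))
  }
  cmp$group <- if (is.null(groups)) {
    "all"
  } else {
    g <- tibble::as_tibble(groups)
    as.character(g$group[match(cmp$bubble, g$bubble)])
  }
  per_group <- cmp |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mism = sum(.data$orientation !=
                                  .data$orientation_truth),
                     .groups = "drop") |>
    dplyr::mutate(wrong = if (up_to_global_flip) {
      pmin(.data$mism, .data$n - .data$mism)
    } else {
      .data$mism
    })
  n <- sum(per_group$n)
  wrong <- sum(per_group$wrong)
  tibble::tibble(n_compared = n, n_wrong = as.integer(wrong),
                 error_rate = wrong / n)
}
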