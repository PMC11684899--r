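#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a solution set
#'
#' One row per solution and objective, with the expected (train-side,
#' possibly adjusted) fitness, its bootstrap SD, and the held-out fitness
#' where measured.
#'
#' @param x An `mo_solution_set`.
#' @param ... Unused.
#' @return A tibble with columns `solution`, `n_feat`, `features`,
#'   `objective`, `fitness`, `sd`, `test_fitness`.
#' @method tidy mo_solution_set
#' @export
tidy.mo_solution_set <- function(x, ...) {
  obj_names <- purrr::map_chr(x$objectives, "name")
  Xt <- test_fitness_matrix(x)
  purrr::map_dfr(seq_along(x$solutions), function(i) {
    sol <- x$solutions[[i]]
    tibble::tibble(
      solution = i,
      n_feat = length(sol$features),
      features = paste(sol$features, collapse = ";"),
      objective = obj_names,
      fitness = sol$fitness,
      sd = sol$sd,
      test_fitness = Xt[i, ]
    )
  })
}

#' Summarize a solution set in one row
#'
#' @param x An `mo_solution_set`.
#' @param ... Unused.
#' @return A tibble with the front size, objective count, number of
#'   solutions evaluated during the run, the training-side hypervolume
#'   (and test-side when held-out fitness is present), and the median
#'   panel size.
#' @method glance mo_solution_set
#' @export
glance.mo_solution_set <- function(x, ...) {
  X <- fitness_matrix(x)
  Xt <- test_fitness_matrix(x)
  tibble::tibble(
    n_solutions = length(x$solutions),
    n_objectives = length(x$objectives),
    n_evaluated = x$meta$n_evaluated %||% NA_integer_,
    hv_train = hypervolume(X),
    hv_test = if (!anyNA(Xt)) hypervolume(Xt) else NA_real_,
    median_n_feat = stats::median(purrr::map_int(x$solutions,
                                                 ~ length(.x$features)))
  )
}

#' Plot a two-objective solution front
#'
#' Expected (train-side) fitness of every solution, and — when held-out
#' fitness is available — the measured fitness with a segment joining the
#' two, making the overestimation of each solution visible.
#'
#' @param object An `mo_solution_set` with exactly two objectives.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mo_solution_set
#' @export
autoplot.mo_solution_set <- function(object, ...) {
  stopifnot(length(object$objectives) == 2)
  tb <- tidy(object) |>
    dplyr::select(-"sd") |>
    tidyr::pivot_longer(c("fitness", "test_fitness"), names_to = "side") |>
    dplyr::mutate(side = ifelse(.data$side == "fitness", "expected",
                                "measured")) |>
    tidyr::pivot_wider(names_from = "objective", values_from = "value")
  obj_names <- purrr::map_chr(object$objectives, "name")
  tb <- tb[stats::complete.cases(tb[, obj_names]), , drop = FALSE]
  gg <- ggplot2::ggplot(
    tb, ggplot2::aes(x = .data[[obj_names[1]]], y = .data[[obj_names[2]]],
                     colour = .data$side, group = .data$solution)) +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(tb$side) > 1) {
    gg <- gg + ggplot2::geom_line(colour = "grey60", linewidth = 0.3)
  }
  gg
}

#' Bar chart of experiment metrics
#'
#' Mean with between-fold SD error bars for each adjuster and metric, from
#' the `metrics` tibble of [run_experiment()].
#'
#' @param metrics Tibble with columns `adjuster`, `fold`, `metric`, `value`.
#' @param which Metrics to show (default all present).
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics, which = unique(metrics$metric)) {
  sm <- metrics |>
    dplyr::filter(.data$metric %in% which) |>
    dplyr::group_by(.data$adjuster, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
                     .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$adjuster, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
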