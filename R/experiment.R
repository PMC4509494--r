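# Batch experiment harness: simulate N datasets per model, run each method
# at each (particles, iterations) setting, and score detection power.

#' Run a detection-power experiment
#'
#' For every model: simulates `n_datasets` case-control datasets, then runs
#' every method at every (particles, iterations) setting on the same
#' datasets and scores Power 1 / Power 2 against the planted truth. All
#' randomness (simulation and optimizer runs) is derived from `seed`, so a
#' repeated call reproduces the report exactly.
#'
#' @param models A named list of `penetrance_model` objects (a bare model is
#'   accepted and wrapped).
#' @param n_datasets Datasets simulated per model.
#' @param n_cases,n_controls,n_snps Simulation design per dataset.
#' @param methods Character vector of optimizer variants to compare
#'   (`"oblpso"`, `"pso"`).
#' @param grid Data frame of optimizer sizes with columns `particles` and
#'   `iterations` (one row per setting).
#' @param order Interaction order K.
#' @param top_n Post-search candidate-set size (oblpso only).
#' @param seed Master seed for the whole experiment.
#' @return A tibble with one row per (method, model, particles, iterations):
#'   `power1`, `power2`, `n_datasets`, and the design echo columns. The
#'   per-dataset reports are attached as the `reports` attribute (a named
#'   list of [power_report()] objects).
#' @export
#' @examples
#' \donttest{
#' m <- calibrate_penetrance(penetrance_shape("threshold_both_minor",
#'                                            effect = 3),
#'                           mafs = c(0.4, 0.4), prevalence = 0.1)
#' run_power_experiment(list(strong = m), n_datasets = 2, n_cases = 200,
#'                      n_controls = 200, n_snps = 20,
#'                      grid = data.frame(particles = 10, iterations = 10),
#'                      seed = 1)
#' }
run_power_experiment <- function(models, n_datasets = 50,
                                 n_cases = 2000, n_controls = 2000,
                                 n_snps = 100,
                                 methods = c("oblpso", "pso"),
                                 grid = data.frame(particles = 100,
                                                   iterations = 100),
                                 order = 2, top_n = 10, seed = NULL) {
  if (inherits(models, "penetrance_model")) models <- list(models)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, function(m) m$name, character(1))
  }
  stopifnot(all(c("particles", "iterations") %in% names(grid)),
            n_datasets >= 1)
  methods <- match.arg(methods, c("oblpso", "pso"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  # pre-draw all sub-seeds so each (method, setting) sees identical datasets
  sim_seeds <- matrix(sample.int(.Machine$integer.max,
                                 length(models) * n_datasets),
                      nrow = length(models))
  run_seed_pool <- sample.int(.Machine$integer.max,
                              length(models) * n_datasets *
                                length(methods) * nrow(grid))
  run_i <- 0L
  rows <- list()
  reports <- list()
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    sims <- lapply(seq_len(n_datasets), function(d) {
      simulate_epistasis(model, n_cases, n_controls, n_snps,
                         seed = sim_seeds[mi, d])
    })
    truths <- lapply(sims, `[[`, "truth")
    for (method in methods) {
      for (gi in seq_len(nrow(grid))) {
        detected <- lapply(sims, function(s) {
          run_i <<- run_i + 1L
          detect_interactions(
            s$data, particles = grid$particles[gi],
            iterations = grid$iterations[gi], order = order,
            top_n = top_n, variant = method,
            seed = run_seed_pool[run_i]
          )
        })
        label <- paste(method, names(models)[mi],
                       grid$particles[gi], grid$iterations[gi], sep = "/")
        rep <- power_report(detected, truths, label = label)
        reports[[label]] <- rep
        rows[[label]] <- tibble::tibble(
          method = method,
          model = names(models)[mi],
          particles = grid$particles[gi],
          iterations = grid$iterations[gi],
          power1 = rep$power1,
          power2 = rep$power2,
          n_datasets = n_datasets,
          n_cases = n_cases,
          n_controls = n_controls,
          n_snps = n_snps,
          order = order
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "reports") <- reports
  class(out) <- c("epi_experiment", class(out))
  out
}

#' Plot a power experiment summary
#'
#' Grouped bars of Power 1 and Power 2 per method, faceted by model and
#' (particles, iterations) setting.
#'
#' @param summary The tibble returned by [run_power_experiment()].
#' @return A ggplot object.
#' @export
plot_power <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(c("power1", "power2"),
                        names_to = "measure", values_to = "power") |>
    dplyr::mutate(
      measure = dplyr::recode(.data$measure,
                              power1 = "Power 1", power2 = "Power 2"),
      setting = paste0("P=", .data$particles, ", T=", .data$iterations)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$power,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$model),
                        cols = ggplot2::vars(.data$setting)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "detection power", fill = "method") +
    ggplot2::theme_minimal()
}

#' @rdname plot_power
#' @param object An `epi_experiment` summary tibble.
#' @param ... Unused.
#' @method autoplot epi_experiment
#' @export
autoplot.epi_experiment <- function(object, ...) plot_power(object)
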