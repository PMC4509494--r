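# User-facing detection runner and result containers.

#' Detect SNP-SNP interactions with a particle swarm
#'
#' Runs the full optimizer on a case-control dataset: swarm initialization,
#' `iterations - 1` update steps (initialization counts as iteration 1), and
#' — for the `oblpso` variant — the exhaustive post-search over the most
#' visited SNPs. The `pso` variant is the plain baseline: static inertia, no
#' opposition step, no post-search. With `runs > 1` the optimizer is
#' restarted that many times on one seeded RNG stream and the runs are
#' aggregated into a report of distinct detected SNP sets with their
#' detection counts.
#'
#' @param data A SNP dataset tibble (see [read_snp_data()], [snp_data()]).
#' @param particles,iterations,order,c1,c2,inertia,top_n,variant,seed
#'   Optimizer settings, see [swarm_config()].
#' @param runs Number of independent restarts (default 1).
#' @return For `runs = 1` an `epi_result`: the detected SNP set with its
#'   interaction MI, per-SNP MI, G-test p-value (raw and Bonferroni-corrected
#'   over all C(M, K) combinations), the per-SNP occupancy counters, and the
#'   per-iteration gbest MI trace. For `runs > 1` an `epi_multirun` whose
#'   `report` groups identical SNP sets with a `times` column, sorted by
#'   decreasing interaction MI. Both have [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
#' @examples
#' m <- calibrate_penetrance(penetrance_shape("threshold_both_minor",
#'                                            effect = 3),
#'                           mafs = c(0.4, 0.4), prevalence = 0.1)
#' sim <- simulate_epistasis(m, 300, 300, n_snps = 20, seed = 1)
#' fit <- detect_interactions(sim$data, particles = 20, iterations = 20,
#'                            seed = 7)
#' glance(fit)
detect_interactions <- function(data, particles = 100, iterations = 100,
                                order = 2, c1 = 2, c2 = 2, inertia = 0.65,
                                top_n = 10, variant = c("oblpso", "pso"),
                                seed = NULL, runs = 1) {
  variant <- match.arg(variant)
  data <- validate_snp_data(data)
  config <- swarm_config(particles, iterations, order, c1, c2, inertia,
                         top_n, variant, seed)
  geno <- geno_matrix(data)
  pheno <- data$phenotype
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_noseed <- config
  cfg_noseed$seed <- NULL  # the stream is seeded once, up front
  if (runs == 1) {
    return(run_swarm_once(data, geno, pheno, cfg_noseed, config))
  }
  results <- lapply(seq_len(runs), function(r) {
    run_swarm_once(data, geno, pheno, cfg_noseed, config)
  })
  aggregate_runs(results, config)
}

# Internal: one full optimizer run on an already-seeded stream.
run_swarm_once <- function(data, geno, pheno, config, config_echo) {
  cache <- new.env(parent = emptyenv())
  state <- .initialize_swarm(geno, pheno, config, cache)
  while (state$iteration < config$iterations) {
    state <- .step_swarm(state, geno, pheno, config, cache)
  }
  if (config$variant == "oblpso") {
    post <- .postprocess_swarm(state, geno, pheno, config, cache)
    snp_set <- post$snp_set
    mi <- post$mi
    improved <- post$improved
  } else {
    snp_set <- sort.int(state$gbest)
    mi <- state$gbest_mi
    improved <- NA
  }
  ids <- snp_ids(data)
  m <- length(ids)
  mi_ind <- vapply(snp_set, function(i) swarm_mi(geno, pheno, i, cache),
                   numeric(1))
  test <- gtest_pvalue(cell_counts(geno, pheno, snp_set))
  n_tests <- choose(m, config$order)
  structure(
    list(
      snp_set = snp_set,
      snp_id = ids[snp_set],
      mi_interaction = mi,
      mi_individual = setNames(mi_ind, ids[snp_set]),
      statistic = test$statistic,
      df = test$df,
      p_value = test$p_value,
      p_bonferroni = min(1, test$p_value * n_tests),
      n_tests = n_tests,
      improved_by_postsearch = improved,
      counters = tibble::tibble(index = seq_len(m), snp_id = ids,
                                count = state$count),
      trace = tibble::tibble(iteration = seq_along(state$trace),
                             gbest_mi = state$trace),
      config = config_echo,
      n_individuals = nrow(data),
      n_snps = m
    ),
    class = "epi_result"
  )
}

# Internal: group identical final SNP sets across restarts (Table-style
# multi-run report).
aggregate_runs <- function(results, config) {
  rows <- purrr::map_dfr(results, function(r) {
    tibble::tibble(
      snp_ids = paste(r$snp_id, collapse = ","),
      snps = list(r$snp_set),
      mi_interaction = r$mi_interaction,
      mi_individual = paste(signif(r$mi_individual, 4), collapse = ","),
      p_value = r$p_value,
      p_bonferroni = r$p_bonferroni
    )
  })
  report <- rows |>
    dplyr::group_by(.data$snp_ids) |>
    dplyr::summarise(
      times = dplyr::n(),
      snps = .data$snps[1],
      mi_interaction = .data$mi_interaction[1],
      mi_individual = .data$mi_individual[1],
      p_value = .data$p_value[1],
      p_bonferroni = .data$p_bonferroni[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mi_interaction)) |>
    dplyr::relocate("snp_ids", "times")
  structure(
    list(report = report, runs = results, config = config),
    class = "epi_multirun"
  )
}

#' @export
print.epi_result <- function(x, ...) {
  cat("<epi_result> ", x$config$variant, ", K = ", x$config$order,
      ", P = ", x$config$particles, ", T = ", x$config$iterations, "\n",
      sep = "")
  cat("  detected set: ", paste(x$snp_id, collapse = ", "),
      "  (indices ", paste(x$snp_set, collapse = ", "), ")\n", sep = "")
  cat("  interaction MI = ", signif(x$mi_interaction, 4), " bits",
      "; individual MI = ",
      paste(signif(x$mi_individual, 4), collapse = ", "), "\n", sep = "")
  cat("  G = ", signif(x$statistic, 4), " (df ", x$df, "), p = ",
      signif(x$p_value, 3), ", Bonferroni p = ",
      signif(x$p_bonferroni, 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.epi_multirun <- function(x, ...) {
  cat("<epi_multirun> ", length(x$runs), " runs, variant ",
      x$config$variant, "\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Tidy a detection result
#'
#' One row per detected SNP: id, 1-based index, its single-SNP MI, its
#' occupancy counter, plus the shared interaction-level columns
#' (`mi_interaction`, `p_value`, `p_bonferroni`).
#'
#' @param x An `epi_result`.
#' @param ... Unused.
#' @return A tibble with `order` rows.
#' @method tidy epi_result
#' @export
tidy.epi_result <- function(x, ...) {
  tibble::tibble(
    snp_id = x$snp_id,
    index = x$snp_set,
    mi_individual = unname(x$mi_individual),
    count = x$counters$count[x$snp_set],
    mi_interaction = x$mi_interaction,
    p_value = x$p_value,
    p_bonferroni = x$p_bonferroni
  )
}

#' Summarise a detection result in one row
#'
#' @param x An `epi_result`.
#' @param ... Unused.
#' @return A one-row tibble (variant, sizes, detected set, MI, G-test).
#' @method glance epi_result
#' @export
glance.epi_result <- function(x, ...) {
  tibble::tibble(
    variant = x$config$variant,
    particles = x$config$particles,
    iterations = x$config$iterations,
    order = x$config$order,
    snp_ids = paste(x$snp_id, collapse = ","),
    mi_interaction = x$mi_interaction,
    statistic = x$statistic,
    df = x$df,
    p_value = x$p_value,
    p_bonferroni = x$p_bonferroni,
    n_individuals = x$n_individuals,
    n_snps = x$n_snps
  )
}

#' @rdname tidy.epi_result
#' @method tidy epi_multirun
#' @export
tidy.epi_multirun <- function(x, ...) x$report

#' @rdname glance.epi_result
#' @method glance epi_multirun
#' @export
glance.epi_multirun <- function(x, ...) {
  tibble::tibble(
    variant = x$config$variant,
    runs = length(x$runs),
    distinct_sets = nrow(x$report),
    top_set = x$report$snp_ids[1],
    top_times = x$report$times[1],
    top_mi = x$report$mi_interaction[1]
  )
}

#' Plot the swarm-best fitness trace
#'
#' Line plot of the best-so-far interaction MI per iteration; the dashed
#' horizontal line marks the final (post-search) MI.
#'
#' @param object An `epi_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epi_result
#' @export
autoplot.epi_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$gbest_mi)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$mi_interaction,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "iteration",
      y = "best-so-far MI (bits)",
      title = paste0("Swarm fitness trace (", object$config$variant, ")"),
      subtitle = paste("final set:", paste(object$snp_id, collapse = ", "))
    ) +
    ggplot2::theme_minimal()
}
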