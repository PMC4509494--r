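# Detection-power scoring over batches of datasets with known ground truth.

# Internal: coerce one detection/truth entry to an integer index set.
as_index_set <- function(x) {
  if (inherits(x, "epi_result")) return(x$snp_set)
  if (is.data.frame(x)) return(as.integer(x$index))
  as.integer(x)
}

#' Strict detection power (Power 1)
#'
#' The proportion of datasets whose entire ground-truth SNP set is recovered
#' with no false positives: dataset i is a success (x_i = 1) only when the
#' detected set equals the truth set exactly (as sets), and
#' Power 1 = sum(x_i) / N.
#'
#' @param detected List of detected SNP sets, one per dataset: `epi_result`
#'   objects, integer index vectors, or truth-style tibbles with an `index`
#'   column.
#' @param truths List of ground-truth sets in the same formats.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' power1(list(c(1, 2), c(3, 4)), list(c(2, 1), c(3, 5)))  # 0.5
power1 <- function(detected, truths) {
  mean(power_tags(detected, truths)$exact)
}

#' Partial detection power (Power 2)
#'
#' The average proportion of ground-truth SNPs among the K reported SNPs:
#' with y_i the number of truth SNPs in dataset i's detected set,
#' Power 2 = sum(y_i) / (K N). Always at least Power 1.
#'
#' @inheritParams power1
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' power2(list(c(1, 2), c(3, 4)), list(c(2, 1), c(3, 5)))  # 0.75
power2 <- function(detected, truths) {
  tags <- power_tags(detected, truths)
  sum(tags$hits) / sum(tags$k)
}

# Internal: per-dataset exact tags and truth-hit counts.
power_tags <- function(detected, truths) {
  if (length(detected) != length(truths)) {
    stop("detected and truths must have equal length", call. = FALSE)
  }
  det <- lapply(detected, as_index_set)
  tru <- lapply(truths, as_index_set)
  tibble::tibble(
    dataset = seq_along(det),
    k = lengths(tru),
    hits = purrr::map2_int(det, tru, ~ length(intersect(.x, .y))),
    exact = purrr::map2_lgl(det, tru, ~ setequal(.x, .y))
  )
}

#' Full power report for a batch of detections
#'
#' Bundles the per-dataset detection tags (x_i, y_i) with the two summary
#' powers. `tidy()` returns the per-dataset table, `glance()` the one-row
#' summary.
#'
#' @inheritParams power1
#' @param label Optional label (e.g. method or model name) echoed in the
#'   summary.
#' @return An object of class `epi_power` with elements `per_dataset`
#'   (tibble of `dataset`, `k`, `hits`, `exact`), `power1`, `power2`, `n`,
#'   `label`.
#' @export
power_report <- function(detected, truths, label = NULL) {
  tags <- power_tags(detected, truths)
  structure(
    list(
      per_dataset = tags,
      power1 = mean(tags$exact),
      power2 = sum(tags$hits) / sum(tags$k),
      n = nrow(tags),
      label = label
    ),
    class = "epi_power"
  )
}

#' @export
print.epi_power <- function(x, ...) {
  cat("<epi_power>", if (!is.null(x$label)) x$label else "", "\n")
  cat("  N =", x$n, " Power 1 =", signif(x$power1, 4),
      " Power 2 =", signif(x$power2, 4), "\n")
  invisible(x)
}

#' @rdname power_report
#' @param x An `epi_power`.
#' @param ... Unused.
#' @method tidy epi_power
#' @export
tidy.epi_power <- function(x, ...) x$per_dataset

#' @rdname power_report
#' @method glance epi_power
#' @export
glance.epi_power <- function(x, ...) {
  tibble::tibble(label = x$label %||% NA_character_, n = x$n,
                 power1 = x$power1, power2 = x$power2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
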