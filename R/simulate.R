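# Penetrance-model case-control simulator: plants a K-SNP interaction drawn
# from a calibrated penetrance table among background SNPs simulated under
# Hardy-Weinberg equilibrium with MAFs drawn uniformly from [0.05, 0.5].

#' Hardy-Weinberg genotype probabilities
#'
#' Genotype class probabilities ((1-q)^2, 2q(1-q), q^2) for minor allele
#' frequency q, in genotype order 0/1/2.
#'
#' @param maf Minor allele frequency in \[0, 0.5\].
#' @return Numeric vector of length 3 summing to 1.
#' @export
#' @examples
#' hwe_probs(0.3)  # 0.49 0.42 0.09
hwe_probs <- function(maf) {
  if (length(maf) != 1L || is.na(maf) || maf < 0 || maf > 0.5) {
    stop("maf must be a single value in [0, 0.5]", call. = FALSE)
  }
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

# Internal: joint HWE probability over K loci, as an array shaped like the
# penetrance table (3 x 3 x ... , first locus = first dimension, so that
# as.vector() enumerates with the FIRST locus fastest).
hwe_joint <- function(mafs) {
  probs <- lapply(mafs, hwe_probs)
  out <- Reduce(function(a, b) outer(a, b), probs)
  array(out, dim = rep(3L, length(mafs)))
}

#' Qualitative penetrance shapes for two-locus disease archetypes
#'
#' Returns the unnormalised 3 x 3 penetrance shape (rows: genotype of SNP a,
#' columns: genotype of SNP b) of a named two-locus architecture; the shape is
#' scaled to a target prevalence by [calibrate_penetrance()].
#'
#' * `threshold_both_minor` — risk elevated by a factor (1 + effect) iff both
#'   SNPs carry at least one minor allele (marginal + interactive effects).
#' * `inverse_marginal` — SNP a's minor allele elevates risk (x (1 + effect))
#'   when SNP b carries no minor allele, but the effect inverts
#'   (x 1 / (1 + effect)) when both SNPs carry minor alleles.
#' * `zz` — checkerboard: risk elevated iff the total minor-allele count
#'   g_a + g_b is odd; has exactly zero single-locus marginal effect under
#'   HWE at MAF 0.5.
#' * `xor` — risk elevated iff exactly one SNP carries a minor allele; zero
#'   marginal effect at MAF 1 - 1/sqrt(2).
#' * `ref39_m3`, `ref39_m4` — placeholders for externally published tables;
#'   the 3 x 3 `table` argument must be supplied.
#'
#' @param model Archetype name (see above).
#' @param baseline Baseline shape value alpha of non-elevated cells.
#' @param effect Effect size theta (relative elevation); ignored for
#'   user-supplied tables.
#' @param table User-supplied 3 x 3 shape, required for `ref39_m3` /
#'   `ref39_m4` and accepted for any name as an override.
#' @return A 3 x 3 numeric matrix of non-negative shape values.
#' @export
penetrance_shape <- function(model = c("threshold_both_minor",
                                       "inverse_marginal", "zz", "xor",
                                       "ref39_m3", "ref39_m4"),
                             baseline = 1, effect = 1, table = NULL) {
  model <- match.arg(model)
  if (!is.null(table)) {
    table <- as.matrix(table)
    if (!all(dim(table) == c(3L, 3L)) || any(table < 0)) {
      stop("user-supplied shape must be a non-negative 3x3 table",
           call. = FALSE)
    }
    return(unname(table))
  }
  if (model %in% c("ref39_m3", "ref39_m4")) {
    stop("model '", model, "' requires a user-supplied 3x3 `table` ",
         "(its published values are external to this package)",
         call. = FALSE)
  }
  g <- expand.grid(ga = 0:2, gb = 0:2)
  val <- switch(model,
    threshold_both_minor = baseline * (1 + effect * (g$ga >= 1 & g$gb >= 1)),
    inverse_marginal = {
      v <- rep(baseline, nrow(g))
      up <- g$ga >= 1 & g$gb == 0
      down <- g$ga >= 1 & g$gb >= 1
      v[up] <- baseline * (1 + effect)
      v[down] <- baseline / (1 + effect)
      v
    },
    zz = baseline + effect * ((g$ga + g$gb) %% 2 == 1),
    xor = baseline + effect * xor(g$ga >= 1, g$gb >= 1)
  )
  matrix(val, nrow = 3L)  # rows ga, cols gb
}

#' Calibrate a penetrance shape to a target prevalence
#'
#' Scales a non-negative penetrance shape by the constant c solving
#' sum_g c shape(g) P_HWE(g) = prevalence, where P_HWE is the joint
#' Hardy-Weinberg genotype distribution at the given MAFs. Shape ratios are
#' preserved; calibration fails if any scaled penetrance would exceed 1.
#'
#' @param shape Non-negative array of 3^K penetrances up to scale (a 3 x 3
#'   matrix for K = 2), first locus on the first dimension.
#' @param mafs K minor allele frequencies in (0, 0.5].
#' @param prevalence Target marginal disease probability in (0, 1).
#' @param name Model label carried through to reports.
#' @return An object of class `penetrance_model`: list with `table` (the
#'   calibrated penetrance array), `mafs`, `prevalence`, `name`.
#' @export
#' @examples
#' m <- calibrate_penetrance(penetrance_shape("xor", 1, 4),
#'                           mafs = c(0.5, 0.5), prevalence = 0.1)
#' m$prevalence
calibrate_penetrance <- function(shape, mafs, prevalence, name = "custom") {
  shape <- as.array(shape)
  k <- length(mafs)
  if (length(shape) != 3^k) {
    stop("shape has ", length(shape), " cells; expected 3^", k, call. = FALSE)
  }
  if (any(shape < 0) || all(shape == 0)) {
    stop("shape must be non-negative and not all zero", call. = FALSE)
  }
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop("mafs must lie in (0, 0.5]", call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }
  p_hwe <- hwe_joint(mafs)
  denom <- sum(shape * p_hwe)
  if (denom <= 0) {
    stop("shape is zero on the entire HWE support", call. = FALSE)
  }
  c0 <- prevalence / denom
  table <- c0 * shape
  if (max(table) > 1 + 1e-12) {
    stop("infeasible: calibrated penetrance ", signif(max(table), 4),
         " exceeds 1; lower the prevalence or flatten the shape",
         call. = FALSE)
  }
  structure(
    list(table = table, mafs = as.numeric(mafs),
         prevalence = prevalence, name = name),
    class = "penetrance_model"
  )
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("<penetrance_model> ", x$name, "\n", sep = "")
  cat("  K = ", length(x$mafs),
      ", MAFs = ", paste(signif(x$mafs, 3), collapse = ", "),
      ", prevalence = ", x$prevalence, "\n", sep = "")
  print(signif(x$table, 4))
  invisible(x)
}

#' Closed-form genotype-class probabilities of a penetrance model
#'
#' Per joint genotype class g of the causal SNPs: the HWE probability
#' P_HWE(g), the penetrance f(g), and the retrospective sampling
#' distributions P(g | case) = f(g) P_HWE(g) / prevalence and
#' P(g | control) = (1 - f(g)) P_HWE(g) / (1 - prevalence) used by
#' [simulate_epistasis()]. These satisfy the mixture identity
#' prevalence P(g|case) + (1 - prevalence) P(g|control) = P_HWE(g).
#'
#' @param model A `penetrance_model`.
#' @return A tibble with one row per genotype class (columns `g1 ... gK`,
#'   `p_hwe`, `penetrance`, `p_case`, `p_control`), ordered with the first
#'   locus varying fastest (array order of the penetrance table).
#' @export
genotype_class_probs <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  k <- length(model$mafs)
  p_hwe <- as.vector(hwe_joint(model$mafs))
  f <- as.vector(model$table)
  grid <- expand.grid(rep(list(0:2), k))
  names(grid) <- paste0("g", seq_len(k))
  out <- tibble::as_tibble(grid)
  out$p_hwe <- p_hwe
  out$penetrance <- f
  out$p_case <- f * p_hwe / model$prevalence
  out$p_control <- (1 - f) * p_hwe / (1 - model$prevalence)
  out
}

#' Simulate a case-control dataset with a planted SNP interaction
#'
#' Retrospective (case-control) sampling: joint genotypes of the K causal
#' SNPs are drawn from P(g | case) proportional to f(g) P_HWE(g) for cases
#' and P(g | control) proportional to (1 - f(g)) P_HWE(g) for controls, where
#' f is the calibrated penetrance table. The causal columns are placed at
#' random distinct positions. Every remaining SNP is drawn i.i.d. under HWE
#' with its own MAF sampled uniformly from `maf_range`, identically in cases
#' and controls (no association, no linkage disequilibrium).
#'
#' @param model A `penetrance_model` from [calibrate_penetrance()].
#' @param n_cases,n_controls Numbers of case (phenotype 1) and control
#'   (phenotype 0) individuals.
#' @param n_snps Total number of SNPs M (must exceed K).
#' @param maf_range Range the background MAFs are drawn from.
#' @param seed Optional integer seed; fixing it makes the dataset
#'   reproducible.
#' @return A list with `data` (a `snp_data` tibble; cases first), `truth`
#'   (tibble of `index`, `snp_id`, `model` for the causal SNPs), `model`,
#'   and `background_mafs` (tibble of the drawn MAF of every non-causal SNP).
#' @export
#' @examples
#' m <- calibrate_penetrance(penetrance_shape("threshold_both_minor",
#'                                            effect = 3),
#'                           mafs = c(0.4, 0.4), prevalence = 0.1)
#' sim <- simulate_epistasis(m, n_cases = 100, n_controls = 100,
#'                           n_snps = 20, seed = 1)
#' sim$truth
simulate_epistasis <- function(model, n_cases = 2000, n_controls = 2000,
                               n_snps = 100, maf_range = c(0.05, 0.5),
                               seed = NULL) {
  stopifnot(inherits(model, "penetrance_model"))
  k <- length(model$mafs)
  if (n_snps <= k) stop("n_snps must exceed the interaction order K",
                        call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  probs <- genotype_class_probs(model)
  ncell <- nrow(probs)
  gmat <- as.matrix(probs[paste0("g", seq_len(k))])
  n <- n_cases + n_controls

  # RNG call order: causal case cells, causal control cells, causal
  # placement, background MAFs, background genotype columns (left to right).
  case_cells <- sample.int(ncell, n_cases, replace = TRUE, prob = probs$p_case)
  ctrl_cells <- sample.int(ncell, n_controls, replace = TRUE,
                           prob = probs$p_control)
  causal_pos <- sort(sample.int(n_snps, k))

  geno <- matrix(0L, nrow = n, ncol = n_snps)
  geno[, causal_pos] <- rbind(gmat[case_cells, , drop = FALSE],
                              gmat[ctrl_cells, , drop = FALSE])
  bg_pos <- setdiff(seq_len(n_snps), causal_pos)
  bg_maf <- runif(length(bg_pos), maf_range[1], maf_range[2])
  for (j in seq_along(bg_pos)) {
    geno[, bg_pos[j]] <- sample(0:2, n, replace = TRUE,
                                prob = hwe_probs(bg_maf[j]))
  }
  ids <- paste0("SNP", seq_len(n_snps))
  data <- snp_data(geno, phenotype = rep(c(1L, 0L), c(n_cases, n_controls)),
                   snp_ids = ids)
  list(
    data = data,
    truth = tibble::tibble(index = causal_pos, snp_id = ids[causal_pos],
                           model = model$name),
    model = model,
    background_mafs = tibble::tibble(index = bg_pos, snp_id = ids[bg_pos],
                                     maf = bg_maf)
  )
}

#' Read / write a penetrance model as JSON
#'
#' Plain-text persistence for calibrated penetrance models, used for the
#' packaged fixture models and by the command-line `simulate` subcommand.
#'
#' @param model A `penetrance_model`.
#' @param path File path.
#' @return `read_penetrance()` a `penetrance_model`; `write_penetrance()`
#'   `path` invisibly.
#' @export
write_penetrance <- function(model, path) {
  stopifnot(inherits(model, "penetrance_model"))
  k <- length(model$mafs)
  jsonlite::write_json(
    list(name = model$name, k = k, mafs = model$mafs,
         prevalence = model$prevalence,
         table = as.vector(model$table)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_penetrance
#' @export
read_penetrance <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  table <- array(as.numeric(x$table), dim = rep(3L, x$k))
  structure(
    list(table = table, mafs = as.numeric(x$mafs),
         prevalence = as.numeric(x$prevalence), name = x$name),
    class = "penetrance_model"
  )
}

#' The packaged strong-effect benchmark model
#'
#' The calibrated two-locus model shipped in `inst/extdata/`
#' (`threshold_both_minor` shape, effect 3, MAFs 0.4/0.4, prevalence 0.1):
#' a marginal-plus-interactive architecture whose causal pair's MI dominates
#' every background pair at moderate sample sizes, used by the package's
#' power benchmarks.
#'
#' @return A `penetrance_model`.
#' @export
strong_effect_model <- function() {
  read_penetrance(system.file("extdata", "model_strong_effect.json",
                              package = "episwarm", mustWork = TRUE))
}
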