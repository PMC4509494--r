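# Fitness: plug-in mutual information between a K-SNP genotype combination
# and the binary phenotype, plus the likelihood-ratio (G) association test.

# Internal: 1-based lexicographic cell code for a genotype tuple, first SNP
# most significant. geno is the integer matrix, idx the (ordered) SNP columns.
geno_cell_code <- function(geno, idx) {
  code <- geno[, idx[1L]]
  if (length(idx) > 1L) {
    for (j in 2:length(idx)) code <- code * 3L + geno[, idx[j]]
  }
  code + 1L
}

# Internal: 3^K x 2 count matrix (controls, cases) for SNP columns idx.
cell_counts <- function(geno, pheno, idx) {
  k <- length(idx)
  ncell <- 3L^k
  code <- geno_cell_code(geno, idx)
  counts <- tabulate(code + ncell * pheno, nbins = 2L * ncell)
  matrix(counts, ncol = 2L, dimnames = list(NULL, c("controls", "cases")))
}

# Internal: MI in bits from a 3^K x 2 count matrix.
mi_from_counts <- function(counts) {
  n <- sum(counts)
  hx <- entropy_bits(rowSums(counts))
  hy <- entropy_bits(colSums(counts))
  hxy <- entropy_bits(counts)
  max(hx + hy - hxy, 0)
}

entropy_bits <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Plug-in Shannon entropy in bits
#'
#' Entropy of the empirical distribution defined by a vector (or array) of
#' non-negative counts, in bits, with the usual convention 0 log 0 = 0.
#'
#' @param counts Non-negative numeric counts summing to a positive total.
#' @return Entropy in bits (a single non-negative number).
#' @export
#' @examples
#' shannon_entropy(c(5, 5))     # 1 bit
#' shannon_entropy(c(1, 1, 2))  # 1.5 bits
shannon_entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (sum(counts) <= 0) stop("counts sum to zero", call. = FALSE)
  entropy_bits(counts)
}

#' Genotype-phenotype contingency table of a SNP combination
#'
#' Tallies individuals over the joint genotype of the selected SNPs and the
#' phenotype. Cells are ordered lexicographically by genotype tuple (first
#' SNP most significant), giving 3^K rows.
#'
#' @param data A SNP dataset tibble.
#' @param snps SNP selection: 1-based column indices or SNP ids; must be
#'   distinct and within range.
#' @return A tibble with one genotype column per selected SNP (named
#'   `g_<snp id>`) and integer `controls` / `cases` counts; attribute `k`
#'   holds the combination order and `n` the total count.
#' @export
snp_contingency <- function(data, snps) {
  data <- validate_snp_data(data)
  idx <- resolve_snps(data, snps)
  counts <- cell_counts(geno_matrix(data), data$phenotype, idx)
  k <- length(idx)
  grid <- rev(expand.grid(rep(list(0:2), k))[seq_len(k)])
  names(grid) <- paste0("g_", snp_ids(data)[idx])
  out <- tibble::as_tibble(grid)
  out$controls <- counts[, 1L]
  out$cases <- counts[, 2L]
  attr(out, "k") <- k
  attr(out, "n") <- sum(counts)
  out
}

# Internal: resolve a SNP selection (indices or ids) to distinct indices.
resolve_snps <- function(data, snps) {
  if (is.character(snps)) {
    idx <- match(snps, snp_ids(data))
    if (anyNA(idx)) {
      stop("unknown SNP id(s): ", paste(snps[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(snps)
  }
  m <- n_snps(data)
  if (any(idx < 1L | idx > m)) {
    stop("SNP index out of range [1, ", m, "]: ",
         paste(idx[idx < 1L | idx > m], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("duplicate SNP index: ", paste(idx[duplicated(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Mutual information between a SNP combination and the phenotype
#'
#' The swarm's fitness function: plug-in mutual information
#' MI(X; Y) = H(X) + H(Y) - H(X, Y) in bits, where X is the joint genotype of
#' the selected SNPs and Y the binary phenotype. For a binary phenotype the
#' value lies in \[0, 1\] bits and is invariant to the order of `snps`.
#'
#' @inheritParams snp_contingency
#' @return MI in bits (single non-negative number).
#' @export
#' @examples
#' d <- snp_data(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), nrow = 4),
#'               phenotype = c(0, 0, 1, 1))
#' snp_mi(d, 1)  # perfectly predictive SNP: 1 bit
snp_mi <- function(data, snps) {
  data <- validate_snp_data(data)
  idx <- resolve_snps(data, snps)
  mi_from_counts(cell_counts(geno_matrix(data), data$phenotype, idx))
}

#' Likelihood-ratio (G) test of genotype-phenotype independence
#'
#' Association test paired with the MI fitness: the G statistic equals
#' 2 n MI in nats, with degrees of freedom reduced for genotype cells that
#' are empty in both phenotype classes
#' (df = (nonzero genotype cells - 1) x (2 - 1)). A degenerate table with a
#' single occupied genotype cell yields p = 1.
#'
#' @param counts A 3^K x 2 count matrix, or the tibble from
#'   [snp_contingency()].
#' @return A tibble with `statistic` (G), `df`, and `p_value`.
#' @seealso [snp_gtest()] to compute directly from a dataset.
#' @export
gtest_pvalue <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- cbind(counts$controls, counts$cases)
  }
  counts <- as.matrix(counts)
  n <- sum(counts)
  if (n <= 0) stop("empty contingency table", call. = FALSE)
  mi <- mi_from_counts(counts)
  g <- 2 * n * mi * log(2)  # bits -> nats
  df <- (sum(rowSums(counts) > 0) - 1L) * (ncol(counts) - 1L)
  p <- if (df < 1L || g <= 0) 1 else stats::pchisq(g, df, lower.tail = FALSE)
  tibble::tibble(statistic = g, df = df, p_value = p)
}

#' @rdname gtest_pvalue
#' @inheritParams snp_contingency
#' @export
snp_gtest <- function(data, snps) {
  gtest_pvalue(snp_contingency(data, snps))
}

#' Exhaustive MI scan over K-SNP combinations
#'
#' Evaluates the MI fitness of every K-subset of the candidate SNPs, sorted
#' by decreasing MI. Used by the swarm's post-search over the most visited
#' SNPs; also handy as a ground-truth reference on small panels.
#'
#' @inheritParams snp_contingency
#' @param k Combination order (default 2).
#' @param candidates Optional subset of SNP indices/ids to restrict the scan
#'   to; defaults to all SNPs.
#' @return A tibble with list-column `snps` (sorted integer indices),
#'   `snp_ids` (comma-separated), and `mi`, ordered by decreasing `mi`.
#' @export
mi_scan <- function(data, k = 2, candidates = NULL) {
  data <- validate_snp_data(data)
  cand <- if (is.null(candidates)) seq_len(n_snps(data)) else {
    resolve_snps(data, candidates)
  }
  if (length(cand) < k) stop("fewer candidates than k", call. = FALSE)
  geno <- geno_matrix(data)
  pheno <- data$phenotype
  sets <- combn(sort(cand), k)
  mi <- apply(sets, 2L, function(idx) {
    mi_from_counts(cell_counts(geno, pheno, idx))
  })
  ids <- snp_ids(data)
  out <- tibble::tibble(
    snps = lapply(seq_len(ncol(sets)), function(j) sets[, j]),
    snp_ids = apply(sets, 2L, function(idx) paste(ids[idx], collapse = ",")),
    mi = mi
  )
  dplyr::arrange(out, dplyr::desc(.data$mi))
}
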