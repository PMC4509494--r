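# Shared fixtures and independent oracles, all built in code.

# Independent MI oracle: direct double sum p(x,y) log2(p(x,y)/(p(x)p(y)))
# over the observed joint cells, via table() on pasted genotype tuples.
# Deliberately shares no code with the package's H(X)+H(Y)-H(X,Y) route.
oracle_mi <- function(data, idx) {
  ids <- setdiff(names(data), "phenotype")[idx]
  x <- apply(as.matrix(data[ids]), 1L, paste, collapse = "-")
  tab <- table(x, data$phenotype)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  s <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (pxy[i, j] > 0) {
        s <- s + pxy[i, j] * log2(pxy[i, j] / (px[i] * py[j]))
      }
    }
  }
  s
}

# Independent MI oracle in nats, straight from a counts matrix.
mi_nats_oracle <- function(counts) {
  n <- sum(counts)
  pxy <- counts / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  s <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (pxy[i, j] > 0) s <- s + pxy[i, j] * log(pxy[i, j] / (px[i] * py[j]))
    }
  }
  s
}

# Random dataset with no planted structure.
random_dataset <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  snp_data(
    matrix(sample(0:2, n * m, replace = TRUE), nrow = n),
    phenotype = sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
  )
}

# Balanced dataset whose first SNP equals the phenotype exactly (1 bit) and
# whose second SNP is the same column in both classes (0 bits).
perfect_and_null_dataset <- function(n_per_class = 10) {
  pattern <- rep_len(c(0L, 1L, 2L), n_per_class)
  snp_data(
    cbind(rep(c(0L, 1L), each = n_per_class),  # mirrors the phenotype
          c(pattern, pattern)),                # identical in both classes
    phenotype = rep(c(0L, 1L), each = n_per_class),
    snp_ids = c("mirror", "null")
  )
}

# Dataset where the (jointly predictive, marginally silent) planted pair is
# the two given columns: phenotype = XOR of two binary SNP columns.
planted_xor_dataset <- function(n = 200, m = 10, pair = c(3, 7),
                                seed = 1) {
  set.seed(seed)
  geno <- matrix(sample(0:2, n * m, replace = TRUE), nrow = n)
  a <- sample(0:1, n, replace = TRUE)
  b <- sample(0:1, n, replace = TRUE)
  geno[, pair[1]] <- a
  geno[, pair[2]] <- b
  snp_data(geno, phenotype = as.integer(xor(a == 1, b == 1)))
}

# The committed strong-effect benchmark model.
fixture_model <- function() strong_effect_model()

# PLINK .raw content for a tiny two-SNP file, written per the format's
# published layout (header FID IID PAT MAT SEX PHENOTYPE + <snp>_<allele>).
plink_raw_lines <- function() {
  c(
    "FID IID PAT MAT SEX PHENOTYPE SNP1_A SNP2_C",
    "fam1 ind1 0 0 1 1 0 2",
    "fam1 ind2 0 0 2 1 1 1",
    "fam2 ind3 0 0 1 2 2 0",
    "fam2 ind4 0 0 2 2 1 2"
  )
}
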