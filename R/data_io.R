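#' Assemble a case-control SNP dataset
#'
#' Builds the tabular genotype container used throughout the package: a tibble
#' with one integer column per SNP (genotypes coded 0 = homozygous common,
#' 1 = heterozygous, 2 = homozygous minor) and a final `phenotype` column
#' (0 = control, 1 = case). One row per individual.
#'
#' @param genotypes Integer matrix, individuals x SNPs, values in \{0, 1, 2\}.
#' @param phenotype Integer vector of 0/1 disease labels, one per individual.
#' @param snp_ids Character vector of unique SNP identifiers; defaults to
#'   `SNP1 ... SNPM`.
#'
#' @return A validated tibble of class `snp_data` with `M + 1` columns.
#' @export
#' @examples
#' g <- matrix(c(0, 1, 2, 1, 0, 0, 2, 2), nrow = 4)
#' snp_data(g, phenotype = c(0, 0, 1, 1))
snp_data <- function(genotypes, phenotype, snp_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(ncol(genotypes)))
  colnames(genotypes) <- snp_ids
  out <- tibble::as_tibble(as.data.frame(genotypes, check.names = FALSE))
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  out$phenotype <- as.integer(phenotype)
  validate_snp_data(out)
}

#' Validate a SNP dataset tibble
#'
#' Checks the container invariants: a `phenotype` column of 0/1 values, all
#' genotype entries in \{0, 1, 2\} with no missing values, unique SNP ids, and
#' at least two SNPs. Violations abort with a diagnostic naming the offending
#' row and SNP column.
#'
#' @param data A data frame as produced by [snp_data()] or [read_snp_data()].
#' @return The validated data, invisibly coerced to a tibble, for piping.
#' @export
validate_snp_data <- function(data) {
  data <- tibble::as_tibble(data, .name_repair = "minimal")
  if (!"phenotype" %in% names(data)) {
    stop("dataset has no 'phenotype' column", call. = FALSE)
  }
  ids <- names(data)[names(data) != "phenotype"]
  if (length(ids) < 2L) {
    stop("dataset must contain at least 2 SNP columns", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(
      "duplicate SNP id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  ph <- data$phenotype
  if (anyNA(ph) || !all(ph %in% c(0L, 1L))) {
    bad <- which(is.na(ph) | !(ph %in% c(0L, 1L)))[1L]
    stop(
      "phenotype must be 0 (control) or 1 (case); offending value '",
      ph[bad], "' at row ", bad,
      call. = FALSE
    )
  }
  for (id in ids) {
    g <- suppressWarnings(as.numeric(data[[id]]))
    ok <- !is.na(g) & g %in% c(0, 1, 2)
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop(
        "genotype must be 0/1/2; offending value '", data[[id]][bad],
        "' at row ", bad, ", SNP '", id, "'",
        call. = FALSE
      )
    }
    data[[id]] <- as.integer(g)
  }
  data$phenotype <- as.integer(ph)
  data <- data[c(ids, "phenotype")]
  class(data) <- unique(c("snp_data", class(data)))
  invisible(data)
}

#' @rdname snp_helpers
#' @export
snp_ids <- function(data) names(data)[names(data) != "phenotype"]

#' Dataset accessors
#'
#' Small helpers reading off the dimensions of a SNP dataset: the SNP
#' identifiers, the number of SNPs `M`, and the case/control counts.
#'
#' @param data A SNP dataset tibble.
#' @return `snp_ids()` a character vector; the others a single integer.
#' @name snp_helpers
#' @export
n_snps <- function(data) length(snp_ids(data))

#' @rdname snp_helpers
#' @export
n_cases <- function(data) sum(data$phenotype == 1L)

#' @rdname snp_helpers
#' @export
n_controls <- function(data) sum(data$phenotype == 0L)

# Internal: genotype matrix + phenotype vector, the hot-loop representation.
geno_matrix <- function(data) {
  ids <- snp_ids(data)
  m <- matrix(0L, nrow = nrow(data), ncol = length(ids),
              dimnames = list(NULL, ids))
  for (j in seq_along(ids)) m[, j] <- data[[ids[j]]]
  m
}

#' Read a case-control genotype file
#'
#' Reads either the package's native tab-separated layout (header of SNP ids
#' plus a final `phenotype` column, one row per individual) or a PLINK `.raw`
#' additive-coded export (whitespace-delimited, columns
#' `FID IID PAT MAT SEX PHENOTYPE` followed by `<snp>_<allele>` dosage
#' columns; phenotypes coded 1/2 are remapped to 0/1). Every file is passed
#' through [validate_snp_data()], so malformed genotypes are rejected with the
#' offending row and column named.
#'
#' @param path Path to the file.
#' @param format `"tabular"` (default) or `"plink_raw"`.
#' @return A validated `snp_data` tibble (individuals x SNPs + phenotype).
#' @seealso [write_snp_data()] for the inverse operation.
#' @export
read_snp_data <- function(path, format = c("tabular", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tabular") {
    raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character")
    return(validate_snp_data(tibble::as_tibble(raw, .name_repair = "minimal")))
  }
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!"PHENOTYPE" %in% names(raw)) {
    stop("PLINK .raw file has no PHENOTYPE column: ", path, call. = FALSE)
  }
  snp_cols <- setdiff(names(raw), meta)
  if (length(snp_cols) < 2L) {
    stop("PLINK .raw file has fewer than 2 SNP columns", call. = FALSE)
  }
  ph <- raw$PHENOTYPE
  if (all(ph %in% c(1, 2))) {
    ph <- ph - 1
  } else if (!all(ph %in% c(0, 1))) {
    stop("PLINK PHENOTYPE must be coded 1/2 or 0/1; found '",
         ph[which(!ph %in% c(0, 1, 2))[1L]], "'", call. = FALSE)
  }
  out <- tibble::as_tibble(raw[snp_cols], .name_repair = "minimal")
  # strip the counted-allele suffix PLINK appends (e.g. rs123_A -> rs123)
  names(out) <- sub("_[^_]*$", "", snp_cols)
  out$phenotype <- ph
  validate_snp_data(out)
}

#' Write a dataset (and optional ground truth) to disk
#'
#' Writes the native tab-separated layout read back by [read_snp_data()];
#' `read_snp_data(write_snp_data(d, path))` is the identity on genotypes,
#' phenotype and SNP ids. When a truth set is supplied, a plain-text sidecar
#' `<path>.truth` is written with one causal SNP id per line.
#'
#' @param data A validated SNP dataset.
#' @param path Output file path.
#' @param truth Optional ground truth: a tibble with a `snp_id` column (as
#'   returned by [simulate_epistasis()]), an integer vector of 1-based SNP
#'   indices, or a character vector of SNP ids. `NULL` writes no sidecar.
#' @return `path`, invisibly.
#' @export
write_snp_data <- function(data, path, truth = NULL) {
  data <- validate_snp_data(data)
  readr::write_tsv(data, path, progress = FALSE)
  if (!is.null(truth) && length(truth)) {
    ids <- truth_ids(truth, data)
    writeLines(ids, paste0(path, ".truth"))
  }
  invisible(path)
}

#' Read a ground-truth sidecar file
#'
#' @param path Path to a `.truth` file (one SNP id per line).
#' @param data Optional dataset used to resolve ids to 1-based column indices.
#' @return A tibble with columns `snp_id` and, when `data` is given, `index`.
#' @export
read_truth <- function(path, data = NULL) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  out <- tibble::tibble(snp_id = ids)
  if (!is.null(data)) {
    out$index <- match(ids, snp_ids(data))
    if (anyNA(out$index)) {
      stop("truth SNP id(s) absent from dataset: ",
           paste(ids[is.na(out$index)], collapse = ", "), call. = FALSE)
    }
    out <- out[c("index", "snp_id")]
  }
  out
}

# Internal: normalise any accepted truth representation to SNP ids.
truth_ids <- function(truth, data) {
  if (is.data.frame(truth)) {
    if ("snp_id" %in% names(truth)) return(as.character(truth$snp_id))
    if ("index" %in% names(truth)) return(snp_ids(data)[truth$index])
    stop("truth data frame needs a 'snp_id' or 'index' column", call. = FALSE)
  }
  if (is.numeric(truth)) return(snp_ids(data)[as.integer(truth)])
  as.character(truth)
}

# Internal: normalise truth to 1-based indices into data's SNP columns.
truth_indices <- function(truth, data) {
  if (is.data.frame(truth) && "index" %in% names(truth)) {
    return(as.integer(truth$index))
  }
  idx <- match(truth_ids(truth, data), snp_ids(data))
  if (anyNA(idx)) stop("truth SNP id(s) not found in dataset", call. = FALSE)
  idx
}
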