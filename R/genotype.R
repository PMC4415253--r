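#' Genotype matrix container
#'
#' Bundles an `n x m` matrix of allele dosages (0, 1 or 2 copies of the
#' counted allele; `NA` for missing) with sample and marker identifiers.
#' Markers are treated as unordered covariates: genomic coordinates, if any,
#' travel only as opaque identifiers.
#'
#' @param dosages Numeric or integer matrix of allele counts, individuals in
#'   rows and markers in columns. Non-missing entries must be 0, 1 or 2.
#' @param sample_ids Character vector of unique individual identifiers
#'   (defaults to the matrix row names, or `ind_1..n`).
#' @param marker_ids Character vector of unique marker identifiers (defaults
#'   to the matrix column names, or `snp_1..m`).
#' @param counted_allele Optional character vector (length `m`) naming the
#'   allele whose copies are counted, as carried in PLINK `.raw` headers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (integer matrix with dimnames), `sample_ids`, `marker_ids`,
#'   `counted_allele`, `n` and `m`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1, 0, 2), nrow = 3))
#' g$n
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, marker_ids = NULL,
                            counted_allele = NULL) {
  dosages <- as.matrix(dosages)
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) {
    stop("non-missing dosages must be 0, 1 or 2; offending entries at rows ",
         paste(utils::head(which(bad, arr.ind = TRUE)[, 1], 3), collapse = ", "))
  }
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages) %||% paste0("ind_", seq_len(n))
  }
  if (is.null(marker_ids)) {
    marker_ids <- colnames(dosages) %||% paste0("snp_", seq_len(m))
  }
  if (length(sample_ids) != n) stop("sample_ids must have length nrow(dosages)")
  if (length(marker_ids) != m) stop("marker_ids must have length ncol(dosages)")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (anyDuplicated(marker_ids)) stop("duplicated marker ids")
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(sample_ids, marker_ids)
  structure(
    list(dosages = dosages, sample_ids = sample_ids, marker_ids = marker_ids,
         counted_allele = counted_allele, n = n, m = m),
    class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", x$n, " individuals x ", x$m, " markers; ",
      sum(is.na(x$dosages)), " missing dosages\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix by individuals
#'
#' @param x A [genotype_matrix()].
#' @param i Row (individual) index vector.
#' @param ... Ignored.
#' @return A `genotype_matrix` restricted to the selected individuals.
#' @export
`[.genotype_matrix` <- function(x, i, ...) {
  genotype_matrix(x$dosages[i, , drop = FALSE],
                  sample_ids = x$sample_ids[i],
                  marker_ids = x$marker_ids,
                  counted_allele = x$counted_allele)
}

#' Allele frequencies from dosages
#'
#' Frequency of the counted allele at each marker: the mean non-missing
#' dosage divided by two. Missing genotypes are excluded marker-wise.
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector of length `m` with values in `[0, 1]`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), ncol = 1))
#' allele_frequencies(g)  # 0.5
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$n < 1) stop("need at least one individual")
  nobs <- g$n - colSums(is.na(g$dosages))
  if (any(nobs == 0)) {
    stop("marker(s) with all dosages missing: ",
         paste(g$marker_ids[nobs == 0], collapse = ", "))
  }
  p <- colSums(g$dosages, na.rm = TRUE) / (2 * nobs)
  names(p) <- g$marker_ids
  p
}

#' Standardize genotypes to unit-variance marker covariates
#'
#' Each retained marker column is centred and scaled as
#' `Z_i = (x_i - 2 p_i) / sqrt(2 p_i (1 - p_i))`, the usual transformation
#' that puts all markers on a common per-allele variance scale so that a
#' genomic relationship matrix `Z Z' / m` has diagonal near one.
#' Monomorphic markers (`p <= 0` or `p >= 1`) carry no information at this
#' scaling and are dropped; their indices are recorded so that downstream
#' effect estimates can treat them as exact zeros.
#'
#' @param g A [genotype_matrix()].
#' @param freqs Allele frequencies to centre and scale by. Defaults to
#'   frequencies estimated from `g` itself; pass the training-set
#'   frequencies when standardizing selection candidates, so predictions
#'   stay on the training scale.
#' @param impute_missing If `TRUE` (default), missing dosages are replaced
#'   by their expectation `2 p_i`, i.e. a zero entry of `Z`.
#' @return An object of class `std_genotypes`: list with `Z` (n x kept
#'   matrix), `freqs`, `scale` (`1/sqrt(2 p q)`), `kept_markers` (integer
#'   indices into the original markers), `marker_ids`, `diag_zz`
#'   (`colSums(Z^2)`), `n`, `m` (number of retained markers).
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2), ncol = 1))
#' standardize_genotypes(g)$Z
#' @export
standardize_genotypes <- function(g, freqs = NULL, impute_missing = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  if (length(freqs) != g$m) stop("freqs must have length m")
  keep <- which(!is.na(freqs) & freqs > 0 & freqs < 1)
  if (length(keep) == 0) stop("all markers are monomorphic")
  p <- freqs[keep]
  sc <- 1 / sqrt(2 * p * (1 - p))
  Z <- g$dosages[, keep, drop = FALSE]
  storage.mode(Z) <- "double"
  if (anyNA(Z)) {
    if (!impute_missing) stop("missing dosages present and impute_missing = FALSE")
    na_idx <- which(is.na(Z), arr.ind = TRUE)
    Z[na_idx] <- 2 * p[na_idx[, 2]]
  }
  Z <- (Z - rep(2 * p, each = g$n)) * rep(sc, each = g$n)
  # compact one-byte dosage copy (3 = missing) for the samplers' fast path:
  # a sweep then streams one byte per genotype instead of a double
  xr <- g$dosages[, keep, drop = FALSE]
  xr[is.na(xr)] <- 3L
  clean <- as.integer(colSums(xr == 3L) == 0L)
  storage.mode(xr) <- "raw"
  structure(
    list(Z = Z, freqs = p, scale = sc, kept_markers = unname(keep),
         marker_ids = g$marker_ids[keep], diag_zz = unname(colSums(Z * Z)),
         dosages_raw = xr, clean_cols = clean,
         n = g$n, m = length(keep), m_input = g$m),
    class = "std_genotypes")
}

#' @export
print.std_genotypes <- function(x, ...) {
  cat("<std_genotypes> ", x$n, " x ", x$m, " (",
      x$m_input - x$m, " monomorphic markers dropped)\n", sep = "")
  invisible(x)
}

#' Read a PLINK 1.9 additive-coding (.raw) file
#'
#' Parses the layout written by `plink --recode A`: a header line
#' `FID IID PAT MAT SEX PHENOTYPE SNP1_A SNP2_C ...` followed by one row per
#' individual with dosages in `{0, 1, 2, NA}`. The allele suffix of each SNP
#' column names the counted allele.
#'
#' @param path Path to the `.raw` file (whitespace separated).
#' @return List with `genotypes` (a [genotype_matrix()], sample ids taken
#'   from the IID column) and `phenotype` (numeric vector, or `NULL` when
#'   the PHENOTYPE column is entirely missing / `-9`).
#' @export
read_plink_raw <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty file: ", path)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) < 6 || !identical(header[1:6], fixed)) {
    stop("malformed .raw header at line 1: expected columns ",
         paste(fixed, collapse = " "))
  }
  snp_cols <- header[-(1:6)]
  marker_ids <- sub("_[^_]*$", "", snp_cols)
  counted <- sub("^.*_", "", snp_cols)
  n <- length(lines) - 1L
  m <- length(snp_cols)
  dos <- matrix(NA_integer_, n, m)
  iid <- character(n)
  phen <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    f <- strsplit(trimws(lines[j + 1]), "[ \t]+")[[1]]
    if (length(f) != 6 + m) {
      stop("line ", j + 1, ": expected ", 6 + m, " fields, found ", length(f))
    }
    iid[j] <- f[2]
    if (!f[6] %in% c("NA", "-9")) phen[j] <- as.numeric(f[6])
    d <- suppressWarnings(as.numeric(f[-(1:6)]))
    d[f[-(1:6)] == "NA"] <- NA
    bad <- which(!is.na(d) & !(d %in% c(0, 1, 2)))
    if (length(bad)) {
      stop("line ", j + 1, ": dosage outside {0,1,2,NA} in column ",
           snp_cols[bad[1]])
    }
    dos[j, ] <- as.integer(d)
  }
  g <- genotype_matrix(dos, sample_ids = iid, marker_ids = marker_ids,
                       counted_allele = counted)
  if (all(is.na(phen))) phen <- NULL else names(phen) <- iid
  list(genotypes = g, phenotype = phen)
}

#' Write a PLINK 1.9 additive-coding (.raw) file
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param phenotype Optional numeric vector aligned with `g$sample_ids`;
#'   missing phenotypes are written as `-9`.
#' @return `path`, invisibly.
#' @export
write_plink_raw <- function(g, path, phenotype = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  allele <- g$counted_allele %||% rep("A", g$m)
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
              paste0(g$marker_ids, "_", allele))
  phen <- if (is.null(phenotype)) rep("-9", g$n) else {
    ifelse(is.na(phenotype), "-9", format(phenotype, digits = 15))
  }
  body <- cbind(g$sample_ids, g$sample_ids, "0", "0", "0", phen,
                ifelse(is.na(g$dosages), "NA", g$dosages))
  writeLines(c(paste(header, collapse = " "),
               apply(body, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Read a plain TSV dosage table
#'
#' First column holds the sample id, remaining columns one marker each, with
#' a header row of marker ids.
#'
#' @param path Path to the tab-separated file.
#' @return A [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("dosage TSV needs a header and at least one row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  m <- length(header) - 1L
  if (m < 1) stop("no marker columns in ", path)
  n <- length(lines) - 1L
  dos <- matrix(NA_integer_, n, m)
  ids <- character(n)
  for (j in seq_len(n)) {
    f <- strsplit(lines[j + 1], "\t", fixed = TRUE)[[1]]
    if (length(f) != m + 1) stop("line ", j + 1, ": ragged row")
    ids[j] <- f[1]
    d <- suppressWarnings(as.numeric(f[-1]))
    d[f[-1] == "NA"] <- NA
    dos[j, ] <- as.integer(d)
  }
  genotype_matrix(dos, sample_ids = ids, marker_ids = header[-1])
}

#' Write a plain TSV dosage table
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  lines <- c(paste(c("sample_id", g$marker_ids), collapse = "\t"),
             vapply(seq_len(g$n), function(j) {
               paste(c(g$sample_ids[j],
                       ifelse(is.na(g$dosages[j, ]), "NA", g$dosages[j, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column phenotype TSV (sample_id, value)
#'
#' @param path Path to the tab-separated file with a header row.
#' @param genotypes Optional [genotype_matrix()]; when supplied, phenotypes
#'   are joined to and ordered by its sample ids (an explicit error if any
#'   genotyped individual lacks a phenotype).
#' @return Named numeric vector.
#' @export
read_phenotype_tsv <- function(path, genotypes = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "numeric"))
  y <- stats::setNames(d[[2]], d[[1]])
  if (!is.null(genotypes)) {
    miss <- setdiff(genotypes$sample_ids, names(y))
    if (length(miss)) {
      stop("no phenotype for sample(s): ", paste(utils::head(miss, 5), collapse = ", "))
    }
    y <- y[genotypes$sample_ids]
  }
  y
}

#' Write a two-column phenotype TSV
#'
#' @param y Named numeric vector of phenotypes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(y, path) {
  utils::write.table(
    data.frame(sample_id = names(y), value = unname(y)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
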