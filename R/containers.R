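# Core data containers: a genotyped gene region and a longitudinal
# phenotype matrix on a shared time grid.

#' Genotyped gene region
#'
#' Holds the additive-coded genotype matrix of one gene region together
#' with SNP positions and per-SNP minor allele frequencies.  Genotypes are
#' coded 0/1/2 (copies of the minor-tagged allele); positions are physical
#' coordinates (base pairs) relative to the region start, on
#' \code{[0, region_length]}.
#'
#' @param G integer matrix, subjects x SNPs, entries in \{0, 1, 2\}.
#' @param positions strictly increasing SNP positions, length
#'   \code{ncol(G)}.
#' @param region_length extent M of the region; defaults to just beyond
#'   the last SNP so every position is interior.
#' @param subject_ids optional subject identifiers (default
#'   \code{rownames(G)} or \code{"s1"..."sn"}).
#' @param snp_ids optional SNP identifiers.
#' @param maf optional per-SNP minor allele frequencies; computed from
#'   \code{G} as \code{min(p, 1-p)} with \code{p = colMeans(G)/2} when
#'   missing.  Simulators pass the drawn (parameter) MAF here.
#' @return an object of class \code{"lfdat_genotypes"}.
#' @export
genotype_region <- function(G, positions, region_length = NULL,
                            subject_ids = NULL, snp_ids = NULL, maf = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (any(is.na(G))) stop("genotype matrix contains missing values")
  if (any(G < 0 | G > 2)) stop("genotypes must lie in [0, 2]")
  L <- ncol(G)
  if (length(positions) != L) stop("positions must have one entry per SNP")
  if (L > 1L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (is.null(region_length)) {
    gap <- if (L > 1L) stats::median(diff(positions)) else 1
    region_length <- positions[L] + gap / 2
  }
  if (positions[1] < 0 || positions[L] > region_length)
    stop("positions must lie within [0, region_length]")
  if (is.null(subject_ids))
    subject_ids <- rownames(G) %||% paste0("s", seq_len(nrow(G)))
  if (is.null(snp_ids))
    snp_ids <- colnames(G) %||% paste0("snp", seq_len(L))
  p <- colMeans(G) / 2
  sample_maf <- pmin(p, 1 - p)
  if (is.null(maf)) maf <- sample_maf
  dimnames(G) <- list(subject_ids, snp_ids)
  structure(list(G = G, positions = as.numeric(positions),
                 region_length = region_length,
                 subject_ids = subject_ids, snp_ids = snp_ids,
                 maf = as.numeric(maf), sample_maf = sample_maf),
            class = "lfdat_genotypes")
}

#' Longitudinal phenotype matrix
#'
#' @param Y numeric matrix, subjects x time points, no missing entries.
#' @param time_grid strictly increasing measurement times, length
#'   \code{ncol(Y)}.
#' @param subject_ids optional subject identifiers.
#' @return an object of class \code{"lfdat_phenotypes"}.
#' @export
longitudinal_phenotype <- function(Y, time_grid, subject_ids = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (any(is.na(Y))) stop("phenotype matrix contains missing values")
  if (length(time_grid) != ncol(Y))
    stop("time_grid must have one entry per phenotype column")
  if (ncol(Y) > 1L && any(diff(time_grid) <= 0))
    stop("time_grid must be strictly increasing")
  if (is.null(subject_ids))
    subject_ids <- rownames(Y) %||% paste0("s", seq_len(nrow(Y)))
  rownames(Y) <- subject_ids
  structure(list(Y = Y, time_grid = as.numeric(time_grid),
                 subject_ids = subject_ids),
            class = "lfdat_phenotypes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_matched <- function(geno, pheno) {
  stopifnot(inherits(geno, "lfdat_genotypes"),
            inherits(pheno, "lfdat_phenotypes"))
  if (nrow(geno$G) != nrow(pheno$Y))
    stop("genotype and phenotype subject counts differ")
  if (!identical(as.character(geno$subject_ids),
                 as.character(pheno$subject_ids)))
    stop("genotype and phenotype subject order differs")
  invisible(TRUE)
}

#' @export
print.lfdat_genotypes <- function(x, ...) {
  cat("Gene region:", nrow(x$G), "subjects,", ncol(x$G),
      "SNPs over [0,", format(x$region_length), "] bp; MAF range",
      format(min(x$maf), digits = 3), "-",
      format(max(x$maf), digits = 3), "\n")
  invisible(x)
}

#' @export
print.lfdat_phenotypes <- function(x, ...) {
  cat("Longitudinal phenotype:", nrow(x$Y), "subjects,",
      ncol(x$Y), "time points (",
      paste(format(range(x$time_grid)), collapse = " - "), ")\n")
  invisible(x)
}
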