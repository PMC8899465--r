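# Readers and writers for the standard interchange formats: VCF and
# CSV/PLINK-raw genotype tables, wide/long phenotype CSVs, scenario YAML,
# and the per-region results TSV.

#' Genomic region specification
#'
#' @param contig chromosome/contig name.
#' @param start,end 1-based inclusive bp coordinates, \code{start <= end}.
#' @param region_id label used in result tables.
#' @return an object of class \code{"lfdat_region_spec"}.
#' @export
region_spec <- function(contig, start, end, region_id = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (start > end) stop("region start must be <= end")
  structure(list(contig = as.character(contig), start = start, end = end,
                 region_id = region_id %||%
                   paste0(contig, ":", start, "-", end)),
            class = "lfdat_region_spec")
}

# "0/1", "0|1" -> dosage; any half-call or missing allele -> NA
.gt_to_dosage <- function(gt) {
  gt <- sub(":.*", "", gt)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  d <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
  d[!(a1 %in% c("0", "1")) | !(a2 %in% c("0", "1"))] <- NA_real_
  d
}

.mean_impute <- function(G) {
  miss <- colSums(is.na(G))
  if (any(colSums(!is.na(G)) == 0L)) stop("SNP with all genotypes missing")
  if (any(miss > 0L)) {
    message("mean-imputing ", sum(miss), " missing genotype call(s) in ",
            sum(miss > 0L), " SNP(s)")
    for (j in which(miss > 0L))
      G[is.na(G[, j]), j] <- mean(G[, j], na.rm = TRUE)
  }
  G
}

.read_positions_file <- function(path, snp_ids) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) == 1L) return(as.numeric(tab[[1L]]))
  pos_col <- intersect(c("pos", "position", "bp"), tolower(names(tab)))
  snp_col <- intersect(c("snp", "id", "snp_id"), tolower(names(tab)))
  if (length(pos_col) == 0L)
    stop("positions file needs a 'pos' column (or a single column)")
  names(tab) <- tolower(names(tab))
  if (length(snp_col) > 0L && !is.null(snp_ids)) {
    idx <- match(snp_ids, as.character(tab[[snp_col[1L]]]))
    if (any(is.na(idx))) stop("positions file is missing some SNP ids")
    return(as.numeric(tab[[pos_col[1L]]][idx]))
  }
  as.numeric(tab[[pos_col[1L]]])
}

#' Read a genotype region from VCF, PLINK-raw, or CSV
#'
#' Produces an additive-coded \code{"lfdat_genotypes"} object.  Only
#' biallelic SNPs are kept (multiallelic records are skipped with a
#' message); missing calls are mean-imputed per SNP; SNPs with sample MAF
#' below \code{maf_min} are removed.
#'
#' @param path input file.
#' @param format \code{"vcf"} (GT field, phased or unphased),
#'   \code{"plink_raw"} (the additive \code{.raw} export: six leading
#'   columns then one dosage column per SNP), or \code{"csv"} (first
#'   column subject id, one column per SNP).
#' @param positions_file sidecar CSV giving SNP base-pair positions
#'   (columns \code{snp,pos}, or a single \code{pos} column in SNP
#'   order); required for \code{plink_raw} and \code{csv}.
#' @param region optional \code{\link{region_spec}}; VCF records outside
#'   it are dropped and positions become relative to \code{start}.
#' @param maf_min minimum sample minor allele frequency (SNPs below it
#'   are deleted; 0 disables).
#' @return an \code{"lfdat_genotypes"} object.
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_raw", "csv"),
                           positions_file = NULL, region = NULL,
                           maf_min = 0) {
  format <- match.arg(format)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    pos <- as.numeric(fix$POS)
    keep <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1L &
      nchar(fix$ALT) == 1L
    if (!is.null(region)) {
      stopifnot(inherits(region, "lfdat_region_spec"))
      keep <- keep & fix$CHROM == region$contig &
        pos >= region$start & pos <= region$end
    }
    if (sum(keep) == 0L) stop("no biallelic SNPs in the requested region")
    if (any(!keep & (grepl(",", fix$ALT) | nchar(fix$REF) > 1L |
                       nchar(fix$ALT) > 1L)))
      message("skipping ", sum(grepl(",", fix$ALT)), " multiallelic and ",
              sum(nchar(fix$REF) > 1L | nchar(fix$ALT) > 1L),
              " non-SNP record(s)")
    gt <- vcfR::extract.gt(vcf, element = "GT")
    G <- apply(gt[keep, , drop = FALSE], c(1L, 2L), .gt_to_dosage)
    G <- t(G)
    pos <- pos[keep]
    offset <- if (!is.null(region)) region$start else 0
    region_length <- if (!is.null(region)) region$end - region$start + 1 else NULL
    snp_ids <- fix$ID[keep]
    snp_ids[is.na(snp_ids) | snp_ids == "."] <-
      paste0(fix$CHROM[keep], "_", pos)[is.na(snp_ids) | snp_ids == "."]
    o <- order(pos)
    G <- G[, o, drop = FALSE]; pos <- pos[o]; snp_ids <- snp_ids[o]
    G <- .mean_impute(G)
    colnames(G) <- snp_ids
    geno <- genotype_region(G, pos - offset, region_length = region_length)
  } else if (format == "plink_raw") {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE)
    meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                      names(tab))
    G <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
    storage.mode(G) <- "double"
    rownames(G) <- if ("IID" %in% meta) as.character(tab$IID) else NULL
    colnames(G) <- sub("_[ACGT]$", "", colnames(G))  # strip allele suffix
    if (is.null(positions_file))
      stop("positions_file is required for plink_raw input")
    pos <- .read_positions_file(positions_file, colnames(G))
    o <- order(pos)
    geno <- genotype_region(.mean_impute(G[, o, drop = FALSE]), pos[o])
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    G <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(G) <- "double"
    rownames(G) <- as.character(tab[[1L]])
    if (is.null(positions_file))
      stop("positions_file is required for csv input")
    pos <- .read_positions_file(positions_file, colnames(G))
    o <- order(pos)
    geno <- genotype_region(.mean_impute(G[, o, drop = FALSE]), pos[o])
  }
  if (maf_min > 0) {
    drop <- geno$sample_maf < maf_min
    if (any(drop)) {
      message("removing ", sum(drop), " SNP(s) with MAF < ", maf_min)
      if (all(drop)) stop("every SNP fails the MAF filter")
      geno <- genotype_region(geno$G[, !drop, drop = FALSE],
                              geno$positions[!drop],
                              region_length = geno$region_length,
                              subject_ids = geno$subject_ids,
                              snp_ids = geno$snp_ids[!drop])
    }
  }
  geno
}

#' Read a longitudinal phenotype table
#'
#' Wide layout: first column subject id, remaining columns one per time
#' point (times parsed from the column names, e.g. \code{t1..t9} or bare
#' numbers).  Long layout: columns \code{subject}, \code{time},
#' \code{value}.  Subjects missing any time point are dropped with a
#' message; duplicate (subject, time) records are an error.
#'
#' @param path CSV file.
#' @param layout \code{"wide"} or \code{"long"}.
#' @return an \code{"lfdat_phenotypes"} object.
#' @export
read_phenotypes <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (layout == "long") {
    if (ncol(tab) < 3L) stop("long layout needs subject, time, value columns")
    names(tab)[1:3] <- c("subject", "time", "value")
    if (anyDuplicated(tab[, c("subject", "time")]))
      stop("duplicate (subject, time) rows")
    times <- sort(unique(tab$time))
    wide <- stats::reshape(tab[, 1:3], idvar = "subject",
                           timevar = "time", direction = "wide")
    Y <- as.matrix(wide[, paste0("value.", times), drop = FALSE])
    rownames(Y) <- as.character(wide$subject)
  } else {
    times <- suppressWarnings(as.numeric(gsub("[^0-9.eE+-]", "",
                                              names(tab)[-1L])))
    if (any(is.na(times)))
      stop("cannot parse time values from the wide header")
    Y <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(Y) <- as.character(tab[[1L]])
    o <- order(times)
    Y <- Y[, o, drop = FALSE]; times <- times[o]
  }
  complete <- rowSums(is.na(Y)) == 0L
  if (!any(complete)) stop("no subject has a complete set of time points")
  if (any(!complete))
    message("dropping ", sum(!complete),
            " subject(s) with missing time points")
  longitudinal_phenotype(Y[complete, , drop = FALSE], times)
}

#' Write a genotype region as a minimal VCF
#'
#' @param geno an \code{"lfdat_genotypes"} object.
#' @param path output file (plain text).
#' @param contig contig name for the records.
#' @return invisibly, \code{path}.
#' @export
write_genotypes_vcf <- function(geno, path, contig = "1") {
  stopifnot(inherits(geno, "lfdat_genotypes"))
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", contig, ">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", geno$subject_ids),
                     collapse = "\t")), con)
  Gint <- round(geno$G)
  for (l in seq_along(geno$positions)) {
    writeLines(paste(c(contig, round(geno$positions[l]), geno$snp_ids[l],
                       "A", "C", ".", "PASS", ".", "GT",
                       gt_codes[Gint[, l] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a longitudinal phenotype table as CSV
#'
#' @param pheno an \code{"lfdat_phenotypes"} object.
#' @param path output file.
#' @param layout \code{"wide"} or \code{"long"}.
#' @return invisibly, \code{path}.
#' @export
write_phenotypes_csv <- function(pheno, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(pheno, "lfdat_phenotypes"))
  if (layout == "wide") {
    tab <- data.frame(subject = pheno$subject_ids,
                      pheno$Y, check.names = FALSE)
    names(tab)[-1L] <- paste0("t", format(pheno$time_grid, trim = TRUE))
  } else {
    tab <- data.frame(
      subject = rep(pheno$subject_ids, times = ncol(pheno$Y)),
      time = rep(pheno$time_grid, each = nrow(pheno$Y)),
      value = as.vector(pheno$Y))
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a genotype region as CSV plus a positions sidecar
#'
#' @param geno an \code{"lfdat_genotypes"} object.
#' @param path genotype CSV (subject id column then one column per SNP).
#' @param positions_path sidecar CSV with columns \code{snp,pos}.
#' @return invisibly, \code{path}.
#' @export
write_genotypes_csv <- function(geno, path, positions_path) {
  stopifnot(inherits(geno, "lfdat_genotypes"))
  tab <- data.frame(subject = geno$subject_ids, geno$G,
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(snp = geno$snp_ids, pos = geno$positions),
                   positions_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-region test results as TSV
#'
#' One row per region: \code{region_id}, \code{n_snps}, then one p-value
#' column per time point.
#'
#' @param results named list of \code{"lfdat_test"} objects (names =
#'   region ids).
#' @param n_snps integer vector, SNP count per region.
#' @param path output file.
#' @return invisibly, the written data.frame.
#' @export
write_results_tsv <- function(results, n_snps, path) {
  stopifnot(length(results) >= 1L, length(n_snps) == length(results))
  tg <- results[[1L]]$time_grid
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    out <- data.frame(region_id = names(results)[i] %||% i,
                      n_snps = n_snps[i])
    p <- as.data.frame(t(r$p_by_time))
    names(p) <- paste0("p_t", format(tg, trim = TRUE))
    cbind(out, p)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(tab)
}

#' Build a scenario from a YAML configuration file
#'
#' The YAML fields mirror the arguments of \code{\link{scenario_config}};
#' \code{ld} may be a two-element list \code{[lo, hi]}.
#'
#' @param path YAML file.
#' @return an \code{"lfdat_scenario"}.
#' @export
read_scenario_yaml <- function(path) {
  # keep bare "n"/"y"/"yes"/"no" scalars (notably the key "n") as strings
  # instead of YAML 1.1 booleans
  keep <- function(x) x
  cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                               "bool#no" = keep))
  allowed <- names(formals(scenario_config))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0L)
    stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$ld)) cfg$ld <- as.numeric(unlist(cfg$ld))
  if (!is.null(cfg$time_grid)) cfg$time_grid <- as.numeric(unlist(cfg$time_grid))
  do.call(scenario_config, cfg)
}
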