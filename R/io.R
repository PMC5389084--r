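#' Read a genotype table from delimited text or VCF
#'
#' TSV dialect: tab-delimited, UTF-8, header row; first column `sample_id`, an
#' optional `phenotype` column, remaining columns one feature each (codes
#' 0/1/2 or real-valued covariates). VCF: biallelic sites are converted to
#' alternate-allele dosage 0/1/2 from the GT field; multi-allelic sites are
#' skipped (count logged); feature coordinates are captured from CHROM/POS
#' (1-based). Missing genotypes are mean-imputed per feature (count logged);
#' features missing in every sample are dropped with a warning.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"vcf"`.
#' @param phenotype optional numeric vector, or path to a single-column file
#'   (header optional), supplying the phenotype when the table has none.
#' @return A [GenoPheno-class].
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf"), phenotype = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gp <- switch(format, tsv = readGenotypesTsv(path), vcf = readGenotypesVcf(path))
  if (!is.null(phenotype)) {
    if (is.character(phenotype) && length(phenotype) == 1) {
      ph <- utils::read.table(phenotype, header = FALSE, sep = "\t",
                              stringsAsFactors = FALSE)[[1]]
      if (is.character(ph) && suppressWarnings(is.na(as.numeric(ph[1]))))
        ph <- ph[-1]  # a header line
      phenotype <- as.numeric(ph)
    }
    if (length(phenotype) != nSamples(gp))
      stop("phenotype length must equal the sample count")
    gp$phenotype <- as.numeric(phenotype)
    methods::validObject(gp)
  }
  gp
}

readGenotypesTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = c("NA", "."))
  if (!ncol(tab) >= 2) stop("TSV must have a sample_id column plus features")
  idCol <- 1L
  sampleIds <- as.character(tab[[idCol]])
  phenotype <- NULL
  featCols <- setdiff(seq_len(ncol(tab)), idCol)
  if ("phenotype" %in% names(tab)) {
    phenotype <- as.numeric(tab[["phenotype"]])
    featCols <- setdiff(featCols, which(names(tab) == "phenotype"))
  }
  for (j in featCols) {
    v <- tab[[j]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     v[bad[1]], bad[1], names(tab)[j]))
      tab[[j]] <- num
    }
  }
  m <- as.matrix(tab[, featCols, drop = FALSE])
  rownames(m) <- sampleIds
  m <- imputeMissing(m)
  GenoPheno(m, phenotype = phenotype, sampleIds = sampleIds)
}

# Per-feature mean imputation; all-missing features are dropped with a warning.
imputeMissing <- function(m) {
  nMiss <- colSums(is.na(m))
  allMiss <- nMiss == nrow(m)
  if (any(allMiss)) {
    warning(sum(allMiss), " feature(s) missing in every sample were dropped")
    m <- m[, !allMiss, drop = FALSE]
    nMiss <- nMiss[!allMiss]
  }
  if (any(nMiss > 0)) {
    logMsg(sprintf("mean-imputed %d missing genotype call(s) across %d feature(s)",
                   sum(nMiss), sum(nMiss > 0)))
    for (j in which(nMiss > 0)) {
      mu <- mean(m[, j], na.rm = TRUE)
      m[is.na(m[, j]), j] <- mu
    }
  }
  m
}

readGenotypesVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    logMsg(sprintf("skipped %d multi-allelic site(s)", sum(multi)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(rownames(v@fix), colnames(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (!nrow(gt)) stop("no biallelic sites in VCF")
  dosage <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
  })
  ids <- fix[, "ID"]
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix[noId, "CHROM"], ":", fix[noId, "POS"])
  m <- t(dosage)  # samples x features
  colnames(m) <- ids
  m <- imputeMissing(m)
  coords <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
  coords <- coords[match(colnames(m), ids), , drop = FALSE]
  GenoPheno(m, coords = coords)
}

#' Write a GenoPheno to the TSV genotype dialect
#'
#' Round-trips exactly through [readGenotypes()]: `sample_id`, an optional
#' `phenotype` column, then one column per feature.
#'
#' @param gp a [GenoPheno-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(gp, path) {
  m <- featureMatrix(gp)
  df <- data.frame(sample_id = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  ph <- phenotype(gp)
  if (!is.null(ph)) df$phenotype <- ph
  feat <- as.data.frame(m, check.names = FALSE)
  # 17 significant digits round-trip doubles exactly through text
  feat[] <- lapply(feat, function(v) sprintf("%.17g", v))
  if (!is.null(ph)) df$phenotype <- sprintf("%.17g", ph)
  df <- cbind(df, feat)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Timestamped log line on stderr.
logMsg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}
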