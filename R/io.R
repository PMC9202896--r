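#' Read a delimited dosage matrix
#'
#' Expects samples in rows and SNPs in columns, with a header row of SNP
#' identifiers; whitespace- or comma-delimited. Values must be 0, 1 or 2.
#' MAFs are estimated from the data as half the mean dosage (folded to
#' (0, 0.5]).
#'
#' @param path file path.
#' @param sep field separator; \code{""} (any whitespace, default) or
#'   \code{","}.
#' @return a [SnpGenotypes-class].
#' @export
readDosage <- function(path, sep = "") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  d <- as.matrix(df)
  storage.mode(d) <- "integer"
  .genotypesFromMatrix(d, colnames(d))
}

#' Write a dosage matrix in the delimited format read by [readDosage()]
#'
#' @param g a [SnpGenotypes-class].
#' @param path file path.
#' @param sep field separator (default tab).
#' @export
writeDosage <- function(g, path, sep = "\t") {
  stopifnot(is(g, "SnpGenotypes"))
  d <- g@dosages
  colnames(d) <- g@snpIds
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a PLINK .raw additive-dosage export
#'
#' Skips the six leading bookkeeping columns (FID, IID, PAT, MAT, SEX,
#' PHENOTYPE) and keeps the per-SNP allele counts.
#'
#' @param path file path to a PLINK \code{--recode A} output.
#' @return a [SnpGenotypes-class] with IID as sample identifiers.
#' @export
readPlinkRaw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  keep <- setdiff(colnames(df), meta)
  if (!length(keep)) stop("no SNP columns found in ", path)
  d <- as.matrix(df[, keep, drop = FALSE])
  storage.mode(d) <- "integer"
  g <- .genotypesFromMatrix(d, keep)
  if ("IID" %in% colnames(df)) g@sampleIds <- as.character(df$IID)
  validObject(g)
  g
}

#' Load a genotype panel with cluster labels from an RData file
#'
#' Loads an \code{.RData} workspace and extracts a dosage matrix plus an
#' optional vector of SNP cluster labels, matched by name or, failing
#' that, by shape (the first matrix-like object is taken as genotypes,
#' the first integer vector of matching length as cluster labels).
#'
#' @param path path to the RData file.
#' @param genotypesName,clustersName optional object names to use.
#' @return a [SnpGenotypes-class].
#' @export
readSnpRData <- function(path, genotypesName = NULL, clustersName = NULL) {
  env <- new.env(parent = emptyenv())
  load(path, envir = env)
  objs <- ls(env)
  pick <- function(nm, pred) {
    if (!is.null(nm)) return(get(nm, envir = env))
    for (o in objs) {
      v <- get(o, envir = env)
      if (pred(v)) return(v)
    }
    NULL
  }
  d <- pick(genotypesName, function(v) is.matrix(v) || is.data.frame(v))
  if (is.null(d)) stop("no genotype matrix found in ", path)
  d <- as.matrix(d)
  storage.mode(d) <- "integer"
  cl <- pick(clustersName,
             function(v) is.atomic(v) && !is.matrix(v) && length(v) == ncol(d))
  g <- .genotypesFromMatrix(d, colnames(d))
  if (!is.null(cl)) g@clusterId <- as.integer(as.factor(cl))
  validObject(g)
  g
}

#' Write SNP cluster labels as a two-column TSV
#'
#' @param snpIds character SNP identifiers.
#' @param clusterId integer cluster labels, parallel to \code{snpIds}.
#' @param path file path.
#' @export
writeClusterLabels <- function(snpIds, clusterId, path) {
  utils::write.table(
    data.frame(snp_id = snpIds, cluster_id = clusterId),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a SelectionResult as a tidy TSV
#'
#' One row per selected column: SNP identifier, role, fitted coefficient.
#'
#' @param sel a [SelectionResult-class].
#' @param snpIds character identifiers of all p SNPs.
#' @param path file path.
#' @export
writeSelection <- function(sel, snpIds, path) {
  stopifnot(is(sel, "SelectionResult"))
  df <- rbind(
    if (length(sel@iBeta))
      data.frame(snp_id = snpIds[sel@iBeta], role = "prognostic",
                 coefficient = sel@beta),
    if (length(sel@iGamma))
      data.frame(snp_id = snpIds[sel@iGamma], role = "predictive",
                 coefficient = sel@gamma))
  if (is.null(df))
    df <- data.frame(snp_id = character(), role = character(),
                     coefficient = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.genotypesFromMatrix <- function(d, ids = NULL) {
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(d)))
  maf <- colMeans(d) / 2
  maf <- pmin(pmax(maf, 1e-6), 1 - 1e-6)
  maf <- ifelse(maf > 0.5, 1 - maf, maf)
  dimnames(d) <- NULL
  new("SnpGenotypes",
      dosages = d, mafs = maf, clusterId = NULL,
      sampleIds = paste0("sample", seq_len(nrow(d))),
      snpIds = as.character(ids))
}
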