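#' Validate an OTU count table
#'
#' An OTU table is a plain base matrix of non-negative integer counts with
#' samples as rows and OTUs as columns, carrying unique sample ids as
#' `rownames` and unique OTU ids as `colnames`. All downstream functions in
#' the package take this orientation.
#'
#' @param counts Matrix to validate.
#' @return The validated matrix, invisibly.
#' @export
validate_otu_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("OTU table must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table must carry sample ids (rownames) and OTU ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("OTU table contains missing values")
  if (any(counts < 0)) stop("OTU table contains negative counts")
  if (any(counts != round(counts))) stop("OTU table contains non-integer counts")
  invisible(counts)
}

#' Read an OTU count table from TSV
#'
#' Reads a tab-separated table with one header row of column ids and a
#' leading column of row ids, and returns it oriented samples x OTUs.
#'
#' @param path Path to a TSV file.
#' @param orientation Orientation of the file on disk: `"samples_by_otus"`
#'   (rows are samples) or `"otus_by_samples"` (rows are OTUs; the result is
#'   transposed).
#' @return A validated integer matrix, samples x OTUs.
#' @export
read_otu_table <- function(path, orientation = c("samples_by_otus", "otus_by_samples")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric cells in column(s): ", paste(names(df)[bad], collapse = ", "))
  m <- as.matrix(df)
  if (orientation == "otus_by_samples") m <- t(m)
  storage.mode(m) <- "double"
  validate_otu_table(m)
  m
}

#' Write an OTU count table to TSV
#'
#' @param counts OTU table (samples x OTUs).
#' @param path Output path.
#' @param orientation Orientation to write; see [read_otu_table()].
#' @export
write_otu_table <- function(counts, path,
                            orientation = c("samples_by_otus", "otus_by_samples")) {
  orientation <- match.arg(orientation)
  validate_otu_table(counts)
  m <- if (orientation == "otus_by_samples") t(counts) else counts
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (orientation == "otus_by_samples") "otu_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample without replacement to a fixed number of reads.
#' Samples whose total falls below `depth` are dropped with a warning; the
#' dropped ids are attached as attribute `"dropped_samples"`. The default
#' depth mirrors the 18,400-read convention for amplicon libraries of the
#' study design this package targets; any positive depth is accepted and the
#' synthetic fixtures use much smaller ones.
#'
#' @param counts OTU table (samples x OTUs).
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer seed; subsampling is reproducible for a fixed seed.
#' @return Rarefied OTU table whose surviving rows each sum to `depth`.
#' @export
rarefy_counts <- function(counts, depth = 18400, seed = 1) {
  validate_otu_table(counts)
  if (length(depth) != 1 || is.na(depth) || depth < 1)
    stop("depth must be a positive integer")
  depth <- as.integer(depth)
  tot <- rowSums(counts)
  keep <- tot >= depth
  dropped <- rownames(counts)[!keep]
  if (length(dropped))
    warning("dropped ", length(dropped), " sample(s) below depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  if (!any(keep)) stop("all samples fall below the rarefaction depth")
  sub <- counts[keep, , drop = FALSE]
  set.seed(seed)
  out <- sub
  exact <- rowSums(sub) == depth
  if (any(!exact)) {
    # rrarefy's "smallest count > 1" heuristic misfires on dense synthetic
    # tables; counts are validated as integers above
    out[!exact, ] <- withCallingHandlers(
      vegan::rrarefy(sub[!exact, , drop = FALSE], depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  storage.mode(out) <- "double"
  attr(out, "dropped_samples") <- dropped
  out
}

#' Convert counts to relative abundances
#'
#' @param counts OTU table (samples x OTUs) with strictly positive row sums.
#' @return Matrix of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  tot <- rowSums(counts)
  zero <- tot <= 0
  if (any(zero))
    stop("zero-sum sample(s): ", paste(rownames(counts)[zero], collapse = ", "))
  sweep(counts, 1, tot, "/")
}
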