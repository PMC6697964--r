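#' FPKM from raw counts
#'
#' `FPKM = 1e9 * C / (N * L)` with `C` reads mapped to the transcript, `N`
#' total mappable reads in the library and `L` the transcript length in bp.
#'
#' @param C mapped-read count(s), nonnegative.
#' @param N library size (total mappable reads), positive.
#' @param L transcript length(s) in bp, positive.
#' @return Numeric FPKM value(s).
#' @export
fpkm <- function(C, N, L) {
  if (any(N <= 0)) stop("library size N must be positive")
  if (any(L <= 0)) stop("transcript length L must be positive")
  if (any(C < 0)) stop("counts must be nonnegative")
  1e9 * C / (as.numeric(N) * as.numeric(L))
}

#' Log2 fold change between conditions
#'
#' `FC = log2(treated / control)`. When both FPKMs are zero the gene is
#' unchanged (FC 0); when only the control is zero the ratio is undefined and
#' `NA` is returned (flagged `UNDEFINED` downstream) unless a positive
#' `pseudocount` is supplied.
#'
#' @param fpkmTreated,fpkmControl nonnegative FPKM values (vectorised).
#' @param pseudocount optional value added to both FPKMs before the ratio
#'   (default 0, i.e. pure ratio with NA guard).
#' @return Numeric log2 fold changes (NA where undefined).
#' @export
foldChange <- function(fpkmTreated, fpkmControl, pseudocount = 0) {
  if (any(fpkmTreated < 0) || any(fpkmControl < 0))
    stop("FPKM values must be nonnegative")
  tr <- fpkmTreated + pseudocount
  ct <- fpkmControl + pseudocount
  fc <- ifelse(tr == 0 & ct == 0, 0,
               ifelse(ct == 0, NA_real_,
                      ifelse(tr == 0, -Inf, log2(tr / ct))))
  fc
}

#' Assemble a two-condition count table
#'
#' @param counts integer matrix, transcripts x `c("control", "treated")`.
#' @param lengths transcript lengths in bp (same order as rows).
#' @param libSizes numeric `c(control=, treated=)`; defaults to column sums.
#' @return A `SummarizedExperiment` as produced by [simulateCounts()].
#' @export
countTable <- function(counts, lengths,
                       libSizes = c(control = sum(counts[, "control"]),
                                    treated = sum(counts[, "treated"]))) {
  stopifnot(all(c("control", "treated") %in% colnames(counts)),
            length(lengths) == nrow(counts), all(lengths > 0),
            all(counts >= 0))
  if (any(libSizes < colSums(counts[, c("control", "treated")])))
    stop("library sizes must be >= the summed counts per condition")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts[, c("control", "treated")]),
    rowData = S4Vectors::DataFrame(length = unname(lengths),
                                   row.names = rownames(counts)),
    metadata = list(libSizes = libSizes))
}

#' Classify differentially expressed genes by fold-change sign
#'
#' Computes per-transcript FPKM for both conditions and the log2 fold change
#' treated/control; transcripts with FC greater than zero are classified
#' up-regulated and those with FC less than zero down-regulated (an optional
#' absolute-FC threshold can tighten the rule). Ratio-undefined transcripts
#' (control FPKM 0, treated > 0) are flagged `UNDEFINED`.
#'
#' @param se `SummarizedExperiment` from [countTable()] or
#'   [simulateCounts()].
#' @param fcThreshold minimum |FC| to call a gene up/down (default 0).
#' @param pseudocount passed to [foldChange()].
#' @return A list: `records` (data.frame `transcriptId`, `fpkmControl`,
#'   `fpkmTreated`, `fc`, `status`) in input row order and `summary`
#'   (`nUp`, `nDown`, `nUnchanged`, `nUndefined`).
#' @export
classifyDegs <- function(se, fcThreshold = 0, pseudocount = 0) {
  counts <- SummarizedExperiment::assay(se, "counts")
  if (!all(c("control", "treated") %in% colnames(counts)))
    stop("count table must have control and treated conditions")
  lens <- SummarizedExperiment::rowData(se)$length
  libSizes <- S4Vectors::metadata(se)$libSizes
  fpkmC <- fpkm(counts[, "control"], libSizes[["control"]], lens)
  fpkmT <- fpkm(counts[, "treated"], libSizes[["treated"]], lens)
  fc <- foldChange(fpkmT, fpkmC, pseudocount)
  status <- ifelse(is.na(fc), "UNDEFINED",
                   ifelse(fc > fcThreshold, "UP",
                          ifelse(fc < -fcThreshold | fc == -Inf, "DOWN",
                                 "UNCHANGED")))
  records <- data.frame(
    transcriptId = rownames(counts), fpkmControl = fpkmC, fpkmTreated = fpkmT,
    fc = fc, status = status, row.names = NULL)
  list(records = records,
       summary = list(nUp = sum(status == "UP"),
                      nDown = sum(status == "DOWN"),
                      nUnchanged = sum(status == "UNCHANGED"),
                      nUndefined = sum(status == "UNDEFINED")))
}

#' Write a DEG classification table
#'
#' @param degs result of [classifyDegs()].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
writeDegTable <- function(degs, path) {
  rec <- degs$records
  rec$fpkmControl <- round(rec$fpkmControl, 3)
  rec$fpkmTreated <- round(rec$fpkmTreated, 3)
  rec$fc <- round(rec$fc, 3)
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
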