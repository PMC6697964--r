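#' Read single-nucleotide variant records from a VCF file
#'
#' Parses a VCF v4.x file into a flat record table. Only biallelic
#' single-base substitutions are kept: for multi-allelic lines the first ALT
#' allele is taken and the remainder skipped, indels and multi-nucleotide
#' variants are skipped, each with a reason code in the `skipped` tally.
#' Zygosity is read from the first sample's GT field when present
#' (heterozygous iff the two alleles differ), defaulting to HOM.
#'
#' @param path VCF file path.
#' @return A list: `records` (data.frame `transcriptId`, `pos`, `refBase`,
#'   `altBase`, `depth`, `mapQuality`, `zygosity`) and `skipped` (named
#'   integer tally of skip reasons).
#' @export
readVariants <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  skipped <- c(`multiallelic-extra-alt` = 0L, indel = 0L, mnp = 0L)
  if (nrow(fix) == 0L) {
    return(list(records = data.frame(
      transcriptId = character(0), pos = integer(0), refBase = character(0),
      altBase = character(0), depth = numeric(0), mapQuality = numeric(0),
      zygosity = character(0)), skipped = skipped))
  }
  alt <- fix$ALT
  multi <- grepl(",", alt, fixed = TRUE)
  skipped["multiallelic-extra-alt"] <- sum(multi)
  alt[multi] <- vapply(strsplit(alt[multi], ",", fixed = TRUE), `[`,
                       character(1), 1L)
  ref <- fix$REF
  isSnv <- nchar(ref) == 1L & nchar(alt) == 1L & ref %in% BASES &
    alt %in% BASES
  indel <- nchar(ref) != nchar(alt)
  skipped["indel"] <- sum(indel)
  skipped["mnp"] <- sum(!isSnv & !indel)
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "DP")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "MQ")))
  zyg <- rep("HOM", nrow(fix))
  gtMat <- tryCatch(vcfR::extract.gt(vcf, "GT"), error = function(e) NULL)
  if (!is.null(gtMat) && ncol(gtMat) >= 1L) {
    g <- gtMat[, 1L]
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    zyg <- vapply(a, function(x) {
      if (length(x) == 2L && x[1] != x[2]) "HET" else "HOM"
    }, character(1))
  }
  records <- data.frame(
    transcriptId = fix$CHROM, pos = as.integer(fix$POS), refBase = ref,
    altBase = alt, depth = dp, mapQuality = mq, zygosity = zyg,
    row.names = NULL)[isSnv, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, skipped = skipped)
}

#' Depth and mapping-quality filter thresholds
#'
#' Defaults follow the variant-filtering settings minimum read depth 20,
#' maximum read depth 200 and minimum mapping quality 10, all bounds
#' inclusive.
#'
#' @param minDepth,maxDepth,minMapQ filter thresholds.
#' @return A validated list of class `FilterThresholds`.
#' @export
filterThresholds <- function(minDepth = 20L, maxDepth = 200L, minMapQ = 10) {
  if (minDepth > maxDepth) stop("minDepth must be <= maxDepth")
  structure(list(minDepth = minDepth, maxDepth = maxDepth, minMapQ = minMapQ),
            class = "FilterThresholds")
}

#' Filter variant records on depth and mapping quality
#'
#' A record is retained iff `minDepth <= depth <= maxDepth` and
#' `mapQuality >= minMapQ` (all boundaries inclusive). Records with a missing
#' depth or quality field are rejected with reason `"missing-field"`.
#'
#' @param records record data.frame (see [readVariants()]).
#' @param thresholds a [filterThresholds()] object.
#' @return A list: `retained` (record subset) and `rejected` (records with a
#'   `reason` column: `low-depth`, `high-depth`, `low-mapq`,
#'   `missing-field`).
#' @export
filterVariants <- function(records, thresholds = filterThresholds()) {
  reason <- rep(NA_character_, nrow(records))
  missing <- is.na(records$depth) | is.na(records$mapQuality)
  reason[missing] <- "missing-field"
  reason[!missing & records$depth < thresholds$minDepth] <- "low-depth"
  reason[!missing & records$depth > thresholds$maxDepth] <- "high-depth"
  reason[is.na(reason) & records$mapQuality < thresholds$minMapQ] <-
    "low-mapq"
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(retained = records[keep, , drop = FALSE], rejected = rejected)
}

#' Transition/transversion classification of a substitution
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G, C<->T); all other base exchanges are transversions.
#'
#' @param refBase,altBase single distinct bases (vectorised).
#' @return A data.frame with `type` (`"TRANSITION"`/`"TRANSVERSION"`) and
#'   `label` (`"ref/alt"`).
#' @export
substitutionType <- function(refBase, altBase) {
  refBase <- toupper(refBase); altBase <- toupper(altBase)
  if (any(!refBase %in% BASES) || any(!altBase %in% BASES))
    stop("bases must be A/C/G/T")
  if (any(refBase == altBase)) stop("ref and alt bases must differ")
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  data.frame(
    type = ifelse(partner[refBase] == altBase, "TRANSITION", "TRANSVERSION"),
    label = paste0(refBase, "/", altBase), row.names = NULL)
}

#' High-resolution-melting SNP class of a substitution
#'
#' Class I: C/T and G/A transitions; class II: C/A and G/T transversions;
#' class III: C/G; class IV: A/T. The class depends only on the unordered
#' base pair.
#'
#' @param refBase,altBase single distinct bases (vectorised).
#' @return Character vector of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
hrmClass <- function(refBase, altBase) {
  refBase <- toupper(refBase); altBase <- toupper(altBase)
  if (any(!refBase %in% BASES) || any(!altBase %in% BASES))
    stop("bases must be A/C/G/T")
  if (any(refBase == altBase)) stop("ref and alt bases must differ")
  key <- paste(pmin(refBase, altBase), pmax(refBase, altBase))
  unname(c(`C T` = "I", `A G` = "I", `A C` = "II", `G T` = "II",
           `C G` = "III", `A T` = "IV")[key])
}

#' Substitution spectrum of a filtered variant set
#'
#' Tallies the 12 directional substitution types, transition/transversion
#' counts and their ratio, zygosity counts, HRM class counts, and the
#' ORF-relative positional distribution of the variants.
#'
#' @param records filtered record data.frame.
#' @param orfs optional `GRanges` from [annotateOrfs()]; variants on
#'   transcripts without an ORF annotation are `UNCLASSIFIED`.
#' @return A `SubstitutionSpectrum` list: `total`, `directional` (named
#'   counts), `tsCount`, `tvCount`, `tsTvRatio` (NA when no transversions),
#'   `homCount`, `hetCount`, `hrmClassCounts`, `regionCounts`, and `shares`
#'   (percentages rounded to one decimal).
#' @export
snpSpectrum <- function(records, orfs = NULL) {
  n <- nrow(records)
  labels <- as.vector(outer(BASES, BASES, paste, sep = "/"))
  labels <- labels[vapply(strsplit(labels, "/"), function(x) x[1] != x[2],
                          logical(1))]
  if (n == 0L) {
    return(structure(list(
      total = 0L, directional = setNames(integer(12), labels),
      tsCount = 0L, tvCount = 0L, tsTvRatio = NA_real_,
      homCount = 0L, hetCount = 0L,
      hrmClassCounts = setNames(integer(4), c("I", "II", "III", "IV")),
      regionCounts = integer(0), shares = list()),
      class = "SubstitutionSpectrum"))
  }
  st <- substitutionType(records$refBase, records$altBase)
  directional <- table(factor(st$label, levels = labels))
  tsCount <- sum(st$type == "TRANSITION")
  tvCount <- n - tsCount
  cls <- table(factor(hrmClass(records$refBase, records$altBase),
                      levels = c("I", "II", "III", "IV")))
  region <- if (is.null(orfs)) {
    rep("UNCLASSIFIED", n)
  } else {
    gr <- GenomicRanges::GRanges(records$transcriptId,
                                 IRanges::IRanges(records$pos, records$pos))
    S4Vectors::mcols(classifyFeatureRegions(gr, orfs))$region
  }
  regionCounts <- table(factor(region, levels = c("FIVE_UTR", "CDS",
                                                  "THREE_UTR",
                                                  "UNCLASSIFIED")))
  pct <- function(x) round(100 * as.numeric(x) / n, 1)
  structure(list(
    total = n,
    directional = setNames(as.integer(directional), labels),
    tsCount = tsCount, tvCount = tvCount,
    tsTvRatio = if (tvCount == 0L) NA_real_ else tsCount / tvCount,
    homCount = sum(records$zygosity == "HOM"),
    hetCount = sum(records$zygosity == "HET"),
    hrmClassCounts = setNames(as.integer(cls), names(cls)),
    regionCounts = setNames(as.integer(regionCounts), names(regionCounts)),
    shares = list(
      ts = pct(tsCount), tv = pct(tvCount),
      directional = setNames(pct(directional), labels),
      region = setNames(pct(regionCounts), names(regionCounts)))),
    class = "SubstitutionSpectrum")
}

#' @export
print.SubstitutionSpectrum <- function(x, ...) {
  cat("Substitution spectrum:", x$total, "SNVs\n")
  if (x$total == 0L) return(invisible(x))
  ratio <- if (is.na(x$tsTvRatio)) "undefined (no transversions)"
           else sprintf("%.2f", x$tsTvRatio)
  cat(sprintf("  Ts %d (%.1f%%), Tv %d (%.1f%%), Ts/Tv %s\n", x$tsCount,
              x$shares$ts, x$tvCount, x$shares$tv, ratio))
  cat("  zygosity: ", x$homCount, " HOM, ", x$hetCount, " HET\n", sep = "")
  cat("  HRM classes:",
      paste0(names(x$hrmClassCounts), "=", x$hrmClassCounts,
             collapse = ", "), "\n")
  if (sum(x$regionCounts) > 0) {
    cat("  regions:",
        paste0(names(x$regionCounts), "=", x$regionCounts, " (",
               x$shares$region, "%)", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a substitution-spectrum report
#'
#' @param spectrum a `SubstitutionSpectrum`.
#' @param path output TSV path; a human-readable `.txt` summary is written
#'   alongside.
#' @return The path, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  df <- data.frame(substitution = names(spectrum$directional),
                   count = spectrum$directional,
                   share_pct = if (spectrum$total)
                     spectrum$shares$directional else NA_real_,
                   row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- file.path(dirname(path),
                   paste0(tools::file_path_sans_ext(basename(path)),
                          "-summary.txt"))
  con <- file(txt, "w"); sink(con); print(spectrum); sink(); close(con)
  invisible(path)
}
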