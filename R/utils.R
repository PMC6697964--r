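#' @import methods
#' @importFrom stats rbinom rnbinom rnorm runif rpois lm predict setNames
#' @importFrom utils write.table read.table
NULL

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's state afterwards so generators never perturb user RNG streams.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Fan a single user-facing seed out into independent per-generator streams by
## stable (platform-independent) string hashing; result stays below 2^31.
seedFor <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stream) == 1L)
  h <- 0
  for (cp in utf8ToInt(stream)) h <- (h * 31 + cp) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

reverseComplement1 <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## TRUE when the motif cannot be written as a repetition of a shorter unit.
isPrimitiveMotif <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(p - 1)) {
    if (p %% d == 0L) {
      unit <- substr(motif, 1L, d)
      if (strrep(unit, p %/% d) == motif) return(FALSE)
    }
  }
  TRUE
}

assertNucleotide <- function(x, allowN = TRUE) {
  pat <- if (allowN) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("sequence contains non-nucleotide characters (expected A/C/G/T",
         if (allowN) "/N", ")")
  }
  invisible(TRUE)
}

asSequenceCharacters <- function(x) {
  if (is(x, "DNAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  if (is(x, "DNAString")) return(c(seq1 = as.character(x)))
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(toupper(x))
  }
  stop("expected a DNAStringSet, DNAString or named character vector")
}

randomBases <- function(n, gcFraction = 0.45) {
  probs <- c((1 - gcFraction) / 2, gcFraction / 2, gcFraction / 2,
             (1 - gcFraction) / 2)
  sample(BASES, n, replace = TRUE, prob = probs)
}
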