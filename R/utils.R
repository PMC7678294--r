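#' @useDynLib ltrcensus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats median runif rbinom rlnorm setNames
#' @importFrom utils head combn write.table
#' @importFrom stats aggregate
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
#' @importFrom BiocGenerics width start end strand
NULL

# Run `expr` under a local RNG stream, restoring the caller's state after.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# All overlapping k-words of a character scalar, in order of start position.
seqWords <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Table-style rounding: ties away from zero (1425.5 -> 1426).
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

asDNACharacter <- function(x) {
  if (is(x, "DNAStringSet")) {
    if (length(x) != 1L)
      stop("expected a single sequence, got ", length(x))
    x <- x[[1L]]
  }
  if (is(x, "DNAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("sequence must be a DNAString, 1-element DNAStringSet or character scalar")
  s <- toupper(x)
  if (nchar(s) == 0L) stop("sequence has length 0")
  if (grepl("[^ACGT]", s)) stop("sequence contains characters outside {A,C,G,T}")
  s
}

contigName <- function(x, default = "contig") {
  if (is(x, "DNAStringSet") && !is.null(names(x)) && nzchar(names(x)[1L]))
    names(x)[1L] else default
}

randomBases <- function(n, gc = 0.5) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# i.i.d. substitutions at rate `rate`; each hit base replaced by one of the
# other three, uniformly. Returns list(seq, n_sub).
mutateBases <- function(s, rate) {
  if (rate <= 0) return(list(seq = s, n_sub = 0L))
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  list(seq = paste(v, collapse = ""), n_sub = length(hit))
}

# Single-base indels at rate `rate` (half insertions, half deletions).
applyIndels <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  u <- runif(length(v))
  out <- character(0)
  for (i in seq_along(v)) {
    if (u[i] < rate / 2) next                       # deletion
    if (u[i] < rate) out <- c(out, sample(c("A", "C", "G", "T"), 1L)) # insertion before
    out <- c(out, v[i])
  }
  paste(out, collapse = "")
}
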