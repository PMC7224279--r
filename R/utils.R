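#' @import methods
#' @importFrom stats cor lm.fit model.matrix pnorm pt rnorm rpois runif
#'   wilcox.test sd setNames complete.cases
#' @importFrom utils head
#' @importFrom Rcpp sourceCpp
#' @useDynLib circSponge, .registration = TRUE
NULL

.datatable.aware <- TRUE

# Run `code` under a seed derived from (seed, offset), restoring the caller's
# RNG state afterwards so simulation stages are reproducible independently of
# call order and of anything the user does with .Random.seed.
withStageSeed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) %% 1000003L) * 2011L + as.integer(offset))
  force(code)
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# display string used in the catalogue outputs: contig:start..end (1-based
# inclusive), optionally with strand
circDisplay <- function(contig, start, end, strand = NULL) {
  s <- sprintf("%s:%d..%d", contig, start, end)
  if (!is.null(strand)) s <- paste0(s, ":", strand)
  s
}

phredChar <- function(q) intToUtf8(q + 33L)

`%||%` <- function(a, b) if (is.null(a)) b else a
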