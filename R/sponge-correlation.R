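# Co-abundance side of the sponge screen: log2 stabilization, all-pairs
# Pearson correlation, and the PCIT significance filter.

#' Log2-stabilize an abundance matrix
#'
#' `log2(x + 1)`; the pseudocount keeps zero abundances finite.
#'
#' @param x numeric matrix (features x samples), e.g. CPM.
#' @return matrix of the same shape.
#' @export
stabilizeAbundance <- function(x) log2(as.matrix(x) + 1)

#' All-pairs Pearson correlation of a feature x sample matrix
#'
#' @param x numeric matrix, features in rows, samples in columns; at least 3
#'   samples; zero-variance features are an error (exclude them first, e.g.
#'   with [dropZeroVariance()]).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearsonAllPairs <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3L) stop("at least 3 samples are required")
  v <- apply(x, 1L, sd)
  if (any(v == 0))
    stop("zero-variance feature(s): ",
         paste((rownames(x) %||% seq_len(nrow(x)))[v == 0], collapse = ", "))
  cor(t(x))
}

#' Drop zero-variance features from an abundance matrix
#'
#' @param x features x samples matrix.
#' @return `x` without its constant rows (message lists any dropped).
#' @export
dropZeroVariance <- function(x) {
  x <- as.matrix(x)
  v <- apply(x, 1L, sd)
  if (any(v == 0)) {
    message("dropping ", sum(v == 0), " zero-variance feature(s)")
    x <- x[v > 0, , drop = FALSE]
  }
  x
}

#' PCIT: partial-correlation significance filter for a correlation matrix
#'
#' For every ordered trio (x, y, z) the first-order partial correlations are
#' formed, the trio tolerance is the mean of the partial/direct ratios, and
#' the x-y association is eliminated when for some z its magnitude falls
#' below the tolerance-scaled magnitudes of both other correlations in the
#' trio. Surviving associations are "significant". With fewer than 3
#' features no trio exists and every association is retained.
#'
#' @param r symmetric correlation matrix.
#' @return logical matrix, `TRUE` where the association is retained
#'   (diagonal `FALSE`).
#' @export
pcit <- function(r) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
  if (nrow(r) > 1L && max(abs(r - t(r))) > 1e-8)
    stop("correlation matrix must be symmetric")
  n <- nrow(r)
  if (n < 3L) {
    keep <- matrix(TRUE, n, n); diag(keep) <- FALSE
    dimnames(keep) <- dimnames(r)
    return(keep)
  }
  keep <- .pcit_cpp(unname(r))
  dimnames(keep) <- dimnames(r)
  keep
}
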