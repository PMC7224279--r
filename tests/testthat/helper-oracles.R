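# Independent oracles used to cross-check the implementation. These are
# deliberately naive (brute force / direct formula) and share no code with
# the package internals.

oracleRevcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

gregexprAll <- function(pat, subject) {
  h <- gregexpr(pat, subject, fixed = TRUE)[[1L]]
  if (h[1L] == -1L) integer(0) else as.integer(h)
}

# Exhaustive splice-scan: try every breakpoint of the read (in the anchor
# range) and every exact genomic placement of its two parts, in both read
# orientations; return the junction if exactly one head-to-tail splice
# explains the read, otherwise NULL.
oracleSpliceScan <- function(read, contigs, k, requireSignal = TRUE) {
  found <- character(0)
  res <- list()
  for (orient in c("fwd", "rc")) {
    s <- if (orient == "fwd") read else oracleRevcomp(read)
    L <- nchar(s)
    for (b in k:(L - k)) {
      pre <- substr(s, 1L, b)
      suf <- substr(s, b + 1L, L)
      for (cn in names(contigs)) {
        g <- contigs[[cn]]
        for (pL in gregexprAll(pre, g)) for (pS in gregexprAll(suf, g)) {
          if (pS + (L - b) > pL) next        # must be head-to-tail
          A <- pS; E <- pL + b - 1L
          if (A <= 2L || E + 2L > nchar(g)) next
          acc <- substr(g, A - 2L, A - 1L)
          don <- substr(g, E + 1L, E + 2L)
          strand <- if (acc == "AG" && don == "GT") "+"
            else if (acc == "AC" && don == "CT") "-" else NA
          if (requireSignal && is.na(strand)) next
          if (is.na(strand)) strand <- if (orient == "fwd") "+" else "-"
          key <- paste(cn, strand, A, E)
          if (!key %in% found) {
            found <- c(found, key)
            res[[key]] <- list(contig = cn, strand = strand,
                               start = A, end = E)
          }
        }
      }
    }
  }
  if (length(res) == 1L) res[[1L]] else NULL
}

# Naive PCIT reference: literal triple loop over trios.
oracleNaivePcit <- function(r) {
  n <- nrow(r)
  lim <- 1 - 1e-12
  r <- pmin(pmax(r, -lim), lim)
  keep <- matrix(TRUE, n, n); diag(keep) <- FALSE
  part <- function(xy, xz, yz)
    (xy - xz * yz) / sqrt((1 - xz^2) * (1 - yz^2))
  if (n < 3L) return(keep)
  for (x in seq_len(n - 1L)) for (y in (x + 1L):n) {
    for (z in setdiff(seq_len(n), c(x, y))) {
      rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
      terms <- numeric(0)
      if (abs(rxy) >= 1e-12)
        terms <- c(terms, part(rxy, rxz, ryz) / rxy)
      if (abs(rxz) >= 1e-12)
        terms <- c(terms, part(rxz, rxy, ryz) / rxz)
      if (abs(ryz) >= 1e-12)
        terms <- c(terms, part(ryz, rxy, rxz) / ryz)
      if (!length(terms)) next
      eps <- mean(terms)
      if (abs(rxy) <= abs(eps * rxz) && abs(rxy) <= abs(eps * ryz)) {
        keep[x, y] <- keep[y, x] <- FALSE
        break
      }
    }
  }
  keep
}

oracleCpm <- function(counts, totals) {
  out <- counts * 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts)))
    out[i, j] <- counts[i, j] / totals[j] * 1e6
  out
}

oraclePearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

oracleResiduals <- function(X, Y) {
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  (diag(nrow(X)) - H) %*% Y
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all assignments.
oracleWilcoxP <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  R <- rank(c(x, y))
  obs <- sum(R[seq_len(n1)])
  W <- utils::combn(n, n1, FUN = function(i) sum(R[i]))
  min(1, 2 * min(mean(W <= obs), mean(W >= obs)))
}

junctionKeys <- function(gr) {
  paste(GenomicRanges::seqnames(gr), BiocGenerics::strand(gr),
        GenomicRanges::start(gr), GenomicRanges::end(gr))
}
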