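# Back-splice junction detection by terminal-anchor splitting. The first and
# last `anchor_length` nt of a read are matched exactly against the genome
# index; a head-to-tail hit pair (right anchor upstream of left anchor on one
# contig) is extended toward the read interior, and the breakpoint with the
# fewest mismatches is the candidate junction. With the canonical-splice
# requirement on, only breakpoints flanked by AG..GT (plus-strand circles) or
# AC..CT (minus-strand circles, pattern read on the plus strand) are
# eligible, which also assigns the circle strand and resolves microhomology
# ties at the junction.

#' Detection parameters for the BSJ caller
#'
#' @param anchor_length terminal anchor length in nt (>= 12).
#' @param max_extension_mismatches maximum mismatches tolerated while
#'   extending the two anchors to explain the full read.
#' @param require_canonical_splice require AG..GT / AC..CT genomic flanks.
#' @param max_anchor_hits maximum genomic hits (both strands) for an anchor
#'   to count as unique.
#' @param min_unique_support minimum uniquely-anchored supporting fragments.
#' @param min_junction_phred minimum (over supporting reads) of the mean base
#'   quality in the +/-10 nt window around the junction.
#' @param max_circle_span maximum genomic span of a reported circle (bp).
#' @return a list of class `DetectionParams`.
#' @export
detectionParams <- function(anchor_length = 20L,
                            max_extension_mismatches = 1L,
                            require_canonical_splice = TRUE,
                            max_anchor_hits = 1L,
                            min_unique_support = 2L,
                            min_junction_phred = 35,
                            max_circle_span = 1000000L) {
  p <- as.list(environment())
  if (p$anchor_length < 12L) stop("anchor_length must be >= 12")
  if (p$max_extension_mismatches < 0L || p$max_anchor_hits < 1L ||
      p$min_unique_support < 0L || p$min_junction_phred < 0 ||
      p$max_circle_span < 1L)
    stop("detection thresholds must be non-negative")
  structure(p, class = "DetectionParams")
}

# evaluate one read in one orientation against its head-to-tail anchor pairs.
# readChars: character vector of bases; pairs: data.frame(contig, gL, gR).
# Returns a list of per-pair results: for each pair either NULL or
# list(mm, ambiguous, junction = c(contig, strand, start, end, b, signal)).
evalPairs <- function(readChars, pairs, contigs, contigLens, params,
                      fallbackStrand) {
  k <- params$anchor_length
  L <- length(readChars)
  m <- L - 2L * k
  out <- vector("list", nrow(pairs))
  # genome bases over [from, to]; positions outside the contig padded with N
  # so out-of-range breakpoints score as mismatches rather than dropping the
  # whole anchor pair
  padSub <- function(cs, from, to, clen) {
    chars <- rep("N", to - from + 1L)
    lo <- max(1L, from); hi <- min(clen, to)
    if (lo <= hi)
      chars[(lo - from + 1L):(hi - from + 1L)] <-
        strsplit(substring(cs, lo, hi), "")[[1L]]
    chars
  }
  for (pi in seq_len(nrow(pairs))) {
    cn <- pairs$contig[pi]; gL <- pairs$gL[pi]; gR <- pairs$gR[pi]
    clen <- contigLens[[cn]]
    cs <- contigs[[cn]]
    donorChars <- padSub(cs, gL, gL + L - k - 1L, clen)
    accChars <- padSub(cs, gR + 2L * k - L, gR + k - 1L, clen)
    mid <- (k + 1L):(L - k)
    d <- readChars[mid] != donorChars[mid]
    a <- readChars[mid] != accChars[seq_len(m)]
    cumd <- cumsum(d)
    suf <- rev(cumsum(rev(a)))                     # sum a[i..m]
    mm <- c(suf[1L] %||% 0L,
            if (m > 0L) cumd + c(suf[-1L], 0L) else integer(0))
    if (m == 0L) mm <- 0L
    bs <- k + 0L:m
    A <- gR + k - L + bs
    E <- gL + bs - 1L
    okb <- A > 2L & E + 2L <= clen & mm <= params$max_extension_mismatches
    if (!any(okb)) next
    acc2 <- substring(cs, A - 2L, A - 1L)
    don2 <- substring(cs, E + 1L, E + 2L)
    isPlus <- acc2 == "AG" & don2 == "GT"
    isMinus <- acc2 == "AC" & don2 == "CT"
    keep <- okb
    if (params$require_canonical_splice) keep <- keep & (isPlus | isMinus)
    if (!any(keep)) next
    best <- min(mm[keep])
    sel <- which(keep & mm == best)
    if (length(sel) > 1L) {
      # prefer a uniquely signal-consistent breakpoint before declaring a tie
      sig <- sel[isPlus[sel] | isMinus[sel]]
      if (length(sig) == 1L) sel <- sig
    }
    if (length(sel) > 1L) {
      out[[pi]] <- list(mm = best, ambiguous = TRUE)
      next
    }
    b <- bs[sel]
    strand <- if (isPlus[sel]) "+" else if (isMinus[sel]) "-"
      else fallbackStrand
    out[[pi]] <- list(
      mm = best, ambiguous = FALSE,
      contig = cn, strand = strand, start = A[sel], end = E[sel],
      breakpoint = b,
      signal = paste0(acc2[sel], "..", don2[sel]))
  }
  out[!vapply(out, is.null, TRUE)]
}

# combine pair results across both orientations into one read-level call
resolveRead <- function(resFwd, resRc) {
  res <- c(lapply(resFwd, function(r) c(r, orientation = "fwd")),
           lapply(resRc, function(r) c(r, orientation = "rc")))
  if (!length(res)) return(NULL)
  mms <- vapply(res, function(r) r$mm, 0L)
  res <- res[mms == min(mms)]
  if (any(vapply(res, function(r) isTRUE(r$ambiguous), TRUE)))
    return(list(ambiguous = TRUE))
  keys <- vapply(res, function(r)
    paste(r$contig, r$strand, r$start, r$end), "")
  if (length(unique(keys)) > 1L) return(list(ambiguous = TRUE))
  c(res[[1L]], list())
}

#' Detect a back-splice junction in a single read
#'
#' Splits the read into terminal anchors, finds head-to-tail anchor hit pairs
#' on both orientations, extends them allowing up to
#' `params$max_extension_mismatches`, and reports the junction if a single
#' best breakpoint exists (see [detectionParams()]). Reads whose best
#' breakpoint is tied between two positions are reported with
#' `breakpoint_ambiguous = TRUE`; colinear reads return `NULL`.
#'
#' @param read character scalar or [Biostrings::DNAString] read sequence.
#' @param index a [GenomeIndex-class] built with the same anchor length.
#' @param params a [detectionParams()] list.
#' @param qualities optional Phred+33 quality string (or integer vector) used
#'   for the junction-window mean quality.
#' @return `NULL` (no detection) or a list with contig, strand, start
#'   (acceptor, leftmost circle base), end (donor, rightmost circle base),
#'   breakpoint, orientation, n_mismatches, splice_signal, anchors_unique,
#'   junction_phred, breakpoint_ambiguous.
#' @export
detectBsjRead <- function(read, index, params = detectionParams(),
                          qualities = NULL) {
  read <- toupper(as.character(read))
  k <- params$anchor_length
  L <- nchar(read)
  if (L < 2L * k + 1L) return(NULL)
  rc <- revcompChr(read)
  leftF <- substr(read, 1L, k); rightF <- substr(read, L - k + 1L, L)
  leftR <- substr(rc, 1L, k); rightR <- substr(rc, L - k + 1L, L)
  hits <- lapply(c(leftF, rightF, leftR, rightR), function(a) {
    q <- data.table::data.table(kmer = a)
    index@table[q, on = "kmer", nomatch = NULL]
  })
  mkPairs <- function(hl, hr) {
    if (!nrow(hl) || !nrow(hr)) return(data.frame())
    p <- merge(data.frame(contig = hl$contig, gL = hl$pos),
               data.frame(contig = hr$contig, gR = hr$pos), by = "contig")
    p[p$gR + k <= p$gL &
        p$gL - p$gR + L - k <= params$max_circle_span, , drop = FALSE]
  }
  contigs <- as.character(index@contigs)
  clens <- setNames(nchar(contigs), names(contigs))
  resF <- evalPairs(strsplit(read, "")[[1L]],
                    mkPairs(hits[[1L]], hits[[2L]]), contigs, clens, params,
                    "+")
  resR <- evalPairs(strsplit(rc, "")[[1L]],
                    mkPairs(hits[[3L]], hits[[4L]]), contigs, clens, params,
                    "-")
  r <- resolveRead(resF, resR)
  if (is.null(r)) return(NULL)
  if (isTRUE(r$ambiguous) && is.null(r$contig))
    return(list(breakpoint_ambiguous = TRUE))

  nAnchorHits <- function(a) nrow(hits[[match(a, c(leftF, rightF, leftR,
                                                   rightR))]])
  # hits of an anchor on both strands: its own occurrences plus those of its
  # reverse complement (rightR == revcomp(leftF), leftR == revcomp(rightF))
  totL <- nrow(hits[[1L]]) + nrow(hits[[4L]])
  totR <- nrow(hits[[2L]]) + nrow(hits[[3L]])
  jq <- NA_real_
  if (!is.null(qualities)) {
    q <- if (is.character(qualities))
      as.integer(charToRaw(qualities)) - 33L else as.integer(qualities)
    if (r$orientation == "rc") q <- rev(q)
    w <- max(1L, r$breakpoint - 9L):min(L, r$breakpoint + 10L)
    jq <- mean(q[w])
  }
  list(contig = r$contig, strand = r$strand, start = r$start, end = r$end,
       breakpoint = r$breakpoint, orientation = r$orientation,
       n_mismatches = r$mm, splice_signal = r$signal,
       anchors_unique = totL <= params$max_anchor_hits &&
         totR <= params$max_anchor_hits,
       junction_phred = jq, breakpoint_ambiguous = FALSE)
}
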