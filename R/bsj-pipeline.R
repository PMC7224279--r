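# Sample-level BSJ calling: bulk anchor lookup via keyed joins, per-candidate
# extension, aggregation per junction, the stringency filters, and the
# multi-sample merge.

#' Call back-splice junction candidates in one sample
#'
#' Reads one FASTQ (or a pair of mate FASTQs), detects back-splice junctions
#' per read with the anchor-split procedure of [detectBsjRead()], and
#' aggregates the evidence per junction. Paired mates are independent
#' junction probes but count once per fragment toward support. Reads whose
#' breakpoint is ambiguous are not counted.
#'
#' @param fastq character vector of 1 (single-end) or 2 (paired) FASTQ paths.
#' @param index a [GenomeIndex-class].
#' @param params a [detectionParams()] list.
#' @param sample_id sample label carried into the output.
#' @return data.frame with one row per junction: contig, strand, start,
#'   end, support, unique_support, junction_phred (min over supporting
#'   reads of the mean +/-10 nt window quality), splice_signal,
#'   breakpoint_ambiguous, sample_id.
#' @export
callSample <- function(fastq, index, params = detectionParams(),
                       sample_id = NA_character_) {
  stopifnot(length(fastq) %in% 1:2, all(file.exists(fastq)))
  k <- params$anchor_length
  recs <- lapply(fastq, function(f) {
    x <- tryCatch(
      Biostrings::readDNAStringSet(f, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) stop(sprintf("malformed FASTQ '%s': %s",
                                       f, conditionMessage(e))))
    list(seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities),
         frag = sub("\\s.*$", "", sub("/[12]$", "", names(x))))
  })
  seqs <- toupper(unlist(lapply(recs, `[[`, "seq"), use.names = FALSE))
  quals <- unlist(lapply(recs, `[[`, "qual"), use.names = FALSE)
  frags <- unlist(lapply(recs, `[[`, "frag"), use.names = FALSE)
  emptyCand <- data.frame(contig = character(0), strand = character(0),
                          start = integer(0), end = integer(0),
                          support = integer(0), unique_support = integer(0),
                          junction_phred = numeric(0),
                          splice_signal = character(0),
                          breakpoint_ambiguous = logical(0),
                          sample_id = character(0))
  L <- nchar(seqs)
  ok <- L >= 2L * k + 1L
  seqs <- seqs[ok]; quals <- quals[ok]; frags <- frags[ok]; L <- L[ok]
  if (!length(seqs)) return(emptyCand)

  leftF <- substr(seqs, 1L, k)
  rightF <- substr(seqs, L - k + 1L, L)
  rcLeft <- revcompChr(rightF)    # left anchor of the reverse complement
  rcRight <- revcompChr(leftF)
  h1 <- anchorHits(index, leftF);  h2 <- anchorHits(index, rightF)
  h3 <- anchorHits(index, rcLeft); h4 <- anchorHits(index, rcRight)

  pairUp <- function(hl, hr, Lv) {
    if (!nrow(hl) || !nrow(hr)) return(NULL)
    data.table::setnames(hl, "pos", "gL")
    data.table::setnames(hr, "pos", "gR")
    p <- merge(hl, hr, by = c("qid", "contig"), allow.cartesian = TRUE)
    p <- p[p$gR + k <= p$gL &
             p$gL - p$gR + Lv[p$qid] - k <= params$max_circle_span, ]
    if (nrow(p)) p else NULL
  }
  pF <- pairUp(h1, h2, L)
  pR <- pairUp(h3, h4, L)
  candReads <- sort(unique(c(if (!is.null(pF)) pF$qid,
                             if (!is.null(pR)) pR$qid)))
  if (!length(candReads)) return(emptyCand)

  # anchor-hit counts (both strands) for uniqueness
  cnt <- function(h) {
    n <- integer(length(seqs))
    if (nrow(h)) {
      t <- h[, .N, by = "qid"]
      n[t$qid] <- t$N
    }
    n
  }
  nLF <- cnt(h1); nRF <- cnt(h2); nRcL <- cnt(h3); nRcR <- cnt(h4)
  totL <- nLF + nRcR   # left anchor: own hits + reverse-complement hits
  totR <- nRF + nRcL

  contigs <- as.character(index@contigs)
  clens <- setNames(nchar(contigs), names(contigs))
  rows <- vector("list", length(candReads))
  for (ii in seq_along(candReads)) {
    qi <- candReads[ii]
    read <- seqs[qi]
    rcRead <- revcompChr(read)
    getP <- function(p) {
      if (is.null(p)) return(data.frame())
      as.data.frame(p[p$qid == qi, c("contig", "gL", "gR")])
    }
    resF <- evalPairs(strsplit(read, "")[[1L]], getP(pF), contigs, clens,
                      params, "+")
    resR <- evalPairs(strsplit(rcRead, "")[[1L]], getP(pR), contigs, clens,
                      params, "-")
    r <- resolveRead(resF, resR)
    if (is.null(r) || (isTRUE(r$ambiguous) && is.null(r$contig))) next
    q <- as.integer(charToRaw(quals[qi])) - 33L
    if (r$orientation == "rc") q <- rev(q)
    w <- max(1L, r$breakpoint - 9L):min(L[qi], r$breakpoint + 10L)
    rows[[ii]] <- data.frame(
      contig = r$contig, strand = r$strand, start = r$start, end = r$end,
      frag = frags[qi],
      uniq = totL[qi] <= params$max_anchor_hits &
        totR[qi] <= params$max_anchor_hits,
      jq = mean(q[w]), signal = r$signal)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(emptyCand)
  dt <- data.table::rbindlist(rows)
  agg <- dt[, list(support = length(unique(frag)),
                   unique_support = length(unique(frag[uniq])),
                   junction_phred = min(jq),
                   splice_signal = signal[1L]),
            by = c("contig", "strand", "start", "end")]
  out <- as.data.frame(agg)
  out$breakpoint_ambiguous <- FALSE
  out$sample_id <- sample_id
  out[order(out$contig, out$start, out$end), , drop = FALSE]
}

#' Apply the stringency filters to aggregated junction candidates
#'
#' Keeps a candidate iff it has at least `min_unique_support` uniquely
#' anchored supporting fragments, its junction-window quality is at least
#' `min_junction_phred`, its breakpoint is unambiguous, and its genomic span
#' does not exceed `max_circle_span`.
#'
#' @param candidates data.frame from [callSample()].
#' @param params a [detectionParams()] list.
#' @return the filtered data.frame.
#' @export
filterCandidates <- function(candidates, params = detectionParams()) {
  if (!nrow(candidates)) return(candidates)
  keep <- candidates$unique_support >= params$min_unique_support &
    candidates$junction_phred >= params$min_junction_phred &
    !candidates$breakpoint_ambiguous &
    (candidates$end - candidates$start + 1L) <= params$max_circle_span
  candidates[keep, , drop = FALSE]
}

#' Merge filtered candidates across samples into a catalogue skeleton
#'
#' Junctions are matched by exact (contig, strand, start, end) and kept iff
#' detected (post-filter) in at least `min_samples` samples. The count matrix
#' holds the per-sample BSJ-spanning read support, 0 where undetected.
#'
#' @param perSample named list of filtered candidate data.frames (one per
#'   sample; names are the sample ids).
#' @param min_samples presence threshold; default `ceiling(0.75 * n_samples)`
#'   (30 of 40 at the design sample size).
#' @return list with `junctions` (GRanges, coordinate-sorted) and `counts`
#'   (junctions x samples integer matrix).
#' @export
mergeSamples <- function(perSample, min_samples = NULL) {
  stopifnot(is.list(perSample), length(perSample) >= 1L)
  ids <- names(perSample)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("perSample must be a named list with unique sample ids")
  min_samples <- min_samples %||% ceiling(0.75 * length(perSample))
  dt <- data.table::rbindlist(lapply(ids, function(s) {
    x <- perSample[[s]]
    if (!nrow(x)) return(NULL)
    if (!is.na(x$sample_id[1L]) && !all(x$sample_id %in% c(s, NA)))
      stop(sprintf("sample id mismatch: list name '%s' vs column '%s'",
                   s, x$sample_id[1L]))
    data.table::data.table(contig = x$contig, strand = x$strand,
                           start = x$start, end = x$end,
                           support = x$support, sample = s)
  }))
  if (is.null(dt) || !nrow(dt)) {
    return(list(junctions = GenomicRanges::GRanges(),
                counts = matrix(0L, 0L, length(ids),
                                dimnames = list(NULL, ids))))
  }
  key <- dt[, list(n_samples = length(unique(sample))),
            by = c("contig", "strand", "start", "end")]
  key <- key[key$n_samples >= min_samples, ]
  if (!nrow(key)) {
    return(list(junctions = GenomicRanges::GRanges(),
                counts = matrix(0L, 0L, length(ids),
                                dimnames = list(NULL, ids))))
  }
  key <- key[order(key$contig, key$start, key$end, key$strand), ]
  jk <- paste(key$contig, key$strand, key$start, key$end)
  counts <- matrix(0L, nrow(key), length(ids),
                   dimnames = list(jk, ids))
  dk <- paste(dt$contig, dt$strand, dt$start, dt$end)
  hit <- dk %in% jk
  counts[cbind(match(dk[hit], jk), match(dt$sample[hit], ids))] <-
    as.integer(dt$support[hit])
  gr <- GenomicRanges::GRanges(key$contig,
                               IRanges::IRanges(key$start, key$end),
                               strand = key$strand)
  rownames(counts) <- NULL
  list(junctions = gr, counts = counts)
}
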