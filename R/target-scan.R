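# Sequence side of the sponge screen: seed-anchored, position-weighted
# complementarity scan of miRNAs against circular (spliced) sequences. Sites
# require a perfect Watson-Crick seed match (miRNA positions 2-7 at minimum)
# and an ungapped complementarity score over the full miRNA length, with
# seed positions up-weighted and G:U wobbles scored reduced. The circle
# sequence is treated as circular: the linear representation is extended by
# its own start so junction-spanning sites are found, and pairing positions
# wrap modulo the circle length.

#' Parameters for the miRNA target-site scan
#'
#' @param seed_span miRNA positions scored with the seed weight (default
#'   2-8).
#' @param required_wc_span miRNA positions requiring perfect Watson-Crick
#'   complementarity (default 2-7).
#' @param allow_GU_wobble score G:U pairs as weak matches instead of
#'   mismatches.
#' @param match,mismatch,gu_wobble per-position scores.
#' @param seed_scale multiplicative weight on seed positions.
#' @param min_score minimum alignment score for a reported site.
#' @return list of class `TargetScanParams`.
#' @export
targetScanParams <- function(seed_span = c(2L, 8L),
                             required_wc_span = c(2L, 7L),
                             allow_GU_wobble = TRUE,
                             match = 5, mismatch = -3, gu_wobble = 1,
                             seed_scale = 2, min_score = 55) {
  p <- as.list(environment())
  if (p$min_score <= 0) stop("min_score must be positive")
  if (!all(is.finite(c(match, mismatch, gu_wobble, seed_scale))))
    stop("scores must be finite")
  structure(p, class = "TargetScanParams")
}

dnaUpper <- function(x) {
  nm <- names(x)
  x <- chartr("U", "T", toupper(as.character(x)))
  if (any(grepl("[^ACGT]", x)))
    stop("non-nucleotide symbols in sequence(s)")
  names(x) <- nm
  x
}

#' Scan circRNA sequences for miRNA target sites
#'
#' @param mirnas named character vector, [Biostrings::RNAStringSet] or
#'   DNAStringSet of miRNA sequences (5'->3').
#' @param circSeqs named character vector or DNAStringSet of spliced circle
#'   sequences (5'->3', starting at the back-splice acceptor).
#' @param params a [targetScanParams()] list.
#' @return data.frame with one row per site: circ_id, mirna_id, position
#'   (1-based start of the seed match in circle coordinates, wrapped modulo
#'   the circle length), score, seed_match ("2-7" or "2-8" for extended
#'   perfect seeds).
#' @export
scanTargets <- function(mirnas, circSeqs, params = targetScanParams()) {
  mir <- dnaUpper(mirnas)
  circ <- dnaUpper(circSeqs)
  if (is.null(names(mir))) names(mir) <- paste0("miR", seq_along(mir))
  if (is.null(names(circ))) names(circ) <- paste0("circ", seq_along(circ))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  ws <- params$required_wc_span
  for (mi in seq_along(mir)) {
    m <- strsplit(mir[[mi]], "")[[1L]]
    Lm <- length(m)
    seedRc <- revcompChr(paste(m[ws[1L]:ws[2L]], collapse = ""))
    wseed <- nchar(seedRc)
    # per-position weights (seed span up-weighted)
    wts <- rep(1, Lm)
    wts[params$seed_span[1L]:min(params$seed_span[2L], Lm)] <-
      params$seed_scale
    for (ci in seq_along(circ)) {
      S <- circ[[ci]]
      Lc <- nchar(S)
      if (Lc < Lm) next
      sChars <- strsplit(S, "")[[1L]]
      ext <- paste0(S, substr(S, 1L, Lm - 1L))
      hit <- gregexpr(seedRc, ext, fixed = TRUE)[[1L]]
      if (hit[1L] == -1L) next
      starts <- unique((as.integer(hit) - 1L) %% Lc + 1L)
      for (q in starts) {
        # circle index pairing miRNA position i: the seed match starts at q,
        # which pairs miRNA position ws[2]; miRNA position i pairs circle
        # position q + ws[2] - i (antiparallel), wrapped modulo the circle.
        idx <- (q + ws[2L] - seq_len(Lm) - 1L) %% Lc + 1L
        cb <- sChars[idx]
        isMatch <- cb == comp[m]
        isGU <- (m == "G" & cb == "T") | (m == "T" & cb == "G")
        per <- ifelse(isMatch, params$match,
                      ifelse(params$allow_GU_wobble & isGU,
                             params$gu_wobble, params$mismatch))
        score <- sum(per * wts)
        if (score < params$min_score) next
        seed8 <- if (params$seed_span[2L] >= 8L && Lm >= 8L &&
                     all(isMatch[2L:8L])) "2-8" else "2-7"
        out[[length(out) + 1L]] <- data.frame(
          circ_id = names(circ)[ci], mirna_id = names(mir)[mi],
          position = q, score = score, seed_match = seed8)
      }
    }
  }
  if (!length(out))
    return(data.frame(circ_id = character(0), mirna_id = character(0),
                      position = integer(0), score = numeric(0),
                      seed_match = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
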