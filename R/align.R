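# Read-to-reference alignment and indel extraction.
#
# Reads are aligned globally to the amplicon reference with affine gap
# penalties (match +2, mismatch -4, gap open -10, gap extend -1; a gap of
# length L costs 10 + L). Indel coordinates are then left-normalised (gaps
# slid to their leftmost equivalent placement, as in VCF normalisation) so
# identical biology yields identical coordinates regardless of the
# aligner's internal tie-breaking.

default_scoring <- function() {
  list(match = 2, mismatch = -4, gap_open = 10, gap_ext = 1)
}

#' Align amplicon reads to a reference
#'
#' Global (Needleman-Wunsch) alignment with affine gaps of each read against
#' the amplicon reference. Reads shorter than `min_length_frac` times the
#' reference length are discarded and counted, not aligned.
#'
#' @param reads Character vector (or `DNAStringSet`) of read sequences,
#'   optionally named by read id.
#' @param ref Reference amplicon sequence.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_ext`
#'   (penalties positive); defaults +2/-4/10/1.
#' @param min_length_frac Discard reads shorter than this fraction of the
#'   reference length (default 0.5).
#' @return An object of class `talen_alignments`: list with `indels` (a
#'   per-read list, each holding data.frames `deletions` — reference
#'   `start` / `end`, 0-based half-open — and `insertions` — reference
#'   `pos` before which the insertion sits, `len`, `seq`), `score`,
#'   `read_id`, `n_discarded`, and `ref`.
#' @examples
#' ref <- "ACGTACGTACGTACGTACGT"
#' align_reads(c(r1 = ref), ref)
#' @export
align_reads <- function(reads, ref, scoring = default_scoring(),
                        min_length_frac = 0.5) {
  if (methods::is(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  stopifnot(is.character(reads), length(reads) >= 1L, nchar(ref) > 0L)
  ref <- toupper(ref)
  reads <- toupper(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  short <- nchar(reads) < min_length_frac * nchar(ref)
  n_disc <- sum(short)
  reads <- reads[!short]
  if (!length(reads)) {
    return(structure(list(indels = list(), score = numeric(0),
                          read_id = character(0), n_discarded = n_disc,
                          ref = ref), class = "talen_alignments"))
  }
  mat <- matrix(scoring$mismatch, 4L, 4L,
                dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(mat) <- scoring$match
  # amplicon read sets are highly redundant (WT and recurrent alleles):
  # align each distinct sequence once and fan the result back out
  uniq <- unique(reads)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(uniq),
    subject = Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  gp <- as.character(Biostrings::alignedPattern(aln))
  gs <- as.character(Biostrings::alignedSubject(aln))
  uniq_indels <- mapply(function(p, s) {
    normalize_indels(extract_indels(p, s), ref)
  }, gp, gs, SIMPLIFY = FALSE)
  idx <- match(reads, uniq)
  indels <- uniq_indels[idx]
  names(indels) <- names(reads)
  structure(list(indels = indels,
                 score = unname(Biostrings::score(aln)[idx]),
                 read_id = names(reads), n_discarded = n_disc, ref = ref),
            class = "talen_alignments")
}

#' @export
print.talen_alignments <- function(x, ...) {
  n_ind <- sum(vapply(x$indels, function(i) {
    nrow(i$deletions) + nrow(i$insertions) > 0L
  }, logical(1L)))
  cat(sprintf("<%d aligned read(s), %d with indels, %d discarded>\n",
              length(x$indels), n_ind, x$n_discarded))
  invisible(x)
}

# walk a gapped read/reference pair and pull out indels in reference
# coordinates (0-based half-open; insertions anchored before `pos`)
extract_indels <- function(gp, gs) {
  sc <- strsplit(gs, "", fixed = TRUE)[[1L]]
  # reference position (0-based) at each alignment column
  refpos_before <- cumsum(sc != "-") - (sc != "-")
  dels <- ins <- NULL
  dr <- gregexpr("-+", gp, perl = TRUE)[[1L]]
  if (dr[1L] != -1L) {
    st <- as.integer(dr)
    len <- attr(dr, "match.length")
    dels <- data.frame(start = refpos_before[st],
                       end = refpos_before[st] + len)
  }
  irx <- gregexpr("-+", gs, perl = TRUE)[[1L]]
  if (irx[1L] != -1L) {
    st <- as.integer(irx)
    len <- attr(irx, "match.length")
    ins <- data.frame(pos = refpos_before[st], len = len,
                      seq = substring(gp, st, st + len - 1L),
                      stringsAsFactors = FALSE)
  }
  list(deletions = if (is.null(dels))
         data.frame(start = integer(0), end = integer(0)) else dels,
       insertions = if (is.null(ins))
         data.frame(pos = integer(0), len = integer(0), seq = character(0),
                    stringsAsFactors = FALSE) else ins)
}

# number of rightward shifts of a LEFT-NORMALISED deletion [s, e) that give
# an equivalent deletion (micro-homology ambiguity); the unbiased centre of
# the event is the midpoint of this equivalence class
deletion_right_ext <- function(s, e, rc) {
  k <- 0L
  n <- length(rc)
  while (e + k < n && rc[s + k + 1L] == rc[e + k + 1L]) k <- k + 1L
  k
}

# slide indels to their leftmost equivalent placement on the reference
normalize_indels <- function(indels, ref) {
  rc <- strsplit(ref, "", fixed = TRUE)[[1L]]
  d <- indels$deletions
  if (nrow(d)) {
    for (i in seq_len(nrow(d))) {
      s <- d$start[i]; e <- d$end[i]
      while (s > 0L && rc[s] == rc[e]) {   # rc is 1-based: rc[s] = base s-1
        s <- s - 1L; e <- e - 1L
      }
      d$start[i] <- s; d$end[i] <- e
    }
    d <- d[order(d$start), , drop = FALSE]
    rownames(d) <- NULL
  }
  ins <- indels$insertions
  if (nrow(ins)) {
    for (i in seq_len(nrow(ins))) {
      p <- ins$pos[i]
      sq <- strsplit(ins$seq[i], "", fixed = TRUE)[[1L]]
      while (p > 0L && rc[p] == sq[length(sq)]) {
        sq <- c(sq[length(sq)], sq[-length(sq)])
        p <- p - 1L
      }
      ins$pos[i] <- p
      ins$seq[i] <- paste(sq, collapse = "")
    }
    ins <- ins[order(ins$pos), , drop = FALSE]
    rownames(ins) <- NULL
  }
  list(deletions = d, insertions = ins)
}
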