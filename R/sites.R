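# Coordinates throughout are 0-based half-open on the reference forward
# strand (BED convention); reverse-strand sites are stored in forward
# coordinates with a strand flag.

#' Find single TALE binding sites
#'
#' A site exists at every position where the bound strand carries a T (the
#' obligatory T0) followed 5'->3' by `L_rec` unambiguous bases. On the minus
#' strand the T0 corresponds to a reference A at the footprint's rightmost
#' base. Soft-masked (lowercase) bases are treated as normal bases unless
#' `respect_mask = TRUE`.
#'
#' @param seq DNA string (reference forward strand).
#' @param strand `"+"` or `"-"`: the strand the TALE binds.
#' @param geom An [array_geometry()]; default 15.5 repeats (16 bases).
#' @param chrom Sequence name used in the output.
#' @param respect_mask If `TRUE`, lowercase bases disqualify a site.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open footprint including T0), `strand`, `t0_pos` (reference
#'   coordinate of the T0 base) and `recognized` (the L_rec bases read
#'   5'->3' on the bound strand, excluding T0).
#' @examples
#' find_sites("TACG", "+", array_geometry(2.5))
#' @export
find_sites <- function(seq, strand = c("+", "-"), geom = array_geometry(),
                       chrom = "seq", respect_mask = FALSE) {
  strand <- match.arg(strand)
  stopifnot(inherits(geom, "array_geometry"))
  L <- geom$L_rec
  masked <- if (respect_mask) {
    chars0 <- strsplit(seq, "", fixed = TRUE)[[1L]]
    chars0 %in% c("a", "c", "g", "t", "n")
  } else NULL
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      t0_pos = integer(0), recognized = character(0),
                      stringsAsFactors = FALSE)
  if (n < L + 1L) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ok <- chars %in% c("A", "C", "G", "T")
  if (!is.null(masked)) ok <- ok & !masked
  # number of invalid bases in any window via a cumulative sum
  bad_cs <- c(0L, cumsum(!ok))
  clean <- function(from0, to0) bad_cs[to0 + 2L] - bad_cs[from0 + 1L] == 0L
  if (strand == "+") {
    # T0 at i (0-based), recognised bases at i+1 .. i+L
    cand <- which(chars == "T") - 1L
    cand <- cand[cand + L + 1L <= n - 1L + 1L & cand + L <= n - 1L]
    cand <- cand[ok[cand + 1L] & clean(cand + 1L, cand + L)]
    if (!length(cand)) return(empty)
    data.frame(chrom = chrom, start = cand, end = cand + L + 1L,
               strand = "+", t0_pos = cand,
               recognized = substring(seq, cand + 2L, cand + L + 1L),
               stringsAsFactors = FALSE)
  } else {
    # T0 on minus strand at reference j => reference base A; recognised
    # bases are reference j-1 .. j-L read 3'->5', i.e. revcomp of j-L .. j-1
    cand <- which(chars == "A") - 1L
    cand <- cand[cand - L >= 0L]
    cand <- cand[ok[cand + 1L] & clean(cand - L, cand - 1L)]
    if (!length(cand)) return(empty)
    data.frame(chrom = chrom, start = cand - L, end = cand + 1L,
               strand = "-", t0_pos = cand,
               recognized = revcomp(substring(seq, cand - L + 1L, cand)),
               stringsAsFactors = FALSE)
  }
}

#' Find paired nuclease targets
#'
#' Enumerates every pair of TALE binding sites laid out according to an
#' architecture's strand/T0 geometry and separated by a spacer in its
#' activity windows. All valid pairs are reported, including overlapping and
#' nested ones; order is deterministic (footprint start, then spacer
#' length). For TtT and HtH the two sites sit on opposite strands and the
#' forward-coordinate layout is strand-symmetric; for TtH both sites sit on
#' the same strand, and pairs are found on either strand.
#'
#' @inheritParams find_sites
#' @param arch A [architecture()] object.
#' @param distinct_monomers If `TRUE`, drop pairs whose two recognised
#'   sequences are identical (palindromic self-pairs for the opposite-strand
#'   geometries, direct repeats for TtH).
#' @return A data.frame with one row per target: `chrom`, `start`, `end`
#'   (full footprint, 0-based half-open), `arch`, `spacer_len`,
#'   `bound_strand` (strand carrying the TALE::FokI tail site for TtH; "+"
#'   for the symmetric geometries), per-site columns
#'   `left_start`, `left_strand`, `left_seq`, `right_start`, `right_strand`,
#'   `right_seq` (left/right in reference order; sequences are T0-included,
#'   read on the bound strand), `spacer_start`, and `cut_rel` (predicted cut
#'   centre relative to the spacer centre, along the bound strand).
#' @examples
#' arch <- architecture("TtH", windows = spacer_windows(c(4, 4)))
#' find_paired_targets("TAAACCCCTGGG", arch, array_geometry(2.5))
#' @export
find_paired_targets <- function(seq, arch, geom = array_geometry(),
                                chrom = "seq", respect_mask = FALSE,
                                distinct_monomers = FALSE) {
  stopifnot(inherits(arch, "talen_architecture"))
  L <- geom$L_rec
  f <- L + 1L
  ss <- spacer_lengths(arch$spacer_windows)
  plus <- find_sites(seq, "+", geom, chrom, respect_mask)
  minus <- find_sites(seq, "-", geom, chrom, respect_mask)
  out <- list()
  pair_up <- function(left, right, s, bound) {
    # left/right: site rows in reference order, left$start + f + s == right$start
    key <- match(left$start + f + s, right$start)
    keep <- !is.na(key)
    if (!any(keep)) return(NULL)
    l <- left[keep, , drop = FALSE]
    r <- right[key[keep], , drop = FALSE]
    data.frame(chrom = chrom, start = l$start, end = r$start + f,
               arch = arch$name, spacer_len = s, bound_strand = bound,
               left_start = l$start, left_strand = l$strand,
               left_seq = paste0("T", l$recognized),
               right_start = r$start, right_strand = r$strand,
               right_seq = paste0("T", r$recognized),
               spacer_start = l$start + f,
               stringsAsFactors = FALSE)
  }
  for (s in ss) {
    res <- switch(arch$name,
      TtT = pair_up(plus, minus, s, "+"),
      HtH = pair_up(minus, plus, s, "+"),
      TtH = rbind(pair_up(plus, plus, s, "+"),
                  pair_up(minus, minus, s, "-")))
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), arch = character(0),
                      spacer_len = integer(0), bound_strand = character(0),
                      left_start = integer(0), left_strand = character(0),
                      left_seq = character(0), right_start = integer(0),
                      right_strand = character(0), right_seq = character(0),
                      spacer_start = integer(0), cut_rel = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  if (distinct_monomers) res <- res[res$left_seq != res$right_seq, , drop = FALSE]
  res <- res[order(res$start, res$spacer_len), , drop = FALSE]
  rownames(res) <- NULL
  res$cut_rel <- predicted_cut_center(arch, 1)$spacer_pos - spacer_center(res$spacer_len)
  res
}
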