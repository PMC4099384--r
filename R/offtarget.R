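#' Find monomer binding-site matches under mismatch tolerance
#'
#' Locates every occurrence of a single TALE binding site (T0 plus
#' recognised sequence) on both strands of a genome with Hamming distance at
#' most `k_max` over the recognised bases. The T0 must match exactly: a
#' non-T at the T0 position disqualifies the locus, it is not a countable
#' mismatch — the 5' thymine is the binding anchor the architecture keeps
#' for specificity.
#'
#' @param genome DNA string.
#' @param site_seq The site sequence including T0 (so `"T"` followed by the
#'   recognised bases), read 5'->3' on the bound strand.
#' @param k_max Maximum Hamming mismatches over the recognised bases.
#' @param chrom Sequence name for the output.
#' @return data.frame with `chrom`, `start`, `end` (footprint, 0-based
#'   half-open), `strand`, `mismatches`.
#' @examples
#' match_monomer("CCTACGCC", "TACG", k_max = 0)
#' @export
match_monomer <- function(genome, site_seq, k_max = 0L, chrom = "seq") {
  stopifnot(k_max >= 0, nchar(site_seq) >= 2L)
  genome <- toupper(genome)
  site_seq <- toupper(site_seq)
  if (substring(site_seq, 1L, 1L) != "T") {
    stop("site_seq must start with the T0 thymine", call. = FALSE)
  }
  subject <- Biostrings::DNAString(genome)
  hit_rows <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subject, max.mismatch = k_max,
                                  fixed = TRUE)
    if (!length(m)) return(NULL)
    st <- IRanges::start(m) - 1L
    en <- IRanges::end(m)
    found <- as.character(m)
    # per-hit mismatch audit on the bound strand; T0 exact required
    bound <- if (strand == "+") found else revcomp(found)
    pat_bound <- site_seq
    mm <- mapply(function(x) {
      a <- strsplit(x, "", fixed = TRUE)[[1L]]
      b <- strsplit(pat_bound, "", fixed = TRUE)[[1L]]
      if (a[1L] != "T") return(NA_integer_)
      sum(a[-1L] != b[-1L])
    }, bound)
    keep <- !is.na(mm) & mm <= k_max
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start = st[keep], end = en[keep],
               strand = strand, mismatches = as.integer(mm[keep]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(hit_rows(site_seq, "+"), hit_rows(revcomp(site_seq), "-"))
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Designed nuclease pair
#'
#' Bundles the two monomers of a designed pair: their scaffold kinds and
#' their full binding-site sequences (T0 included, bound-strand 5'->3').
#'
#' @param left_seq,right_seq Site sequences including T0.
#' @param left_kind,right_kind Scaffold kinds; defaults describe a TtH pair.
#' @return An object of class `talen_pair`.
#' @examples
#' talen_pair("TACGTACGT", "TGGCCAAGG")
#' @export
talen_pair <- function(left_seq, right_seq,
                       left_kind = "TALE_FOKI", right_kind = "FOKI_TALE") {
  stopifnot(left_kind %in% c("TALE_FOKI", "FOKI_TALE"),
            right_kind %in% c("TALE_FOKI", "FOKI_TALE"))
  structure(list(left = list(seq = toupper(left_seq), kind = left_kind),
                 right = list(seq = toupper(right_seq), kind = right_kind)),
            class = "talen_pair")
}

# geometry forced by two scaffold kinds: FokI dimerisation constrains the
# layout, not the monomer identity
geometry_for_kinds <- function(k1, k2) {
  if (k1 == "TALE_FOKI" && k2 == "TALE_FOKI") "TtT"
  else if (k1 == "FOKI_TALE" && k2 == "FOKI_TALE") "HtH"
  else "TtH"
}

#' Enumerate potential off-site targets of a designed pair
#'
#' Off-site targets are combinations of the pair's monomer matches — left +
#' right, left + left and right + right — laid out in the geometry their
#' scaffold kinds force (two tail fusions can only dimerise Tail-to-Tail,
#' two head fusions Head-to-Head, a mixed combination Tail-to-Head) and
#' separated by a spacer admissible for that geometry.
#'
#' @param genome DNA string.
#' @param pair A [talen_pair()].
#' @param k_max Maximum mismatches per monomer (T0 always exact).
#' @param windows_by_geometry Named list of [spacer_windows()] keyed by
#'   geometry name; defaults to the "results" presets.
#' @param pair_types Subset of `c("L+R","L+L","R+R")` to evaluate.
#' @param exclude Optional data.frame with columns `start`, `end`: hits
#'   whose full footprint equals a row (e.g. the on-target) are dropped.
#' @param chrom Sequence name for the output.
#' @return data.frame of hits: `pair_type`, `geometry`, footprint `start` /
#'   `end`, per-monomer positions, strands and mismatch counts, and
#'   `spacer_len`.
#' @examples
#' g <- paste0("TACGTACGT", strrep("C", 20), "TGGCCAAGG")
#' enumerate_offtargets(g, talen_pair("TACGTACGT", "TGGCCAAGG"),
#'                      windows_by_geometry = list(TtH = spacer_windows(c(20, 20))))
#' @export
enumerate_offtargets <- function(genome, pair, k_max = 0L,
                                 windows_by_geometry = list(
                                   TtT = windows_preset("TtT"),
                                   HtH = windows_preset("HtH"),
                                   TtH = windows_preset("TtH")),
                                 pair_types = c("L+R", "L+L", "R+R"),
                                 exclude = NULL, chrom = "seq") {
  stopifnot(inherits(pair, "talen_pair"))
  pair_types <- match.arg(pair_types, several.ok = TRUE)
  hits <- list(L = match_monomer(genome, pair$left$seq, k_max, chrom),
               R = match_monomer(genome, pair$right$seq, k_max, chrom))
  flen <- c(L = nchar(pair$left$seq), R = nchar(pair$right$seq))
  kinds <- c(L = pair$left$kind, R = pair$right$kind)
  out <- list()
  combine <- function(m1, m2, type) {
    # m1/m2 are monomer labels; tail monomer takes the tail role in TtH
    geo <- geometry_for_kinds(kinds[[m1]], kinds[[m2]])
    win <- windows_by_geometry[[geo]]
    if (is.null(win)) return(NULL)
    ss <- spacer_lengths(win)
    h1 <- hits[[m1]]; h2 <- hits[[m2]]
    if (!nrow(h1) || !nrow(h2)) return(NULL)
    if (geo == "TtH" && kinds[[m1]] == "FOKI_TALE") {
      # tail scaffold leads on the bound strand
      tmp <- m1; m1 <- m2; m2 <- tmp
      h1 <- hits[[m1]]; h2 <- hits[[m2]]
    }
    rows <- list()
    add <- function(a, b, s, bound) {
      # a upstream (reference order), b downstream, spacer s
      if (!nrow(a) || !nrow(b)) return()
      key <- outer(a$start + (a$end - a$start) + s, b$start, `==`)
      idx <- which(key, arr.ind = TRUE)
      if (!nrow(idx)) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, pair_type = type, geometry = geo,
        start = a$start[idx[, 1L]], end = b$end[idx[, 2L]],
        m1_start = a$start[idx[, 1L]], m1_strand = a$strand[idx[, 1L]],
        m1_mismatches = a$mismatches[idx[, 1L]],
        m2_start = b$start[idx[, 2L]], m2_strand = b$strand[idx[, 2L]],
        m2_mismatches = b$mismatches[idx[, 2L]],
        spacer_len = s, bound_strand = bound,
        stringsAsFactors = FALSE)
    }
    for (s in ss) {
      if (geo == "TtT") {
        # either monomer may take either side of the opposite-strand pair
        add(h1[h1$strand == "+", ], h2[h2$strand == "-", ], s, "+")
        if (m1 != m2) add(h2[h2$strand == "+", ], h1[h1$strand == "-", ], s, "+")
      } else if (geo == "HtH") {
        add(h1[h1$strand == "-", ], h2[h2$strand == "+", ], s, "+")
        if (m1 != m2) add(h2[h2$strand == "-", ], h1[h1$strand == "+", ], s, "+")
      } else {
        # TtH: tail monomer 5' of head monomer on the shared bound strand
        add(h1[h1$strand == "+", ], h2[h2$strand == "+", ], s, "+")
        add(h2[h2$strand == "-", ], h1[h1$strand == "-", ], s, "-")
      }
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }
  for (pt in pair_types) {
    res <- switch(pt,
                  "L+R" = combine("L", "R", "L+R"),
                  "L+L" = combine("L", "L", "L+L"),
                  "R+R" = combine("R", "R", "R+R"))
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), pair_type = character(0),
                      geometry = character(0), start = integer(0),
                      end = integer(0), m1_start = integer(0),
                      m1_strand = character(0), m1_mismatches = integer(0),
                      m2_start = integer(0), m2_strand = character(0),
                      m2_mismatches = integer(0), spacer_len = integer(0),
                      bound_strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  if (!is.null(exclude) && nrow(res)) {
    drop <- res$start %in% exclude$start & res$end %in% exclude$end
    res <- res[!drop, , drop = FALSE]
  }
  res <- res[order(res$start, res$spacer_len, res$pair_type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fold difference between two off-target counts
#'
#' @param count_a,count_b Non-negative counts; `count_b` must be positive.
#' @return `count_a / count_b`.
#' @examples
#' offtarget_ratio(25, 8)
#' @export
offtarget_ratio <- function(count_a, count_b) {
  stopifnot(is.numeric(count_a), is.numeric(count_b))
  if (any(count_b == 0)) {
    stop("fold ratio undefined: reference count is zero", call. = FALSE)
  }
  count_a / count_b
}

#' Summarise off-target hits
#'
#' @param hits Result of [enumerate_offtargets()].
#' @return List with per-pair-type counts, a spacer-length histogram and
#'   the total.
#' @export
offtarget_summary <- function(hits) {
  list(total = nrow(hits),
       by_pair_type = as.list(table(hits$pair_type)),
       by_geometry = as.list(table(hits$geometry)),
       spacer_histogram = as.list(table(hits$spacer_len)))
}
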