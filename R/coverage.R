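#' Genome targetability scan
#'
#' Computes, for a set of sequences and one or more architectures, which
#' bases are targetable: a base is covered iff it lies inside at least one
#' paired-target footprint of any requested architecture. Maximal uncovered
#' runs are reported as target-devoid regions. Long sequences are scanned in
#' overlapping windows (overlap >= the maximal footprint) so memory stays
#' bounded; the windowed result equals the whole-sequence scan.
#'
#' @param sequences Named character vector of DNA sequences (or a
#'   `DNAStringSet`).
#' @param archs A [architecture()] object or list of them.
#' @param geom An [array_geometry()].
#' @param chunk_size Window size in bp for the streaming scan; `Inf`
#'   disables windowing.
#' @param respect_mask Passed to [find_paired_targets()].
#' @return An object of class `coverage_report`: a list with `total_bp`,
#'   `covered_bp`, `coverage_fraction`, `devoid_regions` (data.frame chrom /
#'   start / end / length, 0-based half-open) and `per_arch` (data.frame of
#'   per-architecture target and covered-base counts).
#' @examples
#' coverage_scan(c(chr = strrep("A", 100)), architecture("TtT"))
#' @export
coverage_scan <- function(sequences, archs, geom = array_geometry(),
                          chunk_size = 100000L, respect_mask = FALSE) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  stopifnot(is.character(sequences))
  if (inherits(archs, "talen_architecture")) archs <- list(archs)
  stopifnot(all(vapply(archs, inherits, logical(1L), "talen_architecture")))
  if (is.null(names(sequences)) && length(sequences)) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  empty_report <- function() {
    structure(list(total_bp = 0L, covered_bp = 0L, coverage_fraction = NA_real_,
                   devoid_regions = data.frame(chrom = character(0),
                                               start = integer(0),
                                               end = integer(0),
                                               length = integer(0)),
                   per_arch = data.frame(arch = character(0),
                                         n_targets = integer(0),
                                         covered_bp = integer(0))),
              class = "coverage_report")
  }
  if (!length(sequences)) return(empty_report())

  max_fp <- max(vapply(archs, function(a) {
    2L * geom$footprint + max(spacer_lengths(a$spacer_windows))
  }, numeric(1L)))

  total_bp <- 0L
  covered_bp <- 0L
  devoid <- list()
  per_arch_targets <- stats::setNames(integer(length(archs)),
                                      vapply(archs, `[[`, "", "name"))
  per_arch_cov <- per_arch_targets

  scan_one <- function(seqname, seq) {
    n <- nchar(seq)
    by_arch <- lapply(archs, function(a) {
      tg <- chunked_targets(seq, a, geom, chunk_size, max_fp, seqname,
                            respect_mask)
      tg
    })
    names(by_arch) <- vapply(archs, `[[`, "", "name")
    for (an in names(by_arch)) {
      tg <- by_arch[[an]]
      per_arch_targets[[an]] <<- per_arch_targets[[an]] + nrow(tg)
      per_arch_cov[[an]] <<- per_arch_cov[[an]] +
        if (nrow(tg)) sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(tg$start + 1L, tg$end)))) else 0L
    }
    all_tg <- do.call(rbind, lapply(by_arch, function(t) t[c("start", "end")]))
    if (nrow(all_tg)) {
      ir <- IRanges::reduce(IRanges::IRanges(all_tg$start + 1L, all_tg$end))
      cov <- sum(IRanges::width(ir))
      gaps <- IRanges::gaps(ir, start = 1L, end = n)
    } else {
      cov <- 0L
      gaps <- IRanges::IRanges(1L, n)
    }
    total_bp <<- total_bp + n
    covered_bp <<- covered_bp + cov
    if (length(gaps)) {
      devoid[[length(devoid) + 1L]] <<- data.frame(
        chrom = seqname,
        start = IRanges::start(gaps) - 1L,
        end = IRanges::end(gaps),
        length = IRanges::width(gaps),
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(sequences)) scan_one(names(sequences)[i], sequences[[i]])

  devoid <- if (length(devoid)) do.call(rbind, devoid) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               length = integer(0))
  rownames(devoid) <- NULL
  structure(list(
    total_bp = total_bp,
    covered_bp = covered_bp,
    coverage_fraction = if (total_bp > 0) covered_bp / total_bp else NA_real_,
    devoid_regions = devoid,
    per_arch = data.frame(arch = names(per_arch_targets),
                          n_targets = unname(per_arch_targets),
                          covered_bp = unname(per_arch_cov),
                          stringsAsFactors = FALSE)
  ), class = "coverage_report")
}

# windowed target enumeration: scan [w, w + chunk + overlap) windows and
# de-duplicate targets found in the overlap
chunked_targets <- function(seq, arch, geom, chunk_size, overlap, chrom,
                            respect_mask) {
  n <- nchar(seq)
  if (!is.finite(chunk_size) || n <= chunk_size + overlap) {
    return(find_paired_targets(seq, arch, geom, chrom, respect_mask))
  }
  starts <- seq(0L, n - 1L, by = chunk_size)
  pieces <- lapply(starts, function(w) {
    sub <- substring(seq, w + 1L, min(n, w + chunk_size + overlap))
    tg <- find_paired_targets(sub, arch, geom, chrom, respect_mask)
    if (nrow(tg)) {
      for (col in c("start", "end", "left_start", "right_start",
                    "spacer_start", "t0_pos")) {
        if (col %in% names(tg)) tg[[col]] <- tg[[col]] + w
      }
    }
    tg
  })
  tg <- do.call(rbind, pieces)
  tg <- tg[!duplicated(tg[c("start", "end", "spacer_len", "bound_strand")]), ,
           drop = FALSE]
  tg <- tg[order(tg$start, tg$spacer_len), , drop = FALSE]
  rownames(tg) <- NULL
  tg
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage report: %d / %d bp covered (%.4f%%), %d devoid region(s)>\n",
              x$covered_bp, x$total_bp, 100 * x$coverage_fraction,
              nrow(x$devoid_regions)))
  if (nrow(x$per_arch)) {
    print(x$per_arch, row.names = FALSE)
  }
  invisible(x)
}
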