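#' Locus specification for indel analysis
#'
#' Binds an amplicon reference to its paired-target annotation: where the
#' two binding-site footprints sit, the spacer interval between them and
#' the architecture, which fixes the predicted cut centre.
#'
#' @param ref Amplicon reference sequence.
#' @param arch A [architecture()] object.
#' @param spacer_start 0-based reference coordinate of the first spacer base.
#' @param spacer_len Spacer length s in bp.
#' @param footprint_start,footprint_end Full-target footprint (0-based
#'   half-open); defaults assume binding sites of an
#'   [array_geometry()] footprint on each side of the spacer.
#' @param geom Array geometry used for the default footprint.
#' @param bound_strand Strand the left (tail) scaffold binds; spacer-relative
#'   coordinates run 5'->3' along this strand.
#' @return An object of class `locus_spec`.
#' @examples
#' ref <- strrep("ACGT", 40)
#' locus_spec(ref, architecture("TtH"), spacer_start = 60, spacer_len = 20)
#' @export
locus_spec <- function(ref, arch, spacer_start, spacer_len,
                       footprint_start = NULL, footprint_end = NULL,
                       geom = array_geometry(), bound_strand = "+") {
  stopifnot(inherits(arch, "talen_architecture"),
            spacer_start >= 0, spacer_len >= 1,
            spacer_start + spacer_len <= nchar(ref))
  if (is.null(footprint_start)) footprint_start <- spacer_start - geom$footprint
  if (is.null(footprint_end)) footprint_end <- spacer_start + spacer_len + geom$footprint
  footprint_start <- max(0L, as.integer(footprint_start))
  footprint_end <- min(nchar(ref), as.integer(footprint_end))
  structure(list(ref = toupper(ref), arch = arch,
                 spacer_start = as.integer(spacer_start),
                 spacer_len = as.integer(spacer_len),
                 footprint_start = footprint_start,
                 footprint_end = footprint_end,
                 bound_strand = bound_strand),
            class = "locus_spec")
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<%s locus: %d bp amplicon, spacer [%d,%d) (s=%d), footprint [%d,%d)>\n",
              x$arch$name, nchar(x$ref), x$spacer_start,
              x$spacer_start + x$spacer_len, x$spacer_len,
              x$footprint_start, x$footprint_end))
  invisible(x)
}

#' Classify aligned reads into WT / insertion / deletion events
#'
#' Indels intersecting the analysis window (target footprint plus a margin;
#' indels entirely outside are regarded as sequencing artefacts and
#' ignored) are called per read. A read with no indel in the window is WT
#' (substitutions alone do not count as events); a read with at least one
#' insertion and at least one deletion is MIXED.
#'
#' @param alignments A [align_reads()] result.
#' @param locus A [locus_spec()].
#' @param margin Window margin in bp around the footprint (default 30).
#' @return data.frame of class `read_classifications`: `read_id`, `class`
#'   (`WT`/`INS`/`DEL`/`MIXED`), `n_ins`, `n_del`, plus attributes
#'   `deletions` (data.frame `read_id`, `start`, `end`, `length`, `center` —
#'   spacer-relative deletion centre) and `insertions` (`read_id`, `pos`,
#'   `len`).
#' @export
classify_reads <- function(alignments, locus, margin = 30L) {
  stopifnot(inherits(alignments, "talen_alignments"),
            inherits(locus, "locus_spec"))
  win_start <- max(0L, locus$footprint_start - margin)
  win_end <- min(nchar(locus$ref), locus$footprint_end + margin)
  ref_chars <- strsplit(locus$ref, "", fixed = TRUE)[[1L]]
  n_reads <- length(alignments$indels)
  cls_v <- character(n_reads)
  nin_v <- ndel_v <- integer(n_reads)
  del_rows <- list()
  ins_rows <- list()
  orient <- if (identical(locus$bound_strand, "-")) -1 else 1
  for (i in seq_len(n_reads)) {
    id <- alignments$read_id[i]
    ind <- alignments$indels[[i]]
    d <- ind$deletions
    d <- d[d$end > win_start & d$start < win_end, , drop = FALSE]
    inx <- ind$insertions
    inx <- inx[inx$pos >= win_start & inx$pos <= win_end, , drop = FALSE]
    cls_v[i] <- if (nrow(d) && nrow(inx)) "MIXED"
                else if (nrow(d)) "DEL"
                else if (nrow(inx)) "INS"
                else "WT"
    nin_v[i] <- nrow(inx)
    ndel_v[i] <- nrow(d)
    if (nrow(d)) {
      # centre of the deletion's equivalence class: left-normalised
      # coordinates are deterministic but sit at the left edge of the
      # micro-homology ambiguity range, so average over the class
      rext <- mapply(deletion_right_ext, d$start, d$end,
                     MoreArgs = list(rc = ref_chars))
      del_rows[[length(del_rows) + 1L]] <- data.frame(
        read_id = id, start = d$start, end = d$end, length = d$end - d$start,
        center = deletion_center(d, locus) + orient * rext / 2,
        stringsAsFactors = FALSE)
    }
    if (nrow(inx)) {
      ins_rows[[length(ins_rows) + 1L]] <- data.frame(
        read_id = id, pos = inx$pos, len = inx$len, stringsAsFactors = FALSE)
    }
  }
  out <- data.frame(read_id = alignments$read_id, class = cls_v,
                    n_ins = nin_v, n_del = ndel_v, stringsAsFactors = FALSE)
  attr(out, "deletions") <- if (length(del_rows)) do.call(rbind, del_rows) else
    data.frame(read_id = character(0), start = integer(0), end = integer(0),
               length = integer(0), center = numeric(0),
               stringsAsFactors = FALSE)
  attr(out, "insertions") <- if (length(ins_rows)) do.call(rbind, ins_rows) else
    data.frame(read_id = character(0), pos = integer(0), len = integer(0),
               stringsAsFactors = FALSE)
  attr(out, "n_discarded") <- alignments$n_discarded
  class(out) <- c("read_classifications", "data.frame")
  out
}

#' Spacer-relative deletion centre
#'
#' The centre of a deletion is the midpoint of the deleted reference
#' interval expressed in spacer-relative coordinates: coordinate 0 is the
#' spacer-centre base of [spacer_center()], and the axis runs 5'->3' along
#' the bound strand.
#'
#' @param deletions data.frame with 0-based half-open `start`, `end`
#'   reference columns (or a single interval as a length-2 vector).
#' @param locus A [locus_spec()].
#' @return Numeric vector of centres c, one per deletion.
#' @examples
#' loc <- locus_spec(strrep("ACGT", 30), architecture("TtT"),
#'                   spacer_start = 40, spacer_len = 15)
#' # deletion covering spacer bases 4-11 (1-based)
#' deletion_center(data.frame(start = 43, end = 51), loc)
#' @export
deletion_center <- function(deletions, locus) {
  stopifnot(inherits(locus, "locus_spec"))
  if (is.numeric(deletions) && length(deletions) == 2L) {
    deletions <- data.frame(start = deletions[1L], end = deletions[2L])
  }
  # midpoint in 1-based spacer coordinates, then relative to the centre base
  first <- deletions$start - locus$spacer_start + 1
  last <- deletions$end - locus$spacer_start
  mid <- (first + last) / 2
  c_fwd <- mid - spacer_center(locus$spacer_len)
  if (identical(locus$bound_strand, "-")) -c_fwd else c_fwd
}

#' Mutagenesis summary (event accounting)
#'
#' Per-locus accounting in the deep-sequencing table convention: total
#' events = reads - WT; a MIXED read (>=1 insertion and >=1 deletion)
#' counts once in the total and once in each of the insertion and deletion
#' tallies, so insertions + deletions can exceed total events.
#'
#' @param reads Total read count.
#' @param wt WT read count.
#' @param n_ins,n_del Reads carrying at least one insertion / deletion.
#' @return Object of class `mutagenesis_summary` with fields `reads`, `wt`,
#'   `total_events`, `n_ins`, `n_del`, `percent_events` (full precision) and
#'   `percent_printed` (table-style formatting).
#' @examples
#' mutagenesis_summary(reads = 5276, wt = 4817, n_ins = 134, n_del = 330)
#' @export
mutagenesis_summary <- function(reads, wt, n_ins = NA_integer_,
                                n_del = NA_integer_) {
  stopifnot(reads >= 0, wt >= 0, wt <= reads)
  if (reads == 0) {
    stop("percent undefined: zero reads", call. = FALSE)
  }
  total <- reads - wt
  pct <- 100 * total / reads
  structure(list(reads = reads, wt = wt, total_events = total,
                 n_ins = n_ins, n_del = n_del, percent_events = pct,
                 percent_printed = format_percent(pct)),
            class = "mutagenesis_summary")
}

#' Summarise read classifications
#'
#' @param classifications A [classify_reads()] result.
#' @return A [mutagenesis_summary()].
#' @export
summarize_classifications <- function(classifications) {
  stopifnot(inherits(classifications, "read_classifications"))
  mutagenesis_summary(
    reads = nrow(classifications),
    wt = sum(classifications$class == "WT"),
    n_ins = sum(classifications$class %in% c("INS", "MIXED")),
    n_del = sum(classifications$class %in% c("DEL", "MIXED")))
}

#' @export
print.mutagenesis_summary <- function(x, ...) {
  cat(sprintf("<mutagenesis: %s%% events (%d/%d reads; %s ins, %s del, %d wt)>\n",
              x$percent_printed, x$total_events, x$reads,
              format(x$n_ins), format(x$n_del), x$wt))
  invisible(x)
}

#' Table-style percentage formatter
#'
#' Percentages at or above 1 are printed with one decimal; below 1 with two
#' significant digits; zero prints as "0". All computation elsewhere uses
#' full precision — this formatter is presentation only.
#'
#' @param p Percentage value(s).
#' @return Character vector.
#' @examples
#' format_percent(c(8.7003, 0.0326, 0))
#' @export
format_percent <- function(p) {
  vapply(p, function(x) {
    if (x == 0) "0"
    else if (x >= 1) sprintf("%.1f", x)
    else format(signif(x, 2), scientific = FALSE)
  }, character(1L))
}
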