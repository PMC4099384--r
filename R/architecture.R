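#' TALE-FokI scaffold
#'
#' A scaffold is one monomer of a paired nuclease: a TALE DNA-binding domain
#' fused to the FokI catalytic domain either at the TALE C-terminus
#' (`TALE_FOKI`, the classical "tail" fusion) or at the TALE N-terminus
#' (`FOKI_TALE`, the "head" fusion). Each scaffold carries a cleavage offset:
#' the distance in bp from the spacer-proximal edge of its binding site to
#' the expected cut centre. Defaults (7.5 bp for TALE_FOKI, 12.5 bp for
#' FOKI_TALE) are the unique half-integer pair under the additive model that
#' reproduces optimal spacers of 15, 20 and 25 bp for the TtT, TtH and HtH
#' pairings.
#'
#' @param kind `"TALE_FOKI"` or `"FOKI_TALE"`.
#' @param cleavage_offset Positive distance in bp (half-integers allowed)
#'   from the spacer-proximal edge of the binding site to the cut centre.
#' @return An object of class `talen_scaffold`.
#' @examples
#' scaffold("TALE_FOKI")
#' @export
scaffold <- function(kind = c("TALE_FOKI", "FOKI_TALE"), cleavage_offset = NULL) {
  kind <- match.arg(kind)
  if (is.null(cleavage_offset)) {
    cleavage_offset <- if (kind == "TALE_FOKI") 7.5 else 12.5
  }
  stopifnot(is.numeric(cleavage_offset), length(cleavage_offset) == 1L,
            cleavage_offset > 0)
  structure(list(kind = kind, cleavage_offset = cleavage_offset),
            class = "talen_scaffold")
}

#' @export
print.talen_scaffold <- function(x, ...) {
  cat(sprintf("<scaffold %s, cleavage offset %.1f bp>\n", x$kind,
              x$cleavage_offset))
  invisible(x)
}

#' Spacer-length windows
#'
#' The set of spacer lengths (bp between the two binding-site footprints)
#' over which a paired architecture is active, as one or more inclusive
#' integer ranges.
#'
#' @param ... Numeric vectors of length 2, each an inclusive `[min, max]`
#'   range with `min >= 1`; ranges must not overlap.
#' @return An object of class `spacer_windows`.
#' @examples
#' spacer_windows(c(18, 22), c(27, 33))
#' @export
spacer_windows <- function(...) {
  ranges <- list(...)
  stopifnot(length(ranges) >= 1L)
  ranges <- lapply(ranges, function(r) {
    stopifnot(is.numeric(r), length(r) == 2L, r[1] >= 1, r[2] >= r[1],
              r == round(r))
    as.integer(r)
  })
  ranges <- ranges[order(vapply(ranges, `[`, integer(1L), 1L))]
  lo <- vapply(ranges, `[`, integer(1L), 1L)
  hi <- vapply(ranges, `[`, integer(1L), 2L)
  if (length(ranges) > 1L && any(lo[-1L] <= hi[-length(hi)])) {
    stop("spacer windows must not overlap", call. = FALSE)
  }
  structure(list(ranges = ranges), class = "spacer_windows")
}

#' @export
print.spacer_windows <- function(x, ...) {
  cat("<spacer windows:",
      paste(vapply(x$ranges, function(r) paste0(r[1], "-", r[2]),
                   character(1L)), collapse = ", "), "bp>\n")
  invisible(x)
}

#' Expand spacer windows to the admissible spacer lengths
#'
#' @param windows A [spacer_windows()] object.
#' @return Sorted integer vector of every admissible spacer length.
#' @examples
#' spacer_lengths(spacer_windows(c(18, 22), c(27, 33)))
#' @export
spacer_lengths <- function(windows) {
  stopifnot(inherits(windows, "spacer_windows"))
  sort(unique(unlist(lapply(windows$ranges, function(r) seq(r[1], r[2])))))
}

#' Spacer-window presets
#'
#' Two presets ship with the package. `"results"` holds the activity windows
#' measured in the yeast cleavage assay (TtT 10-27, HtH 22-27, TtH 18-22 and
#' 27-33 bp). `"chr1-scan"` holds the narrower design windows used for
#' chromosome targetability estimates (TtT 10-16 and 20-25, TtH 17-23 and
#' 26-33 bp; HtH has no separate scan window and keeps its activity window).
#'
#' @param arch Architecture name: `"TtT"`, `"HtH"` or `"TtH"`.
#' @param preset `"results"` (default) or `"chr1-scan"`.
#' @return A [spacer_windows()] object.
#' @examples
#' windows_preset("TtH")
#' windows_preset("TtT", "chr1-scan")
#' @export
windows_preset <- function(arch = c("TtT", "HtH", "TtH"),
                           preset = c("results", "chr1-scan")) {
  arch <- match.arg(arch)
  preset <- match.arg(preset)
  if (preset == "results") {
    switch(arch,
           TtT = spacer_windows(c(10, 27)),
           HtH = spacer_windows(c(22, 27)),
           TtH = spacer_windows(c(18, 22), c(27, 33)))
  } else {
    switch(arch,
           TtT = spacer_windows(c(10, 16), c(20, 25)),
           HtH = spacer_windows(c(22, 27)),
           TtH = spacer_windows(c(17, 23), c(26, 33)))
  }
}

#' Paired-nuclease architecture
#'
#' An architecture is the geometry of a scaffold pair on DNA:
#' \describe{
#'   \item{TtT}{two `TALE_FOKI` scaffolds on opposite strands, T0s distal to
#'     the spacer ("tails" facing): the forward-strand footprint reads
#'     `T + seqL + spacer + revcomp(T + seqR)`.}
#'   \item{HtH}{two `FOKI_TALE` scaffolds on opposite strands, T0s adjacent
#'     to the spacer ("heads" facing): `revcomp(T + seqL) + spacer + T + seqR`.}
#'   \item{TtH}{one `TALE_FOKI` and one `FOKI_TALE` bound in tandem on the
#'     SAME strand: the bound strand reads `T + seqL + spacer + T + seqR`.
#'     Only this asymmetric geometry requires thymines on a single strand.}
#' }
#'
#' @param name `"TtT"`, `"HtH"` or `"TtH"`.
#' @param offsets Named numeric vector of per-kind cleavage offsets in bp,
#'   default `c(TALE_FOKI = 7.5, FOKI_TALE = 12.5)`.
#' @param windows A [spacer_windows()] object, or a preset name passed to
#'   [windows_preset()].
#' @return An object of class `talen_architecture` with fields `name`,
#'   `left_scaffold`, `right_scaffold` (left = 5' on the bound/forward
#'   strand) and `spacer_windows`.
#' @examples
#' architecture("TtH")
#' @export
architecture <- function(name = c("TtT", "HtH", "TtH"),
                         offsets = c(TALE_FOKI = 7.5, FOKI_TALE = 12.5),
                         windows = "results") {
  name <- match.arg(name)
  stopifnot(all(c("TALE_FOKI", "FOKI_TALE") %in% names(offsets)))
  if (is.character(windows)) windows <- windows_preset(name, windows)
  stopifnot(inherits(windows, "spacer_windows"))
  kinds <- switch(name,
                  TtT = c("TALE_FOKI", "TALE_FOKI"),
                  HtH = c("FOKI_TALE", "FOKI_TALE"),
                  TtH = c("TALE_FOKI", "FOKI_TALE"))
  structure(list(
    name = name,
    left_scaffold = scaffold(kinds[1L], unname(offsets[kinds[1L]])),
    right_scaffold = scaffold(kinds[2L], unname(offsets[kinds[2L]])),
    spacer_windows = windows
  ), class = "talen_architecture")
}

#' @export
print.talen_architecture <- function(x, ...) {
  cat(sprintf("<%s architecture: left %s (%.1f) / right %s (%.1f)>\n",
              x$name, x$left_scaffold$kind, x$left_scaffold$cleavage_offset,
              x$right_scaffold$kind, x$right_scaffold$cleavage_offset))
  print(x$spacer_windows)
  cat(sprintf("  predicted optimal spacer: %g bp\n",
              predicted_optimal_spacer(x)))
  invisible(x)
}

#' Predicted optimal spacer length
#'
#' Under the additive cleavage-offset model each scaffold positions the cut
#' at a fixed distance from the spacer-proximal edge of its binding site, so
#' the FokI dimer meets mid-way when the spacer equals the sum of the two
#' offsets. With the default offsets this gives 15 bp (TtT), 20 bp (TtH) and
#' 25 bp (HtH); the asymmetric TtH optimum sits exactly half-way between the
#' two symmetric ones.
#'
#' @param arch A [architecture()] object.
#' @return Predicted optimal spacer in bp.
#' @examples
#' predicted_optimal_spacer(architecture("TtH"))
#' @export
predicted_optimal_spacer <- function(arch) {
  stopifnot(inherits(arch, "talen_architecture"))
  arch$left_scaffold$cleavage_offset + arch$right_scaffold$cleavage_offset
}

#' Spacer centre convention
#'
#' Spacer bases are numbered 1..s along the bound strand; the centre is the
#' (s+1)/2-th base, i.e. base 8 for a 15-bp spacer and base 13 for a 25-bp
#' spacer (half-integer for even s). This base defines spacer-relative
#' coordinate 0 for deletion-centre statistics.
#'
#' @param s Spacer length in bp, `s >= 1`.
#' @return The 1-based spacer coordinate of the centre (possibly .5).
#' @examples
#' spacer_center(15)
#' spacer_center(25)
#' @export
spacer_center <- function(s) {
  stopifnot(is.numeric(s), all(s >= 1))
  (s + 1) / 2
}

#' Predicted cut centre of a paired target
#'
#' The cut centre lies `left_offset` bp into the spacer from the
#' spacer-proximal edge of the left scaffold's site (1-based spacer
#' coordinate along the bound strand), and is also reported relative to the
#' spacer centre of [spacer_center()]. Symmetric architectures cut at the
#' middle of the spacer (relative offset -0.5 for odd s under the centre
#' convention); the asymmetric TtH cuts 2-3 bp left of the middle, toward
#' the TALE::FokI site.
#'
#' @param arch A [architecture()] object.
#' @param s Spacer length in bp.
#' @return List with `spacer_pos` (1-based position in the spacer along the
#'   bound strand) and `rel_offset` (bp relative to the spacer centre).
#' @examples
#' predicted_cut_center(architecture("TtH"), 20)
#' @export
predicted_cut_center <- function(arch, s) {
  stopifnot(inherits(arch, "talen_architecture"), is.numeric(s), s >= 1)
  pos <- arch$left_scaffold$cleavage_offset
  list(spacer_pos = pos, rel_offset = pos - spacer_center(s))
}

#' TALE array geometry
#'
#' A TALE array of `repeats` repeat units recognises one base per full
#' repeat; a trailing half-repeat reads one further base, so the standard
#' 15.5-repeat array recognises 16 bases and its footprint including the
#' obligatory 5' T0 spans 17 bp.
#'
#' @param repeats Repeat count; a fractional part of .5 denotes a trailing
#'   half-repeat. Default 15.5.
#' @return An object of class `array_geometry` with fields `repeats`,
#'   `L_rec` (recognised bases) and `footprint` (`L_rec + 1`, with T0).
#' @examples
#' array_geometry()
#' @export
array_geometry <- function(repeats = 15.5) {
  stopifnot(is.numeric(repeats), length(repeats) == 1L, repeats >= 1)
  frac <- repeats - floor(repeats)
  if (!frac %in% c(0, 0.5)) {
    stop("repeats must be an integer or end in .5", call. = FALSE)
  }
  L <- if (frac == 0.5) as.integer(floor(repeats) + 1) else as.integer(repeats)
  structure(list(repeats = repeats, L_rec = L, footprint = L + 1L),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<TALE array: %.1f repeats, %d recognised bases, %d bp footprint>\n",
              x$repeats, x$L_rec, x$footprint))
  invisible(x)
}
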