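# Thin format wrappers around Biostrings readers/writers plus BED/JSON
# output helpers. All interval outputs are 0-based half-open (BED).

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (!length(x)) stop("no records in FASTA file: ", path, call. = FALSE)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Format is inferred from the extension (`.fq`/`.fastq` vs anything else).
#'
#' @param path Reads file path.
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  if (!length(x)) stop("no reads in file: ", path, call. = FALSE)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Write reads to FASTQ with uniform Q40 qualities
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", names(reads)[i]), reads[[i]], "+",
                 strrep("I", nchar(reads[[i]]))), con)
  }
  invisible(path)
}

#' Write paired targets as BED6+
#'
#' Columns: chrom, footprint start/end, name = architecture, score = spacer
#' length, strand = left-site strand, then the per-site extra columns.
#'
#' @param targets Result of [find_paired_targets()].
#' @param path Output path.
#' @export
write_targets_bed <- function(targets, path) {
  bed <- data.frame(chrom = targets$chrom, start = targets$start,
                    end = targets$end, name = targets$arch,
                    score = targets$spacer_len, strand = targets$left_strand,
                    left_start = targets$left_start,
                    left_seq = targets$left_seq,
                    right_start = targets$right_start,
                    right_strand = targets$right_strand,
                    right_seq = targets$right_seq,
                    bound_strand = targets$bound_strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write target-devoid regions as BED
#'
#' @param report A [coverage_scan()] result.
#' @param path Output path.
#' @export
write_devoid_bed <- function(report, path) {
  stopifnot(inherits(report, "coverage_report"))
  d <- report$devoid_regions
  utils::write.table(d[c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialise a coverage report to JSON
#'
#' @param report A [coverage_scan()] result.
#' @param path Output path.
#' @export
write_coverage_json <- function(report, path) {
  stopifnot(inherits(report, "coverage_report"))
  jsonlite::write_json(list(
    total_bp = report$total_bp,
    covered_bp = report$covered_bp,
    coverage_fraction = report$coverage_fraction,
    n_devoid_regions = nrow(report$devoid_regions),
    devoid_bp = sum(report$devoid_regions$length),
    per_arch = report$per_arch
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialise a mutagenesis summary to JSON
#'
#' @param summary A [mutagenesis_summary()].
#' @param path Output path.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "mutagenesis_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Text report of the most frequent deletion alleles
#'
#' Renders the reference and the top recurrent deletion alleles as aligned
#' text, binding-site footprints uppercased and the rest lowercased, with
#' deleted bases shown as dashes.
#'
#' @param classifications A [classify_reads()] result.
#' @param locus A [locus_spec()].
#' @param top Number of distinct alleles to show.
#' @return Character vector of report lines (invisibly printed with `cat`).
#' @export
allele_report <- function(classifications, locus, top = 5L) {
  stopifnot(inherits(classifications, "read_classifications"),
            inherits(locus, "locus_spec"))
  d <- attr(classifications, "deletions")
  ref <- locus$ref
  fmt_ref <- casemask(ref, locus)
  lines <- c(sprintf("%-12s %s", "WT", fmt_ref))
  if (nrow(d)) {
    key <- paste(d$start, d$end, sep = "-")
    tab <- sort(table(key), decreasing = TRUE)
    tab <- utils::head(tab, top)
    for (k in names(tab)) {
      se <- as.integer(strsplit(k, "-", fixed = TRUE)[[1L]])
      allele <- paste0(substring(fmt_ref, 1L, se[1L]),
                       strrep("-", se[2L] - se[1L]),
                       substring(fmt_ref, se[2L] + 1L))
      lines <- c(lines, sprintf("%-12s %s", paste0("del x", tab[[k]]), allele))
    }
  }
  lines
}

# uppercase binding-site footprints, lowercase elsewhere
casemask <- function(ref, locus) {
  ch <- strsplit(tolower(ref), "", fixed = TRUE)[[1L]]
  sp0 <- locus$spacer_start
  sp1 <- locus$spacer_start + locus$spacer_len
  up <- c(seq(locus$footprint_start + 1L, sp0),
          seq(sp1 + 1L, locus$footprint_end))
  up <- up[up >= 1L & up <= length(ch)]
  ch[up] <- toupper(ch[up])
  paste(ch, collapse = "")
}
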