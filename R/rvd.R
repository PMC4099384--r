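#' Canonical RVD/nucleotide association code
#'
#' Returns the canonical repeat-variable di-residue (RVD) code used to build
#' TALE arrays: NI reads A, HD reads C, NN reads G and NG reads T. The code is
#' bijective over the four unambiguous bases; ambiguous bases (N, IUPAC
#' degenerates) have no mapping.
#'
#' @return A named character vector mapping base (A/C/G/T) to di-residue.
#' @examples
#' rvd_code()
#' @export
rvd_code <- function() {
  c(A = "NI", C = "HD", G = "NN", T = "NG")
}

#' Translate a DNA sequence into an RVD array
#'
#' Applies an RVD code base-by-base, producing the di-residue array a TALE
#' must carry to recognise `seq` (T0 excluded: the array covers only the
#' recognised bases downstream of the obligatory 5' thymine).
#'
#' @param seq A DNA string containing only A/C/G/T (case-insensitive).
#' @param code Named base-to-di-residue map, by default [rvd_code()].
#' @return Character vector of di-residues, one per base of `seq`.
#' @examples
#' rvd_for_sequence("ATATAAACCTAACCCTCT")
#' @seealso [sequence_for_rvds()] for the inverse mapping.
#' @export
rvd_for_sequence <- function(seq, code = rvd_code()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) return(character(0))
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!bases %in% names(code))
  if (length(bad)) {
    stop("invalid or ambiguous base '", bases[bad[1L]], "' at position ",
         bad[1L], call. = FALSE)
  }
  unname(code[bases])
}

#' Back-translate an RVD array into its recognised DNA sequence
#'
#' Inverse of [rvd_for_sequence()] under a bijective code.
#'
#' @param rvds Character vector of di-residues (e.g. `c("NI","NG")`).
#' @param code Named base-to-di-residue map, by default [rvd_code()].
#' @return A DNA string such that `rvd_for_sequence(x)` returns `rvds`.
#' @examples
#' sequence_for_rvds(c("NG"))
#' @export
sequence_for_rvds <- function(rvds, code = rvd_code()) {
  if (length(rvds) == 0L) return("")
  inv <- stats::setNames(names(code), code)
  bad <- which(!rvds %in% names(inv))
  if (length(bad)) {
    stop("unknown di-residue '", rvds[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  }
  paste(inv[rvds], collapse = "")
}

# reverse complement for plain character vectors; ambiguous bases pass
# through via Biostrings' IUPAC handling
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
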