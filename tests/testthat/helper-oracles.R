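# Independent oracles used by the unit and acceptance tests. Everything in
# this file is implemented from first principles (plain string operations,
# quadratic dynamic programming) and deliberately shares no code with the
# package internals it checks.

random_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# position-by-position site scan: T0 on the bound strand followed by L
# unambiguous bases
oracle_find_sites <- function(seq, strand, L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  hits <- list()
  for (i in seq_len(n) - 1L) {           # 0-based T0 candidate
    if (strand == "+") {
      if (i + L + 1L > n) next
      fp <- substring(seq, i + 1L, i + L + 1L)
      bound <- fp
    } else {
      if (i - L < 0L) next
      fp <- substring(seq, i - L + 1L, i + 1L)
      bound <- rc_chr(fp)
    }
    if (grepl("[^ACGT]", fp)) next
    if (substring(bound, 1L, 1L) != "T") next
    hits[[length(hits) + 1L]] <- c(t0 = i)
  }
  vapply(hits, `[[`, numeric(1L), "t0")
}

# direct-definition enumeration of paired targets over every (position,
# spacer) combination; vectorised over positions for each spacer length
oracle_paired_targets <- function(seq, arch_name, L, spacers) {
  seq <- toupper(seq)
  n <- nchar(seq)
  f <- L + 1L
  out <- list()
  for (s in spacers) {
    amax <- n - (2L * f + s)
    if (amax < 0L) next
    a <- 0L:amax
    b <- a + f + s
    sub1 <- substring(seq, a + 1L, a + f)
    sub2 <- substring(seq, b + 1L, b + f)
    clean <- !grepl("[^ACGT]", sub1) & !grepl("[^ACGT]", sub2)
    first1 <- substring(sub1, 1L, 1L); last1 <- substring(sub1, f, f)
    first2 <- substring(sub2, 1L, 1L); last2 <- substring(sub2, f, f)
    emit <- function(keep, strand) {
      if (!any(keep)) return()
      out[[length(out) + 1L]] <<- data.frame(start = a[keep],
                                             end = b[keep] + f,
                                             spacer_len = s,
                                             bound_strand = strand)
    }
    if (arch_name == "TtT") {
      emit(clean & first1 == "T" & last2 == "A", "+")
    } else if (arch_name == "HtH") {
      emit(clean & last1 == "A" & first2 == "T", "+")
    } else {
      # a footprint can host a same-strand pair on either strand
      emit(clean & first1 == "T" & first2 == "T", "+")
      emit(clean & last1 == "A" & last2 == "A", "-")
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      spacer_len = integer(0), bound_strand = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$spacer_len, res$bound_strand), , drop = FALSE]
}

# quadratic Gotoh global aligner with affine gaps; returns indels in
# reference coordinates (0-based half-open deletions; insertions anchored
# before `pos`)
oracle_align_indels <- function(read, ref, match = 2, mismatch = -4,
                                go = 10, ge = 1) {
  a <- strsplit(read, "", fixed = TRUE)[[1L]]
  b <- strsplit(ref, "", fixed = TRUE)[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in read (deletion)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in ref (insertion)
  M[1L, 1L] <- 0
  for (j in 2L:(m + 1L)) X[1L, j] <- -go - ge * (j - 1L)
  for (i in 2L:(n + 1L)) Y[i, 1L] <- -go - ge * (i - 1L)
  for (i in 2L:(n + 1L)) {
    ai <- a[i - 1L]
    for (j in 2L:(m + 1L)) {
      s <- if (ai == b[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i, j - 1L] - go - ge, X[i, j - 1L] - ge,
                     Y[i, j - 1L] - go - ge)
      Y[i, j] <- max(M[i - 1L, j] - go - ge, Y[i - 1L, j] - ge,
                     X[i - 1L, j] - go - ge)
    }
  }
  i <- n + 1L; j <- m + 1L
  state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  dels <- list(); ins <- list()
  cur_del <- NULL; cur_ins <- NULL
  flush_del <- function() {
    if (!is.null(cur_del)) {
      dels[[length(dels) + 1L]] <<- cur_del
      cur_del <<- NULL
    }
  }
  flush_ins <- function() {
    if (!is.null(cur_ins)) {
      ins[[length(ins) + 1L]] <<- cur_ins
      cur_ins <<- NULL
    }
  }
  while (i > 1L || j > 1L) {
    if (state == "M") {
      flush_del(); flush_ins()
      s <- if (a[i - 1L] == b[j - 1L]) match else mismatch
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      state <- c("M", "X", "Y")[which(abs(prev + s - M[i, j]) < 1e-9)[1L]]
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      flush_ins()
      refpos <- j - 2L                  # 0-based ref index consumed
      if (is.null(cur_del)) cur_del <- c(refpos, refpos + 1L)
      else cur_del[1L] <- refpos
      cand <- c(M[i, j - 1L] - go - ge, X[i, j - 1L] - ge,
                Y[i, j - 1L] - go - ge)
      state <- c("M", "X", "Y")[which(abs(cand - X[i, j]) < 1e-9)[1L]]
      j <- j - 1L
    } else {
      flush_del()
      if (is.null(cur_ins)) cur_ins <- list(pos = j - 1L, seq = a[i - 1L])
      else cur_ins$seq <- paste0(a[i - 1L], cur_ins$seq)
      cand <- c(M[i - 1L, j] - go - ge, Y[i - 1L, j] - ge,
                X[i - 1L, j] - go - ge)
      state <- c("M", "Y", "X")[which(abs(cand - Y[i, j]) < 1e-9)[1L]]
      i <- i - 1L
    }
    if (i == 1L && j == 1L) break
    if (i == 1L && state == "M") state <- "X"
    if (j == 1L && state == "M") state <- "Y"
  }
  flush_del(); flush_ins()
  d <- if (length(dels)) {
    dd <- do.call(rbind, dels)
    data.frame(start = dd[, 1L], end = dd[, 2L])
  } else data.frame(start = integer(0), end = integer(0))
  ii <- if (length(ins)) {
    data.frame(pos = vapply(ins, `[[`, numeric(1L), "pos"),
               len = vapply(ins, function(x) nchar(x$seq), integer(1L)),
               seq = vapply(ins, `[[`, character(1L), "seq"),
               stringsAsFactors = FALSE)
  } else data.frame(pos = integer(0), len = integer(0), seq = character(0),
                    stringsAsFactors = FALSE)
  oracle_normalize(list(deletions = d, insertions = ii), ref)
}

# independent left-normalisation of indel placements
oracle_normalize <- function(indels, ref) {
  rc <- strsplit(ref, "", fixed = TRUE)[[1L]]
  d <- indels$deletions
  if (nrow(d)) {
    for (k in seq_len(nrow(d))) {
      while (d$start[k] > 0L && rc[d$start[k]] == rc[d$end[k]]) {
        d$start[k] <- d$start[k] - 1L
        d$end[k] <- d$end[k] - 1L
      }
    }
    d <- d[order(d$start), , drop = FALSE]
    rownames(d) <- NULL
  }
  ii <- indels$insertions
  if (nrow(ii)) {
    for (k in seq_len(nrow(ii))) {
      sq <- strsplit(ii$seq[k], "", fixed = TRUE)[[1L]]
      while (ii$pos[k] > 0L && rc[ii$pos[k]] == sq[length(sq)]) {
        sq <- c(sq[length(sq)], sq[-length(sq)])
        ii$pos[k] <- ii$pos[k] - 1L
      }
      ii$seq[k] <- paste(sq, collapse = "")
    }
    ii <- ii[order(ii$pos), , drop = FALSE]
    rownames(ii) <- NULL
  }
  list(deletions = d, insertions = ii)
}

# closed-form pooled-variance two-sample t statistic and two-sided p
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), df = nx + ny - 2))
}
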