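# Synthetic inputs: genomes with planted repeat expansions and amplicon
# read sets under a parametric NHEJ indel model. Everything is seeded and
# reproducible; a single seed fans out to independent per-component draws.

#' Generate a synthetic genome
#'
#' Random sequence under a base-composition model with optional planted
#' features (e.g. trinucleotide repeat expansions such as (CAG)50, whose
#' forward strand carries no thymine).
#'
#' @param length Genome length in bp.
#' @param base_probs Named probabilities for A/C/G/T; must sum to 1.
#' @param features List of planted features, each a list with `motif` (DNA
#'   string), `copies` (tandem copy number) and `pos` (0-based start).
#'   Features must fit inside the genome and must not overlap.
#' @param seed Optional integer seed.
#' @param name Sequence name.
#' @return Named character vector of length 1 (a FASTA-ready record).
#' @examples
#' make_genome(300, seed = 1,
#'             features = list(list(motif = "CAG", copies = 50, pos = 50)))
#' @export
make_genome <- function(length, base_probs = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                        features = list(), seed = NULL, name = "synthetic") {
  stopifnot(length >= 1, all(names(base_probs) %in% c("A", "C", "G", "T")),
            abs(sum(base_probs) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  bases <- sample(names(base_probs), length, replace = TRUE,
                  prob = unname(base_probs))
  iv <- lapply(features, function(f) {
    stopifnot(!is.null(f$motif), !is.null(f$copies), !is.null(f$pos))
    w <- nchar(f$motif) * f$copies
    if (f$pos < 0 || f$pos + w > length) {
      stop("planted feature out of bounds", call. = FALSE)
    }
    c(f$pos, f$pos + w)
  })
  if (length(iv) > 1L) {
    ord <- order(vapply(iv, `[`, numeric(1L), 1L))
    iv_s <- iv[ord]
    for (i in seq_len(length(iv_s) - 1L)) {
      if (iv_s[[i]][2L] > iv_s[[i + 1L]][1L]) {
        stop("planted features overlap", call. = FALSE)
      }
    }
  }
  for (i in seq_along(features)) {
    f <- features[[i]]
    rep_seq <- strsplit(strrep(toupper(f$motif), f$copies), "", fixed = TRUE)[[1L]]
    bases[(iv[[i]][1L] + 1L):iv[[i]][2L]] <- rep_seq
  }
  stats::setNames(paste(bases, collapse = ""), name)
}

#' NHEJ indel model
#'
#' Parametric model of nuclease-induced repair outcomes at one locus: a
#' read carries an event with probability `event_rate`; given an event it
#' is an insertion with probability `p_ins`, otherwise a deletion.
#' Deletion lengths are geometric (support >= 1) with mean `del_len_mean`;
#' deletion centres are normal around `center_mean` (spacer-relative bp; by
#' default the locus's predicted cut offset) with sd `center_sd`.
#' Insertions take geometric lengths with mean `ins_len_mean` and sit at
#' the base boundary nearest the sampled centre. An optional uniform
#' substitution error rate can be layered on.
#'
#' @param event_rate Probability a read carries an event, in \[0,1\].
#' @param p_ins Probability an event is an insertion (default 0.3).
#' @param del_len_mean Mean deletion length in bp (default 8).
#' @param ins_len_mean Mean insertion length in bp (default 3).
#' @param center_mean Mean spacer-relative centre; `NULL` = locus cut offset.
#' @param center_sd SD of the centre distribution in bp (default 3).
#' @param sub_rate Per-base substitution error rate (default 0).
#' @return Object of class `indel_model`.
#' @examples
#' indel_model(event_rate = 0.087)
#' @export
indel_model <- function(event_rate, p_ins = 0.3, del_len_mean = 8,
                        ins_len_mean = 3, center_mean = NULL, center_sd = 3,
                        sub_rate = 0) {
  stopifnot(event_rate >= 0, event_rate <= 1, p_ins >= 0, p_ins <= 1,
            del_len_mean >= 1, ins_len_mean >= 1, center_sd >= 0,
            sub_rate >= 0, sub_rate <= 1)
  structure(list(event_rate = event_rate, p_ins = p_ins,
                 del_len_mean = del_len_mean, ins_len_mean = ins_len_mean,
                 center_mean = center_mean, center_sd = center_sd,
                 sub_rate = sub_rate),
            class = "indel_model")
}

#' Simulate amplicon reads under an NHEJ indel model
#'
#' Draws `n` full-length amplicon reads from a locus. Deletions are placed
#' symmetric about a normal-sampled spacer-relative centre and clipped to
#' integer endpoints with a seeded floor/ceil split, so the analyser's
#' midpoint definition recovers the sampled centre without bias. Deletions
#' that would leave the amplicon are resampled (and counted).
#'
#' @param locus A [locus_spec()].
#' @param model An [indel_model()].
#' @param n Number of reads.
#' @param seed Optional integer seed.
#' @return List of class `simulated_reads`: `reads` (named character
#'   vector), `truth` (data.frame `read_id`, `class`, `del_start`,
#'   `del_len`, `del_start_norm` — the left-normalised equivalent the
#'   analyser reports —, `center_drawn`, `center_real` — the equivalence
#'   -class midpoint the analyser computes —, `ins_pos`, `ins_pos_norm`,
#'   `ins_len`), and `n_resampled`.
#' @examples
#' loc <- locus_spec(strrep("ACGT", 40), architecture("TtH"),
#'                   spacer_start = 70, spacer_len = 20)
#' simulate_reads(loc, indel_model(0.1), n = 10, seed = 1)
#' @export
simulate_reads <- function(locus, model, n, seed = NULL) {
  stopifnot(inherits(locus, "locus_spec"), inherits(model, "indel_model"),
            n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ref <- locus$ref
  nref <- nchar(ref)
  center_mean <- if (is.null(model$center_mean)) {
    predicted_cut_center(locus$arch, locus$spacer_len)$rel_offset
  } else model$center_mean
  # reference coordinate (0-based, continuous) of spacer-relative 0
  center_ref0 <- locus$spacer_start + spacer_center(locus$spacer_len) - 1
  orient <- if (identical(locus$bound_strand, "-")) -1 else 1
  p_del_len <- 1 / model$del_len_mean
  p_ins_len <- 1 / model$ins_len_mean
  reads <- character(n)
  truth <- data.frame(read_id = paste0("read", seq_len(n)),
                      class = "WT", del_start = NA_integer_,
                      del_len = NA_integer_, del_start_norm = NA_integer_,
                      center_drawn = NA_real_, center_real = NA_real_,
                      ins_pos = NA_integer_, ins_pos_norm = NA_integer_,
                      ins_len = NA_integer_, stringsAsFactors = FALSE)
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  n_resampled <- 0L
  for (i in seq_len(n)) {
    if (stats::runif(1) >= model$event_rate) {
      reads[i] <- ref
    } else if (stats::runif(1) < model$p_ins) {
      c_draw <- stats::rnorm(1, center_mean, model$center_sd)
      len <- stats::rgeom(1, p_ins_len) + 1L
      # boundary nearest the sampled centre, clamped inside the amplicon
      pos <- round(center_ref0 + orient * c_draw + 0.5)
      pos <- max(1L, min(nref - 1L, as.integer(pos)))
      ins_seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
      reads[i] <- paste0(substring(ref, 1L, pos),
                         ins_seq, substring(ref, pos + 1L, nref))
      truth$class[i] <- "INS"
      truth$center_drawn[i] <- c_draw
      truth$ins_pos[i] <- pos
      truth$ins_len[i] <- len
      # left-normalised anchor of the same insertion
      p <- pos
      sq <- strsplit(ins_seq, "", fixed = TRUE)[[1L]]
      while (p > 0L && ref_chars[p] == sq[length(sq)]) {
        sq <- c(sq[length(sq)], sq[-length(sq)])
        p <- p - 1L
      }
      truth$ins_pos_norm[i] <- p
    } else {
      repeat {
        c_draw <- stats::rnorm(1, center_mean, model$center_sd)
        len <- stats::rgeom(1, p_del_len) + 1L
        # symmetric about the centre, integer clip by unbiased rounding
        mid_ref <- center_ref0 + orient * c_draw   # 0-based base-index space
        u <- mid_ref - (len - 1) / 2               # ideal 0-based start
        st <- floor(u) + (stats::runif(1) < (u - floor(u)))
        st <- as.integer(st)
        if (st >= 1L && st + len <= nref) break
        n_resampled <- n_resampled + 1L
      }
      reads[i] <- paste0(substring(ref, 1L, st), substring(ref, st + len + 1L, nref))
      truth$class[i] <- "DEL"
      truth$del_start[i] <- st
      truth$del_len[i] <- len
      truth$center_drawn[i] <- c_draw
      # the analyser reports the left-normalised equivalent interval and the
      # midpoint of the micro-homology equivalence class; record the same
      s0 <- st; e0 <- st + len
      while (s0 > 0L && ref_chars[s0] == ref_chars[e0]) {
        s0 <- s0 - 1L; e0 <- e0 - 1L
      }
      k <- 0L
      while (e0 + k < nref && ref_chars[s0 + k + 1L] == ref_chars[e0 + k + 1L]) {
        k <- k + 1L
      }
      truth$del_start_norm[i] <- s0
      truth$center_real[i] <- orient *
        ((s0 + 1 + s0 + len) / 2 + k / 2 - locus$spacer_start -
           spacer_center(locus$spacer_len))
    }
    if (model$sub_rate > 0) {
      rchars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
      hit <- which(stats::runif(length(rchars)) < model$sub_rate)
      for (h in hit) {
        rchars[h] <- sample(setdiff(c("A", "C", "G", "T"), rchars[h]), 1L)
      }
      reads[i] <- paste(rchars, collapse = "")
    }
  }
  names(reads) <- truth$read_id
  structure(list(reads = reads, truth = truth, n_resampled = n_resampled,
                 locus = locus, model = model),
            class = "simulated_reads")
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("<%d simulated read(s): %d WT, %d DEL, %d INS (%d resampled)>\n",
              nrow(x$truth), sum(x$truth$class == "WT"),
              sum(x$truth$class == "DEL"), sum(x$truth$class == "INS"),
              x$n_resampled))
  invisible(x)
}

#' Build a synthetic amplicon carrying one valid paired target
#'
#' Constructs an amplicon with random flanks around a freshly designed
#' paired target of the requested architecture and spacer length, returning
#' the matching [locus_spec()]. Useful for end-to-end simulations.
#'
#' @param arch A [architecture()] object.
#' @param s Spacer length in bp; default the architecture's predicted
#'   optimum (rounded if fractional).
#' @param geom An [array_geometry()].
#' @param flank Flank length in bp on each side (default 100).
#' @param seed Optional integer seed.
#' @return A [locus_spec()] whose `ref` contains the designed target; the
#'   recognised sequences are in attributes `left_seq` / `right_seq`.
#' @examples
#' simulate_locus(architecture("TtH"), seed = 1)
#' @export
simulate_locus <- function(arch, s = NULL, geom = array_geometry(),
                           flank = 100L, seed = NULL) {
  stopifnot(inherits(arch, "talen_architecture"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(s)) s <- as.integer(round(predicted_optimal_spacer(arch)))
  L <- geom$L_rec
  rand <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                            collapse = "")
  rec_l <- rand(L)
  rec_r <- rand(L)
  spacer <- rand(s)
  core <- switch(arch$name,
                 TtT = paste0("T", rec_l, spacer, revcomp(paste0("T", rec_r))),
                 HtH = paste0(revcomp(paste0("T", rec_l)), spacer, "T", rec_r),
                 TtH = paste0("T", rec_l, spacer, "T", rec_r))
  ref <- paste0(rand(flank), core, rand(flank))
  loc <- locus_spec(ref, arch, spacer_start = flank + L + 1L, spacer_len = s,
                    footprint_start = flank,
                    footprint_end = flank + nchar(core), geom = geom)
  attr(loc, "left_seq") <- paste0("T", rec_l)
  attr(loc, "right_seq") <- paste0("T", rec_r)
  loc
}
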