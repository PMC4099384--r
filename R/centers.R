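#' Deletion-size distribution
#'
#' Relative frequency of deletion lengths per locus, with the multi-locus
#' mean and standard deviation per size bin. Loci with fewer than
#' `min_events` deletion events are excluded (matching the >= 20 events
#' inclusion rule used for the published size profiles).
#'
#' @param lengths_by_locus List of integer vectors, one per locus, of
#'   deletion lengths in bp (a single vector is treated as one locus).
#' @param breaks Right-closed bin edges passed to [cut()]; default 1-bp
#'   bins from 1 to `max_len` with a final open bin.
#' @param max_len Upper edge of the per-bp bins (default 50).
#' @param min_events Per-locus inclusion threshold (default 20).
#' @return data.frame of class `deletion_size_distribution` with columns
#'   `bin`, `mean_freq`, `sd_freq` and one `freq.<locus>` column per
#'   retained locus; per-locus frequencies each sum to 1.
#' @examples
#' deletion_size_distribution(list(a = rep(5, 25), b = c(rep(5, 20), rep(12, 5))))
#' @export
deletion_size_distribution <- function(lengths_by_locus, breaks = NULL,
                                       max_len = 50L, min_events = 20L) {
  if (is.numeric(lengths_by_locus)) lengths_by_locus <- list(lengths_by_locus)
  stopifnot(is.list(lengths_by_locus), length(lengths_by_locus) >= 1L)
  if (is.null(names(lengths_by_locus))) {
    names(lengths_by_locus) <- paste0("locus", seq_along(lengths_by_locus))
  }
  keep <- vapply(lengths_by_locus, length, integer(1L)) >= min_events
  if (!any(keep)) {
    stop("no locus reaches the ", min_events, "-event inclusion threshold",
         call. = FALSE)
  }
  lengths_by_locus <- lengths_by_locus[keep]
  if (is.null(breaks)) breaks <- c(seq(0L, max_len), Inf)
  labs <- c(as.character(seq_len(max_len)), paste0(">", max_len))
  freqs <- vapply(lengths_by_locus, function(x) {
    tab <- table(cut(x, breaks = breaks, labels = labs, right = TRUE))
    as.numeric(tab) / length(x)
  }, numeric(length(labs)))
  freqs <- matrix(freqs, nrow = length(labs),
                  dimnames = list(NULL, names(lengths_by_locus)))
  out <- data.frame(bin = labs,
                    mean_freq = rowMeans(freqs),
                    sd_freq = apply(freqs, 1L, stats::sd),
                    stringsAsFactors = FALSE)
  for (nm in colnames(freqs)) out[[paste0("freq.", nm)]] <- freqs[, nm]
  class(out) <- c("deletion_size_distribution", "data.frame")
  out
}

#' Deletion-centre statistics
#'
#' Sample mean and variance of spacer-relative deletion centres, plus the
#' matching unit-area Gaussian summary curve (the normal density with the
#' same mean and variance, which integrates to 1 by construction).
#'
#' @param centers Numeric vector of spacer-relative deletion centres (c),
#'   e.g. the `center` column of the `deletions` attribute of
#'   [classify_reads()]. Needs `n >= 2` for the variance.
#' @return Object of class `deletion_center_stats`: `n`, `mean`, `var`,
#'   `sd` and `curve` (a function of x giving the Gaussian summary density).
#' @examples
#' center_stats(c(-1, 1))
#' @export
center_stats <- function(centers) {
  centers <- centers[!is.na(centers)]
  n <- length(centers)
  if (n < 2L) {
    stop("need at least 2 deletion centres for a variance", call. = FALSE)
  }
  m <- mean(centers)
  v <- stats::var(centers)
  structure(list(n = n, mean = m, var = v, sd = sqrt(v),
                 curve = function(x) stats::dnorm(x, mean = m, sd = sqrt(v))),
            class = "deletion_center_stats")
}

#' @export
print.deletion_center_stats <- function(x, ...) {
  cat(sprintf("<deletion centres: n=%d, mean=%.3f, var=%.3f>\n",
              x$n, x$mean, x$var))
  invisible(x)
}

#' @export
plot.deletion_center_stats <- function(x, xlim = NULL, ...) {
  if (is.null(xlim)) xlim <- x$mean + c(-4, 4) * x$sd
  xs <- seq(xlim[1L], xlim[2L], length.out = 256L)
  plot(xs, x$curve(xs), type = "l",
       xlab = "deletion centre (bp from spacer centre)", ylab = "density",
       ...)
  graphics::abline(v = x$mean, lty = 2)
  invisible(x)
}

#' Compare deletion-centre locations between two groups
#'
#' Two-sample location test on spacer-relative deletion centres. The
#' default is the pooled-variance Student t-test; Welch's unequal-variance
#' form is available. Two-sided.
#'
#' @param a,b Numeric vectors of centres, each with `n >= 2`.
#' @param method `"student"` (pooled variance, default) or `"welch"`.
#' @return The `htest` object from [stats::t.test()].
#' @examples
#' compare_centers(rnorm(50, -3), rnorm(50, -0.5))
#' @export
compare_centers <- function(a, b, method = c("student", "welch")) {
  method <- match.arg(method)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate comparison: zero variance in both groups", call. = FALSE)
  }
  stats::t.test(a, b, var.equal = method == "student")
}
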