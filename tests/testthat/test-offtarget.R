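test_that("monomer matching requires the T0 and respects the mismatch cap", {
  set.seed(37)
  site <- paste0("T", random_dna(16))
  genome <- paste0(random_dna(200), site, random_dna(200))
  exact <- match_monomer(genome, site, k_max = 0)
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$start, 200L)
  expect_equal(exact$strand, "+")
  expect_equal(exact$mismatches, 0L)

  # plant a single-mismatch copy (recognised base mutated)
  chars <- strsplit(site, "", fixed = TRUE)[[1L]]
  chars[9] <- setdiff(c("A", "C", "G", "T"), chars[9])[1L]
  near <- paste(chars, collapse = "")
  genome2 <- paste0(genome, near, random_dna(50))
  expect_equal(nrow(match_monomer(genome2, site, k_max = 0)), 1L)
  hits1 <- match_monomer(genome2, site, k_max = 1)
  expect_equal(nrow(hits1), 2L)
  expect_equal(sort(hits1$mismatches), c(0L, 1L))

  # T0 -> C disqualifies regardless of k_max
  broken <- paste0("C", substring(site, 2))
  genome3 <- paste0(random_dna(100), broken, random_dna(100))
  expect_equal(nrow(match_monomer(genome3, site, k_max = 3)), 0L)
})

test_that("monomer matches are found on the reverse strand", {
  set.seed(41)
  site <- paste0("T", random_dna(16))
  genome <- paste0(random_dna(80), rc_chr(site), random_dna(80))
  hits <- match_monomer(genome, site, k_max = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 80L)
})

test_that("a genome holding only the on-target yields no off-targets", {
  set.seed(43)
  loc <- simulate_locus(architecture("TtH"), seed = 43)
  pair <- talen_pair(attr(loc, "left_seq"), attr(loc, "right_seq"))
  hits <- enumerate_offtargets(loc$ref, pair, k_max = 0)
  # the designed target itself is the single L+R hit
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pair_type, "L+R")
  expect_equal(hits$geometry, "TtH")
  expect_equal(hits$start, loc$footprint_start)
  none <- enumerate_offtargets(loc$ref, pair, k_max = 0,
                               exclude = data.frame(start = loc$footprint_start,
                                                    end = loc$footprint_end))
  expect_equal(nrow(none), 0L)
})

test_that("planted near-sites are recovered exactly", {
  set.seed(47)
  L <- talen_pair(paste0("T", random_dna(16)), paste0("T", random_dna(16)))
  mutate1 <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    i <- sample(2:length(ch), 1)
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  # three TtH-geometry near-pairs with admissible spacers
  plant <- function(s) paste0(mutate1(L$left$seq), random_dna(s), mutate1(L$right$seq))
  genome <- paste0(random_dna(15000), plant(18), random_dna(15000), plant(20),
                   random_dna(15000), plant(33), random_dna(5000))
  hits <- enumerate_offtargets(genome, L, k_max = 1, pair_types = "L+R")
  tth <- hits[hits$geometry == "TtH", ]
  expect_equal(nrow(tth), 3L)
  expect_equal(sort(tth$spacer_len), c(18L, 20L, 33L))
  expect_true(all(tth$m1_mismatches <= 1 & tth$m2_mismatches <= 1))
})

test_that("hit counts are monotone in k_max and window width", {
  set.seed(53)
  genome <- random_dna(30000)
  pair <- talen_pair(paste0("T", random_dna(16)), paste0("T", random_dna(16)))
  narrow <- list(TtT = spacer_windows(c(14, 16)), HtH = spacer_windows(c(24, 26)),
                 TtH = spacer_windows(c(19, 21)))
  wide <- list(TtT = spacer_windows(c(10, 27)), HtH = spacer_windows(c(22, 27)),
               TtH = spacer_windows(c(18, 22), c(27, 33)))
  counts <- sapply(0:2, function(k) {
    c(nrow(enumerate_offtargets(genome, pair, k, narrow)),
      nrow(enumerate_offtargets(genome, pair, k, wide)))
  })
  expect_true(all(diff(counts[1, ]) >= 0))   # k_max sweep, narrow windows
  expect_true(all(diff(counts[2, ]) >= 0))   # k_max sweep, wide windows
  expect_true(all(counts[2, ] >= counts[1, ]))   # window widening
})

test_that("expected count ratios track admissible spacer-length counts", {
  # with short monomers matches are plentiful and pairing is ~uniform over
  # admissible spacers, so counts scale with the number of spacer lengths
  set.seed(59)
  genome <- random_dna(200000)
  pair <- talen_pair(paste0("T", random_dna(2)), paste0("T", random_dna(2)))
  w10 <- list(TtH = spacer_windows(c(20, 29)))
  w5 <- list(TtH = spacer_windows(c(20, 24)))
  n10 <- nrow(enumerate_offtargets(genome, pair, 0, w10, pair_types = "L+R"))
  n5 <- nrow(enumerate_offtargets(genome, pair, 0, w5, pair_types = "L+R"))
  expect_gt(n5, 50)   # enough hits for a meaningful ratio
  expect_lt(abs(offtarget_ratio(n10, n5) - 2), 0.35)
})

test_that("fold ratios reproduce the spacer-count argument", {
  expect_equal(offtarget_ratio(25, 8), 3.125)
  expect_equal(offtarget_ratio(25, 16), 1.5625)
  expect_equal(offtarget_ratio(7, 7), 1)
  expect_error(offtarget_ratio(5, 0), "zero")
})

test_that("same-scaffold combinations are laid out in their forced geometry", {
  set.seed(61)
  left <- paste0("T", random_dna(16))
  # an L+L TtT-geometry locus: site plus its reverse complement at spacer 15
  genome <- paste0(random_dna(100), left, random_dna(15), rc_chr(left),
                   random_dna(100))
  hits <- enumerate_offtargets(genome, talen_pair(left, paste0("T", random_dna(16))),
                               k_max = 0)
  ll <- hits[hits$pair_type == "L+L", ]
  expect_equal(nrow(ll), 1L)
  expect_equal(ll$geometry, "TtT")
  expect_equal(ll$spacer_len, 15L)
})
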