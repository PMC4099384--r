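g3 <- array_geometry(2.5)   # 3 recognised bases, 4 bp footprint
win4 <- spacer_windows(c(4, 4))

test_that("single-site finder honours the T0 rule on both strands", {
  polyA <- strrep("A", 50)
  expect_equal(nrow(find_sites(polyA, "+", g3)), 0L)
  # minus strand of poly-A is poly-T: a site at every eligible position
  expect_gt(nrow(find_sites(polyA, "-", g3)), 0L)
  s <- find_sites("TACG", "+", g3)
  expect_equal(nrow(s), 1L)
  expect_equal(s$t0_pos, 0L)
  expect_equal(s$recognized, "ACG")
  expect_equal(s$end - s$start, 4L)
})

test_that("ambiguous bases never satisfy T0 and never match recognised bases", {
  expect_equal(nrow(find_sites("TANG", "+", g3)), 0L)
  expect_equal(nrow(find_sites("NACG", "+", g3)), 0L)
  # masked bases excluded only when asked
  expect_equal(nrow(find_sites("TAcG", "+", g3)), 1L)
  expect_equal(nrow(find_sites("TAcG", "+", g3, respect_mask = TRUE)), 0L)
})

test_that("site finder agrees with a brute-force position scan", {
  set.seed(7)
  for (rep in 1:5) {
    seq <- random_dna(1000)
    for (geom in list(g3, array_geometry(15.5))) {
      for (str in c("+", "-")) {
        got <- find_sites(seq, str, geom)
        expect_equal(got$t0_pos, unname(oracle_find_sites(seq, str, geom$L_rec)))
      }
    }
  }
})

test_that("toy paired targets are found in all three layouts", {
  tth <- find_paired_targets("TAAACCCCTGGG", architecture("TtH", windows = win4), g3)
  expect_equal(nrow(tth), 1L)
  expect_equal(tth$left_start, 0L)
  expect_equal(tth$right_start, 8L)
  expect_equal(tth$bound_strand, "+")
  expect_equal(tth$spacer_len, 4L)

  ttt <- find_paired_targets("TAAACCCCGGGA", architecture("TtT", windows = win4), g3)
  expect_equal(nrow(ttt), 1L)
  expect_equal(ttt$right_strand, "-")
  expect_equal(ttt$right_start + 4L - 1L, 11L)   # T0 is the reference A at 11

  hth <- find_paired_targets("GGGACCCCTAAA", architecture("HtH", windows = win4), g3)
  expect_equal(nrow(hth), 1L)
  expect_equal(hth$left_strand, "-")
  expect_equal(hth$right_strand, "+")
})

test_that("(CAG)50 repeats admit TtH but not TtT targets under defaults", {
  cag <- strrep("CAG", 50)
  expect_equal(nrow(find_paired_targets(cag, architecture("TtT"))), 0L)
  tth <- find_paired_targets(cag, architecture("TtH"))
  expect_gt(nrow(tth), 0L)
  expect_true(all(tth$bound_strand == "-"))   # the thymines sit on the CTG strand
})

test_that("paired-target scan matches exhaustive enumeration", {
  set.seed(11)
  for (rep in 1:20) {
    seq <- random_dna(sample(100:500, 1))
    for (nm in c("TtT", "HtH", "TtH")) {
      arch <- architecture(nm)
      got <- find_paired_targets(seq, arch)
      exp <- oracle_paired_targets(seq, nm, array_geometry()$L_rec,
                                   spacer_lengths(arch$spacer_windows))
      got <- got[order(got$start, got$spacer_len, got$bound_strand),
                 c("start", "end", "spacer_len", "bound_strand")]
      rownames(got) <- rownames(exp) <- NULL
      expect_equal(got, exp, info = paste(nm, "rep", rep))
    }
  }
})

test_that("reverse-complement symmetry of the target set", {
  set.seed(13)
  for (rep in 1:5) {
    seq <- random_dna(400)
    n <- nchar(seq)
    rcs <- rc_chr(seq)
    for (nm in c("TtT", "HtH", "TtH")) {
      arch <- architecture(nm)
      fwd <- find_paired_targets(seq, arch)
      rev <- find_paired_targets(rcs, arch)
      mirror <- data.frame(start = n - fwd$end, end = n - fwd$start,
                           spacer_len = fwd$spacer_len,
                           bound_strand = if (nm == "TtH")
                             chartr("+-", "-+", fwd$bound_strand)
                           else fwd$bound_strand)
      o <- function(d) {
        d <- d[order(d$start, d$spacer_len, d$bound_strand), ]
        rownames(d) <- NULL
        d
      }
      expect_equal(o(rev[names(mirror)]), o(mirror), info = nm)
    }
  }
})

test_that("targets are monotone in the spacer windows", {
  set.seed(17)
  seq <- random_dna(400)
  small <- find_paired_targets(seq, architecture("TtH", windows = spacer_windows(c(18, 20))))
  big <- find_paired_targets(seq, architecture("TtH", windows = spacer_windows(c(18, 22), c(27, 33))))
  key <- function(d) paste(d$start, d$end, d$spacer_len, d$bound_strand)
  expect_true(all(key(small) %in% key(big)))
  expect_gte(nrow(big), nrow(small))
})

test_that("palindromic self-pairs can be excluded", {
  # left and right recognised sequences identical by construction
  core <- paste0("TACG", strrep("C", 4), "TACG")
  all_pairs <- find_paired_targets(core, architecture("TtH", windows = win4), g3)
  expect_equal(nrow(all_pairs), 1L)
  none <- find_paired_targets(core, architecture("TtH", windows = win4), g3,
                              distinct_monomers = TRUE)
  expect_equal(nrow(none), 0L)
})
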