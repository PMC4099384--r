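make_test_locus <- function(arch = "TtT", s = 15, seed = 83) {
  simulate_locus(architecture(arch), s = s, flank = 60, seed = seed)
}

test_that("reads are classified into WT / INS / DEL / MIXED", {
  set.seed(89)
  loc <- make_test_locus()
  ref <- loc$ref
  sp <- loc$spacer_start
  wt <- ref
  del <- paste0(substring(ref, 1, sp + 3), substring(ref, sp + 9))
  ins <- paste0(substring(ref, 1, sp + 5), "TTT", substring(ref, sp + 6))
  mixed <- paste0(substring(ref, 1, sp - 30), substring(ref, sp - 25),
                  substring(ref, 1, 0))
  mixed <- paste0(substring(mixed, 1, sp - 10), "GG", substring(mixed, sp - 9))
  subs_only <- ref
  substring(subs_only, sp + 2, sp + 2) <- setdiff(c("A", "C", "G", "T"),
    substring(ref, sp + 2, sp + 2))[1]
  cls <- classify_reads(
    align_reads(c(wt = wt, del = del, ins = ins, mixed = mixed, subs = subs_only),
                ref),
    loc)
  expect_equal(cls$class[cls$read_id == "wt"], "WT")
  expect_equal(cls$class[cls$read_id == "del"], "DEL")
  expect_equal(cls$class[cls$read_id == "ins"], "INS")
  expect_equal(cls$class[cls$read_id == "mixed"], "MIXED")
  expect_equal(cls$class[cls$read_id == "subs"], "WT")
})

test_that("indels outside the analysis window are ignored", {
  set.seed(97)
  loc <- simulate_locus(architecture("TtT"), s = 15, flank = 80, seed = 97)
  ref <- loc$ref
  # a deletion in the far flank, > margin away from the footprint
  far <- paste0(substring(ref, 1, 5), substring(ref, 10))
  cls <- classify_reads(align_reads(c(far = far), ref), loc, margin = 30)
  expect_equal(cls$class, "WT")
  # the same deletion is called when the margin reaches it
  cls2 <- classify_reads(align_reads(c(far = far), ref), loc, margin = 100)
  expect_equal(cls2$class, "DEL")
})

test_that("event accounting follows the table conventions", {
  s1 <- mutagenesis_summary(reads = 5276, wt = 4817, n_ins = 134, n_del = 330)
  expect_equal(s1$total_events, 459)
  expect_equal(s1$percent_printed, "8.7")
  s2 <- mutagenesis_summary(reads = 10731, wt = 10538, n_ins = 58, n_del = 141)
  expect_equal(s2$total_events, 193)
  expect_equal(s2$percent_printed, "1.8")
  # MIXED reads appear once in totals, once in each indel tally: ins + del
  # may exceed total events
  expect_gt(s2$n_ins + s2$n_del, s2$total_events)
  s3 <- mutagenesis_summary(reads = 100, wt = 100)
  expect_equal(s3$total_events, 0)
  expect_equal(s3$percent_printed, "0")
  expect_error(mutagenesis_summary(reads = 0, wt = 0), "zero reads")
})

test_that("summaries computed from classifications obey their invariants", {
  set.seed(101)
  loc <- make_test_locus(seed = 101)
  sim <- simulate_reads(loc, indel_model(event_rate = 0.3, p_ins = 0.4),
                        n = 400, seed = 102)
  cls <- classify_reads(align_reads(sim$reads, loc$ref), loc)
  summ <- summarize_classifications(cls)
  expect_equal(summ$total_events, summ$reads - summ$wt)
  expect_gte(summ$n_ins + summ$n_del, summ$total_events)
  expect_gte(summ$percent_events, 0)
  expect_lte(summ$percent_events, 100)
  # with a clean simulator every event is recovered
  expect_equal(summ$total_events, sum(sim$truth$class != "WT"))
})

test_that("printed-style percent formatting matches the table", {
  expect_equal(format_percent(100 * 193 / 10731), "1.8")
  expect_equal(format_percent(100 * 59 / 2280), "2.6")
  expect_equal(format_percent(100 * 2 / 6131), "0.033")
  expect_equal(format_percent(100 * 2 / 3915), "0.051")
  expect_equal(format_percent(0), "0")
})

test_that("deletion centres follow the spacer-centred convention", {
  set.seed(103)
  loc <- make_test_locus(s = 15, seed = 103)
  sp <- loc$spacer_start
  # deletion covering spacer bases 4-11 (1-based): c = (4+11)/2 - 8 = -0.5
  expect_equal(deletion_center(c(sp + 3, sp + 11), loc), -0.5)
  # symmetric about the centre base
  expect_equal(deletion_center(c(sp + 5, sp + 10), loc), 0)
  # single-base deletion at the centre base (spacer base 8)
  expect_equal(deletion_center(c(sp + 7, sp + 8), loc), 0)
})

test_that("deletion-size distribution normalises and aggregates over loci", {
  d <- deletion_size_distribution(list(a = rep(5, 25),
                                       b = c(rep(5, 30), rep(12, 10))))
  expect_equal(sum(d$freq.a), 1)
  expect_equal(sum(d$freq.b), 1)
  expect_equal(d$mean_freq[d$bin == "5"], (1 + 0.75) / 2)
  expect_equal(d$sd_freq[d$bin == "12"], sd(c(0, 0.25)))
  # loci under the event threshold are dropped
  d2 <- deletion_size_distribution(list(a = rep(5, 25), tiny = rep(3, 4)))
  expect_false("freq.tiny" %in% names(d2))
  expect_error(deletion_size_distribution(list(tiny = rep(3, 4))),
               "threshold")
})

test_that("deletion-size histogram recovers a geometric generator", {
  set.seed(107)
  lens <- rgeom(4000, 1 / 8) + 1
  d <- deletion_size_distribution(list(x = lens), max_len = 30)
  theo <- dgeom(0:29, 1 / 8)
  emp <- d$freq.x[1:30]
  expect_lt(max(abs(emp - theo)), 0.02)
  expect_gt(sum(emp[1:19]), 0.9)   # most deletions are smaller than 20 bp
})

test_that("centre statistics report sample moments and a unit-area curve", {
  cs <- center_stats(c(-1, 1))
  expect_equal(cs$mean, 0)
  expect_equal(cs$var, 2)
  area <- integrate(cs$curve, -Inf, Inf)$value
  expect_equal(area, 1, tolerance = 1e-6)
  expect_error(center_stats(c(0.5)), "at least 2")
})

test_that("centre location test matches the pooled-variance oracle", {
  set.seed(109)
  x <- rnorm(40, -3, 3)
  y <- rnorm(55, -0.5, 2.5)
  got <- compare_centers(x, y)
  exp <- oracle_pooled_t(x, y)
  expect_equal(unname(got$statistic), exp$t)
  expect_equal(got$p.value, exp$p)
  same <- compare_centers(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_error(compare_centers(c(1, 1), c(2, 2)), "degenerate")
})

test_that("a shift of 2.5 bp in centres is reliably detected", {
  set.seed(113)
  hits <- vapply(1:100, function(i) {
    a <- rnorm(200, -3, 5)
    b <- rnorm(200, -0.5, 5)
    compare_centers(a, b)$p.value < 0.01
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
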