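region <- function(start, end, label = "r", anchor = start, transcript = "t") {
  tibble::tibble(transcript = transcript, start = start, end = end,
                 label = label, frame_anchor = anchor)
}

test_that("select_and_offset keeps chosen lengths and offsets to the A site", {
  fp <- tibble::tibble(transcript = "t", pos = 100L, length = 28L, count = 1)
  tr <- select_and_offset(fp)
  expect_equal(tr$pos, 115L)
  expect_equal(tr$count, 1)

  fp27 <- tibble::tibble(transcript = "t", pos = c(100L, 50L),
                         length = c(28L, 27L), count = c(1, 1))
  tr <- select_and_offset(fp27)
  expect_equal(nrow(tr), 1L)  # 27-mers excluded by default

  expect_error(select_and_offset(fp, lengths = c(28L, 30L)), "no offset")

  # mixed table equals per-read manual placement
  withr::with_seed(4, {
    fp <- tibble::tibble(
      transcript = "t",
      pos = sample(0:500, 10),
      length = sample(c(27L, 28L, 29L), 10, replace = TRUE),
      count = sample(1:5, 10, replace = TRUE)
    )
    tr <- select_and_offset(fp, lengths = c(28L, 29L),
                            offsets = c("28" = 15L, "29" = 16L))
    manual <- new.env()
    for (i in 1:10) {
      if (fp$length[i] == 27L) next
      p <- fp$pos[i] + if (fp$length[i] == 28L) 15L else 16L
      k <- as.character(p)
      assign(k, mget(k, manual, ifnotfound = 0)[[1]] + fp$count[i], manual)
    }
    for (i in seq_len(nrow(tr))) {
      expect_equal(tr$count[i], get(as.character(tr$pos[i]), manual))
    }
    expect_equal(sum(tr$count), sum(fp$count[fp$length != 27L]))
  })

  # offsets beyond the transcript end are dropped and reported
  fp_end <- tibble::tibble(transcript = "t", pos = c(10L, 95L),
                           length = 28L, count = c(2, 3))
  expect_message(tr <- select_and_offset(fp_end, transcript_length = 100L),
                 "dropped 3")
  expect_equal(attr(tr, "dropped_weight"), 3)
  expect_equal(tr$pos, 25L)
})

test_that("frame phasing tabulates weight by sub-codon phase", {
  uni <- tibble::tibble(transcript = "t", pos = 0:8, count = 1)
  ph <- frame_phasing(uni, region(0L, 9L))
  expect_equal(ph$fraction, rep(1 / 3, 3))
  expect_equal(sum(ph$count), 9)
  expect_equal(ph$codons, rep(3L, 3))

  only0 <- tibble::tibble(transcript = "t", pos = c(0L, 3L, 6L), count = 2)
  ph0 <- frame_phasing(only0, region(0L, 9L))
  expect_equal(ph0$fraction, c(1, 0, 0))

  # anchor shifts the phase assignment
  ph1 <- frame_phasing(only0, region(0L, 9L, anchor = 1L))
  expect_equal(ph1$fraction, c(0, 0, 1))

  # fractions sum to 1 and equal a hand tally on random tracks,
  # independent of read order
  withr::with_seed(6, {
    for (rep in 1:10) {
      trk <- tibble::tibble(transcript = "t", pos = sample(0:29, 15),
                            count = sample(1:4, 15, replace = TRUE))
      reg <- region(3L, 27L, anchor = 5L)
      ph <- frame_phasing(trk, reg)
      expect_equal(ph$count, oracle_phase_tally(trk, 3L, 27L, 5L))
      expect_equal(sum(ph$fraction), 1)
      ph_shuf <- frame_phasing(trk[sample(nrow(trk)), ], reg)
      expect_equal(ph_shuf$count, ph$count)
    }
  })

  # zero-weight region flagged with undefined fractions
  expect_warning(ph_empty <- frame_phasing(uni[0, ], region(0L, 9L)),
                 "zero read weight")
  expect_true(all(is.na(ph_empty$fraction)))
})

test_that("the efficiency estimator reproduces the worked density ratio", {
  # ORF1: 10 codons, phase-0 weight 90 and phase-1 weight 10 -> density 10
  # ORF2 window: 20 codons, +1-frame weight 40 -> density 2 -> 20.0%
  orf1 <- region(0L, 30L, "ORF1")
  orf2 <- region(33L, 93L, "ORF2", anchor = 33L)
  trk <- tibble::tibble(
    transcript = "t",
    pos = c(seq(0L, 27L, 3L), seq(1L, 28L, 3L), seq(33L, 90L, 3L)),
    count = c(rep(9, 10), rep(1, 10), rep(2, 20))
  )
  est <- estimate_efficiency(trk, orf1, orf2)
  expect_equal(est$percent, 20)
  expect_equal(est$orf1_density, 10)
  expect_equal(est$orf2_density, 2)
  expect_equal(est$orf1_codons, 10L)
  expect_equal(est$orf2_codons, 20L)

  # zero +1-frame weight in ORF2 -> 0%
  trk0 <- trk[trk$pos < 30L, ]
  expect_equal(estimate_efficiency(trk0, orf1, orf2)$percent, 0)

  # equal densities -> 100%
  trk100 <- tibble::tibble(transcript = "t",
                           pos = c(seq(0L, 27L, 3L), seq(33L, 90L, 3L)),
                           count = c(rep(5, 10), rep(5, 20)))
  expect_equal(estimate_efficiency(trk100, orf1, orf2)$percent, 100)

  # invariant under positive rescaling of all weights
  trk2 <- trk; trk2$count <- trk2$count * 7.5
  expect_equal(estimate_efficiency(trk2, orf1, orf2)$percent, 20)

  # undefined when ORF1 carries no reads
  expect_error(estimate_efficiency(trk[trk$pos >= 33L, ], orf1, orf2),
               "undefined")

  td <- tidy(est)
  expect_equal(td$percent, 20)
  expect_true(is.na(td$ci_lo))
})

test_that("bootstrap intervals are deterministic, cover, and tighten with depth", {
  tpl <- make_template_transcript()
  params <- ribo_sim_params(p_fs = 0.2, fidelity = 1, depth = 50,
                            dispersion = Inf, seed = 31)
  sim <- simulate_footprints(tpl$transcript, tpl$regions, tpl$site, params)
  r1 <- tpl$regions[1, ]; r2 <- tpl$regions[2, ]

  e1 <- bootstrap_ci(sim$footprints, r1, r2, B = 200L, seed = 9L)
  e2 <- bootstrap_ci(sim$footprints, r1, r2, B = 200L, seed = 9L)
  expect_equal(e1$ci, e2$ci)
  expect_lt(e1$ci$lo, e1$ci$hi)

  # point estimate inside its own interval at B = 1000
  e3 <- bootstrap_ci(sim$footprints, r1, r2, B = 1000L, seed = 11L)
  expect_gte(e3$percent, e3$ci$lo)
  expect_lte(e3$percent, e3$ci$hi)

  # x100 coverage narrows the interval
  deep <- simulate_footprints(tpl$transcript, tpl$regions, tpl$site,
                              ribo_sim_params(p_fs = 0.2, fidelity = 1,
                                              depth = 5000, dispersion = Inf,
                                              seed = 31))
  e4 <- bootstrap_ci(deep$footprints, r1, r2, B = 200L, seed = 9L)
  expect_lt(e4$ci$hi - e4$ci$lo, e1$ci$hi - e1$ci$lo)

  expect_error(bootstrap_ci(sim$footprints, r1, r2, B = 50L), "at least 100")
})

test_that("reporter arithmetic compares test to in-frame control ratios", {
  rd <- tibble::tibble(
    construct = c("test", "test", "control", "control"),
    firefly = c(10, 12, 10, 12),
    renilla = c(5, 6, 5, 6)
  )
  expect_equal(percent_frameshift_reporter(rd)$percent, 100)

  # test ratio at 48% of control
  rd2 <- tibble::tibble(
    construct = c("test", "control"),
    firefly = c(0.48 * 24, 24),
    renilla = c(8, 8)
  )
  expect_equal(percent_frameshift_reporter(rd2)$percent, 48)

  # orientation flip with swapped channels gives the identical percent
  rd3 <- rd2[, c("construct", "renilla", "firefly")]
  names(rd3) <- c("construct", "firefly", "renilla")
  expect_equal(percent_frameshift_reporter(rd3, "renilla_downstream")$percent, 48)

  expect_error(
    percent_frameshift_reporter(tibble::tibble(construct = c("test", "control"),
                                               firefly = c(1, 1),
                                               renilla = c(0, 1))),
    "positive"
  )

  reps <- attr(percent_frameshift_reporter(rd2), "replicates")
  expect_equal(nrow(reps), 2L)
  expect_equal(reps$percent_vs_control[1], 48)
})
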