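make_aln <- function(...) {
  seqs <- c(...)
  tibble::tibble(species = names(seqs), seq = unname(seqs))
}

test_that("reference projection drops reference-gap columns only", {
  aln <- make_aln(ref = "A-C", oth = "AGC")
  proj <- project_to_reference(aln, "ref")
  expect_equal(proj$seq, c("AC", "AC"))
  expect_equal(attr(proj, "alignment_columns"), c(1L, 3L))

  # gapless reference: identity
  aln2 <- make_aln(ref = "ACDE", oth = "A-DE")
  expect_equal(project_to_reference(aln2, "ref")$seq, aln2$seq)

  expect_error(project_to_reference(aln, "nope"), "absent")

  # projected width equals ungapped reference length on random alignments
  withr::with_seed(3, {
    for (rep in 1:20) {
      r <- random_alignment(5, 40, gap_rate = 0.2)
      proj <- project_to_reference(r, "r1")
      expect_equal(unique(nchar(proj$seq)),
                   nchar(gsub("-", "", r$seq[1])))
    }
  })
})

test_that("conservation counts honor the threshold with gaps as mismatches", {
  aln <- make_aln(a = strrep("T", 96), b = strrep("T", 96), c = strrep("T", 96),
                  d = strrep("T", 96), e = strrep("T", 96), f = strrep("T", 96),
                  g = strrep("T", 96), h = strrep("T", 96))
  prof <- conservation_counts(aln, threshold = 1)
  expect_equal(attr(prof, "n_conserved"), 96L)

  # 9 of 10 rows identical: conserved at 0.9, not at 1.0
  col <- tibble::tibble(species = paste0("s", 1:10), seq = c(rep("T", 9), "S"))
  expect_equal(attr(conservation_counts(col, threshold = 0.9), "n_conserved"), 1L)
  expect_equal(attr(conservation_counts(col, threshold = 1.0), "n_conserved"), 0L)

  # a gap counts against conservation
  gcol <- tibble::tibble(species = paste0("s", 1:10), seq = c(rep("T", 9), "-"))
  expect_equal(attr(conservation_counts(gcol, threshold = 1.0), "n_conserved"), 0L)
  expect_equal(attr(conservation_counts(gcol, threshold = 0.9), "n_conserved"), 1L)

  expect_error(conservation_counts(col, threshold = 0), "threshold")
  expect_error(conservation_counts(col, column_range = integer()), "empty")
})

test_that("conservation counts match a brute-force tally and are row-order invariant", {
  withr::with_seed(5, {
    for (th in c(0.6, 0.9, 1.0)) {
      r <- random_alignment(8, 60, gap_rate = 0.15, alphabet = c("A", "C", "D"))
      prof <- conservation_counts(r, threshold = th)
      expect_equal(attr(prof, "n_conserved"), oracle_conserved_count(r$seq, th))
      shuffled <- r[sample(nrow(r)), ]
      expect_equal(attr(conservation_counts(shuffled, threshold = th), "n_conserved"),
                   attr(prof, "n_conserved"))
    }
  })
})

test_that("projection plus counting ignores all-gap insertion columns", {
  aln <- make_aln(ref = "ACDE", x = "ACDE", y = "AGDE")
  base <- conservation_counts(project_to_reference(aln, "ref"))
  padded <- make_aln(ref = "AC--DE", x = "AC--DE", y = "AG--DE")
  padded_prof <- conservation_counts(project_to_reference(padded, "ref"))
  expect_equal(attr(padded_prof, "n_conserved"), attr(base, "n_conserved"))
  expect_equal(padded_prof$consensus, base$consensus)
})

test_that("synonymous signature needs protein identity plus nucleotide variation", {
  # four Thr codons ACN: amino acid conserved, nucleotides vary -> flagged
  aln <- make_aln(r1 = "ACT", r2 = "ACC", r3 = "ACA", r4 = "ACG")
  sig <- synonymous_frame_signature(aln, 0, "r1")
  expect_true(sig$flag)
  expect_equal(sig$ref_aa, "T")

  # identical codons: no substitution evidence
  aln2 <- make_aln(r1 = "AAA", r2 = "AAA", r3 = "AAA")
  expect_false(synonymous_frame_signature(aln2, 0, "r1")$flag)

  # Lys vs Glu: amino acid differs
  aln3 <- make_aln(r1 = "AAA", r2 = "GAA")
  expect_false(synonymous_frame_signature(aln3, 0, "r1")$flag)

  # trailing partial codon is ignored with a warning
  aln4 <- make_aln(r1 = "ACTG", r2 = "ACCG")
  expect_warning(sig4 <- synonymous_frame_signature(aln4, 0, "r1"), "partial")
  expect_equal(nrow(sig4), 1L)
})

test_that("identity distances are p-distances over shared non-gap columns", {
  aln <- make_aln(a = "ACGT", b = "ACGT")
  expect_equal(unname(identity_distance(aln)["a", "b"]), 0)

  aln2 <- make_aln(a = "AAAA", b = "AAAT")
  expect_equal(unname(identity_distance(aln2)["a", "b"]), 0.25)

  expect_error(identity_distance(make_aln(a = "A--", b = "-CC")), "overlap")

  withr::with_seed(9, {
    r <- random_alignment(6, 50, gap_rate = 0.1)
    d <- identity_distance(r)
    expect_true(isSymmetric(d))
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(unname(d[i, j]), oracle_identity_dist(r$seq[i], r$seq[j]))
    }
  })
})

test_that("neighbor joining handles 2 and 3 taxa in closed form", {
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- neighbor_joining(d2)
  expect_setequal(t2$tip.label, c("a", "b"))
  expect_equal(sum(t2$edge.length), 0.7)

  d3 <- matrix(c(0, 0.5, 0.9, 0.5, 0, 0.6, 0.9, 0.6, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- neighbor_joining(d3)
  cph <- stats::cophenetic(t3)[rownames(d3), colnames(d3)]
  expect_equal(cph, d3, tolerance = 1e-12)

  bad <- d3; bad[1, 2] <- 0.4
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("neighbor joining exactly recovers trees from additive distances", {
  for (n in c(4L, 6L, 8L)) {
    for (seed in 1:3) {
      gen <- random_additive(n, seed = 100 * n + seed)
      tr <- neighbor_joining(gen$dist)
      # same topology as the generating tree
      expect_equal(as.numeric(ape::dist.topo(tr, gen$tree)), 0)
      # and identical path lengths, hence identical branch lengths
      cph <- stats::cophenetic(tr)[rownames(gen$dist), colnames(gen$dist)]
      expect_equal(cph, gen$dist, tolerance = 1e-8)
    }
  }
})

test_that("neighbor joining agrees with an independent implementation", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- sample(5:9, 1)
      M <- matrix(stats::runif(n * n, 0.1, 1), n)
      M <- (M + t(M)) / 2
      diag(M) <- 0
      rownames(M) <- colnames(M) <- paste0("s", seq_len(n))
      expect_equal(as.numeric(ape::dist.topo(neighbor_joining(M), ape::nj(M))), 0)
    }
  })
})
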