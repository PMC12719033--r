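# Independent brute-force oracles and small fixture builders. These are
# deliberately written as plain loops, separate from the package's
# vectorized implementations.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

codon_of <- function(s, p) substr(s, p + 1, p + 3)

# brute-force ORF enumeration: every ATG, walk to the first in-frame stop
oracle_find_orfs <- function(s, min_codons = 2) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(s)
  out <- list()
  for (p in 0:(n - 3L)) {
    if (codon_of(s, p) != "ATG") next
    q <- p + 3L
    while (q + 3L <= n) {
      if (codon_of(s, q) %in% stops) {
        if ((q + 3L - p) / 3 >= min_codons) {
          out[[length(out) + 1]] <- data.frame(start = p, end = q + 3L)
        }
        break
      }
      q <- q + 3L
    }
  }
  if (length(out) == 0) return(data.frame(start = integer(), end = integer()))
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# exhaustive in-frame heptamer scan against exact catalog patterns
oracle_scan_sites <- function(s, start, end, patterns) {
  hits <- integer()
  p <- as.integer(start)
  while (p + 7L <= end) {
    if (substr(s, p + 1L, p + 7L) %in% patterns) hits <- c(hits, p)
    p <- p + 3L
  }
  hits
}

# hand tally of track weight by sub-codon phase inside a region
oracle_phase_tally <- function(track, start, end, anchor) {
  cnt <- c(0, 0, 0)
  for (i in seq_len(nrow(track))) {
    p <- track$pos[i]
    if (p >= start && p < end) {
      ph <- (p - anchor) %% 3
      cnt[ph + 1] <- cnt[ph + 1] + track$count[i]
    }
  }
  cnt
}

# per-column modal-residue tally with gaps as mismatches
oracle_conserved_count <- function(seq_strings, threshold) {
  m <- do.call(rbind, strsplit(seq_strings, ""))
  n_cons <- 0
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    best <- 0
    for (r in unique(col[col != "-"])) best <- max(best, sum(col == r))
    if (best / nrow(m) >= threshold) n_cons <- n_cons + 1
  }
  n_cons
}

oracle_identity_dist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  match <- 0
  overlap <- 0
  for (k in seq_along(ca)) {
    if (ca[k] != "-" && cb[k] != "-") {
      overlap <- overlap + 1
      if (ca[k] == cb[k]) match <- match + 1
    }
  }
  1 - match / overlap
}

# random alignment with controllable gap rate
random_alignment <- function(n_rows, width, gap_rate = 0.1,
                             alphabet = c("A", "C", "D", "E", "G")) {
  seqs <- vapply(seq_len(n_rows), function(i) {
    ch <- sample(alphabet, width, replace = TRUE)
    ch[runif(width) < gap_rate] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  tibble::tibble(species = paste0("r", seq_len(n_rows)), seq = seqs)
}

# additive distance matrix from a random ape tree (the generating tree
# is the oracle for neighbor joining)
random_additive <- function(n_leaves, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_leaves, rooted = FALSE)
    tr$edge.length <- round(runif(nrow(tr$edge), 0.05, 1), 4)
    list(tree = tr, dist = stats::cophenetic(tr))
  })
}
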