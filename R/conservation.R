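aln_matrix <- function(alignment) {
  stopifnot(all(c("species", "seq") %in% names(alignment)))
  if (nrow(alignment) < 2L) abort("alignment needs at least 2 rows")
  w <- nchar(alignment$seq)
  if (length(unique(w)) != 1L) abort("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(alignment$seq), ""))
  rownames(m) <- alignment$species
  m
}

mat_to_aln <- function(m) {
  tibble(species = rownames(m),
         seq = unname(apply(m, 1L, paste, collapse = "")))
}

#' Project an alignment onto a reference sequence
#'
#' Drops every column where the reference row carries a gap, so that the
#' remaining columns are numbered by reference residue position (1-based).
#' This is the usual preprocessing for reference-numbered conservation
#' logos.
#'
#' @param alignment tibble with columns `species`, `seq` (gapped, equal
#'   length, `-` as gap).
#' @param reference species id of the reference row.
#' @return tibble with the same rows and only reference-non-gap columns;
#'   attributes `reference` and `alignment_columns` (original 1-based
#'   column indices kept).
#' @export
project_to_reference <- function(alignment, reference) {
  m <- aln_matrix(alignment)
  if (!reference %in% rownames(m)) {
    abort(paste0("reference '", reference, "' absent from alignment"))
  }
  keep <- which(m[reference, ] != "-")
  out <- mat_to_aln(m[, keep, drop = FALSE])
  attr(out, "reference") <- reference
  attr(out, "alignment_columns") <- keep
  out
}

#' Per-column conservation counts of an alignment
#'
#' A column is conserved when its modal (most frequent) residue reaches
#' the threshold fraction of rows; gaps count as mismatches, so a species
#' missing the residue can never support conservation. Works on any
#' alignment tibble, typically a reference projection.
#'
#' @param alignment alignment tibble (e.g. from [project_to_reference()]).
#' @param column_range optional integer range of 1-based columns to
#'   score; default all columns.
#' @param threshold fraction of rows, in (0, 1], that must share the
#'   modal residue (default 1, absolute conservation).
#' @param reference optional species id; adds `frac_ref`, the fraction of
#'   rows matching the reference residue.
#' @return tibble with one row per scored column: `column`, `consensus`,
#'   `n_consensus`, `frac_consensus`, `frac_ref`, `conserved`, and a
#'   `counts` list-column of named residue counts (gaps included under
#'   `-`). Attribute `n_conserved` holds the conserved-column count.
#' @export
conservation_counts <- function(alignment, column_range = NULL, threshold = 1,
                                reference = NULL) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]")
  }
  m <- aln_matrix(alignment)
  nr <- nrow(m)
  cols <- column_range %||% seq_len(ncol(m))
  if (length(cols) == 0L) abort("empty column range")
  if (any(cols < 1L | cols > ncol(m))) abort("column range outside alignment width")
  ref_row <- if (!is.null(reference)) {
    if (!reference %in% rownames(m)) abort("reference absent from alignment")
    m[reference, ]
  }
  rows <- map(cols, function(j) {
    col <- m[, j]
    tab <- table(col)
    res_tab <- tab[names(tab) != "-"]
    if (length(res_tab)) {
      consensus <- names(res_tab)[which.max(res_tab)]
      n_cons <- as.integer(max(res_tab))
    } else {
      consensus <- NA_character_
      n_cons <- 0L
    }
    tibble(
      column = j,
      consensus = consensus,
      n_consensus = n_cons,
      frac_consensus = n_cons / nr,
      frac_ref = if (is.null(ref_row)) NA_real_ else mean(col == ref_row[j]),
      conserved = n_cons / nr >= threshold,
      counts = list(setNames(as.integer(tab), names(tab)))
    )
  })
  out <- bind_rows(rows)
  attr(out, "n_conserved") <- sum(out$conserved)
  out
}

#' Write a conservation profile as a long count matrix TSV
#'
#' Emits columns `column`, `residue`, `count` — the layout consumed by
#' sequence-logo renderers.
#'
#' @param profile output of [conservation_counts()].
#' @param path output path.
#' @return the profile, invisibly.
#' @export
write_conservation_profile <- function(profile, path) {
  long <- bind_rows(map(seq_len(nrow(profile)), function(i) {
    cts <- profile$counts[[i]]
    tibble(column = profile$column[i], residue = names(cts),
           count = as.integer(cts))
  }))
  readr::write_tsv(long, path)
  invisible(profile)
}

#' Flag codon columns with a synonymous-substitution signature
#'
#' On a reference-projected nucleotide alignment, reads codons in the
#' frame given by `frame_offset` and flags each codon column where the
#' encoded amino acid is shared by at least `threshold` of the rows while
#' at least one row differs from the reference at the nucleotide level
#' within the codon — i.e. the column is conserved at the protein level
#' but not the nucleotide level, the hallmark of coding selection in that
#' frame.
#'
#' @param alignment reference-projected nucleotide alignment tibble.
#' @param frame_offset 0, 1 or 2: offset of the codon frame within the
#'   projected columns.
#' @param reference species id of the reference row.
#' @param threshold fraction of rows that must share the amino acid
#'   (default 1). Rows with gaps or ambiguous codons never match.
#' @return tibble with one row per complete codon column: `codon_index`
#'   (1-based), `col_start` (1-based first column), `ref_codon`,
#'   `ref_aa`, `frac_aa`, `nt_varies`, `flag`.
#' @export
synonymous_frame_signature <- function(alignment, frame_offset, reference,
                                       threshold = 1) {
  if (!frame_offset %in% 0:2) abort("frame_offset must be 0, 1 or 2")
  m <- aln_matrix(alignment)
  if (!reference %in% rownames(m)) abort("reference absent from alignment")
  nc <- ncol(m)
  starts <- seq.int(frame_offset + 1L, by = 3L,
                    length.out = max(0L, (nc - frame_offset) %/% 3L))
  if ((nc - frame_offset) %% 3L != 0L) {
    warn("trailing partial codon ignored")
  }
  if (length(starts) == 0L) abort("no complete codon columns in range")
  ref_idx <- which(rownames(m) == reference)
  rows <- map(seq_along(starts), function(k) {
    j <- starts[k]
    cod <- apply(m[, j:(j + 2L), drop = FALSE], 1L, paste, collapse = "")
    ref_codon <- cod[ref_idx]
    aa <- translate_codons(chartr("U", "T", cod))
    aa[stringr::str_detect(cod, "[^ACGT]")] <- NA_character_
    ref_aa <- aa[ref_idx]
    frac_aa <- if (is.na(ref_aa)) 0 else mean(!is.na(aa) & aa == ref_aa)
    nt_varies <- any(cod != ref_codon)
    tibble(codon_index = k, col_start = j, ref_codon = ref_codon,
           ref_aa = ref_aa, frac_aa = frac_aa, nt_varies = nt_varies,
           flag = frac_aa >= threshold && nt_varies)
  })
  bind_rows(rows)
}

#' Pairwise identity distances of an alignment
#'
#' p-distance on the columns where both rows are non-gap:
#' `d(i, j) = 1 - matches / overlap`. No multiple-substitution
#' correction is applied.
#'
#' @param alignment alignment tibble (typically a reference projection or
#'   full alignment of equal-length sequences).
#' @return symmetric numeric matrix with species dimnames and zero
#'   diagonal. Errors if some pair shares no non-gap column.
#' @export
identity_distance <- function(alignment) {
  m <- aln_matrix(alignment)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      ov <- sum(both)
      if (ov == 0L) {
        abort(paste0("no overlapping non-gap columns between ",
                     rownames(m)[i], " and ", rownames(m)[j]))
      }
      d[i, j] <- d[j, i] <- 1 - sum(m[i, both] == m[j, both]) / ov
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining with the Q-matrix selection criterion and
#' Studier-Keppler distance updates. Ties in Q are broken by the
#' lexicographically smallest pair index, making the result
#' deterministic. Negative branch lengths are clamped to zero. For an
#' additive distance matrix the generating tree (topology and branch
#' lengths) is recovered exactly.
#'
#' @param dm symmetric numeric distance matrix with taxon dimnames (or a
#'   `dist` object).
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) abort("distance matrix must be square")
  if (max(abs(dm - t(dm))) > 1e-9) abort("distance matrix is not symmetric")
  if (any(dm < 0)) abort("distances must be nonnegative")
  n <- nrow(dm)
  if (n < 2L) abort("need at least 2 taxa")
  labs <- rownames(dm) %||% paste0("t", seq_len(n))
  # guard against Newick-breaking label characters
  labs <- gsub("[(),:;\\s]", "_", labs, perl = TRUE)
  fmt <- function(x) format(max(0, x), digits = 15, scientific = FALSE)

  if (n == 2L) {
    nwk <- paste0("(", labs[1], ":", fmt(dm[1, 2] / 2), ",",
                  labs[2], ":", fmt(dm[1, 2] / 2), ");")
    return(ape::read.tree(text = nwk))
  }

  node <- labs  # Newick substring per active cluster
  D <- dm
  while (length(node) > 3L) {
    r <- length(node)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q == qmin, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    new_node <- paste0("(", node[i], ":", fmt(bi), ",", node[j], ":", fmt(bj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    node <- c(node[keep], new_node)
    D <- D2
  }
  # final trifurcation: closed-form three-point lengths
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  nwk <- paste0("(", node[1], ":", fmt(l1), ",", node[2], ":", fmt(l2), ",",
                node[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Write a tree in Newick format
#'
#' @param tree an `ape::phylo` object.
#' @param path output path.
#' @return the tree, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(tree)
}
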