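#' The built-in +1 shift-site catalog
#'
#' Heptameric +1 frameshift sites known from budding yeast: the Ty1 /
#' ABP140 site CTT-AGG-C, the EST3 site CTT-AGT-T, the Ty3 site
#' GCG-AGT-T, the OAZ1 (antizyme) site GCG-TGA-C, and the Kazachstania
#' variant CTT-CGG-C. Each heptamer spans the P-site codon (nt 1-3), the
#' slowly decoded zero-frame A-site codon (nt 4-6) and one further
#' nucleotide, so that nt 5-7 form the +1-frame A-site codon decoded
#' after the shift. Patterns may use IUPAC degeneracy codes; the default
#' entries are exact.
#'
#' @param path optional TSV (columns `name`, `pattern`, `class`)
#'   replacing the default catalog.
#' @return tibble with columns `name`, `pattern`, `class`.
#' @export
#' @examples
#' shift_site_catalog()
shift_site_catalog <- function(path = NULL) {
  catalog <- if (is.null(path)) {
    tibble(
      name = c("Ty1", "EST3", "Ty3", "OAZ1", "Kazachstania_variant"),
      pattern = c("CTTAGGC", "CTTAGTT", "GCGAGTT", "GCGTGAC", "CTTCGGC"),
      class = c("Ty1-like", "Ty1-like", "Ty3-like", "antizyme", "Ty1-like")
    )
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols())
    if (!all(c("name", "pattern") %in% names(raw))) {
      abort("catalog file needs columns name, pattern[, class]")
    }
    tibble(
      name = as.character(raw$name),
      pattern = chartr("U", "T", toupper(as.character(raw$pattern))),
      class = if ("class" %in% names(raw)) as.character(raw$class) else NA_character_
    )
  }
  if (any(nchar(catalog$pattern) != 7L)) abort("catalog patterns must be 7-mers")
  if (anyDuplicated(catalog$name)) abort("catalog names must be unique")
  catalog
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# TRUE where each window matches `pattern` under IUPAC semantics.
iupac_match <- function(windows, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, length(windows))
  for (i in seq_along(pat)) {
    ok <- ok & substr(windows, i, i) %in% IUPAC_SETS[[pat[i]]]
  }
  ok
}

as_seq_string <- function(seq) {
  if (is.data.frame(seq)) {
    if (nrow(seq) != 1L || !"seq" %in% names(seq)) {
      abort("expected a single sequence (one-row tibble with a `seq` column)")
    }
    seq <- seq$seq
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("U", "T", toupper(seq))
}

#' Find all ATG-initiated ORFs in a sequence
#'
#' Enumerates every ATG...stop span in all three frames, including nested
#' ORFs sharing a stop codon. The stop codon is included in the interval.
#'
#' @param seq a sequence string (or one-row tibble from [read_fasta()]).
#' @param min_codons minimum span length in codons, counting the stop
#'   (default 2, i.e. ATG directly followed by a stop).
#' @return tibble sorted by `start` with columns `start`, `end` (0-based
#'   half-open, stop included), `frame` (start modulo 3), `n_codons`.
#' @export
#' @examples
#' find_orfs("ATGAAATAA")
find_orfs <- function(seq, min_codons = 2L) {
  s <- as_seq_string(seq)
  n <- nchar(s)
  if (n < 6L) {
    return(tibble(start = integer(), end = integer(),
                  frame = integer(), n_codons = integer()))
  }
  starts0 <- seq_len(n - 2L) - 1L
  codons <- substring(s, starts0 + 1L, starts0 + 3L)
  atg <- starts0[codons == "ATG"]
  stp <- starts0[codons %in% STOP_CODONS]
  out <- map(0:2, function(f) {
    a <- atg[atg %% 3L == f]
    q <- sort(stp[stp %% 3L == f])
    if (length(a) == 0L || length(q) == 0L) return(NULL)
    idx <- findInterval(a, q) + 1L
    keep <- idx <= length(q)
    a <- a[keep]
    end <- q[idx[keep]] + 3L
    tibble(start = a, end = end, frame = f,
           n_codons = (end - a) %/% 3L)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(start = integer(), end = integer(),
                  frame = integer(), n_codons = integer()))
  }
  res <- res[res$n_codons >= min_codons, , drop = FALSE]
  arrange(res, .data$start, .data$end)
}

#' Scan a host ORF for catalog +1 shift sites
#'
#' Reports every catalog heptamer whose first triplet (the P-site codon)
#' is in frame 0 of the host ORF and whose 7 nucleotides lie within the
#' host interval.
#'
#' @param seq sequence string (or one-row tibble).
#' @param host_orf a list or one-row tibble with `start` and `end`
#'   (0-based half-open, codon-aligned).
#' @param catalog shift-site catalog, see [shift_site_catalog()].
#' @return tibble with one row per match: `position` (first nt of the
#'   P-site codon), `heptamer`, `motif`, `class`, `p_codon`, `a0_codon`,
#'   `a1_codon`.
#' @export
#' @examples
#' scan_shift_sites("ATGCTTAGGCTAANN", list(start = 0, end = 12))
scan_shift_sites <- function(seq, host_orf, catalog = shift_site_catalog()) {
  s <- as_seq_string(seq)
  start <- as.integer(host_orf$start)
  end <- as.integer(host_orf$end)
  if (start < 0 || end > nchar(s) || start >= end) abort("host_orf outside sequence")
  if ((end - start) %% 3L != 0L) abort("host_orf is not codon-aligned")
  empty <- tibble(position = integer(), heptamer = character(),
                  motif = character(), class = character(),
                  p_codon = character(), a0_codon = character(),
                  a1_codon = character())
  if (end - start < 7L) return(empty)
  q <- seq.int(start, end - 7L, by = 3L)
  q <- q[q + 7L <= nchar(s)]
  if (length(q) == 0L) return(empty)
  windows <- substring(s, q + 1L, q + 7L)
  hits <- map(seq_len(nrow(catalog)), function(i) {
    m <- iupac_match(windows, catalog$pattern[i])
    if (!any(m)) return(NULL)
    tibble(position = q[m], heptamer = windows[m],
           motif = catalog$name[i], class = catalog$class[i])
  })
  res <- bind_rows(hits)
  if (nrow(res) == 0L) return(empty)
  res <- arrange(res, .data$position)
  mutate(res,
    p_codon = substr(.data$heptamer, 1L, 3L),
    a0_codon = substr(.data$heptamer, 4L, 6L),
    a1_codon = substr(.data$heptamer, 5L, 7L)
  )
}

#' Test whether the +1 frame is open downstream of a shift site
#'
#' Walks codons in the +1 frame starting at the post-shift A-site codon
#' (nt 5-7 of the heptamer) up to `landmark_end` (e.g. the annotated main
#' ORF start or stop) and reports whether a stop codon intervenes.
#'
#' @param seq sequence string (or one-row tibble).
#' @param site one row of [scan_shift_sites()] output (needs `position`).
#' @param landmark_end 0-based position bounding the walk; codons fully
#'   5' of `landmark_end` are examined.
#' @return one-row tibble: `open`, `first_stop` (0-based position of the
#'   first +1-frame stop, NA if open), `n_codons_scanned`.
#' @export
check_plus1_open <- function(seq, site, landmark_end) {
  s <- as_seq_string(seq)
  a1 <- as.integer(site$position) + 4L
  landmark_end <- as.integer(landmark_end)
  if (landmark_end <= a1) abort("landmark_end must be 3' of the post-shift A-site codon")
  if (landmark_end > nchar(s)) abort("landmark_end beyond sequence end")
  p <- seq.int(a1, by = 3L, length.out = max(0L, (landmark_end - a1) %/% 3L))
  codons <- substring(s, p + 1L, p + 3L)
  stop_at <- which(codons %in% STOP_CODONS)
  tibble(
    open = length(stop_at) == 0L,
    first_stop = if (length(stop_at)) p[stop_at[1]] else NA_integer_,
    n_codons_scanned = length(p)
  )
}

#' Conceptually translate a dual-ORF mRNA through a +1 frameshift
#'
#' Translates from the ATG at `start` in frame 0 through the P-site codon
#' of the shift site, then continues in the +1 frame from the post-shift
#' A-site codon to the first stop. Without a site, performs standard
#' translation to the first stop. The stop is not included in the protein.
#' Equivalent, by construction of the +1 shift, to standard translation
#' of the sequence with the single nucleotide 3' of the P-site codon
#' deleted (see [fuse_inframe()]).
#'
#' @param seq sequence string (or one-row tibble).
#' @param start 0-based position of the initiating ATG.
#' @param site optional shift site (one row of [scan_shift_sites()]
#'   output), in frame with `start`.
#' @return protein string (one-letter code). If no stop is reached before
#'   the sequence end the truncated protein is returned with a warning
#'   and attribute `truncated = TRUE`.
#' @export
#' @examples
#' site <- scan_shift_sites("ATGCTTAGGCGATTAA", list(start = 0, end = 15))
#' translate_with_frameshift("ATGCTTAGGCGATTAA", 0, site)  # "MLGD"
translate_with_frameshift <- function(seq, start, site = NULL) {
  s <- as_seq_string(seq)
  start <- as.integer(start)
  if (substr(s, start + 1L, start + 3L) != "ATG") {
    abort("start position is not an ATG codon")
  }
  walk <- function(from) {
    p <- seq.int(from, by = 3L, length.out = max(0L, (nchar(s) - from) %/% 3L))
    codons <- substring(s, p + 1L, p + 3L)
    stop_at <- which(codons %in% STOP_CODONS)
    if (length(stop_at)) {
      list(aa = translate_codons(codons[seq_len(stop_at[1] - 1L)]), complete = TRUE)
    } else {
      list(aa = translate_codons(codons), complete = FALSE)
    }
  }
  if (is.null(site)) {
    res <- walk(start)
    aa <- res$aa
    complete <- res$complete
  } else {
    pos <- as.integer(site$position)
    if (pos <= start || (pos - start) %% 3L != 0L) {
      abort("shift site is not in frame 0 of the start codon")
    }
    p0 <- seq.int(start, pos, by = 3L)
    head_cod <- substring(s, p0 + 1L, p0 + 3L)
    if (any(head_cod %in% STOP_CODONS)) {
      abort("in-frame stop codon upstream of the shift site")
    }
    res <- walk(pos + 4L)
    aa <- c(translate_codons(head_cod), res$aa)
    complete <- res$complete
  }
  protein <- paste(aa, collapse = "")
  if (!complete) {
    warn("no stop codon reached before sequence end; protein is truncated")
    attr(protein, "truncated") <- TRUE
  }
  protein
}

#' Fuse the two ORFs of a frameshift gene in-frame
#'
#' Deletes the single nucleotide immediately 3' of the P-site codon (the
#' "A" of CTT-AGG-C for a Ty1-type site), placing the downstream ORF in
#' frame with the upstream one so the full-length product no longer
#' requires frameshifting. The mimic of in-frame control constructs.
#'
#' @param seq sequence string (or one-row tibble).
#' @param site shift site (one row, needs `position`).
#' @return the fused sequence string, one nucleotide shorter.
#' @export
fuse_inframe <- function(seq, site) {
  s <- as_seq_string(seq)
  cut <- as.integer(site$position) + 3L
  if (cut < 0L || cut >= nchar(s)) abort("shift site outside sequence")
  paste0(substr(s, 1L, cut), substr(s, cut + 2L, nchar(s)))
}

#' Classify a homolog mRNA as requiring +1 frameshifting
#'
#' Applies the comparative-genomic decision rule for dual-ORF +1
#' frameshift architecture. Relative to the annotated main-ORF start
#' codon, the maximal N-terminal extension runs from the bracketing
#' in-frame stop codon (the first stop 5' of the start) down to the start
#' itself. The homolog `requires_fs` when (a) that extension contains no
#' in-frame ATG of its own, (b) an ATG-initiated upstream ORF overlapping
#' the extension in the shifted frame (ORF1 frame = extension frame - 1
#' modulo 3, so that a +1 shift from ORF1 lands in the extension frame)
#' carries a catalog shift site, and (c) the +1 frame is open from that
#' site to the main-ORF stop. It is `no_fs` when the extension carries an
#' in-frame ATG giving an uninterrupted ORF; `ambiguous` otherwise.
#' When several sites qualify, the 5'-most site satisfying (c) is used.
#'
#' @param seq sequence string (or one-row tibble).
#' @param annotated_start 0-based position of the annotated main-ORF ATG.
#' @param catalog shift-site catalog.
#' @return one-row tibble: `label` (requires_fs/no_fs/ambiguous),
#'   `site_position`, `motif`, and evidence columns `bracketing_stop`,
#'   `extension_start`, `extension_atg`, `plus1_open`, `morf_stop`.
#' @export
classify_homolog <- function(seq, annotated_start, catalog = shift_site_catalog()) {
  s <- as_seq_string(seq)
  annotated_start <- as.integer(annotated_start)
  if (substr(s, annotated_start + 1L, annotated_start + 3L) != "ATG") {
    abort("annotated_start is not an ATG codon")
  }
  call_row <- function(label, site_position = NA_integer_, motif = NA_character_,
                       bracketing_stop = NA_integer_, extension_start = NA_integer_,
                       extension_atg = NA, plus1_open = NA, morf_stop = NA_integer_) {
    tibble(label = label, site_position = site_position, motif = motif,
           bracketing_stop = bracketing_stop, extension_start = extension_start,
           extension_atg = extension_atg, plus1_open = plus1_open,
           morf_stop = morf_stop)
  }

  # main-ORF stop: first in-frame stop at/after the annotated start
  p <- seq.int(annotated_start, by = 3L,
               length.out = max(0L, (nchar(s) - annotated_start) %/% 3L))
  codons <- substring(s, p + 1L, p + 3L)
  st <- which(codons %in% STOP_CODONS)
  if (length(st) == 0L) {
    return(call_row("ambiguous"))
  }
  morf_stop <- p[st[1]]

  # bracketing stop and N-terminal extension
  brk <- NA_integer_
  if (annotated_start >= 3L) {
    up <- seq.int(annotated_start - 3L, annotated_start %% 3L, by = -3L)
    up_cod <- substring(s, up + 1L, up + 3L)
    hit <- which(up_cod %in% STOP_CODONS)  # nearest first
    if (length(hit)) brk <- up[hit[1]]
  }
  ext_start <- if (is.na(brk)) annotated_start %% 3L else brk + 3L

  # (a) in-frame ATG inside the extension?
  ext_pos <- seq.int(ext_start, by = 3L,
                     length.out = max(0L, (annotated_start - ext_start) %/% 3L))
  ext_atg <- length(ext_pos) > 0L &&
    any(substring(s, ext_pos + 1L, ext_pos + 3L) == "ATG")
  if (ext_atg) {
    return(call_row("no_fs", bracketing_stop = brk, extension_start = ext_start,
                    extension_atg = TRUE, morf_stop = morf_stop))
  }

  # (b) upstream ORF in the shifted frame, overlapping the extension,
  # carrying a catalog site; (c) +1 open from the site to the main-ORF stop
  orfs <- find_orfs(s, min_codons = 2L)
  cand_frame <- (annotated_start - 1L) %% 3L
  orfs <- orfs[orfs$frame == cand_frame &
                 orfs$start < annotated_start &
                 orfs$end > ext_start, , drop = FALSE]
  plus1_open <- NA
  if (nrow(orfs)) {
    for (i in seq_len(nrow(orfs))) {
      sites <- scan_shift_sites(s, orfs[i, ], catalog)
      if (nrow(sites) == 0L) next
      for (j in seq_len(nrow(sites))) {
        if (sites$position[j] + 4L >= morf_stop) next
        op <- check_plus1_open(s, sites[j, ], morf_stop)
        plus1_open <- op$open
        if (op$open) {
          return(call_row("requires_fs", site_position = sites$position[j],
                          motif = sites$motif[j], bracketing_stop = brk,
                          extension_start = ext_start, extension_atg = FALSE,
                          plus1_open = TRUE, morf_stop = morf_stop))
        }
      }
    }
  }
  call_row("ambiguous", bracketing_stop = brk, extension_start = ext_start,
           extension_atg = FALSE, plus1_open = plus1_open, morf_stop = morf_stop)
}

#' Classify many homologs at once
#'
#' @param seqs tibble from [read_fasta()] with columns `id`, `seq`.
#' @param annotated_starts named integer vector (by sequence id) or a
#'   vector aligned with `seqs` rows, giving each annotated main-ORF ATG.
#' @param catalog shift-site catalog.
#' @return tibble with one row per sequence: `species` plus the
#'   [classify_homolog()] columns.
#' @export
classify_homologs <- function(seqs, annotated_starts, catalog = shift_site_catalog()) {
  starts <- if (!is.null(names(annotated_starts))) {
    unname(annotated_starts[seqs$id])
  } else {
    annotated_starts
  }
  if (any(is.na(starts))) abort("annotated start missing for some sequences")
  bind_rows(map(seq_len(nrow(seqs)), function(i) {
    res <- classify_homolog(seqs$seq[i], starts[i], catalog)
    mutate(res, species = seqs$id[i], .before = 1L)
  }))
}
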