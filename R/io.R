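#' Read sequences from a FASTA file
#'
#' Reads plain or aligned FASTA. Lowercase letters are uppercased and RNA
#' input (U) is normalized to the internal DNA alphabet (T); whether a
#' record was written with U is remembered in the `input_rna` column so a
#' round trip can restore it. Aligned FASTA may contain `-` gaps when
#' `allow_gaps = TRUE`.
#'
#' @param path path to a FASTA file.
#' @param allow_gaps keep `-` gap characters (aligned FASTA). Default FALSE.
#' @return a tibble with columns `id`, `seq` (uppercase, DNA alphabet) and
#'   `input_rna` (logical).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "AUGC"), f)
#' read_fasta(f)
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- unname(toupper(as.character(ss)))
  if (length(seqs) == 0L) abort(paste0("no FASTA records in ", path))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("empty FASTA record: ", ids[which(empty)[1]]))
  }
  allowed <- c("A", "C", "G", "T", "N", "U", if (allow_gaps) "-")
  bad <- stringr::str_remove_all(seqs, paste0("[", paste(allowed, collapse = ""), "]"))
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    abort(paste0(
      "illegal symbol '", substr(bad[i], 1, 1), "' in FASTA record '", ids[i], "'"
    ))
  }
  input_rna <- stringr::str_detect(seqs, "U")
  tibble(
    id = ids,
    seq = chartr("U", "T", seqs),
    input_rna = input_rna
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs tibble with columns `id` and `seq` (DNA alphabet); an
#'   optional `input_rna` column selects per-record U output when
#'   `as_rna = NULL`.
#' @param path output path.
#' @param as_rna write T as U. `NULL` (default) follows the `input_rna`
#'   column if present, otherwise writes DNA.
#' @param width line width for wrapping.
#' @return the input, invisibly.
#' @export
write_fasta <- function(seqs, path, as_rna = NULL, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  rna <- if (is.null(as_rna)) {
    if ("input_rna" %in% names(seqs)) seqs$input_rna else rep(FALSE, nrow(seqs))
  } else {
    rep(isTRUE(as_rna), nrow(seqs))
  }
  out <- ifelse(rna, chartr("T", "U", seqs$seq), seqs$seq)
  ss <- Biostrings::BStringSet(setNames(out, seqs$id))
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(seqs)
}

#' Read region annotations from a BED3+ file
#'
#' BED columns: transcript, start (0-based), end (exclusive), then an
#' optional name used as the region label and an optional fifth column
#' giving the frame anchor (the 0-based position whose codon position
#' defines sub-codon phase 0 for the region). The default frame anchor is
#' the region start. Overlapping regions are allowed.
#'
#' @param path path to a BED3+ file (tab-separated, no header).
#' @return tibble with columns `transcript`, `start`, `end`, `label`,
#'   `frame_anchor`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) abort(paste0("region file not found: ", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 3L) abort("BED file needs at least 3 columns")
  regions <- tibble(
    transcript = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    label = if (ncol(raw) >= 4L) as.character(raw[[4]]) else NA_character_,
    frame_anchor = if (ncol(raw) >= 5L) as.integer(raw[[5]]) else as.integer(raw[[2]])
  )
  regions$label[is.na(regions$label)] <-
    paste0("region", seq_len(nrow(regions)))[is.na(regions$label)]
  validate_regions(regions)
  regions
}

#' Write region annotations to a BED5 file
#'
#' @param regions tibble as returned by [read_regions()].
#' @param path output path.
#' @return the input, invisibly.
#' @export
write_regions <- function(regions, path) {
  validate_regions(regions)
  utils::write.table(
    regions[, c("transcript", "start", "end", "label", "frame_anchor")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(regions)
}

#' Validate a region table
#'
#' Checks 0 <= start < end and, when sequence lengths are supplied, that
#' intervals and frame anchors fall within their transcript.
#'
#' @param regions region tibble.
#' @param seq_lengths optional named vector of transcript lengths.
#' @return the regions, invisibly; aborts on violation.
#' @export
validate_regions <- function(regions, seq_lengths = NULL) {
  need <- c("transcript", "start", "end", "frame_anchor")
  if (!all(need %in% names(regions))) {
    abort(paste0("region table lacks columns: ",
                 paste(setdiff(need, names(regions)), collapse = ", ")))
  }
  bad <- regions$start < 0 | regions$start >= regions$end
  if (any(bad)) {
    abort(paste0("invalid interval (need 0 <= start < end) in region ",
                 regions$label[which(bad)[1]] %||% which(bad)[1]))
  }
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[regions$transcript]
    if (any(is.na(len))) abort("region transcript absent from sequence set")
    if (any(regions$end > len)) abort("region extends beyond transcript end")
    if (any(regions$frame_anchor < 0 | regions$frame_anchor >= len)) {
      abort("frame_anchor outside transcript")
    }
  }
  invisible(regions)
}

#' Write a per-nucleotide count track as TSV
#'
#' Columns `transcript`, `pos` (0-based), `count`. Serialization is
#' bit-exact for integer and decimal weights: a read-back with
#' [read_counts_track()] reproduces the input.
#'
#' @param track tibble with columns `transcript`, `pos`, `count`.
#' @param path output path.
#' @return the input, invisibly.
#' @export
write_counts_track <- function(track, path) {
  stopifnot(all(c("transcript", "pos", "count") %in% names(track)))
  if (any(track$count < 0)) abort("negative count in track")
  if (any(track$pos < 0)) abort("negative position in track")
  readr::write_tsv(track[, c("transcript", "pos", "count")], path)
  invisible(track)
}

#' Read a per-nucleotide count track from TSV
#'
#' @param path path to a TSV written by [write_counts_track()] (header
#'   `transcript`, `pos`, `count`).
#' @return tibble with columns `transcript`, `pos`, `count`.
#' @export
read_counts_track <- function(path) {
  if (!file.exists(path)) abort(paste0("track file not found: ", path))
  tr <- readr::read_tsv(path, col_types = readr::cols(
    transcript = readr::col_character(),
    pos = readr::col_integer(),
    count = readr::col_double()
  ))
  if (any(tr$count < 0)) abort("negative count in track")
  tr
}

#' Read a footprint table from TSV
#'
#' A footprint table records weighted ribosome-footprint 5' ends:
#' columns `transcript`, `pos` (0-based 5' end), `length` (fragment
#' length, nt) and `count` (weight; defaults to 1 when absent).
#'
#' @param path path to a TSV with a header.
#' @return tibble with columns `transcript`, `pos`, `length`, `count`.
#' @export
read_footprints <- function(path) {
  if (!file.exists(path)) abort(paste0("footprint file not found: ", path))
  fp <- readr::read_tsv(path, col_types = readr::cols())
  need <- c("transcript", "pos", "length")
  if (!all(need %in% names(fp))) {
    abort("footprint table needs columns transcript, pos, length[, count]")
  }
  if (!"count" %in% names(fp)) fp$count <- 1
  if (any(fp$count < 0)) abort("negative footprint weight")
  tibble::as_tibble(fp[, c("transcript", "pos", "length", "count")])
}

#' Write a footprint table as TSV
#'
#' @param footprints tibble with columns `transcript`, `pos`, `length`,
#'   `count`.
#' @param path output path.
#' @return the input, invisibly.
#' @export
write_footprints <- function(footprints, path) {
  stopifnot(all(c("transcript", "pos", "length", "count") %in% names(footprints)))
  readr::write_tsv(footprints, path)
  invisible(footprints)
}
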