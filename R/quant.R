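#' Select footprint lengths and offset 5' ends to the A site
#'
#' Keeps footprints of the selected lengths and moves each 5' end by the
#' per-length offset so that the resulting position is the first
#' nucleotide of the ribosomal A-site codon (the classic choice is 28-nt
#' fragments with a +15 offset). Offset positions falling beyond the
#' transcript end are dropped and the dropped weight is reported.
#'
#' @param footprints tibble with columns `transcript`, `pos` (0-based 5'
#'   end), `length`, `count` (weight).
#' @param lengths integer vector of fragment lengths to keep.
#' @param offsets named numeric vector mapping length (as name) to 5'
#'   offset. Every selected length needs an offset.
#' @param transcript_length optional (named) transcript length(s) used to
#'   drop reads whose A-site position falls off the transcript.
#' @return an A-site count track: tibble `transcript`, `pos`, `count`,
#'   with attributes `dropped_weight` and `settings`.
#' @export
#' @examples
#' fp <- tibble::tibble(transcript = "t", pos = 100, length = 28, count = 1)
#' select_and_offset(fp)
select_and_offset <- function(footprints, lengths = 28L,
                              offsets = c("28" = 15L),
                              transcript_length = NULL) {
  stopifnot(all(c("transcript", "pos", "length", "count") %in% names(footprints)))
  missing_off <- setdiff(as.character(lengths), names(offsets))
  if (length(missing_off)) {
    abort(paste0("no offset defined for length(s): ",
                 paste(missing_off, collapse = ", ")))
  }
  if (any(footprints$count < 0)) abort("negative footprint weight")
  sel <- footprints[footprints$length %in% lengths, , drop = FALSE]
  pos_a <- sel$pos + unname(offsets[as.character(sel$length)])
  keep <- rep(TRUE, nrow(sel))
  if (!is.null(transcript_length)) {
    tlen <- if (is.null(names(transcript_length))) {
      rep(transcript_length[1], nrow(sel))
    } else {
      unname(transcript_length[sel$transcript])
    }
    keep <- pos_a < tlen
  }
  dropped <- sum(sel$count[!keep])
  if (dropped > 0) {
    message(sprintf("select_and_offset: dropped %g read(s) offset beyond transcript end",
                    dropped))
  }
  track <- tibble(transcript = sel$transcript[keep], pos = pos_a[keep],
                  count = sel$count[keep]) |>
    group_by(.data$transcript, .data$pos) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$transcript, .data$pos)
  attr(track, "dropped_weight") <- dropped
  attr(track, "settings") <- list(lengths = lengths, offsets = offsets)
  track
}

#' Tabulate a count track by sub-codon phase within regions
#'
#' For each region the track weight over `[start, end)` is split by
#' sub-codon phase `(pos - frame_anchor) %% 3`. Phases 0/1/2 correspond
#' to display frames 1/2/3. The per-phase mean reads per codon uses the
#' region codon count `floor((end - start) / 3)`.
#'
#' @param track A-site count track (tibble `transcript`, `pos`, `count`).
#' @param regions region tibble (see [read_regions()]).
#' @return long tibble with one row per region and phase: `region`,
#'   `phase`, `count`, `fraction` (NA when the region holds no weight),
#'   `reads_per_codon`, `codons`, `total`.
#' @export
frame_phasing <- function(track, regions) {
  validate_regions(regions)
  rows <- map(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    sel <- track$transcript == r$transcript &
      track$pos >= r$start & track$pos < r$end
    phase <- (track$pos[sel] - r$frame_anchor) %% 3L
    counts <- vapply(0:2, function(ph) sum(track$count[sel][phase == ph]),
                     numeric(1))
    total <- sum(counts)
    codons <- (r$end - r$start) %/% 3L
    tibble(
      region = r$label,
      phase = 0:2,
      count = counts,
      fraction = if (total > 0) counts / total else rep(NA_real_, 3L),
      reads_per_codon = counts / codons,
      codons = codons,
      total = total
    )
  })
  out <- bind_rows(rows)
  if (any(is.na(out$fraction))) {
    warn("some regions hold zero read weight; fractions undefined")
  }
  class(out) <- c("fs_phasing", class(out))
  out
}

#' Estimate +1 frameshift efficiency from an A-site track
#'
#' Implements the density-ratio estimator for programmed +1
#' frameshifting. All reads in phases 0 and +1 of the upstream ORF
#' (ORF1, its own frame anchor) between its start and stop codons are
#' assigned to ORF1, capturing both pre-shift and post-shift ribosomes
#' that initiated there. ORF2 density counts only reads in phase 0 of
#' the ORF2 window anchor — the +1 frame relative to ORF1 — over the
#' window running from the post-shift A-site codon to the last ORF2
#' sense codon. Percent efficiency is
#' `100 * (orf2_reads / orf2_codons) / (orf1_reads / orf1_codons)`.
#'
#' @param track A-site count track.
#' @param orf1_region one-row region tibble anchored at the ORF1 start
#'   codon, spanning its sense codons.
#' @param orf2_region one-row region tibble anchored at the post-shift
#'   A-site codon (so its phase 0 is the +1 frame relative to ORF1).
#' @return an object of class `fs_efficiency`: list with `percent`,
#'   `orf1_density`, `orf2_density`, `orf1_codons`, `orf2_codons`,
#'   `orf1_reads`, `orf2_reads`, `ci` (NULL until [bootstrap_ci()]).
#' @export
estimate_efficiency <- function(track, orf1_region, orf2_region) {
  validate_regions(orf1_region)
  validate_regions(orf2_region)
  r1 <- orf1_region[1, ]
  r2 <- orf2_region[1, ]
  sel1 <- track$transcript == r1$transcript &
    track$pos >= r1$start & track$pos < r1$end &
    ((track$pos - r1$frame_anchor) %% 3L) %in% c(0L, 1L)
  sel2 <- track$transcript == r2$transcript &
    track$pos >= r2$start & track$pos < r2$end &
    ((track$pos - r2$frame_anchor) %% 3L) == 0L
  s1 <- sum(track$count[sel1])
  s2 <- sum(track$count[sel2])
  c1 <- (r1$end - r1$start) %/% 3L
  c2 <- (r2$end - r2$start) %/% 3L
  d1 <- s1 / c1
  d2 <- s2 / c2
  if (d1 == 0) abort("ORF1 density is zero; frameshift efficiency undefined")
  structure(
    list(
      percent = 100 * d2 / d1,
      orf1_density = d1, orf2_density = d2,
      orf1_codons = c1, orf2_codons = c2,
      orf1_reads = s1, orf2_reads = s2,
      orf1_region = r1$label, orf2_region = r2$label,
      ci = NULL
    ),
    class = "fs_efficiency"
  )
}

#' Bootstrap confidence interval for the frameshift-efficiency estimate
#'
#' Resamples footprint reads with replacement (multinomial resampling of
#' read weights), recomputes the efficiency for each replicate, and
#' reports a percentile interval. Replicates with zero ORF1 density are
#' degenerate; they are excluded from the percentiles and counted.
#'
#' @param footprints footprint table (pre-offset 5'-end records).
#' @param orf1_region,orf2_region as in [estimate_efficiency()].
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed; the same seed reproduces the interval.
#' @param lengths,offsets,transcript_length passed to [select_and_offset()].
#' @param conf two-sided confidence level (default 0.95).
#' @return the `fs_efficiency` object for the full data with `ci` set to
#'   a list (`lo`, `hi`, `B`, `seed`, `conf`, `n_degenerate`).
#' @export
bootstrap_ci <- function(footprints, orf1_region, orf2_region, B = 1000L,
                         seed = 1L, lengths = 28L, offsets = c("28" = 15L),
                         transcript_length = NULL, conf = 0.95) {
  if (B < 100L) abort("B must be at least 100")
  track <- select_and_offset(footprints, lengths, offsets, transcript_length)
  est <- estimate_efficiency(track, orf1_region, orf2_region)
  r1 <- orf1_region[1, ]; r2 <- orf2_region[1, ]
  in1 <- track$transcript == r1$transcript &
    track$pos >= r1$start & track$pos < r1$end &
    ((track$pos - r1$frame_anchor) %% 3L) %in% c(0L, 1L)
  in2 <- track$transcript == r2$transcript &
    track$pos >= r2$start & track$pos < r2$end &
    ((track$pos - r2$frame_anchor) %% 3L) == 0L
  n_total <- round(sum(track$count))
  prob <- track$count / sum(track$count)
  w <- withr::with_seed(seed, stats::rmultinom(B, n_total, prob))
  s1 <- as.numeric(crossprod(w, as.numeric(in1)))
  s2 <- as.numeric(crossprod(w, as.numeric(in2)))
  perc <- 100 * (s2 / est$orf2_codons) / (s1 / est$orf1_codons)
  degenerate <- s1 == 0
  qs <- stats::quantile(perc[!degenerate],
                        probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  est$ci <- list(lo = qs[1], hi = qs[2], B = B, seed = seed, conf = conf,
                 n_degenerate = sum(degenerate))
  est
}

#' Percent frameshifting from dual-luciferase reporter readings
#'
#' The downstream-cistron activity (expressed only upon the +1 shift) is
#' normalized to the upstream cistron within each replicate, and the
#' mean normalized ratio of the test construct is divided by that of its
#' in-frame control:
#' `percent = 100 * mean(test down/up) / mean(control down/up)`.
#'
#' @param readings tibble with columns `construct` (`"test"` or
#'   `"control"`), `firefly`, `renilla` — one row per replicate.
#' @param orientation which luciferase is the downstream (frameshift
#'   dependent) cistron.
#' @return one-row tibble: `percent`, `test_mean_ratio`,
#'   `control_mean_ratio`, `n_test`, `n_control`; per-replicate ratios
#'   are kept in the `replicates` attribute for external statistics.
#' @export
#' @examples
#' rd <- tibble::tibble(
#'   construct = c("test", "test", "control", "control"),
#'   firefly = c(12, 11, 25, 24), renilla = c(50, 46, 51, 49)
#' )
#' percent_frameshift_reporter(rd)
percent_frameshift_reporter <- function(readings,
                                        orientation = c("firefly_downstream",
                                                        "renilla_downstream")) {
  orientation <- match.arg(orientation)
  stopifnot(all(c("construct", "firefly", "renilla") %in% names(readings)))
  if (!all(readings$construct %in% c("test", "control"))) {
    abort("construct must be 'test' or 'control'")
  }
  up <- if (orientation == "firefly_downstream") readings$renilla else readings$firefly
  down <- if (orientation == "firefly_downstream") readings$firefly else readings$renilla
  if (any(up <= 0)) abort("normalizing (upstream) cistron readings must be positive")
  ratio <- down / up
  t_r <- ratio[readings$construct == "test"]
  c_r <- ratio[readings$construct == "control"]
  if (length(t_r) == 0L || length(c_r) == 0L) {
    abort("need at least one test and one control replicate")
  }
  if (mean(c_r) <= 0) abort("control ratio must be positive")
  out <- tibble(
    percent = 100 * mean(t_r) / mean(c_r),
    test_mean_ratio = mean(t_r),
    control_mean_ratio = mean(c_r),
    n_test = length(t_r),
    n_control = length(c_r)
  )
  attr(out, "replicates") <- tibble(
    construct = readings$construct,
    ratio = ratio,
    percent_vs_control = 100 * ratio / mean(c_r)
  )
  out
}
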