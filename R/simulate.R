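#' Parameters for the ribosome-footprint simulator
#'
#' Defaults describe a scaled-down Ty1-like dual-ORF locus: true
#' frameshift fraction 10.3%, frame fidelity 0.91 (the fraction of
#' footprints whose recorded A-site position lands in the ribosome's
#' true sub-codon phase), mean depth 1000 reads per codon, gamma-Poisson
#' overdispersion with shape 10 (`Inf` gives Poisson counts), and pause
#' multipliers of 5 at the slowly decoded zero-frame A-site codon and 3
#' at the post-shift +1-frame codon. Footprints are 28 nt with a 15-nt
#' 5'-to-A-site offset.
#'
#' @param p_fs true frameshift fraction in `[0, 1]`.
#' @param fidelity probability a footprint's recorded phase equals the
#'   true phase, in `(1/3, 1]`; errors are split evenly between the two
#'   neighboring positions.
#' @param depth mean reads per codon.
#' @param dispersion gamma shape of per-codon flux noise (`Inf` = Poisson).
#' @param pause_factors named multipliers keyed by absolute codon start
#'   position, or NULL for the default shift-site pauses.
#' @param read_length footprint length emitted.
#' @param offset 5' end to A-site offset.
#' @param seed integer seed driving the whole simulation.
#' @return a list of class `ribo_sim_params`.
#' @export
ribo_sim_params <- function(p_fs = 0.103, fidelity = 0.91, depth = 1000,
                            dispersion = 10, pause_factors = NULL,
                            read_length = 28L, offset = 15L, seed = 1L) {
  stopifnot(p_fs >= 0, p_fs <= 1, fidelity > 1 / 3, fidelity <= 1,
            depth > 0, dispersion > 0)
  structure(
    list(p_fs = p_fs, fidelity = fidelity, depth = depth,
         dispersion = dispersion, pause_factors = pause_factors,
         read_length = as.integer(read_length), offset = as.integer(offset),
         seed = as.integer(seed)),
    class = "ribo_sim_params"
  )
}

# window checks used by the template sampler: no stop codons in the two
# watched frames, no ATG outside the two start codons, no stray catalog
# heptamer. `chars` is the partially filled sequence; windows containing
# NA are skipped (they are re-checked when their last position fills).
template_ok_at <- function(chars, p, geom, patterns) {
  n <- length(chars)
  for (s in max(0L, p - 2L):p) {
    if (s + 3L > n) next
    w <- chars[(s + 1L):(s + 3L)]
    if (anyNA(w)) next
    cod <- paste(w, collapse = "")
    if (cod == "ATG" && !(s %in% geom$allowed_atg)) return(FALSE)
    if (cod %in% STOP_CODONS) {
      in_f0 <- s >= geom$orf1_start && s + 3L <= geom$orf1_sense_end &&
        (s - geom$orf1_start) %% 3L == 0L
      in_p1 <- s >= geom$plus1_open_start && s + 3L <= geom$morf_stop &&
        (s - geom$plus1_open_start) %% 3L == 0L
      if (in_f0 || in_p1) return(FALSE)
    }
  }
  for (s in max(0L, p - 6L):p) {
    if (s + 7L > n) next
    w <- chars[(s + 1L):(s + 7L)]
    if (anyNA(w)) next
    if (s != geom$site_pos && paste(w, collapse = "") %in% patterns) return(FALSE)
  }
  TRUE
}

#' Build a miniature dual-ORF frameshift transcript with known architecture
#'
#' Constructs a transcript mimicking the Ty1/YFS1 locus organisation:
#' a 5' leader; ORF1 beginning with ATG and carrying the Ty1-type
#' CTT-AGG-C heptamer in frame; a stop codon in the +1 frame immediately
#' after the ORF1 start (the bracketing stop of the downstream ORF's
#' N-terminal extension); an open +1 frame running from the post-shift
#' A-site codon through the ORF2 window to the ORF2 stop; and an
#' annotated "main ORF" ATG in the +1 frame downstream of the ORF1 stop.
#' Eight +1-frame codons just after the shift site use 4-fold degenerate
#' codons (Thr/Ala/Gly) reserved for synonymous variation by the family
#' simulator. Filler positions are sampled under rejection so that no
#' stray stop invades the watched frames, no ATG appears outside the two
#' start codons, and no extra catalog heptamer arises.
#'
#' `architecture = "fused"` deletes the nucleotide 3' of the P-site codon
#' (in-frame fusion; no frameshift needed), `"ablated"` mutates the
#' P-site codon CTT to CTA (no functional site).
#'
#' @param architecture one of `"frameshifting"`, `"fused"`, `"ablated"`.
#' @param orf1_codons sense codons in ORF1 (including the ATG).
#' @param shift_codon 0-based codon index of the P-site (CTT) codon.
#' @param orf2_codons codons in the ORF2 window (post-shift A-site codon
#'   through last sense codon).
#' @param leader,trailer flanking lengths in nt.
#' @param seed integer seed for the filler sampler.
#' @return list with elements `transcript` (one-row tibble `id`, `seq`),
#'   `regions` (ORF1 and ORF2 rows), `site` (scan result, one row for
#'   the frameshifting architecture), `annotated_start`, `label`
#'   (ground-truth homolog call), and `geometry` (internal positions).
#' @export
make_template_transcript <- function(architecture = c("frameshifting", "fused",
                                                      "ablated"),
                                     orf1_codons = 200L, shift_codon = 60L,
                                     orf2_codons = 150L, leader = 20L,
                                     trailer = 20L, seed = 101L) {
  architecture <- match.arg(architecture)
  stopifnot(leader >= 18L, shift_codon >= 2L, orf1_codons >= shift_codon + 12L,
            trailer >= 3L)
  orf1_start <- leader
  orf1_sense_end <- orf1_start + 3L * orf1_codons
  site_pos <- orf1_start + 3L * shift_codon
  a1 <- site_pos + 7L - 3L
  # annotated main-ORF ATG: first +1-frame codon clear of the ORF1 stop,
  # plus one spacer codon
  j_ann <- ceiling((orf1_sense_end + 3L - a1) / 3) + 1L
  stopifnot(j_ann + 2L < orf2_codons)
  ann_start <- a1 + 3L * j_ann
  morf_stop <- a1 + 3L * orf2_codons
  total <- morf_stop + 3L + trailer

  geom <- list(
    orf1_start = orf1_start, orf1_sense_end = orf1_sense_end,
    site_pos = site_pos, a1 = a1, ann_start = ann_start,
    morf_stop = morf_stop, plus1_open_start = orf1_start + 4L,
    allowed_atg = c(orf1_start, ann_start), total = total,
    orf1_codons = orf1_codons, orf2_codons = orf2_codons,
    syn_codon_starts = a1 + 3L * (1:8)
  )
  patterns <- shift_site_catalog()$pattern

  place <- function(chars, at, s) {
    chars[(at + 1L):(at + nchar(s))] <- strsplit(s, "")[[1]]
    chars
  }
  syn_template <- c("ACT", "GCT", "GGT", "ACC", "GCA", "GGA", "ACA", "GCC")

  build <- function() {
    chars <- rep(NA_character_, total)
    chars <- place(chars, leader - 6L, "TAA")          # leader in-frame stop
    chars <- place(chars, orf1_start, "ATG")
    chars <- place(chars, orf1_start + 3L, "AAA")       # yields +1-frame TGA
    chars <- place(chars, site_pos, "CTTAGGC")
    for (k in 1:8) chars <- place(chars, geom$syn_codon_starts[k], syn_template[k])
    chars <- place(chars, orf1_sense_end, "TAA")        # ORF1 stop
    chars <- place(chars, ann_start, "ATG")
    chars <- place(chars, morf_stop, "TAA")             # ORF2 stop
    free <- which(is.na(chars)) - 1L
    for (p in free) {
      cands <- sample(c("A", "C", "G", "T"))
      placed <- FALSE
      for (x in cands) {
        chars[p + 1L] <- x
        if (template_ok_at(chars, p, geom, patterns)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        chars[p + 1L] <- NA_character_
        return(NULL)
      }
    }
    paste(chars, collapse = "")
  }

  s <- withr::with_seed(seed, {
    out <- NULL
    for (attempt in 1:100) {
      out <- build()
      if (!is.null(out)) break
    }
    out
  })
  if (is.null(s)) abort("template construction failed; relax geometry")

  regions <- tibble(
    transcript = "template",
    start = c(orf1_start, a1),
    end = c(orf1_sense_end, morf_stop),
    label = c("ORF1", "ORF2"),
    frame_anchor = c(orf1_start, a1)
  )
  site <- scan_shift_sites(s, list(start = orf1_start, end = orf1_sense_end + 3L))
  stopifnot(nrow(site) == 1L, site$position == site_pos)

  if (architecture == "fused") {
    s <- fuse_inframe(s, site)
    site <- site[0, ]
    geom$ann_start <- ann_start - 1L
    geom$morf_stop <- morf_stop - 1L
    geom$allowed_atg <- c(orf1_start, ann_start - 1L)
    geom$syn_codon_starts <- geom$syn_codon_starts - 1L
    label <- "no_fs"
    ann <- ann_start - 1L
  } else if (architecture == "ablated") {
    substr(s, site_pos + 3L, site_pos + 3L) <- "A"   # CTT -> CTA
    site <- site[0, ]
    label <- "ambiguous"
    ann <- ann_start
  } else {
    label <- "requires_fs"
    ann <- ann_start
  }

  list(
    transcript = tibble(id = "template", seq = s, input_rna = FALSE),
    regions = regions,
    site = site,
    annotated_start = ann,
    label = label,
    geometry = geom
  )
}

# enumerate the A-site codons the two ribosome populations traverse:
# returns tibble(pos, mean) of expected reads per A-site codon start.
path_means <- function(regions, site, params) {
  r1 <- regions[regions$label == "ORF1", ]
  r2 <- regions[regions$label == "ORF2", ]
  orf1_start <- r1$start
  L1 <- (r1$end - r1$start) %/% 3L
  cP <- (site$position - orf1_start) %/% 3L
  cA <- cP + 1L
  a1 <- site$position + 4L
  m2 <- (r2$end - r2$start) %/% 3L
  pause <- params$pause_factors %||%
    setNames(c(5, 3), c(site$position + 3L, a1))
  look <- function(pos) {
    m <- pause[as.character(pos)]
    ifelse(is.na(m), 1, m)
  }
  f0 <- tibble(
    pos = orf1_start + 3L * seq.int(1L, L1 - 1L),
    w = ifelse(seq.int(1L, L1 - 1L) <= cA, 1, 1 - params$p_fs)
  )
  p1 <- tibble(
    pos = a1 + 3L * seq.int(0L, m2 - 1L),
    w = params$p_fs
  )
  paths <- bind_rows(f0, p1)
  mutate(paths, mean = params$depth * .data$w * look(.data$pos))[, c("pos", "mean")]
}

#' Simulate a ribosome-footprint table over a dual-ORF transcript
#'
#' Per A-site codon along the two ribosome paths (ORF1 frame 0 for all
#' initiating ribosomes; the +1 frame from the post-shift A-site codon
#' for the fraction `p_fs` that shifts), read counts are drawn
#' gamma-Poisson (negative binomial) around `depth x pause`. Each read's
#' recorded A-site position equals the true one with probability
#' `fidelity`, otherwise it moves one nucleotide left or right with equal
#' probability. Reads are emitted as 5' positions (`A-site - offset`)
#' with the configured length. One seed drives the whole simulation.
#'
#' @param transcript one-row tibble (`id`, `seq`) or sequence string.
#' @param regions region tibble with `ORF1` and `ORF2` rows (see
#'   [make_template_transcript()]).
#' @param site shift-site row (needs `position`).
#' @param params a [ribo_sim_params()] object.
#' @return list with `footprints` (tibble `transcript`, `pos`, `length`,
#'   `count`) and `truth` (parameters plus the analytic expectation of
#'   the efficiency estimator, see [expected_efficiency()]).
#' @export
simulate_footprints <- function(transcript, regions, site, params = ribo_sim_params()) {
  s <- as_seq_string(transcript)
  id <- if (is.data.frame(transcript)) transcript$id[1] else "transcript"
  paths <- path_means(regions, site, params)
  f <- params$fidelity
  sim <- withr::with_seed(params$seed, {
    n <- nrow(paths)
    counts <- if (is.infinite(params$dispersion)) {
      rpois(n, paths$mean)
    } else {
      stats::rnbinom(n, size = params$dispersion, mu = paths$mean)
    }
    stay <- rbinom(n, counts, f)
    plus <- rbinom(n, counts - stay, 0.5)
    minus <- counts - stay - plus
    tibble(
      pos = c(paths$pos, paths$pos + 1L, paths$pos - 1L),
      count = c(stay, plus, minus)
    )
  })
  fp <- sim |>
    filter(.data$count > 0L) |>
    mutate(pos = .data$pos - params$offset) |>
    filter(.data$pos >= 0L, .data$pos + params$read_length <= nchar(s)) |>
    group_by(.data$pos) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(transcript = id, length = params$read_length) |>
    select("transcript", "pos", "length", "count") |>
    arrange(.data$pos)
  truth <- list(
    p_fs = params$p_fs, fidelity = f, depth = params$depth,
    dispersion = params$dispersion, seed = params$seed,
    expected_percent = expected_efficiency(regions, site, params)
  )
  list(footprints = fp, truth = truth)
}

#' Analytic expectation of the efficiency estimator under the simulator
#'
#' Computes, without any sampling, the expected value of the
#' density-ratio estimator for a transcript simulated by
#' [simulate_footprints()]: the expected read mass of every A-site codon
#' on the two ribosome paths is spread over recorded positions
#' (`fidelity` in place, `(1 - fidelity)/2` one nucleotide to either
#' side), and the region/phase sums of the estimator definition are
#' evaluated on that expected track. This is the closed-form
#' leakage-bias oracle: with `fidelity < 1`, off-frame ORF1 ribosomes
#' leak into the +1-frame ORF2 window and bias the estimator upward.
#' The ratio of expectations approximates the expectation of the ratio
#' to O(1/reads).
#'
#' @param regions region tibble with `ORF1` and `ORF2` rows.
#' @param site shift-site row.
#' @param params a [ribo_sim_params()] object.
#' @return expected percent efficiency (scalar).
#' @export
expected_efficiency <- function(regions, site, params = ribo_sim_params()) {
  paths <- path_means(regions, site, params)
  f <- params$fidelity
  exp_track <- tibble(
    pos = c(paths$pos, paths$pos + 1L, paths$pos - 1L),
    w = c(paths$mean * f, paths$mean * (1 - f) / 2, paths$mean * (1 - f) / 2)
  )
  r1 <- regions[regions$label == "ORF1", ]
  r2 <- regions[regions$label == "ORF2", ]
  ph1 <- (exp_track$pos - r1$frame_anchor) %% 3L
  ph2 <- (exp_track$pos - r2$frame_anchor) %% 3L
  s1 <- sum(exp_track$w[exp_track$pos >= r1$start & exp_track$pos < r1$end &
                          ph1 %in% c(0L, 1L)])
  s2 <- sum(exp_track$w[exp_track$pos >= r2$start & exp_track$pos < r2$end &
                          ph2 == 0L])
  c1 <- (r1$end - r1$start) %/% 3L
  c2 <- (r2$end - r2$start) %/% 3L
  100 * (s2 / c2) / (s1 / c1)
}

#' Parameters for the homolog-family simulator
#'
#' @param n_species number of homolog sequences to generate.
#' @param sub_rate per-site substitution probability at unconstrained
#'   positions.
#' @param architectures character vector (recycled over species) of
#'   `"frameshifting"`, `"fused"`, `"ablated"`.
#' @param syn_rate per-species probability of a synonymous third-position
#'   substitution at each designated +1-frame codon.
#' @param seed integer seed.
#' @param template_seed seed for the shared ancestral template.
#' @return list of class `family_sim_params`.
#' @export
family_sim_params <- function(n_species = 12L, sub_rate = 0.03,
                              architectures = "frameshifting",
                              syn_rate = 0.5, seed = 1L, template_seed = 101L) {
  stopifnot(n_species >= 2L, sub_rate >= 0, sub_rate <= 1,
            syn_rate >= 0, syn_rate <= 1,
            all(architectures %in% c("frameshifting", "fused", "ablated")))
  structure(
    list(n_species = as.integer(n_species), sub_rate = sub_rate,
         architectures = rep_len(architectures, n_species),
         syn_rate = syn_rate, seed = as.integer(seed),
         template_seed = as.integer(template_seed)),
    class = "family_sim_params"
  )
}

# positions (0-based) that must never mutate, per architecture
family_constrained <- function(geom, architecture) {
  base <- c(
    (geom$orf1_start - 6L):(geom$orf1_start - 4L),    # leader stop
    geom$orf1_start:(geom$orf1_start + 3L),           # ATG + bracketing-stop A
    geom$site_pos:(geom$site_pos + 6L),               # heptamer
    geom$orf1_sense_end:(geom$orf1_sense_end + 2L),   # ORF1 stop
    geom$ann_start:(geom$ann_start + 2L),             # annotated ATG
    geom$morf_stop:(geom$morf_stop + 2L),             # ORF2 stop
    # first two nt of each designated synonymous codon (fix the amino acid)
    as.vector(outer(0:1, geom$syn_codon_starts, `+`))
  )
  if (architecture == "fused") {
    # coordinates 3' of the deleted nucleotide shift by -1
    cut <- geom$site_pos + 3L
    base <- ifelse(base > cut, base - 1L, base)
    base <- setdiff(base, cut)
  }
  sort(unique(base))
}

# architecture-preserving invariants checked after mutating one homolog;
# `geom` is always the base (frameshifting) geometry, coordinate shifts
# for the fused deletion are applied here.
family_ok <- function(s, geom, architecture) {
  allowed_atg <- if (architecture == "fused") {
    c(geom$orf1_start, geom$ann_start - 1L)
  } else {
    c(geom$orf1_start, geom$ann_start)
  }
  starts0 <- seq_len(nchar(s) - 2L) - 1L
  w3 <- substring(s, starts0 + 1L, starts0 + 3L)
  if (any(w3 == "ATG" & !(starts0 %in% allowed_atg))) return(FALSE)
  # no stray catalog heptamer
  pat <- shift_site_catalog()$pattern
  starts7 <- seq_len(nchar(s) - 6L) - 1L
  w7 <- substring(s, starts7 + 1L, starts7 + 7L)
  site_keep <- if (architecture == "frameshifting") geom$site_pos else -1L
  if (any(w7 %in% pat & starts7 != site_keep)) return(FALSE)
  if (architecture %in% c("frameshifting", "ablated")) {
    # ORF1 frame 0 free of internal stops
    f0 <- seq.int(geom$orf1_start, geom$orf1_sense_end - 3L, by = 3L)
    if (any(substring(s, f0 + 1L, f0 + 3L) %in% STOP_CODONS)) return(FALSE)
    # +1 frame open from just after the bracketing stop to the ORF2 stop,
    # except the ablation-induced stop inside the heptamer
    p1 <- seq.int(geom$plus1_open_start, geom$morf_stop - 3L, by = 3L)
    if (architecture == "ablated") p1 <- setdiff(p1, geom$site_pos + 1L)
    if (any(substring(s, p1 + 1L, p1 + 3L) %in% STOP_CODONS)) return(FALSE)
  } else {
    # fused frame open from the ORF1 ATG to the stop at morf_stop - 1
    ff <- seq.int(geom$orf1_start, geom$morf_stop - 4L, by = 3L)
    if (any(substring(s, ff + 1L, ff + 3L) %in% STOP_CODONS)) return(FALSE)
  }
  TRUE
}

#' Simulate a homolog family with known frameshift architecture
#'
#' Derives each homolog from a shared ancestral template (see
#' [make_template_transcript()]) by i.i.d. substitutions at
#' unconstrained positions. Architecture-defining positions (start and
#' stop codons, the bracketing stop, the heptamer) never mutate, and a
#' proposed homolog is rejected and resampled if a substitution
#' nonetheless breaks the architecture (stop invading a constrained-open
#' frame, stray ATG or catalog heptamer); the rejection count is
#' reported. Eight designated +1-frame codons receive only synonymous
#' third-position substitutions, planting the protein-level conservation
#' signature that [synonymous_frame_signature()] detects. Because only
#' substitutions occur (plus the known single-nucleotide deletion of
#' fused homologs), the true alignment is the sequences themselves with
#' one gap column inserted for fused rows.
#'
#' @param params a [family_sim_params()] object.
#' @return list with `sequences` (tibble `species`, `seq`,
#'   `architecture`, `label`, `annotated_start`), `alignment` (tibble
#'   `species`, `seq`, gapped true nucleotide alignment), `template`
#'   (the ancestral [make_template_transcript()] output), and attributes
#'   via `truth`: designated synonymous codon starts, rejection count.
#' @export
simulate_homolog_family <- function(params = family_sim_params()) {
  base <- make_template_transcript(seed = params$template_seed)
  geom <- base$geometry
  variants <- list(
    frameshifting = base,
    fused = NULL, ablated = NULL
  )
  for (a in setdiff(unique(params$architectures), "frameshifting")) {
    variants[[a]] <- make_template_transcript(architecture = a,
                                              seed = params$template_seed)
  }
  labels <- c(frameshifting = "requires_fs", fused = "no_fs",
              ablated = "ambiguous")
  n_rejected <- 0L
  rows <- withr::with_seed(params$seed, {
    map(seq_len(params$n_species), function(i) {
      arch <- params$architectures[i]
      anc <- variants[[arch]]
      anc_seq <- anc$transcript$seq
      constrained <- family_constrained(geom, arch)
      cut <- geom$site_pos + 3L
      syn_starts <- geom$syn_codon_starts + if (arch == "fused") -1L else 0L
      third <- syn_starts + 2L
      free <- setdiff(seq_len(nchar(anc_seq)) - 1L, c(constrained, third))
      for (attempt in 1:200) {
        chars <- strsplit(anc_seq, "")[[1]]
        mut <- free[runif(length(free)) < params$sub_rate]
        if (length(mut)) {
          chars[mut + 1L] <- vapply(chars[mut + 1L], function(x) {
            sample(setdiff(c("A", "C", "G", "T"), x), 1L)
          }, character(1))
        }
        syn_mut <- third[runif(length(third)) < params$syn_rate]
        if (length(syn_mut)) {
          chars[syn_mut + 1L] <- vapply(chars[syn_mut + 1L], function(x) {
            sample(setdiff(c("A", "C", "G", "T"), x), 1L)  # 4-fold degenerate
          }, character(1))
        }
        s <- paste(chars, collapse = "")
        if (family_ok(s, geom, arch)) {
          return(tibble(
            species = sprintf("sp%02d", i), seq = s, architecture = arch,
            label = unname(labels[arch]), annotated_start = anc$annotated_start
          ))
        }
        n_rejected <<- n_rejected + 1L
      }
      abort("homolog resampling failed; lower sub_rate")
    })
  })
  sequences <- bind_rows(rows)
  # true alignment: insert a gap column at the fused deletion point
  cut <- geom$site_pos + 3L
  aln <- mutate(sequences,
    seq = if_else(.data$architecture == "fused",
                  paste0(substr(.data$seq, 1L, cut), "-",
                         substr(.data$seq, cut + 1L, nchar(.data$seq))),
                  .data$seq)
  )[, c("species", "seq")]
  out <- list(
    sequences = sequences,
    alignment = aln,
    template = base,
    truth = list(
      labels = setNames(sequences$label, sequences$species),
      syn_codon_starts = geom$syn_codon_starts,
      n_rejected = n_rejected,
      params = params
    )
  )
  out
}
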