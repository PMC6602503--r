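# Seeded generators for synthetic loci and training data.  These define the
# study conditions for every simulation in the package: random background
# sequence, loci with an implanted dominant microhomology, and a generative
# repair-fraction model with known signal for regressor recovery tests.

#' Generate a random locus
#'
#' I.i.d. bases at a requested GC content, optionally annotated with exons
#' and a CDS phase origin.  Identical seeds give identical records.
#'
#' @param length Sequence length in nt.
#' @param gc_content Fraction of G+C in \[0, 1\] (default 0.5).
#' @param seed Optional integer seed.
#' @param exons Optional exon intervals (0-based half-open), as in
#'   [seq_record].
#' @param cds_phase_origin Optional 0-based codon-phase-0 index.
#' @param id Record label.
#' @return A [seq_record].
#' @export
random_locus <- function(length, gc_content = 0.5, seed = NULL, exons = NULL,
                         cds_phase_origin = NULL, id = "synthetic_locus") {
  stopifnot(length >= 1L, gc_content >= 0, gc_content <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc_content) / 2, gc_content / 2,
                           gc_content / 2, (1 - gc_content) / 2))
  seq_record(paste(bases, collapse = ""), id = id, exons = exons,
             cds_phase_origin = cds_phase_origin)
}

#' Implant a dominant microhomology into random background
#'
#' Writes two copies of `arm` into a random locus so that the implied MMEJ
#' deletion has the requested length and spans the stated cut, then
#' rejection-samples the background until the implanted pattern is the
#' strict top scorer among all de-duplicated patterns at that cut.  The
#' generator and the enumeration kernel therefore cross-validate each other:
#' the returned ground truth is guaranteed to be recoverable.
#'
#' @param arm DNA string, length >= 2 (the microhomology to implant).
#' @param deletion_length Deletion length in bp (>= arm length).
#' @param dsb_offset Cut position relative to the left arm start, in
#'   (0, deletion_length + arm length); default centres the cut in the
#'   deleted span.
#' @param length Locus length (default 80).
#' @param gc_content Background GC content (default 0.4, mildly AT-rich so
#'   the implant dominates quickly).
#' @param seed Integer seed.
#' @param max_tries Resampling budget before giving up.
#' @return List with `record` (the locus), `dsb_index` (0-based cut) and
#'   `pattern` (one-row data frame: the implanted pattern as enumerated).
#' @export
implant_microhomology <- function(arm, deletion_length,
                                  dsb_offset = NULL, length = 80L,
                                  gc_content = 0.4, seed = 1L,
                                  max_tries = 200L) {
  arm <- toupper(arm)
  validate_dna(arm, what = "arm")
  arm_len <- nchar(arm)
  if (arm_len < 2L) stop("arm must be at least 2 nt")
  if (deletion_length < arm_len) {
    stop("deletion_length must be >= the arm length")
  }
  if (is.null(dsb_offset)) dsb_offset <- (deletion_length + arm_len) %/% 2L
  if (dsb_offset <= 0L || dsb_offset >= deletion_length + arm_len) {
    stop("dsb_offset must lie strictly inside the deleted span")
  }
  span <- deletion_length + arm_len        # left arm start .. right arm end
  if (span + 2L > length) stop("arm/deletion geometry exceeds the locus length")
  left_start <- max(1L, min(length %/% 2L - dsb_offset, length - span - 1L))
  dsb <- left_start + dsb_offset

  set.seed(as.integer(seed))
  for (try in seq_len(max_tries)) {
    rec <- random_locus(length, gc_content)
    chars <- strsplit(rec$sequence, "", fixed = TRUE)[[1]]
    arm_chars <- strsplit(arm, "", fixed = TRUE)[[1]]
    chars[(left_start + 1L):(left_start + arm_len)] <- arm_chars
    right_start <- left_start + deletion_length
    chars[(right_start + 1L):(right_start + arm_len)] <- arm_chars
    seq <- paste(chars, collapse = "")
    pats <- deduplicate_patterns(enumerate_patterns(seq, dsb), seq)
    if (!nrow(pats)) next
    ord <- order(-pats$score)
    top <- pats[ord[1L], ]
    strict <- nrow(pats) == 1L || top$score > pats$score[ord[2L]]
    if (strict && top$left_start == left_start &&
        top$right_start == right_start && top$arm_length == arm_len) {
      return(list(record = seq_record(seq, id = "implanted_locus"),
                  dsb_index = dsb, pattern = top))
    }
  }
  stop("could not place a dominant implant in ", max_tries,
       " background samples; relax the geometry or GC content")
}

# Generative model constants for the synthetic repair-fraction data: the
# latent MMEJ propensity rises with the strength of the best microhomology
# (score_max) and with the longest arm available.  Chosen once so that
# random 60-120 nt sequences span roughly 0.1-0.9 after the logistic.
medjed_synth_coefs <- function() {
  c(intercept = -6.0, score_max = 0.007, arm_length_max = 0.6)
}

#' Generate a synthetic repair-fraction training table
#'
#' Emulates the structure of an experimental deletion-outcome table:
#' sequences of varying microhomology strength paired with an observed MMEJ
#' deletion fraction.  Targets follow a logistic function of `score_max` and
#' `arm_length_max` (see `medjed_synth_coefs`) plus Gaussian noise, clipped
#' to \[0, 1\].  Fully seeded and deterministic.
#'
#' @param n Number of sites (>= 20).
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise standard deviation on the fraction scale
#'   (default 0.05).
#' @param length_range Even sequence lengths are drawn from this range
#'   (default 60-120 nt).
#' @param config List from [gss_config].
#' @return List with `features` (n-row data frame of the six features),
#'   `targets` (numeric vector) and `sequences` (character vector).
#' @export
medjed_dataset <- function(n, seed = 1L, noise_sd = 0.05,
                           length_range = c(60L, 120L),
                           config = gss_config()) {
  stopifnot(n >= 20L, noise_sd >= 0)
  set.seed(as.integer(seed))
  lens <- seq.int(length_range[1], length_range[2], by = 2L)
  feats <- vector("list", n)
  seqs <- character(n)
  for (k in seq_len(n)) {
    repeat {
      len <- sample(lens, 1L)
      gc <- stats::runif(1, 0.30, 0.65)
      rec <- random_locus(len, gc)
      f <- tryCatch(medjed_features(rec$sequence, config),
                    error = function(e) NULL)
      if (!is.null(f)) { feats[[k]] <- f; seqs[k] <- rec$sequence; break }
    }
  }
  feats <- do.call(rbind, feats)
  co <- medjed_synth_coefs()
  eta <- co["intercept"] + co["score_max"] * feats$score_max +
    co["arm_length_max"] * feats$arm_length_max
  targets <- stats::plogis(eta) + stats::rnorm(n, 0, noise_sd)
  targets <- pmin(pmax(targets, 0), 1)
  list(features = feats, targets = unname(targets), sequences = seqs)
}
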