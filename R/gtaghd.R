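# Homology-arm oligonucleotide design for HMEJ-based knock-in: locate the
# integration cut from a guide, extract flanking homology arms (with
# reading-frame repair), and dress them with plasmid-series cloning adapters.

#' Locate the integration cut site from a guide sequence
#'
#' Searches both strands for the 20-nt protospacer, requires exactly one hit
#' genome-wide within the record, and places a Cas9-like cut 3 bp from the
#' PAM-proximal end (between protospacer positions 17 and 18), mapped to
#' forward-strand coordinates.  No PAM check is performed, so any Cas9-like
#' nuclease may be used.
#'
#' @param record A [seq_record].
#' @param guide 20-nt DNA string (no PAM), unambiguous bases.
#' @return List with `dsb_index` (0-based forward-strand cut), `strand` of
#'   the match and `guide`.
#' @export
locate_integration_site <- function(record, guide) {
  stopifnot(inherits(record, "seq_record"))
  guide <- toupper(guide)
  if (nchar(guide) != 20L) stop("guide must be exactly 20 nt")
  validate_dna(guide, allow_n = FALSE, what = "guide")
  seq <- record$sequence
  n <- nchar(seq)
  find_hits <- function(s) {
    if (n < 20L) return(integer(0))
    starts <- 1:(n - 19L)
    starts[substring(s, starts, starts + 19L) == guide] - 1L   # 0-based
  }
  fwd <- find_hits(seq)
  rev <- find_hits(reverse_complement(seq))
  total <- length(fwd) + length(rev)
  if (total == 0L) stop("guide not found in the provided sequence")
  if (total > 1L) {
    stop("guide not unique: found ", total, " matches across both strands")
  }
  if (length(fwd)) {
    list(dsb_index = fwd + 17L, strand = "forward", guide = guide)
  } else {
    list(dsb_index = n - (rev + 17L), strand = "complement", guide = guide)
  }
}

#' Extract homology arms around the integration cut
#'
#' The 5' arm is the `arm_length` bases immediately upstream of the cut and
#' the 3' arm the `arm_length` bases immediately downstream.  When the record
#' carries CDS annotation and the cut falls at codon phase 1 or 2, `3 - phase`
#' bases duplicated from the genome immediately downstream of the cut are
#' appended to the 5' arm (default side) so the cargo junction lands on a
#' codon boundary while leaving the genomic sequence intact.  Without CDS
#' annotation frame repair is disabled with a warning.
#'
#' @param record A [seq_record].
#' @param site List from [locate_integration_site] (or any list with a
#'   `dsb_index` field).
#' @param arm_length Homology length in bp.
#' @param pad_side `"five"` (append pad to the 5' arm) or `"three"` (prepend
#'   to the 3' arm).
#' @return List with `five_arm`, `three_arm`, `frame_pad` (0-2).
#' @export
design_arms <- function(record, site, arm_length, pad_side = c("five", "three")) {
  stopifnot(inherits(record, "seq_record"), arm_length >= 1L)
  pad_side <- match.arg(pad_side)
  dsb <- as.integer(site$dsb_index)
  n <- nchar(record$sequence)
  max_arm <- min(dsb, n - dsb)
  if (arm_length > max_arm) {
    stop("arm_length ", arm_length, " overruns the sequence; the maximum ",
         "feasible arm_length at this site is ", max_arm)
  }
  five_arm <- substr(record$sequence, dsb - arm_length + 1L, dsb)
  three_arm <- substr(record$sequence, dsb + 1L, dsb + arm_length)
  frame_pad <- 0L
  if (is.null(record$cds_phase_origin)) {
    warning("no CDS annotation: reading-frame repair disabled (frame_pad = 0)")
  } else {
    phase <- (dsb - record$cds_phase_origin) %% 3L
    if (phase != 0L) {
      frame_pad <- 3L - phase
      pad <- substr(record$sequence, dsb + 1L, dsb + frame_pad)
      if (nchar(pad) < frame_pad) {
        stop("not enough downstream sequence for the frame-repair pad")
      }
      if (pad_side == "five") five_arm <- paste0(five_arm, pad)
      else three_arm <- paste0(pad, three_arm)
    }
  }
  list(five_arm = five_arm, three_arm = three_arm, frame_pad = frame_pad,
       pad_side = pad_side)
}

#' Built-in plasmid-series adapter configurations
#'
#' Each series defines, for the 5' and 3' homology arms, the sticky-end /
#' restriction adapters prepended and appended to the forward and reverse
#' oligos, plus an optional plasmid template used for map output.  The
#' shipped series are synthetic, documented examples meant to be edited to
#' match the user's vector system; none reproduce a commercial vector.
#' Adapter strings may contain the placeholders `{guide}` and `{guide_rc}`,
#' replaced by the custom cargo-freeing guide and its reverse complement
#' (required by the `custom` series).
#'
#' @return Named list of series configurations.
#' @export
gtaghd_series <- function() {
  empty_pair <- list(forward_prefix = "", forward_suffix = "",
                     reverse_prefix = "", reverse_suffix = "")
  list(
    blunt = list(five = empty_pair, three = empty_pair, template = NULL),
    goldengate_demo = list(
      five = list(forward_prefix = "AAAA", forward_suffix = "",
                  reverse_prefix = "TTTT", reverse_suffix = ""),
      three = list(forward_prefix = "GGGG", forward_suffix = "",
                   reverse_prefix = "CCCC", reverse_suffix = ""),
      template = list(
        upstream = "TTGACGGCTAGCTCAGTCCTAGGTACAGTGCTAGC",
        cargo = "ATGGTGAGCAAGGGCGAGGAGCTGTTCACCGGGGTG",
        downstream = "CGCTGATAGTGCTAGTGTAGATCGCTACTAGAGC"
      )
    ),
    custom = list(
      five = list(forward_prefix = "{guide_rc}", forward_suffix = "",
                  reverse_prefix = "", reverse_suffix = "{guide}"),
      three = list(forward_prefix = "", forward_suffix = "{guide_rc}",
                   reverse_prefix = "{guide}", reverse_suffix = ""),
      template = NULL
    )
  )
}

fill_adapter <- function(x, custom_guide) {
  if (!grepl("{", x, fixed = TRUE)) return(toupper(x))
  if (is.null(custom_guide)) {
    stop("this series requires custom_guide (the cargo-freeing gRNA)")
  }
  x <- gsub("{guide_rc}", reverse_complement(toupper(custom_guide)), x,
            fixed = TRUE)
  x <- gsub("{guide}", toupper(custom_guide), x, fixed = TRUE)
  toupper(x)
}

#' Assemble the four ready-to-order oligonucleotides
#'
#' Each homology arm becomes an annealing forward/reverse pair: the forward
#' oligo carries the arm, the reverse its reverse complement, and the
#' series-specific adapters are added verbatim.  Stripping the adapters from
#' any pair recovers exact reverse complements.
#'
#' @param arms List from [design_arms].
#' @param series Name of a plasmid series in `series_config`.
#' @param custom_guide gRNA freeing the cargo from a custom plasmid; required
#'   when the series adapters use guide placeholders.
#' @param series_config Named list from [gtaghd_series] (or user-edited).
#' @return An object of class `oligo_set` with fields `five_prime_forward`,
#'   `five_prime_reverse`, `three_prime_forward`, `three_prime_reverse`,
#'   `arm_length`, `frame_pad`, `series` and the raw `arms`.
#' @export
assemble_oligos <- function(arms, series = "blunt", custom_guide = NULL,
                            series_config = gtaghd_series()) {
  if (!series %in% names(series_config)) {
    stop("unknown plasmid series '", series, "'; available: ",
         paste(names(series_config), collapse = ", "))
  }
  cfg <- series_config[[series]]
  mk_pair <- function(arm, ad) {
    list(forward = paste0(fill_adapter(ad$forward_prefix, custom_guide), arm,
                          fill_adapter(ad$forward_suffix, custom_guide)),
         reverse = paste0(fill_adapter(ad$reverse_prefix, custom_guide),
                          reverse_complement(arm),
                          fill_adapter(ad$reverse_suffix, custom_guide)))
  }
  five <- mk_pair(arms$five_arm, cfg$five)
  three <- mk_pair(arms$three_arm, cfg$three)
  structure(
    list(five_prime_forward = five$forward,
         five_prime_reverse = five$reverse,
         three_prime_forward = three$forward,
         three_prime_reverse = three$reverse,
         arm_length = (nchar(arms$five_arm) + nchar(arms$three_arm) -
                         arms$frame_pad) %/% 2L,
         frame_pad = arms$frame_pad,
         series = series,
         arms = arms),
    class = "oligo_set"
  )
}

#' @export
print.oligo_set <- function(x, ...) {
  cat(sprintf("<oligo_set> series '%s', arm %d bp, frame pad %d\n",
              x$series, x$arm_length, x$frame_pad))
  cat(sprintf("  5F %s\n  5R %s\n  3F %s\n  3R %s\n",
              x$five_prime_forward, x$five_prime_reverse,
              x$three_prime_forward, x$three_prime_reverse))
  invisible(x)
}

#' Write oligo text output and optional plasmid map
#'
#' Writes `<prefix>_oligos.txt` with the four labelled sequences (5F/5R/3F/3R)
#' and, when the series defines a plasmid template, a GenBank-format map
#' `<prefix>_map.gb` with the homology arms and cargo annotated as features.
#'
#' @param oligos An `oligo_set` from [assemble_oligos].
#' @param path_prefix Output path prefix.
#' @param series_config Named list from [gtaghd_series].
#' @return Character vector of the files written, invisibly.
#' @export
write_oligo_outputs <- function(oligos, path_prefix,
                                series_config = gtaghd_series()) {
  stopifnot(inherits(oligos, "oligo_set"))
  txt_path <- paste0(path_prefix, "_oligos.txt")
  writeLines(c(
    sprintf("# homology-arm oligos, series %s, arm %d bp, frame pad %d",
            oligos$series, oligos$arm_length, oligos$frame_pad),
    paste0("5F\t", oligos$five_prime_forward),
    paste0("5R\t", oligos$five_prime_reverse),
    paste0("3F\t", oligos$three_prime_forward),
    paste0("3R\t", oligos$three_prime_reverse)
  ), txt_path)
  written <- txt_path

  tmpl <- series_config[[oligos$series]]$template
  if (is.null(tmpl)) {
    warning("series '", oligos$series,
            "' has no plasmid template; map output skipped")
  } else {
    five <- oligos$arms$five_arm
    three <- oligos$arms$three_arm
    plasmid <- paste0(tmpl$upstream, five, tmpl$cargo, three, tmpl$downstream)
    s5 <- nchar(tmpl$upstream) + 1L
    sc <- s5 + nchar(five)
    s3 <- sc + nchar(tmpl$cargo)
    feats <- data.frame(
      key = "misc_feature",
      start = c(s5, sc, s3),
      end = c(sc - 1L, s3 - 1L, s3 + nchar(three) - 1L),
      label = c("five_prime_homology_arm", "cargo",
                "three_prime_homology_arm"),
      stringsAsFactors = FALSE
    )
    map_path <- paste0(path_prefix, "_map.gb")
    write_genbank(seq_record(plasmid, id = paste0(oligos$series, "_map")),
                  map_path, extra_features = feats)
    written <- c(written, map_path)
  }
  invisible(written)
}

#' Design knock-in homology-arm oligos in one call
#'
#' Convenience wrapper: locate the guide, design the arms, assemble the
#' oligos.
#'
#' @inheritParams locate_integration_site
#' @inheritParams design_arms
#' @inheritParams assemble_oligos
#' @return An `oligo_set`.
#' @export
gtaghd_design <- function(record, guide, arm_length = 48L, series = "blunt",
                          custom_guide = NULL, pad_side = "five",
                          series_config = gtaghd_series()) {
  site <- locate_integration_site(record, guide)
  arms <- design_arms(record, site, arm_length, pad_side)
  assemble_oligos(arms, series, custom_guide, series_config)
}
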