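# PreMA target-site scanning: find nuclease sites, build the DSB-centred
# context (pseudostring for staggered cutters), score the competition between
# microhomologies, and emit the ten-column report.

#' Find nuclease target sites in a sequence
#'
#' Scans both strands for PAM matches (CRISPR) or enumerates arm/spacer
#' layouts (TALEN).  The cut position is reported as a 0-based index on the
#' forward strand of the input; for staggered cutters it is the leftmost
#' strand cut, so the overhang occupies `[dsb_index, dsb_index + overhang)`.
#'
#' @param record A [seq_record].
#' @param nuclease A [nuclease_spec].
#' @param exon_selection Optional integer vector of 1-based exon ordinals;
#'   only sites cutting inside those exons are returned.
#' @return A data frame of sites: `target_sequence`, `strand` ("forward" or
#'   "complement"), `dsb_index`, `tool_type`, `exon_id` (1 when the record
#'   has no exon annotation, NA when annotation exists but the cut is
#'   intergenic/intronic).
#' @export
find_sites <- function(record, nuclease, exon_selection = NULL) {
  stopifnot(inherits(record, "seq_record"), inherits(nuclease, "nuclease_spec"))
  seq <- record$sequence
  n <- nchar(seq)

  if (nuclease$kind == "crispr") {
    fwd <- crispr_sites_one_strand(seq, nuclease)
    rc <- crispr_sites_one_strand(reverse_complement(seq), nuclease)
    if (nrow(rc)) {
      rc$dsb_index <- n - rc$dsb_index - nuclease$overhang_length
      rc$strand <- "complement"
    }
    sites <- rbind(fwd, rc)
  } else {
    sites <- talen_sites(seq, nuclease)
  }
  if (!nrow(sites)) return(cbind(sites, exon_id = integer(0)))
  sites <- sites[sites$dsb_index > 0L & sites$dsb_index < n, , drop = FALSE]

  if (nrow(record$exons) == 0L) {
    sites$exon_id <- 1L
    if (!is.null(exon_selection)) stop("record has no exon annotation")
  } else {
    left_base <- sites$dsb_index - 1L   # base directly left of the cut
    sites$exon_id <- vapply(left_base, function(b) {
      hit <- which(record$exons[, 1] <= b & b < record$exons[, 2])
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    if (!is.null(exon_selection)) {
      exon_selection <- as.integer(exon_selection)
      if (any(exon_selection < 1L | exon_selection > nrow(record$exons))) {
        stop("unknown exon ordinal; record has ", nrow(record$exons), " exon(s)")
      }
      sites <- sites[!is.na(sites$exon_id) &
                       sites$exon_id %in% exon_selection, , drop = FALSE]
    }
  }
  sites <- sites[order(sites$dsb_index, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# CRISPR sites on one strand, dsb_index in that strand's coordinates
# (leftmost cut when staggered; for the forward strand the top-strand cut).
crispr_sites_one_strand <- function(seq, nz) {
  n <- nchar(seq)
  empty <- data.frame(target_sequence = character(), strand = character(),
                      dsb_index = integer(), tool_type = character(),
                      stringsAsFactors = FALSE)
  if (nz$guide_length + nchar(nz$pam) > n) return(empty)
  pam_at <- iupac_positions(seq, nz$pam) - 1L   # 0-based PAM starts
  if (!length(pam_at)) return(empty)
  plen <- nchar(nz$pam)
  if (nz$pam_side == "3prime") {
    g_start <- pam_at - nz$guide_length
    dsb <- pam_at - nz$cut_offset
  } else {
    g_start <- pam_at + plen
    dsb <- g_start + nz$cut_offset
  }
  ok <- g_start >= 0L & g_start + nz$guide_length <= n
  if (!any(ok)) return(empty)
  data.frame(
    target_sequence = substring(seq, g_start[ok] + 1L,
                                g_start[ok] + nz$guide_length),
    strand = "forward",
    dsb_index = dsb[ok],
    tool_type = nz$pam,
    stringsAsFactors = FALSE
  )
}

talen_sites <- function(seq, nz) {
  n <- nchar(seq)
  rows <- list()
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (a in seq.int(nz$talen_arm_range[1], nz$talen_arm_range[2]))
    for (s in seq.int(nz$talen_spacer_range[1], nz$talen_spacer_range[2]))
      for (b in seq.int(nz$talen_arm_range[1], nz$talen_arm_range[2])) {
        total <- a + s + b
        if (total > n) next
        starts <- 0:(n - total)               # 0-based
        if (nz$require_t_flank) {
          ok <- starts > 0L & starts + total < n
          ok[ok] <- chars[starts[ok]] == "T" &
            chars[starts[ok] + total + 1L] == "A"
          starts <- starts[ok]
        }
        if (!length(starts)) next
        rows[[length(rows) + 1L]] <- data.frame(
          target_sequence = substring(seq, starts + 1L, starts + total),
          strand = "forward",
          dsb_index = starts + a + s %/% 2L,   # spacer midpoint, left-biased
          tool_type = sprintf("%d/%d/%d", a, s, b),
          stringsAsFactors = FALSE
        )
      }
  if (!length(rows)) {
    return(data.frame(target_sequence = character(), strand = character(),
                      dsb_index = integer(), tool_type = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Build the DSB-centred scoring context
#'
#' For blunt cutters this is simply `window/2` bases on each side of the cut.
#' For 5'-overhang cutters, end resection removes the overhang bases, so a
#' pseudostring is built by deleting `overhang_length` bases at the junction
#' before centring the window.  Sites too close to a sequence end to fill the
#' window are skipped with a warning rather than padded.
#'
#' @param record A [seq_record].
#' @param dsb_index 0-based forward-strand cut position (leftmost cut for
#'   staggered nucleases).
#' @param window Context width in nt (default 80).
#' @param overhang_length 5' overhang length in nt (0 = blunt).
#' @return A list with elements `context` (DNA string of length `window`) and
#'   `dsb_index` (`window/2`, the junction position in the context), or
#'   `NULL` when the site is skipped.
#' @export
make_context <- function(record, dsb_index, window = 80L, overhang_length = 0L) {
  stopifnot(inherits(record, "seq_record"))
  seq <- record$sequence
  n <- nchar(seq)
  half <- as.integer(window) %/% 2L
  dsb_index <- as.integer(dsb_index)
  if (dsb_index < half || (n - overhang_length - dsb_index) < half) {
    warning(sprintf(
      "site at dsb_index %d skipped: needs %d bases each side of the junction",
      dsb_index, half))
    return(NULL)
  }
  pseudo_right <- substring(seq, dsb_index + overhang_length + 1L)
  list(
    context = paste0(substr(seq, dsb_index - half + 1L, dsb_index),
                     substr(pseudo_right, 1L, half)),
    dsb_index = half
  )
}

#' Score the microhomology competition at one site
#'
#' Enumerates and de-duplicates the deletion patterns in the context, scores
#' them, and takes the quotient of the two highest pattern scores.  A site is
#' eligible for the report only when its top pattern has at most
#' `intervening_max` bases between the arm copies; a large ratio then means
#' one deletion outcompetes all alternatives (a predominant-allele site).
#'
#' @param context DNA string from [make_context].
#' @param dsb_index 0-based cut position within `context`.
#' @param config List from [gss_config] (arm bounds, decay constant,
#'   intervening cutoff).
#' @return List with `menthu_score` (NA when fewer than two patterns exist),
#'   `top` (one-row pattern data frame or NULL), `eligible` (logical) and
#'   `patterns` (the full de-duplicated, score-sorted table).
#' @export
score_site <- function(context, dsb_index, config = gss_config()) {
  pats <- enumerate_patterns(context, dsb_index, config$min_arm,
                             config$max_arm, config$length_weight)
  pats <- deduplicate_patterns(pats, context)
  if (nrow(pats)) {
    # ties in score are ordered by intervening distance first: that choice is
    # invariant under reverse complement, so eligibility does not depend on
    # which strand the context was read from
    pats <- pats[order(-pats$score, pats$intervening, pats$left_start,
                       pats$right_start), , drop = FALSE]
    rownames(pats) <- NULL
  }
  if (nrow(pats) < 2L) {
    return(list(menthu_score = NA_real_,
                top = if (nrow(pats)) pats[1L, , drop = FALSE] else NULL,
                eligible = FALSE, patterns = pats))
  }
  top <- pats[1L, , drop = FALSE]
  score <- top$score / pats$score[2L]
  list(menthu_score = score, top = top,
       eligible = top$intervening <= config$intervening_max,
       patterns = pats)
}

menthu_columns <- c("Target_Sequence", "MENTHU_Score", "Frame_Shift",
                    "Tool_Type", "Strand", "Exon_ID", "DSB_Location",
                    "Microhomology", "PreMA_Sequence", "Context")

#' Scan a locus for predominant-MMEJ-allele target sites
#'
#' Runs the full pipeline for one or more nucleases: site finding, context
#' construction, microhomology competition scoring, and report assembly.
#' Only sites whose top deletion has at most 5 intervening bases (config)
#' appear; rows are sorted by score, descending.
#'
#' @param record A [seq_record].
#' @param nucleases A [nuclease_spec] or list of them.
#' @param recommended_only Keep only rows with score >= the recommendation
#'   threshold (1.5 by default).
#' @param t7_only Keep only guides starting with GG (T7 transcription);
#'   drops TALEN rows.
#' @param exon_selection Optional exon ordinals passed to [find_sites].
#' @param config List from [gss_config].
#' @return A data frame with the ten report columns: Target_Sequence,
#'   MENTHU_Score, Frame_Shift, Tool_Type, Strand, Exon_ID, DSB_Location
#'   (1-based position of the nucleotide directly left of the cut),
#'   Microhomology, PreMA_Sequence, Context.
#' @export
menthu_scan <- function(record, nucleases, recommended_only = FALSE,
                        t7_only = FALSE, exon_selection = NULL,
                        config = gss_config()) {
  if (inherits(nucleases, "nuclease_spec")) nucleases <- list(nucleases)
  stopifnot(length(nucleases) >= 1L)
  rows <- list()
  for (nz in nucleases) {
    sites <- find_sites(record, nz, exon_selection)
    if (!nrow(sites)) next
    for (k in seq_len(nrow(sites))) {
      ctx <- make_context(record, sites$dsb_index[k], config$window,
                          nz$overhang_length)
      if (is.null(ctx)) next
      sc <- score_site(ctx$context, ctx$dsb_index, config)
      if (!sc$eligible || is.na(sc$menthu_score)) next
      top <- sc$top
      rows[[length(rows) + 1L]] <- data.frame(
        Target_Sequence = sites$target_sequence[k],
        MENTHU_Score = sc$menthu_score,
        Frame_Shift = top$deletion_length %% 3L != 0L,
        Tool_Type = sites$tool_type[k],
        Strand = sites$strand[k],
        Exon_ID = sites$exon_id[k],
        DSB_Location = sites$dsb_index[k],  # 1-based pos of base left of cut
        Microhomology = top$arm,
        PreMA_Sequence = apply_deletion(ctx$context, top$left_start,
                                        top$right_start),
        Context = ctx$context,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(
      list(character(), numeric(), logical(), character(), character(),
           integer(), integer(), character(), character(), character()),
      menthu_columns), stringsAsFactors = FALSE)
  if (recommended_only) {
    out <- out[out$MENTHU_Score >= config$recommend_threshold, , drop = FALSE]
  }
  if (t7_only) {
    out <- out[!grepl("/", out$Tool_Type, fixed = TRUE) &
                 startsWith(out$Target_Sequence, "GG"), , drop = FALSE]
  }
  out <- out[order(-out$MENTHU_Score, out$DSB_Location), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the ten-column report as CSV
#'
#' Scores are rendered with two decimals; column order is fixed.
#'
#' @param rows Data frame from [menthu_scan].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_menthu_csv <- function(rows, path) {
  stopifnot(identical(names(rows), menthu_columns))
  rows$MENTHU_Score <- sprintf("%.2f", rows$MENTHU_Score)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a report CSV back into a data frame
#'
#' @param path CSV written by [write_menthu_csv].
#' @return Data frame with the ten report columns and native types.
#' @export
read_menthu_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(
                           Target_Sequence = "character",
                           MENTHU_Score = "numeric",
                           Frame_Shift = "logical",
                           Tool_Type = "character",
                           Strand = "character",
                           Exon_ID = "integer",
                           DSB_Location = "integer",
                           Microhomology = "character",
                           PreMA_Sequence = "character",
                           Context = "character"))
  stopifnot(identical(names(out), menthu_columns))
  out
}
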