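# Enumeration and scoring of microhomology-mediated deletion patterns.
# This is the computational kernel shared by the target-site scanner and the
# repair-fraction regressor.
#
# A pattern is a pair of identical direct repeats (the microhomology arms)
# flanking a double-strand break; annealing of the two copies deletes the
# sequence between the repeat starts.  Coordinates are 0-based half-open
# throughout: the cut sits between bases dsb_index-1 and dsb_index.

#' Enumerate microhomology deletion patterns spanning a DSB
#'
#' Finds every pair of identical k-mers (`min_arm <= k <= max_arm`) such that
#' the left copy starts before the cut, the right copy ends after it, and the
#' copies do not overlap.  Each pair corresponds to one MMEJ deletion product
#' that removes the break.
#'
#' @param context DNA string (typically the 80-bp window centred on the cut).
#' @param dsb_index 0-based cut position, strictly inside the context.
#' @param min_arm,max_arm Arm-length bounds in bp (defaults 2 and 25, the
#'   length range over which MMEJ operates).
#' @param length_weight Deletion-length decay constant for [pattern_score].
#' @return A data frame with one row per pattern: `left_start`, `right_start`
#'   (0-based), `arm`, `arm_length`, `deletion_length`, `intervening`,
#'   `score`, `frameshift`; sorted by `left_start`, `right_start`,
#'   `arm_length`.
#' @export
enumerate_patterns <- function(context, dsb_index, min_arm = 2L, max_arm = 25L,
                               length_weight = 20) {
  validate_dna(context, what = "context")
  n <- nchar(context)
  if (!is.numeric(dsb_index) || dsb_index <= 0 || dsb_index >= n) {
    stop("dsb_index must satisfy 0 < dsb_index < nchar(context)")
  }
  dsb_index <- as.integer(dsb_index)
  stopifnot(min_arm >= 1L, max_arm >= min_arm)
  empty <- data.frame(left_start = integer(), right_start = integer(),
                      arm = character(), arm_length = integer(),
                      deletion_length = integer(), intervening = integer(),
                      score = numeric(), frameshift = logical(),
                      stringsAsFactors = FALSE)
  if (n < 2L * min_arm) return(empty)

  rows <- vector("list", 0L)
  for (L in seq.int(min_arm, min(max_arm, n %/% 2L))) {
    starts <- 0:(n - L)                       # 0-based k-mer starts
    kmers <- substring(context, starts + 1L, starts + L)
    for (grp in split(starts, kmers)) {
      if (length(grp) < 2L) next
      lefts <- grp[grp < dsb_index]
      rights <- grp[grp + L > dsb_index]
      if (!length(lefts) || !length(rights)) next
      pair <- expand.grid(left_start = lefts, right_start = rights,
                          KEEP.OUT.ATTRS = FALSE)
      pair <- pair[pair$right_start - pair$left_start >= L, , drop = FALSE]
      if (!nrow(pair)) next
      pair$arm_length <- L
      rows[[length(rows) + 1L]] <- pair
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$arm <- substring(context, out$left_start + 1L,
                       out$left_start + out$arm_length)
  out$deletion_length <- out$right_start - out$left_start
  out$intervening <- out$deletion_length - out$arm_length
  out$score <- pattern_score(out$arm, out$deletion_length, length_weight)
  out$frameshift <- out$deletion_length %% 3L != 0L
  out <- out[order(out$left_start, out$right_start, out$arm_length), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("left_start", "right_start", "arm", "arm_length",
          "deletion_length", "intervening", "score", "frameshift")]
}

#' Pattern score of a microhomology deletion
#'
#' The score rewards long, GC-rich arms and short deletions:
#' `100 * round(exp(-D / length_weight), 3) * sum(w(b))` over the arm bases,
#' with `w(A) = w(T) = 1` and `w(G) = w(C) = 2`, where `D` is the deletion
#' length.  Vectorised over arms.
#'
#' @param arm Character vector of arm sequences.
#' @param deletion_length Integer vector of deletion lengths (bp).
#' @param length_weight Exponential decay constant in bp (default 20).
#' @return Numeric vector of scores (strictly positive).
#' @export
pattern_score <- function(arm, deletion_length, length_weight = 20) {
  stopifnot(length(arm) == length(deletion_length), length_weight > 0)
  n_gc <- nchar(gsub("[^GCgc]", "", arm))
  weight_sum <- nchar(arm) + n_gc                # AT=1, GC=2
  100 * round(exp(-deletion_length / length_weight), 3) * weight_sum
}

#' Collapse patterns that yield the same deletion product
#'
#' Nested sub-arms of one repeat describe the same repaired junction; only
#' the maximal pattern is biologically distinct.  Patterns are grouped by the
#' deletion product they produce (context with the deleted span removed);
#' within a group the longest arm is retained, ties broken by the smaller
#' `left_start`.
#'
#' @param patterns Data frame from [enumerate_patterns].
#' @param context The DNA string the patterns came from.
#' @return The de-duplicated data frame, in the same deterministic order.
#' @export
deduplicate_patterns <- function(patterns, context) {
  if (!nrow(patterns)) return(patterns)
  product <- paste0(substr(rep(context, nrow(patterns)), 1L,
                           patterns$left_start),
                    substring(context, patterns$right_start + 1L))
  keep_order <- order(product, -patterns$arm_length, patterns$left_start)
  keep <- keep_order[!duplicated(product[keep_order])]
  out <- patterns[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Deletion product string for one pattern row.
apply_deletion <- function(context, left_start, right_start) {
  paste0(substr(context, 1L, left_start), substring(context, right_start + 1L))
}
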