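# Nuclease definitions: PAM or TALEN geometry, cut offset, 5' overhang.

#' Define a programmable nuclease
#'
#' Describes where a nuclease cuts relative to its recognition sequence.  For
#' CRISPR nucleases the cut offset is measured from the PAM-proximal end of
#' the protospacer (3 bp for Cas9-like enzymes, i.e. between protospacer
#' positions 17 and 18 of a 20-nt guide).  Staggered cutters (Cas12a-like)
#' additionally leave a 5' overhang whose bases are lost to end resection and
#' are therefore removed before microhomology search.
#'
#' @param kind `"crispr"` or `"talen"`.
#' @param pam IUPAC PAM sequence (CRISPR only), e.g. `"NGG"`.
#' @param guide_length Protospacer length in nt (default 20).
#' @param cut_offset bp between the blunt-cut position and the PAM-proximal
#'   end of the protospacer (default 3, Cas9-like).
#' @param overhang_length 5' overhang length in nt; 0 means blunt.
#' @param pam_side `"3prime"` (Cas9-like, PAM downstream of the protospacer)
#'   or `"5prime"` (Cas12a-like, PAM upstream).
#' @param talen_arm_range,talen_spacer_range Min/max TALEN binding-arm and
#'   spacer lengths in nt (TALEN only).
#' @param require_t_flank TALEN only: require the canonical T immediately 5'
#'   of the left arm and A immediately 3' of the right arm.
#' @return An object of class `nuclease_spec`.
#' @export
nuclease_spec <- function(kind = c("crispr", "talen"), pam = NULL,
                          guide_length = 20L, cut_offset = 3L,
                          overhang_length = 0L,
                          pam_side = c("3prime", "5prime"),
                          talen_arm_range = c(15L, 18L),
                          talen_spacer_range = c(14L, 16L),
                          require_t_flank = TRUE) {
  kind <- match.arg(kind)
  pam_side <- match.arg(pam_side)
  stopifnot(cut_offset >= 0L, overhang_length >= 0L, guide_length >= 1L)
  if (kind == "crispr") {
    if (is.null(pam) || !nzchar(pam)) stop("a CRISPR nuclease needs a PAM")
    pam <- toupper(pam)
    if (!all(strsplit(pam, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP))) {
      stop("PAM must use IUPAC codes")
    }
  } else {
    stopifnot(length(talen_arm_range) == 2L, length(talen_spacer_range) == 2L,
              talen_arm_range[1] >= 1L,
              talen_arm_range[1] <= talen_arm_range[2],
              talen_spacer_range[1] >= 1L,
              talen_spacer_range[1] <= talen_spacer_range[2])
  }
  structure(
    list(kind = kind, pam = pam, guide_length = as.integer(guide_length),
         cut_offset = as.integer(cut_offset),
         overhang_length = as.integer(overhang_length), pam_side = pam_side,
         talen_arm_range = as.integer(talen_arm_range),
         talen_spacer_range = as.integer(talen_spacer_range),
         require_t_flank = isTRUE(require_t_flank)),
    class = "nuclease_spec"
  )
}

#' @export
print.nuclease_spec <- function(x, ...) {
  if (x$kind == "crispr") {
    cat(sprintf("<nuclease_spec> CRISPR %s PAM (%s), guide %d nt, cut %d bp, overhang %d nt\n",
                x$pam, x$pam_side, x$guide_length, x$cut_offset,
                x$overhang_length))
  } else {
    cat(sprintf("<nuclease_spec> TALEN arms %d-%d nt, spacer %d-%d nt\n",
                x$talen_arm_range[1], x$talen_arm_range[2],
                x$talen_spacer_range[1], x$talen_spacer_range[2]))
  }
  invisible(x)
}

#' Built-in nuclease presets
#'
#' `spcas9`: NGG PAM, 20-nt guide, blunt cut 3 bp from the PAM.
#' `cas12a`: TTTV 5'-PAM, 23-nt guide, cut 18 bp from the PAM-proximal end
#' with a 4-nt 5' overhang (handled via the pseudostring).
#' `talen`: paired arms 15-18 nt, spacer 14-16 nt, cut at the spacer midpoint.
#'
#' @return Named list of [nuclease_spec] objects.
#' @export
gss_nucleases <- function() {
  list(
    spcas9 = nuclease_spec("crispr", pam = "NGG"),
    cas12a = nuclease_spec("crispr", pam = "TTTV", guide_length = 23L,
                           cut_offset = 18L, overhang_length = 4L,
                           pam_side = "5prime"),
    talen = nuclease_spec("talen")
  )
}
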