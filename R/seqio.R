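# Sequence input and small DNA utilities shared by every other module.

#' Construct a sequence record
#'
#' A `seq_record` bundles a DNA sequence with optional exon intervals and a
#' CDS phase origin, the annotation needed for exon-aware target scanning and
#' for reading-frame repair during knock-in oligo design.
#'
#' @param sequence DNA string over A/C/G/T/N (normalised to upper case).
#' @param id Short text label.
#' @param exons Optional two-column matrix (or list of length-2 vectors) of
#'   0-based, half-open intervals; must be sorted and non-overlapping.
#' @param cds_phase_origin Optional 0-based index at which codon phase 0
#'   begins, taken from a CDS annotation; `NULL` when unannotated.
#' @param source One of `"pasted"`, `"fasta"`, `"genbank"`.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(sequence, id = "seq", exons = NULL,
                       cds_phase_origin = NULL, source = "pasted") {
  sequence <- toupper(sequence)
  validate_dna(sequence, allow_n = TRUE)
  exons <- normalise_exons(exons, nchar(sequence))
  if (!is.null(cds_phase_origin)) {
    cds_phase_origin <- as.integer(cds_phase_origin)
    stopifnot(cds_phase_origin >= 0L, cds_phase_origin < nchar(sequence))
  }
  source <- match.arg(source, c("pasted", "fasta", "genbank"))
  structure(
    list(id = id, sequence = sequence, exons = exons,
         cds_phase_origin = cds_phase_origin, source = source),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bp (%s), %d exon(s)%s\n",
              x$id, nchar(x$sequence), x$source, nrow(x$exons),
              if (is.null(x$cds_phase_origin)) ""
              else sprintf(", CDS phase origin %d", x$cds_phase_origin)))
  invisible(x)
}

normalise_exons <- function(exons, seq_len) {
  if (is.null(exons) || length(exons) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  if (is.list(exons)) exons <- do.call(rbind, exons)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 1] < 0L) || any(exons[, 2] > seq_len) ||
      any(exons[, 2] <= exons[, 1])) {
    stop("exon intervals must be 0-based, half-open and inside the sequence")
  }
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1] < exons[-nrow(exons), 2])) {
    stop("exon intervals must be non-overlapping")
  }
  exons
}

validate_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, " must be a single non-empty string")
  }
  alphabet <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what))
  }
  invisible(seq)
}

#' Read a DNA sequence from text or file
#'
#' Accepts pasted DNA text, FASTA, or a GenBank flat file.  Plain text is
#' stripped of whitespace and digits and upper-cased; FASTA uses the first
#' record (with a warning if more exist); GenBank input also yields exon
#' intervals and the CDS codon-phase origin.
#'
#' @param source A file path, or raw sequence text.
#' @param format `"auto"` (sniffed), `"fasta"`, `"genbank"` or `"plain"`.
#' @return A [seq_record].
#' @export
read_sequence <- function(source, format = c("auto", "fasta", "genbank", "plain")) {
  format <- match.arg(format)
  if (!is.character(source) || length(source) != 1L || !nzchar(source)) {
    stop("source must be a single non-empty string")
  }
  is_file <- file.exists(source) && !dir.exists(source)
  if (format == "auto") {
    head_txt <- if (is_file) paste(readLines(source, n = 1L, warn = FALSE),
                                   collapse = "") else source
    format <- if (startsWith(trimws(head_txt), ">")) "fasta"
      else if (grepl("^LOCUS", trimws(head_txt))) "genbank"
      else "plain"
  }
  switch(format,
    plain = {
      txt <- if (is_file) paste(readLines(source, warn = FALSE), collapse = "")
             else source
      seq <- toupper(gsub("[0-9[:space:]]", "", txt))
      if (!nzchar(seq)) stop("empty sequence")
      validate_dna(seq)
      seq_record(seq, id = if (is_file) basename(source) else "pasted",
                 source = "pasted")
    },
    fasta = {
      path <- source
      if (!is_file) {
        path <- tempfile(fileext = ".fa")
        on.exit(unlink(path), add = TRUE)
        writeLines(source, path)
      }
      set <- Biostrings::readDNAStringSet(path)
      if (length(set) == 0L) stop("empty FASTA input")
      if (length(set) > 1L) {
        warning(sprintf("FASTA contains %d records; using the first ('%s')",
                        length(set), names(set)[1]))
      }
      seq <- toupper(as.character(set[[1]]))
      validate_dna(seq)
      seq_record(seq, id = sub("\\s.*", "", names(set)[1]), source = "fasta")
    },
    genbank = read_genbank(source)
  )
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A/C/G/T/N; N maps to N.
#' @return The reverse complement, same length.
#' @export
reverse_complement <- function(seq) {
  validate_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

iupac_sets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)
    }
    cache
  }
})

#' Match a window against an IUPAC pattern
#'
#' Each window base must belong to the degeneracy set of the corresponding
#' pattern code.  An N in the window is treated as an unknown genome base and
#' satisfies only the pattern code N, so ambiguous sequence is never claimed
#' as a PAM match.
#'
#' @param pattern IUPAC DNA string (15 ambiguity codes allowed).
#' @param window DNA string over A/C/G/T/N, same length as `pattern`.
#' @return `TRUE` or `FALSE`.
#' @export
iupac_match <- function(pattern, window) {
  pattern <- toupper(pattern); window <- toupper(window)
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window must have equal length")
  }
  sets <- iupac_sets()
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  wc <- strsplit(window, "", fixed = TRUE)[[1]]
  if (any(!pc %in% names(sets))) {
    stop("pattern contains a non-IUPAC code: ",
         pc[which(!pc %in% names(sets))[1]])
  }
  validate_dna(window, what = "window")
  for (k in seq_along(pc)) {
    if (pc[k] == "N") next
    if (wc[k] == "N" || !wc[k] %in% sets[[pc[k]]]) return(FALSE)
  }
  TRUE
}

# 1-based start positions where `pattern` (IUPAC) matches `seq`; vectorised
# over positions so PAM scanning stays cheap on long inputs.
iupac_positions <- function(seq, pattern) {
  n <- nchar(seq); m <- nchar(pattern)
  if (m > n) return(integer(0))
  sets <- iupac_sets()
  pc <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (any(!pc %in% names(sets))) stop("non-IUPAC code in pattern")
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  keep <- rep(TRUE, n - m + 1L)
  pos <- seq_len(n - m + 1L)
  for (k in seq_len(m)) {
    if (pc[k] == "N") next
    w <- sc[pos + k - 1L]
    keep <- keep & w %in% sets[[pc[k]]] & w != "N"
  }
  pos[keep]
}
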