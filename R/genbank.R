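# Minimal GenBank flat-file reader/writer covering the feature set this
# package needs: exon intervals, a CDS with /codon_start, and labelled
# misc_features (used for plasmid maps).  Locations are simple `a..b` spans
# on the forward strand; joins/complements are out of scope at this toy
# annotation scale.

#' Read a GenBank flat file
#'
#' Parses LOCUS, FEATURES (exon, CDS with `/codon_start`, misc_feature with
#' `/label`) and ORIGIN into a [seq_record].  The full feature table is kept
#' in the `"features"` attribute as a data frame with 1-based inclusive
#' coordinates.
#'
#' @param path Path to a GenBank (.gb) file.
#' @return A [seq_record] with `source = "genbank"`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]

  feat <- data.frame(key = character(), start = integer(), end = integer(),
                     codon_start = integer(), label = character(),
                     stringsAsFactors = FALSE)
  in_feat <- FALSE
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^FEATURES", ln)) { in_feat <- TRUE; i <- i + 1L; next }
    if (grepl("^(ORIGIN|CONTIG|//)", ln)) break
    if (in_feat && grepl("^\\s{1,10}\\S", ln) && !grepl("^\\s*/", ln)) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) >= 2L) {
        loc <- gsub("[<>]", "", parts[2])
        m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
        if (length(m) == 3L) {
          row <- list(key = parts[1], start = as.integer(m[2]),
                      end = as.integer(m[3]), codon_start = NA_integer_,
                      label = NA_character_)
          # absorb qualifier lines
          j <- i + 1L
          while (j <= length(lines) && grepl("^\\s{11,}", lines[j])) {
            q <- trimws(lines[j])
            if (grepl("^/codon_start=", q)) {
              row$codon_start <- as.integer(sub("^/codon_start=", "", q))
            } else if (grepl("^/label=", q)) {
              row$label <- gsub("\"", "", sub("^/label=", "", q))
            }
            j <- j + 1L
          }
          feat <- rbind(feat, as.data.frame(row, stringsAsFactors = FALSE))
          i <- j
          next
        }
      }
    }
    i <- i + 1L
  }

  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) stop("GenBank file has no ORIGIN section: ", path)
  seq_lines <- lines[(origin_at[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seq)) stop("empty sequence in GenBank file: ", path)
  validate_dna(seq)

  ex <- feat[feat$key == "exon", , drop = FALSE]
  exons <- if (nrow(ex)) cbind(start = ex$start - 1L, end = ex$end) else NULL
  cds <- feat[feat$key == "CDS", , drop = FALSE]
  phase_origin <- NULL
  if (nrow(cds)) {
    cs <- cds$codon_start[1]
    if (is.na(cs)) cs <- 1L
    phase_origin <- (cds$start[1] - 1L) + (cs - 1L)
  }
  rec <- seq_record(seq, id = id, exons = exons,
                    cds_phase_origin = phase_origin, source = "genbank")
  attr(rec, "features") <- feat
  rec
}

#' Write a GenBank flat file
#'
#' Serialises a [seq_record] (exons, CDS phase origin) plus optional extra
#' features to a GenBank flat file readable by [read_genbank] and standard
#' viewers (ApE-compatible).
#'
#' @param record A [seq_record].
#' @param path Output path.
#' @param extra_features Optional data frame with columns `key`, `start`,
#'   `end` (1-based inclusive) and `label`.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path, extra_features = NULL) {
  stopifnot(inherits(record, "seq_record"))
  n <- nchar(record$sequence)
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN", record$id, n),
    sprintf("DEFINITION  %s.", record$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n)
  )
  if (nrow(record$exons)) {
    for (k in seq_len(nrow(record$exons))) {
      out <- c(out, sprintf("     exon            %d..%d",
                            record$exons[k, 1] + 1L, record$exons[k, 2]),
               sprintf("                     /number=%d", k))
    }
  }
  if (!is.null(record$cds_phase_origin)) {
    out <- c(out,
             sprintf("     CDS             %d..%d",
                     record$cds_phase_origin + 1L, n),
             "                     /codon_start=1")
  }
  if (!is.null(extra_features) && nrow(extra_features)) {
    for (k in seq_len(nrow(extra_features))) {
      out <- c(out, sprintf("     %-15s %d..%d", extra_features$key[k],
                            extra_features$start[k], extra_features$end[k]))
      if (!is.null(extra_features$label) && !is.na(extra_features$label[k])) {
        out <- c(out, sprintf("                     /label=\"%s\"",
                              extra_features$label[k]))
      }
    }
  }
  out <- c(out, "ORIGIN")
  seq <- tolower(record$sequence)
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
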