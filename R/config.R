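# Shared run configuration: scoring constants, nuclease presets, plasmid
# series.  Everything user-tunable lives here with its default.

#' Default run configuration
#'
#' Returns the scoring constants and presets used across the package:
#' arm-length bounds (2-25 bp, the microhomology range), the pattern-score
#' decay constant (20 bp), the 80-bp scoring window, the 5-bp intervening
#' cutoff for calling a predominant-allele site, and the 1.5 recommendation
#' threshold on the score ratio.
#'
#' @param ... Named overrides for any default field.
#' @return A named list.
#' @export
gss_config <- function(...) {
  cfg <- list(
    min_arm = 2L,
    max_arm = 25L,
    length_weight = 20,
    window = 80L,
    intervening_max = 5L,
    recommend_threshold = 1.5,
    nucleases = gss_nucleases(),
    series = gtaghd_series()
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Load configuration overrides from a YAML file
#'
#' Fields present in the file replace the built-in defaults; everything else
#' is untouched.  Precedence elsewhere in the package is explicit function
#' argument > config file > default.
#'
#' @param path YAML file with a subset of [gss_config] fields.
#' @return A full config list.
#' @export
read_gss_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files")
  }
  over <- yaml::read_yaml(path)
  do.call(gss_config, over)
}
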