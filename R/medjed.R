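# MMEJ repair-fraction regression: six microhomology summary features feed a
# random-forest model of the proportion of deletion outcomes produced by
# microhomology-mediated repair at a given cut site.

medjed_feature_names <- c("min_deletion_length", "arm_length_max",
                          "arm_length_mean", "arm_length_sd",
                          "score_max", "score_sd")

#' Extract the six microhomology summary features
#'
#' The input is assumed to be cut exactly in the middle.  All deletion
#' patterns spanning that cut are enumerated and de-duplicated, then
#' summarised as: minimum deletion length; maximum, mean and standard
#' deviation (sample sd, 0 when a single pattern) of the arm lengths; and
#' maximum and standard deviation of the pattern scores.
#'
#' @param seq DNA string, even length between 20 and 200 nt.
#' @param config List from [gss_config] (arm bounds, decay constant).
#' @return One-row data frame with the six features.
#' @export
medjed_features <- function(seq, config = gss_config()) {
  validate_dna(seq)
  n <- nchar(seq)
  if (n < 20L || n > 200L) {
    stop("input must be between 20 and 200 nt (got ", n, ")")
  }
  if (n %% 2L != 0L) {
    stop("input length must be even so the cut site is unambiguous; ",
         "trim one terminal base (got ", n, " nt)")
  }
  pats <- deduplicate_patterns(
    enumerate_patterns(seq, n %/% 2L, config$min_arm, config$max_arm,
                       config$length_weight), seq)
  if (!nrow(pats)) {
    stop("no microhomology found spanning the central cut of: ", seq)
  }
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  data.frame(
    min_deletion_length = min(pats$deletion_length),
    arm_length_max = max(pats$arm_length),
    arm_length_mean = mean(pats$arm_length),
    arm_length_sd = sd0(pats$arm_length),
    score_max = max(pats$score),
    score_sd = sd0(pats$score)
  )
}

#' Train the repair-fraction random forest
#'
#' Fits a random-forest regression of observed MMEJ deletion fractions on
#' the six summary features.  The shipped workflow trains on synthetic data
#' from [medjed_dataset]; supply your own `(features, targets)` table to fit
#' a model on experimental deletion-outcome data.
#'
#' @param features Data frame with the six feature columns, one row per site.
#' @param targets Numeric vector of observed MMEJ deletion fractions in
#'   \[0, 1\].
#' @param n_trees Number of trees (default 500).
#' @param seed Integer RNG seed; fits are deterministic given the seed.
#' @param min_rows Minimum number of training rows (default 10).
#' @return An object of class `medjed_model`.
#' @export
medjed_train <- function(features, targets, n_trees = 500L, seed = 1L,
                         min_rows = 10L) {
  stopifnot(is.data.frame(features), nrow(features) == length(targets))
  if (!all(medjed_feature_names %in% names(features))) {
    stop("features must contain columns: ",
         paste(medjed_feature_names, collapse = ", "))
  }
  if (nrow(features) < min_rows) {
    stop("need at least ", min_rows, " training rows (got ", nrow(features), ")")
  }
  if (any(is.na(targets)) || any(targets < 0 | targets > 1)) {
    stop("targets must be fractions in [0, 1]")
  }
  x <- features[, medjed_feature_names, drop = FALSE]
  set.seed(as.integer(seed))
  forest <- randomForest::randomForest(x = x, y = targets,
                                       ntree = as.integer(n_trees))
  structure(
    list(forest = forest,
         meta = list(n_trees = as.integer(n_trees), seed = as.integer(seed),
                     feature_names = medjed_feature_names,
                     n_train = nrow(features),
                     target_range = range(targets),
                     package_version = as.character(
                       utils::packageVersion("mmejdesign")))),
    class = "medjed_model"
  )
}

#' @export
print.medjed_model <- function(x, ...) {
  cat(sprintf(
    "<medjed_model> random forest: %d trees, %d training sites, seed %d\n",
    x$meta$n_trees, x$meta$n_train, x$meta$seed))
  invisible(x)
}

#' Predict the MMEJ deletion fraction for a sequence
#'
#' @param model A [medjed_train] model.
#' @param seq DNA string (cut assumed at the exact middle; see
#'   [medjed_features] for input rules).
#' @param config List from [gss_config].
#' @return List with `prediction` (fraction in \[0, 1\]), `features` (one-row
#'   data frame) and `deletion_table` (all de-duplicated patterns:
#'   `arm`, `deletion_length`, `score`, `frameshift`, sorted by score,
#'   descending).
#' @export
medjed_predict <- function(model, seq, config = gss_config()) {
  stopifnot(inherits(model, "medjed_model"))
  feats <- medjed_features(seq, config)
  pred <- unname(stats::predict(model$forest, feats))
  n <- nchar(seq)
  pats <- deduplicate_patterns(
    enumerate_patterns(seq, n %/% 2L, config$min_arm, config$max_arm,
                       config$length_weight), seq)
  pats <- pats[order(-pats$score, pats$left_start), , drop = FALSE]
  rownames(pats) <- NULL
  list(prediction = pred, features = feats,
       deletion_table = pats[, c("arm", "deletion_length", "score",
                                 "frameshift")])
}

#' Evaluate predicted against observed repair fractions
#'
#' @param predicted,observed Numeric vectors of equal length (>= 2).
#' @return List with `pcc` (Pearson correlation), `mae` and `rmse`, all on
#'   the scale of the inputs.
#' @export
medjed_evaluate <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length")
  }
  if (length(observed) < 2L) stop("need at least two pairs")
  if (stats::sd(observed) == 0) {
    stop("observed values have zero variance; correlation is undefined")
  }
  err <- predicted - observed
  list(pcc = stats::cor(predicted, observed),
       mae = mean(abs(err)),
       rmse = sqrt(mean(err^2)))
}
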