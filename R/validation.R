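#' Normalize scores to the 0-1 scale
#'
#' Both the mapped footprint scores and the visually interpreted plot scores
#' are divided by their respective maxima before agreement statistics are
#' computed.
#'
#' @param scores numeric vector, each in `[0, maximum]`.
#' @param maximum positive scale maximum (e.g. `max_possible_score(scheme)`
#'   for footprint scores).
#' @return numeric vector in `[0, 1]`.
#' @export
normalize_scores <- function(scores, maximum) {
  if (!is.numeric(maximum) || length(maximum) != 1 || maximum <= 0)
    stop("maximum must be a single positive number")
  if (any(scores < 0 | scores > maximum, na.rm = TRUE))
    stop("scores must lie in [0, maximum]")
  scores / maximum
}

#' Root mean squared error
#'
#' @param a,b equal-length numeric vectors.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (!length(a)) stop("empty input")
  sqrt(mean((a - b)^2))
}

#' Chance-corrected threshold-match agreement (kappa)
#'
#' Two continuous normalized scores "agree" on a plot when they are within
#' `match_threshold` of one another on the 0-1 scale. Observed agreement
#' `p_o` is the fraction of plots agreeing; expected agreement `p_e` is the
#' match rate over all ordered pairs `(i, j)` of one vector against the other
#' (the permutation expectation of `p_o` under random re-pairing); kappa is
#' `(p_o - p_e) / (1 - p_e)`. Degenerate data where every cross pair matches
#' (`p_e = 1`, hence `p_o = 1`) returns 1.
#'
#' @param a,b normalized score vectors in `[0, 1]`.
#' @param match_threshold absolute difference treated as a match
#'   (default 0.20).
#' @return kappa in `(-Inf, 1]`.
#' @export
threshold_kappa <- function(a, b, match_threshold = 0.20) {
  if (length(a) != length(b)) stop("length mismatch")
  if (!length(a)) stop("empty input")
  if (any(a < -1e-9 | a > 1 + 1e-9 | b < -1e-9 | b > 1 + 1e-9))
    stop("inputs must be normalized to [0, 1]")
  if (match_threshold <= 0 || match_threshold >= 1)
    stop("match_threshold must lie in (0, 1)")
  p_o <- mean(abs(a - b) <= match_threshold)
  p_e <- mean(abs(outer(a, b, `-`)) <= match_threshold)
  if (p_e >= 1) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Classical Cohen's kappa on equal-width score bins
#'
#' Sensitivity variant: both normalized score vectors are cut into bins of
#' width `bin_width` and the ordinary categorical Cohen's kappa is computed
#' on the resulting classes.
#'
#' @param a,b normalized score vectors in `[0, 1]`.
#' @param bin_width width of the score classes (default 0.20).
#' @return kappa.
#' @export
binned_kappa <- function(a, b, bin_width = 0.20) {
  if (length(a) != length(b) || !length(a)) stop("bad input lengths")
  breaks <- unique(c(seq(0, 1, by = bin_width), 1))
  ca <- cut(a, breaks, include.lowest = TRUE)
  cb <- cut(b, breaks, include.lowest = TRUE)
  tab <- table(factor(ca, levels = levels(ca)), factor(cb, levels = levels(ca)))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Counts of plots over-, under- and within-threshold
#'
#' @param a mapped (footprint) normalized scores.
#' @param b visual normalized scores.
#' @param threshold agreement threshold on the 0-1 scale (default 0.20).
#' @return named integer vector `n_higher` (map exceeds visual by more than
#'   the threshold), `n_lower`, `n_within`; the three sum to `length(a)`.
#' @export
agreement_counts <- function(a, b, threshold = 0.20) {
  if (length(a) != length(b)) stop("length mismatch")
  n_higher <- sum(a - b > threshold)
  n_lower <- sum(b - a > threshold)
  c(n_higher = n_higher, n_lower = n_lower,
    n_within = length(a) - n_higher - n_lower)
}

#' Validation plot table
#'
#' Builds/validates the plot table used by the agreement statistics. Only
#' plots flagged `"certain"` enter the statistics.
#'
#' @param df data frame with columns `plot_id`, `row`, `col`, `visual_score`
#'   (>= 0), `certainty` (`"certain"`/`"uncertain"`); optional `stratum`
#'   (e.g. biome label), `footprint_score`, `image_year`,
#'   `image_resolution_m`.
#' @return A `validation_table` (data frame subclass).
#' @export
validation_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("plot_id", "visual_score", "certainty")
  if (!all(need %in% names(df)))
    stop("validation table needs columns ", paste(need, collapse = ", "))
  if (any(df$visual_score < 0, na.rm = TRUE))
    stop("visual scores must be non-negative")
  if (!all(df$certainty %in% c("certain", "uncertain")))
    stop("certainty must be 'certain' or 'uncertain'")
  class(df) <- c("validation_table", "data.frame")
  df
}

#' Read a validation table from delimited text
#'
#' @param path CSV/TSV file with the columns of [validation_table()].
#' @param sep field separator (default comma).
#' @return A `validation_table`.
#' @export
read_validation_table <- function(path, sep = ",") {
  validation_table(utils::read.table(path, header = TRUE, sep = sep,
                                     stringsAsFactors = FALSE))
}

#' Per-stratum RMSE
#'
#' RMSE between normalized visual and footprint scores, per stratum (e.g.
#' biome), reported only for strata with at least `min_n` plots; smaller
#' strata are omitted with a message.
#'
#' @param table a [validation_table()] with columns `stratum`,
#'   `visual_norm` and `footprint_norm` (as produced by
#'   [validate_footprint()]), or any data frame with those columns.
#' @param min_n minimum plots per reported stratum (default 100).
#' @return named numeric vector of RMSE by stratum (possibly empty, with a
#'   warning if no stratum qualifies).
#' @export
stratified_rmse <- function(table, min_n = 100) {
  df <- as.data.frame(table)
  need <- c("stratum", "visual_norm", "footprint_norm")
  if (!all(need %in% names(df)))
    stop("need columns ", paste(need, collapse = ", "))
  out <- c()
  for (s in sort(unique(df$stratum))) {
    sub <- df[df$stratum == s, ]
    if (nrow(sub) < min_n) {
      message(sprintf("stratum '%s' omitted: %d < %d plots", s, nrow(sub),
                      min_n))
      next
    }
    out[s] <- rmse(sub$visual_norm, sub$footprint_norm)
  }
  if (!length(out)) warning("no stratum reaches the minimum plot count")
  out
}

#' Full accuracy assessment of a footprint map
#'
#' Runs the plot-level agreement analysis: discards `"uncertain"` plots,
#' samples the footprint at plot cells when per-plot scores are absent,
#' normalizes both score sets to 0-1, and reports RMSE, the threshold-match
#' kappa at the requested threshold plus the +/-0.05 sensitivity thresholds,
#' the binned classical kappa, over/under/within agreement counts, and
#' stratified RMSE when strata are present.
#'
#' @param footprint a `footprint_map` (may be `NULL` when the table already
#'   carries `footprint_score`).
#' @param table a [validation_table()].
#' @param visual_max maximum attainable visual score under the interpretation
#'   key (normalization denominator for visual scores).
#' @param match_threshold agreement threshold on the 0-1 scale.
#' @param min_stratum_n minimum plots per stratum for stratified RMSE.
#' @return list with elements `n_plots`, `n_discarded`, `rmse`, `kappa`,
#'   `kappa_sensitivity` (named by threshold), `kappa_binned`,
#'   `agreement` (counts), `stratified_rmse`, and the augmented plot table.
#' @export
validate_footprint <- function(footprint, table, visual_max,
                               match_threshold = 0.20, min_stratum_n = 100) {
  stopifnot(inherits(table, "validation_table"))
  n0 <- nrow(table)
  tab <- table[table$certainty == "certain", , drop = FALSE]
  if (!nrow(tab)) stop("no 'certain' plots to validate against")
  if (is.null(tab$footprint_score) || all(is.na(tab$footprint_score))) {
    if (is.null(footprint))
      stop("table lacks footprint scores and no footprint map was supplied")
    tab$footprint_score <- sample_footprint(footprint, tab$row, tab$col)
  }
  keep <- !is.na(tab$footprint_score)
  tab <- tab[keep, , drop = FALSE]
  fp_max <- if (!is.null(footprint)) max_possible_score(footprint$scheme)
    else max_possible_score(scoring_scheme())
  tab$footprint_norm <- normalize_scores(tab$footprint_score, fp_max)
  tab$visual_norm <- normalize_scores(tab$visual_score, visual_max)
  a <- tab$footprint_norm; b <- tab$visual_norm
  thr <- sort(unique(c(match_threshold, match_threshold - 0.05,
                       match_threshold + 0.05)))
  thr <- thr[thr > 0 & thr < 1]
  ks <- vapply(thr, function(t) threshold_kappa(a, b, t), 0)
  names(ks) <- sprintf("%.2f", thr)
  strat <- if (!is.null(tab$stratum))
    stratified_rmse(tab, min_stratum_n) else NULL
  list(n_plots = nrow(tab), n_discarded = n0 - nrow(tab),
       rmse = rmse(a, b),
       kappa = threshold_kappa(a, b, match_threshold),
       kappa_sensitivity = ks,
       kappa_binned = binned_kappa(a, b, match_threshold),
       agreement = agreement_counts(a, b, match_threshold),
       stratified_rmse = strat,
       table = tab)
}
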