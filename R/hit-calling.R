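#' Per-compound Z-scores of the phagocytic index
#'
#' Aggregates each compound's non-excluded replicate wells (mean phagocytic
#' index) and standardizes against a reference: the DMSO control wells
#' (`vs_dmso`, default) or the distribution of per-compound means across the
#' library (`vs_library`).
#'
#' @param wells well summary data.frame (see [summarize_wells()]) with
#'   columns `role`, `compound`, `phagocytic_index`, `excluded`,
#'   `exclusion_reason`.
#' @param mode reference for standardization.
#' @return data.frame with one row per compound: `mean_pi`, `n_wells`,
#'   `z_score`, `toxic_primary` (all replicate wells lost to toxicity),
#'   `mode`.
#' @export
compound_z_scores <- function(wells, mode = c("vs_dmso", "vs_library")) {
  mode <- match.arg(mode)
  cm <- wells[wells$role == "compound", ]
  ok <- !cm$excluded
  mean_pi <- tapply(cm$phagocytic_index[ok], factor(cm$compound[ok],
                    levels = sort(unique(cm$compound))), mean)
  compounds <- sort(unique(cm$compound))
  res <- data.frame(compound = compounds,
                    mean_pi = as.numeric(mean_pi[compounds]),
                    n_wells = as.integer(table(factor(cm$compound[ok],
                                                      levels = compounds))),
                    stringsAsFactors = FALSE)
  tox <- tapply(cm$exclusion_reason == "toxicity", cm$compound,
                function(v) all(v))
  res$toxic_primary <- as.logical(tox[res$compound])

  if (mode == "vs_dmso") {
    ref <- wells$phagocytic_index[wells$role == "dmso" & !wells$excluded]
    if (length(ref) < 2L)
      stop("vs_dmso Z-scores require >= 2 DMSO wells", call. = FALSE)
    mu <- mean(ref); sig <- stats::sd(ref)
  } else {
    vals <- res$mean_pi[!is.na(res$mean_pi)]
    if (length(vals) < 10L)
      stop("vs_library Z-scores require >= 10 compounds", call. = FALSE)
    mu <- mean(vals); sig <- stats::sd(vals)
  }
  if (!is.finite(sig) || sig == 0)
    stop("Z-score reference has zero standard deviation", call. = FALSE)
  res$z_score <- (res$mean_pi - mu) / sig
  res$mode <- mode
  res
}

#' Call primary hits at a Z-score threshold
#'
#' Non-toxic compounds with `z_score <= z_threshold` (inclusive) are primary
#' inhibitor hits; activators are reported symmetrically at
#' `z_score >= -z_threshold`. Toxicity takes precedence: a compound removed
#' by the toxicity filter is never a hit.
#'
#' @param results data.frame from [compound_z_scores()].
#' @param z_threshold inhibitor threshold (default -2).
#' @return `results` with logical `primary_hit` and `activator` columns.
#' @export
call_primary_hits <- function(results, z_threshold = -2) {
  z <- results$z_score
  ok <- !results$toxic_primary & !is.na(z)
  results$primary_hit <- ok & z <= z_threshold
  results$activator <- ok & z >= -z_threshold
  results
}

#' Secondary-screen ratio to DMSO
#'
#' Ratio of the mean per-field phagocytic index of a compound treatment to
#' the mean of the DMSO-only control, with a standard error propagated from
#' the compound group's field-level SEM divided by the DMSO mean.
#'
#' @param compound_pi,dmso_pi numeric vectors of per-field phagocytic
#'   indices (at least two fields each).
#' @return list with `ratio` and `sem`.
#' @export
secondary_ratio <- function(compound_pi, dmso_pi) {
  if (length(compound_pi) < 2L || length(dmso_pi) < 2L)
    stop("secondary ratio requires >= 2 fields per group", call. = FALSE)
  mu_d <- mean(dmso_pi)
  if (mu_d == 0)
    stop("secondary ratio undefined: DMSO mean is zero", call. = FALSE)
  list(ratio = mean(compound_pi) / mu_d,
       sem = stats::sd(compound_pi) / sqrt(length(compound_pi)) / mu_d)
}

#' Classify a compound from its secondary screen outcome
#'
#' Toxicity dominates; otherwise a ratio of 0.5 or less confirms an
#' inhibitor, ratios within `delta` of 1 are no-effect, ratios above
#' `1 + delta` are activators, and the remainder are weak inhibitors.
#' Missing secondary data yields `not_tested`. Every compound receives
#' exactly one class.
#'
#' @param ratio numeric vector of secondary ratios (NA if untested).
#' @param toxic logical vector: secondary-screen toxicity flag.
#' @param delta half-width of the no-effect band around 1.
#' @return character vector of classifications.
#' @export
classify_compound <- function(ratio, toxic = FALSE, delta = 0.05) {
  n <- max(length(ratio), length(toxic))
  ratio <- rep_len(ratio, n)
  toxic <- rep_len(toxic, n)
  ifelse(toxic, "toxic",
    ifelse(is.na(ratio), "not_tested",
      ifelse(ratio <= 0.5, "confirmed_inhibitor",
        ifelse(ratio < 1 - delta, "weak_inhibitor",
          ifelse(ratio > 1 + delta, "activator", "no_effect")))))
}

#' Run the primary screen end to end
#'
#' Convenience wrapper: field table to well summaries
#' ([summarize_wells()]), per-compound Z-scores
#' ([compound_z_scores()]) and primary hit calls
#' ([call_primary_hits()]).
#'
#' @param fields field measurement table (see [simulate_screen()]).
#' @param mode Z-score reference, see [compound_z_scores()].
#' @param z_threshold hit threshold, see [call_primary_hits()].
#' @param ... passed to [summarize_wells()].
#' @return list with `wells` and `results` (per-compound table with
#'   `z_score`, `toxic_primary`, `primary_hit`, `activator`).
#' @export
run_primary_screen <- function(fields, mode = "vs_dmso",
                               z_threshold = -2, ...) {
  wells <- summarize_wells(fields, ...)
  results <- call_primary_hits(compound_z_scores(wells, mode),
                               z_threshold)
  list(wells = wells, results = results)
}

#' Concordance between primary and secondary screens
#'
#' Pearson correlation (with two-sided t-test p-value on n-2 degrees of
#' freedom) between paired per-compound primary and secondary readouts.
#'
#' @param primary,secondary paired numeric vectors, one value per compound
#'   (at least three pairs).
#' @return list with `r`, `p` and `n`.
#' @export
primary_secondary_concordance <- function(primary, secondary) {
  keep <- stats::complete.cases(primary, secondary)
  x <- primary[keep]; y <- secondary[keep]
  if (length(x) < 3L)
    stop("concordance requires >= 3 paired compounds", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("concordance undefined: zero variance in one screen", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
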