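#' Phagocytic index of a set of image fields
#'
#' The well-level phagocytic index is the sum of the synaptosome signal
#' area divided by the sum of the cell count over the well's non-excluded
#' image fields (a ratio of totals, not a mean of per-field ratios).
#'
#' @param synaptosome_area numeric vector of per-field signal areas (pixels).
#' @param cell_count numeric vector of per-field cell counts.
#' @return the phagocytic index, a non-negative scalar.
#' @export
phagocytic_index <- function(synaptosome_area, cell_count) {
  if (length(synaptosome_area) != length(cell_count))
    stop("area and count vectors must have equal length", call. = FALSE)
  if (length(cell_count) == 0L)
    stop("phagocytic index requires at least one field", call. = FALSE)
  total_cells <- sum(cell_count)
  if (total_cells <= 0)
    stop("phagocytic index undefined: total cell count is zero",
         call. = FALSE)
  sum(synaptosome_area) / total_cells
}

#' Z'-factor of a control plate
#'
#' Screening-window statistic `1 - 3 (sd_pos + sd_neg) / |mu_pos - mu_neg|`
#' computed from the per-well phagocytic indices of the negative (DMSO) and
#' positive (cytochalasin D) controls. Sample (n-1) standard deviations.
#' A value >= 0.5 indicates an excellent assay window.
#'
#' @param neg,pos numeric vectors of control well phagocytic indices,
#'   at least two wells each.
#' @return the Z'-factor (at most 1; 1 only when both groups have zero
#'   variance).
#' @export
z_factor <- function(neg, pos) {
  if (length(neg) < 2L || length(pos) < 2L)
    stop("Z'-factor requires >= 2 wells per control group", call. = FALSE)
  mu_n <- mean(neg); mu_p <- mean(pos)
  if (mu_n == mu_p)
    stop("Z'-factor undefined: control means are equal", call. = FALSE)
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mu_p - mu_n)
}

#' Strictly standardized mean difference of a control plate
#'
#' `(mu_neg - mu_pos) / sqrt(var_neg + var_pos)`, signed so that a
#' phagocytosis inhibitor used as positive control yields a positive value.
#' Values above 5 indicate a robust assay.
#'
#' @inheritParams z_factor
#' @return the SSMD.
#' @export
ssmd <- function(neg, pos) {
  if (length(neg) < 2L || length(pos) < 2L)
    stop("SSMD requires >= 2 wells per control group", call. = FALSE)
  v <- stats::var(neg) + stats::var(pos)
  if (v == 0)
    stop("SSMD undefined: both control variances are zero", call. = FALSE)
  (mean(neg) - mean(pos)) / sqrt(v)
}

#' Flag over-segmented fields
#'
#' Fields whose cell count exceeds `median + k * MAD` of the same-plate DMSO
#' fields are flagged `over_segmented` and excluded from phagocytic-index
#' sums. The MAD is the scaled median absolute deviation
#' (consistent with the normal SD). Plates with fewer than `min_fields`
#' fields are skipped with a warning; plates without DMSO fields fall back
#' to all fields on the plate as reference, with a warning.
#'
#' @param fields data.frame of field measurements with columns `plate`,
#'   `role`, `cell_count` (e.g. from [simulate_screen()] or
#'   [measure_field()] rows).
#' @param k MAD multiplier of the outlier rule.
#' @param min_fields minimum fields per plate for the rule to apply.
#' @return `fields` with a logical `over_segmented` column added (or
#'   overwritten). Idempotent: flags depend only on `cell_count`.
#' @export
overseg_filter <- function(fields, k = 5, min_fields = 8L) {
  fields$over_segmented <- FALSE
  for (p in unique(fields$plate)) {
    on_plate <- fields$plate == p
    if (sum(on_plate) < min_fields) {
      warning("plate ", p, ": fewer than ", min_fields,
              " fields; over-segmentation filter skipped", call. = FALSE)
      next
    }
    ref <- fields$cell_count[on_plate & fields$role == "dmso"]
    if (length(ref) == 0L) {
      warning("plate ", p, ": no DMSO fields; using all fields as ",
              "over-segmentation reference", call. = FALSE)
      ref <- fields$cell_count[on_plate]
    }
    cutoff <- stats::median(ref) + k * stats::mad(ref)
    fields$over_segmented[on_plate] <-
      fields$cell_count[on_plate] > cutoff
  }
  fields
}

#' Flag wells excluded for treatment-induced toxicity
#'
#' Wells (or compounds) whose remaining cell count falls strictly below 10%
#' of the DMSO mean are excluded as possibly toxic. The reference is the
#' mean DMSO total cell count, per plate by default (absorbing plate
#' effects) or screen-wide. In `per_compound` mode (default) the rule is
#' applied to a compound's replicate-mean relative cell count and all of
#' its wells are excluded together; in `per_well` mode each well is judged
#' alone. Control wells are never flagged.
#'
#' @param wells well summary data.frame with columns `plate`, `role`,
#'   `compound`, `total_cell_count`, and (if present) `excluded`,
#'   `exclusion_reason`.
#' @param threshold fraction of the DMSO mean below which (strictly) a well
#'   indicates toxicity.
#' @param mode `"per_compound"` or `"per_well"`.
#' @param scope `"plate"` or `"screen"` DMSO reference.
#' @return `wells` with `excluded` and `exclusion_reason` updated.
#' @export
toxicity_filter <- function(wells, threshold = 0.10,
                            mode = c("per_compound", "per_well"),
                            scope = c("plate", "screen")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (!any(wells$role == "dmso"))
    stop("toxicity filter requires DMSO reference wells", call. = FALSE)
  if (is.null(wells$excluded)) wells$excluded <- FALSE
  if (is.null(wells$exclusion_reason)) wells$exclusion_reason <- "none"

  dmso <- wells[wells$role == "dmso", ]
  if (scope == "screen") {
    ref <- rep(mean(dmso$total_cell_count), nrow(wells))
  } else {
    by_plate <- tapply(dmso$total_cell_count, dmso$plate, mean)
    ref <- as.numeric(by_plate[wells$plate])
    if (anyNA(ref))
      stop("toxicity filter: plate(s) without DMSO wells: ",
           paste(unique(wells$plate[is.na(ref)]), collapse = ", "),
           call. = FALSE)
  }
  rel <- wells$total_cell_count / ref
  is_cmpd <- wells$role == "compound"
  if (mode == "per_well") {
    toxic <- is_cmpd & rel < threshold
  } else {
    rel_mean <- tapply(rel[is_cmpd], wells$compound[is_cmpd], mean)
    toxic_cmpd <- names(rel_mean)[rel_mean < threshold]
    toxic <- is_cmpd & wells$compound %in% toxic_cmpd
  }
  hit <- toxic & !wells$excluded
  wells$excluded[hit] <- TRUE
  wells$exclusion_reason[hit] <- "toxicity"
  wells
}

#' Aggregate field measurements into well summaries
#'
#' Applies the documented filter order -- over-segmentation (field level),
#' then well aggregation, then toxicity (well level) -- and computes the
#' per-well phagocytic index over non-excluded fields. Morphology readouts
#' are unweighted means of the per-field means.
#'
#' @param fields field table as produced by [simulate_screen()] or
#'   accumulated from [measure_field()], with columns `plate`, `well`,
#'   `role`, `compound`, `dose`, `cell_count`, `synaptosome_area` and
#'   optionally `mean_solidity`, `mean_eccentricity`, `mean_iba1`.
#' @param apply_overseg apply [overseg_filter()] first.
#' @param overseg_k MAD multiplier passed to [overseg_filter()].
#' @param toxicity_mode,toxicity_scope passed to [toxicity_filter()].
#' @return data.frame with one row per well: role, compound, dose,
#'   `phagocytic_index`, `total_cell_count`, `n_fields`, morphology means,
#'   `excluded`, `exclusion_reason`.
#' @export
summarize_wells <- function(fields,
                            apply_overseg = TRUE,
                            overseg_k = 5,
                            toxicity_mode = "per_compound",
                            toxicity_scope = "plate") {
  if (apply_overseg) fields <- overseg_filter(fields, k = overseg_k)
  if (is.null(fields$over_segmented)) fields$over_segmented <- FALSE
  keep <- !fields$over_segmented
  key <- interaction(fields$plate, fields$well, drop = TRUE)

  agg <- function(x, f, subset) {
    out <- rep(NA_real_, nlevels(key))
    names(out) <- levels(key)
    v <- tapply(x[subset], key[subset], f)
    out[names(v)] <- as.numeric(v)
    out
  }
  first_of <- function(x) {
    as.vector(tapply(as.character(x), key, function(v) v[1L]))
  }
  wells <- data.frame(
    plate = first_of(fields$plate),
    well = first_of(fields$well),
    role = first_of(fields$role),
    compound = first_of(fields$compound),
    dose = as.numeric(tapply(fields$dose, key, function(v) v[1L])),
    stringsAsFactors = FALSE)
  area <- agg(fields$synaptosome_area, sum, keep)
  cells <- agg(fields$cell_count, sum, keep)
  wells$total_cell_count <- ifelse(is.na(cells), 0, cells)
  wells$phagocytic_index <- ifelse(wells$total_cell_count > 0,
                                   area / cells, NA_real_)
  wells$n_fields <- as.integer(agg(rep(1, nrow(fields)), sum, keep))
  wells$n_fields[is.na(wells$n_fields)] <- 0L
  for (col in c("mean_solidity", "mean_eccentricity", "mean_iba1")) {
    if (!is.null(fields[[col]]))
      wells[[col]] <- agg(fields[[col]],
                          function(v) mean(v, na.rm = TRUE), keep)
  }
  wells$excluded <- FALSE
  wells$exclusion_reason <- "none"
  no_fields <- wells$n_fields == 0L | wells$total_cell_count == 0
  wells$excluded[no_fields] <- TRUE
  wells$exclusion_reason[no_fields] <- "low_field_count"

  wells <- toxicity_filter(wells, mode = toxicity_mode,
                           scope = toxicity_scope)
  rownames(wells) <- NULL
  wells
}

#' Per-plate assay quality control
#'
#' Computes control-group statistics, the Z'-factor and the SSMD for every
#' plate carrying at least two wells of each control.
#'
#' @param wells well summary data.frame (see [summarize_wells()]).
#' @return data.frame with one row per qualifying plate: group means/SDs,
#'   `z_factor`, `ssmd`, and group sizes.
#' @export
plate_qc <- function(wells) {
  out <- list()
  for (p in unique(wells$plate)) {
    neg <- wells$phagocytic_index[wells$plate == p & wells$role == "dmso" &
                                    !wells$excluded]
    pos <- wells$phagocytic_index[wells$plate == p & wells$role == "cytod" &
                                    !wells$excluded]
    if (length(neg) < 2L || length(pos) < 2L) next
    out[[p]] <- data.frame(
      plate = p,
      mu_neg = mean(neg), sd_neg = stats::sd(neg),
      mu_pos = mean(pos), sd_pos = stats::sd(pos),
      z_factor = z_factor(neg, pos),
      ssmd = ssmd(neg, pos),
      n_neg = length(neg), n_pos = length(pos),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
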