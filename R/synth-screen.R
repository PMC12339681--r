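#' Configuration for a simulated phagocytosis screen
#'
#' Builds and validates the parameter set for [simulate_screen()]. Defaults
#' describe a 489-compound primary screen in 96-well plates: three replicate
#' wells per compound split across different plates, 12 image fields per
#' well, DMSO negative controls and cytochalasin D positive controls in
#' fixed plate columns.
#'
#' The phagocytic index (PI) of a field is log-normal around the well's
#' expected value; a compound's expected well PI is `baseline_pi_mean`
#' times its true multiplier (1 for null and toxic compounds,
#' `inhibitor_effect` / `activator_effect` otherwise). Toxicity is binomial
#' thinning of the per-field cell count. Morphology (mean solidity,
#' eccentricity, IBA1 intensity per field) is shifted per effect class and
#' jittered per compound with a configurable solidity-eccentricity
#' correlation.
#'
#' @param n_compounds number of library compounds.
#' @param n_replicates_per_compound replicate wells per compound; replicates
#'   are placed on different plates.
#' @param fields_per_well image fields acquired per well.
#' @param dmso_wells_per_plate,cytod_wells_per_plate control wells per plate
#'   (fixed columns: DMSO on the left, cytochalasin D on the right).
#' @param baseline_pi_mean expected PI of an untreated (DMSO) well.
#' @param baseline_pi_cv field-level coefficient of variation of the PI.
#' @param cells_per_field_mean Poisson mean of the per-field cell count.
#' @param inhibitor_fraction,activator_fraction,toxic_fraction fractions of
#'   the library in each effect class (remainder is null); must sum to <= 1.
#' @param inhibitor_effect multiplicative PI factor for inhibitors, in [0,1).
#' @param activator_effect multiplicative PI factor for activators, > 1.
#' @param toxic_cell_fraction fraction of cells remaining in wells of toxic
#'   compounds, in [0, 0.1).
#' @param cytod_effect,cytod_cv PI multiplier and field-level CV of the
#'   cytochalasin D positive control.
#' @param dose nominal compound dose in micromolar (annotation only).
#' @param morph_shift_model data.frame mapping effect class to morphology
#'   deltas, columns `class`, `d_solidity`, `d_eccentricity`, `d_iba1`.
#' @param morph_base named numeric: DMSO-level `solidity`, `eccentricity`,
#'   `iba1` means.
#' @param morph_sd per-compound SD of the solidity/eccentricity deltas.
#' @param morph_cor correlation between a compound's solidity and
#'   eccentricity deltas (solidity and eccentricity are strongly
#'   anticorrelated in microglia).
#' @param morph_field_sd field-level SD of the morphology readouts.
#' @param iba1_sd per-compound SD of the IBA1 intensity delta.
#' @param effect_classes optional character vector of per-compound effect
#'   classes (`"null"`, `"inhibitor"`, `"activator"`, `"toxic"`,
#'   recycled to `n_compounds`); overrides the random class assignment by
#'   fractions. Useful for paired screens sharing the same true effects.
#' @param pi_multipliers optional numeric vector of per-compound true PI
#'   multipliers (recycled), overriding the class-wide
#'   `inhibitor_effect` / `activator_effect`; gives compounds graded
#'   potencies.
#' @param seed integer seed; identical configs give identical screens.
#' @return a validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_compounds = 489L,
                              n_replicates_per_compound = 3L,
                              fields_per_well = 12L,
                              dmso_wells_per_plate = 8L,
                              cytod_wells_per_plate = 8L,
                              baseline_pi_mean = 1.0,
                              baseline_pi_cv = 0.30,
                              cells_per_field_mean = 100,
                              inhibitor_fraction = 0,
                              inhibitor_effect = 0.5,
                              activator_fraction = 0,
                              activator_effect = 1.5,
                              toxic_fraction = 0,
                              toxic_cell_fraction = 0.05,
                              cytod_effect = 0.12,
                              cytod_cv = 1.0,
                              dose = 10,
                              morph_shift_model = default_morph_shift_model(),
                              morph_base = c(solidity = 0.55,
                                             eccentricity = 0.75,
                                             iba1 = 0.5),
                              morph_sd = 0.05,
                              morph_cor = -0.9,
                              morph_field_sd = 0.02,
                              iba1_sd = 0.05,
                              effect_classes = NULL,
                              pi_multipliers = NULL,
                              seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_replicates_per_compound = as.integer(n_replicates_per_compound),
              fields_per_well = as.integer(fields_per_well),
              dmso_wells_per_plate = as.integer(dmso_wells_per_plate),
              cytod_wells_per_plate = as.integer(cytod_wells_per_plate),
              baseline_pi_mean = baseline_pi_mean,
              baseline_pi_cv = baseline_pi_cv,
              cells_per_field_mean = cells_per_field_mean,
              inhibitor_fraction = inhibitor_fraction,
              inhibitor_effect = inhibitor_effect,
              activator_fraction = activator_fraction,
              activator_effect = activator_effect,
              toxic_fraction = toxic_fraction,
              toxic_cell_fraction = toxic_cell_fraction,
              cytod_effect = cytod_effect,
              cytod_cv = cytod_cv,
              dose = dose,
              morph_shift_model = morph_shift_model,
              morph_base = morph_base,
              morph_sd = morph_sd,
              morph_cor = morph_cor,
              morph_field_sd = morph_field_sd,
              iba1_sd = iba1_sd,
              effect_classes = effect_classes,
              pi_multipliers = pi_multipliers,
              seed = as.integer(seed))
  validate_screen_sim_config(cfg)
  class(cfg) <- "screen_sim_config"
  cfg
}

#' Default morphology shifts per effect class
#'
#' Inhibitors shift towards an ameboid phenotype (higher solidity, lower
#' eccentricity, brighter IBA1); activators towards a ramified one; toxic
#' and null compounds are unshifted.
#' @return data.frame with columns `class`, `d_solidity`, `d_eccentricity`,
#'   `d_iba1`.
#' @export
default_morph_shift_model <- function() {
  data.frame(class = c("null", "inhibitor", "activator", "toxic"),
             d_solidity = c(0, 0.15, -0.10, 0),
             d_eccentricity = c(0, -0.15, 0.10, 0),
             d_iba1 = c(0, 0.10, -0.10, 0),
             stringsAsFactors = FALSE)
}

validate_screen_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid screen configuration: ", msg,
                                 call. = FALSE)
  counts <- c("n_compounds", "n_replicates_per_compound", "fields_per_well",
              "dmso_wells_per_plate", "cytod_wells_per_plate")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop_cfg(paste(f, "must be >= 1"))
  fr <- c(cfg$inhibitor_fraction, cfg$activator_fraction, cfg$toxic_fraction)
  if (any(fr < 0 | fr > 1))
    stop_cfg("effect-class fractions must lie in [0, 1]")
  if (sum(fr) > 1)
    stop_cfg("effect-class fractions must sum to <= 1")
  if (cfg$baseline_pi_cv <= 0 || cfg$cytod_cv <= 0)
    stop_cfg("coefficients of variation must be > 0")
  if (cfg$baseline_pi_mean <= 0)
    stop_cfg("baseline_pi_mean must be > 0")
  if (cfg$inhibitor_effect < 0 || cfg$inhibitor_effect >= 1)
    stop_cfg("inhibitor_effect must lie in [0, 1)")
  if (cfg$activator_effect <= 1)
    stop_cfg("activator_effect must be > 1")
  if (cfg$toxic_cell_fraction < 0 || cfg$toxic_cell_fraction >= 0.1)
    stop_cfg("toxic_cell_fraction must lie in [0, 0.1)")
  need <- c("class", "d_solidity", "d_eccentricity", "d_iba1")
  if (!all(need %in% names(cfg$morph_shift_model)))
    stop_cfg("morph_shift_model must have columns class, d_solidity, d_eccentricity, d_iba1")
  if (abs(cfg$morph_cor) > 1)
    stop_cfg("morph_cor must lie in [-1, 1]")
  if (!is.null(cfg$effect_classes) &&
      !all(cfg$effect_classes %in% c("null", "inhibitor", "activator",
                                     "toxic")))
    stop_cfg("unknown effect class in effect_classes")
  if (!is.null(cfg$pi_multipliers) && any(cfg$pi_multipliers <= 0))
    stop_cfg("pi_multipliers must be > 0")
  invisible(cfg)
}

## log-normal draws parameterised by mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

well_id <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

## Assign plate/well positions. Controls sit in fixed columns: DMSO fills
## column 1 upward (then 2, ...), cytochalasin D fills column 12 downward.
## Replicate r of every compound lands in plate block r, so replicates of a
## compound are always on different plates.
screen_layout <- function(cfg) {
  n_ctrl <- cfg$dmso_wells_per_plate + cfg$cytod_wells_per_plate
  if (n_ctrl >= 96L)
    stop("control wells leave no room for compounds on a 96-well plate",
         call. = FALSE)
  dmso_idx <- seq_len(cfg$dmso_wells_per_plate)
  cytod_idx <- 96L + 1L - seq_len(cfg$cytod_wells_per_plate)
  compound_idx <- setdiff(seq_len(96L), c(dmso_idx, cytod_idx))
  cap <- length(compound_idx)
  plates_per_rep <- ceiling(cfg$n_compounds / cap)
  rows <- list()
  for (r in seq_len(cfg$n_replicates_per_compound)) {
    for (p in seq_len(plates_per_rep)) {
      plate <- sprintf("P%02d", (r - 1L) * plates_per_rep + p)
      on_plate <- seq.int((p - 1L) * cap + 1L, min(p * cap, cfg$n_compounds))
      slots <- compound_idx[seq_along(on_plate)]
      rows[[length(rows) + 1L]] <- data.frame(
        plate = plate,
        well = well_id((c(dmso_idx, cytod_idx, slots) - 1L) %% 8L + 1L,
                       (c(dmso_idx, cytod_idx, slots) - 1L) %/% 8L + 1L),
        role = c(rep("dmso", length(dmso_idx)),
                 rep("cytod", length(cytod_idx)),
                 rep("compound", length(on_plate))),
        compound = c(rep(NA_character_, length(dmso_idx) + length(cytod_idx)),
                     sprintf("cmpd%04d", on_plate)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a plate-based phagocytosis screen
#'
#' Generates one row per image field (cell count, synaptosome signal area,
#' mean solidity/eccentricity/IBA1 intensity) for a full multi-plate screen
#' with known per-compound ground truth. Deterministic given the config
#' (which carries the seed).
#'
#' @param config a [screen_sim_config()].
#' @return list with `fields` (data.frame: plate, well, role, compound,
#'   dose, field_index, cell_count, synaptosome_area, mean_solidity,
#'   mean_eccentricity, mean_iba1) and `truth` (data.frame: compound, class,
#'   pi_multiplier, expected morphology means).
#' @export
simulate_screen <- function(config) {
  cfg <- validate_screen_sim_config(config)
  set.seed(cfg$seed)

  n <- cfg$n_compounds
  if (is.null(cfg$effect_classes)) {
    n_inh <- round(cfg$inhibitor_fraction * n)
    n_act <- round(cfg$activator_fraction * n)
    n_tox <- round(cfg$toxic_fraction * n)
    classes <- rep("null", n)
    planted <- sample.int(n, n_inh + n_act + n_tox)
    classes[planted] <- rep(c("inhibitor", "activator", "toxic"),
                            c(n_inh, n_act, n_tox))
  } else {
    classes <- rep_len(cfg$effect_classes, n)
  }
  multiplier <- if (is.null(cfg$pi_multipliers))
    c(null = 1, inhibitor = cfg$inhibitor_effect,
      activator = cfg$activator_effect, toxic = 1)[classes]
  else rep_len(cfg$pi_multipliers, n)

  msm <- cfg$morph_shift_model
  shift <- msm[match(classes, msm$class), ]
  ## compound-level morphology jitter with planted solidity-eccentricity
  ## correlation
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  d_sol <- cfg$morph_sd * z1
  d_ecc <- cfg$morph_sd * (cfg$morph_cor * z1 +
                             sqrt(1 - cfg$morph_cor^2) * z2)
  truth <- data.frame(
    compound = sprintf("cmpd%04d", seq_len(n)),
    class = classes,
    pi_multiplier = unname(multiplier),
    sol_mean = pmin(pmax(cfg$morph_base[["solidity"]] +
                           shift$d_solidity + d_sol, 0.02), 0.999),
    ecc_mean = pmin(pmax(cfg$morph_base[["eccentricity"]] +
                           shift$d_eccentricity + d_ecc, 0.01), 0.99),
    iba1_mean = pmax(cfg$morph_base[["iba1"]] + shift$d_iba1 +
                       cfg$iba1_sd * stats::rnorm(n), 0.01),
    stringsAsFactors = FALSE)

  layout <- screen_layout(cfg)
  nf <- cfg$fields_per_well
  n_wells <- nrow(layout)
  fields <- layout[rep(seq_len(n_wells), each = nf), ]
  fields$dose <- ifelse(fields$role == "compound", cfg$dose,
                        ifelse(fields$role == "cytod", 2, 0))
  fields$field_index <- rep(seq_len(nf), times = n_wells)
  rownames(fields) <- NULL

  idx <- match(fields$compound, truth$compound)
  is_cytod <- fields$role == "cytod"
  pi_mean <- cfg$baseline_pi_mean *
    ifelse(is.na(idx), 1, truth$pi_multiplier[idx])
  pi_mean[is_cytod] <- cfg$baseline_pi_mean * cfg$cytod_effect
  cv <- ifelse(is_cytod, cfg$cytod_cv, cfg$baseline_pi_cv)
  pi_field <- rlnorm_mean_cv(nrow(fields), pi_mean, cv)

  count <- stats::rpois(nrow(fields), cfg$cells_per_field_mean)
  toxic_here <- !is.na(idx) & truth$class[idx] == "toxic"
  count[toxic_here] <- stats::rbinom(sum(toxic_here), count[toxic_here],
                                     cfg$toxic_cell_fraction)
  fields$cell_count <- count
  fields$synaptosome_area <- round(pi_field * count)

  sol <- ifelse(is.na(idx), cfg$morph_base[["solidity"]], truth$sol_mean[idx])
  ecc <- ifelse(is.na(idx), cfg$morph_base[["eccentricity"]],
                truth$ecc_mean[idx])
  iba <- ifelse(is.na(idx), cfg$morph_base[["iba1"]], truth$iba1_mean[idx])
  m <- nrow(fields)
  fields$mean_solidity <- pmin(pmax(
    sol + stats::rnorm(m, sd = cfg$morph_field_sd), 0), 1)
  fields$mean_eccentricity <- pmin(pmax(
    ecc + stats::rnorm(m, sd = cfg$morph_field_sd), 0), 1)
  fields$mean_iba1 <- pmax(iba + stats::rnorm(m, sd = cfg$morph_field_sd), 0)
  ## fields with no surviving cells carry no measurable signal
  empty <- fields$cell_count == 0L
  fields$synaptosome_area[empty] <- 0
  fields$mean_solidity[empty] <- NA_real_
  fields$mean_eccentricity[empty] <- NA_real_
  fields$mean_iba1[empty] <- NA_real_

  list(fields = fields, truth = truth, config = cfg)
}
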