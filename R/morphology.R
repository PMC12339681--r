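#' Morphotype classification thresholds
#'
#' Cutoffs on solidity and eccentricity defining the ramified / rod /
#' ameboid morphotypes. Numeric cutoffs can be fixed or derived as tertiles
#' of the DMSO cell population of the screen at hand (the default route
#' when DMSO cells are supplied), and the derivation is recorded.
#'
#' @param solidity_low,solidity_high,eccentricity_low,eccentricity_high
#'   fixed cutoffs in [0, 1], low < high within each feature.
#' @param dmso_cells optional data.frame of DMSO cells with `solidity` and
#'   `eccentricity` columns; if given, cutoffs are their tertiles and the
#'   fixed values are ignored.
#' @return list of class `morphotype_thresholds` with the four cutoffs and
#'   a `derivation` field (`"fixed"` or `"dmso_tertiles"`).
#' @export
morphotype_thresholds <- function(solidity_low = 0.70, solidity_high = 0.85,
                                  eccentricity_low = 0.60,
                                  eccentricity_high = 0.80,
                                  dmso_cells = NULL) {
  if (!is.null(dmso_cells)) {
    qs <- stats::quantile(dmso_cells$solidity, c(1, 2) / 3, names = FALSE)
    qe <- stats::quantile(dmso_cells$eccentricity, c(1, 2) / 3,
                          names = FALSE)
    th <- list(solidity_low = qs[1], solidity_high = qs[2],
               eccentricity_low = qe[1], eccentricity_high = qe[2],
               derivation = "dmso_tertiles")
  } else {
    th <- list(solidity_low = solidity_low, solidity_high = solidity_high,
               eccentricity_low = eccentricity_low,
               eccentricity_high = eccentricity_high,
               derivation = "fixed")
  }
  vals <- unlist(th[1:4])
  if (any(vals < 0 | vals > 1))
    stop("morphotype thresholds must lie in [0, 1]", call. = FALSE)
  if (th$solidity_low >= th$solidity_high ||
      th$eccentricity_low >= th$eccentricity_high)
    stop("morphotype thresholds must satisfy low < high", call. = FALSE)
  class(th) <- "morphotype_thresholds"
  th
}

#' Classify cells into morphotypes
#'
#' Ramified cells have low solidity and high eccentricity (branched,
#' elongated, surveillant-like); ameboid cells have high solidity and low
#' eccentricity (compact, activated-like); rod/bipolar cells sit in the
#' middle of both features. Discordant combinations (e.g. high solidity
#' with high eccentricity) are `ambiguous` -- a class of its own, so the
#' four classes partition feature space.
#'
#' @param solidity,eccentricity numeric vectors in [0, 1].
#' @param thresholds a [morphotype_thresholds()].
#' @return character vector in
#'   `{"ramified", "rod", "ameboid", "ambiguous"}`.
#' @export
classify_morphotype <- function(solidity, eccentricity,
                                thresholds = morphotype_thresholds()) {
  th <- thresholds
  ram <- solidity <= th$solidity_low & eccentricity >= th$eccentricity_high
  amo <- solidity >= th$solidity_high & eccentricity <= th$eccentricity_low
  rod <- solidity > th$solidity_low & solidity < th$solidity_high &
    eccentricity > th$eccentricity_low & eccentricity < th$eccentricity_high
  ifelse(ram, "ramified", ifelse(amo, "ameboid",
                                 ifelse(rod, "rod", "ambiguous")))
}

#' Per-compound functional and morphological phenotypes
#'
#' Aggregates well summaries into one phenotype row per compound: mean of
#' the per-field means for eccentricity, solidity and IBA1 intensity, the
#' mean phagocytic index, and (when per-cell shapes are supplied) the
#' fractions of ramified / rod / ameboid / ambiguous cells. The four
#' fractions sum to 1; set `renormalize = TRUE` to rescale the three named
#' morphotype fractions over non-ambiguous cells instead.
#'
#' @param wells well summary data.frame with `compound`,
#'   `phagocytic_index`, `mean_solidity`, `mean_eccentricity`, `mean_iba1`,
#'   `excluded` columns (see [summarize_wells()]).
#' @param cells optional per-cell data.frame with `compound`, `solidity`,
#'   `eccentricity` columns.
#' @param thresholds passed to [classify_morphotype()].
#' @param renormalize renormalize the three named fractions over
#'   non-ambiguous cells.
#' @return data.frame with one row per compound; when `cells` is missing
#'   the fraction columns are NA and `fractions_defined` is FALSE.
#' @export
compound_phenotypes <- function(wells, cells = NULL,
                                thresholds = morphotype_thresholds(),
                                renormalize = FALSE) {
  cm <- wells[wells$role == "compound" & !wells$excluded, ]
  if (nrow(cm) == 0L)
    stop("no non-excluded compound wells", call. = FALSE)
  compounds <- sort(unique(cm$compound))
  f <- factor(cm$compound, levels = compounds)
  m <- function(col) as.numeric(tapply(cm[[col]], f,
                                       function(v) mean(v, na.rm = TRUE)))
  ph <- data.frame(compound = compounds,
                   phagocytic_index = m("phagocytic_index"),
                   mean_solidity = m("mean_solidity"),
                   mean_eccentricity = m("mean_eccentricity"),
                   mean_iba1 = m("mean_iba1"),
                   stringsAsFactors = FALSE)
  ph$frac_ramified <- NA_real_
  ph$frac_rod <- NA_real_
  ph$frac_ameboid <- NA_real_
  ph$frac_ambiguous <- NA_real_
  ph$fractions_defined <- FALSE
  if (!is.null(cells)) {
    cls <- classify_morphotype(cells$solidity, cells$eccentricity,
                               thresholds)
    tab <- table(factor(cells$compound, levels = compounds),
                 factor(cls, levels = c("ramified", "rod", "ameboid",
                                        "ambiguous")))
    tot <- rowSums(tab)
    has <- tot > 0
    pr <- sweep(unclass(tab), 1, pmax(tot, 1), "/")
    ph$frac_ramified[has] <- pr[has, "ramified"]
    ph$frac_rod[has] <- pr[has, "rod"]
    ph$frac_ameboid[has] <- pr[has, "ameboid"]
    ph$frac_ambiguous[has] <- pr[has, "ambiguous"]
    if (renormalize) {
      s <- ph$frac_ramified + ph$frac_rod + ph$frac_ameboid
      for (col in c("frac_ramified", "frac_rod", "frac_ameboid"))
        ph[[col]] <- ifelse(s > 0, ph[[col]] / s, NA_real_)
    }
    ph$fractions_defined <- has
  }
  ph
}

#' Correlation between two phenotype features
#'
#' Pearson correlation across compounds with a two-sided t-test p-value on
#' n - 2 degrees of freedom.
#'
#' @param phenotypes data.frame from [compound_phenotypes()] (or any
#'   per-compound table).
#' @param feature_x,feature_y column names.
#' @return list with `r`, `p`, `n`.
#' @export
feature_correlation <- function(phenotypes, feature_x, feature_y) {
  x <- phenotypes[[feature_x]]
  y <- phenotypes[[feature_y]]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("feature correlation requires >= 3 compounds", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("feature correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' PCA of compound-level phenotypes
#'
#' Principal component analysis of standardized (zero mean, unit variance)
#' compound-level features, as used to relate phagocytic function to
#' morphology. Loadings are orthonormal; each component's sign is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param phenotypes data.frame from [compound_phenotypes()].
#' @param features columns to include.
#' @return list with `scores` (compounds x PCs), `loadings`
#'   (features x PCs), `variance_fraction` (sums to 1), `center`, `scale`.
#' @export
phenotype_pca <- function(phenotypes,
                          features = c("phagocytic_index", "mean_solidity",
                                       "mean_eccentricity", "mean_iba1")) {
  x <- as.matrix(phenotypes[, features, drop = FALSE])
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 3L)
    stop("phenotype PCA requires >= 3 compounds", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant feature(s): ",
         paste(features[sds == 0], collapse = ", "), call. = FALSE)
  xs <- scale(x)
  sv <- svd(xs)
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v, 2, flip, "*")
  scores <- sweep(sv$u %*% diag(sv$d, length(sv$d)), 2, flip, "*")
  rownames(loadings) <- features
  pcs <- paste0("PC", seq_along(sv$d))
  colnames(loadings) <- pcs
  colnames(scores) <- pcs
  if (!is.null(phenotypes$compound))
    rownames(scores) <- phenotypes$compound[keep]
  list(scores = scores, loadings = loadings,
       variance_fraction = sv$d^2 / sum(sv$d^2),
       center = attr(xs, "scaled:center"),
       scale = attr(xs, "scaled:scale"))
}
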