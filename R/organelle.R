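## Marker-anchored organelle assignment from density-gradient
## fractionation proteomics: validity filtering, left-censored (MNAR)
## imputation, PCA projection, robust marker-defined Gaussian cluster
## boundaries and per-protein localisation calls. The workflow follows
## the LOPIT idea: subcellular residence is read off co-fractionation
## profiles anchored on marker proteins.

#' Keep proteins with enough valid values in at least one fraction
#'
#' A protein passes when some fraction has at least `k` non-missing
#' replicate values; quantifications too sparse to carry profile
#' information are removed. Idempotent.
#'
#' @param tab An `intensity_table`.
#' @param k Minimum number of valid replicate values in one fraction.
#' @return The filtered `intensity_table`.
#' @export
filter_min_valid <- function(tab, k = 2) {
  stopifnot(inherits(tab, "intensity_table"), k >= 1)
  fr <- fractions_of(tab)
  keep <- vapply(seq_len(nrow(tab)), function(i) {
    any(tapply(!is.na(unclass(tab)[i, ]), fr, sum) >= k)
  }, TRUE)
  subset_intensity(tab, keep)
}

## subset rows of an intensity_table preserving attributes
subset_intensity <- function(tab, rows) {
  m <- unclass(tab)[rows, , drop = FALSE]
  attr(m, "fractions") <- attr(tab, "fractions")
  attr(m, "replicates") <- attr(tab, "replicates")
  class(m) <- c("intensity_table", "matrix", "array")
  m
}

#' Log2-transform an intensity table
#'
#' Non-positive values cannot be log-transformed and are set to missing
#' with a warning (raw label-free exports encode censored measurements
#' in several ways).
#'
#' @param tab An `intensity_table` on the raw scale.
#' @return The table on the log2 scale.
#' @export
log2_transform <- function(tab) {
  m <- unclass(tab)
  bad <- !is.na(m) & m <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive intensities set to missing before log2")
    m[bad] <- NA
  }
  m <- log2(m)
  out <- intensity_table_nocheck(m, attr(tab, "fractions"),
                                 attr(tab, "replicates"))
  out
}

intensity_table_nocheck <- function(m, fractions, replicates) {
  attr(m, "fractions") <- fractions
  attr(m, "replicates") <- replicates
  class(m) <- c("intensity_table", "matrix", "array")
  m
}

#' Imputation parameters for left-censored missing values
#'
#' Missing label-free values represent low-abundance measurements, so
#' they are drawn from a normal distribution shifted below the bulk of
#' each sample: `Normal(mean - downshift * sd, (width * sd)^2)` using the
#' observed per-column mean and standard deviation. Width 0.3 and
#' downshift 1.8 are the conventional defaults of this procedure in
#' proteomics practice.
#'
#' @param width Imputation SD as a fraction of the per-sample SD (> 0).
#' @param downshift Downshift in per-sample SDs (>= 0).
#' @param seed Integer RNG seed.
#' @return An `imputation_params` list.
#' @export
imputation_params <- function(width = 0.3, downshift = 1.8, seed = 1L) {
  stopifnot(width > 0, downshift >= 0)
  structure(list(width = width, downshift = downshift, seed = as.integer(seed)),
            class = "imputation_params")
}

#' Impute left-censored missing values
#'
#' Each missing cell of column `j` is drawn from
#' `Normal(mean_j - downshift * sd_j, (width * sd_j)^2)` where mean and
#' SD are computed from the observed values of that column (log2 scale
#' expected). Observed cells are returned bit-identical; the draw is
#' fully reproducible from `params$seed`.
#'
#' @param tab A log2-scale `intensity_table`.
#' @param params An [imputation_params()].
#' @return A complete `intensity_table`.
#' @export
impute_missing <- function(tab, params = imputation_params()) {
  stopifnot(inherits(tab, "intensity_table"),
            inherits(params, "imputation_params"))
  m <- unclass(tab)
  nvalid <- colSums(!is.na(m))
  if (any(nvalid < 2))
    stop("column with fewer than 2 valid values: ",
         paste(colnames(m)[nvalid < 2], collapse = ", "))
  if (!anyNA(m)) return(tab)
  mu <- colMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 2, stats::sd, na.rm = TRUE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(params$seed)
  for (j in seq_len(ncol(m))) {
    idx <- which(is.na(m[, j]))
    if (length(idx))
      m[idx, j] <- rnorm(length(idx),
                         mean = mu[j] - params$downshift * sd_[j],
                         sd = params$width * sd_[j])
  }
  intensity_table_nocheck(m, attr(tab, "fractions"), attr(tab, "replicates"))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Project proteins onto the first two principal components
#'
#' Column-centred PCA of the complete table; each protein gets a score on
#' the first two components. The sign of each component is fixed by
#' making its largest-magnitude loading coefficient positive, so the
#' projection is deterministic. The loadings matrix is returned as well
#' for inspection.
#'
#' @param tab A complete `intensity_table` with at least 3 proteins and
#'   3 samples.
#' @return List with `scores` (proteins x 2), `loadings` (samples x 2),
#'   `explained` (proportion of variance of PC1 and PC2, non-increasing),
#'   `sdev` (all component SDs).
#' @export
project_pca2d <- function(tab) {
  m <- unclass(tab)
  if (anyNA(m)) stop("PCA needs a complete table; impute first")
  if (nrow(m) < 3 || ncol(m) < 3) stop("need at least 3 proteins and 3 samples")
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  if (length(p$sdev) < 2 || p$sdev[2] < 1e-12)
    stop("data rank < 2: cannot build a 2-D projection")
  flip <- vapply(1:2, function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))]) < 0
  }, TRUE)
  rot <- p$rotation[, 1:2, drop = FALSE]
  rot[, flip] <- -rot[, flip]
  scores <- p$x[, 1:2, drop = FALSE]
  scores[, flip] <- -scores[, flip]
  colnames(scores) <- colnames(rot) <- c("PC1", "PC2")
  list(scores = scores, loadings = rot,
       explained = (p$sdev[1:2]^2) / sum(p$sdev^2),
       sdev = p$sdev)
}

#' Fit a marker-anchored cluster boundary in PC space
#'
#' The cluster of an organelle is a robust Gaussian ellipse over its
#' marker proteins: classical mean/covariance are fitted, the `trim`
#' fraction of markers with the largest Mahalanobis distances is
#' dropped, the fit is repeated, and the boundary is the chi-square
#' (2 df) quantile of squared Mahalanobis distance. Two standard
#' calibration factors rescale the covariance so the ellipse keeps its
#' nominal coverage: the Gaussian consistency factor for the trimmed
#' scatter (as in MCD-type estimators) and a finite-sample Hotelling-type
#' factor accounting for the estimation error of mean and covariance
#' (without it the plug-in ellipse systematically under-covers, severely
#' so for small marker sets). A near-singular covariance (e.g. collinear
#' markers) is regularised by adding a small multiple of the identity.
#'
#' @param points Numeric matrix proteins x 2 (PC scores, rownames = ids).
#' @param marker_ids Ids of the organelle's marker proteins; markers
#'   absent from `points` are reported via the `missing_markers` field.
#' @param quantile Boundary quantile of the chi-square(2) distribution.
#' @param trim Fraction of markers trimmed before refitting.
#' @param label Cluster label carried into calls.
#' @return A `cluster_model`: `label`, `center`, `cov`, `threshold`
#'   (squared Mahalanobis cut), `n_markers`, `missing_markers`,
#'   `outlier_markers` (markers outside their own fitted boundary).
#' @export
fit_marker_cluster <- function(points, marker_ids, quantile = 0.99,
                               trim = 0.1, label = "cluster") {
  stopifnot(is.matrix(points), ncol(points) == 2)
  present <- intersect(marker_ids, rownames(points))
  missing_markers <- setdiff(marker_ids, rownames(points))
  if (length(present) < 3)
    stop("need at least 3 markers present in the projection (got ",
         length(present), ")")
  x <- points[present, , drop = FALSE]
  fit <- function(xx) {
    mu <- colMeans(xx)
    S <- cov(xx)
    S <- .regularize_cov(S)
    list(mu = mu, S = S)
  }
  f <- fit(x)
  n_kept <- nrow(x)
  if (trim > 0 && nrow(x) >= 5) {
    d2 <- mahalanobis(x, f$mu, f$S)
    ndrop <- floor(trim * nrow(x))
    if (ndrop > 0) {
      keep <- order(d2)[seq_len(nrow(x) - ndrop)]
      f <- fit(x[keep, , drop = FALSE])
      n_kept <- length(keep)
      ## Gaussian consistency factor for the trimmed covariance
      alpha <- 1 - ndrop / nrow(x)
      f$S <- f$S * alpha / pchisq(qchisq(alpha, df = 2), df = 4)
    }
  }
  ## finite-sample coverage calibration: the squared Mahalanobis distance
  ## of a new point to an estimated mean/covariance (n points, p = 2) is
  ## ~ p (n-1)(n+1) / (n (n-p)) F(p, n-p), not chi-square(p). The trimmed
  ## scatter estimator carries extra sampling variance (Gaussian relative
  ## efficiency ~0.7 at 10% trimming), so its effective sample size is
  ## 0.7 n.
  n <- max(4, floor(if (n_kept < nrow(x)) 0.7 * nrow(x) else n_kept))
  fs <- (2 * (n - 1) * (n + 1)) / (n * (n - 2)) *
    qf(quantile, 2, n - 2) / qchisq(quantile, df = 2)
  f$S <- f$S * fs
  threshold <- qchisq(quantile, df = 2)
  d2_all <- mahalanobis(x, f$mu, f$S)
  structure(list(label = label, center = f$mu, cov = f$S,
                 threshold = threshold, n_markers = length(present),
                 missing_markers = missing_markers,
                 outlier_markers = present[d2_all > threshold]),
            class = "cluster_model")
}

.regularize_cov <- function(S, eps_rel = 1e-6) {
  ok <- function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    min(ev) > 1e-10 * max(abs(ev), 1e-12)
  }
  if (ok(S)) return(S)
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  S + diag(eps_rel * scale, nrow(S))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model", x$label, ": center (",
      sprintf("%.3f, %.3f", x$center[1], x$center[2]),
      "), threshold", sprintf("%.2f", x$threshold), ",",
      x$n_markers, "markers\n")
  invisible(x)
}

#' Call the localisation of every projected protein
#'
#' A protein inside exactly one cluster ellipse gets that organelle's
#' label; inside both, or within `margin` (relative squared-distance
#' units, `|d2 - threshold| <= margin * threshold`) of either boundary,
#' it is ambiguous — boundary proteins cannot be assigned confidently;
#' inside neither it is "other".
#'
#' @param points Numeric matrix proteins x 2 with rownames.
#' @param mito_model,perox_model Fitted [fit_marker_cluster()] models.
#' @param margin Relative boundary margin (default 0).
#' @return Data frame `protein`, `label`, `d2_mito`, `d2_perox`, `pc1`,
#'   `pc2`.
#' @export
assign_localisation <- function(points, mito_model, perox_model, margin = 0) {
  stopifnot(inherits(mito_model, "cluster_model"),
            inherits(perox_model, "cluster_model"))
  d2m <- mahalanobis(points, mito_model$center, mito_model$cov)
  d2p <- mahalanobis(points, perox_model$center, perox_model$cov)
  in_m <- d2m <= mito_model$threshold
  in_p <- d2p <= perox_model$threshold
  near <- (abs(d2m - mito_model$threshold) <= margin * mito_model$threshold) |
          (abs(d2p - perox_model$threshold) <= margin * perox_model$threshold)
  label <- rep("other", nrow(points))
  label[in_m] <- "mitochondrial"
  label[in_p] <- "peroxisomal"
  label[(in_m & in_p) | near] <- "ambiguous"
  data.frame(protein = rownames(points), label = label,
             d2_mito = unname(d2m), d2_perox = unname(d2p),
             pc1 = unname(points[, 1]), pc2 = unname(points[, 2]),
             stringsAsFactors = FALSE)
}

#' Run the full organelle-assignment workflow
#'
#' Filter (at least `min_valid` valid values in one fraction), log2
#' transform (optional), left-censored imputation, 2-D PCA, mito- and
#' peroxisome-marker cluster fits, and per-protein localisation calls.
#' Proteins removed by the validity filter appear in the output with
#' label `"not_quantified"`. The whole run is deterministic given
#' `params$seed`.
#'
#' @param tab An `intensity_table` (raw scale unless `log2 = FALSE`).
#' @param mito_markers,perox_markers Marker id vectors (disjoint).
#' @param min_valid Validity filter threshold.
#' @param log2 Log2-transform before imputation/PCA (default `TRUE`; use
#'   `FALSE` when the table is already log-scaled).
#' @param params [imputation_params()].
#' @param quantile,trim Cluster boundary parameters.
#' @param margin Ambiguity margin of [assign_localisation()].
#' @return List with `calls` (all input proteins), `models`, `pca`,
#'   `table` (the imputed table), `n_quantified`.
#' @export
run_organelle_pipeline <- function(tab, mito_markers, perox_markers,
                                   min_valid = 2, log2 = TRUE,
                                   params = imputation_params(),
                                   quantile = 0.99, trim = 0.1, margin = 0) {
  if (length(intersect(mito_markers, perox_markers)))
    stop("marker sets must be disjoint")
  kept <- filter_min_valid(tab, k = min_valid)
  dropped <- setdiff(rownames(tab), rownames(kept))
  if (log2) kept <- log2_transform(kept)
  imputed <- impute_missing(kept, params)
  pca <- project_pca2d(imputed)
  mito <- fit_marker_cluster(pca$scores, mito_markers, quantile = quantile,
                             trim = trim, label = "mitochondrial")
  perox <- fit_marker_cluster(pca$scores, perox_markers, quantile = quantile,
                              trim = trim, label = "peroxisomal")
  calls <- assign_localisation(pca$scores, mito, perox, margin = margin)
  if (length(dropped)) {
    calls <- rbind(calls,
                   data.frame(protein = dropped, label = "not_quantified",
                              d2_mito = NA_real_, d2_perox = NA_real_,
                              pc1 = NA_real_, pc2 = NA_real_,
                              stringsAsFactors = FALSE))
  }
  rownames(calls) <- NULL
  list(calls = calls, models = list(mito = mito, perox = perox),
       pca = pca, table = imputed, n_quantified = nrow(kept))
}
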