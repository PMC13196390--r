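#' @importFrom stats pt p.adjust rnorm quantile sd
NULL

#' Log2-transform and apply the detection filter
#'
#' Raw intensities are log2-transformed (present values must be strictly
#' positive; a non-positive value is an error naming the feature). Features
#' are retained iff they are detected (non-missing) in at least
#' `cfg$detectionMin` replicates of at least one condition — the 2-of-3
#' rule at the defaults; the number of dropped features is logged.
#'
#' @param x an [OmicsLayer-class] (raw or already log2).
#' @param cfg an [analysisConfig()].
#' @return the filtered, log2-scale [OmicsLayer-class].
#' @export
log2AndFilter <- function(x, cfg = analysisConfig()) {
  m <- intensities(x)
  design <- sampleDesign(x)
  if (intensityScale(x) == "raw") {
    bad <- which(rowSums(!is.na(m) & m <= 0) > 0)
    if (length(bad))
      stop("non-positive raw intensity for feature(s): ",
           paste(utils::head(rownames(m)[bad], 5), collapse = ", "))
    m <- log2(m)
  }
  detected <- !is.na(m)
  keep <- rep(FALSE, nrow(m))
  for (cond in design@conditions) {
    idx <- design@condition == cond
    keep <- keep | rowSums(detected[, idx, drop = FALSE]) >= cfg$detectionMin
  }
  .pwLog(layerType(x), ": detection filter dropped ", sum(!keep), " of ",
         nrow(m), " features")
  OmicsLayer(m[keep, , drop = FALSE], layer = layerType(x),
             design = design, scale = "log2")
}

#' Minimum-probability imputation of left-censored missing values
#'
#' Every missing cell of sample *s* is replaced by a draw from
#' `Normal(mu_s, sigma_s)` with `mu_s` the `imputationQ` quantile (default
#' q = 0.01) of the sample's observed values and `sigma_s` =
#' `imputationSdScale` times the sample's observed sd, emulating
#' low-abundance signals. Observed cells are never altered; the result is
#' deterministic under `seed`.
#'
#' @param x a log2-scale [OmicsLayer-class] (after filtering).
#' @param cfg an [analysisConfig()].
#' @param seed integer seed.
#' @return the layer with no missing cells.
#' @export
imputeMinProb <- function(x, cfg = analysisConfig(), seed = cfg$rngSeed) {
  stopifnot(intensityScale(x) == "log2")
  m <- intensities(x)
  if (!anyNA(m)) return(x)
  withSeed(seed, {
    for (j in seq_len(ncol(m))) {
      obs <- m[!is.na(m[, j]), j]
      nNA <- sum(is.na(m[, j]))
      if (nNA == 0) next
      if (length(obs) < 2)
        stop("sample ", colnames(m)[j],
             " has fewer than 2 observed values; quantile undefined")
      mu <- quantile(obs, cfg$imputationQ, names = FALSE)
      sigma <- cfg$imputationSdScale * sd(obs)
      m[is.na(m[, j]), j] <- rnorm(nNA, mu, sigma)
    }
  })
  OmicsLayer(m, layer = layerType(x), design = sampleDesign(x),
             scale = "log2")
}

#' Per-treatment differential testing
#'
#' For every non-control condition, each feature is compared to the control
#' by a two-sided two-sample t-test (equal-variance Student by default,
#' Welch with `varEqual = FALSE`) on the complete (imputed) log2 matrix.
#' P-values are Benjamini-Hochberg adjusted across the features of the
#' layer within each treatment-versus-control comparison. A feature is
#' significant iff |log2FC| > `fcThreshold` and adjusted p <
#' `fdrThreshold`; `direction` is `up`/`down` for significant features and
#' `none` otherwise. With zero pooled variance the p-value is 0 when the
#' means differ and 1 when they are equal (noiseless degenerate input), with
#' a logged warning.
#'
#' @param x a complete log2-scale [OmicsLayer-class].
#' @param cfg an [analysisConfig()].
#' @return a data.frame with columns `feature_id`, `layer`, `treatment`,
#'   `log2FC` (treatment mean minus control mean), `t_statistic`,
#'   `p_value`, `adj_p_value`, `significant`, `direction`.
#' @export
differentialTest <- function(x, cfg = analysisConfig()) {
  m <- intensities(x)
  if (anyNA(m))
    stop("differentialTest expects a complete (imputed) matrix")
  design <- sampleDesign(x)
  ctrl <- m[, design@condition == design@control, drop = FALSE]
  out <- list()
  degenerate <- 0L
  for (trt in treatments(design)) {
    tr <- m[, design@condition == trt, drop = FALSE]
    n1 <- ncol(tr); n0 <- ncol(ctrl)
    m1 <- rowMeans(tr); m0 <- rowMeans(ctrl)
    v1 <- rowSums((tr - m1)^2) / (n1 - 1)
    v0 <- rowSums((ctrl - m0)^2) / (n0 - 1)
    lfc <- m1 - m0
    if (cfg$varEqual) {
      sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n0))
      df <- rep(n1 + n0 - 2, nrow(m))
    } else {
      se <- sqrt(v1 / n1 + v0 / n0)
      df <- (v1 / n1 + v0 / n0)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    }
    tstat <- lfc / se
    p <- 2 * pt(-abs(tstat), df)
    zero <- !is.finite(tstat)
    if (any(zero)) {
      degenerate <- degenerate + sum(zero)
      tstat[zero] <- ifelse(lfc[zero] != 0, Inf * sign(lfc[zero]), 0)
      p[zero] <- ifelse(lfc[zero] != 0, 0, 1)
    }
    adj <- p.adjust(p, method = "BH")
    sig <- abs(lfc) > cfg$fcThreshold & adj < cfg$fdrThreshold
    out[[trt]] <- data.frame(
      feature_id = rownames(m), layer = layerType(x), treatment = trt,
      log2FC = unname(lfc), t_statistic = unname(tstat),
      p_value = unname(p), adj_p_value = unname(adj),
      significant = unname(sig),
      direction = ifelse(sig, ifelse(lfc > 0, "up", "down"), "none"),
      stringsAsFactors = FALSE)
  }
  if (degenerate > 0)
    warning("zero pooled variance for ", degenerate,
            " feature-comparisons; p set to 0/1 by mean equality")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count significant features by layer, treatment and direction
#'
#' @param results one or more `differentialTest()` data.frames (rbind-ed).
#' @return a data.frame with columns `layer`, `treatment`, `up`, `down`,
#'   `total` where `total = up + down`.
#' @export
summarizeCounts <- function(results) {
  stopifnot(nrow(results) > 0)
  keys <- unique(results[, c("layer", "treatment")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- results[results$layer == keys$layer[i] &
                   results$treatment == keys$treatment[i] &
                   results$significant, , drop = FALSE]
    data.frame(layer = keys$layer[i], treatment = keys$treatment[i],
               up = sum(sub$direction == "up"),
               down = sum(sub$direction == "down"),
               total = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$layer, out$treatment), , drop = FALSE]
}
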