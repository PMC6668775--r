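# Evaluation arithmetic: latency transforms, item-level correlation,
# scaled-predictor linear effect sizes, principal-components regression.

#' Inverse-transform naming latencies
#'
#' Maps latencies in ms to `-1000 / RT`, removing the rightward skew of
#' naming latency distributions while preserving order (the transform is
#' monotone increasing).
#'
#' @param latencies Positive latencies in ms.
#' @return Transformed values.
#' @export
inverse_transform <- function(latencies) {
  if (any(!is.finite(latencies)) || any(latencies <= 0)) {
    stop("latencies must be positive and finite", call. = FALSE)
  }
  -1000 / latencies
}

#' Standardize to z-scores
#'
#' Centers and scales to mean 0 and sample (n-1) standard deviation 1.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return z-scores.
#' @export
standardize <- function(values) {
  if (length(unique(values)) < 2L) {
    stop("cannot standardize a constant vector", call. = FALSE)
  }
  as.vector(scale(values))
}

#' Scaled-predictor linear effect size
#'
#' Ordinary least-squares slope of the response on the internally
#' standardized predictor, with its t-statistic. Scaling the predictor
#' makes effect sizes comparable across predictors; the response is used
#' on the scale it is given (latencies are typically inverse-transformed
#' and z-scored beforehand, see [inverse_transform()] and
#' [standardize()]).
#'
#' @param predictor Numeric predictor.
#' @param response Numeric response of the same length.
#' @param name Predictor label for the output.
#' @return Data frame with columns `predictor`, `beta`, `t` and `n`.
#' @export
linear_effect <- function(predictor, response,
                          name = deparse(substitute(predictor))) {
  if (length(predictor) != length(response)) {
    stop("predictor and response must have equal length", call. = FALSE)
  }
  if (length(predictor) < 3L) {
    stop("need at least 3 observations", call. = FALSE)
  }
  zx <- standardize(predictor)
  zy <- response
  fit <- stats::lm(zy ~ zx)
  s <- summary(fit)$coefficients
  data.frame(predictor = name, beta = unname(s["zx", "Estimate"]),
             t = unname(s["zx", "t value"]), n = length(predictor),
             stringsAsFactors = FALSE)
}

#' Principal-components regression
#'
#' Standardizes the predictors, extracts the top `k` principal components
#' (by variance explained), and regresses the response on the component
#' scores. Component signs are fixed by making the largest-magnitude
#' loading of each component positive, so output is deterministic.
#'
#' @param predictors Numeric matrix or data frame of predictors.
#' @param response Numeric response.
#' @param k Number of components (at most the rank of the predictor
#'   matrix).
#' @return List with `loadings` (predictors x k), `coefficients` (named
#'   per-component betas), `t` (t-statistics), `variance_explained`
#'   (fraction per component) and `fitted` values.
#' @export
pca_regression <- function(predictors, response, k) {
  X <- as.matrix(predictors)
  if (nrow(X) != length(response)) {
    stop("predictors and response must have matching rows", call. = FALSE)
  }
  if (nrow(X) <= k) stop("need more items than components", call. = FALSE)
  Z <- scale(X)
  rank <- qr(Z)$rank
  if (k > rank) {
    stop("k = ", k, " exceeds the predictor rank (", rank, ")", call. = FALSE)
  }
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    sign(pc$rotation[which.max(abs(pc$rotation[, j])), j])
  }, 1)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  fit <- stats::lm(response ~ scores)
  s <- summary(fit)$coefficients
  beta <- stats::coef(fit)[-1L]
  names(beta) <- colnames(loadings)
  tval <- s[-1L, "t value"]
  names(tval) <- colnames(loadings)
  list(
    loadings = loadings,
    coefficients = beta,
    t = tval,
    variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
    fitted = unname(stats::fitted(fit))
  )
}

#' Item-level correlation between simulated and observed latencies
#'
#' @param simulated,observed Numeric vectors of equal length (>= 3) with
#'   non-zero variance.
#' @return Pearson product-moment correlation.
#' @export
item_correlation <- function(simulated, observed) {
  if (length(simulated) != length(observed) || length(simulated) < 3L) {
    stop("need equal-length vectors with at least 3 items", call. = FALSE)
  }
  if (stats::sd(simulated) == 0 || stats::sd(observed) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  stats::cor(simulated, observed)
}
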