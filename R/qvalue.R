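#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion pi0 by the smoother method — the natural
#' cubic-spline fit of `pi0(lambda) = mean(p > lambda) / (1 - lambda)`
#' evaluated at the largest lambda — then converts p-values to q-values
#' (`q = pi0 * m * p / rank`, monotonized from the largest p downwards).
#' When pi0 estimation fails or leaves the (0, 1] range, pi0 is set to 1,
#' which reduces exactly to Benjamini-Hochberg; the fallback is reported
#' via `message()`.
#'
#' @param p p-values in (0, 1].
#' @param pi0 optionally fix pi0 (e.g. `pi0 = 1` for plain BH).
#' @param lambda grid for the smoother.
#' @return numeric q-values, same length and order as `p`, with the pi0
#'   used attached as attribute `"pi0"`.
#' @export
fdr_qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05)) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must be in (0, 1] with no NA")
  }
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- tryCatch({
      lambda <- lambda[lambda < max(p)]
      if (length(lambda) < 4) stop("p-value range too narrow for the smoother")
      pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      sp <- stats::smooth.spline(lambda, pl, df = 3)
      est <- stats::predict(sp, max(lambda))$y
      if (!is.finite(est) || est <= 0) stop("pi0 estimate out of range")
      min(est, 1)
    }, error = function(e) {
      message("pi0 smoother failed (", conditionMessage(e),
              "); falling back to pi0 = 1 (Benjamini-Hochberg)")
      1
    })
  }
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))
  attr(q, "pi0") <- pi0
  q
}
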