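## D'Agostino's K-squared omnibus normality test.
##
## Combines the D'Agostino (1970) skewness z and the Anscombe-Glynn (1983)
## kurtosis z into K2 = z1^2 + z2^2, referred to chi-square with 2 df.
## Moments use the biased (1/n) estimators, matching the standard
## formulation.

#' D'Agostino's K-squared normality test
#'
#' @param x Numeric sample, n >= 8, finite, nonzero variance.
#' @return List with `statistic` (K2), `p_value`, and the component
#'   `z_skew`, `z_kurt`.
#' @export
dagostino_k2 <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) {
    stop("D'Agostino K-squared requires n >= 8 (got ", n, ")")
  }
  if (!all(is.finite(x))) {
    stop("sample contains non-finite values")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    stop("sample has zero variance")
  }
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}
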