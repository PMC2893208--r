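#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared omnibus statistic combines the transformed sample skewness
#' Z(sqrt(b1)) and kurtosis Z(b2) (D'Agostino, Belanger & D'Agostino 1990);
#' K2 = Z1^2 + Z2^2 is referred to a chi-squared distribution with 2 df.
#' Requires n >= 8.
#'
#' @param x Numeric sample.
#' @return List with `statistic` (K2) and `p_value`.
#' @export
dagostino_pearson_test <- function(x) {
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson omnibus test requires n >= 8 (got ", n, ")")
  xc <- x - mean(x)
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  if (m2 == 0) stop("sample has zero variance")
  # skewness branch
  g1 <- m3 / m2^1.5
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis branch
  g2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  list(statistic = K2, p_value = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

normality_test_minimum <- c(dagostino_pearson = 8L,
                            shapiro_wilk = 8L,
                            kolmogorov_smirnov_lilliefors = 8L)

#' Run a battery of normality tests on a duration sample
#'
#' Applies the D'Agostino-Pearson omnibus test, Shapiro-Wilk, and the
#' Kolmogorov-Smirnov test with the Lilliefors correction for estimated
#' mean/SD. Shapiro-Wilk is limited to 5000 observations by its p-value
#' approximation; for larger samples it is applied to the first 5000 values
#' (an i.i.d. subsample when the input is exchangeable).
#'
#' @param durations Numeric sample, length >= 8.
#' @param alpha Significance level (default 0.05); a sample "passes" a test
#'   when p > alpha.
#' @param tests Which tests to run (default all three).
#' @return Data frame with columns `test_name`, `statistic`, `p_value`,
#'   `passes`.
#' @export
normality_tests <- function(durations, alpha = 0.05,
                            tests = c("dagostino_pearson", "shapiro_wilk",
                                      "kolmogorov_smirnov_lilliefors")) {
  tests <- match.arg(tests, several.ok = TRUE)
  n <- length(durations)
  minimum <- max(normality_test_minimum[tests])
  if (n < minimum) {
    stop("normality testing requires at least ", minimum,
         " observations (got ", n, ")")
  }
  one <- function(name) {
    res <- switch(name,
      dagostino_pearson = dagostino_pearson_test(durations),
      shapiro_wilk = {
        x <- if (n > 5000L) durations[seq_len(5000L)] else durations
        sw <- stats::shapiro.test(x)
        list(statistic = unname(sw$statistic), p_value = sw$p.value)
      },
      kolmogorov_smirnov_lilliefors = {
        lt <- nortest::lillie.test(durations)
        list(statistic = unname(lt$statistic), p_value = lt$p.value)
      })
    data.frame(test_name = name, statistic = res$statistic,
               p_value = res$p_value, passes = res$p_value > alpha,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(tests, one))
  rownames(out) <- NULL
  out
}
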