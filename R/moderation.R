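# Empirical-Bayes variance moderation. Per-window residual variances s^2 with
# df degrees of freedom are modelled as scaled chi-square draws around a
# scaled-inverse-chi-square prior (d0, s0^2); the prior is estimated by
# method of moments on log variances and the posterior variance
# (d0*s0^2 + df*s^2) / (d0 + df) feeds a t-statistic on df + d0 degrees of
# freedom. This borrowing of strength across windows stabilizes tests when
# per-window replication is small.

# invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to solve trigamma(d0/2) = excess variance of log s^2
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderate per-window variances toward an empirical-Bayes prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s02` by
#' method of moments on the log variances, then returns posterior variances
#' `(d0*s02 + df*s2) / (d0 + df)`. When the log variances show no excess
#' dispersion beyond sampling noise, `d0` is infinite and every posterior
#' variance equals `s02`.
#'
#' @param s2 Numeric vector of per-window residual variances (>= 2 values).
#' @param df Residual degrees of freedom (scalar or per-window vector,
#'   >= 1).
#' @param d0 Optionally force the prior df (0 recovers the ordinary t;
#'   `Inf` fully pools the variances).
#' @return List with `post` (posterior variances), `d0` and `s02`.
#' @export
moderate_variances <- function(s2, df, d0 = NULL) {
  n <- length(s2)
  if (n < 2L) stop("need >= 2 windows to moderate variances")
  if (any(df < 1)) stop("residual df must be >= 1")
  df <- rep_len(df, n)
  if (all(s2 == 0)) {
    warning("all residual variances are zero; falling back to ordinary t ",
            "with an epsilon variance")
    eps <- 1e-8
    return(list(post = rep(eps, n), d0 = 0, s02 = eps))
  }
  ok <- s2 > 0
  z <- log(s2[ok])
  dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  if (is.null(d0)) {
    evar <- stats::var(e) - mean(trigamma(dfo / 2))
    if (is.na(evar) || evar <= 0) {
      d0 <- Inf
    } else {
      d0 <- 2 * trigamma_inverse(evar)
    }
  }
  if (is.infinite(d0)) {
    s02 <- exp(emean)
    post <- rep(s02, n)
  } else if (d0 == 0) {
    s02 <- exp(emean)
    post <- s2
  } else {
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  list(post = post, d0 = d0, s02 = s02)
}

#' Simulate variances from the moderation prior
#'
#' Draws per-window true variances from a scaled-inverse-chi-square prior and
#' observed variances as scaled chi-square around them; used to validate
#' prior-parameter recovery.
#'
#' @param n_windows Number of windows.
#' @param d0,s02 Prior degrees of freedom and prior variance.
#' @param df Residual df of each observed variance.
#' @return Numeric vector of simulated observed variances.
#' @export
simulate_prior_variances <- function(n_windows, d0 = 4, s02 = 1, df = 18) {
  sigma2 <- d0 * s02 / stats::rchisq(n_windows, df = d0)
  sigma2 * stats::rchisq(n_windows, df = df) / df
}
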