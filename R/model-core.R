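#' Half-Normal log-density
#'
#' Density of |X| with X ~ Normal(0, scale^2), used as the weakly informative
#' prior on variance hyperparameters (applied to the variance itself, per the
#' BUGS-style model specification; see the methods vignette).
#'
#' @param x evaluation point(s).
#' @param scale standard deviation of the underlying Normal.
#' @return Log-density; `-Inf` for `x <= 0`.
#' @export
halfNormalLogpdf <- function(x, scale = 1) {
  out <- dnorm(x, 0, scale, log = TRUE) + log(2)
  out[x <= 0] <- -Inf
  out
}

#' Common-model linear predictor
#'
#' The log relative risk under the Common model: one shared BYM spatial
#' surface plus one national temporal trend,
#' `log mu^(C)[i, t] = alpha0 + eta_i + gamma_t`.
#'
#' @param params list with elements `alpha0` (scalar), `eta` (length-N) and
#'   `gamma` (length-T).
#' @return N-by-T matrix.
#' @export
commonLinpred <- function(params) {
  with(params, outer(alpha0 + eta, gamma, "+"))
}

#' Area-specific-model linear predictor
#'
#' The log relative risk under the Area-Specific model: a free intercept and
#' a free RW1 temporal trend per area, `log mu^(AS)[i, t] = nu_i + kappa[i, t]`.
#'
#' @param params list with elements `nu` (length-N) and `kappa` (N-by-T).
#' @return N-by-T matrix.
#' @export
areaSpecificLinpred <- function(params) {
  params$nu + params$kappa
}

#' Mixture linear predictor
#'
#' Selects, per cell, between the Common and Area-Specific log relative
#' risks: `log mu[i, t] = z[i, t] * muC[i, t] + (1 - z[i, t]) * muAS[i, t]`.
#' A length-N binary vector `z` (the baseline model's per-area allocation) is
#' broadcast across time.
#'
#' @param z binary N-vector or N-by-T matrix; 1 selects the Common model.
#' @param muC,muAS N-by-T log relative risk matrices.
#' @return N-by-T matrix.
#' @export
mixtureLinpred <- function(z, muC, muAS) {
  if (!all(z %in% c(0, 1))) stop("'z' must be binary")
  if (!is.matrix(z)) {
    if (length(z) != nrow(muC)) stop("'z' must have one entry per area")
    z <- matrix(z, nrow(muC), ncol(muC))
  }
  if (!identical(dim(z), dim(muC)) || !identical(dim(muC), dim(muAS))) {
    stop("dimension mismatch")
  }
  z * muC + (1 - z) * muAS
}

#' Poisson log-likelihood of a count surface
#'
#' `Y[i, t] ~ Poisson(mu[i, t] * E[i, t])` with `log(mu)` supplied; returns
#' the full log-likelihood including the `-log(Y!)` terms.
#'
#' @param data a [SurveillanceCounts-class] object, or a list with matrices
#'   `Y` and `E`.
#' @param logMu N-by-T matrix of log relative risks.
#' @return Scalar log-likelihood.
#' @export
poissonLogLik <- function(data, logMu) {
  if (is(data, "SurveillanceCounts")) {
    Y <- counts(data); E <- expectedCounts(data)
  } else {
    Y <- data$Y; E <- data$E
  }
  if (any(E <= 0)) stop("'expected' must be strictly positive")
  if (!identical(dim(Y), dim(logMu))) stop("dimension mismatch")
  sum(dpois(Y, E * exp(logMu), log = TRUE))
}

#' Allocation-probability field of the proposed model
#'
#' `phi[i, t] = plogis(pi_i + delta_t + qlogis(tau))`: the prior probability
#' that cell (i, t) follows the Common model, built from a spatial ICAR
#' field, a temporal ICAR field and a global level tau. With both fields at
#' zero, `phi` is `tau` everywhere.
#'
#' @param pi length-N spatial field.
#' @param delta length-T temporal field.
#' @param tau global allocation level, strictly inside (0, 1).
#' @return N-by-T matrix with entries in (0, 1).
#' @export
phiField <- function(pi, delta, tau) {
  if (length(tau) != 1L || is.na(tau) || tau <= 0 || tau >= 1) {
    stop("'tau' must lie strictly inside (0, 1)")
  }
  stats::plogis(outer(pi, delta, "+") + stats::qlogis(tau))
}

#' Joint prior log-density of the baseline model
#'
#' Sums the log prior densities of every baseline-model parameter: ICAR for
#' the structured spatial field v (graph `W`) and the national trend gamma
#' (graph `Q`), Normal(v_i, sigma2Eta) for the convolved field eta, a flat
#' (improper, constant) prior for alpha0, Normal(0, 1000) for the
#' area-specific intercepts nu, per-area ICAR RW1 priors for the kappa rows,
#' a lognormal(a, b^2) hyperprior for each area-specific variance with
#' a ~ Normal(0, 1000) and b half-Normal(0, 2.5^2), half-Normal(0, 1) priors
#' on the three Common-model variances, and independent Bernoulli(0.95)
#' priors on the per-area allocation indicators z.
#'
#' @param state list with elements `alpha0`, `eta`, `v`, `gamma`,
#'   `sigma2Eta`, `sigma2V`, `sigma2Gamma`, `nu`, `kappa`, `sigma2Kappa`
#'   (length-N), `a`, `b`, `z` (binary length-N).
#' @param W spatial [NeighborGraph-class].
#' @param Q temporal [NeighborGraph-class] (path graph).
#' @param priorCommon prior allocation probability (default 0.95).
#' @return Scalar log-density (up to additive constants); `-Inf` outside the
#'   prior support.
#' @export
logPriorBaseline <- function(state, W, Q, priorCommon = 0.95) {
  s <- state
  if (any(c(s$sigma2Eta, s$sigma2V, s$sigma2Gamma, s$sigma2Kappa) <= 0) ||
      s$b < 0) {
    return(-Inf)
  }
  if (!all(s$z %in% c(0, 1))) stop("'z' must be binary")
  lp <- icarLogpdf(s$v, W, s$sigma2V) +
    sum(dnorm(s$eta, s$v, sqrt(s$sigma2Eta), log = TRUE)) +
    icarLogpdf(s$gamma, Q, s$sigma2Gamma) +
    sum(dnorm(s$nu, 0, sqrt(1000), log = TRUE)) +
    sum(vapply(seq_along(s$nu), function(i) {
      icarLogpdf(s$kappa[i, ], Q, s$sigma2Kappa[i])
    }, numeric(1))) +
    sum(stats::dlnorm(s$sigma2Kappa, s$a, s$b, log = TRUE)) +
    dnorm(s$a, 0, sqrt(1000), log = TRUE) +
    halfNormalLogpdf(s$b, 2.5) +
    sum(halfNormalLogpdf(c(s$sigma2Eta, s$sigma2V, s$sigma2Gamma), 1)) +
    sum(s$z * log(priorCommon) + (1 - s$z) * log(1 - priorCommon))
  lp
}

#' Joint prior log-density of the proposed model
#'
#' As [logPriorBaseline()] except that the area-specific variances get the
#' less restrictive half-Normal(0, 1) prior, and the allocation field is the
#' hierarchical per-cell specification: `z[i, t] ~ Bernoulli(phi[i, t])` with
#' [phiField()] built from `pi ~ ICAR(W, sigma2Pi)`,
#' `delta ~ ICAR(Q, sigma2Delta)` (both with half-Normal(0, 1) hyperpriors)
#' and `tau ~ Uniform(0.9, 1)`.
#'
#' @param state list with elements `alpha0`, `eta`, `v`, `gamma`,
#'   `sigma2Eta`, `sigma2V`, `sigma2Gamma`, `nu`, `kappa`, `sigma2Kappa`,
#'   `z` (binary N-by-T), `pi`, `delta`, `tau`, `sigma2Pi`, `sigma2Delta`.
#' @param W spatial [NeighborGraph-class].
#' @param Q temporal [NeighborGraph-class].
#' @return Scalar log-density (up to additive constants); `-Inf` outside the
#'   prior support, in particular for `tau` outside (0.9, 1).
#' @export
logPriorProposed <- function(state, W, Q) {
  s <- state
  if (any(c(s$sigma2Eta, s$sigma2V, s$sigma2Gamma, s$sigma2Kappa,
            s$sigma2Pi, s$sigma2Delta) <= 0)) {
    return(-Inf)
  }
  if (s$tau <= 0.9 || s$tau >= 1) return(-Inf)
  if (!all(s$z %in% c(0, 1))) stop("'z' must be binary")
  phi <- phiField(s$pi, s$delta, s$tau)
  lp <- icarLogpdf(s$v, W, s$sigma2V) +
    sum(dnorm(s$eta, s$v, sqrt(s$sigma2Eta), log = TRUE)) +
    icarLogpdf(s$gamma, Q, s$sigma2Gamma) +
    sum(dnorm(s$nu, 0, sqrt(1000), log = TRUE)) +
    sum(vapply(seq_along(s$nu), function(i) {
      icarLogpdf(s$kappa[i, ], Q, s$sigma2Kappa[i])
    }, numeric(1))) +
    sum(halfNormalLogpdf(s$sigma2Kappa, 1)) +
    sum(halfNormalLogpdf(c(s$sigma2Eta, s$sigma2V, s$sigma2Gamma,
                           s$sigma2Pi, s$sigma2Delta), 1)) +
    icarLogpdf(s$pi, W, s$sigma2Pi) +
    icarLogpdf(s$delta, Q, s$sigma2Delta) +
    stats::dunif(s$tau, 0.9, 1, log = TRUE) +
    sum(s$z * log(phi) + (1 - s$z) * log1p(-phi))
  lp
}
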