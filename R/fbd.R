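## Sampled-ancestor fossilized birth-death tree prior: constant birth rate
## lambda, death rate mu, fossil sampling rate psi, extant sampling
## probability rho, conditioned on the origin time. Sampled ancestors are
## zero-duration pendant tips and contribute a psi factor without a birth
## term or an extinction integral.

fbd_c1 <- function(lambda, mu, psi) {
  sqrt((lambda - mu - psi)^2 + 4 * lambda * psi)
}

fbd_c2 <- function(lambda, mu, psi, rho) {
  -(lambda - mu - 2 * lambda * rho - psi) / fbd_c1(lambda, mu, psi)
}

## q(t): relative density of a lineage at time t before present having the
## observed (singly-sampled) history; log scale for stability.
fbd_log_q <- function(t, lambda, mu, psi, rho) {
  c1 <- fbd_c1(lambda, mu, psi)
  c2 <- fbd_c2(lambda, mu, psi, rho)
  log(4) - log(2 * (1 - c2^2) + (1 - c2)^2 * exp(-c1 * t) +
                 (1 + c2)^2 * exp(c1 * t))
}

## p0(t): probability a lineage at time t leaves no sampled descendants.
fbd_p0 <- function(t, lambda, mu, psi, rho) {
  c1 <- fbd_c1(lambda, mu, psi)
  c2 <- fbd_c2(lambda, mu, psi, rho)
  ect <- exp(-c1 * t)
  (lambda + mu + psi +
      c1 * (ect * (1 - c2) - (1 + c2)) / (ect * (1 - c2) + (1 + c2))) /
    (2 * lambda)
}

#' Log density of a dated tree under the sampled-ancestor birth-death prior
#'
#' Constant-rate fossilized birth-death process conditioned on the origin
#' time. Tips at age (approximately) zero are treated as extant
#' rho-samples; positive-age tips with a positive pendant edge are
#' psi-sampled fossils whose lineage then leaves no further samples;
#' zero-duration tips are sampled ancestors.
#'
#' @param tt A [timetree()].
#' @param lambda,mu,psi Birth, death and fossil-sampling rates (> 0; `psi
#'   = 0` permitted when the tree has no fossil samples).
#' @param rho Extant sampling probability (default 0, the all-fossil case).
#' @param origin Origin time (> root age).
#' @param extant_tol Ages below this count as extant.
#' @return Log prior density; `-Inf` for out-of-support configurations.
#' @export
fbd_log_density <- function(tt, lambda, mu, psi, rho = 0, origin,
                            extant_tol = 1e-8) {
  if (lambda <= 0 || mu < 0 || psi < 0 || rho < 0 || rho > 1) {
    stop("invalid rates: need lambda > 0, mu >= 0, psi >= 0, rho in [0,1]")
  }
  if (origin < tt$age[tt$root]) return(-Inf)
  if (any(tt$age > origin)) return(-Inf)

  tips <- seq_len(tt$ntip)
  tip_age <- tt$age[tips]
  is_sa <- abs(tt$age[tt$parent[tips]] - tip_age) <= SA_TOL
  is_extant <- !is_sa & tip_age <= extant_tol
  n <- sum(is_extant)
  k <- sum(is_sa)
  m <- tt$ntip - n - k
  if (n > 0 && rho == 0) return(-Inf)
  if ((m + k) > 0 && psi == 0) return(-Inf)

  ## birth nodes: internal nodes that are not a sampled ancestor's
  ## attachment point
  nn <- length(tt$parent)
  is_birth <- rep(TRUE, nn)
  is_birth[tips] <- FALSE
  is_birth[tt$parent[tips][is_sa]] <- FALSE
  births <- which(is_birth)
  fossil <- tips[!is_sa & !is_extant]

  c1 <- fbd_c1(lambda, mu, psi)
  c2 <- fbd_c2(lambda, mu, psi, rho)
  a1 <- (1 - c2)^2
  a2 <- (1 + c2)^2
  a0 <- 2 * (1 - c2^2)
  lq <- function(t) {
    ect <- exp(-c1 * t)
    1.3862943611198906 - log(a0 + a1 * ect + a2 / ect)  # log(4) - log(.)
  }
  ll <- length(births) * log(lambda) + lq(origin) + sum(lq(tt$age[births]))
  if (n > 0) ll <- ll + n * log(rho)
  if (m + k > 0) ll <- ll + (m + k) * log(psi)
  if (m > 0) {
    y <- tt$age[fossil]
    ecy <- exp(-c1 * y)
    p0 <- (lambda + mu + psi +
             c1 * (ecy * (1 - c2) - (1 + c2)) /
             (ecy * (1 - c2) + (1 + c2))) / (2 * lambda)
    ll <- ll + sum(log(p0)) - sum(lq(y))
  }
  if (!is.finite(ll)) return(-Inf)
  ll
}
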