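# Archimedean copula primitives shared by the simulator and the
# individual-level estimator. Survival-scale convention throughout:
# the joint survivor function is S(x, y) = C(S1(x), S2(y)).

.copula_families <- c("clayton", "gumbel", "independence")

# theta bounds used for validation and for the pseudo-likelihood search;
# upper bounds keep u^(-theta) and exp(theta * log x) inside double range
# for margins clamped away from 0 and 1.
.theta_bounds <- list(
  clayton = c(1e-3, 50),
  gumbel  = c(1 + 1e-6, 50)
)

match_family <- function(family) {
  rlang::arg_match0(family, .copula_families, arg_nm = "family")
}

#' Convert between Kendall's tau and the copula association parameter
#'
#' One-parameter Archimedean families map one-to-one between the
#' association parameter \eqn{\theta} and Kendall's \eqn{\tau}:
#' Clayton \eqn{\tau = \theta/(\theta+2)}, Gumbel \eqn{\tau = 1 - 1/\theta}.
#' The independence family has \eqn{\tau = 0} for any input.
#'
#' @param tau Kendall's tau, in `[0, 1)`.
#' @param theta Association parameter (`> 0` for Clayton, `>= 1` for Gumbel).
#' @param family One of `"clayton"`, `"gumbel"`, `"independence"`.
#' @return A numeric scalar (vectorised over the first argument).
#' @examples
#' tau_to_theta(0.5, "clayton")  # 2
#' theta_to_tau(2, "gumbel")     # 0.5
#' @export
tau_to_theta <- function(tau, family) {
  family <- match_family(family)
  if (any(tau < 0 | tau >= 1)) {
    rlang::abort("`tau` must lie in [0, 1) for the implemented families.")
  }
  switch(family,
    clayton = 2 * tau / (1 - tau),
    gumbel = 1 / (1 - tau),
    independence = {
      if (any(tau != 0)) {
        rlang::abort("The independence family requires `tau = 0`.")
      }
      rep(NA_real_, length(tau))
    }
  )
}

#' @rdname tau_to_theta
#' @export
theta_to_tau <- function(theta, family) {
  family <- match_family(family)
  switch(family,
    clayton = theta / (theta + 2),
    gumbel = 1 - 1 / theta,
    independence = rep(0, length(theta))
  )
}

# log(u^-theta + v^-theta - 1), computed via a shifted exponential sum so
# large theta * -log(u) does not overflow.
clayton_log_s <- function(log_u, log_v, theta) {
  a <- -theta * log_u
  b <- -theta * log_v
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m) - exp(-m))
}

# log C(u, v) on the uniform scale
copula_log_cdf <- function(log_u, log_v, theta, family) {
  switch(family,
    independence = log_u + log_v,
    clayton = -clayton_log_s(log_u, log_v, theta) / theta,
    gumbel = {
      la <- gumbel_log_a(log_u, log_v, theta)
      -exp(la)
    }
  )
}

# log A where A = ((-log u)^theta + (-log v)^theta)^(1/theta)
gumbel_log_a <- function(log_u, log_v, theta) {
  a <- theta * log(-log_u)
  b <- theta * log(-log_v)
  m <- pmax(a, b)
  (m + log(exp(a - m) + exp(b - m))) / theta
}

# log of the partial derivative dC/du (contribution when the first margin
# is an observed event and the second is censored)
copula_log_du <- function(log_u, log_v, theta, family) {
  switch(family,
    independence = log_v,
    clayton = (-theta - 1) * log_u +
      (-1 / theta - 1) * clayton_log_s(log_u, log_v, theta),
    gumbel = {
      la <- gumbel_log_a(log_u, log_v, theta)
      -exp(la) + (1 - theta) * la + (theta - 1) * log(-log_u) - log_u
    }
  )
}

copula_log_dv <- function(log_u, log_v, theta, family) {
  copula_log_du(log_v, log_u, theta, family)
}

# log copula density c(u, v) (both margins observed events)
copula_log_density <- function(log_u, log_v, theta, family) {
  switch(family,
    independence = rep(0, length(log_u)),
    clayton = log1p(theta) +
      (-theta - 1) * (log_u + log_v) +
      (-1 / theta - 2) * clayton_log_s(log_u, log_v, theta),
    gumbel = {
      la <- gumbel_log_a(log_u, log_v, theta)
      a <- exp(la)
      -a + (theta - 1) * (log(-log_u) + log(-log_v)) +
        (1 - 2 * theta) * la + log(a + theta - 1) - log_u - log_v
    }
  )
}

#' Spearman's rho implied by a copula parameter
#'
#' Evaluates the population Spearman functional
#' \eqn{\rho = 12 \int\int C(u, v)\, du\, dv - 3} by two-dimensional
#' Gauss-Legendre quadrature on the unit square.
#'
#' @inheritParams tau_to_theta
#' @param n_nodes Number of quadrature nodes per axis; 64 gives accuracy
#'   well beyond 1e-6 for the implemented families.
#' @return Spearman's rho as a numeric scalar.
#' @examples
#' spearman_from_theta(2, "clayton")
#' @export
spearman_from_theta <- function(theta, family, n_nodes = 64) {
  family <- match_family(family)
  if (family == "independence") {
    return(0)
  }
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  lu <- log(gl$x)
  grid <- expand.grid(log_u = lu, log_v = lu)
  w <- as.vector(outer(gl$w, gl$w))
  cvals <- exp(copula_log_cdf(grid$log_u, grid$log_v, theta, family))
  12 * sum(w * cvals) - 3
}

#' Draw dependent uniform pairs from an Archimedean copula
#'
#' Samples `(u, v)` pairs by the Marshall-Olkin frailty construction:
#' a gamma frailty for Clayton, a positive stable frailty
#' (Chambers-Mallows-Stuck) for Gumbel.
#'
#' @inheritParams tau_to_theta
#' @param n Number of pairs.
#' @return A two-column numeric matrix with columns `u`, `v`.
#' @export
sample_copula <- function(n, theta, family) {
  family <- match_family(family)
  if (family == "independence" || (family == "gumbel" && isTRUE(theta == 1))) {
    return(cbind(u = stats::runif(n), v = stats::runif(n)))
  }
  bounds <- .theta_bounds[[family]]
  if (!is.finite(theta) || theta < bounds[1] || theta > bounds[2]) {
    rlang::abort(sprintf(
      "`theta` must lie in [%.3g, %.3g] for the %s family.",
      bounds[1], bounds[2], family
    ))
  }
  e1 <- stats::rexp(n)
  e2 <- stats::rexp(n)
  if (family == "clayton") {
    g <- stats::rgamma(n, shape = 1 / theta, rate = 1)
    u <- (1 + e1 / g)^(-1 / theta)
    v <- (1 + e2 / g)^(-1 / theta)
  } else {
    alpha <- 1 / theta
    s <- rpostable(n, alpha)
    u <- exp(-(e1 / s)^alpha)
    v <- exp(-(e2 / s)^alpha)
  }
  cbind(u = u, v = v)
}

# Positive alpha-stable draw with Laplace transform exp(-t^alpha),
# Chambers-Mallows-Stuck construction.
rpostable <- function(n, alpha) {
  w <- stats::runif(n, 0, pi)
  e <- stats::rexp(n)
  sin(alpha * w) / sin(w)^(1 / alpha) *
    (sin((1 - alpha) * w) / e)^((1 - alpha) / alpha)
}
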