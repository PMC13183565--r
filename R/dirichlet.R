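#' Dirichlet log-likelihood (alternative mean/precision parameterization)
#'
#' Log-likelihood of compositions under the Dirichlet distribution written in
#' its mean/precision form: concentrations alpha_c = mu_c * phi, so each row
#' contributes lgamma(phi) - sum_c lgamma(mu_c phi) + sum_c (mu_c phi - 1)
#' log y_c. For k = 2 this is exactly the beta log-density of the second
#' component with mean mu_2 and precision phi.
#'
#' @param Y sample x k matrix of strictly interior compositions (rows sum
#'   to 1, no exact 0 or 1 entries).
#' @param mu sample x k matrix of mean compositions (rows sum to 1), or a
#'   single mean vector recycled over samples.
#' @param phi positive precision, scalar or per-sample vector.
#' @return total log-likelihood (scalar).
#' @examples
#' dirichlet_loglik(rbind(c(0.2, 0.3, 0.5)), rep(1, 3) / 3, 3)  # log(2)
#' @export
dirichlet_loglik <- function(Y, mu, phi) {
  Y <- rbind(Y)
  if (any(Y <= 0 | Y >= 1))
    stop("dirichlet_loglik: boundary values; shrink/unzero the data first")
  if (is.null(dim(mu))) mu <- matrix(mu, nrow(Y), length(mu), byrow = TRUE)
  if (length(phi) == 1L) phi <- rep(phi, nrow(Y))
  if (any(phi <= 0)) stop("dirichlet_loglik: phi must be positive")
  alpha <- mu * phi
  sum(lgamma(phi)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(Y))
}

#' Boundary shrinkage for compositions
#'
#' The standard (y (n - 1) + 1/k) / n adjustment pulling exact zeros and ones
#' off the boundary of the simplex before beta/Dirichlet likelihood work;
#' closure is conserved.
#'
#' @param Y sample x k composition matrix (rows sum to 1).
#' @return shrunk matrix, strictly interior.
#' @export
shrink_composition <- function(Y) {
  Y <- rbind(Y)
  n <- nrow(Y)
  k <- ncol(Y)
  (Y * (n - 1) + 1 / k) / n
}

# negative log-likelihood + analytic gradient for the mean (multinomial
# logit, component 1 reference) / precision (log link) parameterization.
# par = c(vec(beta[k-1, p]), gamma[q]); with fixed_gamma set, par holds the
# beta part only and phi is held at the supplied value.
dirichlet_obj <- function(par, Y, X, Z, logY, fixed_gamma = NULL) {
  n <- nrow(Y); k <- ncol(Y); p <- ncol(X); q <- ncol(Z)
  beta <- matrix(par[seq_len((k - 1) * p)], k - 1, p)
  gamma <- if (is.null(fixed_gamma)) par[(k - 1) * p + seq_len(q)]
  else fixed_gamma
  eta <- cbind(0, X %*% t(beta))              # n x k
  eta <- eta - apply(eta, 1, max)
  mu <- exp(pmax(eta, -500))
  mu <- pmax(mu / rowSums(mu), 1e-300)
  phi <- exp(pmin(pmax(drop(Z %*% gamma), -30), 30))
  alpha <- mu * phi
  ll <- sum(lgamma(phi)) - sum(lgamma(alpha)) + sum((alpha - 1) * logY)
  g <- digamma(phi) - digamma(alpha) + logY    # n x k
  gbar <- rowSums(mu * g)
  deta <- phi * mu * (g - gbar)                # n x k
  gr_beta <- t(deta[, -1, drop = FALSE]) %*% X # (k-1) x p
  grad <- if (is.null(fixed_gamma)) {
    gr_gamma <- drop(crossprod(Z, phi * gbar))
    -c(as.vector(gr_beta), gr_gamma)
  } else {
    -as.vector(gr_beta)
  }
  if (!is.finite(ll) || any(!is.finite(grad)))
    return(list(value = 1e10, gradient = rep(0, length(par))))
  list(value = -ll, gradient = grad)
}

dirichlet_start <- function(Y, p, q) {
  m <- colMeans(Y)
  k <- length(m)
  beta0 <- matrix(0, k - 1, p)
  beta0[, 1] <- log(m[-1] / m[1])
  v <- apply(Y, 2, stats::var)
  phi0 <- stats::median(m * (1 - m) / pmax(v, 1e-8) - 1)
  phi0 <- min(max(phi0, 1), 1e4)
  gamma0 <- c(log(phi0), rep(0, q - 1))
  c(as.vector(beta0), gamma0)
}

#' Dirichlet regression (alternative parameterization)
#'
#' Maximum-likelihood regression of a k-part composition on covariates, with
#' the mean modeled on the multinomial-logit scale (component 1 as the
#' reference) and a scalar precision phi on the log scale, so that the
#' concentrations are alpha_c = mu_c * phi. Fitting is quasi-Newton (BFGS)
#' with analytic gradients and deterministic fallback restarts; the
#' variance-covariance matrix comes from the numerical Hessian at the
#' optimum.
#'
#' @param Y sample x k matrix of interior compositions (k >= 3; use
#'   [fit_beta_regression()] for two parts). Boundary values should be
#'   pre-shrunk with [shrink_composition()].
#' @param X mean-model design matrix (n x p, including the intercept).
#' @param Z precision-model design matrix (default intercept only).
#' @param start optional start vector (used to warm-start nested fits).
#' @return object of class `dirichlet_fit`: `beta` ((k-1) x p mean
#'   coefficients), `gamma` (log-precision coefficients), `mu`, `phi`,
#'   `loglik`, `converged`, `vcov`, `npar`.
#' @export
fit_dirichlet_regression <- function(Y, X, Z = NULL, start = NULL) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 3)
    stop("fit_dirichlet_regression: k = 2 is a beta regression; ",
         "use fit_beta_regression()")
  fit_dirichlet_core(Y, X, Z, start)
}

fit_dirichlet_core <- function(Y, X, Z = NULL, start = NULL,
                               fixed_gamma = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  if (any(Y <= 0 | Y >= 1))
    stop("compositions must be interior; apply shrink_composition()")
  X <- as.matrix(X)
  if (is.null(Z)) Z <- matrix(1, n, 1)
  Z <- as.matrix(Z)
  logY <- log(Y)
  p <- ncol(X); q <- ncol(Z)
  fn <- function(par) dirichlet_obj(par, Y, X, Z, logY, fixed_gamma)$value
  gr <- function(par) dirichlet_obj(par, Y, X, Z, logY, fixed_gamma)$gradient
  s0 <- dirichlet_start(Y, p, q)
  if (!is.null(fixed_gamma)) s0 <- s0[seq_len((k - 1) * p)]
  starts <- list(if (is.null(start)) s0 else start)
  # deterministic fallback starts: flat means / alternative precisions
  starts <- c(starts, list(s0))
  if (is.null(fixed_gamma))
    starts <- c(starts, list(
      replace(s0, length(s0) - q + 1L, log(10)),
      replace(s0, length(s0) - q + 1L, log(200)),
      rep(0, (k - 1) * p + q)))
  else starts <- c(starts, list(rep(0, (k - 1) * p)))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, fn, gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) stop("Dirichlet fit failed from all starts")
  par <- best$par
  beta <- matrix(par[seq_len((k - 1) * p)], k - 1, p,
                 dimnames = list(colnames(Y)[-1], colnames(X)))
  gamma <- if (is.null(fixed_gamma)) par[(k - 1) * p + seq_len(q)]
  else fixed_gamma
  eta <- cbind(0, X %*% t(beta))
  mu <- exp(eta - apply(eta, 1, max))
  mu <- mu / rowSums(mu)
  colnames(mu) <- colnames(Y)
  phi <- exp(drop(Z %*% gamma))
  H <- tryCatch(stats::optimHess(par, fn, gr), error = function(e) NULL)
  V <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) matrix(NA, length(par),
                                                  length(par)))
  else matrix(NA, length(par), length(par))
  structure(list(beta = beta, gamma = gamma, mu = mu, phi = phi,
                 loglik = -best$value,
                 converged = best$convergence == 0,
                 vcov = V, npar = length(par), k = k,
                 n = n, X = X, Z = Z),
            class = "dirichlet_fit")
}

#' Beta regression via maximum likelihood
#'
#' Regression of a fraction y in (0, 1) on covariates with a logit link for
#' the mean and a log link for the precision phi (the k = 2 reduction of the
#' Dirichlet mean/precision model, fitted by the same quasi-Newton core).
#' Exact zeros/ones are pre-shrunk by the standard (y (n - 1) + 0.5) / n
#' adjustment.
#'
#' @param y numeric vector of fractions in [0, 1].
#' @param X mean-model design matrix (n x p, including the intercept).
#' @param Z precision-model design matrix (default intercept only).
#' @param start optional start vector.
#' @return a `dirichlet_fit` with k = 2; `beta` holds the logit-mean
#'   coefficients of y.
#' @export
fit_beta_regression <- function(y, X, Z = NULL, start = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(y < 0 | y > 1)) stop("fit_beta_regression: y outside [0, 1]")
  if (any(y == 0 | y == 1)) y <- (y * (n - 1) + 0.5) / n
  fit_dirichlet_core(cbind(ref = 1 - y, y = y), X, Z, start)
}

#' @export
print.dirichlet_fit <- function(x, ...) {
  cat("Dirichlet regression (alternative parameterization), k =", x$k,
      ", n =", x$n, "\n")
  cat("log-likelihood:", format(x$loglik), if (!x$converged) "(NOT converged)"
      else "", "\n")
  cat("mean coefficients (multinomial logit, reference = component 1):\n")
  print(x$beta)
  cat("precision: phi =", format(unique(round(x$phi, 4))[1]),
      "(log-scale coef", format(round(x$gamma, 4)), ")\n")
  invisible(x)
}

#' @export
coef.dirichlet_fit <- function(object, ...) {
  c(stats::setNames(as.vector(object$beta),
                    paste(rep(rownames(object$beta),
                              ncol(object$beta)),
                          rep(colnames(object$beta),
                              each = nrow(object$beta)), sep = ":")),
    stats::setNames(object$gamma,
                    paste0("logphi", seq_along(object$gamma))))
}

#' @export
logLik.dirichlet_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, class = "logLik")
}

#' @export
vcov.dirichlet_fit <- function(object, ...) object$vcov
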