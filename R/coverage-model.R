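#' Fit a two-Poisson mixture to node coverages
#'
#' The histogram of average node k-mer coverage in a read-cluster de Bruijn
#' graph is a superposition of two distributions: erroneous nodes with mean
#' `lambda_e` and correct nodes with mean `lambda_c`.  A two-component Poisson
#' mixture is fitted by expectation-maximisation (observations may be
#' non-integer node averages, so the Poisson mass is evaluated as the
#' continuous density \eqn{\lambda^x e^{-\lambda}/\Gamma(x+1)}).  The
#' coverage cutoff separating the two classes is the intersection of the two
#' weighted densities, which has the closed form
#' \deqn{x^* = \frac{\lambda_c - \lambda_e + \ln(w_e/w_c)}{\ln(\lambda_c/\lambda_e)}.}
#'
#' Observations can be weighted (e.g. by unitig length, so a long unitig
#' counts as the many k-mers it represents).
#'
#' @param cov numeric vector of average node coverages (>= 10 values with at
#'   least two distinct values).
#' @param weight optional non-negative observation weights.
#' @param init optional list with starting values `lambda_e`, `lambda_c`,
#'   `w_e`; defaults: `lambda_e = 1`, `lambda_c` = mean of observations above
#'   the overall mean, weights 0.5/0.5.
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @return an object of class `coverage_model` with components `lambda_e`,
#'   `lambda_c`, `w_e`, `w_c`, `cutoff`, `loglik` (per-iteration trace),
#'   `n_iter`, `converged`, `n_obs`.
#' @export
fit_coverage_model <- function(cov, weight = NULL, init = NULL,
                               tol = 1e-6, max_iter = 500L) {
  cov <- as.numeric(cov)
  if (is.null(weight)) weight <- rep(1, length(cov))
  stopifnot(length(weight) == length(cov), all(weight >= 0))
  keep <- weight > 0 & is.finite(cov)
  cov <- cov[keep]; weight <- weight[keep]
  if (length(cov) < 10L)
    stop("model error: need at least 10 observations")
  if (length(unique(cov)) < 2L)
    stop("model error: degenerate data (all coverages identical)")

  dens <- function(x, lambda) exp(x * log(lambda) - lambda - lgamma(x + 1))
  wmean <- sum(weight * cov) / sum(weight)
  le <- init$lambda_e %||% 1
  hi <- cov > wmean
  lc <- init$lambda_c %||% if (any(hi)) sum(weight[hi] * cov[hi]) / sum(weight[hi]) else wmean * 2
  we <- init$w_e %||% 0.5
  if (lc <= le) lc <- le * 2 + 1

  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fe <- we * dens(cov, le)
    fc <- (1 - we) * dens(cov, lc)
    tot <- fe + fc
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(weight * log(tot))
    ll_trace <- c(ll_trace, ll)
    if (it > 1L && abs(ll - ll_trace[it - 1L]) < tol) { converged <- TRUE; break }
    r <- fe / tot
    swe <- sum(weight * r); swc <- sum(weight * (1 - r))
    le_new <- sum(weight * r * cov) / swe
    lc_new <- sum(weight * (1 - r) * cov) / swc
    we <- swe / (swe + swc)
    le <- max(le_new, 1e-8); lc <- max(lc_new, 1e-8)
  }
  if (le > lc) {  # keep the erroneous component as the smaller mean
    tmp <- le; le <- lc; lc <- tmp
    we <- 1 - we
  }
  if ((lc - le) < 1e-3 * max(1, lc))
    stop("model error: EM collapsed to a single component (lambda_e == lambda_c)")
  cutoff <- poisson_intersection(le, lc, we, 1 - we)
  structure(list(lambda_e = le, lambda_c = lc, w_e = we, w_c = 1 - we,
                 cutoff = cutoff, loglik = ll_trace, n_iter = length(ll_trace),
                 converged = converged, n_obs = length(cov)),
            class = "coverage_model")
}

#' Intersection cutoff of two weighted Poisson densities
#'
#' Smallest x >= lambda_e at which the correct-node component dominates:
#' `w_c * Pois(x; lambda_c) >= w_e * Pois(x; lambda_e)`, i.e.
#' `(lambda_c - lambda_e + log(w_e/w_c)) / log(lambda_c/lambda_e)`.  Clamped
#' into the open interval `(lambda_e, lambda_c)`.
#'
#' @param lambda_e,lambda_c component means, `lambda_e < lambda_c`.
#' @param w_e,w_c mixture weights (sum to 1).
#' @return the coverage cutoff.
#' @export
poisson_intersection <- function(lambda_e, lambda_c, w_e = 0.5, w_c = 1 - w_e) {
  if (lambda_e >= lambda_c) stop("model error: requires lambda_e < lambda_c")
  x <- (lambda_c - lambda_e + log(w_e / w_c)) / log(lambda_c / lambda_e)
  eps <- 1e-9 * max(1, lambda_c)
  min(max(x, lambda_e + eps), lambda_c - eps)
}

#' @export
print.coverage_model <- function(x, ...) {
  cat("Two-Poisson coverage mixture\n")
  cat(sprintf("  erroneous: lambda_e = %.3f (weight %.3f)\n", x$lambda_e, x$w_e))
  cat(sprintf("  correct:   lambda_c = %.3f (weight %.3f)\n", x$lambda_c, x$w_c))
  cat(sprintf("  cutoff at density intersection: %.4f\n", x$cutoff))
  cat(sprintf("  %d observations, %d EM iterations (%s)\n", x$n_obs, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @exportS3Method stats::coef
coef.coverage_model <- function(object, ...) {
  c(lambda_e = object$lambda_e, lambda_c = object$lambda_c,
    w_e = object$w_e, w_c = object$w_c, cutoff = object$cutoff)
}

#' @exportS3Method stats::logLik
logLik.coverage_model <- function(object, ...) {
  structure(tail(object$loglik, 1L), df = 3L, class = "logLik")
}

#' Classify coverages as erroneous or correct
#'
#' @param object a `coverage_model`.
#' @param newdata numeric coverages to classify.
#' @param ... unused.
#' @return factor with levels `erroneous`, `correct` by the cutoff rule.
#' @export
predict.coverage_model <- function(object, newdata, ...) {
  factor(ifelse(newdata < object$cutoff, "erroneous", "correct"),
         levels = c("erroneous", "correct"))
}
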