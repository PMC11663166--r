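#' Assay-specific CSF amyloid-positivity cutoffs
#'
#' Container for the per-assay cutoffs on the CSF Abeta42/Abeta40 ratio
#' (x10 scale).  Positivity is always defined as a ratio strictly below
#' the assay's cutoff.  The defaults are the data-driven cutoffs of the
#' two analytical platforms: 0.60 for the Innotest ELISA and 0.86 for the
#' Lumipulse chemiluminescent assay.
#'
#' @param innotest,lumipulse positive cutoffs on the x10 ratio scale.
#' @return An object of class `assay_cutoffs`.
#' @examples
#' classify_amyloid(0.59, "Innotest")   # TRUE
#' classify_amyloid(0.60, "Innotest")   # FALSE (strict inequality)
#' @export
assay_cutoffs <- function(innotest = 0.60, lumipulse = 0.86) {
  stop_if_not_scalar_number(innotest, "innotest", positive = TRUE)
  stop_if_not_scalar_number(lumipulse, "lumipulse", positive = TRUE)
  structure(list(innotest = innotest, lumipulse = lumipulse,
                 direction = "below"),
            class = "assay_cutoffs")
}

#' @export
print.assay_cutoffs <- function(x, ...) {
  cat("CSF Abeta42/Abeta40 assay cutoffs (positive below cutoff):\n")
  cat(sprintf("  Innotest  < %.3g\n  Lumipulse < %.3g\n",
              x$innotest, x$lumipulse))
  invisible(x)
}

#' Classify amyloid status from the CSF ratio
#'
#' Strict less-than comparison of the Abeta42/Abeta40 ratio against the
#' assay-specific cutoff.
#'
#' @param ratio positive numeric vector of ratios (x10 scale).
#' @param assay character vector, `"Innotest"` or `"Lumipulse"` (recycled).
#' @param cutoffs an [assay_cutoffs()] object.
#' @return Logical vector: `TRUE` = amyloid-positive.
#' @export
classify_amyloid <- function(ratio, assay, cutoffs = assay_cutoffs()) {
  if (any(ratio <= 0, na.rm = TRUE))
    stop("ratios must be positive", call. = FALSE)
  known <- c("Innotest", "Lumipulse")
  if (!all(assay %in% known | is.na(assay)))
    stop(sprintf("unknown assay label(s): %s",
                 paste(unique(setdiff(assay, known)), collapse = ", ")),
         call. = FALSE)
  cut <- ifelse(assay == "Innotest", cutoffs$innotest, cutoffs$lumipulse)
  ratio < cut
}

gmm_loglik <- function(x, w, m, s) {
  comp <- vapply(seq_along(w),
                 function(j) log(w[j]) + dnorm(x, m[j], s[j], log = TRUE),
                 numeric(length(x)))
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = length(x))
  mx <- apply(comp, 1, max)
  sum(mx + log(rowSums(exp(comp - mx))))
}

em_once <- function(x, w, m, s, tol, max_iter, floor_sd) {
  n <- length(x)
  k <- length(w)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E step (log-space responsibilities)
    lc <- vapply(seq_len(k),
                 function(j) log(w[j]) + dnorm(x, m[j], s[j], log = TRUE),
                 numeric(n))
    mx <- apply(lc, 1, max)
    ll <- sum(mx + log(rowSums(exp(lc - mx))))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
    r <- exp(lc - mx - log(rowSums(exp(lc - mx))))
    # M step
    nk <- colSums(r)
    w <- nk / n
    m <- colSums(r * x) / nk
    s <- sqrt(colSums(r * (outer(x, m, "-"))^2) / nk)
    s <- pmax(s, floor_sd)
  }
  list(w = w, m = m, s = s, ll = ll, trace = trace,
       iter = iter, converged = converged)
}

#' Fit a univariate Gaussian mixture by expectation-maximization
#'
#' Fits a k-component Gaussian mixture to a numeric vector, used to
#' derive data-driven amyloid-positivity cutoffs from the bimodal CSF
#' Abeta42/Abeta40 ratio distribution.  The best of `n_restarts` EM runs
#' by log-likelihood is returned; components are stored sorted by mean
#' ascending.  The EM log-likelihood is non-decreasing across iterations;
#' convergence is declared when successive log-likelihoods differ by less
#' than `tol`.  Component standard deviations are floored at
#' `sqrt(var_floor_frac * var(values))` to guard against variance
#' collapse.
#'
#' @param values numeric vector with at least `2k` distinct finite values.
#' @param k number of components (default 2).
#' @param init initialization: `"quantile"` (deterministic: component
#'   means at evenly spaced quantiles) or `"kmeans"`.  Restarts beyond
#'   the first perturb the initialization randomly.
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param n_restarts number of EM runs (default 5).
#' @param seed optional seed for the random restarts.
#' @param var_floor_frac variance floor as a fraction of the sample
#'   variance (default 1e-6).
#' @return Object of class `csf_gmm` with elements `weights`, `means`,
#'   `sds`, `log_likelihood`, `n_iter`, `converged`, `loglik_trace`
#'   (of the winning restart), `n`, and the fitted `data`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(90, 0.45, 0.08), rnorm(200, 0.95, 0.15))
#' fit <- fit_csf_gmm(x, k = 2)
#' fit
#' derive_cutoff(fit)
#' @seealso [derive_cutoff()], [classify_amyloid()]
#' @export
fit_csf_gmm <- function(values, k = 2L, init = c("quantile", "kmeans"),
                        tol = 1e-8, max_iter = 500L, n_restarts = 5L,
                        seed = NULL, var_floor_frac = 1e-6) {
  init <- match.arg(init)
  x <- values[is.finite(values)]
  if (length(unique(x)) < 2L * k)
    stop(sprintf("need at least %d distinct finite values to fit %d components",
                 2L * k, k), call. = FALSE)
  if (var(x) == 0)
    stop("all values are identical; mixture fit is degenerate", call. = FALSE)
  floor_sd <- sqrt(var_floor_frac * var(x))
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      if (r == 1L && init == "quantile") {
        m0 <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
      } else if (r == 1L && init == "kmeans") {
        km <- kmeans(x, centers = k, nstart = 5)
        m0 <- sort(km$centers[, 1])
      } else {
        m0 <- sort(quantile(x, probs = sort(runif(k)), names = FALSE))
      }
      s0 <- rep(max(sd(x) / k, floor_sd), k)
      w0 <- rep(1 / k, k)
      fit <- em_once(x, w0, m0, s0, tol, max_iter, floor_sd)
      if (is.null(best) || fit$ll > best$ll) best <- fit
    }
    o <- order(best$m)
    structure(list(weights = best$w[o], means = best$m[o], sds = best$s[o],
                   log_likelihood = best$ll, n_iter = best$iter,
                   converged = best$converged, loglik_trace = best$trace,
                   n = length(x), k = k, data = x,
                   call = match.call()),
              class = "csf_gmm")
  })
}

#' @export
print.csf_gmm <- function(x, digits = 4, ...) {
  cat(sprintf("Gaussian mixture fit (%d components, n = %d)\n", x$k, x$n))
  tab <- rbind(weight = x$weights, mean = x$means, sd = x$sds)
  colnames(tab) <- paste0("comp", seq_len(x$k))
  print(round(tab, digits))
  cat(sprintf("log-likelihood %.4f after %d EM iterations (%s)\n",
              x$log_likelihood, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.csf_gmm <- function(object, ...) {
  print(object)
  if (object$k == 2L) {
    cut <- derive_cutoff(object)
    cat(sprintf("density-crossing cutoff: %.4f%s\n", cut,
                if (!attr(cut, "between_means")) " (outside component means)"
                else ""))
  }
  invisible(object)
}

#' @export
coef.csf_gmm <- function(object, ...) {
  k <- object$k
  setNames(c(object$weights, object$means, object$sds),
           c(paste0("weight", seq_len(k)), paste0("mean", seq_len(k)),
             paste0("sd", seq_len(k))))
}

#' @export
logLik.csf_gmm <- function(object, ...) {
  structure(object$log_likelihood, df = 3L * object$k - 1L,
            nobs = object$n, class = "logLik")
}

#' Posterior component membership for new values
#'
#' @param object a `csf_gmm` fit.
#' @param newdata numeric vector (defaults to the fitted data).
#' @param type `"posterior"` for the n-by-k matrix of membership
#'   probabilities, `"class"` for the maximum-posterior component index.
#' @param ... unused.
#' @export
predict.csf_gmm <- function(object, newdata = object$data,
                            type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  lc <- vapply(seq_len(object$k),
               function(j) log(object$weights[j]) +
                 dnorm(newdata, object$means[j], object$sds[j], log = TRUE),
               numeric(length(newdata)))
  if (is.null(dim(lc))) lc <- matrix(lc, nrow = length(newdata))
  mx <- apply(lc, 1, max)
  post <- exp(lc - mx - log(rowSums(exp(lc - mx))))
  colnames(post) <- paste0("comp", seq_len(object$k))
  if (type == "posterior") post else max.col(post)
}

#' @export
simulate.csf_gmm <- function(object, nsim = object$n, seed = NULL, ...) {
  with_seed(seed, {
    comp <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
    rnorm(nsim, object$means[comp], object$sds[comp])
  })
}

#' @export
plot.csf_gmm <- function(x, breaks = 30, main = "Gaussian mixture fit",
                         xlab = "value", ...) {
  hist(x$data, breaks = breaks, freq = FALSE, main = main, xlab = xlab, ...)
  xs <- seq(min(x$data), max(x$data), length.out = 400)
  for (j in seq_len(x$k))
    lines(xs, x$weights[j] * dnorm(xs, x$means[j], x$sds[j]), col = j + 1)
  lines(xs, rowSums(vapply(seq_len(x$k), function(j)
    x$weights[j] * dnorm(xs, x$means[j], x$sds[j]), numeric(length(xs)))),
    lwd = 2)
  if (x$k == 2L) abline(v = derive_cutoff(x), lty = 2)
  invisible(x)
}

#' Data-driven cutoff from a two-component mixture fit
#'
#' Returns the point between the two component means where the weighted
#' component densities cross — equivalently where the posterior
#' probability of either component is 0.5 — located by bisection to
#' 1e-8.  If the weighted densities do not cross between the means
#' (possible with very unequal weights and variances), the crossing
#' nearest the lower mean is returned and flagged via the
#' `between_means` attribute.
#'
#' @param fit a converged `csf_gmm` with `k = 2` and distinct means.
#' @return The cutoff (numeric scalar) with logical attribute
#'   `between_means`.
#' @export
derive_cutoff <- function(fit) {
  if (!inherits(fit, "csf_gmm")) stop("'fit' must be a csf_gmm", call. = FALSE)
  if (fit$k != 2L) stop("cutoff derivation requires exactly 2 components",
                        call. = FALSE)
  m <- fit$means; s <- fit$sds; w <- fit$weights
  if (abs(m[1] - m[2]) < 1e-12)
    stop("component means are identical; no cutoff exists", call. = FALSE)
  f <- function(x) log(w[1]) + dnorm(x, m[1], s[1], log = TRUE) -
    log(w[2]) - dnorm(x, m[2], s[2], log = TRUE)
  if (f(m[1]) > 0 && f(m[2]) < 0) {
    root <- bisect(f, m[1], m[2], tol = 1e-8)
    return(structure(root, between_means = TRUE))
  }
  # No sign change between the means: solve the density-equality
  # quadratic directly and take the root nearest the lower mean.
  a <- 1 / s[2]^2 - 1 / s[1]^2
  b <- 2 * (m[1] / s[1]^2 - m[2] / s[2]^2)
  cc <- m[2]^2 / s[2]^2 - m[1]^2 / s[1]^2 +
    2 * (log(w[1]) - log(w[2]) + log(s[2]) - log(s[1]))
  if (abs(a) < 1e-14) {
    root <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0)
      stop("weighted component densities never cross", call. = FALSE)
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    root <- roots[which.min(abs(roots - m[1]))]
  }
  structure(root, between_means = FALSE)
}

bisect <- function(f, lo, hi, tol = 1e-8, max_iter = 200L) {
  flo <- f(lo)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (hi - lo < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}
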