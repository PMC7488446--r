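## Candidate distribution families for regional T2 samples.
##
## Each family is a list with:
##   name      - identifier used in outputs
##   n_params  - k, number of free parameters
##   support   - function(x) -> TRUE if every sample lies in the support
##   logpdf    - function(x, params) -> log-density vector
##   fit       - function(x) -> list(params = named numeric, converged = flag)
## Families with closed-form MLEs use them; the rest maximize numerically on
## unconstrained transforms of the parameters.

.opt_mle <- function(x, start, nll, maxit = 500) {
  # generic numeric MLE on an unconstrained parameterization
  opt <- tryCatch(
    stats::optim(start, nll, method = if (length(start) > 1) "Nelder-Mead" else "BFGS",
                 control = list(reltol = 1e-10, maxit = maxit)),
    error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  list(par = opt$par, converged = opt$convergence == 0L)
}

.pos <- function(x) all(x > 0)
.any_real <- function(x) TRUE

.fam <- function(name, n_params, support, logpdf, fit) {
  list(name = name, n_params = n_params, support = support,
       logpdf = logpdf, fit = fit)
}

.make_registry <- function() {
  fams <- list(

    .fam("loglogistic", 2L, .pos,
      function(x, p) dloglogis(x, p[["mu"]], p[["sigma"]], log = TRUE),
      function(x) {
        f <- fit_loglogistic_mle(x)
        list(params = c(mu = f$mu, sigma = f$sigma), converged = f$converged)
      }),

    .fam("lognormal", 2L, .pos,
      function(x, p) stats::dlnorm(x, p[["meanlog"]], p[["sdlog"]], log = TRUE),
      function(x) {
        lx <- log(x); m <- mean(lx); s <- sqrt(mean((lx - m)^2))
        list(params = c(meanlog = m, sdlog = s), converged = s > 0)
      }),

    .fam("logistic", 2L, .any_real,
      function(x, p) stats::dlogis(x, p[["location"]], p[["scale"]], log = TRUE),
      function(x) {
        start <- c(stats::median(x), log(max(stats::sd(x) * sqrt(3) / pi, 1e-12)))
        o <- .opt_mle(x, start, function(th)
          -sum(stats::dlogis(x, th[1], exp(th[2]), log = TRUE)))
        if (is.null(o)) return(NULL)
        list(params = c(location = o$par[1], scale = exp(o$par[2])),
             converged = o$converged)
      }),

    .fam("normal", 2L, .any_real,
      function(x, p) stats::dnorm(x, p[["mean"]], p[["sd"]], log = TRUE),
      function(x) {
        m <- mean(x); s <- sqrt(mean((x - m)^2))  # MLE, /n
        list(params = c(mean = m, sd = s), converged = s > 0)
      }),

    .fam("gamma", 2L, .pos,
      function(x, p) stats::dgamma(x, shape = p[["shape"]], rate = p[["rate"]], log = TRUE),
      function(x) {
        s <- log(mean(x)) - mean(log(x))
        if (s <= 0) return(NULL)
        k0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
        k <- tryCatch(stats::uniroot(function(k) log(k) - digamma(k) - s,
                                     interval = c(k0 / 10, k0 * 10),
                                     extendInt = "yes", tol = 1e-12)$root,
                      error = function(e) NA_real_)
        if (!is.finite(k)) return(NULL)
        list(params = c(shape = k, rate = k / mean(x)), converged = TRUE)
      }),

    .fam("weibull", 2L, .pos,
      function(x, p) stats::dweibull(x, p[["shape"]], p[["scale"]], log = TRUE),
      function(x) {
        lx <- log(x); mlx <- mean(lx)
        g <- function(k) sum(x^k * lx) / sum(x^k) - 1 / k - mlx
        k <- tryCatch(stats::uniroot(g, c(0.02, 50), extendInt = "yes",
                                     tol = 1e-12)$root,
                      error = function(e) NA_real_)
        if (!is.finite(k) || k <= 0) return(NULL)
        list(params = c(shape = k, scale = mean(x^k)^(1 / k)), converged = TRUE)
      }),

    .fam("exponential", 1L, .pos,
      function(x, p) stats::dexp(x, p[["rate"]], log = TRUE),
      function(x) list(params = c(rate = 1 / mean(x)), converged = TRUE)),

    .fam("rayleigh", 1L, .pos,
      function(x, p) log(x) - 2 * log(p[["scale"]]) - x^2 / (2 * p[["scale"]]^2),
      function(x) list(params = c(scale = sqrt(mean(x^2) / 2)), converged = TRUE)),

    .fam("invgauss", 2L, .pos,
      function(x, p) 0.5 * (log(p[["lambda"]]) - log(2 * pi) - 3 * log(x)) -
        p[["lambda"]] * (x - p[["mean"]])^2 / (2 * p[["mean"]]^2 * x),
      function(x) {
        m <- mean(x); il <- mean(1 / x) - 1 / m
        if (il <= 0) return(NULL)
        list(params = c(mean = m, lambda = 1 / il), converged = TRUE)
      }),

    .fam("birnbaum-saunders", 2L, .pos,
      function(x, p) {
        a <- p[["shape"]]; b <- p[["scale"]]
        xi <- sqrt(x / b) - sqrt(b / x)
        log(sqrt(x / b) + sqrt(b / x)) - log(2 * a * x) +
          stats::dnorm(xi / a, log = TRUE)
      },
      function(x) {
        b0 <- stats::median(x)
        a0 <- max(stats::sd(sqrt(x / b0) - sqrt(b0 / x)), 1e-6)
        o <- .opt_mle(x, c(log(a0), log(b0)), function(th) {
          a <- exp(th[1]); b <- exp(th[2])
          xi <- sqrt(x / b) - sqrt(b / x)
          -sum(log(sqrt(x / b) + sqrt(b / x)) - log(2 * a * x) +
                 stats::dnorm(xi / a, log = TRUE))
        })
        if (is.null(o)) return(NULL)
        list(params = c(shape = exp(o$par[1]), scale = exp(o$par[2])),
             converged = o$converged)
      }),

    .fam("gev", 3L, .any_real,
      function(x, p) .gev_logpdf(x, p[["location"]], p[["scale"]], p[["shape"]]),
      function(x) {
        s0 <- stats::sd(x) * sqrt(6) / pi
        m0 <- mean(x) - 0.5772156649 * s0
        o <- .opt_mle(x, c(m0, log(s0), 0.1), function(th) {
          ll <- .gev_logpdf(x, th[1], exp(th[2]), th[3])
          if (any(!is.finite(ll))) return(1e10)
          -sum(ll)
        })
        if (is.null(o)) return(NULL)
        list(params = c(location = o$par[1], scale = exp(o$par[2]),
                        shape = o$par[3]), converged = o$converged)
      }),

    .fam("gpd", 2L, .pos,
      function(x, p) .gpd_logpdf(x, p[["scale"]], p[["shape"]]),
      function(x) {
        o <- .opt_mle(x, c(log(mean(x)), 0.05), function(th) {
          ll <- .gpd_logpdf(x, exp(th[1]), th[2])
          if (any(!is.finite(ll))) return(1e10)
          -sum(ll)
        })
        if (is.null(o)) return(NULL)
        list(params = c(scale = exp(o$par[1]), shape = o$par[2]),
             converged = o$converged)
      }),

    .fam("nakagami", 2L, .pos,
      function(x, p) {
        m <- p[["shape"]]; om <- p[["spread"]]
        log(2) + m * log(m / om) - lgamma(m) + (2 * m - 1) * log(x) -
          m * x^2 / om
      },
      function(x) {
        # x^2 ~ Gamma(shape = m, scale = spread/m): reuse the gamma MLE
        y <- x^2
        s <- log(mean(y)) - mean(log(y))
        if (s <= 0) return(NULL)
        k0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
        m <- tryCatch(stats::uniroot(function(k) log(k) - digamma(k) - s,
                                     c(k0 / 10, k0 * 10), extendInt = "yes",
                                     tol = 1e-12)$root,
                      error = function(e) NA_real_)
        if (!is.finite(m)) return(NULL)
        list(params = c(shape = m, spread = mean(y)), converged = TRUE)
      }),

    .fam("rician", 2L, .pos,
      function(x, p) .rician_logpdf(x, p[["nu"]], p[["sigma"]]),
      function(x) {
        v <- stats::var(x); m2 <- mean(x^2)
        nu0 <- sqrt(max(m2 - 2 * v, m2 * 0.01))
        s0 <- sqrt(max(v, m2 * 1e-4))
        o <- .opt_mle(x, c(log(nu0), log(s0)), function(th) {
          ll <- .rician_logpdf(x, exp(th[1]), exp(th[2]))
          if (any(!is.finite(ll))) return(1e10)
          -sum(ll)
        })
        if (is.null(o)) return(NULL)
        list(params = c(nu = exp(o$par[1]), sigma = exp(o$par[2])),
             converged = o$converged)
      }),

    .fam("t-locationscale", 3L, .any_real,
      function(x, p) stats::dt((x - p[["location"]]) / p[["scale"]],
                               df = p[["df"]], log = TRUE) - log(p[["scale"]]),
      function(x) {
        s0 <- max(stats::IQR(x) / 1.349, 1e-12)
        o <- .opt_mle(x, c(stats::median(x), log(s0), log(10)), function(th) {
          -sum(stats::dt((x - th[1]) / exp(th[2]), df = exp(th[3]), log = TRUE) -
                 th[2])
        })
        if (is.null(o)) return(NULL)
        list(params = c(location = o$par[1], scale = exp(o$par[2]),
                        df = exp(o$par[3])), converged = o$converged)
      }),

    .fam("uniform", 2L, .any_real,
      function(x, p) stats::dunif(x, p[["min"]], p[["max"]], log = TRUE),
      function(x) {
        if (max(x) <= min(x)) return(NULL)
        list(params = c(min = min(x), max = max(x)), converged = TRUE)
      }),

    .fam("halfnormal", 1L, .pos,
      function(x, p) 0.5 * log(2 / pi) - log(p[["sigma"]]) -
        x^2 / (2 * p[["sigma"]]^2),
      function(x) list(params = c(sigma = sqrt(mean(x^2))), converged = TRUE)),

    .fam("betaprime", 2L, .pos,
      function(x, p) (p[["alpha"]] - 1) * log(x) -
        (p[["alpha"]] + p[["beta"]]) * log1p(x) -
        lbeta(p[["alpha"]], p[["beta"]]),
      function(x) {
        m <- mean(x); v <- max(stats::var(x), 1e-12)
        b0 <- 2 + m * (m + 1) / v
        a0 <- m * (b0 - 1)
        o <- .opt_mle(x, c(log(a0), log(b0)), function(th) {
          a <- exp(th[1]); b <- exp(th[2])
          -sum((a - 1) * log(x) - (a + b) * log1p(x) - lbeta(a, b))
        })
        if (is.null(o)) return(NULL)
        list(params = c(alpha = exp(o$par[1]), beta = exp(o$par[2])),
             converged = o$converged)
      })
  )
  names(fams) <- vapply(fams, `[[`, "", "name")
  fams
}

.gev_logpdf <- function(x, loc, scale, shape) {
  if (scale <= 0) return(rep(-Inf, length(x)))
  z <- (x - loc) / scale
  if (abs(shape) < 1e-8) {
    -log(scale) - z - exp(-z)
  } else {
    t <- 1 + shape * z
    out <- rep(-Inf, length(x))
    ok <- t > 0
    out[ok] <- -log(scale) - (1 / shape + 1) * log(t[ok]) - t[ok]^(-1 / shape)
    out
  }
}

.gpd_logpdf <- function(x, scale, shape) {
  if (scale <= 0) return(rep(-Inf, length(x)))
  z <- x / scale
  if (abs(shape) < 1e-8) return(-log(scale) - z)
  t <- 1 + shape * z
  out <- rep(-Inf, length(x))
  ok <- t > 0 & x >= 0
  out[ok] <- -log(scale) - (1 / shape + 1) * log(t[ok])
  out
}

.rician_logpdf <- function(x, nu, sigma) {
  if (nu < 0 || sigma <= 0) return(rep(-Inf, length(x)))
  t <- x * nu / sigma^2
  # besselI(..., expon.scaled) avoids overflow: log I0(t) = log(Is) + t
  log(x) - 2 * log(sigma) - (x^2 + nu^2) / (2 * sigma^2) +
    log(besselI(t, 0, expon.scaled = TRUE)) + t
}

#' Default registry of candidate distribution families
#'
#' Returns the catalogue of 18 families fitted to regional T2 samples:
#' log-logistic, log-normal, logistic, normal, gamma, Weibull, exponential,
#' Rayleigh, inverse Gaussian, Birnbaum-Saunders, generalized extreme value,
#' generalized Pareto, Nakagami, Rician, t location-scale, uniform,
#' half-normal and beta-prime. The headline T2 metrics depend only on the
#' log-logistic entry; the rest exist so AIC model selection is a real
#' contest. The registry order is also the tie-break order.
#'
#' @param names optional character vector selecting a subset, in the order
#'   given.
#' @return named list of family definitions.
#' @export
family_registry <- function(names = NULL) {
  reg <- .make_registry()
  if (is.null(names)) return(reg)
  missing <- setdiff(names, base::names(reg))
  if (length(missing))
    stop("unknown families: ", paste(missing, collapse = ", "))
  reg[names]
}

#' Fit one distribution family to a sample by maximum likelihood
#'
#' @param x sample vector.
#' @param family a family definition from [family_registry()], or a family
#'   name.
#' @return an object of class \code{"distribution_fit"}: list with
#'   \code{family}, \code{params}, \code{loglik}, \code{aic}
#'   (\eqn{2k - 2\ell}), \code{n}, \code{converged}, and \code{skipped}
#'   (with \code{reason}) when the sample violates the family's support or
#'   is smaller than the parameter count.
#' @export
fit_family <- function(x, family) {
  if (is.character(family)) family <- family_registry(family)[[1]]
  n <- length(x)
  skip <- function(reason)
    structure(list(family = family$name, params = NULL, loglik = NA_real_,
                   aic = NA_real_, n = n, converged = FALSE, skipped = TRUE,
                   reason = reason), class = "distribution_fit")
  if (n < family$n_params) return(skip("fewer samples than parameters"))
  if (!family$support(x)) return(skip("sample outside family support"))
  res <- tryCatch(family$fit(x), error = function(e) NULL)
  if (is.null(res)) return(skip("fit failed"))
  ll <- sum(family$logpdf(x, res$params))
  if (!is.finite(ll)) return(skip("non-finite log-likelihood at MLE"))
  structure(list(family = family$name, params = res$params, loglik = ll,
                 aic = 2 * family$n_params - 2 * ll, n = n,
                 converged = isTRUE(res$converged), skipped = FALSE,
                 reason = NULL),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat(sprintf("<%s fit skipped: %s (n = %d)>\n", x$family, x$reason, x$n))
  } else {
    cat(sprintf("<%s fit: n = %d, loglik = %.3f, AIC = %.3f, converged = %s>\n",
                x$family, x$n, x$loglik, x$aic, x$converged))
    print(x$params)
  }
  invisible(x)
}

#' Fit every family in a registry to one sample
#'
#' @param x sample vector.
#' @param registry list of family definitions (default: all 18).
#' @return named list of \code{distribution_fit} objects.
#' @export
fit_all_families <- function(x, registry = family_registry()) {
  lapply(registry, function(fam) fit_family(x, fam))
}

#' Select the best-fitting family by lowest AIC
#'
#' Considers converged, non-skipped fits only; ties are broken by fewer
#' parameters, then by position in the supplied list (the registry order).
#'
#' @param fits list of \code{distribution_fit} objects.
#' @return the winning family name (character).
#' @export
select_best <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) && !isTRUE(f$skipped) &&
                 is.finite(f$aic), logical(1))
  if (!any(ok)) stop("no converged fits to select from")
  fits <- fits[ok]
  aic <- vapply(fits, `[[`, 0, "aic")
  k <- vapply(fits, function(f) length(f$params), 0L)
  ord <- order(aic, k, seq_along(fits))
  fits[[ord[1]]]$family
}

#' Modal best-fitting family across many fits
#'
#' @param best character vector of winning family names (one per ROI fit),
#'   or a list of region summaries carrying \code{best_family} entries.
#' @param registry_order character vector giving the tie-break order
#'   (default: the default registry order).
#' @return list with \code{family} (the mode), \code{counts} (named table,
#'   decreasing), and \code{tie} (TRUE when the mode is not unique; broken
#'   by registry order).
#' @export
modal_best_family <- function(best, registry_order = names(family_registry())) {
  if (is.list(best))
    best <- unlist(lapply(best, function(s)
      if (!is.null(s$best_family)) s$best_family else s))
  best <- as.character(best)
  if (!length(best)) stop("no best-family records supplied")
  counts <- sort(table(best), decreasing = TRUE)
  top <- names(counts)[counts == max(counts)]
  tie <- length(top) > 1
  if (tie) {
    in_reg <- top[top %in% registry_order]
    winner <- if (length(in_reg)) in_reg[order(match(in_reg, registry_order))][1] else sort(top)[1]
  } else winner <- top[1]
  list(family = winner, counts = counts, tie = tie)
}

#' Summarize a region's T2 distribution from both hemispheres
#'
#' Fits the family registry to each hemisphere's capped T2 sample, records
#' the AIC winner per hemisphere, and always computes the log-logistic fit
#' (whose parameters are the reported metrics, regardless of which family
#' wins the AIC contest). Region-level T2mu and T2sigma combine the two
#' hemisphere estimates.
#'
#' @param left,right ROI sample vectors (from [extract_roi_samples()]) or
#'   plain numeric vectors; either may be NULL for single-hemisphere mode.
#' @param registry family registry for the AIC contest; set to
#'   \code{family_registry("loglogistic")} to skip the contest.
#' @param combine \code{"average"} (unweighted mean of hemisphere
#'   parameters, default), \code{"weighted"} (voxel-count weighted), or
#'   \code{"pooled"} (single fit to the concatenated sample).
#' @param subject_id,region optional labels carried into the summary.
#' @return an object of class \code{"region_t2_summary"}: list with
#'   \code{T2mu}, \code{T2sigma}, \code{best_family}, per-hemisphere
#'   \code{hemispheres} (mu, sigma, loglik, n, best_family, converged), and
#'   \code{single_hemisphere} flag.
#' @export
summarize_region <- function(left, right, registry = family_registry(),
                             combine = c("average", "weighted", "pooled"),
                             subject_id = NA_character_,
                             region = NA_character_) {
  combine <- match.arg(combine)
  vals <- function(v) if (inherits(v, "roi_samples")) v$values else v
  left <- vals(left); right <- vals(right)
  hem_in <- list(left = left, right = right)
  hem_in <- hem_in[!vapply(hem_in, function(v) is.null(v) || !length(v), logical(1))]
  if (!length(hem_in)) stop("both hemispheres empty: nothing to summarize")

  hems <- lapply(hem_in, function(v) {
    ll <- fit_loglogistic_mle(v)
    best <- if (length(registry) > 1) select_best(fit_all_families(v, registry))
            else registry[[1]]$name
    list(mu = ll$mu, sigma = ll$sigma, loglik = ll$loglik, n = ll$n,
         converged = ll$converged, best_family = best)
  })

  if (combine == "pooled" || length(hems) == 1) {
    if (combine == "pooled" && length(hem_in) > 1) {
      pooled <- fit_loglogistic_mle(unlist(hem_in, use.names = FALSE))
      mu <- pooled$mu; sigma <- pooled$sigma
    } else {
      mu <- hems[[1]]$mu; sigma <- hems[[1]]$sigma
    }
  } else {
    w <- if (combine == "weighted")
      vapply(hems, `[[`, 0, "n") else rep(1, length(hems))
    w <- w / sum(w)
    mu <- sum(w * vapply(hems, `[[`, 0, "mu"))
    sigma <- sum(w * vapply(hems, `[[`, 0, "sigma"))
  }

  best_all <- vapply(hems, `[[`, "", "best_family")
  structure(list(subject_id = subject_id, region = region,
                 T2mu = mu, T2sigma = sigma,
                 best_family = modal_best_family(
                   best_all, registry_order = names(registry))$family,
                 hemispheres = hems,
                 single_hemisphere = length(hems) == 1),
            class = "region_t2_summary")
}

#' @export
print.region_t2_summary <- function(x, ...) {
  cat(sprintf("<region T2 summary: %s / %s>\n", x$subject_id, x$region))
  cat(sprintf("  T2mu = %.4f log-ms (median %.1f ms), T2sigma = %.4f\n",
              x$T2mu, exp(x$T2mu), x$T2sigma))
  cat(sprintf("  best family: %s; hemispheres: %s\n", x$best_family,
              paste(names(x$hemispheres), collapse = ", ")))
  invisible(x)
}
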