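# Drivers of diversity: GLS regression of a per-bin diversity series on
# covariate time series with AR(1) errors, fitted by exact maximum
# likelihood, plus exhaustive subset enumeration ranked by AICc.
#
# Likelihood: y ~ N(X beta, sigma^2 V(rho)) with V the AR(1) correlation
# structure scaled by the innovation variance (V_ij = rho^|i-j| / (1-rho^2)).
# For fixed rho the model is whitened (first observation scaled by
# sqrt(1-rho^2), then successive differences y_t - rho*y_{t-1}); beta and
# sigma have closed-form profile estimates and rho is maximised numerically
# on (-1, 1). log|V| = -log(1-rho^2), so the exact Gaussian log-likelihood is
# -n/2 log(2 pi sigma^2) - n/2 + log(1-rho^2)/2.

#' Log-transform covariate series aligned to time bins
#'
#' Applies a natural log to every strictly positive series; series containing
#' zeros use `log1p` and are flagged. Negative values are an error. Bins with
#' any missing covariate are dropped listwise and counted.
#'
#' @param series Tibble with a `bin` column and one numeric column per
#'   covariate.
#' @param transform `"log"` (default) or `"none"`.
#' @param standardize Also centre/scale each transformed series
#'   (default `FALSE`).
#' @return The transformed tibble; attributes `"transforms"` (named vector
#'   of `log`/`log1p`/`none` per series) and `"dropped_bins"` (count).
#' @export
prepare_covariates <- function(series, transform = c("log", "none"),
                               standardize = FALSE) {
  transform <- arg_match(transform)
  stopifnot("bin" %in% names(series))
  covars <- setdiff(names(series), "bin")
  notes <- setNames(rep("none", length(covars)), covars)
  out <- series
  if (transform == "log") {
    for (cv in covars) {
      x <- out[[cv]]
      if (any(x < 0, na.rm = TRUE)) {
        abort_pd(paste0("series '", cv, "' has negative values; log undefined"),
                 "pd_input_error")
      }
      if (any(x == 0, na.rm = TRUE)) {
        out[[cv]] <- log1p(x)
        notes[cv] <- "log1p"
      } else {
        out[[cv]] <- log(x)
        notes[cv] <- "log"
      }
    }
  }
  if (standardize) {
    for (cv in covars) out[[cv]] <- as.numeric(scale(out[[cv]]))
  }
  complete <- stats::complete.cases(out[covars])
  dropped <- sum(!complete)
  out <- out[complete, ]
  if (dropped > 0) {
    rlang::inform(paste0(dropped, " bin(s) dropped for missing covariates"))
  }
  attr(out, "transforms") <- notes
  attr(out, "dropped_bins") <- dropped
  out
}

ar1_profile <- function(rho, y, X) {
  n <- length(y)
  w <- c(sqrt(1 - rho^2), rep(1, n - 1))
  Wy <- c(y[1] * w[1], y[-1] - rho * y[-n])
  WX <- rbind(X[1, , drop = FALSE] * w[1],
              X[-1, , drop = FALSE] - rho * X[-n, , drop = FALSE])
  fit <- stats::lm.fit(WX, Wy)
  rss <- sum(fit$residuals^2)
  sigma2 <- max(rss / n, 1e-300)
  loglik <- -n / 2 * log(2 * pi * sigma2) - n / 2 + log(1 - rho^2) / 2
  list(loglik = loglik, beta = fit$coefficients, sigma = sqrt(sigma2), rss = rss)
}

#' GLS fit with AR(1) errors by maximum likelihood
#'
#' Fits `y ~ X` with first-order autoregressive errors. For each candidate
#' autocorrelation the model is whitened and the coefficients and residual
#' scale profiled in closed form; the autocorrelation is then maximised
#' numerically on (-1, 1) and the exact Gaussian log-likelihood reported.
#' The parameter count follows the convention `df = p + 2` (coefficients
#' including the intercept, plus the AR(1) parameter and the residual
#' scale), so an intercept-only fit has `df = 3`, and
#' `AICc = -2 loglik + 2 df + 2 df (df + 1) / (n - df - 1)`.
#'
#' @param y Response series (per-bin diversity, untransformed by default
#'   convention).
#' @param X Covariate matrix or tibble (no intercept column; one is added).
#' @param rho `NULL` to estimate the AR(1) parameter by ML (default), or a
#'   fixed value in (-1, 1); `rho = 0` reduces the fit to ordinary least
#'   squares.
#' @return An object of class `"gls_ar1"`: coefficients, `rho`, `sigma`,
#'   `loglik`, `df`, `aicc`, `n`, `terms`.
#' @export
gls_ar1 <- function(y, X = NULL, rho = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X) || (!is.null(dim(X)) && ncol(X) == 0)) {
    Xm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    Xm <- as.matrix(X)
    if (is.null(colnames(Xm))) colnames(Xm) <- paste0("x", seq_len(ncol(Xm)))
    Xm <- cbind("(Intercept)" = 1, Xm)
  }
  if (any(!is.finite(y)) || any(!is.finite(Xm))) {
    abort_pd("non-finite values in response or covariates", "pd_input_error")
  }
  p <- ncol(Xm)
  df <- p + 2
  if (n <= df) {
    abort_pd(sprintf("n = %d too small for df = %d", n, df), "pd_input_error")
  }
  if (is.null(rho)) {
    opt <- stats::optimize(function(r) ar1_profile(r, y, Xm)$loglik,
                           interval = c(-0.99, 0.99), maximum = TRUE,
                           tol = 1e-8)
    rho_hat <- opt$maximum
  } else {
    if (abs(rho) >= 1) abort_pd("fixed rho must lie in (-1, 1)", "pd_input_error")
    rho_hat <- rho
  }
  best <- ar1_profile(rho_hat, y, Xm)
  if (!is.finite(best$loglik)) {
    abort_pd("non-finite log-likelihood", "pd_fit_error")
  }
  aicc <- -2 * best$loglik + 2 * df + 2 * df * (df + 1) / (n - df - 1)
  structure(
    list(
      coefficients = setNames(as.numeric(best$beta), colnames(Xm)),
      rho = rho_hat,
      sigma = best$sigma,
      loglik = best$loglik,
      df = df,
      aicc = aicc,
      n = n,
      terms = setdiff(colnames(Xm), "(Intercept)")
    ),
    class = "gls_ar1"
  )
}

#' @export
print.gls_ar1 <- function(x, ...) {
  cat("<gls_ar1> GLS with AR(1) errors (ML)\n")
  cat("  terms:", if (length(x$terms)) paste(x$terms, collapse = " + ")
      else "(intercept only)", "\n")
  cat(sprintf("  n = %d, df = %d, rho = %.3f, loglik = %.3f, AICc = %.3f\n",
              x$n, x$df, x$rho, x$loglik, x$aicc))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname gls_ar1
#' @param x A `"gls_ar1"` object.
#' @param ... Unused.
#' @method tidy gls_ar1
#' @export
tidy.gls_ar1 <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname gls_ar1
#' @method glance gls_ar1
#' @export
glance.gls_ar1 <- function(x, ...) {
  tibble(
    df = x$df, logLik = x$loglik, AICc = x$aicc,
    rho = x$rho, sigma = x$sigma, nobs = x$n
  )
}

#' Exhaustive covariate-subset selection by AICc
#'
#' Fits a [gls_ar1()] model for every subset of the candidate covariates
#' (including the intercept-only model, `2^p` fits in total) and ranks them
#' by AICc. Ties are broken by fewer parameters, then by the lexical order
#' of the covariate combination.
#'
#' @param y Response series.
#' @param covariates Tibble/matrix of candidate covariates (columns named).
#' @param max_covariates Enumeration guard (default 12).
#' @return A tibble of class `"model_selection"`: `model` (covariate
#'   formula text), `k_covariates`, `df`, `loglik`, `aicc`, `delta_aicc`,
#'   `rank`, and a list-column `fit`.
#' @export
dredge_gls <- function(y, covariates, max_covariates = 12) {
  covariates <- as_tibble(covariates)
  p <- ncol(covariates)
  if (p > max_covariates) {
    abort_pd(
      sprintf("%d covariates would need %s fits; prune the candidate set",
              p, format(2^p, big.mark = ",")),
      "pd_config_error"
    )
  }
  nm <- sort(names(covariates))
  subsets <- purrr::map(0:p, ~ utils::combn(nm, .x, simplify = FALSE)) %>%
    purrr::flatten()
  rows <- purrr::map(subsets, function(vars) {
    fit <- gls_ar1(y, if (length(vars)) covariates[vars] else NULL)
    tibble(
      model = if (length(vars)) {
        paste("(intercept) +", paste(vars, collapse = " + "))
      } else "(intercept)",
      k_covariates = length(vars),
      df = fit$df,
      loglik = fit$loglik,
      aicc = fit$aicc,
      fit = list(fit)
    )
  }) %>%
    bind_rows() %>%
    arrange(.data$aicc, .data$k_covariates, .data$model) %>%
    mutate(delta_aicc = .data$aicc - .data$aicc[1], rank = row_number())
  class(rows) <- c("model_selection", class(rows))
  rows
}

#' Best model of a selection table
#'
#' @param selection A [dredge_gls()] table.
#' @return The top-ranked `"gls_ar1"` fit.
#' @export
best_model <- function(selection) {
  selection$fit[[1]]
}

#' @method glance model_selection
#' @export
glance.model_selection <- function(x, ...) {
  tibble(
    n_models = nrow(x),
    best_model = x$model[1],
    df = x$df[1],
    loglik = x$loglik[1],
    AICc = x$aicc[1]
  )
}
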