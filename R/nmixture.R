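# Zero-inflated Poisson N-mixture models for repeated point counts:
# likelihood, maximum-likelihood fitting, AICc, and two-step detection
# selection. The latent-abundance sum is truncated at K and evaluated in
# log space (compiled core in src/zip_nmixture.cpp).

#' Repeated point-count data for N-mixture modelling
#'
#' Packs a long table of counts (one row per point x visit) and a site
#' covariate table into the sites x visits structure the likelihood needs.
#' Ragged visit histories are kept: unvisited cells are missing and are
#' skipped (never zero-filled) by the likelihood.
#'
#' @param counts_long Tibble with `point_id`, `count` (non-negative
#'   integer), visit covariates `minutes` (since midnight), `day` (ordinal)
#'   and `observer`, and optionally `visit` (index; defaults to row order
#'   within point).
#' @param site_covariates Tibble keyed by `point_id` covering every surveyed
#'   point.
#' @return An object of class `count_data`: `sites` (ordered site covariate
#'   tibble), `y` (sites x max-visits integer matrix with NA for missing
#'   visits), `visit` (list of matrices `minutes`, `day`, `observer`),
#'   `counts_long`, and a data `fingerprint`.
#' @export
count_data <- function(counts_long, site_covariates) {
  need <- c("point_id", "count", "minutes", "day", "observer")
  miss <- setdiff(need, names(counts_long))
  if (length(miss) > 0) {
    abort(paste0("`counts_long` lacks column(s): ", paste(miss, collapse = ", ")),
          class = "elevrange_input_error")
  }
  if (any(counts_long$count < 0) ||
      any(counts_long$count != round(counts_long$count))) {
    abort("Counts must be non-negative integers.", class = "elevrange_input_error")
  }
  ids <- sort(unique(counts_long$point_id))
  uncovered <- setdiff(ids, site_covariates$point_id)
  if (length(uncovered) > 0) {
    abort(paste0("Site covariates missing for surveyed point(s): ",
                 paste(head(uncovered, 5), collapse = ", ")),
          class = "elevrange_input_error")
  }
  sites <- site_covariates[match(ids, site_covariates$point_id), , drop = FALSE]
  sites <- as_tibble(sites)

  if (!"visit" %in% names(counts_long)) {
    counts_long <- counts_long |>
      group_by(.data$point_id) |>
      mutate(visit = dplyr::row_number()) |>
      ungroup()
  }
  n <- length(ids)
  J <- max(counts_long$visit)
  ii <- match(counts_long$point_id, ids)
  jj <- counts_long$visit
  idx <- cbind(ii, jj)

  y <- matrix(NA_integer_, n, J)
  y[idx] <- as.integer(counts_long$count)
  mk <- function(v, default = NA_real_) {
    m <- matrix(default, n, J)
    m[idx] <- v
    m
  }
  minutes <- mk(counts_long$minutes)
  day <- mk(counts_long$day)
  observer <- matrix(NA_character_, n, J)
  observer[idx] <- as.character(counts_long$observer)

  structure(
    list(sites = sites, y = y,
         visit = list(minutes = minutes, day = day, observer = observer),
         counts_long = counts_long,
         fingerprint = hash(list(unname(y), ids, round(unname(minutes), 8),
                                 round(unname(day), 8), unname(observer)))),
    class = "count_data"
  )
}

#' @export
print.count_data <- function(x, ...) {
  cat(sprintf("<count_data: %d sites, up to %d visits, %d observed counts>\n",
              nrow(x$y), ncol(x$y), sum(!is.na(x$y))))
  invisible(x)
}

#' Specify a zero-inflated Poisson N-mixture model
#'
#' @param abundance One-sided formula of site covariates for log expected
#'   abundance (e.g. `~ pct_tree_fern + pct_palm`).
#' @param detection One-sided formula of visit covariates for logit
#'   detection probability; variables restricted to `minutes`, `day`,
#'   `observer`. Numeric visit covariates are z-scored internally.
#' @param zip Include the scalar zero-inflation parameter psi (default
#'   `TRUE`).
#' @param K Latent-abundance truncation: a count at least the maximum
#'   observed count, or `"auto"` for the adaptive rule
#'   `max(y) + max(100, 5 * exp(max fitted log-lambda))` (verified post fit).
#' @return An object of class `nmix_spec`.
#' @export
nmix_spec <- function(abundance = ~1, detection = ~1, zip = TRUE, K = "auto") {
  stopifnot(inherits(abundance, "formula"), inherits(detection, "formula"))
  dv <- all.vars(detection)
  bad <- setdiff(dv, c("minutes", "day", "observer"))
  if (length(bad) > 0) {
    abort(paste0("Detection covariates restricted to minutes, day, observer; got: ",
                 paste(bad, collapse = ", ")),
          class = "elevrange_input_error")
  }
  if (is.numeric(K)) K <- as.integer(K)
  else if (!identical(K, "auto")) {
    abort('`K` must be a count or "auto".', class = "elevrange_input_error")
  }
  structure(list(abundance = abundance, detection = detection,
                 zip = isTRUE(zip), K = K),
            class = "nmix_spec")
}

#' @export
print.nmix_spec <- function(x, ...) {
  cat(sprintf("<nmix_spec: abundance %s; detection %s; %s; K = %s>\n",
              deparse(x$abundance), deparse(x$detection),
              if (x$zip) "zero-inflated Poisson" else "Poisson",
              as.character(x$K)))
  invisible(x)
}

# Build design matrices once per (data, spec). Numeric visit covariates are
# z-scored over observed cells; observer becomes a factor with sorted levels.
nmix_designs <- function(data, spec, check_rank = TRUE) {
  stopifnot(inherits(data, "count_data"), inherits(spec, "nmix_spec"))
  av <- all.vars(spec$abundance)
  miss <- setdiff(av, names(data$sites))
  if (length(miss) > 0) {
    abort(paste0("Abundance covariates absent from site table: ",
                 paste(miss, collapse = ", ")),
          class = "elevrange_input_error")
  }
  if (length(av) > 0 && anyNA(data$sites[av])) {
    abort("Site covariates contain missing values; impute or drop sites first.",
          class = "elevrange_input_error")
  }
  Xab <- model.matrix(spec$abundance, data = data$sites)
  qx <- qr(Xab)
  if (check_rank && qx$rank < ncol(Xab)) {
    abort(paste0("Abundance design is rank deficient; collinear column(s): ",
                 paste(colnames(Xab)[qx$pivot[(qx$rank + 1):ncol(Xab)]],
                       collapse = ", ")),
          class = "elevrange_design_error")
  }
  obs <- which(!is.na(data$y))
  scale_obs <- function(v) {
    vv <- v[obs]
    s <- sd(vv)
    if (!is.finite(s) || s == 0) list(z = rep(0, length(vv)), center = mean(vv), scale = 1)
    else list(z = (vv - mean(vv)) / s, center = mean(vv), scale = s)
  }
  mn <- scale_obs(data$visit$minutes)
  dy <- scale_obs(data$visit$day)
  long <- tibble(
    minutes = mn$z, day = dy$z,
    observer = factor(data$visit$observer[obs],
                      levels = sort(unique(data$visit$observer[obs])))
  )
  Vdet <- model.matrix(spec$detection, data = long)
  qv <- qr(Vdet)
  if (check_rank && qv$rank < ncol(Vdet)) {
    abort(paste0("Detection design is rank deficient; collinear column(s): ",
                 paste(colnames(Vdet)[qv$pivot[(qv$rank + 1):ncol(Vdet)]],
                       collapse = ", ")),
          class = "elevrange_design_error")
  }
  list(Xab = Xab, Vdet = Vdet, obs = obs,
       n = nrow(data$y), J = ncol(data$y),
       scaling = tibble(term = c("minutes", "day"),
                        center = c(mn$center, dy$center),
                        scale = c(mn$scale, dy$scale)))
}

# Split a flat parameter vector into its parts.
nmix_split_par <- function(par, des, zip) {
  pA <- ncol(des$Xab)
  pD <- ncol(des$Vdet)
  need <- pA + pD + as.integer(zip)
  if (length(par) != need) {
    abort(sprintf("Expected %d parameters (%d abundance + %d detection%s), got %d.",
                  need, pA, pD, if (zip) " + psi" else "", length(par)),
          class = "elevrange_input_error")
  }
  list(beta = par[seq_len(pA)],
       alpha = par[pA + seq_len(pD)],
       psi = if (zip) plogis(par[need]) else 0)
}

# Core evaluation shared by the exported likelihood and the fitter.
nmix_loglik_eval <- function(par, des, y, zip, K) {
  if (!all(is.finite(par))) return(structure(-Inf, flag = "nonfinite_params"))
  pp <- nmix_split_par(par, des, zip)
  log_lambda <- drop(des$Xab %*% pp$beta)
  if (any(log_lambda > 50)) return(structure(-Inf, flag = "lambda_overflow"))
  eta <- drop(des$Vdet %*% pp$alpha)
  logit_p <- matrix(NA_real_, des$n, des$J)
  logit_p[des$obs] <- eta
  zip_nmix_loglik_cpp(y, log_lambda, logit_p, pp$psi, as.integer(K))
}

#' Zero-inflated Poisson N-mixture log-likelihood
#'
#' Per site i, the likelihood is
#' `psi * [all y_ij = 0] + (1 - psi) * sum_{N=0}^{K} Pois(N; lambda_i) *
#' prod_j Bin(y_ij; N, p_ij)` over observed visits, with the sum evaluated
#' by log-sum-exp for stability; missing visits are skipped. The function
#' returns the sum over sites of the log of this quantity.
#'
#' @param params Numeric vector: abundance coefficients (log scale, order of
#'   the abundance model matrix), then detection coefficients (logit scale),
#'   then, if `spec$zip`, logit psi.
#' @param data A [count_data] object.
#' @param spec An [nmix_spec()].
#' @param K Truncation bound; defaults to the spec's (with `"auto"` resolved
#'   as `max(y) + 100` for a one-off evaluation).
#' @return The log-likelihood (scalar). Non-finite parameters give `-Inf`
#'   with attribute `flag`.
#' @export
zip_nmixture_loglik <- function(params, data, spec, K = NULL) {
  des <- nmix_designs(data, spec, check_rank = FALSE)  # evaluation, not fitting
  maxy <- max(data$y, na.rm = TRUE)
  K <- K %||% (if (is.numeric(spec$K)) spec$K else maxy + 100L)
  if (K < maxy) {
    abort(sprintf("K = %d is below the maximum observed count (%d).", K, maxy),
          class = "elevrange_input_error")
  }
  nmix_loglik_eval(params, des, data$y, spec$zip, K)
}

# Default starting values: abundance intercept log(mean site max + 0.1),
# detection intercept 0, all other effects 0, psi starting at 0.1.
nmix_start <- function(des, y, zip) {
  site_max <- apply(y, 1, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
  b0 <- log(mean(site_max) + 0.1)
  c(b0, rep(0, ncol(des$Xab) - 1), rep(0, ncol(des$Vdet)),
    if (zip) qlogis(0.1))
}

# Maximize the likelihood for fixed designs/K; quasi-Newton (BFGS) with
# finite-difference gradients.
nmix_optimize <- function(des, y, zip, K, start, control) {
  ctl <- modifyList(list(maxit = 500, reltol = 1e-10), control)
  negll <- function(par) {
    ll <- nmix_loglik_eval(par, des, y, zip, K)
    # sloped penalty so the optimizer is pushed back off degenerate regions
    if (!is.finite(ll)) 1e10 + sum(pmin(abs(par), 1e4)) else -ll
  }
  opt <- optim(start, negll, method = "BFGS", control = ctl)
  # flag ridge divergence (lambda -> Inf with p -> 0, or pinned detection)
  # as non-convergence: such solutions are not interior optima
  pp <- nmix_split_par(opt$par, des, zip)
  log_lambda <- drop(des$Xab %*% pp$beta)
  eta <- drop(des$Vdet %*% pp$alpha)
  degenerate <- max(log_lambda) > 30 || max(abs(eta)) > 30 ||
    opt$value >= 1e10
  list(par = opt$par, logLik = -opt$value,
       converged = opt$convergence == 0 && !degenerate,
       counts = opt$counts, negll = negll)
}

#' Fit a zero-inflated Poisson N-mixture model
#'
#' Maximum-likelihood fit by quasi-Newton (BFGS) optimization from
#' documented starting values; standard errors come from the inverse
#' numerical Hessian and p-values are Wald tests. The fit is deterministic
#' given the data and controls. With `K = "auto"` the truncation bound is
#' chosen adaptively (`max(y) + max(100, 5 * exp(max fitted log-lambda))`)
#' and the model is refitted if the bound grows.
#'
#' @param data A [count_data] object.
#' @param spec An [nmix_spec()].
#' @param start Optional numeric vector of starting values.
#' @param control Passed to [stats::optim()] (`maxit`, `reltol`).
#' @return An object of class `nmix_fit`: `coefficients` tibble (submodel,
#'   term, estimate, se, z, p), `psi`, `logLik`, `aicc`, `n_sites`,
#'   `n_params`, `K`, `converged`, `fingerprint`, fitted `log_lambda`,
#'   `logit_p` and the spec/data needed to refit.
#' @export
fit_nmixture <- function(data, spec, start = NULL, control = list()) {
  des <- nmix_designs(data, spec)
  y <- data$y
  maxy <- max(y, na.rm = TRUE)
  zip <- spec$zip

  if (is.numeric(spec$K)) {
    K <- spec$K
    if (K < maxy) {
      abort(sprintf("K = %d is below the maximum observed count (%d).", K, maxy),
            class = "elevrange_input_error")
    }
    auto <- FALSE
  } else {
    K <- maxy + 100L
    auto <- TRUE
  }
  start <- start %||% nmix_start(des, y, zip)

  res <- nmix_optimize(des, y, zip, K, start, control)
  if (auto) {
    pp <- nmix_split_par(res$par, des, zip)
    lmax <- max(drop(des$Xab %*% pp$beta))
    K2 <- maxy + max(100L, min(1500L, as.integer(ceiling(5 * exp(min(lmax, 20))))))
    if (K2 > K) {
      K <- K2
      res <- nmix_optimize(des, y, zip, K, res$par, control)
    }
  }

  H <- tryCatch(optimHess(res$par, res$negll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(vc)) {
    d <- diag(vc)
    ifelse(d > 0, sqrt(d), NA_real_)
  } else rep(NA_real_, length(res$par))

  pp <- nmix_split_par(res$par, des, zip)
  terms <- c(colnames(des$Xab), colnames(des$Vdet), if (zip) "psi")
  submodel <- c(rep("abundance", ncol(des$Xab)),
                rep("detection", ncol(des$Vdet)),
                if (zip) "zero_inflation")
  z <- res$par / se
  coefs <- tibble(
    submodel = submodel, term = terms, estimate = res$par, se = se,
    z = if (res$converged) z else NA_real_,
    p = if (res$converged) 2 * pnorm(-abs(z)) else NA_real_
  )

  eta <- drop(des$Vdet %*% pp$alpha)
  logit_p <- matrix(NA_real_, des$n, des$J)
  logit_p[des$obs] <- eta

  k <- length(res$par)
  structure(
    list(spec = spec, coefficients = coefs,
         psi = pp$psi,
         logLik = res$logLik,
         aicc = aicc_value(res$logLik, k, des$n),
         n_sites = des$n, n_params = k, K = K,
         converged = res$converged,
         fingerprint = data$fingerprint,
         log_lambda = drop(des$Xab %*% pp$beta),
         logit_p = logit_p,
         par = res$par, vcov = vc,
         designs = des, data = data,
         opt_counts = res$counts, start = start, control = control),
    class = "nmix_fit"
  )
}

#' Small-sample corrected AIC of an N-mixture fit
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)` with `n` the number of sites
#' and `k` the number of free parameters; `Inf` (with a warning) when
#' `n <= k + 1`.
#'
#' @param fit An `nmix_fit`, or a log-likelihood value (then supply `k` and
#'   `n`).
#' @param k,n Parameter count and sample size when `fit` is a scalar.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-5, k = 2, n = 10)  # 14 + 12/7
aicc <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "nmix_fit")) {
    if (!fit$converged) {
      warn("AICc of a non-converged fit.", class = "elevrange_convergence")
    }
    return(aicc_value(fit$logLik, fit$n_params, fit$n_sites))
  }
  aicc_value(fit, k, n)
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat(sprintf("<nmix_fit: %s | %s%s>\n",
              deparse(x$spec$abundance), deparse(x$spec$detection),
              if (x$spec$zip) " | ZIP" else ""))
  cat(sprintf("  %d sites; K = %d; logLik = %.3f; AICc = %.3f; converged: %s\n",
              x$n_sites, x$K, x$logLik, x$aicc, x$converged))
  if (x$spec$zip) cat(sprintf("  psi = %.3f\n", x$psi))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname fit_nmixture
#' @param x An `nmix_fit`.
#' @param ... Unused.
#' @export
tidy.nmix_fit <- function(x, ...) x$coefficients

#' @rdname fit_nmixture
#' @export
glance.nmix_fit <- function(x, ...) {
  tibble(logLik = x$logLik, AICc = x$aicc, n_sites = x$n_sites,
         n_params = x$n_params, K = x$K, psi = x$psi, converged = x$converged)
}

#' Coefficient plot for an N-mixture fit
#'
#' Estimates with 95% Wald intervals, faceted by submodel.
#'
#' @param object An `nmix_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmix_fit <- function(object, ...) {
  cf <- object$coefficients
  ggplot(cf, aes(x = .data$estimate, y = .data$term)) +
    geom_vline(xintercept = 0, linetype = "dotted") +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$estimate - 1.96 * .data$se,
                       xmax = .data$estimate + 1.96 * .data$se),
                   height = 0.2) +
    facet_wrap(~submodel, scales = "free_y", ncol = 1) +
    labs(x = "Estimate (log / logit scale)", y = NULL) +
    theme_minimal()
}

#' Two-step detection-model selection
#'
#' First step of the two-step fitting process: every subset of the candidate
#' detection covariates is fitted against an intercept-only abundance model
#' and ranked by AICc. The winning detection structure is then reused for
#' the abundance models. Ties go to the model with fewer parameters, then
#' lexicographically.
#'
#' @param data A [count_data] object.
#' @param candidates Subset of `c("minutes", "day", "observer")`.
#' @param zip,K Passed to [nmix_spec()].
#' @param control Optimizer controls passed to [fit_nmixture()].
#' @return An object of class `detection_selection`: `best_detection`
#'   (formula), `best_label`, `best_fit`, and the full `ranking` tibble.
#' @export
select_detection_model <- function(data,
                                   candidates = c("minutes", "day", "observer"),
                                   zip = TRUE, K = "auto", control = list()) {
  bad <- setdiff(candidates, c("minutes", "day", "observer"))
  if (length(bad) > 0) {
    abort(paste0("Invalid detection candidates: ", paste(bad, collapse = ", ")),
          class = "elevrange_input_error")
  }
  subsets <- list(character(0))
  for (m in seq_along(candidates)) {
    subsets <- c(subsets,
                 utils::combn(candidates, m, simplify = FALSE))
  }
  rows <- purrr::map(subsets, function(s) {
    label <- if (length(s) == 0) "1" else paste(s, collapse = "+")
    form <- if (length(s) == 0) ~1 else stats::reformulate(s)
    sp <- nmix_spec(abundance = ~1, detection = form, zip = zip, K = K)
    fit <- tryCatch(fit_nmixture(data, sp, control = control),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warn(sprintf("Detection subset '%s' failed to fit; excluded.", label),
           class = "elevrange_convergence")
      return(NULL)
    }
    tibble(detection = label, n_terms = length(s), k = fit$n_params,
           logLik = fit$logLik, AICc = fit$aicc, fit = list(fit))
  })
  rows <- purrr::keep(rows, Negate(is.null))
  if (length(rows) == 0) {
    abort("All detection-subset fits failed.", class = "elevrange_convergence")
  }
  ranking <- purrr::list_rbind(rows) |>
    arrange(.data$AICc, .data$k, .data$detection) |>
    mutate(rank = dplyr::row_number(), delta = .data$AICc - min(.data$AICc)) |>
    relocate("rank")
  best <- ranking$fit[[1]]
  structure(
    list(best_detection = best$spec$detection,
         best_label = ranking$detection[1],
         best_fit = best,
         ranking = select(ranking, -"fit")),
    class = "detection_selection"
  )
}

#' @export
print.detection_selection <- function(x, ...) {
  cat(sprintf("<detection_selection: best = p(~%s)>\n", x$best_label))
  print(as.data.frame(x$ranking), row.names = FALSE, digits = 5)
  invisible(x)
}
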