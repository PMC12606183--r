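# Parametric-bootstrap goodness of fit for N-mixture fits: chi-square and
# sum-of-squares discrepancy statistics, bootstrap p-values and c-hat.

# Discrepancy statistics over observed cells. Expected counts use the
# marginal moment E[y_ij] = (1 - psi) * lambda_i * p_ij; the chi-square
# denominator is floored at 1e-3 to guard near-zero expectations (the same
# rule applies to observed and bootstrap statistics, so calibration is
# unaffected).
gof_stats <- function(y, log_lambda, logit_p, psi) {
  obs <- which(!is.na(y))
  lam <- exp(log_lambda)[((obs - 1) %% nrow(y)) + 1]
  p <- plogis(logit_p[obs])
  e <- (1 - psi) * lam * p
  r2 <- (y[obs] - e)^2
  c(chisq = sum(r2 / pmax(e, 1e-3)), ss = sum(r2))
}

# Simulate one count matrix from fitted (lambda, p, psi) on the observed
# missingness pattern. Caller controls the RNG state.
simulate_counts <- function(y, log_lambda, logit_p, psi) {
  n <- nrow(y)
  lam <- exp(log_lambda)
  z <- runif(n) < psi
  N <- ifelse(z, 0L, rpois(n, lam))
  obs <- which(!is.na(y))
  ynew <- y
  ynew[obs] <- rbinom(length(obs), N[((obs - 1) %% n) + 1], plogis(logit_p[obs]))
  ynew
}

#' Parametric-bootstrap goodness of fit
#'
#' Simulates `n_boot` count matrices from the fitted model (same design and
#' missingness pattern), refits each, and recomputes the chi-square and
#' sum-of-squares discrepancy statistics. Bootstrap p-values use the
#' `(1 + #\{boot >= observed\}) / (1 + B)` convention; the over-dispersion
#' ratio `c_hat` is the observed chi-square divided by the mean bootstrap
#' chi-square. Replicates whose refit fails are excluded and counted; the
#' result is flagged unreliable when more than 20% fail.
#'
#' @param fit A converged [fit_nmixture()] object.
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the simulation stream.
#' @return An object of class `nmix_gof`: observed statistics, `p_chisq`,
#'   `p_ss`, `c_hat`, `n_boot`, `n_failed`, `unreliable`, and the per-
#'   replicate statistics in `boot`.
#' @export
bootstrap_gof <- function(fit, n_boot = 199, seed = 1L) {
  stopifnot(inherits(fit, "nmix_fit"))
  if (!fit$converged) {
    abort("Goodness of fit requires a converged fit.",
          class = "elevrange_convergence")
  }
  n_boot <- check_count(n_boot, "n_boot", min = 1)
  des <- fit$designs
  y <- fit$data$y
  zip <- fit$spec$zip
  obs_stats <- gof_stats(y, fit$log_lambda, fit$logit_p, fit$psi)

  boot <- withr::with_seed(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      ystar <- simulate_counts(y, fit$log_lambda, fit$logit_p, fit$psi)
      Kb <- max(fit$K, max(ystar, na.rm = TRUE) + 50L)
      res <- tryCatch(
        nmix_optimize(des, ystar, zip, Kb,
                      nmix_start(des, ystar, zip), fit$control),
        error = function(e) NULL
      )
      if (is.null(res) || !res$converged) {
        return(tibble(replicate = b, chisq = NA_real_, ss = NA_real_))
      }
      pp <- nmix_split_par(res$par, des, zip)
      ll <- drop(des$Xab %*% pp$beta)
      lp <- matrix(NA_real_, des$n, des$J)
      lp[des$obs] <- drop(des$Vdet %*% pp$alpha)
      st <- gof_stats(ystar, ll, lp, pp$psi)
      tibble(replicate = b, chisq = st[["chisq"]], ss = st[["ss"]])
    }) |> purrr::list_rbind()
  })

  ok <- boot[complete.cases(boot), ]
  n_failed <- n_boot - nrow(ok)
  if (nrow(ok) == 0) {
    abort("All bootstrap refits failed.", class = "elevrange_convergence")
  }
  B <- nrow(ok)
  p_chisq <- (1 + sum(ok$chisq >= obs_stats[["chisq"]] - 1e-12)) / (1 + B)
  p_ss <- (1 + sum(ok$ss >= obs_stats[["ss"]] - 1e-12)) / (1 + B)
  structure(
    list(chisq_obs = obs_stats[["chisq"]], ss_obs = obs_stats[["ss"]],
         p_chisq = p_chisq, p_ss = p_ss,
         c_hat = obs_stats[["chisq"]] / mean(ok$chisq),
         n_boot = n_boot, n_failed = n_failed,
         unreliable = n_failed > 0.2 * n_boot,
         boot = boot),
    class = "nmix_gof"
  )
}

#' @export
print.nmix_gof <- function(x, ...) {
  cat("<nmix_gof (parametric bootstrap)>\n")
  cat(sprintf("  chi-square: observed %.2f, p = %.3f; c-hat = %.3f\n",
              x$chisq_obs, x$p_chisq, x$c_hat))
  cat(sprintf("  sum-of-squares: observed %.2f, p = %.3f\n", x$ss_obs, x$p_ss))
  cat(sprintf("  replicates: %d (%d failed)%s\n", x$n_boot, x$n_failed,
              if (x$unreliable) " [UNRELIABLE: >20% failures]" else ""))
  invisible(x)
}

#' @export
glance.nmix_gof <- function(x, ...) {
  tibble(chisq_obs = x$chisq_obs, p_chisq = x$p_chisq, ss_obs = x$ss_obs,
         p_ss = x$p_ss, c_hat = x$c_hat, n_boot = x$n_boot,
         n_failed = x$n_failed, unreliable = x$unreliable)
}
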