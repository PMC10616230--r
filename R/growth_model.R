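## Site-by-species growth model: log basal area increment regressed on log
## prior basal area, a penalized cubic-regression-spline age smooth, and
## current/prior summer VPD, with a tree random intercept and AR1 residuals
## within trees. Estimation is iterated, whitened, penalized least squares:
## the AR1 transform is the exact bidiagonal whitener, the random intercept
## is absorbed by a rank-one (Woodbury) factor, the smoothing parameter is
## chosen by REML (or GCV), and the AR1 coefficient is updated from the
## lag-1 autocorrelation of within-tree residuals until joint convergence.

#' Growth model specification
#'
#' @param basis_dim Spline basis size for the age smooth (>= 4; default 10).
#' @param smoothness One of "REML" (default) or "GCV" for smoothing
#'   parameter selection.
#' @param include_vpd Include current and prior summer VPD covariates
#'   (default TRUE; FALSE gives the detrending model).
#' @param include_smi Also include current and prior summer soil moisture
#'   covariates (the partial-SMI variant; default FALSE).
#' @param alpha_level Two-sided significance threshold (default 0.05).
#' @param ar1 Model AR1 residual correlation (default TRUE). FALSE fits a
#'   deliberately independence-assuming model (useful to demonstrate the
#'   anticonservative t-tests that motivate the AR1 term).
#' @param random_intercept Tree random intercept (default TRUE).
#' @param max_iter,tol Outer-iteration controls (200, 1e-6 relative).
#' @param fixed_lambda,fixed_phi,fixed_tau Optional fixed values for the
#'   smoothing parameter, the AR1 coefficient, and the variance ratio
#'   sigma_tree^2 / sigma_eps^2 (mainly for oracle tests).
#' @return A `growth_model_spec` list.
#' @export
growth_model_spec <- function(basis_dim = 10, smoothness = c("REML", "GCV"),
                              include_vpd = TRUE, include_smi = FALSE,
                              alpha_level = 0.05, ar1 = TRUE,
                              random_intercept = TRUE,
                              max_iter = 200, tol = 1e-6,
                              fixed_lambda = NULL, fixed_phi = NULL,
                              fixed_tau = NULL) {
  smoothness <- match.arg(smoothness)
  if (basis_dim < 4) stop_config("basis_dim must be >= 4")
  if (alpha_level <= 0 || alpha_level >= 1)
    stop_config("alpha_level must be in (0, 1)")
  structure(list(basis_dim = basis_dim, smoothness = smoothness,
                 include_vpd = include_vpd, include_smi = include_smi,
                 alpha_level = alpha_level, ar1 = ar1,
                 random_intercept = random_intercept,
                 max_iter = max_iter, tol = tol,
                 fixed_lambda = fixed_lambda, fixed_phi = fixed_phi,
                 fixed_tau = fixed_tau),
            class = "growth_model_spec")
}

#' Merge BAI series with site climate into a model frame
#'
#' @param bai Either a list of `bai_series` or an already row-bound data
#'   frame with their columns. Excluded trees are skipped.
#' @param site_climate Data frame with `year`, `vpd_summer` and optionally
#'   `smi_summer` for one site (must also cover the year before each
#'   modelled year, for the lagged covariate).
#' @return Data frame `tree_id, site_id, species, year, log_bai,
#'   log_ba_prev, age, vpd_t, vpd_t1[, smi_t, smi_t1]`, rows with any
#'   missing covariate dropped.
#' @export
prepare_model_frame <- function(bai, site_climate) {
  if (is.list(bai) && !is.data.frame(bai)) {
    bai <- do.call(rbind, Filter(function(b) !isTRUE(attr(b, "excluded")), bai))
  }
  if (is.null(bai) || nrow(bai) == 0) stop_config("no BAI rows to model")
  if (any(bai$ba_prev <= 0))
    stop_config("log BA(t-1) undefined: ba_prev <= 0 (apply the juvenile filter)")
  cl <- site_climate
  idx <- match(bai$year, cl$year)
  idx1 <- match(bai$year - 1, cl$year)
  out <- data.frame(tree_id = bai$tree_id, site_id = bai$site_id,
                    species = bai$species, year = bai$year,
                    log_bai = log(bai$bai), log_ba_prev = log(bai$ba_prev),
                    age = bai$age,
                    vpd_t = cl$vpd_summer[idx], vpd_t1 = cl$vpd_summer[idx1])
  if ("smi_summer" %in% names(cl)) {
    out$smi_t <- cl$smi_summer[idx]
    out$smi_t1 <- cl$smi_summer[idx1]
  }
  keep <- stats::complete.cases(out[, c("log_bai", "log_ba_prev", "age",
                                        "vpd_t", "vpd_t1")])
  out[keep, , drop = FALSE]
}

## AR1 whitening of a matrix by tree and contiguous year run. Returns the
## transformed matrix, the transformed intercept-indicator u per tree, run
## bookkeeping, and the whitening log-determinant contribution.
ar1_whiten <- function(A, tree, year, phi) {
  A <- as.matrix(A)
  n <- nrow(A)
  out <- A
  u <- numeric(n)
  s1 <- sqrt(1 - phi^2)
  trees <- unique(tree)
  logdet <- 0
  first_idx <- logical(n)
  for (tr in trees) {
    ix <- which(tree == tr)
    ix <- ix[order(year[ix])]
    run_id <- cumsum(c(1L, as.integer(diff(year[ix]) != 1L)))
    for (r in unique(run_id)) {
      jx <- ix[run_id == r]
      m <- length(jx)
      out[jx[1], ] <- s1 * A[jx[1], ]
      u[jx[1]] <- s1
      if (m > 1) {
        out[jx[-1], ] <- A[jx[-1], , drop = FALSE] -
          phi * A[jx[-m], , drop = FALSE]
        u[jx[-1]] <- 1 - phi
      }
      logdet <- logdet + 0.5 * log(1 - phi^2)
      first_idx[jx[1]] <- TRUE
    }
  }
  list(A = out, u = u, logdet = logdet)
}

## Apply the rank-one random-intercept whitener per tree:
## M = I - c u u' with c = (1 - 1/sqrt(1 + tau * s)) / s, s = u'u.
re_whiten <- function(A, u, tree, tau) {
  if (tau <= 0) return(list(A = A, logdet = 0))
  out <- A
  logdet <- 0
  for (tr in unique(tree)) {
    ix <- which(tree == tr)
    ui <- u[ix]
    s <- sum(ui^2)
    cc <- (1 - 1 / sqrt(1 + tau * s)) / s
    proj <- drop(crossprod(ui, A[ix, , drop = FALSE]))
    out[ix, ] <- A[ix, , drop = FALSE] - cc * tcrossprod(ui, proj)
    logdet <- logdet - 0.5 * log(1 + tau * s)
  }
  list(A = out, logdet = logdet)
}

## Penalized LS solve plus the pieces the REML/GCV criteria need.
pls_solve <- function(XtX, Xty, yty, n, pen, lambda, p_f, S_rank, logdetS) {
  P <- pen * lambda
  ch <- chol(XtX + P)
  beta <- backsolve(ch, forwardsolve(t(ch), Xty))
  rss <- max(yty - 2 * sum(beta * Xty) + drop(crossprod(beta, XtX %*% beta)), 0)
  pen_term <- drop(crossprod(beta, P %*% beta))
  rss_pen <- rss + pen_term
  # effective degrees of freedom tr[(X'X + P)^-1 X'X]
  edf <- sum(diag(backsolve(ch, forwardsolve(t(ch), XtX))))
  logdet_XtXP <- 2 * sum(log(diag(ch)))
  list(beta = beta, rss = rss, rss_pen = rss_pen, edf = edf,
       logdet_XtXP = logdet_XtXP, chol = ch)
}

## -2 * restricted log-likelihood (whitening log-dets added by caller) or
## GCV score for the whitened penalized system.
smooth_criterion <- function(fitbits, n, p_f, S_rank, logdetS, lambda, type) {
  if (type == "GCV") {
    return(n * fitbits$rss / (n - fitbits$edf)^2)
  }
  sig2 <- fitbits$rss_pen / (n - p_f)
  (n - p_f) * (log(2 * pi * sig2) + 1) +
    fitbits$logdet_XtXP - (S_rank * log(lambda) + logdetS)
}

#' Fit the site-species growth model
#'
#' Fits `log(BAI) ~ log(BA[t-1]) + s(age) + VPD[t] + VPD[t-1]` (terms per
#' the spec) with a tree random intercept and AR1 within-tree residuals, by
#' iterated whitened penalized least squares. See the package vignette for
#' the estimator and its conventions.
#'
#' @param data Model frame from [prepare_model_frame()] (or with the same
#'   columns), for a single site-species combination.
#' @param climate Optional site climate table; when supplied, `data` may be
#'   BAI rows and the model frame is built internally.
#' @param spec A [growth_model_spec()].
#' @return A `growth_model_fit` with elements `coef` (named: intercept,
#'   alpha, beta1, beta2, optional SMI terms), `se`, `t`, `p`, `phi_hat`,
#'   `sigma_tree_hat`, `sigma_eps_hat`, `lambda`, `edf_smooth`, `df_resid`,
#'   `converged`, `reason`, `r2_fluctuations`, `fitted`, `ranef`, `basis`,
#'   `spline_coefs`, `data`, `spec`, `iterations`.
#' @export
fit_growth_gamm <- function(data, climate = NULL, spec = growth_model_spec()) {
  if (!is.null(climate)) data <- prepare_model_frame(data, climate)
  tryCatch(fit_growth_gamm_impl(data, spec),
           error = function(e) nonconvergent_fit(data, spec, conditionMessage(e)))
}

nonconvergent_fit <- function(data, spec, reason) {
  structure(list(converged = FALSE, reason = reason, spec = spec,
                 data = data, coef = NULL, t = NULL, p = NULL),
            class = "growth_model_fit")
}

fit_growth_gamm_impl <- function(data, spec) {
  need <- c("tree_id", "year", "log_bai", "log_ba_prev", "age")
  if (!all(need %in% names(data)))
    stop_config("model frame lacks columns %s",
                paste(setdiff(need, names(data)), collapse = ", "))
  data <- data[order(data$tree_id, data$year), , drop = FALSE]
  n <- nrow(data)
  if (n < 25) stop_config("too few observations (%d < 25)", n)
  y <- data$log_bai
  pf_names <- c("(Intercept)", "alpha")
  Xp <- cbind(1, data$log_ba_prev)
  if (spec$include_vpd) {
    if (!all(c("vpd_t", "vpd_t1") %in% names(data)))
      stop_config("VPD covariates missing")
    Xp <- cbind(Xp, data$vpd_t, data$vpd_t1)
    pf_names <- c(pf_names, "beta1", "beta2")
  }
  if (spec$include_smi) {
    if (!all(c("smi_t", "smi_t1") %in% names(data)))
      stop_config("SMI covariates missing")
    Xp <- cbind(Xp, data$smi_t, data$smi_t1)
    pf_names <- c(pf_names, "smi1", "smi2")
  }
  p_f <- ncol(Xp)
  basis <- build_spline_basis(data$age, spec$basis_dim)
  X <- cbind(Xp, basis$X)
  p <- ncol(X)
  ks <- ncol(basis$X)
  pen <- matrix(0, p, p)
  pen[(p_f + 1):p, (p_f + 1):p] <- basis$S
  eS <- eigen(basis$S, symmetric = TRUE, only.values = TRUE)$values
  S_rank <- sum(eS > max(eS) * 1e-10)
  logdetS <- sum(log(eS[eS > max(eS) * 1e-10]))

  tree <- as.character(data$tree_id)
  year <- data$year
  n_trees <- length(unique(tree))

  phi <- spec$fixed_phi %||% 0
  if (!spec$ar1) phi <- 0
  tau <- spec$fixed_tau %||% if (spec$random_intercept) 0.1 else 0
  if (!spec$random_intercept) tau <- 0
  lambda <- spec$fixed_lambda %||% 1
  crit_type <- spec$smoothness

  A0 <- cbind(y, X)
  state_old <- NULL
  iterations <- 0L
  converged <- FALSE
  for (iter in seq_len(spec$max_iter)) {
    iterations <- iter
    aw <- ar1_whiten(A0, tree, year, phi)

    # cache the whitened cross-products per tau so the 1-D lambda search
    # only re-solves the (small) penalized normal equations
    whiten_tau <- function(tau_v) {
      rw <- re_whiten(aw$A, aw$u, tree, tau_v)
      G <- crossprod(rw$A)
      list(XtX = G[-1, -1, drop = FALSE], Xty = G[-1, 1], yty = G[1, 1],
           logdetW = aw$logdet + rw$logdet)
    }
    crit_at <- function(wt, lam) {
      fb <- pls_solve(wt$XtX, wt$Xty, wt$yty, n, pen, lam, p_f,
                      S_rank, logdetS)
      crit <- smooth_criterion(fb, n, p_f, S_rank, logdetS, lam, crit_type)
      if (crit_type == "REML") crit <- crit - 2 * wt$logdetW
      list(crit = crit, fb = fb)
    }

    wt <- whiten_tau(tau)
    # (ii) smoothing parameter by REML/GCV at current (phi, tau)
    if (is.null(spec$fixed_lambda)) {
      opt <- stats::optimize(function(ll) crit_at(wt, exp(ll))$crit,
                             interval = c(-30, 18), tol = 1e-4)
      lambda <- exp(opt$minimum)
    }
    # (iii) variance ratio by the same criterion at current (phi, lambda)
    if (spec$random_intercept && is.null(spec$fixed_tau)) {
      optt <- stats::optimize(function(lt) crit_at(whiten_tau(exp(lt)),
                                                   lambda)$crit,
                              interval = c(-18, 6), tol = 1e-4)
      tau <- exp(optt$minimum)
      if (tau < 1e-7) tau <- 0
      wt <- whiten_tau(tau)
    }
    ec <- crit_at(wt, lambda)
    beta <- ec$fb$beta

    # (iv) AR1 coefficient from lag-1 autocorrelation of within-tree
    # residuals (random intercept removed by BLUP)
    resid0 <- y - drop(X %*% beta)
    rw_r <- ar1_whiten(matrix(resid0, ncol = 1), tree, year, phi)
    e <- resid0
    blup <- stats::setNames(numeric(n_trees), unique(tree))
    for (tr in unique(tree)) {
      ix <- which(tree == tr)
      ui <- rw_r$u[ix]
      s <- sum(ui^2)
      b_hat <- if (tau > 0) tau * sum(ui * rw_r$A[ix, 1]) / (1 + tau * s) else 0
      blup[tr] <- b_hat
      e[ix] <- resid0[ix] - b_hat
    }
    if (spec$ar1 && is.null(spec$fixed_phi)) {
      pairs_a <- c(); pairs_b <- c()
      for (tr in unique(tree)) {
        ix <- which(tree == tr)
        ix <- ix[order(year[ix])]
        ok <- which(diff(year[ix]) == 1L)
        pairs_a <- c(pairs_a, e[ix[ok]])
        pairs_b <- c(pairs_b, e[ix[ok + 1L]])
      }
      phi_new <- if (length(pairs_a) > 5 && stats::sd(pairs_a) > 0 &&
                     stats::sd(pairs_b) > 0)
        stats::cor(pairs_a, pairs_b) else 0
      phi_new <- min(max(phi_new, -0.98), 0.98)
    } else phi_new <- phi

    ## joint convergence on (parametric coefs, phi) at tol; the smoothing
    ## parameter is compared on the log scale with a looser absolute
    ## tolerance because the REML profile is flat near its optimum (and may
    ## sit on the heavy-smoothing boundary), where golden-section jitter
    ## would otherwise mask a converged fit
    state <- c(beta[seq_len(p_f)], phi_new)
    if (!is.null(state_old)) {
      np <- length(state)
      rel <- max(abs(state - state_old[seq_len(np)]) /
                   pmax(abs(state_old[seq_len(np)]), 1e-3))
      dlam <- abs(log(lambda) - state_old[np + 1L])
      dcrit <- abs(ec$crit - state_old[np + 2L])
      # a stationary criterion value covers the degenerate case where the
      # REML profile is flat in lambda (e.g. an interpolating fit) and
      # lambda itself is indeterminate
      if (rel < spec$tol && (dlam < 1e-3 || dcrit < 1e-6 * (1 + abs(ec$crit)))) {
        phi <- phi_new; converged <- TRUE; break
      }
    }
    state_old <- c(state, log(lambda), ec$crit)
    phi <- phi_new
  }

  # final solve at converged (phi, tau, lambda)
  aw <- ar1_whiten(A0, tree, year, phi)
  rw <- re_whiten(aw$A, aw$u, tree, tau)
  yt <- rw$A[, 1]; Xt <- rw$A[, -1, drop = FALSE]
  XtX <- crossprod(Xt)
  fb <- pls_solve(XtX, crossprod(Xt, yt), sum(yt^2), n, pen, lambda, p_f,
                  S_rank, logdetS)
  beta <- fb$beta
  sig2 <- fb$rss_pen / max(n - p_f, 1)
  Vb <- chol2inv(fb$chol) * sig2
  se <- sqrt(pmax(diag(Vb), 0))
  # effective df of the smooth alone
  H <- backsolve(fb$chol, forwardsolve(t(fb$chol), XtX))
  edf_smooth <- sum(diag(H)[(p_f + 1):p])
  df_resid <- max(n - edf_smooth - p_f - n_trees, 1)
  tval <- beta[seq_len(p_f)] / se[seq_len(p_f)]
  pval <- 2 * stats::pt(-abs(tval), df = df_resid)
  if (any(!is.finite(se[seq_len(p_f)])) || any(se[seq_len(p_f)] == 0))
    return(nonconvergent_fit(data, spec, "degenerate standard errors"))

  # fitted values including tree BLUPs
  resid0 <- y - drop(cbind(Xp, basis$X) %*% beta)
  rw_r <- ar1_whiten(matrix(resid0, ncol = 1), tree, year, phi)
  blup <- stats::setNames(numeric(n_trees), unique(tree))
  for (tr in unique(tree)) {
    ix <- which(tree == tr)
    ui <- rw_r$u[ix]
    s <- sum(ui^2)
    blup[tr] <- if (tau > 0) tau * sum(ui * rw_r$A[ix, 1]) / (1 + tau * s) else 0
  }
  fitted <- drop(cbind(Xp, basis$X) %*% beta) + blup[tree]
  r2 <- if (stats::sd(fitted) > 0) stats::cor(y, fitted)^2 else NA_real_

  names(beta) <- c(pf_names, paste0("s.", seq_len(ks)))
  cf <- beta[seq_len(p_f)]
  structure(list(
    coef = cf, se = stats::setNames(se[seq_len(p_f)], pf_names),
    t = stats::setNames(tval, pf_names), p = stats::setNames(pval, pf_names),
    alpha_hat = unname(cf["alpha"]),
    beta1_hat = if ("beta1" %in% pf_names) unname(cf["beta1"]) else NA_real_,
    beta2_hat = if ("beta2" %in% pf_names) unname(cf["beta2"]) else NA_real_,
    spline_coefs = beta[(p_f + 1):p], lambda = lambda,
    phi_hat = phi, tau_hat = tau,
    sigma_eps_hat = sqrt(sig2), sigma_tree_hat = sqrt(tau * sig2),
    edf_smooth = edf_smooth, df_resid = df_resid,
    converged = if (converged) TRUE else FALSE,
    reason = if (converged) NA_character_ else "max_iter reached",
    iterations = iterations,
    r2_fluctuations = r2, fitted = fitted, ranef = blup,
    basis = basis, include_smi = spec$include_smi,
    site_id = data$site_id[1], species = data$species[1],
    n_obs = n, n_trees = n_trees, data = data, spec = spec),
    class = "growth_model_fit")
}

#' @export
print.growth_model_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<growth_model_fit> NON-CONVERGENT:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<growth_model_fit> site %s / %s: n=%d obs, %d trees\n",
              x$site_id, x$species, x$n_obs, x$n_trees))
  print(round(data.frame(estimate = x$coef, se = x$se, t = x$t, p = x$p), 4))
  cat(sprintf("phi=%.3f sigma_tree=%.3f sigma_eps=%.3f lambda=%.3g edf(s)=%.2f r2=%.3f\n",
              x$phi_hat, x$sigma_tree_hat, x$sigma_eps_hat, x$lambda,
              x$edf_smooth, x$r2_fluctuations))
  invisible(x)
}

#' Wald t-tests for the VPD coefficients
#'
#' @param fit A converged `growth_model_fit`.
#' @return Data frame with `term`, `estimate`, `se`, `t`, `p` for the VPD
#'   (and, if fitted, SMI) covariates, on `df_resid` degrees of freedom.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "growth_model_fit"))
  if (!isTRUE(fit$converged)) stop_config("fit did not converge")
  terms <- intersect(c("beta1", "beta2", "smi1", "smi2"), names(fit$coef))
  data.frame(term = terms, estimate = unname(fit$coef[terms]),
             se = unname(fit$se[terms]), t = unname(fit$t[terms]),
             p = unname(fit$p[terms]), df = fit$df_resid)
}

#' Classify a site's VPD response from the fitted t-values
#'
#' @param fit A `growth_model_fit` (possibly non-convergent).
#' @param alpha_level Significance threshold (default from the fit's spec).
#' @return Data frame with `site_id`, `species`, `class_vpd_t`,
#'   `class_vpd_t1`, each one of "negative", "positive", "nonsignificant",
#'   "nonconvergent", plus the underlying `t_vpd_t`, `t_vpd_t1`.
#' @export
classify_response <- function(fit, alpha_level = NULL) {
  stopifnot(inherits(fit, "growth_model_fit"))
  alpha_level <- alpha_level %||% fit$spec$alpha_level
  if (!isTRUE(fit$converged)) {
    return(data.frame(site_id = fit$data$site_id[1] %||% NA,
                      species = fit$data$species[1] %||% NA,
                      class_vpd_t = "nonconvergent",
                      class_vpd_t1 = "nonconvergent",
                      t_vpd_t = NA_real_, t_vpd_t1 = NA_real_))
  }
  cls <- function(term) {
    if (!term %in% names(fit$t)) return(NA_character_)
    if (fit$p[term] < alpha_level) {
      if (fit$t[term] < 0) "negative" else "positive"
    } else "nonsignificant"
  }
  data.frame(site_id = fit$site_id, species = fit$species,
             class_vpd_t = cls("beta1"), class_vpd_t1 = cls("beta2"),
             t_vpd_t = unname(fit$t["beta1"]),
             t_vpd_t1 = unname(fit$t["beta2"]))
}

#' Fit the partial-SMI growth model variant
#'
#' The growth model augmented with linear current- and prior-summer soil
#' moisture covariates, so the VPD t-tests control for soil moisture.
#'
#' @inheritParams fit_growth_gamm
#' @return A `growth_model_fit` with `include_smi = TRUE`.
#' @export
fit_partial_smi_model <- function(data, climate = NULL,
                                  spec = growth_model_spec()) {
  spec$include_smi <- TRUE
  fit_growth_gamm(data, climate, spec)
}

#' Goodness of fit of a growth model
#'
#' Squared Pearson correlation between observed and fitted log-BAI
#' year-to-year series, pooled over trees.
#'
#' @param fit A converged `growth_model_fit`.
#' @param observed Optional observed log-BAI vector (defaults to the fitting
#'   data).
#' @return r-squared in [0, 1].
#' @export
goodness_of_fit <- function(fit, observed = NULL) {
  stopifnot(inherits(fit, "growth_model_fit"))
  if (!isTRUE(fit$converged)) stop_config("fit did not converge")
  obs <- observed %||% fit$data$log_bai
  if (stats::sd(fit$fitted) == 0) return(0)
  stats::cor(obs, fit$fitted)^2
}
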