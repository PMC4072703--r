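# Cox proportional-hazards engine with crossed Gaussian frailties.
#
# The log-frailty formulation treats random intercepts b ~ N(0, sigma^2) per
# grouping (fawn, year) as penalized coefficients of the partial likelihood
# (Ripatti & Palmgren style): the inner loop maximizes the penalized Efron
# partial likelihood over (beta, b) by Newton-Raphson with step halving; the
# outer loop maximizes the Laplace-approximate marginal (integrated)
# likelihood over the variance parameters. With all variances at zero the
# engine reduces exactly to an ordinary Cox fit, which the test suite checks
# against survival::coxph as an independent oracle.

# Efron partial log-likelihood, gradient and (negative) Hessian.
# time/status/W already ordered by decreasing time.
#
# Vectorized assembly: per tied event time t with d events, Efron's r-th
# denominator is den_{t,r} = S0(t) - (r/d) S0d(t), with matching S1/S2
# corrections. Summing the Hessian contributions
#   sum_{t,r} (S2(t) - c_r S2d(t)) / den_{t,r} - Z_r Z_r'
# is rearranged so each S2-type term becomes a single weighted crossprod
# over subjects (the per-time factors A_t = sum_r 1/den and
# B_t = sum_r c_r/den are spread back onto risk-set members), avoiding any
# per-event p x p allocation.
cox_lgh <- function(theta, t_s, d_s, W_s) {
  n <- length(t_s); p <- ncol(W_s)
  eta <- if (p) drop(W_s %*% theta) else numeric(n)
  eta <- pmin(eta, 500) # overflow guard; never binds in sane fits
  w <- exp(eta)
  D_all <- which(d_s == 1)
  te <- unique(t_s[D_all])            # decreasing (t_s sorted decreasing)
  m <- length(te)
  # risk-set cut: i_t = #\{t_s >= te\}; both sequences sorted
  i_t <- findInterval(-te, -t_s)
  cw0 <- cumsum(w)
  S0_t <- cw0[i_t]
  # events grouped by (decreasing) time
  grp <- match(t_s[D_all], te)
  dD <- tabulate(grp, m)
  wD <- w[D_all]
  S0d_t <- drop(rowsum(wD, grp))
  # per (t, r) expansion
  idx <- rep(seq_len(m), dD)
  cr <- (sequence(dD) - 1) / rep(dD, dD)
  den <- S0_t[idx] - cr * S0d_t[idx]
  l <- sum(eta[D_all]) - sum(log(den))
  if (p == 0L) {
    return(list(loglik = l, grad = numeric(0), neg_hess = matrix(0, 0, 0)))
  }
  WD <- W_s[D_all, , drop = FALSE]
  cw <- apply(W_s * w, 2, cumsum)
  if (is.null(dim(cw))) cw <- matrix(cw, nrow = 1)
  S1_t <- cw[i_t, , drop = FALSE]     # m x p
  S1d_t <- rowsum(WD * wD, grp)       # m x p
  Zmat <- (S1_t[idx, , drop = FALSE] - cr * S1d_t[idx, , drop = FALSE]) / den
  g <- colSums(WD) - colSums(Zmat)
  # spread A_t over risk sets (members 1..i_t), B_t over the tied events
  A_t <- drop(rowsum(1 / den, idx))
  B_t <- drop(rowsum(cr / den, idx))
  tally <- numeric(n)
  tally[i_t] <- tally[i_t] + A_t      # i_t strictly increasing over te
  cumA <- rev(cumsum(rev(tally)))
  H <- crossprod(W_s * sqrt(w * cumA)) -
    crossprod(WD * sqrt(wD * B_t[grp])) -
    crossprod(Zmat)
  list(loglik = l, grad = g, neg_hess = H)
}

# Penalized Newton-Raphson. penalty: diagonal of the quadratic penalty
# matrix (0 for fixed effects, 1/sigma^2 for frailty columns).
cox_newton <- function(t_s, d_s, W_s, penalty, theta0 = NULL,
                       tol = 1e-9, max_iter = 50L) {
  p <- ncol(W_s)
  theta <- if (is.null(theta0)) numeric(p) else theta0
  pen_ll <- function(th, lgh) lgh$loglik - 0.5 * sum(penalty * th^2)
  lgh <- cox_lgh(theta, t_s, d_s, W_s)
  if (p == 0L) {
    return(list(theta = theta, loglik = lgh$loglik, pen_loglik = lgh$loglik,
                neg_hess = lgh$neg_hess, neg_hess_pen = lgh$neg_hess))
  }
  lp <- pen_ll(theta, lgh)
  for (it in seq_len(max_iter)) {
    g_pen <- lgh$grad - penalty * theta
    H_pen <- lgh$neg_hess
    diag(H_pen) <- diag(H_pen) + penalty + 1e-10
    step <- tryCatch(solve(H_pen, g_pen), error = function(e) {
      solve(H_pen + diag(1e-6, p), g_pen)
    })
    fac <- 1
    repeat {
      theta_new <- theta + fac * step
      lgh_new <- cox_lgh(theta_new, t_s, d_s, W_s)
      lp_new <- pen_ll(theta_new, lgh_new)
      if (is.finite(lp_new) && lp_new >= lp - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10) { theta_new <- theta; lgh_new <- lgh; lp_new <- lp; break }
    }
    done <- abs(lp_new - lp) < tol && max(abs(lgh_new$grad - penalty * theta_new)) < 1e-6
    theta <- theta_new; lgh <- lgh_new; lp <- lp_new
    if (done) break
    if (it == max_iter) {
      gn <- max(abs(lgh$grad - penalty * theta))
      if (gn > 1e-3) {
        stop(sprintf("Cox Newton did not converge (max |gradient| = %.3g)", gn),
             call. = FALSE)
      }
    }
  }
  H_pen <- lgh$neg_hess
  diag(H_pen) <- diag(H_pen) + penalty
  list(theta = theta, loglik = lgh$loglik, pen_loglik = lp,
       neg_hess = lgh$neg_hess, neg_hess_pen = H_pen)
}

# Laplace-approximate marginal log-likelihood for given frailty variances.
# b_idx: list of integer index vectors into theta per grouping; sigma2 named.
cox_marginal_ll <- function(inner, sigma2, b_idx) {
  ll <- inner$loglik
  logdet <- 0
  for (gname in names(b_idx)) {
    idx <- b_idx[[gname]]
    s2 <- sigma2[[gname]]
    b <- inner$theta[idx]
    ll <- ll - 0.5 * sum(b^2) / s2
    Hbb <- inner$neg_hess[idx, idx, drop = FALSE]
    M <- s2 * Hbb
    diag(M) <- diag(M) + 1
    logdet <- logdet + determinant(M, logarithm = TRUE)$modulus
  }
  as.numeric(ll - 0.5 * logdet)
}

#' Fit a Cox proportional-hazards model with Gaussian frailties
#'
#' Penalized partial likelihood (Efron ties) with crossed Gaussian random
#' intercepts on the log hazard for the requested groupings; frailty
#' variances are estimated by maximizing the Laplace-approximate marginal
#' likelihood, with the search floored near zero (weakly identified
#' variances -- e.g. per-fawn frailty with at most one event per fawn --
#' shrink to the floor and are reported as ~0). Per-year baseline cumulative
#' survival uses the Breslow estimator on the fixed-effect linear predictor.
#'
#' @param records data.frame with `fawn_id`, `year`, `stop_day`, `event`
#'   (0/1) and z-scored covariate columns.
#' @param terms character vector of model terms; interactions written
#'   `"a:b"`. May be empty (`character(0)`) for the random-effects-only null
#'   model.
#' @param random_effects groupings for Gaussian frailties; subset of
#'   `c("fawn_id", "year")`, or NULL for a plain Cox fit.
#' @param model_name label carried into reports.
#' @param var_floor lower bound for frailty variances in the outer search.
#' @param fixed_var optional named numeric vector fixing the frailty
#'   variance of each grouping instead of estimating it; a variance of 0
#'   removes that frailty exactly (reducing, with all variances 0, to the
#'   ordinary Cox partial-likelihood fit).
#' @return object of class `cox_fit`: coefficient table with hazard ratios
#'   (`exp(beta)` exactly), integrated log-likelihood, frailty variances,
#'   and per-year Breslow baseline survival.
#' @export
fit_cox <- function(records, terms, random_effects = c("fawn_id", "year"),
                    model_name = paste(terms, collapse = " + "),
                    var_floor = 1e-4, fixed_var = NULL) {
  need <- c("fawn_id", "year", "stop_day", "event")
  stopifnot(all(need %in% names(records)))
  if (sum(records$event) < 2) {
    stop("need >= 2 events to fit a Cox model", call. = FALSE)
  }
  mains <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  if (length(mains)) {
    missing <- setdiff(mains, names(records))
    if (length(missing)) {
      stop("missing covariate column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    keep <- complete.cases(records[, mains, drop = FALSE])
    if (any(!keep)) {
      warning("dropping ", sum(!keep), " record(s) with missing covariates")
      records <- records[keep, , drop = FALSE]
    }
  }
  n <- nrow(records)
  X <- if (length(terms)) build_term_matrix(records, terms) else
    matrix(numeric(0), n, 0)
  p <- ncol(X)

  zero_fixed <- character(0)
  if (!is.null(fixed_var)) {
    stopifnot(all(random_effects %in% names(fixed_var)))
    if (any(fixed_var < 0)) stop("fixed_var must be >= 0", call. = FALSE)
    zero_fixed <- random_effects[fixed_var[random_effects] == 0]
    random_effects <- setdiff(random_effects, zero_fixed)
  }
  groups <- list()
  for (g in random_effects) {
    groups[[g]] <- factor(records[[g]])
  }
  Zs <- lapply(groups, function(f) {
    L <- nlevels(f)
    Z <- matrix(0, n, L)
    Z[cbind(seq_len(n), as.integer(f))] <- 1
    Z
  })
  W <- do.call(cbind, c(list(X), Zs))
  if (is.null(W)) W <- X
  q_sizes <- vapply(Zs, ncol, integer(1))
  b_idx <- list()
  off <- p
  for (g in names(Zs)) {
    b_idx[[g]] <- off + seq_len(q_sizes[[g]])
    off <- off + q_sizes[[g]]
  }

  ord <- order(records$stop_day, decreasing = TRUE)
  t_s <- records$stop_day[ord]
  d_s <- records$event[ord]
  W_s <- W[ord, , drop = FALSE]

  fit_at <- local({
    warm <- NULL
    function(log_s2) {
      sigma2 <- as.list(exp(log_s2))
      names(sigma2) <- names(b_idx)
      penalty <- numeric(ncol(W_s))
      for (g in names(b_idx)) penalty[b_idx[[g]]] <- 1 / sigma2[[g]]
      inner <- cox_newton(t_s, d_s, W_s, penalty, theta0 = warm)
      warm <<- inner$theta
      list(inner = inner, sigma2 = sigma2,
           mll = if (length(b_idx)) cox_marginal_ll(inner, sigma2, b_idx)
                 else inner$loglik)
    }
  })

  if (length(b_idx) && !is.null(fixed_var)) {
    final <- fit_at(log(fixed_var[names(b_idx)]))
    frailty_var <- vapply(final$sigma2, identity, numeric(1))
    loglik <- final$mll
  } else if (length(b_idx)) {
    start <- rep(log(0.05), length(b_idx))
    opt <- optim(start, function(ls2) -fit_at(ls2)$mll,
                 method = "L-BFGS-B",
                 lower = rep(log(var_floor), length(b_idx)),
                 upper = rep(log(4), length(b_idx)),
                 control = list(factr = 1e9))
    final <- fit_at(opt$par)
    frailty_var <- vapply(final$sigma2, identity, numeric(1))
    # variances pinned at the floor are effectively zero
    frailty_var[frailty_var <= var_floor * 1.0001] <- 0
    loglik <- final$mll
  } else {
    final <- list(inner = cox_newton(t_s, d_s, W_s, numeric(ncol(W_s))))
    frailty_var <- numeric(0)
    loglik <- final$inner$loglik
  }
  if (length(zero_fixed)) {
    frailty_var <- c(frailty_var, setNames(rep(0, length(zero_fixed)), zero_fixed))
  }
  inner <- final$inner

  coefs <- if (p) {
    V <- solve(inner$neg_hess_pen + diag(1e-12, ncol(W_s)))
    est <- inner$theta[seq_len(p)]
    se <- sqrt(diag(V)[seq_len(p)])
    z <- est / se
    data.frame(term = terms, estimate = est, se = se, z = z,
               p = 2 * pnorm(-abs(z)), hazard_ratio = exp(est),
               row.names = NULL)
  } else {
    data.frame(term = character(), estimate = numeric(), se = numeric(),
               z = numeric(), p = numeric(), hazard_ratio = numeric())
  }

  lp_fixed <- if (p) drop(X %*% inner$theta[seq_len(p)]) else numeric(n)
  baseline <- breslow_baseline(records$stop_day, records$event,
                               records$year, lp_fixed)

  structure(list(
    model_name = model_name, terms = terms,
    random_effects = random_effects,
    coefficients = coefs, frailty_var = frailty_var,
    loglik = loglik, n = n, n_events = sum(records$event),
    df = n - p, n_terms = p,
    baseline = baseline,
    records_fingerprint = records_fingerprint(records)
  ), class = "cox_fit")
}

records_fingerprint <- function(records) {
  c(n = nrow(records), sum_t = sum(records$stop_day),
    sum_e = sum(records$event))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %s: %d fawns, %d events, integrated logLik %.3f\n",
              x$model_name, x$n, x$n_events, x$loglik))
  if (nrow(x$coefficients)) print(x$coefficients, digits = 3)
  if (length(x$frailty_var)) {
    cat("frailty variances:",
        paste(sprintf("%s=%.4f", names(x$frailty_var), x$frailty_var),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Breslow baseline cumulative hazard / survival per year, reference
# covariate vector 0 (covariates are z-scored), frailties excluded.
breslow_baseline <- function(time, status, year, lp) {
  w <- exp(lp)
  out <- lapply(sort(unique(year)), function(yy) {
    sel <- year == yy
    t_y <- time[sel]; d_y <- status[sel]; w_y <- w[sel]
    evt <- sort(unique(t_y[d_y == 1]))
    if (!length(evt)) {
      return(data.frame(year = yy, time = 0, H0 = 0, S0 = 1))
    }
    dk <- vapply(evt, function(te) sum(d_y == 1 & t_y == te), numeric(1))
    rk <- vapply(evt, function(te) sum(w_y[t_y >= te]), numeric(1))
    H0 <- cumsum(dk / rk)
    tt <- c(0, evt); hh <- c(0, H0)
    # the estimator is flat from the last event to the end of follow-up
    if (max(t_y) > max(evt)) {
      tt <- c(tt, max(t_y)); hh <- c(hh, max(H0))
    }
    data.frame(year = yy, time = tt, H0 = hh, S0 = exp(-hh))
  })
  do.call(rbind, out)
}

#' Deviance explained of a model relative to the null
#'
#' The log-likelihood difference between a fitted model and the
#' random-effects-only null on the same records; equals half the
#' likelihood-ratio chi-square. Used to rank the candidate model set.
#'
#' @param fit a `cox_fit`.
#' @param null_fit the null `cox_fit` (same records, no fixed terms).
#' @return list with `deviance_explained`, `lr_chisq`, `lr_p` (chi-square
#'   test on the number of fixed terms).
#' @export
deviance_explained <- function(fit, null_fit) {
  if (!isTRUE(all.equal(fit$records_fingerprint,
                        null_fit$records_fingerprint))) {
    stop("model and null were fitted to different record sets", call. = FALSE)
  }
  de <- fit$loglik - null_fit$loglik
  lr <- 2 * de
  list(deviance_explained = de, lr_chisq = lr,
       lr_p = pchisq(lr, df = max(fit$n_terms, 1), lower.tail = FALSE))
}
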