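#' Fitted regression model container
#'
#' All estimators in the package share one regression layer. A `fitted_model`
#' stores the family tag, coefficient vector(s), model-based and
#' cluster-sandwich covariance matrices, the residual RMSE (linear family
#' only), a convergence flag and the number of rows used. Optimizer failures
#' are recorded in the `converged` flag rather than raised, because failure
#' counts are a first-class output of the simulation harness.
#'
#' @name fitted_model
NULL

new_fitted_model <- function(family, coefficients, vcov_model = NULL,
                             vcov_sandwich = NULL, rmse = NULL,
                             converged = TRUE, n_used = NA_integer_,
                             fit = NULL, terms = NULL, zero = NULL,
                             theta = NULL, diagnostic = NULL,
                             boundary = FALSE) {
  structure(list(family = family, coefficients = coefficients,
                 vcov_model = vcov_model, vcov_sandwich = vcov_sandwich,
                 rmse = rmse, converged = converged, n_used = n_used,
                 fit = fit, terms = terms, zero = zero, theta = theta,
                 diagnostic = diagnostic, boundary = boundary),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model [%s]%s, n = %s\n", x$family,
              if (x$converged) "" else " (NOT CONVERGED)", x$n_used))
  if (!is.null(x$coefficients)) {
    cat("count/mean part:\n"); print(x$coefficients)
  }
  if (!is.null(x$zero)) {
    cat("zero part:\n"); print(x$zero$coefficients)
  }
  if (!is.null(x$theta)) cat(sprintf("dispersion theta: %.4f\n", x$theta))
  if (!is.null(x$rmse)) cat(sprintf("residual RMSE: %.4f\n", x$rmse))
  invisible(x)
}

#' @export
coef.fitted_model <- function(object, ...) object$coefficients

#' @export
vcov.fitted_model <- function(object, type = c("sandwich", "model"), ...) {
  type <- match.arg(type)
  if (type == "sandwich") object$vcov_sandwich else object$vcov_model
}

#' Fit a (weighted) regression model
#'
#' Thin wrapper around [stats::lm()], [stats::glm()] and [MASS::glm.nb()]
#' producing a [fitted_model] with both model-based and cluster-robust
#' (sandwich) covariances. Weights enter as likelihood multipliers, so the
#' coefficient estimates are invariant to rescaling all weights by a constant.
#'
#' @param formula Model formula referring to panel columns.
#' @param data Data frame (typically an analysis view of a panel).
#' @param family One of `"linear"`, `"logistic"`, `"negbin"`, `"gamma_log"`.
#' @param weights Optional strictly positive per-row weights.
#' @param cluster Optional per-row cluster identifier (person id) for the
#'   sandwich covariance; defaults to independent rows.
#' @return A [fitted_model]. On optimizer failure `converged` is `FALSE` and
#'   coefficients are absent.
#' @export
fit_glm <- function(formula, data, family = c("linear", "logistic", "negbin",
                                              "gamma_log"),
                    weights = NULL, cluster = NULL) {
  family <- match.arg(family)
  if (!is.null(weights)) {
    if (any(!is.finite(weights)) || any(weights <= 0)) {
      stop("weights must be strictly positive and finite", call. = FALSE)
    }
  }
  # reference weights through a data column so model-frame evaluation never
  # picks up stats::weights from the search path; keep only the columns the
  # formula needs (analysis views are wide and copying them is costly)
  nr <- nrow(data)
  vars <- intersect(unique(all.vars(formula)), names(data))
  data <- as.data.frame(data)[, vars, drop = FALSE]
  rownames(data) <- NULL
  data$.wts <- if (is.null(weights)) rep(1, nr) else weights
  fit <- tryCatch({
    withCallingHandlers(
      switch(family,
        linear = stats::lm(formula, data = data, weights = .wts),
        logistic = stats::glm(formula, data = data, weights = .wts,
                              family = stats::binomial()),
        negbin = MASS::glm.nb(formula, data = data, weights = .wts),
        gamma_log = stats::glm(formula, data = data, weights = .wts,
                               family = stats::Gamma(link = "log"))),
      warning = function(w) invokeRestart("muffleWarning"))
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_fitted_model(family, NULL, converged = FALSE,
                            diagnostic = conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    return(new_fitted_model(family, NULL, converged = FALSE,
                            diagnostic = "rank-deficient design"))
  }
  converged <- if (inherits(fit, "glm")) isTRUE(fit$converged) else TRUE
  if (inherits(fit, "negbin") && !is.null(fit$th.warn)) {
    # theta estimation hit its iteration limit; flag but keep estimates
    converged <- isTRUE(fit$converged)
  }
  n_used <- stats::nobs(fit)
  vc_model <- tryCatch(suppressWarnings(stats::vcov(fit)),
                       error = function(e) NULL)
  vc_sand <- tryCatch(suppressWarnings({
    if (is.null(cluster)) sandwich::vcovHC(fit, type = "HC0")
    else sandwich::vcovCL(fit, cluster = cluster_for_fit(fit, data, cluster),
                          type = "HC0")
  }), error = function(e) NULL)
  rmse <- NULL
  if (family == "linear") {
    w <- stats::weights(fit)
    res <- stats::residuals(fit)
    if (is.null(w)) w <- rep(1, length(res))
    rmse <- sqrt(sum(w * res^2) / (length(res) - length(cf)))
  }
  new_fitted_model(family, cf, vcov_model = vc_model, vcov_sandwich = vc_sand,
                   rmse = rmse, converged = converged, n_used = n_used,
                   fit = fit, terms = stats::terms(fit))
}

# align a full-data cluster vector with the rows a fit actually used
#' @keywords internal
cluster_for_fit <- function(fit, data, cluster) {
  used <- as.integer(rownames(stats::model.frame(fit)))
  if (length(used) == length(cluster) || is.null(used)) {
    if (!is.null(fit$na.action)) return(cluster[-fit$na.action])
    return(cluster)
  }
  cluster[used]
}

#' Fit a zero-inflated negative binomial model
#'
#' Joint maximum likelihood for a mixture of a structural-zero logistic part
#' and an NB2 count part (variance `mu + mu^2 / theta`, log link). Written
#' in-package so that inverse-probability weights can enter the log-likelihood
#' as frequency-style multipliers and cluster-sandwich covariances can be
#' formed from the analytic per-row scores.
#'
#' @param formula Count-part formula; its response must be a non-negative
#'   integer column.
#' @param zero_formula One-sided formula for the zero-inflation part (e.g.
#'   `~ x + age`). Defaults to the count-part right-hand side.
#' @param data Data frame.
#' @param weights Optional positive weights (likelihood multipliers).
#' @param cluster Optional cluster id for the sandwich covariance.
#' @param start Optional starting values `list(count =, zero =, log_theta =)`;
#'   used to warm-start repeated fits in simulations.
#' @param se Compute the model-based and sandwich covariances (skip for
#'   pure prediction models to save time).
#' @param control Passed to [stats::optim()] (`method = "BFGS"`).
#' @return A [fitted_model] with `family = "zinb"`; `coefficients` holds the
#'   count part, `$zero$coefficients` the zero part, `$theta` the dispersion.
#'   The joint parameter order for the covariance matrices is
#'   `(zero, count, log_theta)`.
#' @export
fit_zinb <- function(formula, zero_formula = NULL, data, weights = NULL,
                     cluster = NULL, start = NULL, se = TRUE,
                     control = list(maxit = 500, reltol = 1e-10)) {
  vars <- unique(c(all.vars(formula),
                   if (!is.null(zero_formula)) all.vars(zero_formula)))
  data <- as.data.frame(data)[, intersect(vars, names(data)), drop = FALSE]
  rownames(data) <- NULL
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  keep <- as.integer(rownames(mf))
  y <- stats::model.response(mf)
  if (any(y < 0) || any(y != floor(y))) {
    stop("zinb response must be a non-negative integer column", call. = FALSE)
  }
  X <- stats::model.matrix(stats::terms(mf), mf)
  if (is.null(zero_formula)) zero_formula <- formula[-2]
  zt <- stats::terms(zero_formula)
  Z <- stats::model.matrix(zt, data[keep, , drop = FALSE])
  w <- if (is.null(weights)) rep(1, length(y)) else weights[keep]
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be strictly positive and finite", call. = FALSE)
  }
  cl <- if (is.null(cluster)) seq_along(y) else cluster[keep]
  if (!any(y == 0)) {
    return(new_fitted_model("zinb", NULL, converged = FALSE,
                            diagnostic = "no zero-inflation identifiable"))
  }
  pz <- ncol(Z); px <- ncol(X)
  # fallback starts: intercept-only mixture moments
  p_zero <- sum(w * (y == 0)) / sum(w)
  mu_pos <- sum(w * y) / sum(w * (y > 0))
  par_fallback <- c(stats::qlogis(max(min(p_zero / 2 + 0.01, 0.98), 0.02)),
                    rep(0, pz - 1), log(max(mu_pos, 0.5)), rep(0, px - 1), 0)
  if (!is.null(start) &&
      length(c(start$zero, start$count, start$log_theta)) != pz + px + 1) {
    start <- NULL  # stale warm start from a different design
  }
  if (!is.null(start)) {
    par0 <- c(start$zero, start$count, start$log_theta)
  } else {
    gz0 <- tryCatch(suppressWarnings(
      stats::glm.fit(Z, as.numeric(y == 0), weights = w,
                     family = stats::binomial())$coefficients),
      error = function(e) rep(NA_real_, pz))
    pos <- y > 0
    gx0 <- tryCatch(suppressWarnings(
      stats::glm.fit(X[pos, , drop = FALSE], y[pos], weights = w[pos],
                     family = stats::poisson())$coefficients),
      error = function(e) rep(NA_real_, px))
    if (anyNA(gz0) || max(abs(gz0)) > 10) gz0 <- par_fallback[1:pz]
    if (anyNA(gx0) || max(abs(gx0)) > 10) gx0 <- par_fallback[pz + 1:px]
    par0 <- c(gz0, gx0, 0)
  }
  is0 <- y == 0
  # split rows once: zero and positive subsets never change during fitting
  i0 <- which(is0); ip <- which(!is0)
  Z0 <- Z[i0, , drop = FALSE]; X0 <- X[i0, , drop = FALSE]
  Zp <- Z[ip, , drop = FALSE]; Xp <- X[ip, , drop = FALSE]
  w0 <- w[i0]; wp <- w[ip]; yp <- y[ip]
  lg_yp1 <- lgamma(yp + 1)

  nll <- function(par) {
    gz <- par[1:pz]; gx <- par[pz + 1:px]; lt <- par[pz + px + 1]
    if (abs(lt) > 30) return(1e12)
    eta_z0 <- drop(Z0 %*% gz); eta_x0 <- drop(X0 %*% gx)
    eta_zp <- drop(Zp %*% gz); eta_xp <- drop(Xp %*% gx)
    if (max(abs(eta_x0), abs(eta_xp), 0) > 30 ||
        max(abs(eta_z0), abs(eta_zp), 0) > 500) return(1e12)
    theta <- exp(lt)
    mu0 <- exp(eta_x0); mup <- exp(eta_xp)
    # zero rows: log(pi + (1 - pi) f0)
    lf0 <- theta * (lt - log(theta + mu0))
    ez <- pmin(eta_z0, 700)
    ll0 <- -log1p(exp(ez)) + log(exp(ez) + exp(lf0))
    # positive rows: log(1 - pi) + NB log density (lgamma(y + 1) precomputed)
    ltm <- log(theta + mup)
    llp <- -log1p(exp(pmin(eta_zp, 700))) +
      lgamma(yp + theta) - lgamma(theta) - lg_yp1 +
      theta * (lt - ltm) + yp * (eta_xp - ltm)
    v <- -(sum(w0 * ll0) + sum(wp * llp))
    if (!is.finite(v)) 1e12 else v
  }

  # per-subset score pieces d loglik / d(eta_z, eta_x, log theta)
  score_parts <- function(par) {
    gz <- par[1:pz]; gx <- par[pz + 1:px]; lt <- par[pz + px + 1]
    theta <- exp(lt)
    eta_z0 <- drop(Z0 %*% gz); eta_x0 <- drop(X0 %*% gx)
    eta_zp <- drop(Zp %*% gz); eta_xp <- drop(Xp %*% gx)
    mu0 <- exp(eta_x0); mup <- exp(eta_xp)
    pi0 <- stats::plogis(eta_z0); pip <- stats::plogis(eta_zp)
    f0 <- exp(theta * (lt - log(theta + mu0)))
    p0 <- pi0 + (1 - pi0) * f0
    dz0 <- pi0 * (1 - pi0) * (1 - f0) / p0
    dx0 <- -(1 - pi0) * f0 * theta * mu0 / (theta + mu0) / p0
    dt0 <- (1 - pi0) * f0 *
      (theta * (lt + 1 - log(theta + mu0) - theta / (theta + mu0))) / p0
    dzp <- -pip
    dxp <- yp - (yp + theta) * mup / (theta + mup)
    dtp <- theta * (digamma(yp + theta) - digamma(theta) +
                      lt - log(theta + mup) + 1 - (yp + theta) / (theta + mup))
    list(dz0 = dz0, dx0 = dx0, dt0 = dt0, dzp = dzp, dxp = dxp, dtp = dtp)
  }

  grad <- function(par) {
    d <- score_parts(par)
    -c(drop(crossprod(Z0, w0 * d$dz0)) + drop(crossprod(Zp, wp * d$dzp)),
       drop(crossprod(X0, w0 * d$dx0)) + drop(crossprod(Xp, wp * d$dxp)),
       sum(w0 * d$dt0) + sum(wp * d$dtp))
  }

  # full score matrix in the original row order (for the cluster sandwich)
  score_rows <- function(par) {
    d <- score_parts(par)
    S <- matrix(0, length(y), pz + px + 1)
    S[i0, ] <- cbind(Z0 * (w0 * d$dz0), X0 * (w0 * d$dx0), w0 * d$dt0)
    S[ip, ] <- cbind(Zp * (wp * d$dzp), Xp * (wp * d$dxp), wp * d$dtp)
    S
  }

  # BHHH ascent: Newton steps with the outer product of scores as curvature,
  # plus halving line search; typically an order of magnitude fewer
  # likelihood evaluations than quasi-Newton on this surface
  bhhh <- function(p0) {
    par <- p0
    val <- nll(par)
    if (val >= 1e12) return(NULL)
    sw <- sum(w)
    for (it in seq_len(100)) {
      d <- score_parts(par)
      S0 <- cbind(Z0 * (w0 * d$dz0), X0 * (w0 * d$dx0), w0 * d$dt0)
      Sp <- cbind(Zp * (wp * d$dzp), Xp * (wp * d$dxp), wp * d$dtp)
      g <- colSums(S0) + colSums(Sp)
      if (max(abs(g)) / sw < 1e-4) break
      A <- crossprod(S0) + crossprod(Sp)
      diag(A) <- diag(A) + 1e-8 * (1 + diag(A))
      delta <- tryCatch(solve(A, g), error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) return(NULL)
      lambda <- 1
      improved <- FALSE
      for (h in seq_len(25)) {
        cand <- par + lambda * delta
        v <- nll(cand)
        if (is.finite(v) && v < val) {
          par <- cand
          improved <- TRUE
          dv <- val - v
          val <- v
          break
        }
        lambda <- lambda / 2
      }
      if (!improved) break
      if (dv < 1e-12 * (abs(val) + 1)) break
    }
    list(par = par, value = val, convergence = 0)
  }
  run_opt <- function(p0) {
    o <- bhhh(p0)
    if (!is.null(o) && max(abs(grad(o$par))) / sum(w) < 2e-3) return(o)
    p_start <- if (!is.null(o)) o$par else p0
    tryCatch(
      stats::optim(p_start, nll, grad, method = "BFGS", control = control),
      error = function(e) e)
  }
  # scaled gradient norm at the solution; restart from the fallback start if
  # the optimizer stalled on a flat or penalized region
  opt_ok <- function(o) {
    !inherits(o, "error") && is.finite(o$value) && o$value < 1e12 &&
      max(abs(grad(o$par))) / sum(w) < 1e-2
  }
  opt <- run_opt(par0)
  if (!opt_ok(opt) && !identical(par0, par_fallback)) {
    opt2 <- run_opt(par_fallback)
    if (opt_ok(opt2) || (!inherits(opt2, "error") &&
                         (inherits(opt, "error") ||
                            opt2$value < opt$value))) {
      opt <- opt2
    }
  }
  if (inherits(opt, "error") || !is.finite(opt$value) || opt$value >= 1e12) {
    return(new_fitted_model("zinb", NULL, converged = FALSE,
                            diagnostic = if (inherits(opt, "error"))
                              conditionMessage(opt) else "likelihood overflow"))
  }
  par <- opt$par
  converged <- opt$convergence == 0 && opt_ok(opt)
  boundary <- max(abs(par[1:pz])) > 15  # zero part drifting to +/- infinity
  vc_model <- NULL
  vc_sand <- NULL
  if (se) {
    # observed information by forward differences of the analytic gradient
    p_all <- length(par)
    g0 <- grad(par)
    hess <- matrix(0, p_all, p_all)
    for (j in seq_len(p_all)) {
      h <- 1e-6 * (1 + abs(par[j]))
      pj <- par; pj[j] <- pj[j] + h
      hess[, j] <- (grad(pj) - g0) / h
    }
    hess <- (hess + t(hess)) / 2
    vc_model <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc_model)) {
      S <- score_rows(par)
      Sc <- rowsum(S, group = cl)
      meat <- crossprod(Sc)
      vc_sand <- vc_model %*% meat %*% vc_model
    }
  }
  names_all <- c(paste0("zero_", colnames(Z)), colnames(X), "log_theta")
  names(par) <- names_all
  if (!is.null(vc_model)) dimnames(vc_model) <- list(names_all, names_all)
  if (!is.null(vc_sand)) dimnames(vc_sand) <- list(names_all, names_all)
  count_cf <- par[pz + 1:px]; names(count_cf) <- colnames(X)
  zero_cf <- par[1:pz]; names(zero_cf) <- colnames(Z)
  m <- new_fitted_model("zinb", count_cf, vcov_model = vc_model,
                        vcov_sandwich = vc_sand, converged = converged,
                        n_used = length(y),
                        terms = stats::delete.response(stats::terms(mf)),
                        zero = list(coefficients = zero_cf, terms = zt),
                        theta = exp(par[pz + px + 1]), boundary = boundary)
  m$par <- par
  m$idx <- list(zero = 1:pz, count = pz + 1:px, log_theta = pz + px + 1)
  m
}

# linear predictors of a zinb model on new data
#' @keywords internal
predict_zinb <- function(model, newdata) {
  X <- stats::model.matrix(model$terms, newdata)
  Z <- stats::model.matrix(stats::delete.response(model$zero$terms), newdata)
  list(mu = exp(drop(X %*% model$coefficients)),
       pi = stats::plogis(drop(Z %*% model$zero$coefficients)))
}

# mean of the zinb conditional distribution
#' @keywords internal
zinb_mean <- function(model, newdata) {
  p <- predict_zinb(model, newdata)
  (1 - p$pi) * p$mu
}

#' Draw from a fitted conditional distribution
#'
#' Draws one outcome per row of `newdata` from the conditional distribution
#' implied by a converged [fitted_model]: mean plus Normal(0, RMSE) noise for
#' the linear family, or a Bernoulli structural zero followed by a negative
#' binomial draw for the zinb family. Uses the current R random stream, so
#' call [set.seed()] beforehand for reproducibility.
#'
#' @param model A converged [fitted_model] (`linear` or `zinb`).
#' @param newdata Data frame of covariate rows.
#' @param cap Upper truncation bound for count draws (default 365, the number
#'   of days in a year).
#' @return Numeric vector of draws, one per row.
#' @export
sample_outcome <- function(model, newdata, cap = 365) {
  if (!model$converged) {
    stop("cannot sample from a non-converged model", call. = FALSE)
  }
  n <- nrow(newdata)
  if (model$family == "linear") {
    mu <- unname(stats::predict(model$fit, newdata = newdata))
    return(mu + stats::rnorm(n, 0, model$rmse))
  }
  if (model$family == "zinb") {
    p <- predict_zinb(model, newdata)
    zero <- stats::rbinom(n, 1, p$pi)
    draws <- stats::rnbinom(n, size = model$theta, mu = p$mu)
    return(pmin(ifelse(zero == 1, 0, draws), cap))
  }
  stop("sampling implemented for linear and zinb families only",
       call. = FALSE)
}
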