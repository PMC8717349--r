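#' Binomial mixed model for the proportion of gleaned prey
#'
#' Models, per sample, the number of prey items likely caught by gleaning
#' out of the sample's classified prey (gleaning + hawking) as a function
#' of the predator species:
#' `y_s ~ Binomial(n_s, pi_s)`, `logit pi_s = X_s beta + u_s`,
#' `u_s ~ N(0, sigma_u^2)` with one random intercept per sample. Because
#' each sample contributes a single binomial observation, the sample-level
#' random intercept is an observation-level random effect absorbing
#' extra-binomial (overdispersion) variation.
#'
#' The marginal likelihood is maximised by adaptive Gauss-Hermite
#' quadrature with `n_quad` nodes, centred and scaled at each sample's
#' conditional mode; `n_quad = 1` gives the Laplace approximation. The
#' fixed-effect covariance is the corresponding block of the inverse
#' observed information of all parameters at the optimum.
#'
#' @param counts a `data.frame` with columns `sample_id`, `predator`,
#'   `n_gleaning`, `n_hawking` (e.g. from [tally_modes()]); rows with
#'   `model_input == FALSE` or zero classified prey are dropped.
#' @param n_quad number of quadrature nodes (default 15; 1 = Laplace).
#' @param reference reference predator level; `beta[2]` is then the
#'   log-odds contrast of the other level against it. Default: the level
#'   `"Myotis ikonnikovi"` when present, else the first level
#'   alphabetically.
#' @param fix_sigma optionally fix the random-intercept SD (e.g. `0` for
#'   the plain binomial GLM limit) instead of estimating it.
#' @param null_model if `TRUE`, drop the predator term (intercept-only
#'   null model for the likelihood-ratio test).
#' @param start optional starting values `list(beta =, log_sigma =)`.
#' @param hessian compute the observed-information covariance of the
#'   estimates (default `TRUE`); bootstrap refits skip it for speed.
#' @return an object of class `binom_glmm` with elements `beta`, `se`,
#'   `vcov`, `sigma_u`, `loglik`, `n_quad`, `converged`, `reference`,
#'   `levels`, `data`.
#' @export
fit_binomial_glmm <- function(counts, n_quad = 15, reference = NULL,
                              fix_sigma = NULL, null_model = FALSE,
                              start = NULL, hessian = TRUE) {
  dat <- counts
  if (!is.null(dat$model_input)) dat <- dat[dat$model_input, , drop = FALSE]
  dat$y <- dat$n_gleaning
  dat$m <- dat$n_gleaning + dat$n_hawking
  dat <- dat[dat$m > 0, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no samples with classified prey", call. = FALSE)

  levs <- sort(unique(dat$predator))
  if (!null_model && length(levs) < 2L) {
    stop("need at least two predators for the species contrast",
         call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- if ("Myotis ikonnikovi" %in% levs) "Myotis ikonnikovi"
                 else levs[1]
  }
  if (!reference %in% levs) stop("reference level not present", call. = FALSE)
  dat$predator <- factor(dat$predator,
                         levels = c(reference, setdiff(levs, reference)))

  X <- if (null_model) matrix(1, nrow(dat), 1,
                              dimnames = list(NULL, "(Intercept)"))
       else stats::model.matrix(~ predator, dat)
  p <- ncol(X)

  # identical (y, m, design-row) observations contribute identical marginal
  # terms; collapse them with multiplicity weights
  key <- paste(dat$y, dat$m, apply(X, 1L, paste, collapse = ","), sep = "|")
  first <- !duplicated(key)
  w <- as.numeric(table(key)[key[first]])
  ya <- dat$y[first]; ma <- dat$m[first]; Xa <- X[first, , drop = FALSE]

  gh <- if (n_quad == 1L) list(x = 0, w = sqrt(pi))
        else pracma::gaussHermite(n_quad)
  lw <- log(gh$w) + gh$x^2  # log weights for the adaptive rule
  lch <- lchoose(ma, ya)    # constant binomial coefficients

  cache <- new.env(parent = emptyenv())
  cache$u <- numeric(length(ya))
  nll <- function(par) {
    beta <- par[seq_len(p)]
    sigma <- if (is.null(fix_sigma)) exp(par[p + 1L]) else fix_sigma
    eta <- as.numeric(Xa %*% beta)
    -sum(w * agq_log_marginal(ya, ma, eta, sigma, gh$x, lw, lch, cache))
  }

  init_beta <- if (!is.null(start$beta)) start$beta else {
    fit0 <- suppressWarnings(
      stats::glm.fit(Xa, ya / ma, weights = w * ma,
                     family = stats::binomial())
    )
    ifelse(is.finite(fit0$coefficients), fit0$coefficients, 0)
  }
  if (is.null(fix_sigma)) {
    init <- c(init_beta, start$log_sigma %||% log(0.5))
    opt <- stats::optim(init, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-9))
    sigma_u <- unname(exp(opt$par[p + 1L]))
    if (sigma_u < 1e-6) sigma_u <- 0
  } else {
    opt <- stats::optim(init_beta, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-9))
    sigma_u <- fix_sigma
  }

  vc <- if (hessian) glmm_vcov(opt$par, nll, p, sigma_u, is.null(fix_sigma))
        else matrix(NA_real_, p, p)
  beta <- stats::setNames(opt$par[seq_len(p)], colnames(X))

  structure(list(beta = beta,
                 se = sqrt(pmax(diag(vc), 0)),
                 vcov = vc,
                 sigma_u = sigma_u,
                 loglik = -opt$value,
                 n_quad = n_quad,
                 converged = opt$convergence == 0L,
                 reference = reference,
                 levels = levels(dat$predator),
                 null_model = null_model,
                 fix_sigma = fix_sigma,
                 data = dat[, c("sample_id", "predator", "y", "m")]),
            class = "binom_glmm")
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# per-observation log marginal likelihood by adaptive Gauss-Hermite
# quadrature; sigma = 0 degenerates to the plain binomial term.
# The kernel is inlined arithmetic (no dbinom/dnorm calls): it runs tens of
# thousands of times inside the parametric bootstrap.
agq_log_marginal <- function(y, m, eta, sigma, z, lw, lch = lchoose(m, y),
                             cache = NULL) {
  if (sigma < 1e-8) {
    return(lch + y * eta - m * log1pexp(eta))
  }
  n <- length(y)
  inv_s2 <- 1 / sigma^2
  # conditional mode by Newton iterations (concave objective), warm-started
  # from the previous evaluation when a cache is supplied
  u <- if (!is.null(cache)) cache$u else numeric(n)
  for (it in 1:8) {
    pr <- 1 / (1 + exp(-(eta + u)))
    step <- (y - m * pr - u * inv_s2) / (m * pr * (1 - pr) + inv_s2)
    u <- u + step
    if (max(abs(step)) < 1e-9) break
  }
  if (!is.null(cache)) cache$u <- u
  pr <- 1 / (1 + exp(-(eta + u)))
  sc <- sqrt(2 / (m * pr * (1 - pr) + inv_s2))
  K <- length(z)
  U <- u + outer(sc, z)                       # n x K node matrix
  ETA <- eta + U
  A <- y * ETA - m * log1pexp(ETA) - (0.5 * inv_s2) * U * U +
    rep(lw, each = n)
  mx <- A[cbind(seq_len(n), max.col(A, ties.method = "first"))]
  log(rowSums(exp(A - mx))) + mx + log(sc) + lch -
    log(sigma) - 0.5 * log(2 * pi)
}

glmm_vcov <- function(par, nll, p, sigma_u, sigma_free) {
  hess <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
  vc <- NULL
  if (!is.null(hess)) {
    # with sigma at the boundary the log-sigma direction is flat; drop it
    if (sigma_free && sigma_u == 0) hess <- hess[seq_len(p), seq_len(p),
                                                 drop = FALSE]
    vc <- tryCatch(solve(hess), error = function(e) NULL)
  }
  if (is.null(vc) || any(!is.finite(vc))) {
    vc <- matrix(NA_real_, p, p)
  }
  vc <- vc[seq_len(p), seq_len(p), drop = FALSE]
  (vc + t(vc)) / 2
}

#' @export
print.binom_glmm <- function(x, ...) {
  cat("<binom_glmm> binomial GLMM, observation-level random intercept\n")
  cat("  fixed effects (logit scale):\n")
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  cat("  sigma_u = ", signif(x$sigma_u, 4), ", logLik = ",
      signif(x$loglik, 6), ", nAGQ = ", x$n_quad,
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  invisible(x)
}

#' Simulate response data from a fitted capture-mode model
#'
#' Draws, for every sample in the fit, a fresh random intercept and a
#' binomial response with the sample's observed classified prey count.
#' Used by the parametric bootstrap.
#'
#' @param fit a [fit_binomial_glmm()] object.
#' @return a `counts` data.frame suitable for refitting.
#' @export
simulate_glmm <- function(fit) {
  dat <- fit$data
  X <- if (fit$null_model) matrix(1, nrow(dat), 1)
       else stats::model.matrix(~ predator, dat)
  eta <- as.numeric(X %*% fit$beta) +
    stats::rnorm(nrow(dat), 0, fit$sigma_u)
  y <- stats::rbinom(nrow(dat), dat$m, stats::plogis(eta))
  data.frame(sample_id = dat$sample_id,
             predator = as.character(dat$predator),
             n_gleaning = y, n_hawking = dat$m - y,
             stringsAsFactors = FALSE)
}

#' Parametric-bootstrap likelihood-ratio test
#'
#' Tests the species effect by comparing the full model against the
#' nested null model: the observed statistic is `2 (l_full - l_null)`,
#' and its null distribution is estimated by simulating `B` datasets from
#' the fitted null model and refitting both models on each. The p-value is
#' `(1 + #{LRT_b >= LRT}) / (B_eff + 1)`; replicates whose refit fails to
#' converge are dropped and the effective `B_eff` reported.
#'
#' @param fit_full full-model fit from [fit_binomial_glmm()].
#' @param fit_null nested null fit (`null_model = TRUE`) on the same data.
#' @param B number of bootstrap replicates, default 500.
#' @param seed integer seed.
#' @return a list with `lrt`, `df`, `p`, `B`, `B_eff` and the bootstrap
#'   statistics `boot`.
#' @export
bootstrap_lrt <- function(fit_full, fit_null, B = 500, seed = NULL) {
  stopifnot(inherits(fit_full, "binom_glmm"), inherits(fit_null, "binom_glmm"))
  if (nrow(fit_full$data) != nrow(fit_null$data)) {
    stop("full and null fits must use the same samples", call. = FALSE)
  }
  df <- length(fit_full$beta) - length(fit_null$beta)
  if (df < 0) stop("null model must be nested in the full model",
                   call. = FALSE)
  lrt <- 2 * (fit_full$loglik - fit_null$loglik)
  if (!is.null(seed)) set.seed(seed)
  boot <- rep(NA_real_, B)
  ref <- fit_full$reference
  for (b in seq_len(B)) {
    sim <- simulate_glmm(fit_null)
    fn <- try(fit_binomial_glmm(sim, n_quad = fit_null$n_quad,
                                reference = ref, null_model = TRUE,
                                hessian = FALSE,
                                start = list(beta = fit_null$beta,
                                             log_sigma =
                                               log(max(fit_null$sigma_u,
                                                       0.1)))),
              silent = TRUE)
    ff <- try(fit_binomial_glmm(sim, n_quad = fit_full$n_quad,
                                reference = ref, hessian = FALSE,
                                start = list(beta = fit_full$beta,
                                             log_sigma =
                                               log(max(fit_full$sigma_u,
                                                       0.1)))),
              silent = TRUE)
    if (inherits(fn, "try-error") || inherits(ff, "try-error") ||
        !fn$converged || !ff$converged) next
    boot[b] <- 2 * (ff$loglik - fn$loglik)
  }
  ok <- !is.na(boot)
  list(lrt = lrt, df = df,
       p = (1 + sum(boot[ok] >= lrt)) / (sum(ok) + 1),
       B = B, B_eff = sum(ok), boot = boot[ok])
}

#' Wald chi-square test of the species effect
#'
#' For the single two-level species factor the Type II Wald test reduces
#' to `chi^2 = (beta_1 / SE_1)^2` on one degree of freedom.
#'
#' @param fit a converged full-model [fit_binomial_glmm()].
#' @return a list with `chisq`, `df`, `p`.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "binom_glmm"))
  if (fit$null_model) stop("wald_test needs the full model", call. = FALSE)
  if (!fit$converged) warning("fit did not converge; Wald test unreliable")
  chisq <- (fit$beta[2] / fit$se[2])^2
  list(chisq = as.numeric(chisq), df = 1L,
       p = stats::pchisq(as.numeric(chisq), df = 1L, lower.tail = FALSE))
}

#' Marginal capture-mode probabilities and odds ratio
#'
#' Per-predator probability of a prey item being of the gleaning-likely
#' class, evaluated at the fixed-effect linear predictor with the random
#' intercept at zero; standard errors by the delta method from the
#' fixed-effect covariance. Also the species odds ratio `exp(beta_1)` with
#' `SE = exp(beta_1) SE(beta_1)`, and the z-ratio `beta_1 / SE(beta_1)`.
#'
#' @param fit a converged full-model [fit_binomial_glmm()].
#' @return a list with `probs` (`data.frame`: `predator`, `prob`, `se`),
#'   `odds_ratio`, `or_se`, `z_ratio`, `p`.
#' @export
marginal_probs <- function(fit) {
  stopifnot(inherits(fit, "binom_glmm"))
  if (fit$null_model) stop("marginal_probs needs the full model",
                           call. = FALSE)
  levs <- fit$levels
  Xl <- cbind(1, diag(length(levs))[, -1, drop = FALSE])
  eta <- as.numeric(Xl %*% fit$beta)
  se_eta <- sqrt(pmax(rowSums((Xl %*% fit$vcov) * Xl), 0))
  prob <- stats::plogis(eta)
  se_prob <- prob * (1 - prob) * se_eta
  b1 <- as.numeric(fit$beta[2])
  se1 <- fit$se[2]
  z <- b1 / se1
  list(probs = data.frame(predator = levs, prob = prob, se = se_prob,
                          stringsAsFactors = FALSE),
       odds_ratio = exp(b1),
       or_se = exp(b1) * se1,
       z_ratio = as.numeric(z),
       p = 2 * stats::pnorm(-abs(as.numeric(z))))
}
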