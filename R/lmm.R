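# REML fitting of the multi-trial phenotype model
#
#   y = X beta + Z_g u_g + Z_gxt u_gxt + Z_b u_b + e
#
# with trial as a fixed effect, genotype effects u_g ~ N(0, A sigma2_g)
# under an optional pedigree numerator relationship matrix A,
# genotype-by-trial and block effects iid, and homogeneous residuals.
#
# The restricted likelihood is maximized over variance ratios
# gamma_t = sigma2_t / sigma2_e on the log scale, with sigma2_e profiled
# out in closed form. Models with a single random term use the spectral
# shortcut (one SVD of Z L, L L' = K, then each likelihood evaluation is
# O(m)); models with several random terms use Nelder-Mead with a dense
# Cholesky per evaluation. Post-processing (BLUPs, BLUEs, the full
# prediction-error covariance of genotype effects) is computed once at the
# optimum from the dense mixed-model algebra.

# Profiled restricted log-likelihood machinery ------------------------------

# Quadratic pieces given H^-1-weighted cross-products.
.reml_profile <- function(yHy, XHy, XHX, ldet_H, n, p) {
  R <- tryCatch(chol(XHX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  ldet_W <- 2 * sum(log(diag(R)))
  beta <- backsolve(R, forwardsolve(t(R), XHy))
  q <- yHy - sum(XHy * beta)
  if (q <= 0) q <- .Machine$double.eps
  s2e <- q / (n - p)
  ll <- -0.5 * ((n - p) * log(s2e) + ldet_H + ldet_W + (n - p))
  list(ll = ll, s2e = s2e, beta = beta)
}

# Dense evaluation: H = I + sum_t gamma_t M_t.
.reml_eval_dense <- function(log_gamma, Ms, X, y) {
  n <- length(y); p <- ncol(X)
  H <- diag(n)
  for (t in seq_along(Ms)) H <- H + exp(log_gamma[t]) * Ms[[t]]
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  ldet_H <- 2 * sum(log(diag(R)))
  Hy <- backsolve(R, forwardsolve(t(R), y))
  HX <- backsolve(R, forwardsolve(t(R), X))
  .reml_profile(sum(y * Hy), crossprod(X, Hy), crossprod(X, HX),
                ldet_H, n, p)
}

# Spectral evaluation for a single random term: M = U diag(d) U' (U n x r).
# H^-1 = I - U diag(gd/(1+gd)) U'.
.reml_eval_spectral <- function(log_gamma, sp, X, y) {
  n <- length(y); p <- ncol(X)
  g <- exp(log_gamma)
  w <- g * sp$d / (1 + g * sp$d)
  ldet_H <- sum(log1p(g * sp$d))
  yHy <- sum(y^2) - sum(w * sp$Uy^2)
  XHy <- crossprod(X, y) - crossprod(sp$UX, w * sp$Uy)
  XHX <- crossprod(X) - crossprod(sp$UX, sp$UX * w)
  .reml_profile(yHy, XHy, XHX, ldet_H, n, p)
}

#' Fit the multi-trial linear mixed model by REML
#'
#' Fits `value ~ trial (fixed) + genotype + genotype:trial + block +
#' residual` with the genotype term either random (BLUPs, optionally
#' correlated through a pedigree relationship matrix `A`) or fixed
#' (BLUEs). Variance components are estimated by direct maximization of
#' the restricted log-likelihood with variances parameterized on the log
#' scale and the residual variance profiled out.
#'
#' @param data long-format data frame with columns `genotype`, `trial`,
#'   `value` and optionally `block`.
#' @param A optional pedigree relationship matrix (from
#'   [build_pedigree_A]) covering every genotype in `data`; identity when
#'   omitted.
#' @param genotype_as `"random"` (default; BLUPs + prediction-error
#'   covariance) or `"fixed"` (BLUEs).
#' @param include_gxt add an iid genotype-by-trial random term (needs
#'   >= 2 trials).
#' @param include_block add an iid block random term (needs a `block`
#'   column with >= 2 levels).
#' @param tol relative convergence tolerance on the restricted
#'   log-likelihood (default 1e-8).
#' @param max_iter iteration cap for the optimizer.
#' @return An object of class `lmm_fit` with elements `fixed_effects`,
#'   `var_components` (named: genotype when random, genotype_trial, block,
#'   residual), `blups`/`blues` (per-genotype predictions with standard
#'   errors; BLUP rows carry prediction-error variances), `pec` (full
#'   prediction-error covariance of genotype effects, genotype-random
#'   only), `loglik`, `converged`, `n_iterations`.
#' @export
fit_lmm <- function(data, A = NULL,
                    genotype_as = c("random", "fixed"),
                    include_gxt = FALSE, include_block = FALSE,
                    tol = 1e-8, max_iter = 200L) {
  genotype_as <- match.arg(genotype_as)
  need <- c("genotype", "trial", "value")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns genotype, trial, value", call. = FALSE)
  }
  data <- data[!is.na(data$value), , drop = FALSE]
  data$genotype <- factor(as.character(data$genotype))
  data$trial <- factor(as.character(data$trial))
  geno_levels <- levels(data$genotype)
  m <- length(geno_levels)
  if (m < 2L) stop("need >= 2 genotypes", call. = FALSE)
  n_trials <- nlevels(data$trial)
  y <- data$value
  n <- length(y)

  if (include_gxt && n_trials < 2L) {
    stop("genotype-by-trial term needs >= 2 trials", call. = FALSE)
  }
  if (include_block &&
      (!"block" %in% names(data) || length(unique(data$block)) < 2L)) {
    stop("block term needs a `block` column with >= 2 levels", call. = FALSE)
  }

  K <- NULL
  if (!is.null(A)) {
    if (inherits(A, "pedigree_matrix")) A <- A$A
    if (!all(geno_levels %in% rownames(A))) {
      stop("relationship matrix A does not cover all genotypes",
           call. = FALSE)
    }
    K <- A[geno_levels, geno_levels]
  }

  # fixed design
  X <- if (genotype_as == "fixed") {
    if (n_trials > 1L) {
      stats::model.matrix(~ 0 + genotype + trial, data)
    } else {
      stats::model.matrix(~ 0 + genotype, data)
    }
  } else if (n_trials > 1L) {
    stats::model.matrix(~ trial, data)
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  p <- ncol(X)
  if (n <= p) {
    stop("singular design: no residual degrees of freedom", call. = FALSE)
  }

  # random terms: list of (name, Z, K or NULL for identity)
  rand <- list()
  Zg <- NULL
  if (genotype_as == "random") {
    Zg <- stats::model.matrix(~ 0 + genotype, data)
    rand$genotype <- list(Z = Zg, K = K)
  }
  if (include_gxt) {
    rand$genotype_trial <- list(
      Z = stats::model.matrix(~ 0 + genotype:trial, data), K = NULL)
  }
  if (include_block) {
    data$block <- factor(as.character(data$block))
    rand$block <- list(Z = stats::model.matrix(~ 0 + block, data), K = NULL)
  }

  n_evals <- 0L
  if (length(rand) == 0L) {
    # pure fixed-effects model: ordinary least squares is the REML fit
    qr_x <- qr(X)
    beta <- qr.coef(qr_x, y)
    res <- y - X %*% beta
    s2e <- sum(res^2) / (n - p)
    gammas <- numeric(0)
    ll <- -0.5 * ((n - p) * log(s2e) +
                    2 * sum(log(abs(diag(qr.R(qr_x))))) + (n - p))
    converged <- TRUE
  } else if (length(rand) == 1L) {
    # spectral shortcut: one SVD, then cheap 1-d profile likelihood
    term <- rand[[1L]]
    ZL <- if (is.null(term$K)) term$Z else {
      ek <- eigen(term$K, symmetric = TRUE)
      term$Z %*% (ek$vectors %*% diag(sqrt(pmax(ek$values, 0)),
                                      nrow = length(ek$values)))
    }
    sv <- svd(ZL, nv = 0)
    keep <- sv$d > max(sv$d) * 1e-10
    sp <- list(d = sv$d[keep]^2,
               Uy = crossprod(sv$u[, keep, drop = FALSE], y),
               UX = crossprod(sv$u[, keep, drop = FALSE], X))
    f <- function(lg) {
      n_evals <<- n_evals + 1L
      r <- .reml_eval_spectral(lg, sp, X, y)
      if (is.null(r)) return(1e10)
      -r$ll
    }
    grid <- seq(-18, 12, length.out = 40)
    vals <- vapply(grid, f, numeric(1))
    i0 <- which.min(vals)
    lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-9)
    gammas <- exp(opt$minimum)
    names(gammas) <- names(rand)
    converged <- TRUE
  } else {
    Ms <- lapply(rand, function(t) {
      if (is.null(t$K)) tcrossprod(t$Z) else t$Z %*% t$K %*% t(t$Z)
    })
    f <- function(lg) {
      n_evals <<- n_evals + 1L
      r <- .reml_eval_dense(lg, Ms, X, y)
      if (is.null(r)) return(1e10)
      -r$ll
    }
    init <- rep(log(1 / (length(rand) + 1)), length(rand))
    opt <- optim(init, f, method = "Nelder-Mead",
                 control = list(reltol = tol, maxit = max_iter * 10L))
    gammas <- exp(opt$par)
    names(gammas) <- names(rand)
    converged <- opt$convergence == 0L
    if (!converged) {
      warning("REML optimizer did not converge (code ", opt$convergence, ")")
    }
  }

  # post-processing at the optimum, dense mixed-model algebra
  H <- diag(n)
  for (t in seq_along(rand)) {
    trm <- rand[[t]]
    M <- if (is.null(trm$K)) tcrossprod(trm$Z) else trm$Z %*% trm$K %*% t(trm$Z)
    H <- H + gammas[t] * M
  }
  Rh <- chol(H)
  solveH <- function(B) backsolve(Rh, forwardsolve(t(Rh), B))
  Hy <- solveH(y)
  HX <- solveH(X)
  XHX <- crossprod(X, HX)
  Rw <- chol(XHX)
  beta <- backsolve(Rw, forwardsolve(t(Rw), crossprod(X, Hy)))
  q <- sum(y * Hy) - sum(crossprod(X, Hy) * beta)
  s2e <- max(q, .Machine$double.eps) / (n - p)
  ldet_H <- 2 * sum(log(diag(Rh)))
  ldet_W <- 2 * sum(log(diag(Rw)))
  ll <- -0.5 * ((n - p) * log(s2e) + ldet_H + ldet_W + (n - p))

  var_components <- c(gammas * s2e, residual = s2e)
  beta <- drop(beta); names(beta) <- colnames(X)

  fit <- list(fixed_effects = beta, var_components = var_components,
              genotype_as = genotype_as, geno_levels = geno_levels,
              n_obs = n, n_trials = n_trials, loglik = ll,
              converged = converged, n_iterations = n_evals)

  if (genotype_as == "random") {
    s2g <- var_components[["genotype"]]
    KZt <- if (is.null(K)) t(Zg) else K %*% t(Zg)      # m x n = (Z K)'
    resid <- y - X %*% fit$fixed_effects
    Hr <- solveH(resid)
    u <- drop(gammas[["genotype"]] * (KZt %*% Hr))
    # prediction-error covariance C = G - G Z' P Z G, G = s2g K
    TT <- solveH(t(KZt))                                # H^-1 Z K, n x m
    XT <- crossprod(X, TT)                              # p x m
    C <- s2g * (if (is.null(K)) diag(m) else K) -
      (gammas[["genotype"]] * s2g) *
      (KZt %*% TT - crossprod(XT, backsolve(Rw, forwardsolve(t(Rw), XT))))
    C <- (C + t(C)) / 2
    dimnames(C) <- list(geno_levels, geno_levels)
    fit$pec <- C
    fit$blups <- data.frame(genotype = geno_levels, blup = u,
                            pev = pmax(diag(C), 0),
                            stringsAsFactors = FALSE)
  } else {
    gi <- grep("^genotype", colnames(X))
    Wi <- chol2inv(Rw) * s2e
    fit$blues <- data.frame(
      genotype = sub("^genotype", "", colnames(X)[gi]),
      blue = fit$fixed_effects[gi],
      se = sqrt(pmax(diag(Wi)[gi], 0)),
      stringsAsFactors = FALSE)
    rownames(fit$blues) <- NULL
  }
  class(fit) <- "lmm_fit"
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> genotype %s, %d obs, %d trial(s)%s\n",
              x$genotype_as, x$n_obs, x$n_trials,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat("variance components:\n")
  print(round(x$var_components, 6))
  invisible(x)
}

#' Arithmetic genotype means
#'
#' The simplest genotype-value estimator: the mean of all replicated
#' measurements per genotype, complementing BLUEs and BLUPs.
#'
#' @param data long-format phenotype data (`genotype`, `value`).
#' @return Data frame with `genotype`, `mean`, `n`.
#' @export
genotype_means <- function(data) {
  agg <- stats::aggregate(value ~ genotype, data = data,
                          FUN = function(v) c(mean(v), length(v)))
  data.frame(genotype = agg$genotype, mean = agg$value[, 1],
             n = agg$value[, 2], stringsAsFactors = FALSE)
}

#' Cullis broad-sense heritability
#'
#' `H2 = 1 - PEVbar / (2 sigma2_g)`, where `PEVbar` is the average over
#' all genotype pairs of the prediction-error variance of the difference
#' of genotype effects, computed exactly from the prediction-error
#' covariance matrix. The result is clamped to \[0, 1\]; a zero genotype
#' variance yields `H2 = 0`.
#'
#' @param fit an [fit_lmm] result with `genotype_as = "random"`.
#' @return Heritability in \[0, 1\].
#' @export
cullis_h2 <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (fit$genotype_as != "random" || is.null(fit$pec)) {
    stop("Cullis H2 needs a genotype-random fit", call. = FALSE)
  }
  s2g <- fit$var_components[["genotype"]]
  if (s2g <= 0) return(0)
  C <- fit$pec
  m <- nrow(C)
  # mean over i != j of C_ii + C_jj - 2 C_ij
  pev_bar <- 2 * (m * sum(diag(C)) - sum(C)) / (m * (m - 1))
  min(max(1 - pev_bar / (2 * s2g), 0), 1)
}

#' Per-trial heritability quality control
#'
#' Fits a genotype-random model to each trial separately, estimates Cullis
#' H2, and excludes trials with convergence issues or `H2 < threshold`.
#'
#' @param data long-format phenotype data (`genotype`, `trial`, `value`,
#'   optional `block`).
#' @param threshold heritability cut-off (default 0.2).
#' @param include_block add a block random term in the per-trial fits.
#' @param A optional pedigree relationship matrix passed to [fit_lmm].
#' @return A list with `retained`, `excluded` (trial names) and `h2`
#'   (per-trial data frame with `trial`, `h2`, `converged`).
#' @export
trial_qc <- function(data, threshold = 0.2, include_block = FALSE, A = NULL) {
  trials <- unique(as.character(data$trial))
  if (length(trials) < 1L) stop("need >= 1 trial", call. = FALSE)
  rows <- lapply(trials, function(tr) {
    d <- data[data$trial == tr, , drop = FALSE]
    res <- tryCatch({
      fit <- fit_lmm(d, A = A, genotype_as = "random",
                     include_block = include_block)
      data.frame(trial = tr, h2 = cullis_h2(fit), converged = fit$converged,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(trial = tr, h2 = NA_real_, converged = FALSE,
                 stringsAsFactors = FALSE)
    })
    res
  })
  h2 <- do.call(rbind, rows)
  ok <- h2$converged & !is.na(h2$h2) & h2$h2 >= threshold
  if (!any(ok)) {
    stop("trial QC excluded every trial (all H2 < ", threshold,
         " or non-converged)", call. = FALSE)
  }
  list(retained = h2$trial[ok], excluded = h2$trial[!ok], h2 = h2)
}
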