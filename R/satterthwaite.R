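# Satterthwaite denominator degrees of freedom for lmer fits.
#
# Follows the standard approach for linear mixed models: the REML criterion
# is treated as a function of the variance parameters (theta, sigma); the
# asymptotic covariance of those parameters is twice the inverse Hessian of
# the criterion, and for a contrast c the df are
#   2 (c' V c)^2 / Var(c' V(theta, sigma) c)
# with the variance obtained by the delta method (finite-difference gradient
# of c' V c). Multi-df contrasts are handled through the eigendecomposition
# of L V L'. All differentiation is numeric (central differences); any
# numerical failure makes callers fall back to a likelihood-ratio test.

# rebuild the (profiled) deviance function of a fitted lmerMod
make_devfun_ <- function(fit) {
  reTrms <- list(Zt = lme4::getME(fit, "Zt"),
                 theta = lme4::getME(fit, "theta"),
                 Lambdat = lme4::getME(fit, "Lambdat"),
                 Lind = lme4::getME(fit, "Lind"),
                 lower = lme4::getME(fit, "lower"),
                 flist = lme4::getME(fit, "flist"),
                 cnms = lme4::getME(fit, "cnms"),
                 Gp = lme4::getME(fit, "Gp"))
  lme4::mkLmerDevfun(fr = fit@frame, X = lme4::getME(fit, "X"),
                     reTrms = reTrms, REML = lme4::isREML(fit))
}

# -2 log-likelihood as a function of varpar = c(theta, sigma)
devfun_vp_ <- function(varpar, devfun, reml) {
  k <- length(varpar)
  sigma <- varpar[k]
  devfun(varpar[-k])
  env <- environment(devfun)
  n <- length(env$resp$y)
  prss <- env$resp$wrss() + env$pp$sqrL(1)
  dev <- env$pp$ldL2() + prss / sigma^2 + n * log(2 * pi * sigma^2)
  if (reml) dev + env$pp$ldRX2() - ncol(env$pp$RX()) * log(2 * pi * sigma^2)
  else dev
}

# vcov of the fixed effects at a given varpar
vcov_beta_at_ <- function(varpar, devfun) {
  k <- length(varpar)
  devfun(varpar[-k])
  varpar[k]^2 * as.matrix(environment(devfun)$pp$unsc())
}

fd_hessian_ <- function(f, x, rel = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x), 1e-2) * rel
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Precompute everything contrast tests need; NULL components signal failure.
sw_prepare_ <- function(fit) {
  out <- tryCatch({
    devfun <- make_devfun_(fit)
    est <- c(lme4::getME(fit, "theta"), sigma(fit))
    reml <- lme4::isREML(fit)
    f <- function(vp) devfun_vp_(vp, devfun, reml)
    H <- fd_hessian_(f, est)
    A <- 2 * solve(H)
    h <- pmax(abs(est), 1e-2) * 1e-4
    Vp <- Vm <- vector("list", length(est))
    for (j in seq_along(est)) {
      vp <- est; vp[j] <- est[j] + h[j]
      vm <- est; vm[j] <- est[j] - h[j]
      Vp[[j]] <- vcov_beta_at_(vp, devfun)
      Vm[[j]] <- vcov_beta_at_(vm, devfun)
    }
    V0 <- vcov_beta_at_(est, devfun)
    list(ok = TRUE, A = A, V0 = V0, Vp = Vp, Vm = Vm, h = h,
         beta = lme4::fixef(fit))
  }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
  if (isTRUE(out$ok) && any(!is.finite(out$A))) out <- list(ok = FALSE,
    msg = "non-finite variance-parameter covariance")
  out
}

# Satterthwaite df for a single contrast (numeric vector over fixef)
sw_df_contrast_ <- function(sw, cc) {
  f0 <- drop(crossprod(cc, sw$V0 %*% cc))
  g <- vapply(seq_along(sw$h), function(j)
    (drop(crossprod(cc, sw$Vp[[j]] %*% cc)) -
       drop(crossprod(cc, sw$Vm[[j]] %*% cc))) / (2 * sw$h[j]), 0)
  den <- drop(crossprod(g, sw$A %*% g))
  if (!is.finite(den) || den <= 0) return(Inf)
  2 * f0^2 / den
}

# Joint F test of L beta = 0 with Satterthwaite denominator df
sw_ftest_ <- function(sw, L) {
  q <- nrow(L)
  Lb <- drop(L %*% sw$beta)
  Q <- L %*% sw$V0 %*% t(L)
  Fstat <- drop(crossprod(Lb, solve(Q, Lb))) / q
  e <- eigen(Q, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  d <- e$values[keep]
  P <- e$vectors[, keep, drop = FALSE]
  nus <- vapply(seq_along(d), function(i)
    sw_df_contrast_(sw, drop(t(L) %*% P[, i])), 0)
  nus_ok <- nus[nus > 2]
  if (length(nus_ok) == 0L)
    return(list(F = Fstat, df1 = q, df2 = NA_real_))
  E <- sum(nus_ok / (nus_ok - 2))
  df2 <- if (E > q) 2 * E / (E - q) else Inf
  list(F = Fstat, df1 = q, df2 = df2)
}
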