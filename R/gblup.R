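#' Fit the single-trait genomic animal model by REML
#'
#' Fits `y = X beta + u + e` with `Var(u) = G sigma2_a`, `Var(e) = I sigma2_e`,
#' where G is a genomic relationship matrix and the fixed effects are
#' contemporary groups (breed x herd x sex x slaughter date in the design the
#' package targets). One record per animal.
#'
#' The model is rotated by the eigenvectors of G so both covariances are
#' diagonal; the restricted likelihood is then maximized exactly over the
#' heritability by Brent search (the total variance profiles out
#' analytically), followed by EM-REML refinement iterations until two
#' successive heritability iterates agree to `tol_sigfigs` significant
#' figures. The restricted log-likelihood is non-decreasing across the EM
#' refinements. GBLUP breeding values are the empirical BLUP at the converged
#' variances.
#'
#' @param formula model formula, phenotype on the left and fixed
#'   (contemporary-group) terms on the right, e.g. `wbsf ~ cg`.
#' @param data data frame with the model variables and an `animal_id` column
#'   matching `rownames(grm$G)`.
#' @param grm a [build_grm()] (optionally [regularize_grm()]) object.
#' @param tol_sigfigs significant figures of heritability agreement that
#'   declare convergence (default 4).
#' @param max_iter cap on EM refinement iterations.
#' @param drop_singletons drop contemporary-group levels with fewer than two
#'   records (their records are removed, with a warning).
#' @return Object of class `gblup` with components `sigma2_a`, `sigma2_e`,
#'   `h2`, `beta`, `u` (GBLUP breeding values, kg), `fitted`, `residuals`,
#'   `loglik`, `trace` (per-iteration h2 and restricted log-likelihood),
#'   `converged`, `boundary`, `n`, plus the eigen-decomposition of G reused
#'   by downstream generalized-least-squares tests.
#' @export
gblup <- function(formula, data, grm, tol_sigfigs = 4L, max_iter = 500L,
                  drop_singletons = TRUE) {
  stopifnot(inherits(grm, "grm"))
  data <- as.data.frame(data)
  if (is.null(data$animal_id)) stop("data must carry an animal_id column")
  ids <- as.character(data$animal_id)
  if (anyDuplicated(ids)) stop("one record per animal is required")
  if (!all(ids %in% rownames(grm$G)))
    stop("animals in data missing from the GRM")
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  # drop singleton fixed-effect cells
  if (drop_singletons) {
    fac <- vapply(mf[-1L], is.factor, logical(1)) |
      vapply(mf[-1L], is.character, logical(1))
    drop <- rep(FALSE, nrow(mf))
    for (v in names(mf[-1L])[fac]) {
      tab <- table(mf[[v]])
      bad <- names(tab)[tab < 2L]
      if (length(bad)) {
        warning("dropping ", length(bad), " singleton level(s) of ", v)
        drop <- drop | mf[[v]] %in% bad
      }
    }
    if (any(drop)) {
      mf <- mf[!drop, , drop = FALSE]
      data <- data[!drop, , drop = FALSE]
      ids <- ids[!drop]
    }
  }
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(mf), mf)
  # drop aliased columns so X has full column rank
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  n <- length(y); p <- ncol(X)
  G <- grm$G[ids, ids, drop = FALSE]
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-8 * max(d) || min(d) <= 1e-12)
    stop("G is not positive definite; apply regularize_grm() first")
  U <- eg$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  # restricted log-likelihood of (sigma2_a, sigma2_e) in the rotated model
  rll <- function(sa, se) {
    v <- sa * d + se
    vi <- 1 / v
    XtVX <- crossprod(Xt * vi, Xt)
    bh <- solve(XtVX, crossprod(Xt * vi, yt))
    r <- yt - Xt %*% bh
    -0.5 * (sum(log(v)) + determinant(XtVX, logarithm = TRUE)$modulus[1] +
              sum(r * vi * r))
  }
  # profile over total variance for a given h2
  prof <- function(h2) {
    v <- h2 * d + (1 - h2)
    vi <- 1 / v
    XtVX <- crossprod(Xt * vi, Xt)
    bh <- solve(XtVX, crossprod(Xt * vi, yt))
    r <- yt - Xt %*% bh
    ss <- sum(r * vi * r)
    sp <- ss / (n - p)
    list(ll = -0.5 * (sum(log(v)) + (n - p) * log(sp) +
                        determinant(XtVX, logarithm = TRUE)$modulus[1] + (n - p)),
         sp = sp)
  }
  opt <- stats::optimize(function(h) prof(h)$ll, c(1e-6, 1 - 1e-6),
                         maximum = TRUE, tol = 1e-9)
  h2 <- opt$maximum
  sp <- prof(h2)$sp
  sa <- h2 * sp; se <- (1 - h2) * sp

  # EM-REML refinement until h2 is stable to tol_sigfigs significant figures
  trace <- data.frame(iter = 0L, h2 = h2, loglik = rll(sa, se))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    v <- sa * d + se
    vi <- 1 / v
    XtVX <- crossprod(Xt * vi, Xt)
    XtVX_inv <- solve(XtVX)
    bh <- solve(XtVX, crossprod(Xt * vi, yt))
    r <- as.numeric(yt - Xt %*% bh)
    Py <- vi * r
    # tr(P D) and tr(P) with P = Vi - Vi X (X'ViX)^-1 X'Vi
    B <- Xt * vi
    trPD <- sum(d * vi) - sum((B %*% XtVX_inv) * (B * d))
    trP <- sum(vi) - sum((B %*% XtVX_inv) * B)
    ut <- sa * d * Py
    sa_new <- (sum(ut^2 / d) + sa * (n - sa * trPD)) / n
    eh <- se * Py
    se_new <- (sum(eh^2) + se * (n - se * trP)) / n
    sa_new <- max(sa_new, 1e-12)
    se_new <- max(se_new, 1e-12)
    h2_new <- sa_new / (sa_new + se_new)
    ll <- rll(sa_new, se_new)
    trace <- rbind(trace, data.frame(iter = it, h2 = h2_new, loglik = ll))
    same <- identical(signif(h2_new, tol_sigfigs), signif(h2, tol_sigfigs))
    sa <- sa_new; se <- se_new; h2 <- h2_new
    if (same) { converged <- TRUE; break }
  }
  boundary <- sa <= 1e-10
  # final BLUP at converged variances
  v <- sa * d + se
  vi <- 1 / v
  XtVX <- crossprod(Xt * vi, Xt)
  bh <- solve(XtVX, crossprod(Xt * vi, yt))
  r <- as.numeric(yt - Xt %*% bh)
  ut <- sa * d * (vi * r)
  u <- as.numeric(U %*% ut)
  beta <- stats::setNames(as.numeric(bh), colnames(X))
  names(u) <- ids
  fitted <- as.numeric(X %*% bh) + u
  structure(list(
    call = match.call(), formula = formula,
    sigma2_a = sa, sigma2_e = se, h2 = h2,
    beta = beta, u = u, fitted = stats::setNames(fitted, ids),
    residuals = stats::setNames(y - fitted, ids),
    y = stats::setNames(as.numeric(y), ids), X = X,
    loglik = rll(sa, se), trace = trace,
    converged = converged, boundary = boundary, iterations = nrow(trace) - 1L,
    n = n, rank_X = p, eigen = list(U = U, d = d), ids = ids,
    grm_scale = grm$scale, grm_epsilon = grm$epsilon
  ), class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat("Genomic animal model (REML / GBLUP)\n")
  cat(sprintf("  n = %d records, %d fixed-effect columns\n", x$n, x$rank_X))
  cat(sprintf("  sigma2_A = %.4f  sigma2_E = %.4f  h2 = %.4f%s\n",
              x$sigma2_a, x$sigma2_e, x$h2,
              if (x$boundary) " (boundary)" else ""))
  cat(sprintf("  restricted logLik = %.3f after %d EM iteration(s)%s\n",
              x$loglik, x$iterations,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  out <- list(fit = object,
              u_summary = summary(object$u),
              resid_summary = summary(object$residuals),
              genetic_n = genetic_sample_size(object$n, object$h2))
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  genetic sample size N*sqrt(h2) = %.1f\n", x$genetic_n))
  cat("  GBLUP breeding values (kg):\n")
  print(x$u_summary)
  cat("  residuals (kg):\n")
  print(x$resid_summary)
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$beta

#' @export
fitted.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, ...) object$residuals

#' @export
logLik.gblup <- function(object, ...) {
  structure(object$loglik, df = 2L + object$rank_X, class = "logLik")
}

#' Predictions from a fitted genomic animal model
#'
#' @param object a [gblup()] fit.
#' @param what `"mu"` for fixed + genetic fitted values, `"bv"` for the GBLUP
#'   breeding values alone.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
predict.gblup <- function(object, what = c("mu", "bv"), ...) {
  what <- match.arg(what)
  if (what == "bv") object$u else object$fitted
}

#' @export
plot.gblup <- function(x, ...) {
  graphics::plot(x$trace$iter, x$trace$h2, type = "b", xlab = "EM iteration",
                 ylab = expression(h^2), main = "REML convergence", ...)
  invisible(x)
}

#' Simulate phenotypes from a fitted genomic animal model
#'
#' Draws `y* ~ N(X beta, G sigma2_a + I sigma2_e)` using the stored
#' eigen-decomposition of G.
#'
#' @param object a [gblup()] fit.
#' @param nsim number of replicate phenotype vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame, one column per replicate.
#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  mu <- as.numeric(object$X %*% object$beta)
  sdv <- sqrt(object$sigma2_a * object$eigen$d + object$sigma2_e)
  out <- replicate(nsim, mu + as.numeric(object$eigen$U %*% (stats::rnorm(n) * sdv)))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$ids
  out
}

#' Genetic sample size
#'
#' `N * sqrt(h2)`: the number of phenotypes multiplied by the square root of
#' the heritability, an estimate of the cumulative additive-genetic
#' information in a sample of N unrelated individuals. Reported rounded to
#' one decimal.
#'
#' @param n_phenotypes record count N.
#' @param h2 heritability in [0, 1].
#' @return `round(N * sqrt(h2), 1)`.
#' @export
genetic_sample_size <- function(n_phenotypes, h2) {
  stopifnot(all(h2 >= 0 & h2 <= 1), all(n_phenotypes >= 0))
  round(n_phenotypes * sqrt(h2), 1)
}
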