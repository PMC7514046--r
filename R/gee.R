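## Cumulative-logit marginal model with cluster-robust inference.
##
## The estimating equations are the cumulative-logit ML score under an
## independence working structure (a valid GEE); standard errors are
## cluster-robust (sandwich) over subjects, so the repeated-measures
## design (16 conditions per subject) is respected without modeling the
## within-subject association. Model: logit P(Y <= j | x) = theta_j - x'beta
## (larger linear predictor -> larger categories), the same convention as
## MASS::polr.

ordinal_loglik <- function(theta, beta, X, yidx, m) {
  eta <- drop(X %*% beta)
  up <- c(theta, Inf)[yidx]
  lo <- c(-Inf, theta)[yidx]
  p <- stats::plogis(up - eta) - stats::plogis(lo - eta)
  sum(log(pmax(p, 1e-300)))
}

## per-observation score in the (theta, beta) parametrization
ordinal_scores <- function(theta, beta, X, yidx, m) {
  eta <- drop(X %*% beta)
  up <- c(theta, Inf)[yidx]
  lo <- c(-Inf, theta)[yidx]
  Fu <- stats::plogis(up - eta); Fl <- stats::plogis(lo - eta)
  fu <- stats::dlogis(up - eta); fl <- stats::dlogis(lo - eta)
  p <- pmax(Fu - Fl, 1e-300)
  n <- length(eta)
  S <- matrix(0, n, m + ncol(X))
  for (j in seq_len(m)) {
    S[, j] <- (fu * (yidx == j) - fl * (yidx == j + 1)) / p
  }
  S[, m + seq_len(ncol(X))] <- -X * ((fu - fl) / p)
  S
}

#' Fit the ordinal cumulative-logit model with subject-clustered inference
#'
#' Fits `logit P(category <= j) = theta_j - x'beta` by maximum likelihood
#' (Fisher scoring via BFGS with analytic gradient) and computes
#' cluster-robust sandwich standard errors with subjects as clusters -
#' i.e. generalized-estimating-equation inference with an independence
#' working correlation. Reports per-term Wald tests (each factor, the
#' two-way interactions, the covariates) and qualitative direction
#' summaries (orderings of estimated effects).
#'
#' Unobserved categories are dropped (collapsed) before fitting, with the
#' level map recorded in the result.
#'
#' @param data bilaterally averaged cohort table (needs `category` plus the
#'   model variables)
#' @param formula model formula on the category; the default mirrors the
#'   full factorial analysis: main effects of facial type, jaw,
#'   interradicular site and insertion angle, all six two-way interactions,
#'   and the sex / mandibular-plane-angle / facial-height-index covariates
#' @param id name of the cluster (subject) identifier column
#' @param corstr working correlation structure; only `"independence"` is
#'   implemented
#' @return object of class `gee_result`: coefficient table, per-term Wald
#'   table, robust vcov, direction summaries
#' @export
fit_ordinal_gee <- function(data,
                            formula = category ~ facial_type * jaw +
                              facial_type * site + facial_type * angle +
                              jaw * site + jaw * angle + site * angle +
                              sex + mp_angle + fhi,
                            id = "subject_id",
                            corstr = "independence") {
  corstr <- match.arg(corstr)
  df <- as.data.frame(data)
  if (!id %in% names(df)) stop("cluster id column '", id, "' not found")
  if ("facial_type" %in% names(df))
    df$facial_type <- factor(df$facial_type,
                             levels = intersect(facial_groups(),
                                                unique(df$facial_type)))
  if ("angle" %in% names(df)) df$angle <- factor(df$angle)
  if ("jaw" %in% names(df)) df$jaw <- factor(df$jaw, levels = c("Mx", "Mn"))
  if ("site" %in% names(df)) df$site <- factor(df$site)
  if ("sex" %in% names(df)) df$sex <- factor(df$sex)

  vars <- unique(c(all.vars(formula), id))
  df <- df[stats::complete.cases(df[, vars, drop = FALSE]), , drop = FALSE]
  rownames(df) <- NULL
  mf <- stats::model.frame(formula, df)
  y <- stats::model.response(mf)
  lev <- sort(unique(y))
  if (length(lev) < 2) stop("response has fewer than 2 observed categories")
  yidx <- match(y, lev)
  m <- length(lev) - 1L
  mm <- stats::model.matrix(formula, mf)
  asgn <- attr(mm, "assign")
  X <- mm[, asgn != 0, drop = FALSE]
  asgn <- asgn[asgn != 0]
  xc <- colMeans(X)
  Xc <- sweep(X, 2, xc)
  p <- ncol(Xc)

  ## start values from marginal cumulative frequencies
  cum <- cumsum(tabulate(yidx, m + 1))[1:m] / length(yidx)
  th0 <- stats::qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
  par0 <- c(th0[1], log(pmax(diff(th0), 1e-3)), rep(0, p))

  unpack <- function(par) {
    theta <- par[1] + c(0, cumsum(exp(par[seq_len(m - 1) + 1])))
    if (m == 1) theta <- par[1]
    list(theta = theta, beta = par[m + seq_len(p)])
  }
  nll <- function(par) {
    u <- unpack(par)
    -ordinal_loglik(u$theta, u$beta, Xc, yidx, m)
  }
  grad <- function(par) {
    u <- unpack(par)
    S <- colSums(ordinal_scores(u$theta, u$beta, Xc, yidx, m))
    ## chain rule to the increment parametrization
    g <- numeric(length(par))
    g[1] <- sum(S[1:m])
    if (m > 1) for (l in 2:m)
      g[l] <- exp(par[l]) * sum(S[l:m])
    g[m + seq_len(p)] <- S[m + seq_len(p)]
    -g
  }
  fit <- stats::optim(par0, nll, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-11))
  for (restart in 1:3) {
    if (fit$convergence == 0) break
    fit <- stats::optim(fit$par, nll, grad, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-11))
  }
  u <- unpack(fit$par)
  converged <- fit$convergence == 0

  ## sandwich in the (theta, beta) parametrization
  S <- ordinal_scores(u$theta, u$beta, Xc, yidx, m)
  f_tb <- function(par) -ordinal_loglik(par[1:m], par[m + seq_len(p)],
                                        Xc, yidx, m)
  H <- stats::optimHess(c(u$theta, u$beta), f_tb)
  clusters <- df[[id]]
  Sc <- rowsum(S, clusters)
  K <- nrow(Sc)
  ## CR1 small-sample factor; with few clusters the raw sandwich is
  ## anticonservative
  meat <- crossprod(Sc) * K / max(K - 1, 1)
  bread <- tryCatch(solve(H), error = function(e) NULL)
  degenerate <- is.null(bread)
  if (degenerate) {
    warning("observed information is singular (separation or empty cells); ",
            "robust inference unavailable")
    V <- matrix(NA_real_, m + p, m + p)
  } else {
    V <- bread %*% meat %*% bread
  }
  bV <- V[m + seq_len(p), m + seq_len(p), drop = FALSE]
  se <- sqrt(pmax(diag(bV), 0))
  z <- u$beta / se
  ## t / F references with cluster-based degrees of freedom: the usual
  ## normal/chi-square reference is anticonservative with few clusters
  coef_tab <- data.frame(term = colnames(Xc), estimate = u$beta,
                         robust_se = se, z = z,
                         p = 2 * stats::pt(-abs(z), df = max(K - 1, 1)),
                         stringsAsFactors = FALSE)

  term_labels <- attr(stats::terms(formula), "term.labels")
  term_tab <- do.call(rbind, lapply(seq_along(term_labels), function(k) {
    ix <- which(asgn == k)
    w <- if (degenerate || !length(ix)) NA_real_ else {
      Vi <- tryCatch(solve(bV[ix, ix, drop = FALSE]), error = function(e) NULL)
      if (is.null(Vi)) NA_real_
      else drop(t(u$beta[ix]) %*% Vi %*% u$beta[ix])
    }
    df1 <- length(ix)
    df2 <- max(K - df1, 1)
    data.frame(term = term_labels[k], df = df1, wald = w,
               p = if (is.na(w)) NA_real_
                   else stats::pf(w / df1, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))

  res <- structure(
    list(coefficients = coef_tab, terms = term_tab,
         zeta = u$theta + sum(xc * u$beta), vcov = V, levels = lev,
         corstr = corstr, n_clusters = K, n_obs = nrow(Xc),
         converged = converged, degenerate = degenerate,
         logLik = -fit$value, center = xc),
    class = "gee_result")
  eta <- drop(Xc %*% u$beta)
  res$directions <- tryCatch(gee_directions(res, df, eta),
                             error = function(e) NULL)
  res
}

## qualitative effect orderings: marginal means of the fitted linear
## predictor (larger eta = larger ordinal category) over observed rows
gee_directions <- function(res, df, eta) {
  ord <- function(sub, var) {
    m <- tapply(eta[sub], df[[var]][sub], mean)
    paste(names(sort(m, decreasing = TRUE)), collapse = " > ")
  }
  all_rows <- rep(TRUE, nrow(df))
  out <- list()
  if (all(c("facial_type", "jaw") %in% names(df))) {
    for (jaw in levels(df$jaw))
      out[[paste0("facial_type_", jaw)]] <- ord(df$jaw == jaw, "facial_type")
  }
  for (v in intersect(c("jaw", "site", "angle"), names(df)))
    out[[v]] <- ord(all_rows, v)
  out
}

#' @export
print.gee_result <- function(x, ...) {
  cat(sprintf("Ordinal cumulative-logit model, %s working correlation\n",
              x$corstr))
  cat(sprintf("%d observations in %d subject clusters; categories: %s\n",
              x$n_obs, x$n_clusters, paste(x$levels, collapse = " ")))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  if (x$degenerate) cat("WARNING: degenerate fit (separation/empty cells)\n")
  tt <- x$terms
  tt$wald <- round(tt$wald, 2)
  tt$p <- signif(tt$p, 3)
  print(tt, row.names = FALSE)
  if (!is.null(x$directions)) {
    cat("directions:\n")
    for (nm in names(x$directions))
      cat(sprintf("  %s: %s\n", nm, x$directions[[nm]]))
  }
  invisible(x)
}
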