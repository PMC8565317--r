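# Stage 2: robust within-arc gradient regression and the age interaction
# model. Reported fits use MASS::rlm (Huber psi, conventional k = 1.345,
# MAD residual scale); a vectorized IRLS implementing the same estimator
# serves the permutation null, where tens of thousands of refits are needed.

# Closed-form simple OLS with normal-theory inference.
.ols_summary <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  sxy <- sum((x - xb) * (y - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  se <- if (n > 2) sqrt(sum(res^2) / (n - 2) / sxx) else NA_real_
  list(intercept = intercept, slope = slope, se = se, residuals = res, n = n)
}

.p_from_t <- function(est, se, df = Inf) {
  if (is.na(se)) return(NA_real_)
  if (se == 0) return(if (est == 0) 1 else 0)
  t <- est / se
  if (is.finite(df)) 2 * stats::pt(-abs(t), df) else 2 * stats::pnorm(-abs(t))
}

#' Vectorized Huber IRLS slopes for many response columns
#'
#' Fits `y ~ x` by iteratively reweighted least squares with Huber weights
#' (`min(1, k/|u|)` on residuals standardized by the MAD/0.6745 scale,
#' re-estimated each iteration from an OLS start) independently to each
#' column of `Y`. This is the same M-estimator as `MASS::rlm(psi =
#' psi.huber, scale.est = "MAD")`, specialized to a single regressor so that
#' permutation replicates can all be fit at once. Columns whose residual MAD
#' collapses to zero (e.g. an exact fit) are frozen at their current, then
#' exact, solution.
#'
#' @param x Regressor vector (bin indices).
#' @param Y Numeric matrix, `length(x)` rows; one fit per column.
#' @param k Huber tuning constant on standardized residuals.
#' @param maxit,tol Iteration controls.
#' @return List with numeric vectors `slope` and `intercept` (one entry per
#'   column) and `iterations`.
#' @export
huber_slope_matrix <- function(x, Y, k = 1.345, maxit = 60, tol = 1e-9) {
  Y <- as.matrix(Y)
  n <- length(x)
  if (nrow(Y) != n) stop("nrow(Y) must equal length(x)")
  if (n < 3L) stop("need at least 3 points")
  m <- ncol(Y)
  xb <- mean(x)
  xc <- x - xb
  sxx <- sum(xc^2)
  slope <- as.vector(crossprod(xc, Y)) / sxx
  intercept <- colMeans(Y) - slope * xb
  yfloor <- pmax(apply(abs(Y), 2, max), .Machine$double.xmin)
  # column medians via one radix sort of (column, value) pairs
  colmed <- function(M) {
    nr <- nrow(M)
    o <- order(rep.int(seq_len(ncol(M)), rep.int(nr, ncol(M))), M)
    S <- matrix(M[o], nr)
    if (nr %% 2L) S[(nr + 1L) %/% 2L, ] else (S[nr %/% 2L, ] +
                                                S[nr %/% 2L + 1L, ]) / 2
  }
  active <- seq_len(m)
  Ya <- Y
  sl <- slope
  ic <- intercept
  fl <- yfloor
  it <- 0L
  while (it < maxit && length(active)) {
    it <- it + 1L
    R <- abs(Ya - tcrossprod(x, sl) - rep(ic, each = n))
    s <- colmed(R) / 0.6745
    degen <- s <= fl * 1e-14
    s[degen] <- Inf
    W <- k * rep(s, each = n) / pmax(R, .Machine$double.xmin)
    W[W > 1] <- 1
    Wx <- W * x
    sw <- colSums(W)
    swx <- colSums(Wx)
    swx2 <- colSums(Wx * x)
    swy <- colSums(W * Ya)
    swxy <- colSums(Wx * Ya)
    ns <- (sw * swxy - swx * swy) / (sw * swx2 - swx^2)
    ni <- (swy - ns * swx) / sw
    ns[degen] <- sl[degen]  # zero robust scale: freeze at current solution
    ni[degen] <- ic[degen]
    move <- sqrt((ns - sl)^2 + (ni - ic)^2)
    done <- degen | move <= tol * pmax(sqrt(sl^2 + ic^2), fl * 1e-6)
    sl <- ns
    ic <- ni
    slope[active] <- sl
    intercept[active] <- ic
    if (any(done)) {
      keep <- !done
      if (!any(keep)) break
      active <- active[keep]
      Ya <- Ya[, keep, drop = FALSE]
      sl <- sl[keep]
      ic <- ic[keep]
      fl <- fl[keep]
    }
  }
  list(slope = slope, intercept = intercept, iterations = it)
}

#' Robust gradient fit of binned frequency within an arc
#'
#' Fits frequency against bin index over the arc's non-missing bins with a
#' Huber M-estimator (`MASS::rlm`, `psi.huber`, `k = 1.345`, MAD scale) and
#' reports the slope per bin, its asymptotic standard error, and a two-sided
#' normal-theory p-value for slope != 0. On data the robust fit cannot
#' handle — an (near-)exact linear fit, a degenerate robust scale, or
#' IRLS non-convergence — it falls back to ordinary least squares, never
#' silently: non-convergence raises a warning; the degenerate cases are the
#' ones where the two estimators coincide anyway.
#'
#' @param table A [binned_frequency()] table filtered to one class (or pass
#'   `class` to filter here).
#' @param arc_bins Integer vector of bin indices forming the arc, e.g.
#'   `arc_bin_range(mouse_mt_arcs(), "major")`.
#' @param estimator `"huber"` (default) or `"ols"`.
#' @param k Huber tuning constant.
#' @param response Response column, default `"frequency"`.
#' @param class Optional class label to filter `table` by.
#' @param arc Optional arc label stored in the result.
#' @return An object of class `arc_fit`: list with `class`, `arc`, `slope`,
#'   `slope_se`, `p_value`, `n_bins`, `intercept`, `estimator`, `converged`.
#' @export
fit_arc_gradient <- function(table, arc_bins,
                             estimator = c("huber", "ols"), k = 1.345,
                             response = "frequency", class = NULL,
                             arc = NULL) {
  estimator <- match.arg(estimator)
  sub <- table
  if ("class" %in% names(sub)) {
    if (!is.null(class)) sub <- sub[sub$class == class, , drop = FALSE]
    cls <- unique(sub$class)
    if (length(cls) > 1L) stop("filter the table to a single class")
    class <- cls
  }
  sub <- sub[sub$bin %in% arc_bins, , drop = FALSE]
  y <- sub[[response]]
  x <- sub$bin
  ok <- is.finite(y)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3L) {
    stop("insufficient data: fewer than 3 usable bins in the arc")
  }
  ols <- .ols_summary(x, y)
  ylev <- max(abs(y), .Machine$double.xmin)
  clean <- max(abs(ols$residuals)) <= 1e-10 * ylev ||
    stats::median(abs(ols$residuals)) == 0
  converged <- TRUE
  used <- estimator
  if (estimator == "ols" || clean) {
    slope <- ols$slope; se <- ols$se; intercept <- ols$intercept
    p <- .p_from_t(slope, se, df = length(y) - 2)
    if (clean && estimator == "huber") used <- "huber (ols limit)"
  } else {
    fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = k,
                     scale.est = "MAD", maxit = 200, acc = 1e-8)
    if (!fit$converged) {
      warning("robust fit did not converge; falling back to OLS")
      converged <- FALSE
      used <- "ols (huber fallback)"
      slope <- ols$slope; se <- ols$se; intercept <- ols$intercept
      p <- .p_from_t(slope, se, df = length(y) - 2)
    } else {
      cf <- summary(fit)$coefficients
      slope <- cf["x", "Value"]
      se <- cf["x", "Std. Error"]
      intercept <- cf["(Intercept)", "Value"]
      p <- .p_from_t(slope, se)
    }
  }
  structure(list(class = class, arc = arc, slope = unname(slope),
                 slope_se = unname(se), p_value = unname(p),
                 n_bins = length(y), intercept = unname(intercept),
                 estimator = used, k = k, converged = converged),
            class = "arc_fit")
}

#' @export
print.arc_fit <- function(x, ...) {
  cat(sprintf("<arc_fit>%s%s slope = %.4g +/- %.4g per bin, p = %.3g (n = %d, %s)\n",
              if (is.null(x$class)) "" else paste0(" ", x$class),
              if (is.null(x$arc)) "" else paste0(" [", x$arc, "]"),
              x$slope, x$slope_se, x$p_value, x$n_bins, x$estimator))
  invisible(x)
}

#' Convert a per-bin slope to a per-bp slope
#' @param fit An `arc_fit`.
#' @param bin_size Bin width in bp.
#' @return Slope per bp (clearly a convenience rescaling of the per-bin
#'   estimate, not a refit).
#' @export
slope_per_bp <- function(fit, bin_size) fit$slope / bin_size

#' Age-by-position interaction model
#'
#' Fits `Y = alpha + beta_bin * bin + beta_age * age + beta_binxage *
#' (bin * age)` over the arc, with age coded 0 (young) / 1 (old), using the
#' same Huber M-estimator as [fit_arc_gradient()]. `beta_binxage` estimates
#' the old-minus-young slope difference — the aging-driven steepening of the
#' gradient.
#'
#' @param table_young,table_old [binned_frequency()] tables for the two
#'   cohorts on the same binning (filtered to one class, or pass `class`).
#' @param arc_bins Integer vector of arc bin indices.
#' @param estimator,k,response,class As in [fit_arc_gradient()].
#' @return An object of class `interaction_fit` with a `coefficients`
#'   `data.frame` (terms `alpha`, `beta_bin`, `beta_age`, `beta_binxage`;
#'   columns `estimate`, `se`, `p_value`), `age_coding`, `estimator`,
#'   `converged`, `n`.
#' @export
fit_age_interaction <- function(table_young, table_old, arc_bins,
                                estimator = c("huber", "ols"), k = 1.345,
                                response = "frequency", class = NULL) {
  estimator <- match.arg(estimator)
  pick <- function(tab) {
    if ("class" %in% names(tab)) {
      if (!is.null(class)) tab <- tab[tab$class == class, , drop = FALSE]
      if (length(unique(tab$class)) > 1L) {
        stop("filter the tables to a single class")
      }
    }
    tab[tab$bin %in% arc_bins, , drop = FALSE]
  }
  ty <- pick(table_young)
  to <- pick(table_old)
  if (!identical(sort(ty$bin), sort(to$bin))) {
    stop("young and old tables use different bin schemes")
  }
  df <- rbind(
    data.frame(y = ty[[response]], bin = ty$bin, age = 0),
    data.frame(y = to[[response]], bin = to$bin, age = 1)
  )
  df <- df[is.finite(df$y), , drop = FALSE]
  if (sum(df$age == 0) < 3L || sum(df$age == 1) < 3L) {
    stop("insufficient data: need >= 3 usable bins per age group")
  }
  fit0 <- stats::lm(y ~ bin * age, data = df)
  res0 <- stats::residuals(fit0)
  ylev <- max(abs(df$y), .Machine$double.xmin)
  clean <- max(abs(res0)) <= 1e-10 * ylev ||
    stats::median(abs(res0)) == 0
  converged <- TRUE
  used <- estimator
  if (estimator == "ols" || clean) {
    sm <- suppressWarnings(summary(fit0))$coefficients
    est <- sm[, "Estimate"]
    se <- sm[, "Std. Error"]
    dfree <- fit0$df.residual
    p <- vapply(seq_along(est), function(i) .p_from_t(est[i], se[i], dfree),
                numeric(1))
    if (clean && estimator == "huber") used <- "huber (ols limit)"
  } else {
    fit <- MASS::rlm(y ~ bin * age, data = df, psi = MASS::psi.huber, k = k,
                     scale.est = "MAD", maxit = 200, acc = 1e-8)
    if (!fit$converged) {
      warning("robust interaction fit did not converge; falling back to OLS")
      converged <- FALSE
      used <- "ols (huber fallback)"
      sm <- suppressWarnings(summary(fit0))$coefficients
      est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
      dfree <- fit0$df.residual
      p <- vapply(seq_along(est), function(i) .p_from_t(est[i], se[i], dfree),
                  numeric(1))
    } else {
      sm <- summary(fit)$coefficients
      est <- sm[, "Value"]; se <- sm[, "Std. Error"]
      p <- vapply(seq_along(est), function(i) .p_from_t(est[i], se[i]),
                  numeric(1))
    }
  }
  terms <- c("(Intercept)" = "alpha", "bin" = "beta_bin",
             "age" = "beta_age", "bin:age" = "beta_binxage")
  ord <- match(names(terms), names(est))
  coefs <- data.frame(term = unname(terms), estimate = unname(est[ord]),
                      se = unname(se[ord]), p_value = unname(p[ord]))
  structure(list(coefficients = coefs, age_coding = "young = 0, old = 1",
                 estimator = used, k = k, converged = converged,
                 n = nrow(df), class = class),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("<interaction_fit>", if (is.null(x$class)) "" else x$class,
      "(", x$age_coding, ";", x$estimator, ")\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
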