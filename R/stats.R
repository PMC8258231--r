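# Statistical layer: ordinary and segmented linear models with nested-model
# F comparison, and the log-linear extinction-risk models fitted to binned
# survey output.

#' Ordinary least-squares fit with the package's reporting conventions
#'
#' Fits `y ~ x` and reports coefficients with standard errors, the adjusted
#' R-squared, the model F statistic, residual degrees of freedom and the
#' overall p-value.
#'
#' @param x,y Numeric vectors (>= 3 points; `x` must vary).
#' @return A `linear_fit` object.
#' @export
#' @examples
#' f <- fit_linear(1:10, 2 * (1:10) + 1)
#' f$adj_r_squared  # 1
fit_linear <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite points", call. = FALSE)
  if (diff(range(x)) == 0) stop("'x' is constant", call. = FALSE)
  model <- lm(y ~ x)
  new_linear_fit(model)
}

new_linear_fit <- function(model, breakpoints = NULL, psi_se = NULL,
                           comparison = NULL, slopes = NULL) {
  sm <- summary(model)
  fstat <- sm$fstatistic
  out <- list(
    coefficients = cbind(estimate = coef(model),
                         se = sm$coefficients[, "Std. Error"]),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(fstat[1]),
    df = model$df.residual,
    p_value = if (!is.null(fstat))
      unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
    else NA_real_,
    rss = sum(model$residuals^2),
    n = length(model$residuals),
    model = model
  )
  if (!is.null(breakpoints)) {
    out$breakpoints <- breakpoints
    out$breakpoint_se <- psi_se
    out$slopes <- slopes
    out$comparison <- comparison
    class(out) <- c("segmented_fit", "linear_fit")
  } else {
    class(out) <- "linear_fit"
  }
  out
}

#' @export
print.linear_fit <- function(x, ...) {
  if (inherits(x, "segmented_fit")) {
    cat(sprintf("Segmented linear fit: %d breakpoint(s)\n",
                length(x$breakpoints)))
    cat("  breakpoints:",
        paste(sprintf("%.4g +/- %.3g", x$breakpoints, x$breakpoint_se),
              collapse = ", "), "\n")
    cat("  segment slopes:", paste(sprintf("%.4g", x$slopes), collapse = ", "),
        "\n")
  } else {
    cat("Linear fit\n")
    cat(sprintf("  slope %.6g +/- %.3g\n", x$coefficients["x", "estimate"],
                x$coefficients["x", "se"]))
  }
  cat(sprintf("  adj R^2 = %.4f, F = %.4g, df = %d, p = %.3g\n",
              x$adj_r_squared, x$f_statistic, x$df, x$p_value))
  if (!is.null(x$comparison))
    cat(sprintf("  vs %d-breakpoint model: F = %.4g, ddf = %d, p = %.3g\n",
                length(x$breakpoints) - 1, x$comparison$F,
                x$comparison$ddf, x$comparison$p))
  invisible(x)
}

# design matrix pieces for a set of breakpoints
.seg_terms <- function(x, psi) {
  U <- vapply(psi, function(p) pmax(x - p, 0), numeric(length(x)))
  V <- vapply(psi, function(p) as.numeric(x > p), numeric(length(x)))
  list(U = U, V = V)
}

#' Continuous piecewise-linear (segmented) regression
#'
#' Fits a continuous piecewise-linear model with `n_breakpoints` interior
#' breakpoints by iterative linearization: at each step the hinge terms are
#' linearized around the current breakpoints, the working linear model is
#' refitted, and each breakpoint is moved by the ratio of its gap
#' coefficient to its slope-change coefficient. Starting values come from
#' quantiles of `x`, with a small set of deterministic restarts if the
#' iteration stalls. Breakpoint standard errors follow from the
#' linearization (`se(gap)/|slope change|`). The returned object includes a
#' nested-model F comparison against the model with one fewer breakpoint.
#'
#' @param x,y Numeric vectors.
#' @param n_breakpoints Number of interior breakpoints (0 gives
#'   [fit_linear()]).
#' @param max_iter,tol Iteration controls.
#' @return A `segmented_fit` (also a `linear_fit`) with `breakpoints`,
#'   `breakpoint_se`, per-segment `slopes` and `comparison` (F, ddf, p
#'   against the reduced model).
#' @export
#' @examples
#' x <- seq(0, 10, by = 0.1)
#' y <- ifelse(x < 4, x, 4 + 3 * (x - 4))
#' fit_segmented(x, y, 1)$breakpoints  # ~4
fit_segmented <- function(x, y, n_breakpoints = 1, max_iter = 60,
                          tol = 1e-8) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (n_breakpoints == 0) return(fit_linear(x, y))
  k <- as.integer(n_breakpoints)
  if (length(x) < 2 * (k + 1) + 2)
    stop("too few points for ", k, " breakpoint(s)", call. = FALSE)
  rng <- range(x)
  span <- diff(rng)
  if (span == 0) stop("'x' is constant", call. = FALSE)
  lo <- rng[1] + 0.02 * span
  hi <- rng[2] - 0.02 * span

  starts <- list(quantile(x, probs = seq_len(k) / (k + 1), names = FALSE))
  # deterministic alternative starts to escape poor initializations
  for (sh in c(-0.15, 0.15))
    starts[[length(starts) + 1]] <-
      pmin(hi, pmax(lo, quantile(x, probs = seq_len(k) / (k + 1) + sh,
                                 names = FALSE)))

  best <- NULL
  for (psi0 in starts) {
    res <- try(.seg_iterate(x, y, sort(psi0), lo, hi, max_iter, tol),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$rss < best$rss) best <- res
  }
  if (is.null(best))
    stop("segmented fit failed to converge from all starts", call. = FALSE)

  psi <- best$psi
  # final model without gap terms
  st <- .seg_terms(x, psi)
  U <- st$U
  dat <- data.frame(y = y, x = x)
  for (j in seq_len(k)) dat[[paste0("U", j)]] <- U[, j]
  fml <- stats::as.formula(paste("y ~ x +",
                                 paste0("U", seq_len(k), collapse = " + ")))
  model <- lm(fml, data = dat)
  beta <- coef(model)[paste0("U", seq_len(k))]
  slopes <- cumsum(c(coef(model)[["x"]], beta))
  reduced <- if (k == 1) fit_linear(x, y) else fit_segmented(x, y, k - 1,
                                                            max_iter, tol)
  fit <- new_linear_fit(model, breakpoints = unname(psi),
                        psi_se = unname(best$psi_se),
                        slopes = unname(slopes))
  fit$comparison <- compare_nested(fit, reduced)
  fit
}

.seg_iterate <- function(x, y, psi, lo, hi, max_iter, tol) {
  k <- length(psi)
  span <- hi - lo
  last_fit <- NULL
  for (it in seq_len(max_iter)) {
    st <- .seg_terms(x, psi)
    dat <- data.frame(y = y, x = x)
    for (j in seq_len(k)) {
      dat[[paste0("U", j)]] <- st$U[, j]
      dat[[paste0("V", j)]] <- st$V[, j]
    }
    fml <- stats::as.formula(paste(
      "y ~ x +", paste0("U", seq_len(k), collapse = " + "), "+",
      paste0("V", seq_len(k), collapse = " + ")))
    fit <- lm(fml, data = dat)
    cf <- coef(fit)
    beta <- cf[paste0("U", seq_len(k))]
    gamma <- cf[paste0("V", seq_len(k))]
    if (any(!is.finite(beta)) || any(!is.finite(gamma)) ||
        any(abs(beta) < 1e-12))
      stop("degenerate segmented design")
    last_fit <- fit
    step <- gamma / beta
    psi_new <- sort(pmin(hi, pmax(lo, psi - step)))
    moved <- max(abs(psi_new - psi)) / span
    psi <- psi_new
    if (max(abs(gamma)) < tol * (1 + stats::sd(y)) || moved < 1e-10) break
  }
  # breakpoint SE from the linearization at the solution
  st <- .seg_terms(x, psi)
  dat <- data.frame(y = y, x = x)
  for (j in seq_len(k)) {
    dat[[paste0("U", j)]] <- st$U[, j]
    dat[[paste0("V", j)]] <- st$V[, j]
  }
  fml <- stats::as.formula(paste(
    "y ~ x +", paste0("U", seq_len(k), collapse = " + "), "+",
    paste0("V", seq_len(k), collapse = " + ")))
  fit <- lm(fml, data = dat)
  beta <- coef(fit)[paste0("U", seq_len(k))]
  se_gamma <- sqrt(diag(vcov(fit)))[paste0("V", seq_len(k))]
  psi_se <- abs(se_gamma / beta)
  st2 <- .seg_terms(x, psi)
  res <- y - fitted(lm(y ~ x + st2$U))
  list(psi = psi, psi_se = psi_se, rss = sum(res^2))
}

#' Nested-model F comparison
#'
#' Compares a full model against a reduced model nested within it, on the
#' same data: `F = ((RSS_r - RSS_f) / ddf) / (RSS_f / df_f)` with `ddf` the
#' difference in residual degrees of freedom.
#'
#' @param full,reduced `linear_fit`/`segmented_fit` objects or `lm` models
#'   fitted to the same response.
#' @return A list with `F`, `ddf` and `p`.
#' @export
compare_nested <- function(full, reduced) {
  g <- function(m) {
    if (inherits(m, "linear_fit")) list(rss = m$rss, df = m$df, n = m$n)
    else if (inherits(m, "lm")) list(rss = sum(m$residuals^2),
                                     df = m$df.residual,
                                     n = length(m$residuals))
    else stop("unsupported model object", call. = FALSE)
  }
  f <- g(full); r <- g(reduced)
  if (f$n != r$n)
    stop("models must be fitted to the same data", call. = FALSE)
  ddf <- r$df - f$df
  if (ddf < 0) stop("'reduced' must be nested in 'full'", call. = FALSE)
  if (ddf == 0 || f$df <= 0) {
    Fv <- 0
    p <- 1
  } else {
    Fv <- max(0, (r$rss - f$rss) / ddf) / (f$rss / f$df)
    p <- pf(Fv, ddf, f$df, lower.tail = FALSE)
  }
  list(F = Fv, ddf = ddf, p = p)
}

#' Log-linear extinction-risk models
#'
#' Fits the three extinction-risk models to a binned extinction survey
#' (see [extinction_survey()]): (A) `log10(mean extinction probability)`
#' against the absolute size-class midpoint, (B) against the relative size
#' (midpoint divided by energy level), and (C) model B with the absolute
#' midpoint added. Classes with zero observed extinction probability are
#' dropped before the log transform. The combined model is compared against
#' the relative model by a nested F test.
#'
#' @param survey A data frame with columns `class_mid`, `energy`,
#'   `mean_extinction` (and optionally `rel_mid`), one row per size class
#'   per energy level — the `by_class_energy` table of
#'   [extinction_survey()].
#' @return A list of class `extinction_models` with elements `absolute`,
#'   `relative`, `combined` (fits), and `comparison` (combined vs relative).
#' @export
fit_extinction_models <- function(survey) {
  req <- c("class_mid", "energy", "mean_extinction")
  if (!all(req %in% names(survey)))
    stop("survey must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  keep <- is.finite(survey$mean_extinction) & survey$mean_extinction > 0
  s <- survey[keep, , drop = FALSE]
  if (nrow(s) < 3)
    stop("fewer than 3 usable (non-zero) size classes", call. = FALSE)
  ly <- log10(s$mean_extinction)
  rel <- if ("rel_mid" %in% names(s)) s$rel_mid else s$class_mid / s$energy
  absolute <- fit_linear(s$class_mid, ly)
  relative <- fit_linear(rel, ly)
  dat <- data.frame(ly = ly, rel = rel, abs = s$class_mid)
  combined_lm <- lm(ly ~ rel + abs, data = dat)
  combined <- new_linear_fit(combined_lm)
  out <- list(absolute = absolute, relative = relative, combined = combined,
              comparison = compare_nested(combined, relative))
  class(out) <- "extinction_models"
  out
}

#' @export
print.extinction_models <- function(x, ...) {
  cat("Log-linear extinction-risk models (binned survey)\n")
  cat(sprintf("  absolute size:        adj R^2 = %.4f\n",
              x$absolute$adj_r_squared))
  cat(sprintf("  relative size:        adj R^2 = %.4f\n",
              x$relative$adj_r_squared))
  cat(sprintf("  relative + absolute:  adj R^2 = %.4f\n",
              x$combined$adj_r_squared))
  cat(sprintf("  combined vs relative: F = %.4g, ddf = %d, p = %.3g\n",
              x$comparison$F, x$comparison$ddf, x$comparison$p))
  invisible(x)
}
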