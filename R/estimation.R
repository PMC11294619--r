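#' Unpaired Student t-test (pooled variance)
#'
#' Two-sample two-tailed Student t-test with pooled variance and
#' df = n_a + n_b - 2, the convention behind the reported group
#' comparisons; the t statistic is mean(a) - mean(b) over its pooled
#' standard error. A Welch (unpooled) variant is available behind a flag.
#' With zero pooled variance and equal means the statistic is defined as
#' t = 0, p = 1; with unequal means it is infinite and an error is raised.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param welch Use the Welch unequal-variance test instead.
#' @return List: t, df, p (two-tailed), mean_a, mean_b.
#' @export
unpaired_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    }
    stop("zero pooled variance with unequal means: t statistic is infinite")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Bootstrapped mean difference with confidence interval
#'
#' Draws `n_resamples` bootstrap resamples with replacement within each
#' group and returns the resampled distribution of mean(test) -
#' mean(control) together with its percentile (default) or BCa confidence
#' interval — the effect-size estimate displayed in Gardner-Altman
#' estimation plots. Also carries the Student t-test of the same
#' comparison. Deterministic under a fixed seed.
#'
#' @param control,test Numeric samples, each of length >= 2.
#' At the very small group sizes typical of primate studies (n of 4-6 per
#' group), percentile and BCa intervals undercover (about 87 percent
#' empirical coverage at nominal 95); the studentized (bootstrap-t)
#' interval restores near-nominal coverage and is the method of choice
#' when calibrated coverage matters. The percentile method remains the
#' default because its resample distribution is the one displayed in
#' estimation graphics.
#'
#' @param n_resamples Number of bootstrap resamples; values below 1000 give
#'   unstable interval endpoints and trigger a warning.
#' @param ci Confidence level in percent (default 95).
#' @param method "percentile", "bca", or "studentized" (bootstrap-t).
#' @param seed Integer seed.
#' @return Object of class `group_comparison`: group labels, n, means, sds,
#'   t, p, mean_diff (test - control), ci_low, ci_high,
#'   resample_distribution, n_resamples, ci_level, method, seed, and the
#'   raw samples.
#' @export
bootstrap_mean_diff <- function(control, test, n_resamples = 5000L,
                                ci = 95,
                                method = c("percentile", "bca", "studentized"),
                                seed = 1L) {
  method <- match.arg(method)
  if (length(control) < 2L || length(test) < 2L) stop("each group needs n >= 2")
  n_resamples <- as.integer(n_resamples)
  if (n_resamples < 1L) stop("n_resamples must be >= 1")
  if (n_resamples < 1000L) {
    warning("n_resamples < 1000 gives unstable CI endpoints")
  }
  set.seed(as.integer(seed))
  nc <- length(control); nt <- length(test)
  mc <- matrix(control[sample.int(nc, nc * n_resamples, replace = TRUE)],
               nc, n_resamples)
  mt <- matrix(test[sample.int(nt, nt * n_resamples, replace = TRUE)],
               nt, n_resamples)
  diffs <- colMeans(mt) - colMeans(mc)
  observed <- mean(test) - mean(control)
  alpha <- (1 - ci / 100) / 2

  ci_lo_hi <- switch(method,
    percentile = unname(stats::quantile(diffs, c(alpha, 1 - alpha))),
    bca = bca_interval(control, test, diffs, observed, alpha),
    studentized = studentized_interval(control, test, mc, mt, diffs,
                                       observed, alpha))
  tt <- tryCatch(unpaired_t(test, control),
                 error = function(e) list(t = NA_real_, p = NA_real_))
  structure(
    list(groups = c("control", "test"), n = c(nc, nt),
         means = c(control = mean(control), test = mean(test)),
         sds = c(control = stats::sd(control), test = stats::sd(test)),
         t = tt$t, p = tt$p,
         mean_diff = observed,
         ci_low = ci_lo_hi[1L], ci_high = ci_lo_hi[2L],
         resample_distribution = diffs, n_resamples = n_resamples,
         ci_level = ci, method = method, seed = seed,
         control = control, test = test),
    class = "group_comparison")
}

# bootstrap-t interval: pivot each resampled difference by its own
# Welch-type standard error, then invert around the observed difference.
# Degenerate resamples (zero within-resample variance in both groups) give
# an infinite pivot and are dropped from the quantile computation.
studentized_interval <- function(control, test, mc, mt, diffs, observed,
                                 alpha) {
  col_sem2 <- function(m) {
    n <- nrow(m)
    (colMeans(m^2) - colMeans(m)^2) * n / (n - 1) / n
  }
  se_star <- sqrt(col_sem2(mt) + col_sem2(mc))
  tstar <- (diffs - observed) / se_star
  tstar <- tstar[is.finite(tstar)]
  if (length(tstar) == 0L) return(c(observed, observed))
  se_obs <- sqrt(stats::var(test) / length(test) +
                   stats::var(control) / length(control))
  q <- unname(stats::quantile(tstar, c(1 - alpha, alpha)))
  c(observed - q[1L] * se_obs, observed - q[2L] * se_obs)
}

# BCa interval for the two-sample mean difference: bias correction from the
# bootstrap distribution, acceleration from grouped jackknife influence
bca_interval <- function(control, test, diffs, observed, alpha) {
  if (stats::sd(diffs) == 0) return(c(observed, observed))
  z0 <- stats::qnorm((sum(diffs < observed) + sum(diffs == observed) / 2) /
                     length(diffs))
  jack <- c(
    vapply(seq_along(control), function(i) mean(test) - mean(control[-i]),
           numeric(1)),
    vapply(seq_along(test), function(i) mean(test[-i]) - mean(control),
           numeric(1)))
  u <- mean(jack) - jack
  a <- sum(u^3) / (6 * sum(u^2)^1.5)
  adj <- function(q) {
    z <- z0 + stats::qnorm(q)
    stats::pnorm(z0 + z / (1 - a * z))
  }
  unname(stats::quantile(diffs, c(adj(alpha), adj(1 - alpha))))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> mean diff (test - control) = %.4g, %g%% CI [%.4g, %.4g] (%s, %d resamples)\n  t = %.4g, p = %.4g; n = %d vs %d\n",
    x$mean_diff, x$ci_level, x$ci_low, x$ci_high, x$method, x$n_resamples,
    x$t, x$p, x$n[1L], x$n[2L]))
  invisible(x)
}

#' Control-referenced z-score profile
#'
#' Standardises every variable of a long measurement table against the
#' control group: z = (x - mean_control) / sd_control, using the sample
#' (n - 1) SD. Following the heat-map convention, the control group can be
#' collapsed to its mean — an all-zero row — while each test hemisphere
#' keeps its own row. Variables whose control SD is zero cannot be
#' standardised; they are dropped with a warning.
#'
#' @param table data.frame with columns group, hemisphere, variable, value.
#' @param control_label Value of `group` identifying controls.
#' @param collapse_control Represent controls as a single mean row
#'   (all-zero) instead of per-hemisphere rows.
#' @return Object of class `profile_matrix`: `z` (rows = observations,
#'   columns = variables), `variables`, `observations`, `dropped`
#'   (variables excluded for zero control SD).
#' @export
zscore_profile <- function(table, control_label = "control",
                           collapse_control = TRUE) {
  need <- c("group", "hemisphere", "variable", "value")
  if (!all(need %in% names(table))) {
    stop("table must have columns group, hemisphere, variable, value")
  }
  if (!any(table$group == control_label)) {
    stop(sprintf("no rows with control label '%s'", control_label))
  }
  vars <- unique(table$variable)
  dropped <- character(0)
  cols <- list()
  for (v in vars) {
    tv <- table[table$variable == v, ]
    ctrl <- tv$value[tv$group == control_label]
    if (length(ctrl) < 2L) stop(sprintf("variable '%s' has < 2 control observations", v))
    s <- stats::sd(ctrl)
    if (s == 0) {
      warning(sprintf("variable '%s' has zero control SD; dropped", v))
      dropped <- c(dropped, v)
      next
    }
    cols[[v]] <- list(mean = mean(ctrl), sd = s, data = tv)
  }
  vars <- setdiff(vars, dropped)
  if (length(vars) == 0L) stop("no variable with non-zero control SD")

  test_rows <- unique(table$hemisphere[table$group != control_label])
  obs <- if (collapse_control) c("control_mean", test_rows) else
    c(unique(table$hemisphere[table$group == control_label]), test_rows)
  z <- matrix(NA_real_, length(obs), length(vars),
              dimnames = list(obs, vars))
  for (v in vars) {
    cv <- cols[[v]]
    tv <- cv$data
    if (collapse_control) z["control_mean", v] <- 0
    for (h in intersect(obs, tv$hemisphere)) {
      z[h, v] <- (tv$value[tv$hemisphere == h][1L] - cv$mean) / cv$sd
    }
  }
  structure(list(z = z, variables = vars, observations = obs,
                 dropped = dropped, control_label = control_label),
            class = "profile_matrix")
}

#' Assemble the plot-data bundle for a Gardner-Altman estimation plot
#'
#' Packs everything the two-panel figure needs: raw per-group values with
#' mean +/- SD for the left panel, and for the right panel the bootstrap
#' resample distribution, the mean difference with its CI, and the axis
#' alignment (the zero of the difference axis sits at the control mean, so
#' the effect marker is horizontally aligned with the test-group mean).
#'
#' @param comparison A [bootstrap_mean_diff()] result.
#' @return List of class `gardner_altman_bundle`.
#' @export
export_gardner_altman <- function(comparison) {
  stopifnot(inherits(comparison, "group_comparison"))
  list_ <- list(
    raw = list(control = comparison$control, test = comparison$test),
    group_stats = data.frame(
      group = comparison$groups, n = comparison$n,
      mean = as.numeric(comparison$means), sd = as.numeric(comparison$sds)),
    mean_diff = comparison$mean_diff,
    ci_low = comparison$ci_low, ci_high = comparison$ci_high,
    ci_level = comparison$ci_level,
    resample_distribution = comparison$resample_distribution,
    n_resamples = comparison$n_resamples,
    diff_axis_origin = unname(comparison$means["control"]))
  class(list_) <- "gardner_altman_bundle"
  list_
}

#' Render a Gardner-Altman estimation plot
#'
#' Base-graphics two-panel figure: raw group scatter with mean +/- SD on
#' the left; the bootstrap distribution of the mean difference with its CI
#' on the right, difference axis anchored at the control mean.
#'
#' @param bundle An [export_gardner_altman()] bundle.
#' @param main Plot title.
#' @export
plot_gardner_altman <- function(bundle, main = "") {
  stopifnot(inherits(bundle, "gardner_altman_bundle"))
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  raw <- bundle$raw
  ylim <- range(unlist(raw))
  graphics::plot(NA, xlim = c(0.5, 2.5), ylim = ylim, xaxt = "n",
                 xlab = "", ylab = "value", main = main)
  graphics::axis(1, at = 1:2, labels = c("control", "test"))
  for (i in 1:2) {
    v <- raw[[i]]
    graphics::points(jitter(rep(i, length(v)), amount = 0.06), v, pch = 16,
                     col = c("grey20", "firebrick")[i])
    graphics::segments(i + 0.15, mean(v) - stats::sd(v),
                       i + 0.15, mean(v) + stats::sd(v))
    graphics::points(i + 0.15, mean(v), pch = 3)
  }
  d <- stats::density(bundle$resample_distribution)
  graphics::plot(d$y, d$x, type = "l", xlab = "density",
                 ylab = "mean difference", main = "effect size")
  graphics::abline(h = 0, lty = 3)
  graphics::segments(0, bundle$ci_low, 0, bundle$ci_high, lwd = 2)
  graphics::points(0, bundle$mean_diff, pch = 16)
  invisible(bundle)
}
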