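# Two-sample comparison layer: Student t and Cohen's d with confidence
# interval and conventional effect-size labels.

#' Two-sample t-test
#'
#' Default is the pooled-variance (Student) form; `variant = "welch"` uses
#' the Welch-Satterthwaite degrees of freedom. When both samples have zero
#' variance and equal means the statistic is undefined and is reported as
#' t = 0, p = 1.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param variant "pooled" (default) or "welch".
#' @return list with `t`, `p` (two-sided), `df`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop_fd("both samples need n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (dm == 0) return(list(t = 0, p = 1, df = na + nb - 2))
    return(list(t = sign(dm) * Inf, p = 0, df = na + nb - 2))
  }
  if (variant == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- dm / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Cohen's d with confidence interval and effect-size label
#'
#' Pooled-SD standardized mean difference
#' `d = (mean(a) - mean(b)) / s_pooled`, with a large-sample normal
#' confidence interval using
#' `SE = sqrt((na + nb)/(na * nb) + d^2 / (2 (na + nb)))`. A noncentral-t
#' interval is available via `method = "noncentral"`. Labels follow the
#' conventional cut points on |d|: below 0.2 negligible, then
#' small [0.2, 0.5), medium [0.5, 0.8), large at 0.8 and above.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param level confidence level (default 0.95).
#' @param method "normal" (default) or "noncentral".
#' @return list with `d`, `ci` (lo, hi), `label`, `se`.
#' @export
cohens_d_ci <- function(a, b, level = 0.95, method = c("normal", "noncentral")) {
  method <- match.arg(method)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop_fd("both samples need n >= 2")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  d <- if (sp == 0) 0 else (mean(a) - mean(b)) / sp
  se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb)))
  alpha <- 1 - level
  if (method == "normal") {
    z <- stats::qnorm(1 - alpha / 2)
    ci <- c(d - z * se, d + z * se)
  } else {
    # invert the noncentral-t distribution of the observed statistic
    scale <- sqrt(na * nb / (na + nb))
    tobs <- d * scale
    df <- na + nb - 2
    # pt() warns about reduced accuracy at large noncentrality; harmless here
    pnt <- function(q, ncp) suppressWarnings(stats::pt(q, df, ncp))
    lo <- tryCatch(stats::uniroot(function(ncp)
      pnt(tobs, ncp) - (1 - alpha / 2),
      interval = tobs + c(-10, 10) * max(1, se * scale))$root,
      error = function(e) NA_real_)
    hi <- tryCatch(stats::uniroot(function(ncp)
      pnt(tobs, ncp) - alpha / 2,
      interval = tobs + c(-10, 10) * max(1, se * scale))$root,
      error = function(e) NA_real_)
    ci <- c(lo, hi) / scale
  }
  ad <- abs(d)
  label <- if (ad < 0.2) "negligible" else if (ad < 0.5) "small"
    else if (ad < 0.8) "medium" else "large"
  list(d = d, ci = ci, label = label, se = se)
}

#' Compare one descriptor between two systems
#'
#' @param name descriptor name (for the report).
#' @param a,b per-frame values from the two systems.
#' @param variant passed to [two_sample_t()].
#' @return one-row data.frame: name, n_a, n_b, mean_a, mean_b, t, p, d,
#'   d_lo, d_hi, label.
#' @export
compare_descriptor <- function(name, a, b, variant = "pooled") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  tt <- two_sample_t(a, b, variant)
  dd <- cohens_d_ci(a, b)
  data.frame(name = name, n_a = length(a), n_b = length(b),
             mean_a = mean(a), mean_b = mean(b),
             t = tt$t, p = tt$p, d = dd$d,
             d_lo = dd$ci[1], d_hi = dd$ci[2], label = dd$label,
             stringsAsFactors = FALSE)
}
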