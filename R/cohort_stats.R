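#' Cohort-level statistics
#'
#' The downstream battery applied to slide-level summaries joined with
#' clinical covariates: two-group tests (Welch/pooled t, Mann-Whitney U),
#' multi-group tests (Kruskal-Wallis with Tukey HSD post-hoc),
#' Youden-index dichotomization, binary logistic regression and
#' proportional-odds ordinal regression. Note on vocabulary: the effect
#' size reported from the logistic models is an odds ratio; the column is
#' named `HR` because that is what this style of forest plot conventionally
#' prints, but no time-to-event model is involved.
#'
#' @name cohort_stats
NULL

#' Two-group comparison
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param method "t" (default Welch; `var_equal = TRUE` pools variances) or
#'   "mannwhitney" (normal approximation, tie-safe).
#' @param var_equal pool variances in the t-test.
#' @return list with `statistic`, `p` (two-sided), `method`.
#' @export
two_group_test <- function(a, b, method = c("t", "mannwhitney"),
                           var_equal = FALSE) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("two_group_test: each group needs n >= 2")
  if (method == "t") {
    if (stats::var(c(a, b)) == 0)
      return(list(statistic = 0, p = 1, method = "t"))
    ht <- stats::t.test(a, b, var.equal = var_equal)
    list(statistic = unname(ht$statistic), p = ht$p.value, method = "t")
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "mannwhitney")
  }
}

#' Multi-group comparison (Kruskal-Wallis, optional Tukey HSD)
#'
#' Kruskal-Wallis rank test with tie correction across >= 3 groups; with
#' `posthoc = TRUE` a Tukey HSD table of pairwise adjusted p-values
#' (computed on an ordinary one-way ANOVA fit) is attached.
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 2).
#' @param posthoc compute the Tukey HSD pairwise table.
#' @return list with `H`, `p` and (when requested) `tukey`, a data.frame
#'   with comparison, diff, lwr, upr, p_adj.
#' @export
multi_group_test <- function(groups, posthoc = FALSE) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("multi_group_test: needs >= 3 groups; use two_group_test() for 2")
  if (any(vapply(groups, function(g) sum(!is.na(g)), integer(1)) < 2L))
    stop("multi_group_test: each group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  out <- if (stats::var(v, na.rm = TRUE) == 0) {
    list(H = 0, p = 1)
  } else {
    kw <- stats::kruskal.test(v, g)
    list(H = unname(kw$statistic), p = kw$p.value)
  }
  if (posthoc) {
    tk <- stats::TukeyHSD(stats::aov(v ~ g))$g
    out$tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                            lwr = tk[, "lwr"], upr = tk[, "upr"],
                            p_adj = tk[, "p adj"], row.names = NULL)
  }
  out
}

#' Optimal dichotomization cutoff by the Youden index
#'
#' Scans every threshold interval (midpoints between consecutive distinct
#' scores, plus the two all-positive / all-negative extremes) under the rule
#' "positive if score >= cutoff" and returns the cutoff maximizing
#' J = sensitivity + specificity - 1; ties resolve to the smallest cutoff.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `J`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2L)
    stop("youden_cutoff: both classes must be present")
  s <- sort(unique(scores))
  cand <- if (length(s) >= 2L) (s[-length(s)] + s[-1]) / 2 else numeric(0)
  cand <- c(s[1] - 1, cand, s[length(s)] + 1)
  pos <- labels == 1L
  stats_at <- vapply(cand, function(cth) {
    pred <- scores >= cth
    c(mean(pred[pos]), mean(!pred[!pos]))
  }, numeric(2))
  J <- stats_at[1, ] + stats_at[2, ] - 1
  best <- which(J >= max(J) - 1e-12)[1]  # candidates ascend: first = smallest
  list(cutoff = cand[best], sensitivity = stats_at[1, best],
       specificity = stats_at[2, best], J = J[best])
}

#' Logistic regression effect estimates ("HR" odds ratios with 95% CI)
#'
#' Binary logistic fit of a 0/1 outcome on one or more predictors (jointly
#' when several are given). Each effect is reported as `HR = exp(coef)`
#' with a Wald interval `exp(coef +- z * SE)` and Wald p-value.
#'
#' `method = "ml"` (default) is the ordinary maximum-likelihood fit; under
#' complete or quasi-complete separation it flags the affected estimates
#' (infinite or zero HR, `NA` interval, a warning) rather than erroring.
#' `method = "firth"` is Firth's bias-reduced penalized likelihood, which
#' stays finite under separation; for a saturated 2x2 table it equals the
#' Haldane-corrected (add 0.5 to each cell) odds ratio, which is the
#' recommended estimator when in-sample cutoffs produce empty cells in
#' small cohorts.
#'
#' @param outcome 0/1 vector (both classes present).
#' @param predictors numeric vector, matrix or data.frame; no predictor may
#'   be constant.
#' @param conf_level confidence level for the Wald interval.
#' @param method "ml" or "firth".
#' @return data.frame of effect rows: `variable`, `cutoff` (NA here; filled
#'   by [forest_table()]), `HR`, `ci_low`, `ci_high`, `p`, `separation`.
#' @export
binary_logit_hr <- function(outcome, predictors, conf_level = 0.95,
                            method = c("ml", "firth")) {
  method <- match.arg(method)
  y <- as.integer(as.logical(outcome))
  if (length(unique(y)) < 2L)
    stop("binary_logit_hr: both outcome classes must be present")
  X <- as.data.frame(predictors)
  if (ncol(X) == 1L && is.null(colnames(predictors)) &&
      identical(names(X), "predictors")) names(X) <- "x"
  cons <- vapply(X, function(x) stats::var(as.numeric(x), na.rm = TRUE) == 0,
                 logical(1))
  if (any(cons))
    stop("binary_logit_hr: constant predictor(s): ",
         paste(names(X)[cons], collapse = ", "))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "firth") {
    ff <- fit_firth(y, as.matrix(X))
    co <- cbind(ff$beta[-1], ff$se[-1])
    est <- data.frame(variable = names(X), cutoff = NA_real_,
                      HR = exp(co[, 1]), ci_low = exp(co[, 1] - z * co[, 2]),
                      ci_high = exp(co[, 1] + z * co[, 2]),
                      p = 2 * stats::pnorm(-abs(co[, 1] / co[, 2])),
                      separation = FALSE, row.names = NULL)
    return(est)
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::summary.glm(fit)$coefficients[-1, , drop = FALSE]
  est <- data.frame(variable = rownames(co), cutoff = NA_real_,
                    HR = exp(co[, 1]), ci_low = exp(co[, 1] - z * co[, 2]),
                    ci_high = exp(co[, 1] + z * co[, 2]), p = co[, 4],
                    separation = FALSE, row.names = NULL)
  # IRLS can stop on the deviance criterion before glm's own
  # fitted-probability warning triggers, so detect diverging coefficients
  # directly as well (on the per-SD scale, so the check is scale-invariant)
  sdx <- apply(stats::model.matrix(fit)[, -1, drop = FALSE], 2, stats::sd)
  big <- abs(co[, 1]) * sdx > 10 | co[, 2] * sdx > 100
  if (sep || any(big)) {
    sep <- TRUE
    est$HR[big] <- ifelse(co[big, 1] > 0, Inf, 0)
    est$ci_low[big] <- NA_real_
    est$ci_high[big] <- NA_real_
    est$separation[big] <- TRUE
    warning("binary_logit_hr: possible complete separation; flagged ",
            "estimate(s) with infinite/zero HR (consider method = \"firth\")")
  }
  est
}

# Firth bias-reduced logistic regression: Newton iterations on the
# modified score U*(b) = X'(y - p + h*(0.5 - p)), h = diag of the hat
# matrix; SEs from the Fisher information at the solution
fit_firth <- function(y, X, maxit = 200, tol = 1e-10) {
  X1 <- cbind(`(Intercept)` = 1, X)
  q <- ncol(X1)
  beta <- rep(0, q)
  penll <- function(beta) {
    eta <- as.vector(X1 %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    I <- crossprod(X1 * w, X1)
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(I)$modulus
  }
  f <- penll(beta)
  Iinv <- NULL
  for (it in seq_len(maxit)) {
    eta <- as.vector(X1 %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    I <- crossprod(X1 * w, X1)
    Iinv <- tryCatch(solve(I), error = function(e)
      solve(I + diag(1e-8, q)))
    h <- rowSums((X1 %*% Iinv) * X1) * w
    U <- as.vector(crossprod(X1, y - p + h * (0.5 - p)))
    if (max(abs(U)) < tol) break
    delta <- as.vector(Iinv %*% U)
    lam <- 1
    repeat {
      f_new <- penll(beta + lam * delta)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    beta <- beta + lam * delta
    f <- f_new
  }
  list(beta = stats::setNames(as.vector(beta), colnames(X1)),
       se = sqrt(diag(Iinv)), vcov = Iinv,
       converged = max(abs(U)) < 1e-6)
}

# cumulative-logit (proportional odds) maximum likelihood:
# logit P(Y <= j | x) = zeta_j - x'beta. Newton iterations with analytic
# gradient and a numerically differentiated Hessian; converges to
# |gradient| < 1e-9 so small-model coefficients are exact to ~1e-8.
fit_prop_odds <- function(y, X) {
  K <- max(y)
  n <- length(y)
  p <- ncol(X)
  stopifnot(K >= 2L, n == nrow(X))
  nll <- function(th) {
    zeta <- th[seq_len(K - 1)]
    beta <- th[K - 1 + seq_len(p)]
    eta <- as.vector(X %*% beta)
    zlo <- c(-Inf, zeta)[y]
    zhi <- c(zeta, Inf)[y]
    pr <- stats::plogis(zhi - eta) - stats::plogis(zlo - eta)
    -sum(log(pmax(pr, 1e-300)))
  }
  gr <- function(th) {
    zeta <- th[seq_len(K - 1)]
    beta <- th[K - 1 + seq_len(p)]
    eta <- as.vector(X %*% beta)
    zlo <- c(-Inf, zeta)[y]
    zhi <- c(zeta, Inf)[y]
    fu <- stats::dlogis(zhi - eta)
    fl <- stats::dlogis(zlo - eta)
    pr <- pmax(stats::plogis(zhi - eta) - stats::plogis(zlo - eta), 1e-300)
    gz <- numeric(K - 1)
    for (j in seq_len(K - 1)) {
      gz[j] <- -(sum(fu[y == j] / pr[y == j]) -
                   sum(fl[y == j + 1L] / pr[y == j + 1L]))
    }
    gb <- as.vector(crossprod(X, (fu - fl) / pr))
    c(gz, gb)
  }
  cum <- cumsum(tabulate(y, K)) / n
  th <- c(stats::qlogis(pmin(pmax(cum[-K], 1e-3), 1 - 1e-3)), rep(0, p))
  f <- nll(th)
  converged <- FALSE
  H <- NULL
  for (it in seq_len(100)) {
    g <- gr(th)
    if (max(abs(g)) < 1e-9) { converged <- TRUE; break }
    H <- pracma::jacobian(gr, th)
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-6, length(th)), g))
    lam <- 1
    repeat {
      th_new <- th - lam * step
      f_new <- nll(th_new)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { th_new <- th; f_new <- f; break }
    }
    th <- th_new; f <- f_new
  }
  if (is.null(H)) H <- pracma::jacobian(gr, th)
  vc <- tryCatch(solve((H + t(H)) / 2), error = function(e)
    matrix(NA_real_, length(th), length(th)))
  list(zeta = th[seq_len(K - 1)], beta = th[K - 1 + seq_len(p)],
       se = sqrt(pmax(diag(vc), 0)), vcov = vc, logLik = -f,
       converged = converged, n = n, K = K)
}

#' Proportional-odds ordinal logistic regression
#'
#' Cumulative-logit maximum-likelihood fit for an ordered outcome (e.g. T
#' stage 1..4): `logit P(Y <= j | x) = zeta_j - x'beta`, so positive
#' coefficients mean higher odds of a higher category. With exactly two
#' outcome levels the model is the ordinary binary logistic regression and
#' the coefficients agree with [binary_logit_hr()] to high precision.
#' Effects are reported as odds ratios with Wald intervals and p-values.
#'
#' @param outcome ordered factor, or numeric with integer-valued codes
#'   (treated as ordered); >= 2 observed levels. Unordered factors are an
#'   error.
#' @param predictors numeric vector, matrix or data.frame.
#' @param conf_level confidence level.
#' @return list with `effects` (data.frame: variable, HR, ci_low, ci_high,
#'   p, separation), `thresholds` (zeta), `logLik`, `converged`.
#' @export
ordinal_logit <- function(outcome, predictors, conf_level = 0.95) {
  if (is.factor(outcome) && !is.ordered(outcome))
    stop("ordinal_logit: outcome must be an ordered factor (or numeric codes)")
  if (is.ordered(outcome)) {
    y <- as.integer(droplevels(outcome))
  } else if (is.numeric(outcome)) {
    if (any(outcome != floor(outcome), na.rm = TRUE))
      stop("ordinal_logit: numeric outcome must have integer-valued codes")
    y <- match(outcome, sort(unique(outcome)))
  } else stop("ordinal_logit: outcome must be ordered factor or numeric codes")
  X <- as.data.frame(predictors)
  if (ncol(X) == 1L && identical(names(X), "predictors")) names(X) <- "x"
  ok <- stats::complete.cases(X) & !is.na(y)
  y <- y[ok]
  Xm <- as.matrix(X[ok, , drop = FALSE])
  if (length(unique(y)) < 2L)
    stop("ordinal_logit: need >= 2 observed outcome levels")
  y <- match(y, sort(unique(y)))  # re-pack observed levels to 1..K
  fit <- fit_prop_odds(y, Xm)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_b <- fit$se[fit$K - 1 + seq_len(ncol(Xm))]
  sep <- !fit$converged | abs(fit$beta) > 15 | !is.finite(se_b) | se_b > 100
  eff <- data.frame(variable = colnames(Xm),
                    HR = exp(fit$beta),
                    ci_low = exp(fit$beta - z * se_b),
                    ci_high = exp(fit$beta + z * se_b),
                    p = 2 * stats::pnorm(-abs(fit$beta / se_b)),
                    separation = sep, row.names = NULL)
  if (any(sep)) {
    eff$HR[sep] <- ifelse(fit$beta[sep] > 0, Inf, 0)
    eff$ci_low[sep] <- NA_real_
    eff$ci_high[sep] <- NA_real_
    warning("ordinal_logit: possible separation / non-convergence; ",
            "flagged estimate(s)")
  }
  list(effects = eff, thresholds = fit$zeta, logLik = fit$logLik,
       converged = fit$converged)
}

#' Forest-plot table: per-variable Youden cutoff + univariate logistic OR
#'
#' For each candidate variable (in the order given): optionally find the
#' Youden-optimal cutoff against the binary outcome, dichotomize at it
#' (`>= cutoff`), then fit a univariate logistic regression and report the
#' odds ratio ("HR"), 95% CI and p-value, plus log-scale columns for
#' plotting. Variables with zero variance (or whose dichotomization is
#' degenerate) are excluded with a message; exclusions are recorded in the
#' `excluded` attribute.
#'
#' @param cohort data.frame of slide rows (summaries joined to covariates).
#' @param outcome name of the binary 0/1 outcome column.
#' @param variables character vector of numeric predictor columns.
#' @param dichotomize dichotomize at the Youden cutoff (default) or use the
#'   continuous predictor.
#' @param method logistic estimator, passed to [binary_logit_hr()].
#'   Default "firth": in-sample optimal cutoffs regularly produce 2x2
#'   tables with empty cells at cohort sizes of tens of slides, where the
#'   ML odds ratio diverges; Firth's penalized fit keeps every forest row
#'   finite and testable. Use "ml" for the classical fit.
#' @param conf_level confidence level.
#' @return data.frame with one row per retained variable: `variable`,
#'   `cutoff`, `HR`, `ci_low`, `ci_high`, `p`, `separation`, `log_hr`,
#'   `log_ci_low`, `log_ci_high`; attribute `excluded` names the dropped
#'   variables and reasons.
#' @export
forest_table <- function(cohort, outcome, variables, dichotomize = TRUE,
                         method = c("firth", "ml"), conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(is.data.frame(cohort), outcome %in% names(cohort),
            all(variables %in% names(cohort)))
  y <- as.integer(as.logical(cohort[[outcome]]))
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("forest_table: outcome must have both classes")
  rows <- list()
  excluded <- character(0)
  for (v in variables) {
    x <- as.numeric(cohort[[v]])
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4L || stats::var(x[ok]) == 0) {
      message("forest_table: excluding '", v, "' (zero variance or too few values)")
      excluded[v] <- "zero variance or too few values"
      next
    }
    cutoff <- NA_real_
    if (dichotomize) {
      yc <- youden_cutoff(x[ok], y[ok])
      cutoff <- yc$cutoff
      xd <- as.integer(x[ok] >= cutoff)
      if (stats::var(xd) == 0) {
        message("forest_table: excluding '", v, "' (degenerate dichotomization)")
        excluded[v] <- "degenerate dichotomization"
        next
      }
      est <- binary_logit_hr(y[ok], stats::setNames(data.frame(xd), v),
                             conf_level = conf_level, method = method)
    } else {
      est <- binary_logit_hr(y[ok], stats::setNames(data.frame(x[ok]), v),
                             conf_level = conf_level, method = method)
    }
    est$cutoff <- cutoff
    rows[[v]] <- est
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), cutoff = numeric(0), HR = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0), p = numeric(0),
               separation = logical(0))
  rownames(out) <- NULL
  out$log_hr <- log(out$HR)
  out$log_ci_low <- log(out$ci_low)
  out$log_ci_high <- log(out$ci_high)
  attr(out, "excluded") <- excluded
  out
}

#' Draw a forest table (log odds-ratio scale)
#'
#' Minimal base-graphics rendering of a [forest_table()]: one line per
#' variable, point at log(HR), whiskers at the CI, dashed null line at 1.
#'
#' @param ft a [forest_table()] result.
#' @param path optional PNG path; NULL draws on the active device.
#' @export
plot_forest <- function(ft, path = NULL) {
  keep <- is.finite(ft$log_hr) & is.finite(ft$log_ci_low) &
    is.finite(ft$log_ci_high)
  ft <- ft[keep, , drop = FALSE]
  if (!nrow(ft)) stop("plot_forest: no finite rows to draw")
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 120 + 60 * nrow(ft), res = 110)
    on.exit(grDevices::dev.off())
  }
  yy <- rev(seq_len(nrow(ft)))
  xlim <- range(c(ft$log_ci_low, ft$log_ci_high, 0))
  graphics::plot(ft$log_hr, yy, xlim = xlim + c(-0.5, 0.5),
                 ylim = c(0.5, nrow(ft) + 0.5), pch = 15, yaxt = "n",
                 xlab = "log odds ratio", ylab = "")
  graphics::segments(ft$log_ci_low, yy, ft$log_ci_high, yy)
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = yy, labels = ft$variable, las = 1, cex.axis = 0.8)
  invisible(ft)
}
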