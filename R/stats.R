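#' Scale and center a variable
#'
#' \eqn{x' = (x - \bar x) / s_x} with the sample standard deviation.
#' A constant vector cannot be scaled and is returned as zeros with the
#' \code{degenerate} attribute set, so a downstream fit drops rather than
#' explodes on it.
#'
#' @param x numeric vector of length at least 2.
#' @return Numeric vector with attributes \code{center}, \code{scale},
#'   \code{degenerate}.
#' @export
scale_center <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values to scale")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
  } else {
    out <- (x - m) / s
    attr(out, "degenerate") <- FALSE
  }
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

.zap <- function(x) { attributes(x) <- NULL; x }

#' Pairwise pruning-method contrasts with a participant random intercept
#'
#' Fits \code{outcome ~ method + (1 | id)} on one analysis cell and
#' reports the three pairwise method contrasts (SCI-only vs CV, full
#' windowed procedure vs CV, full vs SCI-only) with Wald standard errors
#' and normal-approximation p-values, Bonferroni-multiplied by \code{m}
#' (default 3, the contrasts per cell) and capped at 1. The Wald
#' p-values are diagnostics; bootstrap inference via
#' [bootstrap_fixed_effects()] is the primary path when residuals are
#' non-normal.
#'
#' @param rows data.frame with columns \code{id}, \code{method} (values
#'   among \code{"cv"}, \code{"sci_only"}, \code{"qt"}) and
#'   \code{outcome} (e.g. TRC SNR in dB).
#' @param m Bonferroni family size (default 3).
#' @return data.frame of class \code{method_contrasts}: \code{term},
#'   \code{estimate}, \code{se}, \code{p_raw}, \code{p_bonferroni}; the
#'   fitted \code{lme4} model is kept as attribute \code{fit}.
#' @export
fit_method_model <- function(rows, m = 3) {
  stopifnot(all(c("id", "method", "outcome") %in% names(rows)))
  rows <- rows[!is.na(rows$outcome), , drop = FALSE]
  if (length(unique(rows$id)) < 2L) stop("need at least 2 participants")
  rows$method <- factor(rows$method, levels = c("cv", "sci_only", "qt"))
  rows$method <- droplevels(rows$method)
  if (nlevels(rows$method) < 2L) stop("need at least 2 pruning methods")
  fit <- lme4::lmer(outcome ~ method + (1 | id), data = rows, REML = TRUE)
  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  lv <- levels(rows$method)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  contr <- lapply(pairs, function(pr) {
    L <- rep(0, length(fe)); names(L) <- names(fe)
    for (nm in paste0("method", pr))
      if (nm %in% names(L)) L[nm] <- c(-1, 1)[match(nm, paste0("method", pr))]
    est <- sum(L * fe)
    se <- sqrt(drop(t(L) %*% V %*% L))
    z <- if (se > 0) est / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(term = paste(pr[2], "-", pr[1]), estimate = est, se = se,
               p_raw = p, p_bonferroni = min(1, m * p))
  })
  out <- do.call(rbind, contr)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  class(out) <- c("method_contrasts", "data.frame")
  out
}

#' Full fixed-effects model for signal quality or retention
#'
#' Fits the threshold/age/motion model on sweep rows:
#' \deqn{Outcome \sim SCI*PSP + Age*SCI + Age*PSP + SCI*PoM + PSP*PoM +
#'   Age*PoM + Task + Cohort + CSE + (1|ID) + (1|SCI{:}Cohort) +
#'   (1|PSP{:}Cohort)}
#' with SCI/PSP the threshold values, Age in months as an ordered numeric
#' predictor (scaled) by default, PoM the percentage of motion and CSE
#' the dead-channel count. All numeric variables, including the outcome,
#' are scaled and centered (sample convention) so coefficients are
#' standardized; the threshold-by-cohort random intercepts group on the
#' discrete threshold levels crossed with cohort.
#'
#' @param rows data.frame with columns \code{id, age_months, cohort,
#'   task, sci_thr, psp_thr, pom, cse_count} and the outcome column.
#' @param outcome name of the outcome column (e.g. \code{"trc_snr"} or
#'   \code{"cr"}; [simulate_analysis_rows()] uses \code{"outcome"}).
#' @param age_numeric treat age as scaled numeric (default) instead of a
#'   five-level factor.
#' @param scale_outcome standardize the outcome (default TRUE).
#' @return Object of class \code{nirs_mlm}: list with \code{fit} (the
#'   \code{lmerMod}), \code{data} (the model frame used), \code{formula},
#'   \code{converged}, \code{messages}, \code{fixed} (coefficient table).
#' @export
fit_full_model <- function(rows, outcome = "trc_snr", age_numeric = TRUE,
                           scale_outcome = TRUE) {
  need <- c("id", "age_months", "cohort", "task", "sci_thr", "psp_thr",
            "pom", "cse_count", outcome)
  if (!all(need %in% names(rows)))
    stop("rows are missing columns: ",
         paste(setdiff(need, names(rows)), collapse = ", "))
  d <- rows[!is.na(rows[[outcome]]), , drop = FALSE]
  if (nrow(d) < 10L) stop("too few complete rows to fit the model")
  md <- data.frame(
    y = if (scale_outcome) .zap(scale_center(d[[outcome]])) else d[[outcome]],
    SCI = .zap(scale_center(d$sci_thr)),
    PSP = .zap(scale_center(d$psp_thr)),
    PoM = .zap(scale_center(d$pom)),
    CSE = if (stats::sd(d$cse_count) == 0) 0 else .zap(scale_center(d$cse_count)),
    Task = factor(d$task),
    Cohort = factor(d$cohort),
    id = factor(d$id),
    sci_cohort = interaction(d$sci_thr, d$cohort, drop = TRUE),
    psp_cohort = interaction(d$psp_thr, d$cohort, drop = TRUE))
  md$Age <- if (age_numeric) .zap(scale_center(d$age_months))
            else factor(d$age_months)
  fml <- y ~ SCI * PSP + Age * SCI + Age * PSP + SCI * PoM + PSP * PoM +
    Age * PoM + Task + Cohort + CSE +
    (1 | id) + (1 | sci_cohort) + (1 | psp_cohort)
  # drop constant terms (single cohort/task cells, constant CSE)
  if (nlevels(md$Task) < 2L) fml <- stats::update(fml, . ~ . - Task)
  if (nlevels(md$Cohort) < 2L) fml <- stats::update(fml, . ~ . - Cohort)
  if (all(md$CSE == 0)) fml <- stats::update(fml, . ~ . - CSE)
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = md, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular =
                                             "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  conv <- length(fit@optinfo$conv$lme4) == 0L && length(msgs) == 0L
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  fixed <- data.frame(term = names(fe), estimate = as.numeric(fe),
                      se = as.numeric(se), row.names = NULL)
  structure(list(fit = fit, data = md, formula = fml, converged = conv,
                 messages = msgs, fixed = fixed, outcome = outcome),
            class = "nirs_mlm")
}

#' @export
print.nirs_mlm <- function(x, ...) {
  cat(sprintf("<nirs_mlm> outcome=%s, %d rows, converged=%s\n",
              x$outcome, nrow(x$data), x$converged))
  print(x$fixed, digits = 3)
  invisible(x)
}

#' Row-resampling bootstrap of the fixed effects
#'
#' Draws \code{n_boot} datasets by sampling rows of the model frame with
#' replacement (fixed seed), refits the mixed model on each, and
#' summarizes every fixed effect by the mean of its bootstrap estimates,
#' the 2.5/97.5 percentile interval and the bootstrap standard
#' deviation. Resamples that fail to fit (e.g. a grouping factor
#' collapsing to one level) are dropped and counted; it is an error if
#' every resample fails.
#'
#' @param model a [fit_full_model()] result, or any list with elements
#'   \code{fit}, \code{data}, \code{formula}.
#' @param n_boot number of resamples (default 1000; at least 100).
#' @param seed RNG seed (default 1).
#' @param level confidence level (default 0.95).
#' @return data.frame of class \code{effect_estimates}: \code{term,
#'   estimate, ci_lo, ci_hi, se}; attributes \code{n_boot},
#'   \code{n_failed}, \code{seed}, \code{level}.
#' @export
bootstrap_fixed_effects <- function(model, n_boot = 1000, seed = 1,
                                    level = 0.95) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  stopifnot(!is.null(model$data), !is.null(model$formula))
  md <- model$data
  set.seed(seed)
  terms0 <- names(lme4::fixef(model$fit))
  est <- matrix(NA_real_, n_boot, length(terms0),
                dimnames = list(NULL, terms0))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(md), nrow(md), replace = TRUE)
    fb <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(model$formula, data = md[idx, , drop = FALSE],
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                                                 "ignore",
                                               calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (is.null(fb)) next
    fe <- lme4::fixef(fb)
    est[b, intersect(names(fe), terms0)] <- fe[intersect(names(fe), terms0)]
  }
  ok <- stats::complete.cases(est)
  if (!any(ok)) stop("all bootstrap resamples failed to fit")
  est <- est[ok, , drop = FALSE]
  a <- (1 - level) / 2
  out <- data.frame(
    term = terms0,
    estimate = colMeans(est),
    ci_lo = apply(est, 2, stats::quantile, probs = a),
    ci_hi = apply(est, 2, stats::quantile, probs = 1 - a),
    se = apply(est, 2, stats::sd),
    row.names = NULL)
  attr(out, "n_boot") <- n_boot
  attr(out, "n_failed") <- n_boot - sum(ok)
  attr(out, "seed") <- seed
  attr(out, "level") <- level
  class(out) <- c("effect_estimates", "data.frame")
  out
}
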