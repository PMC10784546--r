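# Generalized propensity scores, inverse probability weighting, balance
# diagnostics and doubly robust mixed-effects outcome models.

#' Describe a causal estimation task
#'
#' @param treatment column name of the variable of interest.
#' @param covariates character vector of confounding covariate columns.
#' @param outcome outcome column name.
#' @param group grouping column for the multilevel (random intercept)
#'   structure; default `participant_id`.
#' @param treatment_type `"continuous"` or `"categorical"`.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return list of class `causal_task`.
#' @export
causal_task <- function(treatment, covariates, outcome,
                        group = "participant_id",
                        treatment_type = c("continuous", "categorical"),
                        outcome_type = c("continuous", "binary")) {
  if (treatment %in% covariates)
    stop("treatment must not appear among the covariates")
  structure(list(treatment = treatment, covariates = covariates,
                 outcome = outcome, group = group,
                 treatment_type = match.arg(treatment_type),
                 outcome_type = match.arg(outcome_type)),
            class = "causal_task")
}

check_cols <- function(data, task, need_outcome = TRUE) {
  need <- c(task$treatment, task$covariates, task$group,
            if (need_outcome) task$outcome)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("columns missing from analysis table: ", paste(miss, collapse = ", "))
}

rhs <- function(terms) if (length(terms)) paste(terms, collapse = " + ") else "1"

finalize_weights <- function(w, truncate, model_type, stabilized) {
  n_trunc <- 0L
  if (!is.null(truncate)) {
    q <- stats::quantile(w, truncate, names = FALSE)
    n_trunc <- sum(w < q[1] | w > q[2])
    w <- pmin(pmax(w, q[1]), q[2])
  }
  stopifnot(all(w > 0))
  attr(w, "model") <- model_type
  attr(w, "n_truncated") <- n_trunc
  attr(w, "stabilized") <- stabilized
  w
}

#' Inverse probability weights for a continuous treatment
#'
#' Fits a linear mixed propensity model `T ~ X + (1 | group)` (falling back
#' to a fixed-effects linear model, with a warning, if the mixed fit fails)
#' and converts conditional predictions to generalized-propensity densities
#' with the Normal density: `e_i = phi((T_i - That_i) / sigma) / sigma`.
#' Raw weights are `1 / e_i`; by default they are stabilized by the marginal
#' Normal density of `T` and truncated at the 1st/99th weight percentiles
#' (truncation counts are reported, never silent).
#'
#' @param data analysis table.
#' @param task a [causal_task()] with `treatment_type = "continuous"`.
#' @param stabilize multiply by the marginal density of `T`.
#' @param truncate two percentiles for weight truncation, or `NULL`.
#' @return numeric weights (one per row) with attributes `model`,
#'   `n_truncated`, `stabilized`.
#' @export
propensity_weights_continuous <- function(data, task, stabilize = TRUE,
                                          truncate = c(0.01, 0.99)) {
  stopifnot(task$treatment_type == "continuous")
  check_cols(data, task, need_outcome = FALSE)
  tv <- data[[task$treatment]]
  fml <- stats::as.formula(paste(task$treatment, "~", rhs(task$covariates),
                                 "+ (1 |", task$group, ")"))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(fml, data = data,
                                control = lme4::lmerControl(calc.derivs = FALSE))),
    error = function(e) NULL)
  if (is.null(fit) || (length(fit@optinfo$conv$opt) &&
                       fit@optinfo$conv$opt != 0)) {
    warning("mixed propensity model failed; falling back to fixed effects")
    fit <- stats::lm(stats::as.formula(
      paste(task$treatment, "~", rhs(task$covariates))), data = data)
    mu <- stats::fitted(fit)
    sg <- stats::sigma(fit)
    model_type <- "fixed"
  } else {
    mu <- stats::fitted(fit)
    sg <- stats::sigma(fit)
    model_type <- "mixed"
  }
  dens <- stats::dnorm(tv, mu, sg)
  dens <- pmax(dens, 1e-12)               # guard: perfectly predicted rows
  num <- if (stabilize)
    stats::dnorm(tv, mean(tv), stats::sd(tv)) else 1
  finalize_weights(num / dens, truncate, model_type, stabilize)
}

#' Inverse probability weights for a multi-category treatment
#'
#' Estimates the generalized propensity `P(T = t | X)` with one-vs-rest
#' logistic mixed models (`(1 | group)` random intercept) whose predicted
#' probabilities are normalized across categories — a practical surrogate
#' for a multinomial mixed model. `mixed = FALSE`, or any mixed-fit failure,
#' uses plain logistic regressions instead (warning on failure). Weights are
#' `1 / P(T_i = observed category | X_i)`, optionally stabilized by marginal
#' category shares, truncated as reported.
#'
#' @inheritParams propensity_weights_continuous
#' @param mixed use random-intercept logistic components.
#' @return numeric weights with attributes as in
#'   [propensity_weights_continuous()].
#' @export
propensity_weights_categorical <- function(data, task, stabilize = TRUE,
                                           truncate = c(0.01, 0.99),
                                           mixed = TRUE) {
  stopifnot(task$treatment_type == "categorical")
  check_cols(data, task, need_outcome = FALSE)
  tv <- factor(data[[task$treatment]])
  tv <- droplevels(tv)
  lv <- levels(tv)
  if (length(lv) < 2) stop("treatment has fewer than 2 observed categories")
  tiny <- names(which(table(tv) < 2))
  if (length(tiny))
    warning("category with a single row: ", paste(tiny, collapse = ", "),
            "; its weights rely on truncation")

  p <- matrix(NA_real_, nrow(data), length(lv), dimnames = list(NULL, lv))
  model_type <- if (mixed) "mixed" else "fixed"
  for (l in lv) {
    y <- as.integer(tv == l)
    dd <- data; dd$.y <- y
    fit <- NULL
    if (mixed) {
      fml <- stats::as.formula(paste(".y ~", rhs(task$covariates),
                                     "+ (1 |", task$group, ")"))
      fit <- tryCatch(
        suppressMessages(lme4::glmer(fml, data = dd, family = stats::binomial,
                                     nAGQ = 0L)),
        error = function(e) NULL)
    }
    if (is.null(fit)) {
      if (mixed) {
        warning("mixed propensity component failed for category ", l,
                "; falling back to fixed effects")
        model_type <- "fixed"
      }
      fit <- stats::glm(stats::as.formula(
        paste(".y ~", rhs(task$covariates))), data = dd,
        family = stats::binomial)
    }
    p[, l] <- stats::fitted(fit)
  }
  p <- p / rowSums(p)
  p_obs <- p[cbind(seq_len(nrow(p)), as.integer(tv))]
  p_obs <- pmax(p_obs, 1e-12)
  num <- if (stabilize) as.numeric(prop.table(table(tv))[as.integer(tv)]) else 1
  finalize_weights(num / p_obs, truncate, model_type, stabilize)
}

# Cluster-robust (sandwich) covariance of the fixed effects of a weighted
# random-intercept lmer fit. The marginal covariance is block-diagonal by
# grouping level: V_g = sigma^2 W_g^-1 + tau^2 11', so the GLS estimating
# equation X' V^-1 (y - X b) = 0 admits the exact CR0 sandwich
#   A^-1 (sum_g X_g' V_g^-1 r_g r_g' V_g^-1 X_g) A^-1,  A = X' V^-1 X,
# with a G/(G-1) small-sample factor. Model-based SEs on an IPW-weighted
# fit understate variance (weights are not precision weights); the sandwich
# restores approximately nominal error rates.
robust_vcov_lmer <- function(fit, group_values) {
  X <- lme4::getME(fit, "X")
  y <- lme4::getME(fit, "y")
  w <- stats::weights(fit)
  if (is.null(w) || !length(w)) w <- rep(1, length(y))
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp != "Residual"][1]
  sig2 <- vc$vcov[vc$grp == "Residual"]
  r <- y - as.numeric(X %*% beta)
  groups <- split(seq_along(y), group_values)
  p <- ncol(X)
  A <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  for (idx in groups) {
    Xg <- X[idx, , drop = FALSE]
    Vg <- diag(sig2 / w[idx], length(idx)) + tau2
    XtVi <- crossprod(Xg, solve(Vg))
    A <- A + XtVi %*% Xg
    sg <- XtVi %*% r[idx]
    meat <- meat + tcrossprod(sg)
  }
  G <- length(groups)
  Ai <- solve(A)
  list(vcov = Ai %*% meat %*% Ai * G / (G - 1), df = G - 1)
}

smd_pair <- function(x, w, ga, gb) {
  ma <- wtd_mean(x[ga], w[ga]); mb <- wtd_mean(x[gb], w[gb])
  va <- wtd_var(x[ga], w[ga]); vb <- wtd_var(x[gb], w[gb])
  sp <- sqrt((va + vb) / 2)
  if (sp <= 0) return(NA_real_)
  (ma - mb) / sp
}

# Covariates as single numeric columns. Factor covariates (the elevated
# meal count category is the one in practice) are ordinal-coded by level
# index, so each study covariate yields exactly one balance statistic, as
# in the study's balance tables.
numeric_covariates <- function(data, covs) {
  out <- list()
  for (cv in covs) {
    x <- data[[cv]]
    out[[cv]] <- if (is.numeric(x)) x else as.numeric(factor(x)) - 1
  }
  out
}

#' Covariate balance before and after weighting
#'
#' Continuous treatments: weighted Pearson correlation between treatment and
#' each covariate, balanced when all `|r| < 0.1`. Categorical treatments:
#' maximum pairwise weighted standardized mean difference per covariate,
#' balanced when all `< 0.2`. Factor covariates are expanded to indicator
#' columns; zero-variance covariates are excluded with a note.
#'
#' @param data analysis table.
#' @param task a [causal_task()].
#' @param weights IPW vector, or `NULL` for unweighted.
#' @param cor_threshold,smd_threshold balance thresholds.
#' @return data.frame (`covariate`, `metric`, `unweighted`, `weighted`,
#'   `pass`) with attribute `balanced` = all pass.
#' @export
check_balance <- function(data, task, weights = NULL,
                          cor_threshold = 0.1, smd_threshold = 0.2) {
  check_cols(data, task, need_outcome = FALSE)
  n <- nrow(data)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  covs <- numeric_covariates(data, task$covariates)
  rows <- list(); notes <- character(0)
  for (nm in names(covs)) {
    x <- covs[[nm]]
    if (stats::var(x) <= 0) {
      notes <- c(notes, paste0(nm, ": zero variance, excluded"))
      next
    }
    if (task$treatment_type == "continuous") {
      tv <- data[[task$treatment]]
      uw <- wtd_cor(tv, x, rep(1, n))
      ww <- wtd_cor(tv, x, w)
      rows[[nm]] <- data.frame(covariate = nm, metric = "cor",
                               unweighted = uw, weighted = ww,
                               pass = abs(ww) < cor_threshold,
                               stringsAsFactors = FALSE)
    } else {
      tv <- factor(data[[task$treatment]])
      lv <- levels(droplevels(tv))
      mx_u <- mx_w <- 0
      for (i in seq_along(lv)) for (j in seq_along(lv)) {
        if (j <= i) next
        ga <- tv == lv[i]; gb <- tv == lv[j]
        su <- abs(smd_pair(x, rep(1, n), ga, gb))
        sw <- abs(smd_pair(x, w, ga, gb))
        if (!is.na(su)) mx_u <- max(mx_u, su)
        if (!is.na(sw)) mx_w <- max(mx_w, sw)
      }
      rows[[nm]] <- data.frame(covariate = nm, metric = "smd",
                               unweighted = mx_u, weighted = mx_w,
                               pass = mx_w < smd_threshold,
                               stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(covariate = character(), metric = character(),
                      unweighted = numeric(), weighted = numeric(),
                      pass = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "balanced") <- all(res$pass)
  attr(res, "notes") <- notes
  res
}

#' Estimate a causal effect with a weighted mixed-effects outcome model
#'
#' Fits the weighted outcome regression `Y ~ T (+ X) + (1 | group)` — linear
#' for continuous outcomes (t-test p-values), logistic for binary outcomes
#' (z-test p-values; effects also reported as odds ratios). The covariate
#' set `X` is included (doubly robust) when `doubly_robust = TRUE`, or by
#' default whenever the supplied balance report fails any covariate.
#' Categorical treatments yield one contrast per non-reference category,
#' reference = first level. With `weights = NULL` (or all-ones weights) this
#' is the ordinary mixed-model fit.
#'
#' Standard errors: unweighted fits use the model-based errors of the mixed
#' model (so unit weights reproduce the ordinary fit exactly). When IPW
#' weights are supplied to a linear outcome model, cluster-robust sandwich
#' errors (clustered on the grouping factor) are used by default, because
#' model-based errors treat IPW weights as precision weights and understate
#' sampling variance; `se_type = "model"` restores the naive behaviour.
#'
#' @param data analysis table.
#' @param task a [causal_task()].
#' @param weights IPW vector or `NULL`.
#' @param doubly_robust logical or `NULL` (decide from `balance`).
#' @param balance optional [check_balance()] report.
#' @param se_type `"auto"` (robust when weighted and linear), `"model"`, or
#'   `"robust"`.
#' @return data.frame of class `cgmeal_effect`: one row per treatment term
#'   (`term`, `estimate`, `se`, `statistic`, `p_value`, `significant` at
#'   p < 0.01, `odds_ratio` for binary outcomes, `doubly_robust`, `n`).
#' @export
estimate_effect <- function(data, task, weights = NULL, doubly_robust = NULL,
                            balance = NULL,
                            se_type = c("auto", "model", "robust")) {
  se_type <- match.arg(se_type)
  check_cols(data, task)
  if (is.null(doubly_robust))
    doubly_robust <- if (!is.null(balance)) !all(balance$pass) else FALSE
  dd <- data
  if (task$treatment_type == "categorical")
    dd[[task$treatment]] <- droplevels(factor(dd[[task$treatment]]))
  dd$.ipw <- if (is.null(weights)) 1 else as.numeric(weights)

  terms <- c(task$treatment, if (doubly_robust) task$covariates)
  fml <- stats::as.formula(paste(task$outcome, "~", rhs(terms),
                                 "+ (1 |", task$group, ")"))
  binary <- task$outcome_type == "binary"
  fit <- tryCatch({
    if (binary)
      suppressWarnings(lme4::glmer(fml, data = dd, family = stats::binomial,
                                   weights = .ipw, nAGQ = 0L))
    else
      suppressWarnings(suppressMessages(
        lme4::lmer(fml, data = dd, weights = .ipw,
                   control = lme4::lmerControl(calc.derivs = FALSE))))
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    if (binary && grepl("fitted probabilities|PIRLS|failed", conditionMessage(fit)))
      stop("logistic outcome model failed (possible separation): ",
           conditionMessage(fit))
    stop("outcome model failed: ", conditionMessage(fit))
  }

  cf <- summary(fit)$coefficients
  want <- if (task$treatment_type == "categorical")
    grep(paste0("^", task$treatment), rownames(cf), value = TRUE)
  else task$treatment
  est <- cf[want, "Estimate"]
  se <- cf[want, "Std. Error"]
  weighted <- !is.null(weights) && stats::var(dd$.ipw) > 0
  robust <- se_type == "robust" || (se_type == "auto" && weighted && !binary)
  df_resid <- nrow(dd) - nrow(cf)
  if (robust && !binary) {
    rb <- robust_vcov_lmer(fit, dd[[task$group]])
    se <- sqrt(diag(rb$vcov))[match(want, rownames(cf))]
    df_resid <- rb$df
  }
  stat <- est / se
  if (binary) {
    p <- 2 * stats::pnorm(-abs(stat))
  } else {
    p <- 2 * stats::pt(-abs(stat), df = df_resid)
  }
  p <- pmax(p, .Machine$double.xmin)     # p in (0, 1]
  ref <- if (task$treatment_type == "categorical")
    levels(dd[[task$treatment]])[1] else NA_character_
  out <- data.frame(
    term = if (task$treatment_type == "categorical")
      paste0(ref, " vs ", sub(paste0("^", task$treatment), "", want))
    else task$treatment,
    estimate = unname(est), se = unname(se), statistic = unname(stat),
    p_value = unname(p), significant = unname(p) < 0.01,
    odds_ratio = if (binary) exp(unname(est)) else NA_real_,
    doubly_robust = doubly_robust, n = nrow(dd),
    stringsAsFactors = FALSE)
  class(out) <- c("cgmeal_effect", "data.frame")
  attr(out, "outcome") <- task$outcome
  out
}

#' Run the four study causal analyses
#'
#' (a) elevated meal event count (categories 0/1/2/>=3) on daily TIR and
#' mean glucose, adjusting for baseline glucose, duration and daily steps;
#' (b) daily step count (per 1000 steps) on the same outcomes, adjusting for
#' baseline glucose, elevated count and duration; (c) post-meal step count
#' (per 1000) on MGR_3h and on the odds of an elevated meal, adjusting for
#' calories; (d) calorie content (per 100 kcal) on the same meal outcomes,
#' adjusting for post-meal steps. Daily analyses use IPW (multinomial /
#' Normal-density weights) with balance checks; meal-level analyses skip IPW
#' when `|cor(T, covariate)| < 0.1` (adequate balance) and fall back to
#' covariate-adjusted mixed regression, mirroring the doubly robust route.
#' Meal-level rows are restricted to high-agreement events with non-zero
#' logged calories and a recorded post-meal step count.
#'
#' @param day_records output of [build_day_records()] (included days used).
#' @param meal_biomarkers biomarker table from [compute_meal_biomarkers()].
#' @param stabilize,truncate weight options (see the propensity functions).
#' @param mixed_propensity use mixed-effects propensity models.
#' @return named list of four analyses (`elevated_count`, `daily_steps`,
#'   `post_meal_steps`, `calories`), each either
#'   `list(estimable = FALSE, reason = ...)` or `list(estimable, effects,
#'   balance, weights_info, n)`.
#' @export
run_study_analyses <- function(day_records, meal_biomarkers,
                               stabilize = TRUE, truncate = c(0.01, 0.99),
                               mixed_propensity = TRUE) {
  out <- list()

  dd <- day_records[day_records$included, , drop = FALSE]
  keep <- c("participant_id", "elevated_count_category", "daily_steps",
            "baseline_glucose", "duration", "tir", "mean_glucose")
  dd <- dd[stats::complete.cases(dd[, keep]), keep]
  dd$daily_steps_k <- dd$daily_steps / 1000
  dd$elevated_count_category <- droplevels(dd$elevated_count_category)

  # a covariate with no variation carries no confounding information and
  # breaks model matrices; drop it rather than abort the analysis
  usable <- function(covs) {
    covs[vapply(covs, function(cv) {
      x <- dd[[cv]]
      if (is.numeric(x)) stats::var(x) > 0 else nlevels(droplevels(factor(x))) >= 2
    }, TRUE)]
  }

  daily_analysis <- function(treatment, covariates, type) {
    covariates <- usable(covariates)
    if (!nrow(dd)) return(list(estimable = FALSE, reason = "no included days"))
    if (type == "categorical" &&
        length(unique(as.character(dd[[treatment]]))) < 2)
      return(list(estimable = FALSE,
                  reason = "fewer than 2 treatment categories observed"))
    eff <- list(); bal <- NULL; w <- NULL
    for (oc in c("tir", "mean_glucose")) {
      task <- causal_task(treatment, covariates, oc,
                          treatment_type = type, outcome_type = "continuous")
      if (is.null(w) && length(covariates)) {
        w <- if (type == "categorical")
          propensity_weights_categorical(dd, task, stabilize, truncate,
                                         mixed = mixed_propensity)
        else propensity_weights_continuous(dd, task, stabilize, truncate)
        bal <- check_balance(dd, task, w)
      }
      eff[[oc]] <- estimate_effect(dd, task, w, balance = bal)
      eff[[oc]]$outcome <- oc
    }
    list(estimable = TRUE, effects = do.call(rbind, eff), balance = bal,
         weights_info = attributes(w)[c("model", "n_truncated", "stabilized")],
         n = nrow(dd))
  }
  out$elevated_count <- daily_analysis(
    "elevated_count_category",
    c("baseline_glucose", "duration", "daily_steps_k"), "categorical")
  out$daily_steps <- daily_analysis(
    "daily_steps_k",
    c("baseline_glucose", "elevated_count_category", "duration"), "continuous")

  mm <- meal_biomarkers
  mm <- mm[mm$high_agreement & !is.na(mm$calories) & mm$calories > 0 &
             !is.na(mm$post_meal_steps), , drop = FALSE]
  meal_analysis <- function(treatment_col, covariate_col) {
    if (nrow(mm) < 10)
      return(list(estimable = FALSE,
                  reason = "too few qualifying meal events"))
    md <- data.frame(participant_id = mm$participant_id,
                     post_steps_k = mm$post_meal_steps / 1000,
                     cal_100 = mm$calories / 100,
                     mgr_3h = mm$mgr_3h,
                     elevated = as.integer(mm$label == "elevated"),
                     stringsAsFactors = FALSE)
    r <- stats::cor(md[[treatment_col]], md[[covariate_col]])
    use_ipw <- abs(r) >= 0.1
    eff <- list(); bal <- NULL; w <- NULL
    for (oc in c("mgr_3h", "elevated")) {
      task <- causal_task(treatment_col, covariate_col, oc,
                          treatment_type = "continuous",
                          outcome_type = if (oc == "elevated") "binary"
                          else "continuous")
      if (use_ipw && is.null(w)) {
        w <- propensity_weights_continuous(md, task, stabilize, truncate)
        bal <- check_balance(md, task, w)
      }
      eff[[oc]] <- estimate_effect(md, task, w,
                                   doubly_robust = if (use_ipw) NULL else TRUE,
                                   balance = bal)
      eff[[oc]]$outcome <- oc
    }
    list(estimable = TRUE, effects = do.call(rbind, eff), balance = bal,
         treatment_covariate_cor = r, ipw_used = use_ipw, n = nrow(md))
  }
  out$post_meal_steps <- meal_analysis("post_steps_k", "cal_100")
  out$calories <- meal_analysis("cal_100", "post_steps_k")
  out
}
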