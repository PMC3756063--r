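## Repeated-measures mixed-effects analysis of per-section traits:
## value ~ muscle * age_group with a random intercept per mouse, Wald
## contrasts between age groups within a muscle, and likelihood-ratio
## screening of model factors.

# assemble the analysis frame for one trait; factors with stable levels
rm_frame <- function(traits, trait) {
  d <- as.data.frame(traits)
  need <- c("mouse_id", "age_group", "muscle", "section_id", "trait",
            "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- d[d$trait == trait & !is.na(d$value), , drop = FALSE]
  if (!nrow(d))
    stop("no rows for trait '", trait, "'", call. = FALSE)
  mus_lev <- intersect(MUSCLE_CODES, unique(d$muscle))
  if (!length(mus_lev)) mus_lev <- sort(unique(d$muscle))
  d$muscle <- factor(d$muscle, levels = mus_lev)
  d$age_group <- factor(d$age_group, levels = sort(unique(d$age_group)))
  d$mouse_id <- factor(d$mouse_id)
  d
}

#' Fit the repeated-measures mixed model for one trait
#'
#' Fits \code{value ~ muscle * age_group + (1 | mouse_id)} by REML:
#' muscle, age group and their interaction as fixed effects, animal as a
#' random intercept absorbing the dependence between the repeated
#' sections of one mouse.  Degenerate designs reduce gracefully: with a
#' single muscle (or single group) the corresponding factor and the
#' interaction are dropped from the fixed part.
#'
#' @param traits long trait table (see [trait_table()]).
#' @param trait which trait to model, e.g. \code{"rf_per_mm2"}.
#' @param transform \code{"identity"} (default, analysis on raw values)
#'   or \code{"sqrt"} for count-like heteroscedastic traits.
#' @return Object of class \code{rm_fit}: list with the fitted
#'   \code{lme4} model (\code{$model}), the analysis frame
#'   (\code{$data}), factor levels, mouse count, and variance components
#'   (\code{$varcomp}: mouse-intercept and residual variances).
#' @section Errors: a muscle-by-group cell with no observations makes the
#'   interaction inestimable; the error names the first empty cell.
#'   Fewer than 2 mice in some group is likewise an error.
#' @export
fit_repeated_measures <- function(traits, trait,
                                  transform = c("identity", "sqrt")) {
  transform <- match.arg(transform)
  d <- rm_frame(traits, trait)
  if (transform == "sqrt") {
    if (any(d$value < 0))
      stop("sqrt transform needs non-negative values", call. = FALSE)
    d$value <- sqrt(d$value)
  }
  mice_per_group <- tapply(d$mouse_id, d$age_group,
                           function(m) length(unique(m)))
  if (any(mice_per_group < 2L))
    stop("need >= 2 mice per age group; group ",
         names(mice_per_group)[which(mice_per_group < 2L)[1]],
         " has ", min(mice_per_group), call. = FALSE)
  has_mus <- nlevels(d$muscle) > 1L
  has_grp <- nlevels(d$age_group) > 1L
  if (has_mus && has_grp) {
    cells <- table(d$muscle, d$age_group)
    if (any(cells == 0L)) {
      empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
      stop("empty design cell: muscle ", rownames(cells)[empty[1]],
           " x age group ", colnames(cells)[empty[2]], call. = FALSE)
    }
  }
  fixed <- if (has_mus && has_grp) "muscle * age_group"
           else if (has_mus) "muscle"
           else if (has_grp) "age_group"
           else "1"
  form <- as.formula(paste("value ~", fixed, "+ (1 | mouse_id)"))
  model <- suppressMessages(lme4::lmer(
    form, data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore",
                                calc.derivs = FALSE)))
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(
    list(model = model, data = d, trait = trait, transform = transform,
         formula = form,
         muscles = levels(d$muscle), groups = levels(d$age_group),
         n_mice = nlevels(d$mouse_id),
         varcomp = c(mouse = vc$vcov[vc$grp == "mouse_id"],
                     residual = vc$vcov[vc$grp == "Residual"])),
    class = "rm_fit")
}

#' @export
print.rm_fit <- function(x, ...) {
  cat("<rm_fit> trait:", x$trait, "\n  ",
      deparse(x$formula), "\n  ",
      x$n_mice, "mice,", length(x$muscles), "muscle(s),",
      length(x$groups), "age group(s)\n  variance components:",
      sprintf("mouse %.4g, residual %.4g\n",
              x$varcomp[["mouse"]], x$varcomp[["residual"]]))
  invisible(x)
}

#' Fixed-effect estimates of an \code{rm_fit}
#' @param object an \code{rm_fit}.
#' @param ... unused.
#' @return Named numeric vector of fixed-effect coefficients.
#' @method fixef rm_fit
#' @export
fixef.rm_fit <- function(object, ...) lme4::fixef(object$model)

# model-matrix row for the (muscle, group) cell mean
cell_row <- function(fit, muscle, group) {
  d <- fit$data
  nd <- d[1L, , drop = FALSE]
  if (!muscle %in% levels(d$muscle))
    stop("unknown muscle level: ", muscle, call. = FALSE)
  nd$muscle <- factor(muscle, levels = levels(d$muscle))
  if (!as.character(group) %in% levels(d$age_group))
    stop("unknown age group level: ", group, call. = FALSE)
  nd$age_group <- factor(as.character(group), levels = levels(d$age_group))
  tt <- stats::delete.response(stats::terms(
    lme4::nobars(stats::formula(fit$model))))
  model.matrix(tt, nd)[1L, ]
}

normalize_pairs <- function(pairs) {
  if (is.character(pairs))
    pairs <- lapply(strsplit(pairs, "-", fixed = TRUE), as.integer)
  if (is.numeric(pairs) && length(pairs) == 2L) pairs <- list(pairs)
  lapply(pairs, function(p) {
    p <- sort(as.integer(p))
    if (length(p) != 2L || any(is.na(p)))
      stop("each contrast pair must be two group labels", call. = FALSE)
    p
  })
}

#' Age-group contrasts within a muscle
#'
#' Wald contrasts between the cell means of two age groups for one
#' muscle, from a fitted [fit_repeated_measures()] model.  Degrees of
#' freedom use the between-within approximation with mice as the subject
#' stratum: age group is a between-subject factor, so
#' \code{df = n_mice - n_groups}.  P-values are uncorrected by default,
#' matching the usual reporting of many pairwise muscle/age comparisons;
#' \code{adjust = "holm"} applies a Holm correction across the requested
#' pairs.
#'
#' @param fit an \code{rm_fit}.
#' @param muscle muscle code to condition on (any fitted level).
#' @param pairs group pairs, e.g. \code{list(c(1, 4), c(1, 3))} or
#'   \code{c("1-4", "1-3")}.
#' @param alpha significance level (default 0.05).
#' @param adjust \code{"none"} (default) or \code{"holm"}.
#' @return Data frame: \code{muscle, group_a, group_b, estimate, se,
#'   statistic, df, p_value, significant}.  \code{estimate} is the mean
#'   of \code{group_b} minus that of \code{group_a}.
#' @export
group_contrasts <- function(fit, muscle, pairs, alpha = 0.05,
                            adjust = c("none", "holm")) {
  stopifnot(inherits(fit, "rm_fit"))
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
      alpha > 1)
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  pairs <- normalize_pairs(pairs)
  beta <- lme4::fixef(fit$model)
  V <- as.matrix(vcov(fit$model))
  df_bw <- max(fit$n_mice - length(fit$groups), 1L)
  out <- lapply(pairs, function(p) {
    L <- cell_row(fit, muscle, p[2]) - cell_row(fit, muscle, p[1])
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tstat <- if (se > 0) est / se else 0
    data.frame(muscle = muscle, group_a = p[1], group_b = p[2],
               estimate = est, se = se, statistic = tstat, df = df_bw,
               p_value = 2 * pt(-abs(tstat), df_bw),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_adjusted <- if (adjust == "holm")
    stats::p.adjust(res$p_value, "holm") else res$p_value
  res$significant <- res$p_adjusted < alpha
  rownames(res) <- NULL
  res
}

#' Wald F tests of the fixed terms
#'
#' Joint Wald F statistic for each fixed-effect term of an
#' \code{rm_fit}, with between-within denominator degrees of freedom
#' (between-subject terms use the mouse stratum, within-subject terms
#' the residual stratum).
#'
#' @param fit an \code{rm_fit}.
#' @return Data frame: \code{term, F, df1, df2, p_value}.
#' @export
fixed_effect_anova <- function(fit) {
  stopifnot(inherits(fit, "rm_fit"))
  model <- fit$model
  beta <- lme4::fixef(model)
  V <- as.matrix(vcov(model))
  asg <- attr(model.matrix(model), "assign")
  labels <- attr(stats::terms(lme4::nobars(stats::formula(model))),
                 "term.labels")
  n_obs <- nrow(fit$data)
  p_fix <- length(beta)
  df_between <- max(fit$n_mice - length(fit$groups), 1L)
  df_within <- max(n_obs - p_fix - fit$n_mice + 1L, 1L)
  rows <- lapply(seq_along(labels), function(i) {
    j <- which(asg == i)
    b <- beta[j]
    Fi <- drop(t(b) %*% solve(V[j, j, drop = FALSE]) %*% b) / length(j)
    # age_group varies between mice only; muscle and the interaction
    # vary within mouse
    df2 <- if (labels[i] == "age_group") df_between else df_within
    data.frame(term = labels[i], F = Fi, df1 = length(j), df2 = df2,
               p_value = stats::pf(Fi, length(j), df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Screen design factors by likelihood ratio
#'
#' Compares nested versions of the repeated-measures model (fitted by
#' maximum likelihood) to report which design factors materially improve
#' fit: the muscle and age-group fixed effects and their interaction,
#' the per-mouse random intercept, and a per-section fixed effect
#' (section order within a mouse-muscle).  The random-intercept test is
#' on the boundary of its parameter space, so its likelihood-ratio
#' p-value uses the 0.5 chi-squared(0) + 0.5 chi-squared(1) mixture.
#'
#' @param traits long trait table.
#' @param trait trait name.
#' @param alpha retention threshold (default 0.05).
#' @return Data frame: \code{factor, chisq, df, p_value, retained}.
#'   A factor with a single observed level is reported with
#'   \code{retained = NA} (inestimable).
#' @export
screen_factors <- function(traits, trait, alpha = 0.05) {
  d <- rm_frame(traits, trait)
  has_mus <- nlevels(d$muscle) > 1L
  has_grp <- nlevels(d$age_group) > 1L
  # section order within mouse x muscle, as a factor
  d <- d[order(d$mouse_id, d$muscle, d$section_id), ]
  d$section_index <- factor(stats::ave(
    seq_len(nrow(d)), d$mouse_id, d$muscle, d$trait,
    FUN = seq_along))
  fixed0 <- c(if (has_mus) "muscle", if (has_grp) "age_group",
              if (has_mus && has_grp) "muscle:age_group")
  fml <- function(terms, random = TRUE) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    if (random) rhs <- paste(rhs, "+ (1 | mouse_id)")
    as.formula(paste("value ~", rhs))
  }
  fit_ml <- function(f) {
    if (grepl("|", deparse1(f), fixed = TRUE)) {
      suppressMessages(lme4::lmer(
        f, data = d, REML = FALSE,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    check.nobs.vs.nlev = "ignore",
                                    check.nobs.vs.nRE = "ignore",
                                    calc.derivs = FALSE)))
    } else stats::lm(f, data = d)
  }
  full <- fit_ml(fml(fixed0))
  ll_full <- as.numeric(logLik(full))
  lrt <- function(reduced_terms) {
    red <- fit_ml(fml(reduced_terms))
    k <- attr(logLik(full), "df") - attr(logLik(red), "df")
    ch <- max(0, 2 * (ll_full - as.numeric(logLik(red))))
    c(chisq = ch, df = k, p = pchisq(ch, k, lower.tail = FALSE))
  }
  rows <- list()
  add <- function(name, stat, retained) {
    rows[[length(rows) + 1L]] <<- data.frame(
      factor = name, chisq = stat[["chisq"]], df = stat[["df"]],
      p_value = stat[["p"]], retained = retained,
      stringsAsFactors = FALSE)
  }
  na_row <- c(chisq = NA_real_, df = NA_real_, p = NA_real_)
  if (has_mus) {
    s <- lrt(setdiff(fixed0, c("muscle", "muscle:age_group")))
    add("muscle", s, s[["p"]] < alpha)
  } else add("muscle", na_row, NA)
  if (has_grp) {
    s <- lrt(setdiff(fixed0, c("age_group", "muscle:age_group")))
    add("age_group", s, s[["p"]] < alpha)
  } else add("age_group", na_row, NA)
  if (has_mus && has_grp) {
    s <- lrt(setdiff(fixed0, "muscle:age_group"))
    add("muscle:age_group", s, s[["p"]] < alpha)
  } else add("muscle:age_group", na_row, NA)
  # random intercept: boundary test, mixture p-value
  red <- fit_ml(fml(fixed0, random = FALSE))
  ch <- max(0, 2 * (ll_full - as.numeric(logLik(red))))
  p_mix <- 0.5 * pchisq(ch, 1, lower.tail = FALSE)
  add("mouse (random)", c(chisq = ch, df = 1, p = p_mix), p_mix < alpha)
  # section effect: add section_index to the full model
  if (nlevels(d$section_index) > 1L) {
    aug <- fit_ml(fml(c(fixed0, "section_index")))
    k <- attr(logLik(aug), "df") - attr(logLik(full), "df")
    ch <- max(0, 2 * (as.numeric(logLik(aug)) - ll_full))
    p <- pchisq(ch, k, lower.tail = FALSE)
    add("section", c(chisq = ch, df = k, p = p), p < alpha)
  } else add("section", na_row, NA)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
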