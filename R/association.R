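# Association layer: exposure construction, matched (conditional
# logistic) and unmatched regression models, fixed-effect meta-analysis,
# population-attributable risk, family-adjusted prevalence, severity
# score.

#' Build per-child mitochondrial exposures
#'
#' Applies the design-specific comparator rule for carrying a predicted
#' pathogenic (PP) heteroplasmy: in quartets a child carries a PP
#' heteroplasmy if its fraction exceeds that in the sibling at the same
#' site; in dyads, if the fraction increased relative to the mother.
#' Also tallies heteroplasmy counts overall, coding, OXPHOS, tRNA and by
#' VAF stratum, and attaches mtCNz.
#'
#' @param calls Annotated `het_calls` for all children (must carry `pp`,
#'   `vaf`, `category`, `coding_effect`).
#' @param sample_sheet Data.frame with `sample_id`, `family_id`, `role`,
#'   `sex`, `age`, `maternal_age`, `phenotype` (1 = affected), optional
#'   `ancestry`.
#' @param content Optional `mtcnz` data.frame aligned to children via a
#'   `sample_id` column, contributing `mtcnz` and `tertile`.
#' @param design `"quartet"` (sibling comparator) or `"dyad"` (mother
#'   comparator; mother calls supplied in `calls` under the mother's
#'   sample id).
#' @return Data.frame, one row per child: identifiers, `carry_pp`
#'   (logical; `NA` when the comparator is missing), counts
#'   (`n_het`, `n_coding`, `n_oxphos`, `n_trna`, `n_vaf5`, `n_vaf20`),
#'   covariates (missing parental ages imputed with the group mean).
#' @export
build_exposures <- function(calls, sample_sheet, content = NULL,
                            design = c("quartet", "dyad")) {
  design <- match.arg(design)
  calls <- as.data.frame(calls)
  ss <- sample_sheet
  child_roles <- if (design == "quartet") c("proband", "sibling") else "child"
  kids <- ss[ss$role %in% child_roles, , drop = FALSE]
  comparator_id <- function(row) {
    fam <- ss[ss$family_id == row$family_id, ]
    if (design == "quartet")
      fam$sample_id[fam$role %in% child_roles &
                      fam$sample_id != row$sample_id]
    else fam$sample_id[fam$role == "mother"]
  }
  vaf_at <- function(sid, pos, alt) {
    i <- which(calls$sample_id == sid & calls$pos == pos & calls$alt == alt)
    if (length(i)) calls$vaf[i[1L]] else 0
  }
  out <- kids
  out$carry_pp <- NA
  out$n_het <- out$n_coding <- out$n_oxphos <- out$n_trna <-
    out$n_vaf5 <- out$n_vaf20 <- 0L
  for (i in seq_len(nrow(kids))) {
    mine <- calls[calls$sample_id == kids$sample_id[i], , drop = FALSE]
    out$n_het[i] <- nrow(mine)
    out$n_coding[i] <- sum(mine$category %in% c("OXPHOS", "tRNA", "rRNA"))
    out$n_oxphos[i] <- sum(mine$category == "OXPHOS")
    out$n_trna[i] <- sum(mine$category == "tRNA")
    out$n_vaf5[i] <- sum(mine$vaf >= 0.05)
    out$n_vaf20[i] <- sum(mine$vaf >= 0.20)
    comp <- comparator_id(kids[i, ])
    if (length(comp) != 1L) next  # comparator missing: indeterminate
    pp <- mine[which(mine$pp %in% TRUE), , drop = FALSE]
    out$carry_pp[i] <- nrow(pp) > 0 &&
      any(pp$vaf > vapply(seq_len(nrow(pp)), function(j)
        vaf_at(comp, pp$pos[j], pp$alt[j]), numeric(1)))
  }
  if (!is.null(content)) {
    m <- match(out$sample_id, content$sample_id)
    out$mtcnz <- content$mtcnz[m]
    out$tertile <- content$tertile[m]
  }
  if ("maternal_age" %in% names(out))
    out$maternal_age <- impute_mean(out$maternal_age)
  if ("paternal_age" %in% names(out))
    out$paternal_age <- impute_mean(out$paternal_age)
  rownames(out) <- NULL
  out
}

impute_mean <- function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x }

#' Matched within-family association (conditional logistic)
#'
#' Fits `logit(outcome) ~ exposure(s) + strata(family_id)` by conditional
#' maximum likelihood on within-family strata (via `survival::clogit`).
#' For a single binary exposure in 1:1 matched pairs this equals the
#' discordant-pair ratio.
#'
#' @param data Data.frame of children with `family_id` and the model
#'   variables.
#' @param outcome Name of the binary outcome column.
#' @param exposure Name of the primary exposure column.
#' @param covariates Optional further covariate names.
#' @return Object of class `or_fit` for the exposure term.
#' @export
conditional_logistic <- function(data, outcome = "phenotype",
                                 exposure = "carry_pp",
                                 covariates = character()) {
  d <- data[!is.na(data[[exposure]]) & !is.na(data[[outcome]]), , drop = FALSE]
  d$.y <- as.integer(d[[outcome]])
  disc <- tapply(d[[exposure]], d$family_id, function(x)
    length(unique(x)) > 1L)
  if (!any(disc)) stop("no exposure-discordant family")
  fml <- stats::as.formula(paste(
    ".y ~", paste(c(exposure, covariates), collapse = " + "),
    "+ strata(family_id)"))
  fit <- survival::clogit(fml, data = d)
  co <- summary(fit)$coefficients
  term <- rownames(co)[grep(exposure, rownames(co))[1L]]
  est <- co[term, "coef"]; se <- co[term, "se(coef)"]
  separation <- abs(est) > 10 || se > 10
  structure(list(or = exp(est),
                 ci = if (separation) c(0, Inf) else
                   exp(est + c(-1, 1) * stats::qnorm(0.975) * se),
                 p = co[term, "Pr(>|z|)"], fit = fit,
                 separation = separation, term = exposure),
            class = "or_fit")
}

#' Unmatched logistic model with interaction and LRT support
#'
#' Fits `logit(outcome) ~ exposure(s) + covariates` by maximum likelihood
#' (e.g. sex and mtDNA-inferred ancestry for unrelated children).
#' Interaction terms may be written directly in `exposure`
#' (e.g. `"carry_pp * low_tertile"`). `lrt_against` compares against a
#' nested null model by likelihood ratio.
#'
#' @param data Data.frame of children.
#' @param outcome Binary outcome column name.
#' @param exposure Model terms for the exposure side (character, joined
#'   with `+`).
#' @param covariates Covariate names.
#' @param lrt_against Optional character vector of terms for a nested
#'   null model; adds an `lrt_p` element.
#' @return List with `fit`, `coef` (matrix with OR and CI per term) and
#'   optionally `lrt_p`.
#' @export
logistic_model <- function(data, outcome = "phenotype",
                           exposure = "carry_pp",
                           covariates = character(),
                           lrt_against = NULL) {
  y <- data[[outcome]]
  if (length(unique(stats::na.omit(y))) < 2L) stop("outcome is constant")
  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::glm(fml, family = stats::binomial(), data = data)
  cm <- summary(fit)$coefficients
  se <- cm[, "Std. Error"]
  coefs <- cbind(or = exp(cm[, "Estimate"]),
                 ci_low = exp(cm[, "Estimate"] - stats::qnorm(0.975) * se),
                 ci_high = exp(cm[, "Estimate"] + stats::qnorm(0.975) * se),
                 p = cm[, "Pr(>|z|)"])
  out <- list(fit = fit, coef = coefs,
              separation = any(abs(cm[, "Estimate"]) > 10 | se > 10))
  if (!is.null(lrt_against)) {
    null_fml <- if (length(lrt_against))
      stats::reformulate(lrt_against, response = outcome) else
        stats::reformulate("1", response = outcome)
    fit0 <- stats::glm(null_fml, family = stats::binomial(),
                       data = stats::model.frame(fit))
    out$lrt_p <- stats::anova(fit0, fit, test = "Chisq")[2L, "Pr(>Chi)"]
  }
  out
}

#' Inverse-variance fixed-effect meta-analysis of odds ratios
#'
#' Combines per-stratum odds ratios given as point estimates with 95%
#' confidence intervals. Each stratum's log-OR standard error is
#' back-calculated as `(log(ci_high) - log(ci_low)) / (2 * 1.959964)`
#' (symmetric Wald interval on the log scale); strata are combined with
#' inverse-variance weights. Heterogeneity is summarized by Cochran's
#' `Q` (chi-squared, k-1 df) and `I2 = max(0, (Q - (k-1)) / Q)`.
#'
#' @param strata Data.frame with columns `or`, `ci_low`, `ci_high` and
#'   optionally `label`.
#' @return Object of class `meta_result`: list with `or`, `ci_low`,
#'   `ci_high`, `z_p`, `q_stat`, `q_p`, `i2`, `k`, `weights`.
#' @export
fixed_effect_meta <- function(strata) {
  stopifnot(all(c("or", "ci_low", "ci_high") %in% names(strata)))
  if (any(strata$ci_low >= strata$ci_high))
    stop("degenerate confidence interval in stratum input")
  if (any(strata$ci_low <= 0 | strata$or <= 0))
    stop("odds ratios and CI bounds must be positive")
  k <- nrow(strata)
  lo <- log(strata$or)
  se <- (log(strata$ci_high) - log(strata$ci_low)) / (2 * stats::qnorm(0.975))
  w <- 1 / se^2
  lmean <- sum(w * lo) / sum(w)
  se_comb <- sqrt(1 / sum(w))
  z <- lmean / se_comb
  q <- sum(w * (lo - lmean)^2)
  q_p <- if (k > 1L) stats::pchisq(q, k - 1L, lower.tail = FALSE) else NA_real_
  structure(list(
    or = exp(lmean),
    ci_low = exp(lmean - stats::qnorm(0.975) * se_comb),
    ci_high = exp(lmean + stats::qnorm(0.975) * se_comb),
    z_p = 2 * stats::pnorm(-abs(z)),
    q_stat = q, q_p = q_p,
    i2 = if (q > 0) max(0, (q - (k - 1L)) / q) else 0,
    k = k, weights = w), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Fixed-effect meta-analysis of %d strata:\n  OR = %.2f [%.2f-%.2f], P = %.2g\n",
    x$k, x$or, x$ci_low, x$ci_high, x$z_p))
  cat(sprintf("  heterogeneity: Q = %.2f (P = %.2g), I2 = %.0f%%\n",
              x$q_stat, x$q_p, 100 * x$i2))
  invisible(x)
}

#' Population-attributable risk proportion
#'
#' `PAR = p0 * (OR - 1) / (1 + p0 * (OR - 1))` with `p0` the
#' (family-adjusted) exposure prevalence among controls and `OR` the
#' combined effect.
#'
#' @param p0 Exposure prevalence among controls, in \[0, 1\].
#' @param or Odds ratio (> 0).
#' @return The attributable proportion.
#' @export
attributable_risk <- function(p0, or) {
  stopifnot(p0 >= 0, p0 <= 1, or > 0)
  p0 * (or - 1) / (1 + p0 * (or - 1))
}

#' Bootstrap confidence interval for the attributable risk
#'
#' Resamples matched units (families/dyads) with replacement, recomputing
#' the control prevalence and the discordant-pair odds ratio in each
#' resample, and reports percentile limits of the recomputed PAR.
#'
#' @param data Per-child exposure data with `family_id`, `phenotype`,
#'   and the exposure column.
#' @param exposure Exposure column name.
#' @param B Number of resamples (default 1000).
#' @param conf Confidence level.
#' @return List with `par`, `ci`, `B`.
#' @export
attributable_risk_boot <- function(data, exposure = "carry_pp", B = 1000,
                                   conf = 0.95) {
  fams <- unique(data$family_id)
  one <- function(d) {
    ctrl <- d[d$phenotype == 0 & !is.na(d[[exposure]]), ]
    p0 <- mean(ctrl[[exposure]])
    n10 <- n01 <- 0
    for (f in unique(d$family_id)) {
      fd <- d[d$family_id == f, ]
      ca <- fd[[exposure]][fd$phenotype == 1]
      co <- fd[[exposure]][fd$phenotype == 0]
      if (length(ca) == 1L && length(co) == 1L &&
          !is.na(ca) && !is.na(co)) {
        n10 <- n10 + (ca & !co)
        n01 <- n01 + (!ca & co)
      }
    }
    if (n01 == 0 || n10 == 0) return(NA_real_)
    attributable_risk(p0, n10 / n01)
  }
  est <- one(data)
  draws <- vapply(seq_len(B), function(b) {
    pick <- sample(fams, length(fams), replace = TRUE)
    idx <- unlist(lapply(seq_along(pick), function(j)
      which(data$family_id == pick[j])))
    d <- data[idx, , drop = FALSE]
    d$family_id <- rep(seq_along(pick),
                       vapply(pick, function(f)
                         sum(data$family_id == f), 0L))
    one(d)
  }, numeric(1))
  a <- (1 - conf) / 2
  list(par = est,
       ci = unname(stats::quantile(draws, c(a, 1 - a), na.rm = TRUE)),
       B = B)
}

#' Family-adjusted prevalence of an exposure
#'
#' Proportion of children exposed under the design's comparator rule,
#' with a standard error from resampling matched units (families).
#'
#' @param exposed Logical vector of per-child exposure flags.
#' @param family_id Matched-unit labels aligned with `exposed`.
#' @param B Bootstrap resamples for the SEM (default 1000).
#' @return List with `prevalence`, `sem`, `n_families`.
#' @export
family_adjusted_prevalence <- function(exposed, family_id, B = 1000) {
  keep <- !is.na(exposed)
  exposed <- exposed[keep]; family_id <- family_id[keep]
  if (length(exposed) == 0L) stop("no exposure flags supplied")
  fams <- split(exposed, family_id)
  prev <- mean(exposed)
  boot <- vapply(seq_len(B), function(b)
    mean(unlist(fams[sample.int(length(fams), replace = TRUE)])),
    numeric(1))
  list(prevalence = prev, sem = stats::sd(boot),
       n_families = length(fams))
}

#' Phenotype severity score
#'
#' Sum of four binary severity indicators: non-verbal IQ < 70, verbal
#' IQ < 70, adaptive-behavior composite in the cohort's bottom quartile,
#' and (sign-inverted) communication-social total in the bottom quartile.
#' Quartile cutoffs are computed over the supplied cohort. Any missing
#' component yields `NA`.
#'
#' @param nv_iq,v_iq Numeric IQ scores.
#' @param vabs Adaptive-behavior composite (higher = better).
#' @param neg_ados_cs Sign-inverted communication-social total (higher =
#'   better).
#' @return Integer vector of scores 0-4 (`NA` where a component is
#'   missing).
#' @export
severity_score <- function(nv_iq, v_iq, vabs, neg_ados_cs) {
  q_vabs <- stats::quantile(vabs, 0.25, na.rm = TRUE, names = FALSE)
  q_ados <- stats::quantile(neg_ados_cs, 0.25, na.rm = TRUE, names = FALSE)
  as.integer((nv_iq < 70) + (v_iq < 70) + (vabs <= q_vabs) +
               (neg_ados_cs <= q_ados))
}
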