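# Heteroplasmy origin classification (inherited vs de novo), germline
# purifying-selection tests, maternal-age trend and mutation rate.

#' Classify heteroplasmy origin against the maternal lineage
#'
#' A child heteroplasmy is inherited if the sharing test
#' ([sharing_test()]) is positive in any maternal-lineage member (the
#' mother and, in quartet designs, the other child); otherwise de novo;
#' unknown when no maternal pileup is available or all lineage depths are
#' indeterminate. Maternal heteroplasmies are classified transmitted /
#' untransmitted / indeterminate against each child, including secondary
#' heteroplasmies: maternal sites below the primary VAF floor still count
#' as inherited in the child when the sharing test passes.
#'
#' @param child_calls `het_calls` for one child.
#' @param lineage_pileups Named list of pileups for maternal-lineage
#'   members (mother first; optionally the sibling).
#' @param mother_calls Optional `het_calls` for the mother; when given,
#'   each maternal call also receives a transmitted flag from the child
#'   pileup.
#' @param child_pileup Optional child pileup, required for the
#'   transmitted flags.
#' @param error_rate Per-base error rate for the sharing test.
#' @return List with `child`: `child_calls` plus columns `origin`
#'   (`inherited`/`de_novo`/`unknown`) and `maternal_vaf`; and `mother`:
#'   `mother_calls` plus `transmitted` (`TRUE`/`FALSE`/`NA`) and
#'   `child_vaf`, when mother data were supplied.
#' @export
classify_origin <- function(child_calls, lineage_pileups,
                            mother_calls = NULL, child_pileup = NULL,
                            error_rate = 1e-3) {
  child <- as.data.frame(child_calls)
  if (length(lineage_pileups) == 0L) {
    child$origin <- "unknown"
    child$maternal_vaf <- NA_real_
  } else {
    origin <- character(nrow(child))
    mvaf <- numeric(nrow(child))
    mother_p <- lineage_pileups[[1L]]
    for (i in seq_len(nrow(child))) {
      shared <- vapply(lineage_pileups, function(p) {
        ac <- allele_count_at(p, child$pos[i], child$alt[i])
        sharing_test(ac$alt, ac$depth, error_rate = error_rate)
      }, NA)
      origin[i] <- if (any(shared %in% TRUE)) "inherited"
                   else if (all(is.na(shared))) "unknown" else "de_novo"
      am <- allele_count_at(mother_p, child$pos[i], child$alt[i])
      mvaf[i] <- if (am$depth > 0) am$alt / am$depth else NA_real_
    }
    child$origin <- origin
    child$maternal_vaf <- mvaf
  }
  mother <- NULL
  if (!is.null(mother_calls)) {
    mother <- as.data.frame(mother_calls)
    tr <- rep(NA, nrow(mother)); cvaf <- rep(NA_real_, nrow(mother))
    if (!is.null(child_pileup)) {
      for (i in seq_len(nrow(mother))) {
        ac <- allele_count_at(child_pileup, mother$pos[i], mother$alt[i])
        tr[i] <- sharing_test(ac$alt, ac$depth, error_rate = error_rate)
        cvaf[i] <- if (ac$depth > 0) ac$alt / ac$depth else NA_real_
      }
    }
    mother$transmitted <- tr
    mother$child_vaf <- cvaf
  }
  list(child = child, mother = mother)
}

allele_count_at <- function(pileup, pos, alt) {
  i <- match(pos, pileup$pos)
  if (is.na(i)) return(list(alt = 0L, depth = 0L))
  list(alt = pileup[[paste0("fwd_", alt)]][i] +
         pileup[[paste0("rev_", alt)]][i],
       depth = pileup_depth(pileup[i, , drop = FALSE]))
}

#' One-sample t test for purifying selection
#'
#' Tests whether the mean pathogenicity z-score of a heteroplasmy set
#' deviates from 0, the median pathogenicity of all possible changes.
#' A mean below 0 is the purifying-selection signature.
#'
#' @param z Numeric vector of pathogenicity z-scores (n >= 2,
#'   non-constant).
#' @return List with `mean_z`, `t_p` (two-sided), `n`.
#' @export
selection_t_test <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) < 2L || stats::sd(z) == 0)
    stop("need >= 2 non-constant z values")
  tt <- stats::t.test(z, mu = 0)
  list(mean_z = mean(z), t_p = tt$p.value, n = length(z))
}

#' Stratified-resampling selection test ("P for selection")
#'
#' Compares the observed mean pathogenicity z-score with means of random
#' resamples of nucleotide changes drawn from the change universe to
#' match the observed composition exactly: the same number of changes per
#' gene category and, jointly within category, the same number of
#' transitions and transversions. Resampling is without replacement
#' within each (category x transition) stratum. The default lower-tail
#' probability targets purifying selection;
#' `boot_p = (1 + #{resample mean <= observed}) / (B + 1)`.
#'
#' @param z_obs Observed z-scores of the heteroplasmy set.
#' @param universe Data.frame with columns `z`, `category`, `transition`
#'   covering the full change universe.
#' @param composition Optional data.frame (`category`, `transition`,
#'   `n`); defaults to the composition of `z_obs` taken from columns
#'   `category`/`transition` attached to it via a data.frame input.
#' @param obs Alternative input: data.frame with `z`, `category`,
#'   `transition` for the observed set (supersedes `z_obs`).
#' @param B Number of resamples (default 1e5).
#' @param tail `"lower"` (purifying, default) or `"two.sided"`.
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `selection_test`: list with `mean_z`,
#'   `boot_p`, `B`, `tail`, `n`, `composition`.
#' @export
selection_bootstrap <- function(z_obs = NULL, universe, composition = NULL,
                                obs = NULL, B = 1e5,
                                tail = c("lower", "two.sided"),
                                seed = NULL) {
  tail <- match.arg(tail)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(obs)) {
    z_obs <- obs$z
    composition <- stats::aggregate(
      list(n = obs$z), by = list(category = obs$category,
                                 transition = obs$transition), FUN = length)
  }
  if (is.null(composition))
    stop("supply `obs` (with category/transition) or an explicit composition")
  z_obs <- z_obs[!is.na(z_obs)]
  mean_obs <- mean(z_obs)
  n_tot <- sum(composition$n)

  strata <- list()
  for (i in seq_len(nrow(composition))) {
    zs <- universe$z[universe$category == composition$category[i] &
                       universe$transition == composition$transition[i]]
    zs <- zs[!is.na(zs)]
    if (length(zs) < composition$n[i])
      stop("universe stratum too small: ", composition$category[i],
           ifelse(composition$transition[i], " transition", " transversion"))
    strata[[i]] <- list(z = zs, n = composition$n[i])
  }
  sums <- numeric(B)
  for (b in seq_len(B)) {
    s <- 0
    for (st in strata)
      s <- s + sum(st$z[sample.int(length(st$z), st$n)])
    sums[b] <- s
  }
  means <- sums / n_tot
  p_low <- (1 + sum(means <= mean_obs)) / (B + 1)
  p_high <- (1 + sum(means >= mean_obs)) / (B + 1)
  boot_p <- switch(tail, lower = p_low,
                   two.sided = min(1, 2 * min(p_low, p_high)))
  structure(list(mean_z = mean_obs, boot_p = boot_p, B = B, tail = tail,
                 n = n_tot, composition = composition),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf(
    "Stratified-resampling selection test: n = %d, mean z = %.3f\n", x$n,
    x$mean_z))
  cat(sprintf("P for selection (%s tail, B = %d) = %.3g\n", x$tail, x$B,
              x$boot_p))
  invisible(x)
}

#' Transmission odds per SD of pathogenicity
#'
#' Logistic regression of the transmission indicator of maternal
#' heteroplasmies on the pathogenicity z-score with gene-class, maternal
#' VAF and child-sex covariates:
#' `logit(transmitted) ~ z + RNA-or-OXPHOS + maternal VAF + sex`.
#' Reports the odds ratio of transmission per SD of pathogenicity z with
#' a 95% Wald confidence interval. Complete separation is flagged and the
#' interval reported as unbounded.
#'
#' @param records Data.frame with columns `transmitted` (logical),
#'   `z`, and optionally `category`, `maternal_vaf`, `sex`.
#' @return Object of class `or_fit`: list with `or`, `ci`, `p`, `fit`,
#'   `separation`.
#' @export
transmission_model <- function(records) {
  r <- records[!is.na(records$transmitted) & !is.na(records$z), , drop = FALSE]
  if (sum(r$transmitted) < 10 || sum(!r$transmitted) < 10)
    stop("need >= 10 transmitted and >= 10 untransmitted heteroplasmies")
  covs <- "z"
  for (nm in c("category", "maternal_vaf", "sex"))
    if (nm %in% names(r) && length(unique(r[[nm]])) > 1L)
      covs <- c(covs, nm)
  fit <- stats::glm(stats::reformulate(covs, response = "transmitted"),
                    family = stats::binomial(), data = r)
  co <- summary(fit)$coefficients["z", ]
  separation <- abs(co["Estimate"]) > 10 || co["Std. Error"] > 10
  ci <- if (separation) c(0, Inf) else
    exp(co["Estimate"] + c(-1, 1) * stats::qnorm(0.975) * co["Std. Error"])
  structure(list(or = unname(exp(co["Estimate"])), ci = unname(ci),
                 p = unname(co["Pr(>|z|)"]), fit = fit,
                 separation = separation, term = "z"),
            class = "or_fit")
}

#' @export
print.or_fit <- function(x, ...) {
  cat(sprintf("OR per unit %s = %.3f [95%% CI %.3f-%.3f], P = %.2g%s\n",
              x$term, x$or, x$ci[1L], x$ci[2L], x$p,
              if (isTRUE(x$separation)) " (separation flagged)" else ""))
  invisible(x)
}

#' Maternal-age trend of de novo heteroplasmy counts
#'
#' Linear regression of per-child de novo heteroplasmy counts on maternal
#' age at childbirth; with a group label, the group x age interaction
#' tests slope heterogeneity between cases and controls; a paternal-age
#' covariate may be added.
#'
#' @param counts Integer vector of de novo counts per child.
#' @param maternal_age Numeric vector of maternal ages at childbirth.
#' @param group Optional factor (e.g. case/control).
#' @param paternal_age Optional numeric covariate.
#' @return List with `slope`, `ci`, `p` and, when `group` is supplied,
#'   `interaction_p`; the `lm` fit under `fit`.
#' @export
maternal_age_trend <- function(counts, maternal_age, group = NULL,
                               paternal_age = NULL) {
  if (length(counts) < 10L) stop("need n >= 10 children")
  if (stats::sd(maternal_age, na.rm = TRUE) == 0)
    stop("maternal age is constant")
  df <- data.frame(y = counts, age = maternal_age)
  terms <- "age"
  if (!is.null(paternal_age)) { df$pat <- paternal_age; terms <- c(terms, "pat") }
  inter_p <- NULL
  if (!is.null(group)) {
    df$group <- factor(group)
    fit <- stats::lm(stats::reformulate(c("age * group",
                                          setdiff(terms, "age")),
                                        response = "y"), data = df)
    cm <- summary(fit)$coefficients
    irow <- grep("^age:group", rownames(cm))
    inter_p <- unname(cm[irow, "Pr(>|t|)"])[1L]
  } else {
    fit <- stats::lm(stats::reformulate(terms, response = "y"), data = df)
  }
  cm <- summary(fit)$coefficients
  est <- cm["age", "Estimate"]; se <- cm["age", "Std. Error"]
  out <- list(slope = est,
              ci = est + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se,
              p = cm["age", "Pr(>|t|)"], fit = fit)
  if (!is.null(inter_p)) out$interaction_p <- inter_p
  out
}

#' mtDNA germline mutation rate
#'
#' Point estimate of the per-site per-generation mutation rate from
#' per-child de novo heteroplasmy counts:
#' `rate = sum(counts) / (n_children * callable_sites) / detectable_fraction`.
#' The detectability correction is an explicit user input and is off
#' (factor 1) by default.
#'
#' @param de_novo_counts Integer vector (one entry per child).
#' @param callable_sites Number of callable mtDNA sites.
#' @param detectable_fraction Probability that a true de novo event is
#'   detectable at the study's depth and VAF floor, in (0, 1].
#' @return Rate per site per generation.
#' @export
mutation_rate <- function(de_novo_counts, callable_sites,
                          detectable_fraction = 1) {
  n <- length(de_novo_counts)
  if (n == 0L) stop("no children supplied")
  stopifnot(callable_sites > 0, detectable_fraction > 0,
            detectable_fraction <= 1)
  sum(de_novo_counts) / (n * callable_sites) / detectable_fraction
}
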