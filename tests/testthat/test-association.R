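make_family_calls <- function(rows) {
  calls <- do.call(rbind, rows)
  class(calls) <- c("het_calls", "data.frame")
  calls
}

call_row <- function(sid, pos, vaf, pp = TRUE) {
  data.frame(sample_id = sid, pos = pos, ref = "A", major = "A", alt = "G",
             vaf = vaf, minor_count = round(vaf * 2000), depth = 2000,
             llq = 30, strand_p = 0.5, secondary = FALSE,
             origin = "unknown", pp = pp, category = "OXPHOS",
             coding_effect = "nonsynonymous", z = -0.5,
             stringsAsFactors = FALSE)
}

test_that("the comparator rule decides who carries a PP heteroplasmy", {
  sheet <- data.frame(
    sample_id = c("m1", "f1", "p1", "s1"), family_id = "fam1",
    role = c("mother", "father", "proband", "sibling"),
    sex = c("F", "M", "M", "F"), age = c(40, 42, 10, 12),
    maternal_age = c(NA, NA, 30, 30), phenotype = c(NA, NA, 1, 0),
    stringsAsFactors = FALSE)
  # same PP site: proband 10% vs sibling 12% - only the sibling carries
  calls <- make_family_calls(list(call_row("p1", 5000, 0.10),
                                  call_row("s1", 5000, 0.12)))
  ex <- build_exposures(calls, sheet, design = "quartet")
  expect_false(ex$carry_pp[ex$sample_id == "p1"])
  expect_true(ex$carry_pp[ex$sample_id == "s1"])
  # counts tally by class
  expect_equal(ex$n_het[ex$sample_id == "p1"], 1L)
  expect_equal(ex$n_oxphos[ex$sample_id == "p1"], 1L)
  expect_equal(ex$n_vaf5[ex$sample_id == "p1"], 1L)
  expect_equal(ex$n_vaf20[ex$sample_id == "p1"], 0L)
  # missing comparator: indeterminate
  sheet_solo <- sheet[sheet$role != "sibling", ]
  ex2 <- build_exposures(calls[calls$sample_id == "p1", ], sheet_solo,
                         design = "quartet")
  expect_true(is.na(ex2$carry_pp))
})

test_that("the dyad rule exposes children whose PP fraction increased", {
  sheet <- data.frame(
    sample_id = c("m1", "c1"), family_id = "d1",
    role = c("mother", "child"), sex = c("F", "M"), age = c(28, 0),
    maternal_age = c(NA, 28), phenotype = c(NA, 1),
    stringsAsFactors = FALSE)
  # de novo in the child (absent in the mother): exposed
  calls <- make_family_calls(list(call_row("c1", 6000, 0.05)))
  ex <- build_exposures(calls, sheet, design = "dyad")
  expect_true(ex$carry_pp)
  # present in the mother at a higher fraction: not exposed
  calls2 <- make_family_calls(list(call_row("c1", 6000, 0.05),
                                   call_row("m1", 6000, 0.08)))
  ex2 <- build_exposures(calls2, sheet, design = "dyad")
  expect_false(ex2$carry_pp)
})

test_that("exposures built from noise-free calls match the generator truth", {
  sim <- cached("truth_expo_sim", function()
    simulate_families(sim_config(n_families = 150, seed = 44),
                      test_ref(), test_scores(), test_universe()))
  # noise-free calls: the truth table itself presented as calls
  tru <- sim$truth
  kids <- tru[tru$role %in% c("proband", "sibling"), ]
  calls <- data.frame(sample_id = kids$sample_id, pos = kids$pos,
                      ref = kids$ref, major = kids$ref, alt = kids$alt,
                      vaf = kids$vaf, minor_count = 100L, depth = 2000L,
                      llq = 30, strand_p = 0.5, secondary = FALSE,
                      origin = kids$origin, pp = kids$pp,
                      category = kids$category,
                      coding_effect = kids$coding_effect, z = kids$z,
                      stringsAsFactors = FALSE)
  class(calls) <- c("het_calls", "data.frame")
  built <- build_exposures(calls, sim$sample_sheet, design = "quartet")
  truth <- true_exposures(sim)
  m <- match(built$sample_id, truth$sample_id)
  expect_gte(mean(built$carry_pp == truth$carry_pp[m]), 0.99)
})

test_that("conditional logistic equals the discordant-pair closed form", {
  d <- do.call(rbind, lapply(1:120, function(f) {
    expo <- if (f <= 30) c(TRUE, FALSE) else if (f <= 50)
      c(FALSE, TRUE) else c(FALSE, FALSE)
    data.frame(family_id = f, phenotype = c(1, 0), carry_pp = expo)
  }))
  r <- conditional_logistic(d)
  expect_equal(r$or, 30 / 20, tolerance = 1e-6)
  # 25 proband-exposed and 25 sibling-exposed discordant pairs
  d_eq <- d; d_eq$carry_pp[d_eq$family_id <= 50] <-
    rep(c(TRUE, FALSE, FALSE, TRUE), 25)[1:100]
  expect_equal(conditional_logistic(d_eq)$or, 1, tolerance = 1e-6)
  d_conc <- d; d_conc$carry_pp <- FALSE
  expect_error(conditional_logistic(d_conc), "discordant")
})

test_that("the unmatched logistic layer supports interactions and LRT", {
  set.seed(12)
  n <- 800
  d <- data.frame(phenotype = rbinom(n, 1, 0.3),
                  carry_pp = rbinom(n, 1, 0.1) == 1,
                  sex = sample(c("M", "F"), n, TRUE),
                  mtcnz = rnorm(n))
  r <- logistic_model(d, covariates = c("sex", "mtcnz"))
  ci <- r$coef["carry_ppTRUE", c("ci_low", "ci_high")]
  expect_true(ci[1] <= 1 && 1 <= ci[2])  # null data: CI covers OR 1
  r2 <- logistic_model(d, exposure = "carry_pp * mtcnz",
                       lrt_against = c("carry_pp", "mtcnz"))
  expect_true(r2$lrt_p > 0 && r2$lrt_p <= 1)
  expect_error(logistic_model(transform(d, phenotype = 1)), "constant")
})

test_that("fixed-effect meta matches an independent implementation", {
  skip_if_not_installed("metafor")
  set.seed(33)
  for (rep in 1:5) {
    k <- sample(2:5, 1)
    lo <- rnorm(k, 0.4, 0.3)
    se <- runif(k, 0.1, 0.5)
    strata <- data.frame(or = exp(lo),
                         ci_low = exp(lo - qnorm(0.975) * se),
                         ci_high = exp(lo + qnorm(0.975) * se))
    m <- fixed_effect_meta(strata)
    rma <- metafor::rma(yi = lo, sei = se, method = "FE")
    expect_equal(log(m$or), as.numeric(rma$beta), tolerance = 1e-8)
    expect_equal(m$q_stat, rma$QE, tolerance = 1e-8)
    expect_equal(m$z_p, rma$pval, tolerance = 1e-8)
    # convexity: the combined OR lies within the stratum range
    expect_gte(m$or, min(strata$or))
    expect_lte(m$or, max(strata$or))
  }
})

test_that("degenerate and single-stratum meta inputs behave as defined", {
  se <- 0.2
  s1 <- data.frame(or = 1.5, ci_low = exp(log(1.5) - qnorm(0.975) * se),
                   ci_high = exp(log(1.5) + qnorm(0.975) * se))
  m1 <- fixed_effect_meta(s1)
  expect_equal(m1$or, 1.5)
  expect_equal(m1$ci_low, s1$ci_low, tolerance = 1e-6)
  expect_equal(m1$ci_high, s1$ci_high, tolerance = 1e-6)
  twin <- rbind(s1, s1)
  m2 <- fixed_effect_meta(twin)
  expect_equal(m2$or, 1.5)
  expect_equal(m2$q_stat, 0)
  expect_equal(m2$i2, 0)
  expect_error(fixed_effect_meta(
    data.frame(or = 1.5, ci_low = 1.5, ci_high = 1.5)), "degenerate")
})

test_that("attributable risk follows the prevalence-odds formula", {
  expect_equal(attributable_risk(0.3, 1), 0)
  p0 <- 0.05; or <- 1.56
  expect_equal(attributable_risk(p0, or),
               p0 * (or - 1) / (1 + p0 * (or - 1)))
  expect_equal(attributable_risk(0.05, 1.56), 0.0272, tolerance = 1e-2)
  # monotone in both arguments over a grid
  grid_p <- seq(0.01, 0.5, length.out = 8)
  grid_or <- seq(1, 4, length.out = 8)
  vals <- outer(grid_p, grid_or, Vectorize(attributable_risk))
  expect_true(all(apply(vals, 2, diff) >= 0))
  expect_true(all(apply(vals, 1, diff) >= 0))
})

test_that("bootstrap PAR and family-adjusted prevalence are calibrated", {
  set.seed(55)
  n_fam <- 500
  p_expo <- 0.1
  d <- do.call(rbind, lapply(seq_len(n_fam), function(f)
    data.frame(family_id = f, phenotype = c(1, 0),
               carry_pp = runif(2) < p_expo)))
  fp <- family_adjusted_prevalence(d$carry_pp, d$family_id, B = 500)
  expect_equal(fp$prevalence, mean(d$carry_pp))
  expect_equal(fp$sem, sqrt(p_expo * (1 - p_expo) / (2 * n_fam)),
               tolerance = 0.25)
  # order invariance
  perm <- sample(nrow(d))
  expect_equal(family_adjusted_prevalence(d$carry_pp[perm],
                                          d$family_id[perm],
                                          B = 10)$prevalence,
               fp$prevalence)
  all_in <- family_adjusted_prevalence(rep(TRUE, 20), rep(1:10, 2), B = 50)
  expect_equal(all_in$prevalence, 1)
  expect_equal(all_in$sem, 0)
  pb <- attributable_risk_boot(d, B = 100)
  n10 <- sum(tapply(seq_len(nrow(d)), d$family_id, function(i)
    d$carry_pp[i][d$phenotype[i] == 1] & !d$carry_pp[i][d$phenotype[i] == 0]))
  n01 <- sum(tapply(seq_len(nrow(d)), d$family_id, function(i)
    !d$carry_pp[i][d$phenotype[i] == 1] & d$carry_pp[i][d$phenotype[i] == 0]))
  p0 <- mean(d$carry_pp[d$phenotype == 0])
  expect_equal(pb$par, attributable_risk(p0, n10 / n01))
  expect_true(pb$ci[1] <= pb$par && pb$par <= pb$ci[2])
})

test_that("the severity score is the sum of its four indicators", {
  nv <- c(65, 90, 100, NA)
  v <- c(60, 95, 100, 80)
  vabs <- c(40, 70, 90, 85)      # 40 is the bottom quartile here
  ados <- c(-12, -5, -3, -4)     # -12 is the bottom quartile
  s <- severity_score(nv, v, vabs, ados)
  expect_equal(s[1], 4L)
  expect_equal(s[3], 0L)
  expect_true(is.na(s[4]))
  # oracle: direct indicator sum on random synthetic traits
  set.seed(77)
  nv <- rnorm(200, 85, 20); v <- rnorm(200, 85, 20)
  vb <- rnorm(200, 70, 15); ad <- -rnorm(200, 10, 3)
  expected <- (nv < 70) + (v < 70) +
    (vb <= quantile(vb, 0.25)) + (ad <= quantile(ad, 0.25))
  expect_equal(severity_score(nv, v, vb, ad), as.integer(expected))
})
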