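# Synthetic family-data generator: families/dyads, germline heteroplasmy
# transmission through a bottleneck with pathogenicity-dependent
# selection, maternal-age-dependent de novo mutation, read-level pileups
# with a sequencing-error floor, heritable mtDNA content, and disease
# phenotypes - with truth tables for every stage.

#' Simulation configuration
#'
#' Defaults encode the study conditions the analysis layers assume: a
#' ~0.02% per-base error floor, transmission odds 0.64 per SD of
#' pathogenicity, disease odds 1.5 for carrying a predicted pathogenic
#' heteroplasmy with a low-content interaction, and mtDNA-content
#' heritability 0.65 (parent-child r ~ h2/2) declining with age.
#'
#' @param n_families Number of families or dyads.
#' @param design `"quartet"` (mother/father/proband/sibling) or `"dyad"`
#'   (mother/child).
#' @param seed Integer; fully determines the output. Families use
#'   independent derived streams so growing `n_families` does not perturb
#'   earlier families.
#' @param depth_mean,depth_sd Unique-read depth distribution per site.
#' @param error_floor Per-base variant-allele error rate (default 2e-4).
#' @param baq_phred_mean Mean per-base quality (Phred; default 33).
#' @param q30_frac Fraction of bases with BAQ >= 30 (default 0.9).
#' @param bottleneck_n Effective germline segregating units (default 30).
#' @param mu De novo mutations per site per generation at the reference
#'   maternal age of 30 (default 2e-5; see the methods vignette).
#' @param maternal_age_slope Additional expected de novo heteroplasmies
#'   per year of maternal age (default 0.012).
#' @param de_novo_z_age_shift Location shift of de novo pathogenicity z
#'   per year of maternal age (default 0.02; direction only in the
#'   source data).
#' @param selection_or_per_sd Transmission odds ratio per SD of
#'   pathogenicity z (default 0.64; 1 disables selection).
#' @param het_rate Mean number of heteroplasmies per parent (default 1.5).
#' @param transition_prob Unused placeholder retained for the error
#'   model; substitutions follow the change universe.
#' @param pp_asd_or Disease odds ratio of carrying a PP heteroplasmy
#'   (default 1.5).
#' @param pp_low_interaction_or Extra odds multiplier for PP carriers in
#'   the low-content tertile (default 1.65; 1 disables the interaction).
#' @param content_or_per_sd Disease odds per SD of mtDNA-content z
#'   (default 0.7).
#' @param base_prevalence Disease prevalence at baseline for unmatched
#'   (dyad) designs (default 0.15).
#' @param content_h2 Narrow-sense heritability of mtDNA content
#'   (default 0.65).
#' @param content_mean,content_sd Raw content location/scale (copies per
#'   diploid genome; defaults 160, 40).
#' @param content_age_slope Raw content change per year of age (default
#'   -1.2; negative).
#' @param vaf_overdispersion Beta overdispersion of observed VAF around
#'   truth (0 = pure binomial reads).
#' @param strand_bias_frac Fraction of error events injected on a single
#'   strand (0 = strand-symmetric errors); exercises the strand filter.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_families = 200, design = c("quartet", "dyad"),
                       seed = 1, depth_mean = 4000, depth_sd = 900,
                       error_floor = 2e-4, baq_phred_mean = 33,
                       q30_frac = 0.9, bottleneck_n = 30, mu = 2e-5,
                       maternal_age_slope = 0.012,
                       de_novo_z_age_shift = 0.02,
                       selection_or_per_sd = 0.64, het_rate = 1.5,
                       transition_prob = 0.97, pp_asd_or = 1.5,
                       pp_low_interaction_or = 1.65,
                       content_or_per_sd = 0.7, base_prevalence = 0.15,
                       content_h2 = 0.65, content_mean = 160,
                       content_sd = 40, content_age_slope = -1.2,
                       vaf_overdispersion = 0, strand_bias_frac = 0) {
  design <- match.arg(design)
  cfg <- as.list(environment())
  if (cfg$n_families < 1) stop("n_families must be >= 1")
  if (cfg$bottleneck_n < 1) stop("bottleneck_n must be >= 1")
  if (cfg$content_h2 < 0 || cfg$content_h2 > 1)
    stop("content_h2 must lie in [0, 1]")
  for (nm in c("error_floor", "q30_frac", "vaf_overdispersion",
               "strand_bias_frac", "base_prevalence"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  if (cfg$mu < 0) stop("mu must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

family_seed <- function(config, i) {
  (config$seed %% 100000L) * 20011L + i * 7L
}

#' Synthetic pathogenicity score table
#'
#' Generates a predictor score table over the full OXPHOS and tRNA change
#' universes with realistic marginals: correlated CADD-like raw/Phred
#' scores, PolyPhen-2-like categories and MutPred-like scores for protein
#' changes; MitoTIP-like raw scores for tRNA changes; sparse confirmed
#' disease-mutation and ClinVar-benign flags; and population frequencies
#' concentrated at 0 with a common-polymorphism tail.
#'
#' @param ref_obj A [mito_reference()].
#' @param seed Integer seed.
#' @return Data.frame usable with [classify_pp()] and
#'   [annotate_pathogenicity()]: `pos`, `ref`, `alt`, `cadd_raw`,
#'   `cadd_phred`, `polyphen_cat`, `mutpred`, `mitotip_raw`,
#'   `md_confirmed`, `clinvar_benign`, `pop_freq_max`.
#' @export
simulate_score_table <- function(ref_obj, seed = 1) {
  set.seed(seed)
  uo <- enumerate_changes(ref_obj, "OXPHOS")
  ut <- enumerate_changes(ref_obj, "tRNA")
  n_o <- nrow(uo); n_t <- nrow(ut)
  cadd_raw <- stats::rnorm(n_o)
  r <- rank(cadd_raw) / n_o
  uo$cadd_raw <- cadd_raw
  uo$cadd_phred <- -10 * log10(1 - r + 1 / (2 * n_o))  # monotone in raw
  uo$polyphen_cat <- ifelse(r > 0.85, "probably",
                            ifelse(r > 0.6, "possibly", "benign"))
  uo$mutpred <- stats::plogis(stats::qlogis(r) * 0.8 +
                                stats::rnorm(n_o, 0, 0.5))
  uo$mitotip_raw <- NA_real_
  ut$cadd_raw <- NA_real_
  ut$cadd_phred <- NA_real_
  ut$polyphen_cat <- NA_character_
  ut$mutpred <- NA_real_
  ut$mitotip_raw <- stats::rnorm(n_t, 8, 4)
  u <- rbind(uo, ut)
  n <- nrow(u)
  u$md_confirmed <- stats::runif(n) < 0.003
  u$clinvar_benign <- stats::runif(n) < 0.01
  common <- stats::runif(n) < 0.02
  u$pop_freq_max <- ifelse(common, stats::runif(n, 0.001, 0.2), 0)
  u[, c("pos", "ref", "alt", "cadd_raw", "cadd_phred", "polyphen_cat",
        "mutpred", "mitotip_raw", "md_confirmed", "clinvar_benign",
        "pop_freq_max")]
}

# Full change universe with pathogenicity z, PP truth flag and coding
# consequence; the sampling frame for maternal and de novo heteroplasmies.
build_truth_universe <- function(ref_obj, scores) {
  uo <- enumerate_changes(ref_obj, "OXPHOS")
  ut <- enumerate_changes(ref_obj, "tRNA")
  key <- function(d) paste(d$pos, d$ref, d$alt, sep = ":")
  skey <- key(scores)
  co <- oxphos_consequences(ref_obj)
  uo$coding_effect <- co$coding_effect[match(paste(uo$pos, uo$alt),
                                             paste(co$pos, co$alt))]
  ut$coding_effect <- "tRNA"
  uo$z <- pathogenicity_z(scores$cadd_raw[match(key(uo), skey)])
  ut$z <- pathogenicity_z(scores$mitotip_raw[match(key(ut), skey)])
  u <- rbind(uo, ut)
  sc <- scores[match(key(u), skey), , drop = FALSE]
  u$pp <- classify_pp(sc, u$coding_effect)
  u$pp[is.na(u$pp)] <- FALSE
  u
}

#' Germline transmission of one maternal heteroplasmy
#'
#' Single-generation bottleneck: the child's allele count is a binomial
#' draw of `bottleneck_n` segregating units at the maternal fraction.
#' Purifying selection acts on the transmission probability: the odds of
#' transmission (survival through the bottleneck) are multiplied by
#' `selection_or_per_sd` per SD of pathogenicity z, so a logistic refit
#' of transmission on z recovers `log(selection_or_per_sd)`.
#'
#' @param maternal_vaf Maternal fraction, strictly in (0, 1).
#' @param pathogenicity_z Pathogenicity z-score of the variant (`NA`
#'   treated as 0).
#' @param config A [sim_config()].
#' @return The child's true fraction in \[0, 1\] (0 = lost).
#' @export
transmit_heteroplasmy <- function(maternal_vaf, pathogenicity_z, config) {
  if (maternal_vaf <= 0 || maternal_vaf >= 1)
    stop("maternal_vaf must lie strictly in (0, 1)")
  z <- if (is.na(pathogenicity_z)) 0 else pathogenicity_z
  N <- config$bottleneck_n
  p_survive <- 1 - (1 - maternal_vaf)^N
  p_trans <- stats::plogis(stats::qlogis(p_survive) +
                             log(config$selection_or_per_sd) * z)
  if (stats::runif(1) >= p_trans) return(0)
  k <- 0L
  while (k == 0L) k <- stats::rbinom(1L, N, maternal_vaf)
  k / N
}

#' De novo heteroplasmies for one child
#'
#' The number of new heteroplasmies is Poisson with mean linear in
#' maternal age at childbirth: `n_unmasked * mu` at the reference age of
#' 30 plus `maternal_age_slope` per year. Positions are drawn from the
#' unmasked OXPHOS/tRNA change universe with sampling weights tilted by
#' `exp(de_novo_z_age_shift * (age - 30) * z)`, giving the
#' age-dependent pathogenicity location shift.
#'
#' @param maternal_age Maternal age at childbirth in years (15-50).
#' @param config A [sim_config()].
#' @param universe Truth universe from the generator (columns `pos`,
#'   `ref`, `alt`, `z`, `category`, `coding_effect`, `pp`, `masked`).
#' @return Data.frame of new heteroplasmies (possibly empty) with a true
#'   `vaf` per event.
#' @export
simulate_de_novo <- function(maternal_age, config, universe) {
  if (maternal_age < 15 || maternal_age > 50)
    stop("maternal_age outside plausible range [15, 50]")
  un <- if (any(universe$masked))
    universe[!universe$masked, , drop = FALSE] else universe
  lambda <- (nrow(un) / 3) * config$mu +
    config$maternal_age_slope * (maternal_age - 30)
  if (lambda < 0) stop("negative de novo mean; check maternal_age_slope")
  k <- stats::rpois(1L, lambda)
  if (k == 0L) {
    out <- un[0, , drop = FALSE]
    out$vaf <- numeric(0)
    return(out)
  }
  w <- exp(config$de_novo_z_age_shift * (maternal_age - 30) * un$z)
  idx <- sample.int(nrow(un), k, replace = FALSE, prob = w)
  out <- un[idx, , drop = FALSE]
  out$vaf <- pmin(0.5, pmax(0.015, stats::rbeta(k, 0.6, 10)))
  rownames(out) <- NULL
  out
}

#' Heritable, age-declining mtDNA content
#'
#' Additive-genetic decomposition on the standardized scale: parents
#' carry genetic values `a ~ N(0, h2)` and environmental deviations
#' `e ~ N(0, 1 - h2)`; a child's genetic value is the midparent mean plus
#' Mendelian-segregation noise `N(0, h2/2)`. Raw content is
#' `content_mean + content_age_slope * (age - 10) + content_sd * (a + e)`,
#' so midparent-offspring regression has slope h2 and parent-child
#' correlation ~ h2/2 on the standardized scale.
#'
#' @param n_families Number of families.
#' @param child_ages Matrix/list of child ages per family (vector of one
#'   or two ages recycled across families), or a single number.
#' @param parent_age Mean parental age (scalar or per-family).
#' @param config A [sim_config()].
#' @return List of data.frames `parents` (`family_id`, `who`, `age`,
#'   `content`, `z_std`) and `children` (`family_id`, `child`, `age`,
#'   `content`, `z_std`).
#' @export
simulate_content <- function(n_families, child_ages = 10,
                             parent_age = 40, config = sim_config()) {
  h2 <- config$content_h2
  if (h2 < 0 || h2 > 1) stop("content_h2 must lie in [0, 1]")
  am <- stats::rnorm(n_families, 0, sqrt(h2))
  af <- stats::rnorm(n_families, 0, sqrt(h2))
  em <- stats::rnorm(n_families, 0, sqrt(1 - h2))
  ef <- stats::rnorm(n_families, 0, sqrt(1 - h2))
  pa <- rep_len(parent_age, n_families)
  raw <- function(age, zstd)
    config$content_mean + config$content_age_slope * (age - 10) +
      config$content_sd * zstd
  parents <- rbind(
    data.frame(family_id = seq_len(n_families), who = "mother", age = pa,
               z_std = am + em),
    data.frame(family_id = seq_len(n_families), who = "father", age = pa,
               z_std = af + ef))
  parents$content <- raw(parents$age, parents$z_std)
  ca <- if (is.matrix(child_ages)) child_ages else
    matrix(rep_len(unlist(child_ages), 2 * n_families), ncol = 2)
  n_children <- ncol(ca)
  children <- do.call(rbind, lapply(seq_len(n_children), function(j) {
    ac <- (am + af) / 2 + stats::rnorm(n_families, 0, sqrt(h2 / 2))
    ec <- stats::rnorm(n_families, 0, sqrt(1 - h2))
    data.frame(family_id = seq_len(n_families), child = j, age = ca[, j],
               z_std = ac + ec)
  }))
  children$content <- raw(children$age, children$z_std)
  list(parents = parents, children = children)
}

#' Disease phenotype from mitochondrial exposures
#'
#' Liability model: the log-odds of disease increase by `log(pp_asd_or)`
#' for carrying a PP heteroplasmy, by a further
#' `log(pp_low_interaction_or)` for carriers in the low-content tertile,
#' and by `log(content_or_per_sd)` per SD of content z. In the matched
#' (quartet) design exactly one of the two children is designated the
#' proband, chosen with probability proportional to its disease odds
#' (retrospective ascertainment of one affected child per family), so a
#' conditional-logistic refit recovers the configured effects. In the
#' dyad design each child's status is an independent Bernoulli draw.
#'
#' @param exposures Data.frame with `family_id`, `carry_pp` (logical),
#'   `low_tertile` (logical), `content_z` (numeric); for quartets two
#'   rows per family.
#' @param config A [sim_config()].
#' @return Integer phenotype vector aligned with `exposures` (1 =
#'   affected).
#' @export
simulate_phenotype <- function(exposures, config) {
  eta <- log(config$pp_asd_or) * as.numeric(exposures$carry_pp) +
    log(config$pp_low_interaction_or) *
      as.numeric(exposures$carry_pp & exposures$low_tertile) +
    log(config$content_or_per_sd) * exposures$content_z
  if (config$design == "quartet") {
    y <- integer(nrow(exposures))
    for (f in unique(exposures$family_id)) {
      i <- which(exposures$family_id == f)
      stopifnot(length(i) == 2L)
      p1 <- stats::plogis(eta[i[1L]] - eta[i[2L]])
      pro <- if (stats::runif(1) < p1) i[1L] else i[2L]
      y[pro] <- 1L
    }
    y
  } else {
    stats::rbinom(nrow(exposures), 1L,
                  stats::plogis(stats::qlogis(config$base_prevalence) + eta))
  }
}

#' Simulate a family cohort with truth tables
#'
#' Generates the full synthetic study: pedigrees with ages and sexes,
#' maternal heteroplasmies transmitted through the germline bottleneck
#' with pathogenicity-dependent selection, maternal-age-dependent de novo
#' mutations, parent-child-correlated mtDNA content declining with age,
#' and disease phenotypes. Fathers never transmit. Each family uses an
#' independent random stream derived from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param ref_obj A [mito_reference()].
#' @param scores Score table from [simulate_score_table()]; generated
#'   from `config$seed` when `NULL`.
#' @param universe Optional precomputed truth universe (reused across
#'   calls for speed).
#' @return List of class `mito_sim`: `sample_sheet` (one row per
#'   individual: ids, role, sex, ages, phenotype, true content,
#'   ancestry), `truth` (one row per individual-heteroplasmy: position,
#'   alleles, true VAF, origin, z, PP flag), `scores`, `universe`,
#'   `config`.
#' @export
simulate_families <- function(config = sim_config(), ref_obj = mito_reference(),
                              scores = NULL, universe = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(scores)) scores <- simulate_score_table(ref_obj, config$seed)
  if (is.null(universe)) universe <- build_truth_universe(ref_obj, scores)
  quartet <- config$design == "quartet"
  uni_dn <- universe[!universe$masked, , drop = FALSE]
  sheets <- vector("list", config$n_families)
  truths <- vector("list", config$n_families)
  h2 <- config$content_h2
  ancestries <- c("L0", "H1", "M7", "U5", "B2")

  for (i in seq_len(config$n_families)) {
    set.seed(family_seed(config, i))
    fid <- sprintf("F%04d", i)
    mat_age <- min(45, max(16, stats::rnorm(1, 30, 5)))
    pat_age <- min(55, max(18, mat_age + stats::rnorm(1, 2, 3)))
    child_age <- if (quartet) stats::runif(2, 4, 18) else 0
    gest_age <- if (quartet) NA_real_ else stats::rnorm(1, 39, 2)
    n_children <- if (quartet) 2L else 1L
    kid_ids <- paste0(fid, "-C", seq_len(n_children))
    anc <- sample(ancestries, 1L)

    # content: additive-genetic decomposition (see simulate_content)
    am <- stats::rnorm(1, 0, sqrt(h2)); af <- stats::rnorm(1, 0, sqrt(h2))
    zm <- am + stats::rnorm(1, 0, sqrt(1 - h2))
    zf <- af + stats::rnorm(1, 0, sqrt(1 - h2))
    zk <- vapply(seq_len(n_children), function(j)
      (am + af) / 2 + stats::rnorm(1, 0, sqrt(h2 / 2)) +
        stats::rnorm(1, 0, sqrt(1 - h2)), numeric(1))
    raw_content <- function(age, z)
      config$content_mean + config$content_age_slope * (age - 10) +
        config$content_sd * z
    mother_age_now <- if (quartet) mat_age + mean(child_age) else mat_age

    # maternal and paternal heteroplasmies (fathers never transmit)
    draw_het <- function(n) {
      if (n == 0L) return(universe[0, ])
      idx <- sample.int(nrow(universe), n)
      h <- universe[idx, , drop = FALSE]
      h$vaf <- pmin(0.95, pmax(0.02, stats::rbeta(n, 0.5, 4)))
      h
    }
    mom_het <- draw_het(stats::rpois(1L, config$het_rate))
    dad_het <- draw_het(stats::rpois(1L, config$het_rate))

    kid_rows <- vector("list", n_children)
    for (j in seq_len(n_children)) {
      inh <- universe[0, , drop = FALSE]
      inh$vaf <- numeric(0)
      if (nrow(mom_het)) {
        cv <- vapply(seq_len(nrow(mom_het)), function(r)
          transmit_heteroplasmy(min(mom_het$vaf[r], 0.999),
                                mom_het$z[r], config), numeric(1))
        if (any(cv > 0)) {
          inh <- mom_het[cv > 0, , drop = FALSE]
          inh$vaf <- cv[cv > 0]
        }
      }
      dn <- simulate_de_novo(mat_age, config, uni_dn)
      inh$origin <- rep("inherited", nrow(inh))
      dn$origin <- rep("de_novo", nrow(dn))
      kid_rows[[j]] <- rbind(inh, dn)
    }

    # phenotype from true exposures under the comparator rule
    carry <- vapply(seq_len(n_children), function(j) {
      pp <- kid_rows[[j]][kid_rows[[j]]$pp, , drop = FALSE]
      if (nrow(pp) == 0L) return(FALSE)
      comp_vaf <- function(pos, alt) {
        if (quartet) {
          other <- kid_rows[[if (j == 1L) 2L else 1L]]
          hit <- other$vaf[other$pos == pos & other$alt == alt]
        } else {
          hit <- mom_het$vaf[mom_het$pos == pos & mom_het$alt == alt]
        }
        if (length(hit)) hit[1L] else 0
      }
      any(pp$vaf > mapply(comp_vaf, pp$pos, pp$alt))
    }, logical(1))
    expo <- data.frame(family_id = fid, carry_pp = carry,
                       low_tertile = zk < stats::qnorm(1 / 3),
                       content_z = zk)
    pheno <- simulate_phenotype(expo, config)

    roles <- if (quartet) ifelse(pheno == 1L, "proband", "sibling")
             else "child"
    kid_sex <- sample(c("M", "F"), n_children, replace = TRUE)
    sheet <- data.frame(
      sample_id = c(paste0(fid, "-M"),
                    if (quartet) paste0(fid, "-P") else NULL, kid_ids),
      family_id = fid,
      role = c("mother", if (quartet) "father" else NULL, roles),
      sex = c("F", if (quartet) "M" else NULL, kid_sex),
      age = c(mother_age_now, if (quartet) pat_age + mean(child_age)
              else NULL, child_age),
      gestational_age = c(NA, if (quartet) NA else NULL,
                          rep(gest_age, n_children)),
      maternal_age = c(NA, if (quartet) NA else NULL,
                       rep(mat_age, n_children)),
      paternal_age = c(NA, if (quartet) NA else NULL,
                       rep(if (quartet) pat_age else NA_real_, n_children)),
      phenotype = c(NA, if (quartet) NA else NULL, pheno),
      content = raw_content(
        c(mother_age_now, if (quartet) pat_age + mean(child_age) else NULL,
          child_age + if (quartet) 0 else 0),
        c(zm, if (quartet) zf else NULL, zk)),
      ancestry = anc,
      stringsAsFactors = FALSE)

    tru <- list()
    pack <- function(h, sid, role, origin_default) {
      if (nrow(h) == 0L) return(NULL)
      data.frame(sample_id = sid, family_id = fid, role = role,
                 pos = h$pos, ref = h$ref, alt = h$alt, vaf = h$vaf,
                 origin = if ("origin" %in% names(h)) h$origin
                          else origin_default,
                 z = h$z, category = h$category,
                 coding_effect = h$coding_effect, pp = h$pp,
                 stringsAsFactors = FALSE)
    }
    tru[[1L]] <- pack(mom_het, paste0(fid, "-M"), "mother", "founder")
    if (quartet)
      tru[[2L]] <- pack(dad_het, paste0(fid, "-P"), "father", "founder")
    for (j in seq_len(n_children))
      tru[[length(tru) + 1L]] <- pack(kid_rows[[j]], kid_ids[j],
                                      roles[j], "de_novo")
    sheets[[i]] <- sheet
    truths[[i]] <- do.call(rbind, tru)
  }
  out <- list(sample_sheet = do.call(rbind, sheets),
              truth = do.call(rbind, truths),
              scores = scores, universe = universe, config = config)
  rownames(out$sample_sheet) <- rownames(out$truth) <- NULL
  class(out) <- "mito_sim"
  out
}

#' @export
print.mito_sim <- function(x, ...) {
  cat("Synthetic mtDNA cohort:", x$config$n_families, x$config$design,
      "families;", nrow(x$sample_sheet), "individuals;",
      if (is.null(x$truth)) 0L else nrow(x$truth), "true heteroplasmies\n")
  invisible(x)
}

#' Read-level pileup for one simulated sample
#'
#' Per site, unique-read depth is negative-binomial (Poisson when
#' `depth_sd^2 <= depth_mean`) around `depth_mean`, split ~50/50 by
#' strand. True minor alleles are sampled binomially at the true VAF per
#' strand (optionally Beta-overdispersed); error alleles arrive at
#' `error_floor` per base spread evenly over the three non-reference
#' bases (optionally strand-biased). Per-allele mean BAQ and the site
#' q30 fraction emulate Phred-distributed base qualities.
#'
#' @param truth Data.frame of the sample's true heteroplasmies (`pos`,
#'   `alt`, `vaf`); zero rows for an error-only sample.
#' @param config A [sim_config()].
#' @param ref_obj A [mito_reference()].
#' @param sites Positions to emit (default: whole genome).
#' @return Pileup data.frame (see [read_pileup()] for columns).
#' @export
simulate_pileup <- function(truth, config, ref_obj,
                            sites = seq_len(ref_obj$length)) {
  stopifnot(config$depth_mean > 0)
  n <- length(sites)
  m <- config$depth_mean; s2 <- config$depth_sd^2
  depth <- if (s2 > m)
    stats::rnbinom(n, mu = m, size = m^2 / (s2 - m)) else stats::rpois(n, m)
  depth <- pmax(depth, 1L)
  d_f <- stats::rbinom(n, depth, 0.5)
  d_r <- depth - d_f
  ref <- ref_obj$sequence[sites]
  cnt <- matrix(0L, n, 8L,
                dimnames = list(NULL, c(count_cols("fwd"), count_cols("rev"))))
  # error alleles
  ef <- config$error_floor
  if (ef > 0) {
    biased <- stats::runif(n) < config$strand_bias_frac
    for (st in 1:2) {
      d_st <- if (st == 1L) d_f else d_r
      e_st <- ifelse(biased, if (st == 1L) 2 * ef else 0, ef)
      tot_err <- stats::rbinom(n, d_st, e_st)
      has <- which(tot_err > 0L)
      for (i in has) {
        alts <- BASES[BASES != ref[i]]
        split3 <- stats::rmultinom(1L, tot_err[i], rep(1 / 3, 3))[, 1L]
        cols <- paste0(if (st == 1L) "fwd_" else "rev_", alts)
        cnt[i, cols] <- cnt[i, cols] + split3
      }
    }
  }
  # true minor alleles
  if (nrow(truth)) {
    idx <- match(truth$pos, sites)
    keep <- which(!is.na(idx))
    for (r in keep) {
      i <- idx[r]
      p <- truth$vaf[r]
      if (config$vaf_overdispersion > 0) {
        rho <- config$vaf_overdispersion
        ab <- c(p, 1 - p) * (1 - rho) / rho
        p <- stats::rbeta(1L, ab[1L], ab[2L])
      }
      af <- stats::rbinom(1L, d_f[i], p)
      ar <- stats::rbinom(1L, d_r[i], p)
      cnt[i, paste0("fwd_", truth$alt[r])] <-
        cnt[i, paste0("fwd_", truth$alt[r])] + af
      cnt[i, paste0("rev_", truth$alt[r])] <-
        cnt[i, paste0("rev_", truth$alt[r])] + ar
    }
  }
  # reference takes the remainder (conservation per strand)
  for (st in c("fwd", "rev")) {
    d_st <- if (st == "fwd") d_f else d_r
    used <- rowSums(cnt[, paste0(st, "_", BASES), drop = FALSE])
    over <- used > d_st
    if (any(over)) {   # rare: error+truth draws exceeded depth; rescale
      for (i in which(over)) {
        cols <- paste0(st, "_", BASES)
        cnt[i, cols] <- floor(cnt[i, cols] * d_st[i] / used[i])
      }
      used <- rowSums(cnt[, paste0(st, "_", BASES), drop = FALSE])
    }
    rc <- paste0(st, "_", ref)
    for (b in BASES) {
      sel <- ref == b
      col <- paste0(st, "_", b)
      cnt[sel, col] <- cnt[sel, col] + (d_st - used)[sel]
    }
  }
  out <- data.frame(pos = sites, ref = ref, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cnt))
  for (b in BASES)
    out[[paste0("baq_", b)]] <- ifelse(
      out[[paste0("fwd_", b)]] + out[[paste0("rev_", b)]] > 0,
      stats::rnorm(n, config$baq_phred_mean, 1), NA_real_)
  out$q30_frac <- pmin(1, pmax(0, stats::rnorm(n, config$q30_frac, 0.02)))
  out
}

#' Per-child truth exposures under the comparator rule
#'
#' Recomputes, from the truth table alone, the exposure quantities the
#' analysis layer derives from calls: `carry_pp` (a PP heteroplasmy with
#' fraction above the design comparator - the sibling in quartets, the
#' mother in dyads), the true content z, and the low-content flag at the
#' standard-normal tertile cut.
#'
#' @param sim A `mito_sim` object.
#' @return Data.frame with one row per child: `sample_id`, `family_id`,
#'   `role`, `sex`, `phenotype`, `maternal_age`, `paternal_age`, `age`,
#'   `carry_pp`, `content`, `content_z`, `low_tertile`, `n_de_novo`.
#' @export
true_exposures <- function(sim) {
  ss <- sim$sample_sheet
  quartet <- sim$config$design == "quartet"
  kids <- ss[ss$role %in% c("proband", "sibling", "child"), , drop = FALSE]
  tru <- sim$truth
  if (is.null(tru))
    tru <- data.frame(sample_id = character(), pos = integer(),
                      alt = character(), vaf = numeric(),
                      origin = character(), pp = logical(),
                      stringsAsFactors = FALSE)
  cz <- (kids$content - sim$config$content_mean -
           sim$config$content_age_slope * (kids$age - 10)) /
    sim$config$content_sd
  carry <- logical(nrow(kids))
  ndn <- integer(nrow(kids))
  for (i in seq_len(nrow(kids))) {
    mine <- tru[tru$sample_id == kids$sample_id[i], , drop = FALSE]
    ndn[i] <- sum(mine$origin == "de_novo")
    pp <- mine[mine$pp, , drop = FALSE]
    if (nrow(pp) == 0L) next
    comp_id <- if (quartet) {
      setdiff(kids$sample_id[kids$family_id == kids$family_id[i]],
              kids$sample_id[i])
    } else {
      ss$sample_id[ss$family_id == kids$family_id[i] & ss$role == "mother"]
    }
    other <- tru[tru$sample_id %in% comp_id, , drop = FALSE]
    cv <- vapply(seq_len(nrow(pp)), function(r) {
      hit <- other$vaf[other$pos == pp$pos[r] & other$alt == pp$alt[r]]
      if (length(hit)) hit[1L] else 0
    }, numeric(1))
    carry[i] <- any(pp$vaf > cv)
  }
  data.frame(sample_id = kids$sample_id, family_id = kids$family_id,
             role = kids$role, sex = kids$sex, phenotype = kids$phenotype,
             maternal_age = kids$maternal_age,
             paternal_age = kids$paternal_age, age = kids$age,
             carry_pp = carry, content = kids$content, content_z = cz,
             low_tertile = cz < stats::qnorm(1 / 3), n_de_novo = ndn,
             stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Emits the sample sheet (CSV), truth table (TSV) and configuration
#' (YAML-style key/value text) under `dir`.
#'
#' @param sim A `mito_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$sample_sheet, file.path(dir, "sample_sheet.csv"),
                   row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  writeLines(paste0(names(cfg), ": ", vapply(cfg, function(x)
    paste(format(x), collapse = " "), character(1))),
    file.path(dir, "config.yaml"))
  invisible(dir)
}
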