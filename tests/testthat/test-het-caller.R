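test_that("llq score matches direct likelihood evaluation and is monotone", {
  # independent oracle: direct evaluation of the mixture likelihood ratio
  oracle <- function(k, n, baq) {
    e <- 10^(-baq / 10)
    phat <- k / n
    l1 <- k * log10(phat * (1 - e) + (1 - phat) * e / 3) +
      (n - k) * log10((1 - phat) * (1 - e) + phat * e / 3)
    l0 <- k * log10(e / 3) + (n - k) * log10(1 - e)
    max(0, l1 - l0)
  }
  expect_equal(llq_score(15, 1000, 30), oracle(15, 1000, 30))
  expect_gt(llq_score(15, 1000, 30), 5)
  expect_lt(llq_score(5, 1000, 30), 5)
  expect_equal(llq_score(0, 1000, 30), 0)
  scores <- vapply(0:40, llq_score, numeric(1), depth = 2000,
                   baq_minor = 30)
  expect_true(all(diff(scores) >= 0))
  expect_error(llq_score(10, 5), "minor_count")
  expect_error(llq_score(5, 100, baq_minor = 0), "error probabilities")
})

test_that("strand concordance matches hypergeometric enumeration", {
  # oracle: exact conditional two-sided probability by enumeration
  hyper_two_sided <- function(fa, fr, ra, rr) {
    k <- fa + ra; nf <- fa + fr; nr <- ra + rr
    xs <- max(0, k - nr):min(k, nf)
    probs <- dhyper(xs, nf, nr, k)
    p_obs <- dhyper(fa, nf, nr, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  for (tab in list(c(12, 988, 7, 993), c(20, 980, 0, 1000),
                   c(3, 1500, 9, 1400))) {
    sc <- strand_concordance(tab[1], tab[2], tab[3], tab[4])
    expect_equal(sc$p_value, do.call(hyper_two_sided, as.list(tab)),
                 tolerance = 1e-6)
  }
  # symmetric table passes trivially
  sym <- strand_concordance(10, 990, 10, 990)
  expect_equal(sym$p_value, 1)
  expect_true(sym$nonzero_both)
  # strongly biased table with a bare strand fails both ways
  bad <- strand_concordance(20, 980, 0, 1000)
  expect_lt(bad$p_value, 1e-4)
  expect_false(bad$nonzero_both)
  # minimal nonzero counts on both strands pass
  min2 <- strand_concordance(1, 999, 1, 999)
  expect_equal(min2$p_value, 1)
  expect_true(min2$nonzero_both)
  expect_equal(strand_concordance(0, 0, 0, 0)$p_value, 1)
})

test_that("sharing test uses exact binomial tails with a depth guard", {
  tail_oracle <- function(k, n, e) sum(dbinom(k:n, n, e))
  expect_lt(tail_oracle(6, 1000, 1e-3), 1e-3)
  expect_true(sharing_test(6, 1000))
  expect_gt(tail_oracle(4, 1000, 1e-3), 1e-3)
  expect_false(sharing_test(4, 1000))
  # fraction floor: 3/2000 = 0.15% < 0.2% regardless of the tail
  expect_false(sharing_test(3, 2000, error_rate = 1e-5))
  # depth guard: indeterminate, not "not shared"
  expect_true(is.na(sharing_test(6, 500)))
})

test_that("detection power reproduces exact binomial discrimination", {
  dp <- detection_power(2000, 2e-4, 0.01, 0.05 / 16569)
  # oracle: smallest k with null upper tail <= alpha, by explicit cumsum
  tails <- rev(cumsum(rev(dbinom(0:2000, 2000, 2e-4))))
  k_star <- which(tails <= 0.05 / 16569)[1L] - 1L
  expect_equal(dp$k_crit, k_star)
  expect_equal(dp$power, sum(dbinom(k_star:2000, 2000, 0.01)))
  expect_gt(dp$power, 0.999)
  expect_lte(dp$size, 0.05 / 16569)
  # size of the test: power at p = e is at most alpha
  expect_lte(detection_power(2000, 2e-4, 2e-4, 0.05)$power, 0.05)
  expect_gt(detection_power(500, 1e-3, 0.05, 0.05)$power, 0.9999)
})

test_that("caller detects clean truth variants and applies site filters", {
  ref <- test_ref()
  cfg <- sim_config(seed = 7, depth_mean = 4000, depth_sd = 0)
  pos <- pos_with_ref(ref, "A", from = 3400)
  truth <- data.frame(pos = pos, alt = "G", vaf = 0.05)
  set.seed(7)
  p <- simulate_pileup(truth, cfg, ref, sites = 3000:4000)
  calls <- call_heteroplasmies(p, ref, sample_id = "s1")
  expect_equal(calls$pos, pos)
  expect_lt(abs(calls$vaf - 0.05),
            4 * sqrt(0.05 * 0.95 / 4000))
  # depth filter: same truth at depth 400 is not callable
  cfg_low <- sim_config(seed = 7, depth_mean = 400, depth_sd = 0)
  set.seed(7)
  p_low <- simulate_pileup(truth, cfg_low, ref, sites = 3000:4000)
  expect_equal(nrow(call_heteroplasmies(p_low, ref)), 0L)
  # masked site: a strong variant at m.310 is suppressed
  p310 <- simple_site(ref, 310, setdiff(c("A", "C", "G", "T"),
                                        ref$sequence[310])[1L], 100, 100)
  expect_equal(nrow(call_heteroplasmies(p310, ref)), 0L)
  # unsorted input is rejected
  expect_error(call_heteroplasmies(p[c(2, 1), ], ref), "sorted")
})

test_that("called VAF is an unbiased estimate of the true fraction", {
  ref <- test_ref()
  cfg <- sim_config(seed = 3, depth_mean = 4000, depth_sd = 0)
  sites <- 5950:7400
  pos <- which(!is_masked(ref, seq_len(ref$length)))
  pos <- pos[pos %in% sites]
  pos <- pos[seq(1, length(pos), by = 10)][1:120]
  truth <- data.frame(pos = pos,
                      alt = vapply(ref$sequence[pos], function(r)
                        setdiff(c("A", "C", "G", "T"), r)[1L], ""),
                      vaf = 0.10)
  set.seed(3)
  p <- simulate_pileup(truth, cfg, ref, sites = sites)
  calls <- call_heteroplasmies(p, ref)
  called <- calls[calls$pos %in% pos, ]
  expect_gte(nrow(called), 115)
  se <- sqrt(0.1 * 0.9 / 4000 / nrow(called))
  expect_lt(abs(mean(called$vaf) - 0.10), 3 * se + cfg$error_floor)
})

test_that("consensus construction follows the posterior and flags ties", {
  reads3 <- data.frame(barcode = "b1", pos = 100, base = "C", qual = 30)
  reads3 <- reads3[rep(1, 3), ]
  cs <- build_consensus(reads3)
  expect_equal(cs$base, "C")
  # oracle: direct posterior computation
  e <- 1e-3
  logl <- c(3 * log(1 - e), rep(3 * log(e / 3), 3))
  post <- exp(logl - max(logl)); post <- post / sum(post)
  expect_equal(cs$qual, -10 * log10(1 - max(post)), tolerance = 1e-6)
  expect_gt(cs$qual, 30)

  tie <- data.frame(barcode = "b2", pos = 5, base = c("A", "G"), qual = 25)
  expect_equal(build_consensus(tie)$base, "N")

  single <- data.frame(barcode = "b3", pos = 9, base = "T", qual = 28)
  out <- build_consensus(single)
  expect_equal(out$base, "T")
  expect_equal(out$qual, 28, tolerance = 1e-6)
  expect_equal(out$n_members, 1L)
  expect_error(build_consensus(reads3[0, ]), "empty")
})

test_that("consensus filters drop fold-drop variants and low-quality sites", {
  ref <- test_ref()
  alt_at <- function(pos) setdiff(c("A", "C", "G", "T"),
                                  ref$sequence[pos])[1L]
  mk_call <- function(sid, pos, vaf) {
    data.frame(sample_id = sid, pos = pos, ref = ref$sequence[pos],
               major = ref$sequence[pos], alt = alt_at(pos), vaf = vaf,
               minor_count = round(vaf * 2000), depth = 2000, llq = 50,
               strand_p = NA_real_, secondary = FALSE, origin = "unknown")
  }
  p_bad <- 6000; p_good <- 7000
  calls <- rbind(mk_call("s1", p_bad, 0.10), mk_call("s2", p_bad, 0.10),
                 mk_call("s3", p_bad, 0.10), mk_call("s4", p_bad, 0.095),
                 mk_call("s1", p_good, 0.10))
  class(calls) <- c("het_calls", "data.frame")
  sp <- mp <- list()
  for (s in paste0("s", 1:4)) {
    # single-member reads show 10%; multi-member drop to 1.5% for s1-s3
    multi_vaf <- if (s == "s4") 0.095 else 0.015
    sp[[s]] <- rbind(
      simple_site(ref, p_bad, alt_at(p_bad), 100, 100, 1000, 1000),
      simple_site(ref, p_good, alt_at(p_good), 100, 100, 1000, 1000))
    mp[[s]] <- rbind(
      simple_site(ref, p_bad, alt_at(p_bad), round(1000 * multi_vaf),
                  round(1000 * multi_vaf), 1000, 1000),
      simple_site(ref, p_good, alt_at(p_good), 95, 95, 1000, 1000))
  }
  kept <- consensus_filters(calls, sp, mp)
  # filter vi removes s1-s3 at the bad site; filter vii then removes s4
  # too (3 of 4 variants at the site failed vi); the good site survives
  expect_equal(kept$pos, p_good)
  expect_equal(kept$sample_id, "s1")
  expect_error(consensus_filters(calls, sp[-1], mp), "missing member-class")
})

test_that("comparable single- and multi-member fractions pass filter vi", {
  ref <- test_ref()
  pos <- 8000
  alt <- setdiff(c("A", "C", "G", "T"), ref$sequence[pos])[1L]
  call <- data.frame(sample_id = "s1", pos = pos, ref = ref$sequence[pos],
                     major = ref$sequence[pos], alt = alt, vaf = 0.10,
                     minor_count = 200, depth = 2000, llq = 50,
                     strand_p = NA_real_, secondary = FALSE,
                     origin = "unknown")
  class(call) <- c("het_calls", "data.frame")
  sp <- list(s1 = simple_site(ref, pos, alt, 90, 90, 1000, 1000))   # 9%
  mp <- list(s1 = simple_site(ref, pos, alt, 100, 100, 1000, 1000)) # 10%
  expect_equal(nrow(consensus_filters(call, sp, mp)), 1L)
})

test_that("sample QC flags excess de novo, label swaps and low coverage", {
  sheet <- data.frame(
    sample_id = c("m1", "c1", "m2", "c2"),
    family_id = c("f1", "f1", "f2", "f2"),
    role = c("mother", "child", "mother", "child"))
  seqs <- list(m1 = rep("A", 100), c1 = rep("A", 100),
               m2 = rep("A", 100), c2 = c(rep("G", 6), rep("A", 94)))
  qc <- sample_qc(sheet,
                  de_novo_counts = c(c1 = 16, c2 = 15),
                  major_alleles = seqs,
                  median_depth = c(m1 = 400, c1 = 2000))
  expect_setequal(qc$flag[qc$sample_id == "c1"], "excess_de_novo")
  expect_true(any(qc$sample_id == "c2" & qc$flag == "mislabeling"))
  expect_equal(qc$value[qc$flag == "mislabeling"], 6)
  expect_true(any(qc$sample_id == "m1" & qc$flag == "low_coverage"))
  # 15 de novo calls and concordant majors are not flagged
  expect_false(any(qc$sample_id == "c2" & qc$flag == "excess_de_novo"))
})

test_that("VCF output round-trips through an independent reader", {
  skip_if_not_installed("vcfR")
  ref <- test_ref()
  cfg <- sim_config(seed = 13, depth_mean = 3000, depth_sd = 0)
  pos <- pos_with_ref(ref, "C", from = 9000)
  truth <- data.frame(pos = pos, alt = "T", vaf = 0.2)
  set.seed(13)
  p <- simulate_pileup(truth, cfg, ref, sites = 8900:9600)
  calls <- call_heteroplasmies(p, ref, sample_id = "sampleX")
  f <- tempfile(fileext = ".vcf")
  write_heteroplasmy_vcf(calls, f)
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_equal(unname(as.integer(v@fix[, "POS"])), calls$pos)
  expect_equal(unname(v@fix[, "REF"]), calls$ref)
  expect_equal(unname(v@fix[, "ALT"]), calls$alt)
  af <- as.numeric(sub(".*AF=([0-9.e-]+);.*", "\\1", v@fix[, "INFO"]))
  expect_equal(af, calls$vaf, tolerance = 1e-5)
})
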