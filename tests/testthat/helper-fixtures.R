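# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

test_ref <- function() cached("ref", function() mito_reference())

test_scores <- function() cached("scores", function()
  simulate_score_table(test_ref(), seed = 101))

test_universe <- function() cached("universe", function()
  mitofam:::build_truth_universe(test_ref(), test_scores()))

# large quartet cohort for parameter-recovery checks; interaction and
# content effects disabled so the main disease effect is the configured
# OR (see the methods vignette)
recovery_sim <- function() cached("recovery_sim", function() {
  cfg <- sim_config(n_families = 2000, seed = 20,
                    pp_low_interaction_or = 1, content_or_per_sd = 1)
  simulate_families(cfg, test_ref(), test_scores(), test_universe())
})

# one-row (or multi-row) pileup builder; fwd/rev are A/C/G/T counts
toy_pileup <- function(pos, ref, fwd, rev, baq = 30, q30 = 0.9) {
  stopifnot(length(fwd) == 4L, length(rev) == 4L)
  p <- data.frame(pos = pos, ref = ref, stringsAsFactors = FALSE)
  for (i in 1:4) p[[paste0("fwd_", c("A", "C", "G", "T")[i])]] <- fwd[i]
  for (i in 1:4) p[[paste0("rev_", c("A", "C", "G", "T")[i])]] <- rev[i]
  for (b in c("A", "C", "G", "T")) p[[paste0("baq_", b)]] <- baq
  p$q30_frac <- q30
  p
}

# pileup with the reference allele everywhere plus one minor allele
simple_site <- function(ref_obj, pos, alt, alt_fwd, alt_rev,
                        depth_fwd = 2000, depth_rev = 2000, ...) {
  rb <- ref_obj$sequence[pos]
  fwd <- rev <- stats::setNames(rep(0L, 4L), c("A", "C", "G", "T"))
  fwd[rb] <- depth_fwd - alt_fwd; fwd[alt] <- alt_fwd
  rev[rb] <- depth_rev - alt_rev; rev[alt] <- alt_rev
  toy_pileup(pos, rb, fwd, rev, ...)
}

# first unmasked position whose reference base is `base`, for fixtures
pos_with_ref <- function(ref_obj, base, from = 1000) {
  p <- which(ref_obj$sequence == base)
  p <- p[p >= from & !is_masked(ref_obj, p)]
  p[1L]
}
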