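# Heteroplasmy calling from per-site allele-count pileups: BAQ-based
# likelihood score, exact strand-concordance test, depth/mask/VAF filters,
# barcode consensus construction, sharing test and detection power.

BASES <- c("A", "C", "G", "T")

count_cols <- function(strand) paste0(strand, "_", BASES)

#' Per-site total depth of a pileup table
#'
#' @param pileup A pileup data.frame (see [read_pileup()] for the column
#'   contract).
#' @return Integer vector of per-site depths (sum of all 8 strand-split
#'   allele counts).
#' @export
pileup_depth <- function(pileup) {
  as.integer(rowSums(pileup[, c(count_cols("fwd"), count_cols("rev"))]))
}

validate_pileup <- function(pileup) {
  need <- c("pos", "ref", count_cols("fwd"), count_cols("rev"))
  miss <- setdiff(need, names(pileup))
  if (length(miss)) stop("pileup lacks columns: ", paste(miss, collapse = ", "))
  if (is.unsorted(pileup$pos, strictly = TRUE))
    stop("pileup positions must be sorted and unique")
  cnt <- as.matrix(pileup[, c(count_cols("fwd"), count_cols("rev"))])
  if (any(cnt < 0)) stop("negative allele counts in pileup")
  invisible(pileup)
}

#' Read / write a pileup TSV
#'
#' The pileup format is a TSV with 1-based `pos`, reference base `ref`,
#' strand-split per-allele counts `fwd_A..fwd_T`, `rev_A..rev_T`, mean
#' Phred base quality per allele `baq_A..baq_T` (NA where the allele is
#' absent) and `q30_frac`, the fraction of site bases with BAQ >= 30.
#' Read-level screens (MAPQ >= 20, BAQ >= 30, mismatch and proper-pair
#' filters) are assumed already applied upstream by the pileup producer.
#'
#' @param path File path.
#' @param pileup Pileup data.frame to write.
#' @return `read_pileup` returns the validated pileup data.frame.
#' @export
read_pileup <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_pileup(p)
  p
}

#' @rdname read_pileup
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' BAQ-based log-likelihood quality score
#'
#' Log10 likelihood ratio of a heteroplasmy model at the observed minor
#' fraction against an errors-only model. Under the heteroplasmy model a
#' minor-allele base contributes `phat*(1-e) + (1-phat)*e/3` and a major
#' base `(1-phat)*(1-e) + phat*e/3`; under the null they contribute `e/3`
#' and `1-e`, with `e = 10^(-BAQ/10)` per base and `phat = k/n`. Errors
#' are spread uniformly over the 3 non-reference bases. The score is
#' clamped at 0 (the models coincide at `k = 0`) and is non-decreasing in
#' `k` at fixed depth and qualities.
#'
#' @param minor_count Number of minor-allele bases `k`.
#' @param depth Total bases `n`.
#' @param baq_minor Phred BAQ of minor-allele bases; scalar or length-`k`.
#' @param baq_major Phred BAQ of major-allele bases; scalar or
#'   length-`n - k`. Defaults to `baq_minor`'s first value.
#' @return The score (log10 units); calls require `> 5`.
#' @export
llq_score <- function(minor_count, depth, baq_minor = 30,
                      baq_major = baq_minor[1L]) {
  k <- minor_count; n <- depth
  if (k > n || k < 0) stop("minor_count must lie in [0, depth]")
  if (k == 0) return(0)
  e_min <- 10^(-rep_len(baq_minor, k) / 10)
  e_maj <- 10^(-rep_len(baq_major, n - k) / 10)
  if (any(c(e_min, e_maj) <= 0) || any(c(e_min, e_maj) >= 1))
    stop("per-base error probabilities must lie in (0, 1)")
  phat <- k / n
  l1 <- sum(log10(phat * (1 - e_min) + (1 - phat) * e_min / 3)) +
        sum(log10((1 - phat) * (1 - e_maj) + phat * e_maj / 3))
  l0 <- sum(log10(e_min / 3)) + sum(log10(1 - e_maj))
  max(0, l1 - l0)
}

#' Strand-concordance exact test
#'
#' Two-sided exact conditional (hypergeometric) probability that the
#' minor-allele fraction is the same on the forward and reverse strands
#' (two-sided convention: sum of all tables with point probability at most
#' that of the observed table). A call additionally requires a nonzero
#' minor count on both strands.
#'
#' @param fwd_alt,fwd_ref,rev_alt,rev_ref Strand-split minor/other counts.
#' @return List with `p_value`, `nonzero_both`.
#' @export
strand_concordance <- function(fwd_alt, fwd_ref, rev_alt, rev_ref) {
  tab <- matrix(c(fwd_alt, fwd_ref, rev_alt, rev_ref), nrow = 2)
  if (any(tab < 0)) stop("counts must be non-negative")
  p <- if (sum(tab) == 0 || sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 ||
           sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) 1
       else stats::fisher.test(tab)$p.value
  list(p_value = p, nonzero_both = fwd_alt > 0 && rev_alt > 0)
}

#' Heteroplasmy sharing test between two samples
#'
#' A variant detected in one sample counts as shared with another if, in
#' the other sample's pileup, the variant allele reaches a fraction of at
#' least `min_frac` among more than `min_depth` reads and the probability
#' of observing at least that many error bases is below `tail_p`
#' (exact binomial upper tail at `error_rate`).
#'
#' @param alt_count,depth Variant-allele count and depth in the other
#'   sample.
#' @param error_rate Per-base error rate for the null; defaults to 1e-3,
#'   the BAQ-30 bound. Site-specific rates may be supplied.
#' @param min_frac,min_depth,tail_p Sharing thresholds.
#' @return `TRUE`/`FALSE`, or `NA` when `depth <= min_depth`
#'   (indeterminate, distinct from not-shared).
#' @export
sharing_test <- function(alt_count, depth, error_rate = 1e-3,
                         min_frac = 0.002, min_depth = 500, tail_p = 1e-3) {
  if (depth <= min_depth) return(NA)
  if (alt_count == 0) return(FALSE)
  tail <- stats::pbinom(alt_count - 1L, depth, error_rate,
                        lower.tail = FALSE)
  (alt_count / depth >= min_frac) && (tail < tail_p)
}

#' Exact-binomial detection power for low-fraction heteroplasmies
#'
#' Power to discriminate a true heteroplasmy at fraction `p` from the
#' errors-only null at per-base error rate `e`, given `n` unique reads and
#' per-test level `alpha`. The critical count is the smallest `k` with
#' `P(Binom(n, e) >= k) <= alpha`; power is `P(Binom(n, p) >= k)`. Exact
#' binomial tails throughout, no normal approximation. When `p <= e` the
#' same formula returns at most the achieved size of the test.
#'
#' @param n Unique-read depth.
#' @param e Per-base error rate, in (0, 1).
#' @param p True variant fraction, in (0, 1).
#' @param alpha Test level (e.g. `0.05 / 16569` for genome-wide control).
#' @return List with `power`, `k_crit`, and the achieved `size`.
#' @export
detection_power <- function(n, e, p, alpha) {
  stopifnot(n >= 1, e > 0, e < 1, p > 0, p < 1, alpha > 0, alpha < 1)
  k_crit <- stats::qbinom(1 - alpha, n, e) + 1
  size <- stats::pbinom(k_crit - 1, n, e, lower.tail = FALSE)
  power <- stats::pbinom(k_crit - 1, n, p, lower.tail = FALSE)
  list(power = power, k_crit = as.integer(k_crit), size = size)
}

site_minor <- function(pileup) {
  fwd <- as.matrix(pileup[, count_cols("fwd")])
  rev <- as.matrix(pileup[, count_cols("rev")])
  tot <- fwd + rev
  n <- nrow(tot)
  major_i <- max.col(tot, ties.method = "first")
  tot2 <- tot
  tot2[cbind(seq_len(n), major_i)] <- -1L
  minor_i <- max.col(tot2, ties.method = "first")
  idx_major <- cbind(seq_len(n), major_i)
  idx_minor <- cbind(seq_len(n), minor_i)
  list(major = BASES[major_i], minor = BASES[minor_i],
       major_count = tot[idx_major], minor_count = tot[idx_minor],
       minor_fwd = fwd[idx_minor], minor_rev = rev[idx_minor],
       other_fwd = rowSums(fwd) - fwd[idx_minor],
       other_rev = rowSums(rev) - rev[idx_minor])
}

#' Call heteroplasmies from a pileup
#'
#' Applies the site-level filter cascade: unique-read depth > `min_depth`
#' with more than 70% of bases at BAQ >= 30; position not in a masked
#' low-complexity region; minor-allele count >= `min_minor`; BAQ-based
#' log-likelihood score > `min_llq`; nonzero and concordant minor fractions
#' on both strands (exact test P >= `strand_p`; WGS source only); and
#' minor fraction >= `min_vaf` (the NUMT defense floor). Consensus-source
#' pileups skip the strand test; apply [consensus_filters()] afterwards.
#'
#' @param pileup Pileup data.frame (validated; sorted unique positions).
#' @param ref_obj A [mito_reference()] providing the mask profile.
#' @param sample_id Sample label attached to calls.
#' @param source `"wgs"` or `"consensus"`.
#' @param min_depth,min_q30,min_minor,min_llq,min_vaf,strand_p Filter
#'   thresholds (defaults: 500, 0.7, 5, 5, 0.015, 1e-4).
#' @return A data.frame of class `het_calls`, one row per called
#'   heteroplasmy: `sample_id`, `pos`, `ref`, `major`, `alt`, `vaf`,
#'   `minor_count`, `depth`, `llq`, `strand_p`, `secondary`, `origin`.
#' @export
call_heteroplasmies <- function(pileup, ref_obj, sample_id = "sample",
                                source = c("wgs", "consensus"),
                                min_depth = 500, min_q30 = 0.7,
                                min_minor = 5, min_llq = 5,
                                min_vaf = 0.015, strand_p = 1e-4) {
  source <- match.arg(source)
  validate_pileup(pileup)
  depth <- pileup_depth(pileup)
  q30 <- if ("q30_frac" %in% names(pileup)) pileup$q30_frac else 1
  site_ok <- depth > min_depth & q30 > min_q30 &
    !is_masked(ref_obj, pileup$pos)
  mm <- site_minor(pileup)
  vaf <- ifelse(depth > 0, mm$minor_count / depth, 0)
  cand <- which(site_ok & mm$minor_count >= min_minor & vaf >= min_vaf)
  rows <- lapply(cand, function(i) {
    baq_minor <- baq_of(pileup, i, mm$minor[i])
    baq_major <- baq_of(pileup, i, mm$major[i])
    llq <- llq_score(mm$minor_count[i], depth[i], baq_minor, baq_major)
    if (llq <= min_llq) return(NULL)
    sp <- NA_real_
    if (source == "wgs") {
      sc <- strand_concordance(mm$minor_fwd[i], mm$other_fwd[i],
                               mm$minor_rev[i], mm$other_rev[i])
      if (!sc$nonzero_both || sc$p_value < strand_p) return(NULL)
      sp <- sc$p_value
    }
    data.frame(sample_id = sample_id, pos = pileup$pos[i],
               ref = pileup$ref[i], major = mm$major[i], alt = mm$minor[i],
               vaf = vaf[i], minor_count = mm$minor_count[i],
               depth = depth[i], llq = llq, strand_p = sp,
               secondary = FALSE, origin = "unknown",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty_calls())))
  rownames(out) <- NULL
  class(out) <- c("het_calls", "data.frame")
  out
}

empty_calls <- function() {
  data.frame(sample_id = character(), pos = integer(), ref = character(),
             major = character(), alt = character(), vaf = numeric(),
             minor_count = integer(), depth = integer(), llq = numeric(),
             strand_p = numeric(), secondary = logical(),
             origin = character(), stringsAsFactors = FALSE)
}

baq_of <- function(pileup, i, base) {
  col <- paste0("baq_", base)
  if (!col %in% names(pileup)) return(30)
  b <- pileup[[col]][i]
  if (is.na(b)) 30 else b
}

#' @export
print.het_calls <- function(x, ...) {
  ns <- if ("sample_id" %in% names(x))
    paste("in", length(unique(x$sample_id)), "sample(s)") else ""
  cat("Heteroplasmy calls:", nrow(x), "variants", ns, "\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Bayesian consensus from barcode read families
#'
#' For each molecular-barcode read family and alignment site, combines the
#' member bases under a uniform prior over the four nucleotides with
#' per-read Phred error likelihoods (correct base with probability
#' `1 - e`, each other base `e/3`). The consensus base is the posterior
#' mode; its quality is the Phred-scaled posterior error probability.
#' Posterior ties emit `N` and are excluded from downstream counts.
#'
#' @param reads Data.frame with columns `barcode`, `pos`, `base`, `qual`
#'   (Phred), one row per read base.
#' @return Data.frame with one row per (barcode, pos): `barcode`, `pos`,
#'   `base` (consensus, possibly `"N"`), `qual`, `n_members`.
#' @export
build_consensus <- function(reads) {
  stopifnot(all(c("barcode", "pos", "base", "qual") %in% names(reads)))
  if (nrow(reads) == 0L) stop("empty read-family table")
  key <- interaction(reads$barcode, reads$pos, drop = TRUE)
  parts <- split(reads, key)
  out <- lapply(parts, function(fam) {
    e <- 10^(-fam$qual / 10)
    loglik <- vapply(BASES, function(b)
      sum(ifelse(fam$base == b, log(1 - e), log(e / 3))), numeric(1))
    post <- exp(loglik - max(loglik))
    post <- post / sum(post)
    top <- which(abs(post - max(post)) < 1e-12)
    if (length(top) > 1L) {
      base <- "N"; qual <- 0
    } else {
      base <- BASES[top]
      perr <- max(1 - post[top], 1e-10)
      qual <- -10 * log10(perr)
    }
    data.frame(barcode = fam$barcode[1L], pos = fam$pos[1L], base = base,
               qual = qual, n_members = nrow(fam), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$pos, res$barcode), ]
}

#' Pileup from consensus reads
#'
#' Aggregates per-family consensus bases into the site-pileup format
#' (all counts on the forward strand; strand structure is not meaningful
#' for consensus reads and the strand filter is skipped for
#' `source = "consensus"`).
#'
#' @param consensus Output of [build_consensus()].
#' @param ref_obj A [mito_reference()] supplying reference bases.
#' @param members `"all"`, `"single"` (families of 1 read) or `"multi"`
#'   (families of >= 2 reads).
#' @return A pileup data.frame.
#' @export
consensus_pileup <- function(consensus, ref_obj,
                             members = c("all", "single", "multi")) {
  members <- match.arg(members)
  keep <- switch(members, all = TRUE,
                 single = consensus$n_members == 1L,
                 multi = consensus$n_members >= 2L)
  cs <- consensus[keep & consensus$base != "N", , drop = FALSE]
  pos <- sort(unique(cs$pos))
  p <- data.frame(pos = pos, ref = ref_obj$sequence[pos],
                  stringsAsFactors = FALSE)
  for (b in BASES)
    p[[paste0("fwd_", b)]] <-
      as.integer(vapply(pos, function(x) sum(cs$pos == x & cs$base == b), 0))
  for (b in BASES) p[[paste0("rev_", b)]] <- 0L
  for (b in BASES)
    p[[paste0("baq_", b)]] <- vapply(pos, function(x) {
      q <- cs$qual[cs$pos == x & cs$base == b]
      if (length(q)) mean(q) else NA_real_
    }, numeric(1))
  p$q30_frac <- vapply(pos, function(x)
    mean(cs$qual[cs$pos == x] >= 30), numeric(1))
  p
}

#' Consensus-specific quality filters
#'
#' Filter vi: the fraction of a variant among consensus reads built from
#' multiple read pairs must be comparable to that among single-read
#' consensus reads (exact test P >= `p_min`) and must not drop more than
#' `max_fold`-fold. Filter vii: sites where more than half of the batch's
#' variants fail filter vi are flagged low-quality and all their calls are
#' removed. Filter vii is computed across the whole supplied batch.
#'
#' @param calls A `het_calls` table for the batch (possibly many samples).
#' @param single_pileups,multi_pileups Named lists (by sample id) of
#'   pileups from single-member and multi-member consensus reads.
#' @param p_min,max_fold Filter-vi thresholds (defaults 1e-4 and 5).
#' @return The filtered `het_calls` table, with logical columns `pass_vi`,
#'   `pass_vii` retained on the survivors.
#' @export
consensus_filters <- function(calls, single_pileups, multi_pileups,
                              p_min = 1e-4, max_fold = 5) {
  if (nrow(calls) == 0L) return(calls)
  pass_vi <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    sid <- calls$sample_id[i]
    sp <- single_pileups[[sid]]; mp <- multi_pileups[[sid]]
    if (is.null(sp) || is.null(mp))
      stop("missing member-class pileups for sample ", sid)
    cs <- member_counts(sp, calls$pos[i], calls$alt[i])
    cm <- member_counts(mp, calls$pos[i], calls$alt[i])
    vaf_s <- if (cs$depth > 0) cs$alt / cs$depth else 0
    vaf_m <- if (cm$depth > 0) cm$alt / cm$depth else 0
    p <- if (cs$depth == 0 || cm$depth == 0) 1 else
      stats::fisher.test(matrix(c(cm$alt, cm$depth - cm$alt,
                                  cs$alt, cs$depth - cs$alt), 2))$p.value
    fold_drop <- vaf_s > 0 && vaf_m < vaf_s / max_fold
    pass_vi[i] <- (p >= p_min) && !fold_drop
  }
  frac_fail <- tapply(!pass_vi, calls$pos, mean)
  bad_sites <- as.integer(names(frac_fail)[frac_fail > 0.5])
  pass_vii <- !(calls$pos %in% bad_sites)
  out <- calls[pass_vi & pass_vii, , drop = FALSE]
  out$pass_vi <- TRUE; out$pass_vii <- TRUE
  rownames(out) <- NULL
  class(out) <- c("het_calls", "data.frame")
  out
}

member_counts <- function(pileup, pos, alt) {
  i <- match(pos, pileup$pos)
  if (is.na(i)) return(list(alt = 0L, depth = 0L))
  list(alt = pileup[[paste0("fwd_", alt)]][i] +
         pileup[[paste0("rev_", alt)]][i],
       depth = pileup_depth(pileup[i, , drop = FALSE]))
}

#' Sample- and family-level quality control
#'
#' Report-only screen flagging individuals with an excessive number of de
#' novo heteroplasmies, mother-child pairs whose major-allele sequences
#' differ at 5 or more sites (a mislabeling proxy), and samples with
#' median mtDNA coverage below 500x.
#'
#' @param sample_sheet Data.frame with `sample_id`, `family_id`, `role`
#'   (mother/father/proband/sibling/child).
#' @param de_novo_counts Named integer vector of de novo calls per child.
#' @param major_alleles Named list of per-position major-allele base
#'   vectors (same length per cohort) used for the mother-child check.
#' @param median_depth Named numeric vector of per-sample median coverage.
#' @param max_de_novo,mismatch_min,min_depth Thresholds (15, 5, 500).
#' @return Data.frame of flags, one row per flagged sample, with columns
#'   `sample_id`, `family_id`, `flag`, `value`.
#' @export
sample_qc <- function(sample_sheet, de_novo_counts = NULL,
                      major_alleles = NULL, median_depth = NULL,
                      max_de_novo = 15, mismatch_min = 5, min_depth = 500) {
  flags <- list()
  add <- function(sid, flag, value) {
    fid <- sample_sheet$family_id[match(sid, sample_sheet$sample_id)]
    flags[[length(flags) + 1L]] <<- data.frame(
      sample_id = sid, family_id = fid, flag = flag, value = value,
      stringsAsFactors = FALSE)
  }
  for (sid in names(de_novo_counts))
    if (de_novo_counts[[sid]] > max_de_novo)
      add(sid, "excess_de_novo", de_novo_counts[[sid]])
  if (!is.null(major_alleles)) {
    kids <- sample_sheet[sample_sheet$role %in%
                           c("proband", "sibling", "child"), ]
    for (i in seq_len(nrow(kids))) {
      mom <- sample_sheet$sample_id[sample_sheet$family_id == kids$family_id[i] &
                                      sample_sheet$role == "mother"]
      if (length(mom) != 1L) next
      a <- major_alleles[[kids$sample_id[i]]]
      b <- major_alleles[[mom]]
      if (is.null(a) || is.null(b)) next
      mm <- sum(a != b)
      if (mm >= mismatch_min) add(kids$sample_id[i], "mislabeling", mm)
    }
  }
  for (sid in names(median_depth))
    if (median_depth[[sid]] < min_depth)
      add(sid, "low_coverage", median_depth[[sid]])
  out <- do.call(rbind, c(flags, list(
    data.frame(sample_id = character(), family_id = character(),
               flag = character(), value = numeric(),
               stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}
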