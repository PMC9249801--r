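# mtDNA content estimation (depth-ratio and consensus-read methods) and
# standardization to the family-adjusted z-score mtCNz.

#' mtDNA content from WGS depth ratios
#'
#' Estimates mtDNA copies per diploid nuclear genome as two times the
#' average ratio of mtDNA read coverage to per-autosome coverage. Nuclear
#' coverage per chromosome is the mean over 100-kb/50-kb sliding windows
#' retaining only windows with more than `min_covered` of sites covered;
#' chromosomes left with no usable window are excluded with a warning.
#'
#' @param windows Data.frame with columns `chrom`, `mean_depth`,
#'   `frac_covered` (one row per window).
#' @param mt_depth Mean read depth over the mitochondrial genome.
#' @param min_covered Window inclusion threshold on the covered-site
#'   fraction (default 0.8, exclusive).
#' @return Raw mtDNA content (copies per diploid genome).
#' @export
content_from_depth <- function(windows, mt_depth, min_covered = 0.8) {
  stopifnot(all(c("chrom", "mean_depth", "frac_covered") %in% names(windows)),
            mt_depth >= 0)
  usable <- windows[windows$frac_covered > min_covered, , drop = FALSE]
  cov <- tapply(usable$mean_depth, usable$chrom, mean)
  dropped <- setdiff(unique(windows$chrom), names(cov))
  if (length(dropped))
    warning("chromosome(s) without usable windows excluded: ",
            paste(dropped, collapse = ", "))
  if (length(cov) == 0L) stop("no chromosome has a usable window")
  2 * mean(mt_depth / cov)
}

#' mtDNA content from targeted consensus-read counts
#'
#' Ratio estimator for capture data: two times the mean per-probe
#' consensus-read count over usable mtDNA probes divided by the mean
#' per-target count over nuclear targets. A probe is usable when its arm
#' sequences do not overlap mtDNA polymorphisms segregating in the batch;
#' with `batch_minor_freq` supplied, probes whose annealing region shows a
#' minor allele in at least `max_poly_freq` of batch samples are
#' disqualified.
#'
#' @param mt_counts Named numeric vector of consensus-read counts per
#'   mtDNA probe target.
#' @param nuclear_counts Numeric vector of consensus-read counts per
#'   nuclear probe target.
#' @param usable Optional logical mask over `mt_counts` (probe usability);
#'   defaults to all usable.
#' @param batch_minor_freq Optional numeric vector (same order as
#'   `mt_counts`) of batch minor-allele frequencies in each probe's
#'   annealing region.
#' @param max_poly_freq Disqualification threshold (default 0.002).
#' @return Raw mtDNA content (copies per diploid genome).
#' @export
content_from_consensus <- function(mt_counts, nuclear_counts, usable = NULL,
                                   batch_minor_freq = NULL,
                                   max_poly_freq = 0.002) {
  if (length(nuclear_counts) == 0L || sum(nuclear_counts) == 0)
    stop("no nuclear consensus reads available")
  if (is.null(usable)) usable <- rep(TRUE, length(mt_counts))
  if (!is.null(batch_minor_freq))
    usable <- usable & (batch_minor_freq < max_poly_freq)
  if (!any(usable)) stop("no usable mtDNA probe")
  2 * mean(mt_counts[usable]) / mean(nuclear_counts)
}

#' Standardize mtDNA content to mtCNz
#'
#' mtCNz is the standardized residual from an ordinary least-squares
#' regression of child mtDNA content on age (or gestational age) and the
#' parental mean (or maternal) mtDNA content. Children with missing age
#' receive the cohort mean age before fitting; constant covariates are
#' dropped with a warning. The fit is made once on the full child set so
#' stratified analyses share one scale.
#'
#' @param content Numeric vector of raw child contents (> 0).
#' @param age Numeric vector; `NA`s imputed with the mean.
#' @param parent_content Numeric vector (parental mean or maternal
#'   content); `NA`s imputed with the mean.
#' @return Object of class `mtcnz`: data.frame with columns `content`,
#'   `age`, `parent_content`, `mtcnz`, `tertile`; the fitted `lm` is
#'   attached as attribute `fit`.
#' @export
standardize_mtcnz <- function(content, age = NULL, parent_content = NULL) {
  n <- length(content)
  if (n < 3L) stop("need at least 3 children to standardize")
  impute <- function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x }
  df <- data.frame(content = content)
  covs <- character()
  for (nm in c("age", "parent_content")) {
    v <- get(nm)
    if (is.null(v)) next
    v <- impute(rep_len(v, n))
    if (stats::sd(v) == 0) {
      warning("constant covariate dropped: ", nm)
      next
    }
    df[[nm]] <- v
    covs <- c(covs, nm)
  }
  fml <- if (length(covs))
    stats::reformulate(covs, response = "content") else content ~ 1
  fit <- stats::lm(fml, data = df)
  r <- stats::residuals(fit)
  z <- r / stats::sd(r)
  out <- data.frame(content = content,
                    age = if ("age" %in% names(df)) df$age else NA,
                    parent_content = if ("parent_content" %in% names(df))
                      df$parent_content else NA,
                    mtcnz = z,
                    tertile = assign_tertiles(z))
  attr(out, "fit") <- fit
  class(out) <- c("mtcnz", "data.frame")
  out
}

#' @export
print.mtcnz <- function(x, ...) {
  cat("mtCNz standardization of", nrow(x), "children",
      sprintf("(mean %.2g, sd %.3g)\n", mean(x$mtcnz), stats::sd(x$mtcnz)))
  print(table(x$tertile))
  invisible(x)
}

#' Empirical tertiles of mtCNz
#'
#' Cuts at the 1/3 and 2/3 empirical quantiles of the pooled children
#' (cases and controls together). Ties at a boundary resolve by the
#' quantile cut itself; fully degenerate input (all values equal) is
#' assigned by stable input order and flagged with a warning.
#'
#' @param z Numeric vector (length >= 3).
#' @return Factor with levels `T1 < T2 < T3` (T1 = low content).
#' @export
assign_tertiles <- function(z) {
  if (length(z) < 3L) stop("need at least 3 values")
  if (stats::sd(z) == 0) {
    warning("degenerate input: all values equal; tertiles by stable order")
    k <- ceiling(seq_along(z) / (length(z) / 3))
    return(factor(paste0("T", pmin(k, 3L)), levels = c("T1", "T2", "T3")))
  }
  q <- stats::quantile(z, c(1 / 3, 2 / 3), names = FALSE)
  lab <- ifelse(z <= q[1L], "T1", ifelse(z <= q[2L], "T2", "T3"))
  factor(lab, levels = c("T1", "T2", "T3"))
}
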