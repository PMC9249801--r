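# Predicted-pathogenic (PP) classification from external predictor score
# tables and rank-based inverse-normal pathogenicity z-scores over
# gene-category change universes.

#' Rank-based inverse-normal pathogenicity z-scores
#'
#' Converts raw predictor scores (CADD-like for OXPHOS protein changes,
#' MitoTIP-like for tRNA changes) over a complete change universe into
#' normally distributed z-scores representing each change's pathogenicity
#' rank: `z_i = qnorm((r_i - 0.5) / m)` with `r_i` the ascending rank
#' among the `m` universe entries and ties sharing the mean rank. The
#' transform is invariant to any strictly monotone rescaling of the raw
#' scores and has mean ~0 by construction.
#'
#' @param raw Numeric vector of raw scores over the full universe.
#' @return Numeric vector of z-scores, aligned with `raw`.
#' @export
pathogenicity_z <- function(raw) {
  m <- length(raw)
  if (m < 2L) stop("need at least 2 universe entries")
  r <- rank(raw, ties.method = "average")
  stats::qnorm((r - 0.5) / m)
}

#' Predicted-pathogenic (PP) classification
#'
#' A variant is PP if it (1) exceeds the predictor thresholds applicable
#' to its consequence class - for nonsynonymous OXPHOS changes all of
#' CADD Phred > 15, PolyPhen-2 possibly/probably damaging and MutPred
#' > 0.6; for tRNA changes MitoTIP raw > 12.66 - or (2) is a confirmed
#' mitochondrial-disorder mutation not marked benign in ClinVar; and, in
#' either route, (3) has a maximum population frequency of at most 0.05%
#' across reference panels. rRNA and D-loop changes can only be PP via
#' route (2). Missing required scores yield `NA` (indeterminate),
#' distinct from `FALSE`.
#'
#' @param scores Data.frame with columns (any may be `NA`): `cadd_phred`,
#'   `polyphen_cat` (`"benign"`, `"possibly"`, `"probably"`), `mutpred`,
#'   `mitotip_raw`, `md_confirmed` (logical), `clinvar_benign` (logical),
#'   `pop_freq_max`.
#' @param consequence Character vector: `"nonsynonymous"`, `"synonymous"`,
#'   `"tRNA"`, `"rRNA"`, `"D-loop"` or `"other"` per variant.
#' @param cadd_min,mutpred_min,mitotip_min,freq_max Thresholds
#'   (defaults 15, 0.6, 12.66, 5e-4).
#' @return Logical vector (`NA` = indeterminate).
#' @export
classify_pp <- function(scores, consequence, cadd_min = 15,
                        mutpred_min = 0.6, mitotip_min = 12.66,
                        freq_max = 5e-4) {
  n <- nrow(scores)
  stopifnot(length(consequence) == n)
  get <- function(nm, default = NA) {
    if (nm %in% names(scores)) scores[[nm]] else rep(default, n)
  }
  cadd <- get("cadd_phred"); pp2 <- get("polyphen_cat")
  mutp <- get("mutpred"); tip <- get("mitotip_raw")
  md <- get("md_confirmed", FALSE); benign <- get("clinvar_benign", FALSE)
  freq <- get("pop_freq_max")
  md[is.na(md)] <- FALSE; benign[is.na(benign)] <- FALSE

  predicted <- rep(NA, n)
  ns <- consequence == "nonsynonymous"
  predicted[ns] <- cadd[ns] > cadd_min &
    pp2[ns] %in% c("possibly", "probably") & !is.na(pp2[ns]) &
    mutp[ns] > mutpred_min
  predicted[ns & (is.na(cadd) | is.na(pp2) | is.na(mutp))] <- NA
  tr <- consequence == "tRNA"
  predicted[tr] <- tip[tr] > mitotip_min
  predicted[!ns & !tr] <- FALSE  # rRNA/D-loop/other: route (2) only

  confirmed <- md & !benign
  route12 <- ifelse(confirmed, TRUE, predicted)
  freq_ok <- freq <= freq_max
  out <- route12 & freq_ok
  out[is.na(freq)] <- NA
  out
}

#' Read a variant score table
#'
#' Reads a TSV of per-variant predictor scores and population frequencies
#' with columns `pos`, `ref`, `alt` plus any of the predictor columns
#' documented in [classify_pp()].
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_score_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", "."))
}

#' Annotate heteroplasmy calls with pathogenicity
#'
#' Joins a `het_calls` table against a score table and the change-universe
#' z-scores, attaching consequence class, `pp` flag and pathogenicity `z`.
#' z-scores are computed within the OXPHOS universe from CADD-like raw
#' scores and within the tRNA universe from MitoTIP-like raw scores;
#' other classes receive no z.
#'
#' @param calls A `het_calls` data.frame.
#' @param ref_obj A [mito_reference()].
#' @param scores Score table (see [read_score_table()]); must cover the
#'   full OXPHOS and tRNA change universes for z computation.
#' @return `calls` with added columns `gene`, `category`, `coding_effect`,
#'   `pp`, `z`.
#' @export
annotate_pathogenicity <- function(calls, ref_obj, scores) {
  key <- function(pos, ref, alt) paste(pos, ref, alt, sep = ":")
  skey <- key(scores$pos, scores$ref, scores$alt)
  uni_o <- enumerate_changes(ref_obj, "OXPHOS")
  uni_t <- enumerate_changes(ref_obj, "tRNA")
  z_map <- c(
    stats::setNames(pathogenicity_z(
      scores$cadd_raw[match(key(uni_o$pos, uni_o$ref, uni_o$alt), skey)]),
      key(uni_o$pos, uni_o$ref, uni_o$alt)),
    stats::setNames(pathogenicity_z(
      scores$mitotip_raw[match(key(uni_t$pos, uni_t$ref, uni_t$alt), skey)]),
      key(uni_t$pos, uni_t$ref, uni_t$alt)))
  ann <- lapply(seq_len(nrow(calls)), function(i) {
    a <- annotate_variant(ref_obj, calls$pos[i], calls$ref[i], calls$alt[i])
    # overlap dedupe for counting: prefer OXPHOS, then tRNA, then the rest
    pref <- match(a$category, c("OXPHOS", "tRNA", "rRNA", "D-loop", "noncoding"))
    a[which.min(pref), ]
  })
  ann <- do.call(rbind, ann)
  out <- cbind(as.data.frame(calls),
               ann[, c("gene", "category", "coding_effect")])
  si <- match(key(out$pos, out$ref, out$alt), skey)
  sc <- scores[si, , drop = FALSE]
  out$pp <- classify_pp(sc, out$coding_effect)
  out$z <- unname(z_map[key(out$pos, out$ref, out$alt)])
  class(out) <- c("het_calls", "data.frame")
  out
}
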