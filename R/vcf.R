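# Flat-file output of heteroplasmy calls: VCF and TSV mirrors.

#' Per-site major alleles of a pileup
#'
#' @param pileup A pileup data.frame.
#' @return Character vector of the most frequent base per site (input
#'   order).
#' @export
pileup_major_alleles <- function(pileup) {
  validate_pileup(pileup)
  site_minor(pileup)$major
}

#' Write heteroplasmy calls as VCF
#'
#' One VCF record per called heteroplasmy with the minor-allele fraction
#' in `INFO/AF`, depth in `INFO/DP`, the BAQ-based log-likelihood score
#' in `INFO/LLQ`, the strand-concordance probability in `INFO/SP`, the
#' sample id in `INFO/SAMPLE` and origin in `INFO/ORIGIN`. All emitted
#' records passed the filter cascade, so `FILTER` is `PASS`.
#'
#' @param calls A `het_calls` data.frame.
#' @param path Output path.
#' @param contig Contig name written in the header (default `"chrM"`).
#' @param contig_length Contig length for the header.
#' @return `path`, invisibly.
#' @export
write_heteroplasmy_vcf <- function(calls, path, contig = "chrM",
                                   contig_length = MT_LENGTH) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mitofam",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Minor allele fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Unique-read depth\">",
    "##INFO=<ID=LLQ,Number=1,Type=Float,Description=\"BAQ-based log-likelihood quality score\">",
    "##INFO=<ID=SP,Number=1,Type=Float,Description=\"Strand concordance exact-test probability\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"inherited, de_novo or unknown\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) {
    info <- sprintf("AF=%.6g;DP=%d;LLQ=%.4g;SP=%s;SAMPLE=%s;ORIGIN=%s",
                    calls$vaf, calls$depth, calls$llq,
                    ifelse(is.na(calls$strand_p), ".",
                           sprintf("%.4g", calls$strand_p)),
                    calls$sample_id, calls$origin)
    sprintf("%s\t%d\t.\t%s\t%s\t%.1f\t%s\t%s", contig, calls$pos,
            calls$ref, calls$alt, pmin(10 * calls$llq, 999), "PASS", info)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write heteroplasmy calls as TSV
#'
#' Flat mirror of the VCF output.
#'
#' @param calls A `het_calls` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heteroplasmy_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
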