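# Reference model of the mitochondrial genome: coordinates, gene map,
# masked regions, and the universe of possible single-nucleotide changes.

MT_LENGTH <- 16569L

#' Standard human mitochondrial gene map
#'
#' Returns the canonical 1-based inclusive gene coordinates of the human
#' mitochondrial genome (rCRS coordinate system): 13 OXPHOS protein genes,
#' 22 tRNA genes, 2 rRNA genes and the D-loop control region. Several gene
#' pairs overlap (e.g. ATP8/ATP6, ND4L/ND4); positions in an overlap map to
#' all member genes. The D-loop spans the origin and is represented by two
#' rows (16024-16569 and 1-576).
#'
#' @return A data.frame with columns `gene`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `category` (one of `"OXPHOS"`, `"tRNA"`, `"rRNA"`,
#'   `"D-loop"`) and `complex` (OXPHOS complex label or `NA`).
#' @export
mito_genes <- function() {
  g <- function(gene, start, end, strand, category, complex = NA_character_)
    data.frame(gene = gene, start = as.integer(start), end = as.integer(end),
               strand = strand, category = category, complex = complex,
               stringsAsFactors = FALSE)
  rbind(
    g("D-loop",  16024, 16569, "+", "D-loop"),
    g("D-loop",      1,   576, "+", "D-loop"),
    g("MT-TF",     577,   647, "+", "tRNA"),
    g("MT-RNR1",   648,  1601, "+", "rRNA"),
    g("MT-TV",    1602,  1670, "+", "tRNA"),
    g("MT-RNR2",  1671,  3229, "+", "rRNA"),
    g("MT-TL1",   3230,  3304, "+", "tRNA"),
    g("MT-ND1",   3307,  4262, "+", "OXPHOS", "I"),
    g("MT-TI",    4263,  4331, "+", "tRNA"),
    g("MT-TQ",    4329,  4400, "-", "tRNA"),
    g("MT-TM",    4402,  4469, "+", "tRNA"),
    g("MT-ND2",   4470,  5511, "+", "OXPHOS", "I"),
    g("MT-TW",    5512,  5579, "+", "tRNA"),
    g("MT-TA",    5587,  5655, "-", "tRNA"),
    g("MT-TN",    5657,  5729, "-", "tRNA"),
    g("MT-TC",    5761,  5826, "-", "tRNA"),
    g("MT-TY",    5826,  5891, "-", "tRNA"),
    g("MT-CO1",   5904,  7445, "+", "OXPHOS", "IV"),
    g("MT-TS1",   7446,  7514, "-", "tRNA"),
    g("MT-TD",    7518,  7585, "+", "tRNA"),
    g("MT-CO2",   7586,  8269, "+", "OXPHOS", "IV"),
    g("MT-TK",    8295,  8364, "+", "tRNA"),
    g("MT-ATP8",  8366,  8572, "+", "OXPHOS", "V"),
    g("MT-ATP6",  8527,  9207, "+", "OXPHOS", "V"),
    g("MT-CO3",   9207,  9990, "+", "OXPHOS", "IV"),
    g("MT-TG",    9991, 10058, "+", "tRNA"),
    g("MT-ND3",  10059, 10404, "+", "OXPHOS", "I"),
    g("MT-TR",   10405, 10469, "+", "tRNA"),
    g("MT-ND4L", 10470, 10766, "+", "OXPHOS", "I"),
    g("MT-ND4",  10760, 12137, "+", "OXPHOS", "I"),
    g("MT-TH",   12138, 12206, "+", "tRNA"),
    g("MT-TS2",  12207, 12265, "+", "tRNA"),
    g("MT-TL2",  12266, 12336, "+", "tRNA"),
    g("MT-ND5",  12337, 14148, "+", "OXPHOS", "I"),
    g("MT-ND6",  14149, 14673, "-", "OXPHOS", "I"),
    g("MT-TE",   14674, 14742, "-", "tRNA"),
    g("MT-CYB",  14747, 15887, "+", "OXPHOS", "III"),
    g("MT-TT",   15888, 15953, "+", "tRNA"),
    g("MT-TP",   15956, 16023, "-", "tRNA")
  )
}

#' Default low-complexity masked regions
#'
#' Homopolymeric/low-complexity stretches of the mitochondrial genome in
#' which heteroplasmy calls are unreliable and are excluded.
#'
#' @return A data.frame with 1-based inclusive columns `start`, `end`.
#' @export
mito_masks <- function() {
  data.frame(start = c(302L, 512L, 16184L),
             end   = c(316L, 526L, 16193L))
}

# Deterministic synthetic 16,569-bp sequence (LCG; does not touch the
# session RNG). The packaged sequence is synthetic: users supply a true
# rCRS FASTA for real analyses; no result here depends on the exact bases.
synthetic_mito_sequence <- function(length = MT_LENGTH) {
  x <- numeric(length)
  s <- 20220701
  for (i in seq_len(length)) {          # Park-Miller; exact in doubles
    s <- (16807 * s) %% 2147483647
    x[i] <- s
  }
  c("A", "C", "G", "T")[(x %% 4) + 1]
}

#' Build a mitochondrial reference model
#'
#' Bundles the reference sequence, gene annotation and masked regions into
#' the object consumed by the annotation, calling and selection layers.
#'
#' @param fasta Optional path to a single-sequence FASTA file (e.g. the
#'   rCRS). When `NULL`, a packaged synthetic 16,569-bp sequence is used;
#'   it carries the standard gene map but arbitrary bases.
#' @param genes Gene annotation data.frame as from [mito_genes()].
#' @param masks Masked-region data.frame as from [mito_masks()].
#' @param dloop_wrap_len Length (bp) of the terminal segment duplicated at
#'   the start for circular D-loop alignment support; positions within this
#'   distance of either end are treated as one contiguous region.
#' @return An object of class `mito_reference` with fields `length`,
#'   `sequence` (character vector of single bases), `genes`, `masks`,
#'   `dloop_wrap_len`.
#' @export
mito_reference <- function(fasta = NULL, genes = mito_genes(),
                           masks = mito_masks(), dloop_wrap_len = 150L) {
  if (is.null(fasta)) {
    seq <- synthetic_mito_sequence()
  } else {
    ss <- Biostrings::readDNAStringSet(fasta)
    if (length(ss) != 1L) stop("reference FASTA must contain exactly one sequence")
    seq <- strsplit(as.character(ss[[1L]]), "", fixed = TRUE)[[1L]]
  }
  seq <- toupper(seq)
  if (!all(seq %in% c("A", "C", "G", "T", "N")))
    stop("reference sequence contains characters outside {A,C,G,T,N}")
  stopifnot(all(genes$start >= 1L), all(genes$end <= length(seq)),
            all(genes$start <= genes$end))
  obj <- list(length = length(seq), sequence = seq, genes = genes,
              masks = masks, dloop_wrap_len = as.integer(dloop_wrap_len))
  class(obj) <- "mito_reference"
  obj
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("Mitochondrial reference model\n")
  cat("  length:", x$length, "bp;", nrow(x$genes), "gene records;",
      nrow(x$masks), "masked intervals\n")
  invisible(x)
}

check_pos <- function(ref_obj, pos) {
  if (any(pos < 1L | pos > ref_obj$length))
    stop("position out of range [1, ", ref_obj$length, "]: ",
         paste(pos[pos < 1L | pos > ref_obj$length], collapse = ", "))
  invisible(pos)
}

#' Masked-state of positions
#'
#' @param ref_obj A [mito_reference()] object.
#' @param pos Integer vector of 1-based positions.
#' @return Logical vector: `TRUE` where the position lies in a
#'   low-complexity masked interval.
#' @export
is_masked <- function(ref_obj, pos) {
  check_pos(ref_obj, pos)
  m <- ref_obj$masks
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(m)))
    out <- out | (pos >= m$start[i] & pos <= m$end[i])
  out
}

#' Transition versus transversion
#'
#' @param ref,alt Single bases in `{A,C,G,T}`; vectors recycle.
#' @return Logical: `TRUE` for purine-purine or pyrimidine-pyrimidine
#'   changes (A<->G, C<->T), `FALSE` for transversions.
#' @export
is_transition <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases))
    stop("ref and alt must be in {A,C,G,T}")
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- function(b) b %in% c("A", "G")
  purine(ref) == purine(alt)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

mito_code <- function() Biostrings::getGeneticCode("2")  # vertebrate mitochondrial

# amino acid encoded by the codon containing `pos` in gene row `grow`,
# with the base at `pos` replaced by `base`; NA if the codon is truncated
codon_aa <- function(ref_obj, grow, pos, base) {
  code <- mito_code()
  if (grow$strand == "+") {
    off <- pos - grow$start
    cstart <- grow$start + 3L * (off %/% 3L)
    idx <- cstart + 0:2
    if (idx[3L] > grow$end) return(NA_character_)
    codon <- ref_obj$sequence[idx]
    codon[pos - cstart + 1L] <- base
  } else {
    off <- grow$end - pos
    cstart <- grow$end - 3L * (off %/% 3L)
    idx <- cstart - (0:2)
    if (idx[3L] < grow$start) return(NA_character_)
    codon <- unname(COMPLEMENT[ref_obj$sequence[idx]])
    codon[cstart - pos + 1L] <- unname(COMPLEMENT[base])
  }
  aa <- code[paste(codon, collapse = "")]
  if (is.na(aa)) NA_character_ else unname(aa)
}

#' Annotate a single-nucleotide variant
#'
#' Maps an mtDNA variant to its gene membership(s) and coding consequence.
#' Variants in gene overlaps return one row per gene; consequence is
#' computed per gene with the vertebrate mitochondrial codon table.
#'
#' @param ref_obj A [mito_reference()] object.
#' @param pos 1-based position.
#' @param ref,alt Reference and alternative base. `ref` must match the
#'   reference sequence at `pos`.
#' @return A data.frame with one row per overlapping gene (or one
#'   `"noncoding"` row if none) and columns `pos`, `ref`, `alt`, `gene`,
#'   `category`, `complex`, `coding_effect` (one of `"synonymous"`,
#'   `"nonsynonymous"`, `"tRNA"`, `"rRNA"`, `"D-loop"`, `"other"`),
#'   `transition`, `masked`.
#' @export
annotate_variant <- function(ref_obj, pos, ref, alt) {
  stopifnot(length(pos) == 1L, length(ref) == 1L, length(alt) == 1L)
  check_pos(ref_obj, pos)
  rbase <- ref_obj$sequence[pos]
  if (!identical(toupper(ref), rbase))
    stop("ref allele '", ref, "' does not match reference base '", rbase,
         "' at position ", pos)
  trans <- is_transition(ref, alt)
  g <- ref_obj$genes
  hit <- g[g$start <= pos & g$end >= pos, , drop = FALSE]
  if (nrow(hit) == 0L) {
    hit <- data.frame(gene = "intergenic", start = pos, end = pos,
                      strand = "+", category = "noncoding",
                      complex = NA_character_, stringsAsFactors = FALSE)
  }
  eff <- character(nrow(hit))
  for (i in seq_len(nrow(hit))) {
    eff[i] <- switch(hit$category[i],
      "tRNA"   = "tRNA",
      "rRNA"   = "rRNA",
      "D-loop" = "D-loop",
      "OXPHOS" = {
        a0 <- codon_aa(ref_obj, hit[i, ], pos, ref)
        a1 <- codon_aa(ref_obj, hit[i, ], pos, alt)
        if (is.na(a0) || is.na(a1)) "other"
        else if (a0 == a1) "synonymous" else "nonsynonymous"
      },
      "other")
  }
  data.frame(pos = pos, ref = ref, alt = alt, gene = hit$gene,
             category = hit$category, complex = hit$complex,
             coding_effect = eff, transition = trans,
             masked = is_masked(ref_obj, pos), stringsAsFactors = FALSE)
}

category_positions <- function(ref_obj, category) {
  g <- ref_obj$genes
  if (identical(category, "noncoding")) {
    covered <- rep(FALSE, ref_obj$length)
    for (i in seq_len(nrow(g))) covered[g$start[i]:g$end[i]] <- TRUE
    return(which(!covered))
  }
  rows <- g[g$category == category, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown gene category: ", category)
  sort(unique(unlist(mapply(seq.int, rows$start, rows$end,
                            SIMPLIFY = FALSE))))
}

# Vectorized coding consequence for every possible change in OXPHOS
# genes; positions in gene overlaps are deduped to the most severe effect
# (nonsynonymous > synonymous > other). Agrees with annotate_variant's
# per-codon computation; this form exists because the change universe has
# ~3e4 entries.
oxphos_consequences <- function(ref_obj) {
  code <- mito_code()
  g <- ref_obj$genes[ref_obj$genes$category == "OXPHOS", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(g))) {
    s <- g$start[i]; e <- g$end[i]; len <- e - s + 1L
    ncod <- len %/% 3L
    fwd <- g$strand[i] == "+"
    posv <- if (fwd) s + 0:(3L * ncod - 1L) else e - 0:(3L * ncod - 1L)
    bas <- ref_obj$sequence[posv]
    if (!fwd) bas <- unname(COMPLEMENT[bas])
    pm <- matrix(posv, nrow = 3L)
    bm <- matrix(bas, nrow = 3L)
    ref_codon <- paste0(bm[1L, ], bm[2L, ], bm[3L, ])
    aa_ref <- code[ref_codon]
    for (slot in 1:3) {
      for (alt in BASES) {
        cod_alt <- if (fwd) alt else unname(COMPLEMENT[alt])
        keep <- bm[slot, ] != cod_alt
        if (!any(keep)) next
        mut <- ref_codon[keep]
        substr(mut, slot, slot) <- cod_alt
        aa_alt <- code[mut]
        out[[length(out) + 1L]] <- data.frame(
          pos = pm[slot, keep], alt = alt, gene = g$gene[i],
          coding_effect = ifelse(aa_alt == aa_ref[keep],
                                 "synonymous", "nonsynonymous"),
          stringsAsFactors = FALSE)
      }
    }
    tail_pos <- if (ncod * 3L < len) {
      if (fwd) (s + 3L * ncod):e else s:(e - 3L * ncod)
    } else integer()
    if (length(tail_pos)) {
      tp <- rep(tail_pos, each = 3L)
      tr <- ref_obj$sequence[tp]
      ta <- unlist(lapply(ref_obj$sequence[tail_pos],
                          function(r) BASES[BASES != r]), use.names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        pos = tp, alt = ta, gene = g$gene[i], coding_effect = "other",
        stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, out)
  sev <- match(all$coding_effect, c("nonsynonymous", "synonymous", "other"))
  all <- all[order(all$pos, all$alt, sev), ]
  all[!duplicated(all[, c("pos", "alt")]), c("pos", "alt", "coding_effect")]
}

#' Enumerate all possible nucleotide changes in a gene category
#'
#' The change universe underlying the rank-based pathogenicity z-scores and
#' the stratified resampling selection test: every position of the category
#' contributes exactly its 3 alternative alleles.
#'
#' @param ref_obj A [mito_reference()] object.
#' @param category Gene category: `"OXPHOS"`, `"tRNA"`, `"rRNA"`,
#'   `"D-loop"` or `"noncoding"`.
#' @param exclude_masked Drop changes at masked low-complexity positions.
#' @return A data.frame with columns `pos`, `ref`, `alt`, `transition`,
#'   `category`, `masked` (3 rows per retained position).
#' @export
enumerate_changes <- function(ref_obj, category, exclude_masked = FALSE) {
  pos <- category_positions(ref_obj, category)
  bases <- c("A", "C", "G", "T")
  ref <- ref_obj$sequence[pos]
  keep <- ref %in% bases
  pos <- pos[keep]; ref <- ref[keep]
  pos3 <- rep(pos, each = 3L)
  ref3 <- rep(ref, each = 3L)
  alt3 <- unlist(lapply(ref, function(r) bases[bases != r]), use.names = FALSE)
  out <- data.frame(pos = pos3, ref = ref3, alt = alt3,
                    transition = is_transition(ref3, alt3),
                    category = category,
                    masked = is_masked(ref_obj, pos3),
                    stringsAsFactors = FALSE)
  if (exclude_masked) out <- out[!out$masked, , drop = FALSE]
  rownames(out) <- NULL
  out
}
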