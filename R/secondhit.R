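#' Chi-squared allelic-imbalance test on paired read counts
#'
#' Pearson's chi-squared test (1 degree of freedom, no continuity
#' correction unless `correct = TRUE`) on the 2x2 table
#' `[[g_ref, g_alt], [t_ref, t_alt]]` of germline versus tumor REF/ALT
#' read counts. A shift of the variant allele fraction between tissues is
#' the read-count footprint of a somatic second hit at the locus. The
#' statistic is computed in its determinant form
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` and referred to the
#' chi-squared(1) survival function.
#'
#' All four arguments may be vectors. Tables with a zero row or column
#' margin leave the test undefined; those entries return `NA` with a
#' warning and are treated downstream as no evidence.
#'
#' @param g_ref,g_alt Germline REF/ALT read counts.
#' @param t_ref,t_alt Tumor REF/ALT read counts.
#' @param correct Apply the Yates continuity correction (default FALSE;
#'   the uncorrected test reproduces the worked examples).
#' @return Two-sided p-value(s).
#' @export
allelic_imbalance_test <- function(g_ref, g_alt, t_ref, t_alt,
                                   correct = FALSE) {
  a <- as.numeric(g_ref); b <- as.numeric(g_alt)
  c_ <- as.numeric(t_ref); d <- as.numeric(t_alt)
  if (any(c(a, b, c_, d) < 0, na.rm = TRUE)) stop("counts must be >= 0")
  n <- a + b + c_ + d
  m <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  undef <- is.na(m) | m == 0
  det <- a * d - b * c_
  if (correct) {
    det <- pmax(abs(det) - n / 2, 0)
  }
  stat <- n * det^2 / m
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (any(undef)) {
    warning("zero margin: allelic-imbalance test undefined for ",
            sum(undef), " table(s); returning NA")
    p[undef] <- NA_real_
  }
  p
}

#' Direction of allelic change in the tumor
#'
#' `"variant-retained"` when the tumor variant allele fraction exceeds the
#' germline one (the footprint of losing the wild-type allele),
#' `"wt-retained"` when it is strictly lower, `"balanced"` when equal.
#'
#' @inheritParams allelic_imbalance_test
#' @return Character vector.
#' @export
retention_direction <- function(g_ref, g_alt, t_ref, t_alt) {
  gd <- g_ref + g_alt; td <- t_ref + t_alt
  if (any(gd <= 0 | td <= 0, na.rm = TRUE) || any(is.na(gd + td))) {
    stop("retention direction undefined at zero depth")
  }
  gv <- g_alt / gd; tv <- t_alt / td
  ifelse(tv > gv, "variant-retained",
         ifelse(tv < gv, "wt-retained", "balanced"))
}

#' Look up the single segment covering a position
#'
#' Coordinates are 1-based inclusive; a position on a boundary belongs to
#' the segment containing it.
#'
#' @param chrom,pos Locus.
#' @param segments Segment table for one patient.
#' @return The covering segment row.
#' @export
lookup_segment <- function(chrom, pos, segments) {
  s <- segments[segments$chrom == chrom & segments$start <= pos &
                  segments$end >= pos, , drop = FALSE]
  if (nrow(s) == 0) {
    stop(sprintf("uncovered locus: %s:%d has no segment", chrom, pos))
  }
  if (nrow(s) > 1) {
    stop(sprintf("overlapping segments at %s:%d", chrom, pos))
  }
  s
}

#' Classify the LOH retention type of a variant
#'
#' A second hit by LOH is called only when the allelic-imbalance p-value is
#' at most `p_cutoff`, the variant allele is the retained one, and the
#' minor copy number at the locus is 0. The type then follows the total
#' copy number: 1 = `DEL-LOH` (loss of the wild-type allele), 2 = `CN-LOH`
#' (copy-neutral), >= 3 = `DUP-LOH` (variant multiplied, wild type lost).
#'
#' @param p Allelic-imbalance p-value (NA = no evidence).
#' @param direction From [retention_direction()].
#' @param total_cn,minor_cn Copy state at the locus.
#' @param p_cutoff Inclusive significance cutoff (default 0.05).
#' @return One of `"DEL-LOH"`, `"CN-LOH"`, `"DUP-LOH"`, `"none"`.
#' @export
classify_loh_type <- function(p, direction, total_cn, minor_cn,
                              p_cutoff = 0.05) {
  ifelse(
    is.na(p) | p > p_cutoff | direction != "variant-retained" | minor_cn != 0,
    "none",
    ifelse(total_cn == 1, "DEL-LOH",
           ifelse(total_cn == 2, "CN-LOH",
                  ifelse(total_cn >= 3, "DUP-LOH", "none")))
  )
}

#' Find a somatic second point mutation in a gene
#'
#' Returns the key of a loss-of-function or splice-site somatic variant in
#' the same gene as a germline candidate, or `NA`.
#'
#' @param gene Gene symbol.
#' @param somatic Filtered somatic variant table (one patient).
#' @return `chrom:pos:ref:alt` key or `NA_character_`.
#' @export
detect_somatic_second_hit <- function(gene, somatic) {
  if (is.null(somatic) || nrow(somatic) == 0) return(NA_character_)
  hit <- somatic[!is.na(somatic$gene) & somatic$gene == gene &
                   somatic$consequence %in% .truncating, , drop = FALSE]
  if (nrow(hit) == 0) return(NA_character_)
  variant_key(hit[1, ])
}

#' Scan for purely somatic biallelic inactivation
#'
#' Genes carrying a somatic loss-of-function or splice variant whose locus
#' additionally shows LOH (minor copy number 0) are biallelically
#' inactivated without any germline event; they are reported with the
#' retention type implied by the total copy number.
#'
#' @param somatic Filtered somatic variant table (one patient).
#' @param segments Segment table (same patient).
#' @param gene_table Gene table (restricts the scan to listed genes).
#' @return Data frame `gene`, `key`, `retention` (possibly empty).
#' @export
somatic_biallelic_scan <- function(somatic, segments,
                                   gene_table = default_gene_table()) {
  out <- data.frame(gene = character(), key = character(),
                    retention = character(), stringsAsFactors = FALSE)
  if (is.null(somatic) || nrow(somatic) == 0) return(out)
  lof <- somatic[!is.na(somatic$gene) & somatic$gene %in% gene_table$symbol &
                   somatic$consequence %in% .truncating, , drop = FALSE]
  for (i in seq_len(nrow(lof))) {
    s <- tryCatch(lookup_segment(lof$chrom[i], lof$pos[i], segments),
                  error = function(e) NULL)
    if (is.null(s) || s$minor_cn != 0) next
    ret <- if (s$total_cn == 1) "DEL-LOH" else if (s$total_cn == 2) "CN-LOH"
           else if (s$total_cn >= 3) "DUP-LOH" else NA_character_
    if (is.na(ret)) next
    out <- rbind(out, data.frame(gene = lof$gene[i],
                                 key = variant_key(lof[i, ]),
                                 retention = ret, stringsAsFactors = FALSE))
  }
  out
}

#' Call per-gene copy-number events
#'
#' Hemizygous deletion = total copy number 1 over the gene; homozygous
#' deletion = 0; amplification = total copy number >= `amp_threshold` for
#' the designated amplification genes (ERBB2, MYC, ZNF703 by default).
#'
#' @param segments Segment table (one patient).
#' @param gene_table Gene table with `chrom`, `pos`.
#' @param amp_genes Genes eligible for the amplification call.
#' @param amp_threshold Copy-number threshold (default 6).
#' @return Data frame `gene`, `event`.
#' @export
call_cn_events <- function(segments, gene_table = default_gene_table(),
                           amp_genes = c("ERBB2", "MYC", "ZNF703"),
                           amp_threshold = 6) {
  ev <- vapply(seq_len(nrow(gene_table)), function(i) {
    s <- tryCatch(lookup_segment(gene_table$chrom[i], gene_table$pos[i],
                                 segments), error = function(e) NULL)
    if (is.null(s)) return("none")
    if (s$total_cn == 0) return("homozygous-deletion")
    if (s$total_cn == 1) return("hemizygous-deletion")
    if (s$total_cn >= amp_threshold &&
        gene_table$symbol[i] %in% amp_genes) return("amplification")
    "none"
  }, character(1))
  data.frame(gene = gene_table$symbol, event = ev, stringsAsFactors = FALSE)
}

#' Second-hit evaluation of germline candidates
#'
#' For every candidate variant: the allelic-imbalance test on the paired
#' read counts, the retention direction, LOH typing from the covering
#' allele-specific segment, and the search for a somatic second point
#' mutation in the same gene.
#'
#' @param candidates Candidate germline variant table (one or more
#'   patients).
#' @param segments Cohort segment table with `patient_id`.
#' @param somatic Filtered somatic variant table with `patient_id`.
#' @param p_cutoff Inclusive p cutoff (default 0.05).
#' @param correct Continuity correction flag passed to the test.
#' @return The candidates with `p_value`, `direction`, `retention`,
#'   `somatic_point_hit` columns appended.
#' @export
evaluate_second_hits <- function(candidates, segments, somatic,
                                 p_cutoff = 0.05, correct = FALSE) {
  n <- nrow(candidates)
  p <- rep(NA_real_, n); dir_ <- rep(NA_character_, n)
  ret <- rep("none", n); sp <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- candidates[i, ]
    gd <- v$g_ref + v$g_alt; td <- v$t_ref + v$t_alt
    if (!is.na(gd) && !is.na(td) && gd > 0 && td > 0) {
      p[i] <- suppressWarnings(
        allelic_imbalance_test(v$g_ref, v$g_alt, v$t_ref, v$t_alt, correct))
      dir_[i] <- retention_direction(v$g_ref, v$g_alt, v$t_ref, v$t_alt)
    }
    seg <- tryCatch(
      lookup_segment(v$chrom, v$pos,
                     segments[segments$patient_id == v$patient_id, ]),
      error = function(e) NULL)
    if (!is.null(seg) && !is.na(dir_[i])) {
      ret[i] <- classify_loh_type(p[i], dir_[i], seg$total_cn, seg$minor_cn,
                                  p_cutoff)
    }
    som_p <- somatic[somatic$patient_id == v$patient_id, , drop = FALSE]
    sp[i] <- detect_somatic_second_hit(v$gene, som_p)
  }
  candidates$p_value <- p
  candidates$direction <- dir_
  candidates$retention <- ret
  candidates$somatic_point_hit <- sp
  candidates
}
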