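#' Germline variant quality filter
#'
#' A germline variant is kept iff (i) its position is covered by at least
#' `min_depth` reads, (ii) at least `min_alt` reads support the alternative
#' allele, (iii) its allelic fraction lies inside `af_range` (endpoints
#' inclusive), and (iv) its mapping quality is at least `min_mq`. Each
#' removed variant is tagged with the first failing rule in order
#' (i)-(iv); variants with missing counts are routed to `removed` with
#' reason `"unscorable"`.
#'
#' @param variants Variant table (germline rows).
#' @param min_depth Minimum depth (default 5 reads).
#' @param min_alt Minimum ALT-supporting reads (default 2).
#' @param af_range Allelic-fraction window kept, inclusive (default
#'   `c(0.35, 0.5)`).
#' @param min_mq Minimum mapping quality (default 30).
#' @return List with `kept` and `removed` (the latter with a `reason`
#'   column); the two partition the input.
#' @export
filter_germline_quality <- function(variants, min_depth = 5, min_alt = 2,
                                    af_range = c(0.35, 0.5), min_mq = 30) {
  depth <- variants$g_ref + variants$g_alt
  af <- ifelse(depth > 0, variants$g_alt / depth, NA_real_)
  reason <- rep(NA_character_, nrow(variants))
  unscorable <- is.na(variants$g_ref) | is.na(variants$g_alt)
  reason[unscorable] <- "unscorable"
  ok <- !unscorable
  r4 <- ok & (is.na(variants$mq) | variants$mq < min_mq)
  reason[r4] <- "iv"
  r3 <- ok & !is.na(af) & (af < af_range[1] | af > af_range[2])
  reason[r3] <- "iii"
  r2 <- ok & variants$g_alt < min_alt
  reason[r2] <- "ii"
  r1 <- ok & depth < min_depth
  reason[r1] <- "i"
  removed <- !is.na(reason)
  out_removed <- variants[removed, , drop = FALSE]
  out_removed$reason <- reason[removed]
  list(kept = variants[!removed, , drop = FALSE], removed = out_removed)
}

#' Population allele-frequency filter
#'
#' Keeps variants whose maximum population allele frequency over the
#' provided reference sources is strictly below `threshold` (0.01 by
#' default). A missing frequency is treated as 0: unobserved variants are
#' exactly the search target.
#'
#' @param variants Variant table with a `pop_af` column (maximum over
#'   sources).
#' @param threshold Strict upper bound (default 0.01).
#' @return The kept subset.
#' @export
filter_population_frequency <- function(variants, threshold = 0.01) {
  af <- variants$pop_af
  af[is.na(af)] <- 0
  variants[af < threshold, , drop = FALSE]
}

#' In-silico predictor consensus
#'
#' TRUE iff at least `quorum` of the 8 deleteriousness predictors (SIFT,
#' PolyPhen2, MutationTaster, FATHMM, Provean, MetaSVM, MetaLR, CADD) call
#' the variant deleterious. Absent calls count toward the denominator of 8,
#' not the numerator.
#'
#' @param calls Logical vector of up to 8 calls (NA allowed).
#' @param quorum Minimum number of deleterious calls (default 4).
#' @return Logical scalar.
#' @export
predictor_consensus <- function(calls, quorum = 4) {
  if (length(calls) > 8) stop("more than 8 predictor calls supplied")
  sum(calls, na.rm = TRUE) >= quorum
}

.truncating <- c("nonsense", "frameshift", "splice")

#' Route a candidate variant after quality and frequency filtering
#'
#' Implements the candidate-selection decision: benign/likely-benign by
#' ClinVar (or by ACMG when ClinVar is absent) is dropped; truncating and
#' splice variants go to the master list; missense variants in clinical
#' BCSG genes go to the master list regardless of predictor scores;
#' missense variants in other categories require the 4-of-8 predictor
#' consensus; synonymous and other consequences are dropped.
#'
#' @param variants Variant table (must have passed quality and frequency
#'   filters).
#' @param category Character vector of gene categories, one per variant
#'   (see [assign_gene_category()]).
#' @param quorum Predictor quorum (default 4).
#' @return Character vector of dispositions: `"master-list"`,
#'   `"dropped-benign"`, `"dropped-prediction"` or `"dropped-consequence"`.
#' @export
route_candidate <- function(variants, category, quorum = 4) {
  n <- nrow(variants)
  stopifnot(length(category) == n)
  clin <- variants$clinvar
  clin[is.na(clin)] <- "Unknown"
  benign_class <- c("Benign", "Likely benign", "Likely Benign")
  screen <- ifelse(clin %in% c("Unknown", ""), variants$acmg, clin)
  is_benign <- !is.na(screen) & screen %in% benign_class
  pred <- vapply(seq_len(n), function(i) {
    predictor_consensus(unlist(variants[i, predictor_columns]), quorum)
  }, logical(1))
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (is_benign[i]) {
      "dropped-benign"
    } else if (variants$consequence[i] %in% .truncating) {
      "master-list"
    } else if (variants$consequence[i] == "missense") {
      if (category[i] == "BCSG" || pred[i]) "master-list"
      else "dropped-prediction"
    } else {
      "dropped-consequence"
    }
  }
  out
}

#' Select germline candidate variants
#'
#' Convenience wrapper running the full germline arm: quality filter,
#' population-frequency filter, gene-category assignment and candidate
#' routing. Returns the master list with `category` and `disposition`
#' columns plus the removal log.
#'
#' @param variants Germline variant table.
#' @param gene_table Gene category table.
#' @param config Pipeline configuration (see [pipeline_config()]).
#' @return List with `candidates` (master list), `removed` (quality
#'   removals with reasons), `dropped` (routing drops with disposition).
#' @export
select_germline_candidates <- function(variants,
                                       gene_table = default_gene_table(),
                                       config = pipeline_config()) {
  q <- filter_germline_quality(variants,
                               min_depth = config$germline_min_depth,
                               min_alt = config$germline_min_alt,
                               af_range = config$germline_af_range,
                               min_mq = config$germline_min_mq)
  kept <- filter_population_frequency(q$kept, config$pop_af_threshold)
  if (nrow(kept) == 0) {
    kept$category <- character(0); kept$disposition <- character(0)
    return(list(candidates = kept, removed = q$removed, dropped = kept))
  }
  kept$category <- assign_gene_category(kept$gene, gene_table)
  kept$disposition <- route_candidate(kept, kept$category,
                                      config$predictor_quorum)
  list(candidates = kept[kept$disposition == "master-list", , drop = FALSE],
       removed = q$removed,
       dropped = kept[kept$disposition != "master-list", , drop = FALSE])
}

# two-sided exact binomial test of the alt-read strand split against the
# reference strand ratio (0.5 when unknown); FFPE artifacts pile their
# support on one strand
.strand_bias_p <- function(fwd, rev, p0 = 0.5) {
  n <- fwd + rev
  if (is.na(n) || n == 0) return(1)
  stats::binom.test(fwd, n, p = p0, alternative = "two.sided")$p.value
}

#' Somatic variant filter
#'
#' A somatic call is kept iff it (i) shows no strand bias (two-sided exact
#' binomial test of the ALT forward/reverse split, applied when at least
#' `strand_min_alt` ALT reads are present; removal at `p < strand_p`),
#' (ii) is not present among the patient's germline calls, (iii) is not in
#' the panel of normals, and (iv) has tumor depth of at least `min_depth`
#' reads. Removals are tagged with the first failing rule in order
#' (i)-(iv).
#'
#' @param variants Somatic variant table.
#' @param pon Panel of normals: data frame with `chrom`, `pos`, `ref`,
#'   `alt` (or a character vector of `chrom:pos:ref:alt` keys).
#' @param matched_germline Optional germline variant table for the same
#'   patient(s).
#' @param min_depth Minimum tumor depth (default 10).
#' @param strand_p Strand-bias p-value cutoff (default 0.01).
#' @param strand_min_alt Minimum ALT reads before the strand test applies
#'   (default 6).
#' @return List with `kept` and `removed` (with `reason` column).
#' @export
filter_somatic <- function(variants, pon = NULL, matched_germline = NULL,
                           min_depth = 10, strand_p = 0.01,
                           strand_min_alt = 6) {
  n <- nrow(variants)
  pon_keys <- if (is.null(pon)) character(0)
    else if (is.character(pon)) pon else variant_key(pon)
  germ_keys <- if (is.null(matched_germline) || nrow(matched_germline) == 0) {
    character(0)
  } else {
    paste(matched_germline$patient_id, variant_key(matched_germline))
  }
  reason <- rep(NA_character_, n)
  depth <- variants$t_ref + variants$t_alt
  reason[!is.na(depth) & depth < min_depth] <- "iv"
  reason[is.na(reason) & variant_key(variants) %in% pon_keys] <- "iii"
  reason[is.na(reason) &
           paste(variants$patient_id, variant_key(variants)) %in% germ_keys] <- "ii"
  for (i in seq_len(n)) {
    if (!is.na(reason[i])) next
    alt_n <- variants$alt_fwd[i] + variants$alt_rev[i]
    if (!is.na(alt_n) && alt_n >= strand_min_alt &&
        .strand_bias_p(variants$alt_fwd[i], variants$alt_rev[i]) < strand_p) {
      reason[i] <- "i"
    }
  }
  # report the first failing rule in the documented order
  order_pref <- c(i = 1, ii = 2, iii = 3, iv = 4)
  # reasons ii-iv were assigned before i above only for efficiency; a
  # variant failing several rules must carry the earliest one, so re-check
  redo <- which(reason %in% c("ii", "iii", "iv"))
  for (i in redo) {
    alt_n <- variants$alt_fwd[i] + variants$alt_rev[i]
    if (!is.na(alt_n) && alt_n >= strand_min_alt &&
        .strand_bias_p(variants$alt_fwd[i], variants$alt_rev[i]) < strand_p) {
      reason[i] <- "i"
    } else if (reason[i] %in% c("iii", "iv") &&
               paste(variants$patient_id[i], variant_key(variants[i, ])) %in%
               germ_keys) {
      reason[i] <- "ii"
    } else if (reason[i] == "iv" &&
               variant_key(variants[i, ]) %in% pon_keys) {
      reason[i] <- "iii"
    }
  }
  removed <- !is.na(reason)
  out_removed <- variants[removed, , drop = FALSE]
  out_removed$reason <- reason[removed]
  list(kept = variants[!removed, , drop = FALSE], removed = out_removed)
}
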