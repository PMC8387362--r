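#' Loss-of-function population frequency
#'
#' `LF = 2 * S / m`, where `S` is the allelic count of loss-of-function
#' variants in a gene and `m` the median allele number in the population
#' reference.
#'
#' @param S Allelic count of LoF variants (>= 0).
#' @param m Median allele number (> 0).
#' @return Fraction.
#' @export
lof_frequency <- function(S, m) {
  if (any(m <= 0)) stop("median allele number must be positive")
  if (any(S < 0)) stop("allelic count must be non-negative")
  2 * S / m
}

#' Driver-gene recurrence report
#'
#' Counts how many patients carry a somatic variant in each driver gene;
#' when externally computed q-scores are supplied, genes mutated more than
#' once with q < 0.05 are flagged as drivers.
#'
#' @param somatic Filtered somatic variant table (cohort).
#' @param driver_genes Character vector of driver gene symbols.
#' @param q_scores Optional named numeric vector of per-gene q-scores.
#' @return Data frame `gene`, `n_patients`, `flagged` (NA without
#'   q-scores).
#' @export
driver_recurrence <- function(somatic, driver_genes, q_scores = NULL) {
  cnt <- vapply(driver_genes, function(g) {
    length(unique(somatic$patient_id[!is.na(somatic$gene) &
                                       somatic$gene == g]))
  }, integer(1))
  flagged <- rep(NA, length(driver_genes))
  if (!is.null(q_scores)) {
    q <- q_scores[driver_genes]
    flagged <- cnt > 1 & !is.na(q) & q < 0.05
  }
  data.frame(gene = driver_genes, n_patients = cnt, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Nominate candidate genes from the integrated evidence
#'
#' Applies the final inference of the two-hit HRD framework: a germline
#' candidate variant is nominated (`hrd-candidate-pathogenic`) only when
#' the same patient and gene carry a somatic second hit (LOH retention of
#' the variant or a somatic point hit) and the tumor is HRD by consensus.
#' Candidates with a second hit in a non-HRD tumor are `second-hit-only`;
#' HRD patients without any nominated candidate receive an
#' `hrd-no-candidate` row; everything else is `no-evidence`.
#'
#' Genes on `caveat_genes` (CHEK2 by default) are never nominated: their
#' biallelic loss is not associated with the HRD signature, so second-hit
#' evidence cannot reclassify their variants; such candidates are
#' downgraded to `second-hit-only`.
#'
#' @param candidates Candidate table from [evaluate_second_hits()].
#' @param hrd_calls Per-patient HRD table with `patient_id` and
#'   `consensus_positive` (and `sig3_present`).
#' @param caveat_genes Genes exempt from reclassification.
#' @param require_consensus Use the two-tool consensus for the HRD
#'   requirement (default); FALSE falls back to the Signature-3 call
#'   alone.
#' @return Data frame of candidate reports, one verdict per patient-gene
#'   pair (most damaging consequence first within a pair).
#' @export
nominate <- function(candidates, hrd_calls, caveat_genes = "CHEK2",
                     require_consensus = TRUE) {
  missing_pat <- setdiff(unique(candidates$patient_id), hrd_calls$patient_id)
  if (length(missing_pat) > 0) {
    stop("incomplete patient(s), missing HRD stage: ",
         paste(missing_pat, collapse = ", "))
  }
  hrd_flag <- if (require_consensus) hrd_calls$consensus_positive
              else hrd_calls$sig3_present
  names(hrd_flag) <- hrd_calls$patient_id
  sev <- c(nonsense = 1, frameshift = 2, splice = 3, missense = 4,
           synonymous = 5, other = 6)
  out <- list()
  if (nrow(candidates) > 0) {
    key <- paste(candidates$patient_id, candidates$gene)
    for (k in unique(key)) {
      grp <- candidates[key == k, , drop = FALSE]
      grp <- grp[order(sev[grp$consequence]), , drop = FALSE]
      v <- grp[1, ]
      second_hit <- any(grp$retention != "none") ||
        any(!is.na(grp$somatic_point_hit))
      hrd <- hrd_flag[[v$patient_id]]
      verdict <- if (second_hit && isTRUE(hrd)) {
        if (v$gene %in% caveat_genes) "second-hit-only"
        else "hrd-candidate-pathogenic"
      } else if (second_hit) {
        "second-hit-only"
      } else {
        "no-evidence"
      }
      ret1 <- grp$retention[grp$retention != "none"]
      sp1 <- grp$somatic_point_hit[!is.na(grp$somatic_point_hit)]
      out[[k]] <- data.frame(
        patient_id = v$patient_id, gene = v$gene, category = v$category,
        clinvar = v$clinvar, acmg = v$acmg, consequence = v$consequence,
        key = variant_key(v),
        retention = if (length(ret1)) ret1[1] else "none",
        somatic_point_hit = if (length(sp1)) sp1[1] else NA_character_,
        p_value = v$p_value, verdict = verdict,
        stringsAsFactors = FALSE
      )
    }
  }
  rep_df <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(patient_id = character(), gene = character(),
               category = character(), clinvar = character(),
               acmg = character(), consequence = character(),
               key = character(), retention = character(),
               somatic_point_hit = character(), p_value = numeric(),
               verdict = character(), stringsAsFactors = FALSE)
  # HRD patients with no nominated candidate
  nominated_pat <- unique(rep_df$patient_id[
    rep_df$verdict == "hrd-candidate-pathogenic"])
  hrd_pat <- hrd_calls$patient_id[!is.na(hrd_flag) & hrd_flag]
  for (p in setdiff(hrd_pat, nominated_pat)) {
    rep_df <- rbind(rep_df, data.frame(
      patient_id = p, gene = NA_character_, category = NA_character_,
      clinvar = NA_character_, acmg = NA_character_,
      consequence = NA_character_, key = NA_character_,
      retention = NA_character_, somatic_point_hit = NA_character_,
      p_value = NA_real_, verdict = "hrd-no-candidate",
      stringsAsFactors = FALSE
    ))
  }
  rownames(rep_df) <- NULL
  rep_df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the co-mutation summary
#'
#' Genes x patients matrix of event codes (germline class and second-hit
#' type) with per-patient HRD status rows on top, the machine-readable
#' form of a co-mutation (oncoprint-style) plot. Gene rows are grouped by
#' category.
#'
#' @param reports Candidate reports from [nominate()].
#' @param hrd_calls Per-patient HRD table.
#' @param gene_table Gene table (for category grouping).
#' @return Object of class `comutation_summary`: a character matrix with
#'   attributes `hrd` (per-patient HRD rows) and `categories`.
#' @export
build_comutation_summary <- function(reports, hrd_calls,
                                     gene_table = default_gene_table()) {
  patients <- hrd_calls$patient_id
  genes <- unique(reports$gene[!is.na(reports$gene)])
  cat_ <- assign_gene_category(genes, gene_table)
  ord <- order(match(cat_, c("BCSG", "CSG", "DNA-repair", "C-HRG", "other")))
  genes <- genes[ord]; cat_ <- cat_[ord]
  m <- matrix("", nrow = length(genes), ncol = length(patients),
              dimnames = list(genes, patients))
  for (i in seq_len(nrow(reports))) {
    r <- reports[i, ]
    if (is.na(r$gene) || !r$gene %in% genes) next
    code <- if (!is.na(r$retention) && r$retention != "none") r$retention
            else if (!is.na(r$somatic_point_hit)) "somatic-hit"
            else r$clinvar
    m[r$gene, r$patient_id] <- if (is.na(code)) "germline" else code
  }
  hrd <- rbind(
    sig3 = ifelse(is.na(hrd_calls$sig3_present), "no-call",
                  ifelse(hrd_calls$sig3_present, "positive", "negative")),
    scar = ifelse(hrd_calls$scar_positive, "positive", "negative"),
    consensus = ifelse(is.na(hrd_calls$consensus_positive), "no-call",
                       ifelse(hrd_calls$consensus_positive, "positive",
                              "negative"))
  )
  colnames(hrd) <- patients
  structure(m, hrd = hrd, categories = cat_, class = "comutation_summary")
}

#' @export
print.comutation_summary <- function(x, ...) {
  cat("Co-mutation summary:", nrow(x), "gene(s) x", ncol(x), "patient(s)\n")
  hrd <- attr(x, "hrd")
  cat("HRD consensus-positive patients:",
      paste(colnames(hrd)[hrd["consensus", ] == "positive"],
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.comutation_summary <- function(x, ...) {
  hrd <- attr(x, "hrd")
  all_rows <- rbind(hrd, x)
  codes <- sort(unique(as.vector(all_rows)))
  codes <- c("", setdiff(codes, ""))
  z <- matrix(match(all_rows, codes) - 1, nrow = nrow(all_rows))
  pal <- c("white", grDevices::hcl.colors(max(1, length(codes) - 1),
                                          "Spectral"))
  graphics::image(t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                  col = pal[seq_len(max(z) + 1)], axes = FALSE, ...)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(z)),
                 labels = rev(rownames(all_rows)), las = 2, cex.axis = 0.6)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(z)),
                 labels = colnames(all_rows), las = 2, cex.axis = 0.6)
  invisible(x)
}
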