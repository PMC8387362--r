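#' Run the full two-hit HRD pipeline on a cohort
#'
#' Executes the four analysis stages on cohort-level tables: germline
#' candidate selection, somatic filtering, second-hit evaluation, HRD
#' calling (Signature 3 + genomic scars) and candidate nomination.
#'
#' @param cohort An `hrd_cohort_sim` from [simulate_cohort()], or a list
#'   with elements `germline`, `somatic`, `segments` (cohort tables with
#'   `patient_id`), plus optional `pon`, `gene_table`, `layout`,
#'   `signature_matrix`.
#' @param config A [pipeline_config()].
#' @param calibration Optional pre-computed [calibrate_sig3()] result;
#'   computed from the config otherwise.
#' @return Object of class `hrd_cohort`: list with `candidates`,
#'   `germline_removed`, `germline_dropped`, `somatic_kept`,
#'   `somatic_removed`, `second_hits`, `hrd_calls`, `reports`,
#'   `comutation`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         calibration = NULL) {
  gene_table <- cohort$gene_table %||% default_gene_table()
  layout <- cohort$layout %||% default_genome_layout()
  M <- cohort$signature_matrix %||% synthetic_signatures()
  patients <- unique(c(cohort$germline$patient_id,
                       cohort$somatic$patient_id,
                       cohort$segments$patient_id))
  # stage 1: germline candidates
  germ <- select_germline_candidates(cohort$germline, gene_table, config)
  # stage 2: somatic filtering
  som <- filter_somatic(cohort$somatic, pon = cohort$pon,
                        matched_germline = cohort$germline,
                        min_depth = config$somatic_min_depth,
                        strand_p = config$strand_p,
                        strand_min_alt = config$strand_min_alt)
  # stage 3: second hits
  hits <- evaluate_second_hits(germ$candidates, cohort$segments, som$kept,
                               p_cutoff = config$ai_p_cutoff,
                               correct = config$continuity)
  # stage 4: HRD calls
  if (is.null(calibration)) {
    n_med <- stats::median(table(factor(som$kept$patient_id,
                                        levels = patients)))
    calibration <- calibrate_sig3(M, n_snvs = max(5, round(n_med)),
                                  n_null = config$sig3_n_null,
                                  fpr = config$sig3_fpr,
                                  min_snvs = config$sig3_min_snvs,
                                  seed = config$seed)
  }
  hrd <- do.call(rbind, lapply(patients, function(p) {
    cat_ <- suppressWarnings(
      build_96_catalog(som$kept[som$kept$patient_id == p, , drop = FALSE]))
    segs <- cohort$segments[cohort$segments$patient_id == p, , drop = FALSE]
    cbind(data.frame(patient_id = p, stringsAsFactors = FALSE),
          hrd_call(cat_, segs, M, calibration, layout,
                   config$scar_threshold))
  }))
  reports <- nominate(hits, hrd, caveat_genes = config$caveat_genes,
                      require_consensus = config$require_consensus)
  structure(list(
    candidates = germ$candidates, germline_removed = germ$removed,
    germline_dropped = germ$dropped, somatic_kept = som$kept,
    somatic_removed = som$removed, second_hits = hits, hrd_calls = hrd,
    reports = reports,
    comutation = build_comutation_summary(reports, hrd, gene_table),
    calibration = calibration, config = config
  ), class = "hrd_cohort")
}

#' Write all pipeline artifacts to a directory
#'
#' @param result An `hrd_cohort` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  stopifnot(inherits(result, "hrd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variants(result$second_hits, file.path(dir, "second_hits.tsv"))
  write_variants(result$germline_removed,
                 file.path(dir, "germline_removed.tsv"))
  write_variants(result$somatic_removed, file.path(dir, "somatic_removed.tsv"))
  utils::write.table(result$hrd_calls, file.path(dir, "hrd_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$reports, file.path(dir, "reports.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$reports, file.path(dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  cm <- result$comutation
  utils::write.table(
    rbind(attr(cm, "hrd"), unclass(cm))[, , drop = FALSE],
    file.path(dir, "comutation.tsv"), sep = "\t", quote = FALSE,
    col.names = NA)
  write_config(result$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.hrd_cohort <- function(x, ...) {
  n_pat <- nrow(x$hrd_calls)
  cat("Two-hit HRD cohort analysis\n")
  cat(sprintf("  patients: %d\n", n_pat))
  cat(sprintf("  germline candidates on master list: %d\n",
              nrow(x$candidates)))
  cat(sprintf("  somatic variants kept/removed: %d/%d\n",
              nrow(x$somatic_kept), nrow(x$somatic_removed)))
  cat(sprintf("  Sig3-positive: %d; scar-positive: %d; consensus HRD: %d\n",
              sum(x$hrd_calls$sig3_present, na.rm = TRUE),
              sum(x$hrd_calls$scar_positive, na.rm = TRUE),
              sum(x$hrd_calls$consensus_positive, na.rm = TRUE)))
  nom <- x$reports[x$reports$verdict == "hrd-candidate-pathogenic", ,
                   drop = FALSE]
  if (nrow(nom) > 0) {
    cat("  nominated HRD candidate gene(s):\n")
    for (i in seq_len(nrow(nom))) {
      cat(sprintf("    %s in %s (%s, p = %.3g)\n", nom$gene[i],
                  nom$patient_id[i], nom$retention[i], nom$p_value[i]))
    }
  } else {
    cat("  no HRD candidate gene nominated\n")
  }
  invisible(x)
}

#' @export
summary.hrd_cohort <- function(object, ...) {
  v <- table(object$reports$verdict)
  out <- list(
    n_patients = nrow(object$hrd_calls),
    n_candidates = nrow(object$candidates),
    n_sig3 = sum(object$hrd_calls$sig3_present, na.rm = TRUE),
    n_scar = sum(object$hrd_calls$scar_positive, na.rm = TRUE),
    n_consensus = sum(object$hrd_calls$consensus_positive, na.rm = TRUE),
    verdicts = v
  )
  class(out) <- "summary.hrd_cohort"
  out
}

#' @export
print.summary.hrd_cohort <- function(x, ...) {
  cat("patients:", x$n_patients, "\n")
  cat("master-list candidates:", x$n_candidates, "\n")
  cat(sprintf("HRD: %d Sig3-positive, %d scar-positive, %d consensus\n",
              x$n_sig3, x$n_scar, x$n_consensus))
  cat("verdicts:\n")
  print(x$verdicts)
  invisible(x)
}

#' @export
plot.hrd_cohort <- function(x, ...) {
  plot(x$comutation, ...)
}
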