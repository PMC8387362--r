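#' Pipeline configuration
#'
#' All thresholds of the analysis, with the published values as defaults.
#' Round-trips through YAML unchanged.
#'
#' @param germline_min_depth Minimum germline depth (5 reads).
#' @param germline_min_alt Minimum ALT-supporting reads (2).
#' @param germline_af_range Kept germline allelic-fraction window,
#'   inclusive (`c(0.35, 0.5)`).
#' @param germline_min_mq Minimum mapping quality (30).
#' @param pop_af_threshold Strict population allele-frequency cutoff
#'   (0.01).
#' @param predictor_quorum Deleterious predictors required of 8 (4).
#' @param somatic_min_depth Minimum tumor depth for somatic calls (10).
#' @param strand_p,strand_min_alt Strand-bias test cutoff and minimum ALT
#'   reads (0.01, 6).
#' @param ai_p_cutoff Inclusive allelic-imbalance p cutoff (0.05).
#' @param continuity Yates continuity correction for the test (FALSE).
#' @param scar_threshold Scar sum threshold (42).
#' @param hrd_loh_min_mb,lst_min_seg_mb,lst_smooth_mb Scar length
#'   constants (15, 10, 3 Mb).
#' @param sig3_n_null,sig3_fpr,sig3_min_snvs Signature-3 calibration
#'   settings.
#' @param caveat_genes Genes exempt from reclassification (CHEK2).
#' @param require_consensus Require the two-tool HRD consensus (TRUE).
#' @param seed Integer seed for the calibration.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(germline_min_depth = 5, germline_min_alt = 2,
                            germline_af_range = c(0.35, 0.5),
                            germline_min_mq = 30, pop_af_threshold = 0.01,
                            predictor_quorum = 4, somatic_min_depth = 10,
                            strand_p = 0.01, strand_min_alt = 6,
                            ai_p_cutoff = 0.05, continuity = FALSE,
                            scar_threshold = 42, hrd_loh_min_mb = 15,
                            lst_min_seg_mb = 10, lst_smooth_mb = 3,
                            sig3_n_null = 1000, sig3_fpr = 0.05,
                            sig3_min_snvs = 5, caveat_genes = "CHEK2",
                            require_consensus = TRUE, seed = 1L) {
  cfg <- list(
    germline_min_depth = germline_min_depth,
    germline_min_alt = germline_min_alt,
    germline_af_range = germline_af_range,
    germline_min_mq = germline_min_mq,
    pop_af_threshold = pop_af_threshold,
    predictor_quorum = predictor_quorum,
    somatic_min_depth = somatic_min_depth,
    strand_p = strand_p, strand_min_alt = strand_min_alt,
    ai_p_cutoff = ai_p_cutoff, continuity = continuity,
    scar_threshold = scar_threshold, hrd_loh_min_mb = hrd_loh_min_mb,
    lst_min_seg_mb = lst_min_seg_mb, lst_smooth_mb = lst_smooth_mb,
    sig3_n_null = sig3_n_null, sig3_fpr = sig3_fpr,
    sig3_min_snvs = sig3_min_snvs, caveat_genes = caveat_genes,
    require_consensus = require_consensus, seed = as.integer(seed)
  )
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.required_tsv_cols <- c("patient_id", "chrom", "pos", "ref", "alt", "origin")

#' Read a variant table
#'
#' The TSV dialect is the package's canonical plain-text mirror of
#' VCF/MAF-style records (one row per variant observation, 1-based
#' coordinates, the column set written by [write_variants()]). The VCF
#' dialect reads CHROM/POS/REF/ALT and per-sample AD counts from a VCF via
#' the vcfR package; annotation columns absent from the VCF are NA.
#' Malformed TSV rows are dropped and reported in the `bad_lines`
#' attribute.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param origin Origin assigned to VCF records (default "germline").
#' @return Variant data frame.
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf"),
                          origin = "germline") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(.required_tsv_cols, names(d))
    if (length(miss) > 0) {
      stop("variant table is missing mandatory column(s): ",
           paste(miss, collapse = ", "))
    }
    d$pos <- suppressWarnings(as.integer(d$pos))
    bad <- which(is.na(d$pos) | is.na(d$chrom) | d$chrom == "" |
                   is.na(d$ref) | d$ref == "")
    if (length(bad) > 0) d <- d[-bad, , drop = FALSE]
    for (p in predictor_columns) {
      if (!p %in% names(d)) d[[p]] <- NA
      d[[p]] <- as.logical(d[[p]])
    }
    for (col in setdiff(variant_columns, names(d))) d[[col]] <- NA
    d <- d[, variant_columns, drop = FALSE]
    attr(d, "bad_lines") <- bad
    return(d)
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  n <- nrow(fix)
  ref_c <- alt_c <- rep(NA_integer_, n)
  sample_id <- "sample"
  if (!is.null(ad) && ncol(ad) >= 1) {
    sample_id <- colnames(ad)[1]
    parts <- strsplit(ad[, 1], ",", fixed = TRUE)
    ref_c <- vapply(parts, function(x) as.integer(x[1]), integer(1))
    alt_c <- vapply(parts, function(x) as.integer(x[2]), integer(1))
  }
  d <- empty_variant_table()[rep(1L, 0), ]
  d <- data.frame(
    patient_id = sample_id, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, origin = origin, stringsAsFactors = FALSE
  )
  if (origin == "germline") {
    d$g_ref <- ref_c; d$g_alt <- alt_c
  } else {
    d$t_ref <- ref_c; d$t_alt <- alt_c
  }
  for (col in setdiff(variant_columns, names(d))) d[[col]] <- NA
  d[, variant_columns, drop = FALSE]
}

#' Write a variant table as TSV
#' @param variants Variant data frame.
#' @param path File path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write an allele-specific segment table (SEG-like TSV)
#'
#' Columns `chrom`, `start`, `end`, `total_cn`, `minor_cn` (optionally
#' `patient_id`), 1-based inclusive coordinates.
#'
#' @param path File path.
#' @param segments Segment data frame.
#' @export
read_segments <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("segment table is missing column(s): ", paste(miss, collapse = ", "))
  }
  d
}

#' @rdname read_segments
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a 96-channel catalog TSV (channel label + count)
#' @param path File path.
#' @param catalog Named length-96 count vector.
#' @export
read_catalog <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "count") %in% names(d)), nrow(d) == 96)
  ch <- catalog_channels()$label
  setNames(as.integer(d$count[match(ch, d$channel)]), ch)
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(
    data.frame(channel = names(catalog), count = as.integer(catalog)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a signature matrix TSV (channel column + one column per
#' signature)
#' @param path File path.
#' @param M 96 x K signature matrix.
#' @export
read_signature_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("channel" %in% names(d))
  M <- as.matrix(d[, setdiff(names(d), "channel"), drop = FALSE])
  rownames(M) <- d$channel
  ch <- catalog_channels()$label
  M <- M[match(ch, rownames(M)), , drop = FALSE]
  validate_signature_matrix(M)
  M
}

#' @rdname read_signature_matrix
#' @export
write_signature_matrix <- function(M, path) {
  d <- data.frame(channel = rownames(M), M, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene table TSV (symbol, category, chrom, pos[, start, end])
#' @param path File path.
#' @export
read_gene_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "category") %in% names(d)))
  if (!"start" %in% names(d) && "pos" %in% names(d)) {
    d$start <- pmax(1, d$pos - 5e4); d$end <- d$pos + 5e4
  }
  d
}

#' Write a simulated cohort to a directory
#'
#' Emits the germline and somatic variant TSVs, the SEG-like segment
#' table, the PoN key list, per-patient catalog TSVs, the gene table, the
#' signature matrix and the ground-truth JSON.
#'
#' @param cohort An `hrd_cohort_sim` (see [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hrd_cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variants(cohort$germline, file.path(dir, "germline.tsv"))
  write_variants(cohort$somatic, file.path(dir, "somatic.tsv"))
  write_segments(cohort$segments, file.path(dir, "segments.tsv"))
  utils::write.table(cohort$pon, file.path(dir, "pon.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$gene_table, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_signature_matrix(cohort$signature_matrix,
                         file.path(dir, "signatures.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory path.
#' @return List with the cohort tables.
#' @export
read_cohort <- function(dir) {
  list(
    germline = read_variants(file.path(dir, "germline.tsv"), "tsv"),
    somatic = read_variants(file.path(dir, "somatic.tsv"), "tsv"),
    segments = read_segments(file.path(dir, "segments.tsv")),
    pon = utils::read.delim(file.path(dir, "pon.tsv"),
                            stringsAsFactors = FALSE),
    gene_table = read_gene_table(file.path(dir, "genes.tsv")),
    signature_matrix = read_signature_matrix(file.path(dir,
                                                       "signatures.tsv"))
  )
}
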