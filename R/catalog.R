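#' The 96 trinucleotide substitution channels
#'
#' Channels follow the conventional ordering: six pyrimidine substitutions
#' (C>A, C>G, C>T, T>A, T>C, T>G), each expanded over the 16 flanking-base
#' combinations sorted 5' then 3'. Labels use the `A[C>A]A` convention.
#'
#' @return Data frame with columns `sub`, `five`, `three`, `label` (96 rows).
#' @export
catalog_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  b <- c("A", "C", "G", "T")
  d <- expand.grid(three = b, five = b, sub = subs,
                   stringsAsFactors = FALSE)[, c("sub", "five", "three")]
  d <- d[order(match(d$sub, subs), match(d$five, b), match(d$three, b)), ]
  d$label <- paste0(d$five, "[", d$sub, "]", d$three)
  rownames(d) <- NULL
  d
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

#' Build a 96-channel mutation catalog from SNVs
#'
#' Substitutions with a purine reference (A or G) are reverse-complemented
#' to the pyrimidine strand before binning, so `G>T` in context `TGT`
#' increments the same channel as `C>A` in `ACA`. Records with a non-ACGT
#' base in ref, alt or context are skipped; the number skipped is attached
#' as attribute `"skipped"` with a warning.
#'
#' @param snvs Data frame with columns `ref`, `alt` (single bases) and
#'   `context` (3-mer centered on the variant).
#' @return Named integer vector of length 96 summing to the number of
#'   usable SNVs.
#' @export
build_96_catalog <- function(snvs) {
  ch <- catalog_channels()
  out <- setNames(integer(96), ch$label)
  if (is.null(snvs) || nrow(snvs) == 0) return(out)
  ref <- toupper(snvs$ref); alt <- toupper(snvs$alt)
  ctx <- toupper(snvs$context)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt & grepl("^[ACGT]{3}$", ctx) & substr(ctx, 2, 2) == ref
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    warning(sprintf("%d SNV record(s) skipped (non-ACGT or inconsistent context)",
                    n_skip))
  }
  ref <- ref[ok]; alt <- alt[ok]; ctx <- ctx[ok]
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    ctx[pur] <- .revcomp(ctx[pur])
    ref[pur] <- chartr("AG", "TC", ref[pur])
    alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
  }
  lab <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  tab <- table(factor(lab, levels = ch$label))
  out[] <- as.integer(tab)
  attr(out, "skipped") <- n_skip
  out
}

#' Synthetic COSMIC-like signature reference
#'
#' A six-column 96-channel signature matrix with the broad structural
#' features of the COSMIC v2 exome signatures most used for HRD refitting
#' (clock-like NpCpG C>T, APOBEC TpC C>T and C>G, a flat HRD-associated
#' "Signature 3", broad T>C and C>A processes). It is a synthetic stand-in
#' constructed from those qualitative shapes, not the published COSMIC
#' matrix; simulation and refitting in this package both use it, so all
#' signature analyses are internally consistent.
#'
#' @return 96 x 6 numeric matrix; rows named by channel label, columns
#'   `Signature 1`, `Signature 2`, `Signature 3`, `Signature 5`,
#'   `Signature 8`, `Signature 13`. Each column sums to 1.
#' @export
synthetic_signatures <- function() {
  ch <- catalog_channels()
  norm <- function(v) v / sum(v)
  M <- cbind(
    `Signature 1`  = norm(ifelse(ch$sub == "C>T" & ch$three == "G", 10, 0.2)),
    `Signature 2`  = norm(ifelse(ch$sub == "C>T" & ch$five == "T", 8, 0.15)),
    `Signature 3`  = norm(rep(1, 96)),
    `Signature 5`  = norm(ifelse(ch$sub == "T>C", 4, 0.6)),
    `Signature 8`  = norm(ifelse(ch$sub == "C>A", 5, 0.4)),
    `Signature 13` = norm(ifelse(ch$sub == "C>G" & ch$five == "T", 8, 0.15))
  )
  rownames(M) <- ch$label
  M
}

validate_signature_matrix <- function(M, tol = 1e-8) {
  stopifnot(is.matrix(M), nrow(M) == 96, !is.null(colnames(M)))
  if (any(M < 0)) stop("signature matrix entries must be non-negative")
  s <- colSums(M)
  if (any(abs(s - 1) > tol)) {
    stop("each signature column must sum to 1 (tolerance ", tol, ")")
  }
  invisible(M)
}
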