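validate_segments <- function(segments) {
  stopifnot(all(c("chrom", "start", "end", "total_cn", "minor_cn") %in%
                  names(segments)))
  if (any(segments$start > segments$end)) stop("segment start > end")
  if (any(segments$minor_cn > segments$total_cn - segments$minor_cn)) {
    stop("minor_cn must not exceed total_cn - minor_cn")
  }
  sp <- split(segments, segments$chrom)
  for (s in sp) {
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("overlapping segments on ", s$chrom[1])
    }
  }
  invisible(segments)
}

# merge adjacent segments with identical allele-specific state
.merge_identical <- function(s) {
  s <- s[order(s$start), , drop = FALSE]
  if (nrow(s) <= 1) return(s)
  keep <- c(TRUE, s$total_cn[-1] != s$total_cn[-nrow(s)] |
              s$minor_cn[-1] != s$minor_cn[-nrow(s)] |
              s$start[-1] != s$end[-nrow(s)] + 1)
  grp <- cumsum(keep)
  out <- s[keep, , drop = FALSE]
  out$end <- tapply(s$end, grp, max)
  rownames(out) <- NULL
  out
}

# eliminate segments shorter than min_len by absorbing them into a
# neighbour, then re-merge identical states; repeat to a fixed point
.smooth_chrom <- function(s, min_len) {
  s <- .merge_identical(s)
  repeat {
    len <- s$end - s$start + 1
    small <- which(len < min_len)
    if (length(small) == 0 || nrow(s) == 1) return(s)
    i <- small[which.min(len[small])]
    if (i == 1) {
      s$start[2] <- s$start[1]
      s <- s[-1, , drop = FALSE]
    } else {
      s$end[i - 1] <- s$end[i]
      s <- s[-i, , drop = FALSE]
    }
    s <- .merge_identical(s)
  }
}

#' HRD-LOH score
#'
#' Number of loss-of-heterozygosity regions (maximal runs of segments with
#' minor copy number 0) longer than `min_mb` megabases but shorter than the
#' whole chromosome.
#'
#' @param segments Allele-specific segment table for one tumor.
#' @param layout Genome layout (chromosome lengths).
#' @param min_mb Minimum region length in Mb (default 15).
#' @return Integer count.
#' @export
score_hrd_loh <- function(segments, layout = default_genome_layout(),
                          min_mb = 15) {
  validate_segments(segments)
  total <- 0L
  for (chrom in unique(segments$chrom)) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), ]
    L <- layout$length[layout$chrom == chrom]
    loh <- s$minor_cn == 0
    # maximal runs of adjacent LOH segments
    run <- rle(loh)
    ends <- cumsum(run$lengths); starts <- ends - run$lengths + 1
    for (k in which(run$values)) {
      a <- s$start[starts[k]]; b <- s$end[ends[k]]
      len <- b - a + 1
      if (len > min_mb * 1e6 && (length(L) == 0 || len < L)) {
        total <- total + 1L
      }
    }
  }
  total
}

#' Large-scale transition (LST) score
#'
#' After smoothing away segments shorter than `smooth_mb` megabases, the
#' number of breakpoints between adjacent segments that are each at least
#' `min_seg_mb` megabases long and differ in allele-specific copy number.
#'
#' @param segments Segment table for one tumor.
#' @param layout Genome layout.
#' @param min_seg_mb Minimum flanking segment length (default 10 Mb).
#' @param smooth_mb Smoothing scale (default 3 Mb).
#' @return Integer count.
#' @export
score_lst <- function(segments, layout = default_genome_layout(),
                      min_seg_mb = 10, smooth_mb = 3) {
  validate_segments(segments)
  total <- 0L
  for (chrom in unique(segments$chrom)) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    s <- .smooth_chrom(s, smooth_mb * 1e6)
    if (nrow(s) < 2) next
    len <- s$end - s$start + 1
    for (i in seq_len(nrow(s) - 1)) {
      adjacent <- s$start[i + 1] == s$end[i] + 1
      differ <- s$total_cn[i] != s$total_cn[i + 1] ||
        s$minor_cn[i] != s$minor_cn[i + 1]
      if (adjacent && differ && len[i] >= min_seg_mb * 1e6 &&
          len[i + 1] >= min_seg_mb * 1e6) {
        total <- total + 1L
      }
    }
  }
  total
}

#' Telomeric allelic imbalance (TAI) score
#'
#' Number of allelic-imbalance regions (maximal runs of segments with
#' unequal allele copy numbers, `2 * minor_cn != total_cn`) that extend to
#' a telomere and do not cross the centromere.
#'
#' @param segments Segment table for one tumor.
#' @param layout Genome layout with centromere positions.
#' @return Integer count.
#' @export
score_tai <- function(segments, layout = default_genome_layout()) {
  validate_segments(segments)
  total <- 0L
  for (chrom in unique(segments$chrom)) {
    li <- match(chrom, layout$chrom)
    if (is.na(li)) next
    L <- layout$length[li]; cen <- layout$centromere[li]
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    s <- .merge_identical(s)
    ai <- 2 * s$minor_cn != s$total_cn
    run <- rle(ai)
    ends <- cumsum(run$lengths); starts <- ends - run$lengths + 1
    for (k in which(run$values)) {
      a <- s$start[starts[k]]; b <- s$end[ends[k]]
      telomeric <- a <= 1 || b >= L
      crosses <- a <= cen && b >= cen
      if (telomeric && !crosses) total <- total + 1L
    }
  }
  total
}

#' Scar-based HRD call
#'
#' TRUE exactly when the genomic scar sum HRD-LOH + LST + TAI reaches the
#' threshold (42 by default).
#'
#' @param hrd_loh,lst,tai Component scores.
#' @param threshold Inclusive threshold (default 42).
#' @return Logical.
#' @export
call_scar_hrd <- function(hrd_loh, lst, tai, threshold = 42) {
  stopifnot(all(c(hrd_loh, lst, tai) >= 0))
  (hrd_loh + lst + tai) >= threshold
}

#' Consensus HRD call
#'
#' Logical AND of the Signature-3 call and the scar call. A no-call on
#' either side (NA) propagates to a no-call, never to a negative.
#'
#' @param sig3_present,scar_positive Logical (NA = no-call).
#' @return Logical (NA = no-call).
#' @export
consensus_hrd <- function(sig3_present, scar_positive) {
  ifelse(is.na(sig3_present) | is.na(scar_positive), NA,
         sig3_present & scar_positive)
}

#' Full HRD call for one tumor
#'
#' Combines Signature-3 attribution on the 96-channel catalog with the
#' three genomic scar scores.
#'
#' @param catalog Length-96 catalog.
#' @param segments Segment table for the tumor.
#' @param signature_matrix Signature reference.
#' @param calibration Signature-3 calibration (see [calibrate_sig3()]).
#' @param layout Genome layout.
#' @param scar_threshold Scar sum threshold (default 42).
#' @return One-row data frame: `sig3_present`, `sig3_score`,
#'   `sig3_exposure`, `hrd_loh`, `lst`, `tai`, `scar_sum`, `scar_positive`,
#'   `consensus_positive`.
#' @export
hrd_call <- function(catalog, segments,
                     signature_matrix = synthetic_signatures(), calibration,
                     layout = default_genome_layout(), scar_threshold = 42) {
  s3 <- call_sig3(catalog, signature_matrix, calibration)
  h <- score_hrd_loh(segments, layout)
  l <- score_lst(segments, layout)
  t <- score_tai(segments, layout)
  scar <- call_scar_hrd(h, l, t, scar_threshold)
  data.frame(
    sig3_present = s3$sig3_present, sig3_score = s3$sig3_score,
    sig3_exposure = s3$sig3_exposure, hrd_loh = h, lst = l, tai = t,
    scar_sum = h + l + t, scar_positive = scar,
    consensus_positive = consensus_hrd(s3$sig3_present, scar),
    stringsAsFactors = FALSE
  )
}
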