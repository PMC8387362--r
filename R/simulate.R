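predictor_columns <- c("sift", "polyphen2", "mutationtaster", "fathmm",
                       "provean", "metasvm", "metalr", "cadd")

variant_columns <- c(
  "patient_id", "chrom", "pos", "ref", "alt", "origin", "gene", "consequence",
  "g_ref", "g_alt", "t_ref", "t_alt", "mq", "alt_fwd", "alt_rev", "pop_af",
  "clinvar", "acmg", predictor_columns, "context"
)

empty_variant_table <- function() {
  d <- data.frame(
    patient_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), origin = character(),
    gene = character(), consequence = character(),
    g_ref = integer(), g_alt = integer(), t_ref = integer(), t_alt = integer(),
    mq = numeric(), alt_fwd = integer(), alt_rev = integer(),
    pop_af = numeric(), clinvar = character(), acmg = character(),
    stringsAsFactors = FALSE
  )
  for (p in predictor_columns) d[[p]] <- logical()
  d$context <- character()
  d
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Simulation configuration
#'
#' Holds the generating conditions for a synthetic tumor/normal cohort.
#' Defaults follow the study design being emulated: exome-scale mean
#' coverage of about 141x in both tissues, FFPE tumor material (modest
#' beta-binomial overdispersion, strand-biased C>T artifacts), and a
#' two-hit causal scenario (rare germline variant + CN-LOH second hit +
#' Signature-3-positive, scar-positive tumor) spiked into a configurable
#' fraction of patients.
#'
#' @param n_patients Number of tumor/normal pairs.
#' @param mean_depth_normal,mean_depth_tumor Mean sequencing depths (reads).
#' @param overdispersion Beta-binomial rho in `[0, 1)`; 0 is binomial.
#' @param tumor_purity Tumor cell fraction in `(0, 1]`.
#' @param ffpe_artifact_rate FFPE artifacts per Mb of target territory.
#' @param sig3_exposure Signature-3 exposure given to spiked tumors, in
#'   `[0, 1]`.
#' @param n_somatic_snvs True somatic SNVs per tumor.
#' @param causal_fraction Fraction of patients given a spiked causal
#'   scenario.
#' @param seed Master integer seed; per-patient seeds are derived with
#'   [derive_seed()].
#' @param n_background_germline Mean number of background germline variants
#'   per patient (Poisson).
#' @param spike_scar_targets Length-3 integer vector of (HRD-LOH, LST, TAI)
#'   targets for spiked tumors; must sum to at least the scar threshold.
#' @param exome_mb Target territory size in Mb used to convert the artifact
#'   rate to a count.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_patients = 20L,
                              mean_depth_normal = 141,
                              mean_depth_tumor = 141,
                              overdispersion = 0.01,
                              tumor_purity = 0.6,
                              ffpe_artifact_rate = 1,
                              sig3_exposure = 0.5,
                              n_somatic_snvs = 100L,
                              causal_fraction = 0.1,
                              seed = 1L,
                              n_background_germline = 8,
                              spike_scar_targets = c(20L, 15L, 8L),
                              exome_mb = 30) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    mean_depth_normal = mean_depth_normal,
    mean_depth_tumor = mean_depth_tumor,
    overdispersion = overdispersion,
    tumor_purity = tumor_purity,
    ffpe_artifact_rate = ffpe_artifact_rate,
    sig3_exposure = sig3_exposure,
    n_somatic_snvs = as.integer(n_somatic_snvs),
    causal_fraction = causal_fraction,
    seed = as.integer(seed),
    n_background_germline = n_background_germline,
    spike_scar_targets = as.integer(spike_scar_targets),
    exome_mb = exome_mb
  )
  with(cfg, {
    stopifnot(
      n_patients > 0, mean_depth_normal > 0, mean_depth_tumor > 0,
      overdispersion >= 0, overdispersion < 1,
      tumor_purity > 0, tumor_purity <= 1,
      ffpe_artifact_rate >= 0,
      sig3_exposure >= 0, sig3_exposure <= 1,
      n_somatic_snvs >= 0,
      causal_fraction >= 0, causal_fraction <= 1,
      n_background_germline >= 0,
      length(spike_scar_targets) == 3, all(spike_scar_targets >= 0),
      exome_mb > 0
    )
  })
  structure(cfg, class = "simulation_config")
}

# beta-binomial with mean prob and intra-class correlation rho;
# variance n p (1-p) (1 + (n-1) rho); rho = 0 degenerates to binomial
rbetabinom <- function(n, size, prob, rho) {
  size <- rep_len(size, n); prob <- rep_len(prob, n)
  out <- integer(n)
  degen <- prob <= 0 | prob >= 1 | rho <= 0
  out[degen] <- stats::rbinom(sum(degen), size[degen], prob[degen])
  if (any(!degen)) {
    a <- prob[!degen] * (1 - rho) / rho
    b <- (1 - prob[!degen]) * (1 - rho) / rho
    out[!degen] <- stats::rbinom(sum(!degen), size[!degen],
                                 stats::rbeta(sum(!degen), a, b))
  }
  out
}

#' Simulate REF/ALT read counts at a locus
#'
#' Draws the ALT count from a beta-binomial with mean `allele_fraction` and
#' overdispersion `rho`; `rho = 0` degenerates to the plain binomial. The
#' pair always sums to `depth`.
#'
#' @param allele_fraction Expected variant allele fraction in `[0, 1]`.
#' @param depth Total read depth (> 0); may be a vector.
#' @param overdispersion Beta-binomial rho in `[0, 1)`.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Data frame with integer columns `ref` and `alt`.
#' @export
simulate_read_counts <- function(allele_fraction, depth, overdispersion = 0,
                                 seed = NULL) {
  if (any(allele_fraction < 0 | allele_fraction > 1)) {
    stop("allele_fraction must lie in [0, 1]")
  }
  if (any(depth <= 0)) stop("depth must be positive")
  if (overdispersion < 0 || overdispersion >= 1) {
    stop("overdispersion must lie in [0, 1)")
  }
  n <- max(length(allele_fraction), length(depth))
  rng <- local_rng(seed); on.exit(restore_rng(rng))
  alt <- rbetabinom(n, rep_len(depth, n), rep_len(allele_fraction, n),
                    overdispersion)
  data.frame(ref = as.integer(rep_len(depth, n) - alt), alt = as.integer(alt))
}

#' Expected tumor variant allele fraction at a germline heterozygous site
#'
#' For a tumor of purity `p` whose cells carry `variant_cn` mutant copies
#' out of `total_cn` at the locus, admixed with diploid normal cells at
#' germline allele fraction `g`:
#' `VAF = (p * variant_cn + (1 - p) * 2 * g) / (p * total_cn + (1 - p) * 2)`.
#'
#' @param germline_af Germline allele fraction (0.5 for a het site).
#' @param purity Tumor purity in `[0, 1]`.
#' @param total_cn,variant_cn Tumor total and mutant copy number.
#' @return Expected tumor VAF.
#' @export
expected_tumor_vaf <- function(germline_af, purity, total_cn, variant_cn) {
  stopifnot(total_cn >= 0, variant_cn >= 0)
  if (any(variant_cn > total_cn)) stop("variant_cn must not exceed total_cn")
  den <- purity * total_cn + (1 - purity) * 2
  num <- purity * variant_cn + (1 - purity) * 2 * germline_af
  ifelse(den == 0, NA_real_, num / den)
}

#' Simulate tumor read counts at a germline variant locus
#'
#' Tumor counts are drawn as in [simulate_read_counts()] around the
#' purity- and copy-number-adjusted expected VAF (see
#' [expected_tumor_vaf()]).
#'
#' @inheritParams expected_tumor_vaf
#' @inheritParams simulate_read_counts
#' @export
simulate_tumor_counts_at_locus <- function(germline_af = 0.5, purity,
                                           total_cn, variant_cn, depth,
                                           overdispersion = 0, seed = NULL) {
  if (purity < 0 || purity > 1) stop("purity must lie in [0, 1]")
  vaf <- expected_tumor_vaf(germline_af, purity, total_cn, variant_cn)
  if (is.na(vaf)) {
    return(data.frame(ref = 0L, alt = 0L))
  }
  simulate_read_counts(vaf, depth, overdispersion, seed)
}

#' Simulate a 96-channel mutation catalog
#'
#' Draws `catalog ~ Multinomial(n_mutations, signature_matrix %*% exposures)`.
#'
#' @param exposures Per-signature fractions summing to 1 (named, or in
#'   column order of the matrix).
#' @param n_mutations Number of SNVs.
#' @param signature_matrix 96 x K signature matrix.
#' @param seed Optional integer seed.
#' @return Named integer vector of length 96 summing to `n_mutations`.
#' @export
simulate_catalog <- function(exposures, n_mutations,
                             signature_matrix = synthetic_signatures(),
                             seed = NULL) {
  validate_signature_matrix(signature_matrix)
  if (!is.null(names(exposures))) {
    stopifnot(all(names(exposures) %in% colnames(signature_matrix)))
    e <- setNames(numeric(ncol(signature_matrix)), colnames(signature_matrix))
    e[names(exposures)] <- exposures
  } else {
    stopifnot(length(exposures) == ncol(signature_matrix))
    e <- exposures
  }
  if (any(e < 0)) stop("exposures must be non-negative")
  if (abs(sum(e) - 1) > 1e-8) stop("exposures must sum to 1 (tolerance 1e-8)")
  stopifnot(n_mutations >= 0)
  out <- setNames(integer(96), rownames(signature_matrix))
  if (n_mutations == 0) return(out)
  rng <- local_rng(seed); on.exit(restore_rng(rng))
  p <- as.vector(signature_matrix %*% e)
  out[] <- as.vector(stats::rmultinom(1, n_mutations, p))
  out
}

# ---- allele-specific segment profiles with controllable scar scores ----

# Building blocks (all verified against the scoring functions at run time):
#  * HRD-LOH chromosome: 5 Mb diploid prefix, then k interior 16 Mb (2,0)
#    LOH segments separated by 5 Mb heterozygous spacers; the final spacer
#    is (3,1) so the diploid tail cannot merge with a spacer into a >=10 Mb
#    LST neighbour. Adds k to HRD-LOH and nothing to LST/TAI.
#  * LST chromosome: b+1 alternating balanced segments (2,1)/(4,2), each
#    >= 12 Mb -> exactly b large-scale transitions, no allelic imbalance.
#  * TAI chromosome: 8 Mb (3,1) caps at one or both telomeres (below the
#    10 Mb LST size), heterozygous diploid in between.
.seg_row <- function(chrom, start, end, total, minor) {
  data.frame(chrom = chrom, start = start, end = end,
             total_cn = total, minor_cn = minor, stringsAsFactors = FALSE)
}

.loh_chrom <- function(chrom, L, k) {
  segs <- list(.seg_row(chrom, 1, 5e6, 2, 1))
  p <- 5e6
  for (j in seq_len(k)) {
    segs <- c(segs, list(.seg_row(chrom, p + 1, p + 16e6, 2, 0)))
    p <- p + 16e6
    sp_state <- if (j == k) c(3, 1) else c(2, 1)
    segs <- c(segs, list(.seg_row(chrom, p + 1, p + 5e6, sp_state[1], sp_state[2])))
    p <- p + 5e6
  }
  segs <- c(segs, list(.seg_row(chrom, p + 1, L, 2, 1)))
  do.call(rbind, segs)
}

.loh_capacity <- function(L) max(0L, floor((L - 5e6 - 2e6) / 21e6))

.lst_chrom <- function(chrom, L, b) {
  n_seg <- b + 1
  bounds <- c(seq(0, by = 12e6, length.out = n_seg), L)
  states <- rep(list(c(2, 1), c(4, 2)), length.out = n_seg)
  do.call(rbind, lapply(seq_len(n_seg), function(i) {
    .seg_row(chrom, bounds[i] + 1, bounds[i + 1], states[[i]][1], states[[i]][2])
  }))
}

.lst_capacity <- function(L) max(0L, floor(L / 12e6) - 1L)

.tai_chrom <- function(chrom, L, k) {
  stopifnot(k %in% 1:2)
  segs <- list(.seg_row(chrom, 1, 8e6, 3, 1))
  if (k == 2) {
    segs <- c(segs, list(.seg_row(chrom, 8e6 + 1, L - 8e6, 2, 1),
                         .seg_row(chrom, L - 8e6 + 1, L, 3, 1)))
  } else {
    segs <- c(segs, list(.seg_row(chrom, 8e6 + 1, L, 2, 1)))
  }
  do.call(rbind, segs)
}

#' Simulate an allele-specific segment profile with exact scar scores
#'
#' Constructs a deterministic genome-wide allele-specific copy-number
#' profile whose HRD-LOH, LST and TAI scores (see [score_hrd_loh()],
#' [score_lst()], [score_tai()]) equal the requested targets exactly; the
#' post-condition is verified at run time. Chromosomes are dedicated to one
#' score component each; targets beyond the layout's capacity raise an
#' infeasibility error.
#'
#' @param targets Length-3 non-negative integer vector `(hrd_loh, lst, tai)`.
#' @param layout Genome layout data frame.
#' @param seed Ignored (the construction is deterministic); kept so all
#'   generator operations share a signature.
#' @param reserve_chroms Chromosomes to leave untouched diploid (used when a
#'   causal locus profile is added separately).
#' @return Segment data frame (`chrom`, `start`, `end`, `total_cn`,
#'   `minor_cn`), 1-based inclusive, covering every autosome.
#' @export
simulate_segments <- function(targets, layout = default_genome_layout(),
                              seed = NULL, reserve_chroms = character()) {
  validate_genome_layout(layout)
  stopifnot(length(targets) == 3, all(targets >= 0),
            all(targets == round(targets)))
  h <- as.integer(targets[1]); l <- as.integer(targets[2])
  t <- as.integer(targets[3])
  avail <- layout[!layout$chrom %in% reserve_chroms, , drop = FALSE]
  used <- character()
  segs <- list()
  for (i in seq_len(nrow(avail))) {
    chrom <- avail$chrom[i]; L <- avail$length[i]
    if (h > 0) {
      k <- min(h, .loh_capacity(L))
      if (k > 0) {
        segs <- c(segs, list(.loh_chrom(chrom, L, k)))
        h <- h - k; used <- c(used, chrom)
        next
      }
    } else if (l > 0) {
      b <- min(l, .lst_capacity(L))
      if (b > 0) {
        segs <- c(segs, list(.lst_chrom(chrom, L, b)))
        l <- l - b; used <- c(used, chrom)
        next
      }
    } else if (t > 0) {
      k <- min(t, 2L)
      segs <- c(segs, list(.tai_chrom(chrom, L, k)))
      t <- t - k; used <- c(used, chrom)
      next
    }
  }
  if (h > 0 || l > 0 || t > 0) {
    stop(sprintf(
      "scar targets (%d, %d, %d) are not achievable on this genome layout",
      targets[1], targets[2], targets[3]))
  }
  rest <- layout[!layout$chrom %in% c(used, reserve_chroms), , drop = FALSE]
  if (nrow(rest) > 0) {
    segs <- c(segs, list(.seg_row(rest$chrom, 1, rest$length, 2, 1)))
  }
  out <- do.call(rbind, segs)
  out <- out[order(match(out$chrom, layout$chrom), out$start), ]
  rownames(out) <- NULL
  got <- c(score_hrd_loh(out, layout), score_lst(out, layout),
           score_tai(out, layout))
  if (!all(got == as.integer(targets))) {
    stop(sprintf("internal error: built profile scores (%d, %d, %d) != targets",
                 got[1], got[2], got[3]))
  }
  out
}

# Causal-locus chromosome: a 16 Mb CN-LOH (2,0) segment covering `pos`,
# insulated by 5 Mb (3,1) buffers so it adds exactly +1 HRD-LOH and no LST
# or TAI. Requires pos >= 16 Mb and pos <= L - 3 Mb.
.causal_chrom <- function(chrom, L, pos) {
  e <- min(pos + 8e6, L - 3.1e6)
  s <- e - 16e6 + 1
  if (s < 5e6 + 1 || s > pos) {
    stop("gene locus too close to a telomere for a causal CN-LOH segment")
  }
  rbind(
    .seg_row(chrom, 1, s - 5e6 - 1, 2, 1),
    .seg_row(chrom, s - 5e6, s - 1, 3, 1),
    .seg_row(chrom, s, e, 2, 0),
    .seg_row(chrom, e + 1, e + 5e6, 3, 1),
    .seg_row(chrom, e + 5e6 + 1, L, 2, 1)
  )
}

# germline read counts for an ascertained heterozygous variant: truncated
# beta-binomial restricted to the detectable allele-fraction window (the
# emulated candidates are, by definition, variants that survived germline
# detection)
.detectable_germline_counts <- function(depth, rho, window = c(0.36, 0.495)) {
  for (i in 1:200) {
    alt <- rbetabinom(1, depth, 0.5, rho)
    af <- alt / depth
    if (af >= window[1] && af <= window[2]) {
      return(c(ref = depth - alt, alt = alt))
    }
  }
  alt <- round(0.45 * depth)
  c(ref = depth - alt, alt = alt)
}

.dirichlet1 <- function(n) {
  w <- stats::rgamma(n, 1)
  w / sum(w)
}

# one somatic SNV table drawn from a catalog; contexts are taken from the
# signature-implied channel (no reference FASTA), positions uniform on the
# layout, tumor counts reflect purity and the local copy state
simulate_somatic_snvs <- function(exposures, n_mutations, signature_matrix,
                                  layout, segments, purity, mean_depth, rho,
                                  gene_table, patient_id, seed = NULL) {
  rng <- local_rng(seed); on.exit(restore_rng(rng))
  cat_ <- simulate_catalog(exposures, n_mutations, signature_matrix)
  ch <- catalog_channels()
  idx <- rep(seq_len(96), cat_)
  n <- length(idx)
  out <- empty_variant_table()
  if (n == 0) return(list(variants = out, catalog = cat_))
  ref <- substr(ch$sub[idx], 1, 1)
  alt <- substr(ch$sub[idx], 3, 3)
  ctx <- paste0(ch$five[idx], ref, ch$three[idx])
  flip <- stats::runif(n) < 0.5 # present half on the purine strand
  ctx[flip] <- .revcomp(ctx[flip])
  ref[flip] <- chartr("CT", "GA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  ci <- sample.int(nrow(layout), n, replace = TRUE, prob = layout$length)
  chrom <- layout$chrom[ci]
  pos <- 2 + floor(stats::runif(n) * (layout$length[ci] - 4))
  total <- vapply(seq_len(n), function(j) {
    s <- segments[segments$chrom == chrom[j] & segments$start <= pos[j] &
                    segments$end >= pos[j], ]
    if (nrow(s) == 1) s$total_cn else 2
  }, numeric(1))
  vaf <- purity * 1 / (purity * total + (1 - purity) * 2)
  depth <- pmax(1L, stats::rpois(n, mean_depth))
  t_alt <- rbetabinom(n, depth, vaf, rho)
  t_fwd <- stats::rbinom(n, t_alt, 0.5)
  gene <- rep(NA_character_, n)
  cons <- rep("other", n)
  for (j in seq_len(n)) {
    g <- gene_table[gene_table$chrom == chrom[j] &
                      gene_table$start <= pos[j] & gene_table$end >= pos[j], ]
    if (nrow(g) > 0) {
      gene[j] <- g$symbol[1]
      cons[j] <- sample(c("missense", "synonymous", "nonsense", "frameshift",
                          "splice"), 1, prob = c(.6, .2, .1, .05, .05))
    }
  }
  v <- data.frame(
    patient_id = patient_id, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, origin = "somatic", gene = gene, consequence = cons,
    g_ref = NA_integer_, g_alt = NA_integer_,
    t_ref = as.integer(depth - t_alt), t_alt = as.integer(t_alt),
    mq = 60, alt_fwd = as.integer(t_fwd), alt_rev = as.integer(t_alt - t_fwd),
    pop_af = NA_real_, clinvar = NA_character_, acmg = NA_character_,
    stringsAsFactors = FALSE
  )
  for (p in predictor_columns) v[[p]] <- NA
  v$context <- ctx
  list(variants = v[, variant_columns], catalog = cat_)
}

#' Generate a panel-of-normals blacklist of recurrent FFPE artifact sites
#'
#' @param layout Genome layout.
#' @param n Number of blacklisted sites.
#' @param seed Integer seed.
#' @return Data frame `chrom`, `pos`, `ref`, `alt` of recurrent C>T sites.
#' @export
generate_pon <- function(layout = default_genome_layout(), n = 300,
                         seed = 1L) {
  rng <- local_rng(seed); on.exit(restore_rng(rng))
  ci <- sample.int(nrow(layout), n, replace = TRUE, prob = layout$length)
  data.frame(
    chrom = layout$chrom[ci],
    pos = as.integer(2 + floor(stats::runif(n) * (layout$length[ci] - 4))),
    ref = "C", alt = "T", stringsAsFactors = FALSE
  )
}

#' Inject strand-biased FFPE C>T artifacts into a somatic variant table
#'
#' Adds low-VAF C>T (or G>A, depending on presented strand) calls whose
#' supporting reads are heavily skewed to one strand, emulating formalin
#' fixation damage. A fraction of artifacts is placed at recurrent
#' panel-of-normals sites. The injected keys are returned separately as
#' ground truth and never marked in the emitted table.
#'
#' @param variants Somatic variant table.
#' @param rate Artifacts per Mb of target territory.
#' @param seed Optional integer seed.
#' @param layout Genome layout.
#' @param pon Optional PoN site table (see [generate_pon()]).
#' @param pon_fraction Fraction of artifacts placed at PoN sites.
#' @param mean_depth Mean background depth at artifact sites.
#' @param exome_mb Target territory size (Mb).
#' @param patient_id Patient label for the injected rows.
#' @return List with `variants` (input plus injected rows) and `artifacts`
#'   (data frame of injected keys).
#' @export
inject_ffpe_artifacts <- function(variants, rate, seed = NULL,
                                  layout = default_genome_layout(),
                                  pon = NULL, pon_fraction = 0.3,
                                  mean_depth = 141, exome_mb = 30,
                                  patient_id = NULL) {
  stopifnot(rate >= 0)
  if (rate == 0) {
    return(list(variants = variants,
                artifacts = variants[0, c("patient_id", "chrom", "pos",
                                          "ref", "alt")]))
  }
  rng <- local_rng(seed); on.exit(restore_rng(rng))
  n <- stats::rpois(1, rate * exome_mb)
  pid <- if (!is.null(patient_id)) patient_id else
    if (nrow(variants) > 0) variants$patient_id[1] else "NA"
  if (n == 0) {
    return(list(variants = variants,
                artifacts = variants[0, c("patient_id", "chrom", "pos",
                                          "ref", "alt")]))
  }
  from_pon <- if (!is.null(pon) && nrow(pon) > 0) {
    stats::runif(n) < pon_fraction
  } else rep(FALSE, n)
  ci <- sample.int(nrow(layout), n, replace = TRUE, prob = layout$length)
  chrom <- layout$chrom[ci]
  pos <- as.integer(2 + floor(stats::runif(n) * (layout$length[ci] - 4)))
  if (any(from_pon)) {
    pi <- sample.int(nrow(pon), sum(from_pon), replace = TRUE)
    chrom[from_pon] <- pon$chrom[pi]
    pos[from_pon] <- pon$pos[pi]
  }
  # C>T on the pyrimidine strand, presented as G>A half the time
  b <- c("A", "C", "G", "T")
  ctx <- paste0(sample(b, n, TRUE), "C", sample(b, n, TRUE))
  ref <- rep("C", n); alt <- rep("T", n)
  flip <- stats::runif(n) < 0.5
  ctx[flip] <- .revcomp(ctx[flip])
  ref[flip] <- "G"; alt[flip] <- "A"
  n_alt <- 12L + stats::rpois(n, 6)
  # at least 90% of supporting reads on one strand, by construction
  minor_strand <- pmin(stats::rbinom(n, n_alt, 0.02), floor(n_alt / 10))
  swap <- stats::runif(n) < 0.5 # skew direction
  fwd <- ifelse(swap, minor_strand, n_alt - minor_strand)
  n_ref <- stats::rpois(n, mean_depth)
  art <- data.frame(
    patient_id = pid, chrom = chrom, pos = pos, ref = ref, alt = alt,
    origin = "somatic", gene = NA_character_, consequence = "other",
    g_ref = NA_integer_, g_alt = NA_integer_,
    t_ref = as.integer(n_ref), t_alt = as.integer(n_alt),
    mq = 60, alt_fwd = as.integer(fwd), alt_rev = as.integer(n_alt - fwd),
    pop_af = NA_real_, clinvar = NA_character_, acmg = NA_character_,
    stringsAsFactors = FALSE
  )
  for (p in predictor_columns) art[[p]] <- NA
  art$context <- ctx
  art <- art[, variant_columns]
  list(variants = rbind(variants, art),
       artifacts = art[, c("patient_id", "chrom", "pos", "ref", "alt")])
}

#' Spike a causal two-hit HRD scenario into a patient
#'
#' Gives the patient (i) a rare heterozygous germline missense variant in
#' `gene` with read counts in the detectable allele-fraction window, (ii) a
#' copy-neutral LOH (CN-LOH) second hit retaining the variant at the gene
#' locus, (iii) a genome-wide segment profile meeting the configured scar
#' targets, and (iv) a somatic catalog with the configured Signature-3
#' exposure.
#'
#' @param patient A list with at least `patient_id`; existing `germline`
#'   rows are kept.
#' @param gene Gene symbol (must be present in `gene_table`).
#' @param config A [simulation_config()].
#' @param gene_table,layout,signature_matrix Cohort references.
#' @param seed Optional integer seed.
#' @return List with `patient` (fields `patient_id`, `germline`, `somatic`,
#'   `segments`, `exposures`, `catalog`) and `truth` (ground-truth entry).
#' @export
spike_causal_scenario <- function(patient, gene,
                                  config = simulation_config(),
                                  gene_table = default_gene_table(),
                                  layout = default_genome_layout(),
                                  signature_matrix = synthetic_signatures(),
                                  seed = NULL) {
  g <- gene_table[gene_table$symbol == gene, ]
  if (nrow(g) != 1) stop("gene not present in gene table: ", gene)
  rng <- local_rng(seed); on.exit(restore_rng(rng))
  L <- layout$length[layout$chrom == g$chrom]
  tg <- config$spike_scar_targets
  segs <- simulate_segments(c(tg[1] - 1L, tg[2], tg[3]), layout,
                            reserve_chroms = g$chrom)
  segs <- rbind(segs[segs$chrom != g$chrom, ], .causal_chrom(g$chrom, L, g$pos))
  segs <- segs[order(match(segs$chrom, layout$chrom), segs$start), ]
  rownames(segs) <- NULL
  scores <- c(score_hrd_loh(segs, layout), score_lst(segs, layout),
              score_tai(segs, layout))
  stopifnot(all(scores == tg))
  gdepth <- max(10L, stats::rpois(1, config$mean_depth_normal))
  gc <- .detectable_germline_counts(gdepth, config$overdispersion)
  tdepth <- max(10L, stats::rpois(1, config$mean_depth_tumor))
  tc <- simulate_tumor_counts_at_locus(
    germline_af = gc["alt"] / gdepth, purity = config$tumor_purity,
    total_cn = 2, variant_cn = 2, depth = tdepth,
    overdispersion = config$overdispersion
  )
  grow <- data.frame(
    patient_id = patient$patient_id, chrom = g$chrom, pos = g$pos,
    ref = "C", alt = "T", origin = "germline", gene = gene,
    consequence = "missense",
    g_ref = as.integer(gc["ref"]), g_alt = as.integer(gc["alt"]),
    t_ref = tc$ref, t_alt = tc$alt, mq = 60,
    alt_fwd = NA_integer_, alt_rev = NA_integer_, pop_af = 1e-4,
    clinvar = "VUS", acmg = NA_character_, stringsAsFactors = FALSE
  )
  for (p in predictor_columns) grow[[p]] <- TRUE
  grow$sift <- grow$polyphen2 <- TRUE
  grow$metalr <- grow$cadd <- FALSE # 6 of 8 deleterious
  grow$context <- NA_character_
  grow <- grow[, variant_columns]
  other <- setdiff(colnames(signature_matrix), "Signature 3")
  e <- setNames(numeric(ncol(signature_matrix)), colnames(signature_matrix))
  e["Signature 3"] <- config$sig3_exposure
  e[other] <- (1 - config$sig3_exposure) * .dirichlet1(length(other))
  som <- simulate_somatic_snvs(e, config$n_somatic_snvs, signature_matrix,
                               layout, segs, config$tumor_purity,
                               config$mean_depth_tumor, config$overdispersion,
                               gene_table, patient$patient_id)
  germline <- if (!is.null(patient$germline)) rbind(patient$germline, grow)
              else grow
  truth <- list(patient_id = patient$patient_id, causal_gene = gene,
                causal_chrom = g$chrom, causal_pos = g$pos,
                loh_type = "CN-LOH", sig3_exposure = config$sig3_exposure,
                hrd_loh = tg[1], lst = tg[2], tai = tg[3],
                scar_sum = sum(tg))
  list(
    patient = list(patient_id = patient$patient_id, germline = germline,
                   somatic = som$variants, segments = segs, exposures = e,
                   catalog = som$catalog),
    truth = truth
  )
}

.background_germline <- function(patient_id, config, gene_table, segments) {
  n <- stats::rpois(1, config$n_background_germline)
  if (n == 0) return(empty_variant_table())
  gi <- sample.int(nrow(gene_table), n, replace = TRUE)
  g <- gene_table[gi, ]
  cons <- sample(c("missense", "synonymous", "nonsense", "frameshift",
                   "splice", "other"), n, TRUE,
                 prob = c(.55, .15, .05, .04, .03, .18))
  pop_af <- ifelse(stats::runif(n) < 0.7,
                   stats::runif(n, 0, 0.009), stats::runif(n, 0.011, 0.3))
  pop_af[stats::runif(n) < 0.1] <- NA # novel, unobserved in references
  clinvar <- sample(c("Unknown", "VUS", "CIOP", "Benign", "Likely benign",
                      "Pathogenic"), n, TRUE,
                    prob = c(.45, .25, .05, .1, .1, .05))
  acmg <- ifelse(clinvar == "Unknown",
                 sample(c("VUS", "Likely benign", "Likely pathogenic"), n,
                        TRUE, prob = c(.7, .2, .1)), NA_character_)
  mq <- ifelse(stats::runif(n) < 0.95, 60, 20)
  gdepth <- pmax(1L, stats::rpois(n, config$mean_depth_normal))
  galt <- rbetabinom(n, gdepth, 0.5, config$overdispersion)
  tdepth <- pmax(1L, stats::rpois(n, config$mean_depth_tumor))
  talt <- integer(n); ttot <- integer(n)
  for (j in seq_len(n)) {
    s <- segments[segments$chrom == g$chrom[j] & segments$start <= g$pos[j] &
                    segments$end >= g$pos[j], ]
    total <- if (nrow(s) == 1) s$total_cn[1] else 2
    minor <- if (nrow(s) == 1) s$minor_cn[1] else 1
    vcn <- if (stats::runif(1) < 0.5) minor else total - minor
    vaf <- expected_tumor_vaf(galt[j] / gdepth[j], config$tumor_purity,
                              total, vcn)
    talt[j] <- rbetabinom(1, tdepth[j], if (is.na(vaf)) 0 else vaf,
                          config$overdispersion)
    ttot[j] <- tdepth[j]
  }
  dele <- stats::runif(n) # per-variant deleteriousness propensity
  v <- data.frame(
    patient_id = patient_id, chrom = g$chrom, pos = g$pos,
    ref = "C", alt = "T", origin = "germline", gene = g$symbol,
    consequence = cons, g_ref = as.integer(gdepth - galt),
    g_alt = as.integer(galt), t_ref = as.integer(ttot - talt),
    t_alt = as.integer(talt), mq = mq,
    alt_fwd = NA_integer_, alt_rev = NA_integer_, pop_af = pop_af,
    clinvar = clinvar, acmg = acmg, stringsAsFactors = FALSE
  )
  for (p in predictor_columns) v[[p]] <- stats::runif(n) < dele
  v$context <- NA_character_
  v[, variant_columns]
}

#' Simulate a full tumor/normal cohort
#'
#' Generates germline and somatic variant tables, allele-specific segment
#' profiles, a panel of normals, and complete ground truth for
#' `config$n_patients` patients. `round(causal_fraction * n_patients)`
#' patients receive a spiked causal scenario
#' (see [spike_causal_scenario()]); the remainder get background germline
#' variation, Signature-3-free somatic catalogs and low scar scores.
#' Identical configs (including seed) give identical cohorts.
#'
#' @param config A [simulation_config()].
#' @param gene_table,layout,signature_matrix Cohort references (defaults
#'   are the package's built-ins).
#' @return Object of class `hrd_cohort_sim`: list with `germline`,
#'   `somatic`, `segments` (cohort-level data frames with `patient_id`),
#'   `pon`, `truth` (list: `patients` data frame, `artifacts` data frame),
#'   plus the references and config.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            gene_table = default_gene_table(),
                            layout = default_genome_layout(),
                            signature_matrix = synthetic_signatures()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_patients
  rng <- local_rng(derive_seed(config$seed, 0)); on.exit(restore_rng(rng))
  n_spike <- round(config$causal_fraction * n)
  spiked <- sort(sample.int(n, n_spike))
  pon <- generate_pon(layout, 300, seed = derive_seed(config$seed, 999999))
  bcsg <- gene_table$symbol[gene_table$category == "BCSG"]
  other_sigs <- setdiff(colnames(signature_matrix), "Signature 3")
  germline <- list(); somatic <- list(); segments <- list()
  truth_rows <- list(); artifacts <- list()
  for (i in seq_len(n)) {
    prng <- local_rng(derive_seed(config$seed, i))
    pid <- sprintf("P%03d", i)
    if (i %in% spiked) {
      sp <- spike_causal_scenario(list(patient_id = pid),
                                  gene = sample(bcsg, 1),
                                  config = config, gene_table = gene_table,
                                  layout = layout,
                                  signature_matrix = signature_matrix)
      pat <- sp$patient
      bg <- .background_germline(pid, config, gene_table, pat$segments)
      pat$germline <- rbind(bg, pat$germline)
      tr <- sp$truth
    } else {
      tg <- c(sample(0:3, 1), sample(0:3, 1), sample(0:2, 1))
      segs <- simulate_segments(tg, layout)
      e <- setNames(numeric(ncol(signature_matrix)),
                    colnames(signature_matrix))
      e[other_sigs] <- .dirichlet1(length(other_sigs))
      som <- simulate_somatic_snvs(e, config$n_somatic_snvs,
                                   signature_matrix, layout, segs,
                                   config$tumor_purity,
                                   config$mean_depth_tumor,
                                   config$overdispersion, gene_table, pid)
      pat <- list(patient_id = pid,
                  germline = .background_germline(pid, config, gene_table,
                                                  segs),
                  somatic = som$variants, segments = segs)
      tr <- list(patient_id = pid, causal_gene = NA_character_,
                 causal_chrom = NA_character_, causal_pos = NA_integer_,
                 loh_type = NA_character_, sig3_exposure = 0,
                 hrd_loh = tg[1], lst = tg[2], tai = tg[3],
                 scar_sum = sum(tg))
    }
    ff <- inject_ffpe_artifacts(pat$somatic, config$ffpe_artifact_rate,
                                layout = layout, pon = pon,
                                mean_depth = config$mean_depth_tumor,
                                exome_mb = config$exome_mb,
                                patient_id = pid)
    pat$somatic <- ff$variants
    artifacts[[i]] <- ff$artifacts
    pat$segments$patient_id <- pid
    germline[[i]] <- pat$germline
    somatic[[i]] <- pat$somatic
    segments[[i]] <- pat$segments[, c("patient_id", "chrom", "start", "end",
                                      "total_cn", "minor_cn")]
    tr$spiked <- i %in% spiked
    truth_rows[[i]] <- as.data.frame(tr, stringsAsFactors = FALSE)
    restore_rng(prng)
  }
  structure(list(
    germline = do.call(rbind, germline),
    somatic = do.call(rbind, somatic),
    segments = do.call(rbind, segments),
    pon = pon,
    truth = list(patients = do.call(rbind, truth_rows),
                 artifacts = do.call(rbind, artifacts)),
    gene_table = gene_table, layout = layout,
    signature_matrix = signature_matrix, config = config
  ), class = "hrd_cohort_sim")
}
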