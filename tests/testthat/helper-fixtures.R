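# fixture builders shared across test files

# a minimal two-chromosome layout for hand-enumerable scar fixtures:
# 150 Mb with centromere at 60 Mb, 100 Mb with centromere at 40 Mb
tiny_layout <- function() {
  data.frame(chrom = c("chrA", "chrB"), length = c(150e6, 100e6),
             centromere = c(60e6, 40e6), stringsAsFactors = FALSE)
}

seg <- function(chrom, start, end, total, minor) {
  data.frame(chrom = chrom, start = start, end = end,
             total_cn = total, minor_cn = minor, stringsAsFactors = FALSE)
}

# one germline variant observation with overridable fields
make_variant <- function(...) {
  v <- data.frame(
    patient_id = "P001", chrom = "chr1", pos = 1000000L, ref = "C",
    alt = "T", origin = "germline", gene = "GENE1",
    consequence = "missense", g_ref = 60L, g_alt = 50L, t_ref = 40L,
    t_alt = 80L, mq = 60, alt_fwd = NA_integer_, alt_rev = NA_integer_,
    pop_af = 0.001, clinvar = "VUS", acmg = NA_character_,
    stringsAsFactors = FALSE
  )
  for (p in hrdtwohit:::predictor_columns) v[[p]] <- TRUE
  v$context <- NA_character_
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  v[, hrdtwohit:::variant_columns]
}

make_somatic <- function(...) {
  defaults <- list(origin = "somatic", g_ref = NA_integer_,
                   g_alt = NA_integer_, t_ref = 50L, t_alt = 30L,
                   alt_fwd = 15L, alt_rev = 15L, context = "ACA")
  do.call(make_variant, utils::modifyList(defaults, list(...)))
}

# published read-count worked examples that reproduce under the
# uncorrected Pearson test: gene, germline REF/ALT, tumor REF/ALT,
# printed p-value
worked_examples <- function() {
  data.frame(
    gene = c("APC", "ATM", "CHEK2", "CHEK2", "POLQ", "REV1", "LIG4",
             "XIRP2"),
    g_ref = c(80, 191, 114, 192, 26, 88, 148, 69),
    g_alt = c(64, 142, 128, 180, 28, 80, 83, 56),
    t_ref = c(134, 8, 36, 23, 7, 60, 29, 18),
    t_alt = c(177, 24, 67, 49, 21, 93, 40, 33),
    p_printed = c(0.013197, 0.000446, 0.037132, 0.002237, 0.042667,
                  0.01811, 0.001089, 0.016566),
    stringsAsFactors = FALSE
  )
}

# all 2x2 tables with both row margins in 1..max_margin (zero column
# margins excluded), as vectors of the four cells
all_small_tables <- function(max_margin = 50) {
  ab <- do.call(rbind, lapply(1:max_margin, function(r) cbind(a = 0:r,
                                                              b = r:0)))
  idx <- expand.grid(i = seq_len(nrow(ab)), j = seq_len(nrow(ab)))
  tab <- cbind(ab[idx$i, , drop = FALSE],
               matrix(ab[idx$j, , drop = FALSE], ncol = 2,
                      dimnames = list(NULL, c("c", "d"))))
  tab <- as.data.frame(tab)
  tab[tab$a + tab$c > 0 & tab$b + tab$d > 0, ]
}

# observed-vs-expected form of the Pearson statistic (independent of the
# determinant form used by the implementation)
pearson_oe <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  e11 <- (a + b) * (a + c_) / n
  e12 <- (a + b) * (b + d) / n
  e21 <- (c_ + d) * (a + c_) / n
  e22 <- (c_ + d) * (b + d) / n
  (a - e11)^2 / e11 + (b - e12)^2 / e12 +
    (c_ - e21)^2 / e21 + (d - e22)^2 / e22
}
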