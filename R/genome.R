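#' Default genome layout (hg19 autosomes)
#'
#' Scar scores need chromosome geometry (lengths and centromere positions)
#' but not sequence. The default layout carries the 22 hg19 autosomes with
#' approximate centromere midpoints; a custom layout may be supplied as a
#' data frame with the same columns.
#'
#' @return A data frame with columns `chrom`, `length`, `centromere`
#'   (1-based bp).
#' @export
default_genome_layout <- function() {
  data.frame(
    chrom = paste0("chr", 1:22),
    length = c(
      249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
      159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
      115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
      59128983, 63025520, 48129895, 51304566
    ),
    centromere = c(
      125000000, 93300000, 91000000, 50400000, 48400000, 61000000,
      59900000, 45600000, 49000000, 40200000, 53700000, 35800000,
      17900000, 17600000, 19000000, 36600000, 24000000, 17200000,
      26500000, 27500000, 13200000, 14700000
    ),
    stringsAsFactors = FALSE
  )
}

validate_genome_layout <- function(layout) {
  stopifnot(
    is.data.frame(layout),
    all(c("chrom", "length", "centromere") %in% names(layout)),
    !anyDuplicated(layout$chrom),
    all(layout$length > 0),
    all(layout$centromere > 0 & layout$centromere < layout$length)
  )
  invisible(layout)
}

# Exemplar symbols for each category; the candidate-HR gene list used in the
# original study is unpublished, so the bulk of the table is deterministic
# placeholder symbols with the documented category sizes (20/147/103/594).
.bcsg_symbols <- c(
  "BRCA1", "BRCA2", "PALB2", "CHEK2", "ATM", "RAD51C", "RAD51D", "BARD1",
  "TP53", "PTEN", "CDH1", "STK11", "NF1", "NBN", "BRIP1", "MRE11", "RAD50",
  "MLH1", "MSH2", "MSH6"
)
.csg_symbols <- c("APC", "FLCN", "FANCA", "GJB2", "VHL", "RB1", "MEN1", "RET",
                  "SDHB", "SMAD4")
.repair_symbols <- c("REV1", "LIG4", "POLQ", "ERCC2", "XRCC2", "XPA", "POLE",
                     "POLD1", "FANCM", "RAD54L")
.chrg_symbols <- c("BRDT", "CABIN1", "EIF2D", "FCHO1", "NCOR1", "DNAH6",
                   "TANGO2", "XIRP2")

#' Default gene table
#'
#' Builds the four gene categories used for germline candidate selection:
#' 20 clinical breast-cancer susceptibility genes (BCSG), 147 other cancer
#' susceptibility genes (CSG), 103 DNA-repair genes and 594 candidate
#' homologous-recombination genes (C-HRG), 864 symbols in total. Real,
#' well-known symbols head each category; the remainder are deterministic
#' synthetic placeholders (the full candidate-HR list is not public). Each
#' gene is given a point locus and a +/- 50 kb interval on the layout,
#' placed mid-arm so that simulated copy-number events around a gene never
#' touch a telomere.
#'
#' @param layout Genome layout data frame (see [default_genome_layout()]).
#' @return Data frame with columns `symbol`, `category`, `chrom`, `pos`,
#'   `start`, `end`.
#' @export
default_gene_table <- function(layout = default_genome_layout()) {
  validate_genome_layout(layout)
  fill <- function(prefix, n, have) {
    c(have, sprintf("%s%03d", prefix, seq_len(n - length(have))))
  }
  sym <- c(.bcsg_symbols,
           fill("CSG", 147, .csg_symbols),
           fill("DRG", 103, .repair_symbols),
           fill("HRG", 594, .chrg_symbols))
  cat_ <- rep(c("BCSG", "CSG", "DNA-repair", "C-HRG"), c(20, 147, 103, 594))
  n <- length(sym)
  # deterministic round-robin placement, 20 Mb inside each telomere
  idx <- rep(seq_len(nrow(layout)), length.out = n)
  chrom <- layout$chrom[idx]
  lo <- 2e7
  hi <- layout$length[idx] - 2e7
  slot <- ave(seq_len(n), idx, FUN = seq_along)
  per <- ave(seq_len(n), idx, FUN = length)
  pos <- round(lo + (hi - lo) * slot / (per + 1))
  # pin the worked-example genes to their true hg19 loci
  known <- c(RAD51D = "chr17", CHEK2 = "chr22", ATM = "chr11", BRCA2 = "chr13",
             APC = "chr5", FLCN = "chr17", REV1 = "chr2", LIG4 = "chr13",
             POLQ = "chr3", BRCA1 = "chr17", PALB2 = "chr16", RAD51C = "chr17")
  known_pos <- c(RAD51D = 33426811, CHEK2 = 29083731, ATM = 108093211,
                 BRCA2 = 32889611, APC = 112043195, FLCN = 17115526,
                 REV1 = 100016421, LIG4 = 108859793, POLQ = 121150641,
                 BRCA1 = 41196312, PALB2 = 23614483, RAD51C = 56769934)
  m <- match(names(known), sym)
  ok <- !is.na(m)
  chrom[m[ok]] <- known[ok]
  pos[m[ok]] <- known_pos[ok]
  data.frame(
    symbol = sym, category = cat_, chrom = chrom, pos = pos,
    start = pmax(1, pos - 5e4), end = pos + 5e4,
    stringsAsFactors = FALSE
  )
}

#' Assign the category of a gene symbol
#'
#' Categories are resolved with precedence BCSG > CSG > DNA-repair > C-HRG
#' when a symbol appears on several lists; symbols on no list map to
#' `"other"`.
#'
#' @param symbol Character vector of gene symbols.
#' @param gene_table Data frame with `symbol` and `category` columns.
#' @return Character vector of categories.
#' @export
assign_gene_category <- function(symbol, gene_table = default_gene_table()) {
  prec <- c("BCSG", "CSG", "DNA-repair", "C-HRG")
  out <- rep("other", length(symbol))
  for (cat_ in rev(prec)) { # apply lowest precedence first, higher overwrite
    hit <- symbol %in% gene_table$symbol[gene_table$category == cat_]
    out[hit] <- cat_
  }
  out
}
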