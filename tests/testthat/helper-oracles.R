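# Independent oracles and in-code fixtures used across the suite.

# Brute-force oracle: polymorphic columns as the union over all haplotype
# pairs of pairwise-difference columns.
oracle_polymorphic <- function(haplotypes) {
  m <- itsloci:::hap_state_matrix(haplotypes)
  cols <- as.integer(colnames(m))
  hit <- logical(length(cols))
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m))
    hit <- hit | (m[i, ] != m[j, ])
  cols[hit]
}

# Textbook Pearson goodness-of-fit chi-square.
oracle_gof_chisq <- function(obs, p = rep(1 / length(obs), length(obs))) {
  e <- sum(obs) * p
  sum((obs - e)^2 / e)
}

# Textbook 2x2 contingency chi-square, N(ad-bc)^2 / (r1 r2 c1 c2).
oracle_2x2_chisq <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Direct-definition oracle for parsimony-informative columns.
oracle_informative <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  which(vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    sum(tab >= 2) >= 2
  }, logical(1)))
}

# The published offspring phenotype counts (69 homokaryons and 25
# heterokaryons over the seven ITS classes, canonical label order
# [A] [B] [C] [A+B] [A+C] [B+C] [A+B+C]).
HOM_COUNTS <- c("[A]" = 19, "[B]" = 20, "[C]" = 0, "[A+B]" = 0,
                "[A+C]" = 19, "[B+C]" = 11, "[A+B+C]" = 0)
HET_COUNTS <- c("[A]" = 2, "[B]" = 3, "[C]" = 0, "[A+B]" = 1,
                "[A+C]" = 2, "[B+C]" = 6, "[A+B+C]" = 11)

# The 22-sequence, 9-column inter-specimen matrix (4 type-A, 4 type-B and
# 14 type-C sequences), rebuilt from the group-defining states.
specimen_matrix <- function() {
  g <- itsloci:::GROUP_STATES
  m <- rbind(g[rep("A", 4), ], g[rep("B", 4), ], g[rep("C", 14), ])
  rownames(m) <- paste0("sp", seq_len(nrow(m)))
  m
}

# Published fragment tables: genotype -> fragment multiset (Table of CAPS
# markers) and ITS class -> per-enzyme rendered band strings.
MARKER_FRAGMENTS <- list(
  PRS016 = list("1" = c(481, 219), "2" = c(271, 219, 210),
                "1/2" = c(481, 271, 219, 210)),
  PRS049 = list("1" = c(479), "2" = c(292, 187),
                "1/2" = c(479, 292, 187)),
  PRS088 = list("1" = c(757), "2" = c(449, 308),
                "1/2" = c(757, 449, 308))
)

ITS_BAND_STRINGS <- data.frame(
  label = c("[A]", "[B]", "[C]", "[A+B]", "[A+C]", "[B+C]", "[A+B+C]"),
  MboII = c("396 (+377)", "772", "395+264 (+112)", "772+396 (+377)",
            "396+264 (+395+377+112)", "772+395+264 (+112)",
            "772+396+264 (+395+377+112)"),
  FokI = c("773", "563 (+209)", "562 (+209)", "773+563 (+209)",
           "773+562 (+209)", "563 (562+209)", "773+563 (562+209)"),
  stringsAsFactors = FALSE)

# Build an SSI genotype table realising given phenotype-class counts with
# marker calls that make every isolate's karyotype explicit.
ssi_table_from_counts <- function(hom_counts, het_counts) {
  rows <- list()
  add <- function(label, n, kary) {
    if (n == 0) return()
    for (k in seq_len(n)) {
      rows[[length(rows) + 1]] <<- data.frame(
        id = sprintf("S%03d", length(rows) + 1),
        PRS016 = if (kary == "het") "1/2" else sample(c("1", "2"), 1),
        PRS049 = "1", PRS088 = "2", phenotype = label,
        stringsAsFactors = FALSE)
    }
  }
  for (lb in names(hom_counts)) add(lb, hom_counts[[lb]], "hom")
  for (lb in names(het_counts)) add(lb, het_counts[[lb]], "het")
  do.call(rbind, rows)
}
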