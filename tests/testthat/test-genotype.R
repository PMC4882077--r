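# Karyotype classification, two-locus genotype inference, segregation and
# linkage statistics, hypothesis evaluation.

test_that("karyotype classification is exact over all call combinations", {
  expect_identical(classify_karyotype(c("1/2", "1", "1")), "heterokaryon")
  expect_identical(classify_karyotype(c("1", "2", "2")), "homokaryon")
  expect_warning(k <- classify_karyotype(c("1", NA, "2")), "missing")
  expect_true(is.na(k))
  # exhaustively: heterokaryon iff heteroallelic at >= 1 locus; never a
  # false-positive heterokaryon from homoallelic calls
  combos <- expand.grid(a = c("1", "2", "1/2"), b = c("1", "2", "1/2"),
                        c = c("1", "2", "1/2"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    calls <- unlist(combos[i, ])
    expect_identical(classify_karyotype(calls),
                     if (any(calls == "1/2")) "heterokaryon"
                     else "homokaryon")
  }
  # "2/1" and "1/1" notation
  expect_identical(classify_karyotype(c("2/1", "1", "1")), "heterokaryon")
  expect_identical(classify_karyotype(c("1/1", "2", "2")), "homokaryon")
})

test_that("genotype inference reproduces the full two-locus interpretation table", {
  # homokaryons: haploid at both loci; three classes impossible
  expect_identical(infer_its_genotype("[A]", "homokaryon"),
                   list(list(itsI = "a", itsII = "n")))
  expect_identical(infer_its_genotype("[B]", "homokaryon"),
                   list(list(itsI = "b", itsII = "n")))
  expect_identical(infer_its_genotype("[A+C]", "homokaryon"),
                   list(list(itsI = "a", itsII = "c")))
  expect_identical(infer_its_genotype("[B+C]", "homokaryon"),
                   list(list(itsI = "b", itsII = "c")))
  for (impossible in c("[C]", "[A+B]", "[A+B+C]"))
    expect_length(infer_its_genotype(impossible, "homokaryon"), 0)
  # heterokaryons: diploid, with the c/n vs c/c ambiguity carried
  expect_identical(infer_its_genotype("[A]", "heterokaryon"),
                   list(list(itsI = "a/a", itsII = "n/n")))
  expect_identical(infer_its_genotype("[A+B]", "heterokaryon"),
                   list(list(itsI = "a/b", itsII = "n/n")))
  g <- infer_its_genotype("[A+B+C]", "heterokaryon")
  expect_identical(g[[1]]$itsI, "a/b")
  expect_setequal(g[[1]]$itsII, c("c/n", "c/c"))
  expect_length(infer_its_genotype("[C]", "heterokaryon"), 0)
  expect_error(infer_its_genotype("[Z]", "homokaryon"), "unknown")
  # brackets optional
  expect_identical(infer_its_genotype("A+C", "homokaryon"),
                   infer_its_genotype("[A+C]", "homokaryon"))
})

test_that("allele counting over the published homokaryon counts", {
  al <- count_homokaryon_alleles(HOM_COUNTS)
  expect_identical(al, c(a = 38, b = 31, c = 30, n = 39))
  expect_error(count_homokaryon_alleles(c("[C]" = 1)), "impossible")
})

test_that("segregation tests match the textbook formula to 1e-9", {
  s1 <- segregation_test(c(38, 31))
  expect_equal(s1$statistic, oracle_gof_chisq(c(38, 31)), tolerance = 1e-9)
  expect_equal(round(s1$statistic, 3), 0.710)
  expect_identical(s1$verdict, "ratio not rejected")
  s2 <- segregation_test(c(30, 39))
  expect_equal(round(s2$statistic, 3), 1.174)
  expect_identical(s2$verdict, "ratio not rejected")
  s3 <- segregation_test(c(50, 50))
  expect_equal(s3$statistic, 0)
  expect_equal(s3$p.value, 1)
  expect_error(segregation_test(c(0, 0)), "zero")
  # random cases against the oracle
  set.seed(12)
  for (i in 1:20) {
    cnt <- rpois(2, 30) + 1
    expect_equal(segregation_test(cnt)$statistic, oracle_gof_chisq(cnt),
                 tolerance = 1e-9)
  }
})

test_that("linkage test matches the 2x2 oracle and classifies extremes", {
  lt <- linkage_test(matrix(c(19, 19, 11, 20), 2, 2, byrow = TRUE,
                            dimnames = list(c("a", "b"), c("c", "n"))))
  expect_equal(lt$statistic, oracle_2x2_chisq(19, 19, 11, 20),
               tolerance = 1e-9)
  expect_equal(round(lt$statistic, 3), 1.464)
  expect_identical(lt$verdict, "independent re-assortment not rejected")
  expect_setequal(unname(lt$splits), c(30, 39))
  expect_identical(lt$ratio, "30:39")
  # perfectly independent table
  expect_equal(linkage_test(c(20, 20, 20, 20))$statistic, 0)
  # complete linkage
  cl <- linkage_test(c(30, 0, 0, 39))
  expect_equal(cl$statistic, 69)
  expect_identical(cl$verdict, "linked")
  expect_setequal(unname(cl$splits), c(69, 0))
  # zero margin
  expect_warning(z <- linkage_test(c(5, 7, 0, 0)), "margin")
  expect_true(is.na(z$statistic))
  # random cases against the oracle
  set.seed(13)
  for (i in 1:20) {
    x <- rpois(4, 15) + 1
    expect_equal(linkage_test(x)$statistic,
                 oracle_2x2_chisq(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-9)
  }
})

test_that("homozygosity rates from the published heterokaryon column", {
  h1 <- homozygosity_rate(HET_COUNTS, "ITSI")
  expect_identical(c(h1$homozygous, h1$total), c(13, 25))
  expect_equal(h1$rate, 0.52)
  h2 <- homozygosity_rate(HET_COUNTS, "ITSII")
  expect_identical(c(h2$homozygous, h2$total), c(6, 25))
  expect_equal(h2$rate, 0.24)
  # record-based path on marker calls
  df <- data.frame(PRS088 = c("1/2", "1", "2", "2/2"),
                   phenotype = c("[A]", "[B]", "[A+B]", "[B+C]"))
  h3 <- homozygosity_rate(df, "PRS088")
  expect_equal(h3$rate, 3 / 4)
  expect_equal(homozygosity_rate(df, "ITSII")$rate, 3 / 4)
  all_het <- data.frame(PRS088 = rep("1/2", 5),
                        phenotype = rep("[A+B]", 5))
  expect_equal(homozygosity_rate(all_het, "PRS088")$rate, 0)
  expect_error(homozygosity_rate(df[0, ], "PRS088"), "no heterokaryon")
})

test_that("hypothesis evaluation rejects the trikaryon and keeps two loci", {
  ev <- evaluate_hypotheses(HOM_COUNTS, HET_COUNTS)
  expect_identical(ev$trikaryon$verdict, "rejected")
  expect_setequal(names(ev$trikaryon$witnesses), c("[A+C]", "[B+C]"))
  expect_identical(unname(ev$trikaryon$witnesses[c("[A+C]", "[B+C]")]),
                   c(19, 11))
  expect_identical(ev$two_locus$verdict, "consistent")
  expect_identical(unname(ev$two_locus$allele_counts),
                   c(38, 31, 30, 39))
  expect_equal(round(ev$two_locus$linkage$statistic, 3), 1.464)
  # counts only in the pure classes: trikaryon stands
  pure <- c("[A]" = 20, "[B]" = 22, "[C]" = 18)
  ev2 <- evaluate_hypotheses(pure)
  expect_identical(ev2$trikaryon$verdict, "consistent")
  # a single [A+B+C] homokaryon sinks the two-locus model
  ev3 <- evaluate_hypotheses(c(HOM_COUNTS[c("[A]", "[B]", "[A+C]",
                                            "[B+C]")], "[A+B+C]" = 1))
  expect_identical(ev3$two_locus$verdict, "rejected")
  expect_true("[A+B+C]" %in% names(ev3$two_locus$witnesses))
})

test_that("offspring phenotype enumeration follows the parent genotype", {
  full <- enumerate_offspring_phenotypes("a/b", "c/n")
  # seven combinations of three types are combinatorially possible ...
  expect_length(full$combinatorial, 7)
  # ... but the pure-C class is unreachable by any offspring genotype
  expect_length(full$genotypic, 6)
  expect_false("[C]" %in% full$genotypic)
  noC <- enumerate_offspring_phenotypes("a/b", "n/n")
  expect_setequal(noC$genotypic, c("[A]", "[B]", "[A+B]"))
  expect_setequal(noC$combinatorial, c("[A]", "[B]", "[A+B]"))
  mono <- enumerate_offspring_phenotypes("a/a", "n/n")
  expect_identical(mono$genotypic, "[A]")
})

test_that("the analysis wrapper reproduces the published summary statistics", {
  set.seed(1)
  tab <- ssi_table_from_counts(HOM_COUNTS, HET_COUNTS)
  a <- ssi_analysis(tab)
  expect_identical(a$n, 94L)
  expect_identical(a$n_heterokaryons, 25L)
  expect_identical(a$n_homokaryons, 69L)
  expect_equal(a$heterokaryon_rate, 25 / 94)
  expect_identical(as.numeric(a$hom_counts), unname(HOM_COUNTS))
  expect_identical(as.numeric(a$het_counts), unname(HET_COUNTS))
  expect_identical(unname(a$allele_counts), c(38, 31, 30, 39))
  expect_equal(round(a$segregation$ITSI$statistic, 3), 0.710)
  expect_equal(round(a$segregation$ITSII$statistic, 3), 1.174)
  expect_equal(round(a$linkage$`ITSI-ITSII`$statistic, 3), 1.464)
  expect_equal(a$homozygosity$ITSI$rate, 0.52)
  expect_equal(a$homozygosity$ITSII$rate, 0.24)
  expect_identical(a$hypotheses$trikaryon$verdict, "rejected")
  expect_identical(a$hypotheses$two_locus$verdict, "consistent")
  expect_output(print(a), "heterokaryons: 25")
  s <- summary(a)
  expect_identical(unname(s$verdicts["two_locus"]), "consistent")
})
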