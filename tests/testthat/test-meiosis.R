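# Tetrasporic meiosis simulator: segregation patterns, nucleus pairing,
# heterozygosity loss, misclassification and the SSI generator.

two_locus_parent <- function(f1 = 0, f2 = 0.4, r = NA, same_chr = FALSE) {
  parent_genome(data.frame(
    name = c("L1", "L2"),
    chromosome = if (same_chr) c("c1", "c1") else c("c1", "c2"),
    f = c(f1, f2), allele1 = c("1", "1"), allele2 = c("2", "2"),
    r_to_prev = c(NA, r), stringsAsFactors = FALSE))
}

test_that("meiosis segregates 2:2 with the expected division patterns", {
  # f = 0: both meiosis-II pairs homoallelic and opposite, always
  p0 <- two_locus_parent(f1 = 0, f2 = 1)
  sim <- simulate_basidia(p0, basidium_model(p_mitosis = 0), 500, seed = 3)
  a1 <- matrix(sim$alleles$L1[, 1], ncol = 4, byrow = TRUE)
  expect_true(all(a1[, 1] == a1[, 2] & a1[, 3] == a1[, 4] &
                    a1[, 1] != a1[, 3]))
  # f = 1: every meiosis-II pair carries both alleles
  a2 <- matrix(sim$alleles$L2[, 1], ncol = 4, byrow = TRUE)
  expect_true(all(a2[, 1] != a2[, 2] & a2[, 3] != a2[, 4]))
  # allele conservation: every tetrad is 2:2 at every locus
  expect_true(all(rowSums(a1 == 1) == 2))
  expect_true(all(rowSums(a2 == 1) == 2))
})

test_that("empirical SDS frequency converges to f", {
  p <- two_locus_parent(f1 = 0.4, f2 = 0.4)
  sim <- simulate_basidia(p, basidium_model(p_mitosis = 0), 1e5, seed = 5)
  a <- matrix(sim$alleles$L1[, 1], ncol = 4, byrow = TRUE)
  sds <- mean(a[, 1] != a[, 2])
  expect_lt(abs(sds - 0.4), 0.01)
})

test_that("single-meiosis and single-basidium wrappers expose labelled nuclei", {
  m <- simulate_meiosis(ca487_parent(), seed = 8)
  expect_identical(dim(m), c(4L, 5L))
  expect_setequal(m$ITSI, c("a", "b"))
  expect_identical(sum(m$ITSII == "c"), 2L)
  b <- simulate_basidium(ca487_parent(), basidium_model(p_mitosis = 1),
                         seed = 9)
  expect_length(b, 4)
  expect_true(all(vapply(b, `[[`, TRUE, "heterokaryotic")))
  expect_identical(nrow(b[[1]]$nuclei), 2L)
  b0 <- simulate_basidium(ca487_parent(), basidium_model(p_mitosis = 0),
                          seed = 9)
  expect_true(all(!vapply(b0, `[[`, TRUE, "heterokaryotic")))
})

test_that("nucleus pairing rules give the expected sister-pair fractions", {
  p <- two_locus_parent()
  # random non-twin pairing: one third of heterokaryotic spores are sisters
  sim <- simulate_basidia(p, basidium_model(p_mitosis = 1), 3e4, seed = 6)
  het <- sim$spores$two_nuclei
  expect_true(all(het))
  expect_lt(abs(mean(sim$spores$sister) - 1 / 3), 0.01)
  expect_false(any(sim$spores$twin))
  # sister_bias beta = 1: every spore receives sister nuclei
  sim1 <- simulate_basidia(p, basidium_model(p_mitosis = 1,
                                             pairing = "sister_bias",
                                             beta = 1), 2000, seed = 6)
  expect_true(all(sim1$spores$sister))
  # allow_twin: twins occur (4 of the 10 pairs)
  simt <- simulate_basidia(p, basidium_model(p_mitosis = 1,
                                             pairing = "allow_twin"),
                           2e4, seed = 6)
  expect_lt(abs(mean(simt$spores$twin) - 0.4), 0.02)
})

test_that("heterozygosity loss among heterokaryons is one third at any f", {
  p <- ca487_parent()
  # centromere-linked locus (f = 0)
  h0 <- estimate_het_loss(p, locus = "PRS088", n_basidia = 4e4, seed = 31)
  expect_lt(abs(h0$estimate - 1 / 3), 0.01)
  # distal locus (f = 0.4): same expectation
  h4 <- estimate_het_loss(p, locus = "ITSI", n_basidia = 4e4, seed = 32)
  expect_lt(abs(h4$estimate - 1 / 3), 0.01)
  # f = 0.5 via a custom parent
  p5 <- two_locus_parent(f1 = 0.5)
  h5 <- estimate_het_loss(p5, locus = "L1", n_basidia = 4e4, seed = 33)
  expect_lt(abs(h5$estimate - 1 / 3), 0.01)
  # full sister bias at a centromere-linked locus: loss is total
  h1 <- estimate_het_loss(p, basidium_model(pairing = "sister_bias",
                                            beta = 1),
                          locus = "PRS088", n_basidia = 5000, seed = 34)
  expect_equal(h1$estimate, 1)
  expect_error(estimate_het_loss(p, locus = "nope"), "unknown")
})

test_that("misclassification shrinks as markers are added", {
  p <- ca487_parent()
  expect_equal(estimate_misclassification(p, markers = character())$estimate,
               1)
  m1 <- estimate_misclassification(p, markers = "PRS088",
                                   n_basidia = 3e4, seed = 41)
  # a single centromere-linked marker misses exactly the sister pairs
  expect_lt(abs(m1$estimate - 1 / 3), 0.015)
  m2 <- estimate_misclassification(p, markers = c("PRS088", "PRS016"),
                                   n_basidia = 3e4, seed = 41)
  m3 <- estimate_misclassification(p, n_basidia = 3e4, seed = 41)
  expect_lt(m2$estimate, m1$estimate)
  expect_lt(m3$estimate, m2$estimate)
  expect_lt(m3$estimate, 1 / 3)
})

test_that("unlinked loci pass the linkage test at the nominal error rate", {
  p <- two_locus_parent(f1 = 0.4, f2 = 0.4)
  # one spore per basidium: offspring are independent gametes
  rejections <- vapply(1:60, function(s) {
    sim <- simulate_basidia(p, basidium_model(p_mitosis = 0), 2000,
                            spores = "one", seed = 1000 + s)
    tb <- table(sim$alleles$L1[, 1], sim$alleles$L2[, 1])
    linkage_test(unclass(tb))$p.value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("linked loci are detected with high power", {
  p <- two_locus_parent(f1 = 0.1, f2 = 0.1, r = 0.1, same_chr = TRUE)
  # recombinant-gamete fraction approximates r
  sim0 <- simulate_basidia(p, basidium_model(p_mitosis = 0), 2e4,
                           seed = 50)
  rec <- mean(sim0$alleles$L1[, 1] != sim0$alleles$L2[, 1])
  expect_lt(abs(rec - 0.1), 0.01)
  rejections <- vapply(1:60, function(s) {
    sim <- simulate_basidia(p, basidium_model(p_mitosis = 0), 200,
                            spores = "one", seed = 2000 + s)
    tb <- table(sim$alleles$L1[, 1], sim$alleles$L2[, 1])
    linkage_test(unclass(tb))$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("the SSI generator emits consistent tables with exact truth", {
  d <- generate_ssi_dataset(n_spores = 200, seed = 77)
  expect_identical(nrow(d$table), 200L)
  expect_identical(d$table$id, d$truth$id)
  # every called heterokaryon is a true heterokaryon (calls never invent
  # heterozygosity)
  called <- vapply(seq_len(200), function(i) suppressWarnings(
    classify_karyotype(unlist(d$table[i, c("PRS016", "PRS049",
                                           "PRS088")]))), "")
  expect_true(all(d$truth$karyotype_true[called == "heterokaryon"] ==
                    "heterokaryon"))
  # band strings invert to the phenotype labels
  expect_identical(
    mapply(phenotype_from_bands, d$table$ITS_MboII, d$table$ITS_FokI,
           USE.NAMES = FALSE),
    d$table$phenotype)
  # a parent without the ITSII-c allele never shows type-C bands
  noC <- ca487_parent()
  noC$loci$allele1[noC$loci$name == "ITSII"] <- "n"
  d2 <- generate_ssi_dataset(parent = noC, n_spores = 100, seed = 78)
  expect_false(any(grepl("C", d2$table$phenotype, fixed = TRUE)))
  # empty request
  d0 <- generate_ssi_dataset(n_spores = 0, seed = 1)
  expect_identical(nrow(d0$table), 0L)
})

test_that("simulated genotypes round-trip through phenotype and inference", {
  d <- generate_ssi_dataset(n_spores = 300, seed = 91)
  for (i in seq_len(300)) {
    kary <- d$truth$karyotype_true[i]
    g <- infer_its_genotype(d$table$phenotype[i], kary)
    i1 <- d$truth$ITSI_true[i]
    i2 <- d$truth$ITSII_true[i]
    if (kary == "homokaryon") {
      # a misclassified sister heterokaryon may be diploid; skip the few
      # truly two-nucleus spores called homokaryon at the ITS loci
      if (grepl("/", i1) || grepl("/", i2)) next
      expect_true(any(vapply(g, function(x)
        x$itsI == i1 && i2 %in% x$itsII, logical(1))), label = i)
    } else {
      i1d <- if (grepl("/", i1)) i1 else paste(i1, i1, sep = "/")
      i2d <- if (grepl("/", i2)) i2 else paste(i2, i2, sep = "/")
      expect_true(any(vapply(g, function(x)
        x$itsI == i1d && i2d %in% x$itsII, logical(1))), label = i)
    }
  }
})

test_that("identical seeds replay byte-identically", {
  d1 <- generate_ssi_dataset(n_spores = 50, seed = 123)
  d2 <- generate_ssi_dataset(n_spores = 50, seed = 123)
  expect_identical(d1$table, d2$table)
  expect_identical(d1$truth, d2$truth)
  l1 <- generate_clone_library(clone_library_model(n_clones = 40),
                               seed = 123)
  l2 <- generate_clone_library(clone_library_model(n_clones = 40),
                               seed = 123)
  expect_identical(l1$sequences, l2$sequences)
  # and the global RNG stream of the caller is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_ssi_dataset(n_spores = 10, seed = 5))
  expect_identical(runif(1), before)
})
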