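# In-silico CAPS: degenerate site scanning, digestion, gel rendering and
# the packaged marker fixtures.

test_that("a polymorphic base creates or breaks a recognition site", {
  enz <- its_enzymes()
  # the 334 A/G polymorphism: GAAGA present in the type-A context only
  expect_identical(nrow(find_sites("CGATGAAGAACGC", enz$MboII)), 1L)
  expect_identical(nrow(find_sites("CGATGAAGGACGC", enz$MboII)), 0L)
  # the 466 A/C polymorphism: bottom-strand site in the type-C context
  sC <- find_sites("ACTCTCTTCTACT", enz$MboII)
  expect_identical(nrow(sC), 1L)
  expect_identical(sC$strand, "-")
  expect_identical(nrow(find_sites("ACTCTCTTATACT", enz$MboII)), 0L)
  # the 145-146 polymorphism: FokI site in the B/C context only
  expect_identical(nrow(find_sites("TGCTGGATGTGAG", enz$FokI)), 1L)
  expect_identical(nrow(find_sites("TGCTGGGAGTGAG", enz$FokI)), 0L)
  # degenerate AvaII site GGWCC matches both GGACC and GGTCC
  expect_identical(nrow(find_sites("AAGGACCAA", enz$AvaII)), 1L)
  expect_identical(nrow(find_sites("AAGGTCCAA", enz$AvaII)), 1L)
  expect_identical(nrow(find_sites("AAGGGCCAA", enz$AvaII)), 0L)
  # empty sequence
  expect_identical(nrow(find_sites("", enz$MboII)), 0L)
})

test_that("site scanning is strand symmetric", {
  set.seed(21)
  enz <- its_enzymes()
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    L <- nchar(s)
    rc <- itsloci:::revcomp_string(s)
    for (e in enz[c("MboII", "FokI", "AvaII")]) {
      fwd <- find_sites(s, e)
      rev <- find_sites(rc, e)
      # footprints mirror: [start, end] on one strand maps to
      # [L - end + 1, L - start + 1] with the strand flipped
      key <- function(df, flip) {
        st <- df$start; en <- df$end; str <- df$strand
        if (flip) {
          tmp <- L - en + 1; en <- L - st + 1; st <- tmp
          str <- ifelse(str == "+", "-", ifelse(str == "-", "+", str))
        }
        sort(paste(st, en, str))
      }
      expect_identical(key(fwd, FALSE), key(rev, TRUE))
    }
  }
})

test_that("digestion conserves length and reproduces the ITS fragment sizes", {
  amp <- synthetic_its_amplicons()
  enz <- its_enzymes()
  expect_identical(digest_amplicon(amp["A"], enz$MboII), c(396L, 377L))
  expect_identical(digest_amplicon(amp["B"], enz$MboII), 772L)
  expect_identical(digest_amplicon(amp["C"], enz$MboII),
                   c(395L, 264L, 112L))
  expect_identical(digest_amplicon(amp["A"], enz$FokI), 773L)
  expect_identical(digest_amplicon(amp["B"], enz$FokI), c(563L, 209L))
  expect_identical(digest_amplicon(amp["C"], enz$FokI), c(562L, 209L))
  for (ty in names(amp)) for (e in c("MboII", "FokI"))
    expect_identical(sum(digest_amplicon(amp[ty], enz[[e]])),
                     nchar(amp[ty]) |> as.integer() |> unname())
})

test_that("adding a site by one substitution adds exactly one fragment", {
  amp <- synthetic_its_amplicons()
  enz <- its_enzymes()
  b <- amp[["B"]]
  # restore the GAAGA site that the type-B allele at 334 destroys
  b2 <- b
  substr(b2, 387, 387) <- "A"   # GAAGG -> GAAGA
  expect_identical(length(digest_amplicon(b2, enz$MboII)),
                   length(digest_amplicon(b, enz$MboII)) + 1L)
})

test_that("uncut amplicons return the full length and edge cuts are dropped", {
  enz <- its_enzymes()
  expect_identical(digest_amplicon("CCCAAACCCAAA", enz$MboII), 12L)
  # a site too close to the end for the type IIS offset
  s <- paste0("CCGAAGACC")   # GAAGA at 3..7, cut at 7+8=15 > length 9
  expect_warning(fr <- digest_amplicon(s, enz$MboII), "edge|dropped")
  expect_identical(fr, 9L)
})

test_that("marker fixtures reproduce the published genotype phenotypes", {
  mk <- caps_markers()
  for (locus in names(MARKER_FRAGMENTS)) {
    for (g in names(MARKER_FRAGMENTS[[locus]])) {
      got <- genotype_to_phenotype(mk[[locus]], g)
      expect_identical(unique(got$fragments),
                       sort(MARKER_FRAGMENTS[[locus]][[g]],
                            decreasing = TRUE),
                       info = paste(locus, g))
    }
    # fragment conservation for every allele
    for (al in names(mk[[locus]]$alleles)) {
      fr <- itsloci:::marker_allele_fragments(mk[[locus]], al)
      expect_identical(sum(fr), mk[[locus]]$alleles[[al]]$length,
                       info = paste(locus, al))
    }
  }
  # ITS marker conservation per enzyme
  its <- mk$ITS
  for (al in names(its$alleles)) for (e in names(its$enzyme))
    expect_identical(
      sum(itsloci:::marker_allele_fragments(its, al, e)),
      its$alleles[[al]]$length, info = paste(al, e))
})

test_that("the seven ITS classes render the published band strings", {
  for (i in seq_len(nrow(ITS_BAND_STRINGS))) {
    ph <- its_phenotype(itsloci:::its_types_of_label(
      ITS_BAND_STRINGS$label[i]))
    expect_identical(ph$label, ITS_BAND_STRINGS$label[i])
    expect_identical(format(ph$patterns$MboII), ITS_BAND_STRINGS$MboII[i])
    expect_identical(format(ph$patterns$FokI), ITS_BAND_STRINGS$FokI[i])
  }
  expect_error(its_phenotype(character()), "non-empty")
})

test_that("MboII alone confounds two class pairs; both enzymes separate all seven", {
  # a gel cannot separate co-migrating fragments, so classes are compared
  # by the cluster representatives of their visible bands
  gel_sig <- function(enzyme) {
    pats <- lapply(itsloci:::ITS_CLASS_LABELS, function(lb)
      its_phenotype(itsloci:::its_types_of_label(lb))$patterns[[enzyme]])
    universe <- sort(unique(unlist(lapply(pats, function(p)
      p$visible_bands))), decreasing = TRUE)
    cl <- itsloci:::gel_clusters(universe, gel_model())
    reps <- tapply(universe, cl, max)
    vapply(pats, function(p)
      paste(sort(unique(reps[as.character(cl[as.character(
        p$visible_bands)])])), collapse = "+"), "")
  }
  mbo <- gel_sig("MboII")
  fok <- gel_sig("FokI")
  names(mbo) <- names(fok) <- itsloci:::ITS_CLASS_LABELS
  expect_identical(unname(mbo["[C]"]), unname(mbo["[A+C]"]))
  expect_identical(unname(mbo["[B+C]"]), unname(mbo["[A+B+C]"]))
  # exhaustive pairwise distinctness of the joint (MboII, FokI) signature
  expect_identical(anyDuplicated(paste(mbo, fok, sep = " | ")), 0L)
  # and the band-string lookup inverts every class
  tab <- itsloci:::its_phenotype_table()
  for (i in seq_len(nrow(tab)))
    expect_identical(phenotype_from_bands(tab$MboII[i], tab$FokI[i]),
                     tab$label[i])
})

test_that("gel rendering merges, hides and de-duplicates as specified", {
  g <- gel_model()
  # co-migration: 563/562 merge, represented by the largest
  p <- render_pattern(c(563, 562, 209))
  expect_identical(p$visible_bands, c(563, 209))
  expect_true(p$bands$co_migrating[p$bands$length == 562])
  # below-visibility flag
  p2 <- render_pattern(c(500, 100))
  expect_identical(p2$visible_bands, 500)
  expect_true(p2$bands$below_visibility[p2$bands$length == 100])
  # duplicates collapse, singleton trivial
  expect_identical(render_pattern(c(500, 500))$visible_bands, 500)
  expect_identical(render_pattern(500)$visible_bands, 500)
  expect_identical(length(render_pattern(numeric())$fragments), 0L)
  expect_error(render_pattern(0.5), ">= 1")
})

test_that("heteroallelic patterns are the multiset union of the allele digests", {
  mk <- caps_markers()
  for (locus in c("PRS016", "PRS049", "PRS088")) {
    m <- mk[[locus]]
    u <- sort(c(itsloci:::marker_allele_fragments(m, "1"),
                itsloci:::marker_allele_fragments(m, "2")),
              decreasing = TRUE)
    expect_identical(genotype_to_phenotype(m, "1/2")$fragments,
                     as.numeric(u))
  }
})

test_that("marker config file round-trips the built-in panel", {
  path <- system.file("extdata", "caps_markers.json", package = "itsloci")
  mk2 <- read_marker_config(path)
  mk <- caps_markers()
  expect_setequal(names(mk2), names(mk))
  expect_identical(genotype_to_phenotype(mk2$PRS016, "1/2")$fragments,
                   genotype_to_phenotype(mk$PRS016, "1/2")$fragments)
  expect_identical(format(genotype_to_phenotype(mk2$ITS, "B/C")$MboII),
                   "772+395+264 (+112)")
})
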