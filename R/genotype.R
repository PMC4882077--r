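# Multilocus homokaryon/heterokaryon classification, null-allele-aware
# two-locus ITS genotype inference, segregation/linkage statistics and
# hypothesis evaluation.

#' Classify a single-spore isolate as homo- or heterokaryon
#'
#' The multilocus genotype test: an isolate heteroallelic at one or more of
#' the codominant test loci is unambiguously a heterokaryon; an isolate
#' homoallelic at every locus is a putative homokaryon (a heterokaryon made
#' of genetically identical sister nuclei cannot be excluded).
#'
#' @param calls character vector of locus calls, e.g. `c("1", "1/2", "2")`;
#'   a call containing `/` with two distinct alleles is heteroallelic.
#' @return `"heterokaryon"`, `"homokaryon"`, or `NA` (with a warning) when
#'   a call is missing.
#' @export
classify_karyotype <- function(calls) {
  calls <- as.character(calls)
  if (anyNA(calls) || any(!nzchar(calls))) {
    warning("missing locus call(s); karyotype undetermined")
    return(NA_character_)
  }
  het <- vapply(strsplit(calls, "/", fixed = TRUE),
                function(a) length(unique(a)) > 1, logical(1))
  if (any(het)) "heterokaryon" else "homokaryon"
}

# Two-locus genotype interpretation of each ITS phenotype class.
# ITSI carries alleles a (ITS type A) and b (type B); ITSII carries allele
# c (type C) against a null allele n.  Homokaryons are haploid at both
# loci; c/c and c/n heterokaryons are phenotypically indistinguishable.
ITS_GENOTYPE_MAP <- list(
  homokaryon = list(
    "[A]"     = list(list(itsI = "a", itsII = "n")),
    "[B]"     = list(list(itsI = "b", itsII = "n")),
    "[C]"     = list(),
    "[A+B]"   = list(),
    "[A+C]"   = list(list(itsI = "a", itsII = "c")),
    "[B+C]"   = list(list(itsI = "b", itsII = "c")),
    "[A+B+C]" = list()
  ),
  heterokaryon = list(
    "[A]"     = list(list(itsI = "a/a", itsII = "n/n")),
    "[B]"     = list(list(itsI = "b/b", itsII = "n/n")),
    "[C]"     = list(),
    "[A+B]"   = list(list(itsI = "a/b", itsII = "n/n")),
    "[A+C]"   = list(list(itsI = "a/a", itsII = c("c/n", "c/c"))),
    "[B+C]"   = list(list(itsI = "b/b", itsII = c("c/n", "c/c"))),
    "[A+B+C]" = list(list(itsI = "a/b", itsII = c("c/n", "c/c")))
  )
)

#' Two-locus ITS genotypes compatible with a phenotype
#'
#' Under the two-locus model (types A/B allelic at *ITSI*, type C at the
#' unlinked *ITSII* segregating against a null allele), maps an ITS band
#' phenotype class and karyotype to the set of compatible genotypes.  The
#' `itsII` element is an ambiguity set where `c/c` and `c/n` cannot be
#' separated.  An empty result marks a phenotype that is impossible under
#' the model (e.g. a pure `[C]`, or a homokaryon showing `[A+B]`), the
#' model's diagnostic for rejecting an interpretation.
#'
#' @param phenotype one of the seven class labels `"[A]"` ... `"[A+B+C]"`
#'   (brackets optional).
#' @param karyotype `"homokaryon"` or `"heterokaryon"`.
#' @return List of compatible genotypes, each a list with `itsI` (single
#'   symbol) and `itsII` (possibly a length-2 ambiguity set).
#' @export
infer_its_genotype <- function(phenotype, karyotype = c("homokaryon",
                                                        "heterokaryon")) {
  karyotype <- match.arg(karyotype)
  lb <- phenotype
  if (!grepl("^\\[", lb)) lb <- paste0("[", lb, "]")
  if (!lb %in% ITS_CLASS_LABELS)
    stop("unknown phenotype class: ", phenotype)
  ITS_GENOTYPE_MAP[[karyotype]][[lb]]
}

#' Allele counts implied by homokaryon phenotype counts
#'
#' Each homokaryon carries one *ITSI* allele (a or b) and one *ITSII*
#' allele (c or null); phenotype classes map one-to-one to haploid
#' genotypes, so class counts convert directly to allele counts.
#'
#' @param hom_counts named counts over the seven phenotype classes
#'   (missing classes count 0); classes impossible for homokaryons must be
#'   zero.
#' @return Named numeric vector with counts of alleles `a`, `b`, `c`, `n`.
#' @export
count_homokaryon_alleles <- function(hom_counts) {
  cnt <- .class_counts(hom_counts)
  bad <- cnt[c("[C]", "[A+B]", "[A+B+C]")] > 0
  if (any(bad))
    stop("phenotype class(es) impossible for homokaryons have non-zero ",
         "counts: ", paste(names(bad)[bad], collapse = ", "))
  c(a = unname(cnt["[A]"] + cnt["[A+C]"]),
    b = unname(cnt["[B]"] + cnt["[B+C]"]),
    c = unname(cnt["[A+C]"] + cnt["[B+C]"]),
    n = unname(cnt["[A]"] + cnt["[B]"]))
}

.class_counts <- function(counts) {
  if (is.null(names(counts))) {
    if (length(counts) != 7)
      stop("unnamed counts must cover all 7 classes in canonical order")
    names(counts) <- ITS_CLASS_LABELS
  }
  names(counts) <- ifelse(grepl("^\\[", names(counts)), names(counts),
                          paste0("[", names(counts), "]"))
  unknown <- setdiff(names(counts), ITS_CLASS_LABELS)
  if (length(unknown)) stop("unknown class label(s): ",
                            paste(unknown, collapse = ", "))
  out <- stats::setNames(numeric(7), ITS_CLASS_LABELS)
  out[names(counts)] <- counts
  out
}

#' Goodness-of-fit test of Mendelian segregation
#'
#' Pearson chi-square of observed allele counts against a 1:1 (or supplied)
#' ratio, df = k - 1, no continuity correction.
#'
#' @param counts allele counts at one locus.
#' @param ratio expected ratio (default equal).
#' @param alpha significance level for the verdict.
#' @return List of class `chisq_result` with `statistic`, `df`, `p.value`,
#'   `counts` and `verdict`.
#' @export
segregation_test <- function(counts, ratio = rep(1, length(counts)),
                             alpha = 0.05) {
  counts <- as.numeric(counts)
  if (sum(counts) == 0) stop("total count is zero")
  ht <- suppressWarnings(stats::chisq.test(counts, p = ratio / sum(ratio)))
  structure(list(statistic = unname(ht$statistic),
                 df = as.integer(unname(ht$parameter)),
                 p.value = ht$p.value, counts = counts,
                 verdict = if (ht$p.value < alpha) "ratio rejected"
                           else "ratio not rejected"),
            class = "chisq_result")
}

#' Contingency chi-square test of linkage between two loci
#'
#' Tests independent re-assortment of two loci from the 2x2 table of
#' haploid two-locus classes among homokaryons (df = 1, no continuity
#' correction), and reports the two complementary phase splits of the
#' progeny.  True parental phase is unknown in a heterokaryon, so both
#' arrangements are reported; `parental` is the larger split (under
#' linkage, parental classes are in excess).
#'
#' @param tab 2x2 matrix of joint haploid counts (rows: locus-1 alleles,
#'   columns: locus-2 alleles), or a length-4 count vector in row-major
#'   order.
#' @param alpha significance level.
#' @return List of class `linkage_result` with the statistic, df, p-value,
#'   the two phase splits, the parental:recombinant ratio and a verdict.
#' @export
linkage_test <- function(tab, alpha = 0.05) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (!all(dim(tab) == 2)) stop("need a 2x2 table")
  if (is.null(rownames(tab))) rownames(tab) <- c("A1", "A2")
  if (is.null(colnames(tab))) colnames(tab) <- c("B1", "B2")
  split1 <- tab[1, 1] + tab[2, 2]   # coupling: first alleles together
  split2 <- tab[1, 2] + tab[2, 1]   # repulsion
  names(split1) <- paste0(rownames(tab)[1], "-", colnames(tab)[1], "/",
                          rownames(tab)[2], "-", colnames(tab)[2])
  names(split2) <- paste0(rownames(tab)[1], "-", colnames(tab)[2], "/",
                          rownames(tab)[2], "-", colnames(tab)[1])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("a margin of the table is zero; linkage statistic undefined")
    return(structure(list(statistic = NA_real_, df = 1L, p.value = NA_real_,
                          table = tab, splits = c(split1, split2),
                          parental = NA_real_, recombinant = NA_real_,
                          ratio = NA_character_, verdict = "undefined"),
                     class = "linkage_result"))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  parental <- max(split1, split2)
  recomb <- min(split1, split2)
  structure(list(statistic = unname(ht$statistic),
                 df = as.integer(unname(ht$parameter)),
                 p.value = ht$p.value, table = tab,
                 splits = c(split1, split2),
                 parental = parental, recombinant = recomb,
                 ratio = paste0(recomb, ":", parental),
                 verdict = if (ht$p.value < alpha) "linked"
                           else "independent re-assortment not rejected"),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, digits = 2, ...) {
  cat(sprintf("Linkage chi-square = %.*f, df = %d, p = %.*f (%s)\n",
              digits, x$statistic, x$df, digits, x$p.value, x$verdict))
  cat("Phase splits:", paste(names(x$splits), x$splits, sep = " = ",
                             collapse = "; "), "\n")
  invisible(x)
}

#' Homozygosity rate among heterokaryons
#'
#' Fraction of heterokaryotic isolates homoallelic at a locus.  For the
#' marker loci this is read from the calls; for *ITSI* the genotype is
#' implied by the phenotype class; at *ITSII* only homozygosity for the
#' null allele is observable (`c/c` and `c/n` share the `[C]`-containing
#' phenotypes), so the rate counts phenotypes without the type-C bands.
#'
#' @param x either a data frame of heterokaryon records (with marker call
#'   columns and a `phenotype` column) or, for the ITS loci, named
#'   phenotype-class counts of the heterokaryotic offspring.
#' @param locus locus name: a marker column name, `"ITSI"` or `"ITSII"`.
#' @return List with `rate`, `homozygous`, `total`.
#' @export
homozygosity_rate <- function(x, locus) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0) stop("no heterokaryon records")
    if (locus %in% c("ITSI", "ITSII")) {
      cnt <- table(factor(x$phenotype, levels = ITS_CLASS_LABELS))
      return(homozygosity_rate(stats::setNames(as.numeric(cnt),
                                               names(cnt)), locus))
    }
    if (!locus %in% names(x)) stop("no column for locus ", locus)
    calls <- as.character(x[[locus]])
    ok <- !is.na(calls) & nzchar(calls)
    homo <- vapply(strsplit(calls[ok], "/", fixed = TRUE),
                   function(a) length(unique(a)) == 1, logical(1))
    return(list(rate = mean(homo), homozygous = sum(homo),
                total = sum(ok)))
  }
  cnt <- .class_counts(x)
  total <- sum(cnt)
  if (total == 0) stop("no heterokaryons")
  if (cnt["[C]"] > 0) stop("phenotype [C] is impossible for heterokaryons")
  homo <- switch(locus,
    ITSI = cnt["[A]"] + cnt["[A+C]"] + cnt["[B]"] + cnt["[B+C]"],
    ITSII = cnt["[A]"] + cnt["[B]"] + cnt["[A+B]"],
    stop("counts-based rates are available for loci ITSI and ITSII only"))
  list(rate = unname(homo / total), homozygous = unname(homo),
       total = total)
}

#' Evaluate competing inheritance hypotheses for the three ITS types
#'
#' Confronts the observed phenotype counts, split by karyotype, with two
#' models: (i) a *trikaryon* parent (three genetically distinct nucleus
#' types, one ITS type each), under which every homokaryotic offspring
#' shows a single ITS type and `[A]`, `[B]`, `[C]` are expected in equal
#' thirds; (ii) *two unlinked loci* (A/B allelic at *ITSI*, C against a
#' null at *ITSII*), under which homokaryons show only `[A]`, `[B]`,
#' `[A+C]`, `[B+C]` with 1:1 segregation at each locus, and `[C]` is
#' impossible in any offspring.  Observed counts in classes a model forbids
#' are returned as rejection witnesses.
#'
#' @param hom_counts,het_counts named phenotype-class counts for the
#'   homokaryotic and heterokaryotic offspring.
#' @param alpha significance level for the ratio checks.
#' @return Object of class `hypothesis_eval`: per-model verdicts
#'   (`"consistent"` / `"rejected"`), witness lists and supporting ratio
#'   tests.
#' @export
evaluate_hypotheses <- function(hom_counts, het_counts = NULL,
                                alpha = 0.05) {
  hom <- .class_counts(hom_counts)
  het <- if (is.null(het_counts)) NULL else .class_counts(het_counts)

  witness <- function(cnt, classes) {
    w <- cnt[classes][cnt[classes] > 0]
    if (length(w) == 0) NULL else w
  }

  # trikaryon: homokaryotic offspring can only show one ITS type
  tri_w <- witness(hom, c("[A+B]", "[A+C]", "[B+C]", "[A+B+C]"))
  tri <- list(name = "trikaryon",
              verdict = if (is.null(tri_w)) "consistent" else "rejected",
              witnesses = tri_w, ratio_test = NULL)
  if (is.null(tri_w)) {
    tri$ratio_test <- equal_ratio_chisq(hom[c("[A]", "[B]", "[C]")])
    if (tri$ratio_test$p.value < alpha) {
      tri$verdict <- "rejected"
      tri$witnesses <- c(tri$witnesses,
                         "1:1:1 ratio of homokaryon types rejected")
    }
  }

  # two unlinked loci with a null allele at ITSII
  two_w <- witness(hom, c("[C]", "[A+B]", "[A+B+C]"))
  if (!is.null(het) && het["[C]"] > 0)
    two_w <- c(two_w, stats::setNames(het["[C]"], "heterokaryon [C]"))
  two <- list(name = "two_locus",
              verdict = if (is.null(two_w)) "consistent" else "rejected",
              witnesses = two_w, segregation = NULL, linkage = NULL)
  if (is.null(two_w)) {
    al <- count_homokaryon_alleles(hom)
    two$allele_counts <- al
    two$segregation <- list(
      ITSI = segregation_test(al[c("a", "b")], alpha = alpha),
      ITSII = segregation_test(al[c("c", "n")], alpha = alpha))
    tab <- matrix(c(hom["[A+C]"], hom["[A]"], hom["[B+C]"], hom["[B]"]),
                  2, 2, byrow = TRUE,
                  dimnames = list(ITSI = c("a", "b"), ITSII = c("c", "n")))
    two$linkage <- linkage_test(tab, alpha = alpha)
    segs_ok <- all(vapply(two$segregation, function(s) s$p.value >= alpha,
                          logical(1)))
    if (!segs_ok) {
      two$verdict <- "rejected"
      two$witnesses <- c(two$witnesses, "1:1 segregation rejected")
    }
  }

  structure(list(trikaryon = tri, two_locus = two, alpha = alpha,
                 hom_counts = hom, het_counts = het),
            class = "hypothesis_eval")
}

#' @export
print.hypothesis_eval <- function(x, ...) {
  for (h in list(x$trikaryon, x$two_locus)) {
    cat(sprintf("%-10s %s", h$name, toupper(h$verdict)))
    if (!is.null(h$witnesses) && length(h$witnesses)) {
      wn <- names(h$witnesses) %||% as.character(h$witnesses)
      lab <- ifelse(nzchar(wn) & !is.na(suppressWarnings(
        as.numeric(h$witnesses))),
        paste0(wn, " (n=", h$witnesses, ")"), as.character(h$witnesses))
      cat("  witnesses:", paste(lab, collapse = ", "))
    }
    cat("\n")
  }
  if (!is.null(x$two_locus$linkage) &&
      !is.na(x$two_locus$linkage$statistic)) {
    cat("ITSI x ITSII ")
    print(x$two_locus$linkage)
  }
  invisible(x)
}

#' Phenotype classes an ITS parent genotype can transmit
#'
#' Enumerates the haploid gametic genotypes of a parent and all paired
#' two-nucleus combinations, maps each through the band phenotype, and
#' returns the distinct phenotype classes of the possible offspring.  Also
#' reports the combinatorial phenotype space (every non-empty subset of
#' the parental ITS types), which for a three-type parent comprises the
#' classical seven combinations; under the two-locus model the pure-C
#' class is never realised by an offspring genotype because every nucleus
#' carries an *ITSI* allele.
#'
#' @param itsI parent *ITSI* genotype, e.g. `"a/b"` or `"a"`.
#' @param itsII parent *ITSII* genotype over alleles `c` and `n`,
#'   e.g. `"c/n"`.
#' @return List with `genotypic` (class labels reachable by offspring
#'   genotypes), `combinatorial` (all non-empty subsets of parental types)
#'   and `gametes`.
#' @export
enumerate_offspring_phenotypes <- function(itsI = "a/b", itsII = "c/n") {
  a1 <- strsplit(itsI, "/", fixed = TRUE)[[1]]
  a2 <- strsplit(itsII, "/", fixed = TRUE)[[1]]
  if (!all(a1 %in% c("a", "b")) || !all(a2 %in% c("c", "n")))
    stop("alleles must be a/b at ITSI and c/n at ITSII")
  gametes <- unique(expand.grid(itsI = unique(a1), itsII = unique(a2),
                                stringsAsFactors = FALSE))
  types_of <- function(g1, g2) {
    tt <- character()
    if ("a" %in% g1) tt <- c(tt, "A")
    if ("b" %in% g1) tt <- c(tt, "B")
    if ("c" %in% g2) tt <- c(tt, "C")
    tt
  }
  labels <- character()
  for (i in seq_len(nrow(gametes)))
    labels <- c(labels, its_class_label(
      types_of(gametes$itsI[i], gametes$itsII[i])))
  for (i in seq_len(nrow(gametes))) for (j in i:nrow(gametes))
    labels <- c(labels, its_class_label(
      types_of(c(gametes$itsI[i], gametes$itsI[j]),
               c(gametes$itsII[i], gametes$itsII[j]))))
  parental_types <- types_of(a1, a2)
  subsets <- unlist(lapply(seq_along(parental_types), function(k)
    utils::combn(parental_types, k, its_class_label, simplify = FALSE)),
    recursive = FALSE)
  list(genotypic = intersect(ITS_CLASS_LABELS, unique(labels)),
       combinatorial = intersect(ITS_CLASS_LABELS, unlist(subsets)),
       gametes = gametes)
}
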