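# End-to-end analysis of a single-spore-isolate offspring: karyotype
# classification, phenotype tabulation, genotype inference, segregation
# and linkage statistics, and hypothesis evaluation.

#' Analyse a single-spore-isolate offspring
#'
#' The central entry point: takes an SSI genotype table (from
#' [read_genotype_table()] or [generate_ssi_dataset()]), classifies every
#' isolate as homo- or heterokaryon by the multilocus genotype test,
#' tabulates the ITS phenotype classes by karyotype, infers two-locus ITS
#' genotypes, tests Mendelian 1:1 segregation at every locus and pairwise
#' linkage among the homokaryons, computes heterokaryon homozygosity
#' rates, and evaluates the trikaryon and two-unlinked-loci hypotheses.
#'
#' @param tab an `ssi_table` data frame (or an `ssi_dataset`, whose table
#'   is used).
#' @param markers marker columns used for the karyotype test.
#' @param alpha significance level for all chi-square verdicts.
#' @return Object of class `ssi_analysis`.
#' @export
ssi_analysis <- function(tab, markers = c("PRS016", "PRS049", "PRS088"),
                         alpha = 0.05) {
  if (inherits(tab, "ssi_dataset")) tab <- tab$table
  stopifnot(is.data.frame(tab), all(markers %in% names(tab)))
  if (!"phenotype" %in% names(tab)) {
    if (!all(c("ITS_MboII", "ITS_FokI") %in% names(tab)))
      stop("need a `phenotype` column or ITS band columns")
    tab$phenotype <- mapply(phenotype_from_bands, tab$ITS_MboII,
                            tab$ITS_FokI, USE.NAMES = FALSE)
  }
  n <- nrow(tab)
  kary <- vapply(seq_len(n), function(i) {
    suppressWarnings(classify_karyotype(unlist(tab[i, markers])))
  }, "")
  undetermined <- sum(is.na(kary))
  calls <- data.frame(id = tab$id, tab[, markers, drop = FALSE],
                      phenotype = tab$phenotype, karyotype = kary,
                      stringsAsFactors = FALSE)
  # two-locus genotype interpretation per isolate
  calls$itsI <- NA_character_
  calls$itsII <- NA_character_
  for (i in seq_len(n)) {
    if (is.na(kary[i]) || is.na(tab$phenotype[i])) next
    g <- infer_its_genotype(tab$phenotype[i], kary[i])
    if (length(g)) {
      calls$itsI[i] <- g[[1]]$itsI
      calls$itsII[i] <- paste(g[[1]]$itsII, collapse = " or ")
    } else calls$itsI[i] <- calls$itsII[i] <- "inconsistent"
  }

  lvl <- ITS_CLASS_LABELS
  ok <- !is.na(kary) & !is.na(tab$phenotype)
  hom <- calls[ok & kary == "homokaryon", ]
  het <- calls[ok & kary == "heterokaryon", ]
  hom_counts <- table(factor(hom$phenotype, levels = lvl))
  het_counts <- table(factor(het$phenotype, levels = lvl))

  inconsistent <- sum(calls$itsI %in% "inconsistent")
  hyp <- evaluate_hypotheses(stats::setNames(as.numeric(hom_counts), lvl),
                             stats::setNames(as.numeric(het_counts), lvl),
                             alpha = alpha)

  # per-locus 1:1 segregation among homokaryons
  seg <- list()
  for (m in markers) {
    cnt <- table(hom[[m]])
    if (length(cnt) == 2) seg[[m]] <- segregation_test(cnt, alpha = alpha)
  }
  if (!is.null(hyp$two_locus$segregation)) {
    seg$ITSI <- hyp$two_locus$segregation$ITSI
    seg$ITSII <- hyp$two_locus$segregation$ITSII
  }

  # pairwise linkage among homokaryon haploid calls (ITSI/ITSII read from
  # the phenotype through the genotype map)
  hom$ITSI <- hom$itsI
  hom$ITSII <- ifelse(grepl("C", hom$phenotype, fixed = TRUE), "c", "n")
  loci <- c(markers, "ITSI", "ITSII")
  linkage <- list()
  if (nrow(hom) > 0) {
    for (i in seq_along(loci)) for (j in seq_along(loci)) {
      if (j <= i) next
      a <- hom[[loci[i]]]; b <- hom[[loci[j]]]
      keep <- !is.na(a) & !is.na(b) & a != "inconsistent" &
        b != "inconsistent"
      if (length(unique(a[keep])) == 2 && length(unique(b[keep])) == 2) {
        tb <- table(a[keep], b[keep])
        linkage[[paste(loci[i], loci[j], sep = "-")]] <-
          linkage_test(unclass(tb), alpha = alpha)
      }
    }
  }

  homozygosity <- list()
  if (nrow(het) > 0) {
    for (m in markers) homozygosity[[m]] <- homozygosity_rate(het, m)
    homozygosity$ITSI <- homozygosity_rate(het, "ITSI")
    homozygosity$ITSII <- homozygosity_rate(het, "ITSII")
  }

  structure(list(
    n = n, n_undetermined = undetermined, n_inconsistent = inconsistent,
    heterokaryon_rate = if (sum(ok)) nrow(het) / sum(ok) else NA_real_,
    n_heterokaryons = nrow(het), n_homokaryons = nrow(hom),
    hom_counts = hom_counts, het_counts = het_counts,
    allele_counts = if (is.null(hyp$two_locus$allele_counts)) NULL else
      hyp$two_locus$allele_counts,
    segregation = seg, linkage = linkage, homozygosity = homozygosity,
    hypotheses = hyp, alpha = alpha, calls = calls),
    class = "ssi_analysis")
}

#' @export
print.ssi_analysis <- function(x, ...) {
  cat("Single-spore-isolate analysis:", x$n, "isolates\n")
  cat(sprintf("  heterokaryons: %d (%.2f%%); homokaryons: %d\n",
              x$n_heterokaryons, 100 * x$heterokaryon_rate,
              x$n_homokaryons))
  if (x$n_undetermined)
    cat("  undetermined karyotype:", x$n_undetermined, "\n")
  if (x$n_inconsistent)
    cat("  isolates inconsistent with the two-locus model:",
        x$n_inconsistent, "\n")
  cat("\nITS phenotype classes (homokaryons / heterokaryons):\n")
  m <- rbind(homokaryon = as.integer(x$hom_counts),
             heterokaryon = as.integer(x$het_counts))
  colnames(m) <- names(x$hom_counts)
  print(m)
  if (!is.null(x$allele_counts)) {
    cat("\nHomokaryon allele counts: ",
        paste(names(x$allele_counts), x$allele_counts, sep = "=",
              collapse = ", "), "\n")
  }
  if (length(x$segregation)) {
    cat("\n1:1 segregation tests (homokaryons):\n")
    for (nm in names(x$segregation)) {
      s <- x$segregation[[nm]]
      cat(sprintf("  %-7s %d:%d  chi-square = %.3f, p = %.2f (%s)\n", nm,
                  s$counts[1], s$counts[2], s$statistic, s$p.value,
                  s$verdict))
    }
  }
  if (!is.null(x$linkage$`ITSI-ITSII`)) {
    l <- x$linkage$`ITSI-ITSII`
    cat(sprintf("\nITSI x ITSII linkage: chi-square = %.3f, p = %.2f (%s); split %s\n",
                l$statistic, l$p.value, l$verdict,
                paste(sort(l$splits), collapse = ":")))
  }
  if (length(x$homozygosity)) {
    cat("\nHeterokaryon homozygosity rates:\n")
    for (nm in names(x$homozygosity)) {
      h <- x$homozygosity[[nm]]
      cat(sprintf("  %-7s %d/%d = %.0f%%\n", nm, h$homozygous, h$total,
                  100 * h$rate))
    }
  }
  cat("\nHypothesis evaluation:\n")
  print(x$hypotheses)
  invisible(x)
}

#' @export
summary.ssi_analysis <- function(object, ...) {
  out <- list(
    n = object$n,
    heterokaryon_rate = object$heterokaryon_rate,
    hom_counts = object$hom_counts,
    het_counts = object$het_counts,
    allele_counts = object$allele_counts,
    verdicts = c(trikaryon = object$hypotheses$trikaryon$verdict,
                 two_locus = object$hypotheses$two_locus$verdict))
  class(out) <- "summary.ssi_analysis"
  out
}

#' @export
print.summary.ssi_analysis <- function(x, ...) {
  cat(sprintf("%d isolates; heterokaryon rate %.2f%%\n", x$n,
              100 * x$heterokaryon_rate))
  cat("verdicts:", paste(names(x$verdicts), x$verdicts, sep = " = ",
                         collapse = "; "), "\n")
  invisible(x)
}
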