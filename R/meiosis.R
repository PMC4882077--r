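# Random tetrasporic meiosis with optional post-meiotic mitosis: the
# amphithallic life-cycle engine used both as a theoretical model (expected
# loss of parental heterozygosity among heterokaryotic spores) and as the
# synthetic-data generator for single-spore-isolate genotype tables.
#
# Crossing over is abstracted to a per-locus second-division segregation
# (SDS) frequency f: with probability f the two meiosis-II pairs each carry
# both alleles; otherwise the pairs are homoallelic and opposite.  Meiotic
# products are indexed 1..4, products 1-2 and 3-4 being the two meiosis-II
# pairs ("sister" nuclei).

#' Define a heteroallelic parent genome for the meiosis simulator
#'
#' @param loci data frame with columns `name`, `chromosome`, `f` (SDS
#'   frequency in `[0,1]`), `allele1`, `allele2`, and optionally
#'   `r_to_prev` (recombination fraction to the previous locus on the same
#'   chromosome; `NA` = unlinked or first on its chromosome).
#' @return Object of class `parent_genome`.
#' @export
parent_genome <- function(loci) {
  need <- c("name", "chromosome", "f", "allele1", "allele2")
  if (!all(need %in% names(loci)))
    stop("`loci` must have columns ", paste(need, collapse = ", "))
  if (any(loci$f < 0 | loci$f > 1)) stop("SDS frequency f must be in [0,1]")
  if (is.null(loci$r_to_prev)) loci$r_to_prev <- NA_real_
  if (any(!is.na(loci$r_to_prev) &
          (loci$r_to_prev < 0 | loci$r_to_prev > 0.5)))
    stop("recombination fractions must be in [0, 0.5]")
  if (anyDuplicated(loci$name)) stop("duplicate locus names")
  structure(list(loci = loci), class = "parent_genome")
}

#' @export
print.parent_genome <- function(x, ...) {
  cat("Heteroallelic parent with", nrow(x$loci), "segregating loci\n")
  print(x$loci, row.names = FALSE)
  invisible(x)
}

#' The CA487 parent fixture
#'
#' The wild heterokaryon under study: heteroallelic at the three CAPS
#' markers (PRS088 tightly centromere-linked, f = 0; PRS016 and PRS049
#' distal on other chromosomes) and at the two ITS loci: *ITSI* with
#' alleles a/b (ITS types A/B) and the unlinked *ITSII* with allele c
#' (type C) against a null allele.  A SDS frequency of 0.4 is used for the
#' distal loci; all five loci assort independently.
#'
#' @param f_distal SDS frequency of the non-centromeric loci.
#' @return A [parent_genome()].
#' @export
ca487_parent <- function(f_distal = 0.4) {
  parent_genome(data.frame(
    name = c("PRS016", "PRS049", "PRS088", "ITSI", "ITSII"),
    chromosome = c("chrX", "chrIII", "chrI", "chrITSI", "chrITSII"),
    f = c(f_distal, f_distal, 0, f_distal, f_distal),
    allele1 = c("1", "1", "1", "a", "c"),
    allele2 = c("2", "2", "2", "b", "n"),
    stringsAsFactors = FALSE))
}

#' Basidium model parameters
#'
#' @param p_mitosis probability that a basidium undergoes one round of
#'   post-meiotic mitosis (eight nuclei, every spore receives two) rather
#'   than none (four nuclei, homokaryotic spores).  Default 0.27, the
#'   heterokaryotic-spore rate of the CA487 offspring under study;
#'   published rates in the species range from 40 to 75%.
#' @param pairing nucleus pairing rule in mitotic basidia:
#'   `"random_non_twin"` (each spore receives two distinct meiotic
#'   products drawn uniformly from the 6 unordered pairs; one third of
#'   such pairs are sisters), `"sister_bias"` (sister pair with
#'   probability `beta`, otherwise a uniform non-sister pair; `beta = 1/3`
#'   reduces to the random rule), or `"allow_twin"` (uniform over the 10
#'   unordered pairs with repetition, so a spore may receive two copies of
#'   the same product).
#' @param beta sister-pair probability under `"sister_bias"`.
#' @return Object of class `basidium_model`.
#' @export
basidium_model <- function(p_mitosis = 0.27,
                           pairing = c("random_non_twin", "sister_bias",
                                       "allow_twin"),
                           beta = 1 / 3) {
  pairing <- match.arg(pairing)
  stopifnot(p_mitosis >= 0, p_mitosis <= 1, beta >= 0, beta <= 1)
  structure(list(p_mitosis = p_mitosis, pairing = pairing, beta = beta,
                 spores_per_basidium = 4L),
            class = "basidium_model")
}

# ---- vectorised meiosis ---------------------------------------------------

# Allele codes (1/2) of the four meiotic products at every locus, for n
# independent meioses.  Returns a named list of n x 4 integer matrices.
.meiosis_alleles <- function(loci, n) {
  out <- vector("list", nrow(loci))
  names(out) <- loci$name
  for (i in seq_len(nrow(loci))) {
    r <- loci$r_to_prev[i]
    linked <- i > 1 && !is.na(r) &&
      loci$chromosome[i] == loci$chromosome[i - 1]
    if (!linked) {
      out[[i]] <- .segregate(n, loci$f[i])
    } else {
      # tetrad-type model relative to the previous locus: parental ditype
      # with probability 1 - 2r, tetratype 2r (non-parental ditypes are
      # negligible at the map distances used)
      prev <- out[[i - 1]]
      m <- prev
      tt <- which(runif(n) < 2 * r)
      for (row in tt) {
        ones <- which(prev[row, ] == 1L)
        twos <- which(prev[row, ] == 2L)
        i1 <- ones[sample.int(2, 1)]
        i2 <- twos[sample.int(2, 1)]
        m[row, i1] <- 2L
        m[row, i2] <- 1L
      }
      out[[i]] <- m
    }
  }
  out
}

# One locus, n meioses: with probability f both meiosis-II pairs carry both
# alleles (second-division segregation); otherwise the pairs are
# homoallelic and opposite, with random orientation.
.segregate <- function(n, f) {
  m <- matrix(0L, n, 4)
  sds <- runif(n) < f
  n_fds <- sum(!sds)
  if (n_fds) {
    orient <- runif(n_fds) < 0.5
    m[!sds, ] <- t(vapply(orient, function(o)
      if (o) c(1L, 1L, 2L, 2L) else c(2L, 2L, 1L, 1L), integer(4)))
  }
  n_sds <- sum(sds)
  if (n_sds) {
    o1 <- runif(n_sds) < 0.5
    o2 <- runif(n_sds) < 0.5
    m[sds, 1] <- ifelse(o1, 1L, 2L)
    m[sds, 2] <- ifelse(o1, 2L, 1L)
    m[sds, 3] <- ifelse(o2, 1L, 2L)
    m[sds, 4] <- ifelse(o2, 2L, 1L)
  }
  m
}

#' Simulate one meiosis
#'
#' @param parent a [parent_genome()].
#' @param seed optional RNG seed.
#' @return Data frame of four haploid nuclei (rows) by locus (columns),
#'   holding allele labels.  Nuclei 1-2 and 3-4 are the two meiosis-II
#'   pairs.
#' @export
simulate_meiosis <- function(parent, seed = NULL) {
  codes <- with_seed(seed, .meiosis_alleles(parent$loci, 1L))
  out <- as.data.frame(lapply(seq_along(codes), function(i) {
    lab <- c(parent$loci$allele1[i], parent$loci$allele2[i])
    lab[codes[[i]][1, ]]
  }))
  names(out) <- parent$loci$name
  rownames(out) <- paste0("nucleus", 1:4)
  out
}

# Draw nucleus pairs for mitotic-basidium spores.  Returns a 2-column
# matrix of meiotic-product indices (n draws).
.draw_pairs <- function(n, pairing, beta) {
  sister_pairs <- matrix(c(1L, 2L, 3L, 4L), 2, byrow = TRUE)
  nonsis_pairs <- matrix(c(1L, 3L, 1L, 4L, 2L, 3L, 2L, 4L), 4, byrow = TRUE)
  if (pairing == "allow_twin") {
    all_pairs <- rbind(cbind(1:4, 1:4), sister_pairs, nonsis_pairs)
    return(all_pairs[sample.int(nrow(all_pairs), n, replace = TRUE), ,
                     drop = FALSE])
  }
  b <- if (pairing == "random_non_twin") 1 / 3 else beta
  sis <- runif(n) < b
  out <- matrix(0L, n, 2)
  if (any(sis))
    out[sis, ] <- sister_pairs[sample.int(2, sum(sis), replace = TRUE), ,
                               drop = FALSE]
  if (any(!sis))
    out[!sis, ] <- nonsis_pairs[sample.int(4, sum(!sis), replace = TRUE), ,
                                drop = FALSE]
  out
}

#' Simulate basidia and their spores
#'
#' Vectorised simulation of `n_basidia` basidia.  A basidium without
#' post-meiotic mitosis sheds its four meiotic products as four
#' homokaryotic spores; a mitotic basidium duplicates the products into
#' four twin pairs and every spore receives two nuclei according to the
#' pairing rule.
#'
#' @param parent a [parent_genome()].
#' @param model a [basidium_model()].
#' @param n_basidia number of basidia.
#' @param spores `"all"` (four spores per basidium) or `"one"` (a single
#'   spore sampled per basidium, emulating isolates picked from a spore
#'   print of very many basidia).
#' @param seed optional RNG seed.
#' @return Object of class `basidium_sim`: list with `spores` (data frame:
#'   `basidium`, `spore`, `nuc1`, `nuc2`, `two_nuclei`, `sister`, `twin`)
#'   and `alleles` (per locus, an n_spores x 2 matrix of allele codes;
#'   column 2 is `NA` for one-nucleus spores).
#' @export
simulate_basidia <- function(parent, model = basidium_model(),
                             n_basidia = 1000L, spores = c("all", "one"),
                             seed = NULL) {
  spores <- match.arg(spores)
  with_seed(seed, {
    loci <- parent$loci
    codes <- .meiosis_alleles(loci, n_basidia)
    mitotic <- runif(n_basidia) < model$p_mitosis
    per_bas <- if (spores == "all") 4L else 1L
    basidium <- rep(seq_len(n_basidia), each = per_bas)
    spore_no <- rep(seq_len(per_bas), times = n_basidia)
    n_sp <- length(basidium)
    two <- mitotic[basidium]
    nuc1 <- integer(n_sp)
    nuc2 <- rep(NA_integer_, n_sp)
    # non-mitotic: spore s carries meiotic product s (or a random product
    # when a single spore is sampled)
    if (any(!two)) {
      nuc1[!two] <- if (spores == "all") spore_no[!two] else
        sample.int(4, sum(!two), replace = TRUE)
    }
    if (any(two)) {
      pairs <- .draw_pairs(sum(two), model$pairing, model$beta)
      nuc1[two] <- pairs[, 1]
      nuc2[two] <- pairs[, 2]
    }
    sister <- two & !is.na(nuc2) & nuc1 != nuc2 &
      ((nuc1 - 1L) %/% 2L) == ((nuc2 - 1L) %/% 2L)
    twin <- two & !is.na(nuc2) & nuc1 == nuc2
    alleles <- lapply(codes, function(m) {
      a1 <- m[cbind(basidium, nuc1)]
      a2 <- ifelse(two, m[cbind(basidium, ifelse(is.na(nuc2), 1L, nuc2))],
                   NA_integer_)
      cbind(a1, a2)
    })
    structure(list(
      spores = data.frame(basidium = basidium, spore = spore_no,
                          nuc1 = nuc1, nuc2 = nuc2, two_nuclei = two,
                          sister = sister, twin = twin),
      alleles = alleles, parent = parent, model = model,
      n_basidia = n_basidia),
      class = "basidium_sim")
  })
}

#' Simulate a single basidium
#'
#' @inheritParams simulate_basidia
#' @return List of four spores; each spore is a list with `nuclei` (a 1- or
#'   2-row data frame of allele labels by locus), `heterokaryotic` and
#'   `sister`.
#' @export
simulate_basidium <- function(parent, model = basidium_model(),
                              seed = NULL) {
  sim <- simulate_basidia(parent, model, n_basidia = 1L, spores = "all",
                          seed = seed)
  loci <- parent$loci
  lapply(seq_len(4), function(s) {
    two <- sim$spores$two_nuclei[s]
    nuc <- as.data.frame(lapply(seq_len(nrow(loci)), function(i) {
      lab <- c(loci$allele1[i], loci$allele2[i])
      a <- sim$alleles[[i]][s, ]
      lab[a[!is.na(a)]]
    }))
    names(nuc) <- loci$name
    list(nuclei = nuc, heterokaryotic = two,
         sister = sim$spores$sister[s])
  })
}

#' Expected loss of parental heterozygosity among heterokaryotic spores
#'
#' Monte-Carlo estimate of the fraction of heterokaryotic (two-nucleus)
#' spores that are homoallelic at a locus, under post-meiotic mitosis in
#' every basidium.  Under random pairing of distinct meiotic products the
#' loss rate is 1/3 at any locus regardless of its SDS frequency: sister
#' pairs (one third of pairs) are heteroallelic with probability f,
#' non-sister pairs with probability (1 - f) + f/2, which sum to a
#' constant 2/3 retention.  Spores receiving twin nuclei (possible only
#' under the `allow_twin` rule) are genetically single-nucleus and are
#' excluded.
#'
#' @param parent a [parent_genome()].
#' @param model a [basidium_model()]; only the pairing rule is used (all
#'   basidia are taken mitotic, since only they yield heterokaryotic
#'   spores).
#' @param locus locus name.
#' @param n_basidia number of basidia (four spores each).
#' @param seed optional RNG seed.
#' @return List with `estimate`, `se` (binomial standard error), and
#'   `n_het` (heterokaryotic spores scored).
#' @export
estimate_het_loss <- function(parent, model = basidium_model(),
                              locus = "PRS088", n_basidia = 1e5,
                              seed = NULL) {
  li <- match(locus, parent$loci$name)
  if (is.na(li)) stop("unknown locus: ", locus)
  if (parent$loci$allele1[li] == parent$loci$allele2[li])
    stop("parent is not heteroallelic at ", locus)
  mito <- basidium_model(p_mitosis = 1, pairing = model$pairing,
                         beta = model$beta)
  sim <- simulate_basidia(parent_genome(parent$loci[li, , drop = FALSE]),
                          mito, n_basidia = n_basidia, spores = "all",
                          seed = seed)
  het <- sim$spores$two_nuclei & !sim$spores$twin
  if (!any(het)) stop("no heterokaryotic spores simulated")
  a <- sim$alleles[[1]][het, , drop = FALSE]
  homo <- a[, 1] == a[, 2]
  p <- mean(homo)
  list(estimate = p, se = sqrt(p * (1 - p) / sum(het)), n_het = sum(het))
}

#' Misclassification rate of the multilocus genotype test
#'
#' Probability that a true heterokaryotic spore is homoallelic at every
#' marker locus and is therefore called a (putative) homokaryon.  Adding
#' markers can only decrease the rate; a single centromere-linked marker
#' (f = 0) misses exactly the sister-pair spores (1/3 under random
#' pairing).
#'
#' @inheritParams estimate_het_loss
#' @param markers character vector of marker locus names (empty: every
#'   heterokaryon is missed, rate 1).
#' @return List with `estimate`, `se`, `n_het`.
#' @export
estimate_misclassification <- function(parent, model = basidium_model(),
                                       markers = c("PRS016", "PRS049",
                                                   "PRS088"),
                                       n_basidia = 2e4, seed = NULL) {
  if (length(markers) == 0)
    return(list(estimate = 1, se = 0, n_het = NA_integer_))
  li <- match(markers, parent$loci$name)
  if (anyNA(li)) stop("unknown marker(s): ",
                      paste(markers[is.na(li)], collapse = ", "))
  mito <- basidium_model(p_mitosis = 1, pairing = model$pairing,
                         beta = model$beta)
  sim <- simulate_basidia(parent_genome(parent$loci[li, , drop = FALSE]),
                          mito, n_basidia = n_basidia, spores = "all",
                          seed = seed)
  het <- sim$spores$two_nuclei & !sim$spores$twin
  if (!any(het)) stop("no heterokaryotic spores simulated")
  homo_all <- Reduce(`&`, lapply(sim$alleles, function(a)
    a[het, 1] == a[het, 2]))
  p <- mean(homo_all)
  list(estimate = p, se = sqrt(p * (1 - p) / sum(het)), n_het = sum(het))
}

#' Generate a synthetic single-spore-isolate genotype table
#'
#' Germinates `n_spores` spores (one per simulated basidium, as when
#' isolates are picked from a spore print pooling very many basidia),
#' renders each spore's marker alleles as CAPS calls and its ITS type
#' content as the two-enzyme band phenotype, and returns the genotype
#' table consumed by [ssi_analysis()] together with a hidden truth table
#' for recovery tests.
#'
#' @param parent a [parent_genome()]; ITS loci must be named `ITSI` and
#'   `ITSII` with alleles a/b and c/n.
#' @param model a [basidium_model()].
#' @param n_spores number of isolates.
#' @param seed optional RNG seed.
#' @return Object of class `ssi_dataset`: list with `table` (data frame:
#'   `id`, marker calls, `ITS_MboII`, `ITS_FokI`, `phenotype`), `truth`
#'   (true karyotype, sister/twin status, per-locus genotypes), and the
#'   generating `parent`, `model`, `seed`.
#' @export
generate_ssi_dataset <- function(parent = ca487_parent(),
                                 model = basidium_model(),
                                 n_spores = 94L, seed = NULL) {
  if (n_spores == 0) {
    empty <- data.frame(id = character())
    return(structure(list(table = empty, truth = empty, parent = parent,
                          model = model, seed = seed),
                     class = "ssi_dataset"))
  }
  sim <- simulate_basidia(parent, model, n_basidia = n_spores,
                          spores = "one", seed = seed)
  loci <- parent$loci
  ids <- sprintf("SSI%03d", seq_len(n_spores))
  call_of <- function(i) {
    lab <- c(loci$allele1[i], loci$allele2[i])
    a <- sim$alleles[[i]]
    one <- is.na(a[, 2]) | a[, 1] == a[, 2]
    ifelse(one, lab[a[, 1]],
           paste(lab[pmin(a[, 1], a[, 2])], lab[pmax(a[, 1], a[, 2])],
                 sep = "/"))
  }
  calls <- lapply(seq_len(nrow(loci)), call_of)
  names(calls) <- loci$name
  has <- function(locus, allele)
    grepl(allele, calls[[locus]], fixed = TRUE)
  types <- cbind(A = has("ITSI", "a"), B = has("ITSI", "b"),
                 C = has("ITSII", "c"))
  phen <- apply(types, 1, function(p)
    its_class_label(c("A", "B", "C")[p]))
  ptab <- its_phenotype_table()
  pi <- match(phen, ptab$label)
  tab <- data.frame(id = ids, PRS016 = calls$PRS016,
                    PRS049 = calls$PRS049, PRS088 = calls$PRS088,
                    ITS_MboII = ptab$MboII[pi], ITS_FokI = ptab$FokI[pi],
                    phenotype = phen, stringsAsFactors = FALSE)
  truth <- data.frame(id = ids,
                      karyotype_true = ifelse(
                        sim$spores$two_nuclei & !sim$spores$twin,
                        "heterokaryon", "homokaryon"),
                      sister = sim$spores$sister, twin = sim$spores$twin,
                      stringsAsFactors = FALSE)
  for (nm in loci$name) truth[[paste0(nm, "_true")]] <- calls[[nm]]
  structure(list(table = tab, truth = truth, parent = parent,
                 model = model, seed = seed),
            class = "ssi_dataset")
}

#' @export
print.ssi_dataset <- function(x, ...) {
  cat("Synthetic SSI dataset:", nrow(x$table), "isolates;",
      sum(x$truth$karyotype_true == "heterokaryon"),
      "true heterokaryon(s)\n")
  invisible(x)
}
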