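# In-silico PCR-RFLP (CAPS): degenerate restriction-site scanning on both
# strands, digestion with enzyme-specific cut offsets, and rendering of
# electrophoretic band patterns with co-migration and visibility rules.

#' Define a restriction enzyme
#'
#' Recognition patterns use IUPAC degeneracy codes.  Cut offsets are signed
#' base counts measured from the 3' end of the recognition site on each
#' strand: 0 cuts at the site boundary, negative values cut within the
#' site, positive values describe Type IIS enzymes reaching downstream.
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition pattern, written 5'-3'.
#' @param cut_top,cut_bottom signed offsets of the top- and bottom-strand
#'   nicks from the 3' end of the recognition site.
#' @return An object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, recognition, cut_top, cut_bottom) {
  recognition <- toupper(recognition)
  if (grepl("[^ACGTRYSWKMBDHVN]", recognition))
    stop("recognition pattern contains non-IUPAC characters")
  stopifnot(is.finite(cut_top), is.finite(cut_bottom))
  structure(list(name = name, recognition = recognition,
                 cut_top = as.integer(cut_top),
                 cut_bottom = as.integer(cut_bottom)),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("%s: %s (top %+d / bottom %+d from site 3' end)\n", x$name,
              x$recognition, x$cut_top, x$cut_bottom))
  invisible(x)
}

#' Built-in enzymes of the CAPS marker panel
#'
#' MboII and FokI are Type IIS enzymes cutting downstream of their
#' recognition site (GAAGA 8/7 and GGATG 9/13); SalI, KpnI and AvaII cleave
#' within their palindromic sites.
#'
#' @return Named list of [enzyme_spec()] objects.
#' @export
its_enzymes <- function() {
  list(
    MboII = enzyme_spec("MboII", "GAAGA", 8L, 7L),
    FokI  = enzyme_spec("FokI",  "GGATG", 9L, 13L),
    SalI  = enzyme_spec("SalI",  "GTCGAC", -5L, -1L),
    KpnI  = enzyme_spec("KpnI",  "GGTACC", -1L, -5L),
    AvaII = enzyme_spec("AvaII", "GGWCC", -4L, -1L)
  )
}

#' Find restriction sites on both strands
#'
#' Matches the degenerate recognition pattern on the top strand, and its
#' reverse complement (a bottom-strand site) reported in top-strand
#' coordinates.  Each site carries the top-strand coordinate of the
#' double-strand cut it directs (`NA` when the cut would fall outside the
#' sequence).
#'
#' @param sequence a character string or `DNAString` over the IUPAC
#'   alphabet.
#' @param enzyme an [enzyme_spec()].
#' @return Data frame with columns `start`, `end`, `strand`, `cut` (number
#'   of bases 5' of the top-strand nick).
#' @export
find_sites <- function(sequence, enzyme) {
  subject <- if (is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  L <- length(subject)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), cut = integer())
  if (L == 0) return(empty)
  pat <- Biostrings::DNAString(enzyme$recognition)
  rcpat <- Biostrings::reverseComplement(pat)
  hit_df <- function(p, strand) {
    if (length(p) > L) return(empty)
    mv <- Biostrings::matchPattern(p, subject, fixed = FALSE)
    if (length(mv) == 0) return(empty)
    s <- Biostrings::start(mv); e <- Biostrings::end(mv)
    cut <- if (strand == "+") e + enzyme$cut_top else s - 1L - enzyme$cut_bottom
    data.frame(start = s, end = e, strand = strand, cut = as.integer(cut))
  }
  out <- rbind(hit_df(pat, "+"), hit_df(rcpat, "-"))
  if (as.character(pat) == as.character(rcpat)) {
    # palindromic site: both scans return the same footprints
    out <- out[out$strand == "+", , drop = FALSE]
    out$strand <- rep("+/-", nrow(out))
  }
  out$cut[out$cut <= 0L | out$cut >= L] <- NA_integer_
  out[order(out$start), , drop = FALSE]
}

#' Digest an amplicon in silico
#'
#' Cuts the sequence at every restriction site of the given enzyme(s) and
#' returns fragment lengths.  Fragments always partition the amplicon:
#' their lengths sum to the amplicon length.  Cuts whose offset falls
#' outside the sequence are dropped with a warning.
#'
#' @param sequence amplicon sequence (character or `DNAString`).
#' @param enzymes an [enzyme_spec()] or list of them.
#' @return Integer vector of fragment lengths, sorted decreasing.
#' @export
digest_amplicon <- function(sequence, enzymes) {
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  L <- if (is(sequence, "DNAString")) length(sequence) else nchar(sequence)
  sites <- do.call(rbind, lapply(enzymes, function(e) find_sites(sequence, e)))
  cuts <- integer()
  if (!is.null(sites) && nrow(sites)) {
    if (anyNA(sites$cut))
      warning("cut offset outside sequence for ", sum(is.na(sites$cut)),
              " site(s); cut dropped")
    cuts <- sort(unique(sites$cut[!is.na(sites$cut)]))
  }
  fragments_from_cuts(L, cuts)
}

fragments_from_cuts <- function(length, cuts) {
  cuts <- sort(unique(as.integer(cuts)))
  if (any(cuts <= 0 | cuts >= length))
    stop("cut positions must lie strictly inside the amplicon")
  sort(as.integer(diff(c(0L, cuts, length))), decreasing = TRUE)
}

# ---- gel rendering --------------------------------------------------------

#' Agarose gel resolution model
#'
#' @param resolution_rel minimum relative length difference at which two
#'   fragments migrate as separate bands (default 0.05, i.e. 5%, matching a
#'   2% agarose gel).
#' @param min_visible_bp smallest fragment reliably scored (default 150).
#' @return An object of class `gel_model`.
#' @export
gel_model <- function(resolution_rel = 0.05, min_visible_bp = 150) {
  stopifnot(resolution_rel > 0, min_visible_bp > 0)
  structure(list(resolution_rel = resolution_rel,
                 min_visible_bp = min_visible_bp), class = "gel_model")
}

# Cluster fragment lengths into co-migrating gel bands (chained merging of
# sorted lengths whose relative difference is below the gel resolution).
# Returns an integer cluster id per input length (input sorted decreasing).
gel_clusters <- function(lengths, gel) {
  lengths <- sort(unique(lengths), decreasing = TRUE)
  id <- integer(length(lengths))
  cur <- 1L
  id[1] <- cur
  if (length(lengths) > 1) for (i in 2:length(lengths)) {
    a <- lengths[i - 1]; b <- lengths[i]
    if ((a - b) / mean(c(a, b)) < gel$resolution_rel) id[i] <- cur
    else { cur <- cur + 1L; id[i] <- cur }
  }
  stats::setNames(id, lengths)
}

#' Render fragments as an electrophoretic band pattern
#'
#' Duplicate lengths collapse; fragments whose relative length difference
#' is below the gel resolution merge into a single band represented by the
#' largest member; fragments below the visibility threshold are flagged.
#' When `class_patterns` supplies the fragment sets of all phenotype
#' classes of the marker, a band whose presence pattern across the classes
#' duplicates that of a larger band is additionally flagged as redundant
#' (uninformative), reproducing the convention of printing such bands in
#' parentheses.
#'
#' @param fragments numeric fragment lengths (bp), all >= 1.
#' @param gel a [gel_model()].
#' @param class_patterns optional named list of numeric fragment vectors,
#'   one per phenotype class of the marker, defining band informativeness.
#' @return Object of class `band_pattern`: list with `fragments` (sorted
#'   decreasing), `bands` (data frame with `length`, `band_rep`,
#'   `co_migrating`, `below_visibility`, `redundant`, `visible`) and
#'   `visible_bands`.
#' @export
render_pattern <- function(fragments, gel = gel_model(),
                           class_patterns = NULL) {
  fragments <- as.numeric(fragments)
  if (length(fragments) == 0)
    return(structure(list(fragments = numeric(), bands = NULL,
                          visible_bands = numeric()),
                     class = "band_pattern"))
  if (any(fragments < 1)) stop("fragments must be >= 1 bp")
  lens <- sort(unique(fragments), decreasing = TRUE)

  # cluster on the universe of lengths so band identity is stable across
  # the marker's phenotype classes
  universe <- sort(unique(c(lens, unlist(class_patterns))), decreasing = TRUE)
  uclus <- gel_clusters(universe, gel)
  clus <- uclus[as.character(lens)]
  reps <- tapply(universe, uclus, max)
  # a band is represented by its largest co-migrating member *present here*
  rep_here <- tapply(lens, clus, max)
  band_rep <- as.numeric(rep_here[as.character(clus)])

  redundant_band <- rep(FALSE, length(lens))
  if (!is.null(class_patterns) && length(class_patterns) > 1) {
    pres <- vapply(class_patterns, function(fr)
      as.integer(unique(uclus) %in% uclus[as.character(sort(unique(fr),
                                                            decreasing = TRUE))]),
      integer(length(unique(uclus))))
    rownames(pres) <- as.character(unique(uclus))
    key <- apply(pres, 1, paste, collapse = "")
    for (k in unique(key)) {
      grp <- as.integer(names(key)[key == k])
      if (length(grp) > 1) {
        # the band with the largest representative stays informative
        losing <- grp[-which.max(reps[as.character(grp)])]
        redundant_band[clus %in% losing] <- TRUE
      }
    }
  }

  co_mig <- lens != band_rep
  below <- lens < gel$min_visible_bp
  visible <- !co_mig & !below & !redundant_band
  bands <- data.frame(length = lens, band_rep = band_rep,
                      co_migrating = co_mig, below_visibility = below,
                      redundant = redundant_band, visible = visible)
  structure(list(fragments = sort(fragments, decreasing = TRUE),
                 bands = bands,
                 visible_bands = lens[visible]),
            class = "band_pattern")
}

#' Format a band pattern as in a genotyping table
#'
#' Visible bands are listed largest first; merged, sub-visible and
#' redundant bands follow in parentheses.  A parenthesised group opens
#' without `+` when its first member co-migrates with (differs by at most
#' 2 bp from) the last visible band, indicating that the visible band is a
#' superposition, e.g. `563 (562+209)`.
#'
#' @param x a `band_pattern`.
#' @param ... unused.
#' @return Character scalar such as `"396+264 (+395+377+112)"`.
#' @export
format.band_pattern <- function(x, ...) {
  if (length(x$fragments) == 0) return("")
  vis <- x$visible_bands
  par <- x$bands$length[!x$bands$visible]
  out <- paste(vis, collapse = "+")
  if (length(par)) {
    par <- sort(par, decreasing = TRUE)
    first_rep <- x$bands$band_rep[match(par[1], x$bands$length)]
    last_vis <- if (length(vis)) vis[length(vis)] else NA
    fused <- !is.na(last_vis) && first_rep == last_vis &&
      (last_vis - par[1]) <= 2
    out <- paste0(out, " (", if (!fused) "+", paste(par, collapse = "+"), ")")
  }
  out
}

#' @export
print.band_pattern <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- CAPS markers ---------------------------------------------------------

#' The CAPS marker panel of the CA487 segregation study
#'
#' Three single-copy codominant markers (PRS016/SalI on a distal position
#' of one chromosome, PRS049/KpnI distal on another, PRS088/AvaII tightly
#' linked to a centromere and the *MAT* locus) plus the two-enzyme ITS
#' marker (MboII and FokI digests of the ITS1-5.8S-ITS2 amplicon, whose
#' band patterns read out which of the three ITS types A/B/C are present).
#'
#' Alleles are specified by amplicon length and cut coordinates, calibrated
#' to the published fragment sizes; [synthetic_its_amplicons()] provides a
#' sequence-level counterpart for the ITS marker.
#'
#' @return Named list of `caps_marker` objects.
#' @export
caps_markers <- function() {
  enz <- its_enzymes()
  mk <- function(locus, enzyme, length, alleles) {
    structure(list(locus = locus, enzyme = enzyme, length = length,
                   alleles = alleles), class = "caps_marker")
  }
  list(
    PRS016 = mk("PRS016", enz$SalI, 700L,
                list(`1` = list(length = 700L, cuts = c(481L)),
                     `2` = list(length = 700L, cuts = c(271L, 481L)))),
    PRS049 = mk("PRS049", enz$KpnI, 479L,
                list(`1` = list(length = 479L, cuts = integer()),
                     `2` = list(length = 479L, cuts = c(292L)))),
    PRS088 = mk("PRS088", enz$AvaII, 757L,
                list(`1` = list(length = 757L, cuts = integer()),
                     `2` = list(length = 757L, cuts = c(449L)))),
    ITS = structure(list(
      locus = "ITS", enzyme = list(MboII = enz$MboII, FokI = enz$FokI),
      alleles = list(
        A = list(length = 773L, cuts = list(MboII = c(396L),
                                            FokI = integer())),
        B = list(length = 772L, cuts = list(MboII = integer(),
                                            FokI = c(209L))),
        C = list(length = 771L, cuts = list(MboII = c(395L, 659L),
                                            FokI = c(209L))))),
      class = "caps_marker")
  )
}

marker_allele_fragments <- function(marker, allele, enzyme_name = NULL) {
  al <- marker$alleles[[as.character(allele)]]
  if (is.null(al)) stop("unknown allele '", allele, "' for marker ",
                        marker$locus)
  cuts <- if (is.null(enzyme_name)) al$cuts else al$cuts[[enzyme_name]]
  fragments_from_cuts(al$length, cuts)
}

#' Band phenotype of a marker genotype
#'
#' The phenotype of a one- or two-allele genotype is the union of the
#' per-allele digests, rendered on the gel.  Heteroallelic genotypes show
#' the bands of both alleles.
#'
#' @param marker a `caps_marker` from [caps_markers()].
#' @param genotype allele(s), e.g. `"1"`, `"1/2"` or `c("1", "2")`.
#' @param gel a [gel_model()].
#' @return A `band_pattern` (or a named list of them for multi-enzyme
#'   markers such as the ITS marker).
#' @export
genotype_to_phenotype <- function(marker, genotype, gel = gel_model()) {
  alleles <- if (length(genotype) == 1)
    strsplit(as.character(genotype), "/", fixed = TRUE)[[1]] else
      as.character(genotype)
  alleles <- unique(alleles)   # "1/1" is gel-identical to "1"
  enz_names <- if (inherits(marker$enzyme, "enzyme_spec")) list(NULL) else
    as.list(names(marker$enzyme))
  allele_space <- names(marker$alleles)
  genos <- c(as.list(allele_space),
             utils::combn(allele_space, 2, simplify = FALSE))
  out <- lapply(enz_names, function(en) {
    frs <- unlist(lapply(alleles, marker_allele_fragments, marker = marker,
                         enzyme_name = en))
    cls <- lapply(genos, function(g)
      unlist(lapply(g, marker_allele_fragments, marker = marker,
                    enzyme_name = en)))
    names(cls) <- vapply(genos, paste, "", collapse = "/")
    render_pattern(frs, gel, class_patterns = cls)
  })
  if (length(out) == 1 && is.null(enz_names[[1]])) out[[1]] else
    stats::setNames(out, unlist(enz_names))
}

# Labels of the seven ITS phenotype classes, in canonical order.
ITS_CLASS_LABELS <- c("[A]", "[B]", "[C]", "[A+B]", "[A+C]", "[B+C]",
                      "[A+B+C]")

its_class_label <- function(types) {
  types <- sort(match(types, c("A", "B", "C")))
  paste0("[", paste(c("A", "B", "C")[types], collapse = "+"), "]")
}

its_types_of_label <- function(label) {
  strsplit(gsub("\\[|\\]", "", label), "+", fixed = TRUE)[[1]]
}

#' Band phenotype of an ITS type combination
#'
#' Maps a subset of the ITS types A/B/C present in a mycelium to its
#' phenotype class label and to the MboII and FokI band patterns.  The
#' MboII digest alone confounds `[C]` with `[A+C]` and `[B+C]` with
#' `[A+B+C]`; together the two enzymes separate all seven classes.
#'
#' @param types non-empty subset of `c("A", "B", "C")`.
#' @param gel a [gel_model()].
#' @return Object of class `its_phenotype`: list with `label`, `types` and
#'   `patterns` (band patterns for MboII and FokI).
#' @export
its_phenotype <- function(types, gel = gel_model()) {
  types <- unique(toupper(types))
  if (length(types) == 0 || !all(types %in% c("A", "B", "C")))
    stop("`types` must be a non-empty subset of A, B, C")
  marker <- caps_markers()$ITS
  classes <- lapply(seq_len(7), function(i)
    its_types_of_label(ITS_CLASS_LABELS[i]))
  pats <- lapply(names(marker$enzyme), function(en) {
    cls <- lapply(classes, function(tt)
      unlist(lapply(tt, marker_allele_fragments, marker = marker,
                    enzyme_name = en)))
    names(cls) <- ITS_CLASS_LABELS
    render_pattern(unlist(lapply(types, marker_allele_fragments,
                                 marker = marker, enzyme_name = en)),
                   gel, class_patterns = cls)
  })
  names(pats) <- names(marker$enzyme)
  structure(list(label = its_class_label(types), types = sort(types),
                 patterns = pats),
            class = "its_phenotype")
}

#' @export
print.its_phenotype <- function(x, ...) {
  cat(x$label, " MboII: ", format(x$patterns$MboII),
      "  FokI: ", format(x$patterns$FokI), "\n", sep = "")
  invisible(x)
}

#' Recover the ITS phenotype class from band strings
#'
#' Inverse lookup of [its_phenotype()]: matches formatted MboII and FokI
#' band strings (or visible-band strings) against the seven classes.
#'
#' @param mboii,foki band strings as produced by `format()` on the
#'   corresponding band patterns (parenthesised groups may be omitted).
#' @return The matching class label, or `NA` if none matches.
#' @export
phenotype_from_bands <- function(mboii, foki) {
  tabs <- its_phenotype_table()
  vis <- function(s) sub(" *\\(.*\\)$", "", s)
  hit <- tabs$label[(tabs$MboII == mboii | vis(tabs$MboII) == vis(mboii)) &
                      (tabs$FokI == foki | vis(tabs$FokI) == vis(foki))]
  if (length(hit) == 1) hit else NA_character_
}

# Cached table of the 7 class labels and their formatted band strings.
its_phenotype_table <- function() {
  cache <- get0(".its_phenotype_table", envir = .pkg_cache)
  if (!is.null(cache)) return(cache)
  rows <- lapply(ITS_CLASS_LABELS, function(lb) {
    ph <- its_phenotype(its_types_of_label(lb))
    data.frame(label = lb, MboII = format(ph$patterns$MboII),
               FokI = format(ph$patterns$FokI))
  })
  out <- do.call(rbind, rows)
  assign(".its_phenotype_table", out, envir = .pkg_cache)
  out
}

# ---- synthetic sequence-level ITS amplicons -------------------------------

#' Synthetic ITS amplicon sequences for the three types
#'
#' Sequence-level counterparts of the coordinate-specified ITS marker
#' alleles: three synthetic amplicons of 773, 772 and 771 bp whose MboII
#' and FokI digests reproduce the published fragment sizes.  The invariant
#' backbone is an arbitrary A/C-only background (which cannot contain any
#' recognition site of the panel), into which the diagnostic restriction
#' site contexts are planted: the MboII site created by the A/G
#' polymorphism at alignment position 334, the bottom-strand MboII site
#' created by the A/C polymorphism at 466, and the FokI site created by
#' the 145-146 polymorphism.  These are synthetic stand-ins for the
#' deposited clone sequences, built for testing the sequence-scanning
#' path.
#'
#' @return Named character vector of three amplicon sequences (A, B, C).
#' @export
synthetic_its_amplicons <- function() {
  cache <- get0(".its_amplicons_cache", envir = .pkg_cache)
  if (!is.null(cache)) return(cache)
  backbone <- function(n) paste(with_seed(8031,
    sample(c("A", "C"), n, replace = TRUE)), collapse = "")
  plant <- function(seq, at, what) {
    paste0(substring(seq, 1, at - 1), what,
           substring(seq, at + nchar(what), nchar(seq)))
  }
  # context strings follow the published site neighbourhoods; the
  # polymorphic base is the 9th character of each 13-mer
  ctx_mbo_site  <- "CGATGAAGAACGC"   # GAAGA: site present
  ctx_mbo_none  <- "CGATGAAGGACGC"   # GAAGG: site absent
  ctx_rev_site  <- "ACTCTCTTCTACT"   # TCTTC: bottom-strand GAAGA
  ctx_rev_none  <- "ACTCTCTTATACT"
  ctx_fok_site  <- "TGCTGGATGTGAG"   # GGATG: FokI site
  ctx_fok_none  <- "TGCTGGGAGTGAG"
  a <- backbone(773)
  a <- plant(a, 192, ctx_fok_none)
  a <- plant(a, 380, ctx_mbo_site)   # GAAGA at 384 -> cut after 396
  a <- plant(a, 668, ctx_rev_none)
  b <- backbone(772)
  b <- plant(b, 192, ctx_fok_site)   # GGATG at 196 -> cut after 209
  b <- plant(b, 379, ctx_mbo_none)
  b <- plant(b, 667, ctx_rev_none)
  cc <- backbone(771)
  cc <- plant(cc, 192, ctx_fok_site)
  cc <- plant(cc, 379, ctx_mbo_site) # GAAGA at 383 -> cut after 395
  cc <- plant(cc, 663, ctx_rev_site) # TCTTC at 667 -> cut after 659
  out <- c(A = a, B = b, C = cc)
  assign(".its_amplicons_cache", out, envir = .pkg_cache)
  out
}
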