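# Model of a Sanger chromatogram produced by co-amplified haplotypes.
#
# When several ITS paralogs/alleles of unequal length are sequenced
# together, each indel shifts the downstream peaks of the shorter
# sequence(s) relative to the others.  A substitution can then become
# invisible ("masked") when the shifted peak lands on a position where the
# other sequences already show the same base - on both strands.  This is a
# model of peak superposition, not a base caller.

#' Superpose haplotypes into a mixed-trace profile
#'
#' Converts each haplotype to its own ungapped coordinates and reports, for
#' every trace position, the multiset of bases contributed by the
#' superposed sequences (sequences downstream of a deletion contribute
#' shifted bases).  Every polymorphic alignment column is scored as
#' detectable or masked: a substitution is masked when homogenising it to
#' the consensus state leaves the observed base sets unchanged at every
#' affected trace position, on the forward and on the reverse-complement
#' read.  Columns with a length polymorphism (gap in some haplotype) are
#' always scored detectable, since the frame shift itself is visible
#' downstream.
#'
#' @param haplotypes an `its_haplotype_set` with full aligned sequences, or
#'   a named character vector of aligned sequences (gaps as `-`).
#' @return An object of class `trace_profile`: list with `positions` (trace
#'   length), `profile` (list of per-position contributed bases, named by
#'   haplotype), `shifts` (haplotype x alignment-column matrix of cumulative
#'   indel offsets) and `sites` (data frame scoring each polymorphic
#'   column).
#' @export
superpose_traces <- function(haplotypes) {
  if (inherits(haplotypes, "its_haplotype_set") || is.list(haplotypes)) {
    seqs <- vapply(haplotypes, function(h)
      if (is.list(h)) h$sequence else h, character(1))
    names(seqs) <- vapply(haplotypes, function(h)
      if (is.list(h)) h$name else "", character(1))
  } else seqs <- haplotypes
  if (length(seqs) == 0)
    return(structure(list(positions = 0L, profile = list(),
                          shifts = NULL, sites = NULL),
                     class = "trace_profile"))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("hap", seq_along(seqs))
  seqs <- toupper(norm_gap(seqs))
  if (length(unique(nchar(seqs))) > 1)
    stop("aligned sequences differ in length")

  aln <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(aln) <- names(seqs)
  ncol_aln <- ncol(aln)
  gap <- aln == "-"
  # cumulative indel offset of each haplotype at each aligned column
  shifts <- t(apply(gap, 1, cumsum))
  upos <- matrix(rep(seq_len(ncol_aln), each = nrow(aln)), nrow(aln)) - shifts
  upos[gap] <- NA_integer_

  ungapped <- lapply(rownames(aln), function(h) aln[h, !gap[h, ]])
  names(ungapped) <- rownames(aln)
  lens <- vapply(ungapped, length, integer(1))
  tracelen <- max(lens)
  profile <- lapply(seq_len(tracelen), function(t) {
    contrib <- vapply(ungapped[lens >= t], `[`, "", t)
    contrib
  })

  poly <- which(apply(aln, 2, function(s) length(unique(s)) > 1))
  sites <- NULL
  if (length(poly)) {
    fwd <- ungapped
    rev <- lapply(ungapped, function(s) rev(complement_chars(s)))
    score <- lapply(poly, function(cc) {
      states <- aln[, cc]
      if (any(states == "-"))
        return(data.frame(column = cc, states = paste(states, collapse = "/"),
                          masked_forward = NA, masked_reverse = NA,
                          detectable = TRUE))
      mf <- .masked_one_strand(fwd, upos[, cc], states)
      mr <- .masked_one_strand(rev, lens - upos[, cc] + 1,
                               complement_chars(states))
      data.frame(column = cc, states = paste(states, collapse = "/"),
                 masked_forward = mf, masked_reverse = mr,
                 detectable = !(mf && mr))
    })
    sites <- do.call(rbind, score)
    sites$masked <- !sites$detectable
  }
  structure(list(positions = tracelen, profile = profile, shifts = shifts,
                 sites = sites),
            class = "trace_profile")
}

# Is the variation at one aligned column invisible on one strand?
# `seqs`: per-haplotype ungapped base vectors for that strand;
# `pos`: the trace position at which each haplotype's base for the column
# lands; `states`: the aligned states.  Peak presence is compared as a set:
# chromatogram peak heights are not quantitatively reliable, so a base is
# either seen or not seen at a position.
.masked_one_strand <- function(seqs, pos, states) {
  lens <- vapply(seqs, length, integer(1))
  tab <- table(states)
  consensus <- names(tab)[which.max(tab)]
  affected <- which(states != consensus)
  for (i in affected) {
    t <- pos[i]
    here <- which(lens >= t)
    obs <- unique(vapply(seqs[here], `[`, "", t))
    cf <- vapply(seqs[here], `[`, "", t)
    # homogenise: every haplotype whose column-state differs from consensus
    # and whose base lands at this very position is replaced
    for (j in affected) if (!is.na(pos[j]) && pos[j] == t &&
                            names(seqs)[j] %in% names(cf))
      cf[names(seqs)[j]] <- consensus
    if (!setequal(obs, unique(cf))) return(FALSE)
  }
  TRUE
}

#' @export
print.trace_profile <- function(x, ...) {
  nseq <- if (x$positions > 0) length(x$profile[[1]]) else 0
  cat("Superposed trace over", x$positions, "positions,",
      nseq, "contributing sequence(s)\n")
  if (!is.null(x$sites)) {
    nm <- sum(x$sites$masked)
    cat(nrow(x$sites), "polymorphic column(s);", nm, "masked\n")
    if (nm) print(x$sites[x$sites$masked, c("column", "states")])
  }
  invisible(x)
}
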