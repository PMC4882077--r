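# Synthetic clone libraries: PCR + cloning of a mixed ITS template pool,
# with tunable substitution noise and PCR-mediated template switching
# (chimeras), emitting aligned sequences over the shared 662-column
# coordinate system.

#' Clone-library noise model
#'
#' Defaults emulate the sequencing of 284 clones from a three-type
#' heterokaryon with equal ribosomal copy numbers: equal template weights
#' (1:1:1 expected type ratio), a per-site substitution probability of
#' 7.5e-4 per clone and a 5% chimera probability, which together leave
#' roughly 58% of clones as exact type matches (the remainder being
#' single/double-substitution variants or chimeras).
#'
#' @param n_clones number of clones to draw.
#' @param weights per-type template weights (normalised internally);
#'   proportional to ribosomal copy number of each type.
#' @param substitution_rate per-site, per-clone substitution probability.
#' @param chimera_rate per-clone probability of a single-breakpoint
#'   template switch between two distinct types.
#' @return Object of class `clone_library_model`.
#' @export
clone_library_model <- function(n_clones = 284L,
                                weights = c(A = 1, B = 1, C = 1),
                                substitution_rate = 7.5e-4,
                                chimera_rate = 0.05) {
  stopifnot(n_clones >= 0, all(weights >= 0), sum(weights) > 0,
            substitution_rate >= 0, substitution_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1)
  structure(list(n_clones = as.integer(n_clones),
                 weights = weights / sum(weights),
                 substitution_rate = substitution_rate,
                 chimera_rate = chimera_rate),
            class = "clone_library_model")
}

#' Generate a synthetic ITS clone library
#'
#' Each clone samples a template type with probability proportional to the
#' copy-number weights; with probability `chimera_rate` the clone is
#' instead a single-breakpoint splice of two distinct templates (breakpoint
#' uniform over the alignment interior).  Substitutions then hit each
#' non-gap column independently.  Output is aligned FASTA-style sequences
#' on the haplotype coordinate system, plus a truth table.
#'
#' @param model a [clone_library_model()].
#' @param haplotypes an `its_haplotype_set` with full aligned sequences.
#' @param seed optional RNG seed.
#' @return Object of class `clone_library`: list with `sequences` (named
#'   character vector of aligned sequences), `truth` (data frame: `id`,
#'   `class` = `template`/`chimera`, `template`, `donor2`, `breakpoint`,
#'   `n_substitutions`) and `model`.
#' @export
generate_clone_library <- function(model = clone_library_model(),
                                   haplotypes = its_haplotypes(),
                                   seed = NULL) {
  seqs <- vapply(haplotypes, `[[`, "", "sequence")
  if (any(!nzchar(seqs))) stop("haplotypes need full aligned sequences")
  types <- names(seqs)
  alen <- unique(nchar(seqs))
  stopifnot(length(alen) == 1)
  n <- model$n_clones
  with_seed(seed, {
    w <- model$weights[types]
    if (anyNA(w)) stop("model weights must be named by haplotype")
    is_chim <- runif(n) < model$chimera_rate
    tpl <- sample(types, n, replace = TRUE, prob = w)
    donor2 <- rep(NA_character_, n)
    brk <- rep(NA_integer_, n)
    out <- unname(seqs[tpl])
    for (i in which(is_chim)) {
      pair <- sample(types, 2)
      tpl[i] <- pair[1]; donor2[i] <- pair[2]
      brk[i] <- sample(2:(alen - 1), 1)
      out[i] <- paste0(substring(seqs[pair[1]], 1, brk[i]),
                       substring(seqs[pair[2]], brk[i] + 1, alen))
    }
    # substitution noise at non-gap columns
    nsub <- integer(n)
    if (model$substitution_rate > 0) {
      chars <- c("A", "C", "G", "T")
      for (i in seq_len(n)) {
        s <- strsplit(out[i], "", fixed = TRUE)[[1]]
        hit <- which(runif(alen) < model$substitution_rate & s != "-")
        if (length(hit)) {
          s[hit] <- vapply(s[hit], function(b)
            sample(setdiff(chars, b), 1), "")
          out[i] <- paste(s, collapse = "")
          nsub[i] <- length(hit)
        }
      }
    }
    ids <- sprintf("clone%04d", seq_len(n))
    names(out) <- ids
    truth <- data.frame(id = ids,
                        class = ifelse(is_chim, "chimera", "template"),
                        template = tpl, donor2 = donor2, breakpoint = brk,
                        n_substitutions = nsub, stringsAsFactors = FALSE)
    structure(list(sequences = out, truth = truth, model = model),
              class = "clone_library")
  })
}

#' @export
print.clone_library <- function(x, ...) {
  cat("Synthetic clone library:", length(x$sequences), "clones (",
      sum(x$truth$class == "chimera"), "chimeric )\n")
  invisible(x)
}
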