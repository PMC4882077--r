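# ITS haplotypes over a shared clone alignment, clone typing, and the
# site-level statistics used to describe intragenomic ITS variation.

# Alignment columns (1-based) at which the three intragenomic ITS sequence
# types of the CA487 heterokaryon differ, and their states.  A dash is an
# absent nucleotide and is treated as a coded fifth character throughout.
ITS_POLY_COLUMNS <- c(39L, 114L, 122L, 130L, 145L, 146L, 200L, 269L, 334L,
                      466L, 475L, 559L, 649L)

ITS_TYPE_STATES <- rbind(
  A = c("T", "A", "A", "A", "G", "A", "T", "G", "A", "A", "T", "G", "T"),
  B = c("-", "G", "G", "G", "A", "T", "C", "G", "G", "A", "T", "A", "A"),
  C = c("-", "A", "G", "G", "A", "T", "C", "A", "A", "C", "-", "G", "T")
)
colnames(ITS_TYPE_STATES) <- as.character(ITS_POLY_COLUMNS)

ITS_ALIGNMENT_LENGTH <- 662L

#' Region annotation for the ITS clone alignment
#'
#' Half-open column ranges labelling ITS1, 5.8S and ITS2 on the shared clone
#' alignment.  The exact boundaries of the three regions on this alignment
#' are configurable; the defaults place the eight 5' polymorphic columns in
#' ITS1, column 334 in 5.8S and the four 3' polymorphic columns in ITS2.
#'
#' @param its1,s58,its2 integer vectors of length 2, half-open `[from, to)`
#'   column ranges for ITS1, 5.8S and ITS2.
#' @param length total number of alignment columns.
#' @return A data frame with columns `region`, `from`, `to`.
#' @export
alignment_regions <- function(its1 = c(1L, 300L), s58 = c(300L, 460L),
                              its2 = c(460L, 663L),
                              length = ITS_ALIGNMENT_LENGTH) {
  reg <- data.frame(region = c("ITS1", "5.8S", "ITS2"),
                    from = c(its1[1], s58[1], its2[1]),
                    to = c(its1[2], s58[2], its2[2]))
  if (any(reg$from >= reg$to)) stop("region ranges must be non-empty")
  if (any(reg$from[-1] < reg$to[-nrow(reg)]))
    stop("region ranges must be disjoint and ordered")
  attr(reg, "alignment_length") <- as.integer(length)
  reg
}

region_of <- function(columns, regions) {
  out <- rep(NA_character_, length(columns))
  for (i in seq_len(nrow(regions))) {
    hit <- columns >= regions$from[i] & columns < regions$to[i]
    out[hit] <- regions$region[i]
  }
  out
}

#' Construct an ITS haplotype
#'
#' A haplotype is defined by its states (base or gap) at a set of alignment
#' columns, optionally together with a full aligned sequence.
#'
#' @param name haplotype label, e.g. `"A"`.
#' @param states named character vector; names are 1-based alignment columns,
#'   values are states in `A`, `C`, `G`, `T` or `-`.
#' @param sequence optional full aligned sequence (a single string, gaps as
#'   `-`), consistent with `states`.
#' @return An object of class `its_haplotype`.
#' @export
its_haplotype <- function(name, states, sequence = NULL) {
  states <- toupper(norm_gap(states))
  if (is.null(names(states)) || anyNA(suppressWarnings(as.integer(names(states)))))
    stop("`states` must be named by integer alignment columns")
  bad <- !states %in% c("A", "C", "G", "T", "-")
  if (any(bad)) stop("invalid state(s): ", paste(unique(states[bad]), collapse = ", "))
  if (!is.null(sequence)) {
    sequence <- toupper(norm_gap(sequence))
    cols <- as.integer(names(states))
    got <- substring(sequence, cols, cols)
    if (!all(got == states))
      stop("`sequence` disagrees with `states` for haplotype ", name)
  }
  structure(list(name = name, states = states, sequence = sequence),
            class = "its_haplotype")
}

#' @export
print.its_haplotype <- function(x, ...) {
  cat("ITS haplotype", x$name, "-", length(x$states), "defined column(s)\n")
  print(x$states)
  invisible(x)
}

#' Built-in ITS haplotypes of the CA487 heterokaryon
#'
#' The three intragenomic ITS sequence types (A, B, C) segregating in the
#' wild *Agaricus subrufescens* heterokaryon CA487, defined by their states
#' at the 13 polymorphic columns of the 662-column clone alignment.  Types A
#' and B are alleles at the ribosomal locus *ITSI*; type C is carried by a
#' second, unlinked locus *ITSII* that segregates against a null allele.
#'
#' The full-length aligned sequences attached to each haplotype are
#' synthetic: the published record gives the states at the polymorphic
#' columns but not the complete clone alignment, so the invariant columns
#' are filled with a fixed arbitrary background.  The background places a
#' `G` in the columns flanking position 334 so that the superposed-trace
#' model reproduces the masking of the type-B `G` peak by its neighbours.
#'
#' @param include_sequences attach full synthetic aligned sequences
#'   (default `TRUE`).
#' @param regions region annotation, see [alignment_regions()].
#' @return An object of class `its_haplotype_set`: a list of
#'   [its_haplotype()] objects with attributes `alignment_length` and
#'   `regions`.
#' @export
its_haplotypes <- function(include_sequences = TRUE,
                           regions = alignment_regions()) {
  seqs <- if (include_sequences) synthetic_its_alignment() else
    stats::setNames(vector("list", 3), rownames(ITS_TYPE_STATES))
  haps <- lapply(rownames(ITS_TYPE_STATES), function(nm) {
    its_haplotype(nm, stats::setNames(ITS_TYPE_STATES[nm, ],
                                      colnames(ITS_TYPE_STATES)),
                  sequence = seqs[[nm]])
  })
  names(haps) <- rownames(ITS_TYPE_STATES)
  structure(haps, class = "its_haplotype_set",
            alignment_length = ITS_ALIGNMENT_LENGTH, regions = regions)
}

#' @export
print.its_haplotype_set <- function(x, ...) {
  cat("Set of", length(x), "ITS haplotypes over a",
      attr(x, "alignment_length"), "column alignment:",
      paste(vapply(x, `[[`, "", "name"), collapse = ", "), "\n")
  invisible(x)
}

# Synthetic 662-column aligned template for the three built-in types.
# Deterministic; cached in the package namespace after first use.
synthetic_its_alignment <- function() {
  cache <- get0(".its_alignment_cache", envir = .pkg_cache)
  if (!is.null(cache)) return(cache)
  template <- with_seed(19203, sample(c("A", "C", "G", "T"),
                                      ITS_ALIGNMENT_LENGTH, replace = TRUE))
  # flanking G peaks around the 5.8S polymorphic column 334 (the masking
  # geometry of the mixed chromatogram) and a neutral state at 334 itself
  template[333] <- "G"
  template[335] <- "G"
  # keep immediate neighbours of the other polymorphic columns distinct from
  # every variant state there, so that only column 334 can be masked
  for (j in seq_along(ITS_POLY_COLUMNS)) {
    col <- ITS_POLY_COLUMNS[j]
    if (col == 334L) next
    states <- unique(ITS_TYPE_STATES[, j])
    avoid <- unique(c(states, complement_chars(states)))
    pick <- setdiff(c("A", "C", "G", "T"), avoid)[1]
    if (!is.na(pick)) {
      for (nb in c(col - 1L, col + 1L)) {
        if (nb >= 1 && nb <= ITS_ALIGNMENT_LENGTH &&
            !nb %in% c(ITS_POLY_COLUMNS, 333L, 335L))
          template[nb] <- pick
      }
    }
  }
  out <- lapply(rownames(ITS_TYPE_STATES), function(nm) {
    s <- template
    s[ITS_POLY_COLUMNS] <- ITS_TYPE_STATES[nm, ]
    paste(s, collapse = "")
  })
  names(out) <- rownames(ITS_TYPE_STATES)
  assign(".its_alignment_cache", out, envir = .pkg_cache)
  out
}

.pkg_cache <- new.env(parent = emptyenv())

# ---- polymorphic and diagnostic sites ------------------------------------

hap_state_matrix <- function(haplotypes) {
  cols <- sort(unique(unlist(lapply(haplotypes, function(h)
    as.integer(names(h$states))))))
  lens <- unique(unlist(lapply(haplotypes, function(h) {
    if (is.null(h$sequence)) NULL else nchar(h$sequence)
  })))
  if (length(lens) > 1)
    stop("haplotypes are defined over different alignment lengths (",
         paste(lens, collapse = ", "), "); shared coordinates required")
  m <- do.call(rbind, lapply(haplotypes, function(h) {
    st <- h$states[as.character(cols)]
    if (anyNA(st) && !is.null(h$sequence))
      st[is.na(st)] <- substring(h$sequence, cols[is.na(st)], cols[is.na(st)])
    if (anyNA(st))
      stop("haplotype ", h$name, " has no state at column(s) ",
           paste(cols[is.na(st)], collapse = ", "))
    unname(st)
  }))
  rownames(m) <- vapply(haplotypes, `[[`, "", "name")
  colnames(m) <- as.character(cols)
  m
}

#' Polymorphic sites among a set of haplotypes
#'
#' Returns every alignment column at which at least two haplotypes differ.
#' A gap counts as a state.  For the three built-in CA487 types this yields
#' the 13 published polymorphic positions.
#'
#' @param haplotypes an `its_haplotype_set` or list of [its_haplotype()]
#'   objects sharing one alignment coordinate system.
#' @param regions region annotation used to label each site;
#'   defaults to the annotation attached to `haplotypes`, if any.
#' @return A data frame with one row per polymorphic site: `column`,
#'   `region`, and one state column per haplotype.
#' @export
find_polymorphic_sites <- function(haplotypes, regions = NULL) {
  if (length(haplotypes) < 2)
    stop("need at least two haplotypes")
  regions <- regions %||% attr(haplotypes, "regions") %||% alignment_regions()
  m <- hap_state_matrix(haplotypes)
  poly <- apply(m, 2, function(s) length(unique(s)) > 1)
  cols <- as.integer(colnames(m)[poly])
  out <- data.frame(column = cols, region = region_of(cols, regions))
  st <- t(m[, poly, drop = FALSE])
  colnames(st) <- paste0("state_", rownames(m))
  cbind(out, as.data.frame(st, row.names = seq_along(cols)))
}

#' Sites diagnostic for one haplotype
#'
#' Columns at which the focal haplotype's state differs from all other
#' haplotypes while the others agree among themselves.  With the built-in
#' types this reproduces the published type-specific characters: six for
#' type A, four for type B and three for type C.
#'
#' @inheritParams find_polymorphic_sites
#' @param focal name of the focal haplotype.
#' @return Integer vector of alignment columns.
#' @export
type_specific_sites <- function(haplotypes, focal) {
  if (length(haplotypes) < 3)
    stop("type specificity is undefined for fewer than 3 haplotypes")
  m <- hap_state_matrix(haplotypes)
  if (!focal %in% rownames(m)) stop("unknown focal haplotype: ", focal)
  others <- m[setdiff(rownames(m), focal), , drop = FALSE]
  spec <- vapply(seq_len(ncol(m)), function(j) {
    length(unique(others[, j])) == 1 && m[focal, j] != others[1, j]
  }, logical(1))
  as.integer(colnames(m)[spec])
}

# ---- clone classification -------------------------------------------------

#' Classify one cloned ITS sequence against the haplotype types
#'
#' A clone that matches one type at every polymorphic column and everywhere
#' else is `type-exact`; with up to `max_variant_sites` substitutions at
#' non-diagnostic columns it is a `type-variant`; a clone whose diagnostic
#' columns split into two contiguous blocks donated by two types is a
#' `chimera` (PCR recombinant) with an inferred breakpoint interval;
#' anything else is `unassigned`.
#'
#' @param sequence aligned clone sequence (single string, same coordinate
#'   system as the haplotypes, gaps as `-`).
#' @param haplotypes an `its_haplotype_set` with full sequences.
#' @param max_variant_sites maximum number of off-type substitutions at
#'   non-diagnostic columns tolerated for a `type-variant` call (default 2).
#' @param id clone identifier carried through to the result.
#' @return A list of class `clone_record` with elements `id`, `assignment`
#'   (`type-exact`, `type-variant`, `chimera` or `unassigned`),
#'   `assigned_type`, `variant_positions` and `breakpoint` (a length-2
#'   column interval for chimeras, otherwise `NULL`).
#' @export
classify_clone <- function(sequence, haplotypes = its_haplotypes(),
                           max_variant_sites = 2, id = "clone") {
  res <- classify_clones(stats::setNames(sequence, id), haplotypes,
                         max_variant_sites)
  rec <- as.list(res[1, c("id", "assignment", "assigned_type")])
  rec$variant_positions <- res$variant_positions[[1]]
  rec$breakpoint <- res$breakpoint[[1]]
  structure(rec, class = "clone_record")
}

#' @export
print.clone_record <- function(x, ...) {
  cat("Clone", x$id, "->", x$assignment,
      if (!is.na(x$assigned_type)) paste0("(", x$assigned_type, ")"), "\n")
  if (length(x$variant_positions))
    cat("  variant columns:", paste(x$variant_positions, collapse = ", "), "\n")
  if (length(x$breakpoint))
    cat("  breakpoint interval: (", x$breakpoint[1], ",", x$breakpoint[2], ")\n")
  invisible(x)
}

#' Classify a library of cloned ITS sequences
#'
#' Vectorised form of [classify_clone()].
#'
#' @param sequences named character vector of aligned clone sequences, or a
#'   `clone_library` object from [generate_clone_library()].
#' @inheritParams classify_clone
#' @return A data frame with one row per clone: `id`, `assignment`,
#'   `assigned_type`, plus list columns `variant_positions` and
#'   `breakpoint`.
#' @export
classify_clones <- function(sequences, haplotypes = its_haplotypes(),
                            max_variant_sites = 2) {
  if (inherits(sequences, "clone_library")) sequences <- sequences$sequences
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("clone%04d", seq_along(sequences))
  sequences <- toupper(norm_gap(sequences))
  m <- hap_state_matrix(haplotypes)
  cols <- as.integer(colnames(m))
  types <- rownames(m)
  hseq <- lapply(haplotypes, `[[`, "sequence")
  if (any(vapply(hseq, is.null, logical(1))))
    stop("haplotypes need full sequences for clone classification")
  alen <- nchar(hseq[[1]])

  short <- nchar(sequences) < max(cols)
  if (any(short))
    stop("clone(s) truncated before the last polymorphic column: ",
         paste(names(sequences)[short], collapse = ", "))

  n <- length(sequences)
  # states of every clone at the polymorphic columns
  st <- vapply(cols, function(cc) substring(sequences, cc, cc),
               character(n))
  if (n == 1) st <- matrix(st, nrow = 1)
  # per-type agreement at polymorphic columns
  agree <- vapply(types, function(ty) {
    rowSums(st == matrix(m[ty, ], n, length(cols), byrow = TRUE)) ==
      length(cols)
  }, logical(n))
  if (n == 1) agree <- matrix(agree, nrow = 1, dimnames = list(NULL, types))

  assignment <- rep("unassigned", n)
  assigned_type <- rep(NA_character_, n)
  variant_positions <- rep(list(integer()), n)
  breakpoint <- rep(list(NULL), n)

  exact_str <- vapply(types, function(ty) hseq[[ty]], character(1))
  for (i in seq_len(n)) {
    hit <- types[agree[i, ]]
    if (length(hit)) {
      ty <- hit[1]
      if (sequences[i] == exact_str[ty]) {
        assignment[i] <- "type-exact"; assigned_type[i] <- ty
        next
      }
      if (nchar(sequences[i]) == alen) {
        a <- strsplit(sequences[i], "", fixed = TRUE)[[1]]
        b <- strsplit(exact_str[ty], "", fixed = TRUE)[[1]]
        diffs <- setdiff(which(a != b), cols)
        if (length(diffs) == 0) {
          assignment[i] <- "type-exact"; assigned_type[i] <- ty
        } else if (length(diffs) <= max_variant_sites) {
          assignment[i] <- "type-variant"; assigned_type[i] <- ty
          variant_positions[[i]] <- diffs
        }
        if (assignment[i] != "unassigned") next
      }
    }
    # chimera scan: two contiguous donor blocks over the diagnostic columns
    chim <- .chimera_scan(st[i, ], m)
    if (!is.null(chim)) {
      assignment[i] <- "chimera"
      assigned_type[i] <- paste(chim$donors, collapse = "/")
      breakpoint[[i]] <- chim$interval
    }
  }
  out <- data.frame(id = names(sequences), assignment = assignment,
                    assigned_type = assigned_type,
                    stringsAsFactors = FALSE)
  out$variant_positions <- variant_positions
  out$breakpoint <- breakpoint
  out
}

# Single-breakpoint chimera detection over the diagnostic-column states.
.chimera_scan <- function(states, m) {
  types <- rownames(m)
  cols <- as.integer(colnames(m))
  k <- length(cols)
  match_m <- vapply(types, function(ty) states == m[ty, ], logical(k))
  for (x in types) for (y in setdiff(types, x)) {
    # valid breakpoints: 5' block donated by x, 3' block by y
    ok <- vapply(seq_len(k - 1), function(b) {
      all(match_m[seq_len(b), x]) && all(match_m[(b + 1):k, y])
    }, logical(1))
    if (any(ok)) {
      # both blocks must be informative (otherwise the clone is a plain type)
      if (all(match_m[, x]) || all(match_m[, y])) next
      bs <- which(ok)
      return(list(donors = c(x, y),
                  interval = c(cols[min(bs)], cols[max(bs) + 1])))
    }
  }
  NULL
}

# ---- ratio and alignment statistics ---------------------------------------

#' Chi-square test for equal class frequencies
#'
#' Pearson goodness-of-fit of observed counts against equal expected counts
#' (df = k - 1, no continuity correction).  Applied to the published clone
#' counts 59:47:58 it reproduces the 1:1:1 test of the clone library.
#'
#' @param counts non-negative counts, total > 0.
#' @return List of class `chisq_result` with `statistic`, `df`, `p.value`,
#'   `counts`.
#' @export
equal_ratio_chisq <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("total count is zero; statistic undefined")
  ht <- suppressWarnings(stats::chisq.test(counts))
  structure(list(statistic = unname(ht$statistic),
                 df = as.integer(unname(ht$parameter)),
                 p.value = ht$p.value, counts = counts),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, digits = 2, ...) {
  cat(sprintf("Chi-square = %.*f, df = %d, p = %.*f\n", digits, x$statistic,
              x$df, digits, x$p.value))
  invisible(x)
}

#' Parsimony-informative sites of an alignment
#'
#' Columns with at least two distinct states each present in at least two
#' sequences.  Gaps are coded characters (a fifth state); `N` and `?` are
#' treated as missing and ignored.
#'
#' @param alignment character vector of aligned sequences (equal length), or
#'   a character matrix with one column per alignment position.
#' @return Integer vector of informative columns (empty, with a warning,
#'   for fewer than four sequences).
#' @export
parsimony_informative_sites <- function(alignment) {
  if (is.character(alignment) && !is.matrix(alignment)) {
    if (length(unique(nchar(alignment))) > 1)
      stop("sequences differ in length; not an alignment")
    alignment <- do.call(rbind, strsplit(toupper(norm_gap(alignment)), "",
                                         fixed = TRUE))
  }
  if (nrow(alignment) < 4) {
    warning("fewer than 4 sequences: no site can be parsimony informative")
    return(integer())
  }
  informative <- vapply(seq_len(ncol(alignment)), function(j) {
    s <- alignment[, j]
    s <- s[!s %in% c("N", "?", "")]
    tab <- table(s)
    sum(tab >= 2) >= 2
  }, logical(1))
  which(informative)
}

# ---- haplotype-group assignment (inter-specimen comparison) ---------------

# The nine parsimony-informative columns used to compare specimens from
# different continents, and the group-defining states there.
GROUP_COLUMNS <- c(39L, 122L, 130L, 145L, 146L, 200L, 269L, 466L, 475L)

GROUP_STATES <- ITS_TYPE_STATES[, as.character(GROUP_COLUMNS)]

#' Assign a specimen to an ITS haplotype group
#'
#' Specimens are compared at the nine parsimony-informative columns that
#' separate the three haplotype groups.  Heterokaryotic specimens may carry
#' superposed states (`"T/-"`, `"A/G"`, ...); the specimen is assigned
#' `mixed` when its states superpose two or more groups.
#'
#' @param states character vector of 9 states, in column order
#'   39, 122, 130, 145, 146, 200, 269, 466, 475.  Superposed states are
#'   written with `/`.
#' @return List with `group` (`"A"`, `"B"`, `"C"` or `"mixed"`) and
#'   `constituents` (the matching groups).
#' @export
assign_haplotype_group <- function(states) {
  if (length(states) != ncol(GROUP_STATES))
    stop("states must be given at all ", ncol(GROUP_STATES), " columns")
  iupac <- c(R = "A/G", Y = "C/T", S = "C/G", W = "A/T", K = "G/T",
             M = "A/C")
  states <- toupper(norm_gap(states))
  amb <- states %in% names(iupac)
  states[amb] <- iupac[states[amb]]
  sets <- strsplit(states, "/", fixed = TRUE)
  sets <- lapply(sets, function(s) s[nzchar(s)])
  matches <- rownames(GROUP_STATES)[vapply(rownames(GROUP_STATES),
    function(g) all(mapply(function(set, st) st %in% set,
                           sets, GROUP_STATES[g, ])), logical(1))]
  if (length(matches) == 0)
    stop("states match no haplotype group and no superposition of groups")
  # every observed state must be explained by the matched groups
  explained <- vapply(seq_along(sets), function(j)
    all(sets[[j]] %in% GROUP_STATES[matches, j]), logical(1))
  if (!all(explained))
    stop("states at column(s) ",
         paste(GROUP_COLUMNS[!explained], collapse = ", "),
         " are not explained by any combination of groups")
  if (length(matches) == 1) list(group = matches, constituents = matches)
  else list(group = "mixed", constituents = matches)
}
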