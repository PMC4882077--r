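# File interfaces: FASTA in/out, tab-separated genotype tables, and JSON /
# text reports with a reproducibility manifest.

#' Read sequences from a FASTA file
#'
#' IDs are the header text up to the first whitespace.  Sequences are
#' uppercased and `U` is normalised to `T`; alignment gaps (`-`) are
#' preserved.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (possibly empty, with a
#'   warning).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(), character()))
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  ids <- sub("\\s.*$", "", names(set))
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  if (is.null(names(sequences))) stop("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}

SSI_TABLE_COLUMNS <- c("id", "PRS016", "PRS049", "PRS088", "ITS_MboII",
                       "ITS_FokI")

#' Read a single-spore-isolate genotype table
#'
#' Tab-separated with a header row; mandatory columns `id`, `PRS016`,
#' `PRS049`, `PRS088`, `ITS_MboII`, `ITS_FokI` (the layout written by
#' [write_genotype_table()]).  Marker calls are normalised (`"2/1"` to
#' `"1/2"`); unknown or blank tokens become `NA` and are counted in the
#' `n_undetermined` attribute.  The ITS phenotype class is derived from the
#' two band columns when no `phenotype` column is present.
#'
#' @param path TSV file.
#' @param required mandatory column names.
#' @return Data frame of class `ssi_table`.
#' @export
read_genotype_table <- function(path, required = SSI_TABLE_COLUMNS) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("genotype table lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  n_undet <- 0L
  for (m in c("PRS016", "PRS049", "PRS088")) {
    x <- trimws(tab[[m]])
    x[!nzchar(x)] <- NA_character_
    parts <- strsplit(x, "/", fixed = TRUE)
    x <- vapply(parts, function(a) {
      if (length(a) == 0 || anyNA(a)) return(NA_character_)
      a <- sort(unique(trimws(a)))
      if (!all(grepl("^[A-Za-z0-9]+$", a))) return(NA_character_)
      paste(a, collapse = "/")
    }, "")
    n_undet <- n_undet + sum(is.na(x) & !is.na(tab[[m]]))
    tab[[m]] <- x
  }
  if (!"phenotype" %in% names(tab))
    tab$phenotype <- mapply(phenotype_from_bands, tab$ITS_MboII,
                            tab$ITS_FokI, USE.NAMES = FALSE)
  attr(tab, "n_undetermined") <- n_undet
  class(tab) <- c("ssi_table", "data.frame")
  tab
}

#' Write a single-spore-isolate genotype table
#'
#' @param x a data frame (or `ssi_dataset`) with the SSI table columns.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path) {
  if (inherits(x, "ssi_dataset")) x <- x$table
  utils::write.table(x[, intersect(c(SSI_TABLE_COLUMNS, "phenotype"),
                                   names(x))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a haplotype definition table
#'
#' Tab-separated, one row per haplotype: a `name` column followed by one
#' column per alignment position (column headers are the 1-based
#' positions).  The packaged fixture
#' `system.file("extdata", "its_types.tsv", package = "itsloci")` defines
#' the three CA487 ITS types at their 13 polymorphic columns.
#'
#' @param path TSV file.
#' @param sequences optional named character vector of full aligned
#'   sequences to attach.
#' @return An `its_haplotype_set`.
#' @export
read_haplotypes <- function(path, sequences = NULL) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (!"name" %in% names(tab)) stop("haplotype table needs a `name` column")
  cols <- setdiff(names(tab), "name")
  if (anyNA(suppressWarnings(as.integer(cols))))
    stop("haplotype table columns must be integer alignment positions")
  haps <- lapply(seq_len(nrow(tab)), function(i) {
    its_haplotype(tab$name[i],
                  stats::setNames(unlist(tab[i, cols]), cols),
                  sequence = sequences[[tab$name[i]]] %||% NULL)
  })
  names(haps) <- tab$name
  structure(haps, class = "its_haplotype_set",
            alignment_length = if (is.null(sequences))
              max(as.integer(cols)) else unique(nchar(sequences)),
            regions = alignment_regions())
}

#' Read a marker configuration file
#'
#' JSON description of CAPS markers: per marker an amplicon length, an
#' enzyme (name, IUPAC recognition, cut offsets) or list of enzymes, and
#' per-allele cut coordinates.  The packaged fixture
#' `system.file("extdata", "caps_markers.json", package = "itsloci")`
#' mirrors [caps_markers()].
#'
#' @param path JSON file.
#' @return Named list of `caps_marker` objects.
#' @export
read_marker_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  parse_enzyme <- function(e)
    enzyme_spec(e$name, e$recognition, e$cut_top, e$cut_bottom)
  out <- lapply(cfg, function(mk) {
    enzyme <- if (!is.null(mk$enzyme$name)) parse_enzyme(mk$enzyme) else
      lapply(mk$enzyme, parse_enzyme)
    alleles <- lapply(mk$alleles, function(al) {
      cuts <- if (is.list(al$cuts))
        lapply(al$cuts, function(v) as.integer(unlist(v))) else
          as.integer(unlist(al$cuts))
      list(length = as.integer(al$length), cuts = cuts)
    })
    structure(list(locus = mk$locus, enzyme = enzyme,
                   length = as.integer(mk$length %||% alleles[[1]]$length),
                   alleles = alleles),
              class = "caps_marker")
  })
  stats::setNames(out, vapply(cfg, `[[`, "", "locus"))
}

#' Write an analysis report
#'
#' Emits the results as JSON (full precision), as a tab-separated per-SSI
#' call table when per-isolate calls are present, and as a human-readable
#' text summary; plus a manifest with the package version, seed, and a
#' fingerprint of the configuration, sufficient to reproduce the run.
#'
#' @param results a list (typically an [ssi_analysis()] object).
#' @param dir output directory (created if needed).
#' @param name file-name stem.
#' @param seed the seed used for the run, echoed into the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, dir, name = "report", seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  json <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(.jsonable(results), json, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  files <- c(files, json)
  if (!is.null(results$calls) && is.data.frame(results$calls)) {
    tsv <- file.path(dir, paste0(name, "_calls.tsv"))
    utils::write.table(results$calls, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, tsv)
  }
  txt <- file.path(dir, paste0(name, ".txt"))
  con <- file(txt, "w")
  sink(con)
  tryCatch(print(results), finally = { sink(); close(con) })
  files <- c(files, txt)
  cfg <- deparse(results[setdiff(names(results), "calls")])
  manifest <- list(package = "itsloci",
                   version = as.character(utils::packageVersion("itsloci")),
                   seed = seed, config_hash = fnv1a(cfg),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   files = basename(files))
  mf <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(c(files, mf))
}

# Strip classes/attributes so jsonlite serialises plainly.
.jsonable <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- lapply(x, .jsonable)
    attributes(x) <- list(names = names(x))
    return(x)
  }
  if (is.matrix(x)) return(as.data.frame(x))
  attributes(x) <- if (!is.null(names(x))) list(names = names(x))
  x
}
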