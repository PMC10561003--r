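#' Read taxonomy-labeled sequences from FASTA
#'
#' Reads unaligned DNA sequences and parses genus/species labels from the
#' headers. Bases are uppercased and U is mapped to T on read; gap characters
#' are rejected. Three header conventions are supported:
#' \describe{
#'   \item{`"tax"`}{key-value annotation, e.g.
#'     `>s1 tax=g:Bacillus,s:Bacillus velezensis` (the default written by
#'     [write_fasta()]).}
#'   \item{`"lineage"`}{a semicolon-delimited lineage in the description;
#'     the second-to-last field is taken as genus and the last as species
#'     (a single field is taken as genus). `g__`/`s__` prefixes are
#'     stripped.}
#'   \item{`"none"`}{no taxonomy parsing; genus and species are empty.}
#' }
#'
#' @param path path to a FASTA file.
#' @param header_convention one of `"tax"`, `"lineage"`, `"none"`.
#' @return a `data.frame` with columns `id`, `genus`, `species`, `seq`,
#'   one row per record in file order.
#' @export
read_fasta <- function(path, header_convention = c("tax", "lineage", "none")) {
  header_convention <- match.arg(header_convention)
  sniff_format(path, expect = ">")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) gp_format_error(
                    paste0("malformed FASTA: ", conditionMessage(e))))
  if (length(set) == 0L) gp_empty_input(paste0("no records in ", path))
  headers <- names(set)
  seqs <- normalize_dna(unname(as.character(set)))
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) gp_format_error("duplicate sequence ids in FASTA")
  bad <- !is_valid_dna(seqs)
  if (any(bad)) gp_format_error(paste0(
    "invalid characters (non-IUPAC or gaps) in sequence(s): ",
    paste(head(ids[bad], 3), collapse = ", ")))
  tax <- parse_taxonomy(headers, header_convention)
  data.frame(id = ids, genus = tax$genus, species = tax$species, seq = seqs,
             stringsAsFactors = FALSE)
}

normalize_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

sniff_format <- function(path, expect = NULL) {
  if (!file.exists(path)) gp_format_error(paste0("file not found: ", path))
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) gp_empty_input(paste0("empty file: ", path))
  first <- substr(trimws(lines[[1]]), 1L, 1L)
  if (!is.null(expect) && first != expect)
    gp_format_error(paste0(
      "expected a file starting with '", expect, "' but found '", first,
      "': ", path))
  first
}

parse_taxonomy <- function(headers, convention) {
  n <- length(headers)
  genus <- character(n); species <- character(n)
  if (convention == "none") return(list(genus = genus, species = species))
  desc <- sub("^\\S+\\s*", "", headers)
  if (convention == "tax") {
    has <- grepl("tax=", desc, fixed = TRUE)
    kv <- sub("^.*tax=", "", desc[has])
    for (i in seq_along(kv)) {
      parts <- strsplit(kv[[i]], ",", fixed = TRUE)[[1]]
      for (p in parts) {
        if (startsWith(p, "g:")) genus[which(has)[i]] <- trimws(substring(p, 3))
        if (startsWith(p, "s:")) species[which(has)[i]] <- trimws(substring(p, 3))
      }
    }
  } else {  # lineage
    has <- grepl(";", desc, fixed = TRUE) | nzchar(trimws(desc))
    for (i in which(has)) {
      fields <- trimws(strsplit(desc[[i]], ";", fixed = TRUE)[[1]])
      fields <- fields[nzchar(fields)]
      if (length(fields) == 0L) next
      strip <- function(x) gsub("_", " ", sub("^[a-z]__", "", x))
      if (length(fields) == 1L) {
        genus[i] <- strip(fields)
      } else {
        genus[i] <- strip(fields[length(fields) - 1L])
        species[i] <- strip(fields[length(fields)])
      }
    }
  }
  list(genus = genus, species = species)
}

#' Write taxonomy-labeled sequences to FASTA
#'
#' Headers carry the `tax=g:<genus>,s:<species>` annotation whenever a genus
#' or species label is present, so that [read_fasta()] round-trips the
#' records.
#'
#' @param records a `data.frame` with columns `id`, `seq` and optionally
#'   `genus`, `species`.
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  genus <- if ("genus" %in% names(records)) records$genus
           else rep("", nrow(records))
  species <- if ("species" %in% names(records)) records$species
             else rep("", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[[i]]
    if (nzchar(genus[[i]]) || nzchar(species[[i]]))
      hdr <- paste0(hdr, " tax=g:", genus[[i]], ",s:", species[[i]])
    writeLines(paste0(">", hdr), con)
    s <- records$seq[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and (interleaved) Clustal. Rows must have equal
#' length; the gap character is `-` (Clustal `.` gaps are normalized to
#' `-`). Taxonomy labels are parsed from FASTA headers with the same
#' conventions as [read_fasta()].
#'
#' @param path path to the alignment file.
#' @param dialect `"fasta"` or `"clustal"`.
#' @param header_convention passed to the taxonomy parser (FASTA only).
#' @return a `gp_alignment` object: a list with `id`, `genus`, `species`,
#'   `seq` (aligned rows, gaps as `-`) and `n_cols`.
#' @export
read_alignment <- function(path, dialect = c("fasta", "clustal"),
                           header_convention = c("tax", "lineage", "none")) {
  dialect <- match.arg(dialect)
  header_convention <- match.arg(header_convention)
  if (dialect == "fasta") {
    sniff_format(path, expect = ">")
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) gp_format_error(
                      paste0("malformed aligned FASTA: ", conditionMessage(e))))
    if (length(set) == 0L) gp_empty_input(paste0("no records in ", path))
    headers <- names(set)
    ids <- sub("\\s.*$", "", headers)
    seqs <- unname(as.character(set))
    tax <- parse_taxonomy(headers, header_convention)
  } else {
    aln <- tryCatch(seqinr::read.alignment(path, format = "clustal",
                                           oldclustal = TRUE),
                    error = function(e) gp_format_error(
                      paste0("malformed Clustal file: ", conditionMessage(e))))
    if (aln$nb == 0L) gp_empty_input(paste0("no records in ", path))
    ids <- aln$nam
    seqs <- unlist(aln$seq, use.names = FALSE)
    tax <- list(genus = character(length(ids)), species = character(length(ids)))
  }
  new_alignment(ids, seqs, tax$genus, tax$species)
}

# constructor + validator shared by all parse paths
new_alignment <- function(ids, seqs, genus = NULL, species = NULL) {
  n <- length(ids)
  if (is.null(genus)) genus <- character(n)
  if (is.null(species)) species <- character(n)
  seqs <- chartr(".", "-", normalize_dna(seqs))
  if (n < 2L) gp_format_error("an alignment needs at least 2 rows")
  if (anyDuplicated(ids)) gp_format_error("duplicate row ids in alignment")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    gp_format_error(paste0("ragged alignment: row lengths ",
                           paste(unique(lens), collapse = ", ")))
  degapped <- gsub("-", "", seqs, fixed = TRUE)
  if (!all(is_valid_dna(degapped)))
    gp_format_error("alignment rows contain non-IUPAC characters or are all-gap")
  structure(list(id = ids, genus = genus, species = species, seq = seqs,
                 n_cols = lens[[1]]),
            class = "gp_alignment")
}

#' @export
print.gp_alignment <- function(x, ...) {
  cat("<gp_alignment> ", length(x$id), " rows x ", x$n_cols, " columns\n",
      sep = "")
  invisible(x)
}

# aligned rows as a character matrix (rows x cols)
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
}

#' Read amplicon reads from FASTA or FASTQ
#'
#' The format is sniffed from the first non-blank character (`>` FASTA,
#' `@` FASTQ). FASTQ quality strings are preserved.
#'
#' @param path path to the read file.
#' @return a `data.frame` with columns `id`, `seq` and `qual` (`NA` for
#'   FASTA input).
#' @export
read_reads <- function(path) {
  first <- sniff_format(path)
  if (first == ">") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) gp_format_error(
                      paste0("malformed FASTA: ", conditionMessage(e))))
    qual <- rep(NA_character_, length(set))
  } else if (first == "@") {
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) gp_format_error(
        paste0("malformed FASTQ: ", conditionMessage(e))))
    qual <- unname(as.character(S4Vectors::mcols(set)$qualities))
  } else {
    gp_format_error(paste0("unrecognized read format (first character '",
                           first, "'): ", path))
  }
  if (length(set) == 0L) gp_empty_input(paste0("no reads in ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) gp_format_error("duplicate read ids")
  seqs <- normalize_dna(unname(as.character(set)))
  if (any(!nzchar(seqs))) gp_format_error("empty read sequence")
  data.frame(id = ids, seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Write a data frame as a tab-separated table
#'
#' Emits a header line, no quoting, no row names; row order is preserved.
#'
#' @param records a `data.frame`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a report object as JSON
#'
#' @param x a list or data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
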