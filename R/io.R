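# File input/output: FASTA, one-SMILES-per-line files, interaction tables,
# plain-text corpora and vocabulary serialization.

#' Read a protein FASTA file
#'
#' Accepts wrapped or unwrapped sequence lines.  Record ids are the header
#' up to the first whitespace; `*` stop characters are stripped from the
#' sequences.  Duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names = record ids),
#'   in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate FASTA id(s): %s",
                 paste(sQuote(dup), collapse = ", ")), call. = FALSE)
  }
  seqs <- gsub("*", "", as.character(set), fixed = TRUE)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a one-SMILES-per-line file
#'
#' Each line holds a SMILES string, optionally followed by a tab and an
#' identifier.  Lines without an identifier get `compound<k>`.
#'
#' @param path Path to a `.smi` file.
#' @return A named character vector of SMILES strings.
#' @export
read_smiles_file <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L && nzchar(parts[[i]][2L])) parts[[i]][2L]
    else sprintf("compound%d", i)
  }, character(1))
  names(smiles) <- ids
  smiles
}

#' Write a one-SMILES-per-line file
#'
#' @param smiles Named character vector of SMILES strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(smiles, path) {
  writeLines(paste(smiles, names(smiles), sep = "\t"), path)
  invisible(path)
}

#' Read an interaction table
#'
#' Reads a CSV (or TSV, by file extension) table of compound-protein
#' affinities.  The column map names which columns hold the compound id,
#' protein id and affinity; affinities must be numeric.
#'
#' @param path Path to a CSV/TSV file.
#' @param column_map Named list/character vector with entries
#'   `compound_id`, `protein_id`, `affinity` giving the source column names.
#' @return A data.frame with columns `compound_id`, `protein_id`,
#'   `affinity`, in file order.
#' @export
read_interactions <- function(path,
                              column_map = c(compound_id = "compound_id",
                                             protein_id = "protein_id",
                                             affinity = "affinity")) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  column_map <- unlist(column_map)
  needed <- c("compound_id", "protein_id", "affinity")
  if (!all(needed %in% names(column_map))) {
    stop("column_map must name compound_id, protein_id and affinity",
         call. = FALSE)
  }
  missing <- setdiff(unname(column_map[needed]), names(raw))
  if (length(missing)) {
    stop(sprintf("interaction table lacks column(s): %s",
                 paste(sQuote(missing), collapse = ", ")), call. = FALSE)
  }
  aff <- raw[[column_map[["affinity"]]]]
  if (!is.numeric(aff)) {
    aff2 <- suppressWarnings(as.numeric(aff))
    if (anyNA(aff2)) {
      stop(sprintf("non-numeric affinity value(s), e.g. %s",
                   sQuote(aff[which(is.na(aff2))[1L]])), call. = FALSE)
    }
    aff <- aff2
  }
  data.frame(compound_id = as.character(raw[[column_map[["compound_id"]]]]),
             protein_id = as.character(raw[[column_map[["protein_id"]]]]),
             affinity = aff, stringsAsFactors = FALSE)
}

#' Write an interaction table as CSV
#'
#' @param interactions Data.frame with `compound_id`, `protein_id`,
#'   `affinity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  utils::write.csv(interactions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-text pretraining corpus
#'
#' One tokenizable string per line; blank lines are dropped.
#'
#' @param path Path to a text file.
#' @return Character vector of lines.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path)
  lines[nzchar(trimws(lines))]
}

#' Serialize / restore a vocabulary as JSON
#'
#' @param vocab A `dta_vocabulary`.
#' @param path Output (input) path.
#' @return `write_vocabulary`: `path`, invisibly.  `read_vocabulary`: the
#'   restored `dta_vocabulary` (identical token/id assignment).
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "dta_vocabulary"))
  jsonlite::write_json(list(kind = vocab$kind, tokens = vocab$tokens),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kind = raw$kind, tokens = as.character(raw$tokens),
                 size = length(raw$tokens)),
            class = "dta_vocabulary")
}
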