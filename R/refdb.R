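#' Read reference marker sequences from a FASTA file
#'
#' Reads a FASTA file of marker sequences into a data frame of records with
#' lineages unset. Sequences are uppercased and RNA `U` is normalized to `T`;
#' the record id is the first whitespace-delimited token of the header and
#' the remainder of the header becomes the description.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `seq`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">seq1 Cyprinus carpio 16S", "acgt"), fa)
#' read_reference_fasta(fa)
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- normalize_dna(as.character(ss))
  check_alphabet(seqs, c(iupac_alphabet(), "-"), what = "FASTA record")
  data.frame(id = ids, description = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Read a taxonomy table
#'
#' Reads a tab-separated table mapping sequence ids to ranked lineages. The
#' file must have a header row with an `id` column followed by the seven
#' columns of [rank_ladder()]. Empty cells denote unknown ranks.
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns `id` plus the seven ranks.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL,
                    check.names = FALSE)
  expected <- c("id", rank_ladder())
  missing <- setdiff(expected, names(tab))
  if (length(missing)) {
    stop("taxonomy table is missing column(s): ",
         paste(missing, collapse = ", "),
         "; expected header: ", paste(expected, collapse = "\t"),
         call. = FALSE)
  }
  tab <- tab[, expected]
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup)) {
    stop("duplicate id(s) in taxonomy table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (r in rank_ladder()) tab[[r]][is.na(tab[[r]])] <- ""
  tab
}

#' Build a reference database
#'
#' Joins FASTA records with their lineages and builds a per-rank taxon index.
#'
#' @param records Data frame from [read_reference_fasta()].
#' @param lineages Data frame from [read_taxonomy_table()].
#' @param strict If `TRUE` (default), every record must have a lineage;
#'   otherwise records with no lineage row get an all-empty lineage and a
#'   warning is issued.
#' @return A `reference_db` object: a data frame with columns `id`,
#'   `description`, `seq` and the seven rank columns, in record order.
#' @export
build_db <- function(records, lineages, strict = TRUE) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  missing <- setdiff(records$id, lineages$id)
  if (length(missing)) {
    if (strict) {
      stop("no lineage for record(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    warning(length(missing), " record(s) without lineage; stored with empty ",
            "lineage: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"description" %in% names(records)) records$description <- ""
  idx <- match(records$id, lineages$id)
  lin <- lineages[idx, rank_ladder(), drop = FALSE]
  lin[is.na(idx), ] <- ""
  db <- cbind(records[, c("id", "description", "seq")], lin)
  rownames(db) <- NULL
  class(db) <- c("reference_db", "data.frame")
  db
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d sequence(s)\n", nrow(x)))
  for (r in rank_ladder()) {
    taxa <- setdiff(unique(x[[r]]), "")
    cat(sprintf("  %-13s %d taxa\n", r, length(taxa)))
  }
  invisible(x)
}

#' Look up record ids by taxon
#'
#' @param db A `reference_db`.
#' @param rank One of [rank_ladder()].
#' @param taxon Taxon name.
#' @return Character vector of record ids whose lineage carries `taxon` at
#'   `rank` (possibly empty).
#' @export
db_lookup <- function(db, rank, taxon) {
  rank <- match.arg(rank, rank_ladder())
  db$id[db[[rank]] == taxon]
}

#' Restrict a reference database to one taxon
#'
#' Mirrors taxon-restricted primer searches (e.g. evaluating a primer pair
#' only within one family): the database is filtered to records whose lineage
#' has `taxon` at `rank`. An empty result is valid.
#'
#' @inheritParams db_lookup
#' @return A `reference_db` with the matching records, original order kept.
#' @export
subset_by_taxon <- function(db, rank, taxon) {
  rank <- match.arg(rank, rank_ladder())
  out <- db[db[[rank]] == taxon, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    message("subset_by_taxon: no records for ", rank, " '", taxon, "'")
  }
  class(out) <- c("reference_db", "data.frame")
  out
}

#' Write a reference database back to FASTA + taxonomy TSV
#'
#' Inverse of [read_reference_fasta()] + [read_taxonomy_table()] +
#' [build_db()]: reading the two files back reproduces the database.
#'
#' @param db A `reference_db`.
#' @param fasta_path,tax_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference_db <- function(db, fasta_path, tax_path) {
  ss <- Biostrings::BStringSet(setNames(db$seq, ifelse(
    db$description == "", db$id, paste(db$id, db$description))))
  Biostrings::writeXStringSet(ss, fasta_path)
  write.table(db[, c("id", rank_ladder())], tax_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, tax_path))
}

#' Read a reference database from FASTA + taxonomy TSV
#'
#' @param fasta_path,tax_path Input paths.
#' @param strict Passed to [build_db()].
#' @return A `reference_db`.
#' @export
read_reference_db <- function(fasta_path, tax_path, strict = TRUE) {
  build_db(read_reference_fasta(fasta_path), read_taxonomy_table(tax_path),
           strict = strict)
}

# Lineage of one record as a named character vector over the rank ladder.
db_lineage <- function(db, id) {
  row <- db[db$id == id, rank_ladder(), drop = FALSE]
  if (nrow(row) != 1) stop("unknown record id: ", id, call. = FALSE)
  unlist(row[1, , drop = TRUE])
}
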