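#' Construct a protein record table
#'
#' The package's core sequence container is a plain tibble with one row per
#' protein: `id` (unique), `gene_id`, `sequence` (canonical 20-letter
#' alphabet, upper case) and `modified`, which records any sequence surgery
#' applied downstream (`"intact"`, `"sp_removed"`, `"sp_removed_met_restored"`,
#' `"prefix_removed"`, `"duplicated_copy"`).
#'
#' @param id Character vector of protein identifiers (unique).
#' @param sequence Character vector of amino-acid sequences.
#' @param gene_id Gene identifiers; defaults to `id`.
#' @param modified Modification state; defaults to `"intact"`.
#' @param policy Non-canonical residue policy passed to
#'   [validate_sequence()].
#' @return A tibble with columns `id`, `gene_id`, `sequence`, `modified`.
#' @examples
#' protein_records(c("p1", "p2"), c("MKVLA", "GGSTP"))
#' @export
protein_records <- function(id, sequence, gene_id = id,
                            modified = "intact", policy = "drop") {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  ok <- c("intact", "sp_removed", "sp_removed_met_restored",
          "prefix_removed", "duplicated_copy")
  if (!all(modified %in% ok)) {
    stop("invalid 'modified' value", call. = FALSE)
  }
  tibble::tibble(
    id = id,
    gene_id = as.character(gene_id),
    sequence = vapply(as.character(sequence), validate_sequence, "",
                      policy = policy, USE.NAMES = FALSE),
    modified = modified
  )
}

#' Validate and normalise an amino-acid sequence
#'
#' Upper-cases, strips a single trailing stop (`*`), and resolves
#' non-canonical residue codes (X, B, Z, U, O and anything else outside the
#' 20-letter alphabet). The default policy drops them with a warning so
#' that every downstream feature stays defined on canonical residues;
#' `policy = "reject"` errors instead.
#'
#' @param raw Character scalar, raw sequence.
#' @param policy `"drop"` (default) or `"reject"`.
#' @return Cleaned sequence string.
#' @examples
#' validate_sequence("mKv*")
#' @export
validate_sequence <- function(raw, policy = c("drop", "reject")) {
  policy <- match.arg(policy)
  s <- toupper(gsub("[[:space:]]", "", as.character(raw)))
  s <- sub("\\*$", "", s)
  bad <- gsub(paste0("[", paste(AA_ORDER, collapse = ""), "]"), "", s)
  if (nzchar(bad)) {
    if (policy == "reject") {
      stop("non-canonical residue(s) in sequence: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
           call. = FALSE)
    }
    warning("dropped ", nchar(bad), " non-canonical residue(s)",
            call. = FALSE)
    s <- gsub(paste0("[^", paste(AA_ORDER, collapse = ""), "]"), "", s)
  }
  if (!nzchar(s)) stop("sequence empty after cleaning", call. = FALSE)
  s
}

#' Read protein sequences from FASTA
#'
#' Parses a (multi-line) FASTA file into a protein record tibble. Record
#' ids are the first whitespace-delimited token of each header; gene ids
#' default to the id unless a `gene_map` is supplied.
#'
#' @param path FASTA file path.
#' @param gene_map Optional data frame with columns `id`, `gene_id`.
#' @param policy Non-canonical residue policy (see [validate_sequence()]).
#' @return Protein record tibble (see [protein_records()]).
#' @export
read_fasta <- function(path, gene_map = NULL, policy = "drop") {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, "", 1L)
  recs <- protein_records(ids, as.character(set), policy = policy)
  if (!is.null(gene_map)) {
    gm <- stats::setNames(as.character(gene_map$gene_id),
                          as.character(gene_map$id))
    hit <- recs$id %in% names(gm)
    recs$gene_id[hit] <- gm[recs$id[hit]]
  }
  recs
}

#' Write protein records to FASTA
#'
#' @param records Protein record tibble.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence,
                                                 records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read per-isoform secretory-feature annotations
#'
#' Reads the package's neutral annotation TSV with header columns
#' `protein_id`, `gene_id`, `has_sp`, `sp_cleavage_pos`, `tmd_count`,
#' `has_gpi`, `observed`. `sp_cleavage_pos` is the 1-based index of the
#' last signal-peptide residue (residues `1..pos` are the SP) and must be
#' present exactly when `has_sp` is true; `-`, `NA` or empty mean absent.
#'
#' @param path TSV path.
#' @param records Optional protein record tibble; when given, every
#'   `protein_id` must be present in it and `sp_cleavage_pos` must be
#'   smaller than the referenced sequence length.
#' @return Tibble of annotations.
#' @export
read_annotations <- function(path, records = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    gene_id = readr::col_character(),
    has_sp = readr::col_logical(),
    sp_cleavage_pos = readr::col_character(),
    tmd_count = readr::col_integer(),
    has_gpi = readr::col_logical(),
    observed = readr::col_logical()
  ), na = c("", "NA", "-"), progress = FALSE)
  tbl$sp_cleavage_pos <- suppressWarnings(as.integer(tbl$sp_cleavage_pos))
  validate_annotations(tbl, records)
}

#' Validate an annotation table
#'
#' Enforces the annotation invariants: `sp_cleavage_pos` present iff
#' `has_sp`, positions >= 1, `tmd_count` >= 0, and (when `records` is
#' given) referential integrity against the sequence set.
#'
#' @inheritParams read_annotations
#' @param annotations Annotation tibble (as from [read_annotations()]).
#' @return The validated tibble.
#' @export
validate_annotations <- function(annotations, records = NULL) {
  a <- annotations
  bad <- which(a$has_sp & is.na(a$sp_cleavage_pos))
  if (length(bad)) {
    stop("has_sp is true but sp_cleavage_pos missing at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!a$has_sp & !is.na(a$sp_cleavage_pos))
  if (length(bad)) {
    stop("sp_cleavage_pos given while has_sp is false at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(a$sp_cleavage_pos < 1L, na.rm = TRUE)) {
    stop("sp_cleavage_pos must be >= 1", call. = FALSE)
  }
  if (any(a$tmd_count < 0L, na.rm = TRUE)) {
    stop("tmd_count must be >= 0", call. = FALSE)
  }
  if (!is.null(records)) {
    missing <- setdiff(a$protein_id, records$id)
    if (length(missing)) {
      stop("annotation protein_id(s) absent from sequence set: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    len <- stats::setNames(nchar(records$sequence), records$id)
    too_long <- which(!is.na(a$sp_cleavage_pos) &
                        a$sp_cleavage_pos >= len[a$protein_id])
    if (length(too_long)) {
      stop("sp_cleavage_pos >= sequence length at row(s): ",
           paste(too_long, collapse = ", "), call. = FALSE)
    }
  }
  tibble::as_tibble(a)
}

#' Read a secretome observation list
#'
#' One gene id per line; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of observed gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Read a protein-protein interaction edge list
#'
#' TSV with header `protein_id_a`, `protein_id_b`; undirected edges.
#'
#' @param path TSV path.
#' @return Tibble with columns `protein_id_a`, `protein_id_b`.
#' @export
read_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein_id_a = readr::col_character(),
    protein_id_b = readr::col_character()
  ), progress = FALSE)
}

#' Read a PFAM-domain or GO-term assignment table
#'
#' TSV with header `protein_id`, `accession`; one row per assignment.
#'
#' @param path TSV path.
#' @return Tibble with columns `protein_id`, `accession`.
#' @export
read_assignments <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    accession = readr::col_character()
  ), progress = FALSE)
}
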