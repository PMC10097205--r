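# Assembly of labelled training sets: sequence modification schemes,
# CD-hit-style redundancy reduction, and the six scheme presets.

#' Remove an annotated signal peptide from records
#'
#' Drops residues `1..sp_end` (the annotated signal peptide) from each
#' sequence; optionally restores a translation-initiating methionine at
#' the new N-terminus. Vectorised over rows.
#'
#' @param records Protein record tibble.
#' @param sp_end Integer vector (recycled) of 1-based positions of the
#'   last SP residue; must satisfy `1 <= sp_end < nchar(sequence)`.
#' @param restore_met Prepend `"M"` after removal?
#' @return Modified record tibble; `modified` set to `"sp_removed"` or
#'   `"sp_removed_met_restored"`.
#' @examples
#' r <- protein_records("p", "MKKLLLLSAADEF")
#' remove_signal_peptide(r, 7)$sequence               # "SAADEF"
#' remove_signal_peptide(r, 7, TRUE)$sequence         # "MSAADEF"
#' @export
remove_signal_peptide <- function(records, sp_end, restore_met = FALSE) {
  sp_end <- as.integer(sp_end)
  n <- nchar(records$sequence)
  bad <- which(sp_end < 1L | sp_end >= n)
  if (length(bad)) {
    stop("sp_end out of range (nothing would remain) for record(s): ",
         paste(records$id[utils::head(bad, 5L)], collapse = ", "),
         call. = FALSE)
  }
  out <- records
  out$sequence <- substring(records$sequence, sp_end + 1L, n)
  if (restore_met) out$sequence <- paste0("M", out$sequence)
  out$modified <- if (restore_met) "sp_removed_met_restored" else
    "sp_removed"
  out
}

#' Remove a fixed-length N-terminal prefix
#'
#' Used to modify negative training data by an average-signal-peptide
#' length; records shorter than `prefix + 1` are dropped with a warning.
#'
#' @param records Protein record tibble.
#' @param prefix Number of N-terminal residues to remove.
#' @return Modified record tibble (`modified = "prefix_removed"`).
#' @export
remove_prefix <- function(records, prefix) {
  prefix <- as.integer(prefix)
  stopifnot(prefix >= 1L)
  keep <- nchar(records$sequence) > prefix
  if (!all(keep)) {
    warning("dropped ", sum(!keep),
            " record(s) shorter than the removed prefix", call. = FALSE)
  }
  out <- records[keep, , drop = FALSE]
  out$sequence <- substring(out$sequence, prefix + 1L)
  out$modified <- "prefix_removed"
  out
}

#' Mean annotated signal-peptide length
#'
#' Arithmetic mean of the SP cleavage positions over annotations with a
#' signal peptide, rounded half-up to the nearest integer.
#'
#' @param annotations Annotation tibble.
#' @return Integer length.
#' @examples
#' mean_sp_length(tibble::tibble(has_sp = TRUE, sp_cleavage_pos = c(20, 21)))
#' @export
mean_sp_length <- function(annotations) {
  lens <- annotations$sp_cleavage_pos[annotations$has_sp]
  lens <- lens[!is.na(lens)]
  if (!length(lens)) {
    stop("no annotations with a signal peptide", call. = FALSE)
  }
  as.integer(floor(mean(lens) + 0.5))
}

#' Pairwise global-alignment identity
#'
#' Identity of a Needleman-Wunsch global alignment, defined as exact
#' matches divided by alignment length (including gap columns).
#'
#' @param a,b Sequences (character scalars).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global"
  )
  Biostrings::pid(aln, type = "PID1") / 100
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Greedy redundancy reduction by sequence identity
#'
#' CD-hit-style greedy clustering: sequences are sorted longest first
#' (ties by id for determinism) and each is compared to the
#' representatives retained so far; a sequence joins the first cluster
#' whose representative it matches above `identity_threshold`, otherwise
#' it founds a new cluster. Only cluster representatives are returned, so
#' no retained pair exceeds the threshold under the module's identity
#' definition (global-alignment matches over alignment length). For
#' inputs larger than `screen_above`, a short-word screen skips
#' alignments between sequences sharing no length-`word_size` word.
#'
#' @param records Protein record tibble.
#' @param identity_threshold Maximum allowed pairwise identity among the
#'   retained set (default 0.40).
#' @param word_size k-mer length for the pre-screen.
#' @param screen_above Input size above which the screen is used; smaller
#'   inputs are clustered with exact all-alignments.
#' @return The retained (representative) records, in input order.
#' @export
reduce_redundancy <- function(records, identity_threshold = 0.40,
                              word_size = 5L, screen_above = 50L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  n <- nrow(records)
  if (n <= 1L) return(records)
  ord <- order(-nchar(records$sequence), records$id)
  use_screen <- n > screen_above
  kmers <- if (use_screen) {
    lapply(records$sequence, kmer_set, k = word_size)
  }
  reps <- integer(0)
  for (i in ord) {
    is_new <- TRUE
    for (j in reps) {
      if (use_screen &&
          !any(kmers[[i]] %in% kmers[[j]])) next
      if (pairwise_identity(records$sequence[i], records$sequence[j]) >
          identity_threshold) {
        is_new <- FALSE
        break
      }
    }
    if (is_new) reps <- c(reps, i)
  }
  records[sort(reps), , drop = FALSE]
}

SCHEME_NAMES <- c("LSPpred1", "LSPpred2", "SPLpred1", "SPLpred2",
                  "SPLpred3", "SPLpred4")

#' Training-scheme presets
#'
#' The six classifier variants differ in which database classes supply
#' positive and negative examples and in how sequences are modified:
#' * `LSPpred1`: positives = UNCLASSIFIED High+Medium confidence,
#'   negatives = NONSEC; no modification.
#' * `LSPpred2`: as LSPpred1 but negatives = NONSEC + SEC + SPT.
#' * `SPLpred1`: positives = SEC with the SP removed, negatives = NONSEC
#'   intact.
#' * `SPLpred2`: positives = SEC SP-removed, negatives = NONSEC with a
#'   mean-SP-length N-terminal prefix removed.
#' * `SPLpred3`: positives = SEC SP-removed with the initiator methionine
#'   restored, negatives = NONSEC intact.
#' * `SPLpred4`: both classes duplicated as intact plus modified copies
#'   (positives intact + SP-removed; negatives intact + prefix-removed).
#'
#' @param name One of the six scheme names.
#' @return A list describing the scheme (class `scheme_spec`).
#' @export
scheme_spec <- function(name) {
  name <- match.arg(name, SCHEME_NAMES)
  spec <- switch(name,
    LSPpred1 = list(positive_source = "UNCLASSIFIED_high_medium",
                    negative_source = "NONSEC",
                    positive_modification = "none",
                    negative_modification = "none"),
    LSPpred2 = list(positive_source = "UNCLASSIFIED_high_medium",
                    negative_source = c("NONSEC", "SEC", "SPT"),
                    positive_modification = "none",
                    negative_modification = "none"),
    SPLpred1 = list(positive_source = "SEC",
                    negative_source = "NONSEC",
                    positive_modification = "sp_removed",
                    negative_modification = "none"),
    SPLpred2 = list(positive_source = "SEC",
                    negative_source = "NONSEC",
                    positive_modification = "sp_removed",
                    negative_modification = "mean_sp_prefix_removed"),
    SPLpred3 = list(positive_source = "SEC",
                    negative_source = "NONSEC",
                    positive_modification = "sp_removed_met_restored",
                    negative_modification = "none"),
    SPLpred4 = list(positive_source = "SEC",
                    negative_source = "NONSEC",
                    positive_modification = "duplicated_intact_plus_sp_removed",
                    negative_modification = "duplicated_intact_plus_prefix_removed")
  )
  structure(c(list(name = name), spec), class = "scheme_spec")
}

sp_end_for <- function(ids, annotations) {
  pos <- stats::setNames(annotations$sp_cleavage_pos,
                         annotations$protein_id)[ids]
  if (anyNA(pos)) {
    stop("missing sp_cleavage_pos for SP-bearing record(s): ",
         paste(utils::head(ids[is.na(pos)], 5L), collapse = ", "),
         call. = FALSE)
  }
  as.integer(pos)
}

#' Assemble a labelled training set under a scheme
#'
#' Extracts the scheme's positive and negative protein pools from a built
#' database (all isoforms of a classified gene enter the pool), applies
#' per-class redundancy reduction to the intact sequences, applies the
#' scheme's sequence modifications, and extracts features. Low-confidence
#' and unscored UNCLASSIFIED proteins are never included: they are
#' reserved as evaluation data. Each modified record keeps its unmodified
#' twin retrievable via `source_id`.
#'
#' @param db An `lspdb` object from [build_lspdb()].
#' @param records Protein record tibble covering the database proteins.
#' @param annotations Annotation tibble (for SP positions and the mean SP
#'   length).
#' @param scheme A [scheme_spec()] or scheme name.
#' @param identity_threshold Redundancy threshold (default 0.40).
#' @param exclude Optional protein ids to exclude (e.g. a curated
#'   exclusion list).
#' @param seed Integer seed recorded in the provenance (assembly itself
#'   is deterministic).
#' @return An object of class `lsp_dataset`: list with `records` (with
#'   `label` and `source_id` columns), `features`, and `provenance`.
#' @export
assemble_training_set <- function(db, records, annotations, scheme,
                                  identity_threshold = 0.40,
                                  exclude = NULL, seed = 1L) {
  if (is.character(scheme)) scheme <- scheme_spec(scheme)
  pos_ids <- switch(scheme$positive_source,
    UNCLASSIFIED_high_medium =
      class_proteins(db, "UNCLASSIFIED", c("High", "Medium")),
    SEC = class_proteins(db, "SEC")
  )
  neg_ids <- unlist(lapply(scheme$negative_source, class_proteins, db = db))
  pos_ids <- setdiff(pos_ids, exclude)
  neg_ids <- setdiff(neg_ids, exclude)
  if (!length(pos_ids)) stop("empty positive pool (",
                             scheme$positive_source, ")", call. = FALSE)
  if (!length(neg_ids)) {
    stop("empty negative pool (",
         paste(scheme$negative_source, collapse = "+"), ")", call. = FALSE)
  }
  take <- function(ids) records[records$id %in% ids, , drop = FALSE]
  pos <- reduce_redundancy(take(pos_ids), identity_threshold)
  neg <- reduce_redundancy(take(neg_ids), identity_threshold)
  mean_sp <- if (scheme$negative_modification != "none" ||
                 startsWith(scheme$positive_modification, "dup")) {
    tryCatch(mean_sp_length(annotations), error = function(e) NA_integer_)
  } else {
    NA_integer_
  }

  pos$source_id <- pos$id
  neg$source_id <- neg$id
  pos <- switch(scheme$positive_modification,
    none = pos,
    sp_removed = remove_signal_peptide(pos, sp_end_for(pos$id, annotations)),
    sp_removed_met_restored =
      remove_signal_peptide(pos, sp_end_for(pos$id, annotations),
                            restore_met = TRUE),
    duplicated_intact_plus_sp_removed = {
      modded <- remove_signal_peptide(pos, sp_end_for(pos$id, annotations))
      modded$id <- paste0(modded$id, "|sp_removed")
      modded$modified <- "sp_removed"
      dup <- pos
      dup$modified <- "duplicated_copy"
      dplyr::bind_rows(dup, modded)
    }
  )
  neg <- switch(scheme$negative_modification,
    none = neg,
    mean_sp_prefix_removed = remove_prefix(neg, mean_sp),
    duplicated_intact_plus_prefix_removed = {
      modded <- remove_prefix(neg, mean_sp)
      modded$id <- paste0(modded$id, "|prefix_removed")
      dup <- neg
      dup$modified <- "duplicated_copy"
      dplyr::bind_rows(dup, modded)
    }
  )
  pos$label <- "positive"
  neg$label <- "negative"
  recs <- dplyr::bind_rows(pos, neg)
  structure(
    list(
      records = recs,
      features = extract_features(recs),
      provenance = list(scheme = scheme,
                        identity_threshold = identity_threshold,
                        seed = as.integer(seed),
                        mean_sp_length = mean_sp)
    ),
    class = "lsp_dataset"
  )
}

#' Construct a labelled dataset directly from records
#'
#' Builds an `lsp_dataset` from already-labelled records (used by the
#' synthetic benchmark and by callers that bypass database assembly).
#'
#' @param records Protein record tibble.
#' @param label Character vector `"positive"`/`"negative"` (recycled).
#' @param provenance Optional provenance list.
#' @return An `lsp_dataset`.
#' @export
labelled_dataset <- function(records, label, provenance = list()) {
  stopifnot(all(label %in% c("positive", "negative")))
  recs <- records
  recs$label <- rep_len(label, nrow(recs))
  if (!"source_id" %in% names(recs)) recs$source_id <- recs$id
  if (length(unique(recs$label)) < 2L) {
    stop("dataset must contain both classes", call. = FALSE)
  }
  structure(
    list(records = recs, features = extract_features(recs),
         provenance = provenance),
    class = "lsp_dataset"
  )
}

#' @export
print.lsp_dataset <- function(x, ...) {
  tab <- table(x$records$label)
  cat("Labelled dataset:", nrow(x$records), "records (",
      tab[["positive"]], "positive /", tab[["negative"]], "negative ),",
      ncol(x$features) - 1L, "features\n")
  if (!is.null(x$provenance$scheme)) {
    cat("Scheme:", x$provenance$scheme$name, "\n")
  }
  invisible(x)
}

subset_dataset <- function(dataset, idx) {
  structure(
    list(records = dataset$records[idx, , drop = FALSE],
         features = dataset$features[idx, , drop = FALSE],
         provenance = dataset$provenance),
    class = "lsp_dataset"
  )
}
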