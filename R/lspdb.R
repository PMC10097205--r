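# Gene classification into the database categories and tiered evidence
# scoring of UNCLASSIFIED proteins (the LSP candidates).

CATEGORY_LEVELS <- c("SEC", "SPT", "UNCLASSIFIED", "NONSEC",
                     "SECRETORY_ISOFORM", "TM_ONLY")

#' Classify one gene from its isoform annotations
#'
#' A gene's isoforms are compared on the classifying secretory features
#' (signal peptide or GPI anchor). Genes whose isoforms disagree are
#' `SECRETORY_ISOFORM` and not categorised further; genes whose only
#' secretory feature is one or more transmembrane domains are `TM_ONLY`.
#' The remainder split on features x observation: `SEC` (features,
#' observed), `SPT` (features, unobserved), `UNCLASSIFIED` (no features,
#' observed; the LSP candidates) and `NONSEC` (neither). A gene counts as
#' observed if any isoform is observed.
#'
#' @param isoforms Annotation tibble rows sharing one `gene_id`.
#' @return Character scalar, one of
#'   `SEC, SPT, UNCLASSIFIED, NONSEC, SECRETORY_ISOFORM, TM_ONLY`.
#' @export
classify_gene <- function(isoforms) {
  if (nrow(isoforms) == 0L) {
    stop("classify_gene: empty isoform set", call. = FALSE)
  }
  if ("gene_id" %in% names(isoforms) &&
      length(unique(isoforms$gene_id)) > 1L) {
    stop("classify_gene: isoforms span multiple genes", call. = FALSE)
  }
  feat <- isoforms$has_sp | isoforms$has_gpi
  observed <- any(isoforms$observed)
  if (length(unique(feat)) > 1L) return("SECRETORY_ISOFORM")
  has_feat <- feat[1L]
  if (!has_feat && any(isoforms$tmd_count > 0L)) return("TM_ONLY")
  if (has_feat) {
    if (observed) "SEC" else "SPT"
  } else {
    if (observed) "UNCLASSIFIED" else "NONSEC"
  }
}

#' Classify every gene in an annotation table
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param observations Optional character vector of observed gene ids,
#'   merged (OR) into the per-isoform `observed` flags.
#' @return Tibble with columns `gene_id`, `label`; one row per gene.
#' @export
classify_genes <- function(annotations, observations = NULL) {
  a <- annotations
  if (!is.null(observations)) {
    a$observed <- a$observed | a$gene_id %in% observations
  }
  a |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(label = classify_gene(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
}

#' Build per-protein interaction profiles
#'
#' Counts, for every known protein, its SEC and NONSEC interaction
#' partners (partners classified by the category of their gene) and
#' collects its SPT partners. Edges are undirected; self edges set the
#' `self_interaction` (homodimer) flag and are excluded from partner
#' counts.
#'
#' @param edges Tibble with columns `protein_id_a`, `protein_id_b`.
#' @param classes Gene classification tibble from [classify_genes()].
#' @param protein_gene Tibble with columns `protein_id`, `gene_id` mapping
#'   every protein to its gene.
#' @return Tibble with columns `protein_id`, `n_sec_partners`,
#'   `n_nonsec_partners`, `spt_partners` (list), `self_interaction`.
#' @export
build_interaction_profiles <- function(edges, classes, protein_gene) {
  known <- protein_gene$protein_id
  offenders <- setdiff(unique(c(edges$protein_id_a, edges$protein_id_b)),
                       known)
  if (length(offenders)) {
    stop("edge list references unknown protein id(s): ",
         paste(utils::head(offenders, 10L), collapse = ", "),
         call. = FALSE)
  }
  class_of <- protein_class_map(classes, protein_gene)
  self <- edges$protein_id_a == edges$protein_id_b
  homodimer <- unique(edges$protein_id_a[self])
  e <- edges[!self, , drop = FALSE]
  # undirected: count each edge from both ends
  long <- tibble::tibble(
    protein_id = c(e$protein_id_a, e$protein_id_b),
    partner = c(e$protein_id_b, e$protein_id_a)
  ) |> dplyr::distinct()
  long$partner_class <- class_of[long$partner]
  prof <- long |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_sec_partners = sum(.data$partner_class == "SEC"),
      n_nonsec_partners = sum(.data$partner_class == "NONSEC"),
      spt_partners = list(.data$partner[.data$partner_class == "SPT"]),
      .groups = "drop"
    )
  all_prof <- tibble::tibble(protein_id = known) |>
    dplyr::left_join(prof, by = "protein_id") |>
    dplyr::mutate(
      n_sec_partners = dplyr::coalesce(.data$n_sec_partners, 0L),
      n_nonsec_partners = dplyr::coalesce(.data$n_nonsec_partners, 0L),
      spt_partners = purrr::map(.data$spt_partners,
                                \(x) if (is.null(x)) character() else x),
      self_interaction = .data$protein_id %in% homodimer
    )
  all_prof
}

protein_class_map <- function(classes, protein_gene) {
  gl <- stats::setNames(classes$label, classes$gene_id)
  stats::setNames(unname(gl[protein_gene$gene_id]),
                  protein_gene$protein_id)
}

#' Network evidence tier for an UNCLASSIFIED protein
#'
#' Tiers are evaluated highest first; the first match gives the points.
#' Tier 3 (3 points): more than one SEC partner and at most
#' `nonsec_cutoff` NONSEC partners. Tier 2 (2 points): more than one SEC
#' partner but more than `nonsec_cutoff` NONSEC partners. Tier 1
#' (1 point): some SPT partner whose own profile has more than one SEC
#' partner and zero NONSEC partners. Otherwise 0.
#'
#' @param profile One-row profile (from [build_interaction_profiles()])
#'   of an UNCLASSIFIED protein.
#' @param all_profiles Profile tibble for all proteins (needed for the
#'   Tier-1 SPT-partner test).
#' @param nonsec_cutoff NONSEC-partner cutoff separating Tiers 3 and 2
#'   (default 33; a corpus-derived constant that other datasets should
#'   retune).
#' @return Integer points in 0..3.
#' @export
network_tier <- function(profile, all_profiles, nonsec_cutoff = 33L) {
  if (profile$n_sec_partners > 1L) {
    return(if (profile$n_nonsec_partners <= nonsec_cutoff) 3L else 2L)
  }
  spt <- profile$spt_partners[[1L]]
  if (length(spt)) {
    pp <- all_profiles[match(spt, all_profiles$protein_id), , drop = FALSE]
    if (any(pp$n_sec_partners > 1L & pp$n_nonsec_partners == 0L,
            na.rm = TRUE)) {
      return(1L)
    }
  }
  0L
}

#' Annotation (PFAM/GO) evidence tier for an UNCLASSIFIED protein
#'
#' For each accession the query carries, the set of categories of all its
#' carrier proteins decides the tier; the highest tier over the query's
#' accessions is returned. Tier 3 (3 points): some accession whose
#' carriers are only SEC and UNCLASSIFIED proteins (with at least one SEC
#' carrier). Tier 2 (2 points): carriers only SEC, SPT and UNCLASSIFIED
#' (at least one SEC or SPT). Tier 1 (1 point): accession predominantly
#' in SEC/SPT — at least `predominance` of its carriers are SEC or SPT
#' and at least one carrier is SEC. Otherwise 0.
#'
#' @param protein_id Query protein id (must be UNCLASSIFIED).
#' @param assignments Tibble with columns `protein_id`, `accession`
#'   (PFAM-domain or GO-term assignments for all proteins).
#' @param classes Gene classification tibble from [classify_genes()].
#' @param protein_gene Protein-to-gene map tibble.
#' @param predominance Carrier fraction for Tier 1 (default 0.5).
#' @return Integer points in 0..3.
#' @export
annotation_tier <- function(protein_id, assignments, classes, protein_gene,
                            predominance = 0.5) {
  class_of <- protein_class_map(classes, protein_gene)
  accs <- assignments$accession[assignments$protein_id == protein_id]
  if (length(accs) == 0L) return(0L)
  best <- 0L
  for (acc in unique(accs)) {
    carriers <- unique(assignments$protein_id[assignments$accession == acc])
    cls <- unname(class_of[carriers])
    tier <- accession_tier(cls, predominance)
    best <- max(best, tier)
    if (best == 3L) break
  }
  best
}

accession_tier <- function(carrier_classes, predominance = 0.5) {
  cls <- carrier_classes[!is.na(carrier_classes)]
  if (!length(cls)) return(0L)
  if (all(cls %in% c("SEC", "UNCLASSIFIED")) && any(cls == "SEC")) {
    return(3L)
  }
  if (all(cls %in% c("SEC", "SPT", "UNCLASSIFIED")) &&
      any(cls %in% c("SEC", "SPT"))) {
    return(2L)
  }
  if (mean(cls %in% c("SEC", "SPT")) >= predominance && any(cls == "SEC")) {
    return(1L)
  }
  0L
}

#' Combine evidence tiers into a confidence score
#'
#' The total is the sum of the three per-category tier points (network,
#' PFAM, GO; each the single highest qualifying tier, 0-3). Confidence is
#' `High` for totals of at least 5, `Medium` for 3-4, `Low` below 3. A
#' homodimer (self-interaction) is annotated as worth 0.5 points but is
#' recorded only — it never changes the total or the confidence label.
#'
#' @param network_tier,pfam_tier,go_tier Integer points in 0..3.
#' @param homodimer Logical self-interaction flag.
#' @param protein_id Optional id carried through to the output.
#' @return One-row tibble with columns `protein_id`, `network_tier`,
#'   `pfam_tier`, `go_tier`, `homodimer`, `total`, `confidence`.
#' @examples
#' score_confidence(3, 0, 2, FALSE)   # total 5, High
#' @export
score_confidence <- function(network_tier, pfam_tier, go_tier,
                             homodimer = FALSE, protein_id = NA_character_) {
  stopifnot(all(c(network_tier, pfam_tier, go_tier) %in% 0:3))
  total <- as.integer(network_tier + pfam_tier + go_tier)
  tibble::tibble(
    protein_id = protein_id,
    network_tier = as.integer(network_tier),
    pfam_tier = as.integer(pfam_tier),
    go_tier = as.integer(go_tier),
    homodimer = homodimer,
    total = total,
    confidence = confidence_label(total)
  )
}

confidence_label <- function(total) {
  dplyr::case_when(
    total >= 5 ~ "High",
    total >= 3 ~ "Medium",
    TRUE ~ "Low"
  )
}

#' Build the LSP database: classify genes and score candidates
#'
#' Runs the full database construction: gene classification, interaction
#' profiling, and tiered network/PFAM/GO evidence scoring of every
#' UNCLASSIFIED protein.
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param observations Optional observed gene-id vector.
#' @param edges Optional PPI edge tibble (`protein_id_a`, `protein_id_b`).
#' @param pfam,go Optional assignment tibbles (`protein_id`, `accession`).
#' @param nonsec_cutoff,predominance Tier-rule parameters (see
#'   [network_tier()] and [annotation_tier()]).
#' @return An object of class `lspdb`: a list with `classes` (gene, label),
#'   `scores` (per-UNCLASSIFIED-protein evidence scores), `profiles`,
#'   `protein_gene` and `summary` (class and confidence counts).
#' @export
build_lspdb <- function(annotations, observations = NULL, edges = NULL,
                        pfam = NULL, go = NULL, nonsec_cutoff = 33L,
                        predominance = 0.5) {
  a <- annotations
  if (!is.null(observations)) {
    a$observed <- a$observed | a$gene_id %in% observations
  }
  classes <- classify_genes(a)
  protein_gene <- dplyr::distinct(a[, c("protein_id", "gene_id")])
  class_of <- protein_class_map(classes, protein_gene)
  if (is.null(edges)) {
    edges <- tibble::tibble(protein_id_a = character(),
                            protein_id_b = character())
  }
  profiles <- build_interaction_profiles(edges, classes, protein_gene)
  uncl <- protein_gene$protein_id[class_of[protein_gene$protein_id] ==
                                    "UNCLASSIFIED"]
  empty_assign <- tibble::tibble(protein_id = character(),
                                 accession = character())
  if (is.null(pfam)) pfam <- empty_assign
  if (is.null(go)) go <- empty_assign
  scores <- purrr::map_dfr(uncl, function(pid) {
    prof <- profiles[profiles$protein_id == pid, , drop = FALSE]
    nt <- network_tier(prof, profiles, nonsec_cutoff)
    pt <- annotation_tier(pid, pfam, classes, protein_gene, predominance)
    gt <- annotation_tier(pid, go, classes, protein_gene, predominance)
    score_confidence(nt, pt, gt, homodimer = prof$self_interaction,
                     protein_id = pid)
  })
  if (nrow(scores) == 0L) {
    scores <- score_confidence(0, 0, 0)[0, ]
  }
  structure(
    list(
      classes = classes,
      scores = scores,
      profiles = profiles,
      protein_gene = protein_gene,
      summary = list(
        class_counts = table(factor(classes$label,
                                    levels = CATEGORY_LEVELS)),
        confidence_counts = table(factor(scores$confidence,
                                         levels = c("High", "Medium",
                                                    "Low")))
      )
    ),
    class = "lspdb"
  )
}

#' @export
print.lspdb <- function(x, ...) {
  cat("LSP database:", nrow(x$classes), "genes,",
      nrow(x$protein_gene), "proteins\n")
  cat("Gene classes:\n")
  print(x$summary$class_counts)
  cat("UNCLASSIFIED confidence:\n")
  print(x$summary$confidence_counts)
  invisible(x)
}

#' Proteins of a database class
#'
#' Convenience selector returning the protein ids whose gene carries a
#' given category label, optionally restricted (for UNCLASSIFIED) to a
#' set of confidence labels.
#'
#' @param db An `lspdb` object.
#' @param label Category label (e.g. `"SEC"`).
#' @param confidence Optional confidence filter, e.g. `c("High","Medium")`.
#' @return Character vector of protein ids.
#' @export
class_proteins <- function(db, label, confidence = NULL) {
  class_of <- protein_class_map(db$classes, db$protein_gene)
  ids <- db$protein_gene$protein_id[class_of[db$protein_gene$protein_id] ==
                                      label]
  if (!is.null(confidence)) {
    keep <- db$scores$protein_id[db$scores$confidence %in% confidence]
    ids <- intersect(ids, keep)
  }
  ids
}

#' Export database tables
#'
#' Writes `lspdb_classes.tsv`, `lspdb_scores.tsv` and `summary.txt` to a
#' directory.
#'
#' @param db An `lspdb` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lspdb <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(db$classes, file.path(dir, "lspdb_classes.tsv"))
  readr::write_tsv(db$scores, file.path(dir, "lspdb_scores.tsv"))
  lines <- c(
    "Gene class counts:",
    paste0("  ", names(db$summary$class_counts), "\t",
           as.integer(db$summary$class_counts)),
    "UNCLASSIFIED confidence counts:",
    paste0("  ", names(db$summary$confidence_counts), "\t",
           as.integer(db$summary$confidence_counts))
  )
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
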