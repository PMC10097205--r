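# Synthetic proteome generator: fixture data with planted signal
# peptides, LSP-like compositional shifts, and annotation/PPI/PFAM/GO
# tables wired so that designated candidate proteins satisfy each
# evidence tier exactly. Ground truth is always emitted alongside.

#' Synthetic proteome configuration
#'
#' Defaults emulate the statistical structure the pipeline assumes:
#' classes with and without signal peptides, an LSP-like candidate class
#' separable by a compositional shift (glycine by default), and
#' background sequences with Swiss-Prot-like residue frequencies.
#' Lengths are normal (mean 300, sd 80) truncated at 50. The signal
#' peptide model follows textbook architecture: initiator methionine, a
#' short K/R-enriched n-region (2-5 residues), a hydrophobic h-region
#' (7-15 residues from A/I/L/F/V/M/W) and a c-region (3-7 residues)
#' ending in an A-X-A cleavage motif.
#'
#' @param n_sec,n_spt,n_unclassified,n_nonsec Class sizes.
#' @param n_tm_only,n_secretory_isoform Extra classes for classification
#'   round trips (TM-only genes; genes with discordant isoforms).
#' @param length_mean,length_sd,length_min Mature-sequence length model.
#' @param background Residue frequencies (sum 1).
#' @param sp_n_region,sp_h_region,sp_c_region Signal-peptide region
#'   length ranges (inclusive).
#' @param sp_hydrophobic Residues forming the h-region.
#' @param lsp_shift_residues,lsp_shift_delta Residues up-weighted in the
#'   candidate (LSP-like) class and the total frequency mass added.
#' @param tiers Named list `network`, `pfam`, `go`, each a vector
#'   `c(t1 =, t2 =, t3 =)` giving how many designated UNCLASSIFIED
#'   proteins should satisfy exactly that tier.
#' @param n_homodimer Number of homodimer-only candidates.
#' @param observed_noise Probability of flipping an observation flag.
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_sec = 40L, n_spt = 40L, n_unclassified = 60L,
                         n_nonsec = 600L, n_tm_only = 0L,
                         n_secretory_isoform = 0L,
                         length_mean = 300, length_sd = 80,
                         length_min = 50,
                         background = background_frequencies(),
                         sp_n_region = c(2L, 5L),
                         sp_h_region = c(7L, 15L),
                         sp_c_region = c(3L, 7L),
                         sp_hydrophobic = c("A", "I", "L", "F", "V",
                                            "M", "W"),
                         lsp_shift_residues = "G",
                         lsp_shift_delta = 0.10,
                         tiers = list(network = c(t1 = 0, t2 = 0, t3 = 0),
                                      pfam = c(t1 = 0, t2 = 0, t3 = 0),
                                      go = c(t1 = 0, t2 = 0, t3 = 0)),
                         n_homodimer = 0L, observed_noise = 0,
                         seed = 1L) {
  stopifnot(abs(sum(background) - 1) < 1e-8,
            all(lsp_shift_residues %in% AA_ORDER),
            lsp_shift_delta >= 0, length_min >= 1,
            sp_c_region[1] >= 3L)
  cfg <- as.list(environment())
  shifted <- shift_frequencies(background, lsp_shift_residues,
                               lsp_shift_delta)
  if (any(shifted < 0) || abs(sum(shifted) - 1) > 1e-8) {
    stop("invalid shifted frequencies", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

shift_frequencies <- function(background, residues, delta) {
  f <- background[AA_ORDER]
  target <- sum(f[residues]) + delta
  if (target > 1) stop("invalid shifted frequencies", call. = FALSE)
  f[residues] <- f[residues] * (target / sum(f[residues]))
  others <- setdiff(AA_ORDER, residues)
  f[others] <- f[others] * ((1 - target) / sum(f[others]))
  f
}

sample_lengths <- function(n, config) {
  pmax(config$length_min, round(stats::rnorm(n, config$length_mean,
                                             config$length_sd)))
}

sample_seqs <- function(n, config, freqs, prefix = "bg") {
  lens <- sample_lengths(n, config)
  seqs <- vapply(lens, function(l) {
    paste(sample(AA_ORDER, l, replace = TRUE, prob = freqs),
          collapse = "")
  }, "")
  protein_records(sprintf("%s_%04d", prefix, seq_len(n)), seqs)
}

#' Sample background protein records
#'
#' i.i.d. residues from the configured background frequencies.
#'
#' @param n Number of records.
#' @param config A [synth_config()].
#' @param seed Optional seed (set for standalone reproducibility).
#' @param prefix Id prefix.
#' @return Protein record tibble.
#' @export
sample_background <- function(n, config = synth_config(), seed = NULL,
                              prefix = "bg") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n == 0L) return(protein_records(character(), character()))
  sample_seqs(n, config, config$background[AA_ORDER], prefix)
}

#' Sample LSP-like protein records
#'
#' Background frequencies with the configured residue set up-weighted by
#' the shift delta (other residues rescaled), giving a compositionally
#' separable candidate class.
#'
#' @inheritParams sample_background
#' @return Protein record tibble.
#' @export
sample_lsp_like <- function(n, config = synth_config(), seed = NULL,
                            prefix = "lsp") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n == 0L) return(protein_records(character(), character()))
  freqs <- shift_frequencies(config$background, config$lsp_shift_residues,
                             config$lsp_shift_delta)
  sample_seqs(n, config, freqs, prefix)
}

#' Plant a signal peptide onto records
#'
#' Prepends `M` + n-region + h-region + c-region to each sequence, with
#' region lengths drawn uniformly from the configured ranges. The
#' n-region is K/R-enriched, the h-region is drawn from the hydrophobic
#' set (so the SP region is more hydrophobic than the mature region in
#' expectation) and the c-region ends in the A-X-A cleavage motif.
#'
#' @param records Protein record tibble (the mature sequences).
#' @param config A [synth_config()].
#' @param seed Optional seed.
#' @return List with `records` (SP-bearing) and `sp_end` (integer vector
#'   of 1-based SP end positions).
#' @export
plant_signal_peptide <- function(records, config = synth_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(records)
  sp <- character(n)
  for (i in seq_len(n)) {
    n_len <- sample(config$sp_n_region[1]:config$sp_n_region[2], 1L)
    h_len <- sample(config$sp_h_region[1]:config$sp_h_region[2], 1L)
    c_len <- sample(config$sp_c_region[1]:config$sp_c_region[2], 1L)
    n_reg <- ifelse(stats::runif(n_len) < 0.7,
                    sample(c("K", "R"), n_len, replace = TRUE),
                    sample(AA_ORDER, n_len, replace = TRUE,
                           prob = config$background[AA_ORDER]))
    h_reg <- sample(config$sp_hydrophobic, h_len, replace = TRUE)
    c_core <- sample(AA_ORDER, c_len - 3L, replace = TRUE,
                     prob = config$background[AA_ORDER])
    x <- sample(AA_ORDER, 1L, prob = config$background[AA_ORDER])
    sp[i] <- paste0("M", paste(n_reg, collapse = ""),
                    paste(h_reg, collapse = ""),
                    paste(c_core, collapse = ""), "A", x, "A")
  }
  out <- records
  out$sequence <- paste0(sp, records$sequence)
  list(records = out, sp_end = nchar(sp))
}

#' Generate a complete synthetic fixture
#'
#' Builds records for every database class, the annotation table, and
#' PPI/PFAM/GO tables wired so that the configured numbers of
#' UNCLASSIFIED proteins satisfy each evidence tier exactly (each
#' designated protein satisfies one tier in one category). SEC and
#' UNCLASSIFIED genes are observed; SPT, NONSEC and TM-only are not.
#' Ground-truth classes and tier labels are emitted alongside so every
#' downstream test is self-checking.
#'
#' @param config A [synth_config()].
#' @return List of class `lsp_fixture`: `records`, `annotations`,
#'   `edges`, `pfam`, `go`, `ground_truth`, `config`.
#' @export
generate_fixture <- function(config = synth_config()) {
  set.seed(as.integer(config$seed))
  sec_m <- sample_background(config$n_sec, config, prefix = "SEC")
  sec_pl <- plant_signal_peptide(sec_m, config)
  spt_m <- sample_background(config$n_spt, config, prefix = "SPT")
  spt_pl <- plant_signal_peptide(spt_m, config)
  uncl <- sample_lsp_like(config$n_unclassified, config, prefix = "UNC")
  nons <- sample_background(config$n_nonsec, config, prefix = "NON")
  tm <- sample_background(config$n_tm_only, config, prefix = "TM")
  iso <- if (config$n_secretory_isoform > 0L) {
    base <- sample_background(config$n_secretory_isoform, config,
                              prefix = "ISO")
    with_sp <- plant_signal_peptide(base, config)
    alt <- base
    alt$id <- paste0(base$id, ".2")
    alt$gene_id <- base$gene_id
    sp_rec <- with_sp$records
    sp_rec$id <- paste0(base$id, ".1")
    sp_rec$gene_id <- base$gene_id
    list(records = dplyr::bind_rows(sp_rec, alt),
         sp_end = with_sp$sp_end, gene = base$gene_id)
  }
  records <- dplyr::bind_rows(
    sec_pl$records, spt_pl$records, uncl, nons, tm,
    if (!is.null(iso)) iso$records
  )

  ann_row <- function(recs, has_sp, sp_end, tmd, gpi, observed) {
    pos <- if (has_sp) as.integer(sp_end) else NA_integer_
    tibble::tibble(
      protein_id = recs$id, gene_id = recs$gene_id,
      has_sp = has_sp, sp_cleavage_pos = pos,
      tmd_count = as.integer(tmd), has_gpi = gpi, observed = observed
    )
  }
  annotations <- dplyr::bind_rows(
    ann_row(sec_pl$records, TRUE, sec_pl$sp_end, 0L, FALSE, TRUE),
    ann_row(spt_pl$records, TRUE, spt_pl$sp_end, 0L, FALSE, FALSE),
    ann_row(uncl, FALSE, NA, 0L, FALSE, TRUE),
    ann_row(nons, FALSE, NA, 0L, FALSE, FALSE),
    if (config$n_tm_only > 0L) {
      ann_row(tm, FALSE, NA, sample(1:3, config$n_tm_only, TRUE), FALSE,
              FALSE)
    },
    if (!is.null(iso)) dplyr::bind_rows(
      ann_row(iso$records[seq_len(config$n_secretory_isoform), ], TRUE,
              iso$sp_end, 0L, FALSE, TRUE),
      ann_row(iso$records[-seq_len(config$n_secretory_isoform), ], FALSE,
              NA, 0L, FALSE, TRUE)
    )
  )
  if (config$observed_noise > 0) {
    flip <- stats::runif(nrow(annotations)) < config$observed_noise
    annotations$observed <- xor(annotations$observed, flip)
  }

  # evidence wiring: each designated candidate satisfies one tier in one
  # category; everyone else carries no evidence
  tiers <- config$tiers
  need <- sum(unlist(tiers)) + config$n_homodimer
  if (need > config$n_unclassified) {
    stop("tier designations exceed the number of UNCLASSIFIED proteins",
         call. = FALSE)
  }
  if (any(unlist(tiers) > 0) &&
      (config$n_sec < 2L || config$n_spt < 3L || config$n_nonsec < 34L)) {
    stop("tier wiring needs >= 2 SEC, >= 3 SPT and >= 34 NONSEC",
         call. = FALSE)
  }
  pool <- uncl$id
  take_ids <- function(k) {
    ids <- utils::head(pool, k)
    pool <<- utils::tail(pool, -k)
    ids
  }
  edges <- list(); pfam <- list(); go <- list(); truth <- list()
  mark <- function(ids, cat, tier) {
    if (length(ids)) {
      truth[[length(truth) + 1L]] <<- tibble::tibble(
        protein_id = ids, category = cat, tier = tier
      )
    }
    ids
  }
  sec_ids <- sec_pl$records$id; spt_ids <- spt_pl$records$id
  non_ids <- nons$id
  # network tier 3: >1 SEC, 0 NONSEC partners
  for (id in mark(take_ids(tiers$network[["t3"]]), "network", 3L)) {
    edges[[length(edges) + 1L]] <- tibble::tibble(
      protein_id_a = id, protein_id_b = sec_ids[1:2]
    )
  }
  # network tier 2: >1 SEC, > 33 NONSEC partners
  for (id in mark(take_ids(tiers$network[["t2"]]), "network", 2L)) {
    edges[[length(edges) + 1L]] <- tibble::tibble(
      protein_id_a = id, protein_id_b = c(sec_ids[1:2], non_ids[1:34])
    )
  }
  # network tier 1: an SPT partner whose own profile is >1 SEC, 0 NONSEC
  hub <- spt_ids[1L]
  t1_net <- mark(take_ids(tiers$network[["t1"]]), "network", 1L)
  if (length(t1_net)) {
    edges[[length(edges) + 1L]] <- tibble::tibble(
      protein_id_a = hub, protein_id_b = sec_ids[1:2]
    )
    edges[[length(edges) + 1L]] <- tibble::tibble(
      protein_id_a = t1_net, protein_id_b = hub
    )
  }
  for (id in mark(take_ids(config$n_homodimer), "homodimer", 0L)) {
    edges[[length(edges) + 1L]] <- tibble::tibble(
      protein_id_a = id, protein_id_b = id
    )
  }
  wire_assign <- function(kind, label) {
    out <- list()
    for (id in mark(take_ids(tiers[[kind]][["t3"]]), kind, 3L)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        protein_id = c(id, sec_ids[1L]),
        accession = paste0(label, "_T3_", id)
      )
    }
    for (id in mark(take_ids(tiers[[kind]][["t2"]]), kind, 2L)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        protein_id = c(id, sec_ids[1L], spt_ids[2L]),
        accession = paste0(label, "_T2_", id)
      )
    }
    for (id in mark(take_ids(tiers[[kind]][["t1"]]), kind, 1L)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        protein_id = c(id, sec_ids[1L], spt_ids[3L], non_ids[35L]),
        accession = paste0(label, "_T1_", id)
      )
    }
    out
  }
  pfam <- wire_assign("pfam", "PF")
  go <- wire_assign("go", "GO")

  truth_tbl <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(protein_id = character(), category = character(),
                   tier = integer())
  gt <- tibble::tibble(protein_id = uncl$id) |>
    dplyr::mutate(
      network_tier = tier_lookup(truth_tbl, .data$protein_id, "network"),
      pfam_tier = tier_lookup(truth_tbl, .data$protein_id, "pfam"),
      go_tier = tier_lookup(truth_tbl, .data$protein_id, "go"),
      homodimer = .data$protein_id %in%
        truth_tbl$protein_id[truth_tbl$category == "homodimer"],
      total = .data$network_tier + .data$pfam_tier + .data$go_tier,
      confidence = confidence_label(.data$total)
    )
  class_truth <- tibble::tibble(
    gene_id = c(sec_pl$records$gene_id, spt_pl$records$gene_id,
                uncl$gene_id, nons$gene_id, tm$gene_id,
                if (!is.null(iso)) iso$gene),
    class = c(rep("SEC", config$n_sec), rep("SPT", config$n_spt),
              rep("UNCLASSIFIED", config$n_unclassified),
              rep("NONSEC", config$n_nonsec),
              rep("TM_ONLY", config$n_tm_only),
              rep("SECRETORY_ISOFORM", config$n_secretory_isoform))
  )
  structure(
    list(
      records = records,
      annotations = annotations,
      edges = if (length(edges)) dplyr::bind_rows(edges) else
        tibble::tibble(protein_id_a = character(),
                       protein_id_b = character()),
      pfam = if (length(pfam)) dplyr::bind_rows(pfam) else
        tibble::tibble(protein_id = character(), accession = character()),
      go = if (length(go)) dplyr::bind_rows(go) else
        tibble::tibble(protein_id = character(), accession = character()),
      ground_truth = list(classes = class_truth, scores = gt),
      config = config
    ),
    class = "lsp_fixture"
  )
}

tier_lookup <- function(truth, ids, cat) {
  sub <- truth[truth$category == cat, , drop = FALSE]
  out <- sub$tier[match(ids, sub$protein_id)]
  as.integer(dplyr::coalesce(out, 0L))
}

#' Write a fixture to disk
#'
#' FASTA plus all annotation/evidence TSVs and the ground-truth tables.
#'
#' @param fixture An `lsp_fixture`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixture$records, file.path(dir, "proteome.fasta"))
  ann <- fixture$annotations
  ann$sp_cleavage_pos <- ifelse(is.na(ann$sp_cleavage_pos), "-",
                                as.character(ann$sp_cleavage_pos))
  readr::write_tsv(ann, file.path(dir, "annotations.tsv"))
  readr::write_tsv(fixture$edges, file.path(dir, "ppi.tsv"))
  readr::write_tsv(fixture$pfam, file.path(dir, "pfam.tsv"))
  readr::write_tsv(fixture$go, file.path(dir, "go.tsv"))
  readr::write_tsv(fixture$ground_truth$classes,
                   file.path(dir, "ground_truth_classes.tsv"))
  readr::write_tsv(fixture$ground_truth$scores,
                   file.path(dir, "ground_truth_scores.tsv"))
  invisible(dir)
}

#' Synthetic classification benchmark dataset
#'
#' A labelled dataset of LSP-like positives (compositional shift) against
#' background negatives, at the package's reference study conditions
#' (60 positives / 600 negatives, glycine shift +0.10) unless overridden.
#'
#' @param n_pos,n_neg Class sizes.
#' @param config A [synth_config()] providing the length and composition
#'   models.
#' @param seed Integer seed.
#' @return An `lsp_dataset`.
#' @export
synthetic_benchmark <- function(n_pos = 60L, n_neg = 600L,
                                config = synth_config(), seed = 1L) {
  set.seed(as.integer(seed))
  pos <- sample_lsp_like(n_pos, config, prefix = "pos")
  neg <- sample_background(n_neg, config, prefix = "neg")
  labelled_dataset(dplyr::bind_rows(pos, neg),
                   c(rep("positive", n_pos), rep("negative", n_neg)),
                   provenance = list(seed = as.integer(seed),
                                     shift = config$lsp_shift_delta))
}
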