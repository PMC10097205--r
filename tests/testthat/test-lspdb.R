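test_that("gene classification covers the category semantics", {
  expect_equal(classify_gene(ann1("p", has_sp = TRUE, sp_cleavage_pos = 20,
                                  observed = TRUE)), "SEC")
  expect_equal(classify_gene(ann1("p", has_sp = TRUE,
                                  sp_cleavage_pos = 20)), "SPT")
  expect_equal(classify_gene(ann1("p", observed = TRUE)), "UNCLASSIFIED")
  expect_equal(classify_gene(ann1("p")), "NONSEC")
  expect_equal(classify_gene(ann1("p", tmd_count = 3)), "TM_ONLY")
  expect_equal(classify_gene(ann1("p", has_gpi = TRUE, observed = TRUE)),
               "SEC")
  iso <- dplyr::bind_rows(
    ann1("p.1", "g", has_sp = TRUE, sp_cleavage_pos = 18),
    ann1("p.2", "g")
  )
  expect_equal(classify_gene(iso), "SECRETORY_ISOFORM")
  expect_error(classify_gene(ann1(character())), "empty")
  # a gene is observed if any isoform is observed
  two <- dplyr::bind_rows(ann1("q.1", "g2", observed = TRUE),
                          ann1("q.2", "g2"))
  expect_equal(classify_gene(two), "UNCLASSIFIED")
})

test_that("gene labels partition the gene set", {
  ann <- dplyr::bind_rows(
    class_fixture(2, 2, 2, 2),
    ann1("TM_1", tmd_count = 2),
    ann1("ISO_1.1", "ISO_g", has_sp = TRUE, sp_cleavage_pos = 15),
    ann1("ISO_1.2", "ISO_g")
  )
  classes <- classify_genes(ann)
  expect_equal(nrow(classes), length(unique(ann$gene_id)))
  expect_equal(sum(table(classes$label)), nrow(classes))
  expect_setequal(
    classes$label[classes$gene_id %in% c("TM_1", "ISO_g")],
    c("TM_ONLY", "SECRETORY_ISOFORM")
  )
})

test_that("interaction profiles count undirected partners and flag homodimers", {
  ann <- class_fixture()
  classes <- classify_genes(ann)
  pg <- ann[, c("protein_id", "gene_id")]
  edges <- edge_tbl(c("UNC_1", "SEC_2", "UNC_2", "NON_1"),
                    c("SEC_1", "UNC_1", "UNC_2", "UNC_1"))
  prof <- build_interaction_profiles(edges, classes, pg)
  u1 <- prof[prof$protein_id == "UNC_1", ]
  expect_equal(u1$n_sec_partners, 2L) # counted from both edge directions
  expect_equal(u1$n_nonsec_partners, 1L)
  u2 <- prof[prof$protein_id == "UNC_2", ]
  expect_true(u2$self_interaction)
  expect_equal(u2$n_sec_partners + u2$n_nonsec_partners, 0L)
  zero <- prof[prof$protein_id == "NON_2", ]
  expect_equal(zero$n_sec_partners, 0L)
  expect_false(zero$self_interaction)
  expect_error(
    build_interaction_profiles(edge_tbl("ghost", "UNC_1"), classes, pg),
    "ghost"
  )
})

test_that("network tiers follow the partner-count rules, highest first", {
  mk_prof <- function(n_sec, n_non, spt = character()) {
    tibble::tibble(protein_id = "q", n_sec_partners = n_sec,
                   n_nonsec_partners = n_non, spt_partners = list(spt),
                   self_interaction = FALSE)
  }
  all_prof <- tibble::tibble(
    protein_id = c("spt_hub", "spt_weak"),
    n_sec_partners = c(3L, 1L), n_nonsec_partners = c(0L, 0L),
    spt_partners = list(character(), character()),
    self_interaction = FALSE
  )
  expect_equal(network_tier(mk_prof(2, 0), all_prof), 3L)
  expect_equal(network_tier(mk_prof(2, 33), all_prof), 3L) # boundary
  expect_equal(network_tier(mk_prof(2, 40), all_prof), 2L)
  expect_equal(network_tier(mk_prof(1, 0), all_prof), 0L)
  expect_equal(network_tier(mk_prof(0, 0, "spt_hub"), all_prof), 1L)
  expect_equal(network_tier(mk_prof(0, 0, "spt_weak"), all_prof), 0L)
})

test_that("annotation tiers respect exclusivity then predominance", {
  ann <- class_fixture(2, 2, 2, 2)
  classes <- classify_genes(ann)
  pg <- ann[, c("protein_id", "gene_id")]
  tier_of <- function(assignments) {
    annotation_tier("UNC_1", assignments, classes, pg)
  }
  expect_equal(tier_of(assign_tbl(c("UNC_1", "SEC_1"), "PF1")), 3L)
  expect_equal(tier_of(assign_tbl(c("UNC_1", "SEC_1", "SPT_1"), "PF2")), 2L)
  # SEC+SPT+NONSEC carriers: 2/4 in SEC/SPT meets the 0.5 predominance
  expect_equal(tier_of(assign_tbl(c("UNC_1", "SEC_1", "SPT_1", "NON_1"),
                                  "PF3")), 1L)
  # NONSEC-heavy usage fails all tiers
  expect_equal(tier_of(assign_tbl(c("UNC_1", "SEC_1", "NON_1", "NON_2"),
                                  "PF4")), 0L)
  # no SEC carrier: exclusivity to UNCLASSIFIED alone earns nothing
  expect_equal(tier_of(assign_tbl("UNC_1", "PF5")), 0L)
  # the best accession wins
  expect_equal(tier_of(assign_tbl(c("UNC_1", "SEC_1", "NON_1", "NON_2",
                                    "UNC_1", "SEC_1"),
                                  c("PF4", "PF4", "PF4", "PF4",
                                    "PF6", "PF6"))), 3L)
})

test_that("confidence boundaries and the homodimer annotation behave as documented", {
  expect_equal(score_confidence(3, 0, 2)$total, 5L)
  expect_equal(score_confidence(3, 0, 2)$confidence, "High")
  expect_equal(score_confidence(0, 3, 0)$confidence, "Medium")
  expect_equal(score_confidence(2, 0, 2)$confidence, "Medium")
  expect_equal(score_confidence(0, 0, 2)$confidence, "Low")
  hd <- score_confidence(0, 0, 0, homodimer = TRUE)
  expect_equal(hd$confidence, "Low")
  expect_true(hd$homodimer)
  # the homodimer flag never changes a confidence label
  for (nt in 0:3) for (pt in 0:3) for (gt in 0:3) {
    expect_equal(score_confidence(nt, pt, gt, TRUE)$confidence,
                 score_confidence(nt, pt, gt, FALSE)$confidence)
  }
})

test_that("raising one tier never lowers the total or demotes confidence", {
  rank <- c(Low = 1, Medium = 2, High = 3)
  for (nt in 0:2) for (pt in 0:3) for (gt in 0:3) {
    a <- score_confidence(nt, pt, gt)
    b <- score_confidence(nt + 1, pt, gt)
    expect_gte(b$total, a$total)
    expect_gte(rank[[b$confidence]], rank[[a$confidence]])
  }
})

test_that("tier functions agree with exhaustive predicate evaluation on random fixtures", {
  set.seed(77)
  for (rep in 1:15) {
    n <- 30
    ids <- sprintf("x%02d", 1:n)
    cls_draw <- sample(c("SEC", "SPT", "UNCLASSIFIED", "NONSEC"), n,
                       replace = TRUE, prob = c(.2, .2, .3, .3))
    ann <- ann1(ids, has_sp = FALSE, observed = FALSE)
    ann$has_sp <- cls_draw %in% c("SEC", "SPT")
    ann$sp_cleavage_pos <- ifelse(ann$has_sp, 20L, NA_integer_)
    ann$observed <- cls_draw %in% c("SEC", "UNCLASSIFIED")
    classes <- classify_genes(ann)
    pg <- ann[, c("protein_id", "gene_id")]
    class_of <- stats::setNames(classes$label, classes$gene_id)[ids]
    names(class_of) <- ids
    m <- sample(20:60, 1)
    edges <- edge_tbl(sample(ids, m, TRUE), sample(ids, m, TRUE)) |>
      dplyr::distinct()
    assigns <- assign_tbl(sample(ids, 40, TRUE),
                          sample(paste0("ACC", 1:8), 40, TRUE)) |>
      dplyr::distinct()
    prof <- build_interaction_profiles(edges, classes, pg)
    cutoff <- 2L # small cutoff so both tier-2 and tier-3 arise
    for (pid in ids[class_of == "UNCLASSIFIED"]) {
      got_n <- network_tier(prof[prof$protein_id == pid, ], prof,
                            nonsec_cutoff = cutoff)
      expect_equal(got_n, network_tier_oracle(pid, edges, class_of,
                                              cutoff))
      got_a <- annotation_tier(pid, assigns, classes, pg)
      expect_equal(got_a, annotation_tier_oracle(pid, assigns, class_of))
    }
  }
})

test_that("database construction labels every gene once and scores every candidate", {
  ann <- dplyr::bind_rows(
    class_fixture(2, 2, 2, 2),
    ann1("TM_1", tmd_count = 1),
    ann1("ISO_1.1", "ISO_g", has_sp = TRUE, sp_cleavage_pos = 15),
    ann1("ISO_1.2", "ISO_g")
  )
  edges <- edge_tbl(c("UNC_1", "UNC_1"), c("SEC_1", "SEC_2"))
  go <- assign_tbl(c("UNC_1", "SEC_1", "SPT_1"), "GO:1")
  db <- build_lspdb(ann, edges = edges, go = go)
  expect_s3_class(db, "lspdb")
  expect_equal(sum(db$summary$class_counts), nrow(db$classes))
  expect_equal(sort(db$scores$protein_id), c("UNC_1", "UNC_2"))
  # engineered 3 (network) + 2 (GO) -> exactly one High
  u1 <- db$scores[db$scores$protein_id == "UNC_1", ]
  expect_equal(u1$network_tier, 3L)
  expect_equal(u1$go_tier, 2L)
  expect_equal(u1$total, 5L)
  expect_equal(u1$confidence, "High")
  expect_equal(sum(db$scores$confidence == "High"), 1L)
  # observation lists merge into the observed flags
  db2 <- build_lspdb(ann, observations = c("NON_1"))
  expect_equal(db2$classes$label[db2$classes$gene_id == "NON_1"],
               "UNCLASSIFIED")
  # removing all observations leaves no SEC and no UNCLASSIFIED
  ann_un <- ann
  ann_un$observed <- FALSE
  db3 <- build_lspdb(ann_un)
  expect_equal(unname(db3$summary$class_counts[["SEC"]]), 0L)
  expect_equal(unname(db3$summary$class_counts[["UNCLASSIFIED"]]), 0L)
})

test_that("database export writes the documented tables", {
  dir <- withr::local_tempdir()
  db <- build_lspdb(class_fixture())
  write_lspdb(db, dir)
  expect_true(file.exists(file.path(dir, "lspdb_classes.tsv")))
  back <- readr::read_tsv(file.path(dir, "lspdb_classes.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(db$classes))
  expect_true(file.exists(file.path(dir, "summary.txt")))
})
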