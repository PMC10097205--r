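# Shared fixture builders. Everything is generated in code at test time.

AA20 <- amino_acids()

random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# mutate a fraction of positions, keeping the rest identical
mutate_seq <- function(seq, rate, seed = 1) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  chars[hit] <- sample(AA20, length(hit), replace = TRUE)
  paste(chars, collapse = "")
}

# one-isoform-per-gene annotation row
ann1 <- function(protein_id, gene_id = protein_id, has_sp = FALSE,
                 sp_cleavage_pos = NA_integer_, tmd_count = 0L,
                 has_gpi = FALSE, observed = FALSE) {
  tibble::tibble(protein_id = protein_id, gene_id = gene_id,
                 has_sp = has_sp,
                 sp_cleavage_pos = as.integer(sp_cleavage_pos),
                 tmd_count = as.integer(tmd_count), has_gpi = has_gpi,
                 observed = observed)
}

# minimal multi-class annotation fixture: n proteins per class, 1:1
# gene:protein, ids <CLASS>_<i>
class_fixture <- function(n_sec = 2, n_spt = 2, n_uncl = 2, n_non = 2) {
  mk <- function(class, n, has_sp, observed) {
    if (n == 0) return(NULL)
    ann1(sprintf("%s_%d", class, seq_len(n)),
         has_sp = has_sp,
         sp_cleavage_pos = if (has_sp) 20L else NA_integer_,
         observed = observed)
  }
  dplyr::bind_rows(
    mk("SEC", n_sec, TRUE, TRUE), mk("SPT", n_spt, TRUE, FALSE),
    mk("UNC", n_uncl, FALSE, TRUE), mk("NON", n_non, FALSE, FALSE)
  )
}

edge_tbl <- function(a = character(), b = character()) {
  tibble::tibble(protein_id_a = a, protein_id_b = b)
}

assign_tbl <- function(protein_id = character(), accession = character()) {
  tibble::tibble(protein_id = protein_id, accession = accession)
}

# brute-force Moran autocorrelation (independent of the implementation)
moran_oracle <- function(x, lag) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in 1:(n - lag)) num <- num + (x[i] - xb) * (x[i + lag] - xb)
  num <- num / (n - lag)
  den <- sum((x - xb)^2) / n
  if (den == 0) return(0)
  num / den
}

# brute-force FPR-bounded threshold: try every candidate cutoff, keep the
# feasible one with maximal TPR (ties -> smallest cutoff)
threshold_oracle <- function(scores, label, target) {
  neg <- scores[label == "negative"]
  pos <- scores[label == "positive"]
  cand <- c(sort(unique(scores)), max(neg) + 1e-9)
  fpr <- vapply(cand, function(t) mean(neg >= t), 0)
  tpr <- vapply(cand, function(t) mean(pos >= t), 0)
  feas <- which(fpr <= target)
  best <- feas[which.max(tpr[feas])]
  list(threshold = cand[best], tpr = tpr[best])
}

# independent tier predicates evaluated directly from the raw tables
network_tier_oracle <- function(pid, edges, class_of, cutoff = 33) {
  partners_of <- function(p) {
    setdiff(unique(c(edges$protein_id_b[edges$protein_id_a == p],
                     edges$protein_id_a[edges$protein_id_b == p])), p)
  }
  pt <- partners_of(pid)
  n_sec <- sum(class_of[pt] == "SEC")
  n_non <- sum(class_of[pt] == "NONSEC")
  if (n_sec > 1 && n_non <= cutoff) return(3L)
  if (n_sec > 1 && n_non > cutoff) return(2L)
  for (sp in pt[class_of[pt] == "SPT"]) {
    pt2 <- partners_of(sp)
    if (sum(class_of[pt2] == "SEC") > 1 &&
        sum(class_of[pt2] == "NONSEC") == 0) {
      return(1L)
    }
  }
  0L
}

annotation_tier_oracle <- function(pid, assignments, class_of,
                                   predominance = 0.5) {
  best <- 0L
  for (acc in unique(assignments$accession[assignments$protein_id == pid])) {
    carriers <- unique(assignments$protein_id[assignments$accession == acc])
    cls <- class_of[carriers]
    cls <- cls[!is.na(cls)]
    t <- if (all(cls %in% c("SEC", "UNCLASSIFIED")) && any(cls == "SEC")) {
      3L
    } else if (all(cls %in% c("SEC", "SPT", "UNCLASSIFIED")) &&
               any(cls %in% c("SEC", "SPT"))) {
      2L
    } else if (mean(cls %in% c("SEC", "SPT")) >= predominance &&
               any(cls == "SEC")) {
      1L
    } else {
      0L
    }
    best <- max(best, t)
  }
  best
}

# small labelled dataset with a planted two-feature separation, bypassing
# sequence features (for fast model-level tests)
toy_dataset <- function(n_pos = 20, n_neg = 60, sep = 3, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  lab <- c(rep("positive", n_pos), rep("negative", n_neg))
  f1 <- stats::rnorm(n) + sep * (lab == "positive")
  f2 <- stats::rnorm(n) - sep * (lab == "positive")
  structure(list(
    records = tibble::tibble(id = sprintf("t%03d", seq_len(n)),
                             gene_id = sprintf("t%03d", seq_len(n)),
                             sequence = strrep("A", 10), modified = "intact",
                             source_id = sprintf("t%03d", seq_len(n)),
                             label = lab),
    features = tibble::tibble(protein_id = sprintf("t%03d", seq_len(n)),
                              f1 = f1, f2 = f2,
                              noise = stats::rnorm(n)),
    provenance = list()
  ), class = "lsp_dataset")
}
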