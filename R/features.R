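# Sequence -> fixed-length numeric feature vectors. All features are
# defined on the canonical 20-letter alphabet and are finite for any
# validated sequence of length >= 1.

# map ASCII codes to residue index 1..20 (0 = non-canonical)
AA_LOOKUP <- local({
  lut <- integer(128)
  lut[utf8ToInt(paste(AA_ORDER, collapse = ""))] <-
    seq_along(AA_ORDER)
  lut
})

seq_codes <- function(seq) {
  codes <- AA_LOOKUP[utf8ToInt(seq)]
  if (any(codes == 0L)) {
    stop("sequence contains non-canonical residues; validate first",
         call. = FALSE)
  }
  codes
}

#' Amino-acid composition
#'
#' Residue frequencies over the canonical alphabet; sums to 1.
#'
#' @param seq Validated amino-acid sequence (character scalar).
#' @return Named numeric vector of length 20.
#' @examples
#' aa_composition("ACDG")
#' @export
aa_composition <- function(seq) {
  codes <- seq_codes(seq)
  stats::setNames(tabulate(codes, 20L) / length(codes), AA_ORDER)
}

#' Per-residue Shannon entropy terms
#'
#' For each residue type with frequency p in the sequence, the term
#' -p log2(p) (0 when p = 0). The sum of the 20 terms is the sequence's
#' composition entropy in bits, maximally log2(20) for a uniform
#' composition.
#'
#' @inheritParams aa_composition
#' @return Named numeric vector of length 20.
#' @examples
#' sum(residue_entropy("ACDEFGHIKLMNPQRSTVWY")) # log2(20)
#' @export
residue_entropy <- function(seq) {
  p <- aa_composition(seq)
  ifelse(p > 0, -p * log2(p), 0)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean of the property-scale values over the residues of the sequence;
#' with the default Kyte-Doolittle scale this is the classical GRAVY
#' index (sum of residue hydropathies divided by length).
#'
#' @inheritParams aa_composition
#' @param scale A [property_scale()].
#' @return Numeric scalar.
#' @export
gravy <- function(seq, scale = property_scale("kyte_doolittle")) {
  mean(unclass(scale)[seq_codes(seq)])
}

net_charge <- function(counts, nK, nR, nH, nD, nE, nC, nY, pH) {
  pos <- c(1, nK, nR, nH)
  pos_pka <- c(PKA_EMBOSS$nterm, PKA_EMBOSS$positive[c("K", "R", "H")])
  neg <- c(1, nD, nE, nC, nY)
  neg_pka <- c(PKA_EMBOSS$cterm, PKA_EMBOSS$negative[c("D", "E", "C", "Y")])
  sum(pos / (1 + 10^(pH - pos_pka))) - sum(neg / (1 + 10^(neg_pka - pH)))
}

#' Basic physicochemical summary
#'
#' Sequence length, molecular weight (sum of average residue masses plus
#' one water for the termini) and isoelectric point. The pI is the root of
#' the net-charge curve, solved by bisection on pH in `[0, 14]` using the
#' EMBOSS pKa set (N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5, D 3.9,
#' E 4.1, C 8.5, Y 10.1).
#'
#' @inheritParams aa_composition
#' @return Tibble with columns `length`, `molecular_weight`,
#'   `isoelectric_point`.
#' @export
physchem_summary <- function(seq) {
  codes <- seq_codes(seq)
  counts <- tabulate(codes, 20L)
  names(counts) <- AA_ORDER
  mw <- sum(RESIDUE_MASS[AA_ORDER] * counts) + WATER_MASS
  f <- function(pH) {
    net_charge(counts, counts["K"], counts["R"], counts["H"],
               counts["D"], counts["E"], counts["C"], counts["Y"], pH)
  }
  lo <- 0; hi <- 14
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  tibble::tibble(
    length = length(codes),
    molecular_weight = unname(mw),
    isoelectric_point = (lo + hi) / 2
  )
}

#' Composition over a reduced residue alphabet
#'
#' Group frequencies (summing to 1) after mapping residues through a
#' [reduced_alphabet()]. With the identity alphabet this equals
#' [aa_composition()].
#'
#' @inheritParams aa_composition
#' @param alphabet Named integer vector mapping all 20 residues to groups
#'   (see [reduced_alphabet()]).
#' @return Named numeric vector, one entry per group.
#' @export
reduced_alphabet_composition <- function(seq, alphabet) {
  if (!setequal(names(alphabet), AA_ORDER) || any(is.na(alphabet))) {
    stop("alphabet must cover all 20 canonical residues", call. = FALSE)
  }
  groups <- attr(alphabet, "groups")
  if (is.null(groups)) groups <- paste0("g", seq_len(max(alphabet)))
  g <- unname(alphabet[AA_ORDER])[seq_codes(seq)]
  stats::setNames(tabulate(g, length(groups)) / length(g), groups)
}

ctd_from_groups <- function(g) {
  n <- length(g)
  comp <- tabulate(g, 3L) / n
  trans <- numeric(3)
  if (n >= 2L) {
    a <- g[-n]; b <- g[-1L]
    lohi <- pmin(a, b) * 10L + pmax(a, b)
    diff <- lohi[a != b]
    trans <- c(sum(diff == 12L), sum(diff == 13L), sum(diff == 23L)) /
      (n - 1L)
  }
  dist <- numeric(15)
  for (k in 1:3) {
    pos <- which(g == k)
    m <- length(pos)
    if (m > 0L) {
      idx <- pmax(1L, ceiling(c(0.0001, 0.25, 0.5, 0.75, 1) * m))
      dist[(k - 1L) * 5L + 1:5] <- pos[idx] / n
    }
  }
  c(comp = comp, trans = trans, dist = dist)
}

#' Composition-transition-distribution (CTD) features
#'
#' Encodes a sequence under a 3-group property alphabet as: group
#' compositions (3, sum 1); transition frequencies between unlike adjacent
#' groups (3 pairs, normalised by length - 1; 0 for length-1 sequences);
#' and, per group, the fractional sequence positions of its first, 25%,
#' 50%, 75% and last occurrence (0s for absent groups).
#'
#' @inheritParams aa_composition
#' @param alphabet A 3-group [reduced_alphabet()] (name or mapping).
#' @return Named numeric vector of length 21.
#' @export
ctd_features <- function(seq, alphabet = "polarity") {
  if (is.character(alphabet)) alphabet <- reduced_alphabet(alphabet)
  if (max(alphabet) != 3L) {
    stop("CTD requires a 3-group alphabet", call. = FALSE)
  }
  g <- unname(alphabet[AA_ORDER])[seq_codes(seq)]
  v <- ctd_from_groups(g)
  names(v) <- c(
    paste0("comp_g", 1:3),
    c("trans_g1g2", "trans_g1g3", "trans_g2g3"),
    paste0("dist_g", rep(1:3, each = 5), "_",
           rep(c("p1", "p25", "p50", "p75", "p100"), 3))
  )
  v
}

window_means <- function(x, window) {
  n <- length(x)
  if (n < window) return(mean(x))
  cs <- cumsum(c(0, x))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' Sliding-window property summaries
#'
#' Means of a residue property over all windows of the given width;
#' returns the max, min and mean of those window means. Sequences shorter
#' than the window use the whole-sequence mean as the sole window.
#'
#' @inheritParams gravy
#' @param window Window width (>= 1).
#' @return Tibble with columns `max`, `min`, `mean`.
#' @export
windowed_property <- function(seq, scale = property_scale("kyte_doolittle"),
                              window = 5L) {
  stopifnot(window >= 1L)
  x <- unclass(scale)[seq_codes(seq)]
  w <- window_means(x, window)
  tibble::tibble(max = max(w), min = min(w), mean = mean(w))
}

#' Property autocorrelation at a lag
#'
#' Normalised Moran-type autocorrelation of the residue property series
#' x_1..x_n at lag d:
#' \deqn{I(d) = \frac{\frac{1}{n-d}\sum_{i=1}^{n-d}(x_i-\bar x)(x_{i+d}-\bar x)}
#'                   {\frac{1}{n}\sum_{i=1}^{n}(x_i-\bar x)^2}}
#' A zero-variance series (constant property) returns 0 so that every
#' feature stays finite.
#'
#' @inheritParams gravy
#' @param lag Integer lag, `1 <= lag < length(seq)`.
#' @return Numeric scalar.
#' @export
autocorrelation <- function(seq, scale = property_scale("kyte_doolittle"),
                            lag = 1L) {
  x <- unclass(scale)[seq_codes(seq)]
  n <- length(x)
  if (lag < 1L || lag >= n) {
    stop("lag must satisfy 1 <= lag < sequence length", call. = FALSE)
  }
  moran_lag(x, lag)
}

moran_lag <- function(x, lag) {
  n <- length(x)
  if (lag >= n) return(0)
  xc <- x - mean(x)
  den <- sum(xc^2) / n
  if (den == 0) return(0)
  (sum(xc[1:(n - lag)] * xc[(1 + lag):n]) / (n - lag)) / den
}

#' Post-translational-modification motif counts
#'
#' Counts of PTM-relevant sequence motifs; currently the N-glycosylation
#' sequon N-X-(S/T) with X any residue except proline (overlapping
#' occurrences all counted).
#'
#' @inheritParams aa_composition
#' @return Named integer vector.
#' @examples
#' ptm_motif_counts("NAS") # 1
#' ptm_motif_counts("NPS") # 0
#' @export
ptm_motif_counts <- function(seq) {
  codes <- seq_codes(seq)
  n <- length(codes)
  cnt <- 0L
  if (n >= 3L) {
    iN <- match("N", AA_ORDER); iP <- match("P", AA_ORDER)
    iS <- match("S", AA_ORDER); iT <- match("T", AA_ORDER)
    i <- seq_len(n - 2L)
    cnt <- sum(codes[i] == iN & codes[i + 1L] != iP &
                 (codes[i + 2L] == iS | codes[i + 2L] == iT))
  }
  c(nglyc_sequon = as.integer(cnt))
}

# ---- feature registry -------------------------------------------------

CTD_ALPHABETS <- names(ctd_group_defs)
KD_WINDOWS <- c(5L, 11L)
KD_LAGS <- 1:4

#' Feature registry
#'
#' The fixed, versioned list of features produced by [extract_features()],
#' in column order: basic physicochemical properties (length, weight, pI,
#' GRAVY), amino-acid composition (20), per-residue entropy terms plus the
#' total (21), five-group chemical-alphabet composition (5), CTD blocks on
#' the five property alphabets (5 x 21), Kyte-Doolittle sliding-window
#' summaries (2 windows x 3), Kyte-Doolittle Moran autocorrelation at lags
#' 1-4 (4), and PTM motif counts (1): 166 features.
#'
#' @return Tibble with columns `feature`, `family`, `parameters`.
#' @export
feature_registry <- function() {
  rows <- list(
    tibble::tibble(
      feature = c("length", "mol_weight", "isoelectric_point", "gravy"),
      family = "physchem",
      parameters = c("", "average residue masses", "EMBOSS pKa",
                     "kyte_doolittle")
    ),
    tibble::tibble(feature = paste0("comp_", AA_ORDER),
                   family = "aa_composition", parameters = AA_ORDER),
    tibble::tibble(feature = c(paste0("entropy_", AA_ORDER),
                               "entropy_total"),
                   family = "entropy",
                   parameters = c(AA_ORDER, "sum")),
    tibble::tibble(
      feature = paste0("chem5_",
                       attr(reduced_alphabet("chemical"), "groups")),
      family = "reduced_composition", parameters = "chemical"
    )
  )
  for (alph in CTD_ALPHABETS) {
    nm <- names(ctd_features("AC", alph))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      feature = paste0("ctd_", alph, "_", nm),
      family = "ctd", parameters = alph
    )
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    feature = paste0("kd_win", rep(KD_WINDOWS, each = 3L), "_",
                     rep(c("max", "min", "mean"), length(KD_WINDOWS))),
    family = "windowed_property",
    parameters = paste0("kyte_doolittle, window ",
                        rep(KD_WINDOWS, each = 3L))
  )
  rows[[length(rows) + 1L]] <- tibble::tibble(
    feature = paste0("kd_autocorr_lag", KD_LAGS),
    family = "autocorrelation",
    parameters = paste0("kyte_doolittle, lag ", KD_LAGS)
  )
  rows[[length(rows) + 1L]] <- tibble::tibble(
    feature = "ptm_nglyc_sequon", family = "ptm_motifs",
    parameters = "N-X-[ST], X != P"
  )
  dplyr::bind_rows(rows)
}

feature_vector <- function(seq, ctd_maps, kd) {
  codes <- AA_LOOKUP[utf8ToInt(seq)]
  n <- length(codes)
  counts <- tabulate(codes, 20L)
  p <- counts / n
  ent <- ifelse(p > 0, -p * log2(p), 0)
  x <- kd[codes]
  ps <- physchem_summary(seq)
  chem <- reduced_alphabet_composition(seq, reduced_alphabet("chemical"))
  ctd <- unlist(lapply(ctd_maps, function(map) {
    ctd_from_groups(map[codes])
  }), use.names = FALSE)
  wins <- unlist(lapply(KD_WINDOWS, function(w) {
    wm <- window_means(x, w)
    c(max(wm), min(wm), mean(wm))
  }), use.names = FALSE)
  ac <- vapply(KD_LAGS, function(d) moran_lag(x, d), 0)
  c(n, ps$molecular_weight, ps$isoelectric_point, mean(x),
    p, ent, sum(ent), chem, ctd, wins, ac,
    as.numeric(ptm_motif_counts(seq)))
}

#' Extract the full feature table for a set of records
#'
#' Computes the [feature_registry()] features for every record,
#' deterministically and in fixed column order. No scaling is applied
#' here; fit a scaler on the training partition with
#' [fit_feature_scaling()] and apply it to any table with
#' [apply_feature_scaling()].
#'
#' @param records Protein record tibble (see [protein_records()]).
#' @return Tibble with `protein_id` followed by one column per registry
#'   feature; one row per record, in input order.
#' @export
extract_features <- function(records) {
  reg <- feature_registry()
  ctd_maps <- lapply(CTD_ALPHABETS,
                     function(a) unname(reduced_alphabet(a)[AA_ORDER]))
  kd <- unname(KYTE_DOOLITTLE[AA_ORDER])
  mat <- vapply(records$sequence, feature_vector,
                numeric(nrow(reg)), ctd_maps = ctd_maps, kd = kd,
                USE.NAMES = FALSE)
  mat <- matrix(mat, ncol = nrow(reg), byrow = TRUE,
                dimnames = list(NULL, reg$feature))
  stopifnot(all(is.finite(mat)))
  dplyr::bind_cols(tibble::tibble(protein_id = records$id),
                   tibble::as_tibble(mat))
}

#' Fit a per-feature min-max scaler
#'
#' Records the min and max of every feature column on a fitting set
#' (normally the training partition only, to avoid leakage).
#'
#' @param features Feature table from [extract_features()].
#' @return Tibble with columns `feature`, `min`, `max`.
#' @export
fit_feature_scaling <- function(features) {
  num <- dplyr::select(features, -"protein_id")
  tibble::tibble(
    feature = names(num),
    min = vapply(num, min, 0),
    max = vapply(num, max, 0)
  )
}

#' Apply a fitted min-max scaler
#'
#' Maps each feature to `(x - min) / (max - min)` using the fitted
#' parameters; features constant on the fitting set map to 0. Values
#' outside the fitted range (on new data) may fall outside `[0, 1]`.
#'
#' @inheritParams fit_feature_scaling
#' @param scaling Scaler tibble from [fit_feature_scaling()].
#' @return Scaled feature table.
#' @export
apply_feature_scaling <- function(features, scaling) {
  stopifnot(all(scaling$feature %in% names(features)))
  out <- features
  rng <- scaling$max - scaling$min
  for (i in seq_len(nrow(scaling))) {
    f <- scaling$feature[i]
    out[[f]] <- if (rng[i] > 0) (out[[f]] - scaling$min[i]) / rng[i] else 0
  }
  out
}
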