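#' Median-of-ratios size-factor normalization
#'
#' Per-sample size factors are the median ratio of counts to a reference
#' profile (the per-gene geometric mean over samples, restricted to genes
#' with no zero count). When no gene is nonzero in all samples the
#' procedure falls back to library-size scaling with a warning. Factors
#' are rescaled to geometric mean 1, which makes normalization idempotent
#' (renormalizing an already-normalized matrix yields unit factors).
#'
#' @param counts genes x samples nonnegative matrix.
#' @return list with `normalized` (counts / size factor) and
#'   `size_factors`.
#' @export
size_factor_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stopf("need at least 2 samples")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  all_pos <- rowSums(counts == 0) == 0L
  if (any(all_pos)) {
    logref <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    sf <- apply(counts[all_pos, , drop = FALSE], 2, function(col)
      exp(median(log(col) - logref)))
  } else {
    warning("no gene is nonzero in every sample; using library-size factors")
    libs <- colSums(counts)
    sf <- libs / exp(mean(log(libs)))
  }
  sf <- sf / exp(mean(log(sf)))
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Jensen-Shannon divergence between two expression profiles
#'
#' `JSD(p, q) = KL(p||m)/2 + KL(q||m)/2` with `m = (p + q)/2`, logarithms
#' base 2 and the `0 log 0 = 0` convention, so the result lies in
#' `[0, 1]` bits (1 exactly for disjoint supports). Inputs are
#' renormalized to proportions internally.
#'
#' @param p,q nonnegative vectors of equal length, each with positive sum.
#' @return divergence in bits.
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stopf("profiles differ in length")
  if (any(p < 0) || any(q < 0)) stopf("profiles must be nonnegative")
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) stopf("profiles must have positive sums")
  p <- p / sp; q <- q / sq
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Paired transcriptome divergence between hemispheres, compared across
#' timepoints
#'
#' For every animal with both hemispheres present, computes the
#' Jensen-Shannon divergence between the size-factor-normalized contra
#' and ipsi expression profiles, then compares the per-animal divergences
#' between the two timepoint groups with an exact rank-sum test. Animals
#' missing a hemisphere are excluded with a warning; when every
#' divergence is identical (e.g. all zero) the group test returns p = 1.
#'
#' @param counts genes x samples count matrix (columns named as in
#'   `meta$sample`).
#' @param meta data.frame with columns `sample`, `animal`, `hemisphere`
#'   ("contra"/"ipsi") and `timepoint`.
#' @return list with `per_animal` (data.frame: animal, timepoint, jsd)
#'   and `test` (list: groups, W, p_value) when two timepoints are
#'   present.
#' @export
paired_jsd_compare <- function(counts, meta) {
  norm <- size_factor_normalize(counts)$normalized
  animals <- unique(meta$animal)
  rows <- lapply(animals, function(a) {
    sub <- meta[meta$animal == a, ]
    co <- sub$sample[sub$hemisphere == "contra"]
    ip <- sub$sample[sub$hemisphere == "ipsi"]
    if (length(co) != 1L || length(ip) != 1L) return(NULL)
    data.frame(animal = a, timepoint = sub$timepoint[1],
               jsd = jsd(norm[, co], norm[, ip]))
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0)
    warning(sprintf("%d unpaired animal(s) excluded", dropped))
  per_animal <- do.call(rbind, rows)
  if (is.null(per_animal) || nrow(per_animal) == 0L)
    stopf("no paired animals available")

  test <- NULL
  tps <- unique(per_animal$timepoint)
  if (length(tps) == 2L) {
    g1 <- per_animal$jsd[per_animal$timepoint == tps[1]]
    g2 <- per_animal$jsd[per_animal$timepoint == tps[2]]
    if (stats::sd(c(g1, g2)) < 1e-15) {
      test <- list(groups = tps, W = NA_real_, p_value = 1)
    } else {
      w <- suppressWarnings(wilcox.test(g1, g2, exact = TRUE))
      test <- list(groups = tps, W = unname(w$statistic),
                   p_value = w$p.value)
    }
  }
  list(per_animal = per_animal, test = test)
}

#' Chi-square contingency test for DEG category counts
#'
#' Pearson chi-square without continuity correction on an r x c table of
#' counts (e.g. DEG counts per functional category by hemisphere, or per
#' vascular cell type), with expected counts from the margins and
#' `df = (r-1)(c-1)`.
#'
#' @param tab matrix of nonnegative counts, at least 2 x 2.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
category_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stopf("table must be at least 2 x 2")
  if (any(tab < 0)) stopf("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("zero row or column margin; test undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Build a DEG category count table
#'
#' Counts DEGs per category for each group (e.g. hemisphere), ready for
#' [category_contingency()].
#'
#' @param deg_table data.frame with logical `is_deg`, a `group` column
#'   and a `category` column.
#' @param group,category column names.
#' @return category x group count matrix.
#' @export
deg_category_table <- function(deg_table, group = "group",
                               category = "category") {
  d <- deg_table[deg_table$is_deg, ]
  as.matrix(table(d[[category]], d[[group]]))
}
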