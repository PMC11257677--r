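#' Wilcoxon matched-pairs signed-rank test with exact small-sample p
#'
#' Zero differences are dropped (Wilcoxon's original convention); ranks of
#' the remaining |differences| use midranks for ties. For n <= 25 the null
#' distribution of the positive-rank sum is computed exactly by dynamic
#' programming over the (doubled, hence integer) ranks, which is
#' equivalent to full enumeration of all 2^n sign assignments; above that
#' a normal approximation with tie correction and continuity correction is
#' used. Two-sided p doubles the smaller tail, capped at 1. With n pairs
#' all differing in the same direction the two-sided exact p is 2^(1-n)
#' (0.03125 at n = 6).
#'
#' @param x,y paired measurements; or `x` alone as precomputed
#'   differences.
#' @param alternative "two.sided", "greater" (x tends above y) or "less".
#' @param exact force exact (TRUE) or approximate (FALSE); NULL selects
#'   exact for n <= 25.
#' @return list with `statistic` (V, positive-rank sum), `n` (pairs after
#'   dropping zeros), `p_value`, `alternative`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 exact = NULL) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L) stopf("fewer than 2 nonzero differences; test undefined")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (is.null(exact)) exact <- n <= 25L

  if (exact) {
    r2 <- as.integer(round(2 * r))  # midranks doubled -> integers
    # f[w+1] = number of sign assignments with doubled rank sum w
    f <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), f[seq_len(length(f) - ri)])
      f <- f + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * v))
    p_le <- sum(f[seq_len(w2 + 1L)]) / total
    p_ge <- sum(f[(w2 + 1L):length(f)]) / total
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(ties^3 - ties) / 48)
    z <- v - mu
    cc <- switch(alternative, two.sided = sign(z) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (z - cc) / sigma
    p <- switch(alternative,
                two.sided = 2 * min(stats::pnorm(z),
                                    stats::pnorm(z, lower.tail = FALSE)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, p)
  }
  list(statistic = v, n = n, p_value = p, alternative = alternative,
       exact = exact)
}

# Benjamini-Hochberg linear step-up: indices of rejected hypotheses.
bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- p[o] <= q * seq_len(m) / m
  k <- if (any(ok)) max(which(ok)) else 0L
  if (k == 0L) integer(0) else o[seq_len(k)]
}

#' Two-stage linear step-up FDR (Benjamini, Krieger & Yekutieli)
#'
#' Stage 1 runs the linear step-up procedure at level `q' = q/(1+q)` to
#' estimate the number of true nulls `m - r1`; with `0 < r1 < m`, stage 2
#' reruns the step-up at level `q' * m/(m - r1)`. If stage 1 rejects
#' nothing, nothing is rejected; if it rejects everything, everything is.
#' Per-hypothesis q-values are obtained by inversion: the smallest nominal
#' q at which the two-stage rule would reject that hypothesis.
#'
#' @param pvalues p-values in `[0, 1]`.
#' @param q nominal FDR level.
#' @param compute_qvalues set FALSE to skip the (iterative) q-value
#'   inversion when only the rejection set is needed.
#' @return list with `pvalues`, `rejected` (logical), `qvalues` (or NULL),
#'   `q_level`, `stage1_rejections`.
#' @export
bky_fdr <- function(pvalues, q = 0.05, compute_qvalues = TRUE) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  check_scalar(q, "q", lower = 1e-12, upper = 1)
  m <- length(pvalues)
  reject_at <- function(qq) {
    q1 <- qq / (1 + qq)
    r1 <- length(bh_reject(pvalues, q1))
    if (r1 == 0L) return(integer(0))
    if (r1 == m) return(seq_len(m))
    bh_reject(pvalues, q1 * m / (m - r1))
  }
  rej_idx <- reject_at(q)
  rejected <- logical(m)
  rejected[rej_idx] <- TRUE
  r1 <- length(bh_reject(pvalues, q / (1 + q)))

  qvalues <- NULL
  if (compute_qvalues) {
    qvalues <- vapply(seq_len(m), function(i) {
      if (i %in% reject_at(1)) {
        lo <- 1e-8; hi <- 1
        for (k in seq_len(40)) {
          mid <- sqrt(lo * hi)
          if (i %in% reject_at(mid)) hi <- mid else lo <- mid
        }
        hi
      } else 1
    }, 1)
  }
  list(pvalues = pvalues, rejected = rejected, qvalues = qvalues,
       q_level = q, stage1_rejections = r1)
}

#' Nested t-test (animal-level aggregation)
#'
#' Within-animal replicates (e.g. histological sections) are collapsed to
#' per-animal means, and a two-sample equal-variance t-test is performed
#' on the animal means, with `df = n_A + n_B - 2`. This matches a nested
#' ANOVA in balanced designs and avoids pseudo-replication from treating
#' sections as independent.
#'
#' @param group_a,group_b lists of numeric vectors, one vector of section
#'   values per animal. Animals with no sections are excluded with a
#'   warning.
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `n_animals`.
#' @export
nested_t_test <- function(group_a, group_b) {
  clean <- function(g, nm) {
    len <- vapply(g, length, 1L)
    if (any(len == 0L)) {
      warning(sprintf("%d animal(s) with zero sections excluded from %s",
                      sum(len == 0L), nm))
      g <- g[len > 0L]
    }
    g
  }
  group_a <- clean(group_a, "group A")
  group_b <- clean(group_b, "group B")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stopf("each group needs at least 2 animals")
  ma <- vapply(group_a, mean, 1); mb <- vapply(group_b, mean, 1)
  na <- length(ma); nb <- length(mb)
  sp2 <- ((na - 1) * var(ma) + (nb - 1) * var(mb)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tval <- if (se == 0) 0 else (mean(ma) - mean(mb)) / se
  df <- na + nb - 2
  p <- if (se == 0) 1 else 2 * pt(-abs(tval), df)
  list(t = tval, df = df, p_value = p, mean_a = mean(ma), mean_b = mean(mb),
       n_animals = c(a = na, b = nb))
}

#' Omnibus test with FDR-corrected post-hoc comparisons
#'
#' For `omnibus = "kruskal"`: Kruskal-Wallis across groups, then pairwise
#' rank-sum tests corrected with the two-stage step-up FDR. For
#' `omnibus = "anova2"`: two-way ANOVA `y ~ group * block` (e.g. subject
#' group by brain region), then per-block two-sample t-tests between the
#' two groups, FDR-corrected.
#'
#' @param y response values.
#' @param group primary grouping factor.
#' @param block second factor for the two-way design (required for
#'   "anova2").
#' @param omnibus "kruskal" or "anova2".
#' @param q FDR level for the post-hoc correction.
#' @return list with `omnibus` (statistic(s), df, p) and `posthoc`
#'   (data.frame with per-comparison p, q-value and rejection flag).
#' @export
omnibus_posthoc <- function(y, group, block = NULL,
                            omnibus = c("kruskal", "anova2"), q = 0.05) {
  omnibus <- match.arg(omnibus)
  group <- factor(group)
  if (nlevels(group) < 2L) stopf("need at least 2 groups")
  sizes <- table(group)
  if (any(sizes < 2L)) stopf("every group needs n >= 2")

  if (omnibus == "kruskal") {
    kw <- kruskal.test(y, group)
    levs <- levels(group)
    pairs <- utils::combn(levs, 2)
    ph <- data.frame(a = pairs[1, ], b = pairs[2, ], p = NA_real_)
    for (i in seq_len(ncol(pairs))) {
      w <- suppressWarnings(wilcox.test(y[group == pairs[1, i]],
                                        y[group == pairs[2, i]]))
      ph$p[i] <- w$p.value
    }
    fdr <- bky_fdr(ph$p, q = q)
    ph$q_value <- fdr$qvalues
    ph$rejected <- fdr$rejected
    list(omnibus = list(statistic = unname(kw$statistic),
                        df = unname(kw$parameter), p = kw$p.value),
         posthoc = ph)
  } else {
    if (is.null(block)) stopf("block factor is required for anova2")
    block <- factor(block)
    if (nlevels(group) != 2L)
      stopf("anova2 post-hoc contrasts require exactly 2 groups")
    fit <- aov(y ~ group * block)
    tab <- summary(fit)[[1]]
    rn <- trimws(rownames(tab))
    ph <- do.call(rbind, lapply(levels(block), function(b) {
      yy <- y[block == b]; gg <- group[block == b]
      if (min(table(gg)) < 2L) return(NULL)
      tt <- t.test(yy[gg == levels(group)[1]], yy[gg == levels(group)[2]],
                   var.equal = TRUE)
      data.frame(block = b, p = tt$p.value)
    }))
    fdr <- bky_fdr(ph$p, q = q)
    ph$q_value <- fdr$qvalues
    ph$rejected <- fdr$rejected
    list(omnibus = list(table = tab,
                        p_interaction = tab[rn == "group:block", "Pr(>F)"],
                        p_group = tab[rn == "group", "Pr(>F)"]),
         posthoc = ph)
  }
}
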