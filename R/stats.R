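# Group-comparison statistics: exact/approximate Wilcoxon signed-rank for
# paired healthy-vs-lesion contrasts, MANOVA (Wilks' lambda) across tissue
# groups with Bonferroni-corrected pairwise per-parameter contrasts, and the
# full published contrast grid (letters a-j, x, y, z).

#' Wilcoxon signed-rank test
#'
#' Paired two-sided test. Zero differences are dropped (Wilcoxon's original
#' convention). The statistic W is the smaller of the positive- and
#' negative-difference rank sums (min-rank-sum convention). For n <=
#' `exact_threshold` the p-value is exact, by full enumeration of all 2^n
#' sign assignments of the observed absolute-difference ranks (mid-ranks
#' under ties, so the exact branch remains valid with ties); otherwise a
#' normal approximation with continuity correction and mid-rank tie variance
#' correction is used.
#'
#' @param a,b paired numeric vectors of equal length; at least 5 nonzero
#'   differences are required.
#' @param exact_threshold largest n for which the exact enumeration is used.
#' @return list with `W`, `p`, `n` (nonzero differences) and `method`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p  # 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b, exact_threshold = 12L) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate input: all paired differences are zero")
  if (n < 5L) stop("need at least 5 nonzero paired differences, got ", n)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  if (n <= exact_threshold) {
    # enumerate the rank-sum of positives over all 2^n sign assignments
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    p <- min(1, 2 * min(mean(sums <= w_pos), mean(sums >= w_pos)))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(w_pos - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal approximation"
  }
  list(W = W, p = p, n = n, method = method)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`.
#'
#' @param p raw p-values.
#' @param m family size; defaults to `length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  pmin(1, m * p)
}

#' MANOVA across tissue groups with pairwise contrasts
#'
#' Overall multivariate test (Wilks' lambda) of group differences over the
#' parameter columns, followed by per-parameter pairwise group contrasts
#' using the pooled within-group error of the one-way fit, with Bonferroni
#' adjustment over the contrast family (all group pairs) per parameter.
#'
#' @param table data frame of lesion-level observations.
#' @param group column name holding the group factor (>= 2 groups, each with
#'   >= 2 observations).
#' @param parameters character vector of numeric parameter column names.
#' @param alpha significance level for the flags.
#' @return list with `wilks` (data frame: statistic, approx F, df, p) and
#'   `contrasts` (data frame of class `comparison_result`: contrast,
#'   parameter, statistic, p, p_adj, significant).
#' @export
manova_groups <- function(table, group, parameters, alpha = 0.05) {
  g <- factor(table[[group]])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) {
    stop("every group needs at least 2 observations; got n = ",
         paste(table(g), collapse = ", "))
  }
  Y <- as.matrix(table[parameters])
  if (!is.numeric(Y)) stop("parameter columns must be numeric")

  if (length(parameters) == 1L) {
    # univariate case: Wilks' lambda reduces to one-way ANOVA,
    # lambda = SSE / (SSE + SSH) and F = (1 - lambda)/lambda * (n-k)/(k-1)
    y <- drop(Y)
    n <- length(y); k <- nlevels(g)
    a <- stats::aov(y ~ g)
    sse <- sum(stats::resid(a)^2)
    ssh <- sum((stats::fitted(a) - mean(y))^2)
    lambda <- sse / (sse + ssh)
    Fval <- (1 - lambda) / lambda * (n - k) / (k - 1)
    wilks <- data.frame(statistic = lambda, F = Fval,
                        df1 = k - 1, df2 = n - k,
                        p = stats::pf(Fval, k - 1, n - k, lower.tail = FALSE))
  } else {
    fit <- stats::manova(Y ~ g)
    sm <- try(summary(fit, test = "Wilks"), silent = TRUE)
    if (inherits(sm, "try-error")) {
      stop("singular within-group covariance; reduce the parameter set ",
           "(fewer parameters than residual degrees of freedom are required)")
    }
    st <- sm$stats
    wilks <- data.frame(statistic = st[1, "Wilks"],
                        F = st[1, "approx F"],
                        df1 = st[1, "num Df"], df2 = st[1, "den Df"],
                        p = st[1, "Pr(>F)"])
  }

  # pooled within-group variance per parameter (one-way ANOVA error term)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  m_family <- length(pairs)
  rows <- list()
  for (param in parameters) {
    y <- table[[param]]
    a <- stats::aov(y ~ g)
    mse <- sum(stats::resid(a)^2) / a$df.residual
    for (pr in pairs) {
      i1 <- g == pr[1]; i2 <- g == pr[2]
      se <- sqrt(mse * (1 / sum(i1) + 1 / sum(i2)))
      tval <- (mean(y[i1]) - mean(y[i2])) / se
      p <- 2 * stats::pt(abs(tval), a$df.residual, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste(pr[1], "vs", pr[2]), parameter = param,
        statistic = tval, p = p, stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, rows)
  contrasts$p_adj <- bonferroni(contrasts$p, m_family)
  contrasts$significant <- contrasts$p_adj < alpha
  class(contrasts) <- c("comparison_result", "data.frame")
  list(wilks = wilks, contrasts = contrasts)
}

# The published contrast grid: letters a-j are pairwise group contrasts
# (MANOVA post hoc), x/y/z are paired Wilcoxon signed-rank tests.
PAPER_CONTRASTS <- list(
  a = c("healthy_cortex", "rcc"), b = c("healthy_cortex", "cyst"),
  c = c("healthy_cortex", "benign"), d = c("healthy_medulla", "rcc"),
  e = c("healthy_medulla", "cyst"), f = c("healthy_medulla", "benign"),
  g = c("rcc", "cyst"), h = c("rcc", "benign"), i = c("benign", "cyst"),
  j = c("healthy_cortex", "healthy_medulla"))

#' Run the full published contrast grid
#'
#' Executes the pairwise MANOVA contrasts a-j across the five tissue groups
#' (healthy cortex, healthy medulla, RCC, cyst, benign; Bonferroni family =
#' the 10 contrasts, per parameter) and the paired Wilcoxon signed-rank
#' tests x (cortex vs all solid lesions), y (medulla vs all solid lesions)
#' and z (cortex vs medulla). Emits a per-parameter significance-letter
#' annotation string. Missing groups skip their contrasts with a warning.
#'
#' @param lesions data frame: one row per lesion with a `type` column (preset
#'   names; anything except `"cyst"` counts as solid, `"hemangioma"` and
#'   `"oncocytoma"` as benign, other solid types as RCC) and the parameter
#'   columns.
#' @param healthy data frame: two rows per lesion (`tissue` =
#'   `"healthy_cortex"` / `"healthy_medulla"`, keyed by `lesion_id`) with the
#'   same parameter columns, as produced by [sample_cohort()].
#' @param parameters parameter columns to test.
#' @param alpha significance level.
#' @return list with `contrasts` (combined `comparison_result` table with a
#'   `letter` column), `wilks`, and `significance` (named character vector:
#'   per-parameter letter string, e.g. `"a, b, e"`).
#' @export
run_paper_contrasts <- function(lesions, healthy,
                                parameters = c("MD", "FA", "f_star", "D_bi",
                                               "f_fast", "f_interm", "D_tri"),
                                alpha = 0.05) {
  group_of <- function(type) {
    ifelse(type == "cyst", "cyst",
           ifelse(type %in% c("hemangioma", "oncocytoma"), "benign", "rcc"))
  }
  lesions$group <- group_of(lesions$type)
  grp_tab <- rbind(
    data.frame(group = lesions$group, lesions[parameters],
               stringsAsFactors = FALSE),
    data.frame(group = healthy$tissue, healthy[parameters],
               stringsAsFactors = FALSE))

  present <- names(which(table(grp_tab$group) >= 2L))
  usable <- Filter(function(pr) all(pr %in% present), PAPER_CONTRASTS)
  skipped <- setdiff(names(PAPER_CONTRASTS), names(usable))
  if (length(skipped)) {
    warning("skipping contrasts with missing groups: ",
            paste(skipped, collapse = ", "))
  }
  rows <- list()
  wilks <- NULL
  if (length(present) >= 2L) {
    sub <- grp_tab[grp_tab$group %in% present, ]
    mg <- manova_groups(sub, "group", parameters, alpha = alpha)
    wilks <- mg$wilks
    # keep only the published contrasts, re-adjusted over that family
    for (letter in names(usable)) {
      pr <- usable[[letter]]
      nm <- paste(pr[1], "vs", pr[2])
      nm_rev <- paste(pr[2], "vs", pr[1])
      sel <- mg$contrasts[mg$contrasts$contrast %in% c(nm, nm_rev), ]
      if (!nrow(sel)) next
      sel$letter <- letter
      sel$p_adj <- bonferroni(sel$p, length(usable))
      sel$significant <- sel$p_adj < alpha
      rows[[length(rows) + 1L]] <- sel
    }
  }

  # paired Wilcoxon: healthy tissue of the solid-lesion patients vs lesions
  solid <- lesions[lesions$group != "cyst", ]
  wilcox_letters <- list(
    x = list(tissue = "healthy_cortex", against = "solid"),
    y = list(tissue = "healthy_medulla", against = "solid"),
    z = list(tissue = "healthy_cortex", against = "healthy_medulla"))
  for (letter in names(wilcox_letters)) {
    wl <- wilcox_letters[[letter]]
    for (param in parameters) {
      res <- try({
        if (wl$against == "solid") {
          h <- healthy[healthy$tissue == wl$tissue &
                       healthy$lesion_id %in% solid$lesion_id, ]
          h <- h[match(solid$lesion_id, h$lesion_id), ]
          wilcoxon_signed_rank(h[[param]], solid[[param]])
        } else {
          hc <- healthy[healthy$tissue == "healthy_cortex", ]
          hm <- healthy[healthy$tissue == "healthy_medulla", ]
          hm <- hm[match(hc$lesion_id, hm$lesion_id), ]
          wilcoxon_signed_rank(hc[[param]], hm[[param]])
        }
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        warning("Wilcoxon contrast ", letter, " skipped for ", param)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste0("wilcoxon_", letter), parameter = param,
        statistic = res$W, p = res$p, p_adj = res$p,
        significant = res$p < alpha, letter = letter,
        stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, rows)
  rownames(contrasts) <- NULL
  class(contrasts) <- c("comparison_result", "data.frame")
  significance <- vapply(parameters, function(param) {
    sel <- contrasts[contrasts$parameter == param & contrasts$significant, ]
    paste(sort(sel$letter), collapse = ", ")
  }, character(1))
  list(contrasts = contrasts, wilks = wilks, significance = significance)
}
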