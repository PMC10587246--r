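# Multi-group comparison and agreement statistics.

#' Kruskal-Wallis H test across severity groups
#'
#' H is computed on mid-ranks with the standard tie-correction divisor;
#' the p value comes from the chi-square approximation with k - 1 degrees
#' of freedom.
#'
#' @param groups List of k (>= 2) non-empty numeric vectors.
#' @return List of class `kw_result`: `H`, `df`, `p`, `group_ns`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1) {
    res <- list(H = 0, df = length(groups) - 1L, p = 1,
                group_ns = as.integer(table(g)))
    class(res) <- "kw_result"
    return(res)
  }
  kt <- stats::kruskal.test(x, g)
  res <- list(
    H = unname(kt$statistic), df = unname(kt$parameter),
    p = unname(kt$p.value), group_ns = as.integer(table(g))
  )
  class(res) <- "kw_result"
  res
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (n = %s)\n",
              x$H, x$df, x$p, paste(x$group_ns, collapse = "/")))
  invisible(x)
}

#' Dunn's pairwise procedure with Bonferroni correction
#'
#' Pairwise z statistics from mean-rank differences with the
#' tie-corrected variance; each raw two-sided p value is multiplied by
#' the number of comparisons k(k-1)/2 and capped at 1.
#'
#' @param groups List of k (>= 2) non-empty numeric vectors.
#' @return List of class `dunn_result`: symmetric matrices `z`, `p_raw`
#'   and `p_adjusted`, with `NA` diagonals.
#' @export
dunn_bonferroni <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  ns <- vapply(groups, length, 1L)
  if (any(ns == 0)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), ns)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  z <- p_raw <- p_adj <- matrix(NA_real_, k, k)
  m <- k * (k - 1) / 2
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(v0 * (1 / ns[i] + 1 / ns[j]))
      zz <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
      z[i, j] <- z[j, i] <- zz
      pr <- 2 * stats::pnorm(-abs(zz))
      p_raw[i, j] <- p_raw[j, i] <- pr
      p_adj[i, j] <- p_adj[j, i] <- min(1, pr * m)
    }
  }
  structure(list(z = z, p_raw = p_raw, p_adjusted = p_adj),
            class = "dunn_result")
}

#' Cohen's kappa for two categorical raters
#'
#' Unweighted kappa from the k x k contingency table:
#' `(po - pe) / (1 - pe)` with observed agreement `po` and chance
#' agreement `pe` from the marginals.
#'
#' @param labels_a,labels_b Equal-length category vectors.
#' @return List of class `kappa_result`: `kappa`, `observed_agreement`,
#'   `expected_agreement`, `n`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("unequal label lengths")
  if (!length(labels_a)) stop("empty label vectors")
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  tab <- table(factor(as.character(labels_a), levels = lev),
               factor(as.character(labels_b), levels = lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1 - 1e-12) stop("undefined kappa: chance agreement is 1")
  structure(
    list(kappa = (po - pe) / (1 - pe), observed_agreement = po,
         expected_agreement = pe, n = n),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (po = %.4f, pe = %.4f, n = %d)\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n))
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding where exact halves round up (`6.25 -> 6.3` at one
#' decimal), matching how cohort percentages are conventionally printed,
#' unlike base R's round-half-even.
#'
#' @param x Numeric vector (non-negative use case).
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- sign(x)
  p <- 10^digits
  s * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Per-level cohort shares as printed percentages
#'
#' @param level_counts Named or unnamed non-negative counts.
#' @return Percentages (one decimal, half-up), same names.
#' @export
cohort_shares <- function(level_counts) {
  if (any(level_counts < 0)) stop("negative counts")
  total <- sum(level_counts)
  if (total <= 0) stop("zero total")
  round_half_up(100 * level_counts / total, 1)
}

#' Kruskal-Wallis and Dunn-Bonferroni across severity levels for every
#' lesion metric
#'
#' Applies the group comparison per (lesion type, metric) family over
#' eyes grouped by severity level; the Bonferroni correction is within
#' each family (k(k-1)/2 comparisons).
#'
#' @param metrics Combined `lesion_metrics`.
#' @param grades Grades tibble with `eye_id` and the scale column.
#' @param scale `"icdr"` or `"aa"`.
#' @param levels_used Severity levels to compare (default: ICDR 1-4, the
#'   DR-positive levels).
#' @return List with `tests` (tibble: lesion_type, metric, H, df, p) and
#'   `pairwise` (long tibble of adjusted p values).
#' @export
severity_stats <- function(metrics, grades, scale = c("icdr", "aa"),
                           levels_used = NULL) {
  scale <- match.arg(scale)
  col <- if (scale == "icdr") "icdr" else "aa_level"
  g <- grades[!is.na(grades[[col]]), c("eye_id", col)]
  names(g)[2] <- "level"
  if (is.null(levels_used)) {
    levels_used <- if (scale == "icdr") 1:4 else sort(unique(g$level))
  }
  g <- g[g$level %in% levels_used, ]
  tot <- metrics_totals(metrics)
  types <- setdiff(rq_lesion_types(), c("PFD", "PFE"))
  tests <- list()
  pw <- list()
  for (ty in types) {
    for (metric in c("frequency", "area")) {
      t1 <- tot[tot$lesion_type == ty, ]
      v <- stats::setNames(
        if (metric == "frequency") t1$frequency else t1$area_mm2, t1$eye_id
      )
      vals <- ifelse(g$eye_id %in% names(v), v[g$eye_id], 0)
      vals[is.na(vals)] <- 0
      groups <- split(vals, g$level)
      groups <- groups[vapply(groups, length, 1L) > 0]
      if (length(groups) < 2) next
      kw <- kruskal_wallis(groups)
      tests[[length(tests) + 1]] <- tibble::tibble(
        lesion_type = ty, metric = metric, H = kw$H, df = kw$df, p = kw$p
      )
      dn <- dunn_bonferroni(groups)
      nm <- names(groups)
      for (i in seq_along(nm)[-length(nm)]) {
        for (j in (i + 1):length(nm)) {
          pw[[length(pw) + 1]] <- tibble::tibble(
            lesion_type = ty, metric = metric,
            level_a = nm[i], level_b = nm[j],
            z = dn$z[i, j], p_adjusted = dn$p_adjusted[i, j]
          )
        }
      }
    }
  }
  list(tests = dplyr::bind_rows(tests), pairwise = dplyr::bind_rows(pw))
}
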