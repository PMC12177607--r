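# Statistical evaluation of docking-score tables: Kruskal-Wallis across
# receptors, Dunn's post hoc with multiplicity adjustment, ROC/AUC against
# responsiveness labels, and grouped summaries.

#' Load a docking-score table from CSV
#'
#' Required columns: `receptor`, `ligand`, `engine`, `value`; optional
#' `responsive` (accepted encodings: 1/0, true/false, TRUE/FALSE, yes/no).
#' The (receptor, ligand, engine) key must be unique.
#'
#' @param path CSV path.
#' @return A `score_table` data frame.
#' @export
load_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("receptor", "ligand", "engine", "value")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(df$value) || any(!is.finite(df$value))) {
    stop("schema error: value column must be finite numeric")
  }
  key <- paste(df$receptor, df$ligand, df$engine, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (receptor, ligand, engine) rows: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  if ("responsive" %in% names(df)) {
    raw <- tolower(as.character(df$responsive))
    val <- rep(NA, length(raw))
    val[raw %in% c("1", "true", "t", "yes")] <- TRUE
    val[raw %in% c("0", "false", "f", "no")] <- FALSE
    if (anyNA(val)) stop("schema error: unrecognised responsive value(s)")
    df$responsive <- val
  }
  class(df) <- c("score_table", "data.frame")
  df
}

rank_tie_stats <- function(values) {
  r <- rank(values)
  t <- table(values)
  list(ranks = r, tie_sum = sum(t^3 - t), n = length(values))
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based omnibus comparison of two or more independent groups, with
#' tie correction; p-value from the chi-square approximation with
#' (groups - 1) degrees of freedom. When every value is identical the
#' statistic is reported as H = 0 with p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, each non-empty).
#' @return A `kw_result`: `H`, `df`, `p_value`, `tie_correction`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  pooled <- unlist(groups, use.names = FALSE)
  ts <- rank_tie_stats(pooled)
  C <- 1 - ts$tie_sum / (ts$n^3 - ts$n)
  if (C == 0) {
    res <- list(H = 0, df = length(groups) - 1L, p_value = 1,
                tie_correction = 0)
    class(res) <- "kw_result"
    return(res)
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(pooled, g)
  res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
              p_value = kt$p.value, tie_correction = C)
  class(res) <- "kw_result"
  res
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  invisible(x)
}

#' Dunn's post hoc test
#'
#' Pairwise z statistics from the rank means of the pooled ranking with tie
#' correction:
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))
#' with T = sum(t^3 - t) over tied values. Two-sided p-values are adjusted
#' by the chosen method (default Bonferroni) and capped at 1.
#'
#' @param groups Named list of numeric vectors (>= 2).
#' @param adjust An adjustment method accepted by [stats::p.adjust()]
#'   (default `"bonferroni"`) or `"none"`.
#' @return A `dunn_matrix`: list with `p` (symmetric adjusted p matrix,
#'   unit diagonal), `z` (z matrix), `adjust`.
#' @export
dunn_posthoc <- function(groups, adjust = "bonferroni") {
  g <- length(groups)
  if (g < 2) stop("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(g))
  pooled <- unlist(groups, use.names = FALSE)
  ts <- rank_tie_stats(pooled)
  N <- ts$n
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_len(g), sizes)
  rbar <- vapply(seq_len(g), function(j) mean(ts$ranks[idx == j]), numeric(1))
  varterm <- N * (N + 1) / 12 - ts$tie_sum / (12 * (N - 1))
  z <- matrix(0, g, g, dimnames = list(names(groups), names(groups)))
  praw <- c()
  pairs <- utils::combn(g, 2)
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    se <- sqrt(varterm * (1 / sizes[i] + 1 / sizes[j]))
    zij <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    z[i, j] <- z[j, i] <- zij
    praw[q] <- 2 * stats::pnorm(-abs(zij))
  }
  padj <- pmin(stats::p.adjust(praw, method = adjust), 1)
  p <- diag(g) * 0 + 1
  dimnames(p) <- dimnames(z)
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    p[i, j] <- p[j, i] <- padj[q]
  }
  structure(list(p = p, z = z, adjust = adjust), class = "dunn_matrix")
}

#' ROC curve and AUC for docking scores against activity labels
#'
#' AUC is computed by the rank (Mann-Whitney) formulation with half credit
#' for ties; the stored curve is the standard step curve including (0,0)
#' and (1,1), whose trapezoidal area equals the rank AUC. With the default
#' orientation `lower_is_active`, lower scores (more negative binding
#' energies) indicate activity; use `higher_is_active` for CNN-style
#' scores.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or coercible) activity labels; both classes must
#'   be present.
#' @param orientation `"lower_is_active"` (default) or `"higher_is_active"`.
#' @return A `roc_result`: `auc`, `n_pos`, `n_neg`, `curve` (data frame of
#'   fpr, tpr), `orientation`.
#' @export
roc_auc <- function(scores, labels,
                    orientation = c("lower_is_active", "higher_is_active")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  s <- if (orientation == "lower_is_active") -scores else scores
  r <- rank(s)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # step curve over decreasing thresholds, ties grouped
  ord <- order(-s)
  ss <- s[ord]; ll <- labels[ord]
  grp <- cumsum(c(TRUE, diff(ss) != 0))
  tp <- cumsum(ll); fp <- cumsum(!ll)
  last <- which(!duplicated(grp, fromLast = TRUE))
  curve <- data.frame(fpr = c(0, fp[last] / n_neg),
                      tpr = c(0, tp[last] / n_pos))
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg, curve = curve,
                 orientation = orientation),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d active / %d inactive, %s)\n",
              x$auc, x$n_pos, x$n_neg, x$orientation))
  invisible(x)
}

#' Per-receptor, per-engine score summary
#'
#' @param table A `score_table`.
#' @return Data frame with one row per (receptor, engine): n, mean, median,
#'   sd, min, max.
#' @export
receptor_summary <- function(table) {
  if (nrow(table) == 0) stop("empty score table")
  key <- interaction(table$receptor, table$engine, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    v <- table$value[idx]
    data.frame(receptor = table$receptor[idx[1]],
               engine = table$engine[idx[1]],
               n = length(v), mean = mean(v), median = stats::median(v),
               sd = stats::sd(v), min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$receptor, out$engine), , drop = FALSE]
}
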