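#' Shapiro-Wilk normality gate
#'
#' Classifies a sample as `"normal"` or `"non_normal"` with the
#' Shapiro-Wilk test at level `alpha`. The gate decides between the
#' parametric and nonparametric branches of every downstream test:
#' Pearson vs Spearman for trends, ANOVA / t vs Kruskal-Wallis /
#' rank-sum for comparisons.
#'
#' @param x numeric sample, `n >= 3`.
#' @param alpha gate level (default 0.05).
#' @return list with `classification`, `W`, `p`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L)
    stop("insufficient sample: normality gate needs n >= 3, got ", length(x))
  if (stats::sd(x) == 0)
    stop("insufficient variance: constant sample")
  sw <- stats::shapiro.test(x)
  list(classification = if (sw$p.value > alpha) "normal" else "non_normal",
       W = unname(sw$statistic), p = sw$p.value)
}

gate_class <- function(x, alpha) normality_gate(x, alpha)$classification

#' Correlation of a similarity coefficient with embryonic day
#'
#' Correlates one similarity coefficient against embryonic day treated as
#' a numeric covariate. Under `method = "auto"` the Shapiro-Wilk gate is
#' applied to both variables and Pearson is used only if both pass;
#' otherwise Spearman. (Embryonic day takes a few discrete values, so the
#' auto gate practically always selects Spearman; force
#' `method = "pearson"` for the parametric value.)
#'
#' @param table a scores data.frame with columns `ed` and the coefficient.
#' @param coefficient one of `"cc1"`, `"cc2"`, `"clf"`, `"chf"` (any
#'   numeric column works).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @param alpha gate level.
#' @return data.frame of class `trend_result` with columns `coefficient`,
#'   `method`, `r`, `p`, `n`.
#' @export
trend_with_age <- function(table, coefficient,
                           method = c("auto", "pearson", "spearman"),
                           alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), coefficient %in% names(table),
            "ed" %in% names(table))
  ok <- stats::complete.cases(table[, c("ed", coefficient)])
  ed <- as.numeric(table$ed[ok])
  y <- table[[coefficient]][ok]
  if (length(unique(ed)) < 2L)
    stop("degenerate design: need at least 2 distinct embryonic days")
  if (method == "auto") {
    method <- if (gate_class(y, alpha) == "normal" &&
                  gate_class(ed, alpha) == "normal") "pearson" else "spearman"
  }
  ct <- suppressWarnings(
    stats::cor.test(ed, y, method = method, exact = FALSE))
  structure(data.frame(coefficient = coefficient, method = method,
                       r = unname(ct$estimate), p = ct$p.value,
                       n = length(y), stringsAsFactors = FALSE),
            class = c("trend_result", "data.frame"))
}

two_sample_test <- function(a, b, gate_normal) {
  if (gate_normal) {
    tt <- stats::t.test(a, b)
    list(method = "t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    list(method = "rank_sum", statistic = unname(wt$statistic),
         p = wt$p.value)
  }
}

comparison_row <- function(coefficient, design, contrast, groups, res, ns) {
  data.frame(coefficient = coefficient, design = design,
             contrast = contrast, groups = groups,
             method = res$method, statistic = res$statistic,
             p = res$p, n = paste(ns, collapse = "/"),
             stringsAsFactors = FALSE)
}

#' Group comparisons of a similarity coefficient
#'
#' Two designs. `"stagewise"` compares the coefficient across embryonic
#' days within one group: an omnibus test over all stages (one-way ANOVA
#' if every stage sample passes the normality gate, Kruskal-Wallis
#' otherwise) plus all pairwise stage contrasts (Welch t or Wilcoxon
#' rank-sum by the same per-comparison gate). `"saline_vs_vpa"` contrasts
#' the saline and VPA arms within each embryonic day. If ANY group in a
#' comparison fails the gate, the nonparametric branch is used for that
#' comparison.
#'
#' @param table scores data.frame with columns `ed`, `group`, and the
#'   coefficient; one row per (fetus, epoch) observation by default.
#' @param coefficient column to compare.
#' @param design `"stagewise"` or `"saline_vs_vpa"`.
#' @param alpha gate level.
#' @param adjust p-adjustment across the pairwise contrasts: `"none"`
#'   (default, matching conventional unadjusted reporting) or `"holm"`.
#' @param aggregate `"none"` (each (fetus, epoch) row is an observation),
#'   `"epoch_mean"` (average the epochs of each fetus first). Rows from
#'   fetuses sharing a mother remain non-independent either way; treat
#'   p-values accordingly.
#' @param method `"auto"` applies the gate; `"anova"` or `"rank_sum"`
#'   force a branch (omnibus and contrasts alike).
#' @return data.frame of class `comparison_result`, one row per test.
#' @export
compare_groups <- function(table, coefficient,
                           design = c("stagewise", "saline_vs_vpa"),
                           alpha = 0.05, adjust = c("none", "holm"),
                           aggregate = c("none", "epoch_mean"),
                           method = c("auto", "anova", "rank_sum")) {
  design <- match.arg(design)
  adjust <- match.arg(adjust)
  aggregate <- match.arg(aggregate)
  method <- match.arg(method)
  stopifnot(is.data.frame(table), coefficient %in% names(table))
  if (aggregate == "epoch_mean") {
    agg <- stats::aggregate(table[[coefficient]],
                            by = list(mother_id = table$mother_id,
                                      fetus_id = table$fetus_id,
                                      ed = table$ed, group = table$group),
                            FUN = mean, na.rm = TRUE)
    names(agg)[ncol(agg)] <- coefficient
    table <- agg
  }
  table <- table[!is.na(table[[coefficient]]), , drop = FALSE]
  use_normal <- function(samples) {
    if (method == "anova") return(TRUE)
    if (method == "rank_sum") return(FALSE)
    all(vapply(samples, function(s) gate_class(s, alpha) == "normal",
               logical(1)))
  }
  rows <- list()
  if (design == "stagewise") {
    eds <- sort(unique(table$ed))
    if (length(eds) < 2L)
      stop("stagewise design needs >= 2 embryonic days, found: ",
           paste(eds, collapse = ", "))
    samples <- lapply(eds, function(e) table[[coefficient]][table$ed == e])
    names(samples) <- paste0("ED", eds)
    small <- vapply(samples, length, integer(1)) < 3L
    if (any(small))
      stop("each group needs n >= 3; too small: ",
           paste(names(samples)[small], collapse = ", "))
    if (use_normal(samples)) {
      fit <- stats::oneway.test(y ~ g,
                                data = data.frame(
                                  y = unlist(samples),
                                  g = factor(rep(names(samples),
                                                 lengths(samples)))),
                                var.equal = TRUE)
      omni <- list(method = "anova", statistic = unname(fit$statistic),
                   p = fit$p.value)
    } else {
      kw <- stats::kruskal.test(samples)
      omni <- list(method = "kruskal_wallis",
                   statistic = unname(kw$statistic), p = kw$p.value)
    }
    rows[[1L]] <- comparison_row(coefficient, design, "omnibus",
                                 paste(names(samples), collapse = "|"),
                                 omni, lengths(samples))
    cmb <- utils::combn(seq_along(eds), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1L, k]; j <- cmb[2L, k]
      res <- two_sample_test(samples[[i]], samples[[j]],
                             use_normal(samples[c(i, j)]))
      rows[[length(rows) + 1L]] <-
        comparison_row(coefficient, design,
                       paste0(names(samples)[i], "_vs_", names(samples)[j]),
                       paste(names(samples)[c(i, j)], collapse = "|"),
                       res, lengths(samples[c(i, j)]))
    }
  } else {
    need <- c("saline", "vpa")
    present <- unique(table$group)
    if (!all(need %in% present))
      stop("design needs groups saline and vpa; present: ",
           paste(present, collapse = ", "))
    for (e in sort(unique(table$ed))) {
      a <- table[[coefficient]][table$ed == e & table$group == "saline"]
      b <- table[[coefficient]][table$ed == e & table$group == "vpa"]
      if (length(a) < 3L || length(b) < 3L)
        stop("each group needs n >= 3 at ED", e)
      res <- two_sample_test(a, b, use_normal(list(a, b)))
      rows[[length(rows) + 1L]] <-
        comparison_row(coefficient, design,
                       paste0("ED", e, "_saline_vs_vpa"), "saline|vpa",
                       res, c(length(a), length(b)))
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") {
    pw <- out$contrast != "omnibus"
    out$p_adj <- NA_real_
    out$p_adj[pw] <- stats::p.adjust(out$p[pw], method = "holm")
  }
  structure(out, class = c("comparison_result", "data.frame"))
}

#' Full statistical battery over a scores table
#'
#' Runs [trend_with_age()] for each coefficient (when the design has
#' multiple embryonic days in a single-group cohort) and [compare_groups()]
#' per coefficient under the requested design.
#'
#' @param scores scores data.frame (see [analyze_cohort()]).
#' @param design `"development"` (trends + stagewise comparisons) or
#'   `"asd"` (saline-vs-VPA contrasts per ED).
#' @param coefficients score columns to analyze.
#' @param ... passed to [compare_groups()].
#' @return list with `trends` (data.frame or `NULL`) and `comparisons`
#'   (data.frame).
#' @export
cohort_stats <- function(scores, design = c("development", "asd"),
                         coefficients = c("cc1", "cc2", "clf", "chf"),
                         ...) {
  design <- match.arg(design)
  if ("excluded" %in% names(scores))
    scores <- scores[!scores$excluded %in% TRUE, , drop = FALSE]
  trends <- NULL
  if (design == "development") {
    trends <- do.call(rbind, lapply(coefficients, function(co)
      trend_with_age(scores, co)))
    comparisons <- do.call(rbind, lapply(coefficients, function(co)
      compare_groups(scores, co, design = "stagewise", ...)))
  } else {
    comparisons <- do.call(rbind, lapply(coefficients, function(co)
      compare_groups(scores, co, design = "saline_vs_vpa", ...)))
  }
  list(trends = trends, comparisons = comparisons)
}
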