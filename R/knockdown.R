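# Attribution of knockdown differential-expression and splicing effects to
# binding-site classes.

#' Summarise binding sites per gene by class
#'
#' Counts peaks per gene in the classes TE/nonrepetitive x exon/intron
#' (`alu_split = TRUE` additionally separates Alu from other TEs, for
#' analyses asking whether Alu sites behave differently) and derives each
#' gene's exclusive class: bound only in TEs, only in nonrepetitive sequence,
#' only in Alu (alu mode), mixed, or unbound. Every gene of the annotation is
#' reported; peaks whose gene is absent from the annotation are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param peaks peak table from [call_peaks()].
#' @param isoforms exon table (defines the gene universe).
#' @param alu_split separate Alu-family sites from other TEs (default FALSE).
#' @return data.table with gene_id, one count column per class (e.g.
#'   `TE_exon`, `nonrep_intron`, ...), `n_sites`, `bound`, `exclusive_class`.
#' @export
summarize_binding <- function(peaks, isoforms, alu_split = FALSE) {
  iso <- data.table::as.data.table(isoforms)
  genes <- unique(iso$gene_id)
  genes <- genes[!is.na(genes)]
  pk <- data.table::as.data.table(peaks)
  known <- !is.na(pk$gene_id) & pk$gene_id %in% genes
  n_dropped <- sum(!known)
  pk <- pk[known]
  grp <- function(site_class, alu) {
    base <- data.table::fifelse(site_class == "nonrepetitive", "nonrep", "TE")
    if (alu_split) base[alu] <- "Alu"
    base
  }
  classes <- if (alu_split)
    c("Alu_exon", "Alu_intron", "TE_exon", "TE_intron",
      "nonrep_exon", "nonrep_intron")
  else c("TE_exon", "TE_intron", "nonrep_exon", "nonrep_intron")
  out <- data.table::data.table(gene_id = genes)
  for (cl in classes) out[, (cl) := 0L]
  if (nrow(pk)) {
    pk[, cls := paste(grp(site_class, alu), region, sep = "_")]
    cnt <- pk[, .N, by = .(gene_id, cls)]
    for (cl in classes) {
      m <- cnt[cls == cl]
      if (nrow(m)) out[m, on = "gene_id", (cl) := m$N]
    }
  }
  cm <- as.matrix(out[, ..classes])
  out[, n_sites := rowSums(cm)]
  out[, bound := n_sites > 0L]
  pref <- sub("_.*$", "", classes)
  groups <- unique(pref)
  present <- sapply(groups, function(g)
    rowSums(cm[, pref == g, drop = FALSE]) > 0L)
  if (is.null(dim(present))) present <- matrix(present, nrow = 1L,
                                               dimnames = list(NULL, groups))
  ngrp <- rowSums(present)
  excl <- rep("unbound", nrow(out))
  one <- which(ngrp == 1L)
  if (length(one))
    excl[one] <- paste0(groups[apply(present[one, , drop = FALSE], 1L,
                                     which.max)], "-only")
  excl[ngrp > 1L] <- "mixed"
  out[, exclusive_class := excl]
  data.table::setattr(out, "n_dropped", n_dropped)
  out[]
}

# resolve a class label to a gene subset of the summaries
select_class_genes <- function(summaries, label) {
  s <- data.table::as.data.table(summaries)
  if (label == "bound") return(s[bound == TRUE, gene_id])
  if (label == "unbound") return(s[bound == FALSE, gene_id])
  s[exclusive_class == label, gene_id]
}

#' Compare knockdown statistic distributions between two gene classes
#'
#' Two-sided Mann-Whitney test and median shift of the per-gene statistic
#' between two classes (exclusive-class labels like `"TE-only"`,
#' `"nonrep-only"`, `"Alu-only"`, or the special labels `"bound"` /
#' `"unbound"`). Also bins genes by total site count and reports the median
#' and interquartile range of the statistic per bin.
#'
#' @param summaries binding summaries from [summarize_binding()].
#' @param stats knockdown table with `gene_id` and the statistic column.
#' @param class_a,class_b class labels.
#' @param value statistic column name (default `"de_stat"`); use
#'   [splicing_class_analysis()] for splicing p-values.
#' @param min_n minimum genes per class (default 20).
#' @return list with `p_value`, `shift` (median a - median b), `n_a`, `n_b`,
#'   and `by_count` (site-count bins with median and IQR); all-`NA` when a
#'   class is empty or too small.
#' @export
compare_class_cdfs <- function(summaries, stats, class_a, class_b,
                               value = "de_stat", min_n = 20L) {
  st <- data.table::as.data.table(stats)
  su <- data.table::as.data.table(summaries)
  ga <- select_class_genes(su, class_a)
  gb <- select_class_genes(su, class_b)
  va <- st[gene_id %in% ga][[value]]
  vb <- st[gene_id %in% gb][[value]]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  merged <- merge(su[, .(gene_id, n_sites)], st, by = "gene_id")
  bins <- c(0, 1, 2, 3, 5, 9, Inf)
  merged[, bin := cut(n_sites, breaks = bins, right = FALSE)]
  by_count <- merged[, .(median = stats::median(get(value), na.rm = TRUE),
                         q25 = stats::quantile(get(value), 0.25, na.rm = TRUE),
                         q75 = stats::quantile(get(value), 0.75, na.rm = TRUE),
                         n = .N), by = bin]
  data.table::setorder(by_count, bin)
  if (length(va) < min_n || length(vb) < min_n) {
    return(list(p_value = NA_real_, shift = NA_real_,
                n_a = length(va), n_b = length(vb), by_count = by_count[]))
  }
  wt <- stats::wilcox.test(va, vb, alternative = "two.sided", exact = FALSE)
  list(p_value = wt$p.value,
       shift = stats::median(va) - stats::median(vb),
       n_a = length(va), n_b = length(vb), by_count = by_count[])
}

#' Linear regression of the knockdown statistic on site-class counts
#'
#' Ordinary least squares with intercept predicting the per-gene statistic
#' from `log2(1 + n_sites)` in every class; classes with no sites at all are
#' dropped with a warning (their coefficients are not identifiable).
#'
#' @param summaries binding summaries from [summarize_binding()].
#' @param stats knockdown table.
#' @param value statistic column (default `"de_stat"`).
#' @param classes class columns to use; default all count columns of
#'   `summaries`.
#' @param conf_level confidence level for the normal-theory intervals.
#' @return data.table with term, estimate, ci_lo, ci_hi (intercept included);
#'   dropped classes appear with `NA` estimates.
#' @export
site_class_regression <- function(summaries, stats, value = "de_stat",
                                  classes = NULL, conf_level = 0.95) {
  su <- data.table::as.data.table(summaries)
  st <- data.table::as.data.table(stats)
  classes <- classes %||% setdiff(
    names(su), c("gene_id", "n_sites", "bound", "exclusive_class"))
  d <- merge(su, st, by = "gene_id")
  y <- d[[value]]
  X <- lapply(classes, function(cl) log2(1 + d[[cl]]))
  names(X) <- classes
  active <- vapply(X, function(v) any(v > 0), logical(1))
  if (!all(active))
    warnf("dropping empty site class(es): %s",
          paste(classes[!active], collapse = ", "))
  keep <- classes[active]
  out <- data.table::data.table(term = c("(Intercept)", classes),
                                estimate = NA_real_, ci_lo = NA_real_,
                                ci_hi = NA_real_)
  if (!length(keep)) {
    fit <- stats::lm(y ~ 1)
    ci <- stats::confint(fit, level = conf_level)
    out[term == "(Intercept)", `:=`(estimate = coef(fit)[[1]],
                                    ci_lo = ci[1, 1], ci_hi = ci[1, 2])]
    return(out[])
  }
  df <- data.frame(y = y, X[keep], check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  ci <- stats::confint(fit, level = conf_level)
  est <- coef(fit)
  terms <- c("(Intercept)", keep)
  rn <- rownames(ci)
  for (i in seq_along(terms)) {
    nm <- if (i == 1L) "(Intercept)" else paste0("`", terms[i], "`")
    row <- match(nm, rn)
    if (is.na(row)) row <- match(terms[i], rn)
    out[term == terms[i], `:=`(estimate = est[[row]],
                               ci_lo = ci[row, 1], ci_hi = ci[row, 2])]
  }
  out[]
}

#' Splicing-difference analysis by binding-site class
#'
#' Applies the class-CDF machinery to `-log10(splice_p)`, so a positive shift
#' means more evidence of splicing change in the first class.
#'
#' @inheritParams compare_class_cdfs
#' @return as [compare_class_cdfs()].
#' @export
splicing_class_analysis <- function(summaries, stats, class_a, class_b,
                                    min_n = 20L) {
  st <- data.table::as.data.table(stats)
  st[, neglog_splice := -log10(pmax(splice_p, .Machine$double.xmin))]
  compare_class_cdfs(summaries, st, class_a, class_b,
                     value = "neglog_splice", min_n = min_n)
}
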