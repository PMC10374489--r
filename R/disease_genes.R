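# Disease-relevant gene selection: per-gene rank-sum test on location and
# F-test on variance between disease and control samples, with BH adjustment
# within each test family.

split_conditions <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  list(disease = ds$values[, ds$condition == "disease", drop = FALSE],
       control = ds$values[, ds$condition == "control", drop = FALSE])
}

#' Rank-sum (Wilcoxon) scan over all genes
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test of disease vs control per
#' gene. The exact null distribution is used when `min(n1, n2) <= 8` and
#' the gene has no tied values; otherwise the normal approximation with tie
#' correction and continuity correction. A gene constant across all samples
#' gets `p = 1` and is flagged.
#'
#' @param ds an [expression_dataset()].
#' @return data.frame with columns `gene_id`, `wilcoxon_stat` (Mann-Whitney
#'   U of the disease group), `wilcoxon_p`, `flag_constant`.
#' @export
wilcoxon_scan <- function(ds) {
  sp <- split_conditions(ds)
  n1 <- ncol(sp$disease)
  if (n1 < 2 || ncol(sp$control) < 2)
    stop("need >= 2 samples per condition")
  res <- t(vapply(seq_len(nrow(ds$values)), function(i) {
    x <- sp$disease[i, ]; y <- sp$control[i, ]
    if (var(c(x, y)) == 0) return(c(stat = length(x) * length(y) / 2, p = 1,
                                    flag = 1))
    ties <- anyDuplicated(c(x, y)) > 0
    use_exact <- !ties && min(length(x), length(y)) <= 8
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                              exact = use_exact,
                                              correct = TRUE))
    c(stat = unname(wt$statistic), p = min(1, wt$p.value), flag = 0)
  }, numeric(3)))
  data.frame(gene_id = rownames(ds$values),
             wilcoxon_stat = res[, 1],
             wilcoxon_p = res[, 2],
             flag_constant = res[, 3] == 1,
             stringsAsFactors = FALSE)
}

#' Variance-ratio (F) scan over all genes
#'
#' Per gene, F = s2_disease / s2_control (sample variances, denominator
#' n-1) with two-sided p = 2 * min(P(F <= f), P(F >= f)) capped at 1,
#' computed by [stats::var.test()]. Genes with zero variance in either
#' group are flagged (`flag_zero_var`) and get `NA` p-values; flagged genes
#' are excluded from BH adjustment downstream.
#'
#' @param ds an [expression_dataset()].
#' @return data.frame with `gene_id`, `f_stat`, `f_p`, `flag_zero_var`.
#' @export
variance_f_scan <- function(ds) {
  sp <- split_conditions(ds)
  if (ncol(sp$disease) < 2 || ncol(sp$control) < 2)
    stop("need >= 2 samples per condition")
  res <- t(vapply(seq_len(nrow(ds$values)), function(i) {
    x <- sp$disease[i, ]; y <- sp$control[i, ]
    v1 <- var(x); v2 <- var(y)
    if (v1 == 0 || v2 == 0)
      return(c(f = if (v2 > 0) 0 else NA_real_, p = NA_real_, flag = 1))
    ft <- stats::var.test(x, y, alternative = "two.sided")
    c(f = unname(ft$estimate), p = ft$p.value, flag = 0)
  }, numeric(3)))
  data.frame(gene_id = rownames(ds$values),
             f_stat = res[, 1],
             f_p = res[, 2],
             flag_zero_var = res[, 3] == 1,
             stringsAsFactors = FALSE)
}

#' Run both gene-level tests and adjust for multiplicity
#'
#' @param ds an [expression_dataset()].
#' @return data.frame with both tests' statistics, raw p-values and
#'   Benjamini-Hochberg q-values (adjusted within each test family
#'   separately; flagged genes excluded from adjustment).
#' @export
gene_test_scan <- function(ds) {
  w <- wilcoxon_scan(ds)
  f <- variance_f_scan(ds)
  out <- merge(w, f, by = "gene_id", sort = FALSE)
  out <- out[match(rownames(ds$values), out$gene_id), ]
  rownames(out) <- NULL
  out$wilcoxon_q <- NA_real_
  ok_w <- !out$flag_constant
  out$wilcoxon_q[ok_w] <- p.adjust(out$wilcoxon_p[ok_w], method = "BH")
  out$f_q <- NA_real_
  ok_f <- !out$flag_zero_var & !is.na(out$f_p)
  out$f_q[ok_f] <- p.adjust(out$f_p[ok_f], method = "BH")
  out
}

#' Select disease-relevant genes at an FDR level
#'
#' @param results output of [gene_test_scan()].
#' @param alpha FDR level in (0, 1).
#' @param mode how the two tests are combined: `"union"` (default; selected
#'   when either q-value clears `alpha`), `"intersection"`,
#'   `"location_only"` or `"variance_only"`.
#' @return the input data.frame with a logical `selected` column.
#' @export
select_genes <- function(results, alpha = 0.05,
                         mode = c("union", "intersection", "location_only",
                                  "variance_only")) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)")
  wq <- !is.na(results$wilcoxon_q) & results$wilcoxon_q < alpha
  fq <- !is.na(results$f_q) & results$f_q < alpha
  results$selected <- switch(mode,
    union = wq | fq,
    intersection = wq & fq,
    location_only = wq,
    variance_only = fq)
  results
}

#' Write a gene test table
#' @param results data.frame from [gene_test_scan()]/[select_genes()].
#' @param path output TSV.
#' @param config optional header config.
#' @export
write_gene_results <- function(results, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_config_header(con, config)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
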