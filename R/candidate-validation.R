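#' Per-group summary statistics of a trait
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and standard
#' error of the mean per group.
#'
#' @param fixture data.frame with a group column and a trait column (e.g. from
#'   [table1_fixture()] or [generate_validation_fixture()]).
#' @param trait,group column names.
#' @return data.frame with columns `group`, `n`, `mean`, `sd`, `sem`.
#' @examples
#' group_stats(table1_fixture())
#' @export
group_stats <- function(fixture, trait = "imf_percent", group = "group") {
  stopifnot(is.data.frame(fixture),
            all(c(trait, group) %in% names(fixture)))
  g <- fixture[[group]]
  lv <- if (is.factor(g)) levels(droplevels(g)) else unique(g)
  n <- vapply(lv, function(l) sum(g == l), 0L)
  if (any(n < 2))
    stop("group(s) with fewer than 2 observations (SEM undefined): ",
         paste(lv[n < 2], collapse = ", "), call. = FALSE)
  m <- vapply(lv, function(l) mean(fixture[[trait]][g == l]), 0)
  s <- vapply(lv, function(l) sd(fixture[[trait]][g == l]), 0)
  data.frame(group = lv, n = n, mean = m, sd = s, sem = s / sqrt(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold change of a gene between trait groups
#'
#' Ratio of the high-group mean expression to the low-group mean.
#'
#' @param fixture data.frame with `group` and the gene's expression column.
#' @param gene expression column name.
#' @param high,low group labels forming the ratio.
#' @return A single number, `mean(high) / mean(low)`.
#' @export
fold_change <- function(fixture, gene, high = "high", low = "low") {
  stopifnot(is.data.frame(fixture), gene %in% names(fixture),
            "group" %in% names(fixture))
  m_low <- mean(fixture[[gene]][fixture$group == low])
  m_high <- mean(fixture[[gene]][fixture$group == high])
  if (!is.finite(m_low) || m_low <= 0)
    stop("low-group mean must be positive for a fold change (got ",
         format(m_low), ")", call. = FALSE)
  m_high / m_low
}

#' Covariate-adjusted regression of the trait on a gene's expression
#'
#' Ordinary least squares of the trait on the gene's normalized expression
#' plus covariates (slaughter age and housekeeping expression by default):
#' `trait = mu + b * expression + covariates + residual`. Reports the
#' expression coefficient with its standard error, t statistic and two-sided
#' p-value on the residual degrees of freedom.
#'
#' @param fixture data.frame holding the trait, expression and covariates.
#' @param gene expression column name.
#' @param covariates character vector of covariate column names.
#' @param trait trait column name.
#' @return An object of class `regression_report`: list with `gene`,
#'   `coefficients` (estimate/se/t/p matrix), `expression_estimate`,
#'   `expression_p`, `df_residual`, `n`, `fit`.
#' @export
trait_regression <- function(fixture, gene,
                             covariates = c("age_months", "housekeeping"),
                             trait = "imf_percent") {
  stopifnot(is.data.frame(fixture),
            all(c(gene, covariates, trait) %in% names(fixture)))
  df <- fixture[, c(trait, gene, covariates), drop = FALSE]
  names(df)[1:2] <- c(".trait", ".expression")
  form <- stats::as.formula(paste(".trait ~ .expression",
                                  paste(c("", covariates), collapse = " + ")))
  X <- model.matrix(form, data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    dropped <- sub("^\\.expression$", gene, dropped)
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) <= ncol(X))
    stop("need more observations than coefficients", call. = FALSE)
  fit <- lm(form, data = df)
  cf <- summary(fit)$coefficients
  rownames(cf) <- sub("^\\.expression$", gene, rownames(cf))
  structure(list(gene = gene,
                 coefficients = cf,
                 expression_estimate = cf[gene, "Estimate"],
                 expression_p = cf[gene, "Pr(>|t|)"],
                 df_residual = fit$df.residual,
                 n = nrow(df),
                 fit = fit),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("Trait regression for", x$gene,
      sprintf("(n = %d, residual df = %d)\n", x$n, x$df_residual))
  p <- x$expression_p
  cat(sprintf("  expression coefficient %.4g, p %s\n",
              x$expression_estimate,
              if (p < 1e-15) "< 1e-15" else sprintf("= %.4g", p)))
  invisible(x)
}

#' Pearson correlation between a gene's expression and the trait
#'
#' Pearson r with the two-sided p-value from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. Perfect
#' correlations (|r| = 1) get p = 0.
#'
#' @inheritParams trait_regression
#' @return list with `r`, `p_value`, `n`, `t`.
#' @export
expression_trait_correlation <- function(fixture, gene,
                                         trait = "imf_percent") {
  stopifnot(is.data.frame(fixture),
            all(c(gene, trait) %in% names(fixture)))
  x <- fixture[[gene]]; y <- fixture[[trait]]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in ", if (sd(x) == 0) gene else trait, call. = FALSE)
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p_value = 0, n = n, t = Inf))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE),
       n = n, t = t_stat)
}

#' PCA of candidate-gene expression across samples
#'
#' Principal components of the samples x genes expression matrix, each gene
#' centered and (by default) scaled to unit variance — correlation-matrix PCA,
#' appropriate when gene scales differ. Reports loadings, per-sample scores,
#' the proportion of variance per component, and the sign of each gene's
#' loading on PC2 as its `pc2_relationship` ("positive"/"negative") — the
#' axis along which the validation samples separate into trait groups.
#'
#' @param fixture data.frame holding one expression column per gene.
#' @param genes character vector of gene columns (>= 2).
#' @param scale. scale genes to unit variance (default TRUE).
#' @return An object of class `pca_report`: list with `loadings`, `scores`,
#'   `var_prop`, `cum_prop`, `pc2_relationship`, `sdev`.
#' @export
candidate_pca <- function(fixture, genes, scale. = TRUE) {
  stopifnot(is.data.frame(fixture), length(genes) >= 2,
            all(genes %in% names(fixture)))
  X <- as.matrix(fixture[, genes, drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 samples", call. = FALSE)
  const <- genes[apply(X, 2, sd) == 0]
  if (length(const) > 0)
    stop("constant gene(s): ", paste(const, collapse = ", "), call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = scale.)
  var_prop <- pc$sdev^2 / sum(pc$sdev^2)
  rel <- ifelse(pc$rotation[, min(2, ncol(pc$rotation))] >= 0,
                "positive", "negative")
  structure(list(loadings = pc$rotation,
                 scores = pc$x,
                 var_prop = var_prop,
                 cum_prop = cumsum(var_prop),
                 pc2_relationship = setNames(rel, genes),
                 sdev = pc$sdev),
            class = "pca_report")
}

#' @export
print.pca_report <- function(x, ...) {
  k <- min(3, length(x$var_prop))
  cat("PCA of", nrow(x$loadings), "genes:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_prop[seq_len(k)]),
            collapse = ", "),
      sprintf("(first two: %.1f%%)\n", 100 * x$cum_prop[min(2,
              length(x$cum_prop))]))
  invisible(x)
}
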