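#' Regress virus read abundance on Wolbachia read abundance
#'
#' Fits the simple linear regression of per-sample virus read percentage
#' (response) on *Wolbachia* read percentage (predictor) by ordinary
#' least squares, with the Pearson correlation and its two-sided p-value
#' from the t statistic `r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom (identical to the regression slope test). Used to
#' ask whether endosymbiont load predicts viral load across samples.
#'
#' @param table data.frame with columns `sample`, `pct_virus`,
#'   `pct_wolbachia` (see [simulate_abundance_table()],
#'   [read_abundance_tsv()]).
#' @param drop_samples optional sample IDs to exclude before fitting
#'   (e.g. a suspected outlier); the default keeps every row.
#' @return object of class `abundance_fit`: list with `slope`,
#'   `intercept`, `r`, `p`, `n` and the underlying `lm` fit.
#' @examples
#' tab <- simulate_abundance_table(10, slope = -0.05, intercept = 0.4,
#'                                 noise_sd = 0.1, seed = 2)
#' correlate_abundance(tab)
#' @export
correlate_abundance <- function(table, drop_samples = NULL) {
  stopifnot(is.data.frame(table),
            all(c("sample", "pct_virus", "pct_wolbachia") %in% names(table)))
  if (anyDuplicated(table$sample)) stop("sample IDs must be unique")
  if (!is.null(drop_samples)) {
    unknown <- setdiff(drop_samples, table$sample)
    if (length(unknown)) {
      stop("drop_samples not in table: ", paste(unknown, collapse = ", "))
    }
    table <- table[!table$sample %in% drop_samples, , drop = FALSE]
  }
  n <- nrow(table)
  if (n < 3L) stop("need at least 3 samples for regression")
  x <- table$pct_wolbachia
  y <- table$pct_virus
  if (!all(is.finite(x)) || !all(is.finite(y)) || any(x < 0) || any(y < 0)) {
    stop("read percentages must be finite and >= 0")
  }
  if (isTRUE(all.equal(max(x), min(x)))) {
    stop("zero variance in predictor")
  }
  fit <- lm(y ~ x)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r = unname(ct$estimate), p = ct$p.value, n = n,
                 fit = fit),
            class = "abundance_fit")
}

#' @export
print.abundance_fit <- function(x, ...) {
  # rendering matches the field's reporting: slope to 3 decimals,
  # intercept/r/p to 2
  cat(sprintf("y = %.2f %s %.3f x   (r = %.2f, p = %.2f, n = %d)\n",
              x$intercept, if (x$slope < 0) "-" else "+", abs(x$slope),
              x$r, x$p, x$n))
  invisible(x)
}
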