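#' Classical Gram-Schmidt orthogonalisation with z-normalised output
#'
#' Sequentially removes from each column the projections onto all earlier
#' columns (classical, not modified, Gram-Schmidt), unit-normalises each
#' residual, and finally z-normalises every column (mean 0, SD 1). Column k
#' of the output therefore spans exactly the part of column k of `X` that is
#' orthogonal to columns 1..k-1 — the basis used for incremental variance
#' decomposition of an ordered predictor set. Columns are centred before the
#' sweep.
#'
#' @param X Numeric matrix, p <= n, numerically independent columns.
#' @param tol Relative residual-norm threshold below which a column is
#'   declared collinear with its predecessors (default 1e-12).
#' @return Matrix `U` with orthogonal, z-normalised columns (same dimnames).
#' @examples
#' u <- gram_schmidt(matrix(rnorm(60), 20, 3))
#' max(abs(crossprod(u)[lower.tri(diag(3))]))   # ~0
#' @export
gram_schmidt <- function(X, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (p > n) stop("more columns than rows", call. = FALSE)
  X <- scale(X, center = TRUE, scale = FALSE)
  U <- matrix(0, n, p, dimnames = dimnames(X))
  for (i in seq_len(p)) {
    u <- X[, i]
    orig_norm <- sqrt(sum(u^2))
    if (orig_norm == 0) {
      stop("column ", colnames(X)[i] %||% i, " has zero variance",
           call. = FALSE)
    }
    for (j in seq_len(i - 1)) {
      u <- u - sum(u * U[, j]) * U[, j]
    }
    res_norm <- sqrt(sum(u^2))
    if (res_norm < tol * orig_norm) {
      stop("column ", colnames(X)[i] %||% i,
           " is collinear with preceding columns", call. = FALSE)
    }
    U[, i] <- u / res_norm
  }
  scale(U) # z-normalisation: mean 0, sd 1 per column
}

#' Progressive (incremental) regression via sequential residualisation
#'
#' Decomposes the variance in an outcome explained by an ordered predictor
#' set: predictors are Gram-Schmidt residualised in the declared order
#' (conventional predictors first, the focal network measure last), the
#' z-scored outcome is regressed on the orthogonalised design, and each
#' predictor's incremental R-squared — the extra outcome variance it explains
#' beyond everything before it — is its squared correlation with the outcome.
#' The focal (last) predictor's increment is the headline "incremental
#' significance" statistic. Because the orthogonalised columns are
#' uncorrelated, the incremental R-squared values sum exactly to the joint
#' model's R-squared, and each coefficient's two-sided t-test equals the
#' sequential 1-df F-test.
#'
#' Factor predictors (sex, site) are expanded to dummy columns in level
#' order and centred before orthogonalisation; the declared predictor order
#' is preserved.
#'
#' @param data Data frame holding outcome and predictors, one row per
#'   subject.
#' @param outcome Name of the outcome column (z-scored internally).
#' @param predictors Character vector of predictor columns, in conventional
#'   order — e.g. covariates, then mean edge weight, then common graph
#'   measures, then the focal variability measure.
#' @param focal Name of the focal predictor; default the last of
#'   `predictors`.
#' @param fdr Apply Benjamini-Hochberg adjustment across the reported terms.
#' @return An `incremental_fit`: tibble with one row per design column
#'   (`term`, `beta`, `incremental_r2`, `p_value`, `p_fdr`, `focal`), plus
#'   attributes `r_squared`, `n`, `outcome`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
progressive_models <- function(data, outcome, predictors,
                               focal = predictors[length(predictors)],
                               fdr = TRUE) {
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) stop("outcome column not found",
                                      call. = FALSE)
  missing_pred <- setdiff(predictors, names(data))
  if (length(missing_pred)) {
    stop("predictor column(s) not found: ",
         paste(missing_pred, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data[c(outcome, predictors)])) {
    stop("missing values in outcome or predictors", call. = FALSE)
  }
  X <- expand_design(data, predictors)
  y <- as.numeric(scale(data[[outcome]]))
  n <- length(y)
  U <- gram_schmidt(X)
  fit <- stats::lm(y ~ U)
  sm <- summary(fit)
  coefs <- sm$coefficients[-1, , drop = FALSE]  # drop intercept
  beta <- as.numeric(stats::cor(y, U))
  out <- tibble::tibble(
    term = colnames(X),
    source = attr(X, "source")[colnames(X)],
    beta = beta,
    incremental_r2 = beta^2,
    p_value = coefs[, 4],
    focal = attr(X, "source")[colnames(X)] == focal
  )
  out$p_fdr <- if (fdr) fdr_adjust(out$p_value) else out$p_value
  structure(out,
            class = c("incremental_fit", class(out)),
            r_squared = sm$r.squared, n = n, outcome = outcome,
            U = U)
}

# expand predictors to numeric design columns in declared order; factors
# become centred dummy columns in level order
expand_design <- function(data, predictors) {
  cols <- list()
  source <- character(0)
  for (p in predictors) {
    v <- data[[p]]
    if (is.numeric(v)) {
      cols[[p]] <- v
      source[p] <- p
    } else {
      f <- as.factor(v)
      if (nlevels(f) < 2) stop("factor predictor ", p, " has one level",
                               call. = FALSE)
      for (lev in levels(f)[-1]) {
        nm <- paste0(p, lev)
        cols[[nm]] <- as.numeric(f == lev)
        source[nm] <- p
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance design column(s): ",
         paste(colnames(X)[v == 0], collapse = ", "), call. = FALSE)
  }
  attr(X, "source") <- source
  X
}

#' @export
tidy.incremental_fit <- function(x, ...) {
  tibble::as_tibble(x)[c("term", "source", "beta", "incremental_r2",
                         "p_value", "p_fdr", "focal")]
}

#' @export
glance.incremental_fit <- function(x, ...) {
  focal_rows <- which(x$focal)
  tibble::tibble(
    r_squared = attr(x, "r_squared"),
    n = attr(x, "n"),
    n_terms = nrow(x),
    focal_incremental_r2 = sum(x$incremental_r2[focal_rows]),
    focal_p_fdr = if (length(focal_rows)) min(x$p_fdr[focal_rows]) else
      NA_real_
  )
}

#' @export
autoplot.incremental_fit <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$incremental_r2, y = .data$term,
                                  fill = .data$focal)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(incremental ~ R^2), y = NULL,
                  title = sprintf("Incremental variance decomposition (total R² = %.3f)",
                                  attr(object, "r_squared")))
}

#' Covariate-adjusted association scan over measures
#'
#' For each measure column, residualises both the outcome and the measure on
#' the covariates, z-scores the measure residuals, and reports the
#' standardised coefficient of the z-scored outcome on them (equal to the
#' correlation between the two residual vectors scaled by the outcome's
#' residual share), its two-sided p-value, and the Benjamini-Hochberg
#' adjusted p across the scanned family. Residualising before standardising
#' keeps the coefficient stable even when a measure is nearly a covariate
#' function.
#'
#' @param data Data frame with outcome, covariates, and measure columns.
#' @param measures Character vector of measure column names to scan.
#' @param outcome Outcome column name (e.g. `"g"`).
#' @param covariates Character vector of covariate columns (age, sex,
#'   site, ...); factors handled automatically.
#' @return Tibble: `measure`, `beta`, `p_value`, `p_fdr`, `n`. Measures with
#'   zero residual variance are skipped with a warning.
#' @export
association_scan <- function(data, measures, outcome = "g",
                             covariates = c("age", "sex", "site")) {
  data <- as.data.frame(data)
  cov_fml <- stats::as.formula(paste("..v ~",
                                     paste(covariates, collapse = " + ")))
  rows <- purrr::map(measures, function(mcol) {
    keep <- stats::complete.cases(data[c(outcome, covariates, mcol)])
    d <- data[keep, , drop = FALSE]
    d$..v <- as.numeric(scale(d[[outcome]]))
    ry <- stats::residuals(stats::lm(cov_fml, data = d))
    d$..v <- d[[mcol]]
    rm_ <- stats::residuals(stats::lm(cov_fml, data = d))
    if (stats::var(rm_) < .Machine$double.eps * max(1, stats::var(d$..v))) {
      warning("measure '", mcol, "' has zero residual variance; skipped",
              call. = FALSE)
      return(NULL)
    }
    sm <- summary(stats::lm(ry ~ scale(rm_)))
    co <- sm$coefficients[2, ]
    tibble::tibble(measure = mcol, beta = co[1], p_value = co[4],
                   n = nrow(d))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$p_fdr <- fdr_adjust(out$p_value)
  dplyr::relocate(out, "p_fdr", .after = "p_value")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjusted p-values: monotone, bounded by 1, controlling
#' the FDR across the scanned family.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method Only `"benjamini_hochberg"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p, method = "benjamini_hochberg") {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
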