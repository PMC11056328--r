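## Cohort statistics layer: descriptive summaries, Student's t group
## comparisons, age-adjusted Pearson partial correlations with hat-value
## leverage exclusion, and Fisher z-tests comparing correlations between
## groups. Missing values are handled pairwise-complete per analysis (the
## CPET variables exist only in a subgroup of the cohort).

## coerce the covariate argument to a numeric matrix (or NULL)
.covMatrix <- function(z, n) {
  if (is.null(z) || (is.data.frame(z) && ncol(z) == 0L)) return(NULL)
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (nrow(z) != n) stop("argument error: covariate rows must match x/y")
  z
}

#' Leverage-point detection
#'
#' Hat-matrix leverages from the regression design \code{[1, covariates, x]}
#' predicting y; cases with \eqn{h_i > 3 \bar h} are flagged (a single pass,
#' no iteration). The mean hat value is analytically \eqn{(k+1)/n} for a
#' full-rank design with k predictors, so the threshold is \eqn{3(k+1)/n}.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame/matrix of adjusters.
#' @return a list with \code{kept}, \code{excluded} (indices into the
#'   complete cases), \code{leverage}, \code{threshold} and \code{cases}
#'   (indices of the complete cases in the input).
#' @export
leveragePoints <- function(x, y, covariates = NULL) {
  z <- .covMatrix(covariates, length(x))
  cc <- is.finite(x) & is.finite(y)
  if (!is.null(z)) cc <- cc & apply(is.finite(z), 1, all)
  cases <- which(cc)
  if (length(cases) < 5L)
    stop("argument error: need at least 5 complete cases")
  X <- cbind(1, if (!is.null(z)) z[cases, , drop = FALSE], x[cases])
  if (qr(X)$rank < ncol(X)) stop("collinear design")
  h <- stats::hat(X, intercept = FALSE)          # design already has one
  thr <- 3 * mean(h)
  list(kept = which(h <= thr), excluded = which(h > thr),
       leverage = h, threshold = thr, cases = cases)
}

#' Pearson partial correlation
#'
#' Correlation of x and y after each is regressed on the covariates
#' (age-adjusted when \code{covariates} holds age); with no covariates this
#' reduces to the plain Pearson correlation. The p-value uses the t
#' distribution with \eqn{n - 2 - k} degrees of freedom. Complete cases are
#' used pairwise for this analysis only; optional single-pass leverage
#' exclusion (see [leveragePoints()]) drops high-leverage cases first.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame/matrix of adjusters (e.g. age).
#' @param excludeLeverage drop cases with hat value above three times the
#'   mean before correlating.
#' @param ids optional case identifiers for reporting exclusions.
#' @return an object of class \code{"partialCorrelation"}: \code{estimate},
#'   \code{statistic} (t), \code{df}, \code{p.value}, \code{nUsed},
#'   \code{excluded}, \code{adjusters}.
#' @export
partialCorrelation <- function(x, y, covariates = NULL,
                               excludeLeverage = FALSE, ids = NULL) {
  z <- .covMatrix(covariates, length(x))
  k <- if (is.null(z)) 0L else ncol(z)
  cc <- is.finite(x) & is.finite(y)
  if (!is.null(z)) cc <- cc & apply(is.finite(z), 1, all)
  cases <- which(cc)
  if (length(cases) < 4L + k)
    stop("argument error: need at least ", 4L + k, " complete cases")
  excludedIdx <- integer(0)
  if (excludeLeverage) {
    lev <- leveragePoints(x, y, covariates)
    excludedIdx <- lev$cases[lev$excluded]
    cases <- lev$cases[lev$kept]
  }
  xi <- x[cases]; yi <- y[cases]
  n <- length(cases)
  if (is.null(z)) {
    rx <- xi - mean(xi); ry <- yi - mean(yi)
  } else {
    X <- cbind(1, z[cases, , drop = FALSE])
    rx <- stats::lm.fit(X, xi)$residuals
    ry <- stats::lm.fit(X, yi)$residuals
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("degenerate variable: constant after residualization")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - k
  tstat <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(
    estimate = r, statistic = tstat, df = df, p.value = p,
    nUsed = n,
    excluded = if (is.null(ids)) excludedIdx else ids[excludedIdx],
    adjusters = if (is.null(z)) character(0)
                else colnames(z) %||% paste0("z", seq_len(k))),
    class = "partialCorrelation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.partialCorrelation <- function(x, ...) {
  adj <- if (length(x$adjusters))
    paste0(" adjusted for ", paste(x$adjusters, collapse = ", ")) else ""
  cat(sprintf("Partial correlation%s: r = %.3f, t(%d) = %.2f, p = %.4g, n = %d\n",
              adj, x$estimate, x$df, x$statistic, x$p.value, x$nUsed))
  if (length(x$excluded))
    cat("  leverage cases excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Two-group comparison of means
#'
#' Student's independent t-test (pooled variance by default; Welch available
#' via \code{welch = TRUE}), with the per-group mean +- SD summaries used in
#' cohort tables.
#'
#' @param values numeric vector.
#' @param group two-level grouping (factor, character or logical).
#' @param welch use the Welch correction instead of pooled variance.
#' @return an object of class \code{"groupComparison"}.
#' @export
compareGroups <- function(values, group, welch = FALSE) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("argument error: group must have two levels")
  ok <- is.finite(values) & !is.na(g)
  v <- values[ok]; g <- droplevels(g[ok])
  na <- sum(g == levels(g)[1]); nb <- sum(g == levels(g)[2])
  if (na < 2L || nb < 2L) stop("empty group: both groups need >= 2 values")
  tt <- stats::t.test(v ~ g, var.equal = !welch)
  a <- v[g == levels(g)[1]]; b <- v[g == levels(g)[2]]
  structure(list(
    levels = levels(g),
    meanA = mean(a), sdA = stats::sd(a), nA = na,
    meanB = mean(b), sdB = stats::sd(b), nB = nb,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p.value = tt$p.value,
    formatted = sprintf("%.3g ± %.3g vs %.3g ± %.3g",
                        mean(a), stats::sd(a), mean(b), stats::sd(b))),
    class = "groupComparison")
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf("%s (n=%d) vs %s (n=%d): %s, t(%.4g) = %.3f, p = %.4g\n",
              x$levels[1], x$nA, x$levels[2], x$nB, x$formatted,
              x$df, x$statistic, x$p.value))
  invisible(x)
}

#' Compare two correlation coefficients (Fisher z-test)
#'
#' Fisher z-transforms each correlation and tests their difference:
#' \eqn{z = (z_1 - z_2) / \sqrt{1/(n_1-3) + 1/(n_2-3)}}, two-sided p from
#' the standard normal. Used to check that correlations do not differ
#' between groups (e.g. by gender).
#'
#' @param r1,r2 correlation coefficients, |r| < 1.
#' @param n1,n2 sample sizes, >= 4.
#' @return an object of class \code{"corComparison"}: \code{statistic} (z),
#'   \code{p.value}.
#' @export
compareCorrelations <- function(r1, n1, r2, n2) {
  if (n1 < 4L || n2 < 4L) stop("argument error: n1 and n2 must be >= 4")
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("transform undefined: |r| must be < 1")
  z1 <- atanh(r1); z2 <- atanh(r2)
  z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(statistic = z, p.value = 2 * stats::pnorm(-abs(z)),
                 r1 = r1, n1 = n1, r2 = r2, n2 = n2),
            class = "corComparison")
}

#' @export
print.corComparison <- function(x, ...) {
  cat(sprintf("Fisher z-test: r1 = %.3f (n=%d) vs r2 = %.3f (n=%d): z = %.3f, p = %.4g\n",
              x$r1, x$n1, x$r2, x$n2, x$statistic, x$p.value))
  invisible(x)
}

#' Descriptive summary of a cohort variable
#'
#' Mean +- SD, or median (IQR: 25th; 75th percentiles, linear-interpolation
#' quantiles) for skewed variables. Missing values are dropped; all-missing
#' input is an error.
#'
#' @param values numeric vector.
#' @param style "mean_sd" or "median_iqr".
#' @return a list with numeric fields and a \code{formatted} string.
#' @export
summarizeVariable <- function(values, style = c("mean_sd", "median_iqr")) {
  style <- match.arg(style)
  v <- values[is.finite(values)]
  if (!length(v)) stop("no data: all values missing")
  if (style == "mean_sd") {
    m <- mean(v)
    s <- if (length(v) >= 2L) stats::sd(v) else NA_real_
    list(style = style, n = length(v), mean = m, sd = s,
         sdUndefined = length(v) < 2L,
         formatted = if (is.na(s)) sprintf("%.3g", m)
                     else sprintf("%.3g ± %.3g", m, s))
  } else {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(style = style, n = length(v), median = q[2], q25 = q[1], q75 = q[3],
         formatted = sprintf("%.3g (%.3g, %.3g)", q[2], q[1], q[3]))
  }
}

#' Run a cohort analysis plan
#'
#' Executes a list of analyses against a cohort table and returns a tidy
#' data.frame. Each plan entry is a list with a \code{type}:
#' \describe{
#'   \item{correlation}{fields x, y, optional adjusters (column names) and
#'     excludeLeverage.}
#'   \item{group}{fields value, group (column names), optional welch.}
#'   \item{summary}{fields value, optional style.}
#' }
#'
#' @param table cohort data.frame (one row per subject).
#' @param plan list of analysis descriptions.
#' @return data.frame with one row per analysis: analysis, type, estimate,
#'   statistic, p.value, n, detail.
#' @export
cohortAnalysis <- function(table, plan) {
  rows <- lapply(seq_along(plan), function(i) {
    an <- plan[[i]]
    ## YAML 1.1 reads a bare `y:` key as boolean TRUE; map it back
    names(an)[names(an) == "TRUE"] <- "y"
    type <- an$type %||% stop("configuration error: plan entry missing 'type'")
    nm <- an$name %||% paste0("analysis", i)
    need <- function(f) {
      v <- an[[f]]
      if (is.null(v)) stop("configuration error: '", type,
                           "' entry missing '", f, "'")
      missingCols <- setdiff(v, names(table))
      if (length(missingCols))
        stop("configuration error: column(s) not in table: ",
             paste(missingCols, collapse = ", "))
      v
    }
    if (type == "correlation") {
      adj <- if (!is.null(an$adjusters)) table[need("adjusters")] else NULL
      pc <- partialCorrelation(table[[need("x")]], table[[need("y")]],
                               covariates = adj,
                               excludeLeverage = isTRUE(an$excludeLeverage),
                               ids = table$id)
      data.frame(analysis = nm, type = type, estimate = pc$estimate,
                 statistic = pc$statistic, p.value = pc$p.value,
                 n = pc$nUsed,
                 detail = paste0("df=", pc$df,
                                 if (length(pc$excluded))
                                   paste0("; excluded=",
                                          paste(pc$excluded, collapse = "|"))
                                 else ""))
    } else if (type == "group") {
      gc <- compareGroups(table[[need("value")]], table[[need("group")]],
                          welch = isTRUE(an$welch))
      data.frame(analysis = nm, type = type,
                 estimate = gc$meanA - gc$meanB, statistic = gc$statistic,
                 p.value = gc$p.value, n = gc$nA + gc$nB,
                 detail = gc$formatted)
    } else if (type == "summary") {
      sm <- summarizeVariable(table[[need("value")]],
                              style = an$style %||% "mean_sd")
      data.frame(analysis = nm, type = type, estimate = NA_real_,
                 statistic = NA_real_, p.value = NA_real_, n = sm$n,
                 detail = sm$formatted)
    } else stop("configuration error: unknown analysis type '", type, "'")
  })
  do.call(rbind, rows)
}
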