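# Compositional and correlation statistics: Bray-Curtis dissimilarity,
# principal coordinates analysis, Pearson correlation maps with two-sided
# t-tests, and one-way ANOVA group comparison.

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities between sample compositions,
#' `d(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))`, computed
#' with [vegan::vegdist()].
#'
#' @param x a `gdgt_table` of fractional abundances (or any non-negative
#'   sample-by-compound matrix / data frame).
#' @return Symmetric numeric matrix with zero diagonal, values in `[0, 1]`,
#'   row/column names from `sample_id` when available.
#' @export
bray_curtis_matrix <- function(x) {
  ids <- NULL
  if (is.data.frame(x)) {
    comp <- attr(x, "compounds")
    if (!is.null(comp)) {
      ids <- if ("sample_id" %in% names(x)) x$sample_id else NULL
      x <- as.data.frame(x)[intersect(brgdgt_ids(), comp)]
    } else {
      x <- x[vapply(x, is.numeric, logical(1))]
    }
  }
  m <- as.matrix(x)
  if (any(m < 0, na.rm = TRUE)) stop("negative entries", call. = FALSE)
  if (any(rowSums(m, na.rm = TRUE) == 0)) {
    stop("empty composition: zero row sum", call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  if (!is.null(ids)) dimnames(d) <- list(ids, ids)
  d
}

#' Principal coordinates analysis
#'
#' Classical PCoA (metric multidimensional scaling by Gower
#' double-centering) of a dissimilarity matrix. Negative eigenvalues —
#' which arise for non-Euclidean dissimilarities such as Bray-Curtis —
#' are reported, not silently corrected; Lingoes or Cailliez corrections
#' are available via [ape::pcoa()].
#'
#' @param d symmetric dissimilarity matrix (or `dist`) with zero diagonal.
#' @param k number of axes to return (default: all positive-eigenvalue
#'   axes, capped at n - 1).
#' @param correction `"none"` (default), `"lingoes"` or `"cailliez"`.
#' @return An object of class `gdgt_pcoa`: list with `points` (samples x
#'   axes), `eig` (all eigenvalues, decreasing), `prop_explained`
#'   (relative to the sum of positive eigenvalues), `negative` (count and
#'   most negative eigenvalue) and `correction`.
#' @export
pcoa_ordination <- function(d, k = NULL,
                            correction = c("none", "lingoes", "cailliez")) {
  correction <- match.arg(correction)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(m)) > 1e-12)) {
    stop("dissimilarity matrix must have zero diagonal", call. = FALSE)
  }
  n <- nrow(m)
  if (correction == "none") {
    # cmdscale warns when fewer than k eigenvalues are positive; the full
    # spectrum is reported below, so the warning is redundant here
    full <- suppressWarnings(stats::cmdscale(m, k = n - 1, eig = TRUE))
    eig <- full$eig
    pts <- full$points
  } else {
    ap <- ape::pcoa(m, correction = correction)
    eig <- ap$values$Corr_eig %||% ap$values$Eigenvalues
    pts <- ap$vectors.cor %||% ap$vectors
  }
  tol <- sqrt(.Machine$double.eps) * max(abs(eig), 1)
  npos <- sum(eig > tol)
  nneg <- sum(eig < -tol)
  if (is.null(k)) k <- max(1L, min(npos, ncol(pts)))
  k <- min(k, ncol(pts))
  pts <- pts[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(k))
  if (!is.null(rownames(m))) rownames(pts) <- rownames(m)
  structure(list(
    points = pts,
    eig = eig,
    prop_explained = ifelse(eig > 0, eig / sum(eig[eig > 0]), 0),
    negative = list(n = nneg, min = if (nneg > 0) min(eig) else 0),
    correction = correction
  ), class = "gdgt_pcoa")
}

#' @export
print.gdgt_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes returned (correction: %s)\n",
              nrow(x$points), ncol(x$points), x$correction))
  k <- seq_len(min(ncol(x$points), length(x$prop_explained)))
  cat("proportion explained:",
      paste(sprintf("%.1f%%", 100 * x$prop_explained[k]), collapse = ", "),
      "\n")
  if (x$negative$n > 0) {
    cat(sprintf("negative eigenvalues: %d (most negative %.4g)\n",
                x$negative$n, x$negative$min))
  }
  invisible(x)
}

#' @export
plot.gdgt_pcoa <- function(x, axes = c(1, 2), ...) {
  p <- x$points
  if (ncol(p) < 2) stop("need at least 2 axes to plot", call. = FALSE)
  graphics::plot(p[, axes[1]], p[, axes[2]],
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1],
                                100 * x$prop_explained[axes[1]]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2],
                                100 * x$prop_explained[axes[2]]),
                 main = "PCoA of Bray-Curtis dissimilarities", ...)
  invisible(x)
}

#' Pearson correlation map
#'
#' Pearson correlations with two-sided t-test p-values
#' (`t = r * sqrt((n - 2) / (1 - r^2))`) for a set of variable pairs, on
#' pairwise-complete cases. Variables named in `log10_vars` (by default
#' `"dou"`, which is analyzed on a logarithmic scale) are log10-transformed
#' before correlating. No multiple-testing correction is applied by
#' default; `adjust = "BH"` applies Benjamini-Hochberg across the map.
#'
#' @param data data frame of numeric variables.
#' @param pairs two-column character matrix / data frame of variable name
#'   pairs; default: all distinct pairs of numeric columns.
#' @param log10_vars variables to log10-transform (non-positive values
#'   become `NA`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with `var1`, `var2`, `r`, `p`, `n` and `transform`
#'   notes; pairs with `n < 3` carry `NA` p-values (flagged in
#'   `transform`).
#' @export
correlation_map <- function(data, pairs = NULL, log10_vars = "dou",
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  if (is.null(pairs)) {
    if (length(num) < 2) stop("need at least two numeric variables",
                              call. = FALSE)
    pairs <- t(utils::combn(num, 2))
  }
  pairs <- as.matrix(pairs)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    v1 <- pairs[i, 1]; v2 <- pairs[i, 2]
    if (!all(c(v1, v2) %in% names(data))) {
      stop("unknown variable(s): ", v1, ", ", v2, call. = FALSE)
    }
    x <- as.numeric(data[[v1]]); y <- as.numeric(data[[v2]])
    notes <- character(0)
    if (v1 %in% log10_vars) { x <- ifelse(x > 0, log10(x), NA); notes <- c(notes, paste0("log10(", v1, ")")) }
    if (v2 %in% log10_vars) { y <- ifelse(y > 0, log10(y), NA); notes <- c(notes, paste0("log10(", v2, ")")) }
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      ct <- stats::cor.test(x[ok], y[ok], alternative = "two.sided")
      r <- unname(ct$estimate); pv <- ct$p.value
    } else if (n == 2) {
      r <- unname(stats::cor(x[ok], y[ok])); pv <- NA_real_
      notes <- c(notes, "n=2: p undefined")
    } else {
      r <- NA_real_; pv <- NA_real_
      notes <- c(notes, "insufficient pairwise-complete cases")
    }
    res[[i]] <- data.frame(var1 = v1, var2 = v2, r = r, p = pv, n = n,
                           transform = paste(notes, collapse = "; "),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' One-way ANOVA group comparison
#'
#' Classical one-way analysis of variance (equal-variance F test) of a
#' numeric response across groups, as used to compare brGDGT compositions
#' and indexes between trench regions. Significance is conventionally
#' judged at p < 0.05.
#'
#' @param values numeric response.
#' @param groups grouping vector (coerced to factor).
#' @return List with `statistic` (F), `df` (between, within),
#'   `p.value`, and the underlying [stats::oneway.test()] result.
#' @export
group_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups[!is.na(values)])) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p.value = ht$p.value,
       test = ht)
}
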