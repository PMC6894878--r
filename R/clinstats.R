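## Statistical layer: the hyperdense-artery-sign rule, Bland-Altman
## agreement, Spearman rank correlation, Pearson chi-squared association,
## and the combined cross-method / clinical agreement report.

#' Hyperdense artery sign from mean clot attenuation
#'
#' A positive hyperdense artery sign (HAS) is defined as a mean clot
#' attenuation of at least 50 Hounsfield Units on non-contrast CT.
#'
#' @param meanHu mean Hounsfield Units (vectorized).
#' @return logical, `TRUE` where `meanHu >= 50`.
#' @examples
#' hasFlag(c(54.0, 49.4, 50.0))
#' @export
hasFlag <- function(meanHu) {
  if (!is.numeric(meanHu) || any(!is.finite(meanHu)))
    stop("meanHu must be finite numeric")
  meanHu >= 50
}

#' Bland-Altman agreement between two paired series
#'
#' Differences are oriented `a - b` (machine-learning method minus reference
#' method, in the cross-method use). Bias is the mean difference, `sd` the
#' sample standard deviation (n - 1), and the 95% limits of agreement are
#' `bias +/- 1.96 sd`.
#'
#' @param a,b numeric vectors of equal length (n >= 2), pairwise finite.
#' @return A [BlandAltmanResult-class]; its `points` slot holds the
#'   (average, difference) pairs for plotting.
#' @examples
#' blandAltman(c(1, 2, 3), c(3, 2, 1))
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch: ", length(a), " vs ",
                                   length(b))
  if (length(a) < 2L) stop("need at least 2 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("inputs must be pairwise finite")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  new("BlandAltmanResult", bias = bias, sd = s, loaLow = bias - 1.96 * s,
      loaHigh = bias + 1.96 * s, n = length(a),
      points = data.frame(average = (a + b) / 2, difference = d))
}

#' Spearman rank correlation
#'
#' Ranks use mid-ranks for ties; rho is the Pearson correlation of the
#' ranks. The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom
#' (standard practice at the sample sizes involved here); `rho = +/-1`
#' gives p = 0. For n <= 10 an exact permutation p-value is available.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite, each with
#'   positive variance.
#' @param exact if `TRUE` (only allowed for n <= 10), the p-value is
#'   computed by full enumeration of the n! rank permutations.
#' @return A [RankCorrelationResult-class].
#' @examples
#' spearmanRho(1:5, c(1, 3, 2, 5, 4))  # rho = 0.8
#' @export
spearmanRho <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1 - 1e-12) {
    0
  } else if (exact) {
    if (n > 10L) stop("exact permutation p only supported for n <= 10")
    perms <- .permutations(n)
    obs <- abs(rho)
    rhos <- apply(perms, 1L, function(pm) stats::cor(rx, ry[pm]))
    mean(abs(rhos) >= obs - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new("RankCorrelationResult", rho = rho, p = p, n = as.integer(n))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Pearson chi-squared test of association
#'
#' Expected counts are `row_total x col_total / grand_total`; the statistic
#' is `sum (O - E)^2 / E` on `(r - 1)(c - 1)` degrees of freedom with an
#' upper-tail p-value. No continuity correction is applied by default;
#' Yates' correction is available for 2 x 2 tables.
#'
#' @param observed matrix of non-negative integer counts with positive
#'   margins.
#' @param correct apply Yates' continuity correction (2 x 2 only).
#' @return A [ChiSquareResult-class].
#' @examples
#' pearsonChi2(rbind(c(20, 10), c(10, 20)))  # X2 = 20/3
#' @export
pearsonChi2 <- function(observed, correct = FALSE) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed must hold non-negative integer counts")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop("zero margin: every row and column must have a positive total")
  expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  dev <- abs(observed - expected)
  if (correct) {
    if (!all(dim(observed) == c(2L, 2L)))
      stop("Yates correction applies to 2 x 2 tables only")
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / expected)
  df <- as.integer((nrow(observed) - 1L) * (ncol(observed) - 1L))
  new("ChiSquareResult", statistic = stat, df = df,
      p = stats::pchisq(stat, df, lower.tail = FALSE),
      observed = observed, expected = expected)
}

#' Contingency tables of clot category versus HAS
#'
#' Tallies clots into a 3 x 2 table (rows RBC_RICH / MIXED / FIBRIN_RICH,
#' columns HAS+ / HAS-) and the collapsed 2 x 2 table (RBC_RICH vs other).
#'
#' @param categories character vector of clot categories.
#' @param flags logical vector of HAS positivity, same length.
#' @return list with `table3x2` and `table2x2`.
#' @export
compositionHasTable <- function(categories, flags) {
  if (length(categories) != length(flags)) stop("length mismatch")
  if (!all(categories %in% CATEGORY_LEVELS))
    stop("unknown category value(s): ",
         paste(setdiff(categories, CATEGORY_LEVELS), collapse = ", "))
  cat3 <- factor(categories, levels = CATEGORY_LEVELS)
  f <- factor(ifelse(flags, "HAS+", "HAS-"), levels = c("HAS+", "HAS-"))
  t3 <- matrix(as.integer(table(cat3, f)), 3L, 2L,
               dimnames = list(CATEGORY_LEVELS, c("HAS+", "HAS-")))
  t2 <- rbind(RBC_RICH = t3["RBC_RICH", ],
              OTHER = t3["MIXED", ] + t3["FIBRIN_RICH", ])
  list(table3x2 = t3, table2x2 = t2)
}

.needCols <- function(tab, cols, what) {
  miss <- setdiff(cols, names(tab))
  if (length(miss)) stop(what, " is missing column(s): ",
                         paste(miss, collapse = ", "))
}

#' Cross-method and clinical agreement report
#'
#' Joins two per-clot composition tables (e.g. the ML pipeline and the
#' color-threshold reference) and a clinical table on `clot_id`, then
#' computes (i) the pooled per-component Spearman correlation between the
#' methods (n = clots x 3 components), (ii) Bland-Altman agreement on the
#' pooled pairs (method A minus method B), (iii) per-method Spearman of
#' percent RBC versus mean Hounsfield Units, and (iv) per-method chi-squared
#' association of clot category with HAS, on the 3 x 2 and collapsed 2 x 2
#' tables (reported at their true degrees of freedom).
#'
#' @param methodA,methodB data.frames with columns `clot_id`, `pct_rbc`,
#'   `pct_wbc`, `pct_fibrin` (a `category` column is derived if absent).
#' @param clinical data.frame with columns `clot_id`, `mean_hu`.
#' @return An [AgreementReport-class].
#' @export
agreementReport <- function(methodA, methodB, clinical) {
  .needCols(methodA, c("clot_id", "pct_rbc", "pct_wbc", "pct_fibrin"),
            "methodA")
  .needCols(methodB, c("clot_id", "pct_rbc", "pct_wbc", "pct_fibrin"),
            "methodB")
  .needCols(clinical, c("clot_id", "mean_hu"), "clinical")
  ids <- intersect(intersect(methodA$clot_id, methodB$clot_id),
                   clinical$clot_id)
  if (length(ids) < 3L) stop("need at least 3 clots common to all inputs; ",
                             "found ", length(ids))
  ids <- sort(as.character(ids))
  a <- methodA[match(ids, methodA$clot_id), ]
  b <- methodB[match(ids, methodB$clot_id), ]
  cl <- clinical[match(ids, clinical$clot_id), ]

  comps <- c("pct_rbc", "pct_wbc", "pct_fibrin")
  pooledA <- as.vector(as.matrix(a[, comps]))
  pooledB <- as.vector(as.matrix(b[, comps]))
  pooledRho <- spearmanRho(pooledA, pooledB)
  pooledBA <- blandAltman(pooledA, pooledB)

  flags <- hasFlag(cl$mean_hu)
  catOf <- function(tab) {
    if (!is.null(tab$category) && !anyNA(tab$category)) return(tab$category)
    # derive from the >= 60% rule directly: imported tables need not sum
    # to exactly 100 (rounding in source spreadsheets)
    ifelse(tab$pct_rbc >= 60, "RBC_RICH",
           ifelse(tab$pct_fibrin >= 60, "FIBRIN_RICH", "MIXED"))
  }
  chiOrNull <- function(tab) tryCatch(pearsonChi2(tab),
                                      error = function(e) NULL)
  rep <- list(methodA = a, methodB = b)
  rbcHu <- list(); tables <- list(); chis <- list()
  for (m in names(rep)) {
    tab <- rep[[m]]
    rbcHu[[m]] <- spearmanRho(tab$pct_rbc, cl$mean_hu)
    ht <- compositionHasTable(catOf(tab), flags)
    tables[[m]] <- ht
    chis[paste0(m, "_3x2")] <- list(chiOrNull(ht$table3x2))
    chis[paste0(m, "_2x2")] <- list(chiOrNull(ht$table2x2))
  }
  new("AgreementReport", pooledSpearman = pooledRho,
      pooledBlandAltman = pooledBA, rbcHuSpearman = rbcHu,
      hasTables = tables, hasChi2 = chis, n = length(ids),
      clotIds = ids)
}

#' Serialize an agreement report to a plain list / JSON
#'
#' @param report an [AgreementReport-class].
#' @param path optional path; if given, the report is written as JSON.
#' @return The report as a nested list, invisibly if `path` is given.
#' @export
reportAsList <- function(report, path = NULL) {
  stopifnot(is(report, "AgreementReport"))
  rc <- function(r) list(rho = r@rho, p = r@p, n = r@n)
  chi <- function(x) if (is.null(x)) NULL else
    list(statistic = x@statistic, df = x@df, p = x@p)
  ba <- report@pooledBlandAltman
  out <- list(
    n_clots = report@n,
    clot_ids = report@clotIds,
    pooled_spearman = rc(report@pooledSpearman),
    pooled_bland_altman = list(bias = ba@bias, sd = ba@sd,
                               loa_low = ba@loaLow, loa_high = ba@loaHigh,
                               n = ba@n),
    rbc_vs_mean_hu = lapply(report@rbcHuSpearman, rc),
    has_tables = lapply(report@hasTables, function(t)
      lapply(t, function(m) as.data.frame(as.table(m)))),
    has_chi2 = lapply(report@hasChi2, chi))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(out))
  }
  out
}

## --- table import ---------------------------------------------------------

#' Read per-clot composition and clinical tables
#'
#' `readCompositionCsv` expects columns `clot_id`, `pct_rbc`, `pct_wbc`,
#' `pct_fibrin` (extra columns pass through); `readClinicalCsv` expects
#' `clot_id`, `mean_hu` (optional `max_hu`) and adds the derived
#' `has_positive` flag.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readCompositionCsv <- function(path) {
  tab <- utils::read.csv(path)
  .needCols(tab, c("clot_id", "pct_rbc", "pct_wbc", "pct_fibrin"), path)
  tab
}

#' @rdname readCompositionCsv
#' @export
readClinicalCsv <- function(path) {
  tab <- utils::read.csv(path)
  .needCols(tab, c("clot_id", "mean_hu"), path)
  tab$has_positive <- hasFlag(tab$mean_hu)
  tab
}

#' Import a per-clot table from a spreadsheet with a column mapping
#'
#' Supports importing supplementary per-clot quantification spreadsheets
#' whose exact layout is not fixed: `mapping` names the source columns for
#' the canonical fields. XLSX input requires the readxl package; CSV works
#' without it.
#'
#' @param path `.xlsx` or `.csv` file.
#' @param mapping named character vector mapping canonical names (e.g.
#'   `clot_id`, `pct_rbc`, `pct_wbc`, `pct_fibrin`, `mean_hu`) to the
#'   spreadsheet's column names.
#' @param sheet sheet index or name for XLSX input.
#' @return data.frame with the canonical columns.
#' @export
importClotTable <- function(path, mapping, sheet = 1L) {
  stopifnot(length(names(mapping)) == length(mapping))
  ext <- tolower(sub(".*\\.", "", path))
  tab <- if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
  miss <- setdiff(unname(mapping), names(tab))
  if (length(miss)) stop("mapped column(s) not found in ", path, ": ",
                         paste(miss, collapse = ", "))
  out <- tab[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  out
}
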