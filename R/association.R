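#' Average ranks with ties
#'
#' Ranks a numeric vector ascending, assigning tied values the mean of the
#' ranks they span (the "average rank" convention of common spreadsheet
#' rank functions). Missing values are excluded from ranking and returned
#' as \code{NA} in place.
#'
#' @param values Numeric vector, may contain \code{NA}.
#' @return Numeric vector of ranks, \code{NA} where the input was missing.
#' @export
rank_average <- function(values) {
  if (all(is.na(values))) stop("all values are missing; nothing to rank")
  rank(values, na.last = "keep", ties.method = "average")
}

#' Correlation between phenotype ranks and raw marker scores
#'
#' The rank-based association statistic: the product-moment correlation of
#' the phenotype's average ranks against the raw 0/1/2 marker scores. Note
#' the scores deliberately enter unranked; set \code{both_ranked = TRUE}
#' for a classical Spearman coefficient (both vectors ranked) instead.
#' Pairwise-complete: pairs with a missing rank or score are dropped.
#'
#' @param ranks Numeric vector of phenotype ranks (see
#'   \code{\link{rank_average}}).
#' @param scores Integer vector of 0/1/2 marker scores, same length.
#' @param both_ranked Rank the scores too before correlating.
#' @return List with \code{rho} (\code{NA} when undefined, e.g. zero
#'   variance), \code{n_used} and \code{degenerate} flag.
#' @export
marker_trait_correlation <- function(ranks, scores, both_ranked = FALSE) {
  if (length(ranks) != length(scores)) stop("length mismatch")
  ok <- !is.na(ranks) & !is.na(scores)
  n <- sum(ok)
  if (n < 3L) {
    return(list(rho = NA_real_, n_used = n, degenerate = TRUE))
  }
  x <- ranks[ok]
  y <- as.numeric(scores[ok])
  if (both_ranked) y <- rank(y, ties.method = "average")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, n_used = n, degenerate = TRUE))
  }
  list(rho = stats::cor(x, y), n_used = n, degenerate = FALSE)
}

#' Two-tailed p-value for a correlation coefficient
#'
#' Student's t-test for a product-moment correlation:
#' \code{t = rho * sqrt((n-2) / (1-rho^2))} on \code{n-2} degrees of
#' freedom, two-tailed.
#'
#' @param rho Correlation in [-1, 1].
#' @param n Number of paired observations (>= 3).
#' @return List with \code{p} and \code{saturated} flag (\code{TRUE} when
#'   \code{|rho| = 1}, where p is reported as the smallest representable
#'   positive value).
#' @export
corr_pvalue <- function(rho, n) {
  if (is.na(rho)) return(list(p = NA_real_, saturated = FALSE))
  if (n < 3L) stop("n must be >= 3")
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  if (abs(rho) == 1) {
    return(list(p = .Machine$double.xmin, saturated = TRUE))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(p = 2 * stats::pt(-abs(tstat), df = n - 2), saturated = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies each raw p-value by the family size and caps at 1.
#'
#' @param p_raw Raw p-value(s).
#' @param m Family size (number of tested markers), >= 1.
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p_raw, m) {
  if (any(m < 1L)) stop("family size must be >= 1")
  pmin(1, m * p_raw)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and standard deviation. Because the parameters are estimated
#' from the same data, the asymptotic p-value is approximate and
#' conservative (biased towards retaining normality); it is used here only
#' as a screen before switching to rank-based statistics.
#'
#' @param values Numeric vector, n >= 5 after removing missing values.
#' @param alpha Significance level for the normality flag (default 0.05).
#' @return List of class \code{ft_ks} with \code{D}, \code{p},
#'   \code{normal} (logical), \code{n}.
#' @export
ks_normality <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  if (length(x) < 5L) stop("need at least 5 non-missing values")
  if (stats::sd(x) == 0) stop("zero variance: KS test undefined")
  ks <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
  structure(list(D = unname(ks$statistic), p = ks$p.value,
                 normal = ks$p.value > alpha, n = length(x)),
            class = "ft_ks")
}

#' Aggregate replicate phenotype observations into trait panels
#'
#' Collapses per-replicate observations to per-line means for each trait
#' and year, retaining the replicate count.
#'
#' @param pheno Data frame with columns \code{line_id}, \code{trait},
#'   \code{year}, \code{days} (one row per replicate).
#' @return Data frame with \code{line_id}, \code{trait}, \code{year},
#'   \code{days} (mean) and \code{n_rep}.
#' @export
trait_panel <- function(pheno) {
  need <- c("line_id", "trait", "year", "days")
  if (!all(need %in% names(pheno))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  agg <- stats::aggregate(days ~ line_id + trait + year, data = pheno,
                          FUN = mean, na.action = stats::na.omit)
  cnt <- stats::aggregate(days ~ line_id + trait + year, data = pheno,
                          FUN = length, na.action = stats::na.omit)
  names(cnt)[names(cnt) == "days"] <- "n_rep"
  merge(agg, cnt, by = c("line_id", "trait", "year"), sort = TRUE)
}

#' Marker-trait association scan
#'
#' For every marker x trait x year combination, correlates the per-line
#' phenotype ranks against the raw marker scores, derives a two-tailed
#' t-test p-value and applies Bonferroni correction over the marker family.
#'
#' @param geno Matrix of 0/1/2/NA scores with line ids as row names and
#'   marker ids as column names.
#' @param panel Trait panel from \code{\link{trait_panel}} (per-line means).
#' @param family \code{"all"}: one family of all markers in the run
#'   (default); \code{"per_gene"}: separate families per gene, requires
#'   \code{gene_map}.
#' @param gene_map Named character vector mapping marker id to gene id.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param both_ranked Passed to \code{\link{marker_trait_correlation}}.
#' @return Data frame with one row per marker x trait x year: \code{rho},
#'   \code{n_used}, \code{p_raw}, \code{m} (family size), \code{p_adj},
#'   \code{significant}.
#' @export
association_scan <- function(geno, panel, family = c("all", "per_gene"),
                             gene_map = NULL, alpha = 0.05,
                             both_ranked = FALSE) {
  family <- match.arg(family)
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop("genotype matrix needs line ids as rownames and marker ids as colnames")
  }
  if (family == "per_gene") {
    if (is.null(gene_map) || !all(colnames(geno) %in% names(gene_map))) {
      stop("per-gene families require a gene_map covering every marker")
    }
    fam_sizes <- table(gene_map[colnames(geno)])
    m_of <- function(mk) as.integer(fam_sizes[[gene_map[[mk]]]])
  } else {
    m_all <- ncol(geno)
    m_of <- function(mk) m_all
  }

  combos <- unique(panel[, c("trait", "year")])
  rows <- vector("list", nrow(combos) * ncol(geno))
  k <- 0L
  any_overlap <- FALSE
  for (i in seq_len(nrow(combos))) {
    sub <- panel[panel$trait == combos$trait[i] & panel$year == combos$year[i], ]
    shared <- intersect(sub$line_id, rownames(geno))
    if (length(shared) > 0L) any_overlap <- TRUE
    vals <- sub$days[match(shared, sub$line_id)]
    rks <- if (length(shared) > 0L) rank_average(vals) else numeric(0)
    for (mk in colnames(geno)) {
      ct <- marker_trait_correlation(rks, geno[shared, mk],
                                     both_ranked = both_ranked)
      pv <- corr_pvalue(ct$rho, max(ct$n_used, 3L))
      m <- m_of(mk)
      p_adj <- if (is.na(pv$p)) NA_real_ else bonferroni(pv$p, m)
      k <- k + 1L
      rows[[k]] <- data.frame(
        marker_id = mk, trait = combos$trait[i], year = combos$year[i],
        rho = ct$rho, n_used = ct$n_used, p_raw = pv$p, m = m,
        p_adj = p_adj,
        significant = !is.na(p_adj) && p_adj <= alpha,
        stringsAsFactors = FALSE)
    }
  }
  if (!any_overlap) stop("no overlapping lines between genotypes and phenotypes")
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Between-year trait repeatability
#'
#' Rank-based (Spearman) correlation of per-line trait means between two
#' years, per trait.
#'
#' @param panel Trait panel covering both years (see
#'   \code{\link{trait_panel}}).
#' @param years Length-2 vector of the two year labels; defaults to the two
#'   years present.
#' @return Data frame with \code{trait}, \code{rho}, \code{n}.
#' @export
between_year_correlation <- function(panel, years = NULL) {
  if (is.null(years)) years <- sort(unique(panel$year))
  if (length(years) != 2L) stop("exactly two years required")
  traits <- sort(unique(panel$trait))
  rows <- lapply(traits, function(tr) {
    a <- panel[panel$trait == tr & panel$year == years[1L], ]
    b <- panel[panel$trait == tr & panel$year == years[2L], ]
    shared <- intersect(a$line_id, b$line_id)
    if (length(shared) < 3L) stop("fewer than 3 shared lines for trait ", tr)
    data.frame(
      trait = tr,
      rho = stats::cor(a$days[match(shared, a$line_id)],
                       b$days[match(shared, b$line_id)],
                       method = "spearman"),
      n = length(shared), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Allele-by-phenotype table
#'
#' Plain table of lines sorted by a chosen trait, with their marker scores
#' alongside the phenotype values — the tabular analogue of an allelic
#' composition heatmap.
#'
#' @param geno Genotype matrix (lines x markers).
#' @param panel Trait panel.
#' @param trait,year Trait and year used for sorting.
#' @param markers Marker ids to include; defaults to all columns.
#' @return Data frame sorted by ascending phenotype value.
#' @export
allele_phenotype_table <- function(geno, panel, trait, year,
                                   markers = colnames(geno)) {
  sub <- panel[panel$trait == trait & panel$year == year, ]
  shared <- intersect(sub$line_id, rownames(geno))
  vals <- sub$days[match(shared, sub$line_id)]
  ord <- order(vals)
  out <- data.frame(line_id = shared[ord], days = vals[ord],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(geno[shared[ord], markers, drop = FALSE]))
}
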