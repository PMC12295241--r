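#' Define a PCR marker assay
#'
#' A marker is a primer pair whose outer product endpoints are given on the
#' TSS-relative axis of its gene, together with the observable product
#' pattern expected for the reference allele (score 0) and the alternative
#' allele (score 2). Patterns are encoded as strings: band lengths in bp
#' separated by \code{"/"} (co-amplified products), or the keyword
#' \code{"no_product"} for a presence/absence variant allele.
#'
#' @param marker_id,gene_id Identifiers.
#' @param fwd_end_tss_rel,rev_end_tss_rel Signed TSS-relative positions of
#'   the two outer product endpoints (bp); order free.
#' @param primer_len_f,primer_len_r Primer lengths (bp), i.e. how far each
#'   primer binding window extends inward from its product endpoint.
#'   Defaults to 20 bp when true primer sequences are not supplied.
#' @param allele0,allele2 Pattern strings for scores 0 and 2. Alternative
#'   observable classes for one allele (multi-allelic loci folded into a
#'   binary one-vs-rest encoding) are separated by \code{"|"}, e.g.
#'   \code{"2504|378|no_product"}.
#' @param notes Free text.
#' @return A list of class \code{ft_marker}; \code{allele0}/\code{allele2}
#'   are lists of \code{ft_pattern} alternatives (\code{NULL} when
#'   undeclared).
#' @export
marker_def <- function(marker_id, gene_id, fwd_end_tss_rel, rev_end_tss_rel,
                       primer_len_f = 20L, primer_len_r = 20L,
                       allele0 = NA_character_, allele2 = NA_character_,
                       notes = "") {
  if (fwd_end_tss_rel == rev_end_tss_rel) {
    stop("marker endpoints must differ")
  }
  if (primer_len_f < 1L || primer_len_r < 1L) {
    stop("primer lengths must be >= 1 bp")
  }
  structure(
    list(marker_id = marker_id, gene_id = gene_id,
         fwd_end_tss_rel = as.integer(fwd_end_tss_rel),
         rev_end_tss_rel = as.integer(rev_end_tss_rel),
         primer_len_f = as.integer(primer_len_f),
         primer_len_r = as.integer(primer_len_r),
         allele0 = parse_allele(allele0), allele2 = parse_allele(allele2),
         notes = notes),
    class = "ft_marker"
  )
}

#' Product pattern constructor
#'
#' @param bands Numeric vector of product lengths (bp); ignored when
#'   \code{no_product} is \code{TRUE}.
#' @param no_product Presence/absence flag: \code{TRUE} means the assay
#'   yields no amplification product for this allele.
#' @return A list of class \code{ft_pattern}.
#' @export
product_pattern <- function(bands = numeric(0), no_product = FALSE) {
  if (no_product && length(bands) > 0L) {
    stop("no_product patterns cannot carry bands")
  }
  structure(list(bands = sort(as.numeric(bands)), no_product = no_product),
            class = "ft_pattern")
}

# "826" / "2504/378" / "no_product" -> ft_pattern
parse_pattern <- function(x) {
  if (identical(tolower(x), "no_product")) return(product_pattern(no_product = TRUE))
  bands <- as.numeric(strsplit(x, "/", fixed = TRUE)[[1L]])
  if (anyNA(bands)) stop("unparseable product pattern: ", x)
  product_pattern(bands)
}

# "2504|378|no_product" -> list of ft_pattern alternatives, or NULL
parse_allele <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return(NULL)
  lapply(strsplit(x, "|", fixed = TRUE)[[1L]], parse_pattern)
}

format_pattern <- function(p) {
  if (is.null(p)) return(NA_character_)
  if (p$no_product) return("no_product")
  paste(p$bands, collapse = "/")
}

#' Read a marker definition table
#'
#' Expected TSV columns: \code{marker_id}, \code{gene_id},
#' \code{fwd_end_tss_rel}, \code{rev_end_tss_rel}, optional
#' \code{primer_len_f}, \code{primer_len_r}, \code{allele0}, \code{allele2},
#' \code{notes}.
#'
#' @param path TSV path.
#' @return Named list of \code{ft_marker} objects.
#' @export
read_markers <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "gene_id", "fwd_end_tss_rel", "rev_end_tss_rel")
  if (!all(need %in% names(tab))) {
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  }
  get <- function(col, i, default) {
    if (col %in% names(tab)) tab[[col]][i] else default
  }
  markers <- lapply(seq_len(nrow(tab)), function(i) {
    marker_def(tab$marker_id[i], tab$gene_id[i],
               tab$fwd_end_tss_rel[i], tab$rev_end_tss_rel[i],
               primer_len_f = get("primer_len_f", i, 20L),
               primer_len_r = get("primer_len_r", i, 20L),
               allele0 = as.character(get("allele0", i, NA_character_)),
               allele2 = as.character(get("allele2", i, NA_character_)),
               notes = as.character(get("notes", i, "")))
  })
  names(markers) <- tab$marker_id
  markers
}

#' Predict the PCR product pattern of a marker on one haplotype
#'
#' Virtual PCR over the variant set carried by a single haplotype, in the
#' marker's TSS-relative frame. The product length is the inclusive
#' reference span between the two endpoints, plus the lengths of insertions
#' anchored inside the span, minus the lengths of deletions inside the span.
#' If any deletion removes at least 1 bp of either primer binding window
#' (the \code{primer_len} bp inward from each endpoint), the primer cannot
#' bind and the assay yields no product (a presence/absence variant).
#'
#' @param marker An \code{ft_marker}.
#' @param haplotype_variants Data frame of the haplotype's variants with
#'   columns \code{kind} ("deletion"/"insertion"), \code{tss_rel_start},
#'   \code{tss_rel_end}, \code{length}. May have zero rows.
#' @return An \code{ft_pattern}: one band, or \code{no_product}.
#' @export
predict_products <- function(marker, haplotype_variants) {
  stopifnot(inherits(marker, "ft_marker"))
  hv <- haplotype_variants
  need <- c("kind", "tss_rel_start", "tss_rel_end", "length")
  if (!all(need %in% names(hv))) {
    stop("haplotype variants must be in the TSS-relative frame with columns: ",
         paste(need, collapse = ", "))
  }
  lo <- min(marker$fwd_end_tss_rel, marker$rev_end_tss_rel)
  hi <- max(marker$fwd_end_tss_rel, marker$rev_end_tss_rel)
  p_lo <- c(lo, lo + marker$primer_len_f - 1L)   # left primer window
  p_hi <- c(hi - marker$primer_len_r + 1L, hi)   # right primer window
  len <- span_length(lo, hi)

  if (nrow(hv) > 0L) {
    for (i in seq_len(nrow(hv))) {
      vs <- hv$tss_rel_start[i]; ve <- hv$tss_rel_end[i]
      if (hv$kind[i] == "deletion") {
        if (ve < lo || vs > hi) next
        if (vs <= p_lo[2L] && ve >= p_lo[1L]) return(product_pattern(no_product = TRUE))
        if (vs <= p_hi[2L] && ve >= p_hi[1L]) return(product_pattern(no_product = TRUE))
        len <- len - hv$length[i]
      } else {
        # insertion: anchored at a point; amplified when inside the span
        if (vs >= lo && vs < hi) len <- len + hv$length[i]
      }
    }
  }
  product_pattern(bands = len)
}

#' Group product lengths into gel-resolvable classes
#'
#' Two bands are unresolvable on a gel when their relative length
#' difference \code{|a-b| / max(a,b)} is below \code{resolvability};
#' unresolvable pairs are merged transitively (single linkage), so a chain
#' of close lengths forms one observable class. Absence of a product is
#' always its own class.
#'
#' @param lengths Numeric vector of band lengths (bp).
#' @param resolvability Relative resolution limit in (0,1). The default
#'   0.02 models standard agarose; use \code{0.005} as a high-resolution
#'   agarose preset for small products.
#' @return Integer vector of class ids (1-based, in order of increasing
#'   class minimum length), parallel to \code{lengths}.
#' @export
gel_resolve <- function(lengths, resolvability = 0.02) {
  if (resolvability <= 0 || resolvability >= 1) {
    stop("resolvability must be in (0, 1)")
  }
  n <- length(lengths)
  if (n == 0L) return(integer(0))
  ord <- order(lengths)
  sorted <- lengths[ord]
  cls_sorted <- integer(n)
  cls_sorted[1L] <- 1L
  for (i in seq_len(n - 1L)) {
    gap_rel <- (sorted[i + 1L] - sorted[i]) / max(sorted[i + 1L], sorted[i])
    cls_sorted[i + 1L] <- cls_sorted[i] + as.integer(gap_rel >= resolvability)
  }
  cls <- integer(n)
  cls[ord] <- cls_sorted
  cls
}

# Do two patterns look the same on a gel at the given resolvability?
patterns_match <- function(observed, expected, resolvability = 0.02) {
  if (is.null(expected)) return(FALSE)
  if (observed$no_product || expected$no_product) {
    return(observed$no_product && expected$no_product)
  }
  a <- observed$bands; b <- expected$bands
  cls <- gel_resolve(c(a, b), resolvability)
  obs_cls <- sort(unique(cls[seq_along(a)]))
  exp_cls <- sort(unique(cls[length(a) + seq_along(b)]))
  identical(obs_cls, exp_cls)
}

#' Score a diploid genotype from an observed product pattern
#'
#' Matches the observed gel pattern against the marker's declared allele
#' classes: score 0 when it matches any reference-allele alternative, 2 for
#' any alternative-allele class, 1 (heterozygote) when the observation
#' equals the band union of one class from each allele and differs from
#' each alone, \code{NA} otherwise (unexpected band). A presence/absence
#' heterozygote is indistinguishable from the amplifying homozygote on a
#' gel and therefore never yields score 1.
#'
#' @param observed An \code{ft_pattern}.
#' @param marker An \code{ft_marker} with both allele patterns declared.
#' @param resolvability Gel resolution limit passed to band matching.
#' @return Integer score 0, 1, 2 or \code{NA}.
#' @export
score_genotype <- function(observed, marker, resolvability = 0.02) {
  stopifnot(inherits(observed, "ft_pattern"), inherits(marker, "ft_marker"))
  a0 <- marker$allele0; a2 <- marker$allele2
  if (is.null(a0) || is.null(a2)) {
    stop("marker ", marker$marker_id, " lacks declared allele patterns")
  }
  match_any <- function(alts) {
    any(vapply(alts, patterns_match, logical(1), observed = observed,
               resolvability = resolvability))
  }
  if (match_any(a0)) return(0L)
  if (match_any(a2)) return(2L)
  for (p0 in a0) {
    for (p2 in a2) {
      if (p0$no_product || p2$no_product) next
      het <- product_pattern(bands = unique(c(p0$bands, p2$bands)))
      if (patterns_match(observed, het, resolvability)) return(1L)
    }
  }
  NA_integer_
}

#' Minor allele frequency of one marker
#'
#' Allele-count MAF: \code{(2 n_minor_hom + n_het) / (2 n_called) * 100},
#' with the minor allele chosen so the result is at most 50. A
#' genotype-count mode (fraction of lines carrying the minor allele) is
#' available for comparison.
#'
#' @param scores Integer vector of 0/1/2 scores; \code{NA} = no call.
#' @param mode \code{"allele"} (default) or \code{"genotype"}.
#' @return MAF as a percentage in [0, 50], or \code{NA} if nothing is
#'   called.
#' @export
maf <- function(scores, mode = c("allele", "genotype")) {
  mode <- match.arg(mode)
  s <- scores[!is.na(scores)]
  if (length(s) == 0L) return(NA_real_)
  if (!all(s %in% c(0L, 1L, 2L))) stop("scores must be 0, 1, 2 or NA")
  if (mode == "allele") {
    f2 <- (2 * sum(s == 2L) + sum(s == 1L)) / (2 * length(s))
  } else {
    f2 <- sum(s >= 1L) / length(s)
  }
  min(f2, 1 - f2) * 100
}

#' Summarise a genotype matrix per marker
#'
#' @param geno Matrix or data frame of 0/1/2/NA scores, lines x markers.
#' @param mode MAF mode, see \code{\link{maf}}.
#' @return Data frame with \code{marker_id}, \code{maf_percent},
#'   \code{n_called}, \code{is_monomorphic}.
#' @export
marker_summary <- function(geno, mode = "allele") {
  geno <- as.matrix(geno)
  data.frame(
    marker_id = colnames(geno),
    maf_percent = apply(geno, 2L, maf, mode = mode),
    n_called = apply(geno, 2L, function(x) sum(!is.na(x))),
    is_monomorphic = apply(geno, 2L, function(x) {
      s <- x[!is.na(x)]
      length(unique(s)) <= 1L
    }),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen markers by minor allele frequency
#'
#' Retains markers whose MAF is at least \code{maf_min} percent (boundary
#' inclusive: markers below the threshold are discarded) and which are not
#' monomorphic.
#'
#' @param summaries Data frame from \code{\link{marker_summary}}.
#' @param maf_min MAF threshold in percent (default 1.5).
#' @return The retained subset of \code{summaries}.
#' @export
filter_markers <- function(summaries, maf_min = 1.5) {
  keep <- !summaries$is_monomorphic &
    !is.na(summaries$maf_percent) & summaries$maf_percent >= maf_min
  summaries[keep, , drop = FALSE]
}

#' Discriminatory accuracy of a marker towards a target line set
#'
#' Measures how selectively a marker's alternative allele tags a set of
#' target lines: a mismatch is a non-target line carrying the allele
#' (score 1 or 2) or a target line lacking it (score 0). Accuracy is
#' \code{(N - mismatches) / N * 100}, rounded to one decimal, with N the
#' panel size.
#'
#' @param scores Named integer vector of 0/1/2/NA scores (names = line ids),
#'   or unnamed with \code{line_ids} supplied.
#' @param target_lines Character vector of target line ids.
#' @param line_ids Optional line ids parallel to \code{scores}.
#' @return Accuracy percentage, one decimal.
#' @export
discriminatory_accuracy <- function(scores, target_lines, line_ids = NULL) {
  if (is.null(line_ids)) line_ids <- names(scores)
  if (is.null(line_ids)) stop("line ids required")
  if (length(line_ids) == 0L) stop("empty panel")
  if (!all(target_lines %in% line_ids)) {
    stop("target lines must be a subset of the panel")
  }
  is_target <- line_ids %in% target_lines
  mismatch <- (!is_target & !is.na(scores) & scores >= 1L) |
    (is_target & !is.na(scores) & scores == 0L)
  round((length(scores) - sum(mismatch)) / length(scores) * 100, 1)
}
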