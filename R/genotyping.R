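#' Derive one flanking marker per indel variant
#'
#' Convenience used on simulated catalogues: for every indel in the
#' variant set, defines a primer pair whose product endpoints flank the
#' variant by \code{flank} bp on the TSS-relative axis, with the reference
#' band as allele 0 and the variant-carrying band (or no product, when the
#' variant removes a primer site) as allele 2.
#'
#' @param variants An \code{ft_variants} object annotated with TSS-relative
#'   coordinates (call \code{\link{call_variants}} with an anchor).
#' @param gene_id Gene id recorded on the markers.
#' @param flank Flanking distance from variant to product endpoint (bp).
#' @param primer_len Primer window length (bp).
#' @return Named list of \code{ft_marker} objects, one per indel.
#' @export
markers_from_variants <- function(variants, gene_id = "gene", flank = 400L,
                                  primer_len = 20L) {
  ind <- variants$indels
  if (!"tss_rel_start" %in% names(ind)) {
    stop("variants must carry TSS-relative coordinates")
  }
  markers <- list()
  for (i in seq_len(nrow(ind))) {
    lo <- ind$tss_rel_start[i] - flank
    hi <- ind$tss_rel_end[i] + flank
    mk <- marker_def(paste0("MK_", ind$variant_id[i]), gene_id,
                     fwd_end_tss_rel = lo, rev_end_tss_rel = hi,
                     primer_len_f = primer_len, primer_len_r = primer_len)
    ref_pat <- predict_products(mk, ind[0, , drop = FALSE])
    alt_pat <- predict_products(mk, ind[i, , drop = FALSE])
    mk$allele0 <- list(ref_pat)
    mk$allele2 <- list(alt_pat)
    markers[[mk$marker_id]] <- mk
  }
  markers
}

#' Predict product patterns for every haplotype in a variant catalogue
#'
#' @param markers List of \code{ft_marker} objects.
#' @param variants An \code{ft_variants} object with TSS-relative
#'   coordinates.
#' @param haplotypes Haplotype (sequence) ids; defaults to all carriers
#'   present in the catalogue plus the reference.
#' @return Named list haplotype -> named list marker -> \code{ft_pattern}.
#' @export
predict_haplotype_patterns <- function(markers, variants,
                                       haplotypes = NULL) {
  ind <- variants$indels
  if (is.null(haplotypes)) {
    carriers <- unique(unlist(strsplit(ind$carriers, ",", fixed = TRUE)))
    haplotypes <- c(variants$ref_id, carriers)
  }
  out <- lapply(haplotypes, function(h) {
    mine <- ind[vapply(strsplit(ind$carriers, ",", fixed = TRUE),
                       function(cc) h %in% cc, logical(1)), , drop = FALSE]
    lapply(markers, predict_products, haplotype_variants = mine)
  })
  stats::setNames(out, haplotypes)
}

#' Score homozygous genotypes for every haplotype x marker
#'
#' Runs the virtual PCR and gel scoring end to end: each haplotype is
#' treated as a homozygote, its predicted pattern scored against the
#' marker's declared alleles.
#'
#' @inheritParams predict_haplotype_patterns
#' @param resolvability Gel resolution limit.
#' @return Integer matrix (haplotypes x markers) of 0/1/2/NA scores.
#' @export
score_panel <- function(markers, variants, haplotypes = NULL,
                        resolvability = 0.02) {
  pats <- predict_haplotype_patterns(markers, variants, haplotypes)
  out <- matrix(NA_integer_, nrow = length(pats), ncol = length(markers),
                dimnames = list(names(pats),
                                vapply(markers, `[[`, "", "marker_id")))
  for (h in names(pats)) {
    for (j in seq_along(markers)) {
      out[h, j] <- score_genotype(pats[[h]][[j]], markers[[j]],
                                  resolvability = resolvability)
    }
  }
  out
}
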