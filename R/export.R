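#' Export a variant catalogue to VCF, BED and TSV
#'
#' Writes the indel and SNP calls with explicit REF/ALT alleles. VCF 4.2
#' records use the left-anchored-base convention (a deletion of reference
#' positions s..e is reported at POS = s-1 with the preceding base; a
#' deletion starting at position 1 is right-anchored on the following base).
#' BED intervals are converted from the package's 1-based inclusive
#' coordinates to BED's 0-based half-open convention by
#' \code{rtracklayer::export}. The TSV mirrors the internal catalogue
#' (kind, reference interval, length, TSS-relative interval, carriers).
#'
#' @param variants An \code{ft_variants} object from \code{\link{call_variants}}.
#' @param aln The source \code{ft_alignment} (provides REF/ALT spelling).
#' @param anchor An \code{ft_anchor} providing the chromosome name and the
#'   TSS frame.
#' @param out_prefix Output path prefix; writes \code{<prefix>.vcf},
#'   \code{<prefix>.bed} and \code{<prefix>.tsv}.
#' @param ref_offset Genomic coordinate of ungapped reference position 1.
#' @return Named character vector of the three written paths, invisibly.
#' @export
export_variants <- function(variants, aln, anchor, out_prefix,
                            ref_offset = 1L) {
  stopifnot(inherits(variants, "ft_variants"), inherits(aln, "ft_alignment"),
            inherits(anchor, "ft_anchor"))
  ref_seq <- gsub("-", "", aln$seqs[[aln$ref_id]], fixed = TRUE)
  sub_ref <- function(s, e) substr(ref_seq, s, e)
  m <- NULL  # alignment matrix, built lazily for insertion ALT spelling

  ind <- variants$indels
  snp <- variants$snps
  chrom <- anchor$chromosome
  genomic <- function(p) ref_offset + p - 1L

  vcf_rows <- character(0)
  add_row <- function(pos, id, ref, alt) {
    vcf_rows[[length(vcf_rows) + 1L]] <<- paste(
      chrom, genomic(pos), id, ref, alt, ".", "PASS", ".", sep = "\t")
  }

  if (nrow(ind) > 0L) {
    for (i in seq_len(nrow(ind))) {
      if (ind$kind[i] == "deletion") {
        s <- ind$ref_start[i]; e <- ind$ref_end[i]
        if (s > 1L) {
          add_row(s - 1L, ind$variant_id[i],
                  sub_ref(s - 1L, e), sub_ref(s - 1L, s - 1L))
        } else {
          add_row(1L, ind$variant_id[i],
                  sub_ref(1L, e + 1L), sub_ref(e + 1L, e + 1L))
        }
      } else {
        if (is.null(m)) m <- aln_matrix(aln)
        carrier <- strsplit(ind$carriers[i], ",", fixed = TRUE)[[1L]][1L]
        inserted <- paste(m[carrier, ind$aln_start[i]:ind$aln_end[i]],
                          collapse = "")
        a <- ind$ref_start[i]  # anchor position, 0 = before reference start
        if (a >= 1L) {
          add_row(a, ind$variant_id[i], sub_ref(a, a),
                  paste0(sub_ref(a, a), inserted))
        } else {
          add_row(1L, ind$variant_id[i], sub_ref(1L, 1L),
                  paste0(inserted, sub_ref(1L, 1L)))
        }
      }
    }
  }
  if (nrow(snp) > 0L) {
    for (i in seq_len(nrow(snp))) {
      add_row(snp$ref_pos[i],
              sprintf("SNP_%d_%s", snp$ref_pos[i], snp$alt_base[i]),
              snp$ref_base[i], snp$alt_base[i])
    }
  }

  vcf_path <- paste0(out_prefix, ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ftindelscan",
    sprintf("##contig=<ID=%s>", chrom),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  writeLines(c(header, unlist(vcf_rows)), vcf_path)

  bed_path <- paste0(out_prefix, ".bed")
  if (nrow(ind) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = genomic(pmax(ind$ref_start, 1L)),
                                end = genomic(ind$ref_end)),
      strand = "*")
    gr$name <- ind$variant_id
    gr$score <- 0L
    rtracklayer::export(gr, bed_path, format = "BED")
  } else {
    writeLines(character(0), bed_path)
  }

  tsv_path <- paste0(out_prefix, ".tsv")
  utils::write.table(ind, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf_path, bed = bed_path, tsv = tsv_path))
}

#' Read an indel catalogue TSV written by \code{\link{export_variants}}
#'
#' @param path TSV path.
#' @return Data frame of indel variants.
#' @export
read_variants_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
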