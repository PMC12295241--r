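#' Transcription-factor motif model
#'
#' Either an IUPAC consensus string (e.g. the AGL15 CArG-type motif
#' \code{CARGNCAT}) or a position-frequency matrix with per-position base
#' frequencies.
#'
#' @param tf_id Locus identifier (e.g. \code{AT5G13790}).
#' @param name Factor name (e.g. \code{AGL15}).
#' @param consensus IUPAC consensus string; mutually exclusive with
#'   \code{matrix}.
#' @param matrix Numeric matrix with rows \code{A,C,G,T} and one column per
#'   motif position; columns must each sum to 1 (tolerance 1e-6).
#' @param threshold Similarity threshold in (0, 1], default 0.85. Consensus
#'   models only ever produce similarity 1, so the threshold matters for
#'   matrix models.
#' @return A list of class \code{ft_motif}.
#' @export
motif_model <- function(tf_id, name = tf_id, consensus = NULL, matrix = NULL,
                        threshold = 0.85) {
  if (is.null(consensus) == is.null(matrix)) {
    stop("provide exactly one of consensus or matrix")
  }
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1L]]
    if (grepl(paste0("[^", paste(iupac, collapse = ""), "]"), consensus)) {
      stop("invalid IUPAC letter in consensus: ", consensus)
    }
    kind <- "consensus"
    width <- nchar(consensus)
  } else {
    matrix <- as.matrix(matrix)
    if (!identical(rownames(matrix), c("A", "C", "G", "T"))) {
      stop("matrix rows must be A, C, G, T in order")
    }
    sums <- colSums(matrix)
    if (any(abs(sums - 1) > 1e-6)) {
      stop("matrix columns must each sum to 1")
    }
    kind <- "matrix"
    width <- ncol(matrix)
  }
  structure(list(tf_id = tf_id, name = name, kind = kind,
                 consensus = consensus, matrix = matrix,
                 threshold = threshold, width = width),
            class = "ft_motif")
}

#' Read a motif table
#'
#' TSV columns: \code{tf_id}, \code{name}, \code{kind}
#' (\code{consensus}/\code{matrix}), \code{model}, \code{threshold}. For
#' consensus motifs \code{model} is the IUPAC string; for matrix motifs it
#' serialises one position per \code{;}-separated block as
#' \code{A:0.1,C:0.2,G:0.3,T:0.4}.
#'
#' @param path TSV path.
#' @return Named list of \code{ft_motif} objects keyed by tf_id.
#' @export
read_motifs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf_id", "name", "kind", "model", "threshold")
  if (!all(need %in% names(tab))) {
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  }
  models <- lapply(seq_len(nrow(tab)), function(i) {
    if (tab$kind[i] == "consensus") {
      motif_model(tab$tf_id[i], tab$name[i], consensus = tab$model[i],
                  threshold = tab$threshold[i])
    } else {
      cols <- strsplit(tab$model[i], ";", fixed = TRUE)[[1L]]
      m <- vapply(cols, function(cc) {
        kv <- strsplit(strsplit(cc, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
        v <- as.numeric(vapply(kv, `[`, "", 2L))
        names(v) <- vapply(kv, `[`, "", 1L)
        v[c("A", "C", "G", "T")]
      }, numeric(4))
      rownames(m) <- c("A", "C", "G", "T")
      colnames(m) <- NULL
      motif_model(tab$tf_id[i], tab$name[i], matrix = m,
                  threshold = tab$threshold[i])
    }
  })
  names(models) <- tab$tf_id
  models
}

#' Serialise motif models to a TSV file
#'
#' @param models List of \code{ft_motif} objects.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_motifs <- function(models, path) {
  rows <- lapply(models, function(mo) {
    model <- if (mo$kind == "consensus") mo$consensus else
      paste(apply(mo$matrix, 2L, function(col)
        paste(sprintf("%s:%g", c("A", "C", "G", "T"), col), collapse = ",")),
        collapse = ";")
    data.frame(tf_id = mo$tf_id, name = mo$name, kind = mo$kind,
               model = model, threshold = mo$threshold,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Remove gaps from one alignment row; return the ungapped sequence and the
# alignment column of every ungapped position.
ungap_row <- function(gapped) {
  chars <- strsplit(gapped, "", fixed = TRUE)[[1L]]
  keep <- chars != "-"
  list(seq = paste(chars[keep], collapse = ""), cols = which(keep))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Scan a sequence with an IUPAC consensus motif
#'
#' Scans the ungapped sequence of one alignment row; every window whose
#' bases are each compatible with the IUPAC code at that position is a site
#' with similarity 1. When both strands are scanned, a window matching on
#' both (a palindromic hit) is reported once with strand \code{"both"}.
#' Site positions are mapped back to alignment columns.
#'
#' @param gapped_seq Gapped sequence string (one alignment row).
#' @param model A consensus \code{ft_motif}.
#' @param seq_id Sequence identifier for the output.
#' @param strands Character vector among \code{"+"}, \code{"-"}.
#' @return Data frame of sites: \code{tf_id}, \code{name}, \code{seq_id},
#'   \code{aln_start}, \code{aln_end}, \code{ungapped_start}, \code{strand},
#'   \code{score}.
#' @export
scan_consensus <- function(gapped_seq, model, seq_id = "seq",
                           strands = c("+", "-")) {
  stopifnot(inherits(model, "ft_motif"))
  if (model$kind != "consensus") stop("model is not a consensus motif")
  ug <- ungap_row(gapped_seq)
  n <- nchar(ug$seq)
  if (n < model$width) return(empty_sites())
  subject <- Biostrings::DNAString(ug$seq)
  hit_starts <- function(pattern) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                  fixed = FALSE)
    Biostrings::start(m)
  }
  plus <- if ("+" %in% strands) hit_starts(model$consensus) else integer(0)
  minus <- if ("-" %in% strands) hit_starts(revcomp(model$consensus)) else integer(0)
  both <- intersect(plus, minus)
  starts <- sort(unique(c(plus, minus)))
  if (length(starts) == 0L) return(empty_sites())
  strand <- ifelse(starts %in% both, "both",
                   ifelse(starts %in% plus, "+", "-"))
  data.frame(
    tf_id = model$tf_id, name = model$name, seq_id = seq_id,
    aln_start = ug$cols[starts], aln_end = ug$cols[starts + model$width - 1L],
    ungapped_start = starts, strand = strand, score = 1,
    stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(tf_id = character(0), name = character(0), seq_id = character(0),
             aln_start = integer(0), aln_end = integer(0),
             ungapped_start = integer(0), strand = character(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

# Similarity of every window of width w in chars (ungapped) against a
# frequency matrix: matched-frequency sum / maximal-frequency sum.
matrix_window_scores <- function(chars, freq) {
  w <- ncol(freq)
  n <- length(chars)
  if (n < w) return(numeric(0))
  base_idx <- match(chars, c("A", "C", "G", "T"))  # NA for N
  max_sum <- sum(apply(freq, 2L, max))
  n_win <- n - w + 1L
  scores <- numeric(n_win)
  # accumulate matched frequencies position by position (vectorised over windows)
  has_n <- rep(FALSE, n_win)
  for (j in seq_len(w)) {
    idx <- base_idx[j:(j + n_win - 1L)]
    has_n <- has_n | is.na(idx)
    f <- freq[cbind(ifelse(is.na(idx), 1L, idx), j)]
    f[is.na(idx)] <- 0
    scores <- scores + f
  }
  scores <- scores / max_sum
  scores[has_n] <- NA_real_  # windows containing N are skipped
  scores
}

# Reverse-complement a frequency matrix (reverse columns, swap A/T and C/G).
revcomp_matrix <- function(freq) {
  out <- freq[c("T", "G", "C", "A"), rev(seq_len(ncol(freq))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

#' Scan a sequence with a position-frequency matrix
#'
#' Window similarity is the sum of the matrix frequencies of the observed
#' bases divided by the sum of the per-position maxima, so the
#' best-matching window scores 1. Windows at or above the model threshold
#' are sites. Windows containing \code{N} are skipped. Minus-strand
#' scanning uses the reverse-complemented matrix; windows reaching the
#' threshold on both strands are reported once with strand \code{"both"}.
#'
#' @inheritParams scan_consensus
#' @param model A matrix \code{ft_motif}.
#' @return Data frame of sites (see \code{\link{scan_consensus}}), with the
#'   score of a "both" site being the larger of the two strand scores.
#' @export
scan_matrix <- function(gapped_seq, model, seq_id = "seq",
                        strands = c("+", "-")) {
  stopifnot(inherits(model, "ft_motif"))
  if (model$kind != "matrix") stop("model is not a matrix motif")
  ug <- ungap_row(gapped_seq)
  chars <- strsplit(ug$seq, "", fixed = TRUE)[[1L]]
  if (length(chars) < model$width) return(empty_sites())

  s_plus <- if ("+" %in% strands)
    matrix_window_scores(chars, model$matrix) else NULL
  s_minus <- if ("-" %in% strands)
    matrix_window_scores(chars, revcomp_matrix(model$matrix)) else NULL

  n_win <- length(if (!is.null(s_plus)) s_plus else s_minus)
  hit_p <- if (!is.null(s_plus)) !is.na(s_plus) & s_plus >= model$threshold
           else rep(FALSE, n_win)
  hit_m <- if (!is.null(s_minus)) !is.na(s_minus) & s_minus >= model$threshold
           else rep(FALSE, n_win)
  starts <- which(hit_p | hit_m)
  if (length(starts) == 0L) return(empty_sites())
  strand <- ifelse(hit_p[starts] & hit_m[starts], "both",
                   ifelse(hit_p[starts], "+", "-"))
  score <- pmax(ifelse(hit_p[starts], s_plus[starts], -Inf),
                ifelse(hit_m[starts], s_minus[starts], -Inf))
  data.frame(
    tf_id = model$tf_id, name = model$name, seq_id = seq_id,
    aln_start = ug$cols[starts], aln_end = ug$cols[starts + model$width - 1L],
    ungapped_start = starts, strand = strand, score = score,
    stringsAsFactors = FALSE)
}

#' Scan all alignment rows with a set of motif models
#'
#' @param aln An \code{ft_alignment}.
#' @param models List of \code{ft_motif} objects.
#' @param seq_ids Rows to scan; defaults to all sequences.
#' @param strands Strands to scan.
#' @return Combined site data frame.
#' @export
scan_motifs <- function(aln, models, seq_ids = names(aln$seqs),
                        strands = c("+", "-")) {
  stopifnot(inherits(aln, "ft_alignment"))
  out <- list()
  for (sid in seq_ids) {
    for (mo in models) {
      sites <- if (mo$kind == "consensus") {
        scan_consensus(aln$seqs[[sid]], mo, seq_id = sid, strands = strands)
      } else {
        scan_matrix(aln$seqs[[sid]], mo, seq_id = sid, strands = strands)
      }
      out[[length(out) + 1L]] <- sites
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_sites()
  rownames(res) <- NULL
  res
}

#' Classify motif sites by polymorphic-region membership
#'
#' A site is inside a polymorphic region when at least 1 bp of its
#' alignment-column window overlaps the region set (set
#' \code{mode = "within"} to require full containment). Overlapping indel
#' labels (\code{"<length> bp"}) are attached; sites overlapping only SNP
#' columns are labelled \code{"SNP"}.
#'
#' @param sites Site data frame from the scanners.
#' @param variants An \code{ft_variants} object in the same alignment frame.
#' @param mode Overlap rule, \code{"any"} (default) or \code{"within"}.
#' @return \code{sites} with added columns \code{in_polymorphic_region}
#'   (logical) and \code{indel_labels} (comma-separated, \code{""} when
#'   outside).
#' @export
classify_sites <- function(sites, variants, mode = c("any", "within")) {
  mode <- match.arg(mode)
  regions <- polymorphic_region_set(variants)
  n <- nrow(sites)
  if (n == 0L) {
    sites$in_polymorphic_region <- logical(0)
    sites$indel_labels <- character(0)
    return(sites)
  }
  sites$in_polymorphic_region <- region_overlaps(
    regions, sites$aln_start, sites$aln_end, mode = mode)

  ind <- variants$indels
  snp <- variants$snps
  q <- IRanges::IRanges(start = sites$aln_start, end = sites$aln_end)
  labels <- character(n)
  if (nrow(ind) > 0L) {
    ir <- IRanges::IRanges(start = ind$aln_start, end = ind$aln_end)
    hits <- IRanges::findOverlaps(q, ir)
    lab_by_site <- split(sprintf("%d bp", ind$length[S4Vectors::subjectHits(hits)]),
                         S4Vectors::queryHits(hits))
    for (si in names(lab_by_site)) {
      labels[as.integer(si)] <- paste(unique(lab_by_site[[si]]), collapse = ", ")
    }
  }
  if (nrow(snp) > 0L) {
    sr <- IRanges::IRanges(start = snp$aln_col, width = 1L)
    snp_hit <- IRanges::overlapsAny(q, sr)
    add_snp <- snp_hit & sites$in_polymorphic_region
    labels[add_snp & labels == ""] <- "SNP"
  }
  sites$indel_labels <- labels
  sites
}

#' Exclusivity verdicts per transcription factor
#'
#' Within a promoter scope (an alignment-column interval, typically the
#' region upstream of the TSS column), a factor is "exclusive" when every
#' one of its in-scope binding sites overlaps the polymorphic region set —
#' i.e. the factor's regulatory input is entirely carried by indel/SNP
#' alleles. Factors with no in-scope site are excluded.
#'
#' @param classified Sites annotated by \code{\link{classify_sites}}.
#' @param scope Length-2 integer vector \code{c(start, end)} of alignment
#'   columns delimiting the promoter scope.
#' @return Data frame with \code{tf_id}, \code{name}, \code{n_sites},
#'   \code{n_in_polymorphic}, \code{exclusive}.
#' @export
exclusive_tfs <- function(classified, scope) {
  if (length(scope) != 2L || scope[1L] > scope[2L]) {
    stop("scope must be c(start, end) with start <= end")
  }
  in_scope <- classified[classified$aln_start >= scope[1L] &
                           classified$aln_end <= scope[2L], , drop = FALSE]
  if (nrow(in_scope) == 0L) {
    return(data.frame(tf_id = character(0), name = character(0),
                      n_sites = integer(0), n_in_polymorphic = integer(0),
                      exclusive = logical(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(split(in_scope, in_scope$tf_id), function(chunk) {
    data.frame(tf_id = chunk$tf_id[1L], name = chunk$name[1L],
               n_sites = nrow(chunk),
               n_in_polymorphic = sum(chunk$in_polymorphic_region),
               exclusive = all(chunk$in_polymorphic_region),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$tf_id), , drop = FALSE]
}

#' Per-indel report of exclusive flowering-pathway factors
#'
#' Restricts the classified sites to transcription factors that are both
#' exclusive (all in-scope sites in polymorphic regions) and present in a
#' user-supplied flowering-pathway annotation list, sorted by factor then
#' position.
#'
#' @param classified Sites annotated by \code{\link{classify_sites}}.
#' @param verdicts Output of \code{\link{exclusive_tfs}}.
#' @param flowering_tfs Character vector of tf_ids from flowering
#'   regulatory pathways.
#' @return Data frame with \code{tf_id}, \code{name}, \code{seq_id},
#'   \code{position} (alignment column), \code{indel_labels},
#'   \code{strand}, \code{score}.
#' @export
per_indel_report <- function(classified, verdicts, flowering_tfs) {
  keep_tfs <- intersect(verdicts$tf_id[verdicts$exclusive], flowering_tfs)
  sub <- classified[classified$tf_id %in% keep_tfs, , drop = FALSE]
  out <- data.frame(tf_id = sub$tf_id, name = sub$name, seq_id = sub$seq_id,
                    position = sub$aln_start,
                    indel_labels = sub$indel_labels, strand = sub$strand,
                    score = sub$score, stringsAsFactors = FALSE)
  out <- out[order(out$tf_id, out$position, out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
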