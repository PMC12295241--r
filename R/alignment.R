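#' Read a gapped multiple sequence alignment
#'
#' Reads an aligned multi-FASTA file (gap character \code{-}) into an
#' \code{ft_alignment} object. All sequences must have equal length and use
#' only the characters \code{A,C,G,T,N,-}; other IUPAC ambiguity letters are
#' rejected so that downstream variant calls are unambiguous.
#'
#' @param path Path to an aligned multi-FASTA file.
#' @param ref_id Identifier of the reference sequence. Defaults to the first
#'   record in the file.
#' @return An object of class \code{ft_alignment}: a list with elements
#'   \code{seqs} (named character vector of gapped sequences, upper case),
#'   \code{length} (number of alignment columns) and \code{ref_id}.
#' @export
read_alignment <- function(path, ref_id = NULL) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("alignment file is empty: ", path)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  new_alignment(seqs, ref_id = ref_id)
}

#' Construct an alignment from in-memory sequences
#'
#' @param seqs Named character vector of gapped sequences.
#' @param ref_id Reference sequence id; defaults to the first name.
#' @return An \code{ft_alignment} object.
#' @export
new_alignment <- function(seqs, ref_id = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  if (length(seqs) < 2L) {
    stop("an alignment needs at least 2 sequences, got ", length(seqs))
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(range(widths), collapse = "-"), ")")
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("unsupported characters (only A,C,G,T,N,- allowed) in: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  if (is.null(ref_id)) ref_id <- names(seqs)[1L]
  if (!ref_id %in% names(seqs)) {
    stop("ref_id '", ref_id, "' not present in the alignment")
  }
  structure(
    list(seqs = seqs, length = unname(widths[1L]), ref_id = ref_id),
    class = "ft_alignment"
  )
}

#' @export
print.ft_alignment <- function(x, ...) {
  cat("ft_alignment:", length(x$seqs), "sequences x", x$length,
      "columns; reference:", x$ref_id, "\n")
  invisible(x)
}

#' Write an alignment to aligned multi-FASTA
#'
#' @param aln An \code{ft_alignment}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "ft_alignment"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs), path)
  invisible(path)
}

# Alignment rows as a character matrix (columns = alignment columns).
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  m
}

#' Map alignment columns to reference coordinates
#'
#' Builds the bijection between non-gap reference columns and 1-based
#' ungapped reference positions.
#'
#' @param aln An \code{ft_alignment}.
#' @param seq_id Sequence to map; defaults to the alignment reference.
#' @return A list of class \code{ft_coordmap} with \code{col_to_ref}
#'   (integer vector, one entry per alignment column, \code{NA} where the
#'   mapped sequence has a gap) and \code{ref_to_col} (integer vector, one
#'   entry per ungapped position).
#' @export
build_coord_map <- function(aln, seq_id = aln$ref_id) {
  stopifnot(inherits(aln, "ft_alignment"))
  if (!seq_id %in% names(aln$seqs)) stop("unknown sequence id: ", seq_id)
  chars <- strsplit(aln$seqs[[seq_id]], "", fixed = TRUE)[[1L]]
  is_base <- chars != "-"
  col_to_ref <- rep(NA_integer_, length(chars))
  col_to_ref[is_base] <- seq_len(sum(is_base))
  structure(
    list(col_to_ref = col_to_ref, ref_to_col = which(is_base),
         seq_id = seq_id),
    class = "ft_coordmap"
  )
}

#' Reference anchor for TSS-relative coordinates
#'
#' An anchor fixes the genomic position and orientation of a gene's
#' transcription start site, the origin of the signed coordinate axis used
#' throughout (negative = upstream of the TSS, positive = downstream).
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name.
#' @param tss_genomic 1-based genomic coordinate of the TSS (bp).
#' @param strand \code{"forward"} or \code{"reverse_complement"}.
#' @return A list of class \code{ft_anchor}.
#' @export
make_anchor <- function(gene_id, chromosome, tss_genomic,
                        strand = c("forward", "reverse_complement")) {
  strand <- match.arg(strand)
  tss_genomic <- as.integer(tss_genomic)
  if (is.na(tss_genomic) || tss_genomic < 1L) {
    stop("tss_genomic must be a 1-based coordinate >= 1")
  }
  structure(
    list(gene_id = gene_id, chromosome = chromosome,
         tss_genomic = tss_genomic, strand = strand),
    class = "ft_anchor"
  )
}

#' Read TSS anchors from a TSV file
#'
#' Expected columns: \code{gene_id}, \code{chromosome}, \code{tss_genomic},
#' \code{strand}.
#'
#' @param path TSV path.
#' @return Named list of \code{ft_anchor} objects keyed by gene id.
#' @export
read_anchors <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "tss_genomic", "strand")
  if (!all(need %in% names(tab))) {
    stop("anchor table must have columns: ", paste(need, collapse = ", "))
  }
  anchors <- lapply(seq_len(nrow(tab)), function(i) {
    make_anchor(tab$gene_id[i], tab$chromosome[i], tab$tss_genomic[i],
                tab$strand[i])
  })
  names(anchors) <- tab$gene_id
  anchors
}

#' Convert a genomic position to a TSS-relative coordinate
#'
#' Returns 0 at the TSS, negative upstream of it and positive downstream.
#' For reverse-complement anchors, upstream corresponds to larger genomic
#' coordinates, so the sign of the difference is flipped.
#'
#' @param ref_pos 1-based genomic position(s), vectorised.
#' @param anchor An \code{ft_anchor}.
#' @return Signed integer bp relative to the TSS.
#' @export
tss_relative <- function(ref_pos, anchor) {
  stopifnot(inherits(anchor, "ft_anchor"))
  if (any(ref_pos < 1L, na.rm = TRUE)) stop("ref_pos must be >= 1")
  if (anchor$strand == "forward") {
    as.integer(ref_pos - anchor$tss_genomic)
  } else {
    as.integer(anchor$tss_genomic - ref_pos)
  }
}

#' Inclusive span length between two TSS-relative coordinates
#'
#' Counts every integer position from the smaller to the larger endpoint,
#' including both endpoints and position 0 when the span crosses the TSS:
#' \code{|a - b| + 1}.
#'
#' @param tss_rel_a,tss_rel_b Signed TSS-relative endpoints (bp), vectorised.
#' @return Inclusive length in bp.
#' @export
span_length <- function(tss_rel_a, tss_rel_b) {
  as.integer(abs(tss_rel_a - tss_rel_b) + 1L)
}

#' Call indels and SNP loci from a gapped alignment
#'
#' Compares every non-reference sequence against the reference, pairwise by
#' alignment column. For each pair, columns where both sequences are gapped
#' (gaps induced by a third sequence's insertion) are transparent and do not
#' interrupt a run. A maximal run of contig gaps over reference bases is a
#' deletion; a maximal run of contig bases over reference gaps is an
#' insertion anchored at the last reference base before the run (anchor 0
#' when the run precedes the first reference base). Gap runs touching either
#' end of a contig are unaligned ends (missing sequence), not deletions.
#' Identical gap runs (same kind and alignment column interval) observed in
#' several contigs are merged into one variant with multiple carriers.
#' Aligned base mismatches (both bases in A,C,G,T) are SNP loci.
#'
#' @param aln An \code{ft_alignment}.
#' @param anchor Optional \code{ft_anchor}; when given together with
#'   \code{ref_offset}, variants are annotated with TSS-relative
#'   coordinates.
#' @param ref_offset Genomic coordinate of reference position 1 (so genomic
#'   position = \code{ref_offset + ref_pos - 1}). Default 1.
#' @return A list of class \code{ft_variants} with data frames
#'   \code{indels} (variant_id, kind, ref_start, ref_end, length, aln_start,
#'   aln_end, carriers, and tss_rel_start/tss_rel_end when anchored),
#'   \code{snps} (ref_pos, aln_col, ref_base, alt_base, carriers, tss_rel)
#'   and \code{unaligned} (seq_id, side, aln_start, aln_end).
#' @export
call_variants <- function(aln, anchor = NULL, ref_offset = 1L) {
  stopifnot(inherits(aln, "ft_alignment"))
  m <- aln_matrix(aln)
  ref <- m[aln$ref_id, ]
  cmap <- build_coord_map(aln)
  contigs <- setdiff(rownames(m), aln$ref_id)

  indel_rows <- list()
  snp_rows <- list()
  unaligned_rows <- list()

  for (cid in contigs) {
    seqv <- m[cid, ]
    base_cols <- which(seqv != "-")
    if (length(base_cols) == 0L) {
      unaligned_rows[[length(unaligned_rows) + 1L]] <- data.frame(
        seq_id = cid, side = "both", aln_start = 1L, aln_end = aln$length,
        stringsAsFactors = FALSE)
      next
    }
    first_base <- base_cols[1L]
    last_base <- base_cols[length(base_cols)]
    if (first_base > 1L) {
      unaligned_rows[[length(unaligned_rows) + 1L]] <- data.frame(
        seq_id = cid, side = "left", aln_start = 1L,
        aln_end = first_base - 1L, stringsAsFactors = FALSE)
    }
    if (last_base < aln$length) {
      unaligned_rows[[length(unaligned_rows) + 1L]] <- data.frame(
        seq_id = cid, side = "right", aln_start = last_base + 1L,
        aln_end = aln$length, stringsAsFactors = FALSE)
    }

    # pairwise view: both-gap columns are transparent
    keep <- !(ref == "-" & seqv == "-")
    cols <- which(keep)
    r <- ref[cols]
    s <- seqv[cols]
    # restrict deletion calling to the aligned body of the contig
    inside <- cols >= first_base & cols <= last_base

    state <- rep("match", length(cols))
    state[r != "-" & s == "-"] <- "del"
    state[r == "-" & s != "-"] <- "ins"
    state[r != "-" & s != "-" & r != s &
            r %in% c("A", "C", "G", "T") & s %in% c("A", "C", "G", "T")] <- "snp"

    runs <- rle(state)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      kind <- runs$values[k]
      if (kind == "match") next
      idx <- starts[k]:ends[k]
      run_cols <- cols[idx]
      if (kind == "del") {
        if (!all(inside[idx])) next  # unaligned terminus, already recorded
        ref_pos <- cmap$col_to_ref[run_cols]
        indel_rows[[length(indel_rows) + 1L]] <- data.frame(
          kind = "deletion", ref_start = ref_pos[1L],
          ref_end = ref_pos[length(ref_pos)], length = length(ref_pos),
          aln_start = run_cols[1L], aln_end = run_cols[length(run_cols)],
          carrier = cid, stringsAsFactors = FALSE)
      } else if (kind == "ins") {
        prev_ref <- cmap$col_to_ref[seq_len(run_cols[1L] - 1L)]
        anchor_pos <- if (any(!is.na(prev_ref))) max(prev_ref, na.rm = TRUE) else 0L
        indel_rows[[length(indel_rows) + 1L]] <- data.frame(
          kind = "insertion", ref_start = anchor_pos, ref_end = anchor_pos,
          length = length(run_cols),
          aln_start = run_cols[1L], aln_end = run_cols[length(run_cols)],
          carrier = cid, stringsAsFactors = FALSE)
      } else { # snp: one locus per column
        for (cc in run_cols) {
          snp_rows[[length(snp_rows) + 1L]] <- data.frame(
            ref_pos = cmap$col_to_ref[cc], aln_col = cc,
            ref_base = ref[cc], alt_base = seqv[cc], carrier = cid,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  indels <- merge_carriers(indel_rows,
                           key = c("kind", "aln_start", "aln_end",
                                   "ref_start", "ref_end", "length"))
  snps <- merge_carriers(snp_rows,
                         key = c("ref_pos", "aln_col", "ref_base", "alt_base"))
  if (nrow(snps) > 0L) snps <- snps[order(snps$ref_pos, snps$alt_base), , drop = FALSE]
  if (nrow(indels) > 0L) {
    indels <- indels[order(indels$aln_start, indels$aln_end, indels$kind), ,
                     drop = FALSE]
    indels$variant_id <- sprintf("%s_%d_%dbp",
                                 ifelse(indels$kind == "deletion", "DEL", "INS"),
                                 indels$ref_start, indels$length)
    # disambiguate distinct variants that share kind/position/length
    indels$variant_id <- make.unique(indels$variant_id, sep = ".")
    indels <- indels[, c("variant_id", setdiff(names(indels), "variant_id"))]
  } else {
    indels$variant_id <- character(0)
  }

  if (!is.null(anchor)) {
    genomic <- function(p) ref_offset + p - 1L
    if (nrow(indels) > 0L) {
      a <- tss_relative(genomic(indels$ref_start), anchor)
      b <- tss_relative(genomic(indels$ref_end), anchor)
      indels$tss_rel_start <- pmin(a, b)
      indels$tss_rel_end <- pmax(a, b)
    } else {
      indels$tss_rel_start <- integer(0)
      indels$tss_rel_end <- integer(0)
    }
    snps$tss_rel <- if (nrow(snps) > 0L)
      tss_relative(genomic(snps$ref_pos), anchor) else integer(0)
  }

  unaligned <- if (length(unaligned_rows) > 0L)
    do.call(rbind, unaligned_rows)
  else
    data.frame(seq_id = character(0), side = character(0),
               aln_start = integer(0), aln_end = integer(0))
  rownames(indels) <- rownames(snps) <- rownames(unaligned) <- NULL

  structure(list(indels = indels, snps = snps, unaligned = unaligned,
                 ref_id = aln$ref_id),
            class = "ft_variants")
}

# Collapse per-contig variant rows sharing a key into one row with a
# comma-separated carrier set.
merge_carriers <- function(rows, key) {
  if (length(rows) == 0L) {
    df <- data.frame(matrix(nrow = 0, ncol = length(key) + 1L))
    names(df) <- c(key, "carriers")
    for (k in c("ref_start", "ref_end", "length", "aln_start", "aln_end",
                "ref_pos", "aln_col")) {
      if (k %in% names(df)) df[[k]] <- integer(0)
    }
    for (k in c("kind", "ref_base", "alt_base", "carriers")) {
      if (k %in% names(df)) df[[k]] <- character(0)
    }
    return(df)
  }
  df <- do.call(rbind, rows)
  id <- do.call(paste, c(df[key], sep = "\r"))
  agg <- lapply(split(df, id), function(chunk) {
    out <- chunk[1L, key, drop = FALSE]
    out$carriers <- paste(sort(unique(chunk$carrier)), collapse = ",")
    out
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' @export
print.ft_variants <- function(x, ...) {
  cat("ft_variants:", nrow(x$indels), "indels,", nrow(x$snps),
      "SNP loci,", nrow(x$unaligned), "unaligned contig ends\n")
  invisible(x)
}

#' Polymorphic region set on alignment coordinates
#'
#' The union of indel alignment-column intervals and SNP columns, as an
#' \code{\link[IRanges]{IRanges}} over alignment columns. Used for the
#' binding-site exclusivity filter.
#'
#' @param variants An \code{ft_variants} object (or a list with
#'   \code{indels}/\code{snps} data frames on alignment coordinates).
#' @return An \code{IRanges} of reduced (merged) polymorphic intervals.
#' @export
polymorphic_region_set <- function(variants) {
  ind <- variants$indels
  snp <- variants$snps
  r1 <- if (nrow(ind) > 0L)
    IRanges::IRanges(start = ind$aln_start, end = ind$aln_end)
  else IRanges::IRanges()
  r2 <- if (nrow(snp) > 0L)
    IRanges::IRanges(start = snp$aln_col, width = 1L)
  else IRanges::IRanges()
  IRanges::reduce(c(r1, r2))
}

#' Membership query against a polymorphic region set
#'
#' @param regions An \code{IRanges} from \code{\link{polymorphic_region_set}}.
#' @param start,end Query interval(s) on alignment columns; \code{end}
#'   defaults to \code{start} (point query). Vectorised.
#' @param mode \code{"any"}: >= 1 bp overlap counts (default);
#'   \code{"within"}: the query must lie entirely inside the region set.
#' @return Logical vector.
#' @export
region_overlaps <- function(regions, start, end = start,
                            mode = c("any", "within")) {
  mode <- match.arg(mode)
  q <- IRanges::IRanges(start = start, end = end)
  if (mode == "any") {
    IRanges::overlapsAny(q, regions)
  } else {
    IRanges::countOverlaps(q, regions, type = "within") > 0L
  }
}

#' Pair indel positions across homologous genes
#'
#' For each TSS-relative indel position of one species/gene, finds the
#' nearest indel position in another and reports the signed and absolute
#' distance, e.g. to compare a white lupin promoter indel with its putative
#' yellow lupin homolog.
#'
#' @param pos_a,pos_b Numeric vectors of TSS-relative indel positions.
#' @return Data frame with columns \code{pos_a}, \code{nearest_b},
#'   \code{delta} (signed, \code{pos_a - nearest_b}) and \code{abs_delta}.
#'   Empty when \code{pos_b} is empty.
#' @export
compare_homolog_positions <- function(pos_a, pos_b) {
  if (length(pos_b) == 0L || length(pos_a) == 0L) {
    return(data.frame(pos_a = numeric(0), nearest_b = numeric(0),
                      delta = numeric(0), abs_delta = numeric(0)))
  }
  nearest <- vapply(pos_a, function(p) pos_b[which.min(abs(pos_b - p))],
                    numeric(1))
  data.frame(pos_a = pos_a, nearest_b = nearest, delta = pos_a - nearest,
             abs_delta = abs(pos_a - nearest))
}
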