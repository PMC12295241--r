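# Independent brute-force oracles and fixture builders. These deliberately
# use naive per-column / per-window loops, distinct from the package's
# vectorised implementations.

# --- random gapped alignment --------------------------------------------

random_alignment <- function(n_seq = 3L, n_col = 120L, gap_runs = 4L,
                             max_gap = 20L, snp_rate = 0.05) {
  m <- matrix(sample(c("A", "C", "G", "T"), n_seq * n_col, replace = TRUE),
              nrow = n_seq)
  # shared backbone with sprinkled mismatches
  for (i in 2:n_seq) {
    same <- runif(n_col) > snp_rate
    m[i, same] <- m[1L, same]
  }
  for (i in seq_len(n_seq)) {
    for (g in seq_len(sample(0:gap_runs, 1L))) {
      w <- sample(seq_len(max_gap), 1L)
      s <- sample(seq_len(max(1L, n_col - w)), 1L)
      m[i, s:(s + w - 1L)] <- "-"
    }
  }
  # keep the reference and every row with at least one base
  for (i in seq_len(n_seq)) {
    if (all(m[i, ] == "-")) m[i, sample(n_col, 3L)] <- "A"
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- c("ref", paste0("ctg", seq_len(n_seq - 1L)))
  new_alignment(seqs, ref_id = "ref")
}

# --- per-column variant-calling oracle ----------------------------------

oracle_call_variants <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  ref <- m[aln$ref_id, ]
  ref_pos_of <- cumsum(ref != "-")
  contigs <- setdiff(rownames(m), aln$ref_id)
  dna <- c("A", "C", "G", "T")

  indels <- list(); snps <- list()
  for (cid in contigs) {
    sq <- m[cid, ]
    bases <- which(sq != "-")
    if (length(bases) == 0L) next
    lo <- bases[1L]; hi <- bases[length(bases)]
    cur_kind <- NULL; cur_cols <- integer(0)
    flush <- function() {
      if (is.null(cur_kind)) return()
      if (cur_kind == "del") {
        if (cur_cols[1L] >= lo && cur_cols[length(cur_cols)] <= hi) {
          rp <- ref_pos_of[cur_cols]
          indels[[length(indels) + 1L]] <<- data.frame(
            kind = "deletion", ref_start = rp[1L], ref_end = rp[length(rp)],
            length = length(cur_cols), aln_start = cur_cols[1L],
            aln_end = cur_cols[length(cur_cols)], carrier = cid)
        }
      } else {
        before <- cur_cols[1L] - 1L
        anchor <- if (before >= 1L && any(ref[seq_len(before)] != "-"))
          ref_pos_of[max(which(ref[seq_len(before)] != "-"))] else 0L
        indels[[length(indels) + 1L]] <<- data.frame(
          kind = "insertion", ref_start = anchor, ref_end = anchor,
          length = length(cur_cols), aln_start = cur_cols[1L],
          aln_end = cur_cols[length(cur_cols)], carrier = cid)
      }
    }
    for (col in seq_len(aln$length)) {
      rb <- ref[col]; sb <- sq[col]
      if (rb == "-" && sb == "-") next  # transparent
      kind <- if (rb != "-" && sb == "-") "del"
              else if (rb == "-" && sb != "-") "ins"
              else "base"
      if (!is.null(cur_kind) && kind == cur_kind && kind != "base") {
        cur_cols <- c(cur_cols, col)
      } else {
        flush(); cur_kind <- NULL; cur_cols <- integer(0)
        if (kind != "base") { cur_kind <- kind; cur_cols <- col }
      }
      if (kind == "base" && rb != sb && rb %in% dna && sb %in% dna) {
        snps[[length(snps) + 1L]] <- data.frame(
          ref_pos = ref_pos_of[col], aln_col = col, ref_base = rb,
          alt_base = sb, carrier = cid)
      }
    }
    flush()
  }
  key_merge <- function(rows, key) {
    if (length(rows) == 0L) return(NULL)
    df <- do.call(rbind, rows)
    id <- do.call(paste, c(df[key], sep = "\r"))
    out <- do.call(rbind, lapply(split(df, id), function(ch) {
      o <- ch[1L, key, drop = FALSE]
      o$carriers <- paste(sort(unique(ch$carrier)), collapse = ",")
      o
    }))
    rownames(out) <- NULL
    out
  }
  list(indels = key_merge(indels, c("kind", "ref_start", "ref_end", "length",
                                    "aln_start", "aln_end")),
       snps = key_merge(snps, c("ref_pos", "aln_col", "ref_base", "alt_base")))
}

# canonical string form of a variant set for set comparison
variant_sig <- function(indels, snps) {
  a <- if (!is.null(indels) && nrow(indels) > 0L)
    sprintf("%s:%d-%d:%d:%d-%d:%s", indels$kind, indels$ref_start,
            indels$ref_end, indels$length, indels$aln_start, indels$aln_end,
            indels$carriers)
  else character(0)
  b <- if (!is.null(snps) && nrow(snps) > 0L)
    sprintf("snp:%d:%d:%s>%s:%s", snps$ref_pos, snps$aln_col, snps$ref_base,
            snps$alt_base, snps$carriers)
  else character(0)
  sort(c(a, b))
}

# --- consensus-scanning oracle (regex expansion) ------------------------

iupac_expand <- function(consensus) {
  tab <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  parts <- tab[strsplit(consensus, "")[[1L]]]
  apply(do.call(expand.grid, c(parts, stringsAsFactors = FALSE)), 1L,
        paste, collapse = "")
}

str_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

oracle_scan_consensus <- function(ungapped, consensus) {
  words <- iupac_expand(consensus)
  find_all <- function(word) {
    hits <- integer(0)
    w <- nchar(word)
    if (nchar(ungapped) < w) return(hits)
    for (s in seq_len(nchar(ungapped) - w + 1L)) {
      if (substr(ungapped, s, s + w - 1L) == word) hits <- c(hits, s)
    }
    hits
  }
  plus <- sort(unique(unlist(lapply(words, find_all))))
  minus <- sort(unique(unlist(lapply(vapply(words, str_revcomp, ""), find_all))))
  list(plus = plus, minus = minus)
}

# --- matrix-scanning oracle ---------------------------------------------

oracle_scan_matrix <- function(ungapped, freq, threshold) {
  w <- ncol(freq)
  n <- nchar(ungapped)
  max_sum <- sum(apply(freq, 2L, max))
  score_word <- function(word) {
    chars <- strsplit(word, "")[[1L]]
    if (any(!chars %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(w), function(j) freq[chars[j], j], numeric(1))) / max_sum
  }
  plus <- numeric(0); minus <- numeric(0)
  starts_p <- integer(0); starts_m <- integer(0)
  if (n >= w) {
    for (s in seq_len(n - w + 1L)) {
      word <- substr(ungapped, s, s + w - 1L)
      sp <- score_word(word)
      sm <- score_word(str_revcomp(word))
      if (!is.na(sp) && sp >= threshold) { starts_p <- c(starts_p, s); plus <- c(plus, sp) }
      if (!is.na(sm) && sm >= threshold) { starts_m <- c(starts_m, s); minus <- c(minus, sm) }
    }
  }
  list(starts_plus = starts_p, scores_plus = plus,
       starts_minus = starts_m, scores_minus = minus)
}

# --- exclusivity oracle --------------------------------------------------

oracle_exclusive <- function(sites, poly_mask, scope) {
  in_scope <- sites[sites$aln_start >= scope[1L] & sites$aln_end <= scope[2L], ,
                    drop = FALSE]
  res <- list()
  for (tf in unique(in_scope$tf_id)) {
    ss <- in_scope[in_scope$tf_id == tf, , drop = FALSE]
    inside <- vapply(seq_len(nrow(ss)), function(i) {
      any(poly_mask[ss$aln_start[i]:ss$aln_end[i]])
    }, logical(1))
    res[[tf]] <- all(inside)
  }
  res
}

# random small phenotype panel (single trait/year) for association oracles
random_assoc_fixture <- function(n_lines = 20L, n_markers = 3L) {
  geno <- matrix(sample(0:2, n_lines * n_markers, replace = TRUE,
                        prob = c(0.6, 0.1, 0.3)),
                 nrow = n_lines,
                 dimnames = list(sprintf("L%03d", seq_len(n_lines)),
                                 sprintf("M%02d", seq_len(n_markers))))
  pheno <- data.frame(line_id = rep(rownames(geno), each = 2L),
                      trait = "BE",
                      year = rep(c("y1", "y2"), n_lines),
                      replicate = 1L,
                      days = 40 + stats::rnorm(2L * n_lines, 0, 10))
  list(geno = geno, pheno = pheno)
}
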