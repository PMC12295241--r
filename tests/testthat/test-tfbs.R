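agl15 <- motif_model("AT5G13790", "AGL15", consensus = "CARGNCAT")

test_that("consensus scanning expands IUPAC codes and reports palindromes once", {
  hit <- scan_consensus(paste0("TTT", "CAAGTCAT", "TTT"), agl15, strands = "+")
  expect_equal(nrow(hit), 1L)          # R -> A, N -> T
  expect_equal(hit$aln_start, 4L)
  expect_equal(hit$score, 1)
  none <- scan_consensus("TTTTTTTTTTTT", agl15)
  expect_equal(nrow(none), 0L)
  # gaps are skipped and positions mapped back to alignment columns
  gapped <- scan_consensus(paste0("TT--T", "CAAG--TCAT", "T"), agl15)
  expect_equal(gapped$aln_start, 6L)
  expect_equal(gapped$aln_end, 15L)
  # a perfectly palindromic pattern hit appears once with strand "both"
  pal <- motif_model("x", consensus = "ACGT")
  h <- scan_consensus("TTACGTTT", pal)
  expect_equal(h$strand, "both")
  expect_equal(nrow(h), 1L)
  expect_error(motif_model("x", consensus = "ACQT"), "IUPAC")
})

test_that("consensus scanning equals the regex-expansion oracle on random sequences", {
  set.seed(41)
  for (i in 1:25) {
    seqs <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
    got <- scan_consensus(seqs, agl15)
    want <- oracle_scan_consensus(seqs, "CARGNCAT")
    expect_equal(sort(got$ungapped_start[got$strand %in% c("+", "both")]),
                 want$plus, info = paste("fixture", i))
    expect_equal(sort(got$ungapped_start[got$strand %in% c("-", "both")]),
                 want$minus, info = paste("fixture", i))
  }
})

test_that("matrix scanning scores by matched over maximal frequency sums", {
  freq <- matrix(0.1, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  freq[cbind(match(c("C", "A", "C", "G", "T", "G"), c("A", "C", "G", "T")),
             1:6)] <- 0.7
  mo <- motif_model("m1", matrix = freq, threshold = 0.85)
  # the argmax word scores exactly 1
  hit <- scan_matrix(paste0("TT", "CACGTG", "AA"), mo, strands = "+")
  expect_equal(hit$score, 1)
  # uniform matrix: every window scores 1 on both strands
  unif <- motif_model("u", matrix = matrix(0.25, 4, 4,
    dimnames = list(c("A", "C", "G", "T"), NULL)))
  h <- scan_matrix("ACGTACGT", unif)
  expect_equal(nrow(h), 5L)
  expect_true(all(h$score == 1))
  expect_true(all(h$strand == "both"))
  # windows containing N are skipped
  hn <- scan_matrix("CANGTG", mo, strands = "+")
  expect_equal(nrow(hn), 0L)
  expect_error(motif_model("bad", matrix = freq * 2), "sum to 1")
})

test_that("matrix scanning equals exhaustive per-window recomputation", {
  set.seed(43)
  for (i in 1:15) {
    seqs <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
    freq <- sapply(1:8, function(j) { p <- runif(4); p / sum(p) })
    rownames(freq) <- c("A", "C", "G", "T")
    thr <- runif(1, 0.7, 0.95)
    mo <- motif_model("m", matrix = freq, threshold = thr)
    got <- scan_matrix(seqs, mo)
    want <- oracle_scan_matrix(seqs, freq, thr)
    expect_equal(sort(got$ungapped_start[got$strand %in% c("+", "both")]),
                 sort(want$starts_plus), info = paste("fixture", i))
    expect_equal(sort(got$ungapped_start[got$strand %in% c("-", "both")]),
                 sort(want$starts_minus), info = paste("fixture", i))
    # scores agree where both strands hit
    plus_sc <- got[got$strand == "+", ]
    if (nrow(plus_sc) > 0L) {
      expect_equal(plus_sc$score,
                   want$scores_plus[match(plus_sc$ungapped_start,
                                          want$starts_plus)],
                   tolerance = 1e-12)
    }
  }
})

test_that("consensus scanning equals matrix scanning with a 0/1 matrix at threshold 1", {
  set.seed(47)
  word <- "CACGTG"
  freq <- sapply(strsplit(word, "")[[1L]], function(b) {
    p <- rep(0, 4); p[match(b, c("A", "C", "G", "T"))] <- 1; p
  })
  rownames(freq) <- c("A", "C", "G", "T")
  colnames(freq) <- NULL
  mo_mat <- motif_model("m", matrix = freq, threshold = 1)
  mo_con <- motif_model("m", consensus = word)
  seqs <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  a <- scan_matrix(seqs, mo_mat)
  b <- scan_consensus(seqs, mo_con)
  expect_equal(a[c("aln_start", "strand")], b[c("aln_start", "strand")])
})

test_that("strand symmetry: scanning the reverse complement mirrors positions", {
  set.seed(53)
  seqs <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
                collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seqs, "")[[1L]]),
                                     collapse = ""))
  fwd_minus <- scan_consensus(seqs, agl15, strands = "-")
  rc_plus <- scan_consensus(rc, agl15, strands = "+")
  # a minus-strand site at start s corresponds to a plus site at
  # n - (s + w - 1) + 1 on the reverse complement
  n <- nchar(seqs); w <- 8L
  expect_equal(sort(n - (fwd_minus$ungapped_start + w - 1L) + 1L),
               sort(rc_plus$ungapped_start))
})

test_that("site classification flags polymorphic-region membership with labels", {
  variants <- list(
    indels = data.frame(aln_start = c(150L, 400L), aln_end = c(300L, 450L),
                        length = c(2126L, 51L)),
    snps = data.frame(aln_col = 600L))
  sites <- data.frame(
    tf_id = "t", name = "t", seq_id = "s",
    aln_start = c(161L, 295L, 350L, 596L, 700L),
    aln_end = c(168L, 302L, 357L, 603L, 707L),
    ungapped_start = NA_integer_, strand = "+", score = 1)
  cl <- classify_sites(sites, variants)
  expect_equal(cl$in_polymorphic_region, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(cl$indel_labels[1L], "2126 bp")
  expect_equal(cl$indel_labels[4L], "SNP")
  # all-or-nothing mode requires containment
  cl2 <- classify_sites(sites, variants, mode = "within")
  expect_equal(cl2$in_polymorphic_region, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # empty region set: all sites outside
  cl3 <- classify_sites(sites, list(
    indels = data.frame(aln_start = integer(0), aln_end = integer(0),
                        length = integer(0)),
    snps = data.frame(aln_col = integer(0))))
  expect_false(any(cl3$in_polymorphic_region))
  # randomized fixtures against a per-bp scan
  set.seed(59)
  for (i in 1:10) {
    v <- list(indels = data.frame(aln_start = s <- sample(900, 4),
                                  aln_end = s + sample(5:80, 4),
                                  length = sample(5:80, 4)),
              snps = data.frame(aln_col = sample(990, 5)))
    mask <- rep(FALSE, 1100)
    for (k in 1:4) mask[v$indels$aln_start[k]:v$indels$aln_end[k]] <- TRUE
    mask[v$snps$aln_col] <- TRUE
    st <- sample(1000, 20)
    ss <- data.frame(tf_id = "t", name = "t", seq_id = "s", aln_start = st,
                     aln_end = st + 7L, ungapped_start = NA_integer_,
                     strand = "+", score = 1)
    cls <- classify_sites(ss, v)
    brute <- vapply(seq_len(20), function(j) any(mask[st[j]:(st[j] + 7L)]),
                    logical(1))
    expect_equal(cls$in_polymorphic_region, brute)
  }
})

test_that("exclusivity verdicts match per-TF brute force and are monotone", {
  set.seed(61)
  for (i in 1:10) {
    n_tf <- 20L
    sites <- data.frame(
      tf_id = sample(sprintf("TF%02d", 1:n_tf), 60, replace = TRUE),
      name = "x", seq_id = "s",
      aln_start = st <- sample(2000, 60), aln_end = st + 7L,
      ungapped_start = NA_integer_, strand = "+", score = 1)
    v <- list(indels = data.frame(aln_start = s <- sample(1900, 6),
                                  aln_end = s + sample(10:100, 6),
                                  length = sample(10:100, 6)),
              snps = data.frame(aln_col = integer(0)))
    cl <- classify_sites(sites, v)
    scope <- c(1L, 1500L)
    verd <- exclusive_tfs(cl, scope)
    mask <- rep(FALSE, 2100)
    for (k in seq_len(6)) mask[v$indels$aln_start[k]:v$indels$aln_end[k]] <- TRUE
    brute <- oracle_exclusive(sites, mask, scope)
    expect_equal(nrow(verd), length(brute))
    for (tf in verd$tf_id) {
      expect_equal(verd$exclusive[verd$tf_id == tf], brute[[tf]], info = tf)
    }
    # enlarging the polymorphic set never breaks exclusivity
    v_big <- v
    v_big$indels <- rbind(v_big$indels,
                          data.frame(aln_start = 1L, aln_end = 700L,
                                     length = 700L))
    verd_big <- exclusive_tfs(classify_sites(sites, v_big), scope)
    common <- intersect(verd$tf_id[verd$exclusive], verd_big$tf_id)
    expect_true(all(verd_big$exclusive[match(common, verd_big$tf_id)]))
  }
})

test_that("per-indel report restricts to exclusive flowering factors deterministically", {
  sites <- data.frame(
    tf_id = c("A", "A", "B", "C"), name = c("AGL15x", "AGL15x", "b", "c"),
    seq_id = "s", aln_start = c(161L, 700L, 50L, 80L),
    aln_end = c(168L, 707L, 57L, 87L), ungapped_start = NA_integer_,
    strand = c("+", "-", "+", "+"), score = c(1, 0.96, 0.9, 0.9))
  v <- list(indels = data.frame(aln_start = c(100L, 650L), aln_end = c(200L, 750L),
                                length = c(2126L, 264L)),
            snps = data.frame(aln_col = 80L))
  cl <- classify_sites(sites, v)
  verd <- exclusive_tfs(cl, scope = c(1L, 1000L))
  # empty flowering list -> empty table
  expect_equal(nrow(per_indel_report(cl, verd, character(0))), 0L)
  rep1 <- per_indel_report(cl, verd, c("A", "C"))
  expect_true(all(rep1$tf_id %in% c("A", "C")))
  expect_false("B" %in% rep1$tf_id)    # B's site is outside polymorphic regions
  ord <- order(rep1$tf_id, rep1$position)
  expect_equal(rep1, rep1[ord, ], ignore_attr = TRUE)
  # byte-identical on rerun
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write.table(rep1, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(per_indel_report(cl, verd, c("A", "C")), f2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_equal(tools::md5sum(f1)[[1L]], tools::md5sum(f2)[[1L]])
})

test_that("motif tables round-trip through the TSV serialisation", {
  path <- system.file("extdata", "motifs_synthetic.tsv",
                      package = "ftindelscan", mustWork = TRUE)
  models <- read_motifs(path)
  expect_true("AT5G13790" %in% names(models))
  expect_equal(models$AT5G13790$consensus, "CARGNCAT")
  mats <- Filter(function(m) m$kind == "matrix", models)
  expect_gte(length(mats), 10L)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_motifs(models, out)
  re <- read_motifs(out)
  expect_equal(re$SYNTF01$matrix, models$SYNTF01$matrix, tolerance = 1e-12)
})
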