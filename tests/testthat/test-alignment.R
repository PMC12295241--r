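test_that("alignment reading validates structure and round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ref", "ACGTACGTAC", ">c1", "ACG--CGTAC", ">c2", "ACGTACGTAC"),
             path)
  aln <- read_alignment(path)
  expect_s3_class(aln, "ft_alignment")
  expect_equal(aln$length, 10L)
  expect_equal(aln$ref_id, "ref")

  # round trip preserves gaps and length
  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_equal(read_alignment(out)$seqs, aln$seqs)

  # degenerate inputs
  writeLines(c(">only", "ACGT"), path)
  expect_error(read_alignment(path), "at least 2")
  writeLines(c(">a", "ACGT", ">b", "ACG"), path)
  expect_error(read_alignment(path), "ragged")
  writeLines(c(">a", "ACRT", ">b", "ACGT"), path)
  expect_error(read_alignment(path), "unsupported characters")
})

test_that("coordinate map skips reference gaps and is a bijection", {
  aln <- new_alignment(c(ref = "ACGT----ACGTAC", ctg = "ACGTTTTTACGTAC"))
  cm <- build_coord_map(aln)
  expect_equal(cm$col_to_ref[4L], 4L)
  expect_true(all(is.na(cm$col_to_ref[5:8])))
  expect_equal(cm$col_to_ref[9L], 5L)
  # composing col -> ref -> col is the identity on non-gap columns
  non_gap <- which(!is.na(cm$col_to_ref))
  expect_equal(cm$ref_to_col[cm$col_to_ref[non_gap]], non_gap)
  # gapless reference: identity map
  aln2 <- new_alignment(c(ref = "ACGTACGT", ctg = "ACG--CGT"))
  expect_equal(build_coord_map(aln2)$col_to_ref, 1:8)
})

test_that("TSS-relative coordinates respect strand and the inclusive span rule", {
  fwd <- make_anchor("FTa1", "Lalb_Chr02", 14996788, "forward")
  rev <- make_anchor("FTa2", "Lalb_Chr21", 12758313, "reverse_complement")
  expect_equal(tss_relative(14996788, fwd), 0L)
  expect_equal(tss_relative(14992627, fwd), -4161L)
  expect_equal(tss_relative(12758413, rev), -100L)
  # strand antisymmetry
  flip <- make_anchor("FTa1", "Lalb_Chr02", 14996788, "reverse_complement")
  pos <- c(14990000L, 14996788L, 15000000L)
  expect_equal(tss_relative(pos, flip), -tss_relative(pos, fwd))
  # inclusive span counts position 0
  expect_equal(span_length(-4161, -3336), 826L)
  expect_equal(span_length(-511, 229), 741L)
  expect_equal(span_length(5, 5), 1L)
  expect_equal(span_length(-3, 7), span_length(7, -3))
})

test_that("variant caller handles planted deletions, insertions, termini and SNPs", {
  #          123456789012345678
  aln <- new_alignment(c(
    ref = "AACCGGTTAACC--GGTT",
    del = "AACC----AACC--GGTT",   # 4 bp deletion at ref 5-8
    ins = "AACCGGTTAACCGGGGTT",   # 2 bp insertion anchored at ref 12
    snp = "AACCGGTTAACA--GG--"))  # SNP at ref 12 + unaligned right end
  v <- call_variants(aln)
  del <- v$indels[v$indels$kind == "deletion", ]
  expect_equal(nrow(del), 1L)
  expect_equal(c(del$ref_start, del$ref_end, del$length), c(5L, 8L, 4L))
  ins <- v$indels[v$indels$kind == "insertion", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(c(ins$ref_start, ins$length), c(12L, 2L))
  expect_equal(v$snps$ref_pos, 12L)
  expect_equal(v$snps$alt_base, "A")
  # terminal gap run reported as unaligned end, not a deletion
  expect_equal(v$unaligned$seq_id, "snp")
  expect_equal(v$unaligned$side, "right")

  # identical sequences: nothing called
  v0 <- call_variants(new_alignment(c(ref = "ACGTACGT", c1 = "ACGTACGT")))
  expect_equal(nrow(v0$indels), 0L)
  expect_equal(nrow(v0$snps), 0L)

  # shared identical gap runs merge into one variant with both carriers
  aln2 <- new_alignment(c(ref = "AAAACCCCGGGG",
                          c1  = "AAAA----GGGG",
                          c2  = "AAAA----GGGG"))
  v2 <- call_variants(aln2)
  expect_equal(nrow(v2$indels), 1L)
  expect_equal(v2$indels$carriers, "c1,c2")
})

test_that("variant caller matches the per-column oracle on random alignments", {
  set.seed(101)
  for (i in 1:30) {
    aln <- random_alignment(n_seq = sample(2:4, 1L),
                            n_col = sample(50:200, 1L))
    got <- call_variants(aln)
    want <- oracle_call_variants(aln)
    expect_identical(variant_sig(got$indels, got$snps),
                     variant_sig(want$indels, want$snps),
                     info = paste("fixture", i))
  }
})

test_that("indel/insertion bookkeeping balances contig lengths over the aligned span", {
  set.seed(202)
  for (i in 1:15) {
    aln <- random_alignment(n_seq = 3L, n_col = 150L)
    v <- call_variants(aln)
    m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
    rownames(m) <- names(aln$seqs)
    for (cid in setdiff(names(aln$seqs), aln$ref_id)) {
      bases <- which(m[cid, ] != "-")
      if (length(bases) == 0L) next
      span <- bases[1L]:bases[length(bases)]
      ref_len <- sum(m[aln$ref_id, span] != "-")
      ctg_len <- length(bases)
      mine <- v$indels[vapply(strsplit(v$indels$carriers, ",", fixed = TRUE),
                              function(cc) cid %in% cc, logical(1)), ]
      net <- sum(mine$length[mine$kind == "insertion"]) -
        sum(mine$length[mine$kind == "deletion"])
      expect_equal(ctg_len - ref_len, net)
    }
  }
})

test_that("polymorphic region set supports containment queries", {
  v <- list(indels = data.frame(aln_start = 10L, aln_end = 99L, length = 90L),
            snps = data.frame(aln_col = 150L))
  regions <- polymorphic_region_set(v)
  expect_true(region_overlaps(regions, 10L))
  expect_true(region_overlaps(regions, 99L))
  expect_false(region_overlaps(regions, 9L))
  expect_false(region_overlaps(regions, 100L))
  expect_true(region_overlaps(regions, 150L))
  # empty set: everything outside
  empty <- polymorphic_region_set(list(indels = data.frame(aln_start = integer(0), aln_end = integer(0)),
                                       snps = data.frame(aln_col = integer(0))))
  expect_false(region_overlaps(empty, 1L))
  # overlapping deletions: membership equals a linear-scan union
  v2 <- list(indels = data.frame(aln_start = c(100L, 180L),
                                 aln_end = c(300L, 420L),
                                 length = c(201L, 241L)),
             snps = data.frame(aln_col = 500L))
  mask <- rep(FALSE, 600); mask[100:300] <- TRUE; mask[180:420] <- TRUE
  mask[500] <- TRUE
  r2 <- polymorphic_region_set(v2)
  expect_equal(region_overlaps(r2, 1:600), mask)
})

test_that("homolog position pairing finds nearest neighbours", {
  p <- compare_homolog_positions(-3572, -3848)
  expect_equal(p$abs_delta, 276)
  same <- compare_homolog_positions(c(-10, 5), c(-10, 5))
  expect_equal(same$delta, c(0, 0))
  expect_equal(nrow(compare_homolog_positions(c(-1), numeric(0))), 0L)
  set.seed(7)
  for (i in 1:10) {
    a <- sample(-5000:5000, sample(1:20, 1L))
    b <- sample(-5000:5000, sample(1:20, 1L))
    got <- compare_homolog_positions(a, b)
    brute <- vapply(a, function(p) min(abs(b - p)), numeric(1))
    expect_equal(got$abs_delta, brute)
  }
})

test_that("VCF/BED export uses standard conventions and round-trips", {
  skip_if_not_installed("vcfR")
  aln <- new_alignment(c(
    ref = "AACCGGTTAACCGG--TT",
    del = "AACC----AACCGG--TT",
    ins = "AACCGGTTAACCGGGGTT"))
  anchor <- make_anchor("g", "chr1", 100L, "forward")
  v <- call_variants(aln, anchor = anchor)
  prefix <- withr::local_tempfile()
  paths <- export_variants(v, aln, anchor, prefix)
  vcf <- suppressWarnings(vcfR::read.vcfR(paths[["vcf"]], verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  # deletion ref 5-8: left-anchored at POS 4, REF length 5, ALT length 1
  drow <- fix[grepl("^DEL", fix$ID), ]
  expect_equal(as.integer(drow$POS), 4L)
  expect_equal(nchar(drow$REF) - nchar(drow$ALT), 4L)
  expect_equal(substr(drow$REF, 1, 1), drow$ALT)
  # insertion of 2 bp at anchor 14: ALT longer than REF by the length
  irow <- fix[grepl("^INS", fix$ID), ]
  expect_equal(as.integer(irow$POS), 14L)
  expect_equal(nchar(irow$ALT) - nchar(irow$REF), 2L)
  # BED is 0-based half-open
  bed <- read.table(paths[["bed"]], sep = "\t")
  drow_bed <- bed[grepl("^DEL", bed$V4), ]
  expect_equal(drow_bed$V2, 4L)  # 1-based start 5 -> 0-based 4
  expect_equal(drow_bed$V3, 8L)
})
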