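#' Configuration for the synthetic diversity panel
#'
#' Defaults encode the study conditions the pipeline is validated under: a
#' 626-line, mostly selfing (rate 0.95, hence rare heterozygotes) diploid
#' panel genotyped at 20 independent markers (independence approximates the
#' very rapid LD decay of white lupin), phenotyped for three ordered
#' phenology traits (days to floral bud emergence BE, start of flowering
#' SF, end of flowering EF) in two seasons with 3-10 biological replicates.
#' Phenotypes are additive marker effects on top of a shared-between-years
#' genetic value drawn from a two-component normal mixture (an early and a
#' late subpopulation), which makes the traits clearly non-normal; the
#' year-specific noise variance is set from the target between-year
#' repeatability (default 0.96).
#'
#' @param n_lines Panel size (default 626).
#' @param n_markers Number of markers (default 20).
#' @param allele_freqs Alternative-allele frequency per marker; default
#'   evenly spaced in [0.05, 0.45].
#' @param selfing_rate Selfing rate s in [0, 1); heterozygote frequency is
#'   2pq(1-s).
#' @param causal_effects Named numeric vector of additive effects (days per
#'   score unit) for causal markers; default one causal marker (\code{M14},
#'   alternative-allele frequency ~0.32) with 8 days per allele, sized to
#'   put its score-phenotype correlation in the 0.3-0.4 range at the
#'   default panel size.
#' @param trait_baselines Named numeric, ordered baselines for BE, SF, EF.
#' @param mixture List with \code{prob_late}, \code{late_shift},
#'   \code{sd_early}, \code{sd_late} describing the early/late genetic
#'   mixture (days).
#' @param year_repeatability Target between-year correlation of line means.
#' @param replicate_range Integer range of biological replicates per
#'   line x trait x year.
#' @param replicate_sd Within-line replicate standard deviation (days).
#' @param years Labels of the two seasons.
#' @return A list of class \code{ft_simconfig}.
#' @export
sim_config <- function(n_lines = 626L,
                       n_markers = 20L,
                       allele_freqs = NULL,
                       selfing_rate = 0.95,
                       causal_effects = c(M14 = 8),
                       trait_baselines = c(BE = 45, SF = 52, EF = 70),
                       mixture = list(prob_late = 0.4, late_shift = 35,
                                      sd_early = 6, sd_late = 10),
                       year_repeatability = 0.96,
                       replicate_range = c(3L, 10L),
                       replicate_sd = 1.5,
                       years = c("2020", "2021")) {
  if (is.null(allele_freqs)) {
    allele_freqs <- seq(0.05, 0.45, length.out = n_markers)
  }
  if (length(allele_freqs) != n_markers) {
    stop("allele_freqs must have one entry per marker")
  }
  if (any(allele_freqs <= 0 | allele_freqs >= 1)) {
    stop("allele frequencies must be in (0, 1)")
  }
  if (selfing_rate < 0 || selfing_rate >= 1) {
    stop("selfing_rate must be in [0, 1)")
  }
  if (replicate_range[1L] < 3L || replicate_range[2L] > 10L ||
      replicate_range[1L] > replicate_range[2L]) {
    stop("replicate_range must lie within [3, 10]")
  }
  if (is.unsorted(trait_baselines)) {
    stop("trait baselines must be ordered BE <= SF <= EF")
  }
  marker_ids <- sprintf("M%02d", seq_len(n_markers))
  names(allele_freqs) <- marker_ids
  if (length(causal_effects) > 0 &&
      !all(names(causal_effects) %in% marker_ids)) {
    stop("causal markers must be a subset of the marker set")
  }
  structure(
    list(n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
         marker_ids = marker_ids, allele_freqs = allele_freqs,
         selfing_rate = selfing_rate, causal_effects = causal_effects,
         trait_baselines = trait_baselines, mixture = mixture,
         year_repeatability = year_repeatability,
         replicate_range = as.integer(replicate_range),
         replicate_sd = replicate_sd, years = years),
    class = "ft_simconfig"
  )
}

#' Default planted-variant plan for a simulated alignment
#'
#' Emulates the structure of a promoter indel catalogue: deletions from 7
#' to ~2400 bp including a partially overlapping pair carried by different
#' contigs and one pair of identical gap runs shared by two contigs,
#' insertions from 8 bp to several kbp, and terminal unaligned contig ends.
#' Positions are deterministic fractions of the reference length.
#'
#' @param ref_length Ungapped reference length (bp).
#' @param contigs Character vector of (at least 3) contig names.
#' @return Data frame with columns \code{kind}
#'   (\code{deletion}/\code{insertion}), \code{ref_pos} (deletion start or
#'   insertion anchor), \code{length}, \code{carriers} (comma-separated).
#' @export
default_variant_plan <- function(ref_length = 12000L,
                                 contigs = c("contig_A", "contig_B", "contig_C")) {
  at <- function(f) as.integer(round(f * ref_length))
  data.frame(
    kind = c("deletion", "deletion", "deletion", "deletion", "deletion",
             "deletion", "deletion",
             "insertion", "insertion", "insertion", "insertion"),
    ref_pos = c(at(0.28), at(0.28) + 1000L, at(0.55), at(0.62), at(0.68),
                at(0.72), at(0.745),
                at(0.35), at(0.50), at(0.77), at(0.82)),
    length = c(2126L, 2388L, 90L, 264L, 75L, 28L, 7L,
               59L, 8L, 24L, 3800L),
    carriers = c(contigs[1L], contigs[2L], contigs[1L], contigs[2L],
                 contigs[3L], paste(contigs[1L], contigs[3L], sep = ","),
                 contigs[2L],
                 contigs[2L], contigs[1L], contigs[3L], contigs[3L]),
    stringsAsFactors = FALSE)
}

#' Simulate a gapped promoter alignment with planted variants
#'
#' Generates a random reference sequence, plants the requested deletions,
#' insertions and SNPs into contig copies, and assembles the gapped
#' multiple sequence alignment, recording the full ground truth. Output is
#' reproducible per seed.
#'
#' @param seed Integer seed.
#' @param ref_length Ungapped reference length (bp).
#' @param contigs Contig names (>= 3 for the default plan).
#' @param variants Planted indel plan (see
#'   \code{\link{default_variant_plan}}); deletions of one contig must not
#'   overlap each other or that contig's unaligned ends.
#' @param n_snps Number of planted SNP loci (default 40), placed outside
#'   all planted deletion intervals.
#' @param terminal_missing Named list contig -> c(left_bp, right_bp) of
#'   unaligned terminal reference spans; default: third contig misses the
#'   first 200 bp, first contig the last 150 bp.
#' @return List with \code{aln} (an \code{ft_alignment}) and \code{truth}
#'   (list of data frames \code{indels} and \code{snps} in reference
#'   coordinates).
#' @export
simulate_alignment <- function(seed = 1L,
                               ref_length = 12000L,
                               contigs = c("contig_A", "contig_B", "contig_C"),
                               variants = default_variant_plan(ref_length, contigs),
                               n_snps = 40L,
                               terminal_missing = NULL) {
  set.seed(seed)
  if (is.null(terminal_missing)) {
    terminal_missing <- stats::setNames(
      list(c(0L, 150L), c(0L, 0L), c(200L, 0L)),
      contigs[c(1L, 2L, 3L)][seq_len(min(3L, length(contigs)))])
  }
  ref_chars <- sample(c("A", "C", "G", "T"), ref_length, replace = TRUE)

  dels <- variants[variants$kind == "deletion", , drop = FALSE]
  inss <- variants[variants$kind == "insertion", , drop = FALSE]
  if (nrow(dels) > 0L &&
      any(dels$ref_pos + dels$length - 1L > ref_length | dels$ref_pos < 2L)) {
    stop("deletion plan exceeds the reference interior")
  }
  if (nrow(inss) > 0L &&
      (anyDuplicated(inss$ref_pos) || any(inss$ref_pos < 1L) ||
       any(inss$ref_pos >= ref_length))) {
    stop("insertion anchors must be unique interior reference positions")
  }
  # per-contig overlap check (retry-free: the plan is explicit)
  for (cid in contigs) {
    mine <- dels[grepl(cid, dels$carriers, fixed = TRUE), , drop = FALSE]
    if (nrow(mine) > 1L) {
      ir <- IRanges::IRanges(mine$ref_pos, mine$ref_pos + mine$length - 1L)
      if (any(IRanges::countOverlaps(ir, ir) > 1L)) {
        stop("planted deletions of contig ", cid, " overlap each other")
      }
    }
    my_ins <- inss[grepl(cid, inss$carriers, fixed = TRUE), , drop = FALSE]
    if (nrow(mine) > 0L && nrow(my_ins) > 0L) {
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(my_ins$ref_pos, width = 1L),
        IRanges::IRanges(mine$ref_pos, mine$ref_pos + mine$length - 1L))
      if (any(hit)) {
        stop("variant placement collision: insertion anchor of contig ", cid,
             " lies inside one of its deletions")
      }
    }
  }

  # SNP positions outside any deletion interval (any carrier)
  blocked <- logical(ref_length)
  if (nrow(dels) > 0L) {
    for (i in seq_len(nrow(dels))) {
      blocked[dels$ref_pos[i]:(dels$ref_pos[i] + dels$length[i] - 1L)] <- TRUE
    }
  }
  blocked[c(1L, ref_length)] <- TRUE
  open_pos <- which(!blocked)
  snp_pos <- sort(sample(open_pos, min(n_snps, length(open_pos))))
  snp_contig <- sample(contigs, length(snp_pos), replace = TRUE)
  snp_alt <- vapply(snp_pos, function(p) {
    sample(setdiff(c("A", "C", "G", "T"), ref_chars[p]), 1L)
  }, character(1))

  ins_seqs <- lapply(inss$length, function(w)
    sample(c("A", "C", "G", "T"), w, replace = TRUE))

  # column layout: reference positions interleaved with insertion blocks
  ins_order <- order(inss$ref_pos)
  blocks <- list()
  prev <- 0L
  for (k in ins_order) {
    a <- inss$ref_pos[k]
    blocks[[length(blocks) + 1L]] <- list(type = "ref", from = prev + 1L, to = a)
    blocks[[length(blocks) + 1L]] <- list(type = "ins", idx = k)
    prev <- a
  }
  blocks[[length(blocks) + 1L]] <- list(type = "ref", from = prev + 1L,
                                        to = ref_length)

  build_row <- function(sid) {
    is_ref <- sid == "REF"
    if (!is_ref) {
      row_chars <- ref_chars
      hit <- snp_contig == sid
      row_chars[snp_pos[hit]] <- snp_alt[hit]
      mine <- dels[vapply(strsplit(dels$carriers, ",", fixed = TRUE),
                          function(cc) sid %in% cc, logical(1)), , drop = FALSE]
      if (nrow(mine) > 0L) {
        for (i in seq_len(nrow(mine))) {
          row_chars[mine$ref_pos[i]:(mine$ref_pos[i] + mine$length[i] - 1L)] <- "-"
        }
      }
      tm <- terminal_missing[[sid]]
      if (!is.null(tm)) {
        if (tm[1L] > 0L) row_chars[seq_len(tm[1L])] <- "-"
        if (tm[2L] > 0L) row_chars[(ref_length - tm[2L] + 1L):ref_length] <- "-"
      }
    } else {
      row_chars <- ref_chars
    }
    pieces <- lapply(blocks, function(b) {
      if (b$type == "ref") {
        if (b$from > b$to) return(character(0))
        row_chars[b$from:b$to]
      } else {
        carriers <- strsplit(inss$carriers[b$idx], ",", fixed = TRUE)[[1L]]
        if (!is_ref && sid %in% carriers) ins_seqs[[b$idx]]
        else rep("-", inss$length[b$idx])
      }
    })
    paste(unlist(pieces), collapse = "")
  }

  seqs <- c(REF = build_row("REF"),
            stats::setNames(vapply(contigs, build_row, character(1)), contigs))
  aln <- new_alignment(seqs, ref_id = "REF")

  truth_indels <- data.frame(
    kind = variants$kind,
    ref_start = ifelse(variants$kind == "deletion", variants$ref_pos,
                       variants$ref_pos),
    ref_end = ifelse(variants$kind == "deletion",
                     variants$ref_pos + variants$length - 1L,
                     variants$ref_pos),
    length = variants$length, carriers = variants$carriers,
    stringsAsFactors = FALSE)
  truth_snps <- data.frame(ref_pos = snp_pos, ref_base = ref_chars[snp_pos],
                           alt_base = snp_alt, carrier = snp_contig,
                           stringsAsFactors = FALSE)
  list(aln = aln,
       truth = list(indels = truth_indels, snps = truth_snps,
                    terminal_missing = terminal_missing, seed = seed))
}

#' Simulate a genotyped and phenotyped diversity panel
#'
#' Draws diploid 0/1/2 genotypes per marker under partial selfing
#' (genotype frequencies p^2 + pqs, 2pq(1-s), q^2 + pqs), builds per-line
#' shared genetic values from the early/late mixture plus additive marker
#' effects, adds year-specific deviations scaled to the target between-year
#' repeatability, enforces the BE < SF < EF trait order per line, and draws
#' 3-10 replicates around each line x trait x year mean.
#'
#' @param config An \code{ft_simconfig} from \code{\link{sim_config}}.
#' @param seed Integer seed.
#' @return List with \code{geno} (matrix, lines x markers), \code{pheno}
#'   (data frame: line_id, trait, year, replicate, days) and \code{truth}
#'   (causal effects, allele frequencies, per-line genetic values, seed).
#' @export
simulate_panel <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "ft_simconfig"))
  set.seed(seed)
  n <- config$n_lines
  line_ids <- sprintf("L%04d", seq_len(n))
  s <- config$selfing_rate

  geno <- vapply(config$allele_freqs, function(q) {
    p <- 1 - q
    probs <- c(p^2 + p * q * s, 2 * p * q * (1 - s), q^2 + p * q * s)
    sample(0:2, n, replace = TRUE, prob = probs)
  }, integer(n))
  rownames(geno) <- line_ids
  colnames(geno) <- config$marker_ids

  mix <- config$mixture
  late <- stats::runif(n) < mix$prob_late
  g_mix <- ifelse(late,
                  stats::rnorm(n, mix$late_shift, mix$sd_late),
                  stats::rnorm(n, 0, mix$sd_early))
  marker_part <- rep(0, n)
  for (mk in names(config$causal_effects)) {
    marker_part <- marker_part + config$causal_effects[[mk]] * geno[, mk]
  }
  shared <- g_mix + marker_part
  r <- config$year_repeatability

  # Calibrate the year-specific noise scale against the *rank* correlation
  # of line means, the repeatability statistic used downstream: with a
  # bimodal genetic distribution the rank correlation reacts to noise more
  # strongly inside the dense early cluster than a variance ratio predicts,
  # so the scale is solved numerically on the realised genetic values.
  rep_lo <- config$replicate_range[1L]
  rep_hi <- config$replicate_range[2L]
  e_raw <- matrix(stats::rnorm(2L * n), ncol = 2L)
  z_rep <- matrix(stats::rnorm(2L * n), ncol = 2L) *
    config$replicate_sd / sqrt(mean(rep_lo:rep_hi))
  rank_cor_at <- function(sigma) {
    stats::cor(shared + sigma * e_raw[, 1L] + z_rep[, 1L],
               shared + sigma * e_raw[, 2L] + z_rep[, 2L],
               method = "spearman")
  }
  sigma_year <- if (rank_cor_at(0) <= r) 0 else
    stats::uniroot(function(s) rank_cor_at(s) - r,
                   lower = 0, upper = 2 * stats::sd(shared))$root

  # strictly positive inter-trait gaps keep BE < SF < EF within every line
  gap_sf <- 6 + abs(stats::rnorm(n, 0, 2))
  gap_ef <- 14 + abs(stats::rnorm(n, 0, 3))

  rows <- vector("list", 0L)
  for (yi in seq_along(config$years)) {
    yr <- config$years[yi]
    e_year <- sigma_year * e_raw[, min(yi, 2L)]
    be <- config$trait_baselines[["BE"]] + shared + e_year
    line_means <- cbind(BE = be, SF = be + gap_sf, EF = be + gap_sf + gap_ef)
    for (tr in colnames(line_means)) {
      n_rep <- sample(rep_lo:rep_hi, n, replace = TRUE)
      idx <- rep(seq_len(n), n_rep)
      rows[[length(rows) + 1L]] <- data.frame(
        line_id = line_ids[idx],
        trait = tr, year = yr,
        replicate = unlist(lapply(n_rep, seq_len)),
        days = line_means[idx, tr] +
          stats::rnorm(length(idx), 0, config$replicate_sd),
        stringsAsFactors = FALSE)
    }
  }
  pheno <- do.call(rbind, rows)
  rownames(pheno) <- NULL

  list(geno = geno, pheno = pheno,
       truth = list(causal_effects = config$causal_effects,
                    allele_freqs = config$allele_freqs,
                    genetic_values = stats::setNames(shared, line_ids),
                    sigma_year = sigma_year, seed = seed))
}
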