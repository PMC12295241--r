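#' Run configuration for the full pipeline
#'
#' Collects input paths and the analysis thresholds. Every threshold
#' carries the value used throughout the workflow as its default: MAF
#' screening at 1.5 percent, motif similarity 0.85, significance level
#' 0.05, gel resolvability 0.02.
#'
#' @param alignment,anchors,markers,genotypes,phenotypes,motifs,flowering_tfs
#'   Input file paths; any of them \code{NULL} to use the simulated stage
#'   instead (see \code{\link{run_all}}).
#' @param maf_min MAF screening threshold (percent).
#' @param similarity Motif similarity threshold.
#' @param alpha Significance level on adjusted p-values.
#' @param resolvability Gel resolvability.
#' @param family Bonferroni family policy, \code{"all"} or
#'   \code{"per_gene"}.
#' @param seed Integer seed for the simulated stages.
#' @return A list of class \code{ft_runconfig}.
#' @export
run_config <- function(alignment = NULL, anchors = NULL, markers = NULL,
                       genotypes = NULL, phenotypes = NULL, motifs = NULL,
                       flowering_tfs = NULL,
                       maf_min = 1.5, similarity = 0.85, alpha = 0.05,
                       resolvability = 0.02, family = "all", seed = 1L) {
  stopifnot(maf_min >= 0, similarity > 0, similarity <= 1,
            alpha > 0, alpha < 1, resolvability > 0, resolvability < 1)
  structure(
    list(alignment = alignment, anchors = anchors, markers = markers,
         genotypes = genotypes, phenotypes = phenotypes, motifs = motifs,
         flowering_tfs = flowering_tfs, maf_min = maf_min,
         similarity = similarity, alpha = alpha,
         resolvability = resolvability, family = family,
         seed = as.integer(seed)),
    class = "ft_runconfig"
  )
}

#' Run the complete analysis pipeline
#'
#' Orchestrates every stage: variant calling from the alignment, marker
#' genotyping and MAF screening, marker-trait association, and the
#' binding-site exclusivity scan. Stages whose inputs are not configured
#' run on the synthetic panel (alignment and diversity panel simulated
#' under \code{config$seed}), so the whole pipeline is exercisable without
#' external data. All outputs are TSV/VCF/BED/JSON under \code{out_dir},
#' plus a machine-readable manifest with input/output MD5 hashes, the seed
#' and every threshold; a rerun with the same configuration is
#' byte-identical.
#'
#' @param config An \code{ft_runconfig}.
#' @param out_dir Output directory (created if missing).
#' @return Invisible list with the stage results (\code{variants},
#'   \code{markers}, \code{calls}, \code{summaries}, \code{associations},
#'   \code{tfbs_sites}, \code{tfbs_verdicts}, \code{manifest}) and the
#'   written \code{paths}.
#' @export
run_all <- function(config = run_config(), out_dir = "ft_run") {
  stopifnot(inherits(config, "ft_runconfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- alignment + anchor -------------------------------------------------
  sim_truth <- NULL
  if (is.null(config$alignment)) {
    sim <- stage("alignment", simulate_alignment(seed = config$seed))
    aln <- sim$aln
    sim_truth <- sim$truth
    anchor <- make_anchor("SIMFT1", "chrSim", tss_genomic = 11000L,
                          strand = "forward")
  } else {
    aln <- stage("alignment", read_alignment(config$alignment))
    anchors <- stage("alignment", read_anchors(config$anchors))
    anchor <- anchors[[1L]]
  }

  # --- variant calling ----------------------------------------------------
  variants <- stage("variants", call_variants(aln, anchor = anchor))
  var_paths <- stage("variants", export_variants(
    variants, aln, anchor, file.path(out_dir, "variants")))

  # --- marker genotyping --------------------------------------------------
  markers <- stage("genotype", {
    if (is.null(config$markers)) {
      markers_from_variants(variants, gene_id = anchor$gene_id)
    } else {
      read_markers(config$markers)
    }
  })
  if (is.null(config$genotypes)) {
    n_mk <- max(2L, length(markers))
    panel_sim <- stage("genotype", simulate_panel(
      sim_config(n_markers = n_mk,
                 causal_effects = stats::setNames(
                   8, sprintf("M%02d", max(2L, round(0.7 * n_mk))))),
      seed = config$seed))
    geno <- panel_sim$geno[, seq_len(min(ncol(panel_sim$geno),
                                         length(markers))), drop = FALSE]
    colnames(geno) <- vapply(markers, `[[`, "",
                             "marker_id")[seq_len(ncol(geno))]
    pheno <- panel_sim$pheno
  } else {
    geno <- as.matrix(utils::read.delim(config$genotypes, row.names = 1L,
                                        check.names = FALSE))
    pheno <- NULL
  }
  calls_path <- file.path(out_dir, "calls.tsv")
  utils::write.table(cbind(line_id = rownames(geno), as.data.frame(geno)),
                     calls_path, sep = "\t", quote = FALSE, row.names = FALSE)

  summaries <- stage("maf", marker_summary(geno))
  summaries$retained <- summaries$marker_id %in%
    filter_markers(summaries, maf_min = config$maf_min)$marker_id
  summary_path <- file.path(out_dir, "marker_summary.tsv")
  utils::write.table(summaries, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- association --------------------------------------------------------
  if (is.null(pheno) && !is.null(config$phenotypes)) {
    pheno <- utils::read.delim(config$phenotypes, stringsAsFactors = FALSE)
  }
  if (is.null(pheno)) {
    stop("stage 'association' failed: no phenotype table available")
  }
  panel <- stage("association", trait_panel(pheno))
  retained <- summaries$marker_id[summaries$retained]
  assoc <- stage("association", association_scan(
    geno[, retained, drop = FALSE], panel,
    family = config$family, alpha = config$alpha,
    gene_map = stats::setNames(
      vapply(markers[retained], `[[`, "", "gene_id"), retained)))
  assoc_path <- file.path(out_dir, "associations.tsv")
  utils::write.table(assoc, assoc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  year1 <- sort(unique(panel$year))[1L]
  fig_tab <- allele_phenotype_table(geno, panel, trait = "BE", year = year1)
  fig_path <- file.path(out_dir, "allele_by_phenotype.tsv")
  utils::write.table(fig_tab, fig_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- TFBS scan ----------------------------------------------------------
  motifs <- stage("tfbs", {
    path <- if (is.null(config$motifs)) {
      system.file("extdata", "motifs_synthetic.tsv", package = "ftindelscan",
                  mustWork = TRUE)
    } else {
      config$motifs
    }
    mods <- read_motifs(path)
    lapply(mods, function(mo) { mo$threshold <- max(mo$threshold,
                                                    config$similarity); mo })
  })
  flowering <- stage("tfbs", {
    path <- if (is.null(config$flowering_tfs)) {
      system.file("extdata", "flowering_tfs.tsv", package = "ftindelscan",
                  mustWork = TRUE)
    } else {
      config$flowering_tfs
    }
    utils::read.delim(path, stringsAsFactors = FALSE)$tf_id
  })
  cmap <- build_coord_map(aln)
  tss_col <- if (anchor$strand == "forward") {
    # promoter scope: columns up to (and excluding) the TSS column
    cmap$ref_to_col[min(anchor$tss_genomic, length(cmap$ref_to_col))]
  } else {
    aln$length
  }
  sites <- stage("tfbs", scan_motifs(aln, motifs))
  classified <- stage("tfbs", classify_sites(sites, variants))
  verdicts <- stage("tfbs", exclusive_tfs(classified,
                                          scope = c(1L, tss_col - 1L)))
  report <- stage("tfbs", per_indel_report(classified, verdicts, flowering))
  sites_path <- file.path(out_dir, "tfbs_sites.tsv")
  verdict_path <- file.path(out_dir, "tfbs_verdicts.tsv")
  report_path <- file.path(out_dir, "tfbs_report.tsv")
  utils::write.table(classified, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(verdicts, verdict_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- manifest -----------------------------------------------------------
  paths <- c(var_paths, calls = calls_path, summary = summary_path,
             associations = assoc_path, allele_by_phenotype = fig_path,
             tfbs_sites = sites_path, tfbs_verdicts = verdict_path,
             tfbs_report = report_path)
  manifest <- list(
    seed = config$seed,
    thresholds = list(maf_min = config$maf_min,
                      similarity = config$similarity,
                      alpha = config$alpha,
                      resolvability = config$resolvability,
                      family = config$family),
    outputs = as.list(tools::md5sum(unname(paths))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths <- c(paths, manifest = manifest_path)

  invisible(list(variants = variants, markers = markers, calls = geno,
                 summaries = summaries, associations = assoc,
                 tfbs_sites = classified, tfbs_verdicts = verdicts,
                 tfbs_report = report, manifest = manifest, paths = paths,
                 sim_truth = sim_truth))
}
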