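#' Default run configuration
#'
#' Encodes the pipeline's standard settings: 200 bp bins, segmentation
#' penalty lambda = 2, call filters p < 0.001 / length > 1 kb / q0 < 0.5,
#' CNVR carrier minimum 4, selection quantile 0.99 (top 1%), admixture
#' K range 2..4 at desk scale.
#'
#' @param seed Run seed.
#' @param out_dir Output directory.
#' @param sim Overrides for the [sim_config()] fields, as a list.
#' @param ... Scalar overrides of top-level parameters (lambda,
#'   min_carriers, quantile, k_range, flank).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("cnvpop_run_"),
                       sim = list(), ...) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              lambda = 2, max_p = 0.001, min_len = 1000, max_q0 = 0.5,
              min_carriers = 4L, quantile = 0.99, k_range = 2:4,
              flank = 1000, sim = sim,
              stages = c("simulate", "call", "merge", "annotate",
                         "structure", "fst", "enrich"))
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with `run_config` fields.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage_checksums <- function(dir) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  md5 <- tools::md5sum(files)
  names(md5) <- substring(files, nchar(dir) + 2L)
  md5
}

#' Run the full CNV population-genomics pipeline
#'
#' simulate -> call -> merge -> annotate -> structure -> fst -> enrich, in
#' dependency order, writing each stage's artifacts under `out_dir` and
#' returning a manifest of record counts, per-file checksums, seed and
#' timestamps. A stage failure stops the run with the stage named;
#' downstream outputs are not written.
#'
#' @param cfg A `run_config` (see [run_config()]).
#' @param tracks Optional externally supplied depth tracks (skips the
#'   caller's simulated input); a named list of `depth_track` objects.
#' @param calls Optional externally supplied call data.frame, which
#'   disables the simulate/call stages for calling purposes.
#' @return A `run_manifest` list (invisibly also written as JSON).
#' @export
run_pipeline <- function(cfg = run_config(), tracks = NULL, calls = NULL) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, started = format(Sys.time()),
                   stages = list())
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- res
    res
  }

  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  layout <- sim_layout(scfg)
  cohort <- run_stage("simulate", function() {
    co <- simulate_cohort(scfg, depth = is.null(tracks) && is.null(calls))
    write_gff3(co$genes, file.path(cfg$out_dir, "genes.gff3"))
    write_gmt(co$gene_sets, file.path(cfg$out_dir, "gene_sets.gmt"))
    write_labels(co$truth$breed_labels, file.path(cfg$out_dir, "labels.tsv"))
    utils::write.table(co$truth$locus_table,
                       file.path(cfg$out_dir, "truth_loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(cohort = co, n_loci = nrow(co$truth$locus_table))
  })$cohort
  if (is.null(tracks)) tracks <- cohort$tracks

  if (is.null(calls)) {
    calls <- run_stage("call", function() {
      all <- do.call(rbind, lapply(tracks, call_sample, layout = layout,
                                   lambda = cfg$lambda, max_p = cfg$max_p,
                                   min_len = cfg$min_len,
                                   max_q0 = cfg$max_q0))
      rownames(all) <- NULL
      write_calls_vcf(all, file.path(cfg$out_dir, "calls.vcf"), layout)
      list(calls = all, n_calls = nrow(all))
    })$calls
  }

  labels <- cohort$truth$breed_labels
  geno <- run_stage("merge", function() {
    cnvrs <- merge_cnvrs(calls, labels, min_carriers = cfg$min_carriers)
    merged <- merge_across_breeds(cnvrs)
    g <- genotype_cnvrs(merged, calls, samples = names(labels),
                        breed_labels = labels)
    write_cnvr_bed(merged, file.path(cfg$out_dir, "cnvr.bed"))
    write_cnvr_vcf(g, file.path(cfg$out_dir, "cnvr.vcf"), layout)
    summ <- summarize_cnvrs(calls, merged, layout)
    jsonlite::write_json(
      list(n_calls = summ$n_calls, n_cnvrs = summ$n_cnvrs,
           deletion_seq_proportion = summ$deletion_seq_proportion,
           genome_coverage = summ$genome_coverage),
      file.path(cfg$out_dir, "summary.json"), auto_unbox = TRUE)
    list(geno = g, n_cnvrs = nrow(merged))
  })$geno

  anno <- run_stage("annotate", function() {
    a <- annotate_cnvrs(geno$cnvrs, cohort$genes, flank = cfg$flank)
    utils::write.table(
      a[c("id", "chrom", "start", "end", "type", "carrier_count",
          "region_class", "genes", "exonic_subtype")],
      file.path(cfg$out_dir, "cnvr_annotated.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(anno = a, n_exonic = sum(a$region_class == "exonic"))
  })$anno

  struct <- run_stage("structure", function() {
    mat <- recode_biallelic(geno)
    out <- list(n_loci = ncol(mat$G))
    if (sum(!mat$info$monomorphic) >= 1 && nrow(mat$G) >= 3) {
      pca <- cnv_pca(mat)
      utils::write.table(pca$coords, file.path(cfg$out_dir, "pca_vectors.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      utils::write.table(
        data.frame(eigenvalue = pca$eigenvalues,
                   pct_variance = pca$pct_variance),
        file.path(cfg$out_dir, "pca_values.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      out$pc1_pct <- pca$pct_variance[1]
      if (length(unique(labels)) >= 3) {
        D <- distance_matrix(mat, "fst_population")
        tree <- nj_tree(D)
        write_newick(tree, file.path(cfg$out_dir, "nj_breeds.nwk"))
      }
      for (K in cfg$k_range) {
        if (K > nrow(mat$G)) next
        fit <- admixture_em(mat, K, seed = cfg$seed)
        utils::write.table(fit$Q, file.path(cfg$out_dir,
                                            sprintf("admixture.%d.Q", K)),
                           sep = " ", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
        utils::write.table(t(fit$Fq), file.path(cfg$out_dir,
                                                sprintf("admixture.%d.P", K)),
                           sep = " ", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
    }
    out$mat <- mat
    out
  })$mat

  sel <- run_stage("fst", function() {
    breeds <- sort(unique(labels))
    group_map <- stats::setNames(
      c(breeds[1], rep("others", length(breeds) - 1)), breeds)
    if (length(breeds) < 2) return(list(skipped = "single breed"))
    res <- fst_scan(geno, group_map, quantile = cfg$quantile)
    utils::write.table(
      cbind(res$table, threshold = res$threshold),
      file.path(cfg$out_dir, "fst.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(sel = res, threshold = res$threshold,
         weighted_fst = res$weighted_fst)
  })$sel

  run_stage("enrich", function() {
    if (is.null(sel)) return(list(skipped = "no selection scan"))
    cand <- candidate_genes(sel, anno, sel$mat)
    writeLines(cand, file.path(cfg$out_dir, "candidates.txt"))
    if (length(cand)) {
      er <- enrich_test(cand, cohort$gene_sets)
      utils::write.table(er, file.path(cfg$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(n_candidates = length(cand), top_term = er$Term[1])
    } else list(n_candidates = 0L)
  })

  manifest$finished <- format(Sys.time())
  manifest$checksums <- stage_checksums(cfg$out_dir)
  manifest$stages <- lapply(manifest$stages, function(s)
    s[setdiff(names(s), c("cohort", "calls", "geno", "anno", "mat", "sel"))])
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
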