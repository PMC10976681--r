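write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pipe_log <- function(..., verbose = TRUE) {
  if (verbose) message("[scmetaz] ", ...)
}

# evaluate a stage body, rewrapping any error with the stage name;
# expr is a promise evaluated in the caller's frame, so assignments in
# the block land in run_pipeline's environment
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes qc -> annotation -> composition -> differential expression ->
#' DEG modules -> TMZ scoring/subtyping -> GWAS enrichment on the inputs
#' named by the config, skipping stages whose inputs are absent. When
#' `config$simulate` is set, the cohort (plus a matched reference panel
#' and gene risk table) is generated by the bundled simulator instead of
#' being read from disk. Each stage derives its own sub-seed from
#' `config$seed`. Every output artifact is written under `out`, and a
#' manifest of file MD5 hashes makes reruns comparable bit-for-bit.
#'
#' @param config a [pipeline_config()].
#' @param out output directory.
#' @param verbose log stage progress.
#' @return (invisibly) a list of in-memory stage results, including
#'   `manifest`.
#' @export
run_pipeline <- function(config, out, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  ## ---- input ----------------------------------------------------------
  truth <- NULL; panel <- NULL; risk <- NULL
  if (!is.null(config$simulate)) {
    run_stage("simulate", {
      sc <- do.call(sim_config, c(config$simulate,
                                  list(seed = stage_seed(config$seed, "simulate"))))
      pipe_log("simulating cohort: ", sc$n_case, " cases + ", sc$n_control,
               " controls, seed ", sc$seed, verbose = verbose)
      g <- generate_cohort(sc)
      cm <- g$cm
      truth <- g$truth
      panel <- generate_reference_panel(truth,
                                        seed = stage_seed(config$seed, "panel"))
      risk <- generate_gene_risk_scores(truth,
                                        seed = stage_seed(config$seed, "risk"))
      write_counts(cm, file.path(out, "counts"))
      res$truth <- truth
    })
  } else if (!is.null(config$counts_dir)) {
    run_stage("read", {
      cm <- read_counts(config$counts_dir)
      if (!is.null(config$panel_path)) panel <- read_panel(config$panel_path)
      if (!is.null(config$risk_path)) risk <- utils::read.delim(config$risk_path)
    })
  } else stop("config names neither counts_dir nor simulate")

  ## ---- qc --------------------------------------------------------------
  run_stage("qc", {
    cm <- filter_genes_by_prevalence(cm, config$min_frac_genes)
    cm <- filter_cells(cm, mito_max = config$mito_max,
                       windows = nodg_windows(config$nodg_windows,
                                              config$nodg_default))
    write_tsv(attr(cm, "qc_report"), file.path(out, "qc_report.tsv"))
    res$sex_report <- tryCatch(sex_concordance(cm), error = function(e) NULL)
    if (!is.null(res$sex_report))
      write_tsv(res$sex_report, file.path(out, "sex_concordance.tsv"))
  })
  pipe_log("qc done: ", nrow(cm$counts), " genes x ", ncol(cm$counts),
           " cells", verbose = verbose)

  ## ---- annotation -------------------------------------------------------
  labels <- NULL
  if (!is.null(panel)) {
    run_stage("project", {
      labels <- multiresolution_annotate(cm, panel_hierarchy(panel))
      write_tsv(data.frame(barcode = names(labels), cell_type = labels),
                file.path(out, "cell_types.tsv"))
    })
    pipe_log("annotated ", sum(labels != "ambiguous"), "/", length(labels),
             " cells", verbose = verbose)
  } else if ("true_type" %in% names(cm$cells)) {
    labels <- stats::setNames(cm$cells$true_type, cm$cells$barcode)
    pipe_log("no panel: using provided type labels", verbose = verbose)
  } else {
    pipe_log("no panel and no labels: downstream stages skipped",
             verbose = verbose)
  }
  if (is.null(labels)) {
    res$manifest <- make_manifest(out)
    write_tsv(res$manifest, file.path(out, "manifest.tsv"))
    return(invisible(res))
  }

  ## ---- composition ------------------------------------------------------
  run_stage("composition", {
    covars <- unique(cm$cells[, intersect(c("sample", "disease", "sex",
                                            "gada", "hla_risk"),
                                          names(cm$cells)), drop = FALSE])
    tbl <- compute_proportions(labels, cm$cells$sample, covariates = covars)
    res$composition <- tbl
    write_tsv(data.frame(sample = rownames(tbl), tbl, check.names = FALSE),
              file.path(out, "composition.tsv"))
    cv <- attr(tbl, "covariates")
    cvn <- intersect(c("disease", "sex", "hla_risk"), names(cv))
    if ("disease" %in% cvn && length(unique(cv$disease)) > 1) {
      res$composition_regression <- composition_regression(tbl, cvn)
      write_tsv(res$composition_regression,
                file.path(out, "composition_regression.tsv"))
    }
    if ("disease" %in% names(cm$cells)) {
      emb <- pca_embed(normalize_cells(cm), d = config$pca_d)
      e <- neighborhood_enrichment(emb, cm$cells$disease == 1,
                                   k = min(config$knn_k, nrow(emb) - 1))
      res$knn_enrichment <- e
      write_tsv(data.frame(barcode = names(e), log2_enrichment = e),
                file.path(out, "knn_enrichment.tsv"))
    }
  })
  pipe_log("composition done", verbose = verbose)

  ## ---- differential expression -----------------------------------------
  degs <- NULL
  if ("disease" %in% names(cm$cells)) {
    run_stage("de", {
      pb <- make_pseudobulk(cm, labels, min_cells = config$min_cells,
                            min_sample_frac = config$min_sample_frac,
                            merge_map = config$merge_map)
      degs <- call_degs(de_all_types(pb), lfc_min = config$lfc_min,
                        q_max = config$q_max, quiet = !verbose)
      res$pb <- pb
      res$degs <- degs
      write_tsv(as.data.frame(degs), file.path(out, "deg_table.tsv"))
      write_deg_sets(attr(degs, "deg_sets"), file.path(out, "deg_sets.json"))
    })
    pipe_log("de done: ",
             sum(degs$direction %in% c("up", "down"), na.rm = TRUE),
             " DEG calls", verbose = verbose)
  }

  if (!is.null(degs)) {
    ## ---- DEG modules ---------------------------------------------------
    run_stage("enrich", {
      deg_genes <- unique(degs$gene[!is.na(degs$direction) &
                                      degs$direction != "none"])
      if (length(deg_genes) > config$kmeans_modules_k + 1) {
        tys <- unique(degs$cell_type)
        lfc <- matrix(NA_real_, length(deg_genes), length(tys),
                      dimnames = list(deg_genes, tys))
        hit <- degs$gene %in% deg_genes & is.finite(degs$lfc)
        lfc[cbind(match(degs$gene[hit], deg_genes),
                  match(degs$cell_type[hit], tys))] <- degs$lfc[hit]
        res$deg_modules <- kmeans_deg_modules(
          lfc, k = config$kmeans_modules_k, restarts = config$kmeans_restarts,
          seed = stage_seed(config$seed, "enrich"))
        write_tsv(data.frame(gene = names(res$deg_modules$modules),
                             module = res$deg_modules$modules),
                  file.path(out, "deg_modules.tsv"))
      }
    })

    ## ---- TMZ ------------------------------------------------------------
    run_stage("tmz", {
      tm <- compute_tmz(res$pb, attr(degs, "deg_sets"))
      sub <- subtype_samples(tm, k = config$subtype_k,
                             restarts = config$kmeans_restarts,
                             seed = stage_seed(config$seed, "tmz"))
      res$tmz <- tm
      res$subtypes <- sub
      write_tsv(data.frame(sample = rownames(tm), unclass(tm),
                           average = attr(tm, "average"),
                           subtype = as.character(sub[rownames(tm)]),
                           check.names = FALSE),
                file.path(out, "tmz.tsv"))
      cv <- res$pb$samples
      if (all(c("sex", "gada", "hla_risk", "disease") %in% names(cv))) {
        res$tmz_association <- suppressWarnings(
          tmz_association(tm, cv[, c("sample", "sex", "gada", "hla_risk")],
                          samples = cv$sample[cv$disease == 1]))
        write_tsv(res$tmz_association$regression,
                  file.path(out, "tmz_regression.tsv"))
      }
    })
    pipe_log("tmz done", verbose = verbose)

    ## ---- GWAS -----------------------------------------------------------
    if (!is.null(risk)) {
      run_stage("gwas", {
        nd <- prepare_des(degs, q_keep = config$q_keep)
        if (length(nd)) {
          enr <- tryCatch(
            heritability_covariate_test(nd, risk,
                                        min_genes = config$gwas_min_genes),
            error = function(e) NULL)
          enr_nohla <- tryCatch(
            heritability_covariate_test(nd, risk,
                                        exclude_region = config$exclude_region,
                                        min_genes = config$gwas_min_genes),
            error = function(e) NULL)
          eff <- select_effector_genes(nd, risk, top_n = config$top_n_risk,
                                       des_percentile = config$des_percentile)
          res$gwas <- list(genome_wide = enr, non_hla = enr_nohla,
                           effectors = eff)
          if (!is.null(enr))
            write_tsv(enr, file.path(out, "gwas_enrichment.tsv"))
          if (!is.null(enr_nohla))
            write_tsv(enr_nohla, file.path(out, "gwas_enrichment_nonhla.tsv"))
          jsonlite::write_json(eff, file.path(out, "effector_genes.json"),
                               pretty = TRUE)
        }
      })
      pipe_log("gwas done", verbose = verbose)
    } else {
      pipe_log("no risk table: gwas stage skipped", verbose = verbose)
    }
  }

  res$manifest <- make_manifest(out)
  write_tsv(res$manifest, file.path(out, "manifest.tsv"))
  invisible(res)
}

# manifest of output files with MD5 hashes
make_manifest <- function(out) {
  files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.tsv"))
  data.frame(file = files,
             md5 = unname(tools::md5sum(file.path(out, files))),
             stringsAsFactors = FALSE)
}
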