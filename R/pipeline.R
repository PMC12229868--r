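#' Pipeline configuration
#'
#' Bundles all inputs and tuning knobs of the end-to-end analysis. Input
#' paths are checked at run time, before any computation.
#'
#' @param npx_csv long-format NPX CSV (see [read_npx_long()]).
#' @param samples_csv sample metadata CSV.
#' @param gmt GMT pathway annotation file.
#' @param out_dir output directory (created if needed).
#' @param function_annotation optional two-column CSV (protein, function)
#'   used as a node attribute in exported networks.
#' @param max_below_lod,linearity_threshold QC thresholds, see [qc_npx()].
#' @param pooling_mode,fc_magnitude differential-abundance options.
#' @param coexpression_rule an [edge_rule()].
#' @param min_abs_diff slope-difference threshold for enrichment input.
#' @param n_jgl_proteins size of the protein subset passed to the joint
#'   graphical lasso (chosen as the proteins whose correlation profiles
#'   differ most between groups); `NULL` uses all proteins.
#' @param lambda1_grid,lambda2_grid JGL tuning grids.
#' @param jgl a [jgl_config()].
#' @param min_m minimum pathway background size for enrichment.
#' @param seed integer seed recorded in the manifest and used for any
#'   stochastic step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(npx_csv, samples_csv, gmt, out_dir,
                            function_annotation = NULL,
                            max_below_lod = 2, linearity_threshold = 1,
                            pooling_mode = "fixed_interaction",
                            fc_magnitude = 1.5,
                            coexpression_rule = edge_rule(),
                            min_abs_diff = 1,
                            n_jgl_proteins = 50,
                            lambda1_grid = c(2, 5, 10),
                            lambda2_grid = c(0.5, 2),
                            jgl = jgl_config(tol_primal = 1e-6,
                                             tol_dual = 1e-6,
                                             max_iter = 2000),
                            min_m = 5,
                            seed = 1) {
  stopifnot(max_below_lod >= 0, linearity_threshold > 0, fc_magnitude >= 1)
  structure(list(
    npx_csv = npx_csv, samples_csv = samples_csv, gmt = gmt,
    out_dir = out_dir, function_annotation = function_annotation,
    max_below_lod = max_below_lod,
    linearity_threshold = linearity_threshold,
    pooling_mode = pooling_mode, fc_magnitude = fc_magnitude,
    coexpression_rule = coexpression_rule, min_abs_diff = min_abs_diff,
    n_jgl_proteins = n_jgl_proteins,
    lambda1_grid = lambda1_grid, lambda2_grid = lambda2_grid,
    jgl = jgl, min_m = min_m, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' @param path YAML (requires the yaml package) or JSON file whose keys are
#'   the arguments of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  vals <- if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, vals)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' @param sim result of [simulate_npx_dataset()].
#' @param dir target directory.
#' @param gmt optional pathway annotation tibble to write alongside.
#' @return named list of file paths.
#' @export
write_simulation <- function(sim, dir, gmt = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    npx_csv = file.path(dir, "npx.csv"),
    samples_csv = file.path(dir, "samples.csv"),
    truth_json = file.path(dir, "truth.json")
  )
  readr::write_csv(sim$npx, paths$npx_csv, progress = FALSE)
  readr::write_csv(sim$samples, paths$samples_csv, progress = FALSE)
  jsonlite::write_json(sim$truth, paths$truth_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(gmt)) {
    paths$gmt <- file.path(dir, "pathways.gmt")
    lines <- vapply(seq_len(nrow(gmt)), function(i) {
      paste(c(gmt$pathway[i], gmt$top_name[i], gmt$members[[i]]),
            collapse = "\t")
    }, "")
    writeLines(lines, paths$gmt)
  }
  paths
}

# rank proteins by how much their correlation profile differs between groups
jgl_protein_subset <- function(Zs, group, n_keep) {
  if (is.null(n_keep) || n_keep >= ncol(Zs)) return(colnames(Zs))
  case <- coerce_case(group)
  corr <- function(M) {
    C <- pairwise_covariance(M, psd_repair = FALSE)
    d <- sqrt(pmax(diag(C), 1e-12))
    C / outer(d, d)
  }
  dif <- abs(corr(Zs[!case, , drop = FALSE]) - corr(Zs[case, , drop = FALSE]))
  diag(dif) <- 0
  score <- rowMeans(dif, na.rm = TRUE)
  names(sort(score, decreasing = TRUE))[seq_len(n_keep)] |> sort()
}

#' PCA overview of the filtered expression matrix
#'
#' Principal components of the column-centered samples-by-proteins matrix
#' (singular value decomposition). Missing cells are mean-imputed per
#' protein for this overview only — inferential stages keep their own
#' missing-data handling.
#'
#' @param mat samples x proteins matrix (LOD-filtered).
#' @param group per-sample group labels.
#' @return object of class `npx_pca`: `scores` (tibble sample_id, group,
#'   PC1, PC2), `var_explained` (fractions, all components), `loadings`.
#' @export
pca_overview <- function(mat, group) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop("PCA overview needs at least 3 samples")
  for (j in seq_len(ncol(mat))) {
    mj <- is.na(mat[, j])
    if (any(mj)) mat[mj, j] <- mean(mat[, j], na.rm = TRUE)
  }
  if (all(apply(mat, 2, sd) == 0)) stop("zero-variance matrix")
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = tibble::tibble(
      sample_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
      group = as.character(group),
      PC1 = pc$x[, 1],
      PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0
    ),
    var_explained = ve,
    loadings = pc$rotation
  ), class = "npx_pca")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

edges_to_graphml <- function(edges, path, functions = NULL) {
  if (!nrow(edges)) {
    g <- igraph::make_empty_graph(directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("protein_a", "protein_b", setdiff(names(edges),
                                                  c("protein_a", "protein_b")))],
      directed = FALSE)
    if (!is.null(functions)) {
      fn <- setNames(functions[[2]], functions[[1]])
      igraph::V(g)$molecular_function <-
        unname(fn[igraph::V(g)$name]) %||% NA_character_
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: read and validate inputs, dilution selection,
#' dilution-linearity QC, below-LOD filtering, standardization, the
#' hierarchical differential-abundance model, fold-change classification,
#' all-pairs differential co-expression, enrichment-input and network-edge
#' selection, fused joint graphical lasso with AIC/BIC tuning and
#' group-distinct clusters, the three pathway enrichment analyses, and a
#' PCA overview. All tabular outputs are written as TSV/CSV/JSON/GraphML
#' under `config$out_dir`; identical config and seed give byte-identical
#' outputs. Any stage error aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list, class `npx_manifest`), invisibly
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "preflight"
  result <- tryCatch({
    for (p in c(config$npx_csv, config$samples_csv, config$gmt,
                config$function_annotation)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)
    manifest <- list(
      package = "npxnet",
      version = as.character(utils::packageVersion("npxnet")),
      seed = config$seed,
      config = config[c("npx_csv", "samples_csv", "gmt", "max_below_lod",
                        "linearity_threshold", "pooling_mode",
                        "fc_magnitude", "min_abs_diff", "n_jgl_proteins",
                        "lambda1_grid", "lambda2_grid", "min_m")],
      stages = list()
    )
    note <- function(stage_name, ...) {
      manifest$stages[[stage_name]] <<- list(...)
      log_stage(stage_name, paste(names(list(...)), unlist(list(...)),
                                  sep = "=", collapse = " "))
    }

    stage <- "read"
    npx <- read_npx_long(config$npx_csv)
    samples <- read_samples(config$samples_csv)
    pathways <- read_gmt(config$gmt)
    note("read", rows_npx = nrow(npx), persons = nrow(samples),
         assays = dplyr::n_distinct(npx$assay_id), pathways = nrow(pathways))

    stage <- "qc"
    qc <- qc_npx(npx, samples, linearity_threshold = config$linearity_threshold,
                 max_below = config$max_below_lod)
    qc_report_json(qc$report, file.path(config$out_dir, "qc_report.json"))
    note("qc", assays_in = qc$report$n_assays_in,
         assays_retained = length(qc$report$retained),
         assays_excluded = nrow(qc$report$excluded))
    stopifnot(qc$report$n_assays_in ==
                length(qc$report$retained) + nrow(qc$report$excluded))

    stage <- "standardize"
    wide <- npx_wide(qc$data)
    group <- samples$group[match(rownames(wide), samples$person_id)]
    Zs <- standardize(wide)
    note("standardize", samples = nrow(Zs), proteins = ncol(Zs))

    stage <- "differential_expression"
    de_fit <- fit_hierarchical_model(qc$data, samples,
                                     pooling_mode = config$pooling_mode)
    de_res <- extract_group_contrasts(de_fit)
    de_cls <- classify_de(de_res, fc_magnitude = config$fc_magnitude)
    readr::write_tsv(de_res, file.path(config$out_dir, "de_results.tsv"),
                     progress = FALSE)
    note("differential_expression", proteins = nrow(de_res),
         up = length(de_cls$up), down = length(de_cls$down),
         high_magnitude = length(de_cls$high_magnitude))

    stage <- "coexpression"
    pairs <- all_pairs(Zs, group)
    readr::write_tsv(pairs, file.path(config$out_dir, "pair_models.tsv"),
                     progress = FALSE)
    sel <- select_enrichment_proteins(pairs,
                                      min_abs_diff = config$min_abs_diff)
    edges <- select_network_edges(pairs, rule = config$coexpression_rule)
    readr::write_csv(edges, file.path(config$out_dir, "coexpression_edges.csv"),
                     progress = FALSE)
    fn_ann <- if (!is.null(config$function_annotation)) {
      readr::read_csv(config$function_annotation, show_col_types = FALSE,
                      progress = FALSE)
    }
    for (grp in c("control", "OA")) {
      edges_to_graphml(edges[edges$group == grp, , drop = FALSE],
                       file.path(config$out_dir,
                                 paste0("coexpression_", grp, ".graphml")),
                       functions = fn_ann)
    }
    note("coexpression", pairs = nrow(pairs),
         qualifying_pairs = nrow(sel$pairs),
         edges_control = sum(edges$group == "control"),
         edges_case = sum(edges$group == "OA"))

    stage <- "joint_graphical_lasso"
    keep <- jgl_protein_subset(Zs, group, config$n_jgl_proteins)
    Zj <- Zs[, keep, drop = FALSE]
    gc_cov <- group_covariances(Zj, group)
    msel <- model_selection(gc_cov$S_list, gc_cov$n_list,
                            config$lambda1_grid, config$lambda2_grid,
                            config$jgl)
    readr::write_tsv(msel, file.path(config$out_dir, "model_selection.tsv"),
                     progress = FALSE)
    pick <- msel[grepl("bic;", msel$selected, fixed = TRUE), ][1, ]
    jgl_fit <- joint_graphical_lasso(gc_cov$S_list, gc_cov$n_list,
                                     pick$lambda1, pick$lambda2, config$jgl)
    jgl_edges <- tidy(jgl_fit)
    readr::write_tsv(jgl_edges, file.path(config$out_dir, "jgl_edges.tsv"),
                     progress = FALSE)
    for (k in 1:2) {
      grp <- c("control", "OA")[k]
      th <- as.data.frame(jgl_fit$theta[[k]])
      readr::write_tsv(tibble::as_tibble(cbind(protein = keep, th)),
                       file.path(config$out_dir,
                                 paste0("precision_", grp, ".tsv")),
                       progress = FALSE)
      adj <- as.data.frame(jgl_fit$adjacency[[k]] * 1L)
      readr::write_tsv(tibble::as_tibble(cbind(protein = keep, adj)),
                       file.path(config$out_dir,
                                 paste0("adjacency_", grp, ".tsv")),
                       progress = FALSE)
      ge <- jgl_edges[jgl_edges$group == ifelse(k == 1, "control", "OA"), ]
      edges_to_graphml(
        tibble::tibble(protein_a = ge$protein_a, protein_b = ge$protein_b,
                       precision = ge$precision),
        file.path(config$out_dir, paste0("jgl_", grp, ".graphml")),
        functions = fn_ann)
    }
    clusters <- differential_clusters(jgl_fit)
    jsonlite::write_json(clusters,
                         file.path(config$out_dir,
                                   "differential_clusters.json"),
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
    note("joint_graphical_lasso", proteins = length(keep),
         lambda1 = pick$lambda1, lambda2 = pick$lambda2,
         edges_control = pick$edges_control, edges_case = pick$edges_case,
         clusters_control = length(clusters$control),
         clusters_case = length(clusters$case))

    stage <- "enrichment"
    background <- colnames(Zs)
    enr <- run_three_analyses(c(de_cls$up, de_cls$down),
                              sel$control, sel$case,
                              background, pathways, min_m = config$min_m)
    for (nm in names(enr)) {
      out <- enr[[nm]]
      names(out) <- c("Pathway_name", "TopReactomeName", "q", "m", "p",
                      "Ratio", "Proteins")
      readr::write_tsv(out, file.path(config$out_dir,
                                      paste0("enrichment_", nm, ".tsv")),
                       progress = FALSE)
    }
    note("enrichment",
         A_rows = nrow(enr$A_differential),
         B_rows = nrow(enr$B_coexpression_control),
         C_rows = nrow(enr$C_coexpression_case))

    stage <- "pca"
    pca <- pca_overview(Zs, group)
    readr::write_tsv(pca$scores, file.path(config$out_dir, "pca_scores.tsv"),
                     progress = FALSE)
    note("pca",
         pc1_var = round(pca$var_explained[1], 4),
         pc2_var = round(pca$var_explained[2], 4))

    stage <- "manifest"
    manifest$stage_order <- names(manifest$stages)
    mpath <- file.path(config$out_dir, "manifest.json")
    tmp <- paste0(mpath, ".tmp")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    file.rename(tmp, mpath)
    structure(manifest, class = "npx_manifest")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' @export
print.npx_manifest <- function(x, ...) {
  cat("npxnet pipeline run (seed ", x$seed, ")\n", sep = "")
  for (nm in x$stage_order) {
    vals <- x$stages[[nm]]
    cat("  ", nm, ": ", paste(names(vals), unlist(vals), sep = "=",
                              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
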