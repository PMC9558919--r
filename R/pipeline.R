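#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable parameter of the
#' portraying workflow. Values can be overridden by the \code{...}
#' arguments or by a YAML file via \code{\link{read_config}}.
#'
#' @param ... named overrides of the defaults.
#' @return named list (schema version 1).
#' @export
default_config <- function(...) {
  cfg <- list(
    schema = 1,
    ## input: either a dataset directory (matrix.mtx + genes.tsv +
    ## barcodes.tsv + cell_meta.tsv) or NULL to simulate
    input_dir = NULL,
    simulate = list(n_genes = 2000, n_cells = 5000, n_samples = 8,
                    n_modules = 5, module_size = 40, effect_size = 4,
                    dispersion = 0.1, cycling_fraction = 0.4,
                    group_freq_shift = 0.5),
    normalize = list(scale = 1e4, log_base = exp(1)),
    qc = list(min_genes_per_cell = 0, max_mito_fraction = 1),
    marker_panel_path = NULL,
    car_gene = "FMC63-CD19scFV",
    cell_cycle = list(s_genes_path = NULL, g2m_genes_path = NULL,
                      n_bins = 25, n_ctrl = 100),
    metacell = list(base_k = 16, cells_per_metacell = 100),
    som = list(rows = 40, cols = 40, epochs = 100, sigma_end = 0.3),
    spots = list(threshold_fraction = 0.90, min_units = 3, neighborhood = 8),
    activation = list(major_sigma = 1.0, minor_sigma = 0.5,
                      rare_fraction = 0.005),
    group_column = "group",
    seed = 1)
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override \code{\link{default_config}}.
#' @return configuration list.
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

.log_line <- function(log_path, ...) {
  cat(paste0(..., collapse = ""), "\n", sep = "", file = log_path,
      append = TRUE)
}

#' Run the end-to-end portraying pipeline
#'
#' Executes read/simulate -> normalize -> cell typing -> meta-cells -> SOM
#' -> spot modules -> upscaling -> module expression -> PATs -> group
#' enrichment and flow, writing every intermediate artifact, rendered
#' portraits, a machine-readable summary and a structured parameter log to
#' \code{out_dir}. Fully deterministic for a fixed config and seed. Any
#' stage failure aborts with the stage name; artifacts of completed stages
#' are retained.
#'
#' @param config list from \code{\link{default_config}} or
#'   \code{\link{read_config}}.
#' @param out_dir result directory (created).
#' @return Invisibly, a list with the main in-memory results (matrix,
#'   truth, metacells, som, spots, module expression, assignment,
#'   frequency tables, enrichment, flow, summary).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  .log_line(log_path, "config: ",
            jsonlite::toJSON(config, auto_unbox = TRUE, null = "null"))
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    .log_line(log_path, "stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inp <- stage("input", {
    if (!is.null(config$input_dir)) {
      meta <- read_cell_meta(file.path(config$input_dir, "cell_meta.tsv"))
      list(matrix = read_matrix_market(
             file.path(config$input_dir, "matrix.mtx"),
             file.path(config$input_dir, "genes.tsv"),
             file.path(config$input_dir, "barcodes.tsv"),
             cell_meta = meta),
           truth = NULL)
    } else {
      do.call(generate_dataset, c(config$simulate, list(seed = seed)))
    }
  })
  X <- inp$matrix
  truth <- inp$truth
  X <- stage("qc", qc_filter(X, config$qc$min_genes_per_cell,
                             config$qc$max_mito_fraction))
  Xn <- stage("normalize",
              normalize_cells(X, config$normalize$scale,
                              config$normalize$log_base))

  typing <- stage("cell_typing", {
    panel <- if (!is.null(config$marker_panel_path))
      read_marker_panel(config$marker_panel_path)
    else if (!is.null(truth)) planted_panel(truth)
    else NULL
    if (is.null(panel)) NULL else {
      car <- if (!is.null(config$car_gene) && config$car_gene %in% X$gene_ids)
        config$car_gene else NULL
      ann <- assign_populations(X, panel, car_gene = car)
      utils::write.table(ann, file.path(out_dir, "cell_annotation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ann
    }
  })

  phases <- stage("cell_cycle", {
    cc <- config$cell_cycle
    sg <- if (!is.null(cc$s_genes_path)) readLines(cc$s_genes_path)
    gg <- if (!is.null(cc$g2m_genes_path)) readLines(cc$g2m_genes_path)
    if (is.null(sg) && !is.null(truth)) {
      cyc <- truth$module_genes[[truth$cycling_module]]
      half <- length(cyc) %/% 2
      sg <- cyc[seq_len(half)]; gg <- cyc[-seq_len(half)]
    }
    if (is.null(sg) || is.null(gg)) NULL else {
      ph <- score_cell_cycle(Xn, sg, gg, n_bins = cc$n_bins,
                             n_ctrl = cc$n_ctrl, seed = seed)
      utils::write.table(ph, file.path(out_dir, "cell_cycle.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ph
    }
  })

  M <- stage("metacell", {
    labels <- base_cluster(Xn, k = config$metacell$base_k, seed = seed)
    m <- build_metacells(Xn, labels, config$metacell$cells_per_metacell,
                         seed = seed)
    write_metacells(m, file.path(out_dir, "metacell_centroids.tsv"),
                    file.path(out_dir, "metacell_assignment.tsv"))
    m
  })

  model <- stage("som", {
    prof <- prepare_gene_profiles(M)
    s <- train_som(prof, rows = config$som$rows, cols = config$som$cols,
                   epochs = config$som$epochs,
                   sigma_end = config$som$sigma_end %||% 0.3, seed = seed)
    write_som(s, file.path(out_dir, "som"))
    s
  })

  map <- stage("spots", {
    sp <- extract_spots(model,
                        threshold_fraction = config$spots$threshold_fraction,
                        min_units = config$spots$min_units,
                        neighborhood = config$spots$neighborhood)
    write_module_map(sp, file.path(out_dir, "module_units.tsv"),
                     file.path(out_dir, "module_genes.tsv"))
    render_portrait(group_portrait(model, metacell_portraits(model)),
                    file.path(out_dir, "mean_portrait.png"), pixel_size = 8)
    sp
  })

  up <- stage("upscale", fit_upscaler(model, M))

  E <- stage("module_expression", {
    e <- module_expression(Xn, map)
    utils::write.table(e, file.path(out_dir, "module_expression.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    e
  })

  pats <- stage("pats", {
    thr <- activation_thresholds(config$activation$major_sigma,
                                 config$activation$minor_sigma,
                                 config$activation$rare_fraction)
    lv <- call_activation(E, thr)
    a <- assign_pats(lv, thr)
    a <- reject_rare(a, thr$rare_fraction)
    utils::write.table(a, file.path(out_dir, "pat_assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(assign = a, levels = lv)
  })

  grouping <- X$cell_meta[[config$group_column]]
  if (!is.null(grouping)) names(grouping) <- X$cell_ids
  freq <- stage("frequencies", {
    f <- pat_frequency_table(pats$assign, grouping)
    utils::write.table(f$pat, file.path(out_dir, "pat_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(f$tier, file.path(out_dir, "tier_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  enrich <- flow <- NULL
  if (!is.null(grouping) && length(unique(grouping)) >= 2) {
    enrich <- stage("enrichment", {
      en <- pat_enrichment(pats$assign, grouping)
      utils::write.table(en, file.path(out_dir, "pat_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      en
    })
    if (length(unique(grouping)) == 2) {
      flow <- stage("flow", {
        cen <- pat_centroids(E, pats$assign)
        fg <- pat_flow(pats$assign, grouping, cen)
        write_flow_graph(fg, file.path(out_dir, "pat_flow.tsv"),
                         file.path(out_dir, "pat_flow.json"))
        fg
      })
    }
  }

  summary <- list(
    n_genes = length(X$gene_ids), n_cells = length(X$cell_ids),
    n_metacells = nrow(M$centroids),
    n_modules = length(map$modules),
    module_sizes = vapply(map$modules, function(m) length(m$genes), integer(1)),
    tier_counts = stats::setNames(freq$tier$count, freq$tier$tier),
    n_pats = length(setdiff(unique(pats$assign$label), "none")),
    seed = seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_line(log_path, "done")
  invisible(list(matrix = X, normalized = Xn, truth = truth, typing = typing,
                 phases = phases, metacells = M, som = model, spots = map,
                 upscaler = up, module_expression = E, pats = pats$assign,
                 levels = pats$levels, frequencies = freq,
                 enrichment = enrich, flow = flow, summary = summary))
}
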