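#' Assemble and validate a pipeline run configuration
#'
#' Central place for every tunable constant of the workflow, with the
#' conventional defaults: differential significance on FDR-adjusted
#' p-values at 0.05, enrichment over-representation at 0.1, an 80/20
#' stratified split, and a 1e-4 mean-|SHAP| marker threshold.
#'
#' @param out_dir Output directory (created if needed).
#' @param synthetic `NULL`, `TRUE` (default synthetic design) or a list
#'   of [synthetic_design()] arguments — the pipeline then generates
#'   its own inputs. Otherwise supply `model_path`, `tx_path`,
#'   `metadata_path` (and optionally `gx_path`, `px_path`).
#' @param model_path,tx_path,gx_path,px_path,metadata_path Input files
#'   (ignored when `synthetic` is set).
#' @param reference_gene Normalization anchor (default `"PKM"`).
#' @param vmax Flux-scale constant for expression caps.
#' @param uptake_limit Medium uptake cap; `NULL` uses the synthetic
#'   default (non-limiting 1000) for synthetic runs and 10 otherwise.
#' @param scheme Comparison scheme for [build_groups()].
#' @param alpha_diff FDR threshold calling a reaction significant.
#' @param alpha_enrich Tail-probability threshold calling a pathway
#'   over-represented.
#' @param train_fraction Training fraction of the classifier split.
#' @param grid Hyperparameter grid (default: a single conventional
#'   point; see [default_rf_grid()] for the full grid).
#' @param shap_threshold Marker-selection threshold on mean |SHAP|.
#' @param seed Integer master seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir,
                       synthetic = TRUE,
                       model_path = NULL, tx_path = NULL, gx_path = NULL,
                       px_path = NULL, metadata_path = NULL,
                       reference_gene = "PKM", vmax = 1000,
                       uptake_limit = NULL,
                       scheme = "custom",
                       alpha_diff = 0.05, alpha_enrich = 0.1,
                       train_fraction = 0.8,
                       grid = NULL, shap_threshold = 1e-4, seed = 1) {
  stopifnot(alpha_diff > 0, alpha_diff <= 1,
            alpha_enrich > 0, alpha_enrich <= 1,
            train_fraction > 0, train_fraction < 1,
            shap_threshold > 0)
  if (is.null(synthetic) || identical(synthetic, FALSE)) {
    for (p in c(model_path, tx_path, metadata_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input path missing or unresolvable: ",
             if (is.null(p)) "(NULL)" else p, call. = FALSE)
      }
    }
    synthetic <- NULL
  } else if (isTRUE(synthetic)) {
    synthetic <- list()
  }
  structure(list(
    out_dir = out_dir, synthetic = synthetic,
    model_path = model_path, tx_path = tx_path, gx_path = gx_path,
    px_path = px_path, metadata_path = metadata_path,
    reference_gene = reference_gene, vmax = vmax,
    uptake_limit = uptake_limit, scheme = scheme,
    alpha_diff = alpha_diff, alpha_enrich = alpha_enrich,
    train_fraction = train_fraction, grid = grid,
    shap_threshold = shap_threshold, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `synthetic` may be a
#' nested mapping of [synthetic_design()] arguments.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(y$synthetic) && is.list(y$synthetic) &&
      !is.null(y$synthetic$planted_effects)) {
    y$synthetic$planted_effects <-
      as.data.frame(do.call(rbind, lapply(y$synthetic$planted_effects,
                                          as.data.frame)))
  }
  if (!is.null(y$synthetic) && is.list(y$synthetic) &&
      !is.null(y$synthetic$classes)) {
    y$synthetic$classes <- unlist(y$synthetic$classes)
  }
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Executes, in order: synthetic-input generation (optional), reference
#' min-max normalization, per-sample expression-capped FBA (the `JX`
#' layer), differential testing on the flux and reaction-expression
#' layers, subsystem enrichment, multi-omic ensemble classification,
#' and SHAP marker ranking. Every stage writes plain-text artifacts
#' under `config$out_dir`; a JSON manifest records per-stage status,
#' seeds and output digests. Reruns of an identical config reproduce
#' identical bytes.
#'
#' @param config A `run_config`.
#' @return The manifest, invisibly.
#' @export
run_all <- function(config) {
  od <- config$out_dir
  dir.create(od, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("fluxomix")),
                   seed = config$seed, stages = list())
  t0 <- Sys.time()
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, od)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "completed")
    res
  }

  inputs <- stage("synth", function() {
    if (!is.null(config$synthetic)) {
      des <- do.call(synthetic_design,
                     c(config$synthetic,
                       if (is.null(config$synthetic$seed))
                         list(seed = config$seed)))
      model <- make_toy_model(des)
      cohort <- make_cohort(des, model)
      write_model(model, file.path(od, "model.json"))
      write_omic_matrix(cohort$tx, file.path(od, "tx_raw.tsv"))
      write_omic_matrix(cohort$gx, file.path(od, "gx.tsv"))
      write_omic_matrix(cohort$px, file.path(od, "px.tsv"))
      utils::write.table(cohort$metadata, file.path(od, "metadata.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(model = model, tx = cohort$tx, gx = cohort$gx, px = cohort$px,
           metadata = cohort$metadata, synthetic = TRUE)
    } else {
      list(model = read_model(config$model_path),
           tx = read_omic_matrix(config$tx_path, "TX"),
           gx = if (!is.null(config$gx_path))
             read_omic_matrix(config$gx_path, "GX"),
           px = if (!is.null(config$px_path))
             read_omic_matrix(config$px_path, "PX"),
           metadata = utils::read.table(config$metadata_path, header = TRUE,
                                        sep = "\t",
                                        stringsAsFactors = FALSE),
           synthetic = FALSE)
    }
  })

  tx_norm <- stage("normalize", function() {
    nm <- normalize_reference_minmax(inputs$tx, config$reference_gene)
    write_omic_matrix(nm, file.path(od, "tx_normalized.tsv"))
    nm
  })

  flux_bits <- stage("fluxes", function() {
    irr <- make_irreversible(inputs$model)
    ul <- config$uptake_limit %||% if (inputs$synthetic) 1000 else 10
    medium <- medium_spec(exchange_reactions(inputs$model),
                          uptake_limit = ul)
    jx <- fluxome_for_cohort(irr$model, tx_norm, vmax = config$vmax,
                             medium = medium)
    write_omic_matrix(jx, file.path(od, "flux.tsv"))
    jsonlite::write_json(
      list(objective_values = as.list(attr(jx, "objective_values")),
           solver_status = as.list(attr(jx, "solver_status")),
           n_constrained = attr(jx, "n_constrained")),
      file.path(od, "flux_run_info.json"), auto_unbox = TRUE, digits = NA)
    rx <- reaction_expression(irr$model, tx_norm)
    list(jx = jx, rx = rx, irr = irr)
  })

  groups <- stage("groups", function() {
    build_groups(inputs$metadata, config$scheme)
  })

  diff_results <- stage("diff", function() {
    res <- list()
    for (g in groups) {
      for (layer_name in c("jx", "rx")) {
        d <- diff_test(flux_bits[[layer_name]], g)
        key <- paste0(g$name, ".", attr(d, "layer"))
        utils::write.table(
          data.frame(d, layer = attr(d, "layer"), group = g$name),
          file.path(od, paste0("diff_", gsub("[^A-Za-z0-9._-]", "_", key),
                               ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        res[[key]] <- d
      }
    }
    res
  })

  enrich_results <- stage("enrich", function() {
    tmap <- subsystem_term_map(flux_bits$irr$model)
    res <- list()
    for (key in names(diff_results)) {
      d <- diff_results[[key]]
      sig <- d$feature_id[!is.na(d$p_adj) & d$p_adj < config$alpha_diff]
      sig <- unique(collapse_split_ids(sig))
      sig <- intersect(sig, tmap$universe)
      er <- enrich_terms(sig, tmap, alpha = config$alpha_enrich)
      utils::write.table(
        er, file.path(od, paste0("enrich_",
                                 gsub("[^A-Za-z0-9._-]", "_", key), ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      res[[key]] <- er
    }
    ht <- enrichment_heat_table(res)
    utils::write.table(
      data.frame(term = rownames(ht$wide), ht$wide, check.names = FALSE),
      file.path(od, "enrichment_heat_table.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  clf <- stage("classify", function() {
    md <- inputs$metadata
    y <- stats::setNames(md$condition, md$sample_id)
    layers <- list(TX = tx_norm, JX = flux_bits$jx)
    if (!is.null(inputs$gx)) layers$GX <- inputs$gx
    if (!is.null(inputs$px)) layers$PX <- inputs$px
    sp <- split_train_test(md$sample_id, y[md$sample_id],
                           config$train_fraction, seed = config$seed)
    fits <- lapply(names(layers), function(tag) {
      fit_layer(unclass(layers[[tag]])[, sp$train, drop = FALSE] |> t(),
                y[sp$train], layer = tag, grid = config$grid,
                seed = config$seed)
    })
    ens <- ensemble_model(fits)
    test_data <- lapply(layers, function(m)
      t(unclass(m)[, sp$test, drop = FALSE]))
    v <- vote(ens, test_data)
    rep_ens <- evaluate(v$probabilities, y[sp$test])
    per_layer <- lapply(seq_along(fits), function(i) {
      evaluate(predict_layer(fits[[i]], test_data[[fits[[i]]$layer]]),
               y[sp$test])
    })
    names(per_layer) <- names(layers)
    report <- c(
      list(ensemble = list(accuracy = rep_ens$accuracy,
                           macro_f1 = rep_ens$macro_f1,
                           per_class = rep_ens$per_class)),
      lapply(per_layer, function(r)
        list(accuracy = r$accuracy, macro_f1 = r$macro_f1,
             per_class = r$per_class)))
    jsonlite::write_json(report, file.path(od, "classification_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    list(fits = fits, ensemble = ens, split = sp, test_data = test_data,
         report = rep_ens)
  })

  stage("shap", function() {
    for (fit in clf$fits) {
      sr <- shap_rank(fit, clf$test_data[[fit$layer]],
                      threshold = config$shap_threshold)
      utils::write.table(sr, file.path(od, paste0("shap_", fit$layer, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    NULL
  })

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$outputs <- output_digests(od)
  write_manifest(manifest, od)
  invisible(manifest)
}

output_digests <- function(od) {
  files <- sort(setdiff(list.files(od), "manifest.json"))
  as.list(stats::setNames(unname(tools::md5sum(file.path(od, files))), files))
}

write_manifest <- function(manifest, od) {
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}
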