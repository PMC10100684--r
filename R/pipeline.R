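#' Build and validate a pipeline configuration
#'
#' A configuration is a plain named list (or a path to a JSON file holding
#' one). `pipeline_config()` fills defaults, validates every threshold
#' against its legal range, and fails before any stage runs. The `transform`
#' used for ordination input must be named explicitly — there is no silent
#' default for it.
#'
#' @param config named list or path to a JSON config file. Recognised keys:
#'   `simulation` (arguments for [community_sim_spec()]), or `input` (list
#'   with `otu_table` and optionally `metadata` TSV paths); `transform`
#'   (`"none"`, `"log1p"`, `"sqrt"`; required when ordination runs);
#'   `r_min`, `p_max`, `min_mean_rel_abundance`, `n_permutations`,
#'   `dnci_permutations`, `ci_level`, `attack` (list: `strategies`, `k`,
#'   `adaptive`), `stages` (subset of simulate, diversity, ordination, ncm,
#'   dnci, network, attack), `seed` (mandatory), `output_dir` (mandatory).
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must set an integer 'seed'")
  if (is.null(config$output_dir)) stop("config must set 'output_dir'")
  config$stages <- config$stages %||%
    c("simulate", "diversity", "ordination", "ncm", "dnci", "network",
      "attack")
  bad <- setdiff(config$stages, c("simulate", "diversity", "ordination",
                                  "ncm", "dnci", "network", "attack"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config$r_min <- config$r_min %||% 0.8
  config$p_max <- config$p_max %||% 0.01
  config$min_mean_rel_abundance <- config$min_mean_rel_abundance %||% 1e-4
  config$n_permutations <- config$n_permutations %||% 999
  config$dnci_permutations <- config$dnci_permutations %||% 999
  config$ci_level <- config$ci_level %||% 0.95
  assert_scalar_in(config$r_min, "r_min", 0, 1, open_lo = TRUE)
  assert_scalar_in(config$p_max, "p_max", 0, 1, open_lo = TRUE,
                   open_hi = TRUE)
  assert_scalar_in(config$min_mean_rel_abundance, "min_mean_rel_abundance",
                   0, 1, open_hi = TRUE)
  assert_scalar_in(config$ci_level, "ci_level", 0, 1, open_lo = TRUE,
                   open_hi = TRUE)
  if (config$n_permutations < 99) stop("'n_permutations' must be >= 99")
  if ("ordination" %in% config$stages && is.null(config$transform)) {
    stop("config must name an ordination 'transform' explicitly",
         " ('none', 'log1p' or 'sqrt')")
  }
  if (!is.null(config$transform) &&
      !config$transform %in% c("none", "log1p", "sqrt")) {
    stop("'transform' must be one of none, log1p, sqrt")
  }
  if (is.null(config$simulation) && is.null(config$input)) {
    stop("config needs either a 'simulation' spec or an 'input' block")
  }
  config$attack <- config$attack %||%
    list(strategies = c("betweenness", "degree", "abundance", "random"),
         k = 10, adaptive = FALSE)
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load) the
#' OTU table, alpha/beta diversity, CAP + PERMANOVA, neutral-model fit,
#' DNCI, co-occurrence network, node-removal attacks — writing every artifact
#' into `output_dir` and recording it in a run manifest JSON (with the config
#' hash and seed), so that rerunning an identical config reproduces
#' byte-identical stochastic outputs. A stage failure halts the run with the
#' failing stage named; the manifest is still written with a `failed` marker.
#'
#' @param config a [pipeline_config()] (or list / JSON path accepted by it).
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (list with `config_hash`, `seed`,
#'   `outputs`, `stages`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(cfg$output_dir, f)
  cfg_file <- out_path("config.json")
  jsonlite::write_json(unclass(cfg), cfg_file, auto_unbox = TRUE, digits = NA)
  # hash the analytic configuration only: the same analysis written to a
  # different output directory must hash identically
  hash_file <- tempfile(fileext = ".json")
  cfg_hash <- cfg
  cfg_hash$output_dir <- NULL
  jsonlite::write_json(unclass(cfg_hash), hash_file, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(config_hash = unname(tools::md5sum(hash_file)),
                   output_dir = cfg$output_dir,
                   seed = cfg$seed, outputs = character(0),
                   stages = list())
  unlink(hash_file)
  say <- function(...) if (!quiet) message(...)
  record <- function(stage, files, status = "ok") {
    manifest$outputs <<- c(manifest$outputs, files)
    manifest$stages[[stage]] <<- status
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    say("stage: ", stage)
    tryCatch(fn(), error = function(e) {
      manifest$stages[[stage]] <<- paste("failed:", conditionMessage(e))
      jsonlite::write_json(manifest, out_path("manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  tab <- NULL
  metadata <- NULL
  run_stage("simulate", function() {
    if (!is.null(cfg$simulation)) {
      sim_args <- cfg$simulation
      sim_args$seed <- sim_args$seed %||% derive_seed(cfg$seed, "simulate")
      if (!is.null(sim_args$gradient_groups)) {
        sim_args$gradient_groups <- as.data.frame(sim_args$gradient_groups)
      }
      spec <- do.call(community_sim_spec, sim_args)
      sim <- switch(spec$regime,
                    neutral = simulate_neutral(spec),
                    niche = simulate_niche_gradient(spec),
                    dispersal = simulate_dispersal_structured(spec),
                    block_network = simulate_block_network(spec))
      tab <<- sim$table
      metadata <<- sim$metadata
      write_otu_table(tab, out_path("otu_table.tsv"))
      write_ground_truth(sim$ground_truth, out_path("ground_truth.json"))
      files <- c(out_path("otu_table.tsv"), out_path("ground_truth.json"))
      if (!is.null(metadata)) {
        write_metadata(metadata, out_path("metadata.tsv"))
        files <- c(files, out_path("metadata.tsv"))
      }
      record("simulate", files)
    } else {
      tab <<- read_otu_table(cfg$input$otu_table)
      if (!is.null(cfg$input$metadata)) {
        metadata <<- read_metadata(cfg$input$metadata)
      }
      record("simulate", character(0), "loaded from input")
    }
  })
  if (is.null(tab)) {
    if (!is.null(cfg$input)) {
      tab <- read_otu_table(cfg$input$otu_table)
      if (!is.null(cfg$input$metadata)) metadata <- read_metadata(cfg$input$metadata)
    } else {
      stop("no OTU table available: enable the 'simulate' stage or give 'input'")
    }
  }
  groups <- if (!is.null(metadata) && "region" %in% names(metadata)) {
    metadata$region[match(tab$sample_ids, metadata$sample_id)]
  } else NULL

  run_stage("diversity", function() {
    alpha <- compute_alpha(tab)
    utils::write.table(alpha, out_path("alpha_diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bc <- bray_curtis(tab, transform = cfg$transform %||% "none")
    bm <- as.matrix(bc)
    utils::write.table(data.frame(sample_id = rownames(bm), bm,
                                  check.names = FALSE),
                       out_path("bray_curtis.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(out_path("alpha_diversity.tsv"), out_path("bray_curtis.tsv"))
    if (!is.null(metadata) &&
        all(c("salinity", "temperature") %in% names(metadata))) {
      ec <- env_correlations(alpha, metadata)
      utils::write.table(ec, out_path("env_correlations.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, out_path("env_correlations.tsv"))
    }
    record("diversity", files)
  })

  run_stage("ordination", function() {
    if (is.null(groups)) {
      record("ordination", character(0), "skipped: no group metadata")
      return(invisible(NULL))
    }
    bc <- bray_curtis(tab, transform = cfg$transform)
    cp <- cap(bc, groups)
    utils::write.table(
      data.frame(sample_id = tab$sample_ids, group = groups,
                 cp$sample_scores, check.names = FALSE),
      out_path("cap_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(list(delta_sq = cp$delta_sq, m = cp$m,
                              loo = cp$loo_misclassification_rate),
                         out_path("cap.json"), auto_unbox = TRUE, digits = NA)
    pm <- permanova(bc, groups, n_permutations = cfg$n_permutations,
                    seed = derive_seed(cfg$seed, "permanova"))
    jsonlite::write_json(list(F = pm$pseudo_F, R2 = pm$r_squared,
                              p = pm$p_value, n_perm = pm$n_permutations,
                              seed = cfg$seed),
                         out_path("permanova.json"), auto_unbox = TRUE,
                         digits = NA)
    record("ordination", out_path(c("cap_scores.tsv", "cap.json",
                                    "permanova.json")))
  })

  run_stage("ncm", function() {
    fit <- suppressWarnings(ncm_fit(tab, ci_level = cfg$ci_level))
    write_ncm_fit(fit, out_path("ncm_fit.json"), out_path("ncm_otus.tsv"))
    record("ncm", out_path(c("ncm_fit.json", "ncm_otus.tsv")))
  })

  run_stage("dnci", function() {
    if (is.null(groups)) {
      record("dnci", character(0), "skipped: no group metadata")
      return(invisible(NULL))
    }
    res <- suppressWarnings(
      dnci(tab, groups, n_permutations = cfg$dnci_permutations,
           seed = derive_seed(cfg$seed, "dnci")))
    write_dnci(res, out_path("dnci.json"), out_path("dnci_evalues.tsv"))
    record("dnci", out_path(c("dnci.json", "dnci_evalues.tsv")))
  })

  net <- NULL
  run_stage("network", function() {
    filtered <- suppressMessages(
      filter_low_abundance(tab, cfg$min_mean_rel_abundance))
    net <<- suppressWarnings(
      infer_network(filtered, r_min = cfg$r_min, p_max = cfg$p_max))
    if (igraph::ecount(net) == 0) {
      record("network", character(0), "no edges at thresholds")
      return(invisible(NULL))
    }
    write_network(net, edge_tsv = out_path("edges.tsv"),
                  graphml = out_path("network.graphml"),
                  topology_json = out_path("topology.json"),
                  seed = derive_seed(cfg$seed, "topology"))
    record("network", out_path(c("edges.tsv", "network.graphml",
                                 "topology.json")))
  })

  run_stage("attack", function() {
    if (is.null(net) || igraph::ecount(net) == 0) {
      record("attack", character(0), "skipped: no network")
      return(invisible(NULL))
    }
    k <- min(cfg$attack$k, igraph::vcount(net) - 1)
    traj <- do.call(rbind, lapply(cfg$attack$strategies, function(s) {
      tr <- attack(net, strategy = s, k = k,
                   adaptive = isTRUE(cfg$attack$adaptive),
                   seed = derive_seed(cfg$seed, paste0("attack_", s)))
      cbind(strategy = s, as.data.frame(tr))
    }))
    utils::write.table(traj, out_path("attack_trajectories.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("attack", out_path("attack_trajectories.tsv"))
  })

  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$outputs <- c(manifest$outputs, out_path("manifest.json"))
  invisible(manifest)
}
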