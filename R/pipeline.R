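#' Pipeline configuration
#'
#' Bundles paths, thresholds, and the RNG seed for [run_pipeline()]. The
#' default thresholds are the analysis defaults used throughout the package:
#' DE filter FDR < 0.001 with |logFC| > 1.5, network filter FDR < 0.001 with
#' `|rho| >= 0.8`, communities of at least 100 nodes, 50 hubs per community,
#' walk length 4.
#'
#' @param mode `"synthetic"` (simulate counts) or `"user-data"` (read from
#'   `counts`/`design` paths).
#' @param counts,design,annotation input paths (`user-data` mode; `annotation`
#'   is an optional GMT file in either mode).
#' @param out_dir output directory for all artifacts.
#' @param de_fdr,de_lfc DE filter thresholds.
#' @param net_fdr,rho_min network filter thresholds.
#' @param min_community community size filter.
#' @param hub_k hubs selected per community.
#' @param walktrap_t walk length.
#' @param baseline_repeats random-removal baselines in the cohesion report.
#' @param seed integer seed controlling all randomness.
#' @param generator [generator_params()] for synthetic mode (its seed is
#'   overridden by `seed`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "user-data"),
                            counts = NULL, design = NULL, annotation = NULL,
                            out_dir = tempfile("trichonet_run_"),
                            de_fdr = 0.001, de_lfc = 1.5,
                            net_fdr = 0.001, rho_min = 0.8,
                            min_community = 100, hub_k = 50, walktrap_t = 4,
                            baseline_repeats = 20,
                            seed = 1, generator = generator_params()) {
  mode <- match.arg(mode)
  thresholds <- c(de_fdr = de_fdr, de_lfc = de_lfc, net_fdr = net_fdr,
                  rho_min = rho_min, min_community = min_community,
                  hub_k = hub_k, walktrap_t = walktrap_t)
  if (any(thresholds <= 0)) stop("all thresholds must be positive")
  if (mode == "user-data" && (is.null(counts) || is.null(design))) {
    stop("user-data mode needs counts and design paths")
  }
  structure(list(mode = mode, counts = counts, design = design,
                 annotation = annotation, out_dir = out_dir,
                 de_fdr = de_fdr, de_lfc = de_lfc, net_fdr = net_fdr,
                 rho_min = rho_min, min_community = min_community,
                 hub_k = hub_k, walktrap_t = walktrap_t,
                 baseline_repeats = baseline_repeats,
                 seed = as.integer(seed), generator = generator),
            class = "pipeline_config")
}

#' Run the full co-expression analysis pipeline
#'
#' Executes, in order: data acquisition (simulation or load) -> TMM
#' normalization -> per-timepoint differential expression for every treated
#' arm -> DE filtering with per-arm union across timepoints -> Venn partition
#' and paired logFC comparison between the two treated arms -> matched
#' control/treatment co-expression networks per arm -> differential network
#' comparison -> walktrap communities on each treatment network ->
#' size-filtered communities -> composite hub scores and top-k selection ->
#' hub-removal cohesion report -> term overrepresentation for each large
#' community (when an annotation is supplied).
#'
#' Every intermediate artifact is written under `config$out_dir`, along with
#' `summary.json` (machine-readable stage summaries) and `log.txt` (versions,
#' seed, thresholds, warnings). A rerun with the same config and seed
#' reproduces all outputs identically. A failing stage aborts with the stage
#' name; artifacts of completed stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  log_lines <- c(
    sprintf("trichonet %s | R %s", as.character(utils::packageVersion("trichonet")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", config$seed),
    sprintf("thresholds: de_fdr=%g de_lfc=%g net_fdr=%g rho_min=%g min_community=%d hub_k=%d walktrap_t=%d",
            config$de_fdr, config$de_lfc, config$net_fdr, config$rho_min,
            config$min_community, config$hub_k, config$walktrap_t))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  flush_log <- function() writeLines(log_lines, log_path)
  summary <- list()
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note("warning [%s]: %s", name, conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      note("ERROR in stage '%s': %s", name, conditionMessage(e))
      flush_log()
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## data
  dat <- stage("data", {
    if (config$mode == "synthetic") {
      params <- config$generator
      params$seed <- config$seed
      sim <- simulate_experiment(make_design(), params)
      write_counts(sim$counts, file.path(config$out_dir, "counts.tsv"))
      write_design(sim$design, file.path(config$out_dir, "design.csv"))
      write_json_report(
        list(module_of = as.list(sim$truth$module_of[!is.na(sim$truth$module_of)]),
             hub_genes = sim$truth$hub_genes, de = sim$truth$de),
        file.path(config$out_dir, "truth.json"))
      list(counts = sim$counts, design = sim$design, truth = sim$truth)
    } else {
      counts <- read_counts(config$counts)
      design <- read_design(config$design)
      list(counts = align_counts(counts, design), design = design, truth = NULL)
    }
  })
  counts <- dat$counts; design <- dat$design
  summary$data <- list(n_genes = nrow(counts), n_samples = ncol(counts),
                       mode = config$mode)

  ## normalization
  norm <- stage("normalization", {
    factors <- tmm_factors(counts)
    list(factors = factors, expr = log_cpm(counts, factors))
  })
  summary$normalization <- list(factor_range = range(norm$factors))

  ## differential expression
  conds <- levels(design$condition)
  control <- conds[1]
  treats <- conds[-1]
  timepoints <- sort(unique(design$timepoint))
  de <- stage("diffexpr", {
    out <- list()
    for (tr in treats) {
      tabs <- lapply(timepoints, function(tp) {
        tab <- de_test(counts, design, list(treat = tr, control = control,
                                            timepoint = tp))
        write_atomic(file.path(config$out_dir,
                               sprintf("de_%s_%s.tsv", tr, tp)),
                     function(tmp) utils::write.table(tab, tmp, sep = "\t",
                                                      quote = FALSE,
                                                      row.names = FALSE))
        tab
      })
      sets <- lapply(tabs, filter_de, fdr_max = config$de_fdr,
                     lfc_min = config$de_lfc)
      up <- gene_set(unlist(lapply(sets, function(s) as_gene_ids(s$up))),
                     label = tr, direction = "up")
      down <- gene_set(unlist(lapply(sets, function(s) as_gene_ids(s$down))),
                       label = tr, direction = "down")
      write_gene_set(up, file.path(config$out_dir, sprintf("up_%s.txt", tr)))
      write_gene_set(down, file.path(config$out_dir, sprintf("down_%s.txt", tr)))
      out[[tr]] <- list(tables = tabs, up = up, down = down)
    }
    out
  })
  summary$diffexpr <- lapply(de, function(x) {
    list(n_up = length(x$up), n_down = length(x$down))
  })

  ## cross-treatment comparison
  summary$comparison <- stage("comparison", {
    if (length(treats) < 2) list(skipped = "fewer than two treated arms")
    else {
      cmp <- list()
      for (dir in c("up", "down")) {
        v <- venn_partition(de[[treats[1]]][[dir]], de[[treats[2]]][[dir]])
        entry <- list(only_a = v$sizes[[1]], shared = v$sizes[[2]],
                      only_b = v$sizes[[3]])
        if (length(v$shared) >= 3) {
          mean_lfc <- function(tr) {
            tabs <- de[[tr]]$tables
            rowMeans(vapply(tabs, function(tab) {
              stats::setNames(tab$logFC, tab$gene_id)[v$shared]
            }, numeric(length(v$shared))))
          }
          x <- mean_lfc(treats[1]); y <- mean_lfc(treats[2])
          tt <- compare_logfc(x, y, method = "t", paired = TRUE)
          wt <- if (all(x == y)) list(p.value = NA_real_)
                else compare_logfc(x, y, method = "wilcoxon", paired = TRUE)
          entry$t_pvalue <- tt$p.value
          entry$wilcoxon_pvalue <- wt$p.value
        }
        cmp[[dir]] <- entry
      }
      cmp
    }
  })

  ## networks, communities, hubs per treated arm
  summary$network <- list(); summary$diffnet <- list()
  summary$communities <- list(); summary$hubs <- list()
  summary$enrichment <- list()
  annot <- if (!is.null(config$annotation)) {
    stage("enrichment", read_gmt(config$annotation,
                                 universe = rownames(counts)))
  } else NULL

  for (tr in treats) {
    genes <- unique(c(as_gene_ids(de[[tr]]$up), as_gene_ids(de[[tr]]$down)))
    if (length(genes) < 3) {
      note("arm %s: %d DE genes — network stages skipped", tr, length(genes))
      summary$network[[tr]] <- list(skipped = "fewer than 3 DE genes")
      next
    }
    ctrl_samples <- design$sample_id[design$condition == control]
    treat_samples <- design$sample_id[design$condition == tr]
    nets <- stage(paste0("network_", tr), {
      matched_networks(genes,
                       expr_control = norm$expr[, ctrl_samples, drop = FALSE],
                       expr_treat = norm$expr[, treat_samples, drop = FALSE],
                       fdr_max = config$net_fdr, rho_min = config$rho_min)
    })
    write_edge_list(nets$treat, file.path(config$out_dir,
                                          sprintf("network_%s.tsv", tr)))
    write_edge_list(nets$control, file.path(config$out_dir,
                                            sprintf("network_%s_control.tsv", tr)))
    write_graphml(nets$treat, file.path(config$out_dir,
                                        sprintf("network_%s.graphml", tr)))
    net_sum <- network_summary(nets$treat)
    summary$network[[tr]] <- list(
      n_nodes = net_sum$n_nodes, n_edges = net_sum$n_edges,
      density = net_sum$density, n_components = net_sum$n_components)
    if (net_sum$n_edges == 0) note("arm %s: network has no edges", tr)

    cmpnet <- stage(paste0("diffnet_", tr), {
      compare_networks(nets$control, nets$treat,
                       labels = c("control", tr))
    })
    summary$diffnet[[tr]] <- list(
      control_edges = cmpnet$networks[[1]]$n_edges,
      treat_edges = cmpnet$networks[[2]]$n_edges,
      edge_jaccard = cmpnet$edge_jaccard,
      ks_statistic = cmpnet$ks_statistic)
    write_json_report(unclass(cmpnet),
                      file.path(config$out_dir, sprintf("diffnet_%s.json", tr)))

    comm <- stage(paste0("communities_", tr), {
      tree <- walktrap_dendrogram(nets$treat, steps = config$walktrap_t)
      part <- best_partition(tree)
      big <- large_communities(part, min_size = config$min_community)
      write_atomic(file.path(config$out_dir, sprintf("communities_%s.tsv", tr)),
                   function(tmp) utils::write.table(
                     data.frame(gene_id = names(part$membership),
                                community = unname(part$membership)),
                     tmp, sep = "\t", quote = FALSE, row.names = FALSE))
      list(tree = tree, partition = part, big = big)
    })
    summary$communities[[tr]] <- list(
      n_communities = comm$partition$n_communities,
      modularity = comm$partition$q,
      n_large = length(comm$big),
      large_sizes = unname(lengths(comm$big)))

    hubs <- stage(paste0("hubs_", tr), {
      scores <- hub_scores(centralities(nets$treat))
      if (length(comm$big) > 0) {
        sel <- select_hubs(comm$partition, scores, k = config$hub_k,
                           communities = comm$big)
        rep <- removal_report(nets$treat, sel,
                              baseline_repeats = config$baseline_repeats,
                              seed = config$seed)
        list(scores = scores, selected = sel, report = rep)
      } else {
        note("arm %s: no community reaches %d nodes — hub selection skipped",
             tr, config$min_community)
        list(scores = scores, selected = NULL, report = NULL)
      }
    })
    prov <- attr(hubs$selected, "provenance")
    hub_tab <- hubs$scores
    hub_tab$selected <- hub_tab$gene_id %in% as_gene_ids(hubs$selected)
    write_atomic(file.path(config$out_dir, sprintf("hubs_%s.tsv", tr)),
                 function(tmp) utils::write.table(hub_tab, tmp, sep = "\t",
                                                  quote = FALSE,
                                                  row.names = FALSE))
    summary$hubs[[tr]] <- list(
      n_selected = length(as_gene_ids(hubs$selected)),
      mean_geodesic_before = if (!is.null(hubs$report)) hubs$report$before$mean_geodesic,
      mean_geodesic_after = if (!is.null(hubs$report)) hubs$report$after$mean_geodesic)
    if (!is.null(hubs$report)) {
      write_json_report(unclass(hubs$report)[c("before", "after", "removed")],
                        file.path(config$out_dir, sprintf("removal_%s.json", tr)))
    }

    if (!is.null(annot) && length(comm$big) > 0) {
      enr <- stage(paste0("enrichment_", tr), {
        lapply(comm$big, function(gs) {
          fisher_enrichment(intersect(as_gene_ids(gs), annot$universe), annot)
        })
      })
      for (cn in names(enr)) {
        write_atomic(file.path(config$out_dir,
                               sprintf("enrichment_%s_%s.tsv", tr, cn)),
                     function(tmp) utils::write.table(enr[[cn]], tmp, sep = "\t",
                                                      quote = FALSE,
                                                      row.names = FALSE))
      }
      summary$enrichment[[tr]] <- lapply(enr, function(tab) {
        list(n_terms = nrow(tab), min_fdr = if (nrow(tab)) min(tab$fdr) else NA)
      })
    }
  }
  if (is.null(annot)) summary$enrichment <- list(skipped = "no annotation supplied")

  write_json_report(summary, file.path(config$out_dir, "summary.json"))
  flush_log()
  invisible(summary)
}
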