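# Configuration-driven orchestration of the full analysis:
# prep -> rates -> GO acceleration -> selection -> convergence ->
# enrichment -> network, with persisted intermediates and a run report.

#' Build a pipeline configuration
#'
#' All thresholds of the analysis in one auditable object. Paths are
#' resolved at run time; `run_pipeline()` writes the resolved configuration
#' beside its outputs.
#'
#' @param input_dir Directory containing `alignments/` (codon FASTA per
#'   gene), `proteins/` (protein FASTA per gene, optional), `tree.nwk`,
#'   `annotations.tsv`, `expression.tsv`, `ppi.tsv`.
#' @param out_dir Output directory.
#' @param foreground Foreground branch for the branch-site test.
#' @param rate_pair Two branch ids compared in the lineage-rate stage.
#' @param convergence_pair Two branch ids for parallel/convergent detection.
#' @param e_cutoff,omega_max,ds_max,pp_min,psg_alpha,min_go_genes,
#'   min_subnet_nodes,degree_min,folds Stage thresholds.
#' @param seed Integer seed recorded in the report.
#' @param resume Reuse persisted stage outputs when present (default FALSE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            foreground = "zokor",
                            rate_pair = c("zokor", "rat"),
                            convergence_pair = c("zokor", "naked_mole_rat"),
                            e_cutoff = 1e-5, omega_max = 4, ds_max = 1,
                            pp_min = 0.9, psg_alpha = 0.05,
                            min_go_genes = 20L, min_subnet_nodes = 6L,
                            degree_min = 100L, folds = c(1.5, 3, 4.5),
                            seed = 1L, resume = FALSE) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir,
              foreground = foreground, rate_pair = rate_pair,
              convergence_pair = convergence_pair, e_cutoff = e_cutoff,
              omega_max = omega_max, ds_max = ds_max, pp_min = pp_min,
              psg_alpha = psg_alpha, min_go_genes = min_go_genes,
              min_subnet_nodes = min_subnet_nodes, degree_min = degree_min,
              folds = folds, seed = seed, resume = resume)
  thr <- c(e_cutoff, omega_max, ds_max, pp_min, psg_alpha, min_go_genes,
           min_subnet_nodes, degree_min, folds)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order on the inputs named by the configuration,
#' persisting every intermediate as TSV/JSON under `out_dir`. Reruns with an
#' identical configuration and inputs produce byte-identical outputs
#' (wall-clock timing is written separately to `timing.log`); with
#' `resume = TRUE`, stages whose persisted outputs exist are not recomputed.
#'
#' @param config A `pipeline_config`.
#' @return A `run_report`: per-stage record counts in/out, parameter echo,
#'   package version, seed and wall-clock seconds.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  t_start <- Sys.time()
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  state_dir <- file.path(out, "state")
  dir.create(state_dir, showWarnings = FALSE)
  cfg_json <- config
  cfg_json$resume <- NULL
  jsonlite::write_json(unclass(cfg_json), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  counts <- list()
  stage <- function(name, fn) {
    rds <- file.path(state_dir, paste0(name, ".rds"))
    if (isTRUE(config$resume) && file.exists(rds)) return(readRDS(rds))
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    saveRDS(res, rds)
    res
  }

  # -- load & prep ---------------------------------------------------------
  prep <- stage("prep", function() {
    tree <- prepare_tree(file.path(config$input_dir, "tree.nwk"))
    files <- sort(list.files(file.path(config$input_dir, "alignments"),
                             pattern = "\\.fasta$", full.names = TRUE))
    alns <- lapply(files, read_codon_fasta)
    names(alns) <- sub("\\.fasta$", "", basename(files))
    trimmed <- lapply(alns, trim_codon_blocks)
    keep <- vapply(trimmed, filter_alignment_length, logical(1))
    list(tree = tree, alignments = trimmed[keep],
         n_in = length(alns), n_out = sum(keep))
  })
  counts$prep <- c(n_in = prep$n_in, n_out = prep$n_out)
  tree <- prep$tree
  alns <- prep$alignments

  # -- free-ratio rates ----------------------------------------------------
  rates <- stage("rates", function() {
    recs <- lapply(names(alns), function(g)
      fit_free_ratio(alns[[g]], tree, gene = g))
    names(recs) <- names(alns)
    recs
  })
  rate_tab <- do.call(rbind, lapply(rates, function(r)
    cbind(gene = r$gene, r$branches, kappa = r$kappa, lnL = r$lnL)))
  write_tsv(rate_tab, file.path(out, "free_ratio.tsv"))

  filt <- stage("filters", function() {
    kept1 <- filter_rate_outliers(rates, config$rate_pair, config$omega_max)
    sat <- saturation_filter(kept1, config$rate_pair, config$ds_max)
    cmp <- if (length(sat$records) >= 2)
      compare_lineage_rates(sat$records, config$rate_pair[1], config$rate_pair[2])
    else NULL
    list(records = sat$records, diagnostic = sat$diagnostic,
         removed_outlier = attr(kept1, "removed"),
         removed_saturated = attr(sat$records, "removed"), comparison = cmp)
  })
  counts$rates <- c(n_in = length(rates), n_out = length(filt$records))
  write_tsv(filt$diagnostic, file.path(out, "saturation_diagnostic.tsv"))
  if (!is.null(filt$comparison))
    jsonlite::write_json(filt$comparison, file.path(out, "lineage_comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- GO category acceleration -------------------------------------------
  annotations <- utils::read.table(file.path(config$input_dir, "annotations.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  go <- stage("go_accel", function() {
    kept_genes <- record_genes(filt$records)
    cats <- go_category_rates(alns[kept_genes], annotations, tree,
                              lineages = config$rate_pair,
                              min_genes = config$min_go_genes)
    if (!length(cats)) return(list(categories = cats, tests = NULL))
    totals <- genome_nonsyn_totals(filt$records, alns, config$rate_pair)
    tests <- do.call(rbind, lapply(cats, function(cr)
      cbind(term = cr$term, n_genes = cr$n_genes,
            accelerated_category_test(cr, totals))))
    list(categories = cats, tests = tests)
  })
  counts$go_accel <- c(n_in = length(unique(annotations$term)),
                       n_out = length(go$categories))
  if (!is.null(go$tests)) write_tsv(go$tests, file.path(out, "go_acceleration.tsv"))

  # -- branch-site selection ----------------------------------------------
  sel <- stage("selection", function() {
    tests <- lapply(names(alns), function(g)
      branch_site_test(alns[[g]], tree, foreground = config$foreground,
                       gene = g))
    names(tests) <- names(alns)
    tests
  })
  p <- vapply(sel, function(x) x$p_value, numeric(1))
  q <- benjamini_hochberg(p)
  psg_tab <- data.frame(gene = names(sel),
                        lnL_null = vapply(sel, `[[`, numeric(1), "lnL_null"),
                        lnL_alt = vapply(sel, `[[`, numeric(1), "lnL_alt"),
                        statistic = vapply(sel, `[[`, numeric(1), "statistic"),
                        p_value = p, q_value = q,
                        omega2 = vapply(sel, function(x) x$params_alt$omega2,
                                        numeric(1)),
                        psg = p < config$psg_alpha,
                        stringsAsFactors = FALSE)
  write_tsv(psg_tab, file.path(out, "branch_site.tsv"))
  psg <- psg_tab$gene[psg_tab$psg]
  counts$selection <- c(n_in = length(sel), n_out = length(psg))
  beb_tab <- do.call(rbind, lapply(psg, function(g) {
    bb <- beb_site_posteriors(sel[[g]]$params_alt, alns[[g]], tree)
    cbind(gene = g, bb)
  }))
  if (!is.null(beb_tab)) write_tsv(beb_tab, file.path(out, "beb_sites.tsv"))

  # -- tissue specificity of PSGs -----------------------------------------
  expr_df <- utils::read.table(file.path(config$input_dir, "expression.tsv"),
                               header = TRUE, sep = "\t", check.names = FALSE,
                               stringsAsFactors = FALSE)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$gene
  if (length(psg)) {
    prof <- tissue_specificity_profile(expr, intersect(psg, rownames(expr)),
                                       config$folds)
    write_tsv(prof, file.path(out, "psg_tissue_profile.tsv"))
  }

  # -- convergence ---------------------------------------------------------
  conv <- stage("convergence", function() {
    pdir <- file.path(config$input_dir, "proteins")
    prots <- if (dir.exists(pdir)) {
      files <- sort(list.files(pdir, pattern = "\\.fasta$", full.names = TRUE))
      pl <- lapply(files, function(f) {
        x <- Biostrings::readAAStringSet(f)
        setNames(as.character(x), names(x))
      })
      names(pl) <- sub("\\.fasta$", "", basename(files))
      pl
    } else {
      lapply(alns, function(a)
        setNames(apply(a$codons, 1L, function(r)
          paste0(translate_codons(r), collapse = "")), a$taxa))
    }
    cls <- lapply(prots, function(pa) {
      asr <- marginal_ancestral_reconstruction(pa, tree)
      ev <- call_branch_substitutions(asr, pp_min = config$pp_min)
      classify_pairwise_changes(ev, config$convergence_pair, tree)
    })
    list(classifications = cls, summary = summarize_parallel_genes(cls))
  })
  peg <- names(conv$summary$counts)
  counts$convergence <- c(n_in = length(conv$classifications),
                          n_out = length(peg))
  cls_tab <- do.call(rbind, lapply(names(conv$classifications), function(g) {
    cl <- conv$classifications[[g]]
    if (!nrow(cl)) return(NULL)
    cbind(gene = g, cl)
  }))
  if (!is.null(cls_tab)) write_tsv(cls_tab, file.path(out, "pair_classification.tsv"))
  jsonlite::write_json(list(bin_sizes = as.list(conv$summary$bin_sizes),
                            n_parallel_genes = conv$summary$n_parallel_genes,
                            genes = conv$summary$bins),
                       file.path(out, "peg_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- enrichment ----------------------------------------------------------
  background <- sort(unique(annotations$gene))
  enr <- stage("enrichment", function() {
    res <- list()
    for (set in c("psg", "peg")) {
      cand <- intersect(if (set == "psg") psg else peg, background)
      res[[set]] <- if (length(cand))
        hypergeometric_enrichment(cand, background, annotations)
      else NULL
    }
    res
  })
  for (set in names(enr))
    if (!is.null(enr[[set]]))
      write_tsv(enr[[set]], file.path(out, paste0("enrichment_", set, ".tsv")))
  counts$enrichment <- c(n_in = length(background),
                         n_out = sum(vapply(enr, function(x)
                           if (is.null(x)) 0L else nrow(x), integer(1))))

  # -- network -------------------------------------------------------------
  ppi <- utils::read.table(file.path(config$input_dir, "ppi.tsv"),
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  net <- stage("network", function() {
    seeds <- union(psg, peg)
    sub <- extract_subnetworks(seeds, ppi, config$min_subnet_nodes)
    hubs <- high_degree_nodes(sub, config$degree_min,
                              candidate_labels(psg, peg))
    list(sub = sub, hubs = hubs)
  })
  counts$network <- c(n_in = length(union(psg, peg)),
                      n_out = net$sub$summary$mapped_seeds)
  jsonlite::write_json(net$sub$summary, file.path(out, "network_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv(net$hubs, file.path(out, "network_hubs.tsv"))

  wall <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  report <- list(counts = counts,
                 parameters = unclass(cfg_json),
                 version = as.character(utils::packageVersion("burrowevol")),
                 seed = config$seed)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat(sprintf("wall_clock_seconds\t%.3f\n", wall),
      file = file.path(out, "timing.log"))
  report$wall_clock_seconds <- wall
  structure(report, class = "run_report")
}

# Genome-wide expected nonsynonymous counts per lineage over a record set.
genome_nonsyn_totals <- function(records, alignments, lineages) {
  setNames(vapply(lineages, function(b)
    sum(vapply(records, function(r) {
      n_codons <- alignments[[as.character(r$gene)]]$n_codons
      expected_counts(r, b, n_codons, "nonsyn")
    }, numeric(1))), numeric(1)), lineages)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report (seed", x$seed, ")\n")
  for (s in names(x$counts))
    cat(sprintf("  %-12s in %4d  out %4d\n", s, x$counts[[s]][["n_in"]],
                x$counts[[s]][["n_out"]]))
  if (!is.null(x$wall_clock_seconds))
    cat(sprintf("  wall clock: %.1f s\n", x$wall_clock_seconds))
  invisible(x)
}
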