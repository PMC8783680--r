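#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run. Either a simulation config or
#' paths to an expression table + condition map must be given. Default
#' significance policy is raw p < 0.05 (proteome convention); pass
#' `mode = "bh_fdr"` for RNA-seq-style FDR control or `alpha = 0.10` for
#' low-power tissue data.
#'
#' @param simulation a [sim_config()], or `NULL` to load data from files.
#' @param expression_path,condition_map_path input files when not simulating.
#' @param gmt_path optional reference GMT; when simulating and absent, a
#'   synthetic collection built from the truth classes is used (and labelled
#'   as such in its name).
#' @param mode,alpha significance policy (see [significance_policy()]).
#' @param cutoff enrichment `-log10(p)` cutoff.
#' @param k k-means cluster count.
#' @param n_top molecules used for sample clustering.
#' @param seed integer seed recorded in every output and used for every
#'   stochastic stage.
#' @param out_dir output directory (created if needed).
#' @return A `RunConfig` list.
#' @export
run_config <- function(simulation = sim_config(),
                       expression_path = NULL, condition_map_path = NULL,
                       gmt_path = NULL,
                       mode = "raw_p", alpha = 0.05,
                       cutoff = 1.3, k = 10L, n_top = 500L,
                       seed = 1L, out_dir = tempfile("trajomics_run_")) {
  if (is.null(simulation) &&
      (is.null(expression_path) || is.null(condition_map_path)))
    stop("either `simulation` or expression/condition paths are required")
  if (!is.null(expression_path) && !file.exists(expression_path))
    stop("expression table not found: ", expression_path)
  if (!is.null(condition_map_path) && !file.exists(condition_map_path))
    stop("condition map not found: ", condition_map_path)
  if (!is.null(gmt_path) && !file.exists(gmt_path))
    stop("GMT not found: ", gmt_path)
  structure(list(simulation = simulation,
                 expression_path = expression_path,
                 condition_map_path = condition_map_path,
                 gmt_path = gmt_path,
                 policy = significance_policy(mode, alpha),
                 cutoff = cutoff, k = as.integer(k), n_top = as.integer(n_top),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "RunConfig")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                              auto_unbox = TRUE, force = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full perturbation-withdrawal pipeline
#'
#' simulate/load -> differential contrasts -> trajectory classification ->
#' Venn partition of the three contrasts' significant sets (plus reference
#' overlay when a GMT is given) -> Fisher enrichment of the
#' completely-reversed pool -> k-means / hierarchical concordance. Every
#' stage writes a TSV (or Newick) into `config$out_dir`; a JSON manifest
#' records the config, seed and an md5 for each output, so reruns with an
#' identical config reproduce identical hashes.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return the manifest, invisibly (list with `files`, `hashes`, `config`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  extra <- paste0("seed=", config$seed, " config=", hash)
  say <- function(...) if (!quiet) message("[trajomics] ", ...)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(df, path, extra = extra)
    outputs[[length(outputs) + 1]] <<- path
    path
  }

  # stage 1: data
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    ds <- simulate_dataset(sim)
    em <- ds$matrix; truth <- ds$truth
    write_expression(em, file.path(config$out_dir, "expression.tsv"),
                     file.path(config$out_dir, "condition_map.tsv"))
    outputs <- c(outputs, file.path(config$out_dir, "expression.tsv"),
                 file.path(config$out_dir, "condition_map.tsv"))
    emit(truth, "truth.tsv")
    say("simulate: ", nrow(em$values), " molecules, ",
        ncol(em$values), " samples")
  } else {
    em <- load_expression(config$expression_path, config$condition_map_path)
    say("load: ", nrow(em$values), " molecules")
  }

  # stage 2: differential contrasts
  contrasts <- run_contrasts(em, config$policy)
  emit(contrasts, "contrasts.tsv")
  n_sig <- sum(contrasts$significant)
  say("de: ", n_sig, " significant calls across 3 contrasts (",
      sum(contrasts$insufficient), " insufficient)")

  # stage 3: trajectory classification
  cls <- classify_dataset(contrasts, incomplete = "drop")
  emit(cls$assignments, "assignments.tsv")
  emit(data.frame(cluster = names(cls$counts), n = unname(cls$counts)),
       "cluster_counts.tsv")
  say("classify: ", sum(cls$counts[trajectory_classes()$letter]),
      " molecules in lettered clusters")
  if (!is.null(truth)) {
    conf <- recovery_confusion(cls$assignments, truth)
    cm <- as.data.frame.table(conf$confusion, responseName = "n")
    emit(cm, "confusion.tsv")
    say("classify: overall recovery ", sprintf("%.3f", conf$overall))
  }

  # stage 4: Venn partition of per-contrast significant sets
  sig_sets <- split(contrasts$molecule_id[contrasts$significant],
                    contrasts$contrast[contrasts$significant])
  sig_sets <- sig_sets[lengths(sig_sets) > 0]
  if (length(sig_sets) >= 2) {
    vp <- venn_partition(sig_sets[seq_len(min(3, length(sig_sets)))])
    emit(data.frame(region = names(venn_sizes(vp)), n = unname(venn_sizes(vp))),
         "venn_regions.tsv")
    say("overlap: ", sum(venn_sizes(vp) > 0), " non-empty Venn regions")
  } else {
    emit(data.frame(region = character(0), n = integer(0)), "venn_regions.tsv")
    say("overlap: fewer than 2 non-empty significant sets; empty Venn output")
  }

  # reference collection (given, or synthetic from truth)
  collection <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
  else if (!is.null(truth)) {
    by_class <- split(truth$molecule_id, truth$class)
    by_class <- by_class[lengths(by_class) > 0]
    gene_set_collection(setNames(by_class, paste0("SYNTHETIC_CLASS_", names(by_class))),
                        name = "synthetic_truth_classes")
  } else NULL
  if (!is.null(collection)) {
    ov <- overlay_reference(unique(contrasts$molecule_id[contrasts$significant]),
                            collection)
    emit(data.frame(set_name = names(ov$per_set_counts),
                    n_matched = unname(ov$per_set_counts)),
         "reference_overlay.tsv")
  }

  # stage 5: enrichment of the completely-reversed pool (letters e, f)
  universe <- molecule_ids(em)
  pool <- cls$assignments$molecule_id[cls$assignments$letter %in% c("e", "f")]
  if (!is.null(collection) && length(pool)) {
    s1 <- contrasts[contrasts$contrast == unique(contrasts$contrast)[1], ]
    fc <- setNames(s1$log2fc, s1$molecule_id)
    enr <- enrich_collection(pool, collection, universe, log2fc_of = fc,
                             cutoff = config$cutoff)
    emit(enr, "enrichment.tsv")
    say("enrich: ", sum(enr$passes_cutoff), " set(s) past -log10(p) >= ",
        config$cutoff)
  } else {
    emit(data.frame(), "enrichment.tsv")
  }

  # stage 6: concordance
  feats <- contrast_features(contrasts)
  lettered <- cls$assignments[!is.na(cls$assignments$letter), ]
  ari <- NA_real_
  if (nrow(feats) >= config$k) {
    km <- kmeans_features(feats, k = config$k, seed = config$seed)
    emit(data.frame(molecule_id = rownames(feats), kmeans = km$labels),
         "kmeans_labels.tsv")
    common <- intersect(rownames(feats), lettered$molecule_id)
    if (length(common) > 1) {
      ari <- adjusted_rand_index(
        lettered$letter[match(common, lettered$molecule_id)],
        km$labels[common])
    }
  }
  emit(data.frame(metric = "ARI_supervised_vs_kmeans", value = ari), "ari.tsv")
  say("concord: ARI = ", sprintf("%.3f", ari))
  hs <- hclust_samples(em, n_top = config$n_top)
  nwk <- file.path(config$out_dir, "samples.nwk")
  write_newick(hs$hclust, nwk)
  outputs <- c(outputs, nwk)

  # manifest
  manifest <- list(tool = "trajomics",
                   version = as.character(packageVersion("trajomics")),
                   seed = config$seed,
                   config_hash = hash,
                   config = config[setdiff(names(config), "out_dir")],
                   files = basename(outputs),
                   hashes = setNames(unname(tools::md5sum(outputs)),
                                     basename(outputs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE, digits = NA)
  invisible(manifest)
}
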