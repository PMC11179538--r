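#' End-to-end pipeline on a synthetic study
#'
#' Runs the eight analysis stages in order on a seeded synthetic study --
#' saturation screen, rate fits, fast genes, trends, OU selection,
#' branch-site selection, RMR correlation, enrichment -- writing each
#' stage's table before the next starts, plus a run manifest and the overlap
#' summaries. Stages operate through the same exported functions a user
#' would call directly; per-gene seeds derive from the master seed so any
#' execution order gives identical output.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @param L alignment length controlling rate-estimation precision.
#' @param n_iter MCMC iterations per chain per gene.
#' @param selection_codons codon-alignment length for the selection stage.
#' @param selection_background number of non-selected genes also put through
#'   the branch-site test.
#' @param resume skip stages whose output file already exists.
#' @return invisible list of stage outputs; files under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, L = 10000L, n_iter = 6000L,
                         selection_codons = 150L, selection_background = 2L,
                         resume = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(name) file.path(out_dir, name)
  wr <- function(df, name) {
    df_fmt <- df
    num <- vapply(df_fmt, is.numeric, logical(1))
    df_fmt[num] <- lapply(df_fmt[num], function(x) sprintf("%.10g", x))
    write.table(df_fmt, tsv(name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  stages <- character(0)
  done <- function(name) resume && file.exists(tsv(name))

  study <- simulate_study(config)
  tree <- study$tree
  write_newick(tree, tsv("time_tree.nwk"))
  wr(study$traits, "traits.tsv")

  # stage 2 first computationally (rates feed the saturation pre-filter),
  # but the screen is reported before downstream calls use the matrix
  est <- estimate_rate_matrix(study, L = L, n_iter = n_iter)
  genes <- colnames(est$R)

  ## stage 1: saturation screen -------------------------------------------
  if (!done("saturation.tsv")) {
    blens <- lapply(seq_along(study$genes), function(i) est$fits[[i]]$d_e)
    names(blens) <- genes
    cand <- vapply(blens, saturation_prefilter, logical(1))
    iss_c <- if (any(cand))
      critical_iss(ape::Ntip(tree), 400L, reps = 120L,
                   seed = config$seed + 11L)$iss_c else NA_real_
    alns <- list()
    for (g in genes[cand]) {
      i <- match(g, genes)
      alns[[g]] <- gen_alignment_nt(tree, study$genes[[i]]$process$d_e, 1000L,
                                    seed = gene_seed(config$seed, i) + 3L)
    }
    sat <- if (any(cand)) saturation_screen(blens, alns, iss_c) else
      data.frame(gene = genes, candidate = FALSE, iss = NA_real_,
                 p = NA_real_, decision = "retain")
    wr(sat, "saturation.tsv")
  }
  stages <- c(stages, "saturation")

  ## stage 2: rate fits ----------------------------------------------------
  if (!done("rate_matrix.tsv")) {
    rm_df <- data.frame(species = rownames(est$R), est$R,
                        check.names = FALSE)
    wr(rm_df, "rate_matrix.tsv")
    diag_df <- data.frame(gene = genes,
                          converged = est$converged,
                          sigma2 = vapply(est$fits, `[[`, numeric(1), "sigma2"))
    wr(diag_df, "rate_diagnostics.tsv")
  }
  stages <- c(stages, "rates")

  ## stage 3: fast genes ---------------------------------------------------
  fast <- call_fast_genes(est$R, focal = "F1")
  wr(fast, "fast_genes.tsv")
  stages <- c(stages, "fast_genes")

  ## stage 4: trends -------------------------------------------------------
  node_rates <- vapply(est$fits, `[[`, numeric(length(est$fits[[1]]$rate)),
                       "rate")
  colnames(node_rates) <- genes
  trend <- detect_trend_genes(node_rates, tree, focal = "F1")
  wr(trend, "trends.tsv")
  stages <- c(stages, "trends")

  ## stage 5: OU model selection (fast genes; all genes if none) -----------
  ou_set <- if (any(fast$fast)) fast$gene[fast$fast] else genes
  ou <- ou_select_genes(est$R[, ou_set, drop = FALSE], tree)
  wr(ou, "ou_selection.tsv")
  stages <- c(stages, "ou_selection")

  ## stage 6: branch-site selection ----------------------------------------
  sel_idx <- which(study$truth$classes == "selected")
  bg_idx <- setdiff(seq_along(genes), sel_idx)
  bg_idx <- bg_idx[seq_len(min(selection_background, length(bg_idx)))]
  sel_rows <- lapply(c(sel_idx, bg_idx), function(i) {
    aln <- gen_alignment_codon(tree, config,
                               selected = i %in% sel_idx,
                               branch_subs = study$genes[[i]]$process$d_e * 3,
                               L_codons = selection_codons,
                               seed = gene_seed(config$seed, i) + 2L)
    fit <- branch_site_fit(aln, tree, foreground = "F1")
    data.frame(gene = genes[i], lnL_alt = fit$lnL_alt,
               lnL_null = fit$lnL_null, p = fit$p,
               n_sites = fit$filters$site_count,
               significant = fit$significant, stringsAsFactors = FALSE)
  })
  sel <- do.call(rbind, sel_rows)
  wr(sel, "selection.tsv")
  stages <- c(stages, "selection")

  ## stage 7: metabolic correlation ----------------------------------------
  if (!file.exists(tsv("traits.tsv"))) stop("stage metabolic: traits missing")
  tr_tab <- study$traits
  rmr_norm <- normalize_rmr(tr_tab$rmr_value, tr_tab$rmr_unit,
                            tr_tab$body_temp_C, rq = config$rq,
                            q10 = config$q10_true)
  names(rmr_norm) <- tr_tab$species
  ln_mass <- setNames(log(tr_tab$mass_g), tr_tab$species)
  pg <- pgls_slope(log(rmr_norm), ln_mass, tree)
  rmr_adj <- adjust_rmr(rmr_norm, exp(ln_mass), pg$b)
  corr <- correlation_screen(est$R, rmr_adj, tree)
  wr(data.frame(b = pg$b, lna = pg$lna, se_b = pg$se_b), "allometry.tsv")
  wr(corr, "rmr_correlation.tsv")
  stages <- c(stages, "metabolic")

  ## stage 8: enrichment ---------------------------------------------------
  enr_set <- fast$gene[fast$fast]
  enr <- hypergeom_enrich(enr_set, study$annotations, genes)
  wr(enr, "enrichment.tsv")
  stages <- c(stages, "enrichment")

  ## overlaps + manifest ---------------------------------------------------
  neg <- corr$gene[corr$classification == "negative"]
  ov <- data.frame(
    set = c("fast", "selected_sig", "trend", "negative_corr",
            "fast_and_selected", "fast_and_trend", "fast_and_negative"),
    n = c(length(enr_set), sum(sel$significant), sum(trend$trend),
          length(neg),
          length(intersect(enr_set, sel$gene[sel$significant])),
          length(intersect(enr_set, trend$gene[trend$trend])),
          length(intersect(enr_set, neg))))
  wr(ov, "overlaps.tsv")
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "")],
                               auto_unbox = TRUE, digits = NA)
  cfg_file <- tsv("config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(stages = stages, seed = config$seed,
                   n_genes = config$n_genes, n_taxa = config$n_taxa,
                   config_md5 = unname(md5sum(cfg_file)),
                   outputs = list.files(out_dir))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             tsv("manifest.json"))
  invisible(list(rates = est, fast = fast, trend = trend, ou = ou,
                 selection = sel, correlation = corr, allometry = pg,
                 enrichment = enr, overlaps = ov))
}
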