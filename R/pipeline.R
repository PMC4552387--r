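# Whole-pipeline orchestration: one call takes an alignment plus sample
# metadata and writes the standard report bundle (diversity table, gene-flow
# matrix, AMOVA table, neutrality tests, mismatch fits with expansion dates,
# haplotype network, optional tree-hypothesis classification).

#' Run the full phylogeographic analysis
#'
#' Deterministic given `seed`: stage seeds are derived from the master seed,
#' every stochastic stage logs its seed, and the whole bundle is
#' reproducible from the inputs plus `seed` alone. Stage failures are
#' caught; the bundle is still written with a per-stage status table and a
#' warning.
#'
#' @param fasta path to the alignment FASTA (or a [seq_alignment()]).
#' @param metadata path to the sample-metadata TSV (or a data frame).
#' @param out_dir output directory (created if needed).
#' @param tree optional Newick file (or `ape::phylo`) for hypothesis
#'   classification; requires `region`/`paic` metadata columns.
#' @param permutations permutations for AMOVA / Fst tests (default 10000).
#' @param sim_reps coalescent replicates for neutrality p-values (default
#'   1000).
#' @param boot_B parametric-bootstrap replicates for the tau interval
#'   (default 3000).
#' @param rates mutation-rate calibrations, substitutions/site/year.
#' @param k sites used for dating; default the post-filter alignment length.
#' @param convention dating convention, see [expansion_time()].
#' @param seed master RNG seed (mandatory).
#' @param min_n smallest population analysed for neutrality/mismatch stages.
#' @return (invisibly) list with the computed objects, output paths and a
#'   per-stage status data frame.
#' @export
run_full_analysis <- function(fasta, metadata, out_dir, tree = NULL,
                              permutations = 10000, sim_reps = 1000,
                              boot_B = 3000, rates = default_rates, k = NULL,
                              convention = "table", seed, min_n = 4) {
  if (missing(seed)) stop("a master seed is mandatory", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- if (inherits(fasta, "seq_alignment")) fasta else read_alignment(fasta)
  meta <- if (is.data.frame(metadata)) {
    validate_grouping(metadata); metadata
  } else read_sample_metadata(metadata)
  meta <- check_grouping(aln, meta)
  status <- list()
  bundle <- list(out_dir = out_dir, seed = seed)
  run_stage <- function(name, expr) {
    res <- tryCatch(list(value = expr, ok = TRUE, error = NA_character_),
                    error = function(e) list(value = NULL, ok = FALSE,
                                             error = conditionMessage(e)))
    status[[name]] <<- data.frame(stage = name, ok = res$ok, error = res$error)
    res$value
  }
  p <- function(f) file.path(out_dir, f)
  pops <- sort(unique(meta$population))

  bundle$haplotypes <- run_stage("haplotypes", {
    tab <- collapse_haplotypes(aln, meta)
    write_haplotype_table(tab, p("haplotypes.tsv"))
    tab
  })
  if (is.null(k)) k <- if (!is.null(bundle$haplotypes)) bundle$haplotypes$L_eff else aln$L

  bundle$diversity <- run_stage("diversity", {
    dt <- diversity_table(aln, meta)
    dt$gb_category <- NA_integer_
    ok <- !is.na(dt$Hd)
    dt$gb_category[ok] <- grant_bowen_category(dt$Hd[ok], dt$pi[ok])$category
    utils::write.table(dt, p("diversity.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    dt
  })

  bundle$geneflow <- run_stage("geneflow", {
    gf <- geneflow_matrix(aln, meta, permutations = permutations,
                          seed = seed + 101L)
    utils::write.table(gf$display, p("geneflow_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    gf
  })

  bundle$amova <- run_stage("amova", {
    d <- pairwise_difference_matrix(aln)
    am <- amova3(d, meta, permutations = permutations, seed = seed + 202L)
    utils::write.table(am$table, p("amova.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    am
  })

  bundle$neutrality <- run_stage("neutrality", {
    rows <- list()
    for (i in seq_along(pops)) {
      m <- pop_matrix(aln, meta, pops[i])
      if (nrow(m) < min_n) next
      obs <- observed_neutrality_stats(m)
      if (obs$S < 1) next
      nt <- neutrality_test(m, reps = sim_reps, seed = seed + 303L + i)
      nt$population <- pops[i]
      rows[[pops[i]]] <- nt
    }
    out <- do.call(rbind, rows)
    utils::write.table(out, p("neutrality.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out
  })

  bundle$mismatch <- run_stage("mismatch", {
    fits <- list()
    for (i in seq_along(pops)) {
      m <- pop_matrix(aln, meta, pops[i])
      if (nrow(m) < min_n) next
      obs <- observed_mismatch(m)
      if (max(which(as.numeric(obs) > 0)) == 1) next  # no variation
      fit <- fit_expansion(obs, n = nrow(m))
      ci <- bootstrap_tau_ci(fit, L = k, B = boot_B, seed = seed + 404L + i)
      dt <- dating_table(fit$model$tau, ci, rates = rates, k = k,
                        convention = convention)
      write_mismatch(obs, fit, p(sprintf("mismatch_%s.tsv", pops[i])))
      utils::write.table(dt, p(sprintf("dating_%s.tsv", pops[i])), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      fits[[pops[i]]] <- list(fit = fit, ci = ci, dating = dt)
    }
    fits
  })

  bundle$network <- run_stage("network", {
    net <- median_joining_network(bundle$haplotypes)
    write_network(net, p("network_nodes.tsv"), p("network_edges.tsv"),
                  p("network.graphml"))
    net
  })

  if (!is.null(tree)) {
    bundle$classification <- run_stage("classification", {
      tr <- if (inherits(tree, "phylo")) tree else ape::read.tree(tree)
      cls <- classify_paic_pattern(tr, meta)
      write_classification(cls, p("classification.json"))
      cls
    })
  }

  status_df <- do.call(rbind, status)
  rownames(status_df) <- NULL
  bundle$status <- status_df
  utils::write.table(status_df, p("status.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log <- list(package_version = as.character(utils::packageVersion("paicdemog")),
              seed = seed, permutations = permutations, sim_reps = sim_reps,
              boot_B = boot_B, rates = as.list(rates), k = k,
              convention = convention, populations = pops,
              stage_seeds = list(geneflow = seed + 101L, amova = seed + 202L,
                                 neutrality = paste0(seed + 303L, "+pop_index"),
                                 mismatch = paste0(seed + 404L, "+pop_index")))
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE, pretty = TRUE)
  if (!all(status_df$ok)) {
    warning("stages failed: ",
            paste(status_df$stage[!status_df$ok], collapse = ", "))
  }
  invisible(bundle)
}
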