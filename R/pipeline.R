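#' Configuration for the end-to-end analysis pipeline
#'
#' Defaults mirror the published analysis settings: 1,000 permutations for
#' the differentiation and Mantel tests, 10,000 AMOVA permutations, 1,000
#' bootstrap replicates, the 95% parsimony connection limit, rate
#' mu = 1.52e-9 s/s/y, sequence length k = 2106 bp and a one-year
#' generation time. Search/replicate sizes can be scaled down for quick
#' runs.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param n_perm Permutations for G_ST/N_ST, pairwise Phi_ST and Mantel.
#' @param n_perm_amova Permutations for the hierarchical AMOVA.
#' @param n_boot Bootstrap replicates (NJ supports, dating interval,
#'   mismatch parametric bootstrap).
#' @param connection_p Parsimony connection probability limit.
#' @param count_policy Count-assignment policy for the rebuilt dataset.
#' @param samova_K Values of K to scan.
#' @param samova_rep,samova_steps SAMOVA repetitions and annealing steps.
#' @param mu,k,g Clock rate, sequence length, generation time.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_perm = 1000L, n_perm_amova = 10000L,
                       n_boot = 1000L, connection_p = 0.95,
                       count_policy = "widespread-major",
                       samova_K = 2:10, samova_rep = 100L,
                       samova_steps = 10000L,
                       mu = 1.52e-9, k = 2106L, g = 1,
                       out_dir = NULL) {
  stopifnot(n_perm >= 1L, n_perm_amova >= 1L, n_boot >= 1L,
            connection_p > 0, connection_p < 1)
  structure(list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                 n_perm_amova = as.integer(n_perm_amova),
                 n_boot = as.integer(n_boot), connection_p = connection_p,
                 count_policy = count_policy, samova_K = samova_K,
                 samova_rep = as.integer(samova_rep),
                 samova_steps = as.integer(samova_steps),
                 mu = mu, k = k, g = g, out_dir = out_dir),
            class = "run_config")
}

#' Run the complete cpDNA phylogeography pipeline on the packaged dataset
#'
#' Executes, in order: dataset rebuild and alignment synthesis, variable-site
#' scanning and haplotype calling (with and without indels), diversity and
#' the Pons & Petit G_ST/N_ST permutation test, pairwise Phi_ST, AMOVA (on
#' the SAMOVA K = 2 grouping), the SAMOVA K-scan, Mantel
#' isolation-by-distance, NJ tree with bootstrap and midpoint rooting, the
#' statistical-parsimony network, strict-clock dating of the two
#' haplogroups, and mismatch-distribution analyses per haplogroup. Every
#' stochastic stage is seeded deterministically from `config$seed`.
#'
#' @param config A [run_config()].
#' @return Nested list of stage results plus a flat `summary` list; when
#'   `config$out_dir` is set, per-stage TSV/newick files and a
#'   machine-readable `summary.json` are written there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  const <- hv_constants()

  ## stage 1: fixture rebuild + synthetic alignment round trip
  hm_ref <- load_table2()
  pd <- rebuild_published_dataset(config$count_policy)
  inds <- expand_individuals(pd)
  assignments <- stats::setNames(inds$haplotype, inds$individual_id)
  aln <- synth_alignment(hm_ref, assignments, seed = config$seed)
  sites <- scan_variable_sites(aln)
  hm <- call_haplotypes(aln, sites, reference = hm_ref)
  hm_sub <- call_haplotypes(aln, sites, mode = "substitutions_only")
  d <- pairwise_steps(hm_ref)

  ## stage 2: diversity + differentiation
  div <- permut_stats(pd$counts, d, L = config$k)
  gn <- gst_nst_test(pd$counts, d, n_perm = config$n_perm,
                     seed = config$seed + 1L)

  ## stage 3: spatial structure
  fst <- pairwise_phist(pd$counts, d, n_perm = 0L)
  geo <- geo_matrix(pd$coords)
  mt <- mantel_test(fst$phist, geo, n_perm = config$n_perm,
                    seed = config$seed + 2L)
  sam <- lapply(config$samova_K, function(K)
    samova(pd$counts, d, pd$coords, K, n_rep = config$samova_rep,
           n_steps = config$samova_steps, seed = config$seed + 10L + K))
  names(sam) <- paste0("K", config$samova_K)
  am <- amova(pd$counts, d, grouping = sam[[1L]]$grouping,
              n_perm = config$n_perm_amova, seed = config$seed + 3L)

  ## stage 4: tree, network, dating
  nj <- nj_bootstrap(hm_ref, n_reps = config$n_boot,
                     seed = config$seed + 4L)
  tree <- phangorn::midpoint(nj$tree)
  net <- tcs_network(hm_ref, freqs = colSums(pd$counts),
                     p = config$connection_p)
  dat <- strict_clock_age(hm_ref, const$hpg1, const$hpg2, mu = config$mu,
                          L = config$k, n_boot = config$n_boot,
                          seed = config$seed + 5L)

  ## stage 5: demography per haplogroup
  demog <- lapply(list(HPG_I = const$hpg1, HPG_II = const$hpg2),
                  function(grp) {
    cvec <- colSums(pd$counts)[grp]
    f <- mismatch_distribution(cvec, d, counts = TRUE)
    fit <- fit_sudden_expansion(f)
    pb <- parametric_bootstrap(fit, n = sum(cvec), B = config$n_boot,
                               seed = config$seed + 6L)
    et <- expansion_time(fit$tau, config$mu, config$k, config$g)
    list(spectrum = f, fit = fit, bootstrap = pb, time = et)
  })

  summary <- list(
    n_individuals = sum(pd$counts),
    n_populations = nrow(pd$counts),
    n_haplotypes = nrow(hm),
    n_haplotypes_substitutions_only = nrow(hm_sub),
    n_variable_sites = nrow(sites),
    n_substitutions = sum(sites$kind == "substitution"),
    n_indels = sum(sites$kind == "indel"),
    HS = div$HS, HT = div$HT, GST = div$GST,
    VS = div$VS, VT = div$VT, NST = div$NST,
    gst_nst_p = gn$p,
    species_h = div$h_species, species_pi = div$pi_species,
    mantel_r = mt$r, mantel_p = mt$p,
    amova_FST = am$FST, amova_FCT = am$FCT,
    samova_FCT = vapply(sam, function(s) s$FCT, numeric(1L)),
    split_age_myr = dat$age_myr,
    tau = vapply(demog, function(x) x$fit$tau, numeric(1L)),
    expansion_myr = vapply(demog, function(x) x$time$myr, numeric(1L)),
    p_ssd = vapply(demog, function(x) x$bootstrap$p_ssd, numeric(1L)),
    p_rag = vapply(demog, function(x) x$bootstrap$p_rag, numeric(1L)),
    seed = config$seed)

  res <- list(config = config, alignment = aln, sites = sites,
              haplotypes = hm, haplotypes_substitutions_only = hm_sub,
              steps = d, pop_data = pd, diversity = div, gst_nst = gn,
              phist = fst, mantel = mt, samova = sam, amova = am,
              nj = nj, tree = tree, network = net, dating = dat,
              demography = demog, summary = summary)

  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hm <- res$haplotypes
  write_tsv(data.frame(haplotype = rownames(hm), unclass_hm(hm),
                       check.names = FALSE),
            file.path(out_dir, "haplotype_matrix.tsv"))
  a <- attr(hm, "assignments")
  write_tsv(data.frame(individual_id = names(a), haplotype = a),
            file.path(out_dir, "haplotype_assignments.tsv"))
  write_tsv(data.frame(haplotype = rownames(res$steps), res$steps,
                       check.names = FALSE),
            file.path(out_dir, "step_distances.tsv"))
  div <- res$diversity
  write_tsv(data.frame(code = rownames(res$pop_data$counts),
                       n = rowSums(res$pop_data$counts),
                       h = round(div$h_pop, 3)),
            file.path(out_dir, "population_diversity.tsv"))
  ape::write.tree(res$tree, file.path(out_dir, "nj_tree.nwk"))
  write_tsv(res$network$edges, file.path(out_dir, "network_edges.tsv"))
  write_network_gml(res$network, file.path(out_dir, "network.gml"))
  demog_tab <- data.frame(
    group = names(res$demography),
    SSD = vapply(res$demography, function(x) x$fit$ssd, numeric(1L)),
    P_SSD = vapply(res$demography, function(x) x$bootstrap$p_ssd, numeric(1L)),
    Rag = vapply(res$demography, function(x) raggedness(x$spectrum),
                 numeric(1L)),
    P_Rag = vapply(res$demography, function(x) x$bootstrap$p_rag, numeric(1L)),
    tau = vapply(res$demography, function(x) x$fit$tau, numeric(1L)),
    expansion_myr = vapply(res$demography, function(x) x$time$myr,
                           numeric(1L)))
  write_tsv(demog_tab, file.path(out_dir, "mismatch_analyses.tsv"))
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a haplotype network in GML format
#'
#' @param net A `haplo_network`.
#' @param path Output file.
#' @export
write_network_gml <- function(net, path) {
  ids <- stats::setNames(seq_len(nrow(net$nodes)) - 1L, net$nodes$label)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph [", con)
  for (i in seq_len(nrow(net$nodes))) {
    writeLines(sprintf(
      '  node [ id %d label "%s" type "%s" freq %g ]',
      ids[i], net$nodes$label[i], net$nodes$type[i], net$nodes$freq[i]), con)
  }
  for (e in seq_len(nrow(net$edges))) {
    writeLines(sprintf("  edge [ source %d target %d ]",
                       ids[net$edges$from[e]], ids[net$edges$to[e]]), con)
  }
  writeLines("]", con)
  invisible(path)
}
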