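# End-to-end orchestration: alignment -> diversity -> network/MOTUs ->
# neutrality -> RLR, with reproducible TSV outputs.

# locality code of a specimen id "<code>_<i>"
locality_from_id <- function(ids) sub("_[^_]*$", "", ids)

#' Run the full comparative phylogeographic analysis
#'
#' Executes every stage for one or more species and writes a report bundle:
#' a per-locality diversity table, a neutrality table (complete dataset
#' plus one row per MOTU), network exports, MOTU assignments, an optional
#' McDonald-Kreitman table (first two species) and, when genealogy samples
#' are supplied, a relative-probability-score table per species. Reruns
#' with the same configuration are byte-identical.
#'
#' @param cfg configuration list (or path to a JSON file with the same
#'   fields): \code{species} — named list, one entry per species with
#'   \code{fasta} (aligned FASTA whose ids are \code{"<locality>_<i>"}) and
#'   optionally \code{trees} (Newick/NEXUS rooted genealogy sample) and
#'   \code{motu_level} (nesting level, default 2); \code{locality_table} —
#'   path to the locality TSV (optional); \code{pooling} — path to a
#'   pooling-map TSV (optional); \code{confidence} — parsimony connection
#'   confidence (default 0.95); \code{neutrality_reps} — coalescent
#'   simulations per p-value (default 1000); \code{seed} — integer;
#'   \code{outdir} — output directory.
#' @return invisibly, a named list with every per-species result and the
#'   paths written.
#' @export
run_full_analysis <- function(cfg) {
  if (is.character(cfg)) cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  stopifnot(!is.null(cfg$species), !is.null(cfg$outdir))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  reps <- if (is.null(cfg$neutrality_reps)) 1000L else
    as.integer(cfg$neutrality_reps)
  conf <- if (is.null(cfg$confidence)) 0.95 else cfg$confidence
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  loc_table <- if (!is.null(cfg$locality_table))
    stage("localities", read_locality_table(cfg$locality_table)) else NULL
  pooling <- if (!is.null(cfg$pooling))
    stage("pooling", read_pooling_map(cfg$pooling)) else NULL

  results <- list(); paths <- list()
  table1 <- NULL; table2 <- NULL
  for (sp in names(cfg$species)) {
    spc <- cfg$species[[sp]]
    aln <- stage(paste0("read:", sp), read_fasta_alignment(spc$fasta))
    locs <- locality_from_id(aln$ids)
    index <- stage(paste0("collapse:", sp),
                   collapse_haplotypes(aln, stats::setNames(locs, aln$ids)))
    per <- stage(paste0("diversity:", sp),
                 per_locality_summary(index, loc_table))
    per <- cbind(species = sp, per)
    table1 <- rbind(table1, per)

    limit <- parsimony_connection_limit(aln$L, conf)
    coords <- if (!is.null(loc_table)) loc_table$localities else NULL
    net <- stage(paste0("network:", sp),
                 resolve_loops(build_parsimony_network(index, limit,
                                                       coords = coords)))
    motu_level <- if (is.null(spc$motu_level)) 2L else
      as.integer(spc$motu_level)
    design <- stage(paste0("nesting:", sp),
                    build_nesting_design(net, max_level = motu_level))
    motus <- stage(paste0("motus:", sp), assign_motus(design, motu_level))

    units <- c("complete",
               unique(motus[order(as.integer(sub("^MOTU", "", motus)))]))
    rows <- lapply(units, function(u) {
      sub_aln <- if (u == "complete") expand_index(index) else
        expand_index(index, labels = names(motus)[motus == u])
      sm <- complete_summaries(sub_aln)
      td <- .d_from_summaries(sm$n, sm$S, sm$kbar)
      fs <- .fs_from_summaries(sm$n, sm$k_hap, sm$kbar)
      pd <- pfs <- NA_real_
      if (!is.na(td))
        pd <- coalescent_null_pvalue(sub_aln, "D", reps = reps,
                                     seed = seed)$p
      if (!is.na(fs))
        pfs <- coalescent_null_pvalue(sub_aln, "Fs", reps = reps,
                                      seed = seed + 1L)$p
      data.frame(species = sp, unit = u, N = sm$n, H = sm$k_hap,
                 D = td, p_D = pd, sig_D = !is.na(pd) & pd < 0.05,
                 Fs = fs, p_Fs = pfs, sig_Fs = !is.na(pfs) & pfs < 0.02,
                 stringsAsFactors = FALSE)
    })
    table2 <- rbind(table2, do.call(rbind, rows))

    net_path <- file.path(cfg$outdir, paste0("network_", sp, ".graphml"))
    export_network(net, net_path)
    motu_path <- file.path(cfg$outdir, paste0("motus_", sp, ".tsv"))
    utils::write.table(data.frame(haplotype = names(motus), motu = motus),
                       motu_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[paste0("network_", sp)]] <- net_path
    paths[[paste0("motus_", sp)]] <- motu_path

    rps <- NULL
    if (!is.null(spc$trees)) {
      trees <- stage(paste0("trees:", sp),
                     read_tree_sample(spc$trees, burnin_fraction = 0))
      tip_locs <- locality_from_id(trees[[1L]]$tip.label)
      chars <- if (!is.null(pooling))
        ifelse(tip_locs %in% names(pooling), pooling[tip_locs], tip_locs)
        else tip_locs
      ts <- tree_sample(trees, stats::setNames(as.list(chars),
                                               trees[[1L]]$tip.label))
      rps <- stage(paste0("rlr:", sp), rps_scores(ts))
      rps_path <- file.path(cfg$outdir, paste0("rps_", sp, ".tsv"))
      utils::write.table(rps, rps_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[paste0("rps_", sp)]] <- rps_path
    }
    results[[sp]] <- list(alignment = aln, index = index, network = net,
                          design = design, motus = motus, rps = rps)
  }

  t1 <- table1
  t1$H <- format_stat(t1$H); t1$pi <- format_stat(t1$pi)
  t1_path <- file.path(cfg$outdir, "diversity_by_locality.tsv")
  utils::write.table(t1, t1_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  t2 <- table2
  for (cc in c("D", "p_D", "Fs", "p_Fs"))
    t2[[cc]] <- format_stat(t2[[cc]], digits = 3, na = "n. c.")
  t2_path <- file.path(cfg$outdir, "neutrality_by_unit.tsv")
  utils::write.table(t2, t2_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$table1 <- t1_path; paths$table2 <- t2_path

  mk <- NULL
  if (length(cfg$species) >= 2L) {
    sps <- names(cfg$species)[1:2]
    mk <- stage("mktest",
                mk_counts(results[[sps[1L]]]$alignment,
                          results[[sps[2L]]]$alignment))
    mk_path <- file.path(cfg$outdir, "mk_counts.tsv")
    utils::write.table(data.frame(Ps = mk$Ps, Pn = mk$Pn, Ms = mk$Ms,
                                  Mn = mk$Mn, frame = mk$frame),
                       mk_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$mk <- mk_path
  }

  log_path <- file.path(cfg$outdir, "run_log.txt")
  writeLines(c(paste("refugeo", as.character(utils::packageVersion("refugeo"))),
               paste("seed:", seed),
               paste("neutrality reps:", reps),
               paste("connection confidence:", conf),
               paste("species:", paste(names(cfg$species), collapse = ", "))),
             log_path)
  paths$log <- log_path
  invisible(list(results = results, table1 = table1, table2 = table2,
                 mk = mk, paths = paths))
}
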