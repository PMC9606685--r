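## End-to-end synthetic pipeline: generate -> filter -> profile -> rateshift
## -> trace -> map3d -> mds -> topology, with a machine-readable JSON report.
## Fully deterministic under one global seed, fanned out to per-stage seeds.

.stage_seed <- function(seed, k) (as.integer(seed) + 7919L * k) %% 2147483647L

.default_config <- function() {
  list(
    seed = 1L,
    outdir = "phylowave_out",
    stages = list(msa = TRUE, filter = TRUE, profile = TRUE,
                  rateshift = TRUE, trace = TRUE, map3d = TRUE,
                  mds = TRUE, topology = TRUE),
    msa = list(group_order = c("OG", "MB", "MA", "MH", "pN"),
               sizes = 8, length = 120,
               n_typeII = 4, n_typeI = 4, n_conserved = 6,
               background_identity = 0.85, gap_rate = 0.02,
               modal_freq = 0.97, contrast = c("MA", "MH")),
    filter = list(threshold = 0.9),
    profile = list(n_per_group = 12, decoy_count = 12, rounds = 3,
                   min_freq = 0),
    rateshift = list(c_hi = 0.9, c_lo = 0.6, grantham_min = 60,
                     B = 999, q_alpha = 0.05),
    map3d = list(cluster_sizes = c(4, 4), angle_deg = 25, cutoff = 10),
    mds = list(n_morphs = 6),
    topology = list(n_tms = c(11, 12))
  )
}

.merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section ", path, " must be a list")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key: ", paste0(path, unknown[1]))
  out <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      out[[nm]] <- .merge_config(user[[nm]], defaults[[nm]],
                                 paste0(path, nm, "$"))
    else out[[nm]] <- user[[nm]]
  }
  out
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are rejected before any stage runs; omitted keys take the
#' documented defaults.
#'
#' @param config A (possibly partial) named list, or a path to a YAML file.
#' @return The completed configuration list, of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- .merge_config(config, .default_config())
  if (length(cfg$msa$group_order) < 2) stop("need >= 2 groups")
  if (!all(cfg$msa$contrast %in% cfg$msa$group_order))
    stop("contrast groups must appear in group_order")
  structure(cfg, class = c("pipeline_config", "list"))
}

.config_hash <- function(cfg) {
  ## fingerprint of the scientific parameters; the output location is not
  ## part of the analysis identity
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                           digits = 10)), tmp)
  unname(tools::md5sum(tmp))
}

#' Build the demonstration synthetic alignment spec used by the pipeline
#'
#' Plants `n_typeII` radical and `n_typeI` heterotachous columns between the
#' two contrast groups, and `n_conserved` stepwise-fixation columns spread
#' over the succession, at deterministic (seed-derived) columns.
#'
#' @param msa_cfg The `msa` section of a [pipeline_config()].
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
demo_msa_spec <- function(msa_cfg, seed) {
  g <- msa_cfg$group_order
  c1 <- msa_cfg$contrast[1]; c2 <- msa_cfg$contrast[2]
  gm <- grantham_matrix()
  radical <- which(gm >= 60, arr.ind = TRUE)
  mild <- which(gm < 60 & gm > 0, arr.ind = TRUE)
  .with_seed(seed, {
    n_pl <- msa_cfg$n_typeII + msa_cfg$n_typeI + msa_cfg$n_conserved
    cols <- sort(sample.int(msa_cfg$length, n_pl))
    plants <- list(); k <- 0
    for (i in seq_len(msa_cfg$n_typeII)) {
      k <- k + 1
      pr <- radical[sample.int(nrow(radical), 1), ]
      res <- stats::setNames(rep(.aa20[pr[1]], length(g)), g)
      res[c2] <- .aa20[pr[2]]
      plants <- c(plants, list(plant_typeII(cols[k], res,
                                            contrast = c(c1, c2))))
    }
    for (i in seq_len(msa_cfg$n_typeI)) {
      k <- k + 1
      r <- sample(.aa20, 1)
      vs <- sample(setdiff(.aa20, r), 4)
      plants <- c(plants, list(plant_typeI(cols[k], c1, r, vs)))
    }
    stages <- rep_len(g, msa_cfg$n_conserved)
    for (i in seq_len(msa_cfg$n_conserved)) {
      k <- k + 1
      plants <- c(plants, list(plant_conserved(cols[k], stages[i],
                                               sample(.aa20, 1))))
    }
    synthetic_spec(g, msa_cfg$sizes, msa_cfg$length,
                   planted_sites = plants,
                   background_identity = msa_cfg$background_identity,
                   gap_rate = msa_cfg$gap_rate,
                   modal_freq = msa_cfg$modal_freq,
                   seed = seed)
  })
}

#' Run the synthetic end-to-end pipeline
#'
#' Stages run in declared order; each stage's outputs are written under the
#' configured output directory before the next stage starts, and a versioned
#' JSON report aggregating all counts is written last.  A stage failure
#' halts the run with the stage name and cause; outputs already written are
#' retained.  The report contains no timestamps, so reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config A [pipeline_config()], a partial list, or a YAML path.
#' @param quiet Suppress progress messages.
#' @return The report list, invisibly; the JSON is at
#'   `file.path(config$outdir, "report.json")`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[phylowave] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(schema_version = "1.0",
                 package_version = as.character(utils::packageVersion("phylowave")),
                 seed = cfg$seed, config_hash = .config_hash(cfg))

  aln <- NULL; truth <- NULL; calls <- NULL; stages_df <- NULL
  if (isTRUE(cfg$stages$msa)) {
    res <- stage("msa", {
      spec <- demo_msa_spec(cfg$msa, .stage_seed(cfg$seed, 1L))
      gen <- generate_msa(spec)
      write_fasta(gen$aln$seqs, file.path(cfg$outdir, "msa.fasta"))
      write_labels(gen$aln$labels, file.path(cfg$outdir, "labels.tsv"))
      gen
    })
    aln <- res$aln; truth <- res$truth
    report$msa <- list(
      n_sequences = nrow(aln$seqs), n_columns = aln$L,
      groups = as.list(table(factor(aln$labels, aln$group_order))),
      planted = as.list(table(truth$sites$kind)),
      pi_sites = count_pi_sites(aln))
  }
  if (isTRUE(cfg$stages$filter) && !is.null(aln)) {
    reps <- stage("filter", {
      degapped <- seq_set(aln$seqs$id, gsub("-", "", aln$seqs$seq),
                          taxon = unname(aln$labels[aln$seqs$id]))
      r <- greedy_filter(degapped, cfg$filter$threshold)
      write_fasta(r, file.path(cfg$outdir, "representatives.fasta"))
      r
    })
    report$filter <- list(threshold = cfg$filter$threshold,
                          input = nrow(aln$seqs), retained = nrow(reps))
  }
  if (isTRUE(cfg$stages$profile)) {
    prof <- stage("profile", {
      groups2 <- cfg$msa$group_order[1:2]
      models <- demo_segment_models(groups2)
      db <- generate_scan_db(cfg$profile$n_per_group, models,
                             decoy_count = cfg$profile$decoy_count,
                             seed = .stage_seed(cfg$seed, 2L))
      write_fasta(db$seqs, file.path(cfg$outdir, "scan_db.fasta"))
      pat <- model_pattern(models[[1]])
      writeLines(pat$text, file.path(cfg$outdir, "pattern.txt"))
      hits <- scan_pattern(pat, db$seqs)
      utils::write.table(hits[, c("id", "start", "end")],
                         file.path(cfg$outdir, "hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tp <- profile_hits(hits, stats::setNames(db$truth$group, db$truth$id),
                         target_group = groups2[1])
      ref <- refine_pattern(pat, db$seqs, rounds = cfg$profile$rounds,
                            min_freq = cfg$profile$min_freq)
      list(hits = hits, tp = tp, ref = ref, db = db, group = groups2[1])
    })
    in_group_total <- sum(prof$db$truth$group == prof$group)
    recovered <- length(intersect(
      prof$hits$id, prof$db$truth$id[prof$db$truth$group == prof$group]))
    report$profile <- list(
      db_size = nrow(prof$db$seqs), hits = nrow(prof$hits),
      specificity = prof$tp$specificity,
      recovery = recovered / in_group_total,
      decoy_hits = sum(prof$db$truth$group[
        match(prof$hits$id, prof$db$truth$id)] == "decoy"),
      refine_status = prof$ref$status, refine_rounds = prof$ref$rounds_run)
  }
  if (isTRUE(cfg$stages$rateshift) && !is.null(aln)) {
    calls <- stage("rateshift", {
      cc <- rate_shift_calls(aln, groups = cfg$msa$contrast,
                             c_hi = cfg$rateshift$c_hi,
                             c_lo = cfg$rateshift$c_lo,
                             grantham_min = cfg$rateshift$grantham_min,
                             B = cfg$rateshift$B,
                             seed = .stage_seed(cfg$seed, 3L))
      utils::write.table(cc, file.path(cfg$outdir, "rateshift.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cc
    })
    sig <- calls$type != "none" & !is.na(calls$q) &
      calls$q <= cfg$rateshift$q_alpha
    report$rateshift <- list(
      tested = sum(calls$callable),
      significant = as.list(table(calls$type[sig])),
      q_alpha = cfg$rateshift$q_alpha)
  }
  if (isTRUE(cfg$stages$trace) && !is.null(aln)) {
    stages_df <- stage("trace", {
      sdf <- fixation_stages(aln, c_hi = cfg$rateshift$c_hi)
      utils::write.table(sdf, file.path(cfg$outdir, "stages.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sdf
    })
    planted <- truth$sites[truth$sites$kind == "conserved_since_stage", ]
    rec <- mean(stages_df$stage[planted$column] == planted$stage)
    report$trace <- list(
      stages = as.list(table(factor(stages_df$stage,
                                    c(aln$group_order, "unfixed")))),
      planted_stage_recovery = rec)
    if (!is.null(calls)) {
      coll <- collect_coevolved(calls, stages_df,
                                q_alpha = cfg$rateshift$q_alpha)
      report$trace$collections <- nrow(coll)
    }
  }
  structs <- NULL
  if (isTRUE(cfg$stages$map3d)) {
    m3 <- stage("map3d", {
      st <- generate_structures(cfg$map3d$cluster_sizes,
                                seed = .stage_seed(cfg$seed, 4L),
                                angle_deg = cfg$map3d$angle_deg)
      write_pdb_ca(st$A, file.path(cfg$outdir, "confA.pdb"))
      write_pdb_ca(st$B, file.path(cfg$outdir, "confB.pdb"))
      sites <- unlist(st$truth$clusters)
      netA <- neighbor_network(st$A, NULL, sites, cutoff = cfg$map3d$cutoff)
      netB <- neighbor_network(st$B, NULL, sites, cutoff = cfg$map3d$cutoff)
      cmp <- compare_conformations(netA, netB)
      list(st = st, netA = netA, netB = netB, cmp = cmp)
    })
    structs <- m3$st
    report$map3d <- list(
      n_sites = length(unlist(structs$truth$clusters)),
      clusters_recovered = length(network_components(m3$netA)),
      clusters_planted = length(structs$truth$clusters),
      rearranged_sites = sum(m3$cmp$rearranged),
      conformer_rmsd = kabsch_rmsd(structs$A, structs$B))
  }
  if (isTRUE(cfg$stages$mds) && !is.null(structs)) {
    emb <- stage("mds", {
      nm <- cfg$mds$n_morphs
      ts <- seq(0, 1, length.out = nm)
      models <- lapply(ts, function(t)
        structs$A$xyz + t * (structs$B$xyz - structs$A$xyz))
      names(models) <- sprintf("morph_%02d", seq_len(nm))
      names(models)[1] <- "ref_A"; names(models)[nm] <- "ref_B"
      e <- mds_map(models, references = c("ref_A", "ref_B"))
      utils::write.table(e$points, file.path(cfg$outdir, "conformers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      e
    })
    report$mds <- list(
      models = nrow(emb$points),
      labels = as.list(table(emb$points$nearest_ref)),
      negative_eig = sum(emb$eig < -1e-8))
  }
  if (isTRUE(cfg$stages$topology)) {
    topo <- stage("topology", {
      vapply(seq_along(cfg$topology$n_tms), function(i) {
        s <- generate_tms_sequence(cfg$topology$n_tms[i],
                                   seed = .stage_seed(cfg$seed, 5L + i))
        count_tms(s)$count
      }, numeric(1))
    })
    report$topology <- list(planted = as.list(cfg$topology$n_tms),
                            counted = as.list(topo))
  }
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  say("report written: ", file.path(cfg$outdir, "report.json"))
  invisible(report)
}
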