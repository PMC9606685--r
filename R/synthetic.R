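## Synthetic data with planted ground truth: grouped alignments, pattern-scan
## databases, membrane topologies, and paired-conformation helical structures.
## Every generator is a pure function of its parameters plus a seed.

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification for a synthetic grouped alignment
#'
#' Describes an alignment partitioned into an ordered succession of
#' phylogroups with planted signal columns.  Background columns share one
#' consensus residue across all groups (so groups are exchangeable at null
#' columns); each sequence carries the consensus with probability
#' `sqrt(background_identity)`, making the expected within-group pairwise
#' identity approximately `background_identity`.
#'
#' @param group_order Ordered group names, oldest (outgroup) first.
#' @param sizes Per-group sequence counts (recycled); each must be >= 2.
#' @param length Number of alignment columns.
#' @param planted_sites List of planted-site descriptors built with
#'   [plant_typeII()], [plant_typeI()], [plant_typeI_II()] or
#'   [plant_conserved()].
#' @param background_identity Expected within-group identity at background
#'   columns, in (0, 1].
#' @param gap_rate Per-cell gap probability; gaps are never placed in
#'   planted columns so the planted signal is exact.
#' @param modal_freq Realized modal-residue frequency at planted conserved
#'   positions (off-modal sequences are allocated deterministically as
#'   `floor(n * (1 - modal_freq))` per group, guaranteeing the frequency).
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(group_order, sizes, length,
                           planted_sites = list(),
                           background_identity = 0.85,
                           gap_rate = 0.02,
                           modal_freq = 0.97,
                           seed = 1L) {
  sizes <- rep_len(sizes, base::length(group_order))
  if (any(sizes < 2)) stop("each group needs >= 2 sequences")
  if (background_identity <= 0 || background_identity > 1)
    stop("background_identity must be in (0,1]")
  if (gap_rate < 0 || gap_rate >= 1) stop("gap_rate must be in [0,1)")
  if (modal_freq < 0.95) stop("modal_freq must be >= 0.95")
  cols <- vapply(planted_sites, function(p) p$column, numeric(1))
  if (anyDuplicated(cols)) stop("planted columns must be distinct")
  if (base::length(cols) && (any(cols < 1) || any(cols > length)))
    stop("planted column outside 1..length")
  for (p in planted_sites) .validate_plant(p, group_order)
  structure(list(group_order = group_order, sizes = sizes, length = length,
                 planted_sites = planted_sites,
                 background_identity = background_identity,
                 gap_rate = gap_rate, modal_freq = modal_freq,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Planted-site descriptors
#'
#' `plant_typeII()` plants a column conserved in every group with modal
#' residues that differ radically (Grantham >= 60) between the two contrasted
#' groups.  `plant_typeI()` plants a column conserved in one group and
#' drawn uniformly over a set of >= 4 residues in the others.
#' `plant_typeI_II()` plants a column conserved in both contrasted groups
#' with modal residues that differ but are physicochemically similar
#' (Grantham < 60).  `plant_conserved()` plants a column whose residue is
#' fixed from a named stage onward and uniform noise before it.
#'
#' @param column Alignment column (1-based).
#' @param residues Named character vector: modal residue per group.
#' @param contrast The two groups whose modal residues are contrasted
#'   (defaults to the first two names of `residues`).
#' @param conserved_group Group that is conserved in a type I plant.
#' @param residue Conserved residue.
#' @param variable_set Residue set (>= 4) the non-conserved groups draw from.
#' @param stage Group name from which the residue is fixed onward.
#' @return A planted-site descriptor list.
#' @name planted_sites
NULL

#' @rdname planted_sites
#' @export
plant_typeII <- function(column, residues, contrast = names(residues)[1:2]) {
  list(column = column, kind = "typeII", residues = residues, contrast = contrast)
}

#' @rdname planted_sites
#' @export
plant_typeI <- function(column, conserved_group, residue, variable_set) {
  list(column = column, kind = "typeI", conserved_group = conserved_group,
       residue = residue, variable_set = variable_set)
}

#' @rdname planted_sites
#' @export
plant_typeI_II <- function(column, residues, contrast = names(residues)[1:2]) {
  list(column = column, kind = "typeI_II", residues = residues, contrast = contrast)
}

#' @rdname planted_sites
#' @export
plant_conserved <- function(column, stage, residue) {
  list(column = column, kind = "conserved_since_stage", stage = stage,
       residue = residue)
}

.validate_plant <- function(p, group_order) {
  if (p$kind %in% c("typeII", "typeI_II")) {
    miss <- setdiff(group_order, names(p$residues))
    if (length(miss)) stop("plant at column ", p$column,
                           " lacks a residue for group ", miss[1])
    r1 <- p$residues[p$contrast[1]]; r2 <- p$residues[p$contrast[2]]
    if (r1 == r2) stop("type II plant at column ", p$column,
                       " has identical modal residues")
    g <- grantham(r1, r2)
    if (p$kind == "typeII" && (is.na(g) || g < 60))
      stop("type II plant at column ", p$column,
           " needs Grantham >= 60 between contrasted residues (got ", g, ")")
    if (p$kind == "typeI_II" && (is.na(g) || g >= 60))
      stop("type I/II plant at column ", p$column,
           " needs Grantham < 60 between contrasted residues (got ", g, ")")
  } else if (p$kind == "typeI") {
    if (!p$conserved_group %in% group_order)
      stop("unknown conserved_group at column ", p$column)
    if (length(p$variable_set) < 4)
      stop("type I plant at column ", p$column, " needs >= 4 variable residues")
  } else if (p$kind == "conserved_since_stage") {
    if (!p$stage %in% group_order)
      stop("unknown stage at column ", p$column)
  } else stop("unknown planted kind: ", p$kind)
}

.fill_conserved <- function(n, residue, modal_freq) {
  ## deterministic allocation: realized modal frequency >= modal_freq
  k_off <- floor(n * (1 - modal_freq))
  out <- rep(residue, n)
  if (k_off > 0) {
    idx <- sample.int(n, k_off)
    out[idx] <- sample(setdiff(.aa20, residue), k_off, replace = TRUE)
  }
  out
}

.fill_uniform <- function(n, set) {
  ## even allocation over the set, randomly placed
  sample(rep_len(sort(set), n))
}

#' Generate a grouped alignment with planted rate-shift and fixation signal
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `aln` (a [grouped_alignment()]) and `truth` (a list
#'   with `sites`, a data.frame of planted columns/kinds/stages, and
#'   `labels`, the id to group map).
#' @export
generate_msa <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    groups <- rep(spec$group_order, spec$sizes)
    n <- length(groups)
    ids <- sprintf("%s_%02d", groups, unlist(lapply(spec$sizes, seq_len)))
    m <- matrix("", n, spec$length)
    p_cons <- sqrt(spec$background_identity)
    planted_cols <- vapply(spec$planted_sites, `[[`, numeric(1), "column")
    for (j in seq_len(spec$length)) {
      cons <- sample(.aa20, 1)
      take <- stats::runif(n) < p_cons
      col <- ifelse(take, cons, sample(.aa20, n, replace = TRUE))
      m[, j] <- col
    }
    stage_idx <- stats::setNames(seq_along(spec$group_order), spec$group_order)
    for (p in spec$planted_sites) {
      j <- p$column
      for (g in spec$group_order) {
        rows <- which(groups == g)
        ng <- length(rows)
        m[rows, j] <- switch(p$kind,
          typeII = ,
          typeI_II = .fill_conserved(ng, p$residues[[g]], spec$modal_freq),
          typeI = if (g == p$conserved_group)
              .fill_conserved(ng, p$residue, spec$modal_freq)
            else .fill_uniform(ng, p$variable_set),
          conserved_since_stage = if (stage_idx[g] >= stage_idx[p$stage])
              .fill_conserved(ng, p$residue, spec$modal_freq)
            else .fill_uniform(ng, setdiff(.aa20, p$residue))
        )
      }
    }
    if (spec$gap_rate > 0) {
      gaps <- matrix(stats::runif(n * spec$length) < spec$gap_rate,
                     n, spec$length)
      if (length(planted_cols)) gaps[, planted_cols] <- FALSE
      m[gaps] <- "-"
    }
    seqs <- seq_set(ids, apply(m, 1, paste, collapse = ""), aligned = TRUE)
    labels <- stats::setNames(groups, ids)
    sites <- if (length(spec$planted_sites)) {
      data.frame(
        column = planted_cols,
        kind = vapply(spec$planted_sites, `[[`, character(1), "kind"),
        stage = vapply(spec$planted_sites, function(p)
          if (p$kind == "conserved_since_stage") p$stage else NA_character_,
          character(1)),
        stringsAsFactors = FALSE)
    } else data.frame(column = numeric(0), kind = character(0),
                      stage = character(0))
    list(aln = grouped_alignment(seqs, labels, spec$group_order),
         truth = list(sites = sites, labels = labels,
                      planted = spec$planted_sites))
  })
}

#' Deterministic disjoint segment models for a scan database
#'
#' Builds, for each group, six short segments over a group-private residue
#' alphabet (so group patterns are mutually disjoint), with declared linker
#' ranges between segments.  Intended for scanner recovery experiments.
#'
#' @param groups Group names (at most 6 for disjoint alphabets).
#' @param n_segments Number of segments per group.
#' @param segment_length Positions per segment.
#' @param gap_range Linker length bounds between consecutive segments.
#' @return Named list per group: `segments` (list of character vectors, one
#'   allowed-residue string per position) and `gap_ranges` (list of
#'   c(min, max)).
#' @export
demo_segment_models <- function(groups, n_segments = 6, segment_length = 4,
                                gap_range = c(3, 8)) {
  if (length(groups) > 6) stop("at most 6 disjoint group alphabets")
  split_sets <- split(.aa20, rep(seq_along(groups), length.out = 20))
  out <- lapply(seq_along(groups), function(k) {
    alpha <- split_sets[[k]]
    segs <- lapply(seq_len(n_segments), function(s) {
      vapply(seq_len(segment_length), function(i)
        alpha[((s + i) %% length(alpha)) + 1], character(1))
    })
    list(segments = segs,
         gap_ranges = rep(list(gap_range), n_segments - 1))
  })
  stats::setNames(out, groups)
}

#' Generate a labeled database for pattern scanning
#'
#' Each in-group sequence embeds its group's segments, in order, separated by
#' linkers with lengths drawn within the declared gap ranges; decoys are
#' shuffled-composition sequences carrying no planted segments.
#'
#' @param n_per_group Sequences per group (recycled over groups).
#' @param segment_models As returned by [demo_segment_models()].
#' @param decoy_count Number of decoy sequences.
#' @param seed Integer seed.
#' @param flank_range Length bounds of the random flanks.
#' @return List with `seqs` (a `seq_set` whose `taxon` holds the true group,
#'   `"decoy"` for decoys) and `truth` (data.frame id/group).
#' @export
generate_scan_db <- function(n_per_group, segment_models, decoy_count = 0,
                             seed = 1L, flank_range = c(5, 15)) {
  for (mod in segment_models)
    for (gr in mod$gap_ranges)
      if (gr[1] > gr[2]) stop("gap range with min > max")
  .with_seed(seed, {
    groups <- names(segment_models)
    n_per_group <- rep_len(n_per_group, length(groups))
    ids <- character(0); seqs <- character(0); taxa <- character(0)
    rint <- function(rng) sample(seq(rng[1], rng[2]), 1)
    for (k in seq_along(groups)) {
      mod <- segment_models[[k]]
      for (i in seq_len(n_per_group[k])) {
        parts <- character(0)
        parts <- c(parts, paste(sample(.aa20, rint(flank_range),
                                       replace = TRUE), collapse = ""))
        for (s in seq_along(mod$segments)) {
          seg <- vapply(mod$segments[[s]], function(allowed) {
            ch <- strsplit(allowed, "")[[1]]
            ch[sample.int(length(ch), 1)]
          }, character(1))
          parts <- c(parts, paste(seg, collapse = ""))
          if (s < length(mod$segments))
            parts <- c(parts, paste(sample(.aa20, rint(mod$gap_ranges[[s]]),
                                           replace = TRUE), collapse = ""))
        }
        parts <- c(parts, paste(sample(.aa20, rint(flank_range),
                                       replace = TRUE), collapse = ""))
        ids <- c(ids, sprintf("%s_db%03d", groups[k], i))
        seqs <- c(seqs, paste(parts, collapse = ""))
        taxa <- c(taxa, groups[k])
      }
    }
    if (decoy_count > 0) {
      pool <- strsplit(paste(seqs, collapse = ""), "")[[1]]
      for (i in seq_len(decoy_count)) {
        len <- sample(nchar(seqs), 1)
        ids <- c(ids, sprintf("decoy_%03d", i))
        seqs <- c(seqs, paste(sample(pool, len, replace = TRUE), collapse = ""))
        taxa <- c(taxa, "decoy")
      }
    }
    db <- seq_set(ids, seqs, taxon = taxa)
    list(seqs = db, truth = data.frame(id = ids, group = taxa,
                                       stringsAsFactors = FALSE))
  })
}

## Residue draw weights for synthetic membrane topologies.  Transmembrane
## stretches are biased toward strongly hydrophobic residues (I/V/L) and
## linkers toward the mildly polar residues that dominate real loops
## (S/T/G/P), so a 20-residue stretch yields a Kyte-Doolittle window plateau
## comfortably above the 1.6 detection threshold while linker centers stay
## well below it.
.tms_hydro <- c(I = 0.45, V = 0.45, L = 0.08, F = 0.01, A = 0.005, M = 0.005)
.tms_polar <- c(S = 0.25, T = 0.25, G = 0.20, P = 0.10, N = 0.05, Q = 0.05,
                D = 0.025, E = 0.025, K = 0.0125, R = 0.0125)

#' Generate a membrane-protein-like sequence with a known TMS count
#'
#' Hydrophobic stretches (20-23 residues from L/I/V/F/A/M, biased toward
#' I, V and L) separated by polar linkers (15-25 residues from
#' S/T/N/Q/D/E/K/R/G/P), with polar flanks at both ends.
#'
#' @param n_tms Number of transmembrane stretches (0 gives an all-polar
#'   sequence).
#' @param seed Integer seed.
#' @return Single-row `seq_set`; attribute `"n_tms"` carries the truth.
#' @export
generate_tms_sequence <- function(n_tms, seed = 1L) {
  .with_seed(seed, {
    polar <- function(len) paste(sample(names(.tms_polar), len, replace = TRUE,
                                        prob = .tms_polar), collapse = "")
    if (n_tms == 0) {
      s <- polar(60)
    } else {
      parts <- polar(sample(15:25, 1))
      for (k in seq_len(n_tms)) {
        len <- sample(20:23, 1)
        parts <- c(parts, paste(sample(names(.tms_hydro), len, replace = TRUE,
                                       prob = .tms_hydro), collapse = ""))
        parts <- c(parts, polar(sample(15:25, 1)))
      }
      s <- paste(parts, collapse = "")
    }
    out <- seq_set(sprintf("tms%d_seed%d", n_tms, seed), s)
    attr(out, "n_tms") <- n_tms
    out
  })
}

.helix_trace <- function(n_res, origin = c(0, 0, 0), radius = 2.3,
                         rise = 1.5, turn_deg = 100) {
  i <- seq_len(n_res) - 1
  ang <- i * turn_deg * pi / 180
  cbind(x = origin[1] + radius * cos(ang),
        y = origin[2] + radius * sin(ang),
        z = origin[3] + i * rise)
}

#' Generate paired-conformation helical structures with planted site clusters
#'
#' Builds ideal alpha-helical CA traces (1.5 A rise, 100 deg per residue)
#' arranged as pairs of adjacent helices; each planted cluster is a set of
#' sites on one helix pair selected so that all mutual CA distances are
#' within `cluster_radius`.  Conformation B applies a rigid-body rotation to
#' a declared helix subset, emulating bundle rocking between outward- and
#' inward-open states.
#'
#' @param cluster_sizes Integer vector; one spatial cluster per entry, each
#'   on its own helix pair (pairs are placed far apart, so distinct clusters
#'   are never within `cluster_radius`).
#' @param seed Integer seed.
#' @param helix_len Residues per helix.
#' @param cluster_radius Maximum within-cluster CA-CA distance (A).
#' @param moved_helices Helix ids rotated in conformation B (default: the
#'   second helix of the last pair, so contacts across that pair rearrange
#'   while the rest of the structure is untouched).  The rotation is about
#'   the x axis, which preserves the inter-pair spacing.
#' @param angle_deg Rotation angle for the moved helices.
#' @return List with `A` and `B` (class `structure_model`), and `truth`
#'   (list: `clusters` — residue-number sets, `helix` — helix id per residue,
#'   `moved_helices`, `moved_residues`, `max_within_cluster_dist`).
#' @export
generate_structures <- function(cluster_sizes, seed = 1L, helix_len = 30,
                                cluster_radius = 10, moved_helices = NULL,
                                angle_deg = 25) {
  n_pairs <- length(cluster_sizes)
  if (n_pairs < 1) stop("need at least one cluster")
  if (is.null(moved_helices)) moved_helices <- 2L * n_pairs
  .with_seed(seed, {
    xyz <- NULL; helix <- integer(0)
    for (p in seq_len(n_pairs)) {
      x0 <- 30 * (p - 1)
      xyz <- rbind(xyz, .helix_trace(helix_len, origin = c(x0, 0, 0)))
      helix <- c(helix, rep(2L * p - 1L, helix_len))
      xyz <- rbind(xyz, .helix_trace(helix_len, origin = c(x0 + 8, 0, 0)))
      helix <- c(helix, rep(2L * p, helix_len))
    }
    n <- nrow(xyz)
    resno <- seq_len(n)
    clusters <- vector("list", n_pairs)
    for (p in seq_len(n_pairs)) {
      pair_res <- which(helix %in% c(2L * p - 1L, 2L * p))
      center <- pair_res[which.min(abs(xyz[pair_res, 3] -
                                       stats::median(xyz[pair_res, 3])))]
      cand <- pair_res[order(sqrt(colSums((t(xyz[pair_res, , drop = FALSE]) -
                                           xyz[center, ])^2)))]
      chosen <- center
      for (r in setdiff(cand, center)) {
        if (length(chosen) >= cluster_sizes[p]) break
        d <- sqrt(colSums((t(xyz[chosen, , drop = FALSE]) - xyz[r, ])^2))
        if (all(d <= cluster_radius)) chosen <- c(chosen, r)
      }
      if (length(chosen) < cluster_sizes[p])
        stop("could not place ", cluster_sizes[p],
             " sites within ", cluster_radius, " A on pair ", p)
      clusters[[p]] <- sort(resno[chosen])
    }
    maxd <- max(vapply(clusters, function(cl) {
      if (length(cl) < 2) return(0)
      max(stats::dist(xyz[cl, , drop = FALSE]))
    }, numeric(1)))
    ## conformation B: each moved helix pivots rigidly about its own base
    ## (x-axis rotation, preserving inter-pair x spacing) — a minimal model
    ## of helical-bundle rocking between alternate carrier conformations
    xyzB <- xyz
    th <- angle_deg * pi / 180
    R <- rbind(c(1, 0, 0),
               c(0, cos(th), -sin(th)),
               c(0, sin(th), cos(th)))
    for (hx in moved_helices) {
      idx <- which(helix == hx)
      if (!length(idx)) stop("moved helix ", hx, " does not exist")
      pivot <- xyz[idx[1], ]
      xyzB[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, pivot) %*% t(R),
                           2, pivot, `+`)
    }
    mv <- which(helix %in% moved_helices)
    resid <- sample(c("A", "L", "V", "I", "G", "F"), n, replace = TRUE)
    mk <- function(id, coords) structure(
      list(id = id, resno = resno, resid = resid, xyz = coords),
      class = "structure_model")
    list(A = mk("confA", xyz), B = mk("confB", xyzB),
         truth = list(clusters = clusters, helix = helix,
                      moved_helices = moved_helices,
                      moved_residues = resno[mv],
                      max_within_cluster_dist = maxd))
  })
}
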