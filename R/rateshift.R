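## Type I / type II evolutionary rate-shift detection between phylogroups
## with a permutation null and BH false-discovery-rate control; fixation-stage
## tracing along the ordered phylogroup succession; coevolution collections.

.col_tally <- function(col) {
  ## modal residue (alphabetical tie-break), modal frequency over usable
  ## residues, gap fraction, usable count.  Gaps and 'X' are missing data.
  usable <- col[col %in% .aa20]
  gapf <- mean(col == "-")
  if (!length(usable))
    return(list(modal = NA_character_, freq = NA_real_,
                gap_fraction = gapf, usable = 0L))
  tab <- table(usable)
  modal <- names(tab)[which.max(tab)]  # table is alphabetical; first max wins
  list(modal = modal, freq = as.numeric(max(tab)) / length(usable),
       gap_fraction = gapf, usable = length(usable))
}

#' Per-column, per-group conservation profile
#'
#' For every alignment column and group: the modal residue (ties broken
#' alphabetically), its frequency among usable (non-gap, non-'X') residues,
#' the gap fraction and the usable count.  A column is callable for a group
#' when it has at least two usable residues and a gap fraction of at most
#' the cutoff.
#'
#' @param aln A [grouped_alignment()].
#' @param groups Groups to profile (default: all, in `group_order`).
#' @param columns Columns to profile (default: all).
#' @param max_gap_fraction Callability cutoff on the within-group gap
#'   fraction.
#' @return data.frame of class `conservation_profile`: column, group, modal,
#'   freq, gap_fraction, usable, callable.
#' @export
conservation_profile <- function(aln, groups = aln$group_order,
                                 columns = seq_len(aln$L),
                                 max_gap_fraction = 0.5) {
  bad <- setdiff(groups, aln$group_order)
  if (length(bad)) stop("unknown group: ", bad[1])
  m <- aln_matrix(aln)
  rows <- lapply(groups, function(g) {
    mg <- m[aln$labels == g, , drop = FALSE]
    do.call(rbind, lapply(columns, function(j) {
      t <- .col_tally(mg[, j])
      data.frame(column = j, group = g, modal = t$modal, freq = t$freq,
                 gap_fraction = t$gap_fraction, usable = t$usable,
                 callable = t$usable >= 2 && t$gap_fraction <= max_gap_fraction,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$column, match(out$group, aln$group_order)), ]
  rownames(out) <- NULL
  class(out) <- c("conservation_profile", "data.frame")
  out
}

.classify_from_tallies <- function(f1, r1, f2, r2,
                                   c_hi = 0.9, c_lo = 0.6, grantham_min = 60) {
  if (is.na(f1) || is.na(f2)) return("none")
  differ <- !is.na(r1) && !is.na(r2) && r1 != r2
  g <- if (differ) grantham(r1, r2) else NA_real_
  if (f1 >= c_hi && f2 >= c_hi && differ && !is.na(g) && g >= grantham_min)
    return("II")
  if ((f1 >= c_hi && f2 <= c_lo) || (f2 >= c_hi && f1 <= c_lo))
    return("I")
  if (f1 >= c_hi && f2 >= c_hi && differ && !is.na(g) && g < grantham_min)
    return("I_II")
  if (differ && ((f1 >= c_hi && f2 > c_lo && f2 < c_hi) ||
                 (f2 >= c_hi && f1 > c_lo && f1 < c_hi)))
    return("I_II")
  "none"
}

#' Classify one alignment column as a rate-shift type between two groups
#'
#' Type II: both groups conserved (modal frequency >= `c_hi`) on modal
#' residues that differ radically (Grantham >= `grantham_min`).  Type I:
#' one group conserved, the other variable (modal frequency <= `c_lo`) —
#' heterotachy.  Type I/II (mixed): both conserved but the differing
#' residues are physicochemically similar, or one conserved while the
#' other's modal frequency falls strictly between `c_lo` and `c_hi` with
#' differing modal residues.
#'
#' @param aln A [grouped_alignment()].
#' @param column Alignment column.
#' @param groups The two groups to contrast (default: first two of
#'   `group_order`).
#' @param c_hi Conservation threshold (modal frequency).
#' @param c_lo Variability threshold.
#' @param grantham_min Radical-substitution cutoff.
#' @return List: `type` in {"I","II","I_II","none"} and `reason`
#'   ("uncallable" when a group has too few usable residues or too many
#'   gaps, otherwise "").
#' @export
classify_site <- function(aln, column, groups = aln$group_order[1:2],
                          c_hi = 0.9, c_lo = 0.6, grantham_min = 60) {
  prof <- conservation_profile(aln, groups = groups, columns = column)
  if (!all(prof$callable))
    return(list(type = "none", reason = "uncallable"))
  p1 <- prof[prof$group == groups[1], ]
  p2 <- prof[prof$group == groups[2], ]
  list(type = .classify_from_tallies(p1$freq, p1$modal, p2$freq, p2$modal,
                                     c_hi, c_lo, grantham_min),
       reason = "")
}

.divergence_D <- function(x1, x2) {
  ## x1, x2: integer residue codes (1..20) of usable residues per group.
  ## D = (1 - freq of group2's modal residue in group1) +
  ##     (1 - freq of group1's modal residue in group2)
  t1 <- tabulate(x1, 20); t2 <- tabulate(x2, 20)
  m1 <- which.max(t1); m2 <- which.max(t2)
  (1 - t1[m2] / length(x1)) + (1 - t2[m1] / length(x2))
}

#' Permutation test for between-group divergence at one column
#'
#' The statistic D = (1 - frequency of group 2's modal residue within
#' group 1) + (1 - frequency of group 1's modal residue within group 2)
#' is large when each group is fixed on a residue rare in the other.  The
#' null is built by shuffling group labels over the column's usable
#' residues; p = (1 + #\{D_perm >= D_obs\}) / (B + 1).
#'
#' @param aln A [grouped_alignment()].
#' @param column Alignment column.
#' @param groups Two groups to contrast.
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return List: `D` (observed statistic), `p`, `B`.
#' @export
permutation_test <- function(aln, column, groups = aln$group_order[1:2],
                             B = 999, seed = 1L) {
  m <- aln_matrix(aln)
  .perm_test_col(m[aln$labels == groups[1], column],
                 m[aln$labels == groups[2], column], B, seed)
}

.perm_test_col <- function(col1, col2, B, seed) {
  stopifnot(B >= 1)
  x1 <- match(col1, .aa20); x2 <- match(col2, .aa20)
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  if (!length(x1) || !length(x2))
    return(list(D = NA_real_, p = 1, B = B))
  pooled <- c(x1, x2)
  if (length(unique(pooled)) < 2)
    return(list(D = 0, p = 1, B = B))
  D_obs <- .divergence_D(x1, x2)
  n1 <- length(x1); n <- length(pooled)
  M <- matrix(0, n, 20); M[cbind(seq_len(n), pooled)] <- 1
  tot <- colSums(M)
  .with_seed(seed, {
    P <- matrix(0, B, n)
    for (b in seq_len(B)) P[b, sample.int(n, n1)] <- 1
    C1 <- P %*% M
    C2 <- matrix(tot, B, 20, byrow = TRUE) - C1
    m1 <- max.col(C1, ties.method = "first")
    m2 <- max.col(C2, ties.method = "first")
    D_perm <- (1 - C1[cbind(seq_len(B), m2)] / n1) +
              (1 - C2[cbind(seq_len(B), m1)] / (n - n1))
    p <- (1 + sum(D_perm >= D_obs - 1e-12)) / (B + 1)
    list(D = D_obs, p = p, B = B)
  })
}

#' Rate-shift calls across alignment columns with FDR control
#'
#' Combines the typed classification ([classify_site()]) with the
#' permutation significance ([permutation_test()]); a site must both carry a
#' type and pass the BH-adjusted significance cutoff to be reported as a
#' rate shift (mirroring the practice of requiring agreement between two
#' detection approaches).
#'
#' @param aln A [grouped_alignment()].
#' @param groups Two groups to contrast.
#' @param columns Columns to test (default all).
#' @param c_hi,c_lo,grantham_min Classification thresholds (see
#'   [classify_site()]).
#' @param B Permutations per column.
#' @param seed Integer seed (a distinct stream is derived per column).
#' @return data.frame of class `rate_shift_calls`: column, type, D, p, q
#'   (BH-adjusted across tested columns), callable.
#' @export
rate_shift_calls <- function(aln, groups = aln$group_order[1:2],
                             columns = seq_len(aln$L),
                             c_hi = 0.9, c_lo = 0.6, grantham_min = 60,
                             B = 999, seed = 1L) {
  prof <- conservation_profile(aln, groups = groups, columns = columns)
  p1 <- prof[prof$group == groups[1], ]
  p2 <- prof[prof$group == groups[2], ]
  callable <- p1$callable & p2$callable
  type <- rep("none", length(columns))
  D <- p <- rep(NA_real_, length(columns))
  m <- aln_matrix(aln)
  m1 <- m[aln$labels == groups[1], , drop = FALSE]
  m2 <- m[aln$labels == groups[2], , drop = FALSE]
  for (k in seq_along(columns)) {
    if (!callable[k]) next
    type[k] <- .classify_from_tallies(p1$freq[k], p1$modal[k],
                                      p2$freq[k], p2$modal[k],
                                      c_hi, c_lo, grantham_min)
    pt <- .perm_test_col(m1[, columns[k]], m2[, columns[k]], B,
                         seed = (seed + 7919 * k) %% 2147483647)
    D[k] <- pt$D; p[k] <- pt$p
  }
  q <- rep(NA_real_, length(columns))
  q[callable] <- stats::p.adjust(p[callable], method = "BH")
  out <- data.frame(column = columns, type = type, D = D, p = p, q = q,
                    callable = callable, stringsAsFactors = FALSE)
  class(out) <- c("rate_shift_calls", "data.frame")
  out
}

#' Fixation stage of a column along the phylogroup succession
#'
#' The stage is the earliest group g (in `group_order`, oldest first) such
#' that g and every subsequent group share an identical modal residue with
#' modal frequency >= `c_hi`.  If that holds from the outgroup onward the
#' stage is the outgroup; if no suffix of the succession qualifies the
#' column is "unfixed".
#'
#' @param aln A [grouped_alignment()] whose `group_order` has >= 2 groups.
#' @param column Alignment column.
#' @param c_hi Conservation threshold.
#' @return List of class `fixation_stage`: `column`, `stage` (group name or
#'   `"unfixed"`), `residue` (fixed residue or NA).
#' @export
fixation_stage <- function(aln, column, c_hi = 0.9) {
  if (length(aln$group_order) < 2) stop("need >= 2 ordered groups")
  prof <- conservation_profile(aln, columns = column)
  prof <- prof[match(aln$group_order, prof$group), ]
  conserved <- prof$callable & !is.na(prof$freq) & prof$freq >= c_hi
  ng <- length(aln$group_order)
  stage <- "unfixed"; residue <- NA_character_
  for (g in seq_len(ng)) {
    idx <- g:ng
    if (all(conserved[idx]) && length(unique(prof$modal[idx])) == 1) {
      stage <- aln$group_order[g]; residue <- prof$modal[g]
      break
    }
  }
  structure(list(column = column, stage = stage, residue = residue),
            class = "fixation_stage")
}

#' Fixation stages for many columns
#' @param aln A [grouped_alignment()].
#' @param columns Columns to trace (default all).
#' @param c_hi Conservation threshold.
#' @return data.frame: column, stage, residue.
#' @export
fixation_stages <- function(aln, columns = seq_len(aln$L), c_hi = 0.9) {
  rows <- lapply(columns, function(j) {
    f <- fixation_stage(aln, j, c_hi)
    data.frame(column = j, stage = f$stage, residue = f$residue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group significant rate-shift sites into coevolution collections
#'
#' Significant columns are partitioned by fixation stage; within a stage,
#' when a residue contact network is supplied, members are further split
#' into the network's connected components (spatial waves).  Columns absent
#' from the network become singleton collections.
#'
#' @param calls A [rate_shift_calls()] data.frame.
#' @param stages A [fixation_stages()] data.frame covering the called
#'   columns.
#' @param network Optional [neighbor_network()] result.
#' @param q_alpha FDR cutoff for significance.
#' @return data.frame of class `coevolution_collections`: collection id,
#'   stage, columns (list column), size.
#' @export
collect_coevolved <- function(calls, stages, network = NULL, q_alpha = 0.05) {
  sig <- calls$column[calls$type != "none" & !is.na(calls$q) &
                      calls$q <= q_alpha]
  st <- stats::setNames(stages$stage, stages$column)
  out_stage <- character(0); out_cols <- list()
  for (s in unique(st[as.character(sig)])) {
    members <- sig[st[as.character(sig)] == s]
    if (is.null(network)) {
      comps <- list(members)
    } else {
      in_net <- members[members %in% network$nodes]
      out_net <- setdiff(members, in_net)
      comps <- list()
      if (length(in_net)) {
        e <- network$edges[network$edges$a %in% in_net &
                           network$edges$b %in% in_net, c("a", "b"), drop = FALSE]
        g <- igraph::graph_from_data_frame(
          d = data.frame(a = as.character(e$a), b = as.character(e$b)),
          directed = FALSE,
          vertices = data.frame(name = as.character(in_net)))
        mem <- igraph::components(g)$membership
        comps <- lapply(split(names(mem), mem), as.numeric)
      }
      comps <- c(comps, lapply(out_net, function(x) x))
    }
    for (cc in comps) {
      out_stage <- c(out_stage, s)
      out_cols <- c(out_cols, list(sort(unname(cc))))
    }
  }
  out <- data.frame(collection = seq_along(out_stage), stage = out_stage,
                    stringsAsFactors = FALSE)
  out$columns <- out_cols
  out$size <- lengths(out_cols)
  class(out) <- c("coevolution_collections", "data.frame")
  out
}
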