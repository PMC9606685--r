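## Group-specific sequence logos over selected alignment segments,
## PROSITE-verbose pattern assembly/parsing, database scanning, taxonomic
## profiling of hits, and iterative pattern refinement.

#' Segment specification in alignment coordinates
#'
#' Ordered, disjoint column intervals of the family alignment covered by a
#' group logo, plus the allowed residue spacing between consecutive segments
#' in unaligned target sequences.
#'
#' @param segments List of `c(start, end)` column intervals, ascending.
#' @param gap_ranges List of `c(min, max)` linker bounds, one per adjacent
#'   segment pair.
#' @return A list of class `segment_spec`.
#' @export
segment_spec <- function(segments, gap_ranges = NULL) {
  if (!length(segments)) stop("need at least one segment")
  segments <- lapply(segments, as.numeric)
  for (s in segments)
    if (length(s) != 2 || s[1] > s[2]) stop("bad segment interval")
  starts <- vapply(segments, `[`, numeric(1), 1)
  ends <- vapply(segments, `[`, numeric(1), 2)
  if (is.unsorted(starts, strictly = TRUE) || any(starts[-1] <= ends[-length(ends)]))
    stop("segments must be disjoint and ascending")
  if (is.null(gap_ranges))
    gap_ranges <- rep(list(c(0, 10000)), length(segments) - 1)
  if (length(gap_ranges) != length(segments) - 1)
    stop("need one gap range per adjacent segment pair")
  for (g in gap_ranges) if (g[1] > g[2] || g[1] < 0) stop("bad gap range")
  structure(list(segments = segments, gap_ranges = gap_ranges),
            class = "segment_spec")
}

.spec_columns <- function(spec)
  unlist(lapply(spec$segments, function(s) seq(s[1], s[2])))

#' Build a group-specific logo over selected segments
#'
#' Residue counts, frequencies and information content (in bits) are computed
#' over the members of one group only; gaps are excluded from frequencies but
#' the per-column gap fraction is reported.  IC = log2(20) - Shannon entropy;
#' a column that is all-gap within the group is flagged and its IC is NA.
#'
#' @param aln A [grouped_alignment()].
#' @param group Group name.
#' @param spec A [segment_spec()]; columns must lie within the alignment.
#' @return A list of class `group_logo`: `columns`, `counts` (20 x ncol),
#'   `freq`, `gap_fraction`, `ic`, `all_gap`, `group`, `spec`.
#' @export
build_group_logo <- function(aln, group, spec) {
  if (!group %in% aln$group_order) stop("unknown group: ", group)
  cols <- .spec_columns(spec)
  if (any(cols < 1 | cols > aln$L)) stop("segment columns outside alignment")
  m <- aln_matrix(aln)[aln$labels == group, cols, drop = FALSE]
  counts <- apply(m, 2, function(col)
    table(factor(col[col %in% .aa20], levels = .aa20)))
  counts <- matrix(as.numeric(counts), nrow = 20,
                   dimnames = list(.aa20, cols))
  tot <- colSums(counts)
  freq <- sweep(counts, 2, pmax(tot, 1), "/")
  gap_fraction <- colMeans(m == "-")
  ic <- vapply(seq_along(cols), function(j) {
    if (tot[j] == 0) return(NA_real_)
    f <- freq[, j][freq[, j] > 0]
    log2(20) + sum(f * log2(f))
  }, numeric(1))
  structure(list(columns = cols, counts = counts, freq = freq,
                 gap_fraction = gap_fraction, ic = ic,
                 all_gap = tot == 0, group = group, spec = spec),
            class = "group_logo")
}

## ---- PROSITE-verbose patterns ---------------------------------------------

.pat_class <- function(residues) list(type = "class",
                                      residues = sort(unique(residues)))
.pat_x <- function(min, max) list(type = "x", min = min, max = max)

#' Serialize pattern elements to PROSITE-verbose text
#' @param pattern A `prosite_pattern` or element list.
#' @return Pattern text, e.g. `"D-[DN]-x(2,5)-A"`.
#' @export
pattern_text <- function(pattern) {
  elems <- if (inherits(pattern, "prosite_pattern")) pattern$elements else pattern
  paste(vapply(elems, function(e) {
    if (e$type == "class") {
      if (length(e$residues) == 1) e$residues else
        paste0("[", paste(e$residues, collapse = ""), "]")
    } else {
      if (e$min == e$max) {
        if (e$min == 1) "x" else sprintf("x(%d)", e$min)
      } else sprintf("x(%d,%d)", e$min, e$max)
    }
  }, character(1)), collapse = "-")
}

#' Parse a PROSITE-verbose pattern
#'
#' Supports residue classes (`A` or `[ACD]`) and bounded wildcards
#' (`x`, `x(3)`, `x(2,5)`), dash-separated.
#'
#' @param text Pattern text.
#' @return A `prosite_pattern` (elements + text).
#' @export
parse_pattern <- function(text) {
  toks <- strsplit(gsub("\\s", "", text), "-", fixed = FALSE)[[1]]
  if (!length(toks)) stop("empty pattern")
  elems <- lapply(toks, function(tk) {
    if (grepl("^\\[([A-WY]+)\\]$", tk)) {
      .pat_class(strsplit(sub("^\\[", "", sub("\\]$", "", tk)), "")[[1]])
    } else if (grepl("^[A-WY]$", tk) && tk != "X") {
      .pat_class(tk)
    } else if (tk == "x") {
      .pat_x(1, 1)
    } else if (grepl("^x\\(\\d+\\)$", tk)) {
      n <- as.integer(sub("^x\\((\\d+)\\)$", "\\1", tk))
      .pat_x(n, n)
    } else if (grepl("^x\\(\\d+,\\d+\\)$", tk)) {
      mn <- as.integer(sub("^x\\((\\d+),\\d+\\)$", "\\1", tk))
      mx <- as.integer(sub("^x\\(\\d+,(\\d+)\\)$", "\\1", tk))
      if (mn > mx) stop("wildcard with min > max: ", tk)
      .pat_x(mn, mx)
    } else stop("cannot parse pattern token: ", tk)
  })
  prosite_pattern(elems)
}

#' Construct a PROSITE pattern from elements
#' @param elements List of class/wildcard elements.
#' @return A list of class `prosite_pattern` with `elements` and `text`.
#' @export
prosite_pattern <- function(elements) {
  for (e in elements) {
    if (e$type == "class") {
      if (!length(e$residues)) stop("empty residue class")
      if (any(!e$residues %in% .aa20)) stop("residue class outside 20 amino acids")
    } else if (e$type == "x") {
      if (e$min > e$max || e$min < 0) stop("bad wildcard bounds")
    } else stop("unknown element type")
  }
  structure(list(elements = elements, text = pattern_text(elements)),
            class = "prosite_pattern")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("PROSITE pattern:", x$text, "\n"); invisible(x)
}

#' Assemble a PROSITE pattern from a group logo
#'
#' Each selected column becomes the class of all residues observed above
#' `min_freq` (default 0: every observed substitution is included, the
#' inclusive convention used to probe group membership); between segments a
#' bounded wildcard `x(min,max)` is inserted from the segment spec's gap
#' ranges.
#'
#' @param logo A [build_group_logo()] result.
#' @param spec The [segment_spec()] the logo was built on (defaults to the
#'   one stored in the logo).
#' @param min_freq Frequency floor; residues with frequency strictly greater
#'   are kept.
#' @return A `prosite_pattern`.
#' @export
assemble_pattern <- function(logo, spec = logo$spec, min_freq = 0) {
  elems <- list()
  k <- 0
  for (s in seq_along(spec$segments)) {
    seg <- spec$segments[[s]]
    for (col in seq(seg[1], seg[2])) {
      k <- k + 1
      res <- .aa20[logo$freq[, k] > min_freq]
      if (!length(res))
        stop("empty residue class at alignment column ", col)
      elems <- c(elems, list(.pat_class(res)))
    }
    if (s < length(spec$segments)) {
      g <- spec$gap_ranges[[s]]
      elems <- c(elems, list(.pat_x(g[1], g[2])))
    }
  }
  prosite_pattern(elems)
}

#' PROSITE pattern directly from a synthetic segment model
#'
#' @param model One element of [demo_segment_models()].
#' @return A `prosite_pattern` whose classes are the model's allowed residues
#'   and whose wildcards are the model's linker ranges.
#' @export
model_pattern <- function(model) {
  elems <- list()
  for (s in seq_along(model$segments)) {
    for (allowed in model$segments[[s]])
      elems <- c(elems, list(.pat_class(strsplit(allowed, "")[[1]])))
    if (s < length(model$segments)) {
      g <- model$gap_ranges[[s]]
      elems <- c(elems, list(.pat_x(g[1], g[2])))
    }
  }
  prosite_pattern(elems)
}

## Backtracking matcher.  Wildcards expand leftmost-then-shortest, i.e. the
## reported match at a start position is the one a lazy regular expression
## would produce; one hit is reported per matching start position.
.match_at <- function(codes, start, elems, class_sets, n) {
  nE <- length(elems)
  ends <- integer(nE)  # matched end offset per element
  rec <- function(e, i) {
    if (e > nE) return(i - 1L)
    el <- elems[[e]]
    if (el$type == "class") {
      if (i <= n && class_sets[[e]][codes[i]]) {
        r <- rec(e + 1L, i + 1L)
        if (!is.na(r)) { ends[e] <<- i; return(r) }
      }
      return(NA_integer_)
    }
    for (k in el$min:el$max) {
      if (i + k - 1L > n) break
      r <- rec(e + 1L, i + k)
      if (!is.na(r)) { ends[e] <<- i + k - 1L; return(r) }
    }
    NA_integer_
  }
  end <- rec(1L, start)
  if (is.na(end)) return(NULL)
  list(end = end, ends = ends)
}

#' Scan sequences with a PROSITE pattern
#'
#' Reports every matching start position (overlapping hits included); for
#' variable-length wildcards the leftmost-then-shortest expansion is the one
#' reported for each start.
#'
#' @param pattern A `prosite_pattern` (or pattern text).
#' @param seqs A `seq_set` or named character vector of unaligned sequences.
#' @return data.frame of class `scan_hits`: `id`, `start`, `end` (1-based,
#'   inclusive) and `segments`, a list column of k x 2 matrices giving the
#'   matched span of each run of consecutive class positions.
#' @export
scan_pattern <- function(pattern, seqs) {
  if (is.character(pattern) && length(pattern) == 1)
    pattern <- parse_pattern(pattern)
  if (inherits(seqs, "seq_set")) {
    ids <- seqs$id; ss <- seqs$seq
  } else {
    ss <- unlist(seqs)
    ids <- if (is.null(names(ss))) sprintf("seq%d", seq_along(ss)) else names(ss)
  }
  elems <- pattern$elements
  class_sets <- lapply(elems, function(e) {
    if (e$type != "class") return(NULL)
    v <- logical(26); v[match(e$residues, LETTERS)] <- TRUE; v
  })
  ## element index of each segment run (consecutive classes)
  is_class <- vapply(elems, function(e) e$type == "class", logical(1))
  runs <- rle(is_class)
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  seg_runs <- unique(run_id[is_class])
  out_id <- character(0); out_start <- integer(0); out_end <- integer(0)
  out_seg <- list()
  first_class <- if (is_class[1]) class_sets[[1]] else NULL
  for (si in seq_along(ss)) {
    codes <- match(strsplit(ss[si], "")[[1]], LETTERS)
    n <- length(codes)
    if (n == 0) next
    for (st in seq_len(n)) {
      if (!is.null(first_class) && !first_class[codes[st]]) next
      m <- .match_at(codes, st, elems, class_sets, n)
      if (is.null(m)) next
      spans <- t(vapply(seg_runs, function(r) {
        idx <- which(run_id == r & is_class)
        st_el <- idx[1]; en_el <- idx[length(idx)]
        start_pos <- if (st_el == 1) st else m$ends[st_el - 1L] + 1L
        c(start_pos, m$ends[en_el])
      }, integer(2)))
      out_id <- c(out_id, ids[si])
      out_start <- c(out_start, st)
      out_end <- c(out_end, m$end)
      out_seg <- c(out_seg, list(spans))
    }
  }
  hits <- data.frame(id = out_id, start = out_start, end = out_end,
                     stringsAsFactors = FALSE)
  hits$segments <- out_seg
  class(hits) <- c("scan_hits", "data.frame")
  hits
}

#' Taxonomic profile of scan hits
#'
#' Tallies hits per taxon and, when an intended target group is named,
#' reports the specificity (in-group hits over total hits).
#'
#' @param hits A [scan_pattern()] result.
#' @param taxon_labels Named character vector, sequence id -> taxon.
#' @param target_group Optional taxon the pattern was built for.
#' @return List of class `taxonomic_profile`: `counts` (data.frame
#'   taxon/hits), `total`, `specificity` (NA when no hits or no target).
#' @export
profile_hits <- function(hits, taxon_labels, target_group = NULL) {
  if (nrow(hits) == 0) {
    return(structure(list(counts = data.frame(taxon = character(0),
                                              hits = integer(0)),
                          total = 0L, specificity = NA_real_,
                          target_group = target_group),
                     class = "taxonomic_profile"))
  }
  tax <- taxon_labels[hits$id]
  tax[is.na(tax)] <- "unknown"
  tab <- sort(table(tax), decreasing = TRUE)
  spec <- if (is.null(target_group)) NA_real_ else
    sum(tax == target_group) / length(tax)
  structure(list(counts = data.frame(taxon = names(tab),
                                     hits = as.integer(tab),
                                     stringsAsFactors = FALSE),
                 total = nrow(hits), specificity = spec,
                 target_group = target_group),
            class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat("taxonomic profile:", x$total, "hits\n")
  if (nrow(x$counts)) print(x$counts, row.names = FALSE)
  if (!is.na(x$specificity))
    cat(sprintf("specificity for %s: %.3f\n", x$target_group, x$specificity))
  invisible(x)
}

#' Iteratively refine a pattern against a database
#'
#' Each round scans the database, extracts the matched segment instances
#' (the pattern match itself localizes the segments in every hit),
#' removes exact duplicate segment tuples, rebuilds the per-column residue
#' classes from the retained instances, and reassembles the pattern with the
#' original wildcard ranges.  Stops early when the pattern text reaches a
#' fixed point.
#'
#' @param pattern A `prosite_pattern`.
#' @param db A `seq_set` database.
#' @param rounds Maximum refinement rounds (>= 1).
#' @param min_freq Frequency floor for class membership when rebuilding.
#' @return List of class `refined_pattern`: `pattern`, `rounds_run`,
#'   `status` (`"fixed_point"`, `"max_rounds"` or `"no_hits"`), `n_instances`.
#' @export
refine_pattern <- function(pattern, db, rounds = 5, min_freq = 0) {
  stopifnot(rounds >= 1)
  cur <- pattern
  status <- "max_rounds"; used <- 0L; n_inst <- 0L
  for (r in seq_len(rounds)) {
    hits <- scan_pattern(cur, db)
    if (nrow(hits) == 0) {
      warning("refinement round ", r, " produced no hits; keeping last pattern")
      status <- "no_hits"; used <- r
      break
    }
    seq_lookup <- stats::setNames(db$seq, db$id)
    tuples <- vapply(seq_len(nrow(hits)), function(i) {
      spans <- hits$segments[[i]]
      paste(vapply(seq_len(nrow(spans)), function(k)
        substr(seq_lookup[hits$id[i]], spans[k, 1], spans[k, 2]),
        character(1)), collapse = "|")
    }, character(1))
    inst <- unique(tuples)
    n_inst <- length(inst)
    segs <- strsplit(inst, "|", fixed = TRUE)
    ## positions of class elements, segment by segment
    is_class <- vapply(cur$elements, function(e) e$type == "class", logical(1))
    seg_lens <- rle(is_class)
    widths <- seg_lens$lengths[seg_lens$values]
    col_res <- vector("list", sum(widths))
    p <- 0
    for (s in seq_along(widths)) {
      for (j in seq_len(widths[s])) {
        p <- p + 1
        obs <- vapply(segs, function(tt) substr(tt[s], j, j), character(1))
        tab <- table(factor(obs, levels = .aa20)) / length(obs)
        res <- .aa20[tab > min_freq]
        if (!length(res)) stop("empty class while refining (segment ", s,
                               " position ", j, ")")
        col_res[[p]] <- res
      }
    }
    new_elems <- list(); p <- 0
    for (e in cur$elements) {
      if (e$type == "x") new_elems <- c(new_elems, list(e))
      else { p <- p + 1; new_elems <- c(new_elems, list(.pat_class(col_res[[p]]))) }
    }
    nxt <- prosite_pattern(new_elems)
    used <- r
    if (nxt$text == cur$text) { status <- "fixed_point"; break }
    cur <- nxt
  }
  structure(list(pattern = cur, rounds_run = used, status = status,
                 n_instances = n_inst),
            class = "refined_pattern")
}
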