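## Sequence collections, FASTA I/O, pairwise identity, greedy identity-tier
## filtering and parsimony-informative site counting.
##
## A sequence collection ("seq_set") is a data.frame with columns
## id / desc / taxon / seq; an alignment adds the constraint that all seq
## strings have equal length.  Grouped alignments carry per-sequence group
## labels plus the ordered succession of groups (see grouped_alignment()).

.aa_ok_unaligned <- function(x) grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", x)
.aa_ok_aligned   <- function(x) grepl("^[ACDEFGHIKLMNPQRSTVWYX-]+$", x)

#' Construct a sequence collection
#'
#' @param id Character vector of unique, nonempty identifiers.
#' @param seq Character vector of residues (20 amino acids plus 'X';
#'   '-' permitted only when `aligned = TRUE`).
#' @param desc Optional descriptions.
#' @param taxon Optional taxon labels.
#' @param aligned Allow gap characters (and require equal lengths).
#' @return A data.frame of class `seq_set`.
#' @export
seq_set <- function(id, seq, desc = NULL, taxon = NULL, aligned = FALSE) {
  id <- as.character(id); seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(!nzchar(id))) stop("empty sequence id")
  if (anyDuplicated(id)) stop("duplicate sequence id: ", id[duplicated(id)][1])
  if (length(seq) && any(!nzchar(seq))) stop("empty sequence: ", id[!nzchar(seq)][1])
  ok <- if (aligned) .aa_ok_aligned(seq) else .aa_ok_unaligned(seq)
  if (length(seq) && any(!ok))
    stop("illegal residue character in sequence '", id[!ok][1], "'")
  if (aligned && length(seq) && length(unique(nchar(seq))) != 1L)
    stop("aligned sequences must all have the same length")
  out <- data.frame(
    id = id, seq = seq,
    desc = if (is.null(desc)) rep("", length(id)) else as.character(desc),
    taxon = if (is.null(taxon)) rep(NA_character_, length(id)) else as.character(taxon),
    stringsAsFactors = FALSE
  )
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Accepts aligned or unaligned protein FASTA.  Record order is preserved;
#' the id is the first whitespace-delimited token of the header, the rest
#' becomes the description.
#'
#' @param path Path to a FASTA file.
#' @param aligned Whether gap characters are permitted.
#' @return A `seq_set`.
#' @export
read_fasta <- function(path, aligned = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  nonblank <- nzchar(trimws(lines))
  if (!any(hdr)) stop("not a FASTA file (no '>' header): ", path)
  first_bad <- which(nonblank & !hdr)
  if (length(first_bad) && first_bad[1] < which(hdr)[1])
    stop("FASTA parse error at line ", first_bad[1], ": sequence before first header")
  rec <- cumsum(hdr)
  ids <- desc <- character(sum(hdr))
  seqs <- character(sum(hdr))
  hline <- which(hdr)
  for (k in seq_along(hline)) {
    h <- sub("^>", "", lines[hline[k]])
    ids[k] <- sub("\\s.*$", "", h)
    desc[k] <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    body <- lines[rec == k & !hdr & nonblank]
    seqs[k] <- toupper(gsub("\\s", "", paste(body, collapse = "")))
  }
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  any_gap <- any(grepl("-", seqs, fixed = TRUE))
  if (is.na(aligned)) aligned <- any_gap
  ok <- if (aligned) .aa_ok_aligned(seqs) else .aa_ok_unaligned(seqs)
  if (any(!ok)) {
    bad <- which(!ok)[1]
    body_lines <- which(rec == bad & !hdr & nonblank)
    badline <- body_lines[grepl(if (aligned) "[^ACDEFGHIKLMNPQRSTVWYX-]" else
                                "[^ACDEFGHIKLMNPQRSTVWYX]",
                                toupper(gsub("\\s", "", lines[body_lines])))][1]
    if (is.na(badline)) badline <- body_lines[1]
    stop("FASTA parse error at line ", badline,
         ": illegal character in record '", ids[bad], "'")
  }
  seq_set(ids, seqs, desc = desc, aligned = aligned)
}

#' Write a sequence collection to FASTA
#'
#' @param seqs A `seq_set`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    hdr <- if (nzchar(seqs$desc[i])) paste(seqs$id[i], seqs$desc[i]) else seqs$id[i]
    writeLines(paste0(">", hdr), con)
    s <- seqs$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a two-column id/group label table
#'
#' @param path TSV with columns id and group (no header).
#' @return Named character vector, id -> group.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("id", "group"),
                           colClasses = "character", quote = "")
  stats::setNames(tab$group, tab$id)
}

#' Write id/group labels as TSV
#' @param labels Named character vector (id -> group).
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(names(labels), unname(labels)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Grouped multiple sequence alignment
#'
#' Bundles a gapped protein alignment with per-sequence phylogroup labels and
#' the ordered succession of phylogroups (oldest first) used for
#' fixation-stage tracing.
#'
#' @param seqs A `seq_set` of equal-length gapped sequences.
#' @param labels Named character vector mapping every sequence id to a group.
#' @param group_order Character vector of groups, oldest (outgroup) first.
#'   Defaults to the groups in order of first appearance.
#' @return An object of class `grouped_alignment` with elements `seqs`,
#'   `labels`, `group_order`, `L` (alignment width).
#' @export
grouped_alignment <- function(seqs, labels, group_order = NULL) {
  if (!inherits(seqs, "seq_set")) seqs <- seq_set(seqs$id, seqs$seq, aligned = TRUE)
  if (nrow(seqs) == 0) stop("empty alignment")
  if (length(unique(nchar(seqs$seq))) != 1L) stop("sequences have unequal lengths")
  miss <- setdiff(seqs$id, names(labels))
  if (length(miss)) stop("unlabeled sequence id: ", miss[1])
  labels <- labels[seqs$id]
  if (is.null(group_order)) group_order <- unique(unname(labels))
  bad <- setdiff(unique(labels), group_order)
  if (length(bad)) stop("label not in group_order: ", bad[1])
  if (any(!group_order %in% labels))
    stop("group_order contains empty group: ",
         setdiff(group_order, labels)[1])
  structure(list(seqs = seqs, labels = labels, group_order = group_order,
                 L = nchar(seqs$seq[1])),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat("grouped_alignment:", nrow(x$seqs), "sequences x", x$L, "columns\n")
  cat("groups (ordered):",
      paste(sprintf("%s(%d)", x$group_order, table(factor(x$labels, x$group_order))),
            collapse = " -> "), "\n")
  invisible(x)
}

#' Alignment as a character matrix (rows = sequences, columns = positions)
#' @param aln A `grouped_alignment` or aligned `seq_set`.
#' @return Character matrix with sequence ids as rownames.
#' @export
aln_matrix <- function(aln) {
  seqs <- if (inherits(aln, "grouped_alignment")) aln$seqs else aln
  m <- do.call(rbind, strsplit(seqs$seq, "", fixed = TRUE))
  rownames(m) <- seqs$id
  m
}

#' Pairwise global identity between two unaligned protein sequences
#'
#' Global (Needleman-Wunsch) alignment with affine gaps, BLOSUM62,
#' gap open 11 / extend 1 (via Biostrings).  Identity is the fraction of
#' alignment columns carrying the same residue, over all columns except
#' those where both sequences would have a terminal gap; internal gaps
#' count as mismatches and 'X' matches nothing.
#'
#' @param a,b Unaligned sequence strings (or single-row `seq_set`s).
#' @return A list of class `identity_result`: `aligned_a`, `aligned_b`,
#'   `score`, `identity`.
#' @export
pairwise_identity <- function(a, b) {
  a <- .as_seqstring(a); b <- .as_seqstring(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  ## canonical orientation: co-optimal tracebacks depend on argument order,
  ## so align with the lexicographically smaller sequence as pattern and
  ## swap back, making the result exactly symmetric
  if (a > b) {
    r <- pairwise_identity(b, a)
    return(structure(list(aligned_a = r$aligned_b, aligned_b = r$aligned_a,
                          score = r$score, identity = r$identity),
                     class = "identity_result"))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1, type = "global")
  p <- Biostrings::pattern(pa); s <- Biostrings::subject(pa)
  ## reassemble full gapped strings: the aligned core plus any unaligned
  ## flanks, padded against terminal gaps
  a_pre <- substr(a, 1, BiocGenerics::start(p) - 1)
  a_suf <- substr(a, BiocGenerics::end(p) + 1, nchar(a))
  b_pre <- substr(b, 1, BiocGenerics::start(s) - 1)
  b_suf <- substr(b, BiocGenerics::end(s) + 1, nchar(b))
  al_a <- paste0(a_pre, strrep("-", nchar(b_pre)), as.character(p),
                 a_suf, strrep("-", nchar(b_suf)))
  al_b <- paste0(strrep("-", nchar(a_pre)), b_pre, as.character(s),
                 strrep("-", nchar(a_suf)), b_suf)
  structure(list(aligned_a = al_a, aligned_b = al_b,
                 score = Biostrings::score(pa),
                 identity = aligned_identity(al_a, al_b)),
            class = "identity_result")
}

.pkg_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

.as_seqstring <- function(x) {
  if (inherits(x, "seq_set")) {
    if (nrow(x) != 1L) stop("expected a single sequence")
    x <- x$seq
  }
  toupper(as.character(x))
}

#' Identity fraction of two aligned (gapped) strings
#'
#' Columns where both strings have a terminal gap are excluded from the
#' denominator; a column counts as identical only when both residues are
#' equal, non-gap and not 'X'.
#'
#' @param al_a,al_b Equal-length gapped strings.
#' @return Fraction in [0, 1].
#' @export
aligned_identity <- function(al_a, al_b) {
  ca <- strsplit(al_a, "")[[1]]; cb <- strsplit(al_b, "")[[1]]
  if (length(ca) != length(cb)) stop("aligned strings differ in length")
  term <- function(ch) {
    n <- length(ch); t <- rep(FALSE, n)
    i <- 1; while (i <= n && ch[i] == "-") { t[i] <- TRUE; i <- i + 1 }
    i <- n; while (i >= 1 && ch[i] == "-") { t[i] <- TRUE; i <- i - 1 }
    t
  }
  keep <- !(term(ca) & term(cb))
  if (!any(keep)) return(0)
  same <- ca == cb & ca != "-" & ca != "X"
  sum(same & keep) / sum(keep)
}

#' Greedy identity-tier filtering
#'
#' Visits sequences longest-first (ties broken by id) and retains a sequence
#' iff its pairwise identity to every already-retained representative is
#' below `threshold`.  This is the representative-selection step used to
#' curate sequence sets at, e.g., 95%, 70% or 60% identity tiers.
#'
#' @param seqs A `seq_set` of unaligned sequences.
#' @param threshold Identity fraction in (0, 1].
#' @return The retained representatives, in retention order, as a `seq_set`
#'   with attribute `"discarded"` (ids of removed sequences).
#' @export
greedy_filter <- function(seqs, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(seqs) == 0) return(seqs)
  ord <- order(-nchar(seqs$seq), seqs$id)
  seqs <- seqs[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(seqs))) {
    dup <- FALSE
    for (j in keep) {
      if (pairwise_identity(seqs$seq[i], seqs$seq[j])$identity >= threshold) {
        dup <- TRUE; break
      }
    }
    if (!dup) keep <- c(keep, i)
  }
  out <- seqs[keep, , drop = FALSE]
  class(out) <- c("seq_set", "data.frame")
  attr(out, "discarded") <- setdiff(seqs$id, out$id)
  out
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when it holds at least two distinct
#' residue states, each present in at least two sequences.  Gaps and 'X'
#' are treated as missing data.
#'
#' @param aln A `grouped_alignment` or aligned `seq_set`.
#' @return Integer count of informative columns.
#' @export
count_pi_sites <- function(aln) {
  m <- aln_matrix(aln)
  sum(apply(m, 2, function(col) {
    tab <- table(col[col != "-" & col != "X"])
    sum(tab >= 2) >= 2
  }))
}
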