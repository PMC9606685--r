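# Independent oracles and small random-input generators shared across tests.
# Each oracle is a deliberately naive reimplementation, kept independent of
# the package code paths it checks.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Gotoh affine-gap global alignment *score* (gap of length k costs
# open + k * ext; end gaps penalized), as a dynamic-programming oracle for
# the optimal score underlying pairwise_identity().
nw_affine_score <- function(a, b, open = 11, ext = 1, mat = blosum62) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - (i - 1) * ext
  for (j in 2:(m + 1)) Iy[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Regular-expression translation oracle for PROSITE scanning: classes become
# character sets, bounded wildcards become lazy bounded repeats; one anchored
# lazy match is attempted at every start position.
pattern_to_regex <- function(pattern) {
  paste(vapply(pattern$elements, function(e) {
    if (e$type == "class") {
      if (length(e$residues) == 1) e$residues
      else paste0("[", paste(e$residues, collapse = ""), "]")
    } else {
      if (e$min == e$max) sprintf(".{%d}", e$min)
      else sprintf(".{%d,%d}?", e$min, e$max)
    }
  }, character(1)), collapse = "")
}

regex_scan <- function(pattern, seqs) {
  rx <- paste0("^(", pattern_to_regex(pattern), ")")
  ids <- if (inherits(seqs, "seq_set")) seqs$id else names(seqs)
  ss <- if (inherits(seqs, "seq_set")) seqs$seq else unlist(seqs)
  out <- data.frame(id = character(0), start = integer(0), end = integer(0))
  for (k in seq_along(ss)) {
    n <- nchar(ss[k])
    for (st in seq_len(n)) {
      m <- regexpr(rx, substring(ss[k], st), perl = TRUE)
      if (m == 1) {
        out <- rbind(out, data.frame(
          id = ids[k], start = st,
          end = st + attr(m, "match.length") - 1L))
      }
    }
  }
  out
}

random_pattern <- function(n_elems = sample(3:7, 1), alphabet = AA20) {
  elems <- list()
  last_wild <- TRUE  # avoid leading wildcard ambiguity being untested: allow all
  for (i in seq_len(n_elems)) {
    if (!last_wild && stats::runif(1) < 0.35) {
      mn <- sample(0:3, 1)
      elems <- c(elems, list(list(type = "x", min = mn,
                                  max = mn + sample(0:3, 1))))
      last_wild <- TRUE
    } else {
      elems <- c(elems, list(list(type = "class",
                                  residues = sort(sample(alphabet,
                                                         sample(1:4, 1))))))
      last_wild <- FALSE
    }
  }
  prosite_pattern(elems)
}

# Two-group synthetic spec with planted type I and type II columns, used by
# the recovery tests.
recovery_spec <- function(seed, n_typeII = 10, n_typeI = 10, length = 100,
                          sizes = 20) {
  gm <- grantham_matrix()
  rad <- which(gm >= 60, arr.ind = TRUE)
  set.seed(seed * 131 + 7)
  cols <- sort(sample.int(length, n_typeII + n_typeI))
  plants <- list()
  for (i in seq_len(n_typeII)) {
    pr <- rad[sample.int(nrow(rad), 1), ]
    res <- stats::setNames(c(rownames(gm)[pr[1]], colnames(gm)[pr[2]]),
                           c("g1", "g2"))
    plants <- c(plants, list(plant_typeII(cols[i], res)))
  }
  for (i in seq_len(n_typeI)) {
    r <- sample(rownames(gm), 1)
    plants <- c(plants, list(
      plant_typeI(cols[n_typeII + i], "g1", r,
                  sample(setdiff(rownames(gm), r), 4))))
  }
  synthetic_spec(c("g1", "g2"), sizes = sizes, length = length,
                 planted_sites = plants, seed = seed)
}
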