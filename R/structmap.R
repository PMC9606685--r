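## CA-trace structure models: PDB I/O (via bio3d), MSA-column/residue maps,
## residue neighbor networks per conformation, conformation comparison,
## Kabsch superposition RMSD, and classical MDS conformer maps.

#' Construct a CA-trace structure model
#' @param id Model identifier.
#' @param resno Strictly increasing residue numbers.
#' @param resid One-letter residue codes.
#' @param xyz n x 3 matrix of CA coordinates (Angstrom).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(id, resno, resid, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must be n x 3")
  if (length(resno) != nrow(xyz) || length(resid) != nrow(xyz))
    stop("resno/resid/xyz lengths differ")
  if (is.unsorted(resno, strictly = TRUE))
    stop("residue numbers must be strictly increasing")
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(id = id, resno = as.integer(resno),
                 resid = as.character(resid), xyz = xyz),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model", x$id, "-", length(x$resno), "CA atoms\n")
  invisible(x)
}

#' Read CA coordinates from a PDB file
#'
#' Takes the first model and (by default) the first chain; keeps ATOM
#' records with atom name CA and altloc '' or 'A'.  Insertion codes are
#' appended to the residue number.
#'
#' @param path PDB file.
#' @param chain Chain identifier (default: first chain present).
#' @param id Model id (default: file base name).
#' @return A `structure_model`.
#' @export
read_pdb_ca <- function(path, chain = NULL, id = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$elety == "CA" &
    (is.na(at$alt) | at$alt %in% c("", " ", "A"))
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no CA atoms in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain | is.na(at$chain), , drop = FALSE]
  if (!nrow(at)) stop("no CA atoms for chain ", chain, " in ", path)
  resno <- at$resno
  ins <- !is.na(at$insert) & nzchar(at$insert)
  if (any(ins))
    resno <- as.integer(paste0(at$resno, ifelse(ins, match(at$insert, LETTERS), "")))
  one <- bio3d::aa321(at$resid)
  one[is.na(one) | one == ""] <- "X"
  structure_model(if (is.null(id)) sub("\\.pdb$", "", basename(path)) else id,
                  resno, one, cbind(at$x, at$y, at$z))
}

#' Write a CA-trace model as a PDB file
#' @param model A `structure_model`.
#' @param path Output path.
#' @param chain Chain identifier to write.
#' @export
write_pdb_ca <- function(model, path, chain = "A") {
  resid3 <- bio3d::aa123(model$resid)
  resid3[is.na(resid3)] <- "UNK"
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(model$xyz)),
                   resno = model$resno, resid = resid3,
                   elety = rep("CA", length(model$resno)),
                   chain = rep(chain, length(model$resno)))
  invisible(path)
}

#' Map alignment columns to structure residues
#'
#' Walks two equal-length gapped rows (the family-alignment query and the
#' structure's sequence) and maps every column where both rows are non-gap
#' to the corresponding residue index of the model; columns whose letters
#' disagree are reported as mismatches.
#'
#' @param gapped_query Gapped query row (string).
#' @param gapped_structure_seq Gapped structure-sequence row (string).
#' @return List of class `column_residue_map`: `map` (named integer vector,
#'   column -> residue index) and `mismatches` (data.frame column, query,
#'   structure).
#' @export
map_columns <- function(gapped_query, gapped_structure_seq) {
  q <- strsplit(gapped_query, "")[[1]]
  s <- strsplit(gapped_structure_seq, "")[[1]]
  if (length(q) != length(s)) stop("gapped rows differ in length")
  res_idx <- cumsum(s != "-")
  both <- which(q != "-" & s != "-")
  map <- stats::setNames(res_idx[both], both)
  mm <- both[q[both] != s[both]]
  structure(list(map = map,
                 mismatches = data.frame(column = mm, query = q[mm],
                                         structure = s[mm],
                                         stringsAsFactors = FALSE)),
            class = "column_residue_map")
}

#' Residue neighbor network on one conformation
#'
#' Nodes are alignment columns (sites); an edge joins two sites whose mapped
#' CA atoms lie within `cutoff` Angstrom in this conformation.
#'
#' @param model A `structure_model`.
#' @param map A [map_columns()] result, or a named integer vector
#'   column -> residue index, or NULL for the identity map (site = residue
#'   index).
#' @param sites Alignment columns of interest.
#' @param cutoff CA-CA contact distance (Angstrom, default 10).
#' @return List of class `residue_network`: `nodes` (mapped sites), `edges`
#'   (data.frame a, b, dist), `unmapped`, `conformation`, `cutoff`.
#' @export
neighbor_network <- function(model, map = NULL, sites, cutoff = 10) {
  if (inherits(map, "column_residue_map")) map <- map$map
  if (is.null(map))
    map <- stats::setNames(seq_along(model$resno), seq_along(model$resno))
  ri <- map[as.character(sites)]
  mapped <- sites[!is.na(ri)]
  unmapped <- sites[is.na(ri)]
  ri <- ri[!is.na(ri)]
  edges <- data.frame(a = numeric(0), b = numeric(0), dist = numeric(0))
  if (length(mapped) > 1) {
    d <- as.matrix(stats::dist(model$xyz[ri, , drop = FALSE]))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    if (nrow(idx))
      edges <- data.frame(a = mapped[idx[, 1]], b = mapped[idx[, 2]],
                          dist = d[idx])
  }
  structure(list(nodes = mapped, edges = edges, unmapped = unmapped,
                 conformation = model$id, cutoff = cutoff),
            class = "residue_network")
}

#' Connected components of a residue network
#' @param network A [neighbor_network()] result.
#' @return List of numeric vectors (site sets), ordered by smallest member.
#' @export
network_components <- function(network) {
  if (!length(network$nodes)) return(list())
  g <- igraph::graph_from_data_frame(
    d = data.frame(a = as.character(network$edges$a),
                   b = as.character(network$edges$b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes)))
  mem <- igraph::components(g)$membership
  comps <- unname(lapply(split(names(mem), mem), function(v) sort(as.numeric(v))))
  comps[order(vapply(comps, min, numeric(1)))]
}

#' Compare residue networks between two conformations
#'
#' For each site present in both networks, reports its neighbor sets in A
#' and B and their Jaccard similarity; sites with Jaccard < 1 are flagged as
#' spatially rearranged.  The report is symmetric in (A, B).
#'
#' @param netA,netB [neighbor_network()] results on the same sites.
#' @return data.frame of class `conformation_comparison`: site, jaccard,
#'   rearranged, neighbors_a, neighbors_b.
#' @export
compare_conformations <- function(netA, netB) {
  sites <- sort(intersect(netA$nodes, netB$nodes))
  nbr <- function(net, s) {
    sort(c(net$edges$b[net$edges$a == s], net$edges$a[net$edges$b == s]))
  }
  rows <- lapply(sites, function(s) {
    na <- nbr(netA, s); nb <- nbr(netB, s)
    un <- union(na, nb)
    j <- if (!length(un)) 1 else length(intersect(na, nb)) / length(un)
    data.frame(site = s, jaccard = j, rearranged = j < 1,
               neighbors_a = paste(na, collapse = ","),
               neighbors_b = paste(nb, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("conformation_comparison", "data.frame")
  out
}

#' Kabsch superposition
#'
#' Optimal rigid-body superposition (proper rotation + translation)
#' minimizing the RMSD between two matched point sets, via SVD of the
#' cross-covariance with a determinant correction to exclude reflections.
#'
#' @param X,Y n x 3 coordinate matrices (n >= 3), or `structure_model`s.
#' @return List: `R` (3 x 3 rotation applied to centered X), `rmsd`.
#' @export
kabsch <- function(X, Y) {
  if (inherits(X, "structure_model")) X <- X$xyz
  if (inherits(Y, "structure_model")) Y <- Y$xyz
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("point counts differ")
  if (nrow(X) < 3) stop("need >= 3 points")
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  C <- crossprod(Xc, Yc)           # t(Xc) %*% Yc
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # rotates centered X onto Yc
  diff <- Xc %*% t(R) - Yc
  list(R = R, rmsd = sqrt(sum(diff^2) / nrow(X)))
}

#' Kabsch RMSD between two matched point sets
#' @inheritParams kabsch
#' @return Minimal RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(X, Y) kabsch(X, Y)$rmsd

#' Classical MDS embedding of a distance matrix
#'
#' Double centering of the squared-distance matrix followed by
#' eigendecomposition; the top-2 positive eigenvalues give the planar
#' embedding (exact when the distances are Euclidean of rank <= 2).
#'
#' @param D Symmetric distance matrix.
#' @param k Embedding dimension.
#' @return List: `points` (n x k), `eig` (all eigenvalues).
#' @export
mds_embed <- function(D, k = 2) {
  fit <- stats::cmdscale(as.dist(D), k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  list(points = pts, eig = fit$eig)
}

#' MDS conformer map of structure models
#'
#' Computes the all-against-all Kabsch RMSD matrix over the models' common
#' CA length, embeds it with classical MDS (top 2 components), and labels
#' every model by its nearest reference in the full distance matrix (not in
#' the 2D projection, avoiding projection artifacts).
#'
#' @param models Named list of `structure_model`s (or n x 3 matrices), all
#'   with the same number of CA atoms; >= 3 models required.
#' @param references Names of the models serving as conformational
#'   references.
#' @return List of class `conformer_embedding`: `points` (data.frame model,
#'   x, y, nearest_ref, ref_dist, is_ref), `eig`, `D`.
#' @export
mds_map <- function(models, references) {
  if (length(models) < 3) stop("need >= 3 models")
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("models must be named")
  miss <- setdiff(references, names(models))
  if (length(miss)) stop("unknown reference: ", miss[1])
  n <- length(models)
  D <- matrix(0, n, n, dimnames = list(names(models), names(models)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- kabsch_rmsd(models[[i]], models[[j]])
  emb <- mds_embed(D, k = 2)
  nearest <- vapply(seq_len(n), function(i) {
    dd <- D[i, references]
    references[which.min(dd)]
  }, character(1))
  ref_dist <- vapply(seq_len(n), function(i) min(D[i, references]), numeric(1))
  pts <- data.frame(model = names(models),
                    x = emb$points[, 1], y = emb$points[, 2],
                    nearest_ref = nearest, ref_dist = ref_dist,
                    is_ref = names(models) %in% references,
                    stringsAsFactors = FALSE)
  structure(list(points = pts, eig = emb$eig, D = D),
            class = "conformer_embedding")
}
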