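# All-vs-all protein similarity, Markov clustering into orthogroups, and
# the one-gene-per-species / two-genes-per-species pair extraction rules.

#' Global protein alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment via
#' \code{Biostrings::pairwiseAlignment}, returning the optimal score,
#' percent identity over alignment columns, and coverage of the shorter
#' sequence.
#'
#' @param a,b Protein strings (non-empty).
#' @param matrix Substitution matrix name (default \code{"BLOSUM62"}).
#' @param gap_open,gap_extend Gap penalties as positive costs
#'   (defaults 10 and 1).
#' @return List with \code{score}, \code{identity} (percent, 0-100),
#'   \code{coverage} (aligned both-residue columns / shorter length),
#'   \code{aligned_a}, \code{aligned_b} (gapped strings).
#' @export
align_proteins_global <- function(a, b, matrix = "BLOSUM62",
                                  gap_open = 10, gap_extend = 1) {
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("cannot align an empty protein", call. = FALSE)
  }
  mat <- .subst_matrix(matrix)
  alph <- rownames(mat)
  for (seqs in c(a, b)) {
    bad <- setdiff(unique(strsplit(seqs, "")[[1]]), alph)
    if (length(bad) > 0) {
      stop("characters outside the substitution matrix alphabet: ",
           paste(bad, collapse = ""), call. = FALSE)
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  sa <- as.character(Biostrings::alignedPattern(pa))
  sb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  both <- ca != "-" & cb != "-"
  list(score = Biostrings::score(pa),
       identity = 100 * sum(ca == cb & both) / length(ca),
       coverage = sum(both) / min(nchar(a), nchar(b)),
       aligned_a = sa, aligned_b = sb)
}

.chunked_scores <- function(proteins, ii, jj, mat, chunk = 5000L,
                            gap_open = 10, gap_extend = 1) {
  scores <- numeric(length(ii))
  for (at in seq(1, length(ii), by = chunk)) {
    idx <- at:min(at + chunk - 1L, length(ii))
    scores[idx] <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins[ii[idx]]),
      Biostrings::AAStringSet(proteins[jj[idx]]),
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global", scoreOnly = TRUE)
  }
  scores
}

.subst_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  key <- paste0("mat_", matrix)
  if (is.null(.ksage[[key]])) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    .ksage[[key]] <- get(matrix, envir = e)
  }
  .ksage[[key]]
}

#' Build the all-vs-all protein similarity graph
#'
#' Aligns every unordered pair of proteins and keeps an edge when percent
#' identity, coverage, and raw score all meet their thresholds.  Edge
#' weights are alignment scores normalised by the geometric mean of the
#' two self-alignment scores, clipped to [0, 1], so downstream clustering
#' sees scale-free weights.
#'
#' @param proteins Named character vector of protein sequences (names are
#'   gene ids, unique).
#' @param species Character vector mapping each protein to its species
#'   label (same order/length as \code{proteins}).
#' @param min_identity Minimum percent identity (default 50).
#' @param min_coverage Minimum coverage of the shorter protein (default 0.5).
#' @param min_score Minimum raw alignment score (default 50).
#' @return data.frame of edges (gene_a, gene_b, species_a, species_b,
#'   score, identity, coverage, weight) with gene_a < gene_b.
#' @export
build_similarity_graph <- function(proteins, species, min_identity = 50,
                                   min_coverage = 0.5, min_score = 50) {
  stopifnot(length(proteins) == length(species),
            !is.null(names(proteins)), !anyDuplicated(names(proteins)))
  if (length(proteins) < 2) stop("need at least 2 proteins", call. = FALSE)
  ord <- order(names(proteins))
  proteins <- proteins[ord]
  species <- species[ord]
  ids <- names(proteins)
  mat <- .subst_matrix("BLOSUM62")
  self <- vapply(proteins, function(p) {
    chars <- strsplit(p, "")[[1]]
    sum(mat[cbind(chars, chars)])
  }, numeric(1))
  n <- length(proteins)
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- sequence((n - 1):1, from = 2:n)
  # cheap score-only pass over all pairs, element-wise and chunked; full
  # alignments (for identity/coverage) only where the score gate passes
  scores <- .chunked_scores(proteins, ii, jj, mat)
  keep <- which(scores >= min_score)
  out <- NULL
  if (length(keep) > 0) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins[ii[keep]]),
      Biostrings::AAStringSet(proteins[jj[keep]]),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
      type = "global")
    sa <- as.character(Biostrings::alignedPattern(pa))
    sb <- as.character(Biostrings::alignedSubject(pa))
    stat <- mapply(function(x, y, la, lb) {
      cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
      both <- cx != "-" & cy != "-"
      c(100 * sum(cx == cy & both) / length(cx), sum(both) / min(la, lb))
    }, sa, sb, nchar(proteins[ii[keep]]), nchar(proteins[jj[keep]]))
    identity <- stat[1, ]
    coverage <- stat[2, ]
    sc <- Biostrings::score(pa)
    ok2 <- identity >= min_identity & coverage >= min_coverage
    i <- ii[keep][ok2]; j <- jj[keep][ok2]
    if (any(ok2)) {
      w <- pmax(pmin(sc[ok2] / sqrt(self[i] * self[j]), 1), 1e-6)
      out <- data.frame(gene_a = ids[i], gene_b = ids[j],
                        species_a = species[i], species_b = species[j],
                        score = sc[ok2], identity = identity[ok2],
                        coverage = coverage[ok2], weight = unname(w),
                        stringsAsFactors = FALSE)
    }
  }
  if (is.null(out)) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      species_a = character(0), species_b = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage = numeric(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Markov clustering of a similarity graph
#'
#' Classical MCL on the weighted undirected graph: self-loops added, the
#' column-stochastic matrix alternately squared (expansion) and raised
#' elementwise to the inflation power with renormalisation (inflation)
#' until the matrix change falls below \code{1e-6} or 100 iterations.
#' Clusters are the connected components of the converged flow matrix;
#' singleton clusters are dropped.
#'
#' @param edges data.frame with \code{gene_a}, \code{gene_b},
#'   \code{weight} (and optionally species columns carried through).
#' @param inflation Inflation parameter, > 1 (default 1.5).
#' @param species Optional named vector gene id -> species label used to
#'   annotate members; defaults to species columns in \code{edges}.
#' @return List of orthogroups, each a data.frame (species, gene_id);
#'   groups ordered by size descending then lexicographic first member.
#' @export
mcl_cluster <- function(edges, inflation = 1.5, species = NULL) {
  if (inflation <= 1) stop("inflation must be > 1", call. = FALSE)
  if (nrow(edges) == 0) return(list())
  ids <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  ia <- match(edges$gene_a, ids)
  ib <- match(edges$gene_b, ids)
  w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
  M[cbind(ia, ib)] <- w
  M[cbind(ib, ia)] <- w
  diag(M) <- pmax(apply(M, 2, max), 1e-6)  # self-loops
  M <- sweep(M, 2, colSums(M), "/")
  for (iter in seq_len(100)) {
    M2 <- M %*% M
    M2 <- M2 ^ inflation
    M2[M2 < 1e-12] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-6) break
  }
  g <- igraph::graph_from_adjacency_matrix(M > 1e-6 | t(M) > 1e-6,
                                           mode = "undirected")
  comp <- igraph::components(g)$membership
  sp_of <- .species_lookup(edges, species)
  groups <- split(ids, comp)
  groups <- Filter(function(g) length(g) >= 2, groups)
  groups <- lapply(groups, function(g) {
    g <- sort(g)
    data.frame(species = unname(sp_of[g]), gene_id = g,
               stringsAsFactors = FALSE)
  })
  ord <- order(-vapply(groups, nrow, integer(1)),
               vapply(groups, function(g) g$gene_id[1], character(1)))
  groups <- groups[ord]
  names(groups) <- sprintf("OG%04d", seq_along(groups))
  groups
}

.species_lookup <- function(edges, species) {
  if (!is.null(species)) return(species)
  if (all(c("species_a", "species_b") %in% names(edges))) {
    sp <- c(stats::setNames(edges$species_a, edges$gene_a),
            stats::setNames(edges$species_b, edges$gene_b))
    return(sp[!duplicated(names(sp))])
  }
  ids <- unique(c(edges$gene_a, edges$gene_b))
  stats::setNames(rep(NA_character_, length(ids)), ids)
}

#' Extract one-to-one ortholog pairs from orthogroups
#'
#' For each orthogroup containing exactly one gene from each of the two
#' species (regardless of any other species' contribution), emit that
#' pair.
#'
#' @param orthogroups List of data.frames (species, gene_id) as returned
#'   by \code{\link{mcl_cluster}}.
#' @param species_pair Character vector of two distinct species labels.
#' @return data.frame (gene_a, gene_b, relation, species_a, species_b);
#'   gene_a from the first species of the pair.
#' @export
extract_ortholog_pairs <- function(orthogroups, species_pair) {
  stopifnot(length(species_pair) == 2, species_pair[1] != species_pair[2])
  rows <- lapply(orthogroups, function(g) {
    a <- g$gene_id[g$species == species_pair[1]]
    b <- g$gene_id[g$species == species_pair[2]]
    if (length(a) == 1 && length(b) == 1) {
      data.frame(gene_a = a, gene_b = b, relation = "ortholog",
                 species_a = species_pair[1], species_b = species_pair[2],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) out <- .empty_pairs()
  rownames(out) <- NULL
  out
}

#' Extract within-species paralog pairs from orthogroups
#'
#' For each orthogroup containing exactly two genes of the species
#' (regardless of the other species' contribution), emit that pair.
#'
#' @param orthogroups As in \code{\link{extract_ortholog_pairs}}.
#' @param species One species label.
#' @return data.frame (gene_a, gene_b, relation, species_a, species_b).
#' @export
extract_paralog_pairs <- function(orthogroups, species) {
  rows <- lapply(orthogroups, function(g) {
    a <- sort(g$gene_id[g$species == species])
    if (length(a) == 2) {
      data.frame(gene_a = a[1], gene_b = a[2], relation = "paralog",
                 species_a = species, species_b = species,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) out <- .empty_pairs()
  rownames(out) <- NULL
  out
}

.empty_pairs <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             relation = character(0), species_a = character(0),
             species_b = character(0), stringsAsFactors = FALSE)
}
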