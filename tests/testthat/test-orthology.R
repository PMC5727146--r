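# Protein alignment, similarity graph, Markov clustering, and the pair
# extraction rules.

random_protein <- function(n, seed) {
  set.seed(seed)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

test_that("self-alignment is perfect and scores the diagonal sum", {
  p <- random_protein(60, 41)
  al <- align_proteins_global(p, p)
  expect_equal(al$identity, 100)
  expect_equal(al$coverage, 1)
  chars <- strsplit(p, "")[[1]]
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  expect_equal(al$score, sum(e$BLOSUM62[cbind(chars, chars)]))
})

test_that("alignment score equals the Gotoh DP oracle", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  cases <- list(c("HEAGAWGHEE", "PAWHEAE"),
                c("MKVLA", "MKLA"),
                c(random_protein(25, 42), random_protein(30, 43)))
  for (cs in cases) {
    al <- align_proteins_global(cs[1], cs[2], gap_open = 10,
                                gap_extend = 1)
    oracle <- oracle_gotoh_score(cs[1], cs[2], e$BLOSUM62,
                                 gap_open = 10, gap_extend = 1)
    expect_equal(al$score, oracle, label = paste(cs, collapse = " vs "))
  }
  expect_error(align_proteins_global("MKV", ""), "empty")
})

test_that("similarity graph keeps related pairs and drops unrelated ones", {
  base <- random_protein(120, 44)
  mutate_at <- function(p, k, seed) {
    set.seed(seed)
    chars <- strsplit(p, "")[[1]]
    idx <- sample(length(chars), k)
    chars[idx] <- sample(c("A", "G", "S", "T", "L"), k, replace = TRUE)
    paste(chars, collapse = "")
  }
  prots <- c(x1 = base, x2 = mutate_at(base, 10, 45),
             y1 = random_protein(120, 46))
  edges <- build_similarity_graph(prots, c("sp1", "sp2", "sp1"))
  expect_true(any(edges$gene_a == "x1" & edges$gene_b == "x2"))
  expect_false(any(edges$gene_a == "y1" | edges$gene_b == "y1"))
  expect_true(all(edges$identity >= 50))
  expect_true(all(edges$weight > 0 & edges$weight <= 1))
})

test_that("chained similarity keeps only the adjacent edges", {
  base <- random_protein(120, 47)
  drift <- function(p, from, to) {
    chars <- strsplit(p, "")[[1]]
    chars[from:to] <- "A"
    paste(chars, collapse = "")
  }
  # A and C each share ~half their residues with B but differ from each
  # other over the whole length
  b <- base
  a <- drift(b, 1, 55)
  c_ <- drift(b, 60, 115)
  prots <- c(A = a, B = b, C = c_)
  edges <- build_similarity_graph(prots, rep("sp", 3), min_identity = 50)
  key <- paste(edges$gene_a, edges$gene_b)
  expect_true(all(c("A B", "B C") %in% key))
  expect_false("A C" %in% key)
})

test_that("MCL separates disconnected and weakly joined modules", {
  tri <- function(p) data.frame(gene_a = p[c(1, 1, 2)],
                                gene_b = p[c(2, 3, 3)], weight = 1,
                                stringsAsFactors = FALSE)
  sp <- stats::setNames(rep("s", 6), c("a1", "a2", "a3", "b1", "b2", "b3"))
  g <- mcl_cluster(rbind(tri(c("a1", "a2", "a3")),
                         tri(c("b1", "b2", "b3"))), 1.5, species = sp)
  expect_equal(length(g), 2)
  expect_equal(unname(sort(vapply(g, nrow, integer(1)))), c(3L, 3L))

  k <- t(utils::combn(paste0("x", 1:5), 2))
  e5 <- data.frame(gene_a = k[, 1], gene_b = k[, 2], weight = 1,
                   stringsAsFactors = FALSE)
  g5 <- mcl_cluster(e5, 1.5,
                    species = stats::setNames(rep("s", 5), paste0("x", 1:5)))
  expect_equal(length(g5), 1)
  expect_equal(nrow(g5[[1]]), 5)

  k4 <- function(p) {
    m <- t(utils::combn(p, 2))
    data.frame(gene_a = m[, 1], gene_b = m[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }
  e44 <- rbind(k4(paste0("a", 1:4)), k4(paste0("b", 1:4)),
               data.frame(gene_a = "a1", gene_b = "b1", weight = 0.1,
                          stringsAsFactors = FALSE))
  g44 <- mcl_cluster(e44, 1.5,
                     species = stats::setNames(rep("s", 8),
                                               c(paste0("a", 1:4),
                                                 paste0("b", 1:4))))
  expect_equal(length(g44), 2)
  expect_equal(unname(sort(vapply(g44, nrow, integer(1)))), c(4L, 4L))
  expect_error(mcl_cluster(e44, 1), "inflation")
})

test_that("clustering is invariant to input edge order", {
  set.seed(48)
  k4 <- t(utils::combn(paste0("g", 1:4), 2))
  e <- data.frame(gene_a = k4[, 1], gene_b = k4[, 2],
                  weight = runif(6, 0.5, 1), stringsAsFactors = FALSE)
  sp <- stats::setNames(rep("s", 4), paste0("g", 1:4))
  g1 <- mcl_cluster(e, 1.5, species = sp)
  g2 <- mcl_cluster(e[sample(nrow(e)), ], 1.5, species = sp)
  expect_identical(g1, g2)
})

test_that("ortholog extraction follows the one-gene-per-species rule", {
  groups <- list(
    g1 = data.frame(species = c("cb", "cm", "cc"),
                    gene_id = c("b1", "m1", "c1")),
    g2 = data.frame(species = c("cb", "cb", "cm"),
                    gene_id = c("b2", "b3", "m2")),
    g3 = data.frame(species = c("cb", "cm"),
                    gene_id = c("b4", "m4")))
  pairs <- extract_ortholog_pairs(groups, c("cb", "cm"))
  expect_equal(pairs$gene_a, c("b1", "b4"))
  expect_equal(pairs$gene_b, c("m1", "m4"))
  expect_true(all(pairs$relation == "ortholog"))
  expect_true(all(pairs$species_a != pairs$species_b))
})

test_that("paralog extraction follows the two-genes-per-species rule", {
  groups <- list(
    g1 = data.frame(species = c("cb", "cb", "cm"),
                    gene_id = c("b1", "b2", "m1")),
    g2 = data.frame(species = c("cb", "cb", "cb"),
                    gene_id = c("b3", "b4", "b5")),
    g3 = data.frame(species = c("cb", "cm"),
                    gene_id = c("b6", "m2")))
  pairs <- extract_paralog_pairs(groups, "cb")
  expect_equal(nrow(pairs), 1)
  expect_equal(c(pairs$gene_a, pairs$gene_b), c("b1", "b2"))
  expect_true(all(pairs$species_a == pairs$species_b))
})

test_that("planted paralog pairs are recovered through the full graph path", {
  sc <- two_species_scenario(ks = 0.05, n_families = 15, wgd_ks = 0.1,
                             retention_prob = 1, codon_length = 120,
                             seed = 51)
  sim <- simulate_scenario(sc)
  genes <- sim$genes
  prots <- vapply(stats::setNames(genes$cds, genes$gene_id),
                  translate_cds, character(1), n_tolerant = TRUE)
  edges <- build_similarity_graph(prots, genes$species)
  groups <- mcl_cluster(edges, 1.5)
  found <- rbind(extract_paralog_pairs(groups, "s1"),
                 extract_paralog_pairs(groups, "s2"))
  truth <- sim$truth[sim$truth$relation == "paralog", ]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  recall <- mean(key(truth$gene_a, truth$gene_b) %in%
                   key(found$gene_a, found$gene_b))
  expect_gte(recall, 0.9)
})
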