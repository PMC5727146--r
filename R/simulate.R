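# Codon-level simulator: synthetic multi-species transcriptomes with
# planted speciation and whole-genome duplication/triplication events and
# a ground-truth table of homolog pairs.
#
# The substitution process is deliberately matched to the counting
# estimator's assumptions: synonymous and nonsynonymous single-base
# changes are placed uniformly over the currently eligible changes, with
# expected totals target_ks * S and omega * target_ks * N respectively,
# and changes that would create a stop codon are never eligible.

#' Generate random ancestral coding sequences
#'
#' Each sequence is ATG, then uniformly drawn sense codons, then a stop
#' codon, for a total of \code{codon_length} codons.
#'
#' @param n_genes Number of sequences.
#' @param codon_length Codons per sequence (including start and stop);
#'   at least 50 so that downstream ORF filters pass.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Character vector of CDS strings, named \code{fam0001} ...
#' @export
generate_ancestral_cds <- function(n_genes, codon_length, seed = 1L) {
  if (n_genes < 1 || codon_length < 3) {
    stop("n_genes must be >= 1 and codon_length >= 3", call. = FALSE)
  }
  gc <- genetic_code()
  body <- setdiff(sense_codons(), character(0))
  stops <- names(gc)[gc == "*"]
  rng <- .local_rng(seed)
  seqs <- vapply(seq_len(n_genes), function(i) {
    mid <- sample(body, codon_length - 2L, replace = TRUE)
    stop_codon <- sample(stops, 1L)
    paste(c("ATG", mid, stop_codon), collapse = "")
  }, character(1))
  rng$restore()
  names(seqs) <- sprintf("fam%04d", seq_len(n_genes))
  seqs
}

# Seed-scoped RNG: set the seed, and restore the caller's RNG state on
# $restore() so library code does not clobber the session stream.
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

# Per-codon neighbour classification, cached: for each sense codon the
# synonymous and the (non-stop) nonsynonymous single-base neighbours.
.neighbour_tables <- function() {
  if (!is.null(.ksage$nbrs)) return(.ksage$nbrs)
  gc <- genetic_code()
  codons <- sense_codons()
  syn <- list(); non <- list()
  for (codon in codons) {
    nbs <- codon_neighbours(codon)
    aas <- unname(gc[nbs])
    syn[[codon]] <- nbs[aas == gc[[codon]]]
    non[[codon]] <- nbs[aas != "*" & aas != gc[[codon]]]
  }
  .ksage$nbrs <- list(syn = syn, non = non,
                      n_syn = lengths(syn), n_non = lengths(non))
  .ksage$nbrs
}

# Apply n_events substitutions of one class to a codon vector, each drawn
# uniformly over the currently eligible (non-stop-creating) changes.
.mutate <- function(codons, n_events, synonymous) {
  nb <- .neighbour_tables()
  opts <- if (synonymous) nb$syn else nb$non
  counts <- if (synonymous) nb$n_syn else nb$n_non
  w <- counts[codons]
  w[is.na(w)] <- 0  # stop/ambiguous codons are never touched
  for (k in seq_len(n_events)) {
    tot <- sum(w)
    if (tot == 0) break
    i <- sample.int(length(codons), 1L, prob = w)
    cands <- opts[[codons[i]]]
    codons[i] <- cands[sample.int(length(cands), 1L)]
    w[i] <- counts[codons[i]]
    if (is.na(w[i])) w[i] <- 0
  }
  codons
}

# Total synonymous/nonsynonymous sites of one sequence (stop codons and
# ambiguous codons skipped).
.seq_sites <- function(codons) {
  sites <- ng_site_table()
  ok <- codons %in% rownames(sites)
  c(S = sum(sites[codons[ok], "s"]), N = sum(sites[codons[ok], "n"]))
}

# Evolve a CDS along one branch of expected Ks length branch_ks.
.evolve_branch <- function(cds, branch_ks, omega) {
  if (branch_ks == 0) return(cds)
  codons <- split_codons(cds)
  sn <- .seq_sites(codons)
  n_syn <- stats::rpois(1L, branch_ks * sn[["S"]])
  n_non <- stats::rpois(1L, omega * branch_ks * sn[["N"]])
  codons <- .mutate(codons, n_syn, synonymous = TRUE)
  codons <- .mutate(codons, n_non, synonymous = FALSE)
  paste(codons, collapse = "")
}

#' Evolve one ancestral CDS into a diverged pair
#'
#' The target Ks is split equally between the two descendant branches
#' (only the pairwise sum is identifiable to a pairwise estimator).
#' Synonymous substitutions are drawn Poisson with expectation
#' \code{target_ks * S(cds)} and nonsynonymous with expectation
#' \code{omega * target_ks * N(cds)}, placed uniformly over eligible
#' single-base changes; changes creating stop codons are never made.
#'
#' @param cds Ancestral CDS (valid per \code{\link{generate_ancestral_cds}}).
#' @param target_ks Expected synonymous substitutions per synonymous site
#'   separating the pair (>= 0).
#' @param omega Target Ka/Ks (> 0).
#' @param seed Optional integer seed; when NULL the current RNG stream is
#'   used (so callers can manage reproducibility at a higher level).
#' @return Named list \code{list(cds_a, cds_b)}.
#' @export
evolve_pair <- function(cds, target_ks, omega, seed = NULL) {
  if (target_ks < 0) stop("target_ks must be >= 0", call. = FALSE)
  if (omega <= 0) stop("omega must be > 0", call. = FALSE)
  if (!is.null(seed)) {
    rng <- .local_rng(seed)
    on.exit(rng$restore())
  }
  list(cds_a = .evolve_branch(cds, target_ks / 2, omega),
       cds_b = .evolve_branch(cds, target_ks / 2, omega))
}

#' Define an evolutionary scenario
#'
#' Events are ordered oldest first; ages are expected Ks values (twice the
#' per-branch expectation, i.e. the Ks a pairwise estimator should recover
#' for pairs split at that event).  A speciation event forks a lineage
#' into two named child lineages; a \code{wgd} (\code{wgt}) event copies
#' every gene on the lineage into 2 (3) copies, each extra copy retained
#' independently with probability \code{retention_prob}.
#'
#' @param species Character vector of 2-3 terminal species labels.
#' @param events List of events, each
#'   \code{list(kind = "speciation", lineage, into = c(a, b), ks = ...)} or
#'   \code{list(kind = "wgd"|"wgt", lineage, ks = ...)}.
#' @param n_families Number of independent gene families.
#' @param codon_length Codons per ancestral gene.
#' @param omega Either a single Ka/Ks value applied to every family or a
#'   function \code{function(n)} returning \code{n} per-family values.
#' @param retention_prob Probability an extra post-duplication copy is
#'   retained, in [0, 1].
#' @param seed Integer seed.
#' @return Object of class \code{"evol_scenario"}.
#' @export
evol_scenario <- function(species, events, n_families = 200,
                          codon_length = 300, omega = 0.3,
                          retention_prob = 0.25, seed = 1L) {
  if (length(species) < 2 || length(species) > 3) {
    stop("2 or 3 species labels required", call. = FALSE)
  }
  if (n_families < 1) stop("n_families must be >= 1", call. = FALSE)
  if (retention_prob < 0 || retention_prob > 1) {
    stop("retention_prob must be in [0, 1]", call. = FALSE)
  }
  ks <- vapply(events, function(e) e$ks, numeric(1))
  if (any(ks <= 0)) stop("event ks values must be positive", call. = FALSE)
  # check lineage bookkeeping: start from "root", speciations rename
  live <- "root"
  for (e in events) {
    if (!e$lineage %in% live) {
      stop("event references unknown lineage '", e$lineage, "'",
           call. = FALSE)
    }
    if (e$kind == "speciation") {
      live <- c(setdiff(live, e$lineage), e$into)
    } else if (!e$kind %in% c("wgd", "wgt")) {
      stop("unknown event kind '", e$kind, "'", call. = FALSE)
    }
  }
  if (!setequal(live, species)) {
    stop("terminal lineages (", paste(sort(live), collapse = ", "),
         ") do not match species labels", call. = FALSE)
  }
  structure(list(species = species, events = events,
                 n_families = n_families, codon_length = codon_length,
                 omega = omega, retention_prob = retention_prob,
                 seed = as.integer(seed)),
            class = "evol_scenario")
}

#' The default two-congeners-plus-outgroup scenario
#'
#' Two recently diverged congeners (\code{cb}, \code{cm}) plus an outgroup
#' (\code{cc}): an ancient shared WGD at Ks 0.75, the genus/outgroup split
#' at Ks 0.5, a recent shared WGD at Ks 0.1, and the species split at
#' Ks 0.05.
#'
#' @param n_families,retention_prob,omega,codon_length,seed Overrides
#'   passed to \code{\link{evol_scenario}}.
#' @return An \code{evol_scenario}.
#' @export
default_scenario <- function(n_families = 200, retention_prob = 0.25,
                             omega = 0.3, codon_length = 300, seed = 1L) {
  evol_scenario(
    species = c("cb", "cm", "cc"),
    events = list(
      list(kind = "wgd", lineage = "root", ks = 0.75),
      list(kind = "speciation", lineage = "root", into = c("chrys", "cc"),
           ks = 0.5),
      list(kind = "wgd", lineage = "chrys", ks = 0.1),
      list(kind = "speciation", lineage = "chrys", into = c("cb", "cm"),
           ks = 0.05)
    ),
    n_families = n_families, codon_length = codon_length, omega = omega,
    retention_prob = retention_prob, seed = seed)
}

#' Simulate a scenario into per-species gene sets and a truth table
#'
#' Gene families are propagated through the ordered event list.  Between
#' events each surviving copy accumulates substitutions over the elapsed
#' Ks interval (half per branch); at a speciation the copy is inherited by
#' both child lineages; at a wgd/wgt it is duplicated with independent
#' loss of extra copies.  Terminal sequences are collected per species and
#' every pair of genes descending from a common ancestor is recorded with
#' its planted Ks (the age of their split) and the family's planted omega.
#'
#' @param scenario An \code{\link{evol_scenario}}.
#' @return List with \code{genes}: data.frame (species, gene_id, family,
#'   cds); \code{truth}: data.frame (gene_a, gene_b, relation, planted_ks,
#'   planted_omega); \code{scenario}.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "evol_scenario"))
  rng <- .local_rng(scenario$seed)
  on.exit(rng$restore())
  n <- scenario$n_families
  anc <- generate_ancestral_cds(n, scenario$codon_length,
                                seed = scenario$seed + 1L)
  omegas <- if (is.function(scenario$omega)) scenario$omega(n) else
    rep_len(scenario$omega, n)
  genes <- list()
  truth <- list()
  for (f in seq_len(n)) {
    fam <- .simulate_family(anc[[f]], names(anc)[f], scenario, omegas[f])
    genes[[f]] <- fam$tips
    truth[[f]] <- fam$pairs
  }
  genes <- do.call(rbind, genes)
  truth <- do.call(rbind, Filter(Negate(is.null), truth))
  if (is.null(truth)) {
    truth <- data.frame(gene_a = character(0), gene_b = character(0),
                        relation = character(0), planted_ks = numeric(0),
                        planted_omega = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(genes) <- rownames(truth) <- NULL
  list(genes = genes, truth = truth, scenario = scenario)
}

# Recursive propagation of one family. Returns tips (species, gene_id,
# family, cds) and truth pairs.
.simulate_family <- function(cds, family, scenario, omega) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  root_age <- max(vapply(scenario$events, function(e) e$ks, numeric(1)))
  res <- .descend(cds, "root", root_age, scenario$events, scenario, omega,
                  family, counter)
  tips <- res$tips
  pairs <- res$pairs
  if (!is.null(pairs) && nrow(pairs) > 0) {
    species_of <- stats::setNames(tips$species, tips$gene_id)
    pairs$relation <- ifelse(species_of[pairs$gene_a] ==
                               species_of[pairs$gene_b],
                             "paralog", "ortholog")
    pairs$planted_omega <- omega
  }
  list(tips = tips, pairs = pairs)
}

.descend <- function(cds, lineage, age, events, scenario, omega, family,
                     counter) {
  # next event affecting this lineage
  ev_i <- 0L
  for (i in seq_along(events)) {
    if (events[[i]]$lineage == lineage) { ev_i <- i; break }
  }
  if (ev_i == 0L) {
    # terminal branch: evolve down to the present
    cds <- .evolve_branch(cds, age / 2, omega)
    counter$n <- counter$n + 1L
    gene_id <- sprintf("%s_%s_c%02d", lineage, family, counter$n)
    return(list(
      tips = data.frame(species = lineage, gene_id = gene_id,
                        family = family, cds = cds,
                        stringsAsFactors = FALSE),
      pairs = NULL))
  }
  ev <- events[[ev_i]]
  rest <- events[-seq_len(ev_i)]
  cds <- .evolve_branch(cds, (age - ev$ks) / 2, omega)
  branches <- list()
  if (ev$kind == "speciation") {
    for (child in ev$into) {
      branches[[length(branches) + 1L]] <-
        .descend(cds, child, ev$ks, rest, scenario, omega, family, counter)
    }
  } else {
    n_copies <- if (ev$kind == "wgt") 3L else 2L
    keep <- c(TRUE, stats::runif(n_copies - 1L) < scenario$retention_prob)
    for (k in seq_len(n_copies)) {
      if (!keep[k]) next
      branches[[length(branches) + 1L]] <-
        .descend(cds, lineage, ev$ks, rest, scenario, omega, family, counter)
    }
  }
  tips <- do.call(rbind, lapply(branches, `[[`, "tips"))
  pairs <- do.call(rbind, Filter(Negate(is.null),
                                 lapply(branches, `[[`, "pairs")))
  # cross pairs between distinct branches split at this event
  if (length(branches) > 1L) {
    for (i in seq_len(length(branches) - 1L)) {
      for (j in seq(i + 1L, length(branches))) {
        a <- branches[[i]]$tips$gene_id
        b <- branches[[j]]$tips$gene_id
        cross <- expand.grid(gene_a = a, gene_b = b,
                             stringsAsFactors = FALSE)
        cross$relation <- NA_character_
        cross$planted_ks <- ev$ks
        cross$planted_omega <- NA_real_
        pairs <- rbind(pairs, cross)
      }
    }
  }
  list(tips = tips, pairs = pairs)
}
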