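# End-to-end orchestration: batch Ka/Ks over homolog pairs, file I/O for
# the standard formats, the full transcripts -> orthology -> rates ->
# Ks-model run, and the simulate-then-validate harness.

#' Estimate Ka/Ks for a batch of homolog pairs
#'
#' For every pair, aligns the two proteins globally, back-translates the
#' protein alignment to a codon alignment guided by the coding sequences,
#' and runs the Nei-Gojobori estimator.
#'
#' @param pairs data.frame with columns \code{gene_a}, \code{gene_b} (and
#'   optionally \code{relation}, carried through).
#' @param cds Named character vector gene id -> CDS.
#' @param proteins Optional named vector gene id -> protein; computed by
#'   translation when missing.
#' @param ... Passed to \code{\link{align_proteins_global}}.
#' @return data.frame: pair columns plus \code{n_codons}, \code{S},
#'   \code{N}, \code{Sd}, \code{Nd}, \code{Ka}, \code{Ks}, \code{omega},
#'   \code{p_value}, \code{flag}.
#' @export
pair_rates <- function(pairs, cds, proteins = NULL, ...) {
  if (is.null(proteins)) {
    used <- unique(c(pairs$gene_a, pairs$gene_b))
    proteins <- vapply(cds[used], translate_cds, character(1),
                       n_tolerant = TRUE)
  }
  est <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    for (id in c(a, b)) {
      if (is.na(cds[id]) || is.null(cds[[id]])) {
        stop("no CDS for gene ", id, call. = FALSE)
      }
    }
    pa <- proteins[[a]]; pb <- proteins[[b]]
    if (pa == pb) {
      ca <- .ungapped_codons(cds[[a]])
      cb <- .ungapped_codons(cds[[b]])
      r <- ng_rates(ca, cb)
    } else {
      al <- align_proteins_global(pa, pb, ...)
      ca <- backtranslate_alignment(al$aligned_a, al$aligned_b,
                                    cds[[a]], cds[[b]])
      r <- ng_rates(ca)
    }
    data.frame(n_codons = r$n_codons, S = r$S, N = r$N, Sd = r$Sd,
               Nd = r$Nd, Ka = r$Ka, Ks = r$Ks, omega = r$omega,
               p_value = r$p_value, flag = r$flag,
               stringsAsFactors = FALSE)
  })
  cbind(pairs, do.call(rbind, est))
}

.ungapped_codons <- function(cds) {
  codons <- split_codons(cds)
  gc <- genetic_code()
  if (length(codons) > 0 && !is.na(gc[codons[length(codons)]]) &&
      gc[[codons[length(codons)]]] == "*") {
    codons <- codons[-length(codons)]
  }
  codons
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60) {
  set <- Biostrings::BStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector (uppercase).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write simulation output to a directory
#'
#' One CDS FASTA per species (\code{<label>.cds.fasta}), the truth table
#' as TSV, and the scenario as a key-value config file.
#'
#' @param sim Result of \code{\link{simulate_scenario}}.
#' @param dir Output directory (created).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in unique(sim$genes$species)) {
    rows <- sim$genes[sim$genes$species == sp, ]
    seqs <- stats::setNames(rows$cds, rows$gene_id)
    write_fasta(seqs, file.path(dir, paste0(sp, ".cds.fasta")))
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sc <- sim$scenario
  ev <- vapply(sc$events, function(e) {
    paste(c(e$kind, e$lineage, if (!is.null(e$into)) paste(e$into,
        collapse = ","), e$ks), collapse = ":")
  }, character(1))
  writeLines(c(
    paste0("species=", paste(sc$species, collapse = ",")),
    paste0("events=", paste(ev, collapse = ";")),
    paste0("n_families=", sc$n_families),
    paste0("codon_length=", sc$codon_length),
    paste0("retention_prob=", sc$retention_prob),
    paste0("seed=", sc$seed)
  ), file.path(dir, "scenario.cfg"))
  invisible(dir)
}

#' Run the full comparative pipeline
#'
#' Transcript representatives per species, all-vs-all similarity, Markov
#' clustering, ortholog/paralog pair extraction, batch Ka/Ks, the
#' exclusion ledger, mixture fits and dated peaks per Ks curve, and the
#' selection screen on the within-genus ortholog curve.
#'
#' @param fastas Named list/vector of per-species CDS or transcript FASTA
#'   paths (names are species labels), or a data.frame of genes as
#'   produced by \code{\link{simulate_scenario}} (\code{species},
#'   \code{gene_id}, \code{cds}).
#' @param outgroup Optional label of the outgroup species.
#' @param out_dir Optional directory for TSV outputs.
#' @param min_orf_nt,min_aa ORF thresholds.
#' @param min_identity,min_coverage,min_score Similarity-edge thresholds.
#' @param mcl_inflation MCL inflation.
#' @param ks_cutoff Ks cutoff for the selection screen.
#' @param clock_rate Substitutions per synonymous site per year.
#' @param k_candidates,fit_range Mixture-fit settings.
#' @param min_fit_points Minimum Ks values for a curve to be fitted.
#' @param seed Integer seed recorded in the manifest.
#' @return List with \code{representatives}, \code{edges},
#'   \code{orthogroups}, \code{pairs}, \code{rates}, \code{curves} (per
#'   curve: rates, ledger, fit, peaks, dated events), \code{selection},
#'   and \code{manifest}.
#' @export
run_pipeline <- function(fastas, outgroup = NULL, out_dir = NULL,
                         min_orf_nt = 300, min_aa = 50, min_identity = 50,
                         min_coverage = 0.5, min_score = 50,
                         mcl_inflation = 1.5, ks_cutoff = 0.1,
                         clock_rate = 1.5e-8, k_candidates = 1:3,
                         fit_range = c(0.005, 2), min_fit_points = 20,
                         seed = 1L) {
  genes <- .load_genes(fastas, min_orf_nt, min_aa)
  species <- sort(unique(genes$species))
  if (length(species) < 2) stop("need at least 2 species", call. = FALSE)
  cds <- stats::setNames(genes$cds, genes$gene_id)
  proteins <- stats::setNames(genes$protein, genes$gene_id)
  edges <- build_similarity_graph(proteins,
                                  stats::setNames(genes$species,
                                                  genes$gene_id)[
                                    names(proteins)],
                                  min_identity = min_identity,
                                  min_coverage = min_coverage,
                                  min_score = min_score)
  groups <- mcl_cluster(edges, inflation = mcl_inflation)
  pairs <- .all_pairs(groups, species)
  rates <- if (nrow(pairs) > 0) {
    pair_rates(pairs, cds, proteins)
  } else cbind(pairs, .empty_rates())
  curves <- .fit_curves(rates, species, ks_cutoff, clock_rate,
                        k_candidates, fit_range, min_fit_points)
  ingroup <- setdiff(species, outgroup)
  sel_curve <- paste(sort(ingroup[1:min(2, length(ingroup))]),
                     collapse = "-")
  selection <- NULL
  if (!is.null(curves[[sel_curve]]) &&
      nrow(curves[[sel_curve]]$retained) > 0) {
    selection <- classify_selection(curves[[sel_curve]]$retained)
  }
  manifest <- list(
    species = species, outgroup = outgroup, seed = seed,
    n_genes_in = length(unique(genes$gene_id)),
    n_with_orf = nrow(genes), n_edges = nrow(edges),
    n_orthogroups = length(groups),
    n_pairs = stats::setNames(as.integer(table(pairs$curve)),
                              names(table(pairs$curve))),
    thresholds = list(min_orf_nt = min_orf_nt, min_aa = min_aa,
                      min_identity = min_identity,
                      min_coverage = min_coverage, min_score = min_score,
                      mcl_inflation = mcl_inflation,
                      ks_cutoff = ks_cutoff, clock_rate = clock_rate))
  res <- list(representatives = genes, edges = edges, orthogroups = groups,
              pairs = pairs, rates = rates, curves = curves,
              selection = selection, manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.empty_rates <- function() {
  data.frame(n_codons = integer(0), S = numeric(0), N = numeric(0),
             Sd = numeric(0), Nd = numeric(0), Ka = numeric(0),
             Ks = numeric(0), omega = numeric(0), p_value = numeric(0),
             flag = character(0), stringsAsFactors = FALSE)
}

.load_genes <- function(fastas, min_orf_nt, min_aa) {
  if (is.data.frame(fastas)) {
    genes <- fastas
  } else {
    rows <- lapply(names(fastas), function(sp) {
      seqs <- read_fasta(fastas[[sp]])
      data.frame(species = sp, gene_id = names(seqs), cds = unname(seqs),
                 stringsAsFactors = FALSE)
    })
    genes <- do.call(rbind, rows)
  }
  # treat each input sequence as a single-transcript gene and apply the
  # representative-selection rules (ORF thresholds included)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    tx <- data.frame(id = genes$gene_id[i], gene_id = genes$gene_id[i],
                     sequence = genes$cds[i], stringsAsFactors = FALSE)
    rep <- select_representative(genes$gene_id[i], tx,
                                 min_nt = min_orf_nt, min_aa = min_aa)
    if (is.null(rep)) return(NULL)
    data.frame(species = genes$species[i], gene_id = genes$gene_id[i],
               transcript_id = rep$transcript_id, cds = rep$cds,
               protein = rep$protein, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out) || nrow(out) == 0) {
    stop("no gene passed the ORF thresholds", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

.all_pairs <- function(groups, species) {
  pairs <- list()
  combs <- utils::combn(species, 2, simplify = FALSE)
  for (sp in combs) {
    p <- extract_ortholog_pairs(groups, sp)
    if (nrow(p) > 0) p$curve <- paste(sort(sp), collapse = "-")
    pairs[[length(pairs) + 1L]] <- p
  }
  for (sp in species) {
    p <- extract_paralog_pairs(groups, sp)
    if (nrow(p) > 0) p$curve <- paste(sp, sp, sep = "-")
    pairs[[length(pairs) + 1L]] <- p
  }
  pairs <- Filter(function(p) nrow(p) > 0, pairs)
  if (length(pairs) == 0) {
    out <- .empty_pairs(); out$curve <- character(0); return(out)
  }
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

.fit_curves <- function(rates, species, ks_cutoff, clock_rate,
                        k_candidates, fit_range, min_fit_points) {
  curves <- list()
  for (curve in sort(unique(rates$curve))) {
    sub <- rates[rates$curve == curve, , drop = FALSE]
    scr <- apply_exclusion_ledger(sub, ks_cutoff = ks_cutoff)
    ks <- sub$Ks[!is.na(sub$Ks) & sub$Ks > 0]
    fit <- NULL; peaks <- NULL; events <- NULL; note <- NULL
    if (length(ks[ks >= fit_range[1] & ks <= fit_range[2]]) >=
        min_fit_points) {
      fit <- fit_log_gaussian_mixture(ks, k_candidates = k_candidates,
                                      fit_range = fit_range,
                                      min_points = min_fit_points)
      peaks <- find_peaks(fit)
      events <- lapply(seq_len(nrow(peaks)), function(i) {
        date_event(peaks$ks_peak[i], rate = clock_rate,
                   label = sprintf("%s peak %d", curve, i))
      })
    } else {
      note <- "insufficient data"
    }
    curves[[curve]] <- list(curve = curve, rates = sub,
                            retained = scr$retained, ledger = scr$ledger,
                            fit = fit, peaks = peaks, events = events,
                            note = note)
  }
  curves
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$representatives[, c("species", "gene_id", "transcript_id")],
     "representatives.tsv")
  wt(res$edges, "similarity_edges.tsv")
  og <- do.call(rbind, lapply(names(res$orthogroups), function(id) {
    cbind(group_id = id, res$orthogroups[[id]])
  }))
  if (!is.null(og)) wt(og, "orthogroups.tsv")
  num <- vapply(res$rates, is.numeric, logical(1))
  rates <- res$rates
  rates[num] <- lapply(rates[num], function(x) round(x, 5))
  wt(rates, "rates.tsv")
  mix <- list(); evs <- list()
  for (curve in names(res$curves)) {
    cv <- res$curves[[curve]]
    if (!is.null(cv$fit)) {
      mix[[curve]] <- cbind(curve = curve, k = cv$fit$k,
                            component = seq_len(cv$fit$k),
                            round(cv$fit$components, 5),
                            bic = round(cv$fit$bic, 3))
      evs[[curve]] <- data.frame(
        label = vapply(cv$events, `[[`, character(1), "label"),
        ks_peak = round(vapply(cv$events, `[[`, numeric(1), "ks_peak"), 5),
        T_MY = round(vapply(cv$events, `[[`, numeric(1), "T_my"), 1))
    }
  }
  if (length(mix)) wt(do.call(rbind, mix), "mixtures.tsv")
  if (length(evs)) wt(do.call(rbind, evs), "events.tsv")
  if (!is.null(res$selection)) {
    sel <- res$selection$calls
    num <- vapply(sel, is.numeric, logical(1))
    sel[num] <- lapply(sel[num], function(x) round(x, 5))
    wt(sel, "selection.tsv")
  }
  writeLines(.manifest_lines(res$manifest),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

.manifest_lines <- function(m) {
  th <- m$thresholds
  c(paste0("species=", paste(m$species, collapse = ",")),
    paste0("outgroup=", if (is.null(m$outgroup)) "" else m$outgroup),
    paste0("seed=", m$seed),
    paste0("n_genes_in=", m$n_genes_in),
    paste0("n_with_orf=", m$n_with_orf),
    paste0("n_edges=", m$n_edges),
    paste0("n_orthogroups=", m$n_orthogroups),
    paste0("pairs_", names(m$n_pairs), "=", m$n_pairs),
    vapply(names(th), function(k) paste0(k, "=", th[[k]]), character(1)))
}

#' Simulate a scenario, run the pipeline, and score recovery
#'
#' The acceptance harness: generates data with planted structure, runs the
#' full pipeline, and joins the results back against the truth table.
#'
#' @param scenario An \code{\link{evol_scenario}} (default:
#'   \code{\link{default_scenario}()}).
#' @param ... Passed to \code{\link{run_pipeline}}.
#' @return List with \code{sim}, \code{pipeline}, and \code{report}: pair
#'   recall per relation, dominant-peak errors per curve against the
#'   planted event ages, and (when omega varies) a positive-call
#'   confusion table.
#' @export
simulate_and_validate <- function(scenario = default_scenario(), ...) {
  sim <- simulate_scenario(scenario)
  genes <- sim$genes
  genes$protein <- vapply(genes$cds, translate_cds, character(1),
                          n_tolerant = TRUE)
  genes$transcript_id <- genes$gene_id
  res <- run_pipeline(genes[, c("species", "gene_id", "transcript_id",
                                "cds", "protein")],
                      outgroup = setdiff(scenario$species,
                                         .ingroup(scenario))[1], ...)
  truth_key <- .pair_key(sim$truth$gene_a, sim$truth$gene_b)
  found_key <- .pair_key(res$pairs$gene_a, res$pairs$gene_b)
  recall <- vapply(split(truth_key, sim$truth$relation),
                   function(k) mean(k %in% found_key), numeric(1))
  peak_err <- list()
  for (curve in names(res$curves)) {
    cv <- res$curves[[curve]]
    if (is.null(cv$peaks) || nrow(cv$peaks) == 0) next
    dom <- cv$peaks$ks_peak[cv$peaks$dominant]
    planted <- .planted_age(sim$truth, res$pairs, curve)
    if (!is.na(planted)) {
      peak_err[[curve]] <- c(planted = planted, recovered = dom,
                             rel_error = abs(dom - planted) / planted)
    }
  }
  list(sim = sim, pipeline = res,
       report = list(pair_recall = recall, peak_errors = peak_err))
}

.ingroup <- function(scenario) {
  # species produced by the most recent speciation event
  spec <- Filter(function(e) e$kind == "speciation", scenario$events)
  if (length(spec) == 0) return(scenario$species)
  last <- spec[[length(spec)]]
  intersect(last$into, scenario$species)
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# modal planted ks among truth pairs matching the emitted pairs of a curve
.planted_age <- function(truth, pairs, curve) {
  sub <- pairs[pairs$curve == curve, , drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  key <- .pair_key(sub$gene_a, sub$gene_b)
  tk <- .pair_key(truth$gene_a, truth$gene_b)
  hit <- truth$planted_ks[match(key, tk)]
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) return(NA_real_)
  as.numeric(names(sort(table(hit), decreasing = TRUE))[1])
}
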