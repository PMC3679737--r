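#' @include synthio.R identify.R genemodels.R phylo.R locimap.R compare.R
#' @include conversion.R famstats.R
NULL

#' Build a pipeline configuration
#'
#' One flat list of every stage threshold, with the field's standard
#' values as defaults: clustering joins R-genes separated by at most 8
#' non-R genes; orthologs need an HSP > 500 bp at > 80% identity; synteny
#' needs 14 of 20 flank hits in a 20-gene window; subfamilies are cut at
#' 70% nucleotide identity; amplified fragments are deduplicated at 99.5%;
#' clades need bootstrap support > 80 (of B = 100 replicates) and within-
#' clade distance <= 0.3; conversion events are reported at experiment-wise
#' alpha = 0.05.
#'
#' @param simulation a [SimulationConfig-class], or `NULL` when reading
#'   genomes from `input_dirs`.
#' @param input_dirs character vector of genome bundle directories
#'   (see [writeGenome()]); ignored when `simulation` is given.
#' @param stages stages to run, a subset of the default vector.
#' @param max_intervening,min_hsp,min_identity,window_per_side,min_window_hits,subfamily_threshold,dedup_threshold,min_support,distance_cutoff,alpha,bootstrap_B,n_perm stage thresholds.
#' @param seed RNG seed for bootstrap and permutation stages.
#' @param out_dir report directory, or `NULL` for no file output.
#' @return a named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(simulation = NULL, input_dirs = NULL,
                           stages = c("identify", "models", "phylo",
                                      "loci", "compare", "conversion",
                                      "stats"),
                           max_intervening = 8L, min_hsp = 500,
                           min_identity = 80, window_per_side = 10L,
                           min_window_hits = 14L,
                           subfamily_threshold = 70,
                           dedup_threshold = 99.5, min_support = 80,
                           distance_cutoff = 0.3, alpha = 0.05,
                           bootstrap_B = 100L, n_perm = 1000L,
                           seed = 1L, out_dir = NULL) {
  if (is.null(simulation) && is.null(input_dirs))
    stop("configuration error: need a simulation config or input dirs")
  cfg <- list(simulation = simulation, input_dirs = input_dirs,
              stages = stages, max_intervening = max_intervening,
              min_hsp = min_hsp, min_identity = min_identity,
              window_per_side = window_per_side,
              min_window_hits = min_window_hits,
              subfamily_threshold = subfamily_threshold,
              dedup_threshold = dedup_threshold,
              min_support = min_support,
              distance_cutoff = distance_cutoff, alpha = alpha,
              bootstrap_B = bootstrap_B, n_perm = n_perm, seed = seed,
              out_dir = out_dir)
  stopifnot(max_intervening >= 0, min_hsp >= 0,
            min_identity >= 0 && min_identity <= 100,
            alpha > 0 && alpha < 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

.logStage <- function(log, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
  invisible(line)
}

#' Run the full comparative R-gene pipeline
#'
#' Executes identification, subfamily assignment, pseudogene calling,
#' phylogeny + clade extraction, locus clustering, cross-genome
#' orthology / synteny / presence-absence calling, conversion detection
#' and family statistics in dependency order. With an `out_dir`, every
#' stage writes its TSV, plus a run manifest (thresholds and seed) and a
#' deterministic `summary.tsv`; re-running an identical configuration
#' reproduces identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly, when `out_dir` is set) a list with every stage
#'   result: `genomes`, `truth` (simulation runs only), `candidates`,
#'   `subfamilies`, `pseudogenes`, `tree`, `clades`, `loci`, `orthologs`,
#'   `pa_calls`, `map`, `conversions`, `stats`, `summary`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  log <- NULL
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(out, "log.txt")
    cat("", file = log)
    .logStage(log, "start", paste0(
      "thresholds: intervening<=", config$max_intervening,
      " hsp>", config$min_hsp, " identity>", config$min_identity,
      " window=", config$min_window_hits, "/", 2 * config$window_per_side,
      " subfamily>=", config$subfamily_threshold,
      " dedup>=", config$dedup_threshold,
      " support>", config$min_support,
      " distance<=", config$distance_cutoff,
      " alpha=", config$alpha, " B=", config$bootstrap_B,
      " seed=", config$seed))
  }
  res <- list()
  stage <- "input"
  tryCatch({
    # ---- input -------------------------------------------------------------
    if (!is.null(config$simulation)) {
      sim <- simulateGenomes(config$simulation)
      res$genomes <- sim$genomes
      res$truth <- sim$truth
    } else {
      res$genomes <- lapply(config$input_dirs, function(d)
        readGenome(file.path(d, "genome.gff3"),
                   file.path(d, "proteins.faa"),
                   file.path(d, "cds.fna")))
      names(res$genomes) <- vapply(res$genomes, species, character(1))
    }
    spNames <- names(res$genomes)
    .logStage(log, "input", paste(length(spNames), "genomes:",
                                  paste(spNames, collapse = ", ")))

    # ---- identify ----------------------------------------------------------
    if ("identify" %in% config$stages) {
      stage <- "identify"
      res$candidates <- lapply(res$genomes, function(g)
        findHomologs(identifyCandidates(g), g))
      for (sp in spNames)
        .logStage(log, stage, sprintf(
          "%s: %d R-genes (%d TIR, %d non-TIR), %d LRR-RLK",
          sp, sum(res$candidates[[sp]]$class %in% c("TIR", "non-TIR")),
          sum(res$candidates[[sp]]$class == "TIR"),
          sum(res$candidates[[sp]]$class == "non-TIR"),
          sum(res$candidates[[sp]]$class == "LRR-RLK")))
    }

    rIds <- lapply(res$candidates, function(cand)
      cand$gene_id[cand$class %in% c("TIR", "non-TIR")])

    # ---- subfamilies + pseudogene models ------------------------------------
    if ("models" %in% config$stages) {
      stage <- "models"
      pooled <- do.call(c, unname(lapply(spNames, function(sp)
        cdsSeqs(res$genomes[[sp]])[rIds[[sp]]])))
      res$subfamilies <- if (length(pooled))
        assignSubfamilies(pooled, threshold = config$subfamily_threshold)
      else data.frame(gene_id = character(), subfamily = character())
      pooledMotif <- unlist(lapply(spNames, function(sp) {
        cand <- res$candidates[[sp]]
        cand$gene_id[cand$class %in% c("TIR", "non-TIR") &
                       cand$evidence == "motif"]
      }), use.names = FALSE)
      res$pseudogenes <- do.call(rbind, lapply(spNames, function(sp) {
        calls <- callPseudogenes(res$genomes[[sp]],
                                 res$candidates[[sp]],
                                 subfamilies = res$subfamilies,
                                 ref_cds = pooled,
                                 ref_motif_ids = pooledMotif)
        if (nrow(calls)) calls$species <- sp
        calls
      }))
      .logStage(log, stage, sprintf("%d subfamilies, %d pseudogenes",
        length(unique(res$subfamilies$subfamily)),
        sum(res$pseudogenes$verdict == "pseudogene")))
    }

    # ---- phylogeny + clades --------------------------------------------------
    if ("phylo" %in% config$stages) {
      stage <- "phylo"
      regions <- list()
      for (sp in spNames) {
        cand <- res$candidates[[sp]]
        intact <- cand[cand$class %in% c("TIR", "non-TIR") &
                         cand$evidence == "motif" &
                         !is.na(cand$nbs_start), , drop = FALSE]
        if ("models" %in% config$stages && nrow(res$pseudogenes)) {
          ok <- res$pseudogenes$gene_id[
            res$pseudogenes$verdict == "intact"]
          intact <- intact[intact$gene_id %in% ok, , drop = FALSE]
        }
        prots <- proteinSeqs(res$genomes[[sp]])
        for (r in seq_len(nrow(intact)))
          regions[[intact$gene_id[r]]] <- substr(
            as.character(prots[[intact$gene_id[r]]]),
            intact$nbs_start[r], intact$nbs_end[r])
      }
      lens <- lengths(lapply(regions, function(x) strsplit(x, "")[[1]]))
      if (length(regions) >= 4L && length(unique(lens)) == 1L) {
        aln <- Biostrings::AAStringSet(unlist(regions))
        D <- distanceMatrix(aln, type = "p")
        res$tree <- bootstrapSupport(aln, B = config$bootstrap_B,
                                     type = "p", seed = config$seed)
        res$clades <- extractClades(res$tree, D,
                                    min_support = config$min_support,
                                    distance_cutoff =
                                      config$distance_cutoff)
        .logStage(log, stage, sprintf("%d taxa, %d clades",
          length(regions), length(unique(res$clades$clade))))
      } else {
        res$tree <- NULL; res$clades <- NULL
        .logStage(log, stage,
          "skipped: NBS regions not directly stackable (align externally)")
      }
    }

    # ---- loci ----------------------------------------------------------------
    if ("loci" %in% config$stages) {
      stage <- "loci"
      res$loci <- lapply(spNames, function(sp)
        callClusters(res$genomes[[sp]], rIds[[sp]],
                     max_intervening = config$max_intervening))
      names(res$loci) <- spNames
      .logStage(log, stage, paste(vapply(res$loci, function(l)
        length(unique(l$locus)), integer(1)), collapse = "/"))
    }

    # ---- compare -------------------------------------------------------------
    if ("compare" %in% config$stages && length(spNames) >= 2L) {
      stage <- "compare"
      anchor <- spNames[1]
      hits <- list()
      for (a in spNames) for (b in spNames) if (a != b)
        hits[[paste(a, b, sep = "->")]] <-
          bestHits(res$genomes[[a]], res$genomes[[b]])
      orth <- list()
      for (a in spNames) for (b in spNames) if (a < b) {
        o <- callOrthologs(hits[[paste(a, b, sep = "->")]],
                           hits[[paste(b, a, sep = "->")]],
                           min_hsp = config$min_hsp,
                           min_identity = config$min_identity)
        if (nrow(o)) {
          o$species_a <- a; o$species_b <- b
          orth[[paste(a, b)]] <- o
        }
      }
      res$orthologs <- if (length(orth)) do.call(rbind, unname(orth))
        else data.frame(gene_a = character(), gene_b = character(),
                        hsp_length = numeric(), identity = numeric(),
                        species_a = character(), species_b = character())
      rownames(res$orthologs) <- NULL

      allR <- unlist(rIds, use.names = FALSE)
      pa <- list()
      paFor <- function(qsp, tsp) {
        l <- res$loci[[qsp]]
        ortab <- .orientOrthologs(res$orthologs, qsp, tsp)
        do.call(rbind, lapply(unique(l$locus), function(loc) {
          members <- l$gene_id[l$locus == loc]
          syn <- syntenyWindow(members[1], res$genomes[[qsp]],
                               res$genomes[[tsp]],
                               hits[[paste(qsp, tsp, sep = "->")]],
                               window = config$window_per_side,
                               min_hits = config$min_window_hits,
                               exclude = allR)
          row <- callPaStatus(loc, members, ortab, syn,
                              res$genomes[[tsp]])
          row$species <- qsp
          row
        }))
      }
      for (qsp in spNames) for (tsp in spNames) if (qsp != tsp)
        pa[[paste(qsp, tsp)]] <- paFor(qsp, tsp)
      res$pa_calls <- do.call(rbind, unname(pa))
      rownames(res$pa_calls) <- NULL
      res$map <- buildIntegratedMap(anchor, res$loci, res$orthologs,
                                    res$pa_calls)
      .logStage(log, stage, sprintf("%d ortholog pairs, %d PA calls",
        nrow(res$orthologs), nrow(res$pa_calls)))
    }

    # ---- conversion ------------------------------------------------------------
    if ("conversion" %in% config$stages &&
        "models" %in% config$stages && nrow(res$subfamilies)) {
      stage <- "conversion"
      allCds <- do.call(c, unname(lapply(spNames, function(sp)
        cdsSeqs(res$genomes[[sp]])[rIds[[sp]]])))
      intactIds <- if (!is.null(res$pseudogenes) &&
                       nrow(res$pseudogenes))
        res$pseudogenes$gene_id[res$pseudogenes$verdict == "intact"]
      else names(allCds)
      convRes <- list()
      for (sf in unique(res$subfamilies$subfamily)) {
        ids <- intersect(
          res$subfamilies$gene_id[res$subfamilies$subfamily == sf],
          intactIds)
        if (length(ids) < 3L) next
        seqs <- allCds[ids]
        if (length(unique(Biostrings::width(seqs))) != 1L) next
        det <- detectConversions(seqs, alpha = config$alpha,
                                 n_perm = config$n_perm,
                                 seed = config$seed)
        if (nrow(det$events)) {
          det$events$subfamily <- sf
          convRes[[sf]] <- det$events
        }
      }
      res$conversions <- if (length(convRes))
        do.call(rbind, unname(convRes))
      else data.frame(seq_i = character(), seq_j = character(),
                      first_site = integer(), last_site = integer(),
                      n_sites = integer(), span_bp = integer(),
                      p = numeric(), significant = logical(),
                      subfamily = character())
      rownames(res$conversions) <- NULL
      .logStage(log, stage,
                paste(nrow(res$conversions), "significant fragments"))
    }

    # ---- stats -------------------------------------------------------------
    if ("stats" %in% config$stages) {
      stage <- "stats"
      perSpSub <- lapply(spNames, function(sp)
        res$subfamilies[res$subfamilies$gene_id %in% rIds[[sp]], ,
                        drop = FALSE])
      names(perSpSub) <- spNames
      res$family_summary <- familySummary(res$candidates, perSpSub)
      stats <- list()
      if (length(spNames) >= 3L &&
          stats::sd(res$family_summary$total) > 0 &&
          stats::sd(res$family_summary$rlk) > 0)
        stats$pearson_r <- pearsonR(res$family_summary$total,
                                    res$family_summary$rlk)
      if (!is.null(res$clades)) {
        geneSp <- do.call(rbind, lapply(spNames, function(sp)
          data.frame(gene_id = geneIds(res$genomes[[sp]]), species = sp,
                     stringsAsFactors = FALSE)))
        cf <- data.frame(clade = res$clades$clade,
                         family = geneSp$species[
                           match(res$clades$member, geneSp$gene_id)])
        stats$clade_sharing <- cladeSharingStats(cf)
      }
      res$stats <- stats
      .logStage(log, stage, "done")
    }

    # ---- report ----------------------------------------------------------------
    res$summary <- .pipelineSummary(res, spNames)
    if (!is.null(out)) .writeReport(res, config, out)
    .logStage(log, "end", "ok")
  }, error = function(e) {
    if (!is.null(out))
      writeLines(c(stage, conditionMessage(e)),
                 file.path(out, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(out)) res else invisible(res)
}

# orient the combined ortholog table so gene_a belongs to `qsp`
.orientOrthologs <- function(orthologs, qsp, tsp) {
  if (!nrow(orthologs))
    return(data.frame(gene_a = character(), gene_b = character()))
  fwd <- orthologs[orthologs$species_a == qsp &
                     orthologs$species_b == tsp, , drop = FALSE]
  rev <- orthologs[orthologs$species_a == tsp &
                     orthologs$species_b == qsp, , drop = FALSE]
  data.frame(gene_a = c(fwd$gene_a, rev$gene_b),
             gene_b = c(fwd$gene_b, rev$gene_a),
             stringsAsFactors = FALSE)
}

.pipelineSummary <- function(res, spNames) {
  rows <- lapply(spNames, function(sp) {
    cand <- res$candidates[[sp]]
    data.frame(
      species = sp,
      genes = length(geneIds(res$genomes[[sp]])),
      r_genes = if (!is.null(cand))
        sum(cand$class %in% c("TIR", "non-TIR")) else NA_integer_,
      rlk_genes = if (!is.null(cand))
        sum(cand$class == "LRR-RLK") else NA_integer_,
      pseudogenes = if (!is.null(res$pseudogenes))
        sum(res$pseudogenes$verdict == "pseudogene" &
              res$pseudogenes$species == sp) else NA_integer_,
      loci = if (!is.null(res$loci))
        length(unique(res$loci[[sp]]$locus)) else NA_integer_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.writeReport <- function(res, config, out) {
  writeTable(res$summary, file.path(out, "summary.tsv"))
  for (sp in names(res$candidates))
    writeTable(res$candidates[[sp]],
               file.path(out, paste0("candidates_", sp, ".tsv")))
  if (!is.null(res$subfamilies))
    writeTable(res$subfamilies, file.path(out, "subfamilies.tsv"))
  if (!is.null(res$pseudogenes))
    writeTable(res$pseudogenes, file.path(out, "pseudogenes.tsv"))
  if (!is.null(res$tree))
    writeNewick(res$tree, file.path(out, "tree.nwk"))
  if (!is.null(res$clades))
    writeTable(res$clades, file.path(out, "clades.tsv"))
  if (!is.null(res$loci))
    writeTable(do.call(rbind, unname(res$loci)),
               file.path(out, "loci.tsv"))
  if (!is.null(res$orthologs))
    writeTable(res$orthologs, file.path(out, "orthologs.tsv"))
  if (!is.null(res$pa_calls))
    writeTable(res$pa_calls, file.path(out, "pa_calls.tsv"))
  if (!is.null(res$map))
    writeTable(res$map, file.path(out, "integrated_map.tsv"))
  if (!is.null(res$conversions))
    writeTable(res$conversions, file.path(out, "conversion_events.tsv"))
  if (!is.null(res$family_summary))
    writeTable(res$family_summary, file.path(out, "family_summary.tsv"))
  if (!is.null(res$stats))
    jsonlite::write_json(res$stats, file.path(out, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
  manifest <- c(
    paste0("package=RGeneAtlas ",
           as.character(utils::packageVersion("RGeneAtlas"))),
    paste0("seed=", config$seed),
    paste0("stages=", paste(config$stages, collapse = ",")),
    paste0("thresholds=intervening:", config$max_intervening,
           ";hsp:", config$min_hsp, ";identity:", config$min_identity,
           ";window:", config$min_window_hits, "/",
           2 * config$window_per_side,
           ";subfamily:", config$subfamily_threshold,
           ";dedup:", config$dedup_threshold,
           ";support:", config$min_support,
           ";distance:", config$distance_cutoff,
           ";alpha:", config$alpha, ";B:", config$bootstrap_B,
           ";n_perm:", config$n_perm))
  writeLines(manifest, file.path(out, "manifest.txt"))
  invisible(out)
}
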