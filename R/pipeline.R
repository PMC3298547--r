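#' Run the analysis pipeline
#'
#' Orchestrates the stages end-to-end over a synthetic-input directory:
#' \describe{
#'   \item{`simulate`}{write all generated inputs (reference SIF, pathway
#'     GMT, per-condition tag counts, identifier map, tissue matrix,
#'     reaction table) plus a manifest.}
#'   \item{`build-metabolic`}{enzyme network from the reaction table.}
#'   \item{`filter`}{detection mapping, condition set algebra, strict and
#'     1-extended networks.}
#'   \item{`enrich`}{pathway over-representation in the requested modes with
#'     q-values.}
#'   \item{`keynodes`}{Dis scores of the pruned strict and reference
#'     networks and their Dis-increase.}
#'   \item{`bowtie`}{bow-tie decomposition of the pruned strict network,
#'     per-vertex log fold-changes, and the compartment variance report.}
#'   \item{`all`}{chain of the above.}
#' }
#' Every stage writes TSV outputs into `out_dir/<stage>/` and a
#' `manifest.json` recording inputs, parameters and the seed; a stage whose
#' upstream outputs are missing stops with an error naming the missing
#' stage. Reruns with the same configuration are byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param stage one of `"simulate"`, `"build-metabolic"`, `"filter"`,
#'   `"enrich"`, `"keynodes"`, `"bowtie"`, `"all"`.
#' @param config a [sim_config()] describing the synthetic inputs.
#' @param combine which condition set drives the filtering: `"union"`
#'   (default), `"intersection"` or `"symmetric_difference"`.
#' @param detection_threshold minimum tag count for presence.
#' @param modes enrichment modes to run (see [enrich_all()]).
#' @param min_overlap,T,lambda enrichment parameters.
#' @param dis_pairs Dis pair convention (see [dis_index()]).
#' @param pseudocount log fold-change pseudocount.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(out_dir,
                         stage = c("all", "simulate", "build-metabolic",
                                   "filter", "enrich", "keynodes", "bowtie"),
                         config = sim_config(),
                         combine = c("union", "intersection",
                                     "symmetric_difference"),
                         detection_threshold = 1,
                         modes = c("strict_exact", "extended_mc", "central"),
                         min_overlap = 2, T = 10000, lambda = 0.5,
                         dis_pairs = "mediator", pseudocount = 0.5) {
  stage <- match.arg(stage)
  combine <- match.arg(combine)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all")
    c("simulate", "build-metabolic", "filter", "enrich", "keynodes",
      "bowtie") else stage
  need_stage <- function(s, files) {
    paths <- file.path(out_dir, s, files)
    if (!all(file.exists(paths)))
      stop(sprintf("stage '%s' requires outputs of stage '%s'; run it first",
                   stage, s))
    paths
  }
  tsv <- function(d, s, f) {
    dir.create(file.path(out_dir, s), showWarnings = FALSE)
    utils::write.table(d, file.path(out_dir, s, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- function(s, extra = list()) {
    dir.create(file.path(out_dir, s), showWarnings = FALSE)
    jsonlite::write_json(
      c(list(stage = s, seed = config$seed,
             package_version = as.character(utils::packageVersion("pknfilter")),
             config = unclass(config)), extra),
      file.path(out_dir, s, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }

  for (s in stages) {
    dir.create(file.path(out_dir, s), showWarnings = FALSE)
    if (s == "simulate") {
      sdir <- file.path(out_dir, "simulate")
      dir.create(sdir, showWarnings = FALSE)
      ref <- simulate_reference(config)
      pw <- simulate_pathways(ref, config)
      ex <- simulate_expression(ref, pw, config)
      rt <- simulate_reactions(config)
      write_network(ref, file.path(sdir, "reference.sif"), "sif")
      write_gmt(pw, file.path(sdir, "pathways.gmt"))
      for (cond in c("normal", "disease")) {
        cnt <- ex[[cond]]$counts
        tsv(data.frame(source_id = names(cnt), count = as.numeric(cnt)),
            "simulate", paste0(cond, ".tsv"))
      }
      tsv(as.data.frame(ex$idmap), "simulate", "idmap.tsv")
      tsv(data.frame(spot_id = rownames(ex$tissue), ex$tissue,
                     check.names = FALSE), "simulate", "tissue.tsv")
      write_reaction_table(rt, file.path(sdir, "reactions.tsv"))
      manifest("simulate")
    } else if (s == "build-metabolic") {
      p <- need_stage("simulate", "reactions.tsv")
      net <- build_enzyme_network(read_reaction_table(p))
      write_network(net, file.path(out_dir, "build-metabolic",
                                   "metabolic.sif"), "sif")
      manifest("build-metabolic",
               list(n_enzymes = length(net$vertices),
                    n_edges = n_edges(net)))
    } else if (s == "filter") {
      p <- need_stage("simulate", c("reference.sif", "normal.tsv",
                                    "disease.tsv", "idmap.tsv"))
      ref <- read_network(p[1], "sif")
      idmap <- read_idmap(p[4])
      det_n <- map_detection(read_expression(p[2], "normal"), idmap, ref,
                             detection_threshold)
      det_d <- map_detection(read_expression(p[3], "disease"), idmap, ref,
                             detection_threshold)
      sets <- combine_conditions(det_n, det_d)
      det <- sets[[combine]]
      strict <- strict_filter(ref, det)
      ext <- extended_filter(ref, det, 1)
      write_detection(det, file.path(out_dir, "filter", "detected.tsv"))
      write_network(strict, file.path(out_dir, "filter", "strict.sif"),
                    "sif")
      write_network(ext, file.path(out_dir, "filter", "extended.sif"),
                    "sif")
      counts <- data.frame(
        network = c("reference", "strict", "extended"),
        vertices = c(length(ref$vertices), length(strict$vertices),
                     length(ext$vertices)),
        edges = c(n_edges(ref), n_edges(strict), n_edges(ext)),
        wcc = c(weak_components(ref)$n, weak_components(strict)$n,
                weak_components(ext)$n))
      tsv(counts, "filter", "network_sizes.tsv")
      manifest("filter",
               list(combine = combine,
                    detected = length(det$detected),
                    unmapped = det_n$n_unmapped + det_d$n_unmapped))
    } else if (s == "enrich") {
      ps <- need_stage("simulate", c("reference.sif", "pathways.gmt",
                                     "tissue.tsv", "idmap.tsv"))
      pf <- need_stage("filter", "detected.tsv")
      ref <- read_network(ps[1], "sif")
      pw <- read_gmt(ps[2])
      tm <- read_tissue_matrix(ps[3])
      idmap <- read_idmap(ps[4])
      det <- utils::read.delim(pf, stringsAsFactors = FALSE)$vertex
      w <- compute_weights(tm, idmap, ref$vertices)
      for (m in modes) {
        res <- enrich_all(ref, det, pw, w, mode = m,
                          min_overlap = min_overlap, T = T,
                          seed = config$seed, lambda = lambda)
        tsv(res, "enrich", paste0(m, ".tsv"))
      }
      manifest("enrich", list(modes = modes, min_overlap = min_overlap,
                              T = T, lambda = lambda))
    } else if (s == "keynodes") {
      ps <- need_stage("simulate", "reference.sif")
      pf <- need_stage("filter", "strict.sif")
      ref <- remove_orphans(read_network(ps, "sif"))
      strict <- remove_orphans(read_network(pf, "sif"))
      dis_ref <- dis_index(ref, pairs = dis_pairs)
      dis_strict <- dis_index(strict, pairs = dis_pairs)
      inc <- dis_increase(dis_strict, dis_ref)
      tsv(as.data.frame(dis_ref), "keynodes", "dis_reference.tsv")
      tsv(as.data.frame(dis_strict), "keynodes", "dis_strict.tsv")
      tsv(inc, "keynodes", "dis_increase.tsv")
      manifest("keynodes", list(pairs = dis_pairs))
    } else if (s == "bowtie") {
      ps <- need_stage("simulate", c("normal.tsv", "disease.tsv",
                                     "idmap.tsv"))
      pf <- need_stage("filter", "strict.sif")
      strict <- remove_orphans(read_network(pf, "sif"))
      idmap <- read_idmap(ps[3])
      bt <- bowtie_decompose(strict)
      de <- log_fold_change(read_expression(ps[1], "normal"),
                            read_expression(ps[2], "disease"),
                            idmap, c = pseudocount)
      # variance analysis uses vertices observed in both conditions: genes
      # switched fully on/off are categorical events whose pseudocount
      # ratios would swamp the compartment variances
      de <- de[de$vertex %in% strict$vertices & de$normal_cpm > 0 &
                 de$disease_cpm > 0, , drop = FALSE]
      # small or fragmented networks may lack two compartments with >= 2
      # members; record an empty table rather than abort the run
      rep_ <- tryCatch(compartment_variance_report(bt, de),
                       error = function(e) {
                         list(table = data.frame(compartment = character(),
                                                 n = integer(),
                                                 mean_lfc = numeric(),
                                                 var_lfc = numeric()),
                              levene = list(W = NA_real_, p = NA_real_,
                                            degenerate = TRUE))
                       })
      tsv(data.frame(vertex = names(bt$compartment),
                     compartment = bt$compartment,
                     stringsAsFactors = FALSE), "bowtie", "compartments.tsv")
      tsv(merge(de, data.frame(vertex = names(bt$compartment),
                               compartment = bt$compartment), by = "vertex"),
          "bowtie", "lfc_by_compartment.tsv")
      tsv(rep_$table, "bowtie", "variance_table.tsv")
      manifest("bowtie", list(levene_W = rep_$levene$W,
                              levene_p = rep_$levene$p,
                              sizes = as.list(bt$sizes)))
    }
  }
  invisible(out_dir)
}
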