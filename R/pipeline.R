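#' Default pipeline configuration
#'
#' All thresholds and options of the five analysis stages, overridable via
#' a YAML/JSON file ([read_pipeline_config()]) or by editing the returned
#' list.
#'
#' @return nested list: `thresholds` (progeny test), `linkage`
#'   (`flanks`: two flanking locus names), `haplotype` (`max_exceptions`,
#'   `break_run`), `synteny` (`gap_unit_bp`, `score_min`, `emax`,
#'   `max_hits`), `seed`.
#' @export
pipeline_config <- function() {
  list(thresholds = default_thresholds(),
       linkage = list(flanks = NULL, distance_method = "morgan"),
       haplotype = list(max_exceptions = 1, break_run = 1),
       synteny = list(gap_unit_bp = 10000, score_min = 300,
                      emax = 1e-5, max_hits = 4),
       project = list(marker_distal = NULL, marker_proximal = NULL),
       seed = 1L)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values in the file override the [pipeline_config()] defaults.
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(pipeline_config(), user)
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the fine-mapping pipeline end to end
#'
#' Executes, in order: recombinant screening and map-distance estimation
#' (needs a genotype table and two flanking loci), progeny-test genotype
#' calling (needs F3 families), cosegregation clustering and trait
#' placement (needs both), haplotype-block delineation (needs a haplotype
#' matrix), and synteny chaining / interval projection (needs an anchor
#' table / boundary markers).  Any stage whose inputs are absent is
#' skipped and noted in the manifest.  Per-stage record counts (plants
#' read, excluded, recombinants, clusters, blocks) are logged to stderr.
#'
#' @param config list as from [pipeline_config()] / [read_pipeline_config()].
#' @param inputs named list of file paths: `genotype`, `families` (summary
#'   TSV) or `heights` (per-plant TSV), `haplotype`, `anchors`,
#'   `annotation` (optional).
#' @param output_dir directory for stage outputs and the run manifest.
#' @param quiet suppress stderr logging.
#' @return the run manifest (list), invisibly; outputs are written under
#'   `output_dir` and the manifest to `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = list(),
                         output_dir = tempfile("pmfinemap_run_"),
                         quiet = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(tool = "pmfinemap",
                   version = as.character(utils::packageVersion("pmfinemap")),
                   seed = config$seed,
                   config = config,
                   inputs = lapply(inputs[!vapply(inputs, is.null,
                                                  logical(1))],
                                   function(p)
                                     list(path = p,
                                          md5 = unname(tools::md5sum(p)))),
                   stages = list())
  note <- function(stage, status, counts = list())
    manifest$stages[[stage]] <<- c(list(status = status), counts)
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  geno <- NULL; informative <- NULL
  if (!is.null(inputs$genotype) && !is.null(config$linkage$flanks)) {
    tryCatch({
      geno <- read_genotype_table(inputs$genotype)
      fl <- config$linkage$flanks
      informative <- find_recombinants(geno, fl[1], fl[2])
      md <- map_distance(sum(informative$n_rec_chromosomes),
                         attr(informative, "n_scored"),
                         method = config$linkage$distance_method)
      write_tsv(informative, file.path(output_dir, "informative_plants.tsv"))
      write_tsv(data.frame(recombinant_chromosomes =
                             sum(informative$n_rec_chromosomes),
                           n_plants = attr(informative, "n_scored"),
                           d_cM = md$d_cM, se_cM = md$se_cM),
                file.path(output_dir, "map_distance.tsv"))
      stage_log(quiet,
                "map: %d plants read, %d excluded (missing calls), %d informative, %.2f cM",
                nrow(geno$calls), length(attr(informative, "excluded_na")),
                nrow(informative), md$d_cM)
      note("map", "ok", list(plants = nrow(geno$calls),
                             excluded = length(attr(informative,
                                                    "excluded_na")),
                             informative = nrow(informative),
                             d_cM = md$d_cM))
    }, error = function(e) fail("map", e))
  } else note("map", "skipped (no genotype table / flanks)")

  trait_calls <- NULL
  if (!is.null(inputs$families) || !is.null(inputs$heights)) {
    tryCatch({
      fams <- if (!is.null(inputs$families))
        read_f3_families(inputs$families) else
          read_f3_heights(inputs$heights)
      res <- classify_population(fams, config$thresholds)
      trait_calls <- res$calls
      write_tsv(res$calls, file.path(output_dir, "trait_calls.tsv"))
      write_tsv(data.frame(call = names(res$tally), n = as.integer(res$tally)),
                file.path(output_dir, "trait_call_tally.tsv"))
      stage_log(quiet, "call-genotypes: %d families -> %s",
                length(fams),
                paste(names(res$tally), res$tally, sep = "=",
                      collapse = ", "))
      note("call_genotypes", "ok",
           list(families = length(fams), tally = as.list(res$tally)))
    }, error = function(e) fail("call_genotypes", e))
  } else note("call_genotypes", "skipped (no family data)")

  if (!is.null(geno) && nrow(informative) > 0) {
    tryCatch({
      inf_tab <- subset_plants(geno, informative$plant_id)
      cl <- cluster_markers(inf_tab)
      cl_df <- do.call(rbind, lapply(seq_along(cl$clusters), function(i)
        data.frame(cluster = i,
                   map_position = match(i, cl$order),
                   loci = paste(cl$clusters[[i]]$loci, collapse = ","),
                   stringsAsFactors = FALSE)))
      write_tsv(cl_df, file.path(output_dir, "marker_clusters.tsv"))
      counts <- list(clusters = length(cl$clusters))
      if (!is.null(trait_calls)) {
        pl <- tryCatch(place_trait(cl, trait_calls), error = function(e) NULL)
        if (!is.null(pl)) {
          flags <- flag_double_recombinants(cl, trait_calls)
          write_tsv(data.frame(cluster = seq_along(pl$distances),
                               rec_events = pl$distances,
                               best = seq_along(pl$distances) %in%
                                 pl$best_cluster),
                    file.path(output_dir, "trait_placement.tsv"))
          write_tsv(flags, file.path(output_dir, "double_recombinants.tsv"))
          counts$trait_cosegregates <- pl$cosegregating
          counts$double_recombinant_flags <- nrow(flags)
        }
      }
      stage_log(quiet, "cluster: %d marker cluster(s)", length(cl$clusters))
      note("cluster", "ok", counts)
    }, error = function(e) fail("cluster", e))
  } else note("cluster", "skipped (no informative genotype data)")

  if (!is.null(inputs$haplotype)) {
    tryCatch({
      hm <- read_haplotype_matrix(inputs$haplotype)
      bl <- delineate_block(hm, config$haplotype$max_exceptions,
                            config$haplotype$break_run)
      write_tsv(bl$verdicts, file.path(output_dir, "locus_verdicts.tsv"))
      write_tsv(data.frame(
        block_loci = paste(bl$block_loci, collapse = ","),
        distal_boundary = bl$distal_boundary,
        proximal_boundary = bl$proximal_boundary),
        file.path(output_dir, "haplotype_block.tsv"))
      stage_log(quiet, "haploscan: block of %d loci, boundaries %s / %s",
                length(bl$block_loci), bl$distal_boundary,
                bl$proximal_boundary)
      note("haploscan", "ok",
           list(block_size = length(bl$block_loci),
                distal_boundary = bl$distal_boundary,
                proximal_boundary = bl$proximal_boundary))
    }, error = function(e) fail("haploscan", e))
  } else note("haploscan", "skipped (no haplotype matrix)")

  if (!is.null(inputs$anchors)) {
    tryCatch({
      raw <- read_anchor_table(inputs$anchors)
      flt <- filter_anchors(raw, config$synteny$emax, config$synteny$max_hits)
      bl <- chain_blocks(flt, config$synteny$gap_unit_bp,
                         config$synteny$score_min)
      write_tsv(bl$blocks, file.path(output_dir, "synteny_blocks.tsv"))
      write_tsv(dotplot_data(bl), file.path(output_dir, "dotplot.tsv"))
      if (nrow(bl$blocks)) {
        rr <- detect_rearrangements(bl)
        write_tsv(rr, file.path(output_dir, "rearrangements.tsv"))
      }
      stage_log(quiet, "synteny: %d anchors -> %d block(s)",
                nrow(flt), nrow(bl$blocks))
      note("synteny", "ok", list(anchors_in = nrow(raw),
                                 anchors_kept = nrow(flt),
                                 blocks = nrow(bl$blocks)))
    }, error = function(e) fail("synteny", e))
  } else note("synteny", "skipped (no anchor table)")

  if (!is.null(config$project$marker_distal) &&
      !is.null(config$project$marker_proximal)) {
    tryCatch({
      ci <- project_interval(config$project$marker_distal,
                             config$project$marker_proximal,
                             annotation = inputs$annotation)
      write_bed(ci, file.path(output_dir, "candidate_interval.bed"))
      if (!is.null(ci$genes))
        write_tsv(ci$genes, file.path(output_dir, "interval_genes.tsv"))
      stage_log(quiet, "project: %s:%.0f-%.0f (%.0f kb), %s gene(s)",
                ci$chr, ci$start_bp, ci$end_bp, ci$length_bp / 1000,
                if (is.null(ci$genes)) "NA" else nrow(ci$genes))
      note("project", "ok",
           list(chr = ci$chr, start_bp = ci$start_bp, end_bp = ci$end_bp,
                length_bp = ci$length_bp,
                n_genes = if (is.null(ci$genes)) NA else nrow(ci$genes)))
    }, error = function(e) fail("project", e))
  } else note("project", "skipped (no boundary markers)")

  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
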