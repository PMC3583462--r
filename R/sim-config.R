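#' Height model for simulated F3 families
#'
#' Plant height (cm) is drawn from a two-component Gaussian mixture: the
#' dwarf component for plants homozygous for the recessive dwarfing allele,
#' the tall component otherwise.  A family-level and a batch-level random
#' effect (both Gaussian, shared by all plants of a family / batch) are
#' added on top of the component draw, mimicking glasshouse batches grown
#' at different times.
#'
#' Component defaults (dwarf 75 +/- 15, tall 165 +/- 25 cm) keep the dwarf
#' upper tail above the 110 cm scoring threshold below 2%, the property the
#' original screen relied on when choosing that threshold.  The random
#' effect defaults (3 and 2 cm) are deliberately small so that a family of
#' 13 homozygous-dwarf plants has a median below 90 cm with probability
#' > 0.99; real tall families show a much wider median spread, driven by
#' other segregating height genes that this generator does not model.
#'
#' @param mu_dwarf,sd_dwarf dwarf component mean and sd, cm.
#' @param mu_tall,sd_tall tall component mean and sd, cm.
#' @param family_effect_sd sd of the per-family shared effect, cm.
#' @param batch_effect_sd sd of the per-batch shared effect, cm.
#' @param n_batches number of glasshouse batches to spread families over.
#' @return an object of class `height_model` (named list).
#' @export
height_model <- function(mu_dwarf = 75, sd_dwarf = 15,
                         mu_tall = 165, sd_tall = 25,
                         family_effect_sd = 3, batch_effect_sd = 2,
                         n_batches = 3) {
  stopifnot(sd_dwarf > 0, sd_tall > 0, family_effect_sd >= 0,
            batch_effect_sd >= 0, n_batches >= 1,
            mu_dwarf < mu_tall)
  structure(list(mu_dwarf = mu_dwarf, sd_dwarf = sd_dwarf,
                 mu_tall = mu_tall, sd_tall = sd_tall,
                 family_effect_sd = family_effect_sd,
                 batch_effect_sd = batch_effect_sd,
                 n_batches = as.integer(n_batches)),
            class = "height_model")
}

#' Configuration for a simulated F2 mapping population
#'
#' @param n_f2 number of F2 plants.
#' @param marker_map data.frame with columns `locus` and `pos_cM`
#'   (non-decreasing positions) describing the ordered marker loci.
#' @param trait_locus_position cM position of the recessive trait locus;
#'   must lie within the span of the marker map (use `Inf` for an unlinked
#'   trait).
#' @param dominant_loci character vector naming loci scored dominantly.
#' @param f3_family_size_range integer length-2, min and max F3 family
#'   size; the screen's families ranged over 13--25 plants.
#' @param height_model a [height_model()].
#' @param missing_rate fraction of marker calls replaced by NA, in [0, 1).
#' @param map_function `"haldane"` (default) or `"kosambi"`-free `"morgan"`
#'   (r = d/100 truncated at 0.5); the Haldane function matches the
#'   no-interference crossover model used by the simulator.
#' @param seed integer seed recorded in the config; simulation functions
#'   set it before drawing.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_f2 = 915,
                       marker_map = data.frame(
                         locus = c("FLANK_L", "FLANK_R"),
                         pos_cM = c(0, 1.6)),
                       trait_locus_position = 0.8,
                       dominant_loci = character(),
                       f3_family_size_range = c(13L, 25L),
                       height_model = pmfinemap::height_model(),
                       missing_rate = 0,
                       map_function = c("haldane", "morgan"),
                       seed = 1L) {
  map_function <- match.arg(map_function)
  if (nrow(marker_map) < 1) stop("marker map must contain at least one locus")
  stopifnot(is.data.frame(marker_map),
            all(c("locus", "pos_cM") %in% names(marker_map)))
  if (is.unsorted(marker_map$pos_cM))
    stop("marker map positions must be non-decreasing")
  if (any(diff(marker_map$pos_cM) < 0)) stop("inter-locus distances must be >= 0")
  if (!all(dominant_loci %in% marker_map$locus))
    stop("dominant_loci must name loci of the marker map")
  span <- range(marker_map$pos_cM)
  if (is.finite(trait_locus_position) &&
      (trait_locus_position < span[1] - 1e-9 ||
       trait_locus_position > span[2] + 1e-9) && nrow(marker_map) > 1)
    warning("trait locus lies outside the marker span")
  stopifnot(length(f3_family_size_range) == 2,
            f3_family_size_range[1] >= 1,
            f3_family_size_range[1] <= f3_family_size_range[2])
  stopifnot(missing_rate >= 0, missing_rate < 1)
  stopifnot(inherits(height_model, "height_model"))
  structure(list(n_f2 = as.integer(n_f2), marker_map = marker_map,
                 trait_locus_position = trait_locus_position,
                 dominant_loci = dominant_loci,
                 f3_family_size_range = as.integer(f3_family_size_range),
                 height_model = height_model,
                 missing_rate = missing_rate,
                 map_function = map_function,
                 seed = as.integer(seed)),
            class = "sim_config")
}

map_r <- function(d_cM, map_function = "haldane") {
  switch(map_function,
         haldane = haldane_r(d_cM),
         morgan = pmin(d_cM / 100, 0.5),
         stop("unknown map function: ", map_function))
}
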