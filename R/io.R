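read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stop(what, " file does not exist: ", path)
  if (file.size(path) == 0) stop(what, " file is empty: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE,
                    comment.char = "")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a marker genotype table from TSV
#'
#' Format: a header line `plant_id<TAB>locus1<TAB>...`, a second line
#' `#mode<TAB>codominant|dominant...` declaring each locus' scoring mode,
#' then one row per plant with calls in `{AA, AB, BB, A-, NA}`.  Calls are
#' validated against the declared modes (e.g. `AB` at a dominant locus is
#' rejected with its cell location) and duplicate plant ids are rejected.
#'
#' @param path TSV file path.
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty genotype table: ", path)
  if (length(lines) < 2 || !startsWith(lines[2], "#mode"))
    stop("genotype table must declare locus modes on a '#mode' line: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  modes <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  loci <- header[-1]
  if (length(modes) != length(loci))
    stop("mode line length does not match locus count")
  if (length(lines) < 3) stop("genotype table has no plant rows: ", path)
  body <- do.call(rbind, strsplit(lines[-(1:2)], "\t", fixed = TRUE))
  if (ncol(body) != length(header))
    stop("ragged genotype table: ", path)
  calls <- body[, -1, drop = FALSE]
  calls[calls == "NA" | calls == ""] <- NA_character_
  colnames(calls) <- loci
  tryCatch(genotype_table(calls, modes, plant_id = body[, 1]),
           error = function(e) stop("invalid genotype table ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write a genotype table as TSV (round-trips through
#' [read_genotype_table()])
#' @param table a [genotype_table()].
#' @param path output path.
#' @export
write_genotype_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("plant_id", table$loci$locus), collapse = "\t"), con)
  writeLines(paste(c("#mode", table$loci$mode), collapse = "\t"), con)
  body <- apply(cbind(table$plant_id, table$calls), 1, function(r)
    paste(ifelse(is.na(r), "NA", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read F3 families from per-plant heights or published summaries
#'
#' `read_f3_heights` expects columns `f2_id, plant_id, batch, height_cm`;
#' `read_f3_families` expects the summarised format `f2_id, batch, n,
#' median_cm, mean_cm, sd_cm, n_below_110` (the form in which the
#' published family table ships as a fixture).
#'
#' @param path TSV file path.
#' @return list of [f3_family()] objects, one per (f2_id, batch).
#' @export
read_f3_heights <- function(path) {
  df <- read_tsv_checked(path, "F3 heights")
  need <- c("f2_id", "plant_id", "batch", "height_cm")
  if (!all(need %in% names(df)))
    stop("F3 height table needs columns: ", paste(need, collapse = ", "))
  keys <- unique(df[c("f2_id", "batch")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$f2_id == keys$f2_id[i] & df$batch == keys$batch[i], ]
    f3_family(keys$f2_id[i], heights = sub$height_cm,
              batch = keys$batch[i])
  })
}

#' @rdname read_f3_heights
#' @export
read_f3_families <- function(path) {
  df <- read_tsv_checked(path, "F3 family summary")
  need <- c("f2_id", "batch", "n", "median_cm", "n_below_110")
  if (!all(need %in% names(df)))
    stop("family summary table needs columns: ",
         paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    f3_family(df$f2_id[i], batch = df$batch[i], n = df$n[i],
              median_cm = df$median_cm[i],
              mean_cm = if ("mean_cm" %in% names(df)) df$mean_cm[i]
                        else NA_real_,
              sd_cm = if ("sd_cm" %in% names(df)) df$sd_cm[i] else NA_real_,
              n_below_110 = df$n_below_110[i]))
}

#' Read a haplotype allele matrix from TSV
#'
#' Expected columns: `line_id`, `class` (`tall`/`dwarf`), then one column
#' per locus in map order; `"ND"` marks missing calls.
#'
#' @param path TSV file path.
#' @return a [haplotype_matrix()].
#' @export
read_haplotype_matrix <- function(path) {
  df <- read_tsv_checked(path, "haplotype matrix")
  if (!all(c("line_id", "class") %in% names(df)))
    stop("haplotype matrix needs 'line_id' and 'class' columns")
  loci <- setdiff(names(df), c("line_id", "class"))
  haplotype_matrix(as.matrix(df[loci]), class = df$class,
                   line_id = df$line_id)
}

#' Read / write homologous gene-pair anchor tables
#'
#' Tab-separated columns: `gene_a, chr_a, pos_a, gene_b, chr_b, pos_b,
#' evalue`.
#' @param path TSV file path.
#' @param anchors anchor data.frame.
#' @return data.frame (reader) / path invisibly (writer).
#' @export
read_anchor_table <- function(path) {
  df <- read_tsv_checked(path, "anchor")
  req <- c("gene_a", "chr_a", "pos_a", "gene_b", "chr_b", "pos_b", "evalue")
  if (!all(req %in% names(df)))
    stop("anchor table needs columns: ", paste(req, collapse = ", "))
  df
}

#' @rdname read_anchor_table
#' @export
write_anchor_table <- function(anchors, path) write_tsv(anchors, path)

#' Read a gene annotation as a positional table
#'
#' Accepts a 3+-column TSV (`gene, chr, pos` or `gene, chr, start, end`,
#' in which case `pos` is the start) or a GFF3 file (`.gff`/`.gff3`,
#' gene features; requires the rtracklayer package).  Coordinates are
#' 1-based inclusive internally.
#'
#' @param path annotation file path.
#' @return data.frame with columns `gene`, `chr`, `pos`.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package; ",
           "supply a positional TSV instead")
    gr <- as.data.frame(rtracklayer::import(path))
    gr <- gr[gr$type == "gene", , drop = FALSE]
    ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
    return(data.frame(gene = as.character(ids),
                      chr = as.character(gr$seqnames),
                      pos = gr$start, stringsAsFactors = FALSE))
  }
  df <- read_tsv_checked(path, "annotation")
  if (all(c("gene", "chr", "pos") %in% names(df)))
    return(df[c("gene", "chr", "pos")])
  if (all(c("gene", "chr", "start") %in% names(df)))
    return(data.frame(gene = df$gene, chr = df$chr, pos = df$start,
                      stringsAsFactors = FALSE))
  stop("annotation needs columns gene, chr, pos (or start)")
}

#' Export a candidate interval as BED
#'
#' BED uses 0-based half-open coordinates; the internal representation is
#' 1-based inclusive, so `start_bp - 1` is written.
#'
#' @param interval a [project_interval()] result.
#' @param path output path.
#' @export
write_bed <- function(interval, path) {
  stopifnot(inherits(interval, "candidate_interval"))
  df <- data.frame(chrom = interval$chr,
                   chromStart = format(max(interval$start_bp - 1, 0),
                                       scientific = FALSE),
                   chromEnd = format(interval$end_bp, scientific = FALSE),
                   name = paste(interval$markers, collapse = "--"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
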